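#' Z-scored temporal profiles
#'
#' Averages replicates within each time point and z-scores each gene across
#' time points. Genes with (numerically) constant profiles get an all-zero
#' profile and a `constant` flag.
#'
#' @param norm Log2 normalized matrix.
#' @param samples Sample sheet.
#' @return List with `z` (genes x time points), `times`, `constant` (logical
#'   per gene).
#' @export
z_profiles <- function(norm, samples) {
  times <- sort(unique(samples$time_h))
  prof <- vapply(times, function(tp) {
    rowMeans(norm[, samples$time_h == tp, drop = FALSE])
  }, numeric(nrow(norm)))
  colnames(prof) <- paste0("T", times)
  m <- rowMeans(prof)
  s <- apply(prof, 1, stats::sd)
  constant <- s < 1e-10
  z <- (prof - m) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  list(z = z, times = times, constant = constant)
}

#' Hierarchical clustering of temporal profiles
#'
#' Average-linkage agglomeration on either Pearson correlation distance
#' (`1 - r`) or Euclidean distance between z-scored profiles, cut into `k`
#' clusters. Constant-profile genes are set aside in a sentinel cluster 0
#' with a warning. Assignments are invariant to gene input order: leaves are
#' ordered by gene id before clustering.
#'
#' @param profiles Result of [z_profiles()] (or a list with `z`, `constant`).
#' @param metric `"pearson"` or `"euclidean"`.
#' @param k Number of clusters.
#' @return List with `cluster` (named integer vector; 0 = constant profile),
#'   `tree` (hclust), `metric`, `k`, and `centroids` (k x time matrix of mean
#'   z profiles).
#' @export
hierarchical_cluster <- function(profiles, metric = c("pearson", "euclidean"),
                                 k = 4) {
  metric <- match.arg(metric)
  z <- profiles$z
  constant <- profiles$constant
  if (any(constant)) {
    warning(sum(constant), " constant-profile gene(s) assigned to cluster 0")
  }
  zz <- z[!constant, , drop = FALSE]
  zz <- zz[order(rownames(zz)), , drop = FALSE]
  if (nrow(zz) < k) stop("fewer non-constant genes than clusters")
  d <- if (metric == "pearson") stats::as.dist(1 - stats::cor(t(zz))) else
    stats::dist(zz)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, k = k)
  cluster <- stats::setNames(integer(nrow(z)), rownames(z))
  cluster[names(cl)] <- cl
  centroids <- t(vapply(seq_len(k), function(i) {
    colMeans(zz[cl == i, , drop = FALSE])
  }, numeric(ncol(z))))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  list(cluster = cluster, tree = tree, metric = metric, k = k,
       centroids = centroids)
}

## Simple autocorrelation estimate over one or more segments (replicates):
## lag products are taken within segments only, centered and normalized by
## the pooled variance, so no artificial cross-replicate transitions enter.
acf_segments <- function(segments, n_lags) {
  all_x <- unlist(segments)
  mu <- mean(all_x)
  denom <- sum((all_x - mu)^2)
  if (denom < 1e-24) stop("zero-variance series")
  vapply(seq_len(n_lags), function(k) {
    num <- sum(vapply(segments, function(s) {
      n <- length(s)
      if (n <= k) return(0)
      sum((s[seq_len(n - k)] - mu) * (s[(k + 1):n] - mu))
    }, numeric(1)))
    num / denom
  }, numeric(1))
}

#' Autocorrelation-based dissimilarity between two series
#'
#' Euclidean distance between the first `n_lags` estimated simple
#' autocorrelation coefficients of the two series (uniform lag weights).
#' Each series may be a numeric vector or a list of replicate segments, in
#' which case lagged products never cross segment boundaries.
#'
#' @param x,y Numeric vectors or lists of numeric vectors.
#' @param n_lags Number of autocorrelation lags (default 10).
#' @return Non-negative distance; zero iff the estimated ACFs coincide.
#' @export
acf_distance <- function(x, y, n_lags = 10) {
  as_segments <- function(s) if (is.list(s)) s else list(s)
  xs <- as_segments(x); ys <- as_segments(y)
  if (min(lengths(xs)) <= n_lags + 1 || min(lengths(ys)) <= n_lags + 1) {
    stop("series segments must be longer than n_lags + 1")
  }
  sqrt(sum((acf_segments(xs, n_lags) - acf_segments(ys, n_lags))^2))
}

#' Autocorrelation-distance similarity network and clusters
#'
#' Computes all pairwise [acf_distance()]s on the per-replicate series of
#' each gene, keeps the top `edge_percentile` percent most similar (smallest
#' distance) pairs as edges, and reports connected components as clusters.
#'
#' @param norm Log2 normalized matrix (a subset of interesting genes).
#' @param samples Sample sheet.
#' @param n_lags Autocorrelation lags.
#' @param edge_percentile Percentage (0-100] of pairs kept as edges.
#' @return List with `edges` (data.frame `gene1`, `gene2`, `distance`),
#'   `components` (named membership vector over genes with >= 1 edge), and
#'   `distance` (full symmetric matrix).
#' @export
acf_cluster_network <- function(norm, samples, n_lags = 10,
                                edge_percentile = 1) {
  if (nrow(norm) < 10) stop("need at least 10 genes")
  reps <- sort(unique(samples$replicate))
  ord <- order(samples$time_h)
  series <- lapply(seq_len(nrow(norm)), function(g) {
    lapply(reps, function(r) {
      cols <- ord[samples$replicate[ord] == r]
      norm[g, cols]
    })
  })
  acfs <- t(vapply(series, acf_segments, numeric(n_lags), n_lags = n_lags))
  D <- as.matrix(stats::dist(acfs))
  dimnames(D) <- list(rownames(norm), rownames(norm))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  dvals <- D[pairs]
  n_keep <- max(1L, floor(length(dvals) * edge_percentile / 100))
  if (edge_percentile <= 0 || n_keep < 1) {
    stop("edge percentile retains zero edges; increase it")
  }
  keep <- order(dvals)[seq_len(n_keep)]
  edges <- data.frame(gene1 = rownames(D)[pairs[keep, 1]],
                      gene2 = rownames(D)[pairs[keep, 2]],
                      distance = dvals[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  comp <- igraph::components(g)$membership
  list(edges = edges, components = comp, distance = D)
}
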