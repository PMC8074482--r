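#' Per-timepoint differential expression against the baseline
#'
#' For every post-baseline time point at or below `horizon_h`, tests each
#' gene's mean log2 expression at that time against the 0 h baseline with a
#' moderated t statistic. The gene-wise residual variance comes from a
#' one-way (time-point groups) fit over the full matrix, squeezed across
#' genes by [squeeze_var()] — with two replicates per group, unmoderated
#' per-contrast variances would be hopeless. BH correction is applied across
#' genes within each time point.
#'
#' @param norm Log2 normalized matrix, genes x samples.
#' @param samples Sample sheet.
#' @param horizon_h Test time points with `0 < time_h <= horizon_h`.
#' @return Long-format data.frame: `gene`, `time_h`, `lfc` (log2 fold change
#'   vs baseline), `t`, `p`, `q`; attributes `df_prior`, `df_resid`.
#' @export
pairwise_de <- function(norm, samples, horizon_h = 48) {
  t0 <- samples$time_h == 0
  if (!any(t0)) stop("no baseline (0 h) samples present")
  groups <- factor(samples$time_h)
  G <- nrow(norm)
  ## pooled within-group residual variance over all time points
  group_means <- t(apply(norm, 1, function(x) tapply(x, groups, mean)))
  fitted <- group_means[, as.character(samples$time_h), drop = FALSE]
  rss <- rowSums((norm - fitted)^2)
  df_resid <- ncol(norm) - nlevels(groups)
  if (df_resid <= 0) stop("no residual degrees of freedom for variance pooling")
  sq <- squeeze_var(rss / df_resid, df_resid)
  df_total <- df_resid + min(sq$df_prior, 1e6)
  n0 <- sum(t0)
  base_mean <- rowMeans(norm[, t0, drop = FALSE])
  times <- sort(unique(samples$time_h[samples$time_h > 0 &
                                        samples$time_h <= horizon_h]))
  res <- lapply(times, function(tp) {
    cols <- samples$time_h == tp
    lfc <- rowMeans(norm[, cols, drop = FALSE]) - base_mean
    se <- sqrt(sq$var_post * (1 / sum(cols) + 1 / n0))
    tstat <- lfc / se
    p <- 2 * stats::pt(abs(tstat), df_total, lower.tail = FALSE)
    data.frame(gene = rownames(norm), time_h = tp, lfc = lfc, t = tstat,
               p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "df_resid") <- df_resid
  out
}

#' Tiered gene selection from per-timepoint results
#'
#' Three nested tiers: `A` (FDR < 0.05 and |log2FC| >= 1 at one or more time
#' points), `B` (FDR < 0.05 and |log2FC| >= 2 at one or more time points),
#' and `CORE` (FDR < 0.01 and |log2FC| > 2 at two or more time points). The
#' fold-change inequality is strict only for `CORE`, matching the tier
#' definitions' differing phrasings.
#'
#' @param results Long-format table from [pairwise_de()].
#' @return List of gene-id vectors `A`, `B`, `CORE` with `CORE ⊆ B ⊆ A`.
#' @export
select_tiered <- function(results) {
  count_hits <- function(q_max, lfc_min, strict) {
    hit <- results$q < q_max &
      (if (strict) abs(results$lfc) > lfc_min else abs(results$lfc) >= lfc_min)
    table(factor(results$gene[hit], levels = unique(results$gene)))
  }
  if (nrow(results) == 0) return(list(A = character(), B = character(),
                                      CORE = character()))
  a <- count_hits(0.05, 1, strict = FALSE)
  b <- count_hits(0.05, 2, strict = FALSE)
  core <- count_hits(0.01, 2, strict = TRUE)
  list(A = names(a)[a >= 1], B = names(b)[b >= 1],
       CORE = names(core)[core >= 2])
}

#' Predominant and master gene sets
#'
#' The predominant set unions the spline-detected genes with tier B of the
#' pairwise analysis. The master set (the input universe for lead-lag network
#' inference) keeps predominant genes that have a functional annotation and
#' an estimated |log2FC| of at least 2 at some tested time point.
#'
#' @param spline_sets Result of [select_time_dependent()].
#' @param tier_sets Result of [select_tiered()].
#' @param results Long-format table from [pairwise_de()] (for fold changes).
#' @param annotation data.frame with a `gene_id` column listing annotated
#'   genes.
#' @return List with `predominant` and `master` gene-id vectors.
#' @export
build_union_sets <- function(spline_sets, tier_sets, results, annotation) {
  predominant <- union(spline_sets$union, tier_sets$B)
  max_lfc <- tapply(abs(results$lfc), results$gene, max)
  big <- names(max_lfc)[max_lfc >= 2]
  master <- intersect(predominant, intersect(annotation$gene_id, big))
  list(predominant = predominant, master = master)
}
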