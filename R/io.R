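#' Write a counts (or normalized) matrix as TSV
#'
#' Genes in rows, samples in columns, with a leading `gene_id` column.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix written by [write_counts_tsv()]
#'
#' @param path TSV path with a `gene_id` first column.
#' @return Numeric matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") stop("expected a leading `gene_id` column")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  storage.mode(mat) <- "double"
  mat
}

#' Validate a counts matrix against a sample sheet
#'
#' Checks that every sample-sheet row has a matching matrix column (and vice
#' versa), that times parse as numbers, that counts are numeric and
#' non-negative, and that no sample id is duplicated.
#'
#' @param counts_path Path to a counts TSV (or a matrix).
#' @param samples_path Path to a sample sheet TSV with columns `sample_id`,
#'   `time_h`, `replicate` (or a data.frame).
#' @return List with `counts` (matrix, columns ordered as the sheet) and
#'   `samples` (data.frame).
#' @export
validate_inputs <- function(counts_path, samples_path) {
  counts <- if (is.matrix(counts_path)) counts_path else {
    df <- utils::read.delim(counts_path, check.names = FALSE,
                            stringsAsFactors = FALSE, colClasses = NA)
    if (colnames(df)[1] != "gene_id") stop("expected a leading `gene_id` column")
    m <- df[, -1, drop = FALSE]
    for (j in seq_along(m)) {
      v <- suppressWarnings(as.numeric(m[[j]]))
      if (anyNA(v) && !anyNA(m[[j]])) {
        bad <- which(is.na(v) & !is.na(m[[j]]))[1]
        stop(sprintf("non-numeric count at row %d, column `%s`",
                     bad, colnames(m)[j]))
      }
      m[[j]] <- v
    }
    m <- as.matrix(m)
    rownames(m) <- df$gene_id
    m
  }
  samples <- if (is.data.frame(samples_path)) samples_path else
    utils::read.delim(samples_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "replicate")
  if (!all(need %in% colnames(samples))) {
    stop("sample sheet must have columns: ", toString(need))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample id(s): ",
         toString(unique(samples$sample_id[duplicated(samples$sample_id)])))
  }
  samples$time_h <- suppressWarnings(as.numeric(samples$time_h))
  if (anyNA(samples$time_h)) stop("unparseable `time_h` in sample sheet")
  missing_in_matrix <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_in_matrix)) {
    stop("sample(s) in sheet missing from matrix: ",
         toString(missing_in_matrix))
  }
  extra <- setdiff(colnames(counts), samples$sample_id)
  if (length(extra)) {
    stop("matrix column(s) missing from sheet: ", toString(extra))
  }
  if (any(counts < 0)) stop("negative counts in matrix")
  list(counts = counts[, samples$sample_id, drop = FALSE], samples = samples)
}

grid_from_samples <- function(samples) {
  times <- sort(unique(samples$time_h))
  reps <- max(samples$replicate)
  time_grid(times, reps)
}
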