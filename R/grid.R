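#' Sampling times of the reference experimental design
#'
#' The design samples a baseline at 0 h and 20 post-stimulation time points,
#' dense over the first day and sparser out to five days.
#'
#' @return Numeric vector of 21 sampling times in hours.
#' @export
study_times <- function() {
  c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 20, 24, 30, 36, 42, 48, 72, 96, 120)
}

#' Construct a time grid
#'
#' A time grid records the ordered sampling times (hours) and the number of
#' replicates per time point. Sample identifiers follow the `T<hours>_R<rep>`
#' convention throughout the package.
#'
#' @param times Strictly increasing numeric vector of sampling times in hours;
#'   the first must be 0 (baseline).
#' @param replicates Integer count of replicates per time point (>= 1).
#' @return An object of class `chronoseq_grid` with elements `times`,
#'   `replicates`, and `samples` (the sample sheet as a data.frame with columns
#'   `sample_id`, `time_h`, `replicate`).
#' @export
time_grid <- function(times = study_times(), replicates = 2) {
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with at least two values")
  }
  if (times[1] != 0) stop("the first time must be 0 (baseline)")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1) stop("`replicates` must be >= 1")
  samples <- data.frame(
    sample_id = paste0("T", rep(times, each = replicates), "_R",
                       rep(seq_len(replicates), length(times))),
    time_h = rep(times, each = replicates),
    replicate = rep(seq_len(replicates), length(times)),
    stringsAsFactors = FALSE
  )
  structure(list(times = times, replicates = replicates, samples = samples),
            class = "chronoseq_grid")
}

#' @export
print.chronoseq_grid <- function(x, ...) {
  cat("chronoseq time grid: ", length(x$times), " time points (",
      x$times[1], "-", x$times[length(x$times)], " h), ",
      x$replicates, " replicate(s)\n", sep = "")
  invisible(x)
}

n_samples <- function(grid) length(grid$times) * grid$replicates

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "chronoseq_grid")) stop("expected a `chronoseq_grid`")
  invisible(grid)
}

#' Restrict a grid to times at or below a horizon
#'
#' @param grid A `chronoseq_grid`.
#' @param horizon_h Keep times `<= horizon_h`.
#' @return A new `chronoseq_grid`.
#' @export
restrict_grid <- function(grid, horizon_h) {
  stopifnot_grid(grid)
  time_grid(grid$times[grid$times <= horizon_h], grid$replicates)
}
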