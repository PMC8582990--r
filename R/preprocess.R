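#' Shift well coordinates to a new origin
#'
#' Re-centers planar coordinates so downstream interpolators work with
#' numbers of modest magnitude (e.g. a survey's approximate centroid as
#' the new origin). Concentrations are untouched.
#'
#' @param wells A wells data frame (`well_id, x, y, conc_ugL, censored`).
#' @param origin Numeric `c(x, y)` of the new origin in the input
#'   coordinate system.
#' @return The wells with `x - origin[1]`, `y - origin[2]`.
#' @export
recenter_wells <- function(wells, origin) {
  stopifnot(length(origin) == 2L, is.numeric(origin))
  wells$x <- wells$x - origin[1L]
  wells$y <- wells$y - origin[2L]
  wells
}

#' Log10 transform of concentrations
#'
#' @param conc Positive concentrations (ug/L).
#' @return `log10(conc)`; invertible by `10^(.)`.
#' @export
log_transform <- function(conc) {
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all concentrations must be finite and > 0 for the log transform")
  log10(conc)
}

#' Normality test p-value
#'
#' Tests a sample against normality with estimated mean and variance.
#' The default is the Lilliefors-corrected Kolmogorov-Smirnov test
#' ([nortest::lillie.test()]), appropriate when the null parameters are
#' estimated from the data; Shapiro-Wilk is available for smaller samples.
#'
#' @param values Numeric sample, `n >= 20`, non-constant.
#' @param method `"lilliefors"` (default) or `"shapiro"`.
#' @return The p-value in \\[0, 1\\].
#' @export
normality_pvalue <- function(values, method = c("lilliefors", "shapiro")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 20L) stop("need at least 20 observations")
  if (stats::sd(values) == 0) stop("constant input: normality is undefined")
  switch(method,
    lilliefors = nortest::lillie.test(values)$p.value,
    shapiro = stats::shapiro.test(values)$p.value)
}

#' Concentration-ordered round-robin split
#'
#' Sorts wells by descending concentration (ties broken by `well_id` for
#' determinism) and deals them round-robin into `k` sets labelled A, B,
#' C, ... This yields sets whose sizes differ by at most one and whose
#' concentration distributions are near-identical — the balanced design
#' needed for cross-validation where a random split of heavily skewed
#' data could concentrate the extreme wells in one fold.
#'
#' @param wells A wells data frame.
#' @param k Number of sets (default 3).
#' @return A `split_assignment` data frame with columns `well_id` and
#'   `set` (factor with levels `LETTERS[1:k]`), one row per well, in the
#'   original well order.
#' @export
ordered_split <- function(wells, k = 3L) {
  n <- nrow(wells)
  if (n < k) stop("need at least k wells")
  ord <- order(-wells$conc_ugL, wells$well_id)
  lab <- character(n)
  lab[ord] <- LETTERS[((seq_len(n) - 1L) %% k) + 1L]
  out <- data.frame(well_id = wells$well_id,
                    set = factor(lab, levels = LETTERS[seq_len(k)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Read and write split assignments as CSV
#'
#' @param split A [ordered_split()] result.
#' @param path File path; columns `well_id,set`.
#' @export
write_split <- function(split, path) {
  utils::write.csv(as.data.frame(split)[, c("well_id", "set")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well_id", "set") %in% names(x)))
    stop("split file must have columns well_id,set")
  x$set <- factor(x$set, levels = sort(unique(x$set)))
  class(x) <- c("split_assignment", "data.frame")
  x
}
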