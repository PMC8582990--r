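#' Coefficient of determination
#'
#' `R^2 = 1 - SSE / SStot` with the total sum of squares taken about the
#' observed mean — the predictive-validation definition, which can be
#' negative for predictors worse than the mean (unlike squared Pearson
#' correlation).
#'
#' @param observed Numeric, `n >= 2`, non-constant.
#' @param predicted Numeric of the same length.
#' @return R^2, at most 1.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("constant observed values: R^2 is undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Root mean square error
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1L) stop("need at least 1 observation")
  sqrt(mean((observed - predicted)^2))
}

#' Cross-validated comparison of ordinary kriging and the BPNN
#'
#' For each held-out set of the concentration-ordered split, both
#' interpolators are built on the two remaining sets and evaluated on the
#' held-out wells: an empirical semivariogram is computed and fitted on
#' the training wells for ordinary kriging, and the network is trained
#' with [lm_train()] (best of `restarts` initializations). Metrics (R^2
#' and RMSE) are computed on log10-transformed concentrations — the scale
#' on which both predictors operate.
#'
#' @param wells A wells data frame.
#' @param split A [ordered_split()] assignment covering every well.
#' @param variogram_kind Model kind for the kriging fold fits.
#' @param net_spec A [network_spec()] (default `(2,10,10,1)`).
#' @param config A [train_config()] for network training.
#' @param restarts Network restarts per fold (default 3).
#' @param seed Master seed for network initializations.
#' @param methods Character subset of `c("ok", "bpnn")`.
#' @param variogram_args Optional list passed to
#'   [empirical_semivariogram()] (`bin_width`, `max_lag`, `min_pairs`).
#' @return A `cv_report` data frame with columns
#'   `method, fold, r2, rmse`, including `fold = "average"` rows; folds
#'   that fail for a method are recorded as NA and excluded from the
#'   average.
#' @export
cross_validate <- function(wells, split,
                           variogram_kind = "exponential",
                           net_spec = network_spec(c(2, 10, 10, 1)),
                           config = train_config(),
                           restarts = 3L, seed = 1L,
                           methods = c("ok", "bpnn"),
                           variogram_args = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  sets <- split$set[match(wells$well_id, split$well_id)]
  if (anyNA(sets)) stop("split does not cover every well")
  z <- log_transform(wells$conc_ugL)
  xy <- cbind(wells$x, wells$y)
  folds <- levels(droplevels(sets))
  rows <- list()
  for (m in methods) {
    for (fi in seq_along(folds)) {
      held <- folds[fi]
      tr <- sets != held
      met <- tryCatch({
        pred <- if (m == "ok") {
          emp <- do.call(empirical_semivariogram,
                         c(list(xy[tr, , drop = FALSE], z[tr]),
                           variogram_args))
          vg <- fit_variogram_model(emp, kind = variogram_kind)
          ok_predict_many(xy[tr, , drop = FALSE], z[tr],
                          xy[!tr, , drop = FALSE], vg)$estimate
        } else {
          fit <- train_restarts(net_spec, xy[tr, , drop = FALSE], z[tr],
                                config, restarts,
                                master_seed = derive_seed(seed, fi))
          predict(fit, xy[!tr, , drop = FALSE])
        }
        c(r_squared(z[!tr], pred), rmse(z[!tr], pred))
      }, error = function(e) {
        warning(sprintf("fold %s failed for %s: %s", held, m,
                        conditionMessage(e)))
        c(NA_real_, NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, fold = held, r2 = met[1L], rmse = met[2L],
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  for (m in methods) {
    sub <- rep[rep$method == m, ]
    rep <- rbind(rep, data.frame(
      method = m, fold = "average",
      r2 = mean(sub$r2, na.rm = TRUE),
      rmse = mean(sub$rmse, na.rm = TRUE),
      stringsAsFactors = FALSE))
  }
  rownames(rep) <- NULL
  class(rep) <- c("cv_report", "data.frame")
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report (log10 scale)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Average validation metrics per method from a CV report
#'
#' @param report A [cross_validate()] result.
#' @return Data frame `method, r2, rmse` (the `fold = "average"` rows).
#' @export
cv_averages <- function(report) {
  out <- report[report$fold == "average", c("method", "r2", "rmse")]
  rownames(out) <- NULL
  as.data.frame(out)
}
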