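#' Ordinary kriging prediction at one target location
#'
#' Solves the ordinary kriging system
#' \deqn{\begin{bmatrix}\Gamma & 1\\ 1^T & 0\end{bmatrix}
#'       \begin{bmatrix}\lambda\\ \mu\end{bmatrix} =
#'       \begin{bmatrix}\gamma_0\\ 1\end{bmatrix}}
#' where `Gamma[i,j] = gamma(|x_i - x_j|)` between samples and
#' `gamma_0[i] = gamma(|x_i - x_0|)` to the target, under the unbiasedness
#' constraint `sum(lambda) = 1`. The estimate is `sum(lambda * z)` and the
#' kriging variance `sum(lambda * gamma_0) + mu` (tiny negatives from
#' round-off are clipped to zero). With the `gamma(0) = 0` convention the
#' predictor is exact at sampled locations.
#'
#' All samples enter the system (global neighborhood). Samples sharing
#' coordinates are averaged into one with a warning, since exact
#' duplicates make the system singular.
#'
#' @param coords Two-column matrix/data frame of sample coordinates (m).
#' @param values Sample values (typically log10 concentration).
#' @param target Numeric `c(x, y)` of the prediction location.
#' @param model A [variogram_model()].
#' @return A list of class `kriging_result`: `estimate`, `weights`,
#'   `lagrange_multiplier`, `kriging_variance`.
#' @export
ok_predict <- function(coords, values, target, model) {
  res <- ok_predict_many(coords, values, matrix(target, nrow = 1L), model)
  structure(list(estimate = res$estimate[1L],
                 weights = res$weights[, 1L],
                 lagrange_multiplier = res$lagrange_multiplier[1L],
                 kriging_variance = res$kriging_variance[1L]),
            class = "kriging_result")
}

#' Ordinary kriging at many targets with one factorization
#'
#' Same system as [ok_predict()]; the left-hand side depends only on the
#' samples, so it is factorized once and reused for every target.
#'
#' @inheritParams ok_predict
#' @param targets Two-column matrix/data frame of prediction locations.
#' @return List with `estimate` (length m), `weights` (n x m matrix),
#'   `lagrange_multiplier`, `kriging_variance`.
#' @export
ok_predict_many <- function(coords, values, targets, model) {
  stopifnot(inherits(model, "variogram_model"))
  xy <- as.matrix(coords)
  z <- as.numeric(values)
  if (nrow(xy) < 1L) stop("need at least one sample")
  stopifnot(length(z) == nrow(xy))
  tg <- as.matrix(targets)
  if (ncol(tg) != 2L) stop("targets must have two columns")

  dup <- duplicated(xy)
  if (any(dup)) {
    warning(sprintf("%d duplicate sample location(s) averaged", sum(dup)))
    key <- paste(xy[, 1L], xy[, 2L])
    uk <- unique(key)  # first-appearance order
    z <- vapply(uk, function(k) mean(z[key == k]), numeric(1), USE.NAMES = FALSE)
    xy <- xy[!dup, , drop = FALSE]
  }
  n <- nrow(xy)

  G <- model_gamma(model, as.matrix(stats::dist(xy)))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  # cross-distances target x sample
  d0 <- sqrt(outer(tg[, 1L], xy[, 1L], "-")^2 +
             outer(tg[, 2L], xy[, 2L], "-")^2)
  B <- rbind(t(model_gamma(model, d0)), 1)

  sol <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(sol)) {
    A2 <- A
    diag(A2)[seq_len(n)] <- diag(A2)[seq_len(n)] + 1e-12
    sol <- tryCatch(solve(A2, B), error = function(e)
      stop(paste0("singular kriging system after regularization: ",
                  "check for duplicate or collinear sample locations"),
           call. = FALSE))
  }
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  est <- drop(crossprod(w, z))
  kv <- colSums(w * B[seq_len(n), , drop = FALSE]) + mu
  kv[kv < 0 & kv > -1e-8] <- 0
  kv <- pmax(kv, 0)
  list(estimate = est, weights = w, lagrange_multiplier = mu,
       kriging_variance = kv)
}

#' @export
print.kriging_result <- function(x, ...) {
  cat(sprintf("OK estimate %.6g (kriging variance %.6g, %d weights, sum %.6f)\n",
              x$estimate, x$kriging_variance, length(x$weights),
              sum(x$weights)))
  invisible(x)
}

#' Ordinary kriging over a grid
#'
#' Predicts at every cell center of `grid` from log10-transformed well
#' concentrations and back-transforms to ug/L by `10^(.)` for the
#' concentration layer; the log-scale layer and the kriging variance are
#' retained.
#'
#' @param wells A wells data frame.
#' @param grid A [grid_spec()].
#' @param model A [variogram_model()] fitted to the log10 concentrations.
#' @return A `concentration_grid`: list with the `grid` and matrix layers
#'   `log10_est`, `conc_ugL`, `kriging_variance` (rows top-down, as
#'   stored in ASCII grids).
#' @export
ok_map <- function(wells, grid, model) {
  stopifnot(inherits(grid, "grid_spec"))
  centers <- grid_centers(grid)
  res <- ok_predict_many(cbind(wells$x, wells$y),
                         log_transform(wells$conc_ugL),
                         cbind(centers$x, centers$y), model)
  shape <- function(v) matrix(v, nrow = grid$nrows, ncol = grid$ncols,
                              byrow = TRUE)
  structure(list(grid = grid,
                 layers = list(log10_est = shape(res$estimate),
                               conc_ugL = shape(10^res$estimate),
                               kriging_variance = shape(res$kriging_variance)),
                 method = "ok"),
            class = "concentration_grid")
}
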