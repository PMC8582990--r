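#' Theoretical semivariogram model
#'
#' Container for the three classical isotropic models. The semivariance at
#' separation `h` is `gamma(h) = c0 + c * g(h/a)` with
#' \describe{
#'   \item{spherical}{`g(u) = 1.5*u - 0.5*u^3` for `u <= 1`, else 1}
#'   \item{exponential}{`g(u) = 1 - exp(-3*u)`}
#'   \item{gaussian}{`g(u) = 1 - exp(-(3*u)^2)`}
#' }
#' so that the model reaches (spherical) or effectively reaches (the other
#' two, at ~95%) the sill `c0 + c` at the range `a`. By convention
#' `gamma(0) = 0`: the nugget `c0` applies only for `h > 0`, which makes
#' ordinary kriging an exact interpolator at sampled locations.
#'
#' @param kind One of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget Nugget variance `c0 >= 0`.
#' @param psill Partial sill `c > 0`; total sill is `c0 + c`.
#' @param range Range `a > 0` in meters.
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(kind = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range) {
  kind <- match.arg(kind)
  nugget <- as.numeric(nugget); psill <- as.numeric(psill)
  range <- as.numeric(range)
  if (!is.finite(nugget) || nugget < 0) stop("nugget must be finite and >= 0")
  if (!is.finite(psill) || psill <= 0) stop("psill must be finite and > 0")
  if (!is.finite(range) || range <= 0) stop("range must be finite and > 0")
  structure(list(kind = kind, nugget = nugget, psill = psill, range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram model: nugget c0 = %g, partial sill c = %g, range a = %g m (sill %g)\n",
              x$kind, x$nugget, x$psill, x$range, x$nugget + x$psill))
  invisible(x)
}

#' Evaluate a semivariogram model
#'
#' @param model A [variogram_model()].
#' @param h Non-negative separation distances (m); vector or matrix.
#' @return Semivariances with the shape of `h`; `gamma(0) = 0` exactly.
#' @export
model_gamma <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) stop("separation distance h must be >= 0")
  u <- h / model$range
  g <- switch(model$kind,
    spherical   = ifelse(u <= 1, 1.5 * u - 0.5 * u^3, 1),
    exponential = 1 - exp(-3 * u),
    gaussian    = 1 - exp(-(3 * u)^2))
  out <- model$nugget + model$psill * g
  out[h == 0] <- 0
  out
}

#' Empirical semivariogram by distance binning
#'
#' Computes the classical method-of-moments estimator
#' `gamma_hat(h) = (1 / (2 N(h))) * sum (z_i - z_j)^2` over every unordered
#' pair whose separation falls in the bin around `h`. Pairs at zero
#' separation (duplicate locations) belong to the nugget, not a bin, and
#' are excluded. Bins with fewer than `min_pairs` pairs are dropped.
#'
#' @param coords Two-column matrix/data frame of planar coordinates (m).
#' @param values Numeric values at the coordinates (typically log10
#'   concentration).
#' @param bin_width Bin width (m); default `max_lag / 15`.
#' @param max_lag Largest separation considered (m); default half the
#'   maximum pairwise distance.
#' @param min_pairs Minimum pair count per reported bin (default 30).
#' @return An object of class `empirical_variogram`: a data frame with
#'   columns `lag` (mean pair distance in the bin, strictly increasing),
#'   `gamma` (semivariance estimate) and `np` (pair count).
#' @export
empirical_semivariogram <- function(coords, values, bin_width = NULL,
                                    max_lag = NULL, min_pairs = 30L) {
  xy <- as.matrix(coords)
  values <- as.numeric(values)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 locations")
  stopifnot(length(values) == n)
  d <- as.numeric(stats::dist(xy))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (is.null(bin_width)) bin_width <- max_lag / 15
  if (bin_width <= 0) stop("bin_width must be > 0")
  dz2 <- as.numeric(stats::dist(values))^2
  keep <- d > 0 & d <= max_lag
  if (!any(keep))
    stop("no location pairs within max_lag; increase max_lag")
  d <- d[keep]; dz2 <- dz2[keep]
  bin <- pmin(ceiling(d / bin_width), ceiling(max_lag / bin_width))
  np <- tapply(dz2, bin, length)
  gamma <- tapply(dz2, bin, sum) / (2 * np)
  lag <- tapply(d, bin, mean)
  out <- data.frame(lag = as.numeric(lag), gamma = as.numeric(gamma),
                    np = as.integer(np))
  out <- out[out$np >= min_pairs, , drop = FALSE]
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Fit a semivariogram model to an empirical semivariogram
#'
#' Weighted least squares with pair counts `N(h)` as weights, parameters
#' bounded to `c0 >= 0`, `c > 0`, `a > 0`. The optimizer is a bounded
#' trust-region Levenberg-Marquardt least-squares fit
#' ([minpack.lm::nlsLM()]) launched from five starting ranges spread
#' log-uniformly over the lag span (the range/nugget surface is multimodal);
#' the best weighted SSE wins. If every start fails, a bounded
#' quasi-Newton fallback is tried before erroring with the best parameters
#' seen so far.
#'
#' A flat empirical variogram (all `gamma` equal) makes the range
#' unidentifiable; the fit then returns that constant as the sill with
#' attribute `range_identifiable = FALSE`.
#'
#' @param emp An [empirical_semivariogram()] result (>= 4 usable bins).
#' @param kind Model kind to fit.
#' @param n_starts Number of multistart range values (default 5).
#' @return A [variogram_model()] with attributes `sse` (weighted SSE) and
#'   `range_identifiable`.
#' @export
fit_variogram_model <- function(emp,
                                kind = c("exponential", "spherical",
                                         "gaussian"),
                                n_starts = 5L) {
  kind <- match.arg(kind)
  stopifnot(inherits(emp, "empirical_variogram") || is.data.frame(emp))
  if (nrow(emp) < 4L) stop("need at least 4 usable bins to fit")
  lag <- emp$lag; gam <- emp$gamma; np <- as.numeric(emp$np)
  w <- np / mean(np)  # scale-free weights: fit invariant to common factors

  if (diff(range(gam)) <= 1e-12 * max(abs(gam), 1)) {
    m <- variogram_model(kind, nugget = 0, psill = max(gam[1L], 1e-12),
                         range = max(lag))
    attr(m, "sse") <- 0
    attr(m, "range_identifiable") <- FALSE
    return(m)
  }

  wsse <- function(c0, c, a) {
    m <- variogram_model(kind, max(c0, 0), max(c, 1e-12), max(a, 1e-9))
    sum(w * (model_gamma(m, lag) - gam)^2)
  }

  a_starts <- exp(seq(log(min(lag)), log(2 * max(lag)),
                      length.out = n_starts))
  c0_start <- max(min(gam) / 2, 0)
  c_start <- max(max(gam) - c0_start, 1e-6)
  lower <- c(c0 = 0, c = 1e-10, a = min(lag) / 100)
  upper <- c(c0 = max(gam) * 2, c = max(gam) * 4, a = max(lag) * 20)

  best <- NULL
  best_sse <- Inf
  for (a0 in a_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        gam ~ model_gamma(variogram_model(kind, c0, c, a), lag),
        start = list(c0 = c0_start, c = c_start, a = a0),
        lower = lower, upper = upper, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      s <- wsse(p[["c0"]], p[["c"]], p[["a"]])
      if (s < best_sse) { best <- p; best_sse <- s }
    }
  }
  if (is.null(best)) {
    # quasi-Newton fallback on the same bounded WLS objective
    for (a0 in a_starts) {
      fit <- tryCatch(
        stats::optim(c(c0 = c0_start, c = c_start, a = a0),
                     function(p) wsse(p[1L], p[2L], p[3L]),
                     method = "L-BFGS-B", lower = lower, upper = upper),
        error = function(e) NULL)
      if (!is.null(fit) && fit$value < best_sse) {
        best <- fit$par; best_sse <- fit$value
      }
    }
  }
  if (is.null(best))
    stop(sprintf(paste0("variogram fit did not converge from any start ",
                        "(kind=%s, starts c0=%g c=%g a in [%g, %g])"),
                 kind, c0_start, c_start, min(a_starts), max(a_starts)))
  m <- variogram_model(kind, nugget = max(best[["c0"]], 0),
                       psill = max(best[["c"]], 1e-12),
                       range = best[["a"]])
  attr(m, "sse") <- best_sse
  attr(m, "range_identifiable") <- TRUE
  m
}

#' Serialize / deserialize a variogram model as JSON
#'
#' @param model A [variogram_model()].
#' @param path File path.
#' @return `read_variogram_json()` returns a [variogram_model()].
#' @export
write_variogram_json <- function(model, path) {
  stopifnot(inherits(model, "variogram_model"))
  jsonlite::write_json(
    list(kind = model$kind, nugget = model$nugget, psill = model$psill,
         range = model$range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_variogram_json
#' @export
read_variogram_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variogram_model(x$kind, x$nugget, x$psill, x$range)
}
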