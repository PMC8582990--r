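#' Feed-forward network architecture
#'
#' Describes a coordinate-to-concentration regressor: 2 inputs (x, y),
#' one or two hidden layers of hyperbolic-tangent sigmoid neurons, and a
#' single linear ("pureline") output neuron. Each neuron computes
#' `net_j = sum_i X_i * W_ji - b_j` (note the bias is *subtracted*) and
#' emits `f(net_j)`.
#'
#' @param layer_sizes Integer vector, e.g. `c(2, 10, 10, 1)`: input size
#'   must be 2, output size 1, with 1 or 2 hidden layers.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(layer_sizes) {
  layer_sizes <- as.integer(layer_sizes)
  nl <- length(layer_sizes)
  if (nl < 3L || nl > 4L)
    stop("layer_sizes must describe input, 1-2 hidden layers, and output")
  if (layer_sizes[1L] != 2L) stop("input layer size must be 2 (x, y)")
  if (layer_sizes[nl] != 1L) stop("output layer size must be 1")
  if (any(layer_sizes[-c(1L, nl)] < 1L)) stop("hidden sizes must be >= 1")
  structure(list(layer_sizes = layer_sizes,
                 hidden_activation = "tansig",
                 output_activation = "pureline"),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("BPNN structure (%s): tansig hidden, pureline output\n",
              paste(x$layer_sizes, collapse = ",")))
  invisible(x)
}

#' Candidate architectures over even hidden sizes
#'
#' Enumerates `(2, h1, 1)` and `(2, h1, h2, 1)` structures over even
#' hidden sizes, the conventional grid for this class of coordinate
#' regressors.
#'
#' @param h1 Even first-hidden-layer sizes (default `seq(2, 12, 2)`).
#' @param h2 Even second-hidden-layer sizes; `0` means no second layer
#'   (default `c(0, h1)` paired as `h2 = h1`).
#' @param pair_h2 If `TRUE` (default) two-layer candidates use `h2 = h1`;
#'   otherwise the full `h1 x h2` cross is produced.
#' @return List of [network_spec()] objects.
#' @export
candidate_specs <- function(h1 = seq(2L, 12L, 2L), h2 = h1,
                            pair_h2 = TRUE) {
  stopifnot(all(h1 %% 2 == 0), all(h1 >= 2), all(h1 <= 50))
  out <- lapply(h1, function(h) network_spec(c(2L, h, 1L)))
  if (length(h2) && any(h2 > 0)) {
    h2 <- h2[h2 > 0]
    stopifnot(all(h2 %% 2 == 0), all(h2 <= 50))
    if (pair_h2) {
      two <- lapply(intersect(h1, h2),
                    function(h) network_spec(c(2L, h, h, 1L)))
    } else {
      two <- unlist(lapply(h1, function(a) lapply(h2, function(b)
        network_spec(c(2L, a, b, 1L)))), recursive = FALSE)
    }
    out <- c(out, two)
  }
  out
}

#' Levenberg-Marquardt training configuration
#'
#' @param mse_goal Stop when training mean squared error falls to or
#'   below this (default `1e-2`).
#' @param max_epochs Maximum accepted-iteration count (default 1000).
#' @param lambda_init Initial LM damping (default `1e-3`).
#' @param lambda_factor Multiplicative damping update, > 1 (default 10).
#' @param lambda_max Damping beyond which the search is declared stalled
#'   (default `1e10`).
#' @param seed Seed for the uniform \\[-1, 1\\] weight/bias initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(mse_goal = 1e-2, max_epochs = 1000L,
                         lambda_init = 1e-3, lambda_factor = 10,
                         lambda_max = 1e10, seed = 1L) {
  if (mse_goal <= 0) stop("mse_goal must be > 0")
  if (lambda_factor <= 1) stop("lambda_factor must be > 1")
  structure(list(mse_goal = mse_goal, max_epochs = as.integer(max_epochs),
                 lambda_init = lambda_init, lambda_factor = lambda_factor,
                 lambda_max = lambda_max, seed = as.integer(seed)),
            class = "train_config")
}

#' Random initial parameters for a network
#'
#' Weights and biases i.i.d. uniform in \\[-1, 1\\].
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return A list of per-layer `W` (out x in matrices) and `b` vectors.
#' @export
init_network <- function(spec, seed = 1L) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  sz <- spec$layer_sizes
  lapply(seq_len(length(sz) - 1L), function(l) {
    list(W = matrix(stats::runif(sz[l + 1L] * sz[l], -1, 1),
                    nrow = sz[l + 1L], ncol = sz[l]),
         b = stats::runif(sz[l + 1L], -1, 1))
  })
}

# Forward pass for all samples at once. X: n x 2 (already scaled).
# Returns list(yhat, acts) where acts[[l]] is the n x size activation of
# layer l (acts[[1]] = X).
nn_forward_full <- function(params, X) {
  L <- length(params)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  A <- X
  for (l in seq_len(L)) {
    net <- A %*% t(params[[l]]$W) -
      matrix(params[[l]]$b, nrow(A), length(params[[l]]$b), byrow = TRUE)
    A <- if (l < L) tanh(net) else net  # pureline output
    acts[[l + 1L]] <- A
  }
  list(yhat = drop(A), acts = acts)
}

#' Evaluate a network on (scaled) inputs
#'
#' Computes `net_j = sum_i X_i W_ji - b_j` through tanh-sigmoid hidden
#' layers and a linear output neuron.
#'
#' @param params Per-layer parameter list as from [init_network()].
#' @param X An `n x 2` matrix of inputs.
#' @return Numeric vector of n predictions.
#' @export
nn_forward <- function(params, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != ncol(params[[1L]]$W))
    stop(sprintf("input has %d columns; network expects %d",
                 ncol(X), ncol(params[[1L]]$W)))
  nn_forward_full(params, X)$yhat
}

# Parameter packing order: for each layer, W by column-major, then b.
pack_params <- function(params) {
  unlist(lapply(params, function(p) c(as.numeric(p$W), p$b)),
         use.names = FALSE)
}

unpack_params <- function(theta, spec) {
  sz <- spec$layer_sizes
  out <- vector("list", length(sz) - 1L)
  pos <- 0L
  for (l in seq_len(length(sz) - 1L)) {
    nw <- sz[l + 1L] * sz[l]
    out[[l]] <- list(W = matrix(theta[pos + seq_len(nw)], nrow = sz[l + 1L]),
                     b = theta[pos + nw + seq_len(sz[l + 1L])])
    pos <- pos + nw + sz[l + 1L]
  }
  out
}

#' Jacobian of network outputs with respect to all parameters
#'
#' Analytic backpropagation, vectorized over samples: row i holds
#' `d yhat_i / d theta` in the packing order of [pack_params()] (per
#' layer: weights column-major, then biases). Because each neuron
#' subtracts its bias, bias columns carry a factor of -1.
#'
#' @param params Per-layer parameter list.
#' @param X An `n x 2` matrix of (scaled) inputs.
#' @return An `n x p` matrix.
#' @export
nn_jacobian <- function(params, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  L <- length(params)
  fw <- nn_forward_full(params, X)
  acts <- fw$acts
  # delta[[l]]: n x size(l) sensitivity d yhat / d net_l
  delta <- vector("list", L)
  delta[[L]] <- matrix(1, n, 1L)  # linear output
  if (L > 1L) {
    for (l in seq(L - 1L, 1L)) {
      delta[[l]] <- (delta[[l + 1L]] %*% params[[l + 1L]]$W) *
        (1 - acts[[l + 1L]]^2)
    }
  }
  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    n_out <- nrow(params[[l]]$W); n_in <- ncol(params[[l]]$W)
    # dW[j, i] column-major: column index (i-1)*n_out + j
    JW <- matrix(0, n, n_out * n_in)
    for (i in seq_len(n_in)) {
      JW[, (i - 1L) * n_out + seq_len(n_out)] <-
        delta[[l]] * acts[[l]][, i]
    }
    blocks[[l]] <- cbind(JW, -delta[[l]])
  }
  do.call(cbind, blocks)
}

#' Train a network with the Levenberg-Marquardt algorithm
#'
#' Full-batch damped Gauss-Newton on the residuals `e = y - yhat`:
#' each iteration solves `(J'J + lambda I) step = J'e` with the analytic
#' Jacobian, accepts the step when the sum of squared errors decreases
#' (dividing `lambda` by `lambda_factor`) and otherwise multiplies
#' `lambda` and retries — interpolating between Gauss-Newton (small
#' `lambda`) and gradient descent (large `lambda`). Training stops when
#' the mean squared error reaches `mse_goal`, after `max_epochs` accepted
#' iterations, or when `lambda` exceeds `lambda_max` without an
#' improving step (a stationary point; `status = "stalled"`).
#'
#' Coordinates are centered on the training midrange and divided by the
#' half-extent per axis before entering the network, so tanh units see
#' O(1) inputs regardless of the coordinate units; the scaling constants
#' are stored in the model and applied transparently by
#' [predict.bpnn_model()]. Targets (log10 concentration) are used
#' unscaled so `mse_goal` is in log10^2 units.
#'
#' @param spec A [network_spec()].
#' @param coords `n x 2` matrix of raw coordinates (m), `n >= 10`.
#' @param targets Numeric targets (log10 concentration).
#' @param config A [train_config()].
#' @return An object of class `bpnn_model`: `spec`, `params`, `center`,
#'   `half_extent`, `history` (data frame of accepted epochs: `epoch`,
#'   `mse`, `lambda`), `status` (`"converged"`, `"max_epochs"`,
#'   `"stalled"`), `final_mse`. Bit-reproducible given `config$seed`.
#' @export
lm_train <- function(spec, coords, targets, config = train_config()) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  X_raw <- as.matrix(coords)
  y <- as.numeric(targets)
  if (nrow(X_raw) < 10L) stop("need at least 10 training points")
  if (any(!is.finite(X_raw)) || any(!is.finite(y)))
    stop("training data must be finite")

  center <- (apply(X_raw, 2L, max) + apply(X_raw, 2L, min)) / 2
  half_extent <- pmax((apply(X_raw, 2L, max) - apply(X_raw, 2L, min)) / 2,
                      .Machine$double.eps)
  X <- sweep(sweep(X_raw, 2L, center), 2L, half_extent, "/")

  params <- init_network(spec, seed = config$seed)
  theta <- pack_params(params)
  p <- length(theta)
  n <- length(y)

  yhat <- nn_forward(params, X)
  e <- y - yhat
  sse <- sum(e^2)
  lambda <- config$lambda_init
  hist_epoch <- 0L; hist_mse <- sse / n; hist_lambda <- lambda
  status <- "max_epochs"
  epoch <- 0L

  while (epoch < config$max_epochs) {
    if (sse / n <= config$mse_goal) { status <- "converged"; break }
    J <- nn_jacobian(params, X)
    JtJ <- crossprod(J)
    g <- drop(crossprod(J, e))
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(solve(JtJ + diag(lambda, p), g),
                       error = function(err) NULL)
      if (!is.null(step)) {
        theta_new <- theta + step
        params_new <- unpack_params(theta_new, spec)
        e_new <- y - nn_forward(params_new, X)
        sse_new <- sum(e_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new; params <- params_new
          e <- e_new; sse <- sse_new
          lambda <- lambda / config$lambda_factor
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * config$lambda_factor
      if (lambda > config$lambda_max) break
    }
    if (!accepted) { status <- "stalled"; break }
    epoch <- epoch + 1L
    hist_epoch <- c(hist_epoch, epoch)
    hist_mse <- c(hist_mse, sse / n)
    hist_lambda <- c(hist_lambda, lambda)
  }
  if (status == "max_epochs" && sse / n <= config$mse_goal)
    status <- "converged"

  structure(list(spec = spec, params = params, center = center,
                 half_extent = half_extent,
                 history = data.frame(epoch = hist_epoch, mse = hist_mse,
                                      lambda = hist_lambda),
                 status = status, final_mse = sse / n,
                 config = config),
            class = "bpnn_model")
}

#' @export
print.bpnn_model <- function(x, ...) {
  cat(sprintf("BPNN (%s), %d accepted epochs, final mse %.4g [%s]\n",
              paste(x$spec$layer_sizes, collapse = ","),
              max(x$history$epoch), x$final_mse, x$status))
  invisible(x)
}

#' Predict from a trained network at raw coordinates
#'
#' @param object A [lm_train()] result.
#' @param coords `n x 2` matrix of raw coordinates (m).
#' @param ... Unused.
#' @return Numeric predictions (log10 concentration).
#' @export
predict.bpnn_model <- function(object, coords, ...) {
  X <- as.matrix(coords)
  X <- sweep(sweep(X, 2L, object$center), 2L, object$half_extent, "/")
  nn_forward(object$params, X)
}

#' Map a trained network over a grid
#'
#' @param model A `bpnn_model`.
#' @param grid A [grid_spec()].
#' @return A `concentration_grid` with layers `log10_est` and `conc_ugL`.
#' @export
bpnn_map <- function(model, grid) {
  stopifnot(inherits(model, "bpnn_model"), inherits(grid, "grid_spec"))
  centers <- grid_centers(grid)
  est <- predict(model, cbind(centers$x, centers$y))
  shape <- function(v) matrix(v, nrow = grid$nrows, ncol = grid$ncols,
                              byrow = TRUE)
  structure(list(grid = grid,
                 layers = list(log10_est = shape(est),
                               conc_ugL = shape(10^est)),
                 method = "bpnn"),
            class = "concentration_grid")
}

#' Architecture search by three-fold cross-validation
#'
#' For every candidate structure, trains on each pair of folds (with
#' `restarts` random initializations, keeping the best by training mse),
#' evaluates on the held-out fold, and reports per-fold and average
#' training/validation R^2 and RMSE. The winner has the highest average
#' validation R^2, ties broken by lowest average validation RMSE. A
#' candidate is disqualified only if training fails on every fold;
#' fold-level failures are recorded as NA.
#'
#' @param wells A wells data frame.
#' @param split A [ordered_split()] assignment with 3 sets.
#' @param candidates List of [network_spec()] (e.g. [candidate_specs()]).
#' @param restarts Random restarts per (candidate, fold) (default 3).
#' @param config Base [train_config()]; its seed is re-derived per
#'   restart from `seed`.
#' @param seed Integer master seed.
#' @return List of class `arch_search`: `report` (data frame with one row
#'   per candidate x fold plus `fold = "average"` rows; columns
#'   `structure, fold, r2_train, r2_val, rmse_train, rmse_val`), `best`
#'   (the selected [network_spec()]), `best_structure`.
#' @export
architecture_search <- function(wells, split, candidates, restarts = 3L,
                                config = train_config(), seed = 1L) {
  stopifnot(length(levels(split$set)) == 3L)
  z <- log_transform(wells$conc_ugL)
  sets <- split$set[match(wells$well_id, split$well_id)]
  rows <- list()
  summary_rows <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    sname <- paste0("(", paste(cand$layer_sizes, collapse = ","), ")")
    fold_stats <- matrix(NA_real_, 3L, 4L,
                         dimnames = list(levels(sets),
                                         c("r2_train", "r2_val",
                                           "rmse_train", "rmse_val")))
    for (fi in seq_along(levels(sets))) {
      held <- levels(sets)[fi]
      tr <- sets != held
      fit <- tryCatch(
        train_restarts(cand, cbind(wells$x, wells$y)[tr, , drop = FALSE],
                       z[tr], config, restarts,
                       master_seed = derive_seed(seed, ci * 100L + fi)),
        error = function(e) NULL)
      if (is.null(fit)) next
      pr_tr <- predict(fit, cbind(wells$x, wells$y)[tr, , drop = FALSE])
      pr_va <- predict(fit, cbind(wells$x, wells$y)[!tr, , drop = FALSE])
      fold_stats[fi, ] <- c(r_squared(z[tr], pr_tr),
                            r_squared(z[!tr], pr_va),
                            rmse(z[tr], pr_tr),
                            rmse(z[!tr], pr_va))
      rows[[length(rows) + 1L]] <-
        data.frame(structure = sname, fold = held,
                   r2_train = fold_stats[fi, 1L], r2_val = fold_stats[fi, 2L],
                   rmse_train = fold_stats[fi, 3L],
                   rmse_val = fold_stats[fi, 4L],
                   stringsAsFactors = FALSE)
    }
    if (all(is.na(fold_stats))) next  # disqualified
    summary_rows[[length(summary_rows) + 1L]] <-
      data.frame(structure = sname, fold = "average",
                 r2_train = mean(fold_stats[, 1L], na.rm = TRUE),
                 r2_val = mean(fold_stats[, 2L], na.rm = TRUE),
                 rmse_train = mean(fold_stats[, 3L], na.rm = TRUE),
                 rmse_val = mean(fold_stats[, 4L], na.rm = TRUE),
                 stringsAsFactors = FALSE)
    attr(summary_rows[[length(summary_rows)]], "spec_index") <- ci
  }
  if (!length(summary_rows)) stop("every candidate failed on every fold")
  avg <- do.call(rbind, summary_rows)
  ord <- order(-avg$r2_val, avg$rmse_val)
  best_idx <- attr(summary_rows[[ord[1L]]], "spec_index")
  report <- rbind(do.call(rbind, rows), avg)
  structure(list(report = report, best = candidates[[best_idx]],
                 best_structure = avg$structure[ord[1L]]),
            class = "arch_search")
}

# Train with several random initializations, keep best by training mse.
train_restarts <- function(spec, coords, targets, config, restarts,
                           master_seed) {
  best <- NULL
  for (r in seq_len(restarts)) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, r)
    fit <- lm_train(spec, coords, targets, cfg)
    if (is.null(best) || fit$final_mse < best$final_mse) best <- fit
  }
  best
}

# Deterministic derived seeds kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               2147483647)
}

#' @export
print.arch_search <- function(x, ...) {
  cat("Architecture search (3-fold CV)\n")
  cat(sprintf("  selected: %s\n", x$best_structure))
  avg <- x$report[x$report$fold == "average", ]
  print(avg, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize / deserialize a trained network as JSON
#'
#' Stores layer sizes, weights, biases and the input scaling constants.
#'
#' @param model A `bpnn_model`.
#' @param path File path.
#' @return `read_bpnn_json()` returns a `bpnn_model` (without training
#'   history).
#' @export
write_bpnn_json <- function(model, path) {
  stopifnot(inherits(model, "bpnn_model"))
  jsonlite::write_json(
    list(layer_sizes = model$spec$layer_sizes,
         weights = lapply(model$params, function(p) unname(as.matrix(p$W))),
         biases = lapply(model$params, function(p) unname(p$b)),
         center = unname(model$center),
         half_extent = unname(model$half_extent),
         final_mse = model$final_mse,
         status = model$status),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bpnn_json
#' @export
read_bpnn_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(x$layer_sizes)
  params <- lapply(seq_along(x$weights), function(l) {
    W <- x$weights[[l]]
    if (is.list(W)) W <- do.call(rbind, lapply(W, unlist))  # nested-list form
    if (!is.matrix(W)) W <- matrix(W, nrow = spec$layer_sizes[l + 1L],
                                   ncol = spec$layer_sizes[l], byrow = TRUE)
    storage.mode(W) <- "double"
    dimnames(W) <- NULL
    stopifnot(nrow(W) == spec$layer_sizes[l + 1L],
              ncol(W) == spec$layer_sizes[l])
    list(W = W, b = as.numeric(x$biases[[l]]))
  })
  structure(list(spec = spec, params = params,
                 center = as.numeric(x$center),
                 half_extent = as.numeric(x$half_extent),
                 history = NULL, status = x$status,
                 final_mse = x$final_mse, config = NULL),
            class = "bpnn_model")
}
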