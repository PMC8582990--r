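test_that("network specs enforce the coordinate-regressor shape", {
  expect_s3_class(network_spec(c(2, 10, 10, 1)), "network_spec")
  expect_error(network_spec(c(3, 10, 1)), "input")
  expect_error(network_spec(c(2, 10, 2)), "output")
  expect_error(network_spec(c(2, 1)), "hidden")
  specs <- candidate_specs(h1 = c(2, 4), h2 = c(2, 4))
  expect_length(specs, 4L)
})

test_that("forward pass follows the subtracted-bias neuron model", {
  # all parameters zero: output is zero
  spec <- network_spec(c(2, 3, 1))
  p0 <- init_network(spec, seed = 1)
  for (l in seq_along(p0)) { p0[[l]]$W[] <- 0; p0[[l]]$b[] <- 0 }
  expect_equal(nn_forward(p0, rbind(c(1, -1), c(5, 7))), c(0, 0))
  # single hidden neuron with zero weights: output = tanh(-beta)
  beta <- 0.8
  p1 <- list(list(W = matrix(0, 1, 2), b = beta),
             list(W = matrix(1, 1, 1), b = 0))
  expect_equal(nn_forward(p1, c(2, 3)), tanh(-beta), tolerance = 1e-14)
  # fully specified (2,2,1) net against a frozen hand computation
  p2 <- list(list(W = rbind(c(0.5, -0.3), c(0.2, 0.1)), b = c(0.1, -0.2)),
             list(W = matrix(c(0.7, -0.4), 1, 2), b = 0.25))
  expect_equal(nn_forward(p2, c(1, -1)), 0.05653239900137813,
               tolerance = 1e-14)
  expect_error(nn_forward(p2, matrix(1, 1, 3)), "columns")
})

test_that("analytic Jacobian matches finite differences", {
  for (sizes in list(c(2, 3, 1), c(2, 4, 3, 1))) {
    spec <- network_spec(sizes)
    params <- init_network(spec, seed = sum(sizes))
    X <- matrix(runif(10, -1, 1), 5, 2)
    J <- nn_jacobian(params, X)
    theta <- asriskmap:::pack_params(params)
    eps <- 1e-6
    for (k in seq_along(theta)) {
      tp <- theta; tp[k] <- tp[k] + eps
      tm <- theta; tm[k] <- tm[k] - eps
      fd <- (nn_forward(asriskmap:::unpack_params(tp, spec), X) -
             nn_forward(asriskmap:::unpack_params(tm, spec), X)) / (2 * eps)
      expect_equal(J[, k], fd, tolerance = 1e-4)
    }
  }
})

test_that("training is seed-reproducible and never accepts a worse step", {
  set.seed(41)
  X <- cbind(runif(60, -1, 1), runif(60, -1, 1))
  y <- two_bumps(X[, 1], X[, 2])
  cfg <- train_config(mse_goal = 1e-4, max_epochs = 60, seed = 5)
  f1 <- lm_train(network_spec(c(2, 6, 1)), X, y, cfg)
  f2 <- lm_train(network_spec(c(2, 6, 1)), X, y, cfg)
  expect_identical(f1$params, f2$params)
  expect_true(all(diff(f1$history$mse) <= 0))
})

test_that("large damping turns the update into a gradient step", {
  spec <- network_spec(c(2, 4, 1))
  params <- init_network(spec, seed = 3)
  set.seed(3)
  X <- matrix(runif(40, -1, 1), 20, 2)
  y <- rnorm(20)
  J <- nn_jacobian(params, X)
  e <- y - nn_forward(params, X)
  g <- drop(crossprod(J, e))
  lam <- 1e12
  step <- solve(crossprod(J) + diag(lam, length(g)), g)
  cosine <- sum(step * g) / sqrt(sum(step^2) * sum(g^2))
  expect_gt(cosine, 0.9999)
})

test_that("an infinite mse goal returns immediately with the initial state", {
  set.seed(42)
  X <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  y <- rnorm(20)
  fit <- lm_train(network_spec(c(2, 2, 1)), X, y,
                  train_config(mse_goal = Inf, max_epochs = 100, seed = 1))
  expect_equal(fit$status, "converged")
  expect_equal(nrow(fit$history), 1L)
  expect_equal(max(fit$history$epoch), 0L)
})

test_that("linear targets are learned to the mse goal by a tiny net", {
  set.seed(43)
  X <- cbind(runif(50, 0, 10000), runif(50, 0, 10000))
  y <- 3e-4 * X[, 1] - 2e-4 * X[, 2] + 0.5
  ok <- vapply(1:10, function(s) {
    fit <- lm_train(network_spec(c(2, 2, 1)), X, y,
                    train_config(mse_goal = 1e-2, max_epochs = 200,
                                 seed = s))
    fit$final_mse <= 1e-2
  }, logical(1))
  expect_gte(sum(ok), 9L)
})

test_that("a ten-neuron net fits a smooth two-bump surface", {
  set.seed(44)
  X <- cbind(runif(150, -1, 1), runif(150, -1, 1))
  y <- two_bumps(X[, 1], X[, 2])
  ok <- vapply(1:10, function(s) {
    fit <- lm_train(network_spec(c(2, 10, 1)), X, y,
                    train_config(mse_goal = 1e-2, max_epochs = 300,
                                 seed = s))
    fit$final_mse <= 1e-2
  }, logical(1))
  expect_gte(sum(ok), 8L)
})

test_that("input scaling makes training robust to meter-scale coordinates", {
  set.seed(45)
  X <- cbind(runif(80, 0, 30000), runif(80, 0, 25000))
  y <- two_bumps(X[, 1] / 15000 - 1, X[, 2] / 12500 - 1)
  fit <- lm_train(network_spec(c(2, 8, 1)), X, y,
                  train_config(mse_goal = 1e-2, max_epochs = 300, seed = 2))
  expect_lte(fit$final_mse, 1e-2)
  # prediction applies the stored scaling transparently
  expect_equal(predict(fit, X), nn_forward(
    fit$params, sweep(sweep(X, 2, fit$center), 2, fit$half_extent, "/")))
})

test_that("trained networks round-trip through JSON", {
  set.seed(46)
  X <- cbind(runif(30, 0, 1000), runif(30, 0, 1000))
  y <- rnorm(30)
  fit <- lm_train(network_spec(c(2, 4, 4, 1)), X, y,
                  train_config(max_epochs = 10, seed = 1))
  f <- tempfile(fileext = ".json")
  write_bpnn_json(fit, f)
  fit2 <- read_bpnn_json(f)
  expect_equal(predict(fit2, X), predict(fit, X), tolerance = 1e-12)
})

test_that("architecture search ranks capacity correctly on smooth fields", {
  # a single candidate is trivially selected, and the report has the
  # {train, val} x {R2, RMSE} x {fold, average} shape
  w <- structured_wells(120, seed = 51)
  s <- ordered_split(w)
  cfg <- train_config(mse_goal = 1e-3, max_epochs = 60, seed = 1)
  one <- architecture_search(w, s, list(network_spec(c(2, 4, 1))),
                             restarts = 1, config = cfg, seed = 1)
  expect_equal(one$best_structure, "(2,4,1)")
  expect_named(one$report, c("structure", "fold", "r2_train", "r2_val",
                             "rmse_train", "rmse_val"))
  expect_setequal(unique(one$report$fold), c("A", "B", "C", "average"))

  # on a smooth nonlinear surface, the larger net's average validation
  # R2 is at least the smaller net's (paired over seeds)
  set.seed(52)
  X <- cbind(runif(150, 0, 30000), runif(150, 0, 25000))
  y <- two_bumps(X[, 1] / 15000 - 1, X[, 2] / 12500 - 1)
  wb <- make_wells(10^y, x = X[, 1], y = X[, 2])
  sb <- ordered_split(wb)
  diffs <- vapply(1:10, function(s) {
    cfg <- train_config(mse_goal = 1e-4, max_epochs = 120, seed = s)
    res <- architecture_search(
      wb, sb, list(network_spec(c(2, 2, 1)), network_spec(c(2, 10, 10, 1))),
      restarts = 1, config = cfg, seed = s)
    avg <- res$report[res$report$fold == "average", ]
    avg$r2_val[avg$structure == "(2,10,10,1)"] -
      avg$r2_val[avg$structure == "(2,2,1)"]
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
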