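test_that("make_grid applies the ceiling rule and padding", {
  g1 <- make_grid(c(0, 3000, 0, 2000), cell_size = 1000, padding = 0)
  expect_equal(c(g1$ncols, g1$nrows), c(3L, 2L))
  g2 <- make_grid(c(0, 2500, 0, 1500), cell_size = 1000, padding = 0)
  expect_equal(c(g2$ncols, g2$nrows), c(3L, 2L))
  w <- make_wells(5, x = 10000, y = 20000)
  g3 <- make_grid(w, cell_size = 1000, padding = 1000)
  expect_equal(c(g3$ncols, g3$nrows), c(2L, 2L))
  expect_equal(c(g3$xll, g3$yll), c(9000, 19000))
  expect_error(make_grid(c(5, 5, 0, 10), padding = 0), "empty")
})

test_that("cell centers reproduce exactly from grid metadata", {
  g <- grid_spec(100, 200, 500, ncols = 3, nrows = 2)
  ctr <- grid_centers(g)
  expect_equal(nrow(ctr), 6L)
  # north row first
  expect_equal(ctr$x[1:3], c(350, 850, 1350))
  expect_equal(ctr$y[1:3], rep(950, 3))
  expect_equal(ctr$y[4:6], rep(450, 3))
})

test_that("well tables round-trip through CSV", {
  w <- structured_wells(5, seed = 81)
  f <- tempfile(fileext = ".csv")
  write_wells(w, f)
  w2 <- read_wells(f)
  expect_equal(w2$well_id, w$well_id)
  expect_equal(w2$x, w$x, tolerance = 1e-9)
  expect_equal(w2$conc_ugL, w$conc_ugL, tolerance = 1e-9)
  expect_equal(w2$censored, w$censored)
  # malformed rows error with a line number
  writeLines(c("well_id,x,y,conc_ugL,censored",
               "W1,0,0,1.5,FALSE",
               "W2,oops,0,2.5,FALSE"), f)
  expect_error(read_wells(f), "line 3")
  writeLines(c("id,x,y", "W1,0,0"), f)
  expect_error(read_wells(f), "line 1")
})

test_that("ASCII grids round-trip values, metadata and NODATA", {
  g <- grid_spec(-500.25, 1000.5, 250, ncols = 4, nrows = 3)
  vals <- matrix(rnorm(12), 3, 4)
  vals[2, 3] <- NA
  f <- tempfile(fileext = ".asc")
  write_grid_asc(vals, g, f)
  back <- read_grid_asc(f)
  expect_equal(back$grid$xll, g$xll)
  expect_equal(back$grid$yll, g$yll)
  expect_equal(back$grid$cell_size, g$cell_size)
  expect_equal(back$values, vals, tolerance = 1e-9)
  expect_true(is.na(back$values[2, 3]))
  # malformed header errors with a line number
  writeLines(c("ncols 4", "nrows"), f)
  expect_error(read_grid_asc(f), "line 2")
})

test_that("grid CSV rows align with cell centers and layers", {
  w <- structured_wells(40, seed = 82)
  g <- make_grid(w, cell_size = 5000)
  m <- variogram_model("exponential", 0.01, 0.05, 15000)
  cg <- ok_map(w, g, m)
  f <- tempfile(fileext = ".csv")
  write_grid_csv(cg, f)
  tab <- read_grid_csv(f)
  ctr <- grid_centers(g)
  expect_equal(tab$x, ctr$x)
  expect_equal(tab$y, ctr$y)
  expect_equal(matrix(tab$conc_ugL, g$nrows, g$ncols, byrow = TRUE),
               cg$layers$conc_ugL, tolerance = 1e-9)
})

test_that("uniform 2x2 grid yields a single four-cell zone polygon", {
  g <- grid_spec(0, 0, 1000, 2, 2)
  f <- tempfile(fileext = ".geojson")
  n <- write_zones(matrix(1L, 2, 2), g, f)
  expect_equal(n, 1L)
  gj <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1L)
  feat <- gj$features[[1L]]
  expect_equal(feat$properties$n_cells, 4L)
  ring <- feat$geometry$coordinates[[1L]]
  xs <- vapply(ring, function(p) p[[1L]], numeric(1))
  ys <- vapply(ring, function(p) p[[2L]], numeric(1))
  expect_equal(range(xs), c(0, 2000))
  expect_equal(range(ys), c(0, 2000))
  # closed ring over the outline of the union (4 corners + closure)
  expect_equal(ring[[1L]], ring[[length(ring)]])
})

test_that("checkerboard classes produce one zone per cell", {
  g <- grid_spec(0, 0, 1000, 2, 2)
  f <- tempfile(fileext = ".geojson")
  m <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  expect_equal(write_zones(m, g, f), 4L)
})

test_that("the pipeline runs end to end and is seed-deterministic", {
  cfg <- default_config(seed = 7)
  cfg$simulate$n_wells <- 150L
  cfg$simulate$extent <- c(0, 12000, 0, 10000)
  cfg$simulate$log_mean <- 0.5
  cfg$bpnn <- list(structure = c(2L, 4L, 1L), restarts = 1L,
                   mse_goal = 1e-2, max_epochs = 60L)
  cfg$variogram$min_pairs <- 10L
  cfg$grid <- list(cell_size = 1000, padding = 1000)
  d1 <- file.path(tempdir(), "pipe1"); d2 <- file.path(tempdir(), "pipe2")
  res <- run_pipeline(cfg, d1)
  for (a in c("wells.csv", "split.csv", "variogram.json", "cv_report.csv",
              "conc.asc", "conc_log10.asc", "grid.csv",
              "zones_suitability.geojson", "log.json"))
    expect_true(file.exists(file.path(d1, a)), label = a)
  expect_s3_class(res$cv_report, "cv_report")
  expect_true(res$selected %in% c("ok", "bpnn"))

  run_pipeline(cfg, d2)
  for (a in c("wells.csv", "split.csv", "cv_report.csv", "grid.csv",
              "conc.asc"))
    expect_identical(readLines(file.path(d1, a)),
                     readLines(file.path(d2, a)), label = a)
})

test_that("an OK-only configuration produces no network artifacts", {
  cfg <- default_config(seed = 8)
  cfg$simulate$n_wells <- 100L
  cfg$simulate$extent <- c(0, 10000, 0, 10000)
  cfg$simulate$log_mean <- 0.5
  cfg$methods <- "ok"
  cfg$variogram$min_pairs <- 10L
  cfg$grid <- list(cell_size = 2000, padding = 1000)
  d <- file.path(tempdir(), "pipe_ok")
  res <- run_pipeline(cfg, d)
  expect_equal(res$selected, "ok")
  expect_false(file.exists(file.path(d, "bpnn.json")))
  expect_false(any(res$cv_report$method == "bpnn"))
})

test_that("yaml configuration files are accepted", {
  cfg <- default_config(seed = 9)
  cfg$simulate$n_wells <- 80L
  cfg$simulate$extent <- c(0, 8000, 0, 8000)
  cfg$simulate$log_mean <- 0.5
  cfg$methods <- "ok"
  cfg$variogram$min_pairs <- 5L
  cfg$grid <- list(cell_size = 2000, padding = 1000)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  d <- file.path(tempdir(), "pipe_yaml")
  res <- run_pipeline(f, d)
  expect_true(file.exists(file.path(d, "log.json")))
  log <- jsonlite::read_json(file.path(d, "log.json"))
  expect_equal(log$seed, 9L)
  expect_match(log$config_hash, "^[0-9a-f]{8}$")
})
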