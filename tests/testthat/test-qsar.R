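test_that("PLS with full factors reproduces ordinary least squares", {
  set.seed(61)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- rnorm(30)
    fit <- fit_pls(X, y, n_factors = 5)
    expect_equal(fit$fitted, ols_predictions(X, y), tolerance = 1e-8)
  }
})

test_that("a noiseless single-column signal is fit exactly by one factor", {
  set.seed(62)
  X <- cbind(rnorm(40), matrix(0, 40, 3))
  y <- 2.5 * X[, 1] + 1
  fit <- fit_pls(X, y, n_factors = 1)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-12)
})

test_that("PLS rejects degenerate inputs", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(fit_pls(X, rep(1, 20), 1), "constant")
  expect_error(fit_pls(X, rnorm(20), 4), "achievable rank")
  expect_error(fit_pls(X[1:3, ], rnorm(3), 2), "observations")
})

test_that("training R-squared is non-decreasing across the factor scan", {
  pipe <- small_pipeline()
  scan <- do.call(rbind, pipe$model$scan)
  r2 <- scan[, "r2"]
  expect_true(all(diff(r2) >= -1e-10))
  expect_gte(scan[nrow(scan), "q2"], scan[1, "q2"])  # plateau or improve
})

test_that("cross-validation recovers a noiseless linear signal", {
  set.seed(63)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- as.vector(X %*% c(1, -2, 0.5, 0, 0, 1))
  q2 <- cross_validate(X, y, n_factors = 6, n_folds = 10, seed = 1)
  expect_gte(q2, 0.999)
  expect_identical(q2, cross_validate(X, y, 6, 10, seed = 1))
})

test_that("y-scrambling destroys cross-validated predictivity", {
  set.seed(64)
  # model complexity high relative to the sample, as in the factor scan
  X <- matrix(rnorm(50 * 20), 50, 20)
  y <- as.vector(X %*% rnorm(20)) + rnorm(50, sd = 0.2)
  bad <- 0L
  for (s in 1:100) {
    set.seed(s)
    q2 <- cross_validate(X, sample(y), n_factors = 15, n_folds = 10, seed = s)
    bad <- bad + (q2 <= 0)
  }
  expect_gte(bad, 95L)
})

test_that("Q2F3 matches its closed form on analytic cases", {
  expect_equal(q2f3(c(1, 2, 3), c(1, 2, 3), c(0, 1, 2)), 1)
  # predicting the training mean for a test set that mirrors the training
  # distribution gives exactly zero
  expect_equal(q2f3(c(0, 1, 2), rep(1, 3), c(0, 1, 2)), 0)
  expect_equal(q2f3(c(1, 2), c(0, 2), c(0, 1, 2)), 0.25)
  expect_error(q2f3(1, 1, c(2, 2)), "variance")
  # never exceeds 1, equals 1 only for exact predictions
  set.seed(65)
  for (i in 1:50) {
    yt <- rnorm(20); yo <- rnorm(8); yp <- rnorm(8)
    expect_lte(q2f3(yo, yp, yt), 1)
  }
})

test_that("factor selection uses the SD rule with a Q2 fallback", {
  mk <- function(nf, sd, q2 = NA) list(n_factors = nf, stats = list(sd = sd),
                                       q2 = q2)
  sel <- select_model(list(mk(1, 0.7), mk(2, 0.5), mk(3, 0.3), mk(4, 0.18)),
                      experimental_error = 0.2)
  expect_equal(sel$n_factors, 4)
  sel2 <- select_model(list(mk(1, 0.7, 0.3), mk(2, 0.6, 0.6), mk(3, 0.5, 0.5)),
                       experimental_error = 0.2)
  expect_equal(sel2$n_factors, 2)
  expect_equal(select_model(list(mk(3, 0.4, 0.5)), 0.2)$n_factors, 3)
})

test_that("occupancy bits equal the brute-force sphere test", {
  # single carbon centred exactly on a cube center
  grid <- structure(list(origin = c(-2, -2, -2), spacing = 0.5,
                         extents = c(9L, 9L, 9L),
                         atom_classes = c("H", "X")),
                    class = "grid_spec")
  xyz <- matrix(c(0, 0, 0), 1, 3)
  keys <- occupancy_keys(xyz, "H", 1.70, grid)
  expect_identical(as.integer(keys),
                   as.integer(occupancy_bruteforce(xyz, "H", 1.70, grid)))
  # count equals the number of centers within 1.7 A
  centers <- expand.grid(x = seq(-2, 2, 0.5), y = seq(-2, 2, 0.5),
                         z = seq(-2, 2, 0.5))
  expect_length(keys, sum(centers$x^2 + centers$y^2 + centers$z^2 <= 1.7^2))
})

test_that("occupancy matches brute force on random atom sets", {
  set.seed(66)
  grid <- structure(list(origin = c(-3, -3, -3), spacing = 0.5,
                         extents = c(13L, 13L, 13L),
                         atom_classes = c("D", "H", "W", "X")),
                    class = "grid_spec")
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    xyz <- matrix(runif(3 * n, -2.5, 2.5), n, 3)
    cls <- sample(grid$atom_classes, n, replace = TRUE)
    radii <- runif(n, 1.2, 1.9)
    expect_identical(
      as.integer(occupancy_keys(xyz, cls, radii, grid)),
      as.integer(occupancy_bruteforce(xyz, cls, radii, grid)))
  }
})

test_that("empty poses give empty descriptors and duplicates agree", {
  grid <- structure(list(origin = c(0, 0, 0), spacing = 0.5,
                         extents = c(5L, 5L, 5L), atom_classes = "X"),
                    class = "grid_spec")
  none <- occupancy_keys(matrix(numeric(0), 0, 3), character(0), numeric(0), grid)
  expect_length(none, 0)
  xyz <- matrix(c(1, 1, 1), 1, 3)
  expect_identical(occupancy_keys(xyz, "X", 1.5, grid),
                   occupancy_keys(xyz, "X", 1.5, grid))
})

test_that("training molecules are predicted at their stored fitted values", {
  lib <- small_library()
  pipe <- small_pipeline()
  model <- pipe$model
  train <- pipe$split$train[model$train_ids[1:5]]
  pred <- predict(model, train)
  expect_true(all(pred$matched))
  idx <- match(pred$id, model$train_ids)
  expect_equal(pred$pic50_pred, model$fit$fitted[idx], tolerance = 1e-9)
})

test_that("molecules that cannot match receive the floor prediction", {
  pipe <- small_pipeline()
  dec <- pharmqsar:::build_decoy("d1", "ether", "tBu", "H", "H")
  rec <- list(id = "d1", mol = dec$mol,
              ensemble = conformer_ensemble(dec$mol,
                                            list(pharmqsar:::coords(dec$mol)), 0))
  class(rec) <- "molecule_record"
  pred <- predict(pipe$model, list(rec), partial = TRUE)
  expect_false(pred$matched)
  expect_equal(pred$pic50_pred, pipe$model$floor_prediction)
})

test_that("the coefficient field honours the export threshold", {
  pipe <- small_pipeline()
  all_cubes <- export_coefficient_field(pipe$model, threshold = 0)
  expect_equal(nrow(all_cubes), length(pipe$model$active_keys))
  none <- export_coefficient_field(
    pipe$model, threshold = max(abs(pipe$model$fit$coefficients)) * 1.01)
  expect_equal(nrow(none), 0)
  some <- export_coefficient_field(pipe$model, threshold = 1.5e-2)
  expect_true(all(abs(some$coefficient) >= 1.5e-2))
  expect_equal(attr(some, "n_positive") + attr(some, "n_negative"),
               nrow(some))
})

test_that("positive coefficients concentrate in the beneficial region", {
  lib <- small_library()
  pipe <- small_pipeline()
  model <- pipe$model
  # threshold at the strong tail of this model's own coefficient scale:
  # PLS spreads each substituent effect over many correlated occupancy
  # bits, so absolute display cutoffs from other tools do not transfer
  thr <- quantile(abs(model$fit$coefficients), 0.95)
  field <- export_coefficient_field(model, threshold = thr)
  pos <- field[field$sign == "positive", ]
  expect_gt(nrow(pos), 0)
  # map the template-frame beneficial region into the hypothesis frame via
  # the planted feature correspondence (D and R pairs can swap)
  pf <- lib$ground_truth$planted_features
  hf <- pipe$hypothesis$features
  hp <- as.matrix(hf[order(hf$kind), c("x", "y", "z")])
  best <- NULL
  for (dswap in 0:1) for (rswap in 0:1) {
    ord <- c(1, if (dswap) c(3, 2) else c(2, 3), if (rswap) c(5, 4) else c(4, 5))
    fit <- superpose(hp, as.matrix(pf[ord, c("x", "y", "z")]))
    if (is.null(best) || fit$rmsd < best$rmsd) best <- fit
  }
  center <- as.vector(best$rotation %*% lib$ground_truth$beneficial_region$center) +
    best$translation
  radius <- lib$ground_truth$beneficial_region$radius
  d2 <- (pos$x - center[1])^2 + (pos$y - center[2])^2 + (pos$z - center[3])^2
  n_in <- sum(d2 <= radius^2)
  vol_in <- 4 / 3 * pi * radius^3
  ext <- model$grid$extents * model$grid$spacing
  vol_total <- prod(ext)
  dens_in <- n_in / vol_in
  dens_out <- (nrow(pos) - n_in) / (vol_total - vol_in)
  expect_gte(dens_in, 2 * dens_out)
})

test_that("fitted models round-trip through JSON and keep predicting", {
  pipe <- small_pipeline()
  path <- withr::local_tempfile(fileext = ".json")
  write_qsar_model(pipe$model, path)
  m2 <- read_qsar_model(path)
  expect_equal(m2$fit$coefficients, pipe$model$fit$coefficients,
               tolerance = 1e-12)
  test_rec <- pipe$split$test[1:3]
  p1 <- predict(pipe$model, test_rec, partial = TRUE)
  p2 <- predict(m2, test_rec, partial = TRUE)
  expect_equal(p1$pic50_pred, p2$pic50_pred, tolerance = 1e-9)
})

test_that("the model object supports the standard S3 verbs", {
  pipe <- small_pipeline()
  m <- pipe$model
  expect_output(print(m), "3D-QSAR")
  expect_output(print(summary(m)), "Factor scan")
  expect_length(coef(m), length(m$active_keys))
  expect_equal(length(residuals(m)), length(m$y_train))
  pdf(NULL)
  expect_silent(plot(m))
  dev.off()
})
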