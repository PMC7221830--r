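test_that("enrichment factor and GH agree with direct formula evaluation", {
  # sweep over the lattice of feasible screening counts: the hit list fits
  # in the library and cannot hold more inactives than the library does
  grid <- expand.grid(Ht = 1:20, A = seq(1, 97, by = 8), D = seq(2, 200, by = 11))
  grid <- grid[grid$D > grid$A & grid$Ht <= grid$D, ]
  n_checked <- 0L
  for (i in seq_len(nrow(grid))) {
    Ht <- grid$Ht[i]; A <- grid$A[i]; D <- grid$D[i]
    ha_min <- max(0, Ht - (D - A))
    if (ha_min > min(Ht, A)) next
    Ha <- seq(ha_min, min(Ht, A))
    ef <- vapply(Ha, function(h) enrichment_factor(h, Ht, A, D), numeric(1))
    gh <- vapply(Ha, function(h) gh_score(h, Ht, A, D), numeric(1))
    expect_equal(ef, (Ha / Ht) / (A / D), tolerance = 1e-12)
    expect_equal(gh, (Ha * (3 * A + Ht) / (4 * Ht * A)) *
                   (1 - (Ht - Ha) / (D - A)), tolerance = 1e-12)
    expect_true(all(gh >= 0 & gh <= 1))
    expect_true(all(ef <= D / A + 1e-12))
    n_checked <- n_checked + length(Ha)
  }
  expect_gt(n_checked, 5000)
  # infeasible counts are refused
  expect_error(gh_score(0, 20, 5, 22), "impossible")
  expect_error(enrichment_factor(0, 18, 5, 20), "impossible")
  expect_error(gh_score(0, 20, 5, 10), "Ht <= D")
})

test_that("the published screening counts give GH 0.71 and EF 47.99", {
  expect_equal(round(gh_score(26, 30, 106, 5870), 2), 0.71)
  expect_equal(signif(enrichment_factor(26, 30, 106, 5870), 4), 47.99)
  yr <- yield_and_ratio(26, 30, 106)
  expect_equal(round(unname(yr["pct_ya"]), 2), 86.67)
  expect_equal(round(unname(yr["pct_ra"]), 2), 24.53)
})

test_that("enrichment metrics handle the analytic edge cases", {
  expect_equal(enrichment_factor(10, 10, 50, 50), 1.0)
  expect_equal(enrichment_factor(0, 10, 5, 100), 0.0)
  expect_equal(gh_score(7, 7, 7, 100), 1.0)   # perfect retrieval
  expect_equal(gh_score(0, 10, 5, 100), 0.0)
  expect_equal(unname(yield_and_ratio(5, 5, 9)["pct_ya"]), 100)
  expect_equal(unname(yield_and_ratio(9, 20, 9)["pct_ra"]), 100)
  expect_error(enrichment_factor(5, 0, 5, 10))
  expect_error(enrichment_factor(6, 5, 5, 10))
  expect_error(gh_score(5, 5, 10, 10), "D > A")
})

test_that("ROC handles separable, tied and random score patterns", {
  sep <- setNames(c(5, 4, 3, 1, 0.5, 0.1), paste0("m", 1:6))
  roc <- roc_curve(sep, c("m1", "m2", "m3"))
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$roc_points$fpr[1], 0)
  expect_equal(utils::tail(roc$roc_points$tpr, 1), 1)
  tied <- setNames(rep(1, 10), paste0("m", 1:10))
  expect_equal(roc_curve(tied, paste0("m", 1:4))$auc, 0.5)
  expect_error(roc_curve(sep, paste0("m", 1:6)), "one active")
  set.seed(71)
  scores <- setNames(runif(2000), paste0("m", 1:2000))
  roc_null <- roc_curve(scores, paste0("m", 1:100))
  expect_lt(abs(roc_null$auc - 0.5), 0.05)
})

test_that("trapezoid AUC equals the rank-sum statistic to machine precision", {
  set.seed(72)
  for (i in 1:1000) {
    n <- sample(10:40, 1)
    npos <- sample(2:(n - 2), 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties often
    names(scores) <- paste0("m", 1:n)
    labels <- seq_len(n) <= npos
    auc <- roc_curve(scores, names(scores)[labels])$auc
    expect_equal(auc, ranksum_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric under score negation", {
  set.seed(73)
  for (i in 1:20) {
    scores <- setNames(round(rnorm(30), 1), paste0("m", 1:30))
    act <- paste0("m", 1:10)
    a1 <- roc_curve(scores, act)$auc
    a2 <- roc_curve(-scores, act)$auc
    expect_equal(a1, 1 - a2, tolerance = 1e-12)
  }
})

test_that("screening ranks a library deterministically and sizes the hit list", {
  pipe <- small_pipeline()
  lib <- small_library()
  cls <- sapply(lib$records, function(x) x$activity_class)
  actives <- lib$records[cls == "active"]
  decoys <- suppressWarnings(generate_decoys(actives, n_per = 5, seed = 5))
  screenlib <- c(actives, decoys)
  r1 <- screen(pipe$model, screenlib)
  r2 <- screen(pipe$model, screenlib)
  expect_identical(r1$id, r2$id)                    # stable tie-breaking
  expect_equal(sum(r1$is_hit), max(1, round(0.01 * nrow(r1))))
  r3 <- screen(pipe$model, screenlib, hit_count = 7)
  expect_equal(sum(r3$is_hit), 7)
  single <- screen(pipe$model, screenlib[1])
  expect_equal(sum(single$is_hit), 1)               # floor of one hit
  expect_error(screen(pipe$model, list()), "empty")
  rep <- enrichment_report(r1, sapply(actives, `[[`, "id"))
  expect_equal(rep$D, length(screenlib))
  expect_equal(rep$A, length(actives))
  expect_lte(rep$Ha, min(rep$Ht, rep$A))
})

test_that("external validation reports squared Pearson r and guards overlap", {
  pipe <- small_pipeline()
  ext_lib <- generate_library(synthetic_library_spec(
    n_actives = 5, n_moderate = 25, n_inactive = 5, seed = 31415))
  ext <- lapply(ext_lib$records, function(r) { r$id <- paste0("x_", r$id); r })
  ev <- external_validation(pipe$model, ext)
  expect_true(ev$r2_ext >= 0 && ev$r2_ext <= 1)
  expect_equal(nrow(ev$scatter), length(ext))
  expect_equal(ev$r2_ext,
               cor(ev$scatter$observed, ev$scatter$predicted)^2)
  # overlap with the training ids is refused
  clash <- pipe$split$train[1]
  expect_error(external_validation(pipe$model, clash), "overlap")
})
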