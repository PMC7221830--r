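entries_of <- function(records) {
  lapply(records, function(r) {
    list(ensemble = r$ensemble, features = ensemble_features(r$ensemble),
         pic50 = r$pic50 %||% 2)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical rigid actives give candidates matching all of them", {
  built <- template_benzamide()
  copies <- lapply(1:20, function(i) {
    ens <- rigid_ensemble(built)
    ens$molecule_id <- sprintf("copy%02d", i)
    list(ensemble = ens, features = ensemble_features(ens), pic50 = 2.2)
  })
  cands <- enumerate_hypotheses(copies, k = 5, bin_width = 1.0)
  expect_gt(length(cands), 0)
  expect_true(all(vapply(cands, `[[`, integer(1), "matches") == 20L))
})

test_that("actives sharing no five-feature kind multiset give an empty list", {
  a <- list(ensemble = rigid_ensemble(template_benzamide()))
  b_ens <- conformer_ensemble(mol3d("c1ccccc1"),
                              list(pharmqsar:::coords(mol3d("c1ccccc1"))), 0)
  b <- list(ensemble = b_ens)  # benzene: a single R feature, < 5 features
  cands <- enumerate_hypotheses(list(a, b), k = 5)
  expect_length(cands, 0)
})

test_that("enumeration recovers the planted motif from the synthetic library", {
  lib <- small_library()
  cls <- sapply(lib$records, function(x) x$activity_class)
  actives <- lib$records[cls == "active"]
  ent <- lapply(actives, function(r) {
    list(ensemble = r$ensemble, features = ensemble_features(r$ensemble),
         pic50 = r$pic50)
  })
  cands <- enumerate_hypotheses(ent, k = 5, bin_width = 1.0)
  labels <- vapply(cands, `[[`, character(1), "variant_label")
  expect_true("ADDRR" %in% labels)
  h <- cands[[which(labels == "ADDRR")[1]]]
  pd <- as.matrix(dist(lib$ground_truth$planted_features[, c("x", "y", "z")]))
  expect_lt(max(abs(sort(as.vector(h$distance_matrix)) - sort(as.vector(pd)))),
            1.0)
})

test_that("enumeration output is independent of active-list ordering", {
  lib <- small_library()
  cls <- sapply(lib$records, function(x) x$activity_class)
  actives <- lib$records[cls == "active"]
  ent <- lapply(actives, function(r) {
    list(ensemble = r$ensemble, features = ensemble_features(r$ensemble),
         pic50 = r$pic50)
  })
  c1 <- enumerate_hypotheses(ent, k = 5)
  c2 <- enumerate_hypotheses(rev(ent), k = 5)
  expect_identical(vapply(c1, `[[`, character(1), "key"),
                   vapply(c2, `[[`, character(1), "key"))
})

test_that("hypotheses satisfy the triangle inequality and survival identity", {
  lib <- small_library()
  pipe <- small_pipeline()
  for (h in pipe$candidates) {
    dm <- h$distance_matrix
    k <- nrow(dm)
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    for (i in 1:k) for (j in 1:k) for (l in 1:k) {
      expect_lte(dm[i, j], dm[i, l] + dm[l, j] + 1e-9)
    }
    expect_equal(h$scores$adjusted_survival,
                 h$scores$survival - h$scores$inactive_score)
  }
})

test_that("a reference ligand scores perfectly against itself", {
  built <- template_benzamide()
  ens <- rigid_ensemble(built)
  feats <- ensemble_features(ens)
  addrr <- feats[[1]][feats[[1]]$kind %in% c("A", "D", "R"), ]
  h <- hypothesis(addrr[order(addrr$kind), ][1:5, ], ref_molecule = "tmpl",
                  ref_conformer = 1L, ref_energy = 0)
  self <- list(list(ensemble = ens, features = feats, pic50 = 2))
  expect_warning(hs <- score_hypothesis(h, self, inactives = list()),
                 "inactive")
  expect_equal(hs$scores$site, 1)
  expect_equal(hs$scores$vector, 1, tolerance = 1e-6)
  expect_equal(hs$scores$adjusted_survival, hs$scores$survival)
})

test_that("pairwise volume overlap matches numerical sphere integration", {
  r1 <- 1.7; r2 <- 1.5
  for (d in c(0.8, 1.6, 2.9)) {
    got <- pharmqsar:::volume_overlap_ratio(
      matrix(c(0, 0, 0), 1, 3), r1,
      matrix(c(d, 0, 0), 1, 3), r2)
    common <- sphere_overlap_numeric(r1, r2, d)
    v1 <- 4 / 3 * pi * r1^3; v2 <- 4 / 3 * pi * r2^3
    expect_equal(got, common / (v1 + v2 - common), tolerance = 0.02)
  }
  # disjoint spheres share nothing
  expect_equal(pharmqsar:::volume_overlap_ratio(
    matrix(0, 1, 3), 1.7, matrix(c(10, 0, 0), 1, 3), 1.7), 0)
})

test_that("selection maximizes adjusted survival with the energy tie-break", {
  mk <- function(adj, energy, label) {
    feats <- data.frame(kind = c("A", "D", "D", "R", "R"),
                        x = c(0, 1, 2, 0, 3), y = c(0, 1, 0, 2, 1),
                        z = c(0, 0, 1, 1, 0), dx = NA, dy = NA, dz = NA)
    h <- hypothesis(feats, ref_energy = energy)
    h$variant_label <- label
    h$scores <- list(survival = adj, inactive_score = 0,
                     adjusted_survival = adj)
    h
  }
  single <- mk(1.0, 5, "ADDRR")
  expect_identical(select_best(list(single)), single)
  a <- mk(2.0, 3, "ADDRR"); b <- mk(2.0, 5, "ADDRR")
  expect_equal(select_best(list(b, a))$ref_energy, 3)
  expect_error(select_best(list()), "no candidate")
})

test_that("hypothesis JSON round-trip is lossless", {
  pipe <- small_pipeline()
  h <- pipe$hypothesis
  path <- withr::local_tempfile(fileext = ".json")
  write_hypothesis(h, path)
  h2 <- read_hypothesis(path)
  expect_equal(h2$variant_label, h$variant_label)
  expect_equal(as.matrix(h2$features[, c("x", "y", "z")]),
               as.matrix(h$features[, c("x", "y", "z")]), tolerance = 1e-12)
  expect_equal(h2$distance_matrix, h$distance_matrix,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(h2$scores$adjusted_survival, h$scores$adjusted_survival,
               tolerance = 1e-12)
})

test_that("the planted hypothesis is recovered across many generator seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    # hypothesis-generation regime of the study: 20 targeted potent
    # compounds, as used for the common-pharmacophore step
    lib <- generate_library(synthetic_library_spec(
      n_actives = 20, n_moderate = 60, n_inactive = 20,
      seed = 5000 + s))
    cls <- sapply(lib$records, function(x) x$activity_class)
    actives <- lib$records[cls == "active"]
    inact <- lib$records[cls == "inactive"]
    ent <- function(rs) lapply(rs, function(r) {
      list(ensemble = r$ensemble, features = ensemble_features(r$ensemble),
           pic50 = r$pic50)
    })
    cands <- enumerate_hypotheses(ent(actives), k = 5, bin_width = 1.0)
    if (!length(cands)) next
    cands <- suppressWarnings(
      lapply(cands, score_hypothesis, actives = ent(actives),
             inactives = ent(inact)))
    h <- select_best(cands)
    pd <- as.matrix(dist(lib$ground_truth$planted_features[, c("x", "y", "z")]))
    ok <- identical(h$variant_label, "ADDRR") &&
      max(abs(sort(as.vector(h$distance_matrix)) - sort(as.vector(pd)))) < 1.0
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.95)
})
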