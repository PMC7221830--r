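test_that("library generation is deterministic per seed", {
  spec <- synthetic_library_spec(n_actives = 5, n_moderate = 15,
                                 n_inactive = 5, seed = 77)
  l1 <- generate_library(spec)
  l2 <- generate_library(spec)
  expect_identical(l1$activity, l2$activity)
  expect_equal(l1$records[[3]]$ensemble$conformers[[1]]$xyz,
               l2$records[[3]]$ensemble$conformers[[1]]$xyz)
  expect_identical(l1$ground_truth$compounds, l2$ground_truth$compounds)
})

test_that("zero noise reproduces the noiseless ground truth exactly", {
  spec <- synthetic_library_spec(n_actives = 5, n_moderate = 15,
                                 n_inactive = 5, noise_sigma = 0, seed = 78)
  lib <- generate_library(spec)
  gt <- lib$ground_truth$compounds
  expect_equal(lib$activity$pic50, pmin(pmax(gt$pic50_true, -log10(50)),
                                        -log10(0.006)), tolerance = 1e-12)
})

test_that("IC50 values stay in the assay range with consistent classes", {
  lib <- small_library()
  expect_true(all(lib$activity$ic50_nM >= 6 - 1e-9))
  expect_true(all(lib$activity$ic50_nM <= 50000 + 1e-6))
  expect_identical(lib$activity$class, classify_activity(lib$activity$ic50_nM))
  expect_equal(lib$activity$pic50, to_pic50(lib$activity$ic50_nM),
               tolerance = 1e-9)
})

test_that("every potent compound carries the full planted motif", {
  lib <- small_library()
  cls <- sapply(lib$records, function(x) x$activity_class)
  for (r in lib$records[cls == "active"]) {
    f <- perceive_features(r$mol)
    expect_gte(sum(f$kind == "A"), 1)
    expect_gte(sum(f$kind == "D"), 2)
    expect_gte(sum(f$kind == "R"), 2)
  }
})

test_that("decoys satisfy every property window by construction", {
  lib <- small_library()
  cls <- sapply(lib$records, function(x) x$activity_class)
  actives <- lib$records[cls == "active"]
  expect_length(generate_decoys(actives, n_per = 0, seed = 1), 0)
  decoys <- suppressWarnings(generate_decoys(actives, n_per = 6, seed = 9))
  expect_gt(length(decoys), 0)
  act_fps <- lapply(actives, function(r) path_fingerprint(r$mol))
  act_by_id <- setNames(actives, sapply(actives, `[[`, "id"))
  for (d in decoys) {
    a <- act_by_id[[d$paired_active]]
    expect_lte(abs(pharmqsar:::mol_weight(d$mol) - pharmqsar:::mol_weight(a$mol)),
               25)
    expect_equal(sum(d$mol$atoms$charge), sum(a$mol$atoms$charge))
    # topological dissimilarity against every active, not just the paired one
    fp <- path_fingerprint(d$mol)
    sims <- vapply(act_fps, function(af) tanimoto(fp, af), numeric(1))
    expect_lt(max(sims), 0.4)
    # donor-free by design: no N-H or O-H anywhere
    f <- perceive_features(d$mol)
    expect_false(any(f$kind == "D"))
  }
})

test_that("library files are written in the documented plain-text formats", {
  spec <- synthetic_library_spec(n_actives = 3, n_moderate = 6,
                                 n_inactive = 3, seed = 80)
  lib <- generate_library(spec)
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  expect_true(file.exists(file.path(dir, "library.smi")))
  act <- read.csv(file.path(dir, "activity.csv"))
  expect_identical(sort(names(act)), c("ic50_nM", "id"))
  expect_equal(nrow(act), 12)
  sdf <- ChemmineR::read.SDFset(file.path(dir, "library.sdf"))
  expect_gte(length(sdf), 12)   # one record per conformer
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$planted_features$kind, c("A", "D", "D", "R", "R"))
  # round-trip: the written pair feeds straight back into the ingest step
  recs <- read_dataset(file.path(dir, "library.smi"),
                       file.path(dir, "activity.csv"), embed3d = FALSE)
  expect_length(recs, 12)
  expect_equal(recs[[1]]$ic50, act$ic50_nM[1], tolerance = 1e-9)
})

test_that("the path fingerprint separates scaffolds but not trivial variants", {
  m1 <- template_benzamide("a", para = "H")$mol
  m2 <- template_benzamide("b", para = "Me")$mol
  d1 <- pharmqsar:::build_decoy("d", "biphenyl", "H", "H", "H")$mol
  s_close <- tanimoto(path_fingerprint(m1), path_fingerprint(m2))
  s_far <- tanimoto(path_fingerprint(m1), path_fingerprint(d1))
  expect_gt(s_close, 0.6)
  expect_lt(s_far, s_close)
})
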