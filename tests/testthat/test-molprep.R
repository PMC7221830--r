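test_that("activity classification follows the potency thresholds", {
  expect_equal(classify_activity(6.0), "active")
  expect_equal(classify_activity(10.0), "active")   # boundary inclusive
  expect_equal(classify_activity(10.0001), "moderate")
  expect_equal(classify_activity(4999), "moderate")
  expect_equal(classify_activity(5000), "inactive") # 5 uM inclusive
  expect_equal(classify_activity(50000), "inactive")
  expect_equal(classify_activity(50001), "out_of_domain")
  expect_error(classify_activity(0), "positive")
  expect_error(classify_activity(-1), "positive")
})

test_that("classification is total and monotone non-increasing in potency", {
  x <- sort(10^runif(500, log10(0.5), log10(50000)))
  cls <- classify_activity(x)
  lvl <- c(active = 3, moderate = 2, inactive = 1)
  expect_true(all(cls %in% names(lvl)))
  expect_true(all(diff(lvl[cls]) <= 0))
})

test_that("pIC50 conversion uses the micromolar scale and round-trips", {
  expect_equal(to_pic50(1000), 0)
  expect_equal(to_pic50(6.0), 2.2218, tolerance = 1e-4)
  expect_equal(to_pic50(10), 2.0)
  expect_error(to_pic50(0), "positive")
  set.seed(99)
  x <- 10^runif(1e6, -3, 8)
  expect_true(max(abs(from_pic50(to_pic50(x)) / x - 1)) < 1e-9)
})

test_that("stratified split reproduces the 259/111 partition of 370 records", {
  recs <- lapply(seq_len(370), function(i) {
    r <- list(id = sprintf("r%03d", i), pic50 = runif(1, -1.7, 2.2))
    class(r) <- "molecule_record"
    r
  })
  sp <- split_dataset(recs, train_frac = 0.7, seed = 5)
  expect_length(sp$train, 259)
  expect_length(sp$test, 111)
  expect_setequal(c(sapply(sp$train, `[[`, "id"), sapply(sp$test, `[[`, "id")),
                  sapply(recs, `[[`, "id"))
  expect_true(all(sapply(sp$train, `[[`, "role") == "train"))
  # determinism
  sp2 <- split_dataset(recs, train_frac = 0.7, seed = 5)
  expect_identical(sapply(sp$train, `[[`, "id"), sapply(sp2$train, `[[`, "id"))
  # per-bin proportions deviate by less than one unit count
  pic <- sapply(recs, `[[`, "pic50")
  qs <- quantile(pic, seq(0, 1, length.out = 6))
  bins <- cut(pic, unique(qs), include.lowest = TRUE, labels = FALSE)
  train_ids <- sapply(sp$train, `[[`, "id")
  for (b in unique(bins)) {
    ids_b <- sapply(recs[bins == b], `[[`, "id")
    got <- sum(ids_b %in% train_ids)
    expect_lt(abs(got - 0.7 * length(ids_b)), 1)
  }
})

test_that("split falls back to one stratum for tiny inputs", {
  recs <- lapply(1:10, function(i) {
    r <- list(id = as.character(i), pic50 = 1.0)
    class(r) <- "molecule_record"
    r
  })
  sp <- split_dataset(recs, train_frac = 0.7, n_bins = 5, seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_warning(split_dataset(recs[1:3], n_bins = 5, seed = 1), "stratum")
})

test_that("dataset reading joins structures and activities and validates input", {
  dir <- withr::local_tempdir()
  smi <- file.path(dir, "mols.smi")
  writeLines(c("c1ccccc1\tbenzene", "CCO\tethanol", "CCC\tpropane"), smi)
  act <- file.path(dir, "act.csv")
  writeLines(c("id,ic50_nM", "benzene,6.0", "ethanol,5000"), act)
  recs <- read_dataset(smi, act, embed3d = FALSE)
  expect_length(recs, 3)
  expect_identical(names(recs), c("benzene", "ethanol", "propane"))
  expect_equal(recs$benzene$activity_class, "active")
  expect_equal(recs$ethanol$activity_class, "inactive")
  expect_equal(recs$propane$role, "unassigned")
  expect_true(is.na(recs$propane$ic50))
  # structures without any activity file
  recs2 <- read_dataset(smi, NULL, embed3d = FALSE)
  expect_true(all(sapply(recs2, `[[`, "role") == "unassigned"))
  # duplicate id
  writeLines(c("c1ccccc1\tdup", "CCO\tdup"), smi)
  expect_error(read_dataset(smi, NULL, embed3d = FALSE), "dup")
  # negative IC50
  writeLines(c("c1ccccc1\tbenzene"), smi)
  writeLines(c("id,ic50_nM", "benzene,-1"), act)
  expect_error(read_dataset(smi, act, embed3d = FALSE), "IC50")
})

test_that("ionization rules assign the expected states at pH 7.4", {
  # benzoic acid: carboxylate, net -1
  ba <- ionize(mol3d("OC(=O)c1ccccc1"))
  expect_equal(sum(ba$atoms$charge), -1)
  # the deprotonated oxygen lost its hydrogen
  expect_equal(sum(ba$atoms$elem == "H"), 5)
  # N-(2-aminophenyl)benzamide: aniline + amide stay neutral
  apb <- ionize(mol3d("NC1=CC=CC=C1NC(=O)c1ccccc1"))
  expect_equal(sum(apb$atoms$charge), 0)
  # 4-(aminomethyl)benzamide: benzylic amine protonated, +1
  amb <- ionize(mol3d("NCc1ccc(C(N)=O)cc1"))
  expect_equal(sum(amb$atoms$charge), 1)
  n_idx <- which(amb$atoms$charge == 1)
  expect_equal(amb$atoms$elem[n_idx], "N")
})
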