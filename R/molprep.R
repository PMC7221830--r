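#' Classify HDAC1 inhibitory activity from IC50
#'
#' Potency classes follow the conventions used throughout the package:
#' potent inhibitors ("active") have IC50 <= 10 nM, inactive ligands lie
#' between 5 and 50 uM (both bounds inclusive), everything in between is
#' "moderate". Values above 50 uM are outside the modelled activity domain
#' and are flagged `out_of_domain`.
#'
#' @param ic50 IC50 in nM, positive.
#' @return character vector of classes: "active", "moderate", "inactive" or
#'   "out_of_domain".
#' @examples
#' classify_activity(c(6, 10, 500, 5000, 50000))
#' @export
classify_activity <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stopf("IC50 must be positive and finite (nM)")
  }
  out <- character(length(ic50))
  out[ic50 <= 10] <- "active"
  out[ic50 > 10 & ic50 < 5000] <- "moderate"
  out[ic50 >= 5000 & ic50 <= 50000] <- "inactive"
  out[ic50 > 50000] <- "out_of_domain"
  out
}

#' Convert IC50 (nM) to pIC50 on the micromolar scale
#'
#' `pIC50 = -log10(IC50 / 1000)`, i.e. 1 uM maps to 0. The micromolar
#' convention (rather than molar) is used for all responses in this
#' package.
#'
#' @param ic50 IC50 in nM, positive.
#' @export
to_pic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stopf("IC50 must be positive and finite (nM)")
  }
  -log10(ic50 / 1000)
}

#' Inverse of [to_pic50()]: pIC50 (uM scale) back to IC50 in nM
#' @param pic50 numeric.
#' @export
from_pic50 <- function(pic50) 1000 * 10^(-pic50)

#' Build a molecule record
#' @noRd
molecule_record <- function(mol, id, ic50 = NA_real_, pic50 = NA_real_,
                            role = "unassigned") {
  if (!is.na(ic50) && is.na(pic50)) pic50 <- to_pic50(ic50)
  if (is.na(ic50) && !is.na(pic50)) ic50 <- from_pic50(pic50)
  cls <- if (is.na(ic50)) NA_character_ else classify_activity(ic50)
  structure(
    list(id = id, mol = mol, ic50 = ic50, pic50 = pic50,
         activity_class = cls, role = role, ensemble = NULL,
         features = NULL),
    class = "molecule_record"
  )
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record %s: IC50 %s nM, pIC50 %s, %s, role=%s>\n",
              x$id,
              ifelse(is.na(x$ic50), "NA", format(x$ic50)),
              ifelse(is.na(x$pic50), "NA", format(round(x$pic50, 3))),
              x$activity_class %||% "NA", x$role))
  invisible(x)
}

#' Read a structure file plus an activity table into molecule records
#'
#' Structures come from a SMILES file (one molecule per line, optional
#' whitespace-separated id) or an SDF; activities from a CSV with columns
#' `id` and exactly one of `ic50_nM` / `pic50`. Records without an activity
#' row keep empty activity fields and `role = "unassigned"`. Input order is
#' preserved.
#'
#' @param structures_path path to `.smi`/`.smiles` or `.sdf` file.
#' @param activity_path path to the activity CSV; `NULL` for none.
#' @param embed3d generate 3D coordinates for SMILES input (default TRUE).
#' @return list of `molecule_record` objects.
#' @export
read_dataset <- function(structures_path, activity_path = NULL,
                         embed3d = TRUE) {
  if (!file.exists(structures_path)) {
    stopf("structure file not found: %s", structures_path)
  }
  ext <- tolower(tools::file_ext(structures_path))
  mols <- if (ext %in% c("smi", "smiles", "txt")) {
    read_smiles_file(structures_path, embed3d = embed3d)
  } else if (ext == "sdf") {
    sdfset <- ChemmineR::read.SDFset(structures_path)
    ids <- ChemmineR::sdfid(sdfset)
    out <- lapply(seq_along(sdfset), function(i) {
      sdf_to_molgraph(sdfset[[i]], id = ids[i])
    })
    names(out) <- ids
    out
  } else {
    stopf("unsupported structure format: .%s", ext)
  }
  ids <- vapply(mols, function(m) m$id, character(1))
  if (anyDuplicated(ids)) {
    stopf("duplicate molecule id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  act <- NULL
  if (!is.null(activity_path)) {
    if (!file.exists(activity_path)) {
      stopf("activity file not found: %s", activity_path)
    }
    act <- utils::read.csv(activity_path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
    has_ic50 <- "ic50_nM" %in% names(act)
    has_pic50 <- "pic50" %in% names(act)
    if (!("id" %in% names(act)) || (has_ic50 + has_pic50) != 1L) {
      stopf("activity CSV must have columns id and exactly one of ic50_nM / pic50")
    }
    if (anyDuplicated(act$id)) {
      stopf("duplicate id(s) in activity table: %s",
            paste(unique(act$id[duplicated(act$id)]), collapse = ", "))
    }
    if (has_ic50 && any(!is.finite(act$ic50_nM) | act$ic50_nM <= 0)) {
      bad <- act$id[!is.finite(act$ic50_nM) | act$ic50_nM <= 0]
      stopf("non-positive IC50 for id(s): %s", paste(bad, collapse = ", "))
    }
  }
  records <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    id <- ids[i]
    ic50 <- NA_real_; pic50 <- NA_real_; role <- "unassigned"
    if (!is.null(act) && id %in% act$id) {
      row <- act[act$id == id, ]
      if ("ic50_nM" %in% names(act)) ic50 <- row$ic50_nM else pic50 <- row$pic50
      role <- "unassigned"  # roles assigned later by split_dataset
    }
    records[[i]] <- molecule_record(mols[[i]], id, ic50 = ic50, pic50 = pic50,
                                    role = role)
  }
  names(records) <- ids
  records
}

read_smiles_file <- function(path, embed3d = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][[2]] else as.character(i)
  }, character(1))
  allowed <- c(LETTERS, letters, as.character(0:9), "@", "+", "-", "(",
               ")", "=", "#", "$", ":", "/", "\\", "%", ".", "[", "]")
  bad <- !vapply(smi, function(s) {
    all(strsplit(s, "")[[1]] %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stopf("unparsable structure at line %d: %s", which(bad)[1], smi[which(bad)[1]])
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate molecule id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (embed3d) {
    res <- try(smiles_to_molgraph(smi, ids = ids), silent = TRUE)
    if (inherits(res, "try-error")) {
      stopf("failed to parse/embed SMILES input: %s", attr(res, "condition")$message)
    }
    res
  } else {
    # topological parse only (no coordinates) via ChemmineR
    sdfset <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi, ids)))
    out <- lapply(seq_along(smi), function(i) sdf_to_molgraph(sdfset[[i]], id = ids[i]))
    names(out) <- ids
    out
  }
}

#' Stratified train/test split over pIC50
#'
#' Records are binned by pIC50 quantiles and each bin is split
#' train:test = `train_frac` : (1 - train_frac) with largest-remainder
#' rounding, so the response range is covered in both sets. Deterministic
#' for a fixed seed.
#'
#' @param records list of `molecule_record`s, all with pIC50.
#' @param train_frac fraction of records in the training set (default 0.7).
#' @param n_bins number of quantile strata (default 5).
#' @param seed integer seed (required).
#' @return list with elements `train` and `test` (records with `role` set).
#' @export
split_dataset <- function(records, train_frac = 0.7, n_bins = 5, seed) {
  pic50 <- vapply(records, function(r) r$pic50 %||% NA_real_, numeric(1))
  if (any(is.na(pic50))) stopf("all records need pIC50 before splitting")
  n <- length(records)
  if (n < n_bins) {
    warnf("fewer records (%d) than bins (%d); using a single stratum", n, n_bins)
    n_bins <- 1L
  }
  # quantile bins (ties collapse bins naturally; fully tied responses
  # degenerate to a single stratum)
  if (n_bins > 1) {
    qs <- unique(stats::quantile(pic50, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- if (length(qs) < 2) rep(1L, n) else
      cut(pic50, breaks = qs, include.lowest = TRUE, labels = FALSE)
  } else {
    bins <- rep(1L, n)
  }
  n_train_total <- round(train_frac * n)
  # largest-remainder apportionment of the train quota across bins
  sizes <- tabulate(bins)
  exact <- sizes * train_frac
  base <- floor(exact)
  rem <- exact - base
  need <- n_train_total - sum(base)
  order_rem <- order(rem, decreasing = TRUE)
  add <- rep(0L, length(sizes))
  if (need > 0) add[order_rem[seq_len(need)]] <- 1L
  quota <- base + add
  train_idx <- integer()
  with_seed(seed, {
    for (b in seq_along(sizes)) {
      members <- which(bins == b)
      take <- sample(members, size = min(quota[b], length(members)))
      train_idx <- c(train_idx, take)
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- records[train_idx]
  test <- records[test_idx]
  train <- lapply(train, function(r) { r$role <- "train"; r })
  test <- lapply(test, function(r) { r$role <- "test"; r })
  list(train = train, test = test)
}

#' Rule-based ionization at physiological pH
#'
#' Assigns the single most probable protonation state at pH 7.4 with a
#' fixed pKa-threshold rule table: carboxylic and sulfonic acids are
#' deprotonated; aliphatic amines, amidines and guanidines are protonated;
#' anilines, amides and pyridine-type aromatic nitrogens are left neutral.
#' The rules are total, so the operation never fails on a valid structure.
#'
#' @param record a `molecule_record` (or bare `molgraph`).
#' @param pH numeric, informational (the rule table encodes pH 7.4).
#' @return the input with its structure protonated/deprotonated and formal
#'   charges updated.
#' @export
ionize <- function(record, pH = 7.4) {
  mol <- if (inherits(record, "molecule_record")) record$mol else record
  mol <- ionize_molgraph(mol)
  if (inherits(record, "molecule_record")) {
    record$mol <- mol
    record
  } else {
    mol
  }
}

ionize_molgraph <- function(mol) {
  adj <- adjacency(mol)
  bo <- bond_order_matrix(mol)
  arom <- unlist(aromatic_rings_safe(mol))
  elem <- mol$atoms$elem

  # --- deprotonate acidic O-H: carboxylic (O-H on C(=O)) and sulfonic ---
  drop_h <- integer()
  for (i in which(elem == "O")) {
    hs <- adj[[i]][elem[adj[[i]]] == "H"]
    if (!length(hs)) next
    heavies <- adj[[i]][elem[adj[[i]]] != "H"]
    if (length(heavies) != 1) next
    c_at <- heavies[1]
    acidic <- FALSE
    if (elem[c_at] == "C") {
      # carboxylic acid: the attached carbon double-bonds another oxygen
      others <- setdiff(adj[[c_at]], i)
      acidic <- any(elem[others] == "O" & bo[c_at, others] == 2)
    } else if (elem[c_at] == "S") {
      others <- setdiff(adj[[c_at]], i)
      acidic <- sum(elem[others] == "O" & bo[c_at, others] == 2) >= 1
    }
    if (acidic) {
      mol$atoms$charge[i] <- -1L
      drop_h <- c(drop_h, hs[1])
    }
  }

  # --- protonate basic nitrogens ---
  add_h_on <- integer()
  for (i in which(elem == "N")) {
    if (mol$atoms$charge[i] != 0) next
    if (i %in% arom) next                                   # aromatic N
    nbh <- adj[[i]][elem[adj[[i]]] != "H"]
    if (any(bo[i, ] >= 3)) next                             # nitrile
    dbl_c <- nbh[elem[nbh] == "C" & bo[i, nbh] == 2]
    sgl_c <- nbh[elem[nbh] == "C" & bo[i, nbh] == 1]
    # amide / sulfonamide N: attached carbon carries C=O (or S=O)
    is_amide <- any(vapply(sgl_c, function(cc) {
      oth <- setdiff(adj[[cc]], i)
      any(elem[oth] %in% c("O", "S") & bo[cc, oth] == 2)
    }, logical(1)))
    if (is_amide) next
    # aniline N: attached carbon is aromatic
    is_aniline <- any(sgl_c %in% arom)
    # amidine/guanidine N (C=N where that C also binds another N) is basic
    is_amidine <- any(vapply(dbl_c, function(cc) {
      oth <- setdiff(adj[[cc]], i)
      any(elem[oth] == "N")
    }, logical(1)))
    if (is_amidine) {
      mol$atoms$charge[i] <- 1L
      add_h_on <- c(add_h_on, i)
      next
    }
    if (length(dbl_c)) next                                 # plain imine: skip
    if (is_aniline) next
    # remaining sp3 nitrogen bonded only to sp3 carbons/hydrogens: basic amine
    if (length(nbh) == 0 || all(elem[nbh] == "C")) {
      mol$atoms$charge[i] <- 1L
      add_h_on <- c(add_h_on, i)
    }
  }

  if (length(drop_h)) {
    mol <- remove_atoms(mol, drop_h)
  }
  for (i in add_h_on) {
    # index survives H removal only if recomputed; protonation first maps ids
    mol <- add_hydrogen(mol, match_atom_after_removal(i, drop_h))
  }
  mol
}

match_atom_after_removal <- function(idx, removed) {
  idx - sum(removed < idx)
}

remove_atoms <- function(mol, idx) {
  keep <- setdiff(seq_len(n_atoms(mol)), idx)
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds[!(mol$bonds$a1 %in% idx | mol$bonds$a2 %in% idx), ,
                     drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  rownames(bonds) <- NULL
  molgraph(atoms, bonds, id = mol$id)
}

add_hydrogen <- function(mol, on) {
  # place the new H opposite the mean direction of existing neighbours
  adj <- adjacency(mol)
  pos <- coords(mol, on)
  nb <- adj[[on]]
  dir <- if (length(nb)) {
    v <- -colMeans(coords(mol, nb) - matrix(pos, length(nb), 3, byrow = TRUE))
    if (vnorm(v) < 1e-6) c(0, 0, 1) else unitv(v)
  } else c(0, 0, 1)
  newrow <- data.frame(elem = "H",
                       x = pos[1] + 1.02 * dir[1],
                       y = pos[2] + 1.02 * dir[2],
                       z = pos[3] + 1.02 * dir[3],
                       charge = 0L)
  atoms <- rbind(mol$atoms, newrow)
  bonds <- rbind(mol$bonds,
                 data.frame(a1 = on, a2 = nrow(atoms), order = 1L))
  molgraph(atoms, bonds, id = mol$id)
}

aromatic_rings_safe <- function(mol) {
  tryCatch(aromatic_rings(mol), error = function(e) list())
}
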