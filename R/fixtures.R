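#' Synthetic benzamide library specification
#'
#' Describes a seed-controlled synthetic library of
#' N-(2-aminophenyl)arylamide (benzamide-scaffold) molecules emulating an
#' HDAC1 inhibitor SAR series: a planted five-feature pharmacophore (one
#' acceptor on the amide carbonyl, donors on the amide NH and the
#' 2-aminophenyl NH2, and the two aromatic rings - the ADDRR motif)
#' common to every scaffold, with activity driven linearly by ring
#' substituents: polar para substituents on the aroyl ring are beneficial,
#' bulky meta/ortho substituents are penalized. IC50 values span 6 nM to
#' 50 uM; Gaussian noise (default sd 0.3 pIC50 units, a typical
#' inter-assay error) is added on the pIC50 scale.
#'
#' @param n_actives compounds targeted at the potent class (IC50 <= 10 nM).
#' @param n_moderate compounds targeted between the classes.
#' @param n_inactive compounds targeted at 5-50 uM.
#' @param n_decoys_per_active decoys generated per active by
#'   [generate_decoys()] (default 50).
#' @param noise_sigma pIC50 noise sd (default 0.3).
#' @param seed integer seed.
#' @return a `synthetic_library_spec` list.
#' @export
synthetic_library_spec <- function(n_actives = 20, n_moderate = 220,
                                   n_inactive = 60, n_decoys_per_active = 50,
                                   noise_sigma = 0.3, seed = 1) {
  stopifnot(n_actives >= 0, n_moderate >= 0, n_inactive >= 0,
            noise_sigma >= 0)
  structure(
    list(n_actives = n_actives, n_moderate = n_moderate,
         n_inactive = n_inactive,
         n_decoys_per_active = n_decoys_per_active,
         noise_sigma = noise_sigma, seed = seed,
         planted_motif = c("A", "D", "D", "R", "R")),
    class = "synthetic_library_spec")
}

## ------------------------------------------------------------------
## substituent chemistry tables

SUB_SMILES <- c(H = "", F = "F", Cl = "Cl", Me = "C", Et = "CC",
                iPr = "C(C)C", tBu = "C(C)(C)C", OMe = "OC", OH = "O",
                NH2 = "N", OEt = "OCC", CF3 = "C(F)(F)F", SMe = "SC",
                Ac = "C(C)=O", CO2Me = "C(=O)OC", CN = "C#N",
                SO2Me = "S(C)(=O)=O")

# additive pIC50 effects (uM scale) of the aroyl-ring substituents; the
# beneficial para substituents deliberately span different feature kinds
# (donor NH2, acceptor OMe, donor+acceptor OH, hydrophobe F) so that only
# the scaffold motif is common to every potent compound
PARA_EFFECTS <- c(H = 0, Me = 0.1, F = 0.55, OMe = 0.55, OH = 0.6, NH2 = 0.6)
META_EFFECTS <- c(H = 0, F = -0.15, Cl = -0.35, Me = -0.5, OMe = -0.7,
                  Et = -0.9, iPr = -1.4, tBu = -1.9)
ORTHO_EFFECTS <- c(H = 0, Cl = -0.3, Me = -0.4, Et = -0.8, iPr = -1.2,
                   tBu = -1.7)
ARYL_EFFECTS <- c(phenyl = 0, pyridyl = 0)
BASE_PIC50 <- 1.45

# pIC50 bounds implied by the 6 nM - 50 uM IC50 clip
PIC50_MAX <- -log10(6 / 1000)
PIC50_MIN <- -log10(50000 / 1000)

## ------------------------------------------------------------------
## template geometry builder

new_builder <- function(id) {
  env <- new.env(parent = emptyenv())
  env$elem <- character(); env$pos <- list(); env$charge <- integer()
  env$a1 <- integer(); env$a2 <- integer(); env$order <- integer()
  env$id <- id
  env
}

b_atom <- function(b, elem, pos, charge = 0L) {
  b$elem <- c(b$elem, elem)
  b$pos[[length(b$pos) + 1]] <- pos
  b$charge <- c(b$charge, charge)
  length(b$elem)
}

b_bond <- function(b, i, j, order = 1L) {
  b$a1 <- c(b$a1, i); b$a2 <- c(b$a2, j); b$order <- c(b$order, order)
  invisible(NULL)
}

b_molgraph <- function(b) {
  pos <- do.call(rbind, b$pos)
  molgraph(
    data.frame(elem = b$elem, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               charge = b$charge),
    data.frame(a1 = b$a1, a2 = b$a2, order = b$order),
    id = b$id
  )
}

# hexagon vertex positions: center, ring radius 1.395 A, vertex k at
# angle0 + (k-1)*60 degrees in the plane spanned by u, v
hex_vertices <- function(center, u, v, angle0 = 0) {
  t(vapply(0:5, function(k) {
    a <- (angle0 + k * 60) * pi / 180
    center + 1.395 * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}

# add an aromatic 6-ring with alternating bond orders; hetero: index (1..6)
# of a pyridine-type nitrogen or 0
b_aromatic_ring <- function(b, verts, hetero = 0L) {
  idx <- integer(6)
  for (k in 1:6) {
    idx[k] <- b_atom(b, if (k == hetero) "N" else "C", verts[k, ])
  }
  orders <- c(2L, 1L, 2L, 1L, 2L, 1L)
  for (k in 1:6) {
    b_bond(b, idx[k], idx[k %% 6 + 1], orders[k])
  }
  idx
}

# attach a substituent fragment at ring atom `at`, growing along unit
# direction u (radial), with p in-plane perpendicular and w out-of-plane
b_substituent <- function(b, at, u, p, w, name) {
  P <- b$pos[[at]]
  tet1 <- unitv(0.45 * u + 0.89 * w)
  tet2 <- unitv(0.45 * u - 0.6 * p - 0.55 * w)
  tet3 <- unitv(0.45 * u + 0.6 * p - 0.55 * w)
  add_h3 <- function(c_idx) {
    C <- b$pos[[c_idx]]
    for (d in list(tet1, tet2, tet3)) {
      h <- b_atom(b, "H", C + 1.09 * d)
      b_bond(b, c_idx, h)
    }
  }
  switch(name,
    H = {
      h <- b_atom(b, "H", P + 1.08 * u); b_bond(b, at, h)
    },
    F = {
      f <- b_atom(b, "F", P + 1.35 * u); b_bond(b, at, f)
    },
    Cl = {
      cl <- b_atom(b, "Cl", P + 1.74 * u); b_bond(b, at, cl)
    },
    Me = {
      c1 <- b_atom(b, "C", P + 1.50 * u); b_bond(b, at, c1); add_h3(c1)
    },
    Et = {
      c1 <- b_atom(b, "C", P + 1.50 * u); b_bond(b, at, c1)
      c2 <- b_atom(b, "C", b$pos[[c1]] + 1.53 * unitv(0.5 * u + 0.87 * w))
      b_bond(b, c1, c2)
      for (d in list(unitv(-0.5 * p - 0.5 * w + 0.2 * u),
                     unitv(0.5 * p - 0.5 * w + 0.2 * u))) {
        h <- b_atom(b, "H", b$pos[[c1]] + 1.09 * d); b_bond(b, c1, h)
      }
      add_h3(c2)
    },
    iPr = {
      c1 <- b_atom(b, "C", P + 1.50 * u); b_bond(b, at, c1)
      h <- b_atom(b, "H", b$pos[[c1]] + 1.09 * unitv(0.5 * u - 0.87 * w))
      b_bond(b, c1, h)
      for (s in c(-1, 1)) {
        c2 <- b_atom(b, "C",
                     b$pos[[c1]] + 1.53 * unitv(0.4 * u + s * 0.8 * p + 0.4 * w))
        b_bond(b, c1, c2); add_h3(c2)
      }
    },
    tBu = {
      c1 <- b_atom(b, "C", P + 1.50 * u); b_bond(b, at, c1)
      c2 <- b_atom(b, "C", b$pos[[c1]] + 1.53 * unitv(0.4 * u + 0.9 * w))
      b_bond(b, c1, c2); add_h3(c2)
      for (s in c(-1, 1)) {
        c3 <- b_atom(b, "C",
                     b$pos[[c1]] + 1.53 * unitv(0.4 * u + s * 0.8 * p - 0.45 * w))
        b_bond(b, c1, c3); add_h3(c3)
      }
    },
    OMe = {
      o <- b_atom(b, "O", P + 1.36 * u); b_bond(b, at, o)
      c1 <- b_atom(b, "C", b$pos[[o]] + 1.43 * unitv(0.5 * u + 0.87 * p))
      b_bond(b, o, c1); add_h3(c1)
    },
    OH = {
      o <- b_atom(b, "O", P + 1.36 * u); b_bond(b, at, o)
      h <- b_atom(b, "H", b$pos[[o]] + 0.97 * unitv(0.5 * u + 0.87 * p))
      b_bond(b, o, h)
    },
    NH2 = {
      n <- b_atom(b, "N", P + 1.40 * u); b_bond(b, at, n)
      for (s in c(-1, 1)) {
        h <- b_atom(b, "H", b$pos[[n]] + 1.01 * unitv(0.5 * u + s * 0.84 * p + 0.2 * w))
        b_bond(b, n, h)
      }
    },
    OEt = {
      o <- b_atom(b, "O", P + 1.36 * u); b_bond(b, at, o)
      c1 <- b_atom(b, "C", b$pos[[o]] + 1.43 * unitv(0.5 * u + 0.87 * p))
      b_bond(b, o, c1)
      for (d in list(unitv(0.3 * u - 0.4 * p + 0.85 * w),
                     unitv(0.3 * u - 0.4 * p - 0.85 * w))) {
        h <- b_atom(b, "H", b$pos[[c1]] + 1.09 * d); b_bond(b, c1, h)
      }
      c2 <- b_atom(b, "C", b$pos[[c1]] + 1.53 * unitv(0.87 * p - 0.5 * u))
      b_bond(b, c1, c2); add_h3(c2)
    },
    CF3 = {
      c1 <- b_atom(b, "C", P + 1.50 * u); b_bond(b, at, c1)
      for (d in list(tet1, tet2, tet3)) {
        f <- b_atom(b, "F", b$pos[[c1]] + 1.33 * d); b_bond(b, c1, f)
      }
    },
    SMe = {
      s_at <- b_atom(b, "S", P + 1.77 * u); b_bond(b, at, s_at)
      c1 <- b_atom(b, "C", b$pos[[s_at]] + 1.81 * unitv(0.5 * u + 0.87 * p))
      b_bond(b, s_at, c1); add_h3(c1)
    },
    Ac = {
      c1 <- b_atom(b, "C", P + 1.49 * u); b_bond(b, at, c1)
      o <- b_atom(b, "O", b$pos[[c1]] + 1.23 * unitv(0.5 * u + 0.87 * p))
      b_bond(b, c1, o, 2L)
      c2 <- b_atom(b, "C", b$pos[[c1]] + 1.51 * unitv(0.5 * u - 0.87 * p))
      b_bond(b, c1, c2); add_h3(c2)
    },
    CO2Me = {
      c1 <- b_atom(b, "C", P + 1.49 * u); b_bond(b, at, c1)
      o <- b_atom(b, "O", b$pos[[c1]] + 1.23 * unitv(0.5 * u + 0.87 * p))
      b_bond(b, c1, o, 2L)
      o2 <- b_atom(b, "O", b$pos[[c1]] + 1.34 * unitv(0.5 * u - 0.87 * p))
      b_bond(b, c1, o2)
      c2 <- b_atom(b, "C", b$pos[[o2]] + 1.43 * unitv(u))
      b_bond(b, o2, c2); add_h3(c2)
    },
    CN = {
      c1 <- b_atom(b, "C", P + 1.43 * u); b_bond(b, at, c1)
      n <- b_atom(b, "N", b$pos[[c1]] + 1.16 * u)
      b_bond(b, c1, n, 3L)
    },
    SO2Me = {
      s_at <- b_atom(b, "S", P + 1.77 * u); b_bond(b, at, s_at)
      for (sgn in c(-1, 1)) {
        o <- b_atom(b, "O", b$pos[[s_at]] + 1.44 * unitv(0.4 * u + sgn * 0.9 * w))
        b_bond(b, s_at, o, 2L)
      }
      cm <- b_atom(b, "C", b$pos[[s_at]] + 1.78 * unitv(0.5 * u + 0.87 * p))
      b_bond(b, s_at, cm); add_h3(cm)
    },
    stopf("unknown substituent %s", name)
  )
  invisible(NULL)
}

ring2_smiles <- function(aryl, para, meta, ortho) {
  tok <- function(s) if (s == "H") "" else sprintf("(%s)", SUB_SMILES[[s]])
  a3 <- if (aryl == "pyridyl") "n" else "c"
  # walk: attach, ortho(2'), ring N or CH (3'), para(4'), meta(5'), CH(6')
  paste0("c1c", tok(ortho), a3, "c", tok(para), "c", tok(meta), "c1")
}

#' Build one N-(2-aminophenyl)arylamide molecule from its substituent combo
#'
#' Returns the template-frame molgraph, its SMILES, the index set of the
#' aroyl-ring side (for torsional perturbation), the amide bond axis atoms
#' and the anchor geometry of the planted features.
#' @noRd
build_benzamide <- function(id, aryl = "phenyl", para = "H", meta = "H",
                            ortho = "H") {
  b <- new_builder(id)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  ## 2-aminophenyl ring centred at origin; amide attach vertex at angle 0
  r1 <- b_aromatic_ring(b, hex_vertices(c(0, 0, 0), ex, ey, 0))
  c_amide <- r1[1]                  # vertex at angle 0
  c_nh2 <- r1[2]                    # vertex at angle 60
  ## aromatic hydrogens on the remaining ring-1 carbons
  for (k in 3:6) {
    u <- unitv(b$pos[[r1[k]]])
    h <- b_atom(b, "H", b$pos[[r1[k]]] + 1.08 * u); b_bond(b, r1[k], h)
  }
  ## aniline NH2 (neutral at pH 7.4)
  u2 <- unitv(b$pos[[c_nh2]])
  n_anil <- b_atom(b, "N", b$pos[[c_nh2]] + 1.40 * u2)
  b_bond(b, c_nh2, n_anil)
  p2 <- unitv(pracma_cross(ez, u2))
  for (s in c(-1, 1)) {
    h <- b_atom(b, "H", b$pos[[n_anil]] + 1.01 * unitv(0.5 * u2 + s * 0.8 * p2 + 0.15 * ez))
    b_bond(b, n_anil, h)
  }
  ## amide N at the radial direction of c_amide (+x)
  n_am <- b_atom(b, "N", b$pos[[c_amide]] + 1.41 * ex)
  b_bond(b, c_amide, n_am)
  h_am <- b_atom(b, "H", b$pos[[n_am]] + 1.01 * unitv(c(0.5, 0.866, 0)))
  b_bond(b, n_am, h_am)
  c_co <- b_atom(b, "C", b$pos[[n_am]] + 1.36 * unitv(c(0.5, -0.866, 0)))
  b_bond(b, n_am, c_co)
  o_co <- b_atom(b, "O", b$pos[[c_co]] + 1.23 * unitv(c(-0.5, -0.866, 0)))
  b_bond(b, c_co, o_co, 2L)
  ## aroyl ring along +x from the carbonyl carbon
  n_before_ring2 <- length(b$elem)
  c2_center <- b$pos[[c_co]] + (1.49 + 1.395) * ex
  verts <- hex_vertices(c2_center, ex, ey, 180)  # vertex 1 points back
  hetero <- if (aryl == "pyridyl") 3L else 0L
  r2 <- b_aromatic_ring(b, verts, hetero = hetero)
  b_bond(b, c_co, r2[1])
  ## substituents: walk position 2 = ortho, 4 = para, 5 = meta, 6 = H
  subs <- c(`2` = ortho, `4` = para, `5` = meta, `6` = "H")
  for (k in names(subs)) {
    ki <- as.integer(k)
    if (aryl == "pyridyl" && ki == 3) next
    at <- r2[ki]
    u <- unitv(b$pos[[at]] - c2_center)
    p <- unitv(pracma_cross(ez, u))
    b_substituent(b, at, u, p, ez, subs[[k]])
  }
  if (aryl == "phenyl") {
    at <- r2[3]
    u <- unitv(b$pos[[at]] - c2_center)
    h <- b_atom(b, "H", b$pos[[at]] + 1.08 * u); b_bond(b, at, h)
  }
  mol <- b_molgraph(b)
  ring2_side <- setdiff(seq_len(n_atoms(mol)), seq_len(n_before_ring2))
  smiles <- paste0("O=C(Nc1ccccc1N)", ring2_smiles(aryl, para, meta, ortho))
  ## planted feature anchors (template frame)
  anchors <- rbind(
    A = b$pos[[o_co]],
    D1 = b$pos[[n_am]],
    D2 = b$pos[[n_anil]],
    R1 = c(0, 0, 0),
    R2 = c2_center
  )
  list(mol = mol, smiles = smiles, ring2_side = ring2_side,
       amide_axis = c(c_co, r2[1]), anchors = anchors,
       para_anchor = list(center = verts[4, ] + 1.8 * unitv(verts[4, ] - c2_center)),
       penalty_anchor = list(
         meta = verts[5, ] + 1.8 * unitv(verts[5, ] - c2_center),
         ortho = verts[2, ] + 1.8 * unitv(verts[2, ] - c2_center)))
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# ensemble: planted conformer (jitter + rigid motion) plus alternates with
# the aroyl ring rotated about the amide C - ring bond
fixture_ensemble <- function(built, n_alt = 2, jitter_sd = 0.015,
                             rigid = TRUE) {
  mol <- built$mol
  xyz0 <- coords(mol)
  confs <- list(); energies <- numeric()
  make_conf <- function(xyz, e) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter_sd),
                        nrow(xyz), 3)
    if (rigid) {
      R <- random_rotation()
      t <- stats::runif(3, -4, 4)
      xyz <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
    }
    confs[[length(confs) + 1]] <<- xyz
    energies <<- c(energies, e)
  }
  make_conf(xyz0, 0)
  if (n_alt > 0 && length(built$ring2_side)) {
    ax1 <- built$amide_axis[1]; ax2 <- built$amide_axis[2]
    for (j in seq_len(n_alt)) {
      ang <- sample(c(-1, 1), 1) * stats::runif(1, 25, 75) * pi / 180
      R <- rotation_about_axis(xyz0[ax2, ] - xyz0[ax1, ], ang)
      xyz <- xyz0
      mv <- built$ring2_side
      pts <- sweep(xyz[mv, , drop = FALSE], 2, xyz0[ax1, ])
      xyz[mv, ] <- sweep(pts %*% t(R), 2, -xyz0[ax1, ])
      make_conf(xyz, stats::runif(1, 2, 15))
    }
  }
  conformer_ensemble(mol, confs, energies)
}

## ------------------------------------------------------------------
## library generation

benzamide_combo_table <- function() {
  combos <- expand.grid(
    aryl = names(ARYL_EFFECTS), para = names(PARA_EFFECTS),
    meta = names(META_EFFECTS), ortho = names(ORTHO_EFFECTS),
    stringsAsFactors = FALSE)
  combos$pic50_true <- BASE_PIC50 +
    ARYL_EFFECTS[combos$aryl] + PARA_EFFECTS[combos$para] +
    META_EFFECTS[combos$meta] + ORTHO_EFFECTS[combos$ortho]
  combos
}

#' Generate a synthetic benzamide library with a planted pharmacophore
#'
#' Enumerates substituted N-(2-aminophenyl)arylamide scaffolds (aroyl ring
#' phenyl or pyridyl; substituents varying bulk and polarity), assigns
#' noiseless pIC50 from the additive substituent-effect model, adds
#' Gaussian noise and clips IC50 to the 6 nM - 50 uM range. Every
#' molecule carries the intact planted ADDRR motif; activity classes are
#' assigned from the final IC50 by [classify_activity()]. Deterministic
#' per seed.
#'
#' @param spec a [synthetic_library_spec()].
#' @return list with `records` (molecule records with conformer
#'   ensembles), `activity` (data.frame id, ic50_nM, pic50, class),
#'   `ground_truth` (planted geometry, effect tables, region anchors and
#'   per-compound noiseless activities).
#' @export
generate_library <- function(spec) {
  combos <- benzamide_combo_table()
  # noiseless class bands with margin against noise-induced flips
  act_pool <- which(combos$pic50_true >= 2.0)
  inact_pool <- which(combos$pic50_true >= -1.65 & combos$pic50_true <= -0.75)
  mod_pool <- which(combos$pic50_true > -0.45 & combos$pic50_true < 1.75)
  records <- list(); rows <- list(); truth_rows <- list()
  ref_built <- NULL
  with_seed(spec$seed, {
    pick <- c(sample(act_pool, spec$n_actives, replace = TRUE),
              sample(mod_pool, spec$n_moderate, replace = TRUE),
              sample(inact_pool, spec$n_inactive, replace = TRUE))
    for (i in seq_along(pick)) {
      cb <- combos[pick[i], ]
      id <- sprintf("cmpd_%03d", i)
      built <- build_benzamide(id, cb$aryl, cb$para, cb$meta, cb$ortho)
      if (is.null(ref_built)) ref_built <- built
      pic_true <- cb$pic50_true
      pic_obs <- pic_true + stats::rnorm(1, 0, spec$noise_sigma)
      pic_obs <- max(PIC50_MIN, min(PIC50_MAX, pic_obs))
      ic50 <- from_pic50(pic_obs)
      rec <- molecule_record(built$mol, id, ic50 = ic50)
      rec$ensemble <- fixture_ensemble(built)
      rec$smiles <- built$smiles
      rec$logP <- benzamide_properties(cb$aryl, cb$para, cb$meta,
                                       cb$ortho)$logP
      records[[length(records) + 1]] <- rec
      rows[[length(rows) + 1]] <- data.frame(
        id = id, ic50_nM = ic50, pic50 = pic_obs,
        class = rec$activity_class, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        id = id, aryl = cb$aryl, para = cb$para, meta = cb$meta,
        ortho = cb$ortho, pic50_true = pic_true, pic50_obs = pic_obs,
        stringsAsFactors = FALSE)
    }
  })
  names(records) <- vapply(records, `[[`, character(1), "id")
  anchors <- ref_built$anchors
  ground_truth <- list(
    planted_features = data.frame(
      kind = c("A", "D", "D", "R", "R"),
      x = anchors[, 1], y = anchors[, 2], z = anchors[, 3]),
    planted_distances = as.matrix(stats::dist(anchors)),
    effects = list(base = BASE_PIC50, aryl = ARYL_EFFECTS,
                   para = PARA_EFFECTS, meta = META_EFFECTS,
                   ortho = ORTHO_EFFECTS),
    beneficial_region = list(center = ref_built$para_anchor$center,
                             radius = 3.0),
    penalty_regions = list(
      list(center = ref_built$penalty_anchor$meta, radius = 3.0),
      list(center = ref_built$penalty_anchor$ortho, radius = 3.0)),
    noise_sigma = spec$noise_sigma,
    seed = spec$seed,
    compounds = do.call(rbind, truth_rows)
  )
  list(records = records,
       activity = do.call(rbind, rows),
       ground_truth = ground_truth)
}

## ------------------------------------------------------------------
## decoys

DECOY_SCAFFOLDS <- c("ketone", "propanoyl", "ester", "ether", "ethyl",
                     "biphenyl", "sulfone")
# donor-free substituent pool for decoys; the heavy-but-polar entries
# (OEt, CF3, SMe, Ac, CO2Me) decouple molecular weight from logP so the
# matching windows stay satisfiable
DECOY_SUBS <- c("H", "F", "Cl", "Me", "Et", "iPr", "tBu", "OMe", "OEt",
                "CF3", "SMe", "Ac", "CO2Me", "CN", "SO2Me")

# fragment-additive property tables for the matching windows: molecular
# weight increments over H, and Hansch pi hydrophobicity constants for
# aromatic substituents; scaffold logP values are literature figures for
# the parent compounds
SUB_MW <- c(H = 0, F = 18.0, Cl = 34.4, Me = 14.03, Et = 28.05,
            iPr = 42.08, tBu = 56.11, OMe = 30.03, OH = 16.0, NH2 = 15.02,
            OEt = 44.05, CF3 = 68.0, SMe = 46.09, Ac = 42.04, CO2Me = 58.04,
            CN = 25.03, SO2Me = 78.09)
SUB_PI <- c(H = 0, F = 0.14, Cl = 0.71, Me = 0.56, Et = 1.02,
            iPr = 1.53, tBu = 1.98, OMe = -0.02, OH = -0.67, NH2 = -1.23,
            OEt = 0.38, CF3 = 0.88, SMe = 0.61, Ac = -0.55, CO2Me = -0.01,
            CN = -0.57, SO2Me = -1.63)
SUB_HBA <- c(H = 0, F = 0, Cl = 0, Me = 0, Et = 0, iPr = 0, tBu = 0,
             OMe = 1, OH = 1, NH2 = 1, OEt = 1, CF3 = 0, SMe = 0,
             Ac = 1, CO2Me = 2, CN = 1, SO2Me = 2)
DECOY_SCAFFOLD_MW <- c(ketone = 120.15, propanoyl = 134.18, ester = 136.15,
                       ether = 108.14, ethyl = 106.17, biphenyl = 154.21,
                       sulfone = 156.21)
DECOY_SCAFFOLD_LOGP <- c(ketone = 1.58, propanoyl = 2.10, ester = 2.12,
                         ether = 2.11, ethyl = 3.15, biphenyl = 4.01,
                         sulfone = 0.5)
DECOY_SCAFFOLD_HBA <- c(ketone = 1, propanoyl = 1, ester = 2, ether = 1,
                        ethyl = 0, biphenyl = 0, sulfone = 2)
BENZAMIDE_SCAFFOLD_MW <- 212.25
BENZAMIDE_SCAFFOLD_LOGP <- c(phenyl = 2.2, pyridyl = 0.9)

#' Fragment-additive logP and molecular weight of a library compound
#' @noRd
benzamide_properties <- function(aryl, para, meta, ortho) {
  list(
    MW = BENZAMIDE_SCAFFOLD_MW + (if (aryl == "pyridyl") 1.0 else 0) +
      SUB_MW[[para]] + SUB_MW[[meta]] + SUB_MW[[ortho]],
    logP = BENZAMIDE_SCAFFOLD_LOGP[[aryl]] +
      SUB_PI[[para]] + SUB_PI[[meta]] + SUB_PI[[ortho]]
  )
}

build_decoy <- function(id, scaffold, para = "H", meta = "H", ortho = "H") {
  b <- new_builder(id)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  verts <- hex_vertices(c(0, 0, 0), ex, ey, 0)
  r <- b_aromatic_ring(b, verts)
  attach <- r[1]
  u0 <- ex
  head_smiles <- switch(scaffold,
    ketone = {
      c_co <- b_atom(b, "C", b$pos[[attach]] + 1.49 * u0)
      b_bond(b, attach, c_co)
      o <- b_atom(b, "O", b$pos[[c_co]] + 1.23 * unitv(0.5 * u0 + 0.87 * ey))
      b_bond(b, c_co, o, 2L)
      cm <- b_atom(b, "C", b$pos[[c_co]] + 1.51 * unitv(0.5 * u0 - 0.87 * ey))
      b_bond(b, c_co, cm)
      for (d in list(c(0.2, -0.5, 0.84), c(0.2, -0.5, -0.84), c(0.95, -0.3, 0))) {
        h <- b_atom(b, "H", b$pos[[cm]] + 1.09 * unitv(d)); b_bond(b, cm, h)
      }
      "CC(=O)"
    },
    propanoyl = {
      c_co <- b_atom(b, "C", b$pos[[attach]] + 1.49 * u0)
      b_bond(b, attach, c_co)
      o <- b_atom(b, "O", b$pos[[c_co]] + 1.23 * unitv(0.5 * u0 + 0.87 * ey))
      b_bond(b, c_co, o, 2L)
      c1 <- b_atom(b, "C", b$pos[[c_co]] + 1.51 * unitv(0.5 * u0 - 0.87 * ey))
      b_bond(b, c_co, c1)
      for (d in list(c(0.2, -0.4, 0.89), c(0.2, -0.4, -0.89))) {
        h <- b_atom(b, "H", b$pos[[c1]] + 1.09 * unitv(d)); b_bond(b, c1, h)
      }
      c2 <- b_atom(b, "C", b$pos[[c1]] + 1.53 * unitv(0.95 * u0 - 0.3 * ey))
      b_bond(b, c1, c2)
      for (d in list(c(0.3, 0.8, 0.5), c(0.3, 0.8, -0.5), c(0.95, -0.2, 0))) {
        h <- b_atom(b, "H", b$pos[[c2]] + 1.09 * unitv(d)); b_bond(b, c2, h)
      }
      "CCC(=O)"
    },
    sulfone = {
      s_at <- b_atom(b, "S", b$pos[[attach]] + 1.77 * u0)
      b_bond(b, attach, s_at)
      for (sgn in c(-1, 1)) {
        o <- b_atom(b, "O", b$pos[[s_at]] + 1.44 * unitv(0.4 * u0 + sgn * 0.9 * ez))
        b_bond(b, s_at, o, 2L)
      }
      cm <- b_atom(b, "C", b$pos[[s_at]] + 1.78 * unitv(0.5 * u0 - 0.87 * ey))
      b_bond(b, s_at, cm)
      for (d in list(c(0.2, -0.5, 0.84), c(0.2, -0.5, -0.84), c(0.95, -0.3, 0))) {
        h <- b_atom(b, "H", b$pos[[cm]] + 1.09 * unitv(d)); b_bond(b, cm, h)
      }
      "CS(=O)(=O)"
    },
    ester = {
      c_co <- b_atom(b, "C", b$pos[[attach]] + 1.49 * u0)
      b_bond(b, attach, c_co)
      o <- b_atom(b, "O", b$pos[[c_co]] + 1.23 * unitv(0.5 * u0 + 0.87 * ey))
      b_bond(b, c_co, o, 2L)
      o2 <- b_atom(b, "O", b$pos[[c_co]] + 1.34 * unitv(0.5 * u0 - 0.87 * ey))
      b_bond(b, c_co, o2)
      cm <- b_atom(b, "C", b$pos[[o2]] + 1.43 * unitv(u0))
      b_bond(b, o2, cm)
      for (d in list(c(0.2, -0.5, 0.84), c(0.2, -0.5, -0.84), c(0.95, 0.3, 0))) {
        h <- b_atom(b, "H", b$pos[[cm]] + 1.09 * unitv(d)); b_bond(b, cm, h)
      }
      "COC(=O)"
    },
    ether = {
      o <- b_atom(b, "O", b$pos[[attach]] + 1.36 * u0)
      b_bond(b, attach, o)
      cm <- b_atom(b, "C", b$pos[[o]] + 1.43 * unitv(0.5 * u0 + 0.87 * ey))
      b_bond(b, o, cm)
      for (d in list(c(0.2, 0.5, 0.84), c(0.2, 0.5, -0.84), c(0.95, 0.3, 0))) {
        h <- b_atom(b, "H", b$pos[[cm]] + 1.09 * unitv(d)); b_bond(b, cm, h)
      }
      "CO"
    },
    ethyl = {
      c1 <- b_atom(b, "C", b$pos[[attach]] + 1.50 * u0)
      b_bond(b, attach, c1)
      c2 <- b_atom(b, "C", b$pos[[c1]] + 1.53 * unitv(0.5 * u0 + 0.87 * ez))
      b_bond(b, c1, c2)
      for (d in list(c(0.2, 0.9, -0.4), c(0.2, -0.9, -0.4))) {
        h <- b_atom(b, "H", b$pos[[c1]] + 1.09 * unitv(d)); b_bond(b, c1, h)
      }
      for (d in list(c(0.3, 0.8, 0.5), c(0.3, -0.8, 0.5), c(0.95, 0, 0.3))) {
        h <- b_atom(b, "H", b$pos[[c2]] + 1.09 * unitv(d)); b_bond(b, c2, h)
      }
      "CC"
    },
    biphenyl = {
      c2_center <- b$pos[[attach]] + (1.48 + 1.395) * u0
      verts2 <- hex_vertices(c2_center, ex, ey, 180)
      # twist the second ring slightly out of plane to avoid H clashes
      for (k in 1:6) {
        d <- verts2[k, ] - c2_center
        ang <- 35 * pi / 180
        R <- rotation_about_axis(u0, ang)
        verts2[k, ] <- c2_center + as.vector(R %*% d)
      }
      r2 <- b_aromatic_ring(b, verts2)
      b_bond(b, attach, r2[1])
      for (k in 2:6) {
        u <- unitv(b$pos[[r2[k]]] - c2_center)
        h <- b_atom(b, "H", b$pos[[r2[k]]] + 1.08 * u); b_bond(b, r2[k], h)
      }
      "c1ccccc1-"
    },
    stopf("unknown decoy scaffold %s", scaffold))
  ## ring substituents (walk position 2 = ortho, 4 = para, 5 = meta)
  subs <- c(`2` = ortho, `3` = "H", `4` = para, `5` = meta, `6` = "H")
  for (k in names(subs)) {
    at <- r[as.integer(k)]
    u <- unitv(b$pos[[at]])
    p <- unitv(pracma_cross(ez, u))
    b_substituent(b, at, u, p, ez, subs[[k]])
  }
  tok <- function(s) if (s == "H") "" else sprintf("(%s)", SUB_SMILES[[s]])
  smiles <- paste0(head_smiles,
                   "c1c", tok(ortho), "cc", tok(para), "c", tok(meta), "c1")
  list(mol = b_molgraph(b), smiles = smiles)
}

#' Linear-path 2D fingerprint of a molecular graph
#'
#' Enumerates all simple heavy-atom paths of up to `max_len` atoms,
#' labels each path by its element / bond-order sequence (taking the
#' lexicographically smaller reading direction) and hashes the labels
#' into a fixed-width bit vector - the classic linear-fragment path
#' fingerprint used for 2D dissimilarity filtering.
#'
#' @param mol a [molgraph()].
#' @param max_len maximum path length in atoms (default 6).
#' @param nbits fingerprint width (default 1024).
#' @return logical vector of length `nbits`.
#' @export
path_fingerprint <- function(mol, max_len = 6, nbits = 1024) {
  hv <- heavy_idx(mol)
  remap <- integer(n_atoms(mol)); remap[hv] <- seq_along(hv)
  elem <- mol$atoms$elem[hv]
  keep <- mol$bonds$a1 %in% hv & mol$bonds$a2 %in% hv
  b <- mol$bonds[keep, , drop = FALSE]
  n <- length(hv)
  adj <- vector("list", n); bord <- vector("list", n)
  for (i in seq_len(nrow(b))) {
    x <- remap[b$a1[i]]; y <- remap[b$a2[i]]; o <- b$order[i]
    adj[[x]] <- c(adj[[x]], y); bord[[x]] <- c(bord[[x]], o)
    adj[[y]] <- c(adj[[y]], x); bord[[y]] <- c(bord[[y]], o)
  }
  labels <- character(0)
  walk <- function(path, lab) {
    labels[[length(labels) + 1]] <<- lab
    if (length(path) == max_len) return()
    last <- path[length(path)]
    nb <- adj[[last]]
    for (j in seq_along(nb)) {
      w <- nb[j]
      if (!(w %in% path)) {
        walk(c(path, w), paste0(lab, bord[[last]][j], elem[w]))
      }
    }
  }
  for (s in seq_len(n)) walk(s, elem[s])
  # canonical direction: keep the smaller of the two readings
  canon <- vapply(labels, function(l) {
    r <- rev_path_label(l)
    if (r < l) r else l
  }, character(1), USE.NAMES = FALSE)
  canon <- unique(canon)
  bits <- logical(nbits)
  for (l in canon) {
    h <- 7
    for (ch in utf8ToInt(l)) h <- (h * 31 + ch) %% 1048573
    bits[h %% nbits + 1] <- TRUE
  }
  bits
}

rev_path_label <- function(lab) {
  # tokens: element symbols ([A-Z][a-z]?) and single-digit bond orders
  toks <- regmatches(lab, gregexpr("[A-Z][a-z]?|[0-9]", lab))[[1]]
  paste(rev(toks), collapse = "")
}

#' Tanimoto similarity of two bit vectors
#' @param a,b logical vectors of equal length.
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Generate property-matched decoys for a set of actives
#'
#' Samples from a combinatorial pool of donor-free, non-amide scaffolds
#' (aryl ketones, esters, ethers, alkylbenzenes, biphenyls with varied
#' ring substituents), filtered per paired active to molecular weight
#' within +/- 25, computed logP (fragment-additive Hansch pi-constant
#' estimate, the same scheme used for the actives) within +/- 1,
#' identical net formal charge, 2D path-fingerprint Tanimoto < 0.4
#' against every active, and Lipinski drug-likeness. Deterministic per
#' seed; exhausting the pool yields a warning with the achieved count.
#'
#' @param actives list of `molecule_record`s from [generate_library()].
#' @param n_per decoys per active (default 50).
#' @param seed integer seed.
#' @param tanimoto_max fingerprint similarity ceiling (default 0.4).
#' @return list of decoy `molecule_record`s (role `"decoy"`, single
#'   conformer each).
#' @export
generate_decoys <- function(actives, n_per = 50, seed = 1,
                            tanimoto_max = 0.4) {
  if (!length(actives)) stopf("need at least one active")
  if (n_per == 0) return(list())
  pool <- expand.grid(scaffold = DECOY_SCAFFOLDS, para = DECOY_SUBS,
                      meta = DECOY_SUBS, ortho = DECOY_SUBS,
                      stringsAsFactors = FALSE)
  pool$MW <- DECOY_SCAFFOLD_MW[pool$scaffold] + SUB_MW[pool$para] +
    SUB_MW[pool$meta] + SUB_MW[pool$ortho]
  pool$logP <- DECOY_SCAFFOLD_LOGP[pool$scaffold] + SUB_PI[pool$para] +
    SUB_PI[pool$meta] + SUB_PI[pool$ortho]
  pool$HBA <- DECOY_SCAFFOLD_HBA[pool$scaffold] + SUB_HBA[pool$para] +
    SUB_HBA[pool$meta] + SUB_HBA[pool$ortho]
  # Lipinski: these scaffolds carry no H-bond donors by construction
  available <- which(pool$MW <= 500 & pool$logP <= 5 & pool$HBA <= 10)
  act_fps <- lapply(actives, function(r) path_fingerprint(r$mol))
  act_logp <- vapply(actives, function(r) {
    r$logP %||% BENZAMIDE_SCAFFOLD_LOGP[["phenyl"]]
  }, numeric(1))
  decoys <- list()
  with_seed(seed, {
    for (ai in seq_along(actives)) {
      a <- actives[[ai]]
      amw <- mol_weight(a$mol)
      acharge <- sum(a$mol$atoms$charge)
      cand <- available[
        abs(pool$MW[available] - amw) <= 25 &
          abs(pool$logP[available] - act_logp[ai]) <= 1 &
          0L == acharge]
      got <- 0L
      while (got < n_per && length(cand)) {
        t <- if (length(cand) == 1) cand else sample(cand, 1)
        cand <- setdiff(cand, t)
        available <- setdiff(available, t)
        id <- sprintf("decoy_%04d", length(decoys) + 1)
        built <- build_decoy(id, pool$scaffold[t], pool$para[t],
                             pool$meta[t], pool$ortho[t])
        fp <- path_fingerprint(built$mol)
        sims <- vapply(act_fps, function(af) tanimoto(fp, af), numeric(1))
        if (max(sims) >= tanimoto_max) next
        rec <- molecule_record(built$mol, id)
        rec$role <- "decoy"
        rec$smiles <- built$smiles
        rec$ensemble <- fixture_ensemble(built, n_alt = 0)
        rec$paired_active <- a$id
        decoys[[length(decoys) + 1]] <- rec
        got <- got + 1L
      }
      if (got < n_per) {
        warnf("decoy pool exhausted for active %s: %d of %d generated",
              a$id, got, n_per)
      }
    }
  })
  names(decoys) <- vapply(decoys, `[[`, character(1), "id")
  decoys
}

## ------------------------------------------------------------------
## file output

#' Write a generated library to disk
#'
#' Emits SMILES (`library.smi`), an SDF with every conformer as its own
#' record tagged `<rel_energy_kJmol>` (`library.sdf`), the activity CSV
#' (`activity.csv`, molprep dialect `id,ic50_nM`) and the ground-truth
#' JSON (`ground_truth.json`).
#'
#' @param lib output of [generate_library()].
#' @param dir output directory (created if missing).
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smi <- vapply(lib$records, function(r) sprintf("%s\t%s", r$smiles, r$id),
                character(1))
  writeLines(smi, file.path(dir, "library.smi"))
  utils::write.csv(lib$activity[, c("id", "ic50_nM")],
                   file.path(dir, "activity.csv"), row.names = FALSE)
  sdfs <- list()
  for (r in lib$records) {
    for (ci in seq_along(r$ensemble$conformers)) {
      cf <- r$ensemble$conformers[[ci]]
      mol <- set_coords(r$mol, cf$xyz)
      mol$id <- sprintf("%s_conf%d", r$id, ci)
      sdfs[[length(sdfs) + 1]] <- molgraph_to_sdf(
        mol, data = c(rel_energy_kJmol = format(cf$rel_energy)))
    }
  }
  sdfset <- methods::new("SDFset", SDF = sdfs,
                         ID = vapply(sdfs, function(s) s@header[["Molecule_Name"]],
                                     character(1)))
  ChemmineR::write.SDF(sdfset, file.path(dir, "library.sdf"))
  gt <- lib$ground_truth
  gt$planted_distances <- as.data.frame(gt$planted_distances)
  writeLines(as.character(jsonlite::toJSON(gt, auto_unbox = TRUE,
                                           digits = NA, dataframe = "columns")),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}
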