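# Conformer embedding, mapping, superposition, clashes, torsions, ranking.

test_that("embedding is deterministic and respects ideal geometry", {
  methane <- parse_smiles("C")
  c1 <- embed_conformer(methane, seed = 3)
  c2 <- embed_conformer(methane, seed = 3)
  expect_identical(c1$coords, c2$coords)
  ch <- sqrt(rowSums((c1$coords[-1, , drop = FALSE] -
                      matrix(c1$coords[1, ], 4, 3, byrow = TRUE))^2))
  expect_true(all(abs(ch - 1.09) <= 0.16))

  hexane <- embed_conformer(parse_smiles("C1CCCCC1"), seed = 1)
  cc <- hexane$bonds[hexane$elements[hexane$bonds$a1 + 1] == "C" &
                     hexane$elements[hexane$bonds$a2 + 1] == "C", ]
  d <- sqrt(rowSums((hexane$coords[cc$a1 + 1, ] - hexane$coords[cc$a2 + 1, ])^2))
  expect_true(all(abs(d - 1.54) <= 0.23))
  # heavy-atom non-bonded separation stays open
  heavy <- which(hexane$elements != "H")
  dm <- as.matrix(dist(hexane$coords[heavy, ]))
  bonded <- matrix(FALSE, length(heavy), length(heavy))
  for (k in seq_len(nrow(cc))) {
    i <- match(cc$a1[k] + 1, heavy); j <- match(cc$a2[k] + 1, heavy)
    bonded[i, j] <- bonded[j, i] <- TRUE
  }
  diag(dm) <- Inf
  expect_true(all(dm[!bonded] >= 1.8))
})

test_that("common substructure mapping finds forced answers", {
  toluene <- parse_smiles("Cc1ccccc1")
  benzene <- parse_smiles("c1ccccc1")
  self_map <- common_substructure_map(toluene, toluene)
  expect_equal(nrow(self_map), n_atoms(toluene))

  ring_map <- common_substructure_map(toluene, benzene)
  expect_equal(nrow(ring_map), 6L)
  expect_true(all(toluene$atoms$aromatic[ring_map$query_atom + 1]))

  expect_error(common_substructure_map(parse_smiles("CC"), benzene),
               class = "NoTemplateOverlapError")
})

test_that("MCS equals the exhaustive-search oracle on fused-ring toys", {
  pairs <- list(
    c("c1ccc2ccccc2c1", "c1ccccc1"),       # naphthalene vs benzene
    c("C1CC2CCC1C2", "C1CCCCC1"),          # norbornane vs cyclohexane
    c("c1ccoc1C", "c1ccsc1C"),             # furan vs thiophene toys
    c("C1CCC2(CC1)CCCC2", "C1CCCCC1")      # spiro vs cyclohexane
  )
  for (p in pairs) {
    q <- parse_smiles(p[1]); t <- parse_smiles(p[2])
    got <- tryCatch(nrow(common_substructure_map(q, t, min_size = 2L)),
                    NoTemplateOverlapError = function(e) 0L)
    expect_equal(got, oracle_mcs_size(q, t), label = paste(p, collapse = " vs "))
  }
})

test_that("superposition recovers rigid motions exactly", {
  tol <- parse_smiles("Cc1ccccc1")
  conf <- embed_conformer(tol, seed = 5)
  mapping <- common_substructure_map(tol, tol)

  same <- template_superimpose(conf, conf, mapping)
  expect_lt(same$rmsd, 1e-12)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- conf
  moved$coords <- sweep(conf$coords %*% R, 2, c(5, 5, 5), "+")
  back <- template_superimpose(moved, conf, mapping)
  expect_lt(back$rmsd, 1e-10)
  expect_equal(back$conformer$coords, conf$coords, tolerance = 1e-8)

  expect_error(template_superimpose(conf, conf, mapping[1:2, ]),
               class = "DegenerateAlignmentError")
})

test_that("closed-form rmsd matches the rotation-grid oracle", {
  # tabulated distorted 6-atom toy pair
  P <- matrix(c(0, 0, 0,  1.5, 0, 0,  2.2, 1.3, 0,
                1.6, 2.6, 0.3,  0.2, 2.7, 0.4,  -0.6, 1.4, 0.1),
              ncol = 3, byrow = TRUE)
  set.seed(42)
  true_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(true_R) < 0) true_R[, 1] <- -true_R[, 1]
  Q <- sweep(P %*% true_R, 2, c(3, -2, 1), "+") +
    matrix(rnorm(18, 0, 0.1), ncol = 3)

  closed <- dckdesign:::.kabsch(P, Q)$rmsd
  grid <- oracle_superposition_rmsd(P, Q)
  expect_lt(abs(closed - grid), 1e-4)
  expect_lte(closed, grid + 1e-4)     # optimality

  # invariance: rigid motion of either input leaves the minimised rmsd
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(dckdesign:::.kabsch(sweep(P %*% Rz, 2, c(1, 2, 3), "+"), Q)$rmsd,
               closed, tolerance = 1e-10)
  expect_equal(dckdesign:::.kabsch(P, sweep(Q %*% Rz, 2, c(-4, 0, 2), "+"))$rmsd,
               closed, tolerance = 1e-10)
})

test_that("clash counts equal the all-pairs reference on random fixtures", {
  vdw <- as.list(dckdesign:::.vdw_radii())
  lig_mol <- parse_smiles("CCO")
  set.seed(7)
  for (rep_i in seq_len(100)) {
    n_l <- sample(3:8, 1); n_p <- sample(1:10, 1)
    lig_el <- sample(c("C", "N", "O"), n_l, replace = TRUE)
    coords <- matrix(runif(3 * n_l, 0, 6), ncol = 3)
    # chain bonds 1-2, 2-3, ... so topological exclusion is exercised
    bonds <- data.frame(a1 = 0:(n_l - 2), a2 = 1:(n_l - 1), order = 1L)
    conf <- make_conformer(lig_mol, lig_el, coords, bonds)
    pocket_xyz <- matrix(runif(3 * n_p, -2, 8), ncol = 3)
    pocket <- receptor_pocket(pocket_xyz, rep("C", n_p))
    scale <- runif(1, 0.4, 1)
    got <- clash_scores(conf, pocket, scale = scale)
    topo <- abs(outer(seq_len(n_l), seq_len(n_l), "-"))   # chain distances
    want <- oracle_clash_counts(coords, lig_el, pocket_xyz, rep("C", n_p),
                                topo, scale, vdw)
    expect_identical(got, want)
  }
  expect_error(clash_scores(make_conformer(lig_mol, c("Xx", "C", "C"),
                                           matrix(0, 3, 3),
                                           data.frame(a1 = 0:1, a2 = 1:2, order = 1L)),
                            NULL),
               class = "ConfigError")
})

test_that("clash counts are monotone in the overlap scale", {
  conf <- embed_conformer(parse_smiles("CCCCO"), seed = 2)
  pocket <- pocket_shell(conf, radius = 4, n_points = 32)
  scales <- c(0.3, 0.5, 0.7, 0.9, 1)
  counts <- t(vapply(scales, function(s) clash_scores(conf, pocket, s),
                     integer(2)))
  expect_true(all(diff(counts[, "inter"]) >= 0))
  expect_true(all(diff(counts[, "intra"]) >= 0))
})

test_that("torsion windows flag eclipsed but not staggered butane", {
  butane <- parse_smiles("CCCC")
  geom <- function(dihedral_deg) {
    # C2 at origin, C3 on x; C1 in the +y half-plane; C4 placed at the
    # requested dihedral with a 111-degree bond angle
    phi <- dihedral_deg * pi / 180
    p2 <- c(0, 0, 0); p3 <- c(1.53, 0, 0)
    p1 <- p2 + 1.53 * c(-cos(69 * pi / 180), sin(69 * pi / 180), 0)
    p4 <- p3 + 1.53 * c(cos(69 * pi / 180),
                        sin(69 * pi / 180) * cos(phi),
                        sin(69 * pi / 180) * sin(phi))
    rbind(p1, p2, p3, p4)
  }
  bonds <- butane$bonds
  anti <- make_conformer(butane, rep("C", 4), geom(180), bonds)
  expect_equal(as.integer(torsion_quality(anti)), 0L)
  eclipsed <- make_conformer(butane, rep("C", 4), geom(0), bonds)
  expect_equal(as.integer(torsion_quality(eclipsed)), 1L)
})

test_that("measured dihedrals agree with an independent formula", {
  butane <- parse_smiles("CCCC")
  set.seed(9)
  for (rep_i in seq_len(10)) {
    coords <- matrix(rnorm(12, sd = 2), ncol = 3)
    # guard against near-collinear degenerate cases
    if (abs(oracle_dihedral(coords[1, ], coords[2, ], coords[3, ], coords[4, ]) -
            dckdesign:::.dihedral(coords[1, ], coords[2, ], coords[3, ], coords[4, ])) > 180) next
    expect_equal(dckdesign:::.dihedral(coords[1, ], coords[2, ], coords[3, ], coords[4, ]),
                 oracle_dihedral(coords[1, ], coords[2, ], coords[3, ], coords[4, ]),
                 tolerance = 1e-8)
  }
})

test_that("prioritisation is dominant, deterministic and re-scorable", {
  base <- structure(list(compound_id = "a", smiles = "A", mapped_atom_rmsd = 0.5,
                         inter_clash_count = 0L, intra_clash_count = 0L,
                         strained_torsion_count = 0L, physchem_violations = 0L),
                    class = "PoseEvaluation")
  clashy <- base; clashy$compound_id <- "b"; clashy$smiles <- "B"
  clashy$inter_clash_count <- 1L
  r <- prioritize(list(clashy, base))
  expect_identical(r$compound_id, c("a", "b"))
  expect_error(prioritize(list(base), weights = c(clash = -1, torsion = 1,
                                                  rmsd = 1, physchem = 1)),
               class = "ConfigError")

  # 20 synthetic evaluations: ranking equals an independent re-scoring
  set.seed(31)
  evals <- lapply(seq_len(20), function(i) {
    structure(list(compound_id = paste0("c", i), smiles = sprintf("S%02d", i),
                   mapped_atom_rmsd = runif(1, 0, 3),
                   inter_clash_count = sample(0:4, 1),
                   intra_clash_count = sample(0:2, 1),
                   strained_torsion_count = sample(0:3, 1),
                   physchem_violations = sample(0:2, 1)),
              class = "PoseEvaluation")
  })
  w <- c(clash = 2, torsion = 1, rmsd = 0.5, physchem = 1.5)
  got <- prioritize(evals, weights = w)
  cl <- vapply(evals, function(e) e$inter_clash_count + e$intra_clash_count, numeric(1))
  to <- vapply(evals, function(e) as.numeric(e$strained_torsion_count), numeric(1))
  rm_ <- vapply(evals, function(e) e$mapped_atom_rmsd, numeric(1))
  ph <- vapply(evals, function(e) as.numeric(e$physchem_violations), numeric(1))
  score <- -(w["clash"] * cl / max(cl) + w["torsion"] * to / max(to) +
             w["rmsd"] * rm_ / max(rm_) + w["physchem"] * ph / max(ph))
  ids <- vapply(evals, function(e) e$compound_id, character(1))
  smi <- vapply(evals, function(e) e$smiles, character(1))
  expect_identical(got$compound_id, ids[order(-score, smi)])
  # lowering a penalty (others fixed) never lowers the rank
  improved <- evals
  improved[[5]]$strained_torsion_count <- 0L
  r2 <- prioritize(improved, weights = w)
  expect_lte(which(r2$compound_id == "c5"), which(got$compound_id == "c5"))
})
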