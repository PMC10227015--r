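# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: nested loops instead of vectorised
# algebra, exhaustive search instead of closed forms.

# --- brute-force dictionary enumeration: plain nested loops over the spec,
# canonical-text dedup done with a plain character vector.
oracle_dictionary_texts <- function(spec) {
  spacers <- character(0)
  lens <- sort(unique(as.integer(unlist(spec$spacers$lengths %||% 0L))))
  atoms <- as.character(unlist(spec$spacers$atoms %||% "C"))
  for (len in lens) {
    if (len == 0) spacers <- c(spacers, "")
    else {
      combos <- ""
      for (k in seq_len(len)) combos <- as.vector(outer(combos, atoms, paste0))
      spacers <- c(spacers, combos)
    }
  }
  spacers <- unique(spacers)
  texts <- character(0)
  for (fg in spec$functional_groups %||% list()) {
    body <- substring(fg$smiles, 4)
    for (sp in spacers) {
      can <- tryCatch(dckdesign::canonical_smiles(paste0("[*]", sp, body)),
                      error = function(e) NA_character_)
      if (!is.na(can) && dckdesign:::.valence_ok(can)) texts <- c(texts, can)
    }
  }
  for (ring in spec$rings %||% list()) {
    for (dec in unlist(ring$decorations %||% list("none"))) {
      core <- dckdesign:::.decorate_ring(ring$smiles, ring$id,
                                         as.integer(ring$size), dec, "C")
      if (is.na(core)) next
      body <- substring(core, 4)
      for (sp in spacers) {
        can <- tryCatch(dckdesign::canonical_smiles(paste0("[*]", sp, body)),
                        error = function(e) NA_character_)
        if (!is.na(can) && dckdesign:::.valence_ok(can)) texts <- c(texts, can)
      }
    }
  }
  sort(unique(texts))
}

# --- exhaustive maximum common connected substructure size for small
# molecules: enumerate connected vertex subsets of the template from large
# to small and test induced embedding into the query.
oracle_mcs_size <- function(query, template) {
  gq <- dckdesign:::.mol_igraph(query)
  gt <- dckdesign:::.mol_igraph(template)
  if (igraph::vcount(gq) < igraph::vcount(gt)) {
    tmp <- gq; gq <- gt; gt <- tmp
  }
  nt <- igraph::vcount(gt)
  embeds <- function(sub, target) {
    vc_s <- dckdesign:::.element_colors(igraph::V(sub)$element)
    vc_t <- dckdesign:::.element_colors(igraph::V(target)$element)
    ec_s <- dckdesign:::.border_colors(igraph::E(sub)$border)
    ec_t <- dckdesign:::.border_colors(igraph::E(target)$border)
    igraph::subgraph_isomorphic(sub, target, method = "vf2",
                                vertex.color1 = vc_t, vertex.color2 = vc_s,
                                edge.color1 = ec_t, edge.color2 = ec_s)
  }
  for (size in seq(nt, 1)) {
    for (subset in utils::combn(nt, size, simplify = FALSE)) {
      sub <- igraph::induced_subgraph(gt, subset)
      if (!igraph::is_connected(sub)) next
      if (embeds(sub, gq)) return(size)
    }
  }
  0L
}

# --- rigid-body superposition by rotation-grid search plus Nelder-Mead
# refinement over Euler angles (translation handled by centroid matching).
oracle_superposition_rmsd <- function(P, Q, coarse = 20) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_of <- function(ang) {
    R <- rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  best <- c(0, 0, 0); best_v <- rmsd_of(best)
  step <- 2 * pi / coarse
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step / 2))
      for (c in seq(0, 2 * pi - step, by = step)) {
        v <- rmsd_of(c(a, b, c))
        if (v < best_v) { best_v <- v; best <- c(a, b, c) }
      }
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# --- all-pairs clash reference: explicit double loops.
oracle_clash_counts <- function(lig_xyz, lig_el, pocket_xyz, pocket_el,
                                topo_dist, scale, vdw) {
  inter <- 0L
  if (!is.null(pocket_xyz)) {
    for (i in seq_len(nrow(lig_xyz))) for (j in seq_len(nrow(pocket_xyz))) {
      d <- sqrt(sum((lig_xyz[i, ] - pocket_xyz[j, ])^2))
      if (d < scale * (vdw[[lig_el[i]]] + vdw[[pocket_el[j]]])) inter <- inter + 1L
    }
  }
  intra <- 0L
  n <- nrow(lig_xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (topo_dist[i, j] <= 3) next
    d <- sqrt(sum((lig_xyz[i, ] - lig_xyz[j, ])^2))
    if (d < scale * (vdw[[lig_el[i]]] + vdw[[lig_el[j]]])) intra <- intra + 1L
  }
  c(inter = inter, intra = intra)
}

# --- independent dihedral: angle between plane normals with sign from the
# scalar triple product (different formulation than the implementation).
oracle_dihedral <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  n1 <- c(u1[2] * u2[3] - u1[3] * u2[2], u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  n2 <- c(u2[2] * u3[3] - u2[3] * u3[2], u2[3] * u3[1] - u2[1] * u3[3],
          u2[1] * u3[2] - u2[2] * u3[1])
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  # sign from the handedness of the two plane normals about the central bond
  n12 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
           n1[1] * n2[2] - n1[2] * n2[1])
  if (sum(n12 * u2) > 0) ang <- 360 - ang
  ang %% 360
}

# a bare Conformer3D from explicit tables (for geometric unit tests)
make_conformer <- function(molecule, elements, coords, bonds) {
  structure(list(molecule = molecule, elements = elements,
                 coords = coords, bonds = bonds, seed = 0L),
            class = "Conformer3D")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
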