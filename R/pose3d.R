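#' Template-constrained 3D evaluation of designed compounds
#'
#' The pose module realises the template-based evaluation stage of the
#' campaign with fully transparent components: conformers are embedded
#' deterministically, mapped onto the reference bioactive conformation via
#' a maximum common connected substructure, superimposed by closed-form
#' least-squares (Kabsch) rotation, and scored by van der Waals clash
#' counts, torsion-window violations and physicochemical compliance. No
#' proprietary scoring function is reimplemented; the priority score is an
#' explicit weighted sum of exactly these terms.
#'
#' @name pose3d
#' @keywords internal
NULL

#' Embed a 3D conformer
#'
#' Deterministic embedding: a 2D structure layout with explicit hydrogens
#' is lifted to 3D by a seeded coordinate perturbation and relaxed by
#' steepest-descent MMFF94 minimisation. The same molecule and seed always
#' reproduce bit-identical coordinates.
#'
#' @param mol A `Molecule`.
#' @param seed Integer seed for the coordinate perturbation.
#' @param steps Minimisation steps (default 1500).
#' @param n_retries Additional seeded restarts if the geometry audit fails.
#' @return A `Conformer3D`: list with `molecule`, `elements` (incl. H),
#'   `coords` (n x 3 matrix, Angstrom), `bonds` (explicit-H bond table) and
#'   `seed`.
#' @export
embed_conformer <- function(mol, seed = 1L, steps = 1500L, n_retries = 3L) {
  stopifnot(is_molecule(mol))
  for (attempt in 0:n_retries) {
    conf <- .try_embed(mol, seed + 1000L * attempt, steps)
    if (!is.null(conf) && .geometry_ok(conf)) {
      conf$seed <- as.integer(seed)
      return(conf)
    }
  }
  stop_embedding(sprintf("embedding failed for %s after %d attempts",
                         mol$smiles, n_retries + 1L))
}

.try_embed <- function(mol, seed, steps) {
  mb2d <- .ob_convert("SMI", "SDF", paste0(mol$smiles, "\n"),
                      opts = .ob_options(c("gen2d", "h")))
  if (!nzchar(mb2d)) return(NULL)
  g <- .graph_from_molblock(mb2d)
  n <- nrow(g$atoms)
  coords <- g$coords
  # seeded lift out of the drawing plane (RNG state is restored afterwards)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  coords <- coords + cbind(stats::rnorm(n, 0, 0.05),
                           stats::rnorm(n, 0, 0.05),
                           stats::rnorm(n, 0, 0.35))
  coords <- round(coords, 4)
  mb <- .molblock_from_graph(g$atoms, g$bonds, coords = coords)
  opt <- .ob_convert("SDF", "SDF", mb,
                     opts = .ob_options(c("minimize", "sd", "steps", "ff"),
                                        c("", "", as.character(steps), "MMFF94")))
  if (!nzchar(opt)) return(NULL)
  go <- .graph_from_molblock(opt)
  if (nrow(go$atoms) != n) return(NULL)
  structure(
    list(molecule = mol, elements = go$atoms$element, coords = go$coords,
         bonds = go$bonds, seed = NA_integer_),
    class = "Conformer3D"
  )
}

# Audit: bonded atoms within 15% of the sum of covalent radii, and no two
# atoms closer than 0.5 Angstrom.
.COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                     Se = 1.20, Br = 1.20, I = 1.39)

.geometry_ok <- function(conf, tol = 0.15) {
  b <- conf$bonds
  if (nrow(b) > 0) {
    d <- sqrt(rowSums((conf$coords[b$a1 + 1L, , drop = FALSE] -
                       conf$coords[b$a2 + 1L, , drop = FALSE])^2))
    ideal <- .COVALENT_RADII[conf$elements[b$a1 + 1L]] +
             .COVALENT_RADII[conf$elements[b$a2 + 1L]]
    # double/triple bonds are shorter; allow the slack downward
    if (any(is.na(ideal))) return(FALSE)
    if (any(d > ideal * (1 + tol)) || any(d < ideal * 0.6)) return(FALSE)
  }
  dm <- as.matrix(stats::dist(conf$coords))
  diag(dm) <- Inf
  all(dm >= 0.5)
}

#' @export
print.Conformer3D <- function(x, ...) {
  cat(sprintf("<Conformer3D> %s\n  %d atoms (incl. H), seed %s\n",
              x$molecule$smiles, nrow(x$coords), x$seed))
  invisible(x)
}

#' Read conformers from a multi-record SDF file
#'
#' @param path SDF file path.
#' @return List of `Conformer3D` objects (seed `NA`, coordinates as found).
#' @export
read_conformers_sdf <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("SDF file not found: %s", path))
  txt <- paste(readLines(path), collapse = "\n")
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[vapply(blocks, function(b) grepl("V2000", b), logical(1))]
  if (length(blocks) == 0L) stop_empty_input(sprintf("no molecules in %s", path))
  lapply(blocks, function(b) {
    b <- sub("^\n+", "", b)
    g <- .graph_from_molblock(b)
    can <- .ob_convert("SDF", "CAN", paste0(b, "\n$$$$\n"))
    can <- sub("[\t ].*$", "", trimws(can))
    mol <- if (nzchar(can)) tryCatch(parse_smiles(can), error = function(e) NULL) else NULL
    structure(
      list(molecule = mol, elements = g$atoms$element, coords = g$coords,
           bonds = g$bonds, seed = NA_integer_),
      class = "Conformer3D"
    )
  })
}

# ---- common substructure mapping ------------------------------------------

#' Maximum common connected substructure mapping
#'
#' Finds the largest connected substructure shared by query and template
#' under element and bond-order compatibility (aromatic bonds are one
#' class, so kekulisation cannot split a match) and returns the atom
#' correspondence. Ties are broken deterministically by the
#' lexicographically smallest mapped query-index sequence.
#'
#' @param query,template `Molecule` objects.
#' @param min_size Minimum acceptable mapping size (atoms); below it a
#'   `NoTemplateOverlapError` is signalled. Default 5.
#' @return An `AtomMapping`: data.frame with 0-based columns `query_atom`,
#'   `template_atom`.
#' @export
common_substructure_map <- function(query, template, min_size = 5L) {
  stopifnot(is_molecule(query), is_molecule(template))
  gq <- .mol_igraph(query)
  gt <- .mol_igraph(template)

  # fast path: the template embeds entirely into the query (the standard
  # situation when the query is seed + fragment and the template the seed)
  mapping <- .full_embedding(gt, gq)
  if (!is.null(mapping)) {
    out <- data.frame(query_atom = mapping - 1L,
                      template_atom = seq_along(mapping) - 1L)
  } else if (igraph::vcount(gq) <= igraph::vcount(gt) &&
             !is.null(mapping <- .full_embedding(gq, gt))) {
    out <- data.frame(query_atom = seq_along(mapping) - 1L,
                      template_atom = mapping - 1L)
  } else {
    out <- .mcs_by_cliques(gq, gt)
  }
  if (is.null(out) || nrow(out) < min_size) {
    stop_no_template_overlap(sprintf(
      "common substructure below minimum size %d", min_size))
  }
  out <- out[order(out$template_atom), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("AtomMapping", class(out))
  out
}

# All isomorphic embeddings of pattern into target (induced, element and
# bond-class coloured); returns the lexicographically smallest as a vector
# of target vertices (1-based), or NULL.
.full_embedding <- function(pattern, target) {
  if (igraph::vcount(pattern) > igraph::vcount(target)) return(NULL)
  vc_p <- .element_colors(igraph::V(pattern)$element)
  vc_t <- .element_colors(igraph::V(target)$element)
  ec_p <- .border_colors(igraph::E(pattern)$border)
  ec_t <- .border_colors(igraph::E(target)$border)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(
      pattern, target, method = "vf2",
      vertex.color1 = vc_t, vertex.color2 = vc_p,
      edge.color1 = ec_t, edge.color2 = ec_p
    ),
    error = function(e) list()
  )
  if (length(maps) == 0) return(NULL)
  seqs <- lapply(maps, as.integer)
  .lex_smallest(seqs)
}

.element_colors <- function(elements) as.integer(factor(elements, levels = sort(unique(c(elements, names(.VALENCE_TABLE))))))

.border_colors <- function(border) {
  if (is.null(border)) return(integer(0))
  as.integer(factor(border, levels = c("1", "2", "3", "ar")))
}

.lex_smallest <- function(seqs) {
  best <- seqs[[1]]
  for (s in seqs[-1]) {
    cmp <- s - best
    nz <- which(cmp != 0)
    if (length(nz) > 0 && cmp[nz[1]] < 0) best <- s
  }
  best
}

# Exact MCS by maximum clique in the modular product graph, restricted to
# mappings inducing a connected substructure. Exponential; intended for
# the small molecules this fallback serves.
.mcs_by_cliques <- function(gq, gt) {
  nq <- igraph::vcount(gq); nt <- igraph::vcount(gt)
  if (nq * nt > 2500) {
    stop_config("exact MCS fallback is limited to small molecules (<= ~50x50 atoms)")
  }
  elq <- igraph::V(gq)$element; elt <- igraph::V(gt)$element
  pairs <- which(outer(elq, elt, "=="), arr.ind = TRUE)   # candidate vertex pairs
  np <- nrow(pairs)
  if (np == 0) return(NULL)
  aq <- igraph::as_adjacency_matrix(gq, sparse = FALSE)
  at <- igraph::as_adjacency_matrix(gt, sparse = FALSE)
  bq <- matrix("", nq, nq); bt <- matrix("", nt, nt)
  eq <- igraph::as_edgelist(gq); et <- igraph::as_edgelist(gt)
  if (nrow(eq) > 0) for (i in seq_len(nrow(eq))) bq[eq[i,1], eq[i,2]] <- bq[eq[i,2], eq[i,1]] <- igraph::E(gq)$border[i]
  if (nrow(et) > 0) for (i in seq_len(nrow(et))) bt[et[i,1], et[i,2]] <- bt[et[i,2], et[i,1]] <- igraph::E(gt)$border[i]
  # modular product: (i,a)~(j,b) iff i!=j, a!=b and the edge relations agree
  adj <- matrix(FALSE, np, np)
  for (u in seq_len(np - 1)) {
    i <- pairs[u, 1]; a <- pairs[u, 2]
    for (v in (u + 1):np) {
      j <- pairs[v, 1]; b <- pairs[v, 2]
      if (i == j || a == b) next
      if (aq[i, j] == 1 && at[a, b] == 1 && bq[i, j] == bt[a, b]) {
        adj[u, v] <- adj[v, u] <- TRUE
      } else if (aq[i, j] == 0 && at[a, b] == 0) {
        adj[u, v] <- adj[v, u] <- TRUE
      }
    }
  }
  gp <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::largest_cliques(gp)
  if (length(cliques) == 0) return(NULL)
  best <- NULL
  best_seq <- NULL
  for (cl in cliques) {
    qv <- pairs[as.integer(cl), 1]; tv <- pairs[as.integer(cl), 2]
    sub <- igraph::induced_subgraph(gq, qv)
    if (!igraph::is_connected(sub)) next
    ord <- order(tv)
    s <- qv[ord]
    if (is.null(best_seq) || .lex_less(s, best_seq)) {
      best <- data.frame(query_atom = qv[ord] - 1L, template_atom = tv[ord] - 1L)
      best_seq <- s
    }
  }
  # connected cliques may be smaller than the largest unconstrained clique;
  # fall back to all maximal cliques if none of the largest is connected
  if (is.null(best)) {
    cliques <- igraph::max_cliques(gp, min = 3)
    sizes <- lengths(cliques)
    for (cl in cliques[order(-sizes)]) {
      qv <- pairs[as.integer(cl), 1]; tv <- pairs[as.integer(cl), 2]
      if (!is.null(best) && length(qv) < nrow(best)) break
      sub <- igraph::induced_subgraph(gq, qv)
      if (!igraph::is_connected(sub)) next
      ord <- order(tv)
      s <- qv[ord]
      if (is.null(best) || nrow(best) < length(qv) ||
          (nrow(best) == length(qv) && .lex_less(s, best_seq))) {
        best <- data.frame(query_atom = qv[ord] - 1L, template_atom = tv[ord] - 1L)
        best_seq <- s
      }
    }
  }
  best
}

.lex_less <- function(a, b) {
  if (length(a) != length(b)) return(length(a) > length(b))
  nz <- which(a != b)
  length(nz) > 0 && a[nz[1]] < b[nz[1]]
}

# ---- superposition --------------------------------------------------------

#' Superimpose a conformer onto a template via mapped atoms
#'
#' Closed-form least-squares rigid superposition (Kabsch): the rotation and
#' translation minimising the RMSD over mapped atom pairs is computed from
#' the SVD of the cross-covariance matrix (with the determinant correction
#' that excludes reflections) and applied to the whole query conformer.
#'
#' @param conf Query `Conformer3D`.
#' @param template_conf Template `Conformer3D`.
#' @param mapping An `AtomMapping` (0-based heavy-atom indices). Heavy-atom
#'   indices of the `Molecule` are positional: they index the non-hydrogen
#'   atoms of the conformer in order.
#' @return List with `conformer` (transformed copy) and `rmsd` (Angstrom,
#'   minimised over the mapped atoms).
#' @export
template_superimpose <- function(conf, template_conf, mapping) {
  stopifnot(inherits(conf, "Conformer3D"), inherits(template_conf, "Conformer3D"))
  if (nrow(mapping) < 3L) {
    stop_degenerate_alignment("at least 3 mapped atoms are required")
  }
  qh <- .heavy_indices(conf)
  th <- .heavy_indices(template_conf)
  qi <- qh[mapping$query_atom + 1L]
  ti <- th[mapping$template_atom + 1L]
  if (anyNA(qi) || anyNA(ti)) {
    stop_degenerate_alignment("mapping indices outside the conformers")
  }
  P <- conf$coords[qi, , drop = FALSE]        # moving
  Q <- template_conf$coords[ti, , drop = FALSE]  # fixed
  fit <- .kabsch(P, Q)
  new_coords <- sweep(conf$coords, 2, fit$centroid_P) %*% fit$R
  new_coords <- sweep(new_coords, 2, fit$centroid_Q, "+")
  out <- conf
  out$coords <- new_coords
  list(conformer = out, rmsd = fit$rmsd)
}

.heavy_indices <- function(conf) which(conf$elements != "H")

# Kabsch algorithm: optimal proper rotation of P onto Q.
.kabsch <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  P1 <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((P1 - Q0)^2)))
  list(R = R, centroid_P = cP, centroid_Q = cQ, rmsd = rmsd)
}

# ---- pockets and clashes --------------------------------------------------

#' Build a receptor pocket from raw coordinates
#'
#' @param coords n x 3 matrix of heavy-atom coordinates (Angstrom).
#' @param elements Element symbols (length n).
#' @param source Source tag (PDB id or "synthetic").
#' @return A `ReceptorPocket`.
#' @export
receptor_pocket <- function(coords, elements, source = "synthetic") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(elements), nrow(coords) >= 1)
  vdw <- .vdw_radii()
  unknown <- setdiff(unique(elements), names(vdw))
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown element(s) in pocket: %s",
                        paste(unknown, collapse = ", ")))
  }
  structure(list(coords = coords, elements = elements, source = source),
            class = "ReceptorPocket")
}

.vdw_radii <- function() {
  tab <- utils::read.csv(system.file("extdata", "vdw_radii.csv",
                                     package = "dckdesign", mustWork = TRUE))
  stats::setNames(tab$radius, tab$element)
}

#' Count van der Waals clashes of a pose
#'
#' An inter-molecular clash is a ligand/pocket heavy-atom pair closer than
#' `scale` times the sum of their van der Waals radii; an intra-molecular
#' clash applies the same rule to ligand heavy-atom pairs separated by
#' more than three bonds (1-2, 1-3 and 1-4 pairs are excluded).
#'
#' @param conf A `Conformer3D`.
#' @param pocket A `ReceptorPocket`, or `NULL` for intra-only evaluation.
#' @param scale Overlap tolerance in (0, 1]; default 0.7.
#' @return Named integer vector `c(inter = ..., intra = ...)`.
#' @export
clash_scores <- function(conf, pocket = NULL, scale = 0.7) {
  stopifnot(inherits(conf, "Conformer3D"), scale > 0, scale <= 1)
  vdw <- .vdw_radii()
  hv <- .heavy_indices(conf)
  lig_el <- conf$elements[hv]
  unknown <- setdiff(unique(lig_el), names(vdw))
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown element(s) in ligand: %s",
                        paste(unknown, collapse = ", ")))
  }
  lig <- conf$coords[hv, , drop = FALSE]
  rl <- vdw[lig_el]

  inter <- 0L
  if (!is.null(pocket)) {
    rp <- vdw[pocket$elements]
    dmat <- .cross_dist(lig, pocket$coords)
    lim <- outer(rl, rp, "+") * scale
    inter <- sum(dmat < lim)
  }

  # graph distances on the heavy-atom graph; bonds of the conformer are on
  # all-atom indices, so restrict to heavy atoms first
  hmap <- match(seq_along(conf$elements), hv)     # all-atom -> heavy index
  hb <- conf$bonds[conf$elements[conf$bonds$a1 + 1L] != "H" &
                   conf$elements[conf$bonds$a2 + 1L] != "H", , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(hv), directed = FALSE)
  if (nrow(hb) > 0) {
    g <- igraph::add_edges(g, rbind(hmap[hb$a1 + 1L], hmap[hb$a2 + 1L]))
  }
  topo <- igraph::distances(g)
  dmat <- as.matrix(stats::dist(lig))
  lim <- outer(rl, rl, "+") * scale
  eligible <- topo > 3                            # excludes 1-2, 1-3, 1-4
  intra <- sum(dmat[upper.tri(dmat)][eligible[upper.tri(eligible)]] <
               lim[upper.tri(lim)][eligible[upper.tri(eligible)]])

  c(inter = as.integer(inter), intra = as.integer(intra))
}

.cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# ---- torsion quality ------------------------------------------------------

#' Default torsion rule set shipped with the package
#' @return data.frame with columns `class`, `windows`, `description`.
#' @export
default_torsion_rules <- function() {
  utils::read.csv(system.file("extdata", "torsion_rules.csv",
                              package = "dckdesign", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Count strained torsions of a conformer
#'
#' Rotatable bonds are classified from the molecular graph (sp3-sp3,
#' biaryl, aryl-amide); each classified torsion is measured with the
#' four-point dihedral formula and checked against the allowed angular
#' windows of its class. Unclassified torsions are unscored.
#'
#' @param conf A `Conformer3D`.
#' @param rules Torsion rules as from [default_torsion_rules()]; windows
#'   are `min:max` degree ranges on \[0, 360) joined by `;`.
#' @return Integer count of out-of-window torsions, with attribute
#'   `details` (one row per scored torsion).
#' @export
torsion_quality <- function(conf, rules = default_torsion_rules()) {
  stopifnot(inherits(conf, "Conformer3D"))
  tors <- .classified_torsions(conf)
  if (nrow(tors) == 0) {
    out <- 0L
    attr(out, "details") <- tors
    return(out)
  }
  windows <- lapply(stats::setNames(rules$windows, rules$class), .parse_windows)
  tors$angle <- vapply(seq_len(nrow(tors)), function(i) {
    .dihedral(conf$coords[tors$a[i] + 1L, ], conf$coords[tors$b[i] + 1L, ],
              conf$coords[tors$c[i] + 1L, ], conf$coords[tors$d[i] + 1L, ])
  }, numeric(1))
  tors <- tors[tors$class %in% names(windows), , drop = FALSE]
  tors$strained <- vapply(seq_len(nrow(tors)), function(i) {
    win <- windows[[tors$class[i]]]
    !any(tors$angle[i] >= win[, 1] & tors$angle[i] <= win[, 2])
  }, logical(1))
  out <- sum(tors$strained)
  attr(out, "details") <- tors
  out
}

.parse_windows <- function(txt) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  do.call(rbind, lapply(parts, function(p) {
    v <- as.numeric(strsplit(p, ":", fixed = TRUE)[[1]])
    if (length(v) != 2 || anyNA(v)) stop_config(sprintf("bad torsion window '%s'", p))
    v
  }))
}

# Dihedral angle (degrees, in [0, 360)) of the four points p1-p2-p3-p4.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  (ang + 360) %% 360
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotatable-bond torsions with their class and the deterministic choice of
# flanking atoms (lowest-index heavy neighbour on each side). All-atom
# (explicit-H) indices, 0-based.
.classified_torsions <- function(conf) {
  el <- conf$elements
  b <- conf$bonds
  n <- length(el)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(b) > 0) g <- igraph::add_edges(g, rbind(b$a1 + 1L, b$a2 + 1L))
  bridges <- igraph::bridges(g)
  arom <- logical(n)
  hv <- which(el != "H")
  # aromatic flags live on the heavy-atom Molecule; conformer heavy atoms
  # are in the same order
  arom[hv[seq_len(nrow(conf$molecule$atoms))]] <- conf$molecule$atoms$aromatic

  heavy_deg <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    sum(el[nb] != "H")
  }, integer(1))

  rows <- list()
  for (ei in as.integer(bridges)) {
    ends <- igraph::ends(g, ei)
    i <- ends[1]; j <- ends[2]
    if (el[i] == "H" || el[j] == "H") next
    if (b$order[ei] != 1L) next
    if (heavy_deg[i] < 2L || heavy_deg[j] < 2L) next
    cls <- .torsion_class(i, j, el, arom, g, b)
    if (is.na(cls)) next
    nb_i <- setdiff(as.integer(igraph::neighbors(g, i)), j)
    nb_i <- nb_i[el[nb_i] != "H"]
    nb_j <- setdiff(as.integer(igraph::neighbors(g, j)), i)
    nb_j <- nb_j[el[nb_j] != "H"]
    if (length(nb_i) == 0 || length(nb_j) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      a = min(nb_i) - 1L, b = i - 1L, c = j - 1L, d = min(nb_j) - 1L,
      class = cls, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), class = character(0)))
  }
  do.call(rbind, rows)
}

.torsion_class <- function(i, j, el, arom, g, bonds) {
  if (arom[i] && arom[j]) return("biaryl")
  amide_c <- function(v) {
    if (el[v] != "C") return(FALSE)
    nb <- as.integer(igraph::neighbors(g, v))
    any(vapply(nb, function(w) {
      el[w] == "O" && .bond_order_between(bonds, v, w) == 2L
    }, logical(1)))
  }
  amide_n <- function(v) {
    if (el[v] != "N") return(FALSE)
    nb <- as.integer(igraph::neighbors(g, v))
    any(vapply(nb, amide_c, logical(1)))
  }
  if ((arom[i] && (amide_n(j) || amide_c(j))) ||
      (arom[j] && (amide_n(i) || amide_c(i)))) return("aryl_amide")
  sp3 <- function(v) {
    if (arom[v]) return(FALSE)
    if (!el[v] %in% c("C", "N", "O")) return(FALSE)
    nb <- as.integer(igraph::neighbors(g, v))
    all(vapply(nb, function(w) .bond_order_between(bonds, v, w) == 1L, logical(1)))
  }
  if (sp3(i) && sp3(j)) return("sp3_sp3")
  NA_character_
}

.bond_order_between <- function(bonds, v, w) {
  hit <- which((bonds$a1 == v - 1L & bonds$a2 == w - 1L) |
               (bonds$a1 == w - 1L & bonds$a2 == v - 1L))
  if (length(hit) == 0) return(0L)
  bonds$order[hit[1]]
}

# ---- pose evaluation and prioritisation -----------------------------------

#' Evaluate one designed compound against a template and pocket
#'
#' Runs the full pose pipeline for a single compound: embed, map onto the
#' template, superimpose, count clashes and strained torsions, check
#' physicochemical windows.
#'
#' @param compound A `DesignedCompound` (or `Molecule`).
#' @param template_conf Template `Conformer3D` (bioactive conformation).
#' @param pocket Optional `ReceptorPocket`.
#' @param seed Embedding seed.
#' @param windows Physicochemical windows (as in [filter_library()]).
#' @param scale Clash scale.
#' @param min_mcs Minimum common-substructure size.
#' @return A `PoseEvaluation`: list with `compound_id`, `smiles`,
#'   `mapped_atom_rmsd`, `inter_clash_count`, `intra_clash_count`,
#'   `strained_torsion_count`, `physchem_violations`, `conformer`.
#' @export
evaluate_pose <- function(compound, template_conf, pocket = NULL, seed = 1L,
                          windows = default_filter_windows(), scale = 0.7,
                          min_mcs = 5L) {
  mol <- if (is_molecule(compound)) compound else compound$molecule
  id <- if (is_molecule(compound)) compound$name %||% compound$smiles
        else compound$fragment_id
  conf <- embed_conformer(mol, seed = seed)
  mapping <- common_substructure_map(mol, template_conf$molecule, min_size = min_mcs)
  sup <- template_superimpose(conf, template_conf, mapping)
  clashes <- clash_scores(sup$conformer, pocket, scale = scale)
  strained <- torsion_quality(sup$conformer)
  prof <- physchem_profile(mol)
  viol <- 0L
  for (w in names(windows)) {
    v <- prof[[w]][1]
    if (!is.null(v) && !is.na(v) && (v < windows[[w]][1] || v > windows[[w]][2])) {
      viol <- viol + 1L
    }
  }
  structure(
    list(compound_id = id, smiles = mol$smiles,
         mapped_atom_rmsd = sup$rmsd,
         inter_clash_count = unname(clashes["inter"]),
         intra_clash_count = unname(clashes["intra"]),
         strained_torsion_count = as.integer(strained),
         physchem_violations = viol,
         conformer = sup$conformer),
    class = "PoseEvaluation"
  )
}

#' Default prioritisation weights
#' @return Named numeric vector.
#' @export
default_priority_weights <- function() {
  c(clash = 1, torsion = 1, rmsd = 1, physchem = 1)
}

#' Rank evaluated compounds
#'
#' The priority score is minus the weighted sum of normalised penalty
#' terms (clash counts, strained torsions, mapped-atom RMSD, and
#' physicochemical window violations); each term is scaled by its maximum
#' over the evaluation set so the weights compare like with like. Higher
#' scores rank first; ties are broken by canonical SMILES, and the sort is
#' stable.
#'
#' @param evals List of `PoseEvaluation` objects (one per compound).
#' @param weights Named non-negative weights (`clash`, `torsion`, `rmsd`,
#'   `physchem`).
#' @return data.frame ranked best-first with columns `rank`, `compound_id`,
#'   `smiles`, `priority_score` and the raw penalty terms.
#' @export
prioritize <- function(evals, weights = default_priority_weights()) {
  if (inherits(evals, "PoseEvaluation")) evals <- list(evals)
  stopifnot(length(evals) >= 1)
  if (any(weights < 0)) stop_config("prioritisation weights must be non-negative")
  for (k in c("clash", "torsion", "rmsd", "physchem")) {
    if (is.na(weights[k])) stop_config(sprintf("missing weight '%s'", k))
  }
  tab <- data.frame(
    compound_id = vapply(evals, function(e) as.character(e$compound_id), character(1)),
    smiles = vapply(evals, function(e) e$smiles, character(1)),
    clashes = vapply(evals, function(e) e$inter_clash_count + e$intra_clash_count, numeric(1)),
    torsions = vapply(evals, function(e) as.numeric(e$strained_torsion_count), numeric(1)),
    rmsd = vapply(evals, function(e) e$mapped_atom_rmsd, numeric(1)),
    physchem = vapply(evals, function(e) as.numeric(e$physchem_violations), numeric(1)),
    stringsAsFactors = FALSE
  )
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  tab$priority_score <- -(weights["clash"] * norm(tab$clashes) +
                          weights["torsion"] * norm(tab$torsions) +
                          weights["rmsd"] * norm(tab$rmsd) +
                          weights["physchem"] * norm(tab$physchem))
  ord <- order(-tab$priority_score, tab$smiles, method = "radix")
  out <- tab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "compound_id", "smiles", "priority_score",
          "clashes", "torsions", "rmsd", "physchem")]
}
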