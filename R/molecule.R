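#' Molecules as valence-checked graphs with a canonical text form
#'
#' A `Molecule` is the unit every pipeline stage passes around. It couples a
#' heavy-atom molecular graph (elements, formal charges, aromatic flags,
#' bond orders) with the canonical SMILES that is the single identity notion
#' used everywhere in the package: deduplication, ledger keys and tests all
#' compare molecules by this string. Canonicalisation is delegated to
#' OpenBabel (via \pkg{ChemmineOB}); the valence validator is applied to
#' every molecule the package constructs or emits.
#'
#' @param smiles A single SMILES string.
#' @param name Optional molecule name.
#' @return A `Molecule` object: a list with components `smiles` (canonical),
#'   `name`, `atoms` (data.frame: `element`, `charge`, `aromatic`) and
#'   `bonds` (data.frame: `a1`, `a2`, `order`; 0-based atom indices).
#' @examples
#' \donttest{
#' benzene <- parse_smiles("c1ccccc1", name = "benzene")
#' benzene$smiles
#' n_atoms(benzene)
#' }
#' @export
parse_smiles <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- canonical_smiles(smiles)
  mol <- .molecule_from_canonical(can, name = name)
  check_valence(mol)
  mol
}

#' Canonical SMILES of a SMILES string
#'
#' The package's single canonicalisation authority. Idempotent: applying it
#' to its own output returns the same string.
#'
#' @param smiles A single SMILES string (dummy attachment atoms `[*]`
#'   allowed).
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  out <- .ob_convert("SMI", "CAN", paste0(smiles, "\n"))
  out <- sub("[\t ].*$", "", trimws(out))
  if (!nzchar(out)) {
    stop_chemistry(sprintf("SMILES could not be parsed: '%s'", smiles))
  }
  out
}

# Thin wrapper around ChemmineOB::convertFormat that silences OpenBabel
# chatter and normalises failures to empty strings.
.ob_convert <- function(from, to, text, opts = NULL) {
  if (is.null(opts)) opts <- data.frame()
  res <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat(from, to, source = text, options = opts)
    )),
    error = function(e) ""
  )
  if (is.null(res)) "" else res
}

.ob_options <- function(names, args = rep("", length(names))) {
  data.frame(names = names, args = args, stringsAsFactors = FALSE)
}

#' @rdname parse_smiles
#' @param x Object to test.
#' @export
is_molecule <- function(x) inherits(x, "Molecule")

#' @export
print.Molecule <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("<Molecule%s> %s\n  %d heavy atoms, %d bonds\n",
              nm, x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol A `Molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# Build a Molecule from an already-canonical SMILES. OpenBabel preserves
# input atom order when converting SMILES to a mol block, so graph indices
# correspond to atom tokens of the canonical string; aromatic flags are
# read off the token case.
.molecule_from_canonical <- function(can, name = NULL) {
  mb <- .ob_convert("SMI", "SDF", paste0(can, "\n"), opts = .ob_options("gen2d"))
  if (!nzchar(mb)) stop_chemistry(sprintf("conversion to mol block failed for '%s'", can))
  g <- .graph_from_molblock(mb)
  tok <- .smiles_atom_tokens(can)
  if (length(tok$aromatic) != nrow(g$atoms)) {
    stop_chemistry(sprintf("atom token scan disagrees with mol block for '%s'", can))
  }
  g$atoms$aromatic <- tok$aromatic
  structure(
    list(smiles = can, name = name, atoms = g$atoms, bonds = g$bonds),
    class = "Molecule"
  )
}

# Scan a (canonical) SMILES string and return, in order, the element symbol
# and aromatic flag of every atom token. This is not a SMILES parser: ring
# bonds and branching are ignored, only atom tokens are extracted, and the
# result is cross-checked against the OpenBabel-derived graph.
.smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  elements <- character(0)
  aromatic <- logical(0)
  i <- 1L
  n <- length(chars)
  two_letter <- c("Cl", "Br")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- gsub("^[0-9]+", "", body)          # isotope
      sym <- regmatches(body, regexpr("^(\\*|[A-Za-z][a-z]?)", body))
      if (length(sym) == 0L) stop_chemistry(sprintf("unreadable atom token in '%s'", smiles))
      # Within brackets a trailing lowercase letter may be part of a
      # two-letter element; a single lowercase letter is an aromatic atom.
      if (sym %in% c("c", "n", "o", "s", "p", "b", "se", "as")) {
        elements <- c(elements, paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)))
        aromatic <- c(aromatic, TRUE)
      } else {
        elements <- c(elements, sym)
        aromatic <- c(aromatic, FALSE)
      }
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      elements <- c(elements, paste0(ch, chars[i + 1L]))
      aromatic <- c(aromatic, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      elements <- c(elements, ch)
      aromatic <- c(aromatic, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elements <- c(elements, toupper(ch))
      aromatic <- c(aromatic, TRUE)
      i <- i + 1L
    } else if (ch == "*") {
      elements <- c(elements, "*")
      aromatic <- c(aromatic, FALSE)
      i <- i + 1L
    } else {
      i <- i + 1L                                 # bond, ring, branch tokens
    }
  }
  list(elements = elements, aromatic = aromatic)
}

# Parse a V2000 mol block into atom and bond tables. A compact
# fixed-width reader is used directly (rather than an SDF container
# package) because the package round-trips thousands of single-molecule
# blocks during enumeration and must also accept bond-less records such as
# water. Formal charges are taken from the M  CHG property lines.
.graph_from_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) stop_chemistry("unreadable mol block counts line")
  atom_lines <- lines[seq_len(na) + 4L]
  elements <- trimws(substr(atom_lines, 32, 34))
  coords <- cbind(
    as.numeric(substr(atom_lines, 1, 10)),
    as.numeric(substr(atom_lines, 11, 20)),
    as.numeric(substr(atom_lines, 21, 30))
  )
  bonds <- if (nb > 0) {
    bond_lines <- lines[seq_len(nb) + 4L + na]
    data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)) - 1L,   # 0-based indices
      a2 = as.integer(substr(bond_lines, 4, 6)) - 1L,
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  charge <- integer(na)
  for (line in lines) {
    if (startsWith(line, "M  CHG")) {
      vals <- as.integer(strsplit(trimws(substring(line, 7)), "\\s+")[[1]])
      for (k in seq_len(vals[1])) charge[vals[2 * k]] <- vals[2 * k + 1]
    }
  }
  atoms <- data.frame(
    element = elements,
    charge = charge,
    aromatic = FALSE,
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, bonds = bonds, coords = coords)
}

# Serialise an atom/bond table pair (plus optional coordinates) to a V2000
# mol block so OpenBabel can re-perceive and canonicalise edited graphs.
.molblock_from_graph <- function(atoms, bonds, coords = NULL, name = "") {
  na <- nrow(atoms)
  nb <- nrow(bonds)
  if (is.null(coords)) coords <- matrix(0, na, 3)
  header <- c(name, "  dckdesign", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_lines <- vapply(seq_len(na), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], atoms$element[i])
  }, character(1))
  bond_lines <- if (nb > 0) {
    vapply(seq_len(nb), function(i) {
      sprintf("%3d%3d%3d  0  0  0  0",
              bonds$a1[i] + 1L, bonds$a2[i] + 1L, bonds$order[i])
    }, character(1))
  } else character(0)
  chg_idx <- which(atoms$charge != 0L)
  chg_lines <- character(0)
  if (length(chg_idx) > 0) {
    # M CHG lines carry at most 8 (atom, charge) pairs each
    for (start in seq(1, length(chg_idx), by = 8)) {
      idx <- chg_idx[start:min(start + 7, length(chg_idx))]
      chg_lines <- c(chg_lines, paste0(
        sprintf("M  CHG%3d", length(idx)),
        paste0(sprintf("%4d%4d", idx, atoms$charge[idx]), collapse = "")
      ))
    }
  }
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", ""), collapse = "\n")
}

# Standard valences used by the validator; a vector means several allowed
# states (e.g. sulfur in sulfides, sulfoxides and sulfones). Nitrogen
# admits 5 because the canonicalisation authority (OpenBabel) writes nitro
# and N-oxide groups in the neutral hypervalent form.
.VALENCE_TABLE <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  Cl = 1L, Br = 1L, I = 1L, Se = c(2L, 4L, 6L), "*" = 1L
)

# Allowed valence after a formal charge: N+ is tetravalent, O- monovalent...
.allowed_valence <- function(element, charge) {
  base <- .VALENCE_TABLE[[element]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  if (element %in% c("N", "P")) return(base + charge)
  if (element %in% c("O", "S", "Se")) return(base + charge)
  if (element == "C") return(base - abs(charge))
  if (element == "B") return(base - charge)
  base
}

# Sum of bond orders at each atom; aromatic mol-block bonds (order 4) are
# never produced by OpenBabel's kekulised output, so orders are 1/2/3.
.bond_order_sums <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (i in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[i]
      s[mol$bonds$a1[i] + 1L] <- s[mol$bonds$a1[i] + 1L] + o
      s[mol$bonds$a2[i] + 1L] <- s[mol$bonds$a2[i] + 1L] + o
    }
  }
  s
}

#' Count implicit hydrogens on each atom
#'
#' Implicit hydrogen counts are derived from the standard valence of each
#' element (adjusted for formal charge) minus the explicit bond-order sum.
#'
#' @param mol A `Molecule`.
#' @return Integer vector, one entry per atom (0-based atom `i` is entry
#'   `i + 1`).
#' @export
implicit_hydrogens <- function(mol) {
  sums <- .bond_order_sums(mol)
  vapply(seq_len(nrow(mol$atoms)), function(i) {
    allowed <- .allowed_valence(mol$atoms$element[i], mol$atoms$charge[i])
    if (is.null(allowed)) return(0L)
    fits <- allowed[allowed >= sums[i]]
    if (length(fits) == 0) return(0L)
    as.integer(min(fits) - sums[i])
  }, integer(1))
}

#' Validate standard valence on every atom
#'
#' Every molecule the package constructs or emits passes through this
#' validator. An atom is valid when its explicit bond-order sum does not
#' exceed a standard valence for its element and formal charge.
#'
#' @param mol A `Molecule`.
#' @return Invisibly `TRUE`; signals `ChemistryError` on violation.
#' @export
check_valence <- function(mol) {
  sums <- .bond_order_sums(mol)
  for (i in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[i]
    allowed <- .allowed_valence(el, mol$atoms$charge[i])
    if (is.null(allowed)) {
      stop_chemistry(sprintf("unknown element '%s' at atom %d", el, i - 1L))
    }
    if (all(sums[i] > allowed)) {
      stop_chemistry(sprintf(
        "valence violation at atom %d (%s, charge %+d): bond order sum %g exceeds allowed {%s}",
        i - 1L, el, mol$atoms$charge[i], sums[i], paste(allowed, collapse = ",")
      ))
    }
  }
  invisible(TRUE)
}

# TRUE when a canonical SMILES parses and passes the valence validator.
.valence_ok <- function(smiles) {
  tryCatch({
    check_valence(.molecule_from_canonical(smiles))
    TRUE
  }, error = function(e) FALSE)
}

# igraph view of the heavy-atom graph; vertex attribute 'element',
# edge attribute 'border' (bond order, aromatic pairs coded as "ar" when
# requested so kekulisation cannot break matching).
.mol_igraph <- function(mol, aromatic_as_class = TRUE) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  igraph::V(g)$element <- mol$atoms$element
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1 + 1L, mol$bonds$a2 + 1L))
    cls <- as.character(mol$bonds$order)
    if (aromatic_as_class) {
      arom <- mol$atoms$aromatic[mol$bonds$a1 + 1L] & mol$atoms$aromatic[mol$bonds$a2 + 1L]
      cls[arom] <- "ar"
    }
    igraph::E(g)$border <- cls
  }
  g
}
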