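#' Standardize a molecule
#'
#' Produces the single species every downstream stage works on: formal
#' charges are neutralised where chemically safe (OpenBabel's neutralise
#' operation, which leaves balanced zwitterions such as nitro groups and
#' permanent charges such as quaternary ammonium untouched), and one
#' canonical tautomer is selected deterministically via an InChI
#' round-trip (InChI pools mobile hydrogens, so 2-hydroxypyridine and
#' 2-pyridone map to the same output). The operation is idempotent.
#'
#' @param mol A `Molecule`.
#' @return A standardized `Molecule`; if a permanent charge survives
#'   neutralisation the attribute `note` documents it.
#' @examples
#' \donttest{
#' standardize(parse_smiles("CC(=O)[O-]"))$smiles  # "CC(=O)O"
#' }
#' @export
standardize <- function(mol) {
  stopifnot(is_molecule(mol))
  neut <- .ob_convert("SMI", "CAN", paste0(mol$smiles, "\n"),
                      opts = .ob_options("neutralize"))
  neut <- sub("[\t ].*$", "", trimws(neut))
  if (!nzchar(neut)) neut <- mol$smiles
  # canonical tautomer via InChI round-trip; keep the neutralised form when
  # the molecule has no InChI (e.g. attachment dummies)
  taut <- neut
  inchi <- .ob_convert("SMI", "INCHI", paste0(neut, "\n"))
  if (nzchar(trimws(inchi))) {
    back <- .ob_convert("INCHI", "CAN", inchi)
    back <- sub("[\t ].*$", "", trimws(back))
    if (nzchar(back)) taut <- back
  }
  out <- parse_smiles(taut, name = mol$name)
  if (any(out$atoms$charge != 0L)) {
    attr(out, "note") <- "permanent charge retained (not neutralisable)"
  }
  out
}

#' Physicochemical profile of a molecule
#'
#' Molecular weight (standard atomic masses, implicit hydrogens included),
#' logP by the Wildman-Crippen atomic-contribution scheme as implemented in
#' OpenBabel (pinned estimator of this package), hydrogen-bond donor and
#' acceptor counts, rotatable bonds and topological polar surface area.
#'
#' @param mol A `Molecule` (ideally standardized).
#' @return A `PhyschemProfile`: one-row data.frame with columns
#'   `molecular_weight` (g/mol), `logp`, `hbd`, `hba`, `rotatable_bonds`,
#'   `tpsa` (A^2).
#' @export
physchem_profile <- function(mol) {
  stopifnot(is_molecule(mol))
  out <- .physchem_table(mol$smiles)
  class(out) <- c("PhyschemProfile", class(out))
  out
}

# SMARTS defining a rotatable bond: single, acyclic, both ends heavy and
# non-terminal, neither end triple-bonded.
.ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

# Vectorised property computation over SMILES strings (one OpenBabel pass).
.physchem_table <- function(smiles) {
  if (length(smiles) == 0L) {
    return(data.frame(molecular_weight = numeric(0), logp = numeric(0),
                      hbd = integer(0), hba = integer(0),
                      rotatable_bonds = integer(0), tpsa = numeric(0)))
  }
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  rows <- ChemmineOB::forEachMol("SMILES", src, function(m) {
    p <- ChemmineOB::prop_OB(m)
    r <- ChemmineOB::smartsSearch_OB(list(m), .ROTOR_SMARTS, uniqueMatches = TRUE)
    c(MW = p$MW, logP = p$logP, HBD = p$HBD, HBA1 = p$HBA1,
      rot = as.numeric(r), TPSA = p$TPSA)
  })
  m <- do.call(rbind, rows)
  data.frame(
    molecular_weight = m[, "MW"],
    logp = m[, "logP"],
    hbd = as.integer(m[, "HBD"]),
    hba = as.integer(m[, "HBA1"]),
    rotatable_bonds = as.integer(m[, "rot"]),
    tpsa = m[, "TPSA"],
    row.names = NULL
  )
}

#' Match a molecule against named structural alerts
#'
#' @param mol A `Molecule`.
#' @param alert_set Alerts: a data.frame with columns `id` and `smarts`, or
#'   the path of a text file with one `SMARTS id` pair per line (`#`
#'   comments allowed).
#' @return Character vector of alert ids with at least one substructure
#'   match (empty when clean).
#' @export
substructure_alerts <- function(mol, alert_set = default_alert_set()) {
  stopifnot(is_molecule(mol))
  alerts <- .load_alert_set(alert_set)
  hits <- .alert_matrix(mol$smiles, alerts)
  alerts$id[hits[1, ] > 0]
}

#' Default structural alert set shipped with the package
#' @return data.frame with columns `id`, `smarts`.
#' @export
default_alert_set <- function() {
  .load_alert_set(system.file("extdata", "structural_alerts.txt",
                              package = "dckdesign", mustWork = TRUE))
}

.load_alert_set <- function(alert_set) {
  if (is.character(alert_set) && length(alert_set) == 1L) {
    lines <- readLines(alert_set)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\\s+")
    alert_set <- data.frame(
      id = vapply(parts, `[`, character(1), 2),
      smarts = vapply(parts, `[`, character(1), 1),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(alert_set), all(c("id", "smarts") %in% names(alert_set)))
  alert_set
}

# Hit-count matrix (molecules x alerts); unparsable SMARTS -> ConfigError.
.alert_matrix <- function(smiles, alerts) {
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  patterns <- alerts$smarts
  rows <- ChemmineOB::forEachMol("SMILES", src, function(m) {
    vapply(patterns, function(pat) {
      h <- tryCatch(
        ChemmineOB::smartsSearch_OB(list(m), pat, uniqueMatches = TRUE),
        error = function(e) NA_real_
      )
      as.numeric(h)
    }, numeric(1))
  })
  out <- do.call(rbind, rows)
  bad <- which(colSums(is.na(out)) > 0)
  if (length(bad) > 0) {
    stop_config(sprintf("alert '%s': SMARTS pattern does not parse: %s",
                        alerts$id[bad[1]], alerts$smarts[bad[1]]))
  }
  storage.mode(out) <- "integer"
  out
}

#' Default physicochemical windows
#'
#' Campaign-tunable defaults for discarding compounds with unreasonable
#' properties, not measured values: molecular weight at most 650 g/mol,
#' logP at most 6, at most 12 rotatable bonds.
#'
#' @return Named list of `c(min, max)` windows keyed by profile column.
#' @export
default_filter_windows <- function() {
  list(
    molecular_weight = c(0, 650),
    logp = c(-Inf, 6),
    rotatable_bonds = c(0, 12)
  )
}

#' Filter a designed library by alerts and property windows
#'
#' Compounds are standardized on the fly (profiles are computed on the
#' standardized form), then tested first against the structural alerts and
#' then against each property window, in a fixed rule order; the first
#' triggered rule is the recorded rejection reason.
#'
#' @param lib A `DesignedLibrary` or list of `DesignedCompound`.
#' @param windows Named list of `c(min, max)` property windows (keys among
#'   the `physchem_profile` columns; an absent property is unconstrained).
#' @param alert_set Alerts as in [substructure_alerts()]; `NULL` disables
#'   alert filtering.
#' @param profiles Optional precomputed profile table (one row per library
#'   member) to avoid recomputation.
#' @return List with `retained` (the surviving sub-library) and `report`
#'   (a `FilterReport`: `input_count`, `retained_count`, `rule_counts`,
#'   and per-compound `verdicts`).
#' @export
filter_library <- function(lib, windows = default_filter_windows(),
                           alert_set = default_alert_set(), profiles = NULL) {
  n <- length(lib)
  for (w in names(windows)) {
    win <- windows[[w]]
    if (length(win) != 2L || (!anyNA(win) && win[1] > win[2])) {
      stop_config(sprintf("window '%s': min exceeds max", w))
    }
  }
  smiles <- vapply(lib, function(p) p$molecule$smiles, character(1))

  if (is.null(profiles)) {
    std <- vapply(lib, function(p) standardize(p$molecule)$smiles, character(1))
    profiles <- .physchem_table(std)
  }
  stopifnot(nrow(profiles) == n)

  alerts <- if (is.null(alert_set)) NULL else .load_alert_set(alert_set)
  amat <- if (is.null(alerts) || n == 0L) NULL else .alert_matrix(smiles, alerts)

  rule_ids <- c(if (!is.null(alerts)) paste0("alert:", alerts$id),
                paste0("window:", names(windows)))
  verdict <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.null(amat)) {
      hit <- which(amat[i, ] > 0)
      if (length(hit) > 0) { verdict[i] <- paste0("alert:", alerts$id[hit[1]]); next }
    }
    for (w in names(windows)) {
      v <- profiles[[w]][i]
      win <- windows[[w]]
      if (!is.na(v) && (v < win[1] || v > win[2])) {
        verdict[i] <- paste0("window:", w); break
      }
    }
  }

  keep <- is.na(verdict)
  retained <- lib[keep]
  class(retained) <- class(lib)
  rule_counts <- vapply(rule_ids, function(r) sum(verdict == r, na.rm = TRUE), integer(1))
  report <- structure(
    list(input_count = n,
         retained_count = sum(keep),
         rule_counts = rule_counts,
         verdicts = data.frame(smiles = smiles,
                               retained = keep,
                               rule = ifelse(keep, "", verdict),
                               stringsAsFactors = FALSE)),
    class = "FilterReport"
  )
  list(retained = retained, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("<FilterReport> %d in, %d retained\n", x$input_count, x$retained_count))
  nz <- x$rule_counts[x$rule_counts > 0]
  for (nm in names(nz)) cat(sprintf("  %s: %d\n", nm, nz[[nm]]))
  invisible(x)
}
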