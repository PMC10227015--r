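#' The structure-activity ledger
#'
#' Per-compound experimental summaries of the campaign -- thermal shift
#' (delta Tm), ITC dissociation constant, enzymatic IC50 (censoring-aware),
#' cellular IC50, c-KIT selectivity ratio -- together with the parent links
#' of the hit-to-lead decision tree. The ledger's arithmetic (fold changes,
#' differences) operates exactly on the stored values; censored entries
#' (stored with a `<` or `>` comparator) never enter ratios.
#'
#' @param records Long-format data.frame with columns `id`, `parent`,
#'   `field`, `value`, `comparator` (`""`, `"<"` or `">"`), `units`,
#'   `provenance`.
#' @return A `SarLedger`.
#' @export
sar_ledger <- function(records) {
  needed <- c("id", "parent", "field", "value", "comparator", "units", "provenance")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop_config(sprintf("ledger records lack column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  records$parent[is.na(records$parent)] <- ""
  records$comparator[is.na(records$comparator)] <- ""
  if (!all(records$comparator %in% c("", "<", ">"))) {
    stop_config("comparator must be one of '', '<', '>'")
  }
  if (any(!is.finite(records$value))) stop_config("ledger values must be finite")
  neg <- records$field != "delta_tm" & records$value <= 0
  if (any(neg)) {
    stop_config(sprintf("non-positive value for %s:%s",
                        records$id[neg][1], records$field[neg][1]))
  }
  dup <- duplicated(records[, c("id", "field")])
  if (any(dup)) {
    stop_config(sprintf("duplicate entry for %s:%s",
                        records$id[dup][1], records$field[dup][1]))
  }
  # one parent per compound
  par <- unique(records[, c("id", "parent")])
  if (anyDuplicated(par$id)) {
    stop_config("conflicting parent links for a compound")
  }
  structure(list(records = records), class = "SarLedger")
}

#' @export
print.SarLedger <- function(x, ...) {
  cat(sprintf("<SarLedger> %d compounds, %d values\n",
              length(unique(x$records$id)), nrow(x$records)))
  invisible(x)
}

#' The main-text campaign ledger shipped with the package
#'
#' Contains only values printed in the campaign's main text, each with a
#' provenance note; per-compound values reported only in supplementary
#' material are user-loadable, not shipped.
#'
#' @return A `SarLedger`.
#' @export
default_sar_ledger <- function() {
  read_sar_csv(system.file("extdata", "sar_main_text.csv",
                           package = "dckdesign", mustWork = TRUE))
}

#' Read / write a ledger CSV
#'
#' The CSV schema is the long format of [sar_ledger()]; the round-trip
#' CSV -> ledger -> CSV is lossless.
#'
#' @param path CSV file path.
#' @return `read_sar_csv()` a `SarLedger`; `write_sar_csv()` the path,
#'   invisibly.
#' @export
read_sar_csv <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("ledger file not found: %s", path))
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(comparator = "character",
                                        parent = "character"))
  sar_ledger(rec)
}

#' @rdname read_sar_csv
#' @param ledger A `SarLedger`.
#' @export
write_sar_csv <- function(ledger, path) {
  stopifnot(inherits(ledger, "SarLedger"))
  utils::write.csv(ledger$records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Value lookup; errors are classed so callers can distinguish a censored
# value from a missing one.
.sar_value <- function(ledger, id, field, require_uncensored = FALSE) {
  rec <- ledger$records
  hit <- which(rec$id == id & rec$field == field)
  if (length(hit) == 0) {
    stop_config(sprintf("no %s value for compound '%s'", field, id))
  }
  cmp <- rec$comparator[hit]
  if (require_uncensored && nzchar(cmp)) {
    stop_censored_value(sprintf(
      "%s of '%s' is censored ('%s %g') and cannot enter ratios",
      field, id, cmp, rec$value[hit]))
  }
  list(value = rec$value[hit], comparator = cmp)
}

#' Fold change between two compounds
#'
#' Exact arithmetic on stored values:
#' `value(numerator) / value(denominator)`. Both operands must be present
#' and uncensored.
#'
#' @param ledger A `SarLedger`.
#' @param numerator_id,denominator_id Compound ids.
#' @param field Field name (e.g. `"cellular_ic50"`, `"kd"`).
#' @return Numeric ratio.
#' @examples
#' \donttest{
#' led <- default_sar_ledger()
#' fold_change(led, "dCKi1", "OR0642", "cellular_ic50")  # > 1000
#' }
#' @export
fold_change <- function(ledger, numerator_id, denominator_id, field) {
  stopifnot(inherits(ledger, "SarLedger"))
  num <- .sar_value(ledger, numerator_id, field, require_uncensored = TRUE)
  den <- .sar_value(ledger, denominator_id, field, require_uncensored = TRUE)
  num$value / den$value
}

#' Difference of a field between two compounds
#'
#' @inheritParams fold_change
#' @param id_a,id_b Compound ids; returns `value(a) - value(b)`.
#' @return Numeric difference.
#' @export
delta_field <- function(ledger, id_a, id_b, field) {
  stopifnot(inherits(ledger, "SarLedger"))
  a <- .sar_value(ledger, id_a, field)
  b <- .sar_value(ledger, id_b, field)
  a$value - b$value
}

#' Export the hit-to-lead decision tree
#'
#' Validates that parent links form a forest (a self-parent or any cycle
#' is a `LedgerIntegrityError`), orders nodes topologically (roots first)
#' and annotates every node with its headline values (delta Tm, cellular
#' IC50) and the sign of change relative to its parent (`better`, `worse`,
#' `equal`, or `NA` when either value is absent; lower is better for IC50,
#' higher for delta Tm).
#'
#' @param ledger A `SarLedger`.
#' @param ids Optional subset of compound ids to export (links to
#'   compounds outside the subset are dropped).
#' @return A `DecisionTree`: list with `nodes` (annotated data.frame in
#'   topological order) and `edges` (`parent`, `child`).
#' @export
decision_tree_export <- function(ledger, ids = NULL) {
  stopifnot(inherits(ledger, "SarLedger"))
  rec <- ledger$records
  if (!is.null(ids)) rec <- rec[rec$id %in% ids, , drop = FALSE]
  nodes <- unique(rec$id)
  parent_of <- vapply(nodes, function(id) {
    p <- unique(rec$parent[rec$id == id])
    p <- p[nzchar(p)]
    if (length(p) == 0) "" else p[1]
  }, character(1))
  parent_of[!(parent_of %in% nodes)] <- ""       # dropped by subsetting

  if (any(parent_of == nodes & nzchar(parent_of))) {
    stop_ledger_integrity("compound is its own parent")
  }
  # topological order by repeated root removal; leftovers indicate a cycle
  order_out <- character(0)
  remaining <- nodes
  par <- parent_of
  while (length(remaining) > 0) {
    roots <- remaining[!(par[remaining] %in% remaining)]
    if (length(roots) == 0) {
      stop_ledger_integrity("parent links contain a cycle")
    }
    order_out <- c(order_out, sort(roots))
    remaining <- setdiff(remaining, roots)
  }

  val <- function(id, field) {
    hit <- which(rec$id == id & rec$field == field & !nzchar(rec$comparator))
    if (length(hit) == 0) NA_real_ else rec$value[hit]
  }
  improvement <- function(child, parent, field, higher_better) {
    if (!nzchar(parent)) return(NA_character_)
    cv <- val(child, field); pv <- val(parent, field)
    if (is.na(cv) || is.na(pv)) return(NA_character_)
    if (cv == pv) return("equal")
    better <- if (higher_better) cv > pv else cv < pv
    if (better) "better" else "worse"
  }
  nodes_df <- data.frame(
    id = order_out,
    parent = unname(parent_of[order_out]),
    delta_tm = vapply(order_out, val, numeric(1), field = "delta_tm"),
    cellular_ic50 = vapply(order_out, val, numeric(1), field = "cellular_ic50"),
    delta_tm_vs_parent = vapply(order_out, function(id)
      improvement(id, parent_of[[id]], "delta_tm", TRUE), character(1)),
    cellular_ic50_vs_parent = vapply(order_out, function(id)
      improvement(id, parent_of[[id]], "cellular_ic50", FALSE), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  edges <- nodes_df[nzchar(nodes_df$parent), c("parent", "id")]
  names(edges) <- c("parent", "child")
  rownames(edges) <- NULL
  structure(list(nodes = nodes_df, edges = edges), class = "DecisionTree")
}

#' @export
print.DecisionTree <- function(x, ...) {
  cat(sprintf("<DecisionTree> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Decision tree as DOT graph text
#'
#' @param tree A `DecisionTree` from [decision_tree_export()].
#' @return Character scalar with the DOT source.
#' @export
decision_tree_dot <- function(tree) {
  stopifnot(inherits(tree, "DecisionTree"))
  lab <- vapply(seq_len(nrow(tree$nodes)), function(i) {
    n <- tree$nodes[i, ]
    parts <- n$id
    if (!is.na(n$delta_tm)) parts <- paste0(parts, sprintf("\\ndTm %+.1f C", n$delta_tm))
    if (!is.na(n$cellular_ic50)) parts <- paste0(parts, sprintf("\\nIC50 %g nM", n$cellular_ic50))
    sprintf("  \"%s\" [label=\"%s\"];", n$id, parts)
  }, character(1))
  edg <- vapply(seq_len(nrow(tree$edges)), function(i) {
    sprintf("  \"%s\" -> \"%s\";", tree$edges$parent[i], tree$edges$child[i])
  }, character(1))
  paste(c("digraph sar_campaign {", "  rankdir=TB;", lab, edg, "}"),
        collapse = "\n")
}
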