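#' The generic modification dictionary
#'
#' The enumerable design space of the campaign: every entry is one chemical
#' modification -- a functional group, a (possibly decorated) 3- to
#' 6-membered ring, or either of those behind a short C/O/N spacer -- with a
#' single attachment dummy atom `[*]`. A dictionary is built
#' deterministically from a structured spec file, so rebuilding from the
#' same spec reproduces the identical entry set, in the identical
#' (lexicographic) order.
#'
#' @section Decoration positions:
#' Ring cores are written in the spec with the attachment dummy first and
#' ring atoms in cyclic order. Relative positions are counted from the
#' attachment atom: on 6-membered rings position 2 is *ortho*, 3 is *meta*,
#' 4 is *para*; on 3- to 5-membered rings the adjacent position maps to
#' *ortho* and the first non-adjacent one to *meta*. A decoration that
#' would fall on a hetero atom that cannot carry the substituent
#' (pyridine-type N, ring O) is skipped; a pyrrole-type `[nH]` is
#' N-substituted instead.
#'
#' @param spec A dictionary spec: either a path to a YAML file or an
#'   already-parsed list with components `functional_groups`, `rings`,
#'   `spacers` and optionally `decoration_group` (default `"C"`).
#' @return A `GenericDictionary`: list with `entries` (data.frame with
#'   columns `id`, `fragment_text` (canonical SMILES with one `[*]`),
#'   `category`, `ring_size`, `decoration`, `spacer`) and `spec_digest`
#'   (md5 of the normalised spec).
#' @examples
#' \donttest{
#' dict <- build_generic_dictionary(default_dictionary_spec())
#' nrow(dict$entries)
#' }
#' @export
build_generic_dictionary <- function(spec) {
  spec <- .load_dictionary_spec(spec)
  dec_group <- spec$decoration_group %||% "C"
  spacers <- .spacer_sequences(spec$spacers)

  rows <- list()
  add_row <- function(id, fragment, category, ring_size, decoration, spacer) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, fragment_text = fragment, category = category,
      ring_size = ring_size, decoration = decoration, spacer = spacer,
      stringsAsFactors = FALSE
    )
  }

  for (fg in spec$functional_groups) {
    body <- .fragment_body(fg$smiles, fg$id)
    for (sp in spacers) {
      frag <- paste0("[*]", sp, body)
      can <- .canonical_fragment(frag)
      if (is.na(can)) next
      add_row(.entry_id("fg", fg$id, "none", sp), can, "functional_group",
              NA_integer_, NA_character_, sp)
    }
  }

  for (ring in spec$rings) {
    size <- as.integer(ring$size)
    if (is.na(size) || size < 3L || size > 6L) {
      stop_config(sprintf("ring '%s': size %s outside 3-6", ring$id, ring$size))
    }
    decs <- ring$decorations %||% list("none")
    for (dec in unlist(decs)) {
      core <- .decorate_ring(ring$smiles, ring$id, size, dec, dec_group)
      if (is.na(core)) next
      body <- .fragment_body(core, ring$id)
      for (sp in spacers) {
        frag <- paste0("[*]", sp, body)
        can <- .canonical_fragment(frag)
        if (is.na(can)) next
        if (sp == "" && dec == "none" && !identical(can, .canonical_fragment(ring$smiles))) {
          # undecorated, unspaced core must survive canonicalisation
          stop_config(sprintf("ring '%s': core SMILES fails to canonicalise", ring$id))
        }
        add_row(.entry_id("ring", ring$id, dec, sp), can, "ring", size, dec, sp)
      }
    }
  }

  entries <- if (length(rows) == 0) {
    data.frame(id = character(0), fragment_text = character(0),
               category = character(0), ring_size = integer(0),
               decoration = character(0), spacer = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  # dedup by canonical fragment text (keep the first spec-order generator),
  # then impose the deterministic lexicographic ordering
  entries <- entries[!duplicated(entries$fragment_text), , drop = FALSE]
  entries <- entries[order(entries$fragment_text, method = "radix"), , drop = FALSE]
  rownames(entries) <- NULL

  structure(
    list(entries = entries, spec_digest = .spec_digest(spec)),
    class = "GenericDictionary"
  )
}

#' @export
print.GenericDictionary <- function(x, ...) {
  cat(sprintf("<GenericDictionary> %d entries (digest %s)\n",
              nrow(x$entries), substr(x$spec_digest, 1, 8)))
  tab <- table(x$entries$category)
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Path of the default dictionary spec shipped with the package
#' @return File path to the YAML spec.
#' @export
default_dictionary_spec <- function() {
  system.file("extdata", "dictionary_spec.yaml", package = "dckdesign",
              mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable digest of the generating spec: md5 of its normalised YAML form.
.spec_digest <- function(spec) {
  norm <- spec[order(names(spec))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(yaml::as.yaml(norm), tmp)
  unname(tools::md5sum(tmp))
}

.load_dictionary_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!file.exists(spec)) stop_config(sprintf("dictionary spec file not found: %s", spec))
    spec <- yaml::read_yaml(spec)
  }
  if (!is.list(spec)) stop_config("dictionary spec must be a file path or a list")
  spec$functional_groups <- spec$functional_groups %||% list()
  spec$rings <- spec$rings %||% list()
  spec$spacers <- spec$spacers %||% list(lengths = 0L, atoms = "C")
  for (fg in spec$functional_groups) {
    if (is.null(fg$id) || is.null(fg$smiles)) {
      stop_config("every functional group needs 'id' and 'smiles'")
    }
    .assert_one_dummy(fg$smiles, fg$id)
  }
  for (ring in spec$rings) {
    if (is.null(ring$id) || is.null(ring$smiles) || is.null(ring$size)) {
      stop_config("every ring needs 'id', 'smiles' and 'size'")
    }
    .assert_one_dummy(ring$smiles, ring$id)
  }
  spec
}

.assert_one_dummy <- function(smiles, id) {
  n_dummy <- lengths(regmatches(smiles, gregexpr("\\[\\*\\]", smiles)))
  if (n_dummy != 1L) {
    stop_config(sprintf("entry '%s': fragment must contain exactly one [*] dummy (found %d)",
                        id, n_dummy))
  }
  invisible(TRUE)
}

# All spacer strings for the configured lengths/atoms, e.g. "", "C", "OC".
# The written order is attachment-proximal first: "[*]" + spacer + body.
.spacer_sequences <- function(spacer_spec) {
  lengths <- as.integer(unlist(spacer_spec$lengths %||% 0L))
  atoms <- as.character(unlist(spacer_spec$atoms %||% "C"))
  if (!all(atoms %in% c("C", "O", "N"))) {
    stop_config("spacer atoms must be from {C, O, N}")
  }
  out <- character(0)
  for (len in sort(unique(lengths))) {
    if (len < 0L || len > 3L) stop_config("spacer lengths must be in 0-3")
    if (len == 0L) {
      out <- c(out, "")
    } else {
      grid <- do.call(expand.grid, rep(list(atoms), len))
      out <- c(out, apply(grid[, rev(seq_len(len)), drop = FALSE], 1, paste0, collapse = ""))
    }
  }
  unique(out)
}

.fragment_body <- function(smiles, id) {
  if (!startsWith(smiles, "[*]")) {
    stop_config(sprintf("entry '%s': fragment SMILES must start with [*]", id))
  }
  substring(smiles, 4L)
}

# Canonical fragment text; NA when OpenBabel rejects the SMILES or the
# assembled fragment is not valence-valid.
.canonical_fragment <- function(smiles) {
  can <- tryCatch(canonical_smiles(smiles), error = function(e) NA_character_)
  if (is.na(can)) return(NA_character_)
  ok <- tryCatch({
    check_valence(.molecule_from_canonical(can))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(NA_character_)
  can
}

.entry_id <- function(kind, id, decoration, spacer) {
  sp <- if (nzchar(spacer)) spacer else "0"
  if (decoration == "none") sprintf("%s:%s|sp:%s", kind, id, sp)
  else sprintf("%s:%s|%s|sp:%s", kind, id, decoration, sp)
}

# Relative position (1-based, counted from the attachment atom) of each
# decoration label, by ring size.
.decoration_position <- function(size, decoration) {
  if (decoration == "none") return(NA_integer_)
  pos <- switch(decoration, ortho = 2L, meta = 3L, para = 4L,
                stop_config(sprintf("unknown decoration label '%s'", decoration)))
  if (decoration == "para" && size != 6L) return(NA_integer_)   # undefined
  if (decoration == "meta" && size < 4L) return(NA_integer_)
  if (pos > size) return(NA_integer_)
  pos
}

# Tokenise a ring core written as "[*]" + ring atoms in cyclic order.
# Allowed atom tokens: bracket atoms, Cl/Br, single letters; each may carry
# ring-closure digits. Branches are not allowed in ring cores.
.ring_tokens <- function(core, id) {
  body <- .fragment_body(core, id)
  pat <- "\\[[^]]+\\]|Cl|Br|[A-Za-z]"
  toks <- list()
  i <- 1L
  while (i <= nchar(body)) {
    m <- regexpr(pat, substring(body, i))
    if (m != 1L) stop_config(sprintf("ring '%s': unsupported core SMILES '%s'", id, core))
    atom <- regmatches(substring(body, i), m)
    i <- i + attr(m, "match.length")
    digits <- ""
    while (i <= nchar(body) && grepl("^[0-9%]", substring(body, i, i))) {
      digits <- paste0(digits, substring(body, i, i))
      i <- i + 1L
    }
    toks[[length(toks) + 1L]] <- list(atom = atom, digits = digits)
  }
  toks
}

# Insert the decoration substituent at the requested relative position.
# Returns the decorated core SMILES, or NA when the position cannot carry
# the substituent.
.decorate_ring <- function(core, id, size, decoration, dec_group) {
  if (decoration == "none") return(core)
  pos <- .decoration_position(size, decoration)
  if (is.na(pos)) return(NA_character_)
  toks <- .ring_tokens(core, id)
  if (length(toks) != size) {
    stop_config(sprintf("ring '%s': %d ring atoms found, size says %d",
                        id, length(toks), size))
  }
  t <- toks[[pos]]
  new_atom <- if (t$atom %in% c("C", "c", "N")) {
    t$atom
  } else if (t$atom == "[nH]") {
    "n"                                  # decoration replaces the N-H
  } else {
    return(NA_character_)                # O, o, n (pyridine-type), S...
  }
  toks[[pos]] <- list(atom = new_atom, digits = t$digits, branch = dec_group)
  parts <- vapply(toks, function(tk) {
    paste0(tk$atom, tk$digits,
           if (!is.null(tk$branch)) paste0("(", tk$branch, ")") else "")
  }, character(1))
  paste0("[*]", paste0(parts, collapse = ""))
}
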