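#' Attachment sites on a seed molecule
#'
#' An attachment site names the seed atom (0-based index) where a
#' dictionary fragment is plugged in, the campaign label of the position
#' (ring A..E or one of the linkers), and the attachment mode:
#' `substitute_hydrogen` replaces one hydrogen of the seed atom by the
#' fragment; `replace_terminal_group` deletes a terminal heavy atom at the
#' index and attaches the fragment to its former neighbour.
#'
#' @param seed_atom_index 0-based atom index in the seed.
#' @param site_label Site label, e.g. `"ring_A"` or `"linker_CD"`.
#' @param mode `"substitute_hydrogen"` or `"replace_terminal_group"`.
#' @return An `AttachmentSite` object.
#' @export
attachment_site <- function(seed_atom_index, site_label,
                            mode = c("substitute_hydrogen", "replace_terminal_group")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed_atom_index), length(seed_atom_index) == 1L,
            seed_atom_index >= 0, is.character(site_label), nzchar(site_label))
  structure(
    list(seed_atom_index = as.integer(seed_atom_index),
         site_label = site_label, mode = mode),
    class = "AttachmentSite"
  )
}

#' Attach a dictionary fragment to a seed molecule
#'
#' Replaces the fragment's dummy atom by a single bond to the seed atom,
#' re-perceives aromaticity and sanitises the product, which must pass the
#' same valence validator as every input.
#'
#' @param seed A `Molecule`.
#' @param site An `AttachmentSite`.
#' @param fragment A fragment: a one-row entry of a `GenericDictionary`, a
#'   list with `fragment_text` and `id`, or a bare SMILES string carrying
#'   exactly one `[*]`.
#' @param round_index Optimisation round the product belongs to (>= 1).
#' @return A `DesignedCompound`: list with `molecule`, `seed_name`,
#'   `site_label`, `fragment_id`, `round_index`.
#' @examples
#' \donttest{
#' benzene <- parse_smiles("c1ccccc1", name = "benzene")
#' site <- attachment_site(0, "ring_A")
#' attach_fragment(benzene, site, "[*]C")$molecule$smiles  # toluene
#' }
#' @export
attach_fragment <- function(seed, site, fragment, round_index = 1L) {
  stopifnot(is_molecule(seed), inherits(site, "AttachmentSite"))
  frag <- .as_fragment(fragment)
  idx <- site$seed_atom_index
  if (idx >= n_atoms(seed)) {
    stop_attachment(sprintf("seed atom index %d out of range (seed has %d atoms)",
                            idx, n_atoms(seed)))
  }

  seed_atoms <- seed$atoms
  seed_bonds <- seed$bonds
  anchor <- idx

  if (site$mode == "substitute_hydrogen") {
    if (implicit_hydrogens(seed)[idx + 1L] < 1L) {
      stop_attachment(sprintf(
        "no free valence: seed atom %d (%s) carries no hydrogen to substitute",
        idx, seed_atoms$element[idx + 1L]))
    }
    if (isTRUE(frag$identity)) {
      # hydrogen-for-hydrogen: the product is the seed itself
      return(structure(
        list(molecule = seed, seed_name = seed$name %||% seed$smiles,
             site_label = site$site_label, fragment_id = frag$id,
             round_index = as.integer(round_index)),
        class = "DesignedCompound"
      ))
    }
  } else {
    deg <- sum(seed_bonds$a1 == idx) + sum(seed_bonds$a2 == idx)
    if (deg != 1L) {
      stop_attachment(sprintf(
        "replace_terminal_group requires a terminal atom; atom %d has degree %d",
        idx, deg))
    }
    nb_row <- which(seed_bonds$a1 == idx | seed_bonds$a2 == idx)
    anchor <- if (seed_bonds$a1[nb_row] == idx) seed_bonds$a2[nb_row] else seed_bonds$a1[nb_row]
    # drop the terminal atom and its bond, remap indices
    keep <- setdiff(seq_len(nrow(seed_atoms)) - 1L, idx)
    remap <- integer(nrow(seed_atoms)); remap[keep + 1L] <- seq_along(keep) - 1L
    seed_atoms <- seed_atoms[keep + 1L, , drop = FALSE]
    seed_bonds <- seed_bonds[-nb_row, , drop = FALSE]
    seed_bonds$a1 <- remap[seed_bonds$a1 + 1L]
    seed_bonds$a2 <- remap[seed_bonds$a2 + 1L]
    anchor <- remap[anchor + 1L]
  }

  fmol <- frag$molecule
  dummy <- which(fmol$atoms$element == "*") - 1L
  if (length(dummy) != 1L) {
    stop_chemistry(sprintf("fragment must contain exactly one dummy atom (found %d)",
                           length(dummy)), fragment_id = frag$id)
  }
  nb_row <- which(fmol$bonds$a1 == dummy | fmol$bonds$a2 == dummy)
  if (length(nb_row) != 1L || fmol$bonds$order[nb_row] != 1L) {
    stop_chemistry("fragment dummy atom must have exactly one single bond",
                   fragment_id = frag$id)
  }
  fanchor <- if (fmol$bonds$a1[nb_row] == dummy) fmol$bonds$a2[nb_row] else fmol$bonds$a1[nb_row]

  fkeep <- setdiff(seq_len(nrow(fmol$atoms)) - 1L, dummy)
  fremap <- integer(nrow(fmol$atoms)); fremap[fkeep + 1L] <- seq_along(fkeep) - 1L
  fatoms <- fmol$atoms[fkeep + 1L, , drop = FALSE]
  fbonds <- fmol$bonds[-nb_row, , drop = FALSE]
  fbonds$a1 <- fremap[fbonds$a1 + 1L]
  fbonds$a2 <- fremap[fbonds$a2 + 1L]

  offset <- nrow(seed_atoms)
  atoms <- rbind(seed_atoms, fatoms)
  fbonds$a1 <- fbonds$a1 + offset
  fbonds$a2 <- fbonds$a2 + offset
  join <- data.frame(a1 = anchor, a2 = fremap[fanchor + 1L] + offset, order = 1L)
  bonds <- rbind(seed_bonds, fbonds, join)

  mb <- .molblock_from_graph(atoms, bonds)
  can <- .ob_convert("SDF", "CAN", mb)
  can <- sub("[\t ].*$", "", trimws(can))
  if (!nzchar(can)) {
    stop_chemistry("product could not be sanitised", fragment_id = frag$id)
  }
  product <- tryCatch(
    .molecule_from_canonical(can),
    error = function(e) stop_chemistry(conditionMessage(e), fragment_id = frag$id)
  )
  tryCatch(check_valence(product),
           error = function(e) stop_chemistry(conditionMessage(e), fragment_id = frag$id))

  structure(
    list(molecule = product,
         seed_name = seed$name %||% seed$smiles,
         site_label = site$site_label,
         fragment_id = frag$id,
         round_index = as.integer(round_index)),
    class = "DesignedCompound"
  )
}

#' @export
print.DesignedCompound <- function(x, ...) {
  cat(sprintf("<DesignedCompound> %s\n  seed=%s site=%s fragment=%s round=%d\n",
              x$molecule$smiles, x$seed_name, x$site_label, x$fragment_id,
              x$round_index))
  invisible(x)
}

.as_fragment <- function(fragment) {
  if (is.character(fragment) && length(fragment) == 1L) {
    text <- fragment; id <- fragment
  } else if (is.data.frame(fragment) && nrow(fragment) == 1L) {
    text <- fragment$fragment_text; id <- fragment$id
  } else if (is.list(fragment) && !is.null(fragment$fragment_text)) {
    text <- fragment$fragment_text; id <- fragment$id %||% fragment$fragment_text
  } else if (is.list(fragment) && !is.null(fragment$molecule)) {
    return(fragment)
  } else {
    stop_config("fragment must be a SMILES string or a dictionary entry")
  }
  # the identity modification [*][H] has no heavy-atom graph
  if (grepl("^\\[?\\*\\]?\\[H\\]$|^\\[H\\]\\[?\\*\\]?$", text)) {
    return(list(id = id, molecule = NULL, identity = TRUE))
  }
  list(id = id, molecule = parse_smiles(text))
}

#' Enumerate the analog library of a seed
#'
#' One product per (site, dictionary entry) pair that attaches
#' successfully, deduplicated by canonical SMILES across the whole library.
#' No diversity or clustering reduction is applied: close analogs are kept
#' by design. Ordering of the result is deterministic (lexicographic by
#' canonical product SMILES).
#'
#' @param seed A `Molecule`.
#' @param sites A list of `AttachmentSite` objects (at least one).
#' @param dictionary A `GenericDictionary`.
#' @param round_index Optimisation round recorded on every product.
#' @return A `DesignedLibrary`: list of `DesignedCompound` objects, with
#'   attributes `failure_counts` (named per site) and `n_attempted`.
#' @export
enumerate_library <- function(seed, sites, dictionary, round_index = 1L) {
  stopifnot(is_molecule(seed), inherits(dictionary, "GenericDictionary"))
  if (inherits(sites, "AttachmentSite")) sites <- list(sites)
  if (length(sites) < 1L) stop_config("at least one attachment site is required")
  entries <- dictionary$entries

  # parse each fragment once, not once per site
  frags <- lapply(seq_len(nrow(entries)), function(i) {
    list(id = entries$id[i],
         molecule = tryCatch(parse_smiles(entries$fragment_text[i]),
                             error = function(e) NULL))
  })

  products <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  failures <- integer(length(sites))
  names(failures) <- vapply(sites, function(s) s$site_label, character(1))
  attempted <- 0L

  for (si in seq_along(sites)) {
    site <- sites[[si]]
    for (fr in frags) {
      attempted <- attempted + 1L
      if (is.null(fr$molecule)) { failures[si] <- failures[si] + 1L; next }
      dc <- tryCatch(
        attach_fragment(seed, site, fr, round_index = round_index),
        dckdesign_error = function(e) NULL
      )
      if (is.null(dc)) { failures[si] <- failures[si] + 1L; next }
      key <- dc$molecule$smiles
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      products[[length(products) + 1L]] <- dc
    }
  }

  if (length(products) == 0L) {
    stop_empty_library(
      paste0("no fragment attached at any site (failures per site: ",
             paste(sprintf("%s=%d", names(failures), failures), collapse = ", "), ")"),
      failure_counts = failures
    )
  }

  ord <- order(vapply(products, function(p) p$molecule$smiles, character(1)),
               method = "radix")
  structure(products[ord], class = "DesignedLibrary",
            failure_counts = failures, n_attempted = attempted)
}

#' @export
print.DesignedLibrary <- function(x, ...) {
  cat(sprintf("<DesignedLibrary> %d unique compounds (%d attachments attempted)\n",
              length(x), attr(x, "n_attempted")))
  invisible(x)
}

#' Library as a provenance table
#'
#' @param lib A `DesignedLibrary` (or plain list of `DesignedCompound`).
#' @return data.frame with columns `compound_id`, `seed`, `site`,
#'   `fragment_id`, `round`, `smiles`.
#' @export
library_table <- function(lib) {
  data.frame(
    compound_id = sprintf("DC%04d", seq_along(lib)),
    seed = vapply(lib, function(p) p$seed_name, character(1)),
    site = vapply(lib, function(p) p$site_label, character(1)),
    fragment_id = vapply(lib, function(p) p$fragment_id, character(1)),
    round = vapply(lib, function(p) p$round_index, integer(1)),
    smiles = vapply(lib, function(p) p$molecule$smiles, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a designed library as SDF plus a provenance CSV
#'
#' @param lib A `DesignedLibrary`.
#' @param prefix Output path prefix; writes `<prefix>.sdf` and
#'   `<prefix>.csv`.
#' @return Invisibly the two file paths.
#' @export
write_library <- function(lib, prefix) {
  tab <- library_table(lib)
  sdf_path <- paste0(prefix, ".sdf")
  csv_path <- paste0(prefix, ".csv")
  con <- file(sdf_path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(lib)) {
    mb <- .ob_convert("SMI", "SDF", paste0(lib[[i]]$molecule$smiles, "\n"),
                      opts = .ob_options("gen2d"))
    mb <- sub("\\$\\$\\$\\$\\s*$", "", mb)
    tags <- sprintf("> <%s>\n%s\n", c("compound_id", "seed", "site", "fragment_id"),
                    c(tab$compound_id[i], tab$seed[i], tab$site[i], tab$fragment_id[i]))
    writeLines(c(sub("\n$", "", mb), tags, "$$$$"), con)
  }
  utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(c(sdf = sdf_path, csv = csv_path))
}
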