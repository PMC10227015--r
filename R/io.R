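#' Read molecules from a SMILES or SDF file
#'
#' Per-record error isolation: an unparsable record is skipped (and
#' reported in the `skipped` attribute), the run continues. A file with no
#' valid record is an `EmptyInputError`.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @return List of `Molecule` objects; attributes `skipped` (count) and
#'   `messages`.
#' @export
read_molecules <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config(sprintf("input file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  mols <- list()
  skipped <- 0L
  msgs <- character(0)
  if (format == "smiles") {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      parts <- strsplit(ln, "\\s+")[[1]]
      m <- tryCatch(parse_smiles(parts[1],
                                 name = if (length(parts) > 1)
                                   paste(parts[-1], collapse = " ") else NULL),
                    error = function(e) NULL)
      if (is.null(m)) {
        skipped <- skipped + 1L
        msgs <- c(msgs, sprintf("skipped unparsable SMILES record: %s", parts[1]))
      } else {
        mols[[length(mols) + 1L]] <- m
      }
    }
  } else {
    confs <- tryCatch(read_conformers_sdf(path), error = function(e) list())
    for (cf in confs) {
      if (is.null(cf$molecule)) {
        skipped <- skipped + 1L
        msgs <- c(msgs, "skipped unparsable SDF record")
      } else {
        mols[[length(mols) + 1L]] <- cf$molecule
      }
    }
  }
  if (length(mols) == 0L) {
    stop_empty_input(sprintf("no valid molecule records in %s", path))
  }
  attr(mols, "skipped") <- skipped
  attr(mols, "messages") <- msgs
  mols
}

#' Read a receptor pocket from a PDB file
#'
#' Keeps heavy atoms of the selected records only; waters are excluded by
#' default and alternate locations are resolved to the highest-occupancy
#' conformer. Internal indexing is 0-based regardless of the file's atom
#' numbering.
#'
#' @param path PDB file.
#' @param chain Optional chain filter (character vector).
#' @param resid Optional residue-name filter (keep only these).
#' @param exclude_water Drop HOH/WAT/H2O residues (default `TRUE`).
#' @return A `ReceptorPocket` with `source` set to the file name.
#' @export
read_pocket <- function(path, chain = NULL, resid = NULL, exclude_water = TRUE) {
  if (!file.exists(path)) stop_config(sprintf("PDB file not found: %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (exclude_water) keep <- keep & !(at$resid %in% c("HOH", "WAT", "H2O"))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  at <- at[keep, , drop = FALSE]
  # element symbol: PDB element column when present, else from atom name
  elem <- trimws(at$elesy)
  fallback <- !nzchar(elem) | is.na(elem)
  elem[fallback] <- gsub("[^A-Za-z].*$", "", trimws(at$elety[fallback]))
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substring(elem, 2)))
  heavy <- elem != "H"
  at <- at[heavy, , drop = FALSE]; elem <- elem[heavy]
  if (nrow(at) == 0) stop_empty_selection("PDB selection matches no heavy atoms")
  # alternate locations: keep the highest occupancy per (chain, resno, atom)
  key <- paste(at$chain, at$resno, at$resid, at$elety)
  occ <- at$o; occ[is.na(occ)] <- 1
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]; elem <- elem[ord]; key <- key[ord]
  first <- !duplicated(key)
  at <- at[first, , drop = FALSE]; elem <- elem[first]
  receptor_pocket(cbind(at$x, at$y, at$z), elem, source = basename(path))
}

# ---- assay file readers (tidy CSV, as written by make_fixture) ------------

#' Read assay curves from tidy CSV files
#'
#' Readers for the CSV layouts produced by [make_fixture()]: one row per
#' observation, labelled columns.
#'
#' @param path CSV file.
#' @return The corresponding assay container.
#' @name assay-io
#' @export
read_melt_curve_csv <- function(path) {
  d <- utils::read.csv(path)
  melt_curve(d$temperature_c, d$fluorescence,
             label = if ("label" %in% names(d)) as.character(d$label[1]) else "apo")
}

#' @rdname assay-io
#' @export
read_kinetic_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  kinetic_trace(d$time_s, d$fluorescence,
                condition = if ("condition" %in% names(d))
                  as.character(d$condition[1]) else "drug_free")
}

#' @rdname assay-io
#' @export
read_dose_response_csv <- function(path) {
  d <- utils::read.csv(path)
  dose_response(d$concentration_nm, d$response_pct,
                replicate = if ("replicate" %in% names(d)) d$replicate else NULL)
}

#' @rdname assay-io
#' @export
read_itc_isotherm_csv <- function(path) {
  d <- utils::read.csv(path)
  itc_isotherm(d$heat_kcal_mol,
               injection_volumes = d$injection_volume_ul,
               cell_concentration = d$cell_uM[1],
               syringe_concentration = d$syringe_uM[1],
               cell_volume = d$cell_volume_ul[1])
}

# ---- pipeline -------------------------------------------------------------

#' Assemble and validate a run configuration
#'
#' One structured configuration is the single source of tunables for
#' [run_pipeline()]; unknown keys are rejected so typos cannot silently
#' disable a setting.
#'
#' @param config A named list or the path of a YAML file.
#' @return A validated `RunConfig` list (defaults filled in).
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed_smiles = NULL, seed_file = NULL, seed_name = "seed",
    sites = list(list(atom_index = 0L, label = "site_1",
                      mode = "substitute_hydrogen")),
    dictionary_spec = default_dictionary_spec(),
    windows = default_filter_windows(),
    alert_file = system.file("extdata", "structural_alerts.txt",
                             package = "dckdesign", mustWork = TRUE),
    torsion_rules = system.file("extdata", "torsion_rules.csv",
                                package = "dckdesign", mustWork = TRUE),
    template_sdf = NULL, receptor_pdb = NULL,
    weights = as.list(default_priority_weights()),
    clash_scale = 0.7, min_mcs = 5L, top_n = 25L,
    seed = 1L, log_level = "info"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  cfg[names(config)] <- config                   # wholesale key replacement
  for (key in c("dictionary_spec", "alert_file", "torsion_rules",
                "template_sdf", "receptor_pdb", "seed_file")) {
    p <- cfg[[key]]
    # dictionary_spec may also be an in-memory spec list
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      stop_config(sprintf("config key '%s': file not found: %s", key, p))
    }
  }
  class(cfg) <- c("RunConfig", class(cfg))
  cfg
}

.log_stage <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "silent")) return(invisible())
  message(sprintf("[dckdesign %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full design pipeline
#'
#' Enumerate, standardize, filter, embed, align against the template
#' bioactive conformation, evaluate clashes/torsions and prioritize -- with
#' per-stage counts collected in a single campaign report. The run is
#' fully reproducible from the configuration and its global seed.
#'
#' @param config A `RunConfig` (or list / YAML path accepted by
#'   [run_config()]).
#' @param report_path Optional path for the JSON campaign report.
#' @return The campaign report (list): per-stage counts, the prioritised
#'   ranking, and the effective configuration echo.
#' @export
run_pipeline <- function(config = list(), report_path = NULL) {
  cfg <- if (inherits(config, "RunConfig")) config else run_config(config)

  seed_mol <- if (!is.null(cfg$seed_smiles)) {
    parse_smiles(cfg$seed_smiles, name = cfg$seed_name)
  } else if (!is.null(cfg$seed_file)) {
    read_molecules(cfg$seed_file)[[1]]
  } else {
    toy_seed_set()$masitinib
  }
  sites <- lapply(cfg$sites, function(s) {
    attachment_site(s$atom_index, s$label %||% "site",
                    s$mode %||% "substitute_hydrogen")
  })

  report <- list(config = cfg[setdiff(names(cfg), "windows")],
                 windows = cfg$windows, stages = list())
  stage_fail <- function(stage, e) {
    report$stages[[stage]] <<- list(error = conditionMessage(e))
    report$failed_stage <<- stage
    if (!is.null(report_path)) {
      jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
    }
    stop(e)
  }

  .log_stage(cfg, "dictionary: %s", cfg$dictionary_spec)
  dict <- tryCatch(build_generic_dictionary(cfg$dictionary_spec),
                   error = function(e) stage_fail("dictionary", e))
  report$stages$dictionary <- list(entries = nrow(dict$entries),
                                   digest = dict$spec_digest)

  .log_stage(cfg, "enumerating %d sites x %d entries", length(sites),
             nrow(dict$entries))
  lib <- tryCatch(enumerate_library(seed_mol, sites, dict),
                  error = function(e) stage_fail("enumerate", e))
  report$stages$enumerate <- list(
    attempted = attr(lib, "n_attempted"),
    unique_compounds = length(lib),
    failure_counts = as.list(attr(lib, "failure_counts"))
  )

  .log_stage(cfg, "filtering %d compounds", length(lib))
  filt <- tryCatch(
    filter_library(lib, windows = cfg$windows, alert_set = cfg$alert_file),
    error = function(e) stage_fail("filter", e))
  report$stages$filter <- list(
    input = filt$report$input_count,
    retained = filt$report$retained_count,
    rule_counts = as.list(filt$report$rule_counts)
  )
  retained <- filt$retained

  template_conf <- if (!is.null(cfg$template_sdf)) {
    read_conformers_sdf(cfg$template_sdf)[[1]]
  } else {
    embed_conformer(seed_mol, seed = cfg$seed)
  }
  pocket <- if (!is.null(cfg$receptor_pdb)) read_pocket(cfg$receptor_pdb) else NULL

  n_eval <- min(length(retained), cfg$top_n)
  .log_stage(cfg, "evaluating %d poses", n_eval)
  evals <- list()
  embed_failures <- 0L
  for (i in seq_len(n_eval)) {
    ev <- tryCatch(
      evaluate_pose(retained[[i]], template_conf, pocket,
                    seed = cfg$seed, windows = cfg$windows,
                    scale = cfg$clash_scale, min_mcs = cfg$min_mcs),
      dckdesign_error = function(e) NULL)
    if (is.null(ev)) embed_failures <- embed_failures + 1L
    else evals[[length(evals) + 1L]] <- ev
  }
  if (length(evals) == 0) {
    stage_fail("evaluate", dck_error("EmbeddingError",
                                     "no compound could be evaluated"))
  }
  report$stages$evaluate <- list(evaluated = length(evals),
                                 failures = embed_failures)

  ranking <- prioritize(evals, weights = unlist(cfg$weights))
  report$stages$prioritize <- list(ranked = nrow(ranking))
  report$ranking <- ranking

  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    .log_stage(cfg, "report written to %s", report_path)
  }
  invisible(report)
}
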