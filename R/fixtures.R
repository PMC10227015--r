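#' Synthetic data generators with recorded ground truth
#'
#' Every input the analysis surface needs can be generated locally, with
#' the generating parameters stored alongside the output so recovery tests
#' are self-contained: toy seeds and dictionaries, melt curves, NADH decay
#' traces, dose-response tables, integrated ITC isotherms, pseudo-atom
#' receptor pockets and the main-text SAR ledger. Identical parameters and
#' seed reproduce byte-identical fixtures.
#'
#' @name synthetic-fixtures
#' @keywords internal
NULL

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate a thermal-shift melt curve
#'
#' Boltzmann sigmoid plus additive Gaussian noise on the fluorescence.
#'
#' @param tm True melting temperature (degrees C).
#' @param amplitude Transition amplitude (a.u.).
#' @param slope Transition slope parameter (degrees C).
#' @param baseline Pre-transition fluorescence.
#' @param noise_sd Gaussian noise SD in a.u. (e.g. 2% of amplitude).
#' @param seed RNG seed.
#' @param t_min,t_max,t_step Temperature grid (degrees C).
#' @param label Curve label.
#' @return A `MeltCurve` with attribute `ground_truth`.
#' @export
simulate_melt_curve <- function(tm = 50, amplitude = 1, slope = 1,
                                baseline = 0, noise_sd = 0, seed = 1,
                                t_min = 25, t_max = 95, t_step = 0.5,
                                label = "synthetic") {
  Tg <- seq(t_min, t_max, by = t_step)
  f <- baseline + amplitude / (1 + exp((tm - Tg) / slope))
  if (noise_sd > 0) {
    f <- .with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  }
  out <- melt_curve(Tg, f, label = label)
  attr(out, "ground_truth") <- list(tm = tm, amplitude = amplitude,
                                    slope = slope, noise_sd = noise_sd,
                                    seed = seed)
  out
}

#' Simulate an NADH-decay kinetic trace
#'
#' Linear decay (constant-velocity regime of the coupled assay), optionally
#' followed by a plateau once the signal is exhausted, plus Gaussian noise.
#'
#' @param slope True slope (a.u./s; negative for decay).
#' @param intercept Starting fluorescence (a.u.).
#' @param duration Total time (s).
#' @param n Number of points.
#' @param plateau_start Time at which the trace flattens (`Inf` = never).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param seed RNG seed.
#' @param condition Condition label.
#' @return A `KineticTrace` with attribute `ground_truth`.
#' @export
simulate_kinetic_trace <- function(slope = -3, intercept = 1000,
                                   duration = 120, n = 60,
                                   plateau_start = Inf, noise_sd = 0,
                                   seed = 1, condition = "synthetic") {
  tt <- seq(0, duration, length.out = n)
  y <- intercept + slope * pmin(tt, plateau_start)
  if (noise_sd > 0) y <- .with_seed(seed, y + stats::rnorm(n, 0, noise_sd))
  out <- kinetic_trace(tt, y, condition = condition)
  attr(out, "ground_truth") <- list(slope = slope, intercept = intercept,
                                    plateau_start = plateau_start,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a dose-response table
#'
#' Four-parameter logistic responses on a log-spaced concentration grid
#' (defaults follow the campaign's cellular assay range, 10 pM to 40 uM)
#' with additive Gaussian noise in percent points.
#'
#' @param ic50 True IC50 (nM).
#' @param hill Hill slope.
#' @param top,bottom Response plateaus (% of control).
#' @param conc_min,conc_max Concentration range (nM).
#' @param n_conc Number of concentrations (log-spaced).
#' @param replicates Technical replicates per concentration.
#' @param noise_sd Gaussian noise SD (percent points; 3 = 3%).
#' @param seed RNG seed.
#' @return A `DoseResponse` with attribute `ground_truth`.
#' @export
simulate_dose_response <- function(ic50 = 150, hill = 1, top = 100,
                                   bottom = 0, conc_min = 0.01,
                                   conc_max = 4e4, n_conc = 8,
                                   replicates = 3, noise_sd = 3, seed = 1) {
  conc <- 10^seq(log10(conc_min), log10(conc_max), length.out = n_conc)
  conc <- rep(conc, each = replicates)
  mu <- bottom + (top - bottom) / (1 + (conc / ic50)^hill)
  y <- if (noise_sd > 0) {
    .with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  } else mu
  out <- dose_response(conc, y, replicate = rep(seq_len(replicates),
                                                times = n_conc))
  attr(out, "ground_truth") <- list(ic50 = ic50, hill = hill, top = top,
                                    bottom = bottom, noise_sd = noise_sd,
                                    seed = seed)
  out
}

#' Simulate an integrated ITC isotherm
#'
#' Independent-sites forward model in the campaign's reverse-titration
#' geometry (titrant protein into cell compound), with additive Gaussian
#' noise scaled to the largest injection heat. The default schedule (25 x
#' 2.5 ul into 200 ul; 20 uM cell, 400 uM syringe) reaches molar ratios
#' beyond 5 so that a weak second site is informative.
#'
#' @param sites data.frame with columns `n`, `kd_nm`, `dh` (kcal/mol), one
#'   row per site.
#' @param n_injections Number of injections.
#' @param injection_volume Injection volume (ul).
#' @param cell_concentration,syringe_concentration Concentrations (uM).
#' @param cell_volume Cell volume (ul).
#' @param noise_frac Noise SD as a fraction of the largest |heat|.
#' @param seed RNG seed.
#' @return An `ItcIsotherm` with attribute `ground_truth`.
#' @export
simulate_itc_isotherm <- function(sites = data.frame(n = 1, kd_nm = 37, dh = -8),
                                  n_injections = 25, injection_volume = 2.5,
                                  cell_concentration = 20,
                                  syringe_concentration = 400,
                                  cell_volume = 200,
                                  noise_frac = 0, seed = 1) {
  shell <- itc_isotherm(rep(0, n_injections), injection_volume,
                        cell_concentration, syringe_concentration,
                        cell_volume = cell_volume)
  h <- .itc_forward(sites, shell)
  if (noise_frac > 0) {
    h <- .with_seed(seed, h + stats::rnorm(length(h), 0, noise_frac * max(abs(h))))
  }
  out <- itc_isotherm(h, injection_volume, cell_concentration,
                      syringe_concentration, cell_volume = cell_volume)
  attr(out, "ground_truth") <- list(sites = sites, noise_frac = noise_frac,
                                    seed = seed)
  out
}

#' Pseudo-atom pocket shell around a conformer
#'
#' Places pseudo-carbon atoms on a sphere (deterministic Fibonacci
#' lattice) centred on the conformer's heavy-atom centroid: a synthetic
#' receptor that by construction does not clash with the template at the
#' default clash scale.
#'
#' @param conf A `Conformer3D` (or n x 3 coordinate matrix).
#' @param radius Sphere radius (Angstrom).
#' @param n_points Number of pseudo atoms.
#' @return A `ReceptorPocket` (source `"synthetic"`).
#' @export
pocket_shell <- function(conf, radius = 12, n_points = 64) {
  coords <- if (inherits(conf, "Conformer3D")) {
    conf$coords[.heavy_indices(conf), , drop = FALSE]
  } else as.matrix(conf)
  centre <- colMeans(coords)
  i <- seq_len(n_points) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_points
  r <- sqrt(pmax(1 - z^2, 0))
  theta <- golden * i
  pts <- cbind(r * cos(theta), r * sin(theta), z) * radius
  pts <- sweep(pts, 2, centre, "+")
  receptor_pocket(pts, rep("C", n_points), source = "synthetic")
}

#' Toy seed molecules
#'
#' A masitinib-like seed (the campaign's parent scaffold) plus small toys.
#'
#' @return Named list of `Molecule` objects.
#' @export
toy_seed_set <- function() {
  list(
    masitinib = parse_smiles(
      "Cc1ccc(cc1Nc1nc(cs1)-c1cccnc1)NC(=O)c1ccc(CN2CCN(C)CC2)cc1",
      name = "masitinib"),
    benzene = parse_smiles("c1ccccc1", name = "benzene"),
    toluene = parse_smiles("Cc1ccccc1", name = "toluene"),
    para_xylene = parse_smiles("Cc1ccc(C)cc1", name = "para-xylene")
  )
}

#' Generate a fixture bundle on disk
#'
#' Dispatches on `kind`, writes the fixture files in the package's
#' standard formats and a `manifest.json` holding the generating
#' parameters (the ground truth), so a recovery test needs no other
#' information.
#'
#' @param kind One of `"seed_set"`, `"dictionary"`, `"melt_curve"`,
#'   `"kinetic_trace"`, `"dose_response"`, `"itc_isotherm"`, `"pocket"`,
#'   `"sar_ledger"`.
#' @param params Named list of generator parameters (per-kind).
#' @param seed RNG seed recorded in the manifest and used by noisy kinds.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, list with `files` and `ground_truth`.
#' @export
make_fixture <- function(kind, params = list(), seed = 1, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  files <- character(0)
  truth <- list(kind = kind, seed = seed, params = params)

  if (kind == "seed_set") {
    seeds <- toy_seed_set()
    lines <- vapply(seeds, function(m) paste(m$smiles, m$name), character(1))
    writeLines(lines, path("seeds.smi"))
    files <- path("seeds.smi")
  } else if (kind == "dictionary") {
    spec <- params$spec %||% list(
      functional_groups = list(list(id = "methyl", smiles = "[*]C"),
                               list(id = "methoxy", smiles = "[*]OC"),
                               list(id = "fluoro", smiles = "[*]F")),
      rings = list(list(id = "phenyl", size = 6, smiles = "[*]c1ccccc1",
                        decorations = list("none", "para"))),
      spacers = list(lengths = list(0L, 1L), atoms = list("C"))
    )
    writeLines(yaml::as.yaml(spec), path("dictionary.yaml"))
    files <- path("dictionary.yaml")
    truth$entry_count <- nrow(build_generic_dictionary(spec)$entries)
  } else if (kind == "melt_curve") {
    cur <- do.call(simulate_melt_curve, c(params, list(seed = seed)))
    utils::write.csv(data.frame(temperature_c = cur$temperature,
                                fluorescence = cur$fluorescence,
                                label = cur$label),
                     path("melt_curve.csv"), row.names = FALSE)
    files <- path("melt_curve.csv")
    truth$ground_truth <- attr(cur, "ground_truth")
  } else if (kind == "kinetic_trace") {
    tr <- do.call(simulate_kinetic_trace, c(params, list(seed = seed)))
    utils::write.csv(data.frame(time_s = tr$time,
                                fluorescence = tr$fluorescence,
                                condition = tr$condition),
                     path("kinetic_trace.csv"), row.names = FALSE)
    files <- path("kinetic_trace.csv")
    truth$ground_truth <- attr(tr, "ground_truth")
  } else if (kind == "dose_response") {
    dr <- do.call(simulate_dose_response, c(params, list(seed = seed)))
    utils::write.csv(data.frame(concentration_nm = dr$concentrations,
                                response_pct = dr$responses,
                                replicate = dr$replicate),
                     path("dose_response.csv"), row.names = FALSE)
    files <- path("dose_response.csv")
    truth$ground_truth <- attr(dr, "ground_truth")
  } else if (kind == "itc_isotherm") {
    iso <- do.call(simulate_itc_isotherm, c(params, list(seed = seed)))
    utils::write.csv(data.frame(injection = seq_along(iso$heats),
                                molar_ratio = iso$molar_ratios,
                                heat_kcal_mol = iso$heats,
                                injection_volume_ul = iso$injection_volumes,
                                cell_uM = iso$cell_concentration,
                                syringe_uM = iso$syringe_concentration,
                                cell_volume_ul = iso$cell_volume),
                     path("itc_isotherm.csv"), row.names = FALSE)
    files <- path("itc_isotherm.csv")
    truth$ground_truth <- attr(iso, "ground_truth")
    truth$ground_truth$sites <- as.list(truth$ground_truth$sites)
  } else if (kind == "pocket") {
    mol <- parse_smiles(params$smiles %||% "c1ccccc1")
    conf <- embed_conformer(mol, seed = seed)
    pk <- pocket_shell(conf, radius = params$radius %||% 12,
                       n_points = params$n_points %||% 64)
    .write_pocket_pdb(pk, path("pocket.pdb"))
    files <- path("pocket.pdb")
    truth$ground_truth <- list(radius = params$radius %||% 12,
                               n_points = params$n_points %||% 64,
                               template = mol$smiles)
  } else if (kind == "sar_ledger") {
    file.copy(system.file("extdata", "sar_main_text.csv",
                          package = "dckdesign", mustWork = TRUE),
              path("sar_ledger.csv"), overwrite = TRUE)
    files <- path("sar_ledger.csv")
  } else {
    stop_config(sprintf("unknown fixture kind '%s'", kind))
  }

  manifest <- path("manifest.json")
  jsonlite::write_json(truth, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(files = c(files, manifest), ground_truth = truth))
}

# Minimal PDB writer for pseudo-atom pockets (HETATM records only).
.write_pocket_pdb <- function(pocket, path) {
  lines <- vapply(seq_len(nrow(pocket$coords)), function(i) {
    sprintf("HETATM%5d  %-3s PSD A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, pocket$elements[i], i,
            pocket$coords[i, 1], pocket$coords[i, 2], pocket$coords[i, 3],
            pocket$elements[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
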