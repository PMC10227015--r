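# Synthetic fixture generation: determinism, manifests, recovery.

test_that("identical specs reproduce byte-identical fixture files", {
  for (kind in c("melt_curve", "dose_response", "itc_isotherm", "kinetic_trace")) {
    d1 <- tempfile(); d2 <- tempfile()
    f1 <- make_fixture(kind, params = list(), seed = 9, out_dir = d1)
    f2 <- make_fixture(kind, params = list(), seed = 9, out_dir = d2)
    for (k in seq_along(f1$files)) {
      expect_identical(readLines(f1$files[k]), readLines(f2$files[k]),
                       label = kind)
    }
  }
  expect_error(make_fixture("nonsense"), class = "ConfigError")
})

test_that("manifests carry enough ground truth to run the recovery", {
  d <- tempfile()
  make_fixture("melt_curve", params = list(tm = 61, noise_sd = 0.02),
               seed = 5, out_dir = d)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  curve <- read_melt_curve_csv(file.path(d, "melt_curve.csv"))
  tm <- melting_temperature(curve)
  expect_equal(as.numeric(tm), manifest$ground_truth$tm, tolerance = 0.2)

  d2 <- tempfile()
  make_fixture("dose_response", params = list(ic50 = 150, noise_sd = 3),
               seed = 7, out_dir = d2)
  man2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  dr <- read_dose_response_csv(file.path(d2, "dose_response.csv"))
  expect_equal(fit_ic50(dr)$fitted_ic50, man2$ground_truth$ic50,
               tolerance = 0.10)

  d3 <- tempfile()
  make_fixture("itc_isotherm",
               params = list(sites = data.frame(n = 1, kd_nm = 37, dh = -8)),
               seed = 3, out_dir = d3)
  iso <- read_itc_isotherm_csv(file.path(d3, "itc_isotherm.csv"))
  expect_equal(itc_fit(iso, "one_site")$sites$kd_nm, 37, tolerance = 0.05)
})

test_that("the pocket shell does not clash with its template", {
  conf <- embed_conformer(parse_smiles("Cc1ccccc1"), seed = 2)
  pk <- pocket_shell(conf, radius = 12, n_points = 64)
  counts <- clash_scores(conf, pk, scale = 0.7)
  expect_equal(unname(counts["inter"]), 0L)
  # all-pairs distance confirmation: every pocket atom beyond contact range
  heavy <- conf$coords[conf$elements != "H", , drop = FALSE]
  mind <- min(apply(pk$coords, 1, function(p)
    min(sqrt(rowSums(sweep(heavy, 2, p)^2)))))
  expect_gt(mind, 0.7 * (1.7 + 1.7))
})

test_that("dose-response fixtures recover IC50 within 10% across seeds", {
  errs <- vapply(1:200, function(s) {
    dr <- simulate_dose_response(ic50 = 150, hill = 1, noise_sd = 3, seed = s,
                                 n_conc = 8, replicates = 3)
    abs(fit_ic50(dr)$fitted_ic50 - 150) / 150
  }, numeric(1))
  expect_lt(stats::median(errs), 0.06)
  expect_lt(mean(errs), 0.10)
})

test_that("seed and dictionary fixtures are usable inputs", {
  d <- tempfile()
  make_fixture("seed_set", out_dir = d)
  mols <- read_molecules(file.path(d, "seeds.smi"))
  expect_gte(length(mols), 4L)
  expect_identical(mols[[1]]$name, "masitinib")

  d2 <- tempfile()
  fx <- make_fixture("dictionary", out_dir = d2)
  dict <- build_generic_dictionary(file.path(d2, "dictionary.yaml"))
  expect_equal(nrow(dict$entries), fx$ground_truth$entry_count)

  d3 <- tempfile()
  make_fixture("pocket", params = list(smiles = "c1ccccc1"), seed = 1,
               out_dir = d3)
  pk <- read_pocket(file.path(d3, "pocket.pdb"))
  expect_equal(nrow(pk$coords), 64L)
})
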