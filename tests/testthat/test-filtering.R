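# Standardisation, physicochemical profiles, alerts, filter algebra.

test_that("standardisation neutralises safely and picks one tautomer", {
  expect_identical(standardize(parse_smiles("CC(=O)[O-]"))$smiles,
                   canonical_smiles("CC(=O)O"))
  expect_identical(standardize(parse_smiles("c1ccccc1"))$smiles,
                   canonical_smiles("c1ccccc1"))
  # both tautomer inputs of 2-pyridone map to one canonical output
  a <- standardize(parse_smiles("Oc1ccccn1"))$smiles
  b <- standardize(parse_smiles("O=c1cccc[nH]1"))$smiles
  expect_identical(a, b)
  # permanent charge passes through with a note
  q <- standardize(parse_smiles("C[N+](C)(C)C"))
  expect_identical(q$smiles, canonical_smiles("C[N+](C)(C)C"))
  expect_match(attr(q, "note"), "permanent charge")
})

test_that("standardisation is idempotent on diverse molecules", {
  fixtures <- c("CC(=O)[O-]", "Oc1ccccn1", "CC[NH3+]", "C[N+](C)(C)C",
                "O=[N+]([O-])c1ccccc1", "c1ccc2[nH]ccc2c1",
                "Cc1ccc(cc1Nc1nc(cs1)-c1cccnc1)NC(=O)c1ccc(CN2CCN(C)CC2)cc1")
  for (smi in fixtures) {
    once <- standardize(parse_smiles(smi))
    twice <- standardize(once)
    expect_identical(twice$smiles, once$smiles, label = smi)
  }
})

test_that("physchem profiles match hand-checked values", {
  water <- physchem_profile(parse_smiles("O"))
  expect_equal(water$molecular_weight, 18.02, tolerance = 1e-3)

  benzene <- physchem_profile(parse_smiles("c1ccccc1"))
  expect_equal(benzene$hbd, 0L)
  expect_equal(benzene$hba, 0L)
  expect_equal(benzene$rotatable_bonds, 0L)

  # n-propylbenzene: frozen sum over the Wildman-Crippen atomic
  # contribution table (independently computed from the published scheme)
  pb <- physchem_profile(parse_smiles("CCCc1ccccc1"))
  expect_equal(pb$logp, 2.6391, tolerance = 1e-3)
  expect_equal(pb$rotatable_bonds, 2L)
})

test_that("profiles are stable across atom orderings and repeats", {
  forms <- c("CCCc1ccccc1", "c1ccccc1CCC", "c1ccc(CCC)cc1")
  profs <- lapply(forms, function(s) physchem_profile(standardize(parse_smiles(s))))
  for (p in profs[-1]) expect_equal(p, profs[[1]])
})

test_that("substructure alerts match and the ids are verified by VF2", {
  expect_length(substructure_alerts(parse_smiles("c1ccccc1")), 0L)
  expect_identical(substructure_alerts(parse_smiles("O=[N+]([O-])c1ccccc1")),
                   "nitro")
  hits <- substructure_alerts(parse_smiles("OOCC(=O)Cl"))
  expect_setequal(hits, c("peroxide", "acyl_halide"))

  # independent subgraph-isomorphism confirmation of both hits
  mol <- parse_smiles("OOCC(=O)Cl")
  g <- dckdesign:::.mol_igraph(mol, aromatic_as_class = FALSE)
  embed_pattern <- function(elements, edges) {
    pat <- igraph::make_empty_graph(length(elements), directed = FALSE)
    igraph::V(pat)$element <- elements
    pat <- igraph::add_edges(pat, edges)
    igraph::subgraph_isomorphic(
      pat, g, method = "vf2",
      vertex.color1 = dckdesign:::.element_colors(igraph::V(g)$element),
      vertex.color2 = dckdesign:::.element_colors(elements))
  }
  expect_true(embed_pattern(c("O", "O"), c(1, 2)))            # peroxide O-O
  expect_true(embed_pattern(c("Cl", "C", "O"), c(1, 2, 2, 3)))  # C(=O)Cl core
  expect_error(substructure_alerts(parse_smiles("CC"),
                                   data.frame(id = "bad", smarts = "[[[")),
               class = "ConfigError")
})

test_that("filtering accounts for every compound exactly once", {
  seed <- parse_smiles("c1ccccc1", name = "benzene")
  dict <- build_generic_dictionary(list(
    functional_groups = list(list(id = "methyl", smiles = "[*]C"),
                             list(id = "nitro", smiles = "[*][N+](=O)[O-]"),
                             list(id = "peroxy", smiles = "[*]OO"),
                             list(id = "amino", smiles = "[*]N")),
    spacers = list(lengths = 0L, atoms = "C")))
  lib <- enumerate_library(seed, list(attachment_site(0, "s")), dict)
  res <- filter_library(lib)
  rep <- res$report
  expect_equal(rep$input_count, length(lib))
  expect_equal(rep$retained_count + sum(rep$rule_counts), rep$input_count)
  expect_equal(nrow(rep$verdicts), rep$input_count)
  expect_equal(sum(rep$verdicts$retained), rep$retained_count)
  # vacuous filter keeps everything
  all_in <- filter_library(lib, windows = list(), alert_set = NULL)
  expect_equal(all_in$report$retained_count, length(lib))
  expect_error(filter_library(lib, windows = list(molecular_weight = c(10, 1))),
               class = "ConfigError")
})

test_that("a molecular weight threshold separates the library as expected", {
  lib <- list(
    structure(list(molecule = parse_smiles("c1ccccc1")), class = "DesignedCompound"),
    structure(list(molecule = toy_seed_set()$masitinib), class = "DesignedCompound")
  )
  res <- filter_library(lib, windows = list(molecular_weight = c(0, 100)),
                        alert_set = NULL)
  expect_equal(res$report$retained_count, 1L)
  expect_identical(res$retained[[1]]$molecule$smiles, canonical_smiles("c1ccccc1"))
})

test_that("tightening windows never grows the retained set (500 cases)", {
  seed <- parse_smiles("Cc1ccc(O)cc1", name = "cresol")
  dict <- build_generic_dictionary(list(
    functional_groups = list(list(id = "methyl", smiles = "[*]C"),
                             list(id = "tbutyl", smiles = "[*]C(C)(C)C"),
                             list(id = "methoxy", smiles = "[*]OC"),
                             list(id = "amino", smiles = "[*]N"),
                             list(id = "cyano", smiles = "[*]C#N")),
    spacers = list(lengths = list(0L, 1L, 2L), atoms = list("C", "O"))))
  h <- implicit_hydrogens(seed)
  sites <- lapply(which(seed$atoms$aromatic & h > 0) - 1L,
                  function(i) attachment_site(i, paste0("s", i)))
  lib <- enumerate_library(seed, sites, dict)
  std <- vapply(lib, function(p) standardize(p$molecule)$smiles, character(1))
  profiles <- dckdesign:::.physchem_table(std)

  withr_seed <- 20240915
  set.seed(withr_seed)
  keys <- c("molecular_weight", "logp", "rotatable_bonds", "tpsa")
  ranges <- list(molecular_weight = c(80, 400), logp = c(-2, 6),
                 rotatable_bonds = c(0, 10), tpsa = c(0, 120))
  for (rep_i in seq_len(500)) {
    key <- sample(keys, 1)
    r <- ranges[[key]]
    lo <- sort(runif(2, r[1], r[2]))
    wide <- list(); wide[[key]] <- c(r[1], lo[2])
    tight <- list(); tight[[key]] <- c(r[1], lo[1])       # tighter max
    kept_wide <- filter_library(lib, windows = wide, alert_set = NULL,
                                profiles = profiles)$report$verdicts$retained
    kept_tight <- filter_library(lib, windows = tight, alert_set = NULL,
                                 profiles = profiles)$report$verdicts$retained
    expect_true(all(!kept_tight | kept_wide))             # tight => wide
  }
})
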