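# Attachment semantics and library enumeration.

methyl_dict <- function() {
  build_generic_dictionary(list(
    functional_groups = list(list(id = "methyl", smiles = "[*]C")),
    spacers = list(lengths = 0L, atoms = "C")))
}

test_that("attachment produces the analytically forced products", {
  benzene <- parse_smiles("c1ccccc1", name = "benzene")
  site <- attachment_site(0, "ring_A")
  expect_identical(attach_fragment(benzene, site, "[*]C")$molecule$smiles,
                   canonical_smiles("Cc1ccccc1"))
  # identity modification leaves the seed unchanged
  expect_identical(attach_fragment(benzene, site, "[*][H]")$molecule$smiles,
                   benzene$smiles)
  # replacing a terminal group swaps the methyl of toluene for methoxy
  toluene <- parse_smiles("Cc1ccccc1")
  methyl_at <- which(!toluene$atoms$aromatic) - 1L
  swapped <- attach_fragment(toluene,
                             attachment_site(methyl_at, "x", "replace_terminal_group"),
                             "[*]OC")
  expect_identical(swapped$molecule$smiles, canonical_smiles("COc1ccccc1"))
})

test_that("attachment without free valence fails cleanly", {
  pyridine <- parse_smiles("c1ccncc1")
  n_idx <- which(pyridine$atoms$element == "N") - 1L
  expect_error(attach_fragment(pyridine, attachment_site(n_idx, "ring_A"), "[*]C"),
               class = "AttachmentError")
  # ipso carbon of toluene has no hydrogen either
  toluene <- parse_smiles("Cc1ccccc1")
  h <- implicit_hydrogens(toluene)
  ipso <- which(toluene$atoms$aromatic & h == 0L)[1] - 1L
  expect_error(attach_fragment(toluene, attachment_site(ipso, "x"), "[*]C"),
               class = "AttachmentError")
})

test_that("symmetric sites collapse after canonical dedup", {
  px <- parse_smiles("Cc1ccc(C)cc1", name = "para-xylene")
  h <- implicit_hydrogens(px)
  ch_sites <- which(px$atoms$aromatic & h >= 1L) - 1L   # 4 equivalent CH
  expect_length(ch_sites, 4L)
  sites <- lapply(seq_along(ch_sites), function(i)
    attachment_site(ch_sites[i], paste0("s", i)))
  lib <- enumerate_library(px, sites, methyl_dict())
  expect_length(lib, 1L)                                 # all products identical
  expect_equal(attr(lib, "n_attempted"), 4L)
})

test_that("library size is bounded and enumeration is idempotent", {
  seed <- parse_smiles("Cc1ccc(N)cc1", name = "toy")
  dict <- build_generic_dictionary(list(
    functional_groups = list(list(id = "methyl", smiles = "[*]C"),
                             list(id = "fluoro", smiles = "[*]F"),
                             list(id = "hydroxy", smiles = "[*]O")),
    spacers = list(lengths = list(0L, 1L), atoms = "C")))
  h <- implicit_hydrogens(seed)
  sites <- lapply(which(seed$atoms$aromatic & h >= 1L) - 1L,
                  function(i) attachment_site(i, paste0("s", i)))
  lib1 <- enumerate_library(seed, sites, dict)
  expect_lte(length(lib1), length(sites) * nrow(dict$entries))
  # enumerating twice and merging equals enumerating once
  lib2 <- enumerate_library(seed, sites, dict)
  s1 <- vapply(lib1, function(p) p$molecule$smiles, character(1))
  s2 <- vapply(lib2, function(p) p$molecule$smiles, character(1))
  expect_identical(s1, s2)
  expect_identical(sort(unique(c(s1, s2))), sort(s1))
  # every product passes the same valence validator as the inputs
  for (p in lib1) expect_silent(check_valence(p$molecule))
})

test_that("library matches an independent nested-loop enumerator", {
  seed <- parse_smiles("Cc1ccc(O)cc1", name = "cresol")
  dict <- build_generic_dictionary(list(
    functional_groups = list(list(id = "methyl", smiles = "[*]C"),
                             list(id = "amino", smiles = "[*]N"),
                             list(id = "cyano", smiles = "[*]C#N")),
    rings = list(list(id = "phenyl", size = 6, smiles = "[*]c1ccccc1",
                      decorations = list("none", "para"))),
    spacers = list(lengths = list(0L, 1L), atoms = list("C", "O"))))
  expect_lte(nrow(dict$entries), 50L)
  h <- implicit_hydrogens(seed)
  idx <- which(seed$atoms$aromatic & h >= 1L) - 1L
  sites <- lapply(idx, function(i) attachment_site(i, paste0("s", i)))
  lib <- enumerate_library(seed, sites, dict)

  # reference: plain double loop + character-vector dedup
  ref <- character(0)
  for (s in sites) for (k in seq_len(nrow(dict$entries))) {
    p <- tryCatch(attach_fragment(seed, s, dict$entries[k, ]),
                  error = function(e) NULL)
    if (!is.null(p)) ref <- c(ref, p$molecule$smiles)
  }
  ref <- sort(unique(ref))
  expect_identical(vapply(lib, function(p) p$molecule$smiles, character(1)), ref)
})

test_that("an impossible site yields EmptyLibraryError with counts", {
  pyridine <- parse_smiles("c1ccncc1")
  n_idx <- which(pyridine$atoms$element == "N") - 1L
  err <- tryCatch(
    enumerate_library(pyridine, list(attachment_site(n_idx, "ring_N")),
                      methyl_dict()),
    EmptyLibraryError = function(e) e)
  expect_s3_class(err, "EmptyLibraryError")
  expect_equal(unname(err$failure_counts["ring_N"]), 1L)
})

test_that("library export writes SDF plus provenance CSV", {
  benzene <- parse_smiles("c1ccccc1", name = "benzene")
  lib <- enumerate_library(benzene, list(attachment_site(0, "ring")), methyl_dict())
  prefix <- tempfile()
  paths <- write_library(lib, prefix)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths["csv"])
  expect_identical(tab$smiles, canonical_smiles("Cc1ccccc1"))
  expect_identical(tab$site, "ring")
})
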