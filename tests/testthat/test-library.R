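simple_spec <- function(template = "ACDEFGHIKL",
                        positions = tibble::tibble(position = c(2L, 5L),
                                                   allowed = c("CW", "FY")),
                        insertions = NULL) {
  library_spec(template, positions, insertions, name = "toy")
}

test_that("library size equals distinct-count from full enumeration", {
  ## 2 fully randomised positions + 4 binary positions
  spec <- library_spec(
    "ACDEFGHIKLMNPQRS",
    tibble::tibble(position = c(1L, 2L, 4L, 6L, 8L, 10L),
                   allowed = c(paste(sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]), collapse = ""),
                               paste(sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]), collapse = ""),
                               "DN", "FY", "IV", "LM")))
  vars <- enumerate_library(spec, mode = "full")
  expect_equal(library_size(spec), 20 * 20 * 2^4)
  expect_equal(length(unique(vars$variant)), library_size(spec))
})

test_that("degenerate specs: no diversity gives exactly the template", {
  spec <- library_spec("ACDEFG")
  expect_equal(library_size(spec), 1)
  vars <- enumerate_library(spec, mode = "full")
  expect_equal(vars$variant, "ACDEFG")
  st <- identity_stats(spec)
  expect_equal(st$min_identity, 100)
  expect_equal(st$max_identity, 100)
})

test_that("singleton positions never change the size; optional insertions multiply by k+1", {
  base <- simple_spec()
  with_singleton <- library_spec(
    "ACDEFGHIKL",
    tibble::tibble(position = c(2L, 5L, 7L), allowed = c("CW", "FY", "H")))
  expect_equal(library_size(with_singleton), library_size(base))
  with_ins <- library_spec(
    "ACDEFGHIKL",
    tibble::tibble(position = c(2L, 5L), allowed = c("CW", "FY")),
    tibble::tibble(after = 5L, residues = "GA", optional = TRUE))
  expect_equal(library_size(with_ins), library_size(base) * 3)
  mand <- library_spec(
    "ACDEFGHIKL",
    tibble::tibble(position = c(2L, 5L), allowed = c("CW", "FY")),
    tibble::tibble(after = 5L, residues = "GA", optional = FALSE))
  expect_equal(library_size(mand), library_size(base) * 2)
})

test_that("toy spec of size 8 matches hand enumeration", {
  spec <- library_spec(
    "AAA", tibble::tibble(position = 1:3, allowed = c("AG", "AG", "AG")))
  vars <- enumerate_library(spec, mode = "full")
  expect_setequal(vars$variant,
                  c("AAA", "GAA", "AGA", "GGA", "AAG", "GAG", "AGG", "GGG"))
  expect_equal(nrow(vars), 8L)
})

test_that("every enumerated variant uses only allowed residues at varied positions", {
  spec <- library_spec(
    "ACDEFGHIKL",
    tibble::tibble(position = c(3L, 6L), allowed = c("DE", "GW")),
    tibble::tibble(after = 8L, residues = "P", optional = TRUE))
  vars <- enumerate_library(spec, mode = "full")
  expect_true(all(substr(vars$variant, 3, 3) %in% c("D", "E")))
  expect_true(all(substr(vars$variant, 6, 6) %in% c("G", "W")))
  ## unvaried prefix is untouched
  expect_true(all(substr(vars$variant, 1, 2) == "AC"))
  expect_true(all(nchar(vars$variant) %in% c(10L, 11L)))
})

test_that("sampling is seeded and uniform over the grid", {
  spec <- simple_spec()
  s1 <- enumerate_library(spec, mode = "sample", n = 5, seed = 7)
  s2 <- enumerate_library(spec, mode = "sample", n = 5, seed = 7)
  expect_identical(s1, s2)
  s3 <- enumerate_library(spec, mode = "sample", n = 5, seed = 8)
  expect_false(identical(s1$variant, s3$variant))
  ## the ceiling guards full enumeration
  big <- library_spec(
    strrep("A", 40),
    tibble::tibble(position = 1:25, allowed = rep("AG", 25)))
  expect_error(enumerate_library(big, mode = "full"), "sample")
})

test_that("degenerate codons expand through the genetic code", {
  nns <- expand_degenerate_codon("NNS")
  expect_equal(nns$amino_acids, sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_true(nns$encodes_stop)       # TAG is in NNS
  expect_equal(nns$n_codons, 32L)
  nnk <- expand_degenerate_codon("NNK")
  expect_equal(nnk$amino_acids, nns$amino_acids)
  expect_true(nnk$encodes_stop)
  tgg <- expand_degenerate_codon("TGG")
  expect_equal(tgg$amino_acids, "W")
  expect_false(tgg$encodes_stop)
  expect_error(expand_degenerate_codon("NZS"), "IUPAC")
  expect_error(expand_degenerate_codon("NN"), "length")
  ## codon-tagged positions must match their allowed set
  expect_error(
    library_spec("AW", tibble::tibble(position = 2L, allowed = "WY",
                                      codon = "TGG")),
    "encodes")
})

test_that("identity statistics match the enumeration oracle", {
  ## 10-residue template, 2 binary positions -> min 80%
  spec <- library_spec(
    "ACDEFGHIKL",
    tibble::tibble(position = c(2L, 5L), allowed = c("CW", "FY")))
  st <- identity_stats(spec)
  expect_equal(st$min_identity, 80)
  expect_equal(st$max_identity, 100)
  vars <- enumerate_library(spec, mode = "full")
  ident <- function(v, t) {
    if (nchar(v) == nchar(t)) {
      100 * sum(strsplit(v, "")[[1]] == strsplit(t, "")[[1]]) / nchar(t)
    } else {
      ## single insertion: align by matching prefix/suffix around it
      100 * (nchar(t) - sum(strsplit(v, "")[[1]][seq_len(nchar(t))] !=
                              strsplit(t, "")[[1]])) / nchar(v)
    }
  }
  oracle <- vapply(vars$variant, ident, numeric(1), t = spec$template)
  expect_equal(st$mean_identity, mean(oracle))
  expect_equal(st$min_identity, min(oracle))
  ## with an optional insertion the oracle still agrees on min and mean
  spec_i <- library_spec(
    "ACDEFGHIKL",
    tibble::tibble(position = c(2L, 5L), allowed = c("CW", "FY")),
    tibble::tibble(after = 10L, residues = "P", optional = TRUE))
  vars_i <- enumerate_library(spec_i, mode = "full")
  oracle_i <- vapply(vars_i$variant, ident, numeric(1), t = spec_i$template)
  st_i <- identity_stats(spec_i)
  expect_equal(st_i$min_identity, min(oracle_i))
  expect_equal(st_i$mean_identity, mean(oracle_i))
})

test_that("library specs round-trip through their JSON form", {
  spec <- library_spec(
    "ACDEFGHIKL",
    tibble::tibble(position = c(2L, 5L), allowed = c("CW", "FY")),
    tibble::tibble(after = 5L, residues = "GA", optional = TRUE),
    name = "roundtrip")
  path <- withr::local_tempfile(fileext = ".json")
  write_library_spec(spec, path)
  back <- read_library_spec(path)
  expect_equal(back$template, spec$template)
  expect_equal(library_size(back), library_size(spec))
  expect_equal(back$name, "roundtrip")
})

test_that("spec validation rejects malformed inputs", {
  expect_error(library_spec("ACD", tibble::tibble(position = c(1L, 1L),
                                                  allowed = c("AG", "AC"))),
               "duplicate")
  expect_error(library_spec("ACD", tibble::tibble(position = 9L,
                                                  allowed = "AG")),
               "outside")
  expect_error(library_spec("ACD", tibble::tibble(position = 1L,
                                                  allowed = "")),
               "non-empty")
})
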