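## hand-built numbered antibody and toy antigen used for scoring tests
toy_query <- function() {
  res_h <- c("A", "A", "R", "A", "W", "A")
  res_l <- c("A", "G", "A", "A", "A", "A")
  structure(tibble::tibble(
    chain = rep(c("H", "L"), each = 6),
    seq_index = rep(1:6, 2), residue = c(res_h, res_l),
    position = rep(c(27L, 28L, 29L, 30L, 31L, 32L), 2),
    ins_letter = "", region = "CDR1", germline_flag = NA),
    scheme = "imgt")
}

toy_antigen <- function(seq = "AAGEAGA") {
  spec <- toy_complex_spec(c(nchar(seq), 2), sequences = c(seq, "AA"))
  select_chains(make_toy_complex(spec)$atoms, "A")
}

test_that("corpus curation applies the resolution, antigen-type and redundancy rules", {
  entries <- make_pair_corpus(
    n_entries = 6, seed = 5, redundant_twins = 2,
    resolutions = c(2.0, 2.5, 3.2, 2.2, 1.9, 2.8))
  entries$antigen_type[4] <- "peptide"
  entries$single_chain[5] <- TRUE
  cur <- curate_corpus(entries)
  expect_false("SYN003" %in% cur$entry_id)   # 3.2 A: not better than 3.0
  expect_false("SYN004" %in% cur$entry_id)   # peptide antigen
  expect_false("SYN005" %in% cur$entry_id)   # single-chain antibody
  ## each 96%/90% twin pair collapses to its better-resolution member
  expect_true("SYN001" %in% cur$entry_id)
  expect_false("SYN001T" %in% cur$entry_id)
  expect_true("SYN002" %in% cur$entry_id)
  expect_false("SYN002T" %in% cur$entry_id)
  ## exactly-at-threshold resolution is excluded (strictly better than 3.0)
  at3 <- entries[1, ]
  at3$resolution <- 3.0
  expect_equal(nrow(curate_corpus(at3)), 0L)
  ## empty in, empty out; idempotent; order-independent
  expect_equal(nrow(curate_corpus(entries[0, ])), 0L)
  expect_equal(curate_corpus(cur)$entry_id, cur$entry_id)
  shuffled <- entries[rev(seq_len(nrow(entries))), ]
  expect_equal(curate_corpus(shuffled)$entry_id, cur$entry_id)
})

test_that("pair datasets have the stated positive/negative balance and are seeded", {
  corpus <- make_pair_corpus(n_entries = 4, seed = 3)
  ds1 <- build_pair_dataset(corpus, negative_ratio = 1.0, seed = 2)
  n_pos <- sum(purrr::map_int(corpus$pairs, nrow))
  expect_equal(sum(ds1$label == "contact"), n_pos)
  ## ratio 1 per chain within each entry
  per <- ds1 |>
    dplyr::count(entry_id, chain, label) |>
    tidyr::pivot_wider(names_from = label, values_from = n, values_fill = 0L)
  expect_equal(per$contact, per$non_contact)
  ## ratio 0 keeps positives only
  ds0 <- build_pair_dataset(corpus, negative_ratio = 0, seed = 2)
  expect_true(all(ds0$label == "contact"))
  ## same seed, same negative sample
  ds2 <- build_pair_dataset(corpus, negative_ratio = 1.0, seed = 2)
  expect_equal(ds1, ds2, ignore_attr = TRUE)
  ## an entry with no positives is skipped with a warning
  empty <- corpus
  empty$pairs[[1]] <- empty$pairs[[1]][0, ]
  expect_warning(ds3 <- build_pair_dataset(empty, 1, seed = 2), "skipped")
  expect_false(corpus$entry_id[1] %in% ds3$entry_id)
})

test_that("grouped folds partition entries and too few entries error out", {
  corpus <- make_pair_corpus(n_entries = 4, seed = 3)
  ds <- build_pair_dataset(corpus, 1, seed = 2)
  m <- crossval_pair_classifier(ds, "H", folds = 4, n_trees = 50, seed = 1)
  ## with 4 entries and 4 folds, each fold holds exactly one entry's pairs
  per_entry <- dplyr::count(dplyr::filter(ds, chain == "H"), entry_id)
  expect_setequal(tidy(m)$n, per_entry$n)
  expect_error(crossval_pair_classifier(ds, "H", folds = 8, seed = 1),
               "folds")
})

test_that("the pair forest recovers a planted signal and the null stays flat", {
  corpus <- make_pair_corpus(n_entries = 10, seed = 21)
  ds <- build_pair_dataset(corpus, negative_ratio = 1.5, seed = 2)
  m <- crossval_pair_classifier(ds, "H", folds = 4, n_trees = 200, seed = 3)
  expect_gt(glance(m)$pooled_auc, 0.8)
  ## rank AUC agrees with the independent ROC oracle on held-out-free refit
  d <- dplyr::filter(ds, chain == "H")
  p <- stats::predict(m$forest, as.data.frame(d[, m$feat_cols]),
                      type = "prob")[, "contact"]
  expect_equal(reepitope:::auc_rank(p, d$label == "contact"),
               auc_oracle(p, d$label == "contact"), tolerance = 1e-8)
  ## signal-free corpus (no type enrichment, no exposure preference)
  c0 <- make_pair_corpus(n_entries = 10,
                         signal = list(pairs = list(c("R", "E"), c("W", "G")),
                                       enrichment = 1),
                         exposure_power = 0, seed = 22)
  ds0 <- build_pair_dataset(c0, 1.5, seed = 2)
  m0 <- crossval_pair_classifier(ds0, "H", folds = 4, n_trees = 200, seed = 3)
  expect_gte(glance(m0)$pooled_auc, 0.35)
  expect_lte(glance(m0)$pooled_auc, 0.65)
})

test_that("all-pair scoring covers numbered-position x surface-residue and tie-breaks", {
  corpus <- make_pair_corpus(n_entries = 8, seed = 21)
  ds <- build_pair_dataset(corpus, 1.5, seed = 2)
  models <- list(
    H = crossval_pair_classifier(ds, "H", folds = 4, n_trees = 100, seed = 3),
    L = crossval_pair_classifier(ds, "L", folds = 4, n_trees = 100, seed = 3))
  ann <- toy_query()
  ag <- toy_antigen()
  sm <- score_all_pairs(ann, ag, models, n_points = 60)
  ## shape: every (position, surface residue) pair exactly once
  expect_equal(nrow(sm), 12 * attr(sm, "n_surface"))
  expect_true(all(sm$score >= 0 & sm$score <= 1))
  ## deterministic rescoring
  sm2 <- score_all_pairs(ann, ag, models, n_points = 60)
  expect_equal(sm$score, sm2$score)
  ## argmax tie-break: first row, then column, in stable ordering
  am <- attr(sm, "argmax")
  first_max <- sm[which(sm$score == max(sm$score))[1], ]
  expect_equal(am$position, first_max$position)
  expect_equal(am$ag_resno, first_max$ag_resno)
})

test_that("a charge-driven planted signal puts the argmax on the ARG x GLU pair", {
  ## corpus where contacts are (almost) exclusively arginine-glutamate
  corpus <- make_pair_corpus(
    n_entries = 8, seed = 31,
    signal = list(pairs = list(c("R", "E")), enrichment = 60),
    base_rate = 0.004, composition_bias = 8, exposure_power = 0)
  ds <- build_pair_dataset(corpus, 1.5, seed = 2)
  models <- list(
    H = crossval_pair_classifier(ds, "H", folds = 4, n_trees = 200, seed = 3),
    L = crossval_pair_classifier(ds, "L", folds = 4, n_trees = 200, seed = 3))
  sm <- score_all_pairs(toy_query(), toy_antigen("AAGEAGA"), models,
                        n_points = 60)
  am <- attr(sm, "argmax")
  expect_equal(am$ab_res, "R")
  expect_equal(am$ag_res, "E")
})

test_that("top-1 pair type matches the planted signal in most seeded replicates", {
  ## the planted antigen-side types must carry side chains: glycine has no
  ## side-chain atoms, so it is (correctly) treated as buried and excluded
  ## from the scored surface
  sig <- list(pairs = list(c("R", "E"), c("W", "D")), enrichment = 10)
  hits <- 0L
  for (r in 1:5) {
    corpus <- make_pair_corpus(n_entries = 10, seed = 100 + r, signal = sig)
    ds <- build_pair_dataset(corpus, 1.5, seed = r)
    models <- list(
      H = crossval_pair_classifier(ds, "H", folds = 4, n_trees = 200, seed = r),
      L = crossval_pair_classifier(ds, "L", folds = 4, n_trees = 200, seed = r))
    sm <- score_all_pairs(toy_query(), toy_antigen("ADAEADE"), models,
                          n_points = 60)
    am <- attr(sm, "argmax")
    if (paste0(am$ab_res, am$ag_res) %in% c("RE", "WD")) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("epitope patches seed on top pairs and report contiguity honestly", {
  corpus <- make_pair_corpus(n_entries = 8, seed = 21)
  ds <- build_pair_dataset(corpus, 1.5, seed = 2)
  models <- list(
    H = crossval_pair_classifier(ds, "H", folds = 4, n_trees = 100, seed = 3),
    L = crossval_pair_classifier(ds, "L", folds = 4, n_trees = 100, seed = 3))
  ag <- toy_antigen()
  sm <- score_all_pairs(toy_query(), ag, models, n_points = 60)
  p1 <- predict_epitope_patch(sm, ag, top_k = 1)
  am <- attr(sm, "argmax")
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$resno, am$ag_resno)
  expect_true(attr(p1, "contiguous"))     # singleton is contiguous
  ## toy-complex residues sit 10 A apart: a multi-residue patch on this
  ## antigen cannot be contiguous at an 8 A radius
  pk <- predict_epitope_patch(sm, ag, top_k = 12, neighbor_radius = 8)
  if (nrow(pk) > 1) expect_false(attr(pk, "contiguous"))
  ## clamping warns
  expect_warning(predict_epitope_patch(sm, ag, top_k = nrow(sm) + 10),
                 "clamp")
})

test_that("site overlap is exact set arithmetic", {
  a <- tibble::tibble(chain = "A", resno = 1:10, ins = "")
  b <- tibble::tibble(chain = "A", resno = 6:15, ins = "")
  ov <- site_overlap(a, b)
  expect_equal(ov$intersection, 5L)
  expect_equal(ov$jaccard, 5 / 15)
  expect_equal(site_overlap(a, a)$jaccard, 1.0)
  disjoint <- tibble::tibble(chain = "A", resno = 90:95, ins = "")
  expect_equal(site_overlap(a, disjoint)$intersection, 0L)
  expect_equal(site_overlap(a, disjoint)$jaccard, 0)
})
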