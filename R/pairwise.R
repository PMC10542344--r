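## Antibody-position x antigen-residue pair scoring: corpus curation by the
## published filtering rules, pair featurisation, per-chain random forests
## with grouped fourfold cross-validation, all-pair scoring for a query, and
## epitope-patch derivation.

PAIR_FEATURE_SCHEMA <- "pair-features-1"

#' Curate an antibody-antigen training corpus
#'
#' Keeps entries with resolution strictly below `max_resolution` that are
#' co-crystallised with a protein antigen and are not single-chain
#' antibodies, then removes redundancy: two entries are redundant iff their
#' antigens share more than 95% sequence identity AND their
#' antigen-binding-region (ABR) sequences share more than 85% identity.
#' Within each redundant group the best-resolution entry survives (ties to
#' the lexicographically first id). The survivor set is independent of
#' input order.
#'
#' @param entries Corpus tibble (one row per entry; see
#'   [make_pair_corpus()] for the schema).
#' @param max_resolution Resolution cutoff in Angstrom (strict `<`).
#' @param antigen_id_threshold,abr_id_threshold Redundancy thresholds
#'   (strict `>`), as fractions.
#' @return The filtered corpus tibble.
#' @export
curate_corpus <- function(entries, max_resolution = 3.0,
                          antigen_id_threshold = 0.95,
                          abr_id_threshold = 0.85) {
  if (nrow(entries) == 0) return(entries)
  kept <- dplyr::filter(
    entries,
    .data$resolution < max_resolution,
    .data$antigen_type == "protein",
    !.data$single_chain
  )
  if (nrow(kept) <= 1) return(kept)
  kept <- dplyr::arrange(kept, .data$entry_id)   # order-independence
  n <- nrow(kept)
  abr <- paste0(kept$abr_h, kept$abr_l)
  redundant <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (seq_identity(kept$antigen_seq[i], kept$antigen_seq[j]) >
          antigen_id_threshold &&
          seq_identity(abr[i], abr[j]) > abr_id_threshold) {
        redundant[i, j] <- redundant[j, i] <- TRUE
      }
    }
  }
  ## connected components via label propagation
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) {
      link <- which(redundant[i, ])
      if (length(link) > 0) new[i] <- min(comp[c(i, link)])
    }
    if (identical(new, comp)) break
    comp <- new
  }
  survivors <- tibble::tibble(idx = seq_len(n), comp = comp,
                              res = kept$resolution, id = kept$entry_id) |>
    dplyr::group_by(.data$comp) |>
    dplyr::arrange(.data$res, .data$id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::pull(.data$idx)
  dplyr::arrange(kept[sort(survivors), ], .data$entry_id)
}

## identity of two unaligned sequences: global alignment matches over the
## longer sequence length (equal-length point-mutant pairs reduce to the
## obvious hamming identity)
seq_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  if (nchar(a) == nchar(b)) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    return(sum(va == vb) / length(va))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
}

## featurise (antibody position, antigen residue) pairs of one entry
pair_features <- function(ab_res, ab_region, ab_chain, ag_seq, ag_pos,
                          exposure) {
  ag_vec <- strsplit(ag_seq, "")[[1]]
  ag_res <- ag_vec[ag_pos]
  one_hot <- function(res, prefix) {
    m <- matrix(0, length(res), 20, dimnames = list(NULL, paste0(prefix, AA1)))
    ok <- res %in% AA1
    m[cbind(which(ok), match(res[ok], AA1))] <- 1
    m
  }
  regions <- c("FR", "CDR1", "CDR2", "CDR3")
  reg_base <- ifelse(ab_region %in% regions, ab_region, "FR")
  reg_key <- paste0(ab_chain, "_", reg_base)
  reg_levels <- as.vector(outer(c("H", "L"), regions, paste, sep = "_"))
  reg_m <- matrix(0, length(ab_res), length(reg_levels),
                  dimnames = list(NULL, paste0("region_", reg_levels)))
  reg_m[cbind(seq_along(ab_res), match(reg_key, reg_levels))] <- 1
  ## local sequence context: +-2 antigen residues as physico-chemical terms
  ctx <- do.call(cbind, purrr::map(c(-2, -1, 1, 2), function(off) {
    idx <- ag_pos + off
    inside <- idx >= 1 & idx <= length(ag_vec)
    res <- ifelse(inside, ag_vec[pmin(pmax(idx, 1L), length(ag_vec))], NA)
    m <- cbind(ifelse(is.na(res), 0, KD_HYDROPATHY[res]),
               ifelse(is.na(res), 0, AA_CHARGE[res]),
               ifelse(is.na(res), 0, AA_VOLUME[res]))
    colnames(m) <- paste0("ctx", off, c("_hyd", "_chg", "_vol"))
    m
  }))
  out <- cbind(
    one_hot(ab_res, "ab_"), one_hot(ag_res, "ag_"), reg_m,
    exposure = exposure[ag_pos], ctx,
    charge_prod = AA_CHARGE[ab_res] * AA_CHARGE[ag_res],
    hyd_prod = KD_HYDROPATHY[ab_res] * KD_HYDROPATHY[ag_res],
    vol_sum = AA_VOLUME[ab_res] + AA_VOLUME[ag_res]
  )
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

entry_chain_info <- function(entry, chain) {
  if (chain == "H") {
    list(seq = strsplit(entry$abr_h, "")[[1]], regions = entry$regions_h[[1]])
  } else {
    list(seq = strsplit(entry$abr_l, "")[[1]], regions = entry$regions_l[[1]])
  }
}

#' Build a labelled pair dataset from a curated corpus
#'
#' Positives are the labelled contact pairs of each entry; negatives are a
#' seeded subsample of the entry's non-contact pairs at
#' `negative_ratio` times the positive count. Per-entry provenance is kept
#' for grouped cross-validation folds. Entries with zero positives are
#' skipped with a warning.
#'
#' @param corpus Curated corpus tibble.
#' @param negative_ratio Negatives per positive (0 keeps positives only).
#' @param seed Integer seed for the negative subsample.
#' @return Tibble with `entry_id`, `chain`, `ab_pos`, `ag_pos`, `label`
#'   (factor contact/non_contact) and numeric feature columns; attribute
#'   `schema`.
#' @export
build_pair_dataset <- function(corpus, negative_ratio = 1.0, seed = 1L) {
  stopifnot(nrow(corpus) > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  one_entry <- function(k) {
    entry <- corpus[k, ]
    pairs <- entry$pairs[[1]]
    if (nrow(pairs) == 0) {
      warning("entry ", entry$entry_id, " has no labelled contacts; skipped",
              call. = FALSE)
      return(NULL)
    }
    n_ag <- nchar(entry$antigen_seq)
    per_chain <- purrr::map_dfr(c("H", "L"), function(ch) {
      info <- entry_chain_info(entry, ch)
      grid <- tidyr::expand_grid(ab_pos = seq_along(info$seq),
                                 ag_pos = seq_len(n_ag))
      pos_key <- with(dplyr::filter(pairs, .data$chain == ch),
                      paste(ab_pos, ag_pos))
      grid$label <- ifelse(paste(grid$ab_pos, grid$ag_pos) %in% pos_key,
                           "contact", "non_contact")
      pos <- grid[grid$label == "contact", ]
      neg_pool <- grid[grid$label == "non_contact", ]
      n_neg <- min(nrow(neg_pool), round(negative_ratio * nrow(pos)))
      neg <- neg_pool[sample(nrow(neg_pool), n_neg), ]
      sel <- dplyr::bind_rows(pos, neg)
      if (nrow(sel) == 0) return(NULL)
      feats <- pair_features(info$seq[sel$ab_pos], info$regions[sel$ab_pos],
                             ch, entry$antigen_seq, sel$ag_pos,
                             entry$exposure[[1]])
      dplyr::bind_cols(
        tibble::tibble(entry_id = entry$entry_id, chain = ch,
                       ab_pos = sel$ab_pos, ag_pos = sel$ag_pos,
                       label = factor(sel$label, c("contact", "non_contact"))),
        feats)
    })
    per_chain
  }
  out <- purrr::map_dfr(seq_len(nrow(corpus)), one_entry)
  attr(out, "schema") <- PAIR_FEATURE_SCHEMA
  out
}

#' Cross-validate and fit a per-chain pair classifier
#'
#' Fourfold (by default) cross-validation grouped by source entry: no entry
#' contributes pairs to more than one fold. Heavy and light chains are
#' trained separately. AUC is the rank statistic over held-out pairs; the
#' returned forest is refit on all data of the chain.
#'
#' @param dataset A [build_pair_dataset()] tibble.
#' @param chain `"H"` or `"L"`.
#' @param folds Number of grouped folds (default 4).
#' @param n_trees Forest size.
#' @param seed Integer seed.
#' @return A `pair_rf` object with CV report ([tidy.pair_rf()],
#'   [glance.pair_rf()]).
#' @export
crossval_pair_classifier <- function(dataset, chain = c("H", "L"), folds = 4L,
                                     n_trees = 300, seed = 1L) {
  chain <- match.arg(chain)
  data <- dplyr::filter(dataset, .data$chain == !!chain)
  if (dplyr::n_distinct(data$entry_id) < folds) {
    stop("fewer entries (", dplyr::n_distinct(data$entry_id),
         ") than folds (", folds, ")", call. = FALSE)
  }
  feat_cols <- setdiff(names(data),
                       c("entry_id", "chain", "ab_pos", "ag_pos", "label"))
  cv <- grouped_rf_cv(dplyr::rename(data, complex = "entry_id"),
                      feat_cols, group_col = "complex", label_col = "label",
                      positive = "contact", n_trees = n_trees,
                      max_depth = NULL, seed = seed, folds = folds)
  structure(
    list(forest = cv$final, schema = PAIR_FEATURE_SCHEMA, chain = chain,
         feat_cols = feat_cols, cv = cv$report, pooled = cv$pooled,
         metadata = list(seed = seed, n_trees = n_trees, folds = folds)),
    class = "pair_rf")
}

#' @export
print.pair_rf <- function(x, ...) {
  cat("<pair_rf> chain ", x$chain, ", ", x$metadata$folds,
      "-fold grouped CV pooled AUC = ", round(x$pooled$pooled_auc, 3),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy pair_rf
#' @export
tidy.pair_rf <- function(x, ...) x$cv

#' @method glance pair_rf
#' @export
glance.pair_rf <- function(x, ...) x$pooled

#' Score every antibody-position x antigen-surface-residue pair
#'
#' Buried antigen residues (relative side-chain exposure below
#' `exposure_min`) are excluded from the columns. The argmax pair is
#' reported with a deterministic tie-break (lowest row index, then column).
#'
#' @param annotated A numbered antibody ([number_antibody()]).
#' @param antigen Antigen atom tibble (single chain or several).
#' @param models Named list `list(H = , L = )` of `pair_rf` models.
#' @param exposure_min Surface threshold on relative side-chain exposure.
#' @param n_points SASA sampling points for exposure.
#' @return Long tibble (class `pair_score_tbl`) with `ab_chain`,
#'   `position`, `ins_letter`, `ab_res`, `region`, `ag_chain`, `ag_resno`,
#'   `ag_ins`, `ag_res`, `score`; attributes `argmax` and `n_surface`.
#' @export
score_all_pairs <- function(annotated, antigen, models, exposure_min = 0.05,
                            n_points = 120L) {
  for (ch in c("H", "L")) {
    if (!inherits(models[[ch]], "pair_rf")) {
      stop("models must be a list(H=, L=) of pair_rf objects", call. = FALSE)
    }
    if (!identical(models[[ch]]$schema, PAIR_FEATURE_SCHEMA)) {
      stop("feature schema mismatch", call. = FALSE)
    }
  }
  expo <- residue_exposure(antigen, n_points = n_points)
  res_tab <- residue_table(antigen)
  surface <- dplyr::filter(
    dplyr::left_join(res_tab, expo, by = c("chain", "resno", "ins", "resid")),
    .data$rel_exposure >= exposure_min)
  ag_codes <- unname(AA_3TO1[surface$resid])
  ag_codes[is.na(ag_codes)] <- "X"
  ## antigen residues indexed along their chain sequence for context features
  ag_seq_by_chain <- purrr::map(unique(antigen$chain), function(ch) {
    chain_sequence(antigen, ch)
  })
  names(ag_seq_by_chain) <- unique(antigen$chain)
  chain_index <- res_tab |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(ag_idx = dplyr::row_number()) |>
    dplyr::ungroup()
  surface <- dplyr::left_join(
    surface, chain_index, by = c("chain", "resno", "ins", "resid"))
  rows <- purrr::map_dfr(c("H", "L"), function(ch) {
    ab <- dplyr::filter(tibble::as_tibble(annotated), .data$chain == ch)
    if (nrow(ab) == 0 || nrow(surface) == 0) return(NULL)
    grid <- tidyr::expand_grid(ai = seq_len(nrow(ab)),
                               gi = seq_len(nrow(surface)))
    ## featurise per antigen chain so sequence context is well-defined
    parts <- list()
    for (agc in unique(surface$chain)) {
      sub <- grid[surface$chain[grid$gi] == agc, ]
      if (nrow(sub) == 0) next
      f <- pair_features(
        ab_res = ab$residue[sub$ai],
        ab_region = ab$region[sub$ai],
        ab_chain = ch,
        ag_seq = ag_seq_by_chain[[agc]],
        ag_pos = surface$ag_idx[sub$gi],
        exposure = {
          e <- rep(0, nchar(ag_seq_by_chain[[agc]]))
          ce <- surface[surface$chain == agc, ]
          e[ce$ag_idx] <- ce$rel_exposure
          e
        })
      sc <- stats::predict(models[[ch]]$forest, as.data.frame(f),
                           type = "prob")[, "contact"]
      parts[[agc]] <- tibble::tibble(
        ab_chain = ch, position = ab$position[sub$ai],
        ins_letter = ab$ins_letter[sub$ai], ab_res = ab$residue[sub$ai],
        region = ab$region[sub$ai],
        ag_chain = agc, ag_resno = surface$resno[sub$gi],
        ag_ins = surface$ins[sub$gi], ag_res = ag_codes[sub$gi],
        score = sc)
    }
    dplyr::bind_rows(parts)
  })
  rows <- dplyr::arrange(rows, .data$ab_chain, .data$position,
                         .data$ins_letter, .data$ag_chain, .data$ag_resno,
                         .data$ag_ins)
  best <- which(rows$score == max(rows$score))[1]   # row-major tie-break
  out <- structure(rows, argmax = rows[best, ], n_surface = nrow(surface),
                   class = c("pair_score_tbl", class(rows)))
  out
}

#' Derive an epitope patch from a pair-score table
#'
#' The seed patch is the antigen residues of the `top_k` highest-scoring
#' pairs; it is expanded with spatial neighbours (within
#' `neighbor_radius` of a seed residue) drawn from the next `top_k`
#' top-scoring antigen residues. The patch is reported with its mean
#' supporting score and a surface-contiguity flag (every member within
#' `neighbor_radius` of another member; a singleton is contiguous).
#'
#' @param scores A `pair_score_tbl`.
#' @param antigen The antigen atom tibble the scores refer to.
#' @param top_k Number of top pairs seeding the patch.
#' @param neighbor_radius Expansion / contiguity radius in Angstrom.
#' @return Tibble of patch residues (`chain`, `resno`, `ins`, `ag_res`,
#'   `best_score`, `seed`); attributes `mean_score`, `contiguous`,
#'   `supporting_pairs`.
#' @export
predict_epitope_patch <- function(scores, antigen, top_k = 10,
                                  neighbor_radius = 8.0) {
  if (top_k > nrow(scores)) {
    warning("top_k exceeds the number of scored pairs; clamped",
            call. = FALSE)
    top_k <- nrow(scores)
  }
  ord <- dplyr::arrange(scores, dplyr::desc(.data$score), .data$ab_chain,
                        .data$position, .data$ag_chain, .data$ag_resno)
  top_pairs <- ord[seq_len(top_k), ]
  seed_res <- dplyr::distinct(top_pairs, chain = .data$ag_chain,
                              resno = .data$ag_resno, ins = .data$ag_ins)
  ## candidate expansion set: top-scoring antigen residues (by best pair)
  by_res <- scores |>
    dplyr::group_by(chain = .data$ag_chain, resno = .data$ag_resno,
                    ins = .data$ag_ins, ag_res = .data$ag_res) |>
    dplyr::summarise(best_score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$best_score), .data$chain, .data$resno)
  cand <- by_res[seq_len(min(nrow(by_res), 2 * top_k)), ]
  ## residue centroids for spatial expansion
  centroids <- antigen |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     .groups = "drop")
  ckey <- residue_key(centroids)
  cxyz <- coords(centroids)
  seed_idx <- match(residue_key(seed_res), ckey)
  cand_idx <- match(residue_key(cand), ckey)
  keep <- cand_idx %in% seed_idx
  if (length(seed_idx) > 0) {
    d2 <- outer(rowSums(cxyz[cand_idx, , drop = FALSE]^2),
                rowSums(cxyz[seed_idx, , drop = FALSE]^2), "+") -
      2 * cxyz[cand_idx, , drop = FALSE] %*% t(cxyz[seed_idx, , drop = FALSE])
    keep <- keep | apply(d2 <= neighbor_radius^2, 1, any)
  }
  patch <- cand[keep, ]
  patch$seed <- residue_key(patch) %in% residue_key(seed_res)
  ## contiguity: every member within radius of another member
  pidx <- match(residue_key(patch), ckey)
  contiguous <- if (nrow(patch) <= 1) TRUE else {
    d2 <- as.matrix(stats::dist(cxyz[pidx, , drop = FALSE]))^2
    diag(d2) <- Inf
    all(apply(d2 <= neighbor_radius^2, 1, any))
  }
  structure(patch,
            mean_score = mean(top_pairs$score),
            contiguous = contiguous,
            supporting_pairs = top_pairs)
}

#' Overlap of two residue sets on the same antigen
#'
#' @param patch_a,patch_b Residue tibbles with `chain`, `resno`, `ins`
#'   columns (insertion codes optional).
#' @return One-row tibble `intersection`, `union`, `jaccard`.
#' @export
site_overlap <- function(patch_a, patch_b) {
  key <- function(df) {
    ins <- if ("ins" %in% names(df)) df$ins else ""
    unique(paste(df$chain, df$resno, ins))
  }
  a <- key(patch_a); b <- key(patch_b)
  i <- length(intersect(a, b)); u <- length(union(a, b))
  tibble::tibble(intersection = i, union = u,
                 jaccard = if (u == 0) 0 else i / u)
}
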