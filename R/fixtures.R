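## Deterministic generators for synthetic test inputs: toy complexes with
## planted interfaces, planted-signal pair corpora, and near-germline toy
## antibodies. Fixtures validate code contracts, not biophysics: geometry
## keeps planted contacts at <= 4.5 A and everything else at >= 7 A so the
## contact oracle is robust to floating-point jitter.

#' Specification of a toy complex with a planted interface
#'
#' @param n_residues Integer vector: residues per chain (chains are named
#'   A, B, C, ...). Planted contacts run between chains 1 and 2; any
#'   further chains are placed far from everything.
#' @param pairs Two-column matrix/data frame of planted contact pairs
#'   (residue index in chain 1, residue index in chain 2). A chain-2
#'   residue may appear in at most one pair; a chain-1 residue in at most
#'   three.
#' @param sequences Optional character vector of per-chain sequences
#'   (defaults to poly-alanine).
#' @param seed Integer recorded alongside the geometry (generation is fully
#'   deterministic).
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_residues = c(10, 10), pairs = NULL,
                             sequences = NULL, seed = 1L) {
  pairs <- if (is.null(pairs)) matrix(integer(0), 0, 2) else as.matrix(pairs)
  if (is.null(sequences)) {
    sequences <- purrr::map_chr(n_residues, ~ strrep("A", .x))
  }
  stopifnot(length(sequences) == length(n_residues),
            all(nchar(sequences) == n_residues))
  if (nrow(pairs) > 0) {
    stopifnot(all(pairs[, 1] >= 1), all(pairs[, 1] <= n_residues[1]),
              all(pairs[, 2] >= 1), all(pairs[, 2] <= n_residues[2]))
    if (anyDuplicated(pairs[, 2])) {
      stop("infeasible geometry: a chain-2 residue can partner at most one ",
           "chain-1 residue in this generator", call. = FALSE)
    }
    if (any(table(pairs[, 1]) > 3)) {
      stop("infeasible geometry: at most three partners per chain-1 residue",
           call. = FALSE)
    }
  }
  structure(list(n_residues = n_residues, pairs = pairs,
                 sequences = sequences, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

## fixed compact heavy-atom offsets around the residue centre (<= 0.55 A)
RESIDUE_OFFSETS <- rbind(
  N = c(-0.45, 0.25, 0.00), CA = c(0, 0, 0), C = c(0.45, 0.25, 0.00),
  O = c(0.45, -0.25, 0.30), CB = c(0.00, -0.40, 0.30)
)

#' Build a toy complex with an exactly known contact set
#'
#' Residues are compact 4-5 heavy-atom clusters (N, CA, C, O, and CB for
#' non-glycine) spaced 10 Angstrom apart along each chain. Chain-2 residues
#' that are planted partners sit 3.5 Angstrom (centre-centre) from their
#' chain-1 partner, so every planted residue pair has heavy atoms within
#' 4.6 Angstrom and every non-planted cross-chain pair is beyond 7. The
#' result's 5 Angstrom contact set therefore equals the planted set exactly.
#'
#' @param spec A [toy_complex_spec()].
#' @return List with `atoms` (atom tibble) and `contacts` (ground-truth
#'   tibble `chain_a, resno_a, chain_b, resno_b`).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  chains <- LETTERS[seq_along(spec$n_residues)]
  place_residue <- function(chain, resno, code1, centre) {
    code3 <- AA_1TO3[code1]
    if (is.na(code3)) code3 <- "ALA"
    names_use <- rownames(RESIDUE_OFFSETS)
    if (code1 == "G") names_use <- setdiff(names_use, "CB")
    off <- RESIDUE_OFFSETS[names_use, , drop = FALSE]
    tibble::tibble(
      chain = chain, resno = resno, ins = "", resid = unname(code3),
      elety = names_use,
      element = substr(names_use, 1, 1),
      x = unname(centre[1] + off[, 1]), y = unname(centre[2] + off[, 2]),
      z = unname(centre[3] + off[, 3]), o = 1, altloc = ""
    )
  }
  rows <- list()
  ## chain 1 along x at y = 0
  seq1 <- strsplit(spec$sequences[1], "")[[1]]
  for (i in seq_len(spec$n_residues[1])) {
    rows[[length(rows) + 1]] <- place_residue(chains[1], i, seq1[i],
                                              c(10 * i, 0, 0))
  }
  ## chain 2: partners near their chain-1 residue, the rest far away
  if (length(spec$n_residues) >= 2) {
    seq2 <- strsplit(spec$sequences[2], "")[[1]]
    partner_of <- stats::setNames(spec$pairs[, 1], spec$pairs[, 2])
    slot_z <- c(0, 1.5, -1.5)   # up to three partners around one residue
    used <- integer(0)
    for (j in seq_len(spec$n_residues[2])) {
      if (as.character(j) %in% names(partner_of)) {
        i <- partner_of[[as.character(j)]]
        k <- sum(used == i) + 1
        used <- c(used, i)
        centre <- c(10 * i, 3.5, slot_z[k])
      } else {
        centre <- c(10 * j, 60, 0)
      }
      rows[[length(rows) + 1]] <- place_residue(chains[2], j, seq2[j], centre)
    }
  }
  ## further chains: far from both
  if (length(spec$n_residues) > 2) {
    for (c_idx in 3:length(spec$n_residues)) {
      seqc <- strsplit(spec$sequences[c_idx], "")[[1]]
      for (i in seq_len(spec$n_residues[c_idx])) {
        rows[[length(rows) + 1]] <- place_residue(
          chains[c_idx], i, seqc[i], c(10 * i, -60 - 30 * (c_idx - 3), 0))
      }
    }
  }
  atoms <- dplyr::bind_rows(rows)
  attr(atoms, "title") <- "synthetic toy complex"
  attr(atoms, "source_id") <- paste0("toy-", spec$seed)
  contacts <- tibble::tibble(
    chain_a = chains[1], resno_a = as.integer(spec$pairs[, 1]),
    chain_b = chains[2], resno_b = as.integer(spec$pairs[, 2])
  ) |> dplyr::arrange(.data$resno_a, .data$resno_b)
  list(atoms = atoms, contacts = contacts)
}

#' Toy near-germline antibody with planted mutations
#'
#' Generates a synthetic heavy/light germline V-region pair (with IMGT-style
#' scheme numbers recorded in the reference set), then plants
#' `n_mutations_from_germline` substitutions per chain at seeded positions
#' and appends a fixed CDR3/FR4 tail beyond V-gene coverage. The synthetic
#' germlines stand in for licensed reference databases in tests.
#'
#' @param seed Integer seed.
#' @param n_mutations_from_germline Substitutions planted per chain.
#' @return List with `heavy`, `light` (query sequences), `germline_set`
#'   (tibble as from [read_germline_set()]), and `mutations` (ground truth:
#'   `chain`, `position` scheme number, `germline_res`, `observed_res`).
#' @export
make_toy_antibody <- function(seed = 1L, n_mutations_from_germline = 0L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gaps <- c(10, 73, 81, 82)
  numbers <- setdiff(1:104, gaps)
  gen_chain <- function(gene, chain_type, tail) {
    germ <- paste(sample(AA1, length(numbers), replace = TRUE), collapse = "")
    ## anchor residues so alignment is stable
    substr(germ, 22, 23) <- "CW"
    q <- strsplit(germ, "")[[1]]
    n_mut <- n_mutations_from_germline
    mut_pos <- if (n_mut > 0) sort(sample(seq_along(q), n_mut)) else integer(0)
    muts <- tibble::tibble(chain = character(0), position = integer(0),
                           germline_res = character(0),
                           observed_res = character(0))
    for (p in mut_pos) {
      new <- sample(setdiff(AA1, q[p]), 1)
      muts <- dplyr::add_row(muts, chain = chain_type, position = numbers[p],
                             germline_res = q[p], observed_res = new)
      q[p] <- new
    }
    query <- paste0(paste(q, collapse = ""), tail)
    list(
      germ = tibble::tibble(gene = gene, chain_type = chain_type, seq = germ,
                            numbers = list(numbers)),
      query = query, mutations = muts
    )
  }
  h <- gen_chain("IGHV9-99*01", "H", "AKDFDYWGQGTLVTVSS")
  l <- gen_chain("IGKV9-99*01", "K", "QQYNSFGGGTKVEIK")
  list(
    heavy = h$query, light = l$query,
    germline_set = dplyr::bind_rows(h$germ, l$germ),
    mutations = dplyr::bind_rows(
      h$mutations, dplyr::mutate(l$mutations, chain = "L"))
  )
}

#' Synthetic antibody-antigen pair corpus with a planted signal
#'
#' Generates sequence-level corpus entries (antigen-binding-region sequences
#' per chain, an antigen sequence with per-residue surface exposure, and
#' labelled contact pairs) where contacts are enriched for stated
#' (antibody residue, antigen residue) type pairs by a multiplicative
#' factor. So the planted signal is concentrated rather than diluted over
#' rare residue-type cells, sequences are composition-biased toward the
#' signal residue types, and the per-cell contact probability scales with
#' the cube of the antigen residue's surface exposure (buried residues
#' cannot contact) — both properties the pair features can express.
#' Enrichment 1 gives a signal-free corpus; optional redundancy twins
#' exercise the curation rules.
#'
#' @param n_entries Number of entries.
#' @param signal List with `pairs` (list of c(ab_res, ag_res) type pairs)
#'   and `enrichment` (factor >= 1).
#' @param seed Integer seed.
#' @param n_ab Antibody ABR positions per chain.
#' @param n_ag Antigen residues.
#' @param base_rate Baseline contact probability per (position, residue)
#'   pair at full exposure.
#' @param exposure_power Exponent of the antigen-residue exposure in the
#'   contact probability (0 removes the exposure dependence; together with
#'   enrichment 1 this gives a corpus with no learnable signal at all).
#' @param composition_bias Sampling weight of signal residue types relative
#'   to 1 for all others.
#' @param redundant_twins Number of entries duplicated at 96% antigen / 90%
#'   ABR identity (tests the >95% / >85% redundancy rule from the side that
#'   must be removed).
#' @param resolutions Optional numeric vector recycled over entries
#'   (defaults to draws in 1.8-2.8 Angstrom).
#' @return Tibble of corpus entries (one row each) with list-columns
#'   `regions_h`, `regions_l`, `exposure`, `pairs`.
#' @export
make_pair_corpus <- function(n_entries = 8, signal = list(
                               pairs = list(c("R", "E"), c("W", "G")),
                               enrichment = 10),
                             seed = 1L, n_ab = 16L, n_ag = 40L,
                             base_rate = 0.06, composition_bias = 12,
                             exposure_power = 3, redundant_twins = 0L,
                             resolutions = NULL) {
  stopifnot(signal$enrichment >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sig_key <- purrr::map_chr(signal$pairs, paste, collapse = "")
  ab_w <- ag_w <- stats::setNames(rep(1, 20), AA1)
  for (pr in signal$pairs) {
    ab_w[pr[1]] <- composition_bias
    ag_w[pr[2]] <- composition_bias
  }
  regions <- function(n) rep(c("CDR1", "CDR2", "CDR3"), length.out = n)
  gen_entry <- function(id, resolution) {
    abr_h <- paste(sample(AA1, n_ab, replace = TRUE, prob = ab_w), collapse = "")
    abr_l <- paste(sample(AA1, n_ab, replace = TRUE, prob = ab_w), collapse = "")
    antigen <- paste(sample(AA1, n_ag, replace = TRUE, prob = ag_w), collapse = "")
    exposure <- stats::runif(n_ag, 0.05, 1)
    ab_res <- c(strsplit(abr_h, "")[[1]], strsplit(abr_l, "")[[1]])
    ab_chain <- rep(c("H", "L"), each = n_ab)
    ag_res <- strsplit(antigen, "")[[1]]
    grid <- tidyr::expand_grid(ab_pos = seq_len(2 * n_ab),
                               ag_pos = seq_len(n_ag))
    p <- base_rate * exposure[grid$ag_pos]^exposure_power * ifelse(
      paste0(ab_res[grid$ab_pos], ag_res[grid$ag_pos]) %in% sig_key,
      signal$enrichment, 1)
    hit <- stats::runif(nrow(grid)) < pmin(p, 0.95)
    pairs <- tibble::tibble(
      chain = ab_chain[grid$ab_pos[hit]],
      ab_pos = ifelse(grid$ab_pos[hit] > n_ab, grid$ab_pos[hit] - n_ab,
                      grid$ab_pos[hit]),
      ag_pos = grid$ag_pos[hit]
    )
    tibble::tibble(
      entry_id = id, resolution = resolution, antigen_type = "protein",
      single_chain = FALSE, antigen_seq = antigen,
      abr_h = abr_h, abr_l = abr_l,
      regions_h = list(regions(n_ab)), regions_l = list(regions(n_ab)),
      exposure = list(exposure), pairs = list(pairs)
    )
  }
  res <- if (is.null(resolutions)) round(stats::runif(n_entries, 1.8, 2.8), 2)
         else rep(resolutions, length.out = n_entries)
  ids <- sprintf("SYN%03d", seq_len(n_entries))
  entries <- purrr::map2_dfr(ids, res, gen_entry)
  if (redundant_twins > 0) {
    mutate_seq <- function(s, frac) {
      v <- strsplit(s, "")[[1]]
      k <- max(1L, floor(length(v) * frac))
      at <- sample(seq_along(v), k)
      for (p in at) v[p] <- sample(setdiff(AA1, v[p]), 1)
      paste(v, collapse = "")
    }
    for (t in seq_len(redundant_twins)) {
      src <- entries[t, ]
      twin <- src
      twin$entry_id <- paste0(src$entry_id, "T")
      twin$resolution <- src$resolution + 0.1
      twin$antigen_seq <- mutate_seq(src$antigen_seq, 0.04)  # 96% identity
      twin$abr_h <- mutate_seq(src$abr_h, 0.10)              # 90% identity
      twin$abr_l <- mutate_seq(src$abr_l, 0.10)
      entries <- dplyr::bind_rows(entries, twin)
    }
  }
  entries
}
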