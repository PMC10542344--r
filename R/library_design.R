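#' Define a focused mutation library
#'
#' A focused library varies a small set of chosen positions of a template Fv
#' with restricted residue choices, optionally with single-residue insertion
#' options. Variant counting is at the protein level.
#'
#' @param template Template Fv amino-acid string (heavy + light
#'   concatenated, or any protein sequence).
#' @param positions Tibble (or data frame) with columns `position` (1-based
#'   index into the template) and `allowed` (string of allowed one-letter
#'   codes, e.g. `"WY"`); an optional `codon` column gives a degenerate
#'   codon whose translation must equal the allowed set. The template
#'   residue is typically a member of each allowed set but need not be.
#' @param insertions Optional tibble with columns `after` (template
#'   position), `residues` (string of insertable one-letter codes) and
#'   `optional` (logical; an optional insertion contributes
#'   `nchar(residues) + 1` states, a mandatory one `nchar(residues)`).
#' @param name Library name.
#' @return A `library_spec` object.
#' @export
library_spec <- function(template, positions = NULL, insertions = NULL,
                         name = "library") {
  stopifnot(is.character(template), length(template) == 1, nchar(template) > 0)
  positions <- if (is.null(positions)) {
    tibble::tibble(position = integer(0), allowed = character(0))
  } else tibble::as_tibble(positions)
  insertions <- if (is.null(insertions)) {
    tibble::tibble(after = integer(0), residues = character(0),
                   optional = logical(0))
  } else tibble::as_tibble(insertions)
  if (anyDuplicated(positions$position)) {
    stop("duplicate varied positions", call. = FALSE)
  }
  if (nrow(positions) > 0 &&
      any(positions$position < 1 | positions$position > nchar(template))) {
    stop("varied position outside template", call. = FALSE)
  }
  if (nrow(positions) > 0 && any(nchar(positions$allowed) == 0)) {
    stop("allowed set must be non-empty", call. = FALSE)
  }
  if ("codon" %in% names(positions)) {
    for (i in seq_len(nrow(positions))) {
      cod <- positions$codon[i]
      if (is.na(cod) || cod == "") next
      aa <- expand_degenerate_codon(cod)
      want <- sort(unique(strsplit(positions$allowed[i], "")[[1]]))
      if (!identical(aa$amino_acids, want)) {
        stop("codon ", cod, " encodes {",
             paste(aa$amino_acids, collapse = ""), "} but allowed set is {",
             positions$allowed[i], "} at position ", positions$position[i],
             call. = FALSE)
      }
    }
  }
  structure(list(template = template, positions = positions,
                 insertions = insertions, name = name),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat("<library_spec> ", x$name, ": template of ", nchar(x$template),
      " aa, ", nrow(x$positions), " varied positions, ",
      nrow(x$insertions), " insertion options; size ",
      format(library_size(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

## per-position distinct residue choices (deduplicated)
position_choices <- function(spec) {
  purrr::map(seq_len(nrow(spec$positions)), function(i) {
    sort(unique(strsplit(spec$positions$allowed[i], "")[[1]]))
  })
}

insertion_choices <- function(spec) {
  purrr::map(seq_len(nrow(spec$insertions)), function(i) {
    res <- sort(unique(strsplit(spec$insertions$residues[i], "")[[1]]))
    if (spec$insertions$optional[i]) c("", res) else res
  })
}

#' Exact library size (distinct protein variants)
#'
#' Closed form: the product over varied positions of the number of distinct
#' allowed residues (singleton sets contribute a factor of 1) times, for
#' each insertion option, `k + 1` states if optional and `k` if mandatory.
#' Equals the distinct-sequence count from full enumeration for
#' non-degenerate specs (two insertion slots can in principle collide into
#' one string if the inserted residue duplicates the template; the shipped
#' specs avoid this).
#'
#' @param spec A [library_spec()].
#' @return Integer-valued double (sizes can exceed .Machine$integer.max).
#' @export
library_size <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  f_pos <- purrr::map_int(position_choices(spec), length)
  f_ins <- purrr::map_int(insertion_choices(spec), length)
  prod(c(1, f_pos, f_ins))
}

#' Expand a degenerate codon to its amino-acid set
#'
#' Enumerates every concrete codon in the IUPAC degeneracy and translates it
#' with the standard genetic code.
#'
#' @param codon 3-letter IUPAC nucleotide string (e.g. `"NNS"`).
#' @return List with `amino_acids` (sorted one-letter codes, stops
#'   excluded), `encodes_stop` (logical), and `n_codons`.
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3) stop("codon must have length 3", call. = FALSE)
  letters3 <- strsplit(codon, "")[[1]]
  bad <- setdiff(letters3, names(IUPAC_NT))
  if (length(bad) > 0) {
    stop("invalid IUPAC nucleotide letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  combos <- expand.grid(IUPAC_NT[[letters3[1]]], IUPAC_NT[[letters3[2]]],
                        IUPAC_NT[[letters3[3]]], stringsAsFactors = FALSE)
  concrete <- paste0(combos[, 1], combos[, 2], combos[, 3])
  aa <- unname(Biostrings::GENETIC_CODE[concrete])
  list(
    amino_acids = sort(unique(aa[aa != "*"])),
    encodes_stop = any(aa == "*"),
    n_codons = length(concrete)
  )
}

#' Enumerate or sample library variants
#'
#' Full mode yields every distinct variant exactly once in a deterministic
#' order (positions vary fastest in spec order, then insertion slots);
#' sample mode draws `n` variants uniformly over the combinatorial grid
#' under a seed.
#'
#' @param spec A [library_spec()].
#' @param mode `"full"` or `"sample"`.
#' @param n Number of draws in sample mode.
#' @param seed Integer seed (sample mode).
#' @param ceiling Full mode refuses specs larger than this (default 1e6).
#' @return Tibble with `variant` (sequence string) plus one column per
#'   varied slot recording the chosen state.
#' @export
enumerate_library <- function(spec, mode = c("full", "sample"), n = NULL,
                              seed = NULL, ceiling = 1e6) {
  stopifnot(inherits(spec, "library_spec"))
  mode <- match.arg(mode)
  pos_ch <- position_choices(spec)
  ins_ch <- insertion_choices(spec)
  all_ch <- c(pos_ch, ins_ch)
  size <- library_size(spec)
  if (mode == "full") {
    if (size > ceiling) {
      stop("library size ", format(size, big.mark = ","),
           " exceeds the enumeration ceiling (", format(ceiling, big.mark = ","),
           "); use mode = \"sample\"", call. = FALSE)
    }
    grid <- if (length(all_ch) == 0) {
      tibble::tibble(.rows = 1)
    } else {
      do.call(expand.grid, c(stats::setNames(all_ch, paste0("slot", seq_along(all_ch))),
                             stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
    }
  } else {
    stopifnot(!is.null(n), !is.null(seed))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    grid <- as.data.frame(purrr::map(all_ch, function(ch) {
      sample(ch, n, replace = TRUE)
    }), col.names = paste0("slot", seq_along(all_ch)), stringsAsFactors = FALSE)
    if (length(all_ch) == 0) grid <- data.frame(row.names = seq_len(n))
  }
  seqs <- build_variants(spec, grid, pos_ch)
  out <- tibble::as_tibble(grid)
  out$variant <- seqs
  dplyr::relocate(out, "variant")
}

## vectorised sequence construction: substitutions in place, then insertions
## applied right-to-left so earlier indices stay valid.
build_variants <- function(spec, grid, pos_ch) {
  nvar <- nrow(grid)
  seqs <- rep(spec$template, nvar)
  np <- nrow(spec$positions)
  if (np > 0) {
    for (i in seq_len(np)) {
      p <- spec$positions$position[i]
      substr(seqs, p, p) <- grid[[i]]
    }
  }
  ni <- nrow(spec$insertions)
  if (ni > 0) {
    ord <- order(spec$insertions$after, decreasing = TRUE)
    for (i in ord) {
      after <- spec$insertions$after[i]
      ins <- grid[[np + i]]
      seqs <- paste0(substr(seqs, 1, after), ins,
                     substr(seqs, after + 1, nchar(seqs)))
    }
  }
  seqs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Identity of library variants to the template
#'
#' Percent identity is `100 * matches / aligned length`, where insertions
#' count as non-matches and extend the aligned length. The minimum is
#' computed in closed form (every varied position that can change does, and
#' every insertion state that lengthens the variant is taken); the mean
#' averages the exact per-stratum identity over the uniform grid; both are
#' verified against enumeration on desk-scale specs in the test suite.
#'
#' @param spec A [library_spec()].
#' @return One-row tibble: `min_identity`, `max_identity`, `mean_identity`
#'   (percent).
#' @export
identity_stats <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  L <- nchar(spec$template)
  pos_ch <- position_choices(spec)
  tmpl_res <- purrr::map_chr(spec$positions$position %||% integer(0),
                             function(p) substr(spec$template, p, p))
  can_change <- purrr::map2_lgl(pos_ch, tmpl_res,
                                function(ch, t) any(ch != t))
  must_change <- purrr::map2_lgl(pos_ch, tmpl_res,
                                 function(ch, t) !(t %in% ch))
  p_change <- purrr::map2_dbl(pos_ch, tmpl_res,
                              function(ch, t) sum(ch != t) / length(ch))
  ins_opt <- spec$insertions$optional %||% logical(0)
  n_ins_max <- nrow(spec$insertions)
  n_ins_min <- sum(!ins_opt)
  min_identity <- 100 * (L - sum(can_change)) / (L + n_ins_max)
  max_identity <- 100 * (L - sum(must_change)) / (L + n_ins_min)
  ## mean: numerator linear in per-position change indicators; average the
  ## ratio over insertion-count strata of the uniform grid
  ins_states <- insertion_choices(spec)
  ins_counts <- if (length(ins_states) == 0) {
    tibble::tibble(k = 0L, wt = 1)
  } else {
    combos <- do.call(expand.grid, c(ins_states, stringsAsFactors = FALSE))
    tibble::tibble(k = rowSums(combos != ""), wt = 1 / nrow(combos)) |>
      dplyr::count(.data$k, wt = .data$wt, name = "wt")
  }
  e_matches <- L - sum(p_change)
  mean_identity <- 100 * sum(ins_counts$wt * e_matches / (L + ins_counts$k))
  tibble::tibble(min_identity = min_identity, max_identity = max_identity,
                 mean_identity = mean_identity)
}

#' Read or write a library specification as JSON
#'
#' The JSON document has fields `name`, `template` (string), `positions`
#' (array of `{position, allowed, codon?}`) and `insertions` (array of
#' `{after, residues, optional}`).
#'
#' @param path JSON file path.
#' @return [read_library_spec()]: a `library_spec`;
#'   [write_library_spec()]: `path`, invisibly.
#' @export
read_library_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  library_spec(
    template = doc$template,
    positions = if (!is.null(doc$positions) && length(doc$positions) > 0)
      tibble::as_tibble(doc$positions) else NULL,
    insertions = if (!is.null(doc$insertions) && length(doc$insertions) > 0)
      tibble::as_tibble(doc$insertions) else NULL,
    name = doc$name %||% tools::file_path_sans_ext(basename(path))
  )
}

#' @rdname read_library_spec
#' @param spec A `library_spec`.
#' @export
write_library_spec <- function(spec, path) {
  jsonlite::write_json(
    list(name = spec$name, template = spec$template,
         positions = spec$positions, insertions = spec$insertions),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
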