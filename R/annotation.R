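## Antibody V-region numbering, CDR membership and germline comparison.
##
## Numbering is by alignment transfer: the germline reference FASTA carries
## IMGT scheme numbers in its headers, the query is aligned to the
## best-matching reference, and numbers are transferred across the
## alignment. Desk-scale and dependency-free; appropriate for V regions at
## or near germline identity.

IMGT_REGIONS <- tibble::tibble(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
  from = c(1, 27, 39, 56, 66, 105, 118),
  to = c(26, 38, 55, 65, 104, 117, 128)
)

#' Region label of an IMGT position
#'
#' IMGT boundaries: CDR1 27-38, CDR2 56-65, CDR3 105-117; framework
#' otherwise (FR4 from 118).
#' @param position Integer vector of IMGT positions.
#' @return Character vector of region labels.
#' @export
imgt_region <- function(position) {
  idx <- findInterval(position, IMGT_REGIONS$from)
  idx[position < 1] <- NA_integer_
  out <- IMGT_REGIONS$region[pmax(idx, 1)]
  out[position > 128] <- "FR4"   # sequential tail beyond scheme range
  out
}

#' Read a germline V-gene reference set
#'
#' FASTA headers must carry the gene name first, then optional
#' whitespace-separated `chain=H|K|L` and `numbers=1,2,3,...` tokens (one
#' scheme number per residue, allowing IMGT gaps to be skipped). Without
#' `numbers=`, residues are numbered 1..n.
#'
#' @param path FASTA file of germline V-gene amino-acid sequences.
#' @return Tibble with `gene`, `chain_type`, `seq`, and list-column
#'   `numbers`.
#' @export
read_germline_set <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("empty germline set: ", path, call. = FALSE)
  parse_one <- function(header, seq) {
    toks <- strsplit(header, "\\s+")[[1]]
    gene <- toks[1]
    kv <- grep("=", toks, value = TRUE)
    get <- function(key, default) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit) == 0) default else sub(paste0("^", key, "="), "", hit[1])
    }
    chain_type <- get("chain", guess_chain_type(gene))
    numbers <- get("numbers", "")
    numbers <- if (numbers == "") seq_len(nchar(seq)) else
      as.integer(strsplit(numbers, ",")[[1]])
    if (length(numbers) != nchar(seq)) {
      stop("numbers= token length does not match sequence length for ",
           gene, call. = FALSE)
    }
    tibble::tibble(gene = gene, chain_type = chain_type,
                   seq = seq, numbers = list(numbers))
  }
  purrr::map2_dfr(names(set), as.character(set), parse_one)
}

guess_chain_type <- function(gene) {
  if (grepl("^IGH", gene)) "H" else if (grepl("^IGK", gene)) "K"
  else if (grepl("^IGL", gene)) "L" else "H"
}

align_global_ref <- function(ref_seq, query_seq) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref_seq),
    subject = Biostrings::AAString(query_seq),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
}

#' Assign the closest germline V gene
#'
#' Aligns the query V region against every gene in the set (the full
#' germline span aligned, the query allowed to extend past it, so CDR3/J
#' tail is excluded from the comparison) and returns the highest-identity
#' gene; ties go to the alphabetically first gene name. Gaps count as
#' mismatches.
#'
#' @param v_seq Query V-region amino-acid string.
#' @param germline_set A [read_germline_set()] tibble (or FASTA path).
#' @param chain_type Optional filter (`"H"`, `"K"`, `"L"`) applied to the
#'   set before matching.
#' @return One-row tibble `gene`, `percent_identity`, `n_mutations`,
#'   `compared_positions`; attribute `mutations` holds a tibble
#'   (`position` scheme number, `germline_res`, `observed_res`) and
#'   attribute `covered` a tibble of all compared scheme positions with
#'   their germline residues.
#' @export
assign_germline <- function(v_seq, germline_set, chain_type = NULL) {
  if (is.character(germline_set) && length(germline_set) == 1) {
    germline_set <- read_germline_set(germline_set)
  }
  if (!is.null(chain_type)) {
    keep <- if (chain_type == "L") c("K", "L") else chain_type
    germline_set <- dplyr::filter(germline_set, .data$chain_type %in% keep)
  }
  if (nrow(germline_set) == 0) stop("empty germline set", call. = FALSE)
  score_one <- function(i) {
    ref <- germline_set$seq[i]
    aln <- align_global_ref(ref, v_seq)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    numbers <- germline_set$numbers[[i]]
    ri <- 0L
    rows <- vector("list", length(pat))
    for (k in seq_along(pat)) {
      if (pat[k] != "-") {
        ri <- ri + 1L
        rows[[k]] <- c(numbers[ri], pat[k], sub[k])
      } else {
        rows[[k]] <- c(NA, "-", sub[k])   # insertion in query: mismatch
      }
    }
    cols <- do.call(rbind, rows)
    matches <- sum(cols[, 2] == cols[, 3])
    compared <- nrow(cols)
    covered <- tibble::tibble(
      position = as.integer(cols[cols[, 2] != "-", 1]),
      germline_res = cols[cols[, 2] != "-", 2]
    )
    mut <- cols[cols[, 2] != cols[, 3] & cols[, 2] != "-", , drop = FALSE]
    list(
      identity = 100 * matches / compared,
      compared = compared,
      mutations = tibble::tibble(
        position = as.integer(mut[, 1]),
        germline_res = mut[, 2], observed_res = mut[, 3]
      ),
      covered = covered
    )
  }
  results <- purrr::map(seq_len(nrow(germline_set)), score_one)
  ids <- purrr::map_dbl(results, "identity")
  ord <- order(-ids, germline_set$gene)
  best <- results[[ord[1]]]
  out <- tibble::tibble(
    gene = germline_set$gene[ord[1]],
    chain_type = germline_set$chain_type[ord[1]],
    percent_identity = best$identity,
    n_mutations = nrow(best$mutations),
    compared_positions = best$compared
  )
  attr(out, "mutations") <- best$mutations
  attr(out, "covered") <- best$covered
  out
}

#' Number an antibody Fv under the IMGT scheme
#'
#' Each chain is globally aligned to its best-matching numbered reference
#' germline and scheme numbers are transferred: matched residues inherit the
#' reference number, query insertions get insertion letters (A, B, ...) on
#' the preceding number, and residues past the reference (CDR3 tail / FR4)
#' are numbered sequentially from the last transferred number. Region labels
#' are a pure function of the scheme number.
#'
#' @param heavy_seq,light_seq Amino-acid strings covering full V regions.
#' @param scheme Numbering scheme; only `"imgt"` is implemented.
#' @param reference_set Germline reference set ([read_germline_set()] tibble
#'   or FASTA path) with scheme numbers in headers.
#' @return Tibble (class `annotated_ab`) with one row per residue: `chain`
#'   (`"H"`/`"L"`), `seq_index`, `residue`, `position`, `ins_letter`,
#'   `region`, `germline_flag` (all `NA` until
#'   [germline_flag_positions()]). Attributes: `scheme`, `assignments`.
#' @export
number_antibody <- function(heavy_seq, light_seq, scheme = "imgt",
                            reference_set) {
  scheme <- match.arg(scheme, "imgt")
  if (is.character(reference_set) && length(reference_set) == 1) {
    reference_set <- read_germline_set(reference_set)
  }
  number_chain <- function(seq, want_type, label) {
    if (nchar(seq) < 70) {
      stop(label, " chain sequence too short to cover FR1-FR3", call. = FALSE)
    }
    keep <- if (want_type == "L") c("K", "L") else "H"
    refs <- dplyr::filter(reference_set, .data$chain_type %in% keep)
    if (nrow(refs) == 0) refs <- reference_set
    asg <- assign_germline(seq, refs)
    if (asg$percent_identity < 50) {
      stop("no ", label, "-chain reference above 50% identity (best: ",
           asg$gene, " at ", round(asg$percent_identity, 1),
           "%); is the chain type right?", call. = FALSE)
    }
    ref <- dplyr::filter(refs, .data$gene == asg$gene)
    aln <- align_global_ref(ref$seq[1], seq)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    numbers <- ref$numbers[[1]]
    qstart <- aln@subject@range@start
    if (qstart > 1) {
      stop(label, " chain has ", qstart - 1,
           " unaligned N-terminal residues; trim to the V region",
           call. = FALSE)
    }
    ri <- 0L; last_num <- 0L; ins_i <- 0L
    pos <- integer(0); ins <- character(0); res <- character(0)
    for (k in seq_along(pat)) {
      if (sub[k] == "-") { ri <- ri + 1L; last_num <- numbers[ri]; next }
      if (pat[k] != "-") {
        ri <- ri + 1L; last_num <- numbers[ri]; ins_i <- 0L
        pos <- c(pos, last_num); ins <- c(ins, "")
      } else {
        ins_i <- ins_i + 1L
        pos <- c(pos, last_num); ins <- c(ins, LETTERS[ins_i])
      }
      res <- c(res, sub[k])
    }
    ## sequential tail beyond reference coverage (CDR3 tail, FR4)
    qend <- length(res)
    tail_res <- strsplit(substr(seq, qend + 1, nchar(seq)), "")[[1]]
    if (length(tail_res) > 0) {
      pos <- c(pos, last_num + seq_along(tail_res))
      ins <- c(ins, rep("", length(tail_res)))
      res <- c(res, tail_res)
    }
    tibble::tibble(
      chain = label, seq_index = seq_along(res), residue = res,
      position = as.integer(pos), ins_letter = ins,
      region = imgt_region(pos), germline_flag = NA
    ) -> tb
    list(tb = tb, assignment = asg)
  }
  h <- number_chain(heavy_seq, "H", "H")
  l <- number_chain(light_seq, "L", "L")
  out <- dplyr::bind_rows(h$tb, l$tb)
  stopifnot(nrow(out) == nchar(heavy_seq) + nchar(light_seq))
  attr(out, "scheme") <- scheme
  attr(out, "assignments") <- list(H = h$assignment, L = l$assignment)
  class(out) <- c("annotated_ab", class(out))
  out
}

#' Flag germline vs somatically mutated positions
#'
#' Sets the per-position `germline_flag`: `TRUE` where the residue equals
#' the assigned germline residue at that scheme position, `FALSE` where it
#' differs (or is an insertion inside the covered span), and `NA` beyond
#' V-gene coverage (CDR3 tail, FR4) — uncovered positions are never called
#' germline.
#'
#' @param annotated A [number_antibody()] result.
#' @param assignments Named list `list(H = , L = )` of [assign_germline()]
#'   results; defaults to the assignments recorded during numbering.
#' @return The annotated tibble with `germline_flag` filled in; summary
#'   counts via [glance.annotated_ab()].
#' @export
germline_flag_positions <- function(annotated,
                                    assignments = attr(annotated, "assignments")) {
  if (is.null(assignments)) {
    stop("no germline assignments available", call. = FALSE)
  }
  flag_chain <- function(tb, asg) {
    covered <- attr(asg, "covered")
    if (is.null(covered)) stop("assignment lacks covered-span information",
                               call. = FALSE)
    gl <- stats::setNames(covered$germline_res, covered$position)
    in_span <- tb$position %in% covered$position
    flag <- rep(NA, nrow(tb))
    flag[in_span] <- tb$ins_letter[in_span] == "" &
      tb$residue[in_span] == gl[as.character(tb$position[in_span])]
    tb$germline_flag <- flag
    tb
  }
  hs <- flag_chain(dplyr::filter(annotated, .data$chain == "H"), assignments$H)
  ls <- flag_chain(dplyr::filter(annotated, .data$chain == "L"), assignments$L)
  out <- dplyr::bind_rows(hs, ls)
  for (a in c("scheme", "assignments")) attr(out, a) <- attr(annotated, a)
  class(out) <- c("annotated_ab", class(out))
  out
}

#' Per-chain germline/mutated/uncovered counts
#' @param x An `annotated_ab` tibble with flags set.
#' @param ... Unused.
#' @return Tibble with one row per chain: `n_positions`, `n_germline`,
#'   `n_mutated`, `n_uncovered`.
#' @method glance annotated_ab
#' @export
glance.annotated_ab <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$chain),
    n_positions = dplyr::n(),
    n_germline = sum(.data$germline_flag %in% TRUE),
    n_mutated = sum(.data$germline_flag %in% FALSE),
    n_uncovered = sum(is.na(.data$germline_flag)),
    .groups = "drop"
  )
}
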