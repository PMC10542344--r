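#' Residue-residue contacts across an interface
#'
#' A residue pair (one residue per side) is in contact iff any heavy-atom
#' pair across the two sides is at distance `<= cutoff` (inclusive). The
#' default implementation bins atoms into a spatial grid of cell size
#' `cutoff`; `method = "brute"` runs the defining O(n^2) double loop and is
#' kept as the oracle the grid must reproduce exactly.
#'
#' @param atoms Atom tibble of the complex.
#' @param side_a,side_b Disjoint character vectors of chain ids.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.0, the
#'   conventional antibody-antigen interface criterion).
#' @param method `"grid"` (default) or `"brute"`.
#' @return A tibble of contacting residue pairs with columns
#'   `chain_a, resno_a, ins_a, resid_a, chain_b, resno_b, ins_b, resid_b,
#'   min_dist`, carrying attributes `cutoff`, `side_a`, `side_b`.
#' @seealso [contact_side()] for the projected per-side residue sets.
#' @export
contact_residues <- function(atoms, side_a, side_b, cutoff = 5.0,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  if (length(intersect(side_a, side_b)) > 0) {
    stop("side_a and side_b overlap: ",
         paste(intersect(side_a, side_b), collapse = ", "), call. = FALSE)
  }
  a <- select_chains(atoms, side_a)
  b <- select_chains(atoms, side_b)
  hits <- if (method == "brute") {
    atom_pairs_within_brute(coords(a), coords(b), cutoff)
  } else {
    atom_pairs_within_grid(coords(a), coords(b), cutoff)
  }
  pairs <- tibble::tibble(
    chain_a = a$chain[hits$i], resno_a = a$resno[hits$i],
    ins_a = a$ins[hits$i], resid_a = a$resid[hits$i],
    chain_b = b$chain[hits$j], resno_b = b$resno[hits$j],
    ins_b = b$ins[hits$j], resid_b = b$resid[hits$j],
    dist = hits$d
  )
  if (nrow(pairs) == 0) {
    pairs <- dplyr::rename(pairs, min_dist = "dist")
    return(structure(pairs, cutoff = cutoff, side_a = side_a, side_b = side_b,
                     class = c("contact_tbl", class(pairs))))
  }
  pairs <- pairs |>
    dplyr::group_by(.data$chain_a, .data$resno_a, .data$ins_a, .data$resid_a,
                    .data$chain_b, .data$resno_b, .data$ins_b, .data$resid_b) |>
    dplyr::summarise(min_dist = min(.data$dist), .groups = "drop") |>
    dplyr::arrange(.data$chain_a, .data$resno_a, .data$ins_a,
                   .data$chain_b, .data$resno_b, .data$ins_b)
  structure(pairs, cutoff = cutoff, side_a = side_a, side_b = side_b,
            class = c("contact_tbl", class(pairs)))
}

#' Project a contact table onto one side's residue set
#'
#' @param contacts A tibble from [contact_residues()].
#' @param side `"a"` or `"b"`.
#' @return Tibble of distinct residues (`chain`, `resno`, `ins`, `resid`).
#' @export
contact_side <- function(contacts, side = c("a", "b")) {
  side <- match.arg(side)
  cols <- paste0(c("chain_", "resno_", "ins_", "resid_"), side)
  out <- dplyr::distinct(contacts[, cols])
  names(out) <- c("chain", "resno", "ins", "resid")
  dplyr::arrange(out, .data$chain, .data$resno, .data$ins)
}

## All cross-set atom pairs within cutoff, by exhaustive chunked distance
## computation. Returns list(i, j, d).
atom_pairs_within_brute <- function(xa, xb, cutoff) {
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0 || nb == 0) return(list(i = integer(0), j = integer(0), d = numeric(0)))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0
  chunk <- max(1L, floor(2e6 / nb))
  for (start in seq(1L, na, by = chunk)) {
    idx <- start:min(na, start + chunk - 1L)
    d2 <- outer(rowSums(xa[idx, , drop = FALSE]^2), rowSums(xb^2), "+") -
      2 * (xa[idx, , drop = FALSE] %*% t(xb))
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      k <- k + 1
      out_i[[k]] <- idx[hit[, 1]]
      out_j[[k]] <- hit[, 2]
      out_d[[k]] <- sqrt(pmax(d2[hit], 0))
    }
  }
  list(i = unlist(out_i) %||% integer(0), j = unlist(out_j) %||% integer(0),
       d = unlist(out_d) %||% numeric(0))
}

## Grid-accelerated version: bin B atoms into cells of size cutoff, compare
## each occupied A cell against its 27-neighbourhood.
atom_pairs_within_grid <- function(xa, xb, cutoff) {
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0 || nb == 0) return(list(i = integer(0), j = integer(0), d = numeric(0)))
  origin <- pmin(apply(xa, 2, min), apply(xb, 2, min))
  cell_of <- function(x) {
    ix <- floor(sweep(x, 2, origin) / cutoff)
    ix[, 1] * 73856093 + ix[, 2] * 19349663 + ix[, 3] * 83492791  # hash
  }
  ixa <- floor(sweep(xa, 2, origin) / cutoff)
  ixb <- floor(sweep(xb, 2, origin) / cutoff)
  keyb <- paste(ixb[, 1], ixb[, 2], ixb[, 3])
  b_by_cell <- split(seq_len(nb), keyb)
  keya <- paste(ixa[, 1], ixa[, 2], ixa[, 3])
  a_by_cell <- split(seq_len(na), keya)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0
  for (cell in names(a_by_cell)) {
    ia <- a_by_cell[[cell]]
    cc <- as.integer(strsplit(cell, " ", fixed = TRUE)[[1]])
    neigh_keys <- paste(cc[1] + offsets[, 1], cc[2] + offsets[, 2],
                        cc[3] + offsets[, 3])
    jb <- unlist(b_by_cell[neigh_keys], use.names = FALSE)
    if (is.null(jb) || length(jb) == 0) next
    d2 <- outer(rowSums(xa[ia, , drop = FALSE]^2), rowSums(xb[jb, , drop = FALSE]^2), "+") -
      2 * (xa[ia, , drop = FALSE] %*% t(xb[jb, , drop = FALSE]))
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      k <- k + 1
      out_i[[k]] <- ia[hit[, 1]]
      out_j[[k]] <- jb[hit[, 2]]
      out_d[[k]] <- sqrt(pmax(d2[hit], 0))
    }
  }
  list(i = unlist(out_i) %||% integer(0), j = unlist(out_j) %||% integer(0),
       d = unlist(out_d) %||% numeric(0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
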