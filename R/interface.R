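#' Paratope and epitope residue sets
#'
#' The paratope is the antibody side of the 5 Angstrom heavy-atom contact
#' set, optionally intersected with CDR positions (IMGT definition, which
#' requires a numbered antibody); the epitope is the antigen side, optionally
#' excluding stated author-numbered residue ranges (e.g. flexible segments
#' ordered only by crystal packing).
#'
#' @inheritParams contact_residues
#' @param antibody_chains,antigen_chains Chain-id vectors for the two sides.
#' @param restrict_to_cdr If `TRUE`, keep only antibody residues whose IMGT
#'   region is CDR1/2/3 (requires `annotated`).
#' @param annotated An [number_antibody()] result built from the *same*
#'   structure chains (heavy first); positions map to structure residues by
#'   order within each chain.
#' @param exclude_antigen_ranges Optional list of `list(chain=, from=, to=)`
#'   author-numbered ranges removed from the epitope (and from the contacts
#'   feeding the paratope).
#' @return List with elements `paratope` and `epitope` (residue tibbles; the
#'   paratope gains `chain_type`, `position`, `ins_letter`, `region`,
#'   `residue` columns when `annotated` is given) and `contacts` (the
#'   underlying pair table).
#' @export
paratope_epitope <- function(atoms, antibody_chains, antigen_chains,
                             cutoff = 5.0, restrict_to_cdr = FALSE,
                             annotated = NULL,
                             exclude_antigen_ranges = NULL) {
  if (restrict_to_cdr && is.null(annotated)) {
    stop("restrict_to_cdr = TRUE requires a numbered antibody (annotated)",
         call. = FALSE)
  }
  contacts <- contact_residues(atoms, antibody_chains, antigen_chains, cutoff)
  if (!is.null(exclude_antigen_ranges)) {
    for (rng in exclude_antigen_ranges) {
      contacts <- dplyr::filter(
        contacts,
        !(.data$chain_b == rng$chain &
            .data$resno_b >= rng$from & .data$resno_b <= rng$to))
    }
  }
  paratope <- contact_side(contacts, "a")
  epitope <- contact_side(contacts, "b")
  if (!is.null(annotated)) {
    paratope <- annotate_structure_residues(paratope, atoms, antibody_chains,
                                            annotated)
    if (restrict_to_cdr) {
      paratope <- dplyr::filter(paratope,
                                .data$region %in% c("CDR1", "CDR2", "CDR3"))
    }
  }
  list(paratope = paratope, epitope = epitope, contacts = contacts)
}

## Join scheme numbering onto structure residues by order-within-chain.
## antibody_chains must be c(heavy, light) matching the annotation's H/L.
annotate_structure_residues <- function(residues, atoms, antibody_chains,
                                        annotated) {
  stopifnot(length(antibody_chains) %in% c(1L, 2L))
  maps <- list()
  for (k in seq_along(antibody_chains)) {
    ch <- antibody_chains[k]
    chain_type <- c("H", "L")[k]
    res <- residue_table(select_chains(atoms, ch))
    ann <- dplyr::filter(annotated, .data$chain == chain_type)
    n <- min(nrow(res), nrow(ann))
    maps[[k]] <- tibble::tibble(
      chain = res$chain[seq_len(n)], resno = res$resno[seq_len(n)],
      ins = res$ins[seq_len(n)],
      chain_type = chain_type,
      position = ann$position[seq_len(n)],
      ins_letter = ann$ins_letter[seq_len(n)],
      region = ann$region[seq_len(n)],
      residue = ann$residue[seq_len(n)]
    )
  }
  dplyr::inner_join(residues, dplyr::bind_rows(maps),
                    by = c("chain", "resno", "ins"))
}

#' Shape complementarity of an interface
#'
#' A Lawrence-Colman-style statistic: dot molecular surfaces are built for
#' each side in isolation (points on van der Waals spheres not occluded by
#' the same side), restricted to the interface band, and each point is scored
#' against its nearest point on the facing surface as
#' `(n_a . -n_b) * exp(-w * d^2)`. The reported Sc is the median over both
#' directions. Perfectly nested complementary surfaces approach 1; separated
#' or mismatched surfaces fall toward 0.
#'
#' @inheritParams contact_residues
#' @param w Distance-weight parameter in 1/Angstrom^2 (default 0.5).
#' @param band Interface band: only surface points within this distance of
#'   any atom of the facing side are scored (default 6.0 Angstrom).
#' @param n_points Surface sampling points per atom.
#' @return A single Sc value in [-1, 1].
#' @export
shape_complementarity <- function(atoms, side_a, side_b, w = 0.5,
                                  band = 6.0, n_points = 120L) {
  a <- select_chains(atoms, side_a)
  b <- select_chains(atoms, side_b)
  probe_contacts <- contact_residues(atoms, side_a, side_b, 5.0)
  if (nrow(probe_contacts) == 0) {
    stop("no interface at 5 Angstrom between the given sides", call. = FALSE)
  }
  sa <- dot_surface(a, n_points)
  sb <- dot_surface(b, n_points)
  sa <- restrict_to_band(sa, coords(b), vdw_radius(b$element), band)
  sb <- restrict_to_band(sb, coords(a), vdw_radius(a$element), band)
  if (nrow(sa$p) == 0 || nrow(sb$p) == 0) {
    stop("interface band contains no surface points", call. = FALSE)
  }
  s_ab <- face_scores(sa, sb, w)
  s_ba <- face_scores(sb, sa, w)
  stats::median(c(s_ab, s_ba))
}

## Exposed vdW-surface points of a structure with outward normals.
dot_surface <- function(atoms, n_points) {
  r <- vdw_radius(atoms$element)
  xyz <- coords(atoms)
  pts <- sphere_points(n_points)
  keep_p <- list(); keep_n <- list()
  for (i in seq_len(nrow(atoms))) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    dv <- sweep(xyz, 2, xyz[i, ])
    near <- which(rowSums(dv^2) < (r[i] + max(r))^2)
    near <- near[near != i]
    exposed <- rep(TRUE, n_points)
    for (j in near) {
      if (!any(exposed)) break
      dp <- sweep(p[exposed, , drop = FALSE], 2, xyz[j, ])
      exposed[exposed] <- rowSums(dp^2) >= (0.99 * r[j])^2
    }
    if (any(exposed)) {
      keep_p[[length(keep_p) + 1]] <- p[exposed, , drop = FALSE]
      keep_n[[length(keep_n) + 1]] <- pts[exposed, , drop = FALSE]
    }
  }
  list(p = do.call(rbind, keep_p) %||% matrix(0, 0, 3),
       n = do.call(rbind, keep_n) %||% matrix(0, 0, 3))
}

restrict_to_band <- function(surf, other_xyz, other_r, band) {
  if (nrow(surf$p) == 0) return(surf)
  hits <- atom_pairs_within_grid(surf$p, other_xyz, band + max(other_r))
  keep <- sort(unique(hits$i[hits$d <= band + other_r[hits$j]]))
  list(p = surf$p[keep, , drop = FALSE], n = surf$n[keep, , drop = FALSE])
}

face_scores <- function(sx, sy, w) {
  ## nearest facing point by grid search widening until found
  nx <- nrow(sx$p)
  nn_j <- integer(nx); nn_d <- numeric(nx)
  cutoff <- 3
  remaining <- seq_len(nx)
  while (length(remaining) > 0 && cutoff < 1e3) {
    hits <- atom_pairs_within_grid(sx$p[remaining, , drop = FALSE], sy$p, cutoff)
    if (length(hits$i) > 0) {
      best <- tapply(seq_along(hits$i), hits$i, function(k) k[which.min(hits$d[k])])
      rows <- as.integer(names(best))
      nn_j[remaining[rows]] <- hits$j[unlist(best)]
      nn_d[remaining[rows]] <- hits$d[unlist(best)]
      remaining <- remaining[-rows]
    }
    cutoff <- cutoff * 2
  }
  found <- nn_j > 0
  dots <- rowSums(sx$n[found, , drop = FALSE] * (-sy$n[nn_j[found], , drop = FALSE]))
  dots * exp(-w * nn_d[found]^2)
}

#' Cross-complex paratope conservation
#'
#' Matches paratope positions of antibody A against antibody B by
#' `(chain_type, scheme number, insertion letter)` and reports the nested
#' conservation chain: positions of A, those shared with B's paratope, those
#' with identical residue type among shared, and those germline-identical
#' among identical (germline flags taken from antibody A's annotation).
#'
#' @param annot_a,annot_b Numbered antibodies (same scheme).
#' @param paratope_a,paratope_b Paratope tibbles from [paratope_epitope()]
#'   with annotation columns (`chain_type`, `position`, `ins_letter`,
#'   `region`, `residue`).
#' @return Tibble of A's paratope positions with logical columns `shared`,
#'   `identical_sidechain`, `germline_identical`; summary counts via
#'   [glance.conservation_tbl()].
#' @export
compare_paratopes <- function(annot_a, paratope_a, annot_b, paratope_b) {
  sch_a <- attr(annot_a, "scheme") %||% "imgt"
  sch_b <- attr(annot_b, "scheme") %||% "imgt"
  if (!identical(sch_a, sch_b)) {
    stop("antibodies are numbered under different schemes (", sch_a, " vs ",
         sch_b, ")", call. = FALSE)
  }
  key <- function(df) paste(df$chain_type, df$position, df$ins_letter)
  b_keys <- key(paratope_b)
  b_res <- stats::setNames(paratope_b$residue, b_keys)
  out <- paratope_a
  out$shared <- key(paratope_a) %in% b_keys
  out$identical_sidechain <- out$shared &
    paratope_a$residue == b_res[key(paratope_a)]
  gl <- dplyr::filter(annot_a, !is.na(.data$germline_flag), .data$germline_flag)
  out$germline_identical <- out$identical_sidechain &
    key(paratope_a) %in% paste(gl$chain, gl$position, gl$ins_letter)
  stopifnot(all(out$identical_sidechain[out$germline_identical]),
            all(out$shared[out$identical_sidechain]))
  structure(out, class = c("conservation_tbl", class(out)))
}

#' Summary counts of a conservation comparison
#' @param x A [compare_paratopes()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_positions`, `n_shared`, `n_identical`,
#'   `n_germline_identical`.
#' @method glance conservation_tbl
#' @export
glance.conservation_tbl <- function(x, ...) {
  tibble::tibble(
    n_positions = nrow(x),
    n_shared = sum(x$shared),
    n_identical = sum(x$identical_sidechain),
    n_germline_identical = sum(x$germline_identical)
  )
}
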