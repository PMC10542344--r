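#' Spatial aggregation propensity (SAP) scores
#'
#' Exposure-weighted hydrophobicity summed over a spatial neighbourhood:
#' for every side-chain heavy atom, each side-chain atom within `radius`
#' contributes its residue's relative side-chain exposure (observed
#' side-chain SASA over the fully-exposed reference area) times its
#' residue's hydrophobicity (Black-Mould, zero-centred at glycine, so polar
#' residues contribute negatively). The per-residue score is the maximum
#' over the residue's atoms (hotspots are local maxima); the mean is also
#' reported. Fully buried neighbourhoods score zero; exposed hydrophobic
#' patches score high.
#'
#' @param atoms Atom tibble.
#' @param radius Neighbourhood radius in Angstrom (default 5.0).
#' @param hydrophobicity Named per-residue (one-letter) hydrophobicity
#'   scale; the default ships with the package.
#' @param n_points SASA sampling points.
#' @return Tibble with `chain`, `resno`, `ins`, `resid`, `sap` (max over
#'   atoms), `sap_mean`, `rel_exposure`, `contributing_atoms` (atoms in the
#'   max atom's neighbourhood). Unknown residue types are skipped with a
#'   warning.
#' @export
sap_scores <- function(atoms, radius = 5.0,
                       hydrophobicity = HYDROPHOBICITY_BM,
                       n_points = 240L) {
  known <- atoms$resid %in% names(AA_3TO1)
  if (any(!known)) {
    warning("skipping unknown residue types: ",
            paste(unique(atoms$resid[!known]), collapse = ", "),
            call. = FALSE)
    atoms <- atoms[known, ]
  }
  expo <- residue_exposure(atoms, n_points = n_points)
  rkey <- residue_key(atoms)
  expo_of <- stats::setNames(expo$rel_exposure, residue_key(expo))
  code <- AA_3TO1[atoms$resid]
  hyd <- hydrophobicity[code]
  hyd[is.na(hyd)] <- 0
  ## contribution each atom's residue makes to neighbourhoods it enters
  contrib <- unname(expo_of[rkey] * hyd)
  side <- which(!(atoms$elety %in% BACKBONE_ATOMS))
  if (length(side) == 0) {
    return(dplyr::mutate(residue_table(atoms), sap = 0, sap_mean = 0,
                         rel_exposure = expo_of[residue_key(residue_table(atoms))],
                         contributing_atoms = 0L))
  }
  sxyz <- coords(atoms)[side, , drop = FALSE]
  hits <- atom_pairs_within_grid(sxyz, sxyz, radius)
  sap_atom <- numeric(length(side))
  n_in <- integer(length(side))
  agg <- tapply(contrib[side][hits$j], hits$i, sum)
  cnt <- tapply(hits$j, hits$i, length)
  sap_atom[as.integer(names(agg))] <- as.numeric(agg)
  n_in[as.integer(names(cnt))] <- as.integer(cnt)
  per_atom <- tibble::tibble(key = rkey[side], sap = sap_atom, n = n_in)
  summarised <- per_atom |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(sap_max = max(.data$sap), sap_mean = mean(.data$sap),
                     contributing_atoms = .data$n[which.max(.data$sap)],
                     .groups = "drop")
  res <- residue_table(atoms)
  res$key <- residue_key(res)
  out <- dplyr::left_join(res, summarised, by = "key")
  out$sap_max[is.na(out$sap_max)] <- 0        # glycine: no side-chain atoms
  out$sap_mean[is.na(out$sap_mean)] <- 0
  out$contributing_atoms[is.na(out$contributing_atoms)] <- 0L
  out$rel_exposure <- unname(expo_of[out$key])
  dplyr::select(out, "chain", "resno", "ins", "resid", sap = "sap_max",
                "sap_mean", "rel_exposure", "contributing_atoms")
}

#' Rank aggregation hotspots and suggest polar substitutions
#'
#' Orders residues by SAP score (descending, ties by chain/residue number)
#' and attaches polar substitution suggestions from a fixed
#' aromatic/hydrophobic-to-polar table (Y -> N/S, W -> S/N/F, F -> S/Y,
#' ...), the standard redesign move for aggregation-prone surface
#' positions.
#'
#' @param scores A [sap_scores()] tibble.
#' @param top_n Number of hotspots to return.
#' @param surface_only Keep only residues with positive SAP (exposed
#'   hydrophobics); with all-zero scores this leaves nothing.
#' @return Tibble of hotspots with a `suggested` column (comma-separated
#'   polar substitutions).
#' @export
rank_hotspots <- function(scores, top_n = 10, surface_only = TRUE) {
  stopifnot(nrow(scores) > 0)
  out <- dplyr::arrange(scores, dplyr::desc(.data$sap), .data$chain,
                        .data$resno, .data$ins)
  if (surface_only) out <- dplyr::filter(out, .data$sap > 0)
  out <- utils::head(out, top_n)
  code <- AA_3TO1[out$resid]
  out$suggested <- unname(purrr::map_chr(code, function(c1) {
    s <- POLAR_SUBSTITUTIONS[[c1]]
    if (is.null(s)) "" else paste(s, collapse = ",")
  }))
  out
}

#' Write a structure with SAP scores painted into the B-factor column
#'
#' @param atoms Atom tibble.
#' @param scores Matching [sap_scores()] tibble.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_sap_pdb <- function(atoms, scores, path) {
  b <- scores$sap[match(residue_key(atoms), residue_key(scores))]
  b[is.na(b)] <- 0
  write_structure_pdb(atoms, path, b = b)
}
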