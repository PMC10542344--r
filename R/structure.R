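#' Read a macromolecular structure into an atom tibble
#'
#' Parses a PDB or mmCIF file into a flat tibble of heavy protein atoms, the
#' substrate for all geometry in the package. Waters, ions, non-polymer
#' ligands and hydrogens are dropped at load time; for alternate locations
#' only the highest-occupancy altloc is kept (ties resolved in favour of
#' altloc "A", then lexicographically). Author residue numbering and
#' insertion codes are preserved as the canonical residue coordinate system.
#'
#' @param path Path to a structure file.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (from the file extension).
#' @return A tibble with one row per atom and columns `chain`, `resno`,
#'   `ins`, `resid` (3-letter code), `elety` (atom name), `element`, `x`,
#'   `y`, `z`, `o` (occupancy), `altloc`. Attributes `title` and `source_id`
#'   carry provenance.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' toy <- make_toy_complex(toy_complex_spec(c(3, 3), pairs = cbind(1, 1)))
#' write_structure_pdb(toy$atoms, pdb)
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
      stop("cannot infer structure format from extension '", ext,
           "'; pass format = \"pdb\" or \"cif\"", call. = FALSE)
    )
  }
  if (format == "mmcif") format <- "cif"
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      ## bio3d flags read.cif as beta on every call; real parse failures
      ## come through as errors
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- tibble::as_tibble(parsed$atom)
  at$ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  at$altloc <- ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  element <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                            guess_element(at$elety), at$elesy))
  atoms <- tibble::tibble(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    ins = at$ins, resid = toupper(at$resid), elety = at$elety,
    element = element, x = at$x, y = at$y, z = at$z,
    o = at$o, altloc = at$altloc
  )
  atoms <- dplyr::filter(
    atoms,
    .data$resid %in% names(AA_3TO1),   # polymer amino acids only
    .data$element != "H", .data$element != "D"
  )
  atoms <- resolve_altlocs(atoms)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  attr(atoms, "title") <- if (!is.null(parsed$header)) paste(parsed$header, collapse = " ") else ""
  attr(atoms, "source_id") <- tools::file_path_sans_ext(basename(path))
  atoms
}

## One row per (residue, atom name) after keeping the best altloc:
## highest occupancy first, then altloc "A", then lexicographic.
resolve_altlocs <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$altloc != "A", .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    ## restore file order of residues/atoms
    dplyr::arrange(match(paste(.data$chain, .data$resno, .data$ins, .data$elety),
                         unique(paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety))))
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG"), two, one)
}

#' Subset a structure to named chains
#'
#' @param atoms An atom tibble from [read_structure()] or a fixture
#'   generator.
#' @param chain_ids Character vector of chain identifiers to keep.
#' @return An atom tibble containing exactly the atoms of the named chains,
#'   input order preserved.
#' @export
select_chains <- function(atoms, chain_ids) {
  available <- unique(atoms$chain)
  missing <- setdiff(chain_ids, available)
  if (length(missing) > 0) {
    stop("chain(s) not present: ", paste(missing, collapse = ", "),
         "; available chains: ", paste(available, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::filter(atoms, .data$chain %in% chain_ids)
  attributes(out)[c("title", "source_id")] <- attributes(atoms)[c("title", "source_id")]
  out
}

#' One-letter sequence of a chain
#'
#' One letter per residue in author-numbering (file) order. Standard residues
#' and common modified residues (e.g. selenomethionine) map through the
#' package's 3-to-1 table; anything unknown becomes `"X"`.
#'
#' @inheritParams select_chains
#' @param chain_id A single chain identifier.
#' @return A single amino-acid string.
#' @export
chain_sequence <- function(atoms, chain_id) {
  stopifnot(length(chain_id) == 1)
  res <- residue_table(select_chains(atoms, chain_id))
  code <- AA_3TO1[res$resid]
  code[is.na(code)] <- "X"
  paste(code, collapse = "")
}

#' Distinct residues of a structure, in order of first appearance
#'
#' @inheritParams select_chains
#' @return Tibble with columns `chain`, `resno`, `ins`, `resid`.
#' @export
residue_table <- function(atoms) {
  dplyr::distinct(atoms, .data$chain, .data$resno, .data$ins, .data$resid)
}

residue_key <- function(df) {
  paste(df$chain, df$resno, df$ins, sep = "|")
}

#' Write an atom tibble as a minimal PDB file
#'
#' Fixed-column ATOM records sufficient for round-tripping fixtures and for
#' viewing in any structure viewer. Coordinates are written to 3 decimals.
#'
#' @inheritParams select_chains
#' @param path Output file path.
#' @param b Optional per-atom numeric vector written to the B-factor column
#'   (e.g. to paint per-residue scores); defaults to 0.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path, b = NULL) {
  if (is.null(b)) b <- rep(0, nrow(atoms))
  stopifnot(length(b) == nrow(atoms))
  name <- ifelse(nchar(atoms$elety) < 4, sprintf(" %-3s", atoms$elety),
                 atoms$elety)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000, name,
    ifelse(atoms$altloc == "", " ", atoms$altloc),
    atoms$resid, atoms$chain, atoms$resno,
    ifelse(atoms$ins == "", " ", atoms$ins),
    atoms$x, atoms$y, atoms$z, atoms$o, b, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## coordinates as an n x 3 matrix
coords <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}
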