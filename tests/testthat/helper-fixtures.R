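## Shared fixture builders used across test files. Everything is generated
## in code; no binary fixtures.

## single free-standing atom tibble
one_atom <- function(chain = "A", resno = 1L, resid = "ALA", elety = "CA",
                     element = "C", x = 0, y = 0, z = 0, o = 1,
                     altloc = "") {
  tibble::tibble(chain = chain, resno = as.integer(resno), ins = "",
                 resid = resid, elety = elety, element = element,
                 x = x, y = y, z = z, o = o, altloc = altloc)
}

## a single residue (with side chain) cut out of the toy-complex generator,
## recentred at `centre`
single_residue <- function(code1 = "F", chain = "A", centre = c(0, 0, 0)) {
  spec <- toy_complex_spec(c(1, 1), sequences = c(code1, "A"))
  a <- dplyr::filter(make_toy_complex(spec)$atoms, chain == "A")
  a$chain <- chain
  a$x <- a$x - 10 + centre[1]
  a$y <- a$y + centre[2]
  a$z <- a$z + centre[3]
  a
}

## spherical shell of carbon pseudo-atoms (glycine), used to bury residues
## and to build ideally complementary nested surfaces
atom_shell <- function(chain = "B", radius = 3.4, n = 100, resid = "GLY",
                       resno_offset = 0L) {
  p <- reepitope:::sphere_points(n) * radius
  tibble::tibble(chain = chain, resno = resno_offset + seq_len(n), ins = "",
                 resid = resid, elety = "CA", element = "C",
                 x = p[, 1], y = p[, 2], z = p[, 3], o = 1, altloc = "")
}

## standard planted-interface toy complex used by several files
toy4 <- function(seed = 1L) {
  make_toy_complex(toy_complex_spec(c(8, 8),
                                    pairs = cbind(c(1, 3, 5, 7), c(1, 3, 5, 7)),
                                    seed = seed))
}

## pose training data over several toy complexes (near + far decoys)
pose_training_data <- function(n_complexes = 5, n_near = 6, n_far = 6) {
  purrr::map_dfr(seq_len(n_complexes), function(s) {
    toy <- toy4(s)
    poses <- generate_decoys(toy$atoms, "B", "A", n_near = n_near,
                             n_far = n_far, seed = s)
    lab <- label_poses(poses, toy$atoms)
    feats <- purrr::map_dfr(poses, extract_pose_features)
    dplyr::bind_cols(tibble::tibble(complex = paste0("c", s)), lab, feats)
  })
}

## independent rank AUC used as the oracle against the package's internal one
auc_oracle <- function(scores, positive) {
  as.numeric(pROC::auc(pROC::roc(response = factor(positive, c(FALSE, TRUE)),
                                 predictor = scores, quiet = TRUE,
                                 direction = "<")))
}

## path where a user can drop the deposited crystal structures and germline
## reference sequences for the full-structure checks
real_data_path <- function(...) {
  file.path(system.file("extdata", package = "reepitope"), "real", ...)
}
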