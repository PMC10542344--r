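## Rigid-body docking poses and the random-forest pose discriminator.
##
## The docking engine itself is out of scope: poses come from the decoy
## generator below or from user-supplied transforms; engine scores are
## optional inputs whose distribution becomes a feature group.

quat_to_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

quat_random <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

quat_small <- function(max_angle_deg) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_angle_deg) * pi / 180
  c(cos(ang / 2), sin(ang / 2) * axis)
}

#' Construct a rigid-body docking pose
#'
#' The antibody is rotated about its centroid by the unit quaternion `q`
#' and translated by `t`; the antigen stays in its crystal frame. Internal
#' antibody distances are preserved to numerical tolerance by construction.
#'
#' @param antibody,antigen Atom tibbles.
#' @param q Unit quaternion `c(w, x, y, z)` (default: identity).
#' @param t Translation 3-vector in Angstrom.
#' @param engine_score Optional docking-engine score.
#' @return A `dock_pose` object; the stored antibody atoms are already
#'   transformed.
#' @export
dock_pose <- function(antibody, antigen, q = c(1, 0, 0, 0), t = c(0, 0, 0),
                      engine_score = NA_real_) {
  ctr <- colMeans(coords(antibody))
  rot <- quat_to_rotmat(q)
  xyz <- sweep(coords(antibody), 2, ctr) %*% t(rot)
  xyz <- sweep(xyz, 2, ctr + t, "+")
  ab <- antibody
  ab$x <- xyz[, 1]; ab$y <- xyz[, 2]; ab$z <- xyz[, 3]
  structure(list(antibody = ab, antigen = antigen,
                 transform = list(q = q / sqrt(sum(q^2)), t = t),
                 engine_score = engine_score,
                 ab_chains = unique(ab$chain),
                 ag_chains = unique(antigen$chain)),
            class = "dock_pose")
}

#' @export
print.dock_pose <- function(x, ...) {
  cat("<dock_pose> antibody chains", paste(x$ab_chains, collapse = ","),
      "vs antigen chains", paste(x$ag_chains, collapse = ","),
      sprintf("| t = (%.2f, %.2f, %.2f)", x$transform$t[1], x$transform$t[2],
              x$transform$t[3]), "\n")
  invisible(x)
}

pose_atoms <- function(pose) {
  dplyr::bind_rows(pose$antigen, pose$antibody)
}

#' Generate near-native and random-placement decoy poses
#'
#' Near poses apply a small seeded rotation/translation to the native
#' antibody placement; far poses place the antibody at a uniformly random
#' orientation on a sphere around the antigen, rejecting placements with
#' any heavy-atom pair closer than `min_clearance`.
#'
#' @param native Atom tibble of the native complex.
#' @param antibody_chains,antigen_chains Chain ids of the two sides.
#' @param n_near,n_far Pose counts.
#' @param perturb `c(max rotation degrees, max translation Angstrom)` for
#'   near poses.
#' @param seed Integer seed; same seed, same transforms.
#' @param min_clearance Clash threshold (Angstrom) for far poses.
#' @param offset Extra centre-centre distance range (Angstrom) added beyond
#'   the sum of the two sides' bounding radii for far poses.
#' @param max_tries Rejection-sampling budget per far pose.
#' @return List of `dock_pose` objects (near poses first).
#' @export
generate_decoys <- function(native, antibody_chains, antigen_chains,
                            n_near = 10, n_far = 10, perturb = c(3, 0.5),
                            seed = 1L, min_clearance = 2.0,
                            offset = c(2, 15), max_tries = 200L) {
  ab <- select_chains(native, antibody_chains)
  ag <- select_chains(native, antigen_chains)
  if (nrow(contact_residues(native, antibody_chains, antigen_chains, 5)) == 0) {
    stop("native complex has no interface at 5 Angstrom", call. = FALSE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  poses <- list()
  for (i in seq_len(n_near)) {
    poses[[length(poses) + 1]] <-
      dock_pose(ab, ag, q = quat_small(perturb[1]),
                t = stats::runif(3, -1, 1) * perturb[2] / sqrt(3))
  }
  ag_ctr <- colMeans(coords(ag))
  ab_ctr <- colMeans(coords(ab))
  r_ag <- sqrt(max(rowSums(sweep(coords(ag), 2, ag_ctr)^2)))
  r_ab <- sqrt(max(rowSums(sweep(coords(ab), 2, ab_ctr)^2)))
  for (i in seq_len(n_far)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d <- r_ag + r_ab + stats::runif(1, offset[1], offset[2])
      target_ctr <- ag_ctr + u * d
      pose <- dock_pose(ab, ag, q = quat_random(), t = target_ctr - ab_ctr)
      clash <- atom_pairs_within_grid(coords(pose$antibody), coords(ag),
                                      min_clearance)
      if (length(clash$i) == 0) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not place a clash-free far decoy in ", max_tries,
           " tries (clearance ", min_clearance, " A); the antigen may ",
           "envelop the placement sphere", call. = FALSE)
    }
    poses[[length(poses) + 1]] <- pose
  }
  poses
}

#' Fraction of native contacts preserved in a pose
#'
#' @param pose A `dock_pose`.
#' @param native Atom tibble of the native complex (same residue
#'   identifiers).
#' @param cutoff Contact cutoff in Angstrom.
#' @return fnat in [0, 1]. Errors if the native contact set is empty.
#' @export
fnat <- function(pose, native, cutoff = 5.0) {
  nat <- contact_residues(native, pose$ab_chains, pose$ag_chains, cutoff)
  if (nrow(nat) == 0) {
    stop("native contact set is empty at ", cutoff, " Angstrom", call. = FALSE)
  }
  got <- contact_residues(pose_atoms(pose), pose$ab_chains, pose$ag_chains,
                          cutoff)
  key <- function(x) paste(x$chain_a, x$resno_a, x$ins_a,
                           x$chain_b, x$resno_b, x$ins_b)
  mean(key(nat) %in% key(got))
}

#' Label poses by fraction of native contacts
#'
#' @param poses List of `dock_pose`.
#' @param native Native complex atom tibble.
#' @param thresholds `c(native_like =, decoy =)`: `fnat >= native_like` is
#'   native-like, `fnat <= decoy` is a decoy, anything between is ambiguous
#'   (excluded from training).
#' @param cutoff Contact cutoff.
#' @return Tibble with `fnat` and `class` (factor
#'   native_like/ambiguous/decoy).
#' @export
label_poses <- function(poses, native, thresholds = c(native_like = 0.5,
                                                      decoy = 0.1),
                        cutoff = 5.0) {
  f <- purrr::map_dbl(poses, fnat, native = native, cutoff = cutoff)
  cls <- dplyr::case_when(
    f >= thresholds[["native_like"]] ~ "native_like",
    f <= thresholds[["decoy"]] ~ "decoy",
    TRUE ~ "ambiguous"
  )
  tibble::tibble(fnat = f,
                 class = factor(cls, c("native_like", "ambiguous", "decoy")))
}

POSE_FEATURE_SCHEMA <- "pose-features-1"

#' Interface feature vector of a docking pose
#'
#' Feature groups: interface size (residue counts per side and buried
#' surface area), amino-acid composition of the interface residues (20
#' fractions per side, each side summing to 1 or all-zero when empty),
#' specific interactions (donor/acceptor N/O heavy-atom pairs within 3.5
#' Angstrom; opposite formal-charge side-chain group pairs within 4.0), and
#' the pose's engine-score placement within its docking run (rank fraction,
#' z-score, percentile; neutral constants 0.5/0/0.5 when no run scores are
#' available).
#'
#' @param pose A `dock_pose`.
#' @param run_scores Engine scores of all poses in the same docking run
#'   (may be empty).
#' @param n_points SASA sampling points for the buried-area term.
#' @return One-row tibble of 47 numeric features, in fixed schema order.
#' @export
extract_pose_features <- function(pose, run_scores = numeric(0),
                                  n_points = 60L) {
  atoms <- pose_atoms(pose)
  contacts <- contact_residues(atoms, pose$ab_chains, pose$ag_chains, 5.0)
  res_a <- contact_side(contacts, "a")
  res_b <- contact_side(contacts, "b")
  comp <- function(res) {
    v <- stats::setNames(rep(0, 20), AA1)
    if (nrow(res) > 0) {
      code <- AA_3TO1[res$resid]
      tb <- table(factor(code, AA1))
      v[] <- as.numeric(tb) / sum(tb)
    }
    v
  }
  bsa <- 0
  if (nrow(contacts) > 0) {
    bsa <- interface_area(atoms, pose$ab_chains, pose$ag_chains,
                          n_points = n_points)$delta_sasa
  }
  ab <- pose$antibody; ag <- pose$antigen
  no_ab <- ab[ab$element %in% c("N", "O"), ]
  no_ag <- ag[ag$element %in% c("N", "O"), ]
  hbond <- length(atom_pairs_within_grid(coords(no_ab), coords(no_ag), 3.5)$i)
  pos_atoms <- function(x) x[(x$resid == "ARG" & x$elety %in% c("NH1", "NH2", "NE")) |
                               (x$resid == "LYS" & x$elety == "NZ") |
                               (x$resid == "HIS" & x$elety %in% c("ND1", "NE2")), ]
  neg_atoms <- function(x) x[(x$resid == "ASP" & x$elety %in% c("OD1", "OD2")) |
                               (x$resid == "GLU" & x$elety %in% c("OE1", "OE2")), ]
  salt <- length(atom_pairs_within_grid(coords(pos_atoms(ab)),
                                        coords(neg_atoms(ag)), 4.0)$i) +
    length(atom_pairs_within_grid(coords(neg_atoms(ab)),
                                  coords(pos_atoms(ag)), 4.0)$i)
  if (length(run_scores) > 0 && !is.na(pose$engine_score)) {
    s <- pose$engine_score
    rk <- sum(run_scores >= s - 1e-12)   # 1 = best (maximum)
    rank_frac <- rk / length(run_scores)
    z <- if (stats::sd(run_scores) > 0) (s - mean(run_scores)) / stats::sd(run_scores) else 0
    pctl <- mean(run_scores <= s + 1e-12)
  } else {
    rank_frac <- 0.5; z <- 0; pctl <- 0.5   # neutral constants
  }
  out <- c(
    n_res_ab = nrow(res_a), n_res_ag = nrow(res_b), bsa = bsa,
    stats::setNames(comp(res_a), paste0("comp_ab_", AA1)),
    stats::setNames(comp(res_b), paste0("comp_ag_", AA1)),
    hbond_pairs = hbond, salt_pairs = salt,
    score_rank_frac = rank_frac, score_z = z, score_pctl = pctl
  )
  tb <- tibble::as_tibble(as.list(out))
  attr(tb, "schema") <- POSE_FEATURE_SCHEMA
  tb
}

## rank-statistic (Mann-Whitney) AUC; positives should score high
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the docking-pose random forest with grouped cross-validation
#'
#' Folds partition source complexes (no complex contributes poses to more
#' than one fold). The reported AUCs are rank-statistic AUCs on held-out
#' poses; the returned model is refit on all data.
#'
#' @param data Tibble with columns `complex` (source-complex id), `class`
#'   (factor with levels containing `native_like` and `decoy`; ambiguous
#'   rows are dropped), and numeric feature columns.
#' @param n_trees Forest size (default 500).
#' @param max_depth Optional depth cap (translated to a node-count cap).
#' @param seed Integer seed (required for determinism).
#' @param folds Number of grouped CV folds.
#' @return A `pose_rf` object: the fitted forest, feature schema, CV report
#'   (via [tidy.pose_rf()] / [glance.pose_rf()]) and training metadata.
#' @export
train_pose_classifier <- function(data, n_trees = 500, max_depth = NULL,
                                  seed = 1L, folds = 4L) {
  data <- dplyr::filter(data, .data$class != "ambiguous")
  data$class <- factor(as.character(data$class), c("native_like", "decoy"))
  if (dplyr::n_distinct(data$class) < 2) {
    stop("both native_like and decoy poses are required for training",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(data), c("complex", "class", "fnat"))
  cv <- grouped_rf_cv(data, feat_cols, group_col = "complex",
                      label_col = "class", positive = "native_like",
                      n_trees = n_trees, max_depth = max_depth,
                      seed = seed, folds = folds)
  structure(
    list(forest = cv$final, schema = POSE_FEATURE_SCHEMA,
         feat_cols = feat_cols, cv = cv$report, pooled = cv$pooled,
         metadata = list(seed = seed, n_trees = n_trees, folds = folds,
                         thresholds = c(native_like = 0.5, decoy = 0.1))),
    class = "pose_rf")
}

## shared grouped-CV machinery for both forests
grouped_rf_cv <- function(data, feat_cols, group_col, label_col, positive,
                          n_trees, max_depth, seed, folds) {
  groups <- unique(data[[group_col]])
  if (length(groups) < folds) {
    stop("need at least as many source complexes/entries (", length(groups),
         ") as folds (", folds, ")", call. = FALSE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of <- stats::setNames(rep(seq_len(folds), length.out = length(groups)),
                             sample(groups))
  x <- as.data.frame(data[, feat_cols])
  y <- droplevels(factor(data[[label_col]]))
  maxnodes <- if (is.null(max_depth)) NULL else 2^max_depth
  fit <- function(rows) {
    set.seed(seed)
    randomForest::randomForest(x = x[rows, , drop = FALSE],
                               y = droplevels(y[rows]),
                               ntree = n_trees, maxnodes = maxnodes)
  }
  held_scores <- numeric(nrow(x)); held_fold <- fold_of[data[[group_col]]]
  report <- tibble::tibble(fold = integer(0), auc = numeric(0),
                           accuracy = numeric(0), n = integer(0))
  for (f in seq_len(folds)) {
    test <- which(held_fold == f)
    train <- setdiff(seq_len(nrow(x)), test)
    if (dplyr::n_distinct(y[train]) < 2 || length(test) == 0) {
      stop("fold ", f, " lacks both classes; supply more balanced groups",
           call. = FALSE)
    }
    m <- fit(train)
    p <- stats::predict(m, x[test, , drop = FALSE], type = "prob")[, positive]
    held_scores[test] <- p
    report <- dplyr::add_row(
      report, fold = f,
      auc = auc_rank(p, y[test] == positive),
      accuracy = mean((p >= 0.5) == (y[test] == positive)),
      n = length(test))
  }
  pooled <- auc_rank(held_scores, y == positive)
  list(final = fit(seq_len(nrow(x))), report = report,
       pooled = tibble::tibble(
         pooled_auc = pooled,
         pooled_accuracy = mean((held_scores >= 0.5) == (y == positive)),
         n = nrow(x)))
}

#' @export
print.pose_rf <- function(x, ...) {
  cat("<pose_rf> ", x$metadata$n_trees, " trees, ", x$metadata$folds,
      "-fold grouped CV pooled AUC = ", round(x$pooled$pooled_auc, 3),
      "\n", sep = "")
  invisible(x)
}

#' Per-fold cross-validation report of a pose classifier
#' @param x A `pose_rf`.
#' @param ... Unused.
#' @method tidy pose_rf
#' @export
tidy.pose_rf <- function(x, ...) x$cv

#' Pooled cross-validation summary of a pose classifier
#' @param x A `pose_rf`.
#' @param ... Unused.
#' @method glance pose_rf
#' @export
glance.pose_rf <- function(x, ...) x$pooled

#' Score poses with a trained pose classifier
#'
#' @param model A `pose_rf`.
#' @param features Feature tibble(s) from [extract_pose_features()].
#' @return Numeric vector of native-likeness probabilities.
#' @export
score_poses <- function(model, features) {
  stopifnot(inherits(model, "pose_rf"))
  schema <- attr(features, "schema")
  if (!is.null(schema) && !identical(schema, model$schema)) {
    stop("feature schema mismatch: model ", model$schema, " vs features ",
         schema, call. = FALSE)
  }
  missing <- setdiff(model$feat_cols, names(features))
  if (length(missing) > 0) {
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::predict(model$forest,
                 as.data.frame(features[, model$feat_cols]),
                 type = "prob")[, "native_like"]
}

#' Rank a panel of antibodies against one antigen
#'
#' For each antibody, poses are generated (random placements around the
#' antigen, seeded) or taken from `poses`, scored with the trained pose
#' classifier, and the best score retained. The panel is sorted by best
#' score (descending), ties broken by antibody id; each hit reports the
#' implied epitope (antigen residues within 5 Angstrom of the best pose).
#'
#' @param antibodies Named list of antibody atom tibbles.
#' @param antigen Antigen atom tibble.
#' @param poses_per_antibody Poses generated per antibody when none are
#'   supplied.
#' @param model A `pose_rf`.
#' @param seed Integer seed.
#' @param poses Optional named list (same names) of `dock_pose` lists to
#'   score instead of generating.
#' @return Tibble `antibody`, `best_score`, `n_poses`, with list-columns
#'   `best_pose` and `epitope`.
#' @export
screen_antibody_panel <- function(antibodies, antigen, poses_per_antibody = 20,
                                  model, seed = 1L, poses = NULL) {
  stopifnot(!is.null(names(antibodies)), inherits(model, "pose_rf"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  rows <- purrr::imap_dfr(antibodies, function(ab, id) {
    pl <- if (!is.null(poses)) poses[[id]] else {
      set.seed(seed + match(id, names(antibodies)))
      random_placements(ab, antigen, poses_per_antibody)
    }
    feats <- purrr::map_dfr(pl, extract_pose_features)
    sc <- score_poses(model, feats)
    best <- which.max(sc)
    ep <- contact_side(contact_residues(pose_atoms(pl[[best]]),
                                        pl[[best]]$ab_chains,
                                        pl[[best]]$ag_chains, 5.0), "b")
    tibble::tibble(antibody = id, best_score = sc[best],
                   n_poses = length(pl), best_pose = list(pl[[best]]),
                   epitope = list(ep))
  })
  dplyr::arrange(rows, dplyr::desc(.data$best_score), .data$antibody)
}

## random rigid placements spanning touching to separated, clash-rejected
random_placements <- function(ab, ag, n, min_clearance = 2.0,
                              max_tries = 200L) {
  ag_ctr <- colMeans(coords(ag)); ab_ctr <- colMeans(coords(ab))
  r_ag <- sqrt(max(rowSums(sweep(coords(ag), 2, ag_ctr)^2)))
  r_ab <- sqrt(max(rowSums(sweep(coords(ab), 2, ab_ctr)^2)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d <- stats::runif(1, 0.3, 1.2) * (r_ag + r_ab)
      pose <- dock_pose(ab, ag, q = quat_random(),
                        t = ag_ctr + u * d - ab_ctr)
      clash <- atom_pairs_within_grid(coords(pose$antibody), coords(ag),
                                      min_clearance)
      if (length(clash$i) == 0) { out[[i]] <- pose; break }
    }
    if (is.null(out[[i]])) {
      stop("could not place a clash-free pose in ", max_tries, " tries",
           call. = FALSE)
    }
  }
  out
}
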