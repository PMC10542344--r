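test_that("decoy generation is a pure function of its seed", {
  toy <- toy4()
  p1 <- generate_decoys(toy$atoms, "B", "A", n_near = 4, n_far = 4, seed = 1)
  p2 <- generate_decoys(toy$atoms, "B", "A", n_near = 4, n_far = 4, seed = 1)
  expect_equal(purrr::map(p1, "transform"), purrr::map(p2, "transform"))
  expect_equal(purrr::map(p1, "antibody"), purrr::map(p2, "antibody"))
  p3 <- generate_decoys(toy$atoms, "B", "A", n_near = 4, n_far = 4, seed = 2)
  expect_false(identical(purrr::map(p1, "transform"),
                         purrr::map(p3, "transform")))
})

test_that("near decoys keep most native contacts, far decoys keep none", {
  toy <- toy4()
  poses <- generate_decoys(toy$atoms, "B", "A", n_near = 6, n_far = 6,
                           perturb = c(2, 0.5), seed = 3)
  lab <- label_poses(poses, toy$atoms)
  expect_true(all(lab$fnat[1:6] > 0.5))
  expect_true(all(lab$fnat[7:12] == 0))
  expect_true(all(lab$class[1:6] == "native_like"))
  expect_true(all(lab$class[7:12] == "decoy"))
  ## far decoys are clash-free
  for (p in poses[7:12]) {
    clash <- reepitope:::atom_pairs_within_grid(
      reepitope:::coords(p$antibody), reepitope:::coords(p$antigen), 2.0)
    expect_length(clash$i, 0)
  }
})

test_that("rigid transforms preserve internal antibody distances", {
  toy <- toy4()
  ab <- select_chains(toy$atoms, "B")
  d0 <- stats::dist(reepitope:::coords(ab))
  poses <- generate_decoys(toy$atoms, "B", "A", n_near = 2, n_far = 2,
                           seed = 5)
  for (p in poses) {
    d1 <- stats::dist(reepitope:::coords(p$antibody))
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
})

test_that("fnat hand-checks: identity 1.0, distant 0.0, partial 0.75", {
  native <- make_toy_complex(toy_complex_spec(
    c(8, 8), pairs = cbind(c(1, 3, 5, 7), c(1, 3, 5, 7))))
  ab <- select_chains(native$atoms, "B")
  ag <- select_chains(native$atoms, "A")
  expect_equal(fnat(dock_pose(ab, ag), native$atoms), 1.0)
  expect_equal(fnat(dock_pose(ab, ag, t = c(0, 50, 0)), native$atoms), 0.0)
  ## an arrangement that preserves exactly 3 of the 4 native pairs
  partial <- make_toy_complex(toy_complex_spec(
    c(8, 8), pairs = cbind(c(1, 3, 5), c(1, 3, 5))))
  pose <- dock_pose(select_chains(partial$atoms, "B"), ag)
  expect_equal(fnat(pose, native$atoms), 0.75)
  ## empty native contact set is an error, not zero
  apart <- make_toy_complex(toy_complex_spec(c(3, 3)))
  pose0 <- dock_pose(select_chains(apart$atoms, "B"),
                     select_chains(apart$atoms, "A"))
  expect_error(fnat(pose0, apart$atoms), "empty")
})

test_that("pose features follow their definitions on constructed cases", {
  toy <- toy4()
  ab <- select_chains(toy$atoms, "B")
  ag <- select_chains(toy$atoms, "A")
  ## zero interface: all-zero sizes and compositions
  far <- extract_pose_features(dock_pose(ab, ag, t = c(0, 100, 0)))
  expect_equal(far$n_res_ab, 0)
  expect_equal(far$bsa, 0)
  expect_true(all(dplyr::select(far, dplyr::starts_with("comp_")) == 0))
  expect_equal(far$hbond_pairs, 0)
  ## neutral score placement without run scores
  expect_equal(far$score_rank_frac, 0.5)
  expect_equal(far$score_z, 0)
  ## homogeneous interface composition is exact
  mixed <- make_toy_complex(toy_complex_spec(
    c(4, 4), pairs = cbind(1:4, 1:4),
    sequences = c("GGGG", "AAAA")))
  pose <- dock_pose(select_chains(mixed$atoms, "B"),
                    select_chains(mixed$atoms, "A"))
  f <- extract_pose_features(pose)
  expect_equal(f$comp_ab_A, 1)        # antibody side: all alanine
  expect_equal(f$comp_ag_G, 1)        # antigen side: all glycine
  expect_equal(sum(dplyr::select(f, dplyr::starts_with("comp_ab_"))), 1)
  ## engine score equal to the run maximum: rank 1, percentile 1
  best <- dock_pose(ab, ag, engine_score = 9)
  fb <- extract_pose_features(best, run_scores = c(1, 4, 9, 2))
  expect_equal(fb$score_rank_frac, 1 / 4)
  expect_equal(fb$score_pctl, 1)
})

test_that("feature extraction is deterministic and pose-order independent", {
  toy <- toy4()
  poses <- generate_decoys(toy$atoms, "B", "A", n_near = 2, n_far = 2, seed = 9)
  f1 <- purrr::map_dfr(poses, extract_pose_features)
  f2 <- purrr::map_dfr(rev(poses), extract_pose_features)
  expect_equal(f1, f2[4:1, ])
})

test_that("the pose forest separates planted near/far decoys across grouped folds", {
  data <- pose_training_data()
  m <- train_pose_classifier(data, n_trees = 200, seed = 7, folds = 4)
  expect_gte(glance(m)$pooled_auc, 0.9)
  ## the package's rank AUC agrees with an independent ROC implementation
  scores <- score_poses(m, data[, !(names(data) %in% c("complex", "class", "fnat"))])
  ours <- reepitope:::auc_rank(scores, data$class == "native_like")
  expect_equal(ours, auc_oracle(scores, data$class == "native_like"),
               tolerance = 1e-8)
  ## an interface-size feature carries the signal
  imp <- sort(m$forest$importance[, 1], decreasing = TRUE)
  expect_true(any(c("n_res_ab", "n_res_ag", "bsa") %in% names(imp)[1:3]))
})

test_that("label shuffling destroys the pose signal; a perfect feature saturates it", {
  data <- pose_training_data()
  set.seed(42)
  shuffled <- data
  shuffled$class <- sample(data$class)
  m0 <- train_pose_classifier(shuffled, n_trees = 200, seed = 7, folds = 4)
  expect_gte(glance(m0)$pooled_auc, 0.35)
  expect_lte(glance(m0)$pooled_auc, 0.65)
  ## single perfectly separating feature
  perfect <- tibble::tibble(
    complex = rep(paste0("c", 1:4), each = 10),
    class = factor(rep(c("native_like", "decoy"), 20),
                   c("native_like", "decoy")),
    sep = as.numeric(rep(c("native_like", "decoy"), 20) == "native_like"))
  mp <- train_pose_classifier(perfect, n_trees = 100, seed = 1, folds = 4)
  expect_equal(glance(mp)$pooled_auc, 1.0)
  ## single-class input is refused
  onecls <- dplyr::filter(data, class == "decoy")
  expect_error(train_pose_classifier(onecls, seed = 1), "both")
})

test_that("panel screening ranks the true binder first, deterministically", {
  data <- pose_training_data()
  m <- train_pose_classifier(data, n_trees = 200, seed = 7, folds = 4)
  toy <- toy4(99)
  ag <- select_chains(toy$atoms, "A")
  ab <- select_chains(toy$atoms, "B")
  ## the true binder's pose set includes near-native poses; the decoy
  ## antibodies only get random placements
  poses <- list(
    binder = generate_decoys(toy$atoms, "B", "A", n_near = 3, n_far = 5, seed = 1),
    decoy1 = generate_decoys(toy$atoms, "B", "A", n_near = 0, n_far = 8, seed = 2),
    decoy2 = generate_decoys(toy$atoms, "B", "A", n_near = 0, n_far = 8, seed = 3))
  panel <- list(binder = ab, decoy1 = ab, decoy2 = ab)
  r1 <- screen_antibody_panel(panel, ag, model = m, seed = 5, poses = poses)
  expect_equal(r1$antibody[1], "binder")
  expect_gt(r1$best_score[1], max(r1$best_score[-1]))
  ## implied epitope of the winner covers the planted antigen residues
  expect_setequal(r1$epitope[[1]]$resno, c(1L, 3L, 5L, 7L))
  r2 <- screen_antibody_panel(panel, ag, model = m, seed = 5, poses = poses)
  expect_equal(r1$best_score, r2$best_score)
  ## a panel of one trivially ranks first
  single <- screen_antibody_panel(panel["binder"], ag, model = m, seed = 5,
                                  poses = poses["binder"])
  expect_equal(nrow(single), 1L)
  ## schema mismatch is refused
  bad <- purrr::map_dfr(poses$binder, extract_pose_features)
  bad$n_res_ab <- NULL
  expect_error(score_poses(m, bad), "schema")
})
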