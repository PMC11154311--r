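cascade_frame <- function(mg, ohog, o18) {
  tibble::tibble(d_OG35_Mg = mg, d_OH32_Og = ohog, d_OH32_O18 = o18,
                 d_O12_Og = 5.3, d_OH32_OH40 = 11.6)
}

test_that("the cascade assigns the characteristic signatures correctly", {
  cfg <- classifier_config()
  # OH32-Og near 2.7 A with the Thr35 bond intact: substate OX.
  expect_equal(classify_frame(cascade_frame(2.0, 2.7, 13.0), cfg), "S2_OX")
  # OH32-O18 at 4.3 A, OH32-Og at its farthest 11.3 A: substate OY.
  expect_equal(classify_frame(cascade_frame(2.0, 11.3, 4.3), cfg), "S2_OY")
  # OH32-Og around 7.5 A, no Ala18 contact: substate OZ.
  expect_equal(classify_frame(cascade_frame(2.0, 7.5, 13.0), cfg), "S2_OZ")
  # Broken Thr35-Mg bond dominates everything: state 1.
  expect_equal(classify_frame(cascade_frame(6.0, 2.7, 4.3), cfg), "S1")
  # Outside all signatures: honest UNASSIGNED.
  expect_equal(classify_frame(cascade_frame(2.0, 12.5, 13.0), cfg),
               "UNASSIGNED")
})

test_that("the cascade is total and deterministic on finite input", {
  set.seed(11)
  f <- cascade_frame(runif(500, 0, 15), runif(500, 0, 15), runif(500, 0, 15))
  lab <- classify_frame(f)
  expect_true(all(lab %in% state_levels()))
  expect_identical(lab, classify_frame(f))
  expect_error(classify_frame(cascade_frame(NA, 1, 1)), "finite")
})

test_that("raising t_mg never decreases the state-2 fraction", {
  set.seed(12)
  f <- cascade_frame(runif(400, 1, 8), runif(400, 0, 15), runif(400, 0, 15))
  s2_frac <- vapply(seq(1.5, 7.5, by = 0.5), function(t_mg) {
    lab <- classify_frame(f, classifier_config(t_mg = t_mg,
                                               t_ox = t_mg + 1,
                                               t_oz_max = t_mg + 2))
    mean(lab %in% c("S2_OX", "S2_OY", "S2_OZ"))
  }, numeric(1))
  expect_true(all(diff(s2_frac) >= 0))
})

test_that("mode smoothing matches an enumeration oracle and its examples", {
  # Spike removal: [OX,OX,OY,OX,OX], window 3 -> one OX segment.
  f <- cascade_frame(rep(2, 5), c(2.7, 2.7, 11.3, 2.7, 2.7),
                     c(13, 13, 4.3, 13, 13))
  f$frame <- 1:5
  lab3 <- classify_series(f, classifier_config(smoothing_window = 3))
  expect_equal(unique(lab3$label), "S2_OX")
  expect_equal(nrow(label_segments(lab3)), 1)
  # Window 1 is the identity.
  lab1 <- classify_series(f, classifier_config(smoothing_window = 1))
  expect_equal(lab1$label, lab1$raw_label)

  # Enumeration oracle over all 2-label sequences of length 5, window 3:
  # independent slow reference with the tie-to-previous rule.
  slow_mode <- function(code, w = 3) {
    n <- length(code); half <- w %/% 2; out <- integer(n); prev <- code[1]
    for (i in seq_len(n)) {
      win <- code[max(1, i - half):min(n, i + half)]
      tab <- sort(table(win), decreasing = TRUE)
      top <- as.integer(names(tab[tab == max(tab)]))
      out[i] <- if (length(top) == 1) top
        else if (prev %in% top) prev else win[win %in% top][1]
      prev <- out[i]
    }
    out
  }
  grid <- expand.grid(rep(list(c(1L, 2L)), 5))
  for (r in seq_len(nrow(grid))) {
    code <- as.integer(grid[r, ])
    expect_identical(rasconf:::mode_filter(code, 3L), slow_mode(code),
                     info = paste(code, collapse = ""))
  }
  expect_error(classify_series(f[0, ]), "empty")
})

test_that("occupancy pools trajectories weighted by frame counts", {
  occ <- occupancy(labels_from_states(rep(c("S1", "S2_OX"), c(40, 60))))
  expect_equal(occ$fraction[occ$label == "S1"], 0.40)
  expect_equal(occ$fraction[occ$label == "S2_OX"], 0.60)
  expect_lt(abs(sum(occ$fraction) - 1), 1e-12)

  occ_u <- occupancy(labels_from_states(rep("UNASSIGNED", 7)))
  expect_equal(occ_u$fraction[occ_u$label == "UNASSIGNED"], 1)

  # Frame-weighted pooling oracle: 100 frames all S1 + 300 all OX.
  pooled <- occupancy(list(labels_from_states(rep("S1", 100)),
                           labels_from_states(rep("S2_OX", 300))))
  expect_equal(pooled$fraction[pooled$label == "S1"], 0.25)
  expect_equal(pooled$fraction[pooled$label == "S2_OX"], 0.75)
  expect_equal(attr(pooled, "n_trajectories"), 2L)

  # Pooled occupancy equals the frame-weighted average of per-trajectory
  # occupancies.
  set.seed(13)
  l1 <- labels_from_states(sample(state_levels(), 120, TRUE))
  l2 <- labels_from_states(sample(state_levels(), 380, TRUE))
  o1 <- occupancy(l1); o2 <- occupancy(l2); op <- occupancy(list(l1, l2))
  expect_equal(op$fraction, (120 * o1$fraction + 380 * o2$fraction) / 500,
               tolerance = 1e-12)
  expect_error(occupancy(list()), "at least one")
})

test_that("transition counts equal segment boundaries", {
  lab <- labels_from_states(rep("S2_OX", 10))
  expect_true(all(transition_matrix(lab) == 0))
  lab2 <- labels_from_states(c("S1", "S2_OX", "S1"))
  m <- transition_matrix(lab2)
  expect_equal(sum(m), 2)
  expect_equal(m["S1", "S2_OX"], 1L)
  expect_equal(m["S2_OX", "S1"], 1L)
  expect_true(all(diag(m) == 0))
  # Conservation: transitions = segments - 1 on random series.
  set.seed(14)
  for (k in 1:5) {
    lr <- labels_from_states(sample(state_levels(), 200, TRUE))
    expect_equal(sum(transition_matrix(lr)),
                 nrow(rasconf:::rle_segments(lr$label, lr$frame)) - 1L)
  }
})

test_that("classification recovers true labels at 99%+ under 0.4 A noise", {
  sd04 <- matrix(0.4, 5, 5, dimnames = dimnames(rasconf:::preset_dist_sd()))
  spec <- synthetic_spec("solution_WT", n_frames = 6000, tau = 50, seed = 21,
                         dist_sd = sd04, ions = FALSE)
  sim <- generate_trajectory(spec)
  feats <- extract_features(sim$trajectory, resolve_roles(sim$structure))
  labs <- classify_series(feats)
  expect_gte(mean(labs$label == sim$truth$state), 0.99)
})
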