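# Small rigid scaffold: 4 non-collinear anchors usable as a fit set.
anchors <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))

test_that("superposition is exact on rigid copies and matches oracles", {
  set.seed(41)
  P <- rbind(anchors, matrix(rnorm(9, sd = 4), 3, 3))
  expect_lt(superpose(P, P)$rmsd, 1e-9)

  Rz <- rotation_z(90)
  expect_lt(superpose(P %*% Rz + 3, P)$rmsd, 1e-9)

  # Independent oracles on noisy pairs: bio3d's fitted RMSD, and a direct
  # Euler-angle optimisation of the centered RMSD.
  euler_best <- function(P, Q) {
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    obj <- function(ang) {
      R <- rotation_z(ang[1] * 180 / pi) %*%
        matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE) %*%
        rotation_z(ang[3] * 180 / pi)
      sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
    }
    min(vapply(1:25, function(k) {
      optim(runif(3, -pi, pi), obj)$value
    }, numeric(1)))
  }
  for (k in 1:3) {
    Q4 <- matrix(rnorm(12, sd = 3), 4, 3)
    P4 <- Q4 %*% random_rotation() + rnorm(3) +
      matrix(rnorm(12, sd = 0.3), 4, 3)
    mine <- superpose(P4, Q4)$rmsd
    expect_equal(mine,
                 bio3d::rmsd(as.numeric(t(Q4)), as.numeric(t(P4)),
                             fit = TRUE),
                 tolerance = 1e-3)  # bio3d prints at 3 decimals
    expect_equal(mine, euler_best(P4, Q4), tolerance = 1e-4)
  }

  expect_error(superpose(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(0:3, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("per-frame RMSD is zero on a static copy and larger on switches", {
  n_res <- 8
  base <- rbind(anchors, matrix(rnorm(3 * (n_res - 4), sd = 4), n_res - 4, 3))
  roles <- ca_only_roles(n_res)
  X <- matrix(rep(as.numeric(t(base)), 5), 5, byrow = TRUE)
  tr <- traj_from_matrix(X)
  r <- rmsd_series(tr, roles, base, fit_residues = 1:4, report_residues = 1:8)
  expect_true(all(r$rmsd_A < 1e-9))

  # Perturb "switch" residues 5:6 only: their reported RMSD must dominate.
  set.seed(42)
  X2 <- X
  for (f in 1:5) {
    X2[f, 13:18] <- X2[f, 13:18] + rnorm(6, sd = 2)
  }
  tr2 <- traj_from_matrix(X2)
  r_sw <- rmsd_series(tr2, roles, base, fit_residues = 1:4,
                      report_residues = 5:6)
  r_core <- rmsd_series(tr2, roles, base, fit_residues = 1:4,
                        report_residues = c(1:4, 7:8))
  expect_true(all(r_sw$rmsd_A >= r_core$rmsd_A))
})

test_that("RMSF matches the two-point closed form and pooling identity", {
  n_res <- 6
  base <- rbind(anchors, c(10, 10, 10), c(-5, -5, -5))
  a <- 0.8
  make_frames <- function(n) {
    X <- matrix(rep(as.numeric(t(base)), n), n, byrow = TRUE)
    X[, 13] <- X[, 13] + a * rep_len(c(1, -1), n)  # residue 5, x
    X
  }
  roles <- ca_only_roles(n_res)
  tr <- traj_from_matrix(make_frames(10))
  labs <- labels_from_states(rep("S1", 10))
  prof <- rmsf_by_state(tr, labs, "S1", roles, fit_residues = 1:4)
  expect_equal(prof$rmsf_A[5], a, tolerance = 1e-8)
  expect_lt(max(prof$rmsf_A[-5]), 1e-8)

  # Static frames: identically zero.
  tr0 <- traj_from_matrix(matrix(rep(as.numeric(t(base)), 4), 4, byrow = TRUE))
  prof0 <- rmsf_by_state(tr0, labels_from_states(rep("S1", 4)), "S1", roles,
                         fit_residues = 1:4)
  expect_lt(max(prof0$rmsf_A), 1e-12)

  # Two trajectories with equal per-trajectory RMSF pool to the same value.
  pooled <- rmsf_by_state(list(tr, tr), list(labs, labs), "S1", roles,
                          fit_residues = 1:4)
  expect_equal(pooled$rmsf_A, prof$rmsf_A, tolerance = 1e-10)

  expect_error(rmsf_by_state(tr, labs, "S2_OZ", roles, fit_residues = 1:4),
               "S2_OZ")
})

test_that("RMSF is invariant under global rigid motion of every frame", {
  set.seed(43)
  sim <- small_sim(n_frames = 40)
  roles <- resolve_roles(sim$structure)
  labs <- labels_from_states(sim$truth$state)
  st <- sim$truth$state[1]
  base_prof <- rmsf_by_state(sim$trajectory, labs, st, roles)
  X <- sim$trajectory$coords
  n <- ncol(X) / 3
  for (f in seq_len(nrow(X))) {
    R <- random_rotation(); tt <- rnorm(3, sd = 20)
    m <- matrix(X[f, ], ncol = 3, byrow = TRUE) %*% R +
      matrix(tt, n, 3, byrow = TRUE)
    X[f, ] <- as.numeric(t(m))
  }
  prof2 <- rmsf_by_state(traj_from_matrix(X), labs, st, roles)
  expect_equal(prof2$rmsf_A, base_prof$rmsf_A, tolerance = 1e-8)
})

test_that("state-1 switch fluctuations exceed the core in the generator", {
  spec <- synthetic_spec("solution_WT", n_frames = 300, tau = 20, seed = 44,
                         pi = c(S1 = 1, S2_OX = 0, S2_OY = 0, S2_OZ = 0,
                                UNASSIGNED = 0), ions = FALSE)
  sim <- generate_trajectory(spec)
  roles <- resolve_roles(sim$structure)
  prof <- rmsf_by_state(sim$trajectory, labels_from_states(sim$truth$state),
                        "S1", roles)
  sw <- switch_residues()
  si_mean <- mean(prof$rmsf_A[prof$resno %in% sw$si])
  core_mean <- mean(prof$rmsf_A[prof$resno %in% core_residues()])
  expect_gt(si_mean, core_mean)
})

test_that("PCA: rank-1 motion, trace identity, flat spectrum for iid noise", {
  n_res <- 8
  base <- rbind(anchors, matrix(c(8, 0, 0, 0, 8, 0, 0, 0, 8, 8, 8, 8),
                                4, 3, byrow = TRUE))
  roles <- ca_only_roles(n_res)
  dvec <- rep(0, 24)
  dvec[13:24] <- rnorm(12)          # displace residues 5:8 only
  dvec <- dvec / sqrt(sum(dvec^2))
  amp <- seq(-1, 1, length.out = 9)
  X <- t(vapply(amp, function(t) as.numeric(t(base)) + t * dvec,
                numeric(24)))
  p <- pca_ca(traj_from_matrix(X), roles, fit_residues = 1:4, n_modes = 10)
  expect_gt(p$values[1], 0)
  expect_lt(p$values[2] / p$values[1], 1e-12)
  expect_gt(abs(sum(p$vectors[, 1] * dvec)), 1 - 1e-8)
  # Orthonormality and the covariance-trace identity.
  G <- crossprod(p$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_equal(p$eigenvalue_sum, p$total_variance,
               tolerance = 1e-6)
  # Zero eigenvector components give zero mobility.
  m1 <- p$mobility[p$mobility$mode == 1, ]
  expect_lt(max(m1$mobility_A[1:4]), 1e-9)

  # Isotropic iid noise on 20 residues: leading eigenvalues flat within the
  # Marchenko-Pastur spread of a 60-dof sample covariance.
  set.seed(45)
  sigma <- 0.5; nf <- 3000; n_noisy <- 20
  base2 <- rbind(anchors, matrix(rnorm(3 * n_noisy, sd = 6), n_noisy, 3))
  X2 <- matrix(rep(as.numeric(t(base2)), nf), nf, byrow = TRUE)
  X2[, 13:ncol(X2)] <- X2[, 13:ncol(X2)] +
    rnorm(nf * 3 * n_noisy, sd = sigma)
  p2 <- pca_ca(traj_from_matrix(X2), ca_only_roles(4 + n_noisy),
               fit_residues = 1:4, n_modes = 10)
  edge <- (1 + sqrt(3 * n_noisy / nf))^2
  expect_true(all(p2$values[1:10] / sigma^2 < edge * 1.1))
  expect_true(all(p2$values[1:10] / sigma^2 > 0.7))
  expect_error(pca_ca(traj_from_matrix(X2[1, , drop = FALSE]),
                      ca_only_roles(4 + n_noisy), fit_residues = 1:4),
               "at least 2")
})

test_that("DCCM: exact +-1 constructions, naive oracle, sampling bound", {
  n_res <- 6
  base <- rbind(anchors, c(9, 0, 0), c(0, 9, 0))
  roles <- ca_only_roles(n_res)
  nf <- 40
  set.seed(46)

  # Identical translation of every residue, superposition disabled: all 1.
  shift <- rnorm(nf)
  X <- matrix(rep(as.numeric(t(base)), nf), nf, byrow = TRUE)
  X[, seq(1, 18, by = 3)] <- X[, seq(1, 18, by = 3)] + shift
  C1 <- cross_correlation(traj_from_matrix(X), roles, do_superpose = FALSE)
  expect_lt(max(abs(unclass(C1) - 1)), 1e-10)

  # Residues 5 and 6 in exact opposition (others static -> warned zeros).
  X2 <- matrix(rep(as.numeric(t(base)), nf), nf, byrow = TRUE)
  u <- c(1, 2, -1) / sqrt(6)
  amp <- rnorm(nf)
  X2[, 13:15] <- X2[, 13:15] + outer(amp, u)
  X2[, 16:18] <- X2[, 16:18] - outer(amp, u)
  expect_warning(
    C2 <- cross_correlation(traj_from_matrix(X2), roles,
                            do_superpose = FALSE),
    "zero variance")
  expect_equal(C2[5, 6], -1, tolerance = 1e-10)
  expect_equal(C2[1, 5], 0)
  expect_equal(diag(unclass(C2)), rep(1, n_res), ignore_attr = TRUE)

  # Naive double-loop oracle on random motion.
  X3 <- matrix(rep(as.numeric(t(base)), nf), nf, byrow = TRUE) +
    matrix(rnorm(nf * 18, sd = 0.7), nf)
  C3 <- cross_correlation(traj_from_matrix(X3), roles, do_superpose = FALSE)
  D <- sweep(X3, 2, colMeans(X3))
  naive <- matrix(0, n_res, n_res)
  for (i in 1:n_res) for (j in 1:n_res) {
    di <- D[, (3 * i - 2):(3 * i)]; dj <- D[, (3 * j - 2):(3 * j)]
    naive[i, j] <- mean(rowSums(di * dj)) /
      sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
  }
  expect_equal(unclass(C3), naive, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(C3)))
  expect_true(all(abs(unclass(C3)) <= 1))

  # Independent motions: off-diagonals shrink as 1/sqrt(frames).
  nf2 <- 2000
  X4 <- matrix(rep(as.numeric(t(base)), nf2), nf2, byrow = TRUE) +
    matrix(rnorm(nf2 * 18, sd = 0.5), nf2)
  C4 <- cross_correlation(traj_from_matrix(X4), roles, do_superpose = FALSE)
  off <- abs(unclass(C4)[upper.tri(C4)])
  expect_gte(mean(off < 3 / sqrt(nf2)), 0.95)
  expect_lt(max(off), 4.5 / sqrt(nf2))
})
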