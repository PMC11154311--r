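# Per-(sub)state ensemble statistics on the Calpha trace: superposition,
# RMSD, time-weighted RMSF, essential-dynamics PCA and the dynamic
# cross-correlation matrix.

#' Default switch-region residue ranges
#'
#' Switch I and switch II of the Ras G-domain, standard literature ranges.
#' @return Named list with integer vectors `si` and `sii`.
#' @export
switch_residues <- function() list(si = 30:40, sii = 58:76)

#' Default superposition fit set: the stable G-domain core
#'
#' Calpha residues of the G-domain excluding switch I and switch II. The
#' core stays within ~1 A of the crystal structure across states while the
#' switches move by several Angstrom; fitting on the core keeps switch
#' motion from leaking into core fluctuations.
#'
#' @param resno Residue numbers of the trace (default 1:165).
#' @param switches Switch ranges, see [switch_residues()].
#' @return Integer vector of residue numbers.
#' @export
core_residues <- function(resno = 1:165, switches = switch_residues()) {
  setdiff(resno, c(switches$si, switches$sii))
}

# Optimal rotation (Kabsch, SVD) mapping centered row-vector set P onto Q.
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superposition of two coordinate sets
#'
#' Finds the rigid transform (rotation + translation) minimising the RMSD of
#' `mobile` onto `reference` over the `fit` subset, then reports the RMSD
#' over the `report` subset (default: the fit subset) after applying it.
#'
#' @param mobile,reference N x 3 coordinate matrices (equal N).
#' @param fit Integer row indices used for the fit (default all rows).
#' @param report Integer row indices over which the RMSD is reported.
#' @return List with `rotation` (3 x 3), `translation` (length 3, applied
#'   after rotation), `xyz` (transformed mobile) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference, fit = seq_len(nrow(mobile)),
                      report = fit) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            nrow(mobile) == nrow(reference), ncol(mobile) == 3)
  if (length(fit) < 3) abort("superposition needs at least 3 fit points")
  Pf <- mobile[fit, , drop = FALSE]
  Qf <- reference[fit, , drop = FALSE]
  Pc <- sweep(Pf, 2, colMeans(Pf))
  if (svd(Pc)$d[2] < 1e-8) {
    abort("superposition fit points are collinear or coincident")
  }
  R <- kabsch_rotation(Pc, sweep(Qf, 2, colMeans(Qf)))
  tr <- colMeans(Qf) - colMeans(Pf) %*% R
  xyz <- mobile %*% R + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  dev <- xyz[report, , drop = FALSE] - reference[report, , drop = FALSE]
  list(rotation = R, translation = as.numeric(tr), xyz = xyz,
       rmsd = sqrt(mean(rowSums(dev^2))))
}

# Calpha sub-trajectory: frames x 3n matrix restricted to trace atoms.
ca_matrix <- function(traj, roles) {
  cols <- as.vector(vapply(roles$ca_trace,
                           function(i) c(3L * i - 2L, 3L * i - 1L, 3L * i),
                           integer(3)))
  traj$coords[, cols, drop = FALSE]
}

resno_cols <- function(resno, trace_resno) {
  pos <- match(resno, trace_resno)
  if (any(is.na(pos))) {
    abort(paste0("residues absent from the Calpha trace: ",
                 paste(resno[is.na(pos)], collapse = ", ")))
  }
  as.vector(vapply(pos, function(i) c(3L * i - 2L, 3L * i - 1L, 3L * i),
                   integer(3)))
}

# Superpose every row of X (frames x 3n) onto the reference conformation
# (length 3n), fitting on fit_cols. Lean inner loop: with both fit sets
# centered the Kabsch cross-matrix reduces to crossprod, so each frame costs
# one 3x3 SVD.
superpose_frames <- function(X, ref, fit_cols) {
  refm <- matrix(ref, ncol = 3, byrow = TRUE)
  fit_rows <- unique((fit_cols[seq(1, length(fit_cols), 3)] + 2L) %/% 3L)
  Qf <- refm[fit_rows, , drop = FALSE]
  qc <- colMeans(Qf)
  Qc <- sweep(Qf, 2, qc)
  out <- X
  for (f in seq_len(nrow(X))) {
    m <- matrix(X[f, ], ncol = 3, byrow = TRUE)
    Pf <- m[fit_rows, , drop = FALSE]
    pc <- colMeans(Pf)
    s <- svd(crossprod(Pf, Qc))   # == crossprod(centered Pf, Qc)
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    shift <- qc - as.numeric(pc %*% R)
    out[f, ] <- as.numeric(t(m %*% R + matrix(shift, nrow(m), 3,
                                              byrow = TRUE)))
  }
  out
}

# Two-pass mean structure: fit everything to the first frame, average,
# refit to that average, average again.
fit_to_mean <- function(X, fit_cols, iterate = FALSE, tol = 1e-6,
                        max_iter = 20) {
  X1 <- superpose_frames(X, X[1, ], fit_cols)
  mean1 <- colMeans(X1)
  X2 <- superpose_frames(X, mean1, fit_cols)
  mean2 <- colMeans(X2)
  if (iterate) {
    for (k in seq_len(max_iter)) {
      if (sqrt(mean((mean2 - mean1)^2)) < tol) break
      mean1 <- mean2
      X2 <- superpose_frames(X, mean1, fit_cols)
      mean2 <- colMeans(X2)
    }
  }
  list(X = X2, mean = mean2)
}

#' Per-frame RMSD to a reference structure
#'
#' Each frame is superposed on the reference over the fit residues, then the
#' Calpha RMSD is computed over the report residues (default: the fit set),
#' e.g. core-fitted switch-region RMSD against a crystal reference.
#'
#' @param traj A `ras_trajectory`.
#' @param roles A `ras_roles` map for `traj`.
#' @param reference Reference Calpha coordinates: a `ras_structure` sharing
#'   `traj`'s atom layout, or an n x 3 matrix over the trace residues.
#' @param fit_residues Residue numbers fitted on (default: G-domain core).
#' @param report_residues Residue numbers reported on.
#' @return Tibble with columns `frame`, `rmsd_A`.
#' @export
rmsd_series <- function(traj, roles, reference,
                        fit_residues = core_residues(roles$ca_resno),
                        report_residues = fit_residues) {
  X <- ca_matrix(traj, roles)
  ref <- if (inherits(reference, "ras_structure")) {
    as.numeric(t(reference$xyz[roles$ca_trace, , drop = FALSE]))
  } else if (is.matrix(reference)) {
    as.numeric(t(reference))
  } else {
    abort("reference must be a ras_structure or an n x 3 matrix")
  }
  if (length(ref) != ncol(X)) abort("reference size does not match trace")
  refm <- matrix(ref, ncol = 3, byrow = TRUE)
  fit_rows <- match(fit_residues, roles$ca_resno)
  rep_rows <- match(report_residues, roles$ca_resno)
  if (any(is.na(fit_rows)) || any(is.na(rep_rows))) {
    abort("fit/report residues must lie within the Calpha trace")
  }
  r <- vapply(seq_len(nrow(X)), function(f) {
    superpose(matrix(X[f, ], ncol = 3, byrow = TRUE), refm,
              fit = fit_rows, report = rep_rows)$rmsd
  }, numeric(1))
  tibble(frame = seq_len(nrow(X)), rmsd_A = r)
}

pool_state_frames <- function(traj, labels, state, roles) {
  if (inherits(traj, "ras_trajectory")) traj <- list(traj)
  if (inherits(labels, "ras_labels")) labels <- list(labels)
  stopifnot(length(traj) == length(labels))
  parts <- purrr::map2(traj, labels, function(tr, lb) {
    stopifnot(tr$n_frames == nrow(lb))
    keep <- if (is.null(state)) rep(TRUE, nrow(lb)) else lb$label == state
    ca_matrix(tr, roles)[keep, , drop = FALSE]
  })
  X <- do.call(rbind, parts)
  if (nrow(X) == 0) {
    abort(paste0("no frames carry state ", state %||% "<all>"))
  }
  X
}

#' Time-weighted per-residue Calpha RMSF for one (sub)state
#'
#' Pools the frames carrying `state` across one or several trajectories
#' (weighting by frame count is implicit in the pooling), superposes them on
#' the pooled mean structure (two-pass: fit to the first frame, average,
#' refit to the mean) and reports, per trace residue,
#' `sqrt(mean(|r_i - <r_i>|^2))`.
#'
#' @param traj A `ras_trajectory` or list of them.
#' @param labels Matching `ras_labels` (or list).
#' @param state One of [state_levels()], or `NULL` for all frames.
#' @param roles A `ras_roles` map (shared atom layout).
#' @param fit_residues Residues superposed on (default: G-domain core).
#' @param iterate_mean Iterate the mean-structure fit to convergence instead
#'   of stopping after the second pass.
#' @return A `ras_rmsf` tibble with columns `resno`, `rmsf_A`, `state`;
#'   attributes `n_frames`, `n_trajectories`.
#' @export
rmsf_by_state <- function(traj, labels, state, roles,
                          fit_residues = core_residues(roles$ca_resno),
                          iterate_mean = FALSE) {
  if (!is.null(state) && !state %in% STATE_LEVELS) {
    abort(paste0("unknown state: ", state))
  }
  X <- pool_state_frames(traj, labels, state, roles)
  if (nrow(X) < 2) {
    abort(paste0("need at least 2 frames of state ", state %||% "<all>",
                 " for an RMSF"))
  }
  fit_cols <- resno_cols(fit_residues, roles$ca_resno)
  fm <- fit_to_mean(X, fit_cols, iterate = iterate_mean)
  dev2 <- sweep(fm$X, 2, fm$mean)^2
  n <- length(roles$ca_resno)
  msf <- vapply(seq_len(n), function(i) {
    mean(rowSums(dev2[, c(3L * i - 2L, 3L * i - 1L, 3L * i), drop = FALSE]))
  }, numeric(1))
  out <- tibble(resno = roles$ca_resno, rmsf_A = sqrt(msf),
                state = state %||% "ALL")
  attr(out, "n_frames") <- nrow(X)
  attr(out, "n_trajectories") <- if (inherits(traj, "ras_trajectory")) 1L else length(traj)
  class(out) <- c("ras_rmsf", class(out))
  out
}

#' Essential-dynamics PCA of the Calpha trace
#'
#' Superposes the selected frames on their mean (two-pass), forms the 3N x
#' 3N covariance of Calpha coordinates and eigendecomposes it. By default
#' the analysis runs on the pooled frames of a single (sub)state; pass
#' `state = NULL` (and no labels) for whole-trajectory PCA. Per-residue
#' mobility of a mode is `sqrt(eigenvalue) * |residue 3-vector of the
#' eigenvector|`, in Angstrom.
#'
#' @inheritParams rmsf_by_state
#' @param n_modes Number of leading modes retained (default 10).
#' @param mobility_modes Modes for which per-residue mobility is tabulated
#'   (default first 3).
#' @return A `ras_pca` object: `values` (eigenvalues, A^2, descending),
#'   `vectors` (3N x n_modes, orthonormal), `mobility` (tibble: `resno`,
#'   `mode`, `mobility_A`), `total_variance` (covariance trace), `n_frames`,
#'   `resno`, `state`. Has [tidy()] and [glance()] methods.
#' @export
pca_ca <- function(traj, roles, labels = NULL, state = NULL,
                   fit_residues = core_residues(roles$ca_resno),
                   n_modes = 10, mobility_modes = 1:3) {
  X <- if (is.null(labels)) {
    pool_state_frames(traj, make_null_labels(traj), NULL, roles)
  } else {
    pool_state_frames(traj, labels, state, roles)
  }
  if (nrow(X) < 2) abort("PCA needs at least 2 frames")
  fm <- fit_to_mean(X, resno_cols(fit_residues, roles$ca_resno))
  D <- sweep(fm$X, 2, fm$mean)
  C <- crossprod(D) / (nrow(D) - 1)
  eig <- eigen(C, symmetric = TRUE)
  nm <- min(n_modes, ncol(C))
  vals <- pmax(eig$values, 0)
  mobility_modes <- mobility_modes[mobility_modes <= nm]
  n <- length(roles$ca_resno)
  mob <- purrr::map_dfr(mobility_modes, function(m) {
    v <- eig$vectors[, m]
    tibble(resno = roles$ca_resno, mode = m,
           mobility_A = sqrt(vals[m]) *
             vapply(seq_len(n), function(i) {
               sqrt(sum(v[c(3L * i - 2L, 3L * i - 1L, 3L * i)]^2))
             }, numeric(1)))
  })
  structure(
    list(values = vals[seq_len(nm)],
         vectors = eig$vectors[, seq_len(nm), drop = FALSE],
         mobility = mob,
         total_variance = sum(diag(C)),
         eigenvalue_sum = sum(vals),
         n_frames = nrow(X),
         resno = roles$ca_resno,
         state = state %||% "ALL"),
    class = "ras_pca"
  )
}

make_null_labels <- function(traj) {
  if (inherits(traj, "ras_trajectory")) traj <- list(traj)
  lapply(traj, function(tr) {
    tibble(frame = seq_len(tr$n_frames),
           raw_label = "S1", label = "S1")
  })
}

#' @export
print.ras_pca <- function(x, ...) {
  vf <- x$values / max(x$eigenvalue_sum, .Machine$double.eps)
  cat("<ras_pca> state ", x$state, ": ", x$n_frames, " frames, ",
      length(x$values), " modes; variance captured by first 3: ",
      sprintf("%.1f%%", 100 * sum(vf[seq_len(min(3, length(vf)))])),
      "\n", sep = "")
  invisible(x)
}

#' @rdname pca_ca
#' @param x A `ras_pca` object.
#' @param ... Unused.
#' @export
tidy.ras_pca <- function(x, ...) {
  tibble(mode = seq_along(x$values),
         eigenvalue_A2 = x$values,
         variance_fraction = x$values / x$eigenvalue_sum,
         cumulative_fraction = cumsum(x$values) / x$eigenvalue_sum)
}

#' @rdname pca_ca
#' @export
glance.ras_pca <- function(x, ...) {
  tibble(n_frames = x$n_frames,
         n_modes = length(x$values),
         total_variance_A2 = x$total_variance,
         variance_first3 = sum(x$values[seq_len(min(3, length(x$values)))]) /
           x$eigenvalue_sum,
         state = x$state)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Normalized covariance of per-residue Calpha displacement vectors over
#' superposed frames: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`.
#' Residues with zero variance get row/column 0 and diagonal 1, with a
#' warning.
#'
#' @inheritParams rmsf_by_state
#' @param do_superpose Set `FALSE` to skip the superposition (e.g. to study
#'   raw lab-frame motion).
#' @return A `ras_dccm`: N x N symmetric matrix with unit diagonal, entries
#'   in \[-1, 1\], residue numbers as dimnames.
#' @export
cross_correlation <- function(traj, roles, labels = NULL, state = NULL,
                              fit_residues = core_residues(roles$ca_resno),
                              do_superpose = TRUE) {
  X <- if (is.null(labels)) {
    pool_state_frames(traj, make_null_labels(traj), NULL, roles)
  } else {
    pool_state_frames(traj, labels, state, roles)
  }
  if (nrow(X) < 2) abort("cross-correlation needs at least 2 frames")
  if (do_superpose) {
    X <- fit_to_mean(X, resno_cols(fit_residues, roles$ca_resno))$X
  }
  D <- sweep(X, 2, colMeans(X))
  n <- length(roles$ca_resno)
  ix <- seq(1L, 3L * n, 3L)
  raw <- (crossprod(D[, ix, drop = FALSE]) +
          crossprod(D[, ix + 1L, drop = FALSE]) +
          crossprod(D[, ix + 2L, drop = FALSE])) / nrow(D)
  v <- diag(raw)
  zero <- v <= .Machine$double.eps * 100
  if (any(zero)) {
    warn(paste0(sum(zero), " residue(s) with zero variance; their DCCM ",
                "rows/columns are set to 0"))
    v[zero] <- 1
  }
  C <- raw / sqrt(outer(v, v))
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(roles$ca_resno, roles$ca_resno)
  class(C) <- c("ras_dccm", class(C))
  C
}
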