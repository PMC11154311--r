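# Per-frame geometric features: the five classifier distances and the two
# membrane reaction coordinates.

#' Pairwise distance with optional minimum-image correction
#'
#' Euclidean distance between two points (Angstrom); if an orthorhombic box
#' is supplied, each Cartesian displacement component is wrapped to the
#' nearest periodic image first.
#'
#' @param a,b Numeric length-3 coordinates, or matrices with 3 columns
#'   (row-wise distances).
#' @param box Optional length-3 box edge lengths (Angstrom).
#' @return Distance(s) in Angstrom.
#' @export
#' @examples
#' pair_distance(c(0, 0, 0), c(0, 0, 2))
#' pair_distance(c(0, 0, 0), c(0, 0, 9), box = c(10, 10, 10))
pair_distance <- function(a, b, box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- a - b
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    d <- d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
  }
  out <- sqrt(rowSums(d^2))
  if (length(out) == 1) out[[1]] else out
}

# Distance series between two atoms across all frames of a trajectory.
atom_pair_series <- function(traj, i, j, box = NULL) {
  pair_distance(traj_atom(traj, i), traj_atom(traj, j), box = box)
}

#' Angle between the beta1-sheet direction and the membrane normal
#'
#' The beta1 direction is the first principal axis of the four Calpha
#' positions of residues 2-5, oriented from the smallest-numbered residue
#' toward the largest (for collinear points this reduces to the simple
#' Calpha(2) to Calpha(5) vector). The angle to `normal` is reported in
#' degrees in \[0, 180\].
#'
#' @param ca Numeric 4 x 3 matrix of Calpha positions, ordered by residue.
#' @param normal Membrane normal (defaults to the laboratory +z axis, the
#'   bilayer-in-xy convention); need not be unit length.
#' @return Angle in degrees.
#' @export
beta1_angle <- function(ca, normal = c(0, 0, 1)) {
  stopifnot(is.matrix(ca), nrow(ca) == 4, ncol(ca) == 3)
  cen <- sweep(ca, 2, colMeans(ca))
  if (all(abs(cen) < 1e-12)) {
    abort("degenerate beta1 geometry: all four Calpha positions coincide")
  }
  ax <- svd(cen, nu = 0, nv = 1)$v[, 1]
  if (sum(ax * (ca[4, ] - ca[1, ])) < 0) ax <- -ax
  cosang <- sum(ax * normal) / (sqrt(sum(ax^2)) * sqrt(sum(normal^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Extract per-frame features from a trajectory
#'
#' Computes, for every frame, the five characteristic distances that define
#' the conformational (sub)states -- O12--Ogamma, OH32--O18, OG35--Mg,
#' OH32--Ogamma, OH32--OH40 -- plus the two membrane reaction coordinates:
#' the beta1-sheet tilt angle against the membrane normal and the E132--L184
#' Calpha distance (`NA` for solution-only systems without an HVR).
#'
#' @param traj A `ras_trajectory`.
#' @param roles A `ras_roles` map from [resolve_roles()].
#' @param membrane_normal Membrane normal vector (default laboratory +z).
#' @param box Optional periodic box; defaults to the trajectory's own.
#' @return A `ras_features` tibble with columns `frame`, `time_ns`,
#'   `d_O12_Og`, `d_OH32_O18`, `d_OG35_Mg`, `d_OH32_Og`, `d_OH32_OH40`
#'   (Angstrom), `rc_angle_deg`, `rc_dist_A`.
#' @export
extract_features <- function(traj, roles, membrane_normal = c(0, 0, 1),
                             box = traj$box) {
  stopifnot(inherits(traj, "ras_trajectory"), inherits(roles, "ras_roles"))
  nf <- traj$n_frames
  b1 <- traj$coords[, as.vector(vapply(roles$beta1_ca,
                                       function(i) c(3L * i - 2L, 3L * i - 1L, 3L * i),
                                       integer(3))), drop = FALSE]
  rc_angle <- vapply(seq_len(nf), function(f) {
    beta1_angle(matrix(b1[f, ], 4, 3, byrow = TRUE), membrane_normal)
  }, numeric(1))
  rc_dist <- if (is.na(roles$l184_ca)) {
    rep(NA_real_, nf)
  } else {
    atom_pair_series(traj, roles$e132_ca, roles$l184_ca, box = box)
  }
  out <- tibble(
    frame = seq_len(nf),
    time_ns = traj$time_ns %||% rep(NA_real_, nf),
    d_O12_Og    = atom_pair_series(traj, roles$o12, roles$ogamma, box),
    d_OH32_O18  = atom_pair_series(traj, roles$oh32, roles$o18, box),
    d_OG35_Mg   = atom_pair_series(traj, roles$og35, roles$mg, box),
    d_OH32_Og   = atom_pair_series(traj, roles$oh32, roles$ogamma, box),
    d_OH32_OH40 = atom_pair_series(traj, roles$oh32, roles$oh40, box),
    rc_angle_deg = rc_angle,
    rc_dist_A = rc_dist
  )
  class(out) <- c("ras_features", class(out))
  out
}

feature_cols <- function() {
  c("d_O12_Og", "d_OH32_O18", "d_OG35_Mg", "d_OH32_Og", "d_OH32_OH40")
}

#' Reaction-coordinate pairs for 2D histogramming
#'
#' @param features A `ras_features` tibble from a membrane-bound system.
#' @return Tibble with columns `rc_angle_deg`, `rc_dist_A`, one row per
#'   frame.
#' @export
rc_pair <- function(features) {
  if (nrow(features) > 0 && all(is.na(features$rc_dist_A))) {
    abort("rc_dist is absent: solution-only system (no HVR/L184)")
  }
  tibble(rc_angle_deg = features$rc_angle_deg,
         rc_dist_A = features$rc_dist_A)
}

#' 2D histogram of reaction-coordinate pairs
#'
#' Bins the (angle, distance) pairs on the supplied break vectors. Pairs
#' falling outside the grid are excluded from the counts and reported in the
#' `n_out` attribute; the grid total equals the number of in-range pairs.
#'
#' @param pairs Output of [rc_pair()] (or any two-column data frame).
#' @param angle_breaks,dist_breaks Strictly increasing break vectors.
#' @return Integer matrix of counts (angle bins x distance bins) with
#'   attributes `angle_breaks`, `dist_breaks`, `n_out`.
#' @export
histogram2d <- function(pairs, angle_breaks, dist_breaks) {
  if (length(angle_breaks) < 2 || length(dist_breaks) < 2) {
    abort("need at least two breaks per axis")
  }
  if (is.unsorted(angle_breaks, strictly = TRUE) ||
      is.unsorted(dist_breaks, strictly = TRUE)) {
    abort("histogram breaks must be strictly increasing")
  }
  x <- pairs[[1]]; y <- pairs[[2]]
  keep <- !is.na(x) & !is.na(y) &
    x >= angle_breaks[1] & x <= angle_breaks[length(angle_breaks)] &
    y >= dist_breaks[1] & y <= dist_breaks[length(dist_breaks)]
  ix <- findInterval(x[keep], angle_breaks, rightmost.closed = TRUE)
  iy <- findInterval(y[keep], dist_breaks, rightmost.closed = TRUE)
  grid <- matrix(0L, length(angle_breaks) - 1L, length(dist_breaks) - 1L)
  for (k in seq_along(ix)) grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + 1L
  attr(grid, "angle_breaks") <- angle_breaks
  attr(grid, "dist_breaks") <- dist_breaks
  attr(grid, "n_out") <- sum(!keep)
  grid
}
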