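# Seeded synthetic trajectory generator.
#
# Emulates, frame by frame, the geometric signatures the classifier reads:
# a Markov state sequence with prescribed stationary occupancies and dwell
# structure, role atoms placed so the five characteristic distances follow
# per-state Gaussian distributions, a 165-residue Calpha trace with
# state-dependent switch noise (plus an HVR tail for membrane scenarios),
# and Na+ ions placed by a per-state Poisson shell model around GTP.
# Randomness is split into three substreams (states / geometry / ions) so
# that e.g. enabling ions never perturbs the state sequence.

SYNTH_STATES <- c("S1", "S2_OX", "S2_OY", "S2_OZ", "UNASSIGNED")

#' Available synthetic scenario presets
#' @return Character vector of preset names.
#' @export
scenario_presets <- function() {
  c("solution_WT", "solution_G12V", "membrane_WT", "membrane_G12V")
}

# Per-state distance means (A). Rows: the five classifier distances;
# columns: states. The UNASSIGNED column is the margin state: Thr35 bound
# (state-2-like Mg distance) but Tyr32 in an intermediate orientation
# outside all three substate signatures.
preset_dist_mean <- function(g12v = FALSE) {
  m <- rbind(
    d_O12_Og    = c(5.3, 5.3, 5.3, 5.3, 5.3),
    d_OH32_O18  = c(13.0, 13.0, 4.3, 13.0, 13.0),
    d_OG35_Mg   = c(6.0, 2.0, 2.0, 2.0, 2.0),
    d_OH32_Og   = c(13.0, 2.7, 11.3, 7.5, 12.5),
    d_OH32_OH40 = c(4.4, 11.6, 9.0, 11.6, 9.0)
  )
  colnames(m) <- SYNTH_STATES
  if (g12v) m["d_O12_Og", ] <- 8.5
  m
}

preset_dist_sd <- function() {
  s <- rbind(
    d_O12_Og    = c(0.4, 0.4, 0.4, 0.4, 0.4),
    d_OH32_O18  = c(1.0, 1.0, 0.4, 1.0, 0.4),
    d_OG35_Mg   = c(1.5, 0.15, 0.15, 0.15, 0.15),
    d_OH32_Og   = c(2.5, 0.4, 0.4, 1.0, 0.4),
    d_OH32_OH40 = c(0.8, 0.4, 0.4, 0.4, 0.4)
  )
  colnames(s) <- SYNTH_STATES
  s
}

# Reaction-coordinate presets for membrane scenarios (angle deg, dist A).
preset_rc <- function(g12v = FALSE) {
  if (!g12v) {
    list(angle_mean = c(S1 = 30, S2_OX = 45, S2_OY = 60, S2_OZ = 60,
                        UNASSIGNED = 50),
         angle_sd = c(S1 = 5, S2_OX = 10, S2_OY = 8, S2_OZ = 8,
                      UNASSIGNED = 15),
         dist_mean = c(S1 = 12, S2_OX = 20, S2_OY = 12, S2_OZ = 12,
                       UNASSIGNED = 15),
         dist_sd = c(S1 = 1.5, S2_OX = 3, S2_OY = 2, S2_OZ = 2,
                     UNASSIGNED = 4))
  } else {
    list(angle_mean = c(S1 = 90, S2_OX = 80, S2_OY = 60, S2_OZ = 60,
                        UNASSIGNED = 50),
         angle_sd = c(S1 = 22, S2_OX = 8, S2_OY = 22, S2_OZ = 8,
                      UNASSIGNED = 15),
         dist_mean = c(S1 = 20, S2_OX = 20, S2_OY = 18, S2_OZ = 12,
                       UNASSIGNED = 15),
         dist_sd = c(S1 = 5, S2_OX = 3, S2_OY = 5, S2_OZ = 2,
                     UNASSIGNED = 4))
  }
}

preset_pi <- function(scenario) {
  switch(scenario,
    # Printed occupancies 40/30/20/3 sum to 93; the 7-point shortfall is
    # emitted as the explicit UNASSIGNED margin.
    solution_WT = c(S1 = 0.40, S2_OX = 0.30, S2_OY = 0.20, S2_OZ = 0.03,
                    UNASSIGNED = 0.07),
    # 95% state 1, no state-2 substates in solution for the mutant.
    solution_G12V = c(S1 = 0.95, S2_OX = 0, S2_OY = 0, S2_OZ = 0,
                      UNASSIGNED = 0.05),
    # Printed 40/55/6/2 sum to 103; scaled proportionally.
    membrane_WT = c(S1 = 40, S2_OX = 55, S2_OY = 6, S2_OZ = 2,
                    UNASSIGNED = 0) / 103,
    # OZ never sampled by the mutant.
    membrane_G12V = c(S1 = 0.40, S2_OX = 0.10, S2_OY = 0.30, S2_OZ = 0,
                      UNASSIGNED = 0.20),
    abort(paste0("unknown scenario '", scenario, "'; presets: ",
                 paste(scenario_presets(), collapse = ", ")))
  )
}

preset_lambda <- function(scenario) {
  switch(scenario,
    solution_WT   = c(S1 = 2.53, S2_OX = 0.56, S2_OY = 0.40, S2_OZ = 0.15,
                      UNASSIGNED = 0.5),
    solution_G12V = c(S1 = 1.56, S2_OX = 0, S2_OY = 0, S2_OZ = 0,
                      UNASSIGNED = 0.5),
    membrane_WT   = c(S1 = 1.72, S2_OX = 0.42, S2_OY = 0.75, S2_OZ = 0.06,
                      UNASSIGNED = 0.5),
    membrane_G12V = c(S1 = 2.30, S2_OX = 1.23, S2_OY = 0.88, S2_OZ = 0,
                      UNASSIGNED = 0.5)
  )
}

# Switch-noise SD multipliers (applied to base_sd) per state.
preset_switch_scale <- function() {
  list(si  = c(S1 = 6, S2_OX = 2.5, S2_OY = 2.5, S2_OZ = 1.5,
               UNASSIGNED = 2.5),
       sii = c(S1 = 4, S2_OX = 2.5, S2_OY = 4, S2_OZ = 1.5,
               UNASSIGNED = 2.5))
}

#' Build a synthetic-trajectory specification
#'
#' Presets parameterize the four study conditions: wild-type and G12V, each
#' in solution and membrane-bound. Stationary occupancies, the per-state
#' distance centers and the per-state ion Poisson means come from the
#' published characterization of those systems; distance SDs, dwell time and
#' reaction-coordinate spreads are generator calibration choices (see the
#' methods vignette). Any field can be overridden.
#'
#' @param scenario One of [scenario_presets()], or `NULL` with explicit
#'   overrides.
#' @param n_frames Number of frames (default 20000).
#' @param tau Mean dwell parameter of the state Markov chain, frames.
#' @param seed Integer seed; three substreams (states, geometry, ions) are
#'   derived from it.
#' @param ... Overrides: `pi` (named stationary distribution), `dist_mean`,
#'   `dist_sd` (5 x 5 matrices, distances x states), `lambda` (named ion
#'   Poisson means), `rc` (list angle_mean/angle_sd/dist_mean/dist_sd),
#'   `switch_scale`, `base_sd`, `hvr`, `ions`, `d_og_o18` (optional named
#'   per-state Ogamma--O18 target adding a joint constraint on the O18
#'   placement), `box`.
#' @return A `ras_synth_spec` list.
#' @export
synthetic_spec <- function(scenario = NULL, n_frames = 20000L, tau = 50,
                           seed = 1L, ...) {
  g12v <- !is.null(scenario) && grepl("G12V", scenario)
  membrane <- !is.null(scenario) && grepl("membrane", scenario)
  spec <- list(
    scenario = scenario %||% "custom",
    n_frames = as.integer(n_frames),
    tau = tau,
    seed = as.integer(seed),
    pi = if (is.null(scenario)) {
      c(S1 = 0.25, S2_OX = 0.25, S2_OY = 0.25, S2_OZ = 0.25, UNASSIGNED = 0)
    } else preset_pi(scenario),
    dist_mean = preset_dist_mean(g12v),
    dist_sd = preset_dist_sd(),
    lambda = if (is.null(scenario)) {
      c(S1 = 1, S2_OX = 1, S2_OY = 1, S2_OZ = 1, UNASSIGNED = 1)
    } else preset_lambda(scenario),
    rc = preset_rc(g12v),
    switch_scale = preset_switch_scale(),
    base_sd = 0.3,
    hvr = membrane,
    ions = TRUE,
    n_shell_slots = 12L,
    n_decoys = 10L,
    d_og_o18 = NULL,
    box = c(90, 90, 90)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) {
    abort(paste0("unknown synthetic_spec field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  spec <- modifyList(spec, dots, keep.null = FALSE)
  validate_synth_spec(spec)
  structure(spec, class = "ras_synth_spec")
}

validate_synth_spec <- function(spec) {
  if (spec$n_frames < 1) abort("n_frames must be >= 1")
  if (spec$tau < 1) abort("tau must be >= 1 frame")
  if (abs(sum(spec$pi) - 1) > 1e-8) abort("pi must sum to 1")
  if (any(spec$pi < 0)) abort("pi must be non-negative")
  if (any(spec$dist_sd <= 0)) abort("all distance SDs must be positive")
  if (any(spec$lambda < 0)) abort("ion Poisson means must be >= 0")
  invisible(spec)
}

#' @export
print.ras_synth_spec <- function(x, ...) {
  cat("<ras_synth_spec> scenario ", x$scenario, ": ", x$n_frames,
      " frames, tau = ", x$tau, ", seed = ", x$seed,
      if (x$hvr) ", membrane-bound (HVR present)" else ", solution-only",
      "\n  pi: ", paste(sprintf("%s %.3f", names(x$pi), x$pi),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7L + k * 104729) %% 2147483647)
}

#' Sample a Markov state sequence with prescribed stationary occupancies
#'
#' At each step the chain stays put with probability `1 - 1/tau` and
#' otherwise redraws the state from `pi` (the current state included, so
#' `pi` is exactly the stationary distribution and the mean dwell in state i
#' is about `tau / (1 - pi_i)` frames). States with zero weight are never
#' emitted.
#'
#' @param pi Named stationary distribution over states (sums to 1).
#' @param tau Mean dwell parameter, frames (>= 1).
#' @param n_frames Sequence length.
#' @param seed Optional integer seed.
#' @return Character vector of states.
#' @export
sample_state_sequence <- function(pi, tau, n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(pi) - 1) < 1e-8, all(pi >= 0), tau >= 1)
  states <- names(pi)
  redraw <- runif(n_frames) < 1 / tau
  redraw[1] <- TRUE
  draws <- sample(states, sum(redraw), replace = TRUE, prob = pi)
  idx <- cumsum(redraw)
  draws[idx]
}

# --- atom layout -----------------------------------------------------------

amino3 <- function(resno, g12v) {
  out <- rep("ALA", length(resno))
  out[resno == 12] <- if (g12v) "VAL" else "GLY"
  out[resno == 18] <- "ALA"
  out[resno == 32] <- "TYR"
  out[resno == 35] <- "THR"
  out[resno == 40] <- "TYR"
  out[resno == 132] <- "GLU"
  out[resno == 184] <- "LEU"
  out
}

gtp_offsets <- function() {
  rbind(PG  = c(0, 0, 3.4),  O1G = c(0, 0, 2.0),
        O2G = c(-1.3, 0.8, 2.6), O3G = c(-1.3, -0.8, 2.6),
        PB  = c(1.5, 0, 4.2), O1B = c(2.4, 0.9, 3.8), O2B = c(2.4, -0.9, 3.8),
        PA  = c(3.0, 0, 5.0), O1A = c(3.9, 0.8, 4.6), O2A = c(3.9, -0.8, 4.6))
}

synth_atom_table <- function(spec) {
  g12v <- grepl("G12V", spec$scenario)
  resno <- if (spec$hvr) 1:186 else 1:165
  rows <- list()
  for (r in resno) {
    rn <- amino3(r, g12v)
    rows[[length(rows) + 1]] <- c("CA", rn, r)
    if (r %in% c(12, 18)) rows[[length(rows) + 1]] <- c("O", rn, r)
    if (r %in% c(32, 40)) rows[[length(rows) + 1]] <- c("OH", rn, r)
    if (r == 35) rows[[length(rows) + 1]] <- c("OG1", rn, r)
  }
  rows[[length(rows) + 1]] <- c("MG", "MG", 200)
  for (g in rownames(gtp_offsets())) {
    rows[[length(rows) + 1]] <- c(g, "GTP", 201)
  }
  n_na <- if (spec$ions) spec$n_shell_slots + spec$n_decoys else 0L
  for (k in seq_len(n_na)) {
    rows[[length(rows) + 1]] <- c("NA", "NA", 300 + k)
  }
  m <- do.call(rbind, rows)
  tibble(
    serial = seq_len(nrow(m)),
    name = m[, 1],
    resname = m[, 2],
    resno = as.integer(m[, 3]),
    chain = "A",
    element = dplyr::case_when(
      m[, 1] == "MG" ~ "MG",
      m[, 2] == "NA" ~ "NA",
      substr(m[, 1], 1, 1) == "P" ~ "P",
      substr(m[, 1], 1, 1) == "O" ~ "O",
      TRUE ~ "C"
    )
  )
}

# Template Calpha curve, beta1 (residues 2-5) aligned with +z.
synth_template_trace <- function(n_res) {
  r <- seq_len(n_res)
  raw <- cbind(1.4 * r, 7 * sin(r / 7), 7 * cos(r / 11))
  b1 <- raw[2:5, , drop = FALSE]
  cen <- sweep(b1, 2, colMeans(b1))
  ax <- svd(cen, nu = 0, nv = 1)$v[, 1]
  if (sum(ax * (raw[5, ] - raw[2, ])) < 0) ax <- -ax
  # Rotation taking ax -> +z (Rodrigues).
  z <- c(0, 0, 1)
  v <- c(ax[2] * z[3] - ax[3] * z[2], ax[3] * z[1] - ax[1] * z[3],
         ax[1] * z[2] - ax[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(ax * z)
  R <- if (s < 1e-12) diag(3) * sign(cth) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  sweep(raw, 2, colMeans(raw)) %*% t(R)
}

rnorm_pos <- function(n, mean, sd, lower = 0.5) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

runit <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Unit directions for the OH32 placement, rejected until OH32 is strictly
# closer to O1G than to O2G/O3G (so the gamma-oxygen role binding is stable
# for every sampled distance).
runit_oh32 <- function(n) {
  off <- gtp_offsets()
  c2 <- off["O2G", ] - off["O1G", ]
  c3 <- off["O3G", ] - off["O1G", ]
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  while (length(need) > 0) {
    u <- runit(length(need) * 2L)
    ok <- (u %*% c2 <= 0) & (u %*% c3 <= 0)
    u <- u[ok[, 1], , drop = FALSE]
    take <- min(nrow(u), length(need))
    if (take > 0) {
      out[need[seq_len(take)], ] <- u[seq_len(take), , drop = FALSE]
      need <- need[-seq_len(take)]
    }
  }
  out
}

#' Emit synthetic frames for a given state sequence
#'
#' Deterministic geometric construction per frame (given the geometry
#' substream): Mg at the origin of the role cluster, the GTP gamma oxygen at
#' a fixed 2.0 A coordination offset, OG35 along +x at its sampled Mg
#' distance, and OH32 / O18 / O12 / OH40 placed by spherical sampling at
#' their sampled distances (with rejection keeping the gamma-oxygen role
#' binding unambiguous). When the spec carries a joint `d_og_o18` target the
#' O18 placement solves both sphere constraints and an infeasible
#' combination raises a triangle-inequality error. The Calpha trace is a
#' fixed template curve with per-state switch noise, rotated per frame to
#' the sampled membrane tilt for membrane scenarios.
#'
#' @param spec A `ras_synth_spec`.
#' @param states Character vector of per-frame states.
#' @return List: `coords` (frames x 3N), `atoms` (atom table),
#'   `dist_truth` (tibble of the sampled target distances).
#' @export
emit_frames <- function(spec, states) {
  nf <- length(states)
  atoms <- synth_atom_table(spec)
  natom <- nrow(atoms)
  si <- switch_residues()
  mu <- spec$dist_mean; sg <- spec$dist_sd
  sidx <- match(states, SYNTH_STATES)

  # Sampled target distances, per frame.
  dmat <- vapply(rownames(mu), function(d) {
    rnorm_pos(nf, mu[d, sidx], sg[d, sidx])
  }, numeric(nf))
  if (nf == 1) dmat <- matrix(dmat, 1, dimnames = list(NULL, rownames(mu)))

  cluster_origin <- c(30, 0, 0)  # keep the role cluster clear of the trace
  mg <- matrix(cluster_origin, nf, 3, byrow = TRUE)
  off <- gtp_offsets()
  ogamma <- sweep(mg, 2, off["O1G", ], `+`)
  og35 <- mg + cbind(dmat[, "d_OG35_Mg"], 0, 0)
  u1 <- runit_oh32(nf)
  oh32 <- ogamma + u1 * dmat[, "d_OH32_Og"]
  o18 <- place_o18(spec, states, oh32, ogamma, dmat)
  o12 <- ogamma + runit(nf) * dmat[, "d_O12_Og"]
  oh40 <- oh32 + runit(nf) * dmat[, "d_OH32_OH40"]

  # Calpha trace with per-state switch noise.
  n_res <- if (spec$hvr) 186L else 165L
  tmpl <- synth_template_trace(n_res)
  sd_res <- matrix(spec$base_sd, nf, n_res)
  sd_res[, si$si] <- spec$base_sd * spec$switch_scale$si[sidx]
  sd_res[, si$sii] <- spec$base_sd * spec$switch_scale$sii[sidx]
  theta <- if (spec$hvr) {
    pmin(180, pmax(0, rnorm(nf, spec$rc$angle_mean[sidx],
                            spec$rc$angle_sd[sidx]))) * pi / 180
  } else {
    rep(0, nf)
  }
  ct <- cos(theta); st <- sin(theta)

  coords <- matrix(NA_real_, nf, 3L * natom)
  put <- function(idx, m3) {
    coords[, 3L * idx - 2L] <<- m3[, 1]
    coords[, 3L * idx - 1L] <<- m3[, 2]
    coords[, 3L * idx] <<- m3[, 3]
  }
  at_name <- atoms$name; at_resno <- atoms$resno; at_resname <- atoms$resname
  is_ca <- at_name == "CA" & at_resname != "NA"
  for (r in seq_len(n_res)) {
    i <- which(is_ca & at_resno == r)
    p <- tmpl[r, ]
    # Tilt rotation about the x-axis, then Gaussian jitter.
    put(i, cbind(p[1] + rnorm(nf, 0, sd_res[, r]),
                 p[2] * ct - p[3] * st + rnorm(nf, 0, sd_res[, r]),
                 p[2] * st + p[3] * ct + rnorm(nf, 0, sd_res[, r])))
  }
  # HVR stretch: L184 re-placed at the sampled E132 distance.
  if (spec$hvr) {
    i132 <- which(is_ca & at_resno == 132L)
    i184 <- which(is_ca & at_resno == 184L)
    e132 <- coords[, c(3L * i132 - 2L, 3L * i132 - 1L, 3L * i132)]
    dd <- rnorm_pos(nf, spec$rc$dist_mean[sidx], spec$rc$dist_sd[sidx])
    put(i184, e132 + runit(nf) * dd)
  }
  put(which(at_name == "MG"), mg)
  for (g in rownames(off)) {
    put(which(at_name == g & at_resname == "GTP"),
        sweep(mg, 2, off[g, ], `+`))
  }
  put(which(at_name == "OG1" & at_resno == 35L), og35)
  put(which(at_name == "OH" & at_resno == 32L), oh32)
  put(which(at_name == "OH" & at_resno == 40L), oh40)
  put(which(at_name == "O" & at_resno == 12L), o12)
  put(which(at_name == "O" & at_resno == 18L), o18)

  list(coords = coords, atoms = atoms,
       dist_truth = as_tibble(as.data.frame(dmat)) |>
         dplyr::mutate(frame = seq_len(nf), state = states,
                       .before = 1))
}

place_o18 <- function(spec, states, oh32, ogamma, dmat) {
  nf <- nrow(oh32)
  rA <- dmat[, "d_OH32_O18"]
  joint <- spec$d_og_o18
  if (is.null(joint)) {
    return(oh32 + runit(nf) * rA)
  }
  rB <- unname(joint[states])
  free <- is.na(rB)
  out <- matrix(NA_real_, nf, 3)
  if (any(free)) out[free, ] <- oh32[free, , drop = FALSE] +
      runit(sum(free)) * rA[free]
  if (all(free)) return(out)
  ab <- ogamma - oh32
  dab <- sqrt(rowSums(ab^2))
  bad <- which(!free & (dab > rA + rB | dab < abs(rA - rB)))
  if (length(bad)) {
    abort(paste0("infeasible O18 placement at frame ", bad[1],
                 ": triangle inequality violated for |OH32-Og| = ",
                 sprintf("%.2f", dab[bad[1]]), " A with d_OH32_O18 = ",
                 sprintf("%.2f", rA[bad[1]]), " A and d_Og_O18 = ",
                 sprintf("%.2f", rB[bad[1]]), " A"))
  }
  con <- which(!free)
  x <- (dab[con]^2 + rA[con]^2 - rB[con]^2) / (2 * dab[con])
  rad <- sqrt(pmax(0, rA[con]^2 - x^2))
  e1 <- ab[con, , drop = FALSE] / dab[con]
  # Orthonormal in-plane basis, then a uniform angle on the circle.
  ref <- matrix(rep(c(0, 0, 1), length(con)), ncol = 3, byrow = TRUE)
  swap <- abs(rowSums(e1 * ref)) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), sum(swap)), ncol = 3, byrow = TRUE)
  e2 <- ref - e1 * rowSums(e1 * ref)
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  phi <- runif(length(con), 0, 2 * pi)
  out[con, ] <- oh32[con, , drop = FALSE] + e1 * x +
    e2 * (rad * cos(phi)) + e3 * (rad * sin(phi))
  out
}

place_ions <- function(spec, states, coords, atoms) {
  nf <- length(states)
  lam <- spec$lambda[match(states, SYNTH_STATES)]
  k <- pmin(rpois(nf, lam), spec$n_shell_slots)
  off <- gtp_offsets()
  gtp_abs <- sweep(off, 2, c(30, 0, 0), `+`)
  centroid <- colMeans(gtp_abs)
  na_idx <- which(atoms$resname == "NA")
  n_na <- length(na_idx)
  for (f in seq_len(nf)) {
    pos <- matrix(NA_real_, n_na, 3)
    if (k[f] > 0) {
      anchor <- gtp_abs[sample.int(nrow(gtp_abs), k[f], replace = TRUE), ,
                        drop = FALSE]
      pos[seq_len(k[f]), ] <- anchor +
        runit(k[f]) * runif(k[f], 1.5, 4.4)
    }
    n_far <- n_na - k[f]
    pos[(k[f] + 1):n_na, ] <- matrix(centroid, n_far, 3, byrow = TRUE) +
      runit(n_far) * runif(n_far, 13, 20)
    cols <- as.vector(vapply(na_idx,
                             function(i) c(3L * i - 2L, 3L * i - 1L, 3L * i),
                             integer(3)))
    coords[f, cols] <- as.numeric(t(pos))
  }
  list(coords = coords, shell_count = k)
}

#' Generate a full synthetic trajectory
#'
#' Runs the three seeded substreams -- state sequence, frame geometry, ion
#' placement -- and assembles an in-memory dataset.
#'
#' @param spec A [synthetic_spec()].
#' @return A `ras_synth` list: `structure` (a `ras_structure` built from
#'   frame 1), `trajectory` (`ras_trajectory`), `truth` (tibble: `frame`,
#'   `state`, `shell_ions`), `dist_truth`, `spec`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "ras_synth_spec"))
  states <- sample_state_sequence(spec$pi, spec$tau, spec$n_frames,
                                  seed = substream_seed(spec$seed, 1L))
  set.seed(substream_seed(spec$seed, 2L))
  em <- emit_frames(spec, states)
  shell <- rep(NA_integer_, spec$n_frames)
  if (spec$ions) {
    set.seed(substream_seed(spec$seed, 3L))
    pl <- place_ions(spec, states, em$coords, em$atoms)
    em$coords <- pl$coords
    shell <- pl$shell_count
  }
  struct <- structure(
    list(atoms = em$atoms,
         xyz = matrix(em$coords[1, ], ncol = 3, byrow = TRUE),
         box = spec$box),
    class = "ras_structure"
  )
  structure(
    list(structure = struct,
         trajectory = new_trajectory(em$coords, box = spec$box),
         truth = tibble(frame = seq_len(spec$n_frames), state = states,
                        shell_ions = shell),
         dist_truth = em$dist_truth,
         spec = spec),
    class = "ras_synth"
  )
}

#' Write a synthetic dataset to disk
#'
#' @param sim A `ras_synth` from [generate_trajectory()].
#' @param dir Output directory (created if needed).
#' @param traj_format `"dcd"` (binary, compact; default) or `"pdb"`
#'   (multi-model text).
#' @return Named list of file paths: `structure`, `trajectory`, `truth`,
#'   `spec`.
#' @export
write_synthetic <- function(sim, dir, traj_format = c("dcd", "pdb")) {
  traj_format <- match.arg(traj_format)
  stopifnot(inherits(sim, "ras_synth"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(paste0("cannot write to output directory: ", dir))
  }
  paths <- list(
    structure = file.path(dir, "structure.pdb"),
    trajectory = file.path(dir, paste0("trajectory.", traj_format)),
    truth = file.path(dir, "truth.csv"),
    spec = file.path(dir, "synthetic_spec.json")
  )
  write_structure_pdb(sim$structure, paths$structure)
  if (traj_format == "dcd") {
    write_dcd(sim$trajectory, paths$trajectory)
  } else {
    write_structure_pdb(sim$structure, paths$trajectory,
                        coords = sim$trajectory)
  }
  readr::write_csv(sim$truth, paths$truth)
  write_synth_spec(sim$spec, paths$spec)
  invisible(paths)
}

#' Serialize / restore a synthetic spec
#' @param spec A `ras_synth_spec`.
#' @param path JSON file path.
#' @return `write_synth_spec()`: `path`, invisibly. `read_synth_spec()`: the
#'   restored `ras_synth_spec`.
#' @export
write_synth_spec <- function(spec, path) {
  x <- unclass(spec)
  mat2list <- function(m) {
    lapply(setNames(seq_len(ncol(m)), colnames(m)), function(j) {
      as.list(setNames(m[, j], rownames(m)))
    })
  }
  x$dist_mean <- mat2list(x$dist_mean)
  x$dist_sd <- mat2list(x$dist_sd)
  for (f in c("pi", "lambda", "d_og_o18")) {
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  }
  x$rc <- lapply(x$rc, as.list)
  x$switch_scale <- lapply(x$switch_scale, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synth_spec
#' @export
read_synth_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  list2mat <- function(l) {
    m <- vapply(l, function(col) unlist(col), numeric(length(l[[1]])))
    rownames(m) <- names(l[[1]])
    m
  }
  x$dist_mean <- list2mat(x$dist_mean)
  x$dist_sd <- list2mat(x$dist_sd)
  for (f in c("pi", "lambda", "d_og_o18")) {
    if (!is.null(x[[f]])) x[[f]] <- vapply(x[[f]], as.numeric, numeric(1))
  }
  x$rc <- lapply(x$rc, function(v) vapply(v, as.numeric, numeric(1)))
  x$switch_scale <- lapply(x$switch_scale,
                           function(v) vapply(v, as.numeric, numeric(1)))
  x$box <- as.numeric(unlist(x$box))
  x$n_frames <- as.integer(x$n_frames)
  x$seed <- as.integer(x$seed)
  x$tau <- as.numeric(x$tau)
  x$base_sd <- as.numeric(x$base_sd)
  x$hvr <- isTRUE(x$hvr); x$ions <- isTRUE(x$ions)
  x$n_shell_slots <- as.integer(x$n_shell_slots)
  x$n_decoys <- as.integer(x$n_decoys)
  validate_synth_spec(x)
  structure(x, class = "ras_synth_spec")
}
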