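# Na+ accessibility of the GTP pocket: contact-shell counting.

#' Count Na+ ions near GTP in one frame
#'
#' An ion counts when its minimum distance to *any* GTP atom is within
#' `cutoff` (contact-shell criterion; minimum-image if a box is supplied).
#'
#' @param frame N x 3 coordinate matrix of one frame.
#' @param roles A `ras_roles` map (needs `gtp_atoms`, `na_ions`).
#' @param cutoff Shell radius in Angstrom (default 4.5).
#' @param box Optional orthorhombic box edges.
#' @return Integer count.
#' @export
count_ions_near_gtp <- function(frame, roles, cutoff = 4.5, box = NULL) {
  if (length(roles$gtp_atoms) == 0) abort("GTP_ATOMS role is empty")
  if (length(roles$na_ions) == 0) return(0L)
  gtp <- frame[roles$gtp_atoms, , drop = FALSE]
  ions <- frame[roles$na_ions, , drop = FALSE]
  cnt <- 0L
  for (k in seq_len(nrow(ions))) {
    d <- pair_distance(gtp, matrix(ions[k, ], nrow(gtp), 3, byrow = TRUE),
                       box = box)
    if (min(d) <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

#' Per-frame ion counts over a trajectory
#'
#' @param traj A `ras_trajectory`.
#' @param roles A `ras_roles` map.
#' @param cutoff Shell radius in Angstrom.
#' @param box Optional box (defaults to the trajectory's own).
#' @return A `ras_ion_counts` tibble with columns `frame`, `ion_count`;
#'   attribute `cutoff`.
#' @export
ion_count_series <- function(traj, roles, cutoff = 4.5, box = traj$box) {
  if (length(roles$gtp_atoms) == 0) abort("GTP_ATOMS role is empty")
  nf <- traj$n_frames
  ng <- length(roles$gtp_atoms)
  gcols <- as.vector(vapply(roles$gtp_atoms,
                            function(i) c(3L * i - 2L, 3L * i - 1L, 3L * i),
                            integer(3)))
  counts <- integer(nf)
  for (ion in roles$na_ions) {
    icoord <- traj_atom(traj, ion)                     # nf x 3
    inshell <- rep(FALSE, nf)
    for (g in seq_len(ng)) {
      gc <- traj$coords[, gcols[c(3L * g - 2L, 3L * g - 1L, 3L * g)],
                        drop = FALSE]
      inshell <- inshell | (pair_distance(icoord, gc, box = box) <= cutoff)
    }
    counts <- counts + inshell
  }
  out <- tibble(frame = seq_len(nf), ion_count = as.integer(counts))
  attr(out, "cutoff") <- cutoff
  class(out) <- c("ras_ion_counts", class(out))
  out
}

#' Per-(sub)state ion-count summary
#'
#' Mean and population standard deviation (divisor n, a descriptive SD of
#' the per-frame counts) of the Na+ shell count, per smoothed state label.
#' States with zero frames are absent from the table.
#'
#' @param counts A `ras_ion_counts` tibble (or any data frame with an
#'   `ion_count` column aligned to `labels`).
#' @param labels A `ras_labels` series of the same length.
#' @return Tibble with columns `label`, `mean_ions`, `sd_ions`, `n_frames`.
#' @export
ion_summary_by_state <- function(counts, labels) {
  if (nrow(counts) != nrow(labels)) {
    abort(paste0("length mismatch: ", nrow(counts), " ion counts vs ",
                 nrow(labels), " labels"))
  }
  tibble(label = labels$label, ion_count = counts$ion_count) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      mean_ions = mean(.data$ion_count),
      sd_ions = sqrt(mean((.data$ion_count - mean(.data$ion_count))^2)),
      n_frames = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$label, STATE_LEVELS))
}
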