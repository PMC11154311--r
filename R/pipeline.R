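# End-to-end orchestration: synthesize a scenario, analyze a trajectory,
# compare two occupancy reports. The thin command-line front-end in
# inst/scripts/rasconf-cli.R calls exactly these functions.

#' Synthesize a scenario dataset on disk
#'
#' Convenience wrapper: builds the [synthetic_spec()], runs
#' [generate_trajectory()] and [write_synthetic()].
#'
#' @param scenario One of [scenario_presets()].
#' @param dir Output directory.
#' @param n_frames,tau,seed Passed to [synthetic_spec()].
#' @param traj_format Trajectory format, see [write_synthetic()].
#' @param ... Further [synthetic_spec()] overrides.
#' @return Named list of output paths, invisibly (with the `ras_synth`
#'   attached as attribute `sim`).
#' @export
synthesize_scenario <- function(scenario, dir, n_frames = 20000L, tau = 50,
                                seed = 1L, traj_format = "dcd", ...) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  spec <- synthetic_spec(scenario, n_frames = n_frames, tau = tau,
                         seed = seed, ...)
  sim <- generate_trajectory(spec)
  paths <- write_synthetic(sim, dir, traj_format = traj_format)
  attr(paths, "sim") <- sim
  invisible(paths)
}

#' Run the full conformational-state analysis
#'
#' Feature extraction, cascade classification with smoothing, occupancy and
#' transition summaries, per-(sub)state RMSF / PCA / DCCM, the Na+ shell
#' count summary and (for membrane-bound systems) the reaction-coordinate
#' histogram.
#'
#' @param structure A `ras_structure` or path to a PDB file.
#' @param trajectory A `ras_trajectory` or path to a DCD / multi-model PDB.
#' @param rules Role-selection rules, see [role_rules()].
#' @param cfg Classifier configuration, see [classifier_config()].
#' @param ion_cutoff Na+ shell radius (Angstrom).
#' @param compute_stats Compute per-state RMSF/PCA/DCCM (the costly part).
#' @param stats_states States for which ensemble statistics are computed
#'   (default: every state with at least `min_state_frames` frames).
#' @param min_state_frames Minimum frames for per-state statistics.
#' @param membrane_normal Membrane normal for the beta1 tilt angle.
#' @return A `ras_analysis` list: `features`, `labels`, `occupancy`,
#'   `transitions`, `ion_counts`, `ion_summary`, `rmsf` (tibble over
#'   states), `pca` (named list of `ras_pca`), `dccm` (named list),
#'   `rc_hist` (or `NULL`), `roles`, `config`.
#' @export
run_analysis <- function(structure, trajectory, rules = role_rules(),
                         cfg = classifier_config(), ion_cutoff = 4.5,
                         compute_stats = TRUE, stats_states = NULL,
                         min_state_frames = 10L,
                         membrane_normal = c(0, 0, 1)) {
  if (is.character(structure)) structure <- read_structure(structure)
  if (is.character(trajectory)) {
    trajectory <- read_trajectory(trajectory, structure)
  }
  roles <- resolve_roles(structure, rules)
  features <- extract_features(trajectory, roles,
                               membrane_normal = membrane_normal)
  labels <- classify_series(features, cfg)
  occ <- occupancy(labels)
  trans <- transition_matrix(labels)

  ion_counts <- NULL; ion_summary <- NULL
  if (length(roles$na_ions) > 0) {
    ion_counts <- ion_count_series(trajectory, roles, cutoff = ion_cutoff)
    ion_summary <- ion_summary_by_state(ion_counts, labels)
  }

  rc_hist <- NULL
  if (!is.na(roles$l184_ca)) {
    pairs <- rc_pair(features)
    rc_hist <- histogram2d(pairs,
                           angle_breaks = seq(0, 180, by = 5),
                           dist_breaks = seq(0, ceiling(max(pairs$rc_dist_A,
                                                            na.rm = TRUE) + 2),
                                             by = 1))
  }

  rmsf <- NULL; pca <- NULL; dccm <- NULL
  if (compute_stats) {
    present <- occ$label[occ$n_frames >= max(2L, min_state_frames)]
    if (is.null(stats_states)) stats_states <- present
    stats_states <- intersect(stats_states, present)
    rmsf <- purrr::map_dfr(stats_states, function(s) {
      rmsf_by_state(trajectory, labels, s, roles)
    })
    pca <- setNames(lapply(stats_states, function(s) {
      pca_ca(trajectory, roles, labels, s)
    }), stats_states)
    dccm <- setNames(lapply(stats_states, function(s) {
      cross_correlation(trajectory, roles, labels, s)
    }), stats_states)
  }

  structure(
    list(features = features, labels = labels, occupancy = occ,
         transitions = trans, ion_counts = ion_counts,
         ion_summary = ion_summary, rmsf = rmsf, pca = pca, dccm = dccm,
         rc_hist = rc_hist, roles = roles,
         config = list(classifier = cfg, ion_cutoff = ion_cutoff,
                       membrane_normal = membrane_normal)),
    class = "ras_analysis"
  )
}

#' @export
print.ras_analysis <- function(x, ...) {
  cat("<ras_analysis> ", nrow(x$features), " frames\n", sep = "")
  occ <- x$occupancy
  cat("  occupancy:",
      paste(sprintf("%s %.1f%%", occ$label, 100 * occ$fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write all analysis outputs to a directory
#'
#' Produces the feature/label CSV, occupancy JSON, transition CSV, per-state
#' RMSF CSV, PCA eigenvalue/eigenvector and DCCM matrix files, ion-count CSV
#' and JSON summary, the RC histogram grid and a run manifest (file list
#' with checksums).
#'
#' @param analysis A `ras_analysis`.
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) abort(paste0("cannot create output directory: ", dir))
  paths <- list()
  paths$features <- file.path(dir, "features.csv")
  write_feature_table(analysis$features, analysis$labels, paths$features)
  paths$occupancy <- file.path(dir, "occupancy.json")
  write_occupancy_json(analysis$occupancy, paths$occupancy)
  paths$transitions <- file.path(dir, "transitions.csv")
  readr::write_csv(as_tibble(as.data.frame.matrix(analysis$transitions),
                             rownames = "from"),
                   paths$transitions)
  if (!is.null(analysis$ion_counts)) {
    paths$ion_counts <- file.path(dir, "ion_counts.csv")
    readr::write_csv(tibble(frame = analysis$ion_counts$frame,
                            label = analysis$labels$label,
                            ion_count = analysis$ion_counts$ion_count),
                     paths$ion_counts)
    paths$ion_summary <- file.path(dir, "ion_summary.json")
    jsonlite::write_json(analysis$ion_summary, paths$ion_summary,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(analysis$rmsf)) {
    paths$rmsf <- file.path(dir, "rmsf.csv")
    readr::write_csv(analysis$rmsf, paths$rmsf)
  }
  for (s in names(analysis$pca)) {
    p <- analysis$pca[[s]]
    paths[[paste0("pca_", s)]] <- file.path(dir, paste0("pca_", s, ".txt"))
    write_matrix_txt(t(p$vectors), paths[[paste0("pca_", s)]],
                     metadata = list(state = s, frames = p$n_frames,
                                     eigenvalues_A2 = p$values,
                                     layout = "one eigenvector (3N components) per row, eigenvalue-ordered"))
  }
  for (s in names(analysis$dccm)) {
    paths[[paste0("dccm_", s)]] <- file.path(dir, paste0("dccm_", s, ".txt"))
    write_matrix_txt(analysis$dccm[[s]], paths[[paste0("dccm_", s)]],
                     metadata = list(state = s))
  }
  if (!is.null(analysis$rc_hist)) {
    paths$rc_hist <- file.path(dir, "rc_histogram.txt")
    write_matrix_txt(analysis$rc_hist, paths$rc_hist,
                     metadata = list(
                       angle_breaks = attr(analysis$rc_hist, "angle_breaks"),
                       dist_breaks = attr(analysis$rc_hist, "dist_breaks"),
                       n_out_of_range = attr(analysis$rc_hist, "n_out")))
  }
  manifest <- tibble(
    file = basename(unlist(paths)),
    md5 = vapply(unlist(paths), function(p) unname(tools::md5sum(p)),
                 character(1))
  )
  paths$manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, paths$manifest)
  invisible(paths)
}

#' Compare two occupancy reports
#'
#' Per-state deltas and fold-changes between two occupancy tables (e.g.
#' membrane-bound G12V against membrane-bound WT). A state absent from one
#' report is treated as fraction 0 and its ratio flagged infinite.
#'
#' @param a,b `ras_occupancy` tibbles (or paths to occupancy JSON files).
#'   `b` is the reference of the fold-change.
#' @return Tibble with columns `label`, `fraction_a`, `fraction_b`, `delta`
#'   (a - b), `fold_change` (a / b).
#' @export
compare_occupancy <- function(a, b) {
  if (is.character(a)) a <- read_occupancy_json(a)
  if (is.character(b)) b <- read_occupancy_json(b)
  if (!setequal(a$label, b$label)) {
    abort(paste0("label sets differ: {", paste(a$label, collapse = ","),
                 "} vs {", paste(b$label, collapse = ","), "}"))
  }
  tibble(label = a$label,
         fraction_a = a$fraction,
         fraction_b = b$fraction[match(a$label, b$label)]) |>
    dplyr::mutate(
      delta = .data$fraction_a - .data$fraction_b,
      fold_change = dplyr::if_else(.data$fraction_b > 0,
                                   .data$fraction_a / .data$fraction_b,
                                   dplyr::if_else(.data$fraction_a > 0,
                                                  Inf, NA_real_))
    )
}
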