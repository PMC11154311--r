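# Writers/readers for the pipeline's tabular outputs: features+labels CSV,
# occupancy JSON, plain-text matrices with header metadata.

#' Write the per-frame feature/label table
#'
#' One row per frame: the five distances (Angstrom), the two reaction
#' coordinates (degrees / Angstrom, `rc_dist_A` empty for solution-only
#' systems) and the raw and smoothed labels. Values round-trip through
#' [read_feature_table()] exactly at the printed precision.
#'
#' @param features A `ras_features` tibble.
#' @param labels A `ras_labels` tibble of the same length (optional).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, labels = NULL, path) {
  out <- as_tibble(features)
  if (!is.null(labels)) {
    if (nrow(labels) != nrow(features)) {
      abort(paste0("length mismatch: ", nrow(features), " feature frames vs ",
                   nrow(labels), " labels"))
    }
    out$raw_label <- labels$raw_label
    out$label <- labels$label
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "")
}

#' Write an occupancy report as JSON
#'
#' @param occ A `ras_occupancy` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_json <- function(occ, path) {
  x <- list(
    fraction = as.list(setNames(occ$fraction, occ$label)),
    counts = as.list(setNames(occ$n_frames, occ$label)),
    mean_dwell = as.list(setNames(occ$mean_dwell, occ$label)),
    n_trajectories = attr(occ, "n_trajectories") %||% 1L
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_occupancy_json
#' @export
read_occupancy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble(
    label = names(x$fraction),
    n_frames = as.integer(unlist(x$counts)),
    fraction = as.numeric(unlist(x$fraction)),
    mean_dwell = as.numeric(vapply(x$mean_dwell,
                                   function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                                   numeric(1)))
  )
  attr(out, "n_trajectories") <- x$n_trajectories
  class(out) <- c("ras_occupancy", class(out))
  out
}

#' Write a numeric matrix as plain text with header metadata
#'
#' Header lines start with `#` (`key: value`); the body is one
#' space-separated row per line.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param metadata Named list written into the header.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(m, path, metadata = list()) {
  hdr <- c(
    vapply(names(metadata), function(k) {
      paste0("# ", k, ": ", paste(metadata[[k]], collapse = " "))
    }, character(1)),
    paste0("# dim: ", nrow(m), " ", ncol(m))
  )
  body <- apply(unclass(m), 1, function(r) paste(format(r, digits = 10),
                                                 collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  hdr <- lines[grepl("^#", lines)]
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# *", "", h)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*: *", "", kv))
  }
  attr(m, "metadata") <- meta
  m
}
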