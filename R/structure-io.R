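# Structure and trajectory readers/writers.
#
# Structures are parsed with bio3d; coordinates are kept in Angstrom
# everywhere. A trajectory is stored as a frames x 3N matrix in bio3d xyz
# order (x1, y1, z1, x2, ...), which keeps per-atom slicing and linear
# algebra cheap.

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of a PDB v3.3 file into an atom table plus a
#' coordinate matrix. Insertion codes are rejected (the package assumes the
#' plain crystal numbering of the Ras G-domain, residues 1-165 with an
#' optional HVR tail); duplicate atom serial numbers are accepted with a
#' warning, order preserved.
#'
#' @param path Path to a PDB file.
#' @return A `ras_structure`: list with `atoms` (tibble: `serial`, `name`,
#'   `resname`, `resno`, `chain`, `element`), `xyz` (N x 3 matrix, Angstrom)
#'   and `box` (length-3 numeric from an orthorhombic CRYST1 record, or
#'   `NULL`).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    abort(paste0("no ATOM/HETATM records in PDB file: ", path))
  }
  # Cheap format validation so a parse failure can name the offending line.
  bad <- which(rec & is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))))
  if (length(bad) > 0) {
    abort(paste0("malformed coordinate field in PDB file ", path,
                 " at line ", bad[1]))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("failed to parse PDB file ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  ins <- !is.na(at$insert) & at$insert != ""
  if (any(ins)) {
    abort(paste0("insertion codes are not supported (first at residue ",
                 at$resno[which(ins)[1]], at$insert[which(ins)[1]], ")"))
  }
  if (anyDuplicated(at$eleno)) {
    warn("duplicate atom serial numbers in PDB; order preserved")
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    abort("non-finite coordinates in PDB file")
  }
  atoms <- tibble(
    serial  = as.integer(at$eleno),
    name    = as.character(at$elety),
    resname = toupper(as.character(at$resid)),
    resno   = as.integer(at$resno),
    chain   = ifelse(is.na(at$chain), "", as.character(at$chain)),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     toupper(substr(trimws(at$elety), 1, 1)),
                     toupper(trimws(at$elesy)))
  )
  if (any(atoms$resno <= 0, na.rm = TRUE) || any(is.na(atoms$resno))) {
    abort("every atom must carry a strictly positive residue number")
  }
  xyz <- cbind(at$x, at$y, at$z)
  structure(
    list(atoms = atoms, xyz = xyz, box = parse_cryst1(lines)),
    class = "ras_structure"
  )
}

parse_cryst1 <- function(lines) {
  cl <- lines[grepl("^CRYST1", lines)]
  if (length(cl) == 0) return(NULL)
  box <- suppressWarnings(as.numeric(c(substr(cl[1], 7, 15),
                                       substr(cl[1], 16, 24),
                                       substr(cl[1], 25, 33))))
  if (any(is.na(box)) || all(box == 1)) return(NULL)  # placeholder CRYST1
  box
}

#' @export
print.ras_structure <- function(x, ...) {
  cat("<ras_structure> ", nrow(x$atoms), " atoms, ",
      dplyr::n_distinct(x$atoms$resno), " residues",
      if (!is.null(x$box)) paste0(", box ", paste(round(x$box, 1), collapse = " x ")),
      "\n", sep = "")
  invisible(x)
}

n_atoms <- function(x) {
  if (inherits(x, "ras_structure")) return(nrow(x$atoms))
  if (inherits(x, "ras_trajectory")) return(x$n_atoms)
  abort("expected a ras_structure or ras_trajectory")
}

new_trajectory <- function(coords, box = NULL, time_ns = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) %% 3 == 0, nrow(coords) >= 1)
  structure(
    list(coords = coords, n_atoms = ncol(coords) / 3L,
         n_frames = nrow(coords), box = box, time_ns = time_ns),
    class = "ras_trajectory"
  )
}

#' @export
print.ras_trajectory <- function(x, ...) {
  cat("<ras_trajectory> ", x$n_frames, " frames x ", x$n_atoms, " atoms\n",
      sep = "")
  invisible(x)
}

# Coordinates of one atom across all frames: n_frames x 3 matrix.
traj_atom <- function(traj, i) {
  traj$coords[, c(3L * i - 2L, 3L * i - 1L, 3L * i), drop = FALSE]
}

# One frame as an N x 3 matrix.
traj_frame <- function(traj, f) {
  matrix(traj$coords[f, ], ncol = 3, byrow = TRUE)
}

#' Read a coordinate trajectory
#'
#' Reads a CHARMM/NAMD-format binary DCD file or a multi-model PDB and
#' returns coordinates in Angstrom. The atom count must match the supplied
#' structure; a DCD whose header announces more frames than the file holds
#' is rejected rather than silently truncated.
#'
#' @param path Path to a `.dcd` or multi-model `.pdb` file.
#' @param structure The matching [read_structure()] result (atom-count check,
#'   box propagation).
#' @param coord_unit Unit of the on-disk coordinates, `"angstrom"` (default)
#'   or `"nm"`; nm input is scaled by 10 so downstream code always sees
#'   Angstrom.
#' @return A `ras_trajectory`.
#' @export
read_trajectory <- function(path, structure,
                            coord_unit = c("angstrom", "nm")) {
  coord_unit <- match.arg(coord_unit)
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    coords <- tryCatch(
      unclass(bio3d::read.dcd(path, verbose = FALSE)),
      error = function(e) abort(paste0("failed to read DCD ", path, ": ",
                                       conditionMessage(e)))
    )
    hdr <- read_dcd_header(path)
    if (!is.na(hdr$nset) && hdr$nset > 0 && nrow(coords) < hdr$nset) {
      abort(paste0("truncated DCD: header announces ", hdr$nset,
                   " frames but only ", nrow(coords), " could be read"))
    }
  } else if (ext %in% c("pdb", "ent")) {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) abort(paste0("failed to parse multi-model PDB ",
                                       path, ": ", conditionMessage(e)))
    )
    coords <- pdb$xyz
    if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
    coords <- unclass(coords)
  } else {
    abort(paste0("unsupported trajectory format '.", ext,
                 "' (expected .dcd or multi-model .pdb)"))
  }
  want <- n_atoms(structure)
  got <- ncol(coords) / 3
  if (got != want) {
    abort(paste0("trajectory atom count (", got,
                 ") does not match structure atom count (", want, ")"))
  }
  if (coord_unit == "nm") coords <- coords * 10
  new_trajectory(coords, box = structure$box)
}

read_dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "integer", 1, size = 4)            # record marker (84)
  magic <- readChar(con, 4, useBytes = TRUE)
  nset <- readBin(con, "integer", 1, size = 4)
  list(magic = magic, nset = if (identical(magic, "CORD")) nset else NA_integer_)
}

#' Write a CHARMM-format DCD trajectory
#'
#' Minimal single-segment DCD writer (no unit-cell block; the box, if any,
#' travels with the structure's CRYST1 record). Coordinates are stored as
#' 32-bit floats, the format's native precision.
#'
#' @param coords Frames x 3N matrix in Angstrom, or a `ras_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, path) {
  if (inherits(coords, "ras_trajectory")) coords <- coords$coords
  stopifnot(is.matrix(coords), ncol(coords) %% 3 == 0)
  nframes <- nrow(coords)
  natom <- ncol(coords) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # Fortran unformatted record: payload length before and after.
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nframes   # NSET
  icntrl[2] <- 1L        # ISTART
  icntrl[3] <- 1L        # NSAVC
  icntrl[4] <- nframes   # NSTEP
  icntrl[20] <- 24L      # CHARMM version stamp
  wrec(function(c) {
    writeChar("CORD", c, nchars = 4, eos = NULL)
    writeBin(icntrl, c, size = 4)
  })
  wrec(function(c) {
    writeBin(1L, c, size = 4)
    writeChar(formatC("Synthetic Ras trajectory", width = -80), c,
              nchars = 80, eos = NULL)
  })
  wrec(function(c) writeBin(natom, c, size = 4))
  ix <- seq(1L, 3L * natom, by = 3L)
  for (f in seq_len(nframes)) {
    fr <- coords[f, ]
    wrec(function(c) writeBin(as.numeric(fr[ix]), c, size = 4))
    wrec(function(c) writeBin(as.numeric(fr[ix + 1L]), c, size = 4))
    wrec(function(c) writeBin(as.numeric(fr[ix + 2L]), c, size = 4))
  }
  invisible(path)
}

#' Write a structure (optionally multi-model) as PDB
#'
#' @param structure A `ras_structure` providing the atom table (and box).
#' @param path Output path.
#' @param coords Optional frames x 3N matrix; when supplied each row is
#'   written as one MODEL, giving a multi-model PDB trajectory. Default uses
#'   the structure's own coordinates as a single model.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path, coords = NULL) {
  at <- structure$atoms
  het <- at$resname %in% c("GTP", "MG", "NA", "SOD", "HOH", "CL")
  rectype <- ifelse(het, "HETATM", "ATOM  ")
  # PDB atom-name column convention: names < 4 chars start in column 14.
  nm <- ifelse(nchar(at$name) >= 4, at$name,
               sprintf(" %-3s", at$name))
  fmt_model <- function(xyz3) {
    sprintf("%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rectype, at$serial %% 100000L, nm, "",
            substr(at$resname, 1, 3), substr(at$chain, 1, 1), at$resno, "",
            xyz3[, 1], xyz3[, 2], xyz3[, 3], 1, 0, at$element)
  }
  header <- character(0)
  if (!is.null(structure$box)) {
    header <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                      structure$box[1], structure$box[2], structure$box[3],
                      90, 90, 90)
  }
  if (is.null(coords)) {
    body <- c(fmt_model(structure$xyz), "END")
  } else {
    if (inherits(coords, "ras_trajectory")) coords <- coords$coords
    body <- unlist(lapply(seq_len(nrow(coords)), function(f) {
      c(sprintf("MODEL %8d", f),
        fmt_model(matrix(coords[f, ], ncol = 3, byrow = TRUE)),
        "ENDMDL")
    }))
    body <- c(body, "END")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
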