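# Fixtures are built in code at test time; no binary data ships with the
# package.

pdb_line <- function(rec, serial, name, resname, resno, x, y, z,
                     chain = "A", element = substr(name, 1, 1)) {
  nm <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, "", resname, chain, resno, "", x, y, z, 1, 0,
          element)
}

# Three-atom two-residue fixture (plus optional Mg HETATM).
write_tiny_pdb <- function(path, with_mg = FALSE, dup_serial = FALSE,
                           insert_code = FALSE, bad_coords = FALSE) {
  l <- c(
    pdb_line("ATOM", 1, "N", "ALA", 1, 1.0, 2.0, 3.0),
    pdb_line("ATOM", if (dup_serial) 1 else 2, "CA", "ALA", 1, 2.0, 2.0, 3.0),
    pdb_line("ATOM", 3, "CA", "GLY", 2, 3.5, 2.0, 3.0)
  )
  if (insert_code) {
    l2 <- pdb_line("ATOM", 4, "CA", "GLY", 2, 4.5, 2.0, 3.0)
    substr(l2, 27, 27) <- "A"
    l <- c(l, l2)
  }
  if (bad_coords) {
    l[2] <- paste0(substr(l[2], 1, 30), "  xx.xxx", substr(l[2], 39, nchar(l[2])))
  }
  if (with_mg) l <- c(l, pdb_line("HETATM", 9, "MG", "MG", 99, 0, 0, 0,
                                  element = "MG"))
  writeLines(c(l, "END"), path)
  path
}

# Small seeded scenario dataset, cached per test file run.
small_sim <- local({
  cache <- list()
  function(scenario = "solution_WT", n_frames = 400, seed = 5, ...) {
    key <- paste(scenario, n_frames, seed, ...)
    if (is.null(cache[[key]])) {
      spec <- synthetic_spec(scenario, n_frames = n_frames, tau = 20,
                             seed = seed, ...)
      cache[[key]] <<- generate_trajectory(spec)
    }
    cache[[key]]
  }
})

# A ras_labels-shaped tibble from a plain character vector (for unit tests
# that bypass the classifier).
labels_from_states <- function(states) {
  out <- tibble::tibble(frame = seq_along(states), raw_label = states,
                        label = states)
  class(out) <- c("ras_labels", class(out))
  out
}

# A minimal trajectory object from a frames x 3N matrix.
traj_from_matrix <- function(m, box = NULL) {
  rasconf:::new_trajectory(m, box = box)
}

# Roles object for a bare Calpha-trace system laid out one atom per residue.
ca_only_roles <- function(n_res) {
  r <- list(og35 = 1L, mg = 1L, oh32 = 1L, ogamma = 1L, o12 = 1L, o18 = 1L,
            oh40 = 1L, e132_ca = 1L, l184_ca = NA_integer_,
            ca_trace = seq_len(n_res), ca_resno = seq_len(n_res),
            beta1_ca = 1:4, gtp_atoms = integer(0), na_ions = integer(0))
  class(r) <- "ras_roles"
  r
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
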