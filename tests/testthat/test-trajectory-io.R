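test_that("a minimal PDB parses to the written atoms and residues", {
  p <- write_tiny_pdb(tempfile(fileext = ".pdb"), with_mg = TRUE)
  s <- read_structure(p)
  expect_s3_class(s$atoms, "tbl_df")
  expect_equal(nrow(s$atoms), 4)
  expect_setequal(s$atoms$resno[s$atoms$resname %in% c("ALA", "GLY")],
                  c(1, 1, 2))
  # HETATM record coverage: the Mg is present and typed.
  expect_true(any(s$atoms$resname == "MG"))
  # Identity parse: coordinates equal the written values exactly.
  expect_equal(s$xyz[1, ], c(1, 2, 3))
  expect_equal(s$xyz[3, ], c(3.5, 2, 3))
})

test_that("duplicate serials warn but preserve order; bad records error", {
  p <- write_tiny_pdb(tempfile(fileext = ".pdb"), dup_serial = TRUE)
  expect_warning(s <- read_structure(p), "duplicate")
  # Oracle: column slicing of the raw lines, per the fixed-width layout.
  raw <- readLines(p)
  raw <- raw[grepl("^ATOM", raw)]
  expect_equal(s$xyz[, 1], as.numeric(substr(raw, 31, 38)))
  expect_equal(trimws(vapply(raw, substr, "", 13, 16, USE.NAMES = FALSE)),
               s$atoms$name)

  expect_error(read_structure(write_tiny_pdb(tempfile(fileext = ".pdb"),
                                             insert_code = TRUE)),
               "insertion")
  expect_error(read_structure(write_tiny_pdb(tempfile(fileext = ".pdb"),
                                             bad_coords = TRUE)),
               "line")
  empty <- tempfile(fileext = ".pdb"); writeLines("END", empty)
  expect_error(read_structure(empty), "no ATOM")
})

test_that("DCD and multi-model PDB round-trip the generated coordinates", {
  sim <- small_sim(n_frames = 5)
  d <- tempfile()
  p_dcd <- write_synthetic(sim, d, traj_format = "dcd")
  st <- read_structure(p_dcd$structure)
  tr <- read_trajectory(p_dcd$trajectory, st)
  expect_equal(tr$n_frames, 5)
  # float32 storage precision
  expect_lt(max(abs(tr$coords - sim$trajectory$coords)), 1e-4)

  d2 <- tempfile()
  p_pdb <- write_synthetic(sim, d2, traj_format = "pdb")
  tr2 <- read_trajectory(p_pdb$trajectory, st)
  expect_equal(tr2$n_frames, 5)
  # Two independent on-disk formats agree at PDB printed precision.
  expect_lt(max(abs(tr2$coords - tr$coords)), 2e-3)
})

test_that("atom-count mismatches and truncated files are rejected", {
  sim <- small_sim(n_frames = 3)
  d <- tempfile()
  p <- write_synthetic(sim, d)
  tiny <- write_tiny_pdb(tempfile(fileext = ".pdb"))
  expect_error(read_trajectory(p$trajectory, read_structure(tiny)),
               "3.*does not match|does not match")
  # Truncate the DCD mid-frame: must error, not silently shorten.
  st <- read_structure(p$structure)
  full <- readBin(p$trajectory, "raw", file.size(p$trajectory))
  cut <- file.path(d, "truncated.dcd")
  writeBin(full[1:(length(full) - 900)], cut)
  expect_error(read_trajectory(cut, st), "truncat|frames")
})

test_that("nm-unit trajectories are rescaled so 0.27 nm reads 2.7 A", {
  coords <- rbind(c(0, 0, 0, 0, 0, 0.27),
                  c(0, 0, 0, 0, 0, 0.27))
  f <- tempfile(fileext = ".dcd")
  write_dcd(coords, f)
  st <- list(atoms = tibble::tibble(serial = 1:2, name = c("CA", "CA"),
                                    resname = "ALA", resno = 1:2,
                                    chain = "A", element = "C"),
             xyz = matrix(0, 2, 3), box = NULL)
  class(st) <- "ras_structure"
  tr <- read_trajectory(f, st, coord_unit = "nm")
  expect_equal(pair_distance(tr$coords[1, 1:3], tr$coords[1, 4:6]), 2.7,
               tolerance = 1e-5)
})

test_that("roles resolve deterministically on a 5UHV-like synthetic system", {
  sim <- small_sim(n_frames = 2)
  st <- sim$structure
  roles <- resolve_roles(st)
  at <- st$atoms
  expect_equal(roles$oh32, which(trimws(at$name) == "OH" & at$resno == 32))
  expect_equal(roles$og35, which(trimws(at$name) == "OG1" & at$resno == 35))
  expect_equal(at$resname[roles$mg], "MG")
  expect_length(roles$ca_trace, 165)
  expect_equal(at$resno[roles$ca_trace], 1:165)  # ordered by residue
  expect_equal(at$resno[roles$beta1_ca], 2:5)
  # ogamma is the gamma oxygen closest to OH32 in the reference frame.
  og <- which(trimws(at$name) %in% c("O1G", "O2G", "O3G"))
  d <- sqrt(rowSums((st$xyz[og, , drop = FALSE] -
                     matrix(st$xyz[roles$oh32, ], length(og), 3,
                            byrow = TRUE))^2))
  expect_equal(roles$ogamma, og[which.min(d)])
  # Determinism.
  expect_identical(roles, resolve_roles(st))
})

test_that("G12V systems bind the O12 role on the Val12 backbone oxygen", {
  sim <- small_sim(scenario = "solution_G12V", n_frames = 2)
  roles <- resolve_roles(sim$structure)
  at <- sim$structure$atoms
  expect_equal(at$resname[roles$o12], "VAL")
  expect_equal(at$resno[roles$o12], 12L)
  expect_equal(trimws(at$name[roles$o12]), "O")
})

test_that("missing mandatory roles error with the role name", {
  p <- write_tiny_pdb(tempfile(fileext = ".pdb"))
  expect_error(resolve_roles(read_structure(p)), "MG")
})

test_that("the feature table round-trips and validates lengths", {
  sim <- small_sim(n_frames = 30)
  roles <- resolve_roles(sim$structure)
  feats <- extract_features(sim$trajectory, roles)
  labs <- classify_series(feats)
  f <- tempfile(fileext = ".csv")
  write_feature_table(feats, labs, f)
  back <- read_feature_table(f)
  expect_equal(nrow(back), 30)
  expect_equal(back$d_OH32_Og, feats$d_OH32_Og, tolerance = 1e-12)
  expect_equal(back$label, labs$label)
  # Missing rc_dist round-trips as NA via the empty field.
  expect_true(all(is.na(back$rc_dist_A)))

  # Empty series: header-only file.
  f2 <- tempfile(fileext = ".csv")
  write_feature_table(feats[0, ], NULL, f2)
  expect_equal(length(readLines(f2)), 1L)
  expect_error(write_feature_table(feats, labs[1:3, ], tempfile()),
               "mismatch")
})

test_that("occupancy JSON and matrix text files round-trip", {
  occ <- occupancy(labels_from_states(rep(c("S1", "S2_OX"), c(40, 60))))
  f <- tempfile(fileext = ".json")
  write_occupancy_json(occ, f)
  back <- read_occupancy_json(f)
  expect_equal(back$fraction, occ$fraction)
  expect_equal(back$n_frames, occ$n_frames)

  m <- matrix(rnorm(12), 3, 4)
  fm <- tempfile(fileext = ".txt")
  write_matrix_txt(m, fm, metadata = list(state = "S1", frames = 7))
  mb <- read_matrix_txt(fm)
  expect_equal(unclass(mb), m, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(attr(mb, "metadata")$state, "S1")
})
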