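# Semantic atom roles.
#
# The classifier and ion analysis never address atoms by index directly;
# they go through a role map resolved once per structure. Residue numbering
# is the crystal convention of the Ras G-domain (1-165, optional HVR tail to
# 186); no renumbering is performed.

#' Role-selection rules
#'
#' Defaults encode the atoms behind the five classifier distances and the
#' two membrane reaction coordinates: the Thr35 side-chain hydroxyl oxygen
#' (PDB name OG1), the Tyr ring hydroxyl oxygens of residues 32 and 40 (OH),
#' backbone carbonyl oxygens of residues 12 and 18 (O), the Mg2+ ion, the
#' GTP gamma-phosphate oxygens (O1G/O2G/O3G; the role binds the one closest
#' to OH32 in the reference structure), Na+ ions, the Calpha trace of the
#' G-domain, the beta1-sheet Calphas (residues 2-5) and the E132/L184
#' Calphas.
#'
#' @param ca_range Residue range of the Calpha trace (default 1:165).
#' @param beta1 Residues whose Calphas define the beta1-sheet direction.
#' @param gtp_resnames,mg_resnames,na_resnames HETATM residue-name synonyms,
#'   matched case-insensitively.
#' @return A list of rules consumed by [resolve_roles()].
#' @export
role_rules <- function(ca_range = 1:165,
                       beta1 = 2:5,
                       gtp_resnames = c("GTP", "GNP"),
                       mg_resnames = c("MG"),
                       na_resnames = c("NA", "SOD", "NA+")) {
  list(
    ca_range = ca_range, beta1 = beta1,
    og35 = list(resno = 35L, name = "OG1"),
    oh32 = list(resno = 32L, name = "OH"),
    oh40 = list(resno = 40L, name = "OH"),
    o12  = list(resno = 12L, name = "O"),
    o18  = list(resno = 18L, name = "O"),
    e132 = list(resno = 132L, name = "CA"),
    l184 = list(resno = 184L, name = "CA"),
    gtp_resnames = toupper(gtp_resnames),
    mg_resnames = toupper(mg_resnames),
    na_resnames = toupper(na_resnames)
  )
}

find_one <- function(atoms, resno, name, role) {
  idx <- which(atoms$resno == resno & trimws(atoms$name) == name)
  if (length(idx) == 0) {
    cand <- atoms$name[atoms$resno == resno]
    abort(paste0("cannot resolve role ", role, ": no atom named '", name,
                 "' in residue ", resno, " (candidates: ",
                 if (length(cand)) paste(cand, collapse = ", ") else "none",
                 ")"))
  }
  idx[1]
}

#' Resolve semantic atom roles in a structure
#'
#' Maps the roles used by the feature, classifier and ion modules to atom
#' indices of a concrete structure. For G12V systems the residue-12 backbone
#' oxygen resolves on Val12 (same residue position). The GTP gamma-oxygen
#' role (`ogamma`) binds, among O1G/O2G/O3G, the atom closest to OH32 in the
#' structure's own coordinates, and keeps that binding for all frames.
#'
#' @param structure A [read_structure()] result.
#' @param rules Selection rules from [role_rules()].
#' @return A `ras_roles` list: scalar indices `og35`, `mg`, `oh32`, `ogamma`,
#'   `o12`, `o18`, `oh40`, `e132_ca`, `l184_ca` (`NA` when no HVR) and index
#'   vectors `ca_trace` (ordered by residue number), `beta1_ca`, `gtp_atoms`,
#'   `na_ions`.
#' @export
resolve_roles <- function(structure, rules = role_rules()) {
  at <- structure$atoms
  at$name <- trimws(at$name)

  mg <- which(at$resname %in% rules$mg_resnames)
  if (length(mg) == 0) {
    abort("cannot resolve role MG: no Mg2+ ion (residue name MG) in structure")
  }
  gtp <- which(at$resname %in% rules$gtp_resnames)
  if (length(gtp) == 0) {
    abort(paste0("cannot resolve role GTP_ATOMS: no residue named ",
                 paste(rules$gtp_resnames, collapse = "/"), " in structure"))
  }
  og <- gtp[at$name[gtp] %in% c("O1G", "O2G", "O3G")]
  if (length(og) == 0) {
    abort("cannot resolve role OGAMMA: GTP has no atom named O1G/O2G/O3G")
  }
  oh32 <- find_one(at, rules$oh32$resno, rules$oh32$name, "OH32")
  # Fix the gamma-oxygen binding in the reference frame.
  d2 <- rowSums((structure$xyz[og, , drop = FALSE] -
                 matrix(structure$xyz[oh32, ], length(og), 3,
                        byrow = TRUE))^2)
  ogamma <- og[which.min(d2)]

  ca <- which(at$name == "CA" & at$resno %in% rules$ca_range &
                !(at$resname %in% c(rules$gtp_resnames, rules$mg_resnames,
                                    rules$na_resnames)))
  ca <- ca[order(at$resno[ca])]
  if (anyDuplicated(at$resno[ca])) {
    abort("duplicate Calpha atoms within the trace residue range")
  }
  beta1 <- ca[match(rules$beta1, at$resno[ca])]
  if (any(is.na(beta1))) {
    abort(paste0("cannot resolve role BETA1_CA: missing Calpha for residues ",
                 paste(rules$beta1[is.na(beta1)], collapse = ", ")))
  }
  l184 <- which(at$resno == rules$l184$resno & at$name == rules$l184$name)

  res <- list(
    og35 = find_one(at, rules$og35$resno, rules$og35$name, "OG35"),
    mg = mg[1],
    oh32 = oh32,
    ogamma = ogamma,
    o12 = find_one(at, rules$o12$resno, rules$o12$name, "O12"),
    o18 = find_one(at, rules$o18$resno, rules$o18$name, "O18"),
    oh40 = find_one(at, rules$oh40$resno, rules$oh40$name, "OH40"),
    e132_ca = find_one(at, rules$e132$resno, rules$e132$name, "E132_CA"),
    l184_ca = if (length(l184)) l184[1] else NA_integer_,
    ca_trace = ca,
    ca_resno = at$resno[ca],
    beta1_ca = beta1,
    gtp_atoms = gtp,
    na_ions = which(at$resname %in% rules$na_resnames)
  )
  bad <- vapply(res[c("og35", "mg", "oh32", "ogamma", "o12", "o18", "oh40")],
                function(i) i < 1 || i > nrow(at), logical(1))
  if (any(bad)) abort("resolved role index out of range")  # defensive
  structure(res, class = "ras_roles")
}

#' @export
print.ras_roles <- function(x, ...) {
  cat("<ras_roles> scalar roles: og35=", x$og35, " mg=", x$mg,
      " oh32=", x$oh32, " ogamma=", x$ogamma,
      "; trace: ", length(x$ca_trace), " Calphas; GTP atoms: ",
      length(x$gtp_atoms), "; Na+ ions: ", length(x$na_ions),
      if (is.na(x$l184_ca)) "; no HVR (L184 absent)" else "", "\n", sep = "")
  invisible(x)
}
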