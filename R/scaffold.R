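# Pseudo-protein scaffold: the minimal set of named anchor atoms from which
# the pore geometry of a Kv-type channel is reconstructed.  Residue numbering
# follows the rat Kv2.1 construct (residues 174-426); chains A-D are the four
# subunits.

# Atom roles are inferred from (residue, number, atom name); `plane` tags the
# five filter reference-oxygen groups.
role_table <- function() {
  data.frame(
    resid = c("TYR", "VAL", "TYR", "GLY", "VAL", "THR", "THR", "PRO",
              "VAL", "PRO", "ILE", "ILE", "VAL"),
    resno = c(376L, 409L, 376L, 375L, 374L, 373L, 373L, 408L,
              409L, 406L, 405L, 401L, 398L),
    elety = c("CB", "CB", "O", "O", "O", "O", "OG1", "CA",
              "CG1", "CG", "CD1", "CD1", "CG1"),
    role  = c("axis_anchor_top", "axis_anchor_bottom", rep("filter_plane", 5),
              "gate_marker", rep("s6_sidechain", 5)),
    plane = c(NA, NA, "Y376:O", "G375:O", "V374:O", "T373:O", "T373:OG1",
              rep(NA, 6)),
    stringsAsFactors = FALSE
  )
}

#' Coerce an atom table to a scaffold
#'
#' Attaches role tags (axis anchors, filter-plane oxygens, gate marker, S6
#' side chains) to atom records by residue name, residue number and atom
#' name, and validates the scaffold invariants.
#'
#' @param atoms data.frame with columns `resid` (3-letter residue name),
#'   `resno`, `elety` (PDB atom name), `chain` (subunit, "A".."D"),
#'   `x`, `y`, `z` (Angstrom).
#' @return A `scaffold` object (a data.frame with `role` and `plane` columns).
#' @export
as_scaffold <- function(atoms) {
  need <- c("resid", "resno", "elety", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop_input(paste0("scaffold atom table lacks column(s): ",
                      paste(miss, collapse = ", ")))
  rt <- role_table()
  key <- paste(atoms$resid, atoms$resno, atoms$elety)
  idx <- match(key, paste(rt$resid, rt$resno, rt$elety))
  keep <- !is.na(idx)
  sc <- atoms[keep, need, drop = FALSE]
  sc$role  <- rt$role[idx[keep]]
  sc$plane <- rt$plane[idx[keep]]
  rownames(sc) <- NULL
  class(sc) <- c("scaffold", "data.frame")
  validate_scaffold(sc)
  sc
}

#' Validate scaffold invariants
#'
#' Checks that the four subunits each contribute one Y376:CB and one V409:CB
#' axis anchor, that all five filter-plane oxygen groups (Y376:O, G375:O,
#' V374:O, T373:O, T373:OG1) have four atoms, and that the gate marker
#' (P408:CA) has four atoms.  Errors name the absent role.
#'
#' @param sc A `scaffold`.
#' @return `sc`, invisibly.
#' @export
validate_scaffold <- function(sc) {
  chains <- sort(unique(sc$chain))
  if (!identical(chains, c("A", "B", "C", "D")))
    stop_input(paste0("scaffold must have exactly subunits A-D, found: ",
                      paste(chains, collapse = ", ")))
  for (r in c("axis_anchor_top", "axis_anchor_bottom", "gate_marker")) {
    n <- sum(sc$role == r)
    if (n != 4L)
      stop_input(sprintf("scaffold role '%s' must have 4 atoms (one per subunit), found %d", r, n))
    if (length(unique(sc$chain[sc$role == r])) != 4L)
      stop_input(sprintf("scaffold role '%s' must appear once in each subunit", r))
  }
  for (pl in c("Y376:O", "G375:O", "V374:O", "T373:O", "T373:OG1")) {
    n <- sum(!is.na(sc$plane) & sc$plane == pl)
    if (n != 4L)
      stop_input(sprintf("filter plane '%s' must have 4 atoms, found %d", pl, n))
  }
  if (any(!is.finite(as.matrix(sc[, c("x", "y", "z")]))))
    stop_input("scaffold coordinates must be finite")
  invisible(sc)
}

cyl2cart <- function(r, theta_deg, z) {
  th <- theta_deg * pi / 180
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Build the default synthetic scaffold
#'
#' Emits a four-fold symmetric pseudo-protein carrying every atom role the
#' pore model needs, plus S6 side-chain pseudo-atoms (V409, P406, I405,
#' I401, V398 per subunit) for ligand-contact analysis.  With the defaults,
#' the five filter reference planes sit at z = 14.0, 11.2, 8.4, 5.6, 2.8
#' Angstrom and the two axis-anchor centroids are symmetric about the
#' origin, so along-axis coordinates coincide with laboratory z.
#'
#' @param plane_top z of the Y376:O plane (Angstrom).
#' @param plane_spacing spacing between consecutive filter planes (Angstrom).
#' @param gate_z z of the P408:CA gate marker.
#' @param anchor_top_z,anchor_bottom_z z of the Y376:CB / V409:CB anchors.
#' @param center 3-vector added to all coordinates (rigid translation).
#' @return A `scaffold`.
#' @export
make_scaffold <- function(plane_top = 14, plane_spacing = 2.8, gate_z = -11,
                          anchor_top_z = 12, anchor_bottom_z = -12,
                          center = c(0, 0, 0)) {
  base <- c(A = 0, B = 90, C = 180, D = 270)
  planes_z <- plane_top - plane_spacing * (0:4)
  z_og1 <- planes_z[5]
  z_scav <- (z_og1 + (z_og1 + gate_z) / 2) / 2
  z_cav  <- (gate_z + (z_scav - 2)) / 2   # ligand cavity center (see pore model)

  rows <- list()
  add <- function(resid, resno, elety, chain, r, dth, z) {
    xyz <- cyl2cart(r, base[[chain]] + dth, z)
    rows[[length(rows) + 1L]] <<- data.frame(
      resid = resid, resno = resno, elety = elety, chain = chain,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  for (ch in names(base)) {
    add("TYR", 376L, "CB", ch, 8.0, 45, anchor_top_z)
    add("VAL", 409L, "CB", ch, 5.0, 45, anchor_bottom_z)
    add("TYR", 376L, "O",   ch, 1.4, 0,  planes_z[1])
    add("GLY", 375L, "O",   ch, 1.4, 0,  planes_z[2])
    add("VAL", 374L, "O",   ch, 1.4, 0,  planes_z[3])
    add("THR", 373L, "O",   ch, 1.4, 0,  planes_z[4])
    add("THR", 373L, "OG1", ch, 2.0, 30, planes_z[5])
    add("PRO", 408L, "CA",  ch, 4.0, 0,  gate_z)
    # S6 side-chain carbons lining the cavity wall; the P406/I401/V398 tier
    # faces the subunit interfaces, V409/I405 are rotated toward one subunit.
    add("VAL", 398L, "CG1", ch, 4.243,   0, z_cav + 2.2)
    add("ILE", 401L, "CD1", ch, 4.243,   0, z_cav + 1.5)
    add("ILE", 405L, "CD1", ch, 5.0,   -20, z_cav - 1.3)
    add("PRO", 406L, "CG",  ch, 4.243,   0, z_cav - 1.5)
    add("VAL", 409L, "CG1", ch, 5.0,   -20, z_cav - 2.5)
  }
  df <- do.call(rbind, rows)
  df$x <- df$x + center[1]; df$y <- df$y + center[2]; df$z <- df$z + center[3]
  as_scaffold(df)
}

#' Write / read a scaffold as PDB
#'
#' Standard PDB with chains A-D and the construct's residue numbering, via
#' bio3d.  Coordinates are stored at PDB precision (0.001 Angstrom).
#'
#' @param sc A `scaffold`.
#' @param file Path to a PDB file.
#' @return `read_scaffold_pdb` returns a `scaffold`.
#' @export
write_scaffold_pdb <- function(sc, file) {
  validate_scaffold(sc)
  n <- nrow(sc)
  bio3d::write.pdb(
    pdb = NULL, file = file,
    xyz = as.numeric(t(as.matrix(sc[, c("x", "y", "z")]))),
    resno = sc$resno, resid = sc$resid, eleno = seq_len(n),
    elety = sc$elety, chain = sc$chain,
    o = rep(1, n), b = rep(0, n),
    elesy = ifelse(substr(sc$elety, 1, 1) == "O", "O", "C")
  )
  invisible(file)
}

#' @rdname write_scaffold_pdb
#' @export
read_scaffold_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  as_scaffold(data.frame(
    resid = a$resid, resno = a$resno, elety = a$elety, chain = a$chain,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}
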