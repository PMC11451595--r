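# Geometric frame of reference for the pore: axis, filter-plane offsets and
# binding-site boundaries, all derived from named scaffold anchor atoms.

PLANES <- c("Y376:O", "G375:O", "V374:O", "T373:O", "T373:OG1")
SITE_LABELS <- c("EXT", "S0", "S1", "S2", "S3", "S4",
                 "SCAV", "CAVITY", "GATE", "CYTO")
FILTER_SITES <- c("S0", "S1", "S2", "S3", "S4")

#' Build a pore model from a scaffold
#'
#' The pore axis runs through the centroids of the four Y376:CB atoms (top)
#' and the four V409:CB atoms (bottom), oriented so the extracellular side is
#' positive.  Each filter-plane offset is the mean projection of its four
#' reference oxygens onto the axis; the five K+ sites S0..S4 are the
#' half-open intervals between consecutive planes (S0 extends one mean
#' inter-plane spacing above the Y376:O plane).  A position exactly on a
#' plane belongs to the site on its intracellular side.  The S_cav center is
#' placed midway between the T373:OG1 plane and the midpoint of that plane
#' and the gate; the S_cav region is within `scav_halfwidth` of that center
#' axially and `scav_radius` of the axis.
#'
#' @param scaffold A `scaffold` (see [as_scaffold()]).
#' @param cylinder_diameter Analysis cylinder diameter (Angstrom, default 12).
#' @param lumen_radius Pore lumen radius used for the cavity region (Angstrom).
#' @param scav_halfwidth,scav_radius Axial half-width and radial extent of
#'   the S_cav region (Angstrom).
#' @param gate_halfwidth Axial extent of the GATE compartment below the
#'   P408:CA plane (Angstrom).
#' @return A `pore_model`: axis origin and unit direction, plane offsets,
#'   gate/S_cav coordinates, and the site boundary table (half-open
#'   intervals `(lo, hi]` along the axis).
#' @export
build_pore_model <- function(scaffold, cylinder_diameter = 12,
                             lumen_radius = 8, scav_halfwidth = 2,
                             scav_radius = 3, gate_halfwidth = 2) {
  validate_scaffold(scaffold)
  xyz <- as.matrix(scaffold[, c("x", "y", "z")])
  top <- colMeans(xyz[scaffold$role == "axis_anchor_top", , drop = FALSE])
  bot <- colMeans(xyz[scaffold$role == "axis_anchor_bottom", , drop = FALSE])
  d <- top - bot
  len <- sqrt(sum(d^2))
  if (len < 1e-8)
    stop_geometry("degenerate axis: the two anchor centroids coincide")
  dir <- d / len
  origin <- (top + bot) / 2

  proj <- function(rows) mean((xyz[rows, , drop = FALSE] %*% dir) - sum(origin * dir))
  z_planes <- vapply(PLANES, function(pl)
    proj(!is.na(scaffold$plane) & scaffold$plane == pl), numeric(1))
  if (any(diff(z_planes) >= 0))
    stop_geometry("filter plane offsets must strictly decrease from Y376:O to T373:OG1")
  spacing <- mean(-diff(z_planes))
  s0_ceiling <- z_planes[["Y376:O"]] + spacing
  z_gate <- proj(scaffold$role == "gate_marker")
  z_og1 <- z_planes[["T373:OG1"]]
  if (z_gate >= z_og1)
    stop_geometry("gate marker must lie below the T373:OG1 plane")
  z_scav <- (z_og1 + (z_og1 + z_gate) / 2) / 2
  z_cavity <- (z_gate + (z_scav - scav_halfwidth)) / 2

  # axis-orthogonal basis anchored to subunit A (gate marker azimuth = 0),
  # so in-plane coordinates are covariant under rigid motions of the scaffold
  gA <- colMeans(xyz[scaffold$role == "gate_marker" & scaffold$chain == "A", ,
                     drop = FALSE]) - origin
  perp <- gA - sum(gA * dir) * dir
  if (sqrt(sum(perp^2)) < 1e-8) {
    e <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- e - sum(e * dir) * dir
  }
  u <- perp / sqrt(sum(perp^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])

  breaks <- c(z_gate - gate_halfwidth, z_gate, z_og1,
              z_planes[["T373:O"]], z_planes[["V374:O"]],
              z_planes[["G375:O"]], z_planes[["Y376:O"]], s0_ceiling)
  labels <- c("CYTO", "GATE", "CAVITY", "S4", "S3", "S2", "S1", "S0", "EXT")
  boundary_table <- data.frame(
    label = labels,
    lo = c(-Inf, breaks),
    hi = c(breaks, Inf),
    stringsAsFactors = FALSE
  )

  structure(list(
    origin = origin, direction = dir, u = u, v = v,
    plane_offsets = z_planes, spacing = spacing, s0_ceiling = s0_ceiling,
    z_gate = z_gate, z_scav = z_scav, z_cavity = z_cavity,
    cylinder_diameter = cylinder_diameter, lumen_radius = lumen_radius,
    scav_halfwidth = scav_halfwidth, scav_radius = scav_radius,
    gate_halfwidth = gate_halfwidth,
    boundary_table = boundary_table,
    anchor_bottom = bot
  ), class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat("pore_model: axis origin (", paste(signif(x$origin, 4), collapse = ", "),
      "), direction (", paste(signif(x$direction, 4), collapse = ", "), ")\n", sep = "")
  cat("plane offsets (A):", paste(sprintf("%s=%.2f", names(x$plane_offsets),
                                          x$plane_offsets), collapse = ", "), "\n")
  cat(sprintf("z_gate=%.2f  z_scav=%.2f  S0 ceiling=%.2f  cylinder d=%.1f A\n",
              x$z_gate, x$z_scav, x$s0_ceiling, x$cylinder_diameter))
  invisible(x)
}

as_position_matrix <- function(position) {
  if (is.null(dim(position))) {
    if (length(position) != 3L) stop_value("position must be a 3-vector or n x 3 matrix")
    position <- matrix(position, ncol = 3)
  }
  p <- as.matrix(position)
  if (ncol(p) != 3L) stop_value("position must be a 3-vector or n x 3 matrix")
  if (any(!is.finite(p))) stop_value("position coordinates must be finite")
  p
}

#' Axial and radial coordinates of positions
#'
#' Projects positions onto the pore axis: `z` is the signed along-axis
#' coordinate relative to the axis origin (extracellular positive), `r` the
#' perpendicular distance to the axis.  Both are invariant under rigid
#' motions applied jointly to scaffold and positions.
#'
#' @param position 3-vector or n x 3 matrix (Angstrom).
#' @param model A `pore_model`.
#' @return n x 2 matrix with columns `z`, `r`.
#' @export
axial_and_radial <- function(position, model) {
  p <- as_position_matrix(position)
  rel <- sweep(p, 2, model$origin)
  z <- as.numeric(rel %*% model$direction)
  perp <- rel - outer(z, model$direction)
  r <- sqrt(rowSums(perp^2))
  cbind(z = z, r = r)
}

#' Assign positions to pore compartments
#'
#' Labels each position with one of `EXT, S0..S4, SCAV, CAVITY, GATE, CYTO`
#' by its axial coordinate against the site boundary table (half-open
#' `(lo, hi]` intervals: a position exactly on a plane belongs to the
#' intracellular site).  Within the cavity band a position inside the S_cav
#' box (within `scav_halfwidth` axially of the S_cav center and closer than
#' `scav_radius` to the axis) is SCAV.  Positions between the gate and the
#' Y376:O plane but radially outside the analysis cylinder are labeled
#' CAVITY (off-axis lumen).
#'
#' @inheritParams axial_and_radial
#' @return Character vector of compartment labels.
#' @export
assign_site <- function(position, model) {
  zr <- axial_and_radial(position, model)
  z <- zr[, "z"]; r <- zr[, "r"]
  bt <- model$boundary_table
  idx <- findInterval(z, bt$lo[-1], left.open = TRUE) + 1L
  lab <- bt$label[idx]
  in_scav <- abs(z - model$z_scav) <= model$scav_halfwidth &
    r < model$scav_radius & lab == "CAVITY"
  lab[in_scav] <- "SCAV"
  off_axis <- z > model$z_gate & z <= model$plane_offsets[["Y376:O"]] &
    r > model$cylinder_diameter / 2
  lab[off_axis & lab != "SCAV"] <- "CAVITY"
  lab
}

#' Reference positions of the pore compartments
#'
#' Returns a labeled matrix of on-axis reference points (laboratory frame):
#' the midpoint of each site interval for S0..S4, the S_cav and cavity
#' centers, and conventional points for GATE, CYTO (8 A below the gate) and
#' EXT (5 A above the S0 ceiling).  Used by the synthetic coordinate emitter.
#'
#' @param model A `pore_model`.
#' @return Matrix with rownames = compartment labels, columns x, y, z.
#' @export
site_centers <- function(model) {
  zp <- model$plane_offsets
  zmid <- c(
    EXT    = model$s0_ceiling + 5,
    S0     = (zp[["Y376:O"]] + model$s0_ceiling) / 2,
    S1     = (zp[["G375:O"]] + zp[["Y376:O"]]) / 2,
    S2     = (zp[["V374:O"]] + zp[["G375:O"]]) / 2,
    S3     = (zp[["T373:O"]] + zp[["V374:O"]]) / 2,
    S4     = (zp[["T373:OG1"]] + zp[["T373:O"]]) / 2,
    SCAV   = model$z_scav,
    CAVITY = model$z_cavity,
    GATE   = model$z_gate - model$gate_halfwidth / 2,
    CYTO   = model$z_gate - 8
  )
  pos <- outer(zmid, model$direction)
  pos <- sweep(pos, 2, model$origin, `+`)
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Serialize / deserialize a pore model
#'
#' Writes the model as a structured JSON text document and reads it back.
#'
#' @param model A `pore_model`.
#' @param file Path to a JSON file.
#' @export
write_pore_model <- function(model, file) {
  x <- unclass(model)
  x$boundary_table <- as.list(x$boundary_table)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_pore_model
#' @export
read_pore_model <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  x$boundary_table <- as.data.frame(x$boundary_table, stringsAsFactors = FALSE)
  x$boundary_table$lo <- as.numeric(x$boundary_table$lo)
  x$boundary_table$hi <- as.numeric(x$boundary_table$hi)
  x$boundary_table$lo[1] <- -Inf
  x$boundary_table$hi[nrow(x$boundary_table)] <- Inf
  x$origin <- as.numeric(x$origin)
  x$direction <- as.numeric(x$direction)
  x$u <- as.numeric(x$u); x$v <- as.numeric(x$v)
  x$plane_offsets <- stats::setNames(as.numeric(x$plane_offsets), PLANES)
  x$anchor_bottom <- as.numeric(x$anchor_bottom)
  structure(x, class = "pore_model")
}
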