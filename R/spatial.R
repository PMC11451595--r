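# Axial density profiles, membrane-plane histograms and radial statistics.

select_atoms <- function(frames, atoms) {
  if (is.character(atoms)) {
    idx <- which(frames$atoms$role %in% atoms)
  } else idx <- as.integer(atoms)
  if (!length(idx)) stop_input("atom selection is empty")
  if (any(idx < 1 | idx > nrow(frames$atoms)))
    stop_input("atom selection out of range")
  idx
}

atom_zr <- function(frames, idx, model) {
  pos <- matrix(frames$coords[, idx, , drop = FALSE], ncol = 3)
  axial_and_radial(pos, model)
}

#' Axial ion density relative to bulk
#'
#' Histograms positions along the pore axis, counting an atom only in frames
#' where it lies within a cylinder of the given diameter centered on the
#' axis, and normalizes each bin by `frames x bin volume x bulk number
#' density` so that bulk solution gives density 1.  At 300 mM the bulk
#' number density is 1.8066e-4 ions per cubic Angstrom.
#'
#' @param frames A `frame_set`.
#' @param model A `pore_model`.
#' @param bin_width Axial bin width (Angstrom, default 0.5).
#' @param diameter Analysis cylinder diameter (Angstrom, default the
#'   model's, itself 12 by default).
#' @param bulk_mM Bulk concentration (mM, default 300).
#' @param zlim Axial range to histogram; default spans the data.
#' @param atoms Atom selection (role names or indices; default role "ion").
#' @return data.frame `z` (bin centers), `density` (relative to bulk),
#'   `count`, with attributes `bin_width`, `diameter`, `bulk_mM`.
#' @export
axial_density <- function(frames, model, bin_width = 0.5,
                          diameter = model$cylinder_diameter, bulk_mM = 300,
                          zlim = NULL, atoms = "ion") {
  if (!length(frames$times_ns)) stop_input("frame set has zero frames")
  if (!is_scalar_num(bulk_mM) || bulk_mM <= 0)
    stop_value("bulk concentration must be positive")
  idx <- select_atoms(frames, atoms)
  zr <- atom_zr(frames, idx, model)
  keep <- zr[, "r"] <= diameter / 2
  z <- zr[keep, "z"]
  if (is.null(zlim)) zlim <- if (length(z)) range(z) else c(-1, 1)
  breaks <- seq(floor(zlim[1] / bin_width) * bin_width,
                ceiling(zlim[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(z[z >= breaks[1] & z < breaks[length(breaks)]],
                                  breaks),
                     nbins = length(breaks) - 1L)
  rho <- bulk_mM * N_AVOGADRO / 1e30          # ions per A^3
  vol <- pi * (diameter / 2)^2 * bin_width
  out <- data.frame(z = breaks[-length(breaks)] + bin_width / 2,
                    density = counts / (length(frames$times_ns) * vol * rho),
                    count = counts)
  attr(out, "bin_width") <- bin_width
  attr(out, "diameter") <- diameter
  attr(out, "bulk_mM") <- bulk_mM
  class(out) <- c("axial_density_profile", "data.frame")
  out
}

#' Membrane-plane position histogram
#'
#' 2D histogram of positions projected onto the axis-orthogonal plane, with
#' the origin on the pore axis.  Total counts equal frames x selected atoms.
#'
#' @inheritParams axial_density
#' @param atoms Atom selection (roles or indices).
#' @param bin_width In-plane bin width (Angstrom, default 0.5).
#' @return List with `counts` (matrix), `xbreaks`, `ybreaks`.
#' @export
xy_histogram <- function(frames, atoms, model, bin_width = 0.5) {
  idx <- select_atoms(frames, atoms)
  nf <- length(frames$times_ns)
  pos <- matrix(frames$coords[, idx, , drop = FALSE], ncol = 3)
  rel <- sweep(pos, 2, model$origin)
  xp <- as.numeric(rel %*% model$u)
  yp <- as.numeric(rel %*% model$v)
  m <- max(abs(c(xp, yp))) + bin_width
  breaks <- seq(-ceiling(m / bin_width) * bin_width,
                ceiling(m / bin_width) * bin_width, by = bin_width)
  counts <- table(cut(xp, breaks), cut(yp, breaks))
  list(counts = unclass(counts),
       xbreaks = breaks, ybreaks = breaks)
}

#' Radial distance quantile
#'
#' Empirical q-quantile of the perpendicular distance of selected atoms from
#' the pore axis, pooled over frames.
#'
#' @inheritParams xy_histogram
#' @param q Quantile(s) in (0, 1).
#' @return Numeric quantile(s) in Angstrom.
#' @export
radial_percentile <- function(frames, atoms, model, q) {
  if (any(q <= 0 | q >= 1)) stop_value("q must lie strictly in (0, 1)")
  idx <- select_atoms(frames, atoms)
  zr <- atom_zr(frames, idx, model)
  stats::quantile(zr[, "r"], q, names = FALSE)
}
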