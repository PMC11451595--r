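# Engine-agnostic restraint potentials: dihedral structure bias, flat-bottom
# radial/axial confinements, the knock-on pulling restraint, and
# voltage/electric-field unit conversions.

#' Dihedral structure-bias specification
#'
#' A weak periodic potential that favors a reference (experimental) value of
#' each dihedral while permitting thermal fluctuations:
#' `U(theta) = k * sum_{m=1..M} (1 - cos(m * (theta - theta_exp))) / m!`.
#' The default force constant is 1 kT at 298 K.  The printed form of this
#' potential in the simulation literature carries an ambiguous `(-1)^m ...
#' -180 deg` factor; since `cos(x - 180 deg) = -cos(x)`, the reading adopted
#' here (`form = "favoring"`) is the unique one that is non-negative with
#' its minimum at the reference structure.  The literal alternating-sign
#' reading (`form = "literal"`, minimum at 180 deg from the reference) is
#' available for comparison.
#'
#' @param theta_exp_deg Reference angle (degrees, in [-180, 180)).
#' @param k Force constant (kcal/mol; default kT at 298 K = 0.5922).
#' @param order Number of harmonics M (default 6).
#' @param form `"favoring"` (default) or `"literal"` (see above).
#' @return A `restraint_spec` of kind `dihedral_bias`.
#' @export
dihedral_bias_spec <- function(theta_exp_deg, k = KB_KCAL * 298, order = 6,
                               form = c("favoring", "literal")) {
  form <- match.arg(form)
  if (!is_scalar_num(k) || k < 0) stop_value("k must be non-negative")
  theta_exp_deg <- wrap_angle(theta_exp_deg)
  structure(list(kind = "dihedral_bias", k = k, theta_exp_deg = theta_exp_deg,
                 order = as.integer(order), form = form,
                 units = list(k = "kcal/mol", theta = "degrees")),
            class = "restraint_spec")
}

wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' Dihedral bias energy
#'
#' @param theta_deg Dihedral angle(s) in degrees.
#' @param spec A dihedral [restraint spec][dihedral_bias_spec()].
#' @return Energy (same units as `spec$k`); zero at the reference angle,
#'   non-negative and 360-degree periodic for the default form.
#' @export
dihedral_bias_energy <- function(theta_deg, spec) {
  if (any(!is.finite(theta_deg))) stop_value("angles must be finite")
  delta <- (theta_deg - spec$theta_exp_deg) * pi / 180
  m <- seq_len(spec$order)
  sgn <- if (spec$form == "literal") (-1)^m else rep(1, spec$order)
  vapply(delta, function(d)
    spec$k * sum(sgn * (1 - cos(m * d)) / factorial(m)), numeric(1))
}

#' Flat-bottom confinement specification
#'
#' Zero inside a tolerance `d0`, harmonic beyond:
#' `U(d) = 0.5 k (d - d0)^2` for `d > d0`, else 0.  The radial kind confines
#' to a cylinder co-axial with the pore (defaults: d0 = 10 A, i.e. a 20 A
#' diameter cylinder, k = 100 kcal/mol/A^2); the axial kind confines the
#' along-axis projection of the distance from the center of the four
#' V409:CB atoms (default d0 = 15 A).
#'
#' @param kind `"radial"` (distance to the pore axis, perpendicular to it)
#'   or `"axial"` (projection onto the axis, from the V409:CB center).
#' @param d0 Flat-bottom half-width (Angstrom).
#' @param k Force constant (kcal/mol/A^2).
#' @return A `restraint_spec` of kind `flat_bottom_radial` / `flat_bottom_axial`.
#' @export
flat_bottom_spec <- function(kind = c("radial", "axial"),
                             d0 = if (match.arg(kind) == "radial") 10 else 15,
                             k = 100) {
  kind <- match.arg(kind)
  if (!is_scalar_num(d0) || d0 <= 0) stop_value("d0 must be positive")
  if (!is_scalar_num(k) || k <= 0) stop_value("k must be positive")
  structure(list(kind = paste0("flat_bottom_", kind), d0 = d0, k = k,
                 anchors = if (kind == "radial")
                   "axis through Y376:CB and V409:CB centroids"
                 else "center of the four V409:CB atoms",
                 units = list(d0 = "Angstrom", k = "kcal/mol/A^2")),
            class = "restraint_spec")
}

#' Knock-on pulling restraint specification
#'
#' One-sided harmonic restraint that drives a K+ ion toward coordination
#' distance (about 3 A) of the carbonyl oxygens of Y376 and G375 in all four
#' subunits, activated at `t_activate_ns` in the induced knock-on protocol.
#'
#' @param target_distance Target coordination distance (Angstrom, default 3).
#' @param k Force constant (kcal/mol/A^2, default 3).
#' @param t_activate_ns Activation time (ns, default 100).
#' @return A `restraint_spec` of kind `knockon_pull`.
#' @export
knockon_pull_spec <- function(target_distance = 3, k = 3, t_activate_ns = 100) {
  if (!is_scalar_num(target_distance) || target_distance <= 0)
    stop_value("target distance must be positive")
  if (!is_scalar_num(k) || k <= 0) stop_value("k must be positive")
  structure(list(kind = "knockon_pull", target_distance = target_distance,
                 k = k, t_activate_ns = t_activate_ns,
                 targets = "carbonyl O of Y376 and G375, four subunits",
                 units = list(target_distance = "Angstrom",
                              k = "kcal/mol/A^2", t_activate = "ns")),
            class = "restraint_spec")
}

#' Flat-bottom energy and force
#'
#' @param d Distance(s) (Angstrom, >= 0).
#' @param spec A flat-bottom or knock-on-pull `restraint_spec`.
#' @return List with `energy` (kcal/mol) and `force` (magnitude of the
#'   restoring force, kcal/mol/A); both zero on `[0, d0]` and continuous at
#'   the boundary.
#' @export
flat_bottom_energy <- function(d, spec) {
  if (any(!is.finite(d) | d < 0)) stop_value("distances must be finite and >= 0")
  d0 <- spec$d0 %||% spec$target_distance
  ex <- pmax(d - d0, 0)
  list(energy = 0.5 * spec$k * ex^2, force = spec$k * ex)
}

#' Restraint collective-variable distance
#'
#' Evaluates the distance on which a confinement acts: for the radial kind,
#' the perpendicular distance from the channel axis (defined by the Y376:CB
#' and V409:CB anchor centroids); for the axial kind, the absolute
#' along-axis projection of the displacement from the V409:CB center.
#'
#' @param position 3-vector or n x 3 matrix (Angstrom).
#' @param spec A flat-bottom `restraint_spec`.
#' @param scaffold A `scaffold` providing the anchors.
#' @return Distance(s) in Angstrom.
#' @export
restraint_distance <- function(position, spec, scaffold) {
  validate_scaffold(scaffold)
  p <- as_position_matrix(position)
  xyz <- as.matrix(scaffold[, c("x", "y", "z")])
  top <- colMeans(xyz[scaffold$role == "axis_anchor_top", , drop = FALSE])
  bot <- colMeans(xyz[scaffold$role == "axis_anchor_bottom", , drop = FALSE])
  dvec <- top - bot
  len <- sqrt(sum(dvec^2))
  if (len < 1e-8) stop_input("axis anchors coincide; no axis defined")
  dir <- dvec / len
  if (spec$kind == "flat_bottom_radial") {
    rel <- sweep(p, 2, bot)
    z <- as.numeric(rel %*% dir)
    sqrt(rowSums((rel - outer(z, dir))^2))
  } else if (spec$kind == "flat_bottom_axial") {
    abs(as.numeric(sweep(p, 2, bot) %*% dir))
  } else stop_input(sprintf("no distance definition for spec kind '%s'", spec$kind))
}

#' Voltage / electric-field conversion
#'
#' `unit_constant()` returns the conversion factor between the simulation
#' field unit and laboratory units: 1 kcal/mol/A/e = 43.36 mV/A (from the
#' 2019 SI constants, 4184 J per kcal / Faraday).  `voltage_field_conversion`
#' converts a transmembrane voltage over a box length to the uniform applied
#' field that produces it.
#'
#' @param voltage_mV Voltage difference (mV).
#' @param box_length_A Box length along the field (Angstrom, > 0).
#' @return Field in kcal/mol/A/e; `unit_constant()` in mV/A per kcal/mol/A/e.
#' @export
voltage_field_conversion <- function(voltage_mV, box_length_A) {
  if (!is_scalar_num(box_length_A) || box_length_A <= 0)
    stop_value("box length must be positive")
  (voltage_mV / box_length_A) / unit_constant()
}

#' @rdname voltage_field_conversion
#' @export
unit_constant <- function() {
  1000 * 4184 / FARADAY   # mV/A per kcal/mol/A/e
}

#' Export / import restraint specifications
#'
#' Serializes a list of `restraint_spec`s (with units and anchor
#' definitions) to a JSON-style structured text document; the reader
#' round-trips losslessly.
#'
#' @param specs List of `restraint_spec`s.
#' @param file Path to a JSON file.
#' @return `read_restraints` returns the list of specs.
#' @export
export_restraints <- function(specs, file) {
  known <- c("dihedral_bias", "flat_bottom_radial", "flat_bottom_axial",
             "knockon_pull")
  if (inherits(specs, "restraint_spec")) specs <- list(specs)
  for (s in specs)
    if (!inherits(s, "restraint_spec") || !(s$kind %in% known))
      stop_input(sprintf("cannot export restraint of unknown kind '%s'",
                         if (is.list(s)) s$kind %||% "?" else "?"))
  jsonlite::write_json(lapply(specs, unclass), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname export_restraints
#' @export
read_restraints <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(raw, function(s) {
    s$order <- if (!is.null(s$order)) as.integer(s$order)
    s[vapply(s, is.null, logical(1))] <- NULL
    structure(s, class = "restraint_spec")
  })
}

#' The default restraint set
#'
#' The four restraints used in voltage-driven channel-inhibitor simulations:
#' the dihedral structure bias (k = 1 kT), the radial flat-bottom inhibitor
#' confinement (d0 = 10 A, k = 100 kcal/mol/A^2), the axial confinement
#' (d0 = 15 A) and the knock-on pulling restraint (3 A, k = 3 kcal/mol/A^2).
#'
#' @param theta_exp_deg Reference dihedral for the structure bias.
#' @return List of four `restraint_spec`s.
#' @export
default_restraint_set <- function(theta_exp_deg = 0) {
  list(dihedral_bias_spec(theta_exp_deg),
       flat_bottom_spec("radial"),
       flat_bottom_spec("axial"),
       knockon_pull_spec())
}
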