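# Euler-Bernoulli cantilever mechanics for cylindrical elastomer micropillars.
#
# A pillar of diameter D and length L loaded laterally at its tip behaves as
# a linear spring with k = 3 E I / L^3, I = pi D^4 / 64, i.e.
# k = 3 pi E D^4 / (64 L^3). Valid for small deflections and high aspect
# ratio; no large-deflection or substrate-warping corrections are applied.

#' Pillar geometry
#'
#' @param diameter_um Pillar diameter \eqn{D} in micrometres.
#' @param length_um Pillar length \eqn{L} in micrometres.
#' @return An object of class `pillar_geometry`.
#' @examples
#' pillar_geometry(16, 48)
#' @export
pillar_geometry <- function(diameter_um, length_um) {
  check_positive_scalar(diameter_um, "diameter_um")
  check_positive_scalar(length_um, "length_um")
  structure(list(diameter_um = diameter_um, length_um = length_um),
            class = "pillar_geometry")
}

#' @export
print.pillar_geometry <- function(x, ...) {
  cat(sprintf("Pillar geometry: D = %g um, L = %g um (aspect ratio %.2f)\n",
              x$diameter_um, x$length_um, x$length_um / x$diameter_um))
  invisible(x)
}

#' Elastic material
#'
#' PDMS cured for pillar arrays typically falls in the 0.5-4 MPa range
#' (mixing ratio and bake dependent); a modulus outside that range is
#' accepted with a warning so that other elastomers remain usable.
#'
#' @param youngs_modulus_mpa Young's modulus \eqn{E} in MPa.
#' @return An object of class `elastic_material`.
#' @examples
#' elastic_material(0.5)
#' @export
elastic_material <- function(youngs_modulus_mpa) {
  check_positive_scalar(youngs_modulus_mpa, "youngs_modulus_mpa")
  if (youngs_modulus_mpa < 0.5 || youngs_modulus_mpa > 4) {
    pb_warn(sprintf(
      "Young's modulus %g MPa is outside the typical PDMS range (0.5-4 MPa)",
      youngs_modulus_mpa), "pillarbeat_modulus_range")
  }
  structure(list(youngs_modulus_mpa = youngs_modulus_mpa),
            class = "elastic_material")
}

#' Cantilever spring constant of a cylindrical micropillar
#'
#' Computes \eqn{k = 3 \pi E D^4 / (64 L^3)} with all conversions to SI
#' internal (micrometres to metres, MPa to Pa); the result is in N/m.
#'
#' @param geometry A [pillar_geometry()] (or a single diameter in micrometres
#'   when `length_um` is given directly).
#' @param material An [elastic_material()] (or a modulus in MPa).
#' @return An object of class `spring_constant` with field `k_n_per_m`;
#'   usable as a plain number via `as.numeric()`.
#' @examples
#' k <- spring_constant(pillar_geometry(16, 48), elastic_material(0.5))
#' signif(as.numeric(k), 1) # 0.04 N/m
#' @export
spring_constant <- function(geometry, material) {
  if (!inherits(geometry, "pillar_geometry")) {
    pb_stop("`geometry` must be a pillar_geometry object",
            "pillarbeat_invalid_parameter")
  }
  if (!inherits(material, "elastic_material")) {
    pb_stop("`material` must be an elastic_material object",
            "pillarbeat_invalid_parameter")
  }
  D <- geometry$diameter_um * 1e-6
  L <- geometry$length_um * 1e-6
  E <- material$youngs_modulus_mpa * 1e6
  k <- 3 * pi * E * D^4 / (64 * L^3)
  new_spring_constant(k)
}

#' Wrap a stiffness value (N/m) as a spring constant
#'
#' Used when the stiffness comes from an external calibration (e.g. AFM)
#' rather than from the beam formula.
#'
#' @param k_n_per_m Tip stiffness in N/m, positive.
#' @return A `spring_constant` object.
#' @export
new_spring_constant <- function(k_n_per_m) {
  check_positive_scalar(k_n_per_m, "k_n_per_m")
  structure(list(k_n_per_m = k_n_per_m), class = "spring_constant")
}

#' @export
as.numeric.spring_constant <- function(x, ...) x$k_n_per_m

#' @export
print.spring_constant <- function(x, ...) {
  cat(sprintf("Pillar spring constant: %.6g N/m\n", x$k_n_per_m))
  invisible(x)
}

resolve_k <- function(k) {
  if (inherits(k, "spring_constant")) k <- k$k_n_per_m
  check_positive_scalar(k, "k")
  k
}

#' Contraction force from pillar deflection
#'
#' \eqn{F = k d}, applied componentwise for vector deflections. With
#' deflection in micrometres and stiffness in N/m the force comes out in
#' micronewtons with no extra factor.
#'
#' @param d_um Deflection in micrometres: a scalar, a vector of magnitudes,
#'   or a two-column matrix of `(dx, dy)` components.
#' @param k A [spring_constant()] or a stiffness in N/m.
#' @param pillar_id Optional identifier used in error messages.
#' @return Force in micronewtons, same shape as `d_um`.
#' @examples
#' force_from_deflection(3.0071, 0.04) # ~0.1202 uN
#' @export
force_from_deflection <- function(d_um, k, pillar_id = NULL) {
  k <- resolve_k(k)
  if (!all(is.finite(d_um))) {
    who <- if (is.null(pillar_id)) "" else sprintf(" (pillar %s)", pillar_id)
    pb_stop(sprintf("non-finite deflection%s", who),
            "pillarbeat_nonfinite_deflection")
  }
  d_um * k
}

#' Pillar deflection from an applied force
#'
#' Inverse of [force_from_deflection()]: \eqn{d = F / k}. Round-trips with
#' the forward conversion to machine precision, reflecting the linear
#' force-displacement relation of a small-deflection cantilever.
#'
#' @param force_un Force in micronewtons (scalar, vector, or matrix).
#' @param k A [spring_constant()] or a stiffness in N/m.
#' @return Deflection in micrometres, same shape as `force_un`.
#' @export
deflection_from_force <- function(force_un, k) {
  k <- resolve_k(k)
  force_un / k
}
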