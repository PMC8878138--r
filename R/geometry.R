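#' Idealized diaphysis geometry
#'
#' Describes the idealized tibial diaphysis used throughout the package: a
#' cylinder of the given length and outer radius whose dense cortical shell
#' surrounds a porous trabecular core, the two separated by an interface at
#' \code{initial_interface_radius}. With the defaults the cortical wall is
#' \code{outer_radius - initial_interface_radius = 1} mm thick. When
#' \code{axisymmetric_half_model} is \code{TRUE} (the default) only the upper
#' half of the shaft is meshed, with a symmetry plane at mid-height, and
#' energies are reported for the full bone.
#'
#' @param length Full diaphysis length in mm.
#' @param outer_radius Outer radius in mm.
#' @param initial_interface_radius Radius of the cortical-trabecular interface
#'   at the start of a simulation, mm.
#' @param axisymmetric_half_model Model only the upper half of the shaft?
#' @return An object of class \code{bone_geometry}.
#' @export
#' @examples
#' g <- bone_geometry()
#' g$outer_radius - g$initial_interface_radius  # 1 mm cortical wall
bone_geometry <- function(length = 10, outer_radius = 1.5,
                          initial_interface_radius = 0.5,
                          axisymmetric_half_model = TRUE) {
  stopifnot(is.numeric(length), length > 0,
            is.numeric(outer_radius), outer_radius > 0)
  if (!(initial_interface_radius > 0 && initial_interface_radius < outer_radius))
    stop("initial_interface_radius must lie strictly between 0 and outer_radius")
  structure(list(
    length = length,
    outer_radius = outer_radius,
    initial_interface_radius = initial_interface_radius,
    axisymmetric_half_model = isTRUE(axisymmetric_half_model),
    modeled_height = if (isTRUE(axisymmetric_half_model)) length / 2 else length
  ), class = "bone_geometry")
}

#' Parameters of the idealized radial density distribution
#'
#' The initial bone density is an arctangent ramp of the radius,
#' \deqn{\rho(R) = \mathrm{atan}(s (R - R_c)) / d + o,}
#' with \eqn{R} in meters. It rises smoothly from a low trabecular value at the
#' axis to a near-unit cortical value at the outer wall, with its inflection
#' (value \code{offset}) at \code{center_radius}.
#'
#' @param steepness Ramp steepness, 1/m.
#' @param center_radius Inflection radius, m (0.0005 m = 0.5 mm).
#' @param amplitude_divisor Divisor applied to the arctangent, dimensionless.
#' @param offset Density at the inflection radius, dimensionless.
#' @return An object of class \code{density_profile_params}.
#' @export
density_profile_params <- function(steepness = 12000, center_radius = 5e-4,
                                   amplitude_divisor = 3.4, offset = 0.56) {
  stopifnot(steepness > 0, center_radius > 0, amplitude_divisor > 0,
            offset > 0, offset < 1)
  structure(list(steepness = steepness, center_radius = center_radius,
                 amplitude_divisor = amplitude_divisor, offset = offset),
            class = "density_profile_params")
}

#' Elastic material constants
#'
#' @param E0 Young's modulus of fully dense cortical bone, GPa.
#' @param poisson_ratio Poisson ratio, dimensionless.
#' @param rho_ref Reference bone mass density, mg/mm^3 (1 mg/mm^3 = 1 g/cm^3),
#'   converting the dimensionless density to a mass density.
#' @return An object of class \code{material_params}.
#' @export
material_params <- function(E0 = 20.3, poisson_ratio = 0.3, rho_ref = 1) {
  stopifnot(E0 > 0, poisson_ratio >= 0, poisson_ratio < 0.5, rho_ref > 0)
  structure(list(E0 = E0, poisson_ratio = poisson_ratio, rho_ref = rho_ref),
            class = "material_params")
}

#' Idealized bone density as a function of radius
#'
#' Evaluates the arctangent density ramp at radii given in mm (the native
#' formula works in meters; the conversion is exact). Strictly increasing in
#' radius and, with the default parameters, bounded in (0, 1) over the
#' modeled section.
#'
#' @param radius Radius or vector of radii, mm. Must be non-negative.
#' @param params A [density_profile_params()] object.
#' @return Dimensionless density, same length as \code{radius}.
#' @export
#' @examples
#' density_profile(c(0, 0.5, 1.5))  # ~0.1466, 0.56, ~0.9975
density_profile <- function(radius, params = density_profile_params()) {
  if (any(!is.finite(radius)) || any(radius < 0))
    stop("radius must be finite and non-negative (mm)")
  r_m <- radius / 1000
  atan(params$steepness * (r_m - params$center_radius)) /
    params$amplitude_divisor + params$offset
}

#' Density-dependent Young's modulus
#'
#' The power law \eqn{E = E_0 \rho^2} mapping the dimensionless bone density
#' to a stiffness in GPa.
#'
#' @param density Dimensionless density (non-negative).
#' @param material A [material_params()] object.
#' @return Young's modulus, GPa.
#' @export
young_modulus <- function(density, material = material_params()) {
  if (any(!is.finite(density)) || any(density < 0))
    stop("density must be finite and non-negative")
  material$E0 * density^2
}

#' Structured axisymmetric mesh of the diaphysis
#'
#' Builds a structured quadrilateral (r, z) mesh covering
#' \code{[0, outer_radius] x [0, modeled_height]}. Subdivisions are chosen by
#' rounding so element edges stay within 20\% of the requested size; node
#' coordinates and counts are deterministic for fixed inputs. Element volumes
#' are exact solid-of-revolution annuli, so the meshed volume equals
#' \eqn{\pi R^2 H} to machine precision.
#'
#' @param geometry A [bone_geometry()] object.
#' @param target_element_size Requested element edge length, mm.
#' @param n_z Optional override of the axial subdivision count. The uniaxial
#'   compression solution is exactly uniform in z, so a single axial layer
#'   reproduces the radial physics; coarse \code{n_z} is used for fast
#'   calibration runs.
#' @return An object of class \code{bone_mesh}.
#' @export
build_mesh <- function(geometry = bone_geometry(), target_element_size = 0.1,
                       n_z = NULL) {
  R <- geometry$outer_radius
  H <- geometry$modeled_height
  if (!is.finite(R) || !is.finite(H) || R <= 0 || H <= 0)
    stop("degenerate geometry: non-positive radius or height")
  if (!(target_element_size > 0 && target_element_size <= R))
    stop("target_element_size must lie in (0, outer_radius]")
  nr <- max(1L, as.integer(round(R / target_element_size)))
  nz <- if (is.null(n_z)) max(1L, as.integer(round(H / target_element_size)))
        else as.integer(n_z)
  stopifnot(nz >= 1L)
  dr <- R / nr
  dz <- H / nz
  r_nodes <- seq(0, R, length.out = nr + 1L)
  z_nodes <- seq(0, H, length.out = nz + 1L)
  r_mid <- (r_nodes[-1L] + r_nodes[-(nr + 1L)]) / 2
  # exact annulus volume per element of each radial column (mm^3)
  col_volume <- pi * (r_nodes[-1L]^2 - r_nodes[-(nr + 1L)]^2) * dz
  elem_col <- rep(seq_len(nr), times = nz)       # radial column of each element
  structure(list(
    nr = nr, nz = nz, dr = dr, dz = dz,
    r_nodes = r_nodes, z_nodes = z_nodes,
    r_mid = r_mid,
    elem_col = elem_col,
    elem_r = r_mid[elem_col],
    elem_volume = col_volume[elem_col],
    n_elem = nr * nz, n_node = (nr + 1L) * (nz + 1L),
    outer_radius = R, height = H,
    geometry = geometry
  ), class = "bone_mesh")
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric mesh: %d x %d quads (%d elements, %d nodes), r in [0, %g] mm, z in [0, %g] mm\n",
    x$nr, x$nz, x$n_elem, x$n_node, x$outer_radius, x$height))
  invisible(x)
}

#' Evaluate the initial density field on a mesh
#'
#' Element-wise density sampled at element centroids.
#'
#' @param mesh A [build_mesh()] mesh.
#' @param params A [density_profile_params()] object.
#' @return Numeric vector of per-element densities.
#' @export
initial_density_field <- function(mesh, params = density_profile_params()) {
  density_profile(mesh$elem_r, params)
}

#' Export the idealized density profile as CSV
#'
#' Writes columns \code{radius_mm, density}.
#'
#' @param path Output file path.
#' @param radii Radii to evaluate, mm.
#' @param params A [density_profile_params()] object.
#' @return The data frame written, invisibly.
#' @export
export_density_profile <- function(path, radii = seq(0, 1.5, by = 0.01),
                                   params = density_profile_params()) {
  df <- data.frame(radius_mm = radii, density = density_profile(radii, params))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
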