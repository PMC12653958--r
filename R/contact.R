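#' Geometry of the medial tibiofemoral contact model
#'
#' Two-arc rigid femoral condyle on an elastic-foundation tibial plateau.
#' The femoral condyle is convex with two sagittal arcs (anterior arc
#' engaged below `arc_transition_flexion`, posterior arc above) and one
#' frontal arc; the tibial plateau is concave in both planes.  Cartilage
#' is a bed of independent nonlinear springs of uniform unloaded
#' thickness on a regular grid.
#'
#' The sagittal concavity of the tibial plateau is not tabulated for
#' this model family; the default of 37.0 mm (slightly less conforming
#' than the 35.0 mm anterior femoral arc, and within the anatomical range
#' reported for the medial plateau) was calibrated once so that the
#' model maps the reference cohort-mean peak force (2.68 BW at a
#' 69.31 kg body mass) to the reference cohort-mean peak strain of about
#' 0.22.  `Inf` gives a sagittally flat plateau.  Similarly the femoral
#' frontal radius is not tabulated; 20.0 mm against the 21 mm tibial
#' frontal arc gives a slightly non-conforming frontal pair (perfect
#' conformity would engage the whole width simultaneously).
#'
#' @param tibial_frontal_radius Concave tibial arc radius, frontal
#'   plane, mm (default 21).
#' @param femoral_sagittal_radius_anterior,femoral_sagittal_radius_posterior
#'   Convex femoral sagittal arc radii, mm (defaults 35.0 and 18.9).
#' @param femoral_frontal_radius Convex femoral frontal radius, mm
#'   (default 20.0).
#' @param tibial_sagittal_radius Concave tibial sagittal radius, mm
#'   (default 37.0; `Inf` = flat).
#' @param arc_transition_flexion Flexion angle in degrees at which the
#'   engaged sagittal arc switches from anterior to posterior
#'   (default 30).
#' @param cartilage_thickness Unloaded foundation thickness, mm
#'   (default 5.0).
#' @param element_spacing Grid spacing, mm (default 0.5).
#' @param mesh_nx_ap,mesh_ny_ml Grid dimensions, elements
#'   anteroposterior x mediolateral (defaults 111 x 66, i.e. 7326
#'   elements).
#' @param meniscus_coverage Fraction of the plateau covered by the
#'   meniscus (default 0.46); covered elements carry the covered tibial
#'   modulus.
#' @return An object of class `knee_geometry`.
#' @export
knee_geometry <- function(tibial_frontal_radius = 21,
                          femoral_sagittal_radius_anterior = 35.0,
                          femoral_sagittal_radius_posterior = 18.9,
                          femoral_frontal_radius = 20.0,
                          tibial_sagittal_radius = 37.0,
                          arc_transition_flexion = 30,
                          cartilage_thickness = 5.0,
                          element_spacing = 0.5,
                          mesh_nx_ap = 111,
                          mesh_ny_ml = 66,
                          meniscus_coverage = 0.46) {
  radii <- c(tibial_frontal_radius, femoral_sagittal_radius_anterior,
             femoral_sagittal_radius_posterior, femoral_frontal_radius,
             tibial_sagittal_radius)
  if (any(radii <= 0)) stop("all radii must be positive")
  if (cartilage_thickness <= 0) stop("'cartilage_thickness' must be positive")
  if (element_spacing <= 0) stop("'element_spacing' must be positive")
  if (mesh_nx_ap < 1 || mesh_ny_ml < 1) stop("mesh dimensions must be >= 1")
  if (meniscus_coverage < 0 || meniscus_coverage > 1)
    stop("'meniscus_coverage' must lie in [0, 1]")
  if (is.finite(tibial_sagittal_radius) &&
      tibial_sagittal_radius <= femoral_sagittal_radius_anterior)
    stop("'tibial_sagittal_radius' must exceed the anterior femoral ",
         "sagittal radius (concave plateau enclosing the convex condyle)")
  structure(
    list(tibial_frontal_radius = tibial_frontal_radius,
         femoral_sagittal_radius_anterior = femoral_sagittal_radius_anterior,
         femoral_sagittal_radius_posterior = femoral_sagittal_radius_posterior,
         femoral_frontal_radius = femoral_frontal_radius,
         tibial_sagittal_radius = tibial_sagittal_radius,
         arc_transition_flexion = arc_transition_flexion,
         cartilage_thickness = cartilage_thickness,
         element_spacing = element_spacing,
         mesh_nx_ap = as.integer(mesh_nx_ap),
         mesh_ny_ml = as.integer(mesh_ny_ml),
         meniscus_coverage = meniscus_coverage),
    class = "knee_geometry")
}

#' @export
print.knee_geometry <- function(x, ...) {
  cat("Medial tibiofemoral contact geometry\n")
  cat(sprintf("  femoral sagittal arcs: %.1f mm (anterior) / %.1f mm (posterior), switch at %g deg\n",
              x$femoral_sagittal_radius_anterior,
              x$femoral_sagittal_radius_posterior, x$arc_transition_flexion))
  cat(sprintf("  frontal pair: femur %.1f mm / tibia %.1f mm; tibial sagittal %.1f mm\n",
              x$femoral_frontal_radius, x$tibial_frontal_radius,
              x$tibial_sagittal_radius))
  cat(sprintf("  mesh %d x %d at %.2f mm (%d elements), thickness %.1f mm, meniscus coverage %.0f%%\n",
              x$mesh_nx_ap, x$mesh_ny_ml, x$element_spacing,
              x$mesh_nx_ap * x$mesh_ny_ml, x$cartilage_thickness,
              100 * x$meniscus_coverage))
  invisible(x)
}

#' Cartilage material properties for the elastic foundation
#'
#' Layer moduli of the tibiofemoral foundation and the rule that
#' combines them into a per-element effective modulus.  The default
#' `"harmonic"` rule treats the femoral and tibial cartilage layers as
#' springs in series across the foundation thickness (effective modulus
#' = harmonic mean); `"arithmetic"` averages them; `"tibial"` uses the
#' tibial layer alone.  The meniscus modulus and Poisson's ratio are
#' carried as metadata: an independent-spring foundation uses moduli
#' directly, with no lateral coupling, and meniscal load sharing is not
#' modelled.
#'
#' @param femoral_modulus Femoral cartilage modulus, MPa (default 8.6).
#' @param tibial_uncovered_modulus Uncovered tibial cartilage modulus,
#'   MPa (default 4.0).
#' @param tibial_covered_modulus Modulus of tibial cartilage beneath the
#'   meniscus, MPa (default 10.1).
#' @param meniscus_modulus Meniscus modulus, MPa (default 1.3; inert).
#' @param poisson_ratio Poisson's ratio (default 0.45; metadata).
#' @param modulus_rule One of `"harmonic"`, `"arithmetic"`, `"tibial"`.
#' @return An object of class `cartilage_material`.
#' @export
cartilage_material <- function(femoral_modulus = 8.6,
                               tibial_uncovered_modulus = 4.0,
                               tibial_covered_modulus = 10.1,
                               meniscus_modulus = 1.3,
                               poisson_ratio = 0.45,
                               modulus_rule = c("harmonic", "arithmetic",
                                                "tibial")) {
  modulus_rule <- match.arg(modulus_rule)
  moduli <- c(femoral_modulus, tibial_uncovered_modulus,
              tibial_covered_modulus, meniscus_modulus)
  if (any(moduli <= 0)) stop("all moduli must be positive")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("'poisson_ratio' must lie in [0, 0.5)")
  structure(
    list(femoral_modulus = femoral_modulus,
         tibial_uncovered_modulus = tibial_uncovered_modulus,
         tibial_covered_modulus = tibial_covered_modulus,
         meniscus_modulus = meniscus_modulus,
         poisson_ratio = poisson_ratio,
         modulus_rule = modulus_rule),
    class = "cartilage_material")
}

#' @export
print.cartilage_material <- function(x, ...) {
  cat("Cartilage material (MPa): femoral", x$femoral_modulus,
      "| tibial uncovered", x$tibial_uncovered_modulus,
      "| tibial covered", x$tibial_covered_modulus,
      "| meniscus", x$meniscus_modulus, "\n")
  cat("  effective-modulus rule:", x$modulus_rule,
      "| Poisson", x$poisson_ratio, "\n")
  invisible(x)
}

#' Effective element modulus under a combination rule
#'
#' @param material A [cartilage_material()] object.
#' @param covered Logical vector: is the element beneath the meniscus?
#' @return Effective modulus in MPa, one value per element.
#' @export
effective_modulus <- function(material, covered) {
  ef <- material$femoral_modulus
  et <- ifelse(covered, material$tibial_covered_modulus,
               material$tibial_uncovered_modulus)
  switch(material$modulus_rule,
         harmonic = 2 * ef * et / (ef + et),
         arithmetic = (ef + et) / 2,
         tibial = et)
}

#' Build the tibial plateau contact mesh
#'
#' Regular grid of spring elements at `element_spacing`, centred on the
#' plateau.  Elements are marked as meniscus-covered from the periphery
#' inward (ranked by mediolateral distance from the centreline, ties by
#' anteroposterior distance) until the covered fraction reaches
#' `meniscus_coverage`, reflecting the peripheral, ring-like footprint
#' of the meniscus; each element then carries the effective modulus of
#' its region.
#'
#' @param geometry A [knee_geometry()] object.
#' @param material A [cartilage_material()] object.
#' @return A data frame of class `contact_mesh` with columns `x_ap`,
#'   `y_ml` (element centres, mm), `area` (mm^2), `covered` (logical)
#'   and `modulus` (MPa); geometry and material attached as attributes.
#' @examples
#' mesh <- build_mesh()
#' nrow(mesh)            # 7326 elements at defaults
#' mean(mesh$covered)    # ~0.46
#' @export
build_mesh <- function(geometry = knee_geometry(),
                       material = cartilage_material()) {
  stopifnot(inherits(geometry, "knee_geometry"),
            inherits(material, "cartilage_material"))
  sp <- geometry$element_spacing
  x <- (seq_len(geometry$mesh_nx_ap) - (geometry$mesh_nx_ap + 1) / 2) * sp
  y <- (seq_len(geometry$mesh_ny_ml) - (geometry$mesh_ny_ml + 1) / 2) * sp
  g <- expand.grid(x_ap = x, y_ml = y, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(g)
  n_cov <- round(geometry$meniscus_coverage * n)
  covered <- logical(n)
  if (n_cov > 0) {
    ord <- order(-abs(g$y_ml), -abs(g$x_ap))
    covered[ord[seq_len(n_cov)]] <- TRUE
  }
  mesh <- data.frame(g, area = sp^2, covered = covered,
                     modulus = effective_modulus(material, covered))
  attr(mesh, "geometry") <- geometry
  attr(mesh, "material") <- material
  class(mesh) <- c("contact_mesh", "data.frame")
  mesh
}

.circ_sag <- function(R, u) {
  # sagitta of a circular arc of radius R at offset u; Inf outside support
  if (!is.finite(R)) return(rep(0, length(u)))
  out <- rep(Inf, length(u))
  ok <- abs(u) < R
  out[ok] <- R - sqrt(R^2 - u[ok]^2)
  out
}

.unloaded_gap <- function(x_ap, y_ml, flexion_angle, geometry) {
  # extra femur-tibia separation relative to the contact apex, unloaded
  rs_f <- if (flexion_angle < geometry$arc_transition_flexion)
    geometry$femoral_sagittal_radius_anterior
  else geometry$femoral_sagittal_radius_posterior
  sag_s <- .circ_sag(rs_f, x_ap) - .circ_sag(geometry$tibial_sagittal_radius, x_ap)
  sag_f <- .circ_sag(geometry$femoral_frontal_radius, y_ml) -
    .circ_sag(geometry$tibial_frontal_radius, y_ml)
  g <- sag_s + sag_f
  g[!is.finite(g)] <- Inf
  pmax(g, 0)
}

#' Height of the femoral surface above the tibial subchondral plane
#'
#' At the unloaded reference (`axis_depth = 0`) the gap at the contact
#' centre equals the unloaded cartilage thickness (zero compression
#' everywhere); lowering the flexion axis (`axis_depth > 0`) translates
#' the whole rigid femoral surface down.  The sagittal profile uses the
#' anterior femoral arc below `arc_transition_flexion` and the posterior
#' arc above it; the frontal profile is the sagitta difference of the
#' femoral frontal arc inside the concave tibial frontal arc.
#'
#' @param x_ap,y_ml Element-centre coordinates, mm.
#' @param flexion_angle Knee flexion angle in degrees.
#' @param axis_depth Lowering of the flexion axis below the unloaded
#'   height, mm.
#' @param geometry A [knee_geometry()] object.
#' @return Surface height in mm (`Inf` where the engaged arc has no
#'   support).
#' @export
femoral_surface_height <- function(x_ap, y_ml, flexion_angle, axis_depth,
                                   geometry = knee_geometry()) {
  geometry$cartilage_thickness - axis_depth +
    .unloaded_gap(x_ap, y_ml, flexion_angle, geometry)
}

#' Compressive strain of a cartilage element
#'
#' Strain is element compression divided by the modelled (unloaded)
#' cartilage height.  Compression equal to or exceeding the thickness is
#' rejected: the logarithmic spring law is singular at full compression.
#'
#' @param compression Element compression in mm, in `[0, thickness)`.
#' @param thickness Unloaded cartilage thickness in mm.
#' @return Strain (dimensionless, in `[0, 1)`).
#' @examples
#' element_strain(1.1, 5)   # 0.22
#' @export
element_strain <- function(compression, thickness) {
  if (any(thickness <= 0)) stop("'thickness' must be positive")
  if (any(compression < 0)) stop("'compression' must be non-negative")
  if (any(compression >= thickness))
    stop("compression reached the cartilage thickness (strain >= 1): ",
         "the logarithmic spring law is singular there")
  compression / thickness
}

#' Compressive stress of a cartilage element
#'
#' Nonlinear-elastic foundation law `sigma = -E * ln(1 - eps)`: stress is
#' non-negative, strictly increasing and convex in strain, and diverges
#' as strain approaches 1.
#'
#' @param strain Element strain in `[0, 1)`.
#' @param effective_modulus Effective element modulus in MPa.
#' @return Stress in MPa.
#' @examples
#' element_stress(1 - exp(-1), 1)   # exactly 1 MPa
#' @export
element_stress <- function(strain, effective_modulus) {
  if (any(strain < 0) || any(strain >= 1))
    stop("'strain' must lie in [0, 1)")
  -effective_modulus * log1p(-strain)
}

.mesh_force <- function(depth, gap, modulus, area, thickness) {
  eps <- pmin(pmax(depth - gap, 0) / thickness, 1 - 1e-12)
  sum(-modulus * log1p(-eps) * area)
}

#' Solve the elastic-foundation contact problem for a target force
#'
#' Starting from the unloaded axis height, the knee flexion axis is
#' lowered (bisection on the axis depth) until the summed element force
#' matches the target medial compressive force.  The force-depth
#' relation is strictly monotone, so the solution is unique; the spring
#' assembly stiffens without bound as the deepest element approaches
#' full compression, so any non-negative target is reachable.
#'
#' @param target_force Target compressive force in N (>= 0).
#' @param flexion_angle Knee flexion angle in degrees at the instant the
#'   force applies (selects the engaged sagittal arc).
#' @param geometry A [knee_geometry()] object.
#' @param material A [cartilage_material()] object.
#' @param mesh Optional pre-built [build_mesh()] result (saves rebuild
#'   cost in loops); must match `geometry`/`material` if supplied.
#' @param tol Force residual tolerance in N (default 0.5).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return An object of class `contact_solution`: axis depth (mm),
#'   flexion angle, per-element `compression` (mm), `strain` and
#'   `stress` (MPa) fields, `total_force` (N), `peak_stress`,
#'   `peak_strain`, `loaded_area` (mm^2) and `stressed_volume` (mm^3,
#'   loaded area x unloaded thickness).
#' @examples
#' sol <- solve_contact(bw_to_newtons(2.68, 69.31), flexion_angle = 18)
#' sol$peak_strain
#' @export
solve_contact <- function(target_force, flexion_angle,
                          geometry = knee_geometry(),
                          material = cartilage_material(),
                          mesh = NULL,
                          tol = 0.5, max_iter = 200) {
  stopifnot(inherits(geometry, "knee_geometry"),
            inherits(material, "cartilage_material"))
  if (target_force < 0) stop("'target_force' must be non-negative")
  if (is.null(mesh)) mesh <- build_mesh(geometry, material)
  h <- geometry$cartilage_thickness
  gap <- .unloaded_gap(mesh$x_ap, mesh$y_ml, flexion_angle, geometry)

  finish <- function(depth, iter, converged) {
    compression <- pmax(depth - gap, 0)
    compression <- pmin(compression, h * (1 - 1e-12))
    strain <- compression / h
    stress <- -mesh$modulus * log1p(-strain)
    loaded <- compression > 0
    loaded_area <- sum(mesh$area[loaded])
    structure(
      list(axis_depth = depth,
           flexion_angle = flexion_angle,
           compression = compression,
           strain = strain,
           stress = stress,
           total_force = sum(stress * mesh$area),
           target_force = target_force,
           peak_stress = if (any(loaded)) max(stress) else 0,
           peak_strain = if (any(loaded)) max(strain) else 0,
           loaded_area = loaded_area,
           stressed_volume = loaded_area * h,
           mesh = mesh,
           iterations = iter,
           converged = converged),
      class = "contact_solution")
  }

  if (target_force == 0) return(finish(0, 0L, TRUE))
  if (all(!is.finite(gap)))
    stop("no element lies under the engaged femoral arc; contact impossible")

  lo <- 0
  hi <- h * (1 - 1e-9)
  f_hi <- .mesh_force(hi, gap, mesh$modulus, mesh$area, h)
  if (f_hi < target_force)
    stop(sprintf(paste0("target force %.1f N unreachable before the strain cap; ",
                        "maximum achievable force is %.1f N"),
                 target_force, f_hi))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    f_mid <- .mesh_force(mid, gap, mesh$modulus, mesh$area, h)
    if (abs(f_mid - target_force) <= tol) return(finish(mid, iter, TRUE))
    if (f_mid < target_force) lo <- mid else hi <- mid
    if (iter >= max_iter)
      stop("contact solver did not converge within ", max_iter,
           " iterations (residual ",
           format(abs(f_mid - target_force), digits = 3), " N)")
  }
}

#' @export
print.contact_solution <- function(x, ...) {
  cat("Elastic-foundation contact solution\n")
  cat(sprintf("  target force %.1f N (achieved %.2f N) at %.1f deg flexion\n",
              x$target_force, x$total_force, x$flexion_angle))
  cat(sprintf("  axis depth %.3f mm | peak strain %.3f | peak stress %.2f MPa\n",
              x$axis_depth, x$peak_strain, x$peak_stress))
  cat(sprintf("  loaded area %.0f mm^2 | stressed volume %.0f mm^3 (%d/%d elements)\n",
              x$loaded_area, x$stressed_volume,
              sum(x$compression > 0), length(x$compression)))
  invisible(x)
}
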