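test_that("default mesh has 7326 elements with near-nominal meniscus coverage", {
  mesh <- build_mesh()
  expect_identical(nrow(mesh), 7326L)
  expect_equal(unique(mesh$area), 0.25)
  # covered fraction within one mediolateral element-row of the target
  expect_lt(abs(mean(mesh$covered) - 0.46), 1 / 66)
  # covered band is peripheral: every fully covered row lies outside
  expect_gt(mean(abs(mesh$y_ml[mesh$covered])),
            mean(abs(mesh$y_ml[!mesh$covered])))
})

test_that("custom meshes honour spacing, dimensions and coverage limits", {
  g <- knee_geometry(mesh_nx_ap = 10, mesh_ny_ml = 10, element_spacing = 1.0)
  mesh <- build_mesh(g)
  expect_identical(nrow(mesh), 100L)
  expect_equal(unique(mesh$area), 1.0)
  g0 <- knee_geometry(meniscus_coverage = 0)
  expect_false(any(build_mesh(g0)$covered))
})

test_that("effective modulus rules combine the layer moduli as documented", {
  mat_h <- cartilage_material(modulus_rule = "harmonic")
  expect_equal(effective_modulus(mat_h, TRUE), 2 * 8.6 * 10.1 / (8.6 + 10.1))
  expect_equal(effective_modulus(mat_h, FALSE), 2 * 8.6 * 4.0 / (8.6 + 4.0))
  mat_a <- cartilage_material(modulus_rule = "arithmetic")
  expect_equal(effective_modulus(mat_a, c(TRUE, FALSE)),
               c((8.6 + 10.1) / 2, (8.6 + 4.0) / 2))
  mat_t <- cartilage_material(modulus_rule = "tibial")
  expect_equal(effective_modulus(mat_t, c(TRUE, FALSE)), c(10.1, 4.0))
})

test_that("element strain is compression over thickness with a singular cap", {
  expect_equal(element_strain(0, 5), 0)
  expect_equal(element_strain(1.1, 5), 0.22)
  expect_error(element_strain(5, 5), "singular")
  expect_error(element_strain(-0.1, 5), "non-negative")
})

test_that("logarithmic spring law: anchors, monotonicity and convexity", {
  expect_equal(element_stress(0, 8.6), 0)
  expect_equal(element_stress(1 - exp(-1), 1), 1)
  # representative covered-cartilage stress-strain pair
  expect_equal(element_stress(0.21, 10.19), 2.40, tolerance = 0.005)
  eps <- seq(0, 0.9, by = 0.01)
  sig <- element_stress(eps, 10)
  expect_true(all(diff(sig) > 0))              # strictly increasing
  expect_true(all(diff(diff(sig)) > 0))        # convex
  expect_error(element_stress(1, 10), "\\[0, 1\\)")
})

test_that("unloaded femoral surface calibration and frontal sagitta", {
  g <- knee_geometry()
  # at the contact apex with the axis at unloaded height: gap = thickness
  expect_equal(femoral_surface_height(0, 0, 18, 0, g), 5.0)
  # 5 mm mediolateral excursion: gap grows by the 20 vs 21 mm sagitta difference
  dgap <- femoral_surface_height(0, 5, 18, 0, g) -
    femoral_surface_height(0, 0, 18, 0, g)
  sag_expected <- (20 - sqrt(20^2 - 25)) - (21 - sqrt(21^2 - 25))
  expect_equal(dgap, sag_expected, tolerance = 1e-12)
  # lowering the axis rigidly lowers the surface
  expect_equal(femoral_surface_height(3, -4, 18, 0.7, g),
               femoral_surface_height(3, -4, 18, 0, g) - 0.7)
})

test_that("solver matches the closed-form single-spring inversion", {
  g1 <- single_spring_geometry(spacing = 2)
  mat <- cartilage_material()
  e_unc <- effective_modulus(mat, FALSE)
  for (f_target in c(5, 50, 200)) {
    sol <- solve_contact(f_target, 10, g1, mat, tol = 1e-7)
    d_exact <- 5 * (1 - exp(-f_target / (e_unc * 4)))
    expect_equal(sol$axis_depth, d_exact, tolerance = 1e-6)
    expect_equal(sol$total_force, f_target, tolerance = 1e-6)
  }
})

test_that("solver matches the closed form on a two-element mesh", {
  g2 <- knee_geometry(mesh_nx_ap = 2, mesh_ny_ml = 1, element_spacing = 0.5,
                      meniscus_coverage = 0)
  mat <- cartilage_material()
  e_unc <- effective_modulus(mat, FALSE)
  # both elements sit at x = +/- 0.25 mm with identical arc gap
  gap <- (35 - sqrt(35^2 - 0.25^2)) - (37 - sqrt(37^2 - 0.25^2))
  f_target <- 30
  sol <- solve_contact(f_target, 10, g2, mat, tol = 1e-7)
  d_exact <- gap + 5 * (1 - exp(-f_target / (2 * e_unc * 0.25)))
  expect_equal(sol$axis_depth, d_exact, tolerance = 1e-6)
})

test_that("zero target force returns the unloaded state", {
  sol <- solve_contact(0, 18)
  expect_equal(sol$axis_depth, 0)
  expect_true(all(sol$strain == 0))
  expect_equal(sol$loaded_area, 0)
  expect_equal(sol$stressed_volume, 0)
})

test_that("converged solutions satisfy the field invariants", {
  sol <- solve_contact(1500, 18, tol = 0.5)
  expect_lt(abs(sol$total_force - 1500), 0.5)
  expect_true(all(sol$strain >= 0 & sol$strain < 1))
  expect_true(all(sol$stress >= 0))
  expect_identical(sol$stress == 0, sol$compression == 0)
  expect_equal(sol$stressed_volume, sol$loaded_area * 5)
  expect_equal(sum(sol$stress * sol$mesh$area), sol$total_force)
  # mediolateral symmetry of the stress field under symmetric geometry
  m <- sol$mesh
  key <- paste(m$x_ap, -m$y_ml)
  mirror <- match(key, paste(m$x_ap, m$y_ml))
  expect_equal(sol$stress, sol$stress[mirror], tolerance = 1e-12)
})

test_that("axis depth and total force increase together", {
  forces <- c(200, 600, 1200, 1800)
  depths <- vapply(forces, function(f) solve_contact(f, 18)$axis_depth,
                   numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("the flatter anterior arc spreads load over a larger footprint", {
  f <- 1200
  below <- solve_contact(f, 10)   # anterior arc engaged
  above <- solve_contact(f, 45)   # posterior arc engaged
  expect_gt(below$loaded_area, above$loaded_area)
  expect_lt(below$peak_strain, above$peak_strain)
})

test_that("peak stress is grid-converged at the default spacing", {
  f <- 1822
  coarse <- solve_contact(f, 18)
  g_fine <- knee_geometry(element_spacing = 0.25, mesh_nx_ap = 222,
                          mesh_ny_ml = 132)
  fine <- solve_contact(f, 18, g_fine)
  expect_lt(abs(fine$peak_stress - coarse$peak_stress) / coarse$peak_stress,
            0.02)
})

test_that("unreachable targets and invalid geometry are rejected", {
  g1 <- single_spring_geometry()
  expect_error(solve_contact(1e9, 10, g1), "unreachable")
  expect_error(solve_contact(-5, 10), "non-negative")
  expect_error(knee_geometry(tibial_sagittal_radius = 30), "exceed")
  expect_error(knee_geometry(meniscus_coverage = 1.5), "\\[0, 1\\]")
  expect_error(cartilage_material(poisson_ratio = 0.5), "0.5")
})
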