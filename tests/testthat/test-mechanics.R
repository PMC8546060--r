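# shared small grid keeps the suite fast; physics checks that need the
# default grid say so explicitly
fast_grid <- list(spacing = 8, margin_x = 80, margin_y = 60)

test_that("zero eigenstrain gives a zero field and doubling strain doubles force", {
  s0 <- solve_displacement_field(layer_model(eigenstrain = 0), fast_grid)
  expect_equal(max(abs(s0$ux)), 0)
  expect_equal(max(abs(s0$uy)), 0)
  expect_equal(s0$force_un, 0)
  expect_equal(s0$realized_fs, 0)

  s1 <- solve_displacement_field(layer_model(eigenstrain = 0.05), fast_grid)
  s2 <- solve_displacement_field(layer_model(eigenstrain = 0.10), fast_grid)
  expect_equal(s2$force_un / s1$force_un, 2, tolerance = 0.01)
  expect_equal(s2$realized_fs / s1$realized_fs, 2, tolerance = 0.01)
  expect_gt(s1$force_un, 0)
  expect_lt(s1$residual, 1e-8)
})

test_that("half-space point response matches the Boussinesq closed form", {
  m <- layer_model(thickness = Inf)
  x <- seq(-100, 100, by = 2); y <- seq(-100, 100, by = 2)
  TX <- matrix(0, length(y), length(x))
  P <- 100                              # nN, at the origin
  TX[51, 51] <- P
  u <- surface_displacement(m, TX, x, y)
  # transverse to the load direction, u_x = P (1 - nu^2) / (pi E r)
  for (ri in c(8, 20, 40, 80)) {
    got <- u$ux[which(y == ri), which(x == 0)]
    want <- P * (1 - m$nu_substrate^2) / (pi * m$E_substrate * ri)
    expect_equal(got, want, tolerance = 0.05)
  }
  # superposition: solutions add to machine precision
  T2 <- matrix(0, length(y), length(x)); T2[40, 70] <- -35
  u2 <- surface_displacement(m, T2, x, y)
  u12 <- surface_displacement(m, TX + T2, x, y)
  expect_lt(max(abs(u12$ux - (u$ux + u2$ux))), 1e-12)
})

test_that("thicker substrates monotonically approach the half space", {
  sw <- thickness_decoupling_sweep(layer_model(eigenstrain = 0.05),
                                   h_values = c(10, 20, 40, 70, 150),
                                   grid = fast_grid)
  expect_true(all(diff(sw$deviation) < 0))
  expect_lt(sw$deviation[sw$h_um == 70], sw$deviation[sw$h_um == 40])
  # plateau: the decay flattens with increasing thickness
  expect_lt(sw$deviation[5] / sw$deviation[1], 0.2)
})

test_that("neighbouring micropatterns are mechanically decoupled", {
  m <- layer_model(eigenstrain = 0.05)
  nc_ <- neighbor_coupling(m, gaps = c(60, 120, 240), axis = "long")
  expect_true(all(diff(nc_$coupling) < 0))     # decays with gap
  layout <- neighbor_coupling(m, gaps = c(240, 80),
                              axis = c("long", "short"))
  expect_true(all(layout$coupling < 0.1))
  # zero gap: the contour touches the tissue end, where the displacement is
  # near its global maximum
  z <- neighbor_coupling(m, gaps = 0, axis = "long")
  expect_gt(z$coupling, 0.6)
  expect_lte(z$coupling, 1)
})

test_that("inner-50% ROI spans are least sensitive to placement", {
  m <- layer_model(eigenstrain = 0.05)
  rp <- roi_placement_sensitivity(m, span_fracs = c(0.5, 0.8, 0.9))
  g <- setNames(abs(rp$gradient), rp$span_frac)
  expect_lte(g[["0.5"]], g[["0.8"]])
  expect_lte(g[["0.8"]], g[["0.9"]])    # end placements are worst

  # oracle: a uniform-strain displacement field has zero placement error
  fake <- structure(list(
    tissue_x = seq(-154, 154, length.out = 101),
    tissue_u = -0.05 * seq(-154, 154, length.out = 101),
    model = list(geometry = tissue_geometry(center = c(0, 0)))),
    class = "mechanics_solution")
  rp0 <- roi_placement_sensitivity(fake, span_fracs = c(0.3, 0.5, 0.8))
  expect_true(all(abs(rp0$rel_error) < 1e-9))
  expect_true(all(abs(rp0$gradient) < 1e-9))
})

test_that("shortening-force curve rises from the origin with minor modulus sensitivity", {
  fc <- fs_force_curve(layer_model(), eigenstrains = c(0.02, 0.05, 0.1))
  expect_true(all(diff(fc$curve$force_un) > 0))
  expect_true(all(diff(fc$curve$realized_fs) > 0))
  expect_equal(fc$curve$force_un[2] / fc$curve$realized_fs[2],
               fc$curve$force_un[1] / fc$curve$realized_fs[1],
               tolerance = 0.01)          # passes through the origin
  expect_lt(fc$modulus_sensitivity, 0.2)  # E_tissue 8-12 kPa: minor
  expect_gt(fc$modulus_sensitivity, 0)
  # doubling the substrate modulus of a rigidly bonded tissue doubles the
  # force at fixed realized shortening (substrate-dominated stiffness)
  s1 <- solve_displacement_field(layer_model(eigenstrain = 0.05,
                                             adhesion_stiffness = Inf),
                                 fast_grid)
  s2 <- solve_displacement_field(layer_model(E_substrate = 16,
                                             eigenstrain = 0.05,
                                             adhesion_stiffness = Inf),
                                 fast_grid)
  expect_equal((s2$force_un / s2$realized_fs) / (s1$force_un / s1$realized_fs),
               2, tolerance = 0.1)
})

test_that("the field is grid-converged", {
  m <- layer_model(eigenstrain = 0.05)
  s4 <- solve_displacement_field(m, list(spacing = 4))
  s2 <- solve_displacement_field(m, list(spacing = 2))
  expect_equal(max(abs(s4$ux)), max(abs(s2$ux)), tolerance = 0.02)
})

test_that("solutions round-trip through the field/summary writers", {
  dir <- withr::local_tempdir()
  sol <- solve_displacement_field(layer_model(eigenstrain = 0.05), fast_grid)
  paths <- write_mechanics_solution(sol, file.path(dir, "sol"))
  field <- read.csv(file.path(dir, "sol_field.csv"))
  expect_equal(nrow(field), length(sol$x) * length(sol$y))
  expect_equal(max(abs(field$ux_um)), max(abs(sol$ux)), tolerance = 1e-12)
  summ <- jsonlite::read_json(file.path(dir, "sol_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$force_un, sol$force_un, tolerance = 1e-12)
  expect_equal(summ$model$eigenstrain, 0.05)
})

test_that("model invariants are validated", {
  expect_error(layer_model(nu_substrate = 0.6), "nu_substrate")
  expect_error(layer_model(eigenstrain = 0.5), "eigenstrain")
  expect_error(layer_model(E_substrate = -3), "E_substrate")
  expect_error(layer_model(thickness = 0), "thickness")
})
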