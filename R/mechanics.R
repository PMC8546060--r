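#' Elastic substrate + contractile tissue model
#'
#' Quasi-static linear elasticity for a thin rectangular tissue strip with
#' an imposed axial contractile eigenstrain, bonded to the surface of a
#' soft elastomer layer of finite thickness on rigid glass. The substrate
#' surface response to tangential traction uses the Boussinesq--Cerruti
#' half-space Green's function
#' \deqn{G_{ij}(r) = \frac{1+\nu}{\pi E r}\left[(1-\nu)\delta_{ij} +
#'   \nu \frac{r_i r_j}{r^2}\right]}
#' attenuated by a finite-thickness factor `1 / (1 + (r/h)^3)` that
#' recovers the half space as `h` grows and the local (Winkler-like,
#' `u ~ tau h / E`) response of a thin bonded layer as `h` shrinks. This is
#' a documented qualitative surrogate for the exact layered solution: the
#' suppression of long-range transmission and its thickness scaling are
#' captured, not the exact layered kernel.
#'
#' @param E_substrate substrate Young's modulus, kPa (8 kPa PDMS default).
#' @param nu_substrate substrate Poisson ratio (`0 <= nu < 0.5`;
#'   near-incompressible elastomer default 0.49).
#' @param thickness substrate layer thickness `h`, um (`Inf` = half space).
#' @param E_tissue tissue Young's modulus, kPa (cardiac range 8--12).
#' @param tissue_thickness tissue thickness, um.
#' @param adhesion_stiffness cell--substrate adhesion stiffness, kPa/um
#'   (traction per unit tissue--surface slip; `Inf` = rigidly bonded).
#'   The default places the shear-lag coupling length
#'   `sqrt(E_tissue * tissue_thickness / Y)` at roughly a quarter of the
#'   bundle length, the regime in which the interior of the bundle carries
#'   distributed strain as observed experimentally.
#' @param geometry a [tissue_geometry()]; default centred 308 x 45 um.
#' @param eigenstrain imposed axial contractile strain (0 to 0.2); the
#'   stress-free shortening the active tissue would undergo if uncoupled.
#' @return A `layer_model`.
#' @export
layer_model <- function(E_substrate = 8, nu_substrate = 0.49,
                        thickness = 70, E_tissue = 10,
                        tissue_thickness = 8, adhesion_stiffness = 0.015,
                        geometry = NULL, eigenstrain = 0.05) {
  if (is.null(geometry)) geometry <- tissue_geometry(center = c(0, 0))
  check_scalar_pos(E_substrate, "E_substrate")
  check_scalar_pos(E_tissue, "E_tissue")
  check_scalar_pos(tissue_thickness, "tissue_thickness")
  if (nu_substrate < 0 || nu_substrate >= 0.5)
    stop_mbk("nu_substrate must lie in [0, 0.5)")
  if (!(thickness > 0)) stop_mbk("thickness must be positive")
  if (eigenstrain < 0 || eigenstrain > 0.2)
    stop_mbk("eigenstrain must lie in [0, 0.2]")
  if (!(adhesion_stiffness > 0)) stop_mbk("adhesion_stiffness must be positive")
  structure(list(E_substrate = E_substrate, nu_substrate = nu_substrate,
                 thickness = thickness, E_tissue = E_tissue,
                 tissue_thickness = tissue_thickness,
                 adhesion_stiffness = adhesion_stiffness,
                 geometry = geometry, eigenstrain = eigenstrain),
            class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("<layer_model> substrate %.1f kPa (nu %.2f), h = %s um\n",
              x$E_substrate, x$nu_substrate,
              if (is.finite(x$thickness)) sprintf("%.0f", x$thickness) else "Inf"))
  cat(sprintf("  tissue %.1f kPa, %.0f um thick, %.0f x %.0f um, eigenstrain %.1f%%\n",
              x$E_tissue, x$tissue_thickness, x$geometry$length,
              x$geometry$width, 100 * x$eigenstrain))
  invisible(x)
}

# finite-thickness attenuation of the surface Green's function
layer_atten <- function(r, h) {
  if (!is.finite(h)) return(rep(1, length(r)))
  1 / (1 + (r / h)^3)
}

# Surface Green's function components (displacement per unit tangential
# point force along x), units: um per (kPa um^2)
green_xx <- function(x, y, E, nu, h) {
  r <- sqrt(x^2 + y^2)
  g <- (1 + nu) / (pi * E * r) * ((1 - nu) + nu * x^2 / r^2)
  g * layer_atten(r, h)
}
green_xy <- function(x, y, E, nu, h) {
  r <- sqrt(x^2 + y^2)
  g <- (1 + nu) / (pi * E * r) * (nu * x * y / r^2)
  g * layer_atten(r, h)
}

# 1-D coupling kernel: surface x-displacement on the tissue midline at x_i
# per unit x-force applied as a uniform patch (dx along x, full width w in
# y) centred at x_j.  Numerical patch quadrature (no singular self term
# because the y-integration spreads the load).
coupling_kernel <- function(x_nodes, dx, w, E, nu, h, nq = c(6L, 12L)) {
  # even quadrature counts keep midpoints off the r = 0 singularity
  n <- length(x_nodes)
  xq <- seq(-dx / 2, dx / 2, length.out = nq[1] + 1L)
  xq <- (xq[-1] + xq[-length(xq)]) / 2
  yq <- seq(-w / 2, w / 2, length.out = nq[2] + 1L)
  yq <- (yq[-1] + yq[-length(yq)]) / 2
  wq <- 1 / (nq[1] * nq[2])
  # kernel depends only on the node separation: build one row
  sep <- c(0, x_nodes[-1] - x_nodes[1])
  row <- vapply(sep, function(s) {
    gx <- outer(s - xq, -yq, function(a, b) green_xx(a, b, E, nu, h))
    sum(gx) * wq
  }, numeric(1))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) K[i, ] <- row[abs(seq_len(n) - i) + 1L]
  K
}

#' Solve the coupled tissue--substrate displacement field
#'
#' Shear-lag formulation: the tissue is a thin elastic strip whose axial
#' stress is `E_t (du/dx + e)` (eigenstrain `e > 0` contracts), in
#' equilibrium with the shear traction it transmits to the substrate
#' surface; the substrate surface displacement under that traction follows
#' the layered Green's function; and the tissue displacement equals the
#' surface displacement plus the adhesion-layer slip (`traction / Y`,
#' which vanishes for a rigid bond). The resulting linear system is solved
#' directly and
#' verified self-consistent (relative residual below `tol`; a failed check
#' raises an error with the residual). The 1-D traction solution is then
#' spread over the tissue footprint and convolved (FFT) with the surface
#' Green's function to give the 2-D surface displacement field.
#'
#' @param model a [layer_model()].
#' @param grid list: `spacing` (um between field points), `margin_x`,
#'   `margin_y` (field extent beyond the tissue, um), `n_tissue`
#'   (1-D tissue nodes).
#' @param tol relative residual tolerance for the self-consistency check.
#' @return A `mechanics_solution`: `x`, `y` (field coordinates, um,
#'   tissue-centred), `ux`, `uy` (surface displacement, um),
#'   `tissue_x`, `tissue_u` (1-D tissue displacement, um),
#'   `traction` (nodal axial force on the substrate, kPa um^2 = nN),
#'   `force_un` (total axial reaction force, uN), `traction_per_width`
#'   (width-normalized force, uN/mm), `realized_fs` (end-to-end realized
#'   fractional shortening), `residual` and `model`.
#' @examples
#' sol <- solve_displacement_field(layer_model(eigenstrain = 0.05))
#' sol$realized_fs
#' sol$traction_per_width
#' @export
solve_displacement_field <- function(model, grid = list(), tol = 1e-8) {
  g <- model$geometry
  spacing <- grid$spacing %||% 4
  margin_x <- grid$margin_x %||% 260
  margin_y <- grid$margin_y %||% 100
  n <- grid$n_tissue %||% 155L
  L <- g$length; w <- g$width
  E_s <- model$E_substrate; nu <- model$nu_substrate; h <- model$thickness
  EA <- model$E_tissue * model$tissue_thickness * w   # kPa um^2
  e <- model$eigenstrain
  dx <- L / (n - 1L)
  x_nodes <- seq(-L / 2, L / 2, length.out = n)
  K <- coupling_kernel(x_nodes, dx, w, E_s, nu, h)
  # tissue displacement = surface displacement + adhesion-layer slip
  # (series compliance; slip = traction / Y)
  Y <- model$adhesion_stiffness
  Kt <- K + diag(if (is.finite(Y)) 1 / (Y * dx * w) else 0, n)
  # tissue FD operator rows applied to u, and the traction coupling:
  #   interior: EA (u[i-1] - 2 u[i] + u[i+1]) / dx^2 - q[i]/dx = 0
  #   ends:     (u[2] - u[1])/dx = -e ;  (u[n] - u[n-1])/dx = -e
  M <- matrix(0, n, n)
  S <- diag(1 / dx, n)
  b <- numeric(n)
  for (i in 2:(n - 1L)) {
    M[i, i - 1L] <- EA / dx^2
    M[i, i] <- -2 * EA / dx^2
    M[i, i + 1L] <- EA / dx^2
  }
  M[1L, 1L] <- -1 / dx; M[1L, 2L] <- 1 / dx; b[1L] <- -e
  S[1L, 1L] <- 0
  M[n, n - 1L] <- -1 / dx; M[n, n] <- 1 / dx; b[n] <- -e
  S[n, n] <- 0
  A <- M %*% Kt - S
  q <- solve(A, b)
  u <- as.numeric(Kt %*% q)      # tissue displacement
  res <- sqrt(sum((A %*% q - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (!is.finite(res) || res > tol)
    stop_mbk("coupled solve failed self-consistency (relative residual %.3g)",
             res)
  # realized shortening (end to end; u symmetric, ends move inward)
  realized_fs <- (u[1L] - u[n]) / L
  # axial reaction force: tension transmitted at the bundle midline
  force_nN <- abs(sum(q[x_nodes > 0]))
  force_un <- force_nN / 1000
  traction_per_width <- force_un / (w / 1000)   # uN / mm
  # ---- 2-D surface field by FFT convolution ----
  xf <- seq(-L / 2 - margin_x, L / 2 + margin_x, by = spacing)
  yf <- seq(-w / 2 - margin_y, w / 2 + margin_y, by = spacing)
  TX <- matrix(0, length(yf), length(xf))
  # fraction of each grid row covered by the tissue width (partial cells at
  # the edges), so the deposited footprint is exactly w at any spacing
  wy <- pmax(0, pmin(yf + spacing / 2, w / 2) - pmax(yf - spacing / 2, -w / 2))
  iy <- which(wy > 0)
  rowwt <- wy[iy] / sum(wy[iy])
  # deposit nodal forces as surface traction density (kPa) over the width,
  # tent-weighted between the two nearest grid columns to avoid aliasing
  for (j in seq_len(n)) {
    pos <- (x_nodes[j] - xf[1]) / spacing
    i0 <- max(0L, min(length(xf) - 2L, floor(pos)))
    fr <- pos - i0
    dep <- q[j] * rowwt / spacing^2
    TX[iy, i0 + 1L] <- TX[iy, i0 + 1L] + dep * (1 - fr)
    TX[iy, i0 + 2L] <- TX[iy, i0 + 2L] + dep * fr
  }
  ux <- conv_green(TX, xf, yf, spacing, function(x, y)
    green_xx(x, y, E_s, nu, h), self = green_self_xx(E_s, nu, spacing))
  uy <- conv_green(TX, xf, yf, spacing, function(x, y)
    green_xy(x, y, E_s, nu, h), self = 0)
  structure(list(x = xf, y = yf, ux = ux, uy = uy,
                 tissue_x = x_nodes, tissue_u = u, traction = q,
                 force_un = force_un,
                 traction_per_width = traction_per_width,
                 realized_fs = realized_fs, residual = res, model = model),
            class = "mechanics_solution")
}

# angular average of the direction factor (1-nu) + nu cos^2 over a cell,
# times the cell-averaged 1/r integral (unit square: 3.5255 a)
green_self_xx <- function(E, nu, a) {
  (1 + nu) * (1 - nu / 2) / (pi * E) * 3.5255 / a
}

# FFT convolution of a traction-density field (kPa) with a Green kernel
# (um per kPa um^2); returns displacement in um
conv_green <- function(TX, xf, yf, spacing, gfun, self) {
  nr <- length(yf); ncl <- length(xf)
  # kernel on a grid twice the field size, wrap-around ordering
  kx <- c(0:(ncl - 1L), -(ncl:1L)) * spacing
  ky <- c(0:(nr - 1L), -(nr:1L)) * spacing
  KX <- outer(rep(1, length(ky)), kx)
  KY <- outer(ky, rep(1, length(kx)))
  G <- gfun(KX, KY)
  G[1L, 1L] <- self
  G[!is.finite(G)] <- 0
  # cell-average the kernel where it varies strongly (within 2 cells of the
  # singularity): point sampling there dominates the discretization error
  qq <- seq(-0.5 + 1 / 8, 0.5 - 1 / 8, length.out = 4L) * spacing
  near <- which(abs(KX) <= 2 * spacing & abs(KY) <= 2 * spacing &
                  (KX != 0 | KY != 0), arr.ind = TRUE)
  for (idx in seq_len(nrow(near))) {
    i <- near[idx, 1L]; j <- near[idx, 2L]
    G[i, j] <- mean(gfun(outer(rep(1, 4L), KX[i, j] + qq),
                         outer(KY[i, j] + qq, rep(1, 4L))))
  }
  P <- matrix(0, 2L * nr, 2L * ncl)
  P[1:nr, 1:ncl] <- TX * spacing^2
  out <- Re(fft(fft(P) * fft(G), inverse = TRUE)) / length(P)
  out[1:nr, 1:ncl]
}

#' Surface displacement under an arbitrary tangential traction
#'
#' Direct evaluation of the substrate surface response (no tissue
#' coupling): useful for point-load checks against the closed-form
#' half-space solution and for superposition tests.
#'
#' @param model a [layer_model()] (only the substrate parameters are used).
#' @param traction_x matrix of x-directed nodal forces (kPa um^2 = nN) on
#'   the field grid.
#' @param x,y field coordinates, um (length matching `traction_x` dims:
#'   rows = y, cols = x).
#' @return List `ux`, `uy` (um).
#' @export
surface_displacement <- function(model, traction_x, x, y) {
  spacing <- x[2] - x[1]
  TX <- traction_x / spacing^2
  ux <- conv_green(TX, x, y, spacing, function(a, b)
    green_xx(a, b, model$E_substrate, model$nu_substrate, model$thickness),
    self = green_self_xx(model$E_substrate, model$nu_substrate, spacing))
  uy <- conv_green(TX, x, y, spacing, function(a, b)
    green_xy(a, b, model$E_substrate, model$nu_substrate, model$thickness),
    self = 0)
  list(ux = ux, uy = uy)
}

#' @export
print.mechanics_solution <- function(x, ...) {
  cat(sprintf("<mechanics_solution> realized fs %.2f%%, force %.3f uN (%.1f uN/mm)\n",
              100 * x$realized_fs, x$force_un, x$traction_per_width))
  cat(sprintf("  field %d x %d points, residual %.2g\n",
              length(x$x), length(x$y), x$residual))
  invisible(x)
}

#' @export
plot.mechanics_solution <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2)
  graphics::image(x$x, x$y, t(mag), xlab = "x (um)", ylab = "y (um)",
                  main = "|surface displacement| (um)", ...)
  g <- x$model$geometry
  graphics::rect(-g$length / 2, -g$width / 2, g$length / 2, g$width / 2,
                 border = "white", lwd = 2)
  invisible(x)
}

#' Write a mechanics solution to disk
#'
#' The gridded surface displacement field goes to `<prefix>_field.csv`
#' (long format: `x_um`, `y_um`, `ux_um`, `uy_um`) and the scalar summary
#' (force, realized shortening, model parameters) to `<prefix>_summary.json`.
#'
#' @param solution a [solve_displacement_field()] result.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_mechanics_solution <- function(solution, prefix) {
  field <- data.frame(
    x_um = rep(solution$x, each = length(solution$y)),
    y_um = rep(solution$y, times = length(solution$x)),
    ux_um = as.vector(solution$ux),
    uy_um = as.vector(solution$uy))
  fpath <- paste0(prefix, "_field.csv")
  write.csv(field, fpath, row.names = FALSE)
  m <- solution$model
  spath <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(
    force_un = solution$force_un,
    traction_per_width_un_mm = solution$traction_per_width,
    realized_fs = solution$realized_fs,
    residual = solution$residual,
    model = list(E_substrate_kpa = m$E_substrate,
                 nu_substrate = m$nu_substrate,
                 thickness_um = m$thickness,
                 E_tissue_kpa = m$E_tissue,
                 tissue_thickness_um = m$tissue_thickness,
                 adhesion_stiffness_kpa_um = m$adhesion_stiffness,
                 eigenstrain = m$eigenstrain,
                 length_um = m$geometry$length,
                 width_um = m$geometry$width)),
    spath, auto_unbox = TRUE, digits = NA)
  invisible(c(fpath, spath))
}

#' Mechanical coupling to neighbouring micropatterns
#'
#' For each buffer gap, the coupling metric is the maximum surface
#' displacement magnitude on the buffer-edge contour (the tissue rectangle
#' expanded by the gap) divided by the maximum under the tissue. The
#' standard layout separates bundles by 240 um along the long axis and
#' 80 um along the short axis.
#'
#' @param model a [layer_model()].
#' @param gaps named numeric vector of gap distances, um.
#' @param axis `"long"`, `"short"` or `"both"`: which direction the gap
#'   applies to (recycled against `gaps`).
#' @param solution optional precomputed [solve_displacement_field()] result.
#' @param grid passed to the solver when `solution` is missing.
#' @return Data frame with columns `gap_um`, `axis` and `coupling`.
#' @export
neighbor_coupling <- function(model, gaps = c(240, 80),
                              axis = c("long", "short"),
                              solution = NULL, grid = list()) {
  axis <- rep_len(axis, length(gaps))
  if (is.null(solution)) {
    need_x <- max(gaps[axis != "short"], 0) + 40
    need_y <- max(gaps[axis != "long"], 0) + 40
    solution <- solve_displacement_field(
      model, utils::modifyList(list(margin_x = max(260, need_x),
                                    margin_y = max(100, need_y)), grid))
  }
  g <- model$geometry
  mag <- sqrt(solution$ux^2 + solution$uy^2)
  X <- outer(rep(1, length(solution$y)), solution$x)
  Y <- outer(solution$y, rep(1, length(solution$x)))
  inside <- abs(X) <= g$length / 2 & abs(Y) <= g$width / 2
  ref <- max(mag[inside])
  spacing <- solution$x[2] - solution$x[1]
  coup <- vapply(seq_along(gaps), function(i) {
    # the buffer edge facing the neighbour: offset from the tissue edge by
    # the gap along the relevant axis, spanning the tissue footprint
    if (axis[i] == "short") {
      hy <- g$width / 2 + gaps[i]
      on_edge <- abs(abs(Y) - hy) <= spacing / 2 & abs(X) <= g$length / 2
    } else {
      hx <- g$length / 2 + gaps[i]
      on_edge <- abs(abs(X) - hx) <= spacing / 2 & abs(Y) <= g$width / 2
    }
    if (!any(on_edge)) return(NA_real_)
    max(mag[on_edge]) / ref
  }, numeric(1))
  data.frame(gap_um = gaps, axis = axis, coupling = coup)
}

#' Thickness sweep: deviation from the half-space solution
#'
#' Solves the coupled model for each substrate thickness and reports the
#' normalized maximum difference of the surface displacement field from
#' the infinite-thickness (half-space) solution -- the quantity that decays
#' toward zero as the layer decouples the tissue from the rigid glass
#' below.
#'
#' @param model a [layer_model()]; its `thickness` is overridden.
#' @param h_values thicknesses to evaluate, um.
#' @param grid passed to [solve_displacement_field()].
#' @return Data frame with columns `h_um` and `deviation`
#'   (`max|u_h - u_inf| / max|u_inf|`).
#' @export
thickness_decoupling_sweep <- function(model, h_values = c(10, 20, 40, 70, 150),
                                       grid = list()) {
  solve_h <- function(h) {
    m <- model; m$thickness <- h
    solve_displacement_field(m, grid)
  }
  ref <- solve_h(Inf)
  ref_mag <- sqrt(ref$ux^2 + ref$uy^2)
  dev <- vapply(h_values, function(h) {
    s <- solve_h(h)
    max(sqrt((s$ux - ref$ux)^2 + (s$uy - ref$uy)^2)) / max(ref_mag)
  }, numeric(1))
  data.frame(h_um = h_values, deviation = dev)
}

#' Shortening--force curve and tissue-modulus sensitivity
#'
#' Sweeps the imposed eigenstrain and records the realized fractional
#' shortening against the width-normalized force. The modulus sensitivity
#' is the relative spread (range / mean) of the force at a fixed realized
#' shortening as the tissue modulus varies over `E_range` -- i.e. how much
#' intrinsic tissue-stiffness variability distorts the shortening--force
#' relation.
#'
#' @param model a [layer_model()].
#' @param eigenstrains vector of imposed strains.
#' @param E_range tissue-modulus range, kPa.
#' @param fs_ref realized shortening at which sensitivity is evaluated.
#' @param grid passed to the solver.
#' @return List: `curve` (data frame `eigenstrain`, `realized_fs`,
#'   `force_un`, `traction_per_width`) and `modulus_sensitivity`.
#' @export
fs_force_curve <- function(model, eigenstrains = seq(0.01, 0.12, by = 0.01),
                           E_range = c(8, 12), fs_ref = 0.05,
                           grid = list(spacing = 8, margin_x = 60,
                                       margin_y = 40)) {
  curve <- do.call(rbind, lapply(eigenstrains, function(e) {
    m <- model; m$eigenstrain <- e
    s <- solve_displacement_field(m, grid)
    data.frame(eigenstrain = e, realized_fs = s$realized_fs,
               force_un = s$force_un,
               traction_per_width = s$traction_per_width)
  }))
  # linearity: realized_fs and force are both proportional to e, so the
  # force at fixed realized shortening follows from one solve per modulus
  forces <- vapply(seq(E_range[1], E_range[2], length.out = 5L), function(Et) {
    m <- model; m$E_tissue <- Et; m$eigenstrain <- 0.05
    s <- solve_displacement_field(m, grid)
    s$force_un * fs_ref / s$realized_fs
  }, numeric(1))
  list(curve = curve,
       modulus_sensitivity = diff(range(forces)) / mean(forces))
}

#' Sensitivity of the shortening estimate to ROI placement
#'
#' Using the model's 1-D tissue displacement profile, estimates fractional
#' shortening from ROI pairs placed symmetrically about the centre at a
#' range of span fractions, compares each with the true end-to-end tissue
#' strain, and reports the error and its gradient with respect to span.
#' Placements spanning the inner 50% of the length sit on the flat part of
#' the strain profile, away from the free-end boundary layers, and are the
#' least sensitive to placement error.
#'
#' @param model a [layer_model()] or a precomputed solution.
#' @param span_fracs ROI separations as fractions of tissue length.
#' @param grid passed to the solver when `model` is not yet solved.
#' @return Data frame: `span_frac`, `fs_est`, `rel_error` (vs end-to-end
#'   strain), `gradient` (d fs_est / d span_frac, by central differences).
#' @export
roi_placement_sensitivity <- function(model,
                                      span_fracs = seq(0.2, 0.9, by = 0.05),
                                      grid = list()) {
  sol <- if (inherits(model, "mechanics_solution")) model else
    solve_displacement_field(model, grid)
  L <- sol$model$geometry$length
  if (any(span_fracs <= 0 | span_fracs >= 1))
    stop_mbk("span fractions must lie strictly inside (0, 1)")
  u_at <- function(x) approx(sol$tissue_x, sol$tissue_u, xout = x)$y
  fs_true <- (u_at(-L / 2) - u_at(L / 2)) / L
  fs_est <- vapply(span_fracs, function(s)
    (u_at(-s * L / 2) - u_at(s * L / 2)) / (s * L), numeric(1))
  eps <- 0.01
  grad <- vapply(span_fracs, function(s) {
    sp <- min(s + eps, 0.999); sm <- max(s - eps, 0.001)
    fp <- (u_at(-sp * L / 2) - u_at(sp * L / 2)) / (sp * L)
    fm <- (u_at(-sm * L / 2) - u_at(sm * L / 2)) / (sm * L)
    (fp - fm) / (sp - sm)
  }, numeric(1))
  data.frame(span_frac = span_fracs, fs_est = fs_est,
             rel_error = fs_est / fs_true - 1, gradient = grad)
}
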