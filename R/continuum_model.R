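#' Limb section geometry
#'
#' Geometry of one horizontal measurement section of the leggings--leg
#' system. `garment_stretch` (ul) is the radial extension of the fabric when
#' worn; [garment_stretch_from_circumferences()] derives it from limb and
#' garment circumferences.
#'
#' @param section_id integer 1-6 (1 = high hip ... 6 = calf).
#' @param limb_radius limb cross-section radius R, mm.
#' @param garment_circumference unworn garment circumference at the section,
#'   mm.
#' @param section_height vertical extent of the section, mm.
#' @param garment_stretch radial extension ul of the worn fabric, mm (>= 0).
#' @return an object of class `limb_section_geometry`.
#' @export
limb_section_geometry <- function(section_id, limb_radius,
                                  garment_circumference, section_height,
                                  garment_stretch = 0) {
  assert_scalar_num(limb_radius, "limb_radius", 0, strict_lower = TRUE)
  assert_scalar_num(garment_circumference, "garment_circumference", 0,
                    strict_lower = TRUE)
  assert_scalar_num(section_height, "section_height", 0, strict_lower = TRUE)
  assert_scalar_num(garment_stretch, "garment_stretch", 0)
  structure(list(section_id = as.integer(section_id),
                 limb_radius = limb_radius,
                 garment_circumference = garment_circumference,
                 section_height = section_height,
                 garment_stretch = garment_stretch),
            class = "limb_section_geometry")
}

#' Radial garment stretch from circumferences
#'
#' Circumferential extension is the excess of the limb circumference over
#' the unworn garment circumference (clamped at zero: a loose garment is not
#' stretched); dividing by 2*pi converts it to the radial extension ul used
#' by [interface_pressure()].
#'
#' @param limb_circumference limb circumference at the section, mm.
#' @param garment_circumference unworn garment circumference, mm.
#' @return radial stretch ul in mm.
#' @export
garment_stretch_from_circumferences <- function(limb_circumference,
                                                garment_circumference) {
  pmax(0, limb_circumference - garment_circumference) / (2 * pi)
}

#' Soft-tissue constitutive model
#'
#' Holds the linear-elastic pair (Es, vs) and the equivalent Neo-Hookean
#' pair (C1, D1); supply either pair and the other is derived through
#' [neo_hookean_params()] / [neo_hookean_invert()], keeping the two
#' parameterisations consistent by construction.
#'
#' @param Es tissue Young's modulus, Pa.
#' @param vs tissue Poisson's ratio, in `[0, 0.5)`.
#' @param C1 Neo-Hookean shear-like constant, Pa.
#' @param D1 Neo-Hookean compressibility constant, 1/Pa.
#' @return an object of class `tissue_model` with all four fields.
#' @export
#' @examples
#' tissue_model(Es = 15000, vs = 0.3)
#' tissue_model(C1 = 5000, D1 = 1.4e-7)   # near-incompressible ~30 kPa tissue
tissue_model <- function(Es = NULL, vs = NULL, C1 = NULL, D1 = NULL) {
  if (!is.null(Es) && !is.null(vs)) {
    assert_scalar_num(Es, "Es", 0, strict_lower = TRUE)
    assert_scalar_num(vs, "vs", 0)
    if (vs >= 0.5) stopf("`vs` must be < 0.5 (got %g)", vs)
    nh <- neo_hookean_params(Es, vs)
    C1 <- nh[["C1"]]; D1 <- nh[["D1"]]
  } else if (!is.null(C1) && !is.null(D1)) {
    assert_scalar_num(C1, "C1", 0, strict_lower = TRUE)
    assert_scalar_num(D1, "D1", 0, strict_lower = TRUE)
    lin <- neo_hookean_invert(C1, D1)
    Es <- lin[["Es"]]; vs <- lin[["vs"]]
  } else {
    stopf("supply either (Es, vs) or (C1, D1)")
  }
  structure(list(Es = Es, vs = vs, C1 = C1, D1 = D1), class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> Es=%.4g Pa, vs=%.4f  (C1=%.4g Pa, D1=%.4g 1/Pa)\n",
              x$Es, x$vs, x$C1, x$D1))
  invisible(x)
}

#' Interface pressure from garment stretch
#'
#' Boussinesq-type relation between the radial extension of the worn fabric
#' and the pressure it exerts on the limb:
#' `ul = 2 (1 - vxy^2) P R / (pi Ex)`, solved for P. Pressure is linear in
#' stretch and in the course-direction modulus, and vanishes for an
#' unstretched garment.
#'
#' @param geom a [limb_section_geometry()] (uses `limb_radius` and
#'   `garment_stretch`).
#' @param fabric a [fabric_properties()] (uses `Ex` and `vxy`).
#' @return interface pressure P in Pa.
#' @export
interface_pressure <- function(geom, fabric) {
  if (!inherits(geom, "limb_section_geometry"))
    stopf("`geom` must be a limb_section_geometry")
  if (!inherits(fabric, "fabric_properties"))
    stopf("`fabric` must be a fabric_properties")
  if (geom$limb_radius <= 0) stopf("invalid geometry: limb_radius <= 0")
  pi * fabric$Ex * geom$garment_stretch /
    (2 * (1 - fabric$vxy^2) * geom$limb_radius)
}

#' Lame stress field of the pressurised fabric annulus
#'
#' Closed-form radial and hoop stresses of an annulus with internal radius
#' `a`, external radius `b`, loaded by pressure `P` on the inner face and
#' traction-free on the outer face:
#' sigma_rho(r) = A/r^2 + 2C, sigma_phi(r) = -A/r^2 + 2C with
#' A = -P a^2 b^2 / (b^2 - a^2) and 2C = P a^2 / (b^2 - a^2). The shear
#' stress tau_r_phi is identically zero by axial symmetry.
#'
#' @param a inner radius, mm.
#' @param b outer radius, mm (`b > a`).
#' @param P inner-face pressure, Pa (>= 0).
#' @return object of class `lame_solution` with constants `A` (Pa mm^2) and
#'   `C` (Pa) and vectorised stress functions `sigma_rho(r)`,
#'   `sigma_phi(r)` (r in mm, result in Pa).
#' @export
lame_field <- function(a, b, P) {
  assert_scalar_num(a, "a", 0, strict_lower = TRUE)
  assert_scalar_num(b, "b", 0, strict_lower = TRUE)
  assert_scalar_num(P, "P", 0)
  if (a >= b) stopf("invalid geometry: need b > a > 0 (got a=%g, b=%g)", a, b)
  A <- -P * a^2 * b^2 / (b^2 - a^2)
  twoC <- P * a^2 / (b^2 - a^2)
  structure(list(
    a = a, b = b, P = P, A = A, C = twoC / 2,
    sigma_rho = function(r) A / r^2 + twoC,
    sigma_phi = function(r) -A / r^2 + twoC),
    class = "lame_solution")
}

#' @export
print.lame_solution <- function(x, ...) {
  cat(sprintf("<lame_solution> a=%g mm, b=%g mm, P=%g Pa; A=%.6g Pa*mm^2, 2C=%.6g Pa\n",
              x$a, x$b, x$P, x$A, 2 * x$C))
  invisible(x)
}

#' Neo-Hookean constants from linear-elastic constants
#'
#' Standard conversion `C1 = Es / (4 (1 + vs))` (half the shear modulus) and
#' `D1 = 6 (1 - 2 vs) / Es` (twice the inverse bulk modulus). At exact
#' incompressibility (vs = 0.5) D1 = 0 is returned with a warning.
#'
#' @param Es Young's modulus, Pa.
#' @param vs Poisson's ratio, in `[0, 0.5]`.
#' @return named vector `c(C1 = , D1 = )` in Pa and 1/Pa.
#' @seealso [neo_hookean_invert()]
#' @export
neo_hookean_params <- function(Es, vs) {
  assert_scalar_num(Es, "Es", 0, strict_lower = TRUE)
  assert_scalar_num(vs, "vs", 0, upper = 0.5)
  if (vs == 0.5)
    warnf("vs = 0.5: incompressible limit, D1 = 0")
  c(C1 = Es / (4 * (1 + vs)), D1 = 6 * (1 - 2 * vs) / Es)
}

#' Linear-elastic constants from Neo-Hookean constants
#'
#' Exact inverse of [neo_hookean_params()]:
#' `Es = 18 C1 / (3 + C1 D1)` and `vs = (6 - D1 Es) / 12`.
#'
#' @param C1 Neo-Hookean constant, Pa.
#' @param D1 Neo-Hookean constant, 1/Pa (>= 0).
#' @return named vector `c(Es = , vs = )`.
#' @export
neo_hookean_invert <- function(C1, D1) {
  assert_scalar_num(C1, "C1", 0, strict_lower = TRUE)
  assert_scalar_num(D1, "D1", 0)
  Es <- 18 * C1 / (3 + C1 * D1)
  vs <- (6 - D1 * Es) / 12
  c(Es = Es, vs = vs)
}

#' Static tissue deformation, linear-elastic form
#'
#' Surface deflection of the tissue under the garment's interface pressure:
#' `us = (1 - vs) P R / Es`. Linear in both pressure and limb radius.
#'
#' @param P interface pressure, Pa.
#' @param R limb radius, mm.
#' @param tissue a [tissue_model()].
#' @return tissue deformation us in mm.
#' @export
static_deformation_linear <- function(P, R, tissue) {
  if (!inherits(tissue, "tissue_model")) stopf("`tissue` must be a tissue_model")
  if (tissue$Es <= 0) stopf("invalid tissue: Es <= 0")
  (1 - tissue$vs) * P * R / tissue$Es
}

#' Static tissue deformation, Neo-Hookean parameterisation
#'
#' Same deflection expressed through the Neo-Hookean constants: (C1, D1) are
#' mapped back to (Es, vs) by [neo_hookean_invert()] and substituted into
#' the linear form, so the two routes agree to round-off for any consistent
#' parameter pair. (The tissue operates at small strain under garment
#' pressures; the hyperelastic model only reparameterises the stiffness.)
#'
#' @inheritParams static_deformation_linear
#' @return tissue deformation us in mm.
#' @export
static_deformation_nh <- function(P, R, tissue) {
  if (!inherits(tissue, "tissue_model")) stopf("`tissue` must be a tissue_model")
  if (tissue$C1 <= 0 || tissue$D1 < 0)
    stopf("invalid tissue: need C1 > 0 and D1 >= 0")
  Es <- 18 * tissue$C1 / (3 + tissue$C1 * tissue$D1)
  vs <- (6 - tissue$D1 * Es) / 12
  (1 - vs) * P * R / Es
}

#' Forced damped oscillator description of the vibrating garment
#'
#' @param mass garment section mass m, kg (> 0).
#' @param damping damping coefficient k, N s/m (>= 0).
#' @param forcing function of time (s) returning the inertial force F in N;
#'   vectorised over time.
#' @param u0,v0 initial displacement (m) and velocity (m/s).
#' @param pressure static interface pressure P, Pa, about which the dynamic
#'   load oscillates.
#' @return an object of class `dynamic_system`.
#' @export
dynamic_system <- function(mass, damping = 5, forcing = function(t) 0 * t,
                           u0 = 0, v0 = 0, pressure = 0) {
  assert_scalar_num(mass, "mass", 0, strict_lower = TRUE)
  assert_scalar_num(damping, "damping", 0)
  assert_scalar_num(u0, "u0"); assert_scalar_num(v0, "v0")
  assert_scalar_num(pressure, "pressure", 0)
  if (!is.function(forcing)) stopf("`forcing` must be a function of time")
  structure(list(mass = mass, damping = damping, forcing = forcing,
                 u0 = u0, v0 = v0, pressure = pressure),
            class = "dynamic_system")
}

#' Sinusoidal forcing
#'
#' Convenience constructor `F(t) = F0 sin(2 pi f t)`; the 60 Hz default
#' matches the whole-body vibration protocol.
#'
#' @param F0 force amplitude, N.
#' @param frequency forcing frequency, Hz.
#' @return vectorised function of time (s).
#' @export
sinusoidal_forcing <- function(F0, frequency = 60) {
  force(F0); force(frequency)
  function(t) F0 * sin(2 * pi * frequency * t)
}

# classical 4th-order Runge-Kutta on du/dt = f(t, u), u a numeric vector
rk4 <- function(f, u0, times) {
  n <- length(times)
  out <- matrix(NA_real_, n, length(u0))
  out[1, ] <- u0
  u <- u0
  for (i in seq_len(n - 1L)) {
    t <- times[i]
    h <- times[i + 1L] - t
    k1 <- f(t, u)
    k2 <- f(t + h / 2, u + h / 2 * k1)
    k3 <- f(t + h / 2, u + h / 2 * k2)
    k4 <- f(t + h, u + h * k3)
    u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- u
  }
  out
}

#' Simulate dynamic tissue displacement under vibration
#'
#' Integrates the garment equation of motion `m u'' + k u' = F(t)` with
#' classical 4th-order Runge-Kutta on the first-order system (u, u'), then
#' maps the instantaneous load to tissue displacement through the static
#' Neo-Hookean relation at the effective pressure
#' `P_eff(t) = P + F(t) / A_contact`, where the contact area defaults to the
#' lateral surface of the section, `A_contact = 2 pi R h` (SI m^2). Negative
#' effective pressures (rebound phase) are retained, so the tissue trace can
#' dip below the static level within a cycle.
#'
#' @param sys a [dynamic_system()].
#' @param R limb radius, mm.
#' @param tissue a [tissue_model()].
#' @param t_end integration end time, s.
#' @param dt time step, s (default 1e-4).
#' @param section_height section height used for the contact area, mm.
#' @param contact_area override the contact area, m^2 (optional).
#' @param cycle_period length of one forcing cycle in s, used for the
#'   per-cycle summary (optional; no summary if missing).
#' @return object of class `dynamic_trace`: `times` (s), `u_dl` (garment
#'   displacement, mm), `v_dl` (garment velocity, m/s), `u_ds` (tissue
#'   displacement, mm), and `cycles` (per-cycle max/min/mean of `u_ds`).
#' @export
simulate_dynamic <- function(sys, R, tissue, t_end, dt = 1e-4,
                             section_height = 100, contact_area = NULL,
                             cycle_period = NULL) {
  if (!inherits(sys, "dynamic_system")) stopf("`sys` must be a dynamic_system")
  assert_scalar_num(dt, "dt", 0, strict_lower = TRUE)
  if (t_end <= dt) stopf("`t_end` must exceed `dt`")
  times <- seq(0, t_end, by = dt)
  Fvals <- sys$forcing(times)
  if (!all(is.finite(Fvals)))
    stopf("non-finite forcing at t = %g s", times[which(!is.finite(Fvals))[1L]])
  deriv <- function(t, u) c(u[2L], (sys$forcing(t) - sys$damping * u[2L]) / sys$mass)
  st <- rk4(deriv, c(sys$u0, sys$v0), times)
  if (is.null(contact_area))
    contact_area <- 2 * pi * mm_to_m(R) * mm_to_m(section_height)
  p_eff <- sys$pressure + Fvals / contact_area
  u_ds <- static_deformation_nh(1, R, tissue) * p_eff  # linear in pressure
  cycles <- NULL
  if (!is.null(cycle_period) && cycle_period > 0) {
    idx <- floor(times / cycle_period)
    full <- idx < floor(t_end / cycle_period)  # drop the trailing partial cycle
    if (any(full)) {
      sp <- split(u_ds[full], idx[full])
      cycles <- data.frame(
        cycle = as.integer(names(sp)),
        max = vapply(sp, max, numeric(1)),
        min = vapply(sp, min, numeric(1)),
        mean = vapply(sp, mean, numeric(1)),
        row.names = NULL)
    }
  }
  structure(list(times = times, u_dl = m_to_mm(st[, 1L]), v_dl = st[, 2L],
                 u_ds = u_ds, cycles = cycles),
            class = "dynamic_trace")
}

#' @export
print.dynamic_trace <- function(x, ...) {
  cat(sprintf("<dynamic_trace> %d steps over %.4g s; u_ds in [%.4g, %.4g] mm\n",
              length(x$times), max(x$times), min(x$u_ds), max(x$u_ds)))
  invisible(x)
}

#' Predict static deformation for a batch of sections
#'
#' Batch driver: for each section derives the garment stretch from the limb
#' and garment circumferences, converts it to interface pressure for the
#' given fabric, and evaluates the Neo-Hookean static deformation.
#'
#' @param fabric a [fabric_properties()].
#' @param sections non-empty list of [limb_section_geometry()]; a section
#'   whose `garment_stretch` is zero has it derived from
#'   `2 pi limb_radius` vs `garment_circumference`.
#' @param tissue a [tissue_model()].
#' @param limb_circumferences optional numeric vector overriding the limb
#'   circumference per section (default `2 pi limb_radius`).
#' @return data.frame with one row per section: `section`, `stretch_mm`,
#'   `pressure_pa`, `deformation_mm`; the mean deformation is attached as
#'   attribute `mean_deformation_mm`.
#' @export
predict_sections <- function(fabric, sections, tissue,
                             limb_circumferences = NULL) {
  if (length(sections) == 0L) stopf("`sections` must be non-empty")
  rows <- lapply(seq_along(sections), function(i) {
    g <- sections[[i]]
    if (!inherits(g, "limb_section_geometry"))
      stopf("sections[[%d]] is not a limb_section_geometry", i)
    limb_circ <- if (is.null(limb_circumferences)) 2 * pi * g$limb_radius
                 else limb_circumferences[[i]]
    ul <- g$garment_stretch
    if (ul == 0)
      ul <- garment_stretch_from_circumferences(limb_circ,
                                                g$garment_circumference)
    g$garment_stretch <- ul
    P <- interface_pressure(g, fabric)
    data.frame(section = g$section_id, stretch_mm = ul, pressure_pa = P,
               deformation_mm = static_deformation_nh(P, g$limb_radius, tissue))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_deformation_mm") <- mean(out$deformation_mm)
  out
}
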