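fab1 <- fabric_properties(2230, 2460, 657.40, 0.13)
tis <- tissue_model(Es = 15000, vs = 0.3)

test_that("interface_pressure inverts the stretch-pressure relation", {
  g0 <- limb_section_geometry(1, 50, 300, 75, garment_stretch = 0)
  expect_equal(interface_pressure(g0, fab1), 0)

  g <- limb_section_geometry(1, 50, 300, 75, garment_stretch = 10)
  expect_equal(interface_pressure(g, fab1),
               pi * 2230 * 10 / (2 * (1 - 0.13^2) * 50))
  expect_equal(interface_pressure(g, fab1), 712.7, tolerance = 2e-4)

  # linear in stretch
  g2 <- limb_section_geometry(1, 50, 300, 75, garment_stretch = 20)
  expect_equal(interface_pressure(g2, fab1), 2 * interface_pressure(g, fab1))
  expect_error(limb_section_geometry(1, -50, 300, 75), "limb_radius")
})

test_that("lame_field satisfies its boundary conditions", {
  z <- lame_field(1, 2, 0)
  expect_equal(z$A, 0); expect_equal(z$C, 0)
  expect_equal(z$sigma_rho(1.5), 0)

  L <- lame_field(1, 2, 1)
  expect_equal(L$A, -4 / 3)
  expect_equal(2 * L$C, 1 / 3)
  expect_equal(L$sigma_rho(1), -1)
  expect_equal(L$sigma_rho(2), 0)
  expect_equal(L$sigma_phi(1), 5 / 3)

  # hoop exceeds radial stress throughout the wall when pressurised
  r <- seq(1.01, 1.99, length.out = 50)
  expect_true(all(L$sigma_phi(r) - L$sigma_rho(r) > 0))
  expect_error(lame_field(2, 1, 1), "geometry")
})

test_that("Neo-Hookean conversion and its inverse agree", {
  expect_equal(neo_hookean_params(4, 0), c(C1 = 1, D1 = 1.5))
  expect_warning(nh <- neo_hookean_params(1000, 0.5), "incompressible")
  expect_equal(nh[["D1"]], 0)

  # literature fixture round-trips through the inverse within 1e-9
  lin <- neo_hookean_invert(5000, 1.4e-7)
  back <- neo_hookean_params(lin[["Es"]], lin[["vs"]])
  expect_equal(back[["C1"]], 5000, tolerance = 1e-9)
  expect_equal(back[["D1"]], 1.4e-7, tolerance = 1e-9)

  # C1 strictly increasing in Es at fixed vs
  C1s <- vapply(c(1000, 2000, 4000), function(E)
    neo_hookean_params(E, 0.3)[["C1"]], numeric(1))
  expect_true(all(diff(C1s) > 0))
})

test_that("static deformation: linear form and scaling", {
  expect_equal(static_deformation_linear(0, 50, tis), 0)
  expect_equal(static_deformation_linear(1000, 50, tis), 0.7 * 1000 * 50 / 15000)
  expect_equal(static_deformation_linear(1000, 100, tis),
               2 * static_deformation_linear(1000, 50, tis))
})

test_that("NH deformation equals the linear form under conversion", {
  expect_equal(static_deformation_nh(0, 50, tis), 0)
  expect_equal(static_deformation_nh(1000, 50, tis), 7 / 3, tolerance = 1e-12)

  # property over randomized (Es, vs, P, R)
  set.seed(3)
  for (i in 1:50) {
    t2 <- tissue_model(Es = runif(1, 1e3, 1e5), vs = runif(1, 0, 0.499))
    P <- runif(1, 0, 5e3); R <- runif(1, 20, 150)
    expect_equal(static_deformation_nh(P, R, t2),
                 static_deformation_linear(P, R, t2), tolerance = 1e-6)
  }

  # literature (C1, D1) tissue equals the linear form at the inverted pair
  t3 <- tissue_model(C1 = 5000, D1 = 1.4e-7)
  expect_equal(static_deformation_nh(1000, 50, t3),
               (1 - t3$vs) * 1000 * 50 / t3$Es, tolerance = 1e-12)
})

test_that("RK4 matches the constant-force closed form", {
  m <- 0.2; k <- 5; F0 <- 1
  sys <- dynamic_system(mass = m, damping = k,
                        forcing = function(t) rep(F0, length(t)))
  tr <- simulate_dynamic(sys, 50, tis, t_end = 1, dt = 1e-4)
  # F == 0 -> identically zero
  tr0 <- simulate_dynamic(dynamic_system(m, k), 50, tis, t_end = 0.1, dt = 1e-3)
  expect_true(all(tr0$u_dl == 0) && all(tr0$u_ds == 0))

  i <- length(tr$times)
  expect_equal(tr$v_dl[i], const_force_velocity(1, m, k, F0), tolerance = 1e-6)
  expect_equal(tr$u_dl[i], 1000 * const_force_displacement(1, m, k, F0),
               tolerance = 1e-6)
  expect_error(simulate_dynamic(
    dynamic_system(m, k, forcing = function(t) t / 0 - t / 0),
    50, tis, t_end = 0.1, dt = 1e-3), "non-finite")
})

test_that("RK4 converges at observed order >= 3.5", {
  m <- 0.2; k <- 5; F0 <- 1
  sys <- dynamic_system(mass = m, damping = k,
                        forcing = function(t) rep(F0, length(t)))
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    tr <- simulate_dynamic(sys, 50, tis, t_end = 1, dt = dt)
    abs(tr$v_dl[length(tr$v_dl)] - const_force_velocity(1, m, k, F0))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 3.5))
})

test_that("sinusoidal steady-state velocity amplitude matches the frequency response", {
  m <- 0.2; k <- 5; F0 <- 1; f <- 60; om <- 2 * pi * f
  sys <- dynamic_system(mass = m, damping = k,
                        forcing = sinusoidal_forcing(F0, f))
  tr <- simulate_dynamic(sys, 50, tis, t_end = 0.5, dt = 1e-5)
  tail_idx <- tr$times > 0.4  # transients decay with time constant m/k = 40 ms
  amp <- max(abs(tr$v_dl[tail_idx]))
  expect_equal(amp, F0 / sqrt(k^2 + (m * om)^2), tolerance = 1e-3)
})

test_that("dynamic tissue trace oscillates about the static level", {
  tis3 <- tissue_model(C1 = 5000, D1 = 1.4e-7)
  P <- 800; R <- 55; h <- 185; f <- 60
  sys <- dynamic_system(mass = 0.2, damping = 5,
                        forcing = sinusoidal_forcing(2, f), pressure = P)
  dt <- (1 / f) / 200  # integer steps per cycle
  tr <- simulate_dynamic(sys, R, tis3, t_end = 6 / f, dt = dt,
                         section_height = h, cycle_period = 1 / f)
  us <- static_deformation_nh(P, R, tis3)
  expect_equal(nrow(tr$cycles), 6)
  expect_true(all(tr$cycles$mean >= us * (1 - 1e-9)))
  expect_true(all(tr$cycles$max > us))
  expect_true(all(tr$cycles$min < us))
})

test_that("predict_sections composes stretch -> pressure -> deformation", {
  # loose garment everywhere -> zero deformation
  secs <- lapply(1:3, function(i)
    limb_section_geometry(i, 40, garment_circumference = 2 * pi * 40 + 10,
                          section_height = 100))
  tab <- predict_sections(fab1, secs, tis)
  expect_equal(tab$deformation_mm, rep(0, 3))

  # single section tuned to P = 1000 Pa, R = 50 mm
  ul <- 2 * (1 - 0.13^2) * 1000 * 50 / (pi * 2230)
  s1 <- limb_section_geometry(1, 50, 300, 100, garment_stretch = ul)
  tab1 <- predict_sections(fab1, list(s1), tis)
  expect_equal(tab1$pressure_pa, 1000, tolerance = 1e-12)
  expect_equal(attr(tab1, "mean_deformation_mm"), 7 / 3, tolerance = 1e-12)

  # doubling Ex strictly increases every per-section deformation
  limb <- default_limb(sample = 4)
  secs4 <- lapply(seq_len(nrow(limb)), function(i)
    limb_section_geometry(limb$section[i], limb$limb_radius_mm[i],
                          limb$garment_circumference_mm[i],
                          limb$section_height_mm[i]))
  base <- predict_sections(fab1, secs4, tis)
  fab2x <- fabric_properties(2 * fab1$Ex, fab1$Ey, fab1$Gxy, fab1$vxy)
  up <- predict_sections(fab2x, secs4, tis)
  expect_true(all(up$deformation_mm > base$deformation_mm))
})
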