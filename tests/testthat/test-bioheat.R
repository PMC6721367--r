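test_that("the optical heat source is the pointwise product mu_a * phi", {
  expect_equal(heat_source(c(2, 3), c(3, 0)), c(6, 0))
  expect_equal(heat_source(c(2, 3), c(0, 0)), c(0, 0))
  expect_error(heat_source(c(1, 2, 3), c(1, 2)), "mismatched")
  ph <- coarse_head()
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  q_all <- heat_source(pr$mu_a, f)
  q_brain <- heat_source(pr$mu_a, f, tissues = c("gray_matter",
                                                 "white_matter"))
  brain <- as.vector(ph$tissue) %in% c("gray_matter", "white_matter")
  expect_equal(q_brain[brain], q_all[brain])
  expect_true(all(q_brain[!brain] == 0))
  # the deposited power integrates to the solver's absorbed power
  vol <- tnirsim:::cell_volumes(ph)
  expect_equal(sum(q_all * vol), f$balance$absorbed, tolerance = 1e-10)
  expect_equal(f$balance$absorbed + f$balance$escaped,
               f$balance$injected, tolerance = 1e-8)
})

test_that("without sources or surface exchange the tissue rests at T_a", {
  ph <- coarse_head(spacing = 2e-3)
  th <- assign_thermal(ph, overrides = no_metabolism())
  temp <- solve_steady_bioheat(ph, th, boundary = surface_boundary(h = 0))
  expect_equal(as.vector(temp$values), rep(37, tnirsim:::n_cells(ph)),
               tolerance = 1e-10)
})

test_that("deep perfused brain equilibrates at T_a + Q_met/(rho_b w_b c_b)", {
  ph <- gm_block("slab_1d", spacing = 5e-4, lateral_extent = 0,
                 depth = 0.05)
  th <- assign_thermal(ph)
  temp <- solve_steady_bioheat(ph, th)
  eq <- 37 + 10437 / (1050 * 0.08 * 3600) # 37.0345 degC
  deep <- tnirsim:::cell_depths(ph) > 0.02
  expect_lt(max(abs(as.vector(temp$values)[deep] - eq)), 1e-3)
})

test_that("with K = 0 and no convection the perfusion balance is exact", {
  ph <- gm_block("slab_1d", spacing = 1e-3, lateral_extent = 0,
                 depth = 0.02)
  ov <- list(gray_matter = list(conductivity = 0))
  th <- assign_thermal(ph, overrides = ov)
  set.seed(5)
  Qr <- runif(tnirsim:::n_cells(ph), 0, 1e4)
  temp <- solve_steady_bioheat(ph, th, Qr,
                               boundary = surface_boundary(h = 0))
  s <- 1050 * 0.08 * 3600
  expect_equal(as.vector(temp$values), 37 + (10437 + Qr) / s,
               tolerance = 1e-12)
  expect_equal(as.vector(temp$baseline),
               rep(37 + 10437 / s, length(Qr)), tolerance = 1e-12)
})

test_that("temperature rise is linear in source power", {
  ph <- coarse_head()
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  th <- assign_thermal(ph)
  Qr <- heat_source(pr$mu_a, f, tissues = c("gray_matter",
                                            "white_matter"))
  t1 <- solve_steady_bioheat(ph, th, Qr)
  t2 <- solve_steady_bioheat(ph, th, Qr / 2)
  dT1 <- as.vector(t1$values) - as.vector(t1$baseline)
  dT2 <- as.vector(t2$values) - as.vector(t2$baseline)
  expect_equal(dT1, 2 * dT2, tolerance = 1e-10)
})

test_that("the optical load only ever heats, and decays beyond its peak", {
  ph <- coarse_head(spacing = 5e-4)
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  th <- assign_thermal(ph)
  Qr <- heat_source(pr$mu_a, f, tissues = c("gray_matter",
                                            "white_matter"))
  temp <- solve_steady_bioheat(ph, th, Qr)
  dT <- as.vector(temp$values) - as.vector(temp$baseline)
  expect_gte(min(dT), -1e-12 * max(dT))
  summ <- temperature_rise_summary(temp)
  cut_dT <- summ$cutline$dT_C
  after_peak <- seq(which.max(cut_dT), length(cut_dT))
  expect_true(all(diff(cut_dT[after_peak]) <= 1e-9))
})

test_that("zero optical source means zero temperature rise", {
  ph <- coarse_head(spacing = 2e-3)
  th <- assign_thermal(ph)
  temp <- solve_steady_bioheat(ph, th)
  summ <- temperature_rise_summary(temp)
  expect_true(all(summ$per_tissue$max_dT_C == 0))
  expect_equal(summ$surface_max_dT_C, 0)
})

test_that("as-printed densities are available but warned about", {
  ph <- coarse_head(spacing = 2e-3)
  expect_warning(assign_thermal(ph, as_printed = TRUE), "non-physical")
  th36 <- assign_thermal(ph, blood_specific_heat = 3664)
  th <- assign_thermal(ph)
  expect_equal(max(th36$s / pmax(th$s, 1e-300)), 3664 / 3600,
               tolerance = 1e-10)
})

test_that("the steady solution is a fixed point of the transient solver", {
  ph <- coarse_head(spacing = 2e-3)
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  th <- assign_thermal(ph)
  Qr <- heat_source(pr$mu_a, f, tissues = c("gray_matter",
                                            "white_matter"))
  steady <- solve_steady_bioheat(ph, th, Qr)
  tr <- solve_transient_bioheat(ph, th, Qr, t_end = 10, dt = 1,
                                T_init = as.vector(steady$values))
  expect_lt(max(abs(as.vector(tr$final) - as.vector(steady$values))),
            1e-9)
})

test_that("the transient solution relaxes to the steady state", {
  ph <- coarse_head(spacing = 2e-3)
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  th <- assign_thermal(ph)
  Qr <- heat_source(pr$mu_a, f, tissues = c("gray_matter",
                                            "white_matter"))
  steady <- solve_steady_bioheat(ph, th, Qr)
  # switch the light on from the no-source baseline; the brain relaxes on
  # the perfusion time scale rho c / (rho_b w_b c_b) (~12 s) but the
  # weakly perfused scalp-skull layer takes ~25 minutes, so the horizon
  # must span several of its time constants
  tr <- solve_transient_bioheat(ph, th, Qr, t_end = 7200, dt = 5)
  expect_lt(max(abs(as.vector(tr$final) - as.vector(steady$values))),
            1e-3)
  expect_error(solve_transient_bioheat(ph, th, Qr, t_end = -1, dt = 1),
               "positive")
})

test_that("a uniform perturbation decays at the perfusion rate", {
  ph <- gm_block("slab_1d", spacing = 1e-3, lateral_extent = 0,
                 depth = 0.02)
  th <- assign_thermal(ph)
  steady <- solve_steady_bioheat(ph, th,
                                 boundary = surface_boundary(h = 0))
  T0 <- as.vector(steady$values) + 1
  dt <- 0.1
  tr <- solve_transient_bioheat(ph, th, NULL,
                                boundary = surface_boundary(h = 0),
                                t_end = 10, dt = dt, T_init = T0,
                                save_every = 1)
  dev <- abs(tr$states[1, ] - as.vector(steady$values)[1])
  rate_fit <- -coef(lm(log(dev) ~ tr$times))[2]
  rate_true <- 1050 * 0.08 * 3600 / (1040 * 3630)
  expect_equal(unname(rate_fit), rate_true, tolerance = 0.02)
})
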