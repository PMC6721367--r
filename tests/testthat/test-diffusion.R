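test_that("fluence is linear in source power", {
  ph <- coarse_head()
  pr <- assign_properties(ph, 810)
  dark <- solve_diffusion(ph, pr, source_spec(irradiance = 0))
  expect_true(all(dark$values == 0))
  f1 <- solve_diffusion(ph, pr, source_spec(irradiance = 5000))
  f2 <- solve_diffusion(ph, pr, source_spec(irradiance = 10000))
  expect_equal(as.vector(f2$values), 2 * as.vector(f1$values),
               tolerance = 1e-12)
})

test_that("solver matches the infinite-medium Green's function within 2%", {
  # homogeneous gray-matter medium, interior point source far from all
  # boundaries; phi(r) = P exp(-mu_eff r) / (4 pi D r)
  ph <- gm_block("axisymmetric_2d", spacing = 2e-4,
                 lateral_extent = 0.04, depth = 0.08)
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr, source_depth = 0.04, source_sigma = 2e-4)
  D <- diffusion_coefficient(57.09, 746)
  mu_eff <- effective_attenuation(57.09, 746)
  cut <- extract_cutline(f)
  r <- abs(cut$depth_m - f$source_depth)
  green <- 0.5 * exp(-mu_eff * r) / (4 * pi * D * r)
  mfp <- 1 / (57.09 + 746) # transport mean free path
  sel <- r >= mfp & r <= 10 / mu_eff
  expect_gt(sum(sel), 100)
  expect_lt(max(abs(cut$value[sel] / green[sel] - 1)), 0.02)
})

test_that("absorbed power plus boundary escape equals injected power", {
  for (h in c(1e-3, 5e-4)) {
    ph <- build_phantom(spacing = h)
    pr <- assign_properties(ph, 810)
    f <- solve_diffusion(ph, pr)
    gap <- abs(f$balance$injected - f$balance$absorbed -
                 f$balance$escaped) / f$balance$injected
    expect_lt(gap, 1e-8) # conservative scheme: closure at solver precision
  }
})

test_that("log-fluence decays asymptotically at -mu_eff in a slab", {
  ph <- gm_block("slab_1d", spacing = 2e-4, lateral_extent = 0,
                 depth = 0.04)
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  cut <- extract_cutline(f)
  sel <- cut$depth_m > 0.010 & cut$depth_m < 0.025
  slope <- coef(lm(log(cut$value[sel]) ~ cut$depth_m[sel]))[2]
  mu_eff <- effective_attenuation(57.09, 746)
  expect_equal(unname(slope), -mu_eff, tolerance = 0.05)
})

test_that("cutline extraction interpolates exactly and labels layers", {
  ph <- coarse_head()
  n <- tnirsim:::n_cells(ph)
  constant <- array(3.5, dim = ph$dims)
  cut <- extract_cutline(constant, phantom = ph)
  expect_true(all(cut$value == 3.5))
  # a field linear in depth is reproduced to machine precision
  z <- tnirsim:::cell_depths(ph)
  linear <- array(2 + 5 * z, dim = ph$dims)
  cut <- extract_cutline(linear, phantom = ph, step = 3.3e-4)
  expect_equal(cut$value, 2 + 5 * cut$depth_m, tolerance = 1e-12)
  # labels traverse the anatomical order
  expect_equal(unique(cut$tissue),
               c("scalp_skull", "csf", "gray_matter", "white_matter"))
  expect_error(extract_cutline(constant, direction = c(0, 0, 0),
                               phantom = ph), "degenerate")
  expect_error(extract_cutline(constant, direction = c(1, 0, 0),
                               phantom = ph), "depth-axis")
  expect_error(extract_cutline(constant, phantom = ph, step = -1),
               "positive")
})

test_that("fraction profile is normalized at the entry cell", {
  ph <- coarse_head()
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  prof <- fluence_fraction_profile(f)
  expect_equal(prof$fraction[1], 1.0)
  fr <- fluence_fraction_at(f, 0.020)
  expect_gt(fr, 0)
  expect_lt(fr, 1)
  expect_error(fluence_fraction_at(f, 1), "outside")
})

test_that("about 0.2% of the entering fluence reaches the gray matter at 810 nm", {
  ph <- build_phantom(spacing = 5e-4)
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  fr <- fluence_fraction_at(f, 0.020)
  expect_gt(fr, 5e-4)
  expect_lt(fr, 1e-2)
})

test_that("penetration to the gray matter orders 810 > 700 > 630 nm", {
  ph <- coarse_head()
  fr <- vapply(c(630, 700, 810), function(wl) {
    f <- solve_diffusion(ph, assign_properties(ph, wl))
    fluence_fraction_at(f, 0.020)
  }, numeric(1))
  expect_true(fr[3] > fr[2] && fr[2] > fr[1])
})

test_that("the discrete solution respects the maximum principle", {
  ph <- build_phantom(spacing = 5e-4)
  pr <- assign_properties(ph, 810)
  f <- solve_diffusion(ph, pr)
  expect_gte(min(f$values), -1e-12 * max(f$values))
})

test_that("cutline fluence converges under grid refinement", {
  # the source kernel width is held at two coarse cells so that both
  # grids resolve the same continuous problem
  fields <- lapply(c(5e-4, 2.5e-4), function(h) {
    ph <- build_phantom(spacing = h)
    solve_diffusion(ph, assign_properties(ph, 810), source_sigma = 1e-3)
  })
  d <- seq(0.003, 0.035, by = 1e-3)
  # sample away from the layer interfaces: interpolating across the
  # material discontinuity mixes the two media differently on each grid
  d <- d[vapply(d, function(x)
    min(abs(x - c(0.013, 0.020, 0.024))) > 7.5e-4, logical(1))]
  v <- lapply(fields, function(f) {
    cut <- extract_cutline(f)
    approx(cut$depth_m, cut$value, xout = d)$y
  })
  expect_lt(max(abs(v[[1]] / v[[2]] - 1)), 0.02)
})

test_that("single-chromophore runs attenuate less than the whole tissue", {
  ph <- coarse_head()
  pr <- assign_properties(ph, 810)
  whole <- solve_diffusion(ph, pr)
  brain <- as.vector(ph$tissue) %in% c("gray_matter", "white_matter")
  for (ch in c("water", "oxyhemoglobin")) {
    single <- per_chromophore_run(ph, 810, ch)
    # removing the other chromophores can only increase the fluence
    expect_true(all(as.vector(single$values)[brain] >=
                      as.vector(whole$values)[brain] * (1 - 1e-10)))
  }
})

test_that("deoxyhemoglobin attenuates more than reduced CCO at 630 nm", {
  ph <- coarse_head()
  hb <- per_chromophore_run(ph, 630, "deoxyhemoglobin")
  cco <- per_chromophore_run(ph, 630, "reduced_cco")
  c_hb <- extract_cutline(hb)
  c_cco <- extract_cutline(cco)
  at <- function(cut, d) approx(cut$depth_m, cut$value, xout = d)$y
  expect_lt(at(c_hb, 0.022), at(c_cco, 0.022))
  expect_error(per_chromophore_run(ph, 630, "melanin"))
})

test_that("per-chromophore absorption maps sum to the whole-tissue map", {
  ph <- coarse_head()
  whole <- assign_properties(ph, 700)
  brain <- as.vector(ph$tissue) %in% c("gray_matter", "white_matter")
  total <- rowSums(vapply(tnirsim:::CHROMOPHORES, function(ch) {
    pr <- assign_properties(ph, 700, overrides = list(
      gray_matter = list(mu_a = nir_lookup("gray_matter", 700, ch)),
      white_matter = list(mu_a = nir_lookup("white_matter", 700, ch))))
    pr$mu_a
  }, numeric(tnirsim:::n_cells(ph))))
  expect_true(all(abs(total[brain] - whole$mu_a[brain]) <= 0.05))
})

test_that("solver rejects mismatched inputs", {
  ph <- coarse_head()
  pr <- assign_properties(coarse_head(spacing = 2e-3), 810)
  expect_error(solve_diffusion(ph, pr), "every cell")
})
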