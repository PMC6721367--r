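test_that("reduced scattering follows mu_s (1 - g)", {
  expect_equal(reduced_scattering(100, 0), 100)
  expect_equal(reduced_scattering(100, 1), 0)
  # inverting the gray-matter 810 nm tabulated mu_s' at g = 0.89
  expect_equal(reduced_scattering(6781.82, 0.89), 746, tolerance = 0.1 / 746)
  expect_error(reduced_scattering(-1, 0.5), "non-negative")
  expect_error(reduced_scattering(100, 1.2), "\\[0, 1\\]")
  expect_error(reduced_scattering(100, -0.1), "\\[0, 1\\]")
})

test_that("reduced scattering is linear in mu_s and decreasing in g", {
  set.seed(42)
  for (i in 1:20) {
    mu_s <- runif(1, 10, 1e4)
    a <- runif(1, 0.1, 5)
    g1 <- runif(1, 0, 0.9)
    g2 <- runif(1, g1, 1)
    expect_equal(reduced_scattering(a * mu_s, g1),
                 a * reduced_scattering(mu_s, g1))
    expect_lte(reduced_scattering(mu_s, g2), reduced_scattering(mu_s, g1))
  }
})

test_that("diffusion coefficient is 1/(3(mu_a + mu_s'))", {
  expect_equal(diffusion_coefficient(1 / 3, 0), 1)
  expect_equal(diffusion_coefficient(57.09, 746), 4.150637e-4,
               tolerance = 1e-6)
  expect_equal(diffusion_coefficient(2.6, 250), 1.319609e-3,
               tolerance = 1e-6)
  expect_error(diffusion_coefficient(0, 0), "degenerate")
  expect_error(diffusion_coefficient(-1, 10), "non-negative")
})

test_that("diffusion coefficient is strictly decreasing in both arguments", {
  set.seed(7)
  for (i in 1:20) {
    mu_a <- runif(1, 1, 200)
    musp <- runif(1, 100, 5000)
    d <- runif(1, 1, 50)
    expect_lt(diffusion_coefficient(mu_a + d, musp),
              diffusion_coefficient(mu_a, musp))
    expect_lt(diffusion_coefficient(mu_a, musp + d),
              diffusion_coefficient(mu_a, musp))
  }
})

test_that("effective attenuation matches sqrt(3 mu_a (mu_a + mu_s'))", {
  expect_equal(effective_attenuation(0, 500), 0)
  expect_equal(effective_attenuation(57.09, 746), 370.87,
               tolerance = 0.5 / 370.87)
  expect_equal(effective_attenuation(16, 760), 193.0,
               tolerance = 0.5 / 193)
})

test_that("mu_eff^2 D = mu_a to machine precision", {
  set.seed(3)
  for (i in 1:25) {
    mu_a <- runif(1, 0.1, 300)
    musp <- runif(1, 50, 8000)
    expect_equal(effective_attenuation(mu_a, musp)^2 *
                   diffusion_coefficient(mu_a, musp),
                 mu_a, tolerance = 1e-12)
  }
})

test_that("chromophore contributions apply the right product rule", {
  # water: 75% volume fraction of the pure-water coefficient
  w <- chromophore_contribution("water", "volume_fraction",
                                fraction = 0.75,
                                specific_absorption = 2.213)
  expect_equal(chromophore_mu_a(w), 1.66, tolerance = 0.01 / 1.66)
  # zero concentration of anything absorbs nothing
  expect_equal(chromophore_mu_a(
    chromophore_contribution("oxidized_cco", "molar_concentration",
                             concentration_mM = 0,
                             specific_absorption = 500)), 0)
  expect_equal(chromophore_mu_a(
    chromophore_contribution("water", "volume_fraction", fraction = 0,
                             specific_absorption = 2.213)), 0)
  # CCO: linear in molar concentration
  expect_equal(chromophore_mu_a(
    chromophore_contribution("oxidized_cco", "molar_concentration",
                             concentration_mM = 2,
                             specific_absorption = 5)), 10)
  # lipid: dry-weight mass fraction times density times specific absorbance
  expect_equal(chromophore_mu_a(
    chromophore_contribution("fat", "mass_fraction_x_density",
                             mass_fraction = 0.1, density = 1040,
                             specific_absorption = 1e-3)),
    0.1 * 1040 * 1e-3)
  # hemoglobin: blood volume fraction at mixed arterio-venous saturation
  hb <- chromophore_contribution("hemoglobin",
                                 "blood_volume_fraction_with_SO2",
                                 blood_volume_fraction = 0.05, so2 = 0.7,
                                 mu_a_oxy = 400, mu_a_deoxy = 900)
  expect_equal(chromophore_mu_a(hb), 0.05 * (0.7 * 400 + 0.3 * 900))
})

test_that("chromophore descriptors reject invalid inputs", {
  expect_error(chromophore_contribution("water", "volume_fraction",
                                        fraction = 1.2,
                                        specific_absorption = 1),
               "\\[0, 1\\]")
  expect_error(chromophore_contribution("x", "molar_concentration",
                                        concentration_mM = -1,
                                        specific_absorption = 1),
               "non-negative")
  expect_error(chromophore_contribution("water", "volume_fraction",
                                        specific_absorption = 1),
               "requires parameter")
  expect_error(chromophore_contribution("water", "no_such_kind",
                                        fraction = 0.5))
  expect_error(chromophore_mu_a(42), "chromophore_contribution")
})

test_that("tissue absorption composes additively over chromophores", {
  expect_equal(compose_tissue_mu_a(list()), 0)
  expect_equal(compose_tissue_mu_a(
    list(0.26, 0.04, 14.06, 73, 35.64, 4.25)), 127.25)
  expect_equal(compose_tissue_mu_a(
    list(1.66, 0.05, 22.44, 15.48, 16.2, 1.26)), 57.09)
  expect_error(compose_tissue_mu_a(list(1, -0.1)), "non-negative")
})

test_that("packaged tables load and expose the expected values", {
  tbl <- nir_tables()
  expect_named(tbl, c("optical", "thermal", "perfusion", "chromophore",
                      "whole_tissue"))
  expect_equal(nir_lookup("gray_matter", 810, "whole_tissue_mu_a"), 57.09)
  expect_equal(nir_lookup("white_matter", 630, "deoxyhemoglobin"), 59.92)
  for (wl in c(630, 700, 810))
    expect_equal(nir_lookup("csf", wl, "mu_s_prime"), 250)
  expect_error(nir_lookup("gray_matter", 555, "mu_a"), "no tabulated")
  expect_error(nir_lookup("gray_matter", 810, "melanin"),
               "unknown quantity")
})

test_that("chromophore sums reproduce the whole-tissue absorption", {
  tbl <- nir_tables()
  for (wl in c(630, 700, 810)) {
    gm <- vapply(c("water", "fat", "oxyhemoglobin", "deoxyhemoglobin",
                   "oxidized_cco", "reduced_cco"),
                 function(ch) nir_lookup("gray_matter", wl, ch),
                 numeric(1))
    wm <- vapply(names(gm),
                 function(ch) nir_lookup("white_matter", wl, ch),
                 numeric(1))
    expect_equal(compose_tissue_mu_a(as.list(gm)),
                 nir_lookup("gray_matter", wl, "whole_tissue_mu_a"),
                 tolerance = 0.01 / 60)
    # the white-matter table carries a little rounding slack
    expect_lte(abs(compose_tissue_mu_a(as.list(wm)) -
                     nir_lookup("white_matter", wl, "whole_tissue_mu_a")),
               0.05)
  }
})
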