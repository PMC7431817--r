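test_that("no ligand means no bound ligand and no liganded species", {
  st <- solve_equilibrium(ref_params, Rtot = 5e5, L = 0)
  expect_identical(st$bound, 0)
  expect_true(all(st$species[c("EIL", "EAL", "DESL", "DES2L",
                               "DEAL", "DEA2L")] == 0))
  expect_lt(conservation_error(st), 1e-12)
})

test_that("returned state satisfies the mass-action relations exactly", {
  st <- solve_equilibrium(ref_params, Rtot = 560000, L = 3.9)
  sp <- st$species
  p <- unclass(ref_params)
  expect_equal(sp[["DES"]] * p["K4"], sp[["EI"]]^2,
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(sp[["CI"]], p["K2"] * sp[["EI"]],
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(sp[["DEAL"]] * p["K8"], sp[["DEA"]] * st$L,
               tolerance = 1e-14, ignore_attr = TRUE)
  # bound assembles all singly liganded species once, doubly liganded twice
  expect_equal(st$bound,
               sum(sp[c("EIL", "EAL", "DESL", "DEAL")]) +
                 2 * sum(sp[c("DES2L", "DEA2L")]),
               tolerance = 1e-14)
})

test_that("closed form agrees with a brute-force solve of the full system", {
  skip_if_not_installed("pracma")
  set.seed(42)
  n_draws <- 300
  worst <- 0
  for (i in seq_len(n_draws)) {
    p <- unclass(random_params())
    Rtot <- 10^stats::runif(1, 3, 7)
    L <- 10^stats::runif(1, -3, 3)
    st <- solve_equilibrium(do.call(egfr_params, as.list(p)), Rtot, L)
    bf <- brute_force_state(p, Rtot, L)
    worst <- max(worst, max(abs(st$species - bf) / pmax(bf, 1e-300)))
    expect_lt(conservation_error(st), 1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("reference-condition state matches the brute-force oracle", {
  skip_if_not_installed("pracma")
  st <- solve_equilibrium(ref_params, Rtot = 560000, L = 3.9)
  bf <- brute_force_state(unclass(ref_params), 560000, 3.9)
  expect_equal(st$species, bf, tolerance = 1e-8)
})

test_that("binding curve is monotone, bounded by Rtot, and saturates", {
  grid <- c(0, 10^seq(-3, 5, length.out = 60))
  for (Rt in c(1e3, 390000, 1070000)) {
    b <- binding_curve(ref_params, Rt, grid)
    expect_true(all(diff(b) >= -1e-9 * Rt))
    expect_true(all(b <= Rt * (1 + 1e-12)))
    expect_identical(b[1], 0)
  }
  # all liganded states reachable: occupancy approaches 1 at saturating EGF
  b_sat <- binding_curve(ref_params, 560000, 1e7)
  expect_gt(b_sat / 560000, 0.999)
})

test_that("doubly liganded symmetric dimers obey the linkage identity", {
  # route equivalence: [EIL]^2 / [DES2L] = K4*K5*K6/K3^2, the dissociation
  # constant for dimerization of two liganded monomers
  D <- linkage_constants(ref_params)[["D_inactive"]]
  for (L in c(0.5, 3.9, 130)) {
    sp <- solve_equilibrium(ref_params, 560000, L)$species
    expect_equal(sp[["EIL"]]^2 / sp[["DES2L"]], D, tolerance = 1e-10)
  }
})

test_that("suppressing dimerization reduces binding to the one-site isotherm", {
  p <- unclass(ref_params)
  p["K4"] <- 1e14; p["K7"] <- 1e14
  pp <- do.call(egfr_params, as.list(p))
  grid <- 10^seq(-2, 3, length.out = 40)
  Rt <- 560000
  b <- binding_curve(pp, Rt, grid)
  K1 <- p[["K1"]]; K2 <- p[["K2"]]; K3 <- p[["K3"]]
  iso <- Rt * (grid / K3) * (1 / K1 + 1) /
    (K2 + K2 / K1 + 1 + 1 / K1 + grid / K3 + grid / (K1 * K3))
  expect_equal(b, iso, tolerance = 1e-10)
})

test_that("species fractions sum to one and vanish in the inactive limit", {
  fr <- species_fractions(ref_params, 560000, 10)
  expect_equal(sum(fr), 1, tolerance = 1e-10)
  expect_true(all(fr >= 0 & fr <= 1))
  # very large K1: the active-kinase branch disappears
  p <- unclass(ref_params); p["K1"] <- 1e12
  fr2 <- species_fractions(do.call(egfr_params, as.list(p)), 560000, 10)
  expect_true(all(fr2[c("CA", "EA", "EAL", "DEA", "DEAL", "DEA2L")] < 1e-10))
  expect_error(species_fractions(ref_params, 0, 10), "undefined")
})

test_that("monomers with inactive kinase dominate binding under lapatinib", {
  p <- unclass(ref_params); p["K1"] <- 162
  fr <- species_fractions(do.call(egfr_params, as.list(p)), 560000, 10)
  expect_gt(fr[["EIL"]], fr[["DEAL"]] + 2 * fr[["DEA2L"]])
})

test_that("dimer fraction responds to mass action and kinase state", {
  p <- unclass(ref_params); p["K4"] <- 1e15; p["K7"] <- 1e15
  expect_lt(dimer_fraction(do.call(egfr_params, as.list(p)), 560000, 0), 1e-6)
  expect_gt(dimer_fraction(ref_params, 2 * 560000, 0),
            dimer_fraction(ref_params, 560000, 0))
  expect_error(dimer_fraction(ref_params, 0, 0), "undefined")
  # EGF shifts the dimer pool under erlotinib but barely under lapatinib
  pe <- unclass(ref_params); pe["K1"] <- 25
  pl <- unclass(ref_params); pl["K1"] <- 162
  d_erl <- abs(dimer_fraction(do.call(egfr_params, as.list(pe)), 560000, 130) -
                 dimer_fraction(do.call(egfr_params, as.list(pe)), 560000, 0))
  d_lap <- abs(dimer_fraction(do.call(egfr_params, as.list(pl)), 560000, 130) -
                 dimer_fraction(do.call(egfr_params, as.list(pl)), 560000, 0))
  expect_gt(d_erl, d_lap)
})

test_that("linkage constants reduce correctly in the no-linkage case", {
  p <- egfr_params(K1 = 10, K2 = 1, K3 = 2, K4 = 1, K5 = 8, K6 = 0.5,
                   K7 = 3, K8 = 1, K9 = 4)
  lk <- linkage_constants(p)
  expect_equal(lk[["D_inactive"]], 1)           # K5*K6 = K3^2, K4 = 1
  expect_equal(lk[["D_active"]], 3 * 4 / 4)
})

test_that("degenerate and invalid inputs are handled", {
  st0 <- solve_equilibrium(ref_params, Rtot = 0, L = 10)
  expect_true(all(st0$species == 0))
  expect_identical(st0$bound, 0)
  expect_error(egfr_params(K1 = -1, K2 = 1, K3 = 1, K4 = 1, K5 = 1, K6 = 1,
                           K7 = 1, K8 = 1, K9 = 1), "positive")
  expect_error(binding_curve(ref_params, 1e5, numeric(0)), "empty")
  expect_error(binding_curve(ref_params, 1e5, c(2, 1)), "sorted")
  expect_error(solve_equilibrium(ref_params, 1e5, -1), "L must be")
})

test_that("low-expression root extraction stays accurate", {
  # a*Rtot << b^2 regime: the naive quadratic formula would cancel
  st <- solve_equilibrium(ref_params, Rtot = 10, L = 0.01)
  expect_lt(conservation_error(st), 1e-12)
  expect_true(all(st$species >= 0))
})
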