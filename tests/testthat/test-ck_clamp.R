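test_that("apparent_ck_constant: identity at reference, oracle agreement, smooth pH sweep", {
  p <- default_thermo_params()
  rc <- p$reference_conditions
  expect_equal(
    apparent_ck_constant(p, rc$ph, rc$mg_free, rc$temperature), p$k_ck_ref,
    tolerance = 1e-12)

  # independent species-summation oracle off reference
  for (cond in list(c(7.5, 1e-3), c(6.8, 5e-4), c(7.2, 2e-3))) {
    expect_equal(apparent_ck_constant(p, cond[1], cond[2], 310.15),
                 oracle_kck(p, cond[1], cond[2], 310.15), tolerance = 1e-12)
  }

  phs <- seq(6.5, 7.5, by = 0.05)
  ks <- vapply(phs, function(ph) apparent_ck_constant(p, ph, 1e-3, 310.15),
               numeric(1))
  ko <- vapply(phs, function(ph) oracle_kck(p, ph, 1e-3, 310.15), numeric(1))
  expect_equal(ks, ko, tolerance = 1e-12)
  # monotone in the direction the oracle predicts (here: decreasing with pH)
  expect_true(all(diff(ks) < 0) == all(diff(ko) < 0))
  expect_true(all(sign(diff(ks)) == sign(diff(ks))[1]))
})

test_that("apparent_ck_constant validates its inputs by field", {
  p <- default_thermo_params()
  expect_error(apparent_ck_constant(p, 4.5, 1e-3, 310), "ph")
  expect_error(apparent_ck_constant(p, 7.2, -1e-3, 310), "mg_free")
  expect_error(apparent_ck_constant(p, 7.2, 1e-3, 400), "temperature")
})

test_that("solve_adp: direct arithmetic, limits, and proportionality", {
  comp <- clamp_composition(atp_total = 5, pcr = 5, cr = 5, pi_total = 10,
                            mg_total = 5, units = "mM")
  # ATP 5 mM, Cr 5 mM, PCr 5 mM, K' = 100 -> ADP = 50 uM
  expect_equal(solve_adp(comp, k_ck = 100), 50e-6, tolerance = 1e-12)

  comp0 <- clamp_composition(atp_total = 5, pcr = 5, cr = 0, pi_total = 10,
                             mg_total = 5, units = "mM")
  expect_identical(solve_adp(comp0), 0)

  comp2 <- clamp_composition(atp_total = 5, pcr = 10, cr = 5, pi_total = 10,
                             mg_total = 5, units = "mM")
  expect_equal(solve_adp(comp2, k_ck = 100), 25e-6, tolerance = 1e-12)

  compz <- clamp_composition(atp_total = 5, pcr = 0, cr = 5, pi_total = 10,
                             mg_total = 5, units = "mM")
  expect_error(solve_adp(compz), "undefined")
})

test_that("solve_adp agrees with the independent root-finding solver (100 random compositions)", {
  set.seed(42)
  p <- default_thermo_params()
  worst <- 0
  for (i in 1:100) {
    comp <- random_composition()
    worst <- max(worst, abs(solve_adp(comp, p) - oracle_solve_adp(comp, p)))
  }
  expect_lt(worst, 1e-9)   # mol/L, absolute
})

test_that("delta_g_atp: log term vanishes when the mass-action ratio is 1 M", {
  p <- default_thermo_params()
  make <- function(cr) clamp_composition(atp_total = 1e-3, pcr = 1e-3, cr = cr,
                                         pi_total = 1, mg_total = 1e-3)
  ratio_at <- function(cr) {
    st <- delta_g_atp(make(cr), p, details = TRUE)
    st$adp_free * 1 / 1e-3 - 1
  }
  # engineer [ADP][Pi]/[ATP] = 1 M by tuning Cr
  cr_star <- stats::uniroot(ratio_at, c(1e-3, 10), tol = 1e-15)$root
  st <- delta_g_atp(make(cr_star), p, details = TRUE)
  expect_equal(st$dg_atp, st$dg0_apparent, tolerance = 1e-6)
})

test_that("delta_g_atp guards its domain and records provenance", {
  p <- default_thermo_params()
  expect_error(delta_g_atp(clamp_composition(0, 1e-3, 5e-3, 1e-2, 5e-3), p),
               "atp_total")
  expect_error(delta_g_atp(clamp_composition(5e-3, 1e-3, 5e-3, 0, 5e-3), p),
               "pi_total")
  dg <- delta_g_atp(standard_clamp_composition(), p)
  expect_match(attr(dg, "source_label"), "anchored")
})

test_that("titration_curve reduces to delta_g_atp and rejects bad grids", {
  comp <- standard_clamp_composition()
  single <- titration_curve(comp, 6e-3)
  expect_equal(nrow(single), 1L)
  expect_equal(single$dg_atp, as.numeric(delta_g_atp({
    c2 <- comp; c2$pcr <- 6e-3; c2
  })), tolerance = 1e-12)
  expect_error(titration_curve(comp, c(6e-3, 1e-3)), "increasing")
  expect_error(titration_curve(comp, c(0, 1e-3)), "> 0")
})

test_that("dG_ATP is strictly monotone decreasing in PCr on random compositions", {
  set.seed(7)
  for (i in 1:25) {
    comp <- random_composition()
    levels <- sort(runif(5, 0.5e-3, 25e-3))
    levels <- levels[c(TRUE, diff(levels) > 1e-6)]
    tc <- titration_curve(comp, levels)   # errors internally if not monotone
    expect_true(all(diff(tc$dg_atp) < 0))
  }
})

test_that("delta_g_atp is invariant to the mol/L vs mmol/L input convention", {
  a <- clamp_composition(5, 1, 5, 10, 5, units = "mM")
  b <- clamp_composition(5e-3, 1e-3, 5e-3, 10e-3, 5e-3, units = "M")
  expect_identical(as.numeric(delta_g_atp(a)), as.numeric(delta_g_atp(b)))
})

test_that("composition and parameter validation name the offending field", {
  expect_error(clamp_composition(-1e-3, 1e-3, 5e-3, 1e-2, 5e-3), "atp_total")
  expect_error(clamp_composition(5e-3, 1e-3, 5e-3, 1e-2, 5e-3, ph = 9.5), "ph")
  expect_error(clamp_composition(5e-3, 1e-3, 5e-3, 1e-2, 5e-3, temperature = 350),
               "temperature")
  expect_error(clamp_composition(5e-3, 1e-3, 5e-3, 1e-2, 5e-3, ck_units = 0),
               "ck_units")
  p <- default_thermo_params()
  expect_error(thermo_params(166, -33, p$binding_constants,
                             p$reference_conditions, ""), "source_label")
  bc <- p$binding_constants; bc$atp_h <- -1
  expect_error(thermo_params(166, -33, bc, p$reference_conditions, "x"), "> 0")
})

test_that("free-Mg override and van 't Hoff hooks behave", {
  p <- default_thermo_params()
  comp <- standard_clamp_composition()
  d_auto <- delta_g_atp(comp, p, details = TRUE)
  comp_over <- clamp_composition(5e-3, 1e-3, 5e-3, 10e-3, 5e-3,
                                 mg_free = d_auto$mg_free)
  d_over <- delta_g_atp(comp_over, p, details = TRUE)
  expect_equal(d_over$dg_atp, d_auto$dg_atp, tolerance = 1e-9)

  # with enthalpies supplied, constants shift off the reference temperature
  p2 <- p; p2$enthalpies <- list(dh_ck = -17.5, dh_atp = -20)
  comp_t <- clamp_composition(5e-3, 1e-3, 5e-3, 10e-3, 5e-3, temperature = 305)
  expect_false(isTRUE(all.equal(as.numeric(delta_g_atp(comp_t, p2)),
                                as.numeric(delta_g_atp(comp_t, p)))))
  # at the reference temperature the enthalpies are inert
  expect_equal(as.numeric(delta_g_atp(comp, p2)),
               as.numeric(delta_g_atp(comp, p)), tolerance = 1e-12)
})
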