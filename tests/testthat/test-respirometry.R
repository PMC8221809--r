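test_that("compute_flux recovers exact and noisy slopes with correct units", {
  # linear decline of 10 uM/min in a 1 mL chamber -> 166.7 pmol O2/s
  t <- seq(0, 600, by = 2)
  tr <- oxygen_trace(t, 200 - 10 / 60 * t, chamber_ml = 1)
  fx <- compute_flux(tr, smoothing_halfwidth = 10)
  expect_equal(fx$jo2_pmol_s, rep(10 / 60 * 1e-3 * 1e3 * 1000, length(t)),
               tolerance = 1e-9)
  expect_equal(fx$jo2_pmol_s[1], 166.6667, tolerance = 1e-4)

  # constant O2 -> zero flux
  tr0 <- oxygen_trace(t, rep(150, length(t)), chamber_ml = 2)
  expect_true(all(abs(compute_flux(tr0, 10)$jo2_pmol_s) < 1e-12))

  # noisy known slope, fixed seed: mean within 2%
  set.seed(11)
  tr_n <- oxygen_trace(t, 200 - 10 / 60 * t + rnorm(length(t), 0, 0.5), 1)
  expect_equal(mean(compute_flux(tr_n, 15)$jo2_pmol_s), 166.667,
               tolerance = 0.02)

  expect_error(compute_flux(tr, smoothing_halfwidth = 1e6), "span")
  expect_error(oxygen_trace(1, 2, 1), "2 samples")
})

test_that("flux is invariant under uniform time translation", {
  set.seed(3)
  t <- seq(0, 300, by = 1)
  y <- 180 - 0.05 * t + rnorm(length(t), 0, 0.3)
  f1 <- compute_flux(oxygen_trace(t, y, 2), 10)
  f2 <- compute_flux(oxygen_trace(t + 1234.5, y, 2), 10)
  expect_equal(f1$jo2_pmol_s, f2$jo2_pmol_s, tolerance = 1e-10)
})

test_that("extract_steady_states recovers staircase rates and handles degenerate input", {
  prot <- data.frame(label = c("basal", "A", "B"), duration_s = 240,
                     rate_pmol_s = c(50, 100, 150))
  sim <- make_respirometry_trace(prot, chamber_ml = 1, noise_sd = 0, seed = 1)
  st <- extract_steady_states(
    compute_flux(sim$trace, 10, breaks = sim$events$time_s), sim$events)
  expect_equal(st$label, c("basal", "A", "B"))
  expect_equal(st$jo2_pmol_s, c(50, 100, 150), tolerance = 1e-6)
  expect_true(all(st$accepted))

  # no events: single whole-trace state
  st1 <- extract_steady_states(compute_flux(sim$trace, 10),
                               event_marks(numeric(0), character(0)))
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$label, "basal")

  # event beyond trace span errors
  expect_error(
    extract_steady_states(compute_flux(sim$trace, 10),
                          event_marks(1e6, "X")), "beyond")
})

test_that("short segments are flagged, not dropped", {
  prot <- data.frame(label = c("basal", "A"), duration_s = c(300, 60),
                     rate_pmol_s = c(50, 100))
  sim <- make_respirometry_trace(prot, noise_sd = 0, seed = 1)
  st <- extract_steady_states(
    compute_flux(sim$trace, 5, breaks = sim$events$time_s), sim$events,
    window_policy(lag_s = 90, window_s = 60))
  expect_equal(nrow(st), 2L)
  expect_false(st$accepted[st$label == "A"])
  expect_match(st$flag[st$label == "A"], "short")
})

test_that("staircase recovery holds across 50 random protocols (noise-scaled tolerance)", {
  set.seed(99)
  sigma <- 0.3; halfwidth <- 30; chamber <- 1
  # analytic per-point flux noise: OLS slope sd over a (2h+1)-point window
  w <- 2 * halfwidth + 1
  flux_sd <- sigma * sqrt(12 / (w * (w^2 - 1))) * (chamber / 1000) * 1e6
  worst <- 0
  for (i in 1:50) {
    k <- sample(2:5, 1)
    rates <- runif(k, 50, 300)
    prot <- data.frame(label = c("basal", paste0("S", seq_len(k - 1))),
                       duration_s = 240, rate_pmol_s = rates)
    # hyperoxygenated chamber so no protocol runs anoxic
    sim <- make_respirometry_trace(prot, chamber_ml = chamber, noise_sd = sigma,
                                   o2_start_uM = 450, seed = i)
    st <- extract_steady_states(
      compute_flux(sim$trace, halfwidth, breaks = sim$events$time_s),
      sim$events)
    worst <- max(worst, abs(st$jo2_pmol_s - rates))
  }
  # edge-truncated windows roughly double the point-level sd; 4x that bounds
  # the windowed mean comfortably
  expect_lt(worst, 8 * flux_sd)
})

test_that("correct_nonmito subtracts, floors and validates", {
  st <- structure(data.frame(label = c("basal", "Oligo", "Ant"),
                             jo2_pmol_s = c(100, 60, 5)),
                  class = c("steady_states", "data.frame"))
  cor <- correct_nonmito(st, "Ant")
  expect_equal(cor$jo2_pmol_s, c(95, 55))
  expect_equal(attr(cor, "residual_jo2"), 5)

  st$jo2_pmol_s <- c(100, 60, 0)
  expect_equal(correct_nonmito(st, "Ant")$jo2_pmol_s, c(100, 60))

  st$jo2_pmol_s <- c(100, 60, 70)
  expect_warning(cor2 <- correct_nonmito(st, "Ant"), "floored")
  expect_equal(cor2$jo2_pmol_s, c(30, 0))

  expect_error(correct_nonmito(st, "Rot"), "missing residual")
})

test_that("normalize_rates covers all bases and errors on missing denominators", {
  st <- structure(data.frame(label = c("basal", "FC"),
                             jo2_pmol_s = c(200, 400)),
                  class = c("steady_states", "data.frame"))
  sm <- sample_info(cells_millions = 2, protein_mg = 0.5)
  expect_equal(normalize_rates(st, sm, "cells")$rate, c(100, 200))
  expect_equal(normalize_rates(st, sm, "protein")$rate, c(400, 800))
  pb <- normalize_rates(st, sm, "percent_basal")
  expect_identical(pb$rate[pb$label == "basal"], 100)
  expect_equal(pb$rate, c(100, 200))

  expect_error(normalize_rates(st, sample_info(), "protein"), "protein_mg")
  expect_error(normalize_rates(st, sample_info(), "cells"), "cells_millions")
})

test_that("percent-of-basal maps basal to exactly 100 for any trace", {
  set.seed(5)
  for (i in 1:10) {
    prot <- data.frame(label = c("basal", "X"), duration_s = 240,
                       rate_pmol_s = runif(2, 10, 200))
    sim <- make_respirometry_trace(prot, noise_sd = 0.4, seed = i)
    st <- extract_steady_states(
      compute_flux(sim$trace, 10, breaks = sim$events$time_s), sim$events)
    pb <- normalize_rates(st, sample_info(), "percent_basal")
    expect_identical(pb$rate[pb$label == "basal"], 100)
  }
})

test_that("fccp_km recovers exact and noisy hyperbolae and excludes the collapse tail", {
  doses <- c(0, 0.25, 0.5, 1, 2, 3.5, 5)
  hyper <- function(d, vmax = 100, km = 1) vmax * d / (km + d)
  rates <- 20 + hyper(doses)
  fit <- fccp_km(doses, rates)
  expect_equal(fit$km_uM, 1, tolerance = 1e-6)
  expect_equal(fit$vmax, 100, tolerance = 1e-6)

  set.seed(21)
  fitn <- fccp_km(doses, 20 + hyper(doses) + rnorm(length(doses), 0, 2))
  expect_equal(fitn$km_uM, 1, tolerance = 0.15)

  # declining tail at 5 uM: excluded; compare with a brute-force grid oracle
  # restricted to the same ascending limb
  r_tail <- 20 + hyper(doses)
  r_tail[doses == 5] <- 60   # collapse
  fit_t <- fccp_km(doses, r_tail)
  keep <- doses > 0 & doses < 3.5    # strictly before the peak dose (3.5)
  d <- doses[keep]; y <- r_tail[keep] - 20
  grid <- expand.grid(km = seq(0.05, 5, by = 0.001),
                      vmax = seq(50, 150, by = 0.5))
  rss <- mapply(function(km, vmax) sum((y - vmax * d / (km + d))^2),
                grid$km, grid$vmax)
  best <- grid[which.min(rss), ]
  expect_equal(fit_t$km_uM, best$km, tolerance = 0.01)
  expect_equal(fit_t$n_used, sum(keep))

  expect_error(fccp_km(c(0, 1, 2), c(10, 50, 40)), "3 usable")
})

test_that("trace/events CSV round trip", {
  tdir <- withr::local_tempdir()
  t <- seq(0, 100, 5)
  tr <- oxygen_trace(t, 200 - 0.1 * t, 2)
  write.csv(data.frame(time_s = t, o2_uM = tr$o2_uM),
            file.path(tdir, "tr.csv"), row.names = FALSE)
  tr2 <- read_trace_csv(file.path(tdir, "tr.csv"), 2)
  expect_equal(tr2$o2_uM, tr$o2_uM)
  ev <- event_marks(c(10, 50), c("Oligo", "FC"), conc = c("0.02 uM", "1 uM"))
  write.csv(ev, file.path(tdir, "ev.csv"), row.names = FALSE)
  ev2 <- read_events_csv(file.path(tdir, "ev.csv"))
  expect_equal(ev2$label, c("Oligo", "FC"))
})
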