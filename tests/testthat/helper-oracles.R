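# Independent oracles and shared fixtures. Everything here deliberately takes
# the slow, literal route (explicit species enumeration, exhaustive search,
# brute-force definitions) so that agreement with the package's optimized
# implementations is informative.

# ---- speciation oracle -------------------------------------------------------
# Direct summation of species concentrations: given free H+ and free Mg2+,
# enumerate every protonation/Mg species of a ligand explicitly and sum.
oracle_species_sum <- function(free_anion, h, mg, kh = 0, kmg = 0, kmgh = 0) {
  free_anion + free_anion * h * kh + free_anion * mg * kmg +
    free_anion * h * mg * kmgh
}

# Apparent K'_CK by explicit species bookkeeping (not binding polynomials):
# put 1 unit of each reactant's reference species in place, build totals by
# species summation, and form the totals ratio times the species constant.
oracle_kck <- function(params, ph, mg, temperature) {
  bc <- params$binding_constants
  rc <- params$reference_conditions
  h <- 10^(-ph)
  tot <- function(h, mg) {
    list(
      atp = oracle_species_sum(1, h, mg, bc$atp_h, bc$atp_mg, bc$atp_mgh),
      adp = oracle_species_sum(1, h, mg, bc$adp_h, bc$adp_mg, bc$adp_mgh),
      pcr = oracle_species_sum(1, h, mg, bc$pcr_h, bc$pcr_mg))
  }
  t_ref <- tot(10^(-rc$ph), rc$mg_free)
  k_sp <- params$k_ck_ref * t_ref$pcr * t_ref$adp / (10^(-rc$ph) * t_ref$atp)
  t_now <- tot(h, mg)
  k_sp * h * t_now$atp / (t_now$pcr * t_now$adp)
}

# Root-finding speciation solver: free Mg from conservation of total Mg (with
# ADP itself at CK equilibrium), solved by uniroot rather than fixed point.
oracle_solve_adp <- function(comp, params) {
  bc <- params$binding_constants
  h <- 10^(-comp$ph)
  bound_mg <- function(mg, adp) {
    p_atp <- oracle_species_sum(1, h, mg, bc$atp_h, bc$atp_mg, bc$atp_mgh)
    p_adp <- oracle_species_sum(1, h, mg, bc$adp_h, bc$adp_mg, bc$adp_mgh)
    p_pcr <- oracle_species_sum(1, h, mg, bc$pcr_h, bc$pcr_mg)
    comp$atp_total * (mg * bc$atp_mg + h * mg * bc$atp_mgh) / p_atp +
      adp * (mg * bc$adp_mg + h * mg * bc$adp_mgh) / p_adp +
      comp$pcr * mg * bc$pcr_mg / p_pcr
  }
  adp <- 0
  for (i in 1:60) {
    f <- function(mg) mg + bound_mg(mg, adp) - comp$mg_total
    mg <- stats::uniroot(f, c(1e-12, comp$mg_total), tol = 1e-14)$root
    kck <- oracle_kck(params, comp$ph, mg, comp$temperature)
    adp_new <- comp$atp_total * comp$cr / (kck * comp$pcr)
    if (abs(adp_new - adp) < 1e-16) return(adp_new)
    adp <- adp_new
  }
  adp
}

random_composition <- function() {
  clamp_composition(
    atp_total = runif(1, 1e-3, 8e-3), pcr = runif(1, 0.5e-3, 5e-3),
    cr = runif(1, 1e-3, 10e-3), pi_total = runif(1, 2e-3, 15e-3),
    mg_total = runif(1, 1e-3, 8e-3), ph = runif(1, 6.6, 7.6),
    temperature = runif(1, 300, 315))
}

# ---- Huang threshold oracle --------------------------------------------------
# Exhaustive search over every candidate split of the empirical grey levels,
# recomputing the fuzzy-entropy criterion from scratch each time.
oracle_huang <- function(x) {
  v <- as.numeric(x)
  lev <- sort(unique(v))
  stopifnot(length(lev) >= 2)
  C <- max(v) - min(v)
  best <- Inf; best_thr <- NA
  for (i in seq_len(length(lev) - 1L)) {
    bg <- v[v <= lev[i]]; fg <- v[v > lev[i]]
    mu0 <- mean(bg); mu1 <- mean(fg)
    u <- ifelse(v <= lev[i], 1 / (1 + abs(v - mu0) / C),
                1 / (1 + abs(v - mu1) / C))
    ent <- ifelse(u >= 1 - 1e-15, 0, -u * log(u) - (1 - u) * log(1 - u))
    s <- sum(ent)
    if (s < best) { best <- s; best_thr <- (lev[i] + lev[i + 1L]) / 2 }
  }
  best_thr
}

# ---- BH step-up oracle -------------------------------------------------------
# Literal definition: q_(i) = min_{k >= i} m * p_(k) / k on the sorted scale.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# ---- synthetic pipeline runner ----------------------------------------------
# Generator -> respirometry -> metrics for one ground truth; returns the
# recovered summary statistics. Used by round-trip tests and acceptance.
run_ck_pipeline <- function(gt, seed, noise_sd = gt$noise_sd, halfwidth = 45) {
  prot <- make_ck_protocol(gt)
  simc <- make_respirometry_trace(prot$clamp, noise_sd = noise_sd, seed = seed,
                                  o2_start_uM = 450)
  sime <- make_respirometry_trace(prot$ets, noise_sd = noise_sd,
                                  seed = seed + 1L, o2_start_uM = 450)
  pol <- window_policy(lag_s = 90, window_s = 120)
  stc <- correct_nonmito(extract_steady_states(
    compute_flux(simc$trace, halfwidth, breaks = simc$events$time_s),
    simc$events, pol), "Ant")
  ste <- correct_nonmito(extract_steady_states(
    compute_flux(sime$trace, halfwidth, breaks = sime$events$time_s),
    sime$events, pol), "Ant")
  forces <- prot$kinetics$points$dg_atp
  labels <- c("CK_clamp", paste0("PCR#", seq_along(forces[-1])))
  kin <- kinetics_from_states(stc, forces, labels, fccp_label = "FC_dG")
  jt <- jh_total(ste$jo2_pmol_s[grepl("^FC#", ste$label)])
  jo <- jh_oxphos(kin)
  list(kinetics = kin,
       fractional_oxphos = fractional_oxphos(jo, jt),
       fccp_effect = fccp_effect(structure(kin$fccp_dgatp,
                                           basis = kin$basis), jo),
       jh_total = as.numeric(jt), jh_oxphos = as.numeric(jo))
}
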