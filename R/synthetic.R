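#' Bioenergetic ground truth for a simulated "cell type"
#'
#' The stated world for the generators: a PBMC-like profile has fractional
#' OXPHOS and FCCP effect near 1; a leukemia-like profile has both near 0.5
#' with a larger mitochondrial content. All rates are per million cells.
#'
#' Default magnitudes emulate a chamber loaded with one to two million cells
#' on a high-resolution respirometer: chamber-total fluxes of a few hundred
#' pmol O2/s against ~0.5 uM concentration noise.
#'
#' @param label cell-type label.
#' @param basal_rate basal JO2, pmol O2/s/million cells.
#' @param content_scale mitochondrial content multiplier (dimensionless).
#' @param jh_total maximal uncoupled rate, pmol O2/s/million cells.
#' @param fractional_oxphos target JH+ OXPHOS / JH+ Total, in (0, 1.5].
#' @param fccp_effect target FCCP(dG_ATP) / JH+ OXPHOS, in (0, 1.5].
#' @param dg_sensitivity shape exponent for the decline of JO2 with clamp
#'   force across the titration (larger = steeper decline).
#' @param po_ratio target P/O ratio.
#' @param noise_sd O2 concentration noise, micromolar.
#' @param seed integer seed (mandatory).
#' @return list of class `bioenergetic_truth`.
#' @export
bioenergetic_truth <- function(label = "pbmc_like", basal_rate = 200,
                               content_scale = 1, jh_total = 600,
                               fractional_oxphos = 1.0, fccp_effect = 1.0,
                               dg_sensitivity = 1.5, po_ratio = 2.5,
                               noise_sd = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(basal_rate >= 0, jh_total >= 0,
            fractional_oxphos > 0, fractional_oxphos <= 1.5,
            fccp_effect > 0, fccp_effect <= 1.5)
  structure(list(label = label, basal_rate = basal_rate,
                 content_scale = content_scale, jh_total = jh_total,
                 fractional_oxphos = fractional_oxphos,
                 fccp_effect = fccp_effect, dg_sensitivity = dg_sensitivity,
                 po_ratio = po_ratio, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "bioenergetic_truth")
}

#' Simulate a chamber respirometry trace from a step protocol
#'
#' O2(t) integrates `-rate / volume` within each protocol segment, with seeded
#' gaussian noise added on the concentration. The protocol's per-segment true
#' rates are returned as embedded ground truth.
#'
#' @param protocol data.frame with `label`, `duration_s`, `rate_pmol_s`
#'   (chamber-total rates, >= 0). The first segment is the pre-event baseline
#'   ("basal"); each later segment begins with an event mark of its label.
#' @param chamber_ml chamber volume, mL.
#' @param o2_start_uM starting O2 concentration.
#' @param noise_sd gaussian noise sd on O2, micromolar.
#' @param seed integer seed.
#' @param dt_s sampling interval, seconds.
#' @param sample a [sample_info()].
#' @return list: `trace` ([oxygen_trace]), `events` ([event_marks]), `truth`
#'   (the protocol with segment start/end times).
#' @export
make_respirometry_trace <- function(protocol, chamber_ml = 2, o2_start_uM = 200,
                                    noise_sd = 0.5, seed = 1, dt_s = 1,
                                    sample = sample_info()) {
  stopifnot(is.data.frame(protocol),
            all(c("label", "duration_s", "rate_pmol_s") %in% names(protocol)))
  if (any(protocol$duration_s <= 0)) stop("durations must be > 0")
  if (any(protocol$rate_pmol_s < 0)) stop("segment rates must be >= 0")
  set.seed(seed)
  starts <- cumsum(c(0, head(protocol$duration_s, -1)))
  total <- sum(protocol$duration_s)
  t <- seq(0, total, by = dt_s)
  # pmol/s -> uM/s decline: rate * 1e-6 umol/s / (chamber L) = uM/s
  slope_uM_s <- protocol$rate_pmol_s * 1e-6 / (chamber_ml / 1000)
  seg <- findInterval(t, starts, rightmost.closed = FALSE)
  seg[seg < 1L] <- 1L
  o2 <- o2_start_uM - cumsum(c(0, slope_uM_s[seg[-1]] * diff(t)))
  o2 <- o2 + rnorm(length(o2), 0, noise_sd)
  o2[o2 < 0] <- 0
  truth <- cbind(protocol, start_s = starts,
                 end_s = starts + protocol$duration_s)
  ev <- if (nrow(protocol) > 1L) {
    event_marks(starts[-1], protocol$label[-1])
  } else {
    event_marks(numeric(0), character(0))
  }
  list(trace = oxygen_trace(t, o2, chamber_ml, sample), events = ev,
       truth = truth)
}

#' Planted OXPHOS kinetics for a ground truth
#'
#' Rates decline with clamp force following a power-law sensitivity shape:
#' at force step i of n, `jo2_i = jh_oxphos * (1 - decline * s_i)` with
#' `s_i = ((i-1)/(n-1))^dg_sensitivity`. The landmark identities are planted
#' exactly: `jh_oxphos = fractional_oxphos * jh_total` and
#' `fccp_dgatp = fccp_effect * jh_oxphos`.
#'
#' @param gt a [bioenergetic_truth].
#' @param forces clamp forces (kJ/mol, strictly decreasing); defaults to the
#'   canonical titration.
#' @param decline total fractional decline across the titration (default 0.5).
#' @return an [oxphos_kinetics] with attribute `truth`.
#' @export
make_kinetics <- function(gt, forces = unname(canonical_clamp_forces()),
                          decline = 0.5) {
  stopifnot(inherits(gt, "bioenergetic_truth"))
  n <- length(forces)
  jh_ox <- gt$fractional_oxphos * gt$jh_total
  s <- if (n == 1L) 0 else ((seq_len(n) - 1) / (n - 1))^gt$dg_sensitivity
  jo2 <- jh_ox * (1 - decline * s)
  jo2[jo2 < 0] <- 0
  kin <- oxphos_kinetics(forces, jo2, fccp_dgatp = gt$fccp_effect * jh_ox,
                         assay_id = gt$label)
  attr(kin, "truth") <- gt
  kin
}

#' Full synthetic CK-clamp respirometry protocol
#'
#' Builds the step protocol of the OXPHOS kinetics assay (basal, digitonin,
#' clamp at the minimal force, PCr titration steps, oligomycin, FCCP at
#' dG_ATP, antimycin A) with segment rates planted from the ground truth, and
#' the matching adenylate-free ETS capacity protocol (basal, digitonin, FCCP
#' titration to `jh_total`, antimycin A).
#'
#' @param gt a [bioenergetic_truth].
#' @param forces clamp forces of the titration.
#' @param segment_s duration of each protocol segment, seconds.
#' @param residual_rate non-mitochondrial rate added to every segment.
#' @param decline passed to [make_kinetics()].
#' @return list with `clamp` and `ets` protocols (data.frames usable with
#'   [make_respirometry_trace()]), plus `kinetics` (the planted
#'   [oxphos_kinetics]) and `truth`.
#' @export
make_ck_protocol <- function(gt, forces = unname(canonical_clamp_forces()),
                             segment_s = 300, residual_rate = 10,
                             decline = 0.5) {
  kin <- make_kinetics(gt, forces, decline)
  jo2 <- kin$points$jo2
  clamp <- data.frame(
    label = c("basal", "Digi",
              c("CK_clamp", paste0("PCR#", seq_along(forces[-1])))[seq_along(forces)],
              "Oligo", "FC_dG", "Ant"),
    duration_s = segment_s,
    rate_pmol_s = c(gt$basal_rate, gt$basal_rate * 0.8, jo2,
                    0.15 * gt$jh_total, kin$fccp_dgatp, 0) + residual_rate)
  fc_rates <- gt$jh_total * c(0.6, 0.9, 1.0, 0.95)
  ets <- data.frame(
    label = c("basal", "Digi", paste0("FC#", seq_along(fc_rates)), "Ant"),
    duration_s = segment_s,
    rate_pmol_s = c(gt$basal_rate, gt$basal_rate * 0.8, fc_rates, 0) + residual_rate)
  list(clamp = clamp, ets = ets, kinetics = kin, truth = gt,
       residual_rate = residual_rate)
}

#' Paired synthetic JATP/JO2 measurement for P/O
#'
#' Simulates the parallel ATP-synthesis fluorometry and respirometry
#' experiment: a steady JO2 and an ATP accumulation series whose slope is
#' `jatp = po_ratio * 2 * jo2`, both with seeded noise.
#'
#' @param gt a [bioenergetic_truth].
#' @param jo2 steady-state oxygen flux, pmol O2/s/million cells.
#' @param duration_s series length.
#' @param noise_sd relative noise on the ATP series increments.
#' @param seed integer seed.
#' @return list: `atp_series` (data.frame time_s, atp_pmol), `jo2_series`
#'   (data.frame time_s, jo2), `truth` (planted po_ratio and jatp).
#' @export
make_po_pair <- function(gt, jo2 = 100, duration_s = 300, noise_sd = 0.02,
                         seed = 1) {
  set.seed(seed)
  jatp <- gt$po_ratio * 2 * jo2
  t <- seq(0, duration_s)
  atp <- jatp * t + rnorm(length(t), 0, noise_sd * jatp * 5)
  jo2_series <- jo2 + rnorm(length(t), 0, noise_sd * jo2)
  list(atp_series = data.frame(time_s = t, atp_pmol = atp),
       jo2_series = data.frame(time_s = t, jo2 = jo2_series),
       truth = list(po_ratio = gt$po_ratio, jatp = jatp, jo2 = jo2))
}

#' Synthetic TMRM calibration and potential profile
#'
#' Forward-simulates a membrane-potential time profile through a known
#' monotone mV -> ratio map, returning the trace ratios, the calibration
#' points generated by the same map, and the true mV profile.
#'
#' @param mv_profile true potential series, millivolts (negative = polarized).
#' @param k_out_steps calibration KCl steps, mol/L.
#' @param k_in matrix K+, mol/L.
#' @param temperature kelvin.
#' @param noise_sd gaussian noise on ratios.
#' @param seed integer seed.
#' @return list: `ratios`, `calibration` ([potential_calibration]), `truth`.
#' @export
make_tmrm <- function(mv_profile, k_out_steps = c(1, 2, 5, 10, 30, 60, 120) * 1e-3,
                      k_in = 0.120, temperature = 310.15, noise_sd = 0,
                      seed = 1) {
  set.seed(seed)
  # forward map: ratio rises linearly as the membrane depolarizes
  fwd <- function(mv) 2 + mv / 100
  cal_mv <- nernst_mv(k_out_steps, k_in, temperature)
  cal <- potential_calibration(k_out_steps, fwd(cal_mv), k_in, temperature)
  ratios <- fwd(mv_profile) + rnorm(length(mv_profile), 0, noise_sd)
  list(ratios = ratios, calibration = cal,
       truth = list(mv = mv_profile, forward = fwd))
}

#' Synthetic voxel stack with known signal volumes
#'
#' Places axis-aligned cuboidal "nuclei" and surrounding "mitochondrial"
#' shells on a dim background; the true volume of every labelled region is
#' the exact voxel count times the voxel footprint, so volume recovery can be
#' asserted to machine precision. Border-touching cells can be planted to
#' exercise the whole-cell filter.
#'
#' @param cells data.frame with `cell_id`, `cx`, `cy`, `cz` (voxel centre),
#'   `nuc_half` (half-width of the nuclear cube, voxels) and `mito_extra`
#'   (shell thickness, voxels; 0 for none).
#' @param dims stack dimensions `c(z, y, x)`.
#' @param pixel_size_um,optical_section_um,step_um geometry.
#' @param levels intensity levels: background, nuclear, mito.
#' @param noise_sd gaussian noise sd (applied and rounded; keep small relative
#'   to level separation).
#' @param seed integer seed.
#' @return list: `stack` ([voxel_stack] with channels `nuclear` and `mito`),
#'   `truth` (per-cell true volumes in um^3 and border flags),
#'   `rois` ([roi_table]).
#' @export
make_stack <- function(cells, dims = c(8, 40, 40), pixel_size_um = 0.25,
                       optical_section_um = 1, step_um = 0.5,
                       levels = c(background = 10, nuclear = 200, mito = 150),
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  nuc <- array(levels[["background"]], dims)
  mito <- array(levels[["background"]], dims)
  n_steps <- max(1L, as.integer(round(optical_section_um / step_um)))
  vox_um3 <- pixel_size_um^2 * optical_section_um / n_steps
  truth <- list(); rois <- list()
  clamp <- function(v, n) pmin(pmax(v, 1L), n)
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    zr <- clamp((cl$cz - cl$nuc_half):(cl$cz + cl$nuc_half), dims[1])
    ext <- cl$nuc_half + cl$mito_extra
    border <- (cl$cy - ext) < 1 || (cl$cy + ext) > dims[2] ||
      (cl$cx - ext) < 1 || (cl$cx + ext) > dims[3]
    yr <- clamp((cl$cy - cl$nuc_half):(cl$cy + cl$nuc_half), dims[2])
    xr <- clamp((cl$cx - cl$nuc_half):(cl$cx + cl$nuc_half), dims[3])
    nuc[zr, yr, xr] <- levels[["nuclear"]]
    nuc_vox <- length(zr) * length(unique(yr)) * length(unique(xr))
    mito_vox <- 0L
    if (cl$mito_extra > 0) {
      e <- cl$mito_extra
      yrm <- clamp((cl$cy - cl$nuc_half - e):(cl$cy + cl$nuc_half + e), dims[2])
      xrm <- clamp((cl$cx - cl$nuc_half - e):(cl$cx + cl$nuc_half + e), dims[3])
      mito[zr, yrm, xrm] <- levels[["mito"]]
      inner <- length(zr) * length(unique(yr)) * length(unique(xr))
      mito[zr, yr, xr] <- levels[["background"]]  # hollow shell
      mito_vox <- length(zr) * length(unique(yrm)) * length(unique(xrm)) - inner
    }
    truth[[i]] <- data.frame(
      cell_id = cl$cell_id,
      nuclear_um3 = nuc_vox * vox_um3,
      mito_um3 = mito_vox * vox_um3,
      border = border)
    rois[[i]] <- data.frame(cell_id = cl$cell_id, cx = cl$cx, cy = cl$cy,
                            radius_px = (cl$nuc_half + cl$mito_extra) * 1.9 + 1,
                            z_min = 1L, z_max = dims[1])
  }
  if (noise_sd > 0) {
    nuc <- nuc + round(rnorm(length(nuc), 0, noise_sd))
    mito <- mito + round(rnorm(length(mito), 0, noise_sd))
  }
  r <- do.call(rbind, rois)
  class(r) <- c("roi_table", "data.frame")
  list(stack = voxel_stack(list(nuclear = nuc, mito = mito),
                           pixel_size_um, optical_section_um, step_um),
       truth = do.call(rbind, truth), rois = r)
}

#' Synthetic TMT PSM table with planted effects
#'
#' Intensities are `baseline x channel loading bias x group effect x lognormal
#' noise`, spread over 1-3 PSMs per protein; a fraction of entries is masked
#' to zero (missing). The truth table lists every planted log2 fold-change.
#'
#' @param n_proteins number of proteins.
#' @param kits number of kits.
#' @param channels_per_kit channels per kit (split evenly into two groups,
#'   `"A"` and `"B"`, within each kit).
#' @param loading_biases per-channel multiplicative loading biases (recycled);
#'   1 = balanced.
#' @param planted_lfc numeric vector (recycled over proteins) of log2
#'   fold-changes of group B over group A; 0 = null.
#' @param missing_rate fraction of protein/channel entries masked to 0.
#' @param noise_sdlog sdlog of the lognormal noise.
#' @param seed integer seed.
#' @return list: `psms` ([psm_table]), `design` ([plex_design]), `truth`
#'   (protein, planted lfc).
#' @export
make_tmt <- function(n_proteins = 200, kits = 2, channels_per_kit = 10,
                     loading_biases = 1, planted_lfc = 0, missing_rate = 0,
                     noise_sdlog = 0.1, seed = 1) {
  set.seed(seed)
  chans <- paste0("k", rep(seq_len(kits), each = channels_per_kit), "_c",
                  rep(seq_len(channels_per_kit), kits))
  kit <- rep(seq_len(kits), each = channels_per_kit)
  group <- rep(rep(c("A", "B"), each = ceiling(channels_per_kit / 2))[seq_len(channels_per_kit)],
               kits)
  design <- plex_design(chans, kit = paste0("kit", kit),
                        sample = paste0(chans, "_s"), group = group)
  bias <- rep_len(loading_biases, length(chans))
  lfc <- rep_len(planted_lfc, n_proteins)
  prots <- sprintf("P%04d", seq_len(n_proteins))
  base <- stats::rlnorm(n_proteins, meanlog = log(1e5), sdlog = 1)
  rows <- list()
  for (i in seq_len(n_proteins)) {
    n_psm <- sample(1:3, 1)
    share <- stats::runif(n_psm); share <- share / sum(share)
    for (ps in seq_len(n_psm)) {
      eff <- ifelse(group == "B", 2^lfc[i], 1)
      inten <- base[i] * share[ps] * bias * eff *
        stats::rlnorm(length(chans), 0, noise_sdlog)
      rows[[length(rows) + 1L]] <- c(
        list(protein = prots[i], peptide = paste0(prots[i], "_pep", ps),
             psm_id = paste0(prots[i], "_", ps), coiso = stats::runif(1, 0, 0.4),
             sn = stats::runif(1, 15, 60)),
        as.list(setNames(inten, chans)))
    }
  }
  d <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  if (missing_rate > 0) {
    for (ch in chans) {
      mask <- stats::runif(nrow(d)) < missing_rate
      d[[ch]][mask] <- 0
    }
  }
  list(psms = psm_table(d, chans), design = design,
       truth = data.frame(protein = prots, planted_lfc = lfc))
}
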