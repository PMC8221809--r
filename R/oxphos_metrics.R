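#' OXPHOS kinetics container
#'
#' Holds the (dG_ATP, JO2) curve from a CK-clamp titration plus, optionally,
#' the FCCP-supported rate measured after oligomycin at the final clamp force
#' ("FCCP at dG_ATP"). Rates must share one normalization basis, recorded as a
#' tag and enforced when rates from different sources enter ratios together.
#'
#' @param dg_atp clamp forces, kJ/mol, strictly decreasing across the titration.
#' @param jo2 rates at each force, >= 0.
#' @param fccp_dgatp optional FCCP-supported rate at the final force.
#' @param basis normalization basis tag (e.g. `"per_million_cells"`).
#' @param assay_id free-text identifier.
#' @return object of class `oxphos_kinetics`.
#' @export
oxphos_kinetics <- function(dg_atp, jo2, fccp_dgatp = NULL,
                            basis = "per_million_cells", assay_id = "") {
  stopifnot(length(dg_atp) == length(jo2))
  if (length(dg_atp) > 1L && any(diff(dg_atp) >= 0)) {
    stop("dg_atp values must be strictly decreasing across the titration")
  }
  if (any(jo2 < 0)) stop("rates must be >= 0")
  structure(list(points = data.frame(dg_atp = dg_atp, jo2 = jo2),
                 fccp_dgatp = fccp_dgatp, basis = basis, assay_id = assay_id),
            class = "oxphos_kinetics")
}

#' @export
print.oxphos_kinetics <- function(x, ...) {
  cat("<oxphos_kinetics>", x$assay_id, "(basis:", x$basis, ")\n")
  print(x$points)
  if (!is.null(x$fccp_dgatp)) cat("FCCP at final force:", x$fccp_dgatp, "\n")
  invisible(x)
}

.check_basis <- function(a, b) {
  if (!identical(a, b)) {
    stop(sprintf("normalization basis mismatch: '%s' vs '%s'", a, b))
  }
}

#' Maximal proton current of the respiratory system (JH+ Total)
#'
#' The maximum FCCP-supported rate, either from the substrate-replete
#' adenylate-free permeabilized protocol (`source = "ets"`) or from the
#' intact-cell FCCP titration (`source = "intact"`). The returned value is
#' tagged with its provenance.
#'
#' @param rates FCCP-titration rates (>= 1), one basis.
#' @param source which protocol supplied the rates.
#' @param basis normalization basis tag.
#' @return the maximal rate, with attributes `source` and `basis`.
#' @export
jh_total <- function(rates, source = c("ets", "intact"), basis = "per_million_cells") {
  source <- match.arg(source)
  if (!length(rates)) stop("empty input: need at least one FCCP-titration rate")
  structure(max(rates), source = source, basis = basis)
}

#' Proton current harnessed by the phosphorylation system (JH+ OXPHOS)
#'
#' The rate at the designated minimal clamp force (default -54.16 kJ/mol),
#' matched within `tol` kJ/mol.
#'
#' @param kin an [oxphos_kinetics] object.
#' @param force designated force, kJ/mol.
#' @param tol matching tolerance, kJ/mol.
#' @return the rate at the designated force (basis attribute attached).
#' @export
jh_oxphos <- function(kin, force = -54.16, tol = 0.05) {
  stopifnot(inherits(kin, "oxphos_kinetics"))
  i <- which(abs(kin$points$dg_atp - force) <= tol)
  if (!length(i)) {
    stop(sprintf("no titration point at %g kJ/mol (+-%g); available forces: %s",
                 force, tol, paste(kin$points$dg_atp, collapse = ", ")))
  }
  structure(kin$points$jo2[i[1]], basis = kin$basis)
}

#' Fractional OXPHOS
#'
#' JH+ OXPHOS / JH+ Total: the fraction of total respiratory capacity that the
#' phosphorylation system can harness. Near 1, essentially all proton current
#' is usable for ATP synthesis; near 0, it cannot be.
#'
#' @param jh_ox rate at the minimal clamp force ([jh_oxphos()]).
#' @param jh_tot maximal uncoupled rate ([jh_total()]).
#' @return dimensionless ratio.
#' @export
fractional_oxphos <- function(jh_ox, jh_tot) {
  if (jh_tot == 0) stop("jh_total is 0; fractional OXPHOS undefined")
  b1 <- attr(jh_ox, "basis"); b2 <- attr(jh_tot, "basis")
  if (!is.null(b1) && !is.null(b2)) .check_basis(b1, b2)
  as.numeric(jh_ox) / as.numeric(jh_tot)
}

#' FCCP effect
#'
#' Ratio of the FCCP-supported rate at the final clamp force to JH+ OXPHOS.
#' A value near 1 means the uncoupler fully restores respiration to the
#' minimal-force level; values well below 1 indicate ETS flux inhibition that
#' persists under high ATP free energy.
#'
#' @param fccp_dgatp FCCP-supported rate at the final clamp force.
#' @param jh_ox rate at the minimal clamp force.
#' @return dimensionless ratio.
#' @export
fccp_effect <- function(fccp_dgatp, jh_ox) {
  if (as.numeric(jh_ox) == 0) stop("jh_oxphos is 0; FCCP effect undefined")
  b1 <- attr(fccp_dgatp, "basis"); b2 <- attr(jh_ox, "basis")
  if (!is.null(b1) && !is.null(b2)) .check_basis(b1, b2)
  as.numeric(fccp_dgatp) / as.numeric(jh_ox)
}

#' Per-force relative inhibition profile
#'
#' Percent change of the treated curve relative to vehicle at each clamp
#' force. The two curves must sit on identical force grids (within `tol`).
#' A vehicle rate of exactly 0 yields an explicit `undefined` flag (NA
#' percent), not infinity.
#'
#' @param treated,vehicle [oxphos_kinetics] objects on the same grid/basis.
#' @param tol grid matching tolerance, kJ/mol.
#' @return data.frame: `dg_atp`, `percent_change`, `undefined`.
#' @export
relative_inhibition <- function(treated, vehicle, tol = 0.05) {
  stopifnot(inherits(treated, "oxphos_kinetics"), inherits(vehicle, "oxphos_kinetics"))
  .check_basis(treated$basis, vehicle$basis)
  a <- treated$points; b <- vehicle$points
  if (nrow(a) != nrow(b) || any(abs(a$dg_atp - b$dg_atp) > tol)) {
    stop("force grid mismatch between treated and vehicle kinetics")
  }
  undef <- b$jo2 == 0
  pc <- ifelse(undef, NA_real_, 100 * (a$jo2 - b$jo2) / b$jo2)
  data.frame(dg_atp = b$dg_atp, percent_change = pc, undefined = undef)
}

#' P/O ratio
#'
#' ATP synthesized per atom of oxygen consumed: `JATP / (2 * JO2)` from
#' parallel steady-state measurements on the same normalization basis.
#'
#' @param jatp ATP synthesis rate (pmol ATP/s, normalized).
#' @param jo2_ss steady-state oxygen flux (pmol O2/s, same basis).
#' @param basis_jatp,basis_jo2 basis tags; must match.
#' @return dimensionless P/O ratio.
#' @export
po_ratio <- function(jatp, jo2_ss, basis_jatp = "per_million_cells",
                     basis_jo2 = "per_million_cells") {
  if (jo2_ss == 0) stop("jo2_ss is 0; P/O undefined")
  .check_basis(basis_jatp, basis_jo2)
  jatp / (2 * jo2_ss)
}

#' Energy released per pmol ATP at a clamp force
#'
#' `|dG_ATP| * 1e-9` joule per pmol ATP (e.g. 5.416e-8 J/pmol at
#' -54.16 kJ/mol).
#'
#' @param dg_atp clamp force, kJ/mol.
#' @return J/pmol ATP.
#' @export
energy_per_pmol_atp <- function(dg_atp) abs(dg_atp) * 1e-9

#' OXPHOS power output
#'
#' Converts the clamp-titration oxygen fluxes to ATP production rates using an
#' empirically determined P/O ratio, `JATP = JO2 x P/O x 2`, then to power:
#' `power = JATP x |dG_ATP| x 1e-9` J/pmol, reported in microwatts per million
#' cells (for rates on the per-million-cells basis).
#'
#' @param kin an [oxphos_kinetics] with per-million-cells rates.
#' @param po P/O ratio (>= 0).
#' @return data.frame of class `power_points`: `dg_atp`, `jatp_pmol_s`,
#'   `power_uW`.
#' @export
power_output <- function(kin, po) {
  stopifnot(inherits(kin, "oxphos_kinetics"))
  if (!is.numeric(po) || po < 0) stop("po must be >= 0")
  jatp <- kin$points$jo2 * po * 2
  # pmol ATP/s * J/pmol = W; *1e6 -> uW
  power <- jatp * energy_per_pmol_atp(kin$points$dg_atp) * 1e6
  structure(data.frame(dg_atp = kin$points$dg_atp, jatp_pmol_s = jatp,
                       power_uW = power),
            basis = kin$basis, class = c("power_points", "data.frame"))
}

#' One-line OXPHOS summary
#'
#' @param kin an [oxphos_kinetics] (with `fccp_dgatp` set).
#' @param jh_tot [jh_total()] value for the same sample and basis.
#' @param po optional P/O ratio; when supplied, power at each force is added.
#' @param force designated minimal clamp force.
#' @return data.frame (one row) with jh_oxphos, jh_total, fractional_oxphos,
#'   fccp_effect and, when `po` is given, po_ratio and peak power.
#' @export
oxphos_summary <- function(kin, jh_tot, po = NULL, force = -54.16) {
  jo <- jh_oxphos(kin, force = force)
  out <- data.frame(
    assay_id = kin$assay_id,
    jh_oxphos = as.numeric(jo),
    jh_total = as.numeric(jh_tot),
    jh_total_source = attr(jh_tot, "source") %||% "ets",
    fractional_oxphos = fractional_oxphos(jo, jh_tot),
    fccp_effect = if (is.null(kin$fccp_dgatp)) NA_real_ else
      fccp_effect(structure(kin$fccp_dgatp, basis = kin$basis), jo))
  if (!is.null(po)) {
    pw <- power_output(kin, po)
    out$po_ratio <- po
    out$power_uW_max <- max(pw$power_uW)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble OXPHOS kinetics from steady states
#'
#' Maps labelled steady states from a CK-clamp respirometry run onto a clamp
#' force grid: the states named in `clamp_labels` (in titration order) become
#' the (dG_ATP, JO2) points and `fccp_label`, when present, supplies the
#' FCCP-at-dG_ATP rate.
#'
#' @param states a `steady_states` data.frame (typically after
#'   [correct_nonmito()] and normalization to a common basis).
#' @param forces clamp forces, one per element of `clamp_labels`.
#' @param clamp_labels state labels of the titration steps, in order.
#' @param fccp_label label of the post-oligomycin FCCP state (or `NULL`).
#' @param rates optional rate vector overriding `states$jo2_pmol_s`
#'   (e.g. a `normalized_rates$rate` column).
#' @param basis basis tag for the resulting kinetics.
#' @param assay_id identifier.
#' @return an [oxphos_kinetics].
#' @export
kinetics_from_states <- function(states, forces, clamp_labels,
                                 fccp_label = "FC_dG", rates = NULL,
                                 basis = "per_million_cells", assay_id = "") {
  stopifnot(length(forces) == length(clamp_labels))
  r <- if (is.null(rates)) states$jo2_pmol_s else rates
  idx <- match(clamp_labels, states$label)
  if (anyNA(idx)) {
    stop("missing clamp states: ",
         paste(clamp_labels[is.na(idx)], collapse = ", "))
  }
  fccp <- NULL
  if (!is.null(fccp_label)) {
    j <- match(fccp_label, states$label)
    if (!is.na(j)) fccp <- r[j]
  }
  oxphos_kinetics(forces, r[idx], fccp_dgatp = fccp, basis = basis,
                  assay_id = assay_id)
}
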