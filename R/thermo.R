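# Closed-form transforms from rate/equilibrium constants to free energies.
# Binding: dG_bind = RT ln(K_I), K_I in M. Activation: Eyring relation
# dG# = RT ln(k_B T / (h k)). The GSH arm converts a pseudo-first-order
# half-life into a second-order rate toward the thiolate before the Eyring
# transform, because only the deprotonated thiol is nucleophilic.

#' Thermodynamic context for free-energy transforms
#'
#' Bundles the physical constants and assay conditions used by the
#' free-energy transforms. Defaults: T = 298.15 K; exact SI constants
#' (R = 1.98720425e-3 kcal/mol/K, k_B = 1.380649e-23 J/K,
#' h = 6.62607015e-34 J s); glutathione 5 mM total, pH 7.4, thiol pKa 8.7.
#' The pKa is the standard literature value for the glutathione cysteine
#' thiol and is configurable, not hard-wired.
#'
#' @param T_K absolute temperature, K.
#' @param R_kcal gas constant, kcal/mol/K.
#' @param k_B Boltzmann constant, J/K.
#' @param h Planck constant, J s.
#' @param gsh_total_M total glutathione concentration, M.
#' @param pH assay pH.
#' @param pKa_gsh glutathione thiol pKa.
#' @return object of class \code{thermo_context}.
#' @export
thermo_context <- function(T_K = 298.15,
                           R_kcal = 1.98720425e-3,
                           k_B = 1.380649e-23,
                           h = 6.62607015e-34,
                           gsh_total_M = 5e-3,
                           pH = 7.4,
                           pKa_gsh = 8.7) {
  for (nm in c("T_K", "R_kcal", "k_B", "h", "gsh_total_M", "pH", "pKa_gsh"))
    check_finite(get(nm), nm)
  if (T_K <= 0 || R_kcal <= 0 || k_B <= 0 || h <= 0 || gsh_total_M <= 0)
    stop_domain("temperature, constants and gsh_total_M must be positive")
  structure(list(T_K = T_K, R_kcal = R_kcal, k_B = k_B, h = h,
                 gsh_total_M = gsh_total_M, pH = pH, pKa_gsh = pKa_gsh),
            class = "thermo_context")
}

#' Binding free energy from the noncovalent dissociation constant
#'
#' \code{dG_bind = R T ln(K_I)} with \code{K_I} in molar units; negative for
#' sub-molar dissociation constants.
#'
#' @param K_I dissociation constant, M, > 0. Vectorized.
#' @param ctx a \code{\link{thermo_context}}.
#' @return binding free energy, kcal/mol.
#' @examples
#' binding_free_energy(34.8e-6)  # about -6.1 kcal/mol
#' @export
binding_free_energy <- function(K_I, ctx = thermo_context()) {
  check_finite(K_I, "K_I")
  if (any(K_I <= 0)) stop_domain("K_I must be > 0")
  ctx$R_kcal * ctx$T_K * log(K_I)
}

#' Activation free energy from a first-order rate constant
#'
#' Eyring transition-state relation
#' \code{dG# = R T ln(k_B T / (h k))} with unit transmission coefficient.
#'
#' @param k rate constant, 1/s (or effective second-order rate treated as the
#'   rate entering the Eyring expression), > 0. Vectorized.
#' @param ctx a \code{\link{thermo_context}}.
#' @return activation free energy, kcal/mol.
#' @examples
#' eyring_barrier(31.7e-3)  # about 19.5 kcal/mol
#' @export
eyring_barrier <- function(k, ctx = thermo_context()) {
  check_finite(k, "k")
  if (any(k <= 0)) stop_domain("rate constant must be > 0")
  ctx$R_kcal * ctx$T_K * log(ctx$k_B * ctx$T_K / (ctx$h * k))
}

#' Thiolate fraction of a thiol at given pH
#'
#' Henderson-Hasselbalch deprotonated fraction
#' \code{1 / (1 + 10^(pKa - pH))}; only the thiolate is nucleophilic.
#'
#' @param pH solution pH.
#' @param pKa thiol pKa.
#' @return fraction in (0, 1).
#' @examples
#' thiolate_fraction(7.4, 8.7)  # 0.0477
#' @export
thiolate_fraction <- function(pH, pKa) {
  check_finite(pH, "pH"); check_finite(pKa, "pKa")
  1 / (1 + 10^(pKa - pH))
}

#' GSH reaction barrier from a measured half-life
#'
#' Converts a pseudo-first-order glutathione half-life into an activation
#' free energy: \code{k_pseudo = ln2 / t_half} (per second), divided by the
#' thiolate concentration \code{gsh_total * thiolate_fraction(pH, pKa)} to
#' give the second-order rate toward GS-, which enters the Eyring relation.
#' A censored half-life ("> 72 h", compounds with no detectable GSH
#' consumption over the sampling window) yields a lower bound: the barrier
#' evaluated at exactly the censoring limit, flagged \code{censored}.
#'
#' @param t_half_h glutathione half-life, hours, > 0.
#' @param ctx a \code{\link{thermo_context}}.
#' @param censored logical; TRUE when \code{t_half_h} is a lower censoring
#'   limit rather than a measured value.
#' @return list with \code{dG_kcal} (kcal/mol) and \code{censored}; when
#'   censored, \code{dG_kcal} is the lower bound of the barrier.
#' @examples
#' gsh_barrier(19)$dG_kcal   # about 19.3
#' gsh_barrier(72, censored = TRUE)  # bound: "> 20.1"
#' @export
gsh_barrier <- function(t_half_h, ctx = thermo_context(), censored = FALSE) {
  check_finite(t_half_h, "t_half_h")
  if (t_half_h <= 0) stop_domain("t_half_h must be > 0")
  k_pseudo <- log(2) / h_to_s(t_half_h)
  gs_minus <- ctx$gsh_total_M * thiolate_fraction(ctx$pH, ctx$pKa_gsh)
  k2 <- k_pseudo / gs_minus
  list(dG_kcal = eyring_barrier(k2, ctx), censored = isTRUE(censored))
}

#' Second-order covalent efficiency k_inact / K_I
#'
#' The low-concentration limit of \code{k_obs / c}; the field's standard
#' single-number potency measure for irreversible inhibitors.
#'
#' @param k_inact covalent-step rate, 1/s. Vectorized.
#' @param K_I dissociation constant, M, > 0. Vectorized.
#' @return efficiency, 1/M/s.
#' @examples
#' efficiency(10.1e-3, 34.8e-6)  # 290.2
#' @export
efficiency <- function(k_inact, K_I) {
  check_finite(k_inact, "k_inact"); check_finite(K_I, "K_I")
  if (any(K_I <= 0)) stop_domain("K_I must be > 0")
  k_inact / K_I
}

#' Mutant-selectivity factor from paired IC50s
#'
#' Ratio of the IC50 on a KRAS wild-type cell line to the IC50 on a
#' KRAS G12C mutant line; > 1 means mutant-selective.
#'
#' @param ic50_wt IC50 on the wild-type line (any consistent unit), > 0.
#' @param ic50_mut IC50 on the mutant line (same unit), > 0.
#' @return selectivity ratio.
#' @examples
#' selectivity_factor(82.0, 0.53)  # 154.7
#' @export
selectivity_factor <- function(ic50_wt, ic50_mut) {
  check_finite(ic50_wt, "ic50_wt"); check_finite(ic50_mut, "ic50_mut")
  if (any(ic50_wt <= 0) || any(ic50_mut <= 0))
    stop_domain("IC50 values must be > 0")
  ic50_wt / ic50_mut
}
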