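# Reference measured values for the nine-compound KRAS G12C switch II
# pocket inhibitor panel (acrylamides 1a/1b, chloroacetamides 2a/2b,
# imidazole carboxamides 3a/3b, aziridine carboxamides 4a/4b, and the
# clinical reference ARS-1620). These published summary values are inputs
# to the package: they parameterize the synthetic-data generators and serve
# as ground truth for validation. Values are mean +/- SD; n = 3 for IC50,
# n = 2 for t_1/2, k_inact and K_I.

#' Measured covalent-inhibition kinetics of the KRAS G12C inhibitor panel
#'
#' Per-compound glutathione half-life (h; NA with \code{gsh_censored} set
#' for "> 72 h" entries), nucleotide-exchange IC50 (uM), noncovalent
#' dissociation constant K_I (uM), covalent rate k_inact (1/s) and the
#' printed second-order efficiency k_inact/K_I (1/M/s), with SDs. The
#' \code{schedule} column records which occupancy sampling schedule the
#' compound class used ("fast": minutes; "slow": hours).
#'
#' @return data frame, one row per compound.
#' @examples
#' k <- kras_panel_kinetics()
#' with(k, efficiency(kinact_s, uM_to_M(KI_uM)))  # matches eff_printed
#' @export
kras_panel_kinetics <- function() {
  data.frame(
    compound = c("1a", "1b", "2a", "2b", "3a", "3b", "4a", "4b", "ARS-1620"),
    t_half_gsh_h = c(19, 44, 9, 4, 35, 40, NA, NA, 15),
    t_half_gsh_sd = c(1, 8, 4, 0.1, 11, 18, NA, NA, 2),
    gsh_censored = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     TRUE, TRUE, FALSE),
    ic50_uM = c(0.827, 0.520, 0.305, 0.642, 67.4, 243.2, 198, 84.4, 0.136),
    ic50_sd = c(0.137, 0.108, 0.040, 0.115, 11.3, 52.4, 39.0, 18.9, 0.019),
    KI_uM = c(34.8, 107.6, 40.1, 147.9, 40.9, 42.2, 22.2, 112.2, 17),
    KI_sd = c(9.3, 10.7, 11.7, 10.3, 16.7, 9.9, 1.8, 30.1, 3),
    kinact_s = c(10.1, 31.7, 19.2, 14.9, 0.4, 0.13, 0.091, 1.7, 26) * 1e-3,
    kinact_sd = c(1.0, 4.1, 0.9, 1.9, 0.1, 0.01, 0.002, 0.30, 2) * 1e-3,
    eff_printed = c(290.2, 294.6, 478.8, 100.7, 9.8, 3.1, 4.1, 15.2, 1529),
    eff_sd = c(82.7, 48.1, 141.5, 14.6, 4.7, 0.7, 0.3, 4.9, 294),
    schedule = c("fast", "fast", "fast", "fast", "slow", "slow",
                 "slow", "slow", "fast"))
}

#' Measured free energies of the KRAS G12C inhibitor panel
#'
#' Experimental binding free energy (RT ln K_I at 298.15 K), the
#' glutathione-arm activation barrier (censored rows carry the "> 20.1"
#' lower bound with \code{gsh_censored} set) and the on-target activation
#' barrier from k_inact, all in kcal/mol with replicate SDs.
#'
#' @return data frame, one row per compound.
#' @export
kras_panel_energies <- function() {
  data.frame(
    compound = c("1a", "1b", "2a", "2b", "3a", "3b", "4a", "4b", "ARS-1620"),
    dG_bind = c(-6.1, -5.4, -6.0, -5.2, -6.0, -6.0, -6.3, -5.4, -6.5),
    dG_bind_sd = c(0.3, 0.2, 0.3, 0.3, 0.4, 0.1, 0.1, 0.2, 0.1),
    dG_gsh = c(19.3, 19.8, 18.8, 18.4, 19.6, 19.7, 20.1, 20.1, 19.1),
    dG_gsh_sd = c(0.0, 0.1, 0.2, 0.0, 0.2, 0.3, NA, NA, 0.1),
    gsh_censored = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     TRUE, TRUE, FALSE),
    dG_target = c(20.1, 19.5, 19.8, 19.9, 22.0, 22.7, 22.9, 21.2, 19.6),
    dG_target_sd = c(0.1, 0.1, 0.0, 0.1, 0.2, 0.0, 0.0, 0.1, 0.1))
}

#' Measured cellular potency and selectivity of the panel
#'
#' Anti-proliferative IC50s (uM, MTT after 72 h) on one KRAS wild-type line
#' (LCLC-103H) and three KRAS G12C lines (H1792, MiaPaca2, H358), plus the
#' printed wild-type/mutant selectivity factors.
#'
#' @return list with two data frames: \code{ic50_uM} (cell lines x
#'   compounds) and \code{selectivity} (mutant lines x compounds);
#'   \code{wt_line} names the wild-type reference line.
#' @examples
#' v <- kras_panel_viability()
#' v$ic50_uM["LCLC-103H", "X1b"] / v$ic50_uM["MiaPaca2", "X1b"]  # 154.7
#' @export
kras_panel_viability <- function() {
  cmp <- c("1a", "1b", "2a", "2b", "3a", "3b", "4a", "4b", "ARS-1620")
  ic50 <- rbind(
    `LCLC-103H` = c(34.0, 82.0, 7.5, 4.2, 47.1, 41.6, 78.9, 91.8, 20.24),
    H1792 = c(16.2, 30.1, 2.9, 1.8, 17.9, 17.7, 22.6, 30.8, 10.19),
    MiaPaca2 = c(1.8, 0.53, 3.1, 3.2, 20.4, 8.8, 19.8, 48.2, 0.14),
    H358 = c(2.3, 1.1, 2.7, 1.8, 27.4, 9.9, 27.1, 90.0, 0.31))
  sel <- rbind(
    H1792 = c(2.1, 2.7, 2.6, 2.3, 2.6, 2.4, 3.5, 3.0, 1.9),
    MiaPaca2 = c(18.9, 154.7, 2.4, 1.3, 2.3, 4.7, 4.0, 1.9, 140.6),
    H358 = c(14.8, 74.5, 2.8, 2.3, 1.7, 4.2, 2.9, 1.0, 66.3))
  ic50 <- as.data.frame(ic50); names(ic50) <- make.names(cmp)
  sel <- as.data.frame(sel); names(sel) <- make.names(cmp)
  list(ic50_uM = ic50, selectivity = sel, wt_line = "LCLC-103H",
       compounds = cmp)
}
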