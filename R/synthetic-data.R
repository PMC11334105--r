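# Seeded generators emulating the four assay designs of the study, so every
# fitting stage is testable without external data. Generation starts at the
# occupancy/AUC/fluorescence level (no raw spectra or chromatograms).
# Noise defaults are plausible assay CVs: occupancy additive Gaussian sd
# 0.02 (fraction), AUC multiplicative lognormal sdlog 0.05, fluorescence
# Gaussian at 1% of trace amplitude, viability Gaussian sd 0.05.

#' Assay design container
#'
#' Concentrations, sampling schedule, replication and noise model of one
#' synthetic assay. Constructors with study defaults exist per assay:
#' \code{\link{occupancy_design}}, \code{\link{gsh_design}},
#' \code{\link{exchange_design}}, \code{\link{viability_design}}.
#'
#' @param conc_uM tested concentrations, micromolar.
#' @param times sampling times (unit given by \code{time_unit}).
#' @param time_unit "s" or "h".
#' @param replicates number of replicates (>= 1).
#' @param noise_sd noise scale; interpretation depends on \code{noise_model}.
#' @param noise_model "gaussian_sd" (additive) or "lognormal_sd"
#'   (multiplicative, sdlog).
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @param ... further assay-specific fields stored in the design.
#' @return object of class \code{assay_design} (a list).
#' @export
assay_design <- function(conc_uM, times, time_unit = c("s", "h"),
                         replicates = 1L, noise_sd = 0,
                         noise_model = c("gaussian_sd", "lognormal_sd"),
                         seed = 1L, ...) {
  time_unit <- match.arg(time_unit)
  noise_model <- match.arg(noise_model)
  stopifnot(replicates >= 1, noise_sd >= 0, all(times >= 0))
  structure(list(conc_uM = conc_uM, times = times, time_unit = time_unit,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 noise_model = noise_model, seed = as.integer(seed), ...),
            class = "assay_design")
}

#' Occupancy-assay design (MS target engagement)
#'
#' Study conditions: probe at 20, 40, 80, 160 uM; two biological replicates.
#' Fast-reacting compounds (acrylamides, chloroacetamides) were sampled at
#' 0.5, 2, 5, 15 and 60 min; slow ones (imidazole / aziridine carboxamides)
#' on an hours-scale schedule up to 24 h. A t = 0 point (unlabeled protein)
#' anchors each curve.
#'
#' @param schedule "fast" (minutes) or "slow" (hours).
#' @param conc_uM probe concentrations, uM.
#' @param replicates biological replicates.
#' @param noise_sd additive Gaussian sd on occupancy fractions.
#' @param plateau saturating occupancy used in generation, in (0, 1].
#' @param seed RNG seed.
#' @return an \code{\link{assay_design}} with times in seconds.
#' @export
occupancy_design <- function(schedule = c("fast", "slow"),
                             conc_uM = c(20, 40, 80, 160),
                             replicates = 2L, noise_sd = 0.02,
                             plateau = 0.95, seed = 1L) {
  schedule <- match.arg(schedule)
  times_s <- switch(schedule,
    fast = c(0, 0.5, 2, 5, 15, 60) * 60,
    slow = c(0, 1, 2.5, 4.5, 8.5, 24) * 3600)
  assay_design(conc_uM = conc_uM, times = times_s, time_unit = "s",
               replicates = replicates, noise_sd = noise_sd,
               noise_model = "gaussian_sd", seed = seed,
               plateau = plateau, schedule = schedule)
}

#' Generate a synthetic MS occupancy plate
#'
#' Occupancy values follow the analytic rapid-equilibrium model
#' \code{plateau * (1 - exp(-k_obs(c) t))} plus additive Gaussian noise,
#' clipped to [0, 1]; deterministic for a fixed design seed. (An ODE-based
#' generation path exists for cross-validation via
#' \code{\link{simulate_two_step_ode}}, but the analytic model is the
#' default, matching the assumption the downstream fits make.)
#'
#' @param params a \code{\link{two_step_params}}.
#' @param design an \code{\link{occupancy_design}}.
#' @param compound compound label carried into the table.
#' @return tidy data frame: \code{compound}, \code{conc_uM},
#'   \code{replicate}, \code{time_s}, \code{occupancy}.
#' @export
generate_occupancy_plate <- function(params, design, compound = "cpd") {
  stopifnot(inherits(params, "two_step_params"),
            inherits(design, "assay_design"))
  plateau <- if (is.null(design$plateau)) 0.95 else design$plateau
  grid <- expand.grid(time_s = design$times, conc_uM = design$conc_uM,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  kobs <- analytic_kobs(params, uM_to_M(grid$conc_uM))
  mu <- occupancy_curve_vec(kobs, plateau, grid$time_s)
  occ <- withr::with_seed(design$seed,
    mu + stats::rnorm(nrow(grid), 0, design$noise_sd))
  data.frame(compound = compound, conc_uM = grid$conc_uM,
             replicate = grid$replicate, time_s = grid$time_s,
             occupancy = pmin(pmax(occ, 0), 1))
}

# elementwise occupancy curve for vectors of k_obs and t of equal length
occupancy_curve_vec <- function(k_obs, plateau, times)
  plateau * (1 - exp(-k_obs * times))

#' GSH-reactivity assay design
#'
#' Study conditions: compound 250 uM with 100 uM internal standard, with or
#' without 5 mM glutathione, sampled at 0, 1, 2, 4, 8, 12, 24, 48 and 72 h;
#' duplicate determinations.
#'
#' @param replicates duplicate count.
#' @param noise_sdlog lognormal sdlog of the multiplicative AUC noise.
#' @param auc0 AUC at t = 0 (arbitrary units).
#' @param seed RNG seed.
#' @return an \code{\link{assay_design}} with times in hours.
#' @export
gsh_design <- function(replicates = 2L, noise_sdlog = 0.05, auc0 = 100,
                       seed = 1L) {
  assay_design(conc_uM = 250, times = c(0, 1, 2, 4, 8, 12, 24, 48, 72),
               time_unit = "h", replicates = replicates,
               noise_sd = noise_sdlog, noise_model = "lognormal_sd",
               seed = seed, auc0 = auc0)
}

#' Generate a paired GSH reactivity series
#'
#' The blank arm decays at the aqueous degradation rate \code{k_deg}; the
#' +GSH arm at \code{k_deg + k_gsh} (competing pseudo-first-order routes).
#' AUC noise is multiplicative lognormal.
#'
#' @param k_deg aqueous degradation rate, 1/h.
#' @param k_gsh glutathione consumption rate, 1/h.
#' @param design a \code{\link{gsh_design}}.
#' @param compound compound label.
#' @return tidy data frame: \code{compound}, \code{arm} ("blank"/"gsh"),
#'   \code{replicate}, \code{time_h}, \code{auc}.
#' @export
generate_gsh_series <- function(k_deg, k_gsh, design = gsh_design(),
                                compound = "cpd") {
  check_finite(k_deg, "k_deg"); check_finite(k_gsh, "k_gsh")
  if (k_deg < 0 || k_gsh < 0) stop_domain("rates must be >= 0")
  stopifnot(inherits(design, "assay_design"))
  grid <- expand.grid(time_h = design$times, arm = c("blank", "gsh"),
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rate <- ifelse(grid$arm == "blank", k_deg, k_deg + k_gsh)
  mu <- design$auc0 * exp(-rate * grid$time_h)
  auc <- withr::with_seed(design$seed,
    mu * exp(stats::rnorm(nrow(grid), 0, design$noise_sd)))
  data.frame(compound = compound, arm = grid$arm,
             replicate = grid$replicate, time_h = grid$time_h, auc = auc)
}

#' Nucleotide-exchange assay design
#'
#' Fluorescence read every 30 s for 60 min; three independent experiments.
#' The default inhibitor series is an 8-point 5-fold dilution from 100 uM,
#' wide enough to bracket sub-micromolar IC50s.
#'
#' @param conc_uM inhibitor concentrations, uM.
#' @param replicates independent experiments.
#' @param noise_frac Gaussian noise as a fraction of trace amplitude.
#' @param rate_ras_sos catalyzed exchange rate (positive control), 1/s.
#' @param rate_ras_only intrinsic exchange rate (negative control), 1/s.
#' @param hill Hill slope of the rate suppression.
#' @param seed RNG seed.
#' @return an \code{\link{assay_design}} with times in seconds.
#' @export
exchange_design <- function(conc_uM = 100 / 5^(0:7), replicates = 3L,
                            noise_frac = 0.01, rate_ras_sos = 2e-3,
                            rate_ras_only = 2e-4, hill = 1, seed = 1L) {
  assay_design(conc_uM = conc_uM, times = seq(0, 3600, by = 30),
               time_unit = "s", replicates = replicates,
               noise_sd = noise_frac, noise_model = "gaussian_sd",
               seed = seed, rate_ras_sos = rate_ras_sos,
               rate_ras_only = rate_ras_only, hill = hill)
}

#' Generate synthetic MANT-GDP exchange traces
#'
#' Each well's exchange rate interpolates between the RAS-only and
#' RAS+SOS1 control rates through a log-logistic suppression at the given
#' IC50; the trace is a single exponential at that rate (fluorescence
#' decreasing as MANT-GDP is released) plus Gaussian noise. Control wells
#' for both ends of the dynamic range are included per experiment.
#'
#' @param ic50 inhibitor IC50, M.
#' @param design an \code{\link{exchange_design}}.
#' @param compound compound label.
#' @return tidy data frame: \code{well}, \code{compound}, \code{role}
#'   ("sample"/"ras_sos"/"ras_only"), \code{conc_uM}, \code{replicate},
#'   \code{time_s}, \code{fluorescence}.
#' @export
generate_exchange_traces <- function(ic50, design = exchange_design(),
                                     compound = "cpd") {
  check_finite(ic50, "ic50")
  if (ic50 <= 0) stop_domain("ic50 must be > 0")
  stopifnot(inherits(design, "assay_design"))
  F0 <- 1000; Finf <- 200   # arbitrary fluorescence units, quench on release
  wells <- expand.grid(conc_uM = design$conc_uM,
                       replicate = seq_len(design$replicates),
                       KEEP.OUT.ATTRS = FALSE)
  wells$role <- "sample"
  ctrl <- expand.grid(conc_uM = 0, replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  wells <- rbind(wells,
                 transform(ctrl, role = "ras_sos"),
                 transform(ctrl, role = "ras_only"))
  inhib <- 1 / (1 + (uM_to_M(wells$conc_uM) / ic50)^design$hill)
  wells$rate <- ifelse(
    wells$role == "ras_only", design$rate_ras_only,
    design$rate_ras_only +
      (design$rate_ras_sos - design$rate_ras_only) *
      ifelse(wells$role == "ras_sos", 1, inhib))
  wells$well <- sprintf("W%03d", seq_len(nrow(wells)))
  nt <- length(design$times)
  long <- wells[rep(seq_len(nrow(wells)), each = nt), ]
  long$time_s <- rep(design$times, times = nrow(wells))
  mu <- Finf + (F0 - Finf) * exp(-long$rate * long$time_s)
  noise_sd <- design$noise_sd * abs(F0 - Finf)
  fl <- withr::with_seed(design$seed,
    mu + stats::rnorm(nrow(long), 0, noise_sd))
  out <- data.frame(well = long$well, compound = compound, role = long$role,
                    conc_uM = long$conc_uM, replicate = long$replicate,
                    time_s = long$time_s, fluorescence = fl)
  rownames(out) <- NULL
  out
}

#' Cell-viability assay design
#'
#' Study conditions: 6-point 5-fold dilution from 100 uM down to 32 nM,
#' three replicates per concentration in each of three independent
#' experiments; MTT viability read after 72 h of treatment.
#'
#' @param conc_uM tested concentrations, uM.
#' @param replicates replicates per concentration per experiment.
#' @param experiments independent experiments.
#' @param noise_sd additive Gaussian sd on viability fractions.
#' @param hill Hill slope used in generation.
#' @param seed RNG seed.
#' @return an \code{\link{assay_design}}.
#' @export
viability_design <- function(conc_uM = c(100, 20, 4, 0.8, 0.16, 0.032),
                             replicates = 3L, experiments = 3L,
                             noise_sd = 0.05, hill = 1, seed = 1L) {
  assay_design(conc_uM = conc_uM, times = 72, time_unit = "h",
               replicates = replicates, noise_sd = noise_sd,
               noise_model = "gaussian_sd", seed = seed,
               experiments = as.integer(experiments), hill = hill)
}

#' Generate a synthetic cell-viability plate
#'
#' Viability follows a log-logistic curve (top 1, bottom 0) at each cell
#' line's IC50, with additive Gaussian noise, floored at 0.
#'
#' @param ic50_per_line named numeric vector of IC50s in uM, one per cell
#'   line (names are the cell-line labels).
#' @param design a \code{\link{viability_design}}.
#' @param compound compound label.
#' @return tidy data frame: \code{cell_line}, \code{compound},
#'   \code{conc_uM}, \code{experiment}, \code{replicate}, \code{viability}.
#' @export
generate_viability_plate <- function(ic50_per_line,
                                     design = viability_design(),
                                     compound = "cpd") {
  check_finite(ic50_per_line, "ic50_per_line")
  if (any(ic50_per_line <= 0)) stop_domain("IC50s must be > 0")
  if (is.null(names(ic50_per_line)))
    stop("ic50_per_line must be a named vector of cell lines")
  stopifnot(inherits(design, "assay_design"))
  grid <- expand.grid(conc_uM = design$conc_uM,
                      replicate = seq_len(design$replicates),
                      experiment = seq_len(design$experiments),
                      cell_line = names(ic50_per_line),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ic50 <- ic50_per_line[grid$cell_line]
  mu <- 1 / (1 + (grid$conc_uM / ic50)^design$hill)
  v <- withr::with_seed(design$seed,
    mu + stats::rnorm(nrow(grid), 0, design$noise_sd))
  data.frame(cell_line = grid$cell_line, compound = compound,
             conc_uM = grid$conc_uM, experiment = grid$experiment,
             replicate = grid$replicate, viability = pmax(v, 0))
}
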