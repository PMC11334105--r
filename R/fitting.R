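# Regression stages of the analysis:
#   occupancy time course  --one-phase association-->  k_obs (per conc)
#   k_obs vs concentration --hyperbolic NLS-------->  (K_I, k_inact)
#   AUC decay series       --log-linear OLS-------->  k_deg / k_app -> k_GSH
#   fluorescence trace     --single exponential---->  exchange rate
#   normalized rates       --4-parameter logistic-->  IC50
# All nonlinear fits are unweighted Levenberg-Marquardt (minpack.lm) with
# relative tolerance 1e-10 and at most 1e4 function evaluations;
# non-convergence is a flagged state carried in the result, never an
# exception mid-pipeline.

nls_ctrl <- function() minpack.lm::nls.lm.control(
  ftol = 1e-10, ptol = 1e-10, maxfev = 1e4, maxiter = 1024)

safe_se <- function(fit, names) {
  se <- rep(NA_real_, length(names)); names(se) <- names
  out <- try(summary(fit)$coefficients, silent = TRUE)
  if (!inherits(out, "try-error")) {
    common <- intersect(names, rownames(out))
    se[common] <- out[common, "Std. Error"]
  }
  se
}

#' Fit a one-phase association to an occupancy time course
#'
#' Least-squares fit of \code{occupancy = plateau * (1 - exp(-k_obs * t))}
#' with the plateau free but constrained to (0, 1] (incomplete labeling at
#' saturation is common in intact-MS occupancy data) and occupancy fixed at
#' 0 for t = 0.
#'
#' @param times time points, seconds; at least 4 distinct values.
#' @param occupancy occupancy fractions in [0, 1], same length.
#' @param conc optional inhibitor concentration (M) carried into the result.
#' @return object of class \code{one_phase_fit}: \code{k_obs}, \code{plateau},
#'   their standard errors, \code{n_points}, \code{converged},
#'   \code{degenerate} (no signal), \code{conc}.
#' @examples
#' t <- c(0, 300, 600, 1200, 2400, 4800, 9600, 19200)
#' y <- occupancy_curve(2e-4, 0.95, t)
#' coef(fit_one_phase(t, y))
#' @export
fit_one_phase <- function(times, occupancy, conc = NA_real_) {
  check_finite(times, "times"); check_finite(occupancy, "occupancy")
  if (length(times) != length(occupancy))
    stop("times and occupancy lengths differ")
  if (length(unique(times)) < 4)
    stop("insufficient data: need >= 4 distinct time points, got ",
         length(unique(times)))
  if (any(occupancy < 0 | occupancy > 1))
    stop_domain("occupancy values must lie in [0, 1]")

  res <- list(k_obs = NA_real_, k_obs_se = NA_real_, plateau = NA_real_,
              plateau_se = NA_real_, n_points = length(times), conc = conc,
              converged = FALSE, degenerate = FALSE,
              times = times, occupancy = occupancy, fitted = NULL)

  if (max(occupancy) < 1e-10) {   # null signal: nothing was labeled
    res$k_obs <- 0; res$degenerate <- TRUE; res$converged <- TRUE
    class(res) <- "one_phase_fit"
    return(res)
  }

  # start strictly inside the box: a start on the bound freezes the
  # parameter in the projected Levenberg-Marquardt step
  p0 <- min(max(occupancy) * 1.05, 1 - 1e-6)
  # crude rate start from the linearized unlabeled fraction
  sel <- times > 0 & occupancy < 0.99 * p0 & occupancy > 0
  k0 <- if (any(sel)) {
    stats::median(-log(1 - occupancy[sel] / p0) / times[sel])
  } else 1 / stats::median(times[times > 0])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / stats::median(times[times > 0])

  df <- data.frame(t = times, y = occupancy)
  fit <- try(minpack.lm::nlsLM(
    y ~ plateau * (1 - exp(-k * t)), data = df,
    start = list(k = k0, plateau = p0),
    lower = c(k = 0, plateau = 1e-6), upper = c(k = Inf, plateau = 1),
    control = nls_ctrl()), silent = TRUE)

  if (inherits(fit, "try-error")) {
    class(res) <- "one_phase_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  se <- safe_se(fit, c("k", "plateau"))
  res$k_obs <- unname(cf["k"]); res$plateau <- unname(cf["plateau"])
  res$k_obs_se <- unname(se["k"]); res$plateau_se <- unname(se["plateau"])
  res$converged <- TRUE
  res$fitted <- stats::fitted(fit)
  class(res) <- "one_phase_fit"
  res
}

#' @export
coef.one_phase_fit <- function(object, ...)
  c(k_obs = object$k_obs, plateau = object$plateau)

#' @export
print.one_phase_fit <- function(x, ...) {
  cat("One-phase association fit\n")
  cat(sprintf("  k_obs   = %.4g +/- %.2g 1/s\n", x$k_obs, x$k_obs_se))
  cat(sprintf("  plateau = %.4g +/- %.2g\n", x$plateau, x$plateau_se))
  if (x$degenerate) cat("  [degenerate: no labeling signal]\n")
  if (!x$converged) cat("  [fit did not converge]\n")
  invisible(x)
}

#' @export
residuals.one_phase_fit <- function(object, ...) {
  if (is.null(object$fitted)) return(rep(NA_real_, object$n_points))
  object$occupancy - object$fitted
}

#' Fit the hyperbolic k_obs-concentration relation
#'
#' Unweighted nonlinear least squares of
#' \code{k_obs = k_inact * c / (K_I + c)} over at least three
#' concentrations, starting from \code{k_inact = max(k_obs)} and
#' \code{K_I = max(c)}. When the data are effectively linear in
#' concentration (fitted \code{K_I > 10 * max(c)}) the dissociation
#' constant is unidentifiable and the fit is flagged poorly determined.
#'
#' @param conc inhibitor concentrations, M; at least 3 distinct.
#' @param k_obs observed rates, 1/s, same length.
#' @param k_obs_se optional standard errors (carried, not used as weights).
#' @return object of class \code{two_step_fit}: \code{K_I}, \code{k_inact},
#'   standard errors, \code{poorly_determined}, \code{converged}.
#' @examples
#' p <- two_step_params(34.8e-6, 10.1e-3)
#' cc <- uM_to_M(c(20, 40, 80, 160))
#' coef(fit_kobs_vs_conc(cc, analytic_kobs(p, cc)))
#' @export
fit_kobs_vs_conc <- function(conc, k_obs, k_obs_se = NULL) {
  check_finite(conc, "conc"); check_finite(k_obs, "k_obs")
  if (length(conc) != length(k_obs)) stop("conc and k_obs lengths differ")
  if (length(unique(conc)) < 3)
    stop("need >= 3 distinct concentrations, got ", length(unique(conc)))
  if (any(conc <= 0)) stop_domain("concentrations must be > 0")
  if (any(k_obs < 0)) stop_domain("k_obs must be >= 0")

  res <- list(K_I = NA_real_, K_I_se = NA_real_, k_inact = NA_real_,
              k_inact_se = NA_real_, conc = conc, k_obs = k_obs,
              k_obs_se = k_obs_se, converged = FALSE,
              poorly_determined = FALSE)
  # raw nls.lm: unsaturating (near-linear) data drive K_I to a bound and
  # make the nls model wrapper error out instead of returning a flaggable
  # estimate
  resid_fn <- function(p) k_obs - p[1] * conc / (p[2] + conc)
  fit <- try(minpack.lm::nls.lm(
    par = c(ki = max(k_obs), K = max(conc)),
    fn = resid_fn,
    lower = c(0, 1e-12), upper = c(Inf, 1e9 * max(conc)),
    control = nls_ctrl()), silent = TRUE)
  if (!inherits(fit, "try-error") && fit$info %in% 1:4) {
    cf <- fit$par
    res$k_inact <- unname(cf["ki"]); res$K_I <- unname(cf["K"])
    se <- try(summary(fit)$coefficients[, "Std. Error"], silent = TRUE)
    if (!inherits(se, "try-error")) {
      res$k_inact_se <- unname(se["ki"]); res$K_I_se <- unname(se["K"])
    }
    res$converged <- TRUE
    res$poorly_determined <- res$K_I > 10 * max(conc)
  }
  class(res) <- "two_step_fit"
  res
}

#' @export
coef.two_step_fit <- function(object, ...)
  c(K_I = object$K_I, k_inact = object$k_inact)

#' @export
print.two_step_fit <- function(x, ...) {
  cat("Two-step covalent binding fit (k_obs vs concentration)\n")
  cat(sprintf("  K_I     = %.4g +/- %.2g M (%.3g uM)\n",
              x$K_I, x$K_I_se, M_to_uM(x$K_I)))
  cat(sprintf("  k_inact = %.4g +/- %.2g 1/s\n", x$k_inact, x$k_inact_se))
  cat(sprintf("  k_inact/K_I = %.4g 1/M/s\n", x$k_inact / x$K_I))
  if (x$poorly_determined)
    cat("  [K_I poorly determined: no saturation within tested range]\n")
  if (!x$converged) cat("  [fit did not converge]\n")
  invisible(x)
}

#' @export
predict.two_step_fit <- function(object, conc, ...)
  object$k_inact * conc / (object$K_I + conc)

#' @export
plot.two_step_fit <- function(x, ...) {
  cgrid <- seq(0, max(x$conc) * 1.1, length.out = 200)
  graphics::plot(M_to_uM(x$conc), x$k_obs, xlab = "inhibitor (uM)",
                 ylab = "k_obs (1/s)", pch = 19,
                 ylim = c(0, max(x$k_obs, x$k_inact) * 1.05), ...)
  graphics::lines(M_to_uM(cgrid), predict(x, cgrid))
  graphics::abline(h = x$k_inact, lty = 3)
  invisible(x)
}

#' Fit the full two-stage covalent kinetics procedure for one compound
#'
#' The flagship fitting function: takes a tidy occupancy table for a single
#' compound (columns \code{conc_uM}, \code{replicate}, \code{time_s},
#' \code{occupancy}), fits a one-phase association per concentration within
#' each replicate, then the hyperbolic k_obs-concentration relation per
#' replicate, and aggregates \code{K_I} and \code{k_inact} across replicates
#' as mean and sample SD. This replicate-first ordering matters: derived
#' energies computed per replicate and then averaged differ (slightly) from
#' energies of averaged parameters.
#'
#' @param data data frame with columns \code{conc_uM}, \code{time_s},
#'   \code{occupancy}, and optionally \code{replicate} (default one
#'   replicate) and \code{compound} (must be a single level).
#' @return object of class \code{covalent_fit} with components
#'   \code{K_I}, \code{k_inact} (replicate means, M and 1/s), \code{K_I_sd},
#'   \code{k_inact_sd}, \code{efficiency} (k_inact/K_I), per-replicate
#'   \code{replicate_fits}, the per-concentration \code{kobs_table}, and
#'   flags. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot}, \code{residuals}, \code{simulate}.
#' @examples
#' pars <- two_step_params(uM_to_M(34.8), 10.1e-3)
#' plate <- generate_occupancy_plate(pars, occupancy_design(seed = 1,
#'   noise_sd = 0))
#' fit <- fit_covalent_kinetics(plate)
#' coef(fit)
#' @export
fit_covalent_kinetics <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("conc_uM", "time_s", "occupancy")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if ("compound" %in% names(data) && length(unique(data$compound)) > 1)
    stop("fit_covalent_kinetics() fits one compound; got ",
         length(unique(data$compound)))
  compound <- if ("compound" %in% names(data)) unique(data$compound) else NA
  if (!"replicate" %in% names(data)) data$replicate <- 1L

  reps <- sort(unique(data$replicate))
  rep_fits <- list(); kobs_rows <- list()
  for (r in reps) {
    dr <- data[data$replicate == r, ]
    concs <- sort(unique(dr$conc_uM))
    kobs <- kse <- numeric(length(concs)); ok <- logical(length(concs))
    for (i in seq_along(concs)) {
      dc <- dr[dr$conc_uM == concs[i], ]
      op <- fit_one_phase(dc$time_s, dc$occupancy, conc = uM_to_M(concs[i]))
      kobs[i] <- op$k_obs; kse[i] <- op$k_obs_se
      ok[i] <- op$converged && !op$degenerate
      kobs_rows[[length(kobs_rows) + 1L]] <- data.frame(
        replicate = r, conc_uM = concs[i], k_obs = op$k_obs,
        k_obs_se = op$k_obs_se, plateau = op$plateau,
        converged = op$converged, degenerate = op$degenerate)
    }
    if (sum(ok) >= 3) {
      rep_fits[[as.character(r)]] <-
        fit_kobs_vs_conc(uM_to_M(concs[ok]), kobs[ok], kse[ok])
    }
  }
  if (length(rep_fits) == 0)
    stop("no replicate yielded >= 3 usable k_obs estimates")

  KIs <- vapply(rep_fits, function(f) f$K_I, numeric(1))
  kis <- vapply(rep_fits, function(f) f$k_inact, numeric(1))
  usable <- vapply(rep_fits, function(f) f$converged, logical(1))
  KIs <- KIs[usable]; kis <- kis[usable]
  aggK <- aggregate_replicates(KIs); aggk <- aggregate_replicates(kis)

  structure(list(
    compound = compound,
    K_I = aggK$mean, K_I_sd = aggK$sd,
    k_inact = aggk$mean, k_inact_sd = aggk$sd,
    efficiency = aggk$mean / aggK$mean,
    n_replicates = aggK$n,
    replicate_fits = rep_fits,
    kobs_table = do.call(rbind, kobs_rows),
    poorly_determined = any(vapply(rep_fits,
      function(f) f$poorly_determined, logical(1))),
    data = data), class = "covalent_fit")
}

#' @export
coef.covalent_fit <- function(object, ...)
  c(K_I = object$K_I, k_inact = object$k_inact)

#' @export
print.covalent_fit <- function(x, ...) {
  cat("Covalent inhibition kinetics",
      if (!is.na(x$compound[1])) paste0("for ", x$compound), "\n")
  cat(sprintf("  K_I     = %.3g uM", M_to_uM(x$K_I)))
  if (!is.na(x$K_I_sd)) cat(sprintf(" +/- %.2g", M_to_uM(x$K_I_sd)))
  cat(sprintf("   (n = %d replicates)\n", x$n_replicates))
  cat(sprintf("  k_inact = %.3g 1/s", x$k_inact))
  if (!is.na(x$k_inact_sd)) cat(sprintf(" +/- %.2g", x$k_inact_sd))
  cat("\n")
  cat(sprintf("  k_inact/K_I = %.4g 1/M/s\n", x$efficiency))
  if (x$poorly_determined)
    cat("  [warning: K_I poorly determined in at least one replicate]\n")
  invisible(x)
}

#' @export
summary.covalent_fit <- function(object, ...) {
  print(object)
  cat("\nPer-concentration k_obs:\n")
  print(object$kobs_table, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
predict.covalent_fit <- function(object, conc, ...)
  object$k_inact * conc / (object$K_I + conc)

#' @export
residuals.covalent_fit <- function(object, ...) {
  d <- object$data
  kobs <- predict(object, uM_to_M(d$conc_uM))
  kt <- object$kobs_table   # one row per (replicate, concentration)
  idx <- match(paste(d$conc_uM, d$replicate),
               paste(kt$conc_uM, kt$replicate))
  d$occupancy - kt$plateau[idx] * (1 - exp(-kobs * d$time_s))
}

#' @export
plot.covalent_fit <- function(x, ...) {
  kt <- x$kobs_table
  cgrid <- seq(0, max(uM_to_M(kt$conc_uM)) * 1.1, length.out = 200)
  graphics::plot(kt$conc_uM, kt$k_obs, pch = 19,
                 xlab = "inhibitor (uM)", ylab = "k_obs (1/s)",
                 ylim = c(0, max(kt$k_obs, x$k_inact) * 1.05), ...)
  graphics::lines(M_to_uM(cgrid), predict(x, cgrid))
  graphics::abline(h = x$k_inact, lty = 3)
  invisible(x)
}

#' @export
simulate.covalent_fit <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$data
  design <- assay_design(
    conc_uM = sort(unique(d$conc_uM)),
    times = sort(unique(d$time_s)), time_unit = "s",
    replicates = length(unique(d$replicate)),
    noise_sd = stats::sd(residuals(object), na.rm = TRUE),
    seed = if (is.null(seed)) 1L else seed)
  pars <- two_step_params(object$K_I, object$k_inact)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    design$seed <- design$seed + i - 1L
    out[[i]] <- generate_occupancy_plate(pars, design)
  }
  if (nsim == 1) out[[1]] else out
}

#' Log-linear pseudo-first-order decay rate from an AUC series
#'
#' Ordinary least-squares regression of \code{ln(AUC)} on time; the decay
#' rate is the negated slope. The pseudo-first-order contract: the series
#' must be a single-exponential decay for the slope to be the rate.
#'
#' @param times_h sampling times, hours; at least 3 points.
#' @param auc internal-standard-corrected chromatographic peak areas; all
#'   must be positive.
#' @return decay rate, 1/h (possibly slightly negative for noisy flat
#'   series; downstream correction clamps).
#' @examples
#' t <- c(0, 1, 2, 4, 8, 12, 24, 48, 72)
#' fit_log_linear_rate(t, 100 * exp(-0.05 * t))  # 0.05
#' @export
fit_log_linear_rate <- function(times_h, auc) {
  check_finite(times_h, "times_h"); check_finite(auc, "auc")
  if (length(times_h) != length(auc)) stop("times and auc lengths differ")
  if (length(times_h) < 3) stop("need >= 3 AUC points")
  if (any(auc <= 0))
    stop_domain("nonpositive AUC at t = ",
                paste(times_h[auc <= 0], collapse = ", "), " h")
  -unname(stats::coef(stats::lm(log(auc) ~ times_h))[2])
}

#' Correct an apparent GSH consumption rate for aqueous degradation
#'
#' With glutathione in large excess the compound disappears by two competing
#' pseudo-first-order routes, \code{k_app = k_deg + k_GSH}; the intrinsic
#' thiol reactivity is \code{k_GSH = k_app - k_deg} and its half-life is
#' \code{ln 2 / k_GSH}. Rates whose OLS slope came out slightly negative
#' (down to -1e-3 1/h) are clamped to zero with a warning. When the
#' corrected rate is at or below the censoring threshold \code{ln 2 / 72}
#' (no measurable GSH reaction within the 72 h sampling window) the result
#' is censored and reported as "> 72 h".
#'
#' @param k_app apparent decay rate with GSH, 1/h.
#' @param k_deg aqueous degradation rate (blank arm), 1/h.
#' @param censor_h censoring horizon, hours (last sampled point).
#' @return object of class \code{gsh_result}: \code{k_deg}, \code{k_app},
#'   \code{k_GSH}, \code{t_half_gsh_h} (NA when censored), \code{censored},
#'   \code{censor_h}.
#' @examples
#' correct_gsh_rate(k_app = log(2) / 19 + 0.01, k_deg = 0.01)  # 19 h
#' @export
correct_gsh_rate <- function(k_app, k_deg, censor_h = 72) {
  check_finite(k_app, "k_app"); check_finite(k_deg, "k_deg")
  clamp <- function(k, nm) {
    if (k < 0) {
      if (k < -1e-3)
        return(k)            # beyond clamp tolerance; handled below
      warning(nm, " slightly negative (", signif(k, 3), " 1/h); clamped to 0")
      return(0)
    }
    k
  }
  k_app <- clamp(k_app, "k_app"); k_deg <- clamp(k_deg, "k_deg")
  res <- list(k_deg = k_deg, k_app = k_app, k_GSH = NA_real_,
              t_half_gsh_h = NA_real_, censored = FALSE, censor_h = censor_h,
              diagnostic = NULL)
  if (k_app < 0 || k_deg < 0 || k_app < k_deg - 1e-3) {
    res$censored <- TRUE
    res$k_GSH <- 0
    res$diagnostic <- "k_deg exceeds k_app beyond clamp tolerance"
  } else {
    res$k_GSH <- max(k_app - k_deg, 0)
    if (res$k_GSH <= log(2) / censor_h) {
      res$censored <- TRUE
    } else {
      res$t_half_gsh_h <- log(2) / res$k_GSH
    }
  }
  class(res) <- "gsh_result"
  res
}

#' @export
print.gsh_result <- function(x, ...) {
  cat("GSH surrogate reactivity\n")
  cat(sprintf("  k_deg = %.4g 1/h, k_app = %.4g 1/h, k_GSH = %.4g 1/h\n",
              x$k_deg, x$k_app, x$k_GSH))
  if (x$censored) {
    cat(sprintf("  t_1/2(GSH) > %g h (censored)\n", x$censor_h))
    if (!is.null(x$diagnostic)) cat("  note: ", x$diagnostic, "\n")
  } else cat(sprintf("  t_1/2(GSH) = %.4g h\n", x$t_half_gsh_h))
  invisible(x)
}

#' Fit both arms of a paired GSH reactivity series
#'
#' Convenience wrapper: log-linear rates for the blank and +GSH arms,
#' then the degradation correction.
#'
#' @param times_h sampling times, hours.
#' @param auc_blank AUC series without glutathione (degradation arm).
#' @param auc_gsh AUC series with 5 mM glutathione.
#' @param censor_h censoring horizon, hours.
#' @return a \code{gsh_result} (see \code{\link{correct_gsh_rate}}).
#' @export
fit_gsh_reactivity <- function(times_h, auc_blank, auc_gsh, censor_h = 72) {
  k_deg <- fit_log_linear_rate(times_h, auc_blank)
  k_app <- fit_log_linear_rate(times_h, auc_gsh)
  correct_gsh_rate(k_app, k_deg, censor_h = censor_h)
}

#' Single-exponential fit of a fluorescence exchange trace
#'
#' Fits \code{F(t) = F_inf + (F_0 - F_inf) * exp(-k * t)} with all three
#' parameters free; used for SOS1-catalyzed MANT-GDP exchange traces, where
#' nucleotide release dequenches the fluorophore.
#'
#' @param times seconds; at least 5 points.
#' @param fluorescence measured intensities.
#' @return list with \code{k} (1/s), \code{k_se}, \code{F0}, \code{Finf},
#'   \code{converged}, \code{degenerate} (flat trace).
#' @export
fit_exponential_trace <- function(times, fluorescence) {
  check_finite(times, "times"); check_finite(fluorescence, "fluorescence")
  if (length(times) < 5) stop("need >= 5 trace points")
  res <- list(k = NA_real_, k_se = NA_real_, F0 = NA_real_,
              Finf = NA_real_, converged = FALSE, degenerate = FALSE)
  amp <- diff(range(fluorescence))
  if (amp < 1e-12 * max(abs(fluorescence), 1)) {  # flat trace: no exchange
    res$k <- 0; res$degenerate <- TRUE; res$converged <- TRUE
    res$F0 <- res$Finf <- mean(fluorescence)
    return(res)
  }
  F0_0 <- fluorescence[which.min(times)]
  Finf_0 <- fluorescence[which.max(times)]
  mid <- F0_0 + (Finf_0 - F0_0) * (1 - exp(-1))
  t63 <- times[which.min(abs(fluorescence - mid))]
  k0 <- if (t63 > 0) 1 / t63 else 1 / stats::median(times[times > 0])
  df <- data.frame(t = times, y = fluorescence)
  fit <- try(minpack.lm::nlsLM(
    y ~ Finf + (F0 - Finf) * exp(-k * t), data = df,
    start = list(k = k0, F0 = F0_0, Finf = Finf_0),
    lower = c(k = 0, F0 = -Inf, Finf = -Inf),
    control = nls_ctrl()), silent = TRUE)
  if (inherits(fit, "try-error")) return(res)
  cf <- stats::coef(fit); se <- safe_se(fit, "k")
  res$k <- unname(cf["k"]); res$k_se <- unname(se["k"])
  res$F0 <- unname(cf["F0"]); res$Finf <- unname(cf["Finf"])
  res$converged <- TRUE
  res
}

#' Normalize an exchange rate to the assay dynamic range
#'
#' Scales a fitted exchange rate between the uncatalyzed (RAS-only, 0) and
#' fully catalyzed (RAS + SOS1, 1) controls:
#' \code{(rate - rate_ras_only) / (rate_ras_sos - rate_ras_only)}.
#'
#' @param rate_sample fitted rate for an inhibitor-treated well, 1/s.
#' @param rate_ras_sos positive control rate (no inhibitor), 1/s.
#' @param rate_ras_only negative control rate (no SOS1), 1/s.
#' @return normalized activity fraction (1 = uninhibited, 0 = fully
#'   inhibited). Vectorized over \code{rate_sample}.
#' @export
normalize_exchange_rates <- function(rate_sample, rate_ras_sos,
                                     rate_ras_only) {
  check_finite(rate_sample, "rate_sample")
  check_finite(rate_ras_sos, "rate_ras_sos")
  check_finite(rate_ras_only, "rate_ras_only")
  dr <- rate_ras_sos - rate_ras_only
  if (dr <= 0) stop_domain("zero or negative dynamic range: rate_ras_sos ",
                           "must exceed rate_ras_only")
  (rate_sample - rate_ras_only) / dr
}

#' Four-parameter log-logistic IC50 fit
#'
#' Fits \code{response = bottom + (top - bottom) / (1 + (c / ic50)^hill)}
#' to a concentration-response table (response decreasing with
#' concentration). Top and bottom are constrained to [0, 1.2] times the
#' maximal observed response. An IC50 fitted outside the tested
#' concentration range, or a response table with no transition, yields a
#' censored result ("> max conc" / "< min conc").
#'
#' @param concs concentrations, M; at least 4 distinct, all > 0.
#' @param responses normalized activity or viability fractions.
#' @return object of class \code{ic50_fit}: \code{ic50} (M), \code{ic50_se},
#'   \code{hill}, \code{top}, \code{bottom}, \code{censored},
#'   \code{censor_side} ("none", "above", "below"), \code{converged}.
#' @examples
#' cc <- uM_to_M(c(100, 20, 4, 0.8, 0.16, 0.032))
#' y <- 1 / (1 + (cc / 2.9e-6))
#' fit_ic50(cc, y)$ic50  # 2.9e-6
#' @export
fit_ic50 <- function(concs, responses) {
  check_finite(concs, "concs"); check_finite(responses, "responses")
  if (length(concs) != length(responses))
    stop("concs and responses lengths differ")
  if (length(unique(concs)) < 4)
    stop("need >= 4 distinct concentrations, got ", length(unique(concs)))
  if (any(concs <= 0)) stop_domain("concentrations must be > 0")

  res <- list(ic50 = NA_real_, ic50_se = NA_real_, hill = NA_real_,
              top = NA_real_, bottom = NA_real_, censored = FALSE,
              censor_side = "none", converged = FALSE,
              concs = concs, responses = responses)
  cap <- 1.2 * max(responses)
  # starts strictly inside the box (a start on a bound freezes the
  # parameter in the projected Levenberg-Marquardt step)
  top0 <- min(max(responses), cap - 1e-9)
  bot0 <- min(max(min(responses), 1e-9), cap - 1e-9)
  # start IC50 at the concentration whose mean response is nearest half-range
  half <- bot0 + (top0 - bot0) / 2
  mresp <- tapply(responses, concs, mean)
  ic0 <- as.numeric(names(mresp))[which.min(abs(mresp - half))]
  # log(ic50) parameterization keeps the problem well scaled over the
  # five orders of magnitude a dilution series spans; raw nls.lm is used
  # because an (almost) exact fit makes the nls model wrapper reject the
  # solution as a singular gradient
  lc <- log(concs)
  resid_fn <- function(p)
    responses - (p[4] + (p[3] - p[4]) / (1 + exp(p[2] * (lc - p[1]))))
  fit <- try(minpack.lm::nls.lm(
    par = c(lic50 = log(ic0), hill = 1, top = top0, bottom = bot0),
    fn = resid_fn,
    lower = c(log(1e-15), 0.05, 0, 0),
    upper = c(log(1e3), 20, cap, cap),
    control = nls_ctrl()), silent = TRUE)
  if (!inherits(fit, "try-error") && fit$info %in% 1:4) {
    cf <- fit$par
    res$ic50 <- exp(unname(cf["lic50"]))
    lse <- try(summary(fit)$coefficients["lic50", "Std. Error"],
               silent = TRUE)
    # delta method: se(ic50) = ic50 * se(log ic50)
    res$ic50_se <- if (inherits(lse, "try-error")) NA_real_ else
      res$ic50 * lse
    res$hill <- unname(cf["hill"]); res$top <- unname(cf["top"])
    res$bottom <- unname(cf["bottom"])
    res$converged <- TRUE
  }
  if (!res$converged || !is.finite(res$ic50) || res$ic50 > max(concs)) {
    res$censored <- TRUE; res$censor_side <- "above"
  } else if (res$ic50 < min(concs)) {
    res$censored <- TRUE; res$censor_side <- "below"
  }
  class(res) <- "ic50_fit"
  res
}

#' @export
coef.ic50_fit <- function(object, ...)
  c(ic50 = object$ic50, hill = object$hill,
    top = object$top, bottom = object$bottom)

#' @export
print.ic50_fit <- function(x, ...) {
  cat("Four-parameter log-logistic dose-response fit\n")
  if (x$censored) {
    lim <- if (x$censor_side == "above") max(x$concs) else min(x$concs)
    cat(sprintf("  IC50 %s %.3g uM (censored: no transition in range)\n",
                if (x$censor_side == "above") ">" else "<", M_to_uM(lim)))
  } else {
    cat(sprintf("  IC50 = %.4g uM +/- %.2g\n",
                M_to_uM(x$ic50), M_to_uM(x$ic50_se)))
  }
  cat(sprintf("  hill = %.3g, top = %.3g, bottom = %.3g\n",
              x$hill, x$top, x$bottom))
  invisible(x)
}

#' @export
predict.ic50_fit <- function(object, concs, ...)
  object$bottom + (object$top - object$bottom) /
    (1 + (concs / object$ic50)^object$hill)

#' @export
plot.ic50_fit <- function(x, ...) {
  graphics::plot(M_to_uM(x$concs), x$responses, log = "x", pch = 19,
                 xlab = "concentration (uM)", ylab = "response", ...)
  cg <- exp(seq(log(min(x$concs)), log(max(x$concs)), length.out = 200))
  graphics::lines(M_to_uM(cg), predict(x, cg))
  invisible(x)
}

#' Mean and sample SD of replicate estimates
#'
#' Arithmetic mean with n-1 denominator SD; a single replicate reports its
#' value with the SD absent (NA), never 0.
#'
#' @param values numeric vector, length >= 1.
#' @return list with \code{mean}, \code{sd} (NA when n = 1), \code{n}.
#' @export
aggregate_replicates <- function(values) {
  check_finite(values, "values")
  if (length(values) == 0) stop("no replicate values supplied")
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values))
}
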