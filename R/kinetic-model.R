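# Two-step covalent binding model:
#   E + I  <-> E.I  (k_1 association, k_-1 dissociation; K_I = k_-1 / k_1)
#   E.I    ->  E-I  (k_inact, irreversible chemical step)
# Under rapid pre-equilibrium and excess inhibitor the labeled fraction grows
# as a single exponential with rate k_obs = k_inact * c / (K_I + c).

#' Kinetic parameters of one compound-protein pair
#'
#' Constructs the parameter set of the two-step irreversible binding model:
#' the noncovalent dissociation constant \code{K_I} (M) and the first-order
#' rate of the chemical step \code{k_inact} (1/s). The microscopic rate
#' constants \code{k_1} (1/M/s) and \code{k_minus1} (1/s) are optional; when
#' both are supplied they must satisfy \code{K_I = k_minus1 / k_1} to within
#' 1e-9 relative, since the noncovalent step is treated as a fast equilibrium.
#'
#' @param K_I noncovalent dissociation constant, molar. Must be positive.
#' @param k_inact rate constant of the covalent step, 1/s. Must be >= 0.
#' @param k_1 optional association rate constant, 1/M/s.
#' @param k_minus1 optional dissociation rate constant, 1/s.
#' @return object of class \code{two_step_params}.
#' @examples
#' p <- two_step_params(K_I = 34.8e-6, k_inact = 10.1e-3)
#' analytic_kobs(p, 160e-6)
#' @export
two_step_params <- function(K_I, k_inact, k_1 = NULL, k_minus1 = NULL) {
  check_finite(K_I, "K_I"); check_finite(k_inact, "k_inact")
  if (K_I <= 0) stop_domain("K_I must be > 0 (got ", K_I, ")")
  if (k_inact < 0) stop_domain("k_inact must be >= 0 (got ", k_inact, ")")
  if (!is.null(k_1) && !is.null(k_minus1)) {
    check_finite(k_1, "k_1"); check_finite(k_minus1, "k_minus1")
    if (abs(k_minus1 / k_1 - K_I) > 1e-9 * K_I)
      stop_domain("k_minus1 / k_1 = ", k_minus1 / k_1,
                  " is inconsistent with K_I = ", K_I)
  }
  structure(list(K_I = K_I, k_inact = k_inact, k_1 = k_1, k_minus1 = k_minus1),
            class = "two_step_params")
}

#' @export
print.two_step_params <- function(x, ...) {
  cat("Two-step covalent binding parameters\n")
  cat(sprintf("  K_I      = %.4g M (%.4g uM)\n", x$K_I, M_to_uM(x$K_I)))
  cat(sprintf("  k_inact  = %.4g 1/s\n", x$k_inact))
  cat(sprintf("  k_inact/K_I = %.4g 1/M/s\n", x$k_inact / x$K_I))
  if (!is.null(x$k_1))
    cat(sprintf("  k_1 = %.4g 1/M/s, k_-1 = %.4g 1/s\n", x$k_1, x$k_minus1))
  invisible(x)
}

#' Observed inactivation rate at a given inhibitor concentration
#'
#' The pseudo-first-order inactivation rate of the rapid-equilibrium two-step
#' model, \code{k_obs = k_inact * c / (K_I + c)}. It is concave and saturating
#' in concentration, bounded above by \code{k_inact}.
#'
#' @param params a \code{\link{two_step_params}} object.
#' @param conc inhibitor concentration(s), molar, >= 0. Vectorized.
#' @return observed rate(s), 1/s.
#' @export
analytic_kobs <- function(params, conc) {
  stopifnot(inherits(params, "two_step_params"))
  check_finite(conc, "conc")
  if (any(conc < 0)) stop_domain("conc must be >= 0")
  params$k_inact * conc / (params$K_I + conc)
}

#' One-phase association occupancy curve
#'
#' Fractional target occupancy under pseudo-first-order labeling:
#' \code{occupancy(t) = plateau * (1 - exp(-k_obs * t))}. Equivalently the
#' unlabeled fraction decays exponentially; occupancy starts at 0 because the
#' protein is unlabeled at mixing time.
#'
#' @param k_obs observed inactivation rate, 1/s, >= 0.
#' @param plateau saturating occupancy level, in (0, 1].
#' @param times time points, seconds. Vectorized.
#' @return occupancy fractions, same length as \code{times}.
#' @export
occupancy_curve <- function(k_obs, plateau, times) {
  check_finite(k_obs, "k_obs"); check_finite(plateau, "plateau")
  check_finite(times, "times")
  if (k_obs < 0) stop_domain("k_obs must be >= 0")
  if (plateau <= 0 || plateau > 1)
    stop_domain("plateau must be in (0, 1], got ", plateau)
  plateau * (1 - exp(-k_obs * times))
}

#' Mass-action simulation of the two-step binding scheme
#'
#' Integrates the full mass-action ODE system of the two-step scheme
#' (free enzyme E, free inhibitor I, noncovalent complex EI, covalent adduct
#' EI_cov) without the rapid-equilibrium or excess-inhibitor approximations:
#' \deqn{dE/dt = -k_1 E I + k_{-1} EI}
#' \deqn{dI/dt = -k_1 E I + k_{-1} EI}
#' \deqn{dEI/dt = k_1 E I - (k_{-1} + k_{inact}) EI}
#' \deqn{dEI_{cov}/dt = k_{inact} EI}
#' Used to validate the analytic \code{\link{occupancy_curve}} in the
#' fast-pre-equilibrium regime. Integration uses an adaptive stiff solver
#' (\code{deSolve::lsoda}) with relative tolerance 1e-10 and absolute
#' tolerance 1e-14 M; these regimes are stiff when \code{k_1 I + k_minus1}
#' is much faster than \code{k_inact}.
#'
#' @param k_1 association rate, 1/M/s.
#' @param k_minus1 dissociation rate, 1/s.
#' @param k_inact covalent-step rate, 1/s.
#' @param E0 total enzyme, M, > 0.
#' @param I0 total inhibitor, M, > 0.
#' @param times output time grid, seconds (first element may be 0).
#' @return a \code{species_trajectory}: data frame with columns
#'   \code{time_s}, \code{E_M}, \code{I_M}, \code{EI_M}, \code{EI_cov_M}.
#' @examples
#' tr <- simulate_two_step_ode(1e6, 34.8, 10.1e-3, 2e-6, 160e-6,
#'                             times = seq(0, 300, by = 10))
#' max(abs(tr$E_M + tr$EI_M + tr$EI_cov_M - 2e-6))  # mass conservation
#' @export
simulate_two_step_ode <- function(k_1, k_minus1, k_inact, E0, I0, times) {
  for (nm in c("k_1", "k_minus1", "k_inact", "E0", "I0", "times"))
    check_finite(get(nm), nm)
  if (k_1 < 0 || k_minus1 < 0 || k_inact < 0)
    stop_domain("rate constants must be >= 0")
  if (E0 <= 0 || I0 <= 0) stop_domain("E0 and I0 must be > 0")
  times <- sort(unique(c(0, times)))

  deriv <- function(t, y, parms) {
    bind <- parms$k1 * y[["E"]] * y[["I"]]
    unbind <- parms$km1 * y[["EI"]]
    react <- parms$ki * y[["EI"]]
    list(c(E = -bind + unbind,
           I = -bind + unbind,
           EI = bind - unbind - react,
           EIc = react))
  }
  out <- deSolve::lsoda(
    y = c(E = E0, I = I0, EI = 0, EIc = 0),
    times = times, func = deriv,
    parms = list(k1 = k_1, km1 = k_minus1, ki = k_inact),
    rtol = 1e-10, atol = 1e-14)
  traj <- data.frame(time_s = out[, "time"], E_M = out[, "E"],
                     I_M = out[, "I"], EI_M = out[, "EI"],
                     EI_cov_M = out[, "EIc"])
  # tiny negative round-off from the integrator is clipped, not propagated
  for (col in c("E_M", "I_M", "EI_M", "EI_cov_M"))
    traj[[col]] <- pmax(traj[[col]], 0)
  total <- traj$E_M + traj$EI_M + traj$EI_cov_M
  if (any(abs(total - E0) > 1e-6 * E0))
    stop("enzyme mass balance violated beyond 1e-6 relative; ",
         "integration failed")
  class(traj) <- c("species_trajectory", "data.frame")
  traj
}

#' Covalent adduct fraction of a simulated trajectory
#'
#' @param traj a \code{species_trajectory} from
#'   \code{\link{simulate_two_step_ode}}.
#' @return fraction of total enzyme in the covalent adduct at each time.
#' @export
adduct_fraction <- function(traj) {
  stopifnot(inherits(traj, "species_trajectory"))
  total <- traj$E_M + traj$EI_M + traj$EI_cov_M
  traj$EI_cov_M / total
}
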