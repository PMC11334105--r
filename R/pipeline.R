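# Orchestration over the fitting and thermo modules: one call takes tidy
# assay tables (or CSV paths), runs every per-compound analysis, derives the
# free energies per replicate before averaging (the ordering that produces
# the small replicate SDs on the energy columns), and renders
# publication-style kinetics / energies / selectivity tables.

read_table_arg <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (!file.exists(x)) stop("input file for ", what, " not found: ", x)
    return(utils::read.csv(x, stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(x))
  x
}

#' Study configuration
#'
#' Validated configuration for \code{\link{run_pipeline}}. Inputs may be
#' tidy data frames or CSV paths (tidy dialects: occupancy
#' \code{compound,conc_uM,replicate,time_s,occupancy}; reactivity
#' \code{compound,arm,replicate,time_h,auc}; traces
#' \code{well,compound,role,conc_uM,replicate,time_s,fluorescence};
#' viability \code{cell_line,compound,conc_uM,experiment,replicate,
#' viability}). Unknown keys are rejected.
#'
#' @param occupancy MS occupancy table or path, or NULL.
#' @param reactivity GSH reactivity table or path, or NULL.
#' @param traces nucleotide-exchange trace table or path, or NULL.
#' @param viability cell-viability table or path, or NULL.
#' @param ctx a \code{\link{thermo_context}}.
#' @param wt_line name of the KRAS wild-type cell line for selectivity.
#' @param censor_h GSH censoring horizon, hours.
#' @param seed integer seed recorded for provenance.
#' @param ... rejected; catches misspelled keys.
#' @return object of class \code{study_config}.
#' @export
study_config <- function(occupancy = NULL, reactivity = NULL, traces = NULL,
                         viability = NULL, ctx = thermo_context(),
                         wt_line = "LCLC-103H", censor_h = 72,
                         seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "))
  stopifnot(inherits(ctx, "thermo_context"))
  structure(list(occupancy = occupancy, reactivity = reactivity,
                 traces = traces, viability = viability, ctx = ctx,
                 wt_line = wt_line, censor_h = censor_h,
                 seed = as.integer(seed)),
            class = "study_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(as.integer(charToRaw(txt)) *
                        (seq_along(charToRaw(txt)) %% 251 + 1)) %% .Machine$integer.max)
}

#' Analyze MANT-GDP exchange traces to per-compound IC50s
#'
#' Per experiment: single-exponential rate per well, normalization to the
#' RAS+SOS1 / RAS-only dynamic range, then a four-parameter log-logistic
#' IC50 fit; IC50s are aggregated across experiments as mean and SD.
#'
#' @param traces tidy trace table (see \code{\link{study_config}}).
#' @return data frame: \code{compound}, \code{ic50_M}, \code{ic50_sd_M},
#'   \code{n}, \code{censored}.
#' @export
analyze_exchange <- function(traces) {
  stopifnot(is.data.frame(traces))
  out <- list()
  for (cpd in unique(traces$compound)) {
    tc <- traces[traces$compound == cpd, ]
    ic50s <- c(); censored <- c()
    for (r in sort(unique(tc$replicate))) {
      tr <- tc[tc$replicate == r, ]
      rate_of <- function(d) fit_exponential_trace(d$time_s,
                                                   d$fluorescence)$k
      ctrl_rate <- function(role) {
        wells <- unique(tr$well[tr$role == role])
        mean(vapply(wells, function(w)
          rate_of(tr[tr$well == w, ]), numeric(1)))
      }
      k_sos <- ctrl_rate("ras_sos"); k_only <- ctrl_rate("ras_only")
      sw <- unique(tr$well[tr$role == "sample"])
      conc <- vapply(sw, function(w)
        tr$conc_uM[tr$well == w][1], numeric(1))
      rates <- vapply(sw, function(w) rate_of(tr[tr$well == w, ]),
                      numeric(1))
      act <- normalize_exchange_rates(rates, k_sos, k_only)
      fit <- fit_ic50(uM_to_M(conc), act)
      ic50s <- c(ic50s, fit$ic50); censored <- c(censored, fit$censored)
    }
    usable <- !censored & is.finite(ic50s)
    agg <- if (any(usable)) aggregate_replicates(ic50s[usable]) else
      list(mean = NA_real_, sd = NA_real_, n = 0L)
    out[[cpd]] <- data.frame(compound = cpd, ic50_M = agg$mean,
                             ic50_sd_M = agg$sd, n = agg$n,
                             censored = all(censored))
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Analyze a viability table to IC50s and selectivity factors
#'
#' Per cell line and compound: one log-logistic IC50 fit per independent
#' experiment, aggregated as mean and SD; selectivity factors divide the
#' wild-type line's mean IC50 by each mutant line's.
#'
#' @param viability tidy viability table (see \code{\link{study_config}}).
#' @param wt_line wild-type reference cell line.
#' @return list of data frames: \code{ic50} (per line and compound, uM) and
#'   \code{selectivity} (per mutant line and compound).
#' @export
analyze_viability <- function(viability, wt_line = "LCLC-103H") {
  stopifnot(is.data.frame(viability))
  if (!"experiment" %in% names(viability)) viability$experiment <- 1L
  rows <- list()
  for (cl in unique(viability$cell_line)) {
    for (cpd in unique(viability$compound)) {
      d <- viability[viability$cell_line == cl &
                       viability$compound == cpd, ]
      if (nrow(d) == 0) next
      fits <- lapply(sort(unique(d$experiment)), function(e) {
        de <- d[d$experiment == e, ]
        fit_ic50(uM_to_M(de$conc_uM), de$viability)
      })
      ok <- vapply(fits, function(f) !f$censored && f$converged, logical(1))
      vals <- vapply(fits[ok], function(f) f$ic50, numeric(1))
      agg <- if (length(vals)) aggregate_replicates(vals) else
        list(mean = NA_real_, sd = NA_real_, n = 0L)
      rows[[paste(cl, cpd)]] <- data.frame(
        cell_line = cl, compound = cpd, ic50_uM = M_to_uM(agg$mean),
        ic50_sd_uM = M_to_uM(agg$sd), n = agg$n,
        censored = !any(ok))
    }
  }
  ic50 <- do.call(rbind, rows); rownames(ic50) <- NULL
  sel <- NULL
  if (!is.null(ic50) && wt_line %in% ic50$cell_line) {
    wt <- ic50[ic50$cell_line == wt_line, c("compound", "ic50_uM")]
    mut <- ic50[ic50$cell_line != wt_line, ]
    sel <- merge(mut, wt, by = "compound", suffixes = c("", "_wt"))
    sel$selectivity <- selectivity_factor(sel$ic50_uM_wt, sel$ic50_uM)
    sel <- sel[order(sel$cell_line, sel$compound),
               c("cell_line", "compound", "selectivity")]
    rownames(sel) <- NULL
  }
  list(ic50 = ic50, selectivity = sel)
}

#' Run the full covalent-inhibition dissection pipeline
#'
#' Sequences, for every compound present in the inputs: the two-stage
#' occupancy fit to (K_I, k_inact); the degradation-corrected GSH
#' reactivity; the exchange-assay IC50; the viability IC50s with
#' selectivity factors; and the free-energy transforms. Free energies are
#' computed per replicate and then averaged. Per-compound failures are
#' caught, recorded in the \code{flags} column, and do not abort the run.
#'
#' @param config a \code{\link{study_config}}.
#' @return object of class \code{covkin_report}: \code{results} (one row
#'   per compound), \code{viability_ic50}, \code{selectivity}, \code{meta}
#'   (config hash, seed, timestamp-free provenance fields).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  occupancy <- read_table_arg(config$occupancy, "occupancy")
  reactivity <- read_table_arg(config$reactivity, "reactivity")
  traces <- read_table_arg(config$traces, "traces")
  viability <- read_table_arg(config$viability, "viability")
  ctx <- config$ctx

  compounds <- unique(c(
    if (!is.null(occupancy)) occupancy$compound,
    if (!is.null(reactivity)) reactivity$compound,
    if (!is.null(traces)) traces$compound))
  if (length(compounds) == 0) {
    warning("zero compounds found in the inputs; empty report")
    return(structure(list(results = data.frame(), viability_ic50 = NULL,
                          selectivity = NULL,
                          meta = list(hash = config_hash(config),
                                      seed = config$seed)),
                     class = "covkin_report"))
  }

  exch <- if (!is.null(traces)) analyze_exchange(traces) else NULL
  rows <- list()
  for (cpd in compounds) {
    row <- data.frame(compound = cpd, KI_uM = NA_real_, KI_sd = NA_real_,
                      kinact_s = NA_real_, kinact_sd = NA_real_,
                      kinact_over_KI = NA_real_,
                      t_half_gsh_h = NA_real_, t_half_gsh_sd = NA_real_,
                      gsh_censored = FALSE,
                      IC50_uM = NA_real_, IC50_sd = NA_real_,
                      dG_bind = NA_real_, dG_bind_sd = NA_real_,
                      dG_gsh = NA_real_, dG_gsh_sd = NA_real_,
                      dG_gsh_censored = FALSE,
                      dG_target = NA_real_, dG_target_sd = NA_real_,
                      flags = "")
    flags <- character()
    tryCatch({
      if (!is.null(occupancy) && cpd %in% occupancy$compound) {
        fit <- fit_covalent_kinetics(
          occupancy[occupancy$compound == cpd, ])
        row$KI_uM <- M_to_uM(fit$K_I); row$KI_sd <- M_to_uM(fit$K_I_sd)
        row$kinact_s <- fit$k_inact; row$kinact_sd <- fit$k_inact_sd
        row$kinact_over_KI <- fit$efficiency
        if (fit$poorly_determined) flags <- c(flags, "K_I poorly determined")
        # energies per replicate, then averaged
        KIs <- vapply(fit$replicate_fits, function(f) f$K_I, numeric(1))
        kis <- vapply(fit$replicate_fits, function(f) f$k_inact, numeric(1))
        gb <- aggregate_replicates(binding_free_energy(KIs, ctx))
        gt <- aggregate_replicates(eyring_barrier(kis, ctx))
        row$dG_bind <- gb$mean; row$dG_bind_sd <- gb$sd
        row$dG_target <- gt$mean; row$dG_target_sd <- gt$sd
      }
    }, error = function(e) flags <<- c(flags, paste("occupancy:",
                                                    conditionMessage(e))))
    tryCatch({
      if (!is.null(reactivity) && cpd %in% reactivity$compound) {
        d <- reactivity[reactivity$compound == cpd, ]
        if (!"replicate" %in% names(d)) d$replicate <- 1L
        per_rep <- lapply(sort(unique(d$replicate)), function(r) {
          dr <- d[d$replicate == r, ]
          bl <- dr[dr$arm == "blank", ]; gs <- dr[dr$arm == "gsh", ]
          fit_gsh_reactivity(bl$time_h, bl$auc, auc_gsh = gs$auc,
                             censor_h = config$censor_h)
        })
        cens <- vapply(per_rep, function(x) x$censored, logical(1))
        if (all(cens)) {
          row$gsh_censored <- TRUE
          bound <- gsh_barrier(config$censor_h, ctx, censored = TRUE)
          row$dG_gsh <- bound$dG_kcal; row$dG_gsh_censored <- TRUE
        } else {
          th <- vapply(per_rep[!cens], function(x) x$t_half_gsh_h,
                       numeric(1))
          agg <- aggregate_replicates(th)
          row$t_half_gsh_h <- agg$mean; row$t_half_gsh_sd <- agg$sd
          gg <- aggregate_replicates(vapply(th, function(t)
            gsh_barrier(t, ctx)$dG_kcal, numeric(1)))
          row$dG_gsh <- gg$mean; row$dG_gsh_sd <- gg$sd
          if (any(cens)) flags <- c(flags, "some GSH replicates censored")
        }
      }
    }, error = function(e) flags <<- c(flags, paste("gsh:",
                                                    conditionMessage(e))))
    if (!is.null(exch) && cpd %in% exch$compound) {
      e <- exch[exch$compound == cpd, ]
      row$IC50_uM <- M_to_uM(e$ic50_M); row$IC50_sd <- M_to_uM(e$ic50_sd_M)
      if (e$censored) flags <- c(flags, "exchange IC50 censored")
    }
    row$flags <- paste(flags, collapse = "; ")
    rows[[cpd]] <- row
  }
  results <- do.call(rbind, rows); rownames(results) <- NULL

  viab <- if (!is.null(viability))
    analyze_viability(viability, config$wt_line) else
    list(ic50 = NULL, selectivity = NULL)

  structure(list(results = results, viability_ic50 = viab$ic50,
                 selectivity = viab$selectivity,
                 meta = list(hash = config_hash(config),
                             seed = config$seed)),
            class = "covkin_report")
}

#' @export
print.covkin_report <- function(x, ...) {
  cat("Covalent-inhibition study report (config ", x$meta$hash,
      ", seed ", x$meta$seed, ")\n", sep = "")
  if (nrow(x$results) == 0) { cat("  [no compounds]\n"); return(invisible(x)) }
  print(x$results[, c("compound", "KI_uM", "kinact_s", "kinact_over_KI",
                      "t_half_gsh_h", "IC50_uM")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Round half to even at a fixed number of decimals
#'
#' Display rounding used by the table renderer: exact halves go to the even
#' neighbor (18.85 -> 18.8, 18.75 -> 18.8), other values round normally.
#' Operates on the decimal representation, so 18.85 is treated as an exact
#' half despite binary floating point.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_even <- function(x, digits = 1) {
  s <- x * 10^digits
  frac <- s - floor(s)
  out <- ifelse(abs(frac - 0.5) < 1e-9,
                floor(s) + (floor(s) %% 2),   # tie: pick the even integer
                round(s))
  out / 10^digits
}

fmt1 <- function(x, digits) {
  ifelse(is.na(x), NA_character_,
         sprintf(paste0("%.", digits, "f"), round_half_even(x, digits)))
}

#' Format "mean +/- SD" table entries
#'
#' @param mean,sd numeric vectors; an absent SD (NA) renders the bare mean.
#' @param digits decimal places (round-half-even).
#' @return character vector.
#' @export
fmt_pm <- function(mean, sd, digits = 1) {
  m <- fmt1(mean, digits); s <- fmt1(sd, digits)
  ifelse(is.na(m), NA_character_,
         ifelse(is.na(s), m, paste0(m, " ± ", s)))
}

#' Render publication-style tables from a report
#'
#' Produces the kinetics table (GSH half-life, IC50, K_I, k_inact,
#' k_inact/K_I), the free-energy table and the selectivity matrix as
#' formatted "mean +/- SD" data frames, censored entries rendered as
#' ">72" / ">20.1"-style strings. When \code{dir} is given, also writes
#' formatted CSVs plus a JSON file with the unrounded numeric columns.
#'
#' @param report a \code{covkin_report}.
#' @param dir optional output directory.
#' @return list of data frames: \code{kinetics}, \code{energies},
#'   \code{selectivity} (NULL when no viability input).
#' @export
render_tables <- function(report, dir = NULL) {
  stopifnot(inherits(report, "covkin_report"))
  r <- report$results
  if (nrow(r) == 0) {
    tabs <- list(kinetics = data.frame(), energies = data.frame(),
                 selectivity = NULL)
  } else {
    kinetics <- data.frame(
      compound = r$compound,
      t_half_gsh_h = ifelse(r$gsh_censored, ">72",
                            fmt_pm(r$t_half_gsh_h, r$t_half_gsh_sd, 0)),
      IC50_uM = fmt_pm(r$IC50_uM, r$IC50_sd, 3),
      KI_uM = fmt_pm(r$KI_uM, r$KI_sd, 1),
      kinact_1e3_s = fmt_pm(1e3 * r$kinact_s, 1e3 * r$kinact_sd, 1),
      kinact_over_KI = fmt1(r$kinact_over_KI, 1))
    energies <- data.frame(
      compound = r$compound,
      dG_bind = fmt_pm(r$dG_bind, r$dG_bind_sd, 1),
      dG_barrier_gsh = ifelse(r$dG_gsh_censored,
                              paste0(">", fmt1(r$dG_gsh, 1)),
                              fmt_pm(r$dG_gsh, r$dG_gsh_sd, 1)),
      dG_barrier_target = fmt_pm(r$dG_target, r$dG_target_sd, 1))
    sel <- NULL
    if (!is.null(report$selectivity)) {
      sel <- report$selectivity
      sel$selectivity <- fmt1(sel$selectivity, 1)
    }
    tabs <- list(kinetics = kinetics, energies = energies,
                 selectivity = sel)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tabs$kinetics, file.path(dir, "kinetics.csv"),
                     row.names = FALSE)
    utils::write.csv(tabs$energies, file.path(dir, "energies.csv"),
                     row.names = FALSE)
    if (!is.null(tabs$selectivity))
      utils::write.csv(tabs$selectivity, file.path(dir, "selectivity.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(results = report$results,
           viability_ic50 = report$viability_ic50,
           selectivity = report$selectivity, meta = report$meta),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  tabs
}

#' Materialize a complete synthetic nine-compound study
#'
#' Writes the four tidy assay CSVs (occupancy, reactivity, traces,
#' viability) for the full inhibitor panel, generated from the reference
#' measured values in \code{\link{kras_panel_kinetics}} and
#' \code{\link{kras_panel_viability}} under the study designs. Compounds
#' with a censored GSH half-life are generated with zero GSH rate.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; per-compound seeds are derived from it.
#' @param k_deg aqueous degradation rate used for every compound, 1/h.
#' @param noiseless logical; TRUE sets every noise scale to zero.
#' @return invisibly, the named list of file paths.
#' @export
write_study_fixtures <- function(dir, seed = 1L, k_deg = 0.01,
                                 noiseless = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kin <- kras_panel_kinetics()
  via <- kras_panel_viability()
  occ <- list(); rea <- list(); trc <- list(); vb <- list()
  for (i in seq_len(nrow(kin))) {
    cpd <- kin$compound[i]
    s <- as.integer(seed) + 37L * i
    pars <- two_step_params(uM_to_M(kin$KI_uM[i]), kin$kinact_s[i])
    od <- occupancy_design(schedule = kin$schedule[i], seed = s,
                           noise_sd = if (noiseless) 0 else 0.02)
    occ[[i]] <- generate_occupancy_plate(pars, od, compound = cpd)
    k_gsh <- if (kin$gsh_censored[i]) 0 else log(2) / kin$t_half_gsh_h[i]
    gd <- gsh_design(seed = s + 1L,
                     noise_sdlog = if (noiseless) 0 else 0.05)
    rea[[i]] <- generate_gsh_series(k_deg, k_gsh, gd, compound = cpd)
    ed <- exchange_design(seed = s + 2L,
                          noise_frac = if (noiseless) 0 else 0.01)
    trc[[i]] <- generate_exchange_traces(uM_to_M(kin$ic50_uM[i]), ed,
                                         compound = cpd)
    line_ic50 <- stats::setNames(
      unlist(via$ic50_uM[, make.names(cpd)]), rownames(via$ic50_uM))
    vd <- viability_design(seed = s + 3L,
                           noise_sd = if (noiseless) 0 else 0.05)
    vb[[i]] <- generate_viability_plate(line_ic50, vd, compound = cpd)
  }
  paths <- list(
    occupancy = file.path(dir, "occupancy.csv"),
    reactivity = file.path(dir, "reactivity.csv"),
    traces = file.path(dir, "traces.csv"),
    viability = file.path(dir, "viability.csv"))
  utils::write.csv(do.call(rbind, occ), paths$occupancy, row.names = FALSE)
  utils::write.csv(do.call(rbind, rea), paths$reactivity, row.names = FALSE)
  utils::write.csv(do.call(rbind, trc), paths$traces, row.names = FALSE)
  utils::write.csv(do.call(rbind, vb), paths$viability, row.names = FALSE)
  invisible(paths)
}
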