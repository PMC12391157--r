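#' Solver step count of the steady protocol
#'
#' The steady simulations run a fixed physical duration at a fixed time
#' step; the step count is their ratio (2.5 s at 0.0001 s gives 25,000
#' steps). Retained as protocol metadata by the analytic engine.
#'
#' @param duration simulated physical time in s.
#' @param dt time step in s.
#' @return integer number of solver steps.
#' @export
solver_step_count <- function(duration = 2.5, dt = 1e-4) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  as.integer(round(duration / dt))
}

#' Pipeline run configuration
#'
#' Bundles the protocol constants of the hemodynamics pipeline. The defaults
#' reproduce the analysis protocol: 10 Fourier modes for the inlet waveform,
#' 20 output timepoints per cycle, 0.1 cm centerline resampling, 2 indexed
#' Wood units at each branch outlet (1 iWU total lung resistance), blood
#' density 1.06 g/cm^3 and viscosity 0.04 g/(cm s), and the 2.5 s / 0.0001 s
#' steady-solver protocol carried as metadata.
#'
#' @param mode `"synthetic"` (generate a case) or `"import"` (consume
#'   externally computed WSS fields).
#' @param n_fourier_modes harmonics used for the inlet waveform.
#' @param n_output_timepoints output timepoints per cardiac cycle.
#' @param centerline_step resampling increment in cm.
#' @param fluid a [fluid_properties()].
#' @param resistances named per-outlet resistances in indexed Wood units.
#' @param bsa body surface area in m^2.
#' @param heart_rate beats/min for synthetic waveforms.
#' @param forward_volume forward stroke volume in mL for synthetic
#'   waveforms.
#' @param regurgitant_fraction synthetic-waveform RF in `[0, 1)`.
#' @param steady_duration,steady_dt steady-protocol metadata in s.
#' @param seed integer seed for all stochastic stages.
#' @param sv_convention `"net"` (default: steady inflow uses forward minus
#'   regurgitant volume) or `"forward"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "import"),
                       n_fourier_modes = 10L, n_output_timepoints = 20L,
                       centerline_step = 0.1,
                       fluid = fluid_properties(),
                       resistances = c(LPA = 2, RPA = 2), bsa = 1.3,
                       heart_rate = 75, forward_volume = 153.3,
                       regurgitant_fraction = 0.40,
                       steady_duration = 2.5, steady_dt = 1e-4,
                       seed = 1L,
                       sv_convention = c("net", "forward")) {
  mode <- match.arg(mode)
  sv_convention <- match.arg(sv_convention)
  structure(list(mode = mode, n_fourier_modes = as.integer(n_fourier_modes),
                 n_output_timepoints = as.integer(n_output_timepoints),
                 centerline_step = centerline_step, fluid = fluid,
                 resistances = resistances, bsa = bsa,
                 heart_rate = heart_rate, forward_volume = forward_volume,
                 regurgitant_fraction = regurgitant_fraction,
                 steady_duration = steady_duration, steady_dt = steady_dt,
                 steady_steps = solver_step_count(steady_duration, steady_dt),
                 seed = as.integer(seed), sv_convention = sv_convention),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config> mode %s | %d Fourier modes, %d output ",
                     "timepoints, %.2f cm resampling | HR %.0f bpm, RF %.2f",
                     " | steady protocol %d steps\n"),
              x$mode, x$n_fourier_modes, x$n_output_timepoints,
              x$centerline_step, x$heart_rate, x$regurgitant_fraction,
              x$steady_steps))
  invisible(x)
}

#' Run the hemodynamics pipeline for one case
#'
#' Synthetic mode: generates the bifurcation geometry and flow waveform,
#' computes centerline metrics for the inlet-to-outlet branch paths, builds
#' boundary conditions (Fourier inlet, resistance outlets), synthesizes the
#' steady and pulsatile wall-shear fields, and summarizes them per segment.
#' Import mode: consumes externally computed WSS series via
#' `case$steady_field` / `case$pulsatile_field` (or file paths in
#' `case$wss_files`) together with a waveform, and post-processes them the
#' same way.
#'
#' @param config a [run_config()].
#' @param case optional list of case inputs: `spec`
#'   (`pa_bifurcation_spec`), `waveform_spec` or `waveform`, and in import
#'   mode `steady_field`, `pulsatile_field` or `wss_files`.
#' @param out_dir optional directory: when given, centerlines, the
#'   waveform, fields and the summary are written there (CSV/VTP) with a
#'   JSON manifest of the configuration and seed.
#' @return An object of class `pa_case`: `summary` (`hemo_summary`),
#'   `geometry_metrics` (per-path curvature/tortuosity data.frame),
#'   `waveform`, `fourier`, `steady_field`, `pulsatile_field`, `labeling`,
#'   `config`.
#' @export
run_case <- function(config = run_config(), case = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "import" && is.null(case))
    stop("import mode requires case inputs")
  if (!is.null(case[["wss_files"]]) && !all(file.exists(unlist(case[["wss_files"]]))))
    stop("missing input path(s): ",
         paste(unlist(case[["wss_files"]])[!file.exists(unlist(case[["wss_files"]]))],
               collapse = ", "))
  net <- resistance_network(config$resistances, bsa = config$bsa)

  wf <- if (!is.null(case[["waveform"]])) case[["waveform"]]
    else make_flow_waveform(
      if (!is.null(case[["waveform_spec"]])) case[["waveform_spec"]]
      else waveform_spec(heart_rate = config$heart_rate,
                         forward_volume = config$forward_volume,
                         regurgitant_fraction = config$regurgitant_fraction))
  ff <- fourier_decompose(wf, config$n_fourier_modes)
  rf <- regurgitant_fraction(wf)
  sv <- switch(config$sv_convention,
               net = net_stroke_volume(wf),
               forward = periodic_integral(wf, pmax(wf$flows, 0)))
  q_steady <- steady_inflow(sv, wf$heart_rate)

  if (config$mode == "synthetic") {
    spec <- if (!is.null(case[["spec"]])) case[["spec"]] else default_pa_spec()
    geo <- make_pa_bifurcation(spec)
    labeling <- geo$labeling
    steady <- synthesize_steady_wss(geo$mesh, geo$centerlines, q_steady,
                                    config$fluid, net, labeling)
    puls <- synthesize_wss_field(geo$mesh, geo$centerlines, ff, config$fluid,
                                 net, labeling, config$n_output_timepoints)
    centerlines <- geo$centerlines
  } else {
    if (!is.null(case[["wss_files"]])) {
      puls <- load_external_wss_series(unlist(case[["wss_files"]]),
                                       period = wf$period)
    } else puls <- case[["pulsatile_field"]]
    steady <- if (!is.null(case[["steady_field"]])) case[["steady_field"]]
      else {
        ta <- tawss_field(puls)
        wss_steady_field(puls$wall_points, puls$areas, ta, puls$labeling)
      }
    labeling <- steady$labeling
    centerlines <- case[["centerlines"]]
  }
  steady <- trim_extensions(steady)
  puls <- trim_extensions(puls)

  geom <- NULL
  if (!is.null(centerlines) && all(c("LPA", "RPA") %in% names(centerlines))) {
    paths <- list(LPA = join_centerlines(centerlines$MPA, centerlines$LPA),
                  RPA = join_centerlines(centerlines$MPA, centerlines$RPA))
    geom <- do.call(rbind, lapply(names(paths), function(nm) {
      rs <- resample_centerline(paths[[nm]], config$centerline_step)
      cp <- curvature_profile(rs)
      tm <- tortuosity(rs)
      data.frame(path = nm, mean_curvature = cp$mean_kappa,
                 tortuosity = tm$tortuosity, path_length = tm$path_length)
    }))
  }

  summ <- summarize_case(steady, puls, wf)
  out <- structure(list(summary = summ, geometry_metrics = geom,
                        waveform = wf, fourier = ff,
                        regurgitant_fraction = rf, steady_inflow = q_steady,
                        steady_field = steady, pulsatile_field = puls,
                        labeling = steady$labeling, resistance_network = net,
                        centerlines = centerlines, config = config),
                   class = "pa_case")
  if (!is.null(out_dir)) write_case_artifacts(out, out_dir)
  out
}

#' @export
print.pa_case <- function(x, ...) {
  cat(sprintf("Pulmonary artery case (%s mode)\n", x$config$mode))
  cat(sprintf("  inlet: HR %.1f bpm, RF %.3f, steady inflow %.1f cm^3/s\n",
              x$waveform$heart_rate, x$regurgitant_fraction, x$steady_inflow))
  if (!is.null(x$geometry_metrics)) {
    for (i in seq_len(nrow(x$geometry_metrics)))
      cat(sprintf("  %s path: mean curvature %.3f cm^-1, tortuosity %.3f\n",
                  x$geometry_metrics$path[i],
                  x$geometry_metrics$mean_curvature[i],
                  x$geometry_metrics$tortuosity[i]))
  }
  print(x$summary)
  invisible(x)
}

#' @export
plot.pa_case <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$waveform, main = "inlet flow")
  s <- as.data.frame(x$summary)
  graphics::barplot(s$wss_steady_avg, names.arg = s$region,
                    ylab = expression(WSS[steady, avg] ~ (dynes / cm^2)),
                    main = "steady WSS by segment")
  invisible(x)
}

# Persist case artifacts: centerlines, waveform, fields, summary, manifest.
write_case_artifacts <- function(case, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(case[["centerlines"]])) {
    for (nm in names(case[["centerlines"]]))
      write_centerline_csv(case[["centerlines"]][[nm]],
                           file.path(out_dir, sprintf("centerline_%s.csv", nm)))
  }
  write_waveform_csv(case[["waveform"]], file.path(out_dir, "waveform.csv"))
  write_wss_series(case[["pulsatile_field"]], out_dir, format = "csv")
  summ <- as.data.frame(case$summary)
  write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  cfg <- case$config
  manifest <- list(
    mode = cfg$mode, seed = cfg$seed,
    n_fourier_modes = cfg$n_fourier_modes,
    n_output_timepoints = cfg$n_output_timepoints,
    centerline_step = cfg$centerline_step,
    fluid = unclass(cfg$fluid),
    resistances_iwu = as.list(cfg$resistances), bsa = cfg$bsa,
    sv_convention = cfg$sv_convention,
    steady_protocol = list(duration_s = cfg$steady_duration,
                           dt_s = cfg$steady_dt, steps = cfg$steady_steps),
    regurgitant_fraction = case$regurgitant_fraction,
    steady_inflow_cm3_s = case$steady_inflow,
    rng = RNGkind()[1L])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run a synthetic cohort study end-to-end
#'
#' Generates `n_cases` per-patient synthetic vessels (radii and regurgitant
#' fractions jittered around the defaults), runs the hemodynamics pipeline
#' for each, joins the per-case summaries into a cohort table with outcomes
#' generated under the requested effect structure, and executes the
#' association stages: adjusted linear regression with Benjamini-Hochberg
#' correction per outcome table, Cox proportional-hazards fits, ROC-derived
#' cutoffs for significant Cox predictors, and Kaplan-Meier stratification.
#'
#' @param config a [run_config()].
#' @param n_cases number of synthetic patients (>= 2).
#' @param linear_effects,log_hazards,noise_sd,censoring_rate passed to
#'   [cohort_spec()]; effects must refer to summary predictor columns such
#'   as `"wss_steady_avg_whole"` or `"osi_avg_MPA"`.
#' @param predictors predictor columns carried into the association stages
#'   (default: steady WSS and OSI summaries for all regions).
#' @return An object of class `pa_cohort_study`: `cohort`, `survival`,
#'   `linear_results` (one data.frame per outcome), `cox_results`,
#'   `roc_cutoffs`, `km`, `audit` (character log), `case_summaries`.
#' @export
run_cohort_study <- function(config = run_config(), n_cases = 12L,
                             linear_effects = c(wss_steady_avg_whole = -4.74),
                             log_hazards = c(osi_avg_whole = 0.7),
                             noise_sd = 20, censoring_rate = 0.7,
                             predictors = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (n_cases < 2L) stop("n_cases must be >= 2")
  audit <- character(0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  scale_r <- exp(rnorm(n_cases, 0, 0.15))
  rfs <- pmin(pmax(rbeta(n_cases, 5.5, 8.25), 0.01), 0.95)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  summaries <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    spec <- default_pa_spec(mpa_radius = 1.2 * scale_r[i],
                            lpa_radius = 0.8 * scale_r[i],
                            rpa_radius = 0.9 * scale_r[i],
                            axial_samples = 24L,
                            circumferential_samples = 16L)
    ws <- waveform_spec(heart_rate = config$heart_rate,
                        forward_volume = config$forward_volume,
                        regurgitant_fraction = rfs[i])
    cs <- run_case(config, case = list(spec = spec, waveform_spec = ws))
    summaries[[i]] <- cs$summary
  }
  pred_tab <- do.call(rbind, lapply(seq_len(n_cases), function(i) {
    s <- as.data.frame(summaries[[i]])
    wide <- list(case_id = i)
    for (m in c("wss_steady_avg", "wss_steady_peak", "tawss_avg",
                "osi_avg")) {
      for (j in seq_len(nrow(s)))
        wide[[paste(m, s$region[j], sep = "_")]] <- s[[m]][j]
    }
    as.data.frame(wide)
  }))
  audit <- c(audit, sprintf("generated %d synthetic cases", n_cases))
  cspec <- cohort_spec(n_patients = n_cases,
                       linear_effects = linear_effects,
                       log_hazards = log_hazards, noise_sd = noise_sd,
                       censoring_rate = censoring_rate, seed = config$seed)
  coh <- make_synthetic_cohort(cspec, predictors = pred_tab[, -1L])
  if (is.null(predictors))
    predictors <- grep("^(wss_steady_avg|wss_steady_peak|osi_avg)_",
                       names(pred_tab), value = TRUE)
  # primary analysis: adjusted OLS per outcome table, BH within table
  outcomes <- c("rvedvi", "rvesvi", "rvsvi", "rvef")
  linear_results <- lapply(outcomes, function(oc)
    fit_linear_table(coh$cohort, oc, predictors))
  names(linear_results) <- outcomes
  # secondary analysis: Cox per predictor
  cox_results <- NULL
  roc_cutoffs <- NULL
  km <- NULL
  if (sum(coh$survival$event) < 1L) {
    audit <- c(audit, "Cox stage skipped: no events in the cohort")
  } else {
    cox_list <- lapply(predictors, function(p)
      fit_cox(coh$survival, p, normalize = grepl("^osi", p)))
    cox_results <- data.frame(
      predictor = predictors,
      hazard_ratio = vapply(cox_list, `[[`, numeric(1), "hazard_ratio"),
      ci_low = vapply(cox_list, `[[`, numeric(1), "ci_low"),
      ci_high = vapply(cox_list, `[[`, numeric(1), "ci_high"),
      p = vapply(cox_list, `[[`, numeric(1), "p"),
      schoenfeld_ok = vapply(cox_list, `[[`, logical(1), "schoenfeld_ok"),
      normalized = vapply(cox_list, `[[`, logical(1), "normalized"))
    sig <- cox_results$predictor[cox_results$p < 0.05]
    labels <- tryCatch(dichotomize_by_median_time(coh$survival),
                       error = function(e) NULL)
    if (is.null(labels)) {
      audit <- c(audit, "ROC stage skipped: landmark labels undefined")
    } else if (length(sig)) {
      roc_cutoffs <- do.call(rbind, lapply(sig, function(p) {
        rc <- tryCatch(roc_optimal_cutoff(coh$survival[[p]], labels),
                       error = function(e) NULL)
        if (is.null(rc)) return(NULL)
        data.frame(predictor = p, cutoff = rc$cutoff,
                   sensitivity = rc$sensitivity,
                   specificity = rc$specificity, direction = rc$direction)
      }))
      if (!is.null(roc_cutoffs) && nrow(roc_cutoffs)) {
        p1 <- roc_cutoffs$predictor[1L]
        grp <- ifelse(coh$survival[[p1]] >= roc_cutoffs$cutoff[1L],
                      "above", "below")
        km <- km_curve(coh$survival, grp)
        audit <- c(audit, sprintf("KM stratified on %s at cutoff %.3g",
                                  p1, roc_cutoffs$cutoff[1L]))
      }
    } else {
      audit <- c(audit, "no Cox predictor significant at 0.05: ROC/KM skipped")
    }
  }
  structure(list(cohort = coh$cohort, survival = coh$survival,
                 linear_results = linear_results,
                 cox_results = cox_results, roc_cutoffs = roc_cutoffs,
                 km = km, audit = audit, case_summaries = pred_tab,
                 config = config),
            class = "pa_cohort_study")
}

#' @export
print.pa_cohort_study <- function(x, ...) {
  cat(sprintf("Synthetic cohort study: %d patients, %d events\n",
              nrow(x$cohort), sum(x$survival$event)))
  cat("\nAdjusted linear regression (RVEDVi):\n")
  print(x$linear_results$rvedvi, row.names = FALSE, digits = 3)
  if (!is.null(x$cox_results)) {
    cat("\nCox proportional hazards:\n")
    print(x$cox_results, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$roc_cutoffs)) {
    cat("\nROC-optimal cutoffs:\n")
    print(x$roc_cutoffs, row.names = FALSE, digits = 3)
  }
  cat("\nAudit log:\n", paste(" -", x$audit, collapse = "\n"), "\n")
  invisible(x)
}
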