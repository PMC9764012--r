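#' Validate a pipeline run configuration
#'
#' Reads a YAML (or JSON) run configuration, checks it against the schema,
#' fills documented defaults and returns a validated `run_config`. The
#' schema:
#'
#' ```yaml
#' protocols: [O2_7to2, CO2_5to10]   # built-in names (required)
#' mode: tabular                     # "tabular" (default) or "sti"
#' seed: 1
#' outdir: capkinetics-run
#' population:                       # optional overrides
#'   n_capillaries: 300
#'   amplitude_cv: 0.5
#'   noise: {velocity: 20, lineal_density: 5, so2: 2}
#' optics:                           # sti mode only; optics_config() fields
#'   fps: 60
#' sti_capillaries: 3                # capillaries rendered in sti mode
#' stats:
#'   alpha: 0.05
#'   baseline_window: [51, 60]
#' fits:                             # optional per-measure constraint
#'   x0_step: 0.5                    # overrides for the kinetics fits
#' ```
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return A validated `run_config` object (errors carry the offending
#'   field path).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  known <- c("protocols", "mode", "seed", "outdir", "population", "optics",
             "sti_capillaries", "stats", "fits")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  errs <- character(0)
  err <- function(path, msg) errs <<- c(errs, paste0(path, ": ", msg))

  if (is.null(config$protocols) || length(config$protocols) == 0) {
    err("protocols", "at least one protocol name is required")
  } else {
    bad <- setdiff(config$protocols, names(builtin_protocols()))
    if (length(bad)) err("protocols", paste("unknown protocol(s):",
                                            paste(bad, collapse = ", ")))
  }
  mode <- config$mode %||% "tabular"
  if (!mode %in% c("tabular", "sti")) err("mode", "must be 'tabular' or 'sti'")
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1) err("seed", "must be one integer")

  popc <- config$population %||% list()
  if (!is.null(popc$n_capillaries) &&
      (!is.numeric(popc$n_capillaries) || popc$n_capillaries < 1)) {
    err("population.n_capillaries", "must be >= 1")
  }
  if (!is.null(popc$amplitude_cv) && popc$amplitude_cv < 0) {
    err("population.amplitude_cv", "must be >= 0")
  }
  if (!is.null(popc$noise)) {
    nz <- unlist(popc$noise)
    if (any(nz < 0)) err("population.noise", "noise SDs must be >= 0")
  }

  statc <- config$stats %||% list()
  alpha <- statc$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) err("stats.alpha", "must be in (0, 1)")
  bw <- statc$baseline_window %||% c(51, 60)
  if (length(bw) != 2 || bw[1] >= bw[2]) {
    err("stats.baseline_window", "must be [start, end] with start < end")
  }
  # cross-field checks: windows must fit inside every requested protocol
  if (length(errs) == 0) {
    for (pn in config$protocols) {
      dur <- protocol_duration(make_protocol(pn))
      if (bw[2] > dur) {
        err(paste0("stats.baseline_window/", pn),
            sprintf("window ends at %g s but protocol lasts %g s", bw[2], dur))
      }
      win <- statc$post_window %||% NULL
      if (!is.null(win) && win[2] > dur) {
        err(paste0("stats.post_window/", pn),
            sprintf("window ends at %g s but protocol lasts %g s", win[2], dur))
      }
    }
  }
  fitc <- config$fits %||% list()
  if (!is.null(fitc$tau_range) && any(unlist(fitc$tau_range) <= 0)) {
    err("fits.tau_range", "time-constant search range must be > 0")
  }
  oc <- config$optics %||% list()
  if (length(oc)) {
    ok <- tryCatch({ do.call(optics_config, oc); TRUE },
                   error = function(e) { err("optics", conditionMessage(e)); FALSE })
  }
  if (length(errs)) {
    stop("invalid run config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(protocols = as.character(config$protocols), mode = mode,
                 seed = as.integer(seed),
                 outdir = config$outdir %||% "capkinetics-run",
                 population = popc,
                 optics = oc,
                 sti_capillaries = as.integer(config$sti_capillaries %||% 3L),
                 stats = list(alpha = alpha, baseline_window = as.numeric(bw),
                              post_window = statc$post_window),
                 fits = fitc),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_mean_trace <- function(means_mm, challenge, measure, fits_opt) {
  kin <- reference_kinetics()
  row <- kin[kin$challenge == challenge & kin$measure == measure, ]
  t <- means_mm$t; y <- means_mm$mean
  opts <- fits_opt %||% list()
  if (nrow(row) == 1 && row$model == "bi") {
    cons <- fit_constraints(window = c(row$win_lo, row$win_hi),
                            lower = c(X1 = constraint_gt(60),
                                      X2 = constraint_gt(120)))
    fit <- tryCatch(fit_bi(t, y, cons, opts), error = function(e) .nonconverged("bi"))
  } else {
    win <- if (nrow(row) == 1) c(row$win_lo, row$win_hi) else c(51, 180)
    lb <- if (nrow(row) == 1 && is.finite(row$x0_constraint)) row$x0_constraint else 60
    cons <- if (nrow(row) == 1 && isTRUE(row$x0_pinned)) {
      fit_constraints(window = win, pin = c(X0 = lb))
    } else {
      fit_constraints(window = win, lower = c(X0 = constraint_gt(lb)))
    }
    fit <- tryCatch(fit_mono(t, y, cons, opts), error = function(e) .nonconverged("mono"))
  }
  fit
}

.fit_row <- function(fit, challenge, measure) {
  p <- fit$params
  tibble::tibble(
    challenge = challenge, measure = measure, model = fit$model,
    converged = fit$converged,
    Yb = if (!is.null(p)) p$Yb else NA_real_,
    X0 = if (fit$model == "mono" && !is.null(p)) p$X0 else NA_real_,
    Y0 = if (fit$model == "mono" && !is.null(p)) p$Y0 else NA_real_,
    tau = if (fit$model == "mono" && !is.null(p)) p$tau else NA_real_,
    X1 = if (fit$model == "bi" && !is.null(p)) p$X1 else NA_real_,
    Y1 = if (fit$model == "bi" && !is.null(p)) p$Y1 else NA_real_,
    tau1 = if (fit$model == "bi" && !is.null(p)) p$tau1 else NA_real_,
    X2 = if (fit$model == "bi" && !is.null(p)) p$X2 else NA_real_,
    Y2 = if (fit$model == "bi" && !is.null(p)) p$Y2 else NA_real_,
    tau2 = if (fit$model == "bi" && !is.null(p)) p$tau2 else NA_real_,
    r_squared = fit$r_squared)
}

#' Run the full simulate / (render, analyze) / fit / summarize pipeline
#'
#' For each requested protocol: simulates a ground-truth capillary
#' population under the reference study conditions, optionally renders and
#' re-analyzes dual-wavelength space-time images for a few capillaries
#' (`mode: sti`), fits the delayed-exponential model to every measure's
#' population-mean trace, computes the onset/peak summary table, writes all
#' artifacts (CSV tables, optional TIFF pairs, mean +/- SEM plots with the
#' fitted curve overlaid, and a JSON manifest with seeds and warning
#' tallies) under `outdir/<protocol>/`, and returns the collected tables.
#' Identical config and seed give identical outputs.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list
#'   passed through it).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `fits` (kinetic parameter table), `onsets`
#'   (onset/peak table), `means`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  set.seed(config$seed)
  proto_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(config$protocols))
  all_fits <- list(); all_onsets <- list(); all_means <- list()
  manifest <- list(seed = config$seed, mode = config$mode,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("capkinetics")),
                   protocols = list())

  for (pi in seq_along(config$protocols)) {
    pn <- config$protocols[pi]
    pdir <- file.path(config$outdir, pn)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    say("[%s] simulating population", pn)
    defaults <- default_population_spec(
      pn,
      n_capillaries = config$population$n_capillaries,
      amplitude_cv = config$population$amplitude_cv %||% 0.5,
      noise = unlist(config$population$noise %||%
                       c(velocity = 20, lineal_density = 5, so2 = 2)))
    warn_tally <- character(0)
    pop <- withCallingHandlers(
      simulate_population(make_protocol(pn), defaults$spec, defaults$kinetics,
                          seed = proto_seeds[pi]),
      warning = function(w) {
        warn_tally <<- c(warn_tally, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_ground_truth(pop, file.path(pdir, "ground_truth.csv"))

    recovered <- NULL
    if (config$mode == "sti") {
      say("[%s] rendering and analyzing %d STI pair(s)", pn,
          config$sti_capillaries)
      optics <- do.call(optics_config, config$optics)
      ids <- seq_len(min(config$sti_capillaries, defaults$spec$n_capillaries))
      recovered <- do.call(rbind, lapply(ids, function(id) {
        series <- pop[pop$capillary_id == id, ]
        pair <- render_sti(series, optics, seed = proto_seeds[pi] %% 1e6 + id)
        write_sti_pair(pair, file.path(pdir, sprintf("sti_cap%03d", id)),
                       optics)
        analyze_sti_pair(pair$sti420, pair$sti438, so2_calibration(optics),
                         capillary_id = id)
      }))
      utils::write.csv(recovered, file.path(pdir, "recovered_hemodynamics.csv"),
                       row.names = FALSE)
    }

    say("[%s] fitting mean traces", pn)
    measures <- c("velocity", "lineal_density", "hematocrit", "supply_rate",
                  "so2")
    means <- aggregate_means(pop, measures)
    fits <- list()
    for (mm in measures) {
      fit <- .fit_mean_trace(means[means$measure == mm, ], pn, mm,
                             config$fits)
      if (!fit$converged) {
        warn_tally <- c(warn_tally, paste0("non-converged fit: ", mm))
      }
      fits[[mm]] <- .fit_row(fit, pn, mm)
      # overlay plot: mean +/- SEM ribbon with the fitted curve
      mtab <- means[means$measure == mm, ]
      gg <- ggplot2::ggplot(mtab, ggplot2::aes(x = t, y = mean)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem,
                                          ymax = mean + sem),
                             fill = "grey70", alpha = 0.6) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::labs(x = "time (s)", y = mm,
                      title = sprintf("%s: %s", pn, mm)) +
        ggplot2::theme_minimal()
      if (fit$converged && !is.null(fit$params)) {
        curve_t <- seq(min(mtab$t), max(mtab$t), by = 0.25)
        curve_y <- if (fit$model == "mono") eval_mono(curve_t, fit$params)
                   else eval_bi(curve_t, fit$params)
        gg <- gg + ggplot2::geom_line(
          data = data.frame(t = curve_t, mean = curve_y),
          colour = "red", linewidth = 0.5)
      }
      suppressWarnings(suppressMessages(ggplot2::ggsave(
        file.path(pdir, paste0("mean_", mm, ".png")), gg,
        width = 6, height = 4, dpi = 120)))
    }
    fits <- do.call(rbind, fits)
    utils::write.csv(fits, file.path(pdir, "fit_parameters.csv"),
                     row.names = FALSE)

    say("[%s] onset statistics", pn)
    dur <- protocol_duration(make_protocol(pn))
    steps <- protocol_step_times(make_protocol(pn))
    bw <- config$stats$baseline_window
    post <- config$stats$post_window %||% c(bw[2] + 1, dur)
    ons <- tryCatch(
      onset_table(pop, measures, baseline_window = bw,
                  post_window = post, alpha = config$stats$alpha,
                  step_time = steps[1]),
      error = function(e) {
        warn_tally <<- c(warn_tally, paste0("onset stage failed: ",
                                            conditionMessage(e)))
        NULL
      })
    if (!is.null(ons)) {
      ons <- tibble::add_column(ons, challenge = pn, .before = 1)
      utils::write.csv(ons, file.path(pdir, "onset_table.csv"),
                       row.names = FALSE)
    }

    all_fits[[pn]] <- fits; all_onsets[[pn]] <- ons
    all_means[[pn]] <- tibble::add_column(means, challenge = pn, .before = 1)
    manifest$protocols[[pn]] <- list(
      seed = proto_seeds[pi],
      n_capillaries = defaults$spec$n_capillaries,
      duration_s = dur,
      warnings = as.list(table(warn_tally)))
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", manifest$elapsed_s)
  invisible(list(fits = do.call(rbind, all_fits),
                 onsets = do.call(rbind, all_onsets),
                 means = do.call(rbind, all_means),
                 manifest = manifest))
}
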