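#' Specify a synthetic capillary population
#'
#' Describes the heterogeneity of a simulated capillary population: for each
#' primary measure (RBC velocity in um/s, lineal density in cells/mm, SO2 in
#' %) a cross-capillary baseline mean and SD, a response-amplitude mean and
#' SD, and a per-second observation-noise SD. Hematocrit and supply rate are
#' derived quantities and are not specified directly. Baselines are drawn
#' from normals truncated at the physical bounds (velocity and density >= 0,
#' SO2 in [0, 100]).
#'
#' @param n_capillaries Number of capillaries (>= 1).
#' @param baseline Named list per measure (`velocity`, `lineal_density`,
#'   `so2`) of `c(mean =, sd =)`.
#' @param amplitude Named list per measure of `c(mean =, sd =)` for the
#'   asymptotic response amplitude (signed mean; per-capillary draws are
#'   plain normal and out-of-range excursions of the resulting series are
#'   clipped with a logged count).
#' @param noise Named numeric vector of per-second Gaussian observation-noise
#'   SDs per measure.
#' @param rbc_volume Red blood cell volume (fL = um^3), used to derive
#'   hematocrit.
#' @param capillary_diameter Capillary lumen diameter (um).
#' @param seed Optional root RNG seed recorded with the spec.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_capillaries = 300,
                            baseline = list(velocity = c(mean = 228.5, sd = 190.4),
                                            lineal_density = c(mean = 49.4, sd = 34.2),
                                            so2 = c(mean = 69.7, sd = 13.1)),
                            amplitude = list(velocity = c(mean = 116.5, sd = 58),
                                             lineal_density = c(mean = 13.5, sd = 7),
                                             so2 = c(mean = -27.8, sd = 8)),
                            noise = c(velocity = 20, lineal_density = 5, so2 = 2),
                            rbc_volume = 55, capillary_diameter = 5,
                            seed = NULL) {
  measures <- c("velocity", "lineal_density", "so2")
  stopifnot(n_capillaries >= 1,
            all(measures %in% names(baseline)),
            all(measures %in% names(amplitude)),
            all(measures %in% names(noise)),
            rbc_volume > 0, capillary_diameter > 0)
  for (mm in measures) {
    if (baseline[[mm]][["sd"]] < 0 || amplitude[[mm]][["sd"]] < 0 ||
        noise[[mm]] < 0) {
      stop("all SDs must be >= 0 (measure: ", mm, ")", call. = FALSE)
    }
  }
  structure(list(n_capillaries = as.integer(n_capillaries),
                 baseline = baseline, amplitude = amplitude,
                 noise = noise, rbc_volume = rbc_volume,
                 capillary_diameter = capillary_diameter, seed = seed),
            class = "population_spec")
}

#' Default population spec and kinetics for a named challenge
#'
#' Wires the reference baseline distributions ([reference_baselines()]) and
#' fitted kinetic parameters ([reference_kinetics()]) of a built-in challenge
#' into a ready-to-simulate [population_spec()] plus per-measure kinetic
#' templates. Amplitude SDs are set to 50% of the absolute amplitude mean
#' (the source reports only population-mean amplitudes) and observation
#' noise to modest per-measure defaults; both are overridable.
#'
#' @param challenge A built-in protocol name (see [make_protocol()]).
#' @param n_capillaries Population size; default the per-challenge velocity
#'   capillary count of the reference study.
#' @param amplitude_cv Amplitude SD as a fraction of |amplitude mean|.
#' @param noise Per-second observation-noise SDs, named per measure.
#' @param seed Optional root seed stored in the spec.
#' @return A list with elements `spec` ([population_spec()]) and `kinetics`
#'   (named list of [mono_exp_params()]/[bi_exp_params()] per measure).
#' @export
default_population_spec <- function(challenge, n_capillaries = NULL,
                                    amplitude_cv = 0.5,
                                    noise = c(velocity = 20,
                                              lineal_density = 5, so2 = 2),
                                    seed = NULL) {
  bl <- reference_baselines()
  kin <- reference_kinetics()
  bl <- bl[bl$challenge == challenge, ]
  kin <- kin[kin$challenge == challenge, ]
  if (nrow(bl) == 0) stop("no reference data for challenge '", challenge, "'",
                          call. = FALSE)
  measures <- c("velocity", "lineal_density", "so2")
  baseline <- amplitude <- stats::setNames(vector("list", 3), measures)
  templates <- stats::setNames(vector("list", 3), measures)
  for (mm in measures) {
    b <- bl[bl$measure == mm, ]
    k <- kin[kin$measure == mm, ]
    baseline[[mm]] <- c(mean = b$baseline_mean, sd = b$baseline_sd)
    if (k$model == "mono" && is.finite(k$tau)) {
      templates[[mm]] <- mono_exp_params(b$baseline_mean, k$X0, k$Y0, k$tau)
      amp_mean <- k$Y0
    } else if (k$model == "bi") {
      templates[[mm]] <- bi_exp_params(b$baseline_mean, k$X1, k$Y1, k$tau1,
                                       k$X2, k$Y2, k$tau2)
      amp_mean <- k$Y1 + k$Y2
    } else {
      # no stable reference fit for this measure/challenge: null response
      templates[[mm]] <- mono_exp_params(b$baseline_mean, 61, 0, 1)
      amp_mean <- 0
    }
    amplitude[[mm]] <- c(mean = amp_mean, sd = abs(amp_mean) * amplitude_cv)
  }
  if (is.null(n_capillaries)) {
    n_capillaries <- bl$n_capillaries[bl$measure == "velocity"]
  }
  list(spec = population_spec(n_capillaries, baseline, amplitude, noise,
                              seed = seed),
       kinetics = templates)
}

## Inverse-CDF truncated normal draw.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + (b - a) * stats::runif(n), mean, sd)
}

.measure_bounds <- list(velocity = c(0, Inf),
                        lineal_density = c(0, Inf),
                        so2 = c(0, 100))

#' Simulate a ground-truth capillary population
#'
#' Generates second-by-second hemodynamics for `spec$n_capillaries`
#' capillaries on the 1 Hz grid `t = 1..T` (T = protocol duration). For each
#' capillary and measure, a baseline is drawn from a truncated normal and an
#' amplitude from a normal around the population values in `spec`; the
#' kinetic template (shared delay and time constant across capillaries)
#' is evaluated with those per-capillary values, independent per-second
#' Gaussian observation noise is added, physically impossible excursions
#' (SO2 outside [0, 100], density or velocity below 0) are clipped with a
#' logged count, and hematocrit and supply rate are derived from the noisy
#' velocity and lineal density.
#'
#' Randomness uses a single root seed from which one child seed per capillary
#' is drawn, so populations are reproducible and individual capillaries can
#' be regenerated.
#'
#' @param protocol A [make_protocol()] protocol (sets the grid length; the
#'   kinetic delays must fall inside its duration).
#' @param spec A [population_spec()].
#' @param kinetics Named list with one [mono_exp_params()] or
#'   [bi_exp_params()] template per measure (`velocity`, `lineal_density`,
#'   `so2`). The template's `Yb` and amplitude fields act as population
#'   means; per-capillary draws replace them (bi-exponential templates keep
#'   their `Y1:Y2` split and scale both by the drawn total amplitude).
#' @param seed Root RNG seed (integer). Defaults to `spec$seed`, else 1.
#' @return A tibble of class `ground_truth_population` with columns
#'   `capillary_id`, `t`, `velocity`, `lineal_density`, `hematocrit`,
#'   `supply_rate`, `so2`, and attributes `generating_params` (per-capillary
#'   tibble), `seed`, `child_seeds`, `clipped` (named clip counts),
#'   `protocol_name`.
#' @export
simulate_population <- function(protocol, spec, kinetics, seed = NULL) {
  stopifnot(inherits(protocol, "gas_protocol"), inherits(spec, "population_spec"))
  measures <- c("velocity", "lineal_density", "so2")
  if (!all(measures %in% names(kinetics))) {
    stop("kinetics must supply templates for: ",
         paste(measures, collapse = ", "), call. = FALSE)
  }
  T_end <- protocol_duration(protocol)
  for (mm in measures) {
    k <- kinetics[[mm]]
    delays <- if (inherits(k, "bi_exp_params")) c(k$X1, k$X2) else k$X0
    if (any(delays < 0 | delays > T_end)) {
      stop("kinetic delay for '", mm, "' lies outside the protocol duration",
           call. = FALSE)
    }
  }
  if (is.null(seed)) seed <- if (!is.null(spec$seed)) spec$seed else 1L
  t_grid <- seq_len(T_end)
  n <- spec$n_capillaries

  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)

  clip_count <- c(velocity = 0L, lineal_density = 0L, so2 = 0L)
  gen_rows <- vector("list", n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seeds[i])
    vals <- list()
    gp <- list(capillary_id = i)
    for (mm in measures) {
      bnd <- .measure_bounds[[mm]]
      bl <- rtruncnorm(1, spec$baseline[[mm]][["mean"]],
                       spec$baseline[[mm]][["sd"]], bnd[1], bnd[2])
      amp <- stats::rnorm(1, spec$amplitude[[mm]][["mean"]],
                          spec$amplitude[[mm]][["sd"]])
      k <- kinetics[[mm]]
      if (inherits(k, "bi_exp_params")) {
        tot <- k$Y1 + k$Y2
        f1 <- if (tot != 0) k$Y1 / tot else 0.5
        p <- bi_exp_params(bl, k$X1, amp * f1, k$tau1, k$X2, amp * (1 - f1),
                           k$tau2)
        mcurve <- eval_bi(t_grid, p)
        gp[[paste0(mm, "_amplitude")]] <- amp
      } else {
        p <- mono_exp_params(bl, k$X0, amp, k$tau)
        mcurve <- eval_mono(t_grid, p)
        gp[[paste0(mm, "_amplitude")]] <- amp
      }
      gp[[paste0(mm, "_baseline")]] <- bl
      noisy <- mcurve + stats::rnorm(length(t_grid), 0, spec$noise[[mm]])
      clipped <- pmin(pmax(noisy, bnd[1]), bnd[2])
      clip_count[mm] <- clip_count[mm] + sum(clipped != noisy)
      vals[[mm]] <- clipped
    }
    out[[i]] <- tibble::tibble(
      capillary_id = i, t = t_grid,
      velocity = vals$velocity,
      lineal_density = vals$lineal_density,
      hematocrit = derive_hematocrit(vals$lineal_density, spec$rbc_volume,
                                     spec$capillary_diameter, warn = FALSE),
      supply_rate = derive_supply_rate(vals$velocity, vals$lineal_density),
      so2 = vals$so2)
    gen_rows[[i]] <- tibble::as_tibble(gp)
  }
  res <- do.call(rbind, out)
  if (sum(clip_count) > 0) {
    warning(sum(clip_count), " out-of-range values clipped (",
            paste(names(clip_count), clip_count, sep = ": ", collapse = ", "),
            ")", call. = FALSE)
  }
  attr(res, "generating_params") <- do.call(rbind, gen_rows)
  attr(res, "seed") <- seed
  attr(res, "child_seeds") <- child_seeds
  attr(res, "clipped") <- clip_count
  attr(res, "protocol_name") <- protocol$name
  class(res) <- c("ground_truth_population", class(res))
  res
}

#' Write / read a ground-truth population
#'
#' The per-capillary per-second table goes to CSV (one row per
#' capillary-second) and the generating parameters, seeds and clip counts to
#' a JSON sidecar (`<path>.json`).
#'
#' @param pop A `ground_truth_population`.
#' @param path CSV path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   returns the tibble with sidecar metadata re-attached when present.
#' @export
write_ground_truth <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  meta <- list(seed = attr(pop, "seed"),
               child_seeds = attr(pop, "child_seeds"),
               clipped = as.list(attr(pop, "clipped")),
               protocol_name = attr(pop, "protocol_name"),
               generating_params = attr(pop, "generating_params"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  res <- tibble::as_tibble(utils::read.csv(path))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(res, "seed") <- meta$seed
    attr(res, "child_seeds") <- meta$child_seeds
    attr(res, "clipped") <- unlist(meta$clipped)
    attr(res, "protocol_name") <- meta$protocol_name
    attr(res, "generating_params") <- tibble::as_tibble(meta$generating_params)
  }
  class(res) <- c("ground_truth_population", class(res))
  res
}
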