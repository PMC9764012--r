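#' Reference kinetic parameters for rat EDL capillary gas-challenge responses
#'
#' Fitted delayed-exponential parameters for the population-mean capillary
#' hemodynamic responses of rat extensor digitorum longus muscle to the nine
#' chamber gas challenges, as estimated from intravital video recordings:
#' five measures (RBC velocity, lineal density, hematocrit, supply rate,
#' oxygen saturation) by eight single-gas challenges (mono-exponential, fit
#' window 51-180 s unless noted) plus the combined challenge
#' (two-component model, window 51-240 s). These parameter sets are the
#' default generating kinetics of the synthetic population simulator and the
#' inputs of the round-trip fitting checks. Where the source reports a value
#' at more than one precision, the most precise printed figure is stored.
#'
#' Lineal density and hematocrit in the 10-5% CO2 challenge had no stable
#' exponential fit; their rows carry `NA` parameters.
#'
#' @return A tibble with columns `challenge`, `measure`, `model`
#'   (`"mono"`/`"bi"`), `Yb` (baseline magnitude, from the matching baseline
#'   summary), `X0`, `Y0`, `tau` (mono), `X1`, `Y1`, `tau1`, `X2`, `Y2`,
#'   `tau2` (bi), `r2` (reported fit R^2), `x0_constraint` (lower delay
#'   bound; `NA` means unconstrained, negative pin encoded via
#'   `x0_pinned`), `x0_pinned` (logical), `win_lo`, `win_hi` (fit window, s).
#' @seealso [reference_baselines()], [default_population_spec()]
#' @export
reference_kinetics <- function() {
  m <- function(challenge, measure, Yb, X0, Y0, tau, r2,
                x0c = 60, pin = FALSE, win = c(51, 180)) {
    tibble::tibble(challenge = challenge, measure = measure, model = "mono",
                   Yb = Yb, X0 = X0, Y0 = Y0, tau = tau,
                   X1 = NA_real_, Y1 = NA_real_, tau1 = NA_real_,
                   X2 = NA_real_, Y2 = NA_real_, tau2 = NA_real_,
                   r2 = r2, x0_constraint = x0c, x0_pinned = pin,
                   win_lo = win[1], win_hi = win[2])
  }
  b <- function(measure, Yb, X1, Y1, tau1, X2, Y2, tau2, r2) {
    tibble::tibble(challenge = "combined", measure = measure, model = "bi",
                   Yb = Yb, X0 = NA_real_, Y0 = NA_real_, tau = NA_real_,
                   X1 = X1, Y1 = Y1, tau1 = tau1,
                   X2 = X2, Y2 = Y2, tau2 = tau2,
                   r2 = r2, x0_constraint = 60, x0_pinned = FALSE,
                   win_lo = 51, win_hi = 240)
  }
  rbind(
    # velocity (um/s), O2 challenges
    m("O2_7to12", "velocity", 238.6, 66.7, -29.4, 6.96, 0.8139),
    m("O2_12to7", "velocity", 230.6, 60.0, 49.5, 38.54, 0.8468),
    m("O2_7to2",  "velocity", 228.5, 60.0, 116.5, 35.54, 0.9165),
    m("O2_2to7",  "velocity", 337.2, 61.7, -66.3, 13.36, 0.8634, x0c = 59),
    # lineal density (cells/mm)
    m("O2_7to12", "lineal_density", 56.5, 64.9, -13.9, 24.03, 0.906),
    m("O2_12to7", "lineal_density", 46.3, 64.6, 12.1, 35.93, 0.9547),
    m("O2_7to2",  "lineal_density", 49.4, 64.7, 13.5, 26.93, 0.9415),
    m("O2_2to7",  "lineal_density", 65.1, 64.7, -11.1, 68.24, 0.8729),
    # hematocrit (%)
    m("O2_7to12", "hematocrit", 20.9, 65.7, -4.9, 27.19, 0.9372),
    m("O2_12to7", "hematocrit", 17.2, 64.7, 4.4, 35.21, 0.9475),
    m("O2_7to2",  "hematocrit", 19.0, 63.2, 5.4, 32.42, 0.9582),
    m("O2_2to7",  "hematocrit", 24.0, 63.0, -4.1, 74.75, 0.88),
    # supply rate (cells/s)
    m("O2_7to12", "supply_rate", 13.7, 63.0, -4.3, 20.61, 0.9301),
    m("O2_12to7", "supply_rate", 11.5, 60.0, 5.2, 36.06, 0.9378),
    m("O2_7to2",  "supply_rate", 12.3, 60.0, 10.5, 41.87, 0.9591),
    m("O2_2to7",  "supply_rate", 22.2, 61.4, -6.0, 23.07, 0.8763),
    # oxygen saturation (%); bolded per-fit windows for three of the rows
    m("O2_7to12", "so2", 64.4, 60.6, 18.7, 1.01, 0.9923, win = c(0, 90)),
    m("O2_12to7", "so2", 84.5, 62.2, -18.4, 1.64, 0.9909),
    m("O2_7to2",  "so2", 69.7, 62.3, -27.8, 1.44, 0.9952, win = c(51, 90)),
    m("O2_2to7",  "so2", 46.5, 62.7, 24.5, 1.27, 0.9929),
    # velocity, CO2 challenges
    m("CO2_5to0",  "velocity", 349.1, 60.7, -257.5, 18.88, 0.9902),
    m("CO2_0to5",  "velocity", 71.4, 66.5, 275.8, 21.79, 0.9951),
    m("CO2_5to10", "velocity", 273.4, 60.0, 182.2, 79.34, 0.9735),
    m("CO2_10to5", "velocity", 420.4, 62.8, -94.3, 20.66, 0.9686),
    # lineal density, CO2 (10-5%: no stable fit)
    m("CO2_5to0",  "lineal_density", 70.3, 63.7, -41.8, 15.89, 0.9915),
    m("CO2_0to5",  "lineal_density", 25.0, 70.8, 41.6, 30.63, 0.9929, x0c = NA),
    m("CO2_5to10", "lineal_density", 54.6, 60.0, 10.3, 30.31, 0.8855),
    m("CO2_10to5", "lineal_density", 60.8, NA, NA, NA, NA),
    # hematocrit, CO2 (10-5%: no stable fit)
    m("CO2_5to0",  "hematocrit", 23.4, 63.7, -13.7, 15.27, 0.9912),
    m("CO2_0to5",  "hematocrit", 9.6, 70.9, 15.9, 38.50, 0.9920),
    m("CO2_5to10", "hematocrit", 22.4, 60.0, 4.0, 65.94, 0.8757),
    m("CO2_10to5", "hematocrit", 20.3, NA, NA, NA, NA),
    # supply rate, CO2
    m("CO2_5to0",  "supply_rate", 23.4, 61.6, -21.6, 13.84, 0.9966),
    m("CO2_0to5",  "supply_rate", 1.6, 63.0, 17.1, 32.96, 0.9593),
    m("CO2_5to10", "supply_rate", 15.9, 60.0, 14.4, 88.08, 0.9962),
    m("CO2_10to5", "supply_rate", 26.3, 65.9, -5.8, 20.18, 0.9479),
    # saturation, CO2 (bolded per-fit windows)
    m("CO2_5to0",  "so2", 68.7, 62.4, 6.3, 0.84, 0.8509, win = c(51, 100)),
    m("CO2_0to5",  "so2", 65.7, 67.8, -5.9, 0.39, 0.5907, win = c(51, 100)),
    m("CO2_5to10", "so2", 69.5, 60.0, -5.7, 2.887, 0.9026, win = c(51, 100)),
    m("CO2_10to5", "so2", 62.1, 60.0, 6.1, 5.339, 0.8792, x0c = 60, pin = TRUE),
    # combined challenge, two-component fits
    b("velocity", 259.2, 60.0, 76.4, 23.30, 120, 213.6, 85.78, 0.9843),
    b("lineal_density", 58.6, 64.4, 8.0, 22.38, 120, 3.2, 23.63, 0.9413),
    b("hematocrit", 20.8, 64.0, 2.9, 21.52, 120, 1.4, 20.73, 0.9486),
    b("supply_rate", 16.6, 62.0, 6.6, 20.94, 120, 11.3, 49.87, 0.9792),
    b("so2", 66.1, 63.2, -20.9, 0.6799, 120, 15.9, 92.32, 0.9561)
  )
}

#' Reference baseline distributions of capillary hemodynamic measures
#'
#' Cross-capillary mean and standard deviation over the 51-60 s baseline
#' window of each challenge, for the five hemodynamic measures, together with
#' the number of capillaries analyzed per challenge. These anchor the
#' heterogeneity of the synthetic capillary populations.
#'
#' @return A tibble with columns `challenge`, `measure`, `baseline_mean`,
#'   `baseline_sd`, `n_capillaries`.
#' @export
reference_baselines <- function() {
  row <- function(challenge, measure, mean, sd, n) {
    tibble::tibble(challenge = challenge, measure = measure,
                   baseline_mean = mean, baseline_sd = sd, n_capillaries = n)
  }
  rbind(
    row("O2_7to12", "so2", 64.4, 14.7, 167),
    row("O2_12to7", "so2", 84.5, 13.9, 168),
    row("O2_7to2",  "so2", 69.7, 13.1, 221),
    row("O2_2to7",  "so2", 46.5, 19.6, 214),
    row("O2_7to12", "velocity", 238.6, 183.4, 272),
    row("O2_12to7", "velocity", 230.6, 206.6, 294),
    row("O2_7to2",  "velocity", 228.5, 190.4, 300),
    row("O2_2to7",  "velocity", 337.2, 221.5, 293),
    row("O2_7to12", "lineal_density", 56.5, 36.6, 279),
    row("O2_12to7", "lineal_density", 46.3, 34.0, 298),
    row("O2_7to2",  "lineal_density", 49.4, 34.2, 305),
    row("O2_2to7",  "lineal_density", 65.1, 35.3, 294),
    row("O2_7to12", "hematocrit", 20.9, 10.9, 278),
    row("O2_12to7", "hematocrit", 17.2, 11.2, 298),
    row("O2_7to2",  "hematocrit", 19.0, 12.2, 305),
    row("O2_2to7",  "hematocrit", 24.0, 10.7, 294),
    row("O2_7to12", "supply_rate", 13.7, 15.3, 278),
    row("O2_12to7", "supply_rate", 11.5, 14.9, 298),
    row("O2_7to2",  "supply_rate", 12.3, 15.9, 304),
    row("O2_2to7",  "supply_rate", 22.2, 20.6, 294),
    row("CO2_5to0",  "so2", 68.7, 15.4, 82),
    row("CO2_0to5",  "so2", 65.7, 28.4, 90),
    row("CO2_5to10", "so2", 69.5, 14.0, 197),
    row("CO2_10to5", "so2", 62.1, 17.3, 183),
    row("CO2_5to0",  "velocity", 349.1, 245.8, 245),
    row("CO2_0to5",  "velocity", 71.4, 132.5, 242),
    row("CO2_5to10", "velocity", 273.4, 218.1, 288),
    row("CO2_10to5", "velocity", 420.4, 264.3, 285),
    row("CO2_5to0",  "lineal_density", 70.3, 50.1, 255),
    row("CO2_0to5",  "lineal_density", 25.0, 26.5, 246),
    row("CO2_5to10", "lineal_density", 54.6, 35.0, 292),
    row("CO2_10to5", "lineal_density", 60.8, 35.6, 289),
    row("CO2_5to0",  "hematocrit", 23.4, 12.0, 250),
    row("CO2_0to5",  "hematocrit", 9.6, 10.2, 248),
    row("CO2_5to10", "hematocrit", 22.4, 11.8, 292),
    row("CO2_10to5", "hematocrit", 20.3, 11.3, 289),
    row("CO2_5to0",  "supply_rate", 23.4, 22.4, 250),
    row("CO2_0to5",  "supply_rate", 1.6, 6.0, 246),
    row("CO2_5to10", "supply_rate", 15.9, 19.5, 290),
    row("CO2_10to5", "supply_rate", 26.3, 24.3, 287),
    row("combined", "so2", 66.1, 16.4, 286),
    row("combined", "velocity", 259.2, 194.2, 292),
    row("combined", "lineal_density", 58.6, 39.9, 292),
    row("combined", "hematocrit", 20.8, 13.1, 291),
    row("combined", "supply_rate", 16.6, 19.5, 193)
  )
}
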