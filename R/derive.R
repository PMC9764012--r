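#' Tube hematocrit from lineal density
#'
#' Tube hematocrit is the fraction of the capillary lumen volume occupied by
#' red blood cells: for a lineal density `LD` (cells per mm of capillary),
#' cell volume `V` (fL = um^3) and lumen diameter `d` (um),
#' `Hct = 100 * LD * V / (pi * (d/2)^2 * 1000)`, the denominator being the
#' lumen volume of 1 mm of capillary in um^3.
#'
#' @param lineal_density Cells/mm; vectorized, `NA`-propagating.
#' @param rbc_volume RBC volume in fL (1 fL = 1 um^3).
#' @param diameter Capillary lumen diameter in um.
#' @param warn Warn when results exceed 100% (they are clipped).
#' @return Hematocrit in %, clipped to <= 100.
#' @examples
#' derive_hematocrit(49.4, rbc_volume = 55, diameter = 5)
#' @export
derive_hematocrit <- function(lineal_density, rbc_volume = 55, diameter = 5,
                              warn = TRUE) {
  stopifnot(rbc_volume > 0, diameter > 0)
  if (any(lineal_density < 0, na.rm = TRUE)) {
    stop("lineal_density must be >= 0", call. = FALSE)
  }
  hct <- 100 * lineal_density * rbc_volume / (pi * (diameter / 2)^2 * 1000)
  over <- !is.na(hct) & hct > 100
  if (any(over)) {
    if (warn) warning(sum(over), " hematocrit value(s) > 100% clipped",
                      call. = FALSE)
    hct[over] <- 100
  }
  hct
}

#' RBC supply rate from velocity and lineal density
#'
#' The number of red blood cells passing a point per second:
#' `SR = velocity (um/s) * lineal density (cells/mm) / 1000`.
#'
#' @param velocity RBC velocity, um/s.
#' @param lineal_density Cells/mm.
#' @return Cells/s; `NA` where either input is missing.
#' @examples
#' derive_supply_rate(228.53, 49.4)
#' @export
derive_supply_rate <- function(velocity, lineal_density) {
  velocity * lineal_density / 1000
}

#' Per-second means of frame-level measurements
#'
#' Collapses frame-by-frame values to 1-second means: frames with timestamp
#' in `(s-1, s]` contribute to integer second `s`. The number of
#' contributing frames is kept as a quality flag; seconds with no frames are
#' missing (flag 0), never zero-filled.
#'
#' @param times Frame timestamps in seconds (> 0).
#' @param values Frame-level values (`NA` frames are dropped).
#' @param t_max Last second of the output grid; defaults to
#'   `ceiling(max(times))`.
#' @return A tibble with columns `t` (integer second), `mean`, `n_frames`.
#' @examples
#' summarize_per_second(c(0.2, 0.5, 0.9), c(1, 2, 3))
#' @export
summarize_per_second <- function(times, values, t_max = NULL) {
  stopifnot(length(times) == length(values), all(times > 0))
  if (is.null(t_max)) t_max <- max(1, ceiling(max(times)))
  sec <- ceiling(times)
  ok <- is.finite(values)
  m <- tapply(values[ok], factor(sec[ok], levels = seq_len(t_max)), mean)
  n <- tapply(rep(1L, sum(ok)), factor(sec[ok], levels = seq_len(t_max)), sum)
  n[is.na(n)] <- 0L
  tibble::tibble(t = seq_len(t_max), mean = as.numeric(m),
                 n_frames = as.integer(n))
}
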