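#' Optical configuration of the dual-wavelength space-time image model
#'
#' Parameters of the forward optical model that turns a capillary's
#' ground-truth hemodynamics into a pair of space-time images (kymographs):
#' one at the 420 nm isosbestic wavelength, where oxy- and deoxyhemoglobin
#' absorb equally and RBC contrast is independent of SO2, and one at the
#' oxygen-sensitive 438 nm wavelength, where a cell's optical density
#' interpolates linearly between its SO2 = 0 and SO2 = 100 calibration
#' values. Transmitted intensity follows Beer-Lambert attenuation,
#' `I = I0 * 10^-OD`, with OD = 0 outside cells.
#'
#' @param um_per_px Spatial scale along the capillary axis (um/pixel).
#' @param fps Frame rate (frames/s); one image column per frame.
#' @param I0 Background (cell-free) intensity, counts.
#' @param od420 RBC optical density at 420 nm (same at SO2 0 and 100 by the
#'   isosbestic property).
#' @param od438_deoxy,od438_oxy RBC optical density at 438 nm at SO2 = 0 and
#'   SO2 = 100; must differ.
#' @param rbc_length RBC length along the flow axis (um).
#' @param field_length_px Number of pixels along the capillary segment.
#' @param noise_sd Additive Gaussian sensor noise SD (counts); applied last,
#'   negative intensities clipped at 0.
#' @param seed Optional RNG seed recorded with the config.
#' @return An `optics_config` object.
#' @export
optics_config <- function(um_per_px = 0.65, fps = 60, I0 = 10000,
                          od420 = 0.30, od438_deoxy = 0.45, od438_oxy = 0.15,
                          rbc_length = 6, field_length_px = 160,
                          noise_sd = 0, seed = NULL) {
  stopifnot(um_per_px > 0, fps > 0, I0 > 0, rbc_length > 0,
            field_length_px >= 4, noise_sd >= 0, od420 > 0)
  if (od438_deoxy == od438_oxy) {
    stop("438 nm calibration ODs at SO2 = 0 and 100 must differ ",
         "(oxygen-sensitive wavelength)", call. = FALSE)
  }
  structure(list(um_per_px = um_per_px, fps = fps, I0 = I0, od420 = od420,
                 od438_deoxy = od438_deoxy, od438_oxy = od438_oxy,
                 rbc_length = rbc_length, field_length_px = field_length_px,
                 noise_sd = noise_sd, seed = seed),
            class = "optics_config")
}

#' Calibration OD ratios implied by an optics config
#'
#' @param optics An [optics_config()].
#' @return List with `r0` and `r100`, the OD438/OD420 ratios at SO2 = 0 and
#'   SO2 = 100 used by [estimate_so2()].
#' @export
so2_calibration <- function(optics) {
  list(r0 = optics$od438_deoxy / optics$od420,
       r100 = optics$od438_oxy / optics$od420)
}

new_sti <- function(mat, optics, wavelength, t0) {
  structure(list(image = mat, um_per_px = optics$um_per_px,
                 dt = 1 / optics$fps, wavelength = wavelength,
                 I0 = optics$I0, t0 = t0,
                 rbc_length = optics$rbc_length),
            class = "space_time_image")
}

#' @export
print.space_time_image <- function(x, ...) {
  cat(sprintf("<space_time_image> %d nm, %d px x %d frames (%.2f um/px, %.0f fps), t0 = %g s\n",
              x$wavelength, nrow(x$image), ncol(x$image), x$um_per_px,
              1 / x$dt, x$t0))
  invisible(x)
}

#' Render dual-wavelength space-time images of a capillary
#'
#' Forward model producing the 420 nm / 438 nm kymograph pair for one
#' capillary. RBCs enter the field upstream with exponential gaps of mean
#' `1000 / lineal_density` um (a Poisson point process along the vessel) and
#' are advected at the per-second ground-truth velocity, so each cell traces
#' a streak whose space/time slope equals the velocity. Cell optical density
#' is painted with partial-pixel coverage, attenuates the background
#' intensity by Beer-Lambert, at 438 nm interpolates with the cell's SO2
#' (see [optics_config()]), and Gaussian sensor noise is added last.
#'
#' @param series One capillary's ground-truth tibble with columns `t`
#'   (integer seconds), `velocity`, `lineal_density`, `so2`.
#' @param optics An [optics_config()].
#' @param seed RNG seed (the same seed reproduces cell placement and noise
#'   exactly; the 420 nm image is invariant to SO2 by construction).
#' @param t_range Length-2 integer window of seconds to render (defaults to
#'   the full series). Rendering starts at the beginning of
#'   `t_range[1]`.
#' @return List with elements `sti420` and `sti438`
#'   (`space_time_image` objects sharing dimensions and scales).
#' @export
render_sti <- function(series, optics, seed = 1, t_range = NULL) {
  stopifnot(inherits(optics, "optics_config"),
            all(c("t", "velocity", "lineal_density", "so2") %in% names(series)))
  if (is.null(t_range)) t_range <- range(series$t)
  secs <- seq(t_range[1], t_range[2])
  if (!all(secs %in% series$t)) {
    stop("series does not cover the requested render window", call. = FALSE)
  }
  idx <- match(secs, series$t)
  vel <- series$velocity[idx]
  dens <- series$lineal_density[idx]
  so2 <- series$so2[idx]

  n_px <- optics$field_length_px
  dx <- optics$um_per_px
  field_um <- n_px * dx
  fps <- optics$fps
  n_frames <- length(secs) * fps
  half_len <- optics$rbc_length / 2

  max_step <- max(abs(vel)) / fps
  if (max_step > field_um) {
    warning("velocity so high that cells cross more than the field length ",
            "per frame; streaks will alias", call. = FALSE)
  }

  set.seed(seed)
  # hard-core renewal process: centre-to-centre spacing is one cell length
  # plus an exponential gap, keeping the mean spacing at 1000/density um
  # while forbidding physically impossible cell overlap
  sample_gap <- function(d) {
    gm <- 1000 / d - optics$rbc_length
    if (gm <= 0) gm <- 0.1  # density at the packing limit
    optics$rbc_length + stats::rexp(1, 1 / gm)
  }
  # initial fill over the field and an upstream margin
  d0 <- dens[1]
  cells_pos <- numeric(0)
  cells_so2 <- numeric(0)
  if (d0 > 0) {
    pos <- -optics$rbc_length
    while (pos < field_um + optics$rbc_length) {
      cells_pos <- c(cells_pos, pos)
      pos <- pos + sample_gap(d0)
    }
    cells_so2 <- rep(so2[1], length(cells_pos))
  }
  next_gap <- if (d0 > 0) sample_gap(d0) else Inf

  od420 <- matrix(0, n_px, n_frames)
  od438 <- matrix(0, n_px, n_frames)
  px_lo <- (seq_len(n_px) - 1) * dx  # pixel lower edges, um

  paint <- function(col_od, p, od) {
    lo <- p - half_len; hi <- p + half_len
    j0 <- max(1L, floor(lo / dx) + 1L)
    j1 <- min(n_px, floor(hi / dx) + 1L)
    if (j1 < j0) return(col_od)
    j <- j0:j1
    cov <- (pmin(hi, px_lo[j] + dx) - pmax(lo, px_lo[j])) / dx
    col_od[j] <- col_od[j] + od * pmax(cov, 0)
    col_od
  }

  for (f in seq_len(n_frames)) {
    s <- ((f - 1) %/% fps) + 1  # index into secs
    v <- vel[s]; d <- dens[s]; sat <- so2[s]
    step <- v / fps
    cells_pos <- cells_pos + step
    # drop cells past the downstream margin
    keep <- cells_pos > -2 * optics$rbc_length &
      cells_pos < field_um + 2 * optics$rbc_length
    cells_pos <- cells_pos[keep]; cells_so2 <- cells_so2[keep]
    # injection at the inflow edge, driven by advected distance and density
    if (d > 0 && !is.finite(next_gap)) {
      next_gap <- sample_gap(d)
    }
    if (d > 0 && step > 0) {
      next_gap <- next_gap - step
      while (next_gap <= 0) {
        # the cell entered mid-frame and has already advanced by -next_gap
        cells_pos <- c(cells_pos, -optics$rbc_length - next_gap)
        cells_so2 <- c(cells_so2, sat)
        next_gap <- next_gap + sample_gap(d)
      }
    } else if (d > 0 && step < 0) {
      # reverse flow: cells enter at the downstream edge
      next_gap <- next_gap + step
      while (next_gap <= 0) {
        cells_pos <- c(cells_pos, field_um + optics$rbc_length + next_gap)
        cells_so2 <- c(cells_so2, sat)
        next_gap <- next_gap + sample_gap(d)
      }
    }
    if (length(cells_pos)) {
      col4 <- numeric(n_px); col8 <- numeric(n_px)
      for (ci in seq_along(cells_pos)) {
        p <- cells_pos[ci]
        if (p < -optics$rbc_length || p > field_um + optics$rbc_length) next
        odc438 <- optics$od438_deoxy +
          (cells_so2[ci] / 100) * (optics$od438_oxy - optics$od438_deoxy)
        col4 <- paint(col4, p, optics$od420)
        col8 <- paint(col8, p, odc438)
      }
      od420[, f] <- col4
      od438[, f] <- col8
    }
  }

  img420 <- optics$I0 * 10^(-od420)
  img438 <- optics$I0 * 10^(-od438)
  if (optics$noise_sd > 0) {
    img420 <- img420 + stats::rnorm(length(img420), 0, optics$noise_sd)
    img438 <- img438 + stats::rnorm(length(img438), 0, optics$noise_sd)
    img420[img420 < 0] <- 0
    img438[img438 < 0] <- 0
  }
  t0 <- secs[1] - 1
  list(sti420 = new_sti(img420, optics, 420L, t0),
       sti438 = new_sti(img438, optics, 438L, t0))
}

#' Write / read a space-time image pair
#'
#' Each wavelength goes to a single-raster TIFF (rows = position, columns =
#' time), scaled to 16-bit by the metadata `scale` value, plus one JSON
#' sidecar holding scales, calibration and seed so the pair can be
#' re-analyzed without the generating session.
#'
#' @param pair List with `sti420`, `sti438` as returned by [render_sti()].
#' @param prefix Output path prefix; writes `<prefix>_420.tif`,
#'   `<prefix>_438.tif`, `<prefix>.json`.
#' @param optics The [optics_config()] used for rendering (stored in the
#'   sidecar).
#' @return `write_sti_pair` returns `prefix` invisibly; `read_sti_pair`
#'   returns the pair list with metadata restored.
#' @export
write_sti_pair <- function(pair, prefix, optics) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write STI TIFFs", call. = FALSE)
  }
  scale <- max(pair$sti420$image, pair$sti438$image, optics$I0)
  tiff::writeTIFF(pair$sti420$image / scale, paste0(prefix, "_420.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(pair$sti438$image / scale, paste0(prefix, "_438.tif"),
                  bits.per.sample = 16)
  meta <- list(um_per_px = optics$um_per_px, fps = optics$fps, I0 = optics$I0,
               od420 = optics$od420, od438_deoxy = optics$od438_deoxy,
               od438_oxy = optics$od438_oxy, rbc_length = optics$rbc_length,
               field_length_px = optics$field_length_px,
               noise_sd = optics$noise_sd, seed = optics$seed,
               scale = scale, t0 = pair$sti420$t0)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_sti_pair
#' @export
read_sti_pair <- function(prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read STI TIFFs", call. = FALSE)
  }
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  optics <- optics_config(um_per_px = meta$um_per_px, fps = meta$fps,
                          I0 = meta$I0, od420 = meta$od420,
                          od438_deoxy = meta$od438_deoxy,
                          od438_oxy = meta$od438_oxy,
                          rbc_length = meta$rbc_length,
                          field_length_px = meta$field_length_px,
                          noise_sd = meta$noise_sd)
  rd <- function(w) {
    img <- tiff::readTIFF(paste0(prefix, "_", w, ".tif")) * meta$scale
    new_sti(img, optics, as.integer(w), meta$t0)
  }
  list(sti420 = rd(420), sti438 = rd(438), optics = optics)
}
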