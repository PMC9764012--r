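#' Per-second RBC velocity from a space-time image
#'
#' Radon-style streak velocimetry: within each 1-second block of columns,
#' every pixel is projected onto the axis perpendicular to a candidate
#' streak direction and the count-weighted variance of the binned projection
#' profile is scored. The variance is maximal when the projection runs along
#' the streaks, i.e. when the candidate velocity matches the flow, so the
#' per-second estimate is the maximizing candidate (coarse velocity grid
#' followed by two local grid refinements). Flow toward increasing position
#' is positive; ties in variance break toward the smaller speed.
#'
#' @param sti A `space_time_image` (either wavelength; the 420 nm image is
#'   preferred since its contrast is SO2-independent).
#' @param window Optional length-2 vector of seconds (relative to the
#'   image's `t0`) restricting the analysis.
#' @param v_max Magnitude of the largest resolvable velocity searched
#'   (um/s). Estimates within 2% of `v_max` are flagged saturated.
#' @param n_coarse Number of coarse grid candidates across `[-v_max, v_max]`.
#' @param contrast_min Minimum within-block relative contrast
#'   (`1 - min/max`) below which a block is declared blank (no cells) and
#'   returns `NA` with quality flag 0.
#' @return A tibble with columns `t` (integer second, absolute), `velocity`
#'   (um/s, `NA` for blank blocks), `quality` (number of frames used, 0 for
#'   blank) and `saturated` (logical).
#' @export
estimate_velocity <- function(sti, window = NULL, v_max = 1500,
                              n_coarse = 121, contrast_min = 0.02) {
  stopifnot(inherits(sti, "space_time_image"))
  img <- sti$image
  fps <- round(1 / sti$dt)
  n_sec <- ncol(img) %/% fps
  secs <- sti$t0 + seq_len(n_sec)
  if (!is.null(window)) {
    keep <- secs > window[1] - 1 & secs <= window[2]
  } else keep <- rep(TRUE, n_sec)

  n_px <- nrow(img)
  res <- tibble::tibble(t = secs, velocity = NA_real_, quality = 0L,
                        saturated = FALSE)
  # Radon-projection variance: project every pixel onto the axis
  # perpendicular to the candidate streak direction (u = row - slope * col)
  # and score the count-weighted between-bin variance of bin-mean
  # intensities. The projection needs no common support, so arbitrarily
  # steep streaks score correctly.
  radon_score <- function(block, rowv, colv, v) {
    slope <- v * sti$dt / sti$um_per_px  # px per frame
    u <- rowv - slope * colv
    bin <- floor(u - min(u)) + 1L
    x <- as.vector(block)
    cnt <- tabulate(bin)
    sm <- unname(rowsum(x, bin, reorder = TRUE))[, 1]
    nz <- cnt > 0
    mu <- sm[nz] / cnt[nz]
    gm <- sum(sm[nz]) / sum(cnt[nz])
    sum(cnt[nz] * (mu - gm)^2) / sum(cnt[nz])
  }

  for (s in seq_len(n_sec)) {
    if (!keep[s]) next
    cols <- ((s - 1) * fps + 1):(s * fps)
    block <- img[, cols, drop = FALSE]
    rng <- range(block)
    if (rng[2] <= 0 || 1 - rng[1] / rng[2] < contrast_min) next  # blank
    rowv <- rep(seq_len(n_px), times = ncol(block))
    colv <- rep(seq_len(ncol(block)) - 1L, each = n_px)
    # three-stage grid refinement of the projection angle
    vgrid <- seq(-v_max, v_max, length.out = n_coarse)
    step <- vgrid[2] - vgrid[1]
    for (stage in 1:3) {
      scores <- vapply(vgrid, function(v)
        radon_score(block, rowv, colv, v), numeric(1))
      best <- which(scores >= max(scores) - 1e-12)
      best <- best[which.min(abs(vgrid[best]))]  # tie-break: smaller |v|
      v_hat <- vgrid[best]
      if (stage < 3) {
        lo <- max(-v_max, v_hat - step)
        hi <- min(v_max, v_hat + step)
        vgrid <- seq(lo, hi, length.out = 41)
        step <- vgrid[2] - vgrid[1]
      }
    }
    res$velocity[s] <- v_hat
    res$quality[s] <- length(cols)
    res$saturated[s] <- abs(v_hat) >= 0.98 * v_max
  }
  res
}

## Runs of below-threshold pixels in one column; returns start/end indices.
.cell_runs <- function(colv, thr, min_px) {
  below <- colv < thr
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= min_px
  if (!any(ok)) return(NULL)
  cbind(start = starts[ok], end = ends[ok])
}

#' Per-second RBC lineal density from a space-time image
#'
#' Counts distinct cells along the space axis of each frame column: pixels
#' are thresholded at a fixed fraction (`depth_frac`, default 0.8) of the
#' block's maximum absorbance depth below background -- a deep threshold, so
#' the partially absorbing pixels in sub-resolution gaps between nearly
#' touching cells stay above it and adjacent cells are split rather than
#' merged -- runs shorter than half an RBC length are discarded, and the
#' count is divided by the field length in mm. The per-second value is the mean over the second's columns. The
#' 420 nm (isosbestic) image should be used so counting is independent of
#' oxygenation.
#'
#' @inheritParams estimate_velocity
#' @param min_frac Minimum run extent as a fraction of the RBC length.
#' @param depth_frac Threshold depth as a fraction of the block's maximum
#'   depth below background.
#' @return A tibble with columns `t`, `lineal_density` (cells/mm) and
#'   `quality` (columns used; 0 marks an empty or skipped second, for which
#'   density is 0 only when the field is verifiably cell-free).
#' @export
estimate_lineal_density <- function(sti, window = NULL, min_frac = 0.5,
                                    depth_frac = 0.8, contrast_min = 0.02) {
  stopifnot(inherits(sti, "space_time_image"))
  img <- sti$image
  fps <- round(1 / sti$dt)
  n_px <- nrow(img)
  field_mm <- n_px * sti$um_per_px / 1000
  if (field_mm * 1000 < sti$rbc_length) {
    stop("field shorter than one RBC length; density undefined", call. = FALSE)
  }
  min_px <- max(1L, floor(min_frac * sti$rbc_length / sti$um_per_px))
  n_sec <- ncol(img) %/% fps
  secs <- sti$t0 + seq_len(n_sec)
  if (!is.null(window)) {
    keep <- secs > window[1] - 1 & secs <= window[2]
  } else keep <- rep(TRUE, n_sec)

  res <- tibble::tibble(t = secs, lineal_density = NA_real_, quality = 0L)
  bg <- stats::quantile(img, 0.99)  # cell-free background level
  for (s in seq_len(n_sec)) {
    if (!keep[s]) next
    cols <- ((s - 1) * fps + 1):(s * fps)
    block <- img[, cols, drop = FALSE]
    if (1 - min(block) / bg < contrast_min) {
      # verifiably cell-free block
      res$lineal_density[s] <- 0
      res$quality[s] <- length(cols)
      next
    }
    thr <- bg - depth_frac * (bg - min(block))
    counts <- vapply(seq_len(ncol(block)), function(c) {
      runs <- .cell_runs(block[, c], thr, min_px)
      if (is.null(runs)) 0L else nrow(runs)
    }, integer(1))
    res$lineal_density[s] <- mean(counts) / field_mm
    res$quality[s] <- length(cols)
  }
  res
}

#' Per-second RBC oxygen saturation from a dual-wavelength pair
#'
#' Ratiometric oximetry inverting the two-wavelength forward model: cells
#' are segmented on the isosbestic 420 nm image, and for interior cell
#' pixels (eroded away from run edges so partial-coverage pixels are
#' excluded) the optical densities `OD = -log10(I / I0)` are averaged per
#' cell at both wavelengths. The OD ratio maps linearly to saturation,
#' `SO2 = 100 * (OD438/OD420 - r0) / (r100 - r0)`, with `r0`, `r100` the
#' calibration ratios at SO2 = 0 and 100. The per-second value is the mean
#' over cells detected in that second, clipped to [0, 100] (the unclipped
#' mean is kept in `so2_raw`). Cells with no measurable 420 nm absorbance
#' are skipped, never scored as SO2 = 0; seconds without usable cells are
#' missing with quality flag 0.
#'
#' @param sti420,sti438 The co-registered `space_time_image` pair (equal
#'   dimensions and scales).
#' @param calibration List with `r0`, `r100` (see [so2_calibration()]).
#' @param window,contrast_min As in [estimate_velocity()].
#' @param min_frac Minimum cell run extent as a fraction of RBC length.
#' @param erode_px Pixels eroded from each run end before averaging.
#' @return A tibble with columns `t`, `so2` (%, clipped), `so2_raw`
#'   (unclipped), `quality` (number of cells measured).
#' @export
estimate_so2 <- function(sti420, sti438, calibration, window = NULL,
                         min_frac = 0.5, erode_px = 2L, contrast_min = 0.02) {
  stopifnot(inherits(sti420, "space_time_image"),
            inherits(sti438, "space_time_image"),
            sti420$wavelength == 420, sti438$wavelength == 438,
            all(dim(sti420$image) == dim(sti438$image)),
            isTRUE(all.equal(sti420$um_per_px, sti438$um_per_px)),
            isTRUE(all.equal(sti420$dt, sti438$dt)))
  if (is.null(calibration$r0) || is.null(calibration$r100) ||
      calibration$r0 == calibration$r100) {
    stop("calibration must supply distinct r0 and r100 OD ratios", call. = FALSE)
  }
  i4 <- sti420$image; i8 <- sti438$image
  I0 <- sti420$I0
  fps <- round(1 / sti420$dt)
  min_px <- max(3L, floor(min_frac * sti420$rbc_length / sti420$um_per_px))
  n_sec <- ncol(i4) %/% fps
  secs <- sti420$t0 + seq_len(n_sec)
  if (!is.null(window)) {
    keep <- secs > window[1] - 1 & secs <= window[2]
  } else keep <- rep(TRUE, n_sec)

  res <- tibble::tibble(t = secs, so2 = NA_real_, so2_raw = NA_real_,
                        quality = 0L)
  for (s in seq_len(n_sec)) {
    if (!keep[s]) next
    cols <- ((s - 1) * fps + 1):(s * fps)
    block4 <- i4[, cols, drop = FALSE]
    rng <- range(block4)
    if (rng[2] <= 0 || 1 - rng[1] / rng[2] < contrast_min) next
    thr <- (I0 + rng[1]) / 2
    cell_vals <- numeric(0)
    for (c in seq_along(cols)) {
      runs <- .cell_runs(block4[, c], thr, min_px)
      if (is.null(runs)) next
      for (r in seq_len(nrow(runs))) {
        lo <- runs[r, "start"] + erode_px
        hi <- runs[r, "end"] - erode_px
        if (hi < lo) next
        px <- lo:hi
        od4 <- mean(-log10(pmax(i4[px, cols[c]], .Machine$double.eps) / I0))
        if (od4 <= 1e-6) next  # no measurable isosbestic absorbance
        od8 <- mean(-log10(pmax(i8[px, cols[c]], .Machine$double.eps) / I0))
        ratio <- od8 / od4
        cell_vals <- c(cell_vals,
                       100 * (ratio - calibration$r0) /
                         (calibration$r100 - calibration$r0))
      }
    }
    if (length(cell_vals)) {
      raw <- mean(cell_vals)
      res$so2_raw[s] <- raw
      res$so2[s] <- min(max(raw, 0), 100)
      res$quality[s] <- length(cell_vals)
    }
  }
  res
}

#' Full per-second hemodynamics from a dual-wavelength STI pair
#'
#' Runs [estimate_velocity()] (420 nm), [estimate_lineal_density()] (420 nm)
#' and [estimate_so2()] (pair) over an image pair and derives hematocrit and
#' supply rate, producing a per-second table in the same schema as the
#' ground-truth series plus quality flags. Missing seconds stay missing.
#'
#' @param sti420,sti438 The image pair.
#' @param calibration SO2 calibration ratios (see [so2_calibration()]).
#' @param rbc_volume,diameter Passed to [derive_hematocrit()].
#' @param capillary_id Identifier copied to the output.
#' @param window Optional window of seconds analyzed.
#' @param v_max Velocity search bound, passed to [estimate_velocity()].
#' @return A tibble with columns `capillary_id`, `t`, `velocity`,
#'   `lineal_density`, `hematocrit`, `supply_rate`, `so2`, `quality_velocity`,
#'   `quality_density`, `quality_so2`.
#' @export
analyze_sti_pair <- function(sti420, sti438, calibration,
                             rbc_volume = 55, diameter = 5,
                             capillary_id = 1L, window = NULL, v_max = 1500) {
  v <- estimate_velocity(sti420, window = window, v_max = v_max)
  d <- estimate_lineal_density(sti420, window = window)
  s <- estimate_so2(sti420, sti438, calibration, window = window)
  tibble::tibble(
    capillary_id = capillary_id,
    t = v$t,
    velocity = v$velocity,
    lineal_density = d$lineal_density,
    hematocrit = derive_hematocrit(d$lineal_density, rbc_volume, diameter,
                                   warn = FALSE),
    supply_rate = derive_supply_rate(abs(v$velocity), d$lineal_density),
    so2 = s$so2,
    quality_velocity = v$quality,
    quality_density = d$quality,
    quality_so2 = s$quality)
}
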