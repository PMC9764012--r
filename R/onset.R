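#' Second-by-second population means
#'
#' Available-case cross-capillary mean, SD, SEM and contributing count per
#' integer second, for each hemodynamic measure. Missing values are excluded
#' (a second with no contributing capillary has a missing mean), and the
#' number of contributing capillaries is recorded.
#'
#' @param pop A long table with columns `capillary_id`, `t` and one column
#'   per measure (e.g. a `ground_truth_population` or the output of
#'   [analyze_sti_pair()] row-bound over capillaries).
#' @param measures Character vector of measure columns to aggregate;
#'   defaults to the five hemodynamic measures present.
#' @return A tibble with columns `measure`, `t`, `mean`, `sd`, `sem`, `n`.
#' @export
aggregate_means <- function(pop, measures = NULL) {
  standard <- c("velocity", "lineal_density", "hematocrit", "supply_rate", "so2")
  if (is.null(measures)) measures <- intersect(standard, names(pop))
  stopifnot(all(c("capillary_id", "t") %in% names(pop)),
            length(measures) > 0, all(measures %in% names(pop)))
  t_levels <- sort(unique(pop$t))
  out <- lapply(measures, function(mm) {
    v <- pop[[mm]]
    f <- factor(pop$t, levels = t_levels)
    n <- tapply(!is.na(v), f, sum)
    n[is.na(n)] <- 0L
    mu <- tapply(v, f, mean, na.rm = TRUE)
    sdv <- tapply(v, f, stats::sd, na.rm = TRUE)
    mu[n == 0] <- NA_real_
    sem <- ifelse(n >= 1, sdv / sqrt(n), NA_real_)
    tibble::tibble(measure = mm, t = t_levels, mean = as.numeric(mu),
                   sd = as.numeric(sdv), sem = as.numeric(sem),
                   n = as.integer(n))
  })
  do.call(rbind, out)
}

## CDF of max_j |T_j| for a k-variate equicorrelated t with `df` degrees of
## freedom and common correlation `rho`, by 2D Gaussian quadrature:
## Gauss-Hermite over the shared normal factor, Gauss-Legendre over the
## scaled-chi mixing variable. Vectorized over q.
pmax_abs_equicorr_t <- function(q, k, df, rho, n_nodes = 48) {
  stopifnot(k >= 1, df > 0, rho >= 0, rho < 1)
  gh <- pracma::gaussHermite(n_nodes)
  z <- sqrt(2) * gh$x
  wz <- gh$w / sqrt(pi)
  # mixing variable w = sqrt(chi2_df / df); integrate over its bulk
  wlo <- sqrt(stats::qchisq(1e-12, df) / df)
  whi <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
  gl <- pracma::gaussLegendre(n_nodes, wlo, whi)
  wv <- gl$x
  fw <- exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
              (df - 1) * log(wv) - df * wv^2 / 2)
  ww <- gl$w * fw
  s1 <- sqrt(1 - rho)
  sr <- sqrt(rho)
  # node grids: outer over (z, w)
  Z <- rep(z, times = n_nodes)
  W <- rep(wv, each = n_nodes)
  WT <- rep(wz, times = n_nodes) * rep(ww, each = n_nodes)
  vapply(q, function(qq) {
    if (!is.finite(qq)) return(if (qq > 0) 1 else 0)
    if (qq <= 0) return(0)
    p1 <- stats::pnorm((qq * W - sr * Z) / s1) -
      stats::pnorm((-qq * W - sr * Z) / s1)
    sum(WT * p1^k)
  }, numeric(1))
}

#' Baseline-referenced per-second comparisons with Dunnett-style adjustment
#'
#' Implements the comparison structure of the study's repeated-measures
#' analysis: each capillary's baseline score is its mean over the baseline
#' window, each post-step second is compared to that shared baseline by a
#' paired t-test of the within-capillary differences, and the family of
#' many-to-one comparisons (every post second against the same baseline) is
#' adjusted with the Dunnett max-|T| distribution. Capillaries missing a
#' given second are dropped for that comparison only.
#'
#' When every post second has the same number of complete pairs the
#' adjustment uses the equicorrelated multivariate-t max-|T| CDF (common
#' correlation estimated from the difference columns, quadrature
#' evaluation); with missingness it falls back to a Monte-Carlo
#' approximation of the same distribution with per-second degrees of
#' freedom (fixed seed, `mc_draws` draws).
#'
#' @param pop Long table with `capillary_id`, `t` and the measure column.
#' @param measure Name of the measure column to test.
#' @param baseline_window Length-2 vector, baseline reference window in
#'   seconds (inclusive); default `c(51, 60)`.
#' @param post_window Length-2 vector of post-step seconds to test.
#' @param alpha Family-wise significance level (default 0.05).
#' @param method `"auto"` (quadrature when balanced, Monte Carlo otherwise),
#'   `"mvt"` or `"mc"`.
#' @param mc_draws Monte-Carlo draws for the unbalanced fall-back.
#' @param mc_seed Seed for the Monte-Carlo fall-back (local RNG; does not
#'   disturb the caller's RNG state).
#' @return A tibble with one row per post second: `t`, `n` (complete
#'   pairs), `estimate` (mean difference from baseline), `statistic`
#'   (paired t), `df`, `p_raw` (unadjusted two-sided), `p_adj`
#'   (Dunnett-adjusted), `significant` (`p_adj < alpha`). Seconds with
#'   fewer than 2 complete pairs carry missing p-values.
#' @export
dunnett_vs_baseline <- function(pop, measure, baseline_window = c(51, 60),
                                post_window = c(61, 180), alpha = 0.05,
                                method = c("auto", "mvt", "mc"),
                                mc_draws = 1e5, mc_seed = 20221206) {
  method <- match.arg(method)
  stopifnot(measure %in% names(pop))
  caps <- sort(unique(pop$capillary_id))
  post_t <- seq(post_window[1], post_window[2])
  # wide capillary x second matrices
  base_t <- seq(baseline_window[1], baseline_window[2])
  get_mat <- function(tt) {
    m <- matrix(NA_real_, length(caps), length(tt),
                dimnames = list(caps, tt))
    sel <- pop$t %in% tt
    m[cbind(match(pop$capillary_id[sel], caps), match(pop$t[sel], tt))] <-
      pop[[measure]][sel]
    m
  }
  B <- rowMeans(get_mat(base_t), na.rm = TRUE)
  Y <- get_mat(post_t)
  D <- Y - B  # paired differences vs the shared baseline score
  D[!is.finite(D)] <- NA

  n_s <- colSums(!is.na(D))
  if (sum(n_s >= 2) == 0) {
    stop("need at least 2 capillaries with baseline and post data", call. = FALSE)
  }
  est <- colMeans(D, na.rm = TRUE)
  sd_s <- apply(D, 2, stats::sd, na.rm = TRUE)
  tstat <- ifelse(n_s >= 2,
                  ifelse(sd_s == 0, ifelse(est == 0, 0, sign(est) * Inf),
                         est / (sd_s / sqrt(n_s))),
                  NA_real_)
  dfs <- n_s - 1
  p_raw <- ifelse(n_s >= 2, 2 * stats::pt(-abs(tstat), dfs), NA_real_)

  k <- sum(n_s >= 2)
  # common correlation of the difference columns (shared baseline induces it)
  Dc <- D[, n_s >= 2, drop = FALSE]
  rho <- if (ncol(Dc) > 1) {
    cm <- suppressWarnings(stats::cor(Dc, use = "pairwise.complete.obs"))
    r <- mean(cm[upper.tri(cm)], na.rm = TRUE)
    if (!is.finite(r)) r <- 0  # zero-variance differences (e.g. exact null)
    min(max(r, 0), 0.99)
  } else 0

  balanced <- length(unique(n_s[n_s >= 2])) == 1
  if (method == "auto") method <- if (balanced) "mvt" else "mc"

  p_adj <- rep(NA_real_, length(post_t))
  usable <- which(n_s >= 2)
  if (method == "mvt") {
    df_c <- unique(dfs[usable])[1]
    p_adj[usable] <- 1 - pmax_abs_equicorr_t(abs(tstat[usable]), k, df_c, rho)
  } else {
    maxT <- local({
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(mc_seed)
      draws <- mc_draws
      z0 <- stats::rnorm(draws)
      mx <- rep(0, draws)
      for (j in usable) {
        xj <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(draws)
        wj <- sqrt(stats::rchisq(draws, dfs[j]) / dfs[j])
        mx <- pmax(mx, abs(xj / wj))
      }
      mx
    })
    p_adj[usable] <- vapply(usable, function(j)
      (1 + sum(maxT >= abs(tstat[j]))) / (length(maxT) + 1), numeric(1))
  }
  p_adj <- pmin(pmax(p_adj, p_raw, na.rm = FALSE), 1)

  tibble::tibble(t = post_t, n = as.integer(n_s), estimate = est,
                 statistic = tstat, df = as.integer(dfs), p_raw = p_raw,
                 p_adj = p_adj, significant = !is.na(p_adj) & p_adj < alpha)
}

#' Onset and peak/nadir summary of a post-step response
#'
#' Mirrors one row of the study-style summary tables: the baseline mean and
#' SD, the first post-step second whose Dunnett-adjusted p-value crosses
#' `alpha` (with that second's cross-capillary mean, SD and adjusted p), and
#' the peak (or nadir, for negative-going responses) of the post-step means
#' with its time and adjusted p. When no post second is significant, every
#' post-baseline field is `NA`.
#'
#' @param means Per-second summary for one measure: a tibble with `t`,
#'   `mean`, `sd` (e.g. one measure's rows of [aggregate_means()]).
#' @param comparisons Output of [dunnett_vs_baseline()] for the same measure.
#' @param step_time Time of the gas step change (s); onsets must be after it.
#' @param baseline_window Baseline reference window (s).
#' @param direction `"auto"` (sign of post-window mean minus baseline mean;
#'   ties count as a peak), `"up"`, or `"down"`.
#' @param alpha Significance level for the onset definition.
#' @return A one-row tibble: `baseline_mean`, `baseline_sd`, `onset_time`,
#'   `onset_mean`, `onset_sd`, `onset_p`, `peak_time`, `peak_mean`,
#'   `peak_sd`, `peak_p`, `direction`, `percent_change` (peak vs baseline).
#' @export
find_onset_and_peak <- function(means, comparisons, step_time = 60,
                                baseline_window = c(51, 60),
                                direction = c("auto", "up", "down"),
                                alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(all(c("t", "mean", "sd") %in% names(means)))
  bsel <- means$t >= baseline_window[1] & means$t <= baseline_window[2]
  baseline_mean <- mean(means$mean[bsel], na.rm = TRUE)
  # cross-capillary spread: average the per-second SDs over the window
  baseline_sd <- mean(means$sd[bsel], na.rm = TRUE)

  post <- comparisons[comparisons$t > step_time, ]
  post_means <- means[match(post$t, means$t), ]

  if (direction == "auto") {
    delta <- mean(post_means$mean, na.rm = TRUE) - baseline_mean
    direction <- if (delta >= 0) "up" else "down"
  }

  sig <- which(!is.na(post$p_adj) & post$p_adj < alpha)
  na_row <- tibble::tibble(
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    onset_time = NA_real_, onset_mean = NA_real_, onset_sd = NA_real_,
    onset_p = NA_real_, peak_time = NA_real_, peak_mean = NA_real_,
    peak_sd = NA_real_, peak_p = NA_real_, direction = direction,
    percent_change = NA_real_)
  if (length(sig) == 0) return(na_row)

  o <- sig[1]
  pk_val <- if (direction == "up") {
    suppressWarnings(max(post_means$mean, na.rm = TRUE))
  } else {
    suppressWarnings(min(post_means$mean, na.rm = TRUE))
  }
  pk <- which(post_means$mean == pk_val)[1]

  tibble::tibble(
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    onset_time = post$t[o], onset_mean = post_means$mean[o],
    onset_sd = post_means$sd[o], onset_p = post$p_adj[o],
    peak_time = post$t[pk], peak_mean = post_means$mean[pk],
    peak_sd = post_means$sd[pk], peak_p = post$p_adj[pk],
    direction = direction,
    percent_change = percent_change(baseline_mean, post_means$mean[pk]))
}

#' Percent change of an extreme relative to baseline
#'
#' `100 * (extreme - baseline) / baseline`. Undefined (NA, with a warning)
#' for a zero baseline.
#'
#' @param baseline Baseline mean (non-zero).
#' @param extreme Peak or nadir mean.
#' @return Percent change (signed).
#' @examples
#' percent_change(228.5, 353.2)
#' @export
percent_change <- function(baseline, extreme) {
  out <- 100 * (extreme - baseline) / baseline
  bad <- !is.na(baseline) & baseline == 0
  if (any(bad)) {
    warning("percent change undefined for zero baseline", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Study-style onset table for a simulated or measured population
#'
#' Convenience wrapper producing one summary row per measure: aggregates
#' per-second means, runs the Dunnett-adjusted baseline comparison and
#' extracts onset and peak/nadir, in the column structure of the study's
#' response tables.
#'
#' @param pop Long per-capillary table (see [aggregate_means()]).
#' @param measures Measure columns to summarize.
#' @param baseline_window,post_window,alpha As in [dunnett_vs_baseline()].
#' @param step_time Step-change time (defaults to the end of the baseline
#'   window).
#' @return A tibble with a `measure` column plus the [find_onset_and_peak()]
#'   fields.
#' @export
onset_table <- function(pop, measures = NULL, baseline_window = c(51, 60),
                        post_window = c(61, 180), alpha = 0.05,
                        step_time = baseline_window[2]) {
  standard <- c("velocity", "lineal_density", "hematocrit", "supply_rate", "so2")
  if (is.null(measures)) measures <- intersect(standard, names(pop))
  means <- aggregate_means(pop, measures)
  out <- lapply(measures, function(mm) {
    cmp <- dunnett_vs_baseline(pop, mm, baseline_window, post_window, alpha)
    row <- find_onset_and_peak(means[means$measure == mm, ], cmp,
                               step_time = step_time,
                               baseline_window = baseline_window,
                               alpha = alpha)
    tibble::add_column(row, measure = mm, .before = 1)
  })
  do.call(rbind, out)
}
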