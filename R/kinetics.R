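#' Delayed exponential response models
#'
#' The on-kinetics of capillary hemodynamic measures after a step change in
#' chamber gas composition are described by a delayed mono-exponential,
#'
#' \deqn{Y(t) = Y_b + Y_0 (1 - e^{-(t - X_0)/\tau}) \quad (t \ge X_0),}
#'
#' with `Y(t) = Yb` before the onset delay `X0` (flat baseline), where `Yb` is
#' the baseline magnitude, `Y0` the signed asymptotic amplitude and `tau` the
#' time constant (the time after onset to reach 63% of the full response).
#' Combined challenges superimpose two delayed components (see [eval_bi()]),
#' one per gas step, each gated by its own delay.
#'
#' @param Yb Baseline magnitude, in the units of the measure.
#' @param X0 Onset delay (s).
#' @param Y0 Signed asymptotic amplitude, in the units of the measure.
#' @param tau Time constant (s), must be > 0.
#' @return A parameter object of class `mono_exp_params` (a named list).
#' @seealso [eval_mono()], [fit_mono()]
#' @export
mono_exp_params <- function(Yb, X0, Y0, tau) {
  p <- list(Yb = as.numeric(Yb), X0 = as.numeric(X0),
            Y0 = as.numeric(Y0), tau = as.numeric(tau))
  if (!all(vapply(p, function(x) length(x) == 1 && is.finite(x), logical(1)))) {
    stop("all mono-exponential parameters must be finite scalars", call. = FALSE)
  }
  if (p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(p, class = "mono_exp_params")
}

#' Two-component delayed exponential parameters
#'
#' @param Yb Baseline magnitude.
#' @param X1,X2 Onset delays (s) of the first and second component; `X2 >= X1`.
#' @param Y1,Y2 Signed amplitudes of the two components.
#' @param tau1,tau2 Time constants (s), both > 0.
#' @return A parameter object of class `bi_exp_params`.
#' @seealso [eval_bi()], [fit_bi()]
#' @export
bi_exp_params <- function(Yb, X1, Y1, tau1, X2, Y2, tau2) {
  p <- list(Yb = as.numeric(Yb), X1 = as.numeric(X1), Y1 = as.numeric(Y1),
            tau1 = as.numeric(tau1), X2 = as.numeric(X2), Y2 = as.numeric(Y2),
            tau2 = as.numeric(tau2))
  if (!all(vapply(p, function(x) length(x) == 1 && is.finite(x), logical(1)))) {
    stop("all bi-exponential parameters must be finite scalars", call. = FALSE)
  }
  if (p$tau1 <= 0 || p$tau2 <= 0) stop("tau1 and tau2 must be > 0", call. = FALSE)
  if (p$X2 < p$X1) stop("X2 must be >= X1", call. = FALSE)
  structure(p, class = "bi_exp_params")
}

#' Evaluate the delayed mono-exponential model
#'
#' @param t Time (s); vectorized.
#' @param params A [mono_exp_params()] object (or a list with elements
#'   `Yb`, `X0`, `Y0`, `tau`).
#' @return Model value at each `t`; equals `Yb` for `t < X0`.
#' @examples
#' p <- mono_exp_params(Yb = 228.5, X0 = 60, Y0 = 116.5, tau = 35.5)
#' eval_mono(c(55, 60, 95.5, 180), p)
#' @export
eval_mono <- function(t, params) {
  p <- as.list(params)
  if (is.null(p$tau) || p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  stopifnot(all(is.finite(t)))
  dt <- t - p$X0
  p$Yb + p$Y0 * ifelse(dt >= 0, 1 - exp(-dt / p$tau), 0)
}

#' Evaluate the two-component delayed exponential model
#'
#' Each component contributes zero before its own delay, so for
#' `X1 <= t < X2` the curve coincides with the mono-exponential using the
#' first component alone.
#'
#' @param t Time (s); vectorized.
#' @param params A [bi_exp_params()] object (or compatible list).
#' @return Model value at each `t`.
#' @export
eval_bi <- function(t, params) {
  p <- as.list(params)
  if (is.null(p$tau1) || p$tau1 <= 0 || is.null(p$tau2) || p$tau2 <= 0) {
    stop("tau1 and tau2 must be > 0", call. = FALSE)
  }
  stopifnot(all(is.finite(t)))
  d1 <- t - p$X1
  d2 <- t - p$X2
  p$Yb +
    p$Y1 * ifelse(d1 >= 0, 1 - exp(-d1 / p$tau1), 0) +
    p$Y2 * ifelse(d2 >= 0, 1 - exp(-d2 / p$tau2), 0)
}

#' Coefficient of determination
#'
#' `1 - SSR/SST` with SST taken about the data mean. Can be negative for a
#' model worse than the mean. A zero-variance series has no defined R^2 and
#' returns `NA` with a warning.
#'
#' @param y Observed values.
#' @param yhat Model values on the same grid.
#' @return Scalar R^2 (possibly negative), or `NA` for zero-variance data.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ok <- is.finite(y) & is.finite(yhat)
  y <- y[ok]; yhat <- yhat[ok]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("zero-variance series: R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / sst
}

#' Fit constraints for delayed-exponential least squares
#'
#' Encodes the fit window and per-parameter bounds/pins used by [fit_mono()]
#' and [fit_bi()]. A strict inequality such as "delay greater than the step
#' time" is expressed as a lower bound at `60 + eps`; an equality pin fixes a
#' parameter exactly. Ranges such as 51-180 s denote the fit window, not
#' parameter bounds.
#'
#' @param window Length-2 numeric, fit window `[t_start, t_end]` in seconds.
#' @param lower,upper Named numeric vectors of parameter bounds, using names
#'   `Yb`, `X0`, `Y0`, `tau` (mono) or `Yb`, `X1`, `Y1`, `tau1`, `X2`, `Y2`,
#'   `tau2` (bi). Omitted parameters are unbounded ("no set value").
#' @param pin Named numeric vector of parameters fixed at a given value
#'   (e.g. `c(X0 = 60)`).
#' @param eps Offset applied by [constraint_gt()] for strict bounds.
#' @return A `fit_constraints` object.
#' @examples
#' fit_constraints(window = c(51, 180), lower = c(X0 = constraint_gt(60)))
#' @export
fit_constraints <- function(window = c(51, 180), lower = NULL, upper = NULL,
                            pin = NULL, eps = 1e-6) {
  stopifnot(length(window) == 2, is.numeric(window), window[1] < window[2])
  chk <- function(x, what) {
    if (!is.null(x) && (is.null(names(x)) || any(names(x) == "")))
      stop(what, " must be a named numeric vector", call. = FALSE)
    x
  }
  structure(list(window = as.numeric(window), lower = chk(lower, "lower"),
                 upper = chk(upper, "upper"), pin = chk(pin, "pin"),
                 eps = eps),
            class = "fit_constraints")
}

#' @rdname fit_constraints
#' @param x Bound value excluded by a strict inequality.
#' @export
constraint_gt <- function(x, eps = 1e-6) x + eps

.get_bound <- function(vec, name, default) {
  if (!is.null(vec) && name %in% names(vec)) unname(vec[[name]]) else default
}

## Profile SSR for the mono model at fixed X0: amplitudes (Yb, Y0) enter
## linearly given tau, so tau is optimized in 1D and the amplitudes solved by
## ordinary least squares. Returns list(ssr, Yb, Y0, tau).
.mono_profile <- function(t, y, X0, tau_range) {
  g_of <- function(tau) {
    dt <- t - X0
    ifelse(dt >= 0, 1 - exp(-dt / tau), 0)
  }
  solve_amp <- function(g) {
    X <- cbind(1, g)
    fit <- stats::lm.fit(X, y)
    ssr <- sum(fit$residuals^2)
    cf <- fit$coefficients
    if (any(!is.finite(cf))) {
      # g has no variation in the window (all pre-onset): Y0 unidentified
      cf <- c(mean(y), 0)
      ssr <- sum((y - cf[1])^2)
    }
    list(ssr = ssr, Yb = cf[[1]], Y0 = cf[[2]])
  }
  obj <- function(log_tau) solve_amp(g_of(exp(log_tau)))$ssr
  opt <- stats::optimize(obj, log(tau_range), tol = 1e-10)
  tau <- exp(opt$minimum)
  amp <- solve_amp(g_of(tau))
  list(ssr = amp$ssr, Yb = amp$Yb, Y0 = amp$Y0, tau = tau)
}

.nonconverged <- function(model, restarts = 0L) {
  structure(list(params = NULL, model = model, r_squared = NA_real_,
                 ssr = NA_real_, converged = FALSE, identifiable = FALSE,
                 restarts = restarts, fitted = NULL),
            class = "kinetic_fit")
}

.finish_fit <- function(params, model, t, y, ssr, restarts, noise_floor) {
  yhat <- if (model == "mono") eval_mono(t, params) else eval_bi(t, params)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  amp <- if (model == "mono") abs(params$Y0) else max(abs(params$Y1), abs(params$Y2))
  identifiable <- amp > noise_floor
  if (!identifiable) {
    # amplitude at the noise floor: the time constant is not estimable
    if (model == "mono") params$tau <- NA_real_ else {
      params$tau1 <- NA_real_; params$tau2 <- NA_real_
    }
  }
  structure(list(params = params, model = model, r_squared = r2, ssr = ssr,
                 converged = TRUE, identifiable = identifiable,
                 restarts = restarts, fitted = yhat),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> ", x$model, "-exponential, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  if (!is.null(x$params)) {
    p <- unlist(x$params)
    cat(" ", paste(sprintf("%s = %.6g", names(p), p), collapse = ", "), "\n")
    cat(sprintf("  R^2 = %.4f, SSR = %.4g, identifiable = %s\n",
                x$r_squared, x$ssr, x$identifiable))
  }
  invisible(x)
}

#' Constrained non-linear least-squares fit of the delayed mono-exponential
#'
#' Minimizes the sum of squared residuals of [eval_mono()] over the fit
#' window, subject to parameter bounds and pins. Because the onset delay
#' makes the objective non-smooth in `X0`, the fit runs a coarse grid search
#' over `X0` (0.5 s steps) in which the amplitudes are solved linearly and
#' `tau` is profiled in 1D, then refines `X0` locally, and finally polishes
#' all free parameters with bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Ties in SSR break to the smaller delay, then the
#' smaller |velocity| of change (smaller amplitude).
#'
#' @param t Time grid (s) of the series (typically integer seconds at 1 Hz).
#' @param y Measured values (population mean trace) on `t`.
#' @param constraints A [fit_constraints()] object; defaults to window
#'   51-180 s with `X0 > 60`.
#' @param options List of tuning options: `x0_step` (grid step, s, default
#'   0.5), `x0_max` (upper delay bound when not otherwise constrained,
#'   default `t_end - 5`), `tau_range` (search range for tau, default
#'   `c(1e-3, 5 * window span)`), `noise_floor` (amplitude below which the
#'   fit is flagged unidentifiable and no tau reported, default 0).
#' @return A `kinetic_fit` object: list with `params`
#'   ([mono_exp_params()]), `r_squared`, `ssr`, `converged`, `identifiable`,
#'   `restarts` (number of grid starts evaluated) and `fitted` values.
#' @examples
#' p <- mono_exp_params(Yb = 100, X0 = 65, Y0 = 50, tau = 20)
#' t <- 51:180
#' fit <- fit_mono(t, eval_mono(t, p),
#'                 fit_constraints(window = c(51, 180),
#'                                 lower = c(X0 = constraint_gt(60))))
#' unlist(fit$params)
#' @export
fit_mono <- function(t, y,
                     constraints = fit_constraints(window = c(51, 180),
                                                   lower = c(X0 = constraint_gt(60))),
                     options = list()) {
  stopifnot(length(t) == length(y))
  w <- t >= constraints$window[1] & t <= constraints$window[2] & is.finite(y)
  t <- t[w]; y <- y[w]
  if (length(t) < 6) stop("need at least 6 points inside the fit window", call. = FALSE)

  span <- diff(range(t))
  opt <- utils::modifyList(list(x0_step = 0.5, x0_max = NULL,
                                tau_range = c(1e-3, 5 * span),
                                noise_floor = 0), options)

  x0_lo <- .get_bound(constraints$lower, "X0", min(t))
  x0_hi <- .get_bound(constraints$upper, "X0",
                      if (is.null(opt$x0_max)) max(t) - 5 else opt$x0_max)
  pin_x0 <- .get_bound(constraints$pin, "X0", NA_real_)

  if (!is.na(pin_x0)) {
    grid <- pin_x0
  } else {
    # grid aligned to multiples of the step so exact generator delays are hit
    aligned <- seq(ceiling(x0_lo / opt$x0_step) * opt$x0_step, x0_hi,
                   by = opt$x0_step)
    grid <- unique(c(x0_lo, aligned))
    grid <- grid[grid >= x0_lo & grid <= x0_hi]
  }
  if (length(grid) == 0) return(.nonconverged("mono"))

  best <- NULL
  for (X0 in grid) {
    prof <- tryCatch(.mono_profile(t, y, X0, opt$tau_range),
                     error = function(e) NULL)
    if (is.null(prof)) next
    cand <- c(prof, X0 = X0)
    if (is.null(best) || cand$ssr < best$ssr - 1e-12 ||
        (abs(cand$ssr - best$ssr) <= 1e-12 && X0 < best$X0)) {
      best <- cand
    }
  }
  if (is.null(best)) return(.nonconverged("mono", length(grid)))

  # local refinement of the delay around the best grid point
  if (is.na(pin_x0) && length(grid) > 1) {
    lo <- max(x0_lo, best$X0 - opt$x0_step)
    hi <- min(x0_hi, best$X0 + opt$x0_step)
    if (hi > lo) {
      ref <- stats::optimize(function(X0)
        .mono_profile(t, y, X0, opt$tau_range)$ssr, c(lo, hi), tol = 1e-9)
      if (ref$objective < best$ssr) {
        prof <- .mono_profile(t, y, ref$minimum, opt$tau_range)
        best <- c(prof, X0 = ref$minimum)
      }
    }
  }

  # bounded Levenberg-Marquardt polish of all free parameters
  start <- list(Yb = best$Yb, X0 = best$X0, Y0 = best$Y0, tau = best$tau)
  lower <- c(Yb = .get_bound(constraints$lower, "Yb", -Inf),
             X0 = x0_lo,
             Y0 = .get_bound(constraints$lower, "Y0", -Inf),
             tau = max(.get_bound(constraints$lower, "tau", opt$tau_range[1]),
                       1e-8))
  upper <- c(Yb = .get_bound(constraints$upper, "Yb", Inf),
             X0 = x0_hi,
             Y0 = .get_bound(constraints$upper, "Y0", Inf),
             tau = .get_bound(constraints$upper, "tau", opt$tau_range[2]))
  if (!is.na(pin_x0)) { lower["X0"] <- pin_x0; upper["X0"] <- pin_x0 }
  start <- mapply(function(s, l, u) min(max(s, l), u), start, lower, upper,
                  SIMPLIFY = FALSE)
  polish <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ Yb + Y0 * ifelse(t >= X0, 1 - exp(-(t - X0) / tau), 0),
      data = list(t = t, y = y), start = start,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))
    cf <- as.list(stats::coef(fit))
    list(ssr = sum(stats::resid(fit)^2), Yb = cf$Yb, X0 = cf$X0, Y0 = cf$Y0,
         tau = cf$tau)
  }, error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$ssr) && polish$ssr <= best$ssr) {
    best <- polish
  }

  params <- mono_exp_params(best$Yb, best$X0, best$Y0, best$tau)
  .finish_fit(params, "mono", t, y, best$ssr, length(grid), opt$noise_floor)
}

## Profile SSR for the bi model at fixed delays (X1, X2): amplitudes
## (Yb, Y1, Y2) solved linearly, (tau1, tau2) optimized on the log scale.
.bi_profile <- function(t, y, X1, X2, tau_range, tau_starts) {
  g <- function(X, tau) {
    dt <- t - X
    ifelse(dt >= 0, 1 - exp(-dt / tau), 0)
  }
  solve_amp <- function(tau1, tau2) {
    X <- cbind(1, g(X1, tau1), g(X2, tau2))
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    if (any(!is.finite(cf))) return(NULL)
    list(ssr = sum(fit$residuals^2), Yb = cf[[1]], Y1 = cf[[2]], Y2 = cf[[3]])
  }
  obj <- function(lt) {
    a <- solve_amp(exp(lt[1]), exp(lt[2]))
    if (is.null(a)) return(.Machine$double.xmax)
    a$ssr
  }
  best <- NULL
  for (s in tau_starts) {
    o <- tryCatch(stats::optim(log(s), obj, method = "L-BFGS-B",
                               lower = log(tau_range[1]),
                               upper = log(tau_range[2]),
                               control = list(factr = 1e3, maxit = 300)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) return(NULL)
  tau1 <- exp(best$par[1]); tau2 <- exp(best$par[2])
  amp <- solve_amp(tau1, tau2)
  if (is.null(amp)) return(NULL)
  c(amp, tau1 = tau1, tau2 = tau2)
}

#' Constrained fit of the two-component delayed exponential
#'
#' Same strategy as [fit_mono()] extended to two delays: a coarse grid over
#' `(X1, X2)` with linearly solved amplitudes and jointly profiled time
#' constants, local refinement of the delays around the best grid cell, and a
#' bounded Levenberg-Marquardt polish of all seven parameters. Defaults match
#' the combined-challenge design: window 51-240 s, `X1 > 60`, `X2 > 120`,
#' `X2 >= X1` enforced throughout.
#'
#' @inheritParams fit_mono
#' @param constraints A [fit_constraints()]; defaults to window 51-240 s,
#'   `X1 > 60`, `X2 > 120`.
#' @param options List: `x_step` (coarse delay grid step, s, default 2),
#'   `x_refine_step` (refined step, default 0.5), `x_span` (how far above its
#'   lower bound each delay is searched, s, default 30), `tau_range`,
#'   `noise_floor` as in [fit_mono()].
#' @return A `kinetic_fit` with [bi_exp_params()].
#' @export
fit_bi <- function(t, y,
                   constraints = fit_constraints(window = c(51, 240),
                                                 lower = c(X1 = constraint_gt(60),
                                                           X2 = constraint_gt(120))),
                   options = list()) {
  stopifnot(length(t) == length(y))
  w <- t >= constraints$window[1] & t <= constraints$window[2] & is.finite(y)
  t <- t[w]; y <- y[w]
  if (length(t) < 8) stop("need at least 8 points inside the fit window", call. = FALSE)

  span <- diff(range(t))
  opt <- utils::modifyList(list(x_step = 2, x_refine_step = 0.5, x_span = 30,
                                tau_range = c(1e-3, 5 * span),
                                noise_floor = 0), options)
  tau_starts_full <- list(c(span / 10, span / 10), c(span / 4, span / 4),
                          c(2, 50))

  mk_grid <- function(lo, hi, step, pin) {
    if (!is.na(pin)) return(pin)
    aligned <- seq(ceiling(lo / step) * step, hi, by = step)
    g <- unique(c(lo, aligned))
    g[g >= lo & g <= hi]
  }
  x1_lo <- .get_bound(constraints$lower, "X1", min(t))
  x1_hi <- .get_bound(constraints$upper, "X1", x1_lo + opt$x_span)
  x2_lo <- .get_bound(constraints$lower, "X2", min(t))
  x2_hi <- .get_bound(constraints$upper, "X2", x2_lo + opt$x_span)
  pin_x1 <- .get_bound(constraints$pin, "X1", NA_real_)
  pin_x2 <- .get_bound(constraints$pin, "X2", NA_real_)

  search <- function(g1, g2, tau_starts) {
    best <- NULL
    for (X1 in g1) for (X2 in g2) {
      if (X2 < X1) next
      prof <- .bi_profile(t, y, X1, X2, opt$tau_range, tau_starts)
      if (is.null(prof)) next
      cand <- c(prof, X1 = X1, X2 = X2)
      if (is.null(best) || cand$ssr < best$ssr - 1e-12 ||
          (abs(cand$ssr - best$ssr) <= 1e-12 &&
           (X1 + X2) < (best$X1 + best$X2))) {
        best <- cand
      }
    }
    best
  }
  n_starts <- 0L
  g1 <- mk_grid(x1_lo, x1_hi, opt$x_step, pin_x1)
  g2 <- mk_grid(x2_lo, x2_hi, opt$x_step, pin_x2)
  n_starts <- n_starts + length(g1) * length(g2)
  best <- search(g1, g2, tau_starts_full[1])
  if (is.null(best)) return(.nonconverged("bi", n_starts))

  # refine delays around the best coarse cell
  if (is.na(pin_x1) || is.na(pin_x2)) {
    r1 <- if (is.na(pin_x1)) {
      mk_grid(max(x1_lo, best$X1 - opt$x_step),
              min(x1_hi, best$X1 + opt$x_step), opt$x_refine_step, NA_real_)
    } else pin_x1
    r2 <- if (is.na(pin_x2)) {
      mk_grid(max(x2_lo, best$X2 - opt$x_step),
              min(x2_hi, best$X2 + opt$x_step), opt$x_refine_step, NA_real_)
    } else pin_x2
    n_starts <- n_starts + length(r1) * length(r2)
    ref <- search(r1, r2, tau_starts_full)
    if (!is.null(ref) && ref$ssr <= best$ssr) best <- ref
  }

  start <- list(Yb = best$Yb, X1 = best$X1, Y1 = best$Y1, tau1 = best$tau1,
                X2 = best$X2, Y2 = best$Y2, tau2 = best$tau2)
  lower <- c(Yb = .get_bound(constraints$lower, "Yb", -Inf),
             X1 = x1_lo,
             Y1 = .get_bound(constraints$lower, "Y1", -Inf),
             tau1 = max(.get_bound(constraints$lower, "tau1", opt$tau_range[1]), 1e-8),
             X2 = x2_lo,
             Y2 = .get_bound(constraints$lower, "Y2", -Inf),
             tau2 = max(.get_bound(constraints$lower, "tau2", opt$tau_range[1]), 1e-8))
  upper <- c(Yb = .get_bound(constraints$upper, "Yb", Inf),
             X1 = x1_hi,
             Y1 = .get_bound(constraints$upper, "Y1", Inf),
             tau1 = .get_bound(constraints$upper, "tau1", opt$tau_range[2]),
             X2 = x2_hi,
             Y2 = .get_bound(constraints$upper, "Y2", Inf),
             tau2 = .get_bound(constraints$upper, "tau2", opt$tau_range[2]))
  if (!is.na(pin_x1)) { lower["X1"] <- pin_x1; upper["X1"] <- pin_x1 }
  if (!is.na(pin_x2)) { lower["X2"] <- pin_x2; upper["X2"] <- pin_x2 }
  start <- mapply(function(s, l, u) min(max(s, l), u), start, lower, upper,
                  SIMPLIFY = FALSE)
  polish <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ Yb + Y1 * ifelse(t >= X1, 1 - exp(-(t - X1) / tau1), 0) +
            Y2 * ifelse(t >= X2, 1 - exp(-(t - X2) / tau2), 0),
      data = list(t = t, y = y), start = start,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))
    cf <- as.list(stats::coef(fit))
    c(list(ssr = sum(stats::resid(fit)^2)), cf)
  }, error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$ssr) && polish$ssr <= best$ssr &&
      polish$X2 >= polish$X1) {
    best <- polish
  }

  params <- bi_exp_params(best$Yb, best$X1, best$Y1, best$tau1,
                          best$X2, best$Y2, best$tau2)
  .finish_fit(params, "bi", t, y, best$ssr, n_starts, opt$noise_floor)
}
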