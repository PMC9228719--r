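# Virtual Taylor-dispersion instrument: two-mode dispersion profiles,
# nonlinear peak fitting, and assembly of the ternary diffusion matrix from
# paired injections.

#' Taylor dispersion instrument geometry
#'
#' Geometry and sampling parameters of the dispersion tube and detector.
#' Defaults are a long Teflon capillary (3048.0 cm x 0.03220 cm internal
#' radius), 0.063 cm^3 injections, 5 s detector sampling, and a nominal
#' retention time of 7000 s. Only the combination `D * t_R / r^2` shapes the
#' peak, so analyses are insensitive to the nominal retention time.
#'
#' @param tube_length Tube length (cm).
#' @param tube_radius Internal tube radius (cm).
#' @param injection_volume Injected sample volume (cm^3).
#' @param sampling_interval Detector sampling interval (s).
#' @param retention_time_nominal Nominal mean retention time (s).
#'
#' @return An object of class `"instrument_geometry"`.
#' @examples
#' instrument_geometry()
#' @export
instrument_geometry <- function(tube_length = 3048.0,
                                tube_radius = 0.03220,
                                injection_volume = 0.063,
                                sampling_interval = 5,
                                retention_time_nominal = 7000) {
  vals <- c(tube_length, tube_radius, injection_volume, sampling_interval,
            retention_time_nominal)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be positive")
  if (tube_length / tube_radius <= 1e4)
    warning("tube length / radius ratio <= 1e4: Taylor conditions dubious")
  structure(list(tube_length = tube_length, tube_radius = tube_radius,
                 injection_volume = injection_volume,
                 sampling_interval = sampling_interval,
                 retention_time_nominal = retention_time_nominal),
            class = "instrument_geometry")
}

#' @export
print.instrument_geometry <- function(x, ...) {
  cat(sprintf(
    "Dispersion tube %.1f cm x r = %.5f cm; injection %.3f cm^3; dt = %g s\n",
    x$tube_length, x$tube_radius, x$injection_volume, x$sampling_interval))
  invisible(x)
}

#' Two-mode dispersion peak parameters
#'
#' Parameters of the two-exponential Taylor dispersion profile
#' \deqn{V(t) = V_0 + V_1 t + V_{max} \sqrt{t_R/t}\,
#'   [W_1 e^{-12 D_1 (t-t_R)^2 / (r^2 t)} +
#'    (1-W_1) e^{-12 D_2 (t-t_R)^2 / (r^2 t)}]}
#' where \eqn{D_1 \ge D_2} are the eigenvalues of the ternary diffusion
#' matrix and \eqn{W_1} the (detector-weighted) fraction of the faster
#' eigenmode. Eigenvalues are stored sorted descending so the mode labels
#' are unambiguous.
#'
#' @param v0 Baseline voltage.
#' @param v1 Baseline slope (voltage / s).
#' @param vmax Peak height above the linear baseline at `t = t_r`.
#' @param t_r Mean retention time (s), `> 0`.
#' @param w1 Weight of the mode with the larger eigenvalue, in `[0, 1]`.
#' @param d_eig1,d_eig2 Eigenvalue diffusivities (1e-9 m^2 s^-1), `> 0`.
#'   Swapped (with `w1 -> 1 - w1`) if given in ascending order.
#' @param residual_rms Root-mean-square fit residual (voltage units), `NA`
#'   for constructed parameter sets.
#'
#' @return An object of class `"peak_fit"`.
#' @export
peak_fit <- function(v0, v1, vmax, t_r, w1, d_eig1, d_eig2,
                     residual_rms = NA_real_) {
  stopifnot(is.numeric(c(v0, v1, vmax, t_r, w1, d_eig1, d_eig2)))
  if (t_r <= 0) stop("t_r must be positive")
  if (d_eig1 <= 0 || d_eig2 <= 0) stop("eigenvalues must be positive")
  if (w1 < 0 || w1 > 1) stop("w1 must lie in [0, 1]")
  if (d_eig1 < d_eig2) {       # canonical order: mode 1 = larger eigenvalue
    tmp <- d_eig1; d_eig1 <- d_eig2; d_eig2 <- tmp
    w1 <- 1 - w1
  }
  structure(list(v0 = v0, v1 = v1, vmax = vmax, t_r = t_r, w1 = w1,
                 d_eig1 = d_eig1, d_eig2 = d_eig2,
                 residual_rms = residual_rms),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf(
    "Dispersion peak: t_R = %.1f s, Vmax = %.4g, W1 = %.4f\n", x$t_r,
    x$vmax, x$w1))
  cat(sprintf("  eigenvalues: D1 = %.4f, D2 = %.4f (1e-9 m^2 s^-1)\n",
              x$d_eig1, x$d_eig2))
  if (!is.na(x$residual_rms))
    cat(sprintf("  residual RMS: %.4g\n", x$residual_rms))
  invisible(x)
}

# Internal: evaluate the two-mode profile. times in s (> 0), radius in cm,
# eigenvalues in 1e-9 m^2 s^-1.
.taylor_profile <- function(times, p, tube_radius) {
  r2 <- (tube_radius * 1e-2)^2            # cm -> m
  g <- function(d) exp(-12 * d * 1e-9 * (times - p$t_r)^2 / (r2 * times))
  p$v0 + p$v1 * times +
    p$vmax * sqrt(p$t_r / times) *
      (p$w1 * g(p$d_eig1) + (1 - p$w1) * g(p$d_eig2))
}

# Internal: run code under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards (seeds stay explicit arguments,
# never global side effects).
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Simulate a Taylor dispersion detector trace
#'
#' Evaluates the two-mode dispersion profile (see [peak_fit()]) on a uniform
#' time grid and adds independent Gaussian detector noise.
#'
#' @param fit_params A [peak_fit()] parameter set.
#' @param geometry An [instrument_geometry()]; supplies the tube radius and
#'   the sampling interval.
#' @param noise_sd Standard deviation of the additive Gaussian detector
#'   noise (voltage units), `>= 0`.
#' @param seed Optional integer seed for the noise; recorded in the trace.
#'   The caller's RNG state is left untouched.
#' @param window_halfwidth Half-width (s) of the simulated window around the
#'   retention time. Default: 8 dispersion standard deviations of the slower
#'   eigenmode, truncated so all times are positive.
#' @param injection_excess Optional `c(dC1, dC2)` injected concentration
#'   excess (mol dm^-3) carried as metadata.
#'
#' @return An object of class `"dispersion_trace"`: list with `times`,
#'   `voltages`, `geometry`, `injection_excess`, `noise_sd`, `seed`.
#' @examples
#' p <- peak_fit(0, 0, 1, 7000, 0.7, 1.0, 0.4)
#' tr <- simulate_trace(p, instrument_geometry(), noise_sd = 0)
#' @export
simulate_trace <- function(fit_params, geometry = instrument_geometry(),
                           noise_sd = 0, seed = NULL,
                           window_halfwidth = NULL,
                           injection_excess = c(NA_real_, NA_real_)) {
  stopifnot(inherits(fit_params, "peak_fit"),
            inherits(geometry, "instrument_geometry"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  p <- fit_params
  dt <- geometry$sampling_interval
  if (is.null(window_halfwidth)) {
    # dispersion sd of the slower mode: sigma^2 = r^2 t_R / (24 D)
    r2 <- (geometry$tube_radius * 1e-2)^2
    sigma <- sqrt(r2 * p$t_r / (24 * min(p$d_eig1, p$d_eig2) * 1e-9))
    window_halfwidth <- 8 * sigma
  }
  # grid aligned so the retention time itself is sampled
  n_lo <- floor(min(window_halfwidth, p$t_r - dt) / dt)
  n_hi <- floor(window_halfwidth / dt)
  times <- p$t_r + dt * seq.int(-n_lo, n_hi)
  if (any(times <= 0)) stop("time grid must be strictly positive")
  v <- .taylor_profile(times, p, geometry$tube_radius)
  if (noise_sd > 0)
    v <- v + .with_seed(seed, stats::rnorm(length(v), sd = noise_sd))
  structure(list(times = times, voltages = v, geometry = geometry,
                 injection_excess = injection_excess,
                 noise_sd = noise_sd, seed = seed),
            class = "dispersion_trace")
}

#' @export
print.dispersion_trace <- function(x, ...) {
  cat(sprintf(
    "Dispersion trace: %d points, t in [%.0f, %.0f] s, dt = %g s\n",
    length(x$times), min(x$times), max(x$times),
    x$geometry$sampling_interval))
  invisible(x)
}

# Internal: moment-based starting values for fit_trace.
.init_peak_fit <- function(trace) {
  t <- trace$times; v <- trace$voltages
  n <- length(t)
  k <- max(5L, ceiling(0.05 * n))
  edge_t <- c(t[seq_len(k)], t[seq(n - k + 1L, n)])
  edge_v <- c(v[seq_len(k)], v[seq(n - k + 1L, n)])
  base <- stats::lm.fit(cbind(1, edge_t), edge_v)$coefficients
  resid <- v - (base[1L] + base[2L] * t)
  i_max <- which.max(resid)
  t_r <- t[i_max]
  vmax <- resid[i_max]
  w <- pmax(resid, 0)
  tbar <- sum(w * t) / sum(w)
  sig2 <- sum(w * (t - tbar)^2) / sum(w)
  r2 <- (trace$geometry$tube_radius * 1e-2)^2
  d_eff <- r2 * t_r / (24 * sig2) * 1e9        # back to 1e-9 m^2/s units
  list(v0 = unname(base[1L]), v1 = unname(base[2L]), vmax = vmax, t_r = t_r,
       d_eff = max(d_eff, 1e-4))
}

#' Fit the two-mode dispersion model to a measured trace
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm()]) of
#' the two-mode Taylor dispersion profile in all seven parameters
#' (`v0, v1, vmax, t_r, w1, d_eig1, d_eig2`), with `w1` constrained to
#' `[0, 1]` and the eigenvalues positive. Starting values default to moment
#' estimates (retention time from the peak maximum, dispersion coefficient
#' from the second moment); on poor convergence a small set of perturbed
#' restarts is tried and the best fit returned. Eigenvalues are reported
#' sorted descending (see [peak_fit()]).
#'
#' @param trace A [simulate_trace()]-style `"dispersion_trace"`.
#' @param init Optional [peak_fit()] with starting values.
#' @param n_restarts Number of perturbed restarts tried beyond the moment
#'   initialisation.
#' @param ftol_rel Relative tolerance on the residual sum of squares used to
#'   declare convergence.
#'
#' @return A [peak_fit()] with `residual_rms` filled in.
#' @examples
#' p <- peak_fit(0.1, 1e-5, 1, 7000, 0.7, 1.0, 0.4)
#' fit <- fit_trace(simulate_trace(p, instrument_geometry()))
#' @export
fit_trace <- function(trace, init = NULL, n_restarts = 5, ftol_rel = 1e-12) {
  stopifnot(inherits(trace, "dispersion_trace"))
  t <- trace$times; v <- trace$voltages
  radius <- trace$geometry$tube_radius
  resid_fun <- function(par) {
    p <- list(v0 = par[1L], v1 = par[2L], vmax = par[3L], t_r = par[4L],
              w1 = par[5L], d_eig1 = par[6L], d_eig2 = par[7L])
    .taylor_profile(t, p, radius) - v
  }
  lower <- c(-Inf, -Inf, 0, min(t), 0, 1e-6, 1e-6)
  upper <- c(Inf, Inf, Inf, max(t) * 2, 1, 1e3, 1e3)
  starts <- list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "peak_fit"))
    starts[[1L]] <- c(init$v0, init$v1, init$vmax, init$t_r, init$w1,
                      init$d_eig1, init$d_eig2)
  } else {
    m <- .init_peak_fit(trace)
    splits <- list(c(2, 0.5), c(1.5, 0.75), c(4, 0.25), c(1.2, 0.9),
                   c(8, 0.125), c(1, 1.000001))
    w1s <- c(0.5, 0.5, 0.3, 0.7, 0.5, 0.5)
    for (i in seq_len(min(1 + n_restarts, length(splits))))
      starts[[i]] <- c(m$v0, m$v1, m$vmax, m$t_r, w1s[i],
                       m$d_eff * splits[[i]][1L], m$d_eff * splits[[i]][2L])
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (!is.null(best) && best$deviance <= ftol_rel * sum((v - mean(v))^2))
      break
  }
  if (is.null(best))
    stop("dispersion peak fit failed to converge after ",
         length(starts), " starts")
  par <- best$par
  peak_fit(v0 = par[1L], v1 = par[2L], vmax = par[3L], t_r = par[4L],
           w1 = par[5L], d_eig1 = par[6L], d_eig2 = par[7L],
           residual_rms = sqrt(best$deviance / length(v)))
}

#' Eigenmode weight of an injection into a ternary system
#'
#' Eigendecomposes the 2x2 diffusion matrix, propagates the injected
#' concentration excess onto the two eigenmodes, weights each mode amplitude
#' by the detector sensitivity vector `(1, sensitivity_ratio)` and by
#' `sqrt(eigenvalue)` (a Taylor peak's height scales with the square root of
#' its dispersion eigenvalue at fixed injected amount), and returns the
#' normalised weight of mode 1 (the larger eigenvalue). The two mode weights
#' sum to 1 by construction; for strongly coupled systems a weight can fall
#' outside `[0, 1]`.
#'
#' @param dmat A [dmatrix()] (or plain 2x2 matrix) with real, positive,
#'   distinct eigenvalues.
#' @param injection_excess `c(dC1, dC2)` injected concentration excess
#'   (mol dm^-3); must be nonzero.
#' @param sensitivity_ratio Detector response of component 2 relative to
#'   component 1 (refractive-index increment ratio).
#'
#' @return A list with `w1`, `eigenvalues` (sorted descending) and the raw
#'   mode `amplitudes`.
#' @examples
#' sys <- binding_system(species_diffusivities(1.050, 0.399, 0.390), 10)
#' dm <- predict_dmatrix(composition(0.0035, 0.0035), sys)
#' weights_for_injection(dm, c(0.002, 0))
#' @export
weights_for_injection <- function(dmat, injection_excess,
                                  sensitivity_ratio = 1.0) {
  m <- if (inherits(dmat, "dmatrix")) as.matrix(dmat) else {
    stopifnot(is.matrix(dmat), all(dim(dmat) == 2L)); dmat
  }
  dc <- as.numeric(injection_excess)
  stopifnot(length(dc) == 2L)
  if (all(dc == 0)) stop("injection excess must be nonzero")
  ev <- eigen(m)
  if (is.complex(ev$values))
    stop("diffusion matrix has complex eigenvalues")
  ord <- order(ev$values, decreasing = TRUE)
  lam <- ev$values[ord]
  if (any(lam <= 0)) stop("diffusion matrix eigenvalues must be positive")
  if (abs(lam[1L] - lam[2L]) <= 1e-12 * abs(lam[1L]))
    stop("equal eigenvalues: system is effectively binary; ",
         "treat as a single-mode peak")
  p <- ev$vectors[, ord, drop = FALSE]
  if (abs(det(p)) < 1e-12)
    stop("defective (non-diagonalizable) diffusion matrix")
  a <- solve(p, dc)
  s <- c(1, sensitivity_ratio)
  amp <- sqrt(lam) * as.numeric(s %*% p) * a
  tot <- sum(amp)
  if (abs(tot) < 1e-14 * max(abs(amp), 1e-300))
    stop("detector-weighted mode amplitudes cancel; w1 undefined")
  list(w1 = amp[1L] / tot, eigenvalues = lam, amplitudes = amp)
}

#' Assemble the ternary diffusion matrix from two fitted injections
#'
#' Inverse of [weights_for_injection()]: given the peak fits of two
#' injections with linearly independent concentration excesses, pools their
#' eigenvalue pairs and solves (in closed form) for the unique 2x2 matrix
#' with those eigenvalues whose spectral projector reproduces both measured
#' mode-1 weights under the detector sensitivity vector.
#'
#' @param fit1,fit2 [peak_fit()] results for the two injections (their
#'   `w1`, `d_eig1`, `d_eig2` are used), or plain lists with those fields
#'   (useful for algebraic round trips, where a weight may legitimately sit
#'   just outside `[0, 1]`).
#' @param excess1,excess2 The injected concentration excesses `c(dC1, dC2)`
#'   (mol dm^-3) of the two runs; must be linearly independent.
#' @param sensitivity_ratio Detector response of component 2 relative to
#'   component 1; must match the value in effect when the traces were
#'   recorded.
#' @param eig_rtol Maximum allowed relative disagreement between the two
#'   fits' eigenvalues before they are declared inconsistent.
#'
#' @return A [dmatrix()].
#' @examples
#' sys <- binding_system(species_diffusivities(1.050, 0.399, 0.390), 10)
#' dm <- predict_dmatrix(composition(0.0035, 0.0035), sys)
#' w1 <- weights_for_injection(dm, c(0.002, 0))
#' w2 <- weights_for_injection(dm, c(0, 0.002))
#' f1 <- peak_fit(0, 0, 1, 7000, w1$w1, w1$eigenvalues[1], w1$eigenvalues[2])
#' f2 <- peak_fit(0, 0, 1, 7000, w2$w1, w2$eigenvalues[1], w2$eigenvalues[2])
#' assemble_dmatrix(f1, f2, c(0.002, 0), c(0, 0.002))
#' @export
assemble_dmatrix <- function(fit1, fit2, excess1, excess2,
                             sensitivity_ratio = 1.0, eig_rtol = 0.05) {
  ok <- function(f) is.list(f) &&
    all(c("w1", "d_eig1", "d_eig2") %in% names(f))
  if (!ok(fit1) || !ok(fit2))
    stop("fit1 and fit2 must be peak_fit objects or lists with fields ",
         "w1, d_eig1, d_eig2")
  e1 <- as.numeric(excess1); e2 <- as.numeric(excess2)
  stopifnot(length(e1) == 2L, length(e2) == 2L)
  cmat <- rbind(e1, e2)
  if (abs(det(cmat)) <= 1e-12 * max(abs(cmat)) ^ 2)
    stop("injection excesses must be linearly independent")
  rel <- function(a, b) abs(a - b) / pmax(abs(a), abs(b))
  if (rel(fit1$d_eig1, fit2$d_eig1) > eig_rtol ||
      rel(fit1$d_eig2, fit2$d_eig2) > eig_rtol)
    stop("the two fits' eigenvalue pairs are inconsistent (relative ",
         "disagreement exceeds ", eig_rtol, ")")
  lam <- c(mean(c(fit1$d_eig1, fit2$d_eig1)),
           mean(c(fit1$d_eig2, fit2$d_eig2)))
  s <- c(1, sensitivity_ratio)
  # For each injection, w1 determines the projection g = s' M of the
  # sensitivity vector through the mode-1 spectral projector M:
  #   sqrt(l1) (g . dC) / [sqrt(l1)(g . dC) + sqrt(l2)(s . dC - g . dC)] = w1
  w <- c(fit1$w1, fit2$w1)
  denom <- sqrt(lam[1L]) * (1 - w) + sqrt(lam[2L]) * w
  h <- w * sqrt(lam[2L]) * as.numeric(cmat %*% s) / denom
  g <- solve(cmat, h)
  # Rank-1 idempotent M = [[m11, m12], [m21, 1 - m11]] with s' M = g and
  # det M = 0; the quadratic terms cancel, leaving a unique solution.
  det_gs <- s[1L] * g[2L] - s[2L] * g[1L]
  if (abs(det_gs) < 1e-12)
    stop("no unique solution: sensitivity projection is degenerate")
  m11 <- g[1L] * (g[2L] - s[2L]) / det_gs
  m12 <- (g[2L] - s[2L] + s[2L] * m11) / s[1L]
  if (abs(s[2L]) > 1e-12) {
    m21 <- (g[1L] - s[1L] * m11) / s[2L]
  } else {
    m21 <- if (abs(m12) > 1e-300) (m11 - m11^2) / m12 else 0
  }
  proj <- matrix(c(m11, m12, m21, 1 - m11), 2L, 2L, byrow = TRUE)
  d <- lam[2L] * diag(2L) + (lam[1L] - lam[2L]) * proj
  dmatrix(d[1L, 1L], d[1L, 2L], d[2L, 1L], d[2L, 2L])
}
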