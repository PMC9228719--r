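# Estimation of the association constant from diffusion-coefficient tables,
# with bootstrap uncertainty, plus solubilized-fraction and regime
# diagnostics.

.COEFS <- c("d11", "d12", "d21", "d22")
.CLASS_SD <- c(d11 = 0.02, d12 = 0.05, d21 = 0.05, d22 = 0.02)

# Internal: per-cell weighting SDs for a table. mode "class" uses the
# instrument's blanket run-to-run reproducibility (0.02 main / 0.05 cross);
# "printed" uses the per-cell SD columns where present, class values
# elsewhere.
.fit_sds <- function(df, weights) {
  sds <- matrix(rep(.CLASS_SD, each = nrow(df)), nrow(df),
                dimnames = list(NULL, .COEFS))
  if (weights == "printed") {
    for (cn in .COEFS) {
      v <- df[[paste0("sd", substring(cn, 2L))]]
      ok <- !is.na(v) & v > 0
      sds[ok, cn] <- v[ok]
    }
  }
  sds
}

# Internal: weighted SSE over a K grid (vectorised: nk x nrow forward model).
.kfit_sse <- function(k, df, sds, diff, coefficients) {
  m <- .forward_dmatrix(df$c1, df$c2, k, diff$d_free_drug,
                        diff$d_free_carrier, diff$d_complex)
  sse <- 0
  for (cn in coefficients) {
    obs <- matrix(df[[cn]], length(k), nrow(df), byrow = TRUE)
    w <- matrix(sds[, cn], length(k), nrow(df), byrow = TRUE)
    sse <- sse + rowSums(((obs - m[[cn]]) / w)^2)
  }
  sse
}

# Internal: grid-then-refine 1-D minimiser, deterministic by construction.
.kfit_minimise <- function(df, sds, diff, coefficients, k_grid) {
  sse <- .kfit_sse(k_grid, df, sds, diff, coefficients)
  i <- which.min(sse)
  lo <- k_grid[max(1L, i - 1L)]
  hi <- k_grid[min(length(k_grid), i + 1L)]
  if (lo == hi) return(list(k = k_grid[i], sse = sse[i]))
  opt <- stats::optimize(function(k)
    .kfit_sse(k, df, sds, diff, coefficients), c(lo, hi), tol = 1e-9)
  if (opt$objective <= sse[i]) list(k = opt$minimum, sse = opt$objective)
  else list(k = k_grid[i], sse = sse[i])
}

#' Fit the association constant to a diffusion-coefficient table
#'
#' Weighted least-squares estimate of the 1:1 association constant K: the
#' weighted sum over rows and coefficients of
#' `((D_obs - D_model(K)) / sigma)^2` is minimised over a dense K grid
#' followed by local refinement, which is deterministic and immune to local
#' minima in this one-dimensional problem. Species diffusivities are fixed
#' inputs (taken from the binary-limit rows of the measured tables), not
#' co-fitted.
#'
#' The default weights are the coefficient-class reproducibilities of the
#' Taylor instrument (0.02 for main, 0.05 for cross coefficients, 1e-9 m^2
#' s^-1). `weights = "printed"` instead uses the per-cell SD columns of the
#' table where available; note these repeat precisions can span two orders
#' of magnitude within a class and then a couple of cells dominate the fit
#' (see the package vignette).
#'
#' For micellar carriers (`cmc` given), only rows with `c2 >= cmc` are
#' fitted by default: below the CMC the complexing species (the micelle)
#' does not exist. Other rows are retained in the result as diagnostics.
#'
#' @param dtable Diffusion table (data.frame with the canonical columns, as
#'   from [read_dtable()] or [generate_dtable()]).
#' @param diffusivities A [species_diffusivities()] object.
#' @param cmc Critical micelle concentration (mol dm^-3) or `NULL`.
#' @param regime Rows to fit when `cmc` is given: `"above_cmc"` (default),
#'   `"below_cmc"`, or `"all"`. Ignored for `cmc = NULL`.
#' @param weights `"class"` (default) or `"printed"`; see Details.
#' @param coefficients Which of `d11, d12, d21, d22` enter the objective.
#' @param k_grid Grid of candidate K values (mol^-1 dm^3).
#' @param n_boot Number of bootstrap replicates for the 95% confidence
#'   interval (0 to skip).
#' @param seed Seed for the bootstrap resampling.
#'
#' @return An object of class `"kfit"`: list with `k_hat`, `k_ci`,
#'   `weighted_sse`, `residuals` (per fitted row and coefficient, observed
#'   minus model), `rows_used` (logical), `regime` (per-row labels), and the
#'   fit settings.
#' @examples
#' tab <- read_dtable(ternadiff_extdata("beta_cd_table2.csv"))
#' sp <- species_diffusivities(1.050, 0.399, 0.390, 1.168)
#' fit_k(tab, sp, n_boot = 0)
#' @export
fit_k <- function(dtable, diffusivities, cmc = NULL,
                  regime = c("above_cmc", "all", "below_cmc"),
                  weights = c("class", "printed"),
                  coefficients = c("d11", "d12", "d21", "d22"),
                  k_grid = seq(0, 500, by = 0.1),
                  n_boot = 200, seed = 1L) {
  df <- .validate_dtable(as.data.frame(dtable), check_x1 = FALSE)
  stopifnot(inherits(diffusivities, "species_diffusivities"))
  regime <- match.arg(regime)
  weights <- match.arg(weights)
  coefficients <- match.arg(coefficients, .COEFS, several.ok = TRUE)
  labels <- vapply(seq_len(nrow(df)), function(i)
    classify_regime(composition(df$c1[i], df$c2[i]), cmc), character(1L))
  used <- if (is.null(cmc) || regime == "all") rep(TRUE, nrow(df))
          else labels == regime
  if (sum(used) < 2L)
    stop("need at least 2 rows after regime filtering (have ", sum(used), ")")
  fit_df <- df[used, , drop = FALSE]
  sds <- .fit_sds(fit_df, weights)
  if (all(sds[, coefficients] == 0)) stop("all weights are zero")
  best <- .kfit_minimise(fit_df, sds, diffusivities, coefficients, k_grid)
  mod <- .forward_dmatrix(fit_df$c1, fit_df$c2, best$k,
                          diffusivities$d_free_drug,
                          diffusivities$d_free_carrier,
                          diffusivities$d_complex)
  resid <- sapply(.COEFS, function(cn) fit_df[[cn]] - mod[[cn]][1L, ])
  resid <- matrix(resid, nrow(fit_df), 4L, dimnames = list(NULL, .COEFS))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0)
    ci <- bootstrap_k_ci(dtable, diffusivities, cmc = cmc, regime = regime,
                         weights = weights, coefficients = coefficients,
                         k_grid = k_grid, n_boot = n_boot, seed = seed)
  structure(list(k_hat = best$k, k_ci = ci, weighted_sse = best$sse,
                 residuals = resid, rows_used = used, regime = labels,
                 coefficients = coefficients, weights = weights,
                 diffusivities = diffusivities, cmc = cmc,
                 k_grid = k_grid),
            class = "kfit")
}

#' @export
print.kfit <- function(x, ...) {
  cat(sprintf("Association constant fit: K = %.3f mol^-1 dm^3\n", x$k_hat))
  if (!any(is.na(x$k_ci)))
    cat(sprintf("  bootstrap 95%% CI: [%.3f, %.3f]\n", x$k_ci[1L], x$k_ci[2L]))
  cat(sprintf("  weighted SSE: %.4g over %d rows (%s; coefficients: %s)\n",
              x$weighted_sse, sum(x$rows_used), x$weights,
              paste(x$coefficients, collapse = ", ")))
  invisible(x)
}

#' Bootstrap confidence interval for the association constant
#'
#' Residual-resampling bootstrap: residuals of the point fit are resampled
#' with replacement within coefficient class (main coefficients together,
#' cross coefficients together), added back onto the fitted model table, and
#' K refitted; the percentile 95% interval of the replicate estimates is
#' returned. Deterministic given `seed`. If every residual is zero (a
#' noiseless table) the interval has zero width and a warning is issued.
#'
#' @inheritParams fit_k
#' @param n_boot Number of bootstrap replicates (`>= 100`).
#' @return Numeric `c(lower, upper)` 95% interval (mol^-1 dm^3).
#' @examples
#' tab <- read_dtable(ternadiff_extdata("beta_cd_table2.csv"))
#' sp <- species_diffusivities(1.050, 0.399, 0.390, 1.168)
#' bootstrap_k_ci(tab, sp, n_boot = 100, seed = 42)
#' @export
bootstrap_k_ci <- function(dtable, diffusivities, cmc = NULL,
                           regime = c("above_cmc", "all", "below_cmc"),
                           weights = c("class", "printed"),
                           coefficients = c("d11", "d12", "d21", "d22"),
                           k_grid = seq(0, 500, by = 0.1),
                           n_boot = 1000, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  regime <- match.arg(regime)
  weights <- match.arg(weights)
  fit <- fit_k(dtable, diffusivities, cmc = cmc, regime = regime,
               weights = weights, coefficients = coefficients,
               k_grid = k_grid, n_boot = 0)
  df <- .validate_dtable(as.data.frame(dtable), check_x1 = FALSE)
  fit_df <- df[fit$rows_used, , drop = FALSE]
  sds <- .fit_sds(fit_df, weights)
  resid <- fit$residuals
  mod <- sapply(.COEFS, function(cn) fit_df[[cn]]) - resid
  mod <- matrix(mod, nrow(fit_df), 4L, dimnames = list(NULL, .COEFS))
  main <- as.vector(resid[, c("d11", "d22")])
  cross <- as.vector(resid[, c("d12", "d21")])
  if (all(abs(resid) < 1e-14)) {
    warning("all residuals are zero: bootstrap interval has zero width")
    return(c(fit$k_hat, fit$k_hat))
  }
  ks <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bdf <- fit_df
      for (cn in c("d11", "d22"))
        bdf[[cn]] <- mod[, cn] + sample(main, nrow(bdf), replace = TRUE)
      for (cn in c("d12", "d21"))
        bdf[[cn]] <- mod[, cn] + sample(cross, nrow(bdf), replace = TRUE)
      .kfit_minimise(bdf, sds, diffusivities, fit$coefficients, k_grid)$k
    }, numeric(1L))
  })
  unname(stats::quantile(ks, c(0.025, 0.975), type = 7))
}

#' Solubilized (complexed) fraction from tracer diffusion attenuation
#'
#' In the fast-exchange two-state picture the drug's tracer diffusion
#' coefficient is the population average of the free and complexed species,
#' `D11 = (1 - s) D0 + s Dc`, so the solubilized fraction is
#' `s = (D0 - D11) / (D0 - Dc)`. The result is clipped to `[0, 1]` with a
#' warning if the inputs fall outside the two-state range. The fraction is
#' invariant under a common rescaling of all three diffusivities.
#'
#' @param d11_tracer Measured tracer diffusion coefficient of the drug in
#'   carrier solution (1e-9 m^2 s^-1).
#' @param d0_drug Drug diffusivity at infinite dilution (1e-9 m^2 s^-1).
#' @param d_complex Diffusivity of the complex (or micelle)
#'   (1e-9 m^2 s^-1); must be `< d0_drug`.
#' @param comp Optional [composition()] carried in the result.
#'
#' @return An object of class `"solubilization"`: list with `s`,
#'   `deviation_percent` (`100 (D0 - D11) / D0`), the inputs, and `comp`.
#' @examples
#' solubilized_fraction(1.001, 1.168, 0.100)  # s = 0.156
#' @export
solubilized_fraction <- function(d11_tracer, d0_drug, d_complex,
                                 comp = NULL) {
  stopifnot(is.numeric(d11_tracer), is.numeric(d0_drug),
            is.numeric(d_complex))
  if (d0_drug <= d_complex)
    stop("d0_drug must exceed d_complex (free drug diffuses faster than ",
         "the complex)")
  s <- (d0_drug - d11_tracer) / (d0_drug - d_complex)
  if (s < 0 || s > 1) {
    warning("solubilized fraction ", signif(s, 4), " outside [0, 1]; clipped")
    s <- min(max(s, 0), 1)
  }
  structure(list(s = s,
                 deviation_percent = deviation_percent(d11_tracer, d0_drug),
                 d11_tracer = d11_tracer, d0_drug = d0_drug,
                 d_complex = d_complex, comp = comp),
            class = "solubilization")
}

#' @export
print.solubilization <- function(x, ...) {
  cat(sprintf(
    "Solubilized fraction s = %.3f (tracer D attenuated %.1f%% below D0)\n",
    x$s, x$deviation_percent))
  invisible(x)
}

#' Equilibrium-bound fraction of the drug
#'
#' The fraction of drug bound at equilibrium in the tracer limit (vanishing
#' drug concentration): `K c2 / (1 + K c2)`. This is the speciation-based
#' counterpart of [solubilized_fraction()]; the two agree when the binding
#' model, the measured tracer diffusivity, and the species diffusivities are
#' mutually consistent.
#'
#' @param c2 Free carrier concentration (mol dm^-3), `>= 0`.
#' @param k_assoc Association constant (mol^-1 dm^3), `>= 0`.
#' @return The bound fraction in `[0, 1)`.
#' @examples
#' bound_fraction_equilibrium(0.010, 10)  # 0.0909
#' @export
bound_fraction_equilibrium <- function(c2, k_assoc) {
  if (any(c2 < 0) || any(k_assoc < 0))
    stop("c2 and k_assoc must be non-negative")
  k_assoc * c2 / (1 + k_assoc * c2)
}

#' Percent deviation of a tracer diffusivity from the infinite-dilution value
#'
#' `100 (D0 - D11) / D0`: how far the drug's tracer diffusion coefficient in
#' carrier solution falls below its infinite-dilution value, the raw signal
#' of solubilization.
#'
#' @inheritParams solubilized_fraction
#' @return Percent deviation (positive when the tracer is slowed down).
#' @examples
#' deviation_percent(0.965, 1.168)  # 17.4
#' @export
deviation_percent <- function(d11_tracer, d0_drug) {
  if (any(d11_tracer <= 0) || any(d0_drug <= 0))
    stop("diffusivities must be positive")
  100 * (d0_drug - d11_tracer) / d0_drug
}

#' Classify the surfactant concentration regime of a composition
#'
#' @param comp A [composition()] object.
#' @param cmc Critical micelle concentration (mol dm^-3), or `NULL` for a
#'   non-micellar carrier.
#' @return `"below_cmc"` if `c2 < cmc`, `"above_cmc"` if `c2 >= cmc`
#'   (boundary assigned above by convention), `"non_micellar"` when `cmc`
#'   is `NULL`.
#' @examples
#' classify_regime(composition(0, 0.004), cmc = 0.0083)
#' @export
classify_regime <- function(comp, cmc = NULL) {
  stopifnot(inherits(comp, "composition"))
  if (is.null(cmc)) return("non_micellar")
  if (!is.numeric(cmc) || length(cmc) != 1L || cmc <= 0)
    stop("cmc must be a single positive number or NULL")
  if (comp$c2 < cmc) "below_cmc" else "above_cmc"
}
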