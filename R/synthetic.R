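# Synthetic experiments with the statistical structure the analysis assumes:
# noisy diffusion-coefficient tables from the forward model, and noisy
# detector traces from the instrument model. The defaults emulate the
# measured design: the composition grid of the published beta-CD table and
# the instrument's blanket reproducibilities (0.02 main / 0.05 cross, 1e-9
# m^2 s^-1) as homoscedastic per-class noise.

#' Design of a synthetic ternary diffusion experiment
#'
#' @param compositions List of [composition()] objects (default: the
#'   seven-composition grid of the packaged beta-CD table, so synthetic
#'   recovery experiments share the real design's conditioning).
#' @param true_system The generating [binding_system()].
#' @param noise_main Gaussian SD for the main coefficients d11, d22
#'   (1e-9 m^2 s^-1).
#' @param noise_cross Gaussian SD for the cross coefficients d12, d21.
#' @param seed Integer seed recorded in the design and used by the
#'   generators.
#'
#' @return An object of class `"synthetic_design"`.
#' @examples
#' sys <- binding_system(
#'   species_diffusivities(1.050, 0.399, 0.390, 1.168), 10)
#' synthetic_design(true_system = sys, seed = 7)
#' @export
synthetic_design <- function(compositions = NULL, true_system,
                             noise_main = 0.02, noise_cross = 0.05,
                             seed = 1L) {
  stopifnot(inherits(true_system, "binding_system"))
  if (is.null(compositions)) {
    grid <- list(c(0, 0.007), c(0.0035, 0.0035), c(0.007, 0),
                 c(0, 0.010), c(0.012, 0.008), c(0.018, 0.002), c(0.020, 0))
    compositions <- lapply(grid, function(g) composition(g[1L], g[2L]))
  }
  if (!length(compositions) ||
      !all(vapply(compositions, inherits, logical(1L), "composition")))
    stop("compositions must be a non-empty list of composition objects")
  if (noise_main < 0 || noise_cross < 0) stop("noise SDs must be >= 0")
  structure(list(compositions = compositions, true_system = true_system,
                 noise_main = noise_main, noise_cross = noise_cross,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Generate a synthetic diffusion-coefficient table
#'
#' For each composition in the design, evaluates the forward model
#' [predict_dmatrix()] and adds independent Gaussian noise per cell with the
#' class SDs (main / cross). The SD columns of the output are filled with
#' the class SDs. Deterministic given the design seed.
#'
#' @param design A [synthetic_design()].
#' @return A diffusion table (`"dtable"` data.frame with the canonical
#'   columns) with attribute `"seed"`.
#' @examples
#' sys <- binding_system(
#'   species_diffusivities(1.050, 0.399, 0.390, 1.168), 10)
#' generate_dtable(synthetic_design(true_system = sys, seed = 7))
#' @export
generate_dtable <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  rows <- lapply(design$compositions, function(cp) {
    dm <- predict_dmatrix(cp, design$true_system)
    data.frame(c1 = cp$c1, c2 = cp$c2, x1 = cp$x1,
               d11 = dm$d11, sd11 = design$noise_main,
               d12 = dm$d12, sd12 = design$noise_cross,
               d21 = dm$d21, sd21 = design$noise_cross,
               d22 = dm$d22, sd22 = design$noise_main)
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  noise <- .with_seed(design$seed, list(
    d11 = stats::rnorm(n, 0, design$noise_main),
    d12 = stats::rnorm(n, 0, design$noise_cross),
    d21 = stats::rnorm(n, 0, design$noise_cross),
    d22 = stats::rnorm(n, 0, design$noise_main)))
  for (cn in names(noise)) df[[cn]] <- df[[cn]] + noise[[cn]]
  class(df) <- c("dtable", "data.frame")
  attr(df, "seed") <- design$seed
  df
}

#' Generate paired synthetic dispersion traces for a design
#'
#' For each composition, computes the model diffusion matrix, its
#' eigenvalues, and the eigenmode weight of each of two injections via
#' [weights_for_injection()], then synthesises the two detector traces with
#' [simulate_trace()]. The default excesses are drug-rich and carrier-rich
#' mixtures (not pure single-component pulses): for coupled systems a pure
#' carrier pulse carries a small *negative* drug-mode amplitude, which the
#' two-mode profile with weights pinned to `[0, 1]` cannot represent, while
#' the mixed pulses keep both mode weights interior.
#' The full pipeline [fit_trace()] -> [assemble_dmatrix()] -> [fit_k()]
#' applied to noiseless output recovers the generating K.
#'
#' @param design A [synthetic_design()].
#' @param geometry An [instrument_geometry()].
#' @param sensitivity_ratio Detector response of component 2 relative to
#'   component 1.
#' @param noise_sd Detector noise SD (voltage units).
#' @param excesses List of two linearly independent injection excess vectors
#'   `c(dC1, dC2)` (mol dm^-3).
#' @param seed Seed for the detector noise (default: the design seed).
#'
#' @return A list with one element per composition: list of `composition`,
#'   `dmatrix` (the model matrix), and `traces` (two `"dispersion_trace"`
#'   objects carrying their injection excesses).
#' @examples
#' sys <- binding_system(
#'   species_diffusivities(1.050, 0.399, 0.390, 1.168), 10)
#' des <- synthetic_design(list(composition(0.0035, 0.0035)), sys, seed = 1)
#' ts <- generate_trace_set(des)
#' @export
generate_trace_set <- function(design, geometry = instrument_geometry(),
                               sensitivity_ratio = 1.0, noise_sd = 0,
                               excesses = list(c(0.002, 0.0005),
                                               c(0.0005, 0.002)),
                               seed = NULL) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(geometry, "instrument_geometry"))
  if (length(excesses) != 2L)
    stop("exactly two injection excesses are required")
  e1 <- as.numeric(excesses[[1L]]); e2 <- as.numeric(excesses[[2L]])
  if (abs(e1[1L] * e2[2L] - e1[2L] * e2[1L]) <= 1e-15)
    stop("injection excesses must be linearly independent")
  if (is.null(seed)) seed <- design$seed
  out <- vector("list", length(design$compositions))
  for (i in seq_along(design$compositions)) {
    cp <- design$compositions[[i]]
    dm <- predict_dmatrix(cp, design$true_system)
    traces <- vector("list", 2L)
    for (j in 1:2) {
      exc <- excesses[[j]]
      wt <- weights_for_injection(dm, exc, sensitivity_ratio)
      if (wt$w1 < 0 || wt$w1 > 1)
        stop("injection excess ", paste(exc, collapse = "/"),
             " yields a mode weight outside [0, 1] (", signif(wt$w1, 4),
             "); choose excesses that keep both mode amplitudes positive")
      p <- peak_fit(v0 = 0, v1 = 0, vmax = 1,
                    t_r = geometry$retention_time_nominal, w1 = wt$w1,
                    d_eig1 = wt$eigenvalues[1L], d_eig2 = wt$eigenvalues[2L])
      traces[[j]] <- simulate_trace(p, geometry, noise_sd = noise_sd,
                                    seed = seed + 1000L * i + j,
                                    injection_excess = exc)
    }
    out[[i]] <- list(composition = cp, dmatrix = dm, traces = traces)
  }
  attr(out, "seed") <- seed
  attr(out, "sensitivity_ratio") <- sensitivity_ratio
  out
}
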