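# S3 containers for the quantities the analysis passes around.
#
# Unit conventions (fixed throughout the package, matching the printed tables
# the methods operate on): diffusivities in 1e-9 m^2 s^-1, concentrations in
# mol dm^-3, association constants in mol^-1 dm^3, instrument geometry in cm.

#' Species limiting diffusivities
#'
#' Bundle of the limiting diffusion coefficients of the three species present
#' in a 1:1 host-guest system: the free drug (guest), the free carrier (host,
#' e.g. a cyclodextrin or a micelle), and the complex. Optionally carries the
#' drug's infinite-dilution diffusivity, used by the solubilized-fraction and
#' deviation diagnostics.
#'
#' @param d_free_drug Diffusivity of the free drug (1e-9 m^2 s^-1).
#' @param d_free_carrier Diffusivity of the free carrier (1e-9 m^2 s^-1).
#' @param d_complex Diffusivity of the 1:1 complex (1e-9 m^2 s^-1). The
#'   complex is larger than either partner, so its diffusivity must not
#'   exceed `min(d_free_drug, d_free_carrier)` (small tolerance allowed).
#' @param d_drug_infinite_dilution Optional infinite-dilution diffusivity of
#'   the drug (1e-9 m^2 s^-1); must be at least `d_free_drug` up to
#'   tolerance.
#' @param tol Tolerance for the ordering checks.
#'
#' @return An object of class `"species_diffusivities"`.
#' @examples
#' species_diffusivities(1.050, 0.399, 0.390, d_drug_infinite_dilution = 1.168)
#' @export
species_diffusivities <- function(d_free_drug, d_free_carrier, d_complex,
                                  d_drug_infinite_dilution = NA_real_,
                                  tol = 1e-6) {
  stopifnot(is.numeric(d_free_drug), length(d_free_drug) == 1L,
            is.numeric(d_free_carrier), length(d_free_carrier) == 1L,
            is.numeric(d_complex), length(d_complex) == 1L)
  if (d_free_drug <= 0 || d_free_carrier <= 0 || d_complex <= 0)
    stop("all species diffusivities must be strictly positive")
  if (d_complex > min(d_free_drug, d_free_carrier) + tol)
    stop("d_complex must not exceed min(d_free_drug, d_free_carrier): ",
         "the complex is the largest, slowest species")
  if (!is.na(d_drug_infinite_dilution)) {
    if (d_drug_infinite_dilution <= 0)
      stop("d_drug_infinite_dilution must be strictly positive")
    if (d_drug_infinite_dilution < d_free_drug - tol)
      stop("d_drug_infinite_dilution must be >= d_free_drug (finite ",
           "concentration can only slow the drug down)")
  }
  structure(list(d_free_drug = as.numeric(d_free_drug),
                 d_free_carrier = as.numeric(d_free_carrier),
                 d_complex = as.numeric(d_complex),
                 d_drug_infinite_dilution = as.numeric(d_drug_infinite_dilution)),
            class = "species_diffusivities")
}

#' @export
print.species_diffusivities <- function(x, ...) {
  cat("Species limiting diffusivities (1e-9 m^2 s^-1)\n")
  cat(sprintf("  free drug    : %.3f\n", x$d_free_drug))
  cat(sprintf("  free carrier : %.3f\n", x$d_free_carrier))
  cat(sprintf("  complex      : %.3f\n", x$d_complex))
  if (!is.na(x$d_drug_infinite_dilution))
    cat(sprintf("  drug at infinite dilution: %.3f\n",
                x$d_drug_infinite_dilution))
  invisible(x)
}

#' Host-guest binding system
#'
#' A 1:1 binding system: the species diffusivities, the association constant,
#' and (for micellar carriers) the critical micelle concentration.
#'
#' @param diffusivities A [species_diffusivities()] object.
#' @param k_assoc Association constant K (mol^-1 dm^3), `>= 0`.
#' @param cmc Critical micelle concentration (mol dm^-3) for surfactant
#'   carriers, or `NULL` for non-micellar carriers such as cyclodextrins.
#'
#' @return An object of class `"binding_system"`.
#' @examples
#' sys <- binding_system(
#'   species_diffusivities(1.050, 0.399, 0.390, 1.168), k_assoc = 10)
#' @export
binding_system <- function(diffusivities, k_assoc, cmc = NULL) {
  stopifnot(inherits(diffusivities, "species_diffusivities"))
  if (!is.numeric(k_assoc) || length(k_assoc) != 1L || k_assoc < 0)
    stop("k_assoc must be a single non-negative number")
  if (!is.null(cmc)) {
    if (!is.numeric(cmc) || length(cmc) != 1L || cmc <= 0)
      stop("cmc must be a single positive number (or NULL)")
    cmc <- as.numeric(cmc)
  }
  structure(list(diffusivities = diffusivities,
                 k_assoc = as.numeric(k_assoc),
                 stoichiometry = c(1L, 1L),
                 cmc = cmc),
            class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("1:1 host-guest binding system\n")
  cat(sprintf("  K = %.3g mol^-1 dm^3\n", x$k_assoc))
  if (!is.null(x$cmc))
    cat(sprintf("  micellar carrier, CMC = %.4g mol dm^-3\n", x$cmc))
  print(x$diffusivities)
  invisible(x)
}

#' Solute composition of a ternary solution
#'
#' Total (analytical) concentrations of the two solute components: drug
#' (component 1) and carrier (component 2). The drug solute mole fraction
#' `x1 = c1 / (c1 + c2)` is derived.
#'
#' @param c1 Total drug concentration (mol dm^-3), `>= 0`.
#' @param c2 Total carrier concentration (mol dm^-3), `>= 0`.
#'
#' @return An object of class `"composition"` with fields `c1`, `c2`, `x1`.
#' @examples
#' composition(0.0035, 0.0035)
#' @export
composition <- function(c1, c2) {
  stopifnot(is.numeric(c1), length(c1) == 1L, is.numeric(c2),
            length(c2) == 1L)
  if (is.na(c1) || is.na(c2) || c1 < 0 || c2 < 0)
    stop("concentrations must be non-negative")
  if (c1 + c2 <= 0)
    stop("at least one solute must be present (c1 + c2 > 0)")
  structure(list(c1 = as.numeric(c1), c2 = as.numeric(c2),
                 x1 = c1 / (c1 + c2)),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("Composition: c1 = %.4g, c2 = %.4g mol dm^-3 (x1 = %.3f)\n",
              x$c1, x$c2, x$x1))
  invisible(x)
}

#' Ternary mutual diffusion coefficient matrix
#'
#' The 2x2 matrix of mutual diffusion coefficients for the two total solute
#' components, optionally with per-cell standard deviations. The main
#' coefficients must be positive and the eigenvalues of the matrix real and
#' positive (a physically valid diffusion matrix).
#'
#' @param d11,d12,d21,d22 Mutual diffusion coefficients (1e-9 m^2 s^-1).
#' @param sd11,sd12,sd21,sd22 Optional standard deviations (same units).
#'
#' @return An object of class `"dmatrix"`.
#' @examples
#' dmatrix(1.011, 0.013, -0.030, 0.399)
#' @export
dmatrix <- function(d11, d12, d21, d22,
                    sd11 = NA_real_, sd12 = NA_real_,
                    sd21 = NA_real_, sd22 = NA_real_) {
  d <- c(d11 = d11, d12 = d12, d21 = d21, d22 = d22)
  if (any(!is.finite(d))) stop("diffusion coefficients must be finite")
  if (d[["d11"]] <= 0 || d[["d22"]] <= 0)
    stop("main diffusion coefficients d11, d22 must be positive")
  ev <- eigen(matrix(d, 2L, 2L, byrow = TRUE), only.values = TRUE)$values
  if (is.complex(ev) || any(ev <= 0))
    stop("diffusion matrix must have real positive eigenvalues")
  sds <- c(sd11 = sd11, sd12 = sd12, sd21 = sd21, sd22 = sd22)
  if (any(!is.na(sds) & sds < 0)) stop("standard deviations must be >= 0")
  structure(c(as.list(d), as.list(sds)), class = "dmatrix")
}

#' Convert a diffusion-coefficient object to a 2x2 base matrix
#'
#' @param x A `"dmatrix"` object.
#' @param ... Unused.
#' @return A numeric 2x2 matrix (rows: components; no standard deviations).
#' @export
as.matrix.dmatrix <- function(x, ...) {
  matrix(c(x$d11, x$d12, x$d21, x$d22), 2L, 2L, byrow = TRUE,
         dimnames = list(c("drug", "carrier"), c("grad_drug", "grad_carrier")))
}

#' @export
print.dmatrix <- function(x, ...) {
  cat("Ternary diffusion matrix (1e-9 m^2 s^-1)\n")
  fmt <- function(v, s) if (is.na(s)) sprintf("%8.4f", v) else
    sprintf("%8.4f ± %.3f", v, s)
  cat("  D11:", fmt(x$d11, x$sd11), "  D12:", fmt(x$d12, x$sd12), "\n")
  cat("  D21:", fmt(x$d21, x$sd21), "  D22:", fmt(x$d22, x$sd22), "\n")
  invisible(x)
}

# Internal: validate a diffusion-coefficient table (data.frame with the
# canonical columns) and recompute x1. Used by read_dtable and the fitters.
.validate_dtable <- function(df, check_x1 = TRUE, x1_tol = 1e-3) {
  need <- c("c1", "c2", "x1", "d11", "sd11", "d12", "sd12",
            "d21", "sd21", "d22", "sd22")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("diffusion table is missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  for (cn in need) {
    if (is.logical(df[[cn]]) && all(is.na(df[[cn]])))
      df[[cn]] <- as.numeric(df[[cn]])   # all-NA SD columns
    bad <- which(!is.na(df[[cn]]) & !is.finite(df[[cn]]))
    if (!is.numeric(df[[cn]]))
      stop("column '", cn, "' is not numeric")
    if (length(bad))
      stop("non-finite value in column '", cn, "' at row ", bad[1L])
  }
  bad <- which(df$c1 < 0 | df$c2 < 0 | (df$c1 + df$c2) <= 0)
  if (length(bad))
    stop("invalid concentrations at row ", bad[1L],
         " (need c1 >= 0, c2 >= 0, c1 + c2 > 0)")
  x1 <- df$c1 / (df$c1 + df$c2)
  if (check_x1 && any(!is.na(df$x1))) {
    bad <- which(abs(df$x1 - x1) > x1_tol)
    if (length(bad))
      stop("x1 at row ", bad[1L], " (", df$x1[bad[1L]],
           ") disagrees with c1/(c1+c2) = ", signif(x1[bad[1L]], 6))
  }
  df$x1 <- x1
  class(df) <- c("dtable", "data.frame")
  df
}
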