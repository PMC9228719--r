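# Equilibrium speciation and the coupled-diffusion forward model.
#
# The model: guest (drug, component 1) and host (carrier, component 2) form a
# 1:1 complex with association constant K. Writing the fluxes of the three
# actual species (free drug, free carrier, complex) with the cross terms
# between complex and free species neglected (dilute solutions), and fast
# local equilibrium, the measurable 2x2 mutual-diffusion matrix of the two
# *total* components is an explicit function of K, the composition, and the
# three species diffusivities.

#' Solve the 1:1 complexation equilibrium
#'
#' Computes the speciation (free drug, free carrier, complex) of a solution
#' with total concentrations `c1`, `c2` and association constant `k_assoc`,
#' i.e. the non-negative root of
#' `K (c1 - x)(c2 - x) = x` for the complex concentration `x`.
#'
#' The root is evaluated in the subtraction-free ("citardauq") form
#' `x = 2 K c1 c2 / (B + sqrt(B^2 - 4 K^2 c1 c2))` with
#' `B = 1 + K (c1 + c2)`, which is numerically stable when `K * c` products
#' are small.
#'
#' @param comp A [composition()] object (or a single `c(c1, c2)` pair).
#' @param k_assoc Association constant (mol^-1 dm^3), `>= 0`.
#'
#' @return An object of class `"speciation"`: a list with fields
#'   `free_drug`, `free_carrier`, `complex` (mol dm^-3).
#' @examples
#' solve_equilibrium(composition(0.0035, 0.0035), k_assoc = 10)
#' @export
solve_equilibrium <- function(comp, k_assoc) {
  if (!inherits(comp, "composition")) {
    stopifnot(is.numeric(comp), length(comp) == 2L)
    comp <- composition(comp[1L], comp[2L])
  }
  if (!is.numeric(k_assoc) || length(k_assoc) != 1L || is.na(k_assoc) ||
      k_assoc < 0)
    stop("k_assoc must be a single non-negative number")
  c1 <- comp$c1; c2 <- comp$c2; k <- k_assoc
  b <- 1 + k * (c1 + c2)
  disc <- b * b - 4 * k * k * c1 * c2
  x <- 2 * k * c1 * c2 / (b + sqrt(disc))
  structure(list(free_drug = c1 - x, free_carrier = c2 - x, complex = x),
            class = "speciation")
}

#' @export
print.speciation <- function(x, ...) {
  cat(sprintf(
    "Speciation (mol dm^-3): free drug %.6g, free carrier %.6g, complex %.6g\n",
    x$free_drug, x$free_carrier, x$complex))
  invisible(x)
}

#' Equilibrium coupling factor R
#'
#' The dimensionless factor
#' `R = 1 / sqrt((1 + K (c2 - c1))^2 + 4 K c1)`
#' that carries the composition dependence of the coupled-diffusion model.
#' `R = 1` when `K = 0` and `R` lies in `(0, 1]` for all admissible inputs
#' (algebraically, `R >= 1 / (1 + K (c1 + c2))`).
#'
#' @inheritParams solve_equilibrium
#' @return A single number in `(0, 1]`.
#' @examples
#' r_factor(composition(0.0035, 0.0035), 10)  # (1.14)^(-1/2)
#' @export
r_factor <- function(comp, k_assoc) {
  if (!inherits(comp, "composition")) {
    stopifnot(is.numeric(comp), length(comp) == 2L)
    comp <- composition(comp[1L], comp[2L])
  }
  if (!is.numeric(k_assoc) || length(k_assoc) != 1L || is.na(k_assoc) ||
      k_assoc < 0)
    stop("k_assoc must be a single non-negative number")
  b <- 1 + k_assoc * (comp$c2 - comp$c1)
  (b * b + 4 * k_assoc * comp$c1)^(-0.5)
}

# Internal vectorised forward model. c1, c2 are row vectors; k may be a
# vector (grid); returns list of nk x nrow matrices d11, d12, d21, d22.
# This is the workhorse of both predict_dmatrix and the K-grid fitter.
.forward_dmatrix <- function(c1, c2, k, df, dcar, dc) {
  delta <- outer(k, c2 - c1)          # K (c2 - c1), nk x nrow
  kc1 <- outer(k, c1)
  r <- ((1 + delta)^2 + 4 * kc1)^(-0.5)
  fac <- (1 - delta) * r
  list(d11 = 0.5 * ((df + dc) + (df - dc) * fac),
       d12 = 0.5 * ((dc - df) + (df - dc) * fac),
       d21 = 0.5 * ((dc - dcar) + (dcar - dc) * fac),
       d22 = 0.5 * ((dcar + dc) + (dcar - dc) * fac))
}

#' Predict the ternary diffusion matrix from the binding model
#'
#' Forward model mapping (composition, association constant, species
#' diffusivities) to the 2x2 mutual diffusion coefficient matrix of the
#' total solute components:
#'
#' \deqn{D_{11} = \tfrac12 [(D_g + D_x) + (D_g - D_x)(1 - K(c_2-c_1)) R]}
#' \deqn{D_{12} = \tfrac12 [(D_x - D_g) + (D_g - D_x)(1 - K(c_2-c_1)) R]}
#' \deqn{D_{21} = \tfrac12 [(D_x - D_h) + (D_h - D_x)(1 - K(c_2-c_1)) R]}
#' \deqn{D_{22} = \tfrac12 [(D_h + D_x) + (D_h - D_x)(1 - K(c_2-c_1)) R]}
#'
#' with \eqn{D_g, D_h, D_x} the free-drug, free-carrier and complex
#' diffusivities and \eqn{R} as in [r_factor()]. At `K = 0` the matrix is
#' exactly diagonal; in the tracer limit `c1 = 0` the drug main coefficient
#' is the fast-exchange average
#' `(D_g + K c2 D_x) / (1 + K c2)`.
#'
#' @param comp A [composition()] object.
#' @param sys A [binding_system()] object.
#' @return A [dmatrix()] object (no standard deviations).
#' @examples
#' sys <- binding_system(species_diffusivities(1.050, 0.399, 0.390), 10)
#' predict_dmatrix(composition(0.0035, 0.0035), sys)
#' @export
predict_dmatrix <- function(comp, sys) {
  stopifnot(inherits(comp, "composition"), inherits(sys, "binding_system"))
  d <- sys$diffusivities
  m <- .forward_dmatrix(comp$c1, comp$c2, sys$k_assoc,
                        d$d_free_drug, d$d_free_carrier, d$d_complex)
  dmatrix(m$d11[1L], m$d12[1L], m$d21[1L], m$d22[1L])
}

#' Stokes-Einstein estimate of the complex diffusivity
#'
#' Estimates the diffusivity of a 1:1 complex from its partners' free-species
#' diffusivities by hydrodynamic volume additivity: with radii
#' `r_i` proportional to `1 / D_i` (Stokes-Einstein) and the complex volume
#' taken as the sum of the partner volumes,
#' `D_complex = (D_1^-3 + D_2^-3)^(-1/3)`.
#' The estimate is symmetric in its arguments and strictly smaller than
#' either input.
#'
#' @param d_free_drug,d_free_carrier Free-species diffusivities
#'   (1e-9 m^2 s^-1), both `> 0`.
#' @return The estimated complex diffusivity (1e-9 m^2 s^-1).
#' @examples
#' complex_diffusivity_stokes_einstein(1.050, 0.399)  # ~0.392
#' @export
complex_diffusivity_stokes_einstein <- function(d_free_drug, d_free_carrier) {
  stopifnot(is.numeric(d_free_drug), length(d_free_drug) == 1L,
            is.numeric(d_free_carrier), length(d_free_carrier) == 1L)
  if (is.na(d_free_drug) || is.na(d_free_carrier) ||
      d_free_drug <= 0 || d_free_carrier <= 0)
    stop("free-species diffusivities must be strictly positive")
  (d_free_drug^-3 + d_free_carrier^-3)^(-1 / 3)
}

#' Counter-transport ratios from a diffusion-coefficient table
#'
#' For each row of a ternary diffusion table, `|D12| / D22` is the number of
#' moles of drug transported per mole of carrier through the coupled flux,
#' and `|D21| / D11` the moles of carrier per mole of drug. The reported
#' maxima are restricted to rows where the corresponding cross coefficient
#' is negative (counter-current transport); rows with positive cross terms
#' are still present in the per-row output.
#'
#' @param dtable A diffusion table: a data.frame with columns
#'   `c1, c2, x1, d11, sd11, d12, sd12, d21, sd21, d22, sd22` (as returned by
#'   [read_dtable()] or [generate_dtable()]).
#' @return A list with `max_drug_per_carrier` (max `|D12|/D22` over
#'   negative-`D12` rows), `max_carrier_per_drug` (max `|D21|/D11` over
#'   negative-`D21` rows), and `per_row`, a data.frame of per-row ratios.
#'   Maxima are 0 when no row has a negative cross coefficient.
#' @examples
#' tab <- read_dtable(ternadiff_extdata("beta_cd_table2.csv"))
#' countertransport_ratios(tab)
#' @export
countertransport_ratios <- function(dtable) {
  df <- .validate_dtable(as.data.frame(dtable), check_x1 = FALSE)
  if (nrow(df) == 0L) stop("empty diffusion table")
  if (any(df$d11 <= 0 | df$d22 <= 0))
    stop("main coefficients d11, d22 must be positive in every row")
  per_row <- data.frame(
    c1 = df$c1, c2 = df$c2,
    drug_per_carrier = abs(df$d12) / df$d22,
    carrier_per_drug = abs(df$d21) / df$d11,
    counter_current_12 = df$d12 < 0,
    counter_current_21 = df$d21 < 0)
  mx <- function(r, neg) if (any(neg)) max(r[neg]) else 0
  list(max_drug_per_carrier = mx(per_row$drug_per_carrier,
                                 per_row$counter_current_12),
       max_carrier_per_drug = mx(per_row$carrier_per_drug,
                                 per_row$counter_current_21),
       per_row = per_row)
}
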