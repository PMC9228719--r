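# Shared builders for the two measured systems and small random generators.

beta_cd_species <- function() {
  species_diffusivities(1.050, 0.399, 0.390,
                        d_drug_infinite_dilution = 1.168)
}

sds_species <- function() {
  species_diffusivities(1.050, 0.378, 0.100,
                        d_drug_infinite_dilution = 1.168)
}

beta_cd_sys <- function(k = 10) binding_system(beta_cd_species(), k)

sds_sys <- function(k = 20) binding_system(sds_species(), k, cmc = 0.0083)

beta_cd_table <- function() read_dtable(ternadiff_extdata("beta_cd_table2.csv"))

sds_table <- function() read_dtable(ternadiff_extdata("sds_table5.csv"))

# Random composition with occasional boundary cases (one solute absent).
random_composition <- function() {
  u <- stats::runif(1)
  if (u < 0.1) composition(0, stats::runif(1, 1e-4, 0.05))
  else if (u < 0.2) composition(stats::runif(1, 1e-4, 0.05), 0)
  else composition(stats::runif(1, 1e-4, 0.05), stats::runif(1, 1e-4, 0.05))
}

# Random 2x2 diffusion matrix with real positive distinct eigenvalues,
# shaped like the measured systems (dominant diagonal, small cross terms).
random_valid_dmatrix <- function() {
  repeat {
    m <- matrix(c(stats::rnorm(1, 1.0, 0.2), stats::rnorm(1, 0, 0.05),
                  stats::rnorm(1, 0, 0.05), stats::rnorm(1, 0.45, 0.1)),
                2L, 2L, byrow = TRUE)
    ev <- eigen(m, only.values = TRUE)$values
    if (!is.complex(ev) && all(ev > 0) &&
        abs(diff(ev)) > 1e-3 * max(abs(ev)))
      return(m)
  }
}

# Fixed-point oracle for the 1:1 equilibrium: damped iteration of
# x <- K (c1 - x)(c2 - x), independent of the closed-form root.
speciation_fixed_point <- function(c1, c2, k, tol = 1e-14,
                                   max_iter = 100000L) {
  x <- 0
  damp <- 1 / (1 + k * (c1 + c2))   # keeps the damped map contractive
  for (i in seq_len(max_iter)) {
    xn <- (1 - damp) * x + damp * k * (c1 - x) * (c2 - x)
    xn <- min(max(xn, 0), min(c1, c2))
    if (abs(xn - x) < tol * max(1, abs(xn))) return(xn)
    x <- xn
  }
  x
}
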