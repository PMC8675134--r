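#' Synthetic Gaussian wavefunctions with closed-form sphere integrals
#'
#' Builds a [wavefunction()] whose density is exactly
#' \deqn{\rho(r) = \sum_i w_i (\alpha_i/\pi)^{3/2} e^{-\alpha_i r^2},}
#' i.e. a sum of unit-normalized s-type Gaussians carrying `w_i` electrons
#' each. Because the electron count inside a sphere of radius R has the erf
#' closed form implemented in [sphere_electron_count()], these wavefunctions
#' are exact oracles for the sphere-quadrature engine without any
#' quantum-chemistry run.
#'
#' @param components two-column matrix or data.frame: `exponent` (bohr^-2,
#'   > 0) and `weight` (electrons, >= 0) per Gaussian term.
#' @param center 3-vector, bohr; the common center of all terms.
#' @param element label for the synthetic atom (cosmetic).
#' @return A [wavefunction()] with one s shell and one occupied MO per term.
#' @export
#' @examples
#' wf <- synthetic_wavefunction(cbind(exponent = 1, weight = 2))
#' electron_count(wf)  # 2
synthetic_wavefunction <- function(components, center = c(0, 0, 0),
                                   element = "Fe") {
  components <- as.data.frame(components)
  names(components)[1:2] <- c("exponent", "weight")
  if (any(components$weight < 0)) stop("electron weights must be >= 0")
  if (any(components$exponent <= 0)) stop("exponents must be > 0")
  atoms <- data.frame(element = element, nuclear_charge = 26L,
                      x = center[1], y = center[2], z = center[3])
  # phi_i^2 for a normalized s primitive of exponent a/2 is exactly the
  # unit-normalized density term (a/pi)^{3/2} exp(-a r^2)
  shells <- lapply(components$exponent, function(a) {
    list(atom_index = 1L, angular_momentum = "s",
         primitive_exponents = a / 2, contraction_coefficients = 1,
         pure_spherical = TRUE)
  })
  # a component carrying w electrons is realized as identical orbitals on the
  # same normalized s function, each with occupation <= 2, summing to w
  n <- nrow(components)
  cols <- list(); occs <- numeric(0)
  for (i in seq_len(n)) {
    w <- components$weight[i]
    occ_i <- c(rep(2, floor(w / 2)), if (w %% 2 > 0) w %% 2)
    if (!length(occ_i)) occ_i <- 0
    for (o in occ_i) {
      v <- numeric(n); v[i] <- 1
      cols[[length(cols) + 1L]] <- v
      occs <- c(occs, o)
    }
  }
  wavefunction(atoms, shells, do.call(cbind, cols), occs,
               rep("total", length(occs)))
}

#' Closed-form electron count of a synthetic density inside a sphere
#'
#' For the density of [synthetic_wavefunction()], the number of electrons
#' within radius R of the center is
#' \deqn{N(R) = \sum_i w_i\left[\mathrm{erf}(\sqrt{\alpha_i} R)
#'   - \tfrac{2\sqrt{\alpha_i}}{\sqrt{\pi}} R e^{-\alpha_i R^2}\right].}
#' This is the independent reference the quadrature engine is tested against.
#'
#' @param components as in [synthetic_wavefunction()].
#' @param R sphere radius (bohr), vectorized.
#' @return Electron count(s) inside the sphere.
#' @export
sphere_electron_count <- function(components, R) {
  components <- as.data.frame(components)
  names(components)[1:2] <- c("exponent", "weight")
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  vapply(R, function(r) {
    sum(components$weight *
          (erf(sqrt(components$exponent) * r) -
             2 * sqrt(components$exponent / pi) * r *
               exp(-components$exponent * r^2)))
  }, numeric(1))
}

#' Shell-structured iron-like test density
#'
#' A four-term synthetic density emulating the radial shell structure of an
#' iron atom (K, L, M shells plus diffuse valence; 26 electrons in total).
#' The K-shell exponent is set so that the K-shell density peaks near
#' r = 1/Z bohr, which places the charge-depletion maximum of the density
#' Laplacian a few hundredths of a bohr from the nucleus, as in real Fe
#' compounds. Used to exercise Laplacian profiles and grid-convergence checks
#' on a density with realistic near-nucleus curvature.
#'
#' @param center 3-vector, bohr.
#' @return A [wavefunction()].
#' @export
synthetic_iron_wavefunction <- function(center = c(0, 0, 0)) {
  synthetic_wavefunction(
    cbind(exponent = c(26^2 * 1.5, 60, 6, 0.6),
          weight   = c(2, 8, 14, 2)),
    center = center)
}
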