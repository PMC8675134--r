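#' Principal components of an electric field gradient tensor
#'
#' Diagonalizes a symmetric 3x3 EFG tensor (atomic units,
#' \eqn{E_h e^{-1} a_0^{-2}}) and sorts the eigenvalues by the Mossbauer
#' convention \eqn{|V_{zz}| \ge |V_{xx}| \ge |V_{yy}|} (ties broken by
#' descending signed value). Inputs may also be the three principal values
#' directly. A non-traceless or slightly asymmetric input is symmetrized and
#' flagged with a warning rather than rejected.
#'
#' @param tensor symmetric 3x3 matrix, or a length-3 numeric vector of
#'   principal values.
#' @return Object of class `efg_tensor`: `Vzz`, `Vxx`, `Vyy`, `eta`.
#' @export
efg_tensor <- function(tensor) {
  if (is.matrix(tensor)) {
    if (!all(is.finite(tensor))) stop("EFG tensor entries must be finite")
    if (any(dim(tensor) != c(3, 3))) stop("EFG tensor must be 3 x 3")
    asym <- max(abs(tensor - t(tensor)))
    if (asym > 1e-8) {
      warning("EFG tensor asymmetric by ", format(asym), "; symmetrizing")
    }
    tensor <- (tensor + t(tensor)) / 2
    ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  } else {
    if (length(tensor) != 3 || !all(is.finite(tensor))) {
      stop("principal values must be 3 finite numbers")
    }
    ev <- as.numeric(tensor)
  }
  tr <- sum(ev)
  if (abs(tr) > 1e-8 * max(1, max(abs(ev)))) {
    warning("EFG principal values are not traceless (trace = ",
            format(tr), ")")
  }
  ev <- ev[order(-abs(ev), -ev)]   # |Vzz| >= |Vxx| >= |Vyy|, signed tiebreak
  Vzz <- ev[1]; Vxx <- ev[2]; Vyy <- ev[3]
  eta <- if (Vzz == 0) {
    warning("Vzz = 0 (spherically symmetric EFG); eta defined as 0")
    0
  } else {
    abs(Vxx - Vyy) / abs(Vzz)
  }
  structure(list(Vzz = Vzz, Vxx = Vxx, Vyy = Vyy, eta = eta),
            class = "efg_tensor")
}

#' @export
print.efg_tensor <- function(x, ...) {
  cat(sprintf("EFG principal components (a.u.): Vzz = %.6g, Vxx = %.6g, Vyy = %.6g\n",
              x$Vzz, x$Vxx, x$Vyy))
  cat(sprintf("  asymmetry eta = %.6g\n", x$eta))
  invisible(x)
}

#' Asymmetry parameter of an EFG tensor
#'
#' \eqn{\eta = |V_{xx} - V_{yy}| / |V_{zz}|}, guaranteed in \[0, 1\] under
#' the ordering convention of [efg_tensor()]. The absolute value keeps eta
#' nonnegative for orderings where \eqn{V_{xx} - V_{yy}} and \eqn{V_{zz}}
#' differ in sign; the quadrupole splitting depends on eta only through
#' \eqn{\eta^2}, so the convention is observationally irrelevant.
#'
#' @param efg an `efg_tensor` (or anything [efg_tensor()] accepts).
#' @return eta, dimensionless.
#' @export
asymmetry <- function(efg) {
  if (!inherits(efg, "efg_tensor")) efg <- efg_tensor(efg)
  efg$eta
}

#' Doppler-velocity conversion constant for quadrupole splittings
#'
#' mm/s of Doppler velocity per (a.u. of Vzz x barn of Q) in the splitting
#' formula, chained from CODATA constants at call time:
#' a.u. of EFG -> SI, times eQ/2, divided by the 14.4125 keV gamma energy,
#' times c. Never a memorized literal.
#'
#' @param Q_barn nuclear quadrupole moment, barn.
#' @return mm/s per atomic unit of Vzz.
#' @export
efg_doppler_constant <- function(Q_barn = 0.16) {
  k <- moss_constants
  efg_si <- k$hartree_J / (k$e_C * k$bohr_m^2)     # V/m^2 per a.u.
  dE <- 0.5 * k$e_C * (Q_barn * k$barn_m2) * efg_si  # J per a.u. of Vzz
  E_gamma <- k$E_gamma_57Fe_keV * 1e3 * k$e_C        # J
  dE / E_gamma * k$c_m_s * 1e3                       # mm/s
}

#' Quadrupole splitting from an EFG tensor
#'
#' For the I = 3/2 excited state of 57Fe,
#' \deqn{\Delta E_Q = \tfrac{1}{2} e Q V_{zz} \sqrt{1 + \eta^2/3},}
#' reported as a Doppler velocity in mm/s via the 14.4125 keV gamma energy.
#' The sign of the splitting follows the sign of Vzz; use `abs = TRUE` for
#' the unsigned value usually quoted from powder spectra.
#'
#' @param efg an `efg_tensor` (or anything [efg_tensor()] accepts), Vzz in
#'   atomic units.
#' @param Q_barn 57Fe nuclear quadrupole moment, barn (> 0); default 0.16.
#' @param abs report `|Delta E_Q|` instead of the signed value.
#' @return Object of class `quadrupole_result`: `delta_EQ` (mm/s), `eta`,
#'   `Q_barn`, `conversion_constant` (mm/s per a.u. of Vzz at this Q).
#' @export
quadrupole_splitting <- function(efg, Q_barn = 0.16, abs = FALSE) {
  if (!inherits(efg, "efg_tensor")) efg <- efg_tensor(efg)
  if (!is.numeric(Q_barn) || Q_barn <= 0) stop("Q must be > 0 (barn)")
  const <- efg_doppler_constant(Q_barn)
  dEQ <- const * efg$Vzz * sqrt(1 + efg$eta^2 / 3)
  if (abs) dEQ <- base::abs(dEQ)
  structure(list(delta_EQ = dEQ, eta = efg$eta, Q_barn = Q_barn,
                 conversion_constant = const),
            class = "quadrupole_result")
}

#' @export
print.quadrupole_result <- function(x, ...) {
  cat(sprintf("quadrupole splitting: %.4f mm/s (eta = %.4f, Q = %.3f barn)\n",
              x$delta_EQ, x$eta, x$Q_barn))
  invisible(x)
}
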