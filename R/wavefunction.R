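#' Construct a wavefunction object
#'
#' A `wavefunction` bundles a molecular geometry, a contracted Gaussian basis
#' and occupied molecular orbitals, and is the analytic source of the electron
#' density probed by the Mossbauer descriptors. Positions and exponents are in
#' atomic units (bohr, bohr^-2).
#'
#' @param atoms data.frame with columns `element`, `nuclear_charge`,
#'   `x`, `y`, `z` (bohr).
#' @param shells list of shells; each shell is a list with `atom_index`,
#'   `angular_momentum` (`"s"`, `"p"`, `"d"` or `"f"`), `primitive_exponents`,
#'   `contraction_coefficients` and logical `pure_spherical`.
#' @param mo_coefficients numeric matrix, basis functions in rows, molecular
#'   orbitals in columns.
#' @param occupations numeric vector of per-orbital occupations, each in
#'   \[0, 2\].
#' @param mo_spin character vector, `"alpha"`, `"beta"` or `"total"` per
#'   orbital. Two spin channels are summed when forming the density, so the
#'   container covers restricted and unrestricted (S = 0 to 5) cases alike.
#'
#' @return An object of class `wavefunction`.
#' @export
wavefunction <- function(atoms, shells, mo_coefficients, occupations,
                         mo_spin = rep("total", length(occupations))) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "nuclear_charge", "x", "y", "z") %in% names(atoms)))
  if (any(atoms$nuclear_charge < 1)) {
    stop("nuclear charges must be >= 1")
  }
  for (sh in shells) {
    if (!sh$angular_momentum %in% names(ang_l)) {
      stop("unsupported angular momentum '", sh$angular_momentum,
           "' (supported: s, p, d, f)")
    }
    if (any(sh$primitive_exponents <= 0)) stop("primitive exponents must be > 0")
    if (length(sh$primitive_exponents) != length(sh$contraction_coefficients)) {
      stop("exponent/coefficient length mismatch in shell")
    }
    if (sh$atom_index < 1 || sh$atom_index > nrow(atoms)) {
      stop("shell atom_index out of range")
    }
  }
  nbas <- sum(vapply(shells, n_shell_functions, integer(1)))
  mo_coefficients <- as.matrix(mo_coefficients)
  if (nrow(mo_coefficients) != nbas) {
    stop("MO coefficient rows (", nrow(mo_coefficients),
         ") inconsistent with basis size implied by shells (", nbas, ")")
  }
  if (ncol(mo_coefficients) != length(occupations)) {
    stop("number of MOs and occupations differ")
  }
  if (any(occupations < 0 | occupations > 2)) {
    stop("occupations must lie in [0, 2]")
  }
  # precompute per-basis-function term tables (with owning atom centers)
  basis <- list()
  for (sh in shells) {
    ctr <- as.numeric(atoms[sh$atom_index, c("x", "y", "z")])
    for (fn in shell_basis_terms(sh)) {
      basis[[length(basis) + 1L]] <- list(center = ctr, terms = fn)
    }
  }
  structure(list(atoms = atoms, shells = shells,
                 mo_coefficients = mo_coefficients,
                 occupations = as.numeric(occupations),
                 mo_spin = as.character(mo_spin),
                 spin_channels = length(setdiff(unique(mo_spin), "total")),
                 basis = basis),
            class = "wavefunction")
}

#' Number of electrons described by a wavefunction
#'
#' @param wf a [wavefunction()].
#' @return Sum of orbital occupations.
#' @export
electron_count <- function(wf) sum(wf$occupations)

#' @export
print.wavefunction <- function(x, ...) {
  cat("wavefunction:", nrow(x$atoms), "atom(s),", length(x$shells),
      "shell(s),", length(x$basis), "basis function(s),",
      ncol(x$mo_coefficients), "MO(s)\n")
  cat("  electrons:", format(electron_count(x)), " spin channels:",
      max(1L, x$spin_channels), "\n")
  invisible(x)
}
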