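# Polynomial-times-Gaussian algebra for contracted GTO basis functions.
#
# Every basis function (Cartesian or pure spherical, s through f) is stored as
# a sum of primitive monomial Gaussians
#     coef * (x-cx)^a (y-cy)^b (z-cz)^c * exp(-alpha r^2),
# which makes values, gradients and Laplacians exact by term-wise polynomial
# differentiation, and self-overlaps analytic.

dfact <- function(n) {
  # double factorial with (-1)!! = 0!! = 1
  vapply(n, function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2)), numeric(1))
}

# analytic integral of x^p y^q z^s exp(-g r^2) over R^3 (0 if any power odd)
gauss_moment <- function(p, q, s, g) {
  if (p %% 2 || q %% 2 || s %% 2) return(0)
  dfact(p - 1) * dfact(q - 1) * dfact(s - 1) *
    (pi / g)^1.5 / (2 * g)^((p + q + s) / 2)
}

# terms: data.frame(coef, a, b, c, alpha); center: length-3
new_pg <- function(coef, a, b, c, alpha) {
  data.frame(coef = coef, a = a, b = b, c = c, alpha = alpha)
}

pg_scale <- function(terms, s) { terms$coef <- terms$coef * s; terms }

pg_self_overlap <- function(terms) {
  tot <- 0
  for (i in seq_len(nrow(terms))) for (j in seq_len(nrow(terms))) {
    tot <- tot + terms$coef[i] * terms$coef[j] *
      gauss_moment(terms$a[i] + terms$a[j], terms$b[i] + terms$b[j],
                   terms$c[i] + terms$c[j], terms$alpha[i] + terms$alpha[j])
  }
  tot
}

pg_normalize <- function(terms) pg_scale(terms, 1 / sqrt(pg_self_overlap(terms)))

# d/dx_dim of a term sum, as a new term sum
pg_deriv <- function(terms, dim) {
  key <- c("a", "b", "c")[dim]
  out <- list()
  for (i in seq_len(nrow(terms))) {
    t <- terms[i, ]
    if (t[[key]] > 0) {
      lower <- t; lower$coef <- t$coef * t[[key]]; lower[[key]] <- t[[key]] - 1
      out[[length(out) + 1L]] <- lower
    }
    upper <- t; upper$coef <- -2 * t$alpha * t$coef; upper[[key]] <- t[[key]] + 1
    out[[length(out) + 1L]] <- upper
  }
  do.call(rbind, out)
}

# evaluate a term sum at points (n x 3 matrix, already relative to the center)
pg_eval <- function(terms, rel) {
  r2 <- rowSums(rel^2)
  val <- numeric(nrow(rel))
  for (i in seq_len(nrow(terms))) {
    val <- val + terms$coef[i] *
      rel[, 1]^terms$a[i] * rel[, 2]^terms$b[i] * rel[, 3]^terms$c[i] *
      exp(-terms$alpha[i] * r2)
  }
  val
}

# Cartesian component exponent triplets in Molden order
cart_components <- list(
  s = matrix(c(0, 0, 0), ncol = 3, byrow = TRUE),
  p = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE),
  d = matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2, 1, 1, 0, 1, 0, 1, 0, 1, 1),
             ncol = 3, byrow = TRUE),
  f = matrix(c(3, 0, 0, 0, 3, 0, 0, 0, 3, 1, 2, 0, 2, 1, 0,
               2, 0, 1, 1, 0, 2, 0, 1, 2, 0, 2, 1, 1, 1, 1),
             ncol = 3, byrow = TRUE)
)

# tesseral (real solid harmonic) polynomial parts, Molden spherical ordering
# m = 0, +1, -1, +2, -2, (+3, -3); overall scale irrelevant (functions are
# renormalized), relative coefficients fix the angular shape.
sph_polys <- list(
  s = list(new_pg(1, 0, 0, 0, 0)),
  p = list(new_pg(1, 1, 0, 0, 0),          # x
           new_pg(1, 0, 1, 0, 0),          # y
           new_pg(1, 0, 0, 1, 0)),         # z
  d = list(new_pg(c(2, -1, -1), c(0, 2, 0), c(0, 0, 2), c(2, 0, 0), 0), # 2z2-x2-y2
           new_pg(1, 1, 0, 1, 0),                                       # xz
           new_pg(1, 0, 1, 1, 0),                                       # yz
           new_pg(c(1, -1), c(2, 0), c(0, 2), c(0, 0), 0),              # x2-y2
           new_pg(1, 1, 1, 0, 0)),                                      # xy
  f = list(new_pg(c(2, -3, -3), c(0, 2, 0), c(0, 0, 2), c(3, 1, 1), 0), # z(2z2-3x2-3y2)
           new_pg(c(4, -1, -1), c(1, 3, 1), c(0, 0, 2), c(2, 0, 0), 0), # x(4z2-x2-y2)
           new_pg(c(4, -1, -1), c(0, 2, 0), c(1, 1, 3), c(2, 0, 0), 0), # y(4z2-x2-y2)
           new_pg(c(1, -1), c(2, 0), c(0, 2), c(1, 1), 0),              # z(x2-y2)
           new_pg(1, 1, 1, 1, 0),                                      # xyz
           new_pg(c(1, -3), c(3, 1), c(0, 2), c(0, 0), 0),              # x(x2-3y2)
           new_pg(c(3, -1), c(2, 0), c(1, 3), c(0, 0), 0))              # y(3x2-y2)
)

ang_l <- c(s = 0L, p = 1L, d = 2L, f = 3L)

# radial normalization of a single primitive r^l exp(-alpha r^2)
radial_norm <- function(l, alpha) {
  sqrt(2 * (2 * alpha)^(l + 1.5) / gamma(l + 1.5))
}

# Cartesian primitive normalization for x^a y^b z^c exp(-alpha r^2)
cart_norm <- function(alpha, a, b, c) {
  L <- a + b + c
  (2 * alpha / pi)^0.75 * (4 * alpha)^(L / 2) /
    sqrt(dfact(2 * a - 1) * dfact(2 * b - 1) * dfact(2 * c - 1))
}

#' @keywords internal
#' @noRd
shell_basis_terms <- function(shell) {
  l <- ang_l[[shell$angular_momentum]]
  exps <- shell$primitive_exponents
  coefs <- shell$contraction_coefficients
  funs <- list()
  if (isTRUE(shell$pure_spherical) || l <= 1L) {
    for (poly in sph_polys[[shell$angular_momentum]]) {
      terms <- do.call(rbind, lapply(seq_along(exps), function(i) {
        t <- poly
        t$alpha <- exps[i]
        pg_scale(t, coefs[i] * radial_norm(l, exps[i]))
      }))
      funs[[length(funs) + 1L]] <- pg_normalize(terms)
    }
  } else {
    comps <- cart_components[[shell$angular_momentum]]
    for (k in seq_len(nrow(comps))) {
      a <- comps[k, 1]; b <- comps[k, 2]; c <- comps[k, 3]
      terms <- do.call(rbind, lapply(seq_along(exps), function(i) {
        new_pg(coefs[i] * cart_norm(exps[i], a, b, c), a, b, c, exps[i])
      }))
      funs[[length(funs) + 1L]] <- pg_normalize(terms)
    }
  }
  funs
}

n_shell_functions <- function(shell) {
  l <- ang_l[[shell$angular_momentum]]
  if (isTRUE(shell$pure_spherical) || l <= 1L) 2L * l + 1L
  else nrow(cart_components[[shell$angular_momentum]])
}
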