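# Lebedev quadrature on the unit sphere.
#
# A Lebedev rule of a given size is a union of orbits of the octahedral
# symmetry group; the free orbit parameters and weights are fully determined
# by requiring exactness for all polynomials up to the rule's algebraic
# order. Rather than transcribing node tables, the rules here are *solved*
# from those moment equations by Gauss-Newton (tabulated literature values
# only seed the iteration) and cached; the testsuite pins the exactness.
#
# Orbit classes (points, free parameters):
#   a1 : ( +-1, 0, 0 ) permutations                 ->  6 points
#   a2 : ( +-s, +-s, 0 ) permutations, s = 1/sqrt2  -> 12 points
#   a3 : ( +-t, +-t, +-t ), t = 1/sqrt3             ->  8 points
#   b  : ( +-l, +-l, +-m ), 2 l^2 + m^2 = 1         -> 24 points (1 parameter)
#   c  : ( +-p, +-q, 0 ),  p^2 + q^2 = 1            -> 24 points (1 parameter)

lebedev_specs <- list(
  `6`   = list(order = 3L,  orbits = c("a1"),
               w = 1 / 6, par = numeric(0)),
  `14`  = list(order = 5L,  orbits = c("a1", "a3"),
               w = c(0.06666666666666667, 0.075), par = numeric(0)),
  `26`  = list(order = 7L,  orbits = c("a1", "a2", "a3"),
               w = c(0.04761904761904762, 0.03809523809523810,
                     0.03214285714285714), par = numeric(0)),
  `38`  = list(order = 9L,  orbits = c("a1", "a3", "c"),
               w = c(0.009523809523809524, 0.03214285714285714,
                     0.02857142857142857),
               par = 0.4597008433809831),
  `50`  = list(order = 11L, orbits = c("a1", "a2", "a3", "b"),
               w = c(0.01269841269841270, 0.02257495590828924,
                     0.02109375, 0.02017333553791887),
               par = 0.3015113445777636),
  `110` = list(order = 17L, orbits = c("a1", "a3", "b", "b", "b", "c"),
               w = c(0.003828270494937162, 0.009793737512487512,
                     0.008211737283191111, 0.009942814891178103,
                     0.009595471336070963, 0.009694996361663028),
               par = c(0.1851156353447362, 0.6904210483822922,
                       0.3956894730559419, 0.4783690288121502))
)

signs <- function(k) as.matrix(do.call(expand.grid, rep(list(c(1, -1)), k)))

orbit_points <- function(type, par = NA) {
  if (type == "a1") {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else if (type == "a2") {
    s <- 1 / sqrt(2)
    out <- NULL
    for (ax in list(c(1, 2), c(1, 3), c(2, 3))) {
      for (sg in 1:4) {
        p <- c(0, 0, 0)
        p[ax] <- s * signs(2)[sg, ]
        out <- rbind(out, p)
      }
    }
    out
  } else if (type == "a3") {
    t <- 1 / sqrt(3)
    t * signs(3)
  } else if (type == "b") {
    l <- par; m <- sqrt(max(0, 1 - 2 * l^2))
    out <- NULL
    sg <- signs(3)
    for (base in list(c(m, l, l), c(l, m, l), c(l, l, m))) {
      out <- rbind(out, sweep(sg, 2, base, `*`))
    }
    out
  } else if (type == "c") {
    p <- par; q <- sqrt(max(0, 1 - p^2))
    out <- NULL
    sg <- signs(2)
    combos <- list(c(1, 2), c(2, 1))
    for (ax in list(c(1, 2), c(1, 3), c(2, 3))) {
      for (cb in combos) {
        vals <- c(p, q)[cb]
        for (s in 1:4) {
          v <- c(0, 0, 0)
          v[ax] <- vals * sg[s, ]
          out <- rbind(out, v)
        }
      }
    }
    out
  } else stop("unknown orbit type ", type)
}

orbit_size <- c(a1 = 6L, a2 = 12L, a3 = 8L, b = 24L, c = 24L)

# exact normalized moments of x^(2i) y^(2j) z^(2k) over the unit sphere
sphere_moment <- function(i, j, k) {
  dfact(2 * i - 1) * dfact(2 * j - 1) * dfact(2 * k - 1) /
    dfact(2 * (i + j + k) + 1)
}

lebedev_cache <- new.env(parent = emptyenv())

solve_lebedev <- function(n) {
  spec <- lebedev_specs[[as.character(n)]]
  free <- spec$orbits %in% c("b", "c")
  npar <- sum(free)
  deg <- spec$order %/% 2L
  mono <- do.call(rbind, lapply(0:deg, function(s) {
    g <- expand.grid(i = 0:s, j = 0:s)
    g <- g[g$i + g$j <= s, ]
    cbind(g$i, g$j, s - g$i - g$j)
  }))
  target <- apply(mono, 1, function(m) sphere_moment(m[1], m[2], m[3]))

  resid_fn <- function(theta) {
    w <- theta[seq_along(spec$orbits)]
    pars <- rep(NA_real_, length(spec$orbits))
    if (npar) pars[free] <- theta[length(spec$orbits) + seq_len(npar)]
    got <- numeric(length(target))
    for (o in seq_along(spec$orbits)) {
      pts <- orbit_points(spec$orbits[o], pars[o])
      for (r in seq_along(target)) {
        got[r] <- got[r] + w[o] * sum(pts[, 1]^(2 * mono[r, 1]) *
                                      pts[, 2]^(2 * mono[r, 2]) *
                                      pts[, 3]^(2 * mono[r, 3]))
      }
    }
    got - target
  }

  theta <- c(spec$w, spec$par)
  for (it in 1:60) {
    r0 <- resid_fn(theta)
    if (max(abs(r0)) < 1e-15) break
    J <- matrix(0, length(r0), length(theta))
    h <- 1e-7
    for (p in seq_along(theta)) {
      tp <- theta; tp[p] <- tp[p] + h
      J[, p] <- (resid_fn(tp) - r0) / h
    }
    step <- qr.solve(qr(J, LAPACK = TRUE), -r0)
    theta <- theta + step
    if (max(abs(step)) < 1e-14) break
  }
  if (max(abs(resid_fn(theta))) > 1e-12) {
    stop("Lebedev rule of size ", n, " failed to converge")
  }
  w <- theta[seq_along(spec$orbits)]
  pars <- rep(NA_real_, length(spec$orbits))
  if (npar) pars[free] <- theta[length(spec$orbits) + seq_len(npar)]
  nodes <- NULL; weights <- NULL
  for (o in seq_along(spec$orbits)) {
    pts <- orbit_points(spec$orbits[o], pars[o])
    nodes <- rbind(nodes, pts)
    weights <- c(weights, rep(w[o], nrow(pts)))
  }
  rownames(nodes) <- NULL
  list(nodes = nodes, weights = weights, order = spec$order)
}

#' Lebedev angular quadrature rule
#'
#' Returns unit-sphere nodes and weights of the octahedrally symmetric
#' Lebedev rule of the requested size. Weights are normalized to sum to 1
#' (multiply by `4*pi` for surface integrals). The 110-point rule (order 17)
#' is the angular grid used for the sphere-integrated density descriptor.
#'
#' @param n number of angular points; one of 6, 14, 26, 38, 50, 110.
#' @return list with `nodes` (n x 3 unit vectors), `weights` (length n,
#'   summing to 1) and `order` (algebraic exactness order).
#' @export
lebedev_rule <- function(n = 110) {
  key <- as.character(n)
  if (!key %in% names(lebedev_specs)) {
    stop("unsupported Lebedev size ", n, "; valid sizes: ",
         paste(names(lebedev_specs), collapse = ", "))
  }
  if (is.null(lebedev_cache[[key]])) {
    lebedev_cache[[key]] <- solve_lebedev(n)
  }
  lebedev_cache[[key]]
}
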