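# shared builders for the test suite; everything is generated in code

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# minimal Molden text: one atom, optional extra shells, one or more MOs
molden_text <- function(unit = "AU", shells = "s", nmo = 1,
                        pure_flags = character(0), pos = c(0, 0, 0),
                        coords_scale = 1) {
  shell_block <- character(0)
  nb <- 0L
  for (sh in shells) {
    if (sh == "s") { shell_block <- c(shell_block, " s 1 1.00", "  1.2 1.0"); nb <- nb + 1L }
    if (sh == "p") { shell_block <- c(shell_block, " p 1 1.00", "  0.8 1.0"); nb <- nb + 3L }
    if (sh == "d") { shell_block <- c(shell_block, " d 1 1.00", "  0.5 1.0")
      nb <- nb + if ("[5D]" %in% pure_flags) 5L else 6L }
    if (sh == "g") { shell_block <- c(shell_block, " g 1 1.00", "  0.5 1.0") }
  }
  mo_block <- character(0)
  for (m in seq_len(nmo)) {
    vec <- numeric(nb); vec[((m - 1L) %% nb) + 1L] <- 1
    mo_block <- c(mo_block, "Sym= A", "Ene= -1.0", "Spin= Alpha", "Occup= 2.0",
                  sprintf(" %d %.10f", seq_len(nb), vec))
  }
  c("[Molden Format]", pure_flags,
    sprintf("[Atoms] %s", unit),
    sprintf("Fe 1 26 %.8f %.8f %.8f", pos[1] * coords_scale,
            pos[2] * coords_scale, pos[3] * coords_scale),
    "[GTO]", " 1 0", shell_block, "",
    "[MO]", mo_block)
}

# random 3D rotation matrix from a fixed-seed QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random traceless symmetric 3x3 tensor
random_efg <- function(scale = 2) {
  a <- matrix(rnorm(9, sd = scale), 3, 3)
  s <- (a + t(a)) / 2
  s - diag(3) * sum(diag(s)) / 3
}

# multi-Gaussian synthetic component tables with varied shapes
random_components <- function(n_terms = 2, exp_range = c(50, 2000),
                             w_range = c(0.5, 2)) {
  cbind(exponent = exp(runif(n_terms, log(exp_range[1]), log(exp_range[2]))),
        weight = runif(n_terms, w_range[1], w_range[2]))
}

# constant-valued density grid
constant_grid <- function(value = 1, counts = c(4L, 4L, 4L), step = 0.5,
                          origin = c(-0.75, -0.75, -0.75)) {
  counts <- as.integer(counts)
  structure(list(origin = origin, axes = diag(3) * step, counts = counts,
                 values = array(value, dim = counts), atoms = NULL),
            class = "density_grid")
}
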