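#' Read a Molden wavefunction file
#'
#' Parses the `[Atoms]`, `[GTO]` and `[MO]` sections of a Molden file into a
#' [wavefunction()]. The supported dialect covers angular momenta s through f,
#' `AU`/`Angs` coordinate units, and the `[5D]`/`[7F]` flags selecting pure
#' spherical d/f functions (Cartesian 6d/10f is the Molden default).
#' Contraction coefficients are taken to multiply unit-normalized primitives;
#' each contracted function is renormalized at load.
#'
#' @param file path to a Molden file, or a character vector of its lines.
#' @return A [wavefunction()].
#' @export
read_molden <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE)
           else as.character(file)
  lines <- sub("\r$", "", lines)
  is_tag <- grepl("^\\s*\\[", lines)
  tags <- toupper(gsub("\\s", "", lines[is_tag]))
  tag_at <- which(is_tag)
  section <- function(name) {
    hit <- which(tags == toupper(name))
    if (!length(hit)) return(NULL)
    from <- tag_at[hit[1]]
    to <- if (any(tag_at > from)) min(tag_at[tag_at > from]) - 1L else length(lines)
    if (to < from + 1L) return(character(0))
    lines[(from + 1L):to]
  }
  has_tag <- function(name) any(tags == toupper(name))
  if (any(grepl("^\\[GTO", tags)) == FALSE && !has_tag("[GTO]")) {
    stop("Molden format error: no [GTO] section")
  }

  atoms_hdr <- lines[is_tag][grepl("^\\[ATOMS", tags)]
  atom_lines <- NULL
  for (i in seq_along(tags)) {
    if (grepl("^\\[ATOMS", tags[i])) {
      from <- tag_at[i]
      to <- if (any(tag_at > from)) min(tag_at[tag_at > from]) - 1L else length(lines)
      atom_lines <- lines[(from + 1L):to]
      atoms_hdr <- lines[from]
      break
    }
  }
  if (is.null(atom_lines)) stop("Molden format error: no [Atoms] section")
  to_bohr <- if (grepl("angs", atoms_hdr, ignore.case = TRUE)) {
    moss_constants$angstrom_bohr
  } else 1
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  atoms <- do.call(rbind, lapply(atom_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    data.frame(element = f[1], nuclear_charge = as.integer(f[3]),
               x = as.numeric(f[4]) * to_bohr,
               y = as.numeric(f[5]) * to_bohr,
               z = as.numeric(f[6]) * to_bohr)
  }))

  pure_d <- has_tag("[5D]") || has_tag("[5D7F]") || has_tag("[5D10F]")
  pure_f <- has_tag("[7F]") || has_tag("[5D7F]")

  gto <- section("[GTO]")
  gto <- gto[!grepl("^\\s*$", gto) | TRUE]  # keep blanks: they delimit atoms
  shells <- list()
  i <- 1L
  while (i <= length(gto)) {
    l <- trimws(gto[i])
    if (!nzchar(l)) { i <- i + 1L; next }
    f <- strsplit(l, "\\s+")[[1]]
    atom_index <- as.integer(f[1])
    i <- i + 1L
    while (i <= length(gto) && nzchar(trimws(gto[i]))) {
      hdr <- strsplit(trimws(gto[i]), "\\s+")[[1]]
      am <- tolower(hdr[1])
      if (am %in% c("g", "h", "i")) {
        stop("unsupported feature: angular momentum '", am, "' (max is f)")
      }
      if (am == "sp") stop("unsupported feature: sp shells")
      if (!am %in% c("s", "p", "d", "f")) {
        stop("Molden format error: bad shell header '", gto[i], "'")
      }
      nprim <- as.integer(hdr[2])
      prim <- gto[(i + 1L):(i + nprim)]
      pm <- t(vapply(prim, function(p) {
        as.numeric(strsplit(trimws(gsub("[DdEe]([+-]?[0-9])", "e\\1", p)),
                            "\\s+")[[1]][1:2])
      }, numeric(2)))
      pure <- switch(am, d = pure_d, f = pure_f, TRUE)
      shells[[length(shells) + 1L]] <- list(
        atom_index = atom_index, angular_momentum = am,
        primitive_exponents = pm[, 1], contraction_coefficients = pm[, 2],
        pure_spherical = pure)
      i <- i + 1L + nprim
    }
  }
  mo <- section("[MO]")
  if (is.null(mo)) stop("Molden format error: no [MO] section")

  # If the MO vector length contradicts the [5D]/[7F] flags, fall back to the
  # purity assignment consistent with the coefficient count (some emitters
  # write pure-spherical coefficients without the flag).
  first_len <- {
    cl <- grepl("^[0-9]", trimws(mo))
    runs <- rle(cl)
    if (any(runs$values)) runs$lengths[runs$values][1] else 0L
  }
  nbas_for <- function(pd, pf) {
    sum(vapply(shells, function(sh) {
      sh$pure_spherical <- switch(sh$angular_momentum, d = pd, f = pf, TRUE)
      n_shell_functions(sh)
    }, integer(1)))
  }
  if (first_len > 0L && nbas_for(pure_d, pure_f) != first_len) {
    for (pd in c(TRUE, FALSE)) for (pf in c(TRUE, FALSE)) {
      if (nbas_for(pd, pf) == first_len) { pure_d <- pd; pure_f <- pf }
    }
    shells <- lapply(shells, function(sh) {
      sh$pure_spherical <- switch(sh$angular_momentum,
                                  d = pure_d, f = pure_f, TRUE)
      sh
    })
  }
  nbas <- sum(vapply(shells, n_shell_functions, integer(1)))
  coefs <- list(); occs <- numeric(0); spins <- character(0)
  j <- 1L
  while (j <= length(mo)) {
    l <- trimws(mo[j])
    if (!nzchar(l)) { j <- j + 1L; next }
    if (!grepl("=", l) || grepl("^[0-9]", l)) {
      stop("Molden format error: expected MO header at '", l, "'")
    }
    occ <- 0; spin <- "total"
    while (j <= length(mo) && grepl("=", trimws(mo[j])) &&
           !grepl("^[0-9]", trimws(mo[j]))) {
      kv <- strsplit(trimws(mo[j]), "=")[[1]]
      key <- tolower(trimws(kv[1]))
      if (key == "occup") occ <- as.numeric(trimws(kv[2]))
      if (key == "spin") spin <- tolower(trimws(kv[2]))
      j <- j + 1L
    }
    vec <- numeric(nbas); seen <- 0L
    while (j <= length(mo) && grepl("^[0-9]", trimws(mo[j]))) {
      f <- strsplit(trimws(mo[j]), "\\s+")[[1]]
      idx <- as.integer(f[1])
      if (idx < 1L || idx > nbas) {
        stop("Molden format error: MO coefficient index ", idx,
             " outside basis of size ", nbas)
      }
      vec[idx] <- as.numeric(f[2])
      seen <- seen + 1L
      j <- j + 1L
    }
    if (seen != nbas) {
      stop("Molden format error: MO vector has ", seen,
           " coefficients, basis size is ", nbas)
    }
    coefs[[length(coefs) + 1L]] <- vec
    occs <- c(occs, occ)
    spins <- c(spins, spin)
  }
  wavefunction(atoms, shells, do.call(cbind, coefs), occs, spins)
}
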