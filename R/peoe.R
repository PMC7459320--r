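# Partial Equalization of Orbital Electronegativities (PEOE, the classic
# Gasteiger-Marsili iterative scheme) and an approximate van der Waals
# surface-area (VSA) partition used by the PEOE_VSA / SMR_VSA descriptor
# families. Charges are computed on the explicit-hydrogen graph; hydrogen
# surface and refractivity contributions are folded into the bonded heavy
# atom, and binning follows the conventional PEOE/SMR breakpoints.

# Electronegativity polynomial coefficients (a, b, c) per atom type.
PEOE_PARAMS <- list(
  H      = c(7.17, 6.24, -0.56),
  C.3    = c(7.98, 9.18, 1.88),
  C.2    = c(8.79, 9.32, 1.51),
  C.1    = c(10.39, 9.45, 0.73),
  N.3    = c(11.54, 10.82, 1.36),
  N.2    = c(12.87, 11.15, 0.85),
  N.1    = c(15.68, 11.70, -0.27),
  O.3    = c(14.18, 12.92, 1.39),
  O.2    = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S      = c(10.14, 9.13, 1.38),
  P      = c(8.90, 8.24, 0.96))

peoe_type <- function(el, max_order, n_double) {
  switch(el,
    H = "H", F = "F", Cl = "Cl", Br = "Br", I = "I", S = "S", P = "P",
    C = if (max_order >= 3 || n_double >= 2) "C.1" else if (max_order == 2) "C.2" else "C.3",
    N = if (max_order >= 3) "N.1" else if (max_order == 2) "N.2" else "N.3",
    O = if (max_order >= 2) "O.2" else "O.3",
    "C.3")  # fallback for exotic elements
}

#' PEOE (Gasteiger) partial charges
#'
#' Iterative partial equalization of orbital electronegativities over the
#' explicit-hydrogen connection table, with the damping halved each round.
#'
#' @param ctx Internal molecule context (or a `lan_mol`).
#' @param n_iter Number of equalization rounds (default 6).
#' @return Numeric vector of partial charges, one per atom.
#' @export
peoe_charges <- function(ctx, n_iter = 6L) {
  if (is_lan_mol(ctx)) ctx <- mol_context(ctx)
  el <- ctx$el
  n <- ctx$n
  types <- character(n)
  for (i in seq_len(n)) {
    ords <- ctx$border[[i]]
    types[i] <- peoe_type(el[i], if (length(ords)) max(ords) else 0L,
                          sum(ords == 2L))
  }
  # treat kekulized aromatic atoms as sp2 (already via max_order == 2)
  par <- do.call(rbind, PEOE_PARAMS[types])
  q <- as.numeric(ctx$mol$charges)
  chi_plus <- ifelse(types == "H", 20.02, rowSums(par))
  bonds <- ctx$bonds
  if (nrow(bonds) == 0 || n == 0) return(q)
  damp <- 0.5
  for (t in seq_len(n_iter)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    dq <- numeric(n)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      if (chi[j] > chi[i]) {
        move <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + move; dq[j] <- dq[j] - move
      } else if (chi[i] > chi[j]) {
        move <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + move; dq[i] <- dq[i] - move
      }
    }
    q <- q + dq
    damp <- damp * 0.5
  }
  q
}

# Radii (Angstrom) for the spherical-cap VSA approximation.
VDW_RADIUS <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, As = 1.85,
                Se = 1.90, Br = 1.85, I = 1.98)
COV_RADIUS <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, As = 1.19,
                Se = 1.20, Br = 1.20, I = 1.39)

# Element-level atomic refractivity contributions (cm3/mol).
ATOMIC_MR <- c(H = 1.100, B = 2.00, C = 2.418, N = 2.322, O = 1.643,
               F = 0.997, Si = 6.24, P = 3.919, S = 7.690, Cl = 5.967,
               As = 8.5, Se = 11.17, Br = 8.865, I = 13.900)

# Approximate per-atom van der Waals surface areas: full sphere minus one
# spherical cap per bond, bond length taken as the covalent-radius sum scaled
# down 10% per extra bond order, clamped to the geometrically valid range.
atom_vsa <- function(ctx) {
  el <- ctx$el
  R <- unname(VDW_RADIUS[el]); R[is.na(R)] <- 1.7
  rc <- unname(COV_RADIUS[el]); rc[is.na(rc)] <- 0.77
  area <- 4 * pi * R^2
  bonds <- ctx$bonds
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]; o <- bonds[r, 3]
      d <- (rc[i] + rc[j]) * (1 - 0.1 * (min(o, 3) - 1))
      d <- min(max(d, abs(R[i] - R[j]) + 0.01), R[i] + R[j] - 0.01)
      hi <- R[i] - (d^2 + R[i]^2 - R[j]^2) / (2 * d)
      hj <- R[j] - (d^2 + R[j]^2 - R[i]^2) / (2 * d)
      area[i] <- area[i] - 2 * pi * R[i] * max(min(hi, 2 * R[i]), 0)
      area[j] <- area[j] - 2 * pi * R[j] * max(min(hj, 2 * R[j]), 0)
    }
  }
  pmax(area, 0)
}

# Heavy-atom VSA with bonded-hydrogen areas folded in.
heavy_vsa <- function(ctx) {
  a <- atom_vsa(ctx)
  out <- a[ctx$heavy]
  for (k in seq_along(ctx$heavy)) {
    i <- ctx$heavy[k]
    hs <- ctx$nbr[[i]][ctx$el[ctx$nbr[[i]]] == "H"]
    out[k] <- out[k] + sum(a[hs])
  }
  out
}

PEOE_VSA_BINS <- c(-0.30, -0.25, -0.20, -0.15, -0.10, -0.05, 0,
                   0.05, 0.10, 0.15, 0.20, 0.25, 0.30)
SMR_VSA_BINS <- c(1.29, 1.82, 2.24, 2.45, 2.75, 3.05, 3.63, 3.8, 4.0)

binned_vsa <- function(values, vsa, breaks) {
  idx <- findInterval(values, breaks, left.open = FALSE) + 1L
  out <- numeric(length(breaks) + 1L)
  for (k in seq_along(values)) out[idx[k]] <- out[idx[k]] + vsa[k]
  out
}
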