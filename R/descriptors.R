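# Molecular descriptor engine. The candidate set mixes compositional counts,
# Kier-Hall connectivity (Chi) and shape (Kappa) indices, Balaban's J,
# Morgan-environment fingerprint densities, PEOE- and refractivity-binned
# van der Waals surface areas, OpenBabel's logP/MR/TPSA, and a block of
# fr_* functional-group counts that the pruning stage removes by rule.
# All descriptors are topological: coordinates do not enter any of them, so
# values are invariant to the embedding (the 3D pipeline exists for users
# who want refined geometries, e.g. for export).

# Hall-Kier covalent radii per PEOE atom type (Angstrom), for the alpha shape
# correction.
HK_RADII <- c(H = 0.30, C.3 = 0.77, C.2 = 0.67, C.1 = 0.60, N.3 = 0.74,
              N.2 = 0.62, N.1 = 0.55, O.3 = 0.74, O.2 = 0.62, F = 0.72,
              Cl = 0.99, Br = 1.14, I = 1.33, S = 1.04, P = 1.10)

# --- Kier-Hall deltas on the heavy graph -------------------------------------

heavy_deltas <- function(ctx) {
  el <- ctx$hel
  delta <- vapply(ctx$hadj, length, 1L)                    # simple
  h <- ctx$hcount[ctx$heavy]
  zv <- unname(VALENCE_ELECTRONS[el]); zv[is.na(zv)] <- 4
  z <- unname(ATOMIC_NUMBER[el]); z[is.na(z)] <- 6
  dn <- pmax(zv - h, 0)
  dv <- ifelse(z > 10, (zv - h) / pmax(z - zv - 1, 1), zv - h)
  dv <- pmax(dv, 0)
  list(simple = delta, v = dv, n = dn)
}

chi_path_sum <- function(ctx, deltas, len) {
  if (len == 0L) {
    d <- deltas[deltas > 0]
    return(sum(1 / sqrt(d)))
  }
  if (len == 1L) {
    hb <- ctx$hbonds
    if (nrow(hb) == 0) return(0)
    p <- deltas[hb[, 1]] * deltas[hb[, 2]]
    return(sum(1 / sqrt(p[p > 0])))
  }
  paths <- ctx$paths[[len]]
  if (is.null(paths) || nrow(paths) == 0) return(0)
  s <- 0
  for (r in seq_len(nrow(paths))) {
    p <- prod(deltas[paths[r, ]])
    if (p > 0) s <- s + 1 / sqrt(p)
  }
  s
}

kier_alpha <- function(ctx) {
  el <- ctx$hel
  a <- 0
  for (k in seq_along(el)) {
    ords <- ctx$hbond_orders[[k]]
    typ <- peoe_type(el[k], if (length(ords)) max(ords) else 0L, sum(ords == 2L))
    r <- unname(HK_RADII[typ])
    if (is.na(r)) r <- 0.77
    a <- a + (r / 0.77 - 1)
  }
  a
}

kappa_indices <- function(ctx) {
  A <- ctx$nheavy
  alpha <- kier_alpha(ctx)
  P1 <- nrow(ctx$hbonds)
  P2 <- nrow(ctx$paths[[2]])
  P3 <- nrow(ctx$paths[[3]])
  k1 <- if (P1 > 0) (A + alpha) * (A + alpha - 1)^2 / (P1 + alpha)^2 else 0
  k2 <- if (P2 > 0 && A >= 2) (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2 else 0
  k3 <- if (P3 > 0 && A >= 3) {
    if (A %% 2 == 1) (A + alpha - 1) * (A + alpha - 3)^2 / (P3 + alpha)^2
    else (A + alpha - 3) * (A + alpha - 2)^2 / (P3 + alpha)^2
  } else 0
  c(k1 = k1, k2 = k2, k3 = k3, alpha = alpha)
}

balaban_j <- function(ctx) {
  hb <- ctx$hbonds
  if (nrow(hb) == 0 || ctx$nheavy < 2) return(0)
  D <- ctx$dist
  fin <- is.finite(D)
  s <- rowSums(ifelse(fin, D, 0))
  q <- nrow(hb)
  mu <- q - ctx$nheavy + igraph::count_components(ctx$graph)
  terms <- 1 / sqrt(s[hb[, 1]] * s[hb[, 2]])
  q / (mu + 1) * sum(terms)
}

morgan_env_count <- function(ctx, radius) {
  nh <- ctx$nheavy
  if (nh == 0) return(0)
  h <- ctx$hcount[ctx$heavy]
  inv <- paste(ctx$hel, vapply(ctx$hadj, length, 1L), h,
               ctx$mol$charges[ctx$heavy], sep = "|")
  seen <- unique(inv)
  if (radius > 0) {
    key <- function(i, j) paste(min(i, j), max(i, j))
    ord <- new.env(parent = emptyenv())
    hb <- ctx$hbonds
    if (nrow(hb) > 0)
      for (r in seq_len(nrow(hb))) assign(key(hb[r, 1], hb[r, 2]), hb[r, 3], ord)
    for (rad in seq_len(radius)) {
      nxt <- character(nh)
      for (i in seq_len(nh)) {
        nb <- ctx$hadj[[i]]
        tags <- sort(vapply(nb, function(j)
          paste0(get(key(i, j), ord), ":", inv[j]), ""))
        nxt[i] <- paste0(inv[i], "{", paste(tags, collapse = ","), "}")
      }
      inv <- nxt
      seen <- unique(c(seen, inv))
    }
  }
  length(seen)
}

# --- functional-group helpers ------------------------------------------------

is_carbonyl_c <- function(ctx, k) {
  ctx$hel[k] == "C" &&
    any(ctx$hel[ctx$hadj[[k]]] == "O" & ctx$hbond_orders[[k]] == 2L)
}

ring_bond_set <- function(ctx) {
  keys <- character(0)
  for (ring in ctx$rings) {
    e <- cbind(ring, c(ring[-1], ring[1]))
    keys <- c(keys, paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  unique(keys)
}

# --- registry ----------------------------------------------------------------

make_descriptor_registry <- function() {
  reg <- list()
  d <- function(name, fn) reg[[name]] <<- fn

  hv <- function(ctx) ctx$hel
  # composition
  d("MolWt", function(ctx) sum(ATOMIC_MASS[ctx$el], na.rm = TRUE))
  d("HeavyAtomMolWt", function(ctx) sum(ATOMIC_MASS[ctx$hel], na.rm = TRUE))
  d("HeavyAtomCount", function(ctx) ctx$nheavy)
  d("NumH", function(ctx) sum(ctx$el == "H"))
  d("NumValenceElectrons", function(ctx)
    sum(VALENCE_ELECTRONS[ctx$el], na.rm = TRUE) - sum(ctx$mol$charges))
  d("FormalCharge", function(ctx) sum(ctx$mol$charges))
  d("NumRadicalElectrons", function(ctx) 0)
  d("NumHDonors", function(ctx) {
    sum(vapply(seq_along(ctx$heavy), function(k) {
      i <- ctx$heavy[k]
      ctx$el[i] %in% c("N", "O") && ctx$hcount[i] > 0
    }, TRUE))
  })
  d("NumHAcceptors", function(ctx) {
    acc <- 0L
    for (k in seq_along(ctx$heavy)) {
      e <- ctx$hel[k]
      if (e == "O") acc <- acc + 1L
      else if (e == "N") {
        i <- ctx$heavy[k]
        pyrrole_like <- ctx$aromatic_atoms[k] && ctx$hcount[i] > 0
        amide <- any(vapply(ctx$hadj[[k]], function(j)
          is_carbonyl_c(ctx, j), TRUE))
        if (!pyrrole_like && !amide) acc <- acc + 1L
      }
    }
    acc
  })
  d("NHOHCount", function(ctx) {
    sum(vapply(ctx$heavy, function(i)
      if (ctx$el[i] %in% c("N", "O")) ctx$hcount[i] else 0L, 0L))
  })
  d("NOCount", function(ctx) sum(ctx$hel %in% c("N", "O")))
  d("NumHeteroatoms", function(ctx) sum(ctx$hel %in% HETERO))
  for (e in c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")) {
    local({
      ee <- e
      d(paste0("Num", ee), function(ctx) sum(ctx$hel == ee))
    })
  }
  d("NumHalogens", function(ctx) sum(ctx$hel %in% HALOGENS))
  d("FractionCSP3", function(ctx) {
    cs <- which(ctx$hel == "C")
    if (length(cs) == 0) return(0)
    sp3 <- vapply(cs, function(k)
      all(ctx$hbond_orders[[k]] == 1L) && !ctx$aromatic_atoms[k], TRUE)
    mean(sp3)
  })
  # rings
  d("RingCount", function(ctx)
    nrow(ctx$hbonds) - ctx$nheavy + igraph::count_components(ctx$graph))
  d("NumAromaticRings", function(ctx) length(ctx$aromatic_rings))
  d("NumAliphaticRings", function(ctx) {
    akeys <- vapply(ctx$aromatic_rings, function(r) paste(sort(r), collapse = ","), "")
    sum(!vapply(ctx$rings, function(r)
      paste(sort(r), collapse = ",") %in% akeys, TRUE))
  })
  d("NumSaturatedRings", function(ctx) {
    rb <- function(ring) {
      e <- cbind(ring, c(ring[-1], ring[1]))
      keys <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      all(ctx$hbond_key_order[keys] == 1L)
    }
    sum(vapply(ctx$rings, rb, TRUE))
  })
  d("NumAromaticCarbocycles", function(ctx)
    sum(vapply(ctx$aromatic_rings, function(r) all(ctx$hel[r] == "C"), TRUE)))
  d("NumAromaticHeterocycles", function(ctx)
    sum(vapply(ctx$aromatic_rings, function(r) any(ctx$hel[r] != "C"), TRUE)))
  d("NumAromaticAtoms", function(ctx) sum(ctx$aromatic_atoms))
  d("NumRingAtoms", function(ctx) length(unique(unlist(ctx$rings))))
  for (sz in 3:8) {
    local({
      s <- sz
      d(paste0("RingSize", s), function(ctx)
        sum(vapply(ctx$rings, length, 1L) == s))
    })
  }
  # degrees / bonds
  for (dd in 1:4) {
    local({
      k <- dd
      d(paste0("NumDegree", k), function(ctx)
        sum(vapply(ctx$hadj, length, 1L) == k))
    })
  }
  d("NumSingleBonds", function(ctx) sum(ctx$hbonds[, 3] == 1L))
  d("NumDoubleBonds", function(ctx) sum(ctx$hbonds[, 3] == 2L))
  d("NumTripleBonds", function(ctx) sum(ctx$hbonds[, 3] == 3L))
  d("NumRingBonds", function(ctx) length(ring_bond_set(ctx)))
  d("NumAmideBonds", function(ctx) {
    cnt <- 0L
    hb <- ctx$hbonds
    for (r in seq_len(nrow(hb))) {
      if (hb[r, 3] != 1L) next
      a <- hb[r, 1]; b <- hb[r, 2]
      if ((ctx$hel[a] == "C" && ctx$hel[b] == "N" && is_carbonyl_c(ctx, a)) ||
          (ctx$hel[b] == "C" && ctx$hel[a] == "N" && is_carbonyl_c(ctx, b)))
        cnt <- cnt + 1L
    }
    cnt
  })
  d("NumRotatableBonds", function(ctx) {
    rbs <- ring_bond_set(ctx)
    deg <- vapply(ctx$hadj, length, 1L)
    cnt <- 0L
    hb <- ctx$hbonds
    for (r in seq_len(nrow(hb))) {
      if (hb[r, 3] != 1L) next
      a <- hb[r, 1]; b <- hb[r, 2]
      if (paste(min(a, b), max(a, b)) %in% rbs) next
      if (deg[a] < 2 || deg[b] < 2) next
      amide <- (ctx$hel[a] == "C" && ctx$hel[b] == "N" && is_carbonyl_c(ctx, a)) ||
        (ctx$hel[b] == "C" && ctx$hel[a] == "N" && is_carbonyl_c(ctx, b))
      if (!amide) cnt <- cnt + 1L
    }
    cnt
  })
  # graph indices
  d("BalabanJ", balaban_j)
  for (spec in list(c("Chi0", "simple", 0), c("Chi1", "simple", 1),
                    c("Chi0v", "v", 0), c("Chi1v", "v", 1), c("Chi2v", "v", 2),
                    c("Chi3v", "v", 3), c("Chi4v", "v", 4),
                    c("Chi0n", "n", 0), c("Chi1n", "n", 1), c("Chi2n", "n", 2),
                    c("Chi3n", "n", 3), c("Chi4n", "n", 4))) {
    local({
      nm <- spec[1]; fam <- spec[2]; len <- as.integer(spec[3])
      d(nm, function(ctx) chi_path_sum(ctx, ctx$deltas[[fam]], len))
    })
  }
  d("Kappa1", function(ctx) ctx$kappa[["k1"]])
  d("Kappa2", function(ctx) ctx$kappa[["k2"]])
  d("Kappa3", function(ctx) ctx$kappa[["k3"]])
  d("HallKierAlpha", function(ctx) ctx$kappa[["alpha"]])
  d("KierFlex", function(ctx)
    if (ctx$nheavy > 0) ctx$kappa[["k1"]] * ctx$kappa[["k2"]] / ctx$nheavy else 0)
  d("WienerIndex", function(ctx) {
    D <- ctx$dist
    sum(D[is.finite(D)]) / 2
  })
  d("ZagrebIndex", function(ctx) sum(vapply(ctx$hadj, length, 1L)^2))
  d("TopoDiameter", function(ctx) {
    D <- ctx$dist
    if (length(D) == 0) return(0)
    m <- D[is.finite(D)]
    if (length(m) == 0) 0 else max(m)
  })
  d("TopoRadius", function(ctx) {
    D <- ctx$dist
    if (length(D) <= 1) return(0)
    ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
    min(ecc)
  })
  d("EccentricConnectivityIndex", function(ctx) {
    D <- ctx$dist
    if (length(D) <= 1) return(0)
    ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
    sum(ecc * vapply(ctx$hadj, length, 1L))
  })
  # Morgan environment densities
  for (rr in 1:3) {
    local({
      r <- rr
      d(paste0("FpDensityMorgan", r), function(ctx)
        if (ctx$nheavy > 0) morgan_env_count(ctx, r) / ctx$nheavy else 0)
    })
  }
  # charges
  d("MaxPartialCharge", function(ctx) max(ctx$charges_peoe))
  d("MinPartialCharge", function(ctx) min(ctx$charges_peoe))
  d("MaxAbsPartialCharge", function(ctx) max(abs(ctx$charges_peoe)))
  d("MinAbsPartialCharge", function(ctx) min(abs(ctx$charges_peoe)))
  # surface areas
  d("LabuteASA", function(ctx) sum(ctx$vsa))
  for (b in 1:14) {
    local({
      k <- b
      d(paste0("PEOE_VSA", k), function(ctx) ctx$peoe_vsa[k])
    })
  }
  for (b in 1:10) {
    local({
      k <- b
      d(paste0("SMR_VSA", k), function(ctx) ctx$smr_vsa[k])
    })
  }
  # OpenBabel bulk properties
  d("MolLogP", function(ctx) ctx$obprops[["logP"]])
  d("MolMR", function(ctx) ctx$obprops[["MR"]])
  d("TPSA", function(ctx) ctx$obprops[["TPSA"]])

  # fragment counts (removed by the pruning rule, kept as candidates)
  carboxyl_idx <- function(ctx, charged_ok) {
    which(vapply(seq_len(ctx$nheavy), function(k) {
      if (ctx$hel[k] != "C") return(FALSE)
      nb <- ctx$hadj[[k]]; os <- ctx$hbond_orders[[k]]
      has_dbl_o <- any(ctx$hel[nb] == "O" & os == 2L)
      single_o <- nb[ctx$hel[nb] == "O" & os == 1L]
      if (!has_dbl_o || length(single_o) == 0) return(FALSE)
      any(vapply(single_o, function(j) {
        i <- ctx$heavy[j]
        ctx$hcount[i] > 0 || (charged_ok && ctx$mol$charges[i] < 0)
      }, TRUE))
    }, TRUE))
  }
  d("fr_COO", function(ctx) length(carboxyl_idx(ctx, FALSE)))
  d("fr_COO2", function(ctx) length(carboxyl_idx(ctx, TRUE)))
  d("fr_Ar_COO", function(ctx) {
    idx <- carboxyl_idx(ctx, TRUE)
    sum(vapply(idx, function(k)
      any(ctx$aromatic_atoms[ctx$hadj[[k]]]), TRUE))
  })
  oh_idx <- function(ctx) {
    which(vapply(seq_len(ctx$nheavy), function(k) {
      i <- ctx$heavy[k]
      ctx$hel[k] == "O" && ctx$hcount[i] > 0 &&
        sum(ctx$hel[ctx$hadj[[k]]] == "C") == 1 &&
        !any(vapply(ctx$hadj[[k]], function(j) is_carbonyl_c(ctx, j), TRUE))
    }, TRUE))
  }
  d("fr_Ar_OH", function(ctx) {
    sum(vapply(oh_idx(ctx), function(k)
      any(ctx$aromatic_atoms[ctx$hadj[[k]]]), TRUE))
  })
  d("fr_Al_OH", function(ctx) {
    sum(vapply(oh_idx(ctx), function(k)
      !any(ctx$aromatic_atoms[ctx$hadj[[k]]]), TRUE))
  })
  n_with_h <- function(ctx, nh_count) {
    sum(vapply(seq_len(ctx$nheavy), function(k)
      ctx$hel[k] == "N" && ctx$hcount[ctx$heavy[k]] == nh_count, TRUE))
  }
  d("fr_NH2", function(ctx) n_with_h(ctx, 2L))
  d("fr_NH1", function(ctx) n_with_h(ctx, 1L))
  d("fr_NH0", function(ctx) n_with_h(ctx, 0L))
  d("fr_ether", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "O" && ctx$hcount[ctx$heavy[k]] == 0 &&
        sum(ctx$hel[ctx$hadj[[k]]] == "C" & ctx$hbond_orders[[k]] == 1L) == 2 &&
        !any(vapply(ctx$hadj[[k]], function(j) is_carbonyl_c(ctx, j), TRUE))
    }, TRUE))
  })
  d("fr_ester", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      if (!is_carbonyl_c(ctx, k)) return(FALSE)
      nb <- ctx$hadj[[k]]; os <- ctx$hbond_orders[[k]]
      single_o <- nb[ctx$hel[nb] == "O" & os == 1L]
      any(vapply(single_o, function(j)
        sum(ctx$hel[ctx$hadj[[j]]] == "C") == 2, TRUE))
    }, TRUE))
  })
  d("fr_amide", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k)
      is_carbonyl_c(ctx, k) && any(ctx$hel[ctx$hadj[[k]]] == "N" &
                                     ctx$hbond_orders[[k]] == 1L), TRUE))
  })
  d("fr_ketone", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      if (!is_carbonyl_c(ctx, k)) return(FALSE)
      nb <- ctx$hadj[[k]]; os <- ctx$hbond_orders[[k]]
      sum(ctx$hel[nb] == "C" & os == 1L) == 2
    }, TRUE))
  })
  d("fr_aldehyde", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k)
      is_carbonyl_c(ctx, k) && ctx$hcount[ctx$heavy[k]] > 0, TRUE))
  })
  d("fr_nitro", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "N" && sum(ctx$hel[ctx$hadj[[k]]] == "O") >= 2 &&
        any(ctx$hbond_orders[[k]] == 2L)
    }, TRUE))
  })
  d("fr_nitrile", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k)
      ctx$hel[k] == "N" && any(ctx$hbond_orders[[k]] == 3L), TRUE))
  })
  d("fr_halogen", function(ctx) sum(ctx$hel %in% HALOGENS))
  phos_o <- function(ctx, want_h) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      if (ctx$hel[k] != "P") return(FALSE)
      nb <- ctx$hadj[[k]]; os <- ctx$hbond_orders[[k]]
      if (!any(ctx$hel[nb] == "O" & os == 2L)) return(FALSE)
      single_o <- nb[ctx$hel[nb] == "O" & os == 1L]
      if (want_h)
        any(vapply(single_o, function(j) ctx$hcount[ctx$heavy[j]] > 0, TRUE))
      else
        any(vapply(single_o, function(j)
          sum(ctx$hel[ctx$hadj[[j]]] == "C") > 0, TRUE))
    }, TRUE))
  }
  d("fr_phos_acid", function(ctx) phos_o(ctx, TRUE))
  d("fr_phos_ester", function(ctx) phos_o(ctx, FALSE))
  d("fr_sulfide", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "S" && all(ctx$hbond_orders[[k]] == 1L) &&
        sum(ctx$hel[ctx$hadj[[k]]] == "C") == 2
    }, TRUE))
  })
  d("fr_sulfone", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "S" &&
        sum(ctx$hel[ctx$hadj[[k]]] == "O" & ctx$hbond_orders[[k]] == 2L) == 2
    }, TRUE))
  })
  d("fr_SH", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k)
      ctx$hel[k] == "S" && ctx$hcount[ctx$heavy[k]] > 0, TRUE))
  })
  d("fr_aniline", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "N" && !ctx$aromatic_atoms[k] &&
        any(ctx$aromatic_atoms[ctx$hadj[[k]]] &
              ctx$hel[ctx$hadj[[k]]] == "C")
    }, TRUE))
  })
  d("fr_pyridine", function(ctx) {
    sum(vapply(ctx$aromatic_rings, function(r)
      length(r) == 6 && sum(ctx$hel[r] == "N") >= 1 &&
        all(ctx$hel[r] %in% c("C", "N")), TRUE))
  })
  d("fr_benzene", function(ctx) {
    sum(vapply(ctx$aromatic_rings, function(r)
      length(r) == 6 && all(ctx$hel[r] == "C"), TRUE))
  })
  d("fr_imine", function(ctx) {
    hb <- ctx$hbonds
    cnt <- 0L
    for (r in seq_len(nrow(hb))) {
      if (hb[r, 3] == 2L &&
          sort(c(ctx$hel[hb[r, 1]], ctx$hel[hb[r, 2]]))[1] == "C" &&
          sort(c(ctx$hel[hb[r, 1]], ctx$hel[hb[r, 2]]))[2] == "N" &&
          !(ctx$aromatic_atoms[hb[r, 1]] && ctx$aromatic_atoms[hb[r, 2]]))
        cnt <- cnt + 1L
    }
    cnt
  })
  d("fr_azo", function(ctx) {
    hb <- ctx$hbonds
    sum(hb[, 3] == 2L & ctx$hel[hb[, 1]] == "N" & ctx$hel[hb[, 2]] == "N")
  })
  d("fr_urea", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k)
      is_carbonyl_c(ctx, k) &&
        sum(ctx$hel[ctx$hadj[[k]]] == "N" & ctx$hbond_orders[[k]] == 1L) == 2,
      TRUE))
  })
  d("fr_guanido", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "C" && sum(ctx$hel[ctx$hadj[[k]]] == "N") == 3 &&
        any(ctx$hbond_orders[[k]] == 2L & ctx$hel[ctx$hadj[[k]]] == "N")
    }, TRUE))
  })
  d("fr_amidine", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "C" && sum(ctx$hel[ctx$hadj[[k]]] == "N") == 2 &&
        any(ctx$hbond_orders[[k]] == 2L & ctx$hel[ctx$hadj[[k]]] == "N")
    }, TRUE))
  })
  d("fr_sulfonamide", function(ctx) {
    sum(vapply(seq_len(ctx$nheavy), function(k) {
      ctx$hel[k] == "S" &&
        sum(ctx$hel[ctx$hadj[[k]]] == "O" & ctx$hbond_orders[[k]] == 2L) == 2 &&
        any(ctx$hel[ctx$hadj[[k]]] == "N")
    }, TRUE))
  })
  reg
}

descriptor_registry <- function() {
  if (is.null(.lanbind_env$registry))
    .lanbind_env$registry <- make_descriptor_registry()
  .lanbind_env$registry
}

#' Names of all candidate molecular descriptors
#'
#' The toolkit's full descriptor list, including the fr_* functional-group
#' counts that [prune_descriptor_set()] removes by rule.
#'
#' @return Character vector of descriptor names.
#' @export
all_descriptor_names <- function() names(descriptor_registry())

augment_context <- function(ctx, need_ob = TRUE) {
  ctx$paths <- list(NULL,
                    count_paths(ctx$hadj, 2L),
                    count_paths(ctx$hadj, 3L),
                    count_paths(ctx$hadj, 4L))
  ctx$dist <- if (ctx$nheavy > 0) igraph::distances(ctx$graph) else
    matrix(numeric(0), 0, 0)
  ctx$hbond_orders <- rep(list(integer(0)), max(ctx$nheavy, 1L))
  ctx$hbond_key_order <- integer(0)
  if (nrow(ctx$hbonds) > 0) {
    keys <- character(nrow(ctx$hbonds))
    for (r in seq_len(nrow(ctx$hbonds))) {
      i <- ctx$hbonds[r, 1]; j <- ctx$hbonds[r, 2]; o <- ctx$hbonds[r, 3]
      ctx$hbond_orders[[i]] <- c(ctx$hbond_orders[[i]], o)
      ctx$hbond_orders[[j]] <- c(ctx$hbond_orders[[j]], o)
      keys[r] <- paste(min(i, j), max(i, j))
    }
    ctx$hbond_key_order <- setNames(ctx$hbonds[, 3], keys)
  }
  ctx$deltas <- heavy_deltas(ctx)
  ctx$kappa <- kappa_indices(ctx)
  ctx$charges_peoe <- peoe_charges(ctx)
  ctx$vsa <- heavy_vsa(ctx)
  hq <- ctx$charges_peoe[ctx$heavy]
  ctx$peoe_vsa <- binned_vsa(hq, ctx$vsa, PEOE_VSA_BINS)
  mr <- unname(ATOMIC_MR[ctx$hel]); mr[is.na(mr)] <- 2.418
  mr <- mr + ctx$hcount[ctx$heavy] * ATOMIC_MR[["H"]]
  ctx$smr_vsa <- binned_vsa(mr, ctx$vsa, SMR_VSA_BINS)
  if (need_ob) {
    txt <- paste0(paste(c(ctx$mol$lines, "$$$$"), collapse = "\n"), "\n")
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(
      strsplit(txt, "\n", fixed = TRUE)[[1]]))
    props <- tryCatch(ChemmineR::propOB(sdfset), error = function(e) NULL)
    if (is.null(props) || nrow(props) != 1) {
      lan_abort(sprintf("featurization failure for '%s': property computation failed",
                        ctx$mol$id), "lanbind_featurization_failure")
    }
    ctx$obprops <- c(logP = props$logP[1], MR = props$MR[1], TPSA = props$TPSA[1])
  }
  ctx
}

#' Compute molecular descriptors
#'
#' Evaluates the requested descriptors for one molecule, preserving the
#' requested order. All shipped descriptors are topological (2D); values are
#' identical for any embedding of the same connection table.
#'
#' @param mol A `lan_mol` (explicit hydrogens expected).
#' @param descriptor_names Ordered character vector of descriptor names;
#'   defaults to the frozen 83-name layout from [default_descriptor_names()].
#' @return Named numeric vector aligned to `descriptor_names`.
#' @export
compute_descriptors <- function(mol, descriptor_names = default_descriptor_names()) {
  stopifnot(is_lan_mol(mol))
  reg <- descriptor_registry()
  unknown <- setdiff(descriptor_names, names(reg))
  if (length(unknown) > 0) {
    lan_abort(paste0("unknown descriptor name(s): ", paste(unknown, collapse = ", ")),
              "lanbind_config_error")
  }
  need_ob <- any(c("MolLogP", "MolMR", "TPSA") %in% descriptor_names)
  ctx <- augment_context(mol_context(mol), need_ob = need_ob)
  vals <- vapply(descriptor_names, function(nm) as.numeric(reg[[nm]](ctx)), 0)
  if (any(!is.finite(vals))) {
    bad <- descriptor_names[!is.finite(vals)]
    lan_abort(sprintf("featurization failure for '%s': non-finite descriptor(s) %s",
                      mol$id, paste(bad, collapse = ", ")),
              "lanbind_featurization_failure")
  }
  vals
}

#' Compute a descriptor matrix for a set of molecules
#'
#' Molecules whose featurization fails are collected into a rejects table and
#' skipped (never zero-filled), so downstream applicability-domain bounds see
#' only clean rows.
#'
#' @param mols List of `lan_mol` objects.
#' @param descriptor_names Ordered descriptor names.
#' @return List with `matrix` (rows = molecules, named) and `rejects`
#'   (data.frame id/reason).
#' @export
descriptor_matrix <- function(mols, descriptor_names = default_descriptor_names()) {
  rows <- list()
  rej_id <- character(0); rej_reason <- character(0)
  for (m in mols) {
    v <- tryCatch(compute_descriptors(m, descriptor_names),
                  lanbind_featurization_failure = function(e) e)
    if (inherits(v, "condition")) {
      rej_id <- c(rej_id, m$id); rej_reason <- c(rej_reason, conditionMessage(v))
      warning(sprintf("skipping molecule '%s': %s", m$id, conditionMessage(v)),
              call. = FALSE)
    } else {
      rows[[m$id]] <- v
    }
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(descriptor_names),
           dimnames = list(NULL, descriptor_names))
  list(matrix = mat,
       rejects = data.frame(id = rej_id, reason = rej_reason,
                            stringsAsFactors = FALSE))
}
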