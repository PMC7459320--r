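# Graph machinery behind the topological descriptors. The heavy-atom graph is
# handled through igraph (distances, bridges, components); path enumeration
# and smallest-ring extraction are small exact searches adequate for
# ligand-sized molecules.

HETERO <- c("N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Se", "Si", "As")
HALOGENS <- c("F", "Cl", "Br", "I")

VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                       S = 6, Cl = 7, As = 5, Se = 6, Br = 7, I = 7)
ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                   S = 16, Cl = 17, As = 33, Se = 34, Br = 35, I = 53)
ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453,
                 As = 74.922, Se = 78.971, Br = 79.904, I = 126.904)

# Build the per-molecule context consumed by the descriptor registry.
mol_context <- function(mol) {
  el <- mol$elements
  n <- length(el)
  heavy <- which(el != "H")
  bonds <- mol$bonds
  deg_all <- integer(n)
  hcount <- integer(n)       # explicit H neighbours per atom
  nbr <- rep(list(integer(0)), n)
  border <- rep(list(integer(0)), n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]; o <- bonds[r, 3]
      nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
      border[[i]] <- c(border[[i]], o); border[[j]] <- c(border[[j]], o)
      deg_all[i] <- deg_all[i] + 1L; deg_all[j] <- deg_all[j] + 1L
      if (el[j] == "H") hcount[i] <- hcount[i] + 1L
      if (el[i] == "H") hcount[j] <- hcount[j] + 1L
    }
  }
  # heavy-atom subgraph with re-indexed vertices
  hmap <- integer(n); hmap[heavy] <- seq_along(heavy)
  hb <- bonds[bonds[, 1] %in% heavy & bonds[, 2] %in% heavy, , drop = FALSE]
  hbonds <- cbind(i = hmap[hb[, 1]], j = hmap[hb[, 2]], order = hb[, 3])
  nh <- length(heavy)
  g <- igraph::make_empty_graph(n = nh, directed = FALSE)
  if (nrow(hbonds) > 0) {
    g <- igraph::add_edges(g, as.vector(t(hbonds[, 1:2, drop = FALSE])))
  }
  hadj <- rep(list(integer(0)), nh)
  if (nrow(hbonds) > 0) {
    for (r in seq_len(nrow(hbonds))) {
      hadj[[hbonds[r, 1]]] <- c(hadj[[hbonds[r, 1]]], hbonds[r, 2])
      hadj[[hbonds[r, 2]]] <- c(hadj[[hbonds[r, 2]]], hbonds[r, 1])
    }
  }
  rings <- find_rings(hadj, hbonds, nh)
  arom <- perceive_aromatic(el[heavy], hbonds, rings)
  list(mol = mol, el = el, n = n, heavy = heavy, bonds = bonds,
       deg_all = deg_all, hcount = hcount, nbr = nbr, border = border,
       hel = el[heavy], hbonds = hbonds, hadj = hadj, nheavy = nh,
       graph = g, rings = rings,
       aromatic_atoms = arom$atoms, aromatic_rings = arom$rings)
}

# Smallest ring through each non-bridge edge; unique vertex sets.
find_rings <- function(hadj, hbonds, nh) {
  if (nrow(hbonds) == 0 || nh < 3) return(list())
  rings <- list()
  seen <- character(0)
  for (r in seq_len(nrow(hbonds))) {
    u <- hbonds[r, 1]; v <- hbonds[r, 2]
    path <- bfs_shortest_path(hadj, u, v, skip_edge = c(u, v))
    if (is.null(path)) next
    ring <- sort(path)
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  rings
}

bfs_shortest_path <- function(hadj, from, to, skip_edge) {
  n <- length(hadj)
  prev <- integer(n); prev[] <- -1L
  prev[from] <- from
  queue <- from
  while (length(queue) > 0) {
    x <- queue[1]; queue <- queue[-1]
    for (y in hadj[[x]]) {
      if ((x == skip_edge[1] && y == skip_edge[2]) ||
          (x == skip_edge[2] && y == skip_edge[1])) next
      if (prev[y] == -1L) {
        prev[y] <- x
        if (y == to) {
          path <- y
          while (path[1] != from) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, y)
      }
    }
  }
  NULL
}

# Kekulized aromaticity rule: 5/6-rings of C/N/O/S whose in-ring double-bond
# count matches an alternating pattern (3 for 6-rings, 2 for 5-rings).
perceive_aromatic <- function(hel, hbonds, rings) {
  atoms <- logical(length(hel))
  arings <- list()
  if (length(rings) == 0) return(list(atoms = atoms, rings = arings))
  key <- paste(pmin(hbonds[, 1], hbonds[, 2]), pmax(hbonds[, 1], hbonds[, 2]))
  order_of <- setNames(hbonds[, 3], key)
  for (ring in rings) {
    sz <- length(ring)
    if (!sz %in% c(5L, 6L)) next
    if (!all(hel[ring] %in% c("C", "N", "O", "S"))) next
    edges <- cbind(ring, c(ring[-1], ring[1]))
    k <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    orders <- order_of[k]
    if (any(is.na(orders)) || any(!orders %in% c(1L, 2L))) next
    ndouble <- sum(orders == 2L)
    if ((sz == 6L && ndouble == 3L) || (sz == 5L && ndouble == 2L)) {
      atoms[ring] <- TRUE
      arings[[length(arings) + 1L]] <- ring
    }
  }
  list(atoms = atoms, rings = arings)
}

# Undirected simple paths with `len` edges in the heavy graph, each counted once.
count_paths <- function(hadj, len) {
  n <- length(hadj)
  if (n == 0) return(matrix(integer(0), ncol = len + 1L))
  acc <- list()
  walk <- function(path) {
    if (length(path) == len + 1L) {
      if (path[1] < path[length(path)]) acc[[length(acc) + 1L]] <<- path
      return(invisible())
    }
    for (y in hadj[[path[length(path)]]]) {
      if (!y %in% path) walk(c(path, y))
    }
  }
  for (v in seq_len(n)) walk(v)
  if (length(acc) == 0) return(matrix(integer(0), ncol = len + 1L))
  do.call(rbind, acc)
}
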