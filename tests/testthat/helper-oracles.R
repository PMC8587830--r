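# Independent oracles used to anchor the implementation: brute-force
# geometry scans, an exhaustive shortest-path enumerator for betweenness,
# and a full dynamic-programming global aligner. None of these share code
# with the package internals they check.

# --- geometry ---------------------------------------------------------------

oracle_min_dist <- function(A, B) {
  best <- Inf
  for (a in seq_len(nrow(A))) {
    for (b in seq_len(nrow(B))) {
      d <- sqrt(sum((A[a, ] - B[b, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# O(L^2) all-pairs contact scan straight off the atom table
oracle_contacts <- function(s, cutoff, scheme = "all_atom",
                            min_separation = 2) {
  at <- s$atoms
  if (scheme == "ca") at <- at[at$elety == "CA", , drop = FALSE]
  L <- nrow(s$residues)
  out <- list()
  for (i in seq_len(L - 1)) {
    Ai <- as.matrix(at[at$res_index == i, c("x", "y", "z"), drop = FALSE])
    if (nrow(Ai) == 0) next
    for (j in seq((i + 1), L)) {
      if (j - i < max(min_separation, 1)) next
      Bj <- as.matrix(at[at$res_index == j, c("x", "y", "z"), drop = FALSE])
      if (nrow(Bj) == 0) next
      if (oracle_min_dist(Ai, Bj) <= cutoff)
        out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# --- betweenness ------------------------------------------------------------

# exhaustive enumeration of every shortest path between every node pair
oracle_betweenness <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  bfs_dist <- function(src) {
    d <- rep(Inf, n); d[src] <- 0
    q <- src
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.infinite(d[w])) {
        d[w] <- d[v] + 1; q <- c(q, w)
      }
    }
    d
  }
  bc <- numeric(n)
  if (n < 3) return(bc)
  for (u in seq_len(n - 1)) {
    for (v in seq(u + 1, n)) {
      dv <- bfs_dist(v)
      if (is.infinite(dv[u])) next
      paths <- list()
      walk <- function(node, acc) {
        if (node == v) {
          paths[[length(paths) + 1]] <<- acc
          return(invisible())
        }
        for (w in adj[[node]]) if (dv[w] == dv[node] - 1) walk(w, c(acc, w))
      }
      walk(u, u)
      sigma <- length(paths)
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tt <- table(interior)
        idx <- as.integer(names(tt))
        bc[idx] <- bc[idx] + as.numeric(tt) / sigma
      }
    }
  }
  bc
}

random_graph <- function(n, p_edge = 0.4) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  storage.mode(edges) <- "integer"
  list(n_nodes = n, edges = edges)
}

# --- global affine-gap alignment score --------------------------------------

# full three-state DP (match / gap-in-target / gap-in-reference); a gap of
# length g costs open + g * extend, matching the needle-style convention
oracle_align_score <- function(a, b, subst, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- subst[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sc
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# --- hand-written PDB text fixtures -----------------------------------------

pdb_atom_line <- function(type, serial, name, alt, resn, chain, resno, x, y,
                          z, occ = 1.00) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, paste0(" ", name), alt, resn, chain, resno,
          x, y, z, occ, 0)
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# three-residue Gly-Ala-Ser single-chain toy structure; CA-only, residues
# spaced `spacing` apart along x
toy_gas_pdb <- function(path, spacing = 4, extra_lines = character()) {
  resn <- c("GLY", "ALA", "SER")
  lines <- vapply(1:3, function(k)
    pdb_atom_line("ATOM", k, "CA", " ", resn[k], "A", k,
                  (k - 1) * spacing, 0, 0), "")
  write_toy_pdb(path, c(lines, extra_lines))
}
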