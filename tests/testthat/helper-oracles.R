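# Brute-force reference implementations, independent of the package kernels:
# explicit pairwise-adjacency matrices, label-rewriting simulation and
# per-threshold flood fills instead of union-find sweeps.

axis_count <- c(`6` = 1L, `18` = 2L, `26` = 3L)

# pairwise grid adjacency of a small set of voxel coordinates (n x 3, z y x)
oracle_adjacency <- function(coord, connectivity) {
  ad <- function(a) abs(outer(coord[, a], coord[, a], "-"))
  dz <- ad(1); dy <- ad(2); dx <- ad(3)
  nax <- (dz != 0) + (dy != 0) + (dx != 0)
  pmax(dz, pmax(dy, dx)) <= 1 & nax >= 1 & nax <= axis_count[as.character(connectivity)]
}

# connected components by repeated flood fill over the adjacency matrix
oracle_components_idx <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    nc <- nc + 1L
    frontier <- s; comp[s] <- nc
    while (length(frontier) > 0L) {
      nxt <- which(comp == 0L & apply(adj[frontier, , drop = FALSE], 2, any))
      comp[nxt] <- nc
      frontier <- nxt
    }
  }
  comp
}

oracle_components <- function(mask, connectivity) {
  lin <- which(mask)
  out <- array(0L, dim(mask))
  if (length(lin) == 0L) return(out)
  coord <- arrayInd(lin, dim(mask))
  comp <- oracle_components_idx(oracle_adjacency(coord, connectivity))
  out[lin] <- comp
  out
}

# superlevel-sweep clustering simulation: one voxel enters at a time in
# decreasing density (lexicographic ties); cluster membership is held in a
# plain per-node assignment vector and merges rewrite labels wholesale
oracle_tomato <- function(dens, mask, connectivity, delta) {
  dm <- dim(dens)
  lin <- which(mask)
  coord <- arrayInd(lin, dm)
  f <- dens[lin]
  ord <- order(-f, coord[, 1], coord[, 2], coord[, 3])
  lin <- lin[ord]; coord <- coord[ord, , drop = FALSE]; f <- f[ord]
  n <- length(lin)
  adj <- oracle_adjacency(coord, connectivity)
  assign <- rep(NA_integer_, n)
  peak_of <- integer(0)          # founding node per cluster id
  ncl <- 0L
  for (v in seq_len(n)) {
    nb <- if (v == 1L) integer(0) else which(adj[v, seq_len(v - 1L)])
    if (length(nb) == 0L) {
      ncl <- ncl + 1L; assign[v] <- ncl; peak_of[ncl] <- v
      next
    }
    cl <- unique(assign[nb])
    assign[v] <- assign[min(nb)]     # earliest-processed = steepest neighbor
    cmax <- cl[which.min(peak_of[cl])]
    for (c2 in cl)
      if (c2 != cmax && f[peak_of[c2]] - f[v] < delta)
        assign[assign == c2] <- cmax
  }
  out <- array(0L, dm)
  out[lin] <- assign
  out
}

# elder-rule persistence pairs by per-threshold flood fill (small inputs,
# distinct densities): each local-max peak dies at the highest density level
# at which its superlevel component contains a higher peak
oracle_persistence_pairs <- function(dens, mask, connectivity) {
  dm <- dim(dens)
  lin <- which(mask)
  coord <- arrayInd(lin, dm)
  f <- dens[lin]
  n <- length(lin)
  adj <- oracle_adjacency(coord, connectivity)
  is_peak <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    length(nb) == 0L || all(f[nb] < f[i])
  }, TRUE)
  peaks <- which(is_peak)
  levels <- sort(unique(f), decreasing = TRUE)
  death <- rep(NA_real_, length(peaks))
  for (alpha in levels) {
    sub <- which(f >= alpha)
    comp <- oracle_components_idx(adj[sub, sub, drop = FALSE])
    for (k in seq_along(peaks)) {
      if (!is.na(death[k])) next
      p <- match(peaks[k], sub)
      if (is.na(p)) next
      same <- sub[comp == comp[p]]
      if (any(f[same] > f[peaks[k]])) death[k] <- alpha
    }
  }
  # survivors are component global peaks: death = component minimum
  compfull <- oracle_components_idx(adj)
  for (k in seq_along(peaks))
    if (is.na(death[k])) death[k] <- min(f[compfull == compfull[peaks[k]]])
  data.frame(birth = f[peaks], death = death)
}

# exhaustive argmax of between-class variance over all histogram bin edges,
# with class statistics computed from the raw values
oracle_otsu <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  best <- -Inf; bt <- NA_real_
  for (k in 2:n_bins) {
    t <- edges[k]
    g1 <- x >= t
    if (!any(g1) || all(g1)) next
    w1 <- mean(g1); w0 <- 1 - w1
    sb <- w0 * w1 * (mean(x[!g1]) - mean(x[g1]))^2
    if (sb > best) { best <- sb; bt <- t }
  }
  bt
}

# per-voxel double loop overlap tally
oracle_overlap <- function(clab, nlab) {
  out <- list()
  for (i in seq_along(clab)) {
    if (clab[i] > 0L && nlab[i] > 0L) {
      key <- paste(clab[i], nlab[i])
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(cluster = integer(), nucleus = integer(), voxels = integer()))
  parts <- do.call(rbind, strsplit(names(out), " "))
  df <- data.frame(cluster = as.integer(parts[, 1]),
                   nucleus = as.integer(parts[, 2]),
                   voxels = unlist(out, use.names = FALSE))
  df[order(df$cluster, df$nucleus), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# multi-source geodesic assignment by explicit per-seed Dijkstra over the
# dense distance matrix (small clusters only)
oracle_geodesic <- function(coord, seed_of, spacing, connectivity) {
  n <- nrow(coord)
  adj <- oracle_adjacency(coord, connectivity)
  w <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (adj[i, j]) {
    d <- (coord[i, ] - coord[j, ]) * spacing
    w[i, j] <- sqrt(sum(d^2))
  }
  diag(w) <- 0
  # Floyd-Warshall all-pairs shortest paths
  for (k in seq_len(n)) {
    via <- outer(w[, k], w[k, ], "+")
    w <- pmin(w, via)
  }
  seeds <- sort(unique(seed_of[seed_of > 0L]))
  dmin <- vapply(seeds, function(s)
    apply(w[, seed_of == s, drop = FALSE], 1, min), numeric(n))
  assigned <- seeds[apply(dmin, 1, which.min)]  # which.min ties -> first = smaller id
  assigned
}

# canonical relabeling: clusters numbered by first occurrence in scan order
canon_labels <- function(lab) {
  v <- as.vector(lab)
  u <- unique(v[v > 0L])
  m <- integer(max(c(0L, u)))
  m[u] <- seq_along(u)
  out <- v
  out[v > 0L] <- m[v[v > 0L]]
  array(out, dim(lab))
}
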