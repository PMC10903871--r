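#' Parameters for synthetic scene generation
#'
#' Describes a two-channel 3D stack of ramified cells: each cell is a
#' spherical soma with random-walk branched processes, a bright nuclear
#' sphere inside the soma, a plateau intensity with a centerline-peaked
#' (distance-to-surface) ramp so every cell carries one dominant density
#' peak, optional Gaussian blur and noise, and an optional fraction of
#' physically touching cell pairs (adjacent but voxel-disjoint).
#'
#' @param shape grid dimensions `(z, y, x)` in voxels.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @param n_cells number of cells.
#' @param soma_radius_um soma radius range (uniform draw), micrometres.
#' @param n_branches branch count range per cell.
#' @param branch_length_um branch length range, micrometres.
#' @param branch_radius_um branch tube radius, micrometres.
#' @param tortuosity step-direction jitter of the branch random walk
#'   (0 = straight).
#' @param nucleus_radius_um nuclear radius, micrometres; must be smaller than
#'   the minimum soma radius.
#' @param touching_pair_fraction fraction of cells placed as touching pairs,
#'   in `[0, 1]`.
#' @param plateau base intensity of the cell body (intensity units).
#' @param ramp_per_um intensity rise per micrometre of depth below the cell
#'   surface (gives the soma center its dominant peak).
#' @param nucleus_intensity intensity of the nuclear spheres.
#' @param background background intensity level.
#' @param psf_sigma_um Gaussian blur sigma in micrometres (0 = none).
#' @param noise_sd additive Gaussian noise standard deviation (default 5% of
#'   the plateau); 0 = none.
#' @param poisson_noise replace each voxel by a Poisson draw at its intensity.
#' @param seed RNG seed; scenes are bit-identical for a fixed seed.
#' @return A `synth_params` object.
#' @export
synth_params <- function(shape = c(64L, 128L, 128L),
                         spacing_um = c(1, 0.5, 0.5),
                         n_cells = 4L,
                         soma_radius_um = c(3.5, 5),
                         n_branches = c(2L, 5L),
                         branch_length_um = c(8, 16),
                         branch_radius_um = 0.9,
                         tortuosity = 0.35,
                         nucleus_radius_um = 2.5,
                         touching_pair_fraction = 0,
                         plateau = 100,
                         ramp_per_um = 15,
                         nucleus_intensity = 200,
                         background = 10,
                         psf_sigma_um = 0.4,
                         noise_sd = 5,
                         poisson_noise = FALSE,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            all(soma_radius_um > 0), nucleus_radius_um > 0,
            nucleus_radius_um < min(soma_radius_um),
            touching_pair_fraction >= 0, touching_pair_fraction <= 1)
  structure(list(shape = as.integer(shape), spacing_um = check_spacing(spacing_um),
                 n_cells = as.integer(n_cells), soma_radius_um = soma_radius_um,
                 n_branches = as.integer(n_branches),
                 branch_length_um = branch_length_um,
                 branch_radius_um = branch_radius_um, tortuosity = tortuosity,
                 nucleus_radius_um = nucleus_radius_um,
                 touching_pair_fraction = touching_pair_fraction,
                 plateau = plateau, ramp_per_um = ramp_per_um,
                 nucleus_intensity = nucleus_intensity, background = background,
                 psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "synth_params")
}

# physical coordinates (um) of every voxel center, one axis at a time
axis_coords <- function(shape, spacing) lapply(1:3, function(a)
  (seq_len(shape[a]) - 0.5) * spacing[a])

#' Generate a synthetic two-channel scene
#'
#' Rasterizes the cells described by `params` into a nuclei + cell-marker
#' [image_stack] with exact ground-truth instance labels for cells and
#' nuclei. Touching pairs share at least one adjacent voxel pair but no
#' voxel; contested voxels go to the earlier cell. Intensities are the
#' maximum over primitives of `plateau + ramp_per_um * depth`, where depth
#' is the analytic distance below the primitive surface, then blur, noise,
#' and rounding to integers are applied.
#'
#' @param params a [synth_params] object.
#' @return A `synth_scene`: `stack` (channels nuclei, cells), `gt_cells`,
#'   `gt_nuclei` ([label_volume]s), and the params.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  sp <- p$spacing_um
  extent <- p$shape * sp
  margin <- max(p$soma_radius_um) + max(p$branch_length_um) * 0.4

  n_pairs <- floor(round(p$touching_pair_fraction * p$n_cells) / 2)
  centers <- place_somata(p, extent, margin, n_pairs)
  radii <- centers$radii; ctr <- centers$ctr; pair_of <- centers$pair_of

  cell_int <- array(0, dim = p$shape)   # cell-channel intensity before blur
  gt_cells <- array(0L, dim = p$shape)
  gt_nuclei <- array(0L, dim = p$shape)
  nuc_int <- array(0, dim = p$shape)
  # voxels of earlier cells dilated by one step: branches never enter, so
  # distinct (non-pair) cells stay non-adjacent in the thresholded mask
  occ_dilated <- array(FALSE, dim = p$shape)

  for (i in seq_len(p$n_cells)) {
    vox <- rasterize_cell(p, ctr[i, ], radii[i], pair_of[i], ctr, occ_dilated)
    free <- gt_cells[vox$lin] == 0L       # earlier cells keep contested voxels
    gt_cells[vox$lin[free]] <- i
    cell_int[vox$lin[free]] <- pmax(cell_int[vox$lin[free]], vox$intensity[free])
    nuc <- sphere_voxels(p$shape, sp, ctr[i, ], p$nucleus_radius_um)
    nuc <- nuc$lin[gt_cells[nuc$lin] == i] # nucleus stays inside its own soma
    gt_nuclei[nuc] <- i
    nuc_int[nuc] <- p$nucleus_intensity
    mine <- vox$lin[free]
    occ_dilated[c(mine, dilate_lin(mine, p$shape))] <- TRUE
  }

  cells_ch <- cell_int + p$background
  nuclei_ch <- nuc_int + p$background
  if (p$psf_sigma_um > 0) {
    cells_ch <- gaussian_blur3d(cells_ch, p$psf_sigma_um / sp)
    nuclei_ch <- gaussian_blur3d(nuclei_ch, p$psf_sigma_um / sp)
  }
  if (p$poisson_noise) {
    cells_ch <- array(rpois(length(cells_ch), pmax(cells_ch, 0)), dim = p$shape)
    nuclei_ch <- array(rpois(length(nuclei_ch), pmax(nuclei_ch, 0)), dim = p$shape)
  }
  if (p$noise_sd > 0) {
    cells_ch <- cells_ch + rnorm(length(cells_ch), 0, p$noise_sd)
    nuclei_ch <- nuclei_ch + rnorm(length(nuclei_ch), 0, p$noise_sd)
  }
  cells_ch <- round(pmin(pmax(cells_ch, 0), 65535))
  nuclei_ch <- round(pmin(pmax(nuclei_ch, 0), 65535))

  stack <- array(0, dim = c(2L, p$shape))
  stack[1, , , ] <- nuclei_ch
  stack[2, , , ] <- cells_ch
  structure(list(stack = image_stack(stack, sp, c("nuclei", "cells")),
                 gt_cells = label_volume(gt_cells, sp),
                 gt_nuclei = label_volume(gt_nuclei, sp),
                 params = p),
            class = "synth_scene")
}

# soma centers: touching pairs placed so their rasterized somata share no
# voxel but at least one 26-adjacent pair (distance found by a short search);
# singles separated enough that somata plus clearance-limited branches never
# meet. Retries the random placement until all constraints hold.
place_somata <- function(p, extent, margin, n_pairs) {
  n <- p$n_cells
  radii <- runif(n, p$soma_radius_um[1], p$soma_radius_um[2])
  ctr <- matrix(NA_real_, n, 3)
  pair_of <- rep(NA_integer_, n)
  sep_gap <- 2 * max(p$soma_radius_um) + 4
  lo <- pmin(margin, extent / 2 - 1); hi <- extent - lo
  draw <- function() vapply(1:3, function(a) runif(1, lo[a], hi[a]), 0)
  placed <- 0L
  for (k in seq_len(n_pairs)) {
    r1 <- radii[placed + 1L]; r2 <- radii[placed + 2L]
    ok <- FALSE
    for (try in 1:200) {
      c1 <- draw()
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      d <- touching_distance(p, c1, dirv, r1, r2)
      if (is.na(d)) next
      c2 <- c1 + dirv * d
      if (any(c2 < lo) || any(c2 > hi)) next
      if (placed > 0L && min_center_dist(ctr[seq_len(placed), , drop = FALSE],
                                         rbind(c1, c2)) < sep_gap) next
      ctr[placed + 1L, ] <- c1; ctr[placed + 2L, ] <- c2
      pair_of[placed + 1L] <- placed + 2L; pair_of[placed + 2L] <- placed + 1L
      placed <- placed + 2L; ok <- TRUE; break
    }
    if (!ok) stop("cannot place touching pair ", k, " without overlap")
  }
  while (placed < n) {
    ok <- FALSE
    for (try in 1:200) {
      c1 <- draw()
      if (placed > 0L && min_center_dist(ctr[seq_len(placed), , drop = FALSE],
                                         rbind(c1)) < sep_gap) next
      ctr[placed + 1L, ] <- c1; placed <- placed + 1L; ok <- TRUE; break
    }
    if (!ok) stop("cannot place cell ", placed + 1L, " without overlap")
  }
  list(radii = radii, ctr = ctr, pair_of = pair_of)
}

# smallest center distance along `dirv` at which the two rasterized somata
# are voxel-disjoint; NA if they are then not 26-adjacent either
touching_distance <- function(p, c1, dirv, r1, r2) {
  v1 <- sphere_voxels(p$shape, p$spacing_um, c1, r1)$lin
  for (d in seq(r1 + r2, r1 + r2 + 3 * max(p$spacing_um), by = 0.1)) {
    c2 <- c1 + dirv * d
    if (any(c2 < 0) || any(c2 > p$shape * p$spacing_um)) return(NA_real_)
    v2 <- sphere_voxels(p$shape, p$spacing_um, c2, r2)$lin
    if (length(intersect(v1, v2)) > 0L) next
    if (count_adjacent_pairs_cpp(p$shape, v1, v2, 26L) > 0) return(d)
    return(NA_real_)
  }
  NA_real_
}

# all voxels one 26-step away from the given set (clipped at the borders)
dilate_lin <- function(lin, dm) {
  zyx <- lin_to_zyx(lin, dm)
  out <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    z <- zyx[, 1] + dz; y <- zyx[, 2] + dy; x <- zyx[, 3] + dx
    keep <- z >= 1 & z <= dm[1] & y >= 1 & y <= dm[2] & x >= 1 & x <= dm[3]
    out <- c(out, z[keep] + (y[keep] - 1L) * dm[1] +
               (x[keep] - 1L) * dm[1] * dm[2])
  }
  unique(out)
}

min_center_dist <- function(a, b) {
  min(apply(b, 1, function(q) sqrt(min(colSums((t(a) - q)^2)))))
}

# voxels within radius r of a point; returns linear indices and depth (um)
sphere_voxels <- function(shape, sp, center, r) {
  box <- lapply(1:3, function(a) {
    rng <- floor((center[a] - r) / sp[a]):ceiling((center[a] + r) / sp[a] + 1)
    rng[rng >= 1 & rng <= shape[a]]
  })
  g <- expand.grid(z = box[[1]], y = box[[2]], x = box[[3]])
  pz <- (g$z - 0.5) * sp[1]; py <- (g$y - 0.5) * sp[2]; px <- (g$x - 0.5) * sp[3]
  d <- sqrt((pz - center[1])^2 + (py - center[2])^2 + (px - center[3])^2)
  keep <- d <= r
  lin <- g$z[keep] + (g$y[keep] - 1L) * shape[1] +
    (g$x[keep] - 1L) * shape[1] * shape[2]
  list(lin = as.integer(lin), depth = r - d[keep])
}

# capsule around a segment; depth = tube radius minus distance to the segment
segment_voxels <- function(shape, sp, a, b, r) {
  lo_um <- pmin(a, b) - r; hi_um <- pmax(a, b) + r
  box <- lapply(1:3, function(ax) {
    rng <- floor(lo_um[ax] / sp[ax]):ceiling(hi_um[ax] / sp[ax] + 1)
    rng[rng >= 1 & rng <= shape[ax]]
  })
  if (any(lengths(box) == 0L)) return(list(lin = integer(), depth = numeric()))
  g <- expand.grid(z = box[[1]], y = box[[2]], x = box[[3]])
  pt <- cbind((g$z - 0.5) * sp[1], (g$y - 0.5) * sp[2], (g$x - 0.5) * sp[3])
  ab <- b - a; ab2 <- sum(ab^2)
  t <- if (ab2 == 0) rep(0, nrow(pt)) else
    pmin(pmax((sweep(pt, 2, a) %*% ab) / ab2, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  d <- sqrt(rowSums((pt - proj)^2))
  keep <- d <= r
  lin <- g$z[keep] + (g$y[keep] - 1L) * shape[1] +
    (g$x[keep] - 1L) * shape[1] * shape[2]
  list(lin = as.integer(lin), depth = r - d[keep])
}

# one cell: soma sphere + branch random walks; intensity = plateau +
# ramp * depth, max-combined across primitives. Branches stop growing when
# the next segment would enter the one-voxel clearance zone of earlier cells
# or approach any other soma, so only deliberate touching pairs ever meet.
rasterize_cell <- function(p, center, soma_r, partner, all_ctr, occ_dilated) {
  sp <- p$spacing_um
  s <- sphere_voxels(p$shape, sp, center, soma_r)
  acc_lin <- s$lin; acc_depth <- s$depth
  others <- setdiff(seq_len(nrow(all_ctr)), c(which(is.na(all_ctr[, 1]))))
  others <- setdiff(others, which(apply(all_ctr, 1, function(q)
    all(q == center))))
  clear_um <- max(p$soma_radius_um) + p$branch_radius_um + 2 * max(sp)
  nb <- if (p$n_branches[1] == p$n_branches[2]) p$n_branches[1] else
    sample(p$n_branches[1]:p$n_branches[2], 1)
  for (b in seq_len(nb)) {
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    if (!is.na(partner)) {
      # aim touching-pair branches away from the partner soma
      away <- center - all_ctr[partner, ]; away <- away / sqrt(sum(away^2))
      if (sum(dirv * away) < 0.2) dirv <- away + 0.5 * dirv
      dirv <- dirv / sqrt(sum(dirv^2))
    }
    len <- runif(1, p$branch_length_um[1], p$branch_length_um[2])
    step <- 1.0
    pos <- center + dirv * (soma_r * 0.8)
    travelled <- 0
    while (travelled < len) {
      dirv <- dirv + p$tortuosity * rnorm(3)
      dirv <- dirv / sqrt(sum(dirv^2))
      nxt <- pos + dirv * step
      if (length(others) > 0L &&
          min(sqrt(colSums((t(all_ctr[others, , drop = FALSE]) - nxt)^2))) <
            clear_um) break
      seg <- segment_voxels(p$shape, sp, pos, nxt, p$branch_radius_um)
      if (any(occ_dilated[seg$lin])) break
      acc_lin <- c(acc_lin, seg$lin); acc_depth <- c(acc_depth, seg$depth)
      pos <- nxt; travelled <- travelled + step
    }
  }
  # max depth per voxel
  o <- order(acc_lin, -acc_depth)
  acc_lin <- acc_lin[o]; acc_depth <- acc_depth[o]
  keep <- !duplicated(acc_lin)
  list(lin = acc_lin[keep],
       intensity = p$plateau + p$ramp_per_um * acc_depth[keep])
}

# separable Gaussian blur by circular FFT convolution; sigma in voxels per
# axis. Objects are placed with a margin, so wrap-around is immaterial.
gaussian_blur3d <- function(x, sigma_vox) {
  dm <- dim(x)
  kern <- lapply(1:3, function(a) {
    n <- dm[a]
    if (sigma_vox[a] <= 0) return(c(1, rep(0, n - 1)))
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-d^2 / (2 * sigma_vox[a]^2))
    k / sum(k)
  })
  K <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  dim(K) <- dm
  out <- Re(fft(fft(x) * fft(K), inverse = TRUE)) / length(x)
  array(out, dim = dm)
}

#' @export
print.synth_scene <- function(x, ...) {
  cat(sprintf("synth_scene: %d cell(s) on %s grid (seed %d)\n",
              x$params$n_cells, paste(x$params$shape, collapse = "x"),
              x$params$seed))
  invisible(x)
}

#' Ground-truth manifest of a synthetic scene
#'
#' @param scene a `synth_scene`.
#' @return Tibble with one row per cell: centroid (voxel coordinates), voxel
#'   count and volume in cubic micrometres.
#' @export
scene_manifest <- function(scene) {
  stopifnot(inherits(scene, "synth_scene"))
  lab <- scene$gt_cells$labels
  sp <- scene$gt_cells$spacing_um
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  rows <- lapply(ids, function(i) {
    lin <- which(lab == i)
    zyx <- lin_to_zyx(lin, dim(lab))
    tibble::tibble(cell = i, voxels = length(lin),
                   volume_um3 = length(lin) * prod(sp),
                   centroid_z = mean(zyx[, 1]), centroid_y = mean(zyx[, 2]),
                   centroid_x = mean(zyx[, 3]))
  })
  if (length(rows) == 0L)
    return(tibble::tibble(cell = integer(), voxels = integer(),
                          volume_um3 = double(), centroid_z = double(),
                          centroid_y = double(), centroid_x = double()))
  dplyr::bind_rows(rows)
}
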