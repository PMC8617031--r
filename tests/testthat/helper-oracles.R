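# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (exhaustive enumeration, finite differences, grid
# search) so it shares no code path with the implementation it checks.

# best superposition RMSD by Euler-angle grid search with iterative
# refinement; optimal translation is centroid matching at every rotation
oracle_superpose_rmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  rot_zyz <- function(a, b, c) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                             3, 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                             3, 3, byrow = TRUE)
    rz(a) %*% ry(b) %*% rz(c)
  }
  rmsd_at <- function(a, b, c) {
    fitted <- A %*% t(rot_zyz(a, b, c))
    sqrt(mean(rowSums((fitted - B)^2)))
  }
  step0 <- pi / 6
  grid <- expand.grid(a = seq(-pi, pi, by = step0),
                      b = seq(0, pi, by = step0),
                      c = seq(-pi, pi, by = step0))
  vals <- vapply(seq_len(nrow(grid)), function(i)
    rmsd_at(grid$a[i], grid$b[i], grid$c[i]), 0)
  # refine around the several best coarse cells to dodge local basins
  starts <- order(vals)[1:8]
  best_val <- Inf
  for (sidx in starts) {
    best <- as.numeric(grid[sidx, ])
    val <- vals[sidx]
    step <- step0
    for (round in 1:10) {
      step <- step / 2
      loc <- expand.grid(a = best[1] + step * (-2:2),
                         b = best[2] + step * (-2:2),
                         c = best[3] + step * (-2:2))
      for (i in seq_len(nrow(loc))) {
        v <- rmsd_at(loc$a[i], loc$b[i], loc$c[i])
        if (v < val) { val <- v; best <- as.numeric(loc[i, ]) }
      }
    }
    if (val < best_val) best_val <- val
  }
  best_val
}

# naive recursive DBSCAN (region growing by depth-first search)
oracle_dbscan <- function(D, eps, min_pts) {
  n <- nrow(D)
  labels <- rep(0L, n)  # 0 = unvisited, -1 = noise
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_pts, TRUE)
  cl <- 0L
  grow <- function(i, cl) {
    labels[i] <<- cl
    for (j in which(D[i, ] <= eps)) {
      if (labels[j] <= 0L) {
        was_noise <- labels[j] == -1L
        labels[j] <<- cl
        if (core[j] && !was_noise) grow(j, cl)
        if (core[j] && was_noise) grow(j, cl)
      }
    }
  }
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (!core[i]) { labels[i] <- -1L; next }
    cl <- cl + 1L
    grow(i, cl)
  }
  labels
}

# exhaustive O(n^2) clash count
oracle_clash_count <- function(xyz_a, xyz_b, cutoff, exclude = NULL) {
  excl_key <- if (!is.null(exclude) && nrow(exclude))
    paste(exclude[, 1], exclude[, 2]) else character()
  count <- 0L
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      if (paste(i, j) %in% excl_key) next
      if (sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2)) < cutoff) count <- count + 1L
    }
  }
  count
}

# ANM spring energy of a configuration, contacts fixed at the reference
anm_energy <- function(xyz_flat, ref_xyz, cutoff, gamma) {
  n <- nrow(ref_xyz)
  xyz <- matrix(xyz_flat, n, 3, byrow = TRUE)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d0 <- sqrt(sum((ref_xyz[i, ] - ref_xyz[j, ])^2))
      if (d0 <= cutoff) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        e <- e + gamma / 2 * (d - d0)^2
      }
    }
  }
  e
}

# finite-difference Hessian of the ANM energy at equilibrium
oracle_fd_hessian <- function(ref_xyz, cutoff, gamma, h = 1e-4) {
  x0 <- as.numeric(t(ref_xyz))
  m <- length(x0)
  H <- matrix(0, m, m)
  for (k in seq_len(m)) {
    for (l in k:m) {
      xpp <- x0; xpp[k] <- xpp[k] + h; xpp[l] <- xpp[l] + h
      xpm <- x0; xpm[k] <- xpm[k] + h; xpm[l] <- xpm[l] - h
      xmp <- x0; xmp[k] <- xmp[k] - h; xmp[l] <- xmp[l] + h
      xmm <- x0; xmm[k] <- xmm[k] - h; xmm[l] <- xmm[l] - h
      H[k, l] <- H[l, k] <-
        (anm_energy(xpp, ref_xyz, cutoff, gamma) -
           anm_energy(xpm, ref_xyz, cutoff, gamma) -
           anm_energy(xmp, ref_xyz, cutoff, gamma) +
           anm_energy(xmm, ref_xyz, cutoff, gamma)) / (4 * h^2)
    }
  }
  H
}

# toy structure: atoms at given coordinates, one residue per atom, chain per
# the vector given (handy for clash and distance tests)
toy_points_structure <- function(xyz, chain = "A", name = "CA",
                                 element = "C") {
  n <- nrow(xyz)
  new_structure(data.frame(
    serial = seq_len(n), name = name, altloc = "", resname = "ALA",
    chain = rep_len(chain, n), resid = seq_len(n), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = element, het = FALSE,
    stringsAsFactors = FALSE
  ))
}

# CA RMSD between two structures sharing topology
ca_rmsd <- function(s1, s2) {
  ca <- select_atoms(s1, name = "CA")
  sqrt(mean(rowSums((coords(s1, ca) - coords(s2, ca))^2)))
}

# all bond lengths along a chain backbone (N-CA, CA-C, C-N), for exactness
# checks under dihedral manipulation
backbone_bond_lengths <- function(s, chain) {
  a <- s$atoms
  rows <- which(a$chain == chain & a$name %in% c("N", "CA", "C"))
  rows <- rows[order(a$resid[rows], match(a$name[rows], c("N", "CA", "C")))]
  xyz <- coords(s, rows)
  sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
}
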