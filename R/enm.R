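# Anisotropic network model on CA nodes: Hessian construction, eigenmodes,
# mode animation inside a CA-RMSD budget, and the two-mode combination scan
# that reseeds the network from selected frames of the second mode.

#' Build the CA elastic network of a complex
#'
#' One node per CA atom of the whole complex; springs of uniform stiffness
#' `gamma` connect node pairs closer than `cutoff`.
#'
#' @param s a `Structure`.
#' @param cutoff interaction cutoff in angstrom (default 15).
#' @param gamma uniform spring constant (arbitrary units, default 1).
#' @return an `elastic_network`: node coordinates, the CA atom indices, a node
#'   -> residue map, and the parameters.
#' @export
elastic_network <- function(s, cutoff = 15, gamma = 1) {
  stopifnot(cutoff > 0, gamma > 0)
  ca <- select_atoms(s, name = "CA", het = FALSE)
  if (length(ca) < 3) stop("elastic network needs at least 3 CA nodes")
  a <- s$atoms[ca, , drop = FALSE]
  structure(list(
    node_xyz = cbind(a$x, a$y, a$z),
    ca_idx = ca,
    node_map = data.frame(chain = a$chain, resid = a$resid, icode = a$icode,
                          stringsAsFactors = FALSE),
    cutoff = cutoff, gamma = gamma
  ), class = "elastic_network")
}

#' Anisotropic network model Hessian
#'
#' Standard ANM: for a contacting node pair \eqn{i \ne j} at separation
#' \eqn{d_{ij} \le cutoff}, the 3x3 super-element is
#' \eqn{H_{ij} = -(\gamma / d_{ij}^2)\, r_{ij} r_{ij}^T}, and diagonal blocks
#' are minus the sum of the off-diagonal blocks in their row, which puts the
#' six rigid-body motions in the null space.
#'
#' @param net an `elastic_network`.
#' @return symmetric 3N x 3N matrix.
#' @export
build_anm <- function(net) {
  xyz <- net$node_xyz
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  if (any(d2[upper.tri(d2)] < 1e-12))
    stop("coincident nodes in the elastic network")
  H <- matrix(0, 3 * n, 3 * n)
  cut2 <- net$cutoff^2
  for (i in seq_len(n - 1)) {
    js <- which(d2[i, ] <= cut2)
    js <- js[js > i]
    for (j in js) {
      r <- xyz[j, ] - xyz[i, ]
      block <- -(net$gamma / d2[i, j]) * (r %o% r)
      bi <- (3 * i - 2):(3 * i)
      bj <- (3 * j - 2):(3 * j)
      H[bi, bj] <- block
      H[bj, bi] <- block
      H[bi, bi] <- H[bi, bi] - block
      H[bj, bj] <- H[bj, bj] - block
    }
  }
  H
}

#' Normal modes of an ANM Hessian
#'
#' Diagonalises the Hessian with a dense symmetric eigensolver, discards every
#' eigenpair whose eigenvalue is below the zero threshold (rigid-body modes;
#' `1e-8` times the largest eigenvalue), and returns the `k` lowest-frequency
#' remaining modes — the "major" modes. Eigenvector sign is fixed by making
#' the largest-magnitude component positive so runs are reproducible.
#'
#' @param hessian 3N x 3N ANM Hessian.
#' @param k number of modes to keep.
#' @return a `mode_set`: `values` (ascending eigenvalues, length k), `vectors`
#'   (3N x k, unit columns), `n_zero_skipped`.
#' @export
normal_modes <- function(hessian, k = 5) {
  stopifnot(k >= 1)
  eg <- eigen(hessian, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, rev(seq_along(eg$values)), drop = FALSE]
  zero_thr <- 1e-8 * max(abs(vals))
  nonzero <- which(vals > zero_thr)
  if (k > length(nonzero))
    stop(sprintf("requested %d modes but only %d nonzero modes exist", k,
                 length(nonzero)))
  sel <- nonzero[seq_len(k)]
  V <- vecs[, sel, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
  }
  structure(list(values = vals[sel], vectors = V,
                 n_zero_skipped = min(nonzero) - 1L),
            class = "mode_set")
}

# per-atom displacement field for one mode: every atom of a residue moves
# rigidly with its CA node (per-residue rigid translation)
mode_atom_displacement <- function(s, net, mode_vec) {
  n_nodes <- nrow(net$node_xyz)
  disp_nodes <- matrix(mode_vec, ncol = 3, byrow = TRUE)
  key_nodes <- paste(net$node_map$chain, net$node_map$resid, net$node_map$icode)
  key_atoms <- residue_key(s$atoms)
  m <- match(key_atoms, key_nodes)
  if (anyNA(m))
    stop("structure contains residues without a CA node: cannot animate")
  disp_nodes[m, , drop = FALSE]
}

#' Animate one normal mode within a CA-RMSD budget
#'
#' Generates `n_frames` snapshots at amplitudes following one full sinusoidal
#' cycle, `a_t = A sin(2 pi t / n_frames)`, with the amplitude `A` chosen so
#' the largest frame-to-parent CA RMSD equals `rmsd_max`. Because the mode
#' vector has unit norm over the N CA nodes, `A = rmsd_max * sqrt(N)`. All
#' atoms of a residue translate rigidly with their CA node, so per-residue
#' internal geometry is conserved exactly.
#'
#' @param s parent `Structure`.
#' @param net its `elastic_network`.
#' @param modes a `mode_set` from [normal_modes()].
#' @param mode mode rank to animate (1 = lowest nonzero frequency).
#' @param n_frames frames per cycle (default 28).
#' @param rmsd_max CA RMSD envelope in angstrom (default 10).
#' @return a `conformer_ensemble`: parent structure, a list of n x 3
#'   coordinate frames, and a provenance table (mode, frame, amplitude).
#' @export
animate_mode <- function(s, net, modes, mode = 1, n_frames = 28,
                         rmsd_max = 10) {
  stopifnot(n_frames >= 2)
  if (mode < 1 || mode > ncol(modes$vectors)) stop("mode index out of range")
  v <- modes$vectors[, mode]
  if (sqrt(sum(v^2)) < 1e-12) stop("zero-norm mode vector")
  n_nodes <- nrow(net$node_xyz)
  A <- rmsd_max * sqrt(n_nodes)
  disp <- mode_atom_displacement(s, net, v)
  xyz0 <- coords(s)
  t_idx <- seq_len(n_frames)
  amps <- A * sin(2 * pi * t_idx / n_frames)
  frames <- lapply(amps, function(a) xyz0 + a * disp)
  structure(list(
    parent = s,
    frames = frames,
    provenance = data.frame(stage = "mode", mode = mode, frame = t_idx,
                            amplitude = amps)
  ), class = "conformer_ensemble")
}

#' Number of frames in a conformer ensemble
#' @param x a `conformer_ensemble`.
#' @export
n_frames <- function(x) length(x$frames)

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble: %d frames of %d atoms\n",
              length(x$frames), nrow(x$parent$atoms)))
  invisible(x)
}

# concatenate ensembles sharing a parent topology
bind_ensembles <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) length(p$frames) > 0, TRUE)]
  if (!length(parts))
    return(structure(list(parent = NULL, frames = list(),
                          provenance = data.frame()),
                     class = "conformer_ensemble"))
  all_cols <- unique(unlist(lapply(parts, function(p) names(p$provenance))))
  prov <- do.call(rbind, lapply(parts, function(p) {
    for (col in setdiff(all_cols, names(p$provenance)))
      p$provenance[[col]] <- NA
    p$provenance[all_cols]
  }))
  structure(list(parent = parts[[1]]$parent,
                 frames = do.call(c, lapply(parts, function(p) p$frames)),
                 provenance = prov),
            class = "conformer_ensemble")
}

#' Two-mode combination scan
#'
#' Selected frames of the second major mode become starting structures for a
#' fresh cycle of network analysis: for each picked frame the elastic network
#' is rebuilt on that frame's coordinates, the first major mode is recomputed,
#' and a full animation is emitted. With the defaults (picks 5, 10, 15, 20, 25
#' and 28 frames) this yields 140 conformers.
#'
#' @param s parent `Structure`.
#' @param secondary_frame_picks frame indices of the mode-2 animation used as
#'   restart points (default `c(5, 10, 15, 20, 25)`).
#' @param n_frames frames per animation (default 28).
#' @param rmsd_max CA RMSD envelope per animation (default 10).
#' @param cutoff,gamma elastic-network parameters.
#' @return a `conformer_ensemble` of `length(picks) * n_frames` frames with
#'   two-stage provenance.
#' @export
combined_mode_scan <- function(s, secondary_frame_picks = c(5, 10, 15, 20, 25),
                               n_frames = 28, rmsd_max = 10, cutoff = 15,
                               gamma = 1) {
  if (!length(secondary_frame_picks))
    return(structure(list(parent = s, frames = list(),
                          provenance = data.frame()),
                     class = "conformer_ensemble"))
  net <- elastic_network(s, cutoff = cutoff, gamma = gamma)
  modes <- normal_modes(build_anm(net), k = 2)
  stage1 <- animate_mode(s, net, modes, mode = 2, n_frames = n_frames,
                         rmsd_max = rmsd_max)
  if (any(secondary_frame_picks < 1 | secondary_frame_picks > n_frames))
    stop("secondary frame pick out of range")
  parts <- lapply(secondary_frame_picks, function(pick) {
    s2 <- set_coords(s, stage1$frames[[pick]])
    net2 <- elastic_network(s2, cutoff = cutoff, gamma = gamma)
    modes2 <- normal_modes(build_anm(net2), k = 1)
    ens <- animate_mode(s2, net2, modes2, mode = 1, n_frames = n_frames,
                        rmsd_max = rmsd_max)
    ens$provenance$stage <- "combined"
    ens$provenance$mode2_frame <- pick
    ens
  })
  out <- do.call(bind_ensembles, parts)
  out$parent <- s
  out
}
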