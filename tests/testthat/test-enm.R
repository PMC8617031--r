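# ANM Hessian, modes, animation, combined scan

two_node_structure <- function(d = 5) {
  toy_points_structure(rbind(c(0, 0, 0), c(d, 0, 0), c(0, 100, 0)))
}

test_that("the two-node super-element matches the closed form", {
  s <- toy_points_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4, 0)))
  net <- elastic_network(s, cutoff = 15, gamma = 1)
  H <- build_anm(net)
  # nodes 1-2 are 5 apart along x: off-diagonal block -(g/d^2) r r^T has a
  # single nonzero entry -1 at (x, x)
  block <- H[1:3, 4:6]
  expect_equal(block, diag(c(-1, 0, 0)), tolerance = 1e-12)
  expect_equal(H, t(H), tolerance = 1e-10)
})

test_that("rigid translations are in the null space by construction", {
  hc <- make_hinge_complex(hinge_complex_spec(seed = 2))
  H <- build_anm(elastic_network(hc$structure))
  n <- nrow(H) / 3
  tx <- rep(c(1, 0, 0), n)
  expect_lt(max(abs(H %*% tx)), 1e-10)
})

test_that("a triangle has exactly 6 numerically-zero eigenvalues and a
           disconnected network has more", {
  tri <- toy_points_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4, 0)))
  ev <- eigen(build_anm(elastic_network(tri)), symmetric = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(abs(ev))), 6)

  # two far-apart triangles: 12 rigid modes
  xyz2 <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4, 0),
                c(100, 0, 0), c(105, 0, 0), c(102.5, 4, 0))
  ev2 <- eigen(build_anm(elastic_network(toy_points_structure(xyz2))),
               symmetric = TRUE)$values
  expect_equal(sum(abs(ev2) < 1e-8 * max(abs(ev2))), 12)
})

test_that("an isolated spring has the closed-form stretch mode", {
  # two nodes joined by one spring; a third node beyond the cutoff only
  # satisfies the minimum network size and carries no springs
  s <- two_node_structure(5)
  net <- elastic_network(s, cutoff = 15, gamma = 1)
  H <- build_anm(net)
  ev <- eigen(H, symmetric = TRUE)
  nonzero <- ev$values[abs(ev$values) > 1e-8]
  expect_length(nonzero, 1)
  expect_equal(nonzero, 2, tolerance = 1e-10)  # 2 * gamma
  v <- ev$vectors[, 1]
  # anti-symmetric stretch along the bond axis
  expect_equal(abs(v), c(1, 0, 0, 1, 0, 0, 0, 0, 0) / sqrt(2),
               tolerance = 1e-8)
  expect_lt(sum(v[1:3] * v[4:6]), 0)
})

test_that("coincident nodes are rejected", {
  s <- toy_points_structure(rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0)))
  expect_error(build_anm(elastic_network(s)), "coincident")
})

test_that("the analytic Hessian matches a finite-difference oracle and its
           eigenpairs satisfy the eigen equations", {
  set.seed(11)
  for (n in c(6, 10)) {
    xyz <- matrix(runif(3 * n, 0, 12), n, 3)
    s <- toy_points_structure(xyz)
    net <- elastic_network(s, cutoff = 9, gamma = 1.3)
    H <- build_anm(net)
    expect_equal(H, oracle_fd_hessian(xyz, 9, 1.3), tolerance = 1e-5)
    k <- min(5, 3 * n - 6)
    ms <- normal_modes(H, k = k)
    expect_equal(ms$values, sort(ms$values))
    for (j in seq_len(k)) {
      resid <- H %*% ms$vectors[, j] - ms$values[j] * ms$vectors[, j]
      expect_lt(max(abs(resid)), 1e-8 * max(abs(ms$values)))
    }
    expect_equal(crossprod(ms$vectors), diag(k), tolerance = 1e-6)
  }
})

test_that("modes are orthogonal to all six rigid-body vectors", {
  hc <- make_hinge_complex(hinge_complex_spec(seed = 2))
  net <- elastic_network(hc$structure)
  ms <- normal_modes(build_anm(net), k = 5)
  n <- nrow(net$node_xyz)
  centred <- sweep(net$node_xyz, 2, colMeans(net$node_xyz))
  rigid <- cbind(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    as.numeric(t(cbind(0, -centred[, 3], centred[, 2]))),
    as.numeric(t(cbind(centred[, 3], 0, -centred[, 1]))),
    as.numeric(t(cbind(-centred[, 2], centred[, 1], 0)))
  )
  overlaps <- abs(t(rigid) %*% ms$vectors) /
    outer(sqrt(colSums(rigid^2)), rep(1, 5))
  expect_lt(max(overlaps), 1e-6)
})

test_that("requesting more modes than exist errors", {
  s <- toy_points_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4, 0)))
  H <- build_anm(elastic_network(s))
  expect_error(normal_modes(H, k = 4), "only 3 nonzero")
})

test_that("mode animation respects the RMSD envelope exactly", {
  hc <- make_hinge_complex(hinge_complex_spec(seed = 2))
  s <- hc$structure
  net <- elastic_network(s)
  ms <- normal_modes(build_anm(net), k = 5)
  ens <- animate_mode(s, net, ms, mode = 1, n_frames = 28, rmsd_max = 10)
  expect_equal(length(ens$frames), 28)
  rmsds <- vapply(ens$frames, function(fr)
    ca_rmsd(set_coords(s, fr), s), 0)
  expect_true(all(rmsds <= 10 + 1e-9))
  expect_equal(max(rmsds), 10, tolerance = 0.01)
  # the sin = 0 frame is the parent
  expect_equal(ens$frames[[28]], coords(s), tolerance = 1e-9)
  # closed-form amplitude: unit mode displacement has CA RMSD 1/sqrt(N)
  n_nodes <- nrow(net$node_xyz)
  expect_equal(max(abs(ens$provenance$amplitude)), 10 * sqrt(n_nodes),
               tolerance = 1e-6 * sqrt(n_nodes))
  # doubling the frame count leaves the envelope maximum unchanged within 1%
  ens2 <- animate_mode(s, net, ms, mode = 1, n_frames = 56, rmsd_max = 10)
  rmsds2 <- vapply(ens2$frames, function(fr) ca_rmsd(set_coords(s, fr), s), 0)
  expect_equal(max(rmsds2), max(rmsds), tolerance = 0.01)
})

test_that("per-residue internal geometry is conserved in animation frames", {
  hc <- make_hinge_complex(hinge_complex_spec(seed = 2))
  s <- hc$structure
  net <- elastic_network(s)
  ms <- normal_modes(build_anm(net), k = 1)
  ens <- animate_mode(s, net, ms, mode = 1, n_frames = 8, rmsd_max = 10)
  fr <- set_coords(s, ens$frames[[2]])
  res1 <- select_atoms(s, chain = "A", resid = 5)
  expect_equal(as.matrix(dist(coords(fr, res1))),
               as.matrix(dist(coords(s, res1))), tolerance = 1e-9)
})

test_that("combined scan emits picks x n_frames conformers with two-stage
           provenance, and restarted mode-1 vectors stay correlated", {
  hc <- make_hinge_complex(hinge_complex_spec(seed = 2))
  s <- hc$structure
  ens <- combined_mode_scan(s, secondary_frame_picks = c(5, 10, 15, 20, 25),
                            n_frames = 28)
  expect_equal(length(ens$frames), 140)
  expect_setequal(unique(ens$provenance$mode2_frame), c(5, 10, 15, 20, 25))
  empty <- combined_mode_scan(s, secondary_frame_picks = integer(0))
  expect_equal(length(empty$frames), 0)
  expect_error(combined_mode_scan(s, secondary_frame_picks = 99,
                                  n_frames = 28), "out of range")

  # continuity: mode 1 recomputed on a mildly perturbed start overlaps the
  # original mode 1 but is not identical
  net <- elastic_network(s)
  ms <- normal_modes(build_anm(net), k = 2)
  small <- animate_mode(s, net, ms, mode = 2, n_frames = 28, rmsd_max = 1.5)
  s2 <- set_coords(s, small$frames[[5]])
  ms2 <- normal_modes(build_anm(elastic_network(s2)), k = 1)
  ov <- abs(sum(ms$vectors[, 1] * ms2$vectors[, 1]))
  expect_gt(ov, 0.5)
  expect_lt(ov, 1 - 1e-8)
})
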