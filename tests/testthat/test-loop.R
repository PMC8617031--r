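# Dihedral kinematics: measure/set inverses, rigid propagation, sampling,
# greedy contact refinement

make_loop_toy <- function(n = 8) {
  s <- make_ideal_chain(strrep("A", n), "extended")
  list(s = s, loop = loop_definition("A", c(2, n - 1)))
}

test_that("an ideal extended chain measures at -180 and four coplanar cis
           atoms at 0", {
  toy <- make_loop_toy()
  expect_equal(measure_dihedral(toy$s, "A", 3, "psi"), -180, tolerance = 1e-3)
  expect_equal(measure_dihedral(toy$s, "A", 3, "phi"), -180, tolerance = 1e-3)
  expect_equal(bandregion:::torsion_angle(c(0, 1, 0), c(0, 0, 0),
                                          c(1, 0, 0), c(1, 1, 0)), 0)
})

test_that("set and measure are exact inverses across kinds and residues", {
  toy <- make_loop_toy()
  s <- toy$s
  targets <- c(-179.5, -120, -45.5, 0, 33.3, 90, 150)
  for (resid in c(2, 4, 7)) {
    for (kind in c("phi", "psi")) {
      for (tgt in targets) {
        s2 <- set_backbone_dihedral(s, "A", resid, kind, tgt, toy$loop)
        expect_equal(measure_dihedral(s2, "A", resid, kind), tgt,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("setting a dihedral to its current value is a no-op and rotations
           outside the loop are refused", {
  toy <- make_loop_toy()
  cur <- measure_dihedral(toy$s, "A", 3, "phi")
  s2 <- set_backbone_dihedral(toy$s, "A", 3, "phi", cur, toy$loop)
  expect_lt(max(abs(coords(s2) - coords(toy$s))), 1e-9)
  expect_error(set_backbone_dihedral(toy$s, "A", 1, "psi", 10, toy$loop),
               "outside the declared loop")
})

test_that("a terminal psi rotation matches a hand-built Rodrigues result", {
  s <- make_ideal_chain("AAA", "extended")
  loop <- loop_definition("A", c(1, 3))
  psi0 <- measure_dihedral(s, "A", 2, "psi")
  target <- psi0 + 90
  if (target >= 180) target <- target - 360
  s2 <- set_backbone_dihedral(s, "A", 2, "psi", target, loop)
  # oracle: rotate the downstream N of residue 3 about the CA2->C2 axis
  ca2 <- as.numeric(coords(s, select_atoms(s, resid = 2, name = "CA")))
  c2 <- as.numeric(coords(s, select_atoms(s, resid = 2, name = "C")))
  n3_idx <- select_atoms(s, resid = 3, name = "N")
  u <- bandregion:::unitv(c2 - ca2)
  # +delta about b->c decreases the measured torsion, so rotate by -90
  R <- bandregion:::rodrigues(u, -90)
  expected <- as.numeric(R %*% (as.numeric(coords(s, n3_idx)) - ca2)) + ca2
  expect_equal(as.numeric(coords(s2, n3_idx)), expected, tolerance = 1e-6)
})

test_that("arbitrary dihedral compositions conserve bond lengths exactly and
           keep the attached group internally rigid", {
  hc <- make_hinge_complex(hinge_complex_spec(seed = 6))
  s <- hc$structure
  bonds0 <- backbone_bond_lengths(s, "A")
  attached <- select_atoms(s, chain = "A",
                           resid = (hc$loop$range[2] + 1):max(s$atoms$resid[s$atoms$chain == "A"]))
  d0 <- as.matrix(dist(coords(s, attached)))
  set.seed(5)
  for (rep in 1:20) {
    tor <- bandregion:::loop_torsions(hc$loop)
    for (j in sample(nrow(tor))) {
      s <- set_backbone_dihedral(s, "A", tor$resid[j], tor$kind[j],
                                 runif(1, -180, 180), hc$loop)
    }
  }
  expect_lt(max(abs(backbone_bond_lengths(s, "A") - bonds0)), 1e-9)
  expect_lt(max(abs(as.matrix(dist(coords(s, attached))) - d0)), 1e-9)
})

test_that("sample_hinge is seed-reproducible, yields the requested count and
           draws uniform angles", {
  hc <- make_hinge_complex(hinge_complex_spec(seed = 6))
  r1 <- sample_hinge(hc$structure, hc$loop, 10, seed = 123)
  r2 <- sample_hinge(hc$structure, hc$loop, 10, seed = 123)
  expect_length(r1$conformers, 10)
  expect_identical(r1$provenance, r2$provenance)
  expect_identical(coords(r1$conformers[[7]]), coords(r2$conformers[[7]]))

  ang <- draw_hinge_angles(hc$loop, 10000, seed = 9)
  # Kolmogorov-Smirnov statistic below the 1% critical value per torsion
  crit <- 1.63 / sqrt(nrow(ang))
  for (j in seq_len(ncol(ang))) {
    stat <- suppressWarnings(
      stats::ks.test(ang[, j], "punif", -180, 180)$statistic)
    expect_lt(stat, crit)
  }
})

test_that("refine_contact monotonically shortens the catalytic distance and
           stays clash-free", {
  # toy with a known solution: the target nitrogen sits 2.8 angstrom from
  # where the probe lands after a single +60 degree psi change
  base <- make_ideal_chain(strrep("A", 5), "extended")
  a <- base$atoms
  last_ca <- which(a$name == "CA" & a$resid == 5)
  probe <- a[last_ca, , drop = FALSE]
  probe$name <- "SG"; probe$element <- "S"
  probe$x <- probe$x + 1.8
  a <- rbind(a, probe)
  a$serial <- seq_len(nrow(a))
  s0 <- new_structure(a)
  loop <- loop_definition("A", c(2, 4))
  solved <- set_backbone_dihedral(
    s0, "A", 3, "psi",
    bandregion:::wrap_angle(measure_dihedral(s0, "A", 3, "psi") + 60), loop)
  sg <- select_atoms(s0, name = "SG")
  target_nz <- as.numeric(coords(solved, sg)) + c(0, 0, 2.8)
  lys <- make_ideal_chain("K", chain = "B", start_resid = 50)$atoms
  nz_row <- which(lys$name == "NZ")
  shift <- target_nz - c(lys$x[nz_row], lys$y[nz_row], lys$z[nz_row])
  lys$x <- lys$x + shift[1]; lys$y <- lys$y + shift[2]
  lys$z <- lys$z + shift[3]
  a2 <- rbind(s0$atoms, lys)
  a2$serial <- seq_len(nrow(a2))
  s <- new_structure(a2)
  nz <- select_atoms(s, chain = "B", name = "NZ")
  sg <- select_atoms(s, chain = "A", name = "SG")
  d0 <- catalytic_distance(s, sg, nz)
  expect_gt(d0, 5)  # not already in contact

  out <- refine_contact(s, loop, sg, nz, target = 3.5, max_iter = 500,
                        seed = 2)
  d1 <- attr(out, "distance")
  expect_lte(d1, d0)
  expect_lte(d1, 3.5)
  log <- attr(out, "accepted")
  expect_true(all(diff(log$distance) < 0))  # every accepted move improves
  mov <- bandregion:::moving_set(out, loop, loop$range[1], "phi")
  sta <- setdiff(seq_len(nrow(out$atoms)), mov)
  excl <- bandregion:::seam_exclusions(out, mov, sta)
  expect_equal(detect_clash(out, mov, sta, 2.5, exclude = excl), 0)
  # already at target: nothing changes
  again <- refine_contact(out, loop, sg, nz, target = 3.5, max_iter = 50,
                          seed = 3)
  expect_identical(coords(again), coords(out))
})
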