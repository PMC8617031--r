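# Clash counting, catalytic distances, chemical screen, SASA, band verdicts

test_that("clash counts follow the definition on trivial geometries", {
  s <- toy_points_structure(rbind(c(0, 0, 0), c(10, 0, 0)), chain = c("A", "B"))
  expect_equal(detect_clash(s, 1, 2, cutoff = 2.5), 0)

  # a set against its own zero-translated copy: every atom clashes once
  xyz <- matrix(runif(30, 0, 20), 10, 3)
  s2 <- toy_points_structure(rbind(xyz, xyz), chain = rep(c("A", "B"), each = 10))
  # copies are far apart in residue numbering, so no seam exclusion applies
  expect_gte(detect_clash(s2, 1:10, 11:20, cutoff = 2.5), 10)
  expect_error(detect_clash(s2, 1:10, 5:20, cutoff = 2.5), "disjoint")
})

test_that("grid-based clash counting equals the O(n^2) oracle on random
           clouds", {
  set.seed(21)
  for (rep in 1:3) {
    na <- 200; nb <- 180
    xa <- matrix(runif(3 * na, 0, 25), na, 3)
    xb <- matrix(runif(3 * nb, 0, 25), nb, 3)
    s <- toy_points_structure(rbind(xa, xb), chain = rep(c("A", "B"), c(na, nb)))
    for (cutoff in c(1.5, 2.5, 4)) {
      expect_identical(detect_clash(s, 1:na, na + 1:nb, cutoff = cutoff),
                       oracle_clash_count(xa, xb, cutoff))
    }
  }
})

test_that("seam exclusions drop bonded and 1-3 neighbour pairs only", {
  s <- make_ideal_chain("AAAA", "extended")
  mov <- select_atoms(s, resid = 3:4)
  sta <- select_atoms(s, resid = 1:2)
  excl <- bandregion:::seam_exclusions(s, mov, sta)
  # C2-N3 is a covalent bond (1.33 angstrom) but must not count as a clash
  expect_equal(detect_clash(s, mov, sta, cutoff = 2.5, exclude = excl), 0)
  expect_gt(detect_clash(s, mov, sta, cutoff = 2.5), 0)
})

test_that("catalytic distance is Euclidean and rigid-motion invariant", {
  s <- toy_points_structure(rbind(c(0, 0, 0), c(3, 4, 0)), chain = c("A", "B"))
  expect_equal(catalytic_distance(s, 1, 2), 5)
  expect_equal(catalytic_distance(s, 1, 1), 0)
  R <- bandregion:::rodrigues(bandregion:::unitv(c(1, 2, 3)), 77)
  s2 <- set_coords(s, sweep(coords(s) %*% t(R), 2, c(5, -3, 2), `+`))
  expect_equal(catalytic_distance(s2, 1, 2), 5, tolerance = 1e-9)
})

test_that("chemical screen detects planted salt bridges and ignores inert
           surroundings", {
  s <- make_ideal_chain("AAKAA", "extended")
  site <- lysine_site(s, "A", 3)
  chem <- chemical_screen(s, site)
  expect_false(chem$excluded)
  expect_equal(nrow(chem$salt_bridge), 0)

  # plant a glutamate carboxylate oxygen 3 angstrom from NZ
  nz <- as.numeric(coords(s, site$nz_idx))
  glu <- make_ideal_chain("E", chain = "B")
  oe1 <- select_atoms(glu, name = "OE1")
  shift <- (nz + c(0, 0, 3)) - as.numeric(coords(glu, oe1))
  glu <- set_coords(glu, sweep(coords(glu), 2, shift, `+`))
  atoms <- rbind(s$atoms, glu$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  s2 <- new_structure(atoms)
  chem2 <- chemical_screen(s2, lysine_site(s2, "A", 3))
  expect_true(chem2$excluded)
  expect_true("GLU" %in% chem2$salt_bridge$resname)
  expect_equal(min(chem2$salt_bridge$distance), 3, tolerance = 1e-6)
})

test_that("relative SASA is ~1 in an isolated tripeptide, < 0.05 when caged,
           and stable under quadrature refinement", {
  s <- make_ideal_chain("GKG", "extended")
  expose <- surface_exposure(s, "A", 2)
  expect_gt(expose, 0.9)
  expect_lt(expose, 1.1)

  # bury the lysine: plant a shell of atoms 4 angstrom around every residue
  # atom so no probe-sized pocket survives anywhere around the side chain
  res <- select_atoms(s, resid = 2)
  shell <- do.call(rbind, lapply(seq_along(res), function(i)
    sweep(bandregion:::fibonacci_sphere(100) * 4, 2,
          as.numeric(coords(s, res[i])), `+`)))
  cage <- toy_points_structure(shell, chain = "C")
  cage$atoms$resid <- cage$atoms$resid + 100
  atoms <- rbind(s$atoms, cage$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  s2 <- new_structure(atoms)
  expect_lt(surface_exposure(s2, "A", 2), 0.05)

  # doubling sphere points changes the estimate by < 2%
  e1 <- surface_exposure(s, "A", 2, n_points = 960)
  e2 <- surface_exposure(s, "A", 2, n_points = 1920)
  expect_lt(abs(e1 - e2) / e1, 0.02)
})

test_that("classify_band reproduces planted verdicts, treats the threshold
           inclusively and is rigid-motion invariant", {
  hc <- make_hinge_complex(hinge_complex_spec(
    seed = 9, site_labels = c("in_band", "out_of_band", "excluded")))
  s <- hc$structure
  nz <- vapply(hc$sites, function(x) x$nz_idx, 0L)
  samp <- sample_hinge(s, hc$loop, 60, seed = 31)
  ens <- structure(list(parent = s,
                        frames = lapply(samp$conformers, coords),
                        provenance = samp$provenance),
                   class = "conformer_ensemble")
  mov <- bandregion:::moving_set(s, hc$loop, hc$loop$range[1], "phi")
  rep1 <- classify_band(ens, hc$sites, hc$cys_sg, moving = mov)
  expect_equal(rep1$results$verdict[hc$truth == "out_of_band"], "out_of_band")
  expect_equal(rep1$results$verdict[hc$truth == "excluded"], "excluded")

  # rigid transformation of the whole ensemble leaves verdicts unchanged
  R <- bandregion:::rodrigues(bandregion:::unitv(c(2, 1, -1)), 63)
  shift <- c(12, -5, 8)
  s_rot <- set_coords(s, sweep(coords(s) %*% t(R), 2, shift, `+`))
  ens_rot <- structure(list(parent = s_rot,
                            frames = lapply(ens$frames, function(fr)
                              sweep(fr %*% t(R), 2, shift, `+`)),
                            provenance = ens$provenance),
                       class = "conformer_ensemble")
  rep2 <- classify_band(ens_rot, lapply(hc$sites, function(st)
    lysine_site(s_rot, st$chain, st$resid, st$label)), hc$cys_sg,
    moving = mov)
  expect_equal(rep2$results$verdict, rep1$results$verdict)
  expect_equal(rep2$results$min_distance, rep1$results$min_distance,
               tolerance = 1e-9)

  # verdict monotonicity in the contact threshold
  for (thr in c(6, 8, 10, 14)) {
    repx <- classify_band(ens, hc$sites, hc$cys_sg,
                          criteria = contact_criteria(contact_threshold = thr),
                          moving = mov)
    if (thr >= 8) {
      in8 <- rep1$results$verdict == "in_band"
      expect_true(all(repx$results$verdict[in8] == "in_band"))
    }
  }

  # boundary rule: a site at exactly the threshold counts as contact
  s_b <- toy_points_structure(rbind(c(0, 0, 0), c(8, 0, 0)),
                              chain = c("A", "B"))
  ens_b <- structure(list(parent = s_b, frames = list(coords(s_b)),
                          provenance = data.frame(frame = 1)),
                     class = "conformer_ensemble")
  site_b <- structure(list(chain = "B", resid = 2, label = "K2", nz_idx = 2L,
                           is_mutant = FALSE), class = "lysine_site")
  rep_b <- classify_band(ens_b, list(site_b), cys_sg = 1)
  expect_equal(rep_b$results$verdict, "in_band")
  expect_equal(rep_b$results$min_distance, 8)
})
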