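# Generators for toy structures with known ground truth: ideal-geometry
# peptide chains, hinge complexes with planted reachable / unreachable /
# chemically-excluded lysines, and clustered pose ensembles. Everything is
# deterministic given a seed, and planted labels are verified at generation
# time by an independent sampling scan, not assumed.

.bb_geo <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5)

#' Build an ideal-geometry peptide chain at prescribed torsions
#'
#' Backbone (N, CA, C, O) built with ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 angstrom), omega fixed at 180; side
#' chains at extended rotamers. Supported residues: A, G, K, D, E — enough
#' for lysine targets, Asp/Glu partners and inert scaffolding.
#'
#' @param sequence one-letter string over {A, G, K, D, E}.
#' @param torsions `"extended"` (phi = psi = 180), `"helix"`
#'   (phi = -57, psi = -47), or a data frame with `phi` and `psi` columns,
#'   one row per residue.
#' @param chain chain ID.
#' @param start_resid first residue number.
#' @return a `Structure`.
#' @export
make_ideal_chain <- function(sequence, torsions = "extended", chain = "A",
                             start_resid = 1) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (!length(letters1)) stop("empty sequence")
  bad <- setdiff(letters1, names(.aa321_ref))
  if (length(bad))
    stop("unsupported residue letter(s): ", paste(unique(bad), collapse = ", "))
  nres <- length(letters1)
  if (is.character(torsions)) {
    torsions <- switch(match.arg(torsions, c("extended", "helix")),
                       extended = data.frame(phi = rep(180, nres),
                                             psi = rep(180, nres)),
                       helix = data.frame(phi = rep(-57, nres),
                                          psi = rep(-47, nres)))
  }
  stopifnot(nrow(torsions) == nres)
  g <- .bb_geo
  pos <- list()  # pos[[i]] holds named backbone atom coords of residue i
  # residue 1 bootstrap in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C1 <- CA1 + g$ca_c * c(-cos(ang), sin(ang), 0)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(nres)) {
    if (i < nres) {
      Nn <- place_atom(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                       g$c_n, g$ang_ca_c_n, torsions$psi[i])
      CAn <- place_atom(pos[[i]]$CA, pos[[i]]$C, Nn,
                        g$n_ca, g$ang_c_n_ca, 180)  # omega
      Cn <- place_atom(pos[[i]]$C, Nn, CAn,
                       g$ca_c, g$ang_n_ca_c, torsions$phi[i + 1])
      pos[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
    }
    pos[[i]]$O <- place_atom(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                             g$c_o, g$ang_ca_c_o,
                             wrap_angle(torsions$psi[i] + 180))
  }
  rows <- list()
  for (i in seq_len(nres)) {
    resname <- .aa321_ref[letters1[i]]
    placed <- pos[[i]]
    atoms_i <- list(N = placed$N, CA = placed$CA, C = placed$C, O = placed$O)
    recipe <- .sidechain_recipes[[resname]]
    if (!is.null(recipe)) {
      for (step in recipe) {
        p <- place_atom(placed[[step$ref[1]]], placed[[step$ref[2]]],
                        placed[[step$ref[3]]], step$bond, step$angle,
                        step$torsion)
        placed[[step$atom]] <- p
        atoms_i[[step$atom]] <- p
      }
    }
    rows[[i]] <- data.frame(
      serial = NA_integer_,
      name = names(atoms_i),
      altloc = "",
      resname = resname,
      chain = chain,
      resid = start_resid + i - 1L,
      icode = "",
      x = vapply(atoms_i, `[`, 0, 1),
      y = vapply(atoms_i, `[`, 0, 2),
      z = vapply(atoms_i, `[`, 0, 3),
      occupancy = 1,
      element = substr(names(atoms_i), 1, 1),
      het = FALSE,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, title = sprintf("ideal chain %s", sequence))
}

# rigidly place a single-residue template so that `anchor_atom` lands at
# `target` with the template direction `from`->`to` aligned to `direction`
place_residue_template <- function(template_atoms, from, to, anchor_atom,
                                   target, direction) {
  nm <- template_atoms$name
  pt <- function(n) {
    i <- which(nm == n)
    c(template_atoms$x[i], template_atoms$y[i], template_atoms$z[i])
  }
  R <- align_vectors(pt(to) - pt(from), direction)
  anchor <- pt(anchor_atom)
  xyz <- cbind(template_atoms$x, template_atoms$y, template_atoms$z)
  xyz <- sweep(xyz, 2, anchor) %*% t(R)
  xyz <- sweep(xyz, 2, target, `+`)
  template_atoms$x <- xyz[, 1]
  template_atoms$y <- xyz[, 2]
  template_atoms$z <- xyz[, 3]
  template_atoms
}

#' Specification of a synthetic hinge complex
#'
#' @param pre_loop_length anchored residues before the loop (default 3).
#' @param loop_length flexible loop residues (default 5, mirroring the
#'   canonical five-residue RBX1 hinge).
#' @param attached_group_size residues in the rigid group dangling from the
#'   loop's C-terminal side (default 3; a short lever keeps the probe cloud
#'   dense enough that planted reachable sites are revisited often).
#' @param probe_offset offset of the catalytic probe atom (an SG sulfur) from
#'   the CA of the last attached residue, angstrom.
#' @param site_labels intended ground-truth labels, each one of `"in_band"`,
#'   `"out_of_band"`, `"excluded"`.
#' @param seed integer seed.
#' @return a `hinge_complex_spec`.
#' @export
hinge_complex_spec <- function(pre_loop_length = 3, loop_length = 5,
                               attached_group_size = 3,
                               probe_offset = c(1.8, 0, 0),
                               site_labels = c("in_band", "out_of_band"),
                               seed = 1) {
  stopifnot(pre_loop_length >= 1, loop_length >= 1, attached_group_size >= 1,
            all(site_labels %in% c("in_band", "out_of_band", "excluded")))
  structure(list(pre_loop_length = pre_loop_length, loop_length = loop_length,
                 attached_group_size = attached_group_size,
                 probe_offset = probe_offset, site_labels = site_labels,
                 seed = seed),
            class = "hinge_complex_spec")
}

#' Generate a hinge complex with planted ground-truth lysines
#'
#' Builds an anchored chain A (pre-loop anchor, flexible loop, rigid attached
#' group carrying a catalytic SG probe) and a static chain B carrying lysine
#' sites planted so their labels are guaranteed: reachable sites sit 4
#' angstrom beyond a densely-visited probe position (minimum achievable SG-NZ
#' distance well under the 8 angstrom threshold minus the 2 angstrom margin),
#' unreachable sites sit beyond the loop's maximal reach plus threshold plus
#' margin, and excluded sites are reachable lysines with a glutamate
#' carboxylate planted 3 angstrom from NZ. Labels are verified at generation
#' time by an independent 400-draw sampling scan of the full complex; an
#' inconsistent construction is an error.
#'
#' @param spec a `hinge_complex_spec`.
#' @return list with `structure`, `loop` (a `loop_definition`), `sites`
#'   (list of `lysine_site`s), `truth` (character labels), `cys_sg` (probe
#'   atom index).
#' @export
make_hinge_complex <- function(spec = hinge_complex_spec()) {
  n_a <- spec$pre_loop_length + spec$loop_length + spec$attached_group_size
  chain_a <- make_ideal_chain(strrep("A", n_a), "extended", chain = "A")
  a <- chain_a$atoms
  last_ca <- which(a$name == "CA" & a$resid == n_a)
  probe <- a[last_ca, , drop = FALSE]
  probe$name <- "SG"
  probe$element <- "S"
  probe$x <- probe$x + spec$probe_offset[1]
  probe$y <- probe$y + spec$probe_offset[2]
  probe$z <- probe$z + spec$probe_offset[3]
  a <- rbind(a, probe)
  a$serial <- seq_len(nrow(a))
  chain_a <- new_structure(a, title = "synthetic hinge complex")
  loop <- loop_definition("A", c(spec$pre_loop_length + 1,
                                 spec$pre_loop_length + spec$loop_length))
  sg_idx <- select_atoms(chain_a, chain = "A", name = "SG")

  # probe-position cloud of the bare arm (no POI yet), clash-filtered
  scan <- evaluate_hinge_draws(chain_a, loop, integer(0), sg_idx,
                               n_draws = 400, seed = spec$seed + 7001)
  ok <- which(!scan$clash)
  if (length(ok) < 50) stop("hinge arm too constrained: scan mostly clashes")
  cloud <- scan$probe_xyz[ok, , drop = FALSE]
  kin <- hinge_kinematics(chain_a, loop)
  p0 <- kin$p0
  reach_bound <- kin$bound[sg_idx]
  # rank candidate placements (4 angstrom beyond each visited probe point,
  # outward from the anchor) by how many clash-free probe visits fall within
  # the contact ball around them: maximises the contact fraction directly
  u_out <- sweep(cloud, 2, p0)
  u_out <- u_out / sqrt(rowSums(u_out^2))
  cand_nz <- cloud + 4 * u_out
  score <- vapply(seq_len(nrow(cand_nz)), function(i)
    sum(sqrt(rowSums(sweep(cloud, 2, cand_nz[i, ])^2)) <= 7.5), 0L)
  density_rank <- order(-score)

  lys_template <- make_ideal_chain("K")$atoms
  glu_template <- make_ideal_chain("E")$atoms

  place_all <- function(rank_offset) {
    rows <- list()
    res_counter <- 0L
    cand_i <- rank_offset
    chosen_q <- NULL
    unreach_dirs <- rbind(c(-1, 0, 0), c(0, 0, -1), c(0, -1, 0))
    unreach_n <- 0L
    for (k in seq_along(spec$site_labels)) {
      lab <- spec$site_labels[k]
      res_counter <- res_counter + 1L
      if (lab %in% c("in_band", "excluded")) {
        repeat {
          cand_i <- cand_i + 1L
          if (cand_i > length(density_rank)) return(NULL)
          q <- cloud[density_rank[cand_i], ]
          if (is.null(chosen_q) ||
              min(sqrt(rowSums(sweep(chosen_q, 2, q)^2))) > 8) break
        }
        chosen_q <- rbind(chosen_q, q)
        u <- unitv(q - p0)
        nz_target <- q + 4 * u
        lys <- place_residue_template(lys_template, "CA", "NZ", "NZ",
                                      nz_target, -u)
        lys$chain <- "B"
        lys$resid <- res_counter
        rows[[length(rows) + 1]] <- lys
        if (lab == "excluded") {
          ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          placed_ok <- FALSE
          for (rot in seq(0, 315, by = 45)) {
            v <- as.numeric(rodrigues(u, rot) %*% unitv(vcross(u, ref)))
            glu <- place_residue_template(glu_template, "OE1", "CA", "OE1",
                                          nz_target + 3 * v, v)
            glu_xyz <- cbind(glu$x, glu$y, glu$z)
            lys_xyz <- cbind(lys$x, lys$y, lys$z)
            dd <- sqrt(outer(rowSums(glu_xyz^2), rep(1, nrow(lys_xyz))) -
                         2 * glu_xyz %*% t(lys_xyz) +
                         outer(rep(1, nrow(glu_xyz)), rowSums(lys_xyz^2)))
            # only the intended OE1-NZ contact may come close
            intended <- which(glu$name == "OE1")
            dd[intended, which(lys$name == "NZ")] <- Inf
            if (min(dd) > 2.6) { placed_ok <- TRUE; break }
          }
          if (!placed_ok) return(NULL)
          res_counter <- res_counter + 1L
          glu$chain <- "B"
          glu$resid <- res_counter
          rows[[length(rows) + 1]] <- glu
        }
      } else {
        unreach_n <- unreach_n + 1L
        w <- unitv(unreach_dirs[(unreach_n - 1L) %% 3L + 1L, ])
        # margin covers hinge reach, the contact threshold, and the
        # worst-case relative displacement under mode animation at the
        # canonical 10 angstrom envelope (amplitude 10*sqrt(N) times a unit
        # mode component, twice per animation cycle and per scan stage), so
        # the label holds at every sampling tier
        n_nodes <- n_a + 2 * length(spec$site_labels)
        D <- reach_bound + 8 + 4 + 4 * 10 * sqrt(n_nodes)
        lys <- place_residue_template(lys_template, "CA", "NZ", "NZ",
                                      p0 + D * w, -w)
        lys$chain <- "B"
        lys$resid <- res_counter
        rows[[length(rows) + 1]] <- lys
      }
    }
    do.call(rbind, rows)
  }

  for (attempt in 0:14) {
    poi <- place_all(attempt)
    if (is.null(poi)) next
    atoms <- rbind(chain_a$atoms, poi)
    atoms$serial <- seq_len(nrow(atoms))
    full <- new_structure(atoms, title = "synthetic hinge complex")
    sg_full <- select_atoms(full, chain = "A", name = "SG")
    # static chain A part must not overlap the planted POI
    static_a <- select_atoms(full, chain = "A",
                             resid = seq_len(spec$pre_loop_length))
    poi_idx <- select_atoms(full, chain = "B")
    if (detect_clash(full, static_a, poi_idx, cutoff = 2.5) > 0) next
    lys_resids <- sort(unique(full$atoms$resid[
      poi_idx[full$atoms$resname[poi_idx] == "LYS"]]))
    sites <- lapply(lys_resids, function(r)
      lysine_site(full, "B", r, label = sprintf("K%d", r)))
    truth <- spec$site_labels
    nz_idx <- vapply(sites, function(x) x$nz_idx, 0L)
    ver <- evaluate_hinge_draws(full, loop, nz_idx, sg_full,
                                n_draws = 400, seed = spec$seed + 7013)
    okv <- !ver$clash
    good <- TRUE
    for (k in seq_along(truth)) {
      dmin_free <- if (any(okv)) min(ver$dist[okv, k]) else Inf
      hit_frac <- mean(okv & ver$dist[, k] <= 8)
      if (truth[k] %in% c("in_band", "excluded")) {
        chem <- chemical_screen(full, sites[[k]])
        want_excl <- truth[k] == "excluded"
        if (dmin_free > 6 || hit_frac < 0.02 || chem$excluded != want_excl)
          good <- FALSE
      } else {
        if (min(ver$dist[, k]) < 10) good <- FALSE
      }
    }
    if (good) {
      return(list(structure = full, loop = loop, sites = sites, truth = truth,
                  cys_sg = sg_full))
    }
  }
  stop("could not realise the requested site labels; placement inconsistent")
}

#' Generate a clustered pose ensemble with known labels
#'
#' Builds a two-chain base complex (a fixed E3-like helix, chain E, and a
#' mobile helix, chain M), then emits poses by perturbing cluster-centre
#' rigid placements of the mobile chain: centres are separated by
#' `inter_separation` (pure translations, so centre-to-centre mobile RMSD
#' equals the separation) and within-cluster noise is a random translation of
#' magnitude up to `intra_noise`.
#'
#' @param n_clusters number of planted clusters.
#' @param poses_per_cluster poses per cluster.
#' @param intra_noise within-cluster displacement bound, angstrom.
#' @param inter_separation centre separation, angstrom; must exceed
#'   `4 * intra_noise`.
#' @param seed integer seed.
#' @return list with `poses` (a `pose_set`) and `labels` (true cluster id per
#'   pose, 1-based).
#' @export
make_pose_ensemble <- function(n_clusters = 2, poses_per_cluster = 10,
                               intra_noise = 0.5, inter_separation = 20,
                               seed = 1) {
  if (inter_separation <= 4 * intra_noise)
    stop("inter_separation must exceed 4 * intra_noise")
  e3 <- make_ideal_chain(strrep("A", 8), "helix", chain = "E")
  mob <- make_ideal_chain(strrep("A", 6), "helix", chain = "M")
  mob <- set_coords(mob, sweep(coords(mob), 2, c(15, 0, 0), `+`))
  atoms <- rbind(e3$atoms, mob$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  base <- new_structure(atoms, title = "synthetic pose base")
  mob_idx <- select_atoms(base, chain = "M")
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                unitv(c(1, 1, 0)), unitv(c(1, 0, 1)), unitv(c(0, 1, 1)))
  if (n_clusters > nrow(dirs)) stop("at most 6 planted clusters supported")
  poses <- list()
  labels <- integer(0)
  with_private_seed(seed, {
    for (k in seq_len(n_clusters)) {
      centre_shift <- (k - 1) * inter_separation * dirs[k, ]
      for (p in seq_len(poses_per_cluster)) {
        noise <- if (intra_noise > 0) {
          mag <- stats::runif(1, 0, intra_noise)
          dir <- unitv(stats::rnorm(3))
          mag * dir
        } else c(0, 0, 0)
        pose <- set_coords(base,
                           sweep(coords(base, mob_idx), 2,
                                 centre_shift + noise, `+`),
                           idx = mob_idx)
        poses[[length(poses) + 1]] <- pose
        labels <- c(labels, k)
      }
    }
  })
  list(poses = pose_set(poses, e3_chain = "E", mobile_chain = "M"),
       labels = labels)
}
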