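# Backbone phi/psi manipulation of a hinge loop. Rotating a loop torsion
# moves everything C-terminal to the rotated bond in the loop's chain plus an
# attached rigid group (e.g. the RING domain with its docked E2-Ub module),
# which therefore travels synchronously, conserving its internal geometry.

#' Define a hinge loop and its attached rigid group
#'
#' @param chain chain ID carrying the loop.
#' @param range inclusive residue-number range of the flexible loop, e.g.
#'   `c(36, 40)` for the canonical RBX1 hinge.
#' @param attached_chains chain IDs that move as one rigid body with the
#'   loop's C-terminal side (the dangling subunits).
#' @return a `loop_definition`.
#' @export
loop_definition <- function(chain, range, attached_chains = character()) {
  stopifnot(length(range) == 2, range[2] >= range[1])
  structure(list(chain = chain, range = as.integer(range),
                 attached_chains = attached_chains),
            class = "loop_definition")
}

# torsion table of a loop: one row per rotatable torsion in N->C application
# order (phi_i then psi_i per residue)
loop_torsions <- function(loop) {
  res <- seq(loop$range[1], loop$range[2])
  data.frame(resid = rep(res, each = 2),
             kind = rep(c("phi", "psi"), length(res)),
             stringsAsFactors = FALSE)
}

# the four defining atoms of a backbone torsion, as (chain, resid, name) rows
torsion_atoms <- function(kind, resid) {
  if (kind == "phi") {
    data.frame(resid = c(resid - 1, resid, resid, resid),
               name = c("C", "N", "CA", "C"))
  } else {
    data.frame(resid = c(resid, resid, resid, resid + 1),
               name = c("N", "CA", "C", "N"))
  }
}

#' Measure a backbone dihedral
#'
#' @param s a `Structure`.
#' @param chain chain ID.
#' @param resid residue number.
#' @param kind `"phi"` (C_{i-1}, N_i, CA_i, C_i) or `"psi"`
#'   (N_i, CA_i, C_i, N_{i+1}).
#' @return signed angle in degrees on `[-180, 180)` (IUPAC convention).
#' @export
measure_dihedral <- function(s, chain, resid, kind = c("phi", "psi")) {
  kind <- match.arg(kind)
  ta <- torsion_atoms(kind, resid)
  pts <- lapply(seq_len(4), function(i) {
    j <- atom_index(s, chain, ta$resid[i], ta$name[i],
                    what = sprintf("%s-defining atom", kind))
    as.numeric(coords(s, j))
  })
  torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

# atom indices that move when the given torsion rotates: within the loop's
# chain, residues C-terminal to the pivot residue always move; for phi the
# pivot residue's atoms other than N/CA/H move too, for psi only its carbonyl
# O; the attached chains always move.
moving_set <- function(s, loop, resid, kind) {
  a <- s$atoms
  in_chain <- a$chain == loop$chain
  down <- in_chain & a$resid > resid
  if (kind == "phi") {
    self <- in_chain & a$resid == resid & !(a$name %in% c("N", "CA", "H"))
  } else {
    self <- in_chain & a$resid == resid & a$name == "O"
  }
  attached <- a$chain %in% loop$attached_chains
  which(down | self | attached)
}

#' Set a backbone dihedral by rigid rotation of the moving set
#'
#' Rotates the moving set (see Details) about the torsion's central bond so
#' the measured dihedral equals `angle`. All other atoms are untouched and
#' every pairwise distance within the moving set is conserved (pure rotation).
#'
#' Moving set: atoms C-terminal to the rotated bond within the loop's chain
#' plus the whole attached rigid group of `loop`. The residue must lie inside
#' the loop range; this guards against unintended chain breaks elsewhere.
#'
#' @inheritParams measure_dihedral
#' @param angle target dihedral in degrees.
#' @param loop a `loop_definition`; the rotation is only allowed for residues
#'   inside its range.
#' @return the modified `Structure`.
#' @export
set_backbone_dihedral <- function(s, chain, resid, kind = c("phi", "psi"),
                                  angle, loop) {
  kind <- match.arg(kind)
  if (chain != loop$chain || resid < loop$range[1] || resid > loop$range[2])
    stop(sprintf("residue %s/%d is outside the declared loop range", chain, resid))
  current <- measure_dihedral(s, chain, resid, kind)
  ta <- torsion_atoms(kind, resid)
  b <- as.numeric(coords(s, atom_index(s, chain, ta$resid[2], ta$name[2])))
  c_ <- as.numeric(coords(s, atom_index(s, chain, ta$resid[3], ta$name[3])))
  # +delta about the b->c axis decreases the measured torsion (see geometry
  # calibration), hence current - target
  rt <- axis_rotation(b, unitv(c_ - b), current - angle)
  mov <- moving_set(s, loop, resid, kind)
  set_coords(s, apply_rt(coords(s, mov), rt), idx = mov)
}

#' Draw random hinge torsion angles
#'
#' Each draw assigns every phi and psi in the loop an independent uniform
#' angle on `[-180, 180)` from a private seeded stream.
#'
#' @param loop a `loop_definition`.
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @return numeric matrix `n_draws x n_torsions`, columns in N->C application
#'   order, with the torsion table attached as attribute `"torsions"`.
#' @export
draw_hinge_angles <- function(loop, n_draws, seed) {
  tor <- loop_torsions(loop)
  ang <- with_private_seed(seed, {
    matrix(stats::runif(n_draws * nrow(tor), -180, 180), nrow = n_draws)
  })
  attr(ang, "torsions") <- tor
  ang
}

#' Randomly sample hinge-loop conformations
#'
#' Applies each row of random torsions (phi and psi of every loop residue,
#' N- to C-terminal) to the starting structure and returns the resulting
#' conformers. The attached rigid group moves synchronously. For large draw
#' counts use the streaming classifier ([run_pipeline()]), which evaluates
#' conformations without materialising them; this function is the reference
#' implementation.
#'
#' @param s starting `Structure`.
#' @param loop a `loop_definition`.
#' @param n_draws number of conformers.
#' @param seed integer seed.
#' @return list with `conformers` (list of `Structure`s) and `provenance`
#'   (data frame of drawn angles, one row per conformer, plus the seed as an
#'   attribute).
#' @export
sample_hinge <- function(s, loop, n_draws, seed) {
  stopifnot(n_draws >= 1)
  ang <- draw_hinge_angles(loop, n_draws, seed)
  tor <- attr(ang, "torsions")
  conformers <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    si <- s
    for (j in seq_len(nrow(tor))) {
      si <- set_backbone_dihedral(si, loop$chain, tor$resid[j], tor$kind[j],
                                  ang[d, j], loop)
    }
    conformers[[d]] <- si
  }
  prov <- as.data.frame(ang)
  names(prov) <- paste0(tor$kind, tor$resid)
  attr(prov, "seed") <- seed
  list(conformers = conformers, provenance = prov)
}

#' Greedy stochastic refinement of the catalytic contact
#'
#' Replaces the irreproducible manual "fine-tuning" step with a documented
#' algorithm: at each iteration one random loop torsion is perturbed by a
#' Gaussian step (sigma 15 degrees); the move is accepted iff the
#' cysteine-SG to lysine-NZ distance decreases and the conformation stays
#' clash-free. Stops when the distance reaches `target` or after `max_iter`
#' proposals.
#'
#' @param s starting `Structure`.
#' @param loop a `loop_definition`.
#' @param cys_sg,lys_nz atom indices of the catalytic sulfur and the acceptor
#'   nitrogen.
#' @param target target distance in angstrom (default 3, the near-attack
#'   geometry).
#' @param max_iter proposal budget (default 500).
#' @param seed integer seed.
#' @param clash_cutoff heavy-atom clash distance in angstrom.
#' @return the best `Structure` found, with attributes `"distance"`,
#'   `"accepted"` (log of accepted moves) and `"converged"`; if no clash-free
#'   improvement is found the input is returned with `"converged" = FALSE`
#'   and a warning.
#' @export
refine_contact <- function(s, loop, cys_sg, lys_nz, target = 3, max_iter = 500,
                           seed = 1, clash_cutoff = 2.5) {
  tor <- loop_torsions(loop)
  mov_all <- moving_set(s, loop, loop$range[1], "phi")
  static_idx <- setdiff(seq_len(nrow(s$atoms)), mov_all)
  excl <- seam_exclusions(s, mov_all, static_idx)
  dist_now <- dist3(as.numeric(coords(s, cys_sg)), as.numeric(coords(s, lys_nz)))
  best <- s
  best_d <- dist_now
  log <- list()
  with_private_seed(seed, {
    for (it in seq_len(max_iter)) {
      if (best_d <= target) break
      j <- sample.int(nrow(tor), 1)
      cur <- measure_dihedral(best, loop$chain, tor$resid[j], tor$kind[j])
      prop <- wrap_angle(cur + stats::rnorm(1, 0, 15))
      cand <- set_backbone_dihedral(best, loop$chain, tor$resid[j],
                                    tor$kind[j], prop, loop)
      d <- dist3(as.numeric(coords(cand, cys_sg)),
                 as.numeric(coords(cand, lys_nz)))
      if (d < best_d &&
          detect_clash(cand, mov_all, static_idx, cutoff = clash_cutoff,
                       exclude = excl) == 0) {
        best <- cand
        best_d <- d
        log[[length(log) + 1]] <- data.frame(iter = it, resid = tor$resid[j],
                                             kind = tor$kind[j], angle = prop,
                                             distance = d)
      }
    }
  })
  converged <- length(log) > 0 || best_d <= target
  if (!converged)
    warning("refine_contact found no clash-free improvement within max_iter")
  attr(best, "distance") <- best_d
  attr(best, "accepted") <- if (length(log)) do.call(rbind, log) else NULL
  attr(best, "converged") <- converged
  best
}
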