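# Clash detection, catalytic-distance evaluation, chemical-environment and
# surface-exposure screening of lysines, and the band-region verdict logic.

#' Contact and exclusion criteria
#'
#' @param contact_threshold SG-NZ distance (angstrom) counting as an
#'   E2-accessible contact; inclusive (default 8).
#' @param clash_cutoff heavy-atom distance below which two atoms clash
#'   (default 2.5).
#' @param anchor_max maximal anchor distance for pose filtering (default 50).
#' @param salt_bridge_max NZ to carboxylate-oxygen distance defining a salt
#'   bridge (default 4).
#' @param hbond_max NZ to acceptor distance defining a hydrogen bond
#'   (default 3.5).
#' @param surface_rel_sasa_min relative SASA below which a lysine is
#'   considered buried during automatic site discovery (default 0.25).
#' @param min_contact_frames clash-free contact frames required for an
#'   in-band verdict (default 1).
#' @return a `contact_criteria` list.
#' @export
contact_criteria <- function(contact_threshold = 8, clash_cutoff = 2.5,
                             anchor_max = 50, salt_bridge_max = 4,
                             hbond_max = 3.5, surface_rel_sasa_min = 0.25,
                             min_contact_frames = 1) {
  stopifnot(contact_threshold > clash_cutoff, clash_cutoff > 0,
            anchor_max > 0, salt_bridge_max > 0, hbond_max > 0,
            min_contact_frames >= 1)
  structure(list(contact_threshold = contact_threshold,
                 clash_cutoff = clash_cutoff, anchor_max = anchor_max,
                 salt_bridge_max = salt_bridge_max, hbond_max = hbond_max,
                 surface_rel_sasa_min = surface_rel_sasa_min,
                 min_contact_frames = min_contact_frames),
            class = "contact_criteria")
}

#' Declare a candidate ubiquitination site
#'
#' @param s a `Structure` (after any mutation has been applied).
#' @param chain,resid location of the lysine.
#' @param label display label, e.g. `"K87"` or `"R102K"`.
#' @param is_mutant whether the lysine was introduced by
#'   [mutate_to_lysine()].
#' @return a `lysine_site` with the NZ atom index resolved.
#' @export
lysine_site <- function(s, chain, resid, label = NULL, is_mutant = FALSE) {
  rows <- select_atoms(s, chain = chain, resid = resid)
  if (!length(rows)) stop(sprintf("residue %s/%s not found", chain, resid))
  if (s$atoms$resname[rows[1]] != "LYS")
    stop(sprintf("site %s/%s is %s, not LYS", chain, resid,
                 s$atoms$resname[rows[1]]))
  nz <- select_atoms(s, chain = chain, resid = resid, name = "NZ")
  if (length(nz) != 1) stop(sprintf("site %s/%s has no NZ atom", chain, resid))
  if (is.null(label)) label <- paste0("K", resid)
  structure(list(chain = chain, resid = resid, label = label,
                 nz_idx = nz, is_mutant = is_mutant),
            class = "lysine_site")
}

# exclusion pairs across the covalent seam between a moving and a static set:
# atom pairs in the same or adjacent residues of one chain (covers bonded and
# 1-3 neighbours across the cut)
seam_exclusions <- function(s, idx_a, idx_b) {
  a <- s$atoms
  pairs <- expand.grid(ia = seq_along(idx_a), ib = seq_along(idx_b))
  ga <- idx_a[pairs$ia]
  gb <- idx_b[pairs$ib]
  near <- a$chain[ga] == a$chain[gb] & abs(a$resid[ga] - a$resid[gb]) <= 1
  cbind(pairs$ia[near], pairs$ib[near])
}

#' Count steric clashes between two atom sets
#'
#' Counts heavy-atom pairs (one from each set) closer than `cutoff` (strict).
#' Uses a uniform spatial grid of cell size `cutoff`, so only neighbouring
#' cells are examined. Pairs listed in `exclude` (covalent seam neighbours)
#' are skipped; hydrogens are ignored.
#'
#' @param s a `Structure`.
#' @param idx_a,idx_b disjoint atom index vectors.
#' @param cutoff clash distance in angstrom (default 2.5).
#' @param exclude optional 2-column matrix of (position in `idx_a`, position
#'   in `idx_b`) pairs to skip.
#' @return integer clash count.
#' @export
detect_clash <- function(s, idx_a, idx_b, cutoff = 2.5, exclude = NULL) {
  if (length(intersect(idx_a, idx_b)))
    stop("clash sets overlap; they must be disjoint")
  a <- s$atoms
  heavy_a <- idx_a[a$element[idx_a] != "H"]
  heavy_b <- idx_b[a$element[idx_b] != "H"]
  pos_a <- match(heavy_a, idx_a)
  pos_b <- match(heavy_b, idx_b)
  xa <- coords(s, heavy_a)
  xb <- coords(s, heavy_b)
  if (!nrow(xa) || !nrow(xb)) return(0L)
  excl_key <- character()
  if (!is.null(exclude) && nrow(exclude))
    excl_key <- paste(exclude[, 1], exclude[, 2])
  cell <- function(m) paste(floor(m[, 1] / cutoff), floor(m[, 2] / cutoff),
                            floor(m[, 3] / cutoff))
  cb <- cell(xb)
  grid_b <- split(seq_len(nrow(xb)), cb)
  ca_f <- floor(xa / cutoff)
  count <- 0L
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(xa))) {
    keys <- paste(ca_f[i, 1] + off[, 1], ca_f[i, 2] + off[, 2],
                  ca_f[i, 3] + off[, 3])
    cand <- unlist(grid_b[keys], use.names = FALSE)
    if (!length(cand)) next
    d2 <- (xb[cand, 1] - xa[i, 1])^2 + (xb[cand, 2] - xa[i, 2])^2 +
      (xb[cand, 3] - xa[i, 3])^2
    hit <- cand[d2 < cutoff^2]
    if (length(hit) && length(excl_key)) {
      hit <- hit[!paste(pos_a[i], pos_b[hit]) %in% excl_key]
    }
    count <- count + length(hit)
  }
  count
}

#' Catalytic distance between the E2 cysteine sulfur and a lysine nitrogen
#'
#' @param s a `Structure` (or any frame sharing its topology via `xyz`).
#' @param cys_sg,lys_nz atom indices.
#' @param xyz optional n x 3 frame coordinates overriding the structure's.
#' @return Euclidean distance in angstrom.
#' @export
catalytic_distance <- function(s, cys_sg, lys_nz, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(s)
  if (max(cys_sg, lys_nz) > nrow(xyz)) stop("atom index outside the frame")
  dist3(xyz[cys_sg, ], xyz[lys_nz, ])
}

#' Chemical-environment screen of a lysine
#'
#' Finds salt-bridge partners (Asp/Glu side-chain carboxylate oxygens within
#' `salt_bridge_max` of NZ) and hydrogen-bond partners (other side-chain or
#' backbone O/N acceptors within `hbond_max`, excluding the lysine's own
#' residue). A site with at least one salt-bridge partner is chemically
#' excluded from the band region: the interaction both shields the charge the
#' E2 acidic site must attract and pins the side chain. Hydrogen bonds alone
#' flag a warning but do not exclude.
#'
#' @param s a `Structure`.
#' @param site a `lysine_site`.
#' @param criteria a `contact_criteria`.
#' @return list with `salt_bridge` and `hbond` partner tables and logical
#'   `excluded`.
#' @export
chemical_screen <- function(s, site, criteria = contact_criteria()) {
  a <- s$atoms
  nz <- as.numeric(coords(s, site$nz_idx))
  own <- a$chain == site$chain & a$resid == site$resid
  d <- sqrt((a$x - nz[1])^2 + (a$y - nz[2])^2 + (a$z - nz[3])^2)
  carbox <- a$resname %in% c("ASP", "GLU") &
    a$name %in% c("OD1", "OD2", "OE1", "OE2")
  sb_rows <- which(!own & carbox & d <= criteria$salt_bridge_max)
  acceptor <- a$element %in% c("O", "N") & !a$het
  hb_rows <- which(!own & acceptor & d <= criteria$hbond_max)
  hb_rows <- setdiff(hb_rows, sb_rows)
  partner_tab <- function(rows) {
    data.frame(chain = a$chain[rows], resid = a$resid[rows],
               resname = a$resname[rows], name = a$name[rows],
               distance = d[rows], stringsAsFactors = FALSE)
  }
  list(salt_bridge = partner_tab(sb_rows), hbond = partner_tab(hb_rows),
       excluded = length(sb_rows) > 0)
}

# van der Waals radii by element (angstrom) for SASA
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Shrake-Rupley SASA of selected atoms against a context set
shrake_rupley <- function(xyz, radii, context_xyz, context_radii,
                          probe = 1.4, n_points = 960) {
  sphere <- fibonacci_sphere(n_points)
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    ri <- radii[i] + probe
    pts <- sweep(sphere * ri, 2, xyz[i, ], `+`)
    occluded <- rep(FALSE, n_points)
    if (nrow(context_xyz)) {
      dc <- sqrt(colSums((t(context_xyz) - xyz[i, ])^2))
      near <- which(dc < ri + context_radii + probe & dc > 1e-9)
      for (j in near) {
        rj <- context_radii[j] + probe
        d2 <- (pts[, 1] - context_xyz[j, 1])^2 +
          (pts[, 2] - context_xyz[j, 2])^2 +
          (pts[, 3] - context_xyz[j, 3])^2
        occluded <- occluded | d2 < rj^2
      }
    }
    total <- total + 4 * pi * ri^2 * sum(!occluded) / n_points
  }
  total
}

#' Relative solvent exposure of a residue
#'
#' Shrake-Rupley solvent-accessible surface area of the residue's heavy atoms
#' (probe 1.4 angstrom, 960 sphere points per atom) divided by the SASA of
#' the same residue type in an isolated Gly-X-Gly reference peptide built at
#' extended torsions.
#'
#' @param s a `Structure`.
#' @param chain,resid residue location.
#' @param probe probe radius in angstrom.
#' @param n_points sphere quadrature points per atom.
#' @return relative SASA fraction (can slightly exceed 1 for very exposed
#'   conformers).
#' @export
surface_exposure <- function(s, chain, resid, probe = 1.4, n_points = 960) {
  rows <- select_atoms(s, chain = chain, resid = resid)
  if (!length(rows)) stop(sprintf("residue %s/%s not found", chain, resid))
  a <- s$atoms
  heavy <- rows[a$element[rows] != "H"]
  others <- setdiff(which(a$element != "H"), heavy)
  rad <- function(el) {
    r <- .vdw_radii[el]
    r[is.na(r)] <- 1.7
    unname(r)
  }
  sasa <- shrake_rupley(coords(s, heavy), rad(a$element[heavy]),
                        coords(s, others), rad(a$element[others]),
                        probe = probe, n_points = n_points)
  resname <- a$resname[heavy[1]]
  one <- names(which(.aa321_ref == resname))
  if (!length(one)) one <- "A"
  ref <- make_ideal_chain(paste0("G", one, "G"), torsions = "extended")
  ref_rows <- select_atoms(ref, resid = 2)
  ra <- ref$atoms
  ref_heavy <- ref_rows[ra$element[ref_rows] != "H"]
  ref_others <- setdiff(which(ra$element != "H"), ref_heavy)
  ref_sasa <- shrake_rupley(coords(ref, ref_heavy), rad(ra$element[ref_heavy]),
                            coords(ref, ref_others), rad(ra$element[ref_others]),
                            probe = probe, n_points = n_points)
  sasa / ref_sasa
}

.aa321_ref <- c(A = "ALA", G = "GLY", K = "LYS", D = "ASP", E = "GLU")

#' Classify lysine sites against a conformer ensemble
#'
#' For every frame, conformations where the moving set clashes with the rest
#' of the complex (at `clash_cutoff`, covalent seam excluded) are discarded;
#' over the surviving frames each site's minimum SG-NZ distance and number of
#' contact frames (distance at or below the inclusive `contact_threshold`)
#' are recorded. A site is `in_band` iff it is not chemically excluded and
#' reaches at least `min_contact_frames` clash-free contacts; a salt-bridged
#' site is `excluded` regardless of distance.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param sites list of `lysine_site`s.
#' @param cys_sg atom index of the catalytic cysteine SG.
#' @param criteria a `contact_criteria`.
#' @param moving atom indices forming the moving set for clash filtering;
#'   when `NULL` no clash filter is applied (all frames survive).
#' @return a `band_report` with one row per site.
#' @export
classify_band <- function(ensemble, sites, cys_sg,
                          criteria = contact_criteria(), moving = NULL) {
  if (!length(ensemble$frames)) stop("empty ensemble")
  s <- ensemble$parent
  static_idx <- NULL
  excl <- NULL
  if (!is.null(moving)) {
    static_idx <- setdiff(seq_len(nrow(s$atoms)), moving)
    excl <- seam_exclusions(s, moving, static_idx)
  }
  survive <- logical(length(ensemble$frames))
  for (f in seq_along(ensemble$frames)) {
    sf <- set_coords(s, ensemble$frames[[f]])
    survive[f] <- is.null(moving) ||
      detect_clash(sf, moving, static_idx, cutoff = criteria$clash_cutoff,
                   exclude = excl) == 0
  }
  if (!any(survive))
    warning("all frames clash: no surviving conformations")
  rows <- lapply(sites, function(site) {
    chem <- chemical_screen(s, site, criteria)
    dists <- vapply(which(survive), function(f) {
      catalytic_distance(s, cys_sg, site$nz_idx, xyz = ensemble$frames[[f]])
    }, 0)
    min_d <- if (length(dists)) min(dists) else Inf
    n_contact <- sum(dists <= criteria$contact_threshold)
    best <- if (length(dists)) which(survive)[which.min(dists)] else NA_integer_
    exclusion <- if (chem$excluded) "salt_bridge" else "none"
    verdict <- if (chem$excluded) {
      "excluded"
    } else if (n_contact >= criteria$min_contact_frames) {
      "in_band"
    } else {
      "out_of_band"
    }
    data.frame(label = site$label, chain = site$chain, resid = site$resid,
               min_distance = min_d, n_contact_frames = n_contact,
               best_frame = best, exclusion = exclusion, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  structure(list(results = do.call(rbind, rows),
                 n_frames = length(ensemble$frames),
                 n_surviving = sum(survive),
                 criteria = criteria),
            class = "band_report")
}

#' @export
print.band_report <- function(x, ...) {
  cat(sprintf("band_report: %d sites over %s conformations (%s clash-free)\n",
              nrow(x$results),
              format(x$n_frames, big.mark = ","),
              format(x$n_surviving, big.mark = ",")))
  print(x$results, row.names = FALSE)
  invisible(x)
}
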