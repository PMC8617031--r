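# Rigid-body superposition (least-squares / Kabsch), grafting of subunits
# between complexes via shared scaffolds, and the duplicate-alignment trick
# used to compare homologous proteins occupying different poses.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD between paired
#' atoms of `mobile_xyz` and `ref_xyz`. The fit is a one-shot SVD solution; no
#' outlier-rejection cycles are run unless `trim = TRUE`, in which case pairs
#' beyond 2 standard deviations of the pair-distance distribution are dropped
#' once and the fit repeated.
#'
#' @param mobile_xyz,ref_xyz n x 3 matrices of paired coordinates (row i of
#'   one pairs with row i of the other), n >= 3 and non-collinear.
#' @param trim logical; one 2-sigma trim cycle (default off).
#' @return list with `R` (3 x 3 rotation, det +1), `t` (translation applied
#'   after rotation), and `rmsd` (the minimised value, in angstrom). The
#'   transform maps mobile coordinates onto the reference frame:
#'   `x -> R x + t`.
#' @export
kabsch_fit <- function(mobile_xyz, ref_xyz, trim = FALSE) {
  mobile_xyz <- as.matrix(mobile_xyz)
  ref_xyz <- as.matrix(ref_xyz)
  if (nrow(mobile_xyz) != nrow(ref_xyz))
    stop("pairing mismatch: different numbers of mobile and reference atoms")
  n <- nrow(mobile_xyz)
  if (n < 3) stop("superposition needs at least 3 atom pairs")
  mc <- colMeans(mobile_xyz)
  rc <- colMeans(ref_xyz)
  A <- sweep(mobile_xyz, 2, mc)
  B <- sweep(ref_xyz, 2, rc)
  # collinearity check: centered point sets must span at least a plane
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(A, nu = 0, nv = 0)$d[1]) ||
      svd(B, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(B, nu = 0, nv = 0)$d[1]))
    stop("degenerate (collinear) atom pairing: superposition is ill-defined")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(rc - R %*% mc)
  fitted <- sweep(mobile_xyz %*% t(R), 2, -t_vec)
  dev <- sqrt(rowSums((fitted - ref_xyz)^2))
  if (trim) {
    keep <- dev <= mean(dev) + 2 * stats::sd(dev)
    if (sum(keep) >= 3 && any(!keep))
      return(kabsch_fit(mobile_xyz[keep, , drop = FALSE],
                        ref_xyz[keep, , drop = FALSE], trim = FALSE))
  }
  list(R = R, t = t_vec, rmsd = sqrt(mean(dev^2)))
}

#' Pair atoms of two atom sets by atom identity
#'
#' Pairs atoms that share (chain, resid, icode, name). Used for scaffold
#' pairing when the two selections come from copies of the same protein.
#'
#' @param s_a,s_b `Structure`s.
#' @param idx_a,idx_b atom index vectors.
#' @return 2-column integer matrix of (index in a, index in b) pairs.
#' @export
pair_by_identity <- function(s_a, idx_a, s_b, idx_b) {
  key <- function(s, i) paste(s$atoms$chain[i], s$atoms$resid[i],
                              s$atoms$icode[i], s$atoms$name[i])
  ka <- key(s_a, idx_a)
  kb <- key(s_b, idx_b)
  common <- intersect(ka, kb)
  cbind(idx_a[match(common, ka)], idx_b[match(common, kb)])
}

#' Graft a cargo subunit from a donor complex onto an acceptor complex
#'
#' The donor's scaffold selection is superposed onto the acceptor's scaffold
#' selection; the same rigid transform is then applied to the cargo atoms,
#' which are appended to the acceptor. Cargo internal geometry is conserved
#' exactly (a rigid transform). If a cargo chain ID collides with an acceptor
#' chain, the cargo chain is renamed to a fresh ID with a warning.
#'
#' @param donor,acceptor `Structure`s.
#' @param donor_scaffold,acceptor_scaffold atom index vectors defining the
#'   shared scaffold (paired by atom identity, or positionally when
#'   `pairing = "positional"` and lengths match).
#' @param cargo atom indices in `donor` to transfer.
#' @param pairing `"identity"` or `"positional"`.
#' @return list with `structure` (the grafted complex), `transform`, and
#'   `scaffold_rmsd`.
#' @export
graft_subunit <- function(donor, donor_scaffold, acceptor, acceptor_scaffold,
                          cargo, pairing = c("identity", "positional")) {
  pairing <- match.arg(pairing)
  if (pairing == "identity") {
    pairs <- pair_by_identity(donor, donor_scaffold, acceptor, acceptor_scaffold)
  } else {
    if (length(donor_scaffold) != length(acceptor_scaffold))
      stop("positional pairing needs equal-length scaffolds")
    pairs <- cbind(donor_scaffold, acceptor_scaffold)
  }
  if (nrow(pairs) < 3)
    stop("scaffold pairing yielded fewer than 3 atom pairs")
  fit <- kabsch_fit(coords(donor, pairs[, 1]), coords(acceptor, pairs[, 2]))
  cargo_atoms <- donor$atoms[cargo, , drop = FALSE]
  cargo_xyz <- apply_rt(coords(donor, cargo), fit)
  cargo_atoms$x <- cargo_xyz[, 1]
  cargo_atoms$y <- cargo_xyz[, 2]
  cargo_atoms$z <- cargo_xyz[, 3]
  clash_chains <- intersect(unique(cargo_atoms$chain), unique(acceptor$atoms$chain))
  if (length(clash_chains)) {
    fresh <- setdiff(c(LETTERS, letters, as.character(0:9)),
                     c(unique(acceptor$atoms$chain), unique(cargo_atoms$chain)))
    for (k in seq_along(clash_chains)) {
      warning(sprintf("cargo chain '%s' collides with an acceptor chain; renamed to '%s'",
                      clash_chains[k], fresh[k]))
      cargo_atoms$chain[cargo_atoms$chain == clash_chains[k]] <- fresh[k]
    }
  }
  atoms <- rbind(acceptor$atoms, cargo_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  list(structure = new_structure(atoms, title = acceptor$title),
       transform = fit[c("R", "t")],
       scaffold_rmsd = fit$rmsd)
}

# three-letter -> one-letter residue codes (20 standard amino acids)
.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

# CA trace of one chain: coordinates, one-letter sequence, residue ids
chain_ca_trace <- function(s, chain = NULL) {
  a <- s$atoms
  keep <- a$name == "CA" & !a$het
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop("no CA atoms found for the requested chain")
  seq1 <- .aa321[a$resname]
  seq1[is.na(seq1)] <- "X"
  list(xyz = cbind(a$x, a$y, a$z), seq = paste(seq1, collapse = ""),
       resid = a$resid)
}

# global sequence alignment (match +1, mismatch -1, linear gap -2) returning
# matched (non-gap) position pairs
align_sequences <- function(seq_a, seq_b) {
  letters_all <- unique(c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]]))
  mat <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(seq_a),
    subject = Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(sb != "-")
  keep <- pa != "-" & sb != "-"
  cbind(ia[keep], ib[keep])
}

#' Displacement RMSD between two homologous chains (duplicate alignment)
#'
#' The RMSD between two different proteins is not directly defined, so the
#' spatial separation of two homologs occupying different poses is estimated
#' by the duplicate trick: chain `a` is duplicated, the duplicate is
#' superposed onto chain `b` over sequence-alignment-matched CA pairs, and the
#' CA RMSD between `a` and its own moved duplicate is returned. For identical
#' inputs the result is exactly 0; for homologs superimposed as parts of two
#' complexes it measures how far apart the two subunits sit.
#'
#' @param a,b `Structure`s (or single-chain extracts).
#' @param chain_a,chain_b optional chain IDs restricting each side.
#' @return displacement RMSD in angstrom; the superposition fit RMSD over the
#'   matched pairs is attached as attribute `"fit_rmsd"`.
#' @export
homolog_rmsd <- function(a, b, chain_a = NULL, chain_b = NULL) {
  ta <- chain_ca_trace(a, chain_a)
  tb <- chain_ca_trace(b, chain_b)
  pairs <- align_sequences(ta$seq, tb$seq)
  if (nrow(pairs) < 20)
    stop("fewer than 20 alignment-matched CA pairs; homolog RMSD undefined")
  fit <- kabsch_fit(ta$xyz[pairs[, 1], , drop = FALSE],
                    tb$xyz[pairs[, 2], , drop = FALSE])
  moved <- apply_rt(ta$xyz, fit)
  out <- sqrt(mean(rowSums((moved - ta$xyz)^2)))
  attr(out, "fit_rmsd") <- fit$rmsd
  out
}
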