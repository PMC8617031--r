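# Post-processing of externally generated ternary poses: anchor-distance
# filtering, density clustering on a pose-RMSD metric, and candidate
# selection by externally supplied interface-energy scores.

#' A set of ternary poses sharing one topology
#'
#' @param poses list of `Structure`s with identical chain composition and
#'   atom counts.
#' @param scores optional numeric interface-energy scores (lower = better),
#'   one per pose, supplied by the external docking stage.
#' @param e3_chain chain ID(s) of the E3 selection used as the common
#'   superposition frame.
#' @param mobile_chain chain ID(s) of the mobile subunit whose CA RMSD
#'   defines the clustering metric.
#' @return a `pose_set`.
#' @export
pose_set <- function(poses, scores = NULL, e3_chain, mobile_chain) {
  stopifnot(length(poses) >= 1)
  n_atoms <- vapply(poses, function(p) nrow(p$atoms), 0L)
  if (length(unique(n_atoms)) != 1)
    stop("poses differ in atom count; they must share one topology")
  if (!is.null(scores) && length(scores) != length(poses))
    stop("scores length must match the number of poses")
  structure(list(poses = poses, scores = scores, e3_chain = e3_chain,
                 mobile_chain = mobile_chain),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("pose_set: %d poses (E3 chain %s, mobile chain %s)%s\n",
              length(x$poses), paste(x$e3_chain, collapse = "+"),
              paste(x$mobile_chain, collapse = "+"),
              if (is.null(x$scores)) "" else ", scored"))
  invisible(x)
}

#' Filter poses by an anchor-atom distance criterion
#'
#' Retains exactly the poses whose anchor-anchor distance is strictly below
#' `max_d` — the "less than 50 angstrom" geometric feasibility rule linking
#' the substrate lysine to the catalytic cysteine across the ligase arc. A
#' pose at exactly `max_d` is removed. Order is preserved.
#'
#' @param poses a `pose_set`.
#' @param anchor_a,anchor_b per-pose atom locators, each
#'   `list(chain=, resid=, name=)`.
#' @param max_d cutoff distance in angstrom (default 50).
#' @return a `pose_set` of retained poses, with attributes `"kept"` (original
#'   indices) and `"distances"` (all pose distances).
#' @export
anchor_distance_filter <- function(poses, anchor_a, anchor_b, max_d = 50) {
  d <- vapply(seq_along(poses$poses), function(i) {
    p <- poses$poses[[i]]
    ia <- tryCatch(
      atom_index(p, anchor_a$chain, anchor_a$resid, anchor_a$name),
      error = function(e) stop(sprintf("pose %d: %s", i, conditionMessage(e))))
    ib <- tryCatch(
      atom_index(p, anchor_b$chain, anchor_b$resid, anchor_b$name),
      error = function(e) stop(sprintf("pose %d: %s", i, conditionMessage(e))))
    dist3(as.numeric(coords(p, ia)), as.numeric(coords(p, ib)))
  }, 0)
  keep <- which(d < max_d)
  out <- if (length(keep)) {
    pose_set(poses$poses[keep],
             scores = if (!is.null(poses$scores)) poses$scores[keep],
             e3_chain = poses$e3_chain, mobile_chain = poses$mobile_chain)
  } else {
    structure(list(poses = list(), scores = numeric(0),
                   e3_chain = poses$e3_chain,
                   mobile_chain = poses$mobile_chain),
              class = "pose_set")
  }
  attr(out, "kept") <- keep
  attr(out, "distances") <- d
  out
}

#' Pairwise pose distance matrix (mobile-subunit CA RMSD)
#'
#' Every pose is first superposed on the first pose over the CA atoms of the
#' E3 selection (the common frame); the metric is then the CA RMSD of the
#' mobile subunit between poses, with no further fitting — poses differing
#' only in mobile-subunit placement relative to the fixed E3 score their full
#' displacement.
#'
#' @param poses a `pose_set`.
#' @return symmetric matrix of RMSDs in angstrom.
#' @export
pose_rmsd_matrix <- function(poses) {
  ref <- poses$poses[[1]]
  e3_ca <- select_atoms(ref, chain = poses$e3_chain, name = "CA")
  mob_ca <- select_atoms(ref, chain = poses$mobile_chain, name = "CA")
  ref_e3 <- coords(ref, e3_ca)
  mob_list <- lapply(poses$poses, function(p) {
    fit <- kabsch_fit(coords(p, e3_ca), ref_e3)
    apply_rt(coords(p, mob_ca), fit)
  })
  n <- length(mob_list)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        sqrt(mean(rowSums((mob_list[[i]] - mob_list[[j]])^2)))
    }
  }
  D
}

#' Density-based clustering of poses (DBSCAN)
#'
#' Standard DBSCAN on the pose-RMSD metric of [pose_rmsd_matrix()]: a pose is
#' a core point if at least `min_pts` poses (itself included) lie within
#' `eps`; clusters grow from core points; non-core poses in no cluster are
#' labelled noise (`-1`). The defaults are configuration values, not tuned
#' constants.
#'
#' @param poses a `pose_set`.
#' @param eps neighbourhood radius in angstrom (default 4).
#' @param min_pts core-point threshold including the point itself
#'   (default 3).
#' @return integer cluster label per pose (1, 2, ... in discovery order;
#'   -1 = noise).
#' @export
cluster_poses <- function(poses, eps = 4, min_pts = 3) {
  D <- pose_rmsd_matrix(poses)
  dbscan_labels(D, eps, min_pts)
}

# DBSCAN on a precomputed distance matrix (queue-based expansion)
dbscan_labels <- function(D, eps, min_pts) {
  n <- nrow(D)
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neigh, length, 0L) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neigh[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (is.na(labels[j])) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, neigh[[j]])
      } else if (labels[j] == -1L) {
        labels[j] <- cl
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Select the candidate pose: lowest score among filter survivors
#'
#' Returns the lowest-score pose among those passing the anchor-distance
#' filter; ties break to the lowest pose index. Adding or removing poses that
#' fail the filter cannot change the selection.
#'
#' @param poses a scored `pose_set`.
#' @param filtered the result of [anchor_distance_filter()] on `poses`.
#' @param labels optional cluster labels (from [cluster_poses()]) recorded in
#'   the justification.
#' @return list with `index` (into the original pose set; `NA` if no pose
#'   passes) and `justification` (score, anchor distance, cluster id).
#' @export
select_candidate <- function(poses, filtered, labels = NULL) {
  if (is.null(poses$scores)) stop("select_candidate needs scores")
  kept <- attr(filtered, "kept")
  if (!length(kept))
    return(list(index = NA_integer_,
                justification = list(reason = "no pose passes the anchor filter")))
  sc <- poses$scores[kept]
  best <- kept[which.min(sc)]  # which.min ties break to the first = lowest index
  list(index = best,
       justification = list(
         score = poses$scores[best],
         anchor_distance = attr(filtered, "distances")[best],
         cluster = if (!is.null(labels)) labels[best] else NA_integer_))
}
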