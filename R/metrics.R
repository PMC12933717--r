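# Metric operations: Kabsch superposition, RMSD, neighbour/bond sets,
# pair distances, empirical 1-D Wasserstein distance.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform (rotation + translation, reflections
#' excluded) minimizing the coordinate RMSD of \code{mobile} onto
#' \code{reference}. Mirror images are chemically distinct, so the rotation
#' determinant is forced to +1 even when a reflection would fit better.
#'
#' @param mobile,reference structures with identical element sequences.
#' @return An object of class \code{aefm_superposition}: list with
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length-3), and
#'   \code{rmsd} (Angstrom). The transform maps mobile coordinates as
#'   \code{coords \%*\% t(rotation) + translation}.
#' @examples
#' s <- aefm_structure(c("O", "H", "H"),
#'                     rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' kabsch_superpose(s, s)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference) {
  .check_same_layout(mobile, reference)
  P <- mobile$coords
  Q <- reference$coords
  n <- nrow(P)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)                     # 3 x 3 covariance
  if (n == 1L || max(abs(H)) < 1e-14) {
    R <- diag(3)
  } else {
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  moved <- Pc %*% t(R)
  rmsd_val <- sqrt(sum((moved - Qc)^2) / n)
  translation <- as.numeric(cq - R %*% cp)
  structure(list(rotation = R, translation = translation, rmsd = rmsd_val),
            class = "aefm_superposition")
}

#' Root-mean-square deviation between two structures
#'
#' @param a,b structures with identical element sequences.
#' @param aligned if \code{TRUE} (default), the Kabsch-minimized RMSD after
#'   optimal proper rigid superposition; if \code{FALSE}, the raw
#'   \eqn{\sqrt{\sum_i \|a_i - b_i\|^2 / N}} in the shared frame (the
#'   convention used for successive solver iterates, which live in the
#'   model's working frame).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, aligned = TRUE) {
  .check_same_layout(a, b)
  if (aligned) return(kabsch_superpose(a, b)$rmsd)
  sqrt(sum((a$coords - b$coords)^2) / n_atoms(a))
}

#' Reference neighbour set within a cutoff radius
#'
#' Builds the set of index pairs (i, j), i < j, whose distance in the
#' reference structure is strictly below \code{r_cut}. The default cutoff of
#' 2 Angstrom covers the longest equilibrium bond lengths in H/C/N/O
#' chemistry with a margin for stretched transition-state bonds. The pair
#' list is intended to be built once from the reference geometry and reused
#' on predictions (see \code{\link{bond_loss}}).
#'
#' @param reference an \code{aefm_structure}.
#' @param r_cut cutoff radius in Angstrom (> 0).
#' @return An object of class \code{aefm_bond_set}: list with \code{pairs}
#'   (M x 2 integer matrix, i < j, lexicographic order), \code{r_cut},
#'   \code{n_atoms}, and \code{source_id} (the reference's id).
#' @export
bond_set <- function(reference, r_cut = 2.0) {
  stopifnot(is_aefm_structure(reference))
  if (!is.numeric(r_cut) || length(r_cut) != 1L || !is.finite(r_cut) ||
      r_cut <= 0)
    .aefm_error("r_cut must be a positive number", "aefm_parameter_error")
  n <- n_atoms(reference)
  pairs <- matrix(integer(0), ncol = 2)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(reference$coords))
    idx <- which(upper.tri(d) & d < r_cut, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    }
  }
  dimnames(pairs) <- NULL
  storage.mode(pairs) <- "integer"
  structure(list(pairs = pairs, r_cut = r_cut, n_atoms = n,
                 source_id = reference$id),
            class = "aefm_bond_set")
}

#' Pair distances for a structure
#'
#' Euclidean distances \eqn{d_{ij} = \|x_i - x_j\|} for each pair in a bond
#' set, evaluated on \code{s} (which need not be the structure the set was
#' built from -- that is the point: reference-derived pairs are measured on
#' predictions). Order is deterministic: lexicographic by (i, j).
#'
#' @param s an \code{aefm_structure}.
#' @param bonds an \code{aefm_bond_set}.
#' @return numeric vector of distances (Angstrom), one per pair.
#' @export
pair_distances <- function(s, bonds) {
  stopifnot(is_aefm_structure(s), inherits(bonds, "aefm_bond_set"))
  p <- bonds$pairs
  if (nrow(p) == 0L) return(numeric(0))
  if (max(p) > n_atoms(s) || min(p) < 1L)
    .aefm_error("bond-set indices out of range for this structure",
                "aefm_index_error")
  dv <- s$coords[p[, 1], , drop = FALSE] - s$coords[p[, 2], , drop = FALSE]
  sqrt(rowSums(dv^2))
}

#' Empirical 1-D Wasserstein-1 distance
#'
#' Exact earth-mover's distance between two empirical distributions of real
#' values (possibly of unequal size), computed by merging the quantile
#' breakpoints of both samples and integrating the absolute difference of
#' the quantile functions.
#'
#' @param samples_a,samples_b non-empty numeric vectors.
#' @return non-negative scalar distance (same units as the samples).
#' @examples
#' wasserstein1(c(1, 1, 1), c(3.5, 3.5))  # point masses: |1 - 3.5|
#' @export
wasserstein1 <- function(samples_a, samples_b) {
  if (length(samples_a) == 0L || length(samples_b) == 0L)
    .aefm_error("wasserstein1 requires non-empty samples",
                "aefm_empty_sample")
  if (!all(is.finite(samples_a)) || !all(is.finite(samples_b)))
    .aefm_error("wasserstein1 requires finite samples", "aefm_parameter_error")
  a <- sort(samples_a)
  b <- sort(samples_b)
  na <- length(a)
  nb <- length(b)
  q <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  dq <- diff(c(0, q))
  # left-continuous inverse CDF: F^{-1}(u) = a[k] for u in ((k-1)/n, k/n]
  ia <- pmin(na, ceiling(q * na - 1e-9))
  ib <- pmin(nb, ceiling(q * nb - 1e-9))
  sum(dq * abs(a[ia] - b[ib]))
}
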