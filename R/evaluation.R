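# Refinement metrics and reports: improvement fractions, RMSD statistics,
# bond-length distribution similarity, improvement-vs-initial-quality
# curves.

# Covalent radii (Angstrom) for the bonded/nonbonded classification rule.
.COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                     Br = 1.20, I = 1.39)

#' Covalent-radius bonded/nonbonded classification rule
#'
#' A pair is "bonded" when its reference distance is below the sum of the
#' two covalent radii plus a 0.4 Angstrom margin. The rule is injectable in
#' \code{\link{bond_distribution_report}} so alternative thresholds can be
#' dropped in.
#'
#' @param element_i,element_j element symbols (vectorized).
#' @param distance reference distances (Angstrom).
#' @return logical vector: bonded or not.
#' @export
covalent_bonded_rule <- function(element_i, element_j, distance) {
  ri <- .COVALENT_RADII[element_i]
  rj <- .COVALENT_RADII[element_j]
  ri[is.na(ri)] <- 0.77
  rj[is.na(rj)] <- 0.77
  distance < ri + rj + 0.4
}

#' Summarize a refinement experiment
#'
#' Per-structure aligned RMSDs before and after refinement, improvement
#' fractions (improvement = strict decrease), optional energy errors when
#' an analytic energy callable is supplied (the 2D toy; quantum-chemical
#' energies are out of scope), and bonded/nonbonded distance-distribution
#' Wasserstein-1 distances against the reference pool.
#'
#' @param initial,refined,reference parallel lists of structures (element
#'   sequences must agree within each triple).
#' @param energy_fn optional function taking a structure (or coordinate
#'   matrix) and returning a scalar energy; enables the energy-improvement
#'   metrics as |E(x) - E(x_ref)|.
#' @param fp_results optional list of \code{aefm_fixed_point} results to
#'   merge per-structure \code{n_iter}/\code{converged} columns.
#' @param r_cut cutoff for the distance pools (Angstrom).
#' @return An object of class \code{aefm_refinement_report}: list with
#'   \code{records} (data frame) and \code{aggregates} (list).
#' @export
summarize_refinement <- function(initial, refined, reference,
                                 energy_fn = NULL, fp_results = NULL,
                                 r_cut = 2.0) {
  n <- length(reference)
  stopifnot(length(initial) == n, length(refined) == n, n >= 1L)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    ini <- initial[[i]]; ref <- refined[[i]]; tru <- reference[[i]]
    ok <- tryCatch({
      .check_same_layout(ini, tru)
      .check_same_layout(ref, tru)
      TRUE
    }, aefm_structure_mismatch = function(e) FALSE)
    if (!ok)
      .aefm_error(sprintf("record %d: mismatched triple%s", i,
                          if (is.null(tru$id)) "" else paste0(" (", tru$id, ")")),
                  "aefm_structure_mismatch")
    r0 <- rmsd(ini, tru, aligned = TRUE)
    r1 <- rmsd(ref, tru, aligned = TRUE)
    row <- data.frame(
      id = if (is.null(tru$id)) sprintf("record_%d", i) else tru$id,
      initial_rmsd = r0, refined_rmsd = r1,
      improved_rmsd = r1 < r0)
    if (!is.null(energy_fn)) {
      e_ref <- energy_fn(tru$coords)
      row$initial_energy_err <- abs(energy_fn(ini$coords) - e_ref)
      row$refined_energy_err <- abs(energy_fn(ref$coords) - e_ref)
      row$improved_energy <- row$refined_energy_err < row$initial_energy_err
    }
    if (!is.null(fp_results)) {
      row$n_iter <- fp_results[[i]]$n_iter
      row$converged <- fp_results[[i]]$converged
    }
    rec[[i]] <- row
  }
  records <- do.call(rbind, rec)
  w1 <- tryCatch({
    rep_ini <- bond_distribution_report(initial, references = reference,
                                        r_cut = r_cut)
    rep_fin <- bond_distribution_report(refined, references = reference,
                                        r_cut = r_cut)
    list(initial_bonded = rep_ini$set_a$w1_bonded,
         initial_nonbonded = rep_ini$set_a$w1_nonbonded,
         refined_bonded = rep_fin$set_a$w1_bonded,
         refined_nonbonded = rep_fin$set_a$w1_nonbonded)
  }, aefm_empty_sample = function(e) NULL)
  aggregates <- list(
    n = n,
    mean_initial_rmsd = mean(records$initial_rmsd),
    median_initial_rmsd = median(records$initial_rmsd),
    mean_refined_rmsd = mean(records$refined_rmsd),
    median_refined_rmsd = median(records$refined_rmsd),
    fraction_improved_rmsd = mean(records$improved_rmsd),
    fraction_improved_energy =
      if (is.null(energy_fn)) NA_real_ else mean(records$improved_energy),
    fraction_improved_both =
      if (is.null(energy_fn)) NA_real_
      else mean(records$improved_rmsd & records$improved_energy),
    w1 = w1)
  structure(list(records = records, aggregates = aggregates),
            class = "aefm_refinement_report")
}

#' @export
print.aefm_refinement_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf(
    paste0("<aefm_refinement_report: %d structures\n",
           "  RMSD (A)   mean %.4f -> %.4f | median %.4f -> %.4f\n",
           "  improved in RMSD: %.1f%%%s>\n"),
    a$n, a$mean_initial_rmsd, a$mean_refined_rmsd,
    a$median_initial_rmsd, a$median_refined_rmsd,
    100 * a$fraction_improved_rmsd,
    if (is.na(a$fraction_improved_energy)) ""
    else sprintf(", in energy: %.1f%%, in both: %.1f%%",
                 100 * a$fraction_improved_energy,
                 100 * a$fraction_improved_both)))
  invisible(x)
}

#' Bond-length distribution comparison
#'
#' Pools, for every reference structure, the pair distances within
#' \code{r_cut}, splits the pairs into bonded and nonbonded by the
#' (reference-geometry) classification rule, and evaluates the same
#' reference-derived index pairs on each candidate set. Returns the
#' Wasserstein-1 distance of each candidate pool against the reference
#' pool, overall and per element pair.
#'
#' @param structures_a candidate set (parallel to \code{references}).
#' @param structures_b optional second candidate set.
#' @param references list of reference structures.
#' @param r_cut pooling cutoff (Angstrom).
#' @param bonded_rule function \code{(element_i, element_j, distance) ->
#'   logical}; default \code{\link{covalent_bonded_rule}}.
#' @return list with \code{set_a} (and \code{set_b} if given), each a list
#'   with \code{w1_bonded}, \code{w1_nonbonded} and \code{per_pair} (data
#'   frame with element-pair labels and bonded W1 distances), plus the
#'   pooled reference distances.
#' @export
bond_distribution_report <- function(structures_a, structures_b = NULL,
                                     references, r_cut = 2.0,
                                     bonded_rule = covalent_bonded_rule) {
  n <- length(references)
  stopifnot(length(structures_a) == n)
  if (!is.null(structures_b)) stopifnot(length(structures_b) == n)

  pool <- function(cands) {
    ref_d <- list(); cand_d <- list(); bonded <- list(); label <- list()
    for (i in seq_len(n)) {
      ref <- references[[i]]
      .check_same_layout(cands[[i]], ref)
      bs <- bond_set(ref, r_cut)
      if (nrow(bs$pairs) == 0L) next
      dr <- pair_distances(ref, bs)
      dc <- pair_distances(cands[[i]], bs)
      ei <- ref$elements[bs$pairs[, 1]]
      ej <- ref$elements[bs$pairs[, 2]]
      ref_d[[length(ref_d) + 1L]] <- dr
      cand_d[[length(cand_d) + 1L]] <- dc
      bonded[[length(bonded) + 1L]] <- bonded_rule(ei, ej, dr)
      label[[length(label) + 1L]] <-
        paste(pmin(ei, ej), pmax(ei, ej), sep = "-")
    }
    list(ref = unlist(ref_d), cand = unlist(cand_d),
         bonded = unlist(bonded), label = unlist(label))
  }

  one_report <- function(p) {
    if (!length(p$ref) || !any(p$bonded))
      .aefm_error("empty bonded pool within r_cut", "aefm_empty_sample")
    w1_b <- wasserstein1(p$cand[p$bonded], p$ref[p$bonded])
    w1_n <- if (any(!p$bonded))
      wasserstein1(p$cand[!p$bonded], p$ref[!p$bonded]) else NA_real_
    labs <- sort(unique(p$label[p$bonded]))
    per_pair <- data.frame(
      pair = labs,
      n = vapply(labs, function(l) sum(p$bonded & p$label == l), 0L),
      w1_bonded = vapply(labs, function(l) {
        sel <- p$bonded & p$label == l
        wasserstein1(p$cand[sel], p$ref[sel])
      }, 0.0), row.names = NULL)
    list(w1_bonded = w1_b, w1_nonbonded = w1_n, per_pair = per_pair)
  }

  pa <- pool(structures_a)
  out <- list(set_a = one_report(pa),
              reference_pool = list(distances = pa$ref, bonded = pa$bonded,
                                    label = pa$label))
  if (!is.null(structures_b)) out$set_b <- one_report(pool(structures_b))
  out
}

#' Improvement statistics as a function of initial quality
#'
#' For each threshold, restricts the records to those whose initial RMSD is
#' strictly below it and reports the subset's improvement statistics. Empty
#' subsets yield explicit \code{NA} markers, not zeros.
#'
#' @param records data frame with columns \code{initial_rmsd} and
#'   \code{refined_rmsd} (e.g. from \code{\link{summarize_refinement}}).
#' @param thresholds numeric vector, sorted ascending (Angstrom;
#'   \code{Inf} reproduces the global aggregates).
#' @return data frame with one row per threshold: \code{threshold},
#'   \code{n}, \code{fraction_improved}, \code{mean_improvement} (mean of
#'   initial - refined RMSD), \code{median_refined_rmsd}.
#' @export
improvement_vs_threshold <- function(records, thresholds) {
  stopifnot(is.data.frame(records),
            all(c("initial_rmsd", "refined_rmsd") %in% names(records)))
  if (is.unsorted(thresholds, strictly = FALSE))
    .aefm_error("thresholds must be sorted ascending", "aefm_parameter_error")
  rows <- lapply(thresholds, function(th) {
    sub <- records[records$initial_rmsd < th, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(threshold = th, n = 0L,
                        fraction_improved = NA_real_,
                        mean_improvement = NA_real_,
                        median_refined_rmsd = NA_real_))
    data.frame(threshold = th, n = nrow(sub),
               fraction_improved = mean(sub$refined_rmsd < sub$initial_rmsd),
               mean_improvement = mean(sub$initial_rmsd - sub$refined_rmsd),
               median_refined_rmsd = median(sub$refined_rmsd))
  })
  do.call(rbind, rows)
}
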