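# Refinement reports, bond-length distribution comparisons and
# improvement-vs-threshold curves.

# 2-atom structures with chosen bond-length distortions give closed-form
# aligned RMSDs (each atom moves by delta/2 after superposition).
stretch_pair <- function(d, delta, id = NULL) {
  ref <- aefm_structure(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)), id = id)
  cand <- set_coords(ref, rbind(c(0, 0, 0), c(d + delta, 0, 0)))
  list(ref = ref, cand = cand)
}

test_that("summary extremes: perfect refinement and no-op refinement", {
  set.seed(139)
  refs <- toy_structures(4, 5, seed = 51)
  inis <- lapply(refs, function(r) set_coords(r, r$coords +
                                                0.2 * matrix(rnorm(15), 5, 3)))
  perfect <- summarize_refinement(inis, refs, refs)
  expect_equal(perfect$aggregates$median_refined_rmsd, 0)
  expect_equal(perfect$aggregates$fraction_improved_rmsd, 1)
  noop <- summarize_refinement(inis, inis, refs)
  expect_equal(noop$aggregates$fraction_improved_rmsd, 0)
})

test_that("aggregates match a hand-computed 10-record fixture", {
  deltas_ini <- c(0.10, 0.08, 0.20, 0.12, 0.30, 0.16, 0.24, 0.40, 0.06, 0.18)
  deltas_fin <- c(0.02, 0.10, 0.08, 0.04, 0.10, 0.20, 0.06, 0.12, 0.02, 0.04)
  ini <- list(); fin <- list(); ref <- list()
  for (i in 1:10) {
    p <- stretch_pair(1.4, deltas_ini[i], id = paste0("r", i))
    ref[[i]] <- p$ref
    ini[[i]] <- p$cand
    fin[[i]] <- set_coords(p$ref, rbind(c(0, 0, 0), c(1.4 + deltas_fin[i], 0, 0)))
  }
  rep <- summarize_refinement(ini, fin, ref)
  # aligned rmsd of a stretched 2-atom pair is delta/2
  expect_equal(rep$records$initial_rmsd, deltas_ini / 2, tolerance = 1e-10)
  expect_equal(rep$records$refined_rmsd, deltas_fin / 2, tolerance = 1e-10)
  expect_equal(rep$aggregates$mean_initial_rmsd, mean(deltas_ini) / 2,
               tolerance = 1e-10)
  expect_equal(rep$aggregates$median_refined_rmsd, median(deltas_fin) / 2,
               tolerance = 1e-10)
  expect_equal(rep$aggregates$fraction_improved_rmsd,
               mean(deltas_fin < deltas_ini))

  # energy metrics with an analytic callable: squared bond stretch
  efn <- function(coords) (sqrt(sum((coords[2, ] - coords[1, ])^2)) - 1.4)^2
  repE <- summarize_refinement(ini, fin, ref, energy_fn = efn)
  expect_equal(repE$aggregates$fraction_improved_energy,
               mean(deltas_fin^2 < deltas_ini^2))
  expect_lte(repE$aggregates$fraction_improved_both,
             min(repE$aggregates$fraction_improved_rmsd,
                 repE$aggregates$fraction_improved_energy))
})

test_that("report aggregates are permutation invariant", {
  set.seed(149)
  refs <- toy_structures(6, 5, seed = 61)
  inis <- lapply(refs, function(r)
    set_coords(r, r$coords + 0.15 * matrix(rnorm(15), 5, 3)))
  fins <- lapply(refs, function(r)
    set_coords(r, r$coords + 0.05 * matrix(rnorm(15), 5, 3)))
  a <- summarize_refinement(inis, fins, refs)$aggregates
  p <- sample(6)
  b <- summarize_refinement(inis[p], fins[p], refs[p])$aggregates
  expect_equal(a[names(a) != "w1"], b[names(b) != "w1"], tolerance = 1e-12)
})

test_that("bond distribution W1 honors identity and shift properties", {
  ps <- lapply(c(1.2, 1.4, 1.5, 1.1, 1.3), function(d) stretch_pair(d, 0))
  refs <- lapply(ps, `[[`, "ref")
  ident <- bond_distribution_report(refs, references = refs)
  expect_equal(ident$set_a$w1_bonded, 0)

  delta <- 0.07
  shifted <- lapply(ps, function(p)
    set_coords(p$ref, rbind(c(0, 0, 0),
                            c(p$ref$coords[2, 1] + delta, 0, 0))))
  shift_rep <- bond_distribution_report(shifted, references = refs)
  expect_equal(shift_rep$set_a$w1_bonded, delta, tolerance = 1e-10)

  expect_error(
    bond_distribution_report(
      list(aefm_structure(c("C", "C"), rbind(c(0, 0, 0), c(8, 0, 0)))),
      references = list(aefm_structure(c("C", "C"),
                                       rbind(c(0, 0, 0), c(8, 0, 0))))),
    class = "aefm_empty_sample")
})

test_that("per-element-pair pooling matches a brute-force regroup", {
  set.seed(151)
  refs <- lapply(1:6, function(i) rand_structure(8))
  cands <- lapply(refs, function(r)
    set_coords(r, r$coords + 0.1 * matrix(rnorm(24), 8, 3)))
  rep <- bond_distribution_report(cands, references = refs)
  # brute-force pools
  rd <- list(); cd <- list(); lab <- list(); bnd <- list()
  for (i in seq_along(refs)) {
    bs <- bond_set(refs[[i]], 2.0)
    if (!nrow(bs$pairs)) next
    dr <- pair_distances(refs[[i]], bs)
    dc <- pair_distances(cands[[i]], bs)
    ei <- refs[[i]]$elements[bs$pairs[, 1]]
    ej <- refs[[i]]$elements[bs$pairs[, 2]]
    rd[[i]] <- dr; cd[[i]] <- dc
    lab[[i]] <- paste(pmin(ei, ej), pmax(ei, ej), sep = "-")
    bnd[[i]] <- covalent_bonded_rule(ei, ej, dr)
  }
  rd <- unlist(rd); cd <- unlist(cd); lab <- unlist(lab); bnd <- unlist(bnd)
  for (r in seq_len(nrow(rep$set_a$per_pair))) {
    l <- rep$set_a$per_pair$pair[r]
    sel <- bnd & lab == l
    expect_equal(rep$set_a$per_pair$w1_bonded[r],
                 wasserstein1(cd[sel], rd[sel]), tolerance = 1e-12)
  }
})

test_that("improvement-vs-threshold curves subset records correctly", {
  records <- data.frame(initial_rmsd = c(0.1, 0.2, 0.3, 0.4),
                        refined_rmsd = c(0.05, 0.25, 0.1, 0.2))
  curve <- improvement_vs_threshold(records, c(0.05, 0.25, Inf))
  # below all records: explicit NA markers
  expect_equal(curve$n[1], 0L)
  expect_true(is.na(curve$fraction_improved[1]))
  # threshold 0.25 keeps records 1 and 2: one improved of two
  expect_equal(curve$n[2], 2L)
  expect_equal(curve$fraction_improved[2], 0.5)
  expect_equal(curve$mean_improvement[2], mean(c(0.05, -0.05)),
               tolerance = 1e-12)
  # Inf reproduces the global aggregates
  expect_equal(curve$n[3], 4L)
  expect_equal(curve$fraction_improved[3], 0.75)
  expect_error(improvement_vs_threshold(records, c(0.3, 0.1)),
               class = "aefm_parameter_error")
})
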