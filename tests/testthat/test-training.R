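# Losses and the training loop.

test_that("endpoint loss matches brute-force recomputation", {
  s <- aefm_structure("C", c(0, 0, 0))
  p <- set_coords(s, matrix(c(0.1, 0, 0), 1))
  expect_equal(aefm_loss(p, s), 0.01, tolerance = 1e-15)
  expect_equal(aefm_loss(s, s), 0)

  set.seed(73)
  for (rep in 1:10) {
    x1 <- rand_structure(7)
    pred <- set_coords(x1, x1$coords + 0.2 * matrix(rnorm(21), 7, 3))
    brute <- 0
    for (i in 1:7) for (c in 1:3)
      brute <- brute + (x1$coords[i, c] - pred$coords[i, c])^2
    expect_equal(aefm_loss(pred, x1), brute / 7, tolerance = 1e-12)
  }
  expect_error(aefm_loss(p, rand_structure(3)),
               class = "aefm_structure_mismatch")
})

test_that("bond loss evaluates reference pairs on predictions", {
  x1 <- aefm_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                       id = "two")
  bonds <- bond_set(x1, 2.0)
  expect_equal(bond_loss(x1, x1, bonds), 0)
  pred <- set_coords(x1, rbind(c(0, 0, 0), c(1.3, 0, 0)))
  expect_equal(bond_loss(pred, x1, bonds), 0.01, tolerance = 1e-12)

  set.seed(79)
  for (rep in 1:10) {
    ref <- rand_structure(8)
    bs <- bond_set(ref, 2.0)
    pr <- set_coords(ref, ref$coords + 0.15 * matrix(rnorm(24), 8, 3))
    if (nrow(bs$pairs) == 0) next
    brute <- 0
    for (r in seq_len(nrow(bs$pairs))) {
      i <- bs$pairs[r, 1]; j <- bs$pairs[r, 2]
      dr <- sqrt(sum((ref$coords[i, ] - ref$coords[j, ])^2))
      dp <- sqrt(sum((pr$coords[i, ] - pr$coords[j, ])^2))
      brute <- brute + (dp - dr)^2
    }
    expect_equal(bond_loss(pr, ref, bs), brute / nrow(bs$pairs),
                 tolerance = 1e-12)
  }

  # provenance: a bond set from a different labelled reference is rejected
  other <- aefm_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
                          id = "other")
  expect_error(bond_loss(pred, x1, bond_set(other, 2.0)),
               class = "aefm_provenance_error")
  # empty bond set contributes zero
  far <- aefm_structure(c("C", "C"), rbind(c(0, 0, 0), c(9, 0, 0)),
                        id = "far")
  expect_equal(bond_loss(far, far, bond_set(far, 2.0)), 0)
})

test_that("total loss decomposes with the bond weight", {
  set.seed(83)
  x1 <- rand_structure(6)
  pred <- set_coords(x1, x1$coords + 0.1 * matrix(rnorm(18), 6, 3))
  bonds <- bond_set(x1, 2.0)
  expect_equal(total_loss(pred, x1, bonds, w_b = 0), aefm_loss(pred, x1))
  expect_equal(total_loss(x1, x1, bonds), 0)
  expect_equal(total_loss(pred, x1, bonds, w_b = 1),
               aefm_loss(pred, x1) + bond_loss(pred, x1, bonds),
               tolerance = 1e-15)
  # arithmetic example: components 0.02 and 0.005 at w_b = 1 give 0.025
  expect_equal(0.02 + 1.0 * 0.005, 0.025)
})

test_that("loss terms are invariant under a joint rotation", {
  set.seed(89)
  x1 <- rand_structure(6)
  pred <- set_coords(x1, x1$coords + 0.1 * matrix(rnorm(18), 6, 3))
  bonds <- bond_set(x1, 2.0)
  R <- rand_rotation()
  x1r <- set_coords(x1, x1$coords %*% t(R))
  predr <- set_coords(pred, pred$coords %*% t(R))
  expect_equal(aefm_loss(predr, x1r), aefm_loss(pred, x1), tolerance = 1e-10)
  bondsr <- bond_set(x1r, 2.0)
  expect_equal(bond_loss(predr, x1r, bondsr), bond_loss(pred, x1, bonds),
               tolerance = 1e-10)
})

test_that("degenerate noiseless training is a no-op at identity init", {
  tmpl <- toy_structures(5, 4, seed = 21)
  fit <- train_refiner(tmpl, train_config(sigma = 0, sigma_fm = 0,
                                          epochs = 2, batch_size = 2,
                                          seed = 4),
                       reference_net_config(layers = 2, hidden = 8,
                                            n_basis = 6, seed = 4))
  expect_equal(max(fit$history$total), 0)
  fresh <- build_reference_net(reference_net_config(layers = 2, hidden = 8,
                                                    n_basis = 6, seed = 4))
  expect_equal(aefm:::.flatten_params(fit$model$params),
               aefm:::.flatten_params(fresh$params), tolerance = 1e-12)
})

test_that("toy training reduces the loss deterministically", {
  tmpl <- generate_templates(template_spec(20, atoms_min = 4, atoms_max = 6,
                                           seed = 15))
  cfg <- train_config(sigma = 0.15, epochs = 30, batch_size = 4,
                      learning_rate = 0.01, seed = 5)
  nc <- reference_net_config(layers = 2, hidden = 16, n_basis = 8, seed = 5)
  fit <- train_refiner(tmpl, cfg, nc)
  expect_lt(tail(fit$history$total, 1), fit$history$total[1])
  # decomposition identity on every logged epoch
  expect_equal(fit$history$total,
               fit$history$aefm + cfg$w_b * fit$history$bond,
               tolerance = 1e-12)
  # exact reproducibility
  fit2 <- train_refiner(tmpl, cfg, nc)
  expect_identical(fit$history, fit2$history)
  expect_identical(aefm:::.flatten_params(fit$model$params),
                   aefm:::.flatten_params(fit2$model$params))
})

test_that("training from pairs calibrates sigma automatically", {
  set.seed(95)
  refs <- toy_structures(12, 5, seed = 33)
  pairs <- lapply(seq_along(refs), function(i)
    refinement_pair(refs[[i]], corrupt(refs[[i]], 0.2), paste0("r", i)))
  fit <- train_refiner(pairs, train_config(epochs = 2, batch_size = 4,
                                           seed = 6),
                       reference_net_config(layers = 1, hidden = 4,
                                            n_basis = 4, seed = 6))
  expect_equal(fit$model$calibration$sigma, 0.2, tolerance = 0.25)
  expect_equal(fit$model$metadata$sigma_used, fit$model$calibration$sigma)
})
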