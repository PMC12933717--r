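# Training objective (endpoint-prediction loss + bond-consistency loss)
# and the training loop for the reference equivariant net.

#' Endpoint-prediction loss
#'
#' Mean squared coordinate error of a prediction against the reference,
#' \eqn{\|x_1 - \phi_\theta(x_t)\|^2 / N}, averaged over atoms.
#'
#' @param pred predicted structure.
#' @param x1 reference structure (same element sequence).
#' @return non-negative scalar (Angstrom^2).
#' @export
aefm_loss <- function(pred, x1) {
  .check_same_layout(pred, x1)
  sum((x1$coords - pred$coords)^2) / n_atoms(x1)
}

#' Bond-consistency loss
#'
#' Mean squared error of pair distances over the reference-derived
#' neighbour set: the pair list is built once from the reference geometry
#' and the very same index pairs are measured on the prediction, penalizing
#' bond-length distortions that barely move the positional loss. Returns 0
#' for an empty neighbour set.
#'
#' @param pred predicted structure.
#' @param x1 reference structure the bond set was built from.
#' @param bonds \code{aefm_bond_set} built from \code{x1}.
#' @return non-negative scalar (Angstrom^2).
#' @export
bond_loss <- function(pred, x1, bonds) {
  .check_same_layout(pred, x1)
  stopifnot(inherits(bonds, "aefm_bond_set"))
  if (!is.null(bonds$source_id) && !is.null(x1$id) &&
      !identical(bonds$source_id, x1$id))
    .aefm_error(sprintf(
      "bond set was built from '%s', not from reference '%s'",
      bonds$source_id, x1$id), "aefm_provenance_error")
  if (bonds$n_atoms != n_atoms(x1))
    .aefm_error("bond set atom count disagrees with the reference",
                "aefm_provenance_error")
  if (nrow(bonds$pairs) == 0L) return(0)
  dp <- pair_distances(pred, bonds)
  dr <- pair_distances(x1, bonds)
  mean((dp - dr)^2)
}

#' Total training loss
#'
#' \eqn{L = L_{AEFM} + w_b L_b} with the bond-loss weight defaulting to 1.
#'
#' @inheritParams bond_loss
#' @param w_b bond-loss weight (>= 0, default 1).
#' @return scalar loss.
#' @export
total_loss <- function(pred, x1, bonds, w_b = 1.0) {
  if (!is.numeric(w_b) || length(w_b) != 1L || is.na(w_b) || w_b < 0)
    .aefm_error("w_b must be a single non-negative number",
                "aefm_parameter_error")
  aefm_loss(pred, x1) + w_b * bond_loss(pred, x1, bonds)
}

#' Training configuration
#'
#' @param sigma corruption scale in Angstrom; if \code{NULL} it is
#'   calibrated from the training pairs (required when training from bare
#'   reference structures).
#' @param sigma_fm interpolation path noise (default 0.05).
#' @param w_b bond-loss weight (default 1.0).
#' @param r_cut bond-set cutoff in Angstrom (default 2.0).
#' @param epochs,batch_size,learning_rate optimizer settings (adaptive-
#'   moment gradient descent with cosine learning-rate decay).
#' @param val_fraction fraction of references held out for per-epoch
#'   validation RMSD (split fixed by \code{seed}).
#' @param use_pairs if \code{TRUE} and pairs are supplied, train on the
#'   actual low-fidelity geometries as source samples instead of Gaussian
#'   corruption of the references (optional variant; the default follows
#'   the corruption-prior training scheme).
#' @param seed RNG seed controlling the split, corruption draws and
#'   interpolation times.
#' @return list of class \code{aefm_train_config}.
#' @export
train_config <- function(sigma = NULL, sigma_fm = 0.05, w_b = 1.0,
                         r_cut = 2.0, epochs = 200L, batch_size = 16L,
                         learning_rate = 0.005, val_fraction = 0.1,
                         use_pairs = FALSE, seed = 1L) {
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma < 0))
    .aefm_error("sigma must be >= 0", "aefm_parameter_error")
  if (sigma_fm < 0 || w_b < 0 || r_cut <= 0 || epochs < 1L ||
      batch_size < 1L || learning_rate <= 0 ||
      val_fraction < 0 || val_fraction >= 1)
    .aefm_error("invalid training configuration", "aefm_parameter_error")
  structure(list(sigma = sigma, sigma_fm = sigma_fm, w_b = w_b,
                 r_cut = r_cut, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, use_pairs = isTRUE(use_pairs),
                 seed = as.integer(seed)),
            class = "aefm_train_config")
}

# Gradient of the total loss w.r.t. the predicted coordinates.
.loss_grad_coords <- function(pred_coords, ref_coords, bond_pairs,
                              ref_bond_d, w_b) {
  n <- nrow(pred_coords)
  G <- 2 * (pred_coords - ref_coords) / n
  if (w_b > 0 && nrow(bond_pairs) > 0L) {
    i <- bond_pairs[, 1]
    j <- bond_pairs[, 2]
    dv <- pred_coords[i, , drop = FALSE] - pred_coords[j, , drop = FALSE]
    dp <- sqrt(rowSums(dv^2))
    coef <- w_b * 2 * (dp - ref_bond_d) / nrow(bond_pairs) / pmax(dp, 1e-12)
    G <- G + .scatter_pm(coef * dv, i, j, n)
  }
  G
}

#' Train the reference refiner
#'
#' Fits the time-independent refiner by stochastic gradient descent on the
#' combined objective. Per sample and epoch a fresh corruption
#' \eqn{x_0 = x_1 + \sigma\epsilon} and interpolation point
#' \eqn{x_t = (1-t)x_0 + t x_1 + \sigma_{FM}\epsilon'} with
#' \eqn{t \sim U(0,1)} are drawn, and
#' \eqn{L_{AEFM} + w_b L_b} of \eqn{\phi_\theta(x_t)} against \eqn{x_1} is
#' minimized. Reference-derived bond sets are computed once and cached;
#' they are never rebuilt from predictions. Fully reproducible given the
#' config seed.
#'
#' @param data list of reference \code{aefm_structure}s, or list of
#'   \code{aefm_refinement_pair}s (in which case \code{sigma} is calibrated
#'   from the pairs when not set explicitly).
#' @param cfg an \code{\link{train_config}}.
#' @param net_config optional \code{\link{reference_net_config}}; defaults
#'   to the standard architecture seeded from the training seed.
#' @return list with \code{model} (trained \code{aefm_refnet}, carrying the
#'   calibration and training metadata) and \code{history} (per-epoch
#'   data frame: \code{epoch}, \code{total}, \code{aefm}, \code{bond},
#'   \code{val_rmsd}).
#' @export
train_refiner <- function(data, cfg = train_config(), net_config = NULL) {
  stopifnot(inherits(cfg, "aefm_train_config"))
  if (length(data) == 0L)
    .aefm_error("no training data", "aefm_empty_dataset")
  is_pairs <- inherits(data[[1]], "aefm_refinement_pair")
  refs <- if (is_pairs) lapply(data, `[[`, "reference") else data
  stopifnot(all(vapply(refs, is_aefm_structure, TRUE)))
  calibration <- NULL
  sigma <- cfg$sigma
  if (is.null(sigma)) {
    if (!is_pairs)
      .aefm_error("sigma must be given when training from bare references",
                  "aefm_parameter_error")
    calibration <- calibrate_sigma(data)
    sigma <- calibration$sigma
  } else if (is_pairs) {
    calibration <- calibrate_sigma(data)
  }
  if (is.null(net_config)) net_config <- reference_net_config(seed = cfg$seed)
  model <- build_reference_net(net_config)

  # per-structure static precomputation
  prep <- lapply(seq_along(refs), function(k) {
    x1 <- refs[[k]]
    bonds <- bond_set(x1, cfg$r_cut)
    list(x1 = x1, coords = x1$coords,
         layout = .refnet_layout(net_config, x1$elements),
         bonds = bonds, ref_bond_d = pair_distances(x1, bonds),
         low = if (is_pairs) data[[k]]$low_fidelity else NULL)
  })

  history <- NULL
  .with_seed(cfg$seed, {
    n <- length(prep)
    n_val <- if (n >= 10L) max(1L, round(cfg$val_fraction * n)) else 0L
    val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (!length(train_idx)) train_idx <- seq_len(n)

    theta <- .flatten_params(model$params)
    m1 <- numeric(length(theta))
    m2 <- numeric(length(theta))
    step <- 0L
    hist_rows <- vector("list", cfg$epochs)

    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate *
        (0.05 + 0.95 * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs)))
      order_idx <- sample(train_idx)
      acc <- NULL
      acc_n <- 0L
      ep_aefm <- 0; ep_bond <- 0; ep_total <- 0; ep_n <- 0L
      flush <- function() {
        if (acc_n == 0L) return()
        g <- acc / acc_n
        # an effectively zero gradient (degenerate noiseless objective)
        # must not trigger an adaptive-moment step: Adam rescales even
        # float-rounding noise to full learning-rate updates
        if (max(abs(g)) < 1e-10) {
          acc <<- NULL
          acc_n <<- 0L
          return()
        }
        step <<- step + 1L
        m1 <<- 0.9 * m1 + 0.1 * g
        m2 <<- 0.999 * m2 + 0.001 * g^2
        mhat <- m1 / (1 - 0.9^step)
        vhat <- m2 / (1 - 0.999^step)
        theta <<- theta - lr * mhat / (sqrt(vhat) + 1e-8)
        model$params <<- .unflatten_params(model$params, theta)
        acc <<- NULL
        acc_n <<- 0L
      }
      for (k in order_idx) {
        pk <- prep[[k]]
        na <- nrow(pk$coords)
        x0c <- if (cfg$use_pairs && !is.null(pk$low)) pk$low$coords
               else pk$coords + sigma * matrix(rnorm(3 * na), na, 3)
        t <- runif(1)
        xtc <- (1 - t) * x0c + t * pk$coords +
          cfg$sigma_fm * matrix(rnorm(3 * na), na, 3)
        fwd <- .refnet_forward(model, xtc, pk$layout, record = TRUE)
        l_aefm <- sum((pk$coords - fwd$out)^2) / na
        l_bond <- if (nrow(pk$bonds$pairs)) {
          i <- pk$bonds$pairs[, 1]; j <- pk$bonds$pairs[, 2]
          dp <- sqrt(rowSums((fwd$out[i, , drop = FALSE] -
                                fwd$out[j, , drop = FALSE])^2))
          mean((dp - pk$ref_bond_d)^2)
        } else 0
        l_total <- l_aefm + cfg$w_b * l_bond
        if (!is.finite(l_total))
          .aefm_error(sprintf("training diverged at epoch %d (non-finite loss)",
                              epoch), "aefm_training_failure")
        G <- .loss_grad_coords(fwd$out, pk$coords, pk$bonds$pairs,
                               pk$ref_bond_d, cfg$w_b)
        bk <- .refnet_backward(model, pk$layout, fwd$cache, G)
        gflat <- .flatten_params(bk$grads)
        acc <- if (is.null(acc)) gflat else acc + gflat
        acc_n <- acc_n + 1L
        ep_aefm <- ep_aefm + l_aefm
        ep_bond <- ep_bond + l_bond
        ep_total <- ep_total + l_total
        ep_n <- ep_n + 1L
        if (acc_n >= cfg$batch_size) flush()
      }
      flush()
      val_rmsd <- NA_real_
      if (length(val_idx)) {
        vr <- vapply(val_idx, function(k) {
          pk <- prep[[k]]
          na <- nrow(pk$coords)
          x0c <- pk$coords + sigma * matrix(rnorm(3 * na), na, 3)
          out <- .refnet_forward(model, x0c, pk$layout)$out
          kabsch_superpose(set_coords(pk$x1, out), pk$x1)$rmsd
        }, 0.0)
        val_rmsd <- median(vr)
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, total = ep_total / ep_n, aefm = ep_aefm / ep_n,
        bond = ep_bond / ep_n, val_rmsd = val_rmsd)
    }
    history <- do.call(rbind, hist_rows)
  })
  model$calibration <- if (is.null(calibration) && !is.null(sigma))
    structure(list(sigma = sigma, n_pairs = NA_integer_,
                   mean_sq_dev_per_atom = 3 * sigma^2,
                   provenance = "explicit"),
              class = "aefm_prior_calibration")
  else calibration
  model$metadata <- c(model$metadata,
                      list(train = unclass(cfg), sigma_used = sigma))
  list(model = model, history = history)
}
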