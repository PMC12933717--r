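# Desk-scale synthetic fixtures with the statistical structure the method
# assumes: chemically plausible reference geometries, Gaussian-corrupted
# low-fidelity counterparts of known scale, and a 2D Mueller-Brown
# saddle-refinement toy.

#' Default bond-length table for the template generator
#'
#' Representative equilibrium bond lengths (mean, spread) in Angstrom for
#' unordered element pairs over H/C/N/O. Fixture parameters for synthetic
#' data, not measured constants.
#'
#' @param elements element subset to include.
#' @return named list; names like \code{"C-H"} (alphabetical), values
#'   \code{c(mean, spread)}.
#' @export
default_bond_table <- function(elements = c("H", "C", "N", "O")) {
  tab <- list(
    "H-H" = c(0.95, 0.05), "C-H" = c(1.05, 0.05), "H-N" = c(1.00, 0.05),
    "H-O" = c(0.97, 0.05), "C-C" = c(1.50, 0.05), "C-N" = c(1.45, 0.05),
    "C-O" = c(1.40, 0.05), "N-N" = c(1.45, 0.05), "N-O" = c(1.40, 0.05),
    "O-O" = c(1.45, 0.05))
  keep <- vapply(strsplit(names(tab), "-", fixed = TRUE),
                 function(p) all(p %in% elements), TRUE)
  tab[keep]
}

.pair_key <- function(e1, e2) paste(sort(c(e1, e2)), collapse = "-")

#' Specification of the synthetic template generator
#'
#' @param n_structures number of reference geometries to generate.
#' @param atoms_min,atoms_max atom-count range (uniform; \code{atoms_min >=
#'   2}).
#' @param elements element subset of H, C, N, O.
#' @param bond_length_table mapping element pair -> (mean, spread) in
#'   Angstrom; means must lie in [0.7, 1.8].
#' @param min_nonbonded minimum allowed nonbonded distance (Angstrom).
#' @param seed RNG seed.
#' @return list of class \code{aefm_template_spec}.
#' @export
template_spec <- function(n_structures, atoms_min = 4L, atoms_max = 12L,
                          elements = c("H", "C", "N", "O"),
                          bond_length_table = default_bond_table(elements),
                          min_nonbonded = 0.8, seed = 1L) {
  if (atoms_min < 2L || atoms_max < atoms_min)
    .aefm_error("need atoms_max >= atoms_min >= 2", "aefm_parameter_error")
  if (!all(elements %in% c("H", "C", "N", "O")))
    .aefm_error("template elements must be a subset of H, C, N, O",
                "aefm_parameter_error")
  means <- vapply(bond_length_table, `[`, 0.0, 1L)
  if (any(means < 0.7 | means > 1.8))
    .aefm_error("bond-length means must lie in [0.7, 1.8] Angstrom",
                "aefm_parameter_error")
  structure(list(n_structures = as.integer(n_structures),
                 atoms_min = as.integer(atoms_min),
                 atoms_max = as.integer(atoms_max), elements = elements,
                 bond_length_table = bond_length_table,
                 min_nonbonded = min_nonbonded, seed = as.integer(seed)),
            class = "aefm_template_spec")
}

# Grow one tree-connected geometry; returns NULL if the rejection budget is
# exhausted.
.grow_template <- function(spec, n_at, attempts = 300L) {
  els <- sample(spec$elements, n_at, replace = TRUE)
  coords <- matrix(0, n_at, 3)
  edges <- matrix(integer(0), ncol = 2)
  for (k in seq_len(n_at)[-1]) {
    placed <- FALSE
    for (a in seq_len(attempts)) {
      parent <- if (k == 2L) 1L else sample.int(k - 1L, 1L)
      bl <- spec$bond_length_table[[.pair_key(els[parent], els[k])]]
      len <- max(0.4, rnorm(1, bl[1], bl[2]))
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- coords[parent, ] + len * u
      others <- setdiff(seq_len(k - 1L), parent)
      ok <- !length(others) ||
        all(sqrt(colSums((t(coords[others, , drop = FALSE]) - pos)^2)) >=
              spec$min_nonbonded)
      if (ok) {
        coords[k, ] <- pos
        edges <- rbind(edges, c(parent, k))
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  list(elements = els, coords = coords, edges = edges)
}

#' Generate chemically plausible random reference geometries
#'
#' Random tree-connected geometries grown atom by atom: each new atom bonds
#' to a uniformly chosen existing atom at a distance drawn from the
#' bond-length table, rejection-sampled so that no nonbonded pair comes
#' closer than the spec's minimum. Deterministic given the spec seed. The
#' bonded tree edges are attached to each structure as attribute
#' \code{"tree_edges"} (used by property tests).
#'
#' @param spec an \code{\link{template_spec}}.
#' @return list of \code{aefm_structure}.
#' @export
generate_templates <- function(spec) {
  stopifnot(inherits(spec, "aefm_template_spec"))
  if (spec$n_structures == 0L) return(list())
  .with_seed(spec$seed, {
    out <- vector("list", spec$n_structures)
    for (i in seq_len(spec$n_structures)) {
      g <- NULL
      for (restart in seq_len(50L)) {
        n_at <- sample(spec$atoms_min:spec$atoms_max, 1L)
        g <- .grow_template(spec, n_at)
        if (!is.null(g)) break
      }
      if (is.null(g))
        .aefm_error(
          "rejection budget exhausted; loosen min_nonbonded or the bond table",
          "aefm_generation_error")
      s <- aefm_structure(g$elements, g$coords,
                          id = sprintf("tmpl_%05d", i))
      attr(s, "tree_edges") <- g$edges
      out[[i]] <- s
    }
    out
  })
}

#' Write a synthetic refinement benchmark to disk
#'
#' Corrupts each template with isotropic Gaussian noise of known scale and
#' writes multi-frame reference and low-fidelity XYZ files plus a JSON
#' Lines manifest whose header records \code{sigma_true} (so tests can
#' check calibration round-trips).
#'
#' @param templates list of reference structures.
#' @param sigma_true corruption scale (Angstrom, >= 0).
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the corruption draws.
#' @return path of the manifest file, invisibly.
#' @export
make_benchmark <- function(templates, sigma_true, dir, seed = 1L) {
  if (sigma_true < 0)
    .aefm_error("sigma_true must be >= 0", "aefm_parameter_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lows <- .with_seed(seed, lapply(templates, corrupt, sigma = sigma_true))
  write_xyz(templates, file.path(dir, "reference.xyz"))
  write_xyz(lows, file.path(dir, "low_fidelity.xyz"))
  ids <- vapply(seq_along(templates), function(i) {
    id <- templates[[i]]$id
    if (is.null(id)) sprintf("rxn_%05d", i) else id
  }, "")
  entries <- lapply(seq_along(templates), function(i)
    list(reaction_id = ids[i],
         reference = list(file = "reference.xyz", frame = i - 1L),
         low_fidelity = list(file = "low_fidelity.xyz", frame = i - 1L)))
  path <- file.path(dir, "manifest.jsonl")
  write_manifest(entries, path,
                 header = list(sigma_true = sigma_true,
                               n_entries = length(entries), seed = seed))
  invisible(path)
}

# ---- Mueller-Brown 2D toy ---------------------------------------------

# Standard literature constants of the four-term exponential form.
.MB <- list(A = c(-200, -100, -170, 15),
            a = c(-1, -1, -6.5, 0.7),
            b = c(0, 0, 11, 0.6),
            cc = c(-10, -10, -6.5, 0.7),
            x0 = c(1, 0, -0.5, -1),
            y0 = c(0, 0.5, 1.5, 1))

#' Mueller-Brown potential energy
#' @param p length-2 vector or n x 2 matrix of (x, y) points.
#' @return energy value(s).
#' @export
muller_brown_energy <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  with(.MB, {
    out <- numeric(nrow(p))
    for (k in 1:4) {
      dx <- p[, 1] - x0[k]
      dy <- p[, 2] - y0[k]
      out <- out + A[k] * exp(a[k] * dx^2 + b[k] * dx * dy + cc[k] * dy^2)
    }
    out
  })
}

#' Mueller-Brown analytic gradient
#' @param p length-2 vector (x, y).
#' @return length-2 gradient.
#' @export
muller_brown_gradient <- function(p) {
  with(.MB, {
    g <- c(0, 0)
    for (k in 1:4) {
      dx <- p[1] - x0[k]
      dy <- p[2] - y0[k]
      e <- A[k] * exp(a[k] * dx^2 + b[k] * dx * dy + cc[k] * dy^2)
      g <- g + e * c(2 * a[k] * dx + b[k] * dy, b[k] * dx + 2 * cc[k] * dy)
    }
    g
  })
}

#' Mueller-Brown analytic Hessian
#' @param p length-2 vector (x, y).
#' @return 2 x 2 Hessian matrix.
#' @export
muller_brown_hessian <- function(p) {
  with(.MB, {
    H <- matrix(0, 2, 2)
    for (k in 1:4) {
      dx <- p[1] - x0[k]
      dy <- p[2] - y0[k]
      e <- A[k] * exp(a[k] * dx^2 + b[k] * dx * dy + cc[k] * dy^2)
      u <- 2 * a[k] * dx + b[k] * dy
      v <- b[k] * dx + 2 * cc[k] * dy
      H[1, 1] <- H[1, 1] + e * (u^2 + 2 * a[k])
      H[1, 2] <- H[1, 2] + e * (u * v + b[k])
      H[2, 2] <- H[2, 2] + e * (v^2 + 2 * cc[k])
    }
    H[2, 1] <- H[1, 2]
    H
  })
}

#' Specification of the 2D saddle-refinement toy
#'
#' @param n_samples number of corrupted samples to draw around the saddle.
#' @param sigma isotropic corruption scale (potential units).
#' @param seed RNG seed.
#' @param start Newton start point for the saddle search (the default
#'   converges to the saddle between the two deepest minima).
#' @return list of class \code{aefm_saddle2d_spec}.
#' @export
saddle2d_spec <- function(n_samples = 200L, sigma = 0.15, seed = 1L,
                          start = c(-0.75, 0.6)) {
  if (sigma < 0 || n_samples < 1L)
    .aefm_error("invalid saddle2d spec", "aefm_parameter_error")
  structure(list(n_samples = as.integer(n_samples), sigma = sigma,
                 seed = as.integer(seed), start = start),
            class = "aefm_saddle2d_spec")
}

#' Build the Mueller-Brown saddle-refinement fixture
#'
#' Locates a first-order saddle point numerically (Newton iteration on the
#' analytic gradient; never hard-coded), verifies it (gradient norm below
#' 1e-6; construction fails otherwise), and draws \code{n_samples} noisy
#' "low-fidelity" points as saddle + sigma * eps in 2D. The 2D toy runs
#' through a dedicated dense-network pathway (\code{\link{train_mlp2d}}),
#' not the 3D equivariant net.
#'
#' @param spec an \code{\link{saddle2d_spec}}.
#' @return list with \code{energy}, \code{gradient}, \code{hessian}
#'   (callables), \code{saddle} (length-2), \code{samples}
#'   (\code{n_samples} x 2 matrix) and \code{spec}.
#' @export
muller_brown_fixture <- function(spec = saddle2d_spec()) {
  stopifnot(inherits(spec, "aefm_saddle2d_spec"))
  p <- spec$start
  for (it in 1:100) {
    g <- muller_brown_gradient(p)
    if (sqrt(sum(g^2)) < 1e-10) break
    H <- muller_brown_hessian(p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step))
      .aefm_error("singular Hessian during saddle search",
                  "aefm_fixture_error")
    if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
    p <- p - step
  }
  if (sqrt(sum(muller_brown_gradient(p)^2)) >= 1e-6)
    .aefm_error("saddle search did not converge", "aefm_fixture_error")
  ev <- eigen(muller_brown_hessian(p), symmetric = TRUE,
              only.values = TRUE)$values
  if (sum(ev < 0) != 1L)
    .aefm_error("stationary point is not a first-order saddle",
                "aefm_fixture_error")
  samples <- .with_seed(spec$seed,
    matrix(rep(p, each = spec$n_samples), spec$n_samples, 2) +
      spec$sigma * matrix(rnorm(2 * spec$n_samples), spec$n_samples, 2))
  list(energy = muller_brown_energy, gradient = muller_brown_gradient,
       hessian = muller_brown_hessian, saddle = p, samples = samples,
       spec = spec)
}

# ---- dedicated 2D refiner pathway -------------------------------------

#' Configuration of the 2D toy refiner
#' @param hidden hidden width.
#' @param seed seed for deterministic initialization.
#' @return list of class \code{aefm_mlp2d_config}.
#' @export
mlp2d_config <- function(hidden = 32L, seed = 1L) {
  structure(list(hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "aefm_mlp2d_config")
}

#' Build the 2D toy refiner
#'
#' A tiny residual dense network on raw 2D coordinates,
#' \code{p + tanh(p W1 + b1) W2 + b2}, with zero-initialized output weights
#' (identity map at initialization). Operates on n x 2 coordinate
#' matrices; each row is refined independently.
#'
#' @param cfg an \code{\link{mlp2d_config}}.
#' @return object of class \code{c("aefm_mlp2d", "aefm_refiner")}.
#' @export
build_mlp2d <- function(cfg = mlp2d_config()) {
  h <- cfg$hidden
  params <- .with_seed(cfg$seed, list(
    W1 = matrix(rnorm(2 * h, sd = 1 / sqrt(2)), 2, h),
    b1 = numeric(h),
    W2 = matrix(0, h, 2),
    b2 = numeric(2)))
  structure(list(config = cfg, params = params),
            class = c("aefm_mlp2d", "aefm_refiner"))
}

#' @export
.refiner_apply.aefm_mlp2d <- function(model, template, coords) {
  p <- model$params
  hact <- tanh(sweep(coords %*% p$W1, 2, p$b1, "+"))
  coords + sweep(hact %*% p$W2, 2, p$b2, "+")
}

#' Train the 2D toy refiner
#'
#' Mirrors the 3D training scheme in the dedicated 2D pathway (no bond
#' loss: the toy has no bonds): per epoch, fresh corruptions
#' \eqn{x_0 = x_1 + \sigma\epsilon} and interpolation points
#' \eqn{x_t = (1-t)x_0 + t x_1 + \sigma_{FM}\epsilon'} are drawn for every
#' target row, and the mean squared endpoint-prediction error is minimized
#' by adaptive-moment gradient descent.
#'
#' @param targets n x 2 matrix of reference points (\eqn{x_1} rows; for the
#'   saddle toy, copies of the saddle).
#' @param sigma corruption scale.
#' @param sigma_fm path noise (default 0.05).
#' @param epochs,learning_rate optimizer settings.
#' @param cfg an \code{\link{mlp2d_config}}.
#' @param seed RNG seed for the training draws.
#' @return list with \code{model} and \code{history} (per-epoch loss).
#' @export
train_mlp2d <- function(targets, sigma, sigma_fm = 0.05, epochs = 300L,
                        learning_rate = 0.01, cfg = mlp2d_config(),
                        seed = 1L) {
  targets <- as.matrix(targets)
  stopifnot(ncol(targets) == 2L, nrow(targets) >= 1L, sigma >= 0)
  model <- build_mlp2d(cfg)
  n <- nrow(targets)
  p <- model$params
  m1 <- lapply(p, function(z) z * 0)
  m2 <- lapply(p, function(z) z * 0)
  losses <- numeric(epochs)
  .with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      x0 <- targets + sigma * matrix(rnorm(2 * n), n, 2)
      t <- runif(n)
      xt <- (1 - t) * x0 + t * targets +
        sigma_fm * matrix(rnorm(2 * n), n, 2)
      hpre <- sweep(xt %*% p$W1, 2, p$b1, "+")
      hact <- tanh(hpre)
      out <- xt + sweep(hact %*% p$W2, 2, p$b2, "+")
      diff <- out - targets
      losses[epoch] <- mean(rowSums(diff^2))
      if (!is.finite(losses[epoch]))
        .aefm_error(sprintf("2D training diverged at epoch %d", epoch),
                    "aefm_training_failure")
      G <- 2 * diff / n
      gW2 <- crossprod(hact, G)
      gb2 <- colSums(G)
      ghact <- tcrossprod(G, p$W2)
      ghpre <- ghact * (1 - hact^2)
      gW1 <- crossprod(xt, ghpre)
      gb1 <- colSums(ghpre)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      lr <- learning_rate *
        (0.05 + 0.95 * 0.5 * (1 + cos(pi * (epoch - 1) / epochs)))
      for (nm in names(p)) {
        m1[[nm]] <- 0.9 * m1[[nm]] + 0.1 * grads[[nm]]
        m2[[nm]] <- 0.999 * m2[[nm]] + 0.001 * grads[[nm]]^2
        mh <- m1[[nm]] / (1 - 0.9^epoch)
        vh <- m2[[nm]] / (1 - 0.999^epoch)
        p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
      }
    }
  })
  model$params <- p
  list(model = model, history = data.frame(epoch = seq_len(epochs),
                                           loss = losses))
}
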