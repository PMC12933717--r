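# The time-independent refiner phi_theta: a pluggable coordinate-to-
# coordinate map contract plus a small reference equivariant message-passing
# network with hand-derived gradients.
#
# Reference net architecture (per layer):
#   v_ij = x_j - x_i,  d_ij = |v_ij|
#   c_i  = sum_k kappa(d_ik)            (smooth coordination count)
#   feat_ij = [gaussian radial basis of d_ij, one-hot element-pair type,
#              c_i + c_j, (c_i - c_j)^2]
#   w_ij = (W2 . tanh(W1 feat_ij + b1) + b2) * envelope(d_ij)
#   x_i <- x_i + sum_j w_ij v_ij     (w symmetric in i,j; centroid preserved)
# All learned quantities are invariant scalars; coordinates only enter
# through pairwise difference vectors, giving SE(3) and permutation
# equivariance by construction. Coordinate-update weights (W2, b2) start at
# zero so the untrained map is exactly the identity.

#' Configuration of the reference equivariant network
#'
#' @param layers number of message-passing layers (>= 1).
#' @param hidden hidden width of the per-pair scalar network.
#' @param n_basis number of Gaussian radial basis functions.
#' @param basis_max centre of the last radial basis function (Angstrom).
#' @param interaction_cutoff interaction range in Angstrom. Pair messages
#'   are damped by a smooth cosine envelope that reaches zero here. The
#'   default \code{Inf} means fully connected with the default 5 Angstrom
#'   envelope (distinct from the 2 Angstrom bond-loss cutoff).
#' @param elements element vocabulary the net is built for.
#' @param seed integer seed for deterministic parameter initialization.
#' @return list of class \code{aefm_refnet_config}.
#' @export
reference_net_config <- function(layers = 4L, hidden = 64L, n_basis = 16L,
                                 basis_max = 4.0, interaction_cutoff = Inf,
                                 elements = c("H", "C", "N", "O"),
                                 seed = 1L) {
  if (layers < 1L || hidden < 1L || n_basis < 2L)
    .aefm_error("layers, hidden and n_basis must be positive",
                "aefm_parameter_error")
  if (!all(elements %in% .ELEMENT_SYMBOLS))
    .aefm_error("unrecognized element in vocabulary", "aefm_parameter_error")
  env_cut <- if (is.finite(interaction_cutoff)) interaction_cutoff else 5.0
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 n_basis = as.integer(n_basis), basis_max = basis_max,
                 interaction_cutoff = interaction_cutoff,
                 envelope_cutoff = env_cut,
                 elements = elements, seed = as.integer(seed)),
            class = "aefm_refnet_config")
}

#' Build the reference equivariant refiner
#'
#' Initializes a refiner implementing the refiner contract: \code{predict}
#' maps a structure to a structure with identical elements and new
#' coordinates, with no notion of time anywhere. Initialization is
#' deterministic given the config seed, and the output weights of every
#' layer start at zero, so the fresh network is exactly the identity map
#' (fixed-point inference is well-posed from epoch 0).
#'
#' @param cfg an \code{\link{reference_net_config}}.
#' @return object of class \code{c("aefm_refnet", "aefm_refiner")}.
#' @export
build_reference_net <- function(cfg = reference_net_config()) {
  stopifnot(inherits(cfg, "aefm_refnet_config"))
  ntype <- length(cfg$elements)
  P <- ntype * (ntype + 1L) / 2L
  Fdim <- cfg$n_basis + P + 2L   # + symmetric coordination features
  params <- .with_seed(cfg$seed, lapply(seq_len(cfg$layers), function(l) {
    list(W1 = matrix(rnorm(Fdim * cfg$hidden, sd = 1 / sqrt(Fdim)),
                     Fdim, cfg$hidden),
         b1 = numeric(cfg$hidden),
         W2 = numeric(cfg$hidden),   # zero => identity map at init
         b2 = 0.0)
  }))
  mu <- seq(0, cfg$basis_max, length.out = cfg$n_basis)
  gamma <- mu[2] - mu[1]
  structure(list(config = cfg, params = params, mu = mu, gamma = gamma,
                 calibration = NULL,
                 metadata = list(layers = cfg$layers, hidden = cfg$hidden,
                                 n_basis = cfg$n_basis, seed = cfg$seed)),
            class = c("aefm_refnet", "aefm_refiner"))
}

#' @export
print.aefm_refnet <- function(x, ...) {
  cat(sprintf(
    "<aefm_refnet: %d layers, hidden %d, %d basis fns, elements [%s]%s>\n",
    x$config$layers, x$config$hidden, x$config$n_basis,
    paste(x$config$elements, collapse = ","),
    if (is.null(x$calibration)) ""
    else sprintf(", trained with sigma %.4f", x$calibration$sigma)))
  invisible(x)
}

# ---- pair bookkeeping -------------------------------------------------

# Map element symbols to type indices in the net's vocabulary; unknown
# elements warn (not error) and fall back to type 1.
.refnet_types <- function(cfg, elements) {
  t <- match(elements, cfg$elements)
  if (anyNA(t)) {
    warning(sprintf(
      "element type(s) %s not in the training vocabulary; treating as %s",
      paste(unique(elements[is.na(t)]), collapse = ","), cfg$elements[1]),
      call. = FALSE)
    t[is.na(t)] <- 1L
  }
  t
}

# Static per-structure pair layout: all i < j pairs plus one-hot pair types.
.refnet_layout <- function(cfg, elements) {
  n <- length(elements)
  tidx <- .refnet_types(cfg, elements)
  ntype <- length(cfg$elements)
  P <- ntype * (ntype + 1L) / 2L
  if (n < 2L) {
    return(list(n = n, iidx = integer(0), jidx = integer(0),
                onehot = matrix(0, 0, P)))
  }
  cmb <- utils::combn(n, 2L)
  iidx <- cmb[1, ]
  jidx <- cmb[2, ]
  lo <- pmin(tidx[iidx], tidx[jidx])
  hi <- pmax(tidx[iidx], tidx[jidx])
  ptype <- hi * (hi - 1L) / 2L + lo
  onehot <- matrix(0, length(iidx), P)
  onehot[cbind(seq_along(ptype), ptype)] <- 1
  list(n = n, iidx = iidx, jidx = jidx, onehot = onehot)
}

# Scatter-add pair contributions (+ at i, - at j) into an N x 3 matrix.
.scatter_pm <- function(contrib, iidx, jidx, n) {
  out <- matrix(0, n, 3)
  s <- rowsum(rbind(contrib, -contrib), c(iidx, jidx))
  out[as.integer(rownames(s)), ] <- s
  out
}

# Scatter-add scalar pair values into a length-n atom vector.
.scatter_scalar <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(matrix(vals, ncol = 1), idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Smooth coordination-count kernel and its derivative (cutoff 2 Angstrom,
# matching the scale of bonded neighbourhoods).
.COORD_CUT <- 2.0
.coord_kernel <- function(d) {
  ifelse(d < .COORD_CUT, 0.5 * (1 + cos(pi * d / .COORD_CUT)), 0)
}
.coord_kernel_deriv <- function(d) {
  ifelse(d < .COORD_CUT, -0.5 * pi / .COORD_CUT * sin(pi * d / .COORD_CUT), 0)
}

# ---- forward / backward ----------------------------------------------

# Forward pass on a coordinate matrix. Centroid handling: every pair
# update is antisymmetric, so the net preserves the input centroid exactly,
# and all features are functions of difference vectors only; removing the
# centroid before the network and adding it back after is therefore an
# algebraic no-op and is omitted (this keeps the untrained map bitwise
# identical to the identity). The map is rigorously translation-
# equivariant. Returns the output coordinates and, when record = TRUE, the
# per-layer cache needed for backprop.
.refnet_forward <- function(model, coords, layout, record = FALSE) {
  cfg <- model$config
  X <- coords
  K <- cfg$n_basis
  rc <- cfg$envelope_cutoff
  cache <- if (record) vector("list", cfg$layers) else NULL
  if (layout$n < 2L)
    return(list(out = X, cache = cache))
  for (l in seq_len(cfg$layers)) {
    p <- model$params[[l]]
    v <- X[layout$jidx, , drop = FALSE] - X[layout$iidx, , drop = FALSE]
    d <- sqrt(rowSums(v^2))
    B <- exp(-(outer(d, model$mu, "-"))^2 / (2 * model$gamma^2))
    kap <- .coord_kernel(d)
    cvec <- .scatter_scalar(c(kap, kap), c(layout$iidx, layout$jidx),
                            layout$n)
    ci <- cvec[layout$iidx]
    cj <- cvec[layout$jidx]
    feat <- cbind(B, layout$onehot, 0.5 * (ci + cj), 0.5 * (ci - cj)^2)
    hpre <- sweep(feat %*% p$W1, 2, p$b1, "+")
    hact <- tanh(hpre)
    wraw <- as.numeric(hact %*% p$W2) + p$b2
    env <- ifelse(d < rc, 0.5 * (1 + cos(pi * d / rc)), 0)
    w <- wraw * env
    contrib <- w * v
    Xnew <- X + .scatter_pm(contrib, layout$iidx, layout$jidx, layout$n)
    if (record)
      cache[[l]] <- list(X = X, v = v, d = d, B = B, feat = feat,
                         ci = ci, cj = cj,
                         hact = hact, wraw = wraw, env = env, w = w)
    X <- Xnew
  }
  list(out = X, cache = cache)
}

# Backprop: gradient of a scalar loss w.r.t. parameters (and input coords)
# given the gradient G w.r.t. the output coordinates.
.refnet_backward <- function(model, layout, cache, G) {
  cfg <- model$config
  rc <- cfg$envelope_cutoff
  K <- cfg$n_basis
  grads <- vector("list", cfg$layers)
  if (layout$n < 2L) {
    for (l in seq_len(cfg$layers)) {
      p <- model$params[[l]]
      grads[[l]] <- list(W1 = p$W1 * 0, b1 = p$b1 * 0, W2 = p$W2 * 0, b2 = 0)
    }
    return(list(grads = grads, gX = G))
  }
  gX <- G
  for (l in rev(seq_len(cfg$layers))) {
    cc <- cache[[l]]
    p <- model$params[[l]]
    gcontrib <- gX[layout$iidx, , drop = FALSE] -
      gX[layout$jidx, , drop = FALSE]
    gw <- rowSums(gcontrib * cc$v)
    gv <- cc$w * gcontrib
    gwraw <- gw * cc$env
    genv <- gw * cc$wraw
    gb2 <- sum(gwraw)
    gW2 <- as.numeric(crossprod(cc$hact, gwraw))
    ghact <- outer(gwraw, p$W2)
    ghpre <- ghact * (1 - cc$hact^2)
    gW1 <- crossprod(cc$feat, ghpre)
    gb1 <- colSums(ghpre)
    gfeat <- tcrossprod(ghpre, p$W1)
    gB <- gfeat[, seq_len(K), drop = FALSE]
    Bprime <- cc$B * (-(outer(cc$d, model$mu, "-")) / model$gamma^2)
    nf <- ncol(gfeat)
    gs <- gfeat[, nf - 1L]
    gq <- gfeat[, nf]
    gci <- 0.5 * gs + (cc$ci - cc$cj) * gq
    gcj <- 0.5 * gs - (cc$ci - cc$cj) * gq
    gC <- .scatter_scalar(c(gci, gcj), c(layout$iidx, layout$jidx),
                          layout$n)
    gd <- rowSums(gB * Bprime) +
      genv * ifelse(cc$d < rc, -0.5 * pi / rc * sin(pi * cc$d / rc), 0) +
      (gC[layout$iidx] + gC[layout$jidx]) * .coord_kernel_deriv(cc$d)
    gv <- gv + (gd / pmax(cc$d, 1e-12)) * cc$v
    gX <- gX + .scatter_pm(-gv, layout$iidx, layout$jidx, layout$n)
    grads[[l]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  list(grads = grads, gX = gX)
}

# ---- parameter flattening (optimizer + checkpoints) -------------------

.flatten_params <- function(params) {
  unlist(lapply(params, function(p) c(p$W1, p$b1, p$W2, p$b2)),
         use.names = FALSE)
}

.unflatten_params <- function(template, theta) {
  out <- template
  pos <- 0L
  for (l in seq_along(template)) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      k <- length(template[[l]][[nm]])
      val <- theta[pos + seq_len(k)]
      if (is.matrix(template[[l]][[nm]]))
        val <- matrix(val, nrow(template[[l]][[nm]]),
                      ncol(template[[l]][[nm]]))
      out[[l]][[nm]] <- val
      pos <- pos + k
    }
  }
  out
}

# ---- refiner contract -------------------------------------------------

# Apply a refiner to a coordinate matrix, given a template object carrying
# the element layout. Every refiner class implements this internal generic;
# predict() methods and the fixed-point solver are built on it.
.refiner_apply <- function(model, template, coords) {
  UseMethod(".refiner_apply")
}

#' @export
.refiner_apply.aefm_refnet <- function(model, template, coords) {
  layout <- .refnet_layout(model$config, template$elements)
  .refnet_forward(model, coords, layout)$out
}

#' @export
.refiner_apply.aefm_fn_refiner <- function(model, template, coords) {
  model$fn(coords)
}

#' Refine a structure with a trained (or fresh) refiner
#'
#' One application of the learned map \eqn{\phi_\theta}; deterministic for a
#' fixed model and input. Element types outside the training vocabulary
#' produce a warning (not an error). Predictions are exactly
#' translation-equivariant: every learned feature is a function of
#' interatomic difference vectors, and the antisymmetric pair updates
#' preserve the input centroid, so explicit centering is unnecessary.
#'
#' @param object a refiner (e.g. from \code{\link{build_reference_net}} or
#'   \code{\link{train_refiner}}).
#' @param x an \code{aefm_structure} (or bare coordinate matrix for
#'   coordinate-space refiners such as test doubles).
#' @param ... unused.
#' @return refined structure (same elements and id).
#' @export
predict.aefm_refiner <- function(object, x, ...) {
  coords <- .get_coords(x)
  .with_coords(x, .refiner_apply(object, x, coords))
}

#' Wrap a plain coordinate function as a refiner
#'
#' Mainly for test doubles and analytic maps: \code{fn} receives and returns
#' an N x 3 (or N x d) coordinate matrix.
#'
#' @param fn function mapping a coordinate matrix to a coordinate matrix of
#'   the same shape.
#' @param name optional label.
#' @return object of class \code{c("aefm_fn_refiner", "aefm_refiner")}.
#' @export
as_refiner <- function(fn, name = "function refiner") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, name = name),
            class = c("aefm_fn_refiner", "aefm_refiner"))
}

# ---- equivariance diagnostics ----------------------------------------

# Uniform random proper rotation via quaternions.
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Worst-case symmetry deviations of a refiner
#'
#' Measures, over random group elements, the maximum deviation from
#' translation, rotation and atom-permutation equivariance:
#' \code{predict(g . x)} vs \code{g . predict(x)}. Intended as a release
#' gate for any plugged-in backbone.
#'
#' @param model a refiner.
#' @param structures list of structures to probe.
#' @param n_group random group elements sampled per structure and symmetry.
#' @param seed RNG seed.
#' @param tol pass threshold in Angstrom (default 1e-4).
#' @return list with \code{translation}, \code{rotation}, \code{permutation}
#'   (maximum absolute coordinate deviations, Angstrom) and \code{pass}.
#' @export
equivariance_report <- function(model, structures, n_group = 20L, seed = 1L,
                                tol = 1e-4) {
  stopifnot(length(structures) >= 1L)
  if (is_aefm_structure(structures)) structures <- list(structures)
  dev <- c(translation = 0, rotation = 0, permutation = 0)
  .with_seed(seed, {
    for (s in structures) {
      base <- predict(model, s)$coords
      n <- n_atoms(s)
      for (g in seq_len(n_group)) {
        tvec <- rnorm(3, sd = 5)
        st <- set_coords(s, sweep(s$coords, 2, tvec, "+"))
        dt <- max(abs(predict(model, st)$coords -
                        sweep(base, 2, tvec, "+")))
        R <- .random_rotation()
        sr <- set_coords(s, s$coords %*% t(R))
        dr <- max(abs(predict(model, sr)$coords - base %*% t(R)))
        perm <- sample.int(n)
        sp <- aefm_structure(s$elements[perm],
                             s$coords[perm, , drop = FALSE], id = s$id)
        dp <- max(abs(predict(model, sp)$coords -
                        base[perm, , drop = FALSE]))
        dev <- pmax(dev, c(dt, dr, dp))
      }
    }
  })
  list(translation = unname(dev[1]), rotation = unname(dev[2]),
       permutation = unname(dev[3]), tol = tol, pass = all(dev < tol))
}

# ---- checkpoints ------------------------------------------------------

#' Save a trained refiner to a checkpoint directory
#'
#' Writes \code{params.json} (flat parameter vector) and \code{meta.json}
#' (network config, prior calibration, training config, schema version).
#' Checkpoints are plain text and library-agnostic.
#'
#' @param model an \code{aefm_refnet}.
#' @param dir destination directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_refiner <- function(model, dir) {
  stopifnot(inherits(model, "aefm_refnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(theta = .flatten_params(model$params)),
                       file.path(dir, "params.json"), digits = NA)
  meta <- list(schema_version = 1L,
               config = unclass(model$config),
               calibration = if (is.null(model$calibration)) NULL
                             else unclass(model$calibration),
               metadata = model$metadata)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a refiner checkpoint
#'
#' @param dir directory written by \code{\link{save_refiner}}.
#' @return an \code{aefm_refnet}.
#' @export
load_refiner <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfgl <- meta$config
  cfg <- reference_net_config(
    layers = cfgl$layers, hidden = cfgl$hidden, n_basis = cfgl$n_basis,
    basis_max = cfgl$basis_max,
    interaction_cutoff = if (is.null(cfgl$interaction_cutoff) ||
                             !is.finite(cfgl$interaction_cutoff)) Inf
                         else cfgl$interaction_cutoff,
    elements = cfgl$elements, seed = cfgl$seed)
  model <- build_reference_net(cfg)
  theta <- jsonlite::read_json(file.path(dir, "params.json"),
                               simplifyVector = TRUE)$theta
  model$params <- .unflatten_params(model$params, theta)
  if (!is.null(meta$calibration))
    model$calibration <- structure(meta$calibration,
                                   class = "aefm_prior_calibration")
  model$metadata <- meta$metadata
  model
}
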