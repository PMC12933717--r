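# Fixed-point refinement at inference: plain iteration, Anderson
# acceleration, the stopping rule, and Jacobian spectral-radius diagnostics.

#' Fixed-point solver configuration
#'
#' Defaults follow the method's settings: damping \code{beta = 1.0},
#' history size \code{m = 5}, stopping threshold 0.01 on the RMSD between
#' successive iterates, and a cap of 100 iterations.
#'
#' @param beta damping parameter in [0, 1].
#' @param history_m Anderson history size (number of previous iterates kept
#'   in addition to the current one).
#' @param tol stopping threshold (Angstrom).
#' @param max_iter iteration cap.
#' @param mode \code{"anderson"} (default) or \code{"plain"}.
#' @param stop_metric \code{"rmsd"} (default): stop when
#'   \eqn{\sqrt{\|x^{k+1}-x^k\|^2/N} \le tol}; \code{"norm_over_n"}: the
#'   alternative literal reading \eqn{\|x^{k+1}-x^k\|/N \le tol}.
#' @param ls_regularization Tikhonov regularization of the Anderson
#'   least-squares system.
#' @param diagnostics if \code{TRUE}, record a spectral-radius estimate of
#'   the refiner Jacobian at every iterate (costly; analysis only).
#' @param seed seed for the diagnostics' power/Arnoldi start vector.
#' @return list of class \code{aefm_solver_config}.
#' @export
solver_config <- function(beta = 1.0, history_m = 5L, tol = 0.01,
                          max_iter = 100L, mode = c("anderson", "plain"),
                          stop_metric = c("rmsd", "norm_over_n"),
                          ls_regularization = 1e-8, diagnostics = FALSE,
                          seed = 1L) {
  mode <- match.arg(mode)
  stop_metric <- match.arg(stop_metric)
  if (beta < 0 || beta > 1 || history_m < 0L || tol <= 0 || max_iter < 1L ||
      ls_regularization < 0)
    .aefm_error("invalid solver configuration", "aefm_parameter_error")
  structure(list(beta = beta, history_m = as.integer(history_m), tol = tol,
                 max_iter = as.integer(max_iter), mode = mode,
                 stop_metric = stop_metric,
                 ls_regularization = ls_regularization,
                 diagnostics = isTRUE(diagnostics), seed = as.integer(seed)),
            class = "aefm_solver_config")
}

#' One Anderson-acceleration step
#'
#' Given histories of iterates \eqn{x^i} and residuals
#' \eqn{g(x^i) = \phi(x^i) - x^i} (most recent last, flattened), finds the
#' coefficients \eqn{\alpha} minimizing \eqn{\|\sum_i \alpha_i g(x^i)\|^2}
#' subject to \eqn{\sum_i \alpha_i = 1} (constraint eliminated by the
#' difference formulation, Tikhonov-regularized), and returns the next
#' iterate \eqn{\beta \sum_i \alpha_i \phi(x^i) +
#' (1-\beta)\sum_i \alpha_i x^i}. With a single stored point the update
#' reduces to the plain update scaled by the damping.
#'
#' @param iterate_history list of flattened iterates \eqn{x^i}.
#' @param residual_history list of flattened residuals \eqn{g(x^i)}, same
#'   length and order.
#' @param beta damping parameter in [0, 1].
#' @param reg Tikhonov regularization (default 1e-8).
#' @return next flattened iterate, with attributes \code{"alpha"} (the
#'   coefficient vector) and \code{"fallback"} (\code{TRUE} if the
#'   least-squares system was unsolvable and a plain step was taken).
#' @export
anderson_step <- function(iterate_history, residual_history, beta,
                          reg = 1e-8) {
  h <- length(iterate_history)
  stopifnot(h >= 1L, length(residual_history) == h)
  X <- do.call(cbind, iterate_history)
  G <- do.call(cbind, residual_history)
  fallback <- FALSE
  if (h == 1L) {
    alpha <- 1
  } else {
    A <- G[, -h, drop = FALSE] - G[, h]          # columns g_i - g_h
    rhs <- -crossprod(A, G[, h, drop = FALSE])
    M <- crossprod(A) + diag(reg, h - 1L)
    theta <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(theta) || any(!is.finite(theta))) {
      fallback <- TRUE
      alpha <- c(rep(0, h - 1L), 1)
    } else {
      alpha <- c(theta, 1 - sum(theta))
    }
  }
  phi <- X + G                                    # phi(x_i) = x_i + g_i
  nxt <- as.numeric(beta * (phi %*% alpha) + (1 - beta) * (X %*% alpha))
  attr(nxt, "alpha") <- as.numeric(alpha)
  attr(nxt, "fallback") <- fallback
  nxt
}

#' Refine a structure by fixed-point iteration
#'
#' Iterates \eqn{x^{k+1} = \phi_\theta(x^k)} (plain mode) or the
#' Anderson-accelerated update from the stored history, starting from the
#' low-fidelity guess, until the RMSD between successive iterates falls at
#' or below the threshold or the iteration cap is reached. Deterministic
#' for fixed model and input.
#'
#' @param model a refiner.
#' @param x_init initial structure (the low-fidelity prediction), or a bare
#'   coordinate matrix for coordinate-space refiners.
#' @param cfg an \code{\link{solver_config}}.
#' @return An object of class \code{aefm_fixed_point}: list with
#'   \code{refined} (same type as \code{x_init}), \code{converged},
#'   \code{n_iter}, \code{residual_rmsd_trace} (length \code{n_iter}),
#'   \code{alpha_history} (Anderson mode), and \code{rho_trace} (when
#'   diagnostics are enabled).
#' @export
fixed_point_refine <- function(model, x_init, cfg = solver_config()) {
  stopifnot(inherits(cfg, "aefm_solver_config"))
  coords0 <- .get_coords(x_init)
  dims <- dim(coords0)
  n <- nrow(coords0)
  xk <- as.numeric(coords0)
  hist_x <- list()
  hist_g <- list()
  trace <- numeric(0)
  alpha_hist <- list()
  rho_trace <- if (cfg$diagnostics) numeric(0) else NULL
  converged <- FALSE
  n_iter <- 0L

  step_size <- function(delta) {
    if (cfg$stop_metric == "rmsd") sqrt(sum(delta^2) / n)
    else sqrt(sum(delta^2)) / n
  }

  for (k in seq_len(cfg$max_iter)) {
    fx <- .refiner_apply(model, x_init, matrix(xk, dims[1], dims[2]))
    if (any(!is.finite(fx)))
      stop(errorCondition(
        sprintf("non-finite iterate at iteration %d", k),
        trace = trace,
        class = c("aefm_numerical_failure", "aefm_error", "error",
                  "condition")))
    g <- as.numeric(fx) - xk
    if (cfg$diagnostics)
      rho_trace <- c(rho_trace,
                     spectral_radius(model, .with_coords(
                       x_init, matrix(xk, dims[1], dims[2])),
                       seed = cfg$seed))
    if (cfg$mode == "plain") {
      xnext <- as.numeric(fx)
    } else {
      hist_x[[length(hist_x) + 1L]] <- xk
      hist_g[[length(hist_g) + 1L]] <- g
      keep <- cfg$history_m + 1L
      if (length(hist_x) > keep) {
        hist_x <- hist_x[-1L]
        hist_g <- hist_g[-1L]
      }
      xnext <- anderson_step(hist_x, hist_g, cfg$beta,
                             cfg$ls_regularization)
      alpha_hist[[length(alpha_hist) + 1L]] <- attr(xnext, "alpha")
      attributes(xnext) <- NULL
    }
    res <- step_size(xnext - xk)
    trace <- c(trace, res)
    n_iter <- k
    xk <- xnext
    if (res <= cfg$tol) {
      converged <- TRUE
      break
    }
  }
  refined <- .with_coords(x_init, matrix(xk, dims[1], dims[2]))
  structure(list(refined = refined, converged = converged, n_iter = n_iter,
                 residual_rmsd_trace = trace,
                 alpha_history = if (cfg$mode == "anderson") alpha_hist
                                 else NULL,
                 rho_trace = rho_trace),
            class = "aefm_fixed_point")
}

#' @export
print.aefm_fixed_point <- function(x, ...) {
  cat(sprintf("<aefm_fixed_point: %s in %d iteration(s), final step %.2e>\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (length(x$residual_rmsd_trace))
                tail(x$residual_rmsd_trace, 1) else NA_real_))
  invisible(x)
}

#' Spectral radius of the refiner Jacobian at a point
#'
#' Estimates the largest-magnitude eigenvalue of the Jacobian of the
#' flattened coordinate map at \code{x}, using only Jacobian-vector
#' products (central finite differences), via an Arnoldi/Krylov iteration
#' whose small Hessenberg matrix is diagonalized densely. A spectral radius
#' below 1 certifies local contraction of the fixed-point iteration;
#' advanced solvers often still converge somewhat beyond it.
#'
#' @param model a refiner.
#' @param x structure (or coordinate matrix) at which to linearize.
#' @param n_power_iters maximum Krylov dimension (default 50, capped at the
#'   coordinate dimension).
#' @param seed seed for the random start vector.
#' @param rtol relative convergence tolerance on the estimate (default
#'   1e-4).
#' @param fd_eps finite-difference step.
#' @return non-negative scalar estimate, with attribute \code{"converged"}.
#'   A warning is raised when the iteration budget is exhausted before the
#'   estimate settles.
#' @export
spectral_radius <- function(model, x, n_power_iters = 50L, seed = 1L,
                            rtol = 1e-4, fd_eps = 1e-4) {
  coords <- .get_coords(x)
  dims <- dim(coords)
  x0 <- as.numeric(coords)
  dim_n <- length(x0)
  jvp <- function(v) {
    vm <- matrix(v, dims[1], dims[2])
    xp <- .refiner_apply(model, x, matrix(x0, dims[1], dims[2]) + fd_eps * vm)
    xm <- .refiner_apply(model, x, matrix(x0, dims[1], dims[2]) - fd_eps * vm)
    as.numeric(xp - xm) / (2 * fd_eps)
  }
  kmax <- min(as.integer(n_power_iters), dim_n)
  Q <- matrix(0, dim_n, kmax + 1L)
  H <- matrix(0, kmax + 1L, kmax)
  q1 <- .with_seed(seed, rnorm(dim_n))
  Q[, 1] <- q1 / sqrt(sum(q1^2))
  est <- NA_real_
  converged <- FALSE
  for (j in seq_len(kmax)) {
    w <- jvp(Q[, j])
    for (pass in 1:2) {                 # modified Gram-Schmidt, twice
      for (i in seq_len(j)) {
        hij <- sum(Q[, i] * w)
        if (pass == 1L) H[i, j] <- H[i, j] + hij else H[i, j] <- H[i, j] + hij
        w <- w - hij * Q[, i]
      }
    }
    hnorm <- sqrt(sum(w^2))
    H[j + 1L, j] <- hnorm
    new_est <- max(Mod(eigen(H[seq_len(j), seq_len(j), drop = FALSE],
                             only.values = TRUE)$values))
    if (hnorm < 1e-10) {                # invariant subspace: exact
      est <- new_est
      converged <- TRUE
      break
    }
    if (!is.na(est) && abs(new_est - est) <= rtol * max(new_est, 1e-12)) {
      est <- new_est
      converged <- TRUE
      break
    }
    est <- new_est
    if (j == kmax && j == dim_n) converged <- TRUE  # full Krylov space
    Q[, j + 1L] <- w / hnorm
  }
  if (!converged)
    warning("spectral-radius estimate did not settle within the iteration budget",
            call. = FALSE)
  attr(est, "converged") <- converged
  est
}

#' Refine a batch of structures
#'
#' Runs \code{\link{fixed_point_refine}} independently on each structure;
#' per-structure failures are caught and reported, not fatal.
#'
#' @param model a refiner.
#' @param structures list of structures (or coordinate matrices).
#' @param cfg an \code{\link{solver_config}}.
#' @return An object of class \code{aefm_refine_batch}: list with
#'   \code{results} (per-structure \code{aefm_fixed_point} or error
#'   condition) and \code{summary} (count, convergence fraction, iteration
#'   counts and their median).
#' @export
refine_batch <- function(model, structures, cfg = solver_config()) {
  results <- lapply(structures, function(s)
    tryCatch(fixed_point_refine(model, s, cfg), error = function(e) e))
  ok <- vapply(results, inherits, TRUE, what = "aefm_fixed_point")
  conv <- vapply(results[ok], `[[`, TRUE, "converged")
  iters <- vapply(results[ok], `[[`, 1L, "n_iter")
  summary <- list(
    n = length(results), n_failed = sum(!ok),
    n_converged = sum(conv),
    convergence_rate = if (length(results)) sum(conv) / length(results)
                       else NA_real_,
    iterations = iters,
    median_iterations = if (length(iters)) median(iters) else NA_real_)
  structure(list(results = results, summary = summary),
            class = "aefm_refine_batch")
}

#' @export
print.aefm_refine_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<aefm_refine_batch: %d structures, %.1f%% converged, median %s iterations>\n",
    s$n, 100 * s$convergence_rate,
    format(s$median_iterations)))
  invisible(x)
}
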