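# Noise-scale calibration and the corruption / interpolation samplers used
# to build training inputs.

#' Calibrate the corruption scale from low-fidelity/reference pairs
#'
#' Determines the isotropic Gaussian noise scale sigma whose expected
#' per-atom squared displacement (3 sigma^2, see
#' \code{\link{expected_corruption_msd}}) matches the observed mean per-atom
#' squared deviation of the low-fidelity structures from their references:
#' \deqn{\sigma = \left( \mathrm{mean}_{pairs}\; \|x_1 - x_1^w\|^2 /
#'   (3 N) \right)^{1/2}}
#' computed in the frame as given (no alignment): the low-fidelity source is
#' assumed to be in the reference frame, and any systematic drift is part of
#' the error the prior must cover.
#'
#' @param pairs non-empty list of \code{aefm_refinement_pair}.
#' @param provenance optional text recorded in the result (e.g. a manifest
#'   path).
#' @return An object of class \code{aefm_prior_calibration}: list with
#'   \code{sigma} (Angstrom), \code{n_pairs}, \code{mean_sq_dev_per_atom}
#'   (Angstrom^2, satisfying \code{sigma == sqrt(mean_sq_dev_per_atom / 3)})
#'   and \code{provenance}.
#' @export
calibrate_sigma <- function(pairs, provenance = NULL) {
  if (length(pairs) == 0L)
    .aefm_error("calibrate_sigma needs at least one pair",
                "aefm_empty_dataset")
  msd <- vapply(pairs, function(p) {
    stopifnot(inherits(p, "aefm_refinement_pair"))
    sum((p$reference$coords - p$low_fidelity$coords)^2) /
      n_atoms(p$reference)
  }, 0.0)
  mean_msd <- mean(msd)
  structure(list(sigma = sqrt(mean_msd / 3), n_pairs = length(pairs),
                 mean_sq_dev_per_atom = mean_msd, provenance = provenance),
            class = "aefm_prior_calibration")
}

#' @export
print.aefm_prior_calibration <- function(x, ...) {
  cat(sprintf(
    "<aefm_prior_calibration: sigma = %.5f A from %d pairs (per-atom MSD %.5f A^2)>\n",
    x$sigma, x$n_pairs, x$mean_sq_dev_per_atom))
  invisible(x)
}

#' Corrupt a reference geometry with isotropic Gaussian noise
#'
#' Draws \eqn{x_0 = x_1 + \sigma \epsilon} with \eqn{\epsilon} i.i.d.
#' standard normal per coordinate -- the generative model of "low-fidelity"
#' inputs used as the training prior. Uses R's global RNG stream; set a seed
#' for reproducibility.
#'
#' @param x1 reference structure.
#' @param sigma noise scale in Angstrom (>= 0).
#' @return corrupted structure (same elements and id).
#' @export
corrupt <- function(x1, sigma) {
  stopifnot(is_aefm_structure(x1))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    .aefm_error("sigma must be a single non-negative number",
                "aefm_parameter_error")
  n <- n_atoms(x1)
  set_coords(x1, x1$coords + sigma * matrix(rnorm(3 * n), n, 3))
}

#' Sample a point on the interpolation path
#'
#' Draws \eqn{x_t = (1 - t) x_0 + t x_1 + \sigma_{FM} \epsilon}, the
#' optimal-transport interpolation between a corrupted sample and its
#' reference with small Gaussian path noise. The default
#' \code{sigma_fm = 0.05} follows the method's hyperparameter choice.
#'
#' @param x0 corrupted (source) structure.
#' @param x1 reference (target) structure; same element sequence as
#'   \code{x0}.
#' @param t interpolation variable in [0, 1].
#' @param sigma_fm path noise scale (default 0.05).
#' @return An object of class \code{aefm_flow_sample}: list with fields
#'   \code{x_t}, \code{x0}, \code{x1}, \code{t}.
#' @export
sample_flow_point <- function(x0, x1, t, sigma_fm = 0.05) {
  .check_same_layout(x0, x1)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    .aefm_error("t must lie in [0, 1]", "aefm_parameter_error")
  if (!is.numeric(sigma_fm) || length(sigma_fm) != 1L || is.na(sigma_fm) ||
      sigma_fm < 0)
    .aefm_error("sigma_fm must be a single non-negative number",
                "aefm_parameter_error")
  n <- n_atoms(x1)
  xt <- (1 - t) * x0$coords + t * x1$coords +
    sigma_fm * matrix(rnorm(3 * n), n, 3)
  structure(list(x_t = set_coords(x1, xt), x0 = x0, x1 = x1, t = t),
            class = "aefm_flow_sample")
}

#' Expected per-atom squared displacement of the corruption process
#'
#' For isotropic per-coordinate noise of scale sigma,
#' \eqn{E[\|\sigma\epsilon\|^2 / N] = 3 \sigma^2}: the analytic identity
#' linking the corruption scale to the observable mean squared deviation
#' (used by \code{\link{calibrate_sigma}} and by the test suite).
#'
#' @param sigma noise scale (Angstrom, >= 0).
#' @return \code{3 * sigma^2} (Angstrom^2).
#' @export
expected_corruption_msd <- function(sigma) {
  if (!is.numeric(sigma) || any(sigma < 0))
    .aefm_error("sigma must be non-negative", "aefm_parameter_error")
  3 * sigma^2
}
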