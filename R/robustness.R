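#' Add segmentation-like jitter to vertex positions
#'
#' Emulates image-processing error by perturbing a random subset of
#' vertices: `floor(fraction * V)` vertices are drawn uniformly without
#' replacement and an independent Gaussian offset (standard deviation `sd`)
#' is added to each coordinate. Topology is untouched.
#'
#' @param tis A [tissue()].
#' @param fraction Proportion of coordinate entries (or vertices, see
#'   `unit`) to perturb (default 0.10).
#' @param sd Noise standard deviation, in the tissue's length units.
#'   Default `0.02 * sqrt(median cell area)` for simulated tissues and
#'   `0.05 * sqrt(median cell area)` for segmented ones.
#' @param unit With `"vertex"` (default), `floor(fraction * V)` vertices
#'   are drawn and both of their coordinates are jittered; with
#'   `"coordinate"`, `floor(fraction * 2V)` of the `2V` scalar coordinate
#'   entries are drawn and jittered independently. The two conventions
#'   inject the same total noise variance and give statistically
#'   indistinguishable results.
#' @return The perturbed tissue.
#' @export
add_vertex_noise <- function(tis, fraction = 0.1, sd = NULL,
                             unit = c("vertex", "coordinate")) {
  unit <- match.arg(unit)
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1]",
                                          class = "epimech_config_error")
  if (is.null(sd)) {
    med <- median(cell_geometry(tis)$area)
    sd <- if (tis$meta$provenance == "segmented") 0.05 * sqrt(med) else 0.02 * sqrt(med)
  }
  V <- nrow(tis$vertices)
  if (unit == "vertex") {
    n <- floor(fraction * V)
    if (n == 0) return(tis)
    idx <- sample.int(V, n)
    tis$vertices$x[idx] <- tis$vertices$x[idx] + rnorm(n, 0, sd)
    tis$vertices$y[idx] <- tis$vertices$y[idx] + rnorm(n, 0, sd)
  } else {
    n <- floor(fraction * 2 * V)
    if (n == 0) return(tis)
    idx <- sample.int(2 * V, n)
    xi <- idx[idx <= V]; yi <- idx[idx > V] - V
    tis$vertices$x[xi] <- tis$vertices$x[xi] + rnorm(length(xi), 0, sd)
    tis$vertices$y[yi] <- tis$vertices$y[yi] + rnorm(length(yi), 0, sd)
  }
  tis
}

#' Noise-resistance test of the parameter estimation
#'
#' Quantifies how segmentation error propagates into the estimates. For
#' each of `n_rep` replicates, vertex jitter is applied with
#' [add_vertex_noise()], preprocessing and the fit are re-run with the
#' given model, and two quantities are recorded: the relative parameter
#' deviations \eqn{\delta q = (q_n - q_t)/q_t} (reference \eqn{q_t} is the
#' ground truth for simulated tissues, otherwise the fit on the unperturbed
#' tissue) and the Pearson correlation `r` between predicted junction
#' tensions of the original and noised fits on the junctions retained by
#' both.
#'
#' When `truth` is supplied, the dimensional references (`lambda1`, `k`,
#' `gamma0`) are converted to the estimator's scale (which fixes
#' \eqn{\lambda_0 = 1}) by dividing by the true \eqn{\lambda_0}.
#'
#' @param tis A [tissue()] (unperturbed).
#' @param spec The [model_spec()] to fit (for simulated data, the
#'   generating model; for segmented data, the AIC-selected one).
#' @param truth Optional [mech_params()] ground truth.
#' @param fraction,sd,unit As in [add_vertex_noise()].
#' @param n_rep Number of replicates (default 100).
#' @param seed RNG seed; replicate seeds are derived as `seed + replicate`.
#' @return A `noise_report`: list with `deviations` (tibble: replicate,
#'   term, delta_q), `correlations` (tibble: replicate, r), `medians`
#'   (tibble: term, median_abs_delta_q), `min_r`, `median_r`, `n_failed`.
#' @export
noise_resistance_test <- function(tis, spec, truth = NULL, fraction = 0.1,
                                  sd = NULL, n_rep = 100, seed = 1,
                                  unit = "vertex") {
  if (n_rep < 1) abort("n_rep must be >= 1", class = "epimech_config_error")
  if (is.null(sd)) {
    med <- median(cell_geometry(tis)$area)
    sd <- if (tis$meta$provenance == "segmented") 0.05 * sqrt(med) else 0.02 * sqrt(med)
  }
  fit0 <- fit_tension_model(tis, spec)
  ref <- fit_reference_values(fit0, spec, truth)

  devs <- list(); cors <- numeric(0); failed <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(seed + r)
    noised <- add_vertex_noise(tis, fraction = fraction, sd = sd, unit = unit)
    fit_n <- tryCatch(fit_tension_model(noised, spec),
                      error = function(e) NULL)
    if (is.null(fit_n)) {
      failed <- failed + 1L
      next
    }
    est <- fit_estimate_values(fit_n, spec)
    dq <- (est[names(ref)] - ref) / ref
    devs[[length(devs) + 1L]] <- tibble(replicate = r, term = names(ref),
                                        delta_q = unname(dq))
    shared <- intersect(fit0$predicted_tensions$id, fit_n$predicted_tensions$id)
    t0 <- fit0$predicted_tensions$tension[match(shared, fit0$predicted_tensions$id)]
    t1 <- fit_n$predicted_tensions$tension[match(shared, fit_n$predicted_tensions$id)]
    cors <- c(cors, cor(t0, t1))
  }
  if (length(devs) == 0) abort("all noise replicates failed",
                               class = "epimech_degenerate_error")
  deviations <- dplyr::bind_rows(devs)
  medians <- deviations |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(median_abs_delta_q = median(abs(.data$delta_q)),
                     median_delta_q = median(.data$delta_q), .groups = "drop")
  structure(list(deviations = deviations,
                 correlations = tibble(replicate = seq_along(cors), r = cors),
                 medians = medians, min_r = min(cors),
                 median_r = median(cors), n_failed = failed,
                 sd = sd, fraction = fraction, spec = spec),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> %d replicates (%d failed), min r = %.4f\n",
              nrow(x$correlations) + x$n_failed, x$n_failed, x$min_r))
  print(x$medians)
  invisible(x)
}

# reference parameter values on the estimator's lambda0 = 1 scale
fit_reference_values <- function(fit0, spec, truth) {
  if (is.null(truth)) return(fit_estimate_values(fit0, spec))
  s <- truth$lambda0
  vals <- c(k = truth$k / s)
  if (spec$family == "anisotropic_spring") {
    if (spec$variant %in% c("A", "B", "D")) vals <- c(vals, mu0 = truth$mu0)
    if (spec$variant %in% c("A", "B", "C")) vals <- c(vals, lambda1 = truth$lambda1 / s)
    if (spec$variant == "A") vals <- c(vals, mu1 = truth$mu1)
  } else {
    vals <- c(vals, gamma0 = truth$gamma0 / s)
    if (spec$variant %in% c("both_aniso", "line_aniso")) vals <- c(vals, mu0 = truth$mu0)
    if (spec$variant %in% c("both_aniso", "elasticity_aniso")) vals <- c(vals, mu_gamma = truth$mu_gamma)
  }
  vals[vals != 0] # deviations are undefined for zero-valued references
}

# estimates converted back to the tissue's original length units (the fit
# itself lives in median-area-normalized coordinates, scale factor s:
# lengths were divided by s, so lambda1 and gamma0 pick up a factor s and
# k a factor s^3)
fit_estimate_values <- function(fit, spec) {
  pp <- fit$params
  s <- fit$scale %||% 1
  vals <- c(k = pp$k / s^3)
  if (spec$family == "anisotropic_spring") {
    if (spec$variant %in% c("A", "B", "D")) vals <- c(vals, mu0 = pp$mu0)
    if (spec$variant %in% c("A", "B", "C")) vals <- c(vals, lambda1 = pp$lambda1 / s)
    if (spec$variant == "A") vals <- c(vals, mu1 = pp$mu1)
  } else {
    vals <- c(vals, gamma0 = pp$gamma0 / s)
    if (spec$variant %in% c("both_aniso", "line_aniso")) vals <- c(vals, mu0 = pp$mu0)
    if (spec$variant %in% c("both_aniso", "elasticity_aniso")) vals <- c(vals, mu_gamma = pp$mu_gamma)
  }
  vals
}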