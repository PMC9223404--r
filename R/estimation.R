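#' Preprocess a tissue for force-balance estimation
#'
#' Applies the standard exclusions and scale normalization before fitting.
#' Junctions shorter than `min_junction_length` are excluded (the angle of a
#' very short junction cannot be measured reliably), as are cells larger
#' than `max_cell_area_factor` times the median cell area (unusually large
#' cells may have different mechanics). Finally the spatial scale is
#' normalized by the median cell area: all coordinates are divided by
#' \eqn{\sqrt{\mathrm{median}(A)}} so that the median cell area becomes 1.
#' Exclusion thresholds are applied in the original units, before
#' normalization.
#'
#' @param tis A [tissue()].
#' @param min_junction_length Length threshold. Default: `3 * pixel_scale`
#'   for segmented tissues (the three-pixel rule) and `0.05 * sqrt(A0)`
#'   for simulated ones (matching the T1 threshold of the simulator; the
#'   median cell area stands in for `A0` when the metadata lacks it).
#' @param max_cell_area_factor Cells above this multiple of the median area
#'   are excluded (default 2).
#' @param normalize Rescale coordinates by the median cell area (default
#'   `TRUE`).
#' @return The tissue with logical `excluded` columns added to `junctions`
#'   and `cells`, and an attribute `"preprocess"` holding the exclusion
#'   report (`excluded_junctions`, `excluded_cells`, `scale`). Retrieve the
#'   report with `attr(x, "preprocess")`.
#' @export
preprocess_tissue <- function(tis, min_junction_length = NULL,
                              max_cell_area_factor = 2, normalize = TRUE) {
  fm <- mesh_data(tis, strict = FALSE)
  if (fm$C == 0 || fm$J == 0) abort("tissue has no cells or junctions",
                                    class = "epimech_empty_system_error")
  med <- median(fm$carea)
  if (is.null(min_junction_length)) {
    min_junction_length <- if (tis$meta$provenance == "segmented") {
      3 * tis$meta$pixel_scale
    } else {
      0.05 * sqrt(tis$meta$A0 %||% med)
    }
  }
  if (min_junction_length < 0 || max_cell_area_factor <= 0) {
    abort("thresholds must be positive", class = "epimech_config_error")
  }
  excl_j <- fm$jlen < min_junction_length
  # degenerate (non-positive-area) cells can arise from vertex jitter on
  # sliver cells; they are excluded along with the oversized ones
  excl_c <- fm$carea > max_cell_area_factor * med | fm$carea <= 0
  if (all(excl_j)) abort("all junctions excluded by the length threshold",
                         class = "epimech_empty_system_error")
  scale <- if (normalize) sqrt(med) else 1
  out <- tis
  out$vertices$x <- tis$vertices$x / scale
  out$vertices$y <- tis$vertices$y / scale
  out$junctions$excluded <- excl_j
  out$cells$excluded <- excl_c
  attr(out, "preprocess") <- list(
    excluded_junctions = tis$junctions$id[excl_j],
    excluded_cells = tis$cells$id[excl_c],
    n_excluded_junctions = sum(excl_j),
    n_excluded_cells = sum(excl_c),
    min_junction_length = min_junction_length,
    max_cell_area_factor = max_cell_area_factor,
    scale = scale)
  out
}

#' Assemble the force-balance system of a tissue
#'
#' Builds the linear system behind the estimator. At every usable vertex
#' the net force is a linear combination of junction tensions and cell
#' pressures, \eqn{F = CX}: the tension coefficients are the unit vectors
#' from the vertex toward the far endpoints of its junctions, and the
#' pressure coefficient of an adjacent cell is half the cross-difference of
#' the two neighbour vertices flanking the vertex in that cell's
#' counterclockwise loop (the shoelace area gradient). Substituting the
#' model features \eqn{T = L_T \beta_T}, \eqn{P = L_P \beta_P} gives the
#' design matrix \eqn{M = C\,\mathrm{diag}(L_T, L_P)}.
#'
#' Rows are contributed only by vertices that are interior, not
#' frame-flagged, and whose every incident junction and adjacent cell
#' survived preprocessing; excluded junctions and cells also lose their
#' columns.
#'
#' @param tis A [tissue()], typically from [preprocess_tissue()]; without
#'   `excluded` columns all junctions and cells are used.
#' @param spec A [model_spec()].
#' @return A `balance_system`: list with the sparse coefficient matrix `C`,
#'   feature matrices `L_T`, `L_P`, dense design matrix `M`, the included
#'   `vertex_ids` and retained `junction_ids` / `cell_ids`, equation count
#'   `n`, and the junction/cell geometry used.
#' @export
assemble_balance_system <- function(tis, spec) {
  fm <- mesh_data(tis, strict = FALSE)
  excl_j <- tis$junctions[["excluded"]] %||% rep(FALSE, fm$J)
  excl_c <- tis$cells[["excluded"]] %||% rep(FALSE, fm$C)

  bad_v <- fm$boundary_v
  bad_v[fm$ej[excl_j, ]] <- TRUE
  bad_v[fm$loop_v[excl_c[fm$loop_cell]]] <- TRUE
  inc_v <- which(!bad_v)
  if (length(inc_v) == 0) abort("no usable interior vertices",
                                class = "epimech_empty_system_error")
  keep_j <- which(!excl_j)
  keep_c <- which(!excl_c)
  vrow <- match(seq_len(fm$V), inc_v) # vertex -> included index or NA
  jcol <- match(seq_len(fm$J), keep_j)
  ccol <- match(seq_len(fm$C), keep_c)

  # tension entries: one per (junction, endpoint) with an included endpoint
  ii <- jj <- xx <- list(); m <- 0L
  for (side in 1:2) {
    v <- fm$ej[, side]; o <- fm$ej[, 3L - side]
    sel <- which(!is.na(vrow[v]) & !is.na(jcol))
    if (length(sel) == 0) next
    a <- (fm$pos[o[sel], , drop = FALSE] - fm$pos[v[sel], , drop = FALSE]) /
      fm$jlen[sel]
    m <- m + 1L
    ii[[m]] <- c(2L * vrow[v[sel]] - 1L, 2L * vrow[v[sel]])
    jj[[m]] <- rep(jcol[sel], 2)
    xx[[m]] <- c(a[, 1], a[, 2])
  }
  # pressure entries: one per loop slot with included vertex and kept cell
  sel <- which(!is.na(vrow[fm$loop_v]) & !is.na(ccol[fm$loop_cell]))
  if (length(sel) > 0) {
    vn <- fm$loop_v[fm$loop_next[sel]]; vp <- fm$loop_v[fm$loop_prev[sel]]
    bx <- (fm$pos[vn, 2] - fm$pos[vp, 2]) / 2
    by <- (fm$pos[vp, 1] - fm$pos[vn, 1]) / 2
    m <- m + 1L
    ii[[m]] <- c(2L * vrow[fm$loop_v[sel]] - 1L, 2L * vrow[fm$loop_v[sel]])
    jj[[m]] <- rep(length(keep_j) + ccol[fm$loop_cell[sel]], 2)
    xx[[m]] <- c(bx, by)
  }
  n <- 2L * length(inc_v)
  ncols <- length(keep_j) + length(keep_c)
  C <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, ncols))

  Ls <- if (spec$family == "conventional") {
    g <- flat_geometry(fm)
    junction_L_sum(fm, g)[keep_j]
  } else NULL
  L_T <- tension_features(spec, fm$jlen[keep_j], fm$jangle[keep_j], Ls)
  L_P <- pressure_features(spec, fm$carea[keep_c])
  nT <- ncol(L_T)
  L <- Matrix::bdiag(L_T, L_P)
  M <- as.matrix(C %*% L)
  colnames(M) <- c(colnames(L_T), colnames(L_P))

  structure(list(C = C, L_T = L_T, L_P = L_P, M = M, spec = spec,
                 n = n, m = ncols,
                 vertex_ids = tis$vertices$id[inc_v],
                 junction_ids = tis$junctions$id[keep_j],
                 cell_ids = tis$cells$id[keep_c],
                 length = fm$jlen[keep_j], angle = fm$jangle[keep_j],
                 L_sum = Ls, area = fm$carea[keep_c]),
            class = "balance_system")
}

#' Akaike information criterion for a force-balance fit
#'
#' \deqn{\mathrm{AIC} = n \log(2\pi\hat\sigma^2) + n + 2(p + 1),}
#' where \eqn{\hat\sigma^2 = F^\top F / n} is the mean squared force
#' residual, `n` the number of balance equations and `p` the number of free
#' model parameters (excluding the fixed scale \eqn{\lambda_0}, including
#' `k`).
#'
#' @param sigma2 Mean squared residual (> 0).
#' @param n Equation count.
#' @param p Free-parameter count.
#' @return AIC value.
#' @examples
#' aic(1 / (2 * pi), 2, 1) # 6
#' @export
aic <- function(sigma2, n, p) {
  if (sigma2 <= 0) abort("sigma2 must be positive (a perfect fit has no finite AIC)",
                         class = "epimech_domain_error")
  n * log(2 * pi * sigma2) + n + 2 * (p + 1)
}

# solve min ||y + Mf b||^2 subject to the family constraints; returns
# list(beta, boundary)
solve_balance <- function(Mf, y, spec) {
  qrf <- qr(Mf)
  if (qrf$rank < ncol(Mf)) {
    abort(paste("degenerate geometry: the design matrix is rank deficient",
                "(cell shapes do not vary enough, e.g. a regular hexagonal lattice)"),
          class = "epimech_degenerate_error")
  }
  beta <- qr.coef(qrf, -y)
  boundary <- FALSE
  nm <- colnames(Mf)

  violated <- FALSE
  if (spec$family == "anisotropic_spring" && "lambda1" %in% nm) {
    l1 <- beta[["lambda1"]]
    anis <- all(c("lambda1p", "lambda1pp") %in% nm)
    mu1 <- if (anis) sqrt(beta[["lambda1p"]]^2 + beta[["lambda1pp"]]^2) / l1 else 0
    violated <- l1 <= 0 || (anis && (mu1 < 0 || mu1 >= 1))
  }
  if (spec$family == "conventional") {
    violated <- beta[["gamma0"]] <= 0
  }
  if (!violated) return(list(beta = beta, boundary = FALSE))

  # bound-constrained refit through a smooth reparameterization:
  # lambda1 = t^2 >= 0 with mu1 = (1 - 1e-6) * plogis(s) in (0, 1);
  # gamma0 = t^2 > 0 for the conventional family
  eps <- 1e-6
  if (spec$family == "anisotropic_spring") {
    con_base <- "lambda1"; con_p <- "lambda1p"; con_pp <- "lambda1pp"
  } else {
    con_base <- "gamma0"; con_p <- "gammap"; con_pp <- "gammapp"
  }
  anis <- all(c(con_p, con_pp) %in% nm)
  free_nm <- setdiff(nm, c(con_base, con_p, con_pp))
  mk_beta <- function(th) {
    b <- setNames(numeric(length(nm)), nm)
    b[free_nm] <- th[seq_along(free_nm)]
    extra <- th[-seq_along(free_nm)]
    base <- extra[1]^2
    b[con_base] <- base
    if (anis) {
      mu <- (1 - eps) * stats::plogis(extra[2])
      phi <- extra[3]
      b[con_p] <- base * mu * sin(2 * phi)
      b[con_pp] <- base * mu * cos(2 * phi)
    }
    b
  }
  obj <- function(th) {
    r <- y + Mf %*% mk_beta(th)
    sum(r^2)
  }
  # start from the projection of the unconstrained solution
  base0 <- max(beta[[con_base]], 1e-4)
  th0 <- c(beta[free_nm], sqrt(base0))
  if (anis) {
    mu0 <- min(max(sqrt(beta[[con_p]]^2 + beta[[con_pp]]^2) / base0, 1e-3),
               1 - 1e-3)
    th0 <- c(th0, stats::qlogis(mu0 / (1 - eps)),
             0.5 * atan2(beta[[con_p]], beta[[con_pp]]))
  }
  opt <- optim(th0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  list(beta = mk_beta(opt$par), boundary = TRUE)
}

#' Fit a tension/pressure model by force balance
#'
#' The central estimator. The quasi-static assumption says tensions and
#' pressures balance at every vertex, \eqn{CX \approx 0}. Substituting the
#' linearized model gives \eqn{F = C L \beta \approx 0}; the scale is fixed
#' by \eqn{\lambda_0 = 1} and the remaining coefficients minimize
#' \eqn{\|F\|^2} -- an ordinary multiple linear regression, solved in
#' closed form. The conventional family is refitted under the positivity
#' constraint \eqn{\Gamma > 0}, and the spring family under
#' \eqn{0 \le \mu_1 < 1}, \eqn{\lambda_1 \ge 0}, whenever the unconstrained
#' optimum violates them (the fit is then flagged `boundary`).
#'
#' @param tis A [tissue()]. With `preprocess = TRUE` (default) the tissue
#'   is passed through [preprocess_tissue()] first unless it already
#'   carries exclusion columns.
#' @param spec A [model_spec()].
#' @param preprocess Apply [preprocess_tissue()] defaults first.
#' @param conf_level Confidence level for the reported intervals.
#' @param ... Passed to [preprocess_tissue()].
#' @return A `tension_fit` object: estimated `coefficients` (including the
#'   fixed `lambda0 = 1`), polar `params` ([mech_params()]), residual
#'   vector, `sigma2`, `aic`, `n`, `p`, per-junction `predicted_tensions`,
#'   per-cell `predicted_pressures`, and coefficient/parameter standard
#'   errors. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' spec <- model_spec("anisotropic_spring", "A")
#' par <- mech_params(lambda0 = 0.2, mu0 = 0.15, lambda1 = 0.03,
#'                    mu1 = 0.5, k = 1)
#' sim <- simulate_tissue(spec, par, n_rows = 6, n_cols = 6, t_end = 500,
#'                        seed = 2)
#' fit <- fit_tension_model(sim$tissue, spec)
#' glance(fit)
#' }
#' @export
fit_tension_model <- function(tis, spec, preprocess = TRUE,
                              conf_level = 0.95, ...) {
  if (preprocess && is.null(tis$junctions[["excluded"]])) {
    tis <- preprocess_tissue(tis, ...)
  }
  scale <- attr(tis, "preprocess")$scale %||% 1
  sys <- assemble_balance_system(tis, spec)
  M <- sys$M
  y <- M[, 1]
  Mf <- M[, -1, drop = FALSE]
  p <- ncol(Mf)
  if (sys$n <= p) abort("fewer equations than free parameters",
                        class = "epimech_empty_system_error")
  sol <- solve_balance(Mf, y, spec)
  beta <- sol$beta
  coeffs <- c(lambda0 = 1, beta)
  resid <- as.vector(y + Mf %*% beta)
  sigma2 <- sum(resid^2) / sys$n
  params <- to_polar(spec, coeffs)
  aic_val <- aic(sigma2, sys$n, p)

  tcoef <- coeffs[colnames(sys$L_T)]
  pred_T <- as.vector(sys$L_T %*% tcoef)
  pred_P <- as.vector(sys$L_P %*% coeffs[["k"]])

  se <- if (!sol$boundary) {
    fit_standard_errors(Mf, sigma2, beta, spec, conf_level)
  } else NULL

  structure(list(spec = spec, coefficients = coeffs, params = params,
                 residuals = resid, sigma2 = sigma2, aic = aic_val,
                 n = sys$n, p = p, boundary = sol$boundary,
                 predicted_tensions = tibble(id = sys$junction_ids,
                                             length = sys$length,
                                             angle = sys$angle,
                                             tension = pred_T),
                 predicted_pressures = tibble(id = sys$cell_ids,
                                              area = sys$area,
                                              pressure = pred_P),
                 std_errors = se, scale = scale, system = sys),
            class = "tension_fit")
}

#' @export
print.tension_fit <- function(x, ...) {
  cat(sprintf("<tension_fit> %s: n = %d equations, p = %d, sigma2 = %.3g, AIC = %.2f%s\n",
              format(x$spec), x$n, x$p, x$sigma2, x$aic,
              if (x$boundary) " (constrained at boundary)" else ""))
  print(x$coefficients)
  invisible(x)
}

# coefficient covariance sigma2 * (M'M)^-1 plus first-order propagation to
# the derived polar / normalized quantities
fit_standard_errors <- function(Mf, sigma2, beta, spec, conf_level = 0.95) {
  XtX <- crossprod(Mf)
  cov_beta <- tryCatch(sigma2 * solve(XtX),
                       error = function(e) abort(
                         "singular normal equations in standard-error computation",
                         class = "epimech_degenerate_error"))
  derived <- function(b) {
    pol <- to_polar(spec, c(lambda0 = 1, setNames(b, names(beta))))
    k <- pol$k
    out <- c(lambda0_norm = 1 / k, mu0 = pol$mu0, phi0 = pol$phi0,
             k = k)
    if ("lambda1" %in% names(beta)) {
      out <- c(out, lambda1_norm = pol$lambda1 / k, mu1 = pol$mu1,
               phi1 = pol$phi1)
    }
    if ("gamma0" %in% names(beta)) {
      out <- c(out, gamma0_norm = pol$gamma0 / k, mu_gamma = pol$mu_gamma,
               phi_gamma = pol$phi_gamma)
    }
    out
  }
  est <- derived(beta)
  # numerical Jacobian (central differences)
  J <- matrix(0, length(est), length(beta))
  h <- pmax(abs(beta), 1e-4) * 1e-6
  for (j in seq_along(beta)) {
    bp <- beta; bp[j] <- bp[j] + h[j]
    bm <- beta; bm[j] <- bm[j] - h[j]
    J[, j] <- (derived(bp) - derived(bm)) / (2 * h[j])
  }
  var_d <- pmax(diag(J %*% cov_beta %*% t(J)), 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co_se <- sqrt(pmax(diag(cov_beta), 0))
  tibble(term = c(names(beta), names(est)),
         estimate = c(unname(beta), unname(est)),
         std_error = c(co_se, sqrt(var_d)),
         conf_low = c(unname(beta) - z * co_se, unname(est) - z * sqrt(var_d)),
         conf_high = c(unname(beta) + z * co_se, unname(est) + z * sqrt(var_d)),
         kind = rep(c("coefficient", "derived"),
                    c(length(beta), length(est))))
}

#' Standard errors of a fitted model
#'
#' Returns the coefficient standard errors from the least-squares
#' covariance \eqn{\hat\sigma^2 (M^\top M)^{-1}} together with first-order
#' (delta-method) propagation to the derived quantities (the anisotropy
#' magnitudes and orientations, and the \eqn{\hat k}-normalized tension
#' coefficients), with confidence intervals
#' \eqn{[\hat q - z\hat\sigma_q,\; \hat q + z\hat\sigma_q]}.
#'
#' @param fit A `tension_fit` from an unconstrained solution.
#' @return Tibble with columns `term`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`, `kind`.
#' @export
standard_errors <- function(fit) {
  if (is.null(fit$std_errors)) {
    abort("standard errors are unavailable for boundary-constrained fits",
          class = "epimech_degenerate_error")
  }
  fit$std_errors
}

#' Fit several models and select by AIC
#'
#' Fits each candidate [model_spec()] to the same preprocessed tissue and
#' ranks them by [aic()]; ties are broken toward fewer parameters. Failed
#' fits (for example rank-deficient geometry) are recorded and skipped.
#'
#' @param tis A [tissue()].
#' @param specs List of [model_spec()] candidates; default: the five
#'   anisotropic-spring variants.
#' @param preprocess,... As in [fit_tension_model()].
#' @return A `model_selection`: list with `best` (the winning spec),
#'   `table` (tibble: model, family, variant, p, sigma2, AIC), and `fits`.
#' @export
select_tension_model <- function(tis, specs = spring_specs(),
                                 preprocess = TRUE, ...) {
  if (length(specs) < 1) abort("need at least one candidate model",
                               class = "epimech_config_error")
  if (preprocess && is.null(tis$junctions[["excluded"]])) {
    tis <- preprocess_tissue(tis, ...)
  }
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_tension_model(tis, sp, preprocess = FALSE),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok)) abort("all candidate fits failed", class = "epimech_degenerate_error")
  tab <- tibble(
    model = vapply(specs, format, ""),
    family = vapply(specs, function(s) s$family, ""),
    variant = vapply(specs, function(s) s$variant, ""),
    p = vapply(specs, n_free_params, 0L),
    sigma2 = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$sigma2, 0),
    AIC = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aic, 0),
    error = vapply(fits, function(f) if (inherits(f, "error")) conditionMessage(f) else NA_character_, "")
  )
  cand <- which(ok)
  best_i <- cand[order(tab$AIC[cand], tab$p[cand])][1]
  structure(list(best = specs[[best_i]], best_fit = fits[[best_i]],
                 table = tab, fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> best: %s\n", format(x$best)))
  print(x$table[, c("model", "p", "sigma2", "AIC")])
  invisible(x)
}

#' The five anisotropic-spring model variants
#'
#' @param pressure_form Passed to [model_spec()].
#' @return List of [model_spec()] objects A--E.
#' @export
spring_specs <- function(pressure_form = "linear") {
  lapply(c("A", "B", "C", "D", "E"), function(v)
    model_spec("anisotropic_spring", v, pressure_form))
}

#' The four conventional model variants
#'
#' @inheritParams spring_specs
#' @return List of [model_spec()] objects.
#' @export
conventional_specs <- function(pressure_form = "linear") {
  lapply(c("both_aniso", "line_aniso", "elasticity_aniso", "isotropic"),
         function(v) model_spec("conventional", v, pressure_form))
}

#' Nematic anisotropy of predicted tensions
#'
#' Summarizes how strongly tension depends on junction orientation:
#' \deqn{R_T \langle \hat T \rangle e^{i2\Theta} =
#'   \langle \hat T e^{i 2\theta} \rangle -
#'   \langle \hat T \rangle \langle e^{i 2\theta} \rangle.}
#' \eqn{R_T} vanishes when tension is uncorrelated with orientation;
#' \eqn{\Theta \in [0, \pi)} is the axis of the anisotropy.
#'
#' @param tensions Numeric vector of per-junction tensions, or a
#'   `tension_fit` (its predicted tensions are used).
#' @param angles Junction angles (radians), required when `tensions` is a
#'   vector.
#' @return Tibble with columns `R_T` and `Theta`.
#' @examples
#' th <- seq(0, pi, length.out = 1000)[-1000]
#' tension_anisotropy(1 + cos(2 * th), th) # R_T = 0.5, Theta = 0
#' @export
tension_anisotropy <- function(tensions, angles = NULL) {
  if (inherits(tensions, "tension_fit")) {
    angles <- tensions$predicted_tensions$angle
    tensions <- tensions$predicted_tensions$tension
  }
  if (length(tensions) == 0) abort("no junctions", class = "epimech_domain_error")
  if (length(tensions) != length(angles)) abort("tensions and angles differ in length",
                                                class = "epimech_domain_error")
  mT <- mean(tensions)
  if (mT == 0) abort("mean tension is zero", class = "epimech_domain_error")
  z <- mean(tensions * exp(2i * angles)) - mT * mean(exp(2i * angles))
  tibble(R_T = Mod(z) / abs(mT), Theta = (Arg(z) / 2) %% pi)
}

#' Normalize estimated tension coefficients by the pressure modulus
#'
#' Force-balance estimation determines parameters only up to a scale, fixed
#' by \eqn{\lambda_0 = 1}. To compare against ground truth the dimensional
#' coefficients are normalized by the estimated area modulus \eqn{\hat k}
#' and the target area: \eqn{\lambda_0 = \hat\lambda_0 / (\hat k A_0^{1.5})},
#' \eqn{\lambda_1 = \hat\lambda_1 / (\hat k A_0)} (likewise \eqn{\Gamma});
#' the dimensionless anisotropies \eqn{\mu} and orientations \eqn{\varphi}
#' pass through unchanged.
#'
#' @param fit A `tension_fit`.
#' @param k_hat Estimated area modulus (default: the fit's).
#' @param A0 Target cell area of the generating model (default 1).
#' @return Tibble with columns `term` and `estimate` (`lambda0`, `mu0`,
#'   `phi0`, `lambda1`, `mu1`, `phi1`, `gamma0`, ... as applicable).
#' @examples
#' # lambda1_hat = 0.06, k_hat = 2, A0 = 1 -> lambda1 = 0.03
#' @export
normalize_estimates <- function(fit, k_hat = fit$params$k, A0 = 1) {
  if (k_hat <= 0 || A0 <= 0) abort("k_hat and A0 must be positive",
                                   class = "epimech_domain_error")
  # the fit lives in median-area-normalized coordinates; express the target
  # area in the same units so the ratios are dimensionless
  A0 <- A0 / (fit$scale %||% 1)^2
  pp <- fit$params
  out <- c(lambda0 = pp$lambda0 / (k_hat * A0^1.5))
  if (pp$mu0 > 0 || "lambda0p" %in% names(fit$coefficients)) {
    out <- c(out, mu0 = pp$mu0, phi0 = pp$phi0)
  }
  if ("lambda1" %in% names(fit$coefficients)) {
    out <- c(out, lambda1 = pp$lambda1 / (k_hat * A0))
    if ("lambda1p" %in% names(fit$coefficients)) {
      out <- c(out, mu1 = pp$mu1, phi1 = pp$phi1)
    }
  }
  if ("gamma0" %in% names(fit$coefficients)) {
    out <- c(out, gamma0 = pp$gamma0 / (k_hat * A0))
    if ("gammap" %in% names(fit$coefficients)) {
      out <- c(out, mu_gamma = pp$mu_gamma, phi_gamma = pp$phi_gamma)
    }
  }
  tibble(term = names(out), estimate = unname(out))
}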