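#' Specify a junction-tension / cell-pressure model
#'
#' A model specification names one member of the two tension-model families
#' considered for epithelial junctions, plus the functional form of the cell
#' pressure. The *anisotropic spring* family writes junction tension as
#' \deqn{T(l, \theta) = \Lambda_0(\theta) - \Lambda_1(\theta)\, l,}
#' with orientation-dependent line tension
#' \eqn{\Lambda_0(\theta) = \lambda_0\{1 + \mu_0 \cos 2(\theta - \varphi_0)\}}
#' and spring constant
#' \eqn{\Lambda_1(\theta) = \lambda_1\{1 + \mu_1 \cos 2(\theta - \varphi_1)\}}.
#' Variants `"A"`--`"E"` drop terms in order of decreasing complexity:
#' `"B"` sets \eqn{\mu_1 = 0}, `"C"` sets \eqn{\mu_0 = \mu_1 = 0}, `"D"` drops
#' \eqn{\Lambda_1} entirely, and `"E"` is constant tension
#' \eqn{T = \lambda_0}. The *conventional* family combines line tension with
#' cortical (perimeter) elasticity,
#' \deqn{T(L_i, L_j, \theta) = \Lambda_0(\theta) + \Gamma(\theta)(L_i + L_j),}
#' where \eqn{L_i, L_j} are the perimeters of the two cells flanking the
#' junction and \eqn{\Gamma(\theta)} is parameterized like
#' \eqn{\Lambda_0(\theta)}; its variants drop the anisotropy of either or both
#' coefficients. Cell pressure is \eqn{P(A) = -kA + P_0} (`"linear"`),
#' \eqn{k/A + P_0} (`"inverse"`), or \eqn{k e^{-A} + P_0} (`"exponential"`).
#'
#' @param family `"anisotropic_spring"` or `"conventional"`.
#' @param variant For the spring family one of `"A"`, `"B"`, `"C"`, `"D"`,
#'   `"E"`; for the conventional family one of `"both_aniso"`,
#'   `"line_aniso"`, `"elasticity_aniso"`, `"isotropic"`.
#' @param pressure_form `"linear"` (default), `"inverse"`, or
#'   `"exponential"`.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("anisotropic_spring", "A")
#' model_spec("conventional", "isotropic")
#' @export
model_spec <- function(family = c("anisotropic_spring", "conventional"),
                       variant = NULL,
                       pressure_form = c("linear", "inverse", "exponential")) {
  family <- match.arg(family)
  pressure_form <- match.arg(pressure_form)
  variants <- switch(family,
    anisotropic_spring = c("A", "B", "C", "D", "E"),
    conventional = c("both_aniso", "line_aniso", "elasticity_aniso", "isotropic")
  )
  if (is.null(variant)) variant <- variants[[1L]]
  if (!variant %in% variants) {
    abort(sprintf("variant '%s' is not valid for family '%s' (choose from %s)",
                  variant, family, paste(variants, collapse = ", ")),
          class = "epimech_config_error")
  }
  structure(list(family = family, variant = variant,
                 pressure_form = pressure_form),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s / %s, pressure: %s (%d free coefficients)\n",
              x$family, x$variant, x$pressure_form, n_free_params(x)))
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) paste0(x$family, ":", x$variant)

# Tension-feature column names, in design-matrix order, including the fixed
# lambda0 column first.  Free coefficients are all but "lambda0".
tension_coef_names <- function(spec) {
  if (spec$family == "anisotropic_spring") {
    switch(spec$variant,
      A = c("lambda0", "lambda0p", "lambda0pp", "lambda1", "lambda1p", "lambda1pp"),
      B = c("lambda0", "lambda0p", "lambda0pp", "lambda1"),
      C = c("lambda0", "lambda1"),
      D = c("lambda0", "lambda0p", "lambda0pp"),
      E = "lambda0"
    )
  } else {
    switch(spec$variant,
      both_aniso = c("lambda0", "lambda0p", "lambda0pp", "gamma0", "gammap", "gammapp"),
      line_aniso = c("lambda0", "lambda0p", "lambda0pp", "gamma0"),
      elasticity_aniso = c("lambda0", "gamma0", "gammap", "gammapp"),
      isotropic = c("lambda0", "gamma0")
    )
  }
}

#' Number of free parameters of a model
#'
#' Counts the coefficients estimated from data: the tension coefficients
#' excluding the fixed scale \eqn{\lambda_0}, plus the pressure coefficient
#' \eqn{k}. This is the `p` entering the AIC penalty.
#'
#' @param spec A [model_spec()].
#' @return Integer count.
#' @examples
#' n_free_params(model_spec("anisotropic_spring", "A")) # 6
#' @export
n_free_params <- function(spec) {
  length(tension_coef_names(spec)) - 1L + 1L # drop lambda0, add k
}

#' Mechanical parameter set
#'
#' Bundles the parameters of the tension and pressure models in their
#' physical (polar) form. Only the fields used by a given [model_spec()]
#' matter; the rest are ignored. `P0` is a reporting offset only: constant
#' pressure cancels in the force balance at interior vertices and is never
#' estimated.
#'
#' @param lambda0 Base line tension (sets the force scale); must be > 0.
#' @param mu0,phi0 Magnitude (>= 0) and orientation (radians, folded to
#'   `[0, pi)`) of the line-tension anisotropy.
#' @param lambda1 Junction spring constant (force/length).
#' @param mu1,phi1 Magnitude (in `[0, 1)`) and orientation of the
#'   spring-constant anisotropy.
#' @param gamma0 Cortical elasticity (conventional family); must be >= 0.
#' @param mu_gamma,phi_gamma Anisotropy of the cortical elasticity.
#' @param k Cell area elastic modulus (pressure/area); must be > 0.
#' @param P0 Basal pressure offset.
#' @param A0 Target cell area; must be > 0.
#' @return An object of class `mech_params` (a named list).
#' @examples
#' mech_params(lambda0 = 0.2, mu0 = 0.15, lambda1 = 0.03, mu1 = 0.5, k = 1)
#' @export
mech_params <- function(lambda0 = 1, mu0 = 0, phi0 = 0,
                        lambda1 = 0, mu1 = 0, phi1 = 0,
                        gamma0 = 0, mu_gamma = 0, phi_gamma = 0,
                        k = 1, P0 = 0, A0 = 1) {
  p <- list(lambda0 = lambda0, mu0 = mu0, phi0 = phi0 %% pi,
            lambda1 = lambda1, mu1 = mu1, phi1 = phi1 %% pi,
            gamma0 = gamma0, mu_gamma = mu_gamma, phi_gamma = phi_gamma %% pi,
            k = k, P0 = P0, A0 = A0)
  stopifnot(is.numeric(unlist(p)), all(is.finite(unlist(p))))
  if (lambda0 <= 0) abort("lambda0 must be positive", class = "epimech_config_error")
  if (k <= 0) abort("k must be positive", class = "epimech_config_error")
  if (mu0 < 0) abort("mu0 must be non-negative", class = "epimech_config_error")
  if (mu1 < 0 || mu1 >= 1) abort("mu1 must lie in [0, 1)", class = "epimech_config_error")
  if (gamma0 < 0) abort("gamma0 must be non-negative", class = "epimech_config_error")
  if (A0 <= 0) abort("A0 must be positive", class = "epimech_config_error")
  structure(p, class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("<mech_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

# anisotropic coefficient c(theta) = base * (1 + mu * cos 2(theta - phi))
aniso_coef <- function(base, mu, phi, theta) {
  base * (1 + mu * cos(2 * (theta - phi)))
}

#' Evaluate the junction tension model
#'
#' @param spec A [model_spec()].
#' @param params A [mech_params()].
#' @param l Junction length(s), >= 0.
#' @param theta Junction orientation(s) in radians (pi-periodic).
#' @param L_sum For the conventional family, the summed perimeters
#'   \eqn{L_i + L_j} of the adjacent cells (one value per junction).
#' @return Numeric vector of tensions, recycled to the common length.
#' @examples
#' spec <- model_spec("anisotropic_spring", "A")
#' par <- mech_params(lambda0 = 0.2, mu0 = 0.15, lambda1 = 0.03, mu1 = 0.5, k = 1)
#' tension(spec, par, l = 1, theta = 0) # 0.185
#' @export
tension <- function(spec, params, l, theta, L_sum = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(l < 0)) abort("junction length must be non-negative", class = "epimech_domain_error")
  if (spec$family == "anisotropic_spring") {
    lam0 <- switch(spec$variant,
      A = , B = , D = aniso_coef(params$lambda0, params$mu0, params$phi0, theta),
      C = , E = rep(params$lambda0, length.out = max(length(l), length(theta)))
    )
    lam1 <- switch(spec$variant,
      A = aniso_coef(params$lambda1, params$mu1, params$phi1, theta),
      B = , C = params$lambda1,
      D = , E = 0
    )
    lam0 - lam1 * l
  } else {
    if (is.null(L_sum)) {
      abort("L_sum (summed adjacent-cell perimeters) is required for the conventional family",
            class = "epimech_config_error")
    }
    lam0 <- switch(spec$variant,
      both_aniso = , line_aniso = aniso_coef(params$lambda0, params$mu0, params$phi0, theta),
      elasticity_aniso = , isotropic = rep(params$lambda0, length.out = max(length(theta), length(L_sum)))
    )
    gam <- switch(spec$variant,
      both_aniso = , elasticity_aniso = aniso_coef(params$gamma0, params$mu_gamma, params$phi_gamma, theta),
      line_aniso = , isotropic = params$gamma0
    )
    lam0 + gam * L_sum
  }
}

#' Evaluate the cell pressure model
#'
#' @inheritParams tension
#' @param A Cell area(s), > 0.
#' @return Numeric vector of pressures.
#' @examples
#' pressure(model_spec(), mech_params(k = 1, P0 = 0), A = 1) # -1
#' @export
pressure <- function(spec, params, A) {
  if (any(A <= 0)) abort("cell area must be positive", class = "epimech_domain_error")
  switch(spec$pressure_form,
    linear = -params$k * A + params$P0,
    inverse = params$k / A + params$P0,
    exponential = params$k * exp(-A) + params$P0
  )
}

#' Linearized feature rows of the tension model
#'
#' Returns the design-matrix rows such that
#' `tension_features(...) %*% from_polar(spec, params)` reproduces
#' [tension()] exactly. For the full spring model the row is
#' \eqn{(1, \sin 2\theta, \cos 2\theta, -l, -l\sin 2\theta, -l\cos 2\theta)};
#' simpler variants drop the omitted columns. The conventional family uses
#' \eqn{(L_i + L_j)} in place of \eqn{-l}.
#'
#' @inheritParams tension
#' @return Numeric matrix, one row per junction, with coefficient names as
#'   column names (first column `lambda0`, the fixed scale).
#' @examples
#' tension_features(model_spec("anisotropic_spring", "A"), l = 2, theta = pi / 4)
#' @export
tension_features <- function(spec, l, theta, L_sum = NULL) {
  n <- max(length(l), length(theta), length(L_sum %||% 0))
  l <- rep_len(l, n); theta <- rep_len(theta, n)
  s <- sin(2 * theta); c2 <- cos(2 * theta)
  if (spec$family == "anisotropic_spring") {
    full <- cbind(lambda0 = rep(1, n), lambda0p = s, lambda0pp = c2,
                  lambda1 = -l, lambda1p = -l * s, lambda1pp = -l * c2)
  } else {
    if (is.null(L_sum)) {
      abort("L_sum is required for the conventional family", class = "epimech_config_error")
    }
    L_sum <- rep_len(L_sum, n)
    full <- cbind(lambda0 = rep(1, n), lambda0p = s, lambda0pp = c2,
                  gamma0 = L_sum, gammap = L_sum * s, gammapp = L_sum * c2)
  }
  full[, tension_coef_names(spec), drop = FALSE]
}

#' Linearized feature column of the pressure model
#'
#' The single column multiplying the coefficient \eqn{k}: \eqn{-A} (linear),
#' \eqn{1/A} (inverse), or \eqn{e^{-A}} (exponential). The basal pressure
#' \eqn{P_0} carries no column because constant pressure cancels around
#' interior vertices and is structurally unidentifiable.
#'
#' @inheritParams pressure
#' @return One-column numeric matrix named `k`.
#' @examples
#' pressure_features(model_spec(), A = 1.5) # -1.5
#' @export
pressure_features <- function(spec, A) {
  if (any(A <= 0)) abort("cell area must be positive", class = "epimech_domain_error")
  v <- switch(spec$pressure_form,
    linear = -A,
    inverse = 1 / A,
    exponential = exp(-A)
  )
  cbind(k = v)
}

#' Convert between polar parameters and linear coefficients
#'
#' The anisotropic coefficients are linear in
#' \eqn{(\lambda, \lambda', \lambda'')} with
#' \eqn{\lambda' = \lambda\mu\sin 2\varphi},
#' \eqn{\lambda'' = \lambda\mu\cos 2\varphi}. `from_polar()` produces the
#' full named coefficient vector (including the fixed `lambda0` and `k`)
#' for a parameter set; `to_polar()` inverts it, with
#' \eqn{\mu = \sqrt{\lambda'^2 + \lambda''^2}/\lambda} and
#' \eqn{\varphi = \tfrac 12 \mathrm{atan2}(\lambda', \lambda'')} folded to
#' `[0, pi)`. When \eqn{\mu = 0} the orientation is undefined and reported
#' as 0.
#'
#' @param spec A [model_spec()].
#' @param params A [mech_params()] (for `from_polar`).
#' @param coeffs Named numeric vector of linear coefficients, as produced by
#'   `from_polar()` or by a fit (for `to_polar`).
#' @return `from_polar()`: named numeric vector (tension coefficients then
#'   `k`). `to_polar()`: a [mech_params()] object.
#' @examples
#' spec <- model_spec("anisotropic_spring", "A")
#' par <- mech_params(lambda0 = 2, mu0 = 0.25, phi0 = pi / 4, lambda1 = 0.1, k = 1)
#' to_polar(spec, from_polar(spec, par))
#' @export
from_polar <- function(spec, params) {
  tn <- tension_coef_names(spec)
  co <- c(lambda0 = params$lambda0,
          lambda0p = params$lambda0 * params$mu0 * sin(2 * params$phi0),
          lambda0pp = params$lambda0 * params$mu0 * cos(2 * params$phi0),
          lambda1 = params$lambda1,
          lambda1p = params$lambda1 * params$mu1 * sin(2 * params$phi1),
          lambda1pp = params$lambda1 * params$mu1 * cos(2 * params$phi1),
          gamma0 = params$gamma0,
          gammap = params$gamma0 * params$mu_gamma * sin(2 * params$phi_gamma),
          gammapp = params$gamma0 * params$mu_gamma * cos(2 * params$phi_gamma))
  c(co[tn], k = params$k)
}

#' @rdname from_polar
#' @export
to_polar <- function(spec, coeffs) {
  g <- function(nm) if (nm %in% names(coeffs)) unname(coeffs[[nm]]) else 0
  pol <- function(base, lp, lpp) {
    if (base <= 0) {
      abort("degenerate scale: anisotropy base coefficient is not positive",
            class = "epimech_degenerate_error")
    }
    mu <- sqrt(lp^2 + lpp^2) / base
    phi <- if (mu == 0) 0 else (0.5 * atan2(lp, lpp)) %% pi
    list(mu = mu, phi = phi)
  }
  lambda0 <- g("lambda0")
  out <- list(lambda0 = lambda0, mu0 = 0, phi0 = 0, lambda1 = 0, mu1 = 0,
              phi1 = 0, gamma0 = 0, mu_gamma = 0, phi_gamma = 0,
              k = g("k"), P0 = 0, A0 = 1)
  if (any(c("lambda0p", "lambda0pp") %in% names(coeffs))) {
    p0 <- pol(lambda0, g("lambda0p"), g("lambda0pp"))
    out$mu0 <- p0$mu; out$phi0 <- p0$phi
  }
  if ("lambda1" %in% names(coeffs)) {
    out$lambda1 <- g("lambda1")
    if (any(c("lambda1p", "lambda1pp") %in% names(coeffs))) {
      p1 <- pol(out$lambda1, g("lambda1p"), g("lambda1pp"))
      out$mu1 <- p1$mu; out$phi1 <- p1$phi
    }
  }
  if ("gamma0" %in% names(coeffs)) {
    out$gamma0 <- g("gamma0")
    if (any(c("gammap", "gammapp") %in% names(coeffs))) {
      pg <- pol(out$gamma0, g("gammap"), g("gammapp"))
      out$mu_gamma <- pg$mu; out$phi_gamma <- pg$phi
    }
  }
  structure(out, class = "mech_params")
}

# serialize/deserialize the (spec, params) pair to the flat JSON config block
spec_to_config <- function(spec, params = NULL) {
  cfg <- list(model = list(family = spec$family, variant = spec$variant,
                           pressure_form = spec$pressure_form))
  if (!is.null(params)) cfg$params <- unclass(params)
  cfg
}

config_to_spec <- function(cfg) {
  spec <- model_spec(cfg$model$family, cfg$model$variant,
                     cfg$model$pressure_form %||% "linear")
  params <- if (!is.null(cfg$params)) do.call(mech_params, cfg$params) else NULL
  list(spec = spec, params = params)
}
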