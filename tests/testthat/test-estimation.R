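test_that("preprocessing applies the exclusion rules and rescaling", {
  # short-junction rule
  g <- grid_tissue(2, 2)
  g$vertices$x[g$vertices$id == 1] <- 0.3 # shorten the first bottom edge
  tp <- preprocess_tissue(g, min_junction_length = 0.5, normalize = FALSE)
  rep <- attr(tp, "preprocess")
  short_id <- junction_geometry(g)$id[junction_geometry(g)$length < 0.5]
  expect_setequal(rep$excluded_junctions, short_id)
  # oversized-cell rule: areas {1, 1, 1, 2.5}, 2 x median = 2
  w <- grid_tissue(1, 4)
  w$vertices$x[w$vertices$x == 4] <- 5.5 # widen the last cell to area 2.5
  tp2 <- preprocess_tissue(w, min_junction_length = 0, normalize = FALSE)
  expect_equal(attr(tp2, "preprocess")$excluded_cells, 3L)
  # scale normalization: median area 4 halves all coordinates
  g4 <- grid_tissue(2, 2, w = 2, h = 2)
  tp3 <- preprocess_tissue(g4, min_junction_length = 0)
  expect_equal(attr(tp3, "preprocess")$scale, 2)
  expect_equal(max(tp3$vertices$x), max(g4$vertices$x) / 2)
  expect_equal(median(cell_geometry(tp3)$area), 1)
  # all junctions excluded
  expect_error(preprocess_tissue(g, min_junction_length = 100),
               class = "epimech_empty_system_error")
})

test_that("balance-system coefficients match the printed formulas", {
  tis <- preprocess_tissue(simA_small()$tissue, normalize = FALSE)
  sys <- assemble_balance_system(tis, spec_A())
  C <- as.matrix(sys$C)
  nJ <- length(sys$junction_ids)
  # tension coefficient pairs are unit vectors: a_x^2 + a_y^2 = 1 where present
  for (r in seq(1, min(20, sys$n / 2))) {
    ax <- C[2 * r - 1, seq_len(nJ)]
    ay <- C[2 * r, seq_len(nJ)]
    nz <- which(ax != 0 | ay != 0)
    expect_true(length(nz) >= 3)
    expect_equal(unname(ax[nz]^2 + ay[nz]^2), rep(1, length(nz)),
                 tolerance = 1e-12)
    # pressure columns of a fully ringed vertex cancel in both components
    expect_equal(sum(C[2 * r - 1, -seq_len(nJ)]), 0, tolerance = 1e-12)
    expect_equal(sum(C[2 * r, -seq_len(nJ)]), 0, tolerance = 1e-12)
  }
})

test_that("pressure coefficients are half cross-differences of flanking vertices", {
  # two cells wrap a hub vertex at the origin.  In the big cell's CCW loop
  # the hub's flanking neighbours are x1 = (1,0) (previous) and x2 = (0,1)
  # (next), so b = ((y2 - y1)/2, -(x2 - x1)/2) = (0.5, 0.5); the small
  # first-quadrant cell contributes the opposite and the ring cancels.
  v <- data.frame(id = 0:6,
                  x = c(0, 1, 0, 1, -1.2, -1.2, 1),
                  y = c(0, 0, 1, 1, 1, -1.2, -1.2))
  j <- data.frame(id = 0:7,
                  v1 = c(0, 0, 1, 3, 2, 4, 5, 6),
                  v2 = c(1, 2, 3, 2, 4, 5, 6, 1))
  cl <- tibble::tibble(id = 0:1,
                       vertex_loop = list(c(0L, 1L, 3L, 2L),
                                          c(0L, 2L, 4L, 5L, 6L, 1L)))
  tis <- tissue(v, j, cl, validate = FALSE) # hub has degree 2 by design
  sys <- assemble_balance_system(tis, spec_E())
  expect_equal(sys$vertex_ids, 0L) # only the hub is interior
  C <- as.matrix(sys$C)
  nJ <- length(sys$junction_ids)
  b_big <- C[, nJ + which(sys$cell_ids == 1L)]
  expect_equal(unname(b_big), c(0.5, 0.5))
  b_small <- C[, nJ + which(sys$cell_ids == 0L)]
  expect_equal(unname(b_small), c(-0.5, -0.5))
  expect_equal(unname(rowSums(C[, (nJ + 1):(nJ + 2)])), c(0, 0),
               tolerance = 1e-15)
})

test_that("AIC evaluates its closed form and is linear in p", {
  expect_equal(aic(1 / (2 * pi), 2, 1), 6)
  expect_equal(aic(1 / (2 * pi), 10, 0), 12)
  s2 <- 0.37; n <- 57
  expect_equal(aic(s2, n, 5) - aic(s2, n, 3), 4) # 2 * delta p
  expect_error(aic(0, 10, 2), class = "epimech_domain_error")
})

test_that("fitting a constant-tension equilibrium with the full model finds it", {
  sim <- simE_small() # model E ground truth
  fit <- fit_tension_model(sim$tissue, spec_A())
  expect_lt(fit$sigma2, 1e-10)
  expect_lt(abs(fit$params$mu0), 0.02)
  expect_lt(abs(fit$params$lambda1), 0.02)
  # and the nested-model fit agrees on sigma2 ordering: richer never worse
  fitE <- fit_tension_model(sim$tissue, spec_E())
  expect_lte(fit$sigma2, fitE$sigma2 + 1e-15)
})

test_that("a regular hexagonal lattice is reported as degenerate", {
  hex <- hex_lattice_tissue(4, 4)
  expect_error(fit_tension_model(hex, spec_A()),
               class = "epimech_degenerate_error")
})

test_that("predicted tensions and pressures reproduce the fitted model", {
  fit <- fit_tension_model(simA_small()$tissue, spec_A())
  pt <- fit$predicted_tensions
  again <- tension(spec_A(), fit$params, pt$length, pt$angle)
  expect_equal(pt$tension, again, tolerance = 1e-9)
  pp <- fit$predicted_pressures
  expect_equal(pp$pressure, -fit$params$k * pp$area, tolerance = 1e-9)
  # sigma2 = F'F / n exactly
  expect_equal(fit$sigma2, sum(fit$residuals^2) / fit$n)
  expect_equal(fit$aic, aic(fit$sigma2, fit$n, fit$p))
})

test_that("closed-form least squares agrees with a brute-force minimizer", {
  tis <- preprocess_tissue(simA_small()$tissue)
  sys <- assemble_balance_system(tis, model_spec("anisotropic_spring", "B"))
  M <- sys$M; y <- M[, 1]; Mf <- M[, -1]
  beta_cf <- qr.coef(qr(Mf), -y)
  obj <- function(b) sum((y + Mf %*% b)^2)
  grad <- function(b) as.vector(2 * crossprod(Mf, y + Mf %*% b))
  opt <- optim(rep(0, ncol(Mf)), obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  expect_equal(unname(beta_cf), unname(opt$par), tolerance = 1e-8)
})

test_that("model selection recovers the generating model and breaks ties by parsimony", {
  # constant-tension data: E (1 parameter) must win over the richer variants
  selE <- select_tension_model(simE_small()$tissue, spring_specs())
  expect_equal(format(selE$best), "anisotropic_spring:E")
  # anisotropic-spring data beat every conventional variant by AIC
  selA <- select_tension_model(simA_small()$tissue,
                               c(spring_specs(), conventional_specs()))
  tab <- selA$table
  expect_equal(tab$family[which.min(tab$AIC)], "anisotropic_spring")
  expect_lt(min(tab$AIC[tab$family == "anisotropic_spring"]),
            min(tab$AIC[tab$family == "conventional"]))
  # single candidate returned trivially
  sel1 <- select_tension_model(simE_small()$tissue, list(spec_E()))
  expect_equal(format(sel1$best), "anisotropic_spring:E")
  expect_error(select_tension_model(simE_small()$tissue, list()),
               class = "epimech_config_error")
})

test_that("tension anisotropy matches analytic cases and is equivariant", {
  th <- seq(0, pi, length.out = 2001)[-2001]
  # constant tension: the two averages factor, R_T = 0
  a0 <- tension_anisotropy(rep(2, length(th)), th)
  expect_equal(a0$R_T, 0, tolerance = 1e-12)
  # T = 1 + cos 2 theta over uniform angles: R_T -> 1/2, Theta -> 0
  a1 <- tension_anisotropy(1 + cos(2 * th), th)
  expect_equal(a1$R_T, 0.5, tolerance = 1e-3)
  expect_lt(min(a1$Theta %% pi, pi - a1$Theta %% pi), 1e-6)
  # rotating all angles by delta rotates Theta, R_T invariant
  delta <- 0.7
  a2 <- tension_anisotropy(1 + cos(2 * th), th + delta)
  expect_equal(a2$R_T, a1$R_T, tolerance = 1e-9)
  expect_equal(a2$Theta, (a1$Theta + delta) %% pi, tolerance = 1e-6)
  expect_error(tension_anisotropy(numeric(0), numeric(0)),
               class = "epimech_domain_error")
})

test_that("standard errors follow least-squares algebra", {
  # near-noiseless equilibrium: tiny standard errors
  fitC <- fit_tension_model(simC_conv()$tissue,
                            model_spec("conventional", "isotropic"))
  seC <- standard_errors(fitC)
  expect_true(all(seC$std_error < 1e-10))
  # duplicating every equation leaves the estimate unchanged and scales
  # the standard errors by 1/sqrt(2) (sigma2 is unchanged, X'X doubles)
  tis <- preprocess_tissue(simA_small()$tissue)
  sys <- assemble_balance_system(tis, spec_A())
  y <- sys$M[, 1]; Mf <- sys$M[, -1]
  beta <- qr.coef(qr(Mf), -y)
  s2 <- sum((y + Mf %*% beta)^2) / length(y)
  se1 <- epimech:::fit_standard_errors(Mf, s2, beta, spec_A())
  M2 <- rbind(Mf, Mf); y2 <- c(y, y)
  beta2 <- qr.coef(qr(M2), -y2)
  s2b <- sum((y2 + M2 %*% beta2)^2) / length(y2)
  expect_equal(unname(beta2), unname(beta), tolerance = 1e-10)
  se2 <- epimech:::fit_standard_errors(M2, s2b, beta2, spec_A())
  expect_equal(se2$std_error, se1$std_error / sqrt(2), tolerance = 1e-8)
})

test_that("95% intervals cover the true anisotropies on simulated data", {
  fit <- fit_tension_model(simA_small()$tissue, spec_A())
  se <- standard_errors(fit)
  mu0 <- se[se$term == "mu0", ]
  mu1 <- se[se$term == "mu1", ]
  expect_true(mu0$conf_low <= ref_par()$mu0 && ref_par()$mu0 <= mu0$conf_high)
  expect_true(mu1$conf_low <= ref_par()$mu1 && ref_par()$mu1 <= mu1$conf_high)
})

test_that("normalization by the pressure modulus gives dimensionless estimates", {
  fake <- structure(list(params = mech_params(lambda0 = 1, lambda1 = 0.06, k = 2),
                         coefficients = c(lambda0 = 1, lambda1 = 0.06, k = 2),
                         scale = 1),
                    class = "tension_fit")
  ne <- normalize_estimates(fake, A0 = 1)
  expect_equal(ne$estimate[ne$term == "lambda1"], 0.03)
  expect_equal(ne$estimate[ne$term == "lambda0"], 0.5)
  fake2 <- structure(list(params = mech_params(lambda0 = 8, k = 1),
                          coefficients = c(lambda0 = 8, k = 1), scale = 1),
                     class = "tension_fit")
  expect_equal(normalize_estimates(fake2, A0 = 4)$estimate[1], 1) # 8 / 4^1.5
  expect_error(normalize_estimates(fake, k_hat = -1),
               class = "epimech_domain_error")
})

test_that("normalized estimates are invariant to a global coordinate scale", {
  tis <- simA_small()$tissue
  fit1 <- fit_tension_model(tis, spec_A())
  tis2 <- tis
  tis2$vertices$x <- tis$vertices$x * 3.7
  tis2$vertices$y <- tis$vertices$y * 3.7
  tis2$meta$A0 <- tis$meta$A0 * 3.7^2 # metadata follows the unit change
  fit2 <- fit_tension_model(tis2, spec_A())
  # A0 is expressed in each tissue's own units; rescaling the data by c
  # rescales areas by c^2 and the normalization divides c back out
  n1 <- normalize_estimates(fit1, A0 = 1)
  n2 <- normalize_estimates(fit2, A0 = 3.7^2)
  expect_equal(n1$estimate, n2$estimate, tolerance = 1e-8)
})

test_that("tidy and glance methods expose the fit in broom style", {
  fit <- fit_tension_model(simA_small()$tissue, spec_A())
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$p, 6L)
  expect_equal(gl$AIC, fit$aic)
  sel <- select_tension_model(simE_small()$tissue, spring_specs())
  expect_equal(nrow(tidy(sel)), 5)
  expect_equal(glance(sel)$best, "anisotropic_spring:E")
})
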