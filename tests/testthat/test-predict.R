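test_that("closed-form BLUP reproduces textbook shrinkage", {
  # K = I, equal variances, centered y: halve everything
  y <- c(a = 1, b = -1, c = 0)
  I3 <- diag(3) + 0
  dimnames(I3) <- list(names(y), names(y))
  K <- kernel_matrix(I3, kind = "additive")
  out <- gblup_closed_form(y, list(A = K),
                           c(A = 1, residual = 1))
  expect_equal(unname(out$u[, "A"]), c(0.5, -0.5, 0), tolerance = 1e-10)
  # vanishing genetic variance: predictions collapse to the intercept
  out0 <- gblup_closed_form(y, list(A = K), c(A = 1e-12, residual = 1))
  expect_lt(max(abs(out0$table$predicted_total - out0$mu)), 1e-9)
  expect_error(gblup_closed_form(y, list(A = K), c(A = -1, residual = 1)),
               "positive")
})

test_that("GBLUP predictions equal ridge regression at the matched penalty", {
  set.seed(42)
  n <- 100
  m <- 500
  G <- random_geno(n, m, seed = 42)
  M <- unclass(G)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  M <- M[, keep]
  y <- setNames(rnorm(n, 50, 2), rownames(M))
  train <- rownames(M)[1:70]
  y_fit <- y
  y_fit[!names(y) %in% train] <- NA
  K <- vanraden_g(M)
  s2g <- 1.3
  s2e <- 0.9
  out <- gblup_closed_form(y_fit, list(A = K), c(A = s2g, residual = s2e))
  # matched penalty: marker-effect variance s2g/denom -> lambda = s2e*denom/s2g
  denom <- 2 * sum(colMeans(M) / 2 * (1 - colMeans(M) / 2))
  lambda <- s2e * denom / s2g
  u_ridge <- ridge_genetic_values(M, y[train] - out$mu,
                                  match(train, rownames(M)), lambda)
  expect_lt(max(abs(out$u[, "A"] - u_ridge)), 1e-8)
})

test_that("Gibbs sampler is seed-reproducible and matches the oracle at fixed variances", {
  set.seed(3)
  n <- 60
  G <- random_geno(n, 80, seed = 3)
  K <- normalize_kernel(vanraden_g(G))
  truth <- drop(unclass(K) %*% rnorm(n, 0, 0.5))
  y <- setNames(truth + rnorm(n, 0, 0.7), rownames(G))
  y[55:60] <- NA
  mc <- mcmc_config(n_iter = 1500, burn_in = 500, thin = 2, seed = 9)
  fit1 <- fit_multikernel(y, list(A = K), mc,
                          fix_variances = c(A = 0.8, residual = 0.5))
  fit2 <- fit_multikernel(y, list(A = K), mc,
                          fix_variances = c(A = 0.8, residual = 0.5))
  expect_identical(fit1$g_mean, fit2$g_mean)
  expect_identical(fit1$var_chain, fit2$var_chain)
  oracle <- gblup_closed_form(y, list(A = K), c(A = 0.8, residual = 0.5))
  expect_lt(max(abs(fit1$g_mean - oracle$g_total)), 0.12)
  expect_gt(cor(fit1$g_mean, oracle$g_total), 0.995)
})

test_that("posterior heritability recovers a simulated h2 of one half", {
  set.seed(8)
  n <- 300
  g <- rnorm(n, 0, 1)
  y <- setNames(g + rnorm(n, 0, 1), paste0("l", 1:n))
  I <- diag(n) + 0
  dimnames(I) <- list(names(y), names(y))
  K <- kernel_matrix(I, kind = "additive")
  fit <- fit_multikernel(y, list(A = K),
                         mcmc_config(n_iter = 2500, burn_in = 500, thin = 2,
                                     seed = 4))
  h2 <- fit$var_mean[["A"]] / (fit$var_mean[["A"]] + fit$var_mean[["residual"]])
  expect_gt(h2, 0.4)
  expect_lt(h2, 0.6)
  # fitted variance roughly reconstructs the sample variance of y
  expect_equal(sum(fit$var_mean), var(y), tolerance = 0.25)
})

test_that("degenerate signals concentrate the posterior near the prior floor", {
  y <- setNames(rep(5, 30), paste0("l", 1:30))
  I <- diag(30) + 0
  dimnames(I) <- list(names(y), names(y))
  K <- kernel_matrix(I, kind = "additive")
  fit <- suppressWarnings(
    fit_multikernel(y, list(A = K),
                    mcmc_config(n_iter = 600, burn_in = 200, thin = 2,
                                seed = 1)))
  expect_lt(fit$var_mean[["A"]], 1e-4)
  expect_lt(max(abs(fit$g_mean)), 0.05)
  expect_equal(fit$mu_mean, 5, tolerance = 0.01)
})

test_that("prediction views satisfy the accounting identities", {
  set.seed(5)
  G <- random_geno(40, 60, seed = 5)
  map <- map_for(G, 6)
  y <- setNames(rnorm(40, 50, 1.5), rownames(G))
  ks <- model_kernel_sets("A+E", unclass(G), map)
  fit <- suppressWarnings(
    fit_multikernel(y, ks$kernels,
                    mcmc_config(n_iter = 800, burn_in = 300, thin = 2,
                                seed = 2)))
  pred <- predict_genetic_values(fit, "total", observed = y)
  # total - additive = epistatic component, exactly
  epi <- fit$u_mean[, "E"]
  expect_equal(pred$predicted_total - pred$predicted_additive, unname(epi))
  # model A: additive and total views coincide
  ksA <- model_kernel_sets("A", unclass(G), map)
  fitA <- suppressWarnings(
    fit_multikernel(y, ksA$kernels,
                    mcmc_config(n_iter = 600, burn_in = 200, thin = 2,
                                seed = 2)))
  pA <- predict_genetic_values(fitA, "total")
  expect_equal(pA$predicted_total, pA$predicted_additive)
  expect_error(predict_genetic_values(fit, "everything"), "arg")
})

test_that("prediction ability is the plain product-moment correlation", {
  expect_equal(prediction_ability(1:5, 1:5), 1)
  expect_equal(prediction_ability(1:5, -(1:5)), -1)
  expect_equal(prediction_ability(c(2, 4, 6), c(1, 2, 3)), 1)
  expect_error(prediction_ability(c(1, 1, 1), 1:3), "zero variance")
  expect_error(prediction_ability(1:2, 1:2), "at least 3")
})

test_that("modelling epistasis helps predict an epistatic trait", {
  map <- make_genome_map(3, 15)
  cfg <- sim_config(n_series = 2, lines_per_series = 120,
                    markers_per_panel = 135, n_chrom_per_subgenome = 3,
                    n_qtl_additive = 40, n_qtl_pairs_epistatic = 60,
                    sigma2_A = 0.4, sigma2_E = 1.2, seed = 15)
  sim <- simulate_series_genotypes(map, cfg)
  truth <- simulate_genetic_values(sim$true_codes, map, cfg)
  tt <- setNames(truth$true_total, truth$genotype_id)
  y <- setNames(tt + rnorm(length(tt), 0, 0.5), names(tt))
  test_ids <- names(y)[201:240]
  y_fit <- y
  y_fit[test_ids] <- NA
  mc <- mcmc_config(n_iter = 1200, burn_in = 400, thin = 2, seed = 3)
  pa_of <- function(model) {
    ks <- model_kernel_sets(model, sim$true_codes, map)
    fit <- suppressWarnings(fit_multikernel(y_fit, ks$kernels, mc))
    pred <- predict_genetic_values(fit, "total")
    prediction_ability(pred$predicted_total[match(test_ids, pred$genotype_id)],
                       tt[test_ids])
  }
  expect_gt(pa_of("A+E"), pa_of("A"))
})
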