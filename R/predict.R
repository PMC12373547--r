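#' MCMC settings for the multi-kernel sampler
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before summarizing.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param df0 prior degrees of freedom of every scaled-inverse-chi-squared
#'   variance prior.
#' @param seed RNG seed for the chain.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 6000, burn_in = 1000, thin = 5, df0 = 5,
                        seed = 1) {
  if (burn_in >= n_iter) stop_invalid("burn_in must be smaller than n_iter")
  if (thin < 1) stop_invalid("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), df0 = df0, seed = as.integer(seed)),
            class = "mcmc_config")
}

# Effective sample size from the initial-positive autocorrelation sum.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(rho)))
}

#' Fit a multi-kernel GBLUP by Gibbs sampling
#'
#' Bayesian mixed model `y = mu + sum_k u_k + e` with
#' `u_k ~ N(0, K_k sigma2_k)` and scaled-inverse-chi-squared priors on all
#' variances. Each kernel is eigendecomposed once; genetic values are
#' updated blockwise on the eigenbasis, where the conditional posterior is
#' diagonal. Lines with missing `y` are handled by data augmentation and
#' receive predictions through the joint kernel covariance.
#'
#' By default the prior scales split half the sample variance of the
#' observed `y` equally among the kernels, the other half going to the
#' residual.
#'
#' @param y named numeric vector over lines; `NA` marks lines to predict.
#' @param kernels named list of [kernel_matrix] objects covering all lines
#'   of `y` (e.g. the `kernels` element of [model_kernel_sets()]).
#' @param mcmc an [mcmc_config()].
#' @param fix_variances optional named vector (kernel names plus
#'   `"residual"`); when given, variance components are held fixed and only
#'   genetic values are sampled (deterministic-variance oracle mode).
#' @param keep_g_chain store the thinned chain of total genetic values
#'   (needed for Monte-Carlo standard errors).
#' @return an object of class `mk_fit` with posterior means/SDs of `mu` and
#'   the variance components, posterior-mean genetic values per kernel
#'   (`u_mean`), total genetic values (`g_mean`), effective sample sizes and
#'   the thinned variance chains.
#' @export
fit_multikernel <- function(y, kernels, mcmc = mcmc_config(),
                            fix_variances = NULL, keep_g_chain = FALSE) {
  stopifnot(is.numeric(y), !is.null(names(y)), length(kernels) >= 1L)
  if (is.null(names(kernels))) {
    names(kernels) <- paste0("K", seq_along(kernels))
  }
  lines <- names(y)
  n <- length(y)
  obs <- which(!is.na(y))
  if (length(obs) < 3L) stop_invalid("need at least 3 observed lines")
  eig <- lapply(kernels, function(K) {
    K <- unclass(K)
    if (!all(lines %in% rownames(K))) {
      stop_invalid("kernel does not cover all lines of y")
    }
    e <- eigen(K[lines, lines], symmetric = TRUE)
    keep <- e$values > 1e-8 * max(e$values, 1e-12)
    if (!any(keep)) stop_invalid("kernel is numerically zero")
    if (min(e$values) < -1e-6 * max(e$values)) {
      stop_invalid("kernel has a substantially negative eigenvalue")
    }
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  nk <- length(kernels)
  kn <- names(kernels)
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1e-6
  df0 <- mcmc$df0
  fixed <- !is.null(fix_variances)
  if (fixed) {
    s2 <- fix_variances[kn]
    s2e <- fix_variances[["residual"]]
    if (anyNA(s2) || is.na(s2e)) {
      stop_invalid("fix_variances must name every kernel and 'residual'")
    }
    S0 <- NULL; S0e <- NULL
  } else {
    # prior expectation: half of var(y) split equally among kernels,
    # the other half to the residual (scaled-inv-chi2 mean df*S/(df-2))
    S0 <- rep((vy / 2 / nk) * (df0 - 2) / df0, nk)
    S0e <- (vy / 2) * (df0 - 2) / df0
    s2 <- rep(vy / 2 / nk, nk)
    s2e <- vy / 2
  }
  n_samples <- floor((mcmc$n_iter - mcmc$burn_in) / mcmc$thin)
  with_seed(mcmc$seed, {
    mu <- mean(y[obs])
    y_aug <- y
    y_aug[-obs] <- mu
    u <- matrix(0, n, nk)
    alpha <- lapply(eig, function(e) numeric(length(e$d)))
    var_chain <- matrix(NA_real_, n_samples, nk + 1,
                        dimnames = list(NULL, c(kn, "residual")))
    mu_chain <- numeric(n_samples)
    u_sum <- matrix(0, n, nk)
    g_chain <- if (keep_g_chain) matrix(NA_real_, n, n_samples) else NULL
    s_idx <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      g_tot <- rowSums(u)
      for (k in seq_len(nk)) {
        r <- y_aug - mu - (g_tot - u[, k])
        rt <- crossprod(eig[[k]]$U, r)
        post_var <- 1 / (1 / s2e + 1 / (eig[[k]]$d * s2[k]))
        post_mean <- post_var * rt / s2e
        alpha[[k]] <- stats::rnorm(length(post_mean), post_mean,
                                   sqrt(post_var))
        u[, k] <- drop(eig[[k]]$U %*% alpha[[k]])
        g_tot <- rowSums(u)
        if (!fixed) {
          ssk <- sum(alpha[[k]]^2 / eig[[k]]$d)
          mk <- length(alpha[[k]])
          s2[k] <- (ssk + df0 * S0[k]) / stats::rchisq(1, df0 + mk)
        }
      }
      r <- y_aug - g_tot
      mu <- stats::rnorm(1, mean(r), sqrt(s2e / n))
      e <- y_aug - mu - g_tot
      if (!fixed) {
        s2e <- (sum(e^2) + df0 * S0e) / stats::rchisq(1, df0 + n)
      }
      if (length(obs) < n) {
        miss <- setdiff(seq_len(n), obs)
        y_aug[miss] <- mu + g_tot[miss] +
          stats::rnorm(length(miss), 0, sqrt(s2e))
      }
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        s_idx <- s_idx + 1L
        var_chain[s_idx, ] <- c(s2, s2e)
        mu_chain[s_idx] <- mu
        u_sum <- u_sum + u
        if (keep_g_chain) g_chain[, s_idx] <- g_tot
      }
    }
    u_mean <- u_sum / s_idx
    dimnames(u_mean) <- list(lines, kn)
    g_mean <- rowSums(u_mean)
    ess_v <- apply(var_chain, 2, ess)
    if (!fixed && any(ess_v < 100)) {
      warning(sprintf("low effective sample size (< 100) for: %s",
                      paste(names(ess_v)[ess_v < 100], collapse = ", ")))
    }
    structure(list(
      mu_mean = mean(mu_chain), mu_sd = stats::sd(mu_chain),
      var_mean = colMeans(var_chain), var_sd = apply(var_chain, 2, stats::sd),
      var_chain = var_chain, mu_chain = mu_chain,
      u_mean = u_mean, g_mean = stats::setNames(g_mean, lines),
      g_chain = g_chain, ess = ess_v,
      line_ids = lines, observed = lines[obs],
      kernel_names = kn, kernel_kinds = vapply(kernels, kernel_kind,
                                               character(1)),
      mcmc = mcmc, fixed_variances = fixed
    ), class = "mk_fit")
  })
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("multi-kernel GBLUP fit: %d lines (%d observed), %d kernels\n",
              length(x$line_ids), length(x$observed),
              length(x$kernel_names)))
  vm <- x$var_mean
  cat("posterior mean variances:\n")
  for (k in names(vm)) cat(sprintf("  %-12s %.4f\n", k, vm[[k]]))
  invisible(x)
}

#' Closed-form multi-kernel BLUP at fixed variances
#'
#' Deterministic mixed-model solution used as the oracle for the Gibbs
#' sampler: with `V = sum_k sigma2_k K_k + sigma2_e I` on observed lines,
#' the intercept is the GLS mean and each component is
#' `u_k = sigma2_k K_k[, obs] V^{-1} (y_obs - mu)`, evaluated for all lines
#' (so unphenotyped lines are predicted through the joint covariance).
#'
#' @param y named numeric vector; `NA` marks lines to predict.
#' @param kernels named list of [kernel_matrix] objects.
#' @param variances named vector of kernel variances plus `"residual"`.
#' @return `list(mu, u, g_total, table)` where `u` is lines x kernels and
#'   `table` a [prediction table][predict_genetic_values].
#' @export
gblup_closed_form <- function(y, kernels, variances) {
  stopifnot(!is.null(names(y)))
  if (is.null(names(kernels))) names(kernels) <- paste0("K", seq_along(kernels))
  kn <- names(kernels)
  s2 <- variances[kn]
  s2e <- variances[["residual"]]
  if (anyNA(s2) || is.na(s2e) || any(c(s2, s2e) <= 0)) {
    stop_invalid("variances must be positive and name every kernel and 'residual'")
  }
  lines <- names(y)
  obs <- which(!is.na(y))
  Ks <- lapply(kernels, function(K) unclass(K)[lines, lines])
  V <- diag(s2e, length(obs))
  for (k in seq_along(Ks)) V <- V + s2[k] * Ks[[k]][obs, obs]
  ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop_invalid("summed covariance is not positive definite")
  Vi <- solve(V)
  one <- rep(1, length(obs))
  mu <- drop(crossprod(one, Vi %*% y[obs]) / crossprod(one, Vi %*% one))
  w <- Vi %*% (y[obs] - mu)
  u <- vapply(seq_along(Ks), function(k) {
    drop(s2[k] * Ks[[k]][, obs] %*% w)
  }, numeric(length(lines)))
  dimnames(u) <- list(lines, kn)
  g_total <- rowSums(u)
  kinds <- vapply(kernels, kernel_kind, character(1))
  add <- rowSums(u[, kinds == "additive", drop = FALSE])
  table <- data.frame(genotype_id = lines,
                      predicted_additive = mu + add,
                      predicted_total = mu + g_total,
                      observed = unname(y),
                      stringsAsFactors = FALSE)
  list(mu = mu, u = u, g_total = stats::setNames(g_total, lines),
       table = table)
}

#' Extract predicted genetic values from a fit
#'
#' `total` (the default, recommended for variety selection) sums all kernel
#' components; `additive` keeps only additive-kernel components (the view
#' relevant for parental selection, since epistatic deviations are not
#' transmitted).
#'
#' @param fit an `mk_fit` from [fit_multikernel()].
#' @param which `"total"` or `"additive"`.
#' @param observed optional named vector of observed values to attach.
#' @return a `data.frame` with `genotype_id`, `predicted_additive`,
#'   `predicted_total`, `predicted` (the selected view, intercept added) and
#'   `observed`.
#' @export
predict_genetic_values <- function(fit, which = c("total", "additive"),
                                   observed = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "mk_fit"))
  add <- rowSums(fit$u_mean[, fit$kernel_kinds == "additive", drop = FALSE])
  tot <- fit$g_mean
  obs <- rep(NA_real_, length(fit$line_ids))
  if (!is.null(observed)) {
    obs <- unname(observed[fit$line_ids])
  }
  out <- data.frame(
    genotype_id = fit$line_ids,
    predicted_additive = fit$mu_mean + add,
    predicted_total = fit$mu_mean + tot,
    observed = obs,
    stringsAsFactors = FALSE
  )
  out$predicted <- if (which == "total") out$predicted_total else
    out$predicted_additive
  out
}

#' Prediction ability
#'
#' Product-moment correlation between predicted and observed values over
#' pairs where both are finite.
#'
#' @param pred,obs numeric vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
prediction_ability <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 3L) stop_invalid("need at least 3 paired finite values")
  if (stats::var(pred[ok]) == 0 || stats::var(obs[ok]) == 0) {
    stop_invalid("prediction ability undefined: zero variance")
  }
  stats::cor(pred[ok], obs[ok])
}
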