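#' Within-environment BLUEs (stage 1)
#'
#' Fits the plot-level mixed model for one environment: genotype fixed (so
#' BLUEs stay on the trait scale), trial, replicate-within-trial and
#' block-within-replicate random, variance components by REML (lme4).
#' Random terms whose grouping factor has a single level in the environment
#' are dropped automatically. Residuals are screened with the
#' Bonferroni-Holm / re-scaled-MAD procedure ([detect_outliers_bh_madr()]);
#' flagged plots are set missing and the model refit once.
#'
#' @param plots plot table `data.frame` with columns `genotype_id`,
#'   `environment_id`, `trial_id`, `rep_id`, `block_id`, `value`.
#' @param environment environment id to analyse.
#' @param alpha family-wise level of the outlier test.
#' @param correct_outliers apply the outlier correction (default TRUE).
#' @return an object of class `stage1_fit`: `list(blues, flagged,
#'   dropped_terms, model)` where `blues` has columns `genotype_id`,
#'   `environment_id`, `blue`, `se`, `n_plots`, and `flagged` gives the row
#'   indices (within the environment's plots) set missing.
#' @export
fit_stage1_blues <- function(plots, environment, alpha = 0.05,
                             correct_outliers = TRUE) {
  d <- plots[plots$environment_id == environment & !is.na(plots$value), ,
             drop = FALSE]
  if (nrow(d) == 0L) {
    stop_invalid("no plots with values in environment '%s'", environment)
  }
  if (length(unique(d$genotype_id)) < 2L) {
    stop_invalid("need >= 2 genotypes in environment '%s'", environment)
  }
  d$genotype_id <- factor(d$genotype_id)
  d$.trial <- factor(d$trial_id)
  d$.rep <- factor(paste(d$trial_id, d$rep_id, sep = ":"))
  d$.block <- factor(paste(d$trial_id, d$rep_id, d$block_id, sep = ":"))
  terms <- c()
  dropped <- c()
  for (t in c(".trial", ".rep", ".block")) {
    if (nlevels(d[[t]]) > 1L) terms <- c(terms, t) else dropped <- c(dropped, t)
  }
  fit_once <- function(dd) {
    if (length(terms) == 0L) {
      stats::lm(value ~ 0 + genotype_id, data = dd)
    } else {
      f <- stats::as.formula(paste("value ~ 0 + genotype_id +",
                                   paste(sprintf("(1 | %s)", terms),
                                         collapse = " + ")))
      lme4::lmer(f, data = dd, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    }
  }
  flagged <- integer(0)
  if (correct_outliers && nrow(d) >= 4L) {
    # screening model with genotype random: shrinkage keeps a gross outlier
    # in its own residual instead of splitting it across the genotype's
    # replicate plots
    f_scr <- stats::as.formula(paste(
      "value ~ 1 +",
      paste(sprintf("(1 | %s)", c("genotype_id", terms)), collapse = " + ")))
    scr <- lme4::lmer(f_scr, data = d, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore", calc.derivs = FALSE))
    flagged <- detect_outliers_bh_madr(stats::residuals(scr), alpha = alpha)
    if (length(flagged)) {
      d2 <- d[-flagged, , drop = FALSE]
      d2$genotype_id <- droplevels(d2$genotype_id)
      d <- d2
    }
  }
  fit <- fit_once(d)
  cf <- if (inherits(fit, "lm")) stats::coef(fit) else lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  gnames <- sub("^genotype_id", "", names(cf))
  np <- table(as.character(d$genotype_id))[gnames]
  blues <- data.frame(genotype_id = gnames,
                      environment_id = environment,
                      blue = unname(cf),
                      se = unname(se),
                      n_plots = as.integer(np),
                      stringsAsFactors = FALSE)
  structure(list(blues = blues, flagged = flagged,
                 dropped_terms = sub("^\\.", "", dropped), model = fit),
            class = "stage1_fit")
}

#' Stage-1 BLUEs for every environment
#'
#' @inheritParams fit_stage1_blues
#' @param environments environments to analyse (default: all in `plots`).
#' @return `list(blues =, flagged =)`: the row-bound BLUE table and a
#'   `data.frame` of flagged plots (`environment_id`, plot row index within
#'   the environment).
#' @export
fit_stage1_all <- function(plots, environments = NULL, alpha = 0.05,
                           correct_outliers = TRUE) {
  environments <- environments %||% unique(plots$environment_id)
  out <- lapply(environments, function(e) {
    suppressMessages(fit_stage1_blues(plots, e, alpha = alpha,
                                      correct_outliers = correct_outliers))
  })
  flagged <- do.call(rbind, lapply(seq_along(out), function(i) {
    if (length(out[[i]]$flagged) == 0L) return(NULL)
    data.frame(environment_id = environments[i], plot_row = out[[i]]$flagged,
               stringsAsFactors = FALSE)
  }))
  list(blues = do.call(rbind, lapply(out, `[[`, "blues")),
       flagged = flagged)
}

#' Outlier detection: Bonferroni-Holm on re-scaled MAD residuals
#'
#' Residuals are standardized as `(r - median) / (1.4826 * MAD)`, converted
#' to two-sided normal p-values and tested with the Bonferroni-Holm
#' procedure at family-wise level `alpha`.
#'
#' @param residuals numeric vector (>= 4 values).
#' @param alpha family-wise error level.
#' @return integer indices of flagged residuals; empty (with a warning) when
#'   the MAD is zero.
#' @export
detect_outliers_bh_madr <- function(residuals, alpha = 0.05) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 4L) stop_invalid("need at least 4 residuals")
  md <- stats::mad(residuals)  # already includes the 1.4826 rescaling
  if (md == 0) {
    warning("MAD of residuals is zero; no standardization possible")
    return(integer(0))
  }
  z <- (residuals - stats::median(residuals)) / md
  p <- 2 * stats::pnorm(-abs(z))
  which(stats::p.adjust(p, method = "holm") <= alpha)
}

#' Across-environment BLUPs and reliability (stage 2)
#'
#' Fits the unweighted second-stage model on the within-environment BLUEs:
#' intercept plus random genotype, random environment and residual, REML via
#' lme4. Returns genotype BLUPs, variance components, the average number of
#' environments per genotype and the reliability (broad-sense heritability)
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / N_env)`.
#'
#' @param blues BLUE table (`genotype_id`, `environment_id`, `blue`).
#' @param n_env_mean `"arithmetic"` (default) or `"harmonic"` mean number of
#'   environments per genotype.
#' @return an object of class `stage2_result`: `list(blups, mu, sigma2_g,
#'   sigma2_env, sigma2_eps, N_env, H2, model)`; `blups` is a named vector
#'   of genotype deviations (mean approximately zero).
#' @export
fit_stage2_blups <- function(blues, n_env_mean = c("arithmetic", "harmonic")) {
  n_env_mean <- match.arg(n_env_mean)
  d <- blues[!is.na(blues$blue), , drop = FALSE]
  if (length(unique(d$genotype_id)) < 2L || length(unique(d$environment_id)) < 2L) {
    stop_invalid("stage 2 needs >= 2 genotypes and >= 2 environments")
  }
  inc <- table(d$genotype_id, d$environment_id) > 0
  # connectivity warning: environments sharing no genotype make components
  # estimable only within connected sets
  adj <- crossprod(inc * 1) > 0
  comp <- rep(0L, ncol(adj))
  cur <- 0L
  for (s in seq_along(comp)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    front <- s
    while (length(front)) {
      comp[front] <- cur
      front <- which(comp == 0L & colSums(adj[front, , drop = FALSE]) > 0)
    }
  }
  if (cur > 1L) {
    warning(sprintf("genotype x environment incidence has %d disconnected sets",
                    cur))
  }
  d$genotype_id <- factor(d$genotype_id)
  d$environment_id <- factor(d$environment_id)
  fit <- lme4::lmer(blue ~ (1 | genotype_id) + (1 | environment_id),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  sigma2_g <- getv("genotype_id")
  sigma2_env <- getv("environment_id")
  sigma2_eps <- getv("Residual")
  env_per_g <- rowSums(inc)
  N_env <- if (n_env_mean == "arithmetic") {
    mean(env_per_g)
  } else {
    1 / mean(1 / env_per_g)
  }
  H2 <- if (sigma2_g + sigma2_eps > 0) {
    heritability(sigma2_g, sigma2_eps, N_env)
  } else {
    NA_real_
  }
  re <- lme4::ranef(fit)$genotype_id
  blups <- stats::setNames(re[["(Intercept)"]], rownames(re))
  structure(list(blups = blups, mu = unname(lme4::fixef(fit)[1]),
                 sigma2_g = sigma2_g, sigma2_env = sigma2_env,
                 sigma2_eps = sigma2_eps, N_env = N_env, H2 = H2,
                 model = fit),
            class = "stage2_result")
}

#' @export
print.stage2_result <- function(x, ...) {
  cat(sprintf(paste0("stage-2 fit: %d genotypes, sigma2_g = %.3f, ",
                     "sigma2_env = %.3f, sigma2_eps = %.3f, N_env = %.2f, ",
                     "H2 = %.3f\n"),
              length(x$blups), x$sigma2_g, x$sigma2_env, x$sigma2_eps,
              x$N_env, x$H2))
  invisible(x)
}

#' Reliability (broad-sense heritability) on an entry-mean basis
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_eps / n_env)`, the squared accuracy
#' ceiling used as the empirical upper bound of prediction ability (via its
#' square root).
#'
#' @param sigma2_g genotypic variance (>= 0).
#' @param sigma2_eps residual variance of the stage-2 model (>= 0).
#' @param n_env average number of environments per genotype (> 0).
#' @return a value in `[0, 1]`.
#' @export
heritability <- function(sigma2_g, sigma2_eps, n_env) {
  if (sigma2_g < 0 || sigma2_eps < 0 || n_env <= 0) {
    stop_invalid("variances must be >= 0 and n_env > 0")
  }
  if (sigma2_g + sigma2_eps == 0) {
    stop_invalid("heritability undefined when both variances are zero")
  }
  sigma2_g / (sigma2_g + sigma2_eps / n_env)
}
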