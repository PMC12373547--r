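#' Simulate a complete multi-series study bundle
#'
#' End-to-end glue for validation studies: simulates several partially
#' connected training series plus a deeply replicated, high-reliability test
#' series (the post-registration-trial analogue), runs the two-stage
#' phenotypic analysis, merges and QC-filters the marker panels, and imputes
#' dosages, returning everything downstream scenarios need.
#'
#' @param config a [sim_config()] describing the training series.
#' @param markers_per_chrom markers per chromosome of the genome map.
#' @param test_lines number of lines in the test series.
#' @param test_panel panel size of the test series (default: largest
#'   training panel).
#' @param n_env_train environments per training series.
#' @param n_env_test environments of the test series (many, so its
#'   reliability is high).
#' @param n_trials_per_env,n_rep,n_blocks field layout of training trials.
#' @param placement epistatic-pair placement (see
#'   [simulate_genetic_values()]).
#' @param maf_min,na_max QC thresholds applied to the merged panel before
#'   imputation.
#' @param impute_method `"mean"` or `"knn"`.
#' @return an object of class `gp_bundle`: list with `map`, `geno_raw`
#'   (merged + structural filters), `geno` (QC-filtered, imputed), `truth`,
#'   `plots`, `outlier_rows`, `blues`, `membership`, `env_series`,
#'   `test_series`, `test_ids`, `test_obs` (named observed test values),
#'   `train_ids`, and the config.
#' @export
simulate_study <- function(config = sim_config(),
                           markers_per_chrom = 20,
                           test_lines = 60,
                           test_panel = NULL,
                           n_env_train = 4,
                           n_env_test = 30,
                           n_trials_per_env = 2,
                           n_rep = 2,
                           n_blocks = 2,
                           placement = "genome",
                           maf_min = 0.05,
                           na_max = 0.8,
                           impute_method = "mean") {
  map <- make_genome_map(config$n_chrom_per_subgenome, markers_per_chrom)
  cfg2 <- config
  cfg2$n_series <- config$n_series + 1L
  cfg2$lines_per_series <- c(config$lines_per_series, as.integer(test_lines))
  cfg2$markers_per_panel <- c(config$markers_per_panel,
                              as.integer(test_panel %||%
                                           max(config$markers_per_panel)))
  # checks connect the training series only; the test series stands apart
  sim <- simulate_series_genotypes(map, cfg2,
                                   check_series = seq_len(config$n_series))
  test_series <- paste0("S", cfg2$n_series)
  truth <- simulate_genetic_values(sim$true_codes, map, cfg2,
                                   placement = placement)
  designs <- list()
  for (s in seq_len(config$n_series)) {
    sname <- paste0("S", s)
    g <- sim$membership$genotype_id[sim$membership$series == sname]
    designs[[s]] <- trial_design(g, n_env = n_env_train,
                                 n_trials_per_env = n_trials_per_env,
                                 n_rep = n_rep, n_blocks = n_blocks,
                                 env_prefix = paste0(sname, "_E"),
                                 series_id = sname)
  }
  g_test <- sim$membership$genotype_id[sim$membership$series == test_series]
  designs[[config$n_series + 1L]] <-
    trial_design(g_test, n_env = n_env_test, n_trials_per_env = 1,
                 n_rep = 2, n_blocks = 1,
                 env_prefix = paste0(test_series, "_E"),
                 series_id = test_series)
  design <- do.call(rbind, designs)
  tr <- simulate_trials(truth, design, cfg2)
  plots <- tr$plots
  stage1 <- fit_stage1_all(plots)
  blues <- stage1$blues
  env_series <- stats::setNames(
    plots$series_id[!duplicated(plots$environment_id)],
    plots$environment_id[!duplicated(plots$environment_id)])
  test_ids <- unique(g_test)
  s2_test <- fit_stage2_blups(
    blues[blues$environment_id %in% names(env_series)[env_series == test_series], ,
          drop = FALSE])
  test_obs <- s2_test$blups + s2_test$mu
  sf <- structural_filter(sim$merged, map,
                          phenotyped_ids = unique(plots$genotype_id))
  qc <- qc_filter(sf$geno, maf_min = maf_min, na_max = na_max)
  geno <- impute_genotypes(qc$geno, method = impute_method)
  train_ids <- setdiff(
    unique(sim$membership$genotype_id[sim$membership$series != test_series]),
    test_ids)
  structure(list(
    map = map, geno_raw = sf$geno, geno = geno, qc_report = qc$report,
    truth = truth, plots = plots, outlier_rows = tr$outlier_rows,
    blues = blues, flagged = stage1$flagged,
    membership = sim$membership, env_series = env_series,
    test_series = test_series, test_ids = test_ids,
    test_obs = test_obs, test_H2 = s2_test$H2,
    train_ids = train_ids, config = cfg2
  ), class = "gp_bundle")
}

assert_disjoint <- function(train_ids, test_ids) {
  ov <- intersect(train_ids, test_ids)
  if (length(ov)) {
    stop_invalid("training set overlaps the test set: %s",
                 paste(utils::head(ov, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# Stage-2 driver parameters of a training set, for scenario tables.
training_parameters <- function(bundle, series_labels, train_ids) {
  envs <- names(bundle$env_series)[bundle$env_series %in% series_labels]
  bl <- bundle$blues[bundle$blues$environment_id %in% envs &
                       bundle$blues$genotype_id %in% train_ids, , drop = FALSE]
  s2 <- fit_stage2_blups(bl)
  vals <- s2$blups + s2$mu
  cv <- 100 * stats::sd(vals) / mean(vals)
  list(stage2 = s2, cv = cv,
       y = s2$blups[intersect(names(s2$blups), train_ids)])
}

scenario_row <- function(set, model_id, replicate, pa, N, Ne = NA,
                         sigma2_g = NA, H2 = NA, N_env = NA, CV = NA) {
  data.frame(set = set, model_id = model_id, replicate = replicate,
             pa = pa, N = N, Ne = Ne, N_Ne = N / Ne, sigma2_g = sigma2_g,
             H2 = H2, N_env = N_env, CV = CV, stringsAsFactors = FALSE)
}

# Fit one model on training values and return prediction ability on the
# test set.
fit_and_score <- function(bundle, train_y, model_id, mcmc) {
  test_ids <- intersect(bundle$test_ids, rownames(bundle$geno))
  train_ids <- intersect(names(train_y), rownames(bundle$geno))
  assert_disjoint(train_ids, test_ids)
  lines <- c(train_ids, test_ids)
  freq <- allele_freq(bundle$geno)
  ks <- model_kernel_sets(model_id, bundle$geno[lines, , drop = FALSE],
                          bundle$map, freq = freq)
  y <- stats::setNames(rep(NA_real_, length(lines)), lines)
  y[train_ids] <- train_y[train_ids]
  fit <- suppressWarnings(fit_multikernel(y, ks$kernels, mcmc = mcmc))
  pred <- predict_genetic_values(fit, "total", observed = bundle$test_obs)
  pt <- pred[pred$genotype_id %in% test_ids, ]
  prediction_ability(pt$predicted, pt$observed)
}

#' Scenario 1: training-set combinations predicting the test series
#'
#' For each requested combination of training series: assembles the
#' across-environment BLUPs of that combination (after excluding every
#' genotype that occurs in the test set), fits the model, predicts the test
#' series, and records prediction ability together with the driver
#' parameters of the training set (N, Ne, N/Ne, genotypic variance,
#' reliability, environments per genotype, coefficient of variation of the
#' BLUPs).
#'
#' @param train_sets list of character vectors of training-series labels.
#' @param bundle a `gp_bundle` from [simulate_study()].
#' @param model_id prediction model (default `"A+E"`).
#' @param mcmc an [mcmc_config()].
#' @return a `data.frame` (one row per combination) with columns `set`,
#'   `model_id`, `replicate`, `pa`, `N`, `Ne`, `N_Ne`, `sigma2_g`, `H2`,
#'   `N_env`, `CV`.
#' @export
run_scenario1 <- function(train_sets, bundle, model_id = "A+E",
                          mcmc = mcmc_config(n_iter = 2000, burn_in = 500,
                                             thin = 2)) {
  stopifnot(inherits(bundle, "gp_bundle"))
  rows <- list()
  for (i in seq_along(train_sets)) {
    combo <- train_sets[[i]]
    if (bundle$test_series %in% combo) {
      stop_invalid("training combination contains the test series '%s'",
                   bundle$test_series)
    }
    ids <- unique(bundle$membership$genotype_id[
      bundle$membership$series %in% combo])
    train_ids <- setdiff(ids, bundle$test_ids)
    assert_disjoint(train_ids, bundle$test_ids)
    par <- training_parameters(bundle, combo, train_ids)
    ne <- tryCatch(
      effective_population_size(
        bundle$geno[intersect(train_ids, rownames(bundle$geno)), ,
                    drop = FALSE],
        bundle$map, max_pairs = 20000,
        seed = derive_seed(bundle$config$seed, 40L + i))$ne,
      error = function(e) NA_real_)
    pa <- fit_and_score(bundle, par$y, model_id, mcmc)
    rows[[i]] <- scenario_row(paste(combo, collapse = "+"), model_id, 1L,
                              pa, length(par$y), ne,
                              par$stage2$sigma2_g, par$stage2$H2,
                              par$stage2$N_env, par$cv)
  }
  do.call(rbind, rows)
}

#' Correlate training-set parameters with prediction ability
#'
#' Product-moment correlation of each driver parameter with prediction
#' ability across the rows of a scenario table, with two-sided p-values and
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param table a scenario table (needs >= 4 rows).
#' @param params parameter columns to correlate.
#' @return a `data.frame` with `parameter`, `r`, `p_value`, `n`, `stars`;
#'   constant columns yield `NA` with the reason in `note`.
#' @export
parameter_pa_correlations <- function(table,
                                      params = c("N", "Ne", "N_Ne",
                                                 "sigma2_g", "H2", "N_env",
                                                 "CV")) {
  if (nrow(table) < 4L) stop_invalid("need at least 4 scenario rows")
  out <- lapply(params, function(p) {
    x <- table[[p]]
    ok <- is.finite(x) & is.finite(table$pa)
    if (sum(ok) < 4L || stats::var(x[ok]) == 0 || stats::var(table$pa[ok]) == 0) {
      return(data.frame(parameter = p, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), stars = "",
                        note = "constant or insufficient values",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], table$pa[ok])
    stars <- if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**"
      else if (ct$p.value < 0.05) "*" else ""
    data.frame(parameter = p, r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), stars = stars, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scenario 2: training-set size by model sweep
#'
#' Repeatedly draws random training subsets of each requested size from the
#' pooled training lines (the same draws are reused for every model, so
#' model comparisons are paired), fits every model, and scores prediction
#' ability on the test series.
#'
#' @param sizes training-set sizes.
#' @param n_reps replicate draws per size.
#' @param models model ids to fit.
#' @param bundle a `gp_bundle`.
#' @param seed seed for the subset draws (fit chains derive from it).
#' @param mcmc an [mcmc_config()].
#' @param train_y optional named vector of training values; defaults to the
#'   across-environment BLUPs of all training series combined.
#' @return `list(table =, summary =)`: per-replicate rows and mean/SE of
#'   prediction ability per size x model.
#' @export
run_scenario2 <- function(sizes, n_reps, models, bundle, seed = 1,
                          mcmc = mcmc_config(n_iter = 2000, burn_in = 500,
                                             thin = 2),
                          train_y = NULL) {
  stopifnot(inherits(bundle, "gp_bundle"))
  if (is.null(train_y)) {
    combo <- setdiff(unique(bundle$membership$series), bundle$test_series)
    train_y <- training_parameters(bundle, combo, bundle$train_ids)$y
  }
  pool <- intersect(names(train_y), rownames(bundle$geno))
  assert_disjoint(pool, bundle$test_ids)
  if (max(sizes) > length(pool)) {
    stop_invalid("size %d exceeds the %d available training lines",
                 max(sizes), length(pool))
  }
  rows <- list()
  for (r in seq_len(n_reps)) {
    draws <- with_seed(derive_seed(seed, 100L + r), {
      lapply(sizes, function(s) sample(pool, s))
    })
    for (j in seq_along(sizes)) {
      for (m in models) {
        fit_mcmc <- mcmc
        fit_mcmc$seed <- derive_seed(seed, 1000L + 17L * r + j)
        pa <- fit_and_score(bundle, train_y[draws[[j]]], m, fit_mcmc)
        rows[[length(rows) + 1L]] <-
          scenario_row(sprintf("size%d", sizes[j]), m, r, pa,
                       length(draws[[j]]))
      }
    }
  }
  table <- do.call(rbind, rows)
  agg <- stats::aggregate(pa ~ N + model_id, data = table, function(x) {
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
  })
  summary <- data.frame(N = agg$N, model_id = agg$model_id,
                        mean_pa = agg$pa[, "mean"], se_pa = agg$pa[, "se"],
                        n_reps = agg$pa[, "n"], stringsAsFactors = FALSE)
  list(table = table, summary = summary)
}

#' QC-threshold grid study
#'
#' For every combination of missingness threshold, MAF threshold and
#' training size: filters the raw merged panel, imputes, rebuilds kernels,
#' fits the model on random training draws and scores prediction ability on
#' the test series. Cells whose filters remove all markers are marked
#' failed and the sweep continues.
#'
#' @param bundle a `gp_bundle` (its `geno_raw` matrix is refiltered).
#' @param na_thresholds missingness thresholds (default 1.0/0.8/0.5/0.3).
#' @param maf_thresholds MAF thresholds (default 0 and 0.05).
#' @param sizes training sizes.
#' @param n_reps replicate draws per cell.
#' @param model_id model to fit.
#' @param seed seed for draws.
#' @param mcmc an [mcmc_config()].
#' @return a `data.frame` with `na_max`, `maf_min`, `size`, `replicate`,
#'   `n_markers`, `pa` (`NA` when the cell failed).
#' @export
qc_grid_sweep <- function(bundle, na_thresholds = c(1.0, 0.8, 0.5, 0.3),
                          maf_thresholds = c(0, 0.05), sizes,
                          n_reps = 3, model_id = "A", seed = 1,
                          mcmc = mcmc_config(n_iter = 1500, burn_in = 400,
                                             thin = 2)) {
  stopifnot(inherits(bundle, "gp_bundle"))
  combo <- setdiff(unique(bundle$membership$series), bundle$test_series)
  train_y <- training_parameters(bundle, combo, bundle$train_ids)$y
  rows <- list()
  for (na_max in na_thresholds) {
    for (maf_min in maf_thresholds) {
      cell <- tryCatch({
        qc <- qc_filter(bundle$geno_raw, maf_min = maf_min, na_max = na_max)
        if (ncol(qc$geno) == 0L) stop("all markers removed")
        impute_genotypes(qc$geno, method = "mean")
      }, error = function(e) NULL)
      for (size in sizes) {
        for (r in seq_len(n_reps)) {
          if (is.null(cell)) {
            rows[[length(rows) + 1L]] <- data.frame(
              na_max = na_max, maf_min = maf_min, size = size,
              replicate = r, n_markers = 0L, pa = NA_real_)
            next
          }
          b2 <- bundle
          b2$geno <- cell
          draw <- with_seed(derive_seed(seed, 300L + r), {
            sample(intersect(names(train_y), rownames(cell)),
                   min(size, length(train_y)))
          })
          fit_mcmc <- mcmc
          fit_mcmc$seed <- derive_seed(seed, 5000L + r)
          pa <- fit_and_score(b2, train_y[draw], model_id, fit_mcmc)
          rows[[length(rows) + 1L]] <- data.frame(
            na_max = na_max, maf_min = maf_min, size = size, replicate = r,
            n_markers = ncol(cell), pa = pa)
        }
      }
    }
  }
  do.call(rbind, rows)
}
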