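test_that("genome map has the hexaploid structure and is deterministic", {
  map <- make_genome_map(7, 10)
  expect_equal(length(unique(map$chromosome)), 21)
  expect_equal(nrow(map), 210)
  expect_setequal(unique(map$subgenome), c("A", "B", "D"))
  small <- make_genome_map(1, 5)
  expect_setequal(unique(small$chromosome), c("1A", "1B", "1D"))
  expect_identical(make_genome_map(7, 10), make_genome_map(7, 10))
  # positions non-decreasing within every chromosome
  for (ch in unique(map$chromosome)) {
    expect_false(is.unsorted(map$position[map$chromosome == ch]))
  }
  expect_error(make_genome_map(0, 5), "must be >= 1")
})

test_that("series genotypes are homozygous with block-wise panel missingness", {
  map <- make_genome_map(2, 12)
  cfg <- sim_config(n_series = 3, lines_per_series = 25,
                    markers_per_panel = 40, n_chrom_per_subgenome = 2,
                    check_overlap = 3, seed = 4)
  sim <- simulate_series_genotypes(map, cfg)
  expect_true(all(unlist(sim$true_codes) %in% c(0, 2)))
  # block missingness: within a panel the missing columns are the same for
  # every line, never scattered
  for (P in sim$panels) {
    na_cols <- colSums(is.na(unclass(P)))
    expect_true(all(na_cols %in% c(0L, nrow(P))))
    expect_equal(sum(na_cols == 0L), 40)
  }
  # shared checks appear in every series under one id
  chk <- grep("^CHK", rownames(sim$merged), value = TRUE)
  expect_length(chk, 3)
  counts <- table(sim$membership$genotype_id[
    grepl("^CHK", sim$membership$genotype_id)])
  expect_true(all(counts == 3))
  # determinism
  sim2 <- simulate_series_genotypes(map, cfg)
  expect_identical(sim$merged, sim2$merged)
  expect_error(
    simulate_series_genotypes(
      map, sim_config(n_series = 1, markers_per_panel = 1000,
                      n_chrom_per_subgenome = 2)),
    "exceeds")
})

test_that("disjoint equal panels leave each line missing exactly m entries", {
  map <- make_genome_map(1, 20)  # 60 markers
  cfg <- sim_config(n_series = 2, lines_per_series = 10,
                    markers_per_panel = 30, n_chrom_per_subgenome = 1,
                    check_overlap = 0, panel_core_frac = 0, seed = 1)
  sim <- simulate_series_genotypes(map, cfg)
  # force disjoint panels by masking manually from the true codes
  M <- sim$true_codes
  p1 <- geno_matrix(`[<-`(M[1:10, ], , 31:60, NA_real_))
  p2 <- geno_matrix(`[<-`(M[11:20, ], , 1:30, NA_real_))
  merged <- merge_panels(list(p1, p2))
  expect_true(all(rowSums(is.na(unclass(merged))) == 30))
})

test_that("genetic values hit variance targets and respect pair placement", {
  map <- make_genome_map(2, 15)
  cfg <- sim_config(n_series = 2, lines_per_series = 120,
                    markers_per_panel = 90, n_chrom_per_subgenome = 2,
                    n_qtl_additive = 30, n_qtl_pairs_epistatic = 20,
                    sigma2_A = 1.7, sigma2_E = 0.6, seed = 9)
  sim <- simulate_series_genotypes(map, cfg)
  tr <- simulate_genetic_values(sim$true_codes, map, cfg)
  expect_equal(var(tr$true_additive), 1.7, tolerance = 1e-8)
  expect_equal(var(tr$true_epistatic), 0.6, tolerance = 1e-8)
  expect_equal(tr$true_total, tr$true_additive + tr$true_epistatic)
  # within-subgenome placement: both pair members on the requested subgenome
  trA <- simulate_genetic_values(sim$true_codes, map, cfg,
                                 placement = "subgenome", subgenome = "A")
  pairs <- attr(trA, "qtl_pairs")
  sg <- map$subgenome[match(c(pairs$marker1, pairs$marker2), map$marker_id)]
  expect_true(all(sg == "A"))
  # no epistatic pairs -> identically zero component
  cfg0 <- cfg
  cfg0$n_qtl_pairs_epistatic <- 0L
  tr0 <- simulate_genetic_values(sim$true_codes, map, cfg0)
  expect_true(all(tr0$true_epistatic == 0))
  # more pairs than available -> invalid
  cfg_many <- cfg
  cfg_many$n_qtl_pairs_epistatic <- 10000L
  expect_error(simulate_genetic_values(sim$true_codes, map, cfg_many),
               "available")
})

test_that("trial simulation decomposes as configured and records outliers", {
  map <- make_genome_map(1, 10)
  cfg <- sim_config(n_series = 1, lines_per_series = 30,
                    markers_per_panel = 30, n_chrom_per_subgenome = 1,
                    n_qtl_pairs_epistatic = 0, seed = 3)
  sim <- simulate_series_genotypes(map, cfg)
  truth <- simulate_genetic_values(sim$true_codes, map, cfg)

  # all variances zero and zero genetic values -> every plot equals mu
  cfg0 <- sim_config(n_series = 1, lines_per_series = 30,
                     markers_per_panel = 30, n_chrom_per_subgenome = 1,
                     sigma2_A = 0, sigma2_E = 0, sigma2_env = 0,
                     sigma2_ge = 0, sigma2_trial = 0, sigma2_rep = 0,
                     sigma2_block = 0, sigma2_eps = 0, mu = 50, seed = 3)
  truth0 <- truth
  truth0$true_additive <- truth0$true_epistatic <- truth0$true_total <- 0
  des <- trial_design(truth$genotype_id, n_env = 2, n_rep = 2)
  t0 <- simulate_trials(truth0, des, cfg0)
  expect_true(all(t0$plots$value == 50))

  # outlier bookkeeping: ~rate * n plots, all recorded, shifts >= 6 residual SD
  cfg_out <- sim_config(n_series = 1, lines_per_series = 30,
                        markers_per_panel = 30, n_chrom_per_subgenome = 1,
                        outlier_rate = 0.02, seed = 5)
  des_big <- trial_design(truth$genotype_id, n_env = 40, n_rep = 2)
  tt <- simulate_trials(truth, des_big, cfg_out)
  n <- nrow(des_big)
  expect_gt(length(tt$outlier_rows), 0.02 * n - 3 * sqrt(0.02 * n))
  expect_lt(length(tt$outlier_rows), 0.02 * n + 3 * sqrt(0.02 * n))
  cfg_clean <- cfg_out
  cfg_clean$outlier_rate <- 0
  clean <- simulate_trials(truth, des_big, cfg_clean)
  shift <- abs(tt$plots$value - clean$plots$value)[tt$outlier_rows]
  expect_true(all(shift >= 6 * sqrt(cfg_out$sigma2_eps) - 1e-8))
  # determinism
  tt2 <- simulate_trials(truth, des_big, cfg_out)
  expect_identical(tt$plots, tt2$plots)
  expect_error(simulate_trials(truth, des_big[0, ], cfg_out), "empty")
})

test_that("plot-value variance decomposition matches the configured components", {
  # many levels per stratum so each empirical component is identifiable
  # many environments keep the sampling error of each realized component
  # well under the 5% band
  map <- make_genome_map(1, 10)
  cfg <- sim_config(n_series = 1, lines_per_series = 50,
                    markers_per_panel = 30, n_chrom_per_subgenome = 1,
                    n_qtl_additive = 30, n_qtl_pairs_epistatic = 0,
                    sigma2_A = 1, sigma2_E = 0, sigma2_env = 0.5,
                    sigma2_ge = 0, sigma2_trial = 0.4, sigma2_rep = 0.3,
                    sigma2_block = 0, sigma2_eps = 0.8,
                    check_overlap = 0, seed = 21)
  sim <- simulate_series_genotypes(map, cfg)
  truth <- simulate_genetic_values(sim$true_codes, map, cfg)
  des <- trial_design(truth$genotype_id, n_env = 100, n_trials_per_env = 1,
                      n_rep = 2, n_blocks = 1)
  tt <- simulate_trials(truth, des, cfg)
  expect_gte(nrow(tt$plots), 10000)
  total_cfg <- var(truth$true_total) + cfg$sigma2_env + cfg$sigma2_trial +
    cfg$sigma2_rep + cfg$sigma2_eps
  expect_equal(var(tt$plots$value), total_cfg, tolerance = 0.05)
})

test_that("plot means recover the truth as residual noise vanishes", {
  map <- make_genome_map(1, 10)
  cfg <- sim_config(n_series = 1, lines_per_series = 60,
                    markers_per_panel = 30, n_chrom_per_subgenome = 1,
                    sigma2_env = 0, sigma2_ge = 0, sigma2_trial = 0,
                    sigma2_rep = 0, sigma2_block = 0, sigma2_eps = 1e-8,
                    seed = 6)
  sim <- simulate_series_genotypes(map, cfg)
  truth <- simulate_genetic_values(sim$true_codes, map, cfg)
  des <- trial_design(truth$genotype_id, n_env = 2, n_rep = 2)
  tt <- simulate_trials(truth, des, cfg)
  pm <- tapply(tt$plots$value, tt$plots$genotype_id, mean)
  expect_gt(cor(pm[truth$genotype_id], truth$true_total), 0.999)
})
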