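test_that("panel merging unions markers and resolves duplicate checks by majority", {
  M1 <- rbind(a = c(0, 2), chk = c(2, 0))
  colnames(M1) <- c("m1", "m2")
  M2 <- rbind(b = c(2, 0), chk = c(0, 0))
  colnames(M2) <- c("m2", "m3")
  merged <- merge_panels(list(geno_matrix(M1), geno_matrix(M2)))
  expect_setequal(colnames(merged), c("m1", "m2", "m3"))
  expect_setequal(rownames(merged), c("a", "chk", "b"))
  expect_true(is.na(unclass(merged)["a", "m3"]))
  expect_true(is.na(unclass(merged)["b", "m1"]))
  # check line: m2 called 0 in both panels -> stays 0, no missing added
  expect_equal(unclass(merged)["chk", "m2"], 0)
  # identical panels collapse to the input
  same <- merge_panels(list(geno_matrix(M1), geno_matrix(M1)))
  expect_equal(unclass(same)[rownames(M1), colnames(M1)], M1)
  # conflicting duplicate calls become missing (tie between two codes)
  M3 <- matrix(c(0, 0), 1, 2, dimnames = list("chk", c("m1", "m2")))
  tied <- merge_panels(list(geno_matrix(M1), geno_matrix(M3)))
  expect_true(is.na(unclass(tied)["chk", "m1"]))  # 2 vs 0
})

test_that("structural filters attribute every removed marker to one rule", {
  codes <- cbind(
    all_na = c(NA, NA, NA, NA),
    mono = c(2, 2, 2, 2),
    unmapped = c(0, 2, 0, 2),
    good1 = c(0, 2, 2, 0),
    good2 = c(2, 0, 0, 2))
  rownames(codes) <- sprintf("L%d", 1:4)
  G <- geno_matrix(codes)
  map <- data.frame(marker_id = c("all_na", "mono", "good1", "good2"),
                    chromosome = "1A", subgenome = "A", position = 1:4)
  out <- structural_filter(G, map)
  expect_equal(ncol(out$geno), 2)
  expect_setequal(colnames(out$geno), c("good1", "good2"))
  rep <- out$report
  expect_equal(rep$removed_by_rule$no_calls, 1)
  expect_equal(rep$removed_by_rule$monomorphic, 1)
  expect_equal(rep$removed_by_rule$unmapped, 1)
  expect_equal(rep$n_markers_out + sum(unlist(rep$removed_by_rule)),
               rep$n_markers_in)
  # conflicting map entries
  map2 <- rbind(map, data.frame(marker_id = "good1", chromosome = "2B",
                                subgenome = "B", position = 9))
  out2 <- structural_filter(G, map2)
  expect_equal(out2$report$removed_by_rule$conflicting_map, 1)
  # phenotype index drops lines
  out3 <- structural_filter(G, map, phenotyped_ids = c("L1", "L2"))
  expect_equal(nrow(out3$geno), 2)
})

test_that("MAF/missingness filter honours its boundary conventions", {
  n <- 40
  codes <- cbind(
    maf05 = c(rep(0, 38), 2, 2),     # MAF 0.05: kept at maf_min = 0.05
    maf025 = c(rep(0, 39), 2),       # MAF 0.025: removed
    na80 = c(rep(NA, 32), 0, 0, 0, 0, 2, 2, 2, 2),  # exactly 80%: kept
    na90 = c(rep(NA, 36), 0, 0, 2, 2),              # 90%: removed
    common = rep(c(0, 2), 20))
  rownames(codes) <- sprintf("L%02d", seq_len(n))
  G <- geno_matrix(codes)
  out <- qc_filter(G, maf_min = 0.05, na_max = 0.8)
  expect_setequal(colnames(out$geno), c("maf05", "na80", "common"))
  expect_equal(out$report$removed_by_rule$missingness, 1)
  expect_equal(out$report$removed_by_rule$maf, 1)
  # vacuous thresholds remove nothing
  out0 <- qc_filter(G, maf_min = 0, na_max = 1)
  expect_equal(ncol(out0$geno), ncol(codes))
  # idempotence
  again <- qc_filter(out$geno, maf_min = 0.05, na_max = 0.8)
  expect_equal(unclass(again$geno), unclass(out$geno))
  expect_equal(again$report$n_markers_in, again$report$n_markers_out)
  expect_error(qc_filter(G, maf_min = 0.7, na_max = 0.8), "maf_min")
  expect_error(qc_filter(G, maf_min = 0, na_max = 0), "na_max")
})

test_that("imputation fills every gap with the documented values", {
  G <- random_geno(30, 12, seed = 3, miss = 0.15)
  for (m in c("mean", "knn")) {
    imp <- impute_genotypes(G, method = m)
    expect_false(anyNA(imp))
  }
  # no missing -> unchanged
  G0 <- random_geno(10, 5, seed = 4)
  expect_equal(unclass(impute_genotypes(G0)), unclass(G0))
  # mean rule: frequency 0.25 -> dosage 0.5
  codes <- cbind(m1 = c(NA, 0, 0, 0, 2), m2 = c(0, 2, 0, 2, 0))
  rownames(codes) <- paste0("L", 1:5)
  imp <- impute_genotypes(geno_matrix(codes), "mean")
  expect_equal(unclass(imp)["L1", "m1"], 0.5)
  # knn restores a masked duplicate line exactly
  M <- unclass(random_geno(12, 10, seed = 5))
  M <- rbind(M, dup = M[1, ])
  M["dup", 4] <- NA
  imp2 <- impute_genotypes(geno_matrix(M), "knn", k = 1)
  expect_equal(unclass(imp2)["dup", 4], M[1, 4])
})

test_that("Rogers' distance is a bounded metric on homozygous data", {
  # hand values
  M <- rbind(a = c(0, 0, 0, 0), b = c(2, 2, 0, 0), c = c(2, 2, 2, 2))
  colnames(M) <- paste0("m", 1:4)
  D <- rogers_distance(geno_matrix(M))
  expect_equal(D["a", "b"], 0.5)
  expect_equal(D["a", "c"], 1)
  expect_equal(D["a", "a"], 0)
  # exhaustive 5-line instances: bounds, symmetry, triangle inequality
  set.seed(8)
  for (rep in 1:25) {
    M <- matrix(sample(c(0, 2), 5 * 4, replace = TRUE), 5, 4,
                dimnames = list(paste0("L", 1:5), paste0("m", 1:4)))
    D <- rogers_distance(geno_matrix(M))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    }
  }
  # pairwise-complete mode agrees with complete mode on complete data
  G <- random_geno(8, 6, seed = 9)
  expect_equal(rogers_distance(G, pairwise_complete = TRUE),
               rogers_distance(G))
})

test_that("PCoA reproduces Euclidean configurations", {
  # three points at pairwise distance 1: two positive axes, 50% each
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(paste0("p", 1:3), paste0("p", 1:3))
  out <- pcoa(D)
  expect_equal(ncol(out$coordinates), 2)
  expect_equal(out$percent_explained, c(50, 50), tolerance = 1e-8)
  # round-trip: distances among recovered coordinates match the input
  set.seed(10)
  X <- matrix(rnorm(20 * 3), 20, 3)
  rownames(X) <- paste0("q", 1:20)
  D2 <- as.matrix(dist(X))
  out2 <- pcoa(D2)
  Drec <- as.matrix(dist(out2$coordinates))
  expect_equal(unname(Drec), unname(D2), tolerance = 1e-8)
  expect_equal(sum(out2$percent_explained), 100, tolerance = 1e-8)
  # degenerate all-zero distances
  expect_equal(ncol(pcoa(matrix(0, 4, 4))$coordinates), 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Ne estimator applies the sample-size-corrected unlinked-LD formula", {
  # orthogonal marker columns: mean r2 = 0 -> corrected r2 < 0 -> infinite Ne
  codes <- cbind(matrix(rep(c(0, 2), each = 6), 12, 5),
                 matrix(rep(c(0, 2), times = 6), 12, 5))
  dimnames(codes) <- list(sprintf("L%02d", 1:12), sprintf("m%02d", 1:10))
  map <- data.frame(marker_id = colnames(codes),
                    chromosome = rep(c("1A", "1B"), each = 5),
                    subgenome = rep(c("A", "B"), each = 5),
                    position = 1:10)
  est <- effective_population_size(geno_matrix(codes), map)
  expect_equal(est$mean_r2, 0)
  expect_identical(est$ne, Inf)
  # self-consistency of the reported pieces on arbitrary data
  G <- random_geno(40, 30, seed = 6)
  m40 <- map_for(G, n_chrom = 6)
  est2 <- effective_population_size(G, m40, seed = 2)
  r2a <- est2$mean_r2 - 1 / est2$S
  expect_equal(est2$ne, if (r2a <= 0) Inf else 1 / (3 * r2a))
  expect_error(effective_population_size(random_geno(5, 10), map), "10 lines")
})

test_that("Ne estimates recover the true size of a Wright-Fisher population", {
  ests <- vapply(1:6, function(s) {
    G <- simulate_wf_population(ne = 50, n_loci = 200, n_gen = 100, seed = s)
    map <- map_for(G, n_chrom = 21)
    effective_population_size(G, map, seed = s)$ne
  }, numeric(1))
  expect_true(all(ests > 20 & ests < 130))
  expect_equal(median(ests), 50, tolerance = 0.5)
})

test_that("Ne rises as within-series relatedness falls", {
  map <- make_genome_map(3, 12)
  ne_of <- function(n_founders, pool) {
    cfg <- sim_config(n_series = 1, lines_per_series = 120,
                      markers_per_panel = 108, n_chrom_per_subgenome = 3,
                      n_founders = n_founders, founder_pool_size = pool,
                      seed = 13)
    sim <- simulate_series_genotypes(map, cfg)
    effective_population_size(geno_matrix(sim$true_codes), map, seed = 1)$ne
  }
  expect_lt(ne_of(6, 6), ne_of(40, 40))
})
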