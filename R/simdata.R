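#' Simulation configuration for multi-series breeding data
#'
#' Collects every knob of the synthetic-data generator: the number of
#' breeding series and their sizes, the per-series SNP panel sizes (which
#' create block-missingness after merging), the genetic architecture
#' (additive QTL and additive-by-additive QTL pairs with target variances),
#' and the field-trial variance components of the plot-level model
#' (environment, genotype-by-environment, trial, replicate, block, plot
#' residual).
#'
#' Defaults emulate a set of partially connected Central European winter
#' wheat breeding series: inbred lines (homozygous marker codes 0/2),
#' founder allele frequencies drawn from a truncated Beta(0.8, 0.8) so rare
#' alleles exist for MAF-filter studies, within-series linkage
#' disequilibrium and relatedness induced by copying founder chromosome
#' segments, and trials connected by shared check varieties.
#'
#' @param n_series number of breeding series (training populations).
#' @param lines_per_series integer vector (recycled) of lines per series.
#' @param markers_per_panel integer vector (recycled) of SNP panel size per
#'   series; panels are drawn to overlap partially.
#' @param n_chrom_per_subgenome chromosomes per subgenome (wheat: 7).
#' @param n_qtl_additive number of additive QTL.
#' @param n_qtl_pairs_epistatic number of additive-by-additive QTL pairs.
#' @param sigma2_A,sigma2_E target variances of the additive and epistatic
#'   genetic values in the simulated population (trait units squared).
#' @param sigma2_env,sigma2_ge,sigma2_trial,sigma2_rep,sigma2_block,sigma2_eps
#'   variances of environment, genotype-by-environment, trial, replicate,
#'   block and plot-residual effects.
#' @param mu trait intercept (e.g. grain yield in dt/ha).
#' @param check_overlap number of shared check lines present in every series.
#' @param outlier_rate proportion of plots contaminated with gross outliers
#'   (shifted by 6-10 residual SD); must be < 0.1.
#' @param n_founders founder lines per series (relatedness knob).
#' @param founder_pool_size size of the global elite founder pool the series
#'   sample their founders from; values close to `n_founders` make the
#'   series one connected pool without distinct subpopulations, large values
#'   make them diverge.
#' @param segment_markers expected founder-segment length in markers (LD
#'   knob); smaller values give faster LD decay and lower relatedness.
#' @param panel_core_frac fraction of markers belonging to a core set shared
#'   by all panels.
#' @param het_rate residual heterozygosity rate (default 0: fully inbred).
#' @param freq_shape shape parameters of the founder allele-frequency Beta.
#' @param freq_bounds truncation bounds of the founder allele frequency.
#' @param seed master seed; every generator draw derives from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_series = 4,
                       lines_per_series = 150,
                       markers_per_panel = 300,
                       n_chrom_per_subgenome = 7,
                       n_qtl_additive = 100,
                       n_qtl_pairs_epistatic = 50,
                       sigma2_A = 1,
                       sigma2_E = 0.5,
                       sigma2_env = 2,
                       sigma2_ge = 0.5,
                       sigma2_trial = 0.25,
                       sigma2_rep = 0.25,
                       sigma2_block = 0.1,
                       sigma2_eps = 1,
                       mu = 50,
                       check_overlap = 3,
                       outlier_rate = 0,
                       n_founders = 16,
                       founder_pool_size = NULL,
                       segment_markers = 8,
                       panel_core_frac = 0.5,
                       het_rate = 0,
                       freq_shape = c(0.8, 0.8),
                       freq_bounds = c(0.02, 0.98),
                       seed = 1) {
  cfg <- list(
    n_series = as.integer(n_series),
    lines_per_series = as.integer(rep_len(lines_per_series, n_series)),
    markers_per_panel = as.integer(rep_len(markers_per_panel, n_series)),
    n_chrom_per_subgenome = as.integer(n_chrom_per_subgenome),
    n_qtl_additive = as.integer(n_qtl_additive),
    n_qtl_pairs_epistatic = as.integer(n_qtl_pairs_epistatic),
    sigma2_A = sigma2_A, sigma2_E = sigma2_E,
    sigma2_env = sigma2_env, sigma2_ge = sigma2_ge,
    sigma2_trial = sigma2_trial, sigma2_rep = sigma2_rep,
    sigma2_block = sigma2_block, sigma2_eps = sigma2_eps,
    mu = mu,
    check_overlap = as.integer(check_overlap),
    outlier_rate = outlier_rate,
    n_founders = as.integer(n_founders),
    founder_pool_size = as.integer(founder_pool_size %||%
                                     round(1.5 * n_founders)),
    segment_markers = segment_markers,
    panel_core_frac = panel_core_frac,
    het_rate = het_rate,
    freq_shape = freq_shape,
    freq_bounds = freq_bounds,
    seed = as.integer(seed)
  )
  vars <- c("sigma2_A", "sigma2_E", "sigma2_env", "sigma2_ge", "sigma2_trial",
            "sigma2_rep", "sigma2_block", "sigma2_eps")
  for (v in vars) {
    if (!is_scalar_number(cfg[[v]]) || cfg[[v]] < 0) {
      stop_invalid("variance component '%s' must be a non-negative number", v)
    }
  }
  if (cfg$n_series < 1L) stop_invalid("n_series must be >= 1")
  if (cfg$outlier_rate < 0 || cfg$outlier_rate >= 0.1) {
    stop_invalid("outlier_rate must be in [0, 0.1)")
  }
  if (any(cfg$lines_per_series < 1L) || any(cfg$markers_per_panel < 1L)) {
    stop_invalid("lines_per_series and markers_per_panel must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Build a hexaploid-style genome map
#'
#' Creates a marker map over `3 * n_chrom_per_subgenome` chromosomes labelled
#' `1A..7A`, `1B..7B`, `1D..7D` (for the default of 7), with
#' `markers_per_chrom` uniformly spaced markers per chromosome. The map
#' carries the chromosome and subgenome labels that define the restricted
#' epistasis kernel partitions.
#'
#' @param n_chrom_per_subgenome chromosomes per subgenome (>= 1).
#' @param markers_per_chrom markers per chromosome (>= 1).
#' @param chrom_length_cM map length of each chromosome.
#' @param seed unused placeholder for interface symmetry (the map is
#'   deterministic); kept so configs round-trip.
#'
#' @return a `data.frame` with columns `marker_id`, `chromosome`,
#'   `subgenome`, `position`, sorted by chromosome then position.
#' @export
make_genome_map <- function(n_chrom_per_subgenome = 7, markers_per_chrom = 10,
                            chrom_length_cM = 100, seed = 1) {
  if (n_chrom_per_subgenome < 1 || markers_per_chrom < 1) {
    stop_invalid("chromosome and marker counts must be >= 1")
  }
  subgenomes <- c("A", "B", "D")
  chroms <- as.vector(t(outer(seq_len(n_chrom_per_subgenome), subgenomes,
                              paste0)))
  pos <- seq(0, chrom_length_cM, length.out = markers_per_chrom)
  map <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(
      marker_id = sprintf("M%s_%03d", ch, seq_len(markers_per_chrom)),
      chromosome = ch,
      subgenome = substring(ch, nchar(ch)),
      position = pos,
      stringsAsFactors = FALSE
    )
  }))
  rownames(map) <- NULL
  map
}

# Draw one inbred line as a biparental cross: two founder parents, each
# chromosome copied in segments of expected length `segment_markers`
# alternating between the parents. Sharing parents across chromosomes is
# what creates relatedness and unlinked-locus LD within a series.
mosaic_line <- function(founders, chrom_index, segment_markers) {
  m <- ncol(founders)
  out <- numeric(m)
  par <- sample.int(nrow(founders), 2L, replace = nrow(founders) < 2L)
  for (idx in chrom_index) {
    k <- length(idx)
    n_seg <- max(1L, stats::rpois(1, k / segment_markers))
    cuts <- sort(unique(c(0L, sample.int(k - 1L, min(n_seg, k - 1L)), k)))
    for (s in seq_len(length(cuts) - 1L)) {
      seg <- idx[(cuts[s] + 1L):cuts[s + 1L]]
      out[seg] <- founders[par[1L + (s %% 2L)], seg]
    }
  }
  out
}

#' Simulate genotypes for several breeding series with heterogeneous panels
#'
#' Each series has its own founder pool; lines are founder-segment mosaics,
#' which induces within-series relatedness and LD. All lines are fully
#' homozygous (codes 0/2) unless a residual heterozygosity rate is set.
#' Each series is genotyped on its own marker panel (a shared core plus a
#' series-specific draw), so merging the series reproduces the block-wise
#' missingness of heterogeneous SNP arrays. A configurable number of check
#' lines is shared by all series under a single genotype id.
#'
#' @param map genome map from [make_genome_map()].
#' @param config a [sim_config()].
#' @param series_prefix label prefix for series names.
#' @param check_series integer indices of the series that carry the shared
#'   check lines (default: all series).
#' @param founder_pool_size size of the global founder pool each series
#'   samples its `n_founders` parents from; the overlap between series'
#'   founder subsets controls cross-series relatedness (default
#'   `2 * n_founders`).
#'
#' @return a list with components:
#'   `panels` (per-series [geno_matrix] objects with panel masking applied),
#'   `merged` (the merged matrix, see [merge_panels()]),
#'   `true_codes` (complete unmasked 0/1/2 matrix for every unique line),
#'   `series_of_line` (named character, first series of each line),
#'   `membership` (data.frame line x series).
#' @export
simulate_series_genotypes <- function(map, config, series_prefix = "S",
                                      check_series = NULL,
                                      founder_pool_size = NULL) {
  founder_pool_size <- founder_pool_size %||% config$founder_pool_size
  stopifnot(inherits(config, "sim_config"))
  m_total <- nrow(map)
  if (any(config$markers_per_panel > m_total)) {
    stop_invalid("markers_per_panel exceeds the %d markers in the map", m_total)
  }
  check_series <- check_series %||% seq_len(config$n_series)
  founder_pool_size <- as.integer(founder_pool_size %||%
                                    (2L * config$n_founders))
  with_seed(derive_seed(config$seed, 1L), {
    # founder allele frequencies, shared across series so loci stay comparable
    p <- stats::rbeta(m_total, config$freq_shape[1], config$freq_shape[2])
    p <- pmin(pmax(p, config$freq_bounds[1]), config$freq_bounds[2])
    chrom_index <- split(seq_len(m_total), map$chromosome)

    # core marker set present on every panel
    core <- sort(sample.int(m_total,
                            round(config$panel_core_frac * min(config$markers_per_panel))))

    # one global founder pool: each series samples its parents from it, so
    # series overlap genetically without being copies of each other
    pool <- matrix(stats::rbinom(founder_pool_size * m_total, 1,
                                 rep(p, each = founder_pool_size)) * 2,
                   nrow = founder_pool_size, ncol = m_total)

    # shared check lines, crosses of pool founders
    n_chk <- config$check_overlap
    checks <- NULL
    if (n_chk > 0L) {
      checks <- t(vapply(seq_len(n_chk), function(i) {
        mosaic_line(pool, chrom_index, config$segment_markers)
      }, numeric(m_total)))
      rownames(checks) <- sprintf("CHK%02d", seq_len(n_chk))
    }

    panels <- vector("list", config$n_series)
    true_rows <- list()
    series_of_line <- character(0)
    for (s in seq_len(config$n_series)) {
      sname <- paste0(series_prefix, s)
      n_lines <- config$lines_per_series[s]
      founders <- pool[sample.int(founder_pool_size,
                                  min(config$n_founders, founder_pool_size)), ,
                       drop = FALSE]
      lines <- t(vapply(seq_len(n_lines), function(i) {
        mosaic_line(founders, chrom_index, config$segment_markers)
      }, numeric(m_total)))
      rownames(lines) <- sprintf("%s_L%04d", sname, seq_len(n_lines))
      if (!is.null(checks) && s %in% check_series) lines <- rbind(lines, checks)
      if (config$het_rate > 0) {
        flip <- which(stats::runif(length(lines)) < config$het_rate)
        lines[flip] <- 1
      }
      colnames(lines) <- map$marker_id

      # panel: shared core plus series-specific markers
      extra_pool <- setdiff(seq_len(m_total), core)
      n_extra <- config$markers_per_panel[s] - length(core)
      panel_idx <- sort(c(core, sample(extra_pool, max(0L, n_extra))))
      masked <- lines
      masked[, setdiff(seq_len(m_total), panel_idx)] <- NA_real_
      panels[[s]] <- geno_matrix(masked,
                                 panel_of_line = stats::setNames(
                                   rep(sname, nrow(masked)), rownames(masked)))
      new_ids <- setdiff(rownames(lines), names(series_of_line))
      series_of_line[new_ids] <- sname
      true_rows[[s]] <- lines[new_ids, , drop = FALSE]
    }
    true_codes <- do.call(rbind, true_rows)
    merged <- merge_panels(panels)
    membership <- do.call(rbind, lapply(seq_along(panels), function(s) {
      data.frame(genotype_id = rownames(panels[[s]]),
                 series = paste0(series_prefix, s),
                 stringsAsFactors = FALSE)
    }))
    list(panels = panels, merged = merged, true_codes = true_codes,
         series_of_line = series_of_line, membership = membership)
  })
}

#' Simulate additive and additive-by-additive genetic values
#'
#' Samples additive QTL effects at randomly chosen markers and
#' additive-by-additive effects at random marker pairs, then rescales each
#' component so the realized population variances hit the configured
#' `sigma2_A` and `sigma2_E` targets exactly (up to floating point).
#' Epistatic pair placement can be genome-wide, within a subgenome, or
#' within single chromosomes.
#'
#' @param genotypes complete (no missing) lines x markers dosage matrix, or a
#'   [geno_matrix]; typically the `true_codes` component of
#'   [simulate_series_genotypes()].
#' @param map genome map.
#' @param config a [sim_config()].
#' @param placement `"genome"`, `"subgenome"` or `"chromosome"`: the scope
#'   within which both members of each epistatic pair must lie.
#' @param subgenome when `placement = "subgenome"`, restrict pairs to this
#'   subgenome label (`"A"`, `"B"`, `"D"`); `NULL` draws the scope per pair.
#'
#' @return a `data.frame` (class `truth_table`) with columns `genotype_id`,
#'   `true_additive`, `true_epistatic`, `true_total`; QTL positions and
#'   effects are attached as attributes `qtl_additive` and `qtl_pairs`.
#' @export
simulate_genetic_values <- function(genotypes, map, config,
                                    placement = c("genome", "subgenome", "chromosome"),
                                    subgenome = NULL) {
  placement <- match.arg(placement)
  stopifnot(inherits(config, "sim_config"))
  M <- unclass_geno(genotypes)
  if (anyNA(M)) stop_invalid("genotypes must be complete (no missing codes)")
  M <- M[, map$marker_id[map$marker_id %in% colnames(M)], drop = FALSE]
  m <- ncol(M)
  if (config$n_qtl_additive < 1L) stop_invalid("n_qtl_additive must be >= 1")
  with_seed(derive_seed(config$seed, 2L), {
    Z <- scale(M, center = TRUE, scale = FALSE)
    poly <- which(apply(Z, 2, function(x) any(x != 0)))
    qtl_a <- sample(poly, min(config$n_qtl_additive, length(poly)))
    a <- stats::rnorm(length(qtl_a))
    gA <- drop(Z[, qtl_a, drop = FALSE] %*% a)
    if (config$sigma2_A > 0 && stats::var(gA) > 0) {
      sc <- sqrt(config$sigma2_A / stats::var(gA))
      gA <- gA * sc
      a <- a * sc
    } else {
      gA <- gA * 0
      a <- a * 0
    }

    n_pairs <- config$n_qtl_pairs_epistatic
    gE <- numeric(nrow(M))
    pairs <- NULL
    if (n_pairs > 0L) {
      scope_of <- switch(placement,
        genome = rep("G", m),
        subgenome = map$subgenome[match(colnames(M), map$marker_id)],
        chromosome = map$chromosome[match(colnames(M), map$marker_id)]
      )
      scopes <- if (placement == "subgenome" && !is.null(subgenome)) {
        subgenome
      } else {
        unique(scope_of[poly])
      }
      avail <- sum(vapply(scopes, function(sc) {
        k <- sum(poly %in% which(scope_of == sc))
        choose(k, 2)
      }, numeric(1)))
      if (n_pairs > avail) {
        stop_invalid("requested %d epistatic pairs but only %d are available",
                     n_pairs, avail)
      }
      seen <- character(0)
      pr1 <- integer(n_pairs); pr2 <- integer(n_pairs)
      i <- 1L
      while (i <= n_pairs) {
        sc <- if (length(scopes) == 1L) scopes else sample(scopes, 1L)
        cand <- intersect(poly, which(scope_of == sc))
        if (length(cand) < 2L) next
        pq <- sample(cand, 2L)
        key <- paste(sort(pq), collapse = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        pr1[i] <- pq[1]; pr2[i] <- pq[2]
        i <- i + 1L
      }
      b <- stats::rnorm(n_pairs)
      W <- Z[, pr1, drop = FALSE] * Z[, pr2, drop = FALSE]
      gE <- drop(W %*% b)
      if (config$sigma2_E > 0 && stats::var(gE) > 0) {
        sc <- sqrt(config$sigma2_E / stats::var(gE))
        gE <- gE * sc
        b <- b * sc
      } else {
        gE <- gE * 0
        b <- b * 0
      }
      pairs <- data.frame(marker1 = colnames(M)[pr1],
                          marker2 = colnames(M)[pr2],
                          effect = b, stringsAsFactors = FALSE)
    }
    truth <- data.frame(genotype_id = rownames(M),
                        true_additive = gA,
                        true_epistatic = gE,
                        true_total = gA + gE,
                        stringsAsFactors = FALSE)
    attr(truth, "qtl_additive") <- data.frame(
      marker = colnames(M)[qtl_a], effect = a, stringsAsFactors = FALSE)
    attr(truth, "qtl_pairs") <- pairs
    class(truth) <- c("truth_table", "data.frame")
    truth
  })
}

#' Lay out a multi-environment trial design
#'
#' @param genotypes genotype ids to test.
#' @param n_env number of environments.
#' @param n_trials_per_env trials per environment; genotypes are split
#'   evenly across trials within an environment.
#' @param n_rep replicates per trial.
#' @param n_blocks incomplete blocks per replicate.
#' @param env_prefix environment label prefix.
#' @param series_id series label stored with every plot.
#' @return a `data.frame` of plot assignments (one row per plot, no values).
#' @export
trial_design <- function(genotypes, n_env, n_trials_per_env = 1, n_rep = 2,
                         n_blocks = 2, env_prefix = "E", series_id = "S1") {
  if (length(genotypes) == 0L || n_env < 1L) {
    stop_invalid("trial design needs >= 1 genotype and >= 1 environment")
  }
  rows <- list()
  for (e in seq_len(n_env)) {
    env <- sprintf("%s%02d", env_prefix, e)
    split_idx <- rep(seq_len(n_trials_per_env),
                     length.out = length(genotypes))
    for (tr in seq_len(n_trials_per_env)) {
      g_tr <- genotypes[split_idx == tr]
      blk <- rep(seq_len(n_blocks), length.out = length(g_tr))
      for (r in seq_len(n_rep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genotype_id = g_tr,
          environment_id = env,
          trial_id = sprintf("%s_T%d", env, tr),
          rep_id = sprintf("R%d", r),
          block_id = sprintf("B%d", blk),
          series_id = series_id,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate plot-level trait values on a trial design
#'
#' Generates plot values from the nested field model: intercept + total
#' genetic value + environment + genotype-by-environment + trial +
#' replicate-within-trial + block-within-replicate + plot residual, all
#' random effects drawn independently with the configured variances.
#' Optionally contaminates a fraction of plots with gross outliers
#' (symmetric shifts of 6-10 residual SD), recording their identities so
#' outlier-detection can be scored against ground truth.
#'
#' @param truth a `truth_table` from [simulate_genetic_values()].
#' @param design a plot-assignment `data.frame` from [trial_design()] (or
#'   several row-bound ones).
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to the config seed).
#' @return a list with `plots` (the design plus a `value` column) and
#'   `outlier_rows` (integer row indices of contaminated plots).
#' @export
simulate_trials <- function(truth, design, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design) || nrow(design) == 0L) stop_invalid("empty trial design")
  missing_g <- setdiff(design$genotype_id, truth$genotype_id)
  if (length(missing_g)) {
    stop_invalid("design contains genotypes without true values: %s",
                 paste(utils::head(missing_g, 3), collapse = ", "))
  }
  with_seed(derive_seed(seed %||% config$seed, 3L), {
    g <- stats::setNames(truth$true_total, truth$genotype_id)
    draw <- function(labels, s2) {
      u <- unique(labels)
      stats::setNames(stats::rnorm(length(u), 0, sqrt(s2)), u)[labels]
    }
    env_eff <- draw(design$environment_id, config$sigma2_env)
    ge_key <- paste(design$genotype_id, design$environment_id, sep = "\r")
    ge_eff <- draw(ge_key, config$sigma2_ge)
    tr_key <- paste(design$environment_id, design$trial_id, sep = "\r")
    tr_eff <- draw(tr_key, config$sigma2_trial)
    rep_key <- paste(tr_key, design$rep_id, sep = "\r")
    rep_eff <- draw(rep_key, config$sigma2_rep)
    blk_key <- paste(rep_key, design$block_id, sep = "\r")
    blk_eff <- draw(blk_key, config$sigma2_block)
    eps <- stats::rnorm(nrow(design), 0, sqrt(config$sigma2_eps))
    value <- config$mu + g[design$genotype_id] + env_eff + ge_eff +
      tr_eff + rep_eff + blk_eff + eps
    outlier_rows <- integer(0)
    if (config$outlier_rate > 0) {
      hit <- which(stats::runif(nrow(design)) < config$outlier_rate)
      if (length(hit)) {
        shift <- sample(c(-1, 1), length(hit), replace = TRUE) *
          stats::runif(length(hit), 6, 10) * sqrt(config$sigma2_eps)
        value[hit] <- value[hit] + shift
        outlier_rows <- hit
      }
    }
    plots <- design
    plots$value <- unname(value)
    list(plots = plots, outlier_rows = outlier_rows)
  })
}
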