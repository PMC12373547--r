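#' Genotype matrix container
#'
#' A lines x markers numeric matrix of allele-dosage codes in `[0, 2]`
#' (`0/1/2` before imputation, real dosages after), with line ids as row
#' names, marker ids as column names, and an optional per-line panel/series
#' provenance attribute.
#'
#' @param codes numeric matrix with unique row and column names.
#' @param panel_of_line optional named character vector mapping line id to
#'   the SNP panel (series) it was genotyped on.
#' @return an object of class `geno_matrix` (a plain matrix underneath).
#' @export
geno_matrix <- function(codes, panel_of_line = NULL) {
  if (!is.matrix(codes) || !is.numeric(codes)) {
    stop_invalid("codes must be a numeric matrix")
  }
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    stop_invalid("codes must carry line ids (rownames) and marker ids (colnames)")
  }
  if (anyDuplicated(colnames(codes))) stop_invalid("marker ids must be unique")
  rng <- range(codes, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop_invalid("codes must lie in [0, 2]")
  }
  if (!is.null(panel_of_line)) {
    panel_of_line <- panel_of_line[rownames(codes)]
  }
  structure(codes, panel = panel_of_line, class = c("geno_matrix", "matrix"))
}

# Strip the class but keep dimnames; accepts plain matrices too.
unclass_geno <- function(G) {
  if (inherits(G, "geno_matrix")) {
    attr(G, "panel") <- NULL
    class(G) <- "matrix"
  }
  unclass(G)
}

panel_of <- function(G) attr(G, "panel")

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Per-marker allele frequencies
#'
#' Frequency of the counted allele, computed on non-missing calls.
#'
#' @param G a [geno_matrix] or dosage matrix.
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_freq <- function(G) {
  colMeans(unclass_geno(G), na.rm = TRUE) / 2
}

#' Merge heterogeneous SNP panels
#'
#' Forms the union of the marker sets; entries outside a line's panel become
#' missing (block-missingness). Lines genotyped in several panels (shared
#' checks) are collapsed to one line: at each marker the majority call among
#' non-missing panel calls wins, and ties are set missing.
#'
#' @param panels a list of [geno_matrix] objects sharing an allele-coding
#'   convention.
#' @return a single [geno_matrix]; the `panel` attribute keeps the first
#'   panel each line was seen in.
#' @export
merge_panels <- function(panels) {
  stopifnot(length(panels) >= 1L)
  markers <- Reduce(union, lapply(panels, colnames))
  lines <- Reduce(union, lapply(panels, rownames))
  counts <- lapply(0:2, function(v) {
    matrix(0L, length(lines), length(markers), dimnames = list(lines, markers))
  })
  panel_first <- character(0)
  for (P in panels) {
    M <- unclass_geno(P)
    pl <- panel_of(P)
    new_ids <- setdiff(rownames(M), names(panel_first))
    panel_first[new_ids] <- if (is.null(pl)) NA_character_ else pl[new_ids]
    for (v in 0:2) {
      hit <- (!is.na(M)) & (M == v)
      counts[[v + 1L]][rownames(M), colnames(M)] <-
        counts[[v + 1L]][rownames(M), colnames(M)] + hit
    }
  }
  n0 <- counts[[1]]; n1 <- counts[[2]]; n2 <- counts[[3]]
  total <- n0 + n1 + n2
  top <- pmax(n0, n1, n2)
  # majority call; ties (two codes sharing the max) -> missing
  tie <- (n0 == top) + (n1 == top) + (n2 == top) > 1L
  out <- matrix(NA_real_, length(lines), length(markers),
                dimnames = list(lines, markers))
  out[n0 == top & !tie & total > 0L] <- 0
  out[n1 == top & !tie & total > 0L] <- 1
  out[n2 == top & !tie & total > 0L] <- 2
  geno_matrix(out, panel_of_line = panel_first)
}

qc_report <- function(n_markers_in, n_markers_out, n_lines_in, n_lines_out,
                      removed_by_rule, thresholds = list()) {
  rep <- list(n_markers_in = n_markers_in, n_markers_out = n_markers_out,
              n_lines_in = n_lines_in, n_lines_out = n_lines_out,
              removed_by_rule = removed_by_rule, thresholds = thresholds)
  stopifnot(n_markers_out + sum(unlist(removed_by_rule)) == n_markers_in)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: markers %d -> %d, lines %d -> %d\n",
              x$n_markers_in, x$n_markers_out, x$n_lines_in, x$n_lines_out))
  for (r in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %-14s %d\n", paste0(r, ":"),
                x$removed_by_rule[[r]]))
  }
  invisible(x)
}

#' Structural marker filters
#'
#' Removes markers with no SNP calls, monomorphic markers, markers absent
#' from the genome map, and markers with conflicting (duplicated,
#' inconsistent) map entries, attributing each marker to the first rule it
#' fails, in that order. Optionally removes lines without phenotypes.
#'
#' @param G a [geno_matrix].
#' @param map genome map `data.frame` (columns `marker_id`, `chromosome`,
#'   `position`).
#' @param phenotyped_ids optional character vector; lines outside it are
#'   dropped.
#' @return `list(geno =, report =)` with a [geno_matrix] and a `qc_report`.
#' @export
structural_filter <- function(G, map, phenotyped_ids = NULL) {
  M <- unclass_geno(G)
  n_in <- ncol(M); l_in <- nrow(M)
  no_calls <- colSums(!is.na(M)) == 0L
  mono <- !no_calls &
    apply(M, 2, function(x) length(unique(x[!is.na(x)])) <= 1L)
  dup <- unique(map$marker_id[duplicated(map$marker_id)])
  conflict <- vapply(dup, function(mk) {
    sub <- map[map$marker_id == mk, c("chromosome", "position")]
    nrow(unique(sub)) > 1L
  }, logical(1))
  conflicted_ids <- dup[conflict]
  unmapped <- !no_calls & !mono & !(colnames(M) %in% map$marker_id)
  conflicting <- !no_calls & !mono & !unmapped &
    (colnames(M) %in% conflicted_ids)
  keep <- !(no_calls | mono | unmapped | conflicting)
  out <- M[, keep, drop = FALSE]
  if (!is.null(phenotyped_ids)) {
    out <- out[rownames(out) %in% phenotyped_ids, , drop = FALSE]
  }
  report <- qc_report(
    n_in, sum(keep), l_in, nrow(out),
    removed_by_rule = list(no_calls = sum(no_calls), monomorphic = sum(mono),
                           unmapped = sum(unmapped),
                           conflicting_map = sum(conflicting))
  )
  pl <- panel_of(G)
  list(geno = geno_matrix(out, panel_of_line = pl), report = report)
}

#' Missingness and minor-allele-frequency filters
#'
#' A marker is kept iff its missing fraction is at most `na_max` and its
#' minor allele frequency (on non-missing calls) is at least `maf_min`.
#' Boundary conventions follow "more than 80% missing" / "less than 5% MAF"
#' removal phrasing: a marker at exactly `na_max` missingness or exactly
#' `maf_min` MAF is kept. Removals are attributed missingness-first.
#'
#' @param G a [geno_matrix].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param na_max maximum missing fraction in `(0, 1]`.
#' @return `list(geno =, report =)`.
#' @export
qc_filter <- function(G, maf_min = 0.05, na_max = 0.8) {
  if (!is_scalar_number(maf_min) || maf_min < 0 || maf_min > 0.5) {
    stop_invalid("maf_min must be in [0, 0.5]")
  }
  if (!is_scalar_number(na_max) || na_max <= 0 || na_max > 1) {
    stop_invalid("na_max must be in (0, 1]")
  }
  M <- unclass_geno(G)
  na_frac <- colMeans(is.na(M))
  p <- allele_freq(M)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing marker: treated as zero MAF
  fail_na <- na_frac > na_max
  fail_maf <- !fail_na & (maf < maf_min)
  keep <- !(fail_na | fail_maf)
  report <- qc_report(
    ncol(M), sum(keep), nrow(M), nrow(M),
    removed_by_rule = list(missingness = sum(fail_na), maf = sum(fail_maf)),
    thresholds = list(maf_min = maf_min, na_max = na_max)
  )
  list(geno = geno_matrix(M[, keep, drop = FALSE],
                          panel_of_line = panel_of(G)),
       report = report)
}

#' Impute missing genotype calls
#'
#' `mean` replaces a missing call by twice the marker's allele frequency
#' (a real-valued dosage). `knn` replaces it by the distance-weighted mean
#' dosage of the `k` nearest lines (Rogers' distance on shared markers)
#' having a call at that marker, falling back to the mean dosage when no
#' neighbour shares markers.
#'
#' @param G a [geno_matrix] with no all-missing markers.
#' @param method `"mean"` or `"knn"`.
#' @param k neighbours for `knn`.
#' @return a complete [geno_matrix] of dosages.
#' @export
impute_genotypes <- function(G, method = c("mean", "knn"), k = 5) {
  method <- match.arg(method)
  M <- unclass_geno(G)
  if (any(colSums(!is.na(M)) == 0L)) {
    stop_invalid("all-missing markers must be removed before imputation")
  }
  mean_dose <- 2 * allele_freq(M)
  if (method == "mean") {
    for (j in which(colSums(is.na(M)) > 0L)) {
      M[is.na(M[, j]), j] <- mean_dose[j]
    }
  } else {
    D <- rogers_distance(G, pairwise_complete = TRUE)
    for (i in which(rowSums(is.na(M)) > 0L)) {
      d <- D[i, ]
      d[i] <- NA
      miss <- which(is.na(M[i, ]))
      for (j in miss) {
        cand <- which(!is.na(M[, j]) & !is.na(d))
        if (!length(cand)) {
          warning("knn imputation: no line shares markers; using mean dosage")
          M[i, j] <- mean_dose[j]
          next
        }
        nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
        w <- 1 / (d[nb] + 1e-6)
        M[i, j] <- sum(w * M[nb, j]) / sum(w)
      }
    }
  }
  geno_matrix(M, panel_of_line = panel_of(G))
}

#' Rogers' genetic distance
#'
#' For homozygous dosage data the per-marker Rogers' distance between two
#' lines reduces to `|dosage_i - dosage_j| / 2`; the distance is the mean
#' over markers, bounded in `[0, 1]`.
#'
#' @param G a [geno_matrix] (complete, or set `pairwise_complete = TRUE` to
#'   average over markers both lines were called on).
#' @param pairwise_complete use pairwise-complete markers per line pair.
#' @return a symmetric distance matrix with zero diagonal; in pairwise mode
#'   pairs sharing no markers get `NA`.
#' @export
rogers_distance <- function(G, pairwise_complete = FALSE) {
  M <- unclass_geno(G)
  if (!pairwise_complete) {
    if (anyNA(M)) {
      stop_invalid("matrix has missing codes; impute first or use pairwise_complete = TRUE")
    }
    D <- as.matrix(stats::dist(M / 2, method = "manhattan")) / ncol(M)
  } else {
    n <- nrow(M)
    obs <- !is.na(M)
    Mz <- M; Mz[!obs] <- 0
    # sum over shared markers of |m_i - m_j| via the identity
    # |a-b| = a + b - 2*min(a,b); with codes {0,1,2} use pairwise loops on
    # half-matrices only when n is small, else fall back to a direct loop.
    D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
    for (i in seq_len(n - 1L)) {
      share <- obs[(i + 1L):n, , drop = FALSE] &
        matrix(obs[i, ], n - i, ncol(M), byrow = TRUE)
      diff <- abs(sweep(Mz[(i + 1L):n, , drop = FALSE], 2, Mz[i, ])) * share
      ns <- rowSums(share)
      d <- rowSums(diff) / (2 * ns)
      d[ns == 0L] <- NA_real_
      D[i, (i + 1L):n] <- d
      D[(i + 1L):n, i] <- d
    }
  }
  diag(D) <- 0
  D
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns coordinates scaled
#' by the square roots of the positive eigenvalues, with the percentage of
#' variance each positive axis explains.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k maximum number of axes to return (default all positive).
#' @return `list(coordinates, eigenvalues, percent_explained)`.
#' @export
pcoa <- function(D, k = NULL) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop_invalid("distance matrix must be symmetric")
  }
  n <- nrow(D)
  # cmdscale warns when fewer than k eigenvalues are positive; expected here
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-12 * max(abs(eig), 1))
  if (!is.null(k)) pos <- utils::head(pos, k)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (length(pos) == 0L) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(D), NULL))
  }
  rownames(coords) <- rownames(D)
  pct <- 100 * eig[pos] / sum(eig[eig > 0])
  list(coordinates = coords, eigenvalues = eig,
       percent_explained = pct)
}

#' LD-based effective population size
#'
#' Estimates Ne from squared allele-dosage correlations (`r^2`) between
#' physically unlinked marker pairs (different chromosomes). The mean `r^2`
#' is corrected for finite sample size by subtracting `1/S` (S = number of
#' lines), and Ne is obtained from the unlinked-loci drift expectation
#' `E[r^2_adj] = 1/(3 Ne)`, i.e. `Ne = 1/(3 r^2_adj)`. A non-positive
#' corrected `r^2` yields an infinite estimate.
#'
#' @param G a [geno_matrix] (missing calls allowed; pairwise-complete
#'   correlations are used).
#' @param map genome map assigning markers to chromosomes.
#' @param max_pairs cap on the number of sampled cross-chromosome pairs.
#' @param seed seed for pair subsampling.
#' @return an object of class `ne_estimate`:
#'   `list(ne, mean_r2, n_pairs, S)`.
#' @export
effective_population_size <- function(G, map, max_pairs = 100000, seed = 1) {
  M <- unclass_geno(G)
  S <- nrow(M)
  if (S < 10L) stop_invalid("need at least 10 lines to estimate Ne")
  chrom <- map$chromosome[match(colnames(M), map$marker_id)]
  usable <- which(!is.na(chrom) &
                    apply(M, 2, function(x) stats::var(x, na.rm = TRUE) > 0))
  chrom <- chrom[usable]
  if (length(unique(chrom)) < 2L) {
    stop_invalid("need polymorphic markers on at least 2 chromosomes")
  }
  m <- length(usable)
  with_seed(seed, {
    if (choose(m, 2) <= 2 * max_pairs) {
      idx <- utils::combn(m, 2)
      cross <- idx[, chrom[idx[1, ]] != chrom[idx[2, ]], drop = FALSE]
      if (ncol(cross) > max_pairs) {
        cross <- cross[, sample.int(ncol(cross), max_pairs), drop = FALSE]
      }
    } else {
      i1 <- sample.int(m, 3 * max_pairs, replace = TRUE)
      i2 <- sample.int(m, 3 * max_pairs, replace = TRUE)
      ok <- i1 < i2 & chrom[i1] != chrom[i2]
      key <- unique(cbind(i1[ok], i2[ok]))
      cross <- t(utils::head(key, max_pairs))
    }
    if (ncol(cross) < 10L) stop_invalid("fewer than 10 usable unlinked pairs")
    X <- M[, usable, drop = FALSE]
    r2 <- vapply(seq_len(ncol(cross)), function(k) {
      suppressWarnings(
        stats::cor(X[, cross[1, k]], X[, cross[2, k]],
                   use = "pairwise.complete.obs"))^2
    }, numeric(1))
    r2 <- r2[is.finite(r2)]
    mean_r2 <- mean(r2)
    r2_adj <- mean_r2 - 1 / S
    ne <- if (r2_adj <= 0) Inf else 1 / (3 * r2_adj)
    structure(list(ne = ne, mean_r2 = mean_r2, n_pairs = length(r2), S = S),
              class = "ne_estimate")
  })
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne = %.1f (mean r2 = %.4f over %d unlinked pairs, S = %d)\n",
              x$ne, x$mean_r2, x$n_pairs, x$S))
  invisible(x)
}
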