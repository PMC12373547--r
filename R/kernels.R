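#' Kernel (genomic relationship) matrix container
#'
#' @param K symmetric n x n numeric matrix with line ids as dimnames.
#' @param marker_subset label of the marker partition the kernel was built
#'   from (`"ALL"`, a subgenome `"A"/"B"/"D"`, or a chromosome `"1A".."7D"`).
#' @param kind `"additive"` or `"epistatic"`.
#' @param normalized whether the matrix was rescaled to mean diagonal 1.
#' @return an object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(K, marker_subset = "ALL",
                          kind = c("additive", "epistatic"),
                          normalized = FALSE) {
  kind <- match.arg(kind)
  if (!isSymmetric(unname(K), tol = 1e-8)) {
    stop_invalid("kernel must be symmetric")
  }
  if (is.null(rownames(K))) stop_invalid("kernel needs line ids as dimnames")
  structure(K, marker_subset = marker_subset, kind = kind,
            normalized = normalized, class = c("kernel_matrix", "matrix"))
}

kernel_kind <- function(K) attr(K, "kind")

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s, subset %s): %d lines, mean diag %.3f\n",
              attr(x, "kind"), attr(x, "marker_subset"), nrow(x),
              mean(diag(x))))
  invisible(x)
}

#' Rescale a kernel to mean diagonal one
#'
#' Division by the mean diagonal preserves positive semidefiniteness and the
#' correlation structure while making variance components comparable across
#' kernels built from different marker counts.
#'
#' @param K a [kernel_matrix].
#' @return the rescaled [kernel_matrix].
#' @export
normalize_kernel <- function(K) {
  md <- mean(diag(K))
  if (md <= 0) stop_invalid("kernel has non-positive mean diagonal")
  kernel_matrix(unclass(K) / md, marker_subset = attr(K, "marker_subset"),
                kind = attr(K, "kind"), normalized = TRUE)
}

#' Additive genomic relationship matrix (VanRaden, first method)
#'
#' Centers dosages by twice the allele frequencies, `Z = M - 2P`, and
#' returns `G = Z Z' / (2 * sum p (1 - p))`. Markers with reference
#' frequency 0 or 1 carry no information and are excluded with a warning.
#'
#' @param M complete lines x markers dosage matrix (values in `[0, 2]`) or
#'   [geno_matrix].
#' @param freq optional named allele-frequency vector to center with (e.g.
#'   computed once on the full line set); defaults to frequencies of `M`.
#' @param marker_subset label stored with the kernel.
#' @return an additive [kernel_matrix].
#' @export
vanraden_g <- function(M, freq = NULL, marker_subset = "ALL") {
  M <- unclass_geno(M)
  if (anyNA(M)) stop_invalid("dosage matrix must be complete (impute first)")
  p <- if (is.null(freq)) colMeans(M) / 2 else freq[colnames(M)]
  fixed <- p <= 0 | p >= 1 | is.na(p)
  if (any(fixed)) {
    warning(sprintf("%d markers with allele frequency 0 or 1 excluded",
                    sum(fixed)))
    M <- M[, !fixed, drop = FALSE]
    p <- p[!fixed]
  }
  if (ncol(M) == 0L) stop_invalid("no polymorphic markers left for the kernel")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  G <- (G + t(G)) / 2
  kernel_matrix(G, marker_subset = marker_subset, kind = "additive")
}

#' Additive-by-additive epistasis kernel
#'
#' The Hadamard square of the additive relationship matrix:
#' `G_E[i, j] = G_A[i, j]^2`, the covariance implied by all pairwise
#' products of centered marker dosages.
#'
#' @param GA an additive [kernel_matrix].
#' @return an epistatic [kernel_matrix] over the same marker subset.
#' @export
epistasis_kernel <- function(GA) {
  if (kernel_kind(GA) != "additive") {
    stop_invalid("epistasis kernel is built from an additive kernel")
  }
  kernel_matrix(unclass(GA)^2, marker_subset = attr(GA, "marker_subset"),
                kind = "epistatic", normalized = FALSE)
}

#' Kernel restricted to a subgenome or chromosome
#'
#' Builds the VanRaden kernel from only the markers mapping to the given
#' subgenome (`"A"`, `"B"`, `"D"`) or chromosome (`"1A"` .. `"7D"`), with
#' its own denominator; `kind = "epistatic"` returns its Hadamard square.
#'
#' @param M complete dosage matrix or [geno_matrix].
#' @param map genome map.
#' @param subset subgenome or chromosome label.
#' @param kind `"additive"` or `"epistatic"`.
#' @param freq optional allele-frequency vector (full line set).
#' @return a [kernel_matrix].
#' @export
subset_kernel <- function(M, map, subset, kind = c("additive", "epistatic"),
                          freq = NULL) {
  kind <- match.arg(kind)
  M <- unclass_geno(M)
  sel <- if (subset %in% c("A", "B", "D")) {
    map$marker_id[map$subgenome == subset]
  } else {
    map$marker_id[map$chromosome == subset]
  }
  sel <- intersect(colnames(M), sel)
  if (length(sel) == 0L) stop_invalid("marker subset '%s' is empty", subset)
  GA <- vanraden_g(M[, sel, drop = FALSE], freq = freq,
                   marker_subset = subset)
  if (kind == "additive") GA else epistasis_kernel(GA)
}

#' Kernel sets for the nine prediction models
#'
#' Maps a model id to its list of covariance kernels:
#' \describe{
#'   \item{A}{additive kernel only.}
#'   \item{A+E}{additive plus genome-wide epistasis.}
#'   \item{A+sgA / A+sgB / A+sgD}{additive plus epistasis restricted to one
#'     subgenome.}
#'   \item{A+sgABD}{additive plus the three subgenome epistasis kernels.}
#'   \item{A+chrA / A+chrB / A+chrD}{additive plus one epistasis kernel per
#'     chromosome of the subgenome (7 kernels).}
#'   \item{A+chrABD}{additive plus all 21 per-chromosome epistasis kernels.}
#' }
#'
#' @param model_id one of the ids above.
#' @param M complete dosage matrix or [geno_matrix].
#' @param map genome map.
#' @param normalize rescale every kernel to mean diagonal 1 (default TRUE)
#'   so variance components are comparable across partitions.
#' @param freq optional allele-frequency vector used for all kernels.
#' @return `list(model_id =, kernels =)` where `kernels` is a named list of
#'   [kernel_matrix] objects (first entry always the additive kernel `A`).
#' @export
model_kernel_sets <- function(model_id, M, map, normalize = TRUE,
                              freq = NULL) {
  valid <- c("A", "A+E", "A+sgA", "A+sgB", "A+sgD", "A+sgABD",
             "A+chrA", "A+chrB", "A+chrD", "A+chrABD")
  if (!model_id %in% valid) {
    stop_invalid("unknown model id '%s'; valid ids: %s", model_id,
                 paste(valid, collapse = ", "))
  }
  M <- unclass_geno(M)
  if (is.null(freq)) freq <- stats::setNames(colMeans(M) / 2, colnames(M))
  GA <- suppressWarnings(vanraden_g(M, freq = freq))
  kern <- list(A = GA)
  sg_chroms <- function(sg) {
    unique(map$chromosome[map$subgenome == sg &
                            map$marker_id %in% colnames(M)])
  }
  add_chrom_kernels <- function(kern, sgs) {
    for (sg in sgs) {
      for (ch in sg_chroms(sg)) {
        kern[[paste0("E_chr", ch)]] <- suppressWarnings(
          subset_kernel(M, map, ch, kind = "epistatic", freq = freq))
      }
    }
    kern
  }
  if (model_id == "A+E") {
    kern$E <- epistasis_kernel(GA)
  } else if (model_id %in% c("A+sgA", "A+sgB", "A+sgD")) {
    sg <- substring(model_id, 5)
    kern[[paste0("E_sg", sg)]] <- suppressWarnings(
      subset_kernel(M, map, sg, kind = "epistatic", freq = freq))
  } else if (model_id == "A+sgABD") {
    for (sg in c("A", "B", "D")) {
      kern[[paste0("E_sg", sg)]] <- suppressWarnings(
        subset_kernel(M, map, sg, kind = "epistatic", freq = freq))
    }
  } else if (model_id %in% c("A+chrA", "A+chrB", "A+chrD")) {
    kern <- add_chrom_kernels(kern, substring(model_id, 6))
  } else if (model_id == "A+chrABD") {
    kern <- add_chrom_kernels(kern, c("A", "B", "D"))
  }
  if (normalize) kern <- lapply(kern, normalize_kernel)
  list(model_id = model_id, kernels = kern)
}
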