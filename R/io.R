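#' Write / read coded genotype matrices as CSV
#'
#' Rows are lines, columns marker ids, cells dosages (`NA` for missing);
#' the first column holds line ids, an optional second the panel label.
#'
#' @param G a [geno_matrix].
#' @param path output file.
#' @export
write_geno_csv <- function(G, path) {
  M <- unclass_geno(G)
  df <- data.frame(genotype_id = rownames(M),
                   panel = panel_of(G) %||% NA_character_,
                   M, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_geno_csv
#' @param path CSV file as written by [write_geno_csv()].
#' @export
read_geno_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = "")
  M <- as.matrix(df[, setdiff(colnames(df), c("genotype_id", "panel")),
                    drop = FALSE])
  mode(M) <- "numeric"
  rownames(M) <- df$genotype_id
  pl <- if (all(is.na(df$panel))) NULL else
    stats::setNames(df$panel, df$genotype_id)
  geno_matrix(M, panel_of_line = pl)
}

#' Write / read a genome map as 3-column CSV
#' @param map genome map `data.frame`.
#' @param path file path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(map[, c("marker_id", "chromosome", "position")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  map$subgenome <- substring(map$chromosome, nchar(map$chromosome))
  map
}

#' Write genotypes as a diploid VCF
#'
#' Emits biallelic sites with GT calls `0/0`, `0/1`, `1/1` and `./.` for
#' missing; dosages are rounded to the nearest code. The file is written
#' gzip-compressed via vcfR (use a `.vcf.gz` path).
#'
#' @param G a [geno_matrix].
#' @param map genome map giving chromosome and position per marker.
#' @param path output path (`.vcf.gz`).
#' @export
write_geno_vcf <- function(G, map, path) {
  M <- unclass_geno(G)
  idx <- match(colnames(M), map$marker_id)
  gt_code <- c("0/0", "0/1", "1/1")
  GT <- apply(round(t(M)), c(1, 2), function(v) {
    if (is.na(v)) "./." else gt_code[v + 1]
  })
  fix <- cbind(CHROM = map$chromosome[idx],
               POS = as.character(round(map$position[idx] * 1e4) + 1),
               ID = colnames(M), REF = "A", ALT = "T", QUAL = ".",
               FILTER = "PASS", INFO = ".")
  gt <- cbind(FORMAT = "GT", GT)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a biallelic VCF into a genotype matrix
#'
#' Counts ALT alleles per GT call (`./.` becomes missing).
#'
#' @param path VCF (optionally gzipped).
#' @return a [geno_matrix] (lines x markers).
#' @export
read_geno_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(grepl("\\.", x), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  M <- apply(gt, c(1, 2), count_alt)
  geno_matrix(t(M))
}

#' Serialize a QC report to JSON
#' @param report a `qc_report`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
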