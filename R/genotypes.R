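#' Construct a genotype matrix
#'
#' Container for an individuals-by-SNPs allele-dosage matrix together with its
#' marker map. Dosages count copies of one designated allele (the ALT allele
#' for data read from VCF), so entries are 0, 1 or 2. The per-SNP frequency of
#' the counted allele is kept alongside and always equals `colMeans(dosages)/2`.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns, entries
#'   in \{0, 1, 2\}. Row and column names are used as individual and SNP ids
#'   when `individual_ids`/`snp_ids` are not given.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   one row per SNP, in the column order of `dosages`.
#' @param individual_ids,snp_ids optional character vectors overriding dimnames.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `map`, `allele_freq`.
#' @export
genotype_matrix <- function(dosages, map, individual_ids = NULL, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (!is.null(individual_ids)) rownames(dosages) <- individual_ids
  if (!is.null(snp_ids)) colnames(dosages) <- snp_ids
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  if (anyNA(dosages))
    stop("dosages must not contain missing values (impute before construction)")
  if (!all(dosages %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1 or 2")
  map <- as.data.frame(map)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)))
  if (nrow(map) != ncol(dosages))
    stop("map must have one row per SNP column")
  map$snp_id <- as.character(unname(map$snp_id))
  map$chrom <- as.character(unname(map$chrom))
  map$pos <- unname(map$pos)
  if (!identical(map$snp_id, unname(colnames(dosages))))
    stop("map$snp_id must match SNP column names in order")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("map positions must be strictly increasing within chromosome ", ch)
  }
  structure(
    list(dosages = dosages, map = map, allele_freq = colMeans(dosages) / 2),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs on", length(unique(x$map$chrom)),
      "chromosome(s)\n")
  maf <- pmin(x$allele_freq, 1 - x$allele_freq)
  cat(sprintf("  MAF: min %.3f, median %.3f, max %.3f\n",
              min(maf), median(maf), max(maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Keep a subset of SNPs
#'
#' @param g a [genotype_matrix()].
#' @param which integer, logical or character index into the SNP columns.
#' @return A `genotype_matrix` with the selected SNPs, individuals unchanged.
#' @export
subset_snps <- function(g, which) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages[, which, drop = FALSE]
  genotype_matrix(d, g$map[match(colnames(d), g$map$snp_id), , drop = FALSE])
}

#' Read genotypes from VCF or a plain dosage matrix
#'
#' For VCF input only the GT field is used; each record's ALT allele is the
#' counted allele. Multi-allelic records are skipped with a warning. Missing
#' calls are imputed to the rounded column mean of the observed calls (the
#' number imputed is reported via a message).
#'
#' The dosage-matrix format is tab-delimited with a header row of SNP ids and
#' the individual id in the first column; the marker map is read from a
#' companion file `<path>.map` (columns `snp_id`, `chrom`, `pos`) if present,
#' otherwise all SNPs are placed on chromosome "1" at consecutive positions.
#'
#' @param path path to the input file.
#' @param format `"vcf"` or `"dosage_matrix"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] %in% c(".", "")
  if (any(multi))
    warning(sum(multi), " non-biallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(rownames(fix), names(gt)))
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in VCF")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # allele-dosage of ALT from GT strings; tolerate phased separators
  dose <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean == "1/1"] <- 2
  n_miss <- sum(is.na(dose))
  if (n_miss > 0) {
    for (i in seq_len(nrow(dose))) {
      m <- is.na(dose[i, ])
      if (any(m)) dose[i, m] <- round(mean(dose[i, !m]))
    }
    message(n_miss, " missing call(s) imputed to rounded SNP mean")
  }
  snp_id <- fix[, "ID"]
  blank <- is.na(snp_id) | snp_id == "."
  snp_id[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  map <- data.frame(snp_id = snp_id, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  genotype_matrix(t(dose), map, individual_ids = colnames(gt), snp_ids = snp_id)
}

read_genotypes_dosage <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  n_miss <- sum(is.na(d))
  if (n_miss > 0) {
    for (j in seq_len(ncol(d))) {
      m <- is.na(d[, j])
      if (any(m)) d[m, j] <- round(mean(d[!m, j]))
    }
    message(n_miss, " missing call(s) imputed to rounded SNP mean")
  }
  mapfile <- paste0(path, ".map")
  if (file.exists(mapfile)) {
    map <- read.table(mapfile, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    map <- data.frame(snp_id = colnames(d), chrom = "1",
                      pos = seq_len(ncol(d)), stringsAsFactors = FALSE)
  }
  genotype_matrix(d, map, individual_ids = ids)
}

#' Write genotypes to VCF or a plain dosage matrix
#'
#' The VCF writer emits a minimal VCF 4.2 with GT only; REF/ALT are arbitrary
#' letters (A/B) since only the dosage is meaningful. The dosage writer emits
#' the tab-delimited matrix plus a `<path>.map` sidecar.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param format `"vcf"` or `"dosage_matrix"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "dosage_matrix")) {
  stopifnot(inherits(g, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "vcf") {
    gt_str <- c("0/0", "0/1", "1/1")[g$dosages + 1]
    gt <- matrix(gt_str, nrow = nrow(g$dosages))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", rownames(g$dosages)), collapse = "\t")
    ), con)
    body <- cbind(g$map$chrom, g$map$pos, g$map$snp_id, "A", "B", ".", ".",
                  ".", "GT", t(gt))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  } else {
    tab <- data.frame(id = rownames(g$dosages), g$dosages,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(g$map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Quality-filter a genotype matrix
#'
#' Applies, in order: removal of monomorphic SNPs, removal of SNPs on the
#' listed chromosomes, and a minor-allele-frequency threshold. Surviving SNPs
#' keep their original order; individuals are untouched. A SNP failing several
#' rules is counted once, under the first rule in that order.
#'
#' @param g a [genotype_matrix()].
#' @param drop_monomorphic drop SNPs with no variation?
#' @param drop_chromosomes character vector of chromosome labels to drop
#'   (e.g. `"X"`), or `NULL`.
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`; SNPs with
#'   MAF strictly below it are removed. 0 disables the filter.
#' @return A `genotype_matrix` with attribute `"qc_report"`: a data.frame of
#'   per-rule removal counts (also retrievable with [qc_report()]).
#' @export
qc_filter <- function(g, drop_monomorphic = TRUE, drop_chromosomes = NULL,
                      maf_min = 0) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  p <- g$allele_freq
  maf <- pmin(p, 1 - p)
  fail_mono <- if (drop_monomorphic) apply(g$dosages, 2, function(x) all(x == x[1])) else rep(FALSE, length(p))
  fail_chrom <- g$map$chrom %in% drop_chromosomes & !fail_mono
  fail_maf <- maf < maf_min & !fail_mono & !fail_chrom
  keep <- !(fail_mono | fail_chrom | fail_maf)
  if (!any(keep)) stop("all SNPs removed by QC filters")
  report <- data.frame(
    rule = c("monomorphic", "chromosome", "maf"),
    removed = c(sum(fail_mono), sum(fail_chrom), sum(fail_maf))
  )
  out <- subset_snps(g, which(keep))
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param g a filtered `genotype_matrix`.
#' @return data.frame of per-rule removal counts, or `NULL`.
#' @export
qc_report <- function(g) attr(g, "qc_report")
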