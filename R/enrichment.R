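#' Read a gene annotation
#'
#' GFF3 input is parsed with `rtracklayer` and restricted to `gene` features;
#' the gene id is taken from the `gene_id`, `ID` or `Name` attribute (first
#' available). BED-like input is a 4-column table `chrom`, `start`, `end`,
#' `gene_id` with 0-based half-open coordinates, converted to the 1-based
#' inclusive convention used throughout.
#'
#' @param path input file.
#' @param format `"gff3"` or `"bed"`.
#' @return A data.frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    md <- as.data.frame(gr)
    id <- NULL
    for (field in c("gene_id", "ID", "Name"))
      if (is.null(id) && field %in% names(md)) id <- as.character(md[[field]])
    if (is.null(id)) stop("no gene identifier attribute found in GFF3")
    ann <- data.frame(gene_id = id, chrom = as.character(md$seqnames),
                      start = md$start, end = md$end, stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    ann <- data.frame(gene_id = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      start = tab[[2]] + 1L, end = tab[[3]],
                      stringsAsFactors = FALSE)
  }
  gene_annotation(ann)
}

#' Construct a gene annotation table
#'
#' @param ann data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive, `start <= end`, unique `gene_id`).
#' @return The validated data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(ann) {
  ann <- as.data.frame(ann)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("gene_id values must be unique")
  if (any(ann$start > ann$end)) stop("gene start must be <= end")
  ann$gene_id <- as.character(ann$gene_id)
  ann$chrom <- as.character(ann$chrom)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: id, description, member genes).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, character(1), 1))
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Assign SNPs to genes within a flanking distance
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within
#' `[start - flank_bp, end + flank_bp]` (1-based inclusive). A SNP may land
#' in several overlapping genes. Genes receiving no SNP are absent from the
#' result and therefore excluded from the enrichment universe.
#'
#' @param map marker map data.frame (`snp_id`, `chrom`, `pos`), e.g. the
#'   `map` element of a [genotype_matrix()].
#' @param ann a [gene_annotation()].
#' @param flank_bp flanking distance in bp on each side (default 10,000).
#' @return Named list, gene_id -> character vector of assigned snp_ids.
#' @export
assign_snps_to_genes <- function(map, ann, flank_bp = 10000) {
  stopifnot(inherits(ann, "gene_annotation"))
  map <- as.data.frame(map)
  if (!any(unique(map$chrom) %in% unique(ann$chrom)))
    stop("no chromosome label shared between marker map and annotation")
  out <- list()
  for (ch in intersect(unique(map$chrom), unique(ann$chrom))) {
    sm <- map[map$chrom == ch, ]
    ga <- ann[ann$chrom == ch, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sm$pos, sm$pos),
      IRanges::IRanges(pmax(1, ga$start - flank_bp), ga$end + flank_bp)
    )
    if (length(hits) == 0) next
    assigned <- split(sm$snp_id[S4Vectors::queryHits(hits)],
                      ga$gene_id[S4Vectors::subjectHits(hits)])
    out <- c(out, assigned)
  }
  out
}

#' Flag genes carrying at least one significant SNP
#'
#' @param mapping gene -> SNP mapping from [assign_snps_to_genes()].
#' @param scan a [scan_snps()] result.
#' @param alpha significance threshold on the SNP p-value (default 0.01).
#' @param coding which coding's p-values to use (default `"additive"`).
#' @return A data.frame of class `gene_flags`: `gene_id`, `n_snps` (scanned
#'   SNPs in the gene), `min_p`, `significant`. Mapped SNPs absent from the
#'   scan are dropped with a warning reporting the count.
#' @export
flag_significant_genes <- function(mapping, scan, alpha = 0.01,
                                   coding = "additive") {
  stopifnot(inherits(scan, "scan_result"))
  sub <- scan[scan$coding == coding & !scan$skipped, ]
  pmap <- setNames(sub$p, sub$snp_id)
  missing_n <- sum(!unlist(mapping, use.names = FALSE) %in% names(pmap))
  if (missing_n > 0)
    warning(missing_n, " mapped SNP(s) absent from the scan; excluded")
  rows <- lapply(names(mapping), function(gid) {
    pv <- pmap[intersect(mapping[[gid]], names(pmap))]
    if (length(pv) == 0) return(NULL)
    data.frame(gene_id = gid, n_snps = length(pv), min_p = min(pv),
               significant = min(pv) <= alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no mapped SNP appears in the scan")
  class(out) <- c("gene_flags", "data.frame")
  out
}

#' Fisher's exact gene-set overrepresentation test
#'
#' For each set, tests overrepresentation of significant genes with the
#' one-sided cumulative hypergeometric probability
#' \eqn{p = P(X \ge k)} where, out of `N` analyzed genes of which `n` are
#' significant, the set contains `K` analyzed genes and `k` significant ones.
#' The analyzed universe is the set of genes with at least one scanned SNP
#' (i.e. the rows of `flags`). Sets with `K = 0` are omitted.
#'
#' @param flags a [flag_significant_genes()] result.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param adjust optional multiple-testing correction across sets passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `NULL` (default) reports raw p only.
#' @return A data.frame of class `enrichment_result` with columns `set_id`,
#'   `k`, `K`, `n`, `N`, `p` (and `p_adjust` when requested), ordered by `p`.
#' @export
fisher_enrichment <- function(flags, sets, adjust = NULL) {
  stopifnot(inherits(flags, "gene_flags"))
  universe <- flags$gene_id
  signif <- flags$gene_id[flags$significant]
  N <- length(universe)
  n <- length(signif)
  if (n == 0)
    warning("no significant genes: all enrichment p-values are 1")
  dropped <- sum(!unlist(sets, use.names = FALSE) %in% universe)
  if (dropped > 0)
    message(dropped, " gene-set member(s) outside the analyzed universe ignored")
  rows <- lapply(names(sets), function(sid) {
    members <- intersect(sets[[sid]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, signif))
    p <- phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    data.frame(set_id = sid, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the analyzed universe")
  if (!is.null(adjust)) out$p_adjust <- p.adjust(out$p, method = adjust)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat("enrichment_result:", nrow(x), "gene sets, universe N =", x$N[1],
      "with n =", x$n[1], "significant genes\n")
  print(as.data.frame(head(x, n)), row.names = FALSE, digits = 3)
  invisible(x)
}
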