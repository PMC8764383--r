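#' Relationship matrix container
#'
#' Wraps a symmetric relationship matrix (dense or sparse) with its ordered
#' individual ids and a kind tag (`"A"`, `"G"`, `"A22"`, `"H"`, `"A_inverse"`,
#' `"H_inverse"`).
#'
#' @param values symmetric matrix (base matrix or a `Matrix` sparse matrix).
#' @param ids character vector of individual ids, in matrix order.
#' @param kind character tag.
#' @return An object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, ids, kind) {
  stopifnot(nrow(values) == ncol(values), length(ids) == nrow(values))
  asym <- max(abs(values - Matrix::t(values)))
  if (asym > 1e-10) stop("matrix not symmetric (max asymmetry ", asym, ")")
  structure(list(values = values, ids = as.character(ids), kind = kind),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("relationship_matrix [", x$kind, "]: ", length(x$ids), " x ",
      length(x$ids), if (methods::is(x$values, "sparseMatrix")) " (sparse)",
      "\n", sep = "")
  dg <- Matrix::diag(x$values)
  cat(sprintf("  diagonal: mean %.4f, range [%.4f, %.4f]\n",
              mean(dg), min(dg), max(dg)))
  invisible(x)
}

#' @export
dim.relationship_matrix <- function(x) dim(x$values)

#' @export
as.matrix.relationship_matrix <- function(x, ...) as.matrix(x$values)

ped_parent_idx <- function(ped) {
  list(sire = match(ped$sire, ped$id), dam = match(ped$dam, ped$id))
}

# topological sort of a pedigree; errors on cycles
sort_pedigree <- function(ped) {
  idx <- ped_parent_idx(ped)
  n <- nrow(ped)
  placed <- rep(FALSE, n)
  order <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      s <- idx$sire[i]; d <- idx$dam[i]
      (is.na(s) || placed[s]) && (is.na(d) || placed[d])
    }, logical(1))]
    if (length(ready) == 0)
      stop("pedigree contains a cycle (an individual is its own ancestor)")
    placed[ready] <- TRUE
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pedigree numerator relationship matrix (A)
#'
#' Computes A by the tabular method. The pedigree is topologically sorted
#' first if needed; unknown parents are treated as unrelated founders. The
#' diagonal equals 1 plus the inbreeding coefficient.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (NA for unknown).
#' @return A [relationship_matrix()] of kind `"A"`, in the (possibly
#'   re-sorted) pedigree order.
#' @export
compute_A <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  idx <- ped_parent_idx(ped)
  if (any(!is.na(idx$sire) & idx$sire >= seq_len(nrow(ped))) ||
      any(!is.na(idx$dam) & idx$dam >= seq_len(nrow(ped))))
    ped <- sort_pedigree(ped)
  idx <- ped_parent_idx(ped)
  A <- ped_tabular_A_cpp(idx$sire, idx$dam, nrow(ped))
  dimnames(A) <- list(ped$id, ped$id)
  relationship_matrix(A, ped$id, "A")
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`).
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  ped <- as.data.frame(ped)
  idx <- ped_parent_idx(ped)
  if (any(!is.na(idx$sire) & idx$sire >= seq_len(nrow(ped))) ||
      any(!is.na(idx$dam) & idx$dam >= seq_len(nrow(ped)))) {
    ped <- sort_pedigree(ped)
    idx <- ped_parent_idx(ped)
  }
  setNames(ped_inbreeding_cpp(idx$sire, idx$dam, nrow(ped)), ped$id)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A^-1 directly from the pedigree by Henderson's rules, with
#' Mendelian-sampling variances adjusted for parental inbreeding
#' (Meuwissen-Luo coefficients), so the result is exact for inbred pedigrees.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`).
#' @return A [relationship_matrix()] of kind `"A_inverse"` holding a sparse
#'   symmetric matrix.
#' @export
compute_A_inverse <- function(ped) {
  ped <- as.data.frame(ped)
  idx <- ped_parent_idx(ped)
  if (any(!is.na(idx$sire) & idx$sire >= seq_len(nrow(ped))) ||
      any(!is.na(idx$dam) & idx$dam >= seq_len(nrow(ped)))) {
    ped <- sort_pedigree(ped)
    idx <- ped_parent_idx(ped)
  }
  n <- nrow(ped)
  f <- ped_inbreeding_cpp(idx$sire, idx$dam, n)
  s <- idx$sire; d <- idx$dam
  fs <- ifelse(is.na(s), 0, f[s]); fd <- ifelse(is.na(d), 0, f[d])
  known <- (!is.na(s)) + (!is.na(d))
  dvar <- ifelse(known == 2, 0.5 - 0.25 * (fs + fd),
          ifelse(known == 1, 0.75 - 0.25 * (fs + fd), 1))
  alpha <- 1 / dvar
  i <- seq_len(n)
  ti <- i; tj <- i; tx <- alpha                   # (i, i) += alpha
  add <- function(ii, jj, xx) {
    ti <<- c(ti, ii); tj <<- c(tj, jj); tx <<- c(tx, xx)
  }
  hs <- !is.na(s); hd <- !is.na(d)
  add(c(s[hs], i[hs]), c(i[hs], s[hs]), rep(-alpha[hs] / 2, 2))
  add(c(d[hd], i[hd]), c(i[hd], d[hd]), rep(-alpha[hd] / 2, 2))
  add(s[hs], s[hs], alpha[hs] / 4)
  add(d[hd], d[hd], alpha[hd] / 4)
  both <- hs & hd
  add(c(s[both], d[both]), c(d[both], s[both]), rep(alpha[both] / 4, 2))
  Ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  relationship_matrix(Ainv, ped$id, "A_inverse")
}

#' Prune a pedigree to a set of individuals and their ancestors
#'
#' Drops individuals that are neither in `keep_ids` nor ancestors of any of
#' them. Relationships among the retained individuals are unchanged, so the
#' pruned pedigree gives exactly the same A (and A-inverse) block for them —
#' the usual preparation before fitting an animal model to phenotyped
#' animals.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`).
#' @param keep_ids ids that must be retained (e.g. cows with records).
#' @return The pruned pedigree, original order and class preserved.
#' @export
prune_pedigree <- function(ped, keep_ids) {
  ped_df <- as.data.frame(ped)
  stopifnot(all(keep_ids %in% ped_df$id))
  keep <- unique(as.character(keep_ids))
  frontier <- keep
  while (length(frontier) > 0) {
    i <- match(frontier, ped_df$id)
    parents <- setdiff(stats::na.omit(c(ped_df$sire[i], ped_df$dam[i])), keep)
    keep <- c(keep, parents)
    frontier <- parents
  }
  out <- ped_df[ped_df$id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ped)
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \deqn{G = Z_c Z_c' / k,\quad k = 2\sum_j p_j (1 - p_j)}
#'
#' where `Z_c` is the dosage matrix with each column centered by twice the
#' observed counted-allele frequency. G is invariant to which allele is
#' counted at any SNP.
#'
#' @param g a [genotype_matrix()] with at least 2 polymorphic SNPs.
#' @param method currently only `"vanraden1"`.
#' @return A [relationship_matrix()] of kind `"G"`.
#' @export
compute_G <- function(g, method = c("vanraden1")) {
  method <- match.arg(method)
  stopifnot(inherits(g, "genotype_matrix"))
  p <- g$allele_freq
  k <- 2 * sum(p * (1 - p))
  if (sum(p > 0 & p < 1) < 2) stop("need at least 2 polymorphic SNPs")
  if (k <= 0) stop("all SNPs monomorphic: VanRaden scaling is zero")
  Zc <- sweep(g$dosages, 2, 2 * p)
  G <- tcrossprod(Zc) / k
  relationship_matrix(G, rownames(g$dosages), "G")
}

#' Inverse of the single-step (H) relationship matrix
#'
#' Builds
#' \deqn{H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}
#'   \end{pmatrix}}
#' on the genotyped block, where \eqn{G^* = (1 - w)\,G_{tuned} + w\,A_{22}}.
#' Tuning (on by default) rescales G linearly so that its mean diagonal and
#' mean off-diagonal match those of the pedigree block \eqn{A_{22}}, aligning
#' the two relationship scales; blending with weight `w` guarantees
#' invertibility.
#'
#' @param A pedigree relationship matrix (kind `"A"`), covering all animals.
#' @param G genomic relationship matrix over the genotyped animals (its ids
#'   must be a subset of A's).
#' @param genotyped_ids ids of the genotyped animals (defaults to G's ids);
#'   may be empty, in which case H = A exactly.
#' @param blend_weight proportion `w` of `A22` blended into G (default 0.05).
#' @param tune rescale G to match A22's mean diagonal/off-diagonal?
#' @return A [relationship_matrix()] of kind `"H_inverse"`, in A's id order.
#' @export
compute_H_inverse <- function(A, G = NULL, genotyped_ids = NULL,
                              blend_weight = 0.05, tune = TRUE) {
  stopifnot(inherits(A, "relationship_matrix"), A$kind == "A")
  if (is.null(genotyped_ids) && !is.null(G)) genotyped_ids <- G$ids
  Ainv <- solve(as.matrix(A$values))
  if (is.null(genotyped_ids) || length(genotyped_ids) == 0) {
    dimnames(Ainv) <- list(A$ids, A$ids)
    return(relationship_matrix(Ainv, A$ids, "H_inverse"))
  }
  stopifnot(inherits(G, "relationship_matrix"), G$kind == "G")
  if (!all(genotyped_ids %in% A$ids))
    stop("genotyped_ids must all appear in the pedigree matrix")
  if (!all(genotyped_ids %in% G$ids))
    stop("genotyped_ids must all appear in G")
  gi <- match(genotyped_ids, A$ids)
  A22 <- as.matrix(A$values)[gi, gi, drop = FALSE]
  Gm <- as.matrix(G$values)[match(genotyped_ids, G$ids),
                            match(genotyped_ids, G$ids), drop = FALSE]
  if (tune && length(gi) > 1) {
    md_A <- mean(diag(A22)); mo_A <- mean(A22[upper.tri(A22)])
    md_G <- mean(diag(Gm));  mo_G <- mean(Gm[upper.tri(Gm)])
    if (abs(md_G - mo_G) < 1e-12)
      stop("cannot tune G: no spread between diagonal and off-diagonal")
    bcoef <- (md_A - mo_A) / (md_G - mo_G)
    acoef <- md_A - bcoef * md_G
    Gm <- acoef + bcoef * Gm
  }
  Gstar <- (1 - blend_weight) * Gm + blend_weight * A22
  ev <- eigen(Gstar, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(abs(ev)))
    stop("G* is numerically singular; increase blend_weight")
  Hinv <- Ainv
  Hinv[gi, gi] <- Hinv[gi, gi] + solve(Gstar) - solve(A22)
  Hinv <- (Hinv + t(Hinv)) / 2
  dimnames(Hinv) <- list(A$ids, A$ids)
  relationship_matrix(Hinv, A$ids, "H_inverse")
}
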