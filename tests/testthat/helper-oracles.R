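# Independent oracles used across the suite. These deliberately use naive
# algorithms (recursion, quadratic loops, direct summation) so that they share
# no code path with the package implementations they check.

# Additive relationship between two pedigree members by the recursive
# definition: a(i,i) = 1 + 0.5 a(s_i, d_i); for j older than i,
# a(i,j) = 0.5 [a(s_i, j) + a(d_i, j)]; terms with unknown parents vanish.
oracle_A <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  memo <- new.env(hash = TRUE)
  a <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i < j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    si <- if (is.na(s[i])) 0 else s[i]
    di <- if (is.na(d[i])) 0 else d[i]
    val <- if (i == j) 1 + 0.5 * a(si, di)
           else 0.5 * (a(si, j) + a(di, j))
    memo[[key]] <- val
    val
  }
  out <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) out[i, j] <- out[j, i] <- a(i, j)
  out
}

# Random pedigree allowing consanguineous matings (so inbreeding arises).
random_pedigree <- function(n, founder_frac = 0.3, seed = 1) {
  set.seed(seed)
  n_f <- max(2, round(n * founder_frac))
  sire <- dam <- rep(NA_character_, n)
  ids <- paste0("P", seq_len(n))
  for (i in seq((n_f + 1), n)) {
    pick <- sample(seq_len(i - 1), 2)
    sire[i] <- ids[pick[1]]
    dam[i] <- ids[pick[2]]
  }
  ped <- data.frame(id = ids, sire = sire, dam = dam,
                    sex = sample(c("M", "F"), n, replace = TRUE),
                    generation = 0L, stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Dense partitioned single-step relationship matrix (textbook form):
#   H11 = A11 + A12 A22^-1 (G* - A22) A22^-1 A21,  H12 = A12 A22^-1 G*,
#   H22 = G*.
oracle_H <- function(A, Gstar, gi) {
  ni <- setdiff(seq_len(nrow(A)), gi)
  A22i <- solve(A[gi, gi])
  H <- matrix(0, nrow(A), ncol(A))
  H[ni, ni] <- A[ni, ni] +
    A[ni, gi] %*% A22i %*% (Gstar - A[gi, gi]) %*% A22i %*% A[gi, ni]
  H[ni, gi] <- A[ni, gi] %*% A22i %*% Gstar
  H[gi, ni] <- t(H[ni, gi])
  H[gi, gi] <- Gstar
  H
}

# Blend/tune G* exactly as documented, written independently.
oracle_Gstar <- function(A22, G, w, tune) {
  if (tune) {
    b <- (mean(diag(A22)) - mean(A22[upper.tri(A22)])) /
      (mean(diag(G)) - mean(G[upper.tri(G)]))
    a <- mean(diag(A22)) - b * mean(diag(G))
    G <- a + b * G
  }
  (1 - w) * G + w * A22
}

# One-sided hypergeometric tail P(X >= k) by direct summation of the
# probability mass, computed with log-binomial coefficients for stability.
oracle_hyper_tail <- function(k, N, K, n) {
  kk <- max(k, max(0, n + K - N)):min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Exact GLS Wald z for the SNP coefficient in y ~ X + x at fixed V0.
oracle_gls_wald <- function(y, X, x, V0) {
  W <- cbind(X, x)
  Vi <- solve(V0)
  C <- solve(crossprod(W, Vi %*% W))
  b <- C %*% crossprod(W, Vi %*% y)
  j <- ncol(W)
  b[j] / sqrt(C[j, j])
}

# Quadratic all-pairs SNP-in-gene check.
oracle_snp_gene <- function(map, ann, flank) {
  out <- list()
  for (gi in seq_len(nrow(ann))) {
    hit <- map$chrom == ann$chrom[gi] &
      map$pos >= ann$start[gi] - flank & map$pos <= ann$end[gi] + flank
    if (any(hit)) out[[ann$gene_id[gi]]] <- map$snp_id[hit]
  }
  out
}

# Small deterministic genotype fixture.
toy_genotypes <- function(dosages, chrom = NULL, pos = NULL) {
  d <- as.matrix(dosages)
  m <- ncol(d)
  genotype_matrix(
    d,
    data.frame(snp_id = paste0("s", seq_len(m)),
               chrom = if (is.null(chrom)) rep("1", m) else chrom,
               pos = if (is.null(pos)) seq_len(m) * 1000 else pos),
    individual_ids = paste0("i", seq_len(nrow(d))),
    snp_ids = paste0("s", seq_len(m))
  )
}
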