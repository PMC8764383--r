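#' Validate a repeated binary health-record table
#'
#' @param records data.frame with columns `cow_id`, `lactation`, `hys_id`,
#'   `outcome` (0/1). Lactation numbers of 5 or more are collapsed into the
#'   class `"5+"`.
#' @return The table with `lactation` as a factor, class `health_records`.
#' @export
health_records <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("cow_id", "lactation", "hys_id", "outcome") %in%
                  names(records)))
  if (!all(records$outcome %in% c(0, 1))) stop("outcome must be 0/1")
  lact <- as.character(records$lactation)
  num <- suppressWarnings(as.numeric(lact))
  lact[!is.na(num) & num >= 5] <- "5+"
  present <- intersect(c("1", "2", "3", "4", "5+"), unique(lact))
  records$lactation <- factor(lact, levels = present)
  records$cow_id <- as.character(records$cow_id)
  records$hys_id <- as.character(records$hys_id)
  class(records) <- c("health_records", "data.frame")
  records
}

#' Fit the single-step genomic threshold (probit) model
#'
#' Binary records are modeled through a latent liability
#' \deqn{l = X\beta + Z_1 hys + Z_2 u + W pe + e,\quad e \sim N(0, I)}
#' with outcome 1 when `l > 0`. Fixed effects are the lactation classes
#' (cell-means coding, so the first class estimate plays the role of the
#' intercept); `hys ~ N(0, I s2_hys)`, `u ~ N(0, H s2_u)` via the supplied
#' `H^-1`, and `pe ~ N(0, I s2_pe)`. Estimation is by Gibbs sampling with
#' latent-liability data augmentation: liabilities from truncated normals,
#' location effects from their normal full conditionals (single-site for
#' `u`, so only `H^-1` is ever needed), variance components from
#' scaled-inverse-chi-square full conditionals with `nu` prior degrees of
#' freedom and scales taken from the starting values. The residual liability
#' variance is fixed at 1 for identifiability.
#'
#' @param records a [health_records()] table (or the `records` element of
#'   [simulate_health_records()]).
#' @param H_inv a [relationship_matrix()] of kind `"H_inverse"` or
#'   `"A_inverse"` covering (at least) every cow with records; dense or
#'   sparse.
#' @param n_iter,burn_in,thin chain settings (defaults 20000 / 5000 / 10).
#' @param start_var named numeric starting values for the `hys`, `u`, `pe`
#'   variances.
#' @param prior_scale named numeric scales of the variance priors (defaults
#'   to the starting values).
#' @param nu prior degrees of freedom of the scaled-inverse-chi-square
#'   variance priors (default 4).
#' @param seed integer seed (set before the chain; fixed seed gives a
#'   bitwise-identical chain).
#' @return An object of class `threshold_fit`: posterior means/SDs of `beta`
#'   (per lactation class), `hys`, `u` (named by the H ids; the genotyped
#'   sub-vector is the input to [backsolve_snp_effects()]), `pe`; a
#'   `variances` summary table with posterior mean, SD, 95% interval and
#'   effective sample size; and the raw `var_samples`.
#' @export
fit_threshold_model <- function(records, H_inv,
                                n_iter = 20000, burn_in = 5000, thin = 10,
                                start_var = c(hys = 0.1, u = 0.1, pe = 0.1),
                                prior_scale = start_var, nu = 4, seed = NULL) {
  if (!inherits(records, "health_records")) records <- health_records(records)
  stopifnot(inherits(H_inv, "relationship_matrix"))
  if (!H_inv$kind %in% c("H_inverse", "A_inverse"))
    stop("H_inv must be an inverse relationship matrix (H_inverse/A_inverse)")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  ids <- H_inv$ids
  if (!all(records$cow_id %in% ids))
    stop("every cow with records must appear in the relationship matrix")
  Hm <- methods::as(methods::as(methods::as(
    Matrix::Matrix(H_inv$values, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  cows <- unique(records$cow_id)
  lact <- as.integer(records$lactation) - 1L
  hys_levels <- sort(unique(records$hys_id))
  hys <- match(records$hys_id, hys_levels) - 1L
  anim <- match(records$cow_id, ids) - 1L
  pe <- match(records$cow_id, cows) - 1L
  if (!is.null(seed)) set.seed(seed)
  res <- gibbs_threshold_cpp(
    as.integer(records$outcome), lact, hys, anim, pe,
    nlevels(records$lactation), length(hys_levels), length(ids),
    length(cows), Hm@p, Hm@i, Hm@x,
    as.integer(n_iter), as.integer(burn_in), as.integer(thin),
    nu, prior_scale[["hys"]], prior_scale[["u"]], prior_scale[["pe"]],
    start_var[["hys"]], start_var[["u"]], start_var[["pe"]])
  vs <- res$var_samples
  colnames(vs) <- c("sigma2_hys", "sigma2_u", "sigma2_pe")
  variances <- data.frame(
    component = colnames(vs),
    mean = colMeans(vs), sd = apply(vs, 2, sd),
    lower_95 = apply(vs, 2, quantile, 0.025),
    upper_95 = apply(vs, 2, quantile, 0.975),
    ess = apply(vs, 2, effective_sample_size),
    row.names = NULL
  )
  structure(list(
    beta = setNames(res$beta[, 1], levels(records$lactation)),
    beta_sd = setNames(res$beta[, 2], levels(records$lactation)),
    hys = setNames(res$hys[, 1], hys_levels),
    hys_sd = setNames(res$hys[, 2], hys_levels),
    u = setNames(res$u[, 1], ids),
    u_sd = setNames(res$u[, 2], ids),
    pe = setNames(res$pe[, 1], cows),
    pe_sd = setNames(res$pe[, 2], cows),
    variances = variances, var_samples = vs,
    n_records = nrow(records), n_animals = length(ids),
    n_kept = res$n_kept,
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    nu = nu, start_var = start_var, prior_scale = prior_scale)
  ), class = "threshold_fit")
}

# initial-positive-sequence effective sample size from the empirical acf
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(NA_real_)
  rho <- drop(acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf)[-1]
  neg <- which(rho < 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
  max(1, n / (1 + 2 * sum(rho)))
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Single-step threshold model (Gibbs),", x$n_records, "records,",
      x$n_animals, "animals,", x$n_kept, "posterior samples\n")
  cat("\nVariance components (residual liability variance fixed at 1):\n")
  print(x$variances, row.names = FALSE, digits = 3)
  h2 <- x$var_samples[, "sigma2_u"] /
    (rowSums(x$var_samples) + 1)
  cat(sprintf("\nLiability-scale h2: posterior mean %.3f [%.3f, %.3f]\n",
              mean(h2), quantile(h2, 0.025), quantile(h2, 0.975)))
  invisible(x)
}

#' @export
summary.threshold_fit <- function(object, ...) {
  h2 <- object$var_samples[, "sigma2_u"] / (rowSums(object$var_samples) + 1)
  out <- list(variances = object$variances,
              beta = data.frame(class = names(object$beta),
                                mean = object$beta, sd = object$beta_sd,
                                row.names = NULL),
              h2 = c(mean = mean(h2),
                     lower_95 = unname(quantile(h2, 0.025)),
                     upper_95 = unname(quantile(h2, 0.975))),
              n_records = object$n_records, n_kept = object$n_kept)
  class(out) <- "summary.threshold_fit"
  out
}

#' @export
print.summary.threshold_fit <- function(x, ...) {
  cat("Threshold model:", x$n_records, "records,", x$n_kept,
      "posterior samples\n\nVariance components:\n")
  print(x$variances, row.names = FALSE, digits = 3)
  cat("\nLactation-class effects (liability scale):\n")
  print(x$beta, row.names = FALSE, digits = 3)
  cat(sprintf("\nLiability h2: %.3f [%.3f, %.3f]\n", x$h2["mean"],
              x$h2["lower_95"], x$h2["upper_95"]))
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) object$beta

#' Back-solve SNP effects from genomic breeding values
#'
#' Recovers marker effects from the genomic breeding values of the genotyped
#' animals by \deqn{\hat s = D M' [M D M']^{-1} \hat a_g} where `M` is the
#' dosage matrix of the genotyped animals, column-centered by twice the
#' counted-allele frequency (the same centering as the G matrix), and `D` a
#' diagonal matrix of per-SNP weights (identity by default).
#'
#' @param a_g named numeric vector of genomic breeding values; names must
#'   match rows of `g`.
#' @param g a [genotype_matrix()] of the genotyped animals.
#' @param D optional per-SNP weight vector (default all 1).
#' @param ridge optional ridge proportion added to the diagonal of `MDM'`
#'   (times its mean diagonal) instead of the pseudo-inverse solve.
#' @details Because `M` is column-centered by observed frequencies, its
#'   columns sum to zero and `MDM'` always carries the all-ones vector in
#'   its kernel: only deviations of `a_g` from their mean are identifiable.
#'   `a_g` is therefore mean-centered and the system solved with a
#'   symmetric pseudo-inverse (eigenvalues below `1e-10` of the largest are
#'   treated as null); `M s` then reproduces the centered `a_g` exactly
#'   whenever it lies in the row space of `M`.
#' @return Named numeric vector of SNP effects, with attribute
#'   `"fitted_a_g"` (`M s`, equal to the mean-centered `a_g` up to the
#'   rank of `M`).
#' @export
backsolve_snp_effects <- function(a_g, g, D = NULL, ridge = 0) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- rownames(g$dosages)
  if (is.null(names(a_g))) {
    stopifnot(length(a_g) == length(ids))
    names(a_g) <- ids
  }
  if (!all(ids %in% names(a_g)))
    stop("a_g must cover every genotyped animal")
  a <- a_g[ids] - mean(a_g[ids])
  M <- sweep(g$dosages, 2, 2 * g$allele_freq)
  if (is.null(D)) D <- rep(1, ncol(M))
  stopifnot(length(D) == ncol(M), all(D >= 0))
  MD <- sweep(M, 2, D, `*`)
  K <- tcrossprod(MD, M)                    # M D M'
  if (ridge > 0) {
    sol <- solve(K + diag(ridge * mean(diag(K)), nrow(K)), a)
  } else {
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- eg$values > 1e-10 * max(eg$values)
    if (!any(keep))
      stop("MDM' is numerically zero; no SNP variation to back-solve")
    sol <- eg$vectors[, keep, drop = FALSE] %*%
      (crossprod(eg$vectors[, keep, drop = FALSE], a) / eg$values[keep])
  }
  s <- drop(crossprod(MD, sol))
  names(s) <- colnames(M)
  attr(s, "fitted_a_g") <- drop(M %*% s)
  s
}

#' Variance decomposition over 2.0 Mb SNP windows
#'
#' Tiles each chromosome into disjoint half-open windows
#' `[start, start + window_bp)` from position 1 and, for each window,
#' computes the genomic value restricted to its SNPs,
#' \eqn{u_i = \sum_{j \in i} M_j s_j}, across the genotyped animals. The
#' variance of `u_i` is reported as a percentage of the empirical variance of
#' the total genomic value `M s` (`pct_var_gebv`; this equals 100 for a
#' single window covering everything) and, when `sigma_u2` is supplied, of
#' the additive genetic variance (`pct_var_additive`, the published scale).
#' A sliding-window mode (step of one SNP, same width) is available.
#'
#' @param s named SNP-effect vector from [backsolve_snp_effects()].
#' @param g the [genotype_matrix()] of the genotyped animals.
#' @param sigma_u2 optional additive genetic variance for the published
#'   denominator.
#' @param window_bp window width in bp (default 2,000,000).
#' @param sliding use overlapping windows anchored at every SNP?
#' @return A data.frame of class `window_variance`: `chrom`, `start`, `end`,
#'   `n_snps`, `var_window`, `pct_var_gebv`, `pct_var_additive`.
#' @export
window_variance <- function(s, g, sigma_u2 = NULL, window_bp = 2e6,
                            sliding = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  map <- g$map
  if (is.null(names(s))) {
    stopifnot(length(s) == nrow(map))
    names(s) <- map$snp_id
  } else if (!all(names(s) == map$snp_id)) {
    s <- s[map$snp_id]
  }
  if (anyNA(s)) stop("s must provide an effect for every SNP in g")
  M <- sweep(g$dosages, 2, 2 * g$allele_freq)
  total <- drop(M %*% s)
  v_total <- var(total)
  rows <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    if (sliding) {
      starts <- pos
    } else {
      starts <- seq(1, max(pos), by = window_bp)
    }
    for (st in starts) {
      en <- st + window_bp
      inw <- idx[pos >= st & pos < en]
      vw <- if (length(inw) == 0) 0 else
        var(drop(M[, inw, drop = FALSE] %*% s[inw]))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = st, end = en, n_snps = length(inw),
        var_window = vw,
        pct_var_gebv = if (v_total > 0) 100 * vw / v_total else 0,
        pct_var_additive = if (!is.null(sigma_u2)) 100 * vw / sigma_u2
                           else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("window_variance", "data.frame")
  out
}

#' @export
print.window_variance <- function(x, n = 6, ...) {
  cat("window_variance:", nrow(x), "windows on",
      length(unique(x$chrom)), "chromosome(s)\n")
  top <- x[order(-x$pct_var_gebv), ][seq_len(min(n, nrow(x))), ]
  print(as.data.frame(top), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Needle plot of per-window variance percentages
#'
#' @param x a `window_variance` table.
#' @param which `"gebv"` or `"additive"` denominator.
#' @param ... passed to [graphics::plot()].
#' @export
plot.window_variance <- function(x, which = c("gebv", "additive"), ...) {
  which <- match.arg(which)
  yv <- if (which == "gebv") x$pct_var_gebv else x$pct_var_additive
  chroms <- unique(x$chrom)
  offset <- setNames(c(0, cumsum(vapply(chroms, function(ch)
    max(x$end[x$chrom == ch]), numeric(1))))[seq_along(chroms)], chroms)
  mid <- (x$start + x$end) / 2 + offset[x$chrom]
  graphics::plot(mid, yv, type = "h",
                 col = (match(x$chrom, chroms) %% 2) + 1,
                 xlab = "window midpoint", ylab = "% genetic variance", ...)
  invisible(x)
}
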