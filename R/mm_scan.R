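#' Genotype coding modes
#' @return Character vector of the four supported gene-action codings.
#' @export
genotype_coding_modes <- function()
  c("additive", "dominance", "recessive", "overdominance")

#' Recode allele dosages for a gene-action model
#'
#' Maps dosages (0, 1, 2) to a single regressor per mode:
#' additive (0, 1, 2), dominance (0, 1, 1), recessive (0, 0, 1),
#' overdominance (0, 1, 0).
#'
#' @param dosages numeric vector with entries in \{0, 1, 2\}.
#' @param mode one of [genotype_coding_modes()].
#' @return Numeric vector of the coded genotypes.
#' @export
code_genotype <- function(dosages, mode = genotype_coding_modes()) {
  mode <- match.arg(mode)
  if (!all(dosages %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  codes <- switch(mode,
    additive      = c(0, 1, 2),
    dominance     = c(0, 1, 1),
    recessive     = c(0, 0, 1),
    overdominance = c(0, 1, 0)
  )
  codes[dosages + 1]
}

#' Fit the polygenic null model of the two-step scan
#'
#' Fits `y = Xb + u + e` with `u ~ N(0, G sigma_u^2)` and
#' `e ~ N(0, I sigma_e^2)` by REML. Because there is a single random effect,
#' the restricted likelihood is profiled down to a one-dimensional search
#' over the variance ratio `delta = sigma_u^2 / sigma_e^2` on the eigenbasis
#' of G; `delta` is bounded in `[1e-6, 1e6]` and located by golden-section
#' search on the log scale.
#'
#' @param y numeric phenotype vector (here the 0/1 extreme-group score,
#'   analyzed on the observed scale by a linear model).
#' @param G a [relationship_matrix()] of kind `"G"` (or any PSD matrix), in
#'   the order of `y`.
#' @param X fixed-effect design matrix; default intercept only.
#' @return An object of class `null_fit` with elements `var_u`, `var_e`,
#'   `fixed_estimates`, `V0`, `V0_inv`, `residuals`, `log_likelihood`
#'   (restricted), `X` and the eigendecomposition used.
#' @export
fit_null_model <- function(y, G, X = NULL) {
  if (inherits(G, "relationship_matrix")) G <- as.matrix(G$values)
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  p <- ncol(X)
  eg <- eigen(G, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)

  reml_profile <- function(log_delta) {
    delta <- exp(log_delta)
    w <- delta * evals + 1
    XtW <- Xt / w
    XtWX <- crossprod(Xt, XtW)
    b <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2e) + sum(log(w)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    list(ll = as.numeric(ll), b = b, s2e = s2e, delta = delta)
  }
  opt <- optimize(function(ld) -reml_profile(ld)$ll,
                  interval = log(c(1e-6, 1e6)), tol = 1e-8)
  fit <- reml_profile(opt$minimum)
  var_e <- fit$s2e
  var_u <- fit$delta * var_e
  if (!is.finite(var_e) || var_e < 0)
    stop("null-model REML did not converge to admissible variances")
  w0 <- fit$delta * evals + 1
  V0_inv <- eg$vectors %*% (t(eg$vectors) / (w0 * var_e))
  V0 <- eg$vectors %*% (t(eg$vectors) * (w0 * var_e))
  b <- drop(fit$b)
  names(b) <- colnames(X)
  structure(list(
    var_u = var_u, var_e = var_e, fixed_estimates = b,
    V0 = V0, V0_inv = V0_inv,
    residuals = drop(y - X %*% fit$b),
    log_likelihood = fit$ll, X = X, n = n,
    eigen_values = evals
  ), class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat("Polygenic null model (REML)\n")
  cat(sprintf("  n = %d, sigma_u^2 = %.4f, sigma_e^2 = %.4f, h2 = %.3f\n",
              x$n, x$var_u, x$var_e, x$var_u / (x$var_u + x$var_e)))
  cat("  fixed effects:\n")
  print(round(x$fixed_estimates, 4))
  invisible(x)
}

#' @export
coef.null_fit <- function(object, ...) object$fixed_estimates

#' @export
summary.null_fit <- function(object, ...) {
  out <- list(
    variances = c(sigma_u2 = object$var_u, sigma_e2 = object$var_e,
                  h2 = object$var_u / (object$var_u + object$var_e)),
    fixed = object$fixed_estimates,
    restricted_log_likelihood = object$log_likelihood, n = object$n
  )
  class(out) <- "summary.null_fit"
  out
}

#' @export
print.summary.null_fit <- function(x, ...) {
  cat("Polygenic null model (REML), n =", x$n, "\n\nVariance components:\n")
  print(round(x$variances, 4))
  cat("\nFixed effects:\n")
  print(round(x$fixed, 4))
  cat("\nRestricted log-likelihood:", round(x$restricted_log_likelihood, 3),
      "\n")
  invisible(x)
}

#' Two-step association scan over SNPs and genotype codings
#'
#' Second step of the scan: with the null covariance `V0` fixed, each SNP's
#' coded column `x` is tested with the score statistic
#' \deqn{z = \frac{x' V_0^{-1} (y - X\hat b)}{\sqrt{x' P x}}, \quad
#'   P = V_0^{-1} - V_0^{-1} X (X'V_0^{-1}X)^{-1} X' V_0^{-1}}
#' which equals the Wald z of the SNP coefficient in a GLS fit of
#' `y ~ X + x` at fixed `V0` and is asymptotically standard normal. The
#' effect estimate is `beta = x'V0^-1 r / (x'Px)`. Columns that are constant
#' after coding are flagged and skipped (NA statistics), not an error.
#'
#' @param null a [fit_null_model()] fit on the same individuals, same order.
#' @param g a [genotype_matrix()].
#' @param modes character vector of codings to test (default additive and
#'   recessive).
#' @return A data.frame of class `scan_result` with one row per SNP x coding:
#'   `snp_id`, `chrom`, `pos`, `coding`, `beta`, `z`, `p`, `skipped`; the
#'   per-coding genomic inflation factor is attached as attribute `"lambda"`.
#' @export
scan_snps <- function(null, g, modes = c("additive", "recessive")) {
  stopifnot(inherits(null, "null_fit"), inherits(g, "genotype_matrix"))
  modes <- match.arg(modes, genotype_coding_modes(), several.ok = TRUE)
  if (nrow(g$dosages) != null$n)
    stop("genotypes and null model cover different numbers of individuals")
  Vi <- null$V0_inv
  X <- null$X
  r <- null$residuals
  Vir <- Vi %*% r
  ViX <- Vi %*% X
  XtViX_inv <- solve(crossprod(X, ViX))
  out <- vector("list", length(modes))
  for (mi in seq_along(modes)) {
    mode <- modes[mi]
    C <- apply(g$dosages, 2, code_genotype, mode = mode)
    const <- apply(C, 2, function(x) all(x == x[1]))
    s <- drop(crossprod(C, Vir))
    ViC <- Vi %*% C
    i_raw <- colSums(C * ViC)
    XtViC <- crossprod(X, ViC)                       # p x m
    i_adj <- i_raw - colSums(XtViC * (XtViX_inv %*% XtViC))
    bad <- const | i_adj <= 0
    z <- beta <- rep(NA_real_, length(s))
    z[!bad] <- s[!bad] / sqrt(i_adj[!bad])
    beta[!bad] <- s[!bad] / i_adj[!bad]
    p <- 2 * pnorm(-abs(z))
    out[[mi]] <- data.frame(
      snp_id = g$map$snp_id, chrom = g$map$chrom, pos = g$map$pos,
      coding = mode, beta = beta, z = z, p = p,
      skipped = bad,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("scan_result", "data.frame")
  lam <- vapply(split(res$z, res$coding), function(zz) {
    zz <- zz[is.finite(zz)]
    if (length(zz) == 0) NA_real_ else median(zz^2) / 0.4549364
  }, numeric(1))
  attr(res, "lambda") <- lam
  res
}

#' @export
print.scan_result <- function(x, n = 6, ...) {
  cat("scan_result:", length(unique(x$snp_id)), "SNPs x",
      length(unique(x$coding)), "coding(s)\n")
  lam <- attr(x, "lambda")
  if (!is.null(lam))
    cat("  genomic inflation lambda:",
        paste(sprintf("%s = %.3f", names(lam), lam), collapse = ", "), "\n")
  top <- x[order(x$p), ][seq_len(min(n, nrow(x))), ]
  cat("  top associations:\n")
  print(as.data.frame(top), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Genomic inflation factor and Q-Q table
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)`; the Q-Q table pairs the observed
#' `-log10 p`, sorted, with the expected uniform quantiles `rank / (n + 1)`.
#'
#' @param result a [scan_snps()] result (at least 100 tested SNPs advised).
#' @param coding which coding to diagnose (default first present).
#' @return A list of class `genomic_inflation`: `lambda` and `qq`
#'   (data.frame `expected`, `observed` on the -log10 scale).
#' @export
genomic_inflation <- function(result, coding = NULL) {
  stopifnot(inherits(result, "scan_result"))
  if (is.null(coding)) coding <- result$coding[1]
  sub <- result[result$coding == coding & !result$skipped, ]
  if (nrow(sub) < 100)
    warning("fewer than 100 tested SNPs; lambda is unstable")
  lambda <- median(sub$z^2) / 0.4549364
  pobs <- sort(sub$p)
  n <- length(pobs)
  qq <- data.frame(expected = -log10(seq_len(n) / (n + 1)),
                   observed = -log10(pobs))
  structure(list(lambda = lambda, qq = qq, coding = coding),
            class = "genomic_inflation")
}

#' @export
print.genomic_inflation <- function(x, ...) {
  cat(sprintf("genomic inflation (%s coding): lambda = %.4f over %d SNPs\n",
              x$coding, x$lambda, nrow(x$qq)))
  invisible(x)
}

#' Manhattan plot of a scan result
#'
#' @param x a `scan_result`.
#' @param coding coding to plot (default first present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.scan_result <- function(x, coding = NULL, ...) {
  if (is.null(coding)) coding <- x$coding[1]
  sub <- x[x$coding == coding & !x$skipped, ]
  chroms <- unique(sub$chrom)
  offset <- setNames(c(0, cumsum(vapply(chroms, function(ch)
    max(sub$pos[sub$chrom == ch]), numeric(1))))[seq_along(chroms)], chroms)
  gx <- sub$pos + offset[sub$chrom]
  graphics::plot(gx, -log10(sub$p), pch = 20, cex = 0.5,
                 col = (match(sub$chrom, chroms) %% 2) + 1,
                 xlab = "genome position", ylab = "-log10 p",
                 main = paste(coding, "scan"), ...)
  invisible(x)
}

#' Q-Q plot of a scan result
#'
#' @param x a `genomic_inflation` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.genomic_inflation <- function(x, ...) {
  graphics::plot(x$qq$expected, x$qq$observed, pch = 20, cex = 0.5,
                 xlab = "expected -log10 p", ylab = "observed -log10 p",
                 main = sprintf("Q-Q (%s), lambda = %.3f", x$coding,
                                x$lambda), ...)
  graphics::abline(0, 1, col = 2)
  invisible(x)
}

#' Write a scan result to a tab-delimited association file
#'
#' @param result a `scan_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(result, path) {
  write.table(as.data.frame(result)[, c("chrom", "pos", "snp_id", "coding",
                                        "beta", "z", "p")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
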