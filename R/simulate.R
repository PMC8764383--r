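#' Configuration for the genotype / binary-trait simulator
#'
#' Defines the study conditions under which genotypes and an extreme-group
#' binary phenotype are generated: a biallelic SNP panel in linkage
#' equilibrium (optionally with block correlation), liability QTL with
#' additive or non-additive gene action, a polygenic background, and a
#' liability threshold set from the target case proportion.
#'
#' @param n_individuals number of individuals.
#' @param n_snps number of SNPs.
#' @param n_chromosomes number of chromosomes; SNPs are split as evenly as
#'   possible across them.
#' @param chrom_length_bp chromosome length in bp (positions are 1-based).
#' @param maf_range length-2 numeric in (0, 0.5]: per-SNP allele frequencies
#'   are drawn uniformly from this interval.
#' @param qtl data.frame with columns `snp` (1-based SNP index), `mode`
#'   (one of `"additive"`, `"dominance"`, `"recessive"`, `"overdominance"`)
#'   and `effect` (liability-scale effect size), or `NULL` for no QTL.
#' @param h2_liability proportion of liability variance of genetic origin
#'   (QTL plus polygenic background), in `[0, 1]`.
#' @param prevalence_or_split target proportion of cases (high group) in
#'   (0, 1); the liability threshold is the standard-normal quantile of
#'   `1 - prevalence_or_split`.
#' @param ld_block_snps if not `NULL`, adjacent SNPs are generated in
#'   correlated blocks of this many markers (copy-with-mutation), giving a
#'   crude stand-in for linkage disequilibrium.
#' @param ld_mutation per-allele copy-error probability inside a block.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_snps, n_chromosomes = 1,
                       chrom_length_bp = 100e6, maf_range = c(0.05, 0.5),
                       qtl = NULL, h2_liability = 0.3,
                       prevalence_or_split = 0.5,
                       ld_block_snps = NULL, ld_mutation = 0.02,
                       seed = 1) {
  stopifnot(n_individuals >= 1, n_snps >= 1, n_chromosomes >= 1)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (h2_liability < 0 || h2_liability > 1)
    stop("h2_liability must be in [0, 1]")
  if (prevalence_or_split <= 0 || prevalence_or_split >= 1)
    stop("prevalence_or_split must be in (0, 1)")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    stopifnot(all(c("snp", "mode", "effect") %in% names(qtl)))
    qtl$mode <- as.character(qtl$mode)
    if (!all(qtl$mode %in% genotype_coding_modes()))
      stop("qtl mode must be one of: ",
           paste(genotype_coding_modes(), collapse = ", "))
    if (anyDuplicated(qtl$snp)) stop("qtl snp indices must be distinct")
    if (any(qtl$snp < 1 | qtl$snp > n_snps)) stop("qtl snp index out of range")
  }
  structure(list(
    n_individuals = n_individuals, n_snps = n_snps,
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    maf_range = maf_range, qtl = qtl, h2_liability = h2_liability,
    prevalence_or_split = prevalence_or_split,
    ld_block_snps = ld_block_snps, ld_mutation = ld_mutation,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate biallelic SNP genotypes
#'
#' Each SNP's counted-allele frequency is drawn uniformly from
#' `config$maf_range`; dosages are then binomial(2, p) per individual
#' (Hardy-Weinberg, linkage equilibrium). With `ld_block_snps` set, the
#' first SNP of each block is drawn fresh and subsequent block members copy
#' the previous SNP's alleles with a small per-allele mutation rate.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] with a marker map of increasing positions.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  if (is.null(config$ld_block_snps)) {
    d <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n)
  } else {
    b <- config$ld_block_snps
    mu <- config$ld_mutation
    d <- matrix(0L, nrow = n, ncol = m)
    for (j in seq_len(m)) {
      if ((j - 1) %% b == 0) {
        d[, j] <- rbinom(n, 2, p[j])
      } else {
        d[, j] <- d[, j - 1] - rbinom(n, d[, j - 1], mu) +
          rbinom(n, 2 - d[, j - 1], mu)
      }
    }
  }
  # map: contiguous chromosome blocks, sorted unique positions
  chrom_sizes <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), chrom_sizes)
  pos <- unlist(lapply(chrom_sizes, function(k)
    sort(sample.int(config$chrom_length_bp, k))), use.names = FALSE)
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)), chrom = chrom,
                    pos = pos, stringsAsFactors = FALSE)
  genotype_matrix(d, map, individual_ids = sprintf("ind%04d", seq_len(n)),
                  snp_ids = map$snp_id)
}

#' Simulate a multi-generation pedigree
#'
#' Founders (half male, half female) have unknown parents. In each later
#' generation, every female of the previous generation is mated to a sire
#' sampled from all earlier males, producing `offspring_per_mating` offspring
#' of random sex. The returned table is topologically ordered: parents always
#' precede offspring.
#'
#' @param n_founders number of founders (at least 2).
#' @param n_generations number of descendant generations (0 = founders only).
#' @param offspring_per_mating offspring per dam per generation.
#' @param seed integer seed.
#' @return A data.frame of class `pedigree` with columns `id`, `sire`, `dam`
#'   (NA for unknown), `sex` (`"M"`/`"F"`) and `generation`.
#' @export
simulate_pedigree <- function(n_founders, n_generations = 2,
                              offspring_per_mating = 2, seed = 1) {
  stopifnot(n_founders >= 2, n_generations >= 0, offspring_per_mating >= 1)
  set.seed(seed)
  id <- sprintf("A%05d", seq_len(n_founders))
  sex <- rep(c("M", "F"), length.out = n_founders)
  ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    sex = sex, generation = 0L, stringsAsFactors = FALSE)
  counter <- n_founders
  for (g in seq_len(n_generations)) {
    dams <- ped$id[ped$sex == "F" & ped$generation == g - 1L]
    males <- ped$id[ped$sex == "M" & ped$generation < g]
    if (length(dams) == 0 || length(males) == 0) break
    sires <- sample(males, length(dams), replace = TRUE)
    n_off <- length(dams) * offspring_per_mating
    off <- data.frame(
      id = sprintf("A%05d", counter + seq_len(n_off)),
      sire = rep(sires, each = offspring_per_mating),
      dam = rep(dams, each = offspring_per_mating),
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      generation = g, stringsAsFactors = FALSE
    )
    counter <- counter + n_off
    ped <- rbind(ped, off)
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate an extreme-group binary phenotype with liability QTL
#'
#' Builds a liability as the sum of QTL effects (each injected through its
#' configured genotype coding), a polygenic term over the remaining SNPs, and
#' a normal residual. The genetic part is rescaled so that it contributes the
#' configured fraction `h2_liability` of the liability variance; the residual
#' supplies the rest, so the liability has (approximately) unit variance. The
#' binary score is 1 when the liability exceeds the standard-normal quantile
#' of `1 - prevalence_or_split`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config the [sim_config()] used (its `qtl`, `h2_liability`,
#'   `prevalence_or_split` and `seed` fields are used here).
#' @return A list of class `phenotype_sim`: `phenotype` (data.frame `id`,
#'   `score`, `liability`), `qtl` (truth table with realized allele
#'   frequencies), `threshold`, and `genetic_values`.
#' @export
simulate_binary_trait <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  d <- genotypes$dosages
  n <- nrow(d)
  m <- ncol(d)
  g_qtl <- numeric(n)
  qtl <- config$qtl
  if (!is.null(qtl) && nrow(qtl) > 0) {
    for (q in seq_len(nrow(qtl))) {
      g_qtl <- g_qtl +
        qtl$effect[q] * code_genotype(d[, qtl$snp[q]], qtl$mode[q])
    }
  }
  poly_idx <- setdiff(seq_len(m), if (is.null(qtl)) integer(0) else qtl$snp)
  g_poly <- numeric(n)
  if (length(poly_idx) > 0) {
    zc <- scale(d[, poly_idx, drop = FALSE], center = TRUE, scale = FALSE)
    g_poly <- drop(zc %*% rnorm(length(poly_idx))) / sqrt(length(poly_idx))
  }
  g <- g_qtl + g_poly
  h2 <- config$h2_liability
  sg <- sd(g)
  g <- if (h2 == 0 || sg == 0) numeric(n) else g / sg * sqrt(h2)
  liability <- g + rnorm(n, 0, sqrt(1 - h2))
  threshold <- qnorm(1 - config$prevalence_or_split)
  score <- as.integer(liability > threshold)
  if (all(score == 0) || all(score == 1)) {
    warning("degenerate phenotype (single class); residuals resampled once")
    liability <- g + rnorm(n, 0, sqrt(1 - h2))
    score <- as.integer(liability > threshold)
  }
  truth <- if (is.null(qtl)) NULL else
    cbind(qtl, data.frame(snp_id = genotypes$map$snp_id[qtl$snp],
                          freq = genotypes$allele_freq[qtl$snp]))
  structure(list(
    phenotype = data.frame(id = rownames(d), score = score,
                           liability = liability, stringsAsFactors = FALSE),
    qtl = truth, threshold = threshold, genetic_values = g
  ), class = "phenotype_sim")
}

#' Configuration for the repeated binary health-record simulator
#'
#' Study conditions for producer-recorded metabolic-disorder data: each cow
#' contributes one binary record per lactation, with herd-year-season,
#' additive-genetic (pedigree-structured) and permanent-environment effects on
#' the liability scale and residual liability variance fixed at 1 (probit).
#'
#' @param n_cows number of cows with records.
#' @param max_lactation maximum lactation number per cow (class variable; at
#'   most 5, with 5 meaning "5+").
#' @param n_herd_year_seasons number of herd-year-season contemporary groups.
#' @param var_hys,var_additive,var_pe variance components on the liability
#'   scale (all >= 0).
#' @param incidence_target expected proportion of records with outcome 1.
#' @param genotyped_fraction proportion of cows flagged as genotyped.
#' @param lactation_effects numeric vector of fixed lactation-class effects
#'   (length `max_lactation`); default all zero.
#' @param seed integer seed.
#' @return A list of class `health_sim_config`.
#' @export
health_sim_config <- function(n_cows, max_lactation = 5,
                              n_herd_year_seasons = 20,
                              var_hys = 0.1, var_additive = 0.2, var_pe = 0.1,
                              incidence_target = 0.05,
                              genotyped_fraction = 1,
                              lactation_effects = NULL, seed = 1) {
  stopifnot(n_cows >= 1, max_lactation >= 1, max_lactation <= 5,
            n_herd_year_seasons >= 1)
  if (any(c(var_hys, var_additive, var_pe) < 0))
    stop("variance components must be >= 0")
  if (incidence_target <= 0 || incidence_target >= 1)
    stop("incidence_target must be in (0, 1)")
  if (genotyped_fraction <= 0 || genotyped_fraction > 1)
    stop("genotyped_fraction must be in (0, 1]")
  if (is.null(lactation_effects)) lactation_effects <- rep(0, max_lactation)
  stopifnot(length(lactation_effects) == max_lactation)
  structure(list(
    n_cows = n_cows, max_lactation = max_lactation,
    n_herd_year_seasons = n_herd_year_seasons, var_hys = var_hys,
    var_additive = var_additive, var_pe = var_pe,
    incidence_target = incidence_target,
    genotyped_fraction = genotyped_fraction,
    lactation_effects = lactation_effects, seed = as.integer(seed)
  ), class = "health_sim_config")
}

#' Simulate repeated binary health records on a pedigree
#'
#' Breeding values are gene-dropped through the pedigree (founders
#' N(0, var_additive); offspring get the parent average plus a Mendelian
#' sampling deviation scaled by parental inbreeding), which reproduces the
#' numerator-relationship covariance exactly. Each cow receives 1 to
#' `max_lactation` lactations; each cow-lactation is assigned a
#' herd-year-season group and a binary outcome from the probit liability
#'
#' \deqn{l = \mu + lact + hys + u + pe + e, \quad e \sim N(0, 1)}
#'
#' with `mu` chosen so that the expected incidence equals
#' `incidence_target`. Cows are the most recent females of the pedigree.
#'
#' @param pedigree a `pedigree` data.frame (see [simulate_pedigree()]).
#' @param config a [health_sim_config()].
#' @param genotypes optional [genotype_matrix()] whose individual ids (or, if
#'   they do not overlap the pedigree, a random subset of cows of matching
#'   size) define the genotyped subset.
#' @return A list of class `health_sim`: `records` (data.frame `cow_id`,
#'   `lactation` (factor), `hys_id`, `outcome`), `truth` (true `u` for all
#'   pedigree members, `hys`, `pe`, `intercept`), and `genotyped_ids`.
#' @export
simulate_health_records <- function(pedigree, config, genotypes = NULL) {
  stopifnot(inherits(pedigree, "pedigree"),
            inherits(config, "health_sim_config"))
  set.seed(config$seed)
  ped <- as.data.frame(pedigree)
  n_anim <- nrow(ped)
  fem <- which(ped$sex == "F")
  if (length(fem) < config$n_cows)
    stop("pedigree has fewer females (", length(fem), ") than n_cows")
  cows <- ped$id[rev(rev(fem)[seq_len(config$n_cows)])]

  u <- gene_drop_bv(ped, config$var_additive)

  n_lact <- sample.int(config$max_lactation, config$n_cows, replace = TRUE)
  cow_id <- rep(cows, n_lact)
  lact <- unlist(lapply(n_lact, seq_len), use.names = FALSE)
  nrec <- length(cow_id)
  hys_id <- sample.int(config$n_herd_year_seasons, nrec, replace = TRUE)
  hys <- rnorm(config$n_herd_year_seasons, 0, sqrt(config$var_hys))
  pe <- setNames(rnorm(config$n_cows, 0, sqrt(config$var_pe)), cows)
  vtot <- 1 + config$var_hys + config$var_additive + config$var_pe
  mu <- qnorm(config$incidence_target) * sqrt(vtot)
  eta <- mu + config$lactation_effects[lact] + hys[hys_id] +
    u[cow_id] + pe[cow_id]
  liab <- eta + rnorm(nrec)
  outcome <- as.integer(liab > 0)
  records <- data.frame(
    cow_id = cow_id,
    lactation = factor(pmin(lact, 5), levels = seq_len(min(config$max_lactation, 5)),
                       labels = lactation_labels(config$max_lactation)),
    hys_id = paste0("hys", hys_id),
    outcome = outcome, stringsAsFactors = FALSE
  )
  class(records) <- c("health_records", "data.frame")
  genotyped_ids <- if (!is.null(genotypes)) {
    ids <- rownames(genotypes$dosages)
    if (any(ids %in% ped$id)) intersect(ids, ped$id)
    else sample(cows, min(length(ids), length(cows)))
  } else {
    sample(cows, max(1, round(config$genotyped_fraction * length(cows))))
  }
  structure(list(
    records = records,
    truth = list(u = u, hys = setNames(hys, paste0("hys", seq_along(hys))),
                 pe = pe, intercept = mu,
                 lactation_effects = config$lactation_effects),
    genotyped_ids = genotyped_ids
  ), class = "health_sim")
}

lactation_labels <- function(max_lactation) {
  k <- min(max_lactation, 5)
  lab <- as.character(seq_len(k))
  if (k == 5) lab[5] <- "5+"
  lab
}

# Gene-dropping of breeding values down a topologically ordered pedigree.
# Mendelian sampling variance uses parental inbreeding from the pedigree.
gene_drop_bv <- function(ped, var_additive) {
  n <- nrow(ped)
  u <- numeric(n)
  names(u) <- ped$id
  if (var_additive == 0) return(u)
  f <- ped_inbreeding_cpp(match(ped$sire, ped$id), match(ped$dam, ped$id), n)
  sidx <- match(ped$sire, ped$id)
  didx <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- sidx[i]; d <- didx[i]
    if (is.na(s) && is.na(d)) {
      u[i] <- rnorm(1, 0, sqrt(var_additive))
    } else {
      pa <- 0; msv <- 1
      if (!is.na(s)) { pa <- pa + 0.5 * u[s]; msv <- msv - 0.25 * (1 + f[s]) }
      if (!is.na(d)) { pa <- pa + 0.5 * u[d]; msv <- msv - 0.25 * (1 + f[d]) }
      u[i] <- pa + rnorm(1, 0, sqrt(msv * var_additive))
    }
  }
  u
}

#' Case incidence of a health-record table
#'
#' @param records a data.frame with an `outcome` column of 0/1.
#' @return A list with `cases`, `records` and `percent` (cases/records x 100).
#' @export
incidence <- function(records) {
  stopifnot("outcome" %in% names(records))
  k <- sum(records$outcome == 1)
  n <- nrow(records)
  list(cases = k, records = n, percent = 100 * k / n)
}
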