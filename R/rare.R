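#' Genotype-level sequencing QC
#'
#' Applies exome-style QC: genotypes are set missing when read depth is below
#' `dp_snp` for SNPs (`dp_indel` for INDELs) or genotype quality is below
#' `gq_min`; a variant is excluded when any heterozygous carrier has allele
#' balance below `ab_lo` or above `ab_hi` (the strict reading; set
#' `ab_fraction` to a value in `(0, 1]` to instead exclude only when more
#' than that fraction of heterozygotes fail); a variant is excluded when its
#' post-masking missingness exceeds `miss_max`. The filter is idempotent.
#'
#' @param geno individuals x variants matrix in `{0,1,2}`/`NA`.
#' @param dp,gq matrices of per-genotype depth and quality (same shape).
#' @param ab matrix of heterozygous allele balance (only rows with
#'   `geno == 1` are consulted).
#' @param variant_type character vector `SNP`/`INDEL` per variant (default
#'   all `SNP`).
#' @param dp_snp,dp_indel,gq_min,ab_lo,ab_hi,miss_max thresholds.
#' @param ab_fraction `NULL` for the strict rule, else the tolerated failing
#'   heterozygote fraction above which the variant is excluded.
#' @return list with `genotypes` (surviving variants, failing calls `NA`),
#'   `excluded` (data frame `variant_id`, `reason`), `kept` (ids).
#' @export
genotype_qc <- function(geno, dp = NULL, gq = NULL, ab = NULL,
                        variant_type = NULL, dp_snp = 7, dp_indel = 10,
                        gq_min = 20, ab_lo = 0.25, ab_hi = 0.8,
                        miss_max = 0.5, ab_fraction = NULL) {
  m <- ncol(geno)
  ids <- colnames(geno) %||% sprintf("v%d", seq_len(m))
  colnames(geno) <- ids
  if (is.null(variant_type)) variant_type <- rep("SNP", m)
  dp_thr <- ifelse(variant_type == "INDEL", dp_indel, dp_snp)

  g <- geno
  if (!is.null(dp)) {
    bad <- sweep(dp, 2, dp_thr, "<")
    g[bad & !is.na(bad)] <- NA_integer_
  }
  if (!is.null(gq)) g[gq < gq_min & !is.na(gq)] <- NA_integer_

  excl <- character(0); reason <- character(0)
  if (!is.null(ab)) {
    for (j in seq_len(m)) {
      het <- which(!is.na(g[, j]) & g[, j] == 1L)
      if (!length(het)) next
      fail <- ab[het, j] < ab_lo | ab[het, j] > ab_hi
      fail <- fail[!is.na(fail)]
      bad <- if (is.null(ab_fraction)) any(fail) else mean(fail) > ab_fraction
      if (isTRUE(bad)) { excl <- c(excl, ids[j]); reason <- c(reason, "allele_balance") }
    }
  }
  miss <- colMeans(is.na(g))
  mi <- setdiff(ids[miss > miss_max], excl)
  excl <- c(excl, mi); reason <- c(reason, rep("missingness", length(mi)))

  keep <- setdiff(ids, excl)
  list(genotypes = g[, keep, drop = FALSE],
       excluded = data.frame(variant_id = excl, reason = reason,
                             stringsAsFactors = FALSE),
       kept = keep)
}

#' Read a VCF with DP/GQ/AB FORMAT fields into QC inputs
#'
#' @param path VCF path (plain text or bgzipped).
#' @return list with `genotypes`, `dp`, `gq`, `ab` matrices (individuals x
#'   variants) and `variants` (the fixed columns, with `variant_type`).
#' @export
read_qc_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  num <- function(el) {
    x <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    t(x)
  }
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  geno <- matrix(map[gsub("\\|", "/", t(gt))], nrow = ncol(gt),
                 dimnames = list(colnames(gt), rownames(gt)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fix$variant_type <- ifelse(nchar(fix$REF) != nchar(fix$ALT), "INDEL", "SNP")
  fix$variant_id <- rownames(gt)
  list(genotypes = geno, dp = num("DP"), gq = num("GQ"), ab = num("AB"),
       variants = fix)
}

#' Build per-gene variant masks across MAF bins
#'
#' Applies the six nested/overlapping burden masks plus the synonymous
#' negative control to an annotation table:
#' `M1_pLOF_HC` (high-confidence pLOF), `M2_pLOF` (any pLOF), `M3_pLOF_highmiss`
#' (pLOF + missense with CADD > 20 or REVEL > 0.5), `M4_pLOF_anymiss`
#' (pLOF + any missense), `M5_high_impact` (high-impact only),
#' `M6_missense_only` (missense, not pLOF), `S_synonymous`. Each mask is
#' crossed with the MAF bins `< 0.5%` and `< 0.005%`.
#'
#' @param annotations data frame with `variant_id`, `gene`, `consequence`
#'   (`pLOF`/`missense`/`synonymous`/`other`), `loftee` (`HC`/`LC`/`NA`),
#'   `cadd`, `revel`, `impact` (`HIGH`/...), `af`.
#' @param maf_bins upper MAF thresholds (default `c(0.005, 0.00005)`, i.e.
#'   0.5% and 0.005%).
#' @return nested list `masks[[gene]][[mask]][[bin]]` of variant id vectors;
#'   attribute `unknown_consequence` counts excluded variants.
#' @export
build_masks <- function(annotations, maf_bins = c(0.005, 0.00005)) {
  a <- annotations
  known <- a$consequence %in% c("pLOF", "missense", "synonymous", "other")
  n_unknown <- sum(!known)
  a <- a[known, , drop = FALSE]
  plof <- a$consequence == "pLOF"
  miss <- a$consequence == "missense"
  highmiss <- miss & (a$cadd > 20 | a$revel > 0.5)
  preds <- list(
    M1_pLOF_HC = plof & !is.na(a$loftee) & a$loftee == "HC",
    M2_pLOF = plof,
    M3_pLOF_highmiss = plof | highmiss,
    M4_pLOF_anymiss = plof | miss,
    M5_high_impact = a$impact == "HIGH",
    M6_missense_only = miss,
    S_synonymous = a$consequence == "synonymous")
  maf <- pmin(a$af, 1 - a$af)
  bins <- stats::setNames(maf_bins, paste0("maf_lt_", maf_bins))
  out <- list()
  for (g in unique(a$gene)) {
    ing <- a$gene == g
    out[[g]] <- lapply(preds, function(pr) {
      lapply(bins, function(b) a$variant_id[ing & pr & maf < b])
    })
  }
  attr(out, "unknown_consequence") <- n_unknown
  out
}

#' Collapse mask member variants into a per-individual burden score
#'
#' Burden is the alternate-allele count summed over member variants, capped
#' at 2. Missing genotypes count as 0; the per-gene genotype missingness is
#' attached.
#'
#' @param geno individuals x variants matrix.
#' @param members variant ids of the mask (must be non-empty).
#' @return integer vector of burden scores with attribute `missingness`.
#' @export
burden_collapse <- function(geno, members) {
  members <- intersect(members, colnames(geno))
  if (length(members) == 0) {
    message("empty mask: burden skipped")
    return(NULL)
  }
  g <- geno[, members, drop = FALSE]
  missing <- mean(is.na(g))
  g[is.na(g)] <- 0L
  b <- pmin(2L, as.integer(rowSums(g)))
  attr(b, "missingness") <- missing
  b
}

#' Aggregated Cauchy association test (ACAT)
#'
#' Combines p values via the Cauchy transform:
#' `T = sum(w * tan((0.5 - p) * pi)) / sum(w)`, `p_comb = 0.5 - atan(T)/pi`.
#' The tail is evaluated through the standard Cauchy distribution function
#' (stable against cancellation for small p), and for p below 1e-15 the
#' tangent is replaced by its asymptote `1/(p*pi)`. ACAT of k copies of one
#' p value returns that p value to machine precision.
#'
#' @param p vector of p values in `(0, 1)`.
#' @param weights nonnegative weights (default equal).
#' @export
acat <- function(p, weights = NULL) {
  if (any(p <= 0 | p >= 1)) stop("all p values must be in (0, 1)")
  if (is.null(weights)) weights <- rep(1, length(p))
  stopifnot(length(weights) == length(p), all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  # tan((0.5 - p) * pi) == 1/tan(p * pi), which stays accurate for small p
  # (the direct form evaluates tan near its pole and loses ~5 digits there)
  t_term <- ifelse(p < 1e-15, 1 / (p * pi), 1 / tan(p * pi))
  T_stat <- sum(w * t_term)
  if (T_stat > 1e15) return(1 / (T_stat * pi))
  stats::pcauchy(T_stat, lower.tail = FALSE)
}

#' Gene burden test with polygenic-score robustness check
#'
#' Linear model of the trait on each mask x bin burden score plus
#' covariates, fitted with and without the per-trait common-variant polygenic
#' score (PGS). Per-mask p values are combined by [acat()] into one gene-level
#' p. A finding is `robust` when it is significant in both models and the
#' effect sizes differ by no more than `max_rel_diff` (20%) between them —
#' otherwise the rare signal cannot be distinguished from a shadow of nearby
#' common variants.
#'
#' @param trait numeric vector.
#' @param burdens named list of burden vectors (one per mask x bin; `NULL`
#'   entries and zero-variance burdens are skipped).
#' @param covariates covariate matrix or `NULL`.
#' @param pgs per-individual polygenic score (or `NULL` to skip the
#'   adjusted model).
#' @param sig_threshold gene-level significance (default 1.2e-8).
#' @param max_rel_diff tolerated relative effect change with PGS (default
#'   0.2).
#' @return list with `per_mask` (data frame: mask, beta/se/p with PGS,
#'   beta0/se0/p0 without), `acat_p`, `acat_p0`, `robust`, `best_mask`.
#' @export
burden_test <- function(trait, burdens, covariates = NULL, pgs = NULL,
                        sig_threshold = 1.2e-8, max_rel_diff = 0.2) {
  y <- as.numeric(trait)
  fit1 <- function(x, extra) {
    df <- data.frame(.y = y, .burden = x)
    if (!is.null(extra)) df <- cbind(df, as.data.frame(extra))
    cf <- summary(stats::lm(.y ~ ., data = df))$coefficients
    if (!".burden" %in% rownames(cf)) return(c(NA, NA, NA))
    c(cf[".burden", 1], cf[".burden", 2],
      2 * stats::pnorm(-abs(cf[".burden", 1] / cf[".burden", 2])))
  }
  C0 <- if (is.null(covariates)) NULL else as.matrix(covariates)
  rows <- list()
  for (nm in names(burdens)) {
    b <- burdens[[nm]]
    if (is.null(b) || stats::var(b) == 0) next
    r0 <- fit1(b, C0)
    r1 <- if (is.null(pgs)) r0 else fit1(b, cbind(C0, pgs = pgs))
    rows[[nm]] <- data.frame(mask = nm, beta = r1[1], se = r1[2], p = r1[3],
                             beta0 = r0[1], se0 = r0[2], p0 = r0[3],
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(per_mask = NULL, acat_p = NA_real_, acat_p0 = NA_real_,
                robust = NA, best_mask = NA_character_))
  pm <- do.call(rbind, rows)
  clip <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)
  acat_p <- acat(clip(pm$p))
  acat_p0 <- acat(clip(pm$p0))
  best <- pm$mask[which.min(pm$p)]
  bi <- which(pm$mask == best)
  rel <- abs(pm$beta[bi] - pm$beta0[bi]) / max(abs(pm$beta0[bi]), 1e-12)
  robust <- acat_p < sig_threshold && acat_p0 < sig_threshold &&
    rel <= max_rel_diff
  list(per_mask = pm, acat_p = acat_p, acat_p0 = acat_p0, robust = robust,
       best_mask = best, rel_diff = rel)
}

#' Single rare-variant association (ExWAS)
#'
#' Tests a single rare variant (linear model with covariates and optional
#' PGS adjustment). Variants with minor allele count `<= mac_min` are not
#' tested; results are reported only when MAF `< maf_report` (more common
#' variants are tested but flagged unreported). The PGS robustness contract
#' matches [burden_test()].
#'
#' @param g genotype vector in `{0,1,2}`/`NA`.
#' @param trait numeric trait.
#' @param covariates covariate matrix or `NULL`.
#' @param pgs polygenic score or `NULL`.
#' @param mac_min minimum exclusive minor allele count (default 5: MAC > 5
#'   required).
#' @param maf_report reporting MAF ceiling (default 5e-4).
#' @param variant_id,trait_id labels.
#' @return one-row data frame (`beta`, `se`, `p`, with `beta0/se0/p0` when a
#'   PGS is supplied, `af`, `mac`, `n`, `reported`) or `NULL` when not
#'   tested.
#' @export
exwas <- function(g, trait, covariates = NULL, pgs = NULL, mac_min = 5,
                  maf_report = 5e-4, variant_id = "v", trait_id = "trait") {
  g0 <- g; g0[is.na(g0)] <- 0L
  ac <- sum(g0)
  n <- length(g)
  mac <- min(ac, 2 * n - ac)
  if (mac <= mac_min) return(NULL)
  af <- ac / (2 * n)
  maf <- min(af, 1 - af)
  y <- as.numeric(trait)
  fit1 <- function(extra) {
    df <- data.frame(.y = y, .g = g0)
    if (!is.null(extra)) df <- cbind(df, as.data.frame(extra))
    cf <- summary(stats::lm(.y ~ ., data = df))$coefficients
    c(cf[".g", 1], cf[".g", 2],
      2 * stats::pnorm(-abs(cf[".g", 1] / cf[".g", 2])))
  }
  C0 <- if (is.null(covariates)) NULL else as.matrix(covariates)
  r0 <- fit1(C0)
  r1 <- if (is.null(pgs)) r0 else fit1(cbind(C0, pgs = pgs))
  data.frame(variant_id = variant_id, trait_id = trait_id, beta = r1[1],
             se = r1[2], p = r1[3], beta0 = r0[1], se0 = r0[2], p0 = r0[3],
             af = af, mac = mac, n = n, reported = maf < maf_report,
             stringsAsFactors = FALSE)
}

#' Logistic burden test against a binary outcome
#'
#' Plain logistic regression of the outcome on the burden score (plus
#' covariates) with a minimum-carrier guard and separation detection.
#'
#' @param outcome 0/1 vector.
#' @param burden burden score vector.
#' @param covariates covariate matrix or `NULL`.
#' @param min_carriers guard: minimum carriers among cases + controls
#'   (default 10).
#' @return list with `or`, `beta`, `se`, `p`, `n_carriers`, `status`
#'   (`ok`/`skipped`/`separation`).
#' @export
disease_burden <- function(outcome, burden, covariates = NULL,
                           min_carriers = 10L) {
  nc <- sum(burden > 0, na.rm = TRUE)
  if (nc < min_carriers)
    return(list(or = NA_real_, beta = NA_real_, se = NA_real_, p = NA_real_,
                n_carriers = nc, status = "skipped"))
  X <- if (is.null(covariates)) data.frame(burden = burden)
  else data.frame(burden = burden, as.data.frame(covariates))
  fit <- suppressWarnings(stats::glm(outcome ~ ., data = X,
                                     family = stats::binomial()))
  cf <- summary(fit)$coefficients
  beta <- cf["burden", 1]; se <- cf["burden", 2]
  if (!fit$converged || abs(beta) > 10 || se > 10)
    return(list(or = NA_real_, beta = beta, se = se, p = NA_real_,
                n_carriers = nc, status = "separation"))
  list(or = exp(beta), beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)), n_carriers = nc, status = "ok")
}

#' Rare-to-common allelic-series convergence table
#'
#' For each rare (burden or single-variant) hit, computes the distance to
#' the nearest statistically independent lead credible-set variant for the
#' same trait and flags `within_100kb`, `within_500kb`, `beyond_1mb`. The
#' `series` flag is set when an effector-gene assignment within 200 kb names
#' the rare hit's gene for at least one of its associated traits.
#'
#' @param rare_hits data frame `gene`, `trait_id`, `chrom`, `pos`.
#' @param common_leads data frame `variant_id`, `trait_id`, `chrom`, `pos`
#'   (lead credible-set variants).
#' @param assignments data frame `variant_id`, `gene`, `chrom`, `pos`
#'   (assigned effector genes; may be `NULL`).
#' @return `rare_hits` augmented with `nearest_lead`, `distance_bp`,
#'   `within_100kb`, `within_500kb`, `beyond_1mb`, `series`.
#' @export
allelic_series <- function(rare_hits, common_leads, assignments = NULL) {
  out <- rare_hits
  out$nearest_lead <- NA_character_
  out$distance_bp <- NA_real_
  for (i in seq_len(nrow(out))) {
    d <- common_leads[common_leads$trait_id == out$trait_id[i] &
                        common_leads$chrom == out$chrom[i], , drop = FALSE]
    if (nrow(d) == 0) next
    dist <- abs(d$pos - out$pos[i])
    j <- which.min(dist)
    out$nearest_lead[i] <- d$variant_id[j]
    out$distance_bp[i] <- dist[j]
  }
  out$within_100kb <- !is.na(out$distance_bp) & out$distance_bp < 1e5
  out$within_500kb <- !is.na(out$distance_bp) & out$distance_bp < 5e5
  out$beyond_1mb <- is.na(out$distance_bp) | out$distance_bp > 1e6
  out$series <- FALSE
  if (!is.null(assignments) && nrow(assignments)) {
    for (i in seq_len(nrow(out))) {
      a <- assignments[assignments$gene == out$gene[i] &
                         assignments$chrom == out$chrom[i] &
                         abs(assignments$pos - out$pos[i]) <= 2e5, , drop = FALSE]
      out$series[i] <- nrow(a) > 0
    }
  }
  out
}
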