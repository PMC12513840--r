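#' Estimate and remove medication effects from baseline metabolite data
#'
#' Fits, per trait and per sex, the model
#' `baseline ~ followup + age + BMI + medication` on individuals who were
#' untreated at baseline and have a repeat visit. Under the generating model
#' (medication shifts measures taken while on medication, test--retest slope
#' `rho`), the raw medication term estimates `-rho * effect`; the reported
#' medication coefficient is therefore the rescaled `-beta_med / beta_followup`,
#' which is on the scale of the medication effect itself. That coefficient is
#' subtracted from the baseline values of individuals treated at baseline,
#' sex-specifically.
#'
#' @param baseline individuals x traits baseline matrix (possibly shifted).
#' @param followup follow-up matrix over `followup_ids`.
#' @param followup_ids row indices of `baseline` with a repeat visit (all
#'   untreated at baseline).
#' @param followup_treated logical over the follow-up subset: on medication at
#'   follow-up.
#' @param treated logical over all individuals: on medication at baseline
#'   (these rows get corrected).
#' @param age,bmi numeric covariates over all individuals.
#' @param sex factor/character over all individuals (estimation and correction
#'   are per level).
#' @param min_eligible minimum eligible individuals per sex; below it the sex
#'   is skipped with a warning.
#' @return list with `corrected` (matrix) and `coefficients` (data frame:
#'   trait, sex, med_coef, se, n).
#' @export
adjust_medication <- function(baseline, followup, followup_ids,
                              followup_treated, treated, age, bmi, sex,
                              min_eligible = 100L) {
  stopifnot(nrow(followup) == length(followup_ids),
            length(followup_treated) == length(followup_ids),
            length(treated) == nrow(baseline))
  corrected <- baseline
  sex <- as.character(sex)
  coefs <- list()
  for (sx in unique(sex)) {
    sub <- which(sex[followup_ids] == sx)
    if (length(sub) < min_eligible || sum(followup_treated[sub]) < 2) {
      warning(sprintf("sex '%s': fewer than %d eligible individuals; correction skipped",
                      sx, min_eligible))
      next
    }
    ids <- followup_ids[sub]
    for (t in seq_len(ncol(baseline))) {
      fit <- stats::lm(baseline[ids, t] ~ followup[sub, t] + age[ids] +
                         bmi[ids] + followup_treated[sub])
      cf <- stats::coef(fit)
      b_fu <- cf[2]; b_med <- cf[5]
      med_coef <- as.numeric(-b_med / b_fu)
      se <- tryCatch(summary(fit)$coefficients[5, 2] / abs(b_fu),
                     error = function(e) NA_real_)
      rows <- which(treated & sex == sx)
      if (length(rows) && is.finite(med_coef))
        corrected[rows, t] <- corrected[rows, t] - med_coef
      coefs[[length(coefs) + 1L]] <- data.frame(
        trait = colnames(baseline)[t] %||% t, sex = sx, med_coef = med_coef,
        se = se, n = length(ids), stringsAsFactors = FALSE)
    }
  }
  list(corrected = corrected,
       coefficients = if (length(coefs)) do.call(rbind, coefs) else
         data.frame(trait = character(), sex = character(),
                    med_coef = numeric(), se = numeric(), n = integer()))
}

# residualize columns of x on covariates (with intercept) via QR
.residualize <- function(x, covariates) {
  x <- as.matrix(x)
  C <- cbind(1, as.matrix(covariates))
  qr_c <- qr(C)
  x - C %*% qr.coef(qr_c, x)
}

#' Per-variant additive association scan
#'
#' Ordinary least squares of a standardized trait on each variant's dosage,
#' after projecting both on the covariates (age, sex, principal components,
#' ...). Missing genotypes are mean-imputed. Betas are in trait-SD units per
#' allele; p values are two-sided Wald.
#'
#' @param genotypes individuals x variants matrix (or [generate_genotypes()]
#'   result).
#' @param trait numeric vector (standardized internally).
#' @param covariates matrix/data frame of covariates, or `NULL`.
#' @param trait_id,stratum labels stored in the output records.
#' @param maf_min minimum allele frequency tested (default 0.5%); monomorphic
#'   and sub-threshold variants are skipped and listed in the
#'   `skipped` attribute.
#' @return data frame of summary-statistic records: `variant_id`, `trait_id`,
#'   `stratum`, `beta`, `se`, `p`, `af`, `n`.
#' @export
run_scan <- function(genotypes, trait, covariates = NULL, trait_id = "trait",
                     stratum = "ALL", maf_min = 0.005) {
  geno <- if (is.list(genotypes) && !is.null(genotypes$genotypes)) genotypes$genotypes else genotypes
  n <- nrow(geno)
  stopifnot(length(trait) == n)
  y <- as.numeric(scale(trait))
  G <- geno
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min & maf > 0
  skipped <- colnames(G)[!keep]
  G <- G[, keep, drop = FALSE]
  af <- af[keep]

  if (!is.null(covariates)) {
    y <- .residualize(y, covariates)[, 1]
    G <- .residualize(G, covariates)
    p_cov <- ncol(as.matrix(covariates)) + 1L
  } else {
    y <- y - mean(y)
    G <- sweep(G, 2, colMeans(G))
    p_cov <- 1L
  }
  gg <- colSums(G^2)
  gy <- drop(crossprod(G, y))
  ok <- gg > 1e-10
  beta <- se <- rep(NA_real_, length(gg))
  beta[ok] <- gy[ok] / gg[ok]
  yy <- sum(y^2)
  df <- n - p_cov - 1L
  sigma2 <- pmax(yy - beta[ok] * gy[ok], 0) / df
  se[ok] <- sqrt(sigma2 / gg[ok])
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(variant_id = colnames(G), trait_id = trait_id,
                    stratum = stratum, beta = beta, se = se, p = p, af = af,
                    n = n, stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(skipped, colnames(G)[!ok])
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis across strata
#'
#' Combines per-stratum summary statistics for each variant x trait with
#' weights `1/se^2`. Variant x trait pairs present in fewer than `min_strata`
#' strata are excluded, mirroring the requirement that variants be observed
#' in at least two ancestral groups. Cochran's Q heterogeneity statistic is
#' attached to each meta record.
#'
#' @param records data frame of summary-stat records (stacked strata).
#' @param min_strata minimum number of contributing strata (default 2; set to
#'   1 only for testing single-stratum passthrough).
#' @param het_ancestry_p,het_sex_p flag thresholds for ancestral and
#'   sex-stratified heterogeneity.
#' @return data frame with `variant_id`, `trait_id`, `beta_meta`, `se_meta`,
#'   `z`, `p`, `n_strata`, `n`, `q_stat`, `q_df`, `p_het`,
#'   `het_ancestry_flag`, `het_sex_flag`.
#' @export
inverse_variance_meta <- function(records, min_strata = 2L,
                                  het_ancestry_p = 1e-4, het_sex_p = 5e-8) {
  stopifnot(all(c("variant_id", "trait_id", "beta", "se") %in% names(records)))
  if (any(records$se <= 0, na.rm = TRUE)) stop("all standard errors must be positive")
  key <- interaction(records$variant_id, records$trait_id, drop = TRUE)
  parts <- split(records, key)
  rows <- lapply(parts, function(d) {
    k <- nrow(d)
    if (k < min_strata) return(NULL)
    w <- 1 / d$se^2
    bm <- sum(w * d$beta) / sum(w)
    sem <- 1 / sqrt(sum(w))
    q <- sum(w * (d$beta - bm)^2)
    qdf <- k - 1L
    p_het <- if (qdf > 0) stats::pchisq(q, qdf, lower.tail = FALSE) else NA_real_
    z <- bm / sem
    data.frame(variant_id = d$variant_id[1], trait_id = d$trait_id[1],
               beta_meta = bm, se_meta = sem, z = z,
               p = 2 * stats::pnorm(-abs(z)), n_strata = k,
               n = sum(d$n %||% NA), q_stat = q, q_df = qdf, p_het = p_het,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_id = character(), trait_id = character(),
                      beta_meta = numeric(), se_meta = numeric(), z = numeric(),
                      p = numeric(), n_strata = integer(), n = numeric(),
                      q_stat = numeric(), q_df = integer(), p_het = numeric())
  out$het_ancestry_flag <- !is.na(out$p_het) & out$p_het < het_ancestry_p
  out$het_sex_flag <- !is.na(out$p_het) & out$p_het < het_sex_p
  rownames(out) <- NULL
  out
}

#' Cochran's Q heterogeneity test for one variant x trait
#'
#' @param beta,se per-stratum effect estimates and standard errors.
#' @return list with `q_stat`, `q_df`, `p_het`.
#' @export
heterogeneity_test <- function(beta, se) {
  stopifnot(length(beta) == length(se), all(se > 0))
  k <- length(beta)
  if (k < 2) stop("heterogeneity requires at least two strata")
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bm)^2)
  list(q_stat = q, q_df = k - 1L,
       p_het = stats::pchisq(q, k - 1L, lower.tail = FALSE))
}

#' Variance in a trait explained by a single additive variant
#'
#' Uses the standard `2 f (1 - f) beta^2` for an allele frequency `f` and a
#' per-allele effect `beta` on a trait with variance `trait_variance`.
#'
#' @param af allele frequency in `(0, 1)`.
#' @param beta per-allele effect.
#' @param trait_variance variance of the trait (1 for standardized traits).
#' @export
variance_explained <- function(af, beta, trait_variance = 1) {
  if (any(af <= 0 | af >= 1)) stop("af must be in (0, 1)")
  2 * af * (1 - af) * beta^2 / trait_variance
}

#' Metabolome-adjusted genome-wide significance threshold
#'
#' Divides the conventional genome-wide threshold by the number of tested
#' metabolic phenotypes; e.g. `5e-8 / 249 = 2.0e-10` (two significant
#' figures for display; full precision is returned).
#'
#' @param base base genome-wide threshold.
#' @param n_traits number of phenotypes (>= 1).
#' @export
significance_threshold <- function(base = 5e-8, n_traits = 1L) {
  if (n_traits < 1) stop("n_traits must be >= 1")
  base / n_traits
}
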