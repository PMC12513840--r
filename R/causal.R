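# log(sum(exp(x))) without overflow
.logsum <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# log(exp(a) - exp(b)), a > b
.logdiff <- function(a, b) {
  a + log1p(-exp(b - a))
}

#' Colocalization of two association signals by ABF enumeration
#'
#' Computes the posterior probabilities of the five hypotheses (H0: neither
#' trait associated in the region; H1/H2: only trait 1/2; H3: both, distinct
#' causal variants; H4: both, one shared causal variant) from per-variant
#' Wakefield log ABFs of the two traits, using the standard prior
#' parametrization (`p1`, `p2` per-SNP single-trait priors, `p12` shared
#' prior, default 5e-6). All accumulation is in log space.
#'
#' @param stats1,stats2 data frames over a harmonized variant grid:
#'   `variant_id`, `beta`, `se` (per-signal conditional statistics when
#'   decomposing multi-signal loci).
#' @param p1,p2,p12 priors (defaults 1e-4, 1e-4, 5e-6).
#' @param W1,W2 Wakefield prior variances.
#' @param min_shared minimum shared variants below which the result is
#'   flagged low-confidence (default 10).
#' @return list with `pp` (named `pp0`..`pp4`), `n_variants`,
#'   `low_confidence`, `hit` (PP4 >= 0.8).
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6,
                      W1 = 0.04, W2 = 0.04, min_shared = 10L) {
  shared <- intersect(stats1$variant_id, stats2$variant_id)
  n <- length(shared)
  if (n == 0) stop("no shared variants")
  d1 <- stats1[match(shared, stats1$variant_id), ]
  d2 <- stats2[match(shared, stats2$variant_id), ]
  l1 <- wakefield_log_abf(d1$beta, d1$se, W1)
  l2 <- wakefield_log_abf(d2$beta, d2$se, W2)
  s1 <- .logsum(l1)
  s2 <- .logsum(l2)
  s12 <- .logsum(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = log(p1) + log(p2) +
            (if (s1 + s2 > s12) .logdiff(s1 + s2, s12) else -Inf),
          h4 = log(p12) + s12)
  pp <- exp(lh - .logsum(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("pp", 0:4)
  list(pp = pp, n_variants = n, low_confidence = n < min_shared,
       hit = unname(pp[5] >= 0.8))
}

#' Colocalize all signal pairs between a metabolite and an outcome locus
#'
#' Runs [coloc_abf()] for every (trait signal x outcome signal) pair of
#' conditional statistics, with the outcome decomposition capped at
#' `max_outcome_signals` (5).
#'
#' @param trait_signals,outcome_signals lists of per-signal stats data
#'   frames.
#' @param ... passed to [coloc_abf()].
#' @param max_outcome_signals cap on outcome signals used (default 5).
#' @return data frame with one row per pair: `trait_signal`,
#'   `outcome_signal`, `pp0`..`pp4`, `hit`, `low_confidence`.
#' @export
coloc_all_pairs <- function(trait_signals, outcome_signals,
                            max_outcome_signals = 5L, ...) {
  outcome_signals <- utils::head(outcome_signals, max_outcome_signals)
  rows <- list()
  for (i in seq_along(trait_signals)) for (j in seq_along(outcome_signals)) {
    r <- coloc_abf(trait_signals[[i]], outcome_signals[[j]], ...)
    rows[[length(rows) + 1L]] <- data.frame(
      trait_signal = i, outcome_signal = j, t(r$pp), hit = r$hit,
      low_confidence = r$low_confidence)
  }
  do.call(rbind, rows)
}

#' Wald ratio causal estimate from a single instrument
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome instrument
#'   association statistics.
#' @return list with `ratio`, `se` (first-order delta method), `p`,
#'   `weak_instrument` (|exposure Z| < 2).
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (beta_exposure == 0) stop("beta_exposure must be nonzero")
  ratio <- beta_outcome / beta_exposure
  se <- abs(se_outcome / beta_exposure)
  list(ratio = ratio, se = se, p = 2 * stats::pnorm(-abs(ratio / se)),
       weak_instrument = abs(beta_exposure / se_exposure) < 2)
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Fixed-effect IVW estimate
#' `beta = sum(bx*by/sey^2) / sum(bx^2/sey^2)`, `se = 1/sqrt(sum(bx^2/sey^2))`.
#' With a single instrument the estimate defers to [wald_ratio()].
#'
#' @param instruments data frame with `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @return list with `beta`, `se`, `p`, `n_instruments`, `method`.
#' @export
ivw <- function(instruments) {
  d <- instruments
  if (nrow(d) < 2) {
    if (nrow(d) == 0) stop("no instruments")
    wr <- wald_ratio(d$beta_exposure, d$se_exposure, d$beta_outcome,
                     d$se_outcome)
    return(list(beta = wr$ratio, se = wr$se, p = wr$p, n_instruments = 1L,
                method = "wald_ratio"))
  }
  w <- d$beta_exposure^2 / d$se_outcome^2
  beta <- sum(d$beta_exposure * d$beta_outcome / d$se_outcome^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
       n_instruments = nrow(d), method = "ivw")
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept (weights `1/se_outcome^2`), after orienting instruments so all
#' exposure effects are nonnegative. A nonzero intercept indicates
#' directional pleiotropy; the intercept test is evaluated against
#' `intercept_p_min` (1e-4).
#'
#' @param instruments data frame as in [ivw()] (>= 3 rows).
#' @param intercept_p_min pleiotropy-filter threshold (default 1e-4).
#' @return list with `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `intercept_se`, `intercept_p`, `pleiotropy_pass`.
#' @export
mr_egger <- function(instruments, intercept_p_min = 1e-4) {
  d <- instruments
  if (nrow(d) < 3) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  w <- 1 / d$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  list(slope = cf[2, 1], slope_se = cf[2, 2],
       slope_p = 2 * stats::pt(-abs(cf[2, 3]), nrow(d) - 2),
       intercept = cf[1, 1], intercept_se = cf[1, 2],
       intercept_p = 2 * stats::pt(-abs(cf[1, 3]), nrow(d) - 2),
       pleiotropy_pass = 2 * stats::pt(-abs(cf[1, 3]), nrow(d) - 2) >
         intercept_p_min)
}

#' Instrument tiers by pleiotropy stringency
#'
#' Builds the four nested instrument sets used for the metabolite-to-disease
#' MR screen: (1) sentinel variants; (2) lead credible-set variants; (3)
#' leads restricted for molecular pleiotropy (groups classed `specific` or
#' `pathway`); (4) additionally restricted for phenotypic pleiotropy (EFO
#' class `specific`). Tier 4 is a subset of tier 3, which is a subset of
#' tier 2.
#'
#' @param leads data frame `variant_id`, `group_id` (lead credible-set
#'   variants for one trait).
#' @param sentinels character vector of sentinel variant ids.
#' @param mode_calls data frame `group_id`, `mode` ([classify_mqtl()]).
#' @param efo_calls data frame `group_id`, `phenotypic_class`
#'   ([efo_pleiotropy()]).
#' @return named list `sentinels`, `leads`, `molecular_filtered`,
#'   `molecular_phenotypic_filtered` of variant id vectors.
#' @export
instrument_tiers <- function(leads, sentinels, mode_calls, efo_calls) {
  mode_of <- stats::setNames(mode_calls$mode, mode_calls$group_id)
  efo_of <- stats::setNames(efo_calls$phenotypic_class, efo_calls$group_id)
  ok_mol <- mode_of[leads$group_id] %in% c("specific", "pathway")
  ok_phe <- ok_mol & efo_of[leads$group_id] %in% "specific"
  list(sentinels = unique(sentinels),
       leads = unique(leads$variant_id),
       molecular_filtered = unique(leads$variant_id[ok_mol]),
       molecular_phenotypic_filtered = unique(leads$variant_id[ok_phe]))
}

#' Benjamini--Hochberg q-values
#'
#' @param p vector of p values in `(0, 1]`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Run the full MR screen for one exposure--outcome pair
#'
#' IVW, MR-Egger (when >= 3 instruments) and per-instrument Wald ratios;
#' `pass_filters` requires an Egger intercept p above 1e-4 (no evidence of
#' directional pleiotropy), sign concordance of IVW, Egger slope and the
#' median Wald ratio, and `fdr_q < 0.05` (q value supplied by the caller
#' after screening all pairs).
#'
#' @param instruments instrument data frame.
#' @param tier instrument-tier label carried into the result.
#' @return one-row data frame with the IVW/Egger estimates, the median Wald
#'   ratio, `egger_intercept`, `egger_intercept_p` and `concordant`.
#' @export
mr_screen <- function(instruments, tier = "leads") {
  iv <- ivw(instruments)
  wr <- mapply(function(bx, sx, by, sy) wald_ratio(bx, sx, by, sy)$ratio,
               instruments$beta_exposure, instruments$se_exposure,
               instruments$beta_outcome, instruments$se_outcome)
  med_wr <- stats::median(wr)
  eg <- if (nrow(instruments) >= 3) mr_egger(instruments) else NULL
  concord <- if (is.null(eg)) sign(iv$beta) == sign(med_wr)
  else sign(iv$beta) == sign(eg$slope) && sign(iv$beta) == sign(med_wr)
  data.frame(tier = tier, beta_ivw = iv$beta, se_ivw = iv$se, p_ivw = iv$p,
             beta_egger = eg$slope %||% NA_real_,
             se_egger = eg$slope_se %||% NA_real_,
             p_egger = eg$slope_p %||% NA_real_,
             egger_intercept = eg$intercept %||% NA_real_,
             egger_intercept_p = eg$intercept_p %||% NA_real_,
             median_wald = med_wr, n_instruments = nrow(instruments),
             concordant = concord,
             pleiotropy_pass = if (is.null(eg)) NA else eg$pleiotropy_pass,
             stringsAsFactors = FALSE)
}

#' Level-versus-locus convergence with the LDL-independence rule
#'
#' Convergent metabolite--disease pairs have at least one passing level
#' effect (MR: FDR q < `fdr_max`, Egger intercept filter, sign concordance)
#' and at least one locus effect (colocalization PP4 >= `pp4_min`); loci
#' whose pleiotropy mode is `disproportional` or `nonspecific` are excluded
#' from locus-effect reporting. A locus is flagged LDL-independent when no
#' variant reaches `ldl_p` on the LDL-cholesterol measure there AND
#' (under the default `rank_rule = "exclude_top"`) no variant's |LDL effect|
#' falls at or above the 80th percentile of the locus's |effect| distribution
#' across measures; `rank_rule = "p_only"` applies only the p-value clause.
#'
#' @param mr_results data frame with `trait_id`, `outcome`, `fdr_q`,
#'   `concordant`, `pleiotropy_pass` (from [mr_screen()] + [bh_fdr()]).
#' @param coloc_results data frame with `trait_id`, `outcome`, `locus`,
#'   `pp4`, `mode` (pleiotropy mode of the locus group).
#' @param ldl_stats data frame with `locus`, `variant_id`, `ldl_p`,
#'   `ldl_beta`, `all_betas` unavailable — instead supply `locus_effects`:
#'   see argument.
#' @param locus_effects data frame `locus`, `variant_id`, `trait_id`,
#'   `beta` (per-measure effects at the locus, used for the percentile
#'   clause). `NULL` leaves the flag undetermined.
#' @param fdr_max,pp4_min,ldl_p thresholds (0.05, 0.8, 2e-10).
#' @param rank_rule `"exclude_top"` or `"p_only"`.
#' @return data frame of convergent pairs with `ldl_independent`
#'   (TRUE/FALSE/NA).
#' @export
level_locus_convergence <- function(mr_results, coloc_results,
                                    ldl_stats = NULL, locus_effects = NULL,
                                    fdr_max = 0.05, pp4_min = 0.8,
                                    ldl_p = 2.0e-10,
                                    rank_rule = c("exclude_top", "p_only")) {
  rank_rule <- match.arg(rank_rule)
  lev <- mr_results[mr_results$fdr_q < fdr_max & mr_results$concordant &
                      (is.na(mr_results$pleiotropy_pass) |
                         mr_results$pleiotropy_pass), , drop = FALSE]
  loc <- coloc_results[coloc_results$pp4 >= pp4_min &
                         !coloc_results$mode %in%
                         c("disproportional", "nonspecific"), , drop = FALSE]
  if (nrow(lev) == 0 || nrow(loc) == 0)
    return(data.frame(trait_id = character(), outcome = character(),
                      locus = character(), ldl_independent = logical()))
  key_lev <- paste(lev$trait_id, lev$outcome)
  conv <- loc[paste(loc$trait_id, loc$outcome) %in% key_lev, , drop = FALSE]
  if (nrow(conv) == 0)
    return(data.frame(trait_id = character(), outcome = character(),
                      locus = character(), ldl_independent = logical()))
  conv$ldl_independent <- NA
  if (!is.null(ldl_stats)) {
    for (i in seq_len(nrow(conv))) {
      d <- ldl_stats[ldl_stats$locus == conv$locus[i], , drop = FALSE]
      if (nrow(d) == 0) next
      indep <- all(d$ldl_p >= ldl_p, na.rm = TRUE)
      if (indep && rank_rule == "exclude_top" && !is.null(locus_effects)) {
        le <- locus_effects[locus_effects$locus == conv$locus[i], , drop = FALSE]
        if (nrow(le) > 0) {
          q80 <- stats::quantile(abs(le$beta), 0.8)
          indep <- all(abs(d$ldl_beta) < q80, na.rm = TRUE)
        }
      }
      conv$ldl_independent[i] <- indep
    }
  }
  rownames(conv) <- NULL
  conv[, c("trait_id", "outcome", "locus", "pp4", "mode", "ldl_independent")]
}
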