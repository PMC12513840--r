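#' Classify an mQTL group into one of five pleiotropy modes
#'
#' Each group is summarized by two statistics computed over its associated
#' traits: `q25`, the 25th percentile of pairwise absolute Pearson
#' correlations among the traits, and `statcor`, the Pearson correlation
#' between each trait's association strength (`-log10 p`) and its squared
#' correlation with the lead (most significant) trait. The rule table is:
#' * n <= 3 and q25 >= 0.6 -> `specific`
#' * n > 3, q25 >= 0.6, statcor >= 0.6 -> `pathway`
#' * q25 < 0.6, statcor >= 0.6 -> `proportional`
#' * q25 >= 0.6, statcor < 0.6 -> `disproportional`
#' * otherwise -> `nonspecific`
#'
#' Single-trait groups are `specific` with both metrics missing. With fewer
#' than three associated traits `statcor` is undefined and the call falls
#' back to the q25 rule alone (`specific` if q25 >= 0.6, else `nonspecific`).
#'
#' @param traits character vector of associated trait ids (columns of
#'   `trait_cor` / names in `assoc_stats`).
#' @param trait_cor trait correlation matrix (computed on
#'   medication-corrected traits).
#' @param assoc_stats data frame with `trait_id` and `p` (per-trait lead p
#'   within the group).
#' @param rho_threshold correlation cutoff shared by both rules (default 0.6).
#' @param group_id label carried into the output.
#' @return one-row data frame: `group_id`, `n_traits`, `q25`, `statcor`,
#'   `mode`.
#' @export
classify_mqtl <- function(traits, trait_cor, assoc_stats, rho_threshold = 0.6,
                          group_id = NA_character_) {
  traits <- unique(traits)
  n <- length(traits)
  stopifnot(n >= 1, all(traits %in% rownames(trait_cor)))
  mk <- function(mode, q25 = NA_real_, statcor = NA_real_)
    data.frame(group_id = group_id, n_traits = n, q25 = q25,
               statcor = statcor, mode = mode, stringsAsFactors = FALSE)
  if (n == 1) return(mk("specific"))

  Rg <- abs(trait_cor[traits, traits])
  q25 <- as.numeric(stats::quantile(Rg[upper.tri(Rg)], 0.25))

  st <- assoc_stats[match(traits, assoc_stats$trait_id), , drop = FALSE]
  lead <- traits[order(st$p, traits)][1]
  # the lead itself (x = 1, y = max by construction) carries no information
  # about whether association strength tracks correlation, and its leverage
  # can dominate the Pearson estimate in small groups; it is excluded
  rest <- traits != lead
  x <- trait_cor[traits[rest], lead]^2
  y <- -log10(pmax(st$p[rest], 1e-320))
  statcor <- if (sum(rest) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y) else NA_real_

  if (is.na(statcor)) {
    mode <- if (q25 >= rho_threshold) "specific" else "nonspecific"
    return(mk(mode, q25))
  }
  mode <- if (n <= 3 && q25 >= rho_threshold) "specific"
  else if (n > 3 && q25 >= rho_threshold && statcor >= rho_threshold) "pathway"
  else if (q25 < rho_threshold && statcor >= rho_threshold) "proportional"
  else if (q25 >= rho_threshold && statcor < rho_threshold) "disproportional"
  else "nonspecific"
  mk(mode, q25, statcor)
}

# walk an EFO term up to the parent-category level (children of the roots);
# returns the category term or "unmapped"
.efo_category <- function(term, parent_of, roots, max_depth = 100L) {
  cur <- term
  seen <- character(0)
  for (i in seq_len(max_depth)) {
    if (!cur %in% names(parent_of)) return("unmapped")
    p <- parent_of[[cur]]
    if (p %in% roots) return(cur)
    if (p %in% seen) return("unmapped")  # cycle guard
    seen <- c(seen, cur)
    cur <- p
  }
  "unmapped"
}

#' Phenotypic pleiotropy of an mQTL group via EFO parent terms
#'
#' Looks up the group's variants (and proxies at `r^2 >` `proxy_r2`) in a
#' GWAS-Catalog-dialect table, keeps rows with a mapped trait, genome-wide
#' significance and location information, drops rows whose EFO term descends
#' from an excluded root (e.g. lipid/lipoprotein measurement terms), walks
#' each remaining term up to the parent-category level (the children of the
#' ontology roots), and counts distinct parent categories. Groups hitting
#' fewer than `specific_max` categories are phenotypically `specific`,
#' otherwise `unspecific`.
#'
#' @param variants group member variant ids.
#' @param proxies optional data frame `variant_id`, `proxy_id`, `r2`.
#' @param catalog data frame with columns `SNPS`, `MAPPED_TRAIT_URI`,
#'   `P-VALUE` (or `P_VALUE`), `CHR_ID`, `CHR_POS`.
#' @param ontology two-column data frame `child`, `parent`.
#' @param excluded_roots EFO ids whose descendants (and themselves) are
#'   dropped before counting.
#' @param roots ontology root ids (terms whose children are the parent
#'   categories); defaults to parents that never appear as children.
#' @param p_max catalog significance filter (default 5e-8).
#' @param proxy_r2 proxy threshold (default 0.8).
#' @param specific_max parent-term count below which the group is specific
#'   (default 5).
#' @param group_id label carried into the output.
#' @return one-row data frame: `group_id`, `n_parent_terms`,
#'   `phenotypic_class`, `parents` (comma-joined).
#' @export
efo_pleiotropy <- function(variants, catalog, ontology, excluded_roots =
                             character(0), proxies = NULL, roots = NULL,
                           p_max = 5e-8, proxy_r2 = 0.8, specific_max = 5L,
                           group_id = NA_character_) {
  pcol <- intersect(c("P-VALUE", "P_VALUE", "p"), names(catalog))[1]
  stopifnot(!is.na(pcol))
  query <- variants
  if (!is.null(proxies)) {
    pr <- proxies[proxies$variant_id %in% variants & proxies$r2 > proxy_r2, ]
    query <- unique(c(query, pr$proxy_id))
  }
  d <- catalog[catalog$SNPS %in% query, , drop = FALSE]
  d <- d[!is.na(d$MAPPED_TRAIT_URI) & d$MAPPED_TRAIT_URI != "" &
           !is.na(d[[pcol]]) & d[[pcol]] < p_max &
           !is.na(d$CHR_ID) & !is.na(d$CHR_POS), , drop = FALSE]

  parent_of <- stats::setNames(as.list(as.character(ontology$parent)),
                               as.character(ontology$child))
  if (is.null(roots))
    roots <- setdiff(unique(as.character(ontology$parent)),
                     unique(as.character(ontology$child)))

  is_excluded <- function(term) {
    cur <- term; seen <- character(0)
    repeat {
      if (cur %in% excluded_roots) return(TRUE)
      if (!cur %in% names(parent_of) || cur %in% seen) return(FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  terms <- unique(as.character(d$MAPPED_TRAIT_URI))
  terms <- terms[!vapply(terms, is_excluded, logical(1))]
  parents <- unique(vapply(terms, .efo_category, character(1),
                           parent_of = parent_of, roots = roots))
  n_par <- length(parents)
  data.frame(group_id = group_id, n_parent_terms = n_par,
             phenotypic_class = if (n_par < specific_max) "specific" else "unspecific",
             parents = paste(sort(parents), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Per-category enrichment of EFO hits in pleiotropic versus specific mQTLs
#'
#' For each EFO parent category, fits a logistic regression of the
#' category-hit indicator on a pleiotropic-vs-specific indicator across mQTL
#' groups, reporting the odds ratio, Wald 95% CI and Bonferroni-adjusted p.
#' Degenerate categories (no variance, or complete separation) are flagged
#' and skipped.
#'
#' @param calls data frame with `group_id` and `pleiotropic` (logical).
#' @param hits data frame with `group_id`, `category` (one row per hit).
#' @return data frame per category: `category`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `p_bonf`, `status`.
#' @export
category_enrichment <- function(calls, hits) {
  cats <- sort(unique(hits$category))
  rows <- lapply(cats, function(ct) {
    hit <- calls$group_id %in% hits$group_id[hits$category == ct]
    res <- data.frame(category = ct, or = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, p = NA_real_, p_bonf = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    if (length(unique(hit)) < 2 || length(unique(calls$pleiotropic)) < 2) {
      res$status <- "degenerate"; return(res)
    }
    tab <- table(hit, calls$pleiotropic)
    if (any(tab == 0)) { res$status <- "separation"; return(res) }
    fit <- stats::glm(hit ~ calls$pleiotropic, family = stats::binomial())
    cf <- summary(fit)$coefficients
    res$or <- exp(cf[2, 1])
    res$ci_lo <- exp(cf[2, 1] - 1.96 * cf[2, 2])
    res$ci_hi <- exp(cf[2, 1] + 1.96 * cf[2, 2])
    res$p <- cf[2, 4]
    res
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  out$p_bonf[ok] <- pmin(1, out$p[ok] * sum(ok))
  out
}
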