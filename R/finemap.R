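#' Regional clumping around sentinel variants
#'
#' Builds +/- `window_bp` intervals around sentinel variants, merges
#' overlapping or book-ended intervals per chromosome, and absorbs anything
#' touching the extended MHC interval into one fixed MHC region that is
#' flagged as not fine-mapped.
#'
#' @param sentinels data frame with `variant_id`, `chrom`, `pos` (and
#'   optionally `trait_id`).
#' @param window_bp half-window in bp (default 500 kb).
#' @param mhc `c(chrom, start, end)` of the extended MHC (default
#'   chr6:25.5--34.0 Mb).
#' @return data frame of regions: `region_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `sentinels` (comma-joined), `traits`, `is_mhc`,
#'   `finemap` (FALSE for the MHC region).
#' @export
clump_regions <- function(sentinels, window_bp = 5e5,
                          mhc = c(6, 25.5e6, 34.0e6)) {
  if (is.null(sentinels) || nrow(sentinels) == 0)
    return(data.frame(region_id = character(), chrom = numeric(),
                      start = numeric(), end = numeric(),
                      sentinels = character(), traits = character(),
                      is_mhc = logical(), finemap = logical()))
  s <- sentinels
  s$start <- pmax(1, s$pos - window_bp)
  s$end <- s$pos + window_bp
  in_mhc <- s$chrom == mhc[1] & s$end >= mhc[2] & s$start <= mhc[3]
  out <- list()
  if (any(in_mhc)) {
    d <- s[in_mhc, , drop = FALSE]
    out[[1L]] <- data.frame(
      chrom = mhc[1], start = mhc[2], end = mhc[3],
      sentinels = paste(unique(d$variant_id), collapse = ","),
      traits = paste(unique(d$trait_id %||% ""), collapse = ","),
      is_mhc = TRUE, finemap = FALSE, stringsAsFactors = FALSE)
  }
  s <- s[!in_mhc, , drop = FALSE]
  for (ch in sort(unique(s$chrom))) {
    d <- s[s$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur_start <- d$start[1]; cur_end <- d$end[1]
    members <- 1L
    flush <- function(st, en, idx) {
      data.frame(chrom = ch, start = st, end = en,
                 sentinels = paste(unique(d$variant_id[idx]), collapse = ","),
                 traits = paste(unique(d$trait_id[idx] %||% ""), collapse = ","),
                 is_mhc = FALSE, finemap = TRUE, stringsAsFactors = FALSE)
    }
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      if (d$start[i] <= cur_end + 1) {  # overlap or book-ended
        cur_end <- max(cur_end, d$end[i])
        members <- c(members, i)
      } else {
        out[[length(out) + 1L]] <- flush(cur_start, cur_end, members)
        cur_start <- d$start[i]; cur_end <- d$end[i]; members <- i
      }
    }
    out[[length(out) + 1L]] <- flush(cur_start, cur_end, members)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$region_id <- sprintf("R%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("region_id", "chrom", "start", "end", "sentinels", "traits",
          "is_mhc", "finemap")]
}

#' Wakefield log approximate Bayes factor
#'
#' For an effect estimate `beta` with standard error `se` and a normal effect
#' prior with variance `W`, the log ABF against the null is
#' `0.5 * log(1 - r) + 0.5 * z^2 * r` with `z = beta/se`, `V = se^2` and
#' `r = W / (V + W)`. Computed in log space so it is stable for very large
#' `|z|`.
#'
#' @param beta,se effect estimate and standard error (vectorized).
#' @param W prior effect variance (default 0.04, i.e. prior SD 0.2 on
#'   standardized effects).
#' @export
wakefield_log_abf <- function(beta, se, W = 0.04) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(W <= 0)) stop("prior variance W must be positive")
  V <- se^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' 95% credible set from per-variant log ABFs
#'
#' Posterior inclusion probabilities are the normalized ABFs under a flat
#' prior over variants (log-sum-exp normalization). The credible set is the
#' smallest prefix of variants, sorted by descending posterior, whose
#' cumulative mass reaches `coverage`; ties are broken by position then
#' variant id.
#'
#' @param log_abf numeric vector of log ABFs.
#' @param variant_id,pos identifiers and positions (defaults: index order).
#' @param coverage target coverage (default 0.95).
#' @return data frame of the full ranking with `variant_id`, `pos`,
#'   `posterior`, `cum_mass`, `in_set`; the credible set is the `in_set`
#'   rows.
#' @export
credible_set <- function(log_abf, variant_id = NULL, pos = NULL,
                         coverage = 0.95) {
  stopifnot(length(log_abf) >= 1)
  m <- length(log_abf)
  if (is.null(variant_id)) variant_id <- sprintf("v%d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m)
  mx <- max(log_abf)
  post <- exp(log_abf - mx)
  post <- post / sum(post)
  ord <- order(-post, pos, variant_id)
  cum <- cumsum(post[ord])
  k <- which(cum >= coverage - 1e-12)[1]
  if (is.na(k)) k <- m
  out <- data.frame(variant_id = variant_id[ord], pos = pos[ord],
                    posterior = post[ord], cum_mass = cum,
                    in_set = seq_len(m) <= k, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# conditional summary statistics of all variants given a selected set,
# COJO-style on standardized genotypes: b_cond = b - R[, S] solve(R_S) b_S.
# Standard errors are kept at their marginal scale (documented approximation).
.conditional_stats <- function(beta, se, R, sel, ridge = 1e-8) {
  if (length(sel) == 0) return(list(beta = beta, se = se))
  Rs <- R[sel, sel, drop = FALSE]
  diag(Rs) <- diag(Rs) + ridge
  bs <- tryCatch(solve(Rs, beta[sel]), error = function(e) {
    diag(Rs) <- diag(Rs) + 1e-4
    solve(Rs, beta[sel])
  })
  bc <- beta - drop(R[, sel, drop = FALSE] %*% bs)
  bc[sel] <- 0
  list(beta = bc, se = se)
}

#' Multi-signal fine-mapping by stepwise conditional decomposition
#'
#' Decomposes a region x trait association into statistically independent
#' signals: repeatedly select the variant with the smallest conditional p
#' value (conditioning on previously selected leads through the LD matrix),
#' stopping when no conditional p passes `p_stop` or `max_sets` signals are
#' reached. For each signal, a Wakefield 95% credible set is computed from
#' the signal's conditional statistics (conditioned on the other selected
#' leads); set members with `|r| < min_abs_corr` to the lead are dropped.
#' Sets whose leads are mutually correlated at `r^2 > prune_r2` are pruned
#' (the smaller-p signal wins, ties broken by position). The procedure is
#' evaluated for every cap in `max_sets_range` and the configuration with the
#' largest surviving signal count is reported (smallest cap on ties).
#'
#' @param stats data frame with `variant_id`, `pos`, `beta`, `se` (one trait,
#'   one region).
#' @param ld variant x variant correlation (r) matrix covering `stats`.
#' @param max_sets_range candidate caps on the number of signals (default
#'   2:10).
#' @param min_abs_corr minimum |r| of a set member to its lead (default 0.1).
#' @param p_stop conditional significance required to add a signal (default
#'   5e-8).
#' @param prune_r2 lead--lead r^2 above which sets are pruned (default 0.25).
#' @param W Wakefield prior variance.
#' @param coverage credible-set coverage.
#' @return list of signals, each a list with `lead`, `lead_pos`,
#'   `marginal_beta/se/p`, `conditional_beta/se/p`, and `set` (credible-set
#'   data frame). Attribute `max_sets_used` records the winning cap.
#' @export
multisignal_finemap <- function(stats, ld, max_sets_range = 2:10,
                                min_abs_corr = 0.1, p_stop = 5e-8,
                                prune_r2 = 0.25, W = 0.04, coverage = 0.95) {
  stopifnot(all(c("variant_id", "beta", "se") %in% names(stats)))
  ids <- stats$variant_id
  stopifnot(all(ids %in% rownames(ld)))
  R <- ld[ids, ids, drop = FALSE]
  pos <- stats$pos %||% seq_along(ids)
  beta <- stats$beta; se <- stats$se
  p_marg <- 2 * stats::pnorm(-abs(beta / se))

  # one greedy path up to the largest cap; caps are prefixes of it
  path <- integer(0)
  for (step in seq_len(max(max_sets_range))) {
    cs <- .conditional_stats(beta, se, R, path)
    zc <- cs$beta / cs$se
    pc <- 2 * stats::pnorm(-abs(zc))
    pc[path] <- 1
    j <- order(pc, pos, ids)[1]
    if (pc[j] > p_stop) break
    path <- c(path, j)
  }
  if (length(path) == 0) {
    out <- list()
    attr(out, "max_sets_used") <- NA_integer_
    return(out)
  }

  build_signals <- function(sel) {
    sigs <- lapply(seq_along(sel), function(k) {
      others <- sel[-k]
      cs <- .conditional_stats(beta, se, R, others)
      labf <- wakefield_log_abf(cs$beta, cs$se, W)
      set <- credible_set(labf, ids, pos, coverage)
      set <- set[set$in_set, , drop = FALSE]
      lead_idx <- sel[k]
      keep <- abs(R[set$variant_id, ids[lead_idx]]) >= min_abs_corr
      set <- set[keep, , drop = FALSE]
      if (!ids[lead_idx] %in% set$variant_id) {
        set <- rbind(set, data.frame(variant_id = ids[lead_idx],
                                     pos = pos[lead_idx],
                                     posterior = NA_real_, cum_mass = NA_real_,
                                     in_set = TRUE))
      }
      pcond <- 2 * stats::pnorm(-abs(cs$beta[lead_idx] / cs$se[lead_idx]))
      list(lead = ids[lead_idx], lead_pos = pos[lead_idx],
           marginal_beta = beta[lead_idx], marginal_se = se[lead_idx],
           marginal_p = p_marg[lead_idx],
           conditional_beta = cs$beta[lead_idx],
           conditional_se = cs$se[lead_idx], conditional_p = pcond,
           set = set)
    })
    prune_signals(sigs, R, ids, prune_r2)
  }

  best <- NULL; best_cap <- NA_integer_
  for (cap in sort(max_sets_range)) {
    sel <- path[seq_len(min(cap, length(path)))]
    sigs <- build_signals(sel)
    if (is.null(best) || length(sigs) > length(best)) {
      best <- sigs; best_cap <- cap
    }
  }
  attr(best, "max_sets_used") <- best_cap
  best
}

#' Prune signals whose leads are mutually correlated
#'
#' Among pairs of signals with lead--lead `r^2 > prune_r2`, the signal with
#' the smaller marginal p is retained (ties by lead position, then id). The
#' result is order-independent.
#'
#' @param signals list of signals as built by [multisignal_finemap()].
#' @param R LD correlation matrix; `ids` its variant order.
#' @param ids variant ids corresponding to `R`.
#' @param prune_r2 pruning threshold on r^2.
#' @export
prune_signals <- function(signals, R, ids = rownames(R), prune_r2 = 0.25) {
  if (length(signals) <= 1) return(signals)
  leads <- vapply(signals, `[[`, character(1), "lead")
  pvals <- vapply(signals, `[[`, numeric(1), "marginal_p")
  posv <- vapply(signals, `[[`, numeric(1), "lead_pos")
  ord <- order(pvals, posv, leads)  # strongest first, deterministic
  keep <- logical(length(signals))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (R[leads[i], leads[j]]^2 > prune_r2) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  signals[sort(which(keep))]
}

#' Joint-model concordance filter for fine-mapped signals
#'
#' Fits all signal leads of one region x trait jointly (with the scan
#' covariates) and retains only signals whose lead is genome-wide significant
#' (`p < p_gw`) in both marginal and joint statistics, with joint and marginal
#' effects of the same sign and within `max_rel_diff` relative magnitude.
#' Collinear leads (joint design drop) remove the weaker signal.
#'
#' @param signals list of signals ([multisignal_finemap()]).
#' @param genotypes genotype matrix containing the lead variants.
#' @param trait numeric trait vector.
#' @param covariates covariate matrix or `NULL`.
#' @param p_gw genome-wide threshold (default 5e-8).
#' @param max_rel_diff joint-vs-marginal relative magnitude tolerance
#'   (default 0.25).
#' @return the retained signals, each augmented with `joint_beta`,
#'   `joint_se`, `joint_p`.
#' @export
joint_concordance_filter <- function(signals, genotypes, trait,
                                     covariates = NULL, p_gw = 5e-8,
                                     max_rel_diff = 0.25) {
  if (length(signals) == 0) return(signals)
  geno <- if (is.list(genotypes) && !is.null(genotypes$genotypes)) genotypes$genotypes else genotypes
  leads <- vapply(signals, `[[`, character(1), "lead")
  G <- geno[, leads, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  y <- as.numeric(scale(trait))
  X <- if (is.null(covariates)) G else cbind(G, as.matrix(covariates))
  fit <- stats::lm(y ~ X)
  cf <- summary(fit)$coefficients
  nm <- paste0("X", colnames(X) %||% seq_len(ncol(X)))
  # lm drops aliased (collinear) columns: their coefficients are absent
  keep <- logical(length(signals))
  out <- vector("list", length(signals))
  for (k in seq_along(signals)) {
    rn <- paste0("X", leads[k])
    if (!rn %in% rownames(cf)) { keep[k] <- FALSE; next }  # aliased: dropped
    jb <- cf[rn, 1]; js <- cf[rn, 2]
    jp <- 2 * stats::pnorm(-abs(jb / js))
    mb <- signals[[k]]$marginal_beta
    s <- signals[[k]]
    s$joint_beta <- jb; s$joint_se <- js; s$joint_p <- jp
    out[[k]] <- s
    keep[k] <- s$marginal_p < p_gw && jp < p_gw &&
      sign(jb) == sign(mb) && abs(jb - mb) / abs(mb) <= max_rel_diff
  }
  out[keep]
}

#' Group lead credible-set variants across traits into mQTL groups
#'
#' Builds a graph whose nodes are the lead variants and whose edges connect
#' pairs with LD `r^2 >=` `r2_min`; connected components are the mQTL groups.
#' Each group carries the union of associated traits and the lead trait
#' (smallest p).
#'
#' @param leads data frame with `variant_id`, `trait_id`, `p`.
#' @param ld LD correlation (r) matrix covering all lead variants.
#' @param r2_min grouping threshold (default 0.6).
#' @return data frame with `group_id`, `members`, `traits`, `n_traits`,
#'   `lead_trait`, `lead_p`; attribute `membership` maps variant to group.
#' @export
group_mqtls <- function(leads, ld, r2_min = 0.6) {
  ids <- unique(leads$variant_id)
  R <- ld[ids, ids, drop = FALSE]
  A <- (R^2 >= r2_min)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  rows <- lapply(sort(unique(comp)), function(cid) {
    vs <- ids[comp == cid]
    d <- leads[leads$variant_id %in% vs, , drop = FALSE]
    agg <- tapply(d$p, d$trait_id, min)
    lead_trait <- names(agg)[order(agg, names(agg))][1]
    data.frame(group_id = sprintf("G%03d", cid),
               members = paste(sort(vs), collapse = ","),
               traits = paste(sort(unique(d$trait_id)), collapse = ","),
               n_traits = length(unique(d$trait_id)),
               lead_trait = lead_trait, lead_p = min(d$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "membership") <- stats::setNames(sprintf("G%03d", comp), ids)
  out
}

#' Trans-ancestry refinement of a credible set
#'
#' For credible sets with more than one member and suggestive evidence
#' (`p < suggestive_p`) in at least one non-discovery ancestry, per-variant
#' log ABFs are summed across ancestries (independent-evidence
#' approximation) for variants observed in all contributing ancestries,
#' posteriors are renormalized and a new 95% set computed. The refined set is
#' not guaranteed to be smaller; both sizes are reported.
#'
#' @param set credible-set data frame (`variant_id`, `pos` at least).
#' @param ancestry_stats list of per-ancestry data frames with `variant_id`,
#'   `beta`, `se`, `p`; the first element is the discovery ancestry.
#' @param suggestive_p suggestive threshold for a non-discovery ancestry to
#'   contribute (default 1e-5).
#' @param W,coverage Wakefield prior variance and set coverage.
#' @return list with `set` (refined or unchanged), `refined` (logical),
#'   `size_before`, `size_after`.
#' @export
transancestry_refine <- function(set, ancestry_stats, suggestive_p = 1e-5,
                                 W = 0.04, coverage = 0.95) {
  size0 <- nrow(set)
  if (size0 <= 1)
    return(list(set = set, refined = FALSE, size_before = size0,
                size_after = size0))
  ids <- set$variant_id
  contributing <- c(TRUE, vapply(ancestry_stats[-1], function(d) {
    d <- d[d$variant_id %in% ids, , drop = FALSE]
    nrow(d) > 0 && any(d$p < suggestive_p)
  }, logical(1)))
  if (!any(contributing[-1]))
    return(list(set = set, refined = FALSE, size_before = size0,
                size_after = size0))
  use <- ancestry_stats[contributing]
  shared <- Reduce(intersect, lapply(use, function(d) d$variant_id))
  shared <- ids[ids %in% shared]
  if (length(shared) == 0)
    return(list(set = set, refined = FALSE, size_before = size0,
                size_after = size0))
  labf <- Reduce(`+`, lapply(use, function(d) {
    d <- d[match(shared, d$variant_id), , drop = FALSE]
    wakefield_log_abf(d$beta, d$se, W)
  }))
  pos <- set$pos[match(shared, set$variant_id)]
  new_set <- credible_set(labf, shared, pos, coverage)
  new_set <- new_set[new_set$in_set, , drop = FALSE]
  list(set = new_set, refined = TRUE, size_before = size0,
       size_after = nrow(new_set))
}
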