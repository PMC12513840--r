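#' Cohort simulation configuration
#'
#' Bundles the parameters of the synthetic genotype generator. Genotypes are
#' drawn as diploid mosaics of stratum-specific haplotype pools: within each
#' LD block a pool of haplotypes is generated by thresholding a stationary
#' AR(1) Gaussian process, so adjacent-variant correlation decays with
#' `ld_decay`, and each individual samples two pool haplotypes per block.
#' Separate pools per stratum yield stratum-specific allele frequencies and
#' LD patterns.
#'
#' @param n_individuals individuals per stratum.
#' @param n_strata number of ancestral strata (labelled `S1`, `S2`, ...).
#' @param n_blocks number of LD blocks.
#' @param block_size variants per block (must be >= 2, otherwise within-block
#'   LD is undefined).
#' @param ld_decay AR(1) autocorrelation of the latent haplotype process, in
#'   `[0, 1)`. Zero gives independent variants.
#' @param maf_range lower/upper bound of the common-variant minor allele
#'   frequency distribution (uniform draw), both in `(0, 0.5]`.
#' @param rare_fraction proportion of variants drawn as rare (MAF < 0.0005,
#'   log-uniform in `[2e-5, 5e-4]`), placed outside the haplotype pool and
#'   therefore in linkage equilibrium.
#' @param missing_rate per-genotype missing probability (sentinel `NA`).
#' @param pool_size haplotypes per stratum pool.
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 1000L, n_strata = 2L, n_blocks = 4L,
                          block_size = 25L, ld_decay = 0.9,
                          maf_range = c(0.05, 0.5), rare_fraction = 0,
                          missing_rate = 0, pool_size = 2000L, seed = 1L) {
  stopifnot(n_individuals >= 1, n_strata >= 1, n_blocks >= 1,
            length(maf_range) == 2L, all(maf_range > 0), all(maf_range <= 0.5),
            maf_range[1] <= maf_range[2],
            ld_decay >= 0, ld_decay < 1,
            rare_fraction >= 0, rare_fraction < 1,
            missing_rate >= 0, missing_rate < 1,
            pool_size >= 2)
  if (block_size < 2) stop("block_size must be >= 2 (within-block LD undefined)")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_strata = as.integer(n_strata),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 ld_decay = ld_decay, maf_range = maf_range,
                 rare_fraction = rare_fraction, missing_rate = missing_rate,
                 pool_size = as.integer(pool_size), seed = as.integer(seed)),
            class = "cohort_config")
}

# stationary AR(1) Gaussian paths, one row per haplotype
.ar1_paths <- function(n, m, rho) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

#' Generate LD-blocked genotypes for a multi-stratum cohort
#'
#' @param config a [cohort_config()].
#' @return A list with components:
#'   `genotypes` (individuals x variants integer matrix in `{0,1,2}` with `NA`
#'   for missing), `variants` (data frame: `variant_id`, `chrom`, `pos` 1-based,
#'   `ref`, `alt`, `block`, `is_rare`, per-stratum `af_*` and pooled `af`),
#'   `strata` (character vector of stratum labels per individual), and
#'   `ld` (list of per-block empirical dosage correlation matrices, pooled
#'   across strata).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  m_block <- config$block_size
  m <- config$n_blocks * m_block
  n_per <- config$n_individuals
  n <- n_per * config$n_strata
  strata <- rep(paste0("S", seq_len(config$n_strata)), each = n_per)

  n_rare <- round(config$rare_fraction * m)
  is_rare <- rep(FALSE, m)
  if (n_rare > 0) is_rare[sample.int(m, n_rare)] <- TRUE

  # base MAFs, jittered per stratum on the logit scale for common variants
  base_maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  base_maf[is_rare] <- exp(stats::runif(sum(is_rare), log(2e-5), log(5e-4)))
  af_strat <- matrix(0, m, config$n_strata)
  for (s in seq_len(config$n_strata)) {
    jit <- stats::rnorm(m, 0, 0.15)
    lo <- stats::qlogis(pmin(pmax(base_maf, 1e-6), 0.5 - 1e-6)) + jit
    af_strat[, s] <- pmin(stats::plogis(lo), 0.5)
    af_strat[is_rare, s] <- base_maf[is_rare]  # rare AFs shared across strata
  }

  geno <- matrix(0L, n, m)
  for (s in seq_len(config$n_strata)) {
    rows <- which(strata == paste0("S", s))
    for (b in seq_len(config$n_blocks)) {
      cols <- ((b - 1L) * m_block + 1L):(b * m_block)
      common <- cols[!is_rare[cols]]
      if (length(common) > 0) {
        z <- .ar1_paths(config$pool_size, length(common), config$ld_decay)
        thr <- stats::qnorm(af_strat[common, s])
        hap <- sweep(z, 2, thr, "<")
        i1 <- sample.int(config$pool_size, n_per, replace = TRUE)
        i2 <- sample.int(config$pool_size, n_per, replace = TRUE)
        geno[rows, common] <- hap[i1, , drop = FALSE] + hap[i2, , drop = FALSE]
      }
      rare <- cols[is_rare[cols]]
      for (j in rare) {
        geno[rows, j] <- stats::rbinom(n_per, 2L, af_strat[j, s])
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }

  block <- rep(seq_len(config$n_blocks), each = m_block)
  chrom <- ((block - 1L) %% 22L) + 1L
  within <- rep(seq_len(m_block), config$n_blocks)
  pos <- as.integer(1e6 + (block - 1L) %/% 22L * 5e6 + (within - 1L) * 1000L + 1L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  variant_id <- sprintf("chr%d:%d:%s:%s", chrom, pos, ref, alt)
  colnames(geno) <- variant_id
  rownames(geno) <- sprintf("I%05d", seq_len(n))

  af_emp <- colMeans(geno, na.rm = TRUE) / 2
  variants <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                         ref = ref, alt = alt, block = block, is_rare = is_rare,
                         af = af_emp, stringsAsFactors = FALSE)
  for (s in seq_len(config$n_strata)) {
    variants[[paste0("af_S", s)]] <- af_strat[, s]
  }

  ld <- lapply(seq_len(config$n_blocks), function(b) {
    cols <- ((b - 1L) * m_block + 1L):(b * m_block)
    g <- geno[, cols, drop = FALSE]
    suppressWarnings(r <- if (anyNA(g))
      stats::cor(g, use = "pairwise.complete.obs") else stats::cor(g))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    dimnames(r) <- list(variant_id[cols], variant_id[cols])
    r
  })
  names(ld) <- paste0("block", seq_len(config$n_blocks))

  list(genotypes = geno, variants = variants, strata = strata, ld = ld,
       config = config)
}

#' Describe a planted metabolite QTL
#'
#' Declares one causal variant and its mode of molecular pleiotropy. The four
#' pleiotropic modes plus `specific` mirror the association patterns a locus
#' can show across a correlated metabolite panel:
#' * `specific` — direct effects on at most three traits of one factor;
#' * `pathway` — effects on the traits of one factor, proportional to their
#'   loadings;
#' * `proportional` — the effect is injected on a latent factor, so per-trait
#'   effects scale with each trait's correlation to the lead trait;
#' * `disproportional` — effects on one factor's traits with magnitudes forced
#'   discordant with the loadings;
#' * `nonspecific` — direct effects on traits drawn across several factors
#'   with unrelated magnitudes.
#'
#' @param variant_id variant identifier present in the genotype matrix.
#' @param mode one of the five modes above.
#' @param target_traits trait indices (required for `specific`; optional
#'   override for `nonspecific`).
#' @param factor latent factor index (modes `pathway`, `proportional`,
#'   `disproportional`).
#' @param beta effect size in SD units (scalar scale for factor modes; scalar
#'   or per-trait vector for `specific`).
#' @param n_targets number of target traits for `nonspecific`.
#' @param mediated_disease_effect optional scalar recorded for downstream
#'   disease simulation.
#' @export
planted_effect <- function(variant_id, mode = c("specific", "pathway",
                                                "proportional", "disproportional",
                                                "nonspecific"),
                           target_traits = NULL, factor = NULL, beta = 0.1,
                           n_targets = 8L, mediated_disease_effect = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(beta)))
  if (mode == "specific" && is.null(target_traits))
    stop("specific effects require target_traits")
  if (mode %in% c("pathway", "proportional", "disproportional") && is.null(factor))
    stop(sprintf("%s effects require a factor index", mode))
  if (mode == "specific" && length(target_traits) > 3)
    stop("specific effects act on at most 3 traits")
  structure(list(variant_id = variant_id, mode = mode,
                 target_traits = target_traits, factor = factor, beta = beta,
                 n_targets = as.integer(n_targets),
                 mediated_disease_effect = mediated_disease_effect),
            class = "planted_effect")
}

#' Trait panel specification
#'
#' Describes a correlated metabolite panel with latent factor structure:
#' `Y = F L' + G B + E`, where `F` are iid standard-normal factor scores,
#' `L` the loading matrix, `G` standardized planted genotypes and `E`
#' Gaussian noise. Traits are standardized to unit variance after generation.
#'
#' @param loading_matrix traits x factors loading matrix.
#' @param noise_sd per-trait residual SD (recycled), must be positive.
#' @param med_effect per-trait shift applied to individuals on medication
#'   (recycled).
#' @param retest_rho test--retest correlation used for the follow-up copy.
#' @param sex_beta_ratio optional male/female scaling of planted effects.
#' @export
trait_panel_spec <- function(loading_matrix, noise_sd = 0.5, med_effect = 0,
                             retest_rho = 0.9, sex_beta_ratio = NULL) {
  loading_matrix <- as.matrix(loading_matrix)
  n_traits <- nrow(loading_matrix)
  noise_sd <- rep_len(noise_sd, n_traits)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  # implied trait covariance L L' + diag(noise_sd^2) is PD iff noise_sd > 0
  structure(list(n_traits = n_traits, n_factors = ncol(loading_matrix),
                 loading_matrix = loading_matrix, noise_sd = noise_sd,
                 med_effect = rep_len(med_effect, n_traits),
                 retest_rho = retest_rho, sex_beta_ratio = sex_beta_ratio),
            class = "trait_panel_spec")
}

#' Default lipoprotein-panel-like loading matrix
#'
#' A convenience factor structure emulating an NMR panel: `n_factors` tight
#' "lipoprotein subclass" factors with `traits_per_factor` traits each
#' (loadings 0.7--0.95) plus `n_free` independent "small molecule" traits.
#'
#' @param n_factors number of latent factors.
#' @param traits_per_factor traits loading on each factor.
#' @param n_free factor-free traits appended at the end.
#' @param loading_range range of primary loadings.
#' @param seed seed for the loading draw.
#' @export
default_loadings <- function(n_factors = 6L, traits_per_factor = 8L,
                             n_free = 4L, loading_range = c(0.7, 0.95),
                             seed = 1L) {
  set.seed(seed)
  n_traits <- n_factors * traits_per_factor + n_free
  L <- matrix(0, n_traits, n_factors)
  for (k in seq_len(n_factors)) {
    rows <- ((k - 1L) * traits_per_factor + 1L):(k * traits_per_factor)
    L[rows, k] <- stats::runif(traits_per_factor, loading_range[1], loading_range[2])
  }
  L
}

# resolve a planted_effect into a per-trait direct beta vector and/or a
# factor injection; returns list(direct = numeric(n_traits), factor_inject)
.resolve_effect <- function(eff, spec) {
  L <- spec$loading_matrix
  n_traits <- spec$n_traits
  direct <- numeric(n_traits)
  inject <- NULL
  primary_factor <- apply(abs(L), 1, function(r) if (all(r == 0)) 0L else which.max(r))
  switch(eff$mode,
    specific = {
      if (any(eff$target_traits > n_traits)) stop("effect references absent trait")
      direct[eff$target_traits] <- rep_len(eff$beta, length(eff$target_traits))
    },
    pathway = {
      rows <- which(primary_factor == eff$factor)
      direct[rows] <- eff$beta * L[rows, eff$factor]
    },
    proportional = {
      inject <- list(factor = eff$factor, beta = eff$beta)
    },
    disproportional = {
      rows <- which(primary_factor == eff$factor)
      lo <- L[rows, eff$factor]
      mag <- eff$beta * stats::runif(length(rows), 0.5, 1.5)
      # loading-discordant magnitudes: a fresh random permutation per
      # variant, rejected until its correlation with the loadings is <= 0.
      # A fixed anti-rank profile would make all such variants on a factor
      # share one beta pattern, and their summed genetic covariance would
      # coherently distort the trait correlations the classifier consumes.
      for (try in 1:20) {
        perm <- sample.int(length(rows))
        if (stats::cor(mag[perm], lo) <= 0) break
      }
      direct[rows] <- mag[perm]
    },
    nonspecific = {
      if (!is.null(eff$target_traits)) {
        rows <- eff$target_traits
      } else {
        rows <- sample.int(n_traits, min(eff$n_targets, n_traits))
      }
      if (any(rows > n_traits)) stop("effect references absent trait")
      # constant magnitude, random signs: the variant's own effect then
      # induces the same (tiny) trait correlation for every target, so no
      # magnitude/correlation relationship is created by construction
      direct[rows] <- eff$beta * sample(c(-1, 1), length(rows), replace = TRUE)
    })
  list(direct = direct, inject = inject)
}

#' Generate a correlated trait panel with planted mQTLs
#'
#' @param genotypes result of [generate_genotypes()] (or a genotype matrix).
#' @param spec a [trait_panel_spec()].
#' @param effects list of [planted_effect()] objects.
#' @param seed integer seed.
#' @return list with `traits` (individuals x traits, unit variance),
#'   `truth` (data frame per planted effect x target trait: variant, mode,
#'   trait, beta) and `factors` (latent factor scores, post-injection).
#' @export
generate_trait_panel <- function(genotypes, spec, effects = list(), seed = 1L) {
  stopifnot(inherits(spec, "trait_panel_spec"))
  geno <- if (is.list(genotypes) && !is.null(genotypes$genotypes)) genotypes$genotypes else genotypes
  set.seed(seed)
  n <- nrow(geno)
  L <- spec$loading_matrix
  Fsc <- matrix(stats::rnorm(n * spec$n_factors), n, spec$n_factors)

  B <- matrix(0, n, spec$n_traits)  # accumulated direct genetic effects
  truth <- list()
  for (eff in effects) {
    if (!eff$variant_id %in% colnames(geno))
      stop(sprintf("effect references absent variant %s", eff$variant_id))
    g <- geno[, eff$variant_id]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (stats::sd(g) == 0) stop("planted variant is monomorphic")
    gs <- g - mean(g)  # betas are per allele, in trait-SD units
    res <- .resolve_effect(eff, spec)
    if (!is.null(res$inject)) {
      Fsc[, res$inject$factor] <- Fsc[, res$inject$factor] + gs * res$inject$beta
      implied <- L[, res$inject$factor] * res$inject$beta
      res$direct <- implied  # record implied per-trait effects in the truth
      B <- B  # injection acts through the factor, not through B
    } else {
      B <- B + outer(gs, res$direct)
    }
    hit <- which(res$direct != 0)
    truth[[length(truth) + 1L]] <- data.frame(
      variant_id = eff$variant_id, mode = eff$mode, trait = hit,
      beta = res$direct[hit], stringsAsFactors = FALSE)
  }

  E <- matrix(stats::rnorm(n * spec$n_traits), n, spec$n_traits)
  E <- sweep(E, 2, spec$noise_sd, "*")
  Y <- Fsc %*% t(L) + B + E
  Y <- scale(Y)
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  colnames(Y) <- sprintf("T%03d", seq_len(spec$n_traits))
  rownames(Y) <- rownames(geno)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(variant_id = character(), mode = character(),
               trait = integer(), beta = numeric())
  list(traits = Y, truth = truth, factors = Fsc)
}

#' Simulate medication status, medicated trait shifts and a repeat visit
#'
#' Medication shifts measures taken while the individual is on medication.
#' A fraction `treated_fraction` of the cohort is treated at baseline (their
#' baseline values are shifted by `spec$med_effect`). A follow-up copy of the
#' panel is produced for a subset of individuals untreated at baseline
#' (test--retest correlation `spec$retest_rho`); a fraction `start_fraction`
#' of that subset has started medication by follow-up, so their follow-up
#' values carry the shift. This is the substrate [adjust_medication()] uses
#' to estimate and remove the medication effect.
#'
#' @param traits trait matrix from [generate_trait_panel()] (unshifted).
#' @param spec the [trait_panel_spec()] (provides `med_effect`, `retest_rho`).
#' @param treated_fraction fraction treated at baseline, in `[0, 1)`.
#' @param followup_fraction fraction of untreated-at-baseline individuals with
#'   a repeat visit.
#' @param start_fraction fraction of the follow-up subset that starts
#'   medication between visits.
#' @param seed integer seed.
#' @return list with `baseline` (shifted matrix), `treated` (logical),
#'   `followup` (matrix over the follow-up subset), `followup_ids` (row
#'   indices), `followup_treated` (logical over the subset).
#' @export
generate_medication <- function(traits, spec, treated_fraction = 0.15,
                                followup_fraction = 0.2, start_fraction = 0.3,
                                seed = 1L) {
  stopifnot(treated_fraction >= 0, treated_fraction < 1)
  set.seed(seed)
  n <- nrow(traits)
  treated <- stats::runif(n) < treated_fraction
  baseline <- traits
  if (any(treated))
    baseline[treated, ] <- sweep(baseline[treated, , drop = FALSE], 2,
                                 spec$med_effect, "+")
  untreated_idx <- which(!treated)
  fu_ids <- sort(sample(untreated_idx,
                        round(followup_fraction * length(untreated_idx))))
  rho <- spec$retest_rho
  fu <- rho * traits[fu_ids, , drop = FALSE] +
    sqrt(1 - rho^2) * matrix(stats::rnorm(length(fu_ids) * ncol(traits)),
                             length(fu_ids), ncol(traits))
  fu_treated <- stats::runif(length(fu_ids)) < start_fraction
  if (any(fu_treated))
    fu[fu_treated, ] <- sweep(fu[fu_treated, , drop = FALSE], 2,
                              spec$med_effect, "+")
  list(baseline = baseline, treated = treated, followup = fu,
       followup_ids = fu_ids, followup_treated = fu_treated)
}

#' Generate rare-variant annotations and genotype-level QC fields
#'
#' Assigns each variant a consequence class, LOFTEE-like confidence, CADD- and
#' REVEL-like scores, a VEP-like impact, and a gene; and draws per-genotype
#' sequencing depth (DP), genotype quality (GQ) and heterozygous allele
#' balance (AB) so that QC filters have a known pass/fail truth.
#'
#' @param variants variant table from [generate_genotypes()].
#' @param n_genotypes number of individuals for the QC field matrices (0 to
#'   skip).
#' @param consequence_prob named multinomial over
#'   `c(pLOF, missense, synonymous, other)`.
#' @param genes_per_block genes tiled per LD block.
#' @param dp_mean,gq_mean means of the Poisson/shifted-Poisson DP and GQ draws.
#' @param seed integer seed.
#' @return list with `annotations` (data frame) and, when `n_genotypes > 0`,
#'   matrices `dp`, `gq`, `ab` (individuals x variants).
#' @export
generate_rare_annotations <- function(variants, n_genotypes = 0L,
                                      consequence_prob = c(pLOF = 0.08,
                                                           missense = 0.45,
                                                           synonymous = 0.30,
                                                           other = 0.17),
                                      genes_per_block = 2L,
                                      dp_mean = 30, gq_mean = 60, seed = 1L) {
  set.seed(seed)
  m <- nrow(variants)
  cons <- sample(names(consequence_prob), m, replace = TRUE,
                 prob = consequence_prob)
  loftee <- ifelse(cons == "pLOF",
                   sample(c("HC", "LC"), m, replace = TRUE, prob = c(0.7, 0.3)),
                   NA_character_)
  cadd <- stats::rgamma(m, shape = 2, scale = 6)
  cadd[cons == "pLOF"] <- cadd[cons == "pLOF"] + 20
  revel <- stats::rbeta(m, 1.2, 3)
  revel[cons != "missense"] <- stats::rbeta(sum(cons != "missense"), 1, 8)
  impact <- ifelse(cons == "pLOF", "HIGH",
                   ifelse(cons == "missense", "MODERATE", "LOW"))
  gene_idx <- (variants$block - 1L) * genes_per_block +
    1L + (seq_len(m) %% genes_per_block)
  gene <- sprintf("GENE%03d", gene_idx)
  ann <- data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
                    pos = variants$pos, gene = gene, consequence = cons,
                    loftee = loftee, cadd = cadd, revel = revel,
                    impact = impact, is_rare = variants$is_rare,
                    af = variants$af, stringsAsFactors = FALSE)
  out <- list(annotations = ann)
  if (n_genotypes > 0) {
    dp <- matrix(stats::rpois(n_genotypes * m, dp_mean), n_genotypes, m)
    gq <- matrix(pmin(99L, stats::rpois(n_genotypes * m, gq_mean)),
                 n_genotypes, m)
    ab <- matrix(stats::rbeta(n_genotypes * m, 20, 20), n_genotypes, m)
    colnames(dp) <- colnames(gq) <- colnames(ab) <- variants$variant_id
    out$dp <- dp; out$gq <- gq; out$ab <- ab
  }
  out
}

#' Generate binary disease outcomes under a liability-threshold model
#'
#' Liability = theta * trait + direct variant effects + N(0,1) noise; cases
#' are the top `prevalence` quantile of the liability distribution.
#'
#' @param genotypes genotype matrix or [generate_genotypes()] result.
#' @param traits trait matrix.
#' @param disease_spec list with `trait` (column name or index), `theta`
#'   (causal effect of the trait on liability), `prevalence` in `(0,1)`, and
#'   optionally `direct_effects` (named vector of per-variant liability
#'   effects, names = variant ids).
#' @param seed integer seed.
#' @return list with `outcome` (0/1 vector) and `truth` (theta, prevalence,
#'   direct effects).
#' @export
generate_outcomes <- function(genotypes, traits, disease_spec, seed = 1L) {
  geno <- if (is.list(genotypes) && !is.null(genotypes$genotypes)) genotypes$genotypes else genotypes
  prev <- disease_spec$prevalence
  if (is.null(prev) || prev <= 0 || prev >= 1)
    stop("prevalence must be in (0, 1)")
  set.seed(seed)
  n <- nrow(traits)
  liab <- stats::rnorm(n)
  theta <- disease_spec$theta %||% 0
  if (theta != 0) {
    tr <- traits[, disease_spec$trait]
    liab <- liab + theta * tr
  }
  de <- disease_spec$direct_effects
  if (!is.null(de) && length(de)) {
    for (v in names(de)) {
      g <- geno[, v]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      liab <- liab + de[[v]] * (g - mean(g)) / max(stats::sd(g), 1e-12)
    }
  }
  thr <- stats::quantile(liab, 1 - prev)
  outcome <- as.integer(liab > thr)
  list(outcome = outcome,
       truth = list(theta = theta, prevalence = prev, direct_effects = de))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
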