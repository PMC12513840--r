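#' Simulate one association region with a single planted causal variant
#'
#' Convenience driver used by the calibration experiments: LD-blocked
#' genotypes for one region, a quantitative trait with one causal variant,
#' and the marginal scan statistics.
#'
#' @param n individuals.
#' @param m variants in the region.
#' @param maf target minor allele frequency of all region variants.
#' @param ld_decay LD decay of the block.
#' @param beta per-allele effect of the causal variant (0 for a null region).
#' @param causal index of the causal variant.
#' @param seed integer seed.
#' @return list with `geno` ([generate_genotypes()] result), `stats` (scan
#'   records), `ld` (empirical correlation matrix), `causal` (variant id),
#'   `trait`.
#' @export
simulate_region <- function(n = 50000, m = 50, maf = 0.2, ld_decay = 0.9,
                            beta = 0.15, causal = ceiling(m / 2), seed = 1) {
  cfg <- cohort_config(n_individuals = n, n_strata = 1, n_blocks = 1,
                       block_size = m, ld_decay = ld_decay,
                       maf_range = c(maf, maf), seed = seed)
  g <- generate_genotypes(cfg)
  set.seed(seed + 7L)
  gc_ <- g$genotypes[, causal]
  y <- beta * (gc_ - mean(gc_)) + stats::rnorm(n)
  sc <- run_scan(g, y, maf_min = 0)
  list(geno = g, stats = sc, ld = g$ld[[1]],
       causal = colnames(g$genotypes)[causal], trait = y)
}

#' Simulate the five-mode pleiotropy benchmark panel
#'
#' The frozen benchmark: `5 * n_per_mode` independent variants
#' (MAF 0.15--0.45) planted into a 96-trait panel with 6 tight lipoprotein-
#' like factors (8 traits each, loadings evenly spaced over 0.78--0.95), 4
#' wide factors (10 traits each, loadings evenly spaced over 0.25--0.90) and
#' 8 factor-free traits. Pathway effects use tight factors 1--3 and
#' disproportional effects tight factors 4--6, so the loading-aligned and
#' loading-discordant genetic covariance each mode injects does not distort
#' the other's trait-correlation structure. Per mode: specific (beta 0.12 on
#' 3 tight-factor traits), pathway (theta 0.2 on a tight factor),
#' proportional (theta 0.45 injected on a wide factor), disproportional
#' (theta 0.12, loading-discordant magnitudes), nonspecific (0.15 on 12
#' traits across distinct factors). All planted effects are at least 0.1 SD.
#'
#' @param n_per_mode planted groups per mode (default 50).
#' @param n_individuals cohort size (default 50,000).
#' @param seed integer seed.
#' @return list with `geno`, `traits`, `truth` (data frame `variant_id`,
#'   `mode`), `spec`.
#' @export
simulate_mode_panel <- function(n_per_mode = 50L, n_individuals = 50000L,
                                seed = 1L) {
  modes <- c("specific", "pathway", "proportional", "disproportional",
             "nonspecific")
  n_var <- 5L * n_per_mode
  cfg <- cohort_config(n_individuals = n_individuals, n_strata = 1,
                       n_blocks = 5, block_size = ceiling(n_var / 5),
                       ld_decay = 0, maf_range = c(0.15, 0.45), seed = seed)
  g <- generate_genotypes(cfg)
  set.seed(seed + 1L)
  n_tight <- 6L; n_wide <- 4L
  L <- matrix(0, n_tight * 8 + n_wide * 10 + 8, n_tight + n_wide)
  for (k in seq_len(n_tight))
    L[((k - 1) * 8 + 1):(k * 8), k] <-
      seq(0.78, 0.95, length.out = 8) + stats::runif(8, -0.005, 0.005)
  wide0 <- n_tight * 8
  for (k in seq_len(n_wide))
    L[(wide0 + (k - 1) * 10 + 1):(wide0 + k * 10), n_tight + k] <-
      seq(0.25, 0.9, length.out = 10) + stats::runif(10, -0.01, 0.01)
  free0 <- wide0 + n_wide * 10
  slots <- c(lapply(seq_len(n_tight), function(k) ((k - 1) * 8 + 1):(k * 8)),
             lapply(seq_len(n_wide), function(k)
               (wide0 + (k - 1) * 10 + 1):(wide0 + k * 10)),
             as.list(free0 + 1:8))
  spec <- trait_panel_spec(L, noise_sd = sqrt(1 - rowSums(L^2)))
  vid <- g$variants$variant_id
  effs <- vector("list", n_var)
  truth_mode <- character(n_var)
  for (i in seq_len(n_var)) {
    mo <- modes[(i - 1) %/% n_per_mode + 1]
    truth_mode[i] <- mo
    f_path <- (i %% 3) + 1            # tight factors 1-3: pathway + specific
    f_dis <- 4 + (i %% 3)             # tight factors 4-6: disproportional
    f_w <- n_tight + (i %% n_wide) + 1
    effs[[i]] <- switch(mo,
      specific = planted_effect(vid[i], "specific",
        target_traits = ((f_path - 1) * 8 + 1):((f_path - 1) * 8 + 3),
        beta = 0.12),
      pathway = planted_effect(vid[i], "pathway", factor = f_path,
                               beta = 0.2),
      proportional = planted_effect(vid[i], "proportional", factor = f_w,
                                    beta = 0.45),
      disproportional = planted_effect(vid[i], "disproportional",
                                       factor = f_dis, beta = 0.12),
      nonspecific = {
        tt <- vapply(sample(slots, 12), function(s)
          as.integer(s[sample.int(length(s), 1)]), integer(1))
        planted_effect(vid[i], "nonspecific", target_traits = tt, beta = 0.15)
      })
  }
  tp <- generate_trait_panel(g, spec, effs, seed = seed + 2L)
  list(geno = g, traits = tp$traits,
       truth = data.frame(variant_id = vid[seq_len(n_var)], mode = truth_mode,
                          stringsAsFactors = FALSE),
       spec = spec)
}

#' Classify the planted benchmark and compare with the truth
#'
#' Scans every trait against the benchmark variants, takes the traits passing
#' the metabolome-adjusted threshold as each variant's associated set, runs
#' [classify_mqtl()] and tabulates recovery against the planted modes.
#'
#' @param sim result of [simulate_mode_panel()].
#' @param threshold association threshold (default the metabolome-adjusted
#'   `5e-8 / n_traits`).
#' @return list with `calls` (data frame `variant_id`, `truth`, `called`),
#'   `confusion` (table), `recovery` (named per-mode rate).
#' @export
recover_modes <- function(sim, threshold = NULL) {
  nt <- ncol(sim$traits)
  if (is.null(threshold)) threshold <- significance_threshold(5e-8, nt)
  vid <- sim$truth$variant_id
  P <- matrix(NA_real_, length(vid), nt, dimnames = list(vid, colnames(sim$traits)))
  G <- sim$geno$genotypes[, vid, drop = FALSE]
  for (t in seq_len(nt)) {
    sc <- run_scan(G, sim$traits[, t], maf_min = 0)
    P[sc$variant_id, t] <- sc$p
  }
  rho <- stats::cor(sim$traits)
  tn <- colnames(sim$traits)
  called <- vapply(seq_along(vid), function(i) {
    assoc <- tn[P[i, ] < threshold]
    if (length(assoc) == 0) return("none")
    classify_mqtl(assoc, rho,
                  data.frame(trait_id = assoc, p = P[i, assoc]))$mode
  }, character(1))
  calls <- data.frame(variant_id = vid, truth = sim$truth$mode,
                      called = called, stringsAsFactors = FALSE)
  conf <- table(truth = calls$truth, called = calls$called)
  recovery <- vapply(split(calls$called == calls$truth, calls$truth), mean,
                     numeric(1))
  list(calls = calls, confusion = conf, recovery = recovery)
}

#' Simulate synthetic effector-gene loci with fully informative features
#'
#' Builds `n_loci` loci of `genes_per_locus` candidate genes each, one causal
#' gene per locus. Causal genes carry coding-proxy, eQTL and metabolic-
#' database evidence with high probability; decoys with low probability. Each
#' locus variant is fine-mapped for a trait of one of the three metabolite
#' classes, and the class pathway gene sets contain the causal genes (plus
#' filler genes outside the loci), so PTP construction labels causal genes
#' positive.
#'
#' @param n_loci number of loci/variants.
#' @param genes_per_locus candidate genes per locus.
#' @param p_feature probability a causal gene carries each evidence type.
#' @param p_noise probability a decoy carries an evidence type.
#' @param seed integer seed.
#' @return list with `candidates`, `features`, `finemapped`, `trait_class`,
#'   `gene_sets`, `truth` (data frame `variant_id`, `causal_gene`),
#'   `genes` (gene model table).
#' @export
simulate_effector_loci <- function(n_loci = 60L, genes_per_locus = 6L,
                                   p_feature = 0.9, p_noise = 0.05,
                                   seed = 1L) {
  set.seed(seed)
  classes <- c("cholesterol", "lipid", "amino_acid")
  genes <- list(); cands <- list(); truth <- list(); fm <- list()
  coding <- list(); eqtl <- list()
  metabolic <- character(0)
  for (i in seq_len(n_loci)) {
    chrom <- (i - 1L) %% 22L + 1L
    base <- 3e6 * ((i - 1L) %/% 22L + 1L) + 2e6 * ((i - 1L) %% 22L)
    starts <- base + sort(sample.int(8e5, genes_per_locus)) * 1L
    gid <- sprintf("L%03dG%d", i, seq_len(genes_per_locus))
    genes[[i]] <- data.frame(gene = gid, chrom = chrom, start = starts,
                             end = starts + 2e4, stringsAsFactors = FALSE)
    vpos <- base + sample.int(8.2e5, 1)
    vid <- sprintf("chr%d:%d:A:G", chrom, vpos)
    cand <- collect_candidates(vid, chrom, vpos, genes[[i]])
    causal <- sample(gid, 1)
    truth[[i]] <- data.frame(variant_id = vid, causal_gene = causal,
                             stringsAsFactors = FALSE)
    fm[[i]] <- data.frame(variant_id = vid,
                          trait_id = classes[(i - 1L) %% 3L + 1L],
                          stringsAsFactors = FALSE)
    for (g in cand$gene) {
      is_causal <- g == causal
      if (stats::runif(1) < (if (is_causal) p_feature else p_noise))
        coding[[length(coding) + 1L]] <- data.frame(variant_id = vid, gene = g)
      if (stats::runif(1) < (if (is_causal) p_feature else p_noise))
        eqtl[[length(eqtl) + 1L]] <- data.frame(variant_id = vid, gene = g,
                                                tissue = "liver")
      if (stats::runif(1) < (if (is_causal) 0.8 else p_noise))
        metabolic <- c(metabolic, g)
    }
    cands[[i]] <- cand
  }
  candidates <- do.call(rbind, cands)
  truth <- do.call(rbind, truth)
  finemapped <- do.call(rbind, fm)
  # trait ids are the class names themselves in this synthetic benchmark
  trait_class <- stats::setNames(classes, classes)
  gene_sets <- lapply(stats::setNames(classes, classes), function(cl) {
    vids <- finemapped$variant_id[finemapped$trait_id == cl]
    c(truth$causal_gene[truth$variant_id %in% vids],
      sprintf("FILLER_%s_%d", cl, 1:20))
  })
  features <- build_features(candidates, coding = do.call(rbind, coding),
                             eqtl = do.call(rbind, eqtl),
                             metabolic_genes = unique(metabolic))
  list(candidates = candidates, features = features, finemapped = finemapped,
       trait_class = trait_class, gene_sets = gene_sets, truth = truth,
       genes = do.call(rbind, genes))
}

#' Run the effector-gene scoring benchmark
#'
#' Constructs the three PTP sets, trains the three classifiers, scores all
#' candidates and reports top-1 causal-gene recovery together with the naive
#' closest-gene baseline.
#'
#' @param sim result of [simulate_effector_loci()].
#' @param seed training seed.
#' @return list with `scored` (scored candidate table), `top1_recovery`,
#'   `closest_gene_baseline`, `classifiers`.
#' @export
effector_benchmark <- function(sim, seed = 1L) {
  ptp <- construct_ptp(sim$finemapped, sim$trait_class, sim$gene_sets,
                       sim$candidates, seed = seed)
  feat_cols <- c("distance_bp", "rank", "coding", "eqtl_liver", "metabolic")
  cls <- lapply(seq_along(ptp), function(i)
    train_classifier(ptp[[i]], sim$features, feature_cols = feat_cols,
                     seed = seed + i))
  scored <- score_genes(cls, sim$features)
  top1 <- vapply(unique(scored$variant_id), function(v) {
    d <- scored[scored$variant_id == v, ]
    d$gene[which.max(d$score)] ==
      sim$truth$causal_gene[sim$truth$variant_id == v]
  }, logical(1))
  closest <- vapply(unique(scored$variant_id), function(v) {
    d <- scored[scored$variant_id == v, ]
    d$gene[which.min(d$distance_bp)] ==
      sim$truth$causal_gene[sim$truth$variant_id == v]
  }, logical(1))
  list(scored = scored, top1_recovery = mean(top1),
       closest_gene_baseline = mean(closest), classifiers = cls)
}

#' Simulate one gene for the burden / PGS-robustness experiment
#'
#' Draws rare variant genotypes for one gene plus one common variant. In the
#' `independent` configuration the trait carries a true burden effect and a
#' separate common-variant effect; in the `contaminated` configuration there
#' is no rare effect but rare alleles reside only on common-allele
#' haplotypes, so the burden tags the common signal.
#'
#' @param n individuals.
#' @param n_rare rare variants in the gene.
#' @param carriers approximate total carrier count.
#' @param burden_beta true burden effect (SD units).
#' @param common_maf,common_beta the common variant.
#' @param contaminated logical (see above).
#' @param seed integer seed.
#' @return list with `burden`, `trait`, `pgs` (common-variant score),
#'   `geno_rare`.
#' @export
simulate_burden_gene <- function(n = 20000L, n_rare = 5L, carriers = 30L,
                                 burden_beta = 1.0, common_maf = 0.1,
                                 common_beta = 0.25, contaminated = FALSE,
                                 seed = 1L) {
  set.seed(seed)
  gc_ <- stats::rbinom(n, 2, common_maf)
  geno_rare <- matrix(0L, n, n_rare)
  per_var <- max(1L, round(carriers / n_rare))
  eligible <- if (contaminated) which(gc_ >= 1) else seq_len(n)
  for (j in seq_len(n_rare)) {
    idx <- sample(eligible, per_var)
    geno_rare[idx, j] <- 1L
  }
  colnames(geno_rare) <- sprintf("rv%d", seq_len(n_rare))
  burden <- burden_collapse(geno_rare, colnames(geno_rare))
  y <- common_beta * (gc_ - mean(gc_)) + stats::rnorm(n)
  if (!contaminated) y <- y + burden_beta * burden
  list(burden = burden, trait = y, pgs = common_beta * gc_,
       geno_rare = geno_rare)
}

#' Simulate a two-sample Mendelian randomization instrument table
#'
#' Exposure and outcome statistics are drawn with independent errors
#' (emulating non-overlapping exposure and outcome halves of a cohort), with
#' a planted causal effect `theta` and optional balanced horizontal
#' pleiotropy.
#'
#' @param theta causal effect of the exposure on the outcome.
#' @param n_inst number of instruments.
#' @param pleiotropy_sd SD of per-instrument balanced pleiotropic effects.
#' @param se_x,se_y exposure/outcome standard errors.
#' @param seed integer seed.
#' @return instrument data frame for [ivw()] / [mr_egger()].
#' @export
simulate_mr_instruments <- function(theta = 0.3, n_inst = 50L,
                                    pleiotropy_sd = 0, se_x = 0.01,
                                    se_y = 0.02, seed = 1L) {
  set.seed(seed)
  bx <- stats::runif(n_inst, 0.05, 0.2) * sample(c(-1, 1), n_inst, TRUE)
  alpha <- stats::rnorm(n_inst, 0, pleiotropy_sd)
  data.frame(
    beta_exposure = bx + stats::rnorm(n_inst, 0, se_x),
    se_exposure = se_x,
    beta_outcome = theta * bx + alpha + stats::rnorm(n_inst, 0, se_y),
    se_outcome = se_y)
}
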