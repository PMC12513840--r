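test_that("genotype QC applies DP/GQ/AB/missingness rules on the packaged fixture", {
  vcf <- system.file("extdata", "qc_toy.vcf", package = "metabogen")
  truth <- readLines(system.file("extdata", "qc_toy_truth.txt",
                                 package = "metabogen"))
  x <- read_qc_vcf(vcf)
  res <- genotype_qc(x$genotypes, x$dp, x$gq, x$ab,
                     variant_type = x$variants$variant_type)
  expect_identical(sort(res$kept), sort(truth))
  expect_equal(length(res$kept), 4)
  # idempotence: filtering the filtered output changes nothing
  keep <- res$kept
  res2 <- genotype_qc(res$genotypes, x$dp[, keep], x$gq[, keep],
                      x$ab[, keep])
  expect_identical(res2$genotypes, res$genotypes)
})

test_that("clean calls pass QC untouched; DP thresholds differ for INDELs", {
  n <- 30; m <- 4
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m,
                 dimnames = list(NULL, paste0("v", 1:m)))
  dp <- matrix(30, n, m); gq <- matrix(60, n, m); ab <- matrix(0.5, n, m)
  res <- genotype_qc(geno, dp, gq, ab)
  expect_identical(res$genotypes, geno)
  expect_equal(nrow(res$excluded), 0)

  # DP 8 passes for a SNP but is masked for an INDEL
  dp8 <- matrix(8, n, m)
  res2 <- genotype_qc(geno, dp8, gq, ab,
                      variant_type = c("SNP", "INDEL", "SNP", "INDEL"))
  expect_false(anyNA(res2$genotypes[, "v1"]))
  expect_false("v2" %in% res2$kept)  # all calls masked -> missingness 100%

  # a single failing heterozygote excludes the variant under the strict rule
  ab_bad <- ab
  het <- which(geno[, 3] == 1)[1]
  ab_bad[het, 3] <- 0.9
  res3 <- genotype_qc(geno, dp, gq, ab_bad)
  expect_false("v3" %in% res3$kept)
  # fraction-based alternative tolerates one failing het out of many
  res4 <- genotype_qc(geno, dp, gq, ab_bad, ab_fraction = 0.5)
  expect_true("v3" %in% res4$kept)
})

test_that("variant masks follow the predicate table and nest correctly", {
  ann <- data.frame(
    variant_id = paste0("v", 1:6), gene = "G1",
    consequence = c("pLOF", "pLOF", "missense", "missense", "synonymous",
                    "other"),
    loftee = c("HC", "LC", NA, NA, NA, NA),
    cadd = c(35, 30, 25, 5, 2, 1),
    revel = c(0.1, 0.2, 0.3, 0.2, 0.01, 0.01),
    impact = c("HIGH", "HIGH", "MODERATE", "MODERATE", "LOW", "LOW"),
    af = rep(0.0001, 6))
  masks <- build_masks(ann)
  g1 <- masks$G1
  bin <- "maf_lt_0.005"
  # missense with CADD 25: in M3, M4, M6; not M1/M2
  expect_true("v3" %in% g1$M3_pLOF_highmiss[[bin]])
  expect_true("v3" %in% g1$M4_pLOF_anymiss[[bin]])
  expect_true("v3" %in% g1$M6_missense_only[[bin]])
  expect_false("v3" %in% g1$M2_pLOF[[bin]])
  # HC stop-gained: in M1-M5
  for (mk in c("M1_pLOF_HC", "M2_pLOF", "M3_pLOF_highmiss", "M4_pLOF_anymiss",
               "M5_high_impact"))
    expect_true("v1" %in% g1[[mk]][[bin]])
  # synonymous only in S
  expect_true("v5" %in% g1$S_synonymous[[bin]])
  expect_false("v5" %in% unlist(g1[setdiff(names(g1), "S_synonymous")]))
  # nesting M1 subset M2 subset M4; S disjoint from M1-M6
  expect_true(all(g1$M1_pLOF_HC[[bin]] %in% g1$M2_pLOF[[bin]]))
  expect_true(all(g1$M2_pLOF[[bin]] %in% g1$M4_pLOF_anymiss[[bin]]))
  expect_length(intersect(g1$S_synonymous[[bin]],
                          unlist(g1[setdiff(names(g1), "S_synonymous")])), 0)
  # MAF bins: a 0.3% variant is in the 0.5% bin but not the 0.005% bin
  ann2 <- ann; ann2$af <- 0.003
  g2 <- build_masks(ann2)$G1
  expect_true("v1" %in% g2$M1_pLOF_HC[["maf_lt_0.005"]])
  expect_false("v1" %in% g2$M1_pLOF_HC[["maf_lt_5e-05"]])
})

test_that("mask nesting holds on generated annotation fixtures", {
  cfg <- cohort_config(n_individuals = 10, n_strata = 1, n_blocks = 10,
                       block_size = 60, rare_fraction = 0.8, ld_decay = 0,
                       seed = 31)
  g <- generate_genotypes(cfg)
  ann <- generate_rare_annotations(g$variants, seed = 32)$annotations
  masks <- build_masks(ann)
  for (gene in names(masks)) for (b in c("maf_lt_0.005", "maf_lt_5e-05")) {
    expect_true(all(masks[[gene]]$M1_pLOF_HC[[b]] %in%
                      masks[[gene]]$M2_pLOF[[b]]))
    expect_true(all(masks[[gene]]$M2_pLOF[[b]] %in%
                      masks[[gene]]$M4_pLOF_anymiss[[b]]))
  }
})

test_that("burden collapsing caps at two alleles and logs missingness", {
  geno <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1), c(NA, 1, 0))
  colnames(geno) <- c("a", "b", "c")
  b <- burden_collapse(geno, c("a", "b", "c"))
  expect_equal(as.integer(b), c(0L, 1L, 2L, 1L))
  expect_equal(attr(b, "missingness"), 1 / 12)
  expect_message(expect_null(burden_collapse(geno, character(0))), "empty mask")
})

test_that("ACAT is a fixed point on identical p values and matches the transform", {
  expect_equal(acat(rep(0.01, 5)), 0.01, tolerance = 1e-12)
  expect_equal(acat(0.5), 0.5)
  # p = {0.01, 0.5}: T = tan(0.49 pi)/2, p = 0.5 - atan(T)/pi
  T_stat <- (tan(0.49 * pi) + tan(0 * pi)) / 2
  expect_equal(acat(c(0.01, 0.5)), 0.5 - atan(T_stat) / pi, tolerance = 1e-12)
  expect_lt(abs(acat(c(0.01, 0.5)) - 0.0199), 3e-4)
  # random vectors match direct evaluation
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    w <- runif(length(p))
    direct <- 0.5 - atan(sum(w * tan((0.5 - p) * pi)) / sum(w)) / pi
    expect_equal(acat(p, w), direct, tolerance = 1e-12)
  }
  # tiny p survive the tangent asymptote and remain a fixed point
  expect_equal(acat(rep(1e-20, 3)), 1e-20, tolerance = 1e-12)
  expect_error(acat(c(0.1, 0)), "p values")
})

test_that("burden test recovers a planted effect and the PGS-robustness rule works", {
  sim <- simulate_burden_gene(n = 20000, carriers = 30, burden_beta = 1.0,
                              seed = 41)
  res <- burden_test(sim$trait, list(M1 = sim$burden), pgs = sim$pgs)
  expect_lt(abs(res$per_mask$beta - 1.0), 0.25)

  # burden tagging a common variant: effect collapses under PGS adjustment
  simc <- simulate_burden_gene(n = 20000, carriers = 60, burden_beta = 0,
                               common_beta = 1.0, contaminated = TRUE,
                               seed = 42)
  resc <- burden_test(simc$trait, list(M1 = simc$burden), pgs = simc$pgs)
  expect_false(resc$robust)
  expect_lt(abs(resc$per_mask$beta), abs(resc$per_mask$beta0) * 0.8)

  # zero-variance burden is skipped
  res0 <- burden_test(sim$trait, list(M1 = rep(0L, 20000)))
  expect_true(is.na(res0$acat_p))
})

test_that("null gene-level ACAT p values are uniform", {
  set.seed(43)
  n <- 4000
  ps <- replicate(400, {
    y <- rnorm(n)
    burdens <- lapply(1:3, function(i) rbinom(n, 1, 0.002))
    names(burdens) <- paste0("M", 1:3)
    burden_test(y, burdens)$acat_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ExWAS applies the MAC and MAF reporting rules", {
  set.seed(44)
  n <- 10000
  y <- rnorm(n)
  g5 <- integer(n); g5[1:5] <- 1L   # MAC 5: excluded
  expect_null(exwas(g5, y))
  g6 <- integer(n); g6[1:6] <- 1L   # MAC 6, MAF 3e-4: tested and reported
  r6 <- exwas(g6, y)
  expect_true(r6$reported)
  g20 <- integer(n); g20[1:20] <- 1L  # MAF 1e-3: tested, not reported
  r20 <- exwas(g20, y)
  expect_false(r20$reported)
  expect_equal(r20$mac, 20)
})

test_that("disease burden recovers a planted odds ratio and guards tiny carriers", {
  set.seed(45)
  n <- 50000
  burden <- integer(n); burden[sample(n, 200)] <- 1L
  eta <- log(0.1 / 0.9) + log(2.5) * burden
  y <- rbinom(n, 1, plogis(eta))
  r <- disease_burden(y, burden)
  expect_equal(r$status, "ok")
  expect_lt(abs(r$or - 2.5), 0.5)

  burden3 <- integer(n); burden3[1:3] <- 1L
  r3 <- disease_burden(y, burden3)
  expect_equal(r3$status, "skipped")
})

test_that("allelic series distances and the 200 kb effector rule", {
  rare <- data.frame(gene = c("G1", "G2", "G3"), trait_id = "t",
                     chrom = 1, pos = c(1e6, 5e6, 9e6))
  leads <- data.frame(variant_id = c("l1", "l2"), trait_id = "t",
                      chrom = 1, pos = c(1.05e6, 6.2e6))
  assign <- data.frame(variant_id = "l3", gene = "G3", chrom = 1, pos = 9.15e6)
  out <- allelic_series(rare, leads, assign)
  expect_true(out$within_100kb[1])          # 50 kb away
  expect_false(out$within_100kb[2])
  expect_true(out$beyond_1mb[2])            # 1.2 Mb away
  expect_true(out$series[3])                # assignment at 150 kb names G3
  expect_false(out$series[1])
  # no common results for the trait: distances missing
  out2 <- allelic_series(rare, leads[leads$trait_id == "other", ], NULL)
  expect_true(all(is.na(out2$distance_bp)))
})
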