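test_that("coloc posterior probabilities match brute-force enumeration", {
  set.seed(51)
  for (i in 1:10) {
    m <- sample(3:10, 1)
    ids <- paste0("v", 1:m)
    s1 <- data.frame(variant_id = ids, beta = rnorm(m, 0, 0.1),
                     se = runif(m, 0.01, 0.05))
    s2 <- data.frame(variant_id = ids, beta = rnorm(m, 0, 0.1),
                     se = runif(m, 0.01, 0.05))
    r <- coloc_abf(s1, s2)
    expect_lt(max(abs(r$pp - coloc_oracle(s1, s2))), 1e-10)
    expect_equal(sum(r$pp), 1, tolerance = 1e-10)
  }
})

test_that("a 3-variant toy colocalization matches the oracle and flags low confidence", {
  s1 <- data.frame(variant_id = c("a", "b", "c"), beta = c(0.3, 0.05, 0.01),
                   se = c(0.02, 0.02, 0.02))
  s2 <- data.frame(variant_id = c("a", "b", "c"), beta = c(0.25, 0.04, 0.0),
                   se = c(0.02, 0.02, 0.02))
  r <- coloc_abf(s1, s2)
  expect_lt(max(abs(r$pp - coloc_oracle(s1, s2))), 1e-10)
  expect_true(r$low_confidence)  # < 10 shared variants
  expect_gt(r$pp["pp4"], 0.8)    # same strong variant in both
  expect_error(coloc_abf(s1, transform(s2, variant_id = c("x", "y", "z"))),
               "shared")
})

test_that("raising p12 monotonically increases PP4", {
  set.seed(52)
  ids <- paste0("v", 1:20)
  s1 <- data.frame(variant_id = ids, beta = c(0.2, rnorm(19, 0, 0.02)),
                   se = 0.02)
  s2 <- data.frame(variant_id = ids, beta = c(0.15, rnorm(19, 0, 0.02)),
                   se = 0.02)
  pp4s <- vapply(c(1e-7, 1e-6, 5e-6, 1e-5, 1e-4),
                 function(p12) coloc_abf(s1, s2, p12 = p12)$pp["pp4"],
                 numeric(1))
  expect_true(all(diff(pp4s) > 0))
})

test_that("coloc on a null outcome concentrates on H0/H1", {
  r <- sim_region(n = 10000, m = 25, beta = 0.15, seed = 53)
  set.seed(54)
  null_stats <- r$stats
  null_stats$beta <- rnorm(25, 0, null_stats$se)  # outcome with no signal
  res <- coloc_abf(r$stats, null_stats)
  expect_gt(res$pp["pp0"] + res$pp["pp1"], 0.9)
})

test_that("Wald ratio arithmetic and weak-instrument flag", {
  w <- wald_ratio(0.2, 0.01, 0.06, 0.01)
  expect_equal(w$ratio, 0.3)
  expect_equal(w$se, 0.05)
  expect_false(w$weak_instrument)
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.01)$ratio, 0)
  expect_error(wald_ratio(0, 0.01, 0.06, 0.01), "nonzero")
  expect_true(wald_ratio(0.01, 0.01, 0.06, 0.01)$weak_instrument)
})

test_that("IVW matches its closed form and defers to Wald for one instrument", {
  d <- data.frame(beta_exposure = c(0.1, 0.2, 0.15),
                  se_exposure = 0.01,
                  beta_outcome = c(0.03, 0.06, 0.045),
                  se_outcome = c(0.02, 0.03, 0.025))
  r <- ivw(d)
  expect_equal(r$beta, 0.3, tolerance = 1e-12)  # all share ratio 0.3
  w <- d$beta_exposure^2 / d$se_outcome^2
  expect_equal(r$se, 1 / sqrt(sum(w)))
  expect_equal(r$beta,
               sum(d$beta_exposure * d$beta_outcome / d$se_outcome^2) / sum(w))
  r1 <- ivw(d[1, ])
  expect_equal(r1$method, "wald_ratio")
  expect_equal(r1$beta, 0.3)
})

test_that("IVW recovers a planted causal effect with near-nominal CI coverage", {
  est <- se <- numeric(100)
  for (i in 1:100) {
    d <- sim_instruments(theta = 0.3, n_inst = 50, seed = 600 + i)
    r <- ivw(d)
    est[i] <- r$beta; se[i] <- r$se
  }
  expect_lt(abs(mean(est) - 0.3), 0.02)
  cover <- mean(abs(est - 0.3) < 1.96 * se)
  expect_gte(cover, 0.88)
  expect_lte(cover, 1.0)
})

test_that("MR-Egger fits exactly on noiseless data and respects the instrument minimum", {
  d <- data.frame(beta_exposure = c(0.05, 0.1, 0.15, 0.2),
                  se_exposure = 0.01, se_outcome = 0.02)
  d$beta_outcome <- 0.1 + 0.3 * d$beta_exposure
  e <- mr_egger(d)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$slope, 0.3, tolerance = 1e-10)
  expect_error(mr_egger(d[1:2, ]), "3 instruments")
})

test_that("Egger slope tracks the causal effect under balanced pleiotropy", {
  slopes <- vapply(1:50, function(i) {
    d <- sim_instruments(theta = 0.3, n_inst = 60, pleiotropy_sd = 0.01,
                         seed = 700 + i)
    mr_egger(d)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.3), 0.04)
})

test_that("instrument tiers are nested by stringency", {
  leads <- data.frame(variant_id = paste0("v", 1:6),
                      group_id = paste0("g", c(1, 1, 2, 3, 4, 5)))
  modes <- data.frame(group_id = paste0("g", 1:5),
                      mode = c("specific", "pathway", "proportional",
                               "nonspecific", "pathway"))
  efo <- data.frame(group_id = paste0("g", 1:5),
                    phenotypic_class = c("specific", "unspecific", "specific",
                                         "specific", "specific"))
  tiers <- instrument_tiers(leads, sentinels = c("v1", "v3"), modes, efo)
  expect_true(all(tiers$molecular_phenotypic_filtered %in%
                    tiers$molecular_filtered))
  expect_true(all(tiers$molecular_filtered %in% tiers$leads))
  # nonspecific group g4's lead is excluded from tiers 3-4
  expect_false("v5" %in% tiers$molecular_filtered)
  # pathway + EFO-unspecific g2 (lead v3): in tier 3, not tier 4
  expect_true("v3" %in% tiers$molecular_filtered)
  expect_false("v3" %in% tiers$molecular_phenotypic_filtered)
  # all-specific groups collapse tiers 2-4
  efo2 <- transform(efo, phenotypic_class = "specific")
  modes2 <- transform(modes, mode = "specific")
  t2 <- instrument_tiers(leads, "v1", modes2, efo2)
  expect_setequal(t2$leads, t2$molecular_phenotypic_filtered)
})

test_that("BH q-values follow the step-up arithmetic", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "p > 0")
})

test_that("level-locus convergence applies the filters and the LDL rule", {
  mr <- data.frame(trait_id = c("hdl", "ldl", "gly"),
                   outcome = "cad",
                   fdr_q = c(0.01, 0.2, 0.01),
                   concordant = c(TRUE, TRUE, TRUE),
                   pleiotropy_pass = c(TRUE, TRUE, TRUE))
  coloc <- data.frame(trait_id = c("hdl", "gly", "gly"),
                      outcome = "cad",
                      locus = c("L1", "L2", "L3"),
                      pp4 = c(0.95, 0.9, 0.5),
                      mode = c("pathway", "specific", "specific"))
  # HDL-like locus with no LDL association: independent
  ldl <- data.frame(locus = c("L1", "L1", "L2"),
                    variant_id = c("a", "b", "c"),
                    ldl_p = c(0.5, 0.2, 1e-30),
                    ldl_beta = c(0.01, 0.02, 0.6))
  eff <- data.frame(locus = rep(c("L1", "L2"), each = 5),
                    variant_id = letters[1:10],
                    trait_id = "x",
                    beta = c(seq(0.1, 0.5, 0.1), seq(0.1, 0.5, 0.1)))
  conv <- level_locus_convergence(mr, coloc, ldl, eff)
  expect_equal(sort(conv$locus), c("L1", "L2"))  # L3 fails PP4
  expect_true(conv$ldl_independent[conv$locus == "L1"])
  expect_false(conv$ldl_independent[conv$locus == "L2"])  # LDL-driven
  # ldl trait itself never enters: its MR failed FDR
  expect_false("ldl" %in% conv$trait_id)
  # disproportional/nonspecific loci are excluded from locus effects
  coloc2 <- transform(coloc, mode = "nonspecific")
  expect_equal(nrow(level_locus_convergence(mr, coloc2, ldl, eff)), 0)
  # no coloc passes: empty table
  expect_equal(nrow(level_locus_convergence(mr, coloc[coloc$pp4 < 0.6, ],
                                            ldl, eff)), 0)
})

test_that("the 80th-percentile clause distinguishes the two LDL-rule readings", {
  mr <- data.frame(trait_id = "hdl", outcome = "cad", fdr_q = 0.01,
                   concordant = TRUE, pleiotropy_pass = TRUE)
  coloc <- data.frame(trait_id = "hdl", outcome = "cad", locus = "L1",
                      pp4 = 0.9, mode = "specific")
  # LDL p above threshold everywhere, but its effect tops the locus
  ldl <- data.frame(locus = "L1", variant_id = "a", ldl_p = 1e-6,
                    ldl_beta = 0.9)
  eff <- data.frame(locus = "L1", variant_id = letters[1:5], trait_id = "x",
                    beta = seq(0.1, 0.5, 0.1))
  strict <- level_locus_convergence(mr, coloc, ldl, eff,
                                    rank_rule = "exclude_top")
  lenient <- level_locus_convergence(mr, coloc, ldl, eff,
                                     rank_rule = "p_only")
  expect_false(strict$ldl_independent)
  expect_true(lenient$ldl_independent)
})

test_that("the MR screen wrapper reports concordance and the coloc pair cap holds", {
  d <- sim_instruments(theta = 0.3, n_inst = 30, seed = 900)
  scr <- mr_screen(d, tier = "leads")
  expect_equal(scr$n_instruments, 30)
  expect_true(scr$concordant)
  expect_lt(abs(scr$beta_ivw - 0.3), 0.05)
  expect_true(scr$pleiotropy_pass)

  ids <- paste0("v", 1:15)
  mk <- function(seed) {
    set.seed(seed)
    data.frame(variant_id = ids, beta = c(0.2, rnorm(14, 0, 0.02)), se = 0.02)
  }
  pairs <- coloc_all_pairs(list(mk(1)), list(mk(2), mk(3), mk(4), mk(5),
                                             mk(6), mk(7), mk(8)))
  expect_equal(nrow(pairs), 5)  # outcome decomposition capped at 5 signals
  expect_true(all(abs(rowSums(pairs[, paste0("pp", 0:4)]) - 1) < 1e-10))
})
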