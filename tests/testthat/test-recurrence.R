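test_that("VAF filtering is strict and tallies missing values", {
  df <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:4,
                   ref = "C", alt = "A", vaf = c(0.19, 0.20, 0.21, NA),
                   gene = NA, context = "ACA", variant_class = "SNV")
  out <- filterVariants(MutationTable(df))
  expect_equal(mutationRecords(out)$vaf, 0.21)
  expect_equal(out@report$n_dropped_missing_vaf, 1L)
  expect_equal(out@report$n_dropped_low_vaf, 2L)
  empty <- filterVariants(MutationTable(df[0, ]))
  expect_equal(nrow(mutationRecords(empty)), 0L)
})

test_that("background rates are per-base mutation rates", {
  df <- data.frame(sample_id = rep("S1", 300), chrom = "chr1",
                   pos = 1:300, ref = "C", alt = "A", vaf = 0.5,
                   gene = NA, context = "ACA", variant_class = "SNV")
  tab <- MutationTable(df, groups = c(S1 = "a", S2 = "a"))
  r <- backgroundRates(tab)
  expect_equal(unname(r["S1"]), 1e-5)
  expect_equal(unname(r["S2"]), 0)
  expect_equal(r, mutationRate(tab)$rates / 1e6)
})

test_that("convolution test matches brute-force enumeration and Monte Carlo", {
  expect_equal(convolutionTest(0, 10, c(0.1, 0.2)), 1)
  expect_error(convolutionTest(2, 10, c(0.5, 1.2)), "rates")

  # two-sample oracle: direct product of binomial pmfs
  b1 <- dbinom(0:10, 10, 0.1); b2 <- dbinom(0:10, 10, 0.2)
  tot <- outer(0:10, 0:10, "+")
  pr <- outer(b1, b2)
  for (obs in c(1, 2, 4, 7))
    expect_equal(convolutionTest(obs, 10, c(0.1, 0.2)),
                 sum(pr[tot >= obs]), tolerance = 1e-12)

  # three-sample oracle
  b3 <- dbinom(0:6, 6, 0.3)
  pr3 <- outer(outer(dbinom(0:6, 6, 0.05), dbinom(0:6, 6, 0.15)), b3)
  tot3 <- outer(outer(0:6, 0:6, "+"), 0:6, "+")
  for (obs in c(2, 5))
    expect_equal(convolutionTest(obs, 6, c(0.05, 0.15, 0.3)),
                 sum(pr3[tot3 >= obs]), tolerance = 1e-12)

  # Monte-Carlo agreement on a random 5-sample instance
  set.seed(31)
  rates <- runif(5, 0.001, 0.02)
  len <- 200L
  draws <- colSums(matrix(rbinom(5 * 1e5, len, rates), nrow = 5))
  obs <- 10L
  p_mc <- mean(draws >= obs)
  p <- convolutionTest(obs, len, rates)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(p - p_mc), 3 * se)

  # Poisson limit for small per-gene expectations
  rates2 <- rep(1e-6, 18); len2 <- 1000L
  lambda <- sum(len2 * rates2)
  for (obs in 1:3)
    expect_equal(convolutionTest(obs, len2, rates2),
                 ppois(obs - 1, lambda, lower.tail = FALSE),
                 tolerance = 0.01)
})

test_that("Fisher two-sided p equals the point-probability enumeration", {
  expect_equal(fisherTwoSided(matrix(c(3, 0, 4, 11), 2)), 35 / 816,
               tolerance = 1e-12)
  expect_equal(fisherTwoSided(matrix(c(3, 8, 15, 271), 2)),
               fisher.test(matrix(c(3, 8, 15, 271), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(fisherTwoSided(matrix(c(0, 0, 7, 11), 2)), 1)
  expect_equal(fisherTwoSided(matrix(c(3, 3, 15, 15), 2)), 1)
  # swapping rows or columns leaves p unchanged
  tab <- matrix(c(5, 2, 1, 9), 2)
  expect_equal(fisherTwoSided(tab), fisherTwoSided(tab[2:1, ]))
  expect_equal(fisherTwoSided(tab), fisherTwoSided(tab[, 2:1]))
  expect_error(fisherTwoSided(matrix(c(-1, 0, 1, 2), 2)), "non-negative")
  # spot check against the reference implementation on random tables
  set.seed(17)
  for (i in 1:50) {
    t2 <- matrix(rpois(4, 6), 2)
    expect_equal(fisherTwoSided(t2), fisher.test(t2)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("smg scan gates on recurrence and adjusts within the tested set", {
  gm <- data.frame(gene = c("GA", "GB", "GC"),
                   coding_length = c(1000L, 1000L, 500L))
  mk <- function(sample, gene, n) data.frame(
    sample_id = rep(sample, n), chrom = "chr1", pos = seq_len(n),
    ref = "C", alt = "A", vaf = 0.5, gene = gene, context = "ACA",
    variant_class = "SNV", stringsAsFactors = FALSE)
  # every gene in exactly one patient -> nothing tested
  tab1 <- MutationTable(rbind(mk("S1", "GA", 2), mk("S2", "GB", 1)))
  expect_equal(nrow(smgScan(tab1, gm)), 0L)

  # two genes with identical counts and lengths share p, so BH gives q = p
  tab2 <- MutationTable(rbind(mk("S1", "GA", 1), mk("S2", "GA", 1),
                              mk("S1", "GB", 1), mk("S2", "GB", 1)))
  res <- smgScan(tab2, gm, all = TRUE, fdrMax = 1)
  expect_equal(nrow(res), 2L)
  expect_equal(res$p_value[1], res$p_value[2])
  expect_equal(res$q_value, res$p_value)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # p agrees with a direct convolution call
  rates <- backgroundRates(tab2)
  expect_equal(res$p_value[res$gene == "GA"],
               convolutionTest(2, 1000L, rates))

  # genes absent from the model are excluded with a warning
  tab3 <- MutationTable(rbind(mk("S1", "GX", 1), mk("S2", "GX", 1)))
  expect_warning(out <- smgScan(tab3, gm), "absent")
  expect_equal(attr(out, "n_unknown_genes"), 1L)
})

test_that("planted drivers are detected and subgroup discovery separates scopes", {
  # REV3L is large (9.3 kb coding), so its background expectation is a
  # few mutations cohort-wide: a signal of this size clears the FDR bar
  # within the 7-sample sensitive scope but not over the full cohort
  cfg <- simulationConfig(
    seed = 21, geneModel = smallGeneModel(),
    drivers = list(
      list(gene = "REV3L", group = "sensitive", nPatients = 3L,
           mutationsPerPatient = 4L)))
  sim <- simulateCohort(cfg)
  filt <- filterVariants(sim$table)
  disc <- subgroupDiscovery(filt, smallGeneModel())
  expect_true("REV3L" %in% disc$sensitive$gene)
  expect_false("REV3L" %in% disc$overall$gene)
  expect_true("REV3L" %in% disc$subgroup_only$sensitive)

  nogroups <- MutationTable(mutationRecords(filt))
  expect_error(subgroupDiscovery(nogroups, smallGeneModel()), "groups")
})

test_that("group enrichment counts patients once and is label-symmetric", {
  sim <- rev3lCohort()
  e <- groupEnrichment(sim$table, "REV3L")
  expect_equal(unname(e$table["mutated", c("sensitive", "resistant")]),
               c(3, 0))
  expect_equal(e$p, 35 / 816, tolerance = 1e-12)
  expect_equal(e$odds_direction, "sensitive")

  # duplicating records never changes the patient-level table
  df <- mutationRecords(sim$table)
  dup <- MutationTable(rbind(df, df), groups = sampleGroups(sim$table))
  e2 <- groupEnrichment(dup, "REV3L")
  expect_identical(e2$table, e$table)

  # swapping group labels leaves p unchanged
  g <- sampleGroups(sim$table)
  g2 <- setNames(ifelse(g == "sensitive", "resistant", "sensitive"),
                 names(g))
  e3 <- groupEnrichment(MutationTable(df, groups = g2), "REV3L")
  expect_equal(e3$p, e$p)

  # absent gene: zero mutated row, p = 1
  e4 <- groupEnrichment(sim$table, "NOSUCHGENE")
  expect_equal(sum(e4$table["mutated", ]), 0)
  expect_equal(e4$p, 1)

  # gene mutated in everyone
  allmut <- do.call(rbind, lapply(sampleIds(sim$table), function(s)
    data.frame(sample_id = s, chrom = "chr1", pos = 1L, ref = "C",
               alt = "A", vaf = 0.5, gene = "EVERY", context = "ACA",
               variant_class = "SNV")))
  e5 <- groupEnrichment(MutationTable(allmut,
                                      groups = sampleGroups(sim$table)),
                        "EVERY")
  expect_equal(e5$p, 1)
})

test_that("cohort comparison reproduces per-gene Fisher tests", {
  a <- data.frame(gene = c("REV3L", "TP53", "ONLYA"),
                  mutated = c(3, 9, 1), n = 18)
  b <- data.frame(gene = c("REV3L", "TP53"),
                  mutated = c(8, 180), n = 279)
  expect_warning(res <- cohortComparison(a, b), "ONLYA")
  expect_equal(res$p[res$gene == "REV3L"],
               fisher.test(matrix(c(3, 8, 15, 271), 2))$p.value,
               tolerance = 1e-9)
  same <- data.frame(gene = "G", mutated = 4, n = 20)
  expect_equal(cohortComparison(same, same)$p, 1)
  zero <- data.frame(gene = "G", mutated = 0, n = 18)
  zero2 <- data.frame(gene = "G", mutated = 0, n = 279)
  expect_equal(cohortComparison(zero, zero2)$p, 1)
})
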