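test_that("readMaf parses records, infers variant classes and preserves extras", {
  maf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Sample\tChrom\tPos\tRef\tAlt\tVAF\tGene\tContext\tNote",
    "S1\tchr1\t100\tC\tA\t0.15\tTP53\tACA\tx",
    "S1\tchr1\t200\tC\tCT\t0.4\tKRAS\t\ty",
    "S2\tchr2\t300\tGA\tG\t0.3\tREV3L\t\tz"), maf)
  tab <- readMaf(maf)
  df <- mutationRecords(tab)
  expect_equal(nrow(df), 3L)
  expect_equal(df$variant_class, c("SNV", "insertion", "deletion"))
  expect_equal(df$context[1], "ACA")
  expect_equal(df$vaf, c(0.15, 0.4, 0.3))
  expect_equal(df$Note, c("x", "y", "z"))         # extra column kept
  expect_equal(sampleIds(tab), c("S1", "S2"))
  expect_equal(tab@report$n_snv, 1L)
  expect_equal(tab@report$n_indel, 2L)
})

test_that("readMaf errors name the missing column and the offending rows", {
  maf <- tempfile(fileext = ".tsv")
  writeLines(c("Sample\tChrom\tPos\tRef", "S1\tchr1\t1\tC"), maf)
  expect_error(readMaf(maf), "missing required column: alt")

  maf2 <- tempfile(fileext = ".tsv")
  writeTinyMaf(maf2, c("S1\tchr1\t100\tC\tA\t0.1\tTP53\tACA",
                       "S1\tchr1\t101\tC\tA\t0.1\tTP53\tAGA"))
  expect_error(readMaf(maf2), "context middle base.*2")
})

test_that("readMaf resolves SNV contexts from a reference FASTA", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 synthetic", "AACGTACGTT"), fa)
  maf <- tempfile(fileext = ".tsv")
  writeLines(c("Sample\tChrom\tPos\tRef\tAlt\tVAF\tGene",
               "S1\tchr1\t3\tC\tA\t0.2\tG1",
               "S1\tchr1\t7\tC\tT\t0.5\tG2"), maf)
  tab <- readMaf(maf, fasta = fa)
  expect_equal(mutationRecords(tab)$context, c("ACG", "ACG"))
})

test_that("channel mapping is pyrimidine-referenced and total over 192 stranded cases", {
  expect_equal(channelOf("C", "A", "CCA"), "C[C>A]A")
  expect_equal(channelOf("G", "T", "TGG"), "C[C>A]A")  # reverse complement
  expect_equal(channelOf("C", "T", "ACG"), "A[C>T]G")
  expect_true(is.na(channelOf("C", "A", "NCA")))
  expect_error(channelOf("C", "C", "ACA"), "differ")

  bases <- c("A", "C", "G", "T")
  cases <- expand.grid(ref = bases, alt = bases, five = bases,
                       three = bases, stringsAsFactors = FALSE)
  cases <- cases[cases$ref != cases$alt, ]
  expect_equal(nrow(cases), 192L)
  ctx <- paste0(cases$five, cases$ref, cases$three)
  fwd <- channelOf(cases$ref, cases$alt, ctx)
  rev <- channelOf(chartr("ACGT", "TGCA", cases$ref),
                   chartr("ACGT", "TGCA", cases$alt),
                   reverseComplement(ctx))
  expect_false(anyNA(fwd))
  expect_identical(fwd, rev)
  # the mapping covers all 96 channels and each exactly twice
  expect_equal(sort(unique(fwd)), sort(channelLabels()))
  expect_true(all(table(fwd) == 2L))
})

test_that("buildCatalog counts channels, excludes indels and conserves totals", {
  df <- data.frame(sample_id = c("S1", "S1"), chrom = "chr1",
                   pos = c(10L, 20L), ref = c("C", "C"),
                   alt = c("A", "CT"), vaf = 0.3, gene = NA,
                   context = c("CCA", NA),
                   variant_class = c("SNV", "insertion"))
  catal <- buildCatalog(MutationTable(df))
  m <- counts(catal)
  expect_equal(sum(m), 1)
  expect_equal(m["C[C>A]A", "S1"], 1)

  sim <- simulateCohort(smallConfig(seed = 7, load = 500))
  catal <- buildCatalog(sim$table)
  expect_true(all(colSums(counts(catal)) == 500))

  # strand symmetry: reverse-complementing every record leaves the catalog
  df2 <- mutationRecords(sim$table)
  df2$context <- reverseComplement(df2$context)
  df2$ref <- chartr("ACGT", "TGCA", df2$ref)
  df2$alt <- chartr("ACGT", "TGCA", df2$alt)
  catal2 <- buildCatalog(MutationTable(df2, groups = sampleGroups(sim$table)))
  expect_identical(counts(catal2), counts(catal))
})

test_that("Ti/Tv ratios agree between record-level and catalog-level computation", {
  df <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:3,
                   ref = c("C", "T", "C"), alt = c("T", "C", "A"),
                   vaf = NA, gene = NA, context = c("ACA", "ATA", "ACA"),
                   variant_class = "SNV")
  expect_equal(as.numeric(titvRatio(MutationTable(df))), 2)

  df2 <- df[3, , drop = FALSE]
  df2 <- rbind(df2, within(df2, alt <- "G"))
  expect_equal(as.numeric(titvRatio(MutationTable(df2))), 0)

  df3 <- df[1:2, ]
  r3 <- titvRatio(MutationTable(df3))
  expect_true(is.infinite(r3))
  expect_true(attr(r3, "infinite"))

  sim <- simulateCohort(smallConfig(seed = 11, load = 400))
  tt <- titvRatio(sim$table, perSample = TRUE)
  m <- counts(buildCatalog(sim$table))
  ti_channels <- grepl("C>T|T>C", rownames(m))
  cat_ratio <- colSums(m[ti_channels, ]) / colSums(m[!ti_channels, ])
  expect_equal(tt$per_sample$ratio,
               unname(cat_ratio[tt$per_sample$sample_id]))
  expect_equal(tt$median, median(cat_ratio))
})

test_that("mutation rate is linear in counts and inverse in exome size", {
  df <- data.frame(sample_id = rep("S1", 411), chrom = "chr1",
                   pos = seq_len(411), ref = "C", alt = "A", vaf = NA,
                   gene = NA, context = "ACA", variant_class = "SNV")
  tab <- MutationTable(df)
  expect_equal(unname(mutationRate(tab)$rates), 411 / 30)
  expect_equal(unname(mutationRate(tab)$rates["S1"]), 13.7)
  expect_equal(unname(mutationRate(tab, exomeMb = 60)$rates), 411 / 60)
  tab2 <- MutationTable(rbind(df, df))
  expect_equal(unname(mutationRate(tab2)$rates), 2 * 411 / 30)
  # a grouped sample with zero records appears with rate 0
  tab3 <- MutationTable(df, groups = c(S1 = "sensitive", S2 = "resistant"))
  expect_equal(unname(mutationRate(tab3)$rates["S2"]), 0)
})

test_that("VAF spectrum reports overall and per-class sub-threshold fractions", {
  df <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:3,
                   ref = "C", alt = "A", vaf = c(0.1, 0.1, 0.5),
                   gene = NA, context = "ACA", variant_class = "SNV")
  vs <- vafSpectrum(MutationTable(df))
  expect_equal(vs$overall, 2 / 3)
  expect_equal(unname(vs$by_class["C>A"]), 2 / 3)
  expect_true(is.nan(vs$by_class[["C>T"]]))

  df$vaf <- 0.5
  expect_equal(vafSpectrum(MutationTable(df))$overall, 0)
  expect_error(vafSpectrum(MutationTable(df), threshold = 1.5), "threshold")

  # generator self-consistency: recovered sub-threshold fraction matches
  # the expectation implied by the origin mix and the configured betas
  cfg <- simulationConfig(seed = 5, geneModel = smallGeneModel())
  sim <- simulateCohort(cfg)
  vs <- vafSpectrum(sim$table)
  plat_share <- mean(sim$truth$origins == "platinum")
  expected <- plat_share * pbeta(0.2, 1.2, 13) +
    (1 - plat_share) * pbeta(0.2, 6, 4)
  expect_lt(abs(vs$overall - expected), 0.03)
})
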