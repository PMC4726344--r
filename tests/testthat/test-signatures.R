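test_that("bootstrap preserves per-sample totals and handles degenerate rows", {
  m <- matrix(0, 96, 3, dimnames = list(channelLabels(),
                                        c("A", "B", "Z")))
  m[, 1] <- rpois(96, 4)
  m[5, 2] <- 5                         # all mass on one channel
  catal <- MutationCatalog(m)
  expect_warning(bs <- bootstrapCatalog(catal, seed = 2), "zero mutations")
  expect_equal(colSums(counts(bs)), colSums(m))
  expect_equal(counts(bs)[, "B"], m[, "B"])   # degenerate multinomial
  expect_equal(counts(bs)[, "Z"], m[, "Z"])   # zero row unchanged

  # sample-keyed seeding: permuting columns permutes the resample
  m2 <- m[, c("B", "Z", "A")]
  bs2 <- suppressWarnings(bootstrapCatalog(MutationCatalog(m2), seed = 2))
  expect_identical(counts(bs2), counts(bs)[, c("B", "Z", "A")])
})

test_that("bootstrap counts follow multinomial moments", {
  m <- matrix(100, 96, 1, dimnames = list(channelLabels(), "S"))
  catal <- MutationCatalog(m)                # uniform row, n = 9600
  sigma <- sqrt(9600 * (1 / 96) * (95 / 96))
  draws <- vapply(1:200, function(s)
    counts(bootstrapCatalog(catal, seed = s))[, 1], numeric(96))
  expect_true(all(abs(draws - 100) <= 5 * sigma))
  expect_lt(abs(mean(draws) - 100), 0.5)
})

test_that("cosine similarity has its closed-form values and rejects zero vectors", {
  x <- runif(96)
  expect_equal(cosineSimilarity(x, 3 * x), 1)
  expect_equal(cosineSimilarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosineSimilarity(rep(1, 96), c(1, rep(0, 95))), 1 / sqrt(96))
  expect_error(cosineSimilarity(rep(0, 96), x), "zero vector")
})

test_that("extraction is deterministic and permutation-equivariant", {
  sim <- simulateCohort(smallConfig(seed = 2, load = 300))
  catal <- buildCatalog(sim$table)
  e1 <- extractSignatures(catal, 2, nBootstrap = 8, seed = 5)
  e2 <- extractSignatures(catal, 2, nBootstrap = 8, seed = 5)
  expect_identical(signatureProfiles(e1), signatureProfiles(e2))
  expect_identical(signatureExposures(e1), signatureExposures(e2))

  perm <- c(5:18, 1:4)
  catal_p <- MutationCatalog(counts(catal)[, perm])
  e3 <- extractSignatures(catal_p, 2, nBootstrap = 8, seed = 5)
  expect_equal(signatureProfiles(e3), signatureProfiles(e1),
               tolerance = 1e-6)
  expect_equal(signatureExposures(e3),
               signatureExposures(e1)[perm, ], tolerance = 1e-6)
})

test_that("planted profiles are recovered and nesting lowers reconstruction error", {
  sim <- simulateCohort(smallConfig(seed = 4, nSig = 3, load = 600))
  catal <- buildCatalog(sim$table)
  refs <- referenceSignatures()[, 1:3]
  e3 <- extractSignatures(catal, 3, nBootstrap = 25, seed = 1)
  expect_true(all(recoveryCosines(signatureProfiles(e3), refs) >= 0.95))
  e1 <- extractSignatures(catal, 1, nBootstrap = 25, seed = 1)
  expect_gt(e1@reconstructionError, e3@reconstructionError)
  expect_equal(stability(e1), 1)     # one cluster is trivially stable
  # exposures track the planted mixture weights
  expo <- signatureExposures(e3)
  expo <- sweep(expo, 1, rowSums(expo), "/")
  ann <- annotateSignatures(e3, refs)
  truth <- sim$truth$exposures
  for (i in seq_len(nrow(ann))) {
    if (ann$label[i] == "novel") next
    expect_gt(cor(expo[, ann$signature[i]], truth[, ann$label[i]]), 0.9)
  }
})

test_that("rank-1 data select k = 1 and the curve covers the range", {
  profile <- referenceSignatures()[, "apobec"]
  set.seed(9)
  m <- vapply(1:12, function(i) as.numeric(rmultinom(1, 400, profile)),
              numeric(96))
  dimnames(m) <- list(channelLabels(), paste0("S", 1:12))
  sel <- selectK(MutationCatalog(m), kRange = 1:3, nBootstrap = 10,
                 seed = 2)
  expect_equal(sel$k, 1)
  expect_equal(nrow(sel$curve), 3L)
  expect_error(selectK(MutationCatalog(m), kRange = 1:13), "kRange")
})

test_that("annotation labels matches and flags novel profiles", {
  refs <- referenceSignatures()
  w <- cbind(refs[, "apobec"], rep(0, 96))
  w[96, 2] <- 1                       # profile orthogonal to every reference
  w <- sweep(w, 2, colSums(w), "/")
  colnames(w) <- c("S1", "S2"); rownames(w) <- channelLabels()
  ex <- new("SignatureExtraction", k = 2L, profiles = w,
            exposures = matrix(1, 2, 2), stability = 0.9,
            perSignatureStability = c(0.9, 0.9),
            reconstructionError = 1, nBootstrap = 2L, seed = 1L)
  ann <- annotateSignatures(ex, refs)
  expect_equal(ann$label, c("apobec", "novel"))
  expect_gt(ann$cosine[1], 0.999)
})

test_that("platinum score isolates the CpCpA/CpCpG C>A channels", {
  expect_equal(platinumScore(rep(1 / 96, 96)), 2 / 96)
  p <- rep(0, 96)
  p[match("C[C>A]A", channelLabels())] <- 1
  expect_equal(platinumScore(p), 1)
  expect_gt(platinumScore(referenceSignatures()[, "platinum"]), 0.5)
})
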