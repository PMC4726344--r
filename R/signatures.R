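## De novo signature extraction with bootstrap stability: resample each
## sample's catalog multinomially, factorize every replicate, pool the
## replicate profiles, cluster them into k consensus signatures under
## cosine distance, and report the mean silhouette width as the
## stability of the rank-k solution.

.MOD31 <- 2147483587  # prime below 2^31, keeps derived seeds in int range

.hashString <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 131 + c) %% .MOD31
  h
}

## Per-sample bootstrap seed keyed by sample id (not column position) so
## resampling is invariant under column permutation.
.sampleSeed <- function(seed, id) {
  as.integer((.hashString(id) + as.double(seed) * 48271) %% .MOD31)
}

.bootSeed <- function(seed, b) {
  as.integer((as.double(seed) * 69621 + as.double(b) * 16807) %% .MOD31)
}

#' Multinomial bootstrap of a mutation catalog
#'
#' Redraws each sample's 96-channel count vector from a multinomial with
#' the sample's original total and its normalized channel frequencies, so
#' per-sample totals are preserved exactly. Resampling is keyed by sample
#' id, making the bootstrap invariant under sample reordering. All-zero
#' samples are returned unchanged with a warning.
#'
#' @param catalog a [`MutationCatalog-class`].
#' @param seed integer seed.
#' @return A resampled [`MutationCatalog-class`] with identical column
#'   sums.
#' @export
bootstrapCatalog <- function(catalog, seed = 1L) {
  m <- counts(catalog)
  out <- m
  tot <- colSums(m)
  if (any(tot == 0))
    warning("sample(s) with zero mutations returned unchanged: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
  for (j in which(tot > 0)) {
    set.seed(.sampleSeed(seed, colnames(m)[j]))
    out[, j] <- rmultinom(1, tot[j], m[, j] / tot[j])
  }
  MutationCatalog(out)
}

#' Cosine similarity of two non-negative profiles
#'
#' @param a,b non-negative, non-zero numeric vectors of equal length.
#' @return Cosine similarity in \[0, 1\]; 1 iff proportional.
#' @examples
#' cosineSimilarity(rep(1, 96), c(1, rep(0, 95)))  # 1/sqrt(96)
#' @export
cosineSimilarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

## Columns L2-normalized (for cosine geometry).
.l2norm <- function(m) sweep(m, 2, pmax(sqrt(colSums(m^2)), 1e-300), "/")

## Iterative centroid reassignment of pooled profiles (96 x B*k, stored
## replicate-major) into k clusters under cosine distance, with a
## matching constraint: each bootstrap replicate contributes
## its k profiles one-to-one to the k clusters (greedy best-pair
## matching per replicate). An extraction rank above the true signature
## number then contaminates clusters with the replicate-varying surplus
## profile instead of letting it regroup, which is what makes the
## silhouette drop past the true rank. Returns NULL if a cluster empties
## (impossible under matching unless B = 0; kept for safety).
.clusterProfiles <- function(pool, k, init, maxIter = 200L) {
  m <- ncol(pool)
  B <- m %/% k
  pn <- .l2norm(pool)
  cn <- .l2norm(init)
  cl <- rep(0L, m)
  for (i in seq_len(maxIter)) {
    new_cl <- integer(m)
    for (b in seq_len(B)) {
      idx <- (b - 1L) * k + seq_len(k)
      sim <- crossprod(cn, pn[, idx, drop = FALSE])  # clusters x profiles
      for (step in seq_len(k)) {
        best <- which(sim == max(sim), arr.ind = TRUE)[1, ]
        new_cl[idx[best[2]]] <- best[1]
        sim[best[1], ] <- -Inf
        sim[, best[2]] <- -Inf
      }
    }
    if (length(unique(new_cl)) < k) return(NULL)
    if (identical(new_cl, cl)) break
    cl <- new_cl
    cent <- vapply(seq_len(k), function(g)
      rowMeans(pool[, cl == g, drop = FALSE]), numeric(nrow(pool)))
    cn <- .l2norm(cent)
  }
  cent <- vapply(seq_len(k), function(g)
    rowMeans(pool[, cl == g, drop = FALSE]), numeric(nrow(pool)))
  list(assignment = cl,
       centroids = sweep(cent, 2, colSums(cent), "/"))
}

## Mean silhouette width under cosine distance; k = 1 is defined as 1
## (one cluster is trivially reproducible).
.silhouette <- function(pool, cl, k) {
  if (k == 1L) return(list(mean = 1, per_cluster = 1))
  pn <- .l2norm(pool)
  d <- 1 - crossprod(pn)                 # m x m cosine distances
  m <- ncol(pool)
  s <- numeric(m)
  for (i in seq_len(m)) {
    own <- which(cl == cl[i])
    a <- if (length(own) > 1L) mean(d[i, setdiff(own, i)]) else NA
    b <- min(vapply(setdiff(seq_len(k), cl[i]), function(g)
      mean(d[i, cl == g]), numeric(1)))
    s[i] <- if (is.na(a)) 0 else if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(mean = mean(s),
       per_cluster = vapply(seq_len(k), function(g)
         mean(s[cl == g]), numeric(1)))
}

#' Extract de novo signatures at a fixed signature number
#'
#' Runs [nmfKL()] on `nBootstrap` multinomial bootstrap replicates of the
#' catalog, pools the `nBootstrap * k` replicate profiles, partitions
#' them into `k` clusters by iterative centroid reassignment under cosine
#' distance (initialized from one factorization of the unresampled
#' catalog), and reports the normalized cluster centroids as consensus
#' profiles with the mean silhouette width as stability. Exposures are
#' refit to the original catalog by a non-negative KL fit with the
#' consensus profiles held fixed. Deterministic given `seed`.
#'
#' Signatures are ordered by decreasing total refit exposure and named
#' `S1..Sk`. If a cluster empties, the partition is restarted with a
#' jittered initialization up to 5 times; if it still empties, the run is
#' flagged degenerate and the empty clusters contribute stability -1.
#'
#' @param catalog a [`MutationCatalog-class`].
#' @param k number of signatures (1..10 in routine use).
#' @param nBootstrap number of bootstrap replicates (>= 2, default 100).
#' @param seed master seed; per-replicate seeds are derived from it by
#'   replicate index.
#' @param maxIter,tol stopping rule passed to [nmfKL()].
#' @return A [`SignatureExtraction-class`].
#' @export
extractSignatures <- function(catalog, k, nBootstrap = 100L, seed = 1L,
                              maxIter = 10000L, tol = 1e-9) {
  stopifnot(k >= 1L, nBootstrap >= 2L)
  v <- counts(catalog)
  # reference factorization for the cluster initialization: best of a few
  # restarts by objective, to avoid seeding the consensus from a poor
  # local minimum
  ref_fits <- lapply(0:2, function(r)
    nmfKL(v, k, seed = .bootSeed(seed, -(r + 1L)), maxIter = maxIter,
          tol = tol))
  ref <- ref_fits[[which.min(vapply(ref_fits, function(f)
    f$objective[length(f$objective)], numeric(1)))]]
  pool <- matrix(0, 96L, nBootstrap * k)
  for (b in seq_len(nBootstrap)) {
    bs <- .bootSeed(seed, b)
    cb <- bootstrapCatalog(catalog, seed = bs)
    fit <- nmfKL(counts(cb), k, seed = bs, maxIter = maxIter, tol = tol)
    pool[, (b - 1L) * k + seq_len(k)] <- fit$w
  }
  part <- .clusterProfiles(pool, k, ref$w)
  tries <- 0L
  degenerate <- FALSE
  while (is.null(part) && tries < 5L) {
    tries <- tries + 1L
    set.seed(.bootSeed(seed, nBootstrap + tries))
    jitter <- matrix(runif(96L * k, 0.5, 1.5), 96L, k)
    part <- .clusterProfiles(pool, k, ref$w * jitter)
  }
  if (is.null(part)) {
    # keep the reference solution, report worst-case stability
    degenerate <- TRUE
    part <- list(assignment = rep(1L, ncol(pool)), centroids = ref$w)
    sil <- list(mean = -1, per_cluster = rep(-1, k))
  } else {
    sil <- .silhouette(pool, part$assignment, k)
  }
  w <- part$centroids
  refit <- .fitExposures(v, w, maxIter = maxIter, tol = tol)
  expo <- t(refit$h)                      # samples x k
  ord <- order(colSums(expo), decreasing = TRUE)
  w <- w[, ord, drop = FALSE]
  expo <- expo[, ord, drop = FALSE]
  per_sig <- sil$per_cluster[ord]
  colnames(w) <- colnames(expo) <- paste0("S", seq_len(k))
  rownames(w) <- channelLabels()
  names(per_sig) <- colnames(w)
  new("SignatureExtraction",
      k = as.integer(k), profiles = w, exposures = expo,
      stability = sil$mean, perSignatureStability = per_sig,
      reconstructionError = refit$error,
      nBootstrap = as.integer(nBootstrap), seed = as.integer(seed),
      degenerate = degenerate)
}

#' Select the number of signatures by bootstrap stability
#'
#' Runs [extractSignatures()] for each candidate signature number and
#' selects the largest k whose stability (mean silhouette width of the
#' pooled bootstrap profiles) reaches `stabilityMin`. If no k reaches the
#' threshold, the k with maximal stability is returned and flagged.
#'
#' @param catalog a [`MutationCatalog-class`].
#' @param kRange candidate signature numbers (default `1:10`).
#' @param stabilityMin stability threshold (default 0.8).
#' @param nBootstrap,seed,maxIter,tol passed to [extractSignatures()].
#' @return List with `k` (selected), `flagged` (`TRUE` when no k met the
#'   threshold), `curve` (data.frame: k, stability,
#'   reconstruction_error), and `extractions` (one
#'   [`SignatureExtraction-class`] per candidate, named by k).
#' @export
selectK <- function(catalog, kRange = 1:10, stabilityMin = 0.8,
                    nBootstrap = 100L, seed = 1L,
                    maxIter = 10000L, tol = 1e-9) {
  nmax <- min(dim(counts(catalog)))
  if (any(kRange < 1L) || any(kRange > nmax))
    stop("kRange must lie within 1..min(samples, 96)", call. = FALSE)
  ex <- lapply(kRange, function(k)
    extractSignatures(catalog, k, nBootstrap = nBootstrap, seed = seed,
                      maxIter = maxIter, tol = tol))
  names(ex) <- as.character(kRange)
  curve <- data.frame(
    k = kRange,
    stability = vapply(ex, stability, numeric(1)),
    reconstruction_error = vapply(ex, function(e)
      e@reconstructionError, numeric(1)),
    row.names = NULL)
  ok <- curve$stability >= stabilityMin
  if (any(ok)) {
    k_sel <- max(curve$k[ok]); flagged <- FALSE
  } else {
    k_sel <- curve$k[which.max(curve$stability)]; flagged <- TRUE
  }
  list(k = k_sel, flagged = flagged, curve = curve, extractions = ex)
}

#' Bundled synthetic reference signature profiles
#'
#' Loads the packaged reference set: five synthetic 96-channel profiles
#' (platinum, APOBEC-like, aging, UV-like, smoking-like) constructed to
#' mimic the channel concentrations of the corresponding mutational
#' processes. These are synthetic stand-ins with the qualitative channel
#' structure of the community reference signatures, not copies of any
#' published catalog; they are suitable for annotation tests and
#' simulation, and any user table in the same TSV layout (first column
#' `channel`, one column per named signature) can be supplied instead.
#'
#' @param path optional path to an alternative reference TSV.
#' @return Matrix 96 x signatures, columns normalized to sum 1.
#' @export
referenceSignatures <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_signatures_synthetic.tsv",
                        package = "platisig", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stopifnot(identical(rownames(m), channelLabels()))
  sweep(m, 2, colSums(m), "/")
}

#' Annotate extracted signatures against a reference set
#'
#' Labels each extracted profile with the best-matching reference
#' signature by cosine similarity, or `"novel"` when no reference reaches
#' `minCos`. Ties break to the first reference in column order.
#'
#' @param extraction a [`SignatureExtraction-class`].
#' @param refs reference matrix as returned by [referenceSignatures()].
#' @param minCos minimum cosine similarity for a match (default 0.8).
#' @return data.frame with `signature`, `label`, `best_match`, `cosine`.
#' @export
annotateSignatures <- function(extraction, refs, minCos = 0.8) {
  stopifnot(ncol(refs) >= 1L)
  w <- signatureProfiles(extraction)
  out <- lapply(seq_len(ncol(w)), function(j) {
    cos <- vapply(seq_len(ncol(refs)), function(r)
      cosineSimilarity(w[, j], refs[, r]), numeric(1))
    best <- which.max(cos)
    data.frame(signature = colnames(w)[j],
               label = if (cos[best] >= minCos) colnames(refs)[best]
                       else "novel",
               best_match = colnames(refs)[best],
               cosine = cos[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Platinum signature score of a profile
#'
#' The platinum (cisplatin-associated) signature concentrates C>A
#' transversions at CpCpA and CpCpG trinucleotides — the pyrimidine-strand
#' image of adenine misincorporation opposite the 5' guanine of Pt-GpG
#' intrastrand adducts during translesion synthesis. The score is the
#' summed weight on channels `C[C>A]A` and `C[C>A]G`.
#'
#' @param profile normalized 96-vector (names optional but, when present,
#'   must match [channelLabels()] order is assumed otherwise).
#' @return Fraction in \[0, 1\].
#' @examples
#' platinumScore(rep(1/96, 96))  # 2/96
#' @export
platinumScore <- function(profile) {
  profile <- as.numeric(profile)
  stopifnot(length(profile) == 96L)
  idx <- match(c("C[C>A]A", "C[C>A]G"), channelLabels())
  sum(profile[idx])
}
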