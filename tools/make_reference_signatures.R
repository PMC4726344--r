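# Builds inst/extdata/reference_signatures_synthetic.tsv: five synthetic
# 96-channel profiles with the qualitative channel structure of the
# corresponding mutational processes (platinum: C>A at CpCpA/CpCpG;
# APOBEC-like: C>T/C>G at TpCpW; aging: C>T at NpCpG; UV-like: C>T at
# dipyrimidines; smoking-like: broad C>A). Prints pairwise cosines and
# the platinum score as a sanity report.
suppressMessages(devtools::load_all("/root/pkg", quiet = TRUE))

labs <- channelLabels()
blank <- setNames(numeric(96), labs)

norm1 <- function(x) x / sum(x)

mk <- function(spikes, background = 0.08) {
  p <- blank + background / 96
  for (ch in names(spikes)) p[ch] <- p[ch] + spikes[ch]
  norm1(p)
}

platinum <- mk(c("C[C>A]A" = 0.40, "C[C>A]G" = 0.36,
                 "C[C>A]C" = 0.05, "C[C>A]T" = 0.05,
                 "T[C>A]A" = 0.02, "T[C>A]G" = 0.02))

apobec <- mk(c("T[C>T]A" = 0.24, "T[C>T]T" = 0.22,
               "T[C>G]A" = 0.22, "T[C>G]T" = 0.20))

aging <- mk(c("A[C>T]G" = 0.22, "C[C>T]G" = 0.22,
              "G[C>T]G" = 0.22, "T[C>T]G" = 0.22))

uv <- mk(c("C[C>T]C" = 0.20, "C[C>T]T" = 0.18, "T[C>T]C" = 0.18,
           "C[C>T]A" = 0.12, "T[T>C]T" = 0.08, "C[T>C]C" = 0.08,
           "C[C>T]G" = 0.04))

smoking_spikes <- setNames(rep(0.042, 16),
                           grep("C>A", labs, value = TRUE, fixed = TRUE))
smoking_spikes[c("C[C>A]A", "C[C>A]G")] <- 0.012  # platinum's channels
smoking <- mk(c(smoking_spikes,
                "G[T>A]G" = 0.05, "C[T>A]C" = 0.05, "A[T>A]A" = 0.04))

m <- cbind(platinum = platinum, apobec = apobec, aging = aging,
           uv = uv, smoking = smoking)
m <- round(m, 6)
m <- sweep(m, 2, colSums(m), "/")

cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
cat("pairwise cosines:\n")
for (i in 1:4) for (j in (i + 1):5)
  cat(sprintf("  %-8s %-8s %.3f\n", colnames(m)[i], colnames(m)[j],
              cs(m[, i], m[, j])))
cat("platinum score of platinum profile:", platinumScore(m[, 1]), "\n")

df <- data.frame(channel = labs, round(m, 6), check.names = FALSE)
dir.create("/root/pkg/inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(df, "/root/pkg/inst/extdata/reference_signatures_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("written\n")
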