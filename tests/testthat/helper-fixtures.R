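# Shared fixtures and independent oracles.

# brute-force K-mer counter: substring extraction + dictionary count,
# independent of the integer-encoding path it checks
oracle_count_kmers <- function(seq, K) {
  seq <- toupper(seq)
  n <- nchar(seq)
  counts <- numeric(4^K)
  if (n < K) return(counts)
  bases <- c(A = 0, C = 1, G = 2, T = 3, U = 3)
  for (start in seq_len(n - K + 1)) {
    word <- strsplit(substr(seq, start, start + K - 1), "")[[1]]
    v <- bases[word]
    if (anyNA(v)) next
    idx <- sum(v * 4^((K - 1):0))
    counts[idx + 1] <- counts[idx + 1] + 1
  }
  counts
}

# rank-based (Mann-Whitney) AUC, independent of pROC
oracle_auc <- function(truth, score) {
  ok <- !is.na(score)
  truth <- truth[ok]; score <- score[ok]
  n1 <- sum(truth); n0 <- sum(!truth)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small labelled community + trained stack, built once per test run
.fixture_env <- new.env(parent = emptyenv())

small_community <- function() {
  if (is.null(.fixture_env$comm)) {
    .fixture_env$comm <- generate_community(
      n_genera = 20, genus_sizes = 8, seq_length = 600,
      centroid_divergence = 0.02, within_genus_rate = 0.005, seed = 42)
  }
  .fixture_env$comm
}

small_machine <- function() {
  if (is.null(.fixture_env$mach)) {
    .fixture_env$mach <- suppressWarnings(
      build_taxmachine(small_community(), seed = 42))
  }
  .fixture_env$mach
}
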