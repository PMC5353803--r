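# The multinomial K-mer model: per-taxon K-mer counting, pseudo-count
# smoothed log2-probabilities (the Q matrix), and streaming classification.

#' Aggregate K-mer counts per taxon
#'
#' Counts all K-mers of every sequence and sums the counts within each
#' taxon, giving the M x 4^K count matrix the multinomial model is trained
#' from. Taxa are ordered by first appearance in `data`.
#'
#' @param data A data frame with columns `sequence` (nucleotide strings)
#'   and `genus` (taxon labels).
#' @param K Word length, integer in `[1, 12]`.
#' @return An object of class `taxon_counts`: a list with the count matrix
#'   `X` (taxa in rows), the taxon names `taxa`, and `K`.
#' @export
aggregate_taxon_counts <- function(data, K) {
  K <- .check_k(K)
  stopifnot(all(c("sequence", "genus") %in% names(data)))
  if (nrow(data) == 0L) {
    stop("`data` must contain at least one sequence", call. = FALSE)
  }
  taxa <- unique(data$genus)
  X <- matrix(0, nrow = length(taxa), ncol = 4L^K,
              dimnames = list(taxa, NULL))
  row_of <- match(data$genus, taxa)
  for (i in seq_len(nrow(data))) {
    enc <- encode_sequence(data$sequence[i])
    X[row_of[i], ] <- X[row_of[i], ] + count_kmers(enc, K)
  }
  empty <- rowSums(X) == 0
  if (any(empty)) {
    warning("taxa with zero valid K-mers: ",
            paste(taxa[empty], collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, taxa = taxa, K = K), class = "taxon_counts")
}

#' Train a multinomial K-mer model
#'
#' Converts per-taxon K-mer counts into multinomial log2-probabilities
#' with Laplace-style pseudo-counts: a total pseudo-count mass `P` is
#' spread uniformly over the `4^K` words of each taxon, so
#' `Q[g, j] = log2((x_gj + P/4^K) / (sum_j x_gj + P))`. Rows with no
#' observed K-mers reduce to the uniform distribution. Every row of
#' `2^Q` sums to one.
#'
#' @param counts A `taxon_counts` object from [aggregate_taxon_counts()].
#' @param pseudo Total pseudo-count mass `P` (positive; the ready-to-use
#'   classifier in [build_taxmachine()] uses 100).
#' @return An object of class `multinom_model`: list with the `Q` matrix,
#'   `taxa`, `K`, `pseudo` and `log_base = 2`.
#' @export
train_multinomial <- function(counts, pseudo) {
  stopifnot(inherits(counts, "taxon_counts"))
  if (!is.numeric(pseudo) || length(pseudo) != 1L || is.na(pseudo) ||
      pseudo <= 0) {
    stop("`pseudo` must be a single positive number", call. = FALSE)
  }
  ncol_k <- ncol(counts$X)
  Q <- log2((counts$X + pseudo / ncol_k) / (rowSums(counts$X) + pseudo))
  structure(
    list(Q = Q, taxa = counts$taxa, K = counts$K, pseudo = pseudo,
         log_base = 2),
    class = "multinom_model"
  )
}

#' @export
print.multinom_model <- function(x, ...) {
  cat(sprintf("Multinomial K-mer model: %d taxa, K = %d, pseudo-counts = %g\n",
              length(x$taxa), x$K, x$pseudo))
  invisible(x)
}

# score a single encoded query against Q by streaming column addition;
# never materializes the 4^K count vector
.stream_score <- function(enc, Q, K) {
  idx <- kmer_indices(enc, K)
  if (length(idx) == 0L) {
    return(NULL)
  }
  # duplicated columns carry K-mer multiplicity; <= n - K + 1 additions
  rowSums(Q[, idx + 1L, drop = FALSE])
}

.revcomp <- function(enc) {
  out <- rev(enc)
  ok <- out >= 0L
  out[ok] <- 3L - out[ok]
  out
}

#' Classify sequences by streaming posterior log-probability summation
#'
#' For each query, the columns of the model's `Q` matrix indexed by the
#' query's valid K-mers are summed, yielding the posterior
#' log2-probability of the query under every taxon. This is equivalent to
#' the matrix product of the K-mer count vector with `t(Q)` but never
#' materializes the `4^K`-long count vector, so the work per query is at
#' most `n - K + 1` column additions.
#'
#' Queries shorter than `K`, or with no window free of alien characters,
#' are flagged unscorable (an `NA` score row) rather than failing the
#' batch.
#'
#' @param data A data frame with a `sequence` column (and optionally `id`).
#' @param model A `multinom_model` from [train_multinomial()].
#' @param both_strands If `TRUE`, each query is also scored as its reverse
#'   complement and the orientation with the larger maximum is kept.
#'   Default `FALSE`: reads are assumed correctly oriented.
#' @return An object of class `posterior_scores`: list with the N x M
#'   `scores` matrix, per-query `lengths` (bases), `scorable` flags, `ids`,
#'   and the model's `taxa`.
#' @export
classify_streaming <- function(data, model, both_strands = FALSE) {
  stopifnot(inherits(model, "multinom_model"))
  stopifnot("sequence" %in% names(data))
  if (nrow(data) == 0L) {
    stop("`data` must contain at least one query", call. = FALSE)
  }
  ids <- if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(data)))
  n <- nrow(data)
  scores <- matrix(NA_real_, nrow = n, ncol = length(model$taxa),
                   dimnames = list(ids, model$taxa))
  lengths <- nchar(data$sequence)
  scorable <- logical(n)
  for (i in seq_len(n)) {
    enc <- encode_sequence(data$sequence[i])
    s <- .stream_score(enc, model$Q, model$K)
    if (both_strands) {
      s_rc <- .stream_score(.revcomp(enc), model$Q, model$K)
      if (is.null(s) || (!is.null(s_rc) && max(s_rc) > max(s))) s <- s_rc
    }
    if (!is.null(s)) {
      scores[i, ] <- s
      scorable[i] <- TRUE
    }
  }
  structure(
    list(scores = scores, lengths = lengths, scorable = scorable,
         ids = ids, taxa = model$taxa),
    class = "posterior_scores"
  )
}

#' Extract best and runner-up taxa from posterior scores
#'
#' For each query, returns the taxon with maximum posterior
#' log2-probability (`p1`) and the runner-up (`p2`). Exact ties are broken
#' toward the lower taxon index (first in training order) and flagged, so
#' the downstream d-score is 0. Single-taxon models have no runner-up:
#' `p2 = -Inf`, `taxon2 = NA`.
#'
#' @param scores A `posterior_scores` object from [classify_streaming()].
#' @return A tibble with one row per query, in input order: `id`, `taxon`,
#'   `p1`, `taxon2`, `p2`, `length`, `scorable`, `tie`.
#' @export
predict_taxa <- function(scores) {
  stopifnot(inherits(scores, "posterior_scores"))
  n <- nrow(scores$scores)
  m <- ncol(scores$scores)
  taxon <- taxon2 <- rep(NA_character_, n)
  p1 <- p2 <- rep(NA_real_, n)
  tie <- rep(NA, n)
  for (i in seq_len(n)) {
    if (!scores$scorable[i]) next
    row <- scores$scores[i, ]
    best <- which.max(row)  # lowest index on ties
    taxon[i] <- scores$taxa[best]
    p1[i] <- row[best]
    if (m >= 2L) {
      p2[i] <- max(row[-best])
      taxon2[i] <- scores$taxa[-best][which.max(row[-best])]
      tie[i] <- p2[i] == p1[i]
    } else {
      p2[i] <- -Inf
      tie[i] <- FALSE
    }
  }
  tibble::tibble(
    id = scores$ids, taxon = taxon, p1 = p1, taxon2 = taxon2, p2 = p2,
    length = scores$lengths, scorable = scores$scorable, tie = tie
  )
}

#' Break-even word length of streaming classification
#'
#' Streaming classification costs about `(n - K) * M` operations per query
#' against `4^K * M` for explicit count-vector scoring; the streaming
#' route wins once `4^K > n - K`. Solves `4^K = n - K` for `K`.
#'
#' @param n Sequence length in bases (about 1500 for full-length 16S).
#' @return The break-even word length (about 5.27 at `n = 1500`).
#' @export
streaming_breakeven <- function(n = 1500) {
  stats::uniroot(function(k) 4^k - (n - k), c(0.1, 15),
                 tol = 1e-10)$root
}
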