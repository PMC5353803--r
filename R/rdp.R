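# Bootstrap-free naive-Bayes word-presence classifier (RDP-style), for
# comparison with the multinomial method. Shares the integer K-mer engine;
# words count once per sequence (presence, not multiplicity), and no
# bootstrap confidence is computed.

#' Train a word-presence naive-Bayes model
#'
#' For word `j`, the prior probability of a sequence containing it is
#' `p_j = (n_j + 0.5) / (N + 1)` where `n_j` is the number of training
#' sequences containing the word and `N` the total. The genus-conditional
#' probability is `(m_gj + p_j) / (M_g + 1)` with `m_gj` the number of
#' genus-`g` sequences containing the word and `M_g` the genus size. All
#' probabilities are strictly inside `(0, 1)`.
#'
#' @param data A data frame with columns `sequence` and `genus`.
#' @param K Word length (default 8, the convention of this method).
#' @return An object of class `rdp_model`: list with the M x 4^K matrix
#'   `L` of log word-presence conditionals, the word `prior` vector,
#'   `taxa` and `K`.
#' @export
train_rdp <- function(data, K = 8) {
  K <- .check_k(K)
  stopifnot(all(c("sequence", "genus") %in% names(data)))
  if (nrow(data) == 0L) {
    stop("`data` must contain at least one sequence", call. = FALSE)
  }
  taxa <- unique(data$genus)
  ncol_k <- 4L^K
  n_word <- numeric(ncol_k)              # n_j: sequences containing word j
  m_word <- matrix(0, nrow = length(taxa), ncol = ncol_k,
                   dimnames = list(taxa, NULL))
  row_of <- match(data$genus, taxa)
  for (i in seq_len(nrow(data))) {
    idx <- unique(kmer_indices(encode_sequence(data$sequence[i]), K)) + 1L
    n_word[idx] <- n_word[idx] + 1
    m_word[row_of[i], idx] <- m_word[row_of[i], idx] + 1
  }
  n_total <- nrow(data)
  prior <- (n_word + 0.5) / (n_total + 1)
  genus_size <- tabulate(row_of, nbins = length(taxa))
  L <- log(sweep(m_word, 2L, prior, `+`) / (genus_size + 1))
  structure(list(L = L, prior = prior, taxa = taxa, K = K),
            class = "rdp_model")
}

#' @export
print.rdp_model <- function(x, ...) {
  cat(sprintf("Word-presence naive-Bayes model: %d taxa, K = %d\n",
              length(x$taxa), x$K))
  invisible(x)
}

#' Classify sequences with the word-presence naive-Bayes model
#'
#' The score of genus `g` is the sum, over the *distinct* words of the
#' query, of the log genus-conditional presence probabilities; the query
#' is assigned to the argmax genus (ties to the lower taxon index). No
#' bootstrap confidence is attached.
#'
#' @param data A data frame with a `sequence` column (and optionally
#'   `id`).
#' @param model An `rdp_model` from [train_rdp()].
#' @return A tibble with one row per query: `id`, `taxon`, `score`,
#'   `scorable`.
#' @export
classify_rdp <- function(data, model) {
  stopifnot(inherits(model, "rdp_model"))
  stopifnot("sequence" %in% names(data))
  ids <- if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(data)))
  n <- nrow(data)
  taxon <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  scorable <- logical(n)
  for (i in seq_len(n)) {
    idx <- unique(kmer_indices(encode_sequence(data$sequence[i]), model$K))
    if (length(idx) == 0L) next
    s <- rowSums(model$L[, idx + 1L, drop = FALSE])
    best <- which.max(s)
    taxon[i] <- model$taxa[best]
    score[i] <- s[best]
    scorable[i] <- TRUE
  }
  tibble::tibble(id = ids, taxon = taxon, score = score, scorable = scorable)
}
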