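# Integer encoding of nucleotide sequences and K-mer enumeration.
#
# Bases are mapped A->0, C->1, G->2, T/U->3; any other character (N,
# IUPAC ambiguity codes, gaps, ...) maps to a large negative sentinel so
# that a K-mer window containing one is detected by a single sign test on
# its inner-product index.

# sentinel = -4^15; dominates any positive window contribution for K <= 15
.ALIEN <- -1073741824L

# byte-indexed lookup table; lower case handled directly
.ENC_LUT <- local({
  lut <- rep(.ALIEN, 256L)
  lut[utf8ToInt("Aa")] <- 0L
  lut[utf8ToInt("Cc")] <- 1L
  lut[utf8ToInt("Gg")] <- 2L
  lut[utf8ToInt("TtUu")] <- 3L
  lut
})

#' Encode a nucleotide sequence as an integer vector
#'
#' Maps `A -> 0`, `C -> 1`, `G -> 2`, `T -> 3` and `U -> 3` (so RNA input
#' classifies identically to DNA). Every other character -- `N`, IUPAC
#' ambiguity codes, gaps -- is mapped to the sentinel value `-4^15`, which
#' guarantees that any K-mer window containing such a character has a
#' negative positional index and is discarded during counting. Case is
#' ignored.
#'
#' @param seq A single non-empty nucleotide string.
#' @return An integer vector with one entry per input character.
#' @examples
#' encode_sequence("ACGT")
#' encode_sequence("acgu")
#' @export
encode_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single character string", call. = FALSE)
  }
  if (!nzchar(seq)) {
    stop("`seq` must be non-empty", call. = FALSE)
  }
  .ENC_LUT[utf8ToInt(seq)]
}

#' Decode an encoded sequence back to a nucleotide string
#'
#' Inverse of [encode_sequence()] over the `{A,C,G,T}` alphabet; sentinel
#' entries decode to `N`.
#'
#' @param enc Integer vector produced by [encode_sequence()].
#' @return A single character string.
#' @export
decode_sequence <- function(enc) {
  bases <- c("A", "C", "G", "T")
  out <- rep("N", length(enc))
  ok <- enc >= 0L & enc <= 3L
  out[ok] <- bases[enc[ok] + 1L]
  paste(out, collapse = "")
}

# shared validation for K
.check_k <- function(K, k_max = 12L) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K != as.integer(K) ||
      K < 1L || K > k_max) {
    stop("`K` must be a single integer in [1, ", k_max, "]", call. = FALSE)
  }
  as.integer(K)
}

#' Positional indices of the valid K-mers of a sequence
#'
#' Slides a window of length `K` along the encoded sequence and computes,
#' for each window, the inner product with the positional weights
#' `c(4^(K-1), ..., 4, 1)`. Windows containing at least one alien symbol
#' have a negative inner product (the sentinel magnitude `4^15` dominates
#' any positive contribution for `K <= 15`) and are discarded. Retained
#' indices are returned in window order.
#'
#' @param enc Integer vector from [encode_sequence()].
#' @param K Word length, an integer in `[1, 12]`. The cap keeps `4^K`
#'   count vectors at a sane size (`4^12` is about 1.7e7).
#' @return Integer vector of K-mer indices in `[0, 4^K - 1]`; empty when
#'   `K > length(enc)` or no window is free of alien symbols.
#' @examples
#' kmer_indices(encode_sequence("ACGT"), K = 2) # 1, 6, 11
#' @export
kmer_indices <- function(enc, K) {
  K <- .check_k(K)
  if (length(enc) == 0L) {
    stop("`enc` must be non-empty", call. = FALSE)
  }
  n <- length(enc)
  if (K > n) {
    return(integer(0))
  }
  nw <- n - K + 1L
  # accumulate in double: sentinel * 4^(K-1) overflows 32-bit integers
  idx <- numeric(nw)
  w <- 4^((K - 1L):0L)
  for (j in seq_len(K)) {
    idx <- idx + as.numeric(enc[j:(j + nw - 1L)]) * w[j]
  }
  as.integer(idx[idx >= 0])
}

#' Count the K-mers of a sequence
#'
#' Tabulates the valid K-mer indices of [kmer_indices()] into a dense
#' count vector of length `4^K`. For a sequence of length `n` with no
#' alien characters the counts sum to `n - K + 1`.
#'
#' @inheritParams kmer_indices
#' @return Numeric vector of length `4^K`; entry `j + 1` is the number of
#'   windows with index `j`.
#' @examples
#' count_kmers(encode_sequence("AAAA"), K = 1)
#' @export
count_kmers <- function(enc, K) {
  K <- .check_k(K)
  idx <- kmer_indices(enc, K)
  tabulate(idx + 1L, nbins = 4L^K)
}
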