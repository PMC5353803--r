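# Synthetic 16S community generation and read-error simulation.
#
# Emulates the structure of a curated full-length 16S training set: many
# genera, a cloud of sequences around each genus centroid, highly skewed
# genus sizes (down to singletons), and ~1500-base sequences. Optionally
# a coarser "order"-like grouping above the genus level, for unknown-taxon
# experiments.

.BASES <- c("A", "C", "G", "T")

# mutate an integer-coded sequence: each position substituted i.i.d. with
# probability `rate`, always to a different base
.mutate_iid <- function(v, rate) {
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit) > 0L) {
    v[hit] <- (v[hit] + sample(1:3, length(hit), replace = TRUE)) %% 4L
  }
  v
}

#' Generate a synthetic 16S community
#'
#' Draws one random centroid per genus by mutating a shared ancestral
#' sequence, then draws each genus member by i.i.d. substitutions from
#' the centroid. With `n_groups` set, genera are nested inside
#' coarser groups: the ancestor is first mutated at `group_divergence`
#' into one ancestor per group, and genus centroids diverge from their
#' group ancestor. Genus sizes may be a fixed count, a vector (recycled),
#' or `NULL` for the default skewed size distribution
#' (`1 + rnbinom(size = 1.2, mu = mean_size - 1)`), which produces many
#' small genera and singletons as real taxonomies do.
#'
#' @param n_genera Number of genera.
#' @param genus_sizes Sequences per genus: single count, vector, or
#'   `NULL` for the skewed default.
#' @param mean_size Mean of the default size distribution (default 8).
#' @param seq_length Sequence length in bases (>= 200; default 1500,
#'   full-length 16S).
#' @param centroid_divergence Substitution fraction from the (group)
#'   ancestor to each genus centroid, in `[0, 0.75]`.
#' @param within_genus_rate Substitution fraction from centroid to each
#'   genus member, in `[0, 0.75]`.
#' @param n_groups Optional number of coarse groups above the genus level.
#' @param group_divergence Substitution fraction from the ancestor to each
#'   group ancestor (used only with `n_groups`).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed (applied locally).
#' @return A tibble with columns `id`, `genus`, `sequence` (and `group`
#'   when `n_groups` is set); attribute `"spec"` records all parameters
#'   and attribute `"centroids"` the genus centroid sequences.
#' @export
generate_community <- function(n_genera = 50, genus_sizes = NULL,
                               mean_size = 8, seq_length = 1500,
                               centroid_divergence = 0.005,
                               within_genus_rate = 0.005,
                               n_groups = NULL, group_divergence = 0.02,
                               seed = 1) {
  if (centroid_divergence < 0 || centroid_divergence > 0.75 ||
      within_genus_rate < 0 || within_genus_rate > 0.75) {
    stop("divergence rates must lie in [0, 0.75]", call. = FALSE)
  }
  if (seq_length < 200) {
    stop("`seq_length` must be at least 200 bases", call. = FALSE)
  }
  spec <- list(n_genera = n_genera, genus_sizes = genus_sizes,
               mean_size = mean_size, seq_length = seq_length,
               centroid_divergence = centroid_divergence,
               within_genus_rate = within_genus_rate,
               n_groups = n_groups, group_divergence = group_divergence,
               seed = seed)
  out <- withr::with_seed(seed, {
    sizes <- if (is.null(genus_sizes)) {
      1L + stats::rnbinom(n_genera, size = 1.2, mu = mean_size - 1)
    } else {
      rep_len(as.integer(genus_sizes), n_genera)
    }
    ancestor <- sample(0:3, seq_length, replace = TRUE)
    if (!is.null(n_groups)) {
      group_of <- sort(rep_len(seq_len(n_groups), n_genera))
      group_anc <- lapply(seq_len(n_groups), function(g) {
        .mutate_iid(ancestor, group_divergence)
      })
    } else {
      group_of <- rep(1L, n_genera)
      group_anc <- list(ancestor)
    }
    rows <- lapply(seq_len(n_genera), function(g) {
      centroid <- .mutate_iid(group_anc[[group_of[g]]], centroid_divergence)
      seqs <- vapply(seq_len(sizes[g]), function(j) {
        paste(.BASES[.mutate_iid(centroid, within_genus_rate) + 1L],
              collapse = "")
      }, character(1))
      tibble::tibble(
        id = sprintf("g%03d_s%03d", g, seq_len(sizes[g])),
        group = sprintf("group%02d", group_of[g]),
        genus = sprintf("genus%03d", g),
        centroid = paste(.BASES[centroid + 1L], collapse = ""),
        sequence = seqs
      )
    })
    dplyr::bind_rows(rows)
  })
  centroids <- unique(out[c("genus", "centroid")])
  out$centroid <- NULL
  if (is.null(n_groups)) out$group <- NULL
  attr(out, "spec") <- spec
  attr(out, "centroids") <- centroids
  out
}

#' Sample a contiguous fragment of a sequence
#'
#' Fragment length is uniform on `[min_len, max_len]` and the start
#' position uniform over all valid starts; forward strand only. Uses the
#' current RNG stream (seed at the caller).
#'
#' @param seq A nucleotide string.
#' @param min_len,max_len Length bounds; `max_len` must not exceed the
#'   sequence length.
#' @return The fragment as a string.
#' @export
sample_fragment <- function(seq, min_len, max_len) {
  n <- nchar(seq)
  if (min_len < 1L || min_len > max_len) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  if (max_len > n) {
    stop("`max_len` (", max_len, ") exceeds sequence length (", n, ")",
         call. = FALSE)
  }
  len <- if (min_len == max_len) min_len else sample(min_len:max_len, 1L)
  start <- if (len == n) 1L else sample(seq_len(n - len + 1L), 1L)
  substr(seq, start, start + len - 1L)
}

#' Corrupt a sequence with random substitution errors
#'
#' Replaces bases at `round(rate * n)` distinct positions, each with a
#' uniformly random base different from the original. The exact-count
#' default makes the realized error load deterministic given the rate;
#' `mode = "bernoulli"` flips each position independently instead.
#'
#' @param seq A nucleotide string.
#' @param rate Fraction of positions to corrupt, in `[0, 1]`.
#' @param mode `"exact"` (default) or `"bernoulli"`.
#' @return The corrupted sequence.
#' @export
corrupt_substitutions <- function(seq, rate, mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]", call. = FALSE)
  v <- encode_sequence(seq)
  n <- length(v)
  pos <- if (mode == "exact") {
    k <- round(rate * n)
    if (k == 0L) return(seq)
    sample(n, k)
  } else {
    which(stats::runif(n) < rate)
  }
  if (length(pos) == 0L) return(seq)
  ok <- v[pos] >= 0L
  # alien characters at hit positions become uniform random bases
  v[pos[!ok]] <- sample(0:3, sum(!ok), replace = TRUE)
  p <- pos[ok]
  v[p] <- (v[p] + sample(1:3, length(p), replace = TRUE)) %% 4L
  paste(.BASES[v + 1L], collapse = "")
}

#' Corrupt a sequence with random insertions and deletions
#'
#' Picks `round(position_rate * n)` anchor positions without replacement;
#' at each, with probability 1/2 inserts `indel_len` random bases and
#' otherwise deletes `indel_len` bases (truncated at the sequence end).
#' Events are applied right-to-left so anchors always refer to positions
#' in the original sequence.
#'
#' @param seq A nucleotide string.
#' @param position_rate Fraction of positions receiving an event, `[0, 1]`.
#' @param indel_len Length of each insertion or deletion (>= 1).
#' @return The corrupted sequence.
#' @export
corrupt_indels <- function(seq, position_rate, indel_len) {
  if (position_rate < 0 || position_rate > 1) {
    stop("`position_rate` must be in [0, 1]", call. = FALSE)
  }
  if (indel_len < 1L) stop("`indel_len` must be >= 1", call. = FALSE)
  n <- nchar(seq)
  k <- round(position_rate * n)
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  anchors <- sort(sample(n, k), decreasing = TRUE)
  insert <- stats::runif(k) < 0.5
  for (i in seq_len(k)) {
    a <- anchors[i]
    if (insert[i]) {
      ins <- sample(.BASES, indel_len, replace = TRUE)
      chars <- append(chars, ins, after = a)
    } else {
      drop <- a:min(a + indel_len - 1L, length(chars))
      chars <- chars[-drop]
    }
  }
  if (length(chars) < 1L) {
    stop("corruption removed the entire sequence", call. = FALSE)
  }
  paste(chars, collapse = "")
}
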