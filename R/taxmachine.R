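# Ready-to-use classification stack: multinomial model + length
# normalization + genus score statistics, trained together, plus the
# read-length / unknown-taxon / corruption evaluation experiments.

#' Train the full classification stack
#'
#' Runs [aggregate_taxon_counts()], [train_multinomial()],
#' [fit_length_norm()] and [fit_genus_stats()] on one training set and
#' bundles the results. Defaults are word length `K = 8` and a total
#' pseudo-count mass of 100, a robust compromise across read lengths for
#' genus-level 16S classification.
#'
#' @param data Training sequences: data frame with columns `id` and
#'   `sequence`, and `genus` unless `taxonomy` is given.
#' @param taxonomy Optional taxonomy table (`sequence_id`, `genus`) joined
#'   to `data` by ID; every sequence must have a label.
#' @param K Word length (default 8).
#' @param pseudo Total pseudo-count mass (default 100).
#' @param min_frag Minimum fragment length for the length-normalization
#'   fit (default 100 bases).
#' @param seed Integer seed for the fragment sampling.
#' @param name Training-set name recorded in the metadata.
#' @return An object of class `tax_machine`: list with `model`
#'   (`multinom_model`), `norm` (`length_norm`), `stats` (`genus_stats`)
#'   and `metadata`.
#' @export
build_taxmachine <- function(data, taxonomy = NULL, K = 8, pseudo = 100,
                             min_frag = 100, seed = 1, name = "training") {
  if (!is.null(taxonomy)) {
    data <- .join_taxonomy(data, taxonomy)
  }
  stopifnot(all(c("id", "sequence", "genus") %in% names(data)))
  counts <- aggregate_taxon_counts(data, K)
  model <- train_multinomial(counts, pseudo)
  # one random-length fragment per training sequence backs both the
  # length normalization and the genus statistics, so r-scores are
  # centred across the whole length range rather than at full length
  pred <- .norm_fragment_scores(model, data, min_frag, seed)
  norm <- fit_length_norm_scores(pred$length, pred$p1)
  p_tilde <- normalize_logprob(pred$p1, pred$length, norm, warn = FALSE)
  stats <- fit_genus_stats(
    tibble::tibble(genus = data$genus, p_tilde = p_tilde))
  structure(
    list(
      model = model, norm = norm, stats = stats,
      metadata = list(name = name, K = counts$K, pseudo = pseudo,
                      min_frag = min_frag, seed = seed,
                      n_sequences = nrow(data),
                      n_taxa = length(counts$taxa),
                      format_version = "microtax/1")
    ),
    class = "tax_machine"
  )
}

#' @export
print.tax_machine <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "tax_machine '%s': %d taxa, %d sequences, K = %d, pseudo = %g, seed = %s\n",
    md$name, md$n_taxa, md$n_sequences, md$K, md$pseudo, md$seed))
  invisible(x)
}

# collapse per-record flag matrix into "a;b" strings ("" when clean)
.join_flags <- function(...) {
  flags <- list(...)
  nm <- names(flags)
  apply(do.call(cbind, flags), 1L, function(row) {
    paste(nm[which(row %in% TRUE)], collapse = ";")
  })
}

# shared scoring core: top-2 extraction -> normalization -> d/r scores,
# given an already-computed posterior_scores object
.records_from_scores <- function(scores, machine, exclude_taxa = NULL) {
  if (!is.null(exclude_taxa)) {
    keep <- !(scores$taxa %in% exclude_taxa)
    if (sum(keep) < 2L) {
      stop("masking would leave fewer than two taxa", call. = FALSE)
    }
    scores$scores <- scores$scores[, keep, drop = FALSE]
    scores$taxa <- scores$taxa[keep]
  }
  pred <- predict_taxa(scores)
  norm <- machine$norm
  p1t <- normalize_logprob(pred$p1, pred$length, norm, warn = FALSE)
  p2t <- normalize_logprob(pred$p2, pred$length, norm, warn = FALSE)
  m <- length(scores$taxa)
  d <- if (m >= 2L) d_score(p1t, p2t) else rep(NA_real_, nrow(pred))
  r <- rep(NA_real_, nrow(pred))
  ok <- !is.na(pred$taxon)
  r[ok] <- r_score(p1t[ok], pred$taxon[ok], machine$stats)
  rp <- r_probability(r, machine$stats)
  extrap <- pred$length < norm$fit_range[1] | pred$length > norm$fit_range[2]
  unusual <- !is.na(r) & r < machine$stats$r_train[1]
  tibble::tibble(
    query_id = pred$id,
    taxon = pred$taxon,
    d_score = d,
    r_score = r,
    r_probability = rp,
    flags = .join_flags(unscorable = !pred$scorable, tie = pred$tie,
                        `extrapolated-length` = extrap, unusual = unusual),
    p1 = pred$p1,
    p_tilde = p1t,
    length = pred$length
  )
}

#' Classify sequences with full uncertainty scoring
#'
#' For each query: streaming posterior scores, best and runner-up taxon,
#' length normalization of both, the d-score, the r-score with the
#' predicted genus as plug-in, and its ECDF probability. One output row
#' per input row, in input order; unscorable queries (shorter than `K`,
#' or all alien characters) get `NA` scores and an `unscorable` flag
#' rather than aborting the batch.
#'
#' Flags: `unscorable`, `tie` (exact top-2 tie, d = 0), `extrapolated-length`
#' (query length outside the normalization's fitted range), `unusual`
#' (r-score below every training r-score).
#'
#' @param data Query sequences: data frame with columns `id` and
#'   `sequence`.
#' @param machine A `tax_machine` from [build_taxmachine()].
#' @return A tibble with columns `query_id`, `taxon`, `d_score`,
#'   `r_score`, `r_probability`, `flags`, plus `p1`, `p_tilde` and
#'   `length`.
#' @export
classify_with_uncertainty <- function(data, machine) {
  stopifnot(inherits(machine, "tax_machine"))
  scores <- classify_streaming(data, machine$model)
  .records_from_scores(scores, machine)
}

# sample `per_seq` fragments in a length range from every sequence long
# enough, carrying the true genus along
.sample_fragment_set <- function(data, min_len, max_len, per_seq) {
  data <- data[nchar(data$sequence) >= max_len, , drop = FALSE]
  if (nrow(data) == 0L) {
    stop("no training sequence is at least ", max_len, " bases long",
         call. = FALSE)
  }
  idx <- rep(seq_len(nrow(data)), each = per_seq)
  tibble::tibble(
    id = sprintf("%s_f%02d", data$id[idx], rep(seq_len(per_seq), nrow(data))),
    genus = data$genus[idx],
    sequence = vapply(idx, function(i) {
      sample_fragment(data$sequence[i], min_len, max_len)
    }, character(1))
  )
}

#' Read-length evaluation of a trained classifier
#'
#' Samples `fragments_per_seq` fragments at random locations from every
#' training sequence for each read-length range, classifies them, and
#' reports the error percentage, the ROC AUC of the d-score as a ranker
#' of correct versus incorrect classifications, and the error percentage
#' restricted to calls with `d > 1` (the conventional "safe" threshold).
#'
#' @param machine A `tax_machine`.
#' @param data The sequences to fragment: data frame with `id`, `genus`,
#'   `sequence`.
#' @param length_ranges List of `c(min, max)` read-length ranges; the
#'   defaults are typical short-read, medium-read and merged/long-read
#'   amplicon lengths.
#' @param fragments_per_seq Fragments sampled per sequence per range.
#' @param seed Integer seed for fragment sampling.
#' @return A tibble with one row per range: `range`, `n`, `error_pct`,
#'   `auc_d`, `n_d_gt1`, `error_pct_d_gt1`, plus the per-fragment records
#'   in the `"records"` attribute.
#' @export
evaluate_fragments <- function(machine, data,
                               length_ranges = list(c(120, 150),
                                                    c(270, 300),
                                                    c(450, 500)),
                               fragments_per_seq = 10, seed = 1) {
  stopifnot(inherits(machine, "tax_machine"))
  all_rec <- withr::with_seed(seed, {
    purrr::map(length_ranges, function(rng) {
      frags <- .sample_fragment_set(data, rng[1], rng[2], fragments_per_seq)
      rec <- classify_with_uncertainty(frags, machine)
      rec$true_genus <- frags$genus
      rec$range <- sprintf("%d-%d", rng[1], rng[2])
      rec
    })
  })
  records <- dplyr::bind_rows(all_rec)
  records$correct <- !is.na(records$taxon) & records$taxon == records$true_genus
  summary <- dplyr::summarise(
    dplyr::group_by(records, .data$range),
    n = dplyr::n(),
    error_pct = 100 * mean(!.data$correct),
    auc_d = .auc_safe(.data$correct, .data$d_score),
    n_d_gt1 = sum(!is.na(.data$d_score) & .data$d_score > 1),
    error_pct_d_gt1 = 100 * mean(!.data$correct[
      !is.na(.data$d_score) & .data$d_score > 1]),
    .groups = "drop"
  )
  attr(summary, "records") <- records
  summary
}

# AUC of `score` ranking TRUE above FALSE; NA when one class is absent
.auc_safe <- function(truth, score) {
  ok <- !is.na(score)
  truth <- truth[ok]
  score <- score[ok]
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
}

#' Unknown-taxon (taxon-wise holdout) evaluation of the r-score
#'
#' Classifies read fragments under three conditions: the full model
#' (baseline), with the true genus of each fragment masked from the model
#' (genus unknown to the classifier), and -- when the data carries a
#' coarser `group` column -- with the whole group masked. Because the
#' per-taxon multinomial rows are independent, masking rows of `Q` is
#' exactly equivalent to retraining without the held-out taxon; scores
#' are computed once against the full model and the mask is applied at
#' argmax time.
#'
#' @param machine A `tax_machine`.
#' @param data Data frame with `id`, `genus`, `sequence`, optionally
#'   `group`.
#' @param frag_range Read-length range of the sampled fragments.
#' @param fragments_per_seq Fragments sampled per sequence.
#' @param seed Integer seed.
#' @return A tibble with one row per condition (`none`, `genus`, and
#'   `group` if available): `condition`, `n`, `mean_r`, `median_r`.
#' @export
evaluate_unknown_taxa <- function(machine, data, frag_range = c(450, 500),
                                  fragments_per_seq = 1, seed = 1) {
  stopifnot(inherits(machine, "tax_machine"))
  frags <- withr::with_seed(seed, {
    .sample_fragment_set(data, frag_range[1], frag_range[2],
                         fragments_per_seq)
  })
  # attach group labels through the genus
  if ("group" %in% names(data)) {
    g2grp <- unique(data[c("genus", "group")])
    frags$group <- g2grp$group[match(frags$genus, g2grp$genus)]
  }
  scores <- classify_streaming(frags, machine$model)
  conditions <- list()
  conditions$none <- .records_from_scores(scores, machine)$r_score
  mask_condition <- function(level) {
    unlist(lapply(split(seq_len(nrow(frags)), frags[[level]]),
      function(rows) {
        held <- unique(frags$genus[rows])
        if (length(setdiff(scores$taxa, held)) < 2L) {
          warning("skipping holdout of ", level, " level: fewer than two ",
                  "taxa would remain", call. = FALSE)
          return(numeric(0))
        }
        sub <- scores
        sub$scores <- sub$scores[rows, , drop = FALSE]
        sub$lengths <- sub$lengths[rows]
        sub$scorable <- sub$scorable[rows]
        sub$ids <- sub$ids[rows]
        .records_from_scores(sub, machine, exclude_taxa = held)$r_score
      }), use.names = FALSE)
  }
  conditions$genus <- mask_condition("genus")
  if ("group" %in% names(frags)) {
    conditions$group <- mask_condition("group")
  }
  dplyr::bind_rows(purrr::imap(conditions, function(r, nm) {
    tibble::tibble(condition = nm, n = sum(!is.na(r)),
                   mean_r = mean(r, na.rm = TRUE),
                   median_r = stats::median(r, na.rm = TRUE))
  }))
}

#' Sequencing-error robustness evaluation
#'
#' Samples read fragments, corrupts them with substitution errors and
#' with fixed-length insertions/deletions, classifies each condition, and
#' reports classification accuracy and the r-score distribution.
#'
#' @param machine A `tax_machine`.
#' @param data Data frame with `id`, `genus`, `sequence`.
#' @param substitution_rates Substitution error levels (fractions).
#' @param indel_specs List of `c(position_rate, indel_len)` pairs.
#' @param frag_range Read-length range (default 450-500 bases).
#' @param fragments_per_seq Fragments sampled per sequence.
#' @param seed Integer seed.
#' @return A tibble with one row per condition (including the
#'   uncorrupted baseline `none`): `condition`, `n`, `accuracy_pct`,
#'   `mean_r`, `r_q25`, `r_q50`, `r_q75`.
#' @export
evaluate_corruption <- function(machine, data,
                                substitution_rates = c(0.01, 0.05),
                                indel_specs = list(c(0.01, 5), c(0.01, 10)),
                                frag_range = c(450, 500),
                                fragments_per_seq = 1, seed = 1) {
  stopifnot(inherits(machine, "tax_machine"))
  withr::with_seed(seed, {
    frags <- .sample_fragment_set(data, frag_range[1], frag_range[2],
                                  fragments_per_seq)
    conditions <- list(none = frags$sequence)
    for (rate in substitution_rates) {
      conditions[[sprintf("subs_%g", rate)]] <-
        vapply(frags$sequence, corrupt_substitutions, character(1),
               rate = rate, USE.NAMES = FALSE)
    }
    for (spec in indel_specs) {
      conditions[[sprintf("indel_%g_len%d", spec[1], as.integer(spec[2]))]] <-
        vapply(frags$sequence, corrupt_indels, character(1),
               position_rate = spec[1], indel_len = spec[2],
               USE.NAMES = FALSE)
    }
    dplyr::bind_rows(purrr::imap(conditions, function(seqs, nm) {
      rec <- classify_with_uncertainty(
        tibble::tibble(id = frags$id, sequence = seqs), machine)
      correct <- !is.na(rec$taxon) & rec$taxon == frags$genus
      q <- stats::quantile(rec$r_score, c(0.25, 0.5, 0.75), na.rm = TRUE)
      tibble::tibble(condition = nm, n = nrow(rec),
                     accuracy_pct = 100 * mean(correct),
                     mean_r = mean(rec$r_score, na.rm = TRUE),
                     r_q25 = q[[1]], r_q50 = q[[2]], r_q75 = q[[3]])
    }))
  })
}
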