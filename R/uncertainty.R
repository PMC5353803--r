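# Classification uncertainty: length normalization of posterior
# log-probabilities, the d-score (decision-boundary proximity), and the
# r-score (distance from the predicted genus centre, standardized with a
# loess-smoothed, size-shrunken genus SD) with its ECDF tail probability.

#' Fit the length-normalization model from (length, score) pairs
#'
#' The maximum posterior log2-probability of a read grows (more negative)
#' roughly linearly with read length, and its spread grows with length
#' too. This fits the two linear regressions used by [normalize_logprob()]:
#' the mean of `p1` against length on all pairs, and the standard
#' deviation against length on per-bin sample SDs of the residuals from
#' the mean fit (reads binned by length, bins with fewer than `min_bin`
#' members dropped). Residuals are used so the within-bin slice of the
#' mean trend does not inflate the SD estimate.
#'
#' @param lengths Fragment lengths in bases.
#' @param p1 Maximum posterior log2-probabilities, one per fragment.
#' @param bin_width Length-bin width in bases for the SD regression.
#' @param min_bin Minimum number of fragments per bin.
#' @return An object of class `length_norm`: list with `mean_coef` and
#'   `sd_coef` (intercept, slope), `fit_range` (min/max length seen), and
#'   the fitting data in `fragments` for plotting.
#' @export
fit_length_norm_scores <- function(lengths, p1, bin_width = 50, min_bin = 10) {
  keep <- !is.na(p1) & !is.na(lengths)
  lengths <- lengths[keep]
  p1 <- p1[keep]
  if (length(p1) < 100L) {
    stop("need at least 100 scored fragments to fit the length ",
         "normalization (got ", length(p1), ")", call. = FALSE)
  }
  mean_fit <- stats::lm(p1 ~ lengths)
  resid <- stats::residuals(mean_fit)
  bin <- floor(lengths / bin_width)
  bt <- table(bin)
  good <- as.integer(names(bt)[bt >= min_bin])
  if (length(good) < 2L) {
    stop("fragment lengths span fewer than two length bins; the SD ",
         "regression is degenerate", call. = FALSE)
  }
  bin_mid <- (good + 0.5) * bin_width
  bin_sd <- vapply(good, function(b) stats::sd(resid[bin == b]), numeric(1))
  sd_fit <- stats::lm(bin_sd ~ bin_mid)
  fit_range <- range(lengths)
  sd_coef <- unname(stats::coef(sd_fit))
  if (any(sd_coef[1] + sd_coef[2] * fit_range <= 0)) {
    stop("fitted SD regression is non-positive inside the fitted length ",
         "range", call. = FALSE)
  }
  structure(
    list(
      mean_coef = unname(stats::coef(mean_fit)),
      sd_coef = sd_coef,
      fit_range = fit_range,
      fragments = tibble::tibble(length = lengths, p1 = p1)
    ),
    class = "length_norm"
  )
}

#' Fit length normalization by fragment sampling from the training set
#'
#' Samples one fragment per training sequence -- length uniform between
#' `min_frag` and the full sequence length, start uniform over valid
#' positions -- classifies each fragment with `model`, and fits the
#' mean/SD regressions of [fit_length_norm_scores()] to the resulting
#' (length, p1) pairs.
#'
#' @param model A `multinom_model`; should be trained on `data`.
#' @param data Training sequences: data frame with a `sequence` column.
#' @param min_frag Minimum fragment length in bases (default 100).
#' @param seed Integer seed for the fragment sampling (applied locally;
#'   the global RNG state is untouched).
#' @inheritParams fit_length_norm_scores
#' @return A `length_norm` object.
#' @export
fit_length_norm <- function(model, data, min_frag = 100, seed = NULL,
                            bin_width = 50, min_bin = 10) {
  stopifnot(inherits(model, "multinom_model"))
  pred <- .norm_fragment_scores(model, data, min_frag, seed)
  fit_length_norm_scores(pred$length, pred$p1,
                         bin_width = bin_width, min_bin = min_bin)
}

# one random-length fragment per sequence, classified; the shared
# sampling protocol behind the normalization and the genus statistics
.norm_fragment_scores <- function(model, data, min_frag, seed) {
  sample_one <- function(s) {
    n <- nchar(s)
    len <- if (n <= min_frag) n else sample(min_frag:n, 1L)
    sample_fragment(s, len, len)
  }
  frags <- if (is.null(seed)) {
    vapply(data$sequence, sample_one, character(1), USE.NAMES = FALSE)
  } else {
    withr::with_seed(seed,
      vapply(data$sequence, sample_one, character(1), USE.NAMES = FALSE))
  }
  predict_taxa(classify_streaming(tibble::tibble(sequence = frags), model))
}

#' @export
print.length_norm <- function(x, ...) {
  cat(sprintf(
    "Length normalization: mean = %.4g + %.4g*l, sd = %.4g + %.4g*l, lengths %d-%d\n",
    x$mean_coef[1], x$mean_coef[2], x$sd_coef[1], x$sd_coef[2],
    x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Length-normalize a posterior log-probability
#'
#' Standardizes a posterior log2-probability against the mean and SD
#' predicted at the read's length: `(p - p_hat_l) / s_hat_l`. Lengths
#' outside the fitted range extrapolate with a warning; an extrapolation
#' extreme enough to drive the predicted SD non-positive is an error.
#'
#' @param p Posterior log2-probability (vectorized).
#' @param l Sequence length in bases (scalar or same length as `p`).
#' @param norm A `length_norm` object.
#' @param warn Warn on lengths outside the fitted range (default `TRUE`).
#' @return Normalized score(s).
#' @export
normalize_logprob <- function(p, l, norm, warn = TRUE) {
  stopifnot(inherits(norm, "length_norm"))
  outside <- !is.na(l) & (l < norm$fit_range[1] | l > norm$fit_range[2])
  if (warn && any(outside)) {
    warning("normalizing at ", sum(outside), " length(s) outside the ",
            "fitted range [", norm$fit_range[1], ", ", norm$fit_range[2],
            "]", call. = FALSE)
  }
  s_hat <- norm$sd_coef[1] + norm$sd_coef[2] * l
  if (any(!is.na(s_hat) & s_hat <= 0)) {
    stop("predicted SD is non-positive at some length(s); extrapolation ",
         "too extreme", call. = FALSE)
  }
  p_hat <- norm$mean_coef[1] + norm$mean_coef[2] * l
  (p - p_hat) / s_hat
}

#' The d-score: distance from the decision boundary
#'
#' Difference between the largest and second-largest length-normalized
#' posterior log2-probabilities of a query. Near 0 the runner-up taxon is
#' almost as likely as the winner; large values mean a confident call.
#' Because both scores are normalized with the same affine map (same
#' length), `d >= 0` whenever `p1 >= p2` before normalization.
#'
#' @param p1_tilde,p2_tilde Normalized best and runner-up scores,
#'   normalized at the same length with the same `length_norm`.
#' @return `p1_tilde - p2_tilde` (vectorized).
#' @export
d_score <- function(p1_tilde, p2_tilde) {
  p1_tilde - p2_tilde
}

#' Per-genus score statistics with size-smoothed SD shrinkage
#'
#' From the normalized maximum log-probabilities of the training
#' sequences, computes per genus the mean `p_bar`, the raw sample SD
#' `s_raw` (undefined for singleton genera), and the genus size `n`.
#' Because small genera give unreliable SDs, raw SDs are grouped by genus
#' size, their per-size means are smoothed against size with loess, and
#' the smoothed size-specific SD `s_size` is combined with the raw SD by
#'
#'   `s_bar = sqrt(((n - 1) * s_raw^2 + s_size^2) / n)`
#'
#' so singletons (`n = 1`) get exactly the size-smoothed SD while large
#' genera keep essentially their own. Also computes and stores the sorted
#' training r-scores that back [r_probability()].
#'
#' @param data A data frame with columns `genus` and `p_tilde` (normalized
#'   maximum posterior log2-probabilities), one row per training sequence.
#' @param span,degree loess parameters for the SD-vs-size smooth
#'   (defaults 0.75 and 2, on the raw size scale). When fewer than five
#'   distinct genus sizes carry a raw SD, the per-size mean SDs are used
#'   directly instead of a loess fit.
#' @return An object of class `genus_stats`: list with per-genus tibble
#'   `genus_table` (`genus`, `n`, `p_bar`, `s_raw`, `s_size`, `s_bar`),
#'   the size-SD smooth in `size_table`, sorted training r-scores in
#'   `r_train`, and the per-sequence training scores in `training`.
#' @export
fit_genus_stats <- function(data, span = 0.75, degree = 2) {
  stopifnot(all(c("genus", "p_tilde") %in% names(data)))
  data <- data[!is.na(data$p_tilde), , drop = FALSE]
  per_genus <- dplyr::summarise(
    dplyr::group_by(data, .data$genus),
    n = dplyr::n(),
    p_bar = mean(.data$p_tilde),
    s_raw = stats::sd(.data$p_tilde),  # NA for n = 1
    .groups = "drop"
  )
  # per-size mean of raw SDs (sizes >= 2 only; singletons have no SD)
  with_sd <- per_genus[!is.na(per_genus$s_raw), , drop = FALSE]
  if (nrow(with_sd) == 0L) {
    stop("all genera are singletons; cannot estimate any genus SD",
         call. = FALSE)
  }
  size_table <- dplyr::summarise(
    dplyr::group_by(with_sd, size = .data$n),
    mean_sd = mean(.data$s_raw),
    n_genera = dplyr::n(),
    .groups = "drop"
  )
  size_table <- dplyr::arrange(size_table, .data$size)
  if (nrow(size_table) >= 5L) {
    lo <- stats::loess(mean_sd ~ size, data = size_table,
                       span = span, degree = degree)
    size_table$smooth_sd <- stats::predict(lo, size_table$size)
  } else {
    size_table$smooth_sd <- size_table$mean_sd
  }
  # clamp: smoothed SDs must stay positive
  floor_sd <- min(size_table$smooth_sd[size_table$smooth_sd > 0])
  size_table$smooth_sd <- pmax(size_table$smooth_sd, floor_sd)

  # nearest fitted size serves sizes outside the smooth's support
  lookup_s_size <- function(n) {
    i <- which.min(abs(size_table$size - n))
    size_table$smooth_sd[i]
  }
  miss <- setdiff(unique(per_genus$n), size_table$size)
  if (length(miss) > 0L) {
    warning("no smoothed SD at genus size(s) ",
            paste(sort(miss), collapse = ", "),
            "; using the nearest fitted size", call. = FALSE)
  }
  per_genus$s_size <- vapply(per_genus$n, lookup_s_size, numeric(1))
  s2 <- ifelse(is.na(per_genus$s_raw), 0, per_genus$s_raw^2)
  per_genus$s_bar <- sqrt(((per_genus$n - 1) * s2 + per_genus$s_size^2) /
                            per_genus$n)
  stats_obj <- structure(
    list(genus_table = per_genus, size_table = size_table,
         r_train = numeric(0), training = NULL),
    class = "genus_stats"
  )
  r <- r_score(data$p_tilde, data$genus, stats_obj)
  stats_obj$r_train <- sort(r)
  stats_obj$training <- tibble::tibble(genus = data$genus,
                                      p_tilde = data$p_tilde, r = r)
  stats_obj
}

#' @export
print.genus_stats <- function(x, ...) {
  cat(sprintf(
    "Genus score statistics: %d genera (sizes %d-%d), %d training r-scores\n",
    nrow(x$genus_table), min(x$genus_table$n), max(x$genus_table$n),
    length(x$r_train)))
  invisible(x)
}

#' The r-score: standardized residual from the predicted genus centre
#'
#' `r = (p_tilde - p_bar_g) / s_bar_g`, where `g` is the (predicted)
#' genus and `s_bar_g` its shrunken SD from [fit_genus_stats()]. A large
#' negative r-score means the query scores far below what training
#' sequences of that genus score: a sign of sequencing error, chimeras,
#' or a taxon absent from the training data.
#'
#' @param p_tilde Normalized maximum posterior log2-probabilities.
#' @param genus Predicted genus for each query (plug-in for the unknown
#'   true genus).
#' @param stats A `genus_stats` object.
#' @return r-scores (vectorized); `NA` where `p_tilde` is `NA`.
#' @export
r_score <- function(p_tilde, genus, stats) {
  stopifnot(inherits(stats, "genus_stats"))
  i <- match(genus, stats$genus_table$genus)
  bad <- is.na(i) & !is.na(genus)
  if (any(bad)) {
    stop("unknown genus: ",
         paste(utils::head(unique(genus[bad]), 10L), collapse = ", "),
         call. = FALSE)
  }
  (p_tilde - stats$genus_table$p_bar[i]) / stats$genus_table$s_bar[i]
}

#' ECDF probability of an r-score
#'
#' The probability of observing an r-score this small or smaller among
#' the training sequences, from the empirical cumulative distribution of
#' the stored training r-scores using the Weibull plotting position
#' `rank / (N + 1)`. Values below the training minimum return
#' `1 / (N + 1)`, never exactly 0; values above the maximum return
#' `N / (N + 1)`, never 1. A very small probability flags a sequence
#' unlike anything in the training set.
#'
#' @param r r-score(s) from [r_score()].
#' @param stats A `genus_stats` object.
#' @return Probabilities in `(0, 1)`, monotone non-decreasing in `r`.
#' @export
r_probability <- function(r, stats) {
  stopifnot(inherits(stats, "genus_stats"))
  n <- length(stats$r_train)
  if (n < 100L) {
    warning("only ", n, " training r-scores back the ECDF; tail ",
            "probabilities are coarse", call. = FALSE)
  }
  rank <- findInterval(r, stats$r_train)  # count of training scores <= r
  out <- pmax(rank, 1L) / (n + 1)
  out[is.na(r)] <- NA_real_
  out
}
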