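# crafted genus stats: six two-sequence genera whose raw SDs average to 2,
# so the size-smoothed SD at size 2 is exactly 2
crafted_stats <- function() {
  mk <- function(genus, centre, sd) {
    # two points with sample SD `sd`: centre +/- sd/sqrt(2)
    tibble::tibble(genus = genus,
                   p_tilde = centre + c(-1, 1) * sd / sqrt(2))
  }
  df <- dplyr::bind_rows(
    mk("gA", 0, 1), mk("gB", 0, 3), mk("gC", 1, 1), mk("gD", 1, 3),
    mk("gE", -1, 1), mk("gF", -1, 3),
    tibble::tibble(genus = "gSingleton", p_tilde = 0.5)
  )
  suppressWarnings(fit_genus_stats(df))
}

test_that("length normalization standardizes against the fitted mean and SD", {
  norm <- structure(
    list(mean_coef = c(-10, -1), sd_coef = c(1, 0.01),
         fit_range = c(100, 1500)),
    class = "length_norm")
  expect_equal(normalize_logprob(-120, 100, norm), -5)
  # centered and unit-SD cases
  p_hat <- -10 - 1 * 200
  s_hat <- 1 + 0.01 * 200
  expect_equal(normalize_logprob(p_hat, 200, norm), 0)
  expect_equal(normalize_logprob(p_hat + s_hat, 200, norm), 1)
  expect_warning(normalize_logprob(-100, 80, norm), "outside the")
  # SD model crosses zero far below the fitted range
  norm_bad <- norm
  norm_bad$sd_coef <- c(-1, 0.02)
  expect_error(suppressWarnings(normalize_logprob(-100, 20, norm_bad)),
               "non-positive")
})

test_that("normalization fit recovers known mean and SD coefficients", {
  a <- -10; b <- -10; c0 <- 2; d0 <- 0.01
  withr::with_seed(21, {
    l <- sample(100:1500, 5000, replace = TRUE)
    p1 <- a + b * l + stats::rnorm(5000, sd = c0 + d0 * l)
  })
  fit <- fit_length_norm_scores(l, p1)
  expect_lt(abs(fit$mean_coef[1] - a) / abs(a), 0.05)
  expect_lt(abs(fit$mean_coef[2] - b) / abs(b), 0.05)
  expect_lt(abs(fit$sd_coef[1] - c0) / abs(c0), 0.15)
  expect_lt(abs(fit$sd_coef[2] - d0) / abs(d0), 0.15)
})

test_that("degenerate or tiny fragment sets are refused", {
  expect_error(fit_length_norm_scores(rep(300, 500), rnorm(500)),
               "degenerate")
  expect_error(fit_length_norm_scores(1:99, rnorm(99)), "at least 100")
})

test_that("d-score is the gap between the top two normalized scores", {
  expect_equal(d_score(2.0, 0.5), 1.5)
  expect_equal(d_score(1.0, 1.0), 0)
  # affine invariance: adding a constant to both raw scores at the same
  # length cancels in the difference
  norm <- structure(
    list(mean_coef = c(-10, -1), sd_coef = c(1, 0.01),
         fit_range = c(100, 1500)),
    class = "length_norm")
  for (shift in c(-50, 0, 17)) {
    d1 <- d_score(normalize_logprob(-300 + shift, 250, norm),
                  normalize_logprob(-320 + shift, 250, norm))
    expect_equal(d1, d_score(normalize_logprob(-300, 250, norm),
                             normalize_logprob(-320, 250, norm)))
  }
})

test_that("genus SD shrinkage follows the size-smoothed combination", {
  st <- crafted_stats()
  gt <- st$genus_table
  # size-2 smoothed SD is the mean of raw SDs {1,3,...} = 2
  expect_equal(st$size_table$smooth_sd[st$size_table$size == 2], 2)
  # n = 2, s_raw = 1, s_size = 2 -> sqrt((1*1 + 4)/2) = sqrt(2.5)
  expect_equal(gt$s_bar[gt$genus == "gA"], sqrt(2.5), tolerance = 1e-12)
  # singleton: s_bar equals the size-smoothed SD exactly (nearest size)
  expect_equal(gt$s_bar[gt$genus == "gSingleton"],
               gt$s_size[gt$genus == "gSingleton"])
  expect_true(all(gt$s_bar > 0))
})

test_that("shrinkage limits hold exactly", {
  # s_size = s_raw for every genus -> s_bar = s_raw exactly
  mk <- function(genus, centre) {
    tibble::tibble(genus = genus, p_tilde = centre + c(-1, 0, 1))
  }
  st <- suppressWarnings(
    fit_genus_stats(dplyr::bind_rows(mk("a", 0), mk("b", 2), mk("c", -3))))
  gt <- st$genus_table
  expect_equal(gt$s_bar, gt$s_raw, tolerance = 1e-12)
  # large-n limit: s_bar -> s_raw
  n <- 10000
  s_bar <- sqrt(((n - 1) * 1 + 2^2) / n)
  expect_equal(s_bar, 1.0002, tolerance = 1e-4)
})

test_that("r-score is the standardized residual with plug-in genus", {
  st <- crafted_stats()
  gt <- st$genus_table
  g <- "gB"
  expect_equal(r_score(gt$p_bar[gt$genus == g], g, st), 0)
  expect_equal(
    r_score(gt$p_bar[gt$genus == g] - 2 * gt$s_bar[gt$genus == g], g, st),
    -2)
  expect_error(r_score(0, "nonexistent", st), "unknown genus")
})

test_that("ECDF probability uses rank/(N+1) with a positive floor", {
  st <- structure(list(r_train = sort(c(-3, -1, 0, 2))),
                  class = "genus_stats")
  expect_warning(p <- r_probability(-1, st), "coarse")
  expect_equal(p, 0.4)
  expect_equal(suppressWarnings(r_probability(2, st)), 4 / 5)
  expect_equal(suppressWarnings(r_probability(-99, st)), 1 / 5)
  # monotone, never 0 or 1
  r <- seq(-10, 10, by = 0.25)
  p <- suppressWarnings(r_probability(r, st))
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("r-scores of random-length training fragments are standardized", {
  mach <- small_machine()
  comm <- small_community()
  frags <- withr::with_seed(61, {
    tibble::tibble(
      genus = comm$genus,
      sequence = vapply(comm$sequence, function(s) {
        len <- sample(100:nchar(s), 1L)
        sample_fragment(s, len, len)
      }, character(1), USE.NAMES = FALSE))
  })
  rec <- classify_with_uncertainty(frags, mach)
  # held-out fragments: loose bounds, genus sizes are small here
  by_genus <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(genus = frags$genus, r = rec$r_score),
                    genus),
    m = mean(r), s = stats::sd(r), .groups = "drop")
  expect_lt(mean(abs(by_genus$m)), 0.5)
  expect_true(all(by_genus$s > 0.2 & by_genus$s < 2.5))
  # the training scores themselves are standardized genus by genus
  tr <- dplyr::summarise(
    dplyr::group_by(mach$stats$training, genus),
    m = mean(r), s = stats::sd(r), .groups = "drop")
  expect_lt(max(abs(tr$m)), 0.1)
  expect_true(all(tr$s > 0.5 & tr$s < 1.5))
})
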