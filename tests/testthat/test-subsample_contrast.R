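test_that("degenerate configurations are rejected", {
  expect_error(subsample_config(fraction = 1), "fraction")
  expect_error(subsample_config(fraction = 0), "fraction")
  expect_error(subsample_config(n_draws = 1), "n_draws")
})

test_that("pipeline matches the brute-force loop oracle exactly", {
  cfg <- small_cohort_config(n = c(60, 60), n_regions = 6L, seed = 61L)
  co <- simulate_cohort(cfg, connectivity = FALSE)
  sel <- co$participants$group == "CU"
  sc <- subsample_config(n_draws = 12L, fraction = 0.8, seed = 62L)
  ours <- subsample_t_distribution(co$roi, co$participants$frailty,
                                   co$participants$scanner, subset = sel,
                                   config = sc)
  oracle <- subsample_oracle(co$roi[sel, ], co$participants$frailty[sel],
                             co$participants$scanner[sel], sc)
  expect_equal(unclass(ours)[seq_len(nrow(oracle)), ], oracle,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("null effects give near-zero mean t; strong effects track the full-sample t", {
  n <- 200
  # the draw mean concentrates near each cohort's full-sample t, so the null
  # check averages over replicate cohorts
  null_means <- sapply(1:6, function(r) {
    set.seed(600 + r)
    frailty <- runif(n, 0, 0.5)
    Y <- cbind(null = rnorm(n))
    td <- subsample_t_distribution(Y, frailty, config = subsample_config(
      n_draws = 40L, fraction = 0.8, seed = 64L + r))
    mean(td[, 1])
  })
  expect_lt(abs(mean(null_means)), 2.5 / sqrt(6))
  set.seed(63)
  frailty <- runif(n, 0, 0.5)
  Y <- cbind(strong = 2 - 4 * frailty + rnorm(n, 0, 0.4))
  td <- subsample_t_distribution(Y, frailty, config = subsample_config(
    n_draws = 60L, fraction = 0.8, seed = 64L))
  full_t <- fit_region_models(Y, frailty)$t
  expect_lt(abs(mean(td[, 1]) - full_t) / abs(full_t), 0.15)
})

test_that("empirical t mean SE shrinks as 1/sqrt(n_draws) on fixed data", {
  n <- 120
  set.seed(65)
  frailty <- runif(n, 0, 0.5)
  Y <- cbind(R = 1 - frailty + rnorm(n, 0, 0.5))
  sds <- sapply(c(40L, 160L), function(nd) {
    reps <- sapply(1:12, function(r) {
      td <- subsample_t_distribution(Y, frailty, config = subsample_config(
        n_draws = nd, fraction = 0.8, seed = 100L * r))
      mean(td[, 1])
    })
    sd(reps)
  })
  # quadrupling the draws should roughly halve the SE of the mean t
  expect_lt(sds[2] / sds[1], 0.85)
})

test_that("group contrast flags the stronger-slope group as dominant with correct sign", {
  cfg <- cohort_config(group_specs = data.frame(
    group = c("A", "B"), n = c(250, 250), mean = c(0.2, 0.2),
    sd = c(0.08, 0.08)),
    n_regions = 4L,
    roi_slopes = cbind(A = c(0, 0, 0, 0), B = c(-4, -4, 0, 0)),
    roi_sd = 0.5, seed = 66L)
  co <- simulate_cohort(cfg, connectivity = FALSE)
  sc <- subsample_config(n_draws = 60L, fraction = 0.8, seed = 67L)
  tA <- subsample_t_distribution(co$roi, co$participants$frailty,
                                 co$participants$scanner,
                                 subset = co$participants$group == "A",
                                 config = sc)
  tB <- subsample_t_distribution(co$roi, co$participants$frailty,
                                 co$participants$scanner,
                                 subset = co$participants$group == "B",
                                 config = subsample_config(n_draws = 60L,
                                                           fraction = 0.8,
                                                           seed = 68L))
  ct <- contrast_groups(tA, tB, labels = c("A", "B"))
  affected <- ct[ct$unit %in% c("ROI_001", "ROI_002"), ]
  expect_true(all(affected$significant))
  expect_true(all(affected$dominant == "B"))
  # sign convention: t sign matches sign of mean_a - mean_b (B more negative)
  expect_true(all(sign(affected$t) == sign(affected$mean_a - affected$mean_b)))
  expect_true(all(affected$t > 0))
})

test_that("contrast is antisymmetric and identical samples give t = 0, p = 1", {
  set.seed(69)
  tA <- matrix(rnorm(50 * 3, -2), 50, dimnames = list(NULL, c("u1", "u2", "u3")))
  tB <- matrix(rnorm(50 * 3, -3), 50, dimnames = list(NULL, c("u1", "u2", "u3")))
  class(tA) <- class(tB) <- c("subsample_t", "matrix", "array")
  ab <- contrast_groups(tA, tB, labels = c("A", "B"))
  ba <- contrast_groups(tB, tA, labels = c("B", "A"))
  expect_equal(ab$t, -ba$t, tolerance = 1e-10)
  same <- contrast_groups(tA, tA, labels = c("A", "A2"))
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
})

test_that("null-slope groups produce no contrasts once restricted to associated units", {
  # the full procedure: restriction to units significant in >= 1 group keeps
  # the contrast family empty when neither group carries an association
  n_sig <- 0L
  for (r in 1:5) {
    cfg <- cohort_config(group_specs = data.frame(
      group = c("A", "B"), n = c(150, 150), mean = c(0.2, 0.2),
      sd = c(0.08, 0.08)),
      n_regions = 8L, roi_slopes = c(A = 0, B = 0), roi_sd = 0.5,
      scanner_offsets = c(0, 0, 0),  # fully null generative model
      seed = 70L + r)
    co <- simulate_cohort(cfg, connectivity = FALSE)
    fr <- co$participants$frailty
    assocA <- fit_region_models(co$roi, fr, co$participants$scanner,
                                subset = co$participants$group == "A")
    assocB <- fit_region_models(co$roi, fr, co$participants$scanner,
                                subset = co$participants$group == "B")
    restr <- contrast_restriction(assocA, assocB)
    if (!length(restr)) next
    mk <- function(g, sd_seed) subsample_t_distribution(
      co$roi, fr, co$participants$scanner,
      subset = co$participants$group == g,
      config = subsample_config(n_draws = 40L, seed = sd_seed))
    ct <- suppressMessages(contrast_groups(mk("A", 80L + r), mk("B", 90L + r),
                                           restriction = restr,
                                           labels = c("A", "B")))
    n_sig <- n_sig + sum(ct$significant)
  }
  expect_lte(n_sig, 2L)
})

test_that("the unrestricted contrast is anti-conservative for equal nonzero slopes", {
  # documented property of the draw-count-based Welch SE: dependent draws
  # shrink it with n_draws while full-sample t variability does not, so
  # identical nonzero slopes in independent cohorts still yield large t
  cfg <- cohort_config(group_specs = data.frame(
    group = c("A", "B"), n = c(150, 150), mean = c(0.2, 0.2),
    sd = c(0.08, 0.08)),
    n_regions = 5L, roi_slopes = c(A = -2, B = -2), roi_sd = 0.5, seed = 76L)
  co <- simulate_cohort(cfg, connectivity = FALSE)
  mk <- function(g, sd_seed) subsample_t_distribution(
    co$roi, co$participants$frailty, co$participants$scanner,
    subset = co$participants$group == g,
    config = subsample_config(n_draws = 40L, seed = sd_seed))
  ct <- contrast_groups(mk("A", 81L), mk("B", 91L), labels = c("A", "B"))
  expect_gte(sum(ct$significant), 1L)
})

test_that("restriction set limits the contrast family", {
  set.seed(72)
  tA <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("u", 1:4)))
  tB <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("u", 1:4)))
  ct <- contrast_groups(tA, tB, restriction = c("u2", "u4"),
                        labels = c("A", "B"))
  expect_identical(ct$unit, c("u2", "u4"))
  expect_message(empty <- contrast_groups(tA, tB, restriction = character()),
                 "empty restriction")
  expect_identical(nrow(empty), 0L)
})
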