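test_that("binarization rules map raw values, boundaries and missings correctly", {
  specs <- list(
    bin = health_item_spec("bin", "physical", "binary", "identity"),
    sbp = health_item_spec("sbp", "physical", "continuous", "ge", cut = 140),
    mmse = health_item_spec("mmse", "cognition", "continuous", "le", cut = 23),
    hr = health_item_spec("hr", "physical", "continuous", "outside",
                          lower = 60, upper = 100),
    bmi = health_item_spec("bmi", "physical", "continuous", "range",
                           lower = 18.5, upper = 30),
    vis = health_item_spec("vis", "physical", "ordinal", "map",
                           map = c(normal = 0, impaired = 1)))
  raw <- data.frame(bin = c(1, 0, NA),
                    sbp = c(140, 139.9, NA),   # closed on the deficit side
                    mmse = c(23, 24, NA),
                    hr = c(60, 59.9, 101),
                    bmi = c(18.5, 30, 25),
                    vis = c("normal", "impaired", NA))
  b <- binarize_items(raw, specs, id_cols = character())
  expect_identical(b$bin, c(1L, 0L, NA))
  expect_identical(b$sbp, c(1L, 0L, NA))
  expect_identical(b$mmse, c(1L, 0L, NA))
  expect_identical(b$hr, c(0L, 1L, 1L))
  expect_identical(b$bmi, c(0L, 1L, 0L))
  expect_identical(b$vis, c(0L, 1L, NA))
})

test_that("out-of-range and unmapped raw values become missing with a warning", {
  specs <- list(bin = health_item_spec("bin", "physical", "binary", "identity"))
  expect_warning(b <- binarize_items(data.frame(bin = c(0, 1, 2)), specs,
                                     id_cols = character()),
                 "outside")
  expect_identical(b$bin, c(0L, 1L, NA))
  expect_error(binarize_items(data.frame(mystery = 1), specs,
                              id_cols = character()),
               "schema error.*mystery")
})

test_that("screening drops each pathological item with the right ledger code", {
  tab <- screening_fixture()
  led <- screen_items(tab)
  dec <- setNames(led$decision, led$item)
  expect_identical(unname(dec["rare"]), "dropped_rare")
  expect_identical(unname(dec["common"]), "dropped_common")
  expect_identical(unname(dec["holey"]), "dropped_missing")
  # exactly one of the duplicated pair goes, by the missingness/order tie-break
  expect_identical(unname(dec["twin"]), "dropped_correlated")
  expect_identical(unname(dec["ok_a"]), "kept")
  expect_setequal(retained_items(led), c("ok_a", "ok_b", "ok_c"))
  expect_identical(nrow(led), ncol(tab))
})

test_that("a VIF-inflated item is pruned by the iterative VIF screen", {
  set.seed(4)
  n <- 600
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  # OR + AND = a + b exactly, so {a, b, or, and} is collinear (VIF blows up)
  # while every pairwise |r| stays well under 0.8; a few flips keep the
  # system merely near-singular rather than exactly singular
  or_ <- as.integer(a | b); and_ <- as.integer(a & b)
  flip <- sample(n, 10)
  or_[flip] <- 1L - or_[flip]
  tab <- data.frame(a = a, b = b, either = or_, both = and_,
                    d = rbinom(n, 1, 0.3))
  led <- screen_items(tab)
  expect_lt(max(abs(led$max_abs_r), na.rm = TRUE), 0.8)
  expect_true("dropped_vif" %in% led$decision)
  vifs <- fraildex:::compute_vif(as.matrix(tab[retained_items(led)]))
  expect_lt(max(vifs, na.rm = TRUE), 10)
})

test_that("re-screening the retained set drops nothing", {
  tab <- screening_fixture()
  led <- screen_items(tab)
  led2 <- screen_items(tab[retained_items(led)])
  expect_true(all(led2$decision == "kept"))
})

test_that("screening everything away is a hard error", {
  tab <- data.frame(a = rep(1L, 100), b = rep(1L, 100))
  expect_error(screen_items(tab), "every item")
})

test_that("index arithmetic: observed-denominator scoring and completeness gate", {
  m <- matrix(0L, 3, 32, dimnames = list(NULL, sprintf("it%02d", 1:32)))
  m[2, 1:8] <- 1L           # 8 deficits, 30 observed of 32
  m[2, 31:32] <- NA
  m[3, 1:8] <- NA           # 24 observed of 32 = 75% < 80%
  fr <- compute_frailty_index(as.data.frame(m))
  expect_identical(fr$index[1], 0)
  expect_equal(fr$index[2], 8 / 30, tolerance = 1e-12)
  expect_identical(fr$n_observed[2], 30)
  expect_true(fr$included[2])
  expect_false(fr$included[3])
  expect_true(is.na(fr$index[3]))
})

test_that("index is monotone, bounded and permutation invariant", {
  set.seed(8)
  m <- matrix(rbinom(50 * 12, 1, 0.3), 50, 12,
              dimnames = list(NULL, sprintf("it%02d", 1:12)))
  m[sample(length(m), 40)] <- NA
  df <- as.data.frame(m)
  fr <- compute_frailty_index(df)
  expect_true(all(fr$index[fr$included] >= 0 & fr$index[fr$included] <= 1))
  # flipping an observed 0 to 1 never decreases the index
  i <- which(fr$included & !is.na(m[, 3]) & m[, 3] == 0)[1]
  df2 <- df; df2[i, 3] <- 1L
  fr2 <- compute_frailty_index(df2)
  expect_gt(fr2$index[i], fr$index[i])
  # item order is irrelevant
  perm <- sample(ncol(df))
  fr3 <- compute_frailty_index(df[, perm])
  expect_equal(fr3$index, fr$index)
})

test_that("sensitivity variants exclude tagged items and re-gate completeness", {
  n_items <- 32
  m <- matrix(0L, 2, n_items, dimnames = list(NULL, sprintf("it%02d", 1:n_items)))
  tags <- rep(NA_character_, n_items)
  tags[1:8] <- "CDR"; tags[9] <- "MMSE"; tags[10] <- "GAD7"; tags[11] <- "GDS_SF"
  names(tags) <- colnames(m)
  m[1, 1:8] <- 1L   # all deficits inside the CDR block
  df <- as.data.frame(m)
  attr(df, "sensitivity_tags") <- tags

  full <- variant_index(df, exclude = character())
  base <- compute_frailty_index(df)
  expect_equal(full$index, base$index)

  minus_cdr <- variant_index(df, exclude = "CDR")
  expect_identical(minus_cdr$n_items[1], 24L)
  expect_identical(minus_cdr$index[1], 0)       # deficits were all excluded
  expect_identical(minus_cdr$variant[1], "minus_CDR")

  expect_error(variant_index(df, exclude = "NOPE"), "unknown tag")
})

test_that("variant completeness gate uses the reduced denominator", {
  m <- matrix(0L, 1, 10, dimnames = list(NULL, sprintf("it%02d", 1:10)))
  tags <- c(rep("CDR", 5), rep(NA, 5)); names(tags) <- colnames(m)
  m[1, 6:7] <- NA  # 8/10 observed -> included in full; 3/5 -> excluded in variant
  df <- as.data.frame(m); attr(df, "sensitivity_tags") <- tags
  expect_true(compute_frailty_index(df)$included)
  expect_false(variant_index(df, exclude = "CDR")$included)
})

test_that("index on Table 1-calibrated items reproduces group means within 3 SE", {
  cfg <- cohort_config(seed = 29L)
  co <- simulate_cohort(cfg, connectivity = FALSE)
  fr <- compute_frailty_index(co$items)
  gs <- cfg$group_specs
  for (i in seq_len(nrow(gs))) {
    v <- fr$index[fr$group == gs$group[i] & fr$included]
    se <- sqrt(gs$mean[i] * (1 - gs$mean[i]) / 32 / length(v))
    expect_lt(abs(mean(v) - gs$mean[i]), 3 * se)
  }
})
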