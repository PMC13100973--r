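test_that("fisher z matches atanh with clipping and domain checks", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5), tolerance = 1e-12)
  expect_warning(z <- fisher_z(1), "clipped")
  expect_true(is.finite(z))
  expect_error(fisher_z(1.01), "<= 1")
})

test_that("OLS t values match the normal-equations oracle on a small fixture", {
  set.seed(51)
  n <- 30
  frailty <- runif(n, 0.05, 0.4)
  scanner <- factor(sample(c("s1", "s2"), n, TRUE))
  Y <- sapply(1:5, function(i) 5 - i * frailty + rnorm(n, 0, 0.3))
  colnames(Y) <- sprintf("R%d", 1:5)
  res <- fit_region_models(Y, frailty, scanner)
  # oracle design mirrors the documented coding: most frequent level reference
  ref <- names(which.max(table(scanner)))
  X <- cbind(1, frailty, as.numeric(scanner != ref))
  for (i in 1:5) {
    o <- ols_oracle(Y[, i], X)
    expect_equal(res$t[i], unname(o$t[2]), tolerance = 1e-8)
    expect_equal(res$slope[i], unname(o$beta[2]), tolerance = 1e-8)
  }
})

test_that("injected negative slopes are recovered with sign and significance", {
  cfg <- cohort_config(group_specs = data.frame(group = "G", n = 500L,
                                                mean = 0.2, sd = 0.08),
                       n_regions = 6L, roi_slopes = c(G = -4), roi_sd = 0.5,
                       seed = 52L)
  co <- simulate_cohort(cfg, connectivity = FALSE)
  res <- fit_region_models(co$roi, co$participants$frailty,
                           co$participants$scanner)
  expect_true(all(res$significant))
  expect_true(all(res$t < 0))
})

test_that("null slopes keep the FDR-significant fraction near zero", {
  hits <- 0L
  for (rep in 1:20) {
    cfg <- cohort_config(group_specs = data.frame(group = "G", n = 150L,
                                                  mean = 0.2, sd = 0.08),
                         n_regions = 20L, roi_slopes = c(G = 0), roi_sd = 0.5,
                         scanner_offsets = c(0, 0, 0),  # pure null
                         seed = 52L + rep)
    co <- simulate_cohort(cfg, connectivity = FALSE)
    res <- fit_region_models(co$roi, co$participants$frailty,
                             co$participants$scanner)
    hits <- hits + sum(res$significant)
  }
  expect_lte(hits / (20 * 20), 0.01)
})

test_that("single scanner level reduces to the frailty-only model", {
  set.seed(53)
  n <- 40
  frailty <- runif(n)
  Y <- cbind(A = 1 - frailty + rnorm(n, 0, 0.2))
  one <- fit_region_models(Y, frailty, scanner = factor(rep("s1", n)))
  none <- fit_region_models(Y, frailty)
  expect_equal(one$t, none$t, tolerance = 1e-12)
  expect_equal(one$adj_r2, none$adj_r2, tolerance = 1e-12)
})

test_that("results are invariant to participant and region order", {
  set.seed(54)
  n <- 60
  frailty <- runif(n)
  scanner <- factor(sample(c("s1", "s2", "s3"), n, TRUE))
  Y <- sapply(1:4, function(i) rnorm(n, 2, 0.5) - i * 0.3 * frailty)
  colnames(Y) <- sprintf("R%d", 1:4)
  base <- fit_region_models(Y, frailty, scanner)
  pperm <- sample(n)
  r1 <- fit_region_models(Y[pperm, ], frailty[pperm], scanner[pperm])
  expect_equal(r1$t, base$t, tolerance = 1e-10)
  cperm <- c(3, 1, 4, 2)
  r2 <- fit_region_models(Y[, cperm], frailty, scanner)
  expect_equal(r2$t[match(base$unit, r2$unit)], base$t, tolerance = 1e-10)
})

test_that("FDR adjustment is monotone and the dual criterion is conservative", {
  set.seed(55)
  n <- 80
  frailty <- runif(n)
  Y <- sapply(1:12, function(i) rnorm(n) - (i <= 3) * 2 * frailty)
  colnames(Y) <- sprintf("R%d", 1:12)
  res <- fit_region_models(Y, frailty)
  expect_true(all(res$model_q >= res$model_p - 1e-12))
  expect_true(all(res$frailty_q >= res$p - 1e-12))
  expect_true(all(res$unit[res$significant] %in% res$unit[res$p < 0.05]))
})

test_that("degenerate regions are flagged and excluded from the FDR family", {
  set.seed(56)
  n <- 40
  frailty <- runif(n)
  Y <- cbind(ok = rnorm(n) - frailty, flat = rep(3, n))
  expect_message(res <- fit_region_models(Y, frailty), "degenerate")
  expect_true(res$degenerate[res$unit == "flat"])
  expect_true(is.na(res$model_q[res$unit == "flat"]))
  expect_false(res$significant[res$unit == "flat"])
})

test_that("edge models recover injected edge effects and exclude the diagonal", {
  cfg <- cohort_config(group_specs = data.frame(group = "G", n = 400L,
                                                mean = 0.2, sd = 0.08),
                       n_regions = 5L, edge_slopes = c(G = 2), edge_sd = 0.15,
                       seed = 57L)
  co <- simulate_cohort(cfg)
  res <- fit_edge_models(co$edges, co$participants$frailty,
                         co$participants$scanner)
  expect_identical(nrow(res), 10L)  # 5*4/2 edges, no self-edges
  expect_true(all(res$t > 0))
  expect_true(all(res$significant))
  expect_false(any(grepl("^(\\w+)\\|\\1$", res$unit)))
})

test_that("permuting frailty wipes out significant edges", {
  cfg <- cohort_config(group_specs = data.frame(group = "G", n = 200L,
                                                mean = 0.2, sd = 0.08),
                       n_regions = 6L, edge_slopes = c(G = 1), edge_sd = 0.2,
                       seed = 58L)
  co <- simulate_cohort(cfg)
  set.seed(1)
  perm <- sample(nrow(co$participants))
  res <- fit_edge_models(co$edges, co$participants$frailty[perm],
                         co$participants$scanner)
  expect_lte(sum(res$significant), 1L)
})

test_that("node degrees count signed significant edges with a hub on top", {
  cfg <- cohort_config(group_specs = data.frame(group = "G", n = 300L,
                                                mean = 0.2, sd = 0.08),
                       n_regions = 6L, edge_slopes = c(G = 0), edge_sd = 0.15,
                       seed = 59L)
  # star fixture: only edges touching region 1 carry an effect
  pairs <- fraildex:::edge_pairs(cfg$regions)
  slopes <- matrix(0, nrow(pairs), 1, dimnames = list(NULL, "G"))
  slopes[pairs$i == 1 | pairs$j == 1, 1] <- -3
  cfg$edges$slopes <- slopes
  co <- simulate_cohort(cfg)
  res <- fit_edge_models(co$edges, co$participants$frailty,
                         co$participants$scanner)
  nd <- node_degree_summary(res, top_k = 3)
  expect_identical(nd$region[1], cfg$regions[1])
  expect_identical(nd$n_negative[1], 5L)
  expect_identical(sum(nd$n_total), 2L * sum(res$significant))
  # no significant edges -> all zero counts
  nd0 <- node_degree_summary(res[res$significant == FALSE & FALSE, ])
  expect_true(all(nd0$n_total == 0) || nrow(nd0) == 0)
  # exactly one significant edge contributes one count to each endpoint
  one <- res[1, ]
  one$significant <- TRUE
  attr(one, "pairs") <- attr(res, "pairs")
  nd1 <- node_degree_summary(one)
  ends <- strsplit(one$unit, "|", fixed = TRUE)[[1]]
  expect_true(all(nd1$n_total[match(ends, nd1$region)] == 1L))
})

test_that("extra covariates behave as expected in adjusted models", {
  set.seed(60)
  n <- 250
  frailty <- runif(n, 0, 0.5)
  noise <- rnorm(n, 0, 0.4)
  Y <- cbind(R1 = 4 - 2 * frailty + noise)
  plain <- fit_region_models(Y, frailty)
  # uncorrelated covariate: t approximately unchanged
  adj1 <- adjusted_models(Y, frailty, extra = data.frame(junk = rnorm(n)))
  expect_lt(abs(adj1$t - plain$t) / abs(plain$t), 0.1)
  # covariate tracking the outcome noise: R^2 rises, slope stays unbiased
  adj2 <- adjusted_models(Y, frailty,
                          extra = data.frame(qc = noise + rnorm(n, 0, 0.3)))
  expect_gt(adj2$adj_r2, plain$adj_r2)
  expect_lt(abs(adj2$slope - plain$slope) / abs(plain$slope), 0.15)
  # covariate equal to frailty: rank-deficiency error
  expect_error(adjusted_models(Y, frailty, extra = data.frame(f2 = frailty)),
               "collinear")
})

test_that("long-format connectivity canonicalizes unordered pairs", {
  long <- data.frame(participant = rep(c("p1", "p2"), each = 3),
                     region_i = c("B", "A", "C", "B", "C", "A"),
                     region_j = c("A", "C", "B", "A", "B", "C"),
                     z = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  m <- edges_from_long(long)
  expect_identical(colnames(m), c("A|B", "A|C", "B|C"))
  expect_equal(unname(m["p1", ]), c(0.1, 0.2, 0.3))
  bad <- long
  bad$z[4] <- 9
  bad2 <- rbind(bad, data.frame(participant = "p2", region_i = "A",
                                region_j = "B", z = 0.4))
  expect_error(edges_from_long(bad2), "asymmetric")
})
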