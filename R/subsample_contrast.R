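#' Configure the subsampling contrast procedure
#'
#' @param n_draws Number of subsamples per group (the study design uses
#'   1000; tests scale this down).
#' @param fraction Fraction of the group's participants drawn, without
#'   replacement, per subsample. Must lie strictly inside (0, 1): a fraction
#'   of 1 would make every draw identical and the empirical t-distribution
#'   degenerate.
#' @param max_retries Retries allowed per draw when a subsample is
#'   degenerate (constant outcome or rank-deficient design).
#' @param seed Master seed; each draw's seed is derived from it by draw
#'   index, so distributed execution reproduces serial results.
#' @return Object of class `subsample_config`.
#' @export
subsample_config <- function(n_draws = 1000L, fraction = 0.8,
                             max_retries = 100L, seed = 1L) {
  n_draws <- check_count(n_draws, "n_draws", min = 2L)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_config("fraction", "must lie strictly inside (0, 1)")
  }
  structure(list(n_draws = n_draws, fraction = fraction,
                 max_retries = check_count(max_retries, "max_retries", min = 0L),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "subsample_config")
}

#' Empirical t-statistic distributions under repeated subsampling
#'
#' For each draw, samples `fraction * n` participants of the (sub)group
#' without replacement, refits every unit's OLS model (frailty + scanner
#' dummies) on the subsample, and records the frailty t statistic. Draws
#' whose subsample is degenerate (constant outcome everywhere or a
#' rank-deficient design, e.g. a scanner level vanishing) are redrawn up to
#' `max_retries` times, then error.
#'
#' @param outcomes Participants x units matrix (regions or edges).
#' @param frailty,scanner Per-participant predictor and covariate.
#' @param subset Participant selector (e.g. one diagnostic group).
#' @param config A [subsample_config()].
#' @return Object of class `subsample_t`: `n_draws` x units matrix of t
#'   values with attributes `fraction`, `n_subsample`, `seed`.
#' @export
subsample_t_distribution <- function(outcomes, frailty, scanner = NULL,
                                     subset = NULL,
                                     config = subsample_config()) {
  Y <- as.matrix(outcomes)
  if (!is.null(subset)) {
    Y <- Y[subset, , drop = FALSE]
    frailty <- frailty[subset]
    if (!is.null(scanner)) scanner <- scanner[subset]
  }
  n <- nrow(Y)
  m <- floor(config$fraction * n)
  tmat <- matrix(NA_real_, config$n_draws, ncol(Y),
                 dimnames = list(NULL, colnames(Y)))
  for (d in seq_len(config$n_draws)) {
    set.seed(derive_seed(config$seed, d))
    for (try in 0:config$max_retries) {
      idx <- sample.int(n, m)
      st <- tryCatch({
        X <- build_design(frailty[idx],
                          if (is.null(scanner)) NULL else scanner[idx])
        ols_stats_matrix(Y[idx, , drop = FALSE], X)
      }, error = function(e) NULL)
      if (!is.null(st) && !all(st$degenerate)) break
      st <- NULL
    }
    if (is.null(st)) {
      stop(sprintf("draw %d: no non-degenerate subsample within %d retries",
                   d, config$max_retries), call. = FALSE)
    }
    tmat[d, ] <- st$t
  }
  structure(tmat, fraction = config$fraction, n_subsample = m,
            seed = config$seed, class = c("subsample_t", "matrix", "array"))
}

#' @export
print.subsample_t <- function(x, ...) {
  cat(sprintf(
    "Subsample t-distributions: %d draws x %d units (fraction %.2f, n per draw %d)\n",
    nrow(x), ncol(x), attr(x, "fraction"), attr(x, "n_subsample")))
  invisible(x)
}

#' Contrast two groups' subsampled t-distributions
#'
#' For every unit in the restriction set (conventionally: units with a
#' significant full-sample association in at least one of the two groups),
#' compares the two empirical t-distributions with a Welch two-sample
#' t-test, applies Benjamini-Hochberg correction across the restricted unit
#' family, and labels the dominant group (the one with the larger absolute
#' mean t) on significant units.
#'
#' @param t_a,t_b `subsample_t` matrices for groups A and B (same units).
#' @param restriction Character vector of unit names to analyze; `NULL`
#'   analyzes every shared unit. An empty restriction returns an empty
#'   result with a message.
#' @param labels Length-2 character vector naming groups A and B.
#' @return Object of class `contrast_result` (data frame): `unit`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `t`, `p`, `q`, `significant`, `dominant`.
#' @export
contrast_groups <- function(t_a, t_b, restriction = NULL,
                            labels = c("A", "B")) {
  units <- intersect(colnames(t_a), colnames(t_b))
  if (!is.null(restriction)) units <- intersect(units, restriction)
  if (!length(units)) {
    message("empty restriction set: no units to contrast")
    out <- data.frame(unit = character(), mean_a = numeric(),
                      sd_a = numeric(), mean_b = numeric(), sd_b = numeric(),
                      t = numeric(), p = numeric(), q = numeric(),
                      significant = logical(), dominant = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, labels = labels,
                     class = c("contrast_result", "data.frame")))
  }
  res <- lapply(units, function(u) {
    a <- t_a[, u]; b <- t_b[, u]
    if (isTRUE(all.equal(stats::sd(a - b), 0)) && stats::sd(a) == 0) {
      # identical constant distributions
      ht <- list(statistic = 0, p.value = 1)
    } else if (all(a == b)) {
      ht <- list(statistic = 0, p.value = 1)
    } else {
      ht <- stats::t.test(a, b)
    }
    data.frame(unit = u, mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               t = unname(ht$statistic), p = unname(ht$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < 0.05
  out$dominant <- ifelse(out$significant,
                         ifelse(abs(out$mean_a) >= abs(out$mean_b),
                                labels[1], labels[2]),
                         NA_character_)
  structure(out, labels = labels, n_draws = c(nrow(t_a), nrow(t_b)),
            class = c("contrast_result", "data.frame"))
}

#' @export
print.contrast_result <- function(x, ...) {
  labs <- attr(x, "labels")
  cat(sprintf("Subsampling contrast %s vs %s: %d units, %d significant (FDR < .05)\n",
              labs[1], labs[2], nrow(x), sum(x$significant)))
  if (!is.null(attr(x, "n_draws"))) {
    cat(sprintf("  n_draws: %d / %d (between-group t is on draw-sized samples)\n",
                attr(x, "n_draws")[1], attr(x, "n_draws")[2]))
  }
  invisible(x)
}

#' Restriction set for a pairwise subsampling contrast
#'
#' Units significantly associated with frailty in at least one of the two
#' groups' full-sample analyses.
#'
#' @param assoc_a,assoc_b `assoc_result` objects for the two groups.
#' @return Character vector of unit names.
#' @export
contrast_restriction <- function(assoc_a, assoc_b) {
  union(assoc_a$unit[assoc_a$significant], assoc_b$unit[assoc_b$significant])
}
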