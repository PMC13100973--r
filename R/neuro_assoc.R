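#' Fisher z-transformation of a correlation
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to ROI-to-ROI
#' correlations before edge-level modelling. Values within `1e-7` of ±1 are
#' clipped with a warning; values beyond ±1 are a domain error.
#'
#' @param r Numeric correlations, `|r| <= 1`.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlations must satisfy |r| <= 1", call. = FALSE)
  }
  clip <- !is.na(r) & abs(r) >= 1 - 1e-7
  if (any(clip)) {
    warning(sprintf("%d correlation(s) at |r| ~ 1 clipped before atanh",
                    sum(clip)))
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  atanh(r)
}

# Design matrix: intercept, frailty, scanner dummies (most frequent level as
# reference), optional extra covariates. Errors on rank deficiency, naming
# the offending columns.
build_design <- function(frailty, scanner = NULL, extra = NULL) {
  X <- cbind(`(Intercept)` = 1, frailty = frailty)
  if (!is.null(scanner)) {
    s <- droplevels(factor(scanner))
    if (nlevels(s) > 1) {
      ref <- names(which.max(table(s)))
      s <- stats::relevel(s, ref = ref)
      d <- stats::model.matrix(~s)[, -1, drop = FALSE]
      colnames(d) <- paste0("scanner_", levels(s)[-1])
      X <- cbind(X, d)
    }
  }
  if (!is.null(extra)) {
    extra <- as.matrix(as.data.frame(extra))
    if (is.null(colnames(extra))) {
      colnames(extra) <- sprintf("covariate_%d", seq_len(ncol(extra)))
    }
    X <- cbind(X, extra)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  X
}

# Shared-design mass-univariate OLS: one model per column of Y, vectorized
# through a single QR factorization. Returns per-column frailty t/p, model
# F p, adjusted R^2, and a degeneracy flag (constant outcome).
ols_stats_matrix <- function(Y, X) {
  n <- nrow(Y); p <- ncol(X)
  if (n <= p + 2) stop("too few observations for the design", call. = FALSE)
  qx <- qr(X)
  coef <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  rss <- colSums(res^2)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qx))
  j <- which(colnames(X) == "frailty")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- coef[j, ] / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  fstat <- ((tss - rss) / (p - 1)) / sigma2
  model_p <- stats::pf(fstat, p - 1, df_res, lower.tail = FALSE)
  adj_r2 <- 1 - (rss / df_res) / (tss / (n - 1))
  degenerate <- tss < n * 1e-20
  tval[degenerate] <- NA_real_; pval[degenerate] <- NA_real_
  model_p[degenerate] <- NA_real_; adj_r2[degenerate] <- NA_real_
  data.frame(unit = colnames(Y), slope = coef[j, ], t = tval, p = pval,
             adj_r2 = adj_r2, model_p = model_p, df = df_res,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

finalize_assoc <- function(stats_df, X, kind) {
  ok <- !stats_df$degenerate
  stats_df$model_q <- NA_real_
  stats_df$frailty_q <- NA_real_
  stats_df$model_q[ok] <- bh_adjust(stats_df$model_p[ok])
  stats_df$frailty_q[ok] <- bh_adjust(stats_df$p[ok])
  # Dual criterion: FDR-corrected model p and raw predictor p both < .05.
  stats_df$significant <- !is.na(stats_df$model_q) &
    stats_df$model_q < 0.05 & stats_df$p < 0.05
  if (any(stats_df$degenerate)) {
    message(sprintf("%d degenerate (constant) %s excluded from the FDR family",
                    sum(stats_df$degenerate), kind))
  }
  structure(stats_df, covariates = setdiff(colnames(X),
                                           c("(Intercept)", "frailty")),
            kind = kind, class = c("assoc_result", "data.frame"))
}

#' Per-region association of frailty with gray-matter volume
#'
#' Fits one ordinary-least-squares model per region: volume on frailty plus
#' dummy-coded scanner covariates (most frequent scanner as reference).
#' Per-model outputs are the frailty t and p, the model F p and adjusted R².
#' Model p values are Benjamini-Hochberg corrected across the region family;
#' a region is flagged significant when its FDR-corrected model p and its raw
#' frailty p are both below .05 (FDR-corrected frailty p is also emitted).
#' Constant-outcome regions are flagged degenerate and excluded from the FDR
#' family. Analyses are typically run within one diagnostic group via
#' `subset`.
#'
#' @param roi Participants x regions matrix (columns named).
#' @param frailty Numeric frailty index per participant.
#' @param scanner Scanner/site labels (optional; a single level reduces the
#'   model to frailty-only).
#' @param subset Logical or integer participant selector (e.g. one group).
#' @param extra Optional extra covariates (data frame/matrix), e.g. CDR or
#'   SNR for sensitivity re-runs.
#' @return Object of class `assoc_result` (data frame): `unit`, `slope`,
#'   `t`, `p`, `adj_r2`, `model_p`, `model_q`, `frailty_q`, `significant`,
#'   `degenerate`.
#' @export
fit_region_models <- function(roi, frailty, scanner = NULL, subset = NULL,
                              extra = NULL) {
  Y <- as.matrix(roi)
  if (!is.null(subset)) {
    Y <- Y[subset, , drop = FALSE]
    frailty <- frailty[subset]
    if (!is.null(scanner)) scanner <- scanner[subset]
    if (!is.null(extra)) extra <- as.data.frame(extra)[subset, , drop = FALSE]
  }
  X <- build_design(frailty, scanner, extra)
  finalize_assoc(ols_stats_matrix(Y, X), X, "regions")
}

#' Per-edge association of frailty with functional connectivity
#'
#' Same contract as [fit_region_models()], applied to the canonical
#' strict-upper-triangle edge matrix produced by [generate_connectivity()]
#' (or [edges_from_long()]); the diagonal is excluded by construction and the
#' FDR family is the edge family.
#'
#' @param edges Participants x edges matrix (columns `"regionA|regionB"`).
#' @inheritParams fit_region_models
#' @return An `assoc_result` over edges.
#' @export
fit_edge_models <- function(edges, frailty, scanner = NULL, subset = NULL,
                            extra = NULL) {
  pairs <- attr(edges, "pairs")
  res <- fit_region_models(edges, frailty, scanner, subset, extra)
  attr(res, "kind") <- "edges"
  attr(res, "pairs") <- pairs
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Mass-univariate frailty associations over %d %s\n",
              nrow(x), attr(x, "kind")))
  cat(sprintf("  covariates: %s\n",
              if (length(attr(x, "covariates"))) {
                paste(attr(x, "covariates"), collapse = ", ")
              } else "none"))
  cat(sprintf("  significant (model FDR p < .05 & frailty p < .05): %d\n",
              sum(x$significant)))
  if (any(x$significant)) {
    top <- x[x$significant, ]
    top <- top[order(-abs(top$t)), ][1, ]
    cat(sprintf("  strongest: %s (t = %.3f, adj R2 = %.3f)\n",
                top$unit, top$t, top$adj_r2))
  }
  invisible(x)
}

#' Convert long-format connectivity to the canonical edge matrix
#'
#' Canonicalizes edge identity to the unordered pair with regions sorted by
#' atlas index; rows giving both orientations must agree.
#'
#' @param long Data frame with columns `participant`, `region_i`, `region_j`,
#'   `z`.
#' @param regions Atlas region ordering (defines the canonical edge order).
#' @return Participants x edges matrix with a `"pairs"` attribute.
#' @export
edges_from_long <- function(long, regions = sort(unique(c(long$region_i,
                                                          long$region_j)))) {
  ii <- match(long$region_i, regions)
  jj <- match(long$region_j, regions)
  if (anyNA(ii) || anyNA(jj)) stop("unknown region names", call. = FALSE)
  if (any(ii == jj)) stop("self-edges are not analyzable", call. = FALSE)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  pairs <- edge_pairs(regions)
  col <- edge_index(a, b, length(regions))
  pid <- factor(long$participant, levels = unique(long$participant))
  m <- matrix(NA_real_, nlevels(pid), nrow(pairs),
              dimnames = list(levels(pid), pairs$name))
  key <- paste(as.integer(pid), col)
  if (anyDuplicated(key)) {
    rng <- tapply(long$z, key, function(v) diff(range(v)))
    if (any(rng > 1e-12)) {
      stop("asymmetric connectivity: the two orientations of an edge disagree",
           call. = FALSE)
    }
  }
  m[cbind(as.integer(pid), col)] <- long$z
  attr(m, "pairs") <- pairs
  m
}

#' Node-degree summary of significant edges
#'
#' Counts, for every region, how many significant edges touch it, tallied
#' separately by the sign of the frailty t statistic, and ranks regions by
#' total count (ties broken by region name).
#'
#' @param edge_results An `assoc_result` from [fit_edge_models()].
#' @param top_k Rows to mark in the `top` attribute (default 15).
#' @return Data frame `region`, `n_negative`, `n_positive`, `n_total`,
#'   sorted by `n_total` decreasing then region name; attribute `"top"`
#'   holds the first `top_k` region names.
#' @export
node_degree_summary <- function(edge_results, top_k = 15L) {
  pairs <- attr(edge_results, "pairs")
  regions <- if (!is.null(pairs)) {
    unique(c(pairs$region_i, pairs$region_j))
  } else {
    unique(unlist(strsplit(edge_results$unit, "|", fixed = TRUE)))
  }
  sig <- edge_results[edge_results$significant, , drop = FALSE]
  neg <- pos <- stats::setNames(integer(length(regions)), regions)
  for (i in seq_len(nrow(sig))) {
    ends <- strsplit(sig$unit[i], "|", fixed = TRUE)[[1]]
    if (sig$t[i] < 0) neg[ends] <- neg[ends] + 1L else pos[ends] <- pos[ends] + 1L
  }
  out <- data.frame(region = regions, n_negative = unname(neg),
                    n_positive = unname(pos),
                    n_total = unname(neg + pos), stringsAsFactors = FALSE)
  out <- out[order(-out$n_total, out$region), ]
  rownames(out) <- NULL
  structure(out, top = utils::head(out$region, top_k))
}

#' Sensitivity re-runs with an extended covariate set
#'
#' Re-estimates region or edge models with extra covariates (e.g. CDR total
#' score, structural and temporal SNR) appended to the scanner-adjusted
#' design, as in the circularity/quality sensitivity analyses.
#'
#' @param outcomes Participants x units matrix (regions or edges).
#' @inheritParams fit_region_models
#' @param extra Data frame of additional covariates (required here).
#' @return An `assoc_result`.
#' @export
adjusted_models <- function(outcomes, frailty, scanner = NULL, extra,
                            subset = NULL) {
  if (missing(extra) || is.null(extra)) {
    stop("adjusted_models requires extra covariates; use fit_region_models ",
         "for the scanner-only model", call. = FALSE)
  }
  res <- fit_region_models(outcomes, frailty, scanner, subset, extra)
  if (!is.null(attr(outcomes, "pairs"))) {
    attr(res, "kind") <- "edges"
    attr(res, "pairs") <- attr(outcomes, "pairs")
  }
  res
}
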