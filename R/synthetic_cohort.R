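#' Configure a synthetic clinical cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()] and the
#' individual `generate_*()` stages. The defaults emulate the published
#' three-group study design: cognitively unimpaired (CU, n = 1924, frailty
#' mean 0.14, SD 0.065), Alzheimer's disease (AD, n = 1126, 0.24, 0.075) and
#' frontotemporal lobar degeneration (FTLD, n = 411, 0.27, 0.10); 32 binary
#' health items spanning six domains whose per-group deficit probability
#' equals the group's mean frailty; region-of-interest (ROI) gray-matter
#' volumes that decline linearly in frailty with group-specific slopes plus
#' additive scanner offsets; and Fisher-z connectivity edges with edge-level
#' frailty slopes.
#'
#' @param group_specs Data frame with columns `group`, `n`, `mean`, `sd`
#'   (one row per diagnostic group).
#' @param n_items Number of binary health items (a warning is raised below 30,
#'   the conventional floor for a reliable deficit-accumulation index).
#' @param item_specs Optional data frame with columns `item`, `domain` and one
#'   `prob_<group>` column per group giving the per-item deficit probability.
#'   Defaults to probabilities equal to the group mean frailty for every item.
#' @param item_coupling `"independent"` (default) draws items independently
#'   given group; `"logistic"` shifts each item's logit by
#'   `coupling_strength` times the participant's within-group standardized
#'   latent frailty, so the computed index correlates with the latent score.
#' @param coupling_strength Logit shift per standard deviation of latent
#'   frailty under `"logistic"` coupling.
#' @param missing_rate Probability, in `[0, 1)`, that any item value is
#'   missing (completely at random).
#' @param n_regions Number of ROIs (default 116, labelled per [aal_regions()]).
#' @param roi_intercept,roi_sd Per-region volume intercept and residual SD
#'   (scalar or length-`n_regions`), in arbitrary TIV-adjusted volume units.
#' @param roi_slopes Per-group frailty slope on volume: a named vector (one
#'   value per group, recycled across regions) or an `n_regions x n_groups`
#'   matrix. Units: volume units per unit frailty. Default: `-1, -2, ...` in
#'   group order, i.e. CU -1 / AD -2 / FTLD -3.
#' @param n_scanners Number of scanner/site levels; participants are assigned
#'   uniformly at random.
#' @param scanner_offsets Additive volume offset per scanner (length
#'   `n_scanners`; first value conventionally 0 for the reference scanner).
#' @param edge_baseline,edge_sd Per-edge Fisher-z baseline and residual SD
#'   (scalar or length `n_regions*(n_regions-1)/2`, canonical upper-triangle
#'   order).
#' @param edge_slopes Per-group frailty slope on edge z values (named vector
#'   or `n_edges x n_groups` matrix). Default: `-0.1, -0.2, ...` in group
#'   order.
#' @param edge_spec_table Optional long-format edge specification
#'   (`region_i`, `region_j`, `baseline`, plus `slope_<group>` columns);
#'   pairs listed in both orientations must agree, otherwise an asymmetric
#'   specification error is raised.
#' @param seed Integer master seed; all generation stages derive their
#'   sub-seeds from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_specs = data.frame(
                            group = c("CU", "AD", "FTLD"),
                            n = c(1924L, 1126L, 411L),
                            mean = c(0.14, 0.24, 0.27),
                            sd = c(0.065, 0.075, 0.10)),
                          n_items = 32L,
                          item_specs = NULL,
                          item_coupling = c("independent", "logistic"),
                          coupling_strength = 1,
                          missing_rate = 0.02,
                          n_regions = 116L,
                          roi_intercept = 5,
                          roi_sd = 0.5,
                          roi_slopes = NULL,
                          n_scanners = 3L,
                          scanner_offsets = c(0, 0.2, -0.2),
                          edge_baseline = 0.3,
                          edge_sd = 0.2,
                          edge_slopes = NULL,
                          edge_spec_table = NULL,
                          seed = 1L) {
  item_coupling <- match.arg(item_coupling)
  stopifnot(is.data.frame(group_specs),
            all(c("group", "n", "mean", "sd") %in% names(group_specs)))
  if (anyDuplicated(group_specs$group)) {
    stop_config("group_specs", "has duplicated group labels")
  }
  check_count(group_specs$n, "group_specs$n")
  check_prob(group_specs$mean, "group_specs$mean")
  check_pos(group_specs$sd, "group_specs$sd")
  check_prob(missing_rate, "missing_rate", open_upper = TRUE)
  n_items <- check_count(n_items, "n_items")
  n_regions <- check_count(n_regions, "n_regions")
  n_scanners <- check_count(n_scanners, "n_scanners")
  seed <- check_count(seed, "seed", min = 0L)
  groups <- as.character(group_specs$group)
  k <- length(groups)

  if (is.null(item_specs)) {
    domains <- default_item_domains(n_items)
    item_specs <- data.frame(item = sprintf("item_%02d", seq_len(n_items)),
                             domain = domains,
                             sensitivity_tag = default_item_tags(domains),
                             stringsAsFactors = FALSE)
    for (g in groups) {
      item_specs[[paste0("prob_", g)]] <-
        rep(group_specs$mean[group_specs$group == g], n_items)
    }
  } else {
    need <- c("item", "domain", paste0("prob_", groups))
    if (!all(need %in% names(item_specs))) {
      stop_config("item_specs", paste("must contain columns",
                                      paste(need, collapse = ", ")))
    }
    n_items <- nrow(item_specs)
    for (g in groups) check_prob(item_specs[[paste0("prob_", g)]],
                                 paste0("item_specs$prob_", g))
  }

  # Default slopes grow with group order (CU/AD/FTLD -> -1/-2/-3 volume
  # units and -0.1/-0.2/-0.3 z units per unit frailty): disease groups carry
  # progressively stronger frailty-brain coupling.
  if (is.null(roi_slopes)) roi_slopes <- stats::setNames(-seq_len(k), groups)
  if (is.null(edge_slopes)) edge_slopes <- stats::setNames(-0.1 * seq_len(k), groups)

  regions <- aal_regions(n_regions)
  roi <- list(
    intercept = rep_len(check_pos(roi_intercept, "roi_intercept"), n_regions),
    sd        = rep_len(check_pos(roi_sd, "roi_sd"), n_regions),
    slopes    = expand_slopes(roi_slopes, n_regions, groups, "roi_slopes"))
  if (length(scanner_offsets) != n_scanners) {
    stop_config("scanner_offsets", "must have one entry per scanner")
  }

  n_edges <- n_regions * (n_regions - 1L) / 2L
  if (!is.null(edge_spec_table)) {
    es <- canonicalize_edge_spec(edge_spec_table, regions, groups)
    edge_baseline <- es$baseline
    edge_slopes <- es$slopes
    if (!is.null(es$sd)) edge_sd <- es$sd
  }
  edges <- list(
    baseline = rep_len(as.numeric(edge_baseline), n_edges),
    sd       = rep_len(check_pos(edge_sd, "edge_sd"), n_edges),
    slopes   = expand_slopes(edge_slopes, n_edges, groups, "edge_slopes"))

  structure(list(group_specs = group_specs, groups = groups,
                 item_specs = item_specs, n_items = n_items,
                 item_coupling = item_coupling,
                 coupling_strength = coupling_strength,
                 missing_rate = missing_rate,
                 regions = regions, n_regions = n_regions, roi = roi,
                 n_scanners = n_scanners, scanner_offsets = scanner_offsets,
                 n_edges = n_edges, edges = edges, seed = seed),
            class = "cohort_config")
}

default_item_domains <- function(n_items) {
  # Six domains mirroring the deficit-accumulation design: physical health,
  # health behaviors, global clinical status, neuropsychiatric symptoms,
  # cognition, functional ability.
  base <- c(rep("physical", 13), rep("behavior", 5), rep("global_status", 8),
            rep("neuropsychiatric", 3), "cognition", rep("function", 2))
  rep_len(base, n_items)
}

# Sensitivity tags for the default synthetic battery: the global-status
# block plays the role of the CDR, the cognition item of the MMSE, and the
# first two neuropsychiatric items of GAD-7 / GDS-SF, so index variants are
# exercisable on synthetic cohorts.
default_item_tags <- function(domains) {
  tags <- rep(NA_character_, length(domains))
  tags[domains == "global_status"] <- "CDR"
  tags[domains == "cognition"] <- "MMSE"
  np <- which(domains == "neuropsychiatric")
  if (length(np) >= 1) tags[np[1]] <- "GAD7"
  if (length(np) >= 2) tags[np[2]] <- "GDS_SF"
  tags
}

expand_slopes <- function(slopes, n_units, groups, field) {
  k <- length(groups)
  if (is.matrix(slopes)) {
    if (nrow(slopes) != n_units || ncol(slopes) != k) {
      stop_config(field, sprintf("matrix must be %d x %d", n_units, k))
    }
    colnames(slopes) <- groups
    return(slopes)
  }
  if (!is.null(names(slopes))) {
    if (!all(groups %in% names(slopes))) {
      stop_config(field, "named vector must cover every group")
    }
    slopes <- slopes[groups]
  } else {
    slopes <- rep_len(slopes, k)
  }
  matrix(rep(as.numeric(slopes), each = n_units), nrow = n_units,
         dimnames = list(NULL, groups))
}

canonicalize_edge_spec <- function(tab, regions, groups) {
  need <- c("region_i", "region_j", "baseline")
  if (!all(need %in% names(tab))) {
    stop_config("edge_spec_table", "needs region_i, region_j, baseline columns")
  }
  ii <- match(tab$region_i, regions)
  jj <- match(tab$region_j, regions)
  if (anyNA(ii) || anyNA(jj)) stop_config("edge_spec_table", "names unknown regions")
  if (any(ii == jj)) stop_config("edge_spec_table", "contains self-edges")
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  key <- paste(a, b)
  slope_cols <- paste0("slope_", groups)
  vals <- tab[, c("baseline", intersect(c(slope_cols, "sd"), names(tab))), drop = FALSE]
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      if (!all(vapply(vals, function(v) length(unique(v[rows])) == 1L, TRUE))) {
        stop_config("edge_spec_table",
                    "is asymmetric: the two orientations of a pair disagree")
      }
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]; vals <- vals[keep, , drop = FALSE]
  }
  n_reg <- length(regions)
  n_edges <- n_reg * (n_reg - 1L) / 2L
  idx <- edge_index(a, b, n_reg)
  if (length(idx) != n_edges || anyDuplicated(idx)) {
    stop_config("edge_spec_table", "must cover the full upper triangle exactly once")
  }
  ord <- order(idx)
  slopes <- sapply(slope_cols, function(cn) {
    if (!cn %in% names(vals)) stop_config("edge_spec_table", paste("missing", cn))
    vals[[cn]][ord]
  })
  list(baseline = vals$baseline[ord],
       slopes = matrix(slopes, ncol = length(groups),
                       dimnames = list(NULL, groups)),
       sd = if ("sd" %in% names(vals)) vals$sd[ord] else NULL)
}

# Canonical position of unordered pair (a < b) in the row-major strict upper
# triangle, 1-based: rows 1..a-1 contribute (n - i) entries each.
edge_index <- function(a, b, n) {
  (a - 1) * n - a * (a - 1) / 2 + (b - a)
}

edge_pairs <- function(regions) {
  n <- length(regions)
  a <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  b <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  data.frame(i = a, j = b,
             region_i = regions[a], region_j = regions[b],
             name = paste(regions[a], regions[b], sep = "|"),
             stringsAsFactors = FALSE)
}

#' Draw latent frailty scores per participant
#'
#' Samples each group's frailty scores from a normal distribution with the
#' configured mean and SD, truncated to `[0, 1]` by rejection sampling (so
#' the realized moments stay close to the configured ones rather than piling
#' mass at the boundaries, as clipping would).
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed override; defaults to the config's master seed.
#' @return Data frame with columns `id`, `group` (factor in config order) and
#'   `frailty`.
#' @export
generate_frailty_scores <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(seed, 0L))
  gs <- config$group_specs
  out <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i) {
    data.frame(group = gs$group[i],
               frailty = rtruncnorm01(gs$n[i], gs$mean[i], gs$sd[i]))
  }))
  out <- data.frame(id = sprintf("P%05d", seq_len(nrow(out))),
                    group = factor(out$group, levels = config$groups),
                    frailty = out$frailty, stringsAsFactors = FALSE)
  out
}

# Rejection sampler for N(mean, sd) truncated to [0, 1]. For the study's
# parameter range the acceptance rate is near 1, so the loop rarely iterates.
rtruncnorm01 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw >= 0 & draw <= 1])
  }
  out
}

#' Generate a binary health-item table
#'
#' Draws per-item binary deficits with per-group probabilities (optionally
#' shifted on the logit scale by the participant's standardized latent
#' frailty) and injects completely-at-random missingness.
#'
#' @inheritParams generate_frailty_scores
#' @param frailty_truth Data frame from [generate_frailty_scores()].
#' @return Data frame `id`, `group`, then one 0/1/NA column per item; item
#'   domains are attached as attribute `"domains"`.
#' @export
generate_item_table <- function(config, frailty_truth, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_items < 30) {
    warning("fewer than 30 health items: deficit-accumulation indexes are ",
            "conventionally built from at least 30 items for reliability")
  }
  set.seed(derive_seed(seed, 1L))
  n <- nrow(frailty_truth)
  grp <- as.character(frailty_truth$group)
  gs <- config$group_specs
  probs <- sapply(config$groups, function(g) {
    config$item_specs[[paste0("prob_", g)]]
  })  # n_items x n_groups
  p_mat <- t(probs[, match(grp, config$groups), drop = FALSE])  # n x n_items
  if (config$item_coupling == "logistic") {
    mu <- gs$mean[match(grp, gs$group)]
    sd <- gs$sd[match(grp, gs$group)]
    z <- (frailty_truth$frailty - mu) / sd
    eta <- stats::qlogis(pmin(pmax(p_mat, 1e-9), 1 - 1e-9)) +
      config$coupling_strength * z
    p_mat <- stats::plogis(eta)
    p_mat[, colSums(probs == 0) == ncol(probs)] <- 0  # structural zeros stay zero
  }
  items <- matrix(as.integer(stats::runif(n * config$n_items) < p_mat),
                  nrow = n)
  if (config$missing_rate > 0) {
    items[stats::runif(n * config$n_items) < config$missing_rate] <- NA_integer_
  }
  colnames(items) <- config$item_specs$item
  out <- cbind(frailty_truth[, c("id", "group")], as.data.frame(items))
  attr(out, "domains") <- stats::setNames(config$item_specs$domain,
                                          config$item_specs$item)
  if ("sensitivity_tag" %in% names(config$item_specs)) {
    attr(out, "sensitivity_tags") <- stats::setNames(
      config$item_specs$sensitivity_tag, config$item_specs$item)
  }
  out
}

#' Assign participants to scanners
#'
#' @inheritParams generate_item_table
#' @return Factor of scanner labels (`scanner_1`, ...), one per participant.
#' @export
generate_scanner_labels <- function(config, frailty_truth, seed = config$seed) {
  set.seed(derive_seed(seed, 2L))
  labs <- sprintf("scanner_%d", seq_len(config$n_scanners))
  factor(sample(labs, nrow(frailty_truth), replace = TRUE), levels = labs)
}

#' Generate ROI gray-matter volumes
#'
#' Each region's volume is `intercept + slope[group] * frailty +
#' scanner_offset + N(0, sd)`; the generative slopes are returned as attribute
#' `"truth"` so recovery tests never re-derive them.
#'
#' @inheritParams generate_item_table
#' @param scanner Factor from [generate_scanner_labels()].
#' @return Numeric matrix participants x regions with region column names.
#' @export
generate_roi_volumes <- function(config, frailty_truth, scanner,
                                 seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(seed, 3L))
  n <- nrow(frailty_truth)
  grp_idx <- match(as.character(frailty_truth$group), config$groups)
  slopes <- config$roi$slopes[, grp_idx, drop = FALSE]  # regions x n -> need t
  mu <- matrix(config$roi$intercept, n, config$n_regions, byrow = TRUE) +
    frailty_truth$frailty * t(slopes) +
    config$scanner_offsets[as.integer(scanner)]
  noise <- matrix(stats::rnorm(n * config$n_regions), n) *
    matrix(config$roi$sd, n, config$n_regions, byrow = TRUE)
  vol <- mu + noise
  colnames(vol) <- config$regions
  if (any(vol <= 0)) {
    warning("some generated ROI volumes are non-positive; ",
            "intercepts do not dominate the noise/slope scale")
  }
  attr(vol, "truth") <- list(slopes = config$roi$slopes,
                             intercept = config$roi$intercept,
                             scanner_offsets = config$scanner_offsets)
  vol
}

#' Generate per-participant connectivity edges
#'
#' Edge values are `baseline + slope[group] * frailty + N(0, sd)` on the
#' Fisher-z scale, stored as a participants x edges matrix over the canonical
#' strict upper triangle (columns named `"regionA|regionB"`). Use
#' [connectivity_matrix()] to expand one participant's row into the full
#' symmetric matrix.
#'
#' @inheritParams generate_item_table
#' @return Numeric matrix participants x edges with attribute `"pairs"` (the
#'   canonical edge table) and `"truth"` (generative slopes).
#' @export
generate_connectivity <- function(config, frailty_truth, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(seed, 4L))
  n <- nrow(frailty_truth)
  grp_idx <- match(as.character(frailty_truth$group), config$groups)
  slopes <- config$edges$slopes[, grp_idx, drop = FALSE]
  z <- matrix(config$edges$baseline, n, config$n_edges, byrow = TRUE) +
    frailty_truth$frailty * t(slopes) +
    matrix(stats::rnorm(n * config$n_edges), n) *
      matrix(config$edges$sd, n, config$n_edges, byrow = TRUE)
  pairs <- edge_pairs(config$regions)
  colnames(z) <- pairs$name
  attr(z, "pairs") <- pairs
  attr(z, "truth") <- list(slopes = config$edges$slopes,
                           baseline = config$edges$baseline)
  z
}

#' Expand one participant's edge row to a symmetric matrix
#'
#' @param edges Matrix from [generate_connectivity()] (or any matrix with a
#'   `"pairs"` attribute).
#' @param participant Row index or participant id.
#' @param diag Value to place on the (excluded-from-analysis) diagonal.
#' @return Symmetric numeric matrix regions x regions.
#' @export
connectivity_matrix <- function(edges, participant = 1L, diag = 0) {
  pairs <- attr(edges, "pairs")
  stopifnot(!is.null(pairs))
  if (is.character(participant)) participant <- match(participant, rownames(edges))
  regions <- unique(c(pairs$region_i, pairs$region_j))
  n <- length(regions)
  m <- matrix(diag, n, n, dimnames = list(regions, regions))
  v <- edges[participant, ]
  m[cbind(pairs$i, pairs$j)] <- v
  m[cbind(pairs$j, pairs$i)] <- v
  m
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generation stage under the config's master seed and bundles the
#' results with their ground-truth parameters.
#'
#' @param config A [cohort_config()].
#' @param connectivity Generate the edge matrix too? (It is the largest
#'   component; skip it when only items/volumes are needed.)
#' @return Object of class `frailty_cohort`: list with `participants`
#'   (id, group, frailty, scanner), `items`, `roi`, `edges` (or `NULL`),
#'   `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), connectivity = TRUE) {
  scores <- generate_frailty_scores(config)
  items <- generate_item_table(config, scores)
  scanner <- generate_scanner_labels(config, scores)
  roi <- generate_roi_volumes(config, scores, scanner)
  edges <- if (connectivity) generate_connectivity(config, scores) else NULL
  participants <- cbind(scores, scanner = scanner)
  structure(list(participants = participants, items = items, roi = roi,
                 edges = edges,
                 truth = list(roi = attr(roi, "truth"),
                              edges = if (!is.null(edges)) attr(edges, "truth")),
                 config = config),
            class = "frailty_cohort")
}

#' @export
print.frailty_cohort <- function(x, ...) {
  gs <- x$config$group_specs
  cat("Synthetic frailty cohort\n")
  cat(sprintf("  participants: %d (%s)\n", nrow(x$participants),
              paste(sprintf("%s n=%d", gs$group, gs$n), collapse = ", ")))
  cat(sprintf("  items: %d  regions: %d  edges: %s  scanners: %d  seed: %d\n",
              x$config$n_items, x$config$n_regions,
              if (is.null(x$edges)) "none" else ncol(x$edges),
              x$config$n_scanners, x$config$seed))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes the item table, ROI volumes and scanner labels as CSV, connectivity
#' as long-format CSV (`region_i`, `region_j`, `participant`, `z`), the
#' config as YAML and the ground truth as a JSON sidecar.
#'
#' @param cohort A `frailty_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(items = file.path(dir, "items.csv"),
             roi = file.path(dir, "roi_volumes.csv"),
             participants = file.path(dir, "participants.csv"),
             config = file.path(dir, "config.yaml"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(cohort$items, files["items"], row.names = FALSE)
  utils::write.csv(data.frame(id = cohort$participants$id, cohort$roi,
                              check.names = FALSE),
                   files["roi"], row.names = FALSE)
  utils::write.csv(cohort$participants, files["participants"], row.names = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(list(groups = cfg$group_specs, n_items = cfg$n_items,
                        missing_rate = cfg$missing_rate,
                        n_regions = cfg$n_regions,
                        n_scanners = cfg$n_scanners, seed = cfg$seed),
                   files["config"])
  jsonlite::write_json(cohort$truth, files["truth"], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(cohort$edges)) {
    pairs <- attr(cohort$edges, "pairs")
    long <- data.frame(
      participant = rep(cohort$participants$id, each = nrow(pairs)),
      region_i = rep(pairs$region_i, nrow(cohort$edges)),
      region_j = rep(pairs$region_j, nrow(cohort$edges)),
      z = as.vector(t(cohort$edges)))
    files <- c(files, edges = file.path(dir, "connectivity_long.csv"))
    utils::write.csv(long, files["edges"], row.names = FALSE)
  }
  invisible(files)
}
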