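#' Declare a health item and its binarization rule
#'
#' A deficit-accumulation index is built from binary deficits; raw clinical
#' variables must first be mapped to `{0 = no deficit, 1 = deficit, NA}`.
#' Rules are declarative so the mapping is auditable:
#'
#' * `"identity"` — value already 0/1; anything else becomes `NA` with a
#'   warning at binarization time.
#' * `"ge"` / `"le"` — deficit when `value >= cut` / `value <= cut`.
#'   Thresholds are closed on the deficit side: a value equal to the cut
#'   point is a deficit.
#' * `"outside"` — deficit when the value falls outside `[lower, upper]`
#'   (boundary values are healthy; deficit is `< lower` or `> upper`), e.g.
#'   resting heart rate outside 60–100.
#' * `"range"` — deficit when `value < lower` or `value >= upper` (used for
#'   BMI: deficit if `< 18.5` or `>= 30`).
#' * `"map"` — explicit lookup: `map` is a named vector from raw level to
#'   0/1; unlisted levels become `NA`.
#'
#' @param name Unique item name (must match a column of the raw table).
#' @param domain One of `physical`, `behavior`, `global_status`,
#'   `neuropsychiatric`, `cognition`, `function`.
#' @param kind Raw variable kind: `binary`, `continuous` or `ordinal`.
#' @param rule Rule type (above).
#' @param cut,lower,upper,map Rule parameters.
#' @param sensitivity_tag Optional tag (`CDR`, `MMSE`, `GAD7`, `GDS_SF`)
#'   marking the item for the sensitivity-analysis index variants.
#' @return Object of class `health_item_spec`.
#' @export
health_item_spec <- function(name, domain, kind = c("binary", "continuous", "ordinal"),
                             rule = c("identity", "ge", "le", "outside", "range", "map"),
                             cut = NULL, lower = NULL, upper = NULL, map = NULL,
                             sensitivity_tag = NULL) {
  kind <- match.arg(kind)
  rule <- match.arg(rule)
  domains <- c("physical", "behavior", "global_status", "neuropsychiatric",
               "cognition", "function")
  if (!domain %in% domains) {
    stop_config("domain", paste("must be one of", paste(domains, collapse = ", ")))
  }
  if (rule %in% c("ge", "le") && is.null(cut)) stop_config("cut", "is required")
  if (rule %in% c("outside", "range") && (is.null(lower) || is.null(upper))) {
    stop_config("lower/upper", "are required")
  }
  if (rule == "map" && (is.null(map) || is.null(names(map)))) {
    stop_config("map", "must be a named vector of 0/1 values")
  }
  if (!is.null(sensitivity_tag) &&
      !sensitivity_tag %in% c("CDR", "MMSE", "GAD7", "GDS_SF")) {
    stop_config("sensitivity_tag", "must be CDR, MMSE, GAD7 or GDS_SF")
  }
  structure(list(name = name, domain = domain, kind = kind, rule = rule,
                 cut = cut, lower = lower, upper = upper, map = map,
                 sensitivity_tag = sensitivity_tag),
            class = "health_item_spec")
}

apply_binarization <- function(spec, x) {
  out <- switch(spec$rule,
    identity = {
      bad <- !is.na(x) & !(x %in% c(0, 1))
      y <- as.numeric(x); y[bad] <- NA_real_
      if (any(bad)) warning(sprintf(
        "item '%s': %d value(s) outside {0,1} set to missing", spec$name, sum(bad)))
      y
    },
    ge = as.numeric(x >= spec$cut),
    le = as.numeric(x <= spec$cut),
    outside = as.numeric(x < spec$lower | x > spec$upper),
    range = as.numeric(x < spec$lower | x >= spec$upper),
    map = {
      y <- unname(spec$map[as.character(x)])
      if (any(!is.na(x) & is.na(y))) warning(sprintf(
        "item '%s': unmapped level(s) set to missing", spec$name))
      y
    })
  as.integer(out)
}

#' Default binarization map for the standard item battery
#'
#' Convenience defaults for common clinical instruments (BMI deficit if
#' < 18.5 or >= 30; systolic BP >= 140; diastolic BP >= 90; resting heart
#' rate outside 60–100; GDS-SF >= 5; GAD-7 >= 5; MMSE < 24 i.e. deficit when
#' <= 23; PFAQ >= 6; current smoking; any positive NPI-Q domain). These are
#' conveniences, not study facts: every analysis should state its own rule
#' set, and any item without a spec is a schema error in [binarize_items()].
#'
#' @return Named list of [health_item_spec()] objects.
#' @export
default_item_specs <- function() {
  sp <- list(
    health_item_spec("bmi", "physical", "continuous", "range",
                     lower = 18.5, upper = 30),
    health_item_spec("sbp", "physical", "continuous", "ge", cut = 140),
    health_item_spec("dbp", "physical", "continuous", "ge", cut = 90),
    health_item_spec("resting_hr", "physical", "continuous", "outside",
                     lower = 60, upper = 100),
    health_item_spec("hypertension", "physical", "binary", "identity"),
    health_item_spec("diabetes", "physical", "binary", "identity"),
    health_item_spec("dyslipidemia", "physical", "binary", "identity"),
    health_item_spec("visual_impairment", "physical", "ordinal", "map",
                     map = c(normal = 0, corrected = 0, impaired = 1)),
    health_item_spec("auditory_impairment", "physical", "ordinal", "map",
                     map = c(normal = 0, aid = 1, impaired = 1)),
    health_item_spec("n_diagnoses", "physical", "continuous", "ge", cut = 3),
    health_item_spec("n_medications", "physical", "continuous", "ge", cut = 5),
    health_item_spec("ever_smoked", "behavior", "binary", "identity"),
    health_item_spec("currently_smoking", "behavior", "binary", "identity"),
    health_item_spec("substance_abuse", "behavior", "binary", "identity"),
    health_item_spec("mmse", "cognition", "continuous", "le", cut = 23,
                     sensitivity_tag = "MMSE"),
    health_item_spec("gad7", "neuropsychiatric", "continuous", "ge", cut = 5,
                     sensitivity_tag = "GAD7"),
    health_item_spec("gds_sf", "neuropsychiatric", "continuous", "ge", cut = 5,
                     sensitivity_tag = "GDS_SF"),
    health_item_spec("pfaq", "function", "continuous", "ge", cut = 6))
  for (d in 1:8) {
    sp[[length(sp) + 1L]] <- health_item_spec(
      sprintf("cdr_domain_%d", d), "global_status", "continuous", "ge",
      cut = 0.5, sensitivity_tag = "CDR")
  }
  for (d in 1:3) {
    sp[[length(sp) + 1L]] <- health_item_spec(
      sprintf("npiq_domain_%d", d), "neuropsychiatric", "continuous", "ge",
      cut = 1)
  }
  sp[[length(sp) + 1L]] <- health_item_spec("tadlq_basic", "function",
                                            "continuous", "ge", cut = 2)
  sp[[length(sp) + 1L]] <- health_item_spec("tadlq_instrumental", "function",
                                            "continuous", "ge", cut = 10)
  sp[[length(sp) + 1L]] <- health_item_spec("tadlq_advanced", "function",
                                            "continuous", "ge", cut = 4)
  stats::setNames(sp, vapply(sp, `[[`, "", "name"))
}

#' Binarize raw health items
#'
#' Maps every raw item column to `{0, 1, NA}` using its declared rule.
#'
#' @param raw Data frame of raw item values (non-item columns such as `id`
#'   or `group` are carried through untouched if named in `id_cols`).
#' @param specs Named list of [health_item_spec()]s covering every item
#'   column; a column without a spec is a schema error.
#' @param id_cols Columns to pass through unchanged.
#' @return Data frame of 0/1/NA items (plus pass-through columns), with
#'   attributes `"domains"` and `"sensitivity_tags"`.
#' @export
binarize_items <- function(raw, specs, id_cols = intersect(c("id", "group"), names(raw))) {
  item_cols <- setdiff(names(raw), id_cols)
  missing_spec <- setdiff(item_cols, names(specs))
  if (length(missing_spec)) {
    stop(sprintf("schema error: no binarization spec for item(s): %s",
                 paste(missing_spec, collapse = ", ")), call. = FALSE)
  }
  out <- raw[, id_cols, drop = FALSE]
  for (nm in item_cols) out[[nm]] <- apply_binarization(specs[[nm]], raw[[nm]])
  attr(out, "domains") <- vapply(specs[item_cols], `[[`, "", "domain")
  tags <- lapply(specs[item_cols], `[[`, "sensitivity_tag")
  attr(out, "sensitivity_tags") <-
    vapply(tags, function(t) if (is.null(t)) NA_character_ else t, "")
  out
}

item_matrix <- function(deficits, id_cols = intersect(c("id", "group"), names(deficits))) {
  as.matrix(deficits[, setdiff(names(deficits), id_cols), drop = FALSE])
}

#' Screen health items before index construction
#'
#' Applies, in order: (1) missingness <= `max_missing`; (2) deficit prevalence
#' within `[min_prev, max_prev]` (items reported by < 1% or > 80% of
#' participants carry little deficit-accumulation information); (3) pairwise
#' Pearson correlation `|r| < max_r` on pairwise-complete 0/1 values, dropping
#' one item per offending pair (the one with more missing values; ties broken
#' by later spec order); (4) iterative variance-inflation-factor pruning,
#' dropping the max-VIF item while any VIF >= `max_vif` (computed on complete
#' cases).
#'
#' Every decision is recorded in a ledger with the statistic that triggered
#' it, so re-screening the retained set is a no-op.
#'
#' @param deficits Binary deficit table (from [binarize_items()] or a
#'   generator), id/group columns ignored.
#' @param max_missing,min_prev,max_prev,max_r,max_vif Screening thresholds.
#' @return Object of class `screening_ledger`: data frame with one row per
#'   input item (`item`, `prevalence`, `missing_frac`, `max_abs_r`,
#'   `r_partner`, `vif`, `decision`), with the retained item names in
#'   attribute `"retained"` (also via `retained_items()`).
#' @export
screen_items <- function(deficits, max_missing = 0.15, min_prev = 0.01,
                         max_prev = 0.80, max_r = 0.8, max_vif = 10) {
  m <- item_matrix(deficits)
  if (ncol(m) < 2) stop("screening requires at least 2 items", call. = FALSE)
  items <- colnames(m)
  n <- nrow(m)
  missing_frac <- colMeans(is.na(m))
  prevalence <- colMeans(m, na.rm = TRUE)
  decision <- rep("kept", ncol(m))
  names(decision) <- items

  decision[missing_frac > max_missing] <- "dropped_missing"
  live <- decision == "kept"
  decision[live & prevalence < min_prev] <- "dropped_rare"
  live <- decision == "kept"
  decision[live & prevalence > max_prev] <- "dropped_common"

  # Pairwise correlation screen on the survivors, pairwise-complete Pearson.
  live <- which(decision == "kept")
  max_abs_r <- rep(NA_real_, ncol(m))
  r_partner <- rep(NA_character_, ncol(m))
  if (length(live) >= 2) {
    cr <- suppressWarnings(stats::cor(m[, live, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    diag(cr) <- 0
    cr[is.na(cr)] <- 0
    max_abs_r[live] <- apply(abs(cr), 1, max)
    r_partner[live] <- colnames(cr)[apply(abs(cr), 1, which.max)]
    repeat {
      off <- which(abs(cr) >= max_r, arr.ind = TRUE)
      if (!nrow(off)) break
      off <- off[off[, 1] < off[, 2], , drop = FALSE]
      pair <- colnames(cr)[off[1, ]]
      # Drop the member with more missing values; tie -> later spec order.
      miss <- missing_frac[pair]
      drop_nm <- if (miss[1] != miss[2]) pair[which.max(miss)] else pair[2]
      decision[drop_nm] <- "dropped_correlated"
      keep <- setdiff(colnames(cr), drop_nm)
      if (length(keep) < 2) break
      cr <- cr[keep, keep, drop = FALSE]
    }
  }

  # Iterative VIF on complete cases of the remaining items.
  vif <- rep(NA_real_, ncol(m))
  names(vif) <- items
  repeat {
    live <- which(decision == "kept")
    if (length(live) < 2) break
    v <- compute_vif(m[, live, drop = FALSE])
    vif[live] <- v
    if (all(is.na(v)) || max(v, na.rm = TRUE) < max_vif) break
    decision[names(which.max(v))] <- "dropped_vif"
  }

  if (!any(decision == "kept")) {
    stop("screening dropped every item; no frailty index can be built",
         call. = FALSE)
  }
  ledger <- data.frame(item = items, prevalence = prevalence,
                       missing_frac = missing_frac, max_abs_r = max_abs_r,
                       r_partner = r_partner, vif = unname(vif),
                       decision = unname(decision),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(ledger, retained = items[decision == "kept"],
            thresholds = c(max_missing = max_missing, min_prev = min_prev,
                           max_prev = max_prev, max_r = max_r,
                           max_vif = max_vif),
            class = c("screening_ledger", "data.frame"))
}

# VIF_j = 1 / (1 - R^2_j) of item j regressed on the others, complete cases.
# Computed via the inverse correlation matrix; a numerically singular set
# yields Inf for the implicated items.
compute_vif <- function(m) {
  cc <- stats::complete.cases(m)
  mm <- m[cc, , drop = FALSE]
  sds <- apply(mm, 2, stats::sd)
  out <- rep(NA_real_, ncol(m))
  names(out) <- colnames(m)
  use <- sds > 0
  if (sum(use) < 2) return(out)
  cr <- stats::cor(mm[, use, drop = FALSE])
  inv <- tryCatch(solve(cr), error = function(e) NULL)
  out[use] <- if (is.null(inv)) Inf else diag(inv)
  out
}

#' @export
print.screening_ledger <- function(x, ...) {
  kept <- attr(x, "retained")
  cat(sprintf("Item screening ledger: %d items, %d retained\n",
              nrow(x), length(kept)))
  tab <- table(x$decision)
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Retained items after screening
#' @param ledger A `screening_ledger`.
#' @return Character vector of retained item names.
#' @export
retained_items <- function(ledger) attr(ledger, "retained")

#' Write a screening ledger to CSV and JSON
#' @param ledger A `screening_ledger`.
#' @param path Base path (writes `<path>.csv` and `<path>.json`).
#' @export
write_screening_ledger <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), paste0(path, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(thresholds = as.list(attr(ledger, "thresholds")),
                            retained = attr(ledger, "retained"),
                            ledger = as.data.frame(ledger)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(path, ".csv"), paste0(path, ".json")))
}

#' Compute the deficit-accumulation frailty index
#'
#' Each participant's index is the number of deficits present divided by the
#' number of items *observed* (missing items shrink the denominator, they are
#' not imputed). Participants observing fewer than `min_complete` of the item
#' set get no index (`included = FALSE`).
#'
#' @param deficits Binary deficit table.
#' @param items Item names to score over (e.g. [retained_items()] of a
#'   screening ledger); defaults to every item column.
#' @param min_complete Minimum fraction of items observed (default 0.8).
#' @param variant Label recorded on the result (e.g. `"full"`).
#' @return Object of class `frailty_result`: data frame with `id` (if
#'   present), `index`, `n_observed`, `n_items`, `included`, `variant`.
#' @export
compute_frailty_index <- function(deficits, items = NULL, min_complete = 0.8,
                                  variant = "full") {
  m <- item_matrix(deficits)
  if (!is.null(items)) {
    unknown <- setdiff(items, colnames(m))
    if (length(unknown)) {
      stop(sprintf("unknown item(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    m <- m[, items, drop = FALSE]
  }
  if (ncol(m) < 1) stop("at least one item is required", call. = FALSE)
  n_obs <- rowSums(!is.na(m))
  idx <- ifelse(n_obs > 0, rowSums(m, na.rm = TRUE) / n_obs, NA_real_)
  included <- n_obs / ncol(m) >= min_complete
  idx[!included] <- NA_real_
  out <- data.frame(index = idx, n_observed = n_obs, n_items = ncol(m),
                    included = included, variant = variant,
                    stringsAsFactors = FALSE)
  if ("id" %in% names(deficits)) out <- cbind(deficits["id"], out)
  if ("group" %in% names(deficits)) out$group <- deficits$group
  structure(out, items = colnames(m),
            class = c("frailty_result", "data.frame"))
}

#' @export
print.frailty_result <- function(x, ...) {
  cat(sprintf("Frailty index ('%s' variant): %d participants, %d items, %d scored\n",
              x$variant[1], nrow(x), x$n_items[1], sum(x$included)))
  if (any(x$included)) {
    cat(sprintf("  index mean %.3f, range [%.3f, %.3f]\n",
                mean(x$index[x$included]), min(x$index[x$included]),
                max(x$index[x$included])))
  }
  invisible(x)
}

#' @export
summary.frailty_result <- function(object, ...) {
  if ("group" %in% names(object)) {
    scored <- object[object$included, ]
    agg <- stats::aggregate(index ~ group, data = scored,
                            FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                                n = length(v)))
    out <- do.call(data.frame, agg)
    names(out) <- c("group", "mean", "sd", "n")
    out
  } else {
    summary(object$index)
  }
}

#' Sensitivity-analysis frailty index variants
#'
#' Recomputes the index over the item set minus the items carrying the given
#' sensitivity tags (`CDR`; `CDR`+`MMSE`; `CDR`+`MMSE`+`GAD7`+`GDS_SF`), the
#' standard guard against circularity when the index is used to classify
#' diagnoses that are themselves defined through those instruments. The
#' completeness gate applies to the reduced denominator.
#'
#' @param deficits Binary deficit table carrying a `"sensitivity_tags"`
#'   attribute (as produced by [binarize_items()]), or provide `tags`.
#' @param exclude Character vector of tags to exclude (subset of
#'   `CDR`, `MMSE`, `GAD7`, `GDS_SF`); empty means the full index.
#' @param items Optional base item set (defaults to all item columns).
#' @param tags Optional named character vector item -> tag (NA = untagged).
#' @param min_complete Completeness gate, as in [compute_frailty_index()].
#' @return A `frailty_result` with `variant` naming the exclusion set.
#' @export
variant_index <- function(deficits, exclude = character(), items = NULL,
                          tags = attr(deficits, "sensitivity_tags"),
                          min_complete = 0.8) {
  valid <- c("CDR", "MMSE", "GAD7", "GDS_SF")
  if (length(exclude) && !all(exclude %in% valid)) {
    stop_config("exclude", paste("contains unknown tag(s):",
                                 paste(setdiff(exclude, valid), collapse = ", ")))
  }
  if (is.null(items)) items <- colnames(item_matrix(deficits))
  if (length(exclude)) {
    if (is.null(tags)) {
      stop_config("tags", "are required to resolve the exclusion set")
    }
    drop <- names(tags)[!is.na(tags) & tags %in% exclude]
    items <- setdiff(items, drop)
    if (!length(items)) stop("exclusion removed every item", call. = FALSE)
  }
  label <- if (length(exclude)) paste0("minus_", paste(exclude, collapse = "_"))
           else "full"
  compute_frailty_index(deficits, items = items, min_complete = min_complete,
                        variant = label)
}
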