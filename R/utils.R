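#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing configuration errors name the
# offending field so that pipeline failures are actionable.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open_upper = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_config(field, "must be numeric and non-missing")
  hi <- if (open_upper) all(x < 1) else all(x <= 1)
  if (!(all(x >= 0) && hi)) {
    stop_config(field, sprintf("must lie in [0, 1%s", if (open_upper) ")" else "]"))
  }
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_config(field, "must be numeric and non-missing")
  if (strict && any(x <= 0)) stop_config(field, "must be > 0")
  if (!strict && any(x < 0)) stop_config(field, "must be >= 0")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || anyNA(x) || any(x != floor(x)) || any(x < min)) {
    stop_config(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

# Seed arithmetic stays within 32-bit integer range; sub-stage seeds are
# derived from a master seed by small fixed offsets so stages are individually
# reproducible.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# Benjamini-Hochberg wrapper kept in one place so every FDR family in the
# package goes through the same call.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
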