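#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# classed conditions so callers can distinguish malformed files from bad values
format_error <- function(msg, ...) {
  abort(msg, class = "interologr_format_error", ...)
}

validation_error <- function(msg, ...) {
  abort(msg, class = "interologr_validation_error", ...)
}

# case-insensitive fixed-substring match of `patterns` against `x`;
# returns logical along x. Empty pattern list matches nothing.
matches_any_pattern <- function(x, patterns) {
  if (length(patterns) == 0) {
    return(rep(FALSE, length(x)))
  }
  xl <- tolower(x)
  out <- rep(FALSE, length(x))
  for (p in patterns) {
    out <- out | grepl(tolower(p), xl, fixed = TRUE)
  }
  out
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    format_error(sprintf("file does not exist: %s", path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(tab))
  if (length(missing) > 0) {
    format_error(sprintf(
      "%s: missing required column(s): %s", path,
      paste(missing, collapse = ", ")
    ))
  }
  tab
}

write_tsv_plain <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

check_count_int <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    validation_error(sprintf("%s must be a single non-negative integer", what))
  }
  as.integer(x)
}

check_fraction <- function(x, what, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= lo || x > hi) {
    validation_error(sprintf("%s must be in (%g, %g]", what, lo, hi))
  }
  as.numeric(x)
}
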