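#' Round half-up
#'
#' Rounds `x` to `digits` decimal places with halves rounded away from zero
#' (towards `+Inf` for the non-negative quantities used here), the convention
#' under which every percentage printed by the reporting routines is
#' reproducible (e.g. 692/710 = 97.4647 -> 97.5 at one decimal). This is the
#' single rounding routine shared by all tables so that trigger shares,
#' agreement percentages and cross-tab percentages follow one convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the table convention).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(97.4647)   # 97.5
#' round_half_up(88.3099)   # 88.3
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Format a percentage for display
#'
#' Percentages are computed by rounding to one decimal ([round_half_up]) and
#' rendered with two decimals (trailing zero), e.g. 97.5 -> "97.50".
#'
#' @param x numeric percentage.
#' @return character vector.
#' @export
format_percent <- function(x) sprintf("%.2f", round_half_up(x, 1))

# ---- timestamps ------------------------------------------------------------
# All times are ISO-8601 with an explicit numeric offset; comparisons happen
# in absolute time (POSIXct, stored UTC) so the 24 h return-call window is
# unambiguous across offsets.

ts_format <- "%Y-%m-%dT%H:%M:%S%z"

parse_ts <- function(x) {
  if (inherits(x, "POSIXt")) {
    x <- as.POSIXct(x)
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, ts_format, tz = "UTC"))
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable ISO-8601 timestamp(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  out
}

format_ts <- function(t) {
  ifelse(is.na(t), NA_character_, format(t, ts_format, tz = "UTC"))
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive independent sub-seeds from one master seed (one stream per purpose:
# cohort construction, trigger planting/labels, reviewer simulation, sampling)
# so that e.g. changing the reviewer error rate does not perturb the cohort.
derive_seeds <- function(seed, n = 4L) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# NA-tolerant element-wise equality: NA == NA counts as agreement.
eq_na <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
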