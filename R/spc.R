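# Outcome measures per 10,000 patient encounters and U-chart statistical
# process control with Nelson-rule special-cause detection.
#
# With n_i = encounters_i / 10,000 exposure units per period:
#   u_i     = count_i / n_i                    (events per 10,000 encounters)
#   u_bar   = sum(count) / sum(n)              (center line)
#   sigma_i = sqrt(u_bar / n_i)                (per-period standard error)
#   UCL_i   = u_bar + 3 sigma_i,  LCL_i = max(0, u_bar - 3 sigma_i)
# Limits vary per point with the encounter denominator, the standard
# treatment for U-charts with unequal subgroup sizes; Nelson-rule zones use
# each point's own sigma_i.

#' Events per 10,000 patient encounters
#'
#' @param count non-negative event count(s).
#' @param encounters positive patient-encounter denominator(s).
#' @return `10000 * count / encounters`.
#' @export
rate_per_10k <- function(count, encounters) {
  if (any(encounters <= 0)) stop("rate_per_10k: encounters must be positive",
                                 call. = FALSE)
  if (any(count < 0)) stop("rate_per_10k: negative count", call. = FALSE)
  10000 * count / encounters
}

#' Modified adverse-event count
#'
#' The modified adverse-event measure pools adverse events and harm events
#' into a single count, aligning with the usage in which "adverse event"
#' and "harm" are read interchangeably.
#'
#' @param ae_count,harm_count non-negative counts.
#' @return `ae_count + harm_count`.
#' @export
modified_ae_count <- function(ae_count, harm_count) {
  if (any(ae_count < 0) || any(harm_count < 0))
    stop("modified_ae_count: negative count", call. = FALSE)
  ae_count + harm_count
}

#' Build a U-chart
#'
#' @param periods data frame with columns `period_id`, `count` (events found
#'   in the period) and `encounters` (the period's total patient
#'   encounters); at least two periods.
#' @return an object of class `"u_chart"`: `data` (per-period `u`, `sigma`,
#'   `ucl`, `lcl`) and `center` (u_bar). Inspect special-cause signals with
#'   [nelson_violations()]; `plot()` draws the chart.
#' @export
build_u_chart <- function(periods) {
  stopifnot(is.data.frame(periods),
            all(c("period_id", "count", "encounters") %in% names(periods)))
  if (nrow(periods) < 2) stop("build_u_chart: need at least 2 periods",
                              call. = FALSE)
  if (any(periods$encounters <= 0))
    stop("build_u_chart: encounters must be positive", call. = FALSE)
  if (any(periods$count < 0))
    stop("build_u_chart: negative count", call. = FALSE)
  n <- periods$encounters / 10000
  u <- periods$count / n
  u_bar <- sum(periods$count) / sum(n)
  sigma <- sqrt(u_bar / n)
  d <- data.frame(
    period_id = as.character(periods$period_id),
    count = periods$count,
    encounters = periods$encounters,
    u = u, sigma = sigma,
    ucl = u_bar + 3 * sigma,
    lcl = pmax(0, u_bar - 3 * sigma),
    stringsAsFactors = FALSE
  )
  structure(list(data = d, center = u_bar), class = "u_chart")
}

#' @export
print.u_chart <- function(x, ...) {
  viol <- nelson_violations(x)
  cat(sprintf("<u_chart> %d periods, center %.4g per 10,000; %d Nelson signal(s)\n",
              nrow(x$data), x$center, nrow(viol)))
  if (nrow(viol))
    cat("  rules fired:", paste(sprintf("rule %d @ %s", viol$rule,
                                        viol$period_id), collapse = "; "),
        "\n")
  invisible(x)
}

#' @export
summary.u_chart <- function(object, ...) {
  list(center = object$center, data = object$data,
       violations = nelson_violations(object))
}

#' @export
plot.u_chart <- function(x, main = "U chart", ylab = "events per 10,000 encounters",
                         ...) {
  d <- x$data
  i <- seq_len(nrow(d))
  graphics::plot(i, d$u, type = "b", pch = 16, xaxt = "n", xlab = "period",
                 ylab = ylab, main = main,
                 ylim = range(0, d$u, d$ucl, na.rm = TRUE), ...)
  graphics::axis(1, at = i, labels = d$period_id, las = 2, cex.axis = 0.6)
  graphics::lines(i, d$ucl, lty = 2, type = "s")
  graphics::lines(i, d$lcl, lty = 2, type = "s")
  graphics::abline(h = x$center, lty = 1, col = "grey40")
  viol <- nelson_violations(x)
  if (nrow(viol))
    graphics::points(viol$index, d$u[viol$index], col = "red", pch = 1,
                     cex = 2)
  invisible(x)
}

roll_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# final point of every maximal violating window, deduplicated per rule:
# keep a minimal-window end index only if the next index is not also one.
collapse_runs <- function(ends) ends[!(ends + 1) %in% ends]

#' Nelson-rule special-cause signals on a U-chart
#'
#' Evaluates the eight Nelson rules using per-point zones at
#' `u_bar +/- k * sigma_i` (k = 1, 2, 3): (1) one point beyond 3 sigma;
#' (2) nine consecutive points on one side of the center; (3) six
#' consecutive strictly increasing or decreasing; (4) fourteen consecutive
#' alternating up/down; (5) two of three consecutive beyond 2 sigma on the
#' same side; (6) four of five consecutive beyond 1 sigma on the same side;
#' (7) fifteen consecutive within 1 sigma; (8) eight consecutive beyond
#' 1 sigma with none within. Each maximal violating window is reported by
#' its final point, deduplicated per rule.
#'
#' @param chart a [build_u_chart()] object.
#' @param rules subset of 1:8 to evaluate.
#' @return data frame with columns `rule`, `index`, `period_id`.
#' @export
nelson_violations <- function(chart, rules = 1:8) {
  d <- chart$data
  u <- d$u
  m <- nrow(d)
  z <- ifelse(d$sigma > 0, (u - chart$center) / d$sigma, 0)
  ends <- function(flags, w) {
    if (length(flags) < w) return(integer(0))
    which(roll_sum(as.numeric(flags), w) == w) + w - 1L
  }
  res <- list()
  add <- function(rule, idx) {
    idx <- collapse_runs(idx)
    if (length(idx))
      res[[length(res) + 1]] <<- data.frame(rule = rule, index = idx,
                                            period_id = d$period_id[idx],
                                            stringsAsFactors = FALSE)
  }
  if (1 %in% rules) add(1L, which(abs(z) > 3))
  if (2 %in% rules) add(2L, c(ends(z > 0, 9), ends(z < 0, 9)))
  if (3 %in% rules && m >= 6) {
    dd <- diff(u)
    add(3L, c(ends(dd > 0, 5), ends(dd < 0, 5)) + 1L)
  }
  if (4 %in% rules && m >= 14) {
    dd <- diff(u)
    alt <- dd[-1] * dd[-length(dd)] < 0  # consecutive diffs of opposite sign
    add(4L, ends(alt, 12) + 2L)
  }
  if (5 %in% rules && m >= 3) {
    hi <- roll_sum(as.numeric(z > 2), 3) >= 2
    lo <- roll_sum(as.numeric(z < -2), 3) >= 2
    add(5L, c(which(hi), which(lo)) + 2L)
  }
  if (6 %in% rules && m >= 5) {
    hi <- roll_sum(as.numeric(z > 1), 5) >= 4
    lo <- roll_sum(as.numeric(z < -1), 5) >= 4
    add(6L, c(which(hi), which(lo)) + 4L)
  }
  if (7 %in% rules) add(7L, ends(abs(z) < 1, 15))
  if (8 %in% rules) add(8L, ends(abs(z) > 1, 8))
  if (!length(res))
    return(data.frame(rule = integer(), index = integer(),
                      period_id = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$rule, out$index), , drop = FALSE]
  out <- out[!duplicated(out[c("rule", "index")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled outcome rates per 10,000 patient encounters
#'
#' Pools each measure over periods: `10000 * sum(count) / sum(encounters)`.
#' The modified adverse-event rate pools [modified_ae_count()] of the
#' adverse-event and harm counts. All measures must share the same period
#' set and denominators.
#'
#' @param measures named list of per-measure period data frames
#'   (`period_id`, `count`, `encounters`), with at least `triggers`, `ae`
#'   and `harm`.
#' @return named numeric vector: `triggers`, `ae`, `harm`, `modified_ae`.
#' @export
overall_rates <- function(measures) {
  stopifnot(all(c("triggers", "ae", "harm") %in% names(measures)))
  ref <- measures[[1]][c("period_id", "encounters")]
  for (m in names(measures)) {
    cur <- measures[[m]]
    if (!identical(as.character(cur$period_id), as.character(ref$period_id)) ||
        !identical(as.numeric(cur$encounters), as.numeric(ref$encounters)))
      stop("overall_rates: period ids/denominators differ across measures (",
           m, ")", call. = FALSE)
  }
  pooled <- function(df) rate_per_10k(sum(df$count), sum(df$encounters))
  c(
    triggers = pooled(measures$triggers),
    ae = pooled(measures$ae),
    harm = pooled(measures$harm),
    modified_ae = rate_per_10k(
      modified_ae_count(sum(measures$ae$count), sum(measures$harm$count)),
      sum(measures$ae$encounters))
  )
}
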