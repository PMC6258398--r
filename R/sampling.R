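# Biweekly review sampling: exclusion filtering and the 30-drawn /
# 20-reviewed / 10-spare sample design.

#' Partition records by exclusion criteria
#'
#' A record is excluded iff it carries at least one exclusion flag
#' (care-pathway case, high-risk procedure or medication, infrequent
#' procedure, inter-facility transport); the reason lists the flags.
#'
#' @param records list of `"pcr"` records.
#' @return list with `eligible` (list of records) and `excluded` (data frame
#'   of `record_id`, `reason`).
#' @export
apply_exclusions <- function(records) {
  flagged <- vapply(records, function(r) length(r$exclusion_flags) > 0,
                    logical(1))
  excluded <- data.frame(
    record_id = vapply(records[flagged], function(r) r$record_id,
                       character(1)),
    reason = vapply(records[flagged], function(r)
      paste(r$exclusion_flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  list(eligible = records[!flagged], excluded = excluded)
}

#' Draw a biweekly review sample
#'
#' Draws 30 records (or all, if fewer are eligible) uniformly without
#' replacement, deterministically from the given seed (a seeded PRNG
#' permutation standing in for the study's physical random number table; the
#' seed is recorded in the batch for audit). The review set is the first 20
#' drawn; any of those found excludable after the draw is replaced, in
#' order, by the spares in positions 21-30. If fewer than 20 reviewable
#' records remain after exhausting the spares, the shortfall is recorded as
#' a warning in the batch.
#'
#' @param eligible list of `"pcr"` records restricted to the period.
#' @param period_id period label (e.g. `"2016-03-H1"`).
#' @param seed integer seed for the draw.
#' @param n_drawn,n_review sample design sizes (default 30 drawn, 20
#'   reviewed).
#' @return an object of class `"sample_batch"`: `period_id`, `drawn`
#'   (ordered record ids), `review_set` (ordered record ids, at most
#'   `n_review`), `spares_used`, `seed`, `warning`.
#' @export
draw_sample <- function(eligible, period_id, seed, n_drawn = 30,
                        n_review = 20) {
  n <- length(eligible)
  if (n < 1) stop("draw_sample: no eligible records for period ", period_id,
                  call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  take <- perm[seq_len(min(n_drawn, n))]
  drawn <- eligible[take]
  ids <- vapply(drawn, function(r) r$record_id, character(1))
  # post-draw exclusion discovery: skip flagged members, pulling spares in order
  flagged <- vapply(drawn, function(r) length(r$exclusion_flags) > 0,
                    logical(1))
  ok_pos <- which(!flagged)
  review_pos <- utils::head(ok_pos, n_review)
  spares_used <- sum(review_pos > n_review)
  warn <- NULL
  if (length(review_pos) < n_review)
    warn <- sprintf(
      "period %s: only %d reviewable record(s) after exhausting spares (wanted %d)",
      period_id, length(review_pos), n_review)
  structure(list(
    period_id = period_id,
    drawn = ids,
    review_set = ids[review_pos],
    spares_used = spares_used,
    seed = seed,
    warning = warn
  ), class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("<sample_batch %s> %d drawn, %d in review set, %d spare(s) used (seed %s)\n",
              x$period_id, length(x$drawn), length(x$review_set),
              x$spares_used, format(x$seed)))
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  invisible(x)
}
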