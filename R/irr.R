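# Dual-reviewer consensus and inter-rater reliability.
#
# Percent agreement is computed by rounding to ONE decimal (half-up) and
# displayed with two decimals: the published convention under which 692/710
# prints as 97.50 and 670/710 as 94.40. Cohen's kappa is computed over the
# full paired decision vector (including trigger-negative cases) and returns
# a typed "undefined" sentinel - never a silent zero - when expected
# agreement is 1 (no category variation in either rater).

#' Undefined-kappa sentinel
#'
#' Cohen's kappa is undefined when expected agreement is 1, i.e. both raters
#' are constant (for example, both reviewers calling every case negative).
#' [cohens_kappa()] then returns this typed sentinel: an `NA` carrying class
#' `"kappa_undefined"`, test it with [is_kappa_undefined()].
#'
#' @return the sentinel value.
#' @export
kappa_undefined <- function() {
  structure(NA_real_, class = c("kappa_undefined", "numeric"))
}

#' @rdname kappa_undefined
#' @param x object to test.
#' @export
is_kappa_undefined <- function(x) inherits(x, "kappa_undefined")

#' Percent agreement between two raters
#'
#' `100 * (number of equal positions) / length`, rounded half-up to one
#' decimal. `NA` in both raters counts as agreement (an absent
#' classification both reviewers left absent is a concordant decision).
#'
#' @param v1,v2 equal-length vectors of paired decisions (logical or
#'   categorical).
#' @return percent agreement at one-decimal precision (render with
#'   [format_percent()] for the two-decimal display form).
#' @export
percent_agreement <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("percent_agreement: length mismatch",
                                     call. = FALSE)
  if (!length(v1)) stop("percent_agreement: empty vectors", call. = FALSE)
  round_half_up(100 * mean(eq_na(v1, v2)), 1)
}

#' Cohen's kappa
#'
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and expected
#' agreement p_e the sum over categories of the product of the two raters'
#' marginal proportions. When p_e = 1 (both raters constant) kappa is
#' undefined and the [kappa_undefined()] sentinel is returned.
#'
#' @param v1,v2 equal-length categorical vectors; `NA` is treated as its own
#'   category (an absent classification).
#' @return numeric kappa, or the undefined sentinel.
#' @export
cohens_kappa <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("cohens_kappa: length mismatch",
                                     call. = FALSE)
  a <- as.character(v1)
  b <- as.character(v2)
  a[is.na(a)] <- "(absent)"
  b[is.na(b)] <- "(absent)"
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) return(kappa_undefined())
  (p_o - p_e) / (1 - p_e)
}

#' Merge two reviewers' decisions into a consensus decision
#'
#' Field-wise: where the primary reviewers agree their value stands; where
#' they disagree the third reviewer's adjudication decides. Disagreement
#' with no adjudication supplied is an unresolved-case error listing the
#' fields.
#'
#' @param d1,d2 one-row decision data frames (or named lists) for the same
#'   case, as produced by [generate_reviews()].
#' @param adjudication optional adjudicated decision of the same shape.
#' @return list with `decision` (the consensus), `referred` (logical) and
#'   `referred_fields`.
#' @export
consensus <- function(d1, d2, adjudication = NULL) {
  d1 <- as.list(d1)
  d2 <- as.list(d2)
  if (!identical(as.character(d1$case_id), as.character(d2$case_id)))
    stop("consensus: decisions refer to different cases", call. = FALSE)
  fields <- setdiff(intersect(names(d1), names(d2)),
                    c("case_id", "reviewer_id"))
  final <- d1
  disagree <- fields[!vapply(fields, function(f)
    eq_na(d1[[f]], d2[[f]]), logical(1))]
  if (length(disagree)) {
    if (is.null(adjudication))
      stop("unresolved case ", d1$case_id,
           ": reviewers disagree on ", paste(disagree, collapse = ", "),
           " and no adjudication was supplied", call. = FALSE)
    adjudication <- as.list(adjudication)
    for (f in disagree) final[[f]] <- adjudication[[f]]
  }
  final$reviewer_id <- NULL
  list(decision = final, referred = length(disagree) > 0,
       referred_fields = disagree)
}

irr_row <- function(label, v1, v2) {
  n <- length(v1)
  agree <- sum(eq_na(v1, v2))
  k <- cohens_kappa(v1, v2)
  data.frame(
    item_label = label,
    percent_agreement = round_half_up(100 * agree / n, 1),
    kappa = as.numeric(k),
    kappa_undefined = is_kappa_undefined(k),
    n_agreements = agree,
    n_disagreements = n - agree,
    n_cases = n,
    n_decisions = 2L * n,
    stringsAsFactors = FALSE
  )
}

#' Inter-rater reliability table
#'
#' One row per trigger item (paired per-case trigger calls) plus rows for
#' the adverse-event flag, the harm flag, the MERP category and the severity
#' code. All rows are computed over the full paired case set (absent
#' classifications count as their own category); the severity row is
#' restricted to cases from the severity era (`sample_index >=
#' severity_start_sample`) when a `sample_index` column is present. Row
#' invariants: `n_agreements + n_disagreements = n_cases` and `n_decisions =
#' 2 * n_cases`.
#'
#' @param r1,r2 decision data frames for the two reviewers (see
#'   [generate_reviews()]), paired by `case_id`.
#' @param items trigger items to report (default all eight).
#' @param severity_start_sample first sample index of the severity era
#'   (default 10).
#' @return data frame of reliability rows; `kappa` is `NA` with
#'   `kappa_undefined = TRUE` where both raters are constant.
#' @export
irr_table <- function(r1, r2, items = trigger_items(),
                      severity_start_sample = 10) {
  if (!setequal(r1$case_id, r2$case_id) ||
      anyDuplicated(r1$case_id) || anyDuplicated(r2$case_id)) {
    odd <- c(setdiff(r1$case_id, r2$case_id), setdiff(r2$case_id, r1$case_id))
    stop("irr_table: unpaired case(s): ",
         paste(utils::head(unique(odd), 5), collapse = ", "), call. = FALSE)
  }
  r2 <- r2[match(r1$case_id, r2$case_id), , drop = FALSE]
  rows <- lapply(items, function(it) {
    col <- paste0("trigger_", it)
    irr_row(it, r1[[col]], r2[[col]])
  })
  rows <- c(rows, list(
    irr_row("AE", r1$ae, r2$ae),
    irr_row("Harm", r1$harm, r2$harm),
    irr_row("MERP", r1$merp, r2$merp)
  ))
  if ("severity" %in% names(r1)) {
    keep <- if ("sample_index" %in% names(r1))
      r1$sample_index >= severity_start_sample else rep(TRUE, nrow(r1))
    if (any(keep))
      rows <- c(rows, list(
        irr_row("Severity", r1$severity[keep], r2$severity[keep])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
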