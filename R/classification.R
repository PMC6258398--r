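# Harm classification systems and cross-tabulations.
#
# System 1 is the NCC MERP index with category C modified for EMS use
# (C_EMS: the error reached the patient and the potential for harm was
# present but could not be conclusively determined in the short duration of
# prehospital care); for reporting, C_EMS is counted as harm-positive.
# System 2 is a seven-code EMS adverse-event severity rating index
# introduced part-way through a study period, so it applies only to the
# "severity era" subset of samples.

#' Modified NCC MERP categories
#'
#' @return data frame of the nine categories (C replaced by C_EMS), their
#'   descriptions, and whether each counts as harm-positive.
#' @export
merp_categories <- function() {
  data.frame(
    code = c("A", "B", "C_EMS", "D", "E", "F", "G", "H", "I"),
    description = c(
      "Circumstances or events with the capacity to cause error",
      "Error that did not reach the patient",
      "Error that reached the patient; harm possible but not conclusively determinable over the short duration of EMS care",
      "Error that reached the patient and required monitoring or intervention to confirm no harm",
      "Temporary harm requiring intervention",
      "Temporary harm requiring initial or prolonged hospitalisation",
      "Permanent patient harm",
      "Intervention required to sustain life",
      "Patient death"),
    harm_positive = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                      TRUE),
    stringsAsFactors = FALSE
  )
}

#' Adverse-event severity rating codes
#'
#' @return data frame of the seven severity codes and their descriptions
#'   (code 7 = no adverse event identified).
#' @export
severity_codes <- function() {
  data.frame(
    code = 1:7,
    description = c(
      "AE with harm as a result of commission",
      "AE with harm as a result of omission",
      "AE with harm, no fault",
      "AE with potential to cause harm as a result of commission",
      "AE with potential to cause harm as a result of omission",
      "AE with potential to cause harm, no fault",
      "No AE identified"),
    stringsAsFactors = FALSE
  )
}

#' Is a MERP category harm-positive?
#'
#' Under the EMS-modified convention, C_EMS and E-I count as positive for
#' the occurrence of harm; A, B and D do not. The mapping is total over the
#' nine categories.
#'
#' @param cat character vector of MERP codes.
#' @return logical vector.
#' @export
is_harm_positive <- function(cat) {
  m <- merp_categories()
  bad <- !is.na(cat) & !cat %in% m$code
  if (any(bad)) stop("is_harm_positive: unknown MERP category ",
                     paste(unique(cat[bad]), collapse = ", "), call. = FALSE)
  out <- m$harm_positive[match(cat, m$code)]
  out
}

#' Trigger-item by harm-category cross-tabulation
#'
#' For each trigger item, counts the reviewed cases carrying that item in
#' each category of the requested classification system, plus a "no
#' trigger" cell (cases without the item) and per-row totals; a totals row
#' sums the category columns across items. Percentages use the supplied
#' denominator (the full sample for the MERP system, the severity-era
#' subset for the severity system) with the shared one-decimal rounding.
#' Row conservation holds by construction: no-trigger + trigger-positive
#' cells = `n_total_cases` for every item row.
#'
#' @param decisions final (consensus) decision data frame: per-item logical
#'   columns `trigger_C1` .. `trigger_R1` and a `merp` or `severity` column.
#' @param system `"merp"` or `"severity"`.
#' @param n_total_cases percentage denominator; defaults to
#'   `nrow(decisions)`.
#' @param items trigger items to tabulate.
#' @return an object of class `"emstt_crosstab"`: matrices `counts` and
#'   `percents` (rows = items + `"Total"`, columns = `"no_trigger"`,
#'   categories, `"total"`), plus `system` and `n_total_cases`.
#' @export
classification_crosstab <- function(decisions,
                                    system = c("merp", "severity"),
                                    n_total_cases = nrow(decisions),
                                    items = trigger_items()) {
  system <- match.arg(system)
  cats <- if (system == "merp") merp_categories()$code
          else as.character(7:1)
  cls <- as.character(decisions[[system]])
  counts <- matrix(0L, nrow = length(items) + 1,
                   ncol = length(cats) + 2,
                   dimnames = list(c(items, "Total"),
                                   c("no_trigger", cats, "total")))
  for (it in items) {
    pos <- decisions[[paste0("trigger_", it)]]
    if (any(pos & is.na(cls)))
      stop("classification_crosstab: trigger-positive case(s) without a ",
           system, " classification: ",
           paste(utils::head(decisions$case_id[pos & is.na(cls)], 5),
                 collapse = ", "), call. = FALSE)
    for (cat in cats)
      counts[it, cat] <- sum(pos & cls == cat, na.rm = TRUE)
    counts[it, "total"] <- sum(pos)
    counts[it, "no_trigger"] <- n_total_cases - sum(pos)
  }
  counts["Total", ] <- colSums(counts[items, , drop = FALSE])
  counts["Total", "no_trigger"] <- NA  # not a meaningful sum across items
  percents <- round_half_up(100 * counts / n_total_cases, 1)
  structure(list(counts = counts, percents = percents, system = system,
                 n_total_cases = n_total_cases),
            class = "emstt_crosstab")
}

#' @export
print.emstt_crosstab <- function(x, ...) {
  cat(sprintf("<emstt_crosstab> system %s, %% of %d cases\n", x$system,
              x$n_total_cases))
  disp <- matrix(sprintf("%d (%.1f)", x$counts, x$percents),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  disp[is.na(x$counts)] <- ""
  print(as.data.frame(disp), ...)
  invisible(x)
}

#' Restrict decisions to the severity-classification era
#'
#' The severity rating index was introduced with a later sample, so only
#' decisions from samples at or after `start_sample` may carry severity
#' codes; a severity code on an earlier sample is a validation error.
#'
#' @param decisions decision data frame carrying a `sample_index` column.
#' @param start_sample first sample index of the severity era (default 10).
#' @return the subset of `decisions` with `sample_index >= start_sample`.
#' @export
severity_era_filter <- function(decisions, start_sample = 10) {
  if (!"sample_index" %in% names(decisions))
    stop("severity_era_filter: decisions carry no sample_index",
         call. = FALSE)
  early <- decisions$sample_index < start_sample
  if ("severity" %in% names(decisions) &&
      any(early & !is.na(decisions$severity)))
    stop("severity_era_filter: severity code(s) on pre-era sample(s): ",
         paste(utils::head(decisions$case_id[early & !is.na(decisions$severity)], 5),
               collapse = ", "), call. = FALSE)
  decisions[!early, , drop = FALSE]
}
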