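# End-to-end pipeline: exclusions -> sampling -> screening -> review and
# consensus -> classification -> outcome measures and control charts, plus
# the study-style summary report tables.

#' Per-item trigger count and share table
#'
#' @param hits hit data frame from [screen()] (columns `record_id`, `item`).
#' @param items items to report; items with zero hits are reported as 0
#'   (0.0).
#' @return data frame `item`, `count`, `share_pct` (percent of all hits,
#'   shared one-decimal rounding); total hit count in attribute
#'   `"total_hits"`.
#' @export
trigger_share_table <- function(hits, items = trigger_items()) {
  counts <- vapply(items, function(it) sum(hits$item == it), integer(1))
  total <- sum(counts)
  share <- if (total > 0) round_half_up(100 * counts / total, 1)
           else rep(0, length(counts))
  out <- data.frame(item = items, count = counts, share_pct = share,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total_hits") <- total
  out
}

#' Consensus over whole decision frames
#'
#' Applies [consensus()] row-wise over two reviewers' decision frames,
#' adjudicated field-wise by an optional third frame (in simulated runs the
#' ground truth plays the third reviewer). With no adjudication supplied,
#' any residual disagreement is an unresolved-case error.
#'
#' @param r1,r2 decision frames paired by `case_id`.
#' @param adjudication optional adjudication frame of the same shape.
#' @return the consensus decision frame with a logical `referred` column.
#' @export
consensus_decisions <- function(r1, r2, adjudication = NULL) {
  r2 <- r2[match(r1$case_id, r2$case_id), , drop = FALSE]
  if (!is.null(adjudication))
    adjudication <- adjudication[match(r1$case_id, adjudication$case_id), ,
                                 drop = FALSE]
  out <- vector("list", nrow(r1))
  referred <- logical(nrow(r1))
  for (i in seq_len(nrow(r1))) {
    cs <- consensus(r1[i, ], r2[i, ],
                    if (is.null(adjudication)) NULL else adjudication[i, ])
    out[[i]] <- as.data.frame(cs$decision, stringsAsFactors = FALSE)
    referred[i] <- cs$referred
  }
  final <- do.call(rbind, out)
  final$referred <- referred
  final
}

#' Recast a ground-truth table as a decision frame
#'
#' Useful as the adjudication frame in simulated consensus runs and as the
#' error-free reference in validation studies.
#'
#' @param truth the `truth` data frame from [generate_cohort()].
#' @return a decision frame in the [generate_reviews()] layout.
#' @export
truth_as_decisions <- function(truth) {
  d <- data.frame(case_id = truth$record_id,
                  sample_index = truth$sample_index,
                  stringsAsFactors = FALSE)
  for (it in trigger_items())
    d[[paste0("trigger_", it)]] <- truth[[paste0("true_", it)]]
  d$ae <- truth$true_ae
  d$harm <- truth$true_harm
  d$merp <- truth$true_merp
  d$severity <- truth$true_severity
  d
}

count_by_period <- function(case_period, flag, period_ids) {
  tab <- tapply(flag, factor(case_period, levels = period_ids), sum)
  as.integer(ifelse(is.na(tab), 0L, tab))
}

#' Run the full trigger-tool pipeline on a synthetic cohort
#'
#' Executes, in order: cohort generation, exclusion filtering, per-period
#' sample draws (30 drawn / first 20 reviewed / 10 spares), trigger
#' screening of the reviewed records, paired review simulation with
#' consensus (ground truth adjudicates residual disagreements),
#' classification cross-tabs (MERP over the full reviewed sample, severity
#' over the severity-era subset), inter-rater reliability, and the four
#' outcome measures as pooled rates and U-charts with Nelson-rule signals.
#' Deterministic given the generator seed.
#'
#' @param gen_config a [generator_config()].
#' @param trig_config a [trigger_config()].
#' @param screen_scope `"sample"` (screen only the reviewed sample, the
#'   study design) or `"cohort"` (screen every materialised record, for
#'   prevalence-recovery analyses).
#' @return an object of class `"emstt_report"`; see Details.
#' @details The report carries: `trigger_table` (per-item counts/shares of
#'   the hits), `irr` (reliability table over reviewed cases),
#'   `merp_crosstab` and `severity_crosstab`, `rates` (pooled triggers /
#'   adverse events / harm / modified adverse events per 10,000
#'   encounters), `charts` and `violations` per measure, `hits`,
#'   `decisions`, `batches`, and bookkeeping counts.
#' @export
run_pipeline <- function(gen_config = generator_config(),
                         trig_config = trigger_config(),
                         screen_scope = c("sample", "cohort")) {
  screen_scope <- match.arg(screen_scope)
  seeds <- derive_seeds(gen_config$seed, 4L)

  cohort <- generate_cohort(gen_config)
  truth <- cohort$truth
  ex <- apply_exclusions(cohort$records)
  eligible_ids <- vapply(ex$eligible, function(r) r$record_id, character(1))

  period_ids <- cohort$periods$period_id
  batch_seeds <- with_seed(seeds[4], sample.int(.Machine$integer.max - 1L,
                                                length(period_ids)))
  period_of <- truth$period_id[match(eligible_ids, truth$record_id)]
  batches <- lapply(seq_along(period_ids), function(p) {
    pool <- ex$eligible[period_of == period_ids[p]]
    draw_sample(pool, period_ids[p], batch_seeds[p])
  })
  reviewed_ids <- unlist(lapply(batches, `[[`, "review_set"))

  screened_ids <- if (screen_scope == "sample") reviewed_ids else
    vapply(cohort$records, function(r) r$record_id, character(1))
  screened <- cohort$records[
    match(screened_ids, vapply(cohort$records, function(r) r$record_id,
                               character(1)))]
  hits <- screen(screened, trig_config)

  reviews <- generate_reviews(truth, gen_config)
  keep <- reviews$r1$case_id %in% screened_ids
  r1 <- reviews$r1[keep, , drop = FALSE]
  r2 <- reviews$r2[reviews$r2$case_id %in% screened_ids, , drop = FALSE]
  adj <- truth_as_decisions(truth)
  decisions <- consensus_decisions(r1, r2, adj)

  irr <- irr_table(r1, r2,
                   severity_start_sample = gen_config$severity_start_period)
  # Reporting convention: a consensus that flags a trigger but records no
  # classification (possible when both simulated reviewers err the same way
  # on a truly negative case) is coded to the minimal categories - MERP A
  # (capacity for error) and severity 7 (no adverse event identified).
  xt_dec <- decisions
  pos <- Reduce(`|`, lapply(trigger_items(), function(it)
    xt_dec[[paste0("trigger_", it)]]))
  xt_dec$merp[pos & is.na(xt_dec$merp)] <- "A"
  era <- xt_dec$sample_index >= gen_config$severity_start_period
  xt_dec$severity[pos & era & is.na(xt_dec$severity)] <- 7L
  merp_xt <- classification_crosstab(xt_dec, "merp")
  sev_decisions <- severity_era_filter(
    xt_dec, start_sample = gen_config$severity_start_period)
  severity_xt <- if (nrow(sev_decisions))
    classification_crosstab(sev_decisions, "severity") else NULL

  dec_period <- truth$period_id[match(decisions$case_id, truth$record_id)]
  hit_period <- truth$period_id[match(hits$record_id, truth$record_id)]
  enc <- cohort$denominators$encounters
  measures <- list(
    triggers = data.frame(
      period_id = period_ids,
      count = count_by_period(hit_period, rep(TRUE, nrow(hits)), period_ids),
      encounters = enc, stringsAsFactors = FALSE),
    ae = data.frame(
      period_id = period_ids,
      count = count_by_period(dec_period, decisions$ae, period_ids),
      encounters = enc, stringsAsFactors = FALSE),
    harm = data.frame(
      period_id = period_ids,
      count = count_by_period(dec_period, decisions$harm, period_ids),
      encounters = enc, stringsAsFactors = FALSE)
  )
  measures$modified_ae <- measures$ae
  measures$modified_ae$count <- modified_ae_count(measures$ae$count,
                                                  measures$harm$count)
  charts <- lapply(measures, build_u_chart)
  violations <- lapply(charts, nelson_violations)
  rates <- overall_rates(measures[c("triggers", "ae", "harm")])

  structure(list(
    trigger_table = trigger_share_table(hits),
    irr = irr,
    merp_crosstab = merp_xt,
    severity_crosstab = severity_xt,
    rates = rates,
    measures = measures,
    charts = charts,
    violations = violations,
    hits = hits,
    decisions = decisions,
    batches = batches,
    n_reviewed = length(reviewed_ids),
    n_screened = length(screened_ids),
    n_excluded = nrow(ex$excluded),
    n_records = length(cohort$records),
    encounters_total = sum(enc),
    seed = gen_config$seed
  ), class = "emstt_report")
}

#' @export
print.emstt_report <- function(x, ...) {
  cat("Emergency medical services trigger tool summary\n")
  cat(sprintf("  records: %d materialised, %d excluded, %d reviewed; %s encounters\n",
              x$n_records, x$n_excluded, x$n_reviewed,
              format(x$encounters_total, big.mark = ",")))
  cat(sprintf("  triggers found: %d\n", attr(x$trigger_table, "total_hits")))
  tt <- x$trigger_table[x$trigger_table$count > 0, , drop = FALSE]
  if (nrow(tt))
    cat(paste(sprintf("    %s: %d (%.1f%%)", tt$item, tt$count,
                      tt$share_pct), collapse = "\n"), "\n")
  cat(sprintf("  pooled rates per 10,000 encounters: triggers %.2f, AE %.2f, harm %.2f, modified AE %.2f\n",
              x$rates["triggers"], x$rates["ae"], x$rates["harm"],
              x$rates["modified_ae"]))
  nv <- sum(vapply(x$violations, nrow, integer(1)))
  cat(sprintf("  Nelson signals across the four charts: %d\n", nv))
  invisible(x)
}
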