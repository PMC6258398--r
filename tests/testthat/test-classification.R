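mk_decisions <- function(assign, n_total, prefix = "c") {
  # assign: list of (item, category, count); remaining cases trigger-free
  n_pos <- sum(vapply(assign, function(a) a$count, numeric(1)))
  d <- data.frame(case_id = sprintf("%s%04d", prefix, seq_len(n_total)),
                  stringsAsFactors = FALSE)
  for (it in trigger_items()) d[[paste0("trigger_", it)]] <- FALSE
  d$merp <- NA_character_
  d$severity <- NA_integer_
  i <- 1
  for (a in assign) {
    if (a$count == 0) next
    rows <- i:(i + a$count - 1)
    d[[paste0("trigger_", a$item)]][rows] <- TRUE
    if (is.numeric(a$cat)) d$severity[rows] <- a$cat
    else d$merp[rows] <- a$cat
    i <- i + a$count
  }
  stopifnot(i - 1 == n_pos)
  d
}

test_that("harm positivity partitions the MERP categories per the EMS convention", {
  expect_true(is_harm_positive("C_EMS"))
  expect_true(is_harm_positive("E"))
  expect_false(is_harm_positive("A"))
  expect_false(is_harm_positive("B"))
  expect_false(is_harm_positive("D"))
  all_codes <- merp_categories()$code
  expect_setequal(all_codes[is_harm_positive(all_codes)],
                  c("C_EMS", "E", "F", "G", "H", "I"))
  expect_error(is_harm_positive("Z"), "unknown MERP category")
})

test_that("MERP cross-tab reproduces the study-shaped fixture totals", {
  assign <- list(
    list(item = "C1", cat = "A", count = 6),
    list(item = "C1", cat = "B", count = 3),
    list(item = "C1", cat = "C_EMS", count = 1),
    list(item = "C2", cat = "A", count = 94),
    list(item = "C2", cat = "B", count = 10),
    list(item = "C2", cat = "C_EMS", count = 4),
    list(item = "C3", cat = "A", count = 2),
    list(item = "C3", cat = "B", count = 1),
    list(item = "C4", cat = "A", count = 2),
    list(item = "C4", cat = "B", count = 3),
    list(item = "C4", cat = "C_EMS", count = 2),
    list(item = "C5", cat = "A", count = 41),
    list(item = "C5", cat = "B", count = 17),
    list(item = "C5", cat = "C_EMS", count = 4),
    list(item = "P1", cat = "A", count = 2),
    list(item = "P1", cat = "B", count = 2))
  d <- mk_decisions(assign, 710)
  xt <- classification_crosstab(d, "merp", n_total_cases = 710)
  expect_equal(xt$counts["Total", "A"], 147)
  expect_equal(xt$percents["Total", "A"], 20.7)
  expect_equal(xt$counts["Total", "B"], 36)
  expect_equal(xt$percents["Total", "B"], 5.1)
  expect_equal(xt$counts["Total", "C_EMS"], 11)
  expect_equal(xt$percents["Total", "C_EMS"], 1.5)
  expect_equal(xt$counts["Total", "total"], 194)
  expect_equal(xt$percents["Total", "total"], 27.3)
  expect_equal(xt$counts["C1", "no_trigger"], 700)
  expect_equal(xt$percents["C1", "no_trigger"], 98.6)
  # row conservation for every item
  items <- trigger_items()
  for (it in items)
    expect_equal(xt$counts[it, "no_trigger"] + xt$counts[it, "total"], 710)
  # harm conservation: per-item harm-positive cells equal the flag recount
  for (it in items) {
    pos <- d[[paste0("trigger_", it)]]
    expect_equal(sum(xt$counts[it, c("C_EMS", "E", "F", "G", "H", "I")]),
                 sum(pos & !is.na(d$merp) & is_harm_positive(d$merp)))
  }
})

test_that("severity cross-tab counts codes and an empty decision set is all-zero", {
  assign <- list(
    list(item = "C2", cat = 7, count = 36),
    list(item = "C2", cat = 6, count = 1),
    list(item = "C2", cat = 5, count = 2),
    list(item = "C5", cat = 7, count = 21),
    list(item = "C5", cat = 4, count = 11))
  d <- mk_decisions(assign, 560)
  xt <- classification_crosstab(d, "severity", n_total_cases = 560)
  expect_equal(xt$counts["C2", "7"], 36)
  expect_equal(xt$counts["C2", "total"], 39)
  expect_equal(xt$percents["C2", "no_trigger"], 93.0)
  expect_equal(xt$counts["Total", "7"], 57)

  empty <- mk_decisions(list(), 50)
  xt0 <- classification_crosstab(empty, "merp", n_total_cases = 50)
  expect_true(all(xt0$counts[, setdiff(colnames(xt0$counts), "no_trigger")] == 0))
  # a trigger-positive case without a classification is an error
  bad <- mk_decisions(list(list(item = "C2", cat = "A", count = 1)), 10)
  bad$merp <- NA_character_
  expect_error(classification_crosstab(bad, "merp"),
               "without a merp classification")
})

test_that("the severity era filter keeps samples >= start and validates codes", {
  d <- mk_decisions(list(list(item = "C2", cat = 7, count = 20)), 720)
  d$sample_index <- rep(1:36, each = 20)
  d$severity <- NA_integer_
  d$severity[d$sample_index >= 10][1:5] <- 7L
  kept <- severity_era_filter(d, start_sample = 10)
  expect_equal(sort(unique(kept$sample_index)), 10:36)
  expect_equal(nrow(kept), 27 * 20)
  expect_identical(severity_era_filter(d, start_sample = 1), d)
  d$severity[d$sample_index == 3][1] <- 5L
  expect_error(severity_era_filter(d, start_sample = 10), "pre-era")
})
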