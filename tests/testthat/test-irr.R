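mismatch_pair <- function(n, k) {
  v1 <- rep(FALSE, n)
  v2 <- v1
  if (k > 0) v2[seq_len(k)] <- TRUE
  list(v1 = v1, v2 = v2)
}

test_that("percent agreement uses one-decimal half-up rounding, two-decimal display", {
  p <- mismatch_pair(710, 22)           # 688 agreements
  expect_equal(percent_agreement(p$v1, p$v2), 96.9)
  expect_equal(format_percent(percent_agreement(p$v1, p$v2)), "96.90")
  p <- mismatch_pair(710, 18)           # 692/710 = 97.4647 -> 97.50
  expect_equal(format_percent(percent_agreement(p$v1, p$v2)), "97.50")
  p <- mismatch_pair(710, 40)           # 670/710 = 94.366 -> 94.40
  expect_equal(format_percent(percent_agreement(p$v1, p$v2)), "94.40")
  expect_equal(percent_agreement(letters, letters), 100)
  expect_error(percent_agreement(1:3, 1:4), "length mismatch")
  # symmetric and relabeling-invariant
  a <- sample(c("x", "y"), 50, replace = TRUE)
  b <- sample(c("x", "y"), 50, replace = TRUE)
  expect_equal(percent_agreement(a, b), percent_agreement(b, a))
  relab <- c(x = "u", y = "v")
  expect_equal(percent_agreement(relab[a], relab[b]),
               percent_agreement(a, b))
})

test_that("kappa matches the direct formula, with the undefined sentinel", {
  # 2x2 with a=45, b=5, c=5, d=45: p_o = 0.90, p_e = 0.50, kappa = 0.8
  v1 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(45, 5, 5, 45))
  v2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(45, 5, 5, 45))
  expect_equal(cohens_kappa(v1, v2), 0.8)
  # both raters constant: undefined, never a silent zero
  k <- cohens_kappa(rep(FALSE, 710), rep(FALSE, 710))
  expect_true(is_kappa_undefined(k))
  expect_true(is.na(k))
  # perfect agreement with variation: exactly 1
  v <- rep(c("a", "b", "c"), 10)
  expect_equal(cohens_kappa(v, v), 1)
})

test_that("kappa equals the loop oracle on random paired vectors and obeys bounds", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(8:60, 1)
    n_cat <- sample(2:4, 1)
    v1 <- sample(letters[1:n_cat], n, replace = TRUE)
    v2 <- if (stats::runif(1) < 0.15) v1
          else sample(letters[1:n_cat], n, replace = TRUE)
    got <- cohens_kappa(v1, v2)
    want <- kappa_oracle(v1, v2)
    if (identical(want, "undefined")) {
      expect_true(is_kappa_undefined(got))
    } else {
      expect_equal(as.numeric(got), want, tolerance = 1e-12)
      p_o <- mean(v1 == v2)
      expect_lte(got, p_o + 1e-12)
      expect_lte(got, 1)
      if (p_o == 1) expect_equal(as.numeric(got), 1)
    }
  }
})

test_that("consensus takes agreement as final and adjudicates disagreement", {
  d1 <- list(case_id = "c1", reviewer_id = "r1", ae = TRUE, harm = FALSE,
             merp = "A")
  d2_same <- list(case_id = "c1", reviewer_id = "r2", ae = TRUE,
                  harm = FALSE, merp = "A")
  cs <- consensus(d1, d2_same)
  expect_false(cs$referred)
  expect_true(cs$decision$ae)

  d2_diff <- list(case_id = "c1", reviewer_id = "r2", ae = FALSE,
                  harm = FALSE, merp = "A")
  adj <- list(case_id = "c1", ae = TRUE, harm = FALSE, merp = "A")
  cs <- consensus(d1, d2_diff, adj)
  expect_true(cs$referred)
  expect_equal(cs$referred_fields, "ae")
  expect_true(cs$decision$ae)

  expect_error(consensus(d1, d2_diff), "unresolved case c1.*ae")
  d_other <- list(case_id = "c2", reviewer_id = "r2", ae = TRUE)
  expect_error(consensus(d1, d_other), "different cases")
})

test_that("irr_table rows satisfy their count identities and match a recount", {
  n <- 710
  dis <- c(C1 = 18, C2 = 83, C3 = 4, C4 = 0, C5 = 22, M1 = 0, P1 = 2,
           R1 = 0)
  mk <- function(reviewer) {
    d <- data.frame(case_id = sprintf("c%03d", 1:n), reviewer_id = reviewer,
                    sample_index = rep(1L, n), stringsAsFactors = FALSE)
    for (it in trigger_items()) d[[paste0("trigger_", it)]] <- FALSE
    d$ae <- FALSE; d$harm <- FALSE
    d$merp <- NA_character_; d$severity <- NA_integer_
    d
  }
  r1 <- mk("a"); r2 <- mk("b")
  for (it in names(dis))
    if (dis[[it]] > 0)
      r2[[paste0("trigger_", it)]][seq_len(dis[[it]])] <- TRUE
  tab <- irr_table(r1, r2)
  for (it in names(dis)) {
    row <- tab[tab$item_label == it, ]
    expect_equal(row$n_disagreements, unname(dis[[it]]))
    expect_equal(row$n_agreements + row$n_disagreements, row$n_cases)
    expect_equal(row$n_decisions, 2 * row$n_cases)
    expect_equal(row$percent_agreement,
                 round_half_up(100 * row$n_agreements / n, 1))
  }
  expect_equal(format_percent(tab$percent_agreement[tab$item_label == "C1"]),
               "97.50")
  expect_equal(format_percent(tab$percent_agreement[tab$item_label == "C2"]),
               "88.30")
  expect_equal(format_percent(tab$percent_agreement[tab$item_label == "C5"]),
               "96.90")
  # items with no variation in either rater are undefined-kappa rows
  expect_true(tab$kappa_undefined[tab$item_label == "M1"])
  expect_true(tab$kappa_undefined[tab$item_label == "R1"])
  expect_false(tab$kappa_undefined[tab$item_label == "C2"])
  # unpaired cases are rejected by name
  expect_error(irr_table(r1, r2[-1, ]), "unpaired case")
})

test_that("error-free reviews give 100% agreement on every row", {
  cfg <- generator_config(seed = 2, n_periods = 4,
                          encounters_per_period_mean = 1500,
                          background_per_period = 12,
                          reviewer_error_rate = 0,
                          trigger_prevalence = c(C2 = 25, C5 = 15))
  co <- generate_cohort(cfg)
  rev <- generate_reviews(co$truth, cfg)
  tab <- irr_table(rev$r1, rev$r2)
  expect_true(all(tab$percent_agreement == 100))
  expect_true(all(tab$n_disagreements == 0))
})
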