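# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

naive_ews <- function(obs, table) {
  s <- 0
  for (p in names(table)) {
    if (p == "consciousness") next
    v <- obs[[p]]
    if (is.null(v) || is.na(v)) next
    b <- table[[p]]
    found <- FALSE
    for (j in seq_len(nrow(b))) {
      if (v >= b$lo[j] && v < b$hi[j]) {
        s <- s + b$score[j]
        found <- TRUE
        break
      }
    }
    if (!found) stop("oracle: out of bands")
  }
  cl <- obs[["consciousness"]]
  if (!is.null(table$consciousness) && !is.null(cl) && !is.na(cl))
    s <- s + unname(table$consciousness[cl])
  s
}

naive_item <- function(r, item, cohort, cfg) {
  obs <- r$observations
  if (item == "C1") {
    for (clause in list(c(cfg$spo2_low, "supplemental_oxygen"),
                        c(cfg$spo2_critical, "assisted_ventilation"))) {
      thr <- as.numeric(clause[1])
      first <- NA
      for (i in seq_len(nrow(obs)))
        if (!is.na(obs$spo2[i]) && obs$spo2[i] < thr) { first <- i; break }
      if (!is.na(first)) {
        relieved <- FALSE
        iv <- r$interventions
        for (j in seq_len(nrow(iv)))
          if (iv$kind[j] == clause[2] && !is.na(iv$time[j]) &&
              iv$time[j] >= obs$time[first]) relieved <- TRUE
        if (!relieved) return(TRUE)
      }
    }
    return(FALSE)
  }
  if (item == "C2") {
    idx <- which(!is.na(obs$sbp))
    if (length(idx) < 2) return(FALSE)
    b <- obs$sbp[idx[1]]
    for (j in idx[-1])
      if (abs(obs$sbp[j] - b) / b > cfg$sbp_change_frac) return(TRUE)
    return(FALSE)
  }
  if (item %in% c("C3", "C4")) {
    f <- if (item == "C3") "pain" else "temp"
    thr <- if (item == "C3") cfg$pain_threshold else cfg$temp_threshold
    v <- obs[[f]]
    best <- -Inf; bi <- NA
    for (i in seq_len(nrow(obs)))
      if (!is.na(v[i]) && v[i] > thr && v[i] > best) { best <- v[i]; bi <- i }
    if (is.na(bi)) return(FALSE)
    for (j in seq_len(nrow(obs)))
      if (!is.na(v[j]) && obs$time[j] > obs$time[bi] && v[j] < best)
        return(FALSE)
    return(TRUE)
  }
  if (item == "C5") {
    if (nrow(obs) < 2) return(FALSE)
    s1 <- naive_ews(obs[1, ], cfg$ews_table)
    for (i in 2:nrow(obs))
      if (naive_ews(obs[i, ], cfg$ews_table) - s1 > cfg$ews_increase)
        return(TRUE)
    return(FALSE)
  }
  if (item == "M1") {
    md <- r$medications
    for (i in seq_len(nrow(md)))
      for (j in seq_len(nrow(md)))
        if (md$name[i] %in% cfg$opioid_names &&
            md$name[j] == cfg$antagonist_name) return(TRUE)
    return(FALSE)
  }
  if (item == "P1") {
    iv <- r$interventions
    for (i in seq_len(nrow(iv))) {
      if (iv$kind[i] != "spinal_immobilisation") next
      if (is.na(iv$indicated[i])) next
      performed <- is.na(iv$performed[i]) || iv$performed[i]
      if (!iv$indicated[i] && performed) return(TRUE)
      if (cfg$p1_mode == "mismatch" && iv$indicated[i] && !performed)
        return(TRUE)
    }
    return(FALSE)
  }
  if (item == "R1") {
    for (other in cohort) {
      if (other$record_id == r$record_id) next
      if (other$patient_id != r$patient_id) next
      if (other$disposition != "refusal_of_transport") next
      gap <- as.numeric(difftime(r$encounter_start, other$encounter_end,
                                 units = "hours"))
      if (gap > 0 && gap <= cfg$return_window_hours) return(TRUE)
    }
    return(FALSE)
  }
  stop("unknown item")
}

naive_screen <- function(cohort, cfg = emstt::trigger_config()) {
  out <- NULL
  for (r in cohort)
    for (item in emstt::trigger_items())
      if (suppressWarnings(naive_item(r, item, cohort, cfg)))
        out <- rbind(out, data.frame(record_id = r$record_id, item = item,
                                     stringsAsFactors = FALSE))
  if (is.null(out)) data.frame(record_id = character(), item = character())
  else out
}

# Direct-formula kappa; returns the string "undefined" when p_e = 1.
kappa_oracle <- function(v1, v2) {
  a <- as.character(v1); a[is.na(a)] <- "(absent)"
  b <- as.character(v2); b[is.na(b)] <- "(absent)"
  n <- length(a)
  po <- 0
  for (i in seq_len(n)) if (a[i] == b[i]) po <- po + 1
  po <- po / n
  pe <- 0
  for (k in unique(c(a, b))) pe <- pe + (sum(a == k) / n) * (sum(b == k) / n)
  if (pe >= 1 - 1e-12) return("undefined")
  (po - pe) / (1 - pe)
}

# Sliding-window evaluation of the eight Nelson rules, reporting the final
# point of each maximal violating window (same reporting convention as the
# package, re-derived with explicit loops).
nelson_oracle <- function(chart) {
  d <- chart$data
  u <- d$u
  m <- length(u)
  z <- numeric(m)
  for (i in seq_len(m))
    z[i] <- if (d$sigma[i] > 0) (u[i] - chart$center) / d$sigma[i] else 0
  ends_for <- function(w, pred) {
    e <- integer()
    if (m >= w) for (i in w:m) if (pred(i - w + 1, i)) e <- c(e, i)
    e
  }
  collapse <- function(e) {
    keep <- integer()
    for (x in e) if (!((x + 1) %in% e)) keep <- c(keep, x)
    sort(unique(keep))
  }
  preds <- list(
    `1` = function(a, b) abs(z[b]) > 3,
    `2` = function(a, b) all(z[a:b] > 0) || all(z[a:b] < 0),
    `3` = function(a, b) {
      dd <- diff(u[a:b]); all(dd > 0) || all(dd < 0)
    },
    `4` = function(a, b) {
      dd <- diff(u[a:b])
      all(dd != 0) && all(dd[-1] * dd[-length(dd)] < 0)
    },
    `5` = function(a, b) sum(z[a:b] > 2) >= 2 || sum(z[a:b] < -2) >= 2,
    `6` = function(a, b) sum(z[a:b] > 1) >= 4 || sum(z[a:b] < -1) >= 4,
    `7` = function(a, b) all(abs(z[a:b]) < 1),
    `8` = function(a, b) all(abs(z[a:b]) > 1)
  )
  widths <- c(1, 9, 6, 14, 3, 5, 15, 8)
  out <- NULL
  for (rule in 1:8) {
    e <- collapse(ends_for(widths[rule], preds[[as.character(rule)]]))
    if (length(e))
      out <- rbind(out, data.frame(rule = rule, index = e))
  }
  if (is.null(out)) data.frame(rule = integer(), index = integer()) else out
}

random_chart <- function(len = sample(10:40, 1)) {
  lambda <- stats::runif(1, 0.5, 8)
  periods <- data.frame(
    period_id = sprintf("p%02d", seq_len(len)),
    count = stats::rpois(len, lambda),
    encounters = sample(2000:20000, len, replace = TRUE))
  emstt::build_u_chart(periods)
}
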