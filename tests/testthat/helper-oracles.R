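# Independent oracles, deliberately written with the dumbest possible
# algorithms so they share no code path with the implementation.

# Sample-by-sample saccade oracle: walk the series, flag threshold hits,
# then merge flagged runs whose gap is below merge_gap samples.
oracle_saccade_spans <- function(v, a, v_thr = 30, a_thr = 1000,
                                 merge_gap = 20) {
  n <- length(v)
  hit <- logical(n)
  for (i in seq_len(n)) {
    vi <- v[i]; ai <- a[i]
    hit[i] <- (!is.na(vi) && abs(vi) >= v_thr) ||
      (!is.na(ai) && abs(ai) >= a_thr)
  }
  spans <- list()
  i <- 1
  while (i <= n) {
    if (hit[i]) {
      j <- i
      while (j < n && hit[j + 1]) j <- j + 1
      spans[[length(spans) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(spans) == 0) return(matrix(numeric(0), ncol = 2))
  merged <- list(spans[[1]])
  for (s in spans[-1]) {
    last <- merged[[length(merged)]]
    if (s[1] - last[2] - 1 < merge_gap) {
      merged[[length(merged)]] <- c(last[1], max(last[2], s[2]))
    } else merged[[length(merged) + 1]] <- s
  }
  do.call(rbind, merged)
}

# Interval-union oracle: which integer sample indices fall in the union of
# padded event spans?
oracle_union_mask <- function(n, onsets, offsets, pad) {
  mask <- logical(n)
  for (k in seq_along(onsets)) {
    lo <- max(1, onsets[k] - pad)
    hi <- min(n, offsets[k] + pad)
    mask[lo:hi] <- TRUE
  }
  mask
}

# Repeated-measures ANOVA oracle through base aov() error strata.
oracle_rm_anova <- function(d) {
  d$subject <- factor(d$subject); d$A <- factor(d$A); d$B <- factor(d$B)
  fit <- summary(stats::aov(y ~ A * B + Error(subject / (A * B)), data = d))
  pick <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)[1]
    c(F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
      ss = tab$`Sum Sq`[i], ss_err = tab$`Sum Sq`[nrow(tab)])
  }
  list(A = pick("Error: subject:A", "A"),
       B = pick("Error: subject:B", "B"),
       AB = pick("Error: subject:A:B", "A:B"))
}

# Within-subjects correlation oracle: subject-dummy multiple regression.
oracle_ws_corr <- function(x, y, subject) {
  s <- factor(subject)
  full <- stats::lm(y ~ x + s)
  null <- stats::lm(y ~ s)
  an <- stats::anova(null, full)
  Fv <- an$F[2]
  r <- sign(stats::coef(full)[["x"]]) * sqrt(Fv / (Fv + full$df.residual))
  list(r = r, df = full$df.residual, p = an$`Pr(>F)`[2])
}

# Closed-form expected value of the averaged-trace initial-acceleration
# measurement: acceleration a is "on" while onset latency L <= t <= L + ramp,
# L ~ N(mu, sd); the averaged acceleration at t is a * P(on), and the metric
# averages that over the window [t0, t0 + win].
oracle_expected_init_accel <- function(a, lat_mu, lat_sd, gain, velocities,
                                       t0, win = 100) {
  # int Phi((t-m)/s) dt = (t-m) Phi(z) + s phi(z)
  iPhi <- function(t, m, s) {
    if (s <= 0) return(pmax(t - m, 0))
    z <- (t - m) / s
    (t - m) * stats::pnorm(z) + s * stats::dnorm(z)
  }
  mean(vapply(velocities, function(v) {
    ramp <- 1000 * gain * v / a
    on <- iPhi(t0 + win, lat_mu, lat_sd) - iPhi(t0, lat_mu, lat_sd)
    off <- iPhi(t0 + win, lat_mu + ramp, lat_sd) -
      iPhi(t0, lat_mu + ramp, lat_sd)
    a * (on - off) / win
  }, numeric(1)))
}
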