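#' Two-way repeated-measures ANOVA
#'
#' Classical univariate within-subject decomposition for a complete,
#' balanced design with one observation per (subject, A, B) cell. Each
#' effect is tested against its own effect-by-subject interaction. Partial
#' eta squared is `SS_effect / (SS_effect + SS_error_effect)`, which equals
#' `F df1 / (F df1 + df2)`.
#'
#' @param data data.frame with columns `subject`, `A`, `B`, `y` (or remap
#'   via the `subject`, `A`, `B`, `y` arguments giving column names).
#' @param subject,A,B,y Column names (defaults "subject", "A", "B", "y").
#' @param gg Apply the Greenhouse-Geisser sphericity correction to the
#'   p-values (default FALSE; the uncorrected df are always reported).
#' @return data.frame with one row per effect (A, B, A:B): `effect`, `F`,
#'   `df1`, `df2`, `p`, `partial_eta_sq` (plus `gg_epsilon`, `p_gg` when
#'   `gg = TRUE`).
#' @export
rm_anova_2way <- function(data, subject = "subject", A = "A", B = "B",
                          y = "y", gg = FALSE) {
  d <- data.frame(subject = factor(data[[subject]]),
                  A = factor(data[[A]]),
                  B = factor(data[[B]]),
                  y = as.numeric(data[[y]]))
  if (anyNA(d$y)) stop("missing cell values; rm ANOVA needs complete data")
  s <- nlevels(d$subject); a <- nlevels(d$A); b <- nlevels(d$B)
  if (nrow(d) != s * a * b) {
    stop("design must be balanced with exactly one value per ",
         "(subject, A, B) cell")
  }
  tab <- tapply(d$y, list(d$subject, d$A, d$B), mean)
  if (anyNA(tab)) stop("incomplete design: every subject needs every cell")

  gm <- mean(tab)
  m_s <- apply(tab, 1, mean); m_a <- apply(tab, 2, mean)
  m_b <- apply(tab, 3, mean)
  m_sa <- apply(tab, c(1, 2), mean); m_sb <- apply(tab, c(1, 3), mean)
  m_ab <- apply(tab, c(2, 3), mean)

  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- s * b * sum((m_a - gm)^2)
  ss_b <- s * a * sum((m_b - gm)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, m_a, "+") + gm)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, m_b, "+") + gm)^2)
  ss_ab <- s * sum((m_ab - outer(m_a, m_b, "+") + gm)^2)
  ss_tot <- sum((tab - gm)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_sa - ss_sb - ss_ab

  eff <- function(name, ss_e, df1, ss_err, df2) {
    f <- (ss_e / df1) / (ss_err / df2)
    data.frame(effect = name, F = f, df1 = df1, df2 = df2,
               p = stats::pf(f, df1, df2, lower.tail = FALSE),
               partial_eta_sq = ss_e / (ss_e + ss_err))
  }
  out <- rbind(
    eff("A", ss_a, a - 1, ss_sa, (a - 1) * (s - 1)),
    eff("B", ss_b, b - 1, ss_sb, (b - 1) * (s - 1)),
    eff("A:B", ss_ab, (a - 1) * (b - 1), ss_sab, (a - 1) * (b - 1) * (s - 1)))

  if (gg) {
    orth <- function(k) {
      q <- qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
      q
    }
    u <- function(k) matrix(1 / sqrt(k), k, 1)
    ycells <- matrix(aperm(tab, c(1, 2, 3)), nrow = s) # s x (a*b), B fastest? (A slow)
    # columns ordered with A varying fastest within B (R array order)
    S <- stats::cov(ycells)
    kron <- function(x, z) kronecker(z, x) # cell order: A fastest
    Ms <- list(`A` = kron(orth(a), u(b)),
               `B` = kron(u(a), orth(b)),
               `A:B` = kron(orth(a), orth(b)))
    eps <- vapply(Ms, function(M) {
      G <- t(M) %*% S %*% M
      (sum(diag(G)))^2 / (ncol(M) * sum(G^2))
    }, numeric(1))
    eps <- pmin(pmax(eps, 1 / out$df1), 1)
    out$gg_epsilon <- eps
    out$p_gg <- stats::pf(out$F, out$df1 * eps, out$df2 * eps,
                          lower.tail = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "ss") <- c(subject = ss_s, A = ss_a, B = ss_b, `A:S` = ss_sa,
                       `B:S` = ss_sb, `A:B` = ss_ab, `A:B:S` = ss_sab,
                       total = ss_tot)
  out
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests between all level pairs of one within-subject factor,
#' collapsing the other factor by the subject mean. Adjusted p-values are
#' the raw p multiplied by the number of comparisons, capped at 1.
#'
#' @param data data.frame with `subject`, the factor column, and `y`.
#' @param factor_col Name of the factor column.
#' @param subject,y Column names.
#' @return data.frame: level1, level2, mean_diff, t, df, p_raw, p_adjusted,
#'   n_comparisons.
#' @export
bonferroni_pairwise <- function(data, factor_col, subject = "subject",
                                y = "y") {
  d <- data.frame(subject = factor(data[[subject]]),
                  f = factor(data[[factor_col]]),
                  y = as.numeric(data[[y]]))
  cell <- tapply(d$y, list(d$subject, d$f), mean)
  lv <- colnames(cell)
  if (length(lv) < 2) stop("factor needs at least 2 levels")
  pairs <- utils::combn(lv, 2)
  k <- ncol(pairs)
  out <- lapply(seq_len(k), function(i) {
    x1 <- cell[, pairs[1, i]]; x2 <- cell[, pairs[2, i]]
    dd <- x1 - x2
    if (stats::sd(dd) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(dd) - 1),
                 p.value = 1)
    } else {
      tt <- stats::t.test(x1, x2, paired = TRUE)
    }
    data.frame(level1 = pairs[1, i], level2 = pairs[2, i],
               mean_diff = mean(dd),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_adjusted = min(1, tt$p.value * k),
               n_comparisons = k)
  })
  do.call(rbind, out)
}

#' Within-subjects correlation coefficient
#'
#' The Bland-Altman construction: remove between-subject differences by
#' treating subject as a categorical covariate, then correlate what
#' remains. Computed as the Pearson correlation of within-subject-centred
#' `x` and `y`, with `df = N - n_subjects - 1` and the usual t transform
#' for the p-value. Equivalent to the multiple-regression formulation with
#' subject dummies.
#'
#' @param x,y Numeric vectors of paired repeated measurements.
#' @param subject Subject labels, same length.
#' @return List with `r`, `df`, `t`, `p`, `n`, `n_subjects`.
#' @export
within_subject_corr <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; subject <- factor(subject[ok])
  n <- length(x); k <- nlevels(subject)
  if (k < 2 || any(table(subject) < 2)) {
    stop("need >= 2 observations per subject for >= 2 subjects")
  }
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  if (sum(xc^2) == 0) stop("x is constant within every subject")
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  df <- n - k - 1
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       n = n, n_subjects = k)
}
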