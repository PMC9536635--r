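#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' `OR = ad/bc` with a Haldane-Anscombe 0.5 correction added to every cell
#' when any cell is zero; the standard error and the 95% CI are computed on
#' the log scale.
#'
#' @param table 2x2 numeric matrix `rbind(c(a, b), c(c, d))`.
#' @param conf_level Confidence level (default 0.95).
#' @return list: or, log_or, se, ci_lower, ci_upper, corrected (logical).
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (sum(table) == 0) stop("all-zero table")
  corrected <- any(table == 0)
  t2 <- table + if (corrected) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, log_or = log(or), se = se,
       ci_lower = exp(log(or) - z * se), ci_upper = exp(log(or) + z * se),
       corrected = corrected)
}

#' Mantel-Haenszel common odds ratio
#'
#' @param tables List of 2x2 matrices.
#' @return Numeric scalar.
#' @export
mantel_haenszel_or <- function(tables) {
  num <- sum(vapply(tables, function(t) t[1, 1] * t[2, 2] / sum(t), numeric(1)))
  den <- sum(vapply(tables, function(t) t[1, 2] * t[2, 1] / sum(t), numeric(1)))
  num / den
}

# expected a-cell under a common OR, respecting the table margins:
# solves psi = E(n - r - c + E) / ((r - E)(c - E)) for the admissible root
.expected_a <- function(psi, r, c, n) {
  if (abs(psi - 1) < 1e-12) return(r * c / n)
  A <- 1 - psi
  B <- n - r - c + psi * (r + c)
  C <- -psi * r * c
  disc <- sqrt(B^2 - 4 * A * C)
  roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
  lo <- max(0, r + c - n); hi <- min(r, c)
  ok <- roots >= lo - 1e-9 & roots <= hi + 1e-9
  roots[ok][1L]
}

#' Breslow-Day homogeneity test with Tarone correction
#'
#' Tests whether the odds ratio is homogeneous across K strata. Per stratum
#' the expected a-cell under the Mantel-Haenszel common OR is the
#' margin-respecting root of the conditional quadratic; the Breslow-Day
#' statistic is `sum (a_k - E_k)^2 / V_k` and the Tarone correction
#' subtracts `(sum(a_k - E_k))^2 / sum(V_k)`. The corrected statistic is
#' referred to a chi-square with K-1 degrees of freedom. Strata with a
#' degenerate margin (empty row or column) are excluded with a warning and
#' reduce the degrees of freedom.
#'
#' @param tables List of 2x2 matrices (strata).
#' @return list: statistic (Tarone-corrected), statistic_bd (uncorrected),
#'   df, p_value, or_mh, n_strata (used).
#' @export
breslow_day_tarone <- function(tables) {
  degenerate <- vapply(tables, function(t)
    any(rowSums(t) == 0) || any(colSums(t) == 0), logical(1))
  if (any(degenerate)) {
    warning(sum(degenerate), " stratum/strata with degenerate margins excluded")
    tables <- tables[!degenerate]
  }
  K <- length(tables)
  if (K < 1L) stop("no usable strata")
  or_mh <- mantel_haenszel_or(tables)
  if (K == 1L)
    return(list(statistic = 0, statistic_bd = 0, df = 0L, p_value = NA_real_,
                or_mh = or_mh, n_strata = 1L))
  a <- vapply(tables, function(t) t[1, 1], numeric(1))
  E <- V <- numeric(K)
  for (k in seq_len(K)) {
    t <- tables[[k]]
    r <- sum(t[1, ]); c <- sum(t[, 1]); n <- sum(t)
    E[k] <- .expected_a(or_mh, r, c, n)
    V[k] <- 1 / (1 / E[k] + 1 / (r - E[k]) + 1 / (c - E[k]) +
                   1 / (n - r - c + E[k]))
  }
  bd <- sum((a - E)^2 / V)
  tarone <- bd - sum(a - E)^2 / sum(V)
  df <- K - 1L
  list(statistic = tarone, statistic_bd = bd, df = df,
       p_value = stats::pchisq(tarone, df, lower.tail = FALSE),
       or_mh = or_mh, n_strata = K)
}
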