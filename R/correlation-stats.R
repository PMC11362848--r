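# Correlation and group-comparison statistics applied to density vectors
# and cross tables: Kendall tau-b with tie correction, Pearson, a
# Shapiro-Wilk normality gate driving the method choice, Fisher's exact
# test for 2x2 tables, ANOVA with Bonferroni-adjusted pairwise t-tests,
# and 2D-histogram summaries of paired densities.

correlation_result <- function(method, estimate, p_value, n) {
  structure(list(method = method, estimate = estimate,
                 p_value = p_value, n = n),
            class = "correlation_result")
}

# strict inversions (i < j with v[i] > v[j]) by bottom-up merge counting
count_inversions <- function(v) {
  n <- length(v)
  if (n < 2) return(0)
  inv <- 0
  width <- 1L
  arr <- v
  while (width < n) {
    starts <- seq(1L, n, by = 2L * width)
    for (start in starts) {
      mid <- start + width - 1L
      if (mid >= n) next
      end <- min(start + 2L * width - 1L, n)
      L <- arr[start:mid]
      R <- arr[(mid + 1L):end]
      inv <- inv + sum(length(L) - findInterval(R, L))
      arr[start:end] <- sort.int(c(L, R))
    }
    width <- 2L * width
  }
  inv
}

tie_run_lengths <- function(sorted_is_new) {
  w <- which(sorted_is_new)
  diff(c(w, length(sorted_is_new) + 1L))
}

# S = n_c - n_d plus tie-group sizes, O(n log n) via sort + merge counting
kendall_S <- function(x, y) {
  n <- length(x)
  ord <- order(x, y)
  xs <- x[ord]; ys <- y[ord]
  dis <- count_inversions(ys)
  tx <- tie_run_lengths(c(TRUE, xs[-1] != xs[-n]))
  ty <- tie_run_lengths(c(TRUE, sort(y)[-1] != sort(y)[-n]))
  txy <- tie_run_lengths(c(TRUE, xs[-1] != xs[-n] | ys[-1] != ys[-n]))
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  n3 <- sum(txy * (txy - 1) / 2)
  list(n = n, S = n0 - n1 - n2 + n3 - 2 * dis,
       n0 = n0, n1 = n1, n2 = n2,
       tie_x = tx[tx > 1], tie_y = ty[ty > 1])
}

#' Kendall tau-b rank correlation
#'
#' Tau-b with tie correction:
#' tau_b = (n_c - n_d) / sqrt((n0 - n1)(n0 - n2)) with n0 = n(n-1)/2 and
#' n1, n2 the tie corrections of each margin. The p-value uses the exact
#' permutation null for n <= `exact_limit` (full enumeration of the n!
#' pairings) and the tie-adjusted normal approximation of S = n_c - n_d
#' otherwise.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @param exact_limit largest n for exact permutation enumeration
#'   (default 8; factorial cost above that).
#' @return a `correlation_result` (method "kendall_tau_b"); the estimate
#'   is NA with a warning when either vector is constant.
#' @export
kendall_tau_b <- function(x, y, exact_limit = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("all-tied vector: tau undefined")
    return(correlation_result("kendall_tau_b", NA_real_, NA_real_, n))
  }
  kc <- kendall_S(x, y)
  tau <- kc$S / sqrt((kc$n0 - kc$n1) * (kc$n0 - kc$n2))
  if (n <= exact_limit) {
    # exact permutation null of |S| over all n! pairings
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- sequence((n - 1):1) + i
    dx <- sign(x[j] - x[i])
    s_of <- function(yy) sum(dx * sign(yy[j] - yy[i]))
    perms <- permutations_of(n)
    s_obs <- abs(kc$S)
    s_null <- abs(apply(perms, 1, function(p) s_of(y[p])))
    p <- mean(s_null >= s_obs)
  } else {
    # tie-adjusted variance of S (normal approximation)
    tx <- as.numeric(kc$tie_x); ty <- as.numeric(kc$tie_y)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    z <- kc$S / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  correlation_result("kendall_tau_b", tau, min(p, 1), n)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Pearson correlation
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a `correlation_result` (method "pearson").
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ct <- stats::cor.test(x, y, method = "pearson")
  correlation_result("pearson", unname(ct$estimate), ct$p.value,
                     sum(stats::complete.cases(x, y)))
}

#' Normality gate for the correlation method choice
#'
#' Shapiro-Wilk at alpha: "normal" iff p > alpha, which routes a variable
#' to Pearson; "non_normal" routes to Kendall tau-b. Samples above 5000
#' observations (the test's limit) are thinned to 5000 evenly spaced order
#' statistics, which is order-invariant and deterministic.
#'
#' @param x numeric vector, n >= 3, non-constant.
#' @param alpha significance level of the gate (default 0.05).
#' @return "normal" or "non_normal", with attributes `p_value` and `n`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2) stop("constant vector: normality undefined")
  xs <- x
  if (length(xs) > 5000) {
    xs <- sort(xs)[round(seq(1, length(xs), length.out = 5000))]
  }
  p <- stats::shapiro.test(xs)$p.value
  structure(if (p > alpha) "normal" else "non_normal",
            p_value = p, n = length(x))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing the hypergeometric probabilities of all
#' tables (at fixed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative counts with non-degenerate
#'   margins.
#' @return the p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate margin: a row or column of the 2x2 table is zero")
  }
  stats::fisher.test(table)$p.value
}

#' Hypergeometric enumeration oracle for the 2x2 exact test
#'
#' Direct enumeration of the conditional null: sums dhyper probabilities
#' of all tables with the observed margins whose probability does not
#' exceed the observed table's. Kept as an independent cross-check of
#' [fisher_exact_2x2()].
#'
#' @inheritParams fisher_exact_2x2
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2_enum <- function(table) {
  table <- as.matrix(table)
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(table[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Group comparison: ANOVA plus Bonferroni pairwise t-tests
#'
#' One-way ANOVA across groups followed by all pairwise t-tests with
#' Bonferroni adjustment (adjusted p = min(1, raw p x number of
#' comparisons)).
#'
#' @param values numeric response vector.
#' @param groups categorical group labels (>= 2 groups).
#' @return list with `anova_p`, `pairwise_p` (adjusted p matrix from
#'   [stats::pairwise.t.test()]), `n`.
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  fit <- stats::aov(values ~ groups)
  a_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = FALSE)
  list(anova_p = a_p, pairwise_p = pw$p.value, n = length(values))
}

#' Correlate two density columns of a cortex pixel table
#'
#' Applies the normality gate to both variables (Pearson only when both
#' pass) and returns the correlation together with a 2D histogram of the
#' paired densities — the standard summary plot for pixel-level density
#' couplings.
#'
#' @param table data.frame (e.g. from [extract_cortex_vectors()]).
#' @param var_x,var_y column names.
#' @param bins number of histogram bins per axis (default 50).
#' @param alpha normality-gate level (default 0.05).
#' @return list with `result` (a `correlation_result`), `histogram`
#'   (bins x bins count matrix, rows = x bins), `x_edges`, `y_edges`.
#' @export
density_correlation <- function(table, var_x, var_y, bins = 50, alpha = 0.05) {
  stopifnot(var_x %in% names(table), var_y %in% names(table))
  x <- table[[var_x]]; y <- table[[var_y]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  gate_x <- normality_gate(x, alpha)
  gate_y <- normality_gate(y, alpha)
  res <- if (gate_x == "normal" && gate_y == "normal") {
    pearson_r(x, y)
  } else {
    kendall_tau_b(x, y)
  }
  xe <- seq(min(x), max(x), length.out = bins + 1)
  ye <- seq(min(y), max(y), length.out = bins + 1)
  xi <- pmin(findInterval(x, xe, rightmost.closed = TRUE), bins)
  yi <- pmin(findInterval(y, ye, rightmost.closed = TRUE), bins)
  hist <- matrix(0L, bins, bins)
  tab <- table(factor(xi, levels = seq_len(bins)),
               factor(yi, levels = seq_len(bins)))
  hist[] <- as.integer(tab)
  list(result = res, histogram = hist, x_edges = xe, y_edges = ye,
       gates = c(x = unclass(gate_x), y = unclass(gate_y)))
}

#' Exhaustive pair-count oracle for Kendall tau-b
#'
#' O(n^2) direct enumeration of concordant, discordant and tied pairs —
#' definitionally computes tau-b without the shortcuts of
#' [kendall_tau_b()]; used as its independent oracle.
#'
#' @param x,y equal-length numeric vectors.
#' @return tau-b, or NA for a constant margin.
#' @export
kendall_tau_b_oracle <- function(x, y) {
  n <- length(x)
  nc <- 0L; nd <- 0L; tx <- 0L; ty <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) { tx <- tx + 1L; ty <- ty + 1L }
      else if (dx == 0) tx <- tx + 1L
      else if (dy == 0) ty <- ty + 1L
      else if (sign(dx) == sign(dy)) nc <- nc + 1L
      else nd <- nd + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (nc - nd) / den
}
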