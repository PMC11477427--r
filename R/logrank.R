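# Log-rank machinery: two-group statistic, vectorized evaluation over many
# carrier-label assignments, k-group statistic, and the conditional
# permutation p-value used for sparse carrier groups.

# Precompute the risk-set structure shared by all group assignments:
# distinct event times, events per time (d), numbers at risk (n), the
# at-risk incidence matrix R (times x samples) and the event incidence
# matrix E (times x samples).
.logrank_prep <- function(time, event) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0) stop("no events: log-rank statistic undefined.", call. = FALSE)
  R <- outer(et, time, function(t, s) as.numeric(s >= t))
  E <- outer(et, time, function(t, s) as.numeric(s == t)) *
    rep(event, each = length(et))
  d <- rowSums(E)
  n <- rowSums(R)
  list(event_times = et, d = d, n = n, R = R, E = E)
}

# Vectorized two-group log-rank over columns of a carrier indicator matrix G
# (samples x assignments). Returns chi-square statistics and signed
# observed-minus-expected scores for the carrier group.
.logrank_stats <- function(prep, G) {
  N1 <- prep$R %*% G                       # carriers at risk per event time
  D1 <- prep$E %*% G                       # carrier events per event time
  frac <- N1 / prep$n
  score <- colSums(D1 - prep$d * frac)
  vfac <- ifelse(prep$n > 1, prep$d * (prep$n - prep$d) / (prep$n - 1), 0)
  v <- colSums(vfac * frac * (1 - frac))
  stat <- ifelse(v > 0, score^2 / v, 0)
  list(statistic = stat, score = score, variance = v)
}

#' Two-group log-rank statistic
#'
#' Computes the classical 1-degree-of-freedom log-rank chi-square comparing
#' carriers (`group == 1`) against non-carriers, together with the signed
#' observed-minus-expected event score of the carrier group (positive when
#' carriers die faster than expected) and its hypergeometric variance.
#'
#' @param time Numeric vector of follow-up times (days).
#' @param event Binary vector, 1 = death observed, 0 = censored.
#' @param group Binary carrier indicator of the same length.
#' @return A one-row tibble with `statistic`, `score`, `variance`,
#'   `p_asymptotic` (chi-square with 1 df).
#' @export
logrank_statistic <- function(time, event, group) {
  group <- as.numeric(group)
  stopifnot(all(group %in% c(0, 1)))
  k <- sum(group)
  if (k == 0 || k == length(group)) {
    stop("log-rank needs two non-empty groups.", call. = FALSE)
  }
  prep <- .logrank_prep(time, event)
  st <- .logrank_stats(prep, matrix(group, ncol = 1))
  tibble::tibble(statistic = st$statistic, score = st$score,
                 variance = st$variance,
                 p_asymptotic = stats::pchisq(st$statistic, df = 1,
                                              lower.tail = FALSE))
}

#' Conditional permutation p-value for a sparse carrier group
#'
#' Calibrates the two-group log-rank statistic against its conditional null
#' distribution obtained by reassigning the `k` carrier labels among the `n`
#' samples, holding `k` fixed. The large-sample chi-square reference is
#' unreliable when carrier groups are heavily unbalanced (a handful of
#' carriers among hundreds of patients), which is the typical regime for
#' recurrent copy-number alterations; the permutation null is exact in
#' distribution under exchangeability.
#'
#' When the number of distinct carrier subsets `choose(n, k)` is at most
#' `exhaustive_threshold`, all subsets are enumerated and the p-value is the
#' exact conditional tail probability. Otherwise `n_perm` Monte Carlo draws
#' are used with the add-one correction
#' `p = (1 + #\{stat_perm >= stat_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams logrank_statistic
#' @param n_perm Number of Monte Carlo permutations.
#' @param seed Optional integer seed applied locally for the Monte Carlo
#'   draws (the RNG state of the session is restored afterwards).
#' @param exhaustive_threshold Enumerate all carrier subsets when
#'   `choose(n, k)` does not exceed this value.
#' @return A one-row tibble with `p_value`, `statistic`, `score`, `method`
#'   (`"exhaustive"` or `"monte_carlo"`) and `n_null` (size of the null
#'   sample).
#' @export
permutation_pvalue <- function(time, event, group, n_perm = 10000,
                               seed = NULL, exhaustive_threshold = 25000) {
  group <- as.numeric(group)
  n <- length(group)
  k <- sum(group)
  if (k == 0 || k == n) stop("carrier group must be non-empty and proper.", call. = FALSE)
  prep <- .logrank_prep(time, event)
  obs <- .logrank_stats(prep, matrix(group, ncol = 1))
  tol <- 1e-12
  if (choose(n, k) <= exhaustive_threshold) {
    sets <- utils::combn(n, k)
    G <- matrix(0, nrow = n, ncol = ncol(sets))
    G[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = k))] <- 1
    stats_null <- .logrank_stats(prep, G)$statistic
    p <- mean(stats_null >= obs$statistic - tol)
    method <- "exhaustive"
    n_null <- ncol(sets)
  } else {
    draw <- function() {
      idx <- vapply(seq_len(n_perm), function(i) sample.int(n, k),
                    integer(k))
      G <- matrix(0, nrow = n, ncol = n_perm)
      G[cbind(as.vector(idx), rep(seq_len(n_perm), each = k))] <- 1
      .logrank_stats(prep, G)$statistic
    }
    stats_null <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    p <- (1 + sum(stats_null >= obs$statistic - tol)) / (1 + n_perm)
    method <- "monte_carlo"
    n_null <- n_perm
  }
  tibble::tibble(p_value = p, statistic = obs$statistic, score = obs$score,
                 method = method, n_null = n_null)
}

#' Multi-group log-rank test
#'
#' The k-group log-rank chi-square with k-1 degrees of freedom, computed
#' from per-time observed-minus-expected event counts and their
#' hypergeometric covariance. On two groups it coincides exactly with
#' [logrank_statistic()].
#'
#' @inheritParams logrank_statistic
#' @param labels Group labels (character or factor); `NA` labels are dropped.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `n_groups`.
#' @export
multigroup_logrank <- function(time, event, labels) {
  keep <- !is.na(labels)
  time <- time[keep]; event <- event[keep]
  labels <- factor(as.character(labels)[keep])
  lev <- levels(labels)
  if (length(lev) < 2 || sum(event) == 0) {
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p_value = NA_real_, n_groups = length(lev)))
  }
  prep <- .logrank_prep(time, event)
  Gfull <- vapply(lev, function(l) as.numeric(labels == l),
                  numeric(length(time)))
  N <- prep$R %*% Gfull                      # at risk per group per time
  D <- prep$E %*% Gfull                      # events per group per time
  frac <- N / prep$n
  oe <- colSums(D - prep$d * frac)
  vfac <- ifelse(prep$n > 1, prep$d * (prep$n - prep$d) / (prep$n - 1), 0)
  m <- length(lev) - 1
  V <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(a)) {
      delta <- as.numeric(a == b)
      V[a, b] <- V[b, a] <- sum(vfac * frac[, a] * (delta - frac[, b]))
    }
  }
  qrV <- qr(V)
  df <- qrV$rank
  stat <- if (df == m) {
    drop(t(oe[seq_len(m)]) %*% solve(V, oe[seq_len(m)]))
  } else {
    # singular covariance (e.g. a group never at risk with others): use a
    # generalized inverse
    ev <- eigen(V, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    Vinv <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    drop(t(oe[seq_len(m)]) %*% Vinv %*% oe[seq_len(m)])
  }
  tibble::tibble(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
                 n_groups = length(lev))
}
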