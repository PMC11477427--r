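# Independent reference implementations used as oracles. These deliberately
# follow the textbook definitions step by step (no shared code with the
# package internals).

# Textbook two-group log-rank: loop over distinct event times, accumulate
# observed-minus-expected events in group 1 and the hypergeometric variance.
oracle_logrank <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(score = O1 - E1, variance = V, statistic = (O1 - E1)^2 / V)
}

# Exact conditional permutation p-value by enumerating carrier subsets.
oracle_exhaustive_p <- function(time, event, k) {
  n <- length(time)
  sets <- utils::combn(n, k)
  stats <- apply(sets, 2, function(idx) {
    g <- integer(n); g[idx] <- 1L
    oracle_logrank(time, event, g)$statistic
  })
  function(obs) mean(stats >= obs - 1e-12)
}

# Hand product-limit estimator (no censoring adjustment shortcuts).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Small deterministic cohort used across IO/mode tests: 6 genes x 8 samples
# with hand-chosen calls.
toy_cna <- function() {
  vals <- rbind(
    c(-2, -1,  0,  0,  1,  2,  0,  0),   # mixed
    c( 0,  0,  0,  0,  0,  0,  0,  0),   # silent
    c(-1, -1, -1, -1, -2,  0,  0,  0),   # deletion-heavy (5 soft, 1 deep)
    c( 2,  2,  2,  2,  2,  1,  1,  0),   # amplification-heavy
    c( 0, -2, -2, -2, -2,  0,  0,  0),   # deep deletions x4
    c( 1,  0,  0,  0,  0,  0,  0,  1))   # rare soft amp x2
  cna_matrix(vals,
             gene_ids = paste0("G", 1:6),
             sample_ids = paste0("S", 1:8))
}

toy_clinical <- function() {
  tibble::tibble(
    sample_id = paste0("S", 1:8),
    time = c(100, 200, 350, 400, 500, 650, 800, 900),
    event = c(1, 1, 0, 1, 1, 0, 1, 0),
    stage = c("i", "ii", "i", "ii", "i", "ii", "i", "ii"))
}
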