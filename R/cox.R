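#' Univariate Cox log hazard ratio for a binary alteration indicator
#'
#' Fits `Surv(time, event) ~ group` by maximum partial likelihood and
#' returns the log hazard ratio of carrying the alteration. A positive
#' coefficient means carriers are at higher risk. Monotone-likelihood fits
#' (e.g. all events on one side, so the partial likelihood has no interior
#' maximum) are detected and the coefficient is clamped at
#' `+/- beta_ceiling` so that downstream coefficient sums stay finite.
#'
#' @inheritParams logrank_statistic
#' @param ties Tie-handling method passed to [survival::coxph()]
#'   (`"efron"` default, or `"breslow"`).
#' @param beta_ceiling Absolute clamp applied to monotone/diverging fits.
#' @return A one-row tibble with `beta`, `se`, `p_value` (likelihood-ratio),
#'   `monotone` and `converged`.
#' @export
cox_beta <- function(time, event, group, ties = c("efron", "breslow"),
                     beta_ceiling = 10) {
  ties <- match.arg(ties)
  group <- as.numeric(group)
  k <- sum(group)
  if (k == 0 || k == length(group)) {
    stop("carrier group must be non-empty and proper.", call. = FALSE)
  }
  dat <- data.frame(time = time, event = event, g = group)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, data = dat, ties = ties),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  converged <- is.finite(beta) && is.finite(se)
  monotone <- warned || !converged || abs(beta) > beta_ceiling
  if (!is.finite(beta)) beta <- 0
  if (monotone && abs(beta) > beta_ceiling) {
    beta <- sign(beta) * beta_ceiling
  }
  lr <- 2 * diff(fit$loglik)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  tibble::tibble(beta = beta, se = se, p_value = p,
                 monotone = monotone, converged = converged)
}

# Deterministic per-gene seed derived from the pipeline seed and the gene
# identifier, so per-gene Monte Carlo p-values are reproducible regardless
# of gene order or matrix subsetting.
.gene_seed <- function(seed, gene_id) {
  h <- 0
  for (v in utf8ToInt(gene_id)) h <- (h * 31 + v) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483629)
}
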