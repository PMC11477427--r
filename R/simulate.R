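# Synthetic GISTIC-style cohorts with planted prognostic CNA structure.

#' Configure a synthetic CNA cohort
#'
#' Defines the generative model for a synthetic cohort: a sparse
#' gene-by-sample matrix of integer GISTIC calls with a set of *planted*
#' gene regions whose carriage shifts the hazard, right-censored survival
#' times under proportional hazards, and clinical cofactors.
#'
#' Background gene regions receive Beta-distributed carrier fractions
#' (mass concentrated around 2-10% of samples, mimicking the sparsity of
#' recurrent CNAs), a random sign (amplified or deleted region) and a
#' `deep_frac` admixture of deep calls among altered cells. Planted genes
#' carry their mode's own call for an exact, without-replacement draw of
#' `round(carrier_frac * n_samples)` carriers: deep modes plant ±2; soft
#' modes plant ±1 with a `deep_frac` admixture of ±2.
#'
#' Survival times are exponential with hazard
#' `h0 * exp(sum(beta * carrier) + cofactor effects)`; censoring combines an
#' independent exponential dropout with an administrative horizon.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param planted Tibble with one row per planted gene: `mode` (one of the
#'   four alteration modes), `beta` (true log hazard ratio) and
#'   `carrier_frac`. The default plants five deep-amplification high-risk
#'   genes at beta = 1.5 carried by 8% of samples.
#' @param bg_shape1,bg_shape2 Beta parameters of background carrier
#'   fractions (default Beta(2, 40), mean ~4.8%).
#' @param deep_frac Fraction of deep (±2) calls among altered background
#'   cells and among soft planted carriers.
#' @param baseline_rate Baseline exponential hazard per day (default:
#'   median survival of 3 years).
#' @param censor_rate Exponential dropout hazard per day.
#' @param horizon Administrative censoring horizon in days.
#' @param cofactors Tibble with columns `name`, `type` (`"categorical"` or
#'   `"numeric"`) plus generation/effect fields; see the default for the
#'   expected shape. Use `NULL` for none.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 300, n_genes = 200,
                              planted = default_planted(),
                              bg_shape1 = 2, bg_shape2 = 40,
                              deep_frac = 0.3,
                              baseline_rate = log(2) / 1095,
                              censor_rate = 1 / 2000,
                              horizon = 3650,
                              cofactors = default_cofactors(),
                              seed = 1) {
  stopifnot(n_samples > 0, n_genes >= nrow(planted))
  if (nrow(planted) > 0) {
    stopifnot(all(planted$mode %in% .cna_modes),
              all(is.finite(planted$beta)),
              all(planted$carrier_frac > 0 & planted$carrier_frac < 1))
    if (any(round(planted$carrier_frac * n_samples) < 1)) {
      stop("infeasible config: planted carrier_frac * n_samples < 1.",
           call. = FALSE)
    }
  }
  structure(list(n_samples = n_samples, n_genes = n_genes, planted = planted,
                 bg_shape1 = bg_shape1, bg_shape2 = bg_shape2,
                 deep_frac = deep_frac, baseline_rate = baseline_rate,
                 censor_rate = censor_rate, horizon = horizon,
                 cofactors = cofactors, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default planted-gene scenario
#'
#' Five deep-amplification gene regions with true log hazard ratio 1.5,
#' each carried by 8% of samples.
#' @return A tibble with columns `mode`, `beta`, `carrier_frac`.
#' @export
default_planted <- function() {
  tibble::tibble(mode = "deep_amp", beta = 1.5, carrier_frac = 0.08,
                 .rows = 5)
}

#' Default clinical cofactor specification
#'
#' Sex (no hazard effect), age (normal around 63, +0.01 log hazard per
#' year above 60) and stage (i/ii/iii_iv with increasing hazard).
#' @return A tibble describing the cofactors.
#' @export
default_cofactors <- function() {
  tibble::tibble(
    name = c("sex", "age", "stage"),
    type = c("categorical", "numeric", "categorical"),
    levels = list(c("female", "male"), NULL, c("i", "ii", "iii_iv")),
    probs = list(c(0.5, 0.5), NULL, c(0.4, 0.35, 0.25)),
    mean = c(NA, 63, NA), sd = c(NA, 10, NA),
    effects = list(c(0, 0), 0.01, c(0, 0.25, 0.5)))
}

#' Simulate a GISTIC-style cohort with planted prognostic alterations
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `cna_cohort_sim` with `cna` (a [cna_matrix()]),
#'   `clinical` (tibble: `sample_id`, `time`, `event`, cofactors), `truth`
#'   (list: `genes` — planted genes with true betas and carrier counts;
#'   `samples` — per-sample true linear predictor and risk stratum) and
#'   `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, .simulate_cohort_impl(cfg))
}

.simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  p <- cfg$n_genes
  sample_ids <- sprintf("SIM-%04d-01", seq_len(n))
  n_planted <- nrow(cfg$planted)
  gene_ids <- c(sprintf("PLT%03d", seq_len(n_planted)),
                sprintf("BG%04d", seq_len(p - n_planted)))
  C <- matrix(0L, nrow = p, ncol = n, dimnames = list(gene_ids, sample_ids))
  lp <- numeric(n)
  truth_genes <- NULL
  if (n_planted > 0) {
    plant_val <- c(soft_del = -1L, deep_del = -2L,
                   soft_amp = 1L, deep_amp = 2L)
    deep_val <- c(soft_del = -2L, deep_del = -2L,
                  soft_amp = 2L, deep_amp = 2L)
    carriers_list <- vector("list", n_planted)
    for (i in seq_len(n_planted)) {
      mode_i <- cfg$planted$mode[i]
      k <- round(cfg$planted$carrier_frac[i] * n)
      carriers <- sample.int(n, k)        # exact count, without replacement
      val <- rep(plant_val[[mode_i]], k)
      if (startsWith(mode_i, "soft")) {
        val[stats::runif(k) < cfg$deep_frac] <- deep_val[[mode_i]]
      }
      C[i, carriers] <- val
      lp[carriers] <- lp[carriers] + cfg$planted$beta[i]
      carriers_list[[i]] <- carriers
    }
    truth_genes <- dplyr::mutate(cfg$planted,
                                 gene_id = gene_ids[seq_len(n_planted)],
                                 n_carriers = lengths(carriers_list),
                                 .before = 1)
  }
  # background regions: sparse, random sign, deep admixture, no effect
  if (p > n_planted) {
    for (i in seq.int(n_planted + 1, p)) {
      f <- stats::rbeta(1, cfg$bg_shape1, cfg$bg_shape2)
      k <- stats::rbinom(1, n, f)
      if (k == 0) next
      carriers <- sample.int(n, k)
      sgn <- sample(c(-1L, 1L), 1)
      depth <- ifelse(stats::runif(k) < cfg$deep_frac, 2L, 1L)
      C[i, carriers] <- sgn * depth
    }
  }
  # clinical cofactors and their hazard contributions
  clin <- tibble::tibble(sample_id = sample_ids)
  planted_lp <- lp
  if (!is.null(cfg$cofactors) && nrow(cfg$cofactors) > 0) {
    for (i in seq_len(nrow(cfg$cofactors))) {
      cf <- cfg$cofactors[i, ]
      if (cf$type == "categorical") {
        lev <- cf$levels[[1]]
        x <- sample(lev, n, replace = TRUE, prob = cf$probs[[1]])
        clin[[cf$name]] <- x
        lp <- lp + cf$effects[[1]][match(x, lev)]
      } else {
        x <- stats::rnorm(n, cf$mean, cf$sd)
        clin[[cf$name]] <- round(x, 1)
        lp <- lp + cf$effects[[1]] * (x - cf$mean)
      }
    }
  }
  t_event <- stats::rexp(n, rate = cfg$baseline_rate * exp(lp))
  t_cens <- pmin(stats::rexp(n, rate = cfg$censor_rate), cfg$horizon)
  clin <- dplyr::mutate(clin,
                        time = round(pmin(t_event, t_cens), 1),
                        event = as.numeric(t_event <= t_cens),
                        .after = "sample_id")
  truth_samples <- tibble::tibble(
    sample_id = sample_ids, linear_predictor = planted_lp,
    risk_stratum = dplyr::case_when(planted_lp > 0 ~ "high",
                                    planted_lp < 0 ~ "low",
                                    TRUE ~ "none"))
  structure(list(cna = cna_matrix(C), clinical = clin,
                 truth = list(genes = truth_genes, samples = truth_samples),
                 config = cfg),
            class = c("cna_cohort_sim", "cna_cohort"))
}

#' @export
print.cna_cohort_sim <- function(x, ...) {
  cat(sprintf("<cna_cohort_sim> %d samples x %d gene regions, %d planted, %.0f%% events\n",
              ncol(x$cna$values), nrow(x$cna$values),
              if (is.null(x$truth$genes)) 0 else nrow(x$truth$genes),
              100 * mean(x$clinical$event)))
  invisible(x)
}

#' Coerce a simulated cohort to the analysis cohort structure
#'
#' @param sim A `cna_cohort_sim` from [simulate_cohort()].
#' @return A `cna_cohort` usable by [build_all_models()].
#' @export
as_cohort <- function(sim) {
  structure(list(cna = sim$cna, clinical = sim$clinical,
                 n = nrow(sim$clinical)),
            class = "cna_cohort")
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Emits the GISTIC-dialect matrix TSV, the clinical TSV, the planted-gene
#' truth TSV and a JSON manifest recording the configuration, the seed and
#' an MD5 hash per file. Two runs of the same configuration produce
#' byte-identical files.
#'
#' @param sim A `cna_cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cna = file.path(dir, "all_thresholded_by_genes.txt"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth_genes.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_gistic_thresholded(sim$cna, paths[["cna"]])
  readr::write_tsv(sim$clinical, paths[["clinical"]], progress = FALSE)
  truth <- sim$truth$genes
  if (is.null(truth)) {
    truth <- tibble::tibble(gene_id = character(), mode = character(),
                            beta = numeric(), carrier_frac = numeric(),
                            n_carriers = integer())
  }
  readr::write_tsv(truth, paths[["truth"]], progress = FALSE)
  cfg <- sim$config
  cfg_json <- list(
    n_samples = cfg$n_samples, n_genes = cfg$n_genes,
    planted = cfg$planted, bg_shape1 = cfg$bg_shape1,
    bg_shape2 = cfg$bg_shape2, deep_frac = cfg$deep_frac,
    baseline_rate = cfg$baseline_rate, censor_rate = cfg$censor_rate,
    horizon = cfg$horizon, seed = cfg$seed)
  manifest <- list(
    config = cfg_json,
    files = as.list(unname(tools::md5sum(paths[c("cna", "clinical", "truth")]))))
  names(manifest$files) <- basename(paths[c("cna", "clinical", "truth")])
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
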