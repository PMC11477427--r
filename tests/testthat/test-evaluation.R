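# Kaplan-Meier curves, model ranking, stratification, multivariate Cox.

test_that("KM estimator matches the closed form without censoring", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1), rep("A", 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km2 <- km_curve(c(5, 6, 7), c(0, 0, 0), rep("A", 3))
  expect_true(all(km2$surv == 1))
})

test_that("KM estimator matches a hand product-limit table with censoring", {
  clin <- toy_clinical()   # 8 samples, mixed events/censoring
  km <- km_curve(clin$time, clin$event, rep("all", 8))
  ref <- oracle_km(clin$time, clin$event)
  got <- km[km$n_event > 0, c("time", "surv")]
  expect_equal(got$time, ref$time)
  expect_equal(got$surv, ref$surv, tolerance = 1e-12)
  # per-group curves are non-increasing and bounded by 1
  g <- c(1, 0, 1, 0, 1, 0, 0, 1)
  km3 <- km_curve(clin$time, clin$event, ifelse(g == 1, "carrier", "other"))
  for (grp in unique(km3$group)) {
    s <- km3$surv[km3$group == grp]
    expect_true(all(diff(s) <= 0) && all(s <= 1) && all(s >= 0))
  }
})

test_that("three planted hazard strata are detected with high power", {
  withr::with_seed(606, {
    hits <- replicate(30, {
      n <- 300
      lab <- sample(c("hi", "mid", "lo"), n, replace = TRUE)
      hr <- c(hi = 2, mid = 1, lo = 0.5)[lab]
      time <- rexp(n, log(2) / 1000 * hr)
      event <- as.numeric(time <= pmin(rexp(n, 1 / 2000), 3650))
      time <- pmin(time, pmin(rexp(n, 1 / 2000), 3650))
      multigroup_logrank(time, event, lab)$p_value < 0.001
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("rank_models prefers significant, distinguishable models", {
  sim <- simulate_cohort(simulation_config(seed = 77))
  ms <- build_all_models(as_cohort(sim), engine = "asymptotic", seed = 77)
  rk <- rank_models(ms)
  expect_equal(nrow(rk$ranking), 8)
  expect_identical(rk$ranking$model_id[1], rk$selected)
  expect_true(rk$ranking$distinguishable[1])
  # ranking is a total order: re-running gives the identical table
  expect_identical(rk$ranking, rank_models(ms)$ranking)
  # penalized models never outrank a distinguishable one
  d <- rk$ranking$distinguishable
  expect_true(all(diff(as.integer(!d)) >= 0))
  # every occupied group of the selected model clears the size floor
  sel_groups <- ms$reports$groups[[
    match(rk$selected, ms$reports$model_id)]]
  expect_true(all(sel_groups$n >= 0.02 * nrow(ms$clinical)))
})

test_that("ties in significance break by fewer groups then fixed model order", {
  # two fabricated reports with identical p: 2-group model must precede
  clin <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                         time = rep(c(100, 200, 300, 400), 10),
                         event = rep(c(1, 1, 0, 1), 10))
  lab2 <- rep(c("H", "NA"), 20)
  lab3 <- rep(c("H", "L", "NA", "NA"), 10)
  ms <- structure(list(
    assignments = dplyr::bind_rows(
      tibble::tibble(sample_id = clin$sample_id, model_id = "maxsum_deep",
                     label = lab2),
      tibble::tibble(sample_id = clin$sample_id,
                     model_id = "combinations_deep", label = lab3)),
    reports = dplyr::bind_rows(
      cnarisk:::evaluate_model("maxsum_deep", lab2, clin),
      cnarisk:::evaluate_model("combinations_deep", lab3, clin)),
    clinical = clin), class = "cna_model_set")
  ms$reports$p_value <- c(0.2, 0.2)   # force the tie
  rk <- rank_models(ms, min_group_frac = 0, pairwise_alpha = 1)
  expect_identical(as.character(rk$ranking$model_id[1]), "maxsum_deep")
})

test_that("stratified analysis recovers a cofactor-independent risk effect", {
  withr::with_seed(909, {
    n <- 600
    lab <- sample(c("H", "L", "NA"), n, replace = TRUE,
                  prob = c(0.3, 0.3, 0.4))
    sexes <- sample(c("f", "m"), n, replace = TRUE)
    lp <- c(H = 1.2, L = -0.8, "NA" = 0)[lab]
    time <- rexp(n, log(2) / 1000 * exp(lp))
    event <- as.numeric(time <= 2500)
    time <- pmin(time, 2500)
    surv <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                           time = time, event = event, sex = sexes)
    assignment <- tibble::tibble(sample_id = surv$sample_id, label = lab)
  })
  rep <- stratified_analysis(assignment, surv, "sex")
  expect_setequal(unique(rep$stratum), c("f", "m"))
  h <- dplyr::filter(rep, term == "H")
  expect_true(all(h$significant))
  expect_true(all(h$beta > 0))
  # CI contains the point estimate
  expect_true(all(rep$ci_low <= rep$beta & rep$beta <= rep$ci_high))
  # stratified betas agree with the unstratified fit within CI overlap
  overall <- multivariate_cox(assignment, surv, cofactors = character(0))
  bh <- overall$beta[overall$term == "risk_group_H"]
  expect_true(all(h$ci_low <= bh & bh <= h$ci_high))
})

test_that("a stratum where one risk group has no events is non-estimable", {
  surv <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:30),
    time = c(rep(2000, 10), rexp(20, 1 / 500)),
    event = c(rep(0, 10), rep(1, 20)),   # L group: zero events
    grp = "only")
  assignment <- tibble::tibble(sample_id = surv$sample_id,
                               label = c(rep("L", 10), rep("H", 10),
                                         rep("NA", 10)))
  rep <- stratified_analysis(assignment, surv, "grp")
  expect_false(rep$estimable[rep$term == "L"])
  expect_true(rep$estimable[rep$term == "H"])
})

test_that("numeric cofactors are dichotomized and level maps merge strata", {
  withr::with_seed(22, {
    surv <- tibble::tibble(sample_id = sprintf("s%03d", 1:200),
                           time = rexp(200, 1 / 800),
                           event = rbinom(200, 1, 0.8),
                           age = rnorm(200, 60, 12),
                           t_stage = sample(c("T1", "T2", "T3", "T4"), 200,
                                            replace = TRUE))
    assignment <- tibble::tibble(sample_id = surv$sample_id,
                                 label = sample(c("H", "L", "NA"), 200,
                                                replace = TRUE))
  })
  rep_age <- stratified_analysis(assignment, surv, "age", age_cut = 60)
  expect_setequal(unique(rep_age$stratum), c("<60", ">=60"))
  rep_t <- stratified_analysis(assignment, surv, "t_stage",
                               level_map = c(T3 = "T3/T4", T4 = "T3/T4"))
  expect_setequal(unique(rep_t$stratum), c("T1", "T2", "T3/T4"))
})

test_that("multivariate Cox recovers joint risk-group and stage effects", {
  withr::with_seed(111, {
    n <- 1000
    lab <- sample(c("H", "NA"), n, replace = TRUE)
    stage <- sample(c("early", "late"), n, replace = TRUE)
    lp <- (lab == "H") * 1 + (stage == "late") * 0.5
    t_ev <- rexp(n, log(2) / 1000 * exp(lp))
    t_c <- rexp(n, log(2) / 1000)   # ~50% events
    surv <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                           time = pmin(t_ev, t_c),
                           event = as.numeric(t_ev <= t_c), stage = stage)
    assignment <- tibble::tibble(sample_id = surv$sample_id, label = lab)
  })
  fit <- multivariate_cox(assignment, surv, "stage")
  bh <- dplyr::filter(fit, term == "risk_group_H")
  bs <- dplyr::filter(fit, grepl("stage", term))
  expect_lt(abs(bh$beta - 1), 3 * bh$se)
  expect_lt(abs(bs$beta - 0.5), 3 * bs$se)
})

test_that("constant and duplicated cofactors are dropped with a warning", {
  withr::with_seed(5, {
    surv <- tibble::tibble(sample_id = sprintf("s%02d", 1:80),
                           time = rexp(80, 1 / 500),
                           event = rbinom(80, 1, 0.8),
                           stage = sample(c("a", "b"), 80, replace = TRUE))
    surv$stage_copy <- surv$stage
    surv$constant <- "x"
    assignment <- tibble::tibble(sample_id = surv$sample_id,
                                 label = sample(c("H", "NA"), 80,
                                                replace = TRUE))
  })
  expect_warning(
    fit <- multivariate_cox(assignment, surv,
                            c("stage", "stage_copy", "constant")),
    "stage_copy, constant")
  expect_false(any(grepl("copy|constant", fit$term)))
})

test_that("shuffled risk labels are usually non-significant in multivariate fits", {
  withr::with_seed(77, {
    n <- 200
    surv <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                           time = rexp(n, 1 / 800),
                           event = rbinom(n, 1, 0.6))
    sig <- replicate(60, {
      assignment <- tibble::tibble(
        sample_id = surv$sample_id,
        label = sample(c("H", "L", "NA"), n, replace = TRUE))
      fit <- multivariate_cox(assignment, surv, character(0))
      any(fit$p_value <= 0.05)
    })
  })
  expect_lte(mean(sig), 0.20)   # ~2 terms at alpha 0.05 each
})
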