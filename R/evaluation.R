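# Model evaluation: Kaplan-Meier curves, per-model multi-group log-rank,
# ranking/selection, cofactor stratification and multivariate Cox.

#' Kaplan-Meier curves per risk group
#'
#' Product-limit survival estimates for each group label, as a tidy step
#' function.
#'
#' @inheritParams logrank_statistic
#' @param labels Group labels (character); `NA` values are dropped.
#' @return A tibble with `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `std_err`. Each curve starts implicitly at survival 1.
#' @export
km_curve <- function(time, event, labels) {
  keep <- !is.na(labels)
  df <- data.frame(time = time[keep], event = event[keep],
                   group = as.character(labels)[keep])
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (is.null(fit$strata)) {          # single group
    strata <- rep(unique(df$group), length(fit$time))
  } else {
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  tibble::tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, std_err = fit$std.err)
}

# One-row model report: occupied groups, counts, events, overall log-rank.
evaluate_model <- function(model_id, labels, clinical) {
  grp <- tibble::tibble(label = labels, event = clinical$event) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event),
                     .groups = "drop")
  lr <- multigroup_logrank(clinical$time, clinical$event, labels)
  algorithm <- sub("_(soft|deep).*$", "", model_id)
  depth <- if (grepl("deep", model_id)) "deep" else "soft"
  tibble::tibble(
    model_id = model_id, algorithm = algorithm, depth = depth,
    n_groups = nrow(grp), groups = list(grp),
    statistic = lr$statistic, df = lr$df, p_value = lr$p_value)
}

#' Rank the eight models and select the best
#'
#' Models are ranked primarily by the significance of their overall
#' multi-group log-rank test. A model is additionally required to produce
#' *distinguishable* risk groups: every occupied group must hold at least
#' `min_group_frac` of the cohort, and the two extreme occupied groups
#' (ordered by event rate per unit follow-up time) must separate at a
#' pairwise log-rank `p <= pairwise_alpha`. Models failing either check are
#' penalized below all passing models. Ties break by fewer groups, then by
#' a fixed model-id order (single modes, MaxSum, Combinations).
#'
#' @param model_set A `cna_model_set` from [build_all_models()].
#' @param min_group_frac Minimum occupied-group size as a fraction of the
#'   cohort (default 0.02).
#' @param pairwise_alpha Significance level for the extreme-group pairwise
#'   log-rank (default 0.05).
#' @return A list with `ranking` (tibble ordered best-first, with
#'   `distinguishable`, `extreme_p` and `rank`) and `selected` (the top
#'   model id, or `NA` if every model is degenerate).
#' @export
rank_models <- function(model_set, min_group_frac = 0.02,
                        pairwise_alpha = 0.05) {
  clin <- model_set$clinical
  n <- nrow(clin)
  per_model <- purrr::map(seq_len(nrow(model_set$reports)), function(i) {
    rep_i <- model_set$reports[i, ]
    labels <- dplyr::filter(model_set$assignments,
                            .data$model_id == rep_i$model_id)$label
    grp <- rep_i$groups[[1]]
    size_ok <- all(grp$n >= min_group_frac * n)
    extreme_p <- NA_real_
    if (nrow(grp) >= 2 && sum(clin$event) > 0) {
      # order occupied groups by crude hazard (events per person-day)
      haz <- tibble::tibble(label = labels, time = clin$time,
                            event = clin$event) |>
        dplyr::group_by(.data$label) |>
        dplyr::summarise(h = sum(.data$event) / sum(.data$time),
                         .groups = "drop") |>
        dplyr::arrange(.data$h)
      lo <- haz$label[1]
      hi <- haz$label[nrow(haz)]
      sel <- labels %in% c(lo, hi)
      if (sum(clin$event[sel]) > 0) {
        extreme_p <- multigroup_logrank(clin$time[sel], clin$event[sel],
                                        labels[sel])$p_value
      }
    }
    tibble::tibble(
      model_id = rep_i$model_id, n_groups = rep_i$n_groups,
      p_value = rep_i$p_value, extreme_p = extreme_p,
      distinguishable = isTRUE(size_ok) && isTRUE(extreme_p <= pairwise_alpha))
  })
  ranking <- dplyr::bind_rows(per_model) |>
    dplyr::mutate(.id_order = match(.data$model_id, .model_ids)) |>
    dplyr::arrange(dplyr::desc(.data$distinguishable),
                   dplyr::coalesce(.data$p_value, Inf),
                   .data$n_groups, .data$.id_order) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(-".id_order")
  selected <- if (any(ranking$distinguishable)) ranking$model_id[1] else NA_character_
  list(ranking = ranking, selected = selected)
}

# Build the survival + label analysis frame for one model, with the NA
# group as the Cox reference level.
.model_frame <- function(assignment, surv) {
  stopifnot(all(c("sample_id", "label") %in% names(assignment)))
  df <- dplyr::inner_join(assignment, surv, by = "sample_id")
  lev <- unique(df$label)
  lev <- c(intersect("NA", lev), sort(setdiff(lev, "NA")))
  df$label <- factor(df$label, levels = lev)
  df
}

#' Cofactor-stratified risk-group analysis
#'
#' Within each level (stratum) of a clinical cofactor, fits a Cox model of
#' survival on the risk-group label with the no-risk (`NA`) group as
#' reference, reporting the log hazard ratio of each risk group with its
#' 95% confidence interval. Strata can be coarsened through a level-merging
#' map (e.g. tumor sizes T3 and T4 pooled); numeric cofactors named `age`
#' are dichotomized at `age_cut`.
#'
#' A group with no events inside a stratum has no finite estimate; it is
#' reported with `estimable = FALSE`.
#'
#' @param assignment A tibble with `sample_id` and `label` (one model's
#'   assignments).
#' @param surv Clinical tibble with `time`, `event` and the cofactor column.
#' @param cofactor Name of the cofactor column.
#' @param level_map Optional named character vector mapping raw levels to
#'   merged strata, e.g. `c(T3 = "T3/T4", T4 = "T3/T4")`.
#' @param age_cut Dichotomization cut for numeric cofactors (default 60).
#' @param min_stratum Minimum samples for a stratum to be analyzed.
#' @param conf_level Confidence level for the interval.
#' @return A `StratificationReport` tibble: `cofactor`, `stratum`, `term`,
#'   `n`, `events`, `beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `significant`, `estimable`.
#' @export
stratified_analysis <- function(assignment, surv, cofactor,
                                level_map = NULL, age_cut = 60,
                                min_stratum = 10, conf_level = 0.95) {
  if (!cofactor %in% names(surv)) {
    stop(sprintf("cofactor '%s' not found in clinical table.", cofactor),
         call. = FALSE)
  }
  df <- .model_frame(assignment, surv)
  x <- df[[cofactor]]
  stratum <- if (is.numeric(x)) {
    ifelse(x < age_cut, sprintf("<%s", age_cut), sprintf(">=%s", age_cut))
  } else {
    as.character(x)
  }
  if (!is.null(level_map)) {
    mapped <- unname(level_map[stratum])
    stratum <- ifelse(is.na(mapped), stratum, mapped)
  }
  df$.stratum <- stratum
  df <- dplyr::filter(df, !is.na(.data$.stratum))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::map(sort(unique(df$.stratum)), function(s) {
    sub <- dplyr::filter(df, .data$.stratum == s)
    if (nrow(sub) < min_stratum || dplyr::n_distinct(sub$label) < 2 ||
        sum(sub$event) == 0) {
      return(NULL)
    }
    sub$label <- droplevels(sub$label)
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(time, event) ~ label, data = sub)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    co <- stats::coef(fit)
    se <- sqrt(diag(fit$var))
    terms <- sub("^label", "", names(co))
    # a risk group with no events yields a diverging, non-estimable beta
    ev_by <- tapply(sub$event, sub$label, sum)
    estimable <- is.finite(co) & is.finite(se) & se < 100 &
      ev_by[terms] + ev_by[levels(sub$label)[1]] > 0 & ev_by[terms] > 0
    tibble::tibble(
      cofactor = cofactor, stratum = s, term = terms,
      n = nrow(sub), events = sum(sub$event),
      beta = unname(co), se = unname(se),
      ci_low = unname(co - z * se), ci_high = unname(co + z * se),
      p_value = unname(2 * stats::pnorm(-abs(co / se))),
      estimable = unname(estimable))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(significant = .data$estimable & .data$p_value <= 0.05)
}

#' Multivariate Cox model of risk group plus clinical cofactors
#'
#' Jointly models survival on the risk-group label (no-risk `NA` group as
#' reference) and the requested clinical cofactors, on complete cases for
#' those cofactors. Constant or collinear cofactors are dropped with a
#' warning before fitting.
#'
#' @inheritParams stratified_analysis
#' @param cofactors Character vector of cofactor column names.
#' @param conf_level Confidence level for the intervals.
#' @return A tibble with one row per model term: `term`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, plus attributes `n` and `dropped`
#'   (cofactors removed).
#' @export
multivariate_cox <- function(assignment, surv, cofactors,
                             conf_level = 0.95) {
  df <- .model_frame(assignment, surv)
  missing_cof <- setdiff(cofactors, names(df))
  if (length(missing_cof)) {
    stop("cofactor(s) not found: ", paste(missing_cof, collapse = ", "),
         call. = FALSE)
  }
  df <- df[stats::complete.cases(df[cofactors]), , drop = FALSE]
  keep <- character(0)
  dropped <- character(0)
  mm_cols <- function(cols) {
    stats::model.matrix(
      stats::reformulate(c("label", cols)), data = df)[, -1, drop = FALSE]
  }
  for (cf in cofactors) {
    x <- df[[cf]]
    if (dplyr::n_distinct(x) < 2) {
      dropped <- c(dropped, cf)
      next
    }
    trial <- mm_cols(c(keep, cf))
    if (qr(trial)$rank < ncol(trial)) {
      dropped <- c(dropped, cf)
    } else {
      keep <- c(keep, cf)
    }
  }
  if (length(dropped)) {
    warning("dropping constant/collinear cofactor(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(c("label", keep),
                            response = "survival::Surv(time, event)")
  fit <- suppressWarnings(survival::coxph(fml, data = df))
  co <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = sub("^label", "risk_group_", names(co)),
    beta = unname(co), se = unname(se),
    ci_low = unname(co - z * se), ci_high = unname(co + z * se),
    p_value = unname(2 * stats::pnorm(-abs(co / se))))
  attr(out, "n") <- nrow(df)
  attr(out, "dropped") <- dropped
  out
}
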