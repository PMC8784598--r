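#' Split a roster into exposure groups
#'
#' "Yes" and "Unsure, but I think so" form the exposed group; "No" the
#' unexposed group; participants without an answer belong to neither.
#'
#' @param roster roster data.frame with `participant_id` and
#'   `exposure_answer`.
#' @return list `exposed`, `unexposed`, `excluded` (participant ids).
#' @export
split_groups <- function(roster) {
  ans <- roster$exposure_answer
  valid <- c("Yes", "No", "Unsure, but I think so")
  bad <- !is.na(ans) & !ans %in% valid
  if (any(bad)) {
    stop("split_groups: unknown exposure answer(s): ",
         paste(unique(ans[bad]), collapse = "; "))
  }
  list(exposed = roster$participant_id[!is.na(ans) & ans != "No"],
       unexposed = roster$participant_id[!is.na(ans) & ans == "No"],
       excluded = roster$participant_id[is.na(ans)])
}

#' Group summary (n, mean, SD)
#'
#' @param x numeric vector (NAs dropped).
#' @return list `n`, `mean`, `sd`.
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  list(n = length(x), mean = mean(x), sd = sd(x))
}

#' Upper-tail one-sided p-value of a Student-t statistic
#'
#' P(T_df > t): the convention under which the published table's negative
#' statistics map to p > 0.5.
#'
#' @param t t statistic.
#' @param df degrees of freedom (> 0).
#' @return probability.
#' @export
#' @examples
#' one_sided_p(0, 10)        # 0.5
#' round(one_sided_p(1.17, 380), 2)  # 0.12
one_sided_p <- function(t, df) {
  if (any(df <= 0)) stop("one_sided_p: df must be positive")
  pt(t, df, lower.tail = FALSE)
}

#' Pooled-variance two-sample t-test from group summaries
#'
#' Student's equal-variance t-test computed from (n, mean, SD) summaries:
#' t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2)) with
#' sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2) and
#' df = n1 + n2 - 2. The reported p is one-sided upper-tail by default
#' (group 1 greater), and the interval is mean_diff +/- t_{q, df} * se with
#' q = `ci_quantile` (0.95 reproduces the published bounds, a 90%-width
#' interval despite its "95% CI" label).
#'
#' @param s1,s2 group summaries (lists with `n`, `mean`, `sd`), group 1
#'   conventionally the exposed group.
#' @param ci_quantile Student-t quantile for the interval.
#' @param sided `"greater"` (upper tail) or `"two.sided"`.
#' @return list `t`, `df`, `p`, `mean_diff`, `se`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' # reconstruction from printed summaries: identical groups give t = 0
#' pooled_t(list(n = 10, mean = 1, sd = 1), list(n = 10, mean = 1, sd = 1))$p
pooled_t <- function(s1, s2, ci_quantile = 0.95, sided = "greater") {
  stopifnot(s1$n >= 2, s2$n >= 2)
  df <- s1$n + s2$n - 2
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / df
  se <- sqrt(sp2) * sqrt(1 / s1$n + 1 / s2$n)
  diff <- s1$mean - s2$mean
  if (se == 0) {
    if (diff == 0) {
      warning("pooled_t: zero pooled variance and zero difference")
      t <- 0
    } else {
      warning("pooled_t: zero pooled variance with nonzero difference")
      t <- sign(diff) * Inf
    }
  } else {
    t <- diff / se
  }
  p <- if (sided == "greater") one_sided_p(t, df) else
    2 * pt(-abs(t), df)
  q <- qt(ci_quantile, df)
  list(t = t, df = df, p = p, mean_diff = diff, se = se,
       ci_lower = diff - q * se, ci_upper = diff + q * se)
}

#' Reconstruct an interval from a printed mean difference and t statistic
#'
#' Given the published group mean difference and t, the standard error is
#' diff / t and the interval is diff +/- t_{q, df} * se. With q = 0.95 this
#' reproduces the published bounds of the self-consistent table rows.
#'
#' @param mean_diff printed mean difference.
#' @param t printed t statistic (nonzero).
#' @param df degrees of freedom.
#' @param ci_quantile Student-t quantile.
#' @return list `se`, `ci_lower`, `ci_upper`.
#' @export
reconstruct_interval <- function(mean_diff, t, df, ci_quantile = 0.95) {
  stopifnot(t != 0, df >= 1)
  se <- mean_diff / t
  q <- qt(ci_quantile, df)
  list(se = se, ci_lower = mean_diff - q * se, ci_upper = mean_diff + q * se)
}

#' Significance marker
#'
#' One star below `alpha` (default 0.05), two below `alpha_strong`
#' (default 0.001), following the published starring convention.
#'
#' @param p p-value(s).
#' @param alpha,alpha_strong thresholds.
#' @return character vector of "", "*" or "**".
#' @export
significance_marker <- function(p, alpha = 0.05, alpha_strong = 0.001) {
  ifelse(is.na(p), "", ifelse(p < alpha_strong, "**",
                              ifelse(p < alpha, "*", "")))
}

#' Compare exposure groups on surveys, items and passive features
#'
#' Builds one comparison row per instrument mean, per item of the
#' item-level instruments, and per passive feature: group summaries,
#' pooled t, one-sided p, reconstructed interval and significance marker.
#' Passive rows use per-participant means over available days, so their
#' degrees of freedom may differ from the survey rows. Variables with
#' fewer than 2 observations in either group yield a row with missing
#' statistics.
#'
#' @param participant_means output of [participant_mean()] (instrument-level
#'   normalized means), or NULL.
#' @param item_means named list of [item_matrix()] outputs keyed by
#'   instrument id, or NULL.
#' @param feature_means output of [participant_feature_means()], or NULL.
#' @param groups list from [split_groups()].
#' @param inference an [inference_config()].
#' @return data.frame of comparison rows: `variable`, `kind`, `n_exposed`,
#'   `mean_exposed`, `sd_exposed`, `n_unexposed`, `mean_unexposed`,
#'   `sd_unexposed`, `t`, `df`, `p`, `mean_diff`, `se`, `ci_lower`,
#'   `ci_upper`, `marker`.
#' @export
compare_all <- function(participant_means = NULL, item_means = NULL,
                        feature_means = NULL, groups,
                        inference = inference_config()) {
  if (!length(groups$exposed) || !length(groups$unexposed)) {
    stop("compare_all: both exposure groups must be non-empty")
  }
  rows <- list()
  add <- function(variable, kind, ids, values) {
    v <- setNames(values, ids)
    x <- v[names(v) %in% groups$exposed]
    y <- v[names(v) %in% groups$unexposed]
    rows[[length(rows) + 1]] <<- comparison_row(variable, kind, x, y, inference)
  }
  if (!is.null(participant_means)) {
    for (ins in unique(participant_means$instrument_id)) {
      d <- participant_means[participant_means$instrument_id == ins, ]
      add(ins, "survey_mean", d$participant_id, d$mean_normalized)
    }
  }
  if (!is.null(item_means)) {
    for (ins in names(item_means)) {
      im <- item_means[[ins]]
      for (code in unique(im$item_code)) {
        d <- im[im$item_code == code, ]
        add(paste0(ins, ": ", code), "item", d$participant_id, d$mean_response)
      }
    }
  }
  if (!is.null(feature_means)) {
    for (feat in c("home_time_h", "sleep_duration_h", "screen_duration_h")) {
      add(feat, "passive", feature_means$participant_id, feature_means[[feat]])
    }
  }
  out <- do.call(rbind, rows)
  if (isTRUE(inference$fdr)) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$marker <- significance_marker(out$p_adj, inference$alpha,
                                      inference$alpha_strong)
  }
  rownames(out) <- NULL
  out
}

comparison_row <- function(variable, kind, x, y, inference) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  base <- data.frame(variable = variable, kind = kind,
                     n_exposed = length(x), mean_exposed = NA_real_,
                     sd_exposed = NA_real_, n_unexposed = length(y),
                     mean_unexposed = NA_real_, sd_unexposed = NA_real_,
                     t = NA_real_, df = NA_real_, p = NA_real_,
                     mean_diff = NA_real_, se = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     marker = "", stringsAsFactors = FALSE)
  if (length(x) < 2 || length(y) < 2) {
    warning("compare_all: fewer than 2 observations per group for ", variable)
    return(base)
  }
  s1 <- group_summary(x); s2 <- group_summary(y)
  tt <- pooled_t(s1, s2, inference$ci_quantile, inference$sided)
  base$mean_exposed <- s1$mean; base$sd_exposed <- s1$sd
  base$mean_unexposed <- s2$mean; base$sd_unexposed <- s2$sd
  base$t <- tt$t; base$df <- tt$df; base$p <- tt$p
  base$mean_diff <- tt$mean_diff; base$se <- tt$se
  base$ci_lower <- tt$ci_lower; base$ci_upper <- tt$ci_upper
  base$marker <- significance_marker(tt$p, inference$alpha,
                                     inference$alpha_strong)
  base
}

#' Cohort gender summary
#'
#' Counts per gender with integer percentages (round(100 * count / total)).
#'
#' @param roster roster data.frame with a `gender` column.
#' @return data.frame `gender`, `n`, `pct`.
#' @export
#' @examples
#' r <- data.frame(gender = rep(c("female", "male", "other"), c(237, 133, 11)))
#' cohort_summary(r)  # 62, 35, 3 percent
cohort_summary <- function(roster) {
  stopifnot(nrow(roster) >= 1)
  tab <- table(roster$gender)
  data.frame(gender = names(tab), n = as.integer(tab),
             pct = as.integer(round(100 * as.integer(tab) / nrow(roster))),
             stringsAsFactors = FALSE)
}

#' Format a comparison table for publication-style output
#'
#' @param comparison output of [compare_all()].
#' @return data.frame with "M (SD)" strings, t, p, interval bounds and
#'   stars.
#' @export
format_comparison <- function(comparison) {
  msd <- function(m, s) ifelse(is.na(m), "", sprintf("%.2f (%.2f)", m, s))
  data.frame(variable = comparison$variable,
             exposed = msd(comparison$mean_exposed, comparison$sd_exposed),
             unexposed = msd(comparison$mean_unexposed, comparison$sd_unexposed),
             t = round(comparison$t, 2),
             p = round(comparison$p, 2),
             ci_lower = round(comparison$ci_lower, 2),
             ci_upper = round(comparison$ci_upper, 2),
             marker = comparison$marker,
             stringsAsFactors = FALSE)
}
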