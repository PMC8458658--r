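#' 2x2 contingency table for one feature
#'
#' Cross-tabulates feature presence against diagnosis using either the
#' `first` or `ever` column of a feature matrix. Patients whose entry is
#' missing (region never imaged) are excluded from both numerator and
#' denominator, so `a + b` is the NMOSD denominator after missing-scan
#' reduction and `c + d` the MS denominator.
#'
#' @param feature_matrix Output of [build_feature_matrix()].
#' @param feature_id A single catalogue feature id.
#' @param which `"ever"` (default, used for association) or `"first"`.
#' @return A one-row tibble with columns `feature_id`, `a` (NMOSD present),
#'   `b` (NMOSD absent), `c` (MS present), `d` (MS absent).
#' @export
contingency_from_matrix <- function(feature_matrix, feature_id,
                                    which = c("ever", "first")) {
  which <- match.arg(which)
  fm <- feature_matrix[feature_matrix$feature_id == feature_id, ]
  if (nrow(fm) == 0) stop("unknown feature: ", feature_id)
  x <- fm[[which]]
  nmo <- fm$diagnosis == "NMOSD"
  keep <- !is.na(x)
  if (!any(keep)) {
    warning("all entries missing for feature ", feature_id)
  }
  tibble::tibble(
    feature_id = feature_id,
    a = sum(keep & nmo & x), b = sum(keep & nmo & !x),
    c = sum(keep & !nmo & x), d = sum(keep & !nmo & !x)
  )
}

#' Odds ratio with Haldane-Anscombe correction
#'
#' Computes the NMOSD-vs-MS odds ratio `(a*d)/(b*c)` for a 2x2 table. When
#' any cell is zero, 0.5 is added to all four cells before both the point
#' estimate and the confidence interval are computed (Haldane-Anscombe
#' continuity correction); `corrected` records whether this happened. The
#' 95% interval is the Woolf log-normal interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` on the (possibly
#' corrected) cells. Odds ratios above 1 favour NMOSD.
#'
#' @param a,b,c,d Non-negative integer cells: NMOSD present/absent, MS
#'   present/absent. Vectorised.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with `odds_ratio`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio_ha(10, 5, 2, 20) # (10*20)/(5*2) = 20
#' @export
odds_ratio_ha <- function(a, b, c, d, conf_level = 0.95) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  if (any(a + b + c + d == 0)) stop("odds ratio undefined for an all-zero table")
  corrected <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  shift <- ifelse(corrected, 0.5, 0)
  a2 <- a + shift; b2 <- b + shift; c2 <- c + shift; d2 <- d + shift
  or <- (a2 * d2) / (b2 * c2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  tibble::tibble(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    corrected = corrected
  )
}

#' Sensitivity and specificity of a feature for NMOSD
#'
#' With NMOSD as the target condition, sensitivity is `a / (a + b)` (the
#' feature detects NMOSD) and specificity `d / (c + d)` (absence identifies
#' MS). Zero margins yield `NaN` rather than an error so sparse features are
#' visible downstream.
#'
#' @inheritParams odds_ratio_ha
#' @return A tibble with `sensitivity` and `specificity`.
#' @export
sens_spec <- function(a, b, c, d) {
  tibble::tibble(
    sensitivity = ifelse(a + b > 0, a / (a + b), NaN),
    specificity = ifelse(c + d > 0, d / (c + d), NaN)
  )
}

#' Association statistics for every catalogue feature
#'
#' Builds the 2x2 table for each feature, attaches Haldane-Anscombe corrected
#' odds ratios with Woolf confidence intervals, sensitivity and specificity,
#' and a significance flag (confidence interval excluding 1). Features with
#' an empty table (both denominators zero, or zero total) are dropped rather
#' than raising, so the scan over sparse cohorts is total. No multiple-testing
#' adjustment is applied, matching the design of a hypothesis-generating
#' lesion survey of pre-specified candidate features.
#'
#' @inheritParams contingency_from_matrix
#' @param catalog A feature catalogue.
#' @return A tibble sorted by descending odds ratio (ties broken by
#'   `feature_id`) with columns `feature_id`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `sensitivity`, `specificity`,
#'   `corrected`, `significant`.
#' @export
associate_all <- function(feature_matrix, catalog = nmo_feature_catalog(),
                          which = c("ever", "first")) {
  which <- match.arg(which)
  tabs <- purrr::map_dfr(
    intersect(catalog$feature_id, unique(feature_matrix$feature_id)),
    function(fid) {
      suppressWarnings(contingency_from_matrix(feature_matrix, fid, which))
    }
  )
  tabs <- tabs[tabs$a + tabs$b + tabs$c + tabs$d > 0, , drop = FALSE]
  res <- dplyr::bind_cols(
    tabs,
    odds_ratio_ha(tabs$a, tabs$b, tabs$c, tabs$d),
    sens_spec(tabs$a, tabs$b, tabs$c, tabs$d)
  )
  res$significant <- res$ci_low > 1 | res$ci_high < 1
  res <- dplyr::arrange(res, dplyr::desc(.data$odds_ratio), .data$feature_id)
  class(res) <- c("nmo_assoc", class(res))
  res
}

#' Compare lesion counts between diagnoses
#'
#' Per-patient maximum of a scan count column (e.g. `n_T2_total` for total
#' brain T2 lesions), compared between diagnoses with the Mann-Whitney
#' (Wilcoxon rank-sum) test. Patients without a scan carrying the column
#' are excluded.
#'
#' @param cohort An [nmo_cohort()].
#' @param count Name of the scan count column (default `"n_T2_total"`).
#' @param region Scan region the count lives on (default `"brain"`).
#' @return A tibble with medians per diagnosis, the W statistic and p-value.
#' @export
compare_lesion_counts <- function(cohort, count = "n_T2_total",
                                  region = "brain") {
  stopifnot(inherits(cohort, "nmo_cohort"))
  sc <- cohort$scans[cohort$scans$region == region, ]
  if (!count %in% names(sc)) stop("unknown count column: ", count)
  agg <- tapply(sc[[count]], sc$patient_id, max, na.rm = TRUE)
  diagnosis <- cohort$patients$diagnosis[
    match(names(agg), cohort$patients$patient_id)]
  x <- agg[diagnosis == "NMOSD"]
  y <- agg[diagnosis == "MS"]
  ht <- stats::wilcox.test(x, y, exact = FALSE)
  tibble::tibble(
    count = count,
    median_nmosd = stats::median(x), median_ms = stats::median(y),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Forest plot of feature odds ratios
#'
#' @param object An `nmo_assoc` tibble from [associate_all()].
#' @param ... Unused.
#' @return A ggplot: odds ratios with confidence intervals on a log scale,
#'   NMOSD-favouring features to the right of 1, MS-favouring to the left.
#' @export
autoplot.nmo_assoc <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    feature_id = stats::reorder(.data$feature_id, .data$odds_ratio),
    direction = ifelse(!.data$significant, "not significant",
                       ifelse(.data$odds_ratio > 1, "NMOSD", "MS"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$feature_id,
                                   colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      NMOSD = "#2166ac", MS = "#b2182b", `not significant` = "grey60")) +
    ggplot2::labs(x = "Odds ratio (log scale, >1 favours NMOSD)", y = NULL,
                  colour = NULL)
}
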