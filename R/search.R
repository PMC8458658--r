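#' Configuration for the score-model search
#'
#' The search formalises an iterative spreadsheet-style model exploration:
#' cut-offs on a class score are escalated until specificity reaches 1.00 or
#' sensitivity falls below 0.50; models are then refined by sequentially
#' removing features and increasing weights, preferring higher specificity
#' (aiming above 0.90) and then higher sensitivity; finally the two class
#' scores are combined through a ratio rule chosen to maximise weighted
#' precision.
#'
#' @param nmosd_candidates,ms_candidates Candidate feature ids per class;
#'   defaults are the [default_score_model()] feature lists.
#' @param weight_grid Allowed integer weights (default `1:3`).
#' @param cutoff_grid Cut-offs tried for each class score; `NULL` means all
#'   integers from 1 to the maximum attainable score.
#' @param specificity_stop Escalation stops once specificity reaches this
#'   value (default 1.00).
#' @param sensitivity_floor Escalation stops once sensitivity falls below
#'   this value (default 0.50), and refined models must stay at or above it.
#' @param specificity_goal Documented target the refinement aims for
#'   (default 0.90); it does not gate acceptance.
#' @param ratio_grid Combination ratios tried (default 0.5-step over
#'   (0, 10]).
#' @param max_models Cap on the number of candidate models evaluated during
#'   refinement.
#' @return A list of class `nmo_search_config`.
#' @export
search_config <- function(nmosd_candidates = names(default_score_model()$nmosd_features),
                          ms_candidates = names(default_score_model()$ms_features),
                          weight_grid = 1:3,
                          cutoff_grid = NULL,
                          specificity_stop = 1.00,
                          sensitivity_floor = 0.50,
                          specificity_goal = 0.90,
                          ratio_grid = seq(0.5, 10, by = 0.5),
                          max_models = 500L) {
  stopifnot(
    length(weight_grid) > 0, length(ratio_grid) > 0, all(ratio_grid > 0),
    specificity_stop >= 0, specificity_stop <= 1,
    sensitivity_floor >= 0, sensitivity_floor <= 1,
    specificity_goal >= 0, specificity_goal <= 1
  )
  structure(
    list(nmosd_candidates = nmosd_candidates, ms_candidates = ms_candidates,
         weight_grid = sort(unique(as.integer(weight_grid))),
         cutoff_grid = cutoff_grid,
         specificity_stop = specificity_stop,
         sensitivity_floor = sensitivity_floor,
         specificity_goal = specificity_goal,
         ratio_grid = sort(unique(ratio_grid)),
         max_models = as.integer(max_models)),
    class = "nmo_search_config"
  )
}

# 0/1 design matrix for a candidate feature set (missing -> absent)
search_design <- function(feature_matrix, features, which) {
  wide <- features_wide(feature_matrix, which)
  X <- feature_matrix_numeric(wide, features)
  X[is.na(X)] <- 0
  list(X = X, y = wide$diagnosis, patient_id = wide$patient_id)
}

single_score_perf <- function(score, y, target, cutoff) {
  pos <- y == target
  tibble::tibble(
    cutoff = cutoff,
    sensitivity = mean(score[pos] >= cutoff),
    specificity = mean(score[!pos] < cutoff)
  )
}

#' Escalate the cut-off of a single-class score
#'
#' Walks the cut-off grid upward from its lowest value, recording
#' sensitivity and specificity of the rule "score >= cutoff implies
#' `target`" at each step, and stops at the first cut-off where specificity
#' reaches `specificity_stop` or sensitivity falls below
#' `sensitivity_floor`. The whole trajectory up to termination is returned
#' for audit.
#'
#' @param weights Named integer weights of the class score.
#' @param feature_matrix Output of [build_feature_matrix()].
#' @param target Class the score detects (`"NMOSD"` or `"MS"`).
#' @param config A [search_config()].
#' @param which `"ever"` (default) or `"first"`.
#' @return A tibble with columns `cutoff`, `sensitivity`, `specificity`.
#' @export
escalate_cutoffs <- function(weights, feature_matrix,
                             target = c("NMOSD", "MS"),
                             config = search_config(),
                             which = c("ever", "first")) {
  target <- match.arg(target)
  which <- match.arg(which)
  if (nrow(feature_matrix) == 0) stop("empty feature matrix")
  d <- search_design(feature_matrix, names(weights), which)
  score <- as.vector(d$X %*% weights)
  grid <- config$cutoff_grid %||% seq_len(max(1, sum(weights)))
  grid <- sort(grid)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    rows[[i]] <- single_score_perf(score, d$y, target, grid[i])
    if (rows[[i]]$specificity >= config$specificity_stop ||
        rows[[i]]$sensitivity < config$sensitivity_floor) {
      rows <- rows[seq_len(i)]
      break
    }
  }
  dplyr::bind_rows(rows)
}

# best admissible (cutoff, sens, spec) for a weight vector; NULL if none
best_operating_point <- function(score, y, target, config, max_score) {
  grid <- config$cutoff_grid %||% seq_len(max(1, max_score))
  grid <- sort(unique(grid))
  pos <- y == target
  perf <- tibble::tibble(
    cutoff = grid,
    sensitivity = vapply(grid, function(ct) mean(score[pos] >= ct),
                         numeric(1)),
    specificity = vapply(grid, function(ct) mean(score[!pos] < ct),
                         numeric(1))
  )
  ok <- perf[perf$sensitivity >= config$sensitivity_floor, , drop = FALSE]
  if (nrow(ok) == 0) {
    # degenerate score (e.g. label-permuted data): no cut-off keeps
    # sensitivity at the floor; fall back to the most sensitive cut-off so
    # the search stays total rather than erroring mid-batch
    perf <- perf[order(-perf$sensitivity, -perf$specificity, perf$cutoff), ]
    perf$floor_met <- FALSE
    return(perf[1, ])
  }
  ok <- ok[order(-ok$specificity, -ok$sensitivity, ok$cutoff), ]
  ok$floor_met <- TRUE
  ok[1, ]
}

#' Greedy refinement of a single-class score model
#'
#' Starting from weight-1 (or supplied) weights over the candidate features,
#' repeatedly proposes every single-feature removal and every single-step
#' weight increment (within the weight grid), evaluates each proposal at its
#' best admissible cut-off, and accepts the lexicographically best proposal
#' — higher specificity first, then higher sensitivity — provided it beats
#' the current model and keeps sensitivity at or above the floor. Proposals
#' are enumerated in candidate order (removals before increments), so ties
#' break deterministically by feature order. Iteration stops when no
#' proposal is accepted or `max_models` evaluations are spent. The search is
#' in-sample by design.
#'
#' @param weights Named integer starting weights.
#' @inheritParams escalate_cutoffs
#' @return A list of class `nmo_refined_score`: `weights`, `cutoff`,
#'   `sensitivity`, `specificity`, `target`, `n_evaluated`, and `log` (one
#'   row per evaluated model).
#' @export
refine_model <- function(weights, feature_matrix, target = c("NMOSD", "MS"),
                         config = search_config(),
                         which = c("ever", "first")) {
  target <- match.arg(target)
  which <- match.arg(which)
  weights <- unlist(weights)
  d <- search_design(feature_matrix, names(weights), which)

  evaluate_w <- function(w) {
    w <- w[w > 0]
    if (length(w) == 0) return(NULL)
    score <- as.vector(d$X[, names(w), drop = FALSE] %*% w)
    best_operating_point(score, d$y, target, config, max_score = sum(w))
  }

  cur <- evaluate_w(weights)
  if (is.null(cur)) stop("refinement needs at least one weighted feature")
  n_eval <- 1L
  log_rows <- list(log_row(weights, cur, accepted = TRUE))
  max_w <- max(config$weight_grid)

  repeat {
    proposals <- list()
    for (f in names(weights)) {        # removals first, in candidate order
      if (weights[[f]] > 0) {
        w2 <- weights; w2[[f]] <- 0L
        proposals[[length(proposals) + 1L]] <- w2
      }
    }
    for (f in names(weights)) {        # then single-step weight increments
      if (weights[[f]] > 0 && weights[[f]] < max_w) {
        w2 <- weights; w2[[f]] <- w2[[f]] + 1L
        proposals[[length(proposals) + 1L]] <- w2
      }
    }
    best <- NULL; best_w <- NULL
    for (w2 in proposals) {
      if (n_eval >= config$max_models) break
      perf <- evaluate_w(w2)
      n_eval <- n_eval + 1L
      if (is.null(perf)) next
      log_rows[[length(log_rows) + 1L]] <- log_row(w2, perf, accepted = FALSE)
      if (is.null(best) || point_better(perf, best)) {
        best <- perf; best_w <- w2
      }
    }
    improves <- !is.null(best) && point_better(best, cur)
    if (!improves || n_eval >= config$max_models) break
    weights <- best_w
    cur <- best
    log_rows[[length(log_rows) + 1L]] <- log_row(weights, cur, accepted = TRUE)
  }

  structure(
    list(weights = weights[weights > 0], cutoff = cur$cutoff,
         sensitivity = cur$sensitivity, specificity = cur$specificity,
         target = target, n_evaluated = n_eval,
         log = dplyr::bind_rows(log_rows)),
    class = "nmo_refined_score"
  )
}

# lexicographic preference: meeting the sensitivity floor, then higher
# specificity, then higher sensitivity
point_better <- function(a, b) {
  if (a$floor_met != b$floor_met) return(a$floor_met)
  if (a$specificity != b$specificity) return(a$specificity > b$specificity)
  a$sensitivity > b$sensitivity
}

log_row <- function(w, perf, accepted) {
  w <- w[w > 0]
  tibble::tibble(
    features = paste0(names(w), "(", w, ")", collapse = "+"),
    cutoff = perf$cutoff, sensitivity = perf$sensitivity,
    specificity = perf$specificity, accepted = accepted
  )
}

#' Combined NMOSD/MS score search
#'
#' Refines an NMOSD score and an MS score independently on the `ever` data,
#' then selects the combination ratio from `config$ratio_grid` that
#' maximises the weighted precision of the combined rule "NMOSD score x
#' ratio > MS score implies NMOSD" (smallest ratio on ties). The whole
#' procedure is a deterministic function of the data and configuration.
#'
#' @param feature_matrix Output of [build_feature_matrix()]; must contain
#'   both diagnoses.
#' @param config A [search_config()].
#' @param which Imaging column used for the search (default `"ever"`).
#' @param catalog Catalogue used to validate the assembled model.
#' @return A list of class `nmo_search`: `model` (an `nmo_score_model`),
#'   `ratio`, `nmosd_fit` and `ms_fit` (the per-class refinements),
#'   `evaluation` (an [evaluate_classifier()] result on `which`), and
#'   `ratio_profile` (weighted precision per candidate ratio).
#' @export
search_combined <- function(feature_matrix, config = search_config(),
                            which = c("ever", "first"),
                            catalog = nmo_feature_catalog()) {
  which <- match.arg(which)
  if (length(unique(feature_matrix$diagnosis)) < 2) {
    stop("search requires both diagnosis classes")
  }
  start <- function(ids) stats::setNames(rep(1L, length(ids)), ids)
  nmosd_fit <- refine_model(start(config$nmosd_candidates), feature_matrix,
                            target = "NMOSD", config = config, which = which)
  ms_fit <- refine_model(start(config$ms_candidates), feature_matrix,
                         target = "MS", config = config, which = which)

  d <- search_design(feature_matrix,
                     c(names(nmosd_fit$weights), names(ms_fit$weights)),
                     which)
  s_n <- as.vector(d$X[, names(nmosd_fit$weights), drop = FALSE] %*%
                     nmosd_fit$weights)
  s_m <- as.vector(d$X[, names(ms_fit$weights), drop = FALSE] %*%
                     ms_fit$weights)
  profile <- purrr::map_dfr(config$ratio_grid, function(r) {
    pred <- ifelse(s_n * r > s_m, "NMOSD", "MS")
    cm <- confusion(d$y, pred)
    tibble::tibble(ratio = r,
                   weighted_precision = weighted_metrics(cm)$precision)
  })
  finite <- !is.nan(profile$weighted_precision)
  best <- profile[finite, ][which.max(profile$weighted_precision[finite]), ]

  model <- score_model(nmosd_fit$weights, ms_fit$weights,
                       combination_ratio = best$ratio, catalog = catalog)
  structure(
    list(model = model, ratio = best$ratio,
         nmosd_fit = nmosd_fit, ms_fit = ms_fit,
         evaluation = evaluate_classifier(model, feature_matrix, which),
         ratio_profile = profile),
    class = "nmo_search"
  )
}

#' @export
print.nmo_search <- function(x, ...) {
  cat(sprintf("<nmo_search> combined score, ratio %.1f\n", x$ratio))
  print(x$model)
  print(x$evaluation)
  invisible(x)
}

#' Tidy the searched score model into one row per feature
#'
#' @param x An `nmo_search`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `class`, `weight`.
#' @export
tidy.nmo_search <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(feature_id = names(x$model$nmosd_features),
                   class = "NMOSD", weight = unname(x$model$nmosd_features)),
    tibble::tibble(feature_id = names(x$model$ms_features),
                   class = "MS", weight = unname(x$model$ms_features))
  )
}

#' @rdname tidy.nmo_search
#' @export
glance.nmo_search <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(ratio = x$ratio,
                   nmosd_cutoff = x$nmosd_fit$cutoff,
                   ms_cutoff = x$ms_fit$cutoff,
                   models_evaluated = x$nmosd_fit$n_evaluated +
                     x$ms_fit$n_evaluated),
    glance(x$evaluation)
  )
}
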