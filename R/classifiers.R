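#' Paty brain-MRI criteria
#'
#' Met when the brain MRI shows at least 3 white-matter lesions larger than
#' 3 mm, or at least 2 white-matter lesions of which one is periventricular.
#'
#' @param n_wm Total white-matter lesion count.
#' @param n_wm_gt3mm Count of white-matter lesions larger than 3 mm.
#' @param n_periventricular Periventricular lesion count.
#' @return Logical, vectorised.
#' @examples
#' paty(n_wm = 2, n_wm_gt3mm = 0, n_periventricular = 1)
#' @export
paty <- function(n_wm, n_wm_gt3mm, n_periventricular) {
  paty_rule(n_wm, n_wm_gt3mm, n_periventricular)
}

paty_rule <- function(n_wm, n_wm_gt3mm, n_periventricular) {
  (n_wm_gt3mm >= 3) | (n_wm >= 2 & n_periventricular >= 1)
}

#' Barkhof dissemination-in-space criteria
#'
#' Met when at least three of four conditions hold: (1) a Gd-enhancing lesion
#' or 9 or more T2 lesions; (2) at least 1 infratentorial lesion; (3) at
#' least 1 juxtacortical lesion; (4) at least 3 periventricular lesions.
#'
#' @param gd_lesion Logical, any Gd-enhancing brain lesion.
#' @param n_T2 Total brain T2 lesion count.
#' @param n_infratentorial,n_juxtacortical,n_periventricular Lesion counts.
#' @return Logical, vectorised.
#' @export
barkhof <- function(gd_lesion, n_T2, n_infratentorial, n_juxtacortical,
                    n_periventricular) {
  barkhof_rule(gd_lesion, n_T2, n_infratentorial, n_juxtacortical,
               n_periventricular)
}

barkhof_rule <- function(gd_lesion, n_T2, n_infratentorial, n_juxtacortical,
                         n_periventricular) {
  crit <- (gd_lesion | n_T2 >= 9) + (n_infratentorial >= 1) +
    (n_juxtacortical >= 1) + (n_periventricular >= 3)
  crit >= 3
}

#' Weighted NMOSD/MS score model
#'
#' A score model sums integer weights over present binary features,
#' separately for NMOSD-associated and MS-associated features, and labels a
#' patient NMOSD when `nmo_score * combination_ratio > ms_score` (strictly;
#' ties go to MS, the "if not, MS" reading of the rule). In `regional` mode
#' each region's sub-score (optic nerve / brain / spinal cord) contributes to
#' its class total only when it reaches the region's cut-off.
#'
#' @param nmosd_features,ms_features Named integer vectors of weights
#'   (weight >= 1), names are catalogue feature ids; the two sets must be
#'   disjoint.
#' @param combination_ratio Positive multiplier applied to the NMOSD score in
#'   the decision rule (default 3.5).
#' @param mode `"summative"` (default) or `"regional"`.
#' @param regional_cutoffs Named numeric vector of per-region cut-offs
#'   (`optic_nerve`, `brain`, `spinal_cord`), used in regional mode.
#' @param catalog Catalogue used to validate feature ids and assign regions.
#' @return An object of class `nmo_score_model`.
#' @export
score_model <- function(nmosd_features, ms_features, combination_ratio = 3.5,
                        mode = c("summative", "regional"),
                        regional_cutoffs = c(optic_nerve = 0, brain = 0,
                                             spinal_cord = 0),
                        catalog = nmo_feature_catalog()) {
  mode <- match.arg(mode)
  nmosd_features <- unlist(nmosd_features)
  ms_features <- unlist(ms_features)
  stopifnot(combination_ratio > 0,
            all(nmosd_features >= 1), all(ms_features >= 1))
  if (length(intersect(names(nmosd_features), names(ms_features))) > 0) {
    stop("NMOSD and MS feature sets must be disjoint")
  }
  unknown <- validate_feature_refs(
    catalog, c(names(nmosd_features), names(ms_features)))
  if (length(unknown) > 0) {
    stop("score model references unknown features: ",
         paste(unknown, collapse = ", "))
  }
  region_of <- score_region(catalog)
  structure(
    list(
      nmosd_features = nmosd_features, ms_features = ms_features,
      combination_ratio = combination_ratio, mode = mode,
      regional_cutoffs = regional_cutoffs,
      feature_region = region_of
    ),
    class = "nmo_score_model"
  )
}

score_region <- function(catalog) {
  r <- ifelse(catalog$region == "optic_pathway", "optic_nerve",
       ifelse(catalog$region == "spinal_cord", "spinal_cord", "brain"))
  stats::setNames(r, catalog$feature_id)
}

#' @export
print.nmo_score_model <- function(x, ...) {
  cat(sprintf(
    "<nmo_score_model> %s; ratio %.2f\n  NMOSD (%d): %s\n  MS (%d): %s\n",
    x$mode, x$combination_ratio,
    length(x$nmosd_features),
    paste0(names(x$nmosd_features), "(", x$nmosd_features, ")", collapse = " "),
    length(x$ms_features),
    paste0(names(x$ms_features), "(", x$ms_features, ")", collapse = " ")))
  invisible(x)
}

#' Default reconstructed score model
#'
#' Feature lists follow the significant NMOSD- and MS-associated features
#' from the association analysis, with weight 2 on longitudinally extensive
#' cord and bilateral optic nerve lesions (NMOSD) and on ovoid lesions (MS),
#' weight 1 elsewhere, and combination ratio 3.5. The exact published model
#' weights are not public; this default is a reconstruction and fully
#' overridable via [score_model()] or [read_score_model()].
#'
#' @param catalog A feature catalogue.
#' @return An `nmo_score_model`.
#' @export
default_score_model <- function(catalog = nmo_feature_catalog()) {
  nmo <- c(
    longitudinal_cord_T2 = 2, bilateral_optic_nerve = 2,
    bright_spotty_cord_T2 = 1, whole_cord_T2 = 1, cord_gd = 1,
    optic_nerve_gd = 1, nucleus_tractus_solitarius_T2 = 1,
    periaqueductal_T2 = 1, third_ventricle_T2 = 1, cord_swelling = 1,
    central_cord_T2 = 1, optic_nerve_T2 = 1, hypothalamic_T2 = 1,
    normal_brain = 1, cord_atrophy = 1
  )
  ms <- c(
    ovoid_T2 = 2, dawsons_fingers = 1, pyramidal_cc_T2 = 1,
    periventricular_T2 = 1, temporal_lobe_T2 = 1, black_hole_T1 = 1,
    nine_or_more_T2 = 1, juxtacortical_T2 = 1, subcortical_T2 = 1,
    cortical_T2 = 1, cerebellar_T2 = 1, splenium_T2 = 1,
    inferior_temporal_T2 = 1, short_cord_T2 = 1, partial_cord_T2 = 1
  )
  score_model(nmo, ms, combination_ratio = 3.5, catalog = catalog)
}

#' Score and classify one feature vector
#'
#' Missing features (no imaging of the region) evaluate as absent inside the
#' score; use [predict_diagnosis()] for cohort-level classification with
#' unclassifiable-patient handling.
#'
#' @param record_features Named logical vector of feature presence.
#' @param model An `nmo_score_model`.
#' @return A one-row tibble with `nmo_score`, `ms_score`, `prediction`.
#' @examples
#' m <- default_score_model()
#' score_classify(c(longitudinal_cord_T2 = TRUE), m)
#' @export
score_classify <- function(record_features, model) {
  stopifnot(inherits(model, "nmo_score_model"))
  pres <- function(ids) {
    x <- record_features[ids]
    x[is.na(x)] <- FALSE
    as.numeric(x)
  }
  class_score <- function(weights) {
    ids <- names(weights)
    x <- pres(ids)
    if (model$mode == "summative") return(sum(weights * x))
    reg <- model$feature_region[ids]
    sub <- tapply(weights * x, reg, sum)
    cuts <- model$regional_cutoffs[names(sub)]
    cuts[is.na(cuts)] <- 0
    sum(sub[sub >= cuts])
  }
  nmo <- class_score(model$nmosd_features)
  ms <- class_score(model$ms_features)
  tibble::tibble(
    nmo_score = nmo, ms_score = ms,
    prediction = ifelse(nmo * model$combination_ratio > ms, "NMOSD", "MS")
  )
}

#' Decision-tree engine
#'
#' A tree is a nested structure of nodes `list(feature = id, yes = <node>,
#' no = <node>)` with leaves given as the strings `"NMOSD"` or `"MS"`.
#' Classification descends from the root; an absent or missing feature
#' follows the `no` branch. Trees are validated at load time: every tested
#' feature must exist in the catalogue and every path must end in a leaf.
#'
#' @param tree A nested node list (e.g. parsed from YAML).
#' @param catalog A feature catalogue.
#' @return An object of class `nmo_decision_tree`.
#' @export
decision_tree <- function(tree, catalog = nmo_feature_catalog()) {
  check_node <- function(node, depth = 0) {
    if (depth > 64) stop("decision tree too deep; is it cyclic?")
    if (is.character(node) && length(node) == 1) {
      if (!node %in% c("NMOSD", "MS")) {
        stop("leaf label must be NMOSD or MS, got: ", node)
      }
      return(invisible(TRUE))
    }
    if (!is.list(node) || !all(c("feature", "yes", "no") %in% names(node))) {
      stop("malformed tree node: need feature/yes/no or a leaf label")
    }
    if (length(validate_feature_refs(catalog, node$feature)) > 0) {
      stop("tree tests unknown feature: ", node$feature)
    }
    check_node(node$yes, depth + 1)
    check_node(node$no, depth + 1)
  }
  check_node(tree)
  structure(list(root = tree), class = "nmo_decision_tree")
}

#' @rdname decision_tree
#' @param record_features Named logical vector of feature presence.
#' @return For `tree_classify`, `"NMOSD"` or `"MS"`.
#' @export
tree_classify <- function(record_features, tree) {
  stopifnot(inherits(tree, "nmo_decision_tree"))
  node <- tree$root
  while (!is.character(node)) {
    x <- feature_value(record_features, node$feature)
    node <- if (isTRUE(x)) node$yes else node$no
  }
  node
}

# safe lookup in a named logical vector/list: absent or NA -> FALSE
feature_value <- function(record_features, id) {
  if (!id %in% names(record_features)) return(FALSE)
  x <- record_features[[id]]
  !is.na(x) && x
}

tree_features <- function(tree) {
  collect <- function(node) {
    if (is.character(node)) return(character())
    c(node$feature, collect(node$yes), collect(node$no))
  }
  unique(collect(tree$root))
}

#' Declarative boolean rule sets
#'
#' External comparison criteria are represented as boolean expressions over
#' catalogue feature ids, using `AND`, `OR`, `NOT` (or `&`, `|`, `!`) and
#' parentheses. When the expression is true the rule set's `predicts` class
#' is assigned, otherwise the opposite class. Missing features evaluate as
#' absent. Expressions are validated against the catalogue at load time.
#'
#' @param expression A single expression string, e.g.
#'   `"longitudinal_cord_T2 AND NOT dawsons_fingers"`.
#' @param predicts Class assigned when the expression is true (default
#'   `"NMOSD"`).
#' @param name Optional display name.
#' @param catalog A feature catalogue.
#' @return An object of class `nmo_ruleset`.
#' @export
ruleset <- function(expression, predicts = c("NMOSD", "MS"), name = NULL,
                    catalog = nmo_feature_catalog()) {
  predicts <- match.arg(predicts)
  txt <- gsub("\\bAND\\b", "&", expression)
  txt <- gsub("\\bOR\\b", "|", txt)
  txt <- gsub("\\bNOT\\b", "!", txt)
  expr <- tryCatch(str2lang(txt),
                   error = function(e) stop("cannot parse ruleset: ", expression))
  vars <- all.vars(expr)
  allowed_consts <- c("TRUE", "FALSE", "T", "F")
  vars <- setdiff(vars, allowed_consts)
  unknown <- validate_feature_refs(catalog, vars)
  if (length(unknown) > 0) {
    stop("ruleset references unknown features: ",
         paste(unknown, collapse = ", "))
  }
  structure(
    list(expr = expr, vars = vars, predicts = predicts,
         name = name %||% expression),
    class = "nmo_ruleset"
  )
}

#' @rdname ruleset
#' @param record_features Named logical vector of feature presence.
#' @return For `external_criteria`, `"NMOSD"` or `"MS"`.
#' @export
external_criteria <- function(record_features, ruleset) {
  stopifnot(inherits(ruleset, "nmo_ruleset"))
  env <- new.env(parent = baseenv())
  for (v in ruleset$vars) {
    assign(v, feature_value(record_features, v), envir = env)
  }
  hit <- isTRUE(eval(ruleset$expr, env))
  other <- setdiff(c("NMOSD", "MS"), ruleset$predicts)
  if (hit) ruleset$predicts else other
}

#' Single-feature criterion classifier
#'
#' Wraps one binary catalogue feature as a diagnosis rule: when the feature
#' is present the patient is labelled `when_present`, otherwise the opposite
#' class. Used e.g. to turn the Paty or Barkhof criterion feature into an
#' NMOSD-vs-MS classifier (criteria met implies MS).
#'
#' @param feature_id A catalogue feature id.
#' @param when_present Label assigned when the feature is present.
#' @param catalog A feature catalogue.
#' @return An object of class `nmo_feature_rule`.
#' @export
feature_rule <- function(feature_id, when_present = c("MS", "NMOSD"),
                         catalog = nmo_feature_catalog()) {
  when_present <- match.arg(when_present)
  if (length(validate_feature_refs(catalog, feature_id)) > 0) {
    stop("unknown feature: ", feature_id)
  }
  structure(list(feature_id = feature_id, when_present = when_present),
            class = "nmo_feature_rule")
}

# ---- cohort-level prediction -----------------------------------------------

#' Classify every patient in a feature matrix
#'
#' Applies a classifier to each patient's binary feature vector taken from
#' the `first` or `ever` column of a feature matrix. Missing features
#' evaluate as absent inside the classifier, but a patient for whom *every*
#' feature the classifier consults is missing lacks the imaging the rule
#' requires and receives `NA` (unclassifiable); evaluation drops such
#' patients and reduces the denominator.
#'
#' @param classifier An `nmo_score_model`, `nmo_decision_tree`,
#'   `nmo_ruleset` or `nmo_feature_rule`.
#' @param feature_matrix Output of [build_feature_matrix()].
#' @param which `"first"` or `"ever"` imaging.
#' @return A tibble with `patient_id`, `diagnosis`, `prediction` (and score
#'   columns for score models).
#' @export
predict_diagnosis <- function(classifier, feature_matrix,
                              which = c("first", "ever")) {
  UseMethod("predict_diagnosis")
}

#' @export
predict_diagnosis.nmo_score_model <- function(classifier, feature_matrix,
                                              which = c("first", "ever")) {
  which <- match.arg(which)
  wide <- features_wide(feature_matrix, which)
  ids <- c(names(classifier$nmosd_features), names(classifier$ms_features))
  X <- feature_matrix_numeric(wide, ids)
  all_missing <- rowSums(!is.na(X)) == 0
  X[is.na(X)] <- 0
  w_n <- numeric(length(ids)); names(w_n) <- ids
  w_n[names(classifier$nmosd_features)] <- classifier$nmosd_features
  w_m <- numeric(length(ids)); names(w_m) <- ids
  w_m[names(classifier$ms_features)] <- classifier$ms_features
  if (classifier$mode == "summative") {
    nmo <- as.vector(X %*% w_n)
    ms <- as.vector(X %*% w_m)
  } else {
    sc <- t(apply(X, 1, function(row) {
      r <- score_classify(stats::setNames(row > 0, ids), classifier)
      c(r$nmo_score, r$ms_score)
    }))
    nmo <- sc[, 1]; ms <- sc[, 2]
  }
  pred <- ifelse(nmo * classifier$combination_ratio > ms, "NMOSD", "MS")
  pred[all_missing] <- NA_character_
  tibble::tibble(
    patient_id = wide$patient_id, diagnosis = wide$diagnosis,
    nmo_score = nmo, ms_score = ms, prediction = pred
  )
}

#' @export
predict_diagnosis.nmo_decision_tree <- function(classifier, feature_matrix,
                                                which = c("first", "ever")) {
  which <- match.arg(which)
  wide <- features_wide(feature_matrix, which)
  ids <- tree_features(classifier)
  X <- feature_matrix_numeric(wide, ids)
  all_missing <- rowSums(!is.na(X)) == 0
  pred <- vapply(seq_len(nrow(wide)), function(i) {
    tree_classify(stats::setNames(!is.na(X[i, ]) & X[i, ] > 0, ids), classifier)
  }, character(1))
  pred[all_missing] <- NA_character_
  tibble::tibble(patient_id = wide$patient_id, diagnosis = wide$diagnosis,
                 prediction = pred)
}

#' @export
predict_diagnosis.nmo_ruleset <- function(classifier, feature_matrix,
                                          which = c("first", "ever")) {
  which <- match.arg(which)
  wide <- features_wide(feature_matrix, which)
  ids <- classifier$vars
  if (length(ids) == 0) {
    pred <- rep(external_criteria(logical(), classifier), nrow(wide))
    return(tibble::tibble(patient_id = wide$patient_id,
                          diagnosis = wide$diagnosis, prediction = pred))
  }
  X <- feature_matrix_numeric(wide, ids)
  all_missing <- rowSums(!is.na(X)) == 0
  pred <- vapply(seq_len(nrow(wide)), function(i) {
    external_criteria(stats::setNames(!is.na(X[i, ]) & X[i, ] > 0, ids),
                      classifier)
  }, character(1))
  pred[all_missing] <- NA_character_
  tibble::tibble(patient_id = wide$patient_id, diagnosis = wide$diagnosis,
                 prediction = pred)
}

#' @export
predict_diagnosis.nmo_feature_rule <- function(classifier, feature_matrix,
                                               which = c("first", "ever")) {
  which <- match.arg(which)
  wide <- features_wide(feature_matrix, which)
  x <- wide[[classifier$feature_id]]
  if (is.null(x)) stop("feature matrix lacks feature ", classifier$feature_id)
  other <- setdiff(c("NMOSD", "MS"), classifier$when_present)
  pred <- ifelse(is.na(x), NA_character_,
                 ifelse(x, classifier$when_present, other))
  tibble::tibble(patient_id = wide$patient_id, diagnosis = wide$diagnosis,
                 prediction = pred)
}

# wide logical feature table: patient_id, diagnosis, <feature columns>
features_wide <- function(feature_matrix, which) {
  feature_matrix |>
    dplyr::select("patient_id", "diagnosis", "feature_id",
                  value = dplyr::all_of(which)) |>
    tidyr::pivot_wider(names_from = "feature_id", values_from = "value")
}

feature_matrix_numeric <- function(wide, ids) {
  missing_ids <- setdiff(ids, names(wide))
  if (length(missing_ids) > 0) {
    stop("feature matrix lacks features: ", paste(missing_ids, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(lapply(wide[ids], as.numeric)))
  colnames(X) <- ids
  X
}

# ---- config I/O ------------------------------------------------------------

#' Read / write score models, trees and rule sets as YAML
#'
#' Score models serialise as `nmosd_features` / `ms_features` weight maps
#' plus `combination_ratio`, `mode` and `regional_cutoffs`; trees as nested
#' `feature`/`yes`/`no` maps with string leaves; rule sets as `expression` /
#' `predicts`. All are validated against the catalogue on read.
#'
#' @param path YAML file path.
#' @param catalog A feature catalogue.
#' @return The corresponding classifier object.
#' @export
read_score_model <- function(path, catalog = nmo_feature_catalog()) {
  y <- yaml::read_yaml(path)
  score_model(
    nmosd_features = unlist(y$nmosd_features),
    ms_features = unlist(y$ms_features),
    combination_ratio = y$combination_ratio %||% 3.5,
    mode = y$mode %||% "summative",
    regional_cutoffs = unlist(y$regional_cutoffs) %||%
      c(optic_nerve = 0, brain = 0, spinal_cord = 0),
    catalog = catalog
  )
}

#' @rdname read_score_model
#' @param model An `nmo_score_model`.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "nmo_score_model"))
  yaml::write_yaml(
    list(
      nmosd_features = as.list(model$nmosd_features),
      ms_features = as.list(model$ms_features),
      combination_ratio = model$combination_ratio,
      mode = model$mode,
      regional_cutoffs = as.list(model$regional_cutoffs)
    ),
    path
  )
  invisible(path)
}

#' @rdname read_score_model
#' @export
read_decision_tree <- function(path, catalog = nmo_feature_catalog()) {
  decision_tree(yaml::read_yaml(path), catalog = catalog)
}

#' @rdname read_score_model
#' @export
read_ruleset <- function(path, catalog = nmo_feature_catalog()) {
  y <- yaml::read_yaml(path)
  ruleset(y$expression, predicts = y$predicts %||% "NMOSD",
          name = y$name, catalog = catalog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
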