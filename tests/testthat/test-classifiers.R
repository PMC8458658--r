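test_that("Paty and Barkhof rules follow their stated clauses", {
  expect_true(paty(n_wm = 3, n_wm_gt3mm = 3, n_periventricular = 0))
  expect_true(paty(n_wm = 2, n_wm_gt3mm = 0, n_periventricular = 1))
  expect_false(paty(n_wm = 1, n_wm_gt3mm = 1, n_periventricular = 1))
  expect_false(paty(n_wm = 0, n_wm_gt3mm = 0, n_periventricular = 0))

  expect_true(barkhof(gd_lesion = TRUE, n_T2 = 1, n_infratentorial = 1,
                      n_juxtacortical = 1, n_periventricular = 2))
  expect_false(barkhof(gd_lesion = FALSE, n_T2 = 9, n_infratentorial = 0,
                       n_juxtacortical = 0, n_periventricular = 0))
  expect_false(barkhof(FALSE, 0, 0, 0, 0))
})

test_that("score models validate their structure at construction", {
  expect_error(score_model(c(longitudinal_cord_T2 = 1),
                           c(longitudinal_cord_T2 = 1)), "disjoint")
  expect_error(score_model(c(not_a_feature = 1), c(ovoid_T2 = 1)), "unknown")
  expect_error(score_model(c(longitudinal_cord_T2 = 0), c(ovoid_T2 = 1)))
  m <- default_score_model()
  expect_s3_class(m, "nmo_score_model")
  expect_equal(m$combination_ratio, 3.5)
  expect_equal(m$nmosd_features[["longitudinal_cord_T2"]], 2)
  expect_equal(m$ms_features[["ovoid_T2"]], 2)
})

test_that("the combination rule is strict: nmo x 3.5 > ms", {
  m <- score_model(
    nmosd_features = c(longitudinal_cord_T2 = 2),
    ms_features = c(ovoid_T2 = 2, dawsons_fingers = 1, periventricular_T2 = 1,
                    black_hole_T1 = 1, juxtacortical_T2 = 1,
                    temporal_lobe_T2 = 1),
    combination_ratio = 3.5
  )
  # nmo_score 2, ms_score 6: 7 > 6 -> NMOSD
  r1 <- score_classify(c(longitudinal_cord_T2 = TRUE, ovoid_T2 = TRUE,
                         dawsons_fingers = TRUE, periventricular_T2 = TRUE,
                         black_hole_T1 = TRUE, juxtacortical_T2 = TRUE),
                       m)
  expect_equal(c(r1$nmo_score, r1$ms_score), c(2, 6))
  expect_equal(r1$prediction, "NMOSD")
  # nmo_score 2, ms_score 7: 7 > 7 is false -> MS
  r2 <- score_classify(c(longitudinal_cord_T2 = TRUE, ovoid_T2 = TRUE,
                         dawsons_fingers = TRUE, periventricular_T2 = TRUE,
                         black_hole_T1 = TRUE, juxtacortical_T2 = TRUE,
                         temporal_lobe_T2 = TRUE), m)
  expect_equal(c(r2$nmo_score, r2$ms_score), c(2, 7))
  expect_equal(r2$prediction, "MS")
  # zero NMOSD score is never NMOSD
  r3 <- score_classify(c(ovoid_T2 = FALSE), m)
  expect_equal(r3$prediction, "MS")
  # missing features count as absent
  r4 <- score_classify(c(longitudinal_cord_T2 = NA), m)
  expect_equal(r4$nmo_score, 0)
})

test_that("score classification is monotone in its feature sets", {
  m <- default_score_model()
  ids <- c(names(m$nmosd_features), names(m$ms_features))
  set.seed(7)
  for (i in 1:25) {
    rec <- stats::setNames(stats::runif(length(ids)) < 0.3, ids)
    base <- score_classify(rec, m)
    off <- names(which(!rec))
    if (length(off) == 0) next
    add <- sample(off, 1)
    rec2 <- rec; rec2[add] <- TRUE
    new <- score_classify(rec2, m)
    if (add %in% names(m$nmosd_features)) {
      if (base$prediction == "NMOSD") expect_equal(new$prediction, "NMOSD")
    } else {
      if (base$prediction == "MS") expect_equal(new$prediction, "MS")
    }
  }
})

test_that("regional mode gates sub-scores by their cut-offs", {
  m <- score_model(
    nmosd_features = c(longitudinal_cord_T2 = 1, cord_gd = 1,
                       hypothalamic_T2 = 1),
    ms_features = c(ovoid_T2 = 1),
    mode = "regional",
    regional_cutoffs = c(optic_nerve = 0, brain = 0, spinal_cord = 2)
  )
  # cord sub-score 1 < cutoff 2: contributes nothing
  r <- score_classify(c(longitudinal_cord_T2 = TRUE), m)
  expect_equal(r$nmo_score, 0)
  # cord sub-score 2 meets the cut-off
  r2 <- score_classify(c(longitudinal_cord_T2 = TRUE, cord_gd = TRUE), m)
  expect_equal(r2$nmo_score, 2)
  # brain sub-score has cut-off 0 and always contributes
  r3 <- score_classify(c(hypothalamic_T2 = TRUE), m)
  expect_equal(r3$nmo_score, 1)
})

test_that("decision trees classify deterministically with absent as no", {
  t1 <- decision_tree(list(feature = "longitudinal_cord_T2",
                           yes = "NMOSD", no = "MS"))
  expect_equal(tree_classify(c(longitudinal_cord_T2 = TRUE), t1), "NMOSD")
  expect_equal(tree_classify(c(longitudinal_cord_T2 = FALSE), t1), "MS")
  expect_equal(tree_classify(c(longitudinal_cord_T2 = NA), t1), "MS")
  expect_equal(tree_classify(logical(), t1), "MS")
  rec <- c(longitudinal_cord_T2 = TRUE)
  expect_equal(tree_classify(rec, t1), tree_classify(rec, t1))

  expect_error(decision_tree(list(feature = "nope", yes = "NMOSD",
                                  no = "MS")), "unknown")
  expect_error(decision_tree(list(feature = "ovoid_T2", yes = "NMOSD")),
               "malformed")
  expect_error(decision_tree(list(feature = "ovoid_T2", yes = "NMOSD",
                                  no = "maybe")), "leaf")
})

test_that("a tree encoding the score boundary reproduces score_classify", {
  nmo_ids <- c("longitudinal_cord_T2", "bilateral_optic_nerve", "cord_gd",
               "hypothalamic_T2", "periaqueductal_T2", "optic_nerve_T2")
  ms_ids <- c("ovoid_T2", "dawsons_fingers", "periventricular_T2",
              "black_hole_T1", "juxtacortical_T2", "short_cord_T2")
  w_n <- stats::setNames(c(2, 2, 1, 1, 1, 1), nmo_ids)
  w_m <- stats::setNames(c(2, 1, 1, 1, 1, 1), ms_ids)
  model <- score_model(w_n, w_m, combination_ratio = 3.5)
  ids <- c(nmo_ids, ms_ids)
  w_all <- c(w_n, w_m)
  is_nmo_feat <- c(rep(TRUE, 6), rep(FALSE, 6))

  # enumerate the rule into an explicit tree, feature by feature
  build <- function(i, s_n, s_m) {
    if (i > length(ids)) {
      return(if (s_n * 3.5 > s_m) "NMOSD" else "MS")
    }
    list(
      feature = ids[i],
      yes = build(i + 1, s_n + if (is_nmo_feat[i]) w_all[[i]] else 0,
                  s_m + if (is_nmo_feat[i]) 0 else w_all[[i]]),
      no = build(i + 1, s_n, s_m)
    )
  }
  tr <- decision_tree(build(1, 0, 0))

  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 12)))
  colnames(combos) <- ids
  by_tree <- vapply(seq_len(nrow(combos)),
                    function(r) tree_classify(combos[r, ], tr), character(1))
  by_score <- ifelse(
    as.vector(combos %*% c(w_n, rep(0, 6))) * 3.5 >
      as.vector(combos %*% c(rep(0, 6), w_m)),
    "NMOSD", "MS")
  expect_identical(by_tree, by_score)
  # spot-check the matrix shortcut against score_classify itself
  for (r in sample(nrow(combos), 20)) {
    expect_identical(score_classify(combos[r, ], model)$prediction,
                     by_score[r])
  }
})

test_that("rule sets evaluate boolean expressions over features", {
  rs <- ruleset("longitudinal_cord_T2 AND NOT dawsons_fingers")
  expect_equal(external_criteria(c(longitudinal_cord_T2 = TRUE), rs), "NMOSD")
  expect_equal(external_criteria(c(longitudinal_cord_T2 = TRUE,
                                   dawsons_fingers = TRUE), rs), "MS")
  expect_equal(external_criteria(logical(), ruleset("TRUE")), "NMOSD")
  expect_equal(external_criteria(logical(), ruleset("FALSE")), "MS")
  rs_ms <- ruleset("ovoid_T2 OR periventricular_T2", predicts = "MS")
  expect_equal(external_criteria(c(ovoid_T2 = TRUE), rs_ms), "MS")
  expect_equal(external_criteria(c(ovoid_T2 = FALSE), rs_ms), "NMOSD")
  expect_error(ruleset("unbound_feature"), "unknown")
})

test_that("classifier configs load from YAML and round-trip", {
  m <- default_score_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_score_model(m, path)
  m2 <- read_score_model(path)
  expect_equal(m2$nmosd_features, m$nmosd_features)
  expect_equal(m2$ms_features, m$ms_features)
  expect_equal(m2$combination_ratio, m$combination_ratio)

  tree_path <- system.file("extdata", "decision_tree_synthetic.yaml",
                           package = "nmosdmri")
  tr <- read_decision_tree(tree_path)
  expect_equal(tree_classify(c(longitudinal_cord_T2 = TRUE), tr), "NMOSD")
  expect_equal(tree_classify(c(ovoid_T2 = TRUE), tr), "MS")

  rs <- read_ruleset(system.file("extdata", "ruleset_synthetic.yaml",
                                 package = "nmosdmri"))
  expect_equal(external_criteria(c(longitudinal_cord_T2 = TRUE), rs), "NMOSD")
})

test_that("cohort-level prediction handles unclassifiable patients", {
  co <- make_tiny_cohort()
  fm <- build_feature_matrix(co)
  # a cord-only rule cannot classify the MS patients (no spine imaging)
  rs <- ruleset("longitudinal_cord_T2")
  pred <- predict_diagnosis(rs, fm, "ever")
  expect_true(all(is.na(pred$prediction[pred$patient_id %in% c("P3", "P4")])))
  expect_equal(pred$prediction[pred$patient_id == "P2"], "NMOSD")

  # Paty as a diagnosis rule: criteria met implies MS
  fr <- feature_rule("paty_criteria", when_present = "MS")
  predf <- predict_diagnosis(fr, fm, "first")
  expect_equal(predf$prediction[predf$patient_id == "P3"], "MS")
  expect_equal(predf$prediction[predf$patient_id == "P1"], "NMOSD")
})
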