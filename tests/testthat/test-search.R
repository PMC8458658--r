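test_that("cut-off escalation terminates at perfect specificity on separable data", {
  fm <- make_separable_matrix(10, 15)
  traj <- escalate_cutoffs(c(longitudinal_cord_T2 = 1), fm, target = "NMOSD")
  expect_true(all(diff(traj$cutoff) > 0))
  last <- traj[nrow(traj), ]
  expect_equal(last$specificity, 1.0)
  expect_equal(last$sensitivity, 1.0)
})

test_that("a pure-noise score terminates by the sensitivity floor", {
  set.seed(21)
  n <- 200
  diagnosis <- rep(c("NMOSD", "MS"), each = n / 2)
  fm <- dplyr::bind_rows(lapply(
    c("punctate_T2", "patch_T2", "cystic_T2"),
    function(fid) tibble::tibble(
      patient_id = sprintf("P%03d", 1:n), diagnosis = diagnosis,
      feature_id = fid, first = stats::runif(n) < 0.5,
      ever = stats::runif(n) < 0.5, max_count = NA_integer_
    )))
  w <- c(punctate_T2 = 1, patch_T2 = 1, cystic_T2 = 1)
  traj <- escalate_cutoffs(w, fm, target = "NMOSD")
  last <- traj[nrow(traj), ]
  expect_true(last$sensitivity < 0.5 || last$specificity == 1.0)
  # a non-informative score must cross the floor before hitting spec 1.0
  expect_lt(last$sensitivity, 0.5)

  # cut-off beyond the maximum attainable score: sensitivity 0
  cfg <- search_config(cutoff_grid = 10)
  traj2 <- escalate_cutoffs(w, fm, target = "NMOSD", config = cfg)
  expect_equal(traj2$sensitivity, 0)
  expect_equal(traj2$specificity, 1)
  expect_error(escalate_cutoffs(w, fm[0, ], target = "NMOSD"), "empty")
})

test_that("refinement removes a pure-noise feature from a separable model", {
  set.seed(4)
  fm <- make_separable_matrix(20, 30, noise_features = "punctate_T2")
  fit <- refine_model(c(longitudinal_cord_T2 = 1, punctate_T2 = 1), fm,
                      target = "NMOSD")
  expect_false("punctate_T2" %in% names(fit$weights))
  expect_equal(fit$specificity, 1.0)
  expect_gte(fit$sensitivity, 0.5)
  expect_true(all(c("features", "cutoff", "sensitivity", "specificity",
                    "accepted") %in% names(fit$log)))
})

test_that("an already-optimal single-feature model is returned unchanged", {
  fm <- make_separable_matrix(10, 15)
  fit <- refine_model(c(longitudinal_cord_T2 = 1), fm, target = "NMOSD")
  expect_equal(fit$weights, c(longitudinal_cord_T2 = 1))
})

test_that("the whole search is a pure function of data and config", {
  co <- generate_cohort(cohort_spec(n_nmosd = 40, n_ms = 60), seed = 13)
  fm <- build_feature_matrix(co)
  s1 <- search_combined(fm)
  s2 <- search_combined(fm)
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_score_model(s1$model, f1)
  write_score_model(s2$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$ratio, s2$ratio)

  # symmetric equally-good features resolve reproducibly in feature order
  fm_sym <- dplyr::bind_rows(
    make_separable_matrix(10, 15, feature = "hypothalamic_T2"),
    make_separable_matrix(10, 15, feature = "periaqueductal_T2")
  )
  cfg <- search_config(nmosd_candidates = c("hypothalamic_T2",
                                            "periaqueductal_T2"),
                       ms_candidates = "ovoid_T2")
  fm_sym <- dplyr::bind_rows(
    fm_sym,
    make_separable_matrix(10, 15, feature = "ovoid_T2") |>
      dplyr::mutate(first = !first, ever = !ever)
  )
  r1 <- refine_model(c(hypothalamic_T2 = 1, periaqueductal_T2 = 1), fm_sym,
                     target = "NMOSD", config = cfg)
  r2 <- refine_model(c(hypothalamic_T2 = 1, periaqueductal_T2 = 1), fm_sym,
                     target = "NMOSD", config = cfg)
  expect_identical(r1$weights, r2$weights)
})

test_that("search_combined honours the ratio grid and requires both classes", {
  fm <- make_separable_matrix(10, 15)
  fm <- dplyr::bind_rows(
    fm,
    make_separable_matrix(10, 15, feature = "ovoid_T2") |>
      dplyr::mutate(first = !first, ever = !ever)
  )
  cfg <- search_config(nmosd_candidates = "longitudinal_cord_T2",
                       ms_candidates = "ovoid_T2",
                       ratio_grid = 3.5)
  sr <- search_combined(fm, cfg)
  expect_equal(sr$ratio, 3.5)
  expect_equal(sr$evaluation$metrics$roc_area, 1.0)

  single <- fm[fm$diagnosis == "MS", ]
  expect_error(search_combined(single, cfg), "both")
})

test_that("in-sample search precision exceeds fresh-cohort precision", {
  ins <- oos <- numeric(2)
  for (i in 1:2) {
    co <- generate_cohort(cohort_spec(), seed = i)
    fm <- build_feature_matrix(co)
    sr <- search_combined(fm)
    ins[i] <- sr$evaluation$metrics$precision
    co2 <- generate_cohort(cohort_spec(), seed = 500 + i)
    oos[i] <- evaluate_classifier(sr$model, build_feature_matrix(co2),
                                  "ever")$metrics$precision
  }
  # optimism of the in-sample procedure, demonstrated on synthetic cohorts
  expect_gt(mean(ins), mean(oos))
  expect_true(all(oos > 0.8))  # the signal itself is real

  sr <- search_combined(build_feature_matrix(
    generate_cohort(cohort_spec(n_nmosd = 40, n_ms = 60), seed = 3)))
  td <- tidy(sr)
  expect_true(all(c("feature_id", "class", "weight") %in% names(td)))
  gl <- glance(sr)
  expect_true(all(c("ratio", "precision", "roc_area") %in% names(gl)))
})
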