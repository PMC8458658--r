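test_that("scan timing uses the 90-days-before / 30-days-after window", {
  d0 <- as.Date("2020-01-01")
  expect_equal(classify_scan_timing(d0 + 100, d0 + 30), "relapse")
  expect_equal(classify_scan_timing(d0 + 100, d0 + 125), "relapse")
  expect_equal(classify_scan_timing(d0 + 100, d0 + 135), "remission")
  # inclusive at both ends
  expect_equal(classify_scan_timing(d0 + 100, d0 + 10), "relapse")
  expect_equal(classify_scan_timing(d0 + 100, d0 + 9), "remission")
  expect_equal(classify_scan_timing(d0 + 100, d0 + 130), "relapse")
  expect_equal(classify_scan_timing(d0 + 100, d0 + 131), "remission")
  expect_equal(classify_scan_timing(d0, as.Date(character())), "remission")
  # vectorised over scans with per-scan relapse lists
  expect_equal(
    classify_scan_timing(c(d0 + 100, d0 + 100),
                         list(d0 + 30, d0 + 135)),
    c("relapse", "remission"))
})

test_that("long/short classification partitions cord lesions at 6 hemi-levels", {
  expect_equal(cord_lesion_length_class(3, 8), "long")
  expect_equal(cord_lesion_length_class(3, 7), "short")
  expect_equal(cord_lesion_length_class(5, 5), "short")
  set.seed(42)
  cl <- random_cord_lesions(200)
  cls <- cord_lesion_length_class(cl$start_level, cl$end_level)
  expect_true(all(cls %in% c("long", "short")))
  expect_equal(cls == "long", cl$end_level - cl$start_level + 1 >= 6)
})

test_that("cord features derive from lesion geometry", {
  one <- tibble::tibble(scan_id = "S", start_level = 3L, end_level = 10L,
                        axial_class = "whole", gd_enhancing = TRUE,
                        swelling = FALSE)
  f <- derive_cord_features(one)
  expect_true(all(f[c("longitudinal_cord_T2", "whole_cord_T2",
                      "central_cord_T2", "cord_gd")]))
  expect_false(any(f[c("short_cord_T2", "partial_cord_T2", "cord_swelling")]))

  expect_false(any(derive_cord_features(one[0, ])))

  two <- tibble::tibble(scan_id = "S", start_level = c(3L, 10L),
                        end_level = c(4L, 12L),
                        axial_class = "partial", gd_enhancing = FALSE,
                        swelling = FALSE)
  f2 <- derive_cord_features(two)
  expect_true(f2[["short_cord_T2"]] && f2[["partial_cord_T2"]])
  expect_false(f2[["longitudinal_cord_T2"]])
})

test_that("white-matter lesion class resolves by preference order", {
  expect_equal(resolve_wm_lesion_class(c("periventricular", "subcortical")),
               "periventricular")
  expect_equal(resolve_wm_lesion_class(c("tumefactive", "periventricular")),
               "tumefactive")
  expect_equal(resolve_wm_lesion_class("subcortical"), "subcortical")
  expect_equal(resolve_wm_lesion_class(c("subcortical", "juxtacortical",
                                         "cortical")), "cortical")
  expect_error(resolve_wm_lesion_class(character()), "non-empty")
  expect_error(resolve_wm_lesion_class("elsewhere"), "unknown")
})

test_that("feature matrix aggregates first/ever with missing-region NA", {
  co <- make_tiny_cohort()
  fm <- build_feature_matrix(co)

  # P1's hypothalamic lesion appears only on the second scan
  p1 <- fm[fm$patient_id == "P1" & fm$feature_id == "hypothalamic_T2", ]
  expect_false(p1$first)
  expect_true(p1$ever)

  # P3 has no spine imaging: every cord entry missing
  p3_cord <- fm[fm$patient_id == "P3" &
                  fm$feature_id %in% c("longitudinal_cord_T2", "cord_gd"), ]
  expect_true(all(is.na(p3_cord$first)) && all(is.na(p3_cord$ever)))

  # single-scan patient: first == ever for in-region features
  p4 <- fm[fm$patient_id == "P4" & !is.na(fm$first), ]
  expect_equal(p4$first, p4$ever)

  # cord geometry flows through: P2's 8-level central lesion
  p2 <- fm[fm$patient_id == "P2", ]
  expect_true(p2$ever[p2$feature_id == "longitudinal_cord_T2"])
  expect_true(p2$ever[p2$feature_id == "central_cord_T2"])
  expect_true(p2$ever[p2$feature_id == "cord_gd"])

  # criterion features from counts: P3 (14 T2, 5 PV, 2 JC, 1 infra) meets
  # Paty and Barkhof on its only scan; P4 (2 lesions, 1 PV) meets Paty only
  expect_true(fm$first[fm$patient_id == "P3" &
                         fm$feature_id == "paty_criteria"])
  expect_true(fm$first[fm$patient_id == "P3" &
                         fm$feature_id == "barkhof_criteria"])
  expect_true(fm$first[fm$patient_id == "P4" &
                         fm$feature_id == "paty_criteria"])
  expect_false(fm$first[fm$patient_id == "P4" &
                          fm$feature_id == "barkhof_criteria"])
})

test_that("ever-presence is monotone and order-invariant", {
  co <- make_tiny_cohort()
  fm <- build_feature_matrix(co)
  expect_true(all(fm$ever >= fm$first, na.rm = TRUE))

  # adding a lesion-free scan never turns ever off
  extra <- co$scans[1, ]
  extra$scan_id <- "S99"
  extra$scan_date <- as.Date("2021-01-01")
  extra$hypothalamic_T2 <- FALSE
  extra$n_T2_total <- 0L; extra$n_wm <- 0L; extra$n_wm_gt3mm <- 0L
  extra$n_periventricular <- 0L; extra$n_juxtacortical <- 0L
  extra$n_infratentorial <- 0L
  co2 <- nmo_cohort(co$patients, dplyr::bind_rows(co$scans, extra),
                    co$cord_lesions)
  fm2 <- build_feature_matrix(co2)
  was_on <- !is.na(fm$ever) & fm$ever
  still_on <- !is.na(fm2$ever) & fm2$ever
  expect_true(all(still_on[was_on]))

  # shuffling scan-row order does not change the matrix
  set.seed(1)
  co3 <- nmo_cohort(co$patients, co$scans[sample(nrow(co$scans)), ],
                    co$cord_lesions)
  expect_equal(build_feature_matrix(co3), fm)
})

test_that("cohort validation enforces the data model", {
  co <- make_tiny_cohort()
  dup <- dplyr::bind_rows(co$patients, co$patients[1, ])
  expect_error(nmo_cohort(dup, co$scans, co$cord_lesions), "duplicate")
  bad_cl <- co$cord_lesions
  bad_cl$end_level[1] <- 50L
  expect_error(nmo_cohort(co$patients, co$scans, bad_cl), "44")
  # cord lesions must attach to spine scans
  bad_cl2 <- co$cord_lesions
  bad_cl2$scan_id[1] <- "S1"
  expect_error(nmo_cohort(co$patients, co$scans, bad_cl2), "spine")
  # count > 0 forces presence
  sc <- co$scans
  sc$n_hypothalamic_T2 <- c(2L, 0L, 0L, 0L, 0L, 0L)
  co4 <- nmo_cohort(co$patients, sc, co$cord_lesions)
  expect_true(co4$scans$hypothalamic_T2[co4$scans$scan_id == "S1"])
})

test_that("cohort tables round-trip through the on-disk format", {
  co <- make_tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(co2$patients$patient_id, co$patients$patient_id)
  expect_equal(co2$patients$relapse_dates, co$patients$relapse_dates)
  expect_equal(build_feature_matrix(co2), build_feature_matrix(co))
})

test_that("orbit-coverage switch controls optic feature denominators", {
  co <- make_tiny_cohort()  # brain scans but no orbit scans
  fm_incl <- build_feature_matrix(co, optic_from_brain = TRUE)
  fm_excl <- build_feature_matrix(co, optic_from_brain = FALSE)
  opt_incl <- fm_incl[fm_incl$feature_id == "optic_nerve_T2", ]
  opt_excl <- fm_excl[fm_excl$feature_id == "optic_nerve_T2", ]
  expect_true(any(!is.na(opt_incl$ever)))
  expect_true(all(is.na(opt_excl$ever)))
})
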