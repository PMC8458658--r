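# Small hand-built cohorts used across tests. Fixtures are constructed in
# code so every expected value can be read off the construction.

tiny_catalog <- nmo_feature_catalog()

# two NMOSD, two MS patients; P1 has a brain feature appearing only on the
# second scan; P3 has no spine imaging; P4 has a single scan
make_tiny_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    diagnosis = c("NMOSD", "NMOSD", "MS", "MS"),
    onset_date = as.Date("2019-01-01") + 0:3,
    relapse_dates = list(as.Date("2019-03-01"), as.Date(character()),
                         as.Date("2019-02-01"), as.Date(character()))
  )
  scans <- tibble::tibble(
    scan_id = c("S1", "S2", "S3", "S4", "S5", "S6"),
    patient_id = c("P1", "P1", "P2", "P3", "P4", "P1"),
    region = c("brain", "brain", "spine", "brain", "brain", "spine"),
    scan_date = as.Date(c("2019-06-01", "2020-06-01", "2019-06-01",
                          "2019-06-01", "2019-06-01", "2019-07-01")),
    gd_given = TRUE,
    hypothalamic_T2 = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    ovoid_T2 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    n_T2_total = c(1L, 2L, 0L, 14L, 2L, 0L),
    n_wm = c(1L, 2L, 0L, 14L, 2L, 0L),
    n_wm_gt3mm = c(1L, 2L, 0L, 10L, 1L, 0L),
    n_periventricular = c(0L, 0L, 0L, 5L, 1L, 0L),
    n_juxtacortical = c(0L, 0L, 0L, 2L, 0L, 0L),
    n_infratentorial = c(0L, 0L, 0L, 1L, 0L, 0L)
  )
  cord_lesions <- tibble::tibble(
    scan_id = c("S3", "S6"),
    start_level = c(3L, 10L),
    end_level = c(10L, 11L),
    axial_class = c("central", "partial"),
    gd_enhancing = c(TRUE, FALSE),
    swelling = c(FALSE, FALSE)
  )
  nmo_cohort(patients, scans, cord_lesions)
}

# feature matrix where a single feature separates the classes perfectly
make_separable_matrix <- function(n_nmosd = 10, n_ms = 15,
                                  feature = "longitudinal_cord_T2",
                                  noise_features = character()) {
  ids <- sprintf("P%03d", seq_len(n_nmosd + n_ms))
  diagnosis <- rep(c("NMOSD", "MS"), c(n_nmosd, n_ms))
  rows <- list(tibble::tibble(
    patient_id = ids, diagnosis = diagnosis, feature_id = feature,
    first = diagnosis == "NMOSD", ever = diagnosis == "NMOSD",
    max_count = NA_integer_
  ))
  for (nf in noise_features) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_id = ids, diagnosis = diagnosis, feature_id = nf,
      first = rep(c(TRUE, FALSE), length.out = length(ids)),
      ever = rep(c(TRUE, FALSE), length.out = length(ids)),
      max_count = NA_integer_
    )
  }
  dplyr::bind_rows(rows)
}

# random cord-lesion tables for property tests
random_cord_lesions <- function(n, scan_id = "S1") {
  start <- sample(1:44, n, replace = TRUE)
  len <- sample(1:12, n, replace = TRUE)
  end <- pmin(start + len - 1L, 44L)
  tibble::tibble(
    scan_id = scan_id, start_level = start, end_level = end,
    axial_class = sample(c("central", "partial", "whole", "unknown"), n,
                         replace = TRUE),
    gd_enhancing = sample(c(TRUE, FALSE), n, replace = TRUE),
    swelling = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}
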