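#' Specification for the synthetic cohort generator
#'
#' Default values encode the study conditions the analysis assumes: 66 NMOSD
#' and 100 MS patients; per-class prevalences of binary lesion features
#' back-solved from published odds ratios and printed marginals (and
#' therefore approximate for features whose exact frequencies are not
#' public); brain T2 total counts with medians near 4 (NMOSD) and 14 (MS);
#' spinal cord lesion geometry on 44 hemi-vertebral levels with a 70%
#' longitudinally-extensive-lesion frequency, 31% Gd-enhancement and 11%
#' lesion-free rate among spine-imaged NMOSD patients (30% lesion-free in
#' MS); and per-region scan availability (brain 94%/100%, spine 92%/86%,
#' orbits 27%/6% for NMOSD/MS).
#'
#' @param n_nmosd,n_ms Class sizes (defaults 66 and 100).
#' @param feature_prevalence Tibble `feature_id`, `p_nmosd`, `p_ms` of
#'   ever-presence probabilities for Bernoulli-sampled features. Cord
#'   geometry features (long/short/central/partial/whole/Gd/swelling) are
#'   generated from lesion spans instead and must not appear here.
#' @param brain_counts Negative-binomial parameters for total brain T2
#'   counts, list of `c(mu, size)` per class.
#' @param no_cord_lesion,cord_long_freq,cord_gd_freq,cord_swelling_freq
#'   Per-class probabilities (named `nmosd`, `ms`) of the corresponding
#'   patient-level cord findings among spine-imaged patients.
#' @param scan_availability Per-region, per-class probabilities that the
#'   region was ever imaged.
#' @param p_second_scan Probability a covered region has a second, later
#'   scan.
#' @param p_persist Probability an ever-present feature is already present
#'   on the first scan when a later scan exists.
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return A list of class `nmo_cohort_spec`.
#' @export
cohort_spec <- function(n_nmosd = 66, n_ms = 100,
                        feature_prevalence = default_feature_prevalence(),
                        brain_counts = list(nmosd = c(mu = 6.0, size = 1.0),
                                            ms = c(mu = 16, size = 2.6)),
                        no_cord_lesion = c(nmosd = 0.11, ms = 0.30),
                        cord_long_freq = c(nmosd = 0.70, ms = 0.012),
                        cord_gd_freq = c(nmosd = 0.31, ms = 0.012),
                        cord_swelling_freq = c(nmosd = 0.25, ms = 0.010),
                        scan_availability = list(
                          brain = c(nmosd = 0.94, ms = 1.00),
                          spine = c(nmosd = 0.92, ms = 0.86),
                          orbits = c(nmosd = 0.27, ms = 0.06)),
                        p_second_scan = 0.5, p_persist = 0.8,
                        seed = 1L) {
  spec <- list(
    n_nmosd = n_nmosd, n_ms = n_ms,
    feature_prevalence = tibble::as_tibble(feature_prevalence),
    brain_counts = brain_counts,
    no_cord_lesion = no_cord_lesion, cord_long_freq = cord_long_freq,
    cord_gd_freq = cord_gd_freq, cord_swelling_freq = cord_swelling_freq,
    scan_availability = scan_availability,
    p_second_scan = p_second_scan, p_persist = p_persist,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "nmo_cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_nmosd < 1 || spec$n_ms < 1) stop("class sizes must be >= 1")
  probs <- c(
    spec$feature_prevalence$p_nmosd, spec$feature_prevalence$p_ms,
    spec$no_cord_lesion, spec$cord_long_freq, spec$cord_gd_freq,
    spec$cord_swelling_freq, unlist(spec$scan_availability),
    spec$p_second_scan, spec$p_persist
  )
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (any(cord_feature_ids %in% spec$feature_prevalence$feature_id)) {
    stop("cord geometry features are generated from lesion spans, ",
         "not Bernoulli prevalences")
  }
  invisible(spec)
}

#' Default per-feature ever-prevalences
#'
#' Approximate per-class presence probabilities reproducing the direction
#' (and, loosely, the magnitude) of the published feature-association odds
#' ratios; exact source frequencies for most features are not public, so
#' these are back-solved values, not measurements.
#'
#' @return A tibble `feature_id`, `p_nmosd`, `p_ms`.
#' @export
default_feature_prevalence <- function() {
  tibble::tribble(
    ~feature_id,                     ~p_nmosd, ~p_ms,
    "bilateral_optic_nerve",            0.180, 0.007,
    "optic_nerve_gd",                   0.160, 0.012,
    "optic_nerve_T2",                   0.350, 0.100,
    "longitudinal_optic_nerve_T2",      0.080, 0.000,
    "optic_chiasm",                     0.060, 0.000,
    "nucleus_tractus_solitarius_T2",    0.100, 0.006,
    "periaqueductal_T2",                0.130, 0.009,
    "hypothalamic_T2",                  0.080, 0.012,
    "third_ventricle_T2",               0.100, 0.020,
    "area_postrema_T2",                 0.060, 0.000,
    "central_medullary_T2",             0.080, 0.000,
    "leptomeningeal_gd",                0.050, 0.000,
    "cloud_like_gd",                    0.060, 0.000,
    "longitudinal_cst_T2",              0.050, 0.000,
    "bright_spotty_cord_T2",            0.360, 0.006,
    "cord_atrophy",                     0.150, 0.020,
    "ovoid_T2",                         0.100, 0.800,
    "dawsons_fingers",                  0.070, 0.700,
    "pyramidal_cc_T2",                  0.045, 0.450,
    "periventricular_T2",               0.640, 0.930,
    "temporal_lobe_T2",                 0.170, 0.600,
    "black_hole_T1",                    0.160, 0.550,
    "juxtacortical_T2",                 0.350, 0.700,
    "subcortical_T2",                   0.550, 0.850,
    "cortical_T2",                      0.080, 0.250,
    "cerebellar_T2",                    0.100, 0.350,
    "splenium_T2",                      0.080, 0.300,
    "inferior_temporal_T2",             0.080, 0.350,
    "infratentorial_T2",                0.150, 0.450,
    "brain_gd",                         0.200, 0.400
  )
}

#' Generate a synthetic cohort
#'
#' Draws a reproducible cohort under a [cohort_spec()]: binary features are
#' sampled independently within class at the configured ever-prevalences
#' (the generator encodes no between-feature covariance); total brain T2
#' counts come from class-specific negative-binomial distributions;
#' spinal-cord lesions are sampled as spans on the 44 hemi-vertebral levels
#' with class-specific length and location profiles (NMOSD lesions centred
#' on C2-C6 and T2-T8, MS short lesions on C2-C7); scan availability is
#' thinned per region; and when a region has two scans, ever-present
#' features appear on the first with probability `p_persist`. Derived cord
#' features and criterion features (Paty, Barkhof, nine-or-more, normal
#' brain) emerge from the generated geometry and counts rather than being
#' sampled directly.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return An [nmo_cohort()].
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  validate_cohort_spec(spec)
  set.seed(as.integer(seed))

  n <- spec$n_nmosd + spec$n_ms
  diagnosis <- rep(c("NMOSD", "MS"), c(spec$n_nmosd, spec$n_ms))
  is_nmo <- diagnosis == "NMOSD"
  patient_id <- sprintf("P%04d", seq_len(n))

  onset <- as.Date("2008-01-01") + sample.int(3000, n, replace = TRUE)
  n_relapse <- 1 + stats::rpois(n, 2)
  relapse_dates <- purrr::map2(onset, n_relapse, function(o, k) {
    sort(o + cumsum(30 + stats::rexp(k, rate = 1 / 300)))
  })
  patients <- tibble::tibble(
    patient_id = patient_id, diagnosis = diagnosis,
    onset_date = onset, relapse_dates = relapse_dates
  )

  # per-region availability and scan counts
  avail <- lapply(spec$scan_availability, function(p) {
    stats::runif(n) < ifelse(is_nmo, p[["nmosd"]], p[["ms"]])
  })
  two_scans <- lapply(avail, function(a) a & stats::runif(n) < spec$p_second_scan)

  # ever / first presence per Bernoulli feature
  fp <- spec$feature_prevalence
  ever <- sapply(seq_len(nrow(fp)), function(j) {
    stats::runif(n) < ifelse(is_nmo, fp$p_nmosd[j], fp$p_ms[j])
  })
  colnames(ever) <- fp$feature_id
  persist <- matrix(stats::runif(n * nrow(fp)) < spec$p_persist, nrow = n)
  colnames(persist) <- fp$feature_id

  # brain T2 totals and consistent sub-counts
  bc <- spec$brain_counts
  n_T2 <- ifelse(is_nmo,
    stats::rnbinom(n, size = bc$nmosd[["size"]], mu = bc$nmosd[["mu"]]),
    stats::rnbinom(n, size = bc$ms[["size"]], mu = bc$ms[["mu"]]))
  sub_count <- function(present, p) {
    k <- stats::rbinom(n, size = pmax(n_T2 - 1L, 0L), prob = p)
    ifelse(present, 1L + k, 0L)
  }
  n_pv <- sub_count(ever[, "periventricular_T2"] & n_T2 > 0, 0.30)
  n_jc <- sub_count(ever[, "juxtacortical_T2"] & n_T2 > 0, 0.12)
  n_inf <- sub_count(ever[, "infratentorial_T2"] & n_T2 > 0, 0.08)
  n_wm_gt3mm <- stats::rbinom(n, size = n_T2, prob = 0.7)

  counts <- tibble::tibble(
    n_T2_total = as.integer(n_T2), n_wm = as.integer(n_T2),
    n_wm_gt3mm = as.integer(n_wm_gt3mm),
    n_periventricular = as.integer(n_pv),
    n_juxtacortical = as.integer(n_jc),
    n_infratentorial = as.integer(n_inf)
  )
  # presence consistency: count > 0 forces presence
  ever[, "periventricular_T2"] <- ever[, "periventricular_T2"] | n_pv > 0
  ever[, "juxtacortical_T2"] <- ever[, "juxtacortical_T2"] | n_jc > 0
  ever[, "infratentorial_T2"] <- ever[, "infratentorial_T2"] | n_inf > 0

  # assemble scan rows
  region_cover <- list(brain = c("brain_global", "supratentorial",
                                 "infratentorial", "optic_pathway"),
                       orbits = "optic_pathway",
                       spine = "spinal_cord")
  feat_region <- stats::setNames(
    nmo_feature_catalog()$region, nmo_feature_catalog()$feature_id)

  scan_rows <- list()
  scan_seq <- 0L
  for (region in names(region_cover)) {
    a <- avail[[region]]
    if (!any(a)) next
    covered <- fp$feature_id[feat_region[fp$feature_id] %in%
                               region_cover[[region]]]
    for (pass in 1:2) {
      sel <- if (pass == 1) a else two_scans[[region]]
      if (!any(sel)) next
      idx <- which(sel)
      pres <- ever[idx, covered, drop = FALSE]
      if (pass == 1) {
        later <- two_scans[[region]][idx]
        pres <- pres & (!later | persist[idx, covered, drop = FALSE])
      }
      row <- tibble::tibble(
        scan_id = sprintf("S%05d", scan_seq + seq_along(idx)),
        patient_id = patient_id[idx],
        region = region,
        scan_date = onset[idx] + ifelse(pass == 1, 180L, 540L),
        gd_given = TRUE
      )
      scan_seq <- scan_seq + length(idx)
      pres_df <- tibble::as_tibble(as.data.frame(pres))
      row <- dplyr::bind_cols(row, pres_df)
      if (region == "brain") {
        cnt <- counts[idx, ]
        if (pass == 1) {
          shrink <- ifelse(two_scans[[region]][idx], 0.7, 1)
          cnt <- dplyr::mutate(cnt, dplyr::across(
            dplyr::everything(), ~ as.integer(round(.x * shrink))))
        }
        row <- dplyr::bind_cols(row, cnt)
      }
      scan_rows[[paste(region, pass)]] <- row
    }
  }
  scans <- dplyr::bind_rows(scan_rows)
  for (fid in fp$feature_id) {
    if (!fid %in% names(scans)) scans[[fid]] <- FALSE
    scans[[fid]] <- !is.na(scans[[fid]]) & scans[[fid]]
  }
  for (cc in c("n_T2_total", "n_wm", "n_wm_gt3mm", "n_periventricular",
               "n_juxtacortical", "n_infratentorial")) {
    scans[[cc]] <- dplyr::coalesce(scans[[cc]], 0L)
  }

  cord_lesions <- generate_cord_lesions(spec, patient_id, is_nmo,
                                        avail$spine, two_scans$spine, scans)

  nmo_cohort(patients, scans, cord_lesions)
}

# Cord lesion spans. Patient-level marginals (among spine-imaged patients)
# are set directly: P(lesion-free), P(any long lesion), P(Gd), P(swelling).
generate_cord_lesions <- function(spec, patient_id, is_nmo, spine_avail,
                                  spine_two, scans) {
  n <- length(patient_id)
  p_free <- ifelse(is_nmo, spec$no_cord_lesion[["nmosd"]],
                   spec$no_cord_lesion[["ms"]])
  lesioned <- spine_avail & stats::runif(n) >= p_free
  p_long_marg <- ifelse(is_nmo, spec$cord_long_freq[["nmosd"]],
                        spec$cord_long_freq[["ms"]])
  p_long <- pmin(1, p_long_marg / pmax(1 - p_free, 1e-12))
  has_long <- lesioned & stats::runif(n) < p_long
  p_gd <- pmin(1, ifelse(is_nmo, spec$cord_gd_freq[["nmosd"]],
                         spec$cord_gd_freq[["ms"]]) / pmax(1 - p_free, 1e-12))
  has_gd <- lesioned & stats::runif(n) < p_gd
  p_sw <- pmin(1, ifelse(is_nmo, spec$cord_swelling_freq[["nmosd"]],
                         spec$cord_swelling_freq[["ms"]]) /
                 pmax(1 - p_free, 1e-12))
  has_sw <- lesioned & stats::runif(n) < p_sw

  n_long <- ifelse(has_long, 1L + stats::rbinom(n, 1, 0.3), 0L)
  n_short <- ifelse(lesioned,
    ifelse(has_long, stats::rpois(n, 0.35),
           ifelse(is_nmo, 1L + stats::rpois(n, 0.5),
                  1L + stats::rpois(n, 0.8))),
    0L)
  # a lesioned patient must carry at least one lesion
  n_short <- ifelse(lesioned & n_long + n_short == 0, 1L, n_short)

  expand <- function(count, long) {
    idx <- rep.int(seq_len(n), count)
    if (length(idx) == 0) return(NULL)
    tibble::tibble(p = idx, long = long)
  }
  les <- dplyr::bind_rows(expand(n_long, TRUE), expand(n_short, FALSE))
  if (is.null(les) || nrow(les) == 0) return(empty_cord_lesions())

  m <- nrow(les)
  nmo_l <- is_nmo[les$p]
  len <- ifelse(les$long,
                pmin(6L + stats::rgeom(m, 0.35), 20L),
                pmin(1L + stats::rgeom(m, 0.45), 5L))
  centre <- cord_lesion_centre(m, nmo_l)
  start <- pmax(1L, pmin(centre - len %/% 2L, 44L - len + 1L))
  end <- start + len - 1L

  axial <- character(m)
  axial[nmo_l & les$long] <- sample(
    c("whole", "central", "partial", "unknown"), sum(nmo_l & les$long),
    replace = TRUE, prob = c(0.35, 0.45, 0.15, 0.05))
  axial[nmo_l & !les$long] <- sample(
    c("whole", "central", "partial", "unknown"), sum(nmo_l & !les$long),
    replace = TRUE, prob = c(0.05, 0.30, 0.55, 0.10))
  axial[!nmo_l] <- sample(
    c("whole", "central", "partial", "unknown"), sum(!nmo_l),
    replace = TRUE, prob = c(0.01, 0.04, 0.85, 0.10))

  # patient-level Gd / swelling flags attach to the patient's first lesion
  first_of <- !duplicated(les$p)
  gd <- first_of & has_gd[les$p]
  sw <- first_of & has_sw[les$p]

  # attach to a spine scan: usually the first, sometimes only the later one
  spine_scans <- scans[scans$region == "spine", c("scan_id", "patient_id",
                                                  "scan_date")]
  spine_scans <- dplyr::arrange(spine_scans, .data$patient_id,
                                .data$scan_date)
  first_scan <- spine_scans[!duplicated(spine_scans$patient_id), ]
  last_scan <- spine_scans[!duplicated(spine_scans$patient_id,
                                       fromLast = TRUE), ]
  on_first <- stats::runif(m) < 0.8 | !spine_two[les$p]
  sid <- ifelse(on_first,
                first_scan$scan_id[match(patient_id[les$p],
                                         first_scan$patient_id)],
                last_scan$scan_id[match(patient_id[les$p],
                                        last_scan$patient_id)])

  tibble::tibble(
    scan_id = sid,
    start_level = as.integer(start), end_level = as.integer(end),
    axial_class = axial, gd_enhancing = gd, swelling = sw
  )
}

# lesion centre level: NMOSD mixture of cervical C2-C6 (levels 3-12) and
# mid-thoracic T2-T8 (levels 17-30); MS cervical C2-C7 (levels 3-14);
# triangular weights peaking mid-range
cord_lesion_centre <- function(m, nmo) {
  tri <- function(lo, hi) {
    lv <- lo:hi
    w <- pmin(lv - lo + 1, hi - lv + 1)
    list(lv = lv, w = w / sum(w))
  }
  cerv_n <- tri(3, 12); thor_n <- tri(17, 30); cerv_m <- tri(3, 14)
  out <- integer(m)
  n_nmo <- sum(nmo)
  if (n_nmo > 0) {
    pick_thor <- stats::runif(n_nmo) < 0.45
    cen <- integer(n_nmo)
    cen[!pick_thor] <- sample(cerv_n$lv, sum(!pick_thor), replace = TRUE,
                              prob = cerv_n$w)
    cen[pick_thor] <- sample(thor_n$lv, sum(pick_thor), replace = TRUE,
                             prob = thor_n$w)
    out[nmo] <- cen
  }
  if (m - n_nmo > 0) {
    out[!nmo] <- sample(cerv_m$lv, m - n_nmo, replace = TRUE, prob = cerv_m$w)
  }
  out
}

#' Empirical feature prevalence in a cohort
#'
#' Proportions of ever-presence per diagnosis, computed over non-missing
#' entries only, with the denominators made explicit.
#'
#' @param x An [nmo_cohort()] or a prebuilt feature matrix.
#' @param feature_id A catalogue feature id.
#' @param which `"ever"` (default) or `"first"`.
#' @return A one-row tibble `feature_id`, `p_nmosd`, `p_ms`, `n_nmosd`,
#'   `n_ms` (proportions are `NaN` when a denominator is zero).
#' @export
empirical_prevalence <- function(x, feature_id, which = c("ever", "first")) {
  which <- match.arg(which)
  fm <- if (inherits(x, "nmo_cohort")) build_feature_matrix(x) else x
  tab <- contingency_from_matrix(fm, feature_id, which)
  tibble::tibble(
    feature_id = feature_id,
    p_nmosd = ifelse(tab$a + tab$b > 0, tab$a / (tab$a + tab$b), NaN),
    p_ms = ifelse(tab$c + tab$d > 0, tab$c / (tab$c + tab$d), NaN),
    n_nmosd = tab$a + tab$b, n_ms = tab$c + tab$d
  )
}
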