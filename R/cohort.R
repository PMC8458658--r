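#' Assemble a cohort object
#'
#' A cohort bundles three tidy tables:
#'
#' * `patients`: one row per subject — `patient_id`, `diagnosis`
#'   (`"NMOSD"` or `"MS"`), `onset_date`, and `relapse_dates` (a list-column
#'   of `Date` vectors).
#' * `scans`: one row per MRI set — `scan_id`, `patient_id`, `region`
#'   (`"brain"`, `"spine"` or `"orbits"`), `scan_date`, `gd_given`, logical
#'   feature-presence columns named by catalogue `feature_id`, and optional
#'   integer count columns named `n_<feature_id>` plus the brain totals
#'   `n_T2_total`, `n_wm`, `n_wm_gt3mm`, `n_periventricular`,
#'   `n_juxtacortical`, `n_infratentorial`.
#' * `cord_lesions`: one row per cord lesion — `scan_id`, `start_level`,
#'   `end_level` (1..44 hemi-vertebral levels, C1 superior = 1, L3 inferior
#'   = 44), `axial_class` (`central`, `partial`, `whole`, `unknown`),
#'   `gd_enhancing`, `swelling`.
#'
#' Scans are sorted by patient and date; a presence column is forced `TRUE`
#' wherever its matching count column is positive; cord lesions must attach to
#' spine scans.
#'
#' @param patients,scans,cord_lesions Data frames as described above.
#' @return A list of the three tibbles with class `nmo_cohort`.
#' @export
nmo_cohort <- function(patients, scans,
                       cord_lesions = empty_cord_lesions()) {
  patients <- tibble::as_tibble(patients)
  scans <- tibble::as_tibble(scans)
  cord_lesions <- tibble::as_tibble(cord_lesions)

  stopifnot(all(c("patient_id", "diagnosis") %in% names(patients)))
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table")
  }
  if (!all(patients$diagnosis %in% c("NMOSD", "MS"))) {
    stop("diagnosis must be NMOSD or MS")
  }
  if (!"relapse_dates" %in% names(patients)) {
    patients$relapse_dates <- rep(list(as.Date(character())), nrow(patients))
  }
  stopifnot(all(c("scan_id", "patient_id", "region", "scan_date") %in% names(scans)))
  if (!all(scans$region %in% c("brain", "spine", "orbits"))) {
    stop("scan region must be brain, spine or orbits")
  }
  if (!all(scans$patient_id %in% patients$patient_id)) {
    stop("scan refers to unknown patient_id")
  }
  if (anyDuplicated(scans$scan_id)) stop("duplicate scan_id")
  scans <- dplyr::arrange(scans, .data$patient_id, .data$scan_date, .data$scan_id)

  # presence must be TRUE wherever the matching count is positive
  count_cols <- grep("^n_", names(scans), value = TRUE)
  for (cc in count_cols) {
    fid <- sub("^n_", "", cc)
    if (fid %in% names(scans)) {
      pos <- !is.na(scans[[cc]]) & scans[[cc]] > 0
      scans[[fid]] <- scans[[fid]] | pos
    }
  }

  if (nrow(cord_lesions) > 0) {
    validate_cord_lesions(cord_lesions)
    spine_ids <- scans$scan_id[scans$region == "spine"]
    if (!all(cord_lesions$scan_id %in% spine_ids)) {
      stop("cord lesions may only attach to spine scans")
    }
  }

  structure(
    list(patients = patients, scans = scans, cord_lesions = cord_lesions),
    class = "nmo_cohort"
  )
}

empty_cord_lesions <- function() {
  tibble::tibble(
    scan_id = character(), start_level = integer(), end_level = integer(),
    axial_class = character(), gd_enhancing = logical(), swelling = logical()
  )
}

validate_cord_lesions <- function(x) {
  stopifnot(all(c("scan_id", "start_level", "end_level", "axial_class",
                  "gd_enhancing", "swelling") %in% names(x)))
  if (!all(x$start_level >= 1 & x$end_level <= 44 &
           x$start_level <= x$end_level)) {
    stop("cord lesion levels must satisfy 1 <= start <= end <= 44")
  }
  if (!all(x$axial_class %in% c("central", "partial", "whole", "unknown"))) {
    stop("axial_class must be central, partial, whole or unknown")
  }
  invisible(x)
}

#' @export
print.nmo_cohort <- function(x, ...) {
  n <- table(factor(x$patients$diagnosis, c("NMOSD", "MS")))
  cat(sprintf(
    "<nmo_cohort> %d patients (NMOSD %d, MS %d), %d scans, %d cord lesions\n",
    nrow(x$patients), n[["NMOSD"]], n[["MS"]], nrow(x$scans),
    nrow(x$cord_lesions)))
  invisible(x)
}

#' Relapse-window timing of a scan
#'
#' A scan is relapse-associated if any documented relapse falls in the window
#' from 90 days before to 30 days after the scan (inclusive at both ends);
#' otherwise it is a remission scan. An empty relapse list gives remission.
#'
#' @param scan_date A `Date` (or integer day) vector of scan dates.
#' @param relapse_dates A vector of relapse dates (applied to every scan) or a
#'   list of such vectors parallel to `scan_date`.
#' @param days_before,days_after Window half-widths in days (defaults 90, 30).
#' @return Character vector, `"relapse"` or `"remission"`.
#' @examples
#' classify_scan_timing(as.Date("2020-04-10"), as.Date("2020-01-20"))
#' @export
classify_scan_timing <- function(scan_date, relapse_dates,
                                 days_before = 90, days_after = 30) {
  if (!is.list(relapse_dates)) relapse_dates <- list(relapse_dates)
  relapse_dates <- rep_len(relapse_dates, length(scan_date))
  hit <- purrr::map2_lgl(as.numeric(scan_date), relapse_dates, function(s, rl) {
    rl <- as.numeric(rl)
    length(rl) > 0 && any(rl >= s - days_before & rl <= s + days_after)
  })
  ifelse(hit, "relapse", "remission")
}

#' Long versus short cord lesions
#'
#' A cord lesion is `"long"` (longitudinally extensive) when it spans three
#' or more vertebral bodies, i.e. at least 6 adjacent hemi-vertebral levels;
#' otherwise `"short"`. Span length is `end_level - start_level + 1`.
#'
#' @param start_level,end_level Integer hemi-level bounds (1..44), inclusive.
#' @return Character vector, `"long"` or `"short"`.
#' @examples
#' cord_lesion_length_class(3, 8) # 6 hemi-levels -> long
#' cord_lesion_length_class(3, 7) # 5 hemi-levels -> short
#' @export
cord_lesion_length_class <- function(start_level, end_level) {
  stopifnot(all(start_level <= end_level))
  ifelse(end_level - start_level + 1 >= 6, "long", "short")
}

#' Binary cord features implied by a set of cord lesions
#'
#' Maps lesion geometry to the catalogue's binary cord features: any long
#' lesion sets `longitudinal_cord_T2`, any short lesion `short_cord_T2`,
#' a `central` or `whole` axial class sets `central_cord_T2` (a whole-cord
#' lesion necessarily involves all central quadrants), `whole` sets
#' `whole_cord_T2`, `partial` sets `partial_cord_T2`, and the Gd/swelling
#' flags set `cord_gd` / `cord_swelling`.
#'
#' @param cord_lesions A cord-lesion tibble (possibly empty).
#' @return Named logical vector over the seven derived cord features.
#' @export
derive_cord_features <- function(cord_lesions) {
  cl <- tibble::as_tibble(cord_lesions)
  if (nrow(cl) > 0) validate_cord_lesions(dplyr::mutate(cl, scan_id = ""))
  len <- if (nrow(cl) > 0) {
    cord_lesion_length_class(cl$start_level, cl$end_level)
  } else {
    character()
  }
  c(
    longitudinal_cord_T2 = any(len == "long"),
    short_cord_T2 = any(len == "short"),
    central_cord_T2 = any(cl$axial_class %in% c("central", "whole")),
    partial_cord_T2 = any(cl$axial_class == "partial"),
    whole_cord_T2 = any(cl$axial_class == "whole"),
    cord_gd = any(cl$gd_enhancing),
    cord_swelling = any(cl$swelling)
  )
}

cord_feature_ids <- c("longitudinal_cord_T2", "short_cord_T2",
                      "central_cord_T2", "partial_cord_T2", "whole_cord_T2",
                      "cord_gd", "cord_swelling")

#' Resolve a multi-class white-matter lesion to a single class
#'
#' Lesions meeting several topographic definitions are assigned one class:
#' tumefactive takes precedence, then periventricular, cortical,
#' juxtacortical and finally subcortical.
#'
#' @param candidate_classes Non-empty character vector drawn from
#'   `tumefactive`, `periventricular`, `cortical`, `juxtacortical`,
#'   `subcortical`.
#' @return A single class string.
#' @examples
#' resolve_wm_lesion_class(c("periventricular", "subcortical"))
#' @export
resolve_wm_lesion_class <- function(candidate_classes) {
  order <- c("tumefactive", "periventricular", "cortical", "juxtacortical",
             "subcortical")
  candidate_classes <- unique(candidate_classes)
  if (length(candidate_classes) == 0) {
    stop("candidate_classes must be non-empty")
  }
  if (!all(candidate_classes %in% order)) {
    stop("unknown white-matter lesion class")
  }
  order[min(match(candidate_classes, order))]
}

# OR cord-derived feature columns into spine-scan rows.
augment_cord_features <- function(scans, cord_lesions) {
  for (fid in cord_feature_ids) {
    if (!fid %in% names(scans)) scans[[fid]] <- FALSE
  }
  if (nrow(cord_lesions) == 0) return(scans)
  cl <- cord_lesions
  cl$len <- cord_lesion_length_class(cl$start_level, cl$end_level)
  per_scan <- cl |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::summarise(
      longitudinal_cord_T2 = any(.data$len == "long"),
      short_cord_T2 = any(.data$len == "short"),
      central_cord_T2 = any(.data$axial_class %in% c("central", "whole")),
      partial_cord_T2 = any(.data$axial_class == "partial"),
      whole_cord_T2 = any(.data$axial_class == "whole"),
      cord_gd = any(.data$gd_enhancing),
      cord_swelling = any(.data$swelling),
      .groups = "drop"
    )
  idx <- match(scans$scan_id, per_scan$scan_id)
  for (fid in cord_feature_ids) {
    derived <- per_scan[[fid]][idx]
    derived[is.na(derived)] <- FALSE
    scans[[fid]] <- (!is.na(scans[[fid]]) & scans[[fid]]) | derived
  }
  scans
}

#' First/ever feature matrix for a cohort
#'
#' Aggregates per-scan feature presence to the per-patient level: `first` is
#' presence on the patient's earliest scan of a region covering the feature,
#' `ever` the OR over all covering scans, and `max_count` the maximum count
#' across scans where a matching `n_<feature_id>` column exists. "First" is
#' resolved per region, since brain and spine imaging occur on different
#' dates. Features scoped `first_only` (normal brain, Paty, Barkhof) are
#' evaluated on first imaging only, so `ever` equals `first` for them. All
#' three values are `NA` when the patient has no scan covering the feature's
#' region — downstream denominators are reduced accordingly.
#'
#' Criterion features (`paty_criteria`, `barkhof_criteria`,
#' `nine_or_more_T2`, `normal_brain`) are computed from the scan count
#' columns when not supplied as explicit logical columns.
#'
#' @param cohort An [nmo_cohort()].
#' @param catalog A feature catalogue; defaults to [nmo_feature_catalog()].
#' @param optic_from_brain Treat brain scans as covering optic-pathway
#'   features (default `TRUE`); if `FALSE` only dedicated orbit imaging
#'   counts toward optic denominators.
#' @return A tibble with columns `patient_id`, `diagnosis`, `feature_id`,
#'   `first`, `ever` (logical, `NA` = region never imaged) and `max_count`.
#' @export
build_feature_matrix <- function(cohort, catalog = nmo_feature_catalog(),
                                 optic_from_brain = TRUE) {
  stopifnot(inherits(cohort, "nmo_cohort"))
  patients <- cohort$patients
  scans <- augment_cord_features(cohort$scans, cohort$cord_lesions)
  scans <- add_criterion_features(scans)

  feature_ids <- catalog$feature_id

  # features are aggregated in blocks sharing a covering scan-region set
  cover_key <- vapply(scan_regions_for(catalog$region, optic_from_brain),
                      paste, character(1), collapse = "+")
  out <- vector("list", length(unique(cover_key)))
  names(out) <- unique(cover_key)

  for (key in unique(cover_key)) {
    regs <- strsplit(key, "+", fixed = TRUE)[[1]]
    fids <- feature_ids[cover_key == key]
    sc <- scans[scans$region %in% regs, , drop = FALSE]
    sc <- sc[order(sc$patient_id, sc$scan_date, sc$scan_id), , drop = FALSE]
    have <- intersect(fids, names(sc))
    if (nrow(sc) == 0) have <- character()

    if (length(have) > 0) {
      P <- as.matrix(as.data.frame(lapply(sc[have], function(x) {
        as.numeric(!is.na(x) & x)
      })))
      pid <- sc$patient_id
      first_rows <- !duplicated(pid)
      ever_m <- rowsum(P, pid) > 0                 # sorted by patient id
      first_m <- P[first_rows, , drop = FALSE] > 0
      rownames(first_m) <- pid[first_rows]
      idx_e <- match(patients$patient_id, rownames(ever_m))
      idx_f <- match(patients$patient_id, rownames(first_m))
    }

    imaged <- patients$patient_id %in% sc$patient_id

    block <- lapply(fids, function(fid) {
      if (!fid %in% have) {
        # feature column not recorded: absent wherever the region was
        # imaged, missing only where it was not
        val <- ifelse(imaged, FALSE, NA)
        return(tibble::tibble(patient_id = patients$patient_id,
                              feature_id = fid, first = val, ever = val,
                              max_count = NA_integer_))
      }
      first <- unname(first_m[idx_f, fid])
      ever <- unname(ever_m[idx_e, fid])
      if (catalog$scope[match(fid, feature_ids)] == "first_only") {
        ever <- first
      }
      cnt_col <- paste0("n_", fid)
      max_count <- if (cnt_col %in% names(sc)) {
        agg <- tapply(sc[[cnt_col]], sc$patient_id,
                      function(x) if (all(is.na(x))) NA_integer_
                                  else max(x, na.rm = TRUE))
        as.integer(agg[match(patients$patient_id, names(agg))])
      } else {
        rep(NA_integer_, nrow(patients))
      }
      tibble::tibble(patient_id = patients$patient_id, feature_id = fid,
                     first = first, ever = ever, max_count = max_count)
    })
    out[[key]] <- dplyr::bind_rows(block)
  }

  dplyr::bind_rows(out) |>
    dplyr::left_join(
      dplyr::select(patients, "patient_id", "diagnosis"),
      by = "patient_id"
    ) |>
    dplyr::select("patient_id", "diagnosis", "feature_id", "first", "ever",
                  "max_count") |>
    dplyr::arrange(match(.data$feature_id, feature_ids), .data$patient_id)
}

# Criterion features computed from count columns on brain scans when absent.
# "Few lesions" for the normal-brain feature is taken as <= 3 total T2
# lesions with no Gd enhancement or T1 black holes.
add_criterion_features <- function(scans) {
  has <- function(x) x %in% names(scans)
  num <- function(x) if (has(x)) dplyr::coalesce(scans[[x]], 0L) else 0L
  lgl <- function(x) if (has(x)) dplyr::coalesce(scans[[x]], FALSE) else FALSE

  if (!has("paty_criteria")) {
    scans$paty_criteria <- paty_rule(
      n_wm = num("n_wm"), n_wm_gt3mm = num("n_wm_gt3mm"),
      n_periventricular = num("n_periventricular")
    )
  }
  if (!has("barkhof_criteria")) {
    scans$barkhof_criteria <- barkhof_rule(
      gd_lesion = lgl("brain_gd"), n_T2 = num("n_T2_total"),
      n_infratentorial = num("n_infratentorial"),
      n_juxtacortical = num("n_juxtacortical"),
      n_periventricular = num("n_periventricular")
    )
  }
  if (!has("nine_or_more_T2")) {
    scans$nine_or_more_T2 <- num("n_T2_total") >= 9
  }
  if (!has("normal_brain")) {
    scans$normal_brain <- !scans$paty_criteria & num("n_T2_total") <= 3 &
      !lgl("brain_gd") & !lgl("black_hole_T1")
  }
  brain <- scans$region == "brain"
  for (cc in c("paty_criteria", "barkhof_criteria", "nine_or_more_T2",
               "normal_brain")) {
    scans[[cc]] <- scans[[cc]] & brain
  }
  scans
}

#' Read / write a cohort as delimited tables
#'
#' A cohort directory holds `patients.csv`, `scans.csv` and
#' `cord_lesions.csv` (RFC-4180, header row, UTF-8). Relapse dates are stored
#' as a semicolon-separated list.
#'
#' @param dir Directory containing (or to receive) the three tables.
#' @return For `read_cohort`, an [nmo_cohort()]; for `write_cohort`, `dir`
#'   invisibly.
#' @export
read_cohort <- function(dir) {
  patients <- readr::read_csv(file.path(dir, "patients.csv"),
                              show_col_types = FALSE, progress = FALSE)
  patients$relapse_dates <- lapply(
    strsplit(dplyr::coalesce(as.character(patients$relapse_dates), ""), ";"),
    function(x) as.Date(x[nzchar(x)])
  )
  if ("onset_date" %in% names(patients)) {
    patients$onset_date <- as.Date(patients$onset_date)
  }
  scans <- readr::read_csv(file.path(dir, "scans.csv"),
                           show_col_types = FALSE, progress = FALSE)
  scans$scan_date <- as.Date(scans$scan_date)
  cl_path <- file.path(dir, "cord_lesions.csv")
  cord_lesions <- if (file.exists(cl_path)) {
    readr::read_csv(cl_path, show_col_types = FALSE, progress = FALSE)
  } else {
    empty_cord_lesions()
  }
  nmo_cohort(patients, scans, cord_lesions)
}

#' @rdname read_cohort
#' @param cohort An [nmo_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nmo_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patients <- cohort$patients
  patients$relapse_dates <- vapply(
    patients$relapse_dates, function(x) paste(as.character(x), collapse = ";"),
    character(1)
  )
  readr::write_csv(patients, file.path(dir, "patients.csv"), progress = FALSE)
  readr::write_csv(cohort$scans, file.path(dir, "scans.csv"), progress = FALSE)
  readr::write_csv(cohort$cord_lesions, file.path(dir, "cord_lesions.csv"),
                   progress = FALSE)
  invisible(dir)
}
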