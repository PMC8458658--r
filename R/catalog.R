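#' Lesion-feature catalogue
#'
#' The catalogue is the registry of MRI lesion types and imaging features used
#' throughout the package: every feature column in a cohort, every score-model
#' term and every decision-tree test is keyed against a `feature_id` defined
#' here. Each row records the anatomical region, imaging modality, prior
#' disease association (NMOSD, MS or neutral) and whether the feature is
#' evaluated on first imaging only (`first_only`) or on both first and ever
#' imaging (`first_and_ever`). The default registry ships as a delimited data
#' file so the id-to-name mapping can be audited without reading code.
#'
#' `disease_association` is the resolved prior association used by default
#' score models; `listed_nmosd` / `listed_ms` record the raw literature
#' listings (the cerebral peduncle lesion is listed under both diseases and is
#' resolved to `neutral`).
#'
#' @param path Path to a catalogue CSV. Defaults to the registry shipped with
#'   the package.
#' @return A tibble with one row per feature and columns `feature_id`, `name`,
#'   `region`, `modality`, `disease_association`, `listed_nmosd`, `listed_ms`,
#'   `scope`, `definition_text`.
#' @examples
#' cat <- nmo_feature_catalog()
#' dplyr::count(cat, disease_association)
#' @export
nmo_feature_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_catalog.csv", package = "nmosdmri",
                        mustWork = TRUE)
  }
  cat <- readr::read_csv(
    path,
    col_types = readr::cols(
      feature_id = readr::col_character(),
      name = readr::col_character(),
      region = readr::col_character(),
      modality = readr::col_character(),
      disease_association = readr::col_character(),
      listed_nmosd = readr::col_logical(),
      listed_ms = readr::col_logical(),
      scope = readr::col_character(),
      definition_text = readr::col_character()
    ),
    progress = FALSE
  )
  validate_catalog(cat)
  cat
}

catalog_regions <- c("optic_pathway", "brain_global", "supratentorial",
                     "infratentorial", "spinal_cord")
catalog_modalities <- c("T2", "Gd", "T1_hypointense", "criterion", "composite")

validate_catalog <- function(cat) {
  stopifnot(is.data.frame(cat))
  required <- c("feature_id", "name", "region", "modality",
                "disease_association", "listed_nmosd", "listed_ms",
                "scope", "definition_text")
  missing_cols <- setdiff(required, names(cat))
  if (length(missing_cols) > 0) {
    stop("catalogue is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cat$feature_id)) {
    stop("duplicate feature_id in catalogue: ",
         paste(unique(cat$feature_id[duplicated(cat$feature_id)]), collapse = ", "))
  }
  if (!all(cat$region %in% catalog_regions)) {
    stop("unknown region in catalogue")
  }
  if (!all(cat$modality %in% catalog_modalities)) {
    stop("unknown modality in catalogue")
  }
  if (!all(cat$disease_association %in% c("NMOSD", "MS", "neutral"))) {
    stop("disease_association must be NMOSD, MS or neutral")
  }
  if (!all(cat$scope %in% c("first_only", "first_and_ever"))) {
    stop("scope must be first_only or first_and_ever")
  }
  invisible(cat)
}

#' Write a catalogue back to disk
#'
#' Round-trips losslessly through [nmo_feature_catalog()].
#'
#' @param catalog A catalogue tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  readr::write_csv(catalog, path, progress = FALSE)
  invisible(path)
}

#' Check feature references against a catalogue
#'
#' @param catalog A catalogue tibble.
#' @param feature_ids Character vector of ids to check.
#' @return The ids absent from the catalogue, in input order (possibly empty).
#' @examples
#' validate_feature_refs(nmo_feature_catalog(), c("longitudinal_cord_T2", "nope"))
#' @export
validate_feature_refs <- function(catalog, feature_ids) {
  feature_ids[!feature_ids %in% catalog$feature_id]
}

#' Region imaged by a scan type that covers a catalogue region
#'
#' Optic-pathway features are visible on either dedicated orbit imaging or
#' standard brain MRI, so both scan regions cover `optic_pathway`; all
#' brain-region features require a brain scan and cord features a spine scan.
#'
#' @param region Catalogue region string(s).
#' @param optic_from_brain Should brain scans cover optic-pathway features?
#'   Default `TRUE`.
#' @return A list (parallel to `region`) of scan-region strings.
#' @keywords internal
scan_regions_for <- function(region, optic_from_brain = TRUE) {
  lapply(region, function(r) {
    switch(r,
      optic_pathway = if (optic_from_brain) c("orbits", "brain") else "orbits",
      spinal_cord = "spine",
      "brain")
  })
}
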