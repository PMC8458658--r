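#' Hemi-vertebral level labels
#'
#' The spinal cord coordinate system used throughout the package divides
#' each vertebral body into a superior and an inferior half, giving 44
#' levels from the superior half of C1 (level 1) through the 7 cervical and
#' 12 thoracic vertebrae to the inferior half of L3 (level 44). Two rows
#' therefore correspond to one vertebral segment.
#'
#' @param index Integer level index in 1..44.
#' @return Anatomical label(s), e.g. `"C1-superior"`, `"T1-superior"`,
#'   `"L3-inferior"`.
#' @examples
#' level_label(c(1, 15, 44))
#' @export
level_label <- function(index) {
  if (any(index < 1 | index > 44)) stop("level index must be in 1..44")
  labs <- cord_level_labels()
  labs[index]
}

cord_level_labels <- function() {
  vert <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:3))
  paste0(rep(vert, each = 2), "-", rep(c("superior", "inferior"), 22))
}

#' Build a spinal cord lesion heat map
#'
#' One column per patient with at least one spine scan in the requested
#' diagnosis group, one row per hemi-vertebral level, pooling lesions over
#' all of the patient's spine scans (the "ever" view). A cell's category is
#' `long` if any longitudinally extensive lesion covers the level, else
#' `short` if any short lesion covers it, else `none` (long takes precedence
#' so the extent of long lesions is never truncated); Gd enhancement is an
#' independent overlay flag. Per-level summary frequencies are the
#' proportion of the group's spine-imaged patients with any lesion category
#' at the level.
#'
#' @param cohort An [nmo_cohort()].
#' @param group `"NMOSD"` or `"MS"`.
#' @return An object of class `cord_heatmap`: list with `group`, `patients`
#'   (ids included), `cells` (tibble `patient_id`, `level`, `label`,
#'   `category`, `gd`), and `summary` (tibble `level`, `label`,
#'   `frequency`).
#' @export
build_heatmap <- function(cohort, group = c("NMOSD", "MS")) {
  group <- match.arg(group)
  stopifnot(inherits(cohort, "nmo_cohort"))
  spine <- cohort$scans[cohort$scans$region == "spine", ]
  pts <- cohort$patients[cohort$patients$diagnosis == group &
                           cohort$patients$patient_id %in% spine$patient_id, ]
  labs <- cord_level_labels()

  cl <- dplyr::inner_join(
    cohort$cord_lesions,
    dplyr::select(spine, "scan_id", "patient_id"),
    by = "scan_id"
  )
  cl <- cl[cl$patient_id %in% pts$patient_id, ]

  if (nrow(cl) > 0) {
    cl$len_class <- cord_lesion_length_class(cl$start_level, cl$end_level)
    per_level <- cl |>
      dplyr::mutate(level = purrr::map2(.data$start_level, .data$end_level,
                                        seq)) |>
      tidyr::unnest("level") |>
      dplyr::group_by(.data$patient_id, .data$level) |>
      dplyr::summarise(
        category = ifelse(any(.data$len_class == "long"), "long", "short"),
        gd = any(.data$gd_enhancing),
        .groups = "drop"
      )
  } else {
    per_level <- tibble::tibble(patient_id = character(), level = integer(),
                                category = character(), gd = logical())
  }
  cells <- tidyr::expand_grid(patient_id = pts$patient_id, level = 1:44) |>
    dplyr::left_join(per_level, by = c("patient_id", "level")) |>
    dplyr::mutate(
      category = dplyr::coalesce(.data$category, "none"),
      gd = dplyr::coalesce(.data$gd, FALSE),
      label = labs[.data$level]
    ) |>
    dplyr::select("patient_id", "level", "label", "category", "gd")

  summary <- cells |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      frequency = if (nrow(pts) > 0) mean(.data$category != "none") else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(label = labs[.data$level]) |>
    dplyr::select("level", "label", "frequency")

  structure(
    list(group = group, patients = pts$patient_id, cells = cells,
         summary = summary),
    class = "cord_heatmap"
  )
}

#' Write a heat map as delimited matrices and a figure
#'
#' Writes `matrix.csv` (rows = 44 labelled levels, columns = patient ids,
#' cells 0 = none, 1 = short, 2 = long), a parallel `gd.csv` (0/1 overlay),
#' `summary.csv` (level, label, frequency) and `heatmap.png` under `dir`.
#' Matrix output is deterministic for a fixed map.
#'
#' @param map A `cord_heatmap`.
#' @param dir Output directory (created if needed).
#' @param width,height Figure size in inches.
#' @return `dir`, invisibly.
#' @export
render_heatmap <- function(map, dir, width = 10, height = 7) {
  stopifnot(inherits(map, "cord_heatmap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  code <- c(none = 0L, short = 1L, long = 2L)
  wide <- map$cells |>
    dplyr::mutate(value = code[.data$category]) |>
    dplyr::select("level", "label", "patient_id", "value") |>
    tidyr::pivot_wider(names_from = "patient_id", values_from = "value") |>
    dplyr::arrange(.data$level)
  readr::write_csv(wide, file.path(dir, "matrix.csv"), progress = FALSE)
  gd_wide <- map$cells |>
    dplyr::mutate(value = as.integer(.data$gd)) |>
    dplyr::select("level", "label", "patient_id", "value") |>
    tidyr::pivot_wider(names_from = "patient_id", values_from = "value") |>
    dplyr::arrange(.data$level)
  readr::write_csv(gd_wide, file.path(dir, "gd.csv"), progress = FALSE)
  readr::write_csv(map$summary, file.path(dir, "summary.csv"),
                   progress = FALSE)
  ggplot2::ggsave(file.path(dir, "heatmap.png"), autoplot(map),
                  width = width, height = height, dpi = 150)
  invisible(dir)
}

#' Plot a cord heat map
#'
#' Patients on the x axis, hemi-vertebral levels on the y axis (C1 at the
#' top), colour-coded lesion categories with Gd enhancement marked as an
#' overlay point.
#'
#' @param object A `cord_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cord_heatmap <- function(object, ...) {
  cells <- dplyr::mutate(
    object$cells,
    patient_id = factor(.data$patient_id, levels = object$patients),
    category = factor(.data$category, levels = c("none", "short", "long"))
  )
  labs <- cord_level_labels()
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$patient_id,
                                      y = .data$level)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$category),
                       colour = "grey85", linewidth = 0.1) +
    ggplot2::geom_point(data = cells[cells$gd, ], size = 0.6,
                        colour = "black") +
    ggplot2::scale_y_reverse(breaks = seq(1, 44, by = 2),
                             labels = labs[seq(1, 44, by = 2)]) +
    ggplot2::scale_fill_manual(values = c(none = "white", short = "#fdae61",
                                          long = "#d7191c")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "lesion",
                  title = paste0(object$group,
                                 " spinal cord lesion distribution")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
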