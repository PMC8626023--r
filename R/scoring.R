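#' Control-group reference for colon length/weight scoring
#'
#' Colon length and weight contribute to the macroscopic damage score as a
#' percent change relative to the control-group means; this object carries
#' those two means.
#'
#' @param control_mean_length Control-group mean colon length (cm), > 0.
#' @param control_mean_weight Control-group mean colon weight (g, weighed
#'   with fecal content, as recorded at necropsy), > 0.
#' @return A `control_reference` object.
#' @seealso [macroscopic_total()], [score_cohort()] (which can derive the
#'   reference from the cohort's own control arm).
#' @export
control_reference <- function(control_mean_length, control_mean_weight) {
  stop_if_not_scalar_number(control_mean_length, "control_mean_length")
  stop_if_not_scalar_number(control_mean_weight, "control_mean_weight")
  if (control_mean_length <= 0 || control_mean_weight <= 0) {
    stop("control reference means must be > 0", call. = FALSE)
  }
  structure(list(control_mean_length = control_mean_length,
                 control_mean_weight = control_mean_weight),
            class = "control_reference")
}

#' Percent-change points for colon length/weight
#'
#' Maps the absolute percent change of a colon measurement relative to the
#' control-group mean onto the 0-4 point scale used in the macroscopic
#' damage score: change of at most 5% scores 0; more than 5% and below 15%
#' scores 1; 15% up to (excluding) 25% scores 2; 25% up to (excluding) 35%
#' scores 3; 35% or more scores 4. The deviation is taken as an absolute
#' value because colon length shortens with inflammation while colon weight
#' can rise.
#'
#' The printed rule table overlaps at its seams (5 belongs to both the 0- and
#' 1-point bins as written, 35 to both the 3- and 4-point bins); this
#' implementation resolves them as closed-below bins with exactly 5% scoring
#' 0 and exactly 35% scoring 4 (the more severe reading at the top end).
#'
#' @param value Measurement(s) in the same units as `control_mean`; >= 0.
#' @param control_mean Control-group mean, > 0. May also be a
#'   [control_reference()]-style scalar extracted by the caller.
#' @return Integer points in 0-4, vectorized over `value`.
#' @examples
#' percent_change_points(8, 10)   # 20% change -> 2
#' percent_change_points(6.5, 10) # 35% change -> 4
#' @export
percent_change_points <- function(value, control_mean) {
  stop_if_not_scalar_number(control_mean, "control_mean")
  if (control_mean <= 0) stop("`control_mean` must be > 0", call. = FALSE)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    stop("`value` must be finite and >= 0", call. = FALSE)
  }
  change <- 100 * abs(value - control_mean) / control_mean
  points <- integer(length(change))
  points[change > 5]   <- 1L
  points[change >= 15] <- 2L
  points[change >= 25] <- 3L
  points[change >= 35] <- 4L
  points
}

#' Total macroscopic colon-damage score for one animal
#'
#' Composite 0-15 score: stool consistency (0 = normal well-shaped pellets,
#' 3 = diarrhea), epithelial damage by number of ulcers (0-3; counts above 3
#' are treated as already at the ceiling), colon length and colon weight each
#' binned by percent change from the control means ([percent_change_points()],
#' 0-4 each), and presence of fecal blood (0/1). A total of 0 means no
#' inflammation.
#'
#' @param record A list or one-row data frame with fields `stool_score`,
#'   `ulcer_score`, `colon_length`, `colon_weight`, `fecal_blood`.
#' @param ref A [control_reference()].
#' @return A `macroscopic_result`: list with the five component point values
#'   and `total`.
#' @examples
#' ref <- control_reference(10, 0.25)
#' macroscopic_total(list(stool_score = 3, ulcer_score = 2,
#'                        colon_length = 8, colon_weight = 0.275,
#'                        fecal_blood = 1), ref)
#' @export
macroscopic_total <- function(record, ref) {
  stopifnot(inherits(ref, "control_reference"))
  stool <- check_ordinal(record$stool_score, "stool_score", 0L, 3L)
  ulcer <- record$ulcer_score
  if (any(!is.finite(ulcer)) || any(ulcer != round(ulcer)) || any(ulcer < 0)) {
    stop("`ulcer_score` must be a non-negative integer count", call. = FALSE)
  }
  ulcer <- pmin(as.integer(ulcer), 3L)
  blood <- check_ordinal(record$fecal_blood, "fecal_blood", 0L, 1L)
  length_pts <- percent_change_points(record$colon_length,
                                      ref$control_mean_length)
  weight_pts <- percent_change_points(record$colon_weight,
                                      ref$control_mean_weight)
  structure(
    list(stool_points = stool, ulcer_points = ulcer,
         length_points = length_pts, weight_points = weight_pts,
         blood_points = blood,
         total = stool + ulcer + length_pts + weight_pts + blood),
    class = "macroscopic_result"
  )
}

#' Microscopic total damage score from histology subscores
#'
#' Sum of five expert-assigned histology subscores: goblet cell depletion
#' (absent 0 / present 1), crypt abscesses (0/1), destruction of mucosal
#' architecture (normal 1, moderate 2, extensive 3), muscle thickening
#' (1-3) and immune cell infiltration (normal 1, moderate 2, transmural 3).
#' The total therefore ranges from 3 (fully normal) to 11.
#'
#' @param goblet_depletion,crypt_abscesses 0 or 1.
#' @param mucosal_architecture,muscle_thickening,immune_infiltration 1-3.
#' @return Integer total in \[3, 11\], vectorized.
#' @examples
#' microscopic_total(0, 0, 1, 1, 1) # 3, fully normal
#' microscopic_total(1, 1, 3, 3, 3) # 11, maximal damage
#' @export
microscopic_total <- function(goblet_depletion, crypt_abscesses,
                              mucosal_architecture, muscle_thickening,
                              immune_infiltration) {
  g <- check_ordinal(goblet_depletion, "goblet_depletion", 0L, 1L)
  c_ <- check_ordinal(crypt_abscesses, "crypt_abscesses", 0L, 1L)
  m <- check_ordinal(mucosal_architecture, "mucosal_architecture", 1L, 3L)
  t_ <- check_ordinal(muscle_thickening, "muscle_thickening", 1L, 3L)
  i <- check_ordinal(immune_infiltration, "immune_infiltration", 1L, 3L)
  g + c_ + m + t_ + i
}

#' Score a whole cohort
#'
#' Applies [macroscopic_total()] (and, where histology subscores are present,
#' [microscopic_total()]) to every animal and returns the cohort with
#' per-component point columns and totals appended. When `ref` is `NULL` the
#' control reference is computed from the cohort's own `control_group` arm
#' (mean colon length and weight), which mirrors how the score is defined in
#' practice.
#'
#' @param cohort A cohort data frame as produced by [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param ref A [control_reference()], or `NULL` to derive it from the
#'   cohort's control group.
#' @param control_group Label of the control arm used when `ref` is `NULL`.
#' @return The cohort tibble with columns `stool_points`, `ulcer_points`,
#'   `length_points`, `weight_points`, `blood_points`, `macroscopic_score`
#'   and, if histology is present, `microscopic_score`.
#' @export
score_cohort <- function(cohort, ref = NULL, control_group = "control") {
  stopifnot(is.data.frame(cohort))
  if (is.null(ref)) {
    ctrl <- cohort[cohort$group == control_group, , drop = FALSE]
    if (nrow(ctrl) == 0) {
      stop(sprintf("no animals in control group '%s'; supply `ref` explicitly",
                   control_group), call. = FALSE)
    }
    ref <- control_reference(mean(ctrl$colon_length), mean(ctrl$colon_weight))
  }
  res <- macroscopic_total(cohort, ref)
  out <- dplyr::mutate(tibble::as_tibble(cohort),
                       stool_points = res$stool_points,
                       ulcer_points = res$ulcer_points,
                       length_points = res$length_points,
                       weight_points = res$weight_points,
                       blood_points = res$blood_points,
                       macroscopic_score = res$total)
  histo <- c("goblet_depletion", "crypt_abscesses", "mucosal_architecture",
             "muscle_thickening", "immune_infiltration")
  if (all(histo %in% names(cohort))) {
    out$microscopic_score <- microscopic_total(
      cohort$goblet_depletion, cohort$crypt_abscesses,
      cohort$mucosal_architecture, cohort$muscle_thickening,
      cohort$immune_infiltration)
  }
  out
}
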