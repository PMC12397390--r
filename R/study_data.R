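#' Apomorphine-induced rotation rates of the study cohort
#'
#' The published per-animal rotation table of the 20-animal cohort:
#' 5 saline/ascorbate controls ("sham") and 15 6-OHDA-lesioned animals,
#' with the sensor allocation and the exclusions applied in the study.
#' Rotation rates (rpm, 50-minute test) quantify the unilateral
#' dopaminergic deficit three weeks after lesioning.
#'
#' Cohort membership differs between analyses: animal 13 (insufficient
#' lesioning) is excluded everywhere; animal 11 (sensor failure during
#' acquisition) is excluded from the accelerometry cohort but its
#' rotation measurement is part of the rotation summary. The remaining
#' accelerometry cohort has 18 animals.
#'
#' @return a tibble with columns `animal_id`, `condition` (`sham`/`PD`),
#'   `sensor_id`, `rotation_rpm`, `in_rotation_cohort`,
#'   `in_accel_cohort`.
#' @export
#' @examples
#' rot <- study_rotations()
#' mean(rot$rotation_rpm[rot$condition == "sham"]) # 0.158 -> 0.16 rpm
study_rotations <- function() {
  tibble::tibble(
    animal_id = 1:20,
    condition = rep(c("sham", "PD"), c(5, 15)),
    sensor_id = c(
      "S3", "S4", "S1", "S2", "S5",
      "S6", "S7", "S8", "S5", "S6", "S1", "S2", "S3", "S4",
      "S1", "S2", "S3", "S4", "S6", "S8"
    ),
    rotation_rpm = c(
      -0.01, -0.14, 0.99, 0.27, -0.32,
      9.00, 5.71, 7.56, 5.48, 7.08, 9.40, 6.58, -0.16, 7.76,
      7.58, 7.69, 7.55, 6.03, 7.21, 5.82
    ),
    in_rotation_cohort = animal_id != 13L,
    in_accel_cohort = !(animal_id %in% c(11L, 13L))
  )
}

#' Published per-class means of the segmental statistics
#'
#' The group-level means of the per-animal mean segmental statistics
#' reported for the final 15-dataset cohort (5 sham, 10 PD): segmental
#' mean (m/s^2), variance (m^2/s^4), absolute skewness and plain
#' kurtosis. These values are study-reported inputs, not recomputable
#' without the raw recordings; the synthetic generator is calibrated to
#' the variance levels.
#'
#' @return a tibble with columns `feature`, `sham`, `pd`.
#' @export
#' @examples
#' gm <- study_group_means()
#' # percent decrease sham -> PD of the mean segmental skewness:
#' with(gm[gm$feature == "skewness", ], 100 * (sham - pd) / sham) # 39.9
study_group_means <- function() {
  tibble::tibble(
    feature = c("mean", "variance", "skewness", "kurtosis"),
    sham = c(9.822, 0.279, 0.569, 50.258),
    pd = c(9.818, 0.163, 0.342, 50.798)
  )
}

#' Published MAD-median scores of the excluded datasets
#'
#' The three datasets flagged by the MAD-median rule in the study (all in
#' the PD class) and their scores above the threshold K = 2.24.
#'
#' @return a tibble with columns `animal_id`, `condition`, `score`.
#' @export
study_outlier_scores <- function() {
  tibble::tibble(
    animal_id = c(9L, 12L, 20L),
    condition = "PD",
    score = c(4.812, 4.036, 7.038)
  )
}
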