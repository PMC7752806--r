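#' Score the PCL-5
#'
#' Sums the 20 items (each 0-4) to a 0-80 total, computes the four DSM-5
#' symptom-cluster scores -- B (intrusion, items 1-5), C (avoidance, items
#' 6-7), D (negative alterations in cognition/mood, items 8-14), E (arousal
#' and reactivity, items 15-20) -- and flags provisional PTSD at the
#' recommended total-severity cut-off of 33 (total >= 33).
#'
#' @param items Integer vector of 20 item responses in 0-4.
#' @return List: `total`, `cluster_b`, `cluster_c`, `cluster_d`, `cluster_e`,
#'   `ptsd_positive`.
#' @export
score_pcl5 <- function(items) {
  check_items(items, n = 20, lo = 0, hi = 4, name = "PCL-5")
  total <- sum(items)
  list(total = total,
       cluster_b = sum(items[1:5]),
       cluster_c = sum(items[6:7]),
       cluster_d = sum(items[8:14]),
       cluster_e = sum(items[15:20]),
       ptsd_positive = total >= 33)
}

#' Score the PHQ-8
#'
#' Total is the sum of the 8 items (0-3 each; 0-24 range). Two positive
#' screens are derived: symptom scoring requires depressed mood or anhedonia
#' (items 1-2) endorsed at least "More Than Half the Days" (response >= 2)
#' together with at least 5 of the 8 symptoms at that frequency; aggregate
#' scoring classifies severity as None (0-4), Mild (5-9), Moderate (10-14),
#' Moderately Severe (15-20) or Severe (>20), with total >= 10 taken as
#' clinically significant MDD.
#'
#' @param items Integer vector of 8 item responses in 0-3; items 1 and 2 are
#'   the anhedonia and depressed-mood items.
#' @return List: `total`, `category`, `mdd_symptom_positive`,
#'   `mdd_aggregate_positive`.
#' @export
score_phq8 <- function(items) {
  check_items(items, n = 8, lo = 0, hi = 3, name = "PHQ-8")
  total <- sum(items)
  category <- cut(total, breaks = c(-1, 4, 9, 14, 20, 24),
                  labels = c("None", "Mild", "Moderate",
                             "ModeratelySevere", "Severe"))
  list(total = total,
       category = as.character(category),
       mdd_symptom_positive = (items[1] >= 2 || items[2] >= 2) &&
         sum(items >= 2) >= 5,
       mdd_aggregate_positive = total >= 10)
}

#' Score the AMBI
#'
#' Sums 16 behavioural-inhibition items (0-2 each) to a 0-32 total; totals
#' above 15.5 (i.e. >= 16 for integer totals) are classified as behaviourally
#' inhibited.
#'
#' @param items Integer vector of 16 item responses in 0-2.
#' @return List: `total`, `bi_positive`.
#' @export
score_ambi <- function(items) {
  check_items(items, n = 16, lo = 0, hi = 2, name = "AMBI")
  total <- sum(items)
  list(total = total, bi_positive = total > 15.5)
}

#' Classify mild TBI from the concussion screen
#'
#' A simplified screen predicate: positive when a head-injury event occurred
#' with alteration of consciousness, and any loss of consciousness lasted at
#' most 30 minutes (the conventional upper bound for the mild range; longer
#' LOC indicates moderate/severe injury and is classified negative here).
#' This is an approximation of structured TBI screening interviews, exposed
#' as a single swappable predicate.
#'
#' @param event Head-injury event occurred (logical).
#' @param alteration_of_consciousness Any alteration of consciousness
#'   (dazed/confused/LOC) at the event (logical).
#' @param loc_duration_min Loss-of-consciousness duration in minutes, or `NA`
#'   if no LOC.
#' @return Logical mTBI-positive flag.
#' @export
classify_mtbi <- function(event, alteration_of_consciousness,
                          loc_duration_min = NA_real_) {
  if (is.na(event) || is.na(alteration_of_consciousness)) {
    stop("screen fields 'event' and 'alteration_of_consciousness' are required")
  }
  isTRUE(event) && isTRUE(alteration_of_consciousness) &&
    (is.na(loc_duration_min) || loc_duration_min <= 30)
}

check_items <- function(items, n, lo, hi, name) {
  if (length(items) != n) {
    stop(sprintf("%s requires exactly %d items", name, n))
  }
  if (anyNA(items) || any(items < lo | items > hi) ||
      any(items != round(items))) {
    stop(sprintf("%s items must be integers in %d-%d", name, lo, hi))
  }
  invisible(TRUE)
}

#' Score a cohort table
#'
#' Applies all four instruments to a cohort data frame (one row per subject,
#' item-level columns `pcl01..pcl20`, `phq01..phq08`, `ambi01..ambi16`, and
#' screen columns `tbi_event`, `tbi_aoc`, `tbi_loc_min`) and returns one row
#' per subject with totals, cluster scores and derived group flags.
#'
#' @param cohort Cohort data frame (see [sample_cohort()]).
#' @return Data frame of scored subjects.
#' @export
score_subjects <- function(cohort) {
  pcl_cols <- sprintf("pcl%02d", 1:20)
  phq_cols <- sprintf("phq%02d", 1:8)
  ambi_cols <- sprintf("ambi%02d", 1:16)
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    pcl <- score_pcl5(as.integer(row[pcl_cols]))
    phq <- score_phq8(as.integer(row[phq_cols]))
    ambi <- score_ambi(as.integer(row[ambi_cols]))
    data.frame(
      subject_id = row$subject_id,
      age = row$age,
      sex = row$sex,
      pcl_total = pcl$total,
      pcl_cluster_b = pcl$cluster_b,
      pcl_cluster_c = pcl$cluster_c,
      pcl_cluster_d = pcl$cluster_d,
      pcl_cluster_e = pcl$cluster_e,
      ptsd_positive = pcl$ptsd_positive,
      phq_total = phq$total,
      phq_category = phq$category,
      mdd_symptom_positive = phq$mdd_symptom_positive,
      mdd_aggregate_positive = phq$mdd_aggregate_positive,
      ambi_total = ambi$total,
      bi_positive = ambi$bi_positive,
      mtbi_positive = classify_mtbi(row$tbi_event, row$tbi_aoc,
                                    row$tbi_loc_min),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
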