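#' @name mnss
#' @title Modified Neurological Severity Score (mNSS)
#'
#' @description
#' Composite rodent deficit scale combining three subtests, higher =
#' worse:
#' \describe{
#'   \item{tail-raise (0-3)}{three binary items scored while the animal
#'     is raised by the tail: forelimb flexion (0-1), hindlimb flexion
#'     (0-1), head movement beyond 10 degrees off the vertical axis
#'     within 30 s (0-1). The scorer consumes pre-judged binaries, it
#'     does not measure angles.}
#'   \item{sensory (0-12)}{four ordinal items, each 0-3: visual placement
#'     of forelimbs, tactile placement of forelimbs, proprioceptive
#'     adduction of hindlimbs, tactile placement of hindlimbs.}
#'   \item{beam balance (0-6)}{one ordinal category: 0 balances with
#'     steady posture; 1 grasps side of beam; 2 hugs beam, one limb
#'     falls; 3 hugs beam, two limbs fall, or spins (>60 s); 4 attempts
#'     to balance but falls after 40 s; 5 falls after 20 s; 6 falls off
#'     with no attempt to balance or hang on within 20 s.}
#' }
#' The published scale describes the total as 0 (normal) to 18 (maximal
#' deficit) although the printed subtotals bound the arithmetic sum at
#' 21; [score_mnss()] returns the arithmetic sum of the subscales and
#' warns when a total exceeds 18 rather than rescaling.
NULL

mnss_item_ranges <- c(forelimb_flexion = 1L, hindlimb_flexion = 1L,
                      head_movement = 1L,
                      visual_forelimb = 3L, tactile_forelimb = 3L,
                      proprioceptive_hindlimb = 3L, tactile_hindlimb = 3L,
                      beam_balance = 6L)

#' Score mNSS records
#'
#' @param records Data frame with one row per assessment and the item
#'   columns `forelimb_flexion`, `hindlimb_flexion`, `head_movement`
#'   (each 0-1), `visual_forelimb`, `tactile_forelimb`,
#'   `proprioceptive_hindlimb`, `tactile_hindlimb` (each 0-3), and
#'   `beam_balance` (0-6). Any other columns (subject, timepoint, group)
#'   are passed through.
#' @return The input with `tail_subtotal` (0-3), `sensory_subtotal`
#'   (0-12), `beam_subtotal` (0-6) and `mnss_total` appended.
#' @seealso [mnss]
#' @export
score_mnss <- function(records) {
  records <- as.data.frame(records)
  for (item in names(mnss_item_ranges)) {
    if (!item %in% names(records))
      stop(sprintf("missing mNSS item '%s'", item))
    v <- records[[item]]
    if (any(is.na(v)) || any(v != round(v)) || any(v < 0) ||
        any(v > mnss_item_ranges[[item]]))
      stop(sprintf("mNSS item '%s' out of range 0..%d",
                   item, mnss_item_ranges[[item]]))
  }
  records$tail_subtotal <- records$forelimb_flexion + records$hindlimb_flexion +
    records$head_movement
  records$sensory_subtotal <- records$visual_forelimb + records$tactile_forelimb +
    records$proprioceptive_hindlimb + records$tactile_hindlimb
  records$beam_subtotal <- records$beam_balance
  records$mnss_total <- records$tail_subtotal + records$sensory_subtotal +
    records$beam_subtotal
  if (any(records$mnss_total > 18))
    warning("mNSS total exceeds 18: the published scale tops at 18 but its subscales sum to 21; the arithmetic subscale sum is reported unrescaled")
  records
}

exclusion_reasons <- c("none", "died_24h", "no_deficit", "SAH")

#' Apply cohort exclusion filters
#'
#' Removes animals whose exclusion flag is not `"none"` (deaths within
#' 24 h of stroke, absence of an observable neurological deficit,
#' subarachnoid hemorrhage) and reports per-group, per-reason counts.
#' Idempotent: re-applying to the included set changes nothing.
#'
#' @param cohort Data frame with columns `animal`, `group`, `exclusion`
#'   (values `none`, `died_24h`, `no_deficit`, `SAH`).
#' @return List: `included` (filtered cohort), `report` (list with
#'   `n_enrolled`, `n_included`, `n_excluded`, and a `counts` data frame
#'   of group x reason tallies).
#' @export
apply_exclusions <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!all(c("animal", "group", "exclusion") %in% names(cohort)))
    stop("cohort needs columns animal, group, exclusion")
  bad <- setdiff(unique(as.character(cohort$exclusion)), exclusion_reasons)
  if (length(bad) > 0L)
    stop(sprintf("unknown exclusion flag(s): %s", paste(bad, collapse = ", ")))
  keep <- cohort$exclusion == "none"
  excl <- cohort[!keep, , drop = FALSE]
  counts <- if (nrow(excl) > 0L) {
    as.data.frame(table(group = excl$group, reason = excl$exclusion),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(group = character(), reason = character(), Freq = integer())
  }
  names(counts)[names(counts) == "Freq"] <- "n"
  counts <- counts[counts$n > 0L, , drop = FALSE]
  list(included = cohort[keep, , drop = FALSE],
       report = list(n_enrolled = nrow(cohort),
                     n_included = sum(keep),
                     n_excluded = sum(!keep),
                     counts = counts))
}

#' Example enrollment ledger of the emulated study design
#'
#' A 45-animal cohort randomized over three treatment arms (PBS-only,
#' FBS-hMSCs, SS-hMSCs) with the exclusion pattern of the emulated
#' study: 4 deaths within 24 h (SS 2, FBS 1, PBS 1), 4 animals without
#' observable deficits (SS 1, FBS 1, PBS 2), and 2 subarachnoid
#' hemorrhages (SS 1, FBS 1), leaving 35 animals in the final analysis.
#'
#' @return A cohort data frame suitable for [apply_exclusions()].
#' @export
stroke_cohort_ledger <- function() {
  arm <- function(group, n, died, no_deficit, sah) {
    flags <- c(rep("died_24h", died), rep("no_deficit", no_deficit),
               rep("SAH", sah))
    flags <- c(flags, rep("none", n - length(flags)))
    data.frame(group = group, exclusion = flags)
  }
  out <- rbind(arm("SS-hMSCs", 15L, 2L, 1L, 1L),
               arm("FBS-hMSCs", 15L, 1L, 1L, 1L),
               arm("PBS-only", 15L, 1L, 2L, 0L))
  out <- data.frame(animal = sprintf("rat%02d", seq_len(nrow(out))), out)
  out$assay <- ifelse(out$exclusion == "none", "MRI+behavior", "")
  out
}
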