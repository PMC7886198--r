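#' Default treatment-group effect structure
#'
#' Per-arm longitudinal trajectories for the synthetic cohort: all
#' animals start from the same acute severity (day-1 lesion radius
#' around 2 mm, mNSS around 12), and the arms then diverge with the
#' planted ordering SS-hMSCs < FBS-hMSCs < PBS-only in both final lesion
#' size and final mNSS (serum-preconditioned cells recover best,
#' vehicle worst). Lesion radii are expressed as a day-1 radius times a
#' non-increasing per-timepoint shrink factor, so the monotone lesion
#' evolution constraint holds for every sampled animal.
#'
#' @return Named list (one entry per arm) of lists with fields
#'   `lesion_day1_mean`, `lesion_day1_sd` (mm), `shrink` (per-timepoint
#'   factors), `ventricle_scale`, `lesion_eigenvalue_factor`,
#'   `mnss_mean`, `mnss_sd` (per timepoint).
#' @export
default_group_effects <- function() {
  base <- function(shrink, vent, mnss)
    list(lesion_day1_mean = 2.0, lesion_day1_sd = 0.1,
         shrink = shrink, ventricle_scale = vent,
         lesion_eigenvalue_factor = c(0.5, 0.65, 0.8),
         mnss_mean = mnss, mnss_sd = 1.5)
  list(
    "PBS-only"  = base(c(1, 0.80, 0.70), c(1, 1.30, 1.50), c(12, 11, 10)),
    "FBS-hMSCs" = base(c(1, 0.72, 0.55), c(1, 1.25, 1.40), c(12, 10, 8)),
    "SS-hMSCs"  = base(c(1, 0.65, 0.40), c(1, 1.20, 1.30), c(12, 8, 6))
  )
}

# Deterministic allocation of an integer mNSS total (0..21, practically
# 0..18) to rubric items, filling beam balance first, then the sensory
# battery, then the tail-raise binaries.
allocate_mnss_items <- function(total) {
  total <- max(0L, min(21L, as.integer(round(total))))
  beam <- min(6L, total); rem <- total - beam
  sens_tot <- min(12L, rem); rem <- rem - sens_tot
  sens <- integer(4)
  for (j in seq_len(4)) {
    sens[j] <- min(3L, sens_tot)
    sens_tot <- sens_tot - sens[j]
  }
  tail_tot <- min(3L, rem)
  tails <- as.integer(seq_len(3) <= tail_tot)
  data.frame(forelimb_flexion = tails[1], hindlimb_flexion = tails[2],
             head_movement = tails[3],
             visual_forelimb = sens[1], tactile_forelimb = sens[2],
             proprioceptive_hindlimb = sens[3], tactile_hindlimb = sens[4],
             beam_balance = beam)
}

#' Simulate a longitudinal treated cohort
#'
#' Draws, for each animal, a phantom specification (lesion trajectory,
#' ventricular enlargement, lesion diffusivity factor) and an mNSS item
#' trajectory from its arm's effect structure, plus an exclusion flag.
#' With the default effects the arms carry the planted severity ordering
#' SS-hMSCs < FBS-hMSCs < PBS-only at the final timepoint.
#'
#' @param n_per_group Animals per arm (>= 2).
#' @param group_effects Effect structure as from [default_group_effects()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param exclusion_probs Named probabilities for `died_24h`,
#'   `no_deficit`, `SAH` (default all 0: nothing excluded).
#' @param grid_shape,voxel_size,snr Passed to each [phantom_spec()].
#' @param lesion_scale Multiplier on the sampled lesion radii (default 1,
#'   the study-scale brain); use < 1 when generating on grids smaller
#'   than the default so lesions stay within the hemisphere.
#' @param lesion_free If TRUE, all lesion radii are 0 and mNSS totals 0
#'   (intact control animals).
#' @return List: `cohort` (animal, group, exclusion), `specs` (named list
#'   of [phantom_spec()]s), `mnss` (item-level records per animal and
#'   timepoint), `timepoints`.
#' @export
simulate_cohort <- function(n_per_group, group_effects = default_group_effects(),
                            seed = 1L,
                            exclusion_probs = c(died_24h = 0, no_deficit = 0, SAH = 0),
                            grid_shape = c(64L, 64L, 16L),
                            voxel_size = c(0.156, 0.156, 0.75),
                            snr = 30, lesion_free = FALSE, lesion_scale = 1) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  groups <- names(group_effects)
  known <- c("PBS-only", "FBS-hMSCs", "SS-hMSCs")
  bad <- setdiff(groups, known)
  if (length(bad) > 0L)
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  p_none <- 1 - sum(exclusion_probs)
  if (p_none < 0) stop("exclusion probabilities sum to more than 1")
  timepoints <- c("day1", "wk2", "wk5")

  set.seed(seed)
  cohort <- list(); specs <- list(); mnss <- list()
  a <- 0L
  for (g in groups) {
    eff <- group_effects[[g]]
    for (j in seq_len(n_per_group)) {
      a <- a + 1L
      id <- sprintf("%s_%02d", gsub("[^A-Za-z]", "", g), j)
      flag <- sample(c("none", names(exclusion_probs)), 1L,
                     prob = c(p_none, exclusion_probs))
      if (lesion_free) {
        radii <- rep(0, length(timepoints))
        totals <- rep(0L, length(timepoints))
      } else {
        r1 <- max(0.5, stats::rnorm(1, eff$lesion_day1_mean, eff$lesion_day1_sd))
        radii <- r1 * eff$shrink * lesion_scale
        totals <- round(pmin(18, pmax(0, stats::rnorm(length(timepoints),
                                                      eff$mnss_mean, eff$mnss_sd))))
      }
      spec_seed <- as.integer((as.numeric(seed) * 1009 + a * 7919) %% 2147483647)
      specs[[id]] <- phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                                  timepoints = timepoints,
                                  lesion_radius = radii,
                                  ventricle_scale = eff$ventricle_scale,
                                  lesion_eigenvalue_factor = eff$lesion_eigenvalue_factor,
                                  snr = snr, seed = spec_seed)
      cohort[[id]] <- data.frame(animal = id, group = g, exclusion = flag)
      rec <- do.call(rbind, lapply(totals, allocate_mnss_items))
      mnss[[id]] <- data.frame(animal = id, group = g, timepoint = timepoints, rec)
    }
  }
  list(cohort = do.call(rbind, c(cohort, list(make.row.names = FALSE))),
       specs = specs,
       mnss = do.call(rbind, c(mnss, list(make.row.names = FALSE))),
       timepoints = timepoints)
}
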