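#' Firefly/Renilla normalized luminescence
#'
#' Divides the firefly (CRE-driven, receptor-activity) photon count by
#' the Renilla (constitutive) count, controlling for transfection
#' efficiency and viability in each well.
#'
#' @param luc_counts Non-negative firefly luciferase counts.
#' @param rl_counts Positive Renilla luciferase counts.
#' @return The dimensionless ratio `luc_counts / rl_counts`.
#' @export
#' @examples
#' normalized_luc(1000, 100)
normalized_luc <- function(luc_counts, rl_counts) {
  if (any(is.na(rl_counts)) || any(rl_counts <= 0)) {
    stop("validation error: rl_counts must be > 0 (dead/failed well)",
         call. = FALSE)
  }
  if (any(luc_counts < 0, na.rm = TRUE)) {
    stop("validation error: luc_counts must be non-negative", call. = FALSE)
  }
  luc_counts / rl_counts
}

#' Per-plate standardization scale from the Olfr544 standard wells
#'
#' Every plate carries six wells transfected with the mouse receptor
#' Olfr544: three challenged with 10 uM nonanedioic acid (a known
#' agonist) and three with the diluent. The plate scale is the mean
#' agonist ratio minus the mean diluent ratio; dividing every ratio on
#' the plate by it sets that difference to exactly 1, making responses
#' comparable across plates regardless of reader gain. A non-positive
#' scale (standard failed to respond) flags the plate as failed rather
#' than erroring, so a screening run can continue without it.
#'
#' @param standard_agonist_wells Normalized-luc ratios of the
#'   standard wells challenged with the agonist.
#' @param standard_diluent_wells Ratios of the standard wells challenged
#'   with the diluent.
#' @param plate_id Optional plate identifier carried into the result.
#' @return A list of class `plate_standardization` with elements
#'   `plate_id`, `scale_s`, and `failed` (`TRUE` when `scale_s <= 0`).
#' @export
#' @examples
#' plate_scale(c(2.0, 2.2, 1.8), c(0.5, 0.5, 0.5))
plate_scale <- function(standard_agonist_wells, standard_diluent_wells,
                        plate_id = NA_character_) {
  if (length(standard_agonist_wells) < 1 || length(standard_diluent_wells) < 1) {
    stop("need at least one standard well in each group", call. = FALSE)
  }
  s <- mean(standard_agonist_wells) - mean(standard_diluent_wells)
  structure(
    list(plate_id = plate_id, scale_s = s, failed = !is.finite(s) || s <= 0),
    class = "plate_standardization"
  )
}

#' @export
print.plate_standardization <- function(x, ...) {
  cat("plate", x$plate_id, "scale_s =", format(x$scale_s),
      if (x$failed) "(FAILED: non-positive scale)" else "", "\n")
  invisible(x)
}

#' Subtract the no-odor baseline response per receptor
#'
#' In each screening run one plate receives no odor in any test well and
#' serves as the baseline; the odor response of each receptor is its
#' standardized response on an odor plate minus its standardized
#' response on that baseline plate. Receptors present on only one of the
#' two plates are reported in the `missing` attribute, never silently
#' dropped.
#'
#' @param odor_plate_scores Tibble or data frame with columns
#'   `receptor_id` and `standardized_response` for one odor plate.
#' @param baseline_plate_scores Same columns for the run's baseline
#'   plate.
#' @return A tibble with `receptor_id`, `standardized_response`,
#'   `baseline_response` and `delta`, plus an attribute `missing` naming
#'   receptors without a match. Warns (and returns zero rows) when no
#'   receptor overlaps.
#' @export
baseline_subtract <- function(odor_plate_scores, baseline_plate_scores) {
  base <- tibble(
    receptor_id = baseline_plate_scores$receptor_id,
    baseline_response = baseline_plate_scores$standardized_response
  )
  out <- dplyr::inner_join(
    tibble(receptor_id = odor_plate_scores$receptor_id,
           standardized_response = odor_plate_scores$standardized_response),
    base, by = "receptor_id"
  )
  out$delta <- out$standardized_response - out$baseline_response
  missing <- union(
    setdiff(odor_plate_scores$receptor_id, base$receptor_id),
    setdiff(base$receptor_id, odor_plate_scores$receptor_id)
  )
  if (nrow(out) == 0) {
    warning("no overlapping receptors between odor and baseline plates",
            call. = FALSE)
  }
  attr(out, "missing") <- missing
  out
}

#' Rank primary-screen deltas and select hits for the secondary screen
#'
#' Pairs are ranked by baseline-subtracted delta, descending. The
#' selection budget is the top `fraction` of all pairs
#' (`floor(fraction * N)`); within the budget, at most `per_receptor_cap`
#' ligands are kept per receptor, and pairs displaced by the cap are not
#' backfilled with lower-ranked ones. Ties are broken deterministically
#' by (delta descending, receptor_id ascending, odor_id ascending).
#'
#' @param deltas Tibble with columns `receptor_id`, `odor_id`, `delta`.
#' @param fraction Proportion of pairs to carry forward (default 0.05,
#'   the top 5 percent).
#' @param per_receptor_cap Maximum ligands selected per receptor
#'   (default 10).
#' @return The input with `rank` (1..N, the global order) and `selected`
#'   columns, sorted by rank.
#' @export
rank_and_select <- function(deltas, fraction = 0.05, per_receptor_cap = 10) {
  stopifnot(fraction > 0, fraction <= 1, per_receptor_cap >= 1)
  n <- nrow(deltas)
  if (n == 0) {
    return(mutate(deltas, rank = integer(0), selected = logical(0)))
  }
  if (any(!is.finite(deltas$delta))) {
    stop("deltas must be finite", call. = FALSE)
  }
  budget <- floor(fraction * n)
  out <- arrange(deltas, desc(.data$delta), .data$receptor_id, .data$odor_id)
  out$rank <- seq_len(n)
  out <- out |>
    group_by(.data$receptor_id) |>
    mutate(.receptor_rank = rank(.data$rank)) |>
    ungroup()
  out$selected <- out$rank <= budget & out$.receptor_rank <= per_receptor_cap
  out$.receptor_rank <- NULL
  out
}

#' Standardize and score a full primary screen
#'
#' Runs the complete primary-screen normalization on raw well records:
#' firefly/Renilla ratios, per-plate standardization by the Olfr544
#' standard wells, baseline subtraction against each run's no-odor
#' plate, within-run averaging of replicated receptor/odor pairs, and
#' ranking with top-fraction selection.
#'
#' Plates are grouped into runs by `date` (one transfection master plate
#' per day); within a run the plate whose test wells are all no-odor is
#' the baseline. Each plate is standardized by its own standard wells.
#' Plates with a non-positive standard difference are excluded and
#' reported via the `failed_plates` attribute.
#'
#' @param primary_records Primary-screen well tibble (see
#'   [read_record_table()] / [simulate_primary_run()]).
#' @param layout A [plate_layout()] describing well roles.
#' @param fraction,per_receptor_cap Passed to [rank_and_select()].
#' @param average_within_run Average replicated receptor/odor
#'   measurements sharing a date before ranking (default `TRUE`); when
#'   `FALSE`, replicates are ranked as separate entries.
#' @return A tibble of scores with `receptor_id`, `odor_id`, `delta`,
#'   `rank`, `selected`, plus attributes `failed_plates` and
#'   `missing_receptors`.
#' @export
primary_screen_scores <- function(primary_records, layout = plate_layout(),
                                  fraction = 0.05, per_receptor_cap = 10,
                                  average_within_run = TRUE) {
  rec <- mutate(primary_records,
                ratio = normalized_luc(.data$luc_counts, .data$rl_counts))

  # per-plate standardization by the plate's own standard wells
  scales <- rec |>
    group_by(.data$plate_id) |>
    summarise(
      scale_s = mean(.data$ratio[.data$well_index %in%
                                   layout$standard_agonist_wells]) -
        mean(.data$ratio[.data$well_index %in%
                           layout$standard_diluent_wells]),
      .groups = "drop"
    )
  failed <- scales$plate_id[!is.finite(scales$scale_s) | scales$scale_s <= 0]
  rec <- rec |>
    left_join(scales, by = "plate_id") |>
    filter(!.data$plate_id %in% failed) |>
    mutate(standardized_response = .data$ratio / .data$scale_s)

  test <- filter(rec, .data$well_index %in% layout$test_wells)
  # a run's baseline plate has no odor in every test well
  plate_info <- test |>
    group_by(.data$date, .data$plate_id) |>
    summarise(is_baseline = all(.data$no_odor), .groups = "drop")
  test <- left_join(test, plate_info, by = c("date", "plate_id"))

  missing_all <- character(0)
  deltas <- vector("list", 0L)
  for (run_date in unique(test$date)) {
    run <- filter(test, .data$date == run_date)
    base_plates <- unique(run$plate_id[run$is_baseline])
    if (length(base_plates) == 0) {
      warning("run ", format(run_date), " has no baseline plate; skipped",
              call. = FALSE)
      next
    }
    base <- run |>
      filter(.data$is_baseline) |>
      group_by(.data$well_index, .data$receptor_id) |>
      summarise(standardized_response = mean(.data$standardized_response),
                .groups = "drop")
    for (pid in setdiff(unique(run$plate_id), base_plates)) {
      plate <- filter(run, .data$plate_id == pid)
      base_r <- base
      names(base_r)[names(base_r) == "standardized_response"] <-
        "baseline_response"
      d <- dplyr::inner_join(
        plate[, c("well_index", "receptor_id", "odor_id",
                  "standardized_response")],
        base_r, by = c("well_index", "receptor_id")
      )
      missing_all <- union(missing_all,
                           setdiff(plate$receptor_id, d$receptor_id))
      d$delta <- d$standardized_response - d$baseline_response
      d$date <- run_date
      deltas[[length(deltas) + 1L]] <- d
    }
  }
  deltas <- bind_rows(deltas)
  if (nrow(deltas) == 0) {
    out <- tibble(receptor_id = character(0), odor_id = character(0),
                  delta = numeric(0), rank = integer(0),
                  selected = logical(0))
  } else {
    if (average_within_run) {
      deltas <- deltas |>
        group_by(.data$date, .data$receptor_id, .data$odor_id) |>
        summarise(delta = mean(.data$delta), .groups = "drop")
    }
    out <- rank_and_select(deltas[, c("receptor_id", "odor_id", "delta")],
                           fraction = fraction,
                           per_receptor_cap = per_receptor_cap)
  }
  attr(out, "failed_plates") <- failed
  attr(out, "missing_receptors") <- missing_all
  out
}
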