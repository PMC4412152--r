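#' ROC curve with tie-grouped thresholds
#'
#' Sweeps a decision threshold over the unique score values (ties
#' grouped, so each distinct score contributes one vertex), tracing the
#' false-positive rate against the true-positive rate from (0, 0) to
#' (1, 1). The area under the curve is the trapezoidal area of the
#' tie-grouped polygon, which equals the Mann-Whitney U statistic
#' normalized by `n_pos * n_neg` (ties counting one half).
#'
#' @param scores Numeric scores; larger means more likely positive.
#' @param labels Logical labels, `TRUE` for positives.
#' @return A list of class `roc_curve` with `points` (tibble of `fpr`,
#'   `tpr`, ordered), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(c(3, 2, 1), c(TRUE, FALSE, TRUE))
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete",
                                           call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("domain error: need at least one positive and one negative label",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  pts <- tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(
    list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives, %d vertices)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Run the full three-stage screening pipeline
#'
#' Executes the screen end to end on raw well tables: primary-screen
#' standardization and hit selection, secondary-screen ANOVA filtering,
#' dose-response fitting with the three-criterion agonist call, and ROC
#' summaries of how each stage predicts the next (primary delta ->
#' secondary pass; secondary F -> agonist call). Stages fail with a
#' stage-named diagnostic; outputs computed before a failure are
#' preserved in the error condition's `partial` field.
#'
#' @param raw_primary Primary-screen well tibble.
#' @param raw_secondary Secondary-screen well tibble.
#' @param raw_dose Dose-response well tibble.
#' @param config A list of options: `layout` ([plate_layout()]),
#'   `fraction`, `per_receptor_cap`, `alpha_secondary`, `alpha_dose`,
#'   `sd_limit`, `fix_hill`, `vector_id`. Missing entries take the
#'   defaults of the stage functions.
#' @return A list of class `screen_pipeline_result`: `hits` (primary
#'   scores), `secondary` (ANOVA results), `calls` (agonist calls),
#'   `ec50` (passing-pair table), and `roc` (list of [roc_curve()]
#'   objects `primary_vs_secondary`, `secondary_vs_agonist`; `NULL`
#'   where a stage had only one outcome class).
#' @export
run_screen_pipeline <- function(raw_primary, raw_secondary, raw_dose,
                                config = list()) {
  cfg <- utils::modifyList(
    list(layout = plate_layout(), fraction = 0.05, per_receptor_cap = 10,
         alpha_secondary = 0.05, alpha_dose = 0.05, sd_limit = 1.0,
         fix_hill = 1, vector_id = "vector"),
    config
  )
  stage <- function(name, partial, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(
        class = c("screen_stage_error", "error", "condition"),
        list(message = paste0("stage '", name, "' failed: ",
                              conditionMessage(e)),
             call = sys.call(-1), partial = partial)
      ))
    })
  }

  hits <- stage("primary", list(), {
    if (nrow(raw_primary) == 0) {
      tibble(receptor_id = character(0), odor_id = character(0),
             delta = numeric(0), rank = integer(0), selected = logical(0))
    } else {
      primary_screen_scores(raw_primary, layout = cfg$layout,
                            fraction = cfg$fraction,
                            per_receptor_cap = cfg$per_receptor_cap)
    }
  })

  secondary <- stage("secondary", list(hits = hits), {
    if (nrow(raw_secondary) == 0) {
      tibble(receptor_id = character(0), odor_id = character(0),
             f_stat = numeric(0), p_value = numeric(0),
             p_adjusted = numeric(0), passed = logical(0))
    } else {
      secondary_screen_results(raw_secondary, alpha = cfg$alpha_secondary)
    }
  })

  calls <- stage("dose", list(hits = hits, secondary = secondary), {
    if (nrow(raw_dose) == 0) {
      dose_response_calls(
        tibble(receptor_id = character(0), odor_id = character(0),
               concentration_log10M = numeric(0), normalized_luc = numeric(0)),
        vector_id = cfg$vector_id
      )
    } else {
      dose_response_calls(raw_dose, vector_id = cfg$vector_id,
                          alpha = cfg$alpha_dose, sd_limit = cfg$sd_limit,
                          fix_hill = cfg$fix_hill)
    }
  })

  roc <- stage("roc", list(hits = hits, secondary = secondary, calls = calls), {
    out <- list(primary_vs_secondary = NULL, secondary_vs_agonist = NULL)
    if (nrow(hits) > 0 && nrow(secondary) > 0) {
      m <- dplyr::inner_join(hits, secondary,
                             by = c("receptor_id", "odor_id"))
      if (nrow(m) > 0 && length(unique(m$passed)) == 2) {
        out$primary_vs_secondary <- roc_curve(m$delta, m$passed)
      }
    }
    if (nrow(secondary) > 0 && !is.null(calls) && nrow(calls) > 0) {
      m <- dplyr::inner_join(secondary, calls,
                             by = c("receptor_id", "odor_id"))
      if (nrow(m) > 0 && length(unique(m$is_agonist)) == 2) {
        out$secondary_vs_agonist <- roc_curve(m$f_stat.x, m$is_agonist)
      }
    }
    out
  })

  structure(
    list(hits = hits, secondary = secondary, calls = calls,
         ec50 = ec50_table(calls), roc = roc, config = cfg),
    class = "screen_pipeline_result"
  )
}

#' @export
print.screen_pipeline_result <- function(x, ...) {
  cat("screening pipeline result\n")
  cat("  primary pairs scored:   ", nrow(x$hits),
      " (selected ", sum(x$hits$selected), ")\n", sep = "")
  cat("  secondary pairs tested: ", nrow(x$secondary),
      " (passed ", sum(x$secondary$passed), ")\n", sep = "")
  cat("  dose-response calls:    ", nrow(x$calls),
      " (agonists ", sum(x$calls$is_agonist), ")\n", sep = "")
  if (!is.null(x$roc$primary_vs_secondary)) {
    cat(sprintf("  AUC primary -> secondary: %.3f\n",
                x$roc$primary_vs_secondary$auc))
  }
  if (!is.null(x$roc$secondary_vs_agonist)) {
    cat(sprintf("  AUC secondary -> agonist: %.3f\n",
                x$roc$secondary_vs_agonist$auc))
  }
  invisible(x)
}
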