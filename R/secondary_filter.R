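#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA of a response across concentration groups:
#' `F = MS_between / MS_within` on (k - 1, N - k) degrees of freedom,
#' with the p value from the F distribution. Degenerate inputs are
#' resolved before delegating to the linear-model machinery: if all
#' observations are identical the statistic is 0 with p = 1; if the
#' within-group mean square is zero but group means differ, the F limit
#' is infinite and p = 0, flagged as degenerate.
#'
#' @param groups A list of two or more numeric vectors, one per group.
#' @return A list with `f_stat`, `p_value`, `df_between`, `df_within`
#'   and `degenerate` (`TRUE` when the within mean square vanished).
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(4, 5, 6)))
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("domain error: need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("each group needs at least one value", call. = FALSE)
  k <- length(groups)
  n <- sum(sizes)
  if (n - k < 1) {
    stop("domain error: no residual degrees of freedom (need N - k >= 1)",
         call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), sizes))

  ssw <- sum((y - ave(y, g))^2)
  ssb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2)
  tol <- 1e-12 * max(1, sum(y^2))
  if (ssw <= tol) {
    if (ssb <= tol) {
      return(list(f_stat = 0, p_value = 1, df_between = k - 1L,
                  df_within = n - k, degenerate = FALSE))
    }
    return(list(f_stat = Inf, p_value = 0, df_between = k - 1L,
                df_within = n - k, degenerate = TRUE))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  list(f_stat = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
       degenerate = FALSE)
}

#' Concentration-effect test for one secondary-screen pair
#'
#' Assembles the triplicate responses of one receptor/odor pair at the
#' no-odor control and the 1, 10 and 100 uM challenges into
#' concentration groups and runs a one-way ANOVA; the pair passes to the
#' dose-response stage when the omnibus p value is below `alpha`. The
#' no-odor group (concentration 0) enters as a factor level rather than
#' being subtracted.
#'
#' @param pair_records Secondary-screen well tibble for a single
#'   receptor/odor pair, with columns `receptor_id`, `odor_id`,
#'   `concentration_uM` and `normalized_luc`.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `secondary_result` with the pair's ids, the
#'   per-concentration `groups`, `f_stat`, `p_value` and `passed`.
#' @export
secondary_pass <- function(pair_records, alpha = 0.05) {
  if (length(unique(pair_records$receptor_id)) != 1 ||
      length(unique(pair_records$odor_id)) != 1) {
    stop("pair_records must contain a single receptor/odor pair",
         call. = FALSE)
  }
  concs <- sort(unique(pair_records$concentration_uM))
  if (length(concs) < 2) {
    stop("need at least 2 distinct concentrations", call. = FALSE)
  }
  if (!0 %in% concs) {
    warning("no-odor (concentration 0) group missing; testing available groups",
            call. = FALSE)
  }
  groups <- lapply(concs, function(cc) {
    pair_records$normalized_luc[pair_records$concentration_uM == cc]
  })
  names(groups) <- as.character(concs)
  av <- anova_oneway(groups)
  structure(
    list(receptor_id = pair_records$receptor_id[1],
         odor_id = pair_records$odor_id[1],
         groups = groups, f_stat = av$f_stat, p_value = av$p_value,
         alpha = alpha, passed = av$p_value < alpha,
         degenerate = av$degenerate),
    class = "secondary_result"
  )
}

#' @export
print.secondary_result <- function(x, ...) {
  cat("secondary screen:", x$receptor_id, "x", x$odor_id,
      sprintf("F = %.3f, p = %.4g,", x$f_stat, x$p_value),
      if (x$passed) "PASS" else "fail", "\n")
  invisible(x)
}

#' Run the secondary ANOVA filter over a whole table
#'
#' Applies [secondary_pass()] to every receptor/odor pair in a
#' secondary-screen table. An optional Benjamini-Hochberg correction
#' across pairs is available but off by default (the screening design
#' applies none at this stage).
#'
#' @param secondary_records Secondary-screen well tibble.
#' @param alpha Significance level (default 0.05).
#' @param adjust Multiple-testing adjustment across pairs: `"none"`
#'   (default) or `"BH"`.
#' @return A tibble with one row per pair: `receptor_id`, `odor_id`,
#'   `f_stat`, `p_value`, `p_adjusted`, `passed`.
#' @export
secondary_screen_results <- function(secondary_records, alpha = 0.05,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pairs <- unique(secondary_records[, c("receptor_id", "odor_id")])
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- secondary_records[
      secondary_records$receptor_id == pairs$receptor_id[i] &
        secondary_records$odor_id == pairs$odor_id[i], ]
    sp <- secondary_pass(pr, alpha = alpha)
    tibble(receptor_id = sp$receptor_id, odor_id = sp$odor_id,
           f_stat = sp$f_stat, p_value = sp$p_value)
  })
  out <- bind_rows(res)
  out$p_adjusted <- if (adjust == "BH") {
    stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  out$passed <- out$p_adjusted < alpha
  out
}
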