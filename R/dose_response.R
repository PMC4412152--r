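#' Sigmoidal concentration-response prediction
#'
#' The three-parameter (fixed Hill slope) or four-parameter logistic
#' curve on the log10-molar concentration axis:
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - x)))`.
#' At `x = log_ec50` the response is halfway between bottom and top; the
#' curve is monotone between the two asymptotes for `hill > 0`.
#'
#' @param x Log10 molar concentration (the no-odor condition enters at
#'   -12, far below any EC50, where the curve sits on its bottom
#'   asymptote).
#' @param bottom,top Lower and upper response asymptotes.
#' @param log_ec50 Log10 molar concentration of half-maximal response.
#' @param hill Hill slope (default 1).
#' @return Predicted response, vectorized over `x`.
#' @export
#' @examples
#' predict_sigmoid(-5, bottom = 0, top = 2, log_ec50 = -6)
predict_sigmoid <- function(x, bottom, top, log_ec50, hill = 1) {
  bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - x)))
}

# deterministic multi-start grid: asymptotes from the data extrema,
# log EC50 started at every midpoint of consecutive observed
# concentrations (plus the overall median), ascending order
.sigmoid_starts <- function(x, y, fix_hill) {
  xs <- sort(unique(x))
  le0 <- sort(unique(c((xs[-1] + xs[-length(xs)]) / 2, stats::median(xs))))
  rng <- range(y)
  pad <- 1e-3 * max(diff(rng), 1e-6)
  starts <- lapply(le0, function(le) {
    s <- list(bottom = rng[1], top = rng[2] + pad, log_ec50 = le)
    if (is.null(fix_hill)) s$hill <- 1
    s
  })
  starts
}

#' Fit a sigmoidal dose-response curve by nonlinear least squares
#'
#' Fits the logistic model of [predict_sigmoid()] by Levenberg-Marquardt
#' least squares with deterministic multi-start initialization (bottom
#' and top from the response extrema; log EC50 started at each midpoint
#' of consecutive observed concentrations; the best residual sum of
#' squares wins, ties going to the earlier start). Standard errors come
#' from the asymptotic covariance `(RSS/df) * (J'J)^-1` and 95 percent
#' confidence intervals from `estimate +/- t(0.975, df) * se`.
#' Non-convergence across all starts is reported through the
#' `converged` flag, never as an error.
#'
#' @param points Data frame with columns `x` (log10 molar; no-odor rows
#'   at -12) and `y` (normalized response).
#' @param fix_hill Fix the Hill slope at this value (default 1, the
#'   classic three-parameter sigmoid); `NULL` frees the slope
#'   (four-parameter fit).
#' @return An object of class `dose_response_fit`: a list with `params`
#'   (bottom, top, log_ec50, hill), `se`, `ci95` (2-column matrix),
#'   `rss`, `df`, `n_points`, `converged`.
#' @export
fit_sigmoid <- function(points, fix_hill = 1) {
  x <- points$x
  y <- points$y
  if (anyNA(x) || anyNA(y)) stop("points must be complete", call. = FALSE)
  n_free <- if (is.null(fix_hill)) 4L else 3L
  if (length(unique(x)) < 2) {
    stop("need at least 2 distinct concentrations", call. = FALSE)
  }
  if (length(x) < n_free + 1L) {
    stop("need at least ", n_free + 1L,
         " points for positive residual degrees of freedom", call. = FALSE)
  }

  if (is.null(fix_hill)) {
    form <- y ~ bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - x)))
  } else {
    form <- y ~ bottom + (top - bottom) / (1 + 10^(.hill * (log_ec50 - x)))
  }
  dat <- data.frame(x = x, y = y)
  if (!is.null(fix_hill)) dat$.hill <- fix_hill

  best <- NULL
  for (s in .sigmoid_starts(x, y, fix_hill)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = dat, start = s,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12 * max(1, best$rss)) {
      best <- list(fit = fit, rss = rss)
    }
  }

  n <- length(x)
  df <- n - n_free
  if (is.null(best)) {
    params <- c(bottom = NA_real_, top = NA_real_, log_ec50 = NA_real_,
                hill = if (is.null(fix_hill)) NA_real_ else fix_hill)
    se <- params * NA_real_
    ci <- cbind(lower = se, upper = se)
    return(structure(
      list(params = params, se = se, ci95 = ci, rss = NA_real_, df = df,
           n_points = n, converged = FALSE),
      class = "dose_response_fit"
    ))
  }

  cf <- stats::coef(best$fit)
  params <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
              log_ec50 = unname(cf["log_ec50"]),
              hill = if (is.null(fix_hill)) unname(cf["hill"]) else fix_hill)
  se_free <- tryCatch(
    summary(best$fit)$coefficients[, "Std. Error"],
    error = function(e) stats::setNames(rep(Inf, n_free), names(cf))
  )
  se_free[!is.finite(se_free)] <- Inf
  se <- c(bottom = unname(se_free["bottom"]), top = unname(se_free["top"]),
          log_ec50 = unname(se_free["log_ec50"]),
          hill = if (is.null(fix_hill)) unname(se_free["hill"]) else 0)
  tq <- stats::qt(0.975, df)
  ci <- cbind(lower = params - tq * se, upper = params + tq * se)
  structure(
    list(params = params, se = se, ci95 = ci, rss = best$rss, df = df,
         n_points = n, converged = TRUE),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("dose-response fit: NOT CONVERGED (", x$n_points, "points )\n")
    return(invisible(x))
  }
  cat(sprintf(
    "dose-response fit: bottom %.4g, top %.4g, logEC50 %.3f (se %.3f), hill %.3g\n",
    x$params["bottom"], x$params["top"], x$params["log_ec50"],
    x$se["log_ec50"], x$params["hill"]))
  cat(sprintf("  RSS %.4g on %d df (%d points)\n", x$rss, x$df, x$n_points))
  invisible(x)
}

#' Extra sum-of-squares F test: receptor versus empty-vector control
#'
#' Compares the nested models "one shared sigmoid describes both the
#' receptor-transfected and the empty-vector wells" (null) against
#' "each condition gets its own sigmoid" (alternative). The statistic is
#' `F = ((RSS_null - RSS_alt) / (p_alt - p_null)) / (RSS_alt / df_alt)`
#' with the p value from the F distribution. Because the omnibus F is
#' direction-blind, rejection additionally requires the receptor fit's
#' span (top - bottom) to exceed the vector fit's span, so only
#' receptor-driven activation counts. A flat-line null is available for
#' sensitivity analysis.
#'
#' @param receptor_points,vector_points Data frames with `x`, `y` for
#'   the receptor-transfected and empty-vector dose series.
#' @param alpha Significance level (default 0.05).
#' @param fix_hill Passed to [fit_sigmoid()].
#' @param null `"shared_sigmoid"` (default) pools both series under one
#'   sigmoid; `"flat"` uses a single constant mean as the null.
#' @return A list of class `extra_ss_test` with `f_stat`, `df_num`,
#'   `df_den`, `p_value`, `alpha`, `reject`, `span_receptor`,
#'   `span_vector`, `degenerate` and the three component fits.
#' @export
extra_ss_test <- function(receptor_points, vector_points, alpha = 0.05,
                          fix_hill = 1, null = c("shared_sigmoid", "flat")) {
  null <- match.arg(null)
  fit_r <- fit_sigmoid(receptor_points, fix_hill = fix_hill)
  fit_v <- fit_sigmoid(vector_points, fix_hill = fix_hill)
  pooled <- data.frame(x = c(receptor_points$x, vector_points$x),
                       y = c(receptor_points$y, vector_points$y))
  n_free <- if (is.null(fix_hill)) 4L else 3L
  if (null == "shared_sigmoid") {
    fit_0 <- fit_sigmoid(pooled, fix_hill = fix_hill)
    rss_0 <- fit_0$rss
    p_null <- n_free
  } else {
    fit_0 <- NULL
    rss_0 <- sum((pooled$y - mean(pooled$y))^2)
    p_null <- 1L
  }
  n <- nrow(pooled)
  p_alt <- 2L * n_free
  df_num <- p_alt - p_null
  df_den <- n - p_alt
  if (df_den < 1) stop("not enough points for the nested comparison",
                       call. = FALSE)
  if (!fit_r$converged || !fit_v$converged ||
      (null == "shared_sigmoid" && !fit_0$converged)) {
    return(structure(
      list(f_stat = NA_real_, df_num = df_num, df_den = df_den,
           p_value = NA_real_, alpha = alpha, reject = FALSE,
           span_receptor = NA_real_, span_vector = NA_real_,
           degenerate = FALSE, converged = FALSE,
           fit_receptor = fit_r, fit_vector = fit_v, fit_null = fit_0),
      class = "extra_ss_test"
    ))
  }
  rss_alt <- fit_r$rss + fit_v$rss
  span_r <- unname(fit_r$params["top"] - fit_r$params["bottom"])
  span_v <- unname(fit_v$params["top"] - fit_v$params["bottom"])
  degenerate <- rss_alt <= 1e-12 * max(1, rss_0)
  if (degenerate) {
    f <- if (rss_0 > rss_alt) Inf else 0
    p <- if (rss_0 > rss_alt) 0 else 1
  } else {
    f <- max(0, ((rss_0 - rss_alt) / df_num) / (rss_alt / df_den))
    p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  }
  structure(
    list(f_stat = f, df_num = df_num, df_den = df_den, p_value = p,
         alpha = alpha, reject = (p < alpha) && (span_r > span_v),
         span_receptor = span_r, span_vector = span_v,
         degenerate = degenerate, converged = TRUE,
         fit_receptor = fit_r, fit_vector = fit_v, fit_null = fit_0),
    class = "extra_ss_test"
  )
}

#' @export
print.extra_ss_test <- function(x, ...) {
  cat(sprintf(
    "extra sum-of-squares test: F(%d, %d) = %.3f, p = %.4g -> %s\n",
    x$df_num, x$df_den, x$f_stat, x$p_value,
    if (isTRUE(x$reject)) "reject (receptor > vector)" else "no rejection"))
  invisible(x)
}

# nearest integer log unit, ties toward the more negative (more potent)
.round_log_ec50 <- function(x) as.integer(ceiling(x - 0.5))

#' Three-criterion agonist call
#'
#' An odorant is called an agonist of a receptor when all three
#' statistical criteria hold on the dose-response data: (1) the 95
#' percent confidence intervals of the top and bottom parameters do not
#' overlap; (2) the standard deviation of the fitted log EC50 is
#' strictly less than `sd_limit` log units; (3) the extra sum-of-squares
#' test confirms the odorant activated the receptor significantly more
#' than the empty-vector control. An unconverged fit yields a negative
#' call with a reason code.
#'
#' @param fit A [fit_sigmoid()] result for the receptor series.
#' @param test An [extra_ss_test()] result against the matched vector
#'   series.
#' @param sd_limit Maximum allowed log EC50 standard deviation
#'   (default 1 log unit, strict inequality).
#' @param receptor_id,odor_id Identifiers carried into the call.
#' @return A list of class `agonist_call` with the three booleans
#'   `crit_ci_separation`, `crit_ec50_sd`, `crit_extra_ss`, the overall
#'   `is_agonist`, the fitted `log_ec50` and the integer-rounded
#'   `reported_log_ec50` (ties toward more potent).
#' @export
call_agonist <- function(fit, test, sd_limit = 1.0,
                         receptor_id = NA_character_,
                         odor_id = NA_character_) {
  if (!fit$converged) {
    return(structure(
      list(receptor_id = receptor_id, odor_id = odor_id,
           crit_ci_separation = FALSE, crit_ec50_sd = FALSE,
           crit_extra_ss = FALSE, is_agonist = FALSE,
           log_ec50 = NA_real_, reported_log_ec50 = NA_integer_,
           reason = "fit_not_converged"),
      class = "agonist_call"
    ))
  }
  ci_b <- fit$ci95["bottom", ]
  ci_t <- fit$ci95["top", ]
  crit_ci <- if (fit$params["top"] >= fit$params["bottom"]) {
    is.finite(ci_t["lower"]) && is.finite(ci_b["upper"]) &&
      ci_t["lower"] > ci_b["upper"]
  } else {
    is.finite(ci_b["lower"]) && is.finite(ci_t["upper"]) &&
      ci_b["lower"] > ci_t["upper"]
  }
  crit_sd <- is.finite(fit$se["log_ec50"]) && fit$se["log_ec50"] < sd_limit
  crit_ess <- isTRUE(test$reject)
  le <- unname(fit$params["log_ec50"])
  structure(
    list(receptor_id = receptor_id, odor_id = odor_id,
         crit_ci_separation = unname(crit_ci), crit_ec50_sd = crit_sd,
         crit_extra_ss = crit_ess,
         is_agonist = unname(crit_ci) && crit_sd && crit_ess,
         log_ec50 = le,
         reported_log_ec50 = .round_log_ec50(le),
         reason = NA_character_),
    class = "agonist_call"
  )
}

#' @export
print.agonist_call <- function(x, ...) {
  cat("agonist call:", x$receptor_id, "x", x$odor_id, "->",
      if (x$is_agonist) "AGONIST" else "not an agonist", "\n")
  cat(sprintf(
    "  CI separation %s | logEC50 sd %s | extra-SS %s | logEC50 %s\n",
    x$crit_ci_separation, x$crit_ec50_sd, x$crit_extra_ss,
    format(x$log_ec50, digits = 3)))
  invisible(x)
}

#' Fit and call every receptor/odor pair in a dose-response table
#'
#' For each receptor/odor pair (excluding the empty-vector control
#' itself), fits the receptor dose series, runs the extra sum-of-squares
#' test against the matched vector series for the same odorant, and
#' applies the three-criterion agonist call.
#'
#' @param dose_records Dose-response well tibble (columns
#'   `concentration_log10M`, `normalized_luc`, `receptor_id`,
#'   `odor_id`).
#' @param vector_id `receptor_id` labelling the empty-vector control
#'   series.
#' @param alpha,sd_limit,fix_hill Passed to [extra_ss_test()] and
#'   [call_agonist()].
#' @return A tibble with one row per pair: the three criteria,
#'   `is_agonist`, the fitted and reported log EC50, and the fit
#'   diagnostics (`se_log_ec50`, `f_stat`, `p_value`, `converged`).
#' @export
dose_response_calls <- function(dose_records, vector_id = "vector",
                                alpha = 0.05, sd_limit = 1.0, fix_hill = 1) {
  recs <- dose_records
  pairs <- unique(recs[recs$receptor_id != vector_id,
                       c("receptor_id", "odor_id")])
  empty <- tibble(
    receptor_id = character(0), odor_id = character(0),
    crit_ci_separation = logical(0), crit_ec50_sd = logical(0),
    crit_extra_ss = logical(0), is_agonist = logical(0),
    log_ec50 = numeric(0), reported_log_ec50 = integer(0),
    se_log_ec50 = numeric(0), f_stat = numeric(0), p_value = numeric(0),
    converged = logical(0)
  )
  if (nrow(pairs) == 0) return(empty)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    rid <- pairs$receptor_id[i]
    oid <- pairs$odor_id[i]
    rp <- recs[recs$receptor_id == rid & recs$odor_id == oid, ]
    vp <- recs[recs$receptor_id == vector_id & recs$odor_id == oid, ]
    receptor_points <- data.frame(x = rp$concentration_log10M,
                                  y = rp$normalized_luc)
    if (nrow(vp) == 0) {
      warning("no vector control series for odor ", oid, call. = FALSE)
      return(NULL)
    }
    vector_points <- data.frame(x = vp$concentration_log10M,
                                y = vp$normalized_luc)
    test <- extra_ss_test(receptor_points, vector_points, alpha = alpha,
                          fix_hill = fix_hill)
    call <- call_agonist(test$fit_receptor, test, sd_limit = sd_limit,
                         receptor_id = rid, odor_id = oid)
    tibble(
      receptor_id = rid, odor_id = oid,
      crit_ci_separation = call$crit_ci_separation,
      crit_ec50_sd = call$crit_ec50_sd,
      crit_extra_ss = call$crit_extra_ss,
      is_agonist = call$is_agonist,
      log_ec50 = call$log_ec50,
      reported_log_ec50 = call$reported_log_ec50,
      se_log_ec50 = unname(test$fit_receptor$se["log_ec50"]),
      f_stat = test$f_stat, p_value = test$p_value,
      converged = test$fit_receptor$converged
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) empty else out
}

#' EC50 summary table of passing agonist calls
#'
#' One row per receptor/odor pair that passed all three agonist
#' criteria, with the log EC50 rounded to the nearest integer log unit
#' (ties toward the more potent, i.e. more negative, value). Repeated
#' experiments for the same pair stay as separate rows. Receptor and
#' odor metadata tables, when given, contribute gene labels and odor
#' names.
#'
#' @param calls Tibble from [dose_response_calls()] (or rows of the same
#'   shape).
#' @param receptors Optional receptor metadata (kind `"receptor"`).
#' @param odors Optional odorant metadata (kind `"odor"`).
#' @return A tibble with columns `receptor_id`, `odor_id`,
#'   `reported_log_ec50` and, when metadata is supplied, `odor_name` and
#'   `gene_label`.
#' @export
ec50_table <- function(calls, receptors = NULL, odors = NULL) {
  out <- calls[calls$is_agonist %in% TRUE,
               c("receptor_id", "odor_id", "reported_log_ec50")]
  out <- as_tibble(out)
  if (!is.null(odors)) {
    out <- left_join(out, odors[, c("odor_id", "odor_name")], by = "odor_id")
  }
  if (!is.null(receptors)) {
    out <- left_join(out, receptors[, c("receptor_id", "gene_label")],
                     by = "receptor_id")
  }
  out
}
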