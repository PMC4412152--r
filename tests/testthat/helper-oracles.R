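# Independent brute-force oracles, kept deliberately naive so they share
# no code path with the implementation they check.

# one-way ANOVA straight from the definitional sums of squares
oracle_anova_f <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# AUC by exhaustive positive-negative pair comparison (Mann-Whitney U)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# exhaustive hit selector: order all pairs by the documented tie-break
# key, then walk down the list applying budget and per-receptor cap
oracle_select <- function(deltas, fraction, cap) {
  ord <- order(-deltas$delta, deltas$receptor_id, deltas$odor_id)
  budget <- floor(fraction * nrow(deltas))
  taken_per_receptor <- integer(0)
  selected <- logical(nrow(deltas))
  for (pos in seq_along(ord)) {
    if (pos > budget) break
    i <- ord[pos]
    r <- deltas$receptor_id[i]
    cnt <- if (r %in% names(taken_per_receptor)) taken_per_receptor[[r]] else 0L
    # cap counts the receptor's rank among its own pairs, selected or not
    taken_per_receptor[[r]] <- cnt + 1L
    if (cnt + 1L <= cap) selected[i] <- TRUE
  }
  selected
}

# tiny deterministic dose ladder used across dose-response tests
dose_ladder <- function() c(-12, seq(-8, -2, by = 0.5))

# triplicate noiseless sigmoid points
sigmoid_points <- function(bottom, top, log_ec50, hill = 1,
                           x = dose_ladder(), reps = 3, sigma = 0,
                           seed = NULL) {
  xx <- rep(x, each = reps)
  y <- predict_sigmoid(xx, bottom, top, log_ec50, hill)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), 0, sigma)
  }
  data.frame(x = xx, y = y)
}
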