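#' Confusion counts and the six classification metrics
#'
#' Tallies TP/TN/FP/FN with 1 = malignant (positive) and computes accuracy,
#' precision (positive predictive value), specificity, sensitivity
#' (recall), F1 score, and the Matthews correlation coefficient:
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Any metric whose denominator is zero is reported as 0 and its name is
#' listed in `flags` (the usual MCC convention, applied uniformly).
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return Object of class `"metrics_report"`: list with `counts`
#'   (`TP`, `TN`, `FP`, `FN`), `metrics` (named numeric vector `ACC`,
#'   `PPV`, `SPC`, `SEN`, `F1`, `MCC`), and `flags` (character vector of
#'   zero-denominator metrics).
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be non-empty and of equal length")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  TP <- sum(y_true == 1 & y_pred == 1)
  TN <- sum(y_true == 0 & y_pred == 0)
  FP <- sum(y_true == 0 & y_pred == 1)
  FN <- sum(y_true == 1 & y_pred == 0)
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  ACC <- safe(TP + TN, TP + TN + FP + FN, "ACC")
  PPV <- safe(TP, TP + FP, "PPV")
  SPC <- safe(TN, TN + FP, "SPC")
  SEN <- safe(TP, TP + FN, "SEN")
  F1 <- safe(2 * PPV * SEN, PPV + SEN, "F1")
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  MCC <- if (mcc_den == 0) { flags <- c(flags, "MCC"); 0 } else {
    (TP * TN - FP * FN) / mcc_den
  }
  structure(
    list(counts = list(TP = TP, TN = TN, FP = FP, FN = FN),
         metrics = c(ACC = ACC, PPV = PPV, SPC = SPC, SEN = SEN,
                     F1 = F1, MCC = MCC),
         flags = flags),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  with(x$counts, cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", TP, TN, FP, FN)))
  print(round(x$metrics, 4))
  if (length(x$flags)) {
    cat("zero-denominator metrics reported as 0:",
        paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

# Exact critical value for the rank sum W1 of the size-n1 sample: the
# largest w with P(W1 <= w | H0) <= a/2 (two-sided test at level a).
ranksum_critical <- function(n1, n2, a) {
  mn <- n1 * (n1 + 1) / 2
  w <- mn:(n1 * n2 + mn)
  p <- stats::pwilcox(w - mn, n1, n2)
  ok <- w[p <= a / 2]
  if (!length(ok)) return(mn - 1)  # nothing rejectable at this level
  max(ok)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Ranks the pooled samples with midranks for ties and computes the rank
#' sums `W1` and `W2` (which always total `(n1+n2)(n1+n2+1)/2`). For sample
#' sizes of at most 20 each, the decision compares `min(W1, W2)` against
#' the exact two-sided critical value of the null rank-sum distribution at
#' level `a`; for larger samples a normal approximation on the standardized
#' rank sum is used. The confidence level is `(1 - a) * 100` percent.
#'
#' @param sample_a,sample_b Non-empty numeric vectors (e.g. per-run
#'   accuracies of two optimizers).
#' @param a Significance level (default 0.05).
#' @return Object of class `"ranksum_result"`: `n1`, `n2`, `W1`, `W2`,
#'   `critical` (NA when the normal approximation is used), `decision`
#'   (`"reject"` or `"accept"`), `confidence_level`, and `a`.
#' @export
#' @examples
#' rank_sum_test(1:5, 6:10)  # maximal separation: W1 = 15, W2 = 40
rank_sum_test <- function(sample_a, sample_b, a = 0.05) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  stopifnot(a > 0, a < 1)
  r <- rank(c(sample_a, sample_b))  # midranks for ties
  W1 <- sum(r[seq_len(n1)])
  W2 <- sum(r[n1 + seq_len(n2)])
  if (max(n1, n2) <= 20) {
    nlo <- min(n1, n2)
    nhi <- max(n1, n2)
    Wlo <- if (n1 <= n2) W1 else W2
    critical <- ranksum_critical(nlo, nhi, a)
    # two-sided: the smaller sample's rank sum in either symmetric tail
    reject <- Wlo <= critical || Wlo >= nlo * (n1 + n2 + 1) - critical
  } else {
    mu <- n1 * (n1 + n2 + 1) / 2
    sd <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    z <- (W1 - mu) / sd
    critical <- NA_real_
    reject <- abs(z) > stats::qnorm(1 - a / 2)
  }
  structure(
    list(n1 = n1, n2 = n2, W1 = W1, W2 = W2, critical = critical,
         decision = if (reject) "reject" else "accept",
         confidence_level = (1 - a) * 100, a = a),
    class = "ranksum_result"
  )
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: n1=%d n2=%d W1=%g W2=%g -> %s (CL %.0f%%)\n",
              x$n1, x$n2, x$W1, x$W2, x$decision, x$confidence_level))
  invisible(x)
}

#' Summarize repeated-run metrics
#'
#' Aggregates a set of per-run metric records into the usual repeated-run
#' table: mean, best, worst, and sample standard deviation (n - 1
#' denominator) per metric, plus the mean wall time when provided. A single
#' run reports a standard deviation of 0 with `degenerate = TRUE`.
#'
#' @param per_run Data frame (or list of named vectors) with one row per
#'   run and one column per metric; an optional `time` column is averaged
#'   separately.
#' @return List with `summary` (data frame: metric, mean, best, worst, sd),
#'   `mean_time` (NA if absent), `runs`, and `degenerate`.
#' @export
#' @examples
#' summarize_runs(data.frame(ACC = c(0.8, 0.9)))
summarize_runs <- function(per_run) {
  if (!is.data.frame(per_run)) {
    per_run <- as.data.frame(do.call(rbind, per_run))
  }
  if (nrow(per_run) < 1) stop("at least one run is required")
  time <- if ("time" %in% names(per_run)) per_run$time else NULL
  metrics <- per_run[setdiff(names(per_run), "time")]
  single <- nrow(metrics) == 1
  s <- data.frame(
    metric = names(metrics),
    mean = vapply(metrics, mean, numeric(1)),
    best = vapply(metrics, max, numeric(1)),
    worst = vapply(metrics, min, numeric(1)),
    sd = if (single) 0 else vapply(metrics, stats::sd, numeric(1)),
    row.names = NULL
  )
  list(summary = s,
       mean_time = if (is.null(time)) NA_real_ else mean(time),
       runs = nrow(metrics), degenerate = single)
}
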