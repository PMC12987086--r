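# Sample extraction, class separability and accuracy metrics.

#' Extract per-class index samples at reference points
#'
#' One value per point; points falling on invalid pixels are dropped with a
#' report. Duplicate locations are retained (each point is one sample).
#'
#' @param index a [index_map()].
#' @param points a [read_reference_points()] data frame (or any data frame
#'   with `row`, `col`, `class`, `year`).
#' @return a data frame of class `pki_class_samples` with columns `class`,
#'   `year`, `value`; the index name is kept in `attr(x, "index_name")` and
#'   the number of dropped points in `attr(x, "n_dropped")`.
#' @export
extract_samples <- function(index, points) {
  if (!inherits(index, "pki_index_map")) stop("`index` must be a pki_index_map")
  if (!all(c("row", "col", "class") %in% names(points)))
    stop("`points` needs row, col and class columns")
  d <- dim(index)
  if (any(points$row < 1 | points$row > d[1] |
          points$col < 1 | points$col > d[2]))
    stop("reference point outside the index grid")
  idx <- cbind(points$row, points$col)
  ok <- index$valid_mask[idx]
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message("extract_samples: dropped ", n_drop,
            " point(s) on invalid pixels")
  if (!any(ok)) stop("no reference point resolves to a valid pixel")
  out <- data.frame(class = points$class[ok],
                    year = if ("year" %in% names(points))
                      points$year[ok] else NA_integer_,
                    value = index$values[idx][ok])
  attr(out, "index_name") <- index$index_name
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("pki_class_samples", "data.frame")
  out
}

#' Class separability (M-statistic)
#'
#' `M = |mean(a) - mean(b)| / (sd(a) + sd(b))` with sample (n-1) standard
#' deviations. `M > 1` is conventionally read as good separability between the
#' two class distributions. If both spreads are zero the statistic is 0 for
#' equal means and flagged infinite otherwise.
#'
#' @param a,b numeric vectors of index values for the two classes (each with
#'   at least 2 values).
#' @param class_pair optional length-2 character label, e.g. `c("PK", "OV")`.
#' @return an object of class `pki_separability`: `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `m_value`, `good_separability`, `infinite`.
#' @examples
#' m_statistic(c(2.5, 3, 3.5), c(0.5, 1, 1.5))$m_value  # 2 when sds are 0.5
#' @export
m_statistic <- function(a, b, class_pair = c("a", "b")) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample collection needs at least 2 values")
  mu1 <- mean(a); mu2 <- mean(b)
  s1 <- sd(a); s2 <- sd(b)
  infinite <- FALSE
  if (s1 + s2 == 0) {
    if (mu1 == mu2) m <- 0 else { m <- Inf; infinite <- TRUE }
  } else m <- abs(mu1 - mu2) / (s1 + s2)
  structure(list(class_pair = class_pair, mu1 = mu1, mu2 = mu2,
                 sigma1 = s1, sigma2 = s2, m_value = m,
                 good_separability = is.finite(m) && m > 1.0,
                 infinite = infinite),
            class = "pki_separability")
}

#' @export
print.pki_separability <- function(x, ...) {
  cat(sprintf("<pki_separability> %s vs %s: M = %.4g%s\n", x$class_pair[1],
              x$class_pair[2], x$m_value,
              if (x$good_separability) " (good, M > 1)" else ""))
  invisible(x)
}

as_logical_pred <- function(x, positive = "PK") {
  if (inherits(x, "pki_binary_map")) as.vector(x$presence)
  else if (is.logical(x)) x
  else x == positive
}

#' Binary classification metrics against a reference
#'
#' The target class (PK) is positive; everything else (OV, NV) is negative.
#' Reports the confusion counts plus accuracy, precision, recall, F1 and
#' Cohen's kappa (chance agreement from the marginal products). Undefined
#' ratios (zero denominators) are returned as `NA` with a warning.
#'
#' @param pred predictions: a [binary_map()], logical vector, or label vector.
#' @param truth reference: logical vector or label vector (positive = `PK`),
#'   or a [binary_map()].
#' @param positive label treated as positive when labels are supplied.
#' @return an object of class `pki_confusion`: `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `precision`, `recall`, `f1`, `kappa`.
#' @examples
#' p <- rep(c(TRUE, FALSE), c(10, 10))
#' t <- rep(c(TRUE, FALSE, TRUE, FALSE), c(9, 1, 1, 9))
#' confusion_metrics(p, t)$kappa  # 0.8
#' @export
confusion_metrics <- function(pred, truth, positive = "PK") {
  p <- as_logical_pred(pred, positive)
  t <- as_logical_pred(truth, positive)
  if (length(p) != length(t)) stop("`pred` and `truth` lengths differ")
  if (length(p) == 0) stop("empty input")
  keep <- !is.na(p) & !is.na(t)
  p <- p[keep]; t <- t[keep]
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  n <- tp + fp + fn + tn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning NA")
      NA_real_
    } else num / den
  }
  acc <- (tp + tn) / n
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    if (!is.na(prec) && !is.na(rec))
      warning("F1 undefined (precision + recall = 0); returning NA")
    NA_real_
  } else 2 * prec * rec / (prec + rec)
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) {
    if (acc == 1) 1 else NA_real_
  } else (acc - pe) / (1 - pe)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, accuracy = acc,
                 precision = prec, recall = rec, f1 = f1, kappa = kappa),
            class = "pki_confusion")
}

#' @export
print.pki_confusion <- function(x, ...) {
  cat(sprintf("<pki_confusion> tp %d fp %d fn %d tn %d\n", x$tp, x$fp, x$fn,
              x$tn))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  kappa %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$kappa))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Case-resamples the paired prediction/reference vector `n_boot` times and
#' returns the percentile interval of the chosen metric. Replicates where the
#' metric is undefined (e.g. a resample with no positive reference cases for
#' recall) are skipped and counted.
#'
#' @param pred,truth paired predictions and reference (as in
#'   [confusion_metrics()]).
#' @param metric one of `"accuracy"`, `"precision"`, `"recall"`, `"f1"`,
#'   `"kappa"`.
#' @param n_boot number of resamples (>= 100), default 1000.
#' @param level confidence level, default 0.95.
#' @param seed integer seed; required so intervals are reproducible.
#' @param positive positive-class label for label inputs.
#' @return list with `estimate`, `ci_low`, `ci_high`, `n_boot_used`,
#'   `n_skipped`.
#' @export
bootstrap_ci <- function(pred, truth, metric = "accuracy", n_boot = 1000,
                         level = 0.95, seed, positive = "PK") {
  metric <- match.arg(metric, c("accuracy", "precision", "recall", "f1",
                                "kappa"))
  if (n_boot < 100) stop("`n_boot` must be >= 100")
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  p <- as_logical_pred(pred, positive)
  t <- as_logical_pred(truth, positive)
  if (length(p) != length(t) || length(p) == 0)
    stop("`pred` and `truth` must be non-empty paired vectors")
  est <- suppressWarnings(confusion_metrics(p, t)[[metric]])
  n <- length(p)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    suppressWarnings(confusion_metrics(p[j], t[j])[[metric]])
  }, numeric(1))
  skipped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  if (!length(reps)) stop("all bootstrap replicates were degenerate")
  alpha <- (1 - level) / 2
  ci <- quantile(reps, c(alpha, 1 - alpha), type = 7, names = FALSE)
  list(metric = metric, estimate = est, ci_low = ci[1], ci_high = ci[2],
       level = level, n_boot_used = length(reps), n_skipped = skipped)
}

#' Per-class and pooled validation report
#'
#' Convenience wrapper producing, for one index map, the M-statistics of PK
#' against OV and NV and (given a binary map) the confusion metrics, split by
#' year and pooled ("all years" uses the pooled sample set, not the mean of
#' yearly values).
#'
#' @param samples a [extract_samples()] result.
#' @param pred optional [binary_map()] evaluated at the same points.
#' @param points the reference points matching `samples` (needed with `pred`).
#' @return list with `m_pk_ov`, `m_pk_nv` and optionally `metrics`.
#' @export
validation_report <- function(samples, pred = NULL, points = NULL) {
  pk <- samples$value[samples$class == "PK"]
  ov <- samples$value[samples$class == "OV"]
  nv <- samples$value[samples$class == "NV"]
  out <- list()
  if (length(pk) >= 2 && length(ov) >= 2)
    out$m_pk_ov <- m_statistic(pk, ov, c("PK", "OV"))
  if (length(pk) >= 2 && length(nv) >= 2)
    out$m_pk_nv <- m_statistic(pk, nv, c("PK", "NV"))
  if (!is.null(pred)) {
    if (is.null(points)) stop("`points` is required with `pred`")
    p <- pred$presence[cbind(points$row, points$col)]
    out$metrics <- confusion_metrics(p, points$class == "PK")
  }
  out
}
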