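# Dice / MAE evaluation and comparison reports.

image_values <- function(x) {
  if (inherits(x, "eit_image")) x$grid else as.array(x)
}

#' Dice similarity coefficient between two images
#'
#' Both images are binarized at `threshold` to form masks A (prediction) and
#' B (target); the score is `2|A n B| / (|A| + |B|)`, ranging from 0 (no
#' overlap) to 1 (identical masks).  When both masks are empty the score is
#' defined as 1; when exactly one is empty it is 0.
#'
#' @param pred,target `eit_image`s or numeric matrices of identical shape.
#' @param threshold Binarization threshold in (0, 1), default 0.5, applied
#'   to both images.
#' @return Dice coefficient in \[0, 1\].
#' @examples
#' a <- matrix(0, 3, 3); a[1:4] <- 1
#' b <- matrix(0, 3, 3); b[3:4] <- 1
#' dice(a, b)  # 2*2 / (4+2)
#' @export
dice <- function(pred, target, threshold = 0.5) {
  p <- image_values(pred); t <- image_values(target)
  if (!all(dim(p) == dim(t))) stop("image shapes differ")
  A <- p > threshold; B <- t > threshold
  denom <- sum(A) + sum(B)
  if (denom == 0) return(1)
  2 * sum(A & B) / denom
}

#' Mean absolute error between two images
#'
#' Mean of `|pred - target|` over all N pixels of the grid (inside and
#' outside the disk mask alike; both are zero outside).  On the normalized
#' \[0, 1\] intensity scale this is reported as a percentage by multiplying
#' by 100.
#'
#' @inheritParams dice
#' @return Non-negative mean absolute difference.
#' @export
mae <- function(pred, target) {
  p <- image_values(pred); t <- image_values(target)
  if (!all(dim(p) == dim(t))) stop("image shapes differ")
  mean(abs(p - t))
}

#' Evaluate a trained model on the held-out test split
#'
#' Computes the per-organ mean Dice (as a percentage) and mean MAE (as a
#' percentage of the normalized intensity scale) over all test triplets.
#'
#' @param fit An `eitsep_fit` (semi-Siamese or dual baseline).
#' @param dataset The normalized `eit_dataset` the fit was trained on.
#' @param split The `eit_split` (defaults to the dataset's stored split).
#' @param threshold Dice binarization threshold (default 0.5).
#' @param model_label Label used in comparison reports.
#' @return A tibble of class `eitsep_metrics` with one row per organ:
#'   `model`, `organ`, `dice_percent`, `mae_percent`, `n_test`.
#' @export
evaluate_model <- function(fit, dataset, split = dataset$split,
                           threshold = 0.5, model_label = NULL) {
  idx <- split$test
  if (!length(idx)) stop("empty test split")
  x <- split_matrix(dataset, "mixed", idx)
  targets <- list(lung = split_matrix(dataset, "lung", idx),
                  heart = split_matrix(dataset, "heart", idx))
  preds <- stats::predict(fit, x)
  if (is.null(model_label)) {
    model_label <- if (inherits(fit, "eitsep_dual_fit")) "dual_unet" else
      fit$model$architecture
  }
  rows <- lapply(c("lung", "heart"), function(organ) {
    p <- preds[[organ]]; tg <- targets[[organ]]
    d <- vapply(seq_len(nrow(p)), function(i)
      dice(matrix(p[i, ], 1), matrix(tg[i, ], 1), threshold), 1)
    m <- vapply(seq_len(nrow(p)), function(i)
      mae(matrix(p[i, ], 1), matrix(tg[i, ], 1)), 1)
    tibble::tibble(model = model_label, organ = organ,
                   dice_percent = 100 * mean(d), mae_percent = 100 * mean(m),
                   n_test = length(idx))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eitsep_metrics", class(out))
  out
}

#' Comparison report against a baseline
#'
#' Mirrors the standard comparison-table layout: per organ and metric, the
#' model value, the baseline value and the relative improvement in
#' percentage points.  The sign convention makes positive always better:
#' `model - baseline` for Dice and `baseline - model` for MAE.
#'
#' @param report Metrics tibble of the proposed model
#'   (from [evaluate_model()]).
#' @param baseline Metrics tibble of the baseline model.
#' @return A tibble with `metric`, `organ`, the two model values and
#'   `improvement`; printed as an aligned text table by
#'   [format_report()].
#' @export
render_report <- function(report, baseline) {
  stopifnot(inherits(report, "eitsep_metrics"),
            inherits(baseline, "eitsep_metrics"))
  if (!setequal(report$organ, baseline$organ)) {
    stop("reports cover different organs")
  }
  rows <- list()
  for (metric in c("dice_percent", "mae_percent")) {
    for (org in c("heart", "lung")) {
      mv <- report[[metric]][report$organ == org]
      bv <- baseline[[metric]][baseline$organ == org]
      imp <- if (metric == "dice_percent") mv - bv else bv - mv
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = if (metric == "dice_percent") "DICE (%)" else "MAE (%)",
        organ = org, model = round(mv, 2), baseline = round(bv, 2),
        improvement = round(imp, 2))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model_label") <- report$model[1]
  attr(out, "baseline_label") <- baseline$model[1]
  class(out) <- c("eitsep_report", class(out))
  out
}

#' Format a comparison report as a Markdown table
#'
#' @param report An `eitsep_report` from [render_report()].
#' @return Character vector of Markdown lines.
#' @export
format_report <- function(report) {
  hdr <- sprintf("| Metric | Organ | %s | %s | Relative improvement |",
                 attr(report, "model_label"), attr(report, "baseline_label"))
  sep <- "|---|---|---|---|---|"
  body <- sprintf("| %s | %s | %.2f | %.2f | %.2f |", report$metric,
                  report$organ, report$model, report$baseline,
                  report$improvement)
  c(hdr, sep, body)
}

#' @export
print.eitsep_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
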