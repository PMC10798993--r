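#' Confusion matrix between a predicted and a reference class map
#'
#' Rows index the predicted (map) class, columns the reference (truth) class.
#' Pixels whose reference label equals `ignore_label` are excluded, as are
#' pixels carrying the no-data code in the prediction when `ignore_pred`
#' is supplied.
#'
#' @param pred,truth Integer matrices (or vectors) of equal shape with class
#'   codes in `0..n_classes-1`.
#' @param n_classes Number of classes K.
#' @param ignore_label Reference code to exclude (default -1, the unlabeled
#'   code).
#' @param ignore_pred Optional predicted code to exclude (e.g. 255 for
#'   non-loss no-data pixels).
#' @return A K x K integer matrix of class `lufor_confusion` with map classes
#'   in rows and reference classes in columns.
#' @export
confusion <- function(pred, truth, n_classes, ignore_label = -1L, ignore_pred = NULL) {
  if (length(pred) != length(truth)) stop("pred and truth must have the same shape", call. = FALSE)
  p <- as.integer(pred)
  t <- as.integer(truth)
  keep <- t != ignore_label
  if (!is.null(ignore_pred)) keep <- keep & p != as.integer(ignore_pred)
  p <- p[keep]
  t <- t[keep]
  if (length(p) > 0 && (min(p) < 0 || max(p) >= n_classes || min(t) < 0 || max(t) >= n_classes)) {
    stop("class codes outside 0..K-1 after exclusions", call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  if (length(p) > 0) {
    tab <- table(factor(p, levels = 0:(n_classes - 1)), factor(t, levels = 0:(n_classes - 1)))
    cm <- matrix(as.integer(tab), n_classes, n_classes)
  }
  dimnames(cm) <- list(map = 0:(n_classes - 1), reference = 0:(n_classes - 1))
  class(cm) <- c("lufor_confusion", class(cm))
  cm
}

#' Per-class and averaged F1 scores from a confusion matrix
#'
#' Per-class F1 is `2PR/(P+R)` with precision P = diagonal / row sum and
#' recall R = diagonal / column sum; classes with `P + R = 0` score 0 and are
#' flagged in the `degenerate` column. The macro F1 is the unweighted mean of
#' per-class F1 (equal class importance); the micro F1 pools counts over all
#' classes (equal pixel importance) and for single-label data equals overall
#' accuracy.
#'
#' @param cm A confusion matrix from [confusion()].
#' @return A list with `per_class` (tibble: class, precision, recall, f1,
#'   degenerate), `macro_f1`, `micro_f1`.
#' @export
f1_scores <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  tp <- diag(cm)
  rowt <- rowSums(cm)
  colt <- colSums(cm)
  precision <- ifelse(rowt > 0, tp / rowt, 0)
  recall <- ifelse(colt > 0, tp / colt, 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  per_class <- tibble::tibble(
    class = 0:(k - 1),
    precision = unname(precision),
    recall = unname(recall),
    f1 = unname(f1),
    degenerate = unname(pr == 0)
  )
  micro <- sum(tp) / total # pooled precision == pooled recall for single-label maps
  list(per_class = per_class, macro_f1 = mean(f1), micro_f1 = micro)
}

#' User's and producer's accuracy per class
#'
#' User's accuracy of a map class is the fraction of pixels mapped as that
#' class that the reference confirms (precision); producer's accuracy is the
#' fraction of reference pixels of the class that the map captures (recall).
#' Classes absent from both margins get 0 and are flagged.
#'
#' @inheritParams f1_scores
#' @return A tibble with columns class, users, producers, degenerate.
#' @export
users_producers <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  rowt <- rowSums(cm)
  colt <- colSums(cm)
  tibble::tibble(
    class = 0:(nrow(cm) - 1),
    users = unname(ifelse(rowt > 0, tp / rowt, 0)),
    producers = unname(ifelse(colt > 0, tp / colt, 0)),
    degenerate = unname(rowt == 0 & colt == 0)
  )
}

#' Tidy metric table for a confusion matrix
#'
#' One row per class with precision, recall, F1, user's and producer's
#' accuracy, plus `macro` / `micro` summary rows, ready to write as CSV.
#'
#' @param x A `lufor_confusion` matrix.
#' @param ... Unused.
#' @export
tidy.lufor_confusion <- function(x, ...) {
  f <- f1_scores(x)
  up <- users_producers(x)
  per <- dplyr::left_join(f$per_class, up[, c("class", "users", "producers")], by = "class")
  per$class <- as.character(per$class)
  summary_rows <- tibble::tibble(
    class = c("macro", "micro"),
    precision = NA_real_, recall = NA_real_,
    f1 = c(f$macro_f1, f$micro_f1),
    degenerate = FALSE, users = NA_real_, producers = NA_real_
  )
  dplyr::bind_rows(per, summary_rows)
}

#' @export
glance.lufor_confusion <- function(x, ...) {
  f <- f1_scores(x)
  tibble::tibble(
    n_pixels = sum(unclass(x)),
    accuracy = f$micro_f1,
    macro_f1 = f$macro_f1,
    micro_f1 = f$micro_f1
  )
}
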