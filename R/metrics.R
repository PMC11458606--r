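#' Segmentation and classification metrics
#'
#' Overlap metrics between predicted and ground-truth label masks (Dice
#' similarity coefficient and intersection-over-union), confusion-count
#' metrics (recall, precision, accuracy), a threshold-sweep ROC curve
#' with trapezoidal AUC, and per-structure aggregation with half-up
#' rounding for reporting.
#'
#' Conventions for degenerate inputs: two empty masks score 1 (perfect
#' agreement on absence), one empty mask scores 0; zero-denominator
#' confusion metrics return `NA` with a warning.
#'
#' @name eval_metrics
NULL

check_mask_pair <- function(pred, truth) {
  if (!is.matrix(pred) || !is.matrix(truth))
    stop_ganb("masks must be matrices")
  if (!all(dim(pred) == dim(truth)))
    stop_ganb("mask shapes differ: ", paste(dim(pred), collapse = "x"),
              " vs ", paste(dim(truth), collapse = "x"))
}

#' Dice similarity coefficient for one class
#'
#' `DSC = 2|X n Y| / (|X| + |Y|)` where X and Y are the predicted and
#' truth pixel sets of `class_id`. 1 means complete overlap, 0 none.
#'
#' @param pred,truth integer label masks of equal shape.
#' @param class_id the label under evaluation (default 1).
#' @return A scalar in `[0, 1]`.
#' @export
dice <- function(pred, truth, class_id = 1) {
  check_mask_pair(pred, truth)
  X <- pred == class_id
  Y <- truth == class_id
  if (!any(X) && !any(Y)) {
    message("class ", class_id, " absent from both masks; Dice = 1")
    return(1)
  }
  2 * sum(X & Y) / (sum(X) + sum(Y))
}

#' Intersection over union for one class
#'
#' `IoU = |X n Y| / |X u Y|`.
#'
#' @inheritParams dice
#' @return A scalar in `[0, 1]`.
#' @export
iou <- function(pred, truth, class_id = 1) {
  check_mask_pair(pred, truth)
  X <- pred == class_id
  Y <- truth == class_id
  if (!any(X) && !any(Y)) {
    message("class ", class_id, " absent from both masks; IoU = 1")
    return(1)
  }
  sum(X & Y) / sum(X | Y)
}

#' Mean IoU over the classes present in the truth mask
#'
#' Unweighted mean of per-class IoU; classes absent from the truth mask
#' are skipped (their IoU would be 0/0 against an empty reference).
#'
#' @inheritParams dice
#' @param classes classes to average over; defaults to every label
#'   present in `truth`.
#' @return A scalar in `[0, 1]`.
#' @export
mean_iou <- function(pred, truth, classes = NULL) {
  check_mask_pair(pred, truth)
  if (is.null(classes)) classes <- sort(unique(as.vector(truth)))
  mean(vapply(classes, function(k) iou(pred, truth, k), numeric(1)))
}

#' Confusion counts for a binary decision
#'
#' @param pred,truth vectors (or masks) of predicted and true labels.
#' @param positive the label counted as positive.
#' @return A list with fields `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, truth, positive = "high") {
  if (length(pred) != length(truth))
    stop_ganb("pred and truth lengths differ")
  p <- pred == positive
  t_ <- truth == positive
  structure(list(TP = sum(p & t_), FP = sum(p & !t_),
                 FN = sum(!p & t_), TN = sum(!p & !t_)),
            class = "confusion_counts")
}

check_counts <- function(counts) {
  v <- unlist(counts[c("TP", "FP", "FN", "TN")])
  if (any(is.na(v)) || any(v < 0))
    stop_ganb("confusion counts must be non-negative")
  v
}

ratio_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    return(NA_real_)
  }
  unname(num / den)
}

#' Recall (sensitivity): TP / (TP + FN)
#' @param counts a `confusion_counts` list (fields `TP`, `FP`, `FN`,
#'   `TN`).
#' @return A scalar in `[0, 1]`, or `NA` with a warning when no positives
#'   exist.
#' @export
recall <- function(counts) {
  v <- check_counts(counts)
  ratio_or_na(v["TP"], v["TP"] + v["FN"], "recall")
}

#' Precision (positive predictive value): TP / (TP + FP)
#' @inheritParams recall
#' @return A scalar in `[0, 1]`, or `NA` with a warning when nothing was
#'   predicted positive.
#' @export
precision <- function(counts) {
  v <- check_counts(counts)
  ratio_or_na(v["TP"], v["TP"] + v["FP"], "precision")
}

#' Accuracy: (TP + TN) / total
#' @inheritParams recall
#' @return A scalar in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  v <- check_counts(counts)
  ratio_or_na(v["TP"] + v["TN"], sum(v), "accuracy")
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique score values (ties share a
#' threshold), collects (FPR, TPR) points from (0, 0) to (1, 1), and
#' integrates by the trapezoidal rule. On ties-free scores the AUC equals
#' the concordant-pair fraction (Mann-Whitney statistic).
#'
#' @param scores numeric scores, larger meaning more positive; `Inf` is
#'   allowed (e.g. saturated risk scores).
#' @param labels binary labels aligned with `scores`.
#' @param positive which label counts as positive (default `"high"`; for
#'   0/1 labels pass `positive = 1`).
#' @return A list with `curve` (data frame: threshold, fpr, tpr) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "high") {
  if (length(scores) != length(labels))
    stop_ganb("scores and labels lengths differ")
  if (any(is.na(scores)))
    stop_ganb("scores contain missing values")
  y <- labels == positive
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop_ganb("roc_auc needs at least one sample of each class")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / n_neg, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Aggregate per-structure metric rows
#'
#' Takes one metric row per structure (identical metric names across
#' structures), returns the unweighted arithmetic mean per metric rounded
#' half-up to 2 decimals — the form used for summary reporting. Stored
#' per-structure values are never rounded; only this aggregate is.
#'
#' @param per_structure a data frame with one row per structure and one
#'   numeric column per metric (non-numeric columns such as a structure
#'   name are carried along but not averaged), or a named list of equally
#'   named numeric vectors.
#' @return A named numeric vector of rounded metric means.
#' @export
#' @examples
#' aggregate_metrics(data.frame(dsc = c(0.8, 0.9)))  # dsc = 0.85
aggregate_metrics <- function(per_structure) {
  if (is.data.frame(per_structure)) {
    rows <- lapply(seq_len(nrow(per_structure)), function(i) {
      r <- per_structure[i, sapply(per_structure, is.numeric), drop = FALSE]
      unlist(r)
    })
  } else if (is.list(per_structure)) {
    rows <- lapply(per_structure, unlist)
  } else {
    stop_ganb("per_structure must be a data frame or list of metric rows")
  }
  if (length(rows) == 0) stop_ganb("need at least one structure")
  keys <- names(rows[[1]])
  if (is.null(keys) || any(keys == ""))
    stop_ganb("metric rows must be named")
  for (r in rows) {
    if (!identical(names(r), keys))
      stop_ganb("inconsistent metric keys across structures: [",
                paste(keys, collapse = ", "), "] vs [",
                paste(names(r), collapse = ", "), "]")
  }
  m <- do.call(rbind, rows)
  round_half_up(colMeans(m), 2)
}

#' Bundled reference per-structure segmentation metrics
#'
#' A reference table of published segmentation quality (Dice, IoU,
#' recall, precision) for eleven cardiovascular structures visible in
#' cardiac CT angiography: coronary sinus (CS), descending aorta (DA),
#' inferior vena cava (IVC), left atrial appendage (LAA), left atrial
#' wall (LAW), papillary muscle (PM), posterior mitral leaflet (PML),
#' proximal ascending aorta (PAA), pulmonary aorta (PA), right
#' ventricular wall (RVW) and superior vena cava (SVC). Used as the
#' worked input for [aggregate_metrics()].
#'
#' @return A data frame with columns `structure`, `dsc`, `miou`,
#'   `recall`, `precision`.
#' @export
cardiac_structure_metrics <- function() {
  path <- system.file("extdata", "cardiac_structure_metrics.csv",
                      package = "ganbayes", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
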