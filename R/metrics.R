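#' Match detections to ground-truth boxes
#'
#' PASCAL VOC greedy matching, applied independently per image and class:
#' detections are visited in descending confidence (ties keep input order,
#' which matters for uniform-confidence detectors such as human
#' annotators); each detection claims the unmatched ground-truth box of
#' its class with the highest IoU at or above `iou_threshold` (a true
#' positive), otherwise it is a false positive. Ground-truth boxes left
#' unclaimed are false negatives.
#'
#' @param detections Data frame with `image_id`, corner columns, `label`,
#'   `confidence`.
#' @param ground_truth Data frame with `image_id`, corner columns, `label`.
#' @param iou_threshold Match threshold in (0, 1].
#' @return A `match_result` list: `det`, a tibble of the detections in
#'   input order with a logical `tp` flag; `gt_counts`, ground-truth box
#'   counts per image and class; `iou_threshold`; `image_ids`, the union
#'   of image ids seen in either input.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.3) {
  if (iou_threshold <= 0 || iou_threshold > 1) {
    abort("`iou_threshold` must be in (0, 1].")
  }
  det <- as.data.frame(detections, stringsAsFactors = FALSE)
  gt <- as.data.frame(ground_truth, stringsAsFactors = FALSE)
  if (nrow(det) > 0) validate_boxes(det, "detection")
  if (nrow(gt) > 0) validate_boxes(gt, "ground-truth")
  for (col in c("image_id", "label")) {
    if (nrow(det) > 0 && !col %in% names(det)) {
      abort(sprintf("`detections` needs a `%s` column.", col))
    }
    if (nrow(gt) > 0 && !col %in% names(gt)) {
      abort(sprintf("`ground_truth` needs a `%s` column.", col))
    }
  }
  if (nrow(det) > 0 && !"confidence" %in% names(det)) {
    abort("`detections` needs a `confidence` column.")
  }

  tp <- logical(nrow(det))
  if (nrow(det) > 0 && nrow(gt) > 0) {
    keys_det <- paste(det$image_id, det$label, sep = "\r")
    keys_gt <- paste(gt$image_id, gt$label, sep = "\r")
    for (key in intersect(unique(keys_det), unique(keys_gt))) {
      d_idx <- which(keys_det == key)
      g_idx <- which(keys_gt == key)
      d_idx <- d_idx[order(-det$confidence[d_idx])] # stable for ties
      iou <- box_iou_matrix(det[d_idx, , drop = FALSE], gt[g_idx, , drop = FALSE])
      taken <- logical(length(g_idx))
      for (r in seq_along(d_idx)) {
        cand <- which(!taken & iou[r, ] >= iou_threshold)
        if (length(cand) > 0) {
          best <- cand[which.max(iou[r, cand])]
          taken[best] <- TRUE
          tp[d_idx[r]] <- TRUE
        }
      }
    }
  }

  det_out <- tibble::tibble(
    image_id = if (nrow(det) > 0) det$image_id else character(),
    label = if (nrow(det) > 0) det$label else character(),
    confidence = if (nrow(det) > 0) det$confidence else numeric(),
    tp = tp
  )
  gt_counts <- if (nrow(gt) > 0) {
    gt |>
      dplyr::count(.data$image_id, .data$label, name = "n_gt") |>
      tibble::as_tibble()
  } else {
    tibble::tibble(image_id = character(), label = character(), n_gt = integer())
  }
  structure(
    list(
      det = det_out,
      gt_counts = gt_counts,
      iou_threshold = iou_threshold,
      image_ids = union(unique(det_out$image_id), unique(gt_counts$image_id))
    ),
    class = "match_result"
  )
}

#' Precision-recall curve for one class
#'
#' Sweeps the matched detections in descending confidence and accumulates
#' precision and recall at every rank.
#'
#' @param tp Logical vector of match flags, one per detection.
#' @param confidence Numeric confidences, same length.
#' @param n_gt Number of ground-truth boxes of the class (positive).
#' @return Tibble with `rank`, `confidence`, `recall`, `precision`.
#' @export
pr_curve <- function(tp, confidence, n_gt) {
  if (length(tp) != length(confidence)) {
    abort("`tp` and `confidence` must have equal length.")
  }
  if (n_gt <= 0) abort("`n_gt` must be positive for a PR curve.")
  ord <- order(-confidence)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  tibble::tibble(
    rank = seq_along(tp),
    confidence = confidence[ord],
    recall = cum_tp / n_gt,
    precision = cum_tp / (cum_tp + cum_fp)
  )
}

#' All-point interpolated average precision
#'
#' PASCAL VOC "every point" AP: the precision envelope is made
#' non-increasing from right to left and integrated over recall. This uses
#' all operating points of the curve rather than the 11-point
#' interpolation.
#'
#' @inheritParams pr_curve
#' @return AP in \[0, 1\]; `NA` when `n_gt` is 0 (undefined).
#' @examples
#' average_precision(tp = c(TRUE, FALSE, TRUE), confidence = c(.9, .8, .7), n_gt = 2)
#' @export
average_precision <- function(tp, confidence, n_gt) {
  if (n_gt == 0) {
    return(NA_real_)
  }
  if (length(tp) == 0) {
    return(0)
  }
  ord <- order(-confidence)
  ap_from_flags(tp[ord], n_gt)
}

# AP from flags already in rank order; the hot path shared with the
# bootstrap. Envelope + rectangle integration over recall increments.
ap_from_flags <- function(tp, n_gt) {
  cum_tp <- cumsum(tp)
  rec <- cum_tp / n_gt
  prec <- cum_tp / seq_along(tp)
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' F1-score and false negative rate from match counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)` and `FNR = FN / (FN + TP)`, computed at
#' the operating point that includes every detection (no confidence cut),
#' which keeps scoreless detectors such as human annotators comparable to
#' models. Degenerate cases: with no detections and no ground truth F1 is
#' 0 (with a warning); with no ground truth FNR is undefined (`NA`).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Tibble with columns `f1`, `fnr`.
#' @examples
#' f1_fnr(tp = 3, fp = 1, fn = 2) # f1 = 2/3, fnr = 0.4
#' @export
f1_fnr <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom > 0, 2 * tp / denom, 0)
  if (any(denom == 0)) {
    warn("F1 undefined (no detections and no ground truth); reported as 0.")
  }
  fnr <- ifelse(tp + fn > 0, fn / (fn + tp), NA_real_)
  tibble::tibble(f1 = f1, fnr = fnr)
}

#' Evaluate detections against ground truth
#'
#' The full evaluation protocol: detections are matched to ground truth
#' per image at `iou_threshold` ([match_detections()]), matches are pooled
#' across images per class, and per-class all-point AP, F1 and FNR are
#' computed together with their unweighted means over `classes` (mAP, mF1,
#' mFNR). Classes without any ground-truth box are excluded from the means
#' and reported as `NA` (a message says so).
#'
#' @inheritParams match_detections
#' @param classes Classes to evaluate; the means average over these.
#' @return A `detection_eval` object; see [tidy.detection_eval()] for the
#'   per-class table and [glance.detection_eval()] for the means.
#' @examples
#' gt <- tibble::tibble(
#'   image_id = "a", xmin = 0, ymin = 0, xmax = 10, ymax = 10, label = "enamel"
#' )
#' det <- dplyr::mutate(gt, confidence = 0.9)
#' evaluate_detections(det, gt)
#' @export
evaluate_detections <- function(detections, ground_truth,
                                classes = caries_classes(),
                                iou_threshold = 0.3) {
  match <- match_detections(detections, ground_truth, iou_threshold)
  per_class <- eval_match(match, classes)
  absent <- per_class$class[per_class$n_gt == 0]
  if (length(absent) > 0) {
    inform(sprintf(
      "Class(es) with no ground truth excluded from the means: %s.",
      paste(absent, collapse = ", ")
    ))
  }
  structure(
    list(
      per_class = per_class,
      means = class_means(per_class),
      iou_threshold = iou_threshold,
      n_images = length(match$image_ids),
      match = match
    ),
    class = "detection_eval"
  )
}

# Per-class metric table from a match_result, optionally restricted to a
# multiset of image ids (with repetition; used by the bootstrap).
eval_match <- function(match, classes, image_multiset = NULL) {
  det <- match$det
  gtc <- match$gt_counts
  if (!is.null(image_multiset)) {
    det_rows <- split(seq_len(nrow(det)), det$image_id)
    gt_rows <- split(seq_len(nrow(gtc)), gtc$image_id)
    det <- det[unlist(det_rows[as.character(image_multiset)], use.names = FALSE), , drop = FALSE]
    gtc <- gtc[unlist(gt_rows[as.character(image_multiset)], use.names = FALSE), , drop = FALSE]
  }
  res <- lapply(classes, function(cl) {
    d <- det[det$label == cl, , drop = FALSE]
    n_gt <- sum(gtc$n_gt[gtc$label == cl])
    tp <- sum(d$tp)
    fp <- nrow(d) - tp
    fn <- n_gt - tp
    ap <- if (n_gt == 0) {
      NA_real_
    } else if (nrow(d) == 0) {
      0
    } else {
      ap_from_flags(d$tp[order(-d$confidence)], n_gt)
    }
    denom <- 2 * tp + fp + fn
    tibble::tibble(
      class = cl, n_gt = n_gt, n_det = nrow(d),
      tp = tp, fp = fp, fn = fn,
      ap = ap,
      f1 = if (denom > 0) 2 * tp / denom else 0,
      fnr = if (n_gt > 0) fn / (fn + tp) else NA_real_
    )
  })
  dplyr::bind_rows(res)
}

class_means <- function(per_class) {
  with_gt <- per_class[per_class$n_gt > 0, , drop = FALSE]
  tibble::tibble(
    map = mean(with_gt$ap),
    mf1 = mean(with_gt$f1),
    mfnr = mean(with_gt$fnr)
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    "Detection evaluation (IoU >= %.2f, %d image%s)\n",
    x$iou_threshold, x$n_images, if (x$n_images == 1) "" else "s"
  ))
  print(x$per_class |> dplyr::select("class", "n_gt", "n_det", "ap", "f1", "fnr"))
  cat(sprintf(
    "mAP = %.4f  mF1 = %.4f  mFNR = %.4f\n",
    x$means$map, x$means$mf1, x$means$mfnr
  ))
  invisible(x)
}

#' Tidy a detection evaluation
#'
#' @param x A `detection_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return One row per class: counts, AP, F1, FNR.
#' @method tidy detection_eval
#' @export
tidy.detection_eval <- function(x, ...) {
  x$per_class
}

#' One-row summary of a detection evaluation
#'
#' @param x A `detection_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return One row with `map`, `mf1`, `mfnr`, `iou_threshold`, `n_images`.
#' @method glance detection_eval
#' @export
glance.detection_eval <- function(x, ...) {
  dplyr::bind_cols(
    x$means,
    tibble::tibble(iou_threshold = x$iou_threshold, n_images = x$n_images)
  )
}

#' Treat one annotator's boxes as detections
#'
#' Human annotations carry no confidence score; to evaluate an annotator
#' with the detector protocol, every annotation becomes a detection with
#' confidence 1.0. Equal-confidence ties keep stable input order (the tie
#' policy is immaterial for F1 and FNR, which use the all-detections
#' operating point, and is documented for AP).
#'
#' @param annotations Annotation data frame (`image_id`, corners, `label`
#'   or `grade`, `annotator_id`).
#' @param annotator Which annotator to convert; may be omitted when the
#'   data contains a single annotator.
#' @return Detection tibble (`image_id`, corners, `label`,
#'   `confidence = 1`).
#' @export
annotator_as_detector <- function(annotations, annotator = NULL) {
  ann <- annotations
  if (!is.null(annotator)) {
    ann <- dplyr::filter(ann, .data$annotator_id == annotator)
  } else if ("annotator_id" %in% names(ann) &&
    dplyr::n_distinct(ann$annotator_id) > 1) {
    abort("Multiple annotators present; pick one with `annotator = `.")
  }
  if (!"label" %in% names(ann) && "grade" %in% names(ann)) {
    ann$label <- merge_grade(ann$grade)
  }
  ann |>
    dplyr::select("image_id", dplyr::all_of(box_cols), "label") |>
    dplyr::mutate(confidence = 1) |>
    tibble::as_tibble()
}
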