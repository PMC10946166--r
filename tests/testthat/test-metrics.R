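box_at <- function(x, y, w = 10, h = 10) {
  tibble::tibble(xmin = x, ymin = y, xmax = x + w, ymax = y + h)
}

test_that("greedy matching follows the VOC rule", {
  gt <- dplyr::mutate(box_at(0, 0), image_id = "a", label = "enamel")
  det <- dplyr::mutate(gt, confidence = 0.9)
  m <- match_detections(det, gt, 0.3)
  expect_equal(m$det$tp, TRUE)

  # a detection overlapping two GT boxes takes the higher-IoU one;
  # the other ground truth stays unmatched
  gt2 <- dplyr::bind_rows(
    dplyr::mutate(box_at(0, 0, 10, 10), image_id = "a", label = "enamel"),
    dplyr::mutate(box_at(8, 0, 10, 10), image_id = "a", label = "enamel")
  )
  det2 <- tibble::tibble(
    image_id = "a", xmin = 1, ymin = 0, xmax = 11, ymax = 10,
    label = "enamel", confidence = 0.8
  )
  expect_gt(box_iou(det2, gt2[1, ]), box_iou(det2, gt2[2, ]))
  m2 <- match_detections(det2, gt2, 0.3)
  expect_equal(sum(m2$det$tp), 1)
  ev2 <- suppressMessages(evaluate_detections(det2, gt2))
  row <- ev2$per_class[ev2$per_class$class == "enamel", ]
  expect_equal(row$tp, 1)
  expect_equal(row$fn, 1)

  # below-threshold overlap is a false positive and a false negative
  det3 <- tibble::tibble(
    image_id = "a", xmin = 8, ymin = 8, xmax = 18, ymax = 18,
    label = "enamel", confidence = 0.8
  )
  gt3 <- dplyr::mutate(box_at(0, 0), image_id = "a", label = "enamel")
  expect_lt(box_iou(det3, gt3), 0.3)
  m3 <- match_detections(det3, gt3, 0.3)
  expect_false(any(m3$det$tp))

  # each ground-truth box can be claimed once: the higher-confidence
  # detection wins, the duplicate becomes a false positive
  dup <- dplyr::bind_rows(
    dplyr::mutate(gt3, confidence = 0.6),
    dplyr::mutate(gt3, confidence = 0.9)
  )
  m4 <- match_detections(dup, gt3, 0.3)
  expect_equal(m4$det$tp, c(FALSE, TRUE))

  # class mismatch never matches
  mism <- match_detections(
    dplyr::mutate(gt3, label = "dentine", confidence = 1), gt3, 0.3
  )
  expect_false(any(mism$det$tp))
})

test_that("average precision reproduces hand-computed sweeps", {
  expect_equal(average_precision(TRUE, 1, n_gt = 1), 1)
  # ranks TP, FP, TP with 2 GT: 0.5 * 1 + 0.5 * (2/3)
  expect_equal(
    average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), n_gt = 2),
    0.5 + 0.5 * 2 / 3
  )
  expect_equal(average_precision(logical(0), numeric(0), n_gt = 3), 0)
  expect_true(is.na(average_precision(TRUE, 1, n_gt = 0)))
  # recall never reaching 1 caps the integral
  expect_equal(average_precision(TRUE, 1, n_gt = 2), 0.5)
})

test_that("average precision equals the threshold-enumeration oracle", {
  withr::local_seed(301)
  for (rep in 1:200) {
    n <- sample(0:20, 1)
    n_gt <- sample(1:20, 1)
    tp <- runif(n) < 0.5
    # keep flags consistent with the ground truth count
    while (sum(tp) > n_gt) tp[which(tp)[1]] <- FALSE
    conf <- round(runif(n), 1) # heavy ties
    expect_equal(
      average_precision(tp, conf, n_gt),
      oracle_ap(tp, conf, n_gt),
      tolerance = 1e-9
    )
  }
})

test_that("F1 and FNR reproduce the formulas including degenerate cases", {
  expect_equal(f1_fnr(5, 0, 0), tibble::tibble(f1 = 1, fnr = 0))
  expect_equal(f1_fnr(3, 1, 2), tibble::tibble(f1 = 6 / 9, fnr = 2 / 5))
  expect_equal(f1_fnr(0, 4, 3), tibble::tibble(f1 = 0, fnr = 1))
  # no detections, no ground truth: F1 conventionally 0, with a warning
  expect_warning(res <- f1_fnr(0, 0, 0), "F1")
  expect_equal(res$f1, 0)
  expect_true(is.na(res$fnr))
  # detections but no ground truth: FNR undefined
  res2 <- f1_fnr(0, 2, 0)
  expect_equal(res2$f1, 0)
  expect_true(is.na(res2$fnr))
})

test_that("evaluation is exact on identity and empty detectors", {
  withr::local_seed(302)
  gt <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::mutate(
      random_box_tbl(3),
      image_id = paste0("im", i),
      label = caries_classes()
    )
  }))
  perfect <- dplyr::mutate(gt, confidence = 1)
  ev <- evaluate_detections(perfect, gt)
  expect_equal(ev$per_class$ap, rep(1, 3))
  expect_equal(ev$per_class$f1, rep(1, 3))
  expect_equal(ev$per_class$fnr, rep(0, 3))
  expect_equal(glance(ev)$map, 1)
  expect_equal(glance(ev)$mf1, 1)
  expect_equal(glance(ev)$mfnr, 0)

  empty <- perfect[0, ]
  ev0 <- evaluate_detections(empty, gt)
  expect_equal(glance(ev0)$map, 0)
  expect_equal(glance(ev0)$mf1, 0)
  expect_equal(glance(ev0)$mfnr, 1)
})

test_that("all metrics stay within [0, 1] on random instances", {
  withr::local_seed(303)
  for (rep in 1:50) {
    inst <- random_instance()
    ev <- suppressMessages(suppressWarnings(
      evaluate_detections(inst$det, inst$gt)
    ))
    vals <- unlist(ev$per_class[, c("ap", "f1", "fnr")])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
    # FNR consistency with the counts
    with_gt <- ev$per_class[ev$per_class$n_gt > 0, ]
    expect_equal(with_gt$fnr, 1 - with_gt$tp / (with_gt$tp + with_gt$fn))
  }
})

test_that("evaluation is invariant to image processing order", {
  withr::local_seed(304)
  inst <- random_instance(n_images = 4)
  ev1 <- suppressMessages(suppressWarnings(
    evaluate_detections(inst$det, inst$gt)
  ))
  perm <- sample(nrow(inst$det))
  permg <- sample(nrow(inst$gt))
  ev2 <- suppressMessages(suppressWarnings(
    evaluate_detections(inst$det[perm, ], inst$gt[permg, ])
  ))
  expect_equal(ev1$per_class, ev2$per_class)
})

test_that("adding a top-rank true positive never lowers AP", {
  withr::local_seed(305)
  for (rep in 1:30) {
    n <- sample(1:15, 1)
    n_gt <- sample(2:20, 1)
    tp <- runif(n) < 0.4
    while (sum(tp) >= n_gt) tp[which(tp)[1]] <- FALSE
    conf <- runif(n, 0, 0.9)
    base <- average_precision(tp, conf, n_gt)
    better <- average_precision(c(TRUE, tp), c(0.95, conf), n_gt)
    expect_gte(better, base - 1e-12)
  }
})

test_that("a class absent from the ground truth is excluded from means", {
  gt <- dplyr::mutate(box_at(0, 0), image_id = "a", label = "enamel")
  det <- dplyr::bind_rows(
    dplyr::mutate(gt, confidence = 1),
    dplyr::mutate(box_at(50, 50), image_id = "a", label = "dentine", confidence = 0.5)
  )
  expect_message(ev <- evaluate_detections(det, gt), "dentine")
  expect_true(is.na(ev$per_class$ap[ev$per_class$class == "dentine"]))
  expect_equal(glance(ev)$map, 1) # mean over enamel only
})

test_that("annotators become uniform-confidence detectors", {
  ann <- tibble::tibble(
    image_id = "a", annotator_id = "r1",
    xmin = c(0, 20, 40), ymin = 0, xmax = c(10, 30, 50), ymax = 10,
    grade = c("grade1", "grade3", "secondary")
  )
  det <- annotator_as_detector(ann)
  expect_equal(nrow(det), 3)
  expect_equal(det$confidence, rep(1, 3))
  expect_equal(det$label, c("enamel", "dentine", "secondary"))
  expect_equal(nrow(annotator_as_detector(ann[0, ])), 0)

  # an annotator whose boxes equal the ground truth scores perfectly
  gt <- dplyr::select(dplyr::mutate(ann, label = merge_grade(grade)),
    "image_id", xmin:ymax, "label"
  )
  ev <- suppressMessages(evaluate_detections(det, gt))
  expect_equal(glance(ev)$map, 1)

  multi <- dplyr::bind_rows(ann, dplyr::mutate(ann, annotator_id = "r2"))
  expect_error(annotator_as_detector(multi), "Multiple annotators")
  expect_equal(nrow(annotator_as_detector(multi, annotator = "r2")), 3)
})
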