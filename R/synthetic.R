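#' Synthetic scene configuration
#'
#' Describes the geometry and class mix of a synthetic annotation scene:
#' images of fixed pixel size, a per-image box count range, a box edge
#' length range, and class frequencies. Defaults sketch a bitewing-like
#' radiograph: ~1 megapixel images carrying a handful of small lesions,
#' with secondary lesions the most frequent class.
#'
#' @param image_width,image_height Image size in pixels.
#' @param n_images Number of images.
#' @param boxes_per_image Length-2 integer range (min, max), inclusive,
#'   uniform.
#' @param box_size_range Length-2 range of box edge lengths in pixels,
#'   uniform per axis.
#' @param class_frequencies Named probabilities over [caries_classes()],
#'   summing to 1.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_width = 1000, image_height = 800,
                         n_images = 20,
                         boxes_per_image = c(1, 6),
                         box_size_range = c(20, 80),
                         class_frequencies = c(
                           enamel = 0.30, dentine = 0.25, secondary = 0.45
                         )) {
  if (box_size_range[2] > image_width || box_size_range[2] > image_height) {
    abort("`box_size_range` exceeds the image dimensions.")
  }
  if (box_size_range[1] <= 0 || box_size_range[1] > box_size_range[2]) {
    abort("`box_size_range` must be positive and ordered.")
  }
  if (abs(sum(class_frequencies) - 1) > 1e-8 || any(class_frequencies < 0)) {
    abort("`class_frequencies` must be non-negative and sum to 1.")
  }
  if (is.null(names(class_frequencies)) ||
    !all(names(class_frequencies) %in% caries_classes(include_unknown = TRUE))) {
    abort("`class_frequencies` must be named with valid classes.")
  }
  if (boxes_per_image[1] < 0 || boxes_per_image[1] > boxes_per_image[2]) {
    abort("`boxes_per_image` must be a non-negative ordered range.")
  }
  structure(
    list(
      image_width = image_width, image_height = image_height,
      n_images = n_images,
      boxes_per_image = boxes_per_image,
      box_size_range = box_size_range,
      class_frequencies = class_frequencies
    ),
    class = "scene_config"
  )
}

#' Synthetic rater / detector operating profile
#'
#' `rater_profile()` describes an imperfect annotator: independent
#' Gaussian jitter on each box edge, a per-box miss probability, a
#' Poisson rate of spurious (false positive) boxes per image, and a
#' row-stochastic label confusion matrix. `detector_profile()` adds a
#' confidence model: boxes derived from true lesions draw confidences
#' from `Beta(conf_tp)`, spurious boxes from `Beta(conf_fp)`, so ranking
#' metrics are exercised.
#'
#' Jitter is applied to edges, not to centre and size, deliberately: the
#' fusion model assumes a Gaussian per axis around the centre, and
#' edge-wise noise does not match that assumption exactly, so tests
#' exercise robustness rather than self-confirmation.
#'
#' @param jitter_sigma Edge jitter standard deviation in pixels.
#' @param miss_prob Probability of missing a true box, in \[0, 1\].
#' @param fp_rate Expected spurious boxes per image (Poisson).
#' @param label_confusion Row-stochastic matrix over [caries_classes()]
#'   (rows = true class, columns = reported class); identity if `NULL`.
#' @return A list of class `rater_profile`.
#' @export
rater_profile <- function(jitter_sigma = 2, miss_prob = 0.1, fp_rate = 0.2,
                          label_confusion = NULL) {
  classes <- caries_classes()
  if (is.null(label_confusion)) {
    label_confusion <- diag(length(classes))
    dimnames(label_confusion) <- list(classes, classes)
  }
  if (!all(rownames(label_confusion) == classes) ||
    !all(colnames(label_confusion) == classes) ||
    any(abs(rowSums(label_confusion) - 1) > 1e-8) ||
    any(label_confusion < 0)) {
    abort("`label_confusion` must be row-stochastic over caries_classes().")
  }
  if (miss_prob < 0 || miss_prob > 1) abort("`miss_prob` must be in [0, 1].")
  if (fp_rate < 0) abort("`fp_rate` must be non-negative.")
  if (jitter_sigma < 0) abort("`jitter_sigma` must be non-negative.")
  structure(
    list(
      jitter_sigma = jitter_sigma, miss_prob = miss_prob,
      fp_rate = fp_rate, label_confusion = label_confusion
    ),
    class = "rater_profile"
  )
}

#' @rdname rater_profile
#' @param conf_tp,conf_fp Length-2 Beta shape parameters for the
#'   confidence of true-lesion-derived and spurious boxes.
#' @export
detector_profile <- function(jitter_sigma = 1, miss_prob = 0.05,
                             fp_rate = 0.1, label_confusion = NULL,
                             conf_tp = c(8, 2), conf_fp = c(2, 5)) {
  prof <- rater_profile(jitter_sigma, miss_prob, fp_rate, label_confusion)
  prof$conf_tp <- conf_tp
  prof$conf_fp <- conf_fp
  class(prof) <- c("detector_profile", class(prof))
  prof
}

#' Generate synthetic ground-truth boxes
#'
#' Places boxes uniformly inside the image (fully contained), with edge
#' lengths uniform in the configured range and labels drawn from the
#' configured class frequencies. Fully reproducible under `seed`.
#'
#' @param config A [scene_config()].
#' @param seed Optional integer seed.
#' @return Tibble `image_id`, corners, `label`, with the scene
#'   configuration attached as attribute `"scene_config"`.
#' @export
generate_ground_truth <- function(config = scene_config(), seed = NULL) {
  if (!inherits(config, "scene_config")) {
    abort("`config` must come from scene_config().")
  }
  local_seed(seed)
  count_range <- config$boxes_per_image[1]:config$boxes_per_image[2]
  per_image <- lapply(seq_len(config$n_images), function(i) {
    # sample() would misread a length-1 range as 1:n
    n <- if (length(count_range) == 1) count_range else sample(count_range, 1)
    if (n == 0) {
      return(NULL)
    }
    random_boxes(n, config) |>
      dplyr::mutate(
        image_id = sprintf("img%04d", i),
        label = sample(
          names(config$class_frequencies), n,
          replace = TRUE, prob = config$class_frequencies
        ),
        .before = 1
      )
  })
  out <- dplyr::bind_rows(per_image)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      image_id = character(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), label = character()
    )
  }
  out <- dplyr::select(out, "image_id", dplyr::all_of(box_cols), "label")
  attr(out, "scene_config") <- config
  out
}

# n random boxes fully inside the image.
random_boxes <- function(n, config) {
  w <- runif(n, config$box_size_range[1], config$box_size_range[2])
  h <- runif(n, config$box_size_range[1], config$box_size_range[2])
  x <- runif(n, 0, config$image_width - w)
  y <- runif(n, 0, config$image_height - h)
  tibble::tibble(xmin = x, ymin = y, xmax = x + w, ymax = y + h)
}

#' Simulate multi-rater annotations of a ground-truth scene
#'
#' For each rater and true box: the box is missed with the rater's
#' `miss_prob`; otherwise each edge is independently perturbed by
#' centred Gaussian jitter and clamped to the image, and the label is
#' resampled from the rater's confusion row. Each rater additionally
#' contributes `Poisson(fp_rate)` spurious boxes per image, placed at
#' random but rejected if they overlap any true box above IoU 0.1 (so
#' spurious really means spurious).
#'
#' @param ground_truth Tibble from [generate_ground_truth()] (or any box
#'   tibble carrying a `"scene_config"` attribute / accompanied by
#'   `config`).
#' @param profiles Named list of [rater_profile()]s; names become
#'   annotator ids (unnamed lists get `rater1`, `rater2`, ...).
#' @param seed Optional integer seed.
#' @param config [scene_config()] providing image bounds; defaults to the
#'   attribute on `ground_truth`.
#' @return Annotation tibble: `image_id`, `annotator_id`, corners,
#'   `label`.
#' @export
simulate_annotators <- function(ground_truth, profiles, seed = NULL,
                                config = attr(ground_truth, "scene_config")) {
  if (is.null(config)) abort("No scene_config available; pass `config`.")
  if (length(profiles) == 0) abort("Need at least one rater profile.")
  if (inherits(profiles, "rater_profile")) profiles <- list(profiles)
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("rater", seq_along(profiles))
  }
  local_seed(seed)
  out <- lapply(names(profiles), function(rid) {
    obs <- simulate_one_observer(ground_truth, profiles[[rid]], config)
    if (nrow(obs) == 0) {
      return(NULL)
    }
    dplyr::mutate(obs, annotator_id = rid, .after = "image_id")
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      image_id = character(), annotator_id = character(),
      xmin = numeric(), ymin = numeric(), xmax = numeric(), ymax = numeric(),
      label = character()
    ))
  }
  dplyr::select(out, "image_id", "annotator_id", dplyr::all_of(box_cols), "label")
}

#' Simulate a scored detector on a ground-truth scene
#'
#' Same corruption model as [simulate_annotators()], plus confidences:
#' boxes derived from true lesions draw from `Beta(conf_tp)`, spurious
#' boxes from `Beta(conf_fp)`.
#'
#' @inheritParams simulate_annotators
#' @param quality A [detector_profile()].
#' @return Detection tibble: `image_id`, corners, `label`, `confidence`.
#' @export
simulate_detector <- function(ground_truth, quality = detector_profile(),
                              seed = NULL,
                              config = attr(ground_truth, "scene_config")) {
  if (is.null(config)) abort("No scene_config available; pass `config`.")
  if (!inherits(quality, "detector_profile")) {
    abort("`quality` must come from detector_profile().")
  }
  local_seed(seed)
  det <- simulate_one_observer(ground_truth, quality, config)
  if (nrow(det) == 0) {
    return(tibble::tibble(
      image_id = character(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), label = character(),
      confidence = numeric()
    ))
  }
  n <- nrow(det)
  conf <- numeric(n)
  from_truth <- det$origin == "true"
  conf[from_truth] <- rbeta(sum(from_truth), quality$conf_tp[1], quality$conf_tp[2])
  conf[!from_truth] <- rbeta(sum(!from_truth), quality$conf_fp[1], quality$conf_fp[2])
  det |>
    dplyr::mutate(confidence = conf) |>
    dplyr::select("image_id", dplyr::all_of(box_cols), "label", "confidence")
}

# One observer's corrupted view of the whole scene. Returns boxes with an
# `origin` column ("true" or "spurious").
simulate_one_observer <- function(ground_truth, profile, config) {
  classes <- caries_classes()
  gt <- as.data.frame(ground_truth, stringsAsFactors = FALSE)
  image_ids <- unique(gt$image_id)

  kept <- gt[runif(nrow(gt)) >= profile$miss_prob, , drop = FALSE]
  if (nrow(kept) > 0) {
    kept <- jitter_boxes(kept, profile$jitter_sigma, config)
    kept$label <- vapply(kept$label, function(lbl) {
      sample(classes, 1, prob = profile$label_confusion[lbl, ])
    }, character(1))
    kept$origin <- "true"
  }

  fp <- lapply(image_ids, function(img) {
    n_fp <- rpois(1, profile$fp_rate)
    if (n_fp == 0) {
      return(NULL)
    }
    truth_img <- gt[gt$image_id == img, , drop = FALSE]
    boxes <- spurious_boxes(n_fp, truth_img, config)
    if (nrow(boxes) == 0) {
      return(NULL)
    }
    boxes |>
      dplyr::mutate(
        image_id = img,
        label = sample(
          names(config$class_frequencies), nrow(boxes),
          replace = TRUE, prob = config$class_frequencies
        ),
        origin = "spurious"
      )
  })
  dplyr::bind_rows(
    if (nrow(kept) > 0) tibble::as_tibble(kept) else NULL,
    dplyr::bind_rows(fp)
  )
}

# Edge-wise Gaussian jitter, clamped to the image; degenerate draws for a
# box are retried, falling back to the original box.
jitter_boxes <- function(boxes, sigma, config) {
  if (sigma == 0) {
    return(boxes)
  }
  for (i in seq_len(nrow(boxes))) {
    for (attempt in 1:100) {
      cand <- c(
        boxes$xmin[i], boxes$ymin[i], boxes$xmax[i], boxes$ymax[i]
      ) + rnorm(4, 0, sigma)
      cand[c(1, 3)] <- pmin(pmax(cand[c(1, 3)], 0), config$image_width)
      cand[c(2, 4)] <- pmin(pmax(cand[c(2, 4)], 0), config$image_height)
      if (cand[3] > cand[1] && cand[4] > cand[2]) {
        boxes$xmin[i] <- cand[1]
        boxes$ymin[i] <- cand[2]
        boxes$xmax[i] <- cand[3]
        boxes$ymax[i] <- cand[4]
        break
      }
    }
  }
  boxes
}

# Random boxes rejected when they overlap true boxes above IoU 0.1.
spurious_boxes <- function(n, truth_img, config) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in 1:50) {
      cand <- random_boxes(1, config)
      if (nrow(truth_img) == 0 ||
        max(box_iou_matrix(cand, truth_img)) <= 0.1) {
        out[[i]] <- cand
        break
      }
    }
  }
  dplyr::bind_rows(out)
}
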