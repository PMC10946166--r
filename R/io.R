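#' Read multi-annotator box annotations
#'
#' Two dialects are supported. The CSV dialect has one row per annotation
#' with columns `image_id, annotator_id, xmin, ymin, xmax, ymax, grade`
#' (corner coordinates in pixels). The COCO-style JSON dialect is the
#' usual `images` / `annotations` / `categories` layout with boxes as
#' `[x, y, width, height]`, plus an `annotator_id` field on each
#' annotation; category names are the raw grades. Both are validated:
#' every record must reference a declared image (JSON), and every grade
#' must be in [caries_grades()] (or an already-merged group name) —
#' violations raise an error naming the offending record.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"coco"`.
#' @return Annotation tibble: `image_id`, `annotator_id`, corners,
#'   `grade`, `label` (merged). Image sizes, when declared, are attached
#'   as attribute `"images"`.
#' @export
read_annotations <- function(path, format = c("auto", "csv", "coco")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    ann <- readr::read_csv(path, col_types = readr::cols(
      image_id = readr::col_character(),
      annotator_id = readr::col_character(),
      xmin = readr::col_double(), ymin = readr::col_double(),
      xmax = readr::col_double(), ymax = readr::col_double(),
      grade = readr::col_character()
    ))
    check_grades(ann$grade, path)
    ann$label <- merge_grade(ann$grade)
    validate_boxes(ann, "annotation")
    inform(sprintf("Read %d annotation(s) from %s.", nrow(ann), path))
    return(ann)
  }
  coco <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  images <- tibble::as_tibble(coco$images)
  categories <- tibble::as_tibble(coco$categories)
  check_grades(categories$name, path)
  raw <- coco$annotations
  if (is.null(raw) || length(raw) == 0 || NROW(raw) == 0) {
    ann <- tibble::tibble(
      image_id = character(), annotator_id = character(),
      xmin = numeric(), ymin = numeric(), xmax = numeric(), ymax = numeric(),
      grade = character(), label = character()
    )
    attr(ann, "images") <- images
    return(ann)
  }
  bad_img <- setdiff(unique(raw$image_id), images$id)
  if (length(bad_img) > 0) {
    abort(sprintf(
      "%s: annotation(s) reference undeclared image id(s): %s.",
      path, paste(head(bad_img, 5), collapse = ", ")
    ))
  }
  bad_cat <- setdiff(unique(raw$category_id), categories$id)
  if (length(bad_cat) > 0) {
    abort(sprintf(
      "%s: annotation(s) reference undeclared category id(s): %s.",
      path, paste(head(bad_cat, 5), collapse = ", ")
    ))
  }
  bbox <- do.call(rbind, raw$bbox)
  ann <- tibble::tibble(
    image_id = as.character(raw$image_id),
    annotator_id = as.character(raw$annotator_id),
    xmin = bbox[, 1], ymin = bbox[, 2],
    xmax = bbox[, 1] + bbox[, 3], ymax = bbox[, 2] + bbox[, 4],
    grade = categories$name[match(raw$category_id, categories$id)]
  )
  ann$label <- merge_grade(ann$grade)
  validate_boxes(ann, "annotation")
  attr(ann, "images") <- images
  inform(sprintf("Read %d annotation(s) from %s.", nrow(ann), path))
  ann
}

check_grades <- function(grades, path) {
  valid <- c(caries_grades(), caries_classes(include_unknown = TRUE))
  bad <- which(!grades %in% valid)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid grade '%s' in record %d (valid: %s).",
      path, grades[bad[1]], bad[1], paste(caries_grades(), collapse = ", ")
    ))
  }
  invisible(grades)
}

resolve_format <- function(format, path) {
  if (format != "auto") {
    return(format)
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return("csv")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return("coco")
  }
  abort(sprintf("Cannot infer format of '%s'; pass `format`.", path))
}

#' Write annotations
#'
#' Inverse of [read_annotations()]; both dialects round-trip box
#' coordinates at full double precision. The COCO dialect needs image
#' sizes: they are taken from the `"images"` attribute when present (as
#' set by [read_annotations()]), or from `image_dims`, or bounded from
#' the boxes as a fallback.
#'
#' @param annotations Annotation tibble (needs `grade` or `label`).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"`, or `"coco"`.
#' @param image_dims Optional tibble `id`, `width`, `height`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path,
                              format = c("auto", "csv", "coco"),
                              image_dims = NULL) {
  format <- resolve_format(match.arg(format), path)
  ann <- annotations
  if (!"grade" %in% names(ann)) ann$grade <- ann$label
  if (format == "csv") {
    readr::write_csv(
      ann[, c("image_id", "annotator_id", box_cols, "grade")],
      path
    )
    return(invisible(path))
  }
  images <- image_dims %||% attr(annotations, "images") %||% infer_images(ann)
  categories <- tibble::tibble(
    id = seq_along(caries_grades()), name = caries_grades()
  )
  records <- tibble::tibble(
    id = seq_len(nrow(ann)),
    image_id = ann$image_id,
    annotator_id = ann$annotator_id,
    bbox = lapply(seq_len(nrow(ann)), function(i) {
      c(ann$xmin[i], ann$ymin[i], ann$xmax[i] - ann$xmin[i], ann$ymax[i] - ann$ymin[i])
    }),
    category_id = categories$id[match(ann$grade, categories$name)]
  )
  jsonlite::write_json(
    list(images = images, annotations = records, categories = categories),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

infer_images <- function(boxed) {
  if (nrow(boxed) == 0) {
    return(tibble::tibble(id = character(), width = numeric(), height = numeric()))
  }
  boxed |>
    dplyr::group_by(id = .data$image_id) |>
    dplyr::summarise(
      width = ceiling(max(.data$xmax)), height = ceiling(max(.data$ymax))
    )
}

#' Read and write detection files
#'
#' The CSV dialect has columns `image_id, xmin, ymin, xmax, ymax, label,
#' confidence`; the JSON dialect is a COCO-results-style array of
#' records `{image_id, bbox: [x, y, w, h], category, score}` with
#' `category` a merged class name.
#'
#' @param path File path.
#' @param format `"auto"`, `"csv"`, or `"coco"`.
#' @return `read_detections()`: detection tibble (`image_id`, corners,
#'   `label`, `confidence`).
#' @export
read_detections <- function(path, format = c("auto", "csv", "coco")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    det <- readr::read_csv(path, col_types = readr::cols(
      image_id = readr::col_character(),
      xmin = readr::col_double(), ymin = readr::col_double(),
      xmax = readr::col_double(), ymax = readr::col_double(),
      label = readr::col_character(),
      confidence = readr::col_double()
    ))
  } else {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (length(raw) == 0 || NROW(raw) == 0) {
      return(tibble::tibble(
        image_id = character(), xmin = numeric(), ymin = numeric(),
        xmax = numeric(), ymax = numeric(), label = character(),
        confidence = numeric()
      ))
    }
    bbox <- do.call(rbind, raw$bbox)
    det <- tibble::tibble(
      image_id = as.character(raw$image_id),
      xmin = bbox[, 1], ymin = bbox[, 2],
      xmax = bbox[, 1] + bbox[, 3], ymax = bbox[, 2] + bbox[, 4],
      label = raw$category,
      confidence = raw$score
    )
  }
  if (any(det$confidence < 0 | det$confidence > 1)) {
    abort(sprintf("%s: confidences must lie in [0, 1].", path))
  }
  bad <- which(!det$label %in% caries_classes(include_unknown = TRUE))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid class '%s' in record %d.", path, det$label[bad[1]], bad[1]
    ))
  }
  validate_boxes(det, "detection")
  det
}

#' @rdname read_detections
#' @param detections Detection tibble.
#' @export
write_detections <- function(detections, path, format = c("auto", "csv", "coco")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    readr::write_csv(
      detections[, c("image_id", box_cols, "label", "confidence")],
      path
    )
    return(invisible(path))
  }
  records <- tibble::tibble(
    image_id = detections$image_id,
    bbox = lapply(seq_len(nrow(detections)), function(i) {
      c(
        detections$xmin[i], detections$ymin[i],
        detections$xmax[i] - detections$xmin[i],
        detections$ymax[i] - detections$ymin[i]
      )
    }),
    category = detections$label,
    score = detections$confidence
  )
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write and read consensus ground truth
#'
#' Consensus boxes are stored as a COCO-style ground-truth file whose
#' categories are the merged class groups; each annotation additionally
#' carries the fusion provenance (`annotator_ids`, `group_size`) in
#' extension fields. Records are written sorted by `(image_id, xmin,
#' ymin)` so identical inputs give byte-identical files.
#'
#' @param consensus Tibble from [fuse_annotations()].
#' @param path Output path (JSON).
#' @param image_dims Optional tibble `id`, `width`, `height`.
#' @return `path` invisibly; `read_consensus()` returns the consensus
#'   tibble (with `annotators` as a list column).
#' @export
write_consensus <- function(consensus, path, image_dims = NULL) {
  cons <- dplyr::arrange(consensus, .data$image_id, .data$xmin, .data$ymin)
  classes <- caries_classes(include_unknown = TRUE)
  images <- image_dims %||% attr(consensus, "images") %||% infer_images(cons)
  records <- tibble::tibble(
    id = seq_len(nrow(cons)),
    image_id = cons$image_id,
    bbox = lapply(seq_len(nrow(cons)), function(i) {
      c(cons$xmin[i], cons$ymin[i], cons$xmax[i] - cons$xmin[i], cons$ymax[i] - cons$ymin[i])
    }),
    category_id = match(cons$label, classes),
    annotator_ids = lapply(cons$annotators, as.character),
    group_size = cons$group_size
  )
  jsonlite::write_json(
    list(
      images = images,
      annotations = records,
      categories = tibble::tibble(id = seq_along(classes), name = classes)
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  coco <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  categories <- tibble::as_tibble(coco$categories)
  raw <- coco$annotations
  if (is.null(raw) || NROW(raw) == 0) {
    return(tibble::tibble(
      image_id = character(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), label = character(),
      group_size = integer(), annotators = list()
    ))
  }
  bbox <- do.call(rbind, raw$bbox)
  out <- tibble::tibble(
    image_id = as.character(raw$image_id),
    xmin = bbox[, 1], ymin = bbox[, 2],
    xmax = bbox[, 1] + bbox[, 3], ymax = bbox[, 2] + bbox[, 4],
    label = categories$name[match(raw$category_id, categories$id)],
    group_size = as.integer(raw$group_size),
    annotators = lapply(raw$annotator_ids, as.character)
  )
  attr(out, "images") <- tibble::as_tibble(coco$images)
  out
}

#' K-fold split of images (optionally grouped)
#'
#' Random partition of the image ids into `k` folds by sampling without
#' replacement; fold sizes differ by at most one. When `groups` is given
#' (e.g. a patient id per image), whole groups are assigned to folds and
#' never split across folds — the leakage-safe mode; fold sizes are then
#' balanced greedily and may differ by more than one.
#'
#' @param image_ids Vector of unique image ids.
#' @param k Number of folds (at least 2, at most `length(image_ids)`).
#' @param seed Optional integer seed.
#' @param groups Optional grouping key, one per image id.
#' @return Tibble `image_id`, `fold` (integer in `1..k`), plus `group`
#'   when grouped.
#' @examples
#' kfold_split(paste0("img", 1:10), k = 5, seed = 1)
#' @export
kfold_split <- function(image_ids, k = 5, seed = NULL, groups = NULL) {
  n <- length(image_ids)
  if (anyDuplicated(image_ids)) abort("`image_ids` must be unique.")
  if (k < 2) abort("`k` must be at least 2.")
  if (n < k) abort("Need at least as many images as folds.")
  local_seed(seed)
  if (is.null(groups)) {
    shuffled <- sample(image_ids)
    fold <- rep(seq_len(k), length.out = n)
    out <- tibble::tibble(image_id = shuffled, fold = fold)
    return(dplyr::arrange(out, match(.data$image_id, image_ids)))
  }
  if (length(groups) != n) {
    abort("`groups` must have one entry per image id.")
  }
  ug <- sample(unique(groups))
  sizes <- integer(k)
  g_fold <- integer(length(ug))
  group_n <- table(groups)
  for (i in seq_along(ug)) {
    target <- which.min(sizes)
    g_fold[i] <- target
    sizes[target] <- sizes[target] + group_n[[as.character(ug[i])]]
  }
  tibble::tibble(
    image_id = image_ids,
    group = groups,
    fold = g_fold[match(groups, ug)]
  )
}

#' Enumerate the three-way-split rotation of k folds
#'
#' For each cross-validation iteration, one fold is the held-out test
#' set, the next fold (cyclically) is the validation set used to monitor
#' training, and the remaining `k - 2` folds are the training set.
#'
#' @param k Number of folds (at least 3).
#' @return Tibble `iteration`, `test_fold`, `val_fold`, `train_folds`
#'   (list column).
#' @export
three_way_splits <- function(k = 5) {
  if (k < 3) abort("A three-way split needs at least 3 folds.")
  tibble::tibble(
    iteration = seq_len(k),
    test_fold = seq_len(k),
    val_fold = seq_len(k) %% k + 1L,
    train_folds = lapply(seq_len(k), function(i) {
      setdiff(seq_len(k), c(i, i %% k + 1L))
    })
  )
}

#' Read a fusion/evaluation configuration file
#'
#' YAML or JSON; returns a named list mirroring the command-line flags
#' (flags override config values in the CLI).
#'
#' @param path File path (`.yaml`, `.yml`, or `.json`).
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the 'yaml' package.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
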