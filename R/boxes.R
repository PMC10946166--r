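#' Label vocabularies
#'
#' Annotations carry a raw severity grade; analysis runs on merged class
#' groups. Grades 1-2 mark radiolucency confined to the enamel, grades 3-5
#' reach increasing depths of the dentine, secondary lesions are associated
#' with sealants or restorations, and `unknown` marks lesions whose grade
#' could not be determined.
#'
#' @return Character vector of valid raw grades, or of merged class groups.
#' @examples
#' caries_grades()
#' caries_classes()
#' @export
caries_grades <- function() {
  c("grade1", "grade2", "grade3", "grade4", "grade5", "secondary", "unknown")
}

#' @rdname caries_grades
#' @param include_unknown Keep the `unknown` group in the vocabulary.
#' @export
caries_classes <- function(include_unknown = FALSE) {
  cls <- c("enamel", "dentine", "secondary")
  if (include_unknown) c(cls, "unknown") else cls
}

#' Collapse raw severity grades into merged class groups
#'
#' Grades 1 and 2 merge into `enamel`, grades 3-5 into `dentine`;
#' `secondary` and `unknown` are kept as their own groups. The mapping is
#' idempotent: already-merged values pass through unchanged, so files that
#' store merged labels can be read with the same path.
#'
#' @param grade Character vector of raw grades (see [caries_grades()]) or
#'   already-merged group names.
#' @return Character vector of merged groups, same length as `grade`.
#' @examples
#' merge_grade(c("grade1", "grade4", "secondary"))
#' @export
merge_grade <- function(grade) {
  map <- c(
    grade1 = "enamel", grade2 = "enamel",
    grade3 = "dentine", grade4 = "dentine", grade5 = "dentine",
    secondary = "secondary", unknown = "unknown",
    enamel = "enamel", dentine = "dentine"
  )
  out <- unname(map[as.character(grade)])
  if (anyNA(out) && !anyNA(grade)) {
    bad <- unique(as.character(grade)[is.na(out)])
    abort(sprintf(
      "Unrecognized grade value(s): %s. Valid grades: %s.",
      paste0("'", bad, "'", collapse = ", "),
      paste(caries_grades(), collapse = ", ")
    ))
  }
  out
}

# Columns every box-bearing tibble must carry.
box_cols <- c("xmin", "ymin", "xmax", "ymax")

#' Validate box geometry in a data frame
#'
#' Checks that the four corner columns are present, numeric, finite, and
#' describe strictly positive width and height (origin top-left, x
#' rightward, y downward, continuous pixel coordinates).
#'
#' @param data Data frame with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @param what Noun used in error messages.
#' @return `data`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_boxes <- function(data, what = "box") {
  missing_cols <- setdiff(box_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s data is missing column(s): %s.", what,
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in box_cols) {
    v <- data[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      abort(sprintf("Column '%s' must be finite numeric.", col))
    }
  }
  degenerate <- which(data$xmax <= data$xmin | data$ymax <= data$ymin)
  if (length(degenerate) > 0) {
    abort(sprintf(
      "%s rows with non-positive width or height (xmax <= xmin or ymax <= ymin): %s.",
      what, paste(head(degenerate, 5), collapse = ", ")
    ))
  }
  invisible(data)
}

#' Box areas
#'
#' @param data Data frame with corner columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @return Numeric vector of areas (continuous convention: width times
#'   height of the real-valued extents, no +1 pixel inclusivity).
#' @export
box_area <- function(data) {
  (data$xmax - data$xmin) * (data$ymax - data$ymin)
}

#' Intersection over union of axis-aligned boxes
#'
#' `box_iou()` compares boxes elementwise (rows of `a` against rows of `b`,
#' recycled if one has a single row); `box_iou_matrix()` returns the full
#' cross table. IoU is symmetric, 0 for disjoint boxes and 1 only for
#' identical boxes.
#'
#' @param a,b Data frames with corner columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @return `box_iou()`: numeric vector in \[0, 1\]. `box_iou_matrix()`:
#'   matrix with `nrow(a)` rows and `nrow(b)` columns.
#' @examples
#' a <- tibble::tibble(xmin = 0, ymin = 0, xmax = 10, ymax = 10)
#' b <- tibble::tibble(xmin = 0, ymin = 0, xmax = 10, ymax = 5)
#' box_iou(a, b)
#' @export
box_iou <- function(a, b) {
  validate_boxes(a, "box")
  validate_boxes(b, "box")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1 && nrow(b) != 1) {
    abort("box_iou() needs equal row counts or a single-row argument.")
  }
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  iou_vec(
    a$xmin[idx_a], a$ymin[idx_a], a$xmax[idx_a], a$ymax[idx_a],
    b$xmin[idx_b], b$ymin[idx_b], b$xmax[idx_b], b$ymax[idx_b]
  )
}

#' @rdname box_iou
#' @export
box_iou_matrix <- function(a, b) {
  validate_boxes(a, "box")
  validate_boxes(b, "box")
  na <- nrow(a)
  nb <- nrow(b)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  matrix(
    iou_vec(
      a$xmin[ia], a$ymin[ia], a$xmax[ia], a$ymax[ia],
      b$xmin[ib], b$ymin[ib], b$xmax[ib], b$ymax[ib]
    ),
    nrow = na, ncol = nb
  )
}

# Bare-vector IoU; callers guarantee valid geometry.
iou_vec <- function(axmin, aymin, axmax, aymax, bxmin, bymin, bxmax, bymax) {
  iw <- pmin(axmax, bxmax) - pmax(axmin, bxmin)
  ih <- pmin(aymax, bymax) - pmax(aymin, bymin)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (axmax - axmin) * (aymax - aymin) +
    (bxmax - bxmin) * (bymax - bymin) - inter
  inter / union
}
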