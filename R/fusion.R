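#' Fusion parameters
#'
#' Bundles the tunable parameters of the multi-observer fusion procedure.
#'
#' @details
#' The defaults are chosen so that fusing a group containing a single box
#' returns that box exactly: each box edge sits at `coverage_k` standard
#' deviations from the box centre, and the relative level
#' `exp(-coverage_k^2 / 2)` is precisely the density of a Gaussian at
#' `coverage_k` sigma relative to its mode. `group_iou` defaults to 0.3, the
#' same overlap threshold used when matching detections to ground truth in
#' evaluation.
#'
#' @param group_iou IoU at or above which two boxes on the same image join
#'   the same group (single-linkage), in (0, 1].
#' @param coverage_k Half-extent of a box expressed in standard deviations
#'   of its fitted Gaussian: `sigma = half_extent / coverage_k`. Positive.
#' @param level_p Relative density level in (0, 1): the consensus extent is
#'   the level set `{x : f(x) >= level_p * max f}` of the mixture density.
#' @param grid_resolution Step (pixels) of the level-set grid scan;
#'   crossings are refined by bisection well below this resolution.
#' @param severity Class severity order, least to most severe; used to
#'   break ties in the label vote.
#' @param vote_on `"merged"` votes on merged class groups (the default,
#'   matching how fused ground truth is consumed); `"grade"` votes on raw
#'   severity grades and merges afterwards.
#' @return A list of class `fusion_params`.
#' @examples
#' fusion_params()
#' fusion_params(coverage_k = 3)$level_p  # exp(-9/2)
#' @export
fusion_params <- function(group_iou = 0.3,
                          coverage_k = 2,
                          level_p = exp(-coverage_k^2 / 2),
                          grid_resolution = 0.1,
                          severity = caries_severity(),
                          vote_on = c("merged", "grade")) {
  if (!is.numeric(group_iou) || group_iou <= 0 || group_iou > 1) {
    abort("`group_iou` must be in (0, 1].")
  }
  if (!is.numeric(coverage_k) || coverage_k <= 0) {
    abort("`coverage_k` must be positive.")
  }
  if (!is.numeric(level_p) || level_p <= 0 || level_p >= 1) {
    abort("`level_p` must be in (0, 1).")
  }
  if (!is.numeric(grid_resolution) || grid_resolution <= 0) {
    abort("`grid_resolution` must be positive.")
  }
  structure(
    list(
      group_iou = group_iou,
      coverage_k = coverage_k,
      level_p = level_p,
      grid_resolution = grid_resolution,
      severity = severity,
      vote_on = match.arg(vote_on)
    ),
    class = "fusion_params"
  )
}

#' Default severity order for tie-breaking
#'
#' Least to most severe. Enamel lesions are shallower than dentine lesions;
#' secondary lesions (associated with restorations) are ranked most severe
#' by default, and `unknown` least. Only the enamel-below-dentine ordering
#' is clinically fixed; the rest is configurable via the `severity`
#' argument of [fusion_params()] and [vote_label()].
#'
#' @return Character vector of merged groups, least severe first.
#' @export
caries_severity <- function() {
  c("unknown", "enamel", "dentine", "secondary")
}

#' Group annotations on one image by IoU overlap
#'
#' Builds the graph whose vertices are boxes and whose edges join pairs
#' with IoU at or above `group_iou`, and labels its connected components
#' (single linkage). Boxes from the same annotator may share a group; there
#' is no assignment constraint.
#'
#' @param annotations Data frame of boxes on a single image (columns
#'   `xmin`, `ymin`, `xmax`, `ymax`; other columns pass through).
#' @param group_iou Threshold in (0, 1].
#' @return The input with an integer `group` column; groups are numbered
#'   in order of first appearance, so the result is deterministic for a
#'   fixed row order. Zero rows in, zero rows out.
#' @examples
#' ann <- tibble::tibble(
#'   xmin = c(0, 1, 40), ymin = c(0, 1, 40),
#'   xmax = c(10, 11, 50), ymax = c(10, 11, 50)
#' )
#' group_boxes(ann, group_iou = 0.3)$group
#' @export
group_boxes <- function(annotations, group_iou = 0.3) {
  n <- nrow(annotations)
  if (n == 0) {
    annotations$group <- integer(0)
    return(annotations)
  }
  validate_boxes(annotations, "annotation")
  adj <- box_iou_matrix(annotations, annotations) >= group_iou
  comp <- integer(n) # 0 = unvisited
  next_id <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    next_id <- next_id + 1L
    queue <- s
    comp[s] <- next_id
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  annotations$group <- comp
  annotations
}

#' Fit per-axis Gaussians to boxes
#'
#' Each box is represented by one Gaussian per image axis: the mean is the
#' box centre and the standard deviation is the half-extent divided by
#' `coverage_k`, so the box edges sit at `coverage_k` sigma.
#'
#' @param boxes Data frame with corner columns.
#' @param coverage_k Positive scalar.
#' @return Tibble with columns `mean_x`, `sigma_x`, `mean_y`, `sigma_y`,
#'   one row per input box.
#' @examples
#' fit_axis_gaussians(tibble::tibble(xmin = 0, ymin = 0, xmax = 10, ymax = 20))
#' @export
fit_axis_gaussians <- function(boxes, coverage_k = 2) {
  validate_boxes(boxes, "box")
  if (coverage_k <= 0) abort("`coverage_k` must be positive.")
  tibble::tibble(
    mean_x = (boxes$xmin + boxes$xmax) / 2,
    sigma_x = (boxes$xmax - boxes$xmin) / (2 * coverage_k),
    mean_y = (boxes$ymin + boxes$ymax) / 2,
    sigma_y = (boxes$ymax - boxes$ymin) / (2 * coverage_k)
  )
}

#' Equal-weight Gaussian mixture density
#'
#' Density of the mixture with one component per box and equal weights
#' `1/N`, evaluated along one axis.
#'
#' @param x Numeric vector of evaluation points.
#' @param mean,sigma Component means and standard deviations (equal
#'   length, `sigma > 0`).
#' @return Numeric vector, `length(x)`.
#' @examples
#' mixture_density(0, mean = 0, sigma = 1) # 1/sqrt(2*pi)
#' @export
mixture_density <- function(x, mean, sigma) {
  if (length(mean) != length(sigma) || length(mean) == 0) {
    abort("`mean` and `sigma` must be non-empty and of equal length.")
  }
  if (any(sigma <= 0)) abort("`sigma` must be positive.")
  dens <- numeric(length(x))
  for (i in seq_along(mean)) {
    dens <- dens + dnorm(x, mean[i], sigma[i])
  }
  dens / length(mean)
}

#' Extract the consensus extent from a mixture density
#'
#' Locates the connected component of the relative level set
#' `{x : f(x) >= level_p * max f}` that contains the global maximizer of
#' the mixture density `f`. The maximizer is found by a grid scan over
#' `[min(mean) - 6 max(sigma), max(mean) + 6 max(sigma)]` refined with
#' [stats::optimize()]; the two level crossings are bracketed on the grid
#' and refined by bisection to far below `grid_resolution`.
#'
#' The level is relative to the mixture's own maximum, which makes the
#' extraction invariant to translation and scaling of the pixel
#' coordinates and makes a singleton mixture reproduce `mean +/- k sigma`
#' exactly when `level_p = exp(-k^2/2)`.
#'
#' @param mean,sigma Mixture component parameters (see [mixture_density()]).
#' @param level_p Relative level in (0, 1).
#' @param grid_resolution Grid step in pixels.
#' @return Numeric length-2 vector `c(lo, hi)`.
#' @examples
#' consensus_interval(mean = 5, sigma = 2.5, level_p = exp(-2)) # c(0, 10)
#' @export
consensus_interval <- function(mean, sigma, level_p, grid_resolution = 0.1) {
  if (!is.numeric(level_p) || level_p <= 0 || level_p >= 1) {
    abort("`level_p` must be in (0, 1).")
  }
  if (grid_resolution <= 0) abort("`grid_resolution` must be positive.")
  f <- function(x) mixture_density(x, mean, sigma)
  lo_lim <- min(mean) - 6 * max(sigma)
  hi_lim <- max(mean) + 6 * max(sigma)
  xs <- seq(lo_lim, hi_lim, by = grid_resolution)
  if (tail(xs, 1) < hi_lim) xs <- c(xs, hi_lim)
  dens <- f(xs)
  i <- which.max(dens)
  # Refine the mode inside its bracketing grid cell(s).
  tol <- min(grid_resolution / 100, 1e-9)
  br <- c(xs[max(1L, i - 1L)], xs[min(length(xs), i + 1L)])
  opt <- optimize(f, interval = br, maximum = TRUE, tol = tol / 10)
  f_max <- max(opt$objective, dens[i])
  level <- level_p * f_max
  g <- function(x) f(x) - level

  # Walk outward from the maximizer along the grid, then bisect the
  # bracketing cell. The 6-sigma margin guarantees the density falls below
  # any practical relative level before the scan limits.
  j <- i
  while (j < length(xs) && dens[j + 1L] >= level) j <- j + 1L
  hi <- if (j == length(xs)) {
    xs[j]
  } else {
    uniroot(g, c(xs[j], xs[j + 1L]),
      f.lower = dens[j] - level, f.upper = dens[j + 1L] - level, tol = tol
    )$root
  }
  j <- i
  while (j > 1L && dens[j - 1L] >= level) j <- j - 1L
  lo <- if (j == 1L) {
    xs[j]
  } else {
    uniroot(g, c(xs[j - 1L], xs[j]),
      f.lower = dens[j - 1L] - level, f.upper = dens[j] - level, tol = tol
    )$root
  }
  c(lo, hi)
}

#' Majority vote with severity tie-break
#'
#' Returns the modal label; when several labels tie for the highest count,
#' the most severe of the tied labels wins (for caries groups, dentine
#' over enamel).
#'
#' @param labels Non-empty character vector.
#' @param severity Strict total order over the possible labels, least
#'   severe first.
#' @return Single label.
#' @examples
#' vote_label(c("dentine", "dentine", "enamel")) # majority
#' vote_label(c("enamel", "dentine")) # tie -> more severe
#' @export
vote_label <- function(labels, severity = caries_severity()) {
  if (length(labels) == 0) abort("`labels` must be non-empty.")
  missing_lv <- setdiff(unique(labels), severity)
  if (length(missing_lv) > 0) {
    abort(sprintf(
      "Label(s) not in the severity order: %s.",
      paste0("'", missing_lv, "'", collapse = ", ")
    ))
  }
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  top[which.max(match(top, severity))]
}

#' Fuse one group of annotations into a consensus box
#'
#' Fits per-axis Gaussians to every member box, forms the equal-weight
#' mixture density along each axis, extracts the relative level set as the
#' consensus extent, and votes the label.
#'
#' @param group Data frame of annotations in one IoU group (non-empty);
#'   needs corner columns and a `label` column, optionally `annotator_id`
#'   and `grade`.
#' @param params A [fusion_params()] object.
#' @return One-row tibble: corners, `label`, `group_size`, and
#'   `annotators` (list column of the contributing annotator ids, sorted).
#' @export
fuse_group <- function(group, params = fusion_params()) {
  if (nrow(group) == 0) abort("`group` must contain at least one annotation.")
  gauss <- fit_axis_gaussians(group, params$coverage_k)
  ix <- consensus_interval(
    gauss$mean_x, gauss$sigma_x, params$level_p, params$grid_resolution
  )
  iy <- consensus_interval(
    gauss$mean_y, gauss$sigma_y, params$level_p, params$grid_resolution
  )
  label <- if (params$vote_on == "grade" && "grade" %in% names(group)) {
    merge_grade(vote_label(group$grade, severity = grade_severity()))
  } else {
    vote_label(group$label, severity = params$severity)
  }
  annotators <- if ("annotator_id" %in% names(group)) {
    sort(unique(group$annotator_id))
  } else {
    NA
  }
  tibble::tibble(
    xmin = ix[1], ymin = iy[1], xmax = ix[2], ymax = iy[2],
    label = label,
    group_size = nrow(group),
    annotators = list(annotators)
  )
}

# Severity order over raw grades (used with vote_on = "grade").
grade_severity <- function() {
  c("unknown", "grade1", "grade2", "grade3", "grade4", "grade5", "secondary")
}

#' Fuse multi-observer annotations into consensus ground truth
#'
#' The full merging pipeline: per image, annotations are grouped by IoU
#' (single-linkage connected components at `params$group_iou`), each group
#' is fused into one consensus box ([fuse_group()]), and results are
#' returned sorted by `(image_id, xmin, ymin)` for reproducible output.
#'
#' @param annotations Data frame with columns `image_id`, corner columns,
#'   and a label: either `label` (merged groups) or `grade` (raw grades,
#'   merged on the fly). `annotator_id` is carried into provenance when
#'   present.
#' @param params A [fusion_params()] object.
#' @param keep_unknown Keep annotations whose merged label is `unknown`?
#'   Dropped by default, mirroring the exclusion of unknown-grade
#'   annotations from model training.
#' @return Tibble of consensus boxes: `image_id`, corners, `label`,
#'   `group_size`, `annotators` (list column).
#' @examples
#' ann <- tibble::tibble(
#'   image_id = "img1",
#'   annotator_id = c("a", "b"),
#'   xmin = c(10, 12), ymin = c(10, 11), xmax = c(30, 31), ymax = c(30, 32),
#'   grade = c("grade1", "grade3")
#' )
#' fuse_annotations(ann)
#' @export
fuse_annotations <- function(annotations,
                             params = fusion_params(),
                             keep_unknown = FALSE) {
  if (!inherits(params, "fusion_params")) {
    abort("`params` must come from fusion_params().")
  }
  if (!"image_id" %in% names(annotations)) {
    abort("`annotations` needs an `image_id` column.")
  }
  if (!"label" %in% names(annotations)) {
    if (!"grade" %in% names(annotations)) {
      abort("`annotations` needs a `label` or `grade` column.")
    }
    annotations$label <- merge_grade(annotations$grade)
  }
  if (nrow(annotations) == 0) {
    return(tibble::tibble(
      image_id = character(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), label = character(),
      group_size = integer(), annotators = list()
    ))
  }
  validate_boxes(annotations, "annotation")
  if (!keep_unknown) {
    n_unknown <- sum(annotations$label == "unknown")
    if (n_unknown > 0) {
      inform(sprintf("Excluding %d unknown-grade annotation(s) from fusion.", n_unknown))
      annotations <- dplyr::filter(annotations, .data$label != "unknown")
    }
  }
  annotations |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_modify(function(img, key) {
      grouped <- group_boxes(img, params$group_iou)
      grouped |>
        dplyr::group_by(.data$group) |>
        dplyr::group_modify(~ fuse_group(.x, params)) |>
        dplyr::ungroup() |>
        dplyr::select(-"group")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$image_id, .data$xmin, .data$ymin)
}
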