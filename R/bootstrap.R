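#' BCa bootstrap confidence interval for an image-level statistic
#'
#' Resamples image ids with replacement and forms the bias-corrected and
#' accelerated (BCa) interval for `statistic`. Resampling at the image
#' level keeps each image's detections and ground truth together, which is
#' the only unit that preserves the matching structure of detection
#' metrics.
#'
#' The bias correction `z0` is the normal quantile of the fraction of
#' bootstrap values below the point estimate (continuity-corrected by
#' `0.5/B` when that fraction would be 0 or 1); the acceleration `a` comes
#' from the skewness of leave-one-out jackknife values (set to 0 when the
#' jackknife sum of squares vanishes). Resamples on which the statistic is
#' undefined (`NA`) are redrawn and counted; more than 10% redraws raises
#' a warning.
#'
#' @param statistic Function taking a multiset (vector, possibly with
#'   repeats) of image ids and returning one number, or `NA` when
#'   undefined on that resample.
#' @param image_ids Vector of image ids (at least 2).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level in (0, 1).
#' @param seed Optional integer; fixes the resampling for reproducibility.
#' @param clip Optional length-2 numeric; the interval is clipped to this
#'   range after adjustment (use `c(0, 1)` for rate-type metrics).
#' @return One-row tibble: `point`, `low`, `high`, `level`, `n_boot`,
#'   `n_redraws`.
#' @examples
#' x <- rnorm(30)
#' bca_interval(function(ids) mean(x[ids]), seq_along(x), n_boot = 200, seed = 1)
#' @export
bca_interval <- function(statistic, image_ids, n_boot = 1000, level = 0.95,
                         seed = NULL, clip = NULL) {
  if (length(image_ids) < 2) abort("Need at least 2 image ids.")
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  local_seed(seed)
  point <- statistic(image_ids)
  if (is.na(point)) abort("`statistic` is undefined on the full sample.")
  draw <- resample_statistics(statistic, image_ids, n_boot)
  jack <- vapply(
    seq_along(image_ids),
    function(i) statistic(image_ids[-i]),
    numeric(1)
  )
  ci <- bca_from_samples(point, draw$values, jack, level, clip)
  if (draw$n_redraws > 0.1 * n_boot) {
    warn(sprintf(
      "%d of %d bootstrap resamples were redrawn (statistic undefined).",
      draw$n_redraws, n_boot
    ))
  }
  dplyr::bind_cols(
    ci,
    tibble::tibble(n_boot = n_boot, n_redraws = draw$n_redraws)
  )
}

# Draw n_boot resamples, redrawing any on which the statistic is NA.
resample_statistics <- function(statistic, image_ids, n_boot) {
  values <- numeric(n_boot)
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    val <- NA_real_
    attempts <- 0L
    while (is.na(val)) {
      if (attempts >= 1000L) {
        abort("Statistic undefined on 1000 consecutive resamples.")
      }
      val <- statistic(sample(image_ids, replace = TRUE))
      attempts <- attempts + 1L
    }
    n_redraws <- n_redraws + attempts - 1L
    values[b] <- val
  }
  list(values = values, n_redraws = n_redraws)
}

# BCa endpoints from precomputed bootstrap and jackknife values.
bca_from_samples <- function(point, boot_vals, jack_vals, level, clip = NULL) {
  b <- length(boot_vals)
  # ties at the point estimate count half, so a symmetric bootstrap
  # distribution with an atom at the estimate still gives z0 = 0
  frac_below <- (sum(boot_vals < point) + 0.5 * sum(boot_vals == point)) / b
  frac_below <- min(max(frac_below, 0.5 / b), 1 - 0.5 / b)
  z0 <- qnorm(frac_below)
  jack_vals <- jack_vals[!is.na(jack_vals)]
  dev <- mean(jack_vals) - jack_vals
  ss <- sum(dev^2)
  a <- if (ss > 0) sum(dev^3) / (6 * ss^1.5) else 0
  alpha <- (1 - level) / 2
  z_lo <- qnorm(alpha)
  z_hi <- qnorm(1 - alpha)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  ends <- unname(quantile(boot_vals, probs = c(adj(z_lo), adj(z_hi)), type = 7))
  if (!is.null(clip)) {
    ends <- pmin(pmax(ends, clip[1]), clip[2])
    point <- min(max(point, clip[1]), clip[2])
  }
  tibble::tibble(point = point, low = ends[1], high = ends[2], level = level)
}

# Set the RNG for the calling function's scope, restoring state on exit.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) {
    return(invisible())
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  withr::defer(
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    },
    envir = env
  )
  set.seed(seed)
  invisible()
}

#' Significance by confidence-interval overlap
#'
#' Two estimates are called significantly different when their confidence
#' intervals do not overlap. This is the (conservative) decision rule used
#' to compare detectors and annotators; intervals at different levels are
#' not comparable and raise an error.
#'
#' @param a,b One-row data frames with `low` and `high` (and optionally
#'   `level`) columns, as returned by [bca_interval()], or length-2
#'   numeric vectors `c(low, high)`.
#' @return `TRUE` if the intervals are disjoint.
#' @examples
#' compare_by_overlap(c(0.1, 0.2), c(0.3, 0.4)) # TRUE
#' compare_by_overlap(c(0.1, 0.3), c(0.25, 0.4)) # FALSE
#' @export
compare_by_overlap <- function(a, b) {
  a <- as_interval(a)
  b <- as_interval(b)
  if (!is.na(a$level) && !is.na(b$level) && a$level != b$level) {
    abort("Intervals have different confidence levels.")
  }
  a$high < b$low || b$high < a$low
}

as_interval <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1 || !all(c("low", "high") %in% names(x))) {
      abort("Interval data frames must have one row and `low`, `high` columns.")
    }
    list(
      low = x$low, high = x$high,
      level = if ("level" %in% names(x)) x$level else NA_real_
    )
  } else if (is.numeric(x) && length(x) == 2) {
    if (x[1] > x[2]) abort("Interval must satisfy low <= high.")
    list(low = x[1], high = x[2], level = NA_real_)
  } else {
    abort("Intervals must be length-2 numerics or one-row data frames.")
  }
}

#' Evaluate detections with BCa bootstrap confidence intervals
#'
#' Runs [evaluate_detections()] and adds BCa intervals for the mean
#' metrics (and optionally the per-class metrics), bootstrapping images
#' with replacement. Matching is computed once; each resample only
#' re-aggregates the per-image match results, so the default 1000
#' iterations stay cheap.
#'
#' @inheritParams evaluate_detections
#' @param metrics Which summary metrics to bootstrap.
#' @param per_class Also produce intervals for each class's AP/F1/FNR.
#' @param n_boot,level,seed Passed to the BCa machinery; see
#'   [bca_interval()].
#' @return A tibble of class `metric_ci`: `metric`, `class` (`"mean"` for
#'   the class means), `point`, `low`, `high`, `level`.
#' @export
evaluate_with_ci <- function(detections, ground_truth,
                             classes = caries_classes(),
                             iou_threshold = 0.3,
                             metrics = c("map", "mf1", "mfnr"),
                             per_class = FALSE,
                             n_boot = 1000, level = 0.95, seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  match <- match_detections(detections, ground_truth, iou_threshold)
  ids <- match$image_ids
  if (length(ids) < 2) abort("Need at least 2 images to bootstrap.")
  local_seed(seed)

  stat_tbl <- function(multiset) {
    pc <- eval_match(match, classes, multiset)
    means <- class_means(pc)
    out <- c(map = means$map, mf1 = means$mf1, mfnr = means$mfnr)
    if (per_class) {
      for (cl in classes) {
        row <- pc[pc$class == cl, ]
        out[paste0(c("ap.", "f1.", "fnr."), cl)] <- c(row$ap, row$f1, row$fnr)
      }
    }
    out
  }

  point <- stat_tbl(ids)
  keep <- c(metrics, if (per_class) {
    grep("^(ap|f1|fnr)\\.", names(point), value = TRUE)
  })
  # Shared resamples across metrics: one pass over the data per iteration.
  boot_mat <- matrix(NA_real_, nrow = n_boot, ncol = length(point),
    dimnames = list(NULL, names(point))
  )
  n_redraws <- 0L
  for (bb in seq_len(n_boot)) {
    repeat {
      vals <- stat_tbl(sample(ids, replace = TRUE))
      if (!anyNA(vals[metrics])) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 1000L * n_boot) abort("Too many undefined resamples.")
    }
    boot_mat[bb, ] <- vals
  }
  if (n_redraws > 0.1 * n_boot) {
    warn(sprintf("%d of %d bootstrap resamples were redrawn.", n_redraws, n_boot))
  }
  jack_mat <- t(vapply(
    seq_along(ids),
    function(i) stat_tbl(ids[-i]),
    numeric(length(point))
  ))

  rows <- lapply(keep, function(metric) {
    ci <- bca_from_samples(
      point[[metric]], boot_mat[, metric], jack_mat[, metric],
      level,
      clip = c(0, 1)
    )
    parts <- strsplit(metric, ".", fixed = TRUE)[[1]]
    dplyr::bind_cols(
      tibble::tibble(
        metric = parts[1],
        class = if (length(parts) > 1) parts[2] else "mean"
      ),
      ci
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_ci", class(out))
  out
}
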