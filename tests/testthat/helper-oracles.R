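# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written with naive loops and different formulas
# than the package code paths they validate.

# All-point interpolated AP by direct definition: AP = integral over recall
# of p_interp(r), with p_interp(r) the best precision among operating
# points achieving recall >= r. Operating points are every prefix of the
# ranked detection list (i.e. every confidence threshold).
oracle_ap <- function(tp, confidence, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  tp <- tp[order(-confidence)]
  recalls <- numeric(length(tp))
  precisions <- numeric(length(tp))
  for (i in seq_along(tp)) {
    n_tp <- sum(tp[seq_len(i)])
    recalls[i] <- n_tp / n_gt
    precisions[i] <- n_tp / i
  }
  knots <- sort(unique(recalls[recalls > 0]))
  ap <- 0
  prev <- 0
  for (r in knots) {
    p_interp <- max(precisions[recalls >= r])
    ap <- ap + (r - prev) * p_interp
    prev <- r
  }
  ap
}

# Connected components by transitive closure of the adjacency matrix.
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ]] <- next_id
    }
  }
  comp
}

# Level-set interval by dense scan only (no bisection): contiguous run of
# grid points around the argmax where the density clears the level.
oracle_level_interval <- function(mean, sigma, level_p, step = 1e-3) {
  xs <- seq(min(mean) - 6 * max(sigma), max(mean) + 6 * max(sigma), by = step)
  dens <- mixture_density(xs, mean, sigma)
  keep <- dens >= level_p * max(dens)
  i <- which.max(dens)
  lo <- i
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- i
  while (hi < length(xs) && keep[hi + 1]) hi <- hi + 1
  c(xs[lo], xs[hi])
}

# Majority-then-severity vote by explicit enumeration.
oracle_vote <- function(labels, severity) {
  counts <- sapply(severity, function(s) sum(labels == s))
  counts <- counts[counts > 0]
  best <- names(counts)[counts == max(counts)]
  ranks <- match(best, severity)
  best[which.max(ranks)]
}

# Random valid boxes for property tests.
random_box_tbl <- function(n, lim = 100) {
  x1 <- runif(n, 0, lim)
  y1 <- runif(n, 0, lim)
  w <- runif(n, 1, lim / 2)
  h <- runif(n, 1, lim / 2)
  tibble::tibble(xmin = x1, ymin = y1, xmax = x1 + w, ymax = y1 + h)
}

# Small random detection/ground-truth instance for metric tests.
random_instance <- function(n_det_max = 20, n_gt_max = 20, n_classes = 3,
                            n_images = 3) {
  classes <- caries_classes()[seq_len(n_classes)]
  imgs <- paste0("im", seq_len(n_images))
  n_gt <- sample(0:n_gt_max, 1)
  n_det <- sample(0:n_det_max, 1)
  gt <- if (n_gt > 0) {
    dplyr::mutate(
      random_box_tbl(n_gt),
      image_id = sample(imgs, n_gt, replace = TRUE),
      label = sample(classes, n_gt, replace = TRUE)
    )
  } else {
    tibble::tibble(
      image_id = character(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), label = character()
    )
  }
  det <- if (n_det > 0) {
    base <- random_box_tbl(n_det)
    # Bias some detections towards true boxes so TPs actually occur.
    if (n_gt > 0) {
      n_near <- min(n_det, sample(0:n_gt, 1))
      if (n_near > 0) {
        src <- gt[sample(n_gt, n_near, replace = TRUE), ]
        shift <- runif(n_near, -3, 3)
        base[seq_len(n_near), ] <- tibble::tibble(
          xmin = src$xmin + shift, ymin = src$ymin + shift,
          xmax = src$xmax + shift, ymax = src$ymax + shift
        )
      }
    }
    dplyr::mutate(
      base,
      image_id = sample(imgs, n_det, replace = TRUE),
      label = sample(classes, n_det, replace = TRUE),
      confidence = round(runif(n_det), 2) # rounded: force confidence ties
    )
  } else {
    tibble::tibble(
      image_id = character(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), label = character(),
      confidence = numeric()
    )
  }
  list(det = det, gt = gt)
}
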