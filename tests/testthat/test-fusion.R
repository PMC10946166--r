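test_that("IoU grouping forms single-linkage connected components", {
  # two overlapping boxes join; a distant one stays alone
  ann <- tibble::tibble(
    xmin = c(0, 1, 40), ymin = c(0, 1, 40),
    xmax = c(10, 11, 50), ymax = c(10, 11, 50)
  )
  g <- group_boxes(ann, group_iou = 0.3)
  expect_equal(g$group, c(1L, 1L, 2L))

  # chain A-B-C links even though A and C barely overlap
  chain <- tibble::tibble(
    xmin = c(0, 4, 8), ymin = 0, xmax = c(10, 14, 18), ymax = 10
  )
  expect_true(box_iou(chain[1, ], chain[3, ]) < 0.3)
  expect_equal(group_boxes(chain, 0.3)$group, c(1L, 1L, 1L))

  # three mutually disjoint boxes are three singletons
  disj <- tibble::tibble(
    xmin = c(0, 20, 40), ymin = 0, xmax = c(5, 25, 45), ymax = 5
  )
  expect_equal(group_boxes(disj, 0.3)$group, 1:3)

  expect_equal(nrow(group_boxes(disj[0, ], 0.3)), 0)
})

test_that("grouping matches a transitive-closure oracle on random scenes", {
  withr::local_seed(201)
  for (rep in 1:40) {
    ann <- random_box_tbl(sample(2:12, 1), lim = 60)
    tau <- runif(1, 0.1, 0.6)
    got <- group_boxes(ann, tau)$group
    want <- oracle_components(as.matrix(box_iou_matrix(ann, ann) >= tau))
    # same partition: equal group ids up to relabelling
    expect_equal(
      outer(got, got, "=="),
      outer(want, want, "==")
    )
  }
})

test_that("axis Gaussians put the box edge at k sigma", {
  g <- fit_axis_gaussians(
    tibble::tibble(xmin = 0, ymin = 0, xmax = 10, ymax = 20),
    coverage_k = 2
  )
  expect_equal(g$mean_x, 5)
  expect_equal(g$sigma_x, 2.5)
  expect_equal(g$mean_y, 10)
  expect_equal(g$sigma_y, 5)

  sym <- fit_axis_gaussians(
    tibble::tibble(xmin = -5, ymin = -5, xmax = 5, ymax = 5), 2
  )
  expect_equal(sym$mean_x, 0)
  expect_equal(sym$sigma_x, 2.5)

  # doubling k halves sigma
  g4 <- fit_axis_gaussians(
    tibble::tibble(xmin = 0, ymin = 0, xmax = 10, ymax = 20), 4
  )
  expect_equal(g4$sigma_x, g$sigma_x / 2)
})

test_that("mixture density is the equal-weight average of normal pdfs", {
  expect_equal(mixture_density(0, 0, 1), 1 / sqrt(2 * pi))
  # duplicated component changes nothing
  xs <- seq(-3, 3, by = 0.5)
  expect_equal(
    mixture_density(xs, c(0, 0), c(1, 1)),
    mixture_density(xs, 0, 1)
  )
  # hand arithmetic: 0.5 * (phi(2) + phi(-2))
  expect_equal(
    mixture_density(2, c(0, 4), c(1, 1)),
    0.5 * (dnorm(2) + dnorm(-2))
  )
  expect_error(mixture_density(0, c(0, 1), 1), "equal length")
  expect_error(mixture_density(0, 0, -1), "positive")
})

test_that("consensus interval reproduces the closed-form Gaussian level set", {
  # single Gaussian: {f >= p max f} = mean +/- sigma * sqrt(-2 log p)
  got <- consensus_interval(5, 2.5, level_p = exp(-2))
  expect_equal(got, c(0, 10), tolerance = 1e-7)
  for (p in c(0.05, 0.3, 0.8)) {
    half <- 2.5 * sqrt(-2 * log(p))
    expect_equal(
      consensus_interval(5, 2.5, p),
      c(5 - half, 5 + half),
      tolerance = 1e-6
    )
  }
  # p -> 1 shrinks the interval onto the mode
  tight <- consensus_interval(5, 2.5, 0.9999)
  expect_lt(tight[2] - tight[1], 0.1)
  expect_error(consensus_interval(0, 1, 1.5), "level_p")
})

test_that("consensus interval matches the dense-grid oracle on random mixtures", {
  withr::local_seed(202)
  for (rep in 1:100) {
    n <- sample(1:6, 1)
    mean <- runif(n, 0, 50)
    sigma <- runif(n, 0.5, 8)
    p <- runif(1, 0.05, 0.9)
    got <- consensus_interval(mean, sigma, p, grid_resolution = 0.05)
    want <- oracle_level_interval(mean, sigma, p, step = 1e-3)
    expect_lt(abs(got[1] - want[1]), 2e-3)
    expect_lt(abs(got[2] - want[2]), 2e-3)
  }
})

test_that("label vote is majority with severity tie-break", {
  expect_equal(vote_label(c("dentine", "dentine", "enamel")), "dentine")
  expect_equal(vote_label(c("enamel", "dentine")), "dentine")
  expect_equal(vote_label("enamel"), "enamel")
  expect_equal(vote_label(c("secondary", "enamel")), "secondary")
  # custom severity order flips the tie
  expect_equal(
    vote_label(c("enamel", "dentine"),
      severity = c("dentine", "enamel")
    ),
    "enamel"
  )
  expect_error(vote_label(character(0)), "non-empty")
  expect_error(vote_label("nonsense"), "severity order")
})

test_that("label vote enumerates correctly over all small multisets", {
  classes <- caries_classes()
  severity <- caries_severity()
  for (size in 1:4) {
    combos <- expand.grid(rep(list(classes), size), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      labels <- unlist(combos[i, ], use.names = FALSE)
      expect_identical(
        vote_label(labels, severity),
        oracle_vote(labels, severity)
      )
    }
  }
})

test_that("label vote is permutation invariant", {
  withr::local_seed(203)
  for (rep in 1:20) {
    labels <- sample(caries_classes(), sample(2:7, 1), replace = TRUE)
    expect_identical(vote_label(labels), vote_label(sample(labels)))
  }
})

test_that("singleton fusion is the identity at the default parameters", {
  withr::local_seed(204)
  for (rep in 1:20) {
    box <- dplyr::mutate(random_box_tbl(1), label = "enamel")
    fused <- fuse_group(box, fusion_params())
    expect_equal(fused$xmin, box$xmin, tolerance = 1e-6)
    expect_equal(fused$ymin, box$ymin, tolerance = 1e-6)
    expect_equal(fused$xmax, box$xmax, tolerance = 1e-6)
    expect_equal(fused$ymax, box$ymax, tolerance = 1e-6)
    expect_equal(fused$group_size, 1L)
  }
})

test_that("fusing N identical boxes equals fusing the singleton", {
  box <- tibble::tibble(
    xmin = 12.5, ymin = 30, xmax = 60, ymax = 85, label = "dentine"
  )
  one <- fuse_group(box, fusion_params())
  for (n in c(2, 5)) {
    many <- fuse_group(box[rep(1, n), ], fusion_params())
    expect_equal(
      many[, c("xmin", "ymin", "xmax", "ymax")],
      one[, c("xmin", "ymin", "xmax", "ymax")],
      tolerance = 1e-6
    )
  }
})

test_that("fusion is translation and scale equivariant", {
  withr::local_seed(205)
  params <- fusion_params()
  base <- dplyr::mutate(random_box_tbl(4, lim = 40), label = "enamel")
  # make sure it is one group
  base <- dplyr::mutate(base,
    xmin = 20 + xmin / 10, xmax = 30 + xmax / 10,
    ymin = 20 + ymin / 10, ymax = 30 + ymax / 10
  )
  ref <- fuse_group(base, params)
  t <- c(17.3, -4.2)
  shifted <- dplyr::mutate(base,
    xmin = xmin + t[1], xmax = xmax + t[1],
    ymin = ymin + t[2], ymax = ymax + t[2]
  )
  got <- fuse_group(shifted, params)
  expect_equal(got$xmin, ref$xmin + t[1], tolerance = 1e-5)
  expect_equal(got$xmax, ref$xmax + t[1], tolerance = 1e-5)
  expect_equal(got$ymin, ref$ymin + t[2], tolerance = 1e-5)
  expect_equal(got$ymax, ref$ymax + t[2], tolerance = 1e-5)

  s <- 2.5
  scaled <- dplyr::mutate(base,
    xmin = xmin * s, xmax = xmax * s, ymin = ymin * s, ymax = ymax * s
  )
  # scale the grid too: equivariance is about geometry, not discretization
  got_s <- fuse_group(scaled, fusion_params(grid_resolution = 0.1 * s))
  expect_equal(got_s$xmin, ref$xmin * s, tolerance = 1e-4)
  expect_equal(got_s$xmax, ref$xmax * s, tolerance = 1e-4)
})

test_that("fused centre lands near truth for jittered raters", {
  withr::local_seed(206)
  truth <- c(50, 50, 100, 100)
  centres <- matrix(NA_real_, 20, 2)
  for (rep in 1:20) {
    jit <- matrix(rnorm(24, 0, 2), ncol = 4)
    group <- tibble::tibble(
      xmin = truth[1] + jit[, 1], ymin = truth[2] + jit[, 2],
      xmax = truth[3] + jit[, 3], ymax = truth[4] + jit[, 4],
      label = "enamel"
    )
    fused <- fuse_group(group, fusion_params())
    centres[rep, ] <- c(
      (fused$xmin + fused$xmax) / 2, (fused$ymin + fused$ymax) / 2
    )
  }
  expect_true(all(abs(centres[, 1] - 75) < 2))
  expect_true(all(abs(centres[, 2] - 75) < 2))
})

test_that("fuse_annotations orchestrates grouping and fusion per image", {
  expect_equal(nrow(fuse_annotations(tibble::tibble(
    image_id = character(), annotator_id = character(),
    xmin = numeric(), ymin = numeric(), xmax = numeric(), ymax = numeric(),
    grade = character()
  ))), 0)

  # two disjoint singletons come back unchanged, sorted by position
  ann <- tibble::tibble(
    image_id = "im1", annotator_id = c("a", "b"),
    xmin = c(40, 0), ymin = c(40, 0), xmax = c(60, 10), ymax = c(60, 10),
    grade = c("grade4", "grade1")
  )
  cons <- fuse_annotations(ann)
  expect_equal(nrow(cons), 2)
  expect_equal(cons$xmin, c(0, 40), tolerance = 1e-6)
  expect_equal(cons$label, c("enamel", "dentine"))
  expect_equal(cons$annotators, list("b", "a"))

  # one consensus box per true box when raters neither miss nor invent
  cfg <- scene_config(n_images = 4)
  gt <- generate_ground_truth(cfg, seed = 11)
  perfect <- rater_profile(jitter_sigma = 0.5, miss_prob = 0, fp_rate = 0)
  ann3 <- simulate_annotators(gt, list(
    r1 = perfect, r2 = perfect, r3 = perfect
  ), seed = 12)
  cons3 <- fuse_annotations(ann3)
  expect_equal(nrow(cons3), nrow(gt))
})

test_that("unknown-grade annotations are excluded unless retained", {
  ann <- tibble::tibble(
    image_id = "im1", annotator_id = c("a", "b"),
    xmin = c(0, 30), ymin = c(0, 30), xmax = c(10, 40), ymax = c(10, 40),
    grade = c("grade1", "unknown")
  )
  expect_message(cons <- fuse_annotations(ann), "unknown")
  expect_equal(nrow(cons), 1)
  kept <- fuse_annotations(ann, keep_unknown = TRUE)
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$label, c("enamel", "unknown"))
})

test_that("fusion parameters are validated", {
  expect_error(fusion_params(group_iou = 0), "group_iou")
  expect_error(fusion_params(level_p = 1), "level_p")
  expect_error(fusion_params(coverage_k = -1), "coverage_k")
  expect_error(fusion_params(grid_resolution = 0), "grid_resolution")
  # default level is tied to the coverage factor
  expect_equal(fusion_params(coverage_k = 3)$level_p, exp(-4.5))
})
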