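# Four-axis mirror-symmetry measure and its non-linear transforms.

test_that("worked 2x4 example and degenerate edge cases are exact", {
  m <- matrix(c(1, 0, 0, 1,
                1, 1, 0, 0), nrow = 2, byrow = TRUE)
  # row 1 matches at both pair columns (weights 1 + 2), row 2 at none
  expect_identical(axis_symmetry(m, "vertical"), 0.5)

  # all pairs mismatch -> 0; mirror-symmetric -> 1
  anti <- cbind(matrix(0, 3, 2), matrix(1, 3, 2))
  expect_identical(axis_symmetry(anti, "vertical"), 0)
  symm <- cbind(matrix(c(1, 0, 1), 3, 2), matrix(c(1, 0, 1), 3, 2)[, 2:1])
  expect_identical(axis_symmetry(symm, "vertical"), 1)

  # width-2 image: single pair column, weight defined as 1
  m2 <- matrix(c(1, 1, 0, 1), 2, 2)
  expect_equal(axis_symmetry(m2, "vertical"),
               brute_axis_symmetry(m2, "vertical"))
  expect_error(axis_symmetry(matrix(1, 3, 1), "vertical"), "width")
  expect_error(axis_symmetry(matrix(c(0, 1), 1, 2), "main_diagonal"), "square")
  expect_error(axis_symmetry(matrix(0.5, 4, 4), "vertical"), "binary")
})

test_that("axis scores agree with the brute-force pair oracle", {
  set.seed(101)
  for (size in list(c(7, 7), c(8, 8), c(9, 9), c(7, 10), c(12, 9))) {
    for (rep in 1:60) {
      img <- random_binary(size[1], size[2], p = runif(1, 0.2, 0.8))
      expect_equal(axis_symmetry(img, "vertical"),
                   brute_axis_symmetry(img, "vertical"), tolerance = 1e-12)
      expect_equal(axis_symmetry(img, "horizontal"),
                   brute_axis_symmetry(img, "horizontal"), tolerance = 1e-12)
      if (size[1] == size[2]) {
        expect_equal(axis_symmetry(img, "main_diagonal"),
                     brute_axis_symmetry(img, "main_diagonal"),
                     tolerance = 1e-12)
        expect_equal(axis_symmetry(img, "secondary_diagonal"),
                     brute_axis_symmetry(img, "secondary_diagonal"),
                     tolerance = 1e-12)
      }
    }
  }
  # spot check at stimulus resolution
  big <- random_binary(600, 600)
  expect_equal(axis_symmetry(big, "main_diagonal"),
               brute_axis_symmetry(big, "main_diagonal"), tolerance = 1e-12)
})

test_that("profile aggregates, flips and rotations behave as invariants", {
  set.seed(7)
  for (rep in 1:25) {
    img <- random_binary(8, 8)
    prof <- mirror_symmetry(img)
    expect_true(all(prof$axes >= 0 & prof$axes <= 1))
    expect_equal(prof$ms, 100 * mean(prof$axes))

    # mirroring about any axis leaves ms unchanged
    for (a in c("vertical", "horizontal", "main_diagonal",
                "secondary_diagonal")) {
      expect_equal(mirror_symmetry(reflect_image(img, a))$ms, prof$ms)
    }
    # 90-degree rotation permutes the axis scores (h<->v, d1<->d2)
    rot <- mirror_symmetry(rot90(img))
    expect_equal(unname(rot$axes["vertical"]),
                 unname(prof$axes["horizontal"]))
    expect_equal(unname(rot$axes["horizontal"]),
                 unname(prof$axes["vertical"]))
    expect_equal(unname(rot$axes["main_diagonal"]),
                 unname(prof$axes["secondary_diagonal"]))
    expect_equal(rot$ms, prof$ms)
  }
})

test_that("iid random images score near the chance level of 50", {
  set.seed(11)
  img <- random_binary(100, 100)
  expect_lt(abs(mirror_symmetry(img)$ms - 50), 5)
})

test_that("transforms: identity at a = 1, known values, monotone in a", {
  prof <- mirror_symmetry(render(generate_pattern(
    sim_spec(target_axes = "vertical", seed = 2)), 8))
  expect_equal(transform_profile(prof, transform_spec("power", a = 1)),
               prof$ms)
  # perfect profile is a fixed point of every transform
  expect_equal(transform_profile(c(1, 1, 1, 1),
                                 transform_spec("power", a = 17)), 100)
  expect_equal(transform_profile(c(0.99, 1, 1, 1),
                                 transform_spec("power", a = 20)),
               100 * (0.99^20 + 3) / 4, tolerance = 1e-12)
  expect_equal(100 * (0.99^20 + 3) / 4, 95.45, tolerance = 0.01)
  # threshold-stretch: 0.975 at t = 0.95 maps to 50 on the 0-100 scale
  expect_equal(transform_profile(rep(0.975, 4),
                                 transform_spec("threshold_stretch", t = 0.95)),
               50, tolerance = 1e-12)
  # strictly decreasing in a when some axis < 1
  vals <- vapply(c(1, 2, 5, 10, 20, 40), function(a)
    transform_profile(prof, transform_spec("power", a = a)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(transform_spec("power", a = 0.5), "a must")
  expect_error(transform_spec("threshold_stretch", t = 1), "threshold")
})

test_that("transform_search finds the generating transform", {
  set.seed(42)
  n <- 160
  # per-axis scores spanning symmetric, broken and asymmetric regimes
  S <- cbind(MSA = runif(n), MSB = runif(n), MSC = runif(n), MSD = runif(n))
  near <- sample.int(n, n / 2)
  S[near, ] <- 1 - runif(length(near) * 4, 0, 0.08)
  tab <- as.data.frame(S)
  tab$RMSGIF <- rnorm(n)
  grid <- lapply(c(1, 2, 5, 10, 20), function(a) transform_spec("power", a = a))

  # ratings linear in the *untransformed* aggregate: a = 1 must win
  y1 <- 3 + 0.5 * tab$RMSGIF - 0.02 * (100 * rowMeans(S)) + rnorm(n, 0, 0.01)
  res1 <- transform_search(tab, y1, "RMSGIF", grid)
  expect_equal(res1$parameter[1], 1)

  # ratings penalizing only exact symmetry: the sharpest transform wins
  y2 <- 3 + 0.5 * tab$RMSGIF - 1.5 * rowMeans(S > 0.999) + rnorm(n, 0, 0.01)
  res2 <- transform_search(tab, y2, "RMSGIF", grid)
  expect_equal(res2$parameter[1], 20)

  expect_error(transform_search(tab, y1, "RMSGIF", list()), "empty")
})
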