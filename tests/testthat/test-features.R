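# Compression ratios, edge operators, structural measures, and the
# assembled 24-predictor vector.

test_that("GIF byte streams decode back to the encoded pixels", {
  # Pillow (python on PATH) is the independent decoder for the pinned
  # GIF87a encoder
  set.seed(3)
  img <- random_binary(24, 16)
  f <- tempfile(fileext = ".gif")
  write_image_gif(img, f)
  script <- tempfile(fileext = ".py")
  out <- tempfile()
  writeLines(c(
    "from PIL import Image",
    "import numpy as np, sys",
    sprintf("arr = np.array(Image.open(%s))", shQuote(f)),
    sprintf("np.savetxt(%s, arr.astype(int), fmt='%%d')", shQuote(out))
  ), script)
  status <- system2("python", script)
  expect_identical(status, 0L)
  decoded <- as.matrix(read.table(out))
  dimnames(decoded) <- NULL
  expect_equal(decoded, unname(img))
})

test_that("compression ratios are orientation means and rank by redundancy", {
  set.seed(4)
  white <- matrix(1, 64, 64)
  noise <- random_binary(64, 64)
  for (codec in c("GIF", "PNG", "TIF", "JPG")) {
    r <- compression_ratio(noise, codec, orientations = TRUE)
    o <- attr(r, "orientations")
    expect_equal(as.numeric(r), mean(o))
    expect_gt(r, 0)
  }
  # redundancy compresses: constant < iid noise under GIF
  expect_lt(compression_ratio(white, "GIF"), compression_ratio(noise, "GIF"))
  # determinism of the pinned encoders
  expect_identical(compression_ratio(noise, "GIF"),
                   compression_ratio(noise, "GIF"))
})

test_that("edge operators satisfy their closed-form cases", {
  flat <- matrix(1, 32, 32)
  expect_true(all(edge_map(flat, "CAN")$values == 0))
  expect_true(all(edge_map(flat, "PER")$values == 0))
  expect_true(all(edge_map(flat, "RMS")$values == 0))

  # single black k x k square: perimeter = 4k - 4 boundary pixels
  for (k in c(3, 5, 10)) {
    img <- matrix(1, 32, 32)
    img[10:(10 + k - 1), 8:(8 + k - 1)] <- 0
    per <- edge_map(img, "PER")$values
    expect_equal(sum(per), 4 * k - 4)
    inner <- img == 0 & per == 0
    expect_equal(sum(inner), (k - 2)^2)
  }
  # CAN and PER are binary; PHC bounded in [0, 1]
  set.seed(9)
  img <- render(generate_pattern(sim_spec(seed = 21)), 6)
  expect_true(all(edge_map(img, "CAN")$values %in% c(0, 1)))
  expect_true(all(edge_map(img, "PER")$values %in% c(0, 1)))
  phc <- edge_map(img, "PHC")$values
  expect_true(all(phc >= 0 & phc <= 1))
  expect_gt(max(phc), 0)  # a pattern has edges
  expect_error(edge_map(img, "SOBEL"))
})

test_that("edge statistics match the two-pass arithmetic oracle", {
  expect_equal(edge_stats(matrix(0, 4, 4)), c(MN = 0, SD = 0, MNSD = 0))
  expect_equal(edge_stats(matrix(0.3, 4, 4)),
               c(MN = 0.3, SD = 0, MNSD = 0))
  m <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(edge_stats(m), c(MN = 0.5, SD = 0.5, MNSD = 0.25))
  set.seed(10)
  for (rep in 1:20) {
    v <- matrix(runif(64), 8, 8)
    expect_equal(edge_stats(v), brute_edge_stats(v), tolerance = 1e-12)
  }
})

test_that("edge-map GIF ratio treats binary and 8-bit binary alike", {
  set.seed(12)
  b <- random_binary(32, 32)
  e <- structure(list(values = b, method = "PER"), class = "edge_map")
  expect_identical(edge_gif(e), edge_gif(b))
  # all-zero map compresses below a noisy binary map
  expect_lt(edge_gif(matrix(0, 32, 32)), edge_gif(b))
})

test_that("structural measures hit their closed-form values", {
  # DCM: centrally symmetric -> 0; corner pixel -> 1; two-pixel case exact
  sym <- matrix(1, 10, 10); sym[4:7, 4:7] <- 0
  expect_equal(dcm(sym), 0)
  corner <- matrix(1, 10, 10); corner[1, 1] <- 0
  expect_equal(dcm(corner), 1, tolerance = 2 / sqrt(2 * 81))
  two <- matrix(1, 9, 9); two[1, 1] <- 0; two[1, 9] <- 0
  expect_equal(dcm(two), (4) / (sqrt(8^2 + 8^2) / 2))
  expect_error(dcm(matrix(1, 4, 4)), "all-white")

  # APB: 180-degree symmetric mass balances all eight axes
  rot_sym <- matrix(1, 12, 12)
  rot_sym[2, 3] <- 0; rot_sym[11, 10] <- 0
  rot_sym[5, 8] <- 0; rot_sym[8, 5] <- 0
  expect_equal(apb(rot_sym), 100)
  left <- matrix(1, 8, 8); left[, 1:3] <- 0
  # vertical half-plane imbalance is total: that axis contributes 1
  b <- left < 0.5
  expect_equal(sum(b[, 5:8]), 0)
  expect_lt(apb(left), 100)

  # HG: even mass -> 1; single block -> 0; two blocks -> log2/log64
  even <- matrix(0, 16, 16)
  expect_equal(homogeneity(even), 1)
  one_block <- matrix(1, 16, 16); one_block[1:2, 1:2] <- 0
  expect_equal(homogeneity(one_block), 0)
  two_blocks <- matrix(1, 16, 16)
  two_blocks[1:2, 1:2] <- 0; two_blocks[1:2, 3:4] <- 0
  expect_equal(homogeneity(two_blocks), log(2) / log(64))
})

test_that("extract_all assembles exactly the registry and is consistent", {
  p <- generate_pattern(sim_spec(target_axes = c("vertical", "horizontal",
                                                 "main_diagonal",
                                                 "secondary_diagonal"),
                                 seed = 2))
  img <- render(p, 6)
  v <- extract_all(img)
  expect_true(all(PREDICTOR_NAMES %in% names(v)))
  expect_length(v, 28)  # 24 predictors + MSA..MSD
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["MS"]), 100)
  expect_true(v["DCM"] >= 0 && v["DCM"] <= 1)
  expect_true(v["HG"] >= 0 && v["HG"] <= 1)

  # composition consistency with the single operations
  expect_equal(unname(v["GIF"]), compression_ratio(img, "GIF"))
  expect_equal(unname(v["RMSGIF"]), edge_gif(edge_map(img, "RMS")))
  expect_equal(unname(v[c("CANMN", "CANSD", "CANMNSD")]),
               unname(edge_stats(edge_map(img, "CAN"))))
  expect_equal(unname(v["MS"]), mirror_symmetry(img)$ms)
})

test_that("symmetry is redundancy: symmetric patterns compress better", {
  fix <- contrast_corpus()
  meta <- fix$meta
  tab <- fix$table
  gif_sym <- tab$GIF[meta$symmetry_class == "4-axes"]
  gif_asym <- tab$GIF[meta$symmetry_class == "asymmetric"]
  expect_gt(mean(gif_asym), mean(gif_sym))
})
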