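gauss_pixels <- function(n = 200, p = 4, shift = c(4, rep(0, p - 1)),
                         seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n * p), n, p)
  x2 <- sweep(matrix(rnorm(n * p), n, p), 2, shift, `+`)
  colnames(x1) <- colnames(x2) <- sprintf("ch%02d", seq_len(p))
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(label = "a"), tibble::as_tibble(x1)),
    dplyr::bind_cols(tibble::tibble(label = "b"), tibble::as_tibble(x2)))
}

test_that("isotropic classes put the leading direction on the mean axis", {
  px <- gauss_pixels(n = 800, p = 4, seed = 2)
  m <- mmc_fit(px, d = 1)
  w <- m$W[, 1]
  expect_equal(abs(w[1]), 1, tolerance = 1e-2)
  expect_lt(max(abs(w[-1])), 0.1)
  expect_equal(crossprod(m$W), diag(1), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("identical class means leave no positive margin", {
  px <- gauss_pixels(n = 400, p = 3, shift = rep(0, 3), seed = 3)
  m <- mmc_fit(px, d = 1)
  expect_lte(m$eigenvalues[1], 0.05)  # ~0 up to sampling noise
})

test_that("the projection matches a dense eigensolver on a toy problem", {
  px <- tibble::tibble(
    label = rep(c("a", "b"), each = 4),
    c1 = c(0, 1, 0, 1, 5, 6, 5, 6),
    c2 = c(0, 0, 1, 1, 1, 1, 2, 2),
    c3 = c(2, 1, 2, 1, 2, 1, 2, 1))
  m <- mmc_fit(px, d = 2)
  # oracle: standardize, form the scatters directly, call eigen()
  x <- scale(as.matrix(px[c("c1", "c2", "c3")]))
  y <- px$label
  gm <- colMeans(x)
  s_b <- matrix(0, 3, 3); s_w <- matrix(0, 3, 3)
  for (cl in c("a", "b")) {
    xi <- x[y == cl, ]
    s_b <- s_b + nrow(xi) / nrow(x) * tcrossprod(colMeans(xi) - gm)
    s_w <- s_w + crossprod(sweep(xi, 2, colMeans(xi))) / nrow(x)
  }
  eo <- eigen(s_b - s_w, symmetric = TRUE)
  for (j in 1:2) {
    expect_equal(abs(sum(m$W[, j] * eo$vectors[, j])), 1, tolerance = 1e-8)
  }
  expect_equal(m$eigenvalues, eo$values, tolerance = 1e-8)
})

test_that("classification is nearest class mean with rejection", {
  px <- gauss_pixels(n = 500, p = 5, shift = c(6, rep(0, 4)), seed = 4)
  m <- mmc_fit(px)
  centre_a <- px |> dplyr::filter(label == "a") |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("ch"), mean))
  lab <- predict(m, centre_a)
  expect_equal(as.character(lab), "a")
  expect_lt(attr(lab, "distance"), 0.1)

  far <- centre_a - 50  # away from both classes along the projection
  expect_equal(as.character(predict(m, far)), "unclassified")
  expect_equal(as.character(predict(m, far, reject_threshold = Inf)), "a")
})

test_that("well-separated pixels are recovered almost perfectly", {
  px <- make_phantom("two_class_pixels",
                     params = list(n_per_class = 400, n_channels = 14,
                                   separation = 3, n_sep_channels = 3),
                     seed = 6)
  m <- mmc_fit(px)
  lab <- predict(m, px)
  ok <- lab != "unclassified"
  expect_gte(mean(lab[ok] == px$label[ok]), 0.99)
  # Dice overlap of the predicted tumor set against ground truth
  pred_t <- lab == "tumor"; true_t <- px$label == "tumor"
  dice <- 2 * sum(pred_t & true_t) / (sum(pred_t) + sum(true_t))
  expect_gte(dice, 0.95)
})

test_that("fits are invariant to channel order and constant shifts", {
  px <- gauss_pixels(n = 300, p = 5, shift = c(3, 1, 0, 0, 0), seed = 7)
  m1 <- mmc_fit(px, d = 1)
  perm <- c("ch03", "ch01", "ch05", "ch02", "ch04")
  m2 <- mmc_fit(px[c("label", perm)], d = 1)
  expect_equal(abs(m2$W[match(m1$channels, perm), 1]), abs(m1$W[, 1]),
               tolerance = 1e-8)
  shifted <- px
  shifted$ch02 <- shifted$ch02 + 100
  m3 <- mmc_fit(shifted, d = 1)
  expect_equal(abs(m3$W[, 1]), abs(m1$W[, 1]), tolerance = 1e-8)
})

test_that("constant channels are dropped with a warning", {
  px <- gauss_pixels(n = 100, p = 3, shift = c(4, 0, 0), seed = 8)
  px$ch03 <- 2
  expect_warning(m <- mmc_fit(px), "constant")
  expect_false("ch03" %in% m$channels)
  expect_error(predict(m, px["ch03"]), "channel")
})

test_that("segmentation maps colour only classified pixels", {
  g1 <- matrix(c(rep(0, 10), rep(5, 10)), 4, 5)
  g2 <- matrix(c(rep(5, 10), rep(0, 10)), 4, 5)
  imgs <- list(a = ion_image("a", g1, 1, 1), b = ion_image("b", g2, 1, 1))
  px <- images_to_pixels(imgs)
  px$label <- ifelse(px$a > px$b, "tumor", "stroma")
  m <- mmc_fit(px, d = 1)
  seg <- mmc_segment(m, imgs)
  expect_identical(dim(seg), dim(g1))
  expect_setequal(stats::na.omit(unique(as.vector(seg))),
                  c("tumor", "stroma"))
})
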