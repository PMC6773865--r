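test_that("uniform frames measure exactly zero after background subtraction", {
  mv <- movie_stack(array(37.5, c(32, 32, 5)), (0:4) * 4)
  tr <- measure_fluorescence(mv, 16, 16)
  expect_equal(tr$value, rep(0, 5))
})

test_that("a planted spot matches the brute-force pixel oracle", {
  spot <- data.frame(x = 16.3, y = 14.8, amp = 60)
  img <- planted_image(32, 32, bg = 20, spots = spot, sigma = 1.4)
  mv <- movie_stack(array(img, c(32, 32, 1)), 0)
  tr <- measure_fluorescence(mv, spot$x, spot$y)
  # oracle: direct enumeration of disk/annulus pixels and the trimmed mean
  dd <- sqrt(outer((seq_len(32) - spot$y)^2, (seq_len(32) - spot$x)^2, "+"))
  disk <- img[dd <= 2]
  ann <- img[dd > 2 & dd <= 5]
  q <- quantile(ann, c(0.2, 0.8), names = FALSE)
  bg <- mean(ann[ann >= q[1] & ann <= q[2]])
  expect_equal(tr$value, mean(disk) - bg, tolerance = 1e-9)
})

test_that("percentile trimming excludes an extreme hot pixel from the background", {
  img <- planted_image(32, 32, bg = 50,
                       spots = data.frame(x = 16, y = 16, amp = 40))
  img_hot <- img
  img_hot[16, 20] <- 5000  # a neighbouring object inside the annulus
  v0 <- measure_fluorescence(movie_stack(img, (0)), 16, 16)$value
  v1 <- measure_fluorescence(movie_stack(img_hot, (0)), 16, 16)$value
  # the trimmed background is essentially unchanged, whereas an
  # untrimmed annulus mean would shift by the hot pixel's full weight
  expect_equal(v1, v0, tolerance = 0.005)
  dd <- sqrt(outer((1:32 - 16)^2, (1:32 - 16)^2, "+"))
  naive_shift <- abs(mean(img_hot[dd > 2 & dd <= 5]) -
                       mean(img[dd > 2 & dd <= 5]))
  expect_gt(naive_shift, 100 * abs(v1 - v0))
})

test_that("measurement is invariant to adding a constant to the frame", {
  withr::with_seed(8, {
    img <- matrix(rnorm(32 * 32, 100, 10), 32, 32)
  })
  m1 <- measure_fluorescence(movie_stack(img, 0), 12.4, 17.9)$value
  m2 <- measure_fluorescence(movie_stack(img + 250, 0), 12.4, 17.9)$value
  expect_equal(m1, m2, tolerance = 1e-9)
  expect_error(measure_fluorescence(movie_stack(img, 0), 100, 100), "inside")
})

test_that("traces align to their peak and average correctly", {
  # single triangular trace: time 0 holds the maximum after alignment
  tri <- data.frame(time = (0:6) * 4, value = c(0, 1, 2, 5, 2, 1, 0))
  al <- align_traces(list(tri))
  expect_equal(al$mean[al$time == 0], 5)
  expect_equal(max(al$mean), al$mean[al$time == 0])
  # 100 copies at random integer frame offsets average to the single trace
  withr::with_seed(12, {
    copies <- lapply(1:100, function(i) {
      off <- sample(-5:5, 1) * 4
      data.frame(time = tri$time + off, value = tri$value)
    })
  })
  al2 <- align_traces(copies)
  expect_equal(al2$mean[match(tri$time - 12, al2$time)], tri$value)
  expect_equal(max(al2$n), 100)
  # scission alignment takes the external reference
  al3 <- align_traces(list(tri, tri), reference_kind = "scission",
                      reference_times = c(8, 16))
  expect_equal(al3$aligned[[1]]$time[1], -8)
  expect_equal(al3$aligned[[2]]$time[1], -16)
  expect_error(align_traces(list()), "no traces")
})

test_that("bleed-through factor is recovered and matches the quadratic oracle", {
  withr::with_seed(31, {
    g74 <- runif(200, 50, 150); g55 <- runif(200, 0, 30)
    true_red <- runif(200, 20, 40)  # pH-independent
    r74 <- true_red + 0.1 * g74 + rnorm(200, 0, 0.5)
    r55 <- true_red + 0.1 * g55 + rnorm(200, 0, 0.5)
  })
  res <- correct_bleedthrough(r74, r55, g74, g55)
  expect_equal(res$factor, 0.1, tolerance = 0.01)
  # grid-search oracle over the 1-D quadratic objective
  obj <- function(g) sum(((r74 - g * g74) - (r55 - g * g55))^2)
  grid <- seq(0, 0.5, by = 1e-4)
  expect_equal(res$factor, grid[which.min(vapply(grid, obj, numeric(1)))],
               tolerance = 1e-3)
  # zero green: factor 0, red unchanged
  res0 <- correct_bleedthrough(r74, r55, rep(0, 200), rep(0, 200))
  expect_equal(res0$factor, 0)
  expect_equal(res0$corrected_74, r74)
})

test_that("bleed-through recovery stays within 10% across seeds at SNR 10", {
  errs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      g74 <- runif(150, 50, 150); g55 <- runif(150, 0, 30)
      tr <- runif(150, 20, 40)
      noise_sd <- 0.1 * mean(0.1 * (g74 - g55))  # SNR 10 on the pH contrast
      r74 <- tr + 0.1 * g74 + rnorm(150, 0, noise_sd)
      r55 <- tr + 0.1 * g55 + rnorm(150, 0, noise_sd)
    })
    abs(correct_bleedthrough(r74, r55, g74, g55)$factor - 0.1) / 0.1
  }, numeric(1))
  expect_lt(max(errs), 0.1)
})

test_that("shift-null envelope covers the truth under the null", {
  withr::with_seed(77, {
    arr <- array(rnorm(40 * 40 * 15, 100, 5), c(40, 40, 15))
  })
  mv <- movie_stack(arr, (0:14) * 4)
  mask <- matrix(TRUE, 40, 40)
  coords <- data.frame(x = c(12, 25, 30), y = c(15, 20, 31))
  env <- shift_null_envelope(mv, mask, coords, n_shifts = 200, seed = 3)
  expect_equal(env$n_shifts, 200)
  expect_true(all(env$lower <= env$upper))
  truth <- rowMeans(vapply(seq_len(nrow(coords)), function(i)
    measure_fluorescence(mv, coords$x[i], coords$y[i])$value, numeric(15)))
  covered <- mean(truth >= env$lower & truth <= env$upper)
  expect_gte(covered, 0.85)
})

test_that("planted recruitment exceeds the null envelope at its peak", {
  arr <- array(100, c(40, 40, 15))
  coords <- data.frame(x = c(12, 25, 30), y = c(15, 20, 31))
  for (i in seq_len(nrow(coords)))  # recruitment only at frames 7-9
    for (f in 7:9)
      arr[, , f] <- planted_image(40, 40, bg = 0,
                                  spots = data.frame(x = coords$x[i],
                                                     y = coords$y[i],
                                                     amp = 50)) + arr[, , f]
  withr::with_seed(5, arr <- arr + array(rnorm(length(arr), 0, 2), dim(arr)))
  mv <- movie_stack(arr, (0:14) * 4)
  env <- shift_null_envelope(mv, matrix(TRUE, 40, 40), coords,
                             n_shifts = 100, seed = 3)
  truth <- rowMeans(vapply(seq_len(nrow(coords)), function(i)
    measure_fluorescence(mv, coords$x[i], coords$y[i])$value, numeric(15)))
  expect_true(all(truth[8] > env$upper[8]))
  # a tiny mask admits no valid shift
  tiny <- matrix(FALSE, 40, 40); tiny[15, 12] <- TRUE
  expect_error(shift_null_envelope(mv, tiny, coords, n_shifts = 5,
                                   seed = 1, max_tries = 200), "mask")
})

test_that("channel registration recovers planted transforms", {
  withr::with_seed(41, {
    p2 <- cbind(x = runif(12, 5, 60), y = runif(12, 5, 60))
  })
  # identity
  ident <- register_channels(p2, p2)
  expect_equal(unname(ident$A), cbind(diag(2), c(0, 0)), tolerance = 1e-9)
  expect_lt(ident$residual_rms, 1e-9)
  # pure translation by (3.2, -1.7)
  p1 <- sweep(p2, 2, c(-3.2, 1.7))  # p1 = p2 + (3.2, -1.7)
  tr <- register_channels(p1, p2)
  expect_equal(unname(tr$A[, 3]), c(3.2, -1.7), tolerance = 1e-9)
  expect_equal(unname(apply_transform(tr, p2)), unname(p1), tolerance = 1e-9)
  # noisy correspondences: residual equals the normal-equations minimum
  withr::with_seed(42, {
    p1n <- p1 + matrix(rnorm(24, 0, 0.3), ncol = 2)
  })
  fit <- register_channels(p1n, p2)
  X <- cbind(p2, 1)
  B <- solve(t(X) %*% X, t(X) %*% p1n)
  rms <- sqrt(mean(rowSums((p1n - X %*% B)^2)))
  expect_equal(fit$residual_rms, rms, tolerance = 1e-9)
  # collinear beads fall back to translation with a warning
  coll <- cbind(x = 1:5, y = 2 * (1:5))
  expect_warning(fit2 <- register_channels(coll + 1, coll), "translation")
  expect_equal(fit2$type, "translation")
})
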