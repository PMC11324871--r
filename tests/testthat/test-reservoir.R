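test_that("pixel-to-voltage encoding is the anchored linear map", {
  img <- matrix(0, 4, 4)
  expect_true(all(encode_image(img) == 10.5))
  expect_true(all(encode_image(img + 1) == 12.2))
  expect_equal(encode_image(matrix(0.5, 1, 1))[1, 1], 11.35)
  expect_error(encode_image(matrix(1.2, 2, 2)), "normalize")
  expect_error(encode_image(matrix(0.5, 2, 2), v_lo = 12, v_hi = 11), "v_hi")
})

test_that("feature tensors have the binary shape contract", {
  v <- encode_image(matrix(0.3, 6, 5))
  f <- extract_features(v, t_sim = 2, bin_ns = 500, seed = 2)
  expect_equal(dim(f$tensor), c(6, 5, 4))
  expect_true(all(f$tensor %in% c(0L, 1L)))
  expect_equal(length(f$features), 6 * 5 * 4)
  expect_equal(as.integer(f$tensor), f$features)

  # noise-free features are reproducible across calls
  p0 <- reservoir_params(sigma = 0)
  f1 <- extract_features(v, params = p0, t_sim = 2, seed = 1)
  f2 <- extract_features(v, params = p0, t_sim = 2, seed = 99)
  expect_identical(f1$features, f2$features)
})

test_that("softmax readout fits separable data and reports honest curves", {
  set.seed(5)
  n_per <- 20
  y <- rep(0:9, each = n_per)
  X <- matrix(0, length(y), 40)
  X[cbind(seq_along(y), y + 1L)] <- 1          # one-hot by class
  X <- X + matrix(rnorm(length(X), sd = 0.01), nrow(X))
  m <- train_readout(X, y, epochs = 20, seed = 1)
  hist <- m$history
  expect_equal(nrow(hist), 20)
  expect_equal(hist$train_acc[20], 1)
  expect_lt(hist$train_loss[20], hist$train_loss[1])
  # convex objective + small steps: the loss trend is non-increasing
  expect_lt(max(diff(hist$train_loss)), 1e-3)

  pred <- predict(m, X)
  expect_equal(pred, y)
  pr <- predict(m, X, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(X)))
})

test_that("random labels stay at chance on held-out data", {
  set.seed(21)
  X <- matrix(rbinom(200 * 50, 1, 0.3), 200, 50)
  y <- sample(0:9, 200, replace = TRUE)
  Xte <- matrix(rbinom(1000 * 50, 1, 0.3), 1000, 50)
  yte <- sample(0:9, 1000, replace = TRUE)
  m <- train_readout(X, y, epochs = 20, seed = 2)
  acc <- evaluate_readout(m, Xte, yte)$accuracy
  expect_gt(acc, 2)
  expect_lt(acc, 20)
})

test_that("evaluation metrics behave on degenerate predictors", {
  X <- diag(10)
  y <- 0:9
  zero <- structure(list(W = matrix(0, 10, 10), b = c(10, rep(0, 9)),
                         history = NULL, meta = list()),
                    class = "readout_model")
  expect_equal(evaluate_readout(zero, X, y)$accuracy, 10)  # always class 0
  perfect <- structure(list(W = diag(10) * 50, b = rep(0, 10),
                            history = NULL, meta = list()),
                       class = "readout_model")
  expect_equal(evaluate_readout(perfect, X, y)$accuracy, 100)
  # accuracy invariant under sample permutation
  set.seed(3)
  i <- sample(10)
  expect_equal(evaluate_readout(perfect, X[i, ], y[i])$accuracy, 100)
})

test_that("ridge backend solves the separable problem in closed form", {
  y <- rep(0:4, each = 8)
  X <- matrix(0, length(y), 25)
  X[cbind(seq_along(y), y * 5 + 1L)] <- 1
  m <- train_readout(X, y, method = "ridge", lambda = 0.1)
  expect_equal(predict(m, X), y)
})

test_that("IDX reader parses big-endian MNIST-format files", {
  # write a 2-image 3x4 IDX image file and a matching label file
  imgf <- tempfile(); labf <- tempfile()
  con <- file(imgf, "wb")
  writeBin(c(2051L, 2L, 3L, 4L), con, size = 4, endian = "big")
  pix <- as.integer(c(0:11, 255:244))  # image 1 row-major, then image 2
  writeBin(as.raw(pix), con)
  close(con)
  con <- file(labf, "wb")
  writeBin(c(2049L, 2L), con, size = 4, endian = "big")
  writeBin(as.raw(c(7L, 3L)), con)
  close(con)

  imgs <- read_idx(imgf)
  expect_equal(dim(imgs), c(2, 3, 4))
  expect_equal(imgs[1, 1, ], c(0, 1, 2, 3))    # first row of image 1
  expect_equal(imgs[1, 2, 1], 4)
  expect_equal(imgs[2, 1, 1], 255)
  expect_equal(read_idx(labf), c(7L, 3L))
  bad <- tempfile(); writeBin(1234L, bad, size = 4, endian = "big")
  expect_error(read_idx(bad), "magic")
})
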