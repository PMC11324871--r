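#' Encode a grayscale image as per-site input voltages
#'
#' Linear pixel-to-voltage map: a pixel value `x` in `[0, 1]` becomes
#' `v_lo + x (v_hi - v_lo)` volts at the corresponding lattice site. The
#' default range 10.5-12.2 V places every site inside the spiking regime of
#' the synchronized phase, so that pixel intensity modulates spiking
#' frequency and phase rather than switching sites on and off.
#'
#' @param image numeric matrix with values in `[0, 1]` (rescale 0-255 input
#'   first).
#' @param v_lo,v_hi voltage anchors (V) for pixel values 0 and 1.
#' @return A voltage matrix of the same shape.
#' @export
encode_image <- function(image, v_lo = 10.5, v_hi = 12.2) {
  stopifnot(is.matrix(image))
  if (v_hi <= v_lo) stop("v_hi must exceed v_lo")
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop("pixel values must lie in [0, 1]; normalize the image first")
  v_lo + image * (v_hi - v_lo)
}

#' Default device parameters of the reservoir operating point
#'
#' The reservoir runs with a reduced relative thermal capacitance
#' (`cth_scale = 0.15`, i.e. faster heat dissipation and shorter thermal
#' memory) and weak noise (`sigma = 0.2` uJ s^-1/2), placing the array in
#' the synchronized rigid phase where input-voltage variation imprints
#' complex oscillatory patterns.
#'
#' @param ... overrides passed to [device_params()].
#' @return A [device_params()] object.
#' @export
reservoir_params <- function(...) {
  args <- list(...)
  defaults <- list(cth_scale = 0.15, sigma = 0.2)
  do.call(device_params, utils::modifyList(defaults, args))
}

#' Extract binary spike-train features from the reservoir
#'
#' Drives the lattice with the given voltage map for `t_sim` microseconds
#' (no transient discard: the input-driven transient carries the
#' information), detects spikes, coarse-grains them into `bin_ns` windows
#' and binarises each (site, window) cell: 1 if the site spiked in that
#' window. A 28 x 28 image simulated for 10 us at 500 ns bins yields a
#' 28 x 28 x 20 binary tensor, flattened to 15680 features.
#'
#' @param voltages per-site input voltage matrix (V), e.g. from
#'   [encode_image()].
#' @param params device parameters, default [reservoir_params()].
#' @param t_sim simulated duration (us), default 10.
#' @param bin_ns feature bin length (ns), default 500.
#' @param seed RNG seed for the thermal noise.
#' @param spike_threshold,min_separation spike-detection settings (mA, ns).
#' @return A list with `tensor` (integer 0/1 array rows x cols x n_bins)
#'   and `features` (its flattened integer vector).
#' @export
extract_features <- function(voltages, params = reservoir_params(),
                             t_sim = 10, bin_ns = 500, seed = 1,
                             spike_threshold = 1, min_separation = 200) {
  stopifnot(is.matrix(voltages))
  n_bins <- as.integer(round(t_sim * 1e3 / bin_ns))
  cfg <- lattice_config(nrow(voltages), ncol(voltages), v_in = voltages,
                        params = params, t_total = t_sim, t_transient = 0,
                        seed = seed, spike_threshold = spike_threshold,
                        min_separation = min_separation)
  sim <- simulate_lattice(cfg)
  occ <- coarse_grain(sim$spikes, nrow(voltages), ncol(voltages),
                      bin_ns, n_bins)
  tensor <- array(as.integer(occ > 0), dim = dim(occ))
  list(tensor = tensor, features = as.integer(tensor))
}

#' Reservoir features for a batch of images
#'
#' Encodes each image with [encode_image()] and runs one independently
#' seeded reservoir simulation per image.
#'
#' @param images array `n x rows x cols` with pixel values in `[0, 1]`.
#' @param v_lo,v_hi encoder anchors (V).
#' @param params device parameters, default [reservoir_params()].
#' @param t_sim,bin_ns see [extract_features()].
#' @param seed master seed; image `i` uses sub-seed `seed + i`.
#' @param verbose print progress every 50 images.
#' @return An integer feature matrix `n x (rows * cols * n_bins)`.
#' @export
reservoir_features <- function(images, v_lo = 10.5, v_hi = 12.2,
                               params = reservoir_params(), t_sim = 10,
                               bin_ns = 500, seed = 1, verbose = FALSE) {
  stopifnot(length(dim(images)) == 3)
  n <- dim(images)[1]
  n_feat <- dim(images)[2] * dim(images)[3] *
    as.integer(round(t_sim * 1e3 / bin_ns))
  X <- matrix(0L, n, n_feat)
  for (i in seq_len(n)) {
    v <- encode_image(images[i, , ], v_lo, v_hi)
    X[i, ] <- extract_features(v, params, t_sim, bin_ns,
                               seed = (seed + i) %% 2147483647)$features
    if (verbose && i %% 50 == 0) message("  features: ", i, "/", n)
  }
  X
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nll_loss <- function(prob, y) {
  # y is 0-based class labels
  -mean(log(pmax(prob[cbind(seq_len(nrow(prob)), y + 1L)], 1e-12)))
}

#' Train the linear softmax readout
#'
#' Fits a single fully connected layer (`n_features x n_classes` weights
#' plus biases) with softmax activation by minimising the mean negative
#' log-likelihood with the Adam optimiser (default), or by closed-form
#' kernel ridge regression on one-hot targets (`method = "ridge"`). Weights
#' start at zero (the objective is convex) and the per-epoch shuffling is
#' seeded, so training is deterministic.
#'
#' @param x feature matrix `n x n_features`.
#' @param y integer class labels in `0 .. n_classes-1`.
#' @param n_classes number of classes; inferred from `y` by default.
#' @param epochs training epochs, default 20.
#' @param lr Adam learning rate, default 1e-3.
#' @param batch_size minibatch size, default 128.
#' @param seed seed for minibatch shuffling.
#' @param method `"adam"` (softmax + NLL, default) or `"ridge"`.
#' @param lambda ridge penalty when `method = "ridge"`.
#' @param x_test,y_test optional held-out set evaluated once per epoch.
#' @return An object of class `readout_model`: weights `W`, biases `b`, a
#'   per-epoch `history` data frame (train/test loss and accuracy) and the
#'   training metadata.
#' @export
train_readout <- function(x, y, n_classes = NULL, epochs = 20, lr = 1e-3,
                          batch_size = 128, seed = 1,
                          method = c("adam", "ridge"), lambda = 1,
                          x_test = NULL, y_test = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(y)
  if (is.null(n_classes)) n_classes <- max(y) + 1L
  n <- nrow(x); d <- ncol(x)
  if (n < n_classes) stop("need at least one sample per class")
  if (any(y < 0 | y >= n_classes)) stop("labels must lie in 0 .. n_classes-1")
  Y <- matrix(0, n, n_classes); Y[cbind(seq_len(n), y + 1L)] <- 1

  if (method == "ridge") {
    # dual form: W = X' (X X' + lambda I)^-1 Y, bias via a constant feature
    K <- tcrossprod(x) + 1 + diag(lambda, n)
    alpha <- solve(K, Y)
    W <- crossprod(x, alpha)
    b <- colSums(alpha)
    model <- structure(list(W = W, b = b, history = NULL,
                            meta = list(method = "ridge", lambda = lambda,
                                        n_classes = n_classes, seed = seed)),
                       class = "readout_model")
    return(model)
  }

  W <- matrix(0, d, n_classes); b <- numeric(n_classes)
  mW <- W; vW <- W; mb <- b; vb <- b
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  set.seed(seed)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1, n)]
      xb <- x[bi, , drop = FALSE]
      pb <- softmax_rows(xb %*% W + rep(b, each = length(bi)))
      if (any(!is.finite(pb))) stop("NaN loss during readout training")
      G <- (pb - Y[bi, , drop = FALSE]) / length(bi)
      gW <- crossprod(xb, G)
      gb <- colSums(G)
      t_step <- t_step + 1
      mW <- beta1 * mW + (1 - beta1) * gW
      vW <- beta2 * vW + (1 - beta2) * gW^2
      mb <- beta1 * mb + (1 - beta1) * gb
      vb <- beta2 * vb + (1 - beta2) * gb^2
      c1 <- 1 - beta1^t_step; c2 <- 1 - beta2^t_step
      W <- W - lr * (mW / c1) / (sqrt(vW / c2) + eps)
      b <- b - lr * (mb / c1) / (sqrt(vb / c2) + eps)
    }
    ptr <- softmax_rows(x %*% W + rep(b, each = n))
    row <- data.frame(epoch = ep,
                      train_loss = nll_loss(ptr, y),
                      train_acc = mean(max.col(ptr) - 1L == y),
                      test_loss = NA_real_, test_acc = NA_real_)
    if (!is.null(x_test)) {
      pte <- softmax_rows(as.matrix(x_test) %*% W +
                            rep(b, each = nrow(x_test)))
      row$test_loss <- nll_loss(pte, as.integer(y_test))
      row$test_acc <- mean(max.col(pte) - 1L == as.integer(y_test))
    }
    hist[[ep]] <- row
  }
  structure(list(W = W, b = b, history = do.call(rbind, hist),
                 meta = list(method = "adam", epochs = epochs, lr = lr,
                             batch_size = batch_size, n_classes = n_classes,
                             seed = seed)),
            class = "readout_model")
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("linear softmax readout: %d features -> %d classes (%s)\n",
              nrow(x$W), ncol(x$W), x$meta$method))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epochs: train acc %.1f%%", last$epoch,
                100 * last$train_acc))
    if (!is.na(last$test_acc)) cat(sprintf(", test acc %.1f%%", 100 * last$test_acc))
    cat("\n")
  }
  invisible(x)
}

#' Predict classes or probabilities from a readout model
#'
#' @param object a `readout_model`.
#' @param x feature matrix.
#' @param type `"class"` (0-based labels) or `"prob"`.
#' @param ... unused.
#' @return Integer labels or a probability matrix.
#' @export
predict.readout_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  p <- softmax_rows(x %*% object$W + rep(object$b, each = nrow(x)))
  if (type == "prob") p else max.col(p) - 1L
}

#' Evaluate a readout model
#'
#' @param model a `readout_model`.
#' @param x feature matrix.
#' @param y integer labels (0-based).
#' @return A list with `accuracy` (percent) and `nll` (mean negative
#'   log-likelihood).
#' @export
evaluate_readout <- function(model, x, y) {
  y <- as.integer(y)
  p <- predict(model, x, type = "prob")
  list(accuracy = 100 * mean(max.col(p) - 1L == y),
       nll = nll_loss(p, y))
}

#' Read an IDX-format file (MNIST distribution format)
#'
#' Parses the big-endian IDX binary format used to distribute the MNIST
#' handwritten-digit dataset: magic 2049 for label files (returns an
#' integer vector) and 2051 for image files (returns an integer array
#' `n x rows x cols` with values 0-255).
#'
#' @param path an IDX file (uncompressed).
#' @return Labels vector or image array, depending on the magic number.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic == 2049) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    as.integer(readBin(con, "integer", n, size = 1, signed = FALSE))
  } else if (magic == 2051) {
    dims <- readBin(con, "integer", 3, size = 4, endian = "big")
    raw <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
    # file stores images row-major; build n x rows x cols
    aperm(array(as.integer(raw), dim = rev(dims)), c(3, 2, 1))
  } else {
    stop("not an IDX label (2049) or image (2051) file: magic ", magic)
  }
}
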