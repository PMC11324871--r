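#' Synthetic class-conditional images
#'
#' Deterministic stand-in for a handwritten-digit set: each of the
#' `n_classes` classes has a distinct geometric template (bars, bands,
#' blocks and frames at class-specific positions) on an
#' `shape[1] x shape[2]` canvas, and each sample is the template plus
#' seeded Gaussian pixel noise, clipped to `[0, 1]`. At zero noise the
#' within-class images are identical and the classes are linearly separable
#' by construction.
#'
#' @param n_per_class samples per class (>= 1).
#' @param n_classes number of classes, default 10 (templates are defined
#'   for up to 10).
#' @param shape image shape, default `c(28, 28)`.
#' @param noise pixel noise standard deviation, default 0.05.
#' @param seed RNG seed.
#' @return A list with `images` (array `n x rows x cols`, values in
#'   `[0, 1]`) and `labels` (integer vector, 0-based, class of each image).
#' @export
synth_images <- function(n_per_class, n_classes = 10, shape = c(28, 28),
                         noise = 0.05, seed = 1) {
  stopifnot(n_per_class >= 1, n_classes >= 1, n_classes <= 10)
  n <- n_per_class * n_classes
  set.seed(seed)
  images <- array(0, dim = c(n, shape[1], shape[2]))
  labels <- integer(n)
  i <- 0
  for (k in 0:(n_classes - 1)) {
    tmpl <- class_template(k, shape)
    for (j in seq_len(n_per_class)) {
      i <- i + 1
      img <- tmpl
      if (noise > 0)
        img <- img + matrix(stats::rnorm(prod(shape), sd = noise),
                            shape[1], shape[2])
      images[i, , ] <- pmin(pmax(img, 0), 1)
      labels[i] <- k
    }
  }
  list(images = images, labels = labels)
}

# Distinct geometric glyph for class k (0-9) on background 0.05,
# foreground 0.9; positions scale with the canvas.
class_template <- function(k, shape = c(28, 28)) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(0.05, nr, nc)
  ri <- function(f) pmax(1L, pmin(nr, as.integer(round(f * nr))))
  ci <- function(f) pmax(1L, pmin(nc, as.integer(round(f * nc))))
  rr <- row(img); cc <- col(img)
  fg <- switch(as.character(k),
    "0" = rr >= ri(0.45) & rr <= ri(0.6),                       # horizontal bar
    "1" = cc >= ci(0.45) & cc <= ci(0.6),                       # vertical bar
    "2" = (rr >= ri(0.45) & rr <= ri(0.6)) |
          (cc >= ci(0.45) & cc <= ci(0.6)),                     # cross
    "3" = abs(rr - cc) <= 2,                                    # diagonal band
    "4" = abs(rr + cc - (nr + 1)) <= 2,                         # anti-diagonal
    "5" = rr >= ri(0.35) & rr <= ri(0.7) &
          cc >= ci(0.35) & cc <= ci(0.7),                       # centre block
    "6" = (rr >= ri(0.12) & rr <= ri(0.88) &
           cc >= ci(0.12) & cc <= ci(0.88)) &
          !(rr >= ri(0.25) & rr <= ri(0.75) &
            cc >= ci(0.25) & cc <= ci(0.75)),                   # frame
    "7" = rr <= ri(0.35),                                       # top block
    "8" = rr >= ri(0.65),                                       # bottom block
    "9" = (cc >= ci(0.2) & cc <= ci(0.32)) |
          (cc >= ci(0.68) & cc <= ci(0.8)))                     # two bars
  img[fg] <- 0.9
  img
}

#' Sample integer avalanche sizes from a truncated power law
#'
#' Inverse-CDF sampling of the continuous truncated density
#' `p(s) proportional to s^(-exponent)` on `[s_min, s_max + 1)`, floored to
#' integers, giving i.i.d. integer sizes in `[s_min, s_max]`. Used as the
#' sampling oracle for [fit_power_law()].
#'
#' @param exponent power-law exponent (> 1).
#' @param s_min,s_max integer size range (`s_max > s_min >= 1`).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return Integer vector of length `n`.
#' @export
synth_powerlaw_sizes <- function(exponent, s_min = 1, s_max = 1000, n, seed = 1) {
  stopifnot(exponent > 1, s_max > s_min, s_min >= 1, n >= 1)
  set.seed(seed)
  a <- 1 - exponent
  u <- stats::runif(n)
  x <- (s_min^a + u * ((s_max + 1)^a - s_min^a))^(1 / a)
  pmin(as.integer(floor(x)), as.integer(s_max))
}
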