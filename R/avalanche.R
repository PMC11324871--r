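#' Detect spikes in current traces
#'
#' A spike is a strict local maximum of a site's current trace with peak
#' value at least `threshold`, accepted only if it falls at least
#' `min_separation` after the previously accepted spike at that site
#' (greedy, left to right). This is the same rule the streaming detector of
#' [simulate_lattice()] applies on the fly.
#'
#' @param traces a numeric vector (single site) or a time-by-site matrix of
#'   currents (mA), uniformly sampled.
#' @param times_ns sample times (ns), one per row of `traces`.
#' @param threshold minimum peak current (mA), default 1.
#' @param min_separation refractory separation (ns), default 200.
#' @param n_rows,n_cols lattice shape used to map column `k` of `traces` to
#'   site `(row, col) = ((k-1) %% n_rows, (k-1) %/% n_rows)`; defaults to a
#'   single column of sites.
#' @return A time-sorted spike data frame (`row`, `col`, `t_ns`, `peak_mA`).
#' @export
detect_spikes <- function(traces, times_ns, threshold = 1, min_separation = 200,
                          n_rows = NULL, n_cols = NULL) {
  if (is.vector(traces)) traces <- matrix(traces, ncol = 1)
  stopifnot(length(times_ns) == nrow(traces))
  n_sites <- ncol(traces)
  if (is.null(n_rows)) { n_rows <- n_sites; n_cols <- 1L }
  out <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    x <- traces[, k]
    n <- length(x)
    if (n < 3) next
    i <- 2:(n - 1)
    cand <- i[x[i] > x[i - 1] & x[i] > x[i + 1] & x[i] >= threshold]
    if (!length(cand)) next
    keep <- logical(length(cand))
    last <- -Inf
    for (j in seq_along(cand)) {
      tj <- times_ns[cand[j]]
      if (tj - last >= min_separation) {
        keep[j] <- TRUE
        last <- tj
      }
    }
    cand <- cand[keep]
    if (length(cand))
      out[[k]] <- data.frame(row = (k - 1) %% n_rows, col = (k - 1) %/% n_rows,
                             t_ns = times_ns[cand], peak_mA = x[cand])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(row = integer(), col = integer(),
                      t_ns = numeric(), peak_mA = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$t_ns, res$col, res$row), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Coarse-grain spikes onto a space-time occupancy lattice
#'
#' Assigns each spike to the half-open temporal bin
#' `[k w, (k+1) w)` ns of length `window_ns` and counts spikes per
#' `(row, col, bin)` cell, producing the D+1-dimensional lattice on which
#' avalanches are identified.
#'
#' @param spikes a spike data frame (`row`, `col`, `t_ns`).
#' @param n_rows,n_cols lattice shape.
#' @param window_ns temporal bin length (ns), default 400.
#' @param n_windows number of temporal bins; defaults to the smallest count
#'   covering the latest spike.
#' @return An integer array `n_rows x n_cols x n_windows` of spike counts,
#'   with the bin length attached as attribute `window_ns`.
#' @export
coarse_grain <- function(spikes, n_rows, n_cols, window_ns = 400,
                         n_windows = NULL) {
  stopifnot(window_ns > 0)
  bin <- floor(spikes$t_ns / window_ns) + 1L
  if (is.null(n_windows)) n_windows <- max(bin, 1L)
  if (nrow(spikes) && max(bin) > n_windows)
    stop("spike times extend beyond n_windows bins")
  occ <- array(0L, dim = c(n_rows, n_cols, n_windows))
  if (nrow(spikes)) {
    idx <- spikes$row + 1L + n_rows * spikes$col +
      n_rows * n_cols * (bin - 1L)
    tab <- tabulate(idx, nbins = n_rows * n_cols * n_windows)
    occ[] <- tab
  }
  attr(occ, "window_ns") <- window_ns
  occ
}

#' Label avalanches by Hoshen-Kopelman cluster labelling
#'
#' Occupied cells (count >= 1) of the space-time occupancy lattice are
#' clustered with von Neumann adjacency: two cells belong to the same
#' avalanche if they are nearest spatial neighbours in the same temporal
#' bin (within Manhattan distance `spatial_reach`) or the same site in
#' adjacent bins (6-connectivity for `spatial_reach = 1`, no diagonals).
#' Labelling is a single raster scan with union-find label merging
#' (Hoshen-Kopelman). The size of an avalanche is by default the number of
#' spikes it contains (sum of cell counts); `size_measure = "cells"` counts
#' occupied cells instead.
#'
#' @param occupancy an integer array from [coarse_grain()].
#' @param spatial_reach spatial neighbour radius in sites, default 1.
#' @param size_measure `"spikes"` (default) or `"cells"`.
#' @param window_ns temporal bin length (ns), taken from the occupancy
#'   attribute when present.
#' @return An object of class `avalanche_set`: integer `sizes` (one per
#'   avalanche), a `labels` array (0 = empty), and the coarse-graining
#'   metadata.
#' @export
label_avalanches <- function(occupancy, spatial_reach = 1,
                             size_measure = c("spikes", "cells"),
                             window_ns = attr(occupancy, "window_ns")) {
  size_measure <- match.arg(size_measure)
  stopifnot(length(dim(occupancy)) == 3, all(occupancy >= 0))
  d <- dim(occupancy)
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  occ_idx <- which(occupancy > 0)
  labels <- array(0L, dim = d)
  n_occ <- length(occ_idx)
  if (!n_occ) {
    return(structure(list(sizes = integer(), labels = labels,
                          n_windows = nb, window_ns = window_ns,
                          spatial_reach = spatial_reach,
                          size_measure = size_measure),
                     class = "avalanche_set"))
  }

  # spatial offsets within Manhattan distance `spatial_reach`, plus +-1 bin
  offs <- expand.grid(dr = -spatial_reach:spatial_reach,
                      dc = -spatial_reach:spatial_reach)
  offs <- offs[abs(offs$dr) + abs(offs$dc) <= spatial_reach &
                 !(offs$dr == 0 & offs$dc == 0), ]
  offs <- rbind(cbind(offs, db = 0L),
                data.frame(dr = 0L, dc = 0L, db = c(-1L, 1L)))

  parent <- seq_len(n_occ)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }

  ai <- arrayInd(occ_idx, d)
  for (m in seq_len(n_occ)) {
    r <- ai[m, 1]; c <- ai[m, 2]; b <- ai[m, 3]
    labels[occ_idx[m]] <- m
    for (o in seq_len(nrow(offs))) {
      rr <- r + offs$dr[o]; cc <- c + offs$dc[o]; bb <- b + offs$db[o]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || bb < 1 || bb > nb) next
      lab <- labels[rr, cc, bb]
      if (lab > 0L) {
        ra <- find(m); rb <- find(lab)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }

  roots <- vapply(seq_len(n_occ), find, integer(1))
  cl <- match(roots, unique(roots))
  labels[occ_idx] <- cl
  mass <- if (size_measure == "spikes") occupancy[occ_idx] else rep(1L, n_occ)
  sizes <- as.integer(tapply(mass, cl, sum))
  structure(list(sizes = sizes, labels = labels, n_windows = nb,
                 window_ns = window_ns, spatial_reach = spatial_reach,
                 size_measure = size_measure),
            class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("avalanche set: %d avalanches over %d temporal bins (%g ns each)\n",
              length(x$sizes), x$n_windows,
              if (is.null(x$window_ns)) NA else x$window_ns))
  if (length(x$sizes))
    cat(sprintf("  sizes (%s): total %d, max %d\n", x$size_measure,
                sum(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Avalanche sizes of a lattice simulation
#'
#' Convenience chain: coarse-grain the spike train of a simulation at
#' `window_ns` and label avalanches.
#'
#' @param sim a `neuristor_sim`.
#' @param window_ns temporal bin length (ns), default 400.
#' @param spatial_reach spatial neighbour radius, default 1.
#' @param size_measure see [label_avalanches()].
#' @return An `avalanche_set`.
#' @export
avalanches <- function(sim, window_ns = 400, spatial_reach = 1,
                       size_measure = "spikes") {
  stopifnot(inherits(sim, "neuristor_sim"))
  n_windows <- ceiling(sim$duration_us * 1e3 / window_ns)
  occ <- coarse_grain(sim$spikes, sim$n_rows, sim$n_cols, window_ns, n_windows)
  label_avalanches(occ, spatial_reach, size_measure, window_ns)
}

#' Logarithmically binned avalanche-size histogram
#'
#' Bins are uniform in `log10(s)` with width set by Scott's normal
#' reference rule `3.49 sd(log10 s) n^(-1/3)` applied to the
#' log-transformed sizes. Densities are normalised per unit (linear) size,
#' so that `sum(density * linear width) = 1`.
#'
#' @param sizes positive avalanche sizes (non-empty).
#' @param bin_width_log10 optional fixed bin width in decades, overriding
#'   Scott's rule.
#' @return An object of class `size_histogram`: a data frame
#'   (`bin_center`, `density`, `count`, `lo10`, `hi10`) plus the sample
#'   size `n` and a `degenerate` flag (all sizes equal: a single-bin
#'   histogram that cannot support a fit).
#' @export
size_histogram <- function(sizes, bin_width_log10 = NULL) {
  sizes <- as.numeric(sizes)
  if (!length(sizes)) stop("sizes must be non-empty")
  if (any(sizes < 1)) stop("sizes must be >= 1")
  n <- length(sizes)
  ls <- log10(sizes)
  span <- diff(range(ls))
  degenerate <- FALSE
  if (is.null(bin_width_log10)) {
    h <- 3.49 * stats::sd(ls) * n^(-1 / 3)
    if (!is.finite(h) || h <= 0) degenerate <- TRUE
  } else {
    h <- bin_width_log10
    if (h <= 0) stop("bin_width_log10 must be positive")
    if (span == 0) degenerate <- TRUE
  }
  if (degenerate) {
    tab <- data.frame(bin_center = sizes[1], density = NA_real_,
                      count = n, lo10 = ls[1], hi10 = ls[1])
    return(structure(list(table = tab, n = n, degenerate = TRUE,
                          bin_width_log10 = NA_real_),
                     class = "size_histogram"))
  }
  lo <- min(ls)
  # half-open bins [lo + (i-1) h, lo + i h); the maximum always has a bin
  n_bins <- floor(span / h + 1e-9) + 1L
  bin <- pmin(floor((ls - lo) / h) + 1L, n_bins)
  count <- tabulate(bin, nbins = n_bins)
  lo10 <- lo + (seq_len(n_bins) - 1) * h
  hi10 <- lo10 + h
  lin_w <- 10^hi10 - 10^lo10
  tab <- data.frame(bin_center = 10^((lo10 + hi10) / 2),
                    density = count / lin_w / n,
                    count = count, lo10 = lo10, hi10 = hi10)
  structure(list(table = tab, n = n, degenerate = FALSE, bin_width_log10 = h),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  if (x$degenerate) {
    cat("degenerate size histogram (all sizes equal), n =", x$n, "\n")
  } else {
    cat(sprintf("log-binned size histogram: %d bins of %.3f decades, n = %d\n",
                nrow(x$table), x$bin_width_log10, x$n))
  }
  invisible(x)
}

#' Power-law fit of an avalanche-size histogram
#'
#' Least-squares line in `(log10 s, log10 density)` over the bins that
#' survive tail exclusion; the reported exponent is the absolute slope.
#' Two tails are excluded: sparse bins (count below `min_count`), and bins
#' above the terminal upturn of the density -- the finite-size pile-up of
#' system-spanning avalanches that sits at the upper end of boundary-phase
#' histograms (the fit stops at the last density minimum). For a monotone
#' power-law histogram the second rule removes nothing. The fit is flagged
#' unsuccessful when fewer than 3 bins survive or the histogram is
#' degenerate.
#'
#' @param x a [size_histogram()], or a numeric vector of bin centres.
#' @param densities,counts used when `x` is a vector of bin centres:
#'   per-bin densities, and optionally per-bin counts for tail exclusion
#'   (without counts all positive-density bins are used).
#' @param min_count minimum bin count kept in the fit, default 10.
#' @return An object of class `power_law_fit`: `exponent` (absolute value),
#'   `intercept`, `r_squared`, `fit_range` (`[s_lo, s_hi]`), `n_bins_used`,
#'   `success`.
#' @export
fit_power_law <- function(x, densities = NULL, counts = NULL, min_count = 10) {
  if (inherits(x, "size_histogram")) {
    if (x$degenerate)
      return(structure(list(exponent = NA_real_, intercept = NA_real_,
                            r_squared = NA_real_, fit_range = c(NA_real_, NA_real_),
                            n_bins_used = 0L, success = FALSE),
                       class = "power_law_fit"))
    centers <- x$table$bin_center
    densities <- x$table$density
    counts <- x$table$count
  } else {
    centers <- as.numeric(x)
  }
  keep <- is.finite(densities) & densities > 0
  if (!is.null(counts)) keep <- keep & counts >= min_count
  if (sum(keep) >= 3) {
    # upper-tail exclusion: drop the finite-size pile-up past the last
    # density minimum
    ki <- which(keep)
    cut <- ki[which.min(densities[ki])]
    keep[seq_along(keep) > cut] <- FALSE
  }
  if (sum(keep) < 3)
    return(structure(list(exponent = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, fit_range = c(NA_real_, NA_real_),
                          n_bins_used = as.integer(sum(keep)), success = FALSE),
                     class = "power_law_fit"))
  lx <- log10(centers[keep]); ly <- log10(densities[keep])
  fit <- stats::lm(ly ~ lx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(exponent = abs(unname(stats::coef(fit)[2])),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 fit_range = range(centers[keep]),
                 n_bins_used = as.integer(sum(keep)),
                 success = TRUE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (!x$success) {
    cat("power-law fit: failed (", x$n_bins_used, "usable bins )\n")
  } else {
    cat(sprintf("power-law fit: |exponent| = %.3f, r^2 = %.4f, s in [%.3g, %.3g] (%d bins)\n",
                x$exponent, x$r_squared, x$fit_range[1], x$fit_range[2],
                x$n_bins_used))
  }
  invisible(x)
}
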