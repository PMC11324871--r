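# Independent oracles used across the suite.

# Breadth-first-search connected components over the same von Neumann
# space-time adjacency as the Hoshen-Kopelman labeller; returns cluster
# sizes (spike counts or occupied-cell counts).
bfs_avalanche_sizes <- function(occ, spatial_reach = 1,
                                size_measure = "spikes") {
  d <- dim(occ)
  offs <- expand.grid(dr = -spatial_reach:spatial_reach,
                      dc = -spatial_reach:spatial_reach)
  offs <- offs[abs(offs$dr) + abs(offs$dc) <= spatial_reach &
                 !(offs$dr == 0 & offs$dc == 0), ]
  offs <- rbind(cbind(offs, db = 0L),
                data.frame(dr = 0L, dc = 0L, db = c(-1L, 1L)))
  seen <- array(FALSE, dim = d)
  sizes <- integer(0)
  occ_cells <- which(occ > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(occ_cells))) {
    start <- occ_cells[i, ]
    if (seen[start[1], start[2], start[3]]) next
    queue <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    mass <- 0L
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      mass <- mass + if (size_measure == "spikes")
        occ[cell[1], cell[2], cell[3]] else 1L
      for (o in seq_len(nrow(offs))) {
        r <- cell[1] + offs$dr[o]; c <- cell[2] + offs$dc[o]
        b <- cell[3] + offs$db[o]
        if (r < 1 || r > d[1] || c < 1 || c > d[2] || b < 1 || b > d[3]) next
        if (occ[r, c, b] > 0 && !seen[r, c, b]) {
          seen[r, c, b] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c, b)
        }
      }
    }
    sizes <- c(sizes, mass)
  }
  sizes
}

# Brute-force spike scan of one trace: strict local maxima over threshold,
# greedy refractory acceptance.
brute_force_spikes <- function(x, times, threshold = 1, min_sep = 200) {
  out <- numeric(0)
  last <- -Inf
  for (i in seq_along(x)) {
    if (i == 1 || i == length(x)) next
    if (x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] >= threshold &&
        times[i] - last >= min_sep) {
      out <- c(out, times[i])
      last <- times[i]
    }
  }
  out
}

# random sparse occupancy lattice for clustering property tests
random_occupancy <- function(dims, density, max_count = 3) {
  occ <- array(0L, dim = dims)
  n <- prod(dims)
  k <- rbinom(1, n, density)
  idx <- sample.int(n, k)
  occ[idx] <- sample.int(max_count, k, replace = TRUE)
  attr(occ, "window_ns") <- 400
  occ
}

quiet_params <- function(...) device_params(sigma = 0, ...)
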