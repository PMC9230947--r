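# Independent brute-force oracles, written against the definitions (not the
# package code): topographic peak prominence/width/left-base, and a
# floating-point DDA line reference.

# Local maxima via run-length encoding: a value-run is an apex run iff both
# neighbouring runs are strictly lower; the apex index is the floored run
# midpoint.
oracle_local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ks <- which(seq_along(r$values) > 1 & seq_along(r$values) < length(r$values))
  ks <- ks[r$values[ks - 1] < r$values[ks] & r$values[ks + 1] < r$values[ks]]
  as.integer((starts[ks] + ends[ks]) %/% 2L)
}

# For apex p: the search window on each side runs to the nearest strictly
# higher sample (exclusive) or the signal end; the base is the window
# minimum (rightmost/leftmost occurrence nearest the apex); prominence is
# the apex height above the higher of the two minima.
oracle_peak_scan <- function(x) {
  n <- length(x)
  apexes <- if (n >= 3) oracle_local_maxima(x) else integer(0)
  out <- list(apex = integer(0), prominence = double(0), width = double(0),
              left_base = integer(0), right_base = integer(0))
  for (p in apexes) {
    hi_l <- which(x[seq_len(p - 1)] > x[p])
    wl <- (if (length(hi_l)) max(hi_l) + 1L else 1L):(p - 1L)
    left_min <- min(x[wl])
    left_base <- max(wl[x[wl] == left_min])
    hi_r <- p + which(x[(p + 1):n] > x[p])
    wr <- (p + 1L):(if (length(hi_r)) min(hi_r) - 1L else n)
    right_min <- min(x[wr])
    right_base <- min(wr[x[wr] == right_min])
    prom <- x[p] - max(left_min, right_min)
    if (prom <= 0) next
    h <- x[p] - prom / 2
    # left half-prominence crossing: nearest sample at/below h, interpolated
    cand <- wl <- left_base:p
    below <- wl[x[wl] <= h]
    i0 <- max(below)
    left_ip <- if (x[i0] < h) i0 + (h - x[i0]) / (x[i0 + 1] - x[i0]) else i0
    wr <- p:right_base
    below <- wr[x[wr] <= h]
    i1 <- min(below)
    right_ip <- if (x[i1] < h) i1 - (h - x[i1]) / (x[i1 - 1] - x[i1]) else i1
    out$apex <- c(out$apex, p)
    out$prominence <- c(out$prominence, prom)
    out$width <- c(out$width, right_ip - left_ip)
    out$left_base <- c(out$left_base, left_base)
    out$right_base <- c(out$right_base, right_base)
  }
  out
}

# Continuous DDA line: parameter-stepped reference for rasterization checks.
oracle_dda_line <- function(p0, p1) {
  nsteps <- max(abs(p1 - p0))
  if (nsteps == 0) return(cbind(x = p0[1], y = p0[2]))
  ts <- seq(0, 1, length.out = nsteps + 1)
  cbind(x = round(p0[1] + ts * (p1[1] - p0[1])),
        y = round(p0[2] + ts * (p1[2] - p0[2])))
}

# Perpendicular distance from pixel centres to the ideal segment.
oracle_line_distance <- function(px, py, p0, p1) {
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt((px - p0[1])^2 + (py - p0[2])^2))
  t <- pmin(1, pmax(0, ((px - p0[1]) * d[1] + (py - p0[2]) * d[2]) / len2))
  sqrt((p0[1] + t * d[1] - px)^2 + (p0[2] + t * d[2] - py)^2)
}

expect_same_peaks <- function(x, info = NULL) {
  got <- facemark:::peak_scan(as.numeric(x))
  want <- oracle_peak_scan(as.numeric(x))
  expect_identical(got$apex, want$apex, info = info)
  expect_identical(got$left_base, want$left_base, info = info)
  expect_identical(got$right_base, want$right_base, info = info)
  expect_equal(got$prominence, want$prominence, tolerance = 1e-12, info = info)
  expect_equal(got$width, want$width, tolerance = 1e-12, info = info)
}
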