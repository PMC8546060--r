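# Shared internal helpers: seeded evaluation, peak finding with prominences,
# rolling minima, angle wrapping.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

stop_mbk <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_mbk("`%s` must be a single positive finite number", name)
  invisible(x)
}

# Local maxima of y with topographic prominence.  A point i is a peak when
# y[i] is strictly greater than its immediate neighbours (plateaus take the
# first index).  Prominence of a peak: height above the higher of the two
# key saddles, i.e. y[i] - max(min(left segment), min(right segment)) where
# each segment runs to the nearest strictly higher point or the signal end.
find_peaks <- function(y, min_prominence = 0, min_distance = 1L) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(), height = numeric(),
                                prominence = numeric()))
  dy <- diff(y)
  # candidate peaks: rising then (after optional flat run) falling
  idx <- which(dy[-1L] < 0 & dy[-(n - 1L)] > 0) + 1L
  # include plateau starts
  flat <- which(dy == 0)
  if (length(flat)) {
    for (f in flat) {
      i <- f               # y[i] == y[i+1]
      if (i > 1L && y[i] > y[i - 1L]) {
        j <- i
        while (j < n && y[j + 1L] == y[i]) j <- j + 1L
        if (j < n && y[j + 1L] < y[i]) idx <- c(idx, i)
      }
    }
    idx <- sort(unique(idx))
  }
  if (!length(idx)) return(data.frame(index = integer(), height = numeric(),
                                      prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- y[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(y[seq_len(i - 1L)])
    rmin <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1L }
    if (j > n) rmin <- min(y[(i + 1L):n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  # enforce minimum spacing, keeping taller peaks first
  if (min_distance > 1L && length(idx) > 1L) {
    ord <- order(y[idx], decreasing = TRUE)
    sel <- logical(length(idx))
    taken <- integer()
    for (k in ord) {
      if (!length(taken) || all(abs(idx[k] - taken) >= min_distance)) {
        sel[k] <- TRUE
        taken <- c(taken, idx[k])
      }
    }
    idx <- idx[sel]; prom <- prom[sel]
  }
  o <- order(idx)
  data.frame(index = idx[o], height = y[idx][o], prominence = prom[o])
}

# Width of peak `i` at height (peak - rel_height * prominence), by linear
# interpolation of the crossings on each side.  Returns width in samples
# plus the interpolated crossing positions.
peak_width <- function(y, index, prominence, rel_height = 0.5) {
  level <- y[index] - rel_height * prominence
  n <- length(y)
  j <- index
  while (j > 1L && y[j - 1L] > level) j <- j - 1L
  left <- if (j > 1L)
    (j - 1L) + (level - y[j - 1L]) / (y[j] - y[j - 1L]) else j
  j <- index
  while (j < n && y[j + 1L] > level) j <- j + 1L
  right <- if (j < n)
    j + (y[j] - level) / (y[j] - y[j + 1L]) else j
  c(width = right - left, left = left, right = right)
}

# Rolling minimum with a centred window of `k` samples (k odd recommended);
# edges use the available part of the window.
rolling_min <- function(y, k) {
  n <- length(y)
  h <- k %/% 2L
  vapply(seq_len(n), function(i)
    min(y[max(1L, i - h):min(n, i + h)]), numeric(1))
}

# Wrap angles (degrees) to the half-circle (-90, 90].
wrap_half <- function(theta) {
  w <- (theta + 90) %% 180 - 90
  w[w == -90] <- 90
  w
}

# Circular mean of axial data (degrees in (-90, 90]) via angle doubling.
axial_mean <- function(theta) {
  phi <- theta * pi / 90          # doubled angle in radians
  wrap_half(atan2(mean(sin(phi)), mean(cos(phi))) * 90 / pi)
}
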