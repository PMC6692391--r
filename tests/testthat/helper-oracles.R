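# Independent brute-force oracles, kept deliberately naive: each recomputes
# a quantity from its definition, without sharing code with the package.

# Centered truncated-window median of the leading-repeat |diff| series
oracle_rolling_median <- function(z, window_epochs) {
  d <- c(abs(z[2] - z[1]), abs(diff(z)))
  h <- floor(window_epochs / 2)
  n <- length(d)
  sapply(seq_len(n), function(i) {
    median(sort(d[max(1, i - h):min(n, i + h)]))
  })
}

# Linear-interpolation quantile from sorted order statistics (type 7)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  hpos <- (n - 1) * p + 1
  lo <- floor(hpos); hi <- ceiling(hpos)
  s[lo] + (hpos - lo) * (s[hi] - s[lo])
}

# Exhaustive run-length scan over a logical mask
oracle_runs <- function(mask, min_len = 1L) {
  out <- NULL
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, c(i, j + 1L))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) {
    data.frame(start = integer(0), end = integer(0))
  } else {
    data.frame(start = out[, 1L], end = out[, 2L])
  }
}

# Transitive closure of the bout-merging rule, one pass at a time
oracle_merge <- function(bouts, gap_epochs) {
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(bouts)) {
      if (bouts$start[i + 1L] - bouts$end[i] < gap_epochs) {
        bouts$end[i] <- bouts$end[i + 1L]
        bouts <- bouts[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  rownames(bouts) <- NULL
  bouts
}

# Element-by-element Euclidean distance matrix
oracle_distance <- function(x) {
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

# Definition-level silhouette coefficients
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    mine <- setdiff(which(labels == labels[i]), i)
    if (length(mine) == 0L) { s[i] <- 0; next }
    a <- sum(D[i, mine]) / length(mine)
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      other <- which(labels == g)
      b <- min(b, sum(D[i, other]) / length(other))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Exhaustive agglomeration under a linkage rule; returns the merge heights
# and the k-cut partition as a canonical label vector
oracle_agglomerate <- function(D, k, linkage = "complete") {
  clusters <- as.list(seq_len(nrow(D)))
  link <- function(a, b) {
    vals <- D[a, b, drop = FALSE]
    switch(linkage, complete = max(vals), single = min(vals),
           average = mean(vals))
  }
  heights <- numeric(0)
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- link(clusters[[i]], clusters[[j]])
          if (d < best_d) { best_d <- d; best <- c(i, j) }
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best[2L]]
  }
  labels <- integer(nrow(D))
  for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  list(labels = labels, heights = heights)
}

# Do two partitions agree up to relabelling?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Brute-force double-loop GRS
oracle_grs <- function(dosages, weights) {
  out <- numeric(nrow(dosages))
  for (i in seq_len(nrow(dosages))) {
    for (j in seq_len(ncol(dosages))) {
      out[i] <- out[i] + dosages[i, j] * weights[j]
    }
  }
  out
}

# Weighted heterogeneity statistics from their definitions
oracle_cochran_q <- function(ratio, w) {
  beta <- sum(w * ratio) / sum(w)
  sum(w * (ratio - beta)^2)
}
oracle_rucker_q <- function(ratio, w) {
  x <- sqrt(w); y <- ratio * sqrt(w)
  fit <- lm(y ~ x)
  sum(resid(fit)^2)
}

# Tiny exhaustive L5/M10 search over all window starts
oracle_extreme_window <- function(activity, w_epochs, which = "min") {
  n <- length(activity)
  means <- sapply(seq_len(n - w_epochs + 1L), function(i) {
    mean(activity[i:(i + w_epochs - 1L)])
  })
  if (which == "min") which.min(means) else which.max(means)
}
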