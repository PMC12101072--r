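# Independent brute-force oracles. These deliberately re-derive results with
# explicit loops / direct enumeration, never calling the implementation paths
# they check.

# rotational average by direct double-loop enumeration of ring membership
oracle_rotational_average <- function(amp2d) {
  n <- nrow(amp2d)
  ctr <- floor(n / 2) + 1
  rmax <- floor(n / 2)
  sums <- numeric(rmax)
  cnts <- integer(rmax)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- floor(sqrt((i - ctr)^2 + (j - ctr)^2) + 0.5)
      if (r >= 1 && r <= rmax) {
        sums[r] <- sums[r] + amp2d[i, j]
        cnts[r] <- cnts[r] + 1L
      }
    }
  }
  keep <- cnts > 0L
  data.frame(freq_cpi = which(keep), amplitude = sums[keep] / cnts[keep])
}

# largest all-foreground square side by exhaustive search over every position
# and side, using a summed-area table (independent of the DP recurrence)
oracle_inscribed_side <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask))
  sat <- apply(apply(m, 2, cumsum), 1, cumsum)  # sat[j, i] after transpose
  sat <- t(sat)
  area <- function(r0, c0, s) {  # 1-based top-left, inclusive
    r1 <- r0 + s - 1L; c1 <- c0 + s - 1L
    sat[r1, c1] -
      (if (r0 > 1) sat[r0 - 1L, c1] else 0) -
      (if (c0 > 1) sat[r1, c0 - 1L] else 0) +
      (if (r0 > 1 && c0 > 1) sat[r0 - 1L, c0 - 1L] else 0)
  }
  best <- 0L
  for (s in seq_len(min(dim(m)))) {
    found <- FALSE
    for (r0 in seq_len(nrow(m) - s + 1L)) {
      for (c0 in seq_len(ncol(m) - s + 1L)) {
        if (area(r0, c0, s) == s * s) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) best <- s else break
  }
  best
}

# least-squares weights by explicit normal equations
oracle_normal_equations <- function(A, y) {
  solve(t(A) %*% A, t(A) %*% y)[, 1]
}

# iterative 8-neighbour mean fill with explicit loops
oracle_iterative_fill <- function(image, bad) {
  out <- image
  remaining <- bad & TRUE
  nr <- nrow(image); nc <- ncol(image)
  while (any(remaining)) {
    nxt <- remaining
    upd <- out
    progressed <- FALSE
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        if (!remaining[i, j]) next
        vals <- c()
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              !remaining[ii, jj])
            vals <- c(vals, out[ii, jj])
        }
        if (length(vals)) {
          upd[i, j] <- mean(vals)
          nxt[i, j] <- FALSE
          progressed <- TRUE
        }
      }
    }
    if (!progressed) stop("oracle fill stuck")
    out <- upd
    remaining <- nxt
  }
  out
}

make_disc_mask <- function(n, radius, center = (n + 1) / 2) {
  idx <- seq_len(n)
  outer(idx, idx, function(i, j)
    (i - center)^2 + (j - center)^2 <= radius^2)
}

# basis of 5 synthetic gaussian filter curves on a given grid
make_basis <- function(wl = seq(300, 700, by = 2)) {
  peaks <- c(350, 430, 510, 590, 670)
  out <- lapply(peaks, function(p)
    sensitivity_curve(wl, exp(-(wl - p)^2 / (2 * 35^2))))
  names(out) <- paste0("F", seq_along(peaks))
  out
}
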