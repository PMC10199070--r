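# Independent oracles and fixture builders.  Everything here is deliberately
# naive (per-pixel loops, exhaustive enumeration, closed forms) and stays
# independent of the package's vectorized implementations.

# --- scalar Zhang-Suen thinning (reference implementation) ------------------
oracle_zhang_suen <- function(m) {
  m <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  n1 <- nrow(m); n2 <- ncol(m)
  nb <- function(r, c) {
    g <- function(rr, cc) if (rr < 1 || cc < 1 || rr > n1 || cc > n2) 0L else m[rr, cc]
    c(g(r - 1, c), g(r - 1, c + 1), g(r, c + 1), g(r + 1, c + 1),
      g(r + 1, c), g(r + 1, c - 1), g(r, c - 1), g(r - 1, c - 1))
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- NULL
      for (r in 1:n1) for (c in 1:n2) if (m[r, c] == 1L) {
        p <- nb(r, c)
        B <- sum(p)
        A <- sum(p == 0L & c(p[-1], p[1]) == 1L)
        ok <- if (sub == 1) p[1] * p[3] * p[5] == 0 && p[3] * p[5] * p[7] == 0
              else          p[1] * p[3] * p[7] == 0 && p[1] * p[5] * p[7] == 0
        if (B >= 2 && B <= 6 && A == 1 && ok) del <- rbind(del, c(r, c))
      }
      if (!is.null(del)) {
        # same protection rule as the package: keep pixels whose entire
        # neighborhood is deleted in this subpass
        surv <- m
        surv[del] <- 0L
        keep <- vapply(seq_len(nrow(del)), function(k) {
          r <- del[k, 1]; c <- del[k, 2]
          rr <- max(1, r - 1):min(n1, r + 1)
          cc <- max(1, c - 1):min(n2, c + 1)
          sum(surv[rr, cc]) == 0L
        }, logical(1))
        del <- del[!keep, , drop = FALSE]
      }
      if (!is.null(del) && nrow(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# --- exhaustive two-sided rank-sum p-value ----------------------------------
oracle_ranksum_p <- function(x, y) {
  # two-sided by tail doubling (the standard exact convention), with every
  # group assignment enumerated
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# --- polygon geometry from exact vertices -----------------------------------
oracle_polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
oracle_polygon_perimeter <- function(v) {
  d <- rbind(diff(v), v[1, ] - v[nrow(v), ])
  sum(sqrt(rowSums(d^2)))
}
oracle_polygon_feret <- function(v) {
  n <- nrow(v)
  dmax <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    dmax <- max(dmax, sqrt(sum((v[i, ] - v[j, ])^2)))
  dmin <- Inf
  for (i in 1:n) {
    j <- if (i == n) 1 else i + 1
    e <- v[j, ] - v[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(-e[2], e[1]) / len
    proj <- v %*% nrm
    dmin <- min(dmin, max(proj) - min(proj))
  }
  c(dmax = dmax, dmin = dmin)
}

# --- connected components (8-connectivity), naive flood fill ----------------
oracle_n_components <- function(m) {
  m <- m != 0
  lab <- matrix(0L, nrow(m), ncol(m))
  nextl <- 0L
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (!m[r, c] || lab[r, c] != 0L) next
    nextl <- nextl + 1L
    stack <- list(c(r, c)); lab[r, c] <- nextl
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || cc < 1 || rr > nrow(m) || cc > ncol(m)) next
        if (m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextl
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  nextl
}

# --- fixture builders -------------------------------------------------------
disc_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  outer(1:n, 1:n, function(x, y) as.integer((x - cx)^2 + (y - cy)^2 <= r^2))
}
ellipse_mask <- function(n, a, b, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  outer(1:n, 1:n, function(x, y)
    as.integer(((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1))
}

# horizontal 1-px centerline fixtures through simulate_angiogram's override
line_angiogram <- function(n = 200, row = 40, cols = 51:150, width = 1,
                           noise_sd = 0, ...) {
  simulate_angiogram(
    size = n, vessel_width_px = width, noise_sd = noise_sd,
    faz_semi_axes_px = c(10, 8),
    centerlines = list(cbind(row, cols)), seed = 1L, ...)
}

# small noise-free multi-line fixture whose skeleton equals its centerlines
parallel_lines_angiogram <- function(n = 120, rows = seq(10, 110, by = 10),
                                     width = 1, noise_sd = 0) {
  cls <- lapply(rows, function(r) cbind(r, 5:(n - 5)))
  simulate_angiogram(size = n, vessel_width_px = width, noise_sd = noise_sd,
                     faz_semi_axes_px = c(8, 6), centerlines = cls, seed = 1L)
}
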