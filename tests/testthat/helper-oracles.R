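# Independent brute-force reference implementations used as oracles.
# Deliberately naive (double loops, set operations) and kept free of any code
# shared with the package internals.

oracle_gaussian <- function(px, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  K <- outer(k1, k1)
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; w <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        kv <- K[di + r + 1L, dj + r + 1L]
        acc <- acc + kv * px[ii, jj]; w <- w + kv
      }
    }
    out[i, j] <- acc / w
  }
  out
}

oracle_adaptive_threshold <- function(px, window, ratio) {
  r <- (window - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    wi <- max(1L, i - r):min(nr, i + r)
    wj <- max(1L, j - r):min(nc, j + r)
    mu <- mean(px[wi, wj])
    out[i, j] <- px[i, j] < ratio * mu
  }
  out
}

oracle_disc <- function(width) {
  r <- (width - 1L) / 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs[offs$dr^2 + offs$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

oracle_dilate <- function(m, width) {
  offs <- oracle_disc(width)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      ii <- i - offs$dr[[k]]; jj <- j - offs$dc[[k]]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj]) {
        out[i, j] <- TRUE; break
      }
    }
  }
  out
}

oracle_erode <- function(m, width) {
  offs <- oracle_disc(width)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      ii <- i - offs$dr[[k]]; jj <- j - offs$dc[[k]]
      v <- ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj]
      if (!v) { out[i, j] <- FALSE; break }
    }
  }
  out
}

oracle_close <- function(m, width) oracle_erode(oracle_dilate(m, width), width)

# stack-based flood fill, 8-connectivity, components in raster-scan order
oracle_label <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[[1L]] + di; jj <- p[[2L]] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

oracle_largest <- function(m) {
  lab <- oracle_label(m)
  if (max(lab) == 0L) return(m & FALSE)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

oracle_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(x = mean(idx[, 2L] - 1L), y = mean(idx[, 1L] - 1L))
}

# unique-cell counts per interval by explicit set construction
oracle_occupancy <- function(t, x, y, cell, tau) {
  origin <- c(floor(min(x)), floor(min(y)))
  t0 <- t[[1L]]
  k <- ifelse(t == t0, 1L, ceiling((t - t0) / tau))
  counts <- integer(max(k))
  all_cells <- character(0)
  cum <- integer(max(k))
  for (kk in seq_len(max(k))) {
    sel <- k == kk
    cells <- unique(paste(floor((x[sel] - origin[[1L]]) / cell),
                          floor((y[sel] - origin[[2L]]) / cell)))
    counts[[kk]] <- length(cells)
    all_cells <- union(all_cells, cells)
    cum[[kk]] <- length(all_cells)
  }
  list(counts = counts, cumulative = cum)
}

# independent turning-event walker (outbound reference heading)
oracle_turning_events <- function(x, y, theta) {
  m <- length(x)
  if (m < 2L) return(1L)
  hx <- diff(x); hy <- diff(y)
  h <- atan2(hy, hx) * 180 / pi
  h[hx == 0 & hy == 0] <- NA
  for (i in seq_along(h)) if (is.na(h[[i]]) && i > 1L) h[[i]] <- h[[i - 1L]]
  wrap <- function(a) { a <- (a + 180) %% 360 - 180; ifelse(a == -180, 180, a) }
  ev <- 1L
  phi_p <- h[[1L]]
  i <- 2L
  while (i <= m - 1L) {
    phi_c <- h[[i]]
    if (!is.na(phi_c) && !is.na(phi_p) && abs(wrap(phi_c - phi_p)) > theta) {
      ev <- c(ev, i)
      phi_p <- phi_c
    } else if (is.na(phi_p) && !is.na(phi_c)) phi_p <- phi_c
    i <- i + 1L
  }
  ev
}

# naive Clauset lower-cut-off scan using stats::ecdf
oracle_xmin <- function(s, min_tail = 10L) {
  s <- s[s > 0]
  cand <- sort(unique(s))
  best <- NULL; best_d <- Inf
  for (xm in cand) {
    tail <- s[s >= xm]
    n <- length(tail)
    if (n < min_tail) next
    lsum <- sum(log(tail / xm))
    if (lsum <= 0) next
    a <- 1 + n / lsum
    xs <- sort(tail)
    emp_hi <- seq_len(n) / n
    emp_lo <- (seq_len(n) - 1) / n
    Fm <- 1 - (xs / xm)^(1 - a)
    d <- max(abs(Fm - emp_hi), abs(Fm - emp_lo))
    if (d < best_d - 1e-15) { best_d <- d; best <- xm }
  }
  best
}

# strip class/attributes down to a plain logical matrix for comparisons
plain <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# random blob mask fixture: a few random walks stamped on a grid
random_mask <- function(nr, nc, n_blobs = 3L, len = 12L) {
  m <- matrix(FALSE, nr, nc)
  for (b in seq_len(n_blobs)) {
    r <- sample.int(nr, 1L); c <- sample.int(nc, 1L)
    for (s in seq_len(len)) {
      m[r, c] <- TRUE
      r <- min(nr, max(1L, r + sample(-1:1, 1L)))
      c <- min(nc, max(1L, c + sample(-1:1, 1L)))
    }
  }
  m
}
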