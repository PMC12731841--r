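# Independent brute-force oracles for the four texture matrices. These
# loop pixel by pixel straight from the definitions and share no code
# with the package implementations.

# wrap an integer level matrix (0 = outside ROI) as a quantized_image
qimg <- function(lv, Ng = max(lv), spacing = 1) {
  storage.mode(lv) <- "integer"
  quantized_image(lv, as.integer(max(Ng, 2L)),
                  seq(0, 1, length.out = max(Ng, 2L) + 1L), spacing)
}

# random test image with an optional irregular ROI
random_levels <- function(nr, nc, Ng, p_roi = 1) {
  lv <- matrix(sample.int(Ng, nr * nc, replace = TRUE), nr, nc)
  if (p_roi < 1) lv[stats::runif(nr * nc) > p_roi] <- 0L
  storage.mode(lv) <- "integer"
  lv
}

oracle_glcm <- function(lv, Ng, dr, dc, symmetric = TRUE) {
  nr <- nrow(lv); nc <- ncol(lv)
  cnt <- matrix(0, Ng, Ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- lv[r, c]; b <- lv[r2, c2]
    if (a > 0 && b > 0) cnt[a, b] <- cnt[a, b] + 1
  }
  if (symmetric) cnt <- cnt + t(cnt)
  cnt
}

# 8-connected zones by explicit flood fill
oracle_glszm <- function(lv, Ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (lv[r0, c0] == 0 || seen[r0, c0]) next
    level <- lv[r0, c0]
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (!seen[r, c] && lv[r, c] == level) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level, size)
  }
  zm <- do.call(rbind, zones)
  smax <- max(zm[, 2])
  cnt <- matrix(0, Ng, smax)
  for (k in seq_len(nrow(zm))) {
    cnt[zm[k, 1], zm[k, 2]] <- cnt[zm[k, 1], zm[k, 2]] + 1
  }
  cnt
}

# per-pixel neighbour scan; returns the vector of dependence counts in
# pixel order plus the (Ng x Dmax+1) count matrix
oracle_gldm <- function(lv, Ng, alpha = 0, distance = 1) {
  nr <- nrow(lv); nc <- ncol(lv)
  deps <- c(); levs <- c()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lv[r, c] == 0) next
    dep <- 0L
    for (dr in -distance:distance) for (dc in -distance:distance) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (lv[r2, c2] > 0 && abs(lv[r2, c2] - lv[r, c]) <= alpha) {
        dep <- dep + 1L
      }
    }
    deps <- c(deps, dep); levs <- c(levs, lv[r, c])
  }
  cnt <- matrix(0, Ng, max(deps) + 1L)
  for (k in seq_along(deps)) {
    cnt[levs[k], deps[k] + 1L] <- cnt[levs[k], deps[k] + 1L] + 1
  }
  list(counts = cnt, deps = deps, levels = levs)
}

oracle_ngtdm <- function(lv, Ng, distance = 1) {
  nr <- nrow(lv); nc <- ncol(lv)
  s <- numeric(Ng); n <- integer(Ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lv[r, c] == 0) next
    nb <- c()
    for (dr in -distance:distance) for (dc in -distance:distance) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (lv[r2, c2] > 0) nb <- c(nb, lv[r2, c2])
    }
    if (length(nb) == 0) next
    k <- lv[r, c]
    s[k] <- s[k] + abs(k - mean(nb))
    n[k] <- n[k] + 1L
  }
  list(s = s, n = n)
}

# 2 x 2-block checkerboard helper (levels 1/2)
checkerboard <- function(n = 4L) {
  lv <- outer(seq_len(n), seq_len(n), function(r, c) ((r + c) %% 2L) + 1L)
  storage.mode(lv) <- "integer"
  lv
}
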