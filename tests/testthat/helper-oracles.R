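# Independent oracles and fixture builders. Everything here is deliberately
# naive (brute force / first principles) so it cannot share a bug with the
# implementation it checks.

make_disc <- function(size, radius, cx = (size + 1) / 2, cy = cx) {
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  sqrt((row - cy)^2 + (col - cx)^2) <= radius
}

# all-pairs maximum distance between pixel centres
brute_diameter <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d2 <- (pts[i, 1] - pts[-(1:i), 1])^2 + (pts[i, 2] - pts[-(1:i), 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# exhaustive Youden search written independently of roc_cutoff
brute_roc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  best <- NULL
  for (c in sort(unique(scores))) {
    sens <- sum(pos >= c) / length(pos)
    spec <- sum(neg < c) / length(neg)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12)
      best <- list(cutoff = c, sens = sens, spec = spec, j = j)
  }
  best
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 1 else sum(a & b) / u
}

# a 20x20 test image with a hollow rectangle outline drawn in `col`,
# spanning rows/cols r0..r1 (outline pixels on the perimeter)
rect_outline_image <- function(r0 = 6, r1 = 15, col = c(0L, 255L, 0L),
                               size = 20, fill = 40L) {
  px <- array(fill, c(size, size, 3))
  for (ch in 1:3) {
    px[r0, r0:r1, ch] <- col[ch]; px[r1, r0:r1, ch] <- col[ch]
    px[r0:r1, r0, ch] <- col[ch]; px[r0:r1, r1, ch] <- col[ch]
  }
  annotated_image(px, col)
}

# raw vector of length n with exactly the given mean and sd
vector_with_stats <- function(n, m, s, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  m + s * x
}

expect_vicad_error <- function(expr, class) expect_error(expr, class = class)
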