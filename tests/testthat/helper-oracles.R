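# Independent oracles: brute-force or closed-form reference implementations
# kept deliberately separate from the code paths they check.

# enumerate integer offsets of a pixelated disk
oracle_disk_offsets <- function(radius) {
  f <- floor(radius)
  out <- list()
  for (dr in -f:f) for (dc in -f:f)
    if (dr * dr + dc * dc <= radius^2) out[[length(out) + 1L]] <- c(dr, dc)
  do.call(rbind, out)
}

# does a disk centred at 0-based (x, y) share >= 1 pixel with the mask?
oracle_disk_overlaps <- function(mask, x, y, radius) {
  off <- oracle_disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  for (t in seq_len(nrow(off))) {
    r <- y + off[t, 1] + 1L
    c <- x + off[t, 2] + 1L
    if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]) return(TRUE)
  }
  FALSE
}

# brute-force dilation: pixel true iff a disk centred there overlaps mask
oracle_dilate <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (j in seq_len(w)) for (i in seq_len(h))
    out[i, j] <- oracle_disk_overlaps(mask, j - 1L, i - 1L, radius)
  out
}

# brute-force nearest-seed labels (ties -> lowest index), 0-based seeds x,y
oracle_nearest_labels <- function(width, height, pts) {
  lab <- matrix(0L, height, width)
  for (j in seq_len(width)) for (i in seq_len(height)) {
    d2 <- (pts[, "x"] - (j - 1L))^2 + (pts[, "y"] - (i - 1L))^2
    lab[i, j] <- which.min(d2)
  }
  lab
}

# binomial upper tail from the product formula (independent of pbinom)
oracle_binom_tail <- function(c, n, p) {
  if (c == 0) return(1)
  i <- c:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# exhaustive two-sample permutation p by direct enumeration
oracle_perm_p <- function(a, b, test = "rank-sum") {
  pooled <- c(a, b)
  stat <- function(x, y) {
    if (test == "rank-sum")
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    else stats::t.test(x, y)$p.value
  }
  obs <- stat(a, b)
  splits <- utils::combn(length(pooled), length(a))
  ps <- apply(splits, 2, function(ix) stat(pooled[ix], pooled[-ix]))
  mean(ps <= obs)
}

# small synthetic network shared by unit tests (cheap, deterministic)
unit_network <- local({
  cache <- new.env()
  function(seed = 11, size = 128L, target = 0.25, radius = 3) {
    key <- paste(seed, size, target, radius)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_network(size, size, 16, radius, target,
                                       seed = seed)
    cache[[key]]
  }
})

# the acceptance-scale parameter sweep, generated once per test run
acceptance_sweep <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$sweep))
      cache$sweep <- run_parameter_sweep(300, trials_per_image = 2000,
                                         seed = 20260918)
    cache$sweep
  }
})
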