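# Independent brute-force oracles, written as direct formula loops so they
# share no code path with the package implementations they check.

bf_sd_pop <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

bf_sdann <- function(rr, seg) {
  means <- sapply(unique(seg), function(s) mean(rr[seg == s]))
  bf_sd_pop(means)
}

bf_asdnn <- function(rr, seg) {
  mean(sapply(unique(seg), function(s) bf_sd_pop(rr[seg == s])))
}

bf_tri <- function(rr, bw = 1000 / 128) {
  counts <- integer(0)
  for (v in rr) {
    b <- as.character(floor(v / bw))
    counts[b] <- if (is.na(counts[b])) 1L else counts[b] + 1L
  }
  length(rr) / max(counts)
}

# exhaustive 5-beat regression enumeration over a 15-value tachogram
bf_ts <- function(tach) {
  best <- -Inf
  for (s in 1:11) {
    y <- tach[s:(s + 4)]
    fit <- stats::lm(y ~ x, data = data.frame(x = 1:5, y = y))
    best <- max(best, unname(stats::coef(fit)[2]))
  }
  best
}

# explicit anchor-loop PRSA (deceleration or acceleration)
bf_prsa <- function(x, mode, L = 2, flt = 0.05) {
  n <- length(x)
  anchors <- c()
  for (i in 2:n) {
    up <- x[i] > x[i - 1]
    if ((mode == "deceleration") != up) next
    if (x[i] == x[i - 1]) next
    if (abs(x[i] - x[i - 1]) > flt * x[i - 1]) next
    if (i < L + 1 || i > n - L) next
    anchors <- c(anchors, i)
  }
  if (!length(anchors)) return(list(anchors = integer(0), capacity = NA_real_))
  xk <- sapply(-L:(L - 1), function(k) mean(x[anchors + k]))
  names(xk) <- -L:(L - 1)
  list(anchors = anchors,
       capacity = (xk[["0"]] + xk[["1"]] - xk[["-1"]] - xk[["-2"]]) / 4)
}

# O(n^2) Mann-Whitney concordance probability with half-credit ties
bf_auc <- function(scores, labels) {
  pos <- which(labels == "death")
  neg <- which(labels == "survivor")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# random segmented NN series for property loops
random_nn <- function(n = 120, seed = 1) {
  set.seed(seed)
  rr <- stats::runif(n, 600, 1100)
  nn_series(rr, segment_id = ceiling(cumsum(rr) / 20000))
}

# build a clean VPC episode into a constant-800 series at position `at`
plant_vpc <- function(rr, label, at, coupling = 480, to = 0, ts = 0) {
  ref <- mean(rr[(at - 2):(at - 1)])
  rr[at] <- coupling
  rr[at + 1] <- 2 * ref - coupling
  label[at] <- "V"
  off <- numeric(15)
  off[1:2] <- ref * to / 100
  off[3:7] <- off[2] + ts * (1:5)
  off[8:15] <- off[7] * (15 - (8:15)) / 8
  rr[(at + 2):(at + 16)] <- rr[(at + 2):(at + 16)] + off
  list(rr = rr, label = label)
}
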