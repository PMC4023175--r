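#' Select PRSA anchor points
#'
#' Deceleration anchors are positions `i` with `RR(i) > RR(i-1)`,
#' acceleration anchors positions with `RR(i) < RR(i-1)`. Anchors whose
#' relative change exceeds the artifact filter (5% of the preceding interval
#' by default) are excluded, as are anchors within `L` intervals of either
#' end of the series (so the full averaging window exists; no zero-padding).
#'
#' @param nn An [nn_series()].
#' @param mode `"deceleration"` or `"acceleration"`.
#' @param L Half-window length (intervals).
#' @param anchor_filter Maximum relative change admissible at an anchor.
#' @return Integer vector of anchor indices (possibly empty).
#' @export
select_anchors <- function(nn, mode = c("deceleration", "acceleration"),
                           L = 2, anchor_filter = 0.05) {
  stopifnot(inherits(nn, "nn_series"), L >= 1, anchor_filter > 0)
  mode <- match.arg(mode)
  x <- nn$rr
  n <- length(x)
  if (n < 2 * L + 1) return(integer(0))
  i <- 2:n
  d <- x[i] - x[i - 1]
  sel <- if (mode == "deceleration") d > 0 else d < 0
  sel <- sel & abs(d) <= anchor_filter * x[i - 1]
  idx <- i[sel]
  idx[idx >= L + 1 & idx <= n - L]
}

#' Phase-rectified signal averaging capacity
#'
#' Averages the NN series around the selected anchors: for each lag `k` in
#' `-L .. L-1`, `X(k)` is the mean of `RR(anchor + k)` over anchors. The
#' capacity is the central Haar contrast
#' `(X(0) + X(1) - X(-1) - X(-2)) / 4`, positive for deceleration capacity
#' (DC) and negative for acceleration capacity (AC) on physiologic series.
#' A series with no valid anchor has undefined capacity: the result carries
#' `capacity = NA` with zero anchors (distinct from a numeric 0) and a
#' warning is raised.
#'
#' @param nn An [nn_series()].
#' @param mode `"deceleration"` or `"acceleration"`.
#' @param L Half-window length (`L >= 2`; the Haar contrast uses the central
#'   four lags).
#' @param anchor_filter Passed to [select_anchors()].
#' @return Object of class `prsa_result`: list with `window` (named `X(k)`
#'   values), `anchors` (count), `capacity` (ms), `mode`.
#' @export
#' @examples
#' x <- c(rep(800, 10), rep(808, 10))          # one isolated upward step
#' prsa_capacity(nn_series(x), "deceleration")$capacity   # 4
prsa_capacity <- function(nn, mode = c("deceleration", "acceleration"),
                          L = 2, anchor_filter = 0.05) {
  stopifnot(inherits(nn, "nn_series"), L >= 2)
  mode <- match.arg(mode)
  idx <- select_anchors(nn, mode, L = L, anchor_filter = anchor_filter)
  ks <- seq(-L, L - 1)
  if (!length(idx)) {
    warning("no valid ", mode, " anchors: capacity undefined")
    win <- rep(NA_real_, length(ks))
    names(win) <- ks
    return(structure(list(window = win, anchors = 0L, capacity = NA_real_,
                          mode = mode), class = "prsa_result"))
  }
  x <- nn$rr
  win <- vapply(ks, function(k) mean(x[idx + k]), numeric(1))
  names(win) <- ks
  capacity <- (win[["0"]] + win[["1"]] - win[["-1"]] - win[["-2"]]) / 4
  structure(list(window = win, anchors = length(idx), capacity = capacity,
                 mode = mode), class = "prsa_result")
}

#' Deceleration and acceleration capacity of a recording
#'
#' @param nn An [nn_series()].
#' @param L,anchor_filter Passed to [prsa_capacity()].
#' @return List with `dc` and `ac` (ms; `NA` when no anchors exist).
#' @export
prsa_features <- function(nn, L = 2, anchor_filter = 0.05) {
  dc <- prsa_capacity(nn, "deceleration", L = L, anchor_filter = anchor_filter)
  ac <- prsa_capacity(nn, "acceleration", L = L, anchor_filter = anchor_filter)
  list(dc = dc$capacity, ac = ac$capacity)
}
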