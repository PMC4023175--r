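# Population-convention standard deviation (divide by n). Used throughout the
# time-domain indices; the convention is immaterial at 24-h recording lengths
# but matters for exact unit tests.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' SDNN: standard deviation of all NN intervals
#'
#' @param nn An [nn_series()].
#' @return SDNN in ms (population convention).
#' @export
#' @examples
#' sdnn(nn_series(c(700, 900)))   # 100
sdnn <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (!length(nn$rr)) stop("empty NN series")
  sd_pop(nn$rr)
}

#' SDANN and ASDNN over 5-minute segments
#'
#' SDANN is the standard deviation of the per-segment mean NN intervals
#' (slow, between-segment variability); ASDNN is the mean of the per-segment
#' NN standard deviations (fast, within-segment variability). Both use the
#' population SD convention. The series must carry segment indices (see
#' [segment_5min()]) and at least two segments are required for SDANN.
#'
#' @param nn An [nn_series()] with `segment_id`.
#' @return List with `sdann` and `asdnn` (ms).
#' @export
sdann_asdnn <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (is.null(nn$segment_id))
    stop("NN series has no segment indices; run segment_5min() first")
  if (!length(nn$rr)) stop("empty NN series")
  segs <- split(nn$rr, nn$segment_id)
  if (length(segs) < 2)
    stop("SDANN requires at least 2 segments; got ", length(segs))
  list(sdann = sd_pop(vapply(segs, mean, numeric(1))),
       asdnn = mean(vapply(segs, sd_pop, numeric(1))))
}

#' HRV triangular index
#'
#' Total NN count divided by the modal bin count of the NN-interval
#' histogram. The bin width is one sample of the 128 Hz digitization
#' (1000/128 = 7.8125 ms), bins anchored at zero — the conventional
#' discretization for the geometric HRV indices.
#'
#' @param nn An [nn_series()].
#' @param bin_width Histogram bin width in ms.
#' @return Triangular index (unitless, >= 1 for non-empty input).
#' @export
#' @examples
#' triangular_index(nn_series(rep(800, 50)))   # 1: all beats in one bin
triangular_index <- function(nn, bin_width = 1000 / 128) {
  stopifnot(inherits(nn, "nn_series"), bin_width > 0)
  if (!length(nn$rr)) stop("empty NN series")
  bins <- floor(nn$rr / bin_width)
  length(nn$rr) / max(table(bins))
}

#' Mean NN interval and mean heart rate
#'
#' `mean_nn` is the arithmetic mean of the NN intervals; `mean_hr` is the
#' equivalent rate `60000 / mean_nn`, reported in beats per minute.
#'
#' @param nn An [nn_series()].
#' @return List with `mean_nn` (ms) and `mean_hr` (beats/min).
#' @export
mean_rates <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (!length(nn$rr)) stop("empty NN series")
  m <- mean(nn$rr)
  list(mean_nn = m, mean_hr = 60000 / m)
}

#' All time-domain HRV features of a recording
#'
#' Convenience wrapper computing SDNN, SDANN, ASDNN, mean NN, triangular
#' index and mean heart rate from an NN series (segmenting it first if
#' needed).
#'
#' @param nn An [nn_series()]; segmented with [segment_5min()] if it carries
#'   no segment indices.
#' @return One-row data frame with columns `sdnn`, `sdann`, `asdnn`,
#'   `mean_nn`, `tri_index`, `mean_hr`.
#' @export
hrv_time_features <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (is.null(nn$segment_id)) nn <- segment_5min(nn)
  sa <- sdann_asdnn(nn)
  mr <- mean_rates(nn)
  data.frame(sdnn = sdnn(nn), sdann = sa$sdann, asdnn = sa$asdnn,
             mean_nn = mr$mean_nn, tri_index = triangular_index(nn),
             mean_hr = mr$mean_hr)
}
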