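#' Detect usable ventricular-premature-complex episodes
#'
#' Scans the annotated series for `V`-labelled beats and keeps those whose
#' measurement window is clean enough for heart-rate turbulence: two sinus
#' intervals before the coupling interval, the coupling interval itself, a
#' compensatory pause, and the first `n_post` sinus intervals after the
#' pause. Standard eligibility filters apply: coupling interval at most 80%
#' of the reference interval (mean of the two pre-ectopic sinus intervals),
#' compensatory pause at least 120% of it, all window intervals within
#' 300-2000 ms, and no non-sinus beat anywhere in the window (an episode
#' whose post-window contains another ectopic or artifact beat is excluded).
#'
#' @param series An [rr_series()].
#' @param n_post Number of post-pause sinus intervals collected (>= 15
#'   required for the turbulence-slope window rule).
#' @param coupling_max,pause_min Eligibility bounds as fractions of the
#'   reference interval.
#' @param rr_range Admissible interval range (ms) inside the window.
#' @return List of episodes, each a list with `index` (beat index of the
#'   VPC), `pre_rr` (2 values), `coupling`, `pause`, `post_rr` (`n_post`
#'   values).
#' @export
find_vpc_episodes <- function(series, n_post = 15,
                              coupling_max = 0.80, pause_min = 1.20,
                              rr_range = c(300, 2000)) {
  stopifnot(inherits(series, "rr_series"), n_post >= 15)
  n <- nrow(series)
  out <- list()
  for (i in which(series$label == "V")) {
    if (i - 2 < 1 || i + 1 + n_post > n) next
    win <- (i - 2):(i + 1 + n_post)
    lab <- series$label[win]
    # the only non-sinus beat allowed in the window is the VPC itself
    if (any(lab[-3] != "N")) next
    rr <- series$rr[win]
    if (any(rr < rr_range[1] | rr > rr_range[2])) next
    pre <- series$rr[(i - 2):(i - 1)]
    ref <- mean(pre)
    coupling <- series$rr[i]
    pause <- series$rr[i + 1]
    if (coupling > coupling_max * ref) next
    if (pause < pause_min * ref) next
    out[[length(out) + 1]] <- list(index = i, pre_rr = pre,
                                   coupling = coupling, pause = pause,
                                   post_rr = series$rr[(i + 2):(i + 1 + n_post)])
  }
  out
}

#' Turbulence onset
#'
#' Per episode, `TO = 100 * ((RR1 + RR2) - (RR-2 + RR-1)) / (RR-2 + RR-1)`,
#' where `RR-2`, `RR-1` are the two sinus intervals preceding the coupling
#' interval and `RR1`, `RR2` the first two after the compensatory pause. The
#' recording value is the mean over episodes. The physiologic early
#' acceleration gives negative TO.
#'
#' @param episodes Episode list from [find_vpc_episodes()].
#' @return TO in percent.
#' @export
#' @examples
#' ep <- list(list(pre_rr = c(800, 800), post_rr = c(760, 760, rep(800, 13))))
#' turbulence_onset(ep)   # -5
turbulence_onset <- function(episodes) {
  if (!length(episodes)) stop("no eligible VPC episodes: turbulence onset undefined")
  mean(vapply(episodes, function(e) {
    100 * (sum(e$post_rr[1:2]) - sum(e$pre_rr)) / sum(e$pre_rr)
  }, numeric(1)))
}

#' Turbulence slope
#'
#' The post-ectopic tachograms are averaged beat-position-wise over episodes;
#' over the first 15 averaged sinus intervals, a least-squares line is fitted
#' to every run of 5 consecutive values (11 candidate windows) and TS is the
#' maximum slope, in ms per beat.
#'
#' @param episodes Episode list from [find_vpc_episodes()].
#' @return TS in ms/beat.
#' @export
turbulence_slope <- function(episodes) {
  if (!length(episodes)) stop("no eligible VPC episodes: turbulence slope undefined")
  tach <- rowMeans(vapply(episodes, function(e) e$post_rr[1:15], numeric(15)))
  x <- 1:5
  vx <- sum((x - mean(x))^2)
  slopes <- vapply(1:11, function(s) {
    y <- tach[s:(s + 4)]
    sum((x - mean(x)) * (y - mean(y))) / vx
  }, numeric(1))
  max(slopes)
}

#' Heart-rate turbulence of a recording
#'
#' Detects eligible VPC episodes and computes turbulence onset and slope.
#' Recordings without any eligible episode (no ventricular ectopy, or none
#' with a clean window) carry no turbulence value: `available` is `FALSE`
#' and `to`/`ts` are `NA`. Such recordings are the reason turbulence is
#' excluded from feature vectors handed to the classifiers.
#'
#' @param series An [rr_series()].
#' @param ... Passed to [find_vpc_episodes()].
#' @return List with `to`, `ts`, `n_episodes`, `available`.
#' @export
hrt_features <- function(series, ...) {
  ep <- find_vpc_episodes(series, ...)
  if (!length(ep))
    return(list(to = NA_real_, ts = NA_real_, n_episodes = 0L,
                available = FALSE))
  list(to = turbulence_onset(ep), ts = turbulence_slope(ep),
       n_episodes = length(ep), available = TRUE)
}
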