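#' Annotated RR-interval series
#'
#' Constructs a validated beat-by-beat RR series. Each row is one beat: `t`
#' is the beat onset time (ms, cumulative), `rr` the preceding interval (ms)
#' and `label` the beat class (`N` sinus, `V` ventricular, `A` atrial,
#' `X` artifact). Onset times must satisfy `t[i+1] - t[i] == rr[i+1]` up to
#' the 1/128 s quantization of the recording hardware.
#'
#' @param rr Positive intervals (ms).
#' @param label Per-beat labels in `N`, `V`, `A`, `X`.
#' @param t Onset times (ms); defaults to `cumsum(rr)`.
#' @return Object of class `rr_series` (a data frame with columns `t`, `rr`,
#'   `label`).
#' @export
rr_series <- function(rr, label = rep("N", length(rr)), t = cumsum(rr)) {
  rr <- as.numeric(rr); t <- as.numeric(t); label <- as.character(label)
  if (length(rr) != length(label) || length(rr) != length(t))
    stop("t, rr and label must have equal length")
  if (any(rr <= 0)) stop("all RR intervals must be positive")
  bad <- setdiff(unique(label), c("N", "V", "A", "X"))
  if (length(bad)) stop("unknown beat label(s): ", paste(bad, collapse = ", "))
  if (is.unsorted(t)) stop("onset times must be non-decreasing")
  if (length(rr) > 1) {
    q <- 1000 / 128                       # one sample at the 128 Hz digitization
    dt <- diff(t) - rr[-1]
    if (any(abs(dt) > q + 1e-9))
      stop("onset times inconsistent with RR intervals beyond the 1/128 s quantization")
  }
  structure(data.frame(t = t, rr = rr, label = label,
                       stringsAsFactors = FALSE),
            class = c("rr_series", "data.frame"))
}

#' Read an RR annotation file
#'
#' Reads the beat-per-row CSV dialect (`t_ms`, `rr_ms`, `label`) and returns
#' a validated [rr_series()]. Malformed content is rejected with the file row
#' number (1-based, counting the header as row 1) of the first offending
#' line.
#'
#' @param path Path to the CSV file.
#' @return An [rr_series()].
#' @export
read_rr_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("t_ms", "rr_ms", "label")
  if (!all(req %in% names(d)))
    stop("RR file must have columns t_ms, rr_ms, label; got: ",
         paste(names(d), collapse = ", "))
  row_of <- function(i) i + 1L                     # header occupies file row 1
  bad <- which(!is.finite(d$rr_ms) | d$rr_ms <= 0)
  if (length(bad))
    stop("non-positive RR interval at line ", row_of(bad[1]),
         " (rr_ms = ", d$rr_ms[bad[1]], ")")
  bad <- which(!d$label %in% c("N", "V", "A", "X"))
  if (length(bad))
    stop("unknown beat label '", d$label[bad[1]], "' at line ", row_of(bad[1]))
  bad <- which(diff(d$t_ms) < 0)
  if (length(bad))
    stop("non-monotone onset time at line ", row_of(bad[1] + 1L))
  rr_series(rr = d$rr_ms, label = d$label, t = d$t_ms)
}

#' Write an RR annotation file
#'
#' @param series An [rr_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rr_file <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  write.csv(data.frame(t_ms = series$t, rr_ms = series$rr,
                       label = series$label),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sinus-rhythm coverage gate
#'
#' Computes the fraction of total recording time covered by sinus (`N`)
#' beats. Recordings in sinus rhythm for less than the threshold fraction of
#' the recording (80% by default) are rejected from analysis, mirroring the
#' enrolment exclusion rule.
#'
#' @param series An [rr_series()].
#' @param threshold Minimum admissible sinus-time fraction.
#' @return List with `fraction` and logical `pass` (`fraction >= threshold`).
#' @export
sinus_fraction_gate <- function(series, threshold = 0.80) {
  stopifnot(inherits(series, "rr_series"), threshold >= 0, threshold <= 1)
  frac <- sum(series$rr[series$label == "N"]) / sum(series$rr)
  list(fraction = frac, pass = frac >= threshold)
}

#' Normal-to-normal interval series
#'
#' @param rr NN intervals (ms).
#' @param segment_id Optional non-decreasing 5-minute segment index per
#'   interval (see [segment_5min()]).
#' @return Object of class `nn_series`.
#' @export
nn_series <- function(rr, segment_id = NULL) {
  rr <- as.numeric(rr)
  if (any(rr <= 0)) stop("all NN intervals must be positive")
  if (!is.null(segment_id)) {
    segment_id <- as.integer(segment_id)
    if (length(segment_id) != length(rr))
      stop("segment_id must match rr in length")
    if (is.unsorted(segment_id)) stop("segment_id must be non-decreasing")
  }
  structure(list(rr = rr, segment_id = segment_id), class = "nn_series")
}

#' Extract normal-to-normal intervals
#'
#' Keeps interval `i` iff both the beat ending it and the preceding beat are
#' labelled `N`, preserving order. Applied to an `nn_series` it is the
#' identity (the NN filter is idempotent). An input with no NN interval
#' yields an empty `nn_series`, not an error.
#'
#' @param series An [rr_series()] or [nn_series()].
#' @return An [nn_series()].
#' @export
#' @examples
#' s <- rr_series(c(800, 810, 400, 1200, 805), c("N", "N", "V", "N", "N"))
#' extract_nn(s)$rr   # intervals 2 and 5 only
extract_nn <- function(series) UseMethod("extract_nn")

#' @export
extract_nn.rr_series <- function(series) {
  n <- nrow(series)
  if (n < 2) return(nn_series(numeric(0)))
  keep <- series$label[-1] == "N" & series$label[-n] == "N"
  nn_series(series$rr[-1][keep])
}

#' @export
extract_nn.nn_series <- function(series) series

#' @export
length.nn_series <- function(x) length(x$rr)

#' Assign 5-minute segment indices
#'
#' Splits the NN series into contiguous 300 000 ms windows of cumulative NN
#' time (the conventional 5-minute segmentation behind SDANN and ASDNN). A
#' final partial window is kept iff it covers at least 50% of a full window
#' (>= 150 000 ms); otherwise its intervals are dropped.
#'
#' @param nn An [nn_series()].
#' @param segment_ms Window length in ms.
#' @return The [nn_series()] with `segment_id` populated (1-based).
#' @export
segment_5min <- function(nn, segment_ms = 300000) {
  stopifnot(inherits(nn, "nn_series"), segment_ms > 0)
  if (!length(nn$rr)) return(nn_series(numeric(0), integer(0)))
  cum <- cumsum(nn$rr)
  seg <- as.integer(ceiling(cum / segment_ms))
  last <- max(seg)
  last_time <- sum(nn$rr[seg == last])
  if (last_time < segment_ms / 2) {                  # drop under-filled final window
    keep <- seg < last
    return(nn_series(nn$rr[keep], seg[keep]))
  }
  nn_series(nn$rr, seg)
}
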