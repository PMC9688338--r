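#' Butterworth filter chain
#'
#' Applies, in order: third-order Butterworth high-pass at 0.5 Hz, low-pass at
#' 50 Hz, band-stop 47-53 Hz, and band-stop 97-103 Hz.  Every stage is run
#' forward-backward (zero phase) so spike latencies feeding source
#' localization are not shifted; this doubles the effective order.  The
#' 97-103 Hz stop band is skipped with a warning when `fs <= 206` Hz (band
#' above Nyquist); the low-pass and 47-53 Hz stages are likewise skipped for
#' very low sampling rates.
#'
#' @param rec a [sensor_recording()].
#' @return The filtered [sensor_recording()], same shape.
#' @export
apply_filter_chain <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!all(is.finite(rec$data))) stop("non-finite values in recording")
  fs <- rec$fs
  nyq <- fs / 2
  stages <- list(signal::butter(3, 0.5 / nyq, type = "high"))
  if (50 < nyq) {
    stages <- c(stages, list(signal::butter(3, 50 / nyq, type = "low")))
  } else warning("low-pass 50 Hz skipped: above Nyquist")
  if (53 < nyq) {
    stages <- c(stages, list(signal::butter(3, c(47, 53) / nyq, type = "stop")))
  } else warning("band-stop 47-53 Hz skipped: above Nyquist")
  if (fs > 206) {
    stages <- c(stages, list(signal::butter(3, c(97, 103) / nyq, type = "stop")))
  } else warning("band-stop 97-103 Hz skipped: fs <= 206 Hz")
  x <- rec$data
  for (flt in stages)
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(flt, ch)))
  rec$data <- x
  rec
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels, so the re-referenced
#' data have zero channel-mean at each time point.  Idempotent.
#'
#' @param rec a [sensor_recording()] with at least 2 channels.
#' @return Re-referenced [sensor_recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (nrow(rec$data) < 2L)
    stop("common average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Global field power
#'
#' Per-sample spatial standard deviation of the scalp field:
#' \eqn{GFP(t) = \sqrt{\sum_i (u_i(t) - \bar u(t))^2 / N}} over the `N`
#' electrodes.  GFP is independent of the reference: adding a common offset
#' at any sample leaves it unchanged.
#'
#' @param rec a [sensor_recording()] with at least 2 channels.
#' @return List of class `gfp_series` with `values` (non-negative, one per
#'   sample) and `fs`.
#' @export
global_field_power <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (nrow(rec$data) < 2L) stop("GFP needs at least 2 channels")
  centered <- sweep(rec$data, 2L, colMeans(rec$data))
  structure(list(values = sqrt(colMeans(centered^2)), fs = rec$fs),
            class = "gfp_series")
}

# Local maxima / minima of a numeric vector (interior points only).
local_extrema <- function(v) {
  d <- sign(diff(v))
  list(max = which(diff(d) < 0) + 1L,
       min = which(diff(d) > 0) + 1L)
}

# Topographic prominence of peak at index p.
peak_prominence <- function(v, p) {
  n <- length(v)
  l <- p; lmin <- v[p]
  while (l > 1L && v[l - 1L] <= v[p]) { l <- l - 1L; lmin <- min(lmin, v[l]) }
  lbase <- if (l == 1L && v[l] <= v[p]) min(lmin, v[1L]) else lmin
  r <- p; rmin <- v[p]
  while (r < n && v[r + 1L] <= v[p]) { r <- r + 1L; rmin <- min(rmin, v[r]) }
  rbase <- if (r == n && v[r] <= v[p]) min(rmin, v[n]) else rmin
  v[p] - max(lbase, rbase)
}

#' Detect spike events on a GFP trace
#'
#' Finds GFP local maxima with topographic prominence at least
#' `min_prominence`; for each retained peak, locates the preceding local
#' minimum and returns the sample at the temporal midpoint of the ascending
#' limb (rounding half down).  Peaks closer together than `refractory`
#' seconds collapse to the larger one, so a multi-spike discharge train
#' yields a single event at its (largest) first spike.
#'
#' @param gfp a `gfp_series` from [global_field_power()].
#' @param min_prominence minimum peak prominence, same units as the GFP.
#'   `NULL` uses 5 times the median GFP, a level comfortably above background
#'   fluctuations yet below epileptiform peaks in the synthetic cohort.
#' @param refractory minimum peak separation in seconds.
#' @return Integer vector of strictly increasing event samples.
#' @export
detect_spike_events <- function(gfp, min_prominence = NULL, refractory = 2) {
  stopifnot(inherits(gfp, "gfp_series"))
  v <- gfp$values
  if (length(v) < 3L) return(integer(0))
  if (refractory < 0) stop("refractory must be >= 0")
  if (is.null(min_prominence)) min_prominence <- 5 * stats::median(v)
  ext <- local_extrema(v)
  peaks <- ext$max
  if (length(peaks) == 0L) return(integer(0))
  prom <- vapply(peaks, function(p) peak_prominence(v, p), numeric(1))
  peaks <- peaks[prom >= min_prominence]
  if (length(peaks) == 0L) return(integer(0))
  # refractory: greedy acceptance in decreasing peak height
  keep <- logical(length(peaks))
  ord <- order(v[peaks], decreasing = TRUE)
  min_gap <- refractory * gfp$fs
  acc <- integer(0)
  for (k in ord) {
    if (all(abs(peaks[k] - acc) >= min_gap)) {
      keep[k] <- TRUE
      acc <- c(acc, peaks[k])
    }
  }
  peaks <- sort(peaks[keep])
  mins <- ext$min
  ev <- vapply(peaks, function(p) {
    m <- mins[mins < p]
    m <- if (length(m)) max(m) else 1L
    as.integer(floor((m + p) / 2))
  }, integer(1))
  unique(ev)
}

#' Extract event-locked GSW epochs
#'
#' Cuts windows of `pre` seconds before to `post` seconds after each event.
#' Events closer together than the epoch length are treated as one
#' spike-wave train and merged to the first spike, which anchors the epoch.
#' Events whose window would cross a recording edge are skipped with a
#' warning.
#'
#' @param rec a [sensor_recording()].
#' @param events integer event samples (from [detect_spike_events()]).
#' @param pre,post window half-lengths in seconds.
#' @return An [epoch_set()] with state `"GSW"`.
#' @export
extract_epochs <- function(rec, events, pre = 2, post = 2) {
  stopifnot(inherits(rec, "sensor_recording"))
  fs <- rec$fs
  events <- sort(as.integer(events))
  ep_len <- round((pre + post) * fs)
  # merge trains: keep an event only if >= epoch length after the last kept
  kept <- integer(0)
  for (e in events)
    if (length(kept) == 0L || e - kept[length(kept)] >= ep_len)
      kept <- c(kept, e)
  n_samp <- ncol(rec$data)
  starts <- kept - round(pre * fs)
  ok <- starts >= 1L & (starts + ep_len - 1L) <= n_samp
  if (any(!ok))
    warning(sum(!ok), " event(s) skipped: window outside the recording")
  kept <- kept[ok]; starts <- starts[ok]
  arr <- array(0, dim = c(length(kept), nrow(rec$data), ep_len))
  for (i in seq_along(kept))
    arr[i, , ] <- rec$data[, starts[i]:(starts[i] + ep_len - 1L)]
  epoch_set(arr, fs, state = "GSW", events = kept, window = c(-pre, post),
            channel_labels = rec$channel_labels)
}

#' Select resting-state epochs away from events
#'
#' Draws `n` non-overlapping windows of `dur` seconds, every sample of which
#' lies at least `guard` seconds from every event, uniformly at random over
#' the admissible grid (seeded, hence reproducible).
#'
#' @param rec a [sensor_recording()].
#' @param exclude integer event samples to stay clear of.
#' @param n number of epochs required.
#' @param dur epoch duration, seconds.
#' @param guard minimum distance from any event, seconds.
#' @param seed integer seed for the placement draw.
#' @return An [epoch_set()] with state `"RS"`.
#' @export
select_rs_epochs <- function(rec, exclude, n, dur = 4, guard = 2,
                             seed = 1L) {
  stopifnot(inherits(rec, "sensor_recording"))
  fs <- rec$fs
  ep_len <- round(dur * fs)
  n_samp <- ncol(rec$data)
  if (n == 0L)
    return(epoch_set(array(0, c(0L, nrow(rec$data), ep_len)), fs,
                     state = "RS", events = integer(0), window = c(0, dur),
                     channel_labels = rec$channel_labels))
  g <- round(guard * fs)
  cand <- seq(1L, n_samp - ep_len + 1L, by = max(1L, round(fs / 4)))
  admissible <- vapply(cand, function(s) {
    if (length(exclude) == 0L) return(TRUE)
    all(exclude < s - g | exclude > s + ep_len - 1L + g)
  }, logical(1))
  cand <- cand[admissible]
  set.seed(seed)
  starts <- integer(0)
  pool <- sample(cand)
  for (s in pool) {
    if (length(starts) == n) break
    if (all(abs(s - starts) >= ep_len)) starts <- c(starts, s)
  }
  if (length(starts) < n) {
    # random placement can strand windows; earliest-first greedy packs the
    # maximum number of non-overlapping epochs
    starts <- integer(0)
    for (s in cand) {
      if (length(starts) == n) break
      if (all(abs(s - starts) >= ep_len)) starts <- c(starts, s)
    }
  }
  if (length(starts) < n)
    stop("insufficient spike-free data: needed ", n, " epochs, found ",
         length(starts))
  starts <- sort(starts)
  arr <- array(0, dim = c(n, nrow(rec$data), ep_len))
  for (i in seq_len(n))
    arr[i, , ] <- rec$data[, starts[i]:(starts[i] + ep_len - 1L)]
  epoch_set(arr, fs, state = "RS", events = starts, window = c(0, dur),
            channel_labels = rec$channel_labels)
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Stand-in for expert visual artifact rejection: an epoch is dropped when
#' any sample of any channel exceeds `threshold` in absolute value.
#'
#' @param es an [epoch_set()].
#' @param threshold amplitude bound (same units as the data).
#' @return The [epoch_set()] with offending epochs removed.
#' @export
reject_artifact_epochs <- function(es, threshold = 150) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_epochs(es) == 0L) return(es)
  bad <- apply(es$data, 1L, function(m) any(abs(m) > threshold))
  es$data <- es$data[!bad, , , drop = FALSE]
  es$events <- es$events[!bad]
  es
}
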