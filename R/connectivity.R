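all_freqs_default <- function() 1:12

# Welch-averaged cross-spectral accumulation.
# X: nodes x samples.  Returns list(S = bins x nodes x nodes complex
# cross-spectral sums, n_seg, bin_freqs).  Accumulation (not averaging) so
# multiple epochs can be pooled before forming coherency.
welch_accumulate <- function(X, fs, bins, seg_len = round(fs),
                             overlap = 0.5, S = NULL, n_seg = 0L) {
  n <- nrow(X); n_samp <- ncol(X)
  L <- as.integer(seg_len)
  if (n_samp < L) stop("record shorter than one spectral segment")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n_samp - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hann
  if (is.null(S)) S <- array(0 + 0i, dim = c(length(bins), n, n))
  for (s0 in starts) {
    seg <- X[, s0:(s0 + L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, w, "*")
    F <- stats::mvfft(t(seg))            # L x n, rows = frequency bins
    for (b in seq_along(bins)) {
      v <- F[bins[b], ]
      S[b, , ] <- S[b, , ] + outer(v, Conj(v))
    }
  }
  list(S = S, n_seg = n_seg + length(starts),
       bin_freqs = (bins - 1L) * fs / L)
}

# frequency (Hz) -> FFT bin index for segment length L at rate fs
freq_to_bin <- function(freqs, fs, L) as.integer(round(freqs * L / fs)) + 1L

#' Complex coherency between two signals
#'
#' Welch estimate with 1-s Hann segments and 50% overlap (so integer
#' frequencies map to integer bins at integer sampling rates):
#' \eqn{C_{xy}(f) = S_{xy}(f) / \sqrt{S_{xx}(f) S_{yy}(f)}}.  The magnitude
#' is bounded by 1; the phase reflects the lag between the signals.  A
#' frequency with zero power in either signal yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate, Hz.
#' @param freqs frequencies to evaluate (Hz, below Nyquist); each is mapped
#'   to its nearest Welch bin.
#' @param seg_len spectral segment length in samples (default 1 s).
#' @return Complex vector, one coherency per requested frequency, named by
#'   frequency.
#' @export
coherency <- function(x, y, fs, freqs = all_freqs_default(),
                      seg_len = round(fs)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(freqs >= fs / 2)) stop("frequencies must be below Nyquist")
  bins <- freq_to_bin(freqs, fs, seg_len)
  acc <- welch_accumulate(rbind(x, y), fs, bins, seg_len = seg_len)
  out <- complex(length(freqs))
  for (b in seq_along(bins)) {
    sxx <- Re(acc$S[b, 1L, 1L]); syy <- Re(acc$S[b, 2L, 2L])
    if (sxx <= 0 || syy <= 0) {
      warning("zero power at ", freqs[b], " Hz; coherency set to 0")
      out[b] <- 0
    } else out[b] <- acc$S[b, 1L, 2L] / sqrt(sxx * syy)
  }
  names(out) <- freqs
  out
}

#' Imaginary part of coherence across node pairs
#'
#' For each node pair and each requested frequency, computes the imaginary
#' part of the complex coherency, with cross-spectra pooled over every Welch
#' segment of every epoch before the normalization (estimator consistency
#' across epochs).  The imaginary part is insensitive to instantaneous
#' (zero-lag) mixing such as volume conduction: identical or linearly mixed
#' signals contribute only to the real part.
#'
#' @param roi_activity epochs x nodes x samples array (or nodes x samples
#'   matrix for a single epoch) of source/ROI time courses.
#' @param fs sampling rate, Hz.
#' @param freqs frequencies in Hz (default 1-12).
#' @param seg_len Welch segment length in samples (default 1 s).
#' @return Array `freqs x nodes x nodes` of signed ImCoh values in [-1, 1],
#'   antisymmetric, zero diagonal; dimnames carry the frequencies.
#' @export
imaginary_coherence_matrix <- function(roi_activity, fs,
                                       freqs = all_freqs_default(),
                                       seg_len = round(fs)) {
  if (is.matrix(roi_activity))
    roi_activity <- array(roi_activity,
                          dim = c(1L, nrow(roi_activity), ncol(roi_activity)))
  d <- dim(roi_activity)
  if (length(d) != 3L) stop("roi_activity must be epochs x nodes x samples")
  if (d[1L] < 1L) stop("need at least one epoch")
  if (d[2L] < 2L) stop("need at least two nodes")
  if (d[3L] < 2L) stop("single-sample epochs are not analyzable")
  bins <- freq_to_bin(freqs, fs, seg_len)
  S <- NULL; n_seg <- 0L
  for (e in seq_len(d[1L])) {
    acc <- welch_accumulate(roi_activity[e, , ], fs, bins,
                            seg_len = seg_len, S = S, n_seg = n_seg)
    S <- acc$S; n_seg <- acc$n_seg
  }
  n <- d[2L]
  out <- array(0, dim = c(length(freqs), n, n),
               dimnames = list(freqs, NULL, NULL))
  for (b in seq_along(bins)) {
    p <- Re(diag(S[b, , ]))
    denom <- sqrt(outer(p, p))
    bad <- denom <= 0
    if (any(bad[upper.tri(bad)]))
      warning("zero-power node at ", freqs[b], " Hz; ImCoh set to 0")
    C <- S[b, , ] / pmax(denom, .Machine$double.eps)
    im <- Im(C)
    im[bad] <- 0
    diag(im) <- 0
    out[b, , ] <- im
  }
  out
}

#' Per-subject connectivity tensor for one state
#'
#' Stacks per-subject ImCoh matrices into a subjects x frequencies x nodes x
#' nodes tensor tagged with its state.
#'
#' @param activity_list list (one element per subject) of epochs x nodes x
#'   samples arrays for the same node set.
#' @param fs sampling rate, Hz.
#' @param state `"GSW"` or `"RS"`.
#' @param freqs frequencies in Hz.
#' @param node_labels optional node labels.
#' @return Array of class `connectivity_tensor`, subjects x freqs x nodes x
#'   nodes, with attributes `state`, `freqs`, `node_labels`.
#' @export
connectivity_tensor <- function(activity_list, fs, state = c("GSW", "RS"),
                                freqs = all_freqs_default(),
                                node_labels = NULL) {
  state <- match.arg(state)
  mats <- lapply(activity_list, imaginary_coherence_matrix, fs = fs,
                 freqs = freqs)
  n <- dim(mats[[1L]])[2L]
  out <- array(0, dim = c(length(mats), length(freqs), n, n))
  for (s in seq_along(mats)) out[s, , , ] <- mats[[s]]
  structure(out, state = state, freqs = freqs,
            node_labels = node_labels, class = "connectivity_tensor")
}
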