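#' Noise covariance from resting-state data
#'
#' Sample covariance across time of the channels, averaged over epochs when an
#' [epoch_set()] is supplied, with diagonal loading
#' `epsilon * trace / n_channels` added for numerical invertibility (the
#' covariance of average-referenced data is otherwise rank-deficient).
#'
#' @param x an [epoch_set()], a [sensor_recording()], or a channels x samples
#'   matrix with at least 2 samples.
#' @param epsilon relative diagonal loading.
#' @return Symmetric positive semi-definite channels x channels matrix.
#' @export
estimate_noise_covariance <- function(x, epsilon = 1e-6) {
  mats <- if (inherits(x, "epoch_set")) {
    lapply(seq_len(n_epochs(x)), function(i) x$data[i, , ])
  } else if (inherits(x, "sensor_recording")) list(x$data) else list(as.matrix(x))
  n_ch <- nrow(mats[[1L]])
  if (ncol(mats[[1L]]) < 2L) stop("need at least 2 samples")
  covs <- lapply(mats, function(m) {
    if (any(apply(m, 1L, stats::sd) == 0))
      warning("zero-variance channel in noise epoch")
    stats::cov(t(m))
  })
  C <- Reduce(`+`, covs) / length(covs)
  C <- (C + t(C)) / 2
  C + diag(epsilon * sum(diag(C)) / n_ch, n_ch)
}

#' sLORETA inverse solution
#'
#' Standardized low-resolution electromagnetic tomography: the minimum-norm
#' kernel \eqn{K = G^T (G G^T + \lambda C)^{-1}} (with `G` the lead field and
#' `C` the noise covariance) gives current estimates \eqn{\hat j = K\,data},
#' which are then standardized source-wise by the square root of the
#' resolution-matrix diagonal \eqn{[K G]_{ii}}.  This standardization is what
#' grants the method zero localization error for a single noiseless source.
#'
#' The regularization is set as
#' \eqn{\lambda = \mathrm{tr}(G G^T) / (\mathrm{tr}(C)\,\mathrm{SNR}^2)},
#' an SNR-based heuristic with `snr = 3` by default; pass `lambda_rel` to
#' override the \eqn{1/\mathrm{SNR}^2} factor directly (e.g. `1e-8` for a
#' near-unregularized solve on noiseless data).
#'
#' @param lf sensors x sources lead-field matrix (full row rank).
#' @param ncov sensors x sensors noise covariance.
#' @param epoch channels x samples data matrix (channel count must match the
#'   lead field's sensor count).
#' @param snr assumed amplitude SNR used for regularization.
#' @param lambda_rel optional explicit relative regularization, overriding
#'   `1 / snr^2`.
#' @return List of class `source_estimate` with `activity` (sources x
#'   samples, standardized and hence dimensionless), `fs` (if supplied), and
#'   `kernel`.
#' @param fs optional sampling rate to carry along.
#' @export
sloreta_solve <- function(lf, ncov, epoch, snr = 3, lambda_rel = NULL,
                          fs = NULL) {
  lf <- as.matrix(lf); epoch <- as.matrix(epoch)
  if (nrow(epoch) != nrow(lf))
    stop("epoch channel count must equal the lead-field sensor count")
  if (is.null(lambda_rel)) lambda_rel <- 1 / snr^2
  gg <- tcrossprod(lf)
  lambda <- lambda_rel * sum(diag(gg)) / sum(diag(ncov))
  M <- gg + lambda * ncov
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular sensor covariance model; increase regularization ",
         "(lambda_rel) or supply a loaded noise covariance"))
  K <- crossprod(lf, Minv)               # sources x sensors
  resdiag <- rowSums(K * t(lf))          # diag(K %*% G)
  if (any(resdiag <= 0))
    stop("non-positive resolution diagonal; lead field may be degenerate")
  act <- (K %*% epoch) / sqrt(resdiag)
  structure(list(activity = act, fs = fs, kernel = K,
                 resolution_diag = resdiag),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d sources x %d samples\n",
              nrow(x$activity), ncol(x$activity)))
  invisible(x)
}

#' Select maximum-energy ROIs at events
#'
#' For each event sample, finds the source with the greatest squared
#' standardized activity summed over a `window`-sample half-width around the
#' event (default: the event sample alone).  Ties go to the lower source
#' index, with a message.  The union of winners over events defines the
#' network's node set.
#'
#' @param src a `source_estimate`.
#' @param events integer sample indices within the estimate.
#' @param label_map character vector mapping source index to region label
#'   (names optional); must cover every winning index.
#' @param window half-width in samples of the energy window.
#' @return List of class `roi_set`: `rois` data frame (event, source, label)
#'   and `nodes` (unique winning sources with multiplicity).
#' @export
select_rois <- function(src, events, label_map, window = 0L) {
  stopifnot(inherits(src, "source_estimate"))
  n_samp <- ncol(src$activity)
  events <- as.integer(events)
  if (any(events < 1L | events > n_samp))
    stop("events outside the epoch's sample range")
  winners <- vapply(events, function(e) {
    win <- max(1L, e - window):min(n_samp, e + window)
    en <- rowSums(src$activity[, win, drop = FALSE]^2)
    w <- which(en == max(en))
    if (length(w) > 1L) message("energy tie at event ", e,
                                ": lower source index chosen")
    w[1L]
  }, integer(1))
  if (any(winners > length(label_map)) || anyNA(label_map[winners]))
    stop("label map missing an entry for a winning source")
  tab <- table(winners)
  structure(list(rois = data.frame(event = events, source = winners,
                                   label = label_map[winners]),
                 nodes = data.frame(source = as.integer(names(tab)),
                                    label = label_map[as.integer(names(tab))],
                                    multiplicity = as.integer(tab))),
            class = "roi_set")
}

#' Identity label map for synthetic source spaces
#'
#' @param n_sources number of sources.
#' @return Character vector `src001 ... srcN`.
#' @export
identity_label_map <- function(n_sources) {
  sprintf("src%03d", seq_len(n_sources))
}
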