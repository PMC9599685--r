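#' Analytic signal of band-filtered epochs, with edge trimming
#'
#' Hilbert transform (FFT method) per trial and channel, then removal of a
#' fraction of samples at both ends, where the transform's circularity
#' distorts instantaneous phase. The retained length is
#' `floor(samples * (1 - 2 * trim_fraction))`.
#'
#' @param epochs A band-filtered `epoch_tensor`.
#' @param trim_fraction Fraction of samples discarded per end, in \[0, 0.5).
#' @return An `analytic_set`: complex trials x channels x samples array
#'   with the epoch attributes carried over.
#' @export
analytic_signal <- function(epochs, trim_fraction = 0.10) {
  stopifnot(inherits(epochs, "epoch_tensor"),
            trim_fraction >= 0, trim_fraction < 0.5)
  if (is.null(attr(epochs, "band")))
    warning("epochs carry no band label; Hilbert phase is only meaningful ",
            "for narrow-band signals")
  d <- dim(epochs)
  n <- d[3]
  keep_n <- floor(n * (1 - 2 * trim_fraction))
  left <- (n - keep_n) %/% 2
  keep <- (left + 1):(left + keep_n)
  h <- numeric(n)                       # analytic-signal FFT multiplier
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  # one batched FFT over all trial/channel series (columns)
  x <- matrix(aperm(unclass(epochs), c(3, 2, 1)), n, d[2] * d[1])
  z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  z <- array(z[keep, , drop = FALSE], dim = c(keep_n, d[2], d[1]))
  out <- aperm(z, c(3, 2, 1))
  structure(out, class = "analytic_set",
            sampling_rate = attr(epochs, "sampling_rate"),
            channel_labels = attr(epochs, "channel_labels"),
            trial_ids = attr(epochs, "trial_ids"),
            subject_id = attr(epochs, "subject_id"),
            condition = attr(epochs, "condition"),
            band = attr(epochs, "band"),
            trim_fraction = trim_fraction)
}

#' Weighted phase lag index (WPLI) connectivity matrix
#'
#' For each channel pair (x, y) and trial, the cross-spectrum
#' `Sxy(t) = a_x(t) * Conj(a_y(t))` of the analytic signals is formed and
#' `WPLI = |<|Im Sxy| sign(Im Sxy)>| / <|Im Sxy|>`, with `< >` the time
#' average over retained samples. Zero-lag components have `Im Sxy = 0`
#' and therefore no influence; a pair whose denominator vanishes is set to
#' 0 by convention. With `average = "pooled"` (default) all trials'
#' retained samples enter one expectation; `"within_trial"` computes one
#' WPLI per trial and averages trial values. The pooled form is the
#' default because the per-trial ratio carries a small-sample positive
#' bias of order `1/sqrt(samples_per_trial)` that trial averaging cannot
#' remove, which would defeat the estimator's insensitivity to zero-lag
#' (volume-conducted) components at realistic trial lengths.
#'
#' @param analytic An `analytic_set`.
#' @param average `"pooled"` or `"within_trial"`.
#' @return A `conn_matrix`: symmetric channels x channels matrix in
#'   \[0, 1\], zero diagonal, with `band`, `subject_id`, `condition`,
#'   `n_trials` attributes.
#' @export
wpli <- function(analytic, average = c("pooled", "within_trial")) {
  stopifnot(inherits(analytic, "analytic_set"))
  average <- match.arg(average)
  d <- dim(analytic)
  if (d[3] < 2) stop("need at least 2 retained samples per trial")
  n_ch <- d[2]
  pairs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  # stack trials: (samples * trials) x channels; real arithmetic for speed:
  # Im(a conj(b)) = Im(a) Re(b) - Re(a) Im(b)
  A <- matrix(aperm(analytic, c(3, 1, 2)), d[3] * d[1], n_ch)
  ra <- Re(A); ia <- Im(A)
  im <- ia[, pairs[, 1]] * ra[, pairs[, 2]] -
    ra[, pairs[, 1]] * ia[, pairs[, 2]]
  dim(im) <- c(d[3], d[1] * nrow(pairs))
  if (average == "within_trial") {
    num <- abs(colMeans(im))
    den <- colMeans(abs(im))
    w_tr <- ifelse(den > 0, num / den, 0)
    dim(w_tr) <- c(d[1], nrow(pairs))
    w <- colMeans(w_tr)
  } else {
    dim(im) <- c(d[3] * d[1], nrow(pairs))
    num <- abs(colMeans(im))
    den <- colMeans(abs(im))
    w <- ifelse(den > 0, num / den, 0)
  }
  m <- matrix(0, n_ch, n_ch,
              dimnames = list(attr(analytic, "channel_labels"),
                              attr(analytic, "channel_labels")))
  m[cbind(pairs[, 1], pairs[, 2])] <- w
  m <- m + t(m)
  structure(m, class = c("conn_matrix", "matrix"),
            band = attr(analytic, "band"),
            subject_id = attr(analytic, "subject_id"),
            condition = attr(analytic, "condition"),
            n_trials = d[1])
}

#' Mean connectivity over all channel pairs
#'
#' Arithmetic mean of the strict upper triangle (435 pairs for 30
#' channels).
#'
#' @param matrix A symmetric connectivity matrix.
#' @return Scalar mean.
#' @export
mean_wpli <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  mean(matrix[upper.tri(matrix)])
}

#' Per-channel mean connectivity
#'
#' Entry i is the mean of row i excluding the diagonal.
#'
#' @param matrix A symmetric connectivity matrix.
#' @return Named numeric vector, one entry per channel.
#' @export
channel_mean_wpli <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix), nrow(matrix) > 1)
  out <- (rowSums(matrix) - diag(matrix)) / (ncol(matrix) - 1)
  names(out) <- rownames(matrix)
  out
}

#' Event-related WPLI: baseline-normalised change rate
#'
#' Elementwise `(W - R) / R` of the aiming-window matrix against the
#' pre-event baseline matrix. Baseline entries below `floor` are replaced
#' by `floor` (the ratio is undefined at R = 0); affected pairs are
#' reported in the `floored` attribute, never silently.
#'
#' @param aiming,baseline Conformable symmetric connectivity matrices.
#' @param floor Small positive guard for vanishing baseline entries.
#' @return An `erwpli_matrix` (values >= -1, zero diagonal).
#' @export
erwpli <- function(aiming, baseline, floor = 1e-6) {
  if (!all(dim(aiming) == dim(baseline)))
    stop("aiming and baseline matrices have different shapes")
  stopifnot(floor > 0)
  low <- which(baseline < floor & upper.tri(baseline), arr.ind = TRUE)
  r <- pmax(unclass(baseline), floor)
  m <- (unclass(aiming) - unclass(baseline)) / r
  diag(m) <- 0
  structure(m, class = c("erwpli_matrix", "matrix"),
            band = attr(aiming, "band"),
            subject_id = attr(aiming, "subject_id"),
            condition = attr(aiming, "condition"),
            floored = low)
}

#' Write a connectivity matrix as labelled square CSV
#'
#' @param matrix Connectivity (or ERWPLI) matrix with channel dimnames.
#' @param path Output file.
#' @export
write_conn_csv <- function(matrix, path) {
  df <- data.frame(channel = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a labelled square connectivity CSV
#'
#' @param path File written by [write_conn_csv()].
#' @return Numeric matrix with channel dimnames.
#' @export
read_conn_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
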