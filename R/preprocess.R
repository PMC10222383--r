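# Raw record -> fixed-length, z-scored, DFT-augmented feature matrices.
# Each beat window of length L (256 at 500 Hz, 200 at 1000 Hz) becomes an
# L x 2 matrix: channel 1 the normalized time-domain segment, channel 2 the
# z-scored magnitude of its full-length discrete Fourier transform, turning
# an L x 1 input into the L x 2 representation the encoder consumes.

REFRACTORY_S <- 0.2  # minimum separation between detected R peaks, seconds

#' Detect R peaks in a single-lead record
#'
#' Energy-based QRS detector in the Pan-Tompkins tradition: band-pass
#' (5-15 Hz Butterworth, zero-phase), differentiate, square, integrate over
#' a 150 ms moving window, threshold at a fixed fraction of the peak
#' integrated energy, then refine each candidate to the raw-signal maximum
#' within 100 ms. A 200 ms refractory period is enforced; when two
#' candidates collide the larger raw amplitude wins. Assumes an upright
#' (positive) R wave.
#'
#' @param record An [ecg_record()] of at least one second.
#' @param threshold_frac Detection threshold as a fraction of the maximum
#'   integrated energy (default 0.3).
#' @return Strictly increasing integer sample indices (possibly empty).
#' @export
detect_r_peaks <- function(record, threshold_frac = 0.3) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) < fs) abort_invalid("record must be at least 1 second long")
  if (stats::sd(x) == 0) return(integer(0))

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bp, x)
  energy <- c(0, diff(filtered))^2
  w <- max(1L, round(0.15 * fs))
  integ <- stats::filter(energy, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  thr <- threshold_frac * max(integ)
  if (thr <= 0) return(integer(0))
  half <- max(1L, round(0.1 * fs))
  # local maxima of the integrated energy above threshold
  cand <- which(integ > thr)
  cand <- cand[vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(integ), i + half)
    integ[i] >= max(integ[lo:hi])
  }, logical(1))]
  if (length(cand) == 0L) return(integer(0))
  # refine to the raw-signal maximum near each candidate
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # refractory: greedy left-to-right, keep the larger raw amplitude
  min_gap <- round(REFRACTORY_S * fs)
  keep <- integer(0)
  for (i in refined) {
    if (length(keep) == 0L || i - keep[length(keep)] >= min_gap) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  as.integer(keep)
}

#' Beat-anchored segment
#'
#' A fixed-length window around one R peak, z-scored to zero mean and unit
#' standard deviation. The R peak sits at 1-based position
#' `floor(0.4 * L) + 1`, i.e. 40% of the window precedes R.
#'
#' @param values Numeric vector of length `L` (normalized voltages).
#' @param subject_id Subject label.
#' @param r_index 1-based position of the anchoring R peak in the window.
#' @return An object of class `ecg_segment`.
#' @export
ecg_segment <- function(values, subject_id, r_index) {
  structure(list(values = as.numeric(values), L = length(values),
                 subject_id = subject_id, r_index = as.integer(r_index)),
            class = "ecg_segment")
}

#' Cut beat windows around detected R peaks
#'
#' One window per peak, `floor(0.4 * L)` samples before the R peak and the
#' rest after; windows that would cross a record boundary are discarded.
#' Each kept window is z-scored per segment; constant windows are discarded
#' with a warning.
#'
#' @param record An [ecg_record()].
#' @param peaks Integer R-peak sample indices (e.g. from
#'   [detect_r_peaks()]).
#' @param L Window length in samples; at least 32 and even.
#' @return List of [ecg_segment()] objects.
#' @export
segment_record <- function(record, peaks, L) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is_count(L) || L < 32 || L %% 2 != 0) {
    abort_invalid("L must be an even integer >= 32")
  }
  L <- as.integer(L)
  pre <- as.integer(floor(0.4 * L))
  n <- length(record$samples)
  out <- list()
  for (p in as.integer(peaks)) {
    start <- p - pre
    end <- start + L - 1L
    if (start < 1L || end > n) next  # boundary-crossing window: discard
    v <- record$samples[start:end]
    s <- stats::sd(v)
    if (s == 0) {
      warning("discarding constant segment at peak ", p, call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- ecg_segment((v - mean(v)) / s,
                                           record$subject_id, pre + 1L)
  }
  out
}

#' Discrete Fourier transform
#'
#' Forward transform `X[k] = sum_n x[n] exp(-i 2 pi k n / N)` for
#' `k = 0 ... N-1`, and its inverse `x[n] = (1/N) sum_k X[k] exp(i 2 pi k n
#' / N)`. `dft` is computed with the fast Fourier transform; for real input
#' the coefficients satisfy the conjugate symmetry `X[N-k] = Conj(X[k])`.
#' `idft` returns the real part of the inverse; for spectra of real signals
#' the imaginary residue is at floating-point level.
#'
#' @param values Real numeric vector (finite).
#' @param spectrum Complex coefficient vector as returned by `dft`.
#' @return `dft`: complex vector of length `N`; `idft`: real vector of
#'   length `N`.
#' @export
dft <- function(values) {
  if (length(values) < 1L) abort_invalid("dft input must be non-empty")
  if (!all(is.finite(values))) abort_invalid("dft input must be finite")
  stats::fft(values)
}

#' @rdname dft
#' @export
idft <- function(spectrum) {
  if (length(spectrum) < 1L) abort_invalid("idft input must be non-empty")
  if (!all(is.finite(Re(spectrum))) || !all(is.finite(Im(spectrum)))) {
    abort_invalid("idft input must be finite")
  }
  Re(stats::fft(spectrum, inverse = TRUE)) / length(spectrum)
}

#' Build the L x 2 feature matrix for one segment
#'
#' Channel 1 is the (already normalized) time-domain segment, unchanged.
#' Channel 2 is the z-scored magnitude spectrum `|X[k]|, k = 0 ... L-1` of
#' the segment — the full-length transform, so an `L x 1` segment becomes
#' exactly `L x 2`.
#'
#' @param segment An [ecg_segment()].
#' @return An `L x 2` numeric matrix with columns `time` and `dft_mag` and
#'   attributes `subject_id` and `r_index`.
#' @export
featurize <- function(segment) {
  stopifnot(inherits(segment, "ecg_segment"))
  mag <- Mod(dft(segment$values))
  s <- stats::sd(mag)
  if (s == 0) abort_invalid("constant magnitude spectrum cannot be z-scored")
  fm <- cbind(time = segment$values, dft_mag = (mag - mean(mag)) / s)
  attr(fm, "subject_id") <- segment$subject_id
  attr(fm, "r_index") <- segment$r_index
  fm
}

#' Preprocess a record end to end
#'
#' Detect R peaks (or use the supplied ones), cut and normalize beat
#' windows, and featurize each into an L x 2 matrix.
#'
#' @param record An [ecg_record()].
#' @param L Window length; defaults to the preset's length.
#' @param preset Preset name (see [ecg_preset()]); used for `L` when `L` is
#'   missing.
#' @param peaks Optional R-peak indices; detected when `NULL`.
#' @return List of feature matrices.
#' @export
preprocess_record <- function(record, L = NULL, preset = "ecgid-like",
                              peaks = NULL) {
  if (is.null(L)) L <- ecg_preset(preset)$L
  if (is.null(peaks)) peaks <- detect_r_peaks(record)
  segs <- segment_record(record, peaks, L)
  lapply(segs, featurize)
}
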