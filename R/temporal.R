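#' Interpolate an irregular landmark stream to a uniform frame rate
#'
#' Raw capture rates vary between roughly 30 and 60 fps and are not
#' constant, so all streams are re-gridded before feature extraction: the
#' output grid is `t_k = t_0 + k / targetFps` for
#' `k = 0 ... floor((t_last - t_0) * targetFps)`, and every landmark
#' coordinate and blendshape score at `t_k` is the linear interpolation
#' between the two raw frames bracketing `t_k`. No extrapolation is
#' performed: the grid starts at the first raw timestamp and ends at or
#' before the last.
#'
#' @param stream A [LandmarkStream] with at least 2 frames.
#' @param targetFps Target frame rate in frames/second (default 30).
#' @return A uniform [LandmarkStream] at `targetFps`.
#' @export
interpolateStream <- function(stream, targetFps = 30) {
  stopifnot(is(stream, "LandmarkStream"))
  if (length(targetFps) != 1L || !is.finite(targetFps) || targetFps <= 0) {
    stop("targetFps must be a single positive number")
  }
  tt <- frameTimes(stream)
  if (length(tt) < 2L) stop("interpolation requires at least 2 frames")
  k <- 0:floor((tt[length(tt)] - tt[1]) * targetFps)
  tk <- tt[1] + k / targetFps
  tk[tk > tt[length(tt)]] <- tt[length(tt)]  # guard fp overshoot on last point

  idx <- findInterval(tk, tt, rightmost.closed = TRUE)
  idx[idx >= length(tt)] <- length(tt) - 1L
  w <- (tk - tt[idx]) / (tt[idx + 1L] - tt[idx])

  lm <- landmarks(stream)
  d <- dim(lm)
  flat <- matrix(lm, nrow = d[1])                   # n x (478*3)
  outFlat <- flat[idx, , drop = FALSE] * (1 - w) +
    flat[idx + 1L, , drop = FALSE] * w
  outLm <- array(outFlat, dim = c(length(tk), d[2], d[3]))

  bs <- blendshapes(stream)
  outBs <- bs[idx, , drop = FALSE] * (1 - w) + bs[idx + 1L, , drop = FALSE] * w
  # interpolation can leave values a hair outside [0,1] from fp rounding
  outBs[] <- pmin(1, pmax(0, outBs))
  colnames(outBs) <- colnames(bs)
  LandmarkStream(tk, outLm, outBs)
}

#' Resample an audio track to a target rate
#'
#' All responses are brought to a common analysis rate (22,050 Hz by
#' default) before acoustic feature extraction. Resampling is done in the
#' Fourier domain (spectrum truncation or zero-padding, the ideal
#' brick-wall interpolation), which preserves both the amplitude and the
#' energy of band-limited content exactly; duration is preserved to within
#' one sample period.
#'
#' @param track An [AudioTrack].
#' @param targetRate Target sampling frequency in Hz (default 22050).
#' @return An [AudioTrack] at `targetRate`.
#' @export
resampleAudio <- function(track, targetRate = 22050) {
  stopifnot(is(track, "AudioTrack"))
  if (length(samples(track)) == 0L) stop("cannot resample an empty track")
  if (targetRate <= 0) stop("targetRate must be positive")
  sr <- sampleRate(track)
  if (sr == targetRate) return(track)
  x <- samples(track)
  n <- length(x)
  m <- max(1L, round(n * targetRate / sr))
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  h <- min(n %/% 2L, m %/% 2L)
  Y[seq_len(h)] <- X[seq_len(h)]
  if (h > 1L) Y[(m - h + 2L):m] <- X[(n - h + 2L):n]
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  AudioTrack(pmin(1, pmax(-1, y)), targetRate, track@responseIndex)
}
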