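## Synthetic parcellated BOLD cohort with planted, severity-scaled effects.
##
## The background process in every region is Gaussian noise band-limited to
## 0.008--0.2 Hz plus one random-phase sinusoid per filter-bank band (at the
## band's center frequency, fixed amplitude), so each feature family
## (intensity, band power, sinusoid overlap) takes non-degenerate,
## session-stable values. Patients receive two optional perturbations in
## the configured affected regions, both scaled by severity relative to the
## severity median: a fluctuation-amplitude multiplier and a multiplicative
## power change in one filter-bank band.

# amplitude of the fluctuation process relative to baseline intensity
.FLUCT_SCALE <- 20

# amplitude of each band-center oscillator relative to unit-sd noise
.OSC_AMP <- 0.5

# multiply the spectral power of x inside [lo, hi) by powMult
scaleBandPower <- function(x, fs, lo, hi, powMult) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided bin frequencies
  sel <- f >= lo & f < hi
  X <- fft(x)
  X[sel] <- X[sel] * sqrt(powMult)
  Re(fft(X, inverse = TRUE)) / n
}

# ideal band-pass by rectangular masking of the DFT
bandpassFFT <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X <- fft(x)
  X[!(f >= lo & f < hi)] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Generate the participant table of a synthetic cohort
#'
#' Builds the four-cell cohort (F/M crossed with PD/control) described by a
#' \linkS4class{CohortConfig}. Patient severity scores are log-normal;
#' controls score 0 and contribute a single session. Each participant's
#' draws come from a dedicated RNG substream, so enlarging the cohort never
#' changes existing participants.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return data.frame with columns participant_id, sex, diagnosis,
#'   severity_score, n_sessions.
#' @export
generateParticipants <- function(config) {
  validObject(config)
  cells <- expand.grid(sex = c("F", "M"), diagnosis = c("PD", "control"),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sex <- cells$sex[ci]
    dx <- cells$diagnosis[ci]
    for (i in seq_len(config@nPerGroup)) {
      pid <- sprintf("%s-%s-%03d", sex, ifelse(dx == "PD", "pd", "hc"), i)
      draw <- withSeed(deriveSeed(config@seed, idCode(pid), 0L), {
        sev <- if (dx == "PD")
          rlnorm(1, config@severityMeanlog, config@severitySdlog) else 0
        ns <- if (dx == "PD") {
          rng <- config@sessionsPerPatientRange
          if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
        } else 1L
        list(sev = sev, ns = as.integer(ns))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, sex = sex, diagnosis = dx,
        severity_score = draw$sev, n_sessions = draw$ns,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate one participant-session's ROI time series
#'
#' Frame count and repetition time are drawn uniformly from the configured
#' intervals, independently per session. The draw uses an RNG substream
#' derived from (root seed, participant id, session index), so the same
#' triple always yields the same matrix.
#'
#' @param record one row of the participant table (see
#'   \code{\link{generateParticipants}}).
#' @param config the \linkS4class{CohortConfig}.
#' @param sessionIndex 1-based session number; must not exceed the record's
#'   n_sessions.
#' @param bank \linkS4class{FilterBank} defining the planted band's
#'   frequency interval.
#' @return A \linkS4class{RoiTimeSeriesSet}.
#' @export
generateRoiTimeSeries <- function(record, config, sessionIndex,
                                  bank = buildFilterBank()) {
  validObject(config)
  if (sessionIndex < 1L || sessionIndex > record$n_sessions)
    stop("sessionIndex ", sessionIndex, " out of range for participant ",
         record$participant_id, " (", record$n_sessions, " sessions)")
  isPatient <- record$diagnosis == "PD"
  sevScale <- record$severity_score / exp(config@severityMeanlog)
  bandIv <- bandBounds(bank)[config@bandEffectBand, ]
  sseed <- deriveSeed(config@seed, idCode(record$participant_id),
                      sessionIndex)
  mat <- withSeed(sseed, {
    rng <- config@nTimepointsRange
    n <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    tr <- runif(1, config@trRangeS[1], config@trRangeS[2])
    fs <- 1 / tr
    tt <- (seq_len(n) - 1) * tr
    m <- matrix(0, config@nRegions, n)
    for (r in seq_len(config@nRegions)) {
      bg <- bandpassFFT(rnorm(n), fs, 0.008, 0.2)
      s <- sd(bg)
      if (s > 0) bg <- bg / s
      fr <- bandCenters(bank)
      ph <- runif(length(fr), 0, 2 * pi)
      osc <- drop(rep(.OSC_AMP, length(fr)) %*%
                    sin(outer(2 * pi * fr, tt) + ph))
      x <- bg + osc
      baseline <- runif(1, 700, 900)
      if (isPatient && r %in% config@affectedRegions) {
        powMult <- max(1 + (config@bandEffectFactor - 1) * sevScale, 1e-6)
        if (powMult != 1)
          x <- scaleBandPower(x, fs, bandIv[1], bandIv[2], powMult)
        x <- x * (1 + config@amplitudeEffect * sevScale)
      }
      m[r, ] <- baseline + .FLUCT_SCALE * x
    }
    attr(m, "tr") <- tr
    m
  })
  tr <- attr(mat, "tr")
  attr(mat, "tr") <- NULL
  roiTimeSeriesSet(mat, tr, record$participant_id,
                   sprintf("ses-%02d", sessionIndex))
}

#' Generate a full synthetic cohort
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param bank \linkS4class{FilterBank} defining the planted band.
#' @return list with \code{participants} (data.frame) and
#'   \code{timeseries} (list of \linkS4class{RoiTimeSeriesSet}, one per
#'   participant-session).
#' @export
generateCohort <- function(config, bank = buildFilterBank()) {
  participants <- generateParticipants(config)
  tss <- list()
  for (i in seq_len(nrow(participants))) {
    rec <- participants[i, ]
    for (s in seq_len(rec$n_sessions))
      tss[[length(tss) + 1L]] <- generateRoiTimeSeries(rec, config, s, bank)
  }
  list(participants = participants, timeseries = tss)
}
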