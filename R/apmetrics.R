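# AP shape metrics via moving-average subtraction (MAS). The centered moving
# average minus the trace peaks where the trace has a convex corner (AP
# takeoff and the late-repolarization slow-down) and dips where it has a
# concave one (end of the rapid upstroke), giving detectors that need no
# derivative estimate and are insensitive to the smoothing window.

#' MAS configuration
#'
#' Window sizes are expressed in samples at 1 kHz and rescaled automatically
#' to the trace's sampling rate so the physical width is preserved.
#'
#' @param upstrokeWindow odd window, samples at 1 kHz, for takeoff/upstroke
#'   detection (default 45).
#' @param repolWindow odd window for the repolarization (APDmxr) search;
#'   must be >= upstrokeWindow (default 91).
#' @param apDetectFrac fraction of the median per-recording beat amplitude a
#'   beat must reach to be called excitable (default 0.3).
#' @param searchSpan upstroke search span after each stimulus, ms; capped at
#'   the pacing interval (default 300).
#' @param mxrGuard gap after upstroke completion, ms, before the APDmxr
#'   search starts so the upstroke's own MAS peak is excluded (default 20).
#' @param baselineWindow window before the next stimulus, ms, whose median
#'   defines the beat's subsequent baseline (default 20).
#' @param mxrMinFrac minimum MAS secondary-peak height, as a fraction of the
#'   beat amplitude, below which APDmxr is undefined (default 0.001).
#' @param minSnr absolute excitability floor: a beat's amplitude must also
#'   exceed \code{minSnr} times a robust noise estimate
#'   (\code{mad(diff(x))/sqrt(2)}), so an AP-free noise recording is not
#'   declared excitable by the relative rule alone (default 5).
#' @return a validated list of class "MASConfig".
#' @export
masConfig <- function(upstrokeWindow = 45, repolWindow = 91,
                      apDetectFrac = 0.3, searchSpan = 300, mxrGuard = 20,
                      baselineWindow = 20, mxrMinFrac = 0.001, minSnr = 5) {
  stopifnot(upstrokeWindow %% 2 == 1, repolWindow %% 2 == 1,
            repolWindow >= upstrokeWindow, apDetectFrac >= 0,
            searchSpan > 0, mxrGuard >= 0, baselineWindow > 0, minSnr >= 0)
  structure(list(upstrokeWindow = upstrokeWindow, repolWindow = repolWindow,
                 apDetectFrac = apDetectFrac, searchSpan = searchSpan,
                 mxrGuard = mxrGuard, baselineWindow = baselineWindow,
                 mxrMinFrac = mxrMinFrac, minSnr = minSnr),
            class = "MASConfig")
}

# rescale a 1 kHz window to `sp` ms/sample, forcing odd and >= 3
.scale_window <- function(window_1khz, sp) {
  w <- round(window_1khz / sp)
  w <- max(3, w)
  if (w %% 2 == 0) w <- w + 1
  w
}

#' Moving-average subtraction
#'
#' \code{MAS[i] = centered_moving_average(x, window)[i] - x[i]} with reflect
#' padding at the edges. The sign convention (average minus original) makes
#' the AP takeoff a MAS maximum and the end of the rapid upstroke a MAS
#' minimum.
#'
#' @param x numeric trace or \linkS4class{APTrace}.
#' @param window odd window length in samples.
#' @return numeric MAS series, same length as the trace.
#' @export
movingAvgSubtraction <- function(x, window) {
  vals <- if (is(x, "APTrace")) x@values else x
  stopifnot(window %% 2 == 1, window >= 3, window <= length(vals))
  half <- window %/% 2
  padded <- .reflect_pad(vals, half)
  ma <- as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2))
  ma <- ma[(half + 1):(half + length(vals))]
  ma - vals
}

#' Detect AP takeoff and upstroke completion for one beat
#'
#' Within the post-stimulus search window, takeoff is the MAS maximum and
#' upstroke completion the earliest MAS minimum after takeoff.
#'
#' @param values numeric trace.
#' @param samplePeriod ms per sample.
#' @param stimTime stimulus time, ms.
#' @param cfg a \code{\link{masConfig}}.
#' @param masSeries optional precomputed MAS (with the rescaled upstroke
#'   window) to avoid recomputation across beats.
#' @param searchEnd optional end of the search window, ms (defaults to
#'   stimTime + searchSpan).
#' @return list(takeoff_ms, upstroke_end_ms, takeoff_idx, upstroke_end_idx).
#' @export
detectUpstroke <- function(values, samplePeriod, stimTime, cfg = masConfig(),
                           masSeries = NULL, searchEnd = NULL) {
  sp <- samplePeriod
  if (is.null(masSeries)) {
    w <- .scale_window(cfg$upstrokeWindow, sp)
    masSeries <- movingAvgSubtraction(values, w)
  }
  n <- length(values)
  i0 <- max(1L, floor(stimTime / sp) + 1L)
  if (is.null(searchEnd)) searchEnd <- stimTime + cfg$searchSpan
  i1 <- min(n, ceiling(searchEnd / sp) + 1L)
  if (i1 - i0 < 3) stop("search window too short")
  seg <- masSeries[i0:i1]
  itak <- i0 + which.max(seg) - 1L   # earliest index on ties
  if (itak >= i1 - 1) return(NULL)   # no downstroke of MAS after takeoff
  iend <- itak + which.min(masSeries[(itak + 1):i1])
  list(takeoff_ms = (itak - 1) * sp, upstroke_end_ms = (iend - 1) * sp,
       takeoff_idx = itak, upstroke_end_idx = iend)
}

#' Fractional action potential duration
#'
#' \code{APD_f} is the time from takeoff to the earliest point after the AP
#' peak where the trace falls below
#' \code{peak - f * (peak - beatBaseline)}, with sub-sample linear
#' interpolation at the crossing.
#'
#' @param values numeric trace.
#' @param samplePeriod ms per sample.
#' @param takeoffMs takeoff time, ms.
#' @param peakIdx sample index of the AP peak.
#' @param beatBaseline the beat's subsequent-baseline level.
#' @param fraction repolarization fraction in (0, 1), e.g. 0.5 for APD50.
#' @param endIdx last sample of the beat segment (next stimulus).
#' @return APD in ms, or NA when the trace never crosses before
#'   \code{endIdx} (failure to repolarize for that beat).
#' @export
apdFractional <- function(values, samplePeriod, takeoffMs, peakIdx,
                          beatBaseline, fraction,
                          endIdx = length(values)) {
  stopifnot(fraction > 0, fraction < 1)
  peak <- values[peakIdx]
  thr <- peak - fraction * (peak - beatBaseline)
  seg <- values[peakIdx:endIdx]
  below <- which(seg < thr)
  if (length(below) == 0) return(NA_real_)
  j <- below[1]
  if (j == 1) {
    tcross <- (peakIdx - 1) * samplePeriod
  } else {
    i_hi <- peakIdx + j - 2  # last sample at/above threshold
    v1 <- values[i_hi]; v2 <- values[i_hi + 1]
    frac <- if (v1 == v2) 0 else (v1 - thr) / (v1 - v2)
    tcross <- (i_hi - 1 + frac) * samplePeriod
  }
  tcross - takeoffMs
}

#' Maximum rate change of repolarization (APDmxr)
#'
#' The MAS series computed with the (wider) repolarization window shows a
#' secondary maximum where rapid phase-3 repolarization slows into the
#' resting level; APDmxr is the time from takeoff to that peak. The search
#' starts after upstroke completion plus a guard so the upstroke's own MAS
#' peak is excluded.
#'
#' @param values numeric trace.
#' @param samplePeriod ms per sample.
#' @param takeoffMs takeoff time, ms.
#' @param upstrokeEndMs upstroke completion time, ms.
#' @param cfg a \code{\link{masConfig}}.
#' @param endIdx last sample of the beat segment.
#' @param masRepol optional precomputed MAS with the repolarization window.
#' @param amplitude beat amplitude used for the noise-floor check.
#' @return APDmxr in ms, or NA when no secondary maximum rises above the
#'   noise floor.
#' @export
apdMxr <- function(values, samplePeriod, takeoffMs, upstrokeEndMs,
                   cfg = masConfig(), endIdx = length(values),
                   masRepol = NULL, amplitude = NULL) {
  sp <- samplePeriod
  if (is.null(masRepol)) {
    w <- .scale_window(cfg$repolWindow, sp)
    masRepol <- movingAvgSubtraction(values, w)
  }
  i0 <- floor((upstrokeEndMs + cfg$mxrGuard) / sp) + 1L
  if (i0 >= endIdx) return(NA_real_)
  seg <- masRepol[i0:endIdx]
  imax <- i0 + which.max(seg) - 1L
  if (!is.null(amplitude) && masRepol[imax] < cfg$mxrMinFrac * amplitude)
    return(NA_real_)
  (imax - 1) * sp - takeoffMs
}

#' Per-beat AP metrics and tissue summary
#'
#' Runs the full MAS metric extraction on one trace: per stimulus, detects
#' the upstroke (takeoff = MAS max, completion = MAS min), flags the beat
#' inexcitable when its amplitude falls below \code{apDetectFrac} times the
#' median beat amplitude, and computes stimulation delay, rise time,
#' APD30/50/80 (fractional crossings relative to the subsequent baseline),
#' APDmxr (secondary MAS peak) and APDtri = APDmxr - APD50. The tissue
#' summary averages analyzable beats; excitability is the percentage of
#' stimuli that evoked an AP.
#'
#' @param trace an \linkS4class{APTrace}; when its \code{stimTimes} is empty
#'   and \code{autoBeats} is TRUE, beats are detected from MAS maxima.
#' @param cfg a \code{\link{masConfig}}.
#' @param autoBeats detect beats automatically when no stimulus times are
#'   available.
#' @return list with \code{beats} (data.frame: beat, stim_ms, excitable,
#'   stim_delay_ms, rise_ms, apd30_ms, apd50_ms, apd80_ms, apd_mxr_ms,
#'   apd_tri_ms) and \code{summary} (named list of means over analyzable
#'   beats plus excitability_pct and n_beats).
#' @export
beatMetrics <- function(trace, cfg = masConfig(), autoBeats = FALSE) {
  stopifnot(is(trace, "APTrace"))
  vals <- trace@values * trace@polarity
  sp <- trace@samplePeriod
  n <- length(vals)
  stims <- sort(trace@stimTimes)
  wu <- .scale_window(cfg$upstrokeWindow, sp)
  wr <- .scale_window(cfg$repolWindow, sp)
  mas_up <- movingAvgSubtraction(vals, wu)
  mas_rp <- movingAvgSubtraction(vals, wr)

  if (length(stims) == 0) {
    if (!autoBeats) stop("no stimulus times; set autoBeats = TRUE")
    stims <- .auto_beats(vals, mas_up, sp)
    if (length(stims) == 0) stop("no beats detected")
  }
  nb <- length(stims)
  seg_end <- c(stims[-1], n * sp)  # segment ends at the next stimulus

  # beat amplitudes relative to each beat's subsequent baseline
  base <- amp <- numeric(nb)
  for (b in seq_len(nb)) {
    e_idx <- min(n, floor(seg_end[b] / sp))
    b_idx <- max(1L, floor((seg_end[b] - cfg$baselineWindow) / sp) + 1L)
    base[b] <- median(vals[b_idx:e_idx])
    s_idx <- max(1L, floor(stims[b] / sp) + 1L)
    amp[b] <- max(vals[s_idx:e_idx]) - base[b]
  }
  amp_med <- median(amp)
  noise_sd <- mad(diff(vals)) / sqrt(2)

  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    stim <- stims[b]
    e_idx <- min(n, floor(seg_end[b] / sp))
    row <- data.frame(beat = b, stim_ms = stim, excitable = FALSE,
                      stim_delay_ms = NA_real_, rise_ms = NA_real_,
                      apd30_ms = NA_real_, apd50_ms = NA_real_,
                      apd80_ms = NA_real_, apd_mxr_ms = NA_real_,
                      apd_tri_ms = NA_real_)
    excitable <- amp[b] >= cfg$apDetectFrac * amp_med && amp[b] > 0 &&
      amp[b] > cfg$minSnr * noise_sd
    if (excitable) {
      up <- detectUpstroke(vals, sp, stim, cfg, masSeries = mas_up,
                           searchEnd = min(stim + cfg$searchSpan, seg_end[b]))
      if (!is.null(up)) {
        row$excitable <- TRUE
        row$stim_delay_ms <- up$takeoff_ms - stim
        row$rise_ms <- up$upstroke_end_ms - up$takeoff_ms
        ipk <- up$upstroke_end_idx - 1L +
          which.max(vals[up$upstroke_end_idx:e_idx])
        row$apd30_ms <- apdFractional(vals, sp, up$takeoff_ms, ipk, base[b],
                                      0.30, e_idx)
        row$apd50_ms <- apdFractional(vals, sp, up$takeoff_ms, ipk, base[b],
                                      0.50, e_idx)
        row$apd80_ms <- apdFractional(vals, sp, up$takeoff_ms, ipk, base[b],
                                      0.80, e_idx)
        # stop the APDmxr search half a repol window before the segment end
        # so the MAS never sees the next beat's upstroke
        mxr_end <- max(1L, e_idx - wr %/% 2 - 1L)
        row$apd_mxr_ms <- apdMxr(vals, sp, up$takeoff_ms, up$upstroke_end_ms,
                                 cfg, endIdx = mxr_end, masRepol = mas_rp,
                                 amplitude = amp[b])
        row$apd_tri_ms <- row$apd_mxr_ms - row$apd50_ms
      }
    }
    rows[[b]] <- row
  }
  beats <- do.call(rbind, rows)
  ok <- beats$excitable
  metric_cols <- c("stim_delay_ms", "rise_ms", "apd30_ms", "apd50_ms",
                   "apd80_ms", "apd_mxr_ms", "apd_tri_ms")
  summ <- lapply(metric_cols, function(cl)
    if (any(ok)) mean(beats[[cl]][ok], na.rm = TRUE) else NA_real_)
  names(summ) <- metric_cols
  summ$excitability_pct <- 100 * sum(ok) / nb
  summ$n_beats <- nb
  list(beats = beats, summary = summ)
}

# beat onsets from MAS maxima when stimulus times are unknown: local maxima
# of the upstroke MAS above half its global maximum, separated by >= 200 ms;
# each detected takeoff stands in for a stimulus time
.auto_beats <- function(vals, mas_up, sp) {
  thr <- 0.5 * max(mas_up)
  cand <- which(mas_up > thr)
  if (length(cand) == 0) return(numeric(0))
  min_gap <- round(200 / sp)
  groups <- split(cand, cumsum(c(1, diff(cand) > min_gap)))
  onsets <- vapply(groups, function(g) g[which.max(mas_up[g])], numeric(1))
  # report a pseudo-stimulus slightly before each takeoff
  pmax(0, (onsets - 1) * sp - 5)
}
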