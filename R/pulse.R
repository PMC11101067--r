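#' Construct a force pulse from sampled values
#'
#' A `force_pulse` is a tibble with columns `time` (s, uniform grid) and
#' `force` (N), carrying the sample rate and first-peak summary (peak force,
#' peak time, base width) as attributes.
#'
#' @param time Time stamps in seconds (uniform grid).
#' @param force Force samples in newtons.
#' @param width Optional first-peak base width in seconds (recorded when
#'   known, e.g. for synthetic pulses).
#' @return A `force_pulse` tibble.
#' @export
force_pulse <- function(time, force, width = NA_real_) {
  stopifnot(length(time) == length(force), length(time) >= 2)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1] + 1e-15)) {
    stop("force pulse requires a uniform time grid", call. = FALSE)
  }
  i <- which.max(force)
  structure(
    tibble::tibble(time = as.numeric(time), force = as.numeric(force)),
    sample_rate = 1 / dt[1],
    peak_force = force[[i]],
    peak_time = time[[i]],
    width = width,
    class = c("force_pulse", class(tibble::tibble()))
  )
}

#' @export
#' @rdname force_pulse
#' @param x An object.
is_force_pulse <- function(x) inherits(x, "force_pulse")

pulse_attr <- function(pulse, what) attr(pulse, what, exact = TRUE)

#' Synthetic half-sine mallet pulse
#'
#' Generates the canonical synthetic stand-in for a measured mallet blow: a
#' single half-sine lobe `F(t) = peak * sin(pi (t - start) / width)` on
#' `[start, start + width]`, zero elsewhere. The defaults reproduce the mean
#' measured blow statistics (peak 9247 N, first-peak width 0.140 ms).
#'
#' @param peak Peak force in newtons (> 0).
#' @param width Base width of the lobe in seconds (> 0).
#' @param sample_rate Sampling frequency in Hz.
#' @param start Onset time in seconds.
#' @param duration Total length of the sampled record in seconds.
#' @return A [force_pulse()].
#' @examples
#' p <- pulse_half_sine()
#' attr(p, "peak_force") # 9247 N at t = 0.070 ms
#' @export
pulse_half_sine <- function(peak = 9247, width = 0.140e-3,
                            sample_rate = 800e3, start = 0,
                            duration = 0.8e-3) {
  if (!is.numeric(peak) || peak <= 0) {
    stop("pulse peak must be positive", call. = FALSE)
  }
  if (!is.numeric(width) || width <= 0) {
    stop("pulse width must be positive", call. = FALSE)
  }
  t <- seq(0, duration, by = 1 / sample_rate)
  f <- ifelse(t >= start & t <= start + width,
              peak * sin(pi * (t - start) / width), 0)
  f[f < 0] <- 0 # guard endpoint roundoff
  force_pulse(t, f, width = width)
}

#' Isolate the first peak of a measured mallet waveform
#'
#' Only the first force peak of a mallet recording drives the impaction;
#' later lobes come from instrument rebound. The segment between the
#' threshold crossing (0.5\% of the global maximum, robust to sensor noise
#' around zero) before the global maximum and the one after it is retained
#' and everything else zeroed, preserving the record length.
#'
#' @param pulse A [force_pulse()].
#' @param threshold_frac Crossing threshold as a fraction of the global
#'   maximum.
#' @return A [force_pulse()] containing only the first lobe, zero-padded to
#'   the input duration.
#' @export
extract_first_peak <- function(pulse, threshold_frac = 0.005) {
  stopifnot(is_force_pulse(pulse))
  f <- pulse$force
  imax <- which.max(f)
  if (f[imax] <= 0) {
    stop("no identifiable positive peak in the waveform", call. = FALSE)
  }
  thr <- threshold_frac * f[imax]
  below_left <- which(f[seq_len(imax)] <= thr)
  i0 <- if (length(below_left)) max(below_left) + 1L else 1L
  after <- f[seq(imax, length(f))]
  below_right <- which(after <= thr)
  i1 <- if (length(below_right)) imax + min(below_right) - 2L else length(f)
  out <- numeric(length(f))
  out[i0:i1] <- f[i0:i1]
  force_pulse(pulse$time, out,
              width = (i1 - i0 + 2L) / pulse_attr(pulse, "sample_rate"))
}

#' Draw a random mallet blow
#'
#' Samples a half-sine pulse whose peak and width follow the surgeon-to-
#' surgeon blow variability (truncated-at-zero normal with mean 9247 N,
#' SD 1513 N for the peak and mean 0.140 ms, SD 0.008 ms for the width).
#'
#' @param seed Optional integer seed; a fixed seed gives an identical pulse.
#' @param peak_mean,peak_sd Peak force distribution, newtons.
#' @param width_mean,width_sd Width distribution, seconds.
#' @param sample_rate,duration Passed to [pulse_half_sine()].
#' @return A [force_pulse()].
#' @export
random_blow <- function(seed = NULL, peak_mean = 9247, peak_sd = 1513,
                        width_mean = 0.140e-3, width_sd = 0.008e-3,
                        sample_rate = 800e3, duration = 0.8e-3) {
  draw <- function() {
    peak <- rtrunc_pos(1, peak_mean, peak_sd)
    width <- rtrunc_pos(1, width_mean, width_sd)
    pulse_half_sine(peak, width, sample_rate = sample_rate,
                    duration = duration)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# normal truncated at zero by rejection; truncation mass is negligible for
# the blow statistics (mean ~ 6 SD above zero) so this terminates quickly
rtrunc_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Read or write a sampled force waveform
#'
#' Waveforms are two-column CSV files (`time` in seconds, `force` in
#' newtons) with a header line. A single-column file (force only) is
#' accepted on read, in which case an 800 kHz grid is assumed.
#'
#' @param path File path.
#' @param sample_rate Sample rate assumed when the time column is absent.
#' @param pulse A [force_pulse()] to write.
#' @return `read_pulse_csv()` returns a [force_pulse()];
#'   `write_pulse_csv()` returns `path` invisibly.
#' @export
read_pulse_csv <- function(path, sample_rate = 800e3) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(df) == 1L) {
    force_pulse((seq_len(nrow(df)) - 1) / sample_rate, df[[1]])
  } else {
    force_pulse(df[[1]], df[[2]])
  }
}

#' @rdname read_pulse_csv
#' @export
write_pulse_csv <- function(pulse, path) {
  stopifnot(is_force_pulse(pulse))
  readr::write_csv(tibble::tibble(time = pulse$time, force = pulse$force),
                   path)
  invisible(path)
}
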