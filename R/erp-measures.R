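#' Construct an ERP wave
#'
#' A single time course (one channel or a channel-cluster average) with a
#' uniform time axis in milliseconds.
#'
#' @param times Strictly increasing, uniformly spaced times in ms.
#' @param values Amplitudes in uV, same length as `times`.
#' @param role `"standard"`, `"deviant"` or `"difference"`.
#' @param participant,condition Optional identifiers.
#' @return Object of class `erp_wave`.
#' @export
erp_wave <- function(times, values, role = "difference",
                     participant = NA, condition = NA) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  d <- diff(times)
  if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d))
    stop("`times` must be strictly increasing with a uniform step")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 role = role, participant = participant,
                 condition = condition),
            class = "erp_wave")
}

#' Baseline-correct an ERP wave
#'
#' Subtracts the mean of the pre-stimulus interval (default -100 to 0 ms)
#' from every sample.
#'
#' @param wave An `erp_wave` covering the full baseline window.
#' @param window Baseline interval in ms.
#' @return Corrected `erp_wave`.
#' @export
baseline_correct <- function(wave, window = c(-100, 0)) {
  stopifnot(inherits(wave, "erp_wave"))
  sel <- wave$times >= window[1] & wave$times <= window[2]
  if (!any(sel)) stop("wave does not cover the baseline window")
  wave$values <- wave$values - mean(wave$values[sel])
  wave
}

#' Average the epochs of one role into an ERP
#'
#' Pointwise mean over all epochs of an [generate_epochs()] `epoch_set`
#' carrying the requested role.
#'
#' @param epochs An `epoch_set`.
#' @param role `"standard"` or `"deviant"`.
#' @return `erp_wave` of the averaged response.
#' @export
average_by_role <- function(epochs, role) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$info$role == role
  if (!any(sel)) stop("no epochs with role '", role, "'")
  erp_wave(epochs$times, colMeans(epochs$data[sel, , drop = FALSE]),
           role = role, participant = epochs$participant,
           condition = epochs$condition)
}

#' Deviant-minus-standard difference wave
#'
#' @param deviant,standard `erp_wave`s on identical time axes.
#' @return `erp_wave` with role `"difference"`.
#' @export
difference_wave <- function(deviant, standard) {
  stopifnot(inherits(deviant, "erp_wave"), inherits(standard, "erp_wave"))
  if (length(deviant$times) != length(standard$times) ||
      any(abs(deviant$times - standard$times) > 1e-9))
    stop("time axes differ between deviant and standard waves")
  erp_wave(deviant$times, deviant$values - standard$values,
           role = "difference", participant = deviant$participant,
           condition = deviant$condition)
}

#' Average a set of channel waves into a cluster wave
#'
#' Pointwise mean over a named list of `erp_wave`s (e.g. the fronto-central
#' cluster Fz, F1, F2, AF3, AF4, AFz, F3, F4, FC1, FC2, FCz). Averaging
#' commutes with [difference_wave()], so clusters can be formed before or
#' after subtraction.
#'
#' @param waves Named list of `erp_wave`s on identical time axes.
#' @param channels Optional subset of names to average (default: all).
#' @return `erp_wave` of the cluster average.
#' @export
average_channels <- function(waves, channels = names(waves)) {
  stopifnot(length(waves) >= 1)
  waves <- waves[channels]
  ref <- waves[[1]]
  vals <- rowMeans(vapply(waves, function(w) {
    if (any(abs(w$times - ref$times) > 1e-9)) stop("time axes differ")
    w$values
  }, numeric(length(ref$times))))
  erp_wave(ref$times, vals, role = ref$role,
           participant = ref$participant, condition = ref$condition)
}

#' MMN and P3a peak measures from a difference wave
#'
#' MMN latency is the time of the most negative value in the 70-250 ms
#' window; P3a latency is the time of the most positive value in 150-350 ms.
#' Each amplitude is the mean of the wave over latency +/- 25 ms. Extremum
#' ties resolve to the earliest latency. By default the extremum is global
#' within the window (robust on noisy waves); `local = TRUE` restricts the
#' search to strict local extrema, falling back to the global one with a
#' warning when none exists. If a +/- 25 ms window would extend past the
#' epoch it is truncated with a warning (cannot happen on epochs running to
#' 500 ms).
#'
#' @param diff An `erp_wave` (typically a difference wave) covering at least
#'   45-375 ms.
#' @param mmn_window,p3a_window Search windows in ms.
#' @param half_width Half width of the mean-amplitude window in ms.
#' @param local Require a strict local extremum instead of the windowed
#'   global one.
#' @return Named list: `mmn_amplitude`, `mmn_latency`, `p3a_amplitude`,
#'   `p3a_latency` (uV and ms).
#' @export
peak_measures <- function(diff, mmn_window = c(70, 250),
                          p3a_window = c(150, 350), half_width = 25,
                          local = FALSE) {
  stopifnot(inherits(diff, "erp_wave"))
  mmn <- window_peak(diff, mmn_window, half_width, minimum = TRUE, local)
  p3a <- window_peak(diff, p3a_window, half_width, minimum = FALSE, local)
  list(mmn_amplitude = mmn$amplitude, mmn_latency = mmn$latency,
       p3a_amplitude = p3a$amplitude, p3a_latency = p3a$latency)
}

window_peak <- function(wave, window, half_width, minimum, local = FALSE) {
  idx <- which(wave$times >= window[1] & wave$times <= window[2])
  if (length(idx) == 0L) stop("wave does not cover the peak window")
  v <- wave$values[idx]
  if (minimum) v <- -v
  pick <- NULL
  if (local) {
    is_loc <- which(diff(sign(diff(v))) < 0) + 1L # strict interior maxima
    if (length(is_loc)) pick <- is_loc[which.max(v[is_loc])]
    else warning("no strict local extremum in window; using the global one")
  }
  if (is.null(pick)) pick <- which.max(v) # which.max: earliest tie wins
  latency <- wave$times[idx[pick]]
  lo <- latency - half_width
  hi <- latency + half_width
  if (lo < wave$times[1] || hi > wave$times[length(wave$times)]) {
    warning("mean-amplitude window truncated at the epoch edge")
  }
  sel <- wave$times >= lo & wave$times <= hi
  list(latency = latency, amplitude = mean(wave$values[sel]))
}

#' Epoch rejection rate
#'
#' Percentage of rejected epochs, reported to one decimal.
#'
#' @param n_rejected,n_total Counts with `0 <= n_rejected <= n_total`,
#'   `n_total > 0`.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' rejection_rate(13400, 321389) # 4.2
rejection_rate <- function(n_rejected, n_total) {
  stopifnot(n_total > 0, n_rejected >= 0, n_rejected <= n_total)
  round(100 * n_rejected / n_total, 1)
}

#' Peak table from a list of epoch sets
#'
#' Full single-trace measurement pipeline: average deviants and standards,
#' subtract, baseline-correct, and extract MMN/P3a peak measures for every
#' epoch set (one per participant x condition). The output schema matches
#' [generate_peak_table()].
#'
#' @param epoch_sets List of `epoch_set` objects.
#' @param jitter_rates Named vector mapping condition names to jitter rates
#'   (for the `jitter_rate`/`entropy` columns); conditions absent from it
#'   get `NA` entropy.
#' @return `data.frame` in the peak-table schema.
#' @export
peak_table_from_epochs <- function(epoch_sets, jitter_rates = NULL) {
  rows <- lapply(epoch_sets, function(ep) {
    dw <- baseline_correct(difference_wave(average_by_role(ep, "deviant"),
                                           average_by_role(ep, "standard")))
    pm <- peak_measures(dw)
    jc <- if (!is.null(jitter_rates) && ep$condition %in% names(jitter_rates))
      jitter_rates[[ep$condition]] else NA_real_
    data.frame(participant = ep$participant, condition = ep$condition,
               jitter_rate = jc,
               entropy = if (is.na(jc) || jc <= 0) NA_real_
                         else differential_entropy(jc),
               mmn_amplitude = pm$mmn_amplitude, mmn_latency = pm$mmn_latency,
               p3a_amplitude = pm$p3a_amplitude, p3a_latency = pm$p3a_latency)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
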