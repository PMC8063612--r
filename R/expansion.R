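#' Expansion timecourses and their summary
#'
#' `expansion_curve()` builds a validated timecourse of cumulative population
#' doublings; `max_doublings()` reduces it to the single characteristic
#' measure of proliferative potential used throughout the stratification:
#' the maximum cumulative doubling reached at any point of the expansion.
#'
#' @param days numeric vector of time points in days, strictly increasing.
#' @param doublings cumulative population doublings at each time point
#'   (non-negative; may decline after the peak as the culture comes to rest).
#' @return `expansion_curve` returns an object of class `expansion_curve`;
#'   `max_doublings` returns a single number.
#' @examples
#' curve <- expansion_curve(0:4, c(0, 1, 2, 3, 2.5))
#' max_doublings(curve)  # 3
#' @export
expansion_curve <- function(days, doublings) {
  if (length(days) == 0L) stop("empty expansion curve")
  if (length(days) != length(doublings))
    stop("days and doublings must have equal length")
  if (any(diff(days) <= 0)) stop("time points must be strictly increasing")
  if (any(doublings < 0)) stop("doublings must be non-negative")
  structure(list(days = as.numeric(days), doublings = as.numeric(doublings)),
            class = "expansion_curve")
}

#' @rdname expansion_curve
#' @param curve an `expansion_curve`.
#' @export
max_doublings <- function(curve) {
  if (!inherits(curve, "expansion_curve")) curve <- do.call(expansion_curve, curve)
  max(curve$doublings)
}

#' Simulate an ex vivo expansion timecourse
#'
#' A saturating-growth curve with an optional post-peak decline, emulating
#' bead-activated T-cell expansion: rapid early doubling that levels off at
#' the donor's maximum and then drifts down as cells come to rest.
#'
#' @param d_max the plateau (maximum) number of doublings.
#' @param days vector of sampling days.
#' @param rate exponential approach rate to the plateau, per day.
#' @param decline_per_day linear decline applied after `t_peak` days.
#' @param t_peak day at which the decline starts.
#' @param sd_noise multiplicative measurement noise SD (0 for none).
#' @return an `expansion_curve`.
#' @export
simulate_expansion <- function(d_max, days = seq(0, 21, by = 1.5), rate = 0.25,
                               decline_per_day = 0.03, t_peak = 12,
                               sd_noise = 0) {
  if (d_max < 0) stop("d_max must be non-negative")
  d <- d_max * (1 - exp(-rate * days))
  d <- d - d_max * decline_per_day * pmax(0, days - t_peak)
  if (sd_noise > 0) d <- d * exp(rnorm(length(days), 0, sd_noise))
  expansion_curve(days, pmax(0, d))
}

#' Percent OKT3 of a printing solution
#'
#' Activating micropatterns are printed from an antibody mixture with a
#' fixed total concentration; the strength of the CD3 signal is expressed as
#' the percentage of that total contributed by the alpha-CD3 antibody
#' (clone OKT3). For example, 3 ug/ml OKT3 in a 20 ug/ml total is 15% OKT3.
#'
#' @param okt3_conc alpha-CD3 concentration in ug/ml.
#' @param total_conc total antibody concentration in ug/ml (default 20).
#' @return percent of total antibody that is OKT3.
#' @export
okt3_percent <- function(okt3_conc, total_conc = 20) {
  if (total_conc <= 0) stop("total concentration must be positive")
  if (any(okt3_conc < 0) || any(okt3_conc > total_conc))
    stop("okt3_conc must lie in [0, total_conc]")
  100 * okt3_conc / total_conc
}
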