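#' Detect a stop on an activating feature
#'
#' A stop is a cessation of overall motion for longer than `stop_min_duration`
#' minutes while on an activating feature; a cell that merely crosses a
#' feature, or that pauses away from any feature, has not stopped. The
#' detector finds the earliest frame f such that every position in the
#' window \[t_f, t_f + stop_min_duration\] stays within `stop_tolerance` of
#' the position at f, and that position lies inside a feature's encounter
#' disc. Windows that do not fit inside the trajectory are not evaluated, so
#' a track shorter than the stop window is never stopped. Off-feature
#' confinement is reported separately and never counted as a stop.
#'
#' @param traj a [trajectory()].
#' @param lat a [lattice()].
#' @param stop_min_duration minimum stop duration in minutes (default 3).
#' @param stop_tolerance confinement radius in um (default 2, one feature
#'   diameter).
#' @return list with `stopped` (logical), `stop_onset_min` (absolute frame
#'   time of the onset, minutes; NA when not stopped), `stop_feature`
#'   (lattice feature id or NA) and `confined_off_feature` (logical: some
#'   window satisfied the confinement rule away from any feature).
#' @export
detect_stop <- function(traj, lat = lattice(), stop_min_duration = 3,
                        stop_tolerance = 2) {
  stopifnot(inherits(traj, "trajectory"))
  if (stop_tolerance <= 0) stop("stop_tolerance must be positive")
  dur_s <- stop_min_duration * 60
  if (dur_s < traj$dt_s) stop("stop_min_duration must be at least one frame")
  t <- traj$t_s; x <- traj$x_um; y <- traj$y_um
  n <- length(t)
  off_feature <- FALSE
  for (f in seq_len(n)) {
    if (t[f] + dur_s > t[n] + 1e-9) break          # window no longer fits
    win <- which(t >= t[f] - 1e-9 & t <= t[f] + dur_s + 1e-9)
    confined <- all(sqrt((x[win] - x[f])^2 + (y[win] - y[f])^2)
                    <= stop_tolerance + 1e-12)
    if (!confined) next
    fid <- feature_at(lat, x[f], y[f])
    if (is.na(fid)) { off_feature <- TRUE; next }
    return(list(stopped = TRUE, stop_onset_min = t[f] / 60,
                stop_feature = fid, confined_off_feature = off_feature))
  }
  list(stopped = FALSE, stop_onset_min = NA_real_,
       stop_feature = NA_character_, confined_off_feature = off_feature)
}

#' Average migration speed before stopping
#'
#' Mean frame-to-frame displacement divided by the frame interval,
#' restricted to frames strictly before the stop onset; the whole trajectory
#' is used when the cell never stopped.
#'
#' @param traj a [trajectory()].
#' @param stop_onset_min absolute stop-onset time in minutes, or NULL/NA for
#'   a non-stopping cell.
#' @return speed in um/min.
#' @export
average_speed <- function(traj, stop_onset_min = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  keep <- if (is.null(stop_onset_min) || is.na(stop_onset_min)) {
    seq_along(traj$t_s)
  } else which(traj$t_s < stop_onset_min * 60 - 1e-9)
  if (length(keep) < 2L) stop("fewer than 2 usable frames before the stop")
  steps <- sqrt(diff(traj$x_um[keep])^2 + diff(traj$y_um[keep])^2)
  mean(steps) / traj$dt_s * 60
}

#' Number of features crossed before stopping
#'
#' Counts encounter events — entries of the linearly interpolated centroid
#' path into a feature's encounter disc — that occur before the stop onset,
#' excluding the encounter that becomes the stop itself. Re-entry into the
#' same feature counts as a new event; a cell that starts on a feature is
#' counted as encountering it at time zero. For cells that never stop, all
#' encounter events are counted. Linear interpolation between frames means
#' fast cells cannot tunnel through a feature unnoticed.
#'
#' @param traj a [trajectory()].
#' @param lat a [lattice()].
#' @param stop_feature feature id of the stop, or NA/NULL.
#' @param stop_onset_min absolute stop-onset time in minutes, or NA/NULL.
#' @return integer count of encounter events.
#' @export
features_crossed <- function(traj, lat = lattice(), stop_feature = NULL,
                             stop_onset_min = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ev <- path_encounters(lat, traj$t_s, cbind(traj$x_um, traj$y_um))
  no_stop <- is.null(stop_feature) || is.na(stop_feature)
  if (no_stop) return(nrow(ev))
  onset_s <- stop_onset_min * 60
  ev <- ev[ev$t_in <= onset_s + 1e-9, , drop = FALSE]
  stop_idx <- which(ev$feature == stop_feature)
  if (length(stop_idx)) ev <- ev[-max(stop_idx), , drop = FALSE]
  nrow(ev)
}

#' Time from trajectory start to the stop
#'
#' @param traj a [trajectory()].
#' @param stop_onset_min absolute stop-onset time in minutes.
#' @return elapsed time from the first frame to the stop onset, minutes.
#' @export
time_to_stop <- function(traj, stop_onset_min) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(stop_onset_min) || is.na(stop_onset_min))
    stop("time_to_stop is undefined for a cell that never stopped")
  stop_onset_min - traj$t_s[1] / 60
}

#' Per-cell and per-donor motility summaries
#'
#' Applies [detect_stop()], [average_speed()], [features_crossed()] and
#' [time_to_stop()] to every included trajectory and aggregates means and
#' SDs per donor and PD-1 label. Tracks with `include = FALSE` (no fully
#' formed lamellipodia) are excluded from all metrics. Cells that never stop
#' are reported with `time_to_stop_min = NA` (censored, not imputed).
#'
#' @param trajs list of [trajectory()] objects sharing one frame interval.
#' @param lat a [lattice()].
#' @param stop_min_duration,stop_tolerance passed to [detect_stop()].
#' @return list with `cells` (one row per included cell), `summary`
#'   (per donor x PD-1 label: n_cells, n_stopped, mean/sd of each metric),
#'   `n_cells` and `n_excluded`.
#' @export
summarize_motility <- function(trajs, lat = lattice(), stop_min_duration = 3,
                               stop_tolerance = 2) {
  if (!length(trajs)) stop("empty trajectory list")
  dts <- vapply(trajs, `[[`, 0, "dt_s")
  if (diff(range(dts)) > 1e-6) stop("all trajectories must share dt")
  inc <- vapply(trajs, `[[`, TRUE, "include")
  kept <- trajs[inc]
  empty <- data.frame(donor_id = character(), cell_id = character(),
                      pd1_label = character(), speed_um_min = numeric(),
                      n_features_crossed = integer(), stopped = logical(),
                      time_to_stop_min = numeric(), stop_feature = character(),
                      stringsAsFactors = FALSE)
  if (!length(kept))
    return(list(cells = empty, summary = empty[0, 1:2], n_cells = 0L,
                n_excluded = sum(!inc)))
  cells <- do.call(rbind, lapply(kept, function(tr) {
    st <- detect_stop(tr, lat, stop_min_duration, stop_tolerance)
    data.frame(
      donor_id = tr$donor_id, cell_id = tr$cell_id, pd1_label = tr$pd1_label,
      speed_um_min = tryCatch(average_speed(tr, st$stop_onset_min),
                              error = function(e) NA_real_),
      n_features_crossed = features_crossed(tr, lat, st$stop_feature,
                                            st$stop_onset_min),
      stopped = st$stopped,
      time_to_stop_min = if (st$stopped) time_to_stop(tr, st$stop_onset_min)
                         else NA_real_,
      stop_feature = st$stop_feature, stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  agg <- function(d) {
    data.frame(
      n_cells = nrow(d), n_stopped = sum(d$stopped),
      speed_mean = mean(d$speed_um_min, na.rm = TRUE),
      speed_sd = sd(d$speed_um_min, na.rm = TRUE),
      features_mean = mean(d$n_features_crossed),
      features_sd = sd(d$n_features_crossed),
      time_to_stop_mean = if (any(d$stopped))
        mean(d$time_to_stop_min[d$stopped]) else NA_real_,
      time_to_stop_sd = if (sum(d$stopped) > 1)
        sd(d$time_to_stop_min[d$stopped]) else NA_real_)
  }
  key <- interaction(cells$donor_id, cells$pd1_label, drop = TRUE)
  summ <- do.call(rbind, lapply(split(cells, key), function(d)
    cbind(data.frame(donor_id = d$donor_id[1], pd1_label = d$pd1_label[1],
                     stringsAsFactors = FALSE), agg(d))))
  rownames(summ) <- NULL
  list(cells = cells, summary = summ, n_cells = nrow(cells),
       n_excluded = sum(!inc))
}
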