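#' Construct a single-cell trajectory
#'
#' A time-stamped 2D centroid track for one cell, sampled at a fixed frame
#' interval. The inclusion flag stands in for the morphological criterion
#' used at acquisition time (only cells with fully formed lamellipodia are
#' analysed); it cannot be computed from centroids and is carried as data.
#'
#' @param t_s frame times in seconds, strictly increasing at constant
#'   spacing; at least 2 frames.
#' @param x_um,y_um centroid positions in micrometres.
#' @param donor_id,cell_id identifiers.
#' @param pd1_label `"positive"`, `"negative"` or `"unknown"`.
#' @param include logical inclusion flag.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(t_s, x_um, y_um, donor_id = "D01", cell_id = "c1",
                       pd1_label = c("unknown", "positive", "negative"),
                       include = TRUE) {
  pd1_label <- match.arg(pd1_label)
  n <- length(t_s)
  if (n < 2L) stop("a trajectory needs at least 2 frames")
  if (length(x_um) != n || length(y_um) != n)
    stop("t_s, x_um, y_um must have equal length")
  dts <- diff(t_s)
  if (any(dts <= 0)) stop("frame times must be strictly increasing")
  if (diff(range(dts)) > 1e-6 * dts[1])
    stop("frame spacing must be constant")
  structure(list(t_s = as.numeric(t_s), x_um = as.numeric(x_um),
                 y_um = as.numeric(y_um), donor_id = donor_id,
                 cell_id = cell_id, pd1_label = pd1_label,
                 include = isTRUE(include), dt_s = dts[1]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s/%s: %d frames at dt = %g s, PD-1 %s%s\n",
              x$donor_id, x$cell_id, length(x$t_s), x$dt_s, x$pd1_label,
              if (x$include) "" else " (excluded)"))
  invisible(x)
}

#' Simulate persistent-random-walk trajectories on a lattice
#'
#' Cells perform a constant-speed persistent random walk (heading diffusion
#' with persistence time `persistence_min`). On each entry of the
#' interpolated path into a feature's encounter disc the cell halts
#' permanently with probability `stop_hazard`; a cell that starts inside a
#' disc is treated as entering it at time zero. Halted cells settle onto the
#' feature centre and keep that position, apart from a small residual jitter
#' well below any stop tolerance. Frames are produced at exact `dt_s`
#' spacing from t = 0 to `duration_min`.
#'
#' @param spec a [group_spec()] supplying speed, persistence and stop hazard.
#' @param lat a [lattice()].
#' @param n_cells number of cells to simulate.
#' @param duration_min observation period in minutes (default 60).
#' @param dt_s frame interval in seconds (default 30).
#' @param seed integer seed.
#' @param donor_id donor identifier attached to every track.
#' @param pd1_labels optional vector of PD-1 labels recycled over cells.
#' @param jitter_um SD of the residual jitter of halted cells (default 0.2).
#' @return list of [trajectory()] objects. Each carries attributes
#'   `halted` (logical) and `halt_time_s` (NA when not halted) describing
#'   the generating process, for use as simulation ground truth.
#' @export
simulate_trajectories <- function(spec, lat = lattice(), n_cells,
                                  duration_min = 60, dt_s = 30, seed = 1L,
                                  donor_id = "D01", pd1_labels = "unknown",
                                  jitter_um = 0.2) {
  stopifnot(inherits(spec, "group_spec"), inherits(lat, "lattice"))
  if (duration_min <= 0 || dt_s <= 0 || n_cells < 1)
    stop("duration, dt and n_cells must be positive")
  if (spec$speed_um_min < 0 || spec$persistence_min <= 0)
    stop("non-physical motility parameters")
  set.seed(as.integer(seed))
  n_frames <- floor(duration_min * 60 / dt_s) + 1L
  t_s <- (seq_len(n_frames) - 1L) * dt_s
  dt_min <- dt_s / 60
  step_len <- spec$speed_um_min * dt_min
  sigma_theta <- sqrt(2 * dt_min / spec$persistence_min)
  labels <- rep_len(pd1_labels, n_cells)

  lapply(seq_len(n_cells), function(ci) {
    x <- y <- numeric(n_frames)
    x[1] <- runif(1, 0, lat$pitch); y[1] <- runif(1, 0, lat$pitch)
    theta <- runif(1, 0, 2 * pi)
    halted <- FALSE
    halt_time <- NA_real_
    cur <- feature_at(lat, x[1], y[1])
    if (!is.na(cur) && runif(1) < spec$stop_hazard) {
      halted <- TRUE; halt_time <- 0
      cen <- feature_center(lat, cur)
      x[1] <- cen[1]; y[1] <- cen[2]
    }
    for (k in 2:n_frames) {
      if (halted) {
        x[k] <- x[k - 1]; y[k] <- y[k - 1]
        next
      }
      theta <- theta + rnorm(1, 0, sigma_theta)
      x[k] <- x[k - 1] + step_len * cos(theta)
      y[k] <- y[k - 1] + step_len * sin(theta)
      hits <- segment_disc_hits(lat, c(x[k - 1], y[k - 1]), c(x[k], y[k]))
      for (h in seq_len(nrow(hits))) {
        fid <- hits$feature[h]
        entering <- !(hits$s_in[h] <= 1e-9 && !is.na(cur) && cur == fid)
        if (entering && runif(1) < spec$stop_hazard) {
          halted <- TRUE
          halt_time <- t_s[k - 1] + hits$s_in[h] * dt_s
          cen <- feature_center(lat, fid)
          x[k] <- cen[1]; y[k] <- cen[2]
          cur <- fid
          break
        }
      }
      if (!halted) cur <- feature_at(lat, x[k], y[k])
    }
    if (halted && jitter_um > 0) {
      from <- which(t_s >= halt_time)
      from <- from[from > 1]
      x[from] <- x[from] + rnorm(length(from), 0, jitter_um)
      y[from] <- y[from] + rnorm(length(from), 0, jitter_um)
    }
    tr <- trajectory(t_s, x, y, donor_id = donor_id,
                     cell_id = sprintf("c%03d", ci), pd1_label = labels[ci])
    attr(tr, "halted") <- halted
    attr(tr, "halt_time_s") <- halt_time
    tr
  })
}

#' Read and write trajectory tables
#'
#' Long-format CSV with columns donor_id, cell_id, pd1_label, include,
#' frame, t_s, x_um, y_um.
#'
#' @param trajs list of [trajectory()] objects.
#' @param path CSV path.
#' @return `read_trajectories` returns a list of trajectories.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    data.frame(donor_id = tr$donor_id, cell_id = tr$cell_id,
               pd1_label = tr$pd1_label, include = tr$include,
               frame = seq_along(tr$t_s) - 1L, t_s = tr$t_s,
               x_um = tr$x_um, y_um = tr$y_um, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$donor_id, df$cell_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$frame), ]
    trajectory(d$t_s, d$x_um, d$y_um, donor_id = d$donor_id[1],
               cell_id = d$cell_id[1], pd1_label = d$pd1_label[1],
               include = as.logical(d$include[1]))
  })
}
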