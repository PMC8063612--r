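lat <- lattice()   # 2 um features, 15 um pitch, encounter radius 5 um

test_that("a cell stationary on a feature stops with the correct onset", {
  # moves until t = 10 min, then sits on the feature at the origin
  n_move <- 20                      # frames 0..19 (t = 0 .. 9.5 min) moving
  x <- c(seq(-60, -3, length.out = n_move), rep(0, 101))
  y <- rep(0, length(x))
  tr <- line_traj(x, y)
  st <- detect_stop(tr, lat)
  expect_true(st$stopped)
  expect_equal(st$stop_onset_min, 10)
  expect_identical(st$stop_feature, "0,0")
  expect_false(st$confined_off_feature)
  expect_equal(time_to_stop(tr, st$stop_onset_min), 10)
})

test_that("a straight constant-velocity track never stops", {
  # 10 um/min = 5 um per 30-s frame, along a line between feature rows
  x <- seq(0, 60 * 10, by = 5)
  tr <- line_traj(x, rep(7.5, length(x)))
  st <- detect_stop(tr, lat)
  expect_false(st$stopped)
  expect_true(is.na(st$stop_onset_min))
  expect_equal(average_speed(tr, NULL), 10)
})

test_that("a 2-minute pause on a feature is not a stop (window oracle)", {
  # approach, pause 2 min (5 frames spanning 2 min) on the origin feature,
  # then leave; scan every window by brute force to confirm none qualifies
  x <- c(seq(-30, -5, by = 5), rep(0, 5), seq(5, 30, by = 5))
  y <- rep(0, length(x))
  tr <- line_traj(x, y)
  st <- detect_stop(tr, lat, stop_min_duration = 3, stop_tolerance = 2)
  dur_s <- 180; tol <- 2
  oracle_stop <- FALSE
  for (f in seq_along(tr$t_s)) {
    if (tr$t_s[f] + dur_s > tr$t_s[length(tr$t_s)]) break
    win <- which(tr$t_s >= tr$t_s[f] & tr$t_s <= tr$t_s[f] + dur_s)
    conf <- all(sqrt((x[win] - x[f])^2 + (y[win] - y[f])^2) <= tol)
    on_feat <- sqrt(x[f]^2 + y[f]^2) <= lat$encounter_radius
    if (conf && on_feat) oracle_stop <- TRUE
  }
  expect_false(oracle_stop)
  expect_false(st$stopped)
})

test_that("tracks shorter than the stop window are never stopped", {
  tr <- line_traj(rep(0, 5), rep(0, 5))      # 2 min total, on a feature
  expect_false(detect_stop(tr, lat)$stopped)
})

test_that("average speed follows the arithmetic mean of step displacements", {
  # constant 5-um steps at 30 s -> 10 um/min
  tr <- line_traj(seq(0, 50, by = 5), rep(7.5, 11))
  expect_equal(average_speed(tr), 10)
  # two-phase track: 5-um then 1-um steps, equal step counts -> 6 um/min
  x <- cumsum(c(0, rep(5, 10), rep(1, 10)))
  tr2 <- line_traj(x, rep(7.5, length(x)))
  expect_equal(average_speed(tr2), mean(c(rep(5, 10), rep(1, 10))) * 2)
  expect_equal(average_speed(tr2), 6)
  # stationary pre-stop segment -> 0
  tr3 <- line_traj(rep(0, 20), rep(0, 20))
  expect_equal(average_speed(tr3, stop_onset_min = 5), 0)
  expect_error(average_speed(tr3, stop_onset_min = 0.5), "fewer than 2")
})

test_that("features crossed counts distinct entry events and excludes the stop", {
  # straight row pass through feature centres at x = 0, 15, 30, then halt on 30
  x <- c(seq(-8, 28, by = 2), rep(30, 10))
  tr <- line_traj(x, rep(0, length(x)))
  st <- detect_stop(tr, lat)
  expect_true(st$stopped)
  expect_identical(st$stop_feature, "2,0")
  expect_equal(features_crossed(tr, lat, st$stop_feature, st$stop_onset_min), 2)

  # path far from any disc
  tr2 <- line_traj(seq(0, 50, by = 5), rep(7.5, 11))
  expect_equal(features_crossed(tr2, lat), 0)

  # stop on the first feature touched -> 0
  x3 <- c(seq(-8, -2, by = 2), rep(0, 10))
  tr3 <- line_traj(x3, rep(0, length(x3)))
  st3 <- detect_stop(tr3, lat)
  expect_true(st3$stopped)
  expect_equal(features_crossed(tr3, lat, st3$stop_feature, st3$stop_onset_min), 0)

  # re-entry into the same feature counts as a new event
  x4 <- c(-8, 0, 8, 0, -8)
  tr4 <- line_traj(x4, rep(0, 5))
  expect_equal(features_crossed(tr4, lat), 2)
})

test_that("interpolated crossings are caught even when frames straddle a disc", {
  # 18-um steps jump across whole encounter discs between frames
  tr <- line_traj(c(-9, 9, 27, 45), rep(0, 4))
  expect_equal(features_crossed(tr, lat), 4)   # discs at x = 0, 15, 30, 45
})

test_that("metrics are invariant under rigid translation of track and lattice", {
  set.seed(11)
  for (rep_i in 1:10) {
    x <- cumsum(c(runif(1, 0, 15), rnorm(40, 0, 4)))
    y <- cumsum(c(runif(1, 0, 15), rnorm(40, 0, 4)))
    tr <- line_traj(x, y)
    shift <- c(3, -2) * lat$pitch              # lattice-period translation
    tr2 <- line_traj(x + shift[1], y + shift[2])
    s1 <- detect_stop(tr, lat); s2 <- detect_stop(tr2, lat)
    expect_equal(s1$stopped, s2$stopped)
    expect_equal(s1$stop_onset_min, s2$stop_onset_min)
    expect_equal(features_crossed(tr, lat, s1$stop_feature, s1$stop_onset_min),
                 features_crossed(tr2, lat, s2$stop_feature, s2$stop_onset_min))
    expect_equal(average_speed(tr), average_speed(tr2))
  }
})

test_that("stop detection is monotone in the confinement tolerance", {
  set.seed(21)
  for (rep_i in 1:20) {
    x <- cumsum(c(runif(1, 0, 15), rnorm(60, 0, 2)))
    y <- cumsum(c(runif(1, 0, 15), rnorm(60, 0, 2)))
    tr <- line_traj(x, y)
    stopped <- vapply(c(0.5, 1, 2, 4, 8), function(tol)
      detect_stop(tr, lat, stop_tolerance = tol)$stopped, TRUE)
    expect_true(all(diff(stopped) >= 0))       # FALSE -> TRUE only
  }
})

test_that("donor summaries split by PD-1 label and respect the inclusion flag", {
  sp <- default_group_specs()[[1]]
  trs <- simulate_trajectories(sp, lat, n_cells = 12, duration_min = 30,
                               seed = 6, pd1_labels = c("positive", "negative"))
  ms <- summarize_motility(trs, lat)
  expect_equal(ms$n_cells, 12)
  # per-label means match direct computation on manually split subsets
  for (lab in c("positive", "negative")) {
    sub <- ms$cells[ms$cells$pd1_label == lab, ]
    row <- ms$summary[ms$summary$pd1_label == lab, ]
    expect_equal(row$speed_mean, mean(sub$speed_um_min, na.rm = TRUE))
    expect_equal(row$features_mean, mean(sub$n_features_crossed))
    expect_equal(row$n_stopped, sum(sub$stopped))
  }
  # single stopped cell: summary equals that cell's metrics
  one <- summarize_motility(trs[1], lat)
  expect_equal(one$summary$speed_mean, one$cells$speed_um_min[1])
  expect_equal(one$summary$n_cells, 1)
  # all excluded -> empty summary with explicit zero-cell count
  excl <- lapply(trs, function(tr) { tr$include <- FALSE; tr })
  ms0 <- summarize_motility(excl, lat)
  expect_equal(ms0$n_cells, 0)
  expect_equal(ms0$n_excluded, 12)
  expect_equal(nrow(ms0$cells), 0)
})

test_that("stopped fraction matches 1 - (1 - h)^k for the encounter process", {
  h <- 0.3
  sp0 <- group_spec("1", n = 1, pd1_pct = c(10, 2), alignment_pct = c(10, 2),
                    il2 = c(1, 1), max_doublings = c(1, 1),
                    speed_um_min = 7, persistence_min = 6, stop_hazard = 0)
  sph <- sp0; sph$stop_hazard <- h
  n_cells <- 220
  stopped <- logical(n_cells); p_exp <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    # twin runs share the per-encounter RNG stream until the first halt,
    # so the hazard-0 twin exposes the cell's encounter opportunities k_i
    tw <- simulate_trajectories(sp0, lat, 1, duration_min = 25, seed = 1000 + i,
                                jitter_um = 0)[[1]]
    k_i <- features_crossed(tw, lat)
    p_exp[i] <- 1 - (1 - h)^k_i
    tr <- simulate_trajectories(sph, lat, 1, duration_min = 25, seed = 1000 + i,
                                jitter_um = 0)[[1]]
    stopped[i] <- attr(tr, "halted")
  }
  se <- sqrt(sum(p_exp * (1 - p_exp))) / n_cells
  expect_lt(abs(mean(stopped) - mean(p_exp)), 4 * se + 0.01)
})
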