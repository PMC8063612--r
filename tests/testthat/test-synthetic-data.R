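test_that("cohort generation is deterministic and respects the missingness contract", {
  specs <- default_group_specs()
  a <- generate_cohort(specs, missing_rate = 0.1, seed = 42)
  b <- generate_cohort(specs, missing_rate = 0.1, seed = 42)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)

  no_miss <- generate_cohort(specs, missing_rate = 0, seed = 3)
  expect_false(any(as.matrix(no_miss$missing_mask)))
  expect_false(anyNA(no_miss$table[no_miss$table$status == "cll",
                                   c("pd1_pct", "il2", "max_doublings")]))

  # missingness hits numeric CLL cells only; identifiers and status intact
  expect_false(anyNA(a$table$donor_id))
  expect_false(anyNA(a$table$status))
  healthy <- a$table[a$table$status == "healthy", ]
  expect_false(anyNA(healthy[c("pd1_pct", "alignment_pct", "il2",
                               "max_doublings", "age_dx")]))
  expect_true(all(is.na(healthy$rai)))
  expect_false(anyDuplicated(a$table$donor_id) > 0)
})

test_that("generated percentages stay in [0, 100] and Rai in 0..4 across seeds", {
  specs <- default_group_specs()
  for (s in 1:12) {
    tab <- generate_cohort(specs, missing_rate = 0, seed = s)$table
    expect_true(all(tab$pd1_pct >= 0 & tab$pd1_pct <= 100))
    expect_true(all(tab$alignment_pct >= 0 & tab$alignment_pct <= 100))
    expect_true(all(tab$il2 >= 0))
    expect_true(all(tab$max_doublings >= 0))
    expect_true(all(is.na(tab$rai) | tab$rai %in% 0:4))
  }
})

test_that("healthy doublings match their generating distribution (5.5 +/- 0.4, n = 5)", {
  specs <- default_group_specs()
  means <- vapply(1:40, function(s) {
    tab <- generate_cohort(specs, missing_rate = 0, seed = s)$table
    mean(tab$max_doublings[tab$status == "healthy"])
  }, 0)
  # grand mean of 40 cohorts x 5 healthy donors: SE = 0.4 / sqrt(200)
  expect_lt(abs(mean(means) - 5.5), 3 * 0.4 / sqrt(200))
})

test_that("rai stage is drawn independently of the latent group", {
  co <- generate_cohort(separated_specs(n1 = 60, n2 = 60, n3 = 60),
                        missing_rate = 0, seed = 9)
  cll <- co$table[co$table$status == "cll", ]
  grp <- co$truth$group[match(cll$donor_id, co$truth$donor_id)]
  kw <- kruskal.test(cll$rai, factor(grp))
  expect_gt(kw$p.value, 0.01)
})

test_that("generator input validation rejects bad arguments", {
  expect_error(group_spec("1", n = 0, pd1_pct = c(10, 2),
                          alignment_pct = c(10, 2), il2 = c(1, 1),
                          max_doublings = c(1, 1)), "positive integer")
  expect_error(generate_cohort(rai_weights = c(1, 1, 1, 1, 1)), "summing to 1")
  expect_error(generate_cohort(missing_rate = 0.6), "missing_rate")
})

test_that("expansion-curve maximum and OKT3 percentage follow their definitions", {
  expect_equal(max_doublings(expansion_curve(0:4, c(0, 1, 2, 3, 2.5))), 3)
  mono <- expansion_curve(0:5, seq(0, 4, length.out = 6))
  expect_equal(max_doublings(mono), 4)
  expect_equal(max_doublings(expansion_curve(0:3, rep(0, 4))), 0)
  expect_error(expansion_curve(numeric(0), numeric(0)), "empty")
  expect_error(expansion_curve(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")

  sim <- simulate_expansion(5.5)
  expect_lte(max_doublings(sim), 5.5 + 1e-9)
  expect_true(all(diff(sim$days) > 0))

  expect_equal(okt3_percent(3, 20), 15)
  expect_equal(okt3_percent(0), 0)
  expect_equal(okt3_percent(20, 20), 100)
  expect_error(okt3_percent(-1), "okt3_conc")
  expect_error(okt3_percent(25, 20), "okt3_conc")
})

test_that("simulated trajectories have the contracted frame grid and speed", {
  sp <- group_spec("1", n = 1, pd1_pct = c(10, 2), alignment_pct = c(10, 2),
                   il2 = c(1, 1), max_doublings = c(1, 1),
                   speed_um_min = 8, persistence_min = 1e6, stop_hazard = 0)
  lat <- lattice()
  trs <- simulate_trajectories(sp, lat, n_cells = 5, duration_min = 60,
                               dt_s = 30, seed = 4)
  expect_length(trs[[1]]$t_s, 121)            # 60 * 60 / 30 + 1 frames
  expect_equal(trs[[1]]$t_s[1], 0)
  expect_equal(diff(trs[[1]]$t_s), rep(30, 120))
  for (tr in trs) {
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    expect_lt(abs(mean(steps) / 30 * 60 - 8) / 8, 0.1)
  }
})

test_that("stop hazard 1 halts a cell that starts on a feature at frame 0", {
  lat <- lattice()
  sp <- group_spec("1", n = 1, pd1_pct = c(10, 2), alignment_pct = c(10, 2),
                   il2 = c(1, 1), max_doublings = c(1, 1), stop_hazard = 1)
  # over many seeds, every cell that begins inside an encounter disc and
  # every cell that ever enters one must halt
  trs <- unlist(lapply(1:6, function(s)
    simulate_trajectories(sp, lat, n_cells = 10, duration_min = 20,
                          seed = s)), recursive = FALSE)
  halted <- vapply(trs, function(tr) attr(tr, "halted"), TRUE)
  start_on <- vapply(trs, function(tr)
    !is.na(cllstrat:::feature_at(lat, tr$x_um[1], tr$y_um[1])), TRUE)
  expect_true(all(halted[start_on]))
  ht <- vapply(trs[halted & start_on], function(tr) attr(tr, "halt_time_s"), 0)
  expect_true(all(ht == 0))
})

test_that("stop hazard 0 never produces a downstream stop", {
  lat <- lattice()
  sp <- group_spec("1", n = 1, pd1_pct = c(10, 2), alignment_pct = c(10, 2),
                   il2 = c(1, 1), max_doublings = c(1, 1), stop_hazard = 0,
                   speed_um_min = 6, persistence_min = 4)
  trs <- simulate_trajectories(sp, lat, n_cells = 30, duration_min = 60,
                               seed = 8)
  stops <- vapply(trs, function(tr) detect_stop(tr, lat)$stopped, TRUE)
  expect_false(any(stops))
})

test_that("cohort and trajectory CSV round-trips preserve the data", {
  co <- generate_cohort(missing_rate = 0.1, seed = 5)
  f <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".csv")
  write_cohort(co, f, ft)
  back <- read_cohort(f, ft)
  expect_equal(back$table$pd1_pct, co$table$pd1_pct, tolerance = 1e-12)
  expect_identical(back$table$donor_id, co$table$donor_id)
  expect_identical(back$truth$group, co$truth$group)
  expect_identical(as.matrix(back$missing_mask), as.matrix(co$missing_mask))

  sp <- default_group_specs()[[2]]
  trs <- simulate_trajectories(sp, lattice(), n_cells = 3, duration_min = 10,
                               seed = 2, pd1_labels = c("positive", "negative"))
  f2 <- tempfile(fileext = ".csv")
  write_trajectories(trs, f2)
  back2 <- read_trajectories(f2)
  expect_length(back2, 3)
  expect_equal(back2[[1]]$x_um, trs[[1]]$x_um, tolerance = 1e-12)
  expect_identical(back2[[2]]$pd1_label, trs[[2]]$pd1_label)
})
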