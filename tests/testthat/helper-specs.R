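# Group specifications with between-group separation >= 5 within-group SDs
# on every functional readout, for ground-truth recovery benchmarks.
separated_specs <- function(n1 = 15, n2 = 15, n3 = 12, n_healthy = 5) {
  # group orderings differ between readouts (alignment and PD-1 peak in
  # group 2) so the informative trio spans two ordination dimensions
  list(
    group_spec("1", n = n1, pd1_pct = c(10, 2), alignment_pct = c(50, 2),
               il2 = c(900, 20), max_doublings = c(5.2, 0.2)),
    group_spec("2", n = n2, pd1_pct = c(90, 2), alignment_pct = c(90, 2),
               il2 = c(500, 20), max_doublings = c(3.5, 0.2)),
    group_spec("3", n = n3, pd1_pct = c(50, 2), alignment_pct = c(10, 2),
               il2 = c(100, 20), max_doublings = c(1.5, 0.2)),
    group_spec("healthy", n = n_healthy, pd1_pct = c(15, 5),
               alignment_pct = c(60, 8), il2 = c(900, 150),
               max_doublings = c(5.5, 0.4))
  )
}

# adjusted Rand index between an assignment vector (named by donor) and the
# ground-truth sidecar of a synthetic cohort
ari_vs_truth <- function(assignments, truth) {
  truth_lab <- truth$group[match(names(assignments), truth$donor_id)]
  mclust::adjustedRandIndex(unname(assignments), truth_lab)
}

# straight-line trajectory through given points at fixed dt
line_traj <- function(x, y, dt_s = 30, ...) {
  trajectory(seq_along(x) * dt_s - dt_s, x, y, ...)
}
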