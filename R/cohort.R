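#' Specification of one latent donor group
#'
#' Bundles the sampling parameters used by [generate_cohort()] and
#' [simulate_trajectories()] for a single latent group of donors: truncated
#' normal means and standard deviations for the four functional readouts, a
#' donor count, and the motility parameters of the group's persistent random
#' walk.
#'
#' @param label group label, one of `"1"`, `"2"`, `"3"` or `"healthy"`.
#' @param n number of donors to draw for this group (>= 1).
#' @param pd1_pct,alignment_pct,il2,max_doublings length-2 numeric vectors
#'   `c(mean, sd)`. Percent variables are truncated to \[0, 100\], the other
#'   two to \[0, Inf).
#' @param speed_um_min nominal migration speed in micrometres per minute.
#' @param persistence_min directional persistence time in minutes.
#' @param stop_hazard probability, in \[0, 1\], that the cell halts
#'   permanently on each entry into a feature's encounter disc.
#'
#' @return an object of class `group_spec`.
#' @seealso [default_group_specs()] for the packaged defaults.
#' @export
group_spec <- function(label, n,
                       pd1_pct, alignment_pct, il2, max_doublings,
                       speed_um_min = 6, persistence_min = 4,
                       stop_hazard = 0.3) {
  stopifnot(length(label) == 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("donor count `n` must be a positive integer")
  for (nm in c("pd1_pct", "alignment_pct", "il2", "max_doublings")) {
    v <- get(nm)
    if (length(v) != 2L || !is.numeric(v) || v[2] < 0)
      stop(sprintf("`%s` must be c(mean, sd) with sd >= 0", nm))
  }
  if (stop_hazard < 0 || stop_hazard > 1) stop("stop_hazard must be in [0, 1]")
  if (speed_um_min < 0) stop("speed must be non-negative")
  if (persistence_min <= 0) stop("persistence time must be positive")
  structure(
    list(label = as.character(label), n = as.integer(n),
         pd1_pct = pd1_pct, alignment_pct = alignment_pct, il2 = il2,
         max_doublings = max_doublings,
         speed_um_min = speed_um_min, persistence_min = persistence_min,
         stop_hazard = stop_hazard),
    class = "group_spec")
}

#' Default latent group specifications
#'
#' Three CLL groups plus a small healthy reference. Healthy doublings follow
#' the published healthy benchmark (5.5 +/- 0.4 doublings, n = 5). The CLL
#' groups encode the qualitative orderings the stratification is built to
#' recover: maximum doublings Group 1 > Group 2 > Group 3; pattern alignment
#' highest in Group 2; PD-1 ordered differently from doublings; IL-2 ordered
#' like doublings. The exact means are configuration values, not estimates
#' of any real cohort.
#'
#' @param separation multiplier applied to the spread between group means
#'   around their common centre; `1` keeps the realistic defaults, larger
#'   values produce well-separated benchmark cohorts.
#' @return list of four [group_spec()] objects (groups 1-3 and healthy).
#' @export
default_group_specs <- function(separation = 1) {
  sep <- function(mu, centre) centre + (mu - centre) * separation
  list(
    group_spec("1", n = 15,
               pd1_pct = c(sep(20, 42), 8), alignment_pct = c(sep(55, 55), 8),
               il2 = c(sep(800, 500), 120), max_doublings = c(sep(5.0, 3.3), 0.5)),
    group_spec("2", n = 15,
               pd1_pct = c(sep(65, 42), 8), alignment_pct = c(sep(75, 55), 8),
               il2 = c(sep(500, 500), 120), max_doublings = c(sep(3.5, 3.3), 0.5),
               speed_um_min = 5, stop_hazard = 0.45),
    group_spec("3", n = 12,
               pd1_pct = c(sep(42, 42), 8), alignment_pct = c(sep(35, 55), 8),
               il2 = c(sep(200, 500), 90), max_doublings = c(sep(1.5, 3.3), 0.5),
               speed_um_min = 4.5, persistence_min = 3, stop_hazard = 0.15),
    group_spec("healthy", n = 5,
               pd1_pct = c(15, 5), alignment_pct = c(60, 8),
               il2 = c(900, 150), max_doublings = c(5.5, 0.4),
               stop_hazard = 0.4)
  )
}

# truncated normal by resampling until valid; avoids point masses at bounds
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation bounds incompatible with mean/sd")
  }
  out
}

#' Generate a synthetic donor cohort
#'
#' Draws one row per donor from the truncated normal distributions of each
#' group specification. Rai stage is drawn independently of the latent group
#' (CLL donors only; healthy donors have no Rai stage), reflecting the lack
#' of any Rai-proliferation dependence the stratification assumes. Sex and
#' IgVH mutation status are drawn as balanced binary factors independent of
#' group. Missingness is applied completely at random to numeric CLL cells
#' only, never to identifiers, status, or the ground-truth label.
#'
#' @param specs list of [group_spec()] objects, e.g. [default_group_specs()].
#' @param rai_weights categorical weights for Rai stages 0-4; must sum to 1.
#' @param missing_rate fraction of numeric CLL cells set missing, in
#'   \[0, 0.5).
#' @param seed integer seed; the same seed reproduces the table exactly.
#'
#' @return an object of class `cohort`: a list with `table` (data.frame of
#'   donor_id, status, sex, igvh, age_dx, rai, pd1_pct, alignment_pct, il2,
#'   max_doublings), `truth` (data.frame donor_id, group — the latent label,
#'   kept out of the analysis table), and `missing_mask` (logical data.frame
#'   over the numeric columns).
#' @export
generate_cohort <- function(specs = default_group_specs(),
                            rai_weights = c(0.20, 0.25, 0.25, 0.20, 0.10),
                            missing_rate = 0.05,
                            seed = 1L) {
  if (!length(specs)) stop("at least one group_spec is required")
  if (!all(vapply(specs, inherits, logical(1), "group_spec")))
    stop("`specs` must be a list of group_spec objects")
  if (length(rai_weights) != 5L || any(rai_weights < 0) ||
      abs(sum(rai_weights) - 1) > 1e-8)
    stop("`rai_weights` must be 5 non-negative weights summing to 1")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("`missing_rate` must be in [0, 0.5)")
  set.seed(as.integer(seed))

  rows <- lapply(specs, function(sp) {
    n <- sp$n
    cll <- sp$label != "healthy"
    data.frame(
      group = rep(sp$label, n),
      status = if (cll) "cll" else "healthy",
      sex = sample(c("M", "F"), n, replace = TRUE),
      igvh = sample(c("mutated", "unmutated"), n, replace = TRUE),
      age_dx = rtrunc_norm(n, 65, 10, 30, 90),
      rai = if (cll) sample(0:4, n, replace = TRUE, prob = rai_weights)
            else rep(NA_integer_, n),
      pd1_pct = rtrunc_norm(n, sp$pd1_pct[1], sp$pd1_pct[2], 0, 100),
      alignment_pct = rtrunc_norm(n, sp$alignment_pct[1], sp$alignment_pct[2], 0, 100),
      il2 = rtrunc_norm(n, sp$il2[1], sp$il2[2], 0, Inf),
      max_doublings = rtrunc_norm(n, sp$max_doublings[1], sp$max_doublings[2], 0, Inf),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$donor_id <- sprintf("D%02d", seq_len(nrow(tab)))
  truth <- data.frame(donor_id = tab$donor_id, group = tab$group,
                      stringsAsFactors = FALSE)
  tab$group <- NULL
  tab <- tab[, c("donor_id", "status", "sex", "igvh", "age_dx", "rai",
                 "pd1_pct", "alignment_pct", "il2", "max_doublings")]

  num_cols <- c("age_dx", "rai", "pd1_pct", "alignment_pct", "il2",
                "max_doublings")
  mask <- as.data.frame(matrix(FALSE, nrow(tab), length(num_cols),
                               dimnames = list(tab$donor_id, num_cols)))
  if (missing_rate > 0) {
    cll_rows <- which(tab$status == "cll")
    for (cl in num_cols) {
      hit <- cll_rows[runif(length(cll_rows)) < missing_rate]
      tab[hit, cl] <- NA
      mask[hit, cl] <- TRUE
    }
  }
  rownames(tab) <- tab$donor_id
  structure(list(table = tab, truth = truth, missing_mask = mask,
                 seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic donor cohort: %d donors (%d CLL, %d healthy), %d missing cells\n",
              nrow(x$table), sum(x$table$status == "cll"),
              sum(x$table$status == "healthy"), sum(as.matrix(x$missing_mask))))
  print(head(x$table, 4))
  invisible(x)
}

#' Read and write cohort tables
#'
#' The cohort CSV dialect has one header row, one row per donor, and empty
#' fields for missing cells. The ground-truth labels live in a separate
#' sidecar CSV so they can never leak into the analysis table.
#'
#' @param cohort a `cohort` object.
#' @param path path of the cohort CSV.
#' @param truth_path optional path of the ground-truth sidecar CSV.
#' @return `read_cohort` returns a `cohort` object (with `truth = NULL` when
#'   no sidecar is given).
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  write.csv(cohort$table, path, row.names = FALSE, na = "")
  if (!is.null(truth_path) && !is.null(cohort$truth))
    write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, truth_path = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(donor_id = "character"))
  if (anyDuplicated(tab$donor_id)) stop("donor_id must be unique")
  num_cols <- intersect(c("age_dx", "rai", "pd1_pct", "alignment_pct", "il2",
                          "max_doublings"), names(tab))
  for (cl in c("pd1_pct", "alignment_pct")) {
    bad <- !is.na(tab[[cl]]) & (tab[[cl]] < 0 | tab[[cl]] > 100)
    if (any(bad)) stop(sprintf("%s outside [0, 100]", cl))
  }
  if (any(!is.na(tab$rai) & !(tab$rai %in% 0:4)))
    stop("rai must be in 0..4 or missing")
  if (any(tab$status == "healthy" & !is.na(tab$rai)))
    stop("healthy donors cannot carry a Rai stage")
  mask <- as.data.frame(lapply(tab[num_cols], is.na))
  if ("rai" %in% names(mask))            # healthy Rai is structural, not missing
    mask$rai[tab$status == "healthy"] <- FALSE
  rownames(mask) <- tab$donor_id
  rownames(tab) <- tab$donor_id
  truth <- if (!is.null(truth_path)) {
    read.csv(truth_path, stringsAsFactors = FALSE,
             colClasses = c(donor_id = "character"))
  }
  structure(list(table = tab, truth = truth, missing_mask = mask, seed = NA),
            class = "cohort")
}
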