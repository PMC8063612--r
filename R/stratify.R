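#' Default factor roles for the donor table
#'
#' The seven stratification factors: pattern alignment, IL-2 secretion,
#' PD-1 expression and age at diagnosis as numeric factors; Rai stage as an
#' ordinal factor (rank transformed, then treated as numeric); sex and IgVH
#' mutation status as categorical factors. Maximum doublings is the outcome
#' the groups are evaluated against and is never a clustering factor.
#'
#' @return list with elements `numeric`, `ordinal`, `categorical`.
#' @export
default_roles <- function() {
  list(numeric = c("age_dx", "pd1_pct", "alignment_pct", "il2"),
       ordinal = "rai",
       categorical = c("sex", "igvh"))
}

#' Run the donor-stratification analysis
#'
#' The core sequence applied to a cohort table: impute missing cells
#' (chained equations with predictive mean matching), fit FAMD to the CLL
#' donors over the seven factors, compute combined Dim1 + Dim2
#' contributions, select the factors above the equal-contribution threshold
#' (100/p percent), and cluster the donors by k-medoids on the selected
#' (weighted, centred) factor columns. Cluster labels are renumbered so
#' that Group 1 has the highest mean maximum doublings, making labels
#' interpretable; downstream stability analysis reconciles labels
#' explicitly and never relies on this convention.
#'
#' @param cohort a `cohort` object or cohort data.frame.
#' @param roles factor roles, see [default_roles()].
#' @param k integer number of groups, or `"elbow"` to select it via
#'   [elbow_select()].
#' @param k_max largest k scanned when `k = "elbow"`.
#' @param iterations,pmm_k imputation settings, see [impute_cohort()].
#' @param seed integer seed for the imputation draws.
#' @param order_by_doublings renumber groups by decreasing mean
#'   `max_doublings` (default TRUE).
#' @return object of class `stratification`: the completed table, the
#'   `imputation`, the `famd` fit, `contrib12`, the `selection`, the elbow
#'   `curve` (when used), `k`, the `clustering` (`pam_result`),
#'   `assignments` (named vector over CLL donors) and `dim12_variance_pct`.
#' @export
stratify_donors <- function(cohort, roles = default_roles(), k = 3,
                            k_max = 8L, iterations = 10L, pmm_k = 5L,
                            seed = 1L, order_by_doublings = TRUE) {
  tab <- if (inherits(cohort, "cohort")) cohort$table else cohort
  imp <- impute_cohort(tab, iterations = iterations, pmm_k = pmm_k,
                       seed = seed)
  completed <- imp$data
  cll <- completed[completed$status == "cll", , drop = FALSE]
  fi <- famd_preprocess(cll, roles)
  ft <- famd_fit(fi)
  c12 <- contributions_dim12(ft)
  sel <- select_factors(c12)
  Zsel <- fi$Z[, fi$col_factor %in% sel$selected, drop = FALSE]
  curve <- NULL
  if (identical(k, "elbow")) {
    eb <- elbow_select(Zsel, k_max = k_max)
    k <- eb$k; curve <- eb$curve
  }
  pc <- pam_cluster(Zsel, k)
  assignments <- pc$assignments
  if (order_by_doublings && k > 1) {
    means <- tapply(cll$max_doublings, assignments, mean)
    relab <- integer(k)
    relab[as.integer(names(sort(means, decreasing = TRUE)))] <- seq_len(k)
    assignments <- setNames(relab[assignments], names(assignments))
    pc$assignments <- assignments
    pc$medoids <- pc$medoids[order(relab)]
  }
  structure(list(completed = completed, imputation = imp, famd = ft,
                 contrib12 = c12, selection = sel, elbow_curve = curve,
                 k = as.integer(k), clustering = pc,
                 assignments = assignments,
                 dim12_variance_pct = sum(ft$variance_pct[1:2])),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("Donor stratification: %d CLL donors in %d groups\n",
              length(x$assignments), x$k))
  cat(sprintf("Dim1 + Dim2 variance: %.1f%% (Dim1 %.1f%%, Dim2 %.1f%%)\n",
              x$dim12_variance_pct, x$famd$variance_pct[1],
              x$famd$variance_pct[2]))
  cat(sprintf("Selected factors (> %s%%): %s\n", x$selection$threshold_label,
              paste(x$selection$selected, collapse = ", ")))
  print(table(group = x$assignments))
  invisible(x)
}
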