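# all permutations of 1..k in lexicographic order (k is small: k! rows)
perm_lex <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_lex(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- setdiff(seq_len(k), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

#' Reconcile cluster labels between two runs
#'
#' Cluster labels are arbitrary, so assignments from different runs can only
#' be compared after matching labels. All k! relabelings of the candidate
#' are evaluated and the one maximising agreement with the reference over
#' the shared donors is returned; ties go to the lexicographically smallest
#' permutation.
#'
#' @param reference,candidate named integer vectors (donor -> label in
#'   1..k); names identify donors, and at least one donor must be shared.
#' @param k number of clusters.
#' @return list with `assignments` (the relabeled candidate, all donors),
#'   `permutation` (new label for each old label) and `agreement` (fraction
#'   of shared donors matching the reference after relabeling).
#' @export
reconcile_labels <- function(reference, candidate, k) {
  if (!all(reference %in% seq_len(k)) || !all(candidate %in% seq_len(k)))
    stop("labels must lie in 1..k")
  shared <- intersect(names(reference), names(candidate))
  if (!length(shared)) stop("no shared donors to reconcile on")
  P <- perm_lex(k)
  agree <- apply(P, 1L, function(p)
    mean(p[candidate[shared]] == reference[shared]))
  best <- which.max(agree)                      # first max = lexicographic tie-break
  p <- P[best, ]
  list(assignments = setNames(as.integer(p[candidate]), names(candidate)),
       permutation = as.integer(p), agreement = agree[best])
}

#' Resampling stability of the donor groups
#'
#' Repeats the full analysis (re-imputation, FAMD, equal-contribution factor
#' selection, k-medoids at the reference k) on resampled cohorts —
#' bootstrap samples of size n with replacement, or 90% subsamples without
#' replacement — reconciles each run's labels to the reference assignment,
#' and accumulates the frequency with which each donor lands in each group
#' over the resamples in which it appears. The Dim1 + Dim2 variance of each
#' resample is recorded and summarised as a 2.5/97.5 percentile interval.
#'
#' k is held at the reference value during resampling (re-running elbow
#' selection would make label reconciliation ill-posed across differing k),
#' while factor selection is re-run within every resample. Resamples in
#' which a selected factor degenerates (constant column, single-level
#' categorical, or empty selection) are skipped and counted. In a bootstrap
#' resample a donor drawn several times contributes one assignment (its
#' first sampled row).
#'
#' @param cohort a `cohort` object or cohort data.frame.
#' @param scheme `"bootstrap"` or `"subsample90"`.
#' @param B number of resamples (default 500).
#' @param roles factor roles, see [default_roles()].
#' @param k_ref reference number of groups (default 3).
#' @param reimpute re-impute within each resample (default TRUE); FALSE
#'   reuses the reference completed table, isolating clustering variability.
#' @param iterations,pmm_k imputation settings.
#' @param seed integer seed driving resampling and per-resample imputation.
#' @param reference optional `stratification` to reconcile against;
#'   computed from the cohort when NULL.
#' @return object of class `stability_report`: `freq` (donor x group
#'   assignment frequencies, rows summing to 1 over appearances), `counts`,
#'   `appearances`, `modal` (data.frame donor_id, group, frequency),
#'   `dim12_ci` (2.5% and 97.5% percentiles), `dim12_values`, `B`, `B_used`,
#'   `skipped`, `scheme`, `reference`, `log`.
#' @export
resample_stability <- function(cohort, scheme = c("bootstrap", "subsample90"),
                               B = 500L, roles = default_roles(), k_ref = 3L,
                               reimpute = TRUE, iterations = 10L, pmm_k = 5L,
                               seed = 1L, reference = NULL) {
  scheme <- match.arg(scheme)
  if (B < 1) stop("B must be >= 1")
  tab <- if (inherits(cohort, "cohort")) cohort$table else cohort
  if (is.null(reference))
    reference <- stratify_donors(tab, roles = roles, k = k_ref,
                                 iterations = iterations, pmm_k = pmm_k,
                                 seed = seed)
  ref_assign <- reference$assignments
  cll <- tab[tab$status == "cll", , drop = FALSE]
  ref_completed_cll <- reference$completed[
    reference$completed$status == "cll", , drop = FALSE]
  n <- nrow(cll)
  donors <- cll$donor_id
  m_size <- if (scheme == "bootstrap") n else ceiling(0.9 * n)

  set.seed(as.integer(seed))
  idx_sets <- lapply(seq_len(B), function(b)
    sample.int(n, m_size, replace = scheme == "bootstrap"))

  counts <- matrix(0L, n, k_ref, dimnames = list(donors, seq_len(k_ref)))
  appearances <- setNames(integer(n), donors)
  dim12 <- rep(NA_real_, B)
  skipped <- 0L; log <- character()

  for (b in seq_len(B)) {
    idx <- idx_sets[[b]]
    subtab <- cll[idx, , drop = FALSE]
    rownames(subtab) <- make.unique(subtab$donor_id)
    res <- tryCatch({
      comp <- if (reimpute) {
        seed_b <- (as.integer(seed) %% 100003L) * 10007L + b
        impute_cohort(subtab, iterations = iterations, pmm_k = pmm_k,
                      seed = seed_b)$data
      } else {
        rc <- ref_completed_cll[idx, , drop = FALSE]
        rownames(rc) <- rownames(subtab)
        rc
      }
      fi <- famd_preprocess(comp, roles)
      ft <- famd_fit(fi)
      sel <- select_factors(contributions_dim12(ft))
      Zsel <- fi$Z[, fi$col_factor %in% sel$selected, drop = FALSE]
      pc <- pam_cluster(Zsel, k_ref)
      list(ft = ft, pc = pc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
      log <- c(log, sprintf("resample %d skipped: %s", b,
                            conditionMessage(res)))
      next
    }
    dim12[b] <- sum(res$ft$variance_pct[1:2])
    first <- !duplicated(subtab$donor_id)
    cand <- setNames(res$pc$assignments[first], subtab$donor_id[first])
    rec <- reconcile_labels(ref_assign, cand, k_ref)
    counts[cbind(names(rec$assignments),
                 as.character(rec$assignments))] <-
      counts[cbind(names(rec$assignments), as.character(rec$assignments))] + 1L
    appearances[names(rec$assignments)] <-
      appearances[names(rec$assignments)] + 1L
  }
  freq <- counts / pmax(appearances, 1L)
  modal_idx <- apply(freq, 1L, which.max)
  modal <- data.frame(donor_id = donors,
                      group = as.integer(modal_idx),
                      frequency = freq[cbind(seq_len(n), modal_idx)],
                      appearances = as.integer(appearances),
                      stringsAsFactors = FALSE)
  structure(list(freq = freq, counts = counts, appearances = appearances,
                 modal = modal,
                 dim12_ci = quantile(dim12, c(0.025, 0.975), na.rm = TRUE,
                                     names = FALSE),
                 dim12_values = dim12, B = as.integer(B),
                 B_used = as.integer(B - skipped), skipped = skipped,
                 scheme = scheme, reference = ref_assign, log = log),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability over %d %s resamples (%d used, %d skipped)\n",
              x$B, x$scheme, x$B_used, x$skipped))
  cat(sprintf("Dim1+Dim2 variance 95%% interval: %.1f-%.1f%%\n",
              x$dim12_ci[1], x$dim12_ci[2]))
  cat(sprintf("Minimum modal-assignment frequency: %.3f (donor %s)\n",
              min(x$modal$frequency),
              x$modal$donor_id[which.min(x$modal$frequency)]))
  invisible(x)
}
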