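#' Chained-equation imputation with predictive mean matching
#'
#' Fills missing cells of a mixed-type table by iterated conditional models:
#' numeric targets use predictive mean matching (a linear model predicts the
#' target from the other factors; each missing cell receives the observed
#' value of a donor drawn from the `pmm_k` closest predictions), categorical
#' targets use a logistic draw (falling back to an observed-frequency draw
#' when the logistic fit does not converge; every fallback is logged).
#' Missing cells are initialised by the column mean (numeric) or mode
#' (categorical), then the chain sweeps the target columns in a fixed order
#' for `iterations` rounds. Observed cells are never touched, and imputed
#' numeric values always lie within the observed range of their column — a
#' property of predictive mean matching.
#'
#' @param data data.frame; predictor columns must be complete.
#' @param numeric_cols,categorical_cols names of possible target columns.
#' @param predictor_cols names of predictor columns (may overlap targets;
#'   a target never predicts itself).
#' @param iterations number of chained sweeps (default 10).
#' @param pmm_k donor pool size for predictive mean matching (default 5).
#' @param m number of completed data sets (default 1).
#' @param seed integer seed; same seed and table give identical completions.
#' @return object of class `imputation`: `completions` (list of m completed
#'   data.frames), `data` (the first completion), `flags` (logical
#'   data.frame marking imputed cells), `m`, `log` (character).
#' @export
impute_mixed <- function(data, numeric_cols, categorical_cols = character(),
                         predictor_cols = setdiff(names(data),
                                                  c(numeric_cols, categorical_cols)),
                         iterations = 10L, pmm_k = 5L, m = 1L, seed = 1L) {
  stopifnot(is.data.frame(data), iterations >= 1, pmm_k >= 1, m >= 1)
  targets <- c(numeric_cols, categorical_cols)
  targets <- targets[vapply(targets, function(cl) anyNA(data[[cl]]), TRUE)]
  flags <- as.data.frame(lapply(data, function(v) rep(FALSE, nrow(data))))
  names(flags) <- names(data); rownames(flags) <- rownames(data)
  for (cl in targets) flags[[cl]] <- is.na(data[[cl]])
  for (cl in targets) {
    n_obs <- sum(!is.na(data[[cl]]))
    if (n_obs == 0) stop(sprintf("column '%s' is fully missing", cl))
    if (n_obs < 3) stop(sprintf("column '%s' has fewer than 3 observed values", cl))
  }
  non_target_pred <- setdiff(predictor_cols, targets)
  if (anyNA(data[non_target_pred]))
    stop("predictor columns outside the target set must be complete")
  if (!length(targets))
    return(structure(list(completions = list(data), data = data,
                          flags = flags, m = m, log = character()),
                     class = "imputation"))
  set.seed(as.integer(seed))
  log <- character()
  design <- function(completed, exclude) {
    preds <- setdiff(predictor_cols, exclude)
    if (!length(preds)) return(matrix(1, nrow(completed), 1))
    df <- completed[preds]
    df[] <- lapply(df, function(v)
      if (is.character(v) || is.factor(v)) droplevels(factor(v)) else v)
    df <- df[vapply(df, function(v) !is.factor(v) || nlevels(v) >= 2, TRUE)]
    if (!ncol(df)) return(matrix(1, nrow(completed), 1))
    model.matrix(~ ., df)
  }
  impute_once <- function() {
    comp <- data
    for (cl in targets) {             # mean / mode initialisation
      mis <- flags[[cl]]
      if (cl %in% numeric_cols) {
        comp[[cl]][mis] <- mean(data[[cl]], na.rm = TRUE)
      } else {
        tab <- table(data[[cl]])
        comp[[cl]][mis] <- names(tab)[which.max(tab)]
      }
    }
    int_target <- vapply(targets, function(cl) is.integer(data[[cl]]), TRUE)
    for (it in seq_len(iterations)) {
      for (cl in targets) {
        mis <- which(flags[[cl]]); obs <- which(!flags[[cl]])
        X <- design(comp, cl)
        if (cl %in% numeric_cols) {
          y <- data[[cl]]
          fit <- lm.fit(X[obs, , drop = FALSE], y[obs])
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          yhat <- drop(X %*% beta)
          k <- min(pmm_k, length(obs))
          for (i in mis) {
            pool <- obs[order(abs(yhat[obs] - yhat[i]))[seq_len(k)]]
            comp[[cl]][i] <- y[pool[sample.int(k, 1L)]]
          }
        } else {
          yf <- factor(data[[cl]][obs])
          if (nlevels(yf) == 2) {
            p <- tryCatch({
              g <- suppressWarnings(
                glm.fit(X[obs, , drop = FALSE], as.numeric(yf) - 1,
                        family = binomial()))
              if (!g$converged) stop("logistic fit did not converge")
              beta <- g$coefficients; beta[is.na(beta)] <- 0
              1 / (1 + exp(-drop(X[mis, , drop = FALSE] %*% beta)))
            }, error = function(e) {
              log <<- c(log, sprintf(
                "column '%s' iteration %d: %s; observed-frequency draw used",
                cl, it, conditionMessage(e)))
              rep(mean(as.numeric(yf) - 1), length(mis))
            })
            comp[[cl]][mis] <- levels(yf)[1 + (runif(length(mis)) < p)]
          } else {
            log <<- c(log, sprintf(
              "column '%s': >2 levels, observed-frequency draw used", cl))
            comp[[cl]][mis] <- as.character(
              sample(as.character(yf), length(mis), replace = TRUE))
          }
        }
      }
    }
    # PMM only ever draws observed values, so integer columns stay integral;
    # restore their storage mode after the mean initialisation doubled them
    for (cl in targets[int_target])
      if (cl %in% numeric_cols) comp[[cl]] <- as.integer(comp[[cl]])
    comp
  }
  completions <- lapply(seq_len(m), function(j) impute_once())
  structure(list(completions = completions, data = completions[[1]],
                 flags = flags, m = m, log = log),
            class = "imputation")
}

#' @export
print.imputation <- function(x, ...) {
  cat(sprintf("Chained-equation imputation: %d completed set(s), %d imputed cells\n",
              x$m, sum(vapply(x$flags, sum, 0))))
  if (length(x$log)) cat(length(x$log), "fallback event(s) logged\n")
  invisible(x)
}

#' Impute a donor cohort
#'
#' Cohort-aware wrapper around [impute_mixed()]. Imputation runs on the CLL
#' donors (healthy donors are the complete reference set and keep their
#' structurally missing Rai stage). Rai stage is imputed by predictive mean
#' matching, which can only return observed stages, so imputed values stay
#' in 0-4. Maximum doublings is the evaluation outcome of the
#' stratification, so it is kept out of every conditional model's predictor
#' set (it is still completed if missing).
#'
#' @param cohort a `cohort` object or its `table` data.frame.
#' @param iterations,pmm_k,m,seed see [impute_mixed()].
#' @return an `imputation` whose completions are full cohort tables (healthy
#'   rows unchanged).
#' @export
impute_cohort <- function(cohort, iterations = 10L, pmm_k = 5L, m = 1L,
                          seed = 1L) {
  tab <- if (inherits(cohort, "cohort")) cohort$table else cohort
  stopifnot(is.data.frame(tab), "status" %in% names(tab))
  cll <- tab[tab$status == "cll", , drop = FALSE]
  healthy <- tab[tab$status != "cll", , drop = FALSE]
  num <- intersect(c("age_dx", "rai", "pd1_pct", "alignment_pct", "il2",
                     "max_doublings"), names(cll))
  cat_cols <- intersect(c("sex", "igvh"), names(cll))
  preds <- setdiff(c(num, cat_cols), "max_doublings")
  imp <- impute_mixed(cll, numeric_cols = num, categorical_cols = cat_cols,
                      predictor_cols = preds, iterations = iterations,
                      pmm_k = pmm_k, m = m, seed = seed)
  rebuild <- function(comp) {
    full <- rbind(comp, healthy)
    full[rownames(tab), , drop = FALSE]
  }
  completions <- lapply(imp$completions, rebuild)
  flags <- as.data.frame(lapply(tab, function(v) rep(FALSE, nrow(tab))))
  names(flags) <- names(tab); rownames(flags) <- rownames(tab)
  flags[rownames(imp$flags), names(imp$flags)] <- imp$flags
  structure(list(completions = completions, data = completions[[1]],
                 flags = flags, m = m, log = imp$log),
            class = "imputation")
}
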