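#' Preprocess a mixed donor table for FAMD
#'
#' Builds the weighted, centred design matrix of factor analysis of mixed
#' data. Numeric factors are z-scored (mean 0, SD 1). Ordinal factors (Rai
#' stage) are mid-rank transformed — ties receive their average rank — and
#' then z-scored, making them numeric factors with only their ordering
#' retained. Each level of a categorical factor becomes an indicator column
#' divided by the square root of the level proportion and then centred, the
#' standard FAMD weighting that balances categorical against numeric
#' factors.
#'
#' @param table complete data.frame (no missing values in the used columns),
#'   donors in rows.
#' @param roles list with character vectors `numeric`, `ordinal`,
#'   `categorical` naming columns of `table`.
#' @return object of class `famd_input`: the design matrix `Z` (rownames =
#'   donor rownames of `table`), `col_factor` mapping matrix columns to
#'   source factors, `roles`, `n`, and `p` (number of factors).
#' @export
famd_preprocess <- function(table, roles) {
  used <- c(roles$numeric, roles$ordinal, roles$categorical)
  if (!all(used %in% names(table))) stop("roles name columns absent from table")
  if (anyNA(table[used])) stop("FAMD input must be complete; impute first")
  n <- nrow(table)
  cols <- list(); col_factor <- character()
  zscore <- function(v, nm) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) stop(sprintf("constant numeric column '%s'", nm))
    (v - mean(v)) / s
  }
  for (nm in roles$numeric) {
    cols[[nm]] <- zscore(as.numeric(table[[nm]]), nm)
    col_factor <- c(col_factor, nm)
  }
  for (nm in roles$ordinal) {
    r <- rank(as.numeric(table[[nm]]), ties.method = "average")
    cols[[nm]] <- zscore(r, nm)
    col_factor <- c(col_factor, nm)
  }
  for (nm in roles$categorical) {
    f <- droplevels(factor(table[[nm]]))
    if (nlevels(f) < 2) stop(sprintf("categorical factor '%s' needs >= 2 observed levels", nm))
    for (lv in levels(f)) {
      ind <- as.numeric(f == lv)
      prop <- mean(ind)
      w <- ind / sqrt(prop)
      cols[[paste(nm, lv, sep = ".")]] <- w - mean(w)
      col_factor <- c(col_factor, nm)
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- rownames(table)
  structure(list(Z = Z, col_factor = col_factor, roles = roles,
                 n = n, p = length(used)),
            class = "famd_input")
}

#' Fit factor analysis of mixed data
#'
#' Singular value decomposition of the preprocessed design matrix divided by
#' sqrt(n) (population convention); eigenvalues are the squared singular
#' values. Donor scores are the projections of the design matrix on the
#' right singular vectors. Per-variable contributions to a dimension are the
#' squared loadings in percent, with a categorical factor's contribution
#' summed over its level columns. Sign indeterminacy is fixed by making each
#' dimension's largest-magnitude loading positive. Rank-deficient inputs
#' yield trailing zero eigenvalues, not an error.
#'
#' @param input a `famd_input` from [famd_preprocess()], or a data.frame
#'   together with `roles`.
#' @param roles used only when `input` is a data.frame.
#' @return object of class `famd`: `eigenvalues`, `variance_pct` (summing to
#'   100), `scores` (donors x dimensions), `contrib` (factors x dimensions,
#'   each column summing to 100), `loadings`, `col_factor`, `n`, `p`.
#' @export
famd_fit <- function(input, roles = NULL) {
  if (is.data.frame(input)) input <- famd_preprocess(input, roles)
  stopifnot(inherits(input, "famd_input"))
  if (input$n < 3) stop("FAMD needs at least 3 donors")
  Z <- input$Z
  sv <- svd(Z / sqrt(input$n))
  d <- sv$d
  d[d < 1e-12] <- 0
  lambda <- d^2
  if (sum(lambda) == 0) stop("degenerate input: no variance")
  V <- sv$v; U <- sv$u
  for (s in seq_along(d)) {            # largest-|loading|-positive convention
    j <- which.max(abs(V[, s]))
    if (V[j, s] < 0) { V[, s] <- -V[, s]; U[, s] <- -U[, s] }
  }
  scores <- Z %*% V
  dimnames(scores) <- list(rownames(Z), paste0("Dim", seq_along(d)))
  ctr_col <- 100 * V^2
  contrib <- rowsum(ctr_col, group = input$col_factor, reorder = FALSE)
  colnames(contrib) <- paste0("Dim", seq_along(d))
  structure(list(eigenvalues = lambda,
                 variance_pct = 100 * lambda / sum(lambda),
                 scores = scores, contrib = contrib, loadings = V,
                 col_factor = input$col_factor, n = input$n, p = input$p),
            class = "famd")
}

#' @export
print.famd <- function(x, ...) {
  cat(sprintf("FAMD of %d donors, %d factors\n", x$n, x$p))
  k <- min(5, length(x$eigenvalues))
  cat("Variance explained (%):",
      paste(sprintf("Dim%d %.1f", seq_len(k), x$variance_pct[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Combined factor contributions to the first two dimensions
#'
#' The eigenvalue-weighted average of each factor's contribution to
#' dimensions 1 and 2: `(ctr1 * lambda1 + ctr2 * lambda2) / (lambda1 +
#' lambda2)`. Sums to 100 over factors.
#'
#' @param fit a `famd` object.
#' @return named numeric vector of percentages.
#' @export
contributions_dim12 <- function(fit) {
  stopifnot(inherits(fit, "famd"))
  if (ncol(fit$contrib) < 2) stop("need at least 2 dimensions")
  l <- fit$eigenvalues[1:2]
  if (sum(l) == 0) stop("first two eigenvalues are zero")
  drop(fit$contrib[, 1:2, drop = FALSE] %*% l) / sum(l)
}

#' Equal-contribution factor selection
#'
#' With p factors, a factor pulling its own weight would contribute exactly
#' 100/p percent to the combined Dim1 + Dim2; factors contributing strictly
#' more than that threshold are selected for clustering. With the seven
#' donor factors the threshold is 14.3%.
#'
#' @param contribs named percentages summing to 100 (see
#'   [contributions_dim12()]).
#' @param p number of factors; defaults to `length(contribs)`.
#' @return list with `selected` (factor names), `threshold_pct` (exact
#'   100/p) and `threshold_label` (rounded to one decimal, as reported).
#' @export
select_factors <- function(contribs, p = length(contribs)) {
  if (p < 1) stop("p must be >= 1")
  if (abs(sum(contribs) - 100) > 1e-6)
    stop("contributions must sum to 100")
  thr <- 100 / p
  sel <- names(contribs)[contribs > thr]
  if (!length(sel))
    stop("no factor exceeds the equal-contribution threshold; ",
         "inspect the scree and contribution tables before clustering")
  list(selected = sel, threshold_pct = thr,
       threshold_label = sprintf("%.1f", thr))
}
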