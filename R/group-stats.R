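# Kruskal-Wallis H with tie correction, from pooled ranks
kw_H <- function(r, g, n, tie_c) {
  sums <- rowsum(r, g)
  sizes <- tabulate(g)
  H <- 12 / (n * (n + 1)) * sum(sums^2 / sizes[sizes > 0]) - 3 * (n + 1)
  if (tie_c == 0) 0 else H / tie_c
}

#' Permutation Kruskal-Wallis test
#'
#' The Kruskal-Wallis H statistic (with the usual tie correction) is
#' computed on the observed data, then group labels are permuted N times
#' and the p-value is the add-one-corrected upper tail
#' `(1 + #\{H* >= H\}) / (1 + N)`, which can never be exactly zero. Because
#' the statistic is rank-based, p-values are invariant under monotone
#' transformation of the values. Permutations are processed in chunks so
#' the default N = 1e6 stays within modest memory.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups, each non-empty).
#' @param N number of random permutations (default 1e6).
#' @param seed integer seed.
#' @return object of class `perm_test`: `statistic` (H), `p_value`, `N`,
#'   `seed`.
#' @export
kruskal_wallis_perm <- function(values, groups, N = 1e6, seed = 1L) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  g <- as.integer(factor(groups))
  if (max(g) < 2) stop("need at least 2 groups")
  if (any(tabulate(g) < 1)) stop("every group needs at least 1 observation")
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_c <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- kw_H(r, g, n, tie_c)
  set.seed(as.integer(seed))
  count <- 0
  left <- as.integer(N)
  chunk <- 20000L
  while (left > 0L) {
    m <- min(chunk, left)
    # m independent permutations of the labels, as columns
    idx <- matrix(runif(n * m), n, m)
    ord <- apply(idx, 2L, order)
    gp <- matrix(g[ord], n, m)
    sums2 <- 0
    for (j in seq_len(max(g))) {
      nj <- sum(g == j)
      sums2 <- sums2 + colSums(matrix(r, n, m) * (gp == j))^2 / nj
    }
    Hp <- 12 / (n * (n + 1)) * sums2 - 3 * (n + 1)
    Hp <- if (tie_c == 0) rep(0, m) else Hp / tie_c
    count <- count + sum(Hp >= H - 1e-12)
    left <- left - m
  }
  structure(list(statistic = H, p_value = (1 + count) / (1 + N),
                 N = as.integer(N), seed = as.integer(seed)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation Kruskal-Wallis: H = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$N))
  invisible(x)
}

#' Significance tier marker for figure annotation
#'
#' The tier convention: `****` p < 0.0001, `***` p < 0.0005, `**` p < 0.005,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of markers.
#' @export
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 5e-4, 5e-3, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' One-way ANOVA with Tukey honest-significant-difference comparisons
#'
#' One-way ANOVA acts as the gate at alpha = 0.05; Tukey-Kramer adjusted
#' pairwise p-values (unequal group sizes supported) are computed for every
#' group pair, with tier markers emitted only when the gate passes.
#' Degenerate data with zero total variance yield F = 0 and all p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups; at least one group with >= 2
#'   observations).
#' @return object of class `group_comparison`: `means` (per-group n, mean,
#'   sd), `F`, `p_anova`, `anova_pass`, `pairwise` (pair, diff, lwr, upr,
#'   p_adj, tier).
#' @export
anova_tukey <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  g <- droplevels(factor(groups[ok]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (max(tabulate(g)) < 2) stop("need a group with >= 2 observations")
  means <- do.call(rbind, lapply(split(values, g), function(v)
    data.frame(n = length(v), mean = mean(v), sd = sd(v))))
  means <- cbind(data.frame(group = levels(g), stringsAsFactors = FALSE),
                 means)
  rownames(means) <- NULL
  pairs_lab <- utils::combn(levels(g), 2, FUN = paste, collapse = "-")
  if (var(values) == 0) {
    pairwise <- data.frame(pair = pairs_lab, diff = 0, lwr = 0, upr = 0,
                           p_adj = 1, tier = "ns", stringsAsFactors = FALSE)
    return(structure(list(means = means, F = 0, p_anova = 1,
                          anova_pass = FALSE, pairwise = pairwise),
                     class = "group_comparison"))
  }
  fit <- aov(values ~ g)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$g
  # TukeyHSD labels pairs "b-a"; normalise to "a-b" in combn order
  pairwise <- data.frame(
    pair = vapply(strsplit(rownames(tk), "-", fixed = TRUE),
                  function(x) paste(rev(x), collapse = "-"), ""),
    diff = -tk[, "diff"], lwr = -tk[, "upr"], upr = -tk[, "lwr"],
    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  pairwise <- pairwise[match(pairs_lab, pairwise$pair), ]
  rownames(pairwise) <- NULL
  pass <- an[["Pr(>F)"]][1] < 0.05
  pairwise$tier <- if (pass) significance_tier(pairwise$p_adj) else "ns"
  structure(list(means = means, F = an[["F value"]][1],
                 p_anova = an[["Pr(>F)"]][1], anova_pass = pass,
                 pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (gate %s)\n", x$F,
              x$p_anova, if (x$anova_pass) "passed" else "not passed"))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Two-tailed two-sample t-test
#'
#' Welch's unequal-variance form by default, with the pooled-variance form
#' available. Two zero-variance samples yield p = 1 when their means agree
#' (no evidence of a difference) and p = 0 when they differ (perfect
#' separation).
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param var_equal use the pooled-variance form (default FALSE = Welch).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
ttest2 <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("both samples need >= 2 values")
  if (var(a) == 0 && var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else Inf, df = NA_real_,
                p_value = if (same) 1 else 0))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' PD-1 low/high designation relative to healthy donors
#'
#' Donors whose PD-1+ percentage falls at or below the upper bound of the
#' healthy donors' 95% interval are designated "low"; those above it are
#' "high". The interval is the normal-theory confidence interval of the
#' healthy mean (t multiplier) by default; a reference-range variant
#' (mean +/- 1.96 SD of healthy values) is provided because the two readings
#' of a "95% confidence interval of healthy donors" differ. Boundary values
#' classify as "low" (non-strict comparison).
#'
#' @param healthy_pd1 PD-1+ percentages of >= 2 healthy donors.
#' @param donor_pd1 PD-1+ percentage(s) to classify.
#' @param method `"ci_mean"` (default) or `"reference_range"`.
#' @return character vector of `"low"` / `"high"`, with the upper bound in
#'   attribute `upper`.
#' @export
pd1_designation <- function(healthy_pd1, donor_pd1,
                            method = c("ci_mean", "reference_range")) {
  method <- match.arg(method)
  healthy_pd1 <- healthy_pd1[!is.na(healthy_pd1)]
  n <- length(healthy_pd1)
  if (n < 2) stop("need at least 2 healthy donors")
  m <- mean(healthy_pd1); s <- sd(healthy_pd1)
  upper <- if (method == "ci_mean")
    m + qt(0.975, n - 1) * s / sqrt(n)
  else m + 1.96 * s
  out <- ifelse(donor_pd1 <= upper, "low", "high")
  attr(out, "upper") <- upper
  out
}
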