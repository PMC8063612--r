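make_roles <- function(num = character(), ord = character(), cat = character())
  list(numeric = num, ordinal = ord, categorical = cat)

test_that("preprocessing z-scores numerics, mid-ranks ordinals, weights indicators", {
  df <- data.frame(a = c(1, 2, 3), rai = c(0, 2, 2), sex = c("M", "F", "M"))
  rownames(df) <- paste0("D", 1:3)
  fi <- famd_preprocess(df, make_roles("a", "rai", "sex"))
  expect_equal(mean(fi$Z[, "a"]), 0)
  expect_equal(sd(fi$Z[, "a"]), 1)

  # Rai (0, 2, 2, 4) -> mid-ranks (1, 2.5, 2.5, 4), then z-scored
  df2 <- data.frame(rai = c(0, 2, 2, 4), a = c(1, 2, 3, 4))
  fi2 <- famd_preprocess(df2, make_roles("a", "rai"))
  expect_equal(unname(fi2$Z[, "rai"]), as.vector(scale(c(1, 2.5, 2.5, 4))))

  # balanced binary factor: indicators scaled by 1/sqrt(0.5), centred
  df3 <- data.frame(a = c(1, 2, 3, 4), sex = c("M", "M", "F", "F"))
  fi3 <- famd_preprocess(df3, make_roles("a", cat = "sex"))
  ind_f <- c(0, 0, 1, 1) / sqrt(0.5)
  expect_equal(unname(fi3$Z[, "sex.F"]), ind_f - mean(ind_f))

  expect_error(famd_preprocess(data.frame(a = c(1, 1, 1)), make_roles("a")),
               "constant")
  expect_error(famd_preprocess(data.frame(s = c("M", "M", "M")),
                               make_roles(cat = "s")), "2 observed levels")
  expect_error(famd_preprocess(data.frame(a = c(1, NA, 3)), make_roles("a")),
               "complete")
})

test_that("all-numeric FAMD reproduces the principal-component oracle", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(40), 10, 4,
                dimnames = list(paste0("D", 1:10), paste0("v", 1:4)))
    fit <- famd_fit(as.data.frame(X), make_roles(colnames(X)))
    Zs <- scale(X)
    ev <- eigen(crossprod(Zs) / nrow(X), symmetric = TRUE)
    expect_equal(fit$eigenvalues, ev$values, tolerance = 1e-8)
    expect_equal(fit$variance_pct, 100 * ev$values / sum(ev$values),
                 tolerance = 1e-8)
    expect_equal(abs(unname(fit$scores)), abs(Zs %*% ev$vectors),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(fit$contrib), 100 * ev$vectors^2,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("FAMD contract holds on degenerate and rank-1 inputs", {
  # two perfectly correlated variables: Dim1 explains 100%
  df <- data.frame(a = c(1, 2, 3, 5), b = 2 * c(1, 2, 3, 5))
  fit <- famd_fit(df, make_roles(c("a", "b")))
  expect_equal(fit$variance_pct[1], 100)
  expect_equal(sum(fit$eigenvalues > 1e-10), 1)

  # single numeric factor: its contribution to Dim1 is 100%
  fit1 <- famd_fit(data.frame(a = c(1, 2, 4)), make_roles("a"))
  expect_equal(unname(fit1$contrib["a", 1]), 100)
})

test_that("contribution and variance percentages satisfy their closure invariants", {
  co <- generate_cohort(missing_rate = 0, seed = 13)
  cll <- co$table[co$table$status == "cll", ]
  fit <- famd_fit(cll, default_roles())
  expect_equal(sum(fit$variance_pct), 100, tolerance = 1e-9)
  for (s in seq_along(fit$eigenvalues))
    expect_equal(sum(fit$contrib[, s]), 100, tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(fit$eigenvalues >= 0))
  expect_equal(sum(contributions_dim12(fit)), 100, tolerance = 1e-9)
})

test_that("row permutation permutes scores and leaves the spectrum unchanged", {
  co <- generate_cohort(missing_rate = 0, seed = 14)
  cll <- co$table[co$table$status == "cll", ]
  fit <- famd_fit(cll, default_roles())
  set.seed(1); perm <- sample(nrow(cll))
  fit_p <- famd_fit(cll[perm, ], default_roles())
  expect_equal(fit_p$eigenvalues, fit$eigenvalues)
  keep <- fit$eigenvalues > 1e-8     # null-space dims rotate arbitrarily
  expect_equal(fit_p$contrib[, keep], fit$contrib[, keep], tolerance = 1e-9)
  expect_equal(fit_p$scores[, keep], fit$scores[perm, keep],
               tolerance = 1e-9)
})

test_that("categorical level relabeling leaves variances and contributions alone", {
  co <- generate_cohort(missing_rate = 0, seed = 15)
  cll <- co$table[co$table$status == "cll", ]
  fit <- famd_fit(cll, default_roles())
  relab <- cll
  relab$sex <- c(M = "zzz_male", F = "aaa_female")[relab$sex]
  relab$igvh <- c(mutated = "B", unmutated = "A")[relab$igvh]
  fit2 <- famd_fit(relab, default_roles())
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-10)
  expect_equal(fit2$variance_pct, fit$variance_pct, tolerance = 1e-10)
  # contributions compared on informative dimensions only: dimensions with
  # (near-)zero eigenvalue are an arbitrary rotation of the null space
  keep <- fit$eigenvalues > 1e-8
  expect_equal(unname(fit2$contrib[, keep]), unname(fit$contrib[, keep]),
               tolerance = 1e-8)
})

test_that("a duplicated collinear factor never decreases Dim1 variance share", {
  for (s in 1:5) {
    set.seed(100 + s)
    X <- as.data.frame(matrix(rnorm(48), 12, 4))
    names(X) <- paste0("v", 1:4)
    base_fit <- famd_fit(X, make_roles(names(X)))
    X$dup <- X$v1
    dup_fit <- famd_fit(X, make_roles(names(X)))
    expect_gte(dup_fit$variance_pct[1], base_fit$variance_pct[1] - 1e-10)
  }
})

test_that("combined Dim1+Dim2 contributions are the eigenvalue-weighted average", {
  co <- generate_cohort(missing_rate = 0, seed = 16)
  cll <- co$table[co$table$status == "cll", ]
  fit <- famd_fit(cll, default_roles())
  c12 <- contributions_dim12(fit)
  l <- fit$eigenvalues[1:2]
  # direct summation oracle over the definition
  direct <- (fit$contrib[, 1] * l[1] + fit$contrib[, 2] * l[2]) / (l[1] + l[2])
  expect_equal(c12, direct)

  # equal eigenvalues reduce to the plain average
  fit_eq <- fit
  fit_eq$eigenvalues[1:2] <- c(2, 2)
  expect_equal(contributions_dim12(fit_eq),
               rowMeans(fit$contrib[, 1:2]))

  # a factor owning both dimensions keeps 100%
  solo <- famd_fit(data.frame(a = c(1, 2, 4), b = c(0, 1, 0)),
                   make_roles(c("a", "b")))
  expect_equal(sum(contributions_dim12(solo)), 100)
})

test_that("equal-contribution selection uses the strict 100/p threshold", {
  sel7 <- select_factors(setNames(c(25, 20, 20, 10, 10, 10, 5),
                                  paste0("f", 1:7)))
  expect_equal(sel7$threshold_label, "14.3")
  expect_equal(sel7$threshold_pct, 100 / 7)
  expect_identical(sel7$selected, c("f1", "f2", "f3"))

  sel4 <- select_factors(setNames(c(40, 30, 20, 10), paste0("f", 1:4)))
  expect_equal(sel4$threshold_label, "25.0")
  expect_identical(sel4$selected, c("f1", "f2"))

  # uniform contributions: strict inequality leaves nothing selected
  expect_error(select_factors(setNames(rep(100 / 7, 7), paste0("f", 1:7))),
               "scree")
})
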