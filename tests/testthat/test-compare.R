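test_that("cross-tabulation counts joint labels and conserves the total", {
  a <- rep(c("x", "y"), each = 5)
  tab <- cross_tabulate(a, a)
  expect_equal(unname(diag(tab)), c(5, 5))
  expect_equal(sum(tab) - sum(diag(tab)), 0)

  for (seed in 1:10) {
    set.seed(seed)
    la <- sample(1:3, 40, replace = TRUE)
    lb <- sample(1:4, 40, replace = TRUE)
    tab <- cross_tabulate(la, lb)
    expect_equal(sum(tab), 40)
    brute <- sapply(1:4, function(j) sapply(1:3, function(i)
      sum(la == i & lb == j)))
    expect_equal(unname(unclass(tab)), brute)
  }

  named_a <- setNames(c(1, 2), c("A", "B"))
  named_b <- setNames(c(1, 2), c("B", "C"))
  expect_error(cross_tabulate(named_a, named_b), "different")
})

test_that("chi-square independence reproduces the published degrees of freedom", {
  mk <- function(r, c, n = 5000, seed = 1) {
    set.seed(seed)
    list(a = c(1:r, sample(1:r, n - r, replace = TRUE)),
         b = c(1:c, sample(1:c, n - c, replace = TRUE)))
  }
  p68 <- mk(6, 8)
  expect_equal(chisq_independence(cross_tabulate(p68$a, p68$b))$df, 35)
  p626 <- mk(6, 26)
  expect_equal(chisq_independence(cross_tabulate(p626$a, p626$b))$df, 125)
  p676 <- mk(6, 76, n = 20000)
  expect_equal(chisq_independence(cross_tabulate(p676$a, p676$b))$df, 375)
})

test_that("a perfectly balanced table gives chi-square 0 and p 1", {
  tab <- matrix(c(5, 5, 5, 5), 2)
  ct <- chisq_independence(tab)
  expect_equal(ct$chi2, 0)
  expect_equal(ct$p, 1)
  expect_equal(ct$df, 1)
})

test_that("empty rows and columns are dropped with a warning", {
  tab <- rbind(c(10, 5, 0), c(3, 12, 0), c(0, 0, 0))
  expect_warning(ct <- chisq_independence(tab), "empty")
  expect_equal(ct$df, 1)
  expect_equal(ct$n, 30)
})

test_that("Cramer's V matches its definition and the brute-force label route", {
  expect_equal(cramers_v(20, 20, 2, 2), 1)
  expect_equal(cramers_v(0, 100, 3, 4), 0)
  expect_error(cramers_v(5, 10, 1, 4), "undefined")
  perfect <- classification_association(rep(1:2, each = 10),
                                        rep(1:2, each = 10))
  expect_equal(perfect$cramers_v, 1)
  for (seed in 1:10) {
    set.seed(seed)
    la <- sample(1:3, 200, replace = TRUE)
    lb <- sample(1:4, 200, replace = TRUE)
    res <- classification_association(la, lb)
    chi2 <- sum((res$crosstab - outer(rowSums(res$crosstab),
                                      colSums(res$crosstab)) / 200)^2 /
                (outer(rowSums(res$crosstab), colSums(res$crosstab)) / 200))
    expect_equal(res$cramers_v, sqrt(chi2 / (200 * 2)), tolerance = 1e-12)
  }
})

test_that("V is invariant to permutation and argument order, monotone in association", {
  set.seed(8)
  la <- sample(1:3, 300, replace = TRUE)
  lb <- sample(1:4, 300, replace = TRUE)
  v1 <- classification_association(la, lb)$cramers_v
  v2 <- classification_association(lb, la)$cramers_v
  expect_equal(v1, v2, tolerance = 1e-12)
  relab <- c(3, 1, 2)[la]
  expect_equal(classification_association(relab, lb)$cramers_v, v1,
               tolerance = 1e-12)

  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (seed in 1:5) {
    vs <- sapply(grid, function(assoc) {
      pc <- simulate_paired_classifications(4000, 3, 3, assoc, seed = seed)
      classification_association(pc$labels_a, pc$labels_b)$cramers_v
    })
    expect_true(all(diff(vs) > 0))
  }
})

test_that("correspondence reports flag strong overlaps and even splits", {
  diag_tab <- diag(c(10, 20, 30))
  rep1 <- correspondence_report(diag_tab)
  expect_equal(unname(rowSums(rep1$strong)), c(1, 1, 1))
  expect_false(any(rep1$split))

  uni <- matrix(10, 2, 4)
  rep2 <- correspondence_report(uni)
  expect_true(all(rep2$split))
  expect_equal(unname(rowSums(rep2$shares)), c(1, 1))
})

test_that("labels transfer across geographies by majority areal weight", {
  labels <- c(S1 = "red", S2 = "blue")
  lookup <- data.frame(source_id = c("S1", "S1", "S2"),
                       target_id = c("T1", "T2", "T2"),
                       weight = c(1, 0.4, 0.6))
  out <- transfer_labels(labels, lookup)
  expect_equal(unname(out["T1"]), "red")
  expect_equal(unname(out["T2"]), "blue")
  # ties break to the lowest label alphabetically
  tie <- data.frame(source_id = c("S1", "S2"), target_id = c("T1", "T1"),
                    weight = c(0.5, 0.5))
  expect_equal(unname(transfer_labels(labels, tie)["T1"]), "blue")
  expect_error(transfer_labels(labels["S1"], lookup), "without labels")
})
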