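# Wilcoxon rank-sum (exact and approximate), Welch t, group comparison.

# independent oracle: p-value by full enumeration over rank assignments
perm_wilcoxon_p <- function(a, b, alternative = "two.sided") {
  r <- rank(c(a, b))
  na <- length(a); n <- length(r)
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  sums <- combn(n, na, FUN = function(i) sum(r[i]))
  tol <- 1e-9
  switch(alternative,
         two.sided = mean(abs(sums - mu) >= abs(W - mu) - tol),
         greater = mean(sums >= W - tol),
         less = mean(sums <= W + tol))
}

test_that("identical samples give p = 1 with a warning", {
  expect_warning(w <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2)), "identical")
  expect_equal(w$p_value, 1)
})

test_that("the textbook fully separated case has exact two-sided p = 0.1", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(w$p_value, 2 / 20)
  expect_equal(w$statistic, 6)
})

test_that("exact mode equals the full-permutation oracle for all small samples", {
  set.seed(11)
  cases <- list(
    list(a = c(1.2, 3.4, 2.2), b = c(0.1, 5.5)),
    list(a = c(1, 2, 2, 3), b = c(2, 3, 4)),        # midrank ties
    list(a = rnorm(4), b = rnorm(4) + 1),
    list(a = c(5, 5, 1), b = c(5, 2, 2, 9)),
    list(a = rpois(3, 4), b = rpois(5, 4)))
  for (cs in cases) {
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(
        wilcoxon_rank_sum(cs$a, cs$b, alternative = alt,
                          mode = "exact")$p_value,
        perm_wilcoxon_p(cs$a, cs$b, alt),
        info = paste(alt, paste(cs$a, collapse = ","), "|",
                     paste(cs$b, collapse = ",")))
    }
  }
})

test_that("exact mode agrees with the reference implementation on tie-free data", {
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(7) + 0.4
    expect_equal(wilcoxon_rank_sum(a, b, mode = "exact")$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("the normal approximation tracks the exact p for moderate n", {
  set.seed(6)
  for (i in 1:5) {
    a <- rnorm(9); b <- rnorm(9) + 0.7
    pe <- wilcoxon_rank_sum(a, b, mode = "exact")$p_value
    pn <- wilcoxon_rank_sum(a, b, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  expect_error(wilcoxon_rank_sum(rnorm(15), rnorm(15), mode = "exact"),
               "exact mode")
})

test_that("welch test handles degenerate input, symmetry and the equal-variance case", {
  expect_warning(w <- welch_t(c(1, 1, 1), c(1, 1)), "zero variance")
  expect_equal(w$p_value, 1)
  expect_equal(w$statistic, 0)
  set.seed(7)
  a <- rnorm(12, 0, 1); b <- rnorm(12, 0.8, 1)
  w1 <- welch_t(a, b); w2 <- welch_t(b, a)
  expect_equal(w1$statistic, -w2$statistic)
  expect_equal(w1$p_value, w2$p_value)
  pooled <- t.test(a, b, var.equal = TRUE)$p.value
  expect_lt(abs(w1$p_value - pooled) / pooled, 0.1)
})

test_that("shifting one group in the tested direction never increases the one-sided p", {
  set.seed(8)
  a <- rnorm(8); b <- rnorm(8)
  shifts <- c(0, 0.5, 1, 2, 4)
  pw <- vapply(shifts, function(s)
    wilcoxon_rank_sum(a + s, b, alternative = "greater",
                      mode = "exact")$p_value, 0)
  pt <- vapply(shifts, function(s)
    welch_t(a + s, b, alternative = "greater")$p_value, 0)
  expect_true(all(diff(pw) <= 1e-12))
  expect_true(all(diff(pt) <= 1e-12))
})

test_that("quartiles follow the linear-interpolation convention", {
  bs <- ernet:::box_stats(1:8)
  expect_equal(unname(bs["q1"]), 2.75)
  expect_equal(unname(bs["q3"]), 6.25)
  expect_equal(unname(bs["median"]), 4.5)
})

test_that("group comparison wires metrics to tests and rejects bad metrics", {
  g1 <- generate_network_graph(noiseless_spec(1, n_seeds = 40, size = 160))
  g2 <- generate_network_graph(noiseless_spec(2, n_seeds = 40, size = 160))
  s1 <- summarize_cell(render_phantom(g1)$truth$er_mask)
  s2 <- summarize_cell(render_phantom(g2)$truth$er_mask)
  cmp <- compare_groups(list(s1, s2), list(s1, s2),
                        metric = "polygon_area_um2")
  expect_equal(cmp$test, "wilcoxon")
  expect_gt(cmp$p_value, 0.9)  # identical pooled samples
  expect_error(compare_groups(list(s1), list(s2), metric = "nope"))
  cmp2 <- suppressWarnings(compare_groups(list(s1, s2), list(s2, s1),
                           metric = "cisternae_pct", test = "welch"))
  expect_equal(cmp2$n, c(2L, 2L))
})

test_that("null phantom-free simulations keep the type-I error near nominal", {
  set.seed(9)
  n_rep <- 200
  rej_w <- rej_t <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(12); b <- rnorm(12)
    if (wilcoxon_rank_sum(a, b, mode = "normal")$p_value < 0.05)
      rej_w <- rej_w + 1L
    if (welch_t(a, b)$p_value < 0.05) rej_t <- rej_t + 1L
  }
  expect_gte(rej_w / n_rep, 0.01); expect_lte(rej_w / n_rep, 0.10)
  expect_gte(rej_t / n_rep, 0.01); expect_lte(rej_t / n_rep, 0.10)
})
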