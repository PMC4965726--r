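test_that("association tables count group/trait membership over the universe", {
  # tiny case cross-checked by brute-force membership counting
  set.seed(3)
  for (i in 1:10) {
    uni <- sprintf("U%02d", 1:20)
    grp <- sample(uni, sample(2:8, 1))
    trt <- sample(uni, sample(2:10, 1))
    tab <- build_association_table(grp, trt, uni)
    brute <- table(factor(uni %in% grp, c(TRUE, FALSE)),
                   factor(uni %in% trt, c(TRUE, FALSE)))
    expect_equal(as.vector(as.matrix(tab)), as.vector(brute))
  }
  expect_error(build_association_table(c("A", "ZZZ"), "A", c("A", "B")),
               "subset")
  # trait proteins outside the universe are ignored
  tab <- build_association_table("A", c("A", "OUTSIDE"), c("A", "B"))
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 0, 0, 1))
})

test_that("scaffold/disease counts build the expected 2x2 table", {
  uni <- sprintf("U%05d", 1:20233)
  scaff <- uni[1:616]
  disease <- uni[c(1:188, 617:5378)]  # 188 in the group, 4950 total
  tab <- build_association_table(scaff, disease, uni)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(188, 428, 4762, 14855))
})

test_that("chi-square matches the closed form on random tables", {
  set.seed(21)
  for (i in 1:1000) {
    cells <- stats::rpois(4, 30) + 1
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    n <- sum(cells)
    res <- association_test(do.call(contingency_2x2, as.list(cells)))
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$chi_square, closed)
    expect_equal(res$p_value,
                 stats::pchisq(closed, df = 1, lower.tail = FALSE))
  }
})

test_that("transposition preserves chi-square and odds ratio but not risk ratio", {
  tab <- contingency_2x2(188, 428, 4762, 14855)
  tt <- contingency_2x2(188, 4762, 428, 14855)
  r1 <- association_test(tab); r2 <- association_test(tt)
  expect_equal(r1$chi_square, r2$chi_square)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$odds_ratio, r2$odds_ratio)
  expect_false(isTRUE(all.equal(r1$risk_ratio, r2$risk_ratio)))
})

test_that("degenerate tables error and zero cells suppress the ratios", {
  expect_error(association_test(contingency_2x2(3, 4, 0, 0)), "degenerate")
  res <- suppressWarnings(association_test(contingency_2x2(3, 0, 2, 5)))
  expect_true(is.na(res$odds_ratio))
  expect_false(is.na(res$chi_square))
})

test_that("Yates correction is available but off by default", {
  tab <- contingency_2x2(12, 5, 7, 14)
  expect_equal(association_test(tab)$chi_square,
               unname(stats::chisq.test(as.matrix(tab),
                                        correct = FALSE)$statistic))
  expect_lt(association_test(tab, correct = TRUE)$chi_square,
            association_test(tab)$chi_square)
})

test_that("p-value adjustment reproduces hand-computed examples", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(0.01, "bh"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  # BH step-up by hand: sorted p * m/rank = .04, .04, .04, .04
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.1, 0), "bh"), "0, 1")
  expect_error(adjust_pvalues(1.2, "bh"), "0, 1")
})

test_that("BH-adjusted values sit between raw and Bonferroni, order preserved", {
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(sample(3:12, 1))
    bh <- adjust_pvalues(p, "bh"); bf <- adjust_pvalues(p, "bonferroni")
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bh <= bf + 1e-12))
    expect_true(all(bh <= 1) && all(bf <= 1))
  }
})

make_ann <- function(sets) {
  prot <- unlist(sets, use.names = FALSE)
  term <- rep(names(sets), lengths(sets))
  annotation_map(split(term, prot), "test")
}

test_that("enrichment p-values match closed forms and exhaustive enumeration", {
  bg <- sprintf("B%02d", 1:20)
  fg <- bg[1:5]
  # a term annotating exactly the foreground: p = 1 / C(20, 5)
  ann <- make_ann(list(hit = fg, broad = bg))
  rows <- enrich(fg, ann, background = bg)
  expect_equal(rows$p_value[rows$term == "hit"], 1 / choose(20, 5))
  # a term annotating the whole background: p = 1, fold = 1
  expect_equal(rows$p_value[rows$term == "broad"], 1)
  expect_equal(rows$fold_enrichment[rows$term == "broad"], 1)

  # N = 10, K = 4, n = 5: exhaustive enumeration over all C(10,5) draws
  bg10 <- sprintf("C%02d", 1:10)
  ann10 <- make_ann(list(t = bg10[1:4]))
  draws <- utils::combn(bg10, 5)
  for (k_obs in 1:4) {
    fg10 <- c(bg10[1:k_obs], bg10[5:(9 - k_obs)])  # foreground with k_obs hits
    stopifnot(sum(fg10 %in% bg10[1:4]) == k_obs)
    p_pkg <- enrich(fg10, ann10, background = bg10)$p_value
    p_brute <- mean(apply(draws, 2, function(d)
      sum(d %in% bg10[1:4]) >= k_obs))
    expect_equal(p_pkg, p_brute)
  }
})

test_that("fisher and hypergeometric enrichment agree; foreground must nest", {
  bg <- sprintf("B%02d", 1:30)
  ann <- make_ann(list(t1 = bg[1:10], t2 = bg[c(1:3, 15:20)]))
  fg <- bg[1:8]
  h <- enrich(fg, ann, background = bg, test = "hypergeometric")
  f <- enrich(fg, ann, background = bg, test = "fisher")
  expect_equal(h$p_value, f$p_value)
  expect_error(enrich(c(bg[1], "ALIEN"), ann, background = bg), "subset")
})

test_that("enrichment rows are complete, sorted, and flag significance", {
  bg <- sprintf("B%02d", 1:40)
  ann <- make_ann(list(sig = bg[1:6], null1 = bg[seq(2, 40, 2)],
                       unseen = bg[30:40]))
  fg <- bg[1:6]
  rows <- enrich(fg, ann, background = bg, correction = "bonferroni",
                 alpha = 0.01)
  expect_false("unseen" %in% rows$term)  # k = 0 terms are skipped
  expect_equal(rows$adjusted_p, sort(rows$adjusted_p))
  expect_equal(rows$fold_enrichment, (rows$k / rows$n) / (rows$K / rows$N))
  expect_true(rows$significant[rows$term == "sig"])
  expect_equal(rows$adjusted_p,
               pmin(1, rows$p_value * nrow(rows)))  # bonferroni
})

test_that("enrichment is uniform-conservative under the null", {
  # random foregrounds from an unstructured background: the empirical
  # type-I error at alpha = 0.05 must not exceed it meaningfully
  bg <- sprintf("B%03d", 1:400)
  ann <- make_ann(list(t = bg[1:80]))
  reject <- withr::with_seed(99, {
    vapply(1:500, function(i) {
      fg <- sample(bg, 40)
      enrich(fg, ann, background = bg)$p_value[1] <= 0.05
    }, logical(1))
  })
  expect_lte(mean(reject), 0.07)
})
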