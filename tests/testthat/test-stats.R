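test_that("Mann-Whitney exact mode reproduces hand-enumerated cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1) # 2 of the C(6,3) = 20 assignments are as extreme
  # identical multisets: full symmetry
  expect_equal(mann_whitney_u(c(1, 2, 2), c(2, 1, 2), mode = "exact")$p, 1)
  # identical constant groups: all ties
  r2 <- mann_whitney_u(rep(3, 4), rep(3, 5), mode = "exact")
  expect_equal(r2$U, 4 * 5 / 2)
  expect_equal(r2$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "input error")
})

test_that("exact Mann-Whitney equals brute-force enumeration (n <= 10)", {
  set.seed(17)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:3) {
        # mix of continuous values and ties
        a <- sample(c(rnorm(na), sample(1:3, na, TRUE)), na)
        b <- sample(c(rnorm(nb), sample(1:3, nb, TRUE)), nb)
        expect_equal(mann_whitney_u(a, b, mode = "exact")$p,
                     brute_mw_p(a, b), tolerance = 1e-12,
                     info = sprintf("na=%d nb=%d", na, nb))
      }
    }
  }
})

test_that("Mann-Whitney agrees with wilcox.test on its home ground", {
  set.seed(23)
  a <- rnorm(9); b <- rnorm(11)
  expect_equal(mann_whitney_u(a, b, mode = "exact")$p,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-10)
  a2 <- rnorm(30); b2 <- rnorm(40)
  expect_equal(mann_whitney_u(a2, b2, mode = "normal_approx")$p,
               wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # exact and normal modes agree closely at the feasibility boundary
  for (rep in 1:5) {
    a3 <- rnorm(12); b3 <- rnorm(13)
    expect_lt(abs(mann_whitney_u(a3, b3, "exact")$p -
                    mann_whitney_u(a3, b3, "normal_approx")$p), 0.01)
  }
})

test_that("Fisher exact test reproduces the published center comparisons", {
  # pooled: 2 centers of 19 bleb points vs 2 of 279 non-bleb points
  expect_equal(signif(fisher_exact_2x2(rbind(c(2, 19), c(2, 279))), 2),
               0.025)
  # per case, printed to three decimals
  expect_equal(round(fisher_exact_2x2(rbind(c(1, 11), c(1, 135))), 3),
               0.156)
  expect_equal(round(fisher_exact_2x2(rbind(c(1, 8), c(1, 144))), 3),
               0.114)
  # conventional construction of the pooled table
  expect_equal(round(fisher_exact_2x2(rbind(c(2, 17), c(2, 277))), 3),
               0.021)
  # degenerate margin
  expect_equal(fisher_exact_2x2(rbind(c(0, 10), c(0, 10))), 1)
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))), "input error")
})

test_that("Fisher p matches fisher.test and is swap-invariant", {
  set.seed(41)
  for (i in 1:200) {
    tab <- matrix(rpois(4, lambda = sample(c(2, 10, 60), 1)), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
  }
})

test_that("center contingency tables follow both constructions", {
  d <- data.frame(
    region = rep(c("bleb", "nonbleb"), c(19, 279)),
    is_center = c(rep(TRUE, 2), rep(FALSE, 17), rep(TRUE, 2),
                  rep(FALSE, 277)))
  tab <- build_center_contingency(d, mode = "as_printed")
  expect_equal(unname(tab), rbind(c(2L, 19L), c(2L, 279L)))
  tab2 <- build_center_contingency(d, mode = "conventional")
  expect_equal(unname(tab2), rbind(c(2L, 17L), c(2L, 277L)))
  d$is_center <- FALSE
  expect_equal(unname(build_center_contingency(d)[, 1]), c(0L, 0L))
})

test_that("comparison report summarises groups with sample SD and tests", {
  set.seed(8)
  d <- data.frame(
    region = rep(c("bleb", "nonbleb"), c(10, 40)),
    normalized_pressure = c(rnorm(10, 1.06, 0.01), rnorm(40, 1.0, 0.01)),
    normalized_wss = c(rnorm(10, 0.4, 0.1), rnorm(40, 0.9, 0.1)),
    tawss = rnorm(50, 5, 1),
    osi = c(runif(49, 0, 0.02), NA),
    is_center = rep(c(TRUE, FALSE, TRUE, FALSE), c(1, 9, 1, 39)))
  rep1 <- summarize_comparison(d)
  s <- rep1$summary
  expect_setequal(s$parameter, c("normalized_pressure", "normalized_wss",
                                 "tawss", "osi"))
  prow <- s[s$parameter == "normalized_pressure", ]
  expect_gt(prow$mean_bleb, prow$mean_nonbleb)
  expect_lt(prow$p_value, 0.001)
  expect_equal(prow$sd_bleb,
               sd(d$normalized_pressure[d$region == "bleb"]))
  expect_equal(rep1$n_excluded_osi, 1L)
  expect_equal(s$n_bleb[s$parameter == "osi"] +
                 s$n_nonbleb[s$parameter == "osi"], 49)
  expect_equal(rep1$centers$centers_bleb, 1L)
  expect_equal(rep1$centers$n_bleb, 10L)
  # identical groups give p = 1
  d2 <- data.frame(region = rep(c("bleb", "nonbleb"), each = 5),
                   tawss = rep(1:5, 2), is_center = FALSE)
  rep2 <- summarize_comparison(d2, parameters = "tawss")
  expect_equal(rep2$summary$p_value, 1)
  # single-point group: SD undefined
  d3 <- data.frame(region = c("bleb", rep("nonbleb", 5)),
                   tawss = rnorm(6), is_center = FALSE)
  rep3 <- summarize_comparison(d3, parameters = "tawss")
  expect_true(is.na(rep3$summary$sd_bleb))
})

test_that("per-case and pooled scopes are both reported", {
  set.seed(12)
  d <- data.frame(
    case = rep(c("case1", "case2"), each = 30),
    region = rep(rep(c("bleb", "nonbleb"), c(5, 25)), 2),
    tawss = rnorm(60), is_center = FALSE)
  rep1 <- summarize_comparison(d, parameters = "tawss")
  expect_setequal(rep1$summary$case, c("case1", "case2", "total"))
  tot <- rep1$summary[rep1$summary$case == "total", ]
  expect_equal(tot$n_bleb + tot$n_nonbleb, 60)
})
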