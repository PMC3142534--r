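test_that("Kaplan-Meier matches hand product-limit values", {
  km <- kaplan_meier(surv_toy("1", "2", "3", "4"))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(all(kaplan_meier(surv_toy("1+", "2+", "3+"))$surv == 1))

  # 6-patient mixed toy: events at 2 (risk 5), 4 (risk 3), 5 (risk 2)
  km6 <- kaplan_meier(surv_toy("1+", "2", "3+", "4", "5", "6+"))
  ev <- km6[km6$n_event > 0, ]
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))
})

test_that("log-rank statistic matches the hypergeometric oracle", {
  # identical event/censoring patterns in both groups -> statistic 0
  sv <- surv_toy("1", "2+", "3", "1", "2+", "3")
  t0 <- logrank_test(sv, c("a", "a", "a", "b", "b", "b"))
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_equal(t0$p, 1, tolerance = 1e-10)

  # 6-patient two-group toy vs oracle
  sv2 <- surv_toy("1", "3", "4+", "2", "5", "6+")
  g2 <- c("a", "a", "a", "b", "b", "b")
  t2 <- logrank_test(sv2, g2)
  expect_equal(t2$statistic, logrank_oracle(sv2$time, sv2$event, g2),
               tolerance = 1e-8)
  expect_equal(t2$df, 1L)
  expect_equal(t2$p, pchisq(t2$statistic, 1, lower.tail = FALSE))

  # random instances, 2 and 3 groups
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    sv3 <- surv_outcome(rexp(n, 0.1), rbinom(n, 1, 0.7))
    g3 <- sample(letters[1:(2 + s %% 2)], n, replace = TRUE)
    t3 <- logrank_test(sv3, g3)
    expect_equal(t3$statistic, logrank_oracle(sv3$time, sv3$event, g3),
                 tolerance = 1e-8)
    expect_equal(t3$df, length(unique(g3)) - 1L)
  }
  expect_error(logrank_test(sv2, rep("a", 6)), "2 nonempty groups")
})

test_that("log-rank and KM are invariant to time-unit rescaling", {
  set.seed(7)
  sv <- surv_outcome(rexp(40, 0.05), rbinom(40, 1, 0.6))
  g <- rep(c("x", "y"), 20)
  sv12 <- surv_outcome(sv$time * 12, sv$event)
  expect_equal(logrank_test(sv, g)$statistic,
               logrank_test(sv12, g)$statistic, tolerance = 1e-10)
  expect_equal(kaplan_meier(sv)$surv, kaplan_meier(sv12)$surv)
})

test_that("Cox coefficient matches grid-maximised partial likelihood", {
  sv <- surv_toy("2", "4", "5+", "7", "9", "11+", "12", "14")
  x <- c(1, 0, 1, 0, 1, 0, 1, 0)
  fit <- cox_fit(data.frame(x = x), sv)
  bhat <- optimize(function(b) -cox_loglik_oracle(b, sv$time, sv$event, x),
                   c(-5, 5), tol = 1e-9)$minimum
  expect_equal(fit$coefficients$coef, bhat, tolerance = 1e-4)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
  expect_true(fit$coefficients$lower95 < fit$coefficients$hr &
                fit$coefficients$hr < fit$coefficients$upper95)
  # generalized R^2 from the reported log likelihoods
  ll <- fit$loglik
  expect_equal(fit$r_squared, 1 - exp(-2 * (ll[["fitted"]] - ll[["null"]]) / 8))
})

test_that("degenerate and separating covariates raise informative errors", {
  sv <- surv_toy("2", "4", "6", "8+", "10", "12+")
  expect_error(cox_fit(data.frame(x = rep(1, 6)), sv), "degenerate")
  # all events in one level occur before anything in the other
  sv2 <- surv_toy("1", "2", "3", "10+", "11+", "12+")
  expect_error(cox_fit(data.frame(x = c(1, 1, 1, 0, 0, 0)), sv2),
               "no finite MLE")
  # complete-case n is reported
  sv3 <- surv_toy("2", "4", "6", "8", "10+", "12")
  fit <- cox_fit(data.frame(x = c(1, 0, NA, 1, 0, 1)), sv3)
  expect_equal(fit$n, 5)
})

test_that("Kruskal-Wallis matches hand-ranked tie-corrected H", {
  v <- c(1, 2, 2, 3, 5, 5, 5, 7, 8)
  g <- c("a", "a", "b", "b", "b", "c", "c", "c", "a")
  kw <- kruskal_wallis(v, g)
  # hand computation: ranks with ties, H with tie correction
  r <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(v)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kw$statistic, h, tolerance = 1e-10)
  expect_equal(kw$df, 2L)

  # two groups: monotone relation to the rank-sum statistic
  set.seed(8)
  stats <- t(vapply(1:20, function(i) {
    v2 <- rnorm(12)
    g2 <- rep(c("a", "b"), each = 6)
    c(kruskal_wallis(v2, g2)$statistic,
      abs(sum(rank(v2)[g2 == "a"]) - 6 * 13 / 2))
  }, numeric(2)))
  expect_equal(order(stats[, 1]), order(stats[, 2]))

  expect_equal(kruskal_wallis(rep(3, 8), rep(c("a", "b"), 4))$p, 1)
})

test_that("Fisher's exact test agrees with full enumeration", {
  t1 <- fisher_exact(matrix(c(5, 0, 0, 5), 2))
  expect_equal(t1$p, 2 / choose(10, 5), tolerance = 1e-9)

  # proportional rows -> p = 1
  expect_equal(fisher_exact(matrix(c(4, 2, 8, 4), 2))$p, 1, tolerance = 1e-9)

  # 3x2 table vs enumeration oracle; oracle mass sums to 1
  m <- matrix(c(4, 1, 2, 0, 3, 5), 3, 2)
  enum <- fisher_enum_oracle(m)
  expect_equal(enum$total, 1, tolerance = 1e-9)
  expect_equal(fisher_exact(m)$p, enum$p, tolerance = 1e-7)

  # large table switches to seeded Monte Carlo and stays reproducible
  big <- matrix(rpois(20, 40) + 10, 4, 5)
  mc1 <- fisher_exact(big, max_tables = 10, seed = 9)
  mc2 <- fisher_exact(big, max_tables = 10, seed = 9)
  expect_match(mc1$method, "monte-carlo")
  expect_equal(mc1$p, mc2$p)
  expect_error(fisher_exact(matrix(0, 2, 2)), "empty")
})

test_that("mortality table reproduces printed-style group summaries", {
  # counts 3/56, 4/17, 6/9 with arbitrary times
  g <- rep(c("low", "moderate", "high"), c(56, 17, 9))
  ev <- c(rep(1, 3), rep(0, 53), rep(1, 4), rep(0, 13), rep(1, 6), rep(0, 3))
  sv <- surv_outcome(seq_along(g) + 10, ev)
  mt <- mortality_table(g, sv)
  tab <- mt$table[match(c("low", "moderate", "high"), mt$table$group), ]
  expect_equal(tab$pct_mortality, c(5.4, 24, 67))
  expect_s3_class(mt$logrank, "tma_test")

  # zero deaths in a group
  mt0 <- mortality_table(rep(c("a", "b"), each = 4),
                         surv_outcome(1:8, c(0, 0, 0, 0, 1, 1, 0, 0)))
  expect_equal(mt0$table$pct_mortality[mt0$table$group == "a"], 0)

  # single group: percent only, no log-rank
  m1 <- mortality_table(rep("all", 5), surv_outcome(1:5, c(1, 0, 0, 0, 0)))
  expect_null(m1$logrank)
  expect_equal(m1$table$pct_mortality, 20)
})

test_that("cross-tabulation computes agreement on the joint index", {
  x <- expand_confusion(matrix(c(3, 1, 0, 4), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  ct <- cross_tabulate(x$a, x$b)
  expect_equal(ct$n, 8)
  expect_equal(ct$agree, 7)
  expect_equal(ct$disagree_pct, 12)  # 12.5 -> 2 significant figures (half-even)

  ident <- cross_tabulate(x$a, x$a)
  expect_equal(ident$agree_pct, 100)

  # unassigned patients are excluded and counted
  a <- c(P1 = "x", P2 = "y", P3 = NA)
  b <- c(P1 = "x", P2 = "x", P3 = "y")
  ct2 <- cross_tabulate(a, b)
  expect_equal(ct2$n, 2)
  expect_equal(ct2$n_excluded, 1)
  expect_error(cross_tabulate(c(P1 = NA), c(P1 = "x")), "no jointly")
})

test_that("Cox estimates recover a known log-hazard ratio at n = 500", {
  set.seed(10)
  est <- vapply(1:10, function(i) {
    x <- rbinom(500, 1, 0.5)
    tt <- rexp(500, 0.02 * exp(0.7 * x))
    sv <- surv_outcome(pmin(tt, 60), as.integer(tt <= 60))
    cox_fit(data.frame(x = x), sv)$coefficients$coef
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.1)
})
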