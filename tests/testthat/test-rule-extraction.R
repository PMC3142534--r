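test_that("the WGCNA* rule routes the published example profiles", {
  rule <- wgcna_star_rule()
  m <- percentile_matrix()
  hi <- place_patient(m, list(p53 = 90, NaKATPase_beta1 = 10, TGFbR2_cyt = 50))
  expect_equal(as.character(apply_threshold_rule(rule, hi)[1]), "high")
  mod <- place_patient(m, list(p53 = 20, NaKATPase_beta1 = 50, TGFbR2_cyt = 80))
  expect_equal(as.character(apply_threshold_rule(rule, mod)[1]), "moderate")
  lo <- place_patient(m, list(p53 = 20, NaKATPase_beta1 = 50, TGFbR2_cyt = 20))
  expect_equal(as.character(apply_threshold_rule(rule, lo)[1]), "low")
  # high p53 but high Na-K ATPase is labelled low, not high
  lo2 <- place_patient(m, list(p53 = 90, NaKATPase_beta1 = 80, TGFbR2_cyt = 20))
  expect_equal(as.character(apply_threshold_rule(rule, lo2)[1]), "low")

  expect_error(apply_threshold_rule(rule, m[, 1:2]), "absent")
  m2 <- m; m2[3, "p53"] <- NA
  expect_true(is.na(apply_threshold_rule(rule, m2)[3]))
})

test_that("classification trees recover planted rules and reject noise", {
  # one marker perfectly separating two classes
  m <- cbind(A = c(1:10, 21:30), B = rnorm(20))
  y <- factor(rep(c("x", "y"), each = 10))
  tr <- fit_classification_tree(m, y, complexity = 0.1, min_split = 2)
  expect_equal(tr$root$marker, "A")
  expect_gt(tr$root$cut, 10); expect_lte(tr$root$cut, 21)
  expect_true(is.null(tr$root$left$marker) && is.null(tr$root$right$marker))

  # planted 2-split 3-class rule, n = 200, no label noise
  set.seed(22)
  m3 <- matrix(runif(200 * 2, 0, 100), 200)
  colnames(m3) <- c("A", "B")
  y3 <- factor(ifelse(m3[, "A"] > 70, "high",
                      ifelse(m3[, "B"] > 50, "moderate", "low")))
  tr3 <- fit_classification_tree(m3, y3, complexity = 0.1, min_split = 5)
  expect_equal(tr3$root$marker, "A")
  expect_lt(abs(tr3$root$cut - 70), 3)  # within the local observed gaps
  second <- if (!is.null(tr3$root$left$marker)) tr3$root$left else tr3$root$right
  expect_equal(second$marker, "B")
  expect_lt(abs(second$cut - 50), 3)

  # pure-noise labels with complexity 0.1: root-only in the vast majority
  root_only <- vapply(1:60, function(s) {
    set.seed(s)
    mm <- matrix(rnorm(82 * 10), 82)
    colnames(mm) <- paste0("m", 1:10)
    yy <- factor(sample(c("a", "b", "c"), 82, replace = TRUE))
    is.null(fit_classification_tree(mm, yy, complexity = 0.1,
                                    min_split = 5)$root)
  }, logical(1))
  expect_gte(mean(root_only), 0.85)

  expect_warning(t1 <- fit_classification_tree(m, factor(rep("x", 20)),
                                               0.1, 2), "single-class")
  expect_null(t1$root)
})

test_that("first split matches exhaustive Gini search on small instances", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(8:12, 1)
    m <- matrix(rnorm(n * 2), n)
    colnames(m) <- c("A", "B")
    y <- factor(sample(c("u", "v"), n, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) next
    tr <- fit_classification_tree(m, y, complexity = 1e-9, min_split = 2)
    if (is.null(tr$root)) next
    oracle <- best_gini_split_oracle(m, y)
    # markers can tie on count-based Gini gain; the gain itself is unique
    expect_equal(tr$root$improve, oracle$improve, tolerance = 1e-9)
  }
})

test_that("percentile conversion round-trips tree assignments exactly", {
  # cutpoint at the training median -> 50th percentile
  x <- c(1:10)
  mm <- cbind(A = x, B = 0)
  y <- factor(rep(c("p", "q"), each = 5))
  tr <- fit_classification_tree(mm, y, complexity = 0.1, min_split = 2)
  rule <- tree_to_threshold_rule(tr)
  expect_equal(rule$root$percentile, 50)

  # hand empirical CDF: cut between the 4th and 5th of 12 values
  x2 <- sort(runif(12))
  cutp <- (x2[4] + x2[5]) / 2
  pct <- 100 * sum(x2 < cutp) / 12
  expect_equal(pct, 100 * 4 / 12)

  # round-trip identity on training data for random trees
  for (s in 1:8) {
    set.seed(s + 100)
    m <- matrix(rnorm(70 * 3), 70)
    colnames(m) <- c("A", "B", "C")
    y <- factor(ifelse(m[, 1] + 0.7 * m[, 2] + rnorm(70, 0, 0.4) > 0,
                       "a", "b"))
    tr <- fit_classification_tree(m, y, complexity = 0.02, min_split = 5)
    rule <- tree_to_threshold_rule(tr)
    expect_identical(as.character(apply_threshold_rule(rule, m)),
                     predict(tr))
  }
})

test_that("rule application is invariant under strictly monotone transforms", {
  set.seed(23)
  m <- matrix(rnorm(60 * 3), 60)
  colnames(m) <- c("A", "B", "C")
  y <- factor(ifelse(m[, 1] > 0, ifelse(m[, 2] > 0.3, "a", "b"), "c"))
  rule <- tree_to_threshold_rule(
    fit_classification_tree(m, y, complexity = 0.05, min_split = 5))
  g0 <- apply_threshold_rule(rule, m)
  transforms <- list(function(v) exp(v), function(v) v^3,
                     function(v) 10 + 5 * v, function(v) atan(v))
  for (f in transforms) {
    m2 <- m
    for (j in 1:3) m2[, j] <- f(m2[, j])
    expect_identical(apply_threshold_rule(rule, m2), g0)
  }
})

test_that("median imputation changes only missing cells", {
  m <- cbind(A = c(1, 2, NA, 100), B = c(NA, 5, 6, 7))
  out <- median_impute(m)
  expect_equal(unname(out[3, "A"]), 2)
  expect_equal(unname(out[1, "B"]), 6)
  expect_equal(out[!is.na(m)], m[!is.na(m)])
  expect_identical(median_impute(out), out)
  expect_error(median_impute(cbind(A = c(NA_real_, NA_real_))), "entirely")
  expect_error(median_impute(m, "Z"), "no such column")
})

test_that("missingness-vs-survival flags fully observed markers", {
  sv <- surv_outcome(1:6, c(1, 0, 1, 0, 0, 1))
  m <- cbind(A = c(1, 2, 3, 4, 5, 6), B = c(NA, 2, NA, 4, 5, 6))
  res <- missingness_vs_survival(m, sv)
  expect_false(res$applicable[res$marker == "A"])
  expect_true(res$applicable[res$marker == "B"])
  expect_true(res$p[res$marker == "B"] >= 0 &&
                res$p[res$marker == "B"] <= 1)
})

test_that("optimal dichotomization matches the exhaustive scan oracle", {
  set.seed(24)
  n <- 30
  x <- rnorm(n)
  tt <- rexp(n, 0.03 * exp(1.2 * (x > 0.2)))
  sv <- surv_outcome(pmin(tt, 50), as.integer(tt <= 50))
  res <- optimal_dichotomize(x, sv, min_group_size = 5)

  # independent oracle: full scan with the formula interface
  vals <- sort(unique(x))
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  mids <- mids[sapply(mids, function(t) min(sum(x <= t), sum(x > t)) >= 5)]
  ps <- sapply(mids, function(t) {
    f <- survival::coxph(survival::Surv(sv$time, sv$event) ~ I(x > t),
                         ties = "efron")
    summary(f)$coefficients[1, "Pr(>|z|)"]
  })
  expect_equal(res$p, min(ps), tolerance = 1e-6)
  expect_equal(res$threshold, mids[which.min(ps)])
  expect_gte(min(res$n_low, res$n_high), 5)

  # thresholds leaving < min_group_size per side are never chosen
  res2 <- optimal_dichotomize(x, sv, min_group_size = 12)
  expect_gte(min(res2$n_low, res2$n_high), 12)

  # too few observations -> non-qualifying
  expect_false(optimal_dichotomize(x[1:8], sv[1:8, ], 5)$qualifies)
})

test_that("a marker duplicating the event indicator hits the divergence path", {
  sv <- surv_outcome(c(1, 2, 3, 4, 30, 31, 32, 33, 34, 35),
                     c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  x <- c(rep(10, 4), rep(1, 6)) + seq(0, 0.9, 0.1)  # separates risk sets
  res <- optimal_dichotomize(x, sv, min_group_size = 4)
  # every admissible separating threshold has a non-finite MLE
  expect_false(res$qualifies)
})

test_that("stepwise Cox retains planted markers and handles collinearity", {
  retained <- vapply(1:30, function(s) {
    set.seed(s)
    n <- 300
    x <- matrix(rnorm(n * 10), n)
    colnames(x) <- paste0("m", 1:10)
    tt <- rexp(n, 0.004 * exp(1.0 * (x[, 1] > 0)))
    sv <- surv_outcome(pmin(tt, 120), as.integer(tt <= 120))
    ind <- as.data.frame(lapply(seq_len(10), function(j)
      as.integer(x[, j] > median(x[, j]))))
    names(ind) <- colnames(x)
    st <- suppressWarnings(stepwise_cox(ind, sv))
    "m1" %in% st$retained
  }, logical(1))
  expect_gte(mean(retained), 0.9)

  # duplicate copies: never both retained
  set.seed(25)
  n <- 120
  x1 <- as.integer(rnorm(n) > 0)
  tt <- rexp(n, 0.01 * exp(0.9 * x1))
  sv <- surv_outcome(pmin(tt, 80), as.integer(tt <= 80))
  ind <- data.frame(a = x1, b = x1)
  expect_warning(st <- stepwise_cox(ind, sv), "collinear")
  expect_lte(length(st$retained), 1L)

  # all-noise: empty retained set is a valid return
  set.seed(26)
  noise <- as.data.frame(matrix(rbinom(50 * 3, 1, 0.5), 50))
  names(noise) <- c("u", "v", "w")
  svn <- surv_outcome(rexp(50, 0.02), rbinom(50, 1, 0.4))
  stn <- suppressWarnings(stepwise_cox(noise, svn))
  expect_type(stn$retained, "character")
})

test_that("the comparator pipeline recovers a planted two-marker rule", {
  set.seed(27)
  n <- 400
  x <- matrix(rnorm(n * 10), n)
  colnames(x) <- c("MED28_cyt", "Smad4_cyt", paste0("noise", 1:8))
  g <- apply_threshold_rule(cox_comparator_rule(), x)
  hz <- c(low = 0.002, moderate = 0.012, high = 0.035)[as.character(g)]
  tt <- rexp(n, hz)
  sv <- surv_outcome(pmin(tt, 100), as.integer(tt <= 100))
  rule <- suppressWarnings(suppressMessages(build_cox_rule(x, sv)))
  expect_equal(rule$root$marker, "MED28_cyt")
  expect_lt(abs(rule$root$percentile - 75), 5)
  second <- if (!is.null(rule$root$le$marker)) rule$root$le else rule$root$gt
  expect_equal(second$marker, "Smad4_cyt")
  expect_lt(abs(second$percentile - 75), 5)
  expect_setequal(rule_leaves(rule)[rule_leaves(rule) %in%
                                      c("low", "moderate", "high")],
                  c("low", "moderate", "high"))

  # pure noise -> "no qualifying markers"
  set.seed(28)
  xn <- matrix(rnorm(60 * 5), 60)
  colnames(xn) <- paste0("m", 1:5)
  svn <- surv_outcome(rexp(60, 0.02), rbinom(60, 1, 0.3))
  expect_error(suppressWarnings(build_cox_rule(xn, svn)), "no qualifying")
})

test_that("threshold rules serialize and round-trip through text", {
  rules <- list(wgcna_star_rule(), cox_comparator_rule())
  m <- percentile_matrix(80, c("p53", "NaKATPase_beta1", "TGFbR2_cyt",
                               "MED28_cyt", "Smad4_cyt"), seed = 29)
  for (rule in rules) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_threshold_rule(path, rule)
    back <- read_threshold_rule(path)
    expect_identical(apply_threshold_rule(back, m),
                     apply_threshold_rule(rule, m))
  }
  expect_error(threshold_rule(list(marker = "x", percentile = 100,
                                   le = rule_leaf("a"), gt = rule_leaf("b"))))
})
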