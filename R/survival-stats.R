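#' Construct a right-censored survival outcome
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator: 1 = death, 0 = censored.
#' @param patient_ids Optional patient ids.
#' @return Data frame of class `surv_outcome` with columns `time`, `event`.
#' @export
surv_outcome <- function(time, event, patient_ids = NULL) {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  out <- data.frame(time = as.numeric(time), event = as.integer(event))
  if (!is.null(patient_ids)) rownames(out) <- patient_ids
  class(out) <- c("surv_outcome", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' @param survival Data frame with columns `time`, `event`.
#' @return Data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv` (right-continuous step function; `S(0) = 1`).
#' @export
kaplan_meier <- function(survival) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' k-group log-rank test
#'
#' Chi-square log-rank statistic on `k - 1` degrees of freedom, comparing
#' observed to expected events (hypergeometric variance) at each event time.
#'
#' @param survival Data frame with columns `time`, `event`.
#' @param groups Group labels aligned to patients.
#' @return List of class `tma_test`: `statistic`, `df`, `p`, `method`, `n`.
#' @export
logrank_test <- function(survival, groups) {
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2L)
    stop("log-rank test needs at least 2 nonempty groups", call. = FALSE)
  dat <- data.frame(time = survival$time, event = survival$event, g = g)
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- nlevels(g) - 1L
  tma_test(statistic = fit$chisq, df = df,
           p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
           method = "logrank", n = nrow(dat))
}

tma_test <- function(statistic, df, p, method, n = NA_integer_) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), method = method, n = n),
            class = "tma_test")
}

#' @export
print.tma_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation (Efron tie handling) with Wald
#' confidence intervals and p-values per coefficient, plus the generalized
#' R-squared `1 - exp(-2 (l1 - l0) / n)` computed from the null and fitted
#' log partial likelihoods. Rows with any missing covariate are dropped and
#' the complete-case `n` reported.
#'
#' @param covariates Numeric data frame or matrix (categoricals pre-encoded
#'   as indicators).
#' @param survival Data frame with columns `time`, `event`.
#' @return List of class `cox_fit`: `coefficients` (data frame with `coef`,
#'   `hr`, `lower95`, `upper95`, `p`), `r_squared`, `loglik` (null, fitted),
#'   `lr_p` (likelihood-ratio model p), `n`.
#' @export
cox_fit <- function(covariates, survival) {
  x <- as.data.frame(covariates)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  sv <- survival[keep, , drop = FALSE]
  consts <- vapply(x, function(v) length(unique(v)) < 2L, logical(1))
  if (any(consts))
    stop("degenerate covariate(s): ", paste(names(x)[consts], collapse = ", "),
         call. = FALSE)
  dat <- cbind(sv[, c("time", "event")], x)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", names(x)), collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (diverged || any(abs(stats::coef(fit)) > 15))
    stop("monotone partial likelihood: no finite MLE (coefficient diverging); ",
         "a covariate perfectly separates the risk sets", call. = FALSE)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  n <- fit$n
  ll <- fit$loglik
  res <- data.frame(
    coef = cf, hr = exp(cf),
    lower95 = exp(cf - 1.96 * se), upper95 = exp(cf + 1.96 * se),
    se = se, p = 2 * stats::pnorm(-abs(cf / se)))
  rownames(res) <- names(x)
  lr <- 2 * (ll[2] - ll[1])
  structure(list(
    coefficients = res,
    r_squared = 1 - exp(-lr / n),
    loglik = c(null = ll[1], fitted = ll[2]),
    lr_p = stats::pchisq(lr, length(cf), lower.tail = FALSE),
    n = n,
    r_squared_formula = "1 - exp(-2*(l1 - l0)/n)"),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties), n =", x$n, "\n")
  tab <- x$coefficients
  tab$hr_ci <- sprintf("%.2g (%.2g, %.2g)", tab$hr, tab$lower95, tab$upper95)
  print(data.frame(`HR (CI)` = tab$hr_ci, p = signif(tab$p, 3),
                   row.names = rownames(tab), check.names = FALSE))
  cat("Model R^2 =", signif(x$r_squared, 3),
      "(LR p =", format.pval(x$lr_p, digits = 3), ")\n")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with chi-square approximation on `k - 1`
#' degrees of freedom; missing values dropped. When all observations are
#' identical the statistic is 0 and p = 1 by convention.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned to `values`.
#' @return A `tma_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  v <- values[keep]; g <- droplevels(factor(groups[keep]))
  if (nlevels(g) < 2L) stop("need at least 2 nonempty groups", call. = FALSE)
  if (length(unique(v)) == 1L)
    return(tma_test(0, nlevels(g) - 1L, 1, "kruskal-wallis", length(v)))
  kt <- stats::kruskal.test(v, g)
  tma_test(kt$statistic, kt$parameter, kt$p.value, "kruskal-wallis", length(v))
}

#' Fisher's exact test on an r x c count table
#'
#' Exact conditional p-value by enumeration of tables with the observed
#' margins when the enumeration is tractable (bound <= `max_tables`);
#' otherwise a seeded Monte-Carlo p-value with `B` replicates.
#'
#' @param counts Matrix of nonnegative integer counts.
#' @param max_tables Enumeration bound before switching to Monte Carlo.
#' @param B Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo branch.
#' @return A `tma_test` whose `method` records the mode used.
#' @export
fisher_exact <- function(counts, max_tables = 1e6, B = 1e5, seed = 1L) {
  m <- as.matrix(counts)
  if (length(m) == 0L || sum(m) == 0) stop("empty table", call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  # upper bound on number of margin-consistent tables: free inner cells
  bound <- prod(outer(rs[-length(rs)], cs[-length(cs)], pmin) + 1)
  if (is.finite(bound) && bound <= max_tables) {
    ft <- stats::fisher.test(m)
    method <- "fisher-exact (enumeration)"
  } else {
    set.seed(seed)
    ft <- stats::fisher.test(m, simulate.p.value = TRUE, B = as.integer(B))
    method <- sprintf("fisher-exact (monte-carlo, B=%d)", as.integer(B))
  }
  tma_test(NA_real_, NA_integer_, ft$p.value, method, sum(m))
}

#' Per-group mortality table with overall log-rank test
#'
#' Deaths, group size and percent mortality (2 significant figures, the
#' convention used for printed tissue-microarray mortality tables) per
#' group, with the k-group log-rank test when at least two groups exist.
#'
#' @param groups Group labels per patient.
#' @param survival Data frame with columns `time`, `event`.
#' @return List of class `mortality_table`: `table` (data frame) and
#'   `logrank` (`tma_test` or `NULL` for a single group).
#' @export
mortality_table <- function(groups, survival) {
  g <- droplevels(factor(groups))
  if (any(table(g) == 0L)) stop("empty group", call. = FALSE)
  tab <- data.frame(
    group = levels(g),
    deaths = as.vector(tapply(survival$event, g, sum)),
    n = as.vector(table(g)))
  tab$pct_mortality <- signif(100 * tab$deaths / tab$n, 2)
  lr <- if (nlevels(g) >= 2L) logrank_test(survival, g) else NULL
  structure(list(table = tab, logrank = lr), class = "mortality_table")
}

#' @export
print.mortality_table <- function(x, ...) {
  df <- x$table
  df$summary <- sprintf("%d/%d (%g%%)", df$deaths, df$n, df$pct_mortality)
  print(df[, c("group", "summary")], row.names = FALSE)
  if (!is.null(x$logrank))
    cat("Log-rank p =", format.pval(x$logrank$p, digits = 3), "\n")
  invisible(x)
}

#' Cross-tabulate two group assignments
#'
#' Counts of assignment pairs over the jointly assigned patients, with
#' agreement (matching labels) and disagreement percentages (2 significant
#' figures).
#'
#' @param a,b Group labels (named by patient id where alignment matters);
#'   `NA` marks unassigned patients, which are excluded and counted.
#' @return List of class `confusion_table`: `counts`, `n`, `agree`,
#'   `disagree`, `agree_pct`, `disagree_pct`, `n_excluded`.
#' @export
cross_tabulate <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b))
    stop("assignments must align on a shared patient index", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  n_excluded <- sum(!keep)
  a <- factor(a[keep]); b <- factor(b[keep])
  n <- length(a)
  if (n == 0L) stop("no jointly assigned patients", call. = FALSE)
  counts <- table(a, b)
  shared <- intersect(levels(a), levels(b))
  agree <- sum(vapply(shared, function(l) counts[l, l], numeric(1)))
  structure(list(
    counts = counts, n = n, agree = agree, disagree = n - agree,
    agree_pct = signif(100 * agree / n, 2),
    disagree_pct = signif(100 * (n - agree) / n, 2),
    n_excluded = n_excluded),
    class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("N = %d, agree = %d (%g%%), disagree = %d (%g%%)\n",
              x$n, x$agree, x$agree_pct, x$disagree, x$disagree_pct))
  invisible(x)
}

#' Serialize test results to a flat TSV
#'
#' @param path Output path.
#' @param tests A list of `tma_test` objects.
#' @export
write_test_results <- function(path, tests) {
  df <- do.call(rbind, lapply(tests, function(t) {
    data.frame(method = t$method, statistic = t$statistic,
               df = t$df, p = t$p, n = t$n)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
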