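# Independent brute-force oracles used to cross-check the implementation.

# Naive O(n^3) average-linkage (UPGMA): average of ORIGINAL pairwise
# dissimilarities between cluster members; returns merge heights in order.
upgma_oracle_heights <- function(d) {
  d <- as.matrix(d)
  members <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(members) > 1L) {
    k <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        h <- mean(d[members[[i]], members[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    members[[best[2]]] <- c(members[[best[2]]], members[[best[3]]])
    members[[best[3]]] <- NULL
  }
  heights
}

gini_impurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

# Exhaustive first-split search by count-scale Gini improvement.
best_gini_split_oracle <- function(m, y) {
  n <- length(y)
  best <- list(improve = -Inf, marker = NA, cut = NA)
  for (j in colnames(m)) {
    v <- sort(unique(m[, j]))
    if (length(v) < 2L) next
    mids <- (v[-1] + v[-length(v)]) / 2
    for (cc in mids) {
      l <- y[m[, j] < cc]
      r <- y[m[, j] >= cc]
      imp <- n * gini_impurity(y) -
        length(l) * gini_impurity(l) - length(r) * gini_impurity(r)
      if (imp > best$improve + 1e-9)
        best <- list(improve = imp, marker = j, cut = cc)
    }
  }
  best
}

# Cox partial log-likelihood for a single covariate, no ties assumed.
cox_loglik_oracle <- function(b, time, event, x) {
  sum(vapply(which(event == 1), function(i) {
    risk <- time >= time[i]
    b * x[i] - log(sum(exp(b * x[risk])))
  }, numeric(1)))
}

# k-group log-rank chi-square with full hypergeometric covariance.
logrank_oracle <- function(time, event, g) {
  g <- droplevels(factor(g))
  k <- nlevels(g)
  OmE <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    n_t <- sum(risk)
    d_t <- sum(event == 1 & time == t)
    n_i <- vapply(levels(g), function(l) sum(risk & g == l), numeric(1))
    o_i <- vapply(levels(g), function(l)
      sum(event == 1 & time == t & g == l), numeric(1))
    OmE <- OmE + o_i - d_t * n_i / n_t
    if (n_t > 1) {
      frac <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + frac * (diag(n_i / n_t, k) - tcrossprod(n_i / n_t))
    }
  }
  drop(t(OmE[-k]) %*% solve(V[-k, -k, drop = FALSE]) %*% OmE[-k])
}

# Full enumeration of r x c tables with fixed margins; returns the exact
# conditional p-value and the total probability mass enumerated.
fisher_enum_oracle <- function(m) {
  m <- as.matrix(m)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  tab_prob <- function(t) exp(log_const - sum(lgamma(t + 1)))
  p_obs <- tab_prob(m)
  total <- 0; p_le <- 0
  fill_row <- function(i, col_left, acc) {
    if (i == nrow(m)) {
      if (any(col_left < 0)) return(invisible(NULL))
      t <- rbind(acc, col_left)
      pr <- tab_prob(t)
      total <<- total + pr
      if (pr <= p_obs * (1 + 1e-7)) p_le <<- p_le + pr
      return(invisible(NULL))
    }
    # enumerate compositions of rs[i] into ncol cells bounded by col_left
    cells <- function(j, left, row) {
      if (j == ncol(m)) {
        if (left <= col_left[j]) fill_row(i + 1L, col_left - c(row, left),
                                          rbind(acc, c(row, left)))
        return(invisible(NULL))
      }
      for (v in 0:min(left, col_left[j])) cells(j + 1L, left - v, c(row, v))
    }
    cells(1L, rs[i], numeric(0))
  }
  # wrapper handles the 1-row recursion base uniformly
  if (nrow(m) == 1L) return(list(p = 1, total = 1))
  fill_row(1L, cs, matrix(numeric(0), 0, ncol(m)))
  list(p = p_le, total = total)
}

# Expand a confusion-count matrix into two aligned label vectors.
expand_confusion <- function(counts) {
  a <- character(0); b <- character(0)
  for (i in rownames(counts)) {
    for (j in colnames(counts)) {
      a <- c(a, rep(i, counts[i, j]))
      b <- c(b, rep(j, counts[i, j]))
    }
  }
  n <- length(a)
  ids <- sprintf("P%03d", seq_len(n))
  list(a = stats::setNames(a, ids), b = stats::setNames(b, ids))
}

# Survival toy constructor: "12+" style strings -> time/event.
surv_toy <- function(...) {
  spec <- c(...)
  cens <- grepl("\\+$", spec)
  surv_outcome(as.numeric(sub("\\+$", "", spec)), as.integer(!cens))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
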