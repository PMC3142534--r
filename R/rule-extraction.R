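#' Construct a percentile threshold rule
#'
#' A threshold rule is a small binary decision tree over markers. Each
#' internal node carries a marker id, a percentile in (0, 100) and two
#' branches: `le` for values at or below the threshold and `gt` for values
#' strictly above it; each leaf carries a group label. Thresholds are stored
#' as percentiles, not raw values, so a rule transfers across platforms: on
#' any dataset the raw cutoff is re-derived from that dataset's own marker
#' distribution (type-7 empirical quantile).
#'
#' @param root Nested node list. Internal node:
#'   `list(marker =, percentile =, le =, gt =)`; leaf: `list(leaf = label)`.
#' @param provenance Optional list (training dataset id, raw cutpoints).
#' @return Object of class `threshold_rule`.
#' @export
threshold_rule <- function(root, provenance = list()) {
  check_node <- function(node) {
    if (!is.null(node$leaf)) return(invisible(TRUE))
    stopifnot(is.character(node$marker),
              node$percentile > 0, node$percentile < 100)
    check_node(node$le); check_node(node$gt)
  }
  check_node(root)
  structure(list(root = root, provenance = provenance),
            class = "threshold_rule")
}

rule_leaf <- function(label) list(leaf = label)

#' Markers referenced by a rule, in pre-order
#' @param rule A `threshold_rule`.
#' @return Character vector of marker ids (unique, root first).
#' @export
rule_markers <- function(rule) {
  walk <- function(node) {
    if (!is.null(node$leaf)) return(character(0))
    c(node$marker, walk(node$le), walk(node$gt))
  }
  unique(walk(rule$root))
}

#' The three-marker WGCNA* mortality rule
#'
#' The published percentile rule approximating the network-derived
#' mortality groups: high mortality when p53 is above its 75th percentile
#' and Na-K ATPase beta-1 at or below its 33rd percentile; moderate when
#' p53 is at or below its 75th percentile and TGF-beta receptor II
#' (cytoplasmic) above its 66th percentile; low otherwise (including the
#' high-p53 / high-Na-K-ATPase branch).
#'
#' @param p53,na_k_atpase,tgfbr2 Column names of the three markers in the
#'   marker matrix the rule will be applied to.
#' @return A `threshold_rule`.
#' @export
wgcna_star_rule <- function(p53 = "p53", na_k_atpase = "NaKATPase_beta1",
                            tgfbr2 = "TGFbR2_cyt") {
  threshold_rule(list(
    marker = p53, percentile = 75,
    le = list(marker = tgfbr2, percentile = 66,
              le = rule_leaf("low"), gt = rule_leaf("moderate")),
    gt = list(marker = na_k_atpase, percentile = 33,
              le = rule_leaf("high"), gt = rule_leaf("low"))),
    provenance = list(name = "WGCNA*"))
}

#' The two-marker stepwise-Cox comparator rule
#'
#' High mortality when cytoplasmic MED28 is above its 75th percentile;
#' moderate when MED28 is low but cytoplasmic Smad4 is above its 75th
#' percentile; low otherwise.
#'
#' @param med28,smad4 Column names of the two markers.
#' @return A `threshold_rule`.
#' @export
cox_comparator_rule <- function(med28 = "MED28_cyt", smad4 = "Smad4_cyt") {
  threshold_rule(list(
    marker = med28, percentile = 75,
    le = list(marker = smad4, percentile = 75,
              le = rule_leaf("low"), gt = rule_leaf("moderate")),
    gt = rule_leaf("high")),
    provenance = list(name = "COX"))
}

#' Apply a threshold rule to a marker matrix
#'
#' Percentile thresholds are re-evaluated on this dataset's marker
#' distributions (type-7 quantiles over observed values), then each patient
#' is routed through the rule. Patients with a missing value at a node they
#' reach are left unassigned (`NA`) unless the matrix was imputed first.
#'
#' @param rule A `threshold_rule`.
#' @param markers Patients x markers matrix containing all rule markers.
#' @return Factor of group labels per patient (`NA` = unassigned).
#' @export
apply_threshold_rule <- function(rule, markers) {
  m <- as.matrix(markers)
  missing_cols <- setdiff(rule_markers(rule), colnames(m))
  if (length(missing_cols) > 0L)
    stop("rule marker(s) absent from matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- rep(NA_character_, nrow(m))
  route <- function(node, idx) {
    if (length(idx) == 0L) return(invisible(NULL))
    if (!is.null(node$leaf)) {
      out[idx] <<- node$leaf
      return(invisible(NULL))
    }
    x <- m[, node$marker]
    thr <- stats::quantile(x, node$percentile / 100, na.rm = TRUE,
                           names = FALSE, type = 7)
    xi <- x[idx]
    route(node$le, idx[!is.na(xi) & xi <= thr])
    route(node$gt, idx[!is.na(xi) & xi > thr])
  }
  route(rule$root, seq_len(nrow(m)))
  res <- factor(out, levels = intersect(c("low", "moderate", "high", "all"),
                                        unique(stats::na.omit(out))))
  if (nlevels(res) == 0L)
    res <- factor(out)
  names(res) <- rownames(m)
  res
}

#' Fit a classification tree to approximate a grouping
#'
#' CART with Gini impurity via `rpart`, grown without an rpart-internal
#' complexity penalty and then pruned on the impurity scale: a split is
#' retained only if it reduces the total Gini impurity by at least
#' `complexity` times the root impurity (both on the count-weighted
#' scale), snipping top-down. Surrogate splits are disabled; observations
#' missing the split variable are dropped at that split (listwise per
#' split), keeping the tree deterministic.
#'
#' @param markers Patients x markers matrix.
#' @param target Factor of class labels per patient (e.g. network mortality
#'   groups).
#' @param complexity Minimum impurity improvement as a fraction of the root
#'   impurity (default 0.1).
#' @param min_split Minimum node size eligible for splitting.
#' @return Object of class `tree_model`: list with `root` (nested split
#'   structure after pruning; `NULL` means root-only), the underlying
#'   `rpart` fit, the training data and class levels.
#' @export
fit_classification_tree <- function(markers, target, complexity = 0.1,
                                    min_split = 5L) {
  m <- as.data.frame(as.matrix(markers))
  y <- droplevels(factor(target))
  if (nlevels(y) < 2L) {
    warning("single-class target: returning a root-only tree", call. = FALSE)
    return(structure(list(root = NULL, rpart = NULL, markers = m,
                          levels = levels(y), root_class = levels(y)[1L]),
                     class = "tree_model"))
  }
  dat <- cbind(m, .group = y)
  fit <- rpart::rpart(
    .group ~ ., data = dat, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      cp = 0, minsplit = min_split, maxsurrogate = 0,
      usesurrogate = 0, maxcompete = 0, xval = 0))
  props <- table(y) / length(y)
  root_gini <- length(y) * (1 - sum(props^2))
  root <- prune_rpart_gini(fit, complexity * root_gini)
  structure(list(root = root, rpart = fit, markers = m, levels = levels(y),
                 root_class = if (is.null(root)) {
                   attr(fit, "ylevels")[fit$frame$yval[1L]]
                 } else NULL),
            class = "tree_model")
}

# Convert an rpart fit into a nested split structure, keeping only splits
# whose count-scale Gini improvement meets `threshold` (top-down snip).
# Leaves carry the majority class of their (possibly collapsed) node.
prune_rpart_gini <- function(fit, threshold) {
  frame <- fit$frame
  nodenums <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  split_idx <- integer(nrow(frame))
  split_idx[!is_leaf] <- seq_len(sum(!is_leaf))
  ylevels <- attr(fit, "ylevels")
  build <- function(nn) {
    i <- match(nn, nodenums)
    label <- ylevels[frame$yval[i]]
    if (is_leaf[i]) return(list(label = label, n = frame$n[i], node = nn))
    s <- fit$splits[split_idx[i], ]
    if (s["improve"] < threshold)
      return(list(label = label, n = frame$n[i], node = nn))
    left <- build(2L * nn); right <- build(2L * nn + 1L)
    list(marker = as.character(frame$var[i]), cut = unname(s["index"]),
         ncat = unname(s["ncat"]), improve = unname(s["improve"]),
         n = frame$n[i], node = nn, left = left, right = right)
  }
  root <- build(1L)
  if (is.null(root$marker)) NULL else root
}

#' Predict training-style class assignments from a fitted tree
#'
#' Routes observations through the pruned tree using the raw cutpoints
#' (rpart split semantics: with `ncat = -1` the left branch takes values
#' below the cutpoint, with `ncat = +1` values at or above it). Rows with
#' a missing value at a node they reach get `NA`.
#'
#' @param object A `tree_model`.
#' @param newdata Marker matrix/data frame (default: training data).
#' @param ... Unused.
#' @return Character vector of leaf labels.
#' @export
predict.tree_model <- function(object, newdata = object$markers, ...) {
  m <- as.data.frame(as.matrix(newdata))
  out <- rep(NA_character_, nrow(m))
  if (is.null(object$root)) {
    out[] <- if (!is.null(object$root_class)) object$root_class else
      object$levels[1L]
    return(out)
  }
  route <- function(node, idx) {
    if (length(idx) == 0L) return(invisible(NULL))
    if (!is.null(node$label)) {
      out[idx] <<- node$label
      return(invisible(NULL))
    }
    x <- m[[node$marker]][idx]
    below <- !is.na(x) & x < node$cut
    above <- !is.na(x) & x >= node$cut
    if (node$ncat < 0) {
      route(node$left, idx[below]); route(node$right, idx[above])
    } else {
      route(node$left, idx[above]); route(node$right, idx[below])
    }
  }
  route(object$root, seq_len(nrow(m)))
  out
}

#' Convert a fitted tree's raw cutpoints to a percentile rule
#'
#' Each raw cutpoint is re-expressed as the empirical percentile of the
#' training distribution of its marker: the fraction of observed training
#' values strictly below the cutpoint. Applying the converted rule to the
#' training data reproduces the tree's leaf assignments exactly, because
#' the type-7 quantile at that percentile always falls in the same
#' inter-observation gap as the raw cutpoint.
#'
#' @param tree A `tree_model` from [fit_classification_tree()].
#' @param markers Training marker matrix (defaults to the matrix stored in
#'   the tree).
#' @param leaf_labels `"class"` (default) labels each leaf with its
#'   majority class, so several leaves may share a label; `"node"` gives
#'   each leaf a unique `leaf_<id>` label (used when leaves are re-ranked
#'   by mortality afterwards).
#' @return A `threshold_rule`; raw cutpoints kept in `provenance`.
#' @export
tree_to_threshold_rule <- function(tree, markers = tree$markers,
                                   leaf_labels = c("class", "node")) {
  leaf_labels <- match.arg(leaf_labels)
  m <- as.data.frame(as.matrix(markers))
  if (is.null(tree$root))
    return(threshold_rule(rule_leaf(tree$root_class),
                          provenance = list(source = "root-only tree")))
  cutpoints <- list()
  build <- function(node) {
    if (!is.null(node$label)) {
      lab <- if (leaf_labels == "node") paste0("leaf_", node$node)
             else node$label
      return(rule_leaf(lab))
    }
    x <- m[[node$marker]]
    x <- x[!is.na(x)]
    if (node$cut <= min(x) || node$cut > max(x))
      stop("cutpoint outside the observed training range for ", node$marker,
           call. = FALSE)
    pct <- 100 * sum(x < node$cut) / length(x)
    cutpoints[[length(cutpoints) + 1L]] <<- list(
      marker = node$marker, cut = node$cut, percentile = pct)
    left <- build(node$left)
    right <- build(node$right)
    if (node$ncat < 0) {   # left branch takes x < cut
      list(marker = node$marker, percentile = pct, le = left, gt = right)
    } else {               # left branch takes x >= cut
      list(marker = node$marker, percentile = pct, le = right, gt = left)
    }
  }
  threshold_rule(build(tree$root),
                 provenance = list(source = "classification tree",
                                   cutpoints = cutpoints))
}

#' @export
print.threshold_rule <- function(x, ...) {
  nm <- x$provenance$name
  cat("Threshold rule", if (!is.null(nm)) paste0("(", nm, ")"), "\n")
  show <- function(node, indent, prefix) {
    pad <- strrep("  ", indent)
    if (!is.null(node$leaf)) {
      cat(pad, prefix, "-> ", node$leaf, "\n", sep = "")
    } else {
      cat(pad, prefix, node$marker, " @ ", signif(node$percentile, 3),
          "th percentile\n", sep = "")
      show(node$le, indent + 1L, "<=: ")
      show(node$gt, indent + 1L, " >: ")
    }
  }
  show(x$root, 0L, "")
  invisible(x)
}

#' Median imputation of missing staining values
#'
#' Replaces missing entries in the listed columns by the column median of
#' observed values (the median, not the mean, because staining
#' distributions are heavily skewed). Observed entries are untouched.
#'
#' @param markers Patients x markers matrix.
#' @param columns Columns to impute (default: all).
#' @return The matrix with listed columns imputed.
#' @export
median_impute <- function(markers, columns = colnames(markers)) {
  m <- as.matrix(markers)
  for (col in columns) {
    if (!col %in% colnames(m)) stop("no such column: ", col, call. = FALSE)
    x <- m[, col]
    if (all(is.na(x))) stop("column entirely missing: ", col, call. = FALSE)
    m[is.na(x), col] <- stats::median(x, na.rm = TRUE)
  }
  m
}

#' Test whether missingness is related to survival
#'
#' For every marker with at least one missing and one observed value, a
#' two-group log-rank test of the missing-vs-observed indicator. A
#' threshold rule should only be rescued by imputation when this check does
#' not suggest informative missingness.
#'
#' @param markers Patients x markers matrix.
#' @param survival Data frame with columns `time`, `event`.
#' @return Data frame: `marker`, `n_missing`, `statistic`, `p`,
#'   `applicable` (FALSE for fully observed or fully missing markers).
#' @export
missingness_vs_survival <- function(markers, survival) {
  m <- as.matrix(markers)
  res <- lapply(colnames(m), function(col) {
    miss <- is.na(m[, col])
    if (all(miss) || !any(miss)) {
      data.frame(marker = col, n_missing = sum(miss),
                 statistic = NA_real_, p = NA_real_, applicable = FALSE)
    } else {
      t <- logrank_test(survival, ifelse(miss, "missing", "observed"))
      data.frame(marker = col, n_missing = sum(miss),
                 statistic = t$statistic, p = t$p, applicable = TRUE)
    }
  })
  do.call(rbind, res)
}

#' Optimal survival dichotomization of one marker
#'
#' Scans every midpoint between consecutive distinct observed values that
#' leaves at least `min_group_size` patients on each side, fits a
#' univariate Cox model to the above-threshold indicator at each candidate,
#' and returns the threshold with the smallest Wald p-value (ties broken
#' toward the more balanced split). The result is non-qualifying when the
#' best p-value is not below 0.05 or no admissible threshold exists.
#'
#' @param values Numeric marker values (`NA` allowed).
#' @param survival Data frame with columns `time`, `event`.
#' @param min_group_size Minimum patients per side (default 5).
#' @return List of class `dichotomization`: `threshold`, `p`, `n_low`,
#'   `n_high`, `qualifies`, `n_candidates`.
#' @export
optimal_dichotomize <- function(values, survival, min_group_size = 5L) {
  obs <- !is.na(values)
  x <- values[obs]
  sv <- survival[obs, , drop = FALSE]
  nonq <- structure(list(threshold = NA_real_, p = NA_real_,
                         n_low = NA_integer_, n_high = NA_integer_,
                         qualifies = FALSE, n_candidates = 0L),
                    class = "dichotomization")
  if (length(x) < 2L * min_group_size) return(nonq)
  vals <- sort(unique(x))
  if (length(vals) < 2L) return(nonq)
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  cand <- mids[vapply(mids, function(t) {
    min(sum(x <= t), sum(x > t)) >= min_group_size
  }, logical(1))]
  if (length(cand) == 0L) return(nonq)
  yy <- survival::Surv(sv$time, sv$event)
  scan <- lapply(cand, function(t) {
    ind <- as.integer(x > t)
    diverged <- FALSE
    p <- tryCatch({
      fit <- withCallingHandlers(
        survival::coxph.fit(matrix(as.double(ind)), yy,
                            strata = NULL, offset = NULL, init = 0,
                            control = survival::coxph.control(),
                            weights = NULL, method = "efron",
                            rownames = NULL),
        warning = function(w) {
          if (grepl("infinite|did not converge", conditionMessage(w)))
            diverged <<- TRUE
          invokeRestart("muffleWarning")
        })
      b <- fit$coefficients
      if (diverged || !is.finite(b) || abs(b) > 15) NA_real_
      else 2 * stats::pnorm(-abs(b / sqrt(fit$var[1, 1])))
    }, error = function(e) NA_real_)
    list(threshold = t, p = p, n_low = sum(ind == 0L), n_high = sum(ind == 1L))
  })
  ps <- vapply(scan, `[[`, numeric(1), "p")
  if (all(is.na(ps))) {
    nonq$n_candidates <- length(cand)
    return(nonq)
  }
  pmin_ <- min(ps, na.rm = TRUE)
  tied <- which(!is.na(ps) & ps <= pmin_ + 1e-12)
  bal <- vapply(scan[tied], function(s) abs(s$n_high - s$n_low), numeric(1))
  best <- scan[[tied[which.min(bal)]]]
  structure(list(threshold = best$threshold, p = best$p,
                 n_low = best$n_low, n_high = best$n_high,
                 qualifies = is.finite(best$p) && best$p < 0.05,
                 n_candidates = length(cand)),
            class = "dichotomization")
}

#' Backward stepwise Cox selection over dichotomized markers
#'
#' Starting from all supplied indicator covariates, repeatedly removes the
#' covariate with the largest Wald p-value at or above `alpha` and refits,
#' until every remaining covariate is significant or none remain. Exact
#' duplicate columns are collapsed first; a covariate whose coefficient
#' diverges (monotone likelihood) is removed with a warning.
#'
#' @param dichotomized Data frame/matrix of 0/1 indicator columns.
#' @param survival Data frame with columns `time`, `event`.
#' @param alpha Retention threshold (default 0.05).
#' @return List: `retained` (character), `fit` (a `cox_fit`, or `NULL` when
#'   nothing is retained).
#' @export
stepwise_cox <- function(dichotomized, survival, alpha = 0.05) {
  x <- as.data.frame(dichotomized)
  if (ncol(x) == 0L) stop("no qualifying dichotomized markers", call. = FALSE)
  dup <- duplicated(as.list(x))
  if (any(dup)) {
    warning("collinear duplicate covariate(s) removed: ",
            paste(names(x)[dup], collapse = ", "), call. = FALSE)
    x <- x[, !dup, drop = FALSE]
  }
  repeat {
    if (ncol(x) == 0L) return(list(retained = character(0), fit = NULL))
    fit <- tryCatch(cox_fit(x, survival), error = function(e) e)
    if (inherits(fit, "error")) {
      # drop the covariate responsible for degeneracy/divergence: refit each
      # leave-one-out model and drop the one whose removal restores a fit
      drop_idx <- NULL
      for (j in seq_len(ncol(x))) {
        ok <- tryCatch({
          if (ncol(x) > 1L) cox_fit(x[, -j, drop = FALSE], survival)
          TRUE
        }, error = function(e) FALSE)
        if (isTRUE(ok)) { drop_idx <- j; break }
      }
      if (is.null(drop_idx)) drop_idx <- 1L
      warning("covariate removed after failed fit: ", names(x)[drop_idx],
              call. = FALSE)
      x <- x[, -drop_idx, drop = FALSE]
      next
    }
    ps <- fit$coefficients$p
    if (all(ps < alpha)) return(list(retained = names(x), fit = fit))
    worst <- which.max(ps)
    x <- x[, -worst, drop = FALSE]
  }
}

#' Build the stepwise-Cox comparator threshold rule
#'
#' The conventional multimarker pipeline: (1) optimally dichotomize every
#' marker for survival prediction, keeping markers with at least
#' `min_group_size` patients per side and univariate Cox p < 0.05;
#' (2) backward stepwise Cox selection at `alpha` over the qualifying
#' indicators; (3) a classification tree (complexity `complexity`) over the
#' retained markers against the death indicator, whose leaves -- ranked by
#' training mortality -- become the low/moderate/high groups of a
#' percentile threshold rule.
#'
#' @param markers Patients x markers matrix.
#' @param survival Data frame with columns `time`, `event`.
#' @param complexity Tree complexity parameter (default 0.1).
#' @param min_group_size Minimum patients per dichotomization side.
#' @param alpha Stepwise retention level.
#' @return A `threshold_rule` with mortality-ranked leaf labels; the
#'   retained marker set and per-marker dichotomizations in `provenance`.
#' @export
build_cox_rule <- function(markers, survival, complexity = 0.1,
                           min_group_size = 5L, alpha = 0.05) {
  m <- as.matrix(markers)
  dich <- lapply(colnames(m), function(col)
    optimal_dichotomize(m[, col], survival, min_group_size))
  names(dich) <- colnames(m)
  qual <- names(dich)[vapply(dich, `[[`, logical(1), "qualifies")]
  if (length(qual) == 0L) stop("no qualifying markers", call. = FALSE)
  ind <- as.data.frame(lapply(qual, function(col)
    as.integer(m[, col] > dich[[col]]$threshold)))
  names(ind) <- qual
  step <- stepwise_cox(ind, survival, alpha)
  if (length(step$retained) == 0L)
    stop("no qualifying markers", call. = FALSE)
  tree <- fit_classification_tree(
    m[, step$retained, drop = FALSE],
    factor(ifelse(survival$event == 1, "death", "alive")),
    complexity = complexity)
  if (is.null(tree$root))
    stop("no qualifying markers", call. = FALSE)
  rule <- tree_to_threshold_rule(tree, leaf_labels = "node")
  # rank leaves by training mortality and relabel low/moderate/high
  groups <- apply_threshold_rule(rule, m)
  leaf_labels <- levels(droplevels(factor(groups)))
  rate <- vapply(leaf_labels, function(l) {
    idx <- which(!is.na(groups) & groups == l)
    mean(survival$event[idx])
  }, numeric(1))
  size <- vapply(leaf_labels, function(l)
    sum(!is.na(groups) & groups == l), numeric(1))
  ord <- order(rate, -size)
  k <- length(leaf_labels)
  new_labels <- if (k == 2L) c("low", "high")
                else if (k == 3L) c("low", "moderate", "high")
                else paste0("group_", seq_len(k))
  mapping <- stats::setNames(new_labels, leaf_labels[ord])
  if (k < 3L)
    message("comparator rule has ", k, " leaves; labels used: ",
            paste(new_labels, collapse = ", "))
  relabel <- function(node) {
    if (!is.null(node$leaf)) return(rule_leaf(unname(mapping[node$leaf])))
    node$le <- relabel(node$le); node$gt <- relabel(node$gt)
    node
  }
  threshold_rule(relabel(rule$root),
                 provenance = list(name = "COX",
                                   retained = step$retained,
                                   dichotomizations = dich[qual],
                                   cutpoints = rule$provenance$cutpoints))
}

#' Serialize a threshold rule to a structured text file
#'
#' One tab-separated line per node: `node_id`, `marker`, `percentile`,
#' `le`, `gt`, where branch fields are `node:<id>` or `leaf:<label>`.
#' Round-trip stable with [read_threshold_rule()].
#'
#' @param path Output path.
#' @param rule A `threshold_rule`.
#' @export
write_threshold_rule <- function(path, rule) {
  rows <- list()
  emit <- function(node) {
    if (!is.null(node$leaf)) return(paste0("leaf:", node$leaf))
    id <- length(rows) + 1L
    rows[[id]] <<- list(id = id, marker = node$marker,
                        percentile = node$percentile, le = NA, gt = NA)
    le <- emit(node$le); gt <- emit(node$gt)
    rows[[id]]$le <<- le; rows[[id]]$gt <<- gt
    paste0("node:", id)
  }
  if (!is.null(rule$root$leaf)) {
    writeLines(c("id\tmarker\tpercentile\tle\tgt",
                 paste0("1\t.\tNA\tleaf:", rule$root$leaf,
                        "\tleaf:", rule$root$leaf)), path)
    return(invisible(path))
  }
  emit(rule$root)
  lines <- vapply(rows, function(r) {
    paste(r$id, r$marker, format(r$percentile, digits = 15), r$le, r$gt,
          sep = "\t")
  }, character(1))
  writeLines(c("id\tmarker\tpercentile\tle\tgt", lines), path)
  invisible(path)
}

#' Read a threshold rule written by [write_threshold_rule()]
#'
#' @param path Input path.
#' @return A `threshold_rule`.
#' @export
read_threshold_rule <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  parse_ref <- function(ref) {
    if (startsWith(ref, "leaf:")) return(rule_leaf(sub("^leaf:", "", ref)))
    build(as.integer(sub("^node:", "", ref)))
  }
  build <- function(id) {
    r <- df[df$id == id, ]
    if (r$marker == ".") return(rule_leaf(sub("^leaf:", "", r$le)))
    list(marker = r$marker, percentile = as.numeric(r$percentile),
         le = parse_ref(r$le), gt = parse_ref(r$gt))
  }
  threshold_rule(build(1L), provenance = list(source = path))
}
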