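#' Module detection parameters
#'
#' @param minClusterSize Smallest allowed module; smaller branches are
#'   absorbed into the nearest module. Default 2, suitable for small
#'   tissue-microarray cohorts.
#' @param deepSplit Split sensitivity 0-3. Indexes the quantile of merge
#'   heights used as the adaptive cut height (0.50, 0.75, 0.90, 0.95):
#'   higher values cut lower relative to the tree and yield more, finer
#'   modules. Default 3.
#' @param cutHeight Eigensample dissimilarity `1 - cor(ME_a, ME_b)` below
#'   which two modules are merged. Default 0.15.
#' @param optimize_merge If `TRUE`, the merge height is chosen from
#'   `merge_grid` to minimise the log-rank p-value against survival. The
#'   resulting p-value is overfit and flagged as descriptive.
#' @param merge_grid Candidate cut heights for [optimize_merge()].
#' @return An object of class `module_config`.
#' @export
module_config <- function(minClusterSize = 2L, deepSplit = 3L,
                          cutHeight = 0.15, optimize_merge = FALSE,
                          merge_grid = seq(0.05, 0.30, by = 0.05)) {
  if (!deepSplit %in% 0:3) stop("`deepSplit` must be in 0:3", call. = FALSE)
  if (cutHeight <= 0 || cutHeight >= 1)
    stop("`cutHeight` must be in (0, 1)", call. = FALSE)
  structure(list(minClusterSize = as.integer(minClusterSize),
                 deepSplit = as.integer(deepSplit), cutHeight = cutHeight,
                 optimize_merge = isTRUE(optimize_merge),
                 merge_grid = merge_grid),
            class = "module_config")
}

#' Average-linkage hierarchical clustering of patients
#'
#' UPGMA clustering of the network dissimilarity `dissA = 1 - adjacency`.
#'
#' @param dissimilarity Square symmetric matrix with zero diagonal.
#' @return An `hclust` object (merge sequence, heights, leaf order).
#' @export
hierarchical_cluster <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("dissimilarity must be square and symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-8))
    stop("dissimilarity must have zero diagonal", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Adaptive branch cut of a patient dendrogram
#'
#' Cuts the tree at an adaptive height -- the `q`-quantile of merge heights
#' with `q` in (0.50, 0.75, 0.90, 0.95) indexed by `deepSplit` -- then
#' absorbs every branch smaller than `minClusterSize` into the module with
#' the smallest average dissimilarity to it. This is a simplified
#' quantile-height variant of dynamic tree cutting: it keeps the adaptive
#' height and minimum-size semantics without per-branch shape analysis.
#'
#' @param dend `hclust` object from [hierarchical_cluster()].
#' @param dissimilarity The matrix the tree was built from.
#' @param config A [module_config()].
#' @return Integer vector of module ids (1..k), named by patient.
#' @export
dynamic_cut <- function(dend, dissimilarity, config = module_config()) {
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  if (config$minClusterSize > n)
    stop("`minClusterSize` exceeds the number of patients", call. = FALSE)
  q <- c(0.50, 0.75, 0.90, 0.95)[config$deepSplit + 1L]
  h0 <- stats::quantile(dend$height, q, names = FALSE, type = 7)
  labs <- stats::cutree(dend, h = h0)
  labs <- absorb_small_modules(labs, d, config$minClusterSize)
  names(labs) <- rownames(d)
  labs
}

# Reassign members of undersized modules to the module with smallest average
# dissimilarity; iterates smallest-first until all modules reach min_size or
# a single module remains.
absorb_small_modules <- function(labs, d, min_size) {
  repeat {
    sizes <- table(labs)
    if (length(sizes) <= 1L) break
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0L) break
    victim <- small[order(sizes[small])][1L]
    members <- which(labs == victim)
    others <- setdiff(names(sizes), victim)
    avg <- vapply(others, function(m) {
      mean(d[members, labs == m, drop = FALSE])
    }, numeric(1))
    labs[members] <- as.integer(others[which.min(avg)])
  }
  # renumber 1..k preserving order of first appearance
  ids <- unique(labs)
  match(labs, ids)
}

#' Module eigensample
#'
#' The first principal component of a module, a vector of length
#' `n_markers` summarising the module's patients: the first right-singular
#' direction of the row-standardised members x markers submatrix. Each
#' patient profile is centred and scaled across markers before the
#' decomposition so the eigensample captures the shared profile shape, and
#' its sign is chosen so the average correlation with member profiles is
#' non-negative (the "weighted average profile" orientation). Missing
#' staining values are median-imputed per marker within the module first.
#'
#' @param markers Patients x markers matrix (`NA` allowed).
#' @param members Patient ids or row indices belonging to the module.
#' @return List of class `eigensample`: `vector` (unit norm, length
#'   `n_markers`), `explained` (variance fraction), `sign`.
#' @export
eigensample <- function(markers, members) {
  x <- as.matrix(markers)[members, , drop = FALSE]
  if (nrow(x) == 0L) stop("module has no members", call. = FALSE)
  # within-module median imputation; fall back to full-cohort median
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) {
      med <- stats::median(x[!nas, j])
      if (is.na(med)) med <- stats::median(as.matrix(markers)[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      x[nas, j] <- med
    }
  }
  sds <- apply(x, 1L, stats::sd)
  if (all(sds == 0 | is.na(sds)))
    stop("degenerate module: all profiles constant", call. = FALSE)
  xs <- t(scale(t(x)))
  xs[is.na(xs)] <- 0  # constant rows contribute nothing
  sv <- svd(xs, nu = 0, nv = min(dim(xs)))
  v1 <- sv$v[, 1L]
  orient <- mean(apply(xs, 1L, function(r) {
    if (stats::sd(r) == 0) 0 else stats::cor(r, v1)
  }))
  sgn <- if (orient < 0) -1 else 1
  structure(list(vector = sgn * v1,
                 explained = sv$d[1L]^2 / sum(sv$d^2),
                 sign = sgn),
            class = "eigensample")
}

module_eigensamples <- function(markers, assignment) {
  ids <- sort(unique(assignment))
  vapply(ids, function(m) {
    eigensample(markers, which(assignment == m))$vector
  }, numeric(ncol(markers)))
}

#' Merge modules with similar eigensamples
#'
#' Iteratively merges the module pair with the smallest eigensample
#' dissimilarity `1 - cor(ME_a, ME_b)` while that dissimilarity is below
#' `cutHeight`, recomputing eigensamples after every merge.
#'
#' @param markers Patients x markers matrix.
#' @param assignment Integer module ids per patient.
#' @param cutHeight Merge threshold on eigensample dissimilarity.
#' @return Merged integer module assignment (renumbered 1..k).
#' @export
merge_modules <- function(markers, assignment, cutHeight = 0.15) {
  labs <- as.integer(factor(assignment))
  names(labs) <- names(assignment)
  repeat {
    ids <- sort(unique(labs))
    if (length(ids) <= 1L) break
    me <- module_eigensamples(markers, labs)
    dme <- 1 - stats::cor(me)
    dme[is.na(dme)] <- Inf
    diag(dme) <- Inf
    best <- which(dme == min(dme), arr.ind = TRUE)[1L, ]
    if (min(dme) >= cutHeight) break
    a <- ids[min(best)]; b <- ids[max(best)]
    labs[labs == b] <- a
  }
  out <- match(labs, unique(labs))
  names(out) <- names(labs)
  out
}

#' Mortality-optimised module merging
#'
#' Evaluates each candidate merge height and selects the one whose merged
#' modules minimise the log-rank p-value against survival. Because the
#' grouping is chosen with respect to the outcome, the selected p-value is
#' overfit; the result carries `overfit = TRUE` and the p-value should be
#' read as descriptive, not inferential.
#'
#' @param markers Patients x markers matrix.
#' @param assignment Pre-merge module assignment.
#' @param survival Data frame with columns `time`, `event`.
#' @param merge_grid Candidate cut heights.
#' @return List: `cutHeight`, `assignment`, `logrank_p`, `overfit = TRUE`.
#' @export
optimize_merge <- function(markers, assignment, survival,
                           merge_grid = seq(0.05, 0.30, by = 0.05)) {
  if (length(merge_grid) == 0L) stop("`merge_grid` is empty", call. = FALSE)
  best <- NULL
  for (ch in merge_grid) {
    merged <- merge_modules(markers, assignment, ch)
    p <- if (length(unique(merged)) >= 2L) {
      logrank_test(survival, merged)$p
    } else 1
    if (is.null(best) || p < best$logrank_p) {
      best <- list(cutHeight = ch, assignment = merged, logrank_p = p,
                   overfit = TRUE)
    }
  }
  best
}

#' Label modules as mortality groups
#'
#' Ranks modules by crude mortality (deaths / size, ascending; ties broken
#' by larger module first) and labels them `low`/`moderate`/`high` when
#' there are exactly three, `all` for a single module, and
#' `group_1 ... group_k` otherwise.
#'
#' @param assignment Integer module ids per patient.
#' @param survival Data frame with columns `time`, `event` aligned to
#'   patients.
#' @return Factor of group labels per patient, levels ordered by mortality.
#' @export
label_mortality_groups <- function(assignment, survival) {
  ids <- sort(unique(assignment))
  sizes <- vapply(ids, function(m) sum(assignment == m), integer(1))
  if (any(sizes == 0L)) stop("empty module", call. = FALSE)
  deaths <- vapply(ids, function(m) sum(survival$event[assignment == m]),
                   numeric(1))
  rate <- deaths / sizes
  ord <- order(rate, -sizes)
  k <- length(ids)
  lab <- if (k == 1L) "all" else if (k == 3L) {
    c("low", "moderate", "high")
  } else paste0("group_", seq_len(k))
  out <- factor(lab[match(assignment, ids[ord])], levels = lab)
  names(out) <- names(assignment)
  out
}

#' Write group assignments as two-column TSV
#'
#' @param path Output path.
#' @param groups Named factor/vector of group labels per patient.
#' @export
write_assignments <- function(path, groups) {
  utils::write.table(
    data.frame(patient_id = names(groups), group = as.character(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
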