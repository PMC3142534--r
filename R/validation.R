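#' Enumerate probe combinations for a rule
#'
#' On expression platforms a protein marker is typically represented by
#' several probe sets; a three-marker rule with two probes per marker
#' therefore has eight (2 x 2 x 2) versions. Returns the cartesian product
#' of probe choices, one column per rule marker, in deterministic
#' annotation order (first marker's probes vary slowest).
#'
#' @param annotation Named list mapping marker id to a character vector of
#'   probe ids.
#' @param rule A `threshold_rule`.
#' @return Data frame of probe ids, one row per combination, columns named
#'   by marker.
#' @export
enumerate_probe_combinations <- function(annotation, rule) {
  mk <- rule_markers(rule)
  missing <- setdiff(mk, names(annotation))
  if (length(missing) > 0L)
    stop("unannotated rule marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  empty <- mk[vapply(annotation[mk], length, integer(1)) == 0L]
  if (length(empty) > 0L)
    stop("marker(s) with empty probe list: ", paste(empty, collapse = ", "),
         call. = FALSE)
  grid <- rev(expand.grid(rev(annotation[mk]), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- mk
  grid
}

#' Validate a threshold rule on an independent expression dataset
#'
#' For every probe combination the rule's percentile thresholds are
#' recomputed on this dataset's probe distributions, patients are assigned
#' to groups, and a univariate Cox model is fitted with the low group as
#' reference and indicators for the moderate and high groups. A combination
#' validates when the Wald p-value of the high-mortality indicator is below
#' `alpha`; the moderate-group p-value is reported but does not gate the
#' flag. An empty moderate or high group makes its hazard ratio
#' not-estimable and the flag false; an empty low (reference) group is an
#' error.
#'
#' @param rule A `threshold_rule` with `low`/`moderate`/`high` leaves (a
#'   two-leaf rule with `low`/`high` is accepted).
#' @param expression Samples x probes numeric matrix.
#' @param survival Data frame with columns `time`, `event`, aligned to the
#'   expression rows.
#' @param annotation Named list: marker id -> probe ids.
#' @param alpha Significance level for the validation flag (default 0.1).
#' @param dataset_id Optional label recorded in the report.
#' @return Data frame of class `validation_report`, one row per probe
#'   combination: probe ids, group sizes, `hr_moderate`, `hr_high`,
#'   `p_moderate`, `p_high`, `model_p`, `validates`.
#' @export
validate_rule <- function(rule, expression, survival, annotation,
                          alpha = 0.1, dataset_id = "validation") {
  expr <- as.matrix(expression)
  combos <- enumerate_probe_combinations(annotation, rule)
  probes_needed <- unique(unlist(annotation[rule_markers(rule)]))
  absent <- setdiff(probes_needed, colnames(expr))
  if (length(absent) > 0L)
    stop("probe(s) absent from expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    probe_of <- unlist(combos[i, , drop = FALSE])
    m <- expr[, probe_of, drop = FALSE]
    colnames(m) <- names(probe_of)
    groups <- apply_threshold_rule(rule, m)
    sizes <- c(low = sum(groups == "low", na.rm = TRUE),
               moderate = sum(groups == "moderate", na.rm = TRUE),
               high = sum(groups == "high", na.rm = TRUE))
    if (sizes["low"] == 0L)
      stop("empty low (reference) group in combination ", i, call. = FALSE)
    hr_mod <- hr_high <- p_mod <- p_high <- model_p <- NA_real_
    cov <- data.frame(moderate = as.integer(groups == "moderate"),
                      high = as.integer(groups == "high"))
    cov <- cov[, sizes[c("moderate", "high")] > 0L, drop = FALSE]
    if (ncol(cov) > 0L && sizes["high"] > 0L) {
      fit <- tryCatch(cox_fit(cov, survival), error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- fit$coefficients
        if ("moderate" %in% rownames(cf)) {
          hr_mod <- cf["moderate", "hr"]; p_mod <- cf["moderate", "p"]
        }
        if ("high" %in% rownames(cf)) {
          hr_high <- cf["high", "hr"]; p_high <- cf["high", "p"]
        }
        model_p <- fit$lr_p
      }
    }
    validates <- !is.na(p_high) && p_high < alpha
    data.frame(combination = i,
               as.data.frame(as.list(probe_of), stringsAsFactors = FALSE),
               n_low = sizes[["low"]], n_moderate = sizes[["moderate"]],
               n_high = sizes[["high"]],
               hr_moderate = hr_mod, hr_high = hr_high,
               p_moderate = p_mod, p_high = p_high, model_p = model_p,
               validates = validates)
  })
  out <- do.call(rbind, rows)
  attr(out, "dataset_id") <- dataset_id
  attr(out, "alpha") <- alpha
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Leaf labels of a threshold rule
#' @param rule A `threshold_rule`.
#' @return Character vector of unique leaf labels.
#' @export
rule_leaves <- function(rule) {
  walk <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    c(walk(node$le), walk(node$gt))
  }
  unique(walk(rule$root))
}

#' Write a validation report as TSV
#'
#' @param path Output path.
#' @param report A `validation_report`.
#' @export
write_report <- function(path, report) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
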