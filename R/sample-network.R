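#' Network construction parameters
#'
#' Parameters of the weighted sample (patient) correlation network. The
#' signed network maps a Pearson correlation `r` to an adjacency
#' `(0.5 + 0.5 r)^beta`, so that strongly positively correlated patients are
#' connected while anti-correlated ones are not; the unsigned variant uses
#' `|r|^beta`. Raising to the power `beta` is a soft threshold: it
#' de-emphasises weak correlations without imposing a hard cutoff.
#'
#' @param beta Positive soft-threshold power. Default 10, the value used for
#'   patient networks over tissue-microarray staining profiles.
#' @param network_type `"signed"` (default) or `"unsigned"`.
#' @param min_overlap Minimum number of markers observed in both patients for
#'   their pairwise correlation to be considered estimable. Must be >= 3.
#' @return An object of class `network_config`.
#' @export
network_config <- function(beta = 10, network_type = c("signed", "unsigned"),
                           min_overlap = 5L) {
  network_type <- match.arg(network_type)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1)
    stop("`beta` must be a single number >= 1", call. = FALSE)
  if (!is.numeric(min_overlap) || min_overlap < 3)
    stop("`min_overlap` must be >= 3", call. = FALSE)
  structure(list(beta = beta, network_type = network_type,
                 min_overlap = as.integer(min_overlap)),
            class = "network_config")
}

#' Pairwise Pearson correlation between patients
#'
#' Correlates every pair of patient staining profiles across the markers
#' observed in both (pairwise-complete Pearson). Pairs sharing fewer than
#' `min_overlap` observed markers, and pairs involving a profile with zero
#' variance over the shared markers, are flagged as missing (`NA`).
#'
#' @param markers Numeric matrix, patients in rows, markers in columns,
#'   `NA` for missing staining values. Row names are patient ids.
#' @param min_overlap Minimum shared observed markers per pair.
#' @return Symmetric patients x patients correlation matrix with unit
#'   diagonal; `NA` marks inestimable pairs.
#' @export
pairwise_sample_correlation <- function(markers, min_overlap = 5L) {
  markers <- as.matrix(markers)
  if (nrow(markers) < 2L)
    stop("need at least 2 patients", call. = FALSE)
  suppressWarnings(
    rho <- stats::cor(t(markers), use = "pairwise.complete.obs",
                      method = "pearson")
  )
  obs <- !is.na(markers)
  overlap <- obs %*% t(obs)
  thin <- overlap < min_overlap
  if (any(thin[upper.tri(thin)]))
    warning(sum(thin[upper.tri(thin)]),
            " patient pair(s) share fewer than ", min_overlap,
            " observed markers; correlations flagged missing", call. = FALSE)
  if (any(is.na(rho[upper.tri(rho)]) & !thin[upper.tri(thin)]))
    warning("zero-variance profile over shared markers; ",
            "affected correlations flagged missing", call. = FALSE)
  rho[thin] <- NA_real_
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(markers), rownames(markers))
  rho
}

#' Soft-threshold adjacency and dissimilarity
#'
#' Transforms a patient correlation matrix into a weighted network adjacency:
#' signed `a = (0.5 + 0.5 r)^beta` or unsigned `a = |r|^beta`, together with
#' the clustering dissimilarity `dissA = 1 - a`. Missing correlations
#' propagate as missing adjacencies.
#'
#' @param cor_matrix Symmetric correlation matrix with entries in `[-1, 1]`.
#' @param config A [network_config()].
#' @return An object of class `patient_network`: list with `adjacency`,
#'   `dissimilarity` and `config`.
#' @export
adjacency <- function(cor_matrix, config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  cm <- as.matrix(cor_matrix)
  rng <- range(cm, na.rm = TRUE)
  if (rng[1] < -1 - 1e-12 || rng[2] > 1 + 1e-12)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  a <- if (config$network_type == "signed") {
    (0.5 + 0.5 * cm)^config$beta
  } else {
    abs(cm)^config$beta
  }
  diag(a) <- 1
  structure(list(adjacency = a, dissimilarity = 1 - a, config = config),
            class = "patient_network")
}

#' Build a patient network from a marker matrix
#'
#' Convenience wrapper: pairwise-complete correlation, soft-threshold
#' adjacency, and imputation of inestimable pairs with the median
#' off-diagonal adjacency (logged via a warning) so that the dissimilarity
#' is a complete input for clustering.
#'
#' @inheritParams pairwise_sample_correlation
#' @param config A [network_config()].
#' @return A `patient_network` whose adjacency has no missing entries.
#' @export
build_patient_network <- function(markers, config = network_config()) {
  rho <- pairwise_sample_correlation(markers, config$min_overlap)
  net <- adjacency(rho, config)
  a <- net$adjacency
  miss <- is.na(a)
  if (any(miss)) {
    off <- a[upper.tri(a)]
    fill <- stats::median(off, na.rm = TRUE)
    warning(sum(miss[upper.tri(miss)]),
            " inestimable pair(s) filled with median off-diagonal adjacency ",
            signif(fill, 4), call. = FALSE)
    a[miss] <- fill
    net$adjacency <- a
    net$dissimilarity <- 1 - a
    diag(net$dissimilarity) <- 0
  }
  net
}

#' @export
print.patient_network <- function(x, ...) {
  cat("Patient network:", nrow(x$adjacency), "patients,",
      x$config$network_type, "adjacency, beta =", x$config$beta, "\n")
  invisible(x)
}

#' Write a square network matrix as TSV
#'
#' @param x Square matrix with patient ids as dimnames.
#' @param path Output file path.
#' @export
write_network_matrix <- function(x, path) {
  df <- data.frame(patient_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
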