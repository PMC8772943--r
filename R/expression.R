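#' Construct a TPM expression matrix
#'
#' Features in rows, samples in columns; values are transcripts-per-million
#' (or any non-negative expression unit). No missing cells are allowed.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); finite, >= 0.
#' @return An `expression_matrix` (a classed numeric matrix).
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("feature and sample ids must be unique", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and >= 0", call. = FALSE)
  }
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' Read a TPM matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#'
#' @param path Path to the TSV.
#' @return An [expression_matrix()].
#' @export
read_tpm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  expression_matrix(m)
}

#' Write a TPM matrix to TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm <- function(m, path) {
  df <- data.frame(feature = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' All-pairs Pearson correlation screen between two expression matrices
#'
#' Computes Pearson's r between every feature of `a` and every feature of
#' `b` across their shared samples, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' A pair is flagged significant when `p < alpha` (default 0.01). Features
#' with zero variance have undefined r; their pairs are excluded and the
#' dropped feature ids reported in the `"zero_variance"` attribute. When the
#' two matrices are the same object, self-pairs are dropped. No
#' multiple-testing correction is applied by default; `adjust = "BH"` adds a
#' Benjamini-Hochberg `p_adj` column (significance then uses `p_adj`).
#'
#' @param a,b [expression_matrix()] objects with identical `sample_ids` in
#'   identical order (columns); at least 3 samples.
#' @param alpha Significance level on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param features_a,features_b Optional character vectors restricting the
#'   screen to a pre-selected feature subset (e.g. an externally supplied
#'   differential-expression list).
#' @return A data.frame `feature_a`, `feature_b`, `r`, `p` (and `p_adj` when
#'   adjusted), `n`, `significant`, ordered by feature index.
#' @export
correlation_screen <- function(a, b, alpha = 0.01, adjust = c("none", "BH"),
                               features_a = NULL, features_b = NULL) {
  adjust <- match.arg(adjust)
  same <- identical(unclass(a), unclass(b))
  if (!identical(colnames(a), colnames(b))) {
    stop("sample ids of the two matrices must be identical and in the same ",
         "order", call. = FALSE)
  }
  if (!is.null(features_a)) a <- a[rownames(a) %in% features_a, , drop = FALSE]
  if (!is.null(features_b)) b <- b[rownames(b) %in% features_b, , drop = FALSE]
  n <- ncol(a)
  if (n < 3L) stop("need at least 3 samples for the correlation screen",
                   call. = FALSE)
  sda <- apply(a, 1L, stats::sd)
  sdb <- apply(b, 1L, stats::sd)
  zv <- c(rownames(a)[sda == 0], rownames(b)[sdb == 0])
  a2 <- a[sda > 0, , drop = FALSE]
  b2 <- b[sdb > 0, , drop = FALSE]
  r <- stats::cor(t(a2), t(b2))
  pairs <- expand.grid(ia = seq_len(nrow(a2)), ib = seq_len(nrow(b2)))
  out <- data.frame(feature_a = rownames(a2)[pairs$ia],
                    feature_b = rownames(b2)[pairs$ib],
                    r = r[cbind(pairs$ia, pairs$ib)],
                    stringsAsFactors = FALSE)
  if (same) out <- out[out$feature_a != out$feature_b, , drop = FALSE]
  out$r <- pmin(1, pmax(-1, out$r))
  tt <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, 0))
  out$p <- 2 * stats::pt(-abs(tt), df = n - 2)
  out$p[abs(out$r) == 1] <- 0
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out$n <- rep(n, nrow(out))
  rownames(out) <- NULL
  attr(out, "zero_variance") <- unique(zv)
  out
}
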