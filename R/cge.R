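#' Chromosome genome expression (CGE) index
#'
#' Percent transcriptional variation between two or more conditions at one
#' locus, computed from the per-condition mean coverages X1..Xn:
#'
#'   CGE = 100 * (max(X) - min(X)) / (max(X) + min(X))
#'
#' The index is 0 when all conditions agree, 100 when a locus is transcribed
#' in some conditions and silent (mean 0) in at least one, and symmetric in
#' the conditions. An all-zero locus (max = 0) is defined to have CGE 0: an
#' untranscribed locus shows no variation. With
#' `denominator = "mean"` the alternative normalization
#' 100 * (max - min) / mean(X) is used instead (range 0..n*100/1 bounded by
#' 100*n for n groups; the default is bounded in \[0, 100\]).
#'
#' @param group_means Numeric vector (length >= 2) of non-negative, finite
#'   mean coverages, one per condition.
#' @param denominator `"extremes"` (default; max + min) or `"mean"`.
#' @return The CGE percent.
#' @examples
#' cge_index(c(10000, 10000)) # 0
#' cge_index(c(0, 5000))      # 100
#' cge_index(c(30000, 10000)) # 50
#' @export
cge_index <- function(group_means, denominator = c("extremes", "mean")) {
  denominator <- match.arg(denominator)
  if (length(group_means) < 2L) {
    stop("CGE needs at least 2 group means", call. = FALSE)
  }
  if (any(!is.finite(group_means)) || any(group_means < 0)) {
    stop("group means must be finite and >= 0", call. = FALSE)
  }
  mx <- max(group_means)
  if (mx == 0) return(0)
  mn <- min(group_means)
  den <- if (denominator == "extremes") mx + mn else mean(group_means)
  100 * (mx - mn) / den
}

#' Score regions with per-condition mean coverage and CGE
#'
#' For each region, computes the mean per-base depth of every condition
#' track over the region and the CGE index of those means.
#'
#' @param tracks Named list of [coverage_track()] objects (>= 2, unique
#'   labels) sharing one layout.
#' @param regions A [genomic_regions()] table.
#' @param denominator Passed to [cge_index()].
#' @param scale Optional named numeric vector of per-track scale factors
#'   (e.g. library-size normalizers); depths are multiplied by it before
#'   averaging. Default 1 for every track.
#' @return A `cge_records` data.frame in input region order: `chrom`,
#'   `start`, `end`, `label`, one `mean_<condition>` column per track, and
#'   `cge`. The condition labels are kept in the `"group_labels"` attribute.
#' @export
score_regions <- function(tracks, regions, denominator = "extremes",
                          scale = NULL) {
  labels <- names(tracks)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("tracks must be a named list with unique non-empty labels",
         call. = FALSE)
  }
  if (length(tracks) < 2L) stop("need >= 2 condition tracks", call. = FALSE)
  layout <- tracks[[1L]]$layout
  for (tr in tracks) {
    if (!identical(tr$layout$chrom, layout$chrom) ||
        !identical(tr$layout$length, layout$length)) {
      stop("all tracks must share one genome layout", call. = FALSE)
    }
  }
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(tracks)), labels)
  scale <- scale[labels]
  if (anyNA(scale)) stop("scale must name every track", call. = FALSE)
  n <- nrow(regions)
  means <- matrix(0, nrow = n, ncol = length(tracks),
                  dimnames = list(NULL, paste0("mean_", labels)))
  for (j in seq_along(tracks)) {
    d <- tracks[[j]]$depth
    for (i in seq_len(n)) {
      ch <- regions$chrom[i]
      if (!ch %in% layout$chrom) {
        stop("region chromosome not in layout: ", ch, call. = FALSE)
      }
      idx <- (regions$start[i] + 1L):regions$end[i]
      means[i, j] <- mean(d[[ch]][idx]) * scale[j]
    }
  }
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    label = if ("label" %in% names(regions)) regions$label
                            else NA_character_,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(means))
  out$cge <- apply(means, 1L, cge_index, denominator = denominator)
  if (n == 0L) out$cge <- numeric(0)
  attr(out, "group_labels") <- labels
  class(out) <- c("cge_records", "genomic_regions", "data.frame")
  out
}

cge_group_means <- function(records) {
  labels <- attr(records, "group_labels")
  cols <- paste0("mean_", labels)
  if (is.null(labels) || !all(cols %in% names(records))) {
    stop("not a cge_records table (missing group_labels/mean columns)",
         call. = FALSE)
  }
  as.matrix(records[, cols, drop = FALSE])
}

#' Summarize CGE records per chromosome
#'
#' Aggregates region-level CGE to one row per chromosome: the
#' region-length-weighted mean CGE (length weighting prevents many tiny
#' regions from dominating), the max CGE, and a rank (1 = highest mean CGE).
#' Chromosomes with no scored regions are reported with `n_regions = 0`,
#' `mean_cge = 0` and rank after all chromosomes that have regions; ties
#' break by layout order.
#'
#' @param records A `cge_records` table from [score_regions()].
#' @param layout The [genome_layout()]; defines the chromosome universe and
#'   tie-break order.
#' @return A data.frame `chrom`, `n_regions`, `mean_cge`, `max_cge`, `rank`,
#'   in layout order.
#' @export
chromosome_summary <- function(records, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  out <- data.frame(chrom = layout$chrom, n_regions = 0L, mean_cge = 0,
                    max_cge = 0, stringsAsFactors = FALSE)
  if (nrow(records) > 0L) {
    wlen <- records$end - records$start
    for (i in seq_len(nrow(out))) {
      j <- which(records$chrom == out$chrom[i])
      if (length(j)) {
        out$n_regions[i] <- length(j)
        out$mean_cge[i] <- sum(records$cge[j] * wlen[j]) / sum(wlen[j])
        out$max_cge[i] <- max(records$cge[j])
      }
    }
  }
  o <- order(-out$mean_cge, out$n_regions == 0L, seq_len(nrow(out)))
  out$rank <- integer(nrow(out))
  out$rank[o] <- seq_len(nrow(out))
  out
}

#' Classify mRNA-vs-miRNA opposition at overlapping loci
#'
#' Matches mRNA and miRNA CGE records by genomic overlap (>= 1 bp by
#' default, or a reciprocal-overlap fraction) and calls a locus *opposed*
#' when the between-condition coverage change of the two molecule classes
#' has opposite sign and both loci vary enough (both CGE >= `cge_cutoff`).
#' Only two-condition records are accepted; the change is
#' `mean_2 - mean_1` in the shared group-label order.
#'
#' @param mrna_records,mirna_records `cge_records` over the same two
#'   conditions with identical, identically ordered group labels.
#' @param cge_cutoff Minimum CGE (percent) both loci must reach (default 20).
#' @param min_reciprocal Minimum reciprocal overlap fraction; 0 (default)
#'   means any >= 1 bp overlap matches.
#' @return A data.frame with one row per overlapping (mRNA, miRNA) region
#'   pair: coordinates of both, `mrna_delta_sign`, `mirna_delta_sign`,
#'   `mrna_cge`, `mirna_cge`, `opposed`.
#' @export
opposition_classify <- function(mrna_records, mirna_records,
                                cge_cutoff = 20, min_reciprocal = 0) {
  la <- attr(mrna_records, "group_labels")
  lb <- attr(mirna_records, "group_labels")
  if (!identical(la, lb)) {
    stop("group labels differ between mRNA and miRNA records: [",
         paste(la, collapse = ", "), "] vs [", paste(lb, collapse = ", "),
         "]", call. = FALSE)
  }
  if (length(la) != 2L) {
    stop("opposition calls are defined for exactly 2 conditions",
         call. = FALSE)
  }
  ma <- cge_group_means(mrna_records)
  mb <- cge_group_means(mirna_records)
  rows <- list()
  for (i in seq_len(nrow(mrna_records))) {
    j <- which(mirna_records$chrom == mrna_records$chrom[i] &
                 mirna_records$start < mrna_records$end[i] &
                 mirna_records$end > mrna_records$start[i])
    for (k in j) {
      ov <- min(mrna_records$end[i], mirna_records$end[k]) -
        max(mrna_records$start[i], mirna_records$start[k])
      if (min_reciprocal > 0) {
        frac <- min(ov / (mrna_records$end[i] - mrna_records$start[i]),
                    ov / (mirna_records$end[k] - mirna_records$start[k]))
        if (frac < min_reciprocal) next
      }
      sa <- sign(ma[i, 2L] - ma[i, 1L])
      sb <- sign(mb[k, 2L] - mb[k, 1L])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = mrna_records$chrom[i],
        mrna_start = mrna_records$start[i], mrna_end = mrna_records$end[i],
        mirna_start = mirna_records$start[k],
        mirna_end = mirna_records$end[k],
        mrna_delta_sign = sa, mirna_delta_sign = sb,
        mrna_cge = mrna_records$cge[i], mirna_cge = mirna_records$cge[k],
        opposed = (sa * sb == -1) && mrna_records$cge[i] >= cge_cutoff &&
          mirna_records$cge[k] >= cge_cutoff,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), mrna_start = numeric(0),
                      mrna_end = numeric(0), mirna_start = numeric(0),
                      mirna_end = numeric(0), mrna_delta_sign = numeric(0),
                      mirna_delta_sign = numeric(0), mrna_cge = numeric(0),
                      mirna_cge = numeric(0), opposed = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
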