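#' Construct a dense per-base coverage track
#'
#' @param layout A [genome_layout()].
#' @param depth Named list of numeric vectors, one per chromosome in the
#'   layout, each of length equal to the chromosome length; all values must
#'   be finite and >= 0. Missing chromosomes are filled with zeros.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(layout, depth = list()) {
  stopifnot(inherits(layout, "genome_layout"), is.list(depth))
  full <- vector("list", nrow(layout))
  names(full) <- layout$chrom
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    L <- layout$length[i]
    d <- depth[[ch]]
    if (is.null(d)) d <- numeric(L)
    d <- as.numeric(d)
    if (length(d) != L) {
      stop("depth vector for ", ch, " has length ", length(d),
           " but chromosome length is ", L, call. = FALSE)
    }
    if (any(!is.finite(d)) || any(d < 0)) {
      stop("depth values for ", ch, " must be finite and >= 0", call. = FALSE)
    }
    full[[i]] <- d
  }
  structure(list(layout = layout, depth = full), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", nrow(x$layout), "chromosomes,",
      format(sum(x$layout$length), big.mark = ","), "bases\n")
  invisible(x)
}

#' Read a bedGraph file into a dense coverage track
#'
#' Records are 0-based half-open. Bases not covered by any record get depth
#' 0. Overlapping records are an error (silent summation would hide
#' malformed input). Records on chromosomes absent from the layout are
#' skipped with a warning reporting the count; records extending beyond a
#' chromosome end are an error.
#'
#' @param path Path to a bedGraph file.
#' @param layout A [genome_layout()].
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  known <- chrom %in% layout$chrom
  if (any(!known)) {
    warning(sum(!known), " bedGraph record(s) on unknown chromosome(s) ",
            "skipped: ", paste(unique(chrom[!known]), collapse = ", "),
            call. = FALSE)
    gr <- gr[known]
    chrom <- chrom[known]
  }
  # rtracklayer imports as 1-based closed; convert back to 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  value <- as.numeric(gr$score)
  track <- coverage_track(layout)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    L <- layout_length(layout, ch)
    if (any(end0[i] > L) || any(start0[i] < 0)) {
      stop("bedGraph record beyond bounds of ", ch, " (length ", L, ")",
           call. = FALSE)
    }
    o <- i[order(start0[i])]
    if (length(o) > 1L && any(start0[o][-1L] < end0[o][-length(o)])) {
      stop("overlapping bedGraph records on ", ch, call. = FALSE)
    }
    d <- track$depth[[ch]]
    for (j in o) {
      if (start0[j] < end0[j]) d[(start0[j] + 1L):end0[j]] <- value[j]
    }
    track$depth[[ch]] <- d
  }
  track
}

#' Write a coverage track as bedGraph
#'
#' Consecutive equal-depth bases are merged into one record (run-length
#' encoding); zero-depth runs are omitted, matching common practice.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param keep_zero Write zero-depth runs too (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in track$layout$chrom) {
    r <- rle(track$depth[[ch]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(start[keep]),
                         as.integer(end[keep]),
                         format(r$values[keep], trim = TRUE,
                                scientific = FALSE)), con)
    }
  }
  invisible(path)
}

#' Compute per-base depth from a SAM/BAM file
#'
#' Depth at a base is the number of retained reads whose aligned reference
#' span covers it: CIGAR M/=/X and D operations count as covered, N (intron)
#' gaps do not. Unmapped, secondary and supplementary alignments are always
#' excluded; reads with MAPQ below `min_mapq` are dropped.
#'
#' @param path SAM or BAM file. SAM input is converted in a temporary
#'   directory via [Rsamtools::asBam()].
#' @param layout A [genome_layout()]; chromosomes must be present in the
#'   alignment header with matching lengths.
#' @param min_mapq Minimum mapping quality (default 0, i.e. keep all mapped
#'   primary reads — the mapper's multi-mapping policy is not second-guessed).
#' @return A [coverage_track()].
#' @export
depth_from_alignments <- function(path, layout, min_mapq = 0) {
  stopifnot(inherits(layout, "genome_layout"))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    Rsamtools::indexBam(bam)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing <- setdiff(layout$chrom, names(hdr))
  mism <- layout$chrom[!layout$chrom %in% missing &
                         hdr[layout$chrom] != layout$length]
  if (length(missing) || length(mism)) {
    stop("alignment header does not match layout; missing: [",
         paste(missing, collapse = ", "), "]; length mismatch: [",
         paste(mism, collapse = ", "), "]", call. = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  keep <- as.character(GenomicAlignments::seqnames(gal)) %in% layout$chrom
  if (any(!keep)) {
    warning(sum(!keep), " alignment(s) on chromosomes outside the layout ",
            "skipped", call. = FALSE)
    gal <- gal[keep]
  }
  # coverage() covers M/=/X and (by default) D, and splits on N gaps
  cov <- GenomicAlignments::coverage(gal)
  depth <- list()
  for (ch in layout$chrom) {
    if (ch %in% names(cov)) {
      v <- as.numeric(cov[[ch]])
      L <- layout_length(layout, ch)
      depth[[ch]] <- c(v, numeric(max(0, L - length(v))))[seq_len(L)]
    }
  }
  coverage_track(layout, depth)
}
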