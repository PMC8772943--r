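#' Construct a genome layout
#'
#' A genome layout is the coordinate frame for every other object in the
#' package: an ordered set of chromosome names and lengths. Input order is
#' preserved exactly, because it drives the Circos karyotype order.
#'
#' @param chrom Character vector of unique, non-empty chromosome names.
#' @param length Integer-like vector of chromosome lengths in bases (> 0).
#' @return A `genome_layout`: a data.frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e5, 5e4))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have equal length", call. = FALSE)
  }
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chromosome names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    dup <- unique(chrom[duplicated(chrom)])
    stop("duplicate chromosome name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  len <- suppressWarnings(as.numeric(length))
  if (any(is.na(len)) || any(len <= 0) || any(len != floor(len))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  structure(
    data.frame(chrom = chrom, length = len, stringsAsFactors = FALSE),
    class = c("genome_layout", "data.frame")
  )
}

#' Read a chromosome sizes table
#'
#' Parses a two-column TSV (`name<TAB>length`), the standard `chrom.sizes`
#' format. Row order is preserved; duplicate names and non-positive lengths
#' are rejected.
#'
#' @param path Path to a chrom.sizes TSV.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- character(length(parts))
  len <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L || !nzchar(p[1L])) {
      stop("malformed chrom.sizes line ", i, ": '", lines[i], "'", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(p[2L]))
    if (is.na(v)) {
      stop("malformed chrom.sizes line ", i, ": length not numeric", call. = FALSE)
    }
    chrom[i] <- p[1L]
    len[i] <- v
  }
  genome_layout(chrom, len)
}

#' Write a chromosome sizes table
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  writeLines(sprintf("%s\t%d", layout$chrom, as.integer(layout$length)), path)
  invisible(path)
}

layout_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in layout: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  layout$length[i]
}

#' Construct a table of genomic regions
#'
#' Regions are 0-based half-open intervals (`start` inclusive, `end`
#' exclusive), matching BED/bedGraph conventions. If `layout` is supplied,
#' regions are checked against chromosome bounds.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive starts.
#' @param end Exclusive ends.
#' @param label Optional labels (recycled).
#' @param layout Optional [genome_layout()] for bounds validation.
#' @return A `genomic_regions` data.frame with columns
#'   `chrom`, `start`, `end`, `label`.
#' @export
genomic_regions <- function(chrom, start, end, label = NA_character_,
                            layout = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (any(!lengths(list(chrom, start, end)) %in% c(1L, n))) {
    stop("chrom, start and end must have equal length (or length 1)",
         call. = FALSE)
  }
  if (n > 0L) {
    chrom <- rep_len(chrom, n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  label <- rep_len(as.character(label), max(n, 1L))[seq_len(n)]
  if (n > 0 && (any(start < 0) || any(start >= end))) {
    stop("regions must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(layout) && n > 0) {
    L <- layout_length(layout, chrom)
    bad <- end > L
    if (any(bad)) {
      stop("region(s) beyond chromosome end: ",
           paste(sprintf("%s:%g-%g (len %g)", chrom[bad], start[bad],
                         end[bad], L[bad]), collapse = "; "),
           call. = FALSE)
    }
  }
  structure(
    data.frame(chrom = chrom, start = start, end = end, label = label,
               stringsAsFactors = FALSE),
    class = c("genomic_regions", "data.frame")
  )
}

#' Write regions to a BED file
#'
#' Standard BED, 0-based half-open. If the region table carries a
#' `mean_coverage` or `cge` column (threshold-scan or CGE output), its value
#' is written to the BED score column; otherwise score is 0. The name column
#' carries the region label when present.
#'
#' @param regions A `genomic_regions` data.frame (threshold-region and CGE
#'   record tables qualify).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("label" %in% names(regions) && !all(is.na(regions$label))) {
    ifelse(is.na(regions$label), ".", regions$label)
  } else rep(".", nrow(regions))
  score <- if ("mean_coverage" %in% names(regions)) {
    regions$mean_coverage
  } else if ("cge" %in% names(regions)) {
    regions$cge
  } else rep(0, nrow(regions))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", regions$chrom,
                     as.integer(regions$start), as.integer(regions$end),
                     name, format(score, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a BED file into a region table
#'
#' @param path Path to a BED file (>= 3 columns).
#' @param layout Optional [genome_layout()] for bounds validation.
#' @return A [genomic_regions()] table; a 5th BED column, when present, is
#'   returned as a `score` column.
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(genomic_regions(character(0), numeric(0), numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  if (ncol < 3L) stop("BED file needs at least 3 columns: ", path, call. = FALSE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  label <- if (ncol >= 4L) {
    nm <- vapply(parts, `[[`, "", 4L)
    ifelse(nm == ".", NA_character_, nm)
  } else NA_character_
  out <- genomic_regions(chrom, start, end, label, layout = layout)
  if (ncol >= 5L) out$score <- as.numeric(vapply(parts, `[[`, "", 5L))
  out
}
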