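#' Windowed mean coverage
#'
#' Tiles each chromosome with non-overlapping windows of `window_size` bases
#' and averages the per-base depth in each window. The trailing window may be
#' partial and is averaged over its actual length. Windows are tiling, not
#' sliding: each base contributes to exactly one window.
#'
#' @param track A [coverage_track()].
#' @param window_size Window width in bases (>= 1; default 10, the number of
#'   consecutive positions of the coverage graph averaged per window).
#' @return A named list of `windowed_track` objects, one per chromosome, each
#'   with fields `chrom`, `window_size`, `values`, `origin` (0) and
#'   `chrom_length`.
#' @export
windowed_mean <- function(track, window_size = 10) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      window_size < 1 || window_size != floor(window_size)) {
    stop("window_size must be a positive integer", call. = FALSE)
  }
  w <- as.integer(window_size)
  out <- list()
  for (i in seq_len(nrow(track$layout))) {
    ch <- track$layout$chrom[i]
    L <- track$layout$length[i]
    d <- track$depth[[ch]]
    nwin <- ceiling(L / w)
    cs <- c(0, cumsum(d))
    ends <- pmin(seq_len(nwin) * w, L)
    starts <- (seq_len(nwin) - 1L) * w
    vals <- (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
    out[[ch]] <- structure(
      list(chrom = ch, window_size = w, values = vals, origin = 0L,
           chrom_length = L),
      class = "windowed_track"
    )
  }
  out
}

window_base_lengths <- function(wtrack) {
  n <- length(wtrack$values)
  ends <- pmin(seq_len(n) * wtrack$window_size, wtrack$chrom_length)
  ends - (seq_len(n) - 1L) * wtrack$window_size
}

empty_threshold_regions <- function(low = NA_real_, high = NA_real_) {
  out <- genomic_regions(character(0), numeric(0), numeric(0))
  out$mean_coverage <- numeric(0)
  out$n_windows <- integer(0)
  out$low <- numeric(0)
  out$high <- numeric(0)
  class(out) <- c("threshold_regions", class(out))
  out
}

#' Detect threshold areas in a windowed coverage track
#'
#' A threshold area is a maximal run of consecutive windows whose mean
#' coverage lies inside the inclusive band `[low, high]`. Runs separated by
#' at most `merge_gap` out-of-band windows are merged into one region
#' spanning the gap; regions spanning fewer than `min_windows` windows are
#' dropped. `mean_coverage` is the base-weighted mean depth over the full
#' region span. One-sided scans are obtained with `low = 0` or `high = Inf`.
#'
#' @param wtrack A `windowed_track` from [windowed_mean()], or a list of them
#'   (results are row-bound in list order).
#' @param low,high Band bounds in the units of the input track
#'   (defaults 10000 and 90000, the read-coverage band used for scanning
#'   whole transcriptome tracks).
#' @param min_windows Minimum number of windows a region must span.
#' @param merge_gap Maximum number of consecutive out-of-band windows bridged
#'   when merging neighbouring runs.
#' @return A `threshold_regions` data.frame: `chrom`, `start`, `end`,
#'   `label`, `mean_coverage`, `n_windows`, `low`, `high`, sorted by start.
#' @export
threshold_areas <- function(wtrack, low = 10000, high = 90000,
                            min_windows = 1, merge_gap = 0) {
  if (is.list(wtrack) && !inherits(wtrack, "windowed_track")) {
    parts <- lapply(wtrack, threshold_areas, low = low, high = high,
                    min_windows = min_windows, merge_gap = merge_gap)
    out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    if (is.null(out)) out <- empty_threshold_regions(low, high)
    return(out)
  }
  stopifnot(inherits(wtrack, "windowed_track"))
  if (length(low) != 1L || length(high) != 1L || low > high) {
    stop("band bounds must be scalars with low <= high", call. = FALSE)
  }
  if (min_windows < 1) stop("min_windows must be >= 1", call. = FALSE)
  if (merge_gap < 0) stop("merge_gap must be >= 0", call. = FALSE)
  v <- wtrack$values
  inband <- v >= low & v <= high
  if (!any(inband)) return(empty_threshold_regions(low, high))
  r <- rle(inband)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ti <- which(r$values)
  # merge TRUE runs separated by FALSE runs of length <= merge_gap
  seg_first <- run_start[ti[1L]]
  firsts <- integer(0); lasts <- integer(0)
  last <- run_end[ti[1L]]
  for (k in ti[-1L]) {
    gap <- run_start[k] - last - 1L
    if (gap <= merge_gap) {
      last <- run_end[k]
    } else {
      firsts <- c(firsts, seg_first); lasts <- c(lasts, last)
      seg_first <- run_start[k]; last <- run_end[k]
    }
  }
  firsts <- c(firsts, seg_first); lasts <- c(lasts, last)
  span <- lasts - firsts + 1L
  keep <- span >= min_windows
  firsts <- firsts[keep]; lasts <- lasts[keep]; span <- span[keep]
  if (length(firsts) == 0L) return(empty_threshold_regions(low, high))
  w <- wtrack$window_size
  blen <- window_base_lengths(wtrack)
  start <- (firsts - 1L) * w
  end <- pmin(lasts * w, wtrack$chrom_length)
  meancov <- vapply(seq_along(firsts), function(j) {
    i <- firsts[j]:lasts[j]
    sum(v[i] * blen[i]) / sum(blen[i])
  }, numeric(1))
  out <- genomic_regions(rep(wtrack$chrom, length(firsts)), start, end)
  out$mean_coverage <- meancov
  out$n_windows <- span
  out$low <- low
  out$high <- high
  class(out) <- c("threshold_regions", class(out))
  out
}

#' Merge a region table into its interval union
#'
#' Overlapping or book-ended regions on the same chromosome are collapsed
#' into one. Used to pool threshold areas detected on several condition
#' tracks before CGE scoring.
#'
#' @param regions A [genomic_regions()] table.
#' @param layout Optional [genome_layout()] controlling chromosome output
#'   order (defaults to first-appearance order).
#' @return A [genomic_regions()] table of disjoint regions.
#' @export
merge_regions <- function(regions, layout = NULL) {
  chrom_order <- if (!is.null(layout)) layout$chrom else unique(regions$chrom)
  ch_all <- character(0); s_all <- numeric(0); e_all <- numeric(0)
  for (ch in chrom_order) {
    i <- which(regions$chrom == ch)
    if (!length(i)) next
    o <- i[order(regions$start[i], regions$end[i])]
    s <- regions$start[o]; e <- regions$end[o]
    cs <- s[1L]; ce <- e[1L]
    for (j in seq_along(o)[-1L]) {
      if (s[j] <= ce) ce <- max(ce, e[j]) else {
        ch_all <- c(ch_all, ch); s_all <- c(s_all, cs); e_all <- c(e_all, ce)
        cs <- s[j]; ce <- e[j]
      }
    }
    ch_all <- c(ch_all, ch); s_all <- c(s_all, cs); e_all <- c(e_all, ce)
  }
  genomic_regions(ch_all, s_all, e_all, layout = layout)
}

#' Scan several condition tracks and pool the detected regions
#'
#' Runs [windowed_mean()] and [threshold_areas()] on each condition track and
#' returns the interval union of all detected regions (a locus in band in any
#' condition is kept), plus the per-condition area tables.
#'
#' @param tracks Named list of [coverage_track()] objects sharing one layout.
#' @inheritParams threshold_areas
#' @inheritParams windowed_mean
#' @return A list with `regions` (pooled [genomic_regions()]) and
#'   `per_condition` (named list of `threshold_regions` tables).
#' @export
detect_threshold_regions <- function(tracks, window_size = 10, low = 10000,
                                     high = 90000, min_windows = 1,
                                     merge_gap = 0) {
  stopifnot(is.list(tracks), length(tracks) >= 1,
            !is.null(names(tracks)), all(nzchar(names(tracks))))
  layout <- tracks[[1L]]$layout
  per <- lapply(tracks, function(tr) {
    threshold_areas(windowed_mean(tr, window_size), low = low, high = high,
                    min_windows = min_windows, merge_gap = merge_gap)
  })
  pooled <- do.call(rbind, c(lapply(per, function(x) {
    x[, c("chrom", "start", "end", "label")]
  }), list(make.row.names = FALSE)))
  regions <- if (nrow(pooled) == 0L) {
    genomic_regions(character(0), numeric(0), numeric(0))
  } else merge_regions(pooled, layout)
  list(regions = regions, per_condition = per)
}
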