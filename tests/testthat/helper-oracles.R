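# Independent oracles and fixture builders. Everything here is deliberately
# naive (per-base loops, O(n^2) closures) and written against the contracts,
# not against the package internals.

random_layout <- function(n_chrom, min_len = 50, max_len = 200) {
  genome_layout(sprintf("chr%d", seq_len(n_chrom)),
                sample(min_len:max_len, n_chrom, replace = TRUE))
}

random_track <- function(layout, max_depth = 100) {
  depth <- lapply(layout$length, function(L) {
    sample(0:max_depth, L, replace = TRUE)
  })
  names(depth) <- layout$chrom
  coverage_track(layout, depth)
}

# brute-force per-base window means
oracle_window_means <- function(depth, w) {
  L <- length(depth)
  n <- ceiling(L / w)
  vapply(seq_len(n), function(i) {
    mean(depth[((i - 1) * w + 1):min(i * w, L)])
  }, numeric(1))
}

# O(n^2) threshold-area finder: link in-band windows at index distance
# <= merge_gap + 1, take connected components by transitive closure, then
# report each component's full span.
oracle_threshold_areas <- function(wtrack, low, high, min_windows = 1,
                                   merge_gap = 0) {
  v <- wtrack$values
  idx <- which(v >= low & v <= high)
  if (!length(idx)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      mean_coverage = numeric(0), n_windows = integer(0)))
  }
  comp <- seq_along(idx)
  repeat {
    changed <- FALSE
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (abs(idx[a] - idx[b]) <= merge_gap + 1 && comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  w <- wtrack$window_size
  L <- wtrack$chrom_length
  blen <- pmin(seq_along(v) * w, L) - (seq_along(v) - 1) * w
  rows <- lapply(unique(comp), function(cc) {
    wins <- idx[comp == cc]
    first <- min(wins); last <- max(wins)
    span <- first:last
    data.frame(start = (first - 1) * w, end = min(last * w, L),
               mean_coverage = sum(v[span] * blen[span]) / sum(blen[span]),
               n_windows = length(span))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_windows >= min_windows, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# textbook Pearson r and t-test p, coded from sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# spreadsheet-style ddCt recomputation
oracle_ddct <- function(tab, reference_gene, calibrator_group) {
  out <- tab[tab$gene != reference_gene, ]
  out$re <- NA_real_
  for (i in seq_len(nrow(out))) {
    ref_ct <- tab$ct[tab$sample == out$sample[i] &
                       tab$gene == reference_gene]
    dct <- out$ct[i] - ref_ct
    cal <- out[out$gene == out$gene[i] & out$group == calibrator_group, ]
    cal_dct <- vapply(seq_len(nrow(cal)), function(j) {
      cal$ct[j] - tab$ct[tab$sample == cal$sample[j] &
                           tab$gene == reference_gene]
    }, numeric(1))
    out$re[i] <- 2^(-(dct - mean(cal_dct)))
  }
  out
}

# --- SAM fixture machinery -------------------------------------------------

random_cigar <- function(max_ref_span) {
  # M runs interleaved with occasional I/D/N, optional soft clips
  ops <- character(0)
  ref_left <- max_ref_span
  m1 <- sample(5:min(20, ref_left), 1)
  ops <- c(ops, paste0(m1, "M")); ref_left <- ref_left - m1
  if (ref_left > 12 && runif(1) < 0.5) {
    mid <- sample(c("I", "D", "N"), 1)
    len <- sample(1:3, 1)
    if (mid != "I") ref_left <- ref_left - len
    m2 <- sample(5:min(10, ref_left), 1)
    ops <- c(ops, paste0(len, mid), paste0(m2, "M"))
  }
  if (runif(1) < 0.3) ops <- c(paste0(sample(1:4, 1), "S"), ops)
  if (runif(1) < 0.3) ops <- c(ops, paste0(sample(1:4, 1), "S"))
  paste(ops, collapse = "")
}

cigar_lengths <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", tok))
  op <- sub("^\\d+", "", tok)
  list(len = len, op = op)
}

cigar_ref_span <- function(cigar) {
  cl <- cigar_lengths(cigar)
  sum(cl$len[cl$op %in% c("M", "D", "N", "=", "X")])
}

cigar_read_len <- function(cigar) {
  cl <- cigar_lengths(cigar)
  sum(cl$len[cl$op %in% c("M", "I", "S", "=", "X")])
}

# Writes a SAM file of n reads (plus a few unmapped/secondary/supplementary
# records that must be ignored) and returns its path.
write_sam_fixture <- function(layout, n_reads, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                   as.integer(layout$length)))
  recs <- list()
  for (i in seq_len(n_reads)) {
    ci <- sample(nrow(layout), 1)
    ch <- layout$chrom[ci]; L <- layout$length[ci]
    pos <- sample(1:(L - 25), 1)
    cigar <- random_cigar(min(25, L - pos + 1))
    qlen <- cigar_read_len(cigar)
    mapq <- sample(0:60, 1)
    recs[[i]] <- sprintf("r%03d\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                         i, ch, pos, mapq, cigar,
                         paste(rep("A", qlen), collapse = ""))
  }
  # records that the depth computation must skip
  skip <- c(sprintf("u1\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*"),
            sprintf("s1\t256\t%s\t1\t60\t8M\t*\t0\t0\tAAAAAAAA\t*",
                    layout$chrom[1]),
            sprintf("p1\t2048\t%s\t1\t60\t8M\t*\t0\t0\tAAAAAAAA\t*",
                    layout$chrom[1]))
  body <- vapply(recs, identity, "")
  ord <- order(vapply(strsplit(body, "\t"), function(f) {
    match(f[3], layout$chrom) * 1e9 + as.integer(f[4])
  }, numeric(1)))
  writeLines(c(hdr, body[ord], skip), path)
  path
}

# per-base pileup recount straight from the SAM text
oracle_pileup <- function(sam_path, layout, min_mapq = 0) {
  depth <- lapply(layout$length, numeric)
  names(depth) <- layout$chrom
  for (line in readLines(sam_path)) {
    if (startsWith(line, "@")) next
    f <- strsplit(line, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0 || bitwAnd(flag, 256L) > 0 ||
        bitwAnd(flag, 2048L) > 0) next
    if (as.integer(f[5]) < min_mapq) next
    ch <- f[3]
    if (!ch %in% layout$chrom) next
    ref <- as.integer(f[4])  # 1-based
    cl <- cigar_lengths(f[6])
    for (k in seq_along(cl$op)) {
      if (cl$op[k] %in% c("M", "=", "X", "D")) {
        span <- ref:(ref + cl$len[k] - 1)
        depth[[ch]][span] <- depth[[ch]][span] + 1
        ref <- ref + cl$len[k]
      } else if (cl$op[k] == "N") {
        ref <- ref + cl$len[k]
      }
      # I, S, H, P consume no reference
    }
  }
  coverage_track(layout, depth)
}

random_fasta <- function(layout, path = tempfile(fileext = ".fa")) {
  seqs <- Biostrings::DNAStringSet(vapply(layout$length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, ""))
  names(seqs) <- layout$chrom
  Biostrings::writeXStringSet(seqs, path)
  path
}

# study-condition simulation used by recovery tests: ten 2 kb differential
# regions (rates 30x vs 90x) on a 5x background
recovery_truth <- function(seed, layout = genome_layout("chr1", 70000),
                           rates = c(gsc = 30, ss = 90), background = 5,
                           noise = "poisson") {
  specs <- lapply(0:9, function(i) {
    planted_region_spec("chr1", 4000 + i * 6000, 6000 + i * 6000, rates,
                        "mrna")
  })
  simulation_truth(layout, background_rate = background, specs = specs,
                   noise_model = noise, seed = seed)
}

jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / (max(e1, e2) - min(s1, s2))
}
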