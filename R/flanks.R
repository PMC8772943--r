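#' Extract flanking sequence around regions from a genome FASTA
#'
#' For each region, returns the sequence of
#' `[max(0, start - flank_bp), min(L, end + flank_bp))` where `L` is the
#' chromosome length. Clipping at a chromosome bound is silent but flagged
#' in the returned `clipped` column. Record ids carry the realized 0-based
#' half-open coordinates as `chrom:start-end` (1-based inclusive if
#' `one_based_ids = TRUE`).
#'
#' @param fasta Path to the genome FASTA (read whole; intended for
#'   chromosome-level assemblies that fit in memory, and for test genomes).
#' @param regions A [genomic_regions()] table.
#' @param flank_bp Flank width in bases on each side (default 10000, the
#'   10 kb window used around coverage threshold areas).
#' @param one_based_ids Format ids 1-based inclusive instead of 0-based
#'   half-open.
#' @return A data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `clipped`, `seq`.
#' @export
extract_flanks <- function(fasta, regions, flank_bp = 10000,
                           one_based_ids = FALSE) {
  stopifnot(flank_bp >= 0)
  genome <- Biostrings::readDNAStringSet(fasta)
  # FASTA headers may carry descriptions after the first whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  n <- nrow(regions)
  out <- data.frame(id = character(n), chrom = regions$chrom,
                    start = numeric(n), end = numeric(n),
                    clipped = logical(n), seq = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ch <- regions$chrom[i]
    if (!ch %in% names(genome)) {
      stop("chromosome ", ch, " not present in FASTA ", fasta, call. = FALSE)
    }
    L <- Biostrings::width(genome[ch])
    if (regions$end[i] > L) {
      stop("region ", ch, ":", regions$start[i], "-", regions$end[i],
           " beyond FASTA sequence length ", L, call. = FALSE)
    }
    s <- regions$start[i] - flank_bp
    e <- regions$end[i] + flank_bp
    clipped <- s < 0 || e > L
    s <- max(0, s)
    e <- min(L, e)
    out$start[i] <- s
    out$end[i] <- e
    out$clipped[i] <- clipped
    out$id[i] <- if (one_based_ids) {
      sprintf("%s:%d-%d", ch, as.integer(s) + 1L, as.integer(e))
    } else {
      sprintf("%s:%d-%d", ch, as.integer(s), as.integer(e))
    }
    out$seq[i] <- as.character(Biostrings::subseq(genome[[ch]], s + 1L, e))
  }
  out
}

#' Write extracted flank records to FASTA
#'
#' @param flanks Output of [extract_flanks()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flanks_fasta <- function(flanks, path) {
  seqs <- Biostrings::DNAStringSet(flanks$seq)
  names(seqs) <- ifelse(flanks$clipped, paste0(flanks$id, " clipped"),
                        flanks$id)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
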