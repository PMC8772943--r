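# Fixed palettes so every Circos file is byte-identical across runs.
.karyotype_palette <- sprintf("chr%d", 1:24)
.link_palette <- c("red", "green", "blue", "orange", "purple", "dgrey")

#' Write a Circos karyotype file
#'
#' One `chr - <id> <label> 0 <length> <color>` line per chromosome, in
#' layout order; colors cycle the standard Circos `chrN` palette
#' deterministically.
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- nrow(layout)
  col <- .karyotype_palette[((seq_len(n) - 1L) %% length(.karyotype_palette)) + 1L]
  writeLines(sprintf("chr - %s %s 0 %d %s", layout$chrom, layout$chrom,
                     as.integer(layout$length), col)[seq_len(n)], path)
  invisible(path)
}

#' Write a CGE heatmap data track for Circos
#'
#' `chrom start end value` lines where the value is the raw CGE percent of
#' each scored region, sorted by chromosome (layout order when given) and
#' start. Color binning is left to the Circos configuration.
#'
#' @param records A `cge_records` table from [score_regions()].
#' @param path Output path.
#' @param layout Optional [genome_layout()] controlling chromosome sort
#'   order (defaults to alphabetical).
#' @return `path`, invisibly.
#' @export
write_heatmap_track <- function(records, path, layout = NULL) {
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom_levels <- if (is.null(layout)) sort(unique(records$chrom))
                  else layout$chrom
  o <- order(match(records$chrom, chrom_levels), records$start)
  writeLines(sprintf("%s %d %d %s", records$chrom[o],
                     as.integer(records$start[o]),
                     as.integer(records$end[o]),
                     format(records$cge[o], trim = TRUE,
                            scientific = FALSE)), path)
  invisible(path)
}

#' Write a windowed-coverage line track for Circos
#'
#' One `chrom start end value` line per window, giving the black coverage
#' line graph drawn alongside the CGE heatmap.
#'
#' @param wtracks A list of `windowed_track` objects from [windowed_mean()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_line_track <- function(wtracks, path) {
  if (inherits(wtracks, "windowed_track")) wtracks <- list(wtracks)
  con <- file(path, "w")
  on.exit(close(con))
  for (wt in wtracks) {
    n <- length(wt$values)
    if (!n) next
    start <- (seq_len(n) - 1L) * wt$window_size
    end <- pmin(seq_len(n) * wt$window_size, wt$chrom_length)
    writeLines(sprintf("%s %d %d %s", wt$chrom, as.integer(start),
                       as.integer(end),
                       format(wt$values, trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Construct a homeology link table
#'
#' @param region_a,region_b [genomic_regions()] tables of equal row count;
#'   row i of each forms one link (e.g. a homeologous region pair from a
#'   salmonid duplication map).
#' @param class_label Optional character vector of ribbon color groups.
#' @return A `homeology_links` data.frame.
#' @export
homeology_links <- function(region_a, region_b, class_label = NA_character_) {
  stopifnot(nrow(region_a) == nrow(region_b))
  same <- region_a$chrom == region_b$chrom &
    region_a$start == region_b$start & region_a$end == region_b$end
  if (any(same)) stop("link endpoints must differ", call. = FALSE)
  structure(
    data.frame(chrom_a = region_a$chrom, start_a = region_a$start,
               end_a = region_a$end, chrom_b = region_b$chrom,
               start_b = region_b$start, end_b = region_b$end,
               class_label = rep_len(as.character(class_label),
                                     nrow(region_a)),
               stringsAsFactors = FALSE),
    class = c("homeology_links", "data.frame"))
}

#' Read a homeology link table from TSV
#'
#' Expects columns `chrom_a start_a end_a chrom_b start_b end_b` and an
#' optional 7th `class_label` column (header optional; detected).
#'
#' @param path Path to the TSV.
#' @param layout Optional [genome_layout()] for bounds validation.
#' @return A [homeology_links()] table.
#' @export
read_links <- function(path, layout = NULL) {
  first <- readLines(path, n = 1L)
  header <- grepl("chrom_a", first, fixed = TRUE)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) {
    names(df)[1:6] <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                        "end_b")
    if (ncol(df) >= 7L) names(df)[7L] <- "class_label"
  }
  a <- genomic_regions(df$chrom_a, df$start_a, df$end_a, layout = layout)
  b <- genomic_regions(df$chrom_b, df$start_b, df$end_b, layout = layout)
  homeology_links(a, b, if ("class_label" %in% names(df)) df$class_label
                        else NA_character_)
}

#' Write Circos ribbon links restricted to selected chromosomes
#'
#' Emits the two-endpoint single-line link dialect
#' (`chromA startA endA chromB startB endB [options]`). Only links with
#' **both** endpoints on kept chromosomes are written. Class labels map to a
#' deterministic `color=` option (labels sorted, fixed palette).
#'
#' @param links A [homeology_links()] table.
#' @param keep_chroms Character vector of chromosome names to keep; `NULL`
#'   keeps all.
#' @param path Output path.
#' @return `path`, invisibly; the number of written links as attribute `n`.
#' @export
write_links <- function(links, keep_chroms = NULL, path) {
  keep <- if (is.null(keep_chroms)) rep(TRUE, nrow(links)) else {
    links$chrom_a %in% keep_chroms & links$chrom_b %in% keep_chroms
  }
  lk <- links[keep, , drop = FALSE]
  opt <- rep("", nrow(lk))
  if (nrow(lk) && !all(is.na(lk$class_label))) {
    labels <- sort(unique(lk$class_label[!is.na(lk$class_label)]))
    col <- stats::setNames(
      .link_palette[((seq_along(labels) - 1L) %% length(.link_palette)) + 1L],
      labels)
    opt <- ifelse(is.na(lk$class_label), "",
                  paste0(" color=", col[lk$class_label]))
  }
  writeLines(sprintf("%s %d %d %s %d %d%s", lk$chrom_a,
                     as.integer(lk$start_a), as.integer(lk$end_a),
                     lk$chrom_b, as.integer(lk$start_b),
                     as.integer(lk$end_b), opt)[seq_len(nrow(lk))], path)
  out <- invisible(path)
  attr(out, "n") <- nrow(lk)
  out
}

#' Write a commented Circos configuration template
#'
#' A starting-point `circos.conf` wiring the karyotype, CGE heatmap, coverage
#' line and ribbon link files this package emits. Users edit colors/radii and
#' run the Circos renderer themselves.
#'
#' @param path Output path.
#' @param karyotype,heatmap,line,links File names referenced by the template.
#' @return `path`, invisibly.
#' @export
write_circos_conf <- function(path, karyotype = "karyotype.txt",
                              heatmap = "cge_heatmap.txt",
                              line = "coverage_line.txt",
                              links = "links.txt") {
  writeLines(c(
    "# Circos configuration template (edit radii/colors, then run circos)",
    sprintf("karyotype = %s", karyotype),
    "<ideogram>",
    "  <spacing> default = 0.005r </spacing>",
    "  radius = 0.90r",
    "  thickness = 20p",
    "  fill = yes",
    "  show_label = yes",
    "  label_radius = 1.05r",
    "  label_size = 30",
    "</ideogram>",
    "<plots>",
    "  # CGE percent heatmap (0-100), red scale",
    "  <plot>",
    "    type = heatmap",
    sprintf("    file = %s", heatmap),
    "    r0 = 0.85r",
    "    r1 = 0.95r",
    "    color = reds-9-seq",
    "    min = 0",
    "    max = 100",
    "  </plot>",
    "  # windowed coverage line graph",
    "  <plot>",
    "    type = line",
    sprintf("    file = %s", line),
    "    r0 = 0.70r",
    "    r1 = 0.84r",
    "    color = black",
    "  </plot>",
    "</plots>",
    "<links>",
    "  <link>",
    sprintf("    file = %s", links),
    "    radius = 0.68r",
    "    ribbon = yes",
    "    bezier_radius = 0r",
    "  </link>",
    "</links>",
    "<image> <<include etc/image.conf>> </image>",
    "<<include etc/colors_fonts_patterns.conf>>",
    "<<include etc/housekeeping.conf>>"
  ), path)
  invisible(path)
}
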