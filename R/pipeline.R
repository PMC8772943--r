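#' Default run configuration
#'
#' The shipped defaults are the published workflow parameters: scan window
#' of 10 positions, coverage band 10,000-90,000 reads, 10 kb flank window,
#' CGE opposition cutoff 20 percent, correlation alpha 0.01.
#'
#' @return A named list of default parameter values.
#' @export
default_run_config <- function() {
  list(window_size = 10, low = 10000, high = 90000, min_windows = 1,
       merge_gap = 0, flank_bp = 10000, cge_cutoff = 20, alpha = 0.01,
       denominator = "extremes", seed = 1)
}

#' Read and validate a pipeline run configuration
#'
#' YAML key-value file; any parameter not given takes its
#' [default_run_config()] value. Required keys: `chrom_sizes`, `coverage`
#' (a mapping `molecule_class -> condition -> bedGraph path`, classes
#' `mrna` and/or `mirna`) and `outdir`. Optional: `fasta` (enables flank
#' extraction), `links` + `keep_chroms` (enables ribbon export), and any
#' default parameter. Every referenced file must exist at validation time.
#'
#' @param path Path to the YAML config.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  defaults <- default_run_config()
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("chrom_sizes", "coverage", "outdir")) {
    if (is.null(cfg[[k]])) stop("config key missing: ", k, call. = FALSE)
  }
  bad_cls <- setdiff(names(cfg$coverage), c("mrna", "mirna"))
  if (length(bad_cls)) {
    stop("unknown molecule class(es) in coverage config: ",
         paste(bad_cls, collapse = ", "), call. = FALSE)
  }
  files <- c(cfg$chrom_sizes, unlist(cfg$coverage, use.names = FALSE),
             cfg$fasta, cfg$links)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$low > cfg$high) stop("config: low > high", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write CGE records to TSV
#'
#' @param records A `cge_records` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cge_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read CGE records from TSV
#'
#' Group labels are recovered from the `mean_<label>` columns in order.
#'
#' @param path Path to a TSV written by [write_cge_records()].
#' @return A `cge_records` table.
#' @export
read_cge_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mc <- grep("^mean_", names(df), value = TRUE)
  if (!length(mc) || !all(c("chrom", "start", "end", "cge") %in% names(df))) {
    stop("not a CGE record table: ", path, call. = FALSE)
  }
  attr(df, "group_labels") <- sub("^mean_", "", mc)
  class(df) <- c("cge_records", "genomic_regions", "data.frame")
  df
}

run_stage <- function(name, quiet, code) {
  t0 <- Sys.time()
  if (!quiet) message("[cgescan] stage '", name, "' ...")
  out <- tryCatch(force(code), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[cgescan] stage '%s' done (%.2fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run the full scan -> score -> summarize -> oppose -> flanks -> Circos
#' pipeline
#'
#' Executes every analysis stage from one validated configuration and writes
#' all outputs under `cfg$outdir`: pooled threshold areas (BED) and CGE
#' record tables (TSV) per molecule class, chromosome summaries, opposition
#' calls when both classes are configured, flank FASTA when a genome is
#' given, Circos karyotype/heatmap/line/link files, and a `manifest.json`
#' listing every output with its md5 hash. Reruns on identical inputs
#' reproduce identical hashes.
#'
#' @param cfg A `run_config` (from [read_run_config()] /
#'   [validate_run_config()]) or a path to a YAML config.
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly: a data.frame `file`, `md5`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  circos_dir <- file.path(cfg$outdir, "circos")
  dir.create(circos_dir, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  layout <- run_stage("load", quiet, read_chrom_sizes(cfg$chrom_sizes))
  tracks <- run_stage("load", quiet, {
    lapply(cfg$coverage, function(by_cond) {
      lapply(by_cond, read_bedgraph, layout = layout)
    })
  })

  records <- list()
  wtracks <- list()
  for (cls in names(tracks)) {
    scan <- run_stage(paste0("scan_", cls), quiet, {
      detect_threshold_regions(tracks[[cls]], window_size = cfg$window_size,
                               low = cfg$low, high = cfg$high,
                               min_windows = cfg$min_windows,
                               merge_gap = cfg$merge_gap)
    })
    write_bed(scan$regions,
              emit(file.path(cfg$outdir, paste0("areas_", cls, ".bed"))))
    wtracks[[cls]] <- windowed_mean(tracks[[cls]][[1L]], cfg$window_size)
    records[[cls]] <- run_stage(paste0("score_", cls), quiet, {
      score_regions(tracks[[cls]], scan$regions,
                    denominator = cfg$denominator)
    })
    write_cge_records(records[[cls]],
                      emit(file.path(cfg$outdir,
                                     paste0("cge_", cls, ".tsv"))))
    summ <- run_stage(paste0("summary_", cls), quiet,
                      chromosome_summary(records[[cls]], layout))
    utils::write.table(summ,
                       emit(file.path(cfg$outdir,
                                      paste0("chrom_summary_", cls,
                                             ".tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (all(c("mrna", "mirna") %in% names(records))) {
    calls <- run_stage("oppose", quiet, {
      opposition_classify(records$mrna, records$mirna,
                          cge_cutoff = cfg$cge_cutoff)
    })
    utils::write.table(calls,
                       emit(file.path(cfg$outdir, "opposition.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$fasta)) {
    for (cls in names(records)) {
      fl <- run_stage(paste0("flanks_", cls), quiet, {
        extract_flanks(cfg$fasta, records[[cls]], flank_bp = cfg$flank_bp)
      })
      write_flanks_fasta(fl, emit(file.path(cfg$outdir,
                                            paste0("flanks_", cls, ".fa"))))
    }
  }

  run_stage("circos", quiet, {
    write_karyotype(layout, emit(file.path(circos_dir, "karyotype.txt")))
    for (cls in names(records)) {
      write_heatmap_track(records[[cls]],
                          emit(file.path(circos_dir,
                                         paste0("cge_heatmap_", cls,
                                                ".txt"))),
                          layout = layout)
      write_line_track(wtracks[[cls]],
                       emit(file.path(circos_dir,
                                      paste0("coverage_line_", cls,
                                             ".txt"))))
    }
    if (!is.null(cfg$links)) {
      links <- read_links(cfg$links, layout = layout)
      write_links(links, cfg$keep_chroms,
                  emit(file.path(circos_dir, "links.txt")))
    }
    write_circos_conf(emit(file.path(circos_dir, "circos.conf")))
  })

  manifest <- data.frame(file = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
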