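#' Specify a planted differential region for simulation
#'
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param rates Named numeric vector of per-condition mean depths (lambda),
#'   one per simulated condition; names are the condition labels.
#' @param molecule_class `"mrna"` or `"mirna"`.
#' @return A `planted_region_spec` list. Its expected CGE under the default
#'   index is `100 * (max(rates) - min(rates)) / (max(rates) + min(rates))`.
#' @export
planted_region_spec <- function(chrom, start, end, rates,
                                molecule_class = c("mrna", "mirna")) {
  molecule_class <- match.arg(molecule_class)
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be a named vector (condition labels)", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  if (start < 0 || start >= end) {
    stop("planted region must satisfy 0 <= start < end", call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end, rates = rates,
                 molecule_class = molecule_class),
            class = "planted_region_spec")
}

#' Expected CGE of a planted region
#'
#' Closed-form value the scored CGE should converge to as the region grows:
#' `100 * (max - min) / (max + min)` over the planted rates (0 when all
#' rates are 0).
#'
#' @param spec A [planted_region_spec()] (or a bare rates vector).
#' @return The analytic CGE percent.
#' @export
expected_cge <- function(spec) {
  rates <- if (inherits(spec, "planted_region_spec")) spec$rates else spec
  if (max(rates) == 0) return(0)
  100 * (max(rates) - min(rates)) / (max(rates) + min(rates))
}

#' Assemble a coverage-simulation truth object
#'
#' @param layout A [genome_layout()].
#' @param background_rate Mean depth lambda0 outside planted regions.
#' @param specs List of [planted_region_spec()]; regions must be pairwise
#'   disjoint within each molecule class and share one set of condition
#'   labels.
#' @param noise_model `"poisson"` (default), `"negative_binomial"`
#'   (overdispersed; see `dispersion`), or `"none"` (deterministic: depth
#'   equals the rate exactly — the noise-free limit used for exact
#'   ground-truth checks).
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersion); used only by the `negative_binomial` model.
#' @param seed Integer seed recorded in the truth and used by
#'   [simulate_coverage()].
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(layout, background_rate = 5, specs = list(),
                             noise_model = c("poisson", "negative_binomial",
                                             "none"),
                             dispersion = 10, seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(layout, "genome_layout"), background_rate >= 0)
  labels <- NULL
  for (sp in specs) {
    stopifnot(inherits(sp, "planted_region_spec"))
    if (!sp$chrom %in% layout$chrom) {
      stop("planted region on unknown chromosome ", sp$chrom, call. = FALSE)
    }
    if (sp$end > layout_length(layout, sp$chrom)) {
      stop("planted region beyond chromosome end: ", sp$chrom, call. = FALSE)
    }
    if (is.null(labels)) labels <- names(sp$rates)
    if (!identical(names(sp$rates), labels)) {
      stop("all planted regions must use the same condition labels",
           call. = FALSE)
    }
  }
  for (cls in c("mrna", "mirna")) {
    sub <- Filter(function(s) s$molecule_class == cls, specs)
    if (length(sub) > 1L) {
      df <- data.frame(chrom = vapply(sub, `[[`, "", "chrom"),
                       start = vapply(sub, `[[`, 0, "start"),
                       end = vapply(sub, `[[`, 0, "end"))
      for (ch in unique(df$chrom)) {
        d <- df[df$chrom == ch, ]
        d <- d[order(d$start), ]
        if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
          stop("overlapping planted ", cls, " regions on ", ch,
               call. = FALSE)
        }
      }
    }
  }
  structure(list(layout = layout, background_rate = background_rate,
                 specs = specs, noise_model = noise_model,
                 dispersion = dispersion, seed = seed,
                 condition_labels = labels),
            class = "simulation_truth")
}

sim_draw <- function(n, rate, noise_model, dispersion) {
  switch(noise_model,
         poisson = stats::rpois(n, rate),
         negative_binomial = stats::rnbinom(n, size = dispersion, mu = rate),
         none = rep(rate, n))
}

#' Simulate multi-condition coverage tracks with planted differential regions
#'
#' Per-base depth is drawn independently from the truth's noise model with
#' rate `background_rate` outside planted regions and the planted
#' per-condition rate inside; one track per condition and molecule class.
#' Fully reproducible from the recorded seed.
#'
#' @param truth A [simulation_truth()].
#' @return A list with one element per molecule class present (plus both
#'   classes when no specs exist), each a named list of [coverage_track()]
#'   objects keyed by condition label, and the `truth` object itself.
#' @export
simulate_coverage <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  labels <- truth$condition_labels
  if (is.null(labels)) labels <- c("cond1", "cond2")
  classes <- unique(vapply(truth$specs, `[[`, "", "molecule_class"))
  if (!length(classes)) classes <- "mrna"
  out <- list(truth = truth)
  with_local_seed(truth$seed, {
    for (cls in classes) {
      tracks <- list()
      for (lab in labels) {
        depth <- list()
        for (i in seq_len(nrow(truth$layout))) {
          ch <- truth$layout$chrom[i]
          L <- truth$layout$length[i]
          d <- sim_draw(L, truth$background_rate, truth$noise_model,
                        truth$dispersion)
          for (sp in truth$specs) {
            if (sp$molecule_class == cls && sp$chrom == ch) {
              n <- sp$end - sp$start
              d[(sp$start + 1L):sp$end] <-
                sim_draw(n, sp$rates[[lab]], truth$noise_model,
                         truth$dispersion)
            }
          }
          depth[[ch]] <- d
        }
        tracks[[lab]] <- coverage_track(truth$layout, depth)
      }
      out[[cls]] <- tracks
    }
  })
  out
}

#' Simulate paired gene/miRNA TPM matrices with planted correlations
#'
#' Non-planted features are independent log-normal TPM-like positives.
#' Each planted (gene, miRNA) pair is drawn from a bivariate Gaussian on the
#' log scale with the requested correlation, then exponentiated, so the
#' *population* log-scale Pearson correlation equals `true_r` exactly.
#'
#' @param n_genes,n_mirnas Feature counts of the two matrices.
#' @param n_samples Number of shared samples (>= 4).
#' @param planted_pairs Data.frame with columns `gene` (index into genes),
#'   `mirna` (index into miRNAs) and `true_r` in \[-1, 1\]; a feature may be
#'   planted at most once. May be empty.
#' @param seed Integer seed.
#' @param log_mean,log_sd Mean and sd of the log-scale expression values.
#'   The planted correlation lives on the log scale; exponentiation
#'   attenuates it on the TPM scale by the lognormal factor
#'   `(exp(r * sd^2) - 1) / (exp(sd^2) - 1)`, so the default `log_sd = 0.1`
#'   keeps the attenuation below 1 percent and the planted coefficient
#'   carries through to Pearson correlation of the TPM values themselves.
#' @return A list: `genes` and `mirnas` ([expression_matrix()] objects) and
#'   `truth` (the planted pairs with feature ids resolved, plus the seed).
#' @export
simulate_expression <- function(n_genes, n_mirnas, n_samples,
                                planted_pairs = NULL, seed = 1,
                                log_mean = 3, log_sd = 0.1) {
  if (n_samples < 4L) stop("need n_samples >= 4", call. = FALSE)
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(gene = integer(0), mirna = integer(0),
                                true_r = numeric(0))
  }
  if (nrow(planted_pairs)) {
    if (any(abs(planted_pairs$true_r) > 1)) {
      stop("|true_r| must be <= 1", call. = FALSE)
    }
    if (anyDuplicated(planted_pairs$gene) ||
        anyDuplicated(planted_pairs$mirna)) {
      stop("a feature may be planted in at most one pair", call. = FALSE)
    }
    stopifnot(all(planted_pairs$gene >= 1 & planted_pairs$gene <= n_genes),
              all(planted_pairs$mirna >= 1 &
                    planted_pairs$mirna <= n_mirnas))
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  mirna_ids <- sprintf("mir%04d", seq_len(n_mirnas))
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  with_local_seed(seed, {
    lg <- matrix(stats::rnorm(n_genes * n_samples, log_mean, log_sd),
                 n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
    lm <- matrix(stats::rnorm(n_mirnas * n_samples, log_mean, log_sd),
                 n_mirnas, n_samples, dimnames = list(mirna_ids, sample_ids))
    for (i in seq_len(nrow(planted_pairs))) {
      r <- planted_pairs$true_r[i]
      z1 <- stats::rnorm(n_samples)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_samples)
      lg[planted_pairs$gene[i], ] <- log_mean + log_sd * z1
      lm[planted_pairs$mirna[i], ] <- log_mean + log_sd * z2
    }
    genes <- expression_matrix(exp(lg))
    mirnas <- expression_matrix(exp(lm))
  })
  truth <- planted_pairs
  if (nrow(truth)) {
    truth$gene_id <- gene_ids[truth$gene]
    truth$mirna_id <- mirna_ids[truth$mirna]
  } else {
    truth$gene_id <- character(0)
    truth$mirna_id <- character(0)
  }
  list(genes = genes, mirnas = mirnas,
       truth = list(pairs = truth, seed = seed))
}
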