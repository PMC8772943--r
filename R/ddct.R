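#' Read a qPCR Ct table
#'
#' CSV with columns `sample`, `group`, `gene`, `ct` (threshold cycles).
#' Each (sample, gene) pair may appear once.
#'
#' @param path Path to the CSV.
#' @return A validated data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_ct_table(df[, need])
}

validate_ct_table <- function(df) {
  if (anyDuplicated(df[, c("sample", "gene")])) {
    stop("each (sample, gene) pair may appear only once in the Ct table",
         call. = FALSE)
  }
  if (any(!is.finite(df$ct))) stop("Ct values must be finite", call. = FALSE)
  df
}

#' Comparative ddCt relative quantification
#'
#' Standard two-step comparative Ct method: per sample,
#' `dCt = Ct_gene - Ct_reference`; per gene,
#' `ddCt = dCt - mean(dCt over calibrator-group samples)`; relative
#' expression is `2^(-ddCt)`. The reference (housekeeping) gene must be
#' measured in every sample; the calibrator group supplies the baseline
#' (e.g. the freshwater control group, against an EF-alpha-style reference
#' gene).
#'
#' @param table A Ct data.frame with columns `sample`, `group`, `gene`,
#'   `ct` (see [read_ct_table()]).
#' @param reference_gene Name of the housekeeping gene.
#' @param calibrator_group Name of the baseline group.
#' @return A data.frame `sample`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `relative_expression`, one row per non-reference
#'   (sample, gene) measurement.
#' @export
ddct <- function(table, reference_gene, calibrator_group) {
  table <- validate_ct_table(table)
  if (!reference_gene %in% table$gene) {
    stop("reference gene '", reference_gene, "' not in table", call. = FALSE)
  }
  if (!calibrator_group %in% table$group) {
    stop("calibrator group '", calibrator_group, "' not in table",
         call. = FALSE)
  }
  ref <- table[table$gene == reference_gene, ]
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  tg <- table[table$gene != reference_gene, ]
  missing_ref <- setdiff(unique(tg$sample), names(ref_ct))
  if (length(missing_ref)) {
    stop("reference gene measurement missing for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  tg$delta_ct <- tg$ct - ref_ct[tg$sample]
  tg$delta_delta_ct <- NA_real_
  for (g in unique(tg$gene)) {
    i <- which(tg$gene == g)
    cal <- i[tg$group[i] == calibrator_group]
    if (!length(cal)) {
      stop("no calibrator-group measurement for gene ", g, call. = FALSE)
    }
    tg$delta_delta_ct[i] <- tg$delta_ct[i] - mean(tg$delta_ct[cal])
  }
  tg$relative_expression <- 2^(-tg$delta_delta_ct)
  out <- tg[, c("sample", "group", "gene", "delta_ct", "delta_delta_ct",
                "relative_expression")]
  rownames(out) <- NULL
  out
}
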