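#' Relative quantity from a Cq pair
#'
#' Delta-Cq relative quantification of a target transcript against a
#' reference transcript measured in the same sample:
#' `efficiency^(cq_reference - cq_target)`. With perfect doubling
#' (`efficiency = 2`) a target three cycles later than the reference is
#' at 1/8 the reference level. Vectorised.
#'
#' @param cq_target,cq_reference Quantification cycles (finite numerics).
#' @param efficiency Amplification factor per cycle, in `(1, 2.2]`;
#'   default 2 (perfect doubling).
#' @return Dimensionless relative quantity.
#' @export
relative_quantity <- function(cq_target, cq_reference, efficiency = 2) {
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference))) {
    stop("Cq values must be finite", call. = FALSE)
  }
  if (!is.finite(efficiency) || efficiency <= 1 || efficiency > 2.2) {
    stop("efficiency must be in (1, 2.2]", call. = FALSE)
  }
  efficiency^(cq_reference - cq_target)
}

#' Percent repression of a replicate group
#'
#' The percent-repression statistic for CRISPRi knockdown data. Relative
#' mRNA levels (already normalized to a reference transcript) are first
#' divided by the mean level of the nonsense-control group; the
#' reciprocal of each rescaled level is the repression index `R`. Per
#' replicate,
#'
#' `%R_i = (R_i - mean(R_ns)) / (mean(R_max) - mean(R_ns)) * 100`
#'
#' where `R_ns` are the nonsense-control indices (the background) and
#' `R_max` the indices of the designated most-effective guide. By
#' construction the `R_max` group averages exactly 100% and the nonsense
#' group exactly 0%, for any positive inputs.
#'
#' @param test_rel Replicate relative-mRNA values of the guide under
#'   evaluation.
#' @param nonsense_rel Replicate values of the nonsense control.
#' @param rmax_rel Replicate values of the designated maximum-repression
#'   guide.
#' @return A list with `per_replicate` (the `%R_i`), `mean`, and `sd`
#'   (sample SD, `n - 1` denominator; `NA` for a single replicate).
#' @export
percent_repression <- function(test_rel, nonsense_rel, rmax_rel) {
  vals <- c(test_rel, nonsense_rel, rmax_rel)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("relative mRNA values must be positive and finite", call. = FALSE)
  }
  if (length(nonsense_rel) == 0L || length(rmax_rel) == 0L) {
    stop("nonsense and R_max groups must be non-empty", call. = FALSE)
  }
  ns_mean <- mean(nonsense_rel)
  r_test <- 1 / (test_rel / ns_mean)
  r_ns <- 1 / (nonsense_rel / ns_mean)
  r_max <- 1 / (rmax_rel / ns_mean)
  denom <- mean(r_max) - mean(r_ns)
  if (denom == 0) {
    stop("degenerate normalization: mean(R_max) equals mean(R_ns)",
         call. = FALSE)
  }
  pr <- (r_test - mean(r_ns)) / denom * 100
  list(per_replicate = pr, mean = mean(pr),
       sd = if (length(pr) > 1L) stats::sd(pr) else NA_real_)
}

#' Percent reduction of mRNA level
#'
#' `(1 - rel_mrna) * 100`: an mRNA level reduced to 13% of the control
#' is an 87% reduction. Vectorised.
#'
#' @param rel_mrna Relative mRNA level(s), positive.
#' @return Percent reduction.
#' @export
percent_reduction <- function(rel_mrna) {
  if (any(!is.finite(rel_mrna)) || any(rel_mrna <= 0)) {
    stop("rel_mrna must be positive and finite", call. = FALSE)
  }
  (1 - rel_mrna) * 100
}

#' Read a qPCR Cq table
#'
#' CSV with header columns `sample_id`, `guide_id`, `gene_role`
#' (`target` or `reference`), `replicate`, `cq`.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of measurements.
#' @export
read_qpcr_csv <- function(path) {
  if (!file.exists(path)) {
    stop("qPCR file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_qpcr(tab)
}

validate_qpcr <- function(tab) {
  need <- c("sample_id", "guide_id", "gene_role", "replicate", "cq")
  if (!all(need %in% names(tab))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, need]
  tab$cq <- suppressWarnings(as.numeric(tab$cq))
  if (!all(tab$gene_role %in% c("target", "reference"))) {
    stop("gene_role must be 'target' or 'reference'", call. = FALSE)
  }
  if (any(!is.finite(tab$cq)) || any(tab$cq <= 0)) {
    stop("cq values must be positive and finite", call. = FALSE)
  }
  key <- paste(tab$sample_id, tab$gene_role, tab$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, gene_role, replicate) measurement(s)",
         call. = FALSE)
  }
  tab
}

#' Summarize CRISPRi repression from qPCR measurements
#'
#' The full quantification chain, per guide: pair each replicate's target
#' and reference Cq within a sample and compute the delta-Cq relative
#' quantity; divide by the mean of the nonsense-control guide's values;
#' take reciprocals to get repression indices; convert to percent
#' repression against the designated maximum-repression guide; summarize
#' replicates as mean and sample SD. Guides with fewer than 3 replicates
#' are summarized but flagged.
#'
#' @param measurements Data.frame of Cq measurements (see
#'   [read_qpcr_csv()]).
#' @param control_guide `guide_id` of the nonsense control (the
#'   no-repression baseline).
#' @param rmax_guide `guide_id` of the maximum-repression guide, or
#'   `"auto"` to pick the guide with the highest mean repression index.
#' @param efficiency Amplification efficiency for [relative_quantity()].
#' @return A data.frame of class `repression_summary` with one row per
#'   guide: `guide_id`, `n`, `rel_mrna_mean`, `rel_mrna_sd`, `r_mean`,
#'   `pct_repression_mean`, `pct_repression_sd`, `pct_reduction`,
#'   `low_replicates`. The control and R_max guide ids are recorded as
#'   attributes.
#' @export
summarize_repression <- function(measurements, control_guide,
                                 rmax_guide = "auto", efficiency = 2) {
  tab <- validate_qpcr(measurements)
  if (!control_guide %in% tab$guide_id) {
    stop("control guide '", control_guide,
         "' not present in measurements", call. = FALSE)
  }
  if (!identical(rmax_guide, "auto") && !rmax_guide %in% tab$guide_id) {
    stop("rmax guide '", rmax_guide, "' not present in measurements",
         call. = FALSE)
  }

  target <- tab[tab$gene_role == "target", ]
  reference <- tab[tab$gene_role == "reference", ]
  key_t <- paste(target$sample_id, target$replicate)
  key_r <- paste(reference$sample_id, reference$replicate)
  miss <- setdiff(key_t, key_r)
  if (length(miss)) {
    stop("missing reference Cq for sample/replicate: ",
         paste(miss, collapse = "; "), call. = FALSE)
  }
  idx <- match(key_t, key_r)
  rel <- relative_quantity(target$cq, reference$cq[idx], efficiency)
  guide <- target$guide_id

  rel_by_guide <- split(rel, guide)
  ctrl_mean <- mean(rel_by_guide[[control_guide]])
  rel_norm <- lapply(rel_by_guide, function(v) v / ctrl_mean)
  r_by_guide <- lapply(rel_norm, function(v) 1 / v)
  r_means <- vapply(r_by_guide, mean, 0)

  if (identical(rmax_guide, "auto")) {
    rmax_guide <- names(which.max(r_means))
  }

  ids <- names(rel_norm)
  rows <- lapply(ids, function(id) {
    v <- rel_norm[[id]]
    pr <- percent_repression(v, rel_norm[[control_guide]],
                             rel_norm[[rmax_guide]])
    data.frame(
      guide_id = id,
      n = length(v),
      rel_mrna_mean = mean(v),
      rel_mrna_sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      r_mean = r_means[[id]],
      pct_repression_mean = pr$mean,
      pct_repression_sd = pr$sd,
      pct_reduction = (1 - mean(v)) * 100,
      low_replicates = length(v) < 3L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pct_repression_mean), ]
  rownames(out) <- NULL
  if (any(out$low_replicates)) {
    warning("guide(s) with fewer than 3 replicates: ",
            paste(out$guide_id[out$low_replicates], collapse = ", "),
            call. = FALSE)
  }
  attr(out, "control_guide") <- control_guide
  attr(out, "rmax_guide") <- rmax_guide
  attr(out, "efficiency") <- efficiency
  class(out) <- c("repression_summary", "data.frame")
  out
}

#' @export
print.repression_summary <- function(x, digits = 4, ...) {
  cat("CRISPRi repression summary:", nrow(x), "guide(s); control =",
      attr(x, "control_guide"), "; R_max =", attr(x, "rmax_guide"), "\n")
  show <- as.data.frame(x)
  num <- vapply(show, is.numeric, TRUE)
  show[num] <- lapply(show[num], signif, digits)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write a repression summary as TSV
#'
#' Floats with 4 significant digits; the low-replicate flag in the final
#' column.
#'
#' @param summary A `repression_summary`.
#' @param path Output path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_repression_tsv <- function(summary, path = "") {
  out <- as.data.frame(summary)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) signif(v, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
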