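#' Efficacy scoring rules for CRISPRi targeting sequences
#'
#' Window constants and peak centers for the strand-aware, TSS-distance
#' scoring of targeting sequences. Offsets are measured in bp from the TSS
#' to the center of the protospacer, positive downstream in the direction
#' of transcription. dCas9 represses best from two positions: forward
#' guides (identical to the non-template strand) peak roughly 60-120 bp
#' downstream of the TSS, and reverse guides peak in a narrow band around
#' -5 bp, overlapping the TSS. A broader -30..+100 bp band is still
#' preferred over distant sites.
#'
#' Tier A: forward with offset in `[fwd_lo, fwd_hi]`, or reverse with
#' offset in `[rev_lo, rev_hi]`. Tier B: any orientation with offset in
#' `[broad_lo, broad_hi]` (and not tier A). Tier C: everything else.
#' The numeric score is `base[tier] - penalty * |offset - peak|`, clamped
#' at `floor`, with peaks at `peak_forward` / `peak_reverse`; it breaks
#' ties within a tier by distance to the preferred position while keeping
#' every tier-A score above every tier-B score above every tier-C score.
#'
#' @param fwd_lo,fwd_hi Tier-A offset window (bp) for forward guides.
#' @param rev_lo,rev_hi Tier-A offset window (bp) for reverse guides.
#' @param broad_lo,broad_hi Tier-B offset window (bp), any orientation.
#' @param peak_forward,peak_reverse Peak offsets (bp) used by the distance
#'   penalty.
#' @param base Named numeric vector of tier base scores.
#' @param penalty Score units lost per bp of distance from the peak.
#' @param floor Minimum score after clamping.
#' @return A list of class `scoring_rules`.
#' @export
scoring_rules <- function(fwd_lo = 60, fwd_hi = 120,
                          rev_lo = -30, rev_hi = 15,
                          broad_lo = -30, broad_hi = 100,
                          peak_forward = 90, peak_reverse = -5,
                          base = c(A = 1.0, B = 0.5, C = 0.1),
                          penalty = 1e-4, floor = 0.01) {
  stopifnot(fwd_lo <= fwd_hi, rev_lo <= rev_hi, broad_lo <= broad_hi,
            all(c("A", "B", "C") %in% names(base)))
  structure(list(fwd_lo = fwd_lo, fwd_hi = fwd_hi,
                 rev_lo = rev_lo, rev_hi = rev_hi,
                 broad_lo = broad_lo, broad_hi = broad_hi,
                 peak_forward = peak_forward, peak_reverse = peak_reverse,
                 base = base, penalty = penalty, floor = floor),
            class = "scoring_rules")
}

#' Scan a sequence window for protospacer+PAM sites
#'
#' Enumerates every position where a `spacer_length`-nt window is followed
#' immediately 3' by an NGG PAM, on both strands, and keeps candidates
#' whose protospacer center falls inside `[window_start, window_end]`
#' (1-based, inclusive, plus-strand coordinates). Windows containing `N`
#' in the protospacer or PAM are excluded. Reported `start`/`end` are
#' always plus-strand coordinates of the protospacer (PAM excluded);
#' `protospacer` and `pam` are given 5'->3' on the carrying strand.
#'
#' @param bases A single DNA string (one genome sequence).
#' @param window_start,window_end 1-based window bounds; candidates are
#'   kept when their center lies inside. Defaults cover the whole sequence.
#' @param spacer_length Protospacer length in nt (default 20).
#' @return A data.frame with columns `protospacer`, `pam`, `strand`,
#'   `start`, `end`, sorted by `(start, strand)` with `+` before `-`.
#' @export
scan_pams <- function(bases, window_start = 1L, window_end = nchar(bases),
                      spacer_length = 20L) {
  stopifnot(length(bases) == 1L, is.character(bases))
  L <- nchar(bases)
  if (window_start < 1L || window_end > L || window_end < window_start) {
    stop("scan window [", window_start, ", ", window_end,
         "] out of bounds for sequence of length ", L, call. = FALSE)
  }
  k <- as.integer(spacer_length)

  empty <- data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)

  # plus strand: protospacer [g-k-1, g-2], PAM [g-1, g+1] where bases[g..g+1] == "GG"
  gg <- gregexpr("(?=GG)", bases, perl = TRUE)[[1]]
  gg <- gg[gg > 0L]
  g <- gg[gg - k - 1L >= 1L & gg + 1L <= L]
  plus <- if (length(g)) {
    data.frame(start = g - k - 1L, end = g - 2L, strand = "+",
               stringsAsFactors = FALSE)
  } else empty[, c("start", "end", "strand")]

  # minus strand: plus-strand "CC" at p is the reverse complement of the
  # PAM GG; PAM occupies plus [p, p+2], protospacer plus [p+3, p+2+k]
  cc <- gregexpr("(?=CC)", bases, perl = TRUE)[[1]]
  cc <- cc[cc > 0L]
  p <- cc[cc + 2L + k <= L]
  minus <- if (length(p)) {
    data.frame(start = p + 3L, end = p + 2L + k, strand = "-",
               stringsAsFactors = FALSE)
  } else empty[, c("start", "end", "strand")]

  cand <- rbind(plus, minus)
  if (nrow(cand) == 0L) return(empty)

  center <- (cand$start + cand$end) / 2
  cand <- cand[center >= window_start & center <= window_end, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  proto_plus <- substring(bases, cand$start, cand$end)
  pam_plus <- ifelse(cand$strand == "+",
                     substring(bases, cand$end + 1L, cand$end + 3L),
                     substring(bases, cand$start - 3L, cand$start - 1L))
  keep <- !grepl("N", proto_plus, fixed = TRUE) &
          !grepl("N", pam_plus, fixed = TRUE)
  cand <- cand[keep, , drop = FALSE]
  proto_plus <- proto_plus[keep]
  pam_plus <- pam_plus[keep]
  if (nrow(cand) == 0L) return(empty)

  is_minus <- cand$strand == "-"
  protospacer <- proto_plus
  pam <- pam_plus
  if (any(is_minus)) {
    protospacer[is_minus] <- reverse_complement(proto_plus[is_minus])
    pam[is_minus] <- reverse_complement(pam_plus[is_minus])
  }

  out <- data.frame(protospacer = protospacer, pam = pam,
                    strand = cand$strand, start = cand$start,
                    end = cand$end, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify candidates relative to a gene
#'
#' Fills in `orientation` and `offset` for raw protospacer candidates. A
#' candidate is `forward` when its carrying genomic strand equals the
#' gene's strand (the targeting sequence is then identical to the
#' non-template strand), `reverse` otherwise. The offset is the signed
#' distance from the TSS to the protospacer center, positive downstream in
#' the direction of transcription; for an even spacer length it is an
#' exact half-integer.
#'
#' @param cand Data.frame from [scan_pams()] (columns `strand`, `start`,
#'   `end`, ...).
#' @param gene A one-row TSS record (list or data.frame row with
#'   `gene_id`, `seq_id`, `strand`, `tss`).
#' @param seq_id Optional seq_id of the scanned sequence, checked against
#'   `gene$seq_id`.
#' @return `cand` with `gene_id`, `seq_id`, `orientation`, `offset` added.
#' @export
classify_candidates <- function(cand, gene, seq_id = gene$seq_id) {
  if (!identical(as.character(seq_id), as.character(gene$seq_id))) {
    stop("candidate sequence '", seq_id, "' does not match gene sequence '",
         gene$seq_id, "'", call. = FALSE)
  }
  center <- (cand$start + cand$end) / 2
  offset <- if (gene$strand == "+") center - gene$tss else gene$tss - center
  orientation <- ifelse(cand$strand == gene$strand, "forward", "reverse")
  cbind(data.frame(gene_id = rep(gene$gene_id, nrow(cand)),
                   seq_id = rep(as.character(gene$seq_id), nrow(cand)),
                   stringsAsFactors = FALSE),
        cand, orientation = orientation, offset = offset)
}

#' Score a candidate by orientation and TSS offset
#'
#' Applies the tiered two-peak efficacy rule (see [scoring_rules()]).
#' Vectorised over `orientation`/`offset`.
#'
#' @param orientation Character vector, `"forward"` or `"reverse"`.
#' @param offset Numeric vector of TSS offsets in bp.
#' @param rules A [scoring_rules()] object.
#' @return A data.frame with columns `tier` (`"A"`, `"B"`, `"C"`) and
#'   `score` in `(0, 1]`.
#' @export
score_candidate <- function(orientation, offset, rules = scoring_rules()) {
  stopifnot(all(orientation %in% c("forward", "reverse")))
  fwd <- orientation == "forward"
  tierA <- (fwd & offset >= rules$fwd_lo & offset <= rules$fwd_hi) |
           (!fwd & offset >= rules$rev_lo & offset <= rules$rev_hi)
  tierB <- !tierA & offset >= rules$broad_lo & offset <= rules$broad_hi
  tier <- ifelse(tierA, "A", ifelse(tierB, "B", "C"))
  peak <- ifelse(fwd, rules$peak_forward, rules$peak_reverse)
  score <- rules$base[tier] - rules$penalty * abs(offset - peak)
  score <- pmax(score, rules$floor)
  data.frame(tier = tier, score = unname(score), stringsAsFactors = FALSE)
}

#' Design ranked CRISPRi guides for a gene
#'
#' The full design chain: scan the promoter-proximal window of the gene
#' for protospacer+PAM sites on both strands, classify orientation and TSS
#' offset, score by the two-peak efficacy rule, annotate genome-wide
#' exact-match counts, optionally drop non-unique guides, and rank. The
#' scan window spans `tss - upstream` to `tss + downstream` in the
#' direction of transcription (so for a minus-strand gene, downstream is
#' decreasing plus-strand coordinate), clipped to the sequence; candidates
#' overlapping the window edge are kept when their center lies inside.
#'
#' Ranking is deterministic: tier A before B before C, then score
#' descending, then distance to the orientation peak ascending, then
#' `start` ascending, then `+` strand before `-`.
#'
#' @param genome A `crispri_genome`.
#' @param tss_table Data.frame from [read_tss_table()].
#' @param gene_id Gene to design against.
#' @param upstream,downstream Window extent in bp from the TSS (defaults
#'   200 upstream, 300 downstream).
#' @param top_n Keep at most this many guides (default all).
#' @param unique_only Drop guides whose 20-mer+PAM occurs more than once
#'   in the genome.
#' @param rules A [scoring_rules()] object.
#' @param spacer_length Protospacer length in nt; 18-25 accepted, a
#'   warning is issued when not 20.
#' @param index Optional prebuilt [build_site_index()]; built from
#'   `genome` when `NULL`.
#' @return A data.frame of class `guide_design` with columns `gene_id`,
#'   `seq_id`, `strand`, `start`, `end`, `protospacer`, `pam`,
#'   `orientation`, `offset`, `tier`, `score`, `n20`, `n12`, `unique`.
#' @export
design_guides <- function(genome, tss_table, gene_id,
                          upstream = 200L, downstream = 300L,
                          top_n = Inf, unique_only = FALSE,
                          rules = scoring_rules(), spacer_length = 20L,
                          index = NULL) {
  spacer_length <- check_spacer_length(spacer_length)
  hit <- which(tss_table$gene_id == gene_id)
  if (length(hit) != 1L) {
    stop("gene '", gene_id, "' not found in TSS table", call. = FALSE)
  }
  gene <- as.list(tss_table[hit, ])
  bases <- genome[[gene$seq_id]]
  L <- nchar(bases)

  if (gene$strand == "+") {
    ws <- gene$tss - upstream; we <- gene$tss + downstream
  } else {
    ws <- gene$tss - downstream; we <- gene$tss + upstream
  }
  ws <- max(1L, ws); we <- min(L, we)
  if (we < ws) {
    warning("empty scan window for gene '", gene_id, "'", call. = FALSE)
    return(empty_guide_design())
  }

  cand <- scan_pams(bases, ws, we, spacer_length = spacer_length)
  if (nrow(cand) == 0L) {
    warning("no protospacer+PAM candidates in window for gene '",
            gene_id, "'", call. = FALSE)
    return(empty_guide_design())
  }
  cand <- classify_candidates(cand, gene)
  sc <- score_candidate(cand$orientation, cand$offset, rules)
  cand$tier <- sc$tier
  cand$score <- sc$score

  if (is.null(index)) index <- build_site_index(genome, spacer_length)
  counts <- count_matches(cand$protospacer, index)
  cand$n20 <- counts$n20
  cand$n12 <- counts$n12
  cand$unique <- cand$n20 == 1L
  if (unique_only) cand <- cand[cand$unique, , drop = FALSE]

  peak <- ifelse(cand$orientation == "forward",
                 rules$peak_forward, rules$peak_reverse)
  ord <- order(match(cand$tier, c("A", "B", "C")), -cand$score,
               abs(cand$offset - peak), cand$start,
               match(cand$strand, c("+", "-")))
  cand <- cand[ord, , drop = FALSE]
  if (is.finite(top_n)) cand <- utils::head(cand, top_n)
  cand <- cand[, guide_design_columns(), drop = FALSE]
  rownames(cand) <- NULL
  class(cand) <- c("guide_design", "data.frame")
  cand
}

check_spacer_length <- function(spacer_length) {
  spacer_length <- as.integer(spacer_length)
  if (is.na(spacer_length) || spacer_length < 18L || spacer_length > 25L) {
    stop("spacer_length must be between 18 and 25", call. = FALSE)
  }
  if (spacer_length != 20L) {
    warning("spacer_length ", spacer_length,
            " differs from the recommended 20 nt", call. = FALSE)
  }
  spacer_length
}

guide_design_columns <- function() {
  c("gene_id", "seq_id", "strand", "start", "end", "protospacer", "pam",
    "orientation", "offset", "tier", "score", "n20", "n12", "unique")
}

empty_guide_design <- function() {
  out <- data.frame(gene_id = character(0), seq_id = character(0),
                    strand = character(0), start = integer(0),
                    end = integer(0), protospacer = character(0),
                    pam = character(0), orientation = character(0),
                    offset = numeric(0), tier = character(0),
                    score = numeric(0), n20 = integer(0), n12 = integer(0),
                    unique = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("guide_design", "data.frame")
  out
}

#' @export
print.guide_design <- function(x, ...) {
  cat("CRISPRi guide design:", nrow(x), "candidate(s)")
  if (nrow(x) && !is.null(x$gene_id)) {
    cat(" for", paste(unique(x$gene_id), collapse = ", "),
        "| tiers:", paste(names(table(x$tier)), table(x$tier),
                          sep = "=", collapse = " "))
  }
  cat("\n")
  if (nrow(x)) {
    show <- as.data.frame(x)
    if (!is.null(show$offset)) show$offset <- sprintf("%.1f", show$offset)
    if (!is.null(show$score)) show$score <- sprintf("%.4f", show$score)
    print(utils::head(show, 12), row.names = FALSE)
    if (nrow(x) > 12) cat("...", nrow(x) - 12, "more\n")
  }
  invisible(x)
}

#' Write a guide design table as TSV
#'
#' Columns in the documented order; offsets printed with one decimal.
#'
#' @param guides A `guide_design` data.frame.
#' @param path Output path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(guides, path = "") {
  out <- as.data.frame(guides)[, guide_design_columns(), drop = FALSE]
  out$offset <- sprintf("%.1f", out$offset)
  out$unique <- ifelse(out$unique, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
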