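#' Build the Golden-Gate annealing oligo pair for a targeting sequence
#'
#' Constructs the two single-stranded oligos that, once annealed, carry
#' the targeting sequence flanked by 4-nt 5' overhangs complementary to a
#' BbsI-cut sgRNA expression vector:
#'
#' ```
#' 5'-CACC<targeting sequence>-3'        (top strand)
#'     3'-<complement          >CAAA-5'  (bottom strand)
#' ```
#'
#' so the bottom oligo read 5'->3' is `AAAC` followed by the reverse
#' complement of the targeting sequence. The overhangs are configuration
#' values for use with other vector digestions.
#'
#' @param protospacer Targeting sequence, 18-25 nt over A/C/G/T (a
#'   warning is issued when the length is not 20).
#' @param tm_method Melting-temperature method, `"wallace"` (default) or
#'   `"nn"` (nearest-neighbor); see [melting_temperature()].
#' @param top_overhang,bottom_overhang 4-nt 5' overhangs (defaults
#'   `CACC` / `AAAC` for the BbsI-cut vector).
#' @return A list of class `oligo_pair` with elements `protospacer`,
#'   `top`, `bottom` (both 5'->3'), `tm_c`, and `schedule` (see
#'   [annealing_schedule()]).
#' @examples
#' make_oligo_pair("ACGTACGTACGTACGTACGT")
#' @export
make_oligo_pair <- function(protospacer, tm_method = c("wallace", "nn"),
                            top_overhang = "CACC", bottom_overhang = "AAAC") {
  tm_method <- match.arg(tm_method)
  stopifnot(length(protospacer) == 1L)
  if (grepl("[^ACGT]", protospacer)) {
    stop("protospacer must contain only A/C/G/T", call. = FALSE)
  }
  n <- nchar(protospacer)
  if (n < 18L || n > 25L) {
    stop("protospacer length must be 18-25 nt, got ", n, call. = FALSE)
  }
  if (n != 20L) {
    warning("protospacer length ", n,
            " differs from the recommended 20 nt", call. = FALSE)
  }
  tm <- melting_temperature(protospacer, method = tm_method)
  structure(list(protospacer = protospacer,
                 top = paste0(top_overhang, protospacer),
                 bottom = paste0(bottom_overhang,
                                 reverse_complement(protospacer)),
                 tm_c = tm,
                 schedule = annealing_schedule(tm)),
            class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat("Annealing oligo pair (5'->3'):\n")
  cat("  top:    ", x$top, "\n")
  cat("  bottom: ", x$bottom, "\n")
  cat(sprintf("  spacer Tm: %.1f degC\n", x$tm_c))
  cat("Annealing program:\n")
  for (i in seq_len(nrow(x$schedule))) {
    s <- x$schedule[i, ]
    cat(sprintf("  %-8s %s, %.1f min\n", s$step, s$temperature, s$minutes))
  }
  cat("Protocol notes: anneal at 20 uM each oligo; ligate 2.0 pmol",
      "insert with 0.03 pmol BbsI-cut vector.\n")
  invisible(x)
}

#' Melting temperature of a targeting sequence
#'
#' Default is the Wallace rule, `2 x (#A + #T) + 4 x (#G + #C)` degrees
#' Celsius, the usual quick estimate for short oligos. `method = "nn"`
#' uses unified nearest-neighbor thermodynamics (SantaLucia-style
#' dimer enthalpies/entropies with a monovalent-salt correction),
#' appropriate when a more physical estimate is wanted.
#'
#' @param seq DNA string over A/C/G/T.
#' @param method `"wallace"` (default) or `"nn"`.
#' @param na_molar Monovalent cation concentration (M) for `"nn"`.
#' @param oligo_molar Total oligo concentration (M) for `"nn"`; default
#'   20 uM, the annealing concentration used downstream.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")  # 60
#' @export
melting_temperature <- function(seq, method = c("wallace", "nn"),
                                na_molar = 0.05, oligo_molar = 20e-6) {
  method <- match.arg(method)
  stopifnot(length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGT]", seq)) {
    stop("sequence must contain only A/C/G/T", call. = FALSE)
  }
  b <- strsplit(seq, "")[[1]]
  if (method == "wallace") {
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  }
  nn_tm(b, na_molar, oligo_molar)
}

# Unified nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K).
nn_params <- function() {
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  # complete under strand symmetry: dimer == revcomp(dimer)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  full_H <- full_S <- numeric(0)
  for (x in c("A", "C", "G", "T")) for (y in c("A", "C", "G", "T")) {
    d <- paste0(x, y)
    rc <- paste0(comp[y], comp[x])
    full_H[d] <- if (d %in% names(dH)) dH[[d]] else dH[[rc]]
    full_S[d] <- if (d %in% names(dS)) dS[[d]] else dS[[rc]]
  }
  list(dH = full_H, dS = full_S)
}

nn_tm <- function(b, na_molar, oligo_molar) {
  p <- nn_params()
  dimers <- paste0(b[-length(b)], b[-1])
  dH <- sum(p$dH[dimers])
  dS <- sum(p$dS[dimers])
  # initiation with terminal penalties
  init_H <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
  init_S <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
  dH <- dH + init_H[[b[1]]] + init_H[[b[length(b)]]]
  dS <- dS + init_S[[b[1]]] + init_S[[b[length(b)]]]
  tm_k <- dH * 1000 / (dS + 1.987 * log(oligo_molar / 4))
  tm_k + 16.6 * log10(na_molar) - 273.15
}

#' Thermal-cycler program for oligo annealing
#'
#' Builds the annealing schedule used to form the spacer duplex:
#' denature at 95 degC for 2 min, cool to the spacer Tm at -2 degC/min,
#' hold at Tm for 5 min, then cool to 25 degC at -2 degC/min. Ramp
#' durations follow from the rate; a ramp of zero span is retained as a
#' no-op step.
#'
#' @param tm_c Spacer melting temperature in degC, between 25 and 95.
#' @param ramp_rate Cooling rate in degC per minute (positive; default 2).
#' @return A data.frame with columns `step`, `temperature` (a label),
#'   `minutes`.
#' @export
annealing_schedule <- function(tm_c, ramp_rate = 2) {
  if (!is.finite(tm_c) || tm_c < 25 || tm_c > 95) {
    stop("tm_c must be between 25 and 95 degC, got ", tm_c, call. = FALSE)
  }
  data.frame(
    step = c("denature", "ramp", "hold", "ramp"),
    temperature = c("95", sprintf("95->%g", tm_c), sprintf("%g", tm_c),
                    sprintf("%g->25", tm_c)),
    minutes = c(2, (95 - tm_c) / ramp_rate, 5, (tm_c - 25) / ramp_rate),
    stringsAsFactors = FALSE
  )
}

#' Write an oligo report as TSV
#'
#' One row per guide: id, both oligos 5'->3', and the spacer Tm. The
#' annealing program for each guide is available through
#' [annealing_schedule()] or by printing the `oligo_pair`.
#'
#' @param pairs A list of `oligo_pair` objects, optionally named.
#' @param path Output path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_oligos_tsv <- function(pairs, path = "") {
  if (inherits(pairs, "oligo_pair")) pairs <- list(pairs)
  ids <- names(pairs)
  if (is.null(ids)) ids <- paste0("guide", seq_along(pairs))
  out <- data.frame(
    guide_id = ids,
    top_oligo = vapply(pairs, `[[`, "", "top"),
    bottom_oligo = vapply(pairs, `[[`, "", "bottom"),
    tm_c = vapply(pairs, `[[`, 0, "tm_c"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
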