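#' Build a genome-wide index of protospacer+PAM sites
#'
#' Enumerates every `spacer_length`-nt window followed immediately 3' by
#' an NGG PAM, on both strands of every sequence in the genome, excluding
#' windows containing `N`. The index stores occurrence counts of the full
#' protospacer (the "20-mer") and of its PAM-proximal 12-nt seed (the
#' 3'-most 12 nt), the portion that dominates Cas9 binding specificity.
#' The PAM's first base is not compared: any NGG qualifies.
#'
#' @param genome A `crispri_genome`.
#' @param spacer_length Protospacer length in nt (default 20).
#' @param seed_length Seed length in nt for the secondary count
#'   (default 12).
#' @return An object of class `site_index` with the site table and count
#'   maps.
#' @export
build_site_index <- function(genome, spacer_length = 20L, seed_length = 12L) {
  stopifnot(length(genome) >= 1L)
  sites <- do.call(rbind, lapply(names(genome), function(id) {
    s <- scan_pams(genome[[id]], spacer_length = spacer_length)
    if (nrow(s)) s$seq_id <- id
    s
  }))
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.frame(protospacer = character(0), pam = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), seq_id = character(0),
                        stringsAsFactors = FALSE)
  }
  seeds <- substring(sites$protospacer,
                     spacer_length - seed_length + 1L, spacer_length)
  structure(list(sites = sites,
                 n20_map = table_to_counts(sites$protospacer),
                 n12_map = table_to_counts(seeds),
                 spacer_length = as.integer(spacer_length),
                 seed_length = as.integer(seed_length)),
            class = "site_index")
}

table_to_counts <- function(x) {
  if (length(x) == 0L) return(integer(0))
  tab <- table(x)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @export
print.site_index <- function(x, ...) {
  cat("CRISPRi site index:", nrow(x$sites), "protospacer+PAM site(s),",
      length(x$n20_map), "distinct", paste0(x$spacer_length, "-mers,"),
      length(x$n12_map), "distinct", paste0(x$seed_length, "-nt seeds\n"))
  invisible(x)
}

#' Count genome-wide matches of targeting sequences
#'
#' For each query protospacer, `n20` is the number of genomic sites whose
#' full protospacer equals the query (with any NGG PAM), and `n12` the
#' number of sites whose PAM-proximal seed matches the query's seed;
#' `n12 >= n20` always. A guide is considered unique when `n20 == 1`.
#'
#' @param protospacer Character vector of query sequences (no `N`), each
#'   of the index's spacer length.
#' @param index A [build_site_index()] object.
#' @return A data.frame with columns `protospacer`, `n20`, `n12`,
#'   `unique`.
#' @export
count_matches <- function(protospacer, index) {
  stopifnot(inherits(index, "site_index"))
  if (any(grepl("N", protospacer, fixed = TRUE))) {
    stop("query protospacer contains N", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", protospacer))) {
    stop("query protospacer contains characters outside A/C/G/T",
         call. = FALSE)
  }
  if (any(nchar(protospacer) != index$spacer_length)) {
    stop("query length must equal the index spacer length (",
         index$spacer_length, ")", call. = FALSE)
  }
  seed <- substring(protospacer,
                    index$spacer_length - index$seed_length + 1L,
                    index$spacer_length)
  n20 <- unname(index$n20_map[protospacer])
  n12 <- unname(index$n12_map[seed])
  n20[is.na(n20)] <- 0L
  n12[is.na(n12)] <- 0L
  data.frame(protospacer = protospacer, n20 = n20, n12 = n12,
             unique = n20 == 1L, stringsAsFactors = FALSE)
}

#' Write an off-target match report as TSV
#'
#' @param counts Data.frame from [count_matches()].
#' @param path Output path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_offtarget_tsv <- function(counts, path = "") {
  utils::write.table(counts[, c("protospacer", "n20", "n12", "unique")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
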