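#' Read a genome from a FASTA file
#'
#' Loads a multi-record FASTA into a named character vector of uppercase
#' DNA sequences, the container used throughout the package as the search
#' space for protospacers. Bases are case-folded on read; only the alphabet
#' `A`, `C`, `G`, `T`, `N` is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `crispri_genome`; names are
#'   record identifiers, values are uppercase sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", ">c2", "NNNN"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  bases <- toupper(as.character(set))
  # first whitespace-delimited token of the header is the record id
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty identifier in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(bases) <- ids
  as_crispri_genome(bases)
}

#' Construct a genome object from named sequences
#'
#' @param bases Named character vector of DNA sequences (A/C/G/T/N; case
#'   folded to upper).
#' @return A `crispri_genome` object.
#' @export
as_crispri_genome <- function(bases) {
  if (is.null(names(bases)) || any(!nzchar(names(bases)))) {
    stop("genome sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(bases))) {
    stop("duplicate sequence id(s) in genome", call. = FALSE)
  }
  nm <- names(bases)
  bases <- toupper(as.character(bases))
  names(bases) <- nm
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad)) {
    stop("sequence(s) contain characters outside A/C/G/T/N: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(nchar(bases) < 1L)) {
    stop("zero-length sequence(s) in genome", call. = FALSE)
  }
  structure(bases, class = "crispri_genome")
}

#' @export
print.crispri_genome <- function(x, ...) {
  cat("CRISPRi genome:", length(x), "sequence(s),",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  df <- data.frame(seq_id = names(x), length = unname(nchar(x)))
  print(utils::head(df, 10), row.names = FALSE)
  if (length(x) > 10) cat("...", length(x) - 10, "more\n")
  invisible(x)
}

#' Write a genome to a FASTA file
#'
#' @param genome A `crispri_genome` (or named character vector).
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::BStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Reads a tab-delimited table of transcription start sites with header
#' columns `gene_id`, `seq_id`, `strand`, `tss`. Lines starting with `#`
#' are skipped. Coordinates are 1-based; each record is validated against
#' the genome: the chromosome must exist, `strand` must be `+` or `-`,
#' and `tss` must be within the sequence. The TSS is the single first
#' transcribed base of the gene; one TSS per gene is enforced.
#'
#' @param path Path to the TSV file.
#' @param genome A `crispri_genome` used to validate references and bounds.
#' @return A data.frame with columns `gene_id`, `seq_id`, `strand`, `tss`.
#' @export
read_tss_table <- function(path, genome) {
  if (!file.exists(path)) {
    stop("TSS table not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "seq_id", "strand", "tss")
  if (!all(need %in% names(tab))) {
    stop("TSS table must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, need]
  tab$tss <- suppressWarnings(as.integer(tab$tss))
  validate_tss_table(tab, genome)
}

validate_tss_table <- function(tab, genome) {
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id(s) in TSS table: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(tab$seq_id, names(genome))
  if (length(unknown)) {
    stop("TSS table references unknown seq_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(tab$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (anyNA(tab$tss)) {
    stop("non-numeric tss value(s) in TSS table", call. = FALSE)
  }
  len <- nchar(genome)[tab$seq_id]
  out <- tab$tss < 1L | tab$tss > len
  if (any(out)) {
    stop("tss out of bounds (1-based) for gene(s): ",
         paste(tab$gene_id[out], collapse = ", "), call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Reverse complement of DNA strings
#'
#' Standard Watson-Crick reverse complement over the alphabet
#' `A`/`C`/`G`/`T`/`N`; `N` maps to `N`. Vectorised.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GATTACA")  # "TGTAATC"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTNacgtn]", seq))) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}
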