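# Independent brute-force oracles, deliberately written with none of the
# package's internals: plain substr loops and a chartr-based complement.

oracle_rc <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# enumerate every k-mer window with an NGG 3' context on both strands
oracle_scan <- function(bases, window_start = 1, window_end = nchar(bases),
                        k = 20) {
  L <- nchar(bases)
  rows <- list()
  for (s in seq_len(max(0, L - k + 1))) {
    e <- s + k - 1
    if (e + 3 <= L) {
      proto <- substr(bases, s, e)
      pam <- substr(bases, e + 1, e + 3)
      if (substr(pam, 2, 3) == "GG" &&
          !grepl("N", proto) && !grepl("N", pam)) {
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = proto, pam = pam, strand = "+",
          start = s, end = e, stringsAsFactors = FALSE)
      }
    }
    if (s - 3 >= 1) {
      proto <- oracle_rc(substr(bases, s, e))
      pam <- oracle_rc(substr(bases, s - 3, s - 1))
      if (substr(pam, 2, 3) == "GG" &&
          !grepl("N", proto) && !grepl("N", pam)) {
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = proto, pam = pam, strand = "-",
          start = s, end = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  center <- (out$start + out$end) / 2
  out <- out[center >= window_start & center <= window_end, , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive full-genome exact-occurrence count of a spacer with any NGG PAM
oracle_count_n20 <- function(genome_strings, proto) {
  total <- 0L
  for (s in genome_strings) {
    L <- nchar(s)
    k <- nchar(proto)
    for (i in seq_len(max(0, L - k - 2))) {
      if (substr(s, i, i + k - 1) == proto &&
          substr(s, i + k + 1, i + k + 2) == "GG") {
        total <- total + 1L
      }
    }
    rcp <- oracle_rc(proto)
    for (i in seq_len(max(0, L - k - 2))) {
      # minus-strand site: plus slice [i..i+2] is CCN, spacer at [i+3..]
      if (i + 2 + k <= L && substr(s, i, i + 1) == "CC" &&
          substr(s, i + 3, i + 2 + k) == rcp) {
        total <- total + 1L
      }
    }
  }
  total
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_fasta_lines <- function(named, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(named)) {
    writeLines(c(paste0(">", id), named[[id]]), con)
  }
  path
}
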