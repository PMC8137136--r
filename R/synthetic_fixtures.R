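#' Evaluate code under a fixed RNG seed, restoring state afterwards
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

count_occurrences <- function(strings, pattern) {
  # overlapping fixed-string occurrences across a set of sequences
  hits <- vapply(strings, function(s) {
    m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
    sum(m > 0L)
  }, 0L)
  sum(hits)
}

#' Generate a synthetic genome with planted guide sites
#'
#' Builds a seeded random genome (i.i.d. bases at a given GC fraction,
#' emulating the AT-rich fission-yeast genome by default), places one TSS
#' per requested gene, and plants protospacer+NGG sites at prescribed
#' TSS offsets and orientations, so that the design chain can be
#' exercised against known ground truth. Uniqueness of a planted 20-mer
#' is enforced by rejection sampling against the rest of the genome
#' (both strands), with a bounded number of retries. Since promoter
#' regions upstream of TSSs are typically AT-rich in vivo, an optional
#' mode resamples the 150 bp upstream of each TSS at a lower GC fraction
#' to emulate realistic candidate sparsity.
#'
#' @param n_chrom Number of chromosomes.
#' @param length Length of each chromosome in bp (at least 500).
#' @param gc Background GC fraction (default 0.36, fission-yeast-like).
#' @param genes Data.frame with columns `gene_id`, `seq_id`, `strand`,
#'   `tss` (1-based). `seq_id`s must be among the generated chromosomes
#'   (`chr1`, `chr2`, ...).
#' @param plants Data.frame with columns `gene_id`, `orientation`
#'   (`forward`/`reverse`), `offset` (half-integer bp from the TSS to
#'   the protospacer center, positive downstream), `unique` (logical);
#'   or `NULL` for no plants.
#' @param seed Integer seed; the same seed reproduces the fixture
#'   byte-identically.
#' @param spacer_length Planted protospacer length (default 20).
#' @param at_rich_promoters Resample 150 bp upstream of each TSS at
#'   `promoter_gc`.
#' @param promoter_gc GC fraction for the AT-rich promoter mode.
#' @param max_retries Rejection-sampling cap per plant (default 1000).
#' @return A list with `genome` (a `crispri_genome`), `tss` (validated
#'   TSS table), and `manifest` (one row per plant with the expected
#'   `seq_id`, `strand`, `start`, `end`, `protospacer`, `pam`,
#'   `orientation`, `offset`, `unique`).
#' @export
generate_genome_fixture <- function(n_chrom = 1L, length = 5000L, gc = 0.36,
                                    genes, plants = NULL, seed = NULL,
                                    spacer_length = 20L,
                                    at_rich_promoters = FALSE,
                                    promoter_gc = 0.25,
                                    max_retries = 1000L) {
  stopifnot(length >= 500L, n_chrom >= 1L, gc > 0, gc < 1)
  k <- as.integer(spacer_length)
  with_seed(seed, {
    chroms <- lapply(seq_len(n_chrom), function(i) random_bases(length, gc))
    names(chroms) <- paste0("chr", seq_len(n_chrom))

    genes$tss <- as.integer(genes$tss)
    if (!all(genes$seq_id %in% names(chroms))) {
      stop("gene seq_id(s) outside the generated chromosomes", call. = FALSE)
    }
    if (at_rich_promoters) {
      for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        rng <- if (g$strand == "+") {
          seq(max(1L, g$tss - 150L), max(1L, g$tss - 1L))
        } else {
          seq(min(length, g$tss + 1L), min(length, g$tss + 150L))
        }
        chroms[[g$seq_id]][rng] <- random_bases(base::length(rng), promoter_gc)
      }
    }

    manifest <- NULL
    footprints <- list()
    if (!is.null(plants) && nrow(plants)) {
      for (i in seq_len(nrow(plants))) {
        p <- plants[i, ]
        gi <- which(genes$gene_id == p$gene_id)
        if (length(gi) != 1L) {
          stop("plant references unknown gene '", p$gene_id, "'",
               call. = FALSE)
        }
        g <- genes[gi, ]
        center <- if (g$strand == "+") g$tss + p$offset else g$tss - p$offset
        start <- center - (k - 1) / 2
        end <- center + (k - 1) / 2
        if (start != floor(start)) {
          stop("plant offset ", p$offset, " for gene '", p$gene_id,
               "' does not align the ", k,
               "-nt protospacer on integer coordinates", call. = FALSE)
        }
        start <- as.integer(start); end <- as.integer(end)
        cand_strand <- if (identical(p$orientation, "forward")) g$strand
                       else setdiff(c("+", "-"), g$strand)
        fp <- if (cand_strand == "+") c(start, end + 3L)
              else c(start - 3L, end)
        if (fp[1] < 1L || fp[2] > length) {
          stop("plant for gene '", p$gene_id,
               "' falls outside the chromosome", call. = FALSE)
        }
        for (prev in footprints) {
          if (prev$seq_id == g$seq_id && fp[1] <= prev$to && fp[2] >= prev$from) {
            stop("plant for gene '", p$gene_id,
                 "' overlaps a previous plant", call. = FALSE)
          }
        }
        footprints[[i]] <- list(seq_id = g$seq_id, from = fp[1], to = fp[2])

        planted <- FALSE
        for (try in seq_len(max_retries)) {
          proto <- paste(random_bases(k, gc), collapse = "")
          pam <- paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
          if (cand_strand == "+") {
            chroms[[g$seq_id]][start:end] <- strsplit(proto, "")[[1]]
            chroms[[g$seq_id]][(end + 1L):(end + 3L)] <- strsplit(pam, "")[[1]]
          } else {
            chroms[[g$seq_id]][start:end] <-
              strsplit(reverse_complement(proto), "")[[1]]
            chroms[[g$seq_id]][(start - 3L):(start - 1L)] <-
              strsplit(reverse_complement(pam), "")[[1]]
          }
          if (!isTRUE(p$unique)) { planted <- TRUE; break }
          strings <- vapply(chroms, paste, "", collapse = "")
          n_fwd <- count_occurrences(strings, proto)
          n_rev <- count_occurrences(strings, reverse_complement(proto))
          if (n_fwd + n_rev == 1L) { planted <- TRUE; break }
        }
        if (!planted) {
          stop("could not place a unique protospacer for gene '",
               p$gene_id, "' after ", max_retries, " attempts",
               call. = FALSE)
        }
        manifest <- rbind(manifest, data.frame(
          gene_id = p$gene_id, seq_id = g$seq_id, strand = cand_strand,
          start = start, end = end, protospacer = proto, pam = pam,
          orientation = p$orientation, offset = p$offset,
          unique = isTRUE(p$unique), stringsAsFactors = FALSE
        ))
      }
    }

    genome <- as_crispri_genome(vapply(chroms, paste, "", collapse = ""))
    tss <- validate_tss_table(genes[, c("gene_id", "seq_id", "strand", "tss")],
                              genome)
    list(genome = genome, tss = tss, manifest = manifest)
  })
}

#' Write a genome fixture to disk
#'
#' Writes the FASTA, the TSS TSV and (when present) the plant manifest
#' TSV into a directory, in the formats the rest of the toolkit reads.
#'
#' @param fixture A [generate_genome_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_genome_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             tss = file.path(dir, "tss.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  write_genome_fasta(fixture$genome, paths[["fasta"]])
  utils::write.table(fixture$tss, paths[["tss"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fixture$manifest)) {
    utils::write.table(fixture$manifest, paths[["manifest"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[c("fasta", "tss")]
  }
  invisible(paths)
}

#' Generate a synthetic qPCR Cq table with known true repression
#'
#' Inverse of the delta-Cq quantification model: for each guide with true
#' relative mRNA level `L`, reference Cq is drawn near a baseline and
#' target Cq is set to `reference - log_efficiency(L)` plus Gaussian
#' noise. With zero noise, [summarize_repression()] recovers the planted
#' levels exactly (levels are relative to the control guide, whose level
#' should be 1).
#'
#' @param true_levels Named numeric vector: `guide_id` -> true relative
#'   mRNA level (positive; the nonsense control should be 1).
#' @param n_replicates Replicates per guide (default 3, the usual
#'   biological-replicate count).
#' @param cq_noise_sd SD of Gaussian Cq noise in cycles (default 0).
#' @param efficiency Amplification factor per cycle (default 2).
#' @param seed Integer seed for reproducibility.
#' @param baseline_cq Mean reference-gene Cq (default 15).
#' @return A data.frame of measurements with columns `sample_id`,
#'   `guide_id`, `gene_role`, `replicate`, `cq`.
#' @export
generate_qpcr_fixture <- function(true_levels, n_replicates = 3L,
                                  cq_noise_sd = 0, efficiency = 2,
                                  seed = NULL, baseline_cq = 15) {
  if (is.null(names(true_levels)) || any(!nzchar(names(true_levels)))) {
    stop("true_levels must be a named vector", call. = FALSE)
  }
  if (any(!is.finite(true_levels)) || any(true_levels <= 0)) {
    stop("true relative mRNA levels must be positive", call. = FALSE)
  }
  stopifnot(n_replicates >= 1L, cq_noise_sd >= 0)
  with_seed(seed, {
    rows <- lapply(names(true_levels), function(g) {
      lvl <- true_levels[[g]]
      ref <- baseline_cq + stats::rnorm(n_replicates, 0, cq_noise_sd)
      targ <- ref - log(lvl, base = efficiency) +
        stats::rnorm(n_replicates, 0, cq_noise_sd)
      data.frame(
        sample_id = rep(g, 2L * n_replicates),
        guide_id = rep(g, 2L * n_replicates),
        gene_role = rep(c("target", "reference"), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2L),
        cq = c(targ, ref),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
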