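test_that("scan_pams finds planted plus- and minus-strand sites", {
  s <- "ACGTACGTACGTACGTACGTAGG"
  hits <- scan_pams(s)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$protospacer, "ACGTACGTACGTACGTACGT")
  expect_identical(hits$pam, "AGG")
  expect_equal(c(hits$start, hits$end), c(1L, 20L))

  expect_equal(nrow(scan_pams(strrep("A", 30))), 0L)

  s2 <- paste0("CCT", strrep("A", 20))
  hits2 <- scan_pams(s2)
  expect_equal(nrow(hits2), 1L)
  expect_identical(hits2$strand, "-")
  expect_identical(hits2$protospacer, strrep("T", 20))
  expect_identical(hits2$pam, "AGG")
  expect_equal(c(hits2$start, hits2$end), c(4L, 23L))

  expect_error(scan_pams(s, 0, 23), "out of bounds")
  expect_error(scan_pams(s, 1, 24), "out of bounds")
})

test_that("scan_pams equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:20) {
    s <- random_dna(sample(200:5000, 1), gc = runif(1, 0.3, 0.6))
    got <- scan_pams(s)
    want <- oracle_scan(s)
    expect_equal(got, want)
  }
})

test_that("scan_pams excludes windows poisoned by N and honors the window", {
  s <- paste0("ACGTACGTACNTACGTACGTAGG", strrep("T", 5),
              "ACGTACGTACGTACGTACGTAGG")
  got <- scan_pams(s)
  expect_equal(got, oracle_scan(s))
  expect_false(any(grepl("N", got$protospacer)))
  # restrict window so only centers inside are kept
  set.seed(7)
  s2 <- random_dna(1500)
  full <- scan_pams(s2)
  sub <- scan_pams(s2, 400, 900)
  centers <- (full$start + full$end) / 2
  expect_equal(sub, {
    w <- full[centers >= 400 & centers <= 900, ]
    rownames(w) <- NULL
    w
  })
})

test_that("candidate sets on a sequence and its reverse complement mirror", {
  set.seed(55)
  for (i in 1:8) {
    s <- random_dna(sample(300:2000, 1))
    L <- nchar(s)
    a <- scan_pams(s)
    b <- scan_pams(reverse_complement(s))
    # reflect b back onto s coordinates and swap strands
    b2 <- data.frame(protospacer = b$protospacer, pam = b$pam,
                     strand = ifelse(b$strand == "+", "-", "+"),
                     start = L - b$end + 1L, end = L - b$start + 1L,
                     stringsAsFactors = FALSE)
    b2 <- b2[order(b2$start, b2$strand), ]
    rownames(b2) <- NULL
    expect_equal(b2, a)
  }
})

test_that("slice-back reproduces protospacer and PAM for every candidate", {
  set.seed(77)
  s <- random_dna(3000)
  hits <- scan_pams(s)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    slice <- substr(s, h$start, h$end)
    if (h$strand == "+") {
      expect_identical(slice, h$protospacer)
      expect_identical(substr(s, h$end + 1, h$end + 3), h$pam)
    } else {
      expect_identical(reverse_complement(slice), h$protospacer)
      expect_identical(reverse_complement(substr(s, h$start - 3, h$start - 1)),
                       h$pam)
    }
    expect_match(h$pam, "^[ACGT]GG$")
  }
})

test_that("classification fills orientation and half-integer TSS offsets", {
  cand <- data.frame(strand = c("+", "-"), start = c(1081L, 991L),
                     end = c(1100L, 1010L), stringsAsFactors = FALSE)
  gplus <- list(gene_id = "g", seq_id = "c1", strand = "+", tss = 1000L)
  got <- classify_candidates(cand, gplus)
  expect_identical(got$orientation, c("forward", "reverse"))
  expect_equal(got$offset, c(90.5, 0.5))

  gminus <- list(gene_id = "h", seq_id = "c1", strand = "-", tss = 2000L)
  cand2 <- data.frame(strand = "-", start = 1911L, end = 1930L,
                      stringsAsFactors = FALSE)
  got2 <- classify_candidates(cand2, gminus)
  expect_identical(got2$orientation, "forward")
  expect_equal(got2$offset, 79.5)

  expect_error(classify_candidates(cand, gplus, seq_id = "c2"),
               "does not match")
})

test_that("orientation law holds for genes on both strands", {
  for (gene_strand in c("+", "-")) {
    for (cand_strand in c("+", "-")) {
      g <- list(gene_id = "g", seq_id = "c", strand = gene_strand,
                tss = 500L)
      cand <- data.frame(strand = cand_strand, start = 601L, end = 620L,
                         stringsAsFactors = FALSE)
      got <- classify_candidates(cand, g)
      expect_identical(got$orientation,
                       if (gene_strand == cand_strand) "forward"
                       else "reverse")
    }
  }
})

test_that("scoring implements the two-peak tier rule", {
  expect_identical(score_candidate("forward", 90.5)$tier, "A")
  expect_identical(score_candidate("reverse", -5.5)$tier, "A")
  expect_identical(score_candidate("forward", 300.5)$tier, "C")
  expect_identical(score_candidate("reverse", 80.5)$tier, "B")
  # boundaries of the tier-A windows
  expect_identical(score_candidate("forward", 60)$tier, "A")
  expect_identical(score_candidate("forward", 120)$tier, "A")
  expect_identical(score_candidate("forward", 59.5)$tier, "B")
  expect_identical(score_candidate("reverse", -30)$tier, "A")
  expect_identical(score_candidate("reverse", 15)$tier, "A")
  expect_identical(score_candidate("reverse", 15.5)$tier, "B")
  # outside the broad band on the upstream side
  expect_identical(score_candidate("forward", -30.5)$tier, "C")
  # score is base minus a small distance penalty
  expect_equal(score_candidate("forward", 90.5)$score, 1 - 1e-4 * 0.5)
  expect_equal(score_candidate("reverse", -5)$score, 1)
})

test_that("tier score bands never overlap across a wide offset grid", {
  offs <- seq(-500, 500, by = 0.5)
  for (ori in c("forward", "reverse")) {
    sc <- score_candidate(rep(ori, length(offs)), offs)
    a <- sc$score[sc$tier == "A"]
    b <- sc$score[sc$tier == "B"]
    cc <- sc$score[sc$tier == "C"]
    expect_gt(min(a), max(b))
    expect_gt(min(b), max(cc))
    expect_true(all(sc$score >= 0.01 & sc$score <= 1))
  }
})

test_that("design_guides ranks a planted tier-A site over a tier-C site", {
  genes <- data.frame(gene_id = "g1", seq_id = "chr1", strand = "+",
                      tss = 1000L, stringsAsFactors = FALSE)
  plants <- data.frame(gene_id = c("g1", "g1"),
                       orientation = c("forward", "forward"),
                       offset = c(90.5, 250.5), unique = c(TRUE, TRUE),
                       stringsAsFactors = FALSE)
  fix <- generate_genome_fixture(length = 3000L, genes = genes,
                                 plants = plants, seed = 301)
  guides <- design_guides(fix$genome, fix$tss, "g1")
  expect_gt(nrow(guides), 0)
  expect_identical(guides$tier[1], "A")
  near <- guides[guides$protospacer == fix$manifest$protospacer[1], ]
  expect_identical(near$tier, "A")
  expect_equal(near$offset, 90.5)
  # the distant plant is found too, in tier C, ranked below the near one
  far <- guides[guides$protospacer == fix$manifest$protospacer[2], ]
  expect_identical(far$tier, "C")
  expect_gt(which(guides$protospacer == fix$manifest$protospacer[2]),
            which(guides$protospacer == fix$manifest$protospacer[1]))
})

test_that("design_guides output satisfies its column and ordering contract", {
  genes <- data.frame(gene_id = c("gp", "gm"), seq_id = c("chr1", "chr1"),
                      strand = c("+", "-"), tss = c(800L, 2600L),
                      stringsAsFactors = FALSE)
  fix <- generate_genome_fixture(length = 3500L, genes = genes, seed = 99)
  for (g in genes$gene_id) {
    guides <- design_guides(fix$genome, fix$tss, g)
    expect_identical(names(guides),
                     c("gene_id", "seq_id", "strand", "start", "end",
                       "protospacer", "pam", "orientation", "offset",
                       "tier", "score", "n20", "n12", "unique"))
    expect_true(all(nchar(guides$protospacer) == 20))
    expect_true(all(grepl("^[ACGT]GG$", guides$pam)))
    expect_true(all(guides$n20 >= 1))
    expect_true(all(guides$n12 >= guides$n20))
    # tiers are in sorted order and scores descend within tier
    expect_true(!is.unsorted(match(guides$tier, c("A", "B", "C"))))
    for (tier in unique(guides$tier)) {
      expect_true(!is.unsorted(-guides$score[guides$tier == tier]))
    }
    # ranking is deterministic across reruns
    expect_identical(guides, design_guides(fix$genome, fix$tss, g))
  }
})

test_that("design_guides respects top_n, unique_only, and warns when empty", {
  genes <- data.frame(gene_id = "g1", seq_id = "chr1", strand = "+",
                      tss = 1000L, stringsAsFactors = FALSE)
  fix <- generate_genome_fixture(length = 3000L, genes = genes, seed = 17)
  all_g <- design_guides(fix$genome, fix$tss, "g1")
  top5 <- design_guides(fix$genome, fix$tss, "g1", top_n = 5)
  expect_equal(nrow(top5), 5L)
  expect_identical(top5, {
    h <- all_g[1:5, ]
    class(h) <- class(top5)
    h
  })
  uniq <- design_guides(fix$genome, fix$tss, "g1", unique_only = TRUE)
  expect_true(all(uniq$n20 == 1))

  expect_error(design_guides(fix$genome, fix$tss, "nope"), "not found")

  # a window with no GG/CC context yields an empty result with a warning
  gpoor <- as_crispri_genome(c(chr1 = strrep("AT", 400)))
  tss <- data.frame(gene_id = "flat", seq_id = "chr1", strand = "+",
                    tss = 400L, stringsAsFactors = FALSE)
  expect_warning(res <- design_guides(gpoor, tss, "flat"), "no protospacer")
  expect_equal(nrow(res), 0L)
})

test_that("ties between symmetric candidates break on start coordinate", {
  # two guides with identical tier/score/|offset-peak| on opposite sides
  # of the forward peak: deterministic order by start
  genes <- data.frame(gene_id = "g1", seq_id = "chr1", strand = "+",
                      tss = 1000L, stringsAsFactors = FALSE)
  plants <- data.frame(gene_id = c("g1", "g1"),
                       orientation = c("forward", "forward"),
                       offset = c(78.5, 101.5), unique = c(TRUE, TRUE),
                       stringsAsFactors = FALSE)
  fix <- generate_genome_fixture(length = 3000L, genes = genes,
                                 plants = plants, seed = 23)
  guides <- design_guides(fix$genome, fix$tss, "g1")
  pair <- guides[guides$protospacer %in% fix$manifest$protospacer, ]
  expect_equal(nrow(pair), 2L)
  expect_equal(abs(pair$offset - 90), c(11.5, 11.5))
  expect_equal(pair$score[1], pair$score[2])
  expect_lt(pair$start[1], pair$start[2])
  expect_identical(guides, design_guides(fix$genome, fix$tss, "g1"))
})

test_that("nonstandard spacer lengths warn and propagate through the scan", {
  set.seed(5)
  g <- as_crispri_genome(c(chr1 = random_dna(600)))
  tss <- data.frame(gene_id = "g", seq_id = "chr1", strand = "+",
                    tss = 300L, stringsAsFactors = FALSE)
  expect_warning(chk <- design_guides(g, tss, "g", spacer_length = 18L),
                 "18")
  expect_true(all(nchar(chk$protospacer) == 18))
  expect_error(suppressWarnings(
    design_guides(g, tss, "g", spacer_length = 30L)), "18 and 25")
})
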