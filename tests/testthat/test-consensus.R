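test_that("barcode correction follows the distance-1 / margin-2 rule", {
  wl <- c("AAAA", "TTTT")
  expect_equal(correct_barcode("AAAA", wl), "AAAA")   # exact
  expect_equal(correct_barcode("AAAT", wl), "AAAA")   # d=1, margin 2
  expect_true(is.na(correct_barcode("AATT", wl)))     # d=2 rejected
  # margin violation: two whitelist tags both within reach
  wl2 <- c("AAAA", "AAAT")
  expect_true(is.na(correct_barcode("AAAC", wl2)))    # d1=1, d2=2, margin 1
  expect_error(correct_barcode("AAAA", character(0)), "empty")
  expect_error(correct_barcode("AAA", wl), "length")
})

test_that("family grouping partitions reads by barcode pair and shear points", {
  wl <- generate_barcode_whitelist(8, 6, seed = 1)
  mk <- function(n, u1, u2, start = 0L, end = 10L) {
    tibble::tibble(read_id = seq_len(n), target = "t", molecule = 1L,
                   start = start, end = end, strand = "x",
                   bases = strrep("A", end - start),
                   quals = strrep("I", end - start),
                   cigar = paste0(end - start, "M"), umi1 = u1, umi2 = u2)
  }
  r <- mk(6, wl[1], wl[2])
  g <- group_families(r, wl)
  expect_equal(length(unique(g$family)), 1)
  expect_equal(nrow(g), 6)

  # same barcodes, different shear points -> separate families
  r2 <- dplyr::bind_rows(mk(2, wl[1], wl[2], 0L, 10L),
                         mk(2, wl[1], wl[2], 2L, 10L))
  g2 <- group_families(r2, wl)
  expect_equal(length(unique(g2$family)), 2)

  # swapped pair orientation -> same family, opposite strands
  r3 <- dplyr::bind_rows(mk(1, wl[1], wl[2]), mk(1, wl[2], wl[1]))
  g3 <- group_families(r3, wl)
  expect_equal(length(unique(g3$family)), 1)
  expect_setequal(g3$strand, c("top", "bottom"))

  # zero reads -> empty
  g0 <- group_families(mk(0, character(0), character(0)), wl)
  expect_equal(nrow(g0), 0)

  # every read lands in exactly one family
  expect_equal(sum(table(g2$read_id)), nrow(g2))
})

# exhaustive suffix-scan oracle for the running-sum trim
trim_oracle <- function(q, threshold) {
  L <- length(q)
  scores <- vapply(1:(L + 1), function(k) {
    if (k > L) 0 else sum(q[k:L] - threshold)
  }, numeric(1))
  best <- min(scores)
  max(which(scores == best))  # ties -> shortest trim
}

test_that("quality trimming matches the exhaustive suffix-scan oracle", {
  to_qual <- function(q) intToUtf8(q + 33L)
  # unchanged when all qualities clear the threshold
  r <- quality_trim("ACGT", to_qual(rep(30, 4)), trim_quality = 20)
  expect_equal(r$bases, "ACGT")
  # fully trimmed when uniformly poor
  r <- quality_trim("ACGT", to_qual(rep(2, 4)), trim_quality = 20)
  expect_equal(r$bases, "")
  # randomised mixed tails vs oracle
  withr::with_seed(42, {
    for (i in 1:25) {
      L <- sample(5:30, 1)
      q <- sample(2:40, L, replace = TRUE)
      bases <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      got <- quality_trim(bases, to_qual(q), trim_quality = 20,
                          mask_quality = 0)
      cut <- trim_oracle(q, 20)
      expect_equal(nchar(got$bases), cut - 1)
      expect_equal(got$bases, substr(bases, 1, cut - 1))
    }
  })
})

test_that("bases below the masking quality are replaced by N", {
  q <- intToUtf8(c(40, 10, 40, 40) + 33L)
  r <- quality_trim("ACGT", q, trim_quality = 2, mask_quality = 20)
  expect_equal(r$bases, "ANGT")
})

test_that("cigar filtering keeps the plurality and rejects ties", {
  mk <- function(fam, cigars) {
    tibble::tibble(family = fam, cigar = cigars,
                   bases = strrep("A", 10), strand = "top",
                   target = "t", start = 0L, end = 10L)
  }
  r <- mk(1L, c(rep("150M", 5), "75M1I74M"))
  f <- filter_cigar_groups(r)
  expect_equal(nrow(f), 5)
  expect_true(all(f$cigar == "150M"))

  r2 <- mk(1L, rep("10M", 4))
  expect_identical(nrow(filter_cigar_groups(r2)), 4L)

  r3 <- suppressMessages(filter_cigar_groups(
    mk(1L, c(rep("10M", 3), rep("5M1D5M", 3)))))
  expect_equal(nrow(r3), 0)
  expect_equal(attr(r3, "n_families_rejected"), 1)
})

mk_family <- function(top, bottom, start = 0L) {
  n <- length(top) + length(bottom)
  w <- nchar(c(top, bottom)[1])
  tibble::tibble(
    family = 1L, target = "t", molecule = 1L,
    start = start, end = start + w,
    strand = rep(c("top", "bottom"), c(length(top), length(bottom))),
    bases = c(top, bottom), quals = strrep("I", w),
    cigar = paste0(w, "M"))
}

test_that("duplex consensus requires both strands and flags disagreements", {
  # full agreement
  fam <- mk_family(rep("ACGTACGT", 3), rep("ACGTACGT", 3))
  d <- call_duplex_consensus(fam, end_trim = 0)
  expect_equal(d$bases, "ACGTACGT")
  expect_equal(d$n_top, 3)

  # single disagreeing position becomes N
  fam2 <- mk_family(rep("ACGTACGT", 3), rep("ACGTACGA", 3))
  d2 <- call_duplex_consensus(fam2, end_trim = 0)
  expect_equal(d2$bases, "ACGTACGN")

  # no bottom strand reads -> no duplex consensus at all
  fam3 <- mk_family(rep("ACGTACGT", 4), character(0))
  expect_equal(nrow(call_duplex_consensus(fam3, end_trim = 0)), 0)

  # below min_reads_per_strand -> none
  fam4 <- mk_family(rep("ACGTACGT", 3), "ACGTACGT")
  expect_equal(nrow(call_duplex_consensus(fam4, min_reads_per_strand = 2,
                                          end_trim = 0)), 0)
})

test_that("strand consensus masks sub-threshold pluralities and ties to N", {
  fam <- mk_family(c("AAAA", "AAAA", "CAAA"), character(0))
  s <- call_strand_consensus(fam, min_agreement = 0.7)
  expect_equal(s$bases, "NAAA")
  # 2 vs 2 tie
  fam2 <- mk_family(c("AAAA", "AAAA", "CAAA", "CAAA"), character(0))
  s2 <- call_strand_consensus(fam2, min_agreement = 0.5)
  expect_equal(s2$bases, "NAAA")
  # N input bases support nothing
  fam3 <- mk_family(c("NAAA", "NAAA"), character(0))
  s3 <- call_strand_consensus(fam3, min_agreement = 0.5)
  expect_equal(s3$bases, "NAAA")
})

test_that("end trimming shortens the duplex consensus interval symmetrically", {
  fam <- mk_family(rep(strrep("ACGT", 5), 2), rep(strrep("ACGT", 5), 2),
                   start = 10L)
  d <- call_duplex_consensus(fam, end_trim = 3)
  expect_equal(d$start, 13L)
  expect_equal(d$end, 27L)
  expect_equal(d$bases, substr(strrep("ACGT", 5), 4, 17))
})

test_that("balanced overlap clipping covers the union exactly once", {
  # non-overlapping pair unchanged
  p <- tibble::tibble(start1 = 0L, end1 = 10L, start2 = 20L, end2 = 30L)
  expect_identical(clip_overlap(p), p)

  # fully overlapping pair of even length: split in half, left gets extra
  p2 <- clip_overlap(tibble::tibble(start1 = 0L, end1 = 10L,
                                    start2 = 0L, end2 = 10L))
  expect_equal(p2$end1 - p2$start1, 5)
  expect_equal(p2$start2, 5)
  # odd length: left mate keeps the extra base
  p3 <- clip_overlap(tibble::tibble(start1 = 0L, end1 = 9L,
                                    start2 = 0L, end2 = 9L))
  expect_equal(p3$end1 - p3$start1, 5)
  expect_equal(p3$end2 - p3$start2, 4)

  # partial overlap of 10: each side clipped 5; verify per-position coverage
  p4 <- clip_overlap(tibble::tibble(start1 = 0L, end1 = 20L,
                                    start2 = 10L, end2 = 30L))
  cov <- integer(30)
  cov[(p4$start1 + 1):p4$end1] <- cov[(p4$start1 + 1):p4$end1] + 1L
  cov[(p4$start2 + 1):p4$end2] <- cov[(p4$start2 + 1):p4$end2] + 1L
  expect_true(all(cov == 1))

  # randomised coverage oracle: union covered exactly once, nothing outside
  withr::with_seed(7, {
    for (i in 1:20) {
      s1 <- sample(0:20, 1); e1 <- s1 + sample(1:20, 1)
      s2 <- sample(0:20, 1); e2 <- s2 + sample(1:20, 1)
      cl <- clip_overlap(tibble::tibble(start1 = s1, end1 = e1,
                                        start2 = s2, end2 = e2))
      cov <- integer(60)
      if (cl$end1 > cl$start1) {
        cov[(cl$start1 + 1):cl$end1] <- cov[(cl$start1 + 1):cl$end1] + 1L
      }
      if (cl$end2 > cl$start2) {
        cov[(cl$start2 + 1):cl$end2] <- cov[(cl$start2 + 1):cl$end2] + 1L
      }
      union <- integer(60)
      union[(s1 + 1):e1] <- 1L
      union[(s2 + 1):e2] <- 1L
      expect_true(all(cov <= 1))
      expect_equal(sum(cov), sum(union))
    }
  })

  # bases are clipped consistently with coordinates
  p5 <- clip_overlap(tibble::tibble(start1 = 0L, end1 = 8L,
                                    start2 = 4L, end2 = 12L,
                                    bases1 = "AAAACCCC", bases2 = "CCCCGGGG"))
  expect_equal(nchar(p5$bases1), p5$end1 - p5$start1)
  expect_equal(nchar(p5$bases2), p5$end2 - p5$start2)
  expect_equal(p5$bases1, "AAAACC")
  expect_equal(p5$bases2, "CCGGGG")
})

test_that("no duplex consensus ever arises from single-strand-only families", {
  panel <- generate_reference_panel(1, 40, seed = 3)
  sc <- mutagenesis_scenario(mf = 1e-4, seed = 4)
  truth <- simulate_true_mutations(panel, sc, n_genomes = 400)
  reads <- simulate_read_families(panel, truth, n_molecules = 400L,
                                  reads_per_strand = 2,
                                  strand_dropout = 0.5, error_rate = 0,
                                  damage_rate = 0, barcode_error_rate = 0,
                                  seed = 6)
  fams <- suppressMessages(filter_cigar_groups(group_families(reads)))
  cons <- call_duplex_consensus(fams, end_trim = 0)
  strands_per_family <- tapply(fams$strand, fams$family,
                               function(s) length(unique(s)))
  expect_true(all(strands_per_family[as.character(cons$family)] == 2))
  both <- sum(strands_per_family == 2)
  expect_equal(nrow(cons), both)
})
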