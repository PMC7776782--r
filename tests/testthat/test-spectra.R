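test_that("substitution class labels enumerate pyrimidine space", {
  expect_equal(length(sbs6_classes()), 6)
  cls <- sbs96_classes()
  expect_equal(length(cls), 96)
  expect_equal(length(unique(cls)), 96)
  # exactly 6 substitution types x 16 flank combinations
  subs <- substr(cls, 3, 5)
  flanks <- paste0(substr(cls, 1, 1), substr(cls, 7, 7))
  expect_equal(sort(unique(subs)), sbs6_classes())
  expect_equal(length(unique(flanks)), 16)
  expect_equal(nrow(unique(cbind(subs, flanks))), 96)
})

test_that("pyrimidine orientation complements purine references with context", {
  o <- pyrimidine_orient("G", "T")
  expect_equal(o$class6, "C>A")
  o2 <- pyrimidine_orient("A", "T", "C", "G")
  # A>T at context C_G reverse-complements to T>A at context C_G
  expect_equal(o2$class96, "C[T>A]G")
  o3 <- pyrimidine_orient("C", "T", "A", "G")
  expect_equal(o3$class96, "A[C>T]G")
})

test_that("simple spectrum maps, normalises and rejects ref == alt", {
  panel <- toy_panel(strrep("ACGT", 15))
  one <- toy_calls(panel$target, 10L, "G", "T")
  sp <- simple_spectrum(one, panel)
  expect_equal(sp$count[sp$class == "C>A"], 1L)
  expect_equal(sum(sp$count), 1L)
  expect_equal(sum(sp$proportion), 1)

  bad <- toy_calls(panel$target, 10L, "G", "G")
  expect_error(simple_spectrum(bad, panel), "ref == alt")

  # uniform composition + equal class counts -> proportions all 1/6
  calls6 <- toy_calls(panel$target, c(1L, 2L, 3L, 5L, 6L, 7L),
                      c("C", "C", "C", "T", "T", "T"),
                      c("A", "G", "T", "A", "C", "G"))
  sp6 <- simple_spectrum(calls6, panel)
  expect_equal(sp6$proportion, rep(1 / 6, 6))
})

test_that("simple spectrum normalisation matches a direct tally on skewed bases", {
  # composition-skewed toy target: many C:G pairs, few T:A pairs
  seqs <- paste0(strrep("C", 30), strrep("G", 20), strrep("T", 10))
  panel <- toy_panel(seqs)
  calls <- toy_calls(panel$target, c(1L, 2L, 55L), c("C", "C", "T"),
                     c("A", "A", "G"))
  sp <- simple_spectrum(calls, panel)
  # brute force: counts / pyrimidine-pair abundance, renormalised
  n_c <- 30 + 20   # C + G
  n_t <- 10 + 0    # T + A
  w <- c("C>A" = 2 / n_c, "T>G" = 1 / n_t)
  expect_equal(sp$proportion[sp$class == "C>A"],
               unname(w["C>A"] / sum(w)))
  expect_equal(sp$proportion[sp$class == "T>G"],
               unname(w["T>G"] / sum(w)))
})

test_that("pyrimidine-space spectrum is invariant under strand complementation", {
  panel <- generate_reference_panel(1, 200, seed = 8)
  sc <- mutagenesis_scenario(mf = 2e-3, seed = 12)
  truth <- simulate_true_mutations(panel, sc, n_genomes = 100)
  calls <- toy_calls(truth$target, truth$pos, truth$ref, truth$alt)
  flipped <- calls
  flipped$ref <- chartr("ACGT", "TGCA", calls$ref)
  flipped$alt <- chartr("ACGT", "TGCA", calls$alt)
  sp1 <- simple_spectrum(calls, panel)
  sp2 <- simple_spectrum(flipped, panel)
  expect_equal(sp1$proportion, sp2$proportion)
})

test_that("trinucleotide spectrum drops boundary calls and matches brute force", {
  seqs <- paste0("AC", strrep("GTCA", 14), "GT")
  panel <- toy_panel(seqs)
  L <- nchar(seqs)
  calls <- toy_calls(panel$target,
                     c(0L, as.integer(L - 1), 5L, 9L, 20L, 21L, 33L),
                     c("A", "T", "A", "A", "C", "A", "A"),
                     c("T", "A", "G", "C", "A", "C", "T"))
  expect_message(sp <- trinucleotide_spectrum(calls, panel), "2 boundary")
  expect_equal(sum(sp$count), 5L)
  expect_equal(sum(sp$proportion), 1)

  # independent brute-force tally: context/class by hand per interior call
  ch <- strsplit(seqs, "")[[1]]
  brute <- setNames(numeric(96), sbs96_classes())
  for (i in 3:7) {
    p <- calls$pos[i]
    ref <- ch[p + 1]; alt <- calls$alt[i]
    p5 <- ch[p]; p3 <- ch[p + 2]
    if (ref %in% c("A", "G")) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      lab <- paste0(comp[p3], "[", comp[ref], ">", comp[alt], "]", comp[p5])
    } else {
      lab <- paste0(p5, "[", ref, ">", alt, "]", p3)
    }
    brute[lab] <- brute[lab] + 1
  }
  expect_equal(setNames(as.numeric(sp$count), sp$class), brute)

  # brute-force double-stranded 3-mer abundance for the normalisation
  revcomp <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  tri_all <- substring(seqs, 1:(L - 2), 3:L)
  ab_brute <- vapply(names(context_abundance(panel)), function(ctx) {
    sum(tri_all == ctx) + sum(tri_all == revcomp(ctx))
  }, numeric(1))
  expect_equal(context_abundance(panel), ab_brute)

  # normalised proportions equal count/abundance renormalised
  ctx_of <- paste0(substr(sp$class, 1, 1), substr(sp$class, 3, 3),
                   substr(sp$class, 7, 7))
  w <- brute / ab_brute[ctx_of]
  w[!is.finite(w)] <- 0
  expect_equal(sp$proportion, unname(w / sum(w)))
})

test_that("empty call set yields an unnormalisable zero spectrum", {
  panel <- toy_panel(strrep("ACGT", 10))
  sp <- trinucleotide_spectrum(toy_calls(character(0), integer(0),
                                         character(0), character(0)), panel)
  expect_equal(nrow(sp), 96)
  expect_true(all(sp$proportion == 0))
  expect_false(attr(sp, "normalized"))
})

test_that("strand bias recovers an unbiased generator and flags nontranscribed", {
  panel <- generate_reference_panel(2, 2000, seed = 14,
                                    transcribed = c(TRUE, FALSE))
  sc <- mutagenesis_scenario(mf = 5e-4, strand_bias_factor = 1, seed = 3)
  truth <- simulate_true_mutations(panel, sc, n_genomes = 2000)
  calls <- toy_calls(truth$target, truth$pos, truth$ref, truth$alt)
  sb <- strand_bias(calls, panel)
  tr <- sb[sb$target == panel$target[1], ]
  expect_true(all(tr$applicable))
  ok <- !is.na(tr$fold)
  # folds scatter around 1 (each 95% CI may individually just miss it)
  expect_true(all(tr$fold[ok] > 0.5 & tr$fold[ok] < 2))
  expect_gte(mean(tr$ci_lo[ok] <= 1 & 1 <= tr$ci_hi[ok]), 10 / 12)
  nt <- sb[sb$target == panel$target[2], ]
  expect_true(all(!nt$applicable))
  expect_true(all(is.na(nt$fold)))
})

test_that("strand bias recovers the generator suppression factor", {
  panel <- generate_reference_panel(1, 3000, seed = 15, transcribed = TRUE)
  sc <- mutagenesis_scenario(mf = 1e-3, strand_bias_factor = 10, seed = 23)
  truth <- simulate_true_mutations(panel, sc, n_genomes = 3000)
  calls <- toy_calls(truth$target, truth$pos, truth$ref, truth$alt)
  sb <- strand_bias(calls, panel)
  # purine-reference rows on the transcribed strand should be ~10x their
  # pyrimidine reciprocals; check T>A vs A>T specifically
  row <- sb[sb$sub == "A>T", ]
  expect_true(row$ci_lo <= 10 & 10 <= row$ci_hi)
  # and the aggregate purine:pyrimidine count ratio is near the factor
  pur <- sum(sb$count[substr(sb$sub, 1, 1) %in% c("A", "G")])
  pyr <- sum(sb$count[substr(sb$sub, 1, 1) %in% c("C", "T")])
  expect_gt(pur / pyr, 5)
})

test_that("consequence annotation follows the genetic code", {
  # frame 0 coding target: TAC GAA ATG CTG ...
  seqs <- paste0("TACGAAATGCTG", strrep("ACGTT", 8))
  panel <- toy_panel(seqs, frame_offset = 0L)
  calls <- toy_calls(panel$target,
                     c(2L, 11L, 8L),
                     c("C", "G", "G"),
                     c("A", "A", "A"))
  ann <- annotate_consequence(calls, panel)
  expect_equal(ann$consequence[1], "nonsense")    # TAC -> TAA
  expect_equal(ann$consequence[2], "synonymous")  # CTG -> CTA (Leu)
  expect_equal(ann$consequence[3], "missense")    # ATG -> ATA (Met->Ile)

  # noncoding target
  nc <- toy_panel(seqs, frame_offset = NA_integer_)
  expect_equal(annotate_consequence(calls, nc)$consequence,
               rep("noncoding", 3))

  # minus-strand coding: the codon is read on the reverse complement
  minus <- toy_panel(seqs, transcribed = TRUE, transcribed_strand = "minus",
                     frame_offset = 0L)
  ann_m <- annotate_consequence(toy_calls(minus$target, 2L, "C", "A"), minus)
  expect_true(ann_m$consequence %in%
                c("synonymous", "missense", "nonsense", "unclassified"))
})

test_that("uniform coding mutations match the genetic-code dN/dS expectation", {
  panel <- generate_reference_panel(1, 3000, seed = 33, frame_offset = 0L)
  sc <- mutagenesis_scenario(mf = 1e-3, seed = 17)
  truth <- simulate_true_mutations(panel, sc, n_genomes = 2000)
  calls <- toy_calls(truth$target, truth$pos, truth$ref, truth$alt)
  ann <- annotate_consequence(calls, panel)
  coding <- ann$consequence %in% c("synonymous", "missense", "nonsense")
  obs_syn <- mean(ann$consequence[coding] == "synonymous")
  # expectation: enumerate all 9 possible substitutions of every complete
  # codon position in the target and tally synonymous changes
  gc_tab <- Biostrings::GENETIC_CODE
  ch <- strsplit(panel$sequence, "")[[1]]
  n_syn <- 0; n_all <- 0
  for (cs in seq(1, length(ch) - 2, by = 3)) {
    codon <- paste(ch[cs:(cs + 2)], collapse = "")
    for (k in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[cs + k - 1])) {
      alt <- codon
      substr(alt, k, k) <- b
      n_all <- n_all + 1
      if (gc_tab[[codon]] == gc_tab[[alt]]) n_syn <- n_syn + 1
    }
  }
  expected <- n_syn / n_all
  se <- sqrt(expected * (1 - expected) / sum(coding))
  expect_lt(abs(obs_syn - expected), 4 * se)
})

test_that("chi-square spectrum test behaves at the extremes and by hand", {
  a <- c(30, 20, 10, 25, 30, 40)
  expect_gt(chi_square_spectrum_test(a, a)$p_value, 0.99)

  div <- chi_square_spectrum_test(c(50, 0), c(0, 50))
  expect_lt(div$p_value, 0.01)

  # hand-computed toy statistic
  x <- c(10, 20, 30)
  y <- c(30, 20, 10)
  res <- chi_square_spectrum_test(x, y, min_expected = 5)
  tot <- x + y
  e_x <- tot * sum(x) / (sum(x) + sum(y))
  e_y <- tot * sum(y) / (sum(x) + sum(y))
  stat_hand <- sum((x - e_x)^2 / e_x) + sum((y - e_y)^2 / e_y)
  expect_equal(res$statistic, stat_hand)

  # sparse classes are pooled before testing
  pooled <- chi_square_spectrum_test(c(100, 1, 1, 1), c(100, 1, 1, 1))
  expect_equal(pooled$n_classes_tested, 2)

  expect_error(chi_square_spectrum_test(c(0, 0), c(0, 0)), "all-zero")
})
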