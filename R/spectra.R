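#' Pyrimidine-space context abundance of a panel
#'
#' Counts, over the given target sequences, the abundance of each
#' pyrimidine-centred trinucleotide context on both strands (each position
#' contributes its context once and its reverse complement once), via
#' Biostrings 3-mer counting. Used to normalise 96-class spectra.
#'
#' @param panel Panel tibble (or subset of rows).
#' @return Named numeric vector over the 32 pyrimidine-centred contexts.
#' @export
context_abundance <- function(panel) {
  seqs <- Biostrings::DNAStringSet(panel$sequence)
  tri <- colSums(Biostrings::trinucleotideFrequency(seqs))
  cls <- sbs96_classes()
  # "A[C>A]G" -> context "ACG"; centre base is always a pyrimidine
  ctx <- unique(paste0(substr(cls, 1, 1), substr(cls, 3, 3),
                       substr(cls, 7, 7)))
  # plus-strand occurrences of the context plus its reverse complement
  ab <- tri[ctx] + tri[dna_revcomp(ctx)]
  setNames(as.numeric(ab), ctx)
}

#' Pyrimidine base abundance (both strands) of a panel
#' @noRd
pyrimidine_abundance <- function(panel) {
  seqs <- Biostrings::DNAStringSet(panel$sequence)
  f <- colSums(Biostrings::alphabetFrequency(seqs)[, DNA_BASES, drop = FALSE])
  c(C = unname(f["C"] + f["G"]), T = unname(f["T"] + f["A"]))
}

#' @noRd
new_spectrum <- function(df, n_classes, normalized, dropped = 0L) {
  structure(df, class = c("mut_spectrum", class(df)),
            n_classes = n_classes, normalized = normalized,
            dropped_calls = dropped)
}

#' Simple (6-class) base substitution spectrum
#'
#' Maps every SNV call into pyrimidine space (purine-reference calls are
#' complemented) and tallies the six substitution types. Counts are divided
#' by the abundance of the pyrimidine reference base over both strands of
#' the panel ("normalising by the frequencies of nucleotides in the target
#' region") and renormalised to sum to 1. Each call counts as one event.
#'
#' @param calls SNV call tibble (`ref`, `alt` single bases; `ref != alt`).
#' @param panel Panel tibble (the territory the calls were made in).
#' @return A `mut_spectrum` tibble: `class`, `count`, `proportion`. An empty
#'   call set yields zero proportions and the attribute
#'   `normalized = FALSE`.
#' @export
simple_spectrum <- function(calls, panel) {
  check_panel(panel)
  if (nrow(calls) > 0 && any(calls$ref == calls$alt)) {
    abort("calls with ref == alt are not substitutions")
  }
  cls <- sbs6_classes()
  counts <- setNames(numeric(6), cls)
  if (nrow(calls) > 0) {
    ori <- pyrimidine_orient(calls$ref, calls$alt)
    tab <- table(factor(ori$class6, levels = cls))
    counts <- as.numeric(tab)
    names(counts) <- cls
  }
  ab <- pyrimidine_abundance(panel)
  weights <- counts / ab[substr(cls, 1, 1)]
  total <- sum(weights)
  prop <- if (total > 0) weights / total else rep(0, 6)
  new_spectrum(tibble(class = cls, count = as.integer(counts),
                      proportion = unname(prop)),
               n_classes = 6L, normalized = total > 0)
}

#' Trinucleotide (96-class) substitution spectrum
#'
#' Builds the 96-class substitution-in-context spectrum: each SNV is placed
#' in pyrimidine orientation with its 5' and 3' flanking reference bases
#' (context reverse-complemented for purine references). Calls at the first
#' or last base of a target lack a flanking context and are excluded (and
#' counted in the `dropped_calls` attribute). Class counts are divided by
#' the double-stranded context abundance of the panel and renormalised to
#' sum to 1.
#'
#' @inheritParams simple_spectrum
#' @return A `mut_spectrum` tibble with 96 rows: `class`, `count`,
#'   `proportion`.
#' @export
trinucleotide_spectrum <- function(calls, panel) {
  check_panel(panel)
  cls <- sbs96_classes()
  dropped <- 0L
  counts <- setNames(numeric(96), cls)
  if (nrow(calls) > 0) {
    idx <- match(calls$target, panel$target)
    if (anyNA(idx)) abort("calls reference targets absent from the panel")
    rel <- calls$pos - panel$start[idx]
    len <- panel$end[idx] - panel$start[idx]
    interior <- rel >= 1 & rel <= len - 2
    dropped <- sum(!interior)
    if (dropped > 0) {
      inform(sprintf(
        "trinucleotide_spectrum: %d boundary call(s) without context dropped",
        dropped))
    }
    calls <- calls[interior, , drop = FALSE]
    idx <- idx[interior]; rel <- rel[interior]
    if (nrow(calls) > 0) {
      p5 <- substr(panel$sequence[idx], rel, rel)
      p3 <- substr(panel$sequence[idx], rel + 2, rel + 2)
      ori <- pyrimidine_orient(calls$ref, calls$alt, p5, p3)
      tab <- table(factor(ori$class96, levels = cls))
      counts <- setNames(as.numeric(tab), cls)
    }
  }
  ab <- context_abundance(panel)
  ctx_of <- paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7))
  weights <- counts / ab[ctx_of]
  weights[!is.finite(weights)] <- 0
  total <- sum(weights)
  prop <- if (total > 0) weights / total else rep(0, 96)
  new_spectrum(tibble(class = cls, count = as.integer(counts),
                      proportion = unname(prop)),
               n_classes = 96L, normalized = total > 0, dropped = dropped)
}

#' Combine spectra into a sample-by-class matrix
#'
#' @param spectra Named list of `mut_spectrum` tibbles with identical class
#'   labels.
#' @param value `"proportion"` (default) or `"count"`.
#' @return Wide tibble: `sample` column plus one column per class.
#' @export
bind_spectra <- function(spectra, value = c("proportion", "count")) {
  value <- match.arg(value)
  stopifnot(length(spectra) >= 1, !is.null(names(spectra)))
  cls <- spectra[[1]]$class
  rows <- purrr::imap(spectra, function(sp, nm) {
    stopifnot(identical(sp$class, cls))
    setNames(as.list(sp[[value]]), cls)
  })
  dplyr::bind_cols(tibble(sample = names(spectra)),
                   dplyr::bind_rows(rows))
}

#' Reciprocal substitution strand bias
#'
#' For each target with a defined transcribed strand, orients every SNV onto
#' the forward direction of the transcribed strand and compares the
#' mutant frequency of each of the 12 substitution types against its
#' reciprocal (complement) substitution. Frequencies are corrected for the
#' abundance of each reference base on the oriented strand, optionally
#' scaled by the mean per-base duplex depth. The fold difference and its
#' 95% CI come from the exact conditional rate-ratio test
#' ([stats::poisson.test()]); a zero reciprocal count reports `NA` fold with
#' the one-sided CI rather than infinity. Nontranscribed targets are
#' returned flagged not applicable.
#'
#' @param calls SNV call tibble.
#' @param panel Panel tibble.
#' @param mean_depth Mean per-base duplex depth used to scale counts into
#'   per-nucleotide frequencies (default 1: relative frequencies).
#' @return Tibble per (target, substitution type): `target`, `sub`,
#'   `reciprocal`, `count`, `reciprocal_count`, `mf`, `reciprocal_mf`,
#'   `fold`, `ci_lo`, `ci_hi`, `applicable`.
#' @export
strand_bias <- function(calls, panel, mean_depth = 1) {
  check_panel(panel)
  subs12 <- {
    refs <- rep(DNA_BASES, each = 3)
    alts <- unlist(lapply(DNA_BASES, function(r) setdiff(DNA_BASES, r)))
    paste0(refs, ">", alts)
  }
  recip <- function(s) {
    paste0(dna_complement(substr(s, 1, 1)), ">",
           dna_complement(substr(s, 3, 3)))
  }
  out <- vector("list", 0)
  for (t in seq_len(nrow(panel))) {
    row <- panel[t, ]
    if (row$transcribed_strand == "none") {
      out[[length(out) + 1]] <- tibble(
        target = row$target, sub = subs12, reciprocal = recip(subs12),
        count = NA_integer_, reciprocal_count = NA_integer_,
        mf = NA_real_, reciprocal_mf = NA_real_, fold = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, applicable = FALSE)
      next
    }
    sub_calls <- calls[calls$target == row$target, , drop = FALSE]
    flip <- row$transcribed_strand == "minus"
    ref_o <- if (flip) dna_complement(sub_calls$ref) else sub_calls$ref
    alt_o <- if (flip) dna_complement(sub_calls$alt) else sub_calls$alt
    seq_o <- if (flip) dna_complement(row$sequence) else row$sequence
    base_n <- table(factor(strsplit(seq_o, "", fixed = TRUE)[[1]],
                           levels = DNA_BASES))
    cnt <- table(factor(paste0(ref_o, ">", alt_o), levels = subs12))
    res <- tibble(target = row$target, sub = subs12,
                  reciprocal = recip(subs12),
                  count = as.integer(cnt[subs12]))
    res$reciprocal_count <- res$count[match(res$reciprocal, res$sub)]
    denom <- as.numeric(base_n[substr(subs12, 1, 1)]) * mean_depth
    denom_r <- as.numeric(base_n[substr(res$reciprocal, 1, 1)]) * mean_depth
    res$mf <- res$count / denom
    res$reciprocal_mf <- res$reciprocal_count / denom_r
    ci <- t(vapply(seq_len(nrow(res)), function(i) {
      if (res$count[i] == 0 && res$reciprocal_count[i] == 0) {
        return(c(0, Inf))
      }
      pt <- poisson.test(c(res$count[i], res$reciprocal_count[i]),
                         c(denom[i], denom_r[i]))
      pt$conf.int
    }, numeric(2)))
    res$fold <- ifelse(res$reciprocal_count == 0, NA_real_,
                       res$mf / res$reciprocal_mf)
    res$ci_lo <- ci[, 1]
    res$ci_hi <- ci[, 2]
    res$applicable <- TRUE
    out[[length(out) + 1]] <- res
  }
  dplyr::bind_rows(out)
}

#' Annotate coding consequences of SNV calls
#'
#' Applies each substitution to its reference codon (reading frame given by
#' the target's `frame_offset`, on the transcribed strand when that is
#' `minus`) and classifies it under the standard genetic code: stop gain is
#' `nonsense`, an amino acid change `missense`, otherwise `synonymous`.
#' Targets without a reading frame give `noncoding`; incomplete codons or
#' ambiguous bases give `unclassified`.
#'
#' @param calls SNV call tibble.
#' @param panel Panel tibble.
#' @return `calls` with a `consequence` column.
#' @export
annotate_consequence <- function(calls, panel) {
  check_panel(panel)
  gc_tab <- Biostrings::GENETIC_CODE
  consequence <- character(nrow(calls))
  idx <- match(calls$target, panel$target)
  for (i in seq_len(nrow(calls))) {
    row <- panel[idx[i], ]
    if (is.na(row$frame_offset)) { consequence[i] <- "noncoding"; next }
    L <- row$end - row$start
    rel <- calls$pos[i] - row$start
    minus <- identical(row$transcribed_strand, "minus")
    if (minus) rel <- L - 1L - rel
    seq_o <- if (minus) dna_revcomp(row$sequence) else row$sequence
    ref_o <- if (minus) dna_complement(calls$ref[i]) else calls$ref[i]
    alt_o <- if (minus) dna_complement(calls$alt[i]) else calls$alt[i]
    cs <- row$frame_offset + 3L * floor((rel - row$frame_offset) / 3)
    if (cs < 0 || cs + 3 > L) { consequence[i] <- "unclassified"; next }
    codon <- substr(seq_o, cs + 1L, cs + 3L)
    if (grepl("[^ACGT]", codon) || !alt_o %in% DNA_BASES) {
      consequence[i] <- "unclassified"; next
    }
    alt_codon <- codon
    substr(alt_codon, rel - cs + 1L, rel - cs + 1L) <- alt_o
    aa_ref <- gc_tab[[codon]]
    aa_alt <- gc_tab[[alt_codon]]
    consequence[i] <-
      if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else "missense"
  }
  calls$consequence <- consequence
  calls
}

#' Chi-square comparison of two spectra
#'
#' Pearson chi-square test of homogeneity between two spectra given as raw
#' class counts. Classes whose expected count under homogeneity falls below
#' `min_expected` in either group are pooled into a single `other` class
#' before testing, honouring the usual validity rule.
#'
#' @param a,b Numeric count vectors over identical classes, or
#'   `mut_spectrum` tibbles.
#' @param min_expected Minimum expected count per retained class.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_classes_tested`.
#' @export
chi_square_spectrum_test <- function(a, b, min_expected = 5) {
  if (is.data.frame(a)) a <- setNames(a$count, a$class)
  if (is.data.frame(b)) b <- setNames(b$count, b$class)
  stopifnot(length(a) == length(b))
  if (sum(a) + sum(b) == 0) abort("both spectra are all-zero")
  tot <- a + b
  N <- sum(tot)
  # expected counts under homogeneity for each class and group
  e_a <- tot * sum(a) / N
  e_b <- tot * sum(b) / N
  sparse <- pmin(e_a, e_b) < min_expected
  if (any(sparse)) {
    a <- c(a[!sparse], other = sum(a[sparse]))
    b <- c(b[!sparse], other = sum(b[sparse]))
  }
  keep <- (a + b) > 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) {
    return(tibble(statistic = 0, df = 0L, p_value = 1,
                  n_classes_tested = length(a)))
  }
  ct <- suppressWarnings(chisq.test(rbind(a, b), correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = as.integer(ct$parameter),
         p_value = unname(ct$p.value), n_classes_tested = length(a))
}
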