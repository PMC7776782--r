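BASE_CODE <- local({
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("N")] <- 5L
  code
})
CODE_BASE <- c("A", "C", "G", "T", "N")

#' Equal-width strings to integer code matrix (rows = strings)
#' @noRd
dna_code_matrix <- function(strings) {
  w <- nchar(strings[1])
  ints <- utf8ToInt(paste(strings, collapse = ""))
  matrix(BASE_CODE[ints], ncol = w, byrow = TRUE)
}

#' Correct observed UMI tags against a whitelist
#'
#' Implements the standard UMI rescue rule for semidegenerate duplex
#' adapters: an observed tag is corrected to the unique whitelist tag within
#' `max_mismatch` Hamming distance whose margin to the next-best whitelist
#' tag is at least `min_margin`; otherwise it is rejected (`NA`).
#'
#' @param observed Character vector of observed tags (all the same length as
#'   the whitelist tags).
#' @param whitelist Character vector of known tags.
#' @param max_mismatch Maximum accepted Hamming distance (default 1).
#' @param min_margin Minimum distance margin to the second-best tag
#'   (default 2).
#'
#' @return Character vector: corrected tag or `NA` where rejected.
#' @export
#' @examples
#' correct_barcode(c("AAAA", "AAAT", "AATT"), c("AAAA", "TTTT"))
correct_barcode <- function(observed, whitelist,
                            max_mismatch = 1, min_margin = 2) {
  if (length(whitelist) == 0) abort("`whitelist` must not be empty")
  if (any(nchar(whitelist) != nchar(whitelist[1])) ||
      any(nchar(observed) != nchar(whitelist[1]))) {
    abort("all tags must have the same length")
  }
  out <- whitelist[match(observed, whitelist)]   # exact-match fast path
  todo <- which(is.na(out))
  if (length(todo) == 0) return(out)

  uniq <- unique(observed[todo])
  wl_mat <- dna_code_matrix(whitelist)           # n_wl x len
  res <- vapply(uniq, function(tag) {
    d <- rowSums(wl_mat != rep(BASE_CODE[utf8ToInt(tag)],
                               each = nrow(wl_mat)))
    o <- order(d)
    d1 <- d[o[1]]
    d2 <- if (length(d) > 1) d[o[2]] else Inf
    if (d1 <= max_mismatch && (d2 - d1) >= min_margin) whitelist[o[1]]
    else NA_character_
  }, character(1))
  out[todo] <- res[match(observed[todo], uniq)]
  out
}

#' Group reads into duplex families
#'
#' Corrects both UMI tags of every read against the whitelist, drops reads
#' with an uncorrectable tag (counted, never silent), and partitions the
#' remainder into families keyed by the corrected barcode pair (unordered)
#' together with the fragment shear points. Strand assignment follows
#' barcode-pair orientation: reads observing the pair in one order are the
#' `top` strand, reads observing it reversed are the `bottom` strand. Reads
#' whose two tags are identical cannot be oriented and are dropped.
#'
#' @param reads Read tibble with columns `target`, `start`, `end`, `bases`,
#'   `quals`, `cigar`, `umi1`, `umi2`.
#' @param whitelist Barcode whitelist (defaults to the `whitelist` attribute
#'   of `reads`).
#' @inheritParams correct_barcode
#'
#' @return The retained reads with added columns `family` (integer id) and
#'   `strand`; attributes `n_rejected` (uncorrectable tags) and
#'   `n_unoriented` (identical tag pairs).
#' @export
group_families <- function(reads, whitelist = attr(reads, "whitelist"),
                           max_mismatch = 1, min_margin = 2) {
  if (is.null(whitelist)) abort("`whitelist` is required")
  u1 <- correct_barcode(reads$umi1, whitelist, max_mismatch, min_margin)
  u2 <- correct_barcode(reads$umi2, whitelist, max_mismatch, min_margin)
  ok <- !is.na(u1) & !is.na(u2)
  n_rejected <- sum(!ok)
  same <- ok & u1 == u2
  n_unoriented <- sum(same)
  keep <- ok & !same
  out <- reads[keep, , drop = FALSE]
  u1 <- u1[keep]; u2 <- u2[keep]
  lo <- pmin(u1, u2)
  hi <- pmax(u1, u2)
  key <- paste(out$target, out$start, out$end, lo, hi, sep = "\r")
  out$family <- match(key, unique(key))
  out$strand <- ifelse(u1 == lo, "top", "bottom")
  out$umi1 <- u1
  out$umi2 <- u2
  if (n_rejected + n_unoriented > 0) {
    inform(sprintf(
      "group_families: dropped %d read(s) with uncorrectable tags, %d unorientable",
      n_rejected, n_unoriented))
  }
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_unoriented") <- n_unoriented
  attr(out, "whitelist") <- whitelist
  out
}

#' Quality trimming and masking
#'
#' 3' quality trimming by the running-sum rule: over all suffixes (including
#' the empty suffix, score 0) the cut point is placed at the suffix
#' minimising the running sum of `quality - trim_quality` accumulated from
#' the 3' end; ties are broken toward the shorter trim. Afterwards every
#' remaining base with quality below `mask_quality` is masked to `N`.
#'
#' @param bases,quals Equal-length character vectors (Phred+33 qualities).
#' @param trim_quality Threshold for the running-sum trim.
#' @param mask_quality Bases below this quality are masked to `N`.
#'
#' @return Tibble with trimmed `bases` and `quals`.
#' @export
#' @examples
#' quality_trim("ACGT", "IIII")          # unchanged
#' quality_trim("ACGT", "II##")$bases    # low-quality tail trimmed
quality_trim <- function(bases, quals, trim_quality = 20, mask_quality = 20) {
  stopifnot(length(bases) == length(quals),
            all(nchar(bases) == nchar(quals)))
  n <- length(bases)
  out_b <- character(n)
  out_q <- character(n)
  by_len <- split(seq_len(n), nchar(bases))
  for (grp in by_len) {
    L <- nchar(bases[grp[1]])
    if (L == 0) { out_b[grp] <- ""; out_q[grp] <- ""; next }
    qm <- matrix(utf8ToInt(paste(quals[grp], collapse = "")) - 33L,
                 ncol = L, byrow = TRUE)
    # suffix running sums S[, k] = sum_{i >= k} (q_i - T); S(L+1) = 0
    S <- matrix(0, nrow = length(grp), ncol = L + 1L)
    for (k in L:1) S[, k] <- S[, k + 1L] + (qm[, k] - trim_quality)
    minS <- S[, L + 1L]
    cut <- rep(L + 1L, length(grp))
    for (k in L:1) {                      # prefer larger k (shorter trim)
      better <- S[, k] < minS
      minS[better] <- S[better, k]
      cut[better] <- k
    }
    b <- substr(bases[grp], 1L, cut - 1L)
    q <- substr(quals[grp], 1L, cut - 1L)
    # mask low-quality bases anywhere
    if (any(cut > 1L)) {
      bm <- strsplit(b, "", fixed = TRUE)
      qs <- strsplit(q, "", fixed = TRUE)
      for (i in seq_along(grp)) {
        if (length(qs[[i]]) == 0) next
        low <- (utf8ToInt(q[i]) - 33L) < mask_quality
        if (any(low)) {
          ch <- bm[[i]]
          ch[low] <- "N"
          b[i] <- paste(ch, collapse = "")
        }
      }
    }
    out_b[grp] <- b
    out_q[grp] <- q
  }
  tibble(bases = out_b, quals = out_q)
}

#' Remove cigar-discordant reads from families
#'
#' Within each family, keeps only reads whose cigar matches the family's
#' plurality cigar; families whose plurality is tied are rejected entirely
#' (artifactual indels in a subset of reads poison the positional alignment
#' of a family, and a tie leaves no trustworthy majority).
#'
#' @param reads Grouped read tibble (from [group_families()]) with `family`
#'   and `cigar` columns.
#' @return Filtered tibble; attribute `n_families_rejected` counts tied
#'   families.
#' @export
filter_cigar_groups <- function(reads) {
  tab <- reads |>
    dplyr::count(family, cigar, name = "n_reads") |>
    dplyr::group_by(family) |>
    dplyr::summarise(
      top = max(n_reads),
      tie = sum(n_reads == max(n_reads)) > 1,
      best = cigar[which.max(n_reads)],
      .groups = "drop")
  rejected <- tab$family[tab$tie]
  keep_map <- setNames(tab$best, as.character(tab$family))
  out <- reads[!(reads$family %in% rejected) &
                 reads$cigar == keep_map[as.character(reads$family)], ,
               drop = FALSE]
  if (length(rejected) > 0) {
    inform(sprintf("filter_cigar_groups: rejected %d tied family(ies)",
                   length(rejected)))
  }
  attr(out, "n_families_rejected") <- length(rejected)
  attr(out, "whitelist") <- attr(reads, "whitelist")
  out
}

#' Per-strand consensus of read families
#'
#' Collapses each (family, strand) read group into a single-strand consensus
#' by per-position plurality: the plurality base is emitted when its
#' supporting fraction of the strand's reads is at least `min_agreement` and
#' it is not tied; otherwise `N`. `N` bases in input reads support nothing.
#' All reads of a family must share fragment coordinates (guaranteed by
#' grouping on shear points).
#'
#' @param reads Grouped (and cigar-filtered) read tibble.
#' @param min_agreement Minimum plurality fraction.
#' @return Tibble: `family`, `strand`, `target`, `start`, `end`, `bases`,
#'   `n_reads` (plus `molecule` when present in the input).
#' @export
call_strand_consensus <- function(reads, min_agreement = 0.7) {
  if (nrow(reads) == 0) {
    return(tibble(family = integer(), strand = character(),
                  target = character(), start = integer(), end = integer(),
                  bases = character(), n_reads = integer()))
  }
  out <- vector("list", 0)
  by_len <- split(seq_len(nrow(reads)), nchar(reads$bases))
  for (grp in by_len) {
    sub <- reads[grp, , drop = FALSE]
    L <- nchar(sub$bases[1])
    key <- paste(sub$family, sub$strand, sep = "\r")
    g <- match(key, unique(key))
    G <- max(g)
    M <- dna_code_matrix(sub$bases)
    n_reads <- tabulate(g, G)
    counts <- lapply(1:4, function(b) rowsum((M == b) + 0L, g))
    top <- counts[[1]]
    top_base <- matrix(1L, nrow = G, ncol = L)
    for (b in 2:4) {
      better <- counts[[b]] > top
      top[better] <- counts[[b]][better]
      top_base[better] <- b
    }
    # tie: a second base reaches the top count
    n_at_top <- (counts[[1]] == top) + (counts[[2]] == top) +
      (counts[[3]] == top) + (counts[[4]] == top)
    frac <- top / n_reads
    is_n <- top == 0 | n_at_top > 1 | frac < min_agreement
    top_base[is_n] <- 5L
    first <- match(unique(key), key)
    cons <- vapply(seq_len(G), function(i) {
      paste(CODE_BASE[top_base[i, ]], collapse = "")
    }, character(1))
    res <- tibble(
      family = sub$family[first],
      strand = sub$strand[first],
      target = sub$target[first],
      start = sub$start[first],
      end = sub$end[first],
      bases = cons,
      n_reads = n_reads
    )
    if ("molecule" %in% names(sub)) res$molecule <- sub$molecule[first]
    out <- c(out, list(res))
  }
  dplyr::bind_rows(out)
}

#' Duplex consensus calling
#'
#' Produces one duplex consensus read per family that has a qualifying
#' single-strand consensus on **both** strands; families with reads on only
#' one strand (or below `min_reads_per_strand` on either) yield nothing —
#' the defining contract of duplex sequencing. A duplex base is emitted only
#' where the two strand consensuses agree and neither is `N`; disagreements
#' become `N`. Consensus reads are finally end-trimmed by `end_trim` bases
#' on each side (fragment termini carry residual artifacts from end repair).
#'
#' @param reads Grouped, cigar-filtered read tibble.
#' @param min_reads_per_strand Minimum reads required on each strand.
#' @param min_family_agreement Plurality fraction for strand consensus.
#' @param end_trim Bases trimmed from each end of the duplex consensus.
#' @return Tibble: `family`, `target`, `start`, `end`, `bases`, `n_top`,
#'   `n_bottom` (plus `molecule` when present). Families failing the duplex
#'   requirement are absent.
#' @export
call_duplex_consensus <- function(reads, min_reads_per_strand = 1,
                                  min_family_agreement = 0.7,
                                  end_trim = 5L) {
  ssc <- call_strand_consensus(reads, min_agreement = min_family_agreement)
  ssc <- ssc[ssc$n_reads >= min_reads_per_strand, , drop = FALSE]
  if (nrow(ssc) == 0) return(empty_duplex())
  top <- ssc[ssc$strand == "top", , drop = FALSE]
  bot <- ssc[ssc$strand == "bottom", , drop = FALSE]
  common <- intersect(top$family, bot$family)
  if (length(common) == 0) return(empty_duplex())
  top <- top[match(common, top$family), ]
  bot <- bot[match(common, bot$family), ]

  out <- vector("list", 0)
  by_len <- split(seq_along(common), nchar(top$bases))
  for (grp in by_len) {
    Mt <- dna_code_matrix(top$bases[grp])
    Mb <- dna_code_matrix(bot$bases[grp])
    agree <- Mt == Mb & Mt != 5L
    Md <- ifelse(agree, Mt, 5L)
    cons <- vapply(seq_len(nrow(Md)), function(i) {
      paste(CODE_BASE[Md[i, ]], collapse = "")
    }, character(1))
    res <- tibble(
      family = top$family[grp],
      target = top$target[grp],
      start = top$start[grp],
      end = top$end[grp],
      bases = cons,
      n_top = top$n_reads[grp],
      n_bottom = bot$n_reads[grp]
    )
    if ("molecule" %in% names(top)) res$molecule <- top$molecule[grp]
    out <- c(out, list(res))
  }
  res <- dplyr::bind_rows(out)
  if (end_trim > 0) {
    w <- nchar(res$bases)
    keep <- w > 2 * end_trim
    res <- res[keep, , drop = FALSE]
    if (nrow(res) > 0) {
      res$bases <- substr(res$bases, end_trim + 1L,
                          nchar(res$bases) - end_trim)
      res$start <- res$start + as.integer(end_trim)
      res$end <- res$end - as.integer(end_trim)
    }
  }
  res
}

#' @noRd
empty_duplex <- function() {
  tibble(family = integer(), target = character(), start = integer(),
         end = integer(), bases = character(), n_top = integer(),
         n_bottom = integer())
}

#' Balanced overlap clipping of duplex read pairs
#'
#' Mates of a duplex read pair that overlap on the reference would count the
#' overlapped bases twice; balanced clipping splits the overlap at its
#' midpoint so every reference position is covered exactly once (the
#' left-most mate keeps the extra base when the overlap length is odd).
#' When one mate's interval is properly contained in the other's, the
#' contained mate is clipped away entirely (the container already covers
#' the union). Non-overlapping pairs are unchanged.
#'
#' @param pairs Tibble with columns `start1`, `end1`, `start2`, `end2`
#'   (0-based half-open) and optionally `bases1`, `bases2`.
#' @return The tibble with clipped coordinates (and bases).
#' @export
clip_overlap <- function(pairs) {
  s1 <- pairs$start1; e1 <- pairs$end1
  s2 <- pairs$start2; e2 <- pairs$end2
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  has_b <- all(c("bases1", "bases2") %in% names(pairs))
  for (i in which(ov > 0)) {
    # proper containment: clip the contained mate entirely
    # (identical intervals fall through to the balanced split)
    same <- s1[i] == s2[i] && e1[i] == e2[i]
    if (!same && s2[i] >= s1[i] && e2[i] <= e1[i]) {
      s2[i] <- e2[i] <- e1[i]
      if (has_b) pairs$bases2[i] <- ""
      next
    }
    if (!same && s1[i] >= s2[i] && e1[i] <= e2[i]) {
      s1[i] <- e1[i] <- e2[i]
      if (has_b) pairs$bases1[i] <- ""
      next
    }
    left_is_1 <- s1[i] <= s2[i]
    b <- pmax(s1[i], s2[i]) + ceiling(ov[i] / 2)
    if (left_is_1) {
      new_e1 <- min(e1[i], b)
      new_s2 <- max(s2[i], b)
      if (has_b) {
        pairs$bases1[i] <- substr(pairs$bases1[i], 1, new_e1 - s1[i])
        pairs$bases2[i] <- substr(pairs$bases2[i], new_s2 - s2[i] + 1,
                                  e2[i] - s2[i])
      }
      e1[i] <- new_e1; s2[i] <- new_s2
    } else {
      new_e2 <- min(e2[i], b)
      new_s1 <- max(s1[i], b)
      if (has_b) {
        pairs$bases2[i] <- substr(pairs$bases2[i], 1, new_e2 - s2[i])
        pairs$bases1[i] <- substr(pairs$bases1[i], new_s1 - s1[i] + 1,
                                  e1[i] - s1[i])
      }
      e2[i] <- new_e2; s1[i] <- new_s1
    }
  }
  pairs$start1 <- s1; pairs$end1 <- e1
  pairs$start2 <- s2; pairs$end2 <- e2
  pairs
}
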