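#' Pile up duplex consensus reads against the panel
#'
#' Tallies per-base duplex molecule counts at every target position covered
#' by at least one consensus read. `N` bases are excluded from depth (a
#' strand disagreement carries no information at that site) but the position
#' still appears as a column. Reads extending outside their target's
#' interval raise an error: simulated reads are on-target by construction,
#' so an out-of-bounds read indicates corrupted input.
#'
#' @param consensus Duplex consensus tibble from [call_duplex_consensus()]
#'   (columns `target`, `start`, `end`, `bases`).
#' @param panel Panel tibble.
#' @return Tibble with one row per covered position: `target`, `pos`
#'   (0-based), `ref`, `A`, `C`, `G`, `T`, `N`, `depth` (non-N molecules).
#' @export
pileup <- function(consensus, panel) {
  check_panel(panel)
  if (nrow(consensus) == 0) {
    return(tibble(target = character(), pos = integer(), ref = character(),
                  A = integer(), C = integer(), G = integer(),
                  T = integer(), N = integer(), depth = integer()))
  }
  if (!all(consensus$target %in% panel$target)) {
    abort("consensus reads reference targets absent from the panel")
  }
  out <- vector("list", 0)
  for (t in unique(consensus$target)) {
    prow <- panel_row(panel, t)
    L <- prow$end - prow$start
    sub <- consensus[consensus$target == t, , drop = FALSE]
    if (any(sub$start < prow$start | sub$end > prow$end)) {
      abort(paste0("read outside panel interval on target ", t))
    }
    counts <- matrix(0L, nrow = 5, ncol = L)
    covered <- integer(L)
    for (grp in split(seq_len(nrow(sub)), nchar(sub$bases))) {
      w <- nchar(sub$bases[grp[1]])
      if (w == 0) next
      M <- dna_code_matrix(sub$bases[grp])
      pos0 <- sub$start[grp] - prow$start          # 0-based within target
      posm <- outer(pos0, 0:(w - 1L), "+")         # n x w positions
      idx <- as.vector(posm) * 5L + (as.vector(M) - 1L) # 0-based flat
      tab <- tabulate(idx + 1L, nbins = 5L * L)
      counts <- counts + matrix(tab, nrow = 5)
      covered <- covered + tabulate(as.vector(posm) + 1L, nbins = L)
    }
    cov_pos <- which(covered > 0) - 1L
    if (length(cov_pos) == 0) next
    refc <- strsplit(prow$sequence, "", fixed = TRUE)[[1]][cov_pos + 1L]
    cm <- t(counts[, cov_pos + 1L, drop = FALSE])
    out[[length(out) + 1]] <- tibble(
      target = t, pos = as.integer(cov_pos + prow$start), ref = refc,
      A = cm[, 1], C = cm[, 2], G = cm[, 3], T = cm[, 4], N = cm[, 5],
      depth = cm[, 1] + cm[, 2] + cm[, 3] + cm[, 4]
    )
  }
  dplyr::bind_rows(out)
}

#' Total duplex base pairs of a pileup
#'
#' The denominator of the per-nucleotide mutant frequency: the sum of non-N
#' duplex molecule depths over all interrogated positions.
#'
#' @param columns Pileup tibble.
#' @return Integer scalar.
#' @export
duplex_base_pairs <- function(columns) {
  sum(as.numeric(columns$depth))
}

#' Call variants from a duplex pileup
#'
#' Emits one call per (position, alternate base) whose duplex molecule count
#' reaches `min_alt_count` (default 1: with duplex consensus input every
#' single-molecule nonreference observation is reportable). Multi-allelic
#' positions yield multiple calls.
#'
#' @param columns Pileup tibble from [pileup()].
#' @param min_alt_count Minimum alternate molecule count.
#' @return Tibble of calls: `target`, `pos`, `ref`, `alt`, `alt_count`,
#'   `depth`, `vaf`.
#' @export
call_variants <- function(columns, min_alt_count = 1) {
  if (nrow(columns) == 0) return(empty_calls())
  long <- columns |>
    tidyr::pivot_longer(cols = c("A", "C", "G", "T"),
                        names_to = "alt", values_to = "alt_count") |>
    dplyr::filter(alt != ref, alt_count >= min_alt_count)
  if (nrow(long) == 0) return(empty_calls())
  long |>
    dplyr::transmute(target, pos, ref, alt,
                     alt_count = as.integer(alt_count),
                     depth = as.integer(depth),
                     vaf = alt_count / depth) |>
    dplyr::arrange(target, pos, alt)
}

#' @noRd
empty_calls <- function() {
  tibble(target = character(), pos = integer(), ref = character(),
         alt = character(), alt_count = integer(), depth = integer(),
         vaf = double())
}

#' Flag putative germline variants
#'
#' Adds a logical `germline` column: calls at or above the VAF threshold are
#' treated as inherited (heterozygous or homozygous) alleles and excluded
#' from mutant-frequency and clonality analyses downstream. A fixed VAF
#' cutoff (default 0.3) separates the germline regime from even the largest
#' somatic clonal expansions, which sit orders of magnitude lower in these
#' data.
#'
#' @param calls Variant call tibble.
#' @param vaf_threshold Minimum VAF flagged as germline.
#' @return `calls` with a `germline` column.
#' @export
flag_germline <- function(calls, vaf_threshold = 0.3) {
  dplyr::mutate(calls, germline = vaf >= vaf_threshold)
}
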