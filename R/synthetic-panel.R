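#' Generate a synthetic reference target panel
#'
#' Builds a panel of target regions analogous to a hybrid-capture design for
#' mutagenesis assessment: a mix of transcribed and nontranscribed loci, some
#' protein-coding, each on its own contig with 0-based half-open coordinates.
#' Sequences are random with the requested GC content.
#'
#' When `n_targets >= 2` the default annotation alternates transcription
#' status so at least one transcribed and one nontranscribed target exist
#' (required for strand-bias analyses). Odd-indexed targets are coding
#' (`frame_offset = 0`) by default, emulating exon-plus-flanking-intron
#' capture designs.
#'
#' @param n_targets Number of target regions (>= 1).
#' @param length Length of every target in bp (>= 30, so that trinucleotide
#'   contexts and complete codons exist).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param gc GC fraction of the random sequences.
#' @param transcribed Optional logical vector (recycled) overriding the
#'   alternating default.
#' @param frame_offset Optional integer vector (0-2 or `NA`, recycled)
#'   overriding the coding default.
#' @param copies_per_genome Positive integer vector (recycled); multicopy
#'   values emulate tandem transgenes such as a multicopy reporter.
#'
#' @return A tibble with one row per target: `target`, `contig`, `start`,
#'   `end`, `sequence`, `transcribed`, `transcribed_strand`, `frame_offset`,
#'   `copies_per_genome`.
#' @export
#' @examples
#' panel <- generate_reference_panel(2, 300, seed = 1)
#' panel$target
generate_reference_panel <- function(n_targets, length, seed,
                                     gc = 0.5,
                                     transcribed = NULL,
                                     frame_offset = NULL,
                                     copies_per_genome = 1L) {
  stopifnot(n_targets >= 1)
  if (length < 30) {
    abort("`length` must be >= 30 (trinucleotide contexts plus codons)")
  }
  if (is.null(transcribed)) {
    transcribed <- rep_len(c(TRUE, FALSE), n_targets)
    if (n_targets == 1) transcribed <- FALSE
  } else {
    transcribed <- rep_len(transcribed, n_targets)
  }
  if (is.null(frame_offset)) {
    frame_offset <- rep_len(c(0L, NA_integer_), n_targets)
  } else {
    frame_offset <- rep_len(as.integer(frame_offset), n_targets)
  }
  stopifnot(all(is.na(frame_offset) | frame_offset %in% 0:2))
  copies_per_genome <- rep_len(as.integer(copies_per_genome), n_targets)
  stopifnot(all(copies_per_genome >= 1L))

  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(n_targets), function(i) {
      paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  name <- sprintf("target_%02d", seq_len(n_targets))
  tibble(
    target = name,
    contig = name,
    start = 0L,
    end = as.integer(length),
    sequence = seqs,
    transcribed = transcribed,
    transcribed_strand = ifelse(transcribed, "plus", "none"),
    frame_offset = frame_offset,
    copies_per_genome = copies_per_genome
  )
}

#' Validate a panel tibble
#' @noRd
check_panel <- function(panel) {
  needed <- c("target", "start", "end", "sequence", "transcribed",
              "transcribed_strand", "frame_offset", "copies_per_genome")
  missing <- setdiff(needed, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing columns: ", paste(missing, collapse = ", ")))
  }
  len <- panel$end - panel$start
  if (!all(nchar(panel$sequence) == len)) {
    abort("panel sequence lengths must equal interval lengths")
  }
  if (anyDuplicated(panel$target)) {
    abort("panel target names must be unique")
  }
  if (!all(panel$transcribed_strand %in% c("plus", "minus", "none"))) {
    abort("`transcribed_strand` must be one of plus/minus/none")
  }
  invisible(panel)
}

#' Look up one panel row
#' @noRd
panel_row <- function(panel, target) {
  i <- match(target, panel$target)
  if (is.na(i)) abort(paste0("unknown target: ", target))
  panel[i, ]
}
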