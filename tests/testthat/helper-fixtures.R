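# shared fixture builders; all fixtures are generated in code

# hand-built panel from explicit sequences
toy_panel <- function(sequences,
                      transcribed = FALSE,
                      transcribed_strand = NULL,
                      frame_offset = NA_integer_,
                      copies_per_genome = 1L,
                      names = NULL) {
  n <- length(sequences)
  if (is.null(names)) names <- sprintf("toy_%02d", seq_len(n))
  transcribed <- rep_len(transcribed, n)
  if (is.null(transcribed_strand)) {
    transcribed_strand <- ifelse(transcribed, "plus", "none")
  } else {
    transcribed_strand <- rep_len(transcribed_strand, n)
  }
  tibble::tibble(
    target = names, contig = names,
    start = 0L, end = nchar(sequences),
    sequence = sequences,
    transcribed = transcribed,
    transcribed_strand = transcribed_strand,
    frame_offset = rep_len(as.integer(frame_offset), n),
    copies_per_genome = rep_len(as.integer(copies_per_genome), n)
  )
}

# a call tibble row with defaults, for metric/spectra unit tests
toy_calls <- function(target, pos, ref, alt, alt_count = 1L, depth = 1000L) {
  tibble::tibble(target = target, pos = as.integer(pos), ref = ref,
                 alt = alt, alt_count = as.integer(alt_count),
                 depth = as.integer(depth), vaf = alt_count / depth)
}

# noise-free simulate -> consensus -> call chain used by recovery tests
noise_free_calls <- function(panel, truth, n_molecules, seed,
                             reads_per_strand = 2) {
  reads <- simulate_read_families(
    panel, truth, n_molecules = n_molecules,
    reads_per_strand = reads_per_strand, reads_dist = "fixed",
    strand_dropout = 0, error_rate = 0, damage_rate = 0,
    barcode_error_rate = 0, seed = seed)
  fams <- suppressMessages(filter_cigar_groups(group_families(reads)))
  cons <- call_duplex_consensus(fams, end_trim = 0)
  cols <- pileup(cons, panel)
  list(consensus = cons, pileup = cols, calls = call_variants(cols))
}

# truth table restricted to molecules/positions covered by a duplex consensus
recoverable_truth <- function(truth, consensus) {
  j <- dplyr::inner_join(
    as.data.frame(truth),
    as.data.frame(consensus[, c("target", "molecule", "start", "end")]),
    by = c("target", "molecule"), relationship = "many-to-many")
  j <- j[j$pos >= j$start & j$pos < j$end, , drop = FALSE]
  unique(j[, c("target", "pos", "ref", "alt")])
}
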