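#' Read a target panel from BED + FASTA (+ annotations)
#'
#' Builds a panel tibble from a reference FASTA, a BED file of target
#' intervals (0-based half-open, as BED natively is) and an optional
#' annotation TSV with columns `target`, `transcribed`, `transcribed_strand`,
#' `frame_offset`, `copies_per_genome` (missing annotations default to a
#' nontranscribed, noncoding, single-copy target). Overlapping BED records
#' on the same contig are merged with a warning.
#'
#' An optional repeat-mask BED removes masked intervals, padded by
#' `mask_pad` bp on each side, from the reportable territory: variant calls
#' and duplex base pairs within the padding of a masked repeat are not
#' trustworthy and are excluded from reporting. The reportable sub-intervals
#' are returned in the `reportable` list-column; a fully masked target
#' triggers a warning.
#'
#' @param bed_path BED file of target intervals (column 4 = target name).
#' @param fasta_path Reference FASTA containing the BED contigs.
#' @param annotation_path Optional annotation TSV.
#' @param mask_bed Optional repeat-mask BED.
#' @param mask_pad Padding around masked intervals (bp).
#' @return Panel tibble (see [generate_reference_panel()]) with additional
#'   `reportable` (list of tibbles with `start`, `end`) and `reportable_bp`
#'   columns.
#' @export
read_targets <- function(bed_path, fasta_path, annotation_path = NULL,
                         mask_bed = NULL, mask_pad = 10) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_targets requires the rtracklayer package")
  }
  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  gr <- rtracklayer::import(bed_path)
  if (!all(as.character(GenomicRanges::seqnames(gr)) %in% names(fa))) {
    abort("BED contigs missing from FASTA")
  }
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  if (length(red) < length(gr)) {
    warn("overlapping BED records merged")
    # carry the first overlapped record's name
    revmap <- S4Vectors::mcols(red)$revmap
    nm <- vapply(revmap, function(i) {
      n <- S4Vectors::mcols(gr)$name[i[1]]
      if (is.null(n) || is.na(n)) "" else n
    }, character(1))
    gr <- red
    S4Vectors::mcols(gr)$name <- nm
  }
  contig <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L     # back to 0-based
  end0 <- GenomicRanges::end(gr)
  name <- S4Vectors::mcols(gr)$name
  if (is.null(name) || any(is.na(name) | name == "")) {
    name <- paste0(contig, ":", start0, "-", end0)
  }
  if (any(end0 > Biostrings::width(fa)[match(contig, names(fa))]) ||
      any(start0 < 0)) {
    abort("BED interval out of contig bounds")
  }
  seqs <- as.character(Biostrings::subseq(fa[contig], start0 + 1L, end0))
  panel <- tibble(
    target = name, contig = contig, start = start0, end = end0,
    sequence = unname(seqs),
    transcribed = FALSE, transcribed_strand = "none",
    frame_offset = NA_integer_, copies_per_genome = 1L
  )
  if (!is.null(annotation_path)) {
    ann <- readr::read_tsv(annotation_path, show_col_types = FALSE)
    stopifnot("target" %in% names(ann))
    i <- match(panel$target, ann$target)
    for (col in intersect(c("transcribed", "transcribed_strand",
                            "frame_offset", "copies_per_genome"),
                          names(ann))) {
      hit <- !is.na(i)
      panel[[col]][hit] <- ann[[col]][i[hit]]
    }
    panel$frame_offset <- as.integer(panel$frame_offset)
    panel$copies_per_genome <- as.integer(panel$copies_per_genome)
  }

  # reportable territory after padded mask subtraction
  if (!is.null(mask_bed)) {
    mk <- rtracklayer::import(mask_bed)
    mk <- GenomicRanges::reduce(
      GenomicRanges::resize(mk, GenomicRanges::width(mk) + 2 * mask_pad,
                            fix = "center"))
    tgt_gr <- GenomicRanges::GRanges(
      panel$contig, IRanges::IRanges(panel$start + 1L, panel$end))
    keep <- GenomicRanges::setdiff(tgt_gr, mk)
    rep_list <- lapply(seq_len(nrow(panel)), function(i) {
      hit <- keep[as.character(GenomicRanges::seqnames(keep)) ==
                    panel$contig[i]]
      hit <- IRanges::restrict(IRanges::ranges(hit),
                               panel$start[i] + 1L, panel$end[i])
      tibble(start = IRanges::start(hit) - 1L, end = IRanges::end(hit))
    })
  } else {
    rep_list <- lapply(seq_len(nrow(panel)), function(i) {
      tibble(start = panel$start[i], end = panel$end[i])
    })
  }
  panel$reportable <- rep_list
  panel$reportable_bp <- vapply(rep_list, function(r) {
    sum(r$end - r$start)
  }, numeric(1))
  if (any(panel$reportable_bp == 0)) {
    warn(paste0("target(s) fully repeat-masked: ",
                paste(panel$target[panel$reportable_bp == 0],
                      collapse = ", ")))
  }
  check_panel(panel)
  panel
}

#' Write a panel to FASTA + BED + annotation TSV
#'
#' Inverse of [read_targets()]: one FASTA record per contig, one BED record
#' per target (0-based half-open), and the annotation TSV.
#'
#' @param panel Panel tibble.
#' @param fasta_path,bed_path,annotation_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_panel <- function(panel, fasta_path, bed_path, annotation_path) {
  check_panel(panel)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("write_panel requires the rtracklayer package")
  }
  seqs <- Biostrings::DNAStringSet(setNames(panel$sequence, panel$contig))
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    panel$contig, IRanges::IRanges(panel$start + 1L, panel$end),
    name = panel$target)
  rtracklayer::export(gr, bed_path, format = "BED")
  readr::write_tsv(
    panel[, c("target", "transcribed", "transcribed_strand",
              "frame_offset", "copies_per_genome")],
    annotation_path)
  invisible(c(fasta_path, bed_path, annotation_path))
}

#' Write reads as a gzipped FASTQ-like dump plus family-membership TSV
#'
#' The FASTQ-like dump stores one 4-line record per read, with the read id,
#' target, coordinates, strand and UMI pair in the header comment; the
#' companion TSV carries the family membership table.
#'
#' @param reads Read tibble from [simulate_read_families()].
#' @param fastq_path Output path (`.gz` gets gzip compression).
#' @param tsv_path Family membership TSV path.
#' @return Invisibly, the paths.
#' @export
write_read_dump <- function(reads, fastq_path, tsv_path) {
  con <- if (grepl("\\.gz$", fastq_path)) gzfile(fastq_path, "w")
         else file(fastq_path, "w")
  on.exit(close(con))
  hdr <- sprintf("@read_%d %s:%d-%d/%s UMI=%s+%s",
                 reads$read_id, reads$target, reads$start, reads$end,
                 reads$strand, reads$umi1, reads$umi2)
  writeLines(rbind(hdr, reads$bases, "+", reads$quals), con)
  readr::write_tsv(
    reads[, c("read_id", "target", "molecule", "start", "end", "strand",
              "umi1", "umi2")],
    tsv_path)
  invisible(c(fastq_path, tsv_path))
}

#' Write variant calls as VCF (1-based) with a TSV mirror
#'
#' Coordinates are converted from the internal 0-based convention to VCF's
#' 1-based positions. INFO fields carry the alternate duplex molecule count
#' (`AC`) and duplex depth (`DP`). Uses VariantAnnotation when available;
#' the TSV mirror is always written.
#'
#' @param calls Call tibble for one sample.
#' @param vcf_path,tsv_path Output paths.
#' @param sample_id Sample name recorded in the VCF.
#' @return Invisibly, the paths written.
#' @export
write_variants <- function(calls, vcf_path, tsv_path, sample_id = "sample") {
  readr::write_tsv(calls, tsv_path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    inform("VariantAnnotation not installed; VCF skipped, TSV written")
    return(invisible(tsv_path))
  }
  if (nrow(calls) == 0) return(invisible(tsv_path))
  vr <- VariantAnnotation::VRanges(
    seqnames = calls$target,
    ranges = IRanges::IRanges(calls$pos + 1L, calls$pos + 1L),
    ref = calls$ref, alt = calls$alt,
    altDepth = calls$alt_count, totalDepth = calls$depth,
    refDepth = calls$depth - calls$alt_count,
    sampleNames = sample_id)
  VariantAnnotation::writeVcf(vr, vcf_path)
  invisible(c(vcf_path, tsv_path))
}
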