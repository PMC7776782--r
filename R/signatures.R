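#' Substitution class labels
#'
#' Canonical label sets for mutational spectra in pyrimidine space. The
#' 6-class set collapses the 12 strand-specific substitutions onto a
#' pyrimidine reference (C or T). The 96-class set is the product of the 6
#' substitution types and the 16 combinations of 5' and 3' flanking bases,
#' written in the conventional bracket notation (e.g. `A[C>A]G`), ordered by
#' substitution type, then 5' base, then 3' base.
#'
#' @return Character vector of class labels.
#' @export
#' @examples
#' sbs6_classes()
#' head(sbs96_classes())
sbs6_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname sbs6_classes
#' @export
sbs96_classes <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(sbs6_classes(), function(sub) {
    unlist(lapply(bases, function(p5) paste0(p5, "[", sub, "]", bases)))
  }))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Complement and reverse-complement of DNA strings
#'
#' Thin vectorised wrappers kept internal; heavy lifting on real sequence
#' data goes through Biostrings.
#' @noRd
dna_complement <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' @noRd
dna_revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(dna_complement(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Orient substitutions into pyrimidine space
#'
#' Substitutions with a purine reference are complemented (and their flanking
#' context reverse-complemented) so that every event is reported on the strand
#' carrying the pyrimidine reference base.
#'
#' @param ref,alt Character vectors of single reference/alternate bases.
#' @param p5,p3 Optional 5' and 3' flanking bases (reference strand).
#'
#' @return A tibble with columns `ref`, `alt` (pyrimidine-space) and, when
#'   context was supplied, `p5`, `p3`, `class6` and `class96`.
#' @export
#' @examples
#' pyrimidine_orient("G", "T")            # reported as C>A
#' pyrimidine_orient("A", "T", "C", "G")  # context is reverse-complemented
pyrimidine_orient <- function(ref, alt, p5 = NULL, p3 = NULL) {
  stopifnot(length(ref) == length(alt))
  is_pur <- ref %in% c("A", "G")
  o_ref <- ifelse(is_pur, dna_complement(ref), ref)
  o_alt <- ifelse(is_pur, dna_complement(alt), alt)
  out <- tibble(ref = o_ref, alt = o_alt,
                class6 = paste0(o_ref, ">", o_alt))
  if (!is.null(p5)) {
    stopifnot(length(p5) == length(ref), length(p3) == length(ref))
    o_p5 <- ifelse(is_pur, dna_complement(p3), p5)
    o_p3 <- ifelse(is_pur, dna_complement(p5), p3)
    out$p5 <- o_p5
    out$p3 <- o_p3
    out$class96 <- paste0(o_p5, "[", out$class6, "]", o_p3)
  }
  out
}

#' Construct a 96-class signature vector
#'
#' A signature is a named probability vector over the 96 substitution-in-
#' trinucleotide-context classes. `signature_flat()` is uniform;
#' `signature_concentrated()` puts probability mass `weight` on the classes
#' matching a substitution type (optionally restricted to given flanks) and
#' spreads the remainder uniformly — a convenient way to emulate the sharply
#' peaked spectra of strong mutagens (e.g. the T>A-in-NTG pattern of
#' urethane, or C>A-dominated polycyclic aromatic hydrocarbon exposure).
#'
#' @param sub Substitution type, one of `sbs6_classes()`.
#' @param p5,p3 Optional flanking base restriction (`NULL` = any).
#' @param weight Total probability assigned to the selected classes.
#'
#' @return Named numeric vector of length 96 summing to 1.
#' @export
#' @examples
#' sig <- signature_concentrated("T>A", p3 = "G", weight = 0.8)
#' sum(sig)
signature_flat <- function() {
  setNames(rep(1 / 96, 96), sbs96_classes())
}

#' @rdname signature_flat
#' @export
signature_concentrated <- function(sub, p5 = NULL, p3 = NULL, weight = 0.9) {
  stopifnot(sub %in% sbs6_classes(), weight > 0, weight <= 1)
  cls <- sbs96_classes()
  sel <- grepl(paste0("\\[", sub, "\\]"), cls, fixed = FALSE)
  if (!is.null(p5)) sel <- sel & startsWith(cls, p5)
  if (!is.null(p3)) sel <- sel & endsWith(cls, p3)
  if (!any(sel)) abort("no signature class matches the requested context")
  out <- numeric(96)
  out[sel] <- weight / sum(sel)
  if (weight < 1) out[!sel] <- (1 - weight) / sum(!sel)
  setNames(out, cls)
}

#' Validate a signature vector
#' @noRd
check_signature <- function(signature, tol = 1e-8) {
  if (length(signature) != 96) {
    abort("`signature` must have length 96")
  }
  if (is.null(names(signature))) {
    names(signature) <- sbs96_classes()
  }
  if (!setequal(names(signature), sbs96_classes())) {
    abort("`signature` names must be the 96 canonical class labels")
  }
  if (any(signature < 0) || abs(sum(signature) - 1) > tol) {
    abort("`signature` must be a probability vector summing to 1")
  }
  signature[sbs96_classes()]
}
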