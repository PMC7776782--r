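#' Define a mutagenesis scenario
#'
#' A scenario bundles the ground-truth parameters of a simulated cohort
#' study: per-(tissue, treatment) true per-nucleotide mutant frequencies, a
#' 96-class mutational signature, a transcription-coupled-repair strand-bias
#' factor, clonal expansions, and the cohort design.
#'
#' Defaults emulate a two-arm rodent mutagenesis study at desk scale: a
#' vehicle-control arm at a background mutant frequency of 1.5e-7 per
#' nucleotide and a mutagen arm induced roughly 8-fold to 1.2e-6, in two
#' tissues with 5 replicate animals each — the frequency range where duplex
#' error correction is required for detection at all.
#'
#' @param mf Either a single true mutant frequency applied everywhere, or a
#'   tibble with columns `tissue`, `treatment`, optionally `target`, and `mf`.
#' @param signature 96-class probability vector (see [signature_flat()]).
#'   May also be a named list of signatures keyed by treatment.
#' @param strand_bias_factor Multiplier >= 1 by which mutations whose
#'   pyrimidine reference base lies on the transcribed strand of a transcribed
#'   target are suppressed (emulating transcription-coupled repair).
#' @param clones Tibble of clonal expansions with columns `target`, `pos`
#'   (0-based), `alt`, `fraction` (cell fraction in (0, 1]) and optionally
#'   `tissue`, `treatment`, `replicate` restricting which samples carry the
#'   clone.
#' @param tissues,treatments,n_replicates Cohort design.
#' @param seed Integer master seed, mandatory.
#'
#' @return An object of class `mut_scenario`.
#' @export
#' @examples
#' sc <- mutagenesis_scenario(mf = 1e-6, seed = 7)
#' sc$tissues
mutagenesis_scenario <- function(mf = NULL,
                                 signature = signature_flat(),
                                 strand_bias_factor = 1,
                                 clones = NULL,
                                 tissues = c("liver", "marrow"),
                                 treatments = c("VC", "mutagen"),
                                 n_replicates = 5,
                                 seed) {
  if (missing(seed)) abort("`seed` is mandatory in a scenario")
  if (is.null(mf)) {
    mf <- tibble(
      tissue = rep(tissues, each = length(treatments)),
      treatment = rep(treatments, length(tissues)),
      mf = ifelse(rep(treatments, length(tissues)) == treatments[1],
                  1.5e-7, 1.2e-6)
    )
  }
  if (is.numeric(mf) && length(mf) == 1) {
    mf <- tidyr::expand_grid(tissue = tissues, treatment = treatments) |>
      dplyr::mutate(mf = !!mf)
  }
  stopifnot(is.data.frame(mf), all(c("tissue", "treatment", "mf") %in% names(mf)))
  if (any(mf$mf < 0)) abort("true mutant frequencies must be >= 0")
  if (is.list(signature) && !is.numeric(signature)) {
    signature <- lapply(signature, check_signature)
  } else {
    signature <- check_signature(signature)
  }
  stopifnot(strand_bias_factor >= 1)
  if (!is.null(clones) && nrow(clones) > 0) {
    stopifnot(all(c("target", "pos", "alt", "fraction") %in% names(clones)))
    if (any(clones$fraction <= 0 | clones$fraction > 1)) {
      abort("clone cell fractions must lie in (0, 1]")
    }
  }
  structure(
    list(mf = as_tibble(mf), signature = signature,
         strand_bias_factor = strand_bias_factor,
         clones = if (is.null(clones)) tibble() else as_tibble(clones),
         tissues = tissues, treatments = treatments,
         n_replicates = n_replicates, seed = as.integer(seed)),
    class = "mut_scenario"
  )
}

#' @export
print.mut_scenario <- function(x, ...) {
  cat("<mut_scenario>\n")
  cat("  cohort:", length(x$tissues), "tissue(s) x", length(x$treatments),
      "treatment(s) x", x$n_replicates, "replicate(s)\n")
  cat("  true MF range:", format(range(x$mf$mf), digits = 3), "\n")
  cat("  strand bias factor:", x$strand_bias_factor,
      " clones:", nrow(x$clones), " seed:", x$seed, "\n")
  invisible(x)
}

#' Scenario lookups
#' @noRd
scenario_mf <- function(scenario, tissue, treatment, target) {
  tab <- scenario$mf
  hit <- tab$tissue == tissue & tab$treatment == treatment
  if ("target" %in% names(tab)) {
    hit2 <- hit & !is.na(tab$target) & tab$target == target
    if (any(hit2)) hit <- hit2 else hit <- hit & is.na(tab$target)
  }
  if (!any(hit)) {
    abort(paste0("no true MF defined for (", tissue, ", ", treatment, ")"))
  }
  tab$mf[which(hit)[1]]
}

#' @noRd
scenario_signature <- function(scenario, treatment) {
  sig <- scenario$signature
  if (is.list(sig) && !is.numeric(sig)) {
    if (!treatment %in% names(sig)) {
      abort(paste0("no signature defined for treatment ", treatment))
    }
    sig[[treatment]]
  } else {
    sig
  }
}

#' Per-site mutation channels of one target
#'
#' For every interior position (0-based 1..L-2) and each of the 3 alternate
#' bases, returns the pyrimidine-space 96-class label, the plus-strand alt
#' base, and whether the pyrimidine reference lies on the given strand.
#' Boundary positions lack a trinucleotide context and are not mutable in
#' the simulator.
#' @noRd
site_channels <- function(sequence) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(s)
  i <- 2:(L - 1)                       # 1-based interior indices
  ref <- s[i]
  p5 <- s[i - 1]
  p3 <- s[i + 1]
  # expand: 3 alt channels per site
  alt_plus <- unlist(lapply(seq_along(i), function(k) {
    setdiff(DNA_BASES, ref[k])
  }))
  idx <- rep(seq_along(i), each = 3)
  ref_x <- ref[idx]
  ori <- pyrimidine_orient(ref_x, alt_plus, p5[idx], p3[idx])
  tibble(
    pos = (i - 1L)[idx],               # back to 0-based
    ref = ref_x,
    alt = alt_plus,
    class96 = ori$class96,
    pyr_on_plus = ref_x %in% c("C", "T")
  )
}

#' Simulate true mutations for one sample
#'
#' Draws independent somatic mutations across all molecules of a panel under
#' a scenario: each genome-equivalent contributes `copies_per_genome`
#' molecules per target, and mutations occur per nucleotide at the scenario's
#' true mutant frequency, redistributed across substitution-in-context
#' channels by the signature. On transcribed targets, channels whose
#' pyrimidine reference base lies on the transcribed strand are down-weighted
#' by the strand-bias factor (total rate is preserved by renormalisation).
#' Clonal variants are additionally injected into
#' `floor(fraction * n_molecules)` molecules (lowest molecule indices first,
#' for reproducibility).
#'
#' Total mutation counts are drawn Poisson with mean
#' `mf * target_length * n_molecules`, the limit of independent per-site
#' Bernoulli draws at the ultrarare frequencies this simulator targets.
#'
#' @param panel Panel tibble from [generate_reference_panel()].
#' @param scenario A [mutagenesis_scenario()].
#' @param n_genomes Number of genome equivalents sequenced (>= 1).
#' @param tissue,treatment Which cohort cell this sample belongs to.
#' @param replicate Replicate index (used to match clone restrictions).
#' @param seed Seed; defaults to the scenario seed.
#'
#' @return Tibble of true mutations: `molecule` (1-based index within
#'   target), `target`, `pos` (0-based), `ref`, `alt`, `clone` (logical).
#'   The attribute `n_molecules` records molecules per target.
#' @export
simulate_true_mutations <- function(panel, scenario, n_genomes,
                                    tissue = scenario$tissues[1],
                                    treatment = scenario$treatments[1],
                                    replicate = 1L,
                                    seed = scenario$seed) {
  check_panel(panel)
  stopifnot(n_genomes >= 1)
  sig <- scenario_signature(scenario, treatment)
  sbf <- scenario$strand_bias_factor

  withr::with_seed(seed, {
    out <- vector("list", nrow(panel))
    n_mol <- setNames(integer(nrow(panel)), panel$target)
    for (t in seq_len(nrow(panel))) {
      row <- panel[t, ]
      L <- nchar(row$sequence)
      mols <- as.integer(n_genomes) * row$copies_per_genome
      n_mol[t] <- mols
      mf <- scenario_mf(scenario, tissue, treatment, row$target)
      ch <- site_channels(row$sequence)
      w <- sig[ch$class96]
      if (row$transcribed && sbf > 1) {
        pyr_strand <- ifelse(ch$pyr_on_plus, "plus", "minus")
        w <- ifelse(pyr_strand == row$transcribed_strand, w / sbf, w)
      }
      muts <- NULL
      if (mf > 0 && sum(w) > 0) {
        lambda <- mf * L * mols
        n <- rpois(1, lambda)
        if (n > 0) {
          k <- sample.int(nrow(ch), n, replace = TRUE, prob = w)
          muts <- tibble(
            molecule = sample.int(mols, n, replace = TRUE),
            target = row$target,
            pos = ch$pos[k], ref = ch$ref[k], alt = ch$alt[k],
            clone = FALSE
          )
        }
      }
      cl <- scenario$clones
      if (nrow(cl) > 0) {
        cl <- cl[cl$target == row$target, , drop = FALSE]
        if ("tissue" %in% names(cl)) {
          cl <- cl[is.na(cl$tissue) | cl$tissue == tissue, , drop = FALSE]
        }
        if ("treatment" %in% names(cl)) {
          cl <- cl[is.na(cl$treatment) | cl$treatment == treatment, , drop = FALSE]
        }
        if ("replicate" %in% names(cl)) {
          cl <- cl[is.na(cl$replicate) | cl$replicate == replicate, , drop = FALSE]
        }
        if (nrow(cl) > 0) {
          if (any(cl$pos < 0 | cl$pos >= L)) {
            abort("clone position outside target")
          }
          seq_chars <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
          for (j in seq_len(nrow(cl))) {
            n_carrier <- floor(cl$fraction[j] * mols)
            if (n_carrier < 1) next
            muts <- dplyr::bind_rows(muts, tibble(
              molecule = seq_len(n_carrier),
              target = row$target,
              pos = as.integer(cl$pos[j]),
              ref = seq_chars[cl$pos[j] + 1],
              alt = cl$alt[j],
              clone = TRUE
            ))
          }
        }
      }
      out[[t]] <- muts
    }
    res <- dplyr::bind_rows(out)
    if (nrow(res) == 0) {
      res <- tibble(molecule = integer(), target = character(),
                    pos = integer(), ref = character(), alt = character(),
                    clone = logical())
    }
    res <- dplyr::distinct(res, molecule, target, pos, .keep_all = TRUE)
    attr(res, "n_molecules") <- n_mol
    res
  })
}
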