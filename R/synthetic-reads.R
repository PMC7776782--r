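#' Generate a UMI barcode whitelist
#'
#' Greedily selects random fixed-length tags with a minimum pairwise Hamming
#' distance. The default minimum distance of 4 guarantees that a tag observed
#' with a single mismatch is still uniquely correctable under the
#' "max 1 mismatch, margin >= 2 to the next-best tag" rule used by
#' [correct_barcode()].
#'
#' @param n Number of tags.
#' @param length Tag length in bp.
#' @param seed Integer seed.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return Character vector of `n` distinct tags.
#' @export
generate_barcode_whitelist <- function(n = 1024, length = 10, seed,
                                       min_dist = 4) {
  stopifnot(n >= 1, length >= min_dist)
  withr::with_seed(seed, {
    kept <- matrix(integer(0), nrow = length, ncol = 0)
    tags <- character(0)
    tries <- 0
    while (ncol(kept) < n) {
      cand <- sample.int(4, length, replace = TRUE)
      ok <- ncol(kept) == 0 || all(colSums(kept != cand) >= min_dist)
      if (ok) {
        kept <- cbind(kept, cand)
        tags <- c(tags, paste(DNA_BASES[cand], collapse = ""))
      }
      tries <- tries + 1
      if (tries > 1000 * n) {
        abort("could not build whitelist; increase `length` or lower `n`")
      }
    }
    tags
  })
}

#' Zero-truncated Poisson draws
#' @noRd
rztpois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(runif(n, p0, 1), lambda)
}

#' Replace single characters inside strings
#' @noRd
replace_chars <- function(strings, read_idx, pos, newchar) {
  if (length(read_idx) == 0) return(strings)
  by_read <- split(seq_along(read_idx), read_idx)
  for (r in names(by_read)) {
    i <- as.integer(r)
    sel <- by_read[[r]]
    ch <- strsplit(strings[i], "", fixed = TRUE)[[1]]
    ch[pos[sel]] <- newchar[sel]
    strings[i] <- paste(ch, collapse = "")
  }
  strings
}

#' Corrupt barcode tags
#' @noRd
corrupt_tags <- function(tags, rate, max_mm = 2) {
  n <- length(tags)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(tags)
  len <- nchar(tags[1])
  for (i in hit) {
    n_mm <- sample(c(1L, 2L), 1, prob = c(0.8, 0.2))
    n_mm <- min(n_mm, max_mm)
    p <- sample.int(len, n_mm)
    ch <- strsplit(tags[i], "", fixed = TRUE)[[1]]
    for (j in p) ch[j] <- sample(setdiff(DNA_BASES, ch[j]), 1)
    tags[i] <- paste(ch, collapse = "")
  }
  tags
}

#' Simulate raw duplex read families
#'
#' Turns a molecule-level mutation truth table into raw paired-strand read
#' families with the error structure duplex sequencing is designed to
#' resolve:
#'
#' * true mutations are present on reads from **both** strands of their
#'   molecule;
#' * single-strand damage (a chemically directional lesion, default the
#'   oxidative `G>T`) is applied per molecule-strand at `damage_rate` per
#'   eligible base and therefore appears on **one** strand only, discordant
#'   with its mate strand by construction;
#' * sequencing errors are independent per read per base at `error_rate`;
#' * family sizes per strand are zero-truncated Poisson (or fixed), with an
#'   optional per-strand dropout probability producing single-strand-only
#'   families that must never yield a duplex consensus.
#'
#' Each molecule receives a barcode pair from the whitelist and shear points
#' jittered by up to `shear_jitter` bp; observed barcodes are corrupted with
#' up to 2 mismatches at `barcode_error_rate` to exercise the downstream
#' correction rule.
#'
#' @param panel Panel tibble.
#' @param mutations Truth tibble from [simulate_true_mutations()] (may have 0
#'   rows).
#' @param n_molecules Molecules per target: scalar or named vector; defaults
#'   to the `n_molecules` attribute of `mutations`.
#' @param reads_per_strand Mean family size per strand (zero-truncated
#'   Poisson), or the exact size when `reads_dist = "fixed"`.
#' @param reads_dist `"ztpois"` or `"fixed"`.
#' @param strand_dropout Probability a strand yields no reads.
#' @param error_rate Per-base sequencing error probability, in [0, 0.5).
#' @param damage_rate Per-base single-strand damage probability at lesion-
#'   eligible sites, in [0, 0.5).
#' @param damage_lesion Lesion spec `"X>Y"` applied on each physical strand.
#' @param fragment_length Fragment length (NULL = full target, minus jitter).
#' @param shear_jitter Max random shear-point shift at each fragment end.
#' @param whitelist Barcode whitelist; generated if NULL.
#' @param barcode_error_rate Probability an observed tag is corrupted.
#' @param base_quality Phred quality assigned to simulated bases.
#' @param seed Integer seed.
#'
#' @return Tibble of reads: `read_id`, `target`, `molecule`, `start`, `end`
#'   (0-based half-open fragment coordinates), `strand` (`top`/`bottom`),
#'   `bases`, `quals`, `cigar`, `umi1`, `umi2`. The barcode whitelist is
#'   attached as attribute `whitelist`.
#' @export
simulate_read_families <- function(panel, mutations,
                                   n_molecules = NULL,
                                   reads_per_strand = 3,
                                   reads_dist = c("ztpois", "fixed"),
                                   strand_dropout = 0.2,
                                   error_rate = 1e-3,
                                   damage_rate = 0,
                                   damage_lesion = "G>T",
                                   fragment_length = NULL,
                                   shear_jitter = 5,
                                   whitelist = NULL,
                                   barcode_error_rate = 0.02,
                                   base_quality = 30L,
                                   seed) {
  check_panel(panel)
  reads_dist <- match.arg(reads_dist)
  if (error_rate < 0 || error_rate >= 0.5 ||
      damage_rate < 0 || damage_rate >= 0.5) {
    abort("error rates must lie in [0, 0.5)")
  }
  lesion <- strsplit(damage_lesion, ">", fixed = TRUE)[[1]]
  stopifnot(length(lesion) == 2, all(lesion %in% DNA_BASES))
  if (is.null(n_molecules)) {
    n_molecules <- attr(mutations, "n_molecules")
    if (is.null(n_molecules)) abort("`n_molecules` is required")
  }
  if (length(n_molecules) == 1 && is.null(names(n_molecules))) {
    n_molecules <- setNames(rep(as.integer(n_molecules), nrow(panel)),
                            panel$target)
  }

  withr::with_seed(seed, {
    if (is.null(whitelist)) {
      whitelist <- generate_barcode_whitelist(
        n = 256, length = 10, seed = sample.int(2^30, 1))
    }
    qchar <- intToUtf8(base_quality + 33L)
    per_target <- vector("list", nrow(panel))
    for (t in seq_len(nrow(panel))) {
      row <- panel[t, ]
      L <- nchar(row$sequence)
      mols <- n_molecules[[row$target]]
      if (is.na(mols) || mols < 1) next

      # shear points
      if (is.null(fragment_length)) {
        fs <- sample.int(shear_jitter + 1L, mols, replace = TRUE) - 1L
        fe <- L - (sample.int(shear_jitter + 1L, mols, replace = TRUE) - 1L)
      } else {
        fl <- min(fragment_length, L)
        fs <- sample.int(L - fl + 1L, mols, replace = TRUE) - 1L
        fe <- fs + fl
      }
      frag <- substring(row$sequence, fs + 1L, fe)

      # inject true mutations into their molecules' fragments
      mut_t <- mutations[mutations$target == row$target, , drop = FALSE]
      if (nrow(mut_t) > 0) {
        if (any(mut_t$molecule > mols)) {
          abort("mutation truth table references molecules beyond `n_molecules`")
        }
        keep <- mut_t$pos >= fs[mut_t$molecule] & mut_t$pos < fe[mut_t$molecule]
        mut_t <- mut_t[keep, , drop = FALSE]
        frag <- replace_chars(frag, mut_t$molecule,
                              mut_t$pos - fs[mut_t$molecule] + 1L, mut_t$alt)
      }

      # strand templates with directional single-strand damage
      top_tpl <- frag
      bot_tpl <- frag
      if (damage_rate > 0) {
        # top physical strand: lesion base as written in plus orientation
        top_sites <- gregexpr(lesion[1], frag, fixed = TRUE)
        # bottom physical strand: lesion on the complement, i.e. plus-strand
        # positions carrying complement(lesion ref), read out as
        # complement(lesion alt)
        bot_ref <- dna_complement(lesion[1])
        bot_alt <- dna_complement(lesion[2])
        bot_sites <- gregexpr(bot_ref, frag, fixed = TRUE)
        dmg <- function(sites, newbase, tpl) {
          midx <- rep(seq_along(sites), lengths2(sites))
          p <- unlist(lapply(sites, valid_match), use.names = FALSE)
          if (length(p) == 0) return(tpl)
          hit <- runif(length(p)) < damage_rate
          replace_chars(tpl, midx[hit], p[hit],
                        rep(newbase, sum(hit)))
        }
        top_tpl <- dmg(top_sites, lesion[2], top_tpl)
        bot_tpl <- dmg(bot_sites, bot_alt, bot_tpl)
      }

      # family sizes
      n_top <- if (reads_dist == "fixed") rep(as.integer(reads_per_strand), mols)
               else rztpois(mols, reads_per_strand)
      n_bot <- if (reads_dist == "fixed") rep(as.integer(reads_per_strand), mols)
               else rztpois(mols, reads_per_strand)
      if (strand_dropout > 0) {
        n_top[runif(mols) < strand_dropout] <- 0L
        n_bot[runif(mols) < strand_dropout] <- 0L
      }

      # barcode pair per molecule
      umiA <- sample(whitelist, mols, replace = TRUE)
      umiB <- sample(whitelist, mols, replace = TRUE)

      mk_reads <- function(nvec, tpl, strand, u1, u2) {
        midx <- rep(seq_len(mols), nvec)
        if (length(midx) == 0) return(NULL)
        tibble(
          target = row$target,
          molecule = midx,
          start = fs[midx], end = fe[midx],
          strand = strand,
          bases = tpl[midx],
          quals = strrep(qchar, fe[midx] - fs[midx]),
          cigar = paste0(fe[midx] - fs[midx], "M"),
          umi1 = u1[midx], umi2 = u2[midx]
        )
      }
      reads <- dplyr::bind_rows(
        mk_reads(n_top, top_tpl, "top", umiA, umiB),
        mk_reads(n_bot, bot_tpl, "bottom", umiB, umiA)
      )
      per_target[[t]] <- reads
    }
    reads <- dplyr::bind_rows(per_target)
    if (nrow(reads) == 0) {
      abort("no reads simulated; check `n_molecules`")
    }

    # independent sequencing errors
    if (error_rate > 0) {
      widths <- nchar(reads$bases)
      total <- sum(widths)
      n_err <- rbinom(1, total, error_rate)
      if (n_err > 0) {
        flat <- sample.int(total, n_err)
        cum <- cumsum(widths)
        ridx <- findInterval(flat - 1L, cum) + 1L
        p <- flat - c(0L, cum)[ridx]
        old <- substring(reads$bases[ridx], p, p)
        newb <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1),
                       character(1), USE.NAMES = FALSE)
        reads$bases <- replace_chars(reads$bases, ridx, p, newb)
      }
    }

    # barcode corruption
    if (barcode_error_rate > 0) {
      reads$umi1 <- corrupt_tags(reads$umi1, barcode_error_rate / 2)
      reads$umi2 <- corrupt_tags(reads$umi2, barcode_error_rate / 2)
    }

    reads <- dplyr::mutate(reads, read_id = dplyr::row_number(),
                           .before = 1)
    attr(reads, "whitelist") <- whitelist
    reads
  })
}

#' gregexpr helpers: -1 means no match
#' @noRd
valid_match <- function(m) {
  if (length(m) == 1 && m[1] == -1L) integer(0) else as.integer(m)
}

#' @noRd
lengths2 <- function(sites) {
  vapply(sites, function(m) length(valid_match(m)), integer(1))
}
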