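#' Exact (Garwood) Poisson confidence interval on a count
#' @noRd
poisson_ci <- function(k, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- ifelse(k == 0, 0, qchisq(a, 2 * k) / 2)
  hi <- qchisq(1 - a, 2 * k + 2) / 2
  cbind(unname(lo), unname(hi))
}

#' Per-nucleotide mutant frequency
#'
#' MF is the number of unique mutant nucleotides divided by the duplex base
#' pairs interrogated. Each variant call contributes its alternate molecule
#' count (identical variants in different molecules count as independent
#' events) — except calls classified as clonal expansions, which contribute
#' a single event when `clone_collapse = TRUE` (the default): a clone is one
#' initial mutagenic event regardless of how many descendant molecules were
#' sampled. Germline-flagged calls are excluded. The 95% CI is the exact
#' (Garwood) Poisson interval on the event count, scaled by `duplex_bp`.
#'
#' @param calls Variant call tibble (after [flag_germline()] and optionally
#'   [classify_clonality()]). Calls lacking a `clonal` column are treated as
#'   independent.
#' @param duplex_bp Duplex base pairs interrogated (> 0). When `by` is used,
#'   a tibble keyed by the same columns with a `duplex_bp` column.
#' @param clone_collapse Collapse clonal calls to one event each.
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("sample_id", "target")`).
#' @param conf Confidence level.
#'
#' @return Tibble with `n_mutations` (event count used for MF),
#'   `n_uncollapsed` (molecule count), `duplex_bp`, `mf`, `ci_lo`, `ci_hi`
#'   — one row per group (or a single row).
#' @export
#' @examples
#' calls <- tibble::tibble(target = "t", pos = c(3L, 9L, 20L), ref = "C",
#'                         alt = "T", alt_count = 1L, depth = 1000L,
#'                         vaf = 1e-3)
#' mutant_frequency(calls, duplex_bp = 2e7)
mutant_frequency <- function(calls, duplex_bp, clone_collapse = TRUE,
                             by = NULL, conf = 0.95) {
  if ("germline" %in% names(calls)) {
    calls <- calls[!calls$germline, , drop = FALSE]
  }
  contrib <- function(df) {
    clonal <- if ("clonal" %in% names(df)) df$clonal else
      rep(FALSE, nrow(df))
    events <- ifelse(clonal & clone_collapse, 1L, df$alt_count)
    tibble(n_mutations = sum(events), n_uncollapsed = sum(df$alt_count))
  }
  if (is.null(by)) {
    if (!is.numeric(duplex_bp) || length(duplex_bp) != 1 || duplex_bp <= 0) {
      abort("`duplex_bp` must be a single positive number")
    }
    res <- contrib(calls)
    res$duplex_bp <- duplex_bp
  } else {
    if (!is.data.frame(duplex_bp)) {
      abort("with `by`, `duplex_bp` must be a tibble keyed by the same columns")
    }
    res <- calls |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ contrib(.x)) |>
      dplyr::ungroup() |>
      dplyr::right_join(duplex_bp, by = by) |>
      dplyr::mutate(
        n_mutations = dplyr::coalesce(n_mutations, 0L),
        n_uncollapsed = dplyr::coalesce(n_uncollapsed, 0L))
    if (any(res$duplex_bp <= 0)) abort("`duplex_bp` must be positive")
  }
  ci <- poisson_ci(res$n_mutations, conf)
  res$mf <- res$n_mutations / res$duplex_bp
  res$ci_lo <- ci[, 1] / res$duplex_bp
  res$ci_hi <- ci[, 2] / res$duplex_bp
  res
}

#' Fold induction of mutant frequency
#'
#' Ratio of a treated group's mean MF to the control (vehicle) group's mean
#' MF. A zero control frequency leaves the fold undefined and is reported as
#' `NA` with a warning.
#'
#' @param treated,control Mean mutant frequencies (vectorised).
#' @return Numeric vector of fold inductions.
#' @export
#' @examples
#' fold_induction(1.16e-6, 1.48e-7)
fold_induction <- function(treated, control) {
  bad <- !is.na(control) & control == 0
  if (any(bad)) {
    warn("control MF of 0: fold induction undefined, reported as NA")
  }
  out <- treated / control
  out[bad] <- NA_real_
  out
}

#' Classify calls as singlets, independent multiplets, or clonal expansions
#'
#' Fits a normal distribution to log10(VAF) of all non-germline calls (a
#' log-normal model of allele frequencies). A call is classified `clonal`
#' when its log-VAF exceeds `mean + cutoff_sd * sd` **and** it was observed
#' in at least two molecules: a single-molecule observation can never
#' evidence a clonal expansion, however extreme its VAF. Remaining calls are
#' `singlet` (one molecule) or `multiplet_independent`. Fewer than 5
#' non-germline calls leave the model unfit (warning) and nothing is
#' classified clonal.
#'
#' @param calls Variant call tibble with `vaf` and `alt_count` (and
#'   optionally `germline`).
#' @param cutoff_sd Outlier cutoff in standard deviations (default 3).
#' @return `calls` with `classification` and `clonal` columns; the fitted
#'   model (class `clonality_model`) is attached as attribute `model` and
#'   available via [generics::glance()].
#' @export
classify_clonality <- function(calls, cutoff_sd = 3) {
  somatic <- if ("germline" %in% names(calls)) !calls$germline else
    rep(TRUE, nrow(calls))
  lv <- log10(calls$vaf[somatic])
  n <- sum(somatic)
  if (n < 5) {
    warn("fewer than 5 non-germline calls: clonality model not fit")
    model <- structure(list(mean = NA_real_, sd = NA_real_,
                            cutoff_sd = cutoff_sd, n = n), class = "clonality_model")
    clonal <- rep(FALSE, nrow(calls))
  } else {
    m <- mean(lv)
    s <- sqrt(mean((lv - m)^2))    # ML variance of the normal fit
    model <- structure(list(mean = m, sd = s, cutoff_sd = cutoff_sd, n = n),
                       class = "clonality_model")
    clonal <- somatic & log10(calls$vaf) > m + cutoff_sd * s &
      calls$alt_count >= 2
  }
  calls$clonal <- clonal
  calls$classification <- dplyr::case_when(
    !somatic ~ "germline",
    clonal ~ "clonal",
    calls$alt_count >= 2 ~ "multiplet_independent",
    .default = "singlet"
  )
  attr(calls, "model") <- model
  calls
}

#' @export
print.clonality_model <- function(x, ...) {
  cat("<clonality_model> log10(VAF) ~ Normal(mean =",
      format(x$mean, digits = 4), ", sd =", format(x$sd, digits = 4),
      ") on", x$n, "calls; cutoff", x$cutoff_sd, "sd\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method glance clonality_model
#' @export
glance.clonality_model <- function(x, ...) {
  tibble(mean_log10_vaf = x$mean, sd_log10_vaf = x$sd,
         cutoff_sd = x$cutoff_sd, n_calls = x$n,
         log10_vaf_cutoff = x$mean + x$cutoff_sd * x$sd)
}

#' Summarise clonal hotspot residues across samples
#'
#' For each annotated residue (e.g. an oncogenic codon), reports in how many
#' samples a clonal call was observed, supporting the "n of m samples"
#' summary style used for driver hotspots.
#'
#' @param calls Classified call tibble carrying `sample_id` (and optionally
#'   `tissue`) columns.
#' @param hotspots Tibble of annotated residues: `target`, `pos` (0-based;
#'   several rows may share a `label`, e.g. the three bases of a codon),
#'   `label`.
#' @return Tibble per (label, tissue): `n_samples` (samples observed in
#'   `calls`), `n_samples_clonal`, `alt_alleles`, `max_vaf`. Empty when no
#'   clonal calls exist.
#' @export
hotspot_report <- function(calls, hotspots) {
  stopifnot(all(c("target", "pos", "label") %in% names(hotspots)),
            "sample_id" %in% names(calls))
  has_tissue <- "tissue" %in% names(calls)
  grp <- if (has_tissue) c("label", "tissue") else "label"
  hits <- calls |>
    dplyr::inner_join(hotspots, by = c("target", "pos"),
                      relationship = "many-to-many") |>
    dplyr::filter(clonal)
  if (nrow(hits) == 0) {
    return(tibble(label = character(), n_samples = integer(),
                  n_samples_clonal = integer(), alt_alleles = character(),
                  max_vaf = double()))
  }
  denom <- if (has_tissue) {
    calls |> dplyr::distinct(tissue, sample_id) |>
      dplyr::count(tissue, name = "n_samples")
  } else {
    tibble(n_samples = dplyr::n_distinct(calls$sample_id))
  }
  out <- hits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_samples_clonal = dplyr::n_distinct(sample_id),
      alt_alleles = paste(sort(unique(alt)), collapse = ","),
      max_vaf = max(vaf), .groups = "drop")
  if (has_tissue) {
    dplyr::left_join(out, denom, by = "tissue") |>
      dplyr::relocate(label, tissue, n_samples, n_samples_clonal)
  } else {
    dplyr::mutate(out, n_samples = denom$n_samples[1],
                  .after = "label")
  }
}
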