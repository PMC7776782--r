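#' Cosine similarity between spectra
#'
#' `dot(u, v) / (||u|| ||v||)`; for nonnegative spectra the value lies in
#' [0, 1]. Zero vectors have no direction and raise an error.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Similarity in [-1, 1].
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Pairwise cosine distance (1 - similarity) of matrix rows
#' @noRd
cosine_dist <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) abort("cosine distance undefined for zero rows")
  sim <- (m %*% t(m)) / outer(norms, norms)
  sim[sim > 1] <- 1
  d <- 1 - sim
  diag(d) <- 0
  as.dist(d)
}

#' Coerce a sample-by-class spectrum input to a labelled matrix
#' @noRd
spectrum_input_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
    return(x)
  }
  stopifnot(is.data.frame(x))
  lab_col <- intersect(c("sample", "label"), names(x))[1]
  if (is.na(lab_col)) abort("data-frame input needs a `sample` column")
  m <- as.matrix(x[setdiff(names(x), lab_col)])
  rownames(m) <- x[[lab_col]]
  m
}

#' Hierarchical clustering of spectra by cosine distance
#'
#' Agglomerative clustering of sample spectra under WPGMA (weighted average,
#' the default) or Ward linkage on cosine distance. Merges are deterministic
#' for a given input; the displayed leaf order comes from a recursive
#' traversal that places the smaller subtree first (ties: the subtree
#' containing the smallest original row index) — a simple deterministic
#' stand-in for optimal leaf ordering that affects display only, never the
#' merges.
#'
#' @param x Sample-by-class matrix, or wide tibble from [bind_spectra()]
#'   with a `sample` column. At least 2 rows.
#' @param linkage `"wpgma"` or `"ward"`.
#' @return A `spectrum_dendrogram`: list with the underlying `hclust`
#'   object, `labels`, `leaf_order`, and `linkage`. [generics::tidy()] gives
#'   the merge table; [as_newick()] serialises the tree.
#' @export
hierarchical_cluster <- function(x, linkage = c("wpgma", "ward")) {
  linkage <- match.arg(linkage)
  m <- spectrum_input_matrix(x)
  if (nrow(m) < 2) abort("clustering needs at least 2 spectra")
  d <- cosine_dist(m)
  hc <- hclust(d, method = if (linkage == "wpgma") "mcquitty" else "ward.D2")
  structure(
    list(hclust = hc, labels = rownames(m),
         leaf_order = deterministic_leaf_order(hc$merge),
         linkage = linkage),
    class = "spectrum_dendrogram")
}

#' Smaller-subtree-first leaf order from an hclust merge matrix
#' @noRd
deterministic_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  info <- function(node) {
    # node < 0: leaf -(node); node > 0: internal merge row
    if (node < 0) {
      list(leaves = -node, size = 1L, minidx = -node)
    } else {
      a <- info(merge[node, 1])
      b <- info(merge[node, 2])
      first_a <- (a$size < b$size) ||
        (a$size == b$size && a$minidx < b$minidx)
      ordered <- if (first_a) c(a$leaves, b$leaves) else c(b$leaves, a$leaves)
      list(leaves = ordered, size = a$size + b$size,
           minidx = min(a$minidx, b$minidx))
    }
  }
  info(nrow(merge))$leaves
}

#' @export
print.spectrum_dendrogram <- function(x, ...) {
  cat("<spectrum_dendrogram>", length(x$labels), "leaves,",
      x$linkage, "linkage on cosine distance\n")
  cat("  leaf order:", paste(x$labels[x$leaf_order], collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy spectrum_dendrogram
#' @export
tidy.spectrum_dendrogram <- function(x, ...) {
  m <- x$hclust$merge
  lab <- function(v) {
    out <- character(length(v))
    neg <- v < 0
    out[neg] <- x$labels[-v[neg]]
    out[!neg] <- paste0("node", v[!neg])
    out
  }
  tibble(merge = seq_len(nrow(m)),
         left = lab(m[, 1]), right = lab(m[, 2]),
         height = x$hclust$height)
}

#' @method glance spectrum_dendrogram
#' @export
glance.spectrum_dendrogram <- function(x, ...) {
  tibble(n_leaves = length(x$labels), linkage = x$linkage,
         max_height = max(x$hclust$height))
}

#' Cut a spectrum dendrogram into k clusters
#'
#' @param dend A `spectrum_dendrogram`.
#' @param k Number of clusters.
#' @return Tibble: `sample`, `cluster`.
#' @export
cut_dendrogram <- function(dend, k) {
  ct <- cutree(dend$hclust, k = k)
  tibble(sample = dend$labels, cluster = unname(ct))
}

#' Serialise a spectrum dendrogram to Newick
#'
#' @param dend A `spectrum_dendrogram`.
#' @return Newick string (terminated by `;`).
#' @export
as_newick <- function(dend) {
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy)
}

#' Rank catalog signatures by similarity to a spectrum
#'
#' Computes the cosine similarity of a sample spectrum against every
#' signature of a catalog and returns them in descending order (stable ties:
#' catalog order).
#'
#' @param spectrum A `mut_spectrum` tibble (96-class) or named numeric
#'   vector over the 96 classes.
#' @param catalog Signature catalog: tibble with a `class` column (96
#'   canonical labels) and one numeric column per signature, as read by
#'   [read_signature_catalog()].
#' @return Tibble: `signature`, `similarity`, sorted descending.
#' @export
match_signatures <- function(spectrum, catalog) {
  if (is.data.frame(spectrum)) {
    spectrum <- setNames(spectrum$proportion, spectrum$class)
  }
  if (!"class" %in% names(catalog)) {
    abort("catalog must have a `class` label column")
  }
  if (!setequal(catalog$class, names(spectrum)) ||
      length(spectrum) != nrow(catalog)) {
    abort("catalog classes do not match the spectrum classes")
  }
  v <- spectrum[catalog$class]
  sigs <- setdiff(names(catalog), "class")
  sim <- vapply(sigs, function(s) cosine_similarity(v, catalog[[s]]),
                numeric(1))
  tibble(signature = sigs, similarity = unname(sim)) |>
    dplyr::arrange(dplyr::desc(similarity))
}

#' Read / write a signature catalog TSV
#'
#' The catalog format is a TSV with 96 rows labelled in the conventional
#' bracket notation (first column, e.g. `A[C>A]A`) and one numeric column
#' per signature.
#'
#' @param path File path.
#' @return Tibble with a `class` column and signature columns.
#' @export
read_signature_catalog <- function(path) {
  cat <- readr::read_tsv(path, show_col_types = FALSE)
  names(cat)[1] <- "class"
  if (!setequal(cat$class, sbs96_classes())) {
    abort("catalog must contain exactly the 96 canonical classes")
  }
  cat
}

#' @rdname read_signature_catalog
#' @param catalog Catalog tibble.
#' @export
write_signature_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}
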