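#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correspondence analysis
#'
#' @param x A `codon_coa` object.
#' @param what `"genes"` (default), `"codons"` or `"inertia"`.
#' @param ... Ignored.
#' @return A tibble of coordinates (or per-axis inertia).
#' @export
tidy.codon_coa <- function(x, what = c("genes", "codons", "inertia"), ...) {
  what <- match.arg(what)
  switch(what,
    genes = x$gene_coords,
    codons = x$codon_coords,
    inertia = x$inertia
  )
}

#' @rdname tidy.codon_coa
#' @export
glance.codon_coa <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$gene_coords),
    n_codons = nrow(x$codon_coords),
    n_axes = x$n_axes,
    total_inertia = x$total_inertia,
    axis1_fraction = x$inertia$fraction[1],
    axis2_fraction = if (x$n_axes >= 2) x$inertia$fraction[2] else NA_real_
  )
}

#' Tidy a species RSCU PCA
#'
#' @param x A `codon_pca` object.
#' @param ... Ignored.
#' @return Scores tibble (tidy) / one-row fit summary (glance).
#' @export
tidy.codon_pca <- function(x, ...) {
  x$scores
}

#' @rdname tidy.codon_pca
#' @export
glance.codon_pca <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$scores),
    n_components = length(x$explained),
    pc1_fraction = x$explained[1],
    pc2_fraction = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}

#' Summarise a codon pair table
#'
#' @param x A `codon_pair_table`.
#' @param ... Ignored.
#' @return One-row tibble: total and distinct pair counts.
#' @export
glance.codon_pair_table <- function(x, ...) {
  tibble::tibble(n_pairs = attr(x, "n_pairs"), n_distinct = nrow(x))
}

#' Summarise an optimal-codon table
#'
#' @param x An `optimal_codon_table`.
#' @param ... Ignored.
#' @return One-row tibble: optimal-codon count and C/G-ending tallies.
#' @export
glance.optimal_codon_table <- function(x, ...) {
  opt <- optimal_codon_set(x)
  tally <- attr(opt, "ending_base_tally")
  tibble::tibble(
    n_codons = nrow(x),
    n_optimal = nrow(opt),
    ending_c = unname(tally["C"]),
    ending_g = unname(tally["G"]),
    ending_a = unname(tally["A"]),
    ending_t = unname(tally["T"]),
    threshold = attr(x, "threshold"),
    alpha = attr(x, "alpha")
  )
}
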