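# Long-form correlation table between two column sets of a data frame.
correlate_columns <- function(df, xvars, yvars, method = "spearman") {
  grid <- expand.grid(var1 = xvars, var2 = yvars,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    x <- df[[grid$var1[i]]]
    y <- df[[grid$var2[i]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(
        var1 = grid$var1[i], var2 = grid$var2[i],
        r = NA_real_, p = NA_real_, n = sum(ok)
      ))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
    )
    tibble::tibble(
      var1 = grid$var1[i], var2 = grid$var2[i],
      r = unname(ct$estimate), p = ct$p.value, n = sum(ok)
    )
  })
  res$sig_05 <- !is.na(res$p) & res$p < 0.05
  res$sig_01 <- !is.na(res$p) & res$p < 0.01
  attr(res, "method") <- method
  class(res) <- c("codon_corr", class(res))
  res
}

#' Correspondence analysis of a gene x codon RSCU matrix
#'
#' Classical correspondence analysis: the table is converted to relative
#' frequencies P, row and column masses r and c computed, standardized
#' residuals `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` decomposed by SVD, and
#' principal coordinates returned for genes (rows) and codons (columns).
#' The explained inertia of axis k is `sigma_k^2 / sum(sigma^2)`; total
#' inertia equals the table's Pearson chi-square statistic divided by its
#' grand total.
#'
#' Undefined RSCU entries (families absent from a gene) are imputed as 0 and
#' the per-gene missingness recorded; genes with more than `max_missing`
#' missing entries are excluded.
#'
#' @param mat Non-negative numeric matrix (genes x codons), e.g. from
#'   [rscu_by_gene()] columns; or a CDS tibble (RSCU is computed).
#' @param n_axes Number of axes to return.
#' @param max_missing Maximum tolerated fraction of undefined RSCU entries
#'   per gene.
#' @return An object of class `codon_coa`: list with `gene_coords` (tibble:
#'   `gene_id`, `Axis1..k`, `missing_frac`), `codon_coords` (tibble: `codon`,
#'   `Axis1..k`), `inertia` (tibble: `axis`, `inertia`, `fraction`),
#'   `total_inertia`, `n_axes`.
#' @export
correspondence_analysis <- function(mat, n_axes = 5L, max_missing = 0.5) {
  if (is.data.frame(mat) && "sequence" %in% names(mat)) {
    mat <- rscu_matrix(codon_count_matrix(mat))
  }
  abort_if(!is.matrix(mat), "`mat` must be a numeric matrix")
  missing_frac <- rowMeans(is.na(mat))
  keep <- missing_frac <= max_missing
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) with > ", max_missing * 100,
            "% undefined entries excluded", call. = FALSE)
  }
  mat <- mat[keep, , drop = FALSE]
  missing_frac <- missing_frac[keep]
  mat[is.na(mat)] <- 0
  abort_if(any(mat < 0), "matrix must be non-negative")
  rs <- rowSums(mat)
  cs <- colSums(mat)
  abort_if(any(rs == 0), "all-zero row(s) after imputation")
  if (any(cs == 0)) {
    warning(sum(cs == 0), " all-zero column(s) dropped", call. = FALSE)
    mat <- mat[, cs > 0, drop = FALSE]
    cs <- cs[cs > 0]
  }

  p <- mat / sum(mat)
  r <- rowSums(p)
  c_m <- colSums(p)
  s <- sweep(sweep(p - outer(r, c_m), 1, sqrt(r), "/"), 2, sqrt(c_m), "/")
  sv <- svd(s)
  tol <- max(dim(s)) * max(sv$d) * .Machine$double.eps * 100
  pos <- which(sv$d > tol & sv$d > 1e-12)
  rank <- length(pos)
  if (rank < n_axes) {
    if (rank == 0) {
      # no variation at all: all coordinates zero on one degenerate axis
      rank <- 1L
      pos <- 1L
      sv$d[1] <- 0
    } else {
      warning("rank ", rank, " < n_axes; returning ", rank, " axes", call. = FALSE)
    }
  }
  k <- min(n_axes, rank)
  d <- sv$d[seq_len(k)]
  gene_pc <- sweep(sv$u[, seq_len(k), drop = FALSE], 1, sqrt(r), "/") %*% diag(d, k)
  codon_pc <- sweep(sv$v[, seq_len(k), drop = FALSE], 1, sqrt(c_m), "/") %*% diag(d, k)
  axis_names <- paste0("Axis", seq_len(k))
  colnames(gene_pc) <- colnames(codon_pc) <- axis_names

  total_inertia <- sum(sv$d^2)
  inertia <- tibble::tibble(
    axis = axis_names,
    inertia = d^2,
    fraction = if (total_inertia > 0) d^2 / total_inertia else rep(0, k)
  )
  out <- list(
    gene_coords = dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat)))),
      tibble::as_tibble(gene_pc),
      tibble::tibble(missing_frac = missing_frac)
    ),
    codon_coords = dplyr::bind_cols(
      tibble::tibble(codon = colnames(mat)),
      tibble::as_tibble(codon_pc)
    ),
    inertia = inertia,
    total_inertia = total_inertia,
    n_axes = k
  )
  class(out) <- "codon_coa"
  out
}

#' @export
print.codon_coa <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$gene_coords), "genes x",
      nrow(x$codon_coords), "codons\n")
  cat("Total inertia:", format(x$total_inertia, digits = 4), "\n")
  frac <- x$inertia$fraction
  cat("Axis fractions:", paste(sprintf("%.2f%%", 100 * frac), collapse = ", "), "\n")
  invisible(x)
}

#' Correlate CA axes with codon-usage indices
#'
#' @param coa A [correspondence_analysis()] result.
#' @param indices A [codon_usage_indices()] table sharing gene ids.
#' @param axes Axis names to correlate (default Axis1, Axis2).
#' @param method Correlation method.
#' @return A correlation tibble (class `codon_corr`).
#' @export
axis_correlations <- function(coa, indices, axes = c("Axis1", "Axis2"),
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  axes <- intersect(axes, names(coa$gene_coords))
  joined <- dplyr::inner_join(coa$gene_coords, indices, by = "gene_id")
  abort_if(nrow(joined) < 3, "fewer than 3 shared gene ids")
  idx_vars <- intersect(
    c("fpkm", "enc", "cai", "cbi", "fop", "gc", "gc3s", "gc12",
      "a3s", "t3s", "g3s", "c3s"),
    names(indices)
  )
  correlate_columns(joined, axes, idx_vars, method = method)
}

#' GC content class
#'
#' Three-way GC classification used to colour ordination plots: low when
#' GC < 45%, mid when 45% <= GC <= 60% (boundaries belong to the middle
#' class), high when GC > 60%.
#'
#' @param gc GC fraction(s) in `[0, 1]`.
#' @return Factor with levels `low`, `mid`, `high`.
#' @examples
#' gc_class(c(0.44, 0.45, 0.61))
#' @export
gc_class <- function(gc) {
  abort_if(any(gc < 0 | gc > 1, na.rm = TRUE), "gc must be in [0, 1]")
  factor(
    dplyr::case_when(gc < 0.45 ~ "low", gc > 0.60 ~ "high", TRUE ~ "mid"),
    levels = c("low", "mid", "high")
  )
}

#' GC3s tertile gene sets
#'
#' Ranks genes by GC3s (ties broken by gene id) and returns the bottom,
#' middle (centred on the median rank) and top `n_per_group` genes — the
#' low/mid/high GC3s groups used for downstream functional comparisons.
#'
#' @param indices A table with `gene_id` and `gc3s`.
#' @param n_per_group Genes per group.
#' @return A list of character vectors `low`, `mid`, `high`.
#' @export
gc3_tertiles <- function(indices, n_per_group) {
  ok <- !is.na(indices$gc3s)
  n <- sum(ok)
  abort_if(n < 3 * n_per_group, "too few genes for three disjoint groups")
  ids <- indices$gene_id[ok]
  ranked <- ids[order(indices$gc3s[ok], ids)]
  mid_start <- floor((n - n_per_group) / 2) + 1L
  list(
    low = ranked[seq_len(n_per_group)],
    mid = ranked[seq.int(mid_start, mid_start + n_per_group - 1L)],
    high = ranked[seq.int(n - n_per_group + 1L, n)]
  )
}

#' All-pairs correlation matrix of codon-usage indices
#'
#' Pairwise correlations among the per-gene usage indices (FPKM, ENc, CAI,
#' CBI, Fop, GC, GC3s, GC12, A3s, T3s, G3s, C3s), with two-sided p-values and
#' significance flags at 0.05 and 0.01. Columns absent from the table are
#' dropped with a warning.
#'
#' @param indices A [codon_usage_indices()] table.
#' @param method `"spearman"` (default; robust for index data) or
#'   `"pearson"`.
#' @return A long correlation tibble (class `codon_corr`): `var1`, `var2`,
#'   `r`, `p`, `n`, `sig_05`, `sig_01`.
#' @export
index_correlation_matrix <- function(indices, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  wanted <- c("fpkm", "enc", "cai", "cbi", "fop", "gc", "gc3s", "gc12",
              "a3s", "t3s", "g3s", "c3s")
  have <- intersect(wanted, names(indices))
  if (length(have) < length(wanted)) {
    warning("missing index column(s) dropped: ",
            paste(setdiff(wanted, have), collapse = ", "), call. = FALSE)
  }
  abort_if(nrow(indices) < 3, "need at least 3 genes")
  correlate_columns(indices, have, have, method = method)
}

#' Pooled per-species RSCU matrix
#'
#' Pools codon counts within each species and returns one RSCU row per
#' species over the 59 informative codons, in fixed codon order — the input
#' for cross-species clustering and PCA.
#'
#' @param cds A CDS tibble with a `species` column covering >= 2 species, or
#'   a named list of pooled 64-codon count vectors.
#' @return Numeric matrix, species x 59 codons.
#' @export
species_rscu_matrix <- function(cds) {
  pools <- if (is.data.frame(cds)) {
    assert_cds_tbl(cds)
    split(cds, cds$species) |> lapply(function(d) colSums(codon_count_matrix(d)))
  } else {
    lapply(cds, as_count_vector)
  }
  abort_if(length(pools) < 2, "need at least 2 species")
  code <- genetic_code()
  rows <- lapply(names(pools), function(sp) {
    v <- as_count_vector(pools[[sp]])
    abort_if(sum(v[code$sense_codons]) == 0, paste0("empty corpus for species ", sp))
    r <- rscu(v)
    stats::setNames(r$rscu, r$codon)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(pools)
  out
}

#' Hierarchical clustering of species by RSCU
#'
#' Agglomerative clustering of the species x codon RSCU matrix. The
#' dendrogram can be exported as Newick with branch heights via
#' [write_dendrogram_newick()].
#'
#' @param mat A [species_rscu_matrix()] result.
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (ward.D2).
#' @param distance `"euclidean"` (default) or `"correlation"` (1 - Pearson r).
#' @return An `hclust` object.
#' @export
cluster_species <- function(mat, linkage = c("average", "complete", "ward"),
                            distance = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  abort_if(nrow(mat) < 2, "need at least 2 species")
  m <- mat
  m[is.na(m)] <- 0
  d <- if (distance == "euclidean") {
    stats::dist(m)
  } else {
    stats::as.dist(1 - stats::cor(t(m)))
  }
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` object (see [cluster_species()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' PCA of the species x codon RSCU matrix
#'
#' Column-centred principal component analysis (SVD) of pooled RSCU rows.
#'
#' @param mat A [species_rscu_matrix()] result.
#' @param n_components Number of components to keep.
#' @return An object of class `codon_pca`: list with `scores` (tibble:
#'   `species`, `PC1..k`), `explained` (variance fractions, non-increasing)
#'   and the underlying `prcomp` fit.
#' @export
pca_species <- function(mat, n_components = 2L) {
  abort_if(nrow(mat) < 2, "need at least 2 species")
  m <- mat
  m[is.na(m)] <- 0
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > 1e-12)
  if (n_components > rank) {
    warning("n_components > rank; truncated to ", max(rank, 1L), call. = FALSE)
    n_components <- max(rank, 1L)
  }
  k <- seq_len(n_components)
  out <- list(
    scores = dplyr::bind_cols(
      tibble::tibble(species = rownames(m)),
      tibble::as_tibble(fit$x[, k, drop = FALSE])
    ),
    explained = (fit$sdev^2 / sum(fit$sdev^2))[k],
    fit = fit
  )
  class(out) <- "codon_pca"
  out
}

#' @export
print.codon_pca <- function(x, ...) {
  cat("PCA of species RSCU:", nrow(x$scores), "species\n")
  cat("Explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
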