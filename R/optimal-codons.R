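#' Split genes into high- and low-bias sets by ENc extremes
#'
#' The 10% of genes with the lowest ENc are treated as the high-bias
#' (high-expression-proxy) dataset and the 10% with the highest ENc as the
#' low-bias dataset. Ties are broken by lexicographic `gene_id`, so the split
#' is deterministic. Genes with undefined ENc are ignored.
#'
#' @param indices A per-gene table with `gene_id` and `enc` columns (see
#'   [codon_usage_indices()]), or any tibble with those columns.
#' @param fraction Tail fraction per side, in `(0, 0.5)`; set sizes are
#'   `floor(fraction * n)`.
#' @param by Ranking variable: `"enc"` (default, low = high bias) or `"fpkm"`
#'   (high = high expression).
#' @return A list with character vectors `high` and `low` of gene ids.
#' @export
split_by_enc <- function(indices, fraction = 0.10, by = c("enc", "fpkm")) {
  by <- match.arg(by)
  abort_if(fraction <= 0 || fraction >= 0.5, "`fraction` must be in (0, 0.5)")
  abort_if(!all(c("gene_id", by) %in% names(indices)),
           paste0("`indices` must have columns gene_id and ", by))
  v <- indices[[by]]
  ok <- !is.na(v)
  abort_if(sum(ok) < 20, "need at least 20 genes with a defined ranking value")
  ids <- indices$gene_id[ok]
  v <- v[ok]
  ord <- order(v, ids)
  n_sel <- floor(fraction * length(ids))
  ranked <- ids[ord]
  if (by == "enc") {
    list(high = ranked[seq_len(n_sel)], low = rev(ranked)[seq_len(n_sel)])
  } else {
    list(high = rev(ranked)[seq_len(n_sel)], low = ranked[seq_len(n_sel)])
  }
}

#' Delta-RSCU table comparing high- and low-bias codon pools
#'
#' Computes pooled RSCU for the high- and low-bias gene pools and their
#' difference for each of the 59 informative codons, with a per-codon 2x2
#' chi-square test (this codon vs the rest of its family, high vs low pool;
#' Yates continuity correction, Fisher's exact test when an expected cell is
#' below 5). A codon is flagged optimal when `rscu_high > 1`,
#' `delta_rscu >= threshold` and `chi2_p < alpha`.
#'
#' @param high,low Pooled codon counts for each set: named 64-vectors, count
#'   matrices, or CDS tibbles.
#' @param threshold Minimum delta-RSCU for optimality (default 0.08).
#' @param alpha Chi-square significance level (default 0.01).
#' @return A tibble of class `optimal_codon_table`: `aa`, `codon`,
#'   `rscu_high`, `rscu_low`, `delta_rscu`, `chi2_p`, `is_optimal`, sorted by
#'   amino acid then codon. Codons of families absent from either pool carry
#'   `NA` statistics and are never optimal.
#' @examples
#' # identical pools: all deltas 0, nothing optimal
#' pool <- count_codons(strrep("ATGGCTGCCAAAGAATTT", 40))
#' tab <- delta_rscu_table(pool, pool)
#' sum(tab$is_optimal, na.rm = TRUE) # 0
#' @export
delta_rscu_table <- function(high, low, threshold = 0.08, alpha = 0.01) {
  if (is.data.frame(high)) high <- codon_count_matrix(high)
  if (is.data.frame(low)) low <- codon_count_matrix(low)
  vh <- as_count_vector(high)
  vl <- as_count_vector(low)
  code <- genetic_code()
  abort_if(sum(vh[code$sense_codons]) == 0 || sum(vl[code$sense_codons]) == 0,
           "both pools must be non-empty")
  rh <- rscu(vh)
  rl <- rscu(vl)

  fam_tot_h <- tapply(rh$count, rh$aa, sum)
  fam_tot_l <- tapply(rl$count, rl$aa, sum)
  p <- purrr::map_dbl(seq_len(nrow(rh)), function(i) {
    ch <- rh$count[i]; cl <- rl$count[i]
    resth <- fam_tot_h[[rh$aa[i]]] - ch
    restl <- fam_tot_l[[rl$aa[i]]] - cl
    tab <- matrix(c(ch, resth, cl, restl), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(NA_real_)
    }
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 5)) {
      stats::fisher.test(tab)$p.value
    } else {
      stats::chisq.test(tab, correct = TRUE)$p.value
    }
  })

  delta <- rh$rscu - rl$rscu
  out <- tibble::tibble(
    aa = rh$aa,
    codon = rh$codon,
    rscu_high = rh$rscu,
    rscu_low = rl$rscu,
    delta_rscu = delta,
    chi2_p = p,
    is_optimal = !is.na(rh$rscu) & !is.na(rl$rscu) & !is.na(p) &
      rh$rscu > 1 & delta >= threshold & p < alpha
  )
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("optimal_codon_table", class(out))
  out
}

#' Extract the optimal-codon set from a delta-RSCU table
#'
#' @param records A [delta_rscu_table()] result.
#' @return The optimal rows as a tibble, with attribute `ending_base_tally`
#'   (a table of third bases over the optimal codons, reporting e.g. how many
#'   are C-ending vs G-ending).
#' @export
optimal_codon_set <- function(records) {
  abort_if(!all(c("codon", "is_optimal") %in% names(records)),
           "`records` must come from delta_rscu_table()")
  opt <- records[!is.na(records$is_optimal) & records$is_optimal, , drop = FALSE]
  tally <- table(factor(substr(opt$codon, 3, 3), levels = c("A", "C", "G", "T")))
  attr(opt, "ending_base_tally") <- tally
  opt
}

#' Find optimal codons for a CDS set
#'
#' End-to-end optimal-codon determination: rank genes by ENc, pool the codon
#' counts of the two 10% extremes, and run the delta-RSCU + chi-square
#' comparison.
#'
#' @param cds A filtered CDS tibble.
#' @param indices Optional precomputed index table with `enc` (saves
#'   recomputation).
#' @param fraction,threshold,alpha,by See [split_by_enc()] and
#'   [delta_rscu_table()].
#' @return An `optimal_codon_table` (see [delta_rscu_table()]); the gene id
#'   sets used are attached as attribute `split`.
#' @export
find_optimal_codons <- function(cds, indices = NULL, fraction = 0.10,
                                threshold = 0.08, alpha = 0.01, by = "enc") {
  assert_cds_tbl(cds)
  m <- codon_count_matrix(cds)
  if (is.null(indices)) {
    indices <- enc_from_counts(m)
    if (by == "fpkm") indices$fpkm <- cds$fpkm[match(indices$gene_id, cds$gene_id)]
  }
  sets <- split_by_enc(indices, fraction = fraction, by = by)
  pool <- function(ids) colSums(m[rownames(m) %in% ids, , drop = FALSE])
  out <- delta_rscu_table(pool(sets$high), pool(sets$low),
                          threshold = threshold, alpha = alpha)
  attr(out, "split") <- sets
  out
}
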