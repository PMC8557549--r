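#' Count in-frame adjacent codon pairs (duplex codons)
#'
#' Slides a window of two codons (step one codon) along each gene separately —
#' no cross-gene pairs — and counts every ordered sense-codon pair. Pairs
#' containing a stop codon are excluded, so a trailing stop contributes
#' nothing.
#'
#' @param cds A filtered CDS tibble, or a list of codon-token vectors.
#' @return A tibble of class `codon_pair_table`: `codon1`, `codon2`, `n`
#'   (counts > 0 only), with attribute `n_pairs` = total pairs counted.
#' @examples
#' cds <- tibble::tibble(gene_id = "g", species = "toy",
#'                       sequence = "ATGGCTGCT", fpkm = NA_real_)
#' count_codon_pairs(cds)
#' @export
count_codon_pairs <- function(cds) {
  code <- genetic_code()
  tokens <- if (is.data.frame(cds)) {
    assert_cds_tbl(cds)
    lapply(cds$sequence, split_codons)
  } else {
    cds
  }
  pair_strings <- unlist(lapply(tokens, function(cod) {
    if (length(cod) < 2L) {
      return(character(0))
    }
    a <- cod[-length(cod)]
    b <- cod[-1L]
    keep <- a %in% code$sense_codons & b %in% code$sense_codons
    paste(a[keep], b[keep])
  }))
  if (length(pair_strings) == 0) {
    out <- tibble::tibble(codon1 = character(0), codon2 = character(0), n = integer(0))
  } else {
    tab <- table(pair_strings)
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    out <- tibble::tibble(
      codon1 = vapply(parts, `[[`, "", 1L),
      codon2 = vapply(parts, `[[`, "", 2L),
      n = as.integer(tab)
    )
  }
  attr(out, "n_pairs") <- sum(out$n)
  class(out) <- c("codon_pair_table", class(out))
  out
}

#' Preferred codon pair per amino-acid pair
#'
#' For every amino-acid pair present in the table, the most frequent codon
#' pair encoding it. Ties are broken lexicographically on the concatenated
#' codon pair and flagged.
#'
#' @param pairs A [count_codon_pairs()] table.
#' @param normalize Divide each pair count by the product of the two codons'
#'   marginal frequencies before taking the maximum (frequency-normalized
#'   mode); default uses raw counts.
#' @return A tibble: `aa1`, `aa2` (three-letter), `codon1`, `codon2`, `n`,
#'   `tie` (logical).
#' @export
preferred_pairs <- function(pairs, normalize = FALSE) {
  abort_if(nrow(pairs) == 0, "empty codon pair table")
  code <- genetic_code()
  df <- dplyr::mutate(
    tibble::as_tibble(pairs),
    aa1 = unname(code$aa3[code$codon_to_aa[.data$codon1]]),
    aa2 = unname(code$aa3[code$codon_to_aa[.data$codon2]]),
    score = if (normalize) {
      m1 <- stats::ave(.data$n, .data$codon1, FUN = sum)
      m2 <- stats::ave(.data$n, .data$codon2, FUN = sum)
      .data$n / (m1 * m2)
    } else {
      as.numeric(.data$n)
    }
  )
  df |>
    dplyr::group_by(.data$aa1, .data$aa2) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$codon1, .data$codon2,
                   .by_group = TRUE) |>
    dplyr::summarise(
      codon1 = .data$codon1[1], codon2 = .data$codon2[1], n = .data$n[1],
      tie = sum(.data$score == .data$score[1]) > 1L,
      .groups = "drop"
    )
}

#' Differing preferred codon pairs between two species
#'
#' Rows only for amino-acid pairs present in both maps whose preferred codon
#' pairs differ — the cross-species duplex-codon comparison.
#'
#' @param a,b [preferred_pairs()] tables for the two species.
#' @param rna Render codons in the RNA alphabet (U for T) in the output.
#' @return A tibble: `aa1`, `aa2`, `pair_a`, `pair_b`.
#' @export
diff_preferred_pairs <- function(a, b, rna = FALSE) {
  j <- dplyr::inner_join(
    dplyr::transmute(a, .data$aa1, .data$aa2,
                     pair_a = paste0(.data$codon1, .data$codon2)),
    dplyr::transmute(b, .data$aa1, .data$aa2,
                     pair_b = paste0(.data$codon1, .data$codon2)),
    by = c("aa1", "aa2")
  )
  out <- dplyr::filter(j, .data$pair_a != .data$pair_b)
  if (rna) {
    out$pair_a <- gsub("T", "U", out$pair_a, fixed = TRUE)
    out$pair_b <- gsub("T", "U", out$pair_b, fixed = TRUE)
  }
  out
}

#' Consistency of same-amino-acid preferred pairs with the optimal codons
#'
#' For each homopair (Asp-Asp, Arg-Arg, ...), checks whether either codon of
#' the preferred duplex belongs to the optimal-codon set. Inconsistencies —
#' a high-frequency codon pair built from non-optimal codons — are a known
#' signature of pair-level usage differing from single-codon preference.
#'
#' @param preferred A [preferred_pairs()] table.
#' @param optimal_set Character vector of optimal codons (DNA alphabet).
#' @return A tibble: `aa`, `codon1`, `codon2`, `consistent` (TRUE when either
#'   codon of the pair is optimal for that amino acid).
#' @export
pair_vs_optimal_consistency <- function(preferred, optimal_set) {
  same <- dplyr::filter(preferred, .data$aa1 == .data$aa2)
  tibble::tibble(
    aa = same$aa1,
    codon1 = same$codon1,
    codon2 = same$codon2,
    consistent = same$codon1 %in% optimal_set | same$codon2 %in% optimal_set
  )
}
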