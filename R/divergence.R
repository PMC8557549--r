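# ---- NG86 lookup tables -----------------------------------------------------
# Site fractions and pathway-averaged difference counts are pure functions of
# the genetic code; they are computed once and cached.

ng86_tables <- function() {
  if (!is.null(.cs_cache$ng86)) {
    return(.cs_cache$ng86)
  }
  code <- genetic_code()
  c2a <- code$codon_to_aa
  sense <- code$sense_codons
  bases <- c("A", "C", "G", "T")

  # Synonymous site fraction per codon: at each position, the fraction of
  # non-stop single-base changes that are synonymous; S + N = 3 per codon.
  syn_sites <- stats::setNames(rep(NA_real_, 64), code$codons)
  for (cod in sense) {
    s <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(bases, substr(cod, pos, pos)), function(b) {
        x <- cod
        substr(x, pos, pos) <- b
        x
      }, character(1))
      ok <- c2a[alts] != "*"
      if (any(ok)) s <- s + sum(c2a[alts[ok]] == c2a[cod]) / sum(ok)
    }
    syn_sites[cod] <- s
  }

  # Pathway-averaged synonymous / nonsynonymous difference counts for every
  # ordered sense-codon pair. Minimal mutational pathways through stop codons
  # are excluded (all-blocked pairs fall back to all pathways).
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  perms <- list(
    `1` = matrix(1, 1, 1),
    `2` = rbind(c(1, 2), c(2, 1)),
    `3` = rbind(
      c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
    )
  )
  for (i in seq_len(n)) {
    ci <- sense[i]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- sense[j]
      diffpos <- which(strsplit(ci, "")[[1]] != strsplit(cj, "")[[1]])
      d <- length(diffpos)
      orders <- perms[[as.character(d)]]
      path_sd <- path_nd <- numeric(0)
      blocked_sd <- blocked_nd <- numeric(0)
      for (r in seq_len(nrow(orders))) {
        cur <- ci
        sd <- nd <- 0
        blocked <- FALSE
        for (pos in diffpos[orders[r, ]]) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(cj, pos, pos)
          if (c2a[nxt] == "*") blocked <- TRUE
          if (c2a[nxt] == c2a[cur]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        if (blocked) {
          blocked_sd <- c(blocked_sd, sd)
          blocked_nd <- c(blocked_nd, nd)
        } else {
          path_sd <- c(path_sd, sd)
          path_nd <- c(path_nd, nd)
        }
      }
      if (length(path_sd) == 0) {
        path_sd <- blocked_sd
        path_nd <- blocked_nd
      }
      sd_mat[i, j] <- mean(path_sd)
      nd_mat[i, j] <- mean(path_nd)
    }
  }
  .cs_cache$ng86 <- list(syn_sites = syn_sites, sd = sd_mat, nd = nd_mat)
  .cs_cache$ng86
}

# ---- Alignment --------------------------------------------------------------

#' Codon alignment of an ortholog pair
#'
#' Globally aligns the translated amino-acid sequences (BLOSUM62, affine
#' gaps) and back-translates the alignment to codons. Gap columns are
#' excluded from the returned codon pairs. A trailing stop codon is removed
#' before translation.
#'
#' @param a,b One-row CDS tibbles or nucleotide strings.
#' @param id_a,id_b Identifiers (taken from the tibbles when present).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A tibble of aligned codon pairs (`codon_a`, `codon_b`), class
#'   `codon_alignment`, with attributes `id_a`, `id_b`, `n_codons_aligned`.
#' @export
align_ortholog_pair <- function(a, b, id_a = NULL, id_b = NULL,
                                gap_opening = 10, gap_extension = 0.5) {
  get_seq <- function(x, default_id) {
    if (is.data.frame(x)) {
      abort_if(nrow(x) != 1L, "pass single sequences to align_ortholog_pair()")
      list(seq = x$sequence, id = x$gene_id)
    } else {
      list(seq = x, id = default_id)
    }
  }
  sa <- get_seq(a, id_a %||% "a")
  sb <- get_seq(b, id_b %||% "b")
  code <- genetic_code()

  strip_stop <- function(s) {
    cod <- split_codons(s)
    if (length(cod) > 0 && cod[length(cod)] %in% code$stop_codons) {
      cod <- cod[-length(cod)]
    }
    cod
  }
  cod_a <- strip_stop(sa$seq)
  cod_b <- strip_stop(sb$seq)
  abort_if(length(cod_a) == 0 || length(cod_b) == 0, "translated length is 0")

  aa_a <- paste(code$codon_to_aa[cod_a], collapse = "")
  aa_b <- paste(code$codon_to_aa[cod_b], collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  ia <- cumsum(pat != "-")
  ib <- cumsum(sub != "-")
  keep <- pat != "-" & sub != "-"
  out <- tibble::tibble(codon_a = cod_a[ia[keep]], codon_b = cod_b[ib[keep]])
  attr(out, "id_a") <- sa$id
  attr(out, "id_b") <- sb$id
  attr(out, "n_codons_aligned") <- nrow(out)
  class(out) <- c("codon_alignment", class(out))
  out
}

# ---- NG86 estimator ---------------------------------------------------------

#' Nei-Gojobori (1986) Ka/Ks estimation for a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the two
#' sequences), pathway-averages the difference counts for codons differing at
#' multiple positions (pathways through stop codons excluded), and applies the
#' Jukes-Cantor correction `d = -3/4 * ln(1 - 4p/3)` to both proportions.
#'
#' @param alignment A [align_ortholog_pair()] result, or a two-column tibble /
#'   data frame of aligned codons.
#' @return One-row tibble: `id_a`, `id_b`, `ka`, `ks`, `omega` (`NA` when
#'   `ks = 0`; `Inf` flagged when `ka > 0, ks = 0`), `selection_class`,
#'   `n_codons_aligned`, `saturated` (`TRUE` when a proportion reached the
#'   Jukes-Cantor singularity p >= 3/4).
#' @examples
#' aln <- align_ortholog_pair("ATGGAAGAA", "ATGGAAGAG")
#' ng86_kaks(aln)$ka # 0
#' @export
ng86_kaks <- function(alignment) {
  tabs <- ng86_tables()
  code <- genetic_code()
  ca <- alignment[[1]]
  cb <- alignment[[2]]
  keep <- ca %in% code$sense_codons & cb %in% code$sense_codons
  ca <- ca[keep]
  cb <- cb[keep]
  abort_if(length(ca) == 0, "no aligned sense codon pairs")

  s_a <- sum(tabs$syn_sites[ca])
  s_b <- sum(tabs$syn_sites[cb])
  s_sites <- (s_a + s_b) / 2
  n_sites <- 3 * length(ca) - s_sites

  idx <- cbind(match(ca, rownames(tabs$sd)), match(cb, colnames(tabs$sd)))
  sd <- sum(tabs$sd[idx])
  nd <- sum(tabs$nd[idx])

  jc <- function(p) {
    if (p >= 0.75) {
      return(NA_real_)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  ks <- jc(ps)
  ka <- jc(pn)
  saturated <- is.na(ks) || is.na(ka)
  omega <- if (saturated || is.na(ks) || ks == 0) {
    if (!saturated && !is.na(ka) && ka > 0) Inf else NA_real_
  } else {
    ka / ks
  }
  tibble::tibble(
    id_a = attr(alignment, "id_a") %||% "a",
    id_b = attr(alignment, "id_b") %||% "b",
    ka = ka, ks = ks, omega = omega,
    selection_class = classify_omega(omega),
    n_codons_aligned = length(ca),
    saturated = saturated
  )
}

classify_omega <- function(omega) {
  dplyr::case_when(
    is.na(omega) | is.infinite(omega) ~ "undefined",
    omega > 1 ~ "positive",
    omega < 1 ~ "purifying",
    TRUE ~ "neutral"
  )
}

#' Ka/Ks for a table of ortholog pairs
#'
#' Aligns and estimates NG86 Ka/Ks for every ortholog pair in a mapping
#' table.
#'
#' @param cds_a,cds_b CDS tibbles for the two species.
#' @param orthologs A tibble with columns `id_a`, `id_b` (see
#'   [read_ortholog_tsv()]).
#' @return A tibble of per-pair divergence records (see [ng86_kaks()]); pairs
#'   whose ids are missing from the CDS sets are skipped with a warning.
#' @export
kaks_table <- function(cds_a, cds_b, orthologs) {
  abort_if(!all(c("id_a", "id_b") %in% names(orthologs)),
           "`orthologs` needs columns id_a, id_b")
  ok <- orthologs$id_a %in% cds_a$gene_id & orthologs$id_b %in% cds_b$gene_id
  if (any(!ok)) {
    warning(sum(!ok), " ortholog pair(s) with unknown gene ids skipped", call. = FALSE)
  }
  orth <- orthologs[ok, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(orth)), function(i) {
    aln <- align_ortholog_pair(
      cds_a$sequence[cds_a$gene_id == orth$id_a[i]][1],
      cds_b$sequence[cds_b$gene_id == orth$id_b[i]][1],
      id_a = orth$id_a[i], id_b = orth$id_b[i]
    )
    ng86_kaks(aln)
  })
}

#' Read an ortholog-pair mapping (TSV of id_a, id_b)
#'
#' @param path Path to a TSV with header `id_a<TAB>id_b`.
#' @return A tibble with `id_a`, `id_b`.
#' @export
read_ortholog_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Read externally computed Ka/Ks values
#'
#' Injection hook for divergence estimates produced outside the package
#' (e.g. a maximum-likelihood codon model): a TSV with columns `id_a`, `id_b`,
#' `ka`, `ks` is loaded and omega plus the selection class are derived.
#'
#' @param path Path to the TSV.
#' @return A per-pair divergence tibble compatible with [classify_selection()].
#' @export
read_kaks_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id_a = readr::col_character(), id_b = readr::col_character(),
    ka = readr::col_double(), ks = readr::col_double()
  ))
  df$omega <- ifelse(df$ks > 0, df$ka / df$ks, ifelse(df$ka > 0, Inf, NA_real_))
  df$selection_class <- classify_omega(df$omega)
  df
}

#' Partition ortholog pairs by selection regime
#'
#' Splits divergence records into positive (omega > 1), purifying (omega < 1),
#' neutral (omega = 1) and undefined (omega not computable: ks = 0 or
#' saturated) strata, with per-stratum means. Infinite omegas are excluded
#' from means, matching the convention of reporting only the computable
#' subset.
#'
#' @param pairs A per-pair divergence tibble ([kaks_table()] or
#'   [read_kaks_tsv()]).
#' @return A list: `pairs` (input with `selection_class` refreshed) and
#'   `summary` (tibble of n and mean ka/ks/omega per stratum, plus an
#'   `overall` row for pairs with defined omega).
#' @export
classify_selection <- function(pairs) {
  pairs$selection_class <- classify_omega(pairs$omega)
  strata <- pairs |>
    dplyr::group_by(.data$selection_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ka = mean(.data$ka, na.rm = TRUE),
      mean_ks = mean(.data$ks, na.rm = TRUE),
      mean_omega = mean(.data$omega[is.finite(.data$omega)], na.rm = TRUE),
      .groups = "drop"
    )
  defined <- pairs[is.finite(pairs$omega), , drop = FALSE]
  overall <- tibble::tibble(
    selection_class = "overall",
    n = nrow(defined),
    mean_ka = mean(defined$ka, na.rm = TRUE),
    mean_ks = mean(defined$ks, na.rm = TRUE),
    mean_omega = mean(defined$omega, na.rm = TRUE)
  )
  list(pairs = pairs, summary = dplyr::bind_rows(strata, overall))
}

#' Correlate divergence with codon-usage indices within a selection stratum
#'
#' Joins per-pair Ka/Ks records (by the species-A gene id) to the per-gene
#' index table and correlates ka, ks and omega against the usage indices.
#'
#' @param pairs A per-pair divergence tibble.
#' @param indices A [codon_usage_indices()] table for species A.
#' @param stratum `"purifying"`, `"positive"`, or `"all"`.
#' @param method Correlation method (default Spearman).
#' @return A correlation tibble (class `codon_corr`; see
#'   [index_correlation_matrix()] for columns).
#' @export
divergence_index_correlation <- function(pairs, indices,
                                         stratum = c("purifying", "positive", "all"),
                                         method = c("spearman", "pearson")) {
  stratum <- match.arg(stratum)
  method <- match.arg(method)
  pairs$selection_class <- classify_omega(pairs$omega)
  sel <- if (stratum == "all") pairs else pairs[pairs$selection_class == stratum, , drop = FALSE]
  abort_if(nrow(sel) < 3, "need at least 3 pairs with defined values in stratum")
  joined <- dplyr::inner_join(sel, indices, by = c(id_a = "gene_id"))
  idx_vars <- intersect(
    c("enc", "cai", "cbi", "fop", "gc", "gc3s", "gc12", "a3s", "t3s", "g3s", "c3s"),
    names(joined)
  )
  correlate_columns(joined, c("ka", "ks", "omega"), idx_vars, method = method)
}
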