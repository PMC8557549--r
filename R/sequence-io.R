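#' Read coding sequences from a FASTA file
#'
#' Reads a (plain or gzipped) multi-FASTA file of coding sequences into a
#' tibble, one row per record. Sequences are case-folded to upper case and RNA
#' `U` is normalized to DNA `T`; record order is preserved. The FASTA id is
#' taken as the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param species_label Species label attached to every record.
#' @return A tibble with columns `gene_id`, `species`, `sequence`, `fpkm`
#'   (`NA` until joined with an expression table).
#' @seealso [filter_cds()], [read_expression_tsv()]
#' @export
read_cds_fasta <- function(path, species_label = NA_character_) {
  abort_if(!file.exists(path), paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(
      gene_id = character(0), species = character(0),
      sequence = character(0), fpkm = numeric(0)
    ))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  tibble::tibble(
    gene_id = ids,
    species = species_label,
    sequence = unname(seqs),
    fpkm = NA_real_
  )
}

#' Write coding sequences to a FASTA file
#'
#' @param cds A CDS tibble (see [read_cds_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, width = 70L) {
  assert_cds_tbl(cds)
  set <- Biostrings::DNAStringSet(stats::setNames(cds$sequence, cds$gene_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene expression table (FPKM)
#'
#' Reads a two-column TSV with header `gene_id<TAB>fpkm` and joins the FPKM
#' values onto a CDS tibble when one is supplied.
#'
#' @param path Path to the TSV.
#' @param cds Optional CDS tibble; if given, the return value is `cds` with its
#'   `fpkm` column filled in by `gene_id`.
#' @return A tibble of expression values, or `cds` with `fpkm` joined.
#' @export
read_expression_tsv <- function(path, cds = NULL) {
  expr <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), fpkm = readr::col_double()
  ))
  abort_if(any(expr$fpkm < 0, na.rm = TRUE), "fpkm values must be >= 0")
  if (is.null(cds)) {
    return(expr)
  }
  assert_cds_tbl(cds)
  cds$fpkm <- expr$fpkm[match(cds$gene_id, expr$gene_id)]
  cds
}

#' Filter coding sequences by length, ambiguity and internal stops
#'
#' Applies the standard pre-analysis filters to a CDS set: minimum length
#' (default 400 bp, sequences strictly shorter are eliminated), removal of
#' sequences containing ambiguity codes (`N` or any non-ACGT IUPAC letter) and,
#' optionally, removal of sequences with an in-frame internal stop codon.
#' A trailing incomplete codon is trimmed from every kept sequence. Each
#' rejected sequence is counted against the *first* failing rule, in the fixed
#' order length, then ambiguity, then internal stop, so the report is
#' deterministic.
#'
#' @param cds A CDS tibble (see [read_cds_fasta()]).
#' @param min_length Minimum length in bp; sequences with fewer bases are
#'   rejected. Must be >= 3.
#' @param drop_ambiguous Drop sequences containing characters outside
#'   `{A,C,G,T}`.
#' @param drop_internal_stops Drop sequences with an in-frame stop codon before
#'   the final codon.
#' @return The kept rows (with trimmed sequences), with a `report` attribute —
#'   a tibble of per-rule rejection counts (`length_fail`, `ambiguous`,
#'   `internal_stop`) plus `trimmed`, the number of kept sequences whose
#'   trailing partial codon was removed. Retrieve it with [cds_filter_report()].
#'   Filtering never raises on bad sequences; everything is recorded.
#' @examples
#' cds <- tibble::tibble(
#'   gene_id = c("a", "b"), species = "toy",
#'   sequence = c(strrep("ATGGCT", 70), "ATGNNN"), fpkm = NA_real_
#' )
#' kept <- filter_cds(cds)
#' cds_filter_report(kept)
#' @export
filter_cds <- function(cds, min_length = 400L, drop_ambiguous = TRUE,
                       drop_internal_stops = TRUE) {
  assert_cds_tbl(cds)
  abort_if(min_length < 3, "`min_length` must be >= 3")
  code <- genetic_code()

  n_in <- nrow(cds)
  if (n_in == 0) {
    report <- tibble::tibble(
      rule = c("length_fail", "ambiguous", "internal_stop"),
      n = c(0L, 0L, 0L)
    )
    out <- cds
    attr(out, "report") <- report
    attr(out, "trimmed") <- 0L
    return(out)
  }

  seqs <- cds$sequence
  len_fail <- nchar(seqs) < min_length
  ambiguous <- !len_fail & grepl("[^ACGT]", seqs)
  if (!drop_ambiguous) ambiguous[] <- FALSE

  internal_stop <- rep(FALSE, n_in)
  if (drop_internal_stops) {
    candidate <- which(!len_fail & !ambiguous)
    internal_stop[candidate] <- vapply(seqs[candidate], function(s) {
      cod <- split_codons(s)
      length(cod) > 1L && any(cod[-length(cod)] %in% code$stop_codons)
    }, logical(1), USE.NAMES = FALSE)
  }

  keep <- !(len_fail | ambiguous | internal_stop)
  kept <- cds[keep, , drop = FALSE]
  trimmed_len <- nchar(kept$sequence) %/% 3L * 3L
  n_trimmed <- sum(trimmed_len != nchar(kept$sequence))
  kept$sequence <- substr(kept$sequence, 1L, trimmed_len)

  report <- tibble::tibble(
    rule = c("length_fail", "ambiguous", "internal_stop"),
    n = c(sum(len_fail), sum(ambiguous), sum(internal_stop))
  )
  attr(kept, "report") <- report
  attr(kept, "trimmed") <- n_trimmed
  kept
}

#' Rejection report of a filtered CDS set
#'
#' @param cds The return value of [filter_cds()].
#' @return A tibble of per-rule rejection counts.
#' @export
cds_filter_report <- function(cds) {
  rep <- attr(cds, "report")
  abort_if(is.null(rep), "no filter report attached; did this come from filter_cds()?")
  rep
}

#' Split a coding sequence into codons
#'
#' Tokenizes a CDS into its in-frame codons (reading frame 0). A trailing
#' incomplete codon is dropped. A trailing stop codon is retained in the token
#' list; the return value carries a `has_stop` attribute flagging it.
#'
#' @param sequence A nucleotide string (or a one-row CDS tibble).
#' @return Character vector of codons, with attribute `has_stop`.
#' @examples
#' tokenize_codons("ATGGCTTAA") # "ATG" "GCT" "TAA"
#' @export
tokenize_codons <- function(sequence) {
  if (is.data.frame(sequence)) {
    abort_if(nrow(sequence) != 1L, "pass a single sequence to tokenize_codons()")
    sequence <- sequence$sequence
  }
  abort_if(nchar(sequence) < 3L, "sequence shorter than one codon")
  cod <- split_codons(sequence)
  attr(cod, "has_stop") <- cod[length(cod)] %in% genetic_code()$stop_codons
  cod
}
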