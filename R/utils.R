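`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

# Split a nucleotide string into codons, dropping a trailing incomplete codon.
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L * 3L
  if (n < 3L) {
    return(character(0))
  }
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

assert_cds_tbl <- function(cds) {
  abort_if(!is.data.frame(cds), "`cds` must be a data frame of coding sequences")
  missing <- setdiff(c("gene_id", "sequence"), names(cds))
  abort_if(
    length(missing) > 0,
    paste0("`cds` is missing column(s): ", paste(missing, collapse = ", "))
  )
  invisible(cds)
}

# Named 64-vector of codon counts from a genes x 64 matrix or a named vector.
as_count_vector <- function(counts, code = genetic_code()) {
  if (is.matrix(counts)) counts <- colSums(counts)
  abort_if(is.null(names(counts)), "codon counts must be named by codon")
  out <- stats::setNames(numeric(64), code$codons)
  unknown <- setdiff(names(counts), code$codons)
  abort_if(
    length(unknown) > 0,
    paste0("unknown codon(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  )
  out[names(counts)] <- counts
  out
}
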