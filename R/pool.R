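# tRNA pool container and TSV input/output.

#' Construct a tRNA pool
#'
#' @param id Character vector of unique tRNA species identifiers.
#' @param anticodon Anticodons, 5'->3', over `{A,C,G,U,L}` (`L` = lysidine,
#'   wobble slot only).
#' @param amino_acid One-letter codes of the carried amino acids.
#' @param abundance Cellular abundance in molecules per cell; strictly
#'   positive.
#' @return A data.frame of class `trna_pool`.
#' @export
trna_pool <- function(id, anticodon, amino_acid, abundance) {
  if (anyDuplicated(id)) stop("tRNA ids must be unique")
  .check_anticodon(anticodon)
  bad <- setdiff(unique(amino_acid), .AA_CANONICAL)
  if (length(bad)) {
    stop("unknown amino acid code(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("abundances must be strictly positive")
  }
  pool <- data.frame(
    id = as.character(id),
    anticodon = as.character(anticodon),
    amino_acid = as.character(amino_acid),
    abundance = as.numeric(abundance),
    stringsAsFactors = FALSE
  )
  class(pool) <- c("trna_pool", "data.frame")
  pool
}

#' Read a tRNA pool from TSV
#'
#' Expects a header with columns `id`, `anticodon`, `amino_acid`,
#' `abundance`; sequences use the U (not T) alphabet.
#'
#' @param path Path to a tab-separated file.
#' @return A `trna_pool`.
#' @export
read_trna_pool <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "anticodon", "amino_acid", "abundance")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("tRNA pool file is missing column(s): ", paste(miss, collapse = ", "))
  }
  trna_pool(tab$id, tab$anticodon, tab$amino_acid, tab$abundance)
}

#' Write a tRNA pool to TSV
#'
#' @param pool A `trna_pool`.
#' @param path Output path.
#' @export
write_trna_pool <- function(pool, path) {
  utils::write.table(as.data.frame(pool), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.trna_pool <- function(x, ...) {
  cat("tRNA pool:", nrow(x), "species,",
      length(unique(x$amino_acid)), "amino acids,",
      "total abundance", format(sum(x$abundance), big.mark = ","), "\n")
  NextMethod()
}
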