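#' Read a multiple sequence alignment from a FASTA file
#'
#' Parses a standard multi-FASTA file (wrapped or unwrapped lines) into an
#' alignment object.  The identifier of each record is the first
#' whitespace-delimited token of its header line; residues are normalised to
#' lower case.
#'
#' @param path Path to a FASTA file containing at least two aligned
#'   (equal-length) sequences.
#' @return An object of class `hb_alignment`: a list with elements `ids`
#'   (character vector of unique sequence identifiers, in file order) and
#'   `residues` (character matrix, one row per sequence, one column per
#'   alignment position).
#' @seealso [encode_snp_matrix()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt", ">s2", "acgt", ">s3", "tcgt"), fa)
#' aln <- load_fasta(fa)
#' dim(aln$residues)
#' @export
load_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_hb("hb_bad_argument", "`path` must be a single file path")
  if (!file.exists(path))
    stop_hb("hb_missing_file", sprintf("FASTA file not found: '%s'", path))
  recs <- ape::read.FASTA(path)
  if (length(recs) < 2L)
    stop_hb("hb_too_few_records",
            "alignment must contain at least 2 sequences")
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_hb("hb_duplicate_ids",
            sprintf("duplicate sequence identifiers: %s",
                    paste(dup, collapse = ", ")))
  }
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop_hb("hb_unequal_lengths",
            sprintf("sequences are not aligned: lengths range %d-%d",
                    min(lens), max(lens)))
  res <- do.call(rbind, lapply(as.character(recs), tolower))
  dimnames(res) <- NULL
  new_alignment(ids, res)
}

#' Construct an alignment object from a character matrix
#'
#' Mostly useful for tests and simulations; [load_fasta()] is the usual entry
#' point.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param residues Character matrix of single characters,
#'   `length(ids)` rows.
#' @return An `hb_alignment` object.
#' @export
new_alignment <- function(ids, residues) {
  residues <- as.matrix(residues)
  if (nrow(residues) != length(ids))
    stop_hb("hb_dimension_mismatch", "one row of residues per id required")
  if (anyDuplicated(ids))
    stop_hb("hb_duplicate_ids", "sequence identifiers must be unique")
  if (nrow(residues) < 2L)
    stop_hb("hb_too_few_records", "at least 2 sequences required")
  if (ncol(residues) < 1L)
    stop_hb("hb_bad_argument", "alignment must have at least one column")
  structure(list(ids = as.character(ids), residues = residues),
            class = "hb_alignment")
}

HB_ALLELES <- c("a", "c", "g", "t")

# Encode one alignment column.  Returns NULL when the column is filtered out,
# otherwise list(codes, alleles).  Characters outside a/c/g/t (gaps, 'n',
# IUPAC ambiguity codes) are treated as missing.  Under the default filter a
# locus is kept only when at least two of its alleles are each carried by at
# least two sequences; alleles seen exactly once at a kept locus are recoded
# missing, and the allele inventory is recomputed after that recoding.
encode_column <- function(col, keep_singletons) {
  col[!(col %in% HB_ALLELES)] <- NA_character_
  tab <- table(col)                      # names sorted a < c < g < t
  if (keep_singletons) {
    alleles <- names(tab)
    if (length(alleles) < 2L) return(NULL)
  } else {
    alleles <- names(tab)[tab >= 2L]
    if (length(alleles) < 2L) return(NULL)
    col[!is.na(col) & !(col %in% alleles)] <- NA_character_
  }
  list(codes = match(col, alleles), alleles = alleles)
}

build_snp_matrix <- function(residues, ids, keep_singletons, source_columns,
                             allow_empty = FALSE) {
  cols <- lapply(seq_len(ncol(residues)), function(j)
    encode_column(residues[, j], keep_singletons))
  keep <- !vapply(cols, is.null, logical(1))
  if (!any(keep) && !allow_empty)
    stop_hb("hb_no_polymorphic_loci",
            paste("no polymorphic loci survive filtering; the alignment has",
                  "no site with two alleles each carried by >= 2 sequences",
                  "(rerun with keep_singletons = TRUE to relax the filter)"))
  cols <- cols[keep]
  codes <- if (length(cols))
    vapply(cols, `[[`, integer(nrow(residues)), "codes")
  else
    matrix(NA_integer_, nrow(residues), 0L)
  codes <- matrix(as.integer(codes), nrow = nrow(residues))
  locus_alleles <- lapply(cols, `[[`, "alleles")
  n_alleles <- vapply(locus_alleles, length, integer(1))
  structure(list(
    ids = as.character(ids),
    codes = codes,
    locus_alleles = locus_alleles,
    n_alleles = n_alleles,
    alpha = if (length(n_alleles)) 1 / n_alleles else numeric(0),
    source_columns = as.integer(source_columns[keep]),
    keep_singletons = keep_singletons
  ), class = "hb_snp")
}

#' Encode an alignment as an integer SNP matrix
#'
#' Extracts the polymorphic loci of an alignment and encodes each retained
#' locus as integer allele indices.  Only `a`, `c`, `g`, `t`
#' (case-insensitive) count as alleles; every other character (gap, `n`,
#' IUPAC ambiguity codes) is treated as missing and never enters any allele
#' count.  Columns with fewer than two distinct observed alleles are dropped.
#'
#' With the default `keep_singletons = FALSE`, singleton SNPs are additionally
#' filtered: a locus is retained only when at least two of its alleles are
#' each observed in at least two sequences, and alleles observed exactly once
#' at a retained locus are recoded as missing.  The per-locus allele number
#' (which sets the Dirichlet hyperparameter `1 / N_A(j)`) is computed after
#' this recoding.
#'
#' @param aln An `hb_alignment` from [load_fasta()] or [new_alignment()].
#' @param keep_singletons Keep loci whose minor allele occurs in only one
#'   sequence (default `FALSE`).
#' @return An object of class `hb_snp` with elements `ids`, `codes` (integer
#'   matrix, `NA` = missing, values index into `locus_alleles`),
#'   `locus_alleles` (list of ordered allele characters per retained locus),
#'   `n_alleles`, `alpha` (`1 / n_alleles`), `source_columns` (1-based column
#'   index of each retained locus in the original alignment) and
#'   `keep_singletons`.
#' @examples
#' aln <- new_alignment(c("s1", "s2", "s3", "s4"),
#'                      rbind(c("a", "a"), c("a", "a"),
#'                            c("t", "a"), c("t", "t")))
#' snp <- encode_snp_matrix(aln)
#' snp$codes
#' @export
encode_snp_matrix <- function(aln, keep_singletons = FALSE) {
  if (!inherits(aln, "hb_alignment"))
    stop_hb("hb_bad_argument", "`aln` must be an hb_alignment")
  res <- tolower(aln$residues)
  dim(res) <- dim(aln$residues)
  build_snp_matrix(res, aln$ids, keep_singletons,
                   source_columns = seq_len(ncol(res)))
}

#' Decode a SNP matrix back to allele characters
#'
#' Inverse of the encoding at all non-missing cells: cell `(i, j)` holds
#' `locus_alleles[[j]][codes[i, j]]`, and missing cells are `NA`.
#'
#' @param snp An `hb_snp` object.
#' @return Character matrix with `NA` at missing cells.
#' @export
decode_snp_matrix <- function(snp) {
  m <- matrix(NA_character_, nrow(snp$codes), ncol(snp$codes))
  for (j in seq_len(ncol(snp$codes)))
    m[, j] <- snp$locus_alleles[[j]][snp$codes[, j]]
  m
}

#' Restrict a SNP matrix to a subset of sequences
#'
#' Subsets the rows and re-applies the full locus filter within the subset:
#' loci that become invariant (or fail the singleton rule recorded in the
#' object) are dropped, singleton alleles are recoded missing, and the
#' per-locus allele inventories and hyperparameters are recomputed from the
#' surviving observations.  The result may have zero loci (for example when
#' the subset sequences are identical); callers treat that as "nothing left
#' to subdivide" rather than an error.
#'
#' @param snp An `hb_snp` object.
#' @param rows Integer (or logical) index of the sequences to keep.
#' @return An `hb_snp` object over the selected sequences, possibly with zero
#'   loci.
#' @export
subset_snp_matrix <- function(snp, rows) {
  rows <- seq_len(nrow(snp$codes))[rows]
  res <- decode_snp_matrix(snp)[rows, , drop = FALSE]
  build_snp_matrix(res, snp$ids[rows], snp$keep_singletons,
                   source_columns = snp$source_columns, allow_empty = TRUE)
}

#' Pairwise SNP distances
#'
#' Hamming distance between sequences counted over the loci where both
#' members of a pair are observed (non-missing).  A pair sharing no observed
#' locus is assigned the maximal distance (the number of loci), so fully
#' unobserved pairs are "far" rather than undefined.
#'
#' @param snp An `hb_snp` object.
#' @return A symmetric numeric matrix of mismatch counts.
#' @export
snp_hamming <- function(snp) {
  codes <- snp$codes
  n <- nrow(codes)
  M <- ncol(codes)
  obs <- !is.na(codes)
  storage.mode(obs) <- "double"
  shared <- obs %*% t(obs)
  matches <- matrix(0, n, n)
  for (a in seq_len(max(c(1L, snp$n_alleles)))) {
    ia <- !is.na(codes) & codes == a
    storage.mode(ia) <- "double"
    matches <- matches + ia %*% t(ia)
  }
  d <- shared - matches
  d[shared == 0] <- M
  diag(d) <- 0
  dimnames(d) <- list(snp$ids, snp$ids)
  d
}

#' @export
print.hb_snp <- function(x, ...) {
  cat(sprintf("SNP matrix: %d sequences x %d polymorphic loci\n",
              nrow(x$codes), ncol(x$codes)))
  cat(sprintf("  singleton filter: %s\n",
              if (x$keep_singletons) "off" else "on"))
  invisible(x)
}

#' @export
print.hb_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              nrow(x$residues), ncol(x$residues)))
  invisible(x)
}
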