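#' Read sequences from a FASTA file
#'
#' Thin wrapper around [ape::read.FASTA()] returning plain uppercase character
#' strings, the representation used throughout the package.
#'
#' @param path Path to a FASTA file (aligned or not).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  chars <- as.character(dna)
  out <- vapply(chars, function(x) toupper(paste0(x, collapse = "")),
                character(1L))
  names(out) <- names(dna)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (gaps allowed).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con, sep = "\n")
  }
  invisible(path)
}

## character strings -> single-character matrix (rows = sequences)
seqs_to_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(range(lens), collapse = "-"),
         "); an alignment is required")
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

matrix_to_seqs <- function(m) {
  out <- apply(m, 1L, paste0, collapse = "")
  names(out) <- rownames(m)
  out
}

#' Drop masked columns from aligned sequences
#'
#' Utility to restrict an alignment to its comparable core, e.g. removing
#' the unalignable R2 array region before haplotype comparison.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param mask 1-based columns to remove.
#' @return Named character vector of the reduced sequences.
#' @export
mask_columns <- function(seqs, mask) {
  if (!length(mask)) return(seqs)
  m <- seqs_to_matrix(seqs)[, -mask, drop = FALSE]
  matrix_to_seqs(m)
}

## Parse clone identifiers of the form <taxon>|<individual>|<sizeclass>|clone<k>
parse_clone_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed clone id(s): ", paste(ids[bad][seq_len(min(3, sum(bad)))],
                                          collapse = ", "))
  data.frame(id = ids,
             taxon = vapply(parts, `[`, "", 1L),
             individual = vapply(parts, `[`, "", 2L),
             size_class = vapply(parts, `[`, "", 3L),
             clone = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE)
}
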