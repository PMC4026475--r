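#' Built-in R2 repeat motif inventory
#'
#' The five 11-bp repeat motifs (A--E) observed in the R2 tandem array of the
#' CSB domain of the *Rhinolophus sinicus* mitochondrial control region.
#' Members of the inventory differ from each other by one or two base pairs.
#'
#' @return Named character vector of unit sequences; names are the one-letter
#'   motif labels.
#' @examples
#' default_motif_inventory()
#' @export
default_motif_inventory <- function() {
  c(A = "AACGTACACGT",
    B = "GACGTACACGT",
    C = "AACGTATACGC",
    D = "AACGCATACGC",
    E = "AACACATACGC")
}

## Shared validation: equal unit lengths, distinct units, single-letter labels.
validate_inventory <- function(inventory) {
  if (is.null(names(inventory)) || any(!nzchar(names(inventory))))
    stop("motif inventory must be a named character vector (label -> unit)")
  lens <- nchar(inventory)
  if (length(unique(lens)) != 1L)
    stop("all units in a motif inventory must share one length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  if (anyDuplicated(inventory))
    stop("motif inventory units must be pairwise distinct")
  toupper(inventory)
}

#' Read a motif inventory from a TSV file
#'
#' The file must have two columns, `label` and `unit` (header optional as long
#' as the first column holds labels and the second the unit sequences).
#'
#' @param path Path to a tab-separated file.
#' @return Named character vector usable wherever an inventory is accepted.
#' @export
read_motif_inventory <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("inventory TSV needs columns: label, unit")
  inv <- toupper(tab[[2L]])
  names(inv) <- as.character(tab[[1L]])
  validate_inventory(inv)
}

#' Parse a run-length structure string
#'
#' Structure strings use the `(X)n` notation, e.g. `"(A)4(B)1(A)5(B)2(A)6(B)2"`,
#' where `X` is a motif label and `n` a run length. Bare base strings between
#' runs (e.g. the 5-bp `AACGC` segment of some arrays) are literal partial
#' units. Whitespace is ignored.
#'
#' @param structure Structure string.
#' @return Data frame with columns `label` (motif label or literal string),
#'   `count` (run length; 1 for literals) and `literal` (logical).
#' @export
parse_structure <- function(structure) {
  s <- gsub("[[:space:]_]", "", structure)
  out <- list()
  while (nzchar(s)) {
    m <- regmatches(s, regexec("^\\(([A-Za-z])\\)([0-9]+)", s))[[1L]]
    if (length(m)) {
      out[[length(out) + 1L]] <-
        data.frame(label = m[2L], count = as.integer(m[3L]), literal = FALSE,
                   stringsAsFactors = FALSE)
      s <- substring(s, nchar(m[1L]) + 1L)
      next
    }
    m <- regmatches(s, regexec("^([ACGTNacgtn]+)", s))[[1L]]
    if (length(m)) {
      out[[length(out) + 1L]] <-
        data.frame(label = toupper(m[2L]), count = 1L, literal = TRUE,
                   stringsAsFactors = FALSE)
      s <- substring(s, nchar(m[1L]) + 1L)
      next
    }
    stop("cannot parse structure string near: ", s)
  }
  if (!length(out))
    return(data.frame(label = character(), count = integer(),
                      literal = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Format runs back into a structure string
#'
#' Inverse of [parse_structure()].
#'
#' @param runs Data frame with columns `label`, `count`, `literal`.
#' @return A structure string in `(X)n` notation, literals printed bare.
#' @export
format_structure <- function(runs) {
  if (!nrow(runs)) return("")
  paste0(ifelse(runs$literal, runs$label,
                paste0("(", runs$label, ")", runs$count)),
         collapse = "")
}

#' Rebuild a sequence from a run-length repeat structure
#'
#' Expands a structure string (or parsed run table) over a motif inventory,
#' concatenating `count` copies of each motif unit and inserting literal
#' partial-unit segments verbatim.
#'
#' @param structure Structure string in `(X)n` notation, or a run data frame
#'   as returned by [parse_structure()].
#' @param inventory Named character vector of motif units; defaults to the
#'   built-in A--E inventory.
#' @return The reconstructed array sequence. Its length equals
#'   `unit length * sum(full-unit counts) + sum(literal lengths)`.
#' @examples
#' nchar(reconstruct_from_structure("(C)7"))   # 77
#' @export
reconstruct_from_structure <- function(structure,
                                       inventory = default_motif_inventory()) {
  inventory <- validate_inventory(inventory)
  runs <- if (is.data.frame(structure)) structure else parse_structure(structure)
  if (!nrow(runs)) return("")
  unknown <- setdiff(runs$label[!runs$literal], names(inventory))
  if (length(unknown))
    stop("unknown motif label(s): ", paste(unknown, collapse = ", "),
         "; valid labels: ", paste(names(inventory), collapse = ", "))
  pieces <- ifelse(runs$literal, runs$label,
                   strrep(inventory[runs$label], runs$count))
  paste0(pieces, collapse = "")
}

#' Published R2 repeat structures
#'
#' Loads the bundled table of R2 size classes reported for 18 *R. sinicus*
#' individuals: per size class the taxon, individual, printed array length,
#' printed total unit count `N` and the run-length structure string. A
#' `consistent` column is computed at load time and flags rows whose printed
#' columns agree with their own structure string (i.e. the run counts sum to
#' `N` and `11 * N +` literal lengths equals `length`); a few published rows
#' fail this arithmetic self-check and are flagged `FALSE`.
#'
#' @return Data frame with columns `taxon`, `individual`, `size_class`,
#'   `length`, `N`, `structure`, `consistent`.
#' @export
published_structures <- function() {
  path <- system.file("extdata", "r2_size_classes.tsv", package = "numtscan",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  unit_len <- nchar(default_motif_inventory()[[1L]])
  chk <- vapply(seq_len(nrow(tab)), function(i) {
    runs <- parse_structure(tab$structure[i])
    n_units <- sum(runs$count[!runs$literal])
    lit_len <- sum(nchar(runs$label[runs$literal]))
    n_units == tab$N[i] && unit_len * n_units + lit_len == tab$length[i]
  }, logical(1L))
  tab$consistent <- chk
  tab
}
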