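#' Polymerase error model for cloned PCR products
#'
#' Per-clone polymerase/cloning artefacts are modelled as Poisson with mean
#' `lambda = rate * length * cycles`: errors are rare, independent across
#' sites and cycles, and counted per bp. `lambda` is always recomputed from
#' its three factors.
#'
#' @param rate Error rate per bp per cycle (Taq is commonly taken as
#'   7.2e-5).
#' @param length Amplicon length in bp.
#' @param cycles Number of PCR cycles.
#' @return Object of class `error_model` with fields `rate`, `length`,
#'   `cycles` and `lambda`.
#' @examples
#' error_model(7.2e-5, 724, 34)$lambda  # about 1.77 errors per clone
#' @export
error_model <- function(rate = 7.2e-5, length = 724, cycles = 34) {
  structure(list(rate = rate, length = length, cycles = cycles,
                 lambda = expected_errors(rate, length, cycles)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "error_model: %.3g /bp/cycle x %d bp x %d cycles -> lambda = %.3f errors/clone\n",
    x$rate, x$length, x$cycles, x$lambda))
  invisible(x)
}

#' Expected polymerase errors per cloned sequence
#'
#' @param rate Error rate per bp per cycle.
#' @param length Sequence length in bp.
#' @param cycles Number of PCR cycles.
#' @return `rate * length * cycles`.
#' @export
expected_errors <- function(rate, length, cycles) {
  vals <- c(rate = rate, length = length, cycles = cycles)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rate, length and cycles must be non-negative; got ",
         paste(names(vals)[vals < 0 | !is.finite(vals)], collapse = ", "))
  rate * length * cycles
}

#' Poisson upper-tail fraction of clones with more than k errors
#'
#' `P(X > k)` for `X ~ Poisson(lambda)`: the expected fraction of clones
#' carrying more than `k` polymerase errors.
#'
#' @param lambda Expected errors per clone (see [expected_errors()]).
#' @param k Error-count threshold (integer, >= 0).
#' @return Probability in `[0, 1]`.
#' @examples
#' tail_fraction(error_model()$lambda, 2)  # about 0.26
#' @export
tail_fraction <- function(lambda, k) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (any(k < 0)) stop("k must be non-negative")
  stats::ppois(k, lambda, lower.tail = FALSE)
}

#' Summarise a re-cloning experiment against its consensus
#'
#' Re-cloning a single cloned fragment isolates polymerase/cloning error from
#' biological variation: every difference from the clone set's consensus is
#' an artefact. The consensus is the per-site majority base (ties broken
#' towards the first-seen base and flagged).
#'
#' @param clones Named character vector of equal-length clone sequences.
#' @return Object of class `clone_error_summary`: `n_clones`,
#'   `total_mutations`, `mean_per_clone`, `n_identical` (clones identical to
#'   the consensus), `fraction_identical`, `per_clone` difference counts, the
#'   `consensus` sequence and the flagged `tie_sites`.
#' @export
summarize_recloning <- function(clones) {
  if (length(clones) < 2L) stop("need at least two clones")
  m <- seqs_to_matrix(clones)
  cons <- character(ncol(m))
  ties <- integer(0)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      ties <- c(ties, j)
      top <- m[match(TRUE, m[, j] %in% top), j]  # first-seen among the tied
    }
    cons[j] <- top[1L]
  }
  per_clone <- as.integer(rowSums(m != matrix(cons, nrow(m), ncol(m),
                                              byrow = TRUE)))
  names(per_clone) <- rownames(m)
  structure(list(n_clones = nrow(m),
                 total_mutations = as.integer(sum(per_clone)),
                 mean_per_clone = sum(per_clone) / nrow(m),
                 n_identical = sum(per_clone == 0L),
                 fraction_identical = mean(per_clone == 0L),
                 per_clone = per_clone,
                 consensus = paste0(cons, collapse = ""),
                 tie_sites = ties),
            class = "clone_error_summary")
}

#' @export
print.clone_error_summary <- function(x, ...) {
  cat(sprintf(
    "clone_error_summary: %d mutations across %d clones (%.1f/clone), %d identical (%.0f%%)\n",
    x$total_mutations, x$n_clones, x$mean_per_clone, x$n_identical,
    100 * x$fraction_identical))
  if (length(x$tie_sites))
    cat("  consensus ties at", length(x$tie_sites), "site(s)\n")
  invisible(x)
}

#' Inject polymerase errors into a clone sequence
#'
#' Draws the error count from `Poisson(rate * nchar(seq) * cycles)` and
#' applies that many substitutions at uniformly chosen sites (errors are
#' substitution-only; each erroneous site receives a uniformly chosen
#' different base). Repeated draws can hit the same site, matching the
#' per-bp-count interpretation of the error rate.
#'
#' @param seq Clone sequence (character string).
#' @param rate Error rate per bp per cycle.
#' @param cycles Number of PCR cycles.
#' @return List with `seq` (mutated sequence) and `positions` (1-based error
#'   sites, possibly repeated).
#' @export
inject_taq_errors <- function(seq, rate = 7.2e-5, cycles = 34) {
  s <- strsplit(seq, "")[[1L]]
  lambda <- expected_errors(rate, length(s), cycles)
  n_err <- stats::rpois(1L, lambda)
  pos <- integer(0)
  if (n_err > 0L) {
    pos <- sample.int(length(s), n_err, replace = TRUE)
    for (p in pos) s[p] <- sample(setdiff(BASES, s[p]), 1L)
  }
  list(seq = paste0(s, collapse = ""), positions = pos)
}
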