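#' Infer the repeat unit length of a tandem array
#'
#' Scans candidate periods and counts, for each period `p`, the number of
#' positions whose `k`-mer recurs exactly `p` bases downstream. The period
#' with the most recurrences wins; a period is only reported when supported
#' by at least `min_recurrences` recurrences, so sequences without tandem
#' structure (e.g. numts) return `NA`.
#'
#' @param seq A sequence (single character string).
#' @param k K-mer size used to score recurrences.
#' @param min_period,max_period Inclusive period search range.
#' @param min_recurrences Minimum recurrence count supporting a period.
#' @return Integer period, or `NA_integer_` when no period is supported.
#' @examples
#' infer_period(strrep("AACGTATACGC", 7))           # 11
#' infer_period("ACGACGACGACGACGACG", k = 3, min_period = 2, max_period = 9)
#' @export
infer_period <- function(seq, k = 8L, min_period = 5L, max_period = 50L,
                         min_recurrences = 3L) {
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  best_p <- NA_integer_
  best_count <- -1L
  for (p in seq.int(min_period, max_period)) {
    if (n < p + k) next
    eq <- s[seq_len(n - p)] == s[seq.int(p + 1L, n)]
    ## positions i where all k consecutive comparisons hold
    cs <- cumsum(c(0L, eq))
    count <- sum(cs[seq.int(k + 1L, length(cs))] -
                   cs[seq_len(length(cs) - k)] == k)
    if (count > best_count) {
      best_count <- count
      best_p <- p
    }
  }
  if (best_count >= min_recurrences) best_p else NA_integer_
}

empty_decomposition <- function(seq) {
  structure(list(array_start = 0L, array_end = 0L, array_length = 0L,
                 N = 0L,
                 runs = data.frame(label = character(), count = integer(),
                                   literal = logical(),
                                   stringsAsFactors = FALSE),
                 units = data.frame(start = integer(), label = character(),
                                    dist = integer(), observed = character(),
                                    literal = logical(),
                                    stringsAsFactors = FALSE),
                 structure = "",
                 sequence = seq),
            class = "repeat_decomposition")
}

## Distance of every u-length block to every inventory unit. Hamming first
## (vectorised); Levenshtein refinement via adist() only for blocks whose
## Hamming distance exceeds the tolerance but might still be within it by
## edit operations.
block_distances <- function(s, inventory, max_dist, refine_range = NULL) {
  u <- nchar(inventory[[1L]])
  n <- length(s)
  starts <- seq_len(n - u + 1L)
  idx <- outer(seq_len(u) - 1L, starts, "+")
  B <- matrix(s[idx], nrow = u)
  D <- vapply(inventory, function(m) {
    colSums(B != strsplit(m, "")[[1L]])
  }, numeric(length(starts)))
  D <- matrix(D, nrow = length(starts),
              dimnames = list(NULL, names(inventory)))
  if (!is.null(refine_range)) {
    cand <- which(apply(D, 1L, min) > max_dist &
                    starts >= refine_range[1L] & starts <= refine_range[2L])
    if (length(cand)) {
      blocks <- substring(paste0(s, collapse = ""), cand, cand + u - 1L)
      E <- utils::adist(blocks, inventory)
      D[cand, ] <- pmin(D[cand, , drop = FALSE], E)
    }
  }
  D
}

#' Decompose a sequence into its R2 tandem-repeat structure
#'
#' Finds the best window of the input parseable as a tandem array: an
#' alternation of full repeat units (each within edit distance
#' `max_unit_dist` of some inventory motif) and short interior literal
#' segments (partial units of fewer than one unit length, e.g. the 5-bp
#' `AACGC` remnant seen in some published arrays). The parse maximises,
#' lexicographically, the number of full units, then the number of units
#' matching a motif class exactly, then the fewest literal bases; among
#' equal-scoring parses the leftmost is kept. Units not exactly matching any
#' class are assigned to the nearest class (ties broken towards the earlier
#' label) and flagged via their `dist` column. Sequences with no tileable
#' window -- numts in particular -- yield an empty decomposition with
#' `N = 0`.
#'
#' When `inventory` is `NULL` the unit period is inferred with
#' [infer_period()] and a provisional inventory is built from the unit
#' sequences that recur tandemly in the input itself, ranked by frequency.
#'
#' @param seq A sequence (single character string, no gaps).
#' @param inventory Named character vector of motif units of equal length, or
#'   `NULL` to auto-build one from the sequence.
#' @param max_unit_dist Maximum edit distance between an accepted unit and
#'   its motif class.
#' @param min_units Minimum number of full units for a window to count as an
#'   array.
#' @return An object of class `repeat_decomposition`: 0-based half-open array
#'   coordinates, the ordered `runs` table, the per-unit `units` table, the
#'   total full-unit count `N`, `array_length` in bp and the structure string.
#'   Concatenating the observed unit and literal segments reproduces
#'   `substr(seq, array_start + 1, array_end)` exactly, and
#'   `array_length == unit_length * N + sum(literal lengths)`.
#' @examples
#' d <- decompose_repeats(strrep("AACGTATACGC", 7))
#' d$N            # 7
#' d$structure    # "(C)7"
#' @export
decompose_repeats <- function(seq, inventory = default_motif_inventory(),
                              max_unit_dist = 2L, min_units = 2L) {
  seq <- toupper(seq)
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)

  if (is.null(inventory)) {
    inventory <- auto_inventory(seq)
    if (is.null(inventory)) return(empty_decomposition(seq))
  }
  inventory <- validate_inventory(inventory)
  u <- nchar(inventory[[1L]])
  if (n < u * max(2L, min_units)) return(empty_decomposition(seq))

  D <- block_distances(s, inventory, max_unit_dist)
  dmin <- apply(D, 1L, min)
  seeds <- which(dmin <= max_unit_dist)
  if (!length(seeds)) return(empty_decomposition(seq))

  rs <- max(1L, min(seeds) - 2L * u)
  re <- min(n, max(seeds) + u - 1L + 2L * u)
  D <- block_distances(s, inventory, max_unit_dist, refine_range = c(rs, re))
  dmin <- apply(D, 1L, min)
  kbest <- max.col(-D, ties.method = "first")

  ## DP over parse boundaries: state "unit" (parse ends in a full unit) and
  ## "lit" (ends in a literal). Score packs (units, exact units, -literal bp)
  ## lexicographically; ties resolved towards the leftmost array start.
  UNIT <- 1e6; EXACT <- 1e3
  m <- re + 1L
  f_unit <- rep(-Inf, m); f_lit <- rep(-Inf, m)
  st_unit <- rep(NA_integer_, m); st_lit <- rep(NA_integer_, m)  # array starts
  pv_unit <- rep(NA_integer_, m); pv_lit <- rep(NA_integer_, m)  # prev boundary
  ty_unit <- rep(NA_integer_, m); ty_lit <- rep(NA_integer_, m)  # prev state 0 new,1 unit,2 lit

  for (b in seq.int(rs + u, re + 1L)) {
    i <- b - u  # unit start
    if (i >= rs && i <= length(dmin) && dmin[i] <= max_unit_dist) {
      gain <- UNIT + EXACT * (dmin[i] == 0)
      ## candidate predecessors: fresh start, previous unit, previous literal
      cands <- c(0, f_unit[i], f_lit[i])
      starts <- c(i, st_unit[i], st_lit[i])
      sc <- cands + gain
      best <- which(sc == max(sc))
      if (length(best) > 1L) best <- best[which.min(starts[best])]
      if (sc[best] > f_unit[b] ||
          (sc[best] == f_unit[b] && !is.na(st_unit[b]) &&
             starts[best] < st_unit[b])) {
        f_unit[b] <- sc[best]
        st_unit[b] <- starts[best]
        pv_unit[b] <- i
        ty_unit[b] <- best - 1L
      }
    }
    for (l in seq_len(u - 1L)) {
      j <- b - l  # literal start
      if (j <= rs) break
      if (is.finite(f_unit[j])) {
        sc <- f_unit[j] - l
        if (sc > f_lit[b] ||
            (sc == f_lit[b] && st_unit[j] < st_lit[b])) {
          f_lit[b] <- sc
          st_lit[b] <- st_unit[j]
          pv_lit[b] <- j
          ty_lit[b] <- 1L
        }
      }
    }
  }

  if (!any(is.finite(f_unit))) return(empty_decomposition(seq))
  fmax <- max(f_unit, na.rm = TRUE)
  ends <- which(f_unit == fmax)
  end_b <- ends[which.min(st_unit[ends])]
  if (fmax %/% UNIT < min_units) return(empty_decomposition(seq))

  ## backtrack
  segs <- list()
  b <- end_b; state <- 1L
  repeat {
    if (state == 1L) {
      i <- pv_unit[b]
      segs[[length(segs) + 1L]] <-
        list(start = i, label = names(inventory)[kbest[i]],
             dist = dmin[i],
             observed = substr(seq, i, i + u - 1L), literal = FALSE)
      nxt <- ty_unit[b]
    } else {
      i <- pv_lit[b]
      segs[[length(segs) + 1L]] <-
        list(start = i, label = substr(seq, i, b - 1L), dist = NA_integer_,
             observed = substr(seq, i, b - 1L), literal = TRUE)
      nxt <- ty_lit[b]
    }
    if (nxt == 0L) break
    b <- i; state <- nxt
  }
  segs <- rev(segs)
  units <- data.frame(
    start = vapply(segs, function(x) x$start, 1L) - 1L,  # 0-based
    label = vapply(segs, function(x) x$label, ""),
    dist = vapply(segs, function(x) as.integer(x$dist), 1L),
    observed = vapply(segs, function(x) x$observed, ""),
    literal = vapply(segs, function(x) x$literal, TRUE),
    stringsAsFactors = FALSE)

  ## merge consecutive same-label full units into runs
  grp <- cumsum(c(TRUE, units$label[-1L] != units$label[-nrow(units)] |
                    units$literal[-1L] | units$literal[-nrow(units)]))
  runs <- do.call(rbind, lapply(split(seq_len(nrow(units)), grp), function(ix) {
    data.frame(label = units$label[ix[1L]], count = length(ix),
               literal = units$literal[ix[1L]], stringsAsFactors = FALSE)
  }))
  rownames(runs) <- NULL

  a_start <- units$start[1L]
  a_end <- units$start[nrow(units)] + nchar(units$observed[nrow(units)])
  structure(list(array_start = a_start, array_end = a_end,
                 array_length = a_end - a_start,
                 N = sum(!units$literal),
                 runs = runs, units = units,
                 structure = format_structure(runs),
                 sequence = seq),
            class = "repeat_decomposition")
}

## Provisional inventory from the sequence itself: unit period by
## periodicity, units ranked by how often they recur tandemly.
auto_inventory <- function(seq, ...) {
  p <- infer_period(seq, ...)
  if (is.na(p)) return(NULL)
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  if (n < 2L * p) return(NULL)
  eq <- s[seq_len(n - p)] == s[seq.int(p + 1L, n)]
  cs <- cumsum(c(0L, eq))
  hits <- which(cs[seq.int(p + 1L, length(cs))] -
                  cs[seq_len(length(cs) - p)] == p)
  if (!length(hits)) return(NULL)
  units <- substring(seq, hits, hits + p - 1L)
  tab <- sort(table(units), decreasing = TRUE)
  inv <- names(tab)
  names(inv) <- LETTERS[seq_along(inv)]
  inv
}

#' @export
print.repeat_decomposition <- function(x, ...) {
  if (x$N == 0L) {
    cat("repeat_decomposition: no tandem array (N = 0)\n")
  } else {
    cat(sprintf("repeat_decomposition: [%d, %d) length %d bp, N = %d\n",
                x$array_start, x$array_end, x$array_length, x$N))
    cat("  structure:", x$structure, "\n")
    n_flag <- sum(!x$units$literal & x$units$dist > 0L)
    if (n_flag) cat("  ", n_flag, "unit(s) assigned by nearest class\n")
  }
  invisible(x)
}

#' Discover the motif inventory used by a set of decompositions
#'
#' Collects the observed full-unit sequences across decompositions, ranks the
#' distinct unit strings by total count, and labels them `A`, `B`, ... in
#' rank order. When a canonical inventory is supplied, units present in it
#' keep their canonical labels and novel units receive the next free letters.
#'
#' @param decompositions List of `repeat_decomposition` objects.
#' @param canonical Optional named inventory whose labels should be preserved.
#' @param min_count Drop unit sequences observed fewer than this many times.
#' @return Named character vector: discovered inventory, most frequent first
#'   (canonical labels, where given, keep their canonical order).
#' @export
discover_motifs <- function(decompositions, canonical = NULL, min_count = 1L) {
  obs <- unlist(lapply(decompositions, function(d) {
    d$units$observed[!d$units$literal]
  }), use.names = FALSE)
  if (!length(obs)) stop("no repeat arrays found")
  tab <- table(obs)
  tab <- tab[tab >= min_count]
  if (!length(tab)) stop("no repeat arrays found")
  ord <- order(-as.integer(tab), match(names(tab), unique(obs)))
  units <- names(tab)[ord]
  if (is.null(canonical)) {
    names(units) <- make_labels(length(units))
    return(units)
  }
  canonical <- validate_inventory(canonical)
  labels <- character(length(units))
  known <- match(units, canonical)
  labels[!is.na(known)] <- names(canonical)[known[!is.na(known)]]
  free <- setdiff(make_labels(length(units) + length(canonical)),
                  names(canonical))
  labels[is.na(known)] <- free[seq_len(sum(is.na(known)))]
  names(units) <- labels
  units
}

make_labels <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS))[seq_len(k)]
}

#' Summarise repeat structures across sequences
#'
#' Builds a per-sequence table (unit count `N`, array length, structure
#' string) and, when group labels are provided, a per-group summary of motif
#' richness: the number of distinct motif classes appearing in the arrays of
#' each group.
#'
#' @param decompositions Named list of `repeat_decomposition` objects.
#' @param groups Optional character vector (recycled-to-names) assigning each
#'   decomposition to a group such as its taxon.
#' @return List with `sequences` (per-sequence table) and, when `groups` is
#'   given, `groups` (per-group motif richness and `N` range).
#' @export
structure_summary <- function(decompositions, groups = NULL) {
  ids <- names(decompositions)
  if (is.null(ids)) ids <- as.character(seq_along(decompositions))
  seq_tab <- data.frame(
    id = ids,
    N = vapply(decompositions, function(d) d$N, 1L),
    array_length = vapply(decompositions, function(d) d$array_length, 1L),
    structure = vapply(decompositions, function(d) d$structure, ""),
    stringsAsFactors = FALSE)
  rownames(seq_tab) <- NULL
  out <- list(sequences = seq_tab)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    motifs_of <- lapply(decompositions, function(d) {
      unique(d$units$label[!d$units$literal])
    })
    gsplit <- split(seq_along(decompositions), groups)
    out$groups <- data.frame(
      group = names(gsplit),
      n_sequences = lengths(gsplit),
      motif_richness = vapply(gsplit, function(ix) {
        length(unique(unlist(motifs_of[ix])))
      }, 1L),
      min_N = vapply(gsplit, function(ix) {
        v <- seq_tab$N[ix]; if (all(v == 0L)) 0L else min(v[v > 0L])
      }, 1L),
      max_N = vapply(gsplit, function(ix) max(seq_tab$N[ix]), 1L),
      stringsAsFactors = FALSE)
    rownames(out$groups) <- NULL
  }
  out
}
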