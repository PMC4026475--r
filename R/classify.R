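#' Partition sequences into clades from a distance matrix
#'
#' Average-linkage hierarchical clustering on the distance matrix, cut at the
#' number of clades `k` that maximises the relative gap between successive
#' merge heights (the height of the first broken merge divided by the tallest
#' kept merge). The cut is only accepted when the resulting partition is
#' well separated -- mean between-clade distance at least `min_ratio` times
#' the mean within-clade distance -- otherwise the trivial one-clade
#' partition is returned. With clone sets containing ancient numts the deep
#' numt/mtDNA splits dwarf within-clade variation and the partition recovers
#' the origin clades.
#'
#' @param dm `k2p_matrix` or plain symmetric distance matrix.
#' @param min_ratio Minimum between/within mean-distance ratio for a
#'   non-trivial cut (default 5).
#' @param max_k Largest number of clades considered.
#' @return Object of class `clade_partition`: named `labels` vector
#'   (`"C1"`, `"C2"`, ...), `k`, the merge `heights`, the achieved
#'   `gap_ratio` and `between_within_ratio`, and per-clade silhouette-style
#'   `separation` scores.
#' @export
partition_clades <- function(dm, min_ratio = 5, max_k = 10L) {
  d <- as_dist_matrix(dm)
  n <- nrow(d)
  if (n < 2L) stop("need at least two sequences to partition")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- as.character(seq_len(n))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  h <- hc$height
  ks <- seq.int(2L, min(max_k, n - 1L))
  ratio <- vapply(ks, function(k) {
    top <- h[n - k + 1L]
    kept <- h[n - k]
    if (kept <= 0) {
      if (top > 0) Inf else NA_real_
    } else top / kept
  }, numeric(1L))
  trivial <- structure(
    list(labels = stats::setNames(rep("C1", n), rownames(d)),
         k = 1L, heights = h, gap_ratio = NA_real_,
         between_within_ratio = NA_real_,
         separation = c(C1 = NA_real_)),
    class = "clade_partition")
  if (!length(ks) || all(is.na(ratio))) return(trivial)
  best <- ks[which.max(ratio)]
  cl <- stats::cutree(hc, k = best)
  labels <- stats::setNames(paste0("C", cl), rownames(d))
  same <- outer(cl, cl, "==")
  within <- d[same & upper.tri(d)]
  between <- d[!same & upper.tri(d)]
  bw <- if (length(within) && mean(within) > 0) mean(between) / mean(within)
        else Inf
  if (!is.finite(bw) && length(within) && mean(within) == 0) bw <- Inf
  if (bw < min_ratio) return(trivial)
  structure(list(labels = labels, k = best, heights = h,
                 gap_ratio = max(ratio, na.rm = TRUE),
                 between_within_ratio = bw,
                 separation = clade_silhouette(d, labels)),
            class = "clade_partition")
}

## mean silhouette width per clade (0 for singleton-only comparisons)
clade_silhouette <- function(d, labels) {
  clades <- unique(labels)
  if (length(clades) < 2L) return(stats::setNames(NA_real_, clades))
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(d[i, own & seq_along(labels) != i]) else 0
    b <- min(vapply(setdiff(clades, labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1L)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1L))
  vapply(split(s, labels), mean, numeric(1L))[clades]
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("clade_partition: %d clade(s) over %d sequences\n",
              x$k, length(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Export the clustering dendrogram used for clade partitioning
#'
#' @param dm `k2p_matrix` or plain distance matrix.
#' @param file Optional path; when given the tree is written in newick
#'   format.
#' @return An [ape::as.phylo()] tree of the average-linkage dendrogram.
#' @export
clade_dendrogram <- function(dm, file = NULL) {
  d <- as_dist_matrix(dm)
  tree <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  if (!is.null(file)) ape::write.tree(tree, file)
  tree
}

#' Mutational steps between two aligned haplotypes
#'
#' Counts substitution differences per site plus one step per maximal
#' contiguous gap run (an indel of any length is a single event). Columns
#' gapped in both sequences are removed before runs are delimited.
#'
#' @param x,y Aligned sequences of equal length (gaps as `-`).
#' @return Integer step count.
#' @examples
#' mutational_steps("AC--GT", "ACTTGT")  # 1
#' @export
mutational_steps <- function(x, y) {
  a <- strsplit(toupper(x), "")[[1L]]
  b <- strsplit(toupper(y), "")[[1L]]
  if (length(a) != length(b))
    stop("aligned haplotypes must have equal length (", length(a), " vs ",
         length(b), ")")
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  ga <- a == "-"; gb <- b == "-"
  subs <- sum(a != b & !ga & !gb)
  one_gap <- xor(ga, gb)
  gap_runs <- if (any(one_gap)) sum(rle(one_gap)$values) else 0L
  as.integer(subs + gap_runs)
}

#' Pairwise mutational-step matrix
#'
#' @param seqs Named character vector of equal-length aligned sequences, or a
#'   character matrix (one row per sequence).
#' @param mask Optional 1-based columns to exclude before counting.
#' @return Symmetric integer matrix of step counts.
#' @export
mutational_steps_matrix <- function(seqs, mask = NULL) {
  m <- if (is.matrix(seqs)) seqs else seqs_to_matrix(seqs)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (!is.null(mask)) m <- m[, -mask, drop = FALSE]
  if (!any(m == "-")) {
    ## gap-free fast path: substitution counts via indicator algebra
    chars <- setdiff(unique(as.vector(m)), "-")
    I <- lapply(chars, function(b) (m == b) * 1)
    V <- Reduce(`+`, I)
    matches <- Reduce(`+`, lapply(I, function(x) x %*% t(x)))
    steps <- V %*% t(V) - matches
    dimnames(steps) <- list(rownames(m), rownames(m))
    return(round(steps))
  }
  n <- nrow(m)
  steps <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  ss <- matrix_to_seqs(m)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    steps[i, j] <- steps[j, i] <- mutational_steps(ss[i], ss[j])
  }
  steps
}

#' Minimum spanning haplotype network
#'
#' Builds the minimum spanning network over distinct haplotypes: every edge
#' that belongs to at least one minimum spanning tree of the complete
#' mutational-step graph is kept, so co-minimal alternative connections
#' (ties) are all represented. Node sizes carry clone multiplicities and
#' optional group (taxon) attributes for colouring.
#'
#' @param haplotypes Named character vector of distinct aligned haplotypes,
#'   or `NULL` when `steps` is supplied directly.
#' @param counts Optional named multiplicities (defaults to 1 per haplotype).
#' @param groups Optional named group/taxon attribute per haplotype.
#' @param steps Optional precomputed step matrix (see
#'   [mutational_steps_matrix()]).
#' @return Object of class `haplotype_network`: `nodes` data frame (id,
#'   count, group) and `edges` data frame (from, to, steps).
#' @export
build_network <- function(haplotypes = NULL, counts = NULL, groups = NULL,
                          steps = NULL) {
  if (is.null(steps)) {
    if (is.null(haplotypes) || !length(haplotypes))
      stop("need at least one haplotype")
    steps <- mutational_steps_matrix(haplotypes)
  }
  ids <- rownames(steps)
  n <- length(ids)
  if (is.null(counts)) counts <- stats::setNames(rep(1L, n), ids)
  nodes <- data.frame(id = ids,
                      count = as.integer(counts[ids]),
                      group = if (is.null(groups)) NA_character_
                              else as.character(groups[ids]),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      steps = integer(), stringsAsFactors = FALSE)
  if (n > 1L) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    pairs <- which(upper.tri(steps), arr.ind = TRUE)
    w <- steps[pairs]
    for (lev in sort(unique(w))) {
      at <- pairs[w == lev, , drop = FALSE]
      comp_before <- vapply(seq_len(n), find, 1L)
      keep <- comp_before[at[, 1L]] != comp_before[at[, 2L]]
      at <- at[keep, , drop = FALSE]
      if (nrow(at)) {
        edges <- rbind(edges, data.frame(
          from = ids[at[, 1L]], to = ids[at[, 2L]],
          steps = as.integer(rep(lev, nrow(at))), stringsAsFactors = FALSE))
        for (r in seq_len(nrow(at))) {
          ri <- find(at[r, 1L]); rj <- find(at[r, 2L])
          if (ri != rj) parent[ri] <- rj
        }
      }
      if (length(unique(vapply(seq_len(n), find, 1L))) == 1L) break
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d haplotypes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a haplotype network as edge-list TSV and GraphML
#'
#' @param net `haplotype_network`.
#' @param tsv,graphml Output paths; either may be `NULL`.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, tsv = NULL, graphml = NULL) {
  if (!is.null(tsv))
    utils::write.table(net$edges, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphml)) {
    con <- file(graphml, "wb")
    on.exit(close(con))
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="count" for="node" attr.name="count" attr.type="int"/>',
      '<key id="group" for="node" attr.name="group" attr.type="string"/>',
      '<key id="steps" for="edge" attr.name="steps" attr.type="int"/>',
      '<graph edgedefault="undirected">'), con)
    for (i in seq_len(nrow(net$nodes))) {
      writeLines(sprintf(
        '<node id="%s"><data key="count">%d</data><data key="group">%s</data></node>',
        esc(net$nodes$id[i]), net$nodes$count[i],
        esc(ifelse(is.na(net$nodes$group[i]), "", net$nodes$group[i]))), con)
    }
    for (i in seq_len(nrow(net$edges))) {
      writeLines(sprintf(
        '<edge source="%s" target="%s"><data key="steps">%d</data></edge>',
        esc(net$edges$from[i]), esc(net$edges$to[i]), net$edges$steps[i]), con)
    }
    writeLines(c("</graph>", "</graphml>"), con)
  }
  invisible(net)
}

#' Call numt versus authentic mtDNA clades
#'
#' Applies the three lines of evidence that separate nuclear mitochondrial
#' pseudogenes from authentic mtDNA in clone sets: (1) numt sequences lack
#' the R2 tandem array, so a clade in which at least `absent_threshold` of
#' members have `N = 0` is repeat-negative; (2) anchor sequences
#' (independently verified mtDNA, e.g. derived from long-range PCR) pin their
#' clade as authentic -- a clade containing an anchor is never called numt;
#' (3) the mean number of mutational steps within each clade is reported as
#' corroborating evidence, numts being expected to show fewer steps owing to
#' their reduced post-translocation substitution rate. When no anchors are
#' supplied, the clade with the highest repeat-bearing fraction is presumed
#' to be the mtDNA clade.
#'
#' @param partition `clade_partition` or named clade-label vector.
#' @param N Named integer vector of full-unit counts per sequence (from
#'   [decompose_repeats()]), or a named list of `repeat_decomposition`
#'   objects.
#' @param anchors Character vector of anchor sequence ids (optional).
#' @param aln Optional aligned sequences (named) used to compute mean
#'   internal mutational steps per clade.
#' @param mask Optional columns excluded from step counting (the R2 region).
#' @param absent_threshold Repeat-absent fraction at or above which a
#'   non-anchored clade is called numt (default 0.9).
#' @return Object of class `numt_call`: per-clade evidence table with
#'   `verdict` (`"numt"` or `"mtDNA"`), plus any warnings (e.g. anchors split
#'   across clades).
#' @export
call_numts <- function(partition, N, anchors = character(), aln = NULL,
                       mask = NULL, absent_threshold = 0.9) {
  labels <- if (inherits(partition, "clade_partition")) partition$labels
            else partition
  if (is.list(N)) N <- vapply(N, function(d) d$N, 1L)
  missing <- setdiff(names(labels), names(N))
  if (length(missing))
    stop("no decomposition for sequence(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  clades <- sort(unique(labels))
  warnings <- character(0)
  steps_mat <- NULL
  if (!is.null(aln)) steps_mat <- mutational_steps_matrix(aln, mask)
  ev <- do.call(rbind, lapply(clades, function(cl) {
    members <- names(labels)[labels == cl]
    data.frame(
      clade = cl,
      n = length(members),
      repeat_absent_fraction = mean(N[members] == 0L),
      contains_anchor = any(members %in% anchors),
      mean_internal_steps = if (is.null(steps_mat)) NA_real_
                            else group_mean(steps_mat, members),
      stringsAsFactors = FALSE)
  }))
  if (sum(ev$contains_anchor) > 1L)
    warnings <- c(warnings, paste0(
      "anchor sequences are split across clades: ",
      paste(ev$clade[ev$contains_anchor], collapse = ", ")))
  presumed_mt <- if (any(ev$contains_anchor)) ev$contains_anchor
                 else seq_len(nrow(ev)) ==
                   which.max(1 - ev$repeat_absent_fraction)
  ev$verdict <- ifelse(!presumed_mt &
                         ev$repeat_absent_fraction >= absent_threshold,
                       "numt", "mtDNA")
  rownames(ev) <- NULL
  structure(list(evidence = ev, warnings = warnings,
                 absent_threshold = absent_threshold),
            class = "numt_call")
}

#' @export
print.numt_call <- function(x, ...) {
  print(x$evidence)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Call sequence and length heteroplasmy for one individual
#'
#' Operates on the authentic-mtDNA clones of a single individual. Core
#' haplotypes are the distinct sequences after masking the R2 array. Because
#' most clones carry at least one polymerase error at realistic error rates,
#' raw haplotype counting is preceded by an error-aware cleanup driven by the
#' Poisson error model:
#'
#' 1. Site-support correction: a clone's difference from the per-site
#'    majority consensus that is shared by fewer than `min_site_support`
#'    clones is treated as a putative polymerase error and corrected back to
#'    the consensus, provided the clone carries no more than the Poisson
#'    plausibility threshold `ceiling(lambda + 2 sqrt(lambda))` of such
#'    private sites. True heteroplasmic variants recur across the clones of
#'    the minor haplotype and are therefore left untouched.
#' 2. Singleton collapse: haplotypes still supported by a single clone and
#'    within the same threshold of the nearest multi-clone haplotype are
#'    folded into it; more divergent singletons are kept as genuine distinct
#'    haplotypes. A haplotype supported by two or more clones is never
#'    removed.
#'
#' Sequence heteroplasmy is called when at least two haplotypes survive;
#' length heteroplasmy when the individual's clones carry at least two
#' distinct R2 array lengths.
#'
#' @param seqs Named character vector: aligned core (R2-masked) sequences of
#'   the individual's mtDNA clones.
#' @param array_lengths Named numeric vector of R2 array lengths per clone
#'   (`NA` allowed).
#' @param em [error_model()] supplying the expected errors per clone.
#' @param collapse_threshold Override for the Poisson plausibility threshold.
#' @param min_site_support Clone support at or above which a variant site is
#'   treated as real (default 2).
#' @return Object of class `heteroplasmy_call`: `sequence_het`, `length_het`,
#'   `n_core_haplotypes`, `n_size_classes`, the surviving `haplotypes` table
#'   with clone counts, and bookkeeping on corrected sites.
#' @export
call_heteroplasmy <- function(seqs, array_lengths = NULL,
                              em = error_model(),
                              collapse_threshold = NULL,
                              min_site_support = 2L) {
  if (!length(seqs)) stop("need at least one clone")
  lambda <- em$lambda
  thr <- if (is.null(collapse_threshold)) ceiling(lambda + 2 * sqrt(lambda))
         else collapse_threshold
  if (is.null(array_lengths))
    array_lengths <- stats::setNames(rep(NA_real_, length(seqs)), names(seqs))
  lens <- unique(array_lengths[!is.na(array_lengths)])
  n_size <- length(lens)

  if (length(seqs) == 1L) {
    return(structure(list(sequence_het = FALSE, length_het = FALSE,
                          n_core_haplotypes = 1L, n_size_classes = n_size,
                          haplotypes = data.frame(
                            sequence = unname(seqs), count = 1L,
                            stringsAsFactors = FALSE),
                          n_corrected_sites = 0L, threshold = thr),
                     class = "heteroplasmy_call"))
  }

  m <- seqs_to_matrix(seqs)
  n <- nrow(m)
  ## per-site majority consensus (ties -> first-seen base)
  cons <- apply(m, 2L, function(col) {
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else col[match(TRUE, col %in% top)]
  })
  cons_mat <- matrix(cons, n, ncol(m), byrow = TRUE)
  diff_mat <- m != cons_mat
  n_corrected <- 0L
  for (i in seq_len(n)) {
    sites <- which(diff_mat[i, ])
    if (!length(sites)) next
    support <- vapply(sites, function(j) sum(m[, j] == m[i, j]), 1L)
    priv <- sites[support < min_site_support]
    if (length(priv) && length(priv) <= thr) {
      m[i, priv] <- cons[priv]
      n_corrected <- n_corrected + length(priv)
    }
  }
  corrected <- matrix_to_seqs(m)
  tab <- table(corrected)
  haps <- names(tab)
  counts <- as.integer(tab)
  ## collapse plausible-error singletons into the nearest multi-clone haplotype
  multi <- which(counts >= 2L)
  if (length(multi) && any(counts == 1L)) {
    for (i in which(counts == 1L)) {
      dists <- vapply(multi, function(j) mutational_steps(haps[i], haps[j]), 1L)
      if (min(dists) <= thr) {
        j <- multi[which.min(dists)]
        counts[j] <- counts[j] + 1L
        counts[i] <- 0L
      }
    }
  }
  keep <- counts > 0L
  haplotypes <- data.frame(sequence = haps[keep], count = counts[keep],
                           stringsAsFactors = FALSE)
  haplotypes <- haplotypes[order(-haplotypes$count), , drop = FALSE]
  rownames(haplotypes) <- NULL
  structure(list(sequence_het = nrow(haplotypes) >= 2L,
                 length_het = n_size >= 2L,
                 n_core_haplotypes = nrow(haplotypes),
                 n_size_classes = n_size,
                 haplotypes = haplotypes,
                 n_corrected_sites = n_corrected,
                 threshold = thr),
            class = "heteroplasmy_call")
}

#' @export
print.heteroplasmy_call <- function(x, ...) {
  cat(sprintf(
    "heteroplasmy_call: sequence_het = %s (%d haplotype(s)), length_het = %s (%d size class(es))\n",
    x$sequence_het, x$n_core_haplotypes, x$length_het, x$n_size_classes))
  invisible(x)
}
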