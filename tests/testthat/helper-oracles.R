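## Independent oracles and fixture builders shared across tests.

## Brute-force decomposition oracle for arrays that are pure unit
## concatenations: try every phase offset, tile consecutive unit-length
## blocks, keep the offset tiling the most exact-class units, and assign
## each block to its minimum-edit-distance class (ties -> earlier label).
oracle_decompose <- function(seq, inventory) {
  u <- nchar(inventory[[1L]])
  n <- nchar(seq)
  best <- NULL
  for (off in 0:(u - 1L)) {
    k <- (n - off) %/% u
    if (k < 1L) next
    starts <- off + u * (seq_len(k) - 1L) + 1L
    blocks <- substring(seq, starts, starts + u - 1L)
    D <- utils::adist(blocks, inventory)
    if (any(apply(D, 1L, min) > 2L)) next
    exact <- sum(apply(D, 1L, min) == 0L)
    if (is.null(best) || exact > best$exact) {
      labels <- names(inventory)[apply(D, 1L, which.min)]
      best <- list(exact = exact, labels = labels, offset = off, k = k)
    }
  }
  if (is.null(best)) return(NULL)
  r <- rle(best$labels)
  paste0("(", r$values, ")", r$lengths, collapse = "")
}

## Random run-length structure over two motif labels with distinct adjacent
## labels; returns the structure string.
random_structure <- function(max_units = 30L, labels = c("A", "B")) {
  total <- sample(2:max_units, 1L)
  runs <- c()
  lab <- sample(labels, 1L)
  left <- total
  while (left > 0L) {
    ct <- sample(seq_len(min(left, 7L)), 1L)
    runs <- c(runs, paste0("(", lab, ")", ct))
    lab <- sample(setdiff(labels, lab), 1L)
    left <- left - ct
  }
  paste0(runs, collapse = "")
}

## Apply at most one random substitution per unit with probability p.
fuzz_units <- function(seq, unit_len = 11L, p = 0.3) {
  s <- strsplit(seq, "")[[1L]]
  n_units <- length(s) %/% unit_len
  for (i in seq_len(n_units)) {
    if (stats::runif(1L) < p) {
      pos <- (i - 1L) * unit_len + sample.int(unit_len, 1L)
      s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1L)
    }
  }
  paste0(s, collapse = "")
}

## All spanning trees of the complete graph on n labelled nodes via Prufer
## sequences; returns the union of edge sets of all minimum-weight trees.
oracle_min_spanning_edges <- function(w) {
  n <- nrow(w)
  stopifnot(n >= 2L, n <= 6L)
  if (n == 2L) return(matrix(c(1L, 2L), 1L))
  prufer_decode <- function(p) {
    n <- length(p) + 2L
    degree <- rep(1L, n)
    for (x in p) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    for (i in seq_along(p)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, p[i])
      degree[leaf] <- degree[leaf] - 1L
      degree[p[i]] <- degree[p[i]] - 1L
    }
    edges[n - 1L, ] <- which(degree == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  kept <- list()
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(as.integer(seqs[r, ]))
    wt <- sum(w[ed])
    if (wt < best - 1e-9) {
      best <- wt
      kept <- list(ed)
    } else if (abs(wt - best) <= 1e-9) {
      kept[[length(kept) + 1L]] <- ed
    }
  }
  edges <- unique(do.call(rbind, lapply(kept, function(ed) {
    t(apply(ed, 1L, sort))
  })))
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

## canonical sorted edge matrix from a haplotype_network (integer node ids)
network_edge_matrix <- function(net) {
  if (!nrow(net$edges)) return(matrix(integer(0), 0L, 2L))
  e <- cbind(as.integer(net$edges$from), as.integer(net$edges$to))
  e <- t(apply(e, 1L, sort))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

## Deterministic re-cloning fixture: 26 clones of a 724-bp fragment with 23
## planted private mutations (8 clones identical to the template).
make_recloning_fixture <- function() {
  set.seed(20140519)
  base <- sample(c("A", "C", "G", "T"), 724, replace = TRUE)
  clones <- list()
  for (i in 1:8) clones[[i]] <- base
  muts_per_clone <- c(rep(1L, 13L), rep(2L, 5L))   # 13 + 10 = 23 mutations
  pos_pool <- sample.int(724, sum(muts_per_clone))  # all sites distinct
  p <- 1L
  for (i in seq_along(muts_per_clone)) {
    cl <- base
    for (k in seq_len(muts_per_clone[i])) {
      site <- pos_pool[p]; p <- p + 1L
      cl[site] <- sample(setdiff(c("A", "C", "G", "T"), cl[site]), 1L)
    }
    clones[[8L + i]] <- cl
  }
  out <- vapply(clones, paste0, "", collapse = "")
  names(out) <- sprintf("reclone%02d", seq_along(out))
  out
}

## K2P via ape on a set of aligned sequences (mask removed beforehand).
ape_k2p <- function(seqs) {
  m <- do.call(rbind, strsplit(tolower(unname(seqs)), ""))
  rownames(m) <- names(seqs)
  as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                          pairwise.deletion = TRUE))
}

## small simulation used by several tests
small_sim_config <- function(seed = 1L) {
  sim_config(seed = seed,
             individuals_per_taxon = c(East = 2L, Hainan = 1L, Central = 1L,
                                       septentrionalis = 1L),
             clones_per_size_class = 6L)
}
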