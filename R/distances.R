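## Sites usable for distance computation: unambiguous bases outside the mask.
BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q`
#' are the proportions of transitions and transversions over comparable
#' sites. Sites carrying a gap or ambiguity code in either sequence, or
#' listed in `mask` (typically the unalignable R2 repeat stretch), are
#' excluded (pairwise deletion).
#'
#' @param x,y Aligned sequences (equal-length character strings).
#' @param mask Optional integer vector of 1-based alignment columns to
#'   exclude.
#' @return Distance in substitutions/site, with attributes `P`, `Q` and
#'   `n_sites` retained for audit.
#' @examples
#' s <- strrep("A", 99)
#' k2p_distance(paste0(s, "A"), paste0(s, "G"))  # one transition in 100 sites
#' @export
k2p_distance <- function(x, y, mask = NULL) {
  a <- strsplit(toupper(x), "")[[1L]]
  b <- strsplit(toupper(y), "")[[1L]]
  if (length(a) != length(b))
    stop("aligned sequences must have equal length (", length(a), " vs ",
         length(b), ")")
  keep <- a %in% BASES & b %in% BASES
  if (!is.null(mask)) keep[mask] <- FALSE
  n <- sum(keep)
  if (n == 0L) stop("no comparable sites between the two sequences")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  ts <- diff & ((a %in% PURINES) == (b %in% PURINES))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturated) for this pair: P = ",
         signif(P, 4), ", Q = ", signif(Q, 4))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  attr(d, "P") <- P
  attr(d, "Q") <- Q
  attr(d, "n_sites") <- n
  d
}

#' Pairwise K2P distance matrix for an aligned sequence set
#'
#' Vectorised all-against-all version of [k2p_distance()], using pairwise
#' deletion of gap/ambiguity sites and an optional column mask. The
#' transition proportion `P`, transversion proportion `Q` and comparable-site
#' counts of every pair are kept alongside the distances.
#'
#' @param seqs Named character vector of equal-length aligned sequences, or a
#'   character matrix with one row per sequence.
#' @param mask Optional integer vector of 1-based alignment columns to
#'   exclude (e.g. the R2 array region).
#' @return Object of class `k2p_matrix`: list with `labels` and symmetric
#'   matrices `d`, `P`, `Q`, `n_sites`.
#' @export
k2p_matrix <- function(seqs, mask = NULL) {
  m <- if (is.matrix(seqs)) seqs else seqs_to_matrix(seqs)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (!is.null(mask)) m <- m[, -mask, drop = FALSE]
  labels <- rownames(m)
  ## indicator algebra: per-base 0/1 matrices give transition / transversion
  ## counts for every pair in a handful of matrix products
  I <- lapply(BASES, function(b) (m == b) * 1)
  names(I) <- BASES
  V <- I$A + I$C + I$G + I$T                 # valid (unambiguous) sites
  n_sites <- V %*% t(V)
  match_ct <- Reduce(`+`, lapply(I, function(x) x %*% t(x)))
  ts_ct <- I$A %*% t(I$G) + I$G %*% t(I$A) +
    I$C %*% t(I$T) + I$T %*% t(I$C)
  tv_ct <- n_sites - match_ct - ts_ct
  if (any(n_sites[upper.tri(n_sites)] == 0)) {
    ij <- which(n_sites == 0 & upper.tri(n_sites), arr.ind = TRUE)[1L, ]
    stop("no comparable sites between ", labels[ij[1L]], " and ",
         labels[ij[2L]])
  }
  P <- ts_ct / n_sites
  Q <- tv_ct / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  bad <- (w1 <= 0 | w2 <= 0) & upper.tri(P)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop("K2P distance undefined (saturated) for pair ", labels[ij[1L]],
         " / ", labels[ij[2L]])
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  diag(d) <- 0
  dimnames(d) <- dimnames(P) <- dimnames(Q) <- dimnames(n_sites) <-
    list(labels, labels)
  structure(list(labels = labels, d = d, P = P, Q = Q, n_sites = n_sites),
            class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat(sprintf("k2p_matrix: %d sequences, mean distance %.4f\n",
              length(x$labels), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "k2p_matrix")) dm$d
  else if (is.matrix(dm)) dm
  else stop("expected a k2p_matrix or a square distance matrix")
}

group_mean <- function(d, members) {
  if (length(members) < 2L) return(0)
  sub <- d[members, members, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Net between-group sequence divergence
#'
#' Nei's net divergence: the mean between-group distance minus the average of
#' the two within-group means,
#' `d_net = mean(d[x, y]) - (mean_within(X) + mean_within(Y)) / 2`.
#' The within-group mean of a singleton group is 0.
#'
#' @param dm A `k2p_matrix` or plain symmetric distance matrix with labelled
#'   rows/columns.
#' @param group_x,group_y Disjoint, non-empty label vectors.
#' @return List with `net`, the plain `between` mean divergence, and the two
#'   within-group means.
#' @export
net_divergence <- function(dm, group_x, group_y) {
  d <- as_dist_matrix(dm)
  labs <- rownames(d)
  if (length(intersect(group_x, group_y)))
    stop("groups overlap: ", paste(intersect(group_x, group_y), collapse = ", "))
  if (!length(group_x) || !length(group_y)) stop("groups must be non-empty")
  missing <- setdiff(c(group_x, group_y), labs)
  if (length(missing))
    stop("labels absent from distance matrix: ", paste(missing, collapse = ", "))
  between <- mean(d[group_x, group_y, drop = FALSE])
  wx <- group_mean(d, group_x)
  wy <- group_mean(d, group_y)
  list(net = between - (wx + wy) / 2,
       between = between, within_x = wx, within_y = wy)
}

#' Write a distance matrix as TSV and PHYLIP lower triangle
#'
#' @param dm `k2p_matrix` or plain matrix.
#' @param tsv,phylip Output paths; either may be `NULL` to skip.
#' @return Invisibly, the distance matrix.
#' @export
write_distances <- function(dm, tsv = NULL, phylip = NULL) {
  d <- as_dist_matrix(dm)
  if (!is.null(tsv)) {
    tab <- data.frame(id = rownames(d), round(d, 8), check.names = FALSE)
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(phylip)) {
    con <- file(phylip, "wb")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      vals <- if (i > 1L) paste(sprintf("%.6f", d[i, seq_len(i - 1L)]),
                                collapse = " ") else ""
      writeLines(trimws(paste(sprintf("%-12s", rownames(d)[i]), vals),
                        which = "right"), con)
    }
  }
  invisible(d)
}
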