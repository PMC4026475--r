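## partitions compared up to label permutation
canonical_partition <- function(labels) {
  labels <- labels[order(names(labels))]
  as.integer(factor(labels, levels = unique(labels)))
}

test_that("clade partitioning separates well-spaced groups and not noise", {
  seqs <- c(a1 = "AAAAAAAAAAAAAAAAAAAA", a2 = "AAAAAAAAAAAAAAAAAAAA",
            b1 = "GGGGAAAAAAAAAAAAAAAA", b2 = "GGGGAAAAAAAAAAAAAAAA")
  part <- partition_clades(k2p_matrix(seqs))
  expect_identical(part$k, 2L)
  expect_identical(unname(part$labels["a1"]), unname(part$labels["a2"]))
  expect_false(part$labels[["a1"]] == part$labels[["b1"]])

  ## all-identical sequences: trivial single clade
  same <- c(x = "ACGTACGT", y = "ACGTACGT", z = "ACGTACGT")
  expect_identical(partition_clades(k2p_matrix(same))$k, 1L)

  ## weakly structured noise stays a single clade under the separation gate
  set.seed(31)
  base <- sample(c("A", "C", "G", "T"), 200, TRUE)
  noisy <- vapply(1:10, function(i) {
    s <- base
    for (p in sample.int(200, 5L)) s[p] <- sample(c("A", "C", "G", "T"), 1L)
    paste0(s, collapse = "")
  }, "")
  names(noisy) <- paste0("n", 1:10)
  expect_identical(partition_clades(k2p_matrix(noisy))$k, 1L)

  expect_error(partition_clades(k2p_matrix(same[1L])), "at least two")
})

test_that("clade partitioning is invariant to input order", {
  sim <- simulate_dataset(small_sim_config(seed = 8))
  dm <- k2p_matrix(sim$alignment, sim$mask)
  part1 <- partition_clades(dm)
  perm <- sample(length(sim$alignment))
  dm2 <- k2p_matrix(sim$alignment[perm], sim$mask)
  part2 <- partition_clades(dm2)
  expect_identical(part1$k, part2$k)
  expect_identical(canonical_partition(part1$labels),
                   canonical_partition(part2$labels))
})

test_that("simulated clone sets resolve into their true origin clades", {
  sim <- simulate_dataset(small_sim_config(seed = 2))
  dm <- k2p_matrix(sim$alignment, sim$mask)
  part <- partition_clades(dm)
  expect_identical(part$k, 3L)
  origin <- sim$records$origin[match(names(part$labels), sim$records$id)]
  ## perfect agreement up to label permutation
  expect_identical(max(table(part$labels, origin) > 0), 1L |> as.integer())
  tab <- table(part$labels, origin)
  expect_true(all(rowSums(tab > 0) == 1L))
  ## the separation scores mark all clades as well separated
  expect_true(all(part$separation > 0.8))
})

test_that("mutational steps count substitutions and whole gap runs", {
  expect_identical(mutational_steps("ACGT", "ACGT"), 0L)
  expect_identical(mutational_steps("ACGT", "ATGT"), 1L)
  expect_identical(mutational_steps("AC--GT", "ACTTGT"), 1L)
  expect_identical(mutational_steps("AC--GT", "ATTTGT"), 2L)
  expect_identical(mutational_steps("A-C-T", "AACCT"), 2L)
  expect_error(mutational_steps("ACG", "ACGT"), "equal length")

  ## identity, symmetry, non-negativity over enumerated gapped strings
  alpha <- c("A", "C", "-")
  strs <- apply(expand.grid(alpha, alpha, alpha), 1L, paste0, collapse = "")
  for (x in strs) for (y in strs) {
    d <- mutational_steps(x, y)
    expect_gte(d, 0L)
    expect_identical(d, mutational_steps(y, x))
    if (x == y) expect_identical(d, 0L)
  }
  ## triangle inequality on the gap-free subset
  nog <- strs[!grepl("-", strs)]
  for (x in nog) for (y in nog) for (z in nog) {
    expect_lte(mutational_steps(x, y),
               mutational_steps(x, z) + mutational_steps(z, y))
  }
})

test_that("the step matrix matches pairwise calls", {
  set.seed(12)
  seqs <- vapply(1:6, function(i) {
    paste0(sample(c("A", "C", "G", "T", "-"), 30, TRUE,
                  prob = c(rep(0.23, 4), 0.08)), collapse = "")
  }, "")
  names(seqs) <- paste0("h", 1:6)
  sm <- mutational_steps_matrix(seqs)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_identical(sm[i, j],
                     mutational_steps(seqs[[i]], seqs[[j]]))
  }
})

test_that("minimum spanning networks keep exactly the co-minimal edges", {
  one <- build_network(c(h1 = "ACGT"))
  expect_identical(nrow(one$edges), 0L)
  expect_identical(one$nodes$id, "h1")

  ## three haplotypes at steps {1,2,3}: the 3-step edge is excluded, the
  ## retained tree carries edge weights {1,2}
  steps <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3L,
                  dimnames = list(1:3, 1:3))
  net <- build_network(steps = steps)
  expect_identical(network_edge_matrix(net),
                   matrix(c(1L, 2L, 2L, 3L), 2L))
  expect_identical(sort(net$edges$steps), c(1L, 2L))

  ## equilateral triangle: all ties kept
  tri <- matrix(1, 3L, 3L, dimnames = list(1:3, 1:3)); diag(tri) <- 0
  expect_identical(nrow(build_network(steps = tri)$edges), 3L)

  ## random cases against exhaustive spanning-tree enumeration
  set.seed(55)
  for (case in 1:20) {
    n <- sample(3:6, 1L)
    w <- matrix(0L, n, n, dimnames = list(1:n, 1:n))
    w[upper.tri(w)] <- sample(1:4, n * (n - 1L) / 2L, TRUE)
    w <- w + t(w)
    net <- build_network(steps = w)
    expect_identical(network_edge_matrix(net), oracle_min_spanning_edges(w),
                     label = paste("case", case))
  }
})

test_that("numt calling combines repeat absence, anchors and step density", {
  sim <- simulate_dataset(small_sim_config(seed = 4))
  dm <- k2p_matrix(sim$alignment, sim$mask)
  part <- partition_clades(dm)
  N <- vapply(stats::setNames(sim$records$sequence, sim$records$id),
              function(s) decompose_repeats(s)$N, 1L)
  anchors <- sim$records$id[sim$records$is_anchor]
  call <- call_numts(part, N, anchors = anchors, aln = sim$alignment,
                     mask = sim$mask)
  ev <- call$evidence
  origin <- sim$records$origin[match(names(part$labels), sim$records$id)]
  truth_mt <- names(which(table(part$labels[origin == "mtDNA"]) > 0))
  expect_identical(sort(ev$clade[ev$verdict == "mtDNA"]), truth_mt)
  expect_identical(sum(ev$verdict == "numt"), 2L)
  ## repeat-bearing fractions are clean and numts show fewer internal steps
  expect_true(all(ev$repeat_absent_fraction[ev$verdict == "numt"] >= 0.9))
  mt_steps <- ev$mean_internal_steps[ev$verdict == "mtDNA"]
  expect_true(all(mt_steps > ev$mean_internal_steps[ev$verdict == "numt"]))

  ## an anchor shields its clade regardless of repeat content
  labels <- c(a = "C1", b = "C1", c = "C2", d = "C2")
  N0 <- c(a = 0L, b = 0L, c = 0L, d = 0L)
  shielded <- call_numts(labels, N0, anchors = "a")
  evs <- shielded$evidence
  expect_identical(evs$verdict[evs$clade == "C1"], "mtDNA")
  expect_identical(evs$verdict[evs$clade == "C2"], "numt")

  ## single repeat-bearing clade: mtDNA, no numt calls
  labels1 <- c(a = "C1", b = "C1")
  expect_identical(
    call_numts(labels1, c(a = 5L, b = 6L))$evidence$verdict, "mtDNA")

  ## anchors split across clades are recorded as a warning, not an error
  split_call <- call_numts(labels, N0, anchors = c("a", "c"))
  expect_match(split_call$warnings, "split across clades")
})

test_that("heteroplasmy calls separate planted variants from polymerase error", {
  em <- error_model(7.2e-5, 724, 34)

  ## two array lengths, one core haplotype: length-only heteroplasmy
  core <- strrep("ACGT", 25)
  h <- call_heteroplasmy(
    c(c1 = core, c2 = core, c3 = core),
    array_lengths = c(c1 = 209, c2 = 209, c3 = 176), em = em)
  expect_false(h$sequence_het)
  expect_true(h$length_het)
  expect_identical(h$n_size_classes, 2L)

  ## a single clone can support neither flag
  h1 <- call_heteroplasmy(c(c1 = core), array_lengths = c(c1 = 209), em = em)
  expect_false(h1$sequence_het)
  expect_false(h1$length_het)

  ## haplotypes supported by >= 2 clones are never collapsed
  minor <- sub("^ACGT", "TCGA", core)   # 2 substitutions from core
  h2 <- call_heteroplasmy(
    c(a = core, b = core, c = core, d = minor, e = minor),
    em = em)
  expect_true(h2$sequence_het)
  expect_identical(h2$n_core_haplotypes, 2L)
  expect_identical(sort(h2$haplotypes$count), c(2L, 3L))

  ## an error-plausible singleton collapses into the nearest haplotype ...
  one_err <- sub("G$", "A", core)
  h3 <- call_heteroplasmy(c(a = core, b = core, c = one_err), em = em)
  expect_false(h3$sequence_het)
  expect_identical(h3$haplotypes$count, 3L)
  ## ... but a divergent singleton beyond the Poisson threshold survives
  diverged <- paste0(strrep("TTTT", 3), substr(core, 13, nchar(core)))
  h4 <- call_heteroplasmy(c(a = core, b = core, c = diverged), em = em)
  expect_true(h4$sequence_het)
  expect_identical(h4$n_core_haplotypes, 2L)
})

test_that("planted minor haplotypes are recovered despite Taq noise", {
  em <- error_model(7.2e-5, 724, 34)
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    sim <- simulate_dataset(sim_config(seed = seed))
    core <- mask_columns(sim$alignment, sim$mask)
    mt <- sim$records[sim$records$origin == "mtDNA" & !sim$records$is_anchor, ]
    for (ind in unique(mt$individual)) {
      truth <- sim$individuals[sim$individuals$individual == ind, ]
      if (!truth$sequence_het) next
      ids <- mt$id[mt$individual == ind]
      h <- call_heteroplasmy(
        core[ids],
        stats::setNames(mt$array_length[mt$individual == ind], ids), em = em)
      total <- total + 1L
      hits <- hits + h$sequence_het
    }
  }
  expect_gte(hits / total, 0.85)
})
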