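test_that("structure strings reconstruct to sequences of the expected length", {
  expect_identical(nchar(reconstruct_from_structure("(C)7")), 77L)
  expect_identical(reconstruct_from_structure("(C)7"),
                   strrep("AACGTATACGC", 7))
  expect_identical(nchar(reconstruct_from_structure("(A)4(B)1(A)5(B)2(A)6(B)2")),
                   220L)
  expect_identical(reconstruct_from_structure(""), "")
  expect_error(reconstruct_from_structure("(Z)3"), "valid labels.*A.*B")
  ## length identity: unit_len * full units + literal lengths
  set.seed(11)
  for (i in 1:25) {
    st <- random_structure()
    runs <- parse_structure(st)
    expect_identical(nchar(reconstruct_from_structure(st)),
                     11L * sum(runs$count[!runs$literal]))
  }
  ## literals are inserted verbatim
  expect_identical(
    nchar(reconstruct_from_structure("(C)1AACGC(D)6")),
    11L * 7L + 5L)
})

test_that("parse_structure and format_structure are inverse", {
  st <- "(C)1AACGC(D)6(C)1(D)1(C)3(D)2(C)1(D)1(C)3"
  expect_identical(format_structure(parse_structure(st)), st)
  expect_identical(format_structure(parse_structure("(A)10 (B)7")), "(A)10(B)7")
})

test_that("period inference finds the repeat unit and rejects random sequence", {
  expect_identical(infer_period(strrep("AACGTATACGC", 7)), 11L)
  expect_identical(
    infer_period("ACGACGACGACGACGACG", k = 3L, min_period = 2L,
                 max_period = 9L), 3L)
  set.seed(5)
  fgb008 <- reconstruct_from_structure("(A)4(B)1(A)5(B)2(A)6(B)2")
  flank <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  expect_identical(infer_period(paste0(flank(200), fgb008, flank(200))), 11L)
  for (i in 1:5) {
    expect_identical(infer_period(flank(300)), NA_integer_)
  }
})

test_that("published size classes decompose back to their printed structures", {
  tab <- published_structures()
  inv <- default_motif_inventory()
  for (i in seq_len(nrow(tab))) {
    seq <- reconstruct_from_structure(tab$structure[i], inv)
    d <- decompose_repeats(seq, inv)
    ## structure <-> sequence round trip holds for every row
    expect_identical(d$structure, tab$structure[i], label = tab$structure[i])
    expect_identical(d$array_length, nchar(seq))
    ## printed length and N agree for the arithmetically consistent rows
    if (tab$consistent[i]) {
      expect_identical(d$array_length, tab$length[i])
      expect_identical(d$N, tab$N[i])
    }
  }
  ## the interior 5-bp partial unit is reported as a literal run
  ygl <- decompose_repeats(
    reconstruct_from_structure(tab$structure[tab$individual == "YGL418" &
                                               tab$size_class == "S1"]), inv)
  expect_true(any(ygl$runs$literal & ygl$runs$label == "AACGC"))
  expect_identical(ygl$N, 19L)
  expect_identical(ygl$array_length, 214L)
})

test_that("arrays embedded in flanking sequence are delimited correctly", {
  set.seed(21)
  flank <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  arr <- reconstruct_from_structure("(C)5(D)3(C)2")
  full <- paste0(flank(150), arr, flank(90))
  d <- decompose_repeats(full)
  expect_identical(d$array_start, 150L)
  expect_identical(d$array_end, 150L + nchar(arr))
  expect_identical(d$structure, "(C)5(D)3(C)2")
  expect_identical(substr(full, d$array_start + 1L, d$array_end), arr)
})

test_that("sequences without tandem structure yield empty decompositions", {
  set.seed(3)
  for (i in 1:5) {
    s <- paste0(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    d <- decompose_repeats(s)
    expect_identical(d$N, 0L)
    expect_identical(nrow(d$runs), 0L)
    d2 <- decompose_repeats(s, inventory = NULL)
    expect_identical(d2$N, 0L)
  }
  expect_error(decompose_repeats("ACGT", inventory = c(A = "ACGT", B = "ACG")),
               "share one length")
})

test_that("decomposer agrees with the exhaustive-phase brute-force oracle", {
  set.seed(77)
  inv <- default_motif_inventory()[c("A", "B")]
  for (i in 1:120) {
    st <- random_structure()
    clean <- reconstruct_from_structure(st, inv)
    fuzzed <- fuzz_units(clean)
    d <- decompose_repeats(fuzzed, inv)
    expect_identical(d$structure, oracle_decompose(fuzzed, inv),
                     label = paste("case", i))
    ## reconstruction fidelity: observed segments tile the array substring
    expect_identical(paste0(d$units$observed, collapse = ""),
                     substr(fuzzed, d$array_start + 1L, d$array_end))
    ## length identity and idempotence under re-decomposition
    expect_identical(d$array_length,
                     11L * d$N + sum(nchar(d$units$observed[d$units$literal])))
    arr <- substr(fuzzed, d$array_start + 1L, d$array_end)
    expect_identical(decompose_repeats(arr, inv)$structure, d$structure)
  }
})

test_that("decomposition round-trips run-length structures over the inventory", {
  set.seed(13)
  for (i in 1:40) {
    st <- random_structure(labels = sample(c("A", "B", "C", "D", "E"), 2L))
    d <- decompose_repeats(reconstruct_from_structure(st))
    expect_identical(d$structure, st)
  }
})

test_that("auto-built inventories recover homogeneous and mixed arrays", {
  d <- decompose_repeats(strrep("AACGTATACGC", 9), inventory = NULL)
  expect_identical(d$N, 9L)
  expect_identical(d$structure, "(A)9")  # provisional labels are rank-based
  mixed <- reconstruct_from_structure("(C)6(D)4(C)3")
  d2 <- decompose_repeats(mixed, inventory = NULL)
  expect_identical(d2$N, 13L)
  expect_identical(d2$array_length, nchar(mixed))
})

test_that("motif discovery ranks unit classes by frequency", {
  tab <- published_structures()
  decomps <- lapply(tab$structure, function(st) {
    decompose_repeats(reconstruct_from_structure(st))
  })
  found <- discover_motifs(decomps, canonical = default_motif_inventory())
  expect_identical(sort(names(found)), c("A", "B", "C", "D", "E"))
  expect_true(all(nchar(found) == 11L))
  expect_setequal(unname(found), unname(default_motif_inventory()))

  ## counts drive label order when no canonical inventory is given
  ab <- decompose_repeats(reconstruct_from_structure("(A)10(B)3"))
  found2 <- discover_motifs(list(ab))
  expect_identical(unname(found2["A"]),
                   unname(default_motif_inventory()["A"]))
  expect_identical(unname(found2["B"]),
                   unname(default_motif_inventory()["B"]))

  expect_error(discover_motifs(list(decompose_repeats("ACGTACGTACAA"))),
               "no repeat arrays found")
})

test_that("structure summaries report per-group motif richness", {
  tab <- published_structures()
  decomps <- lapply(tab$structure, function(st) {
    decompose_repeats(reconstruct_from_structure(st))
  })
  names(decomps) <- paste(tab$individual, tab$size_class)

  summ <- structure_summary(decomps, groups = tab$taxon)
  expect_identical(nrow(summ$sequences), nrow(tab))
  expect_identical(max(summ$sequences$N[tab$consistent]), 20L)

  ## Central sinicus + septentrionalis arrays are homogeneous except SHC009
  south <- tab$taxon %in% c("Central", "septentrionalis")
  ssum <- structure_summary(decomps[south], groups = tab$taxon[south])
  expect_identical(sum(ssum$groups$motif_richness > 1L), 1L)
  by_ind <- structure_summary(decomps[south], groups = tab$individual[south])
  rich <- setNames(by_ind$groups$motif_richness, by_ind$groups$group)
  expect_identical(unname(rich["SHC009"]), 2L)
  expect_true(all(rich[setdiff(names(rich), "SHC009")] == 1L))

  ## small published arrays aside, N spans 13-20 in the table
  cons <- tab$consistent & !(tab$individual == "JJ08") &
    !(tab$individual == "YBG15" & tab$size_class == "S2")
  Ns <- summ$sequences$N[cons]
  expect_identical(range(Ns), c(13L, 20L))

  empty <- structure_summary(list())
  expect_identical(nrow(empty$sequences), 0L)
})
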