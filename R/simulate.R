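#' Configuration for the clone-set simulator
#'
#' Bundles and validates every knob of [simulate_dataset()]. The defaults
#' emulate the study regime the analysis stages expect: a four-taxon species
#' history `((East,Hainan),(Central,septentrionalis))` with 18 sampled
#' individuals; two ancient translocations of the control region into the
#' nucleus on the stem lineage (at or before the root split), each founding a
#' numt lineage that loses the R2 array and thereafter evolves at a reduced
#' rate; heteroplasmic minor haplotypes differing at a couple of core
#' positions; replication-slippage copy-number variation of the R2 array;
#' and per-clone Taq polymerase errors at 7.2e-5 per bp per cycle over 34
#' cycles.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration including the seed.
#' @param topology Rooted newick string with branch lengths in expected
#'   substitutions/site on mtDNA.
#' @param stem_length Expected substitutions/site on the mtDNA stem lineage
#'   above the root split; translocation times are fractions of this stem.
#' @param core_length Length in bp of the non-repeat control-region core.
#' @param array_position Core position after which the R2 array sits.
#' @param motif_inventory Named motif units for the R2 array.
#' @param initial_array Structure string of the ancestral R2 array.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process.
#' @param numt_rate_factor Multiplier in `(0, 1]` applied to branch lengths
#'   after a translocation (numts evolve at a reduced rate).
#' @param translocation_events Numeric vector of translocation times as
#'   fractions of the stem before the root split (`0` = at the split, `1` =
#'   at the top of the stem); one numt lineage per event.
#' @param individuals_per_taxon Named integer vector of sampled individuals.
#' @param ind_branch Expected substitutions/site on the within-taxon branch
#'   leading to each individual.
#' @param p_sequence_het Probability that an individual carries a minor
#'   mtDNA haplotype.
#' @param het_positions Core positions at which a minor haplotype differs.
#' @param het_minor_freq Frequency with which a clone of a heteroplasmic
#'   individual derives from the minor haplotype.
#' @param taxon_slippage_events,ind_slippage_events Slippage steps applied to
#'   the ancestral array on the way to each taxon / individual.
#' @param slippage_geom_prob Success probability of the geometric
#'   distribution of per-clone slippage event counts (each event changes one
#'   run by one unit); `1` disables per-clone slippage.
#' @param clones_per_size_class Clones sequenced per individual and fragment
#'   size class.
#' @param numt_amp_weights Relative amplification propensities of the numt
#'   lineages within the small fragment (recycled to the number of
#'   translocations).
#' @param taq_rate,cycles Per-bp-per-cycle polymerase error rate and PCR
#'   cycle count.
#' @param include_anchors Emit one error-free reference mtDNA sequence per
#'   taxon (the in-silico analogue of a long-range-PCR-verified sequence).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       topology = paste0(
                         "((East:0.003,Hainan:0.003):0.003,",
                         "(Central:0.003,septentrionalis:0.003):0.003);"),
                       stem_length = 0.22,
                       core_length = 724L,
                       array_position = 500L,
                       motif_inventory = default_motif_inventory(),
                       initial_array = "(C)17",
                       kappa = 4,
                       numt_rate_factor = 0.1,
                       translocation_events = c(0.65, 0.9),
                       individuals_per_taxon = c(East = 7L, Hainan = 4L,
                                                 Central = 3L,
                                                 septentrionalis = 4L),
                       ind_branch = 0.001,
                       p_sequence_het = 0.6,
                       het_positions = 2L,
                       het_minor_freq = 0.4,
                       taxon_slippage_events = 2L,
                       ind_slippage_events = 1L,
                       slippage_geom_prob = 0.65,
                       clones_per_size_class = 10L,
                       numt_amp_weights = c(0.2, 0.8),
                       taq_rate = 7.2e-5,
                       cycles = 34L,
                       include_anchors = TRUE) {
  cfg <- as.list(environment())
  for (f in c("seed", "core_length", "array_position", "het_positions",
              "taxon_slippage_events", "ind_slippage_events",
              "clones_per_size_class", "cycles"))
    cfg[[f]] <- as.integer(cfg[[f]])
  for (f in c("stem_length", "kappa", "numt_rate_factor",
              "translocation_events", "ind_branch", "p_sequence_het",
              "het_minor_freq", "slippage_geom_prob", "taq_rate",
              "numt_amp_weights"))
    cfg[[f]] <- as.numeric(cfg[[f]])
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_nonneg <- function(field) {
    v <- cfg[[field]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("invalid sim_config: field '", field, "' must be non-negative")
  }
  for (f in c("stem_length", "ind_branch", "p_sequence_het", "het_minor_freq",
              "taq_rate", "taxon_slippage_events", "ind_slippage_events",
              "translocation_events", "numt_amp_weights", "kappa"))
    chk_nonneg(f)
  if (cfg$numt_rate_factor <= 0 || cfg$numt_rate_factor > 1)
    stop("invalid sim_config: field 'numt_rate_factor' must be in (0, 1]")
  if (any(cfg$translocation_events > 1))
    stop("invalid sim_config: field 'translocation_events' must be fractions",
         " of the stem in [0, 1]")
  if (cfg$slippage_geom_prob <= 0 || cfg$slippage_geom_prob > 1)
    stop("invalid sim_config: field 'slippage_geom_prob' must be in (0, 1]")
  tree <- suppressWarnings(tryCatch(ape::read.tree(text = cfg$topology),
                                    error = function(e) NULL))
  if (is.null(tree) || is.null(tree$edge.length))
    stop("invalid sim_config: field 'topology' must be a newick tree with",
         " branch lengths")
  if (is.null(names(cfg$individuals_per_taxon)) ||
      !all(names(cfg$individuals_per_taxon) %in% tree$tip.label))
    stop("invalid sim_config: field 'individuals_per_taxon' must be named by",
         " topology tip labels")
  if (cfg$array_position >= cfg$core_length)
    stop("invalid sim_config: field 'array_position' must fall inside the core")
  cfg$motif_inventory <- validate_inventory(cfg$motif_inventory)
  structure(cfg, class = "sim_config")
}

## -- substitution machinery ------------------------------------------------

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

## evolve a character vector of bases along a branch (expected subs/site)
evolve_seq <- function(s, brlen, kappa) {
  if (brlen <= 0) return(s)
  n_sub <- stats::rpois(1L, brlen * length(s))
  if (n_sub == 0L) return(s)
  sites <- sample.int(length(s), n_sub, replace = TRUE)
  p_ts <- kappa / (kappa + 2)
  for (p in sites) {
    if (stats::runif(1L) < p_ts) {
      s[p] <- TRANSITION[[s[p]]]
    } else {
      s[p] <- sample(setdiff(BASES, c(s[p], TRANSITION[[s[p]]])), 1L)
    }
  }
  s
}

## evolve a root state down a phylo tree; returns list(tip label -> vector)
evolve_along_tree <- function(root_state, tree, kappa, rate_factor = 1) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- root_state
  ## tree$edge rows are in preorder for read.tree output; process as given
  for (e in seq_len(nrow(tree$edge))) {
    from <- tree$edge[e, 1L]; to <- tree$edge[e, 2L]
    states[[to]] <- evolve_seq(states[[from]],
                               tree$edge.length[e] * rate_factor, kappa)
  }
  stats::setNames(states[seq_len(n_tip)], tree$tip.label)
}

## -- slippage on run-length structures ------------------------------------

## one slippage event: +-1 copy of one run, merging neighbours when a run
## empties; never empties the whole array
apply_slippage <- function(runs, n_events) {
  for (k in seq_len(n_events)) {
    if (!nrow(runs)) break
    i <- sample.int(nrow(runs), 1L)
    delta <- sample(c(-1L, 1L), 1L)
    if (delta < 0L && sum(runs$count) <= 1L) next
    runs$count[i] <- runs$count[i] + delta
    if (runs$count[i] == 0L) {
      runs <- runs[-i, , drop = FALSE]
      if (nrow(runs) >= 2L && i > 1L && i <= nrow(runs) &&
          runs$label[i - 1L] == runs$label[i]) {
        runs$count[i - 1L] <- runs$count[i - 1L] + runs$count[i]
        runs <- runs[-i, , drop = FALSE]
      }
    }
  }
  rownames(runs) <- NULL
  runs
}

#' Simulate a clone-sequence data set with ground truth
#'
#' Generates, deterministically for a given configuration, the clone
#' sequences an amplify-clone-sequence experiment would produce under the
#' configured history: authentic mtDNA clones (large size class `L`)
#' carrying the R2 array with slippage copy-number variation, optional minor
#' heteroplasmic haplotypes and per-clone polymerase errors; numt clones
#' (small size class `S`, present when translocation events are configured)
#' lacking the array and carrying the reduced post-translocation divergence;
#' and optional per-taxon anchor references. Alongside the clone set it
#' returns the true alignment (gap columns pad the unalignable array region,
#' which is reported as the mask) and per-sequence / per-individual truth
#' tables.
#'
#' @param config A [sim_config()].
#' @return Object of class `clone_simulation` with elements `records`
#'   (per-clone truth and sequences; ids follow
#'   `<taxon>|<individual>|<sizeclass>|clone<k>`), `individuals`
#'   (per-individual truth: planted and sampled heteroplasmy flags, size
#'   classes), `alignment` (named gapped sequences), `mask` (1-based array
#'   columns), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(unclass(config))
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$topology)
  inv <- config$motif_inventory
  kappa <- config$kappa

  root_core <- sample(BASES, config$core_length, replace = TRUE)

  ## stem lineage: pause at each translocation point to copy the core into
  ## the nuclear genome (the array is lost at translocation); numt lineages
  ## are numbered by increasing age (numt-1 = most recent translocation)
  ev_frac <- sort(config$translocation_events, decreasing = TRUE)  # oldest first
  ev_label <- rev(seq_along(ev_frac))                # numt-1 = youngest
  ev_pos <- (1 - ev_frac) * config$stem_length       # distance from stem top
  cur <- root_core
  prev <- 0
  numt_taxon_cores <- list()
  for (k in seq_along(ev_pos)) {
    cur <- evolve_seq(cur, ev_pos[k] - prev, kappa)
    prev <- ev_pos[k]
    numt_anc <- evolve_seq(cur,
                           (config$stem_length - ev_pos[k]) *
                             config$numt_rate_factor, kappa)
    numt_taxon_cores[[paste0("numt-", ev_label[k])]] <-
      evolve_along_tree(numt_anc, tree, kappa, config$numt_rate_factor)
  }
  if (length(numt_taxon_cores))
    numt_taxon_cores <- numt_taxon_cores[order(names(numt_taxon_cores))]
  mt_root <- evolve_seq(cur, config$stem_length - prev, kappa)
  mt_taxon_cores <- evolve_along_tree(mt_root, tree, kappa, 1)

  base_runs <- parse_structure(config$initial_array)
  taxa <- names(config$individuals_per_taxon)
  taxon_arrays <- lapply(stats::setNames(taxa, taxa), function(tx) {
    apply_slippage(base_runs, config$taxon_slippage_events)
  })

  n_numt <- length(ev_pos)
  amp_w <- rep_len(config$numt_amp_weights, max(n_numt, 1L))

  recs <- list()
  ind_rows <- list()
  add_rec <- function(...) recs[[length(recs) + 1L]] <<- list(...)

  for (tx in taxa) {
    for (i in seq_len(config$individuals_per_taxon[[tx]])) {
      ind <- sprintf("%s%02d", tx, i)
      major <- evolve_seq(mt_taxon_cores[[tx]], config$ind_branch, kappa)
      het <- stats::runif(1L) < config$p_sequence_het
      minor <- NULL
      if (het) {
        pos <- sample.int(config$core_length, config$het_positions)
        minor <- major
        for (p in pos) minor[p] <- sample(setdiff(BASES, minor[p]), 1L)
      }
      ind_numt_cores <- lapply(numt_taxon_cores, function(tcore) {
        evolve_seq(tcore[[tx]], config$ind_branch * config$numt_rate_factor,
                   kappa)
      })
      ind_runs <- apply_slippage(taxon_arrays[[tx]],
                                 config$ind_slippage_events)
      n_minor <- 0L
      mt_lengths <- integer(0)
      for (cl in seq_len(config$clones_per_size_class)) {
        use_minor <- het && stats::runif(1L) < config$het_minor_freq
        if (use_minor) n_minor <- n_minor + 1L
        core <- if (use_minor) minor else major
        n_slip <- stats::rgeom(1L, config$slippage_geom_prob)
        runs <- apply_slippage(ind_runs, n_slip)
        array_seq <- reconstruct_from_structure(runs, inv)
        full <- paste0(
          paste0(core[seq_len(config$array_position)], collapse = ""),
          array_seq,
          paste0(core[seq.int(config$array_position + 1L,
                              config$core_length)], collapse = ""))
        err <- inject_taq_errors(full, config$taq_rate, config$cycles)
        mt_lengths <- c(mt_lengths, nchar(array_seq))
        add_rec(id = sprintf("%s|%s|L|clone%d", tx, ind, cl),
                taxon = tx, individual = ind, size_class = "L",
                origin = "mtDNA",
                haplotype = paste0(ind, if (use_minor) ":minor" else ":major"),
                true_structure = format_structure(runs),
                array_length = nchar(array_seq),
                core_length_bp = config$core_length,
                n_errors = length(err$positions),
                error_positions = paste(err$positions, collapse = ","),
                is_anchor = FALSE,
                sequence = err$seq,
                core = paste0(core, collapse = ""),
                array = array_seq)
      }
      if (n_numt > 0L) {
        for (cl in seq_len(config$clones_per_size_class)) {
          k <- sample.int(n_numt, 1L, prob = amp_w[seq_len(n_numt)])
          core <- ind_numt_cores[[paste0("numt-", k)]]
          full <- paste0(core, collapse = "")
          err <- inject_taq_errors(full, config$taq_rate, config$cycles)
          add_rec(id = sprintf("%s|%s|S|clone%d", tx, ind, cl),
                  taxon = tx, individual = ind, size_class = "S",
                  origin = paste0("numt-", k),
                  haplotype = paste0(ind, ":numt-", k),
                  true_structure = "",
                  array_length = 0L,
                  core_length_bp = config$core_length,
                  n_errors = length(err$positions),
                  error_positions = paste(err$positions, collapse = ","),
                  is_anchor = FALSE,
                  sequence = err$seq,
                  core = full,
                  array = "")
        }
      }
      ind_rows[[ind]] <- data.frame(
        individual = ind, taxon = tx,
        sequence_het = het,
        sequence_het_sampled = n_minor >= 1L,
        n_minor_clones = n_minor,
        length_het = length(unique(mt_lengths)) >= 2L,
        n_size_classes = length(unique(mt_lengths)),
        stringsAsFactors = FALSE)
    }
  }

  if (config$include_anchors) {
    for (tx in taxa) {
      array_seq <- reconstruct_from_structure(taxon_arrays[[tx]], inv)
      core <- mt_taxon_cores[[tx]]
      full <- paste0(
        paste0(core[seq_len(config$array_position)], collapse = ""),
        array_seq,
        paste0(core[seq.int(config$array_position + 1L, config$core_length)],
               collapse = ""))
      add_rec(id = sprintf("%s|REF%s|L|clone0", tx, tx),
              taxon = tx, individual = paste0("REF", tx), size_class = "L",
              origin = "mtDNA", haplotype = paste0("REF", tx),
              true_structure = format_structure(taxon_arrays[[tx]]),
              array_length = nchar(array_seq),
              core_length_bp = config$core_length,
              n_errors = 0L, error_positions = "",
              is_anchor = TRUE,
              sequence = full,
              core = paste0(core, collapse = ""),
              array = array_seq)
    }
  }

  records <- do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL
  individuals <- do.call(rbind, ind_rows)
  rownames(individuals) <- NULL

  ## true alignment: core columns as simulated (no core indels), array region
  ## padded with gap columns to the widest array; reported as the mask
  maxw <- max(records$array_length)
  left <- substr(records$core, 1L, config$array_position)
  right <- substr(records$core, config$array_position + 1L,
                  config$core_length)
  ## the observed clone (with errors) split back into its regions
  obs_left <- substr(records$sequence, 1L, config$array_position)
  obs_array <- substr(records$sequence, config$array_position + 1L,
                      config$array_position + records$array_length)
  obs_right <- substr(records$sequence,
                      config$array_position + records$array_length + 1L,
                      nchar(records$sequence))
  pad <- strrep("-", maxw - records$array_length)
  alignment <- stats::setNames(paste0(obs_left, obs_array, pad, obs_right),
                               records$id)
  mask <- if (maxw > 0L)
    seq.int(config$array_position + 1L, config$array_position + maxw)
  else integer(0)

  records$core <- NULL
  records$array <- NULL
  structure(list(records = records, individuals = individuals,
                 alignment = alignment, mask = mask,
                 config = config),
            class = "clone_simulation")
}

#' @export
print.clone_simulation <- function(x, ...) {
  cat(sprintf(
    "clone_simulation: %d clones from %d individuals (%d taxa); origins: %s\n",
    nrow(x$records), nrow(x$individuals),
    length(unique(x$records$taxon)),
    paste(names(table(x$records$origin)), collapse = ", ")))
  invisible(x)
}

#' Write simulation outputs to disk
#'
#' Emits the clone set as FASTA, the true alignment as FASTA, the
#' per-sequence and per-individual truth tables as TSV, a combined truth
#' JSON, and the configuration as JSON.
#'
#' @param sim A `clone_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    clones = file.path(dir, "clones.fasta"),
    alignment = file.path(dir, "alignment.fasta"),
    truth_seq = file.path(dir, "truth_sequences.tsv"),
    truth_ind = file.path(dir, "truth_individuals.tsv"),
    truth_json = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json"))
  write_fasta(stats::setNames(sim$records$sequence, sim$records$id),
              paths[["clones"]])
  write_fasta(sim$alignment, paths[["alignment"]])
  seq_truth <- sim$records[, setdiff(names(sim$records), "sequence")]
  utils::write.table(seq_truth, paths[["truth_seq"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$individuals, paths[["truth_ind"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sequences = seq_truth,
                            individuals = sim$individuals,
                            mask = sim$mask),
                       paths[["truth_json"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(sim_config_to_list(sim$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

## JSON-safe view of a sim_config (named vectors kept as objects)
sim_config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$motif_inventory <- as.list(out$motif_inventory)
  out$individuals_per_taxon <- as.list(out$individuals_per_taxon)
  out
}

#' Restore a simulator configuration from JSON
#'
#' @param path Path to a JSON file written by [write_simulation()] (or a
#'   `--dump-config` call of the command-line interface).
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$motif_inventory <- unlist(raw$motif_inventory)
  raw$individuals_per_taxon <- unlist(raw$individuals_per_taxon)
  int_fields <- c("seed", "core_length", "array_position", "het_positions",
                  "taxon_slippage_events", "ind_slippage_events",
                  "clones_per_size_class", "cycles")
  for (f in int_fields) raw[[f]] <- as.integer(raw[[f]])
  raw$individuals_per_taxon <- stats::setNames(
    as.integer(raw$individuals_per_taxon), names(raw$individuals_per_taxon))
  do.call(sim_config, raw)
}
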