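# Synthetic TileSeq data generator.
#
# Emulates the study design of a codon-randomized complementation screen:
# a mutagenized library with a stated mean number of amino-acid changes per
# clone, bimodal true fitness with a small hyper-complementing fraction,
# competitive selection with growth map g(w) = exp(r (w - 1)), multinomial
# tile sequencing with an additive error process shared between the mutant
# pool and a wild-type-control template, two replicates, two mutagenesis
# regions, and an isoform pair differing by a 17-residue N-terminal
# truncation.

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic TileSeq
#' generator. Defaults encode the study conditions: a 361-residue protein,
#' 1.7 amino-acid changes per clone, two mutagenesis regions of five tiles
#' each, two replicates, a 2.5% hyper-complementing fraction, and a
#' scaled-down sequencing depth of 200,000 reads per tile (the real-scale
#' experiment used ~2,000,000).
#'
#' @param protein_length Protein length in residues.
#' @param wt_sequence Optional wild-type amino-acid sequence (character
#'   vector of single letters, length `protein_length`). Drawn at random from
#'   `rng_seed` when `NULL`.
#' @param mean_aa_changes_per_clone Mean amino-acid changes per library clone
#'   (within its mutagenized region).
#' @param n_regions Number of separately mutagenized regions.
#' @param n_tiles_per_region Sequencing tiles per region.
#' @param n_replicates Selection replicates.
#' @param n_control_replicates Wild-type-control sequencing replicates.
#' @param reads_per_tile Sequencing depth per tile (reads).
#' @param generations Number of competitive growth generations.
#' @param growth_rate Selection strength `r` in the growth map
#'   `g(w) = exp(r (w - 1))`; `g(1) = 1` anchors wild-type growth.
#' @param sequencing_error_rate Per-variant probability that a read is
#'   miscalled as that variant (the duplex-calling error floor).
#' @param sigma_log Log-normal spread (sdlog) of per-variant library
#'   abundance.
#' @param frac_deleterious Proportion of missense variants that are null-like.
#' @param frac_hyper Proportion of missense variants that hyper-complement
#'   (true fitness above wild type).
#' @param tolerated_terminal_nonsense Number of C-terminal residues at which
#'   truncations are functionally tolerated (true fitness 1 instead of 0).
#' @param rng_seed Integer seed; all generator randomness derives from it.
#' @param isoform Isoform label attached to emitted tables.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(protein_length = 361L,
                              wt_sequence = NULL,
                              mean_aa_changes_per_clone = 1.7,
                              n_regions = 2L,
                              n_tiles_per_region = 5L,
                              n_replicates = 2L,
                              n_control_replicates = 2L,
                              reads_per_tile = 200000L,
                              generations = 3,
                              growth_rate = 1,
                              sequencing_error_rate = 5e-6,
                              sigma_log = 0.5,
                              frac_deleterious = 0.35,
                              frac_hyper = 0.025,
                              tolerated_terminal_nonsense = 14L,
                              rng_seed = 42L,
                              isoform = "ubiquitous") {
  cfg <- list(
    protein_length = as.integer(protein_length),
    wt_sequence = wt_sequence,
    mean_aa_changes_per_clone = mean_aa_changes_per_clone,
    n_regions = as.integer(n_regions),
    n_tiles_per_region = as.integer(n_tiles_per_region),
    n_replicates = as.integer(n_replicates),
    n_control_replicates = as.integer(n_control_replicates),
    reads_per_tile = as.integer(reads_per_tile),
    generations = generations,
    growth_rate = growth_rate,
    sequencing_error_rate = sequencing_error_rate,
    sigma_log = sigma_log,
    frac_deleterious = frac_deleterious,
    frac_hyper = frac_hyper,
    tolerated_terminal_nonsense = as.integer(tolerated_terminal_nonsense),
    rng_seed = as.integer(rng_seed),
    isoform = isoform
  )
  stopifnot(
    cfg$protein_length > 0, cfg$n_regions > 0, cfg$n_tiles_per_region > 0,
    cfg$n_replicates > 0, cfg$n_control_replicates > 0, cfg$reads_per_tile > 0,
    cfg$mean_aa_changes_per_clone >= 0, cfg$generations >= 0,
    cfg$sequencing_error_rate >= 0, cfg$sigma_log >= 0
  )
  if (cfg$frac_deleterious < 0 || cfg$frac_deleterious > 1 ||
      cfg$frac_hyper < 0 || cfg$frac_hyper > 1 ||
      cfg$frac_deleterious + cfg$frac_hyper > 1) {
    stop("fitness-class fractions must lie in [0,1] and sum to at most 1")
  }
  if (is.null(cfg$wt_sequence)) {
    cfg$wt_sequence <- with_stream(cfg$rng_seed, "wt_sequence", {
      c("M", sample(AA_ALPHABET, cfg$protein_length - 1L, replace = TRUE))
    })
  }
  if (length(cfg$wt_sequence) != cfg$protein_length) {
    stop("wt_sequence length must equal protein_length")
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Deterministic derived seeds: one RNG stream per named stage (and per
# region/replicate/condition for sequencing), keyed off rng_seed. Keeps all
# derived seeds below 2^31.
stream_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- (seed %% 32749) + 1
  for (k in codes) {
    h <- (h * 131 + k) %% 2147483629
  }
  as.integer(h)
}

with_stream <- function(seed, key, expr) {
  set.seed(stream_seed(seed, key))
  expr
}

region_breaks <- function(L, n_regions) {
  sizes <- rep(L %/% n_regions, n_regions)
  extra <- L %% n_regions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Assign protein positions to regions and tiles
#'
#' Positions 1..L are split into `n_regions` contiguous near-equal regions,
#' each subdivided into `n_tiles_per_region` contiguous tiles. Tile labels
#' have the form `"R<region>T<tile>"`.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `position`, `region`, `tile`.
#' @export
position_layout <- function(config) {
  L <- config$protein_length
  rsizes <- region_breaks(L, config$n_regions)
  region <- rep(seq_len(config$n_regions), rsizes)
  tile <- character(L)
  start <- 1L
  for (r in seq_len(config$n_regions)) {
    tsizes <- region_breaks(rsizes[r], config$n_tiles_per_region)
    tidx <- rep(seq_len(config$n_tiles_per_region), tsizes)
    tile[start:(start + rsizes[r] - 1L)] <- paste0("R", r, "T", tidx)
    start <- start + rsizes[r]
  }
  data.frame(position = seq_len(L), region = paste0("R", region), tile = tile,
             stringsAsFactors = FALSE)
}

#' Enumerate all single-amino-acid variants of a protein
#'
#' For each position: 19 missense substitutions, one synonymous marker
#' (`"="`) and one nonsense (`"*"`).
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `variant`, `position`, `ref`, `alt`,
#'   `class`, `region`, `tile`.
#' @export
enumerate_variants <- function(config) {
  L <- config$protein_length
  wt <- config$wt_sequence
  layout <- position_layout(config)
  per_pos <- lapply(seq_len(L), function(p) {
    alts <- c(setdiff(AA_ALPHABET, wt[p]), "=", "*")
    data.frame(position = p, ref = wt[p], alt = alts, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_pos)
  tab$variant <- format_variant(tab$position, tab$ref, tab$alt)
  tab$class <- variant_class(tab$alt)
  tab <- merge(tab, layout, by = "position", sort = FALSE)
  tab[order(tab$position, tab$alt), c("variant", "position", "ref", "alt",
                                      "class", "region", "tile")]
}

#' Draw ground-truth fitness for a variant table
#'
#' Missense fitness is drawn from a bimodal mixture: with probability
#' `frac_hyper` a hyper-complementing value above 1, with probability
#' `frac_deleterious` a null-like value near 0, otherwise a wild-type-like
#' value at or below 1 (so `w > 1` identifies exactly the hyper class).
#' Synonymous variants have `w = 1` exactly; nonsense variants have `w = 0`
#' except within the tolerated C-terminal window, where truncation does not
#' abolish function.
#'
#' @param config A [simulation_config()].
#' @param variants Variant table from [enumerate_variants()]; enumerated from
#'   `config` when `NULL`.
#' @return The variant table with a true-fitness column `w` appended.
#' @export
draw_true_fitness <- function(config, variants = NULL) {
  if (is.null(variants)) variants <- enumerate_variants(config)
  n <- nrow(variants)
  w <- numeric(n)
  with_stream(config$rng_seed, "truth", {
    mis <- variants$class == "missense"
    n_mis <- sum(mis)
    u <- runif(n_mis)
    w_mis <- pmax(1 - abs(rnorm(n_mis, 0, 0.05)), 0.6)     # wild-type-like
    del <- u < config$frac_deleterious
    w_mis[del] <- abs(rnorm(sum(del), 0, 0.03))            # null-like
    hyp <- u >= config$frac_deleterious &
           u < config$frac_deleterious + config$frac_hyper
    w_mis[hyp] <- 1 + rgamma(sum(hyp), shape = 2, scale = 0.15)
    w[mis] <- w_mis
  })
  w[variants$class == "synonymous"] <- 1
  non <- variants$class == "nonsense"
  tolerated <- variants$position >
    config$protein_length - config$tolerated_terminal_nonsense
  w[non] <- ifelse(tolerated[non], 1, 0)
  variants$w <- w
  variants
}

#' Simulate pre-selection marginal library frequencies
#'
#' Each position within a mutagenized region is altered with probability
#' `mean_aa_changes_per_clone / region_length`, so the expected number of
#' amino-acid changes per clone matches the configured mean. Within a
#' position, the altered fraction is shared among the 21 possible changes in
#' proportion to log-normal abundance weights, giving the heavy-tailed
#' representation typical of oligo-directed mutagenesis. Frequencies within
#' any tile sum to less than 1; the remainder is wild-type at that tile.
#'
#' @param config A [simulation_config()].
#' @param truth Ground-truth table from [draw_true_fitness()].
#' @return `truth` with a pre-selection frequency column `freq` appended.
#' @export
simulate_library_frequencies <- function(config, truth) {
  rsizes <- region_breaks(config$protein_length, config$n_regions)
  names(rsizes) <- paste0("R", seq_along(rsizes))
  q_pos <- config$mean_aa_changes_per_clone / rsizes[truth$region]
  with_stream(config$rng_seed, "library", {
    wgt <- stats::rlnorm(nrow(truth), meanlog = 0, sdlog = config$sigma_log)
    tot <- tapply(wgt, truth$position, sum)
    truth$freq <- as.numeric(q_pos * wgt / tot[as.character(truth$position)])
  })
  if (config$mean_aa_changes_per_clone == 0) truth$freq <- 0
  truth
}

#' Simulate competitive selection
#'
#' Post-selection frequencies are proportional to
#' `pre * g(w)^generations` with growth map `g(w) = exp(r (w - 1))`,
#' renormalized within each pool together with the wild-type remainder
#' (which grows with `g(1) = 1`).
#'
#' @param pre_freqs Pre-selection marginal frequencies.
#' @param fitness True fitness values `w`, parallel to `pre_freqs`.
#' @param generations Number of growth generations (>= 0).
#' @param growth_rate Selection strength `r`.
#' @param pool Optional pool assignment (e.g. tile labels); frequencies are
#'   renormalized within each pool. A single pool is assumed when `NULL`.
#' @return Post-selection frequencies, same length and order as `pre_freqs`.
#' @export
simulate_selection <- function(pre_freqs, fitness, generations,
                               growth_rate = 1, pool = NULL) {
  stopifnot(generations >= 0, all(pre_freqs >= 0))
  if (is.null(pool)) pool <- rep("all", length(pre_freqs))
  growth <- exp(growth_rate * (fitness - 1) * generations)
  post <- numeric(length(pre_freqs))
  for (p in unique(pool)) {
    idx <- pool == p
    wt_rem <- 1 - sum(pre_freqs[idx])
    if (wt_rem < 0) stop("pre-selection frequencies in pool ", p, " exceed 1")
    z <- sum(pre_freqs[idx] * growth[idx]) + wt_rem
    post[idx] <- pre_freqs[idx] * growth[idx] / z
  }
  post
}

# Multinomial tile counts plus a shared additive error process. Spurious
# counts are moved from the wild-type read mass so each tile's total stays
# exactly at reads_per_tile.
draw_tile_counts <- function(freqs, reads, error_rate) {
  k <- length(freqs)
  wt_rem <- max(0, 1 - sum(freqs))
  counts <- as.integer(rmultinom(1, reads, c(freqs, wt_rem))[seq_len(k)])
  spurious <- rpois(k, error_rate * reads)
  counts + as.integer(spurious)
}

#' Simulate tile sequencing of a variant pool
#'
#' Counts are drawn multinomially per tile at `reads_per_tile` depth; an
#' additive Poisson error process contributes spurious counts drawn from the
#' same distribution for the mutant pool and for the wild-type-control
#' template, so the expected control frequency equals the error floor.
#'
#' @param freqs Data frame with columns `variant`, `tile` and `freq` (true
#'   pool frequencies for one condition).
#' @param config A [simulation_config()].
#' @param condition `"nonselect"` or `"select"`.
#' @param replicate Replicate index (used for labeling and RNG streams).
#' @return List with `counts` (pool count records) and `control`
#'   (wild-type-control count records, one per control replicate), both in
#'   the [read_count_table()] schema.
#' @export
simulate_sequencing <- function(freqs, config, condition, replicate = 1L) {
  condition <- match.arg(condition, c("nonselect", "select"))
  reads <- config$reads_per_tile
  err <- config$sequencing_error_rate
  pool_rows <- list()
  ctrl_rows <- list()
  for (tl in unique(freqs$tile)) {
    idx <- freqs$tile == tl
    key <- paste("seq", tl, replicate, condition, sep = ":")
    counts <- with_stream(config$rng_seed, key, {
      draw_tile_counts(freqs$freq[idx], reads, err)
    })
    pool_rows[[tl]] <- data.frame(
      variant = freqs$variant[idx], tile = tl, condition = condition,
      replicate = as.integer(replicate), count = pmin(counts, reads),
      depth = reads, stringsAsFactors = FALSE
    )
    ctrl_list <- lapply(seq_len(config$n_control_replicates), function(cr) {
      ckey <- paste("ctrl", tl, cr, condition, sep = ":")
      ccounts <- with_stream(config$rng_seed, ckey, {
        rpois(sum(idx), err * reads)
      })
      data.frame(
        variant = freqs$variant[idx], tile = tl, condition = condition,
        replicate = as.integer(cr), count = as.integer(ccounts), depth = reads,
        stringsAsFactors = FALSE
      )
    })
    ctrl_rows[[tl]] <- do.call(rbind, ctrl_list)
  }
  list(counts = do.call(rbind, pool_rows), control = do.call(rbind, ctrl_rows))
}

#' Simulate a complete TileSeq experiment
#'
#' Runs the generator end to end for one isoform: ground truth, library
#' frequencies, competitive selection, and tile sequencing of the nonselect
#' and select pools for each replicate plus wild-type controls.
#'
#' @param config A [simulation_config()].
#' @param truth Optional pre-drawn ground-truth table (used to share truth
#'   between isoforms); drawn from `config` when `NULL`.
#' @return List of class `"tileseq_simulation"` with elements `config`,
#'   `truth` (including pre-selection `freq`), `counts` and `controls`.
#' @export
simulate_tileseq <- function(config = simulation_config(), truth = NULL) {
  if (is.null(truth)) truth <- draw_true_fitness(config)
  lib <- simulate_library_frequencies(config, truth)
  post <- simulate_selection(lib$freq, lib$w, config$generations,
                             config$growth_rate, pool = lib$tile)
  counts <- list()
  controls <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    ns <- simulate_sequencing(
      data.frame(variant = lib$variant, tile = lib$tile, freq = lib$freq),
      config, "nonselect", rep_i)
    sel <- simulate_sequencing(
      data.frame(variant = lib$variant, tile = lib$tile, freq = post),
      config, "select", rep_i)
    counts[[rep_i]] <- rbind(ns$counts, sel$counts)
    if (rep_i == 1L) controls <- list(ns$control, sel$control)
  }
  out <- list(
    config = config,
    truth = lib,
    counts = do.call(rbind, counts),
    controls = do.call(rbind, controls)
  )
  rownames(out$counts) <- NULL
  rownames(out$controls) <- NULL
  class(out) <- "tileseq_simulation"
  out
}

#' Simulate a matched isoform pair
#'
#' Simulates the ubiquitous isoform from `config` and an erythroid isoform
#' lacking the first 17 residues. The two isoforms share ground-truth
#' fitness at corresponding residues (the erythroid truth is the ubiquitous
#' truth restricted to positions 18..L and renumbered), but have
#' independently drawn libraries and sequencing noise.
#'
#' @param config A [simulation_config()] for the ubiquitous isoform.
#' @return List with elements `ubiquitous` and `erythroid`, each a
#'   `"tileseq_simulation"`. Erythroid tables are in erythroid-local
#'   coordinates.
#' @export
simulate_isoform_pair <- function(config = simulation_config()) {
  ubi <- simulate_tileseq(config)
  L_e <- config$protein_length - ISOFORM_OFFSET
  cfg_e <- simulation_config(
    protein_length = L_e,
    wt_sequence = config$wt_sequence[(ISOFORM_OFFSET + 1L):config$protein_length],
    mean_aa_changes_per_clone = config$mean_aa_changes_per_clone,
    n_regions = config$n_regions,
    n_tiles_per_region = config$n_tiles_per_region,
    n_replicates = config$n_replicates,
    n_control_replicates = config$n_control_replicates,
    reads_per_tile = config$reads_per_tile,
    generations = config$generations,
    growth_rate = config$growth_rate,
    sequencing_error_rate = config$sequencing_error_rate,
    sigma_log = config$sigma_log,
    frac_deleterious = config$frac_deleterious,
    frac_hyper = config$frac_hyper,
    tolerated_terminal_nonsense = config$tolerated_terminal_nonsense,
    rng_seed = stream_seed(config$rng_seed, "erythroid") %% 2000000000L,
    isoform = "erythroid"
  )
  # shared truth: ubiquitous positions 18..L renumbered to 1..L-17
  truth_u <- draw_true_fitness(config)
  keep <- truth_u$position > ISOFORM_OFFSET
  truth_e <- truth_u[keep, ]
  truth_e$position <- truth_e$position - ISOFORM_OFFSET
  truth_e$variant <- format_variant(truth_e$position, truth_e$ref, truth_e$alt)
  layout_e <- position_layout(cfg_e)
  truth_e$region <- layout_e$region[truth_e$position]
  truth_e$tile <- layout_e$tile[truth_e$position]
  rownames(truth_e) <- NULL
  ery <- simulate_tileseq(cfg_e, truth = truth_e)
  list(ubiquitous = ubi, erythroid = ery)
}
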