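# Simulation-backed experiments: self-contained study designs used to
# validate calibration and parameter recovery of the analysis modules.

#' Simulated ABBA-BABA calibration/power experiment
#'
#' Runs replicate coalescent simulations of a 4-population tree
#' (((P1,P2),P3),O) in a rapid-radiation regime (splits at 10k / 30k / 150k
#' generations, Ne 10,000, 400 windows of 10 kb at mu = 1e-7, two diploids
#' per population) and computes Patterson's D with one jackknife block per
#' window from the true genotypes. With `f = 0` this checks null calibration
#' of |Z| < 3; with a pulse fraction `f > 0` (P3 -> P2 at 2,500 generations)
#' it checks power.
#'
#' @param n_reps number of replicates.
#' @param f pulse admixture fraction P3 -> P2 (0 = null).
#' @param seed integer master seed.
#' @param n_windows,window_length,mu simulation scale overrides.
#' @return data.frame with one row per replicate: D, Z, n_informative.
#' @export
simulate_dstat_experiment <- function(n_reps = 100, f = 0, seed = 1L,
                                      n_windows = 400, window_length = 10000,
                                      mu = 1e-7) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pulses <- if (f > 0) data.frame(source = "P3", target = "P2",
                                    time = 2500, f = f) else NULL
    cfg <- species_tree_config(
      labels = c("P1", "P2", "P3", "O"),
      merges = data.frame(time = c(10000, 30000, 150000),
                          child = c("P2", "P3", "O"),
                          parent = c("P1", "P1", "P1")),
      ne = c(P1 = 10000, P2 = 10000, P3 = 10000, O = 10000),
      samples = c(P1 = 2, P2 = 2, P3 = 2, O = 2),
      pulses = pulses, mu = mu, window_length = window_length,
      n_windows = n_windows, seed = subseed(seed, 20L, r))
    gen <- simulate_genealogies(cfg)
    truth <- truth_set(gen)
    dosage <- do.call(rbind, lapply(truth$genotypes, t))   # site x ind
    colnames(dosage) <- gen$sheet$individuals
    blk <- rep(seq_along(truth$genotypes),
               vapply(truth$genotypes, ncol, numeric(1)))
    pm <- stats::setNames(gen$sheet$ind_pop, gen$sheet$individuals)
    sets <- lapply(c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"),
                   function(p) names(pm)[pm == p])
    freqs <- cbind(P1 = pop_allele_freqs(dosage, sets$P1),
                   P2 = pop_allele_freqs(dosage, sets$P2),
                   P3 = pop_allele_freqs(dosage, sets$P3),
                   O = pop_allele_freqs(dosage, sets$O))
    pol <- polarize_freqs(freqs, "O")
    ds <- d_statistic(pol[, "P1"], pol[, "P2"], pol[, "P3"], pol[, "O"])
    jk <- block_jackknife(ds$abba, ds$baba, blk[attr(pol, "kept")][ds$kept])
    out[[r]] <- data.frame(rep = r, D = jk$D, Z = jk$Z,
                           n_informative = ds$n_informative)
  }
  do.call(rbind, out)
}

#' Divergence-dating recovery experiment
#'
#' Simulates two populations (4 diploids each, Ne 500) that split a known
#' number of generations ago at the flycatcher mutation rate, sequences them
#' to 30x with phred-30 errors, runs the full calling -> consensus ->
#' p-distance -> divergence-dating chain, and reports the mean between- and
#' within-population divergence-time estimates. The error budget drives the
#' design: the ancestral coalescent adds ~2 Ne generations (+2% at Ne 500),
#' and with ~2,000 informative mutations on the cross-population paths
#' (100 windows x 40 kb at mu = 4.6e-9) the Poisson noise is ~2.3%, so the
#' estimate sits several standard errors inside a 10% recovery band.
#'
#' @param seed integer seed.
#' @param split true split time in generations (default 50000).
#' @param n_windows number of windows (default 100).
#' @param window_length window length in bp (default 40000).
#' @param ne diploid effective size per population (default 500).
#' @param depth,qual sequencing depth and phred quality.
#' @param mu mutation rate (default 4.6e-9).
#' @return list with `t_between` (mean between-population estimate),
#'   `t_within` (mean within-population estimate), `split`, and the full
#'   generation matrix.
#' @export
simulate_divergence_experiment <- function(seed = 1L, split = 50000,
                                           n_windows = 100,
                                           window_length = 40000, ne = 500,
                                           depth = 30, qual = 30,
                                           mu = 4.6e-9) {
  cfg <- species_tree_config(
    labels = c("A", "B"),
    merges = data.frame(time = split, child = "B", parent = "A"),
    ne = c(A = ne, B = ne), samples = c(A = 4, B = 4),
    mu = mu, window_length = window_length, n_windows = n_windows, seed = seed)
  gen <- simulate_genealogies(cfg)
  panel <- mutate_sequences(gen)
  piles <- generate_pileups(panel, depth = depth, qual = qual,
                            depth_track = TRUE)
  st <- filter_sites(call_snps(piles))
  dosage <- hard_call(st)
  keep <- !st$sites$flag_triallelic      # consensus keeps low-MAF variants
  ref <- stats::setNames(lapply(panel$windows, function(w) w$ancestral),
                         panel$contigs)
  tracks <- stats::setNames(piles$depth_tracks, panel$contigs)
  cons <- build_consensus(ref, st$sites[keep, , drop = FALSE],
                          dosage[keep, , drop = FALSE], tracks)
  concat <- concatenate_windows(consensus_windows(cons))
  gens <- divergence_generations(p_distance(concat),
                                 divergence_config(mu = mu))
  pops <- stats::setNames(gen$sheet$ind_pop, gen$sheet$individuals)
  a <- names(pops)[pops == "A"]; b <- names(pops)[pops == "B"]
  list(t_between = mean(gens[a, b]),
       t_within = mean(c(gens[a, a][upper.tri(gens[a, a])],
                         gens[b, b][upper.tri(gens[b, b])])),
       split = split, generations = gens)
}

#' Topology-weighting experiments on simulated regimes
#'
#' Simulates the five-taxon study design (MEL, TRA, ROB in-group; ARD + NIG
#' as the outgroup clade), builds per-window NJ trees from IUPAC consensus
#' p-distances of the true genotypes, and returns the genome-wide topology
#' weight summary. Two regimes matter: `deep` (splits much older than Ne, so
#' the species topology should carry nearly all weight) and `radiation` (the
#' two in-group splits one generation apart, so incomplete lineage sorting
#' makes the three in-group topologies equally frequent).
#'
#' @param regime "deep" or "radiation".
#' @param n_windows windows to simulate (default 40 deep / 300 radiation).
#' @param seed integer seed.
#' @return list with `summary` (from [weight_summary()]), `weights`, and
#'   `species_topology` (the canonical label of the simulated species tree).
#' @export
simulate_topology_experiment <- function(regime = c("deep", "radiation"),
                                         n_windows = NULL, seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(n_windows)) n_windows <- if (regime == "deep") 40 else 300
  if (regime == "deep") {
    merges <- data.frame(time = c(60000, 120000, 100000, 400000),
                         child = c("TRA", "ROB", "NIG", "ARD"),
                         parent = c("MEL", "MEL", "ARD", "MEL"))
    ne <- stats::setNames(rep(1000, 5), c("MEL", "TRA", "ROB", "ARD", "NIG"))
  } else {
    merges <- data.frame(time = c(40000, 40001, 100000, 400000),
                         child = c("TRA", "ROB", "NIG", "ARD"),
                         parent = c("MEL", "MEL", "ARD", "MEL"))
    ne <- stats::setNames(rep(20000, 5), c("MEL", "TRA", "ROB", "ARD", "NIG"))
  }
  cfg <- species_tree_config(
    merges = merges, ne = ne,
    samples = c(MEL = 2, TRA = 2, ROB = 2, ARD = 1, NIG = 1),
    mu = 2.5e-8, window_length = 10000, n_windows = n_windows, seed = seed)
  gen <- simulate_genealogies(cfg)
  truth <- truth_set(gen)
  groups <- stats::setNames(ifelse(gen$sheet$ind_pop %in% c("ARD", "NIG"),
                                   "OUT", gen$sheet$ind_pop),
                            gen$sheet$individuals)
  weights <- list()
  for (w in seq_along(gen$windows)) {
    seqs <- truth_consensus(truth, panel_window = w, gen = gen)
    dm <- tryCatch(p_distance(seqs), error = function(e) NULL)
    if (is.null(dm) || anyNA(dm$d)) next
    phy <- nj_tree(dm)
    weights[[length(weights) + 1L]] <-
      topology_weights(phy, groups, "OUT", seed = subseed(seed, 7L, w))
  }
  list(summary = weight_summary(weights), weights = weights,
       species_topology = "(((MEL,TRA),ROB),OUT)")
}

# IUPAC consensus of the true genotypes for one window (no sequencing noise);
# used by tree-based experiments where calling noise is not under test.
truth_consensus <- function(truth, panel_window, gen) {
  win <- gen$windows[[panel_window]]
  L <- gen$config$window_length
  set.seed(subseed(gen$config$seed, 2L, panel_window))
  anc <- sample(BASES, L, replace = TRUE)
  # the same ancestral draw and derived-base scheme as mutate_sequences
  base_raw <- charToRaw(paste(BASES, collapse = ""))
  anc_idx <- match(anc[win$pos], BASES)
  shift <- sample.int(3, length(win$pos), replace = TRUE)
  der <- BASES[(anc_idx - 1L + shift) %% 4L + 1L]
  g <- truth$genotypes[[panel_window]]
  out <- vapply(rownames(g), function(ind) {
    s <- anc
    gi <- g[ind, ]
    if (length(win$pos)) {
      s[win$pos[gi == 2L]] <- der[gi == 2L]
      het <- gi == 1L
      if (any(het)) s[win$pos[het]] <- iupac_het(anc[win$pos[het]], der[het])
    }
    paste(s, collapse = "")
  }, character(1))
  out
}

#' Damage-profile recovery experiment
#'
#' Injects a known deamination curve (defaults d5 = d3 = 0.3, lambda = 0.5)
#' into simulated fragments and re-estimates it with
#' [estimate_damage_profile()], returning injected and recovered curves at
#' offsets 0..`max_offset`.
#'
#' @param seed integer seed.
#' @param d5,d3,lambda injected damage parameters.
#' @param coverage haploid fragment coverage (default 25, about 1e5 bases
#'   per offset at the defaults).
#' @param max_offset largest offset compared (default 5).
#' @return data.frame with offset, injected, recovered_ct5, recovered_ga3,
#'   and denominators.
#' @export
simulate_damage_experiment <- function(seed = 1L, d5 = 0.3, d3 = 0.3,
                                       lambda = 0.5, coverage = 25,
                                       max_offset = 5) {
  cfg <- species_tree_config(labels = "POP",
                             merges = NULL,
                             ne = c(POP = 1000), samples = c(POP = 2),
                             mu = 1e-8, window_length = 20000,
                             n_windows = 10, seed = seed)
  gen <- simulate_genealogies(cfg)
  panel <- mutate_sequences(gen)
  dm <- damage_model(d5 = d5, d3 = d3, lambda = lambda)
  reads <- fragment_and_damage(panel, dm, coverage = coverage)
  prof <- estimate_damage_profile(reads, max_offset = max_offset)
  data.frame(offset = prof$offset,
             injected_ct5 = d5 * lambda^prof$offset,
             injected_ga3 = d3 * lambda^prof$offset,
             recovered_ct5 = prof$ct5, recovered_ga3 = prof$ga3,
             n_c5 = prof$n_c5, n_g3 = prof$n_g3)
}

#' Population-structure recovery experiment
#'
#' Simulates the study's five-taxon sampling (6 MEL, 5 TRA, 3 ROB, 1 ARD,
#' 1 NIG) as a rapid four-way radiation: MEL, TRA, ROB and the island clade
#' split 45,000-62,000 generations ago with Ne 20,000 (substantial
#' incomplete lineage sorting, so the three-cluster models are genuinely
#' ambiguous), and the island pair ARD+NIG is joined by a very shallow
#' 3,000-generation split so it forms one cluster. The depths are chosen so
#' each successive real cluster contributes a comparable likelihood gain,
#' giving the Evanno statistic the sharp knee at K = 4 it is designed to
#' detect. Sequencing, calling and filtering run through the full chain,
#' then replicate admixture EM across K, the DeltaK choice and a PCA.
#'
#' @param seed integer seed.
#' @param n_windows simulated windows (default 40).
#' @param K_range K values (default 1:6).
#' @param reps replicates per K (default 15).
#' @param depth,qual sequencing depth and quality.
#' @param max_sites deterministic subsample cap on passing SNPs (default
#'   1500; enough sites to separate the clusters while keeping replicate EM
#'   runs fast).
#' @param max_iter EM iteration cap per run (default 700; past the point
#'   where between-K likelihood differences dwarf any remaining gain).
#' @return list with `delta_k` table (attribute `best_k`), `replicates`,
#'   `best_q4` (best K = 4 Q matrix), `pop_map`, `pca`, `site_table`.
#' @export
simulate_structure_experiment <- function(seed = 1L, n_windows = 40,
                                          K_range = 1:6, reps = 15,
                                          depth = 20, qual = 30,
                                          max_sites = 1500, max_iter = 700) {
  cfg <- species_tree_config(
    merges = data.frame(time = c(45000, 48000, 3000, 62000),
                        child = c("TRA", "ROB", "NIG", "ARD"),
                        parent = c("MEL", "MEL", "ARD", "MEL")),
    ne = stats::setNames(rep(20000, 5), c("MEL", "TRA", "ROB", "ARD", "NIG")),
    samples = c(MEL = 6, TRA = 5, ROB = 3, ARD = 1, NIG = 1),
    mu = 2e-8, window_length = 10000, n_windows = n_windows, seed = seed)
  gen <- simulate_genealogies(cfg)
  panel <- mutate_sequences(gen)
  piles <- generate_pileups(panel, depth = depth, qual = qual)
  st <- passing_sites(filter_sites(call_snps(piles)))
  n_all <- nrow(st$sites)
  take <- function(idx) {
    s <- st
    s$sites <- s$sites[idx, , drop = FALSE]
    s$gl <- s$gl[idx, , , drop = FALSE]
    s$depth <- s$depth[idx, , drop = FALSE]
    s
  }
  # each replicate analyses its own random draw of max_sites SNPs, shared
  # across all K within the replicate: the center-seeded EM is effectively
  # deterministic per data set, so the replicate scatter that Evanno's
  # denominator needs comes from honest data resampling, at a comparable
  # scale for every K
  n_sub <- min(max_sites, n_all)
  rows <- list(); best <- list()
  for (r in seq_len(reps)) {
    set.seed(subseed(seed, 50L, r))
    st_r <- take(sort(sample.int(n_all, n_sub)))
    for (K in K_range) {
      s_em <- subseed(seed, 10L + K, r)
      m <- admixture_em(st_r, K, seed = s_em, max_iter = max_iter)
      rows[[length(rows) + 1L]] <- data.frame(K = K, rep = r, seed = s_em,
                                              loglik = m$loglik)
      kk <- as.character(K)
      if (is.null(best[[kk]]) || m$loglik > best[[kk]]$loglik) best[[kk]] <- m
    }
  }
  reps_out <- structure(list(table = do.call(rbind, rows), best = best),
                        class = "admixture_replicates")
  dk <- delta_k(reps_out)
  ed <- expected_genotypes(st)
  pca <- gl_pca(ed, freq = st$sites$f_minor)
  list(delta_k = dk, replicates = reps_out,
       best_q4 = reps_out$best[["4"]]$Q,
       pop_map = stats::setNames(gen$sheet$ind_pop, gen$sheet$individuals),
       pca = pca, site_table = st)
}
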