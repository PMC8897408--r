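# Synthetic museomics data: structured coalescent on a species tree, Jukes-Cantor
# mutations, log-normal fragmenting with terminal deamination damage, and
# Poisson-depth pileups. Every downstream module has parameter-recovery tests
# against the truth objects produced here.

BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-seed
#'
#' Expands one global seed into per-stage, per-unit seeds by a fixed affine
#' scheme, keeping every derived seed a valid 32-bit integer.
#'
#' @param seed integer global seed.
#' @param stage integer stage code (each simulation/analysis stage uses its own).
#' @param k integer unit index (e.g. window number), default 0.
#' @return a single integer seed.
#' @export
subseed <- function(seed, stage, k = 0L) {
  # multiplicative mixing keeps nested derivations (seed -> rep -> window)
  # collision-free; all intermediates stay below 2^53 so arithmetic is exact
  x <- (abs(as.numeric(seed)) %% 2147483647) * 69069 +
    as.numeric(stage) * 1000003 + as.numeric(k) * 7919
  as.integer(x %% 2147483646 + 1)
}

#' Species-tree configuration for the coalescent simulator
#'
#' Describes the demography the simulator emulates: by default five oriole
#' taxa (MEL, TRA, ROB, ARD, NIG) on the rooted topology
#' `(((MEL,TRA),ROB),(ARD,NIG))`, splits on the order of 1e5 generations, a
#' flycatcher-calibrated mutation rate of 4.6e-9 per site per generation, and
#' the study's sampling design (6 MEL, 5 TRA, 3 ROB, 1 NIG, 1 ARD diploids).
#'
#' Population merges are specified backward in time: at `time`, all lineages
#' of `child` move into `parent` (the parent label keeps its effective size).
#' Admixture pulses are forward-time statements "fraction `f` of `target` came
#' from `source` at `time`"; backward in time each `target` lineage jumps to
#' `source` with probability `f`.
#'
#' @param labels population labels.
#' @param merges data.frame with columns `time`, `child`, `parent` (backward-time
#'   population merges; generations).
#' @param ne named vector of diploid effective sizes per population.
#' @param samples named integer vector of diploid samples per population.
#' @param pulses data.frame with columns `source`, `target`, `time`, `f`
#'   (forward-time pulse admixture), or NULL.
#' @param mu per-site per-generation mutation rate.
#' @param window_length window length in bp.
#' @param n_windows number of independent windows.
#' @param seed integer seed.
#' @return an object of class `species_tree_config`.
#' @export
species_tree_config <- function(labels = c("MEL", "TRA", "ROB", "ARD", "NIG"),
                                merges = data.frame(
                                  time = c(127000, 224000, 250000, 500000),
                                  child = c("TRA", "ROB", "NIG", "ARD"),
                                  parent = c("MEL", "MEL", "ARD", "MEL"),
                                  stringsAsFactors = FALSE),
                                ne = stats::setNames(rep(50000, length(labels)), labels),
                                samples = stats::setNames(c(6, 5, 3, 1, 1)[seq_along(labels)], labels),
                                pulses = NULL,
                                mu = 4.6e-9,
                                window_length = 10000,
                                n_windows = 10,
                                seed = 1L) {
  stopifnot(length(labels) >= 1, !anyDuplicated(labels))
  if (mu <= 0) stop("mu must be > 0")
  if (window_length < 1 || n_windows < 1) stop("window_length and n_windows must be >= 1")
  if (!all(labels %in% names(ne)) || any(ne[labels] <= 0)) {
    stop("ne must name every population with a positive size")
  }
  if (!all(names(samples) %in% labels) || any(samples < 0)) {
    stop("samples must map populations to non-negative diploid counts")
  }
  if (length(labels) > 1) {
    if (is.null(merges) || nrow(merges) != length(labels) - 1) {
      stop("merges must contain exactly n_populations - 1 rows")
    }
    merges <- merges[order(merges$time), , drop = FALSE]
    if (any(merges$time <= 0)) stop("split times must be strictly positive")
    alive <- labels
    for (i in seq_len(nrow(merges))) {
      ch <- merges$child[i]; pa <- merges$parent[i]
      if (!(ch %in% alive)) {
        stop(sprintf("inconsistent split times: population '%s' merges at %g after it was already merged",
                     ch, merges$time[i]))
      }
      if (!(pa %in% alive)) {
        stop(sprintf("inconsistent split times: parent '%s' of child '%s' is already merged at time %g",
                     pa, ch, merges$time[i]))
      }
      alive <- setdiff(alive, ch)
    }
    if (length(alive) != 1) stop("merges must reduce the populations to a single root")
  } else {
    merges <- data.frame(time = numeric(0), child = character(0), parent = character(0))
  }
  if (!is.null(pulses) && nrow(pulses)) {
    if (any(pulses$f < 0 | pulses$f > 1)) stop("pulse fraction f must lie in [0,1]")
    if (any(pulses$time <= 0)) stop("pulse times must be positive")
    if (!all(c(pulses$source, pulses$target) %in% labels)) stop("pulse populations must be in labels")
  } else {
    pulses <- data.frame(source = character(0), target = character(0),
                         time = numeric(0), f = numeric(0))
  }
  structure(list(labels = labels, merges = merges, ne = ne[labels],
                 samples = samples, pulses = pulses, mu = mu,
                 window_length = as.integer(window_length),
                 n_windows = as.integer(n_windows), seed = as.integer(seed)),
            class = "species_tree_config")
}

#' Post-mortem damage model
#'
#' Terminal deamination: a C at offset i from the 5' end of a fragment is read
#' as T with probability `d5 * lambda^i`; a G at offset i from the 3' end is
#' read as A with probability `d3 * lambda^i` (geometric decay, the standard
#' shape of post-mortem cytosine deamination). Fragment lengths are log-normal,
#' truncated to [20, window length]. Damage is a real base change in the
#' molecule; base qualities are untouched by it.
#'
#' @param d5 5' terminal C->T rate in [0,1].
#' @param d3 3' terminal G->A rate in [0,1].
#' @param lambda per-offset decay in (0,1].
#' @param frag_mean,frag_sd mean and sd of fragment length (bp).
#' @param qual phred base quality assigned to every sequenced base.
#' @return object of class `damage_model`.
#' @export
damage_model <- function(d5 = 0.3, d3 = 0.3, lambda = 0.5,
                         frag_mean = 80, frag_sd = 30, qual = 30) {
  if (any(c(d5, d3) < 0 | c(d5, d3) > 1)) stop("damage rates must lie in [0,1]")
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0,1]")
  if (frag_mean < 20) stop("fragment mean must be >= 20 bp")
  structure(list(d5 = d5, d3 = d3, lambda = lambda,
                 frag_mean = frag_mean, frag_sd = frag_sd, qual = qual),
            class = "damage_model")
}

# individual ids and haplotype->individual/population maps for a config
sim_sample_sheet <- function(config) {
  pops <- rep(config$labels, config$samples[config$labels])
  ind <- unlist(lapply(config$labels, function(p) {
    n <- config$samples[[p]]
    if (n == 0) character(0) else sprintf("%s_%d", p, seq_len(n))
  }))
  hap_ind <- rep(seq_along(ind), each = 2)
  list(individuals = ind, ind_pop = pops,
       hap_ind = hap_ind, hap_pop = pops[hap_ind],
       n_hap = 2L * length(ind))
}

# One-window structured coalescent. Returns edges (child time, parent time,
# tip set), the rooted genealogy as newick, and per-pulse migrant counts.
sim_window_genealogy <- function(config) {
  sheet <- sim_sample_sheet(config)
  n <- sheet$n_hap
  labels <- paste0(sheet$individuals[sheet$hap_ind], "_h", rep(1:2, length.out = n))
  n_pop <- length(config$labels)
  t_now <- 0
  # active lineages
  tipsets <- as.list(seq_len(n))
  nwk <- labels
  born <- numeric(n)
  lin_pop <- match(sheet$hap_pop, config$labels)
  ne <- unname(config$ne[config$labels])
  # demographic events, sorted by time (a/b are population indices)
  ev <- rbind(
    if (nrow(config$merges)) data.frame(time = config$merges$time, type = "merge",
                                        a = match(config$merges$child, config$labels),
                                        b = match(config$merges$parent, config$labels),
                                        f = NA_real_, stringsAsFactors = FALSE),
    if (nrow(config$pulses)) data.frame(time = config$pulses$time, type = "pulse",
                                        a = match(config$pulses$target, config$labels),
                                        b = match(config$pulses$source, config$labels),
                                        f = config$pulses$f, stringsAsFactors = FALSE))
  if (!is.null(ev)) ev <- ev[order(ev$time), , drop = FALSE]
  n_ev <- if (is.null(ev)) 0L else nrow(ev)
  ev_time <- ev$time; ev_type <- ev$type; ev_a <- ev$a; ev_b <- ev$b; ev_f <- ev$f
  ev_i <- 1L
  edges <- vector("list", 2 * n)
  n_edge <- 0L
  migrants <- if (nrow(config$pulses)) data.frame(config$pulses, n_target = 0L, n_moved = 0L) else NULL
  repeat {
    k <- length(tipsets)
    if (k <= 1 && ev_i > n_ev) break
    # per-population coalescence rates
    cnt <- tabulate(lin_pop, n_pop)
    rate_p <- cnt * (cnt - 1) / (4 * ne)
    total <- sum(rate_p)
    t_next_ev <- if (ev_i <= n_ev) ev_time[ev_i] else Inf
    wait <- if (total > 0) stats::rexp(1, total) else Inf
    if (t_now + wait < t_next_ev) {
      t_now <- t_now + wait
      p <- if (sum(rate_p > 0) == 1) which(rate_p > 0) else
        sample.int(n_pop, 1, prob = rate_p)
      idx <- which(lin_pop == p)
      pair <- if (length(idx) == 2) idx else sample(idx, 2)
      i1 <- pair[1]; i2 <- pair[2]
      # close the two child edges
      for (ii in pair) {
        n_edge <- n_edge + 1L
        edges[[n_edge]] <- list(len = t_now - born[ii], tips = tipsets[[ii]])
      }
      tipsets[[i1]] <- c(tipsets[[i1]], tipsets[[i2]])
      nwk[i1] <- sprintf("(%s:%g,%s:%g)", nwk[i1], t_now - born[i1], nwk[i2], t_now - born[i2])
      born[i1] <- t_now
      tipsets <- tipsets[-i2]; nwk <- nwk[-i2]; born <- born[-i2]; lin_pop <- lin_pop[-i2]
    } else {
      if (is.infinite(t_next_ev)) break
      t_now <- t_next_ev
      if (ev_type[ev_i] == "merge") {
        lin_pop[lin_pop == ev_a[ev_i]] <- ev_b[ev_i]
      } else {
        tgt <- which(lin_pop == ev_a[ev_i])
        moved <- tgt[stats::runif(length(tgt)) < ev_f[ev_i]]
        lin_pop[moved] <- ev_b[ev_i]
        if (!is.null(migrants)) {
          j <- which(migrants$time == ev_time[ev_i] &
                       migrants$target == config$labels[ev_a[ev_i]] &
                       migrants$source == config$labels[ev_b[ev_i]])[1]
          migrants$n_target[j] <- migrants$n_target[j] + length(tgt)
          migrants$n_moved[j] <- migrants$n_moved[j] + length(moved)
        }
      }
      ev_i <- ev_i + 1L
    }
  }
  edges <- edges[seq_len(n_edge)]
  list(edges = edges, newick = paste0(nwk[1], ";"), tmrca = t_now,
       labels = labels, migrants = migrants)
}

#' Simulate per-window genealogies and a segregating-site haplotype panel
#'
#' Runs an independent structured coalescent for each window (windows emulate
#' distant 10-kb slices of the genome, so there is no intra-window
#' recombination), then drops mutations on the genealogy at rate
#' `mu * window_length` per generation of total branch length. Derived states
#' are recorded per haplotype as a 0/1 matrix; each segregating site carries a
#' window-relative 1-based position.
#'
#' @param config a [species_tree_config()].
#' @return object of class `genealogy_set`: per-window genealogies (newick,
#'   TMRCA), the haplotype panel, sample sheet, and pulse-migration truth.
#' @export
simulate_genealogies <- function(config) {
  stopifnot(inherits(config, "species_tree_config"))
  sheet <- sim_sample_sheet(config)
  L <- config$window_length
  windows <- vector("list", config$n_windows)
  for (w in seq_len(config$n_windows)) {
    set.seed(subseed(config$seed, 1L, w))
    g <- sim_window_genealogy(config)
    lens <- vapply(g$edges, `[[`, numeric(1), "len")
    total_len <- sum(lens)
    n_mut <- stats::rpois(1, config$mu * total_len * L)
    n_mut <- min(n_mut, L)  # infinite-sites approximation on a finite window
    if (n_mut > 0) {
      pos <- sort(sample.int(L, n_mut))
      edge_of <- sample.int(length(lens), n_mut, replace = TRUE, prob = lens)
      derived <- matrix(0L, nrow = sheet$n_hap, ncol = n_mut)
      for (e in unique(edge_of)) {
        derived[g$edges[[e]]$tips, which(edge_of == e)] <- 1L
      }
      # drop sites where the mutation sits above the root-side MRCA (all derived)
      seg <- colSums(derived) < sheet$n_hap & colSums(derived) > 0
      pos <- pos[seg]; derived <- derived[, seg, drop = FALSE]
    } else {
      pos <- integer(0)
      derived <- matrix(0L, nrow = sheet$n_hap, ncol = 0)
    }
    rownames(derived) <- g$labels
    windows[[w]] <- list(newick = g$newick, tmrca = g$tmrca, pos = pos,
                         derived = derived, migrants = g$migrants)
  }
  structure(list(windows = windows, sheet = sheet, config = config,
                 contigs = sprintf("win%05d", seq_len(config$n_windows))),
            class = "genealogy_set")
}

#' Realize A/C/G/T sequences from a haplotype panel
#'
#' Draws an i.i.d. uniform ancestral base per position and converts derived
#' 0/1 states to bases under Jukes-Cantor (the derived base is a uniform draw
#' from the three alternatives). Returns full window-length sequences per
#' haplotype; two haplotypes whose TMRCA is T generations differ at
#' approximately `2 * mu * T` of positions.
#'
#' @param genealogies a `genealogy_set` from [simulate_genealogies()].
#' @return object of class `sequence_panel`: per window a raw character matrix
#'   (haplotype x position) plus the ancestral sequence.
#' @export
mutate_sequences <- function(genealogies) {
  stopifnot(inherits(genealogies, "genealogy_set"))
  config <- genealogies$config
  L <- config$window_length
  base_raw <- charToRaw(paste(BASES, collapse = ""))
  windows <- vector("list", length(genealogies$windows))
  for (w in seq_along(windows)) {
    set.seed(subseed(config$seed, 2L, w))
    win <- genealogies$windows[[w]]
    anc <- base_raw[sample.int(4, L, replace = TRUE)]
    seqs <- matrix(rep(anc, each = genealogies$sheet$n_hap),
                   nrow = genealogies$sheet$n_hap)
    if (length(win$pos)) {
      anc_idx <- match(anc[win$pos], base_raw)
      # Jukes-Cantor: derived base uniform over the three non-ancestral bases
      shift <- sample.int(3, length(win$pos), replace = TRUE)
      der_idx <- (anc_idx - 1L + shift) %% 4L + 1L
      for (s in seq_along(win$pos)) {
        carriers <- win$derived[, s] == 1L
        seqs[carriers, win$pos[s]] <- base_raw[der_idx[s]]
      }
    }
    rownames(seqs) <- rownames(win$derived)
    windows[[w]] <- list(seqs = seqs, ancestral = anc)
  }
  structure(list(windows = windows, sheet = genealogies$sheet, config = config,
                 contigs = genealogies$contigs, panel = genealogies),
            class = "sequence_panel")
}

revcomp_raw <- function(x) {
  map <- raw(256)
  map[as.integer(charToRaw("ACGTN")) + 1L] <- charToRaw("TGCAN")
  rev(map[as.integer(x) + 1L])
}

#' Fragment sequences and inject post-mortem damage
#'
#' Draws sequencing fragments from each haplotype (log-normal lengths
#' truncated to [20, window length], uniform start, random strand), then
#' applies terminal deamination in read orientation: C at 5' offset i becomes
#' T with probability `d5 * lambda^i`, G at 3' offset i becomes A with
#' probability `d3 * lambda^i`. Base qualities are not modified by damage.
#'
#' @param panel a `sequence_panel`.
#' @param damage a [damage_model()].
#' @param coverage expected haploid coverage per haplotype (a diploid
#'   individual gets twice this).
#' @param seed integer seed (defaults to the panel's config seed).
#' @return object of class `read_set`: a data.frame of fragments (window,
#'   haplotype, individual, start, length, strand) with the read-orientation
#'   damaged sequence, the read-orientation reference (pre-damage) sequence,
#'   and the phred quality.
#' @export
fragment_and_damage <- function(panel, damage, coverage = 15, seed = NULL) {
  stopifnot(inherits(panel, "sequence_panel"), inherits(damage, "damage_model"))
  config <- panel$config
  if (is.null(seed)) seed <- config$seed
  L <- config$window_length
  sdlog <- sqrt(log(1 + (damage$frag_sd / damage$frag_mean)^2))
  meanlog <- log(damage$frag_mean) - sdlog^2 / 2
  out <- vector("list", length(panel$windows))
  for (w in seq_along(panel$windows)) {
    set.seed(subseed(seed, 3L, w))
    seqs <- panel$windows[[w]]$seqs
    n_hap <- nrow(seqs)
    n_frag <- max(1L, round(coverage * L / damage$frag_mean))
    hap <- rep(seq_len(n_hap), each = n_frag)
    len <- pmin(pmax(round(stats::rlnorm(length(hap), meanlog, sdlog)), 20L), L)
    start <- floor(stats::runif(length(hap), 1, L - len + 1 + 1))
    start <- pmin(start, L - len + 1L)
    strand <- ifelse(stats::runif(length(hap)) < 0.5, "+", "-")
    seq_chr <- character(length(hap))
    ref_chr <- character(length(hap))
    for (i in seq_along(hap)) {
      sl <- seqs[hap[i], start[i]:(start[i] + len[i] - 1L)]
      if (strand[i] == "-") sl <- revcomp_raw(sl)
      ref_chr[i] <- rawToChar(sl)
    }
    # vectorized damage over all bases of all fragments
    all_ref <- charToRaw(paste(ref_chr, collapse = ""))
    frag_of <- rep(seq_along(hap), len)
    off5 <- sequence(len) - 1L
    off3 <- len[frag_of] - 1L - off5
    dam <- all_ref
    if (damage$d5 > 0) {
      is_c <- dam == charToRaw("C")
      hit <- is_c & stats::runif(length(dam)) < damage$d5 * damage$lambda^off5
      dam[hit] <- charToRaw("T")
    }
    if (damage$d3 > 0) {
      is_g <- dam == charToRaw("G")
      hit <- is_g & stats::runif(length(dam)) < damage$d3 * damage$lambda^off3
      dam[hit] <- charToRaw("A")
    }
    ends <- cumsum(len)
    starts_cat <- c(1L, utils::head(ends, -1) + 1L)
    seq_chr <- substring(rawToChar(dam), starts_cat, ends)
    out[[w]] <- data.frame(
      contig = panel$contigs[w], hap = hap,
      individual = panel$sheet$individuals[panel$sheet$hap_ind[hap]],
      start = as.integer(start), length = as.integer(len), strand = strand,
      seq = seq_chr, ref = ref_chr, qual = damage$qual,
      stringsAsFactors = FALSE)
  }
  structure(list(fragments = do.call(rbind, out), sheet = panel$sheet,
                 config = config, contigs = panel$contigs,
                 damage = damage), class = "read_set")
}

#' Generate per-site, per-individual pileups
#'
#' From a `sequence_panel`: per individual and site, read depth is
#' Poisson(`depth`), reads are drawn from the two haplotypes with equal
#' probability, and each sequenced base is miscalled to one of the three other
#' bases with total probability `10^(-qual/10)`. From a `read_set`: fragment
#' bases are piled onto their reference positions (reverse-strand fragments
#' are complemented back) and the same miscall model is applied.
#'
#' @param x a `sequence_panel` or `read_set`.
#' @param depth mean per-individual read depth (sequence-panel mode).
#' @param qual phred base quality.
#' @param positions "segregating" (default: truth segregating sites only) or
#'   "all" (sequence-panel mode only; memory-heavy for long windows).
#' @param depth_track logical; also return full per-position depth tracks per
#'   individual (needed for consensus masking).
#' @param seed integer seed (defaults to the config seed).
#' @return object of class `pileup_set`: site coordinates, a site x individual
#'   x base count array, depth matrix, quality, and optional depth tracks.
#' @export
generate_pileups <- function(x, depth = 30, qual = 30, positions = "segregating",
                             depth_track = FALSE, seed = NULL) {
  UseMethod("generate_pileups")
}

#' @export
generate_pileups.sequence_panel <- function(x, depth = 30, qual = 30,
                                            positions = "segregating",
                                            depth_track = FALSE, seed = NULL) {
  config <- x$config
  if (depth <= 0) stop("mean depth must be > 0")
  if (is.null(seed)) seed <- config$seed
  sheet <- x$sheet
  n_ind <- length(sheet$individuals)
  err <- 10^(-qual / 10)
  L <- config$window_length
  res_contig <- character(0); res_pos <- integer(0)
  counts_list <- list(); tracks <- if (depth_track) list() else NULL
  for (w in seq_along(x$windows)) {
    set.seed(subseed(seed, 4L, w))
    pos <- if (identical(positions, "all")) seq_len(L) else x$panel$windows[[w]]$pos
    trk <- matrix(stats::rpois(n_ind * L, depth), nrow = n_ind,
                  dimnames = list(sheet$individuals, NULL))
    if (depth_track) tracks[[w]] <- trk
    if (length(pos)) {
      seqs <- x$windows[[w]]$seqs
      cnt <- array(0L, dim = c(length(pos), n_ind, 4),
                   dimnames = list(NULL, sheet$individuals, BASES))
      hap1 <- match(rawToChar(seqs[seq(1, 2 * n_ind, by = 2), pos, drop = FALSE],
                              multiple = TRUE), BASES)
      hap2 <- match(rawToChar(seqs[seq(2, 2 * n_ind, by = 2), pos, drop = FALSE],
                              multiple = TRUE), BASES)
      dim(hap1) <- dim(hap2) <- c(n_ind, length(pos))
      n_reads <- t(trk[, pos, drop = FALSE])          # site x ind
      n_h1 <- matrix(stats::rbinom(length(n_reads), as.vector(n_reads), 0.5),
                     nrow = nrow(n_reads))
      for (b in 1:4) {
        # true-base read counts before error
        nb <- n_h1 * (t(hap1) == b) + (n_reads - n_h1) * (t(hap2) == b)
        cnt[, , b] <- nb
      }
      if (err > 0) {
        # move erroneous reads: each read errs with prob err, uniformly to the
        # other three bases
        for (b in 1:4) {
          nb <- cnt[, , b, drop = FALSE]; dim(nb) <- dim(cnt)[1:2]
          ne_ <- matrix(stats::rbinom(length(nb), as.vector(nb), err), nrow = nrow(nb))
          cnt[, , b] <- nb - ne_
          if (any(ne_ > 0)) {
            others <- setdiff(1:4, b)
            n1 <- matrix(stats::rbinom(length(ne_), as.vector(ne_), 1 / 3), nrow = nrow(ne_))
            rest <- ne_ - n1
            n2 <- matrix(stats::rbinom(length(rest), as.vector(rest), 1 / 2), nrow = nrow(rest))
            for (oi in 1:3) {
              slab <- cnt[, , others[oi], drop = FALSE]; dim(slab) <- dim(ne_)
              cnt[, , others[oi]] <- slab + switch(oi, n1, n2, rest - n2)
            }
          }
        }
      }
      res_contig <- c(res_contig, rep(x$contigs[w], length(pos)))
      res_pos <- c(res_pos, as.integer(pos))
      counts_list[[length(counts_list) + 1L]] <- cnt
    }
  }
  counts <- if (length(counts_list)) {
    do.call(abind3, counts_list)
  } else {
    array(0L, dim = c(0, n_ind, 4), dimnames = list(NULL, sheet$individuals, BASES))
  }
  structure(list(contig = res_contig, pos = res_pos,
                 individuals = sheet$individuals,
                 counts = counts, depth = apply(counts, c(1, 2), sum),
                 qual = qual,
                 depth_tracks = tracks, contigs = x$contigs,
                 window_length = L),
            class = "pileup_set")
}

# rbind for 3-d arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0L, dim = c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))), d[2], d[3]),
               dimnames = c(list(NULL), dimnames(parts[[1]])[2:3]))
  at <- 0L
  for (p in parts) {
    if (dim(p)[1]) out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
generate_pileups.read_set <- function(x, depth = 30, qual = NULL,
                                      positions = "segregating",
                                      depth_track = FALSE, seed = NULL) {
  if (is.null(seed)) seed <- x$config$seed
  if (is.null(qual)) qual <- x$damage$qual
  err <- 10^(-qual / 10)
  fr <- x$fragments
  n_ind <- length(x$sheet$individuals)
  set.seed(subseed(seed, 5L))
  # expand fragments to (contig, pos, individual, base) in reference orientation
  n_base <- sum(fr$length)
  frag_of <- rep(seq_len(nrow(fr)), fr$length)
  within <- sequence(fr$length)
  minus <- fr$strand[frag_of] == "-"
  pos <- fr$start[frag_of] + ifelse(minus, fr$length[frag_of] - within, within - 1L)
  base <- unlist(strsplit(fr$seq, ""), use.names = FALSE)
  base[minus] <- c(A = "T", C = "G", G = "C", T = "A")[base[minus]]
  if (err > 0) {
    hit <- stats::runif(n_base) < err
    base[hit] <- BASES[(match(base[hit], BASES) - 1L + sample.int(3, sum(hit), replace = TRUE)) %% 4L + 1L]
  }
  ind <- match(fr$individual[frag_of], x$sheet$individuals)
  win <- match(fr$contig[frag_of], x$contigs)
  L <- x$config$window_length
  key <- (win - 1) * L + pos                         # global site key
  ukey <- sort(unique(key))
  site <- match(key, ukey)
  bidx <- match(base, BASES)
  counts <- array(0L, dim = c(length(ukey), n_ind, 4),
                  dimnames = list(NULL, x$sheet$individuals, BASES))
  # tabulate with base varying fastest, then individual, then site
  tab <- tabulate((site - 1L) * (n_ind * 4L) + (ind - 1L) * 4L + bidx,
                  nbins = length(ukey) * n_ind * 4L)
  counts[] <- aperm(array(tab, dim = c(4, n_ind, length(ukey))), c(3, 2, 1))
  structure(list(contig = x$contigs[(ukey - 1) %/% L + 1],
                 pos = as.integer((ukey - 1) %% L + 1),
                 individuals = x$sheet$individuals,
                 counts = counts, depth = apply(counts, c(1, 2), sum),
                 qual = qual, depth_tracks = NULL, contigs = x$contigs,
                 window_length = L),
            class = "pileup_set")
}

#' Truth set for recovery tests
#'
#' Collects true diploid genotypes per individual at every segregating site,
#' the per-window genealogy (newick), configured split times, pulse fractions
#' and the injected damage curve into one object downstream tests compare
#' against.
#'
#' @param genealogies a `genealogy_set`.
#' @param damage optional [damage_model()] whose curve is part of the truth.
#' @return object of class `truth_set` with elements `genotypes` (list per
#'   window: individual x site derived-allele dosage), `newick`, `config`,
#'   `damage`.
#' @export
truth_set <- function(genealogies, damage = NULL) {
  stopifnot(inherits(genealogies, "genealogy_set"))
  sheet <- genealogies$sheet
  geno <- lapply(genealogies$windows, function(win) {
    if (!ncol(win$derived)) {
      return(matrix(0L, nrow = length(sheet$individuals), ncol = 0,
                    dimnames = list(sheet$individuals, NULL)))
    }
    g <- win$derived[seq(1, nrow(win$derived), 2), , drop = FALSE] +
      win$derived[seq(2, nrow(win$derived), 2), , drop = FALSE]
    rownames(g) <- sheet$individuals
    g
  })
  structure(list(genotypes = geno,
                 positions = lapply(genealogies$windows, `[[`, "pos"),
                 newick = vapply(genealogies$windows, `[[`, character(1), "newick"),
                 config = genealogies$config, damage = damage,
                 contigs = genealogies$contigs, sheet = sheet),
            class = "truth_set")
}
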