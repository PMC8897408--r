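# Per-window neighbor-joining trees, nonparametric bootstrap support, and
# topology weighting (the fraction of one-tip-per-group subsamples of a
# window tree matching each possible rooted group-level topology).

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (per-window trees use NJ on p-distances as a fast, faithful
#' stand-in for per-window maximum-likelihood searches; the analysis surface
#' downstream is topology frequencies). Negative branch lengths are clamped
#' to zero. Undefined distance entries are an error listing the offending
#' pairs.
#'
#' @param dist a `distance_matrix` from [p_distance()] or a plain symmetric
#'   numeric matrix with at least 3 labels.
#' @return an `ape::phylo` (unrooted).
#' @export
nj_tree <- function(dist) {
  d <- if (inherits(dist, "distance_matrix")) dist$d else as.matrix(dist)
  if (nrow(d) < 3) stop("nj_tree needs at least 3 labels")
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop(sprintf("undefined distance entries: %s",
                 paste(rownames(d)[bad[, 1]], colnames(d)[bad[, 2]],
                       sep = "-", collapse = ", ")))
  }
  phy <- ape::nj(d)
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Nonparametric bootstrap support for an alignment's NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the p-distance
#' NJ tree per replicate, and reports for each internal edge of the
#' point-estimate tree the fraction of replicates containing the same
#' bipartition.
#'
#' @param alignment a `window_alignment`, `concat_alignment` or named
#'   character vector of equal-length sequences.
#' @param n_reps number of bootstrap replicates (0 = point tree only).
#' @param seed integer seed.
#' @return list with `tree` (the point-estimate `phylo`) and `support`
#'   (numeric vector in [0,1] per internal node, NULL when `n_reps = 0`).
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1L) {
  if (inherits(alignment, "concat_alignment") || inherits(alignment, "window_alignment")) {
    alignment <- alignment$seqs
  }
  point <- nj_tree(p_distance(alignment))
  if (n_reps <= 0) return(list(tree = point, support = NULL))
  al <- p_dist_alphabet()
  enc <- t(vapply(alignment, function(s) al$idx[as.integer(charToRaw(s)) + 1L],
                  integer(nchar(alignment[[1]]))))
  rownames(enc) <- names(alignment)
  L <- ncol(enc)
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- nj_tree(p_dist_core(enc[, cols, drop = FALSE], al$score))
  }
  cnt <- ape::prop.clades(point, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  list(tree = point, support = cnt / n_reps)
}

# p-distance from an encoded (0 = N) integer matrix; returns plain matrix
p_dist_core <- function(enc, score) {
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- enc[i, ] > 0L & enc[j, ] > 0L
      m <- sum(ok)
      d[i, j] <- d[j, i] <- if (m == 0) NA_real_ else
        sum(score[cbind(enc[i, ok], enc[j, ok])]) / m
    }
  }
  d
}

# canonical rooted-topology label: nested parentheses with children sorted
canonical_topology <- function(phy, labels = phy$tip.label) {
  n_tip <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) return(labels[node])
    kids <- sort(vapply(children[[as.character(node)]], rec, character(1)))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  rec(n_tip + 1L)
}

#' Enumerate rooted group-level topologies
#'
#' All rooted binary topologies over the in-group labels, each attached to
#' the outgroup at the root, as canonical labels. Three in-group labels give
#' exactly three topologies.
#'
#' @param ingroups character vector of in-group labels.
#' @param outgroup outgroup label.
#' @return character vector of canonical topology labels.
#' @export
enumerate_topologies <- function(ingroups, outgroup) {
  grow <- function(trees, taxon) {
    unlist(lapply(trees, function(tr) {
      spots <- attach_points(tr)
      vapply(spots, function(s) s(taxon), character(1))
    }))
  }
  # represent trees as nested lists; enumerate by successive insertion
  insert_all <- function(tr, taxon) {
    if (is.character(tr)) return(list(list(tr, taxon)))
    res <- list(list(tr, taxon))
    for (k in 1:2) {
      for (sub in insert_all(tr[[k]], taxon)) {
        nt <- tr; nt[[k]] <- sub
        res <- c(res, list(nt))
      }
    }
    res
  }
  canon <- function(tr) {
    if (is.character(tr)) return(tr)
    kids <- sort(c(canon(tr[[1]]), canon(tr[[2]])))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  trees <- list(ingroups[1])
  for (tx in ingroups[-1]) {
    trees <- unlist(lapply(trees, insert_all, taxon = tx), recursive = FALSE)
  }
  sort(unique(vapply(trees, function(tr) {
    paste0("(", paste(sort(c(canon(tr), outgroup)), collapse = ","), ")")
  }, character(1))))
}

#' Topology weights for one window tree
#'
#' Iterates over combinations of one leaf per group (exhaustive when the
#' number of combinations is at most `max_exhaustive`, otherwise a uniform
#' random sample of `n_samples` combinations), prunes the tree to those
#' leaves, roots it on the outgroup leaf, and classifies the induced rooted
#' group-level topology. The weight of a topology is the fraction of
#' combinations inducing it; weights sum to 1.
#'
#' @param tree an `ape::phylo` whose tips are individuals.
#' @param groups named character vector mapping every leaf to its group.
#' @param outgroup the outgroup group's name.
#' @param max_exhaustive combination-count threshold for exhaustive
#'   enumeration (default 10000).
#' @param n_samples combinations drawn in sampled mode (default 1000).
#' @param seed integer seed used in sampled mode.
#' @return object of class `topology_weights`: named weight vector over the
#'   enumerated topology set, with attributes `mode` ("exhaustive" or
#'   "sampled") and `n_combinations`.
#' @export
topology_weights <- function(tree, groups, outgroup, max_exhaustive = 10000,
                             n_samples = 1000, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(groups))) {
    stop(sprintf("leaves without a group: %s",
                 paste(setdiff(tips, names(groups)), collapse = ", ")))
  }
  by_group <- split(tips, groups[tips])
  if (!(outgroup %in% names(by_group))) stop("outgroup group has zero sampled leaves")
  if (any(lengths(by_group) == 0)) stop("every group needs at least one sampled leaf")
  g_names <- names(by_group)
  ingroups <- setdiff(g_names, outgroup)
  if (length(g_names) < 4) stop("topology weighting needs at least 4 groups (incl. outgroup)")
  topo_set <- enumerate_topologies(sort(ingroups), outgroup)
  n_comb <- prod(lengths(by_group))
  if (n_comb <= max_exhaustive) {
    combos <- as.matrix(expand.grid(by_group, stringsAsFactors = FALSE))
    mode <- "exhaustive"
  } else {
    set.seed(seed)
    combos <- vapply(by_group, function(ls) sample(ls, n_samples, replace = TRUE),
                     character(n_samples))
    mode <- "sampled"
  }
  counts <- stats::setNames(numeric(length(topo_set)), topo_set)
  leaf_group <- groups
  for (r in seq_len(nrow(combos))) {
    leaves <- combos[r, ]
    sub <- ape::keep.tip(tree, leaves)
    og_leaf <- leaves[[which(g_names == outgroup)]]
    sub <- ape::root(sub, outgroup = og_leaf, resolve.root = TRUE)
    lab <- canonical_topology(sub, unname(leaf_group[sub$tip.label]))
    if (is.na(match(lab, topo_set))) {
      # multifurcating resolution artifacts cannot arise from binary NJ trees,
      # but guard against unexpected labels
      counts[lab] <- ifelse(is.na(counts[lab]), 0, counts[lab])
    }
    counts[lab] <- counts[lab] + 1
  }
  w <- counts / sum(counts)
  structure(w, mode = mode, n_combinations = nrow(combos),
            class = "topology_weights")
}

#' Genome-wide topology frequency summary
#'
#' Mean weight per topology across windows, plus the count of windows where
#' each topology is the (unique) argmax.
#'
#' @param weight_list list of `topology_weights` over a consistent topology
#'   set.
#' @return data.frame with `topology`, `mean_weight`, `n_best`.
#' @export
weight_summary <- function(weight_list) {
  stopifnot(length(weight_list) > 0)
  topo <- names(weight_list[[1]])
  for (w in weight_list) {
    if (!identical(names(w), topo)) stop("inconsistent topology sets across windows")
  }
  m <- do.call(rbind, lapply(weight_list, as.numeric))
  best <- apply(m, 1, which.max)
  data.frame(topology = topo,
             mean_weight = colMeans(m),
             n_best = tabulate(best, nbins = length(topo)),
             row.names = NULL)
}
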