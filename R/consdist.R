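# IUPAC consensus building with depth masking, windowed alignments,
# concatenation, uncorrected p-distances and mutation-rate divergence dating.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
IUPAC_SET <- list(A = "A", C = "C", G = "G", T = "T",
                  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))

iupac_het <- function(a1, a2) {
  key <- ifelse(a1 < a2, paste0(a1, a2), paste0(a2, a1))
  unname(IUPAC_CODES[key])
}

#' Mutation-rate and generation-length configuration for divergence dating
#'
#' @param mu per-site per-generation mutation rate (default the flycatcher
#'   rate 4.6e-9).
#' @param generation_years generation length in years (default 3.7, the
#'   BirdLife estimate for orioles).
#' @return object of class `divergence_config`.
#' @export
divergence_config <- function(mu = 4.6e-9, generation_years = 3.7) {
  stopifnot(mu > 0, generation_years > 0)
  structure(list(mu = mu, generation_years = generation_years),
            class = "divergence_config")
}

#' Build masked IUPAC consensus sequences
#'
#' Per individual and contig: start from the reference sequence, overwrite
#' called variant sites (hom-minor emits the minor allele, hets emit the IUPAC
#' code of the two alleles, missing genotypes emit N), then mask every
#' position whose depth is below `depth_min` (inclusive boundary: exactly
#' `depth_min` is kept) or strictly above `depth_mult` times the individual's
#' mean depth.
#'
#' @param ref named list of reference sequences (character strings or raw
#'   vectors), one per contig.
#' @param sites data.frame with `contig`, `pos` (1-based), `major`, `minor`.
#' @param dosage integer matrix site x individual of minor-allele dosages
#'   (NA = missing), as returned by [hard_call()].
#' @param depth_tracks named list per contig of individual x position depth
#'   matrices.
#' @param mean_depth optional named per-individual mean depth; computed from
#'   the tracks when omitted. A zero mean depth is an error.
#' @param depth_min minimum unmasked depth (default 10).
#' @param depth_mult upper masking bound as a multiple of the individual mean
#'   (default 3).
#' @return object of class `consensus_set`: per contig a named list of raw
#'   vectors (one per individual), plus a mask-fraction summary.
#' @export
build_consensus <- function(ref, sites, dosage, depth_tracks,
                            mean_depth = NULL, depth_min = 10, depth_mult = 3) {
  individuals <- colnames(dosage)
  if (is.null(individuals)) stop("dosage must have individual column names")
  contigs <- names(ref)
  if (is.null(mean_depth)) {
    tot <- Reduce(`+`, lapply(depth_tracks, rowSums))
    len <- sum(vapply(depth_tracks, ncol, numeric(1)))
    mean_depth <- tot / len
  }
  if (any(mean_depth[individuals] <= 0)) {
    stop(sprintf("mean depth is zero for individual(s): %s",
                 paste(individuals[mean_depth[individuals] <= 0], collapse = ", ")))
  }
  n_raw <- charToRaw("N")
  out <- vector("list", length(contigs))
  names(out) <- contigs
  masked <- 0; total <- 0
  for (ctg in contigs) {
    r <- ref[[ctg]]
    if (is.character(r)) r <- charToRaw(r)
    L <- length(r)
    here <- which(sites$contig == ctg)
    trk <- depth_tracks[[ctg]]
    seqs <- vector("list", length(individuals))
    names(seqs) <- individuals
    for (i in seq_along(individuals)) {
      s <- r
      if (length(here)) {
        g <- dosage[here, i]
        pos <- sites$pos[here]
        s[pos[!is.na(g) & g == 2L]] <- charToRaw(paste(sites$minor[here][!is.na(g) & g == 2L], collapse = ""))
        s[pos[!is.na(g) & g == 0L]] <- charToRaw(paste(sites$major[here][!is.na(g) & g == 0L], collapse = ""))
        het <- !is.na(g) & g == 1L
        if (any(het)) {
          s[pos[het]] <- charToRaw(paste(iupac_het(sites$major[here][het],
                                                   sites$minor[here][het]), collapse = ""))
        }
        s[pos[is.na(g)]] <- n_raw
      }
      d <- trk[individuals[i], ]
      bad <- d < depth_min | d > depth_mult * mean_depth[[individuals[i]]]
      s[bad] <- n_raw
      masked <- masked + sum(bad); total <- total + L
      seqs[[i]] <- s
    }
    out[[ctg]] <- seqs
  }
  structure(list(seqs = out, individuals = individuals,
                 contig_lengths = vapply(out, function(x) length(x[[1]]), numeric(1)),
                 mask_fraction = masked / max(total, 1)),
            class = "consensus_set")
}

#' Extract spaced windows from consensus sequences
#'
#' Windows of `window` bp start at offsets 0, `step`, 2*`step`, ... (0-based)
#' on contigs whose length strictly exceeds `min_contig`, wherever the full
#' window fits. A window is retained iff at least `min_col_frac` of its
#' columns carry non-N data in at least `min_ind_frac` of individuals.
#'
#' @param consensus a `consensus_set`.
#' @param window window length in bp (default 10000).
#' @param step distance between window starts (default 100000, i.e. 10-kb
#'   windows separated by 90-kb gaps).
#' @param min_contig minimum (strict) contig length (default 100000).
#' @param min_col_frac,min_ind_frac inclusion thresholds (default 0.5 each).
#' @return list of `window_alignment` objects; each has `contig`, `start`,
#'   `end` (0-based half-open), `seqs` (named character vector) and
#'   per-individual completeness.
#' @export
extract_windows <- function(consensus, window = 10000, step = 100000,
                            min_contig = 100000, min_col_frac = 0.5,
                            min_ind_frac = 0.5) {
  stopifnot(inherits(consensus, "consensus_set"))
  n_raw <- charToRaw("N")
  out <- list()
  for (ctg in names(consensus$seqs)) {
    L <- consensus$contig_lengths[[ctg]]
    if (L <= min_contig) next
    starts <- seq(0, L - window, by = step)
    for (s0 in starts) {
      idx <- (s0 + 1):(s0 + window)
      slab <- vapply(consensus$seqs[[ctg]], function(x) x[idx] != n_raw,
                     logical(window))                  # window x ind
      good_col <- rowSums(slab) >= min_ind_frac * length(consensus$individuals)
      if (mean(good_col) >= min_col_frac) {
        seqs <- vapply(consensus$seqs[[ctg]],
                       function(x) rawToChar(x[idx]), character(1))
        out[[length(out) + 1L]] <- structure(
          list(contig = ctg, start = s0, end = s0 + window, seqs = seqs,
               completeness = colMeans(slab)),
          class = "window_alignment")
      }
    }
  }
  out
}

#' Concatenate window alignments into a supermatrix
#'
#' @param windows list of `window_alignment` objects sharing one individual
#'   set (mismatches are an error listing the offenders).
#' @return object of class `concat_alignment`: `seqs` (named character
#'   vector) and an invertible coordinate `map` data.frame (contig, start,
#'   end, offset of the window's first column in the concatenation, 1-based).
#' @export
concatenate_windows <- function(windows) {
  if (!length(windows)) {
    return(structure(list(seqs = character(0),
                          map = data.frame(contig = character(0), start = integer(0),
                                           end = integer(0), offset = integer(0))),
                     class = "concat_alignment"))
  }
  inds <- names(windows[[1]]$seqs)
  for (w in windows) {
    if (!identical(sort(names(w$seqs)), sort(inds))) {
      bad <- union(setdiff(names(w$seqs), inds), setdiff(inds, names(w$seqs)))
      stop(sprintf("window %s:%d-%d has mismatched individuals: %s",
                   w$contig, w$start, w$end, paste(bad, collapse = ", ")))
    }
  }
  lens <- vapply(windows, function(w) w$end - w$start, numeric(1))
  offset <- c(1, utils::head(cumsum(lens), -1) + 1)
  seqs <- vapply(inds, function(i) {
    paste(vapply(windows, function(w) w$seqs[[i]], character(1)), collapse = "")
  }, character(1))
  map <- data.frame(contig = vapply(windows, `[[`, character(1), "contig"),
                    start = vapply(windows, `[[`, numeric(1), "start"),
                    end = vapply(windows, `[[`, numeric(1), "end"),
                    offset = as.integer(offset))
  structure(list(seqs = seqs, map = map), class = "concat_alignment")
}

#' Map a concatenated column back to its window coordinate
#' @param concat a `concat_alignment`.
#' @param column 1-based column index in the concatenation.
#' @return list(contig, pos) with `pos` the 1-based position on the contig.
#' @export
concat_coordinate <- function(concat, column) {
  m <- concat$map
  j <- findInterval(column, m$offset)
  if (j < 1 || column >= m$offset[j] + (m$end[j] - m$start[j])) {
    stop("column outside the concatenation")
  }
  list(contig = m$contig[j], pos = m$start[j] + (column - m$offset[j]) + 1L)
}

# 11-state alphabet: 4 bases + 6 two-allele IUPAC codes + everything else = N
p_dist_alphabet <- function() {
  codes <- names(IUPAC_SET)
  score <- matrix(NA_real_, 10, 10, dimnames = list(codes, codes))
  for (i in 1:10) {
    for (j in 1:10) {
      s1 <- IUPAC_SET[[i]]; s2 <- IUPAC_SET[[j]]
      shared <- length(intersect(s1, s2))
      score[i, j] <-
        if (codes[i] == codes[j]) 0
        else if (shared == 0) 1
        else if (length(s1) == 1 || length(s2) == 1) 0.5  # het vs compatible hom
        else 0.75                                         # two hets sharing one allele
    }
  }
  idx <- integer(256)
  idx[as.integer(charToRaw(paste(codes, collapse = ""))) + 1L] <- seq_along(codes)
  list(score = score, idx = idx)
}

#' Uncorrected p-distances with IUPAC-aware scoring
#'
#' Pairwise deletion: any column where either sequence is N (or a gap) is
#' skipped for that pair. Scoring per compared column: identical codes 0;
#' heterozygote versus a compatible homozygote 0.5 (R vs A); heterozygote
#' versus an incompatible homozygote 1; two different heterozygotes sharing
#' one allele 0.75; disjoint codes 1. The distance is the summed score over
#' compared columns. Pairs with zero compared columns get NA and are listed
#' in the `undefined` attribute.
#'
#' @param seqs named character vector of equal-length sequences (a
#'   `concat_alignment` or `window_alignment` is also accepted).
#' @return object of class `distance_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal), `n` (compared columns per pair).
#' @export
p_distance <- function(seqs) {
  if (inherits(seqs, "concat_alignment") || inherits(seqs, "window_alignment")) {
    seqs <- seqs$seqs
  }
  if (length(seqs) < 2) stop("p_distance needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1) stop("sequences must have equal length")
  al <- p_dist_alphabet()
  n <- length(seqs)
  labs <- names(seqs)
  enc <- lapply(seqs, function(s) al$idx[as.integer(charToRaw(s)) + 1L])
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  cnt <- matrix(nchar(seqs)[1], n, n, dimnames = list(labs, labs))
  undefined <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e1 <- enc[[i]]; e2 <- enc[[j]]
      ok <- e1 > 0L & e2 > 0L
      m <- sum(ok)
      cnt[i, j] <- cnt[j, i] <- m
      if (m == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        undefined <- c(undefined, paste(labs[i], labs[j], sep = "-"))
      } else {
        sc <- sum(al$score[cbind(e1[ok], e2[ok])])
        d[i, j] <- d[j, i] <- sc / m
      }
    }
  }
  structure(list(d = d, n = cnt, undefined = undefined),
            class = "distance_matrix")
}

#' Scale p-distances to divergence times in generations
#'
#' Two lineages accumulate mutations independently after their split, so
#' `T = p / (2 * mu)` generations.
#'
#' @param dist a `distance_matrix` (or plain numeric matrix of p-distances).
#' @param config a [divergence_config()].
#' @return matrix of divergence times in generations.
#' @export
divergence_generations <- function(dist, config = divergence_config()) {
  d <- if (inherits(dist, "distance_matrix")) dist$d else dist
  d / (2 * config$mu)
}

#' Convert divergence times from generations to years
#' @param generations matrix (or vector) of generation counts.
#' @param config a [divergence_config()] supplying the generation length.
#' @return the input scaled to years.
#' @export
generations_to_years <- function(generations, config = divergence_config()) {
  generations * config$generation_years
}

#' Treat whole consensus contigs as analysis windows
#'
#' For simulated data the contigs are themselves the distant, independent
#' windows, so no spaced extraction is needed; each contig becomes one
#' `window_alignment` spanning its full length.
#'
#' @param consensus a `consensus_set`.
#' @return list of `window_alignment` objects.
#' @export
consensus_windows <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_set"))
  lapply(names(consensus$seqs), function(ctg) {
    seqs <- vapply(consensus$seqs[[ctg]], rawToChar, character(1))
    n_frac <- vapply(consensus$seqs[[ctg]],
                     function(x) mean(x != charToRaw("N")), numeric(1))
    structure(list(contig = ctg, start = 0L,
                   end = as.integer(consensus$contig_lengths[[ctg]]),
                   seqs = seqs, completeness = n_frac),
              class = "window_alignment")
  })
}
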