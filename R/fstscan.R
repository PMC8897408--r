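# Per-site Weir-Cockerham variance components, 50-kb windowed Fst summaries,
# Z(Fst) outlier calling and annotation-interval overlap.

#' Per-site Weir-Cockerham variance components (two or more populations)
#'
#' The 1984 diploid estimator with among-population (a), among-individual-
#' within-population (b) and within-individual (c) components computed from
#' per-population sample sizes, allele frequencies and observed
#' heterozygosity; per-site Fst = a / (a + b + c). A site monomorphic across
#' all populations yields components (0, 0, c) with undefined Fst.
#'
#' @param geno_counts matrix populations x 3 of genotype counts
#'   (hom-ref, het, hom-alt), or a list of per-population dosage vectors.
#' @return list with `a`, `b`, `c`, `fst` (NA when a + b + c = 0), `p`
#'   (per-population frequencies), `n` (sample sizes).
#' @export
wc_fst_site <- function(geno_counts) {
  if (is.list(geno_counts) && !is.matrix(geno_counts)) {
    geno_counts <- t(vapply(geno_counts, function(g) {
      g <- g[!is.na(g)]
      c(sum(g == 0), sum(g == 1), sum(g == 2))
    }, numeric(3)))
  }
  n_i <- rowSums(geno_counts)
  if (any(n_i < 2)) stop("wc_fst_site needs >= 2 non-missing diploids per population")
  r <- nrow(geno_counts)
  p_i <- (geno_counts[, 2] + 2 * geno_counts[, 3]) / (2 * n_i)
  h_i <- geno_counts[, 2] / n_i
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       fst = if (denom != 0) a / denom else NA_real_,
       p = p_i, n = n_i)
}

#' Per-site Weir-Cockerham components for two populations along a genome
#'
#' @param dosage integer matrix site x individual of minor-allele dosages
#'   (NA = missing).
#' @param pop_map named character vector individual -> population; exactly
#'   two populations are used.
#' @param pops length-2 character vector choosing the populations (default:
#'   the two taxa of the map).
#' @param contig,pos site coordinates.
#' @return object of class `fst_sites`: data.frame with contig, pos, a, b, c,
#'   fst (NA where undefined).
#' @export
wc_fst_sites <- function(dosage, pop_map, pops = NULL, contig, pos) {
  if (is.null(pops)) pops <- unique(unname(pop_map))
  stopifnot(length(pops) == 2)
  idx1 <- intersect(colnames(dosage), names(pop_map)[pop_map == pops[1]])
  idx2 <- intersect(colnames(dosage), names(pop_map)[pop_map == pops[2]])
  out <- data.frame(contig = contig, pos = pos,
                    a = NA_real_, b = NA_real_, c = NA_real_, fst = NA_real_)
  for (s in seq_len(nrow(dosage))) {
    g1 <- dosage[s, idx1]; g2 <- dosage[s, idx2]
    if (sum(!is.na(g1)) < 2 || sum(!is.na(g2)) < 2) next
    w <- wc_fst_site(list(g1, g2))
    out$a[s] <- w$a; out$b[s] <- w$b; out$c[s] <- w$c; out$fst[s] <- w$fst
  }
  class(out) <- c("fst_sites", "data.frame")
  out
}

#' Windowed Fst summaries
#'
#' Nonoverlapping windows tiled from offset 0 on each contig. Two summaries
#' per window: mean-of-ratios (the average of per-site a/(a+b+c) over sites
#' where it is defined, negative values retained) and ratio-of-sums
#' (sum a / sum(a+b+c)).
#'
#' @param fst_sites an `fst_sites` data.frame (sorted by contig, position).
#' @param window window length in bp (default 50000).
#' @param contig_lengths optional named contig lengths; windows extend to the
#'   last site otherwise.
#' @return object of class `fst_window_track`: data.frame with contig, start,
#'   end (0-based half-open), n_sites (defined per-site Fst values),
#'   fst_mean (mean-of-ratios), fst_ratio (ratio-of-sums).
#' @export
fst_windows <- function(fst_sites, window = 50000, contig_lengths = NULL) {
  s <- fst_sites[order(fst_sites$contig, fst_sites$pos), , drop = FALSE]
  win_id <- paste(s$contig, (s$pos - 1) %/% window, sep = ":")
  contigs <- if (is.null(contig_lengths)) unique(s$contig) else names(contig_lengths)
  rows <- list()
  for (ctg in contigs) {
    here <- s[s$contig == ctg, , drop = FALSE]
    max_pos <- if (is.null(contig_lengths)) max(here$pos, 0) else contig_lengths[[ctg]]
    if (max_pos < 1) next
    n_win <- (max_pos - 1) %/% window + 1
    for (wi in seq_len(n_win)) {
      lo <- (wi - 1) * window
      hi <- min(wi * window, max_pos)
      in_w <- here$pos > lo & here$pos <= hi
      fsts <- here$fst[in_w]
      fsts <- fsts[!is.na(fsts)]
      num <- sum(here$a[in_w], na.rm = TRUE)
      den <- sum(here$a[in_w] + here$b[in_w] + here$c[in_w], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, start = lo, end = hi, n_sites = length(fsts),
        fst_mean = if (length(fsts)) mean(fsts) else NA_real_,
        fst_ratio = if (den > 0) num / den else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fst_window_track", "data.frame")
  out
}

#' Z(Fst) outlier windows
#'
#' Z-transforms the chosen window summary over eligible windows (at least
#' `min_sites` defined sites) and flags windows with Z above the cutoff
#' (default 1.15, the top-5% convention); the empirical top-`top_frac` set is
#' reported alongside, with a flag telling whether the two coincide.
#'
#' @param track an `fst_window_track`.
#' @param z_cutoff Z threshold (default 1.15).
#' @param top_frac empirical top fraction (default 0.05).
#' @param statistic "fst_mean" (default, mirroring mean Fst) or "fst_ratio".
#' @param min_sites minimum defined sites per eligible window (default 5).
#' @return the track restricted to eligible windows with columns `z`,
#'   `outlier_z`, `outlier_top` added; attributes `same_set` (logical),
#'   `mean`, `sd`.
#' @export
zscore_outliers <- function(track, z_cutoff = 1.15, top_frac = 0.05,
                            statistic = c("fst_mean", "fst_ratio"),
                            min_sites = 5) {
  statistic <- match.arg(statistic)
  elig <- track[!is.na(track[[statistic]]) & track$n_sites >= min_sites, , drop = FALSE]
  if (nrow(elig) < 20) stop("need >= 20 eligible windows for Z-scoring")
  x <- elig[[statistic]]
  mu <- mean(x); sdev <- stats::sd(x)
  if (sdev == 0) {
    warning("window Fst has zero variance; no outliers")
    elig$z <- 0
    elig$outlier_z <- FALSE
    elig$outlier_top <- FALSE
  } else {
    elig$z <- (x - mu) / sdev
    elig$outlier_z <- elig$z > z_cutoff
    k <- max(1L, floor(top_frac * nrow(elig)))
    thr <- sort(x, decreasing = TRUE)[k]
    elig$outlier_top <- x >= thr
  }
  attr(elig, "same_set") <- identical(elig$outlier_z, elig$outlier_top)
  attr(elig, "mean") <- mu
  attr(elig, "sd") <- sdev
  rownames(elig) <- NULL
  elig
}

#' Genes overlapping outlier windows
#'
#' Half-open interval overlap (>= 1 bp) between outlier windows and a gene
#' annotation, computed with GenomicRanges. The annotation may be a BED/GFF
#' file path (read via rtracklayer) or a data.frame with `contig`, `start`,
#' `end` (0-based half-open) and `name`.
#'
#' @param windows data.frame of windows with `contig`, `start`, `end`
#'   (0-based half-open), e.g. the outlier rows of [zscore_outliers()].
#' @param genes annotation data.frame or a BED/GFF path.
#' @return data.frame with one row per (window, gene) overlap: contig,
#'   start, end, gene.
#' @export
annotate_overlaps <- function(windows, genes) {
  if (is.character(genes)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading annotation files needs the rtracklayer package")
    }
    gr <- rtracklayer::import(genes)
    genes <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        name = if (!is.null(gr$name)) gr$name else
                          if (!is.null(gr$ID)) gr$ID else
                            as.character(seq_along(gr)))
  }
  bad <- which(genes$end <= genes$start | is.na(genes$start) | is.na(genes$end))
  if (length(bad)) {
    stop(sprintf("malformed intervals at line(s): %s", paste(bad, collapse = ", ")))
  }
  w_gr <- GenomicRanges::GRanges(windows$contig,
                                 IRanges::IRanges(windows$start + 1L, windows$end))
  g_gr <- GenomicRanges::GRanges(genes$contig,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(w_gr, g_gr)
  data.frame(contig = windows$contig[S4Vectors::queryHits(hits)],
             start = windows$start[S4Vectors::queryHits(hits)],
             end = windows$end[S4Vectors::queryHits(hits)],
             gene = genes$name[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}
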