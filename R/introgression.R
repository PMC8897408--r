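# Patterson's D (ABBA-BABA) with weighted block-jackknife significance, in
# individual-level and population-level modes.

#' Per-site allele frequencies for a set of individuals
#'
#' Count mode: the minor-allele frequency from hard-called dosages, missing
#' individuals excluded from the denominator. GL mode: the ML frequency from
#' an EM over the individuals' genotype likelihoods. Sites where every
#' individual of the set is missing get NA.
#'
#' @param x a `site_table` (GL mode allowed) or an integer dosage matrix
#'   (site x individual, NA = missing).
#' @param individuals character vector of individuals to use.
#' @param mode "counts" or "gl".
#' @return numeric vector of per-site minor-allele frequencies.
#' @export
pop_allele_freqs <- function(x, individuals, mode = c("counts", "gl")) {
  mode <- match.arg(mode)
  if (mode == "gl") {
    stopifnot(inherits(x, "site_table"))
    gl <- x$gl[, individuals, , drop = FALSE]
    L0 <- 10^gl[, , 1, drop = FALSE]; dim(L0) <- dim(gl)[1:2]
    L1 <- 10^gl[, , 2, drop = FALSE]; dim(L1) <- dim(gl)[1:2]
    L2 <- 10^gl[, , 3, drop = FALSE]; dim(L2) <- dim(gl)[1:2]
    f <- em_maf(L0, L1, L2)
    f[rowSums(!is.na(L0)) == 0] <- NA_real_
    return(f)
  }
  dosage <- if (inherits(x, "site_table")) hard_call(x) else x
  d <- dosage[, individuals, drop = FALSE]
  n <- rowSums(!is.na(d))
  out <- rowSums(d, na.rm = TRUE) / (2 * n)
  out[n == 0] <- NA_real_
  out
}

#' Polarize taxon frequencies by the outgroup
#'
#' The ancestral allele is the outgroup's major allele: at sites where the
#' outgroup frequency exceeds 0.5 all frequencies are flipped to `1 - p`.
#' Sites where the outgroup is polymorphic at more than `max_outgroup_poly`
#' minor frequency are dropped, as are sites with an undefined frequency in
#' any taxon.
#'
#' @param freqs matrix site x taxon of minor-allele frequencies; the last
#'   column (or the column named by `outgroup`) is the outgroup.
#' @param outgroup column name of the outgroup (default: last column).
#' @param max_outgroup_poly outgroup polymorphism tolerance (default 0.2).
#' @return the polarized frequency matrix (derived-allele frequencies),
#'   dropped sites removed; attribute `kept` holds the surviving row indices.
#' @export
polarize_freqs <- function(freqs, outgroup = colnames(freqs)[ncol(freqs)],
                           max_outgroup_poly = 0.2) {
  pO <- freqs[, outgroup]
  keep <- stats::complete.cases(freqs) & pmin(pO, 1 - pO) <= max_outgroup_poly
  out <- freqs[keep, , drop = FALSE]
  flip <- out[, outgroup] > 0.5
  out[flip, ] <- 1 - out[flip, , drop = FALSE]
  attr(out, "kept") <- which(keep)
  out
}

#' Patterson's D point estimate from per-site frequencies
#'
#' With derived-allele frequencies p1, p2, p3, pO, the per-site pattern
#' weights are `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`;
#' `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)`. A zero denominator
#' leaves D undefined (NA).
#'
#' @param p1,p2,p3,pO numeric vectors of derived-allele frequencies (equal
#'   length; NA sites are skipped).
#' @return list with `abba`, `baba` (per-site contributions), `ABBA`, `BABA`
#'   (sums), `D`, and `n_informative` (sites with abba + baba > 0).
#' @export
d_statistic <- function(p1, p2, p3, pO) {
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
  abba <- (1 - p1[ok]) * p2[ok] * p3[ok] * (1 - pO[ok])
  baba <- p1[ok] * (1 - p2[ok]) * p3[ok] * (1 - pO[ok])
  A <- sum(abba); B <- sum(baba)
  list(abba = abba, baba = baba, ABBA = A, BABA = B,
       D = if (A + B > 0) (A - B) / (A + B) else NA_real_,
       n_informative = sum(abba + baba > 0), kept = which(ok))
}

#' Weighted delete-one-block jackknife for Patterson's D
#'
#' Blocks carry unequal information (their masses `m_j = ABBA_j + BABA_j`
#' differ), so delete-one estimates are combined with influence weights:
#' `SE^2 = g/(g-1) * sum_j [(1 - m_j/n) (D - D_(-j))]^2` with `n = sum m_j`
#' and `g` blocks. For equal masses this reduces to the classic delete-one
#' jackknife, and it remains consistent whether per-block variance scales
#' with the inverse site count (many independent genealogies per block) or
#' stays constant (one shared genealogy per window-block), unlike the
#' pseudovalue form that assumes the former.
#'
#' @param abba,baba per-site pattern contributions.
#' @param block integer/character vector assigning each site to a block.
#' @param min_blocks minimum number of non-empty blocks (default 10).
#' @return list with `D`, `SE`, `Z`, `n_blocks`; `SE = 0` (Z undefined,
#'   flagged `degenerate`) when all delete-one estimates coincide.
#' @export
block_jackknife <- function(abba, baba, block, min_blocks = 10) {
  stopifnot(length(abba) == length(baba), length(block) == length(abba))
  A_j <- tapply(abba, block, sum)
  B_j <- tapply(baba, block, sum)
  m <- A_j + B_j
  nz <- m > 0
  A_j <- A_j[nz]; B_j <- B_j[nz]; m <- m[nz]
  g <- length(m)
  if (g < min_blocks) {
    stop(sprintf("only %d non-empty blocks; use smaller blocks (need >= %d)",
                 g, min_blocks))
  }
  A <- sum(A_j); B <- sum(B_j)
  D <- (A - B) / (A + B)
  n <- sum(m)
  D_del <- ((A - A_j) - (B - B_j)) / ((A - A_j) + (B - B_j))
  se2 <- g / (g - 1) * sum(((1 - m / n) * (D - D_del))^2)
  se <- sqrt(max(se2, 0))
  list(D = D, SE = se, Z = if (se > 0) D / se else NA_real_,
       n_blocks = g, degenerate = se == 0)
}

#' One ABBA-BABA comparison
#'
#' Computes derived-allele frequencies for the four taxa sets, polarizes by
#' the outgroup, forms Patterson's D and its weighted block-jackknife Z.
#' Blocks default to one per contig (simulated windows are independent); a
#' `block_size` in bp subdivides contigs instead.
#'
#' @param x a `site_table` or dosage matrix with known site coordinates.
#' @param sets named list with elements `P1`, `P2`, `P3`, `O`, each a
#'   character vector of individuals.
#' @param contig,pos site coordinates (defaulted from the `site_table`).
#' @param mode "counts" or "gl" frequency estimation.
#' @param block_size optional block length in bp; NULL = one block per contig.
#' @param z_threshold significance threshold on |Z| (default 3).
#' @return one-row data.frame (a DStatResult): taxa, ABBA, BABA, D, SE, Z,
#'   nSites, nBlocks, significant.
#' @export
abba_baba <- function(x, sets, contig = NULL, pos = NULL,
                      mode = c("counts", "gl"), block_size = NULL,
                      z_threshold = 3) {
  mode <- match.arg(mode)
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(sets)))
  if (inherits(x, "site_table")) {
    contig <- x$sites$contig; pos <- x$sites$pos
  }
  freqs <- cbind(P1 = pop_allele_freqs(x, sets$P1, mode),
                 P2 = pop_allele_freqs(x, sets$P2, mode),
                 P3 = pop_allele_freqs(x, sets$P3, mode),
                 O = pop_allele_freqs(x, sets$O, mode))
  pol <- polarize_freqs(freqs, outgroup = "O")
  kept <- attr(pol, "kept")
  ds <- d_statistic(pol[, "P1"], pol[, "P2"], pol[, "P3"], pol[, "O"])
  idx <- kept[ds$kept]
  block <- if (is.null(block_size)) contig[idx] else
    paste(contig[idx], (pos[idx] - 1) %/% block_size, sep = ":")
  jk <- block_jackknife(ds$abba, ds$baba, block)
  data.frame(P1 = paste(sets$P1, collapse = ","),
             P2 = paste(sets$P2, collapse = ","),
             P3 = paste(sets$P3, collapse = ","),
             O = paste(sets$O, collapse = ","),
             ABBA = ds$ABBA, BABA = ds$BABA, D = jk$D, SE = jk$SE, Z = jk$Z,
             nSites = ds$n_informative, nBlocks = jk$n_blocks,
             significant = !is.na(jk$Z) & abs(jk$Z) > z_threshold,
             stringsAsFactors = FALSE)
}

#' Scan all ABBA-BABA comparisons for a population map
#'
#' Individual mode enumerates every unordered conspecific pair (P1, P2)
#' together with every P3 individual from a different non-outgroup taxon and
#' every outgroup individual. Population mode uses all individuals per taxon,
#' with P1 and P2 the designated sister taxa and P3 each remaining
#' non-outgroup taxon (with three in-group taxa this is the single possible
#' population comparison).
#'
#' @param x a `site_table` or dosage matrix.
#' @param pop_map named character vector individual -> taxon.
#' @param outgroup taxon used as O in every comparison.
#' @param mode "individual" or "population".
#' @param sisters length-2 character vector of sister taxa for population
#'   mode (default the first two non-outgroup taxa in map order).
#' @param freq_mode "counts" or "gl".
#' @param contig,pos,block_size,z_threshold passed to [abba_baba()].
#' @return data.frame with one DStatResult row per comparison.
#' @export
abba_baba_scan <- function(x, pop_map, outgroup,
                           mode = c("individual", "population"),
                           sisters = NULL, freq_mode = c("counts", "gl"),
                           contig = NULL, pos = NULL, block_size = NULL,
                           z_threshold = 3) {
  mode <- match.arg(mode)
  freq_mode <- match.arg(freq_mode)
  taxa <- unique(unname(pop_map))
  ing <- setdiff(taxa, outgroup)
  og_ind <- names(pop_map)[pop_map == outgroup]
  if (!length(og_ind)) stop("outgroup taxon has no individuals")
  empty <- ing[vapply(ing, function(t) sum(pop_map == t) == 0, logical(1))]
  if (length(empty)) warning("taxa without individuals skipped: ",
                             paste(empty, collapse = ", "))
  rows <- list()
  try_cmp <- function(sets) {
    tryCatch(abba_baba(x, sets, contig = contig, pos = pos, mode = freq_mode,
                       block_size = block_size, z_threshold = z_threshold),
             error = function(e) {
               warning(sprintf("comparison (%s; %s; %s; %s) skipped: %s",
                               paste(sets$P1, collapse = ","), paste(sets$P2, collapse = ","),
                               paste(sets$P3, collapse = ","), paste(sets$O, collapse = ","),
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  }
  if (mode == "individual") {
    for (tx in ing) {
      members <- names(pop_map)[pop_map == tx]
      if (length(members) < 2) next
      pairs <- utils::combn(members, 2)
      p3_pool <- names(pop_map)[pop_map %in% setdiff(ing, tx)]
      for (k in seq_len(ncol(pairs))) {
        for (p3 in p3_pool) {
          for (og in og_ind) {
            rows[[length(rows) + 1L]] <- try_cmp(
              list(P1 = pairs[1, k], P2 = pairs[2, k], P3 = p3, O = og))
          }
        }
      }
    }
  } else {
    if (is.null(sisters)) sisters <- ing[1:2]
    stopifnot(length(sisters) == 2, all(sisters %in% ing))
    for (p3_tax in setdiff(ing, sisters)) {
      rows[[length(rows) + 1L]] <- try_cmp(
        list(P1 = names(pop_map)[pop_map == sisters[1]],
             P2 = names(pop_map)[pop_map == sisters[2]],
             P3 = names(pop_map)[pop_map == p3_tax],
             O = og_ind))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no comparison produced a result")
  out
}
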