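# Genotype likelihoods (GATK read model), EM allele frequencies, SNP and
# triallelic likelihood-ratio tests, the filter cascade, hard calls, SNP
# thinning, damage profiling and the low-complexity read filter.

#' Filter configuration for SNP calling
#'
#' Defaults follow the conservative museum-specimen settings: base and mapping
#' quality 20, SNP p-value threshold 1e-6, per-individual depth within
#' [10, 100], at most one individual missing per site, and minor-allele
#' frequency at least 0.12.
#'
#' @param min_base_qual minimum phred base quality.
#' @param min_map_qual minimum mapping quality (metadata only for simulated
#'   pileups, which carry no mapping step).
#' @param snp_p SNP likelihood-ratio p-value threshold.
#' @param depth_min,depth_max per-individual depth bounds; genotypes outside
#'   are set missing.
#' @param max_missing maximum number of individuals allowed missing at a site.
#' @param maf_min minor-allele-frequency threshold.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_base_qual = 20, min_map_qual = 20, snp_p = 1e-6,
                          depth_min = 10, depth_max = 100, max_missing = 1,
                          maf_min = 0.12) {
  stopifnot(min_base_qual > 0, snp_p > 0, depth_min < depth_max,
            max_missing >= 0, maf_min >= 0, maf_min <= 0.5)
  structure(list(min_base_qual = min_base_qual, min_map_qual = min_map_qual,
                 snp_p = snp_p, depth_min = depth_min, depth_max = depth_max,
                 max_missing = max_missing, maf_min = maf_min),
            class = "filter_config")
}

#' Minimum minor-allele chromosome count implied by a MAF cutoff
#'
#' The smallest integer chromosome count c such that c / (2 * n_diploids)
#' reaches the MAF threshold; with 16 diploids and a 0.12 cutoff this is 4.
#'
#' @param n_diploids number of diploid individuals.
#' @param maf_min MAF threshold.
#' @return integer chromosome count.
#' @export
min_minor_chromosomes <- function(n_diploids = 16, maf_min = 0.12) {
  as.integer(ceiling(maf_min * 2 * n_diploids - 1e-12))
}

#' Genotype likelihoods for one individual at one biallelic site
#'
#' GATK read model: a read carrying base b has `P(b | allele a) = 1 - eps` if
#' `b == a` and `eps / 3` otherwise, with `eps = 10^(-Q/10)`; a heterozygote
#' mixes its two alleles with weight 1/2 each, and the genotype likelihood is
#' the product over reads. Returned on log10 scale, normalized so the maximum
#' of the triple (hom-a1, het, hom-a2) is 0. An empty read set yields an
#' all-`NA` triple (missing data), not an error.
#'
#' @param bases character vector of observed bases.
#' @param quals phred qualities (recycled).
#' @param alleles length-2 character vector (a1, a2).
#' @param normalize subtract the max log-likelihood (default TRUE).
#' @return named numeric triple `c(hom1, het, hom2)` of log10 likelihoods.
#' @export
genotype_likelihood <- function(bases, quals, alleles, normalize = TRUE) {
  stopifnot(length(alleles) == 2, all(alleles %in% BASES))
  if (!length(bases)) {
    return(c(hom1 = NA_real_, het = NA_real_, hom2 = NA_real_))
  }
  quals <- rep_len(quals, length(bases))
  eps <- 10^(-quals / 10)
  p1 <- ifelse(bases == alleles[1], 1 - eps, eps / 3)
  p2 <- ifelse(bases == alleles[2], 1 - eps, eps / 3)
  ll <- c(hom1 = sum(log10(p1)),
          het = sum(log10(0.5 * p1 + 0.5 * p2)),
          hom2 = sum(log10(p2)))
  if (normalize) ll <- ll - max(ll)
  ll
}

# Vectorized log10 GL triples from a site x individual x base count array with
# a single phred quality. Returns list(hom1, het, hom2): site x ind matrices.
gl_from_counts <- function(counts, qual, major_idx, minor_idx) {
  eps <- 10^(-qual / 10)
  n_site <- dim(counts)[1]; n_ind <- dim(counts)[2]
  l_match <- log10(1 - eps); l_mis <- log10(eps / 3)
  l_het_allele <- log10(0.5 * (1 - eps) + 0.5 * eps / 3)
  tot <- matrix(0, n_site, n_ind)
  n_maj <- matrix(0, n_site, n_ind); n_min <- matrix(0, n_site, n_ind)
  for (b in 1:4) {
    cb <- counts[, , b, drop = FALSE]; dim(cb) <- c(n_site, n_ind)
    tot <- tot + cb
    n_maj <- n_maj + cb * (major_idx == b)
    n_min <- n_min + cb * (minor_idx == b)
  }
  n_other <- tot - n_maj - n_min
  list(hom1 = n_maj * l_match + (n_min + n_other) * l_mis,
       het = (n_maj + n_min) * l_het_allele + n_other * l_mis,
       hom2 = n_min * l_match + (n_maj + n_other) * l_mis,
       depth = tot)
}

# EM for the minor-allele frequency from normalized linear-scale likelihood
# matrices (site x ind). Missing individuals (all-NA rows) are skipped.
# Returns list(f, loglik_at_f); loglik uses natural log of the per-individual
# HWE mixture.
em_maf <- function(L0, L1, L2, start = 0.25, tol = 1e-8, max_iter = 100) {
  ok <- !is.na(L0)
  n_eff <- rowSums(ok)
  f <- rep(start, nrow(L0))
  L0z <- ifelse(ok, L0, 0); L1z <- ifelse(ok, L1, 0); L2z <- ifelse(ok, L2, 0)
  for (it in seq_len(max_iter)) {
    w0 <- L0z * (1 - f)^2
    w1 <- L1z * 2 * f * (1 - f)
    w2 <- L2z * f^2
    s <- w0 + w1 + w2
    s[s == 0 | !ok] <- NA
    dose <- (w1 + 2 * w2) / s
    f_new <- rowSums(dose, na.rm = TRUE) / (2 * pmax(n_eff, 1))
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  f
}

ll_at_f <- function(L0, L1, L2, f) {
  ok <- !is.na(L0)
  m <- ifelse(ok, L0 * (1 - f)^2 + L1 * 2 * f * (1 - f) + L2 * f^2, 1)
  m[m <= 0] <- .Machine$double.xmin
  rowSums(log(m))
}

#' Call biallelic SNPs from pileups
#'
#' Per site, the two highest pooled-count alleles become major/minor; genotype
#' likelihoods use the GATK read model; the minor-allele frequency is the ML
#' estimate from an EM over genotype likelihoods under Hardy-Weinberg; the SNP
#' test is the likelihood ratio of `maf = maf_hat` versus `maf = 0`, with the
#' p-value from the boundary mixture `0.5 * delta_0 + 0.5 * chi2(1)`. Sites
#' with `p < snp_p` are retained. A third-allele test runs the same machinery
#' on (major, third-most-common) and sites significant at the same threshold
#' are flagged triallelic. Monomorphic input yields an empty table.
#'
#' @param pileups a `pileup_set`.
#' @param config a [filter_config()].
#' @return object of class `site_table`: per-site statistics data.frame
#'   (`sites`), log10 GL arrays (`gl`: site x individual x 3), and the depth
#'   matrix.
#' @export
call_snps <- function(pileups, config = filter_config()) {
  stopifnot(inherits(pileups, "pileup_set"))
  n_ind <- length(pileups$individuals)
  if (n_ind < 2) stop("call_snps needs at least 2 individuals")
  counts <- pileups$counts
  n_site <- dim(counts)[1]
  if (!n_site) return(empty_site_table(pileups$individuals))
  pooled <- apply(counts, c(1, 3), sum)
  ord <- t(apply(pooled, 1, order, decreasing = TRUE))  # ties: base order A<C<G<T
  major <- ord[, 1]; minor <- ord[, 2]; third <- ord[, 3]
  gl <- gl_from_counts(counts, pileups$qual, major, minor)
  mx <- pmax(gl$hom1, gl$het, gl$hom2)
  gl$hom1 <- gl$hom1 - mx; gl$het <- gl$het - mx; gl$hom2 <- gl$hom2 - mx
  L0 <- 10^gl$hom1; L1 <- 10^gl$het; L2 <- 10^gl$hom2
  miss <- gl$depth == 0
  L0[miss] <- NA; L1[miss] <- NA; L2[miss] <- NA
  f_hat <- em_maf(L0, L1, L2)
  lr <- 2 * (ll_at_f(L0, L1, L2, f_hat) - ll_at_f(L0, L1, L2, 0))
  lr <- pmax(lr, 0)
  p_snp <- ifelse(lr <= 0, 1, 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE))
  # third-allele test (major vs third)
  gl3 <- gl_from_counts(counts, pileups$qual, major, third)
  mx3 <- pmax(gl3$hom1, gl3$het, gl3$hom2)
  gl3$hom1 <- gl3$hom1 - mx3; gl3$het <- gl3$het - mx3; gl3$hom2 <- gl3$hom2 - mx3
  M0 <- 10^gl3$hom1; M1 <- 10^gl3$het; M2 <- 10^gl3$hom2
  M0[miss] <- NA; M1[miss] <- NA; M2[miss] <- NA
  f3 <- em_maf(M0, M1, M2)
  lr3 <- pmax(2 * (ll_at_f(M0, M1, M2, f3) - ll_at_f(M0, M1, M2, 0)), 0)
  p_tri <- ifelse(lr3 <= 0, 1, 0.5 * stats::pchisq(lr3, df = 1, lower.tail = FALSE))
  keep <- p_snp < config$snp_p
  maf <- pmin(f_hat, 1 - f_hat)
  sites <- data.frame(contig = pileups$contig, pos = pileups$pos,
                      major = BASES[major], minor = BASES[minor],
                      maf = maf, f_minor = f_hat,
                      p_snp = p_snp, p_tri = p_tri,
                      triallelic = p_tri < config$snp_p,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  gl_arr <- array(NA_real_, dim = c(sum(keep), n_ind, 3),
                  dimnames = list(NULL, pileups$individuals, c("hom_major", "het", "hom_minor")))
  gl_arr[, , 1] <- gl$hom1[keep, , drop = FALSE]
  gl_arr[, , 2] <- gl$het[keep, , drop = FALSE]
  gl_arr[, , 3] <- gl$hom2[keep, , drop = FALSE]
  gl_arr[, , 1][miss[keep, , drop = FALSE]] <- NA
  gl_arr[, , 2][miss[keep, , drop = FALSE]] <- NA
  gl_arr[, , 3][miss[keep, , drop = FALSE]] <- NA
  rownames(sites) <- NULL
  structure(list(sites = sites, gl = gl_arr,
                 depth = pileups$depth[keep, , drop = FALSE],
                 individuals = pileups$individuals,
                 filtered = FALSE, config = config),
            class = "site_table")
}

empty_site_table <- function(individuals) {
  structure(list(sites = data.frame(contig = character(0), pos = integer(0),
                                    major = character(0), minor = character(0),
                                    maf = numeric(0), f_minor = numeric(0),
                                    p_snp = numeric(0), p_tri = numeric(0),
                                    triallelic = logical(0)),
                 gl = array(NA_real_, dim = c(0, length(individuals), 3),
                            dimnames = list(NULL, individuals,
                                            c("hom_major", "het", "hom_minor"))),
                 depth = matrix(0, 0, length(individuals),
                                dimnames = list(NULL, individuals)),
                 individuals = individuals, filtered = FALSE,
                 config = filter_config()),
            class = "site_table")
}

#' Apply the depth / missingness / MAF / biallelic filter cascade
#'
#' Individual genotypes with depth below `depth_min` or above `depth_max` are
#' set missing; a site fails if more than `max_missing` individuals are
#' missing, if its ML minor-allele frequency is below `maf_min`, or if it is
#' flagged triallelic. Idempotent: the flags and pass column are recomputed
#' from scratch each call.
#'
#' @param site_table a `site_table` from [call_snps()].
#' @param config a [filter_config()].
#' @return the `site_table` with columns `n_missing`, `flag_missing`,
#'   `flag_maf`, `flag_triallelic` and `pass` added, GLs masked to NA where
#'   depth is out of bounds, and `filtered = TRUE`.
#' @export
filter_sites <- function(site_table, config = filter_config()) {
  stopifnot(inherits(site_table, "site_table"))
  st <- site_table
  bad_depth <- st$depth < config$depth_min | st$depth > config$depth_max
  for (k in 1:3) {
    slab <- st$gl[, , k]
    slab[bad_depth] <- NA_real_
    st$gl[, , k] <- slab
  }
  missing <- is.na(st$gl[, , 1, drop = FALSE])
  dim(missing) <- dim(st$depth)
  n_missing <- rowSums(missing)
  st$sites$n_missing <- n_missing
  st$sites$flag_missing <- n_missing > config$max_missing
  st$sites$flag_maf <- st$sites$maf < config$maf_min
  st$sites$flag_triallelic <- st$sites$triallelic
  st$sites$pass <- !(st$sites$flag_missing | st$sites$flag_maf | st$sites$flag_triallelic)
  st$filtered <- TRUE
  st$config <- config
  st
}

#' Keep only passing sites of a filtered site table
#' @param site_table a filtered `site_table`.
#' @return the `site_table` restricted to `pass` sites.
#' @export
passing_sites <- function(site_table) {
  stopifnot(isTRUE(site_table$filtered))
  keep <- site_table$sites$pass
  st <- site_table
  st$sites <- st$sites[keep, , drop = FALSE]
  rownames(st$sites) <- NULL
  st$gl <- st$gl[keep, , , drop = FALSE]
  st$depth <- st$depth[keep, , drop = FALSE]
  st
}

#' Hard-call genotypes as the argmax of the likelihood triple
#'
#' Per individual and site the genotype is the argmax of (hom-major, het,
#' hom-minor), reported as minor-allele dosage 0/1/2. Exact ties are reported
#' missing (NA), as are individuals whose depth falls outside the configured
#' bounds.
#'
#' @param site_table a `site_table` (filtered or not; depth bounds are applied
#'   here regardless).
#' @param config a [filter_config()].
#' @return integer matrix site x individual of minor-allele dosages with NA
#'   for missing.
#' @export
hard_call <- function(site_table, config = filter_config()) {
  stopifnot(inherits(site_table, "site_table"))
  g0 <- site_table$gl[, , 1, drop = FALSE]; dim(g0) <- dim(site_table$depth)
  g1 <- site_table$gl[, , 2, drop = FALSE]; dim(g1) <- dim(site_table$depth)
  g2 <- site_table$gl[, , 3, drop = FALSE]; dim(g2) <- dim(site_table$depth)
  dosage <- matrix(NA_integer_, nrow(g0), ncol(g0),
                   dimnames = dimnames(site_table$depth))
  mx <- pmax(g0, g1, g2)
  n_max <- (g0 == mx) + (g1 == mx) + (g2 == mx)
  dosage[which(g0 == mx & n_max == 1)] <- 0L
  dosage[which(g1 == mx & n_max == 1)] <- 1L
  dosage[which(g2 == mx & n_max == 1)] <- 2L
  dosage[site_table$depth < config$depth_min | site_table$depth > config$depth_max] <- NA_integer_
  dosage
}

#' Thin SNPs to a minimum pairwise separation
#'
#' Greedy left-to-right pass per contig: the first site of each contig is
#' kept, and every subsequent site is kept iff more than `min_sep` bp of
#' sequence separate it from the last kept site on the same contig (i.e.
#' position difference strictly greater than `min_sep`). Used to reduce
#' linkage disequilibrium before SNP-based analyses.
#'
#' @param site_table a `site_table` (sites must be sorted by contig then
#'   position; unsorted input is an error).
#' @param min_sep minimum separation in bp (default 10000).
#' @return the thinned `site_table`.
#' @export
thin_snps <- function(site_table, min_sep = 10000) {
  stopifnot(inherits(site_table, "site_table"))
  s <- site_table$sites
  if (!nrow(s)) return(site_table)
  o <- order(s$contig, s$pos)
  if (!all(o == seq_len(nrow(s)))) {
    stop("sites are not sorted by contig and position; sort them before thinning")
  }
  keep <- logical(nrow(s))
  last_contig <- ""
  last_pos <- -Inf
  for (i in seq_len(nrow(s))) {
    if (s$contig[i] != last_contig || s$pos[i] - last_pos > min_sep) {
      keep[i] <- TRUE
      last_contig <- s$contig[i]
      last_pos <- s$pos[i]
    }
  }
  st <- site_table
  st$sites <- s[keep, , drop = FALSE]
  rownames(st$sites) <- NULL
  st$gl <- st$gl[keep, , , drop = FALSE]
  st$depth <- st$depth[keep, , drop = FALSE]
  st
}

#' Estimate terminal damage profiles from aligned reads
#'
#' At each offset 0..`max_offset` from the 5' end, the frequency of read-T at
#' reference-C positions; analogously G->A from the 3' end. Fragments are
#' compared in read orientation, so reverse-strand fragments contribute the
#' same profile as their plus-strand twins. Offsets whose denominator is zero
#' are reported NA (undefined), never 0.
#'
#' @param read_set a `read_set` whose fragments carry their reference sequence.
#' @param max_offset largest offset from either end (default 24).
#' @return object of class `damage_profile`: data.frame with `offset`,
#'   `ct5` / `n_c5` (5' C->T frequency and denominator), `ga3` / `n_g3`.
#' @export
estimate_damage_profile <- function(read_set, max_offset = 24) {
  stopifnot(inherits(read_set, "read_set"))
  fr <- read_set$fragments
  ref <- charToRaw(paste(fr$ref, collapse = ""))
  obs <- charToRaw(paste(fr$seq, collapse = ""))
  len <- fr$length
  frag_of <- rep(seq_along(len), len)
  off5 <- sequence(len) - 1L
  off3 <- len[frag_of] - 1L - off5
  is_c <- ref == charToRaw("C")
  is_g <- ref == charToRaw("G")
  ct <- is_c & obs == charToRaw("T")
  ga <- is_g & obs == charToRaw("A")
  k <- max_offset
  tab <- function(flag, off) tabulate(off[flag] + 1L, nbins = k + 1L)
  n_c5 <- tab(is_c & off5 <= k, off5)
  n_ct5 <- tab(ct & off5 <= k, off5)
  n_g3 <- tab(is_g & off3 <= k, off3)
  n_ga3 <- tab(ga & off3 <= k, off3)
  structure(data.frame(offset = 0:k,
                       ct5 = ifelse(n_c5 > 0, n_ct5 / n_c5, NA_real_), n_c5 = n_c5,
                       ga3 = ifelse(n_g3 > 0, n_ga3 / n_g3, NA_real_), n_g3 = n_g3),
            class = c("damage_profile", "data.frame"))
}

#' Shannon entropy of the base composition of a read
#' @param seq character vector of read sequences.
#' @return numeric entropies in bits.
#' @export
read_entropy <- function(seq) {
  vapply(seq, function(s) {
    f <- tabulate(match(strsplit(s, "")[[1]], BASES), nbins = 4)
    p <- f[f > 0] / sum(f)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Remove low-complexity reads
#'
#' Drops fragments whose Shannon entropy over base frequencies is strictly
#' below the threshold (default 1.0 bits), reporting how many were removed.
#' A read at exactly the threshold is kept.
#'
#' @param read_set a `read_set`.
#' @param min_entropy entropy threshold in bits.
#' @return the filtered `read_set` with attribute `n_removed`.
#' @export
filter_low_complexity <- function(read_set, min_entropy = 1.0) {
  stopifnot(inherits(read_set, "read_set"))
  ent <- read_entropy(read_set$fragments$seq)
  keep <- ent >= min_entropy
  rs <- read_set
  rs$fragments <- rs$fragments[keep, , drop = FALSE]
  rownames(rs$fragments) <- NULL
  attr(rs, "n_removed") <- sum(!keep)
  rs
}
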