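# Shared fixture builders. Everything is generated in code; no stored data.

# A pileup_set built directly from a count array (sites x individuals x ACGT).
make_pileups <- function(counts, qual = 30, contig = NULL, pos = NULL) {
  n_site <- dim(counts)[1]
  if (is.null(contig)) contig <- rep("ctg1", n_site)
  if (is.null(pos)) pos <- seq_len(n_site)
  if (is.null(dimnames(counts)[[2]])) {
    dimnames(counts) <- list(NULL, paste0("ind", seq_len(dim(counts)[2])),
                             c("A", "C", "G", "T"))
  }
  structure(list(contig = contig, pos = as.integer(pos),
                 individuals = dimnames(counts)[[2]],
                 counts = counts, depth = apply(counts, c(1, 2), sum),
                 qual = qual, depth_tracks = NULL,
                 contigs = unique(contig), window_length = NA),
            class = "pileup_set")
}

# counts for one individual at one site given observed bases
base_counts <- function(...) {
  bases <- c(...)
  tabulate(match(bases, c("A", "C", "G", "T")), nbins = 4)
}

# pileup counts for a diallelic site: per individual, (n_major, n_minor) reads
diallelic_counts <- function(n_major, n_minor, major = "A", minor = "C") {
  n_ind <- length(n_major)
  cnt <- array(0L, dim = c(1, n_ind, 4),
               dimnames = list(NULL, paste0("ind", seq_len(n_ind)),
                               c("A", "C", "G", "T")))
  cnt[1, , match(major, c("A", "C", "G", "T"))] <- n_major
  cnt[1, , match(minor, c("A", "C", "G", "T"))] <- n_minor
  cnt
}

# independent Weir-Cockerham oracle via the allele-copy ANOVA formulation:
# y_ijk in {0,1} indicator of the alternate allele for copy k of individual j
# in population i; components from the mean squares MSG/MSI/MSP.
wc_anova_oracle <- function(geno_counts) {
  r <- nrow(geno_counts)
  n_i <- rowSums(geno_counts)
  y <- list()
  for (i in seq_len(r)) {
    dos <- rep(c(0, 1, 2), geno_counts[i, ])
    # two allele copies per diploid; a het is encoded (alt, ref)
    y[[i]] <- cbind(ifelse(dos >= 1, 1, 0), ifelse(dos == 2, 1, 0))
  }
  ybar_ij <- lapply(y, function(m) rowMeans(m))
  ybar_i <- vapply(ybar_ij, mean, numeric(1))
  ybar <- sum(n_i * ybar_i) / sum(n_i)
  SSG <- sum(vapply(seq_len(r), function(i) {
    sum((y[[i]] - ybar_ij[[i]])^2)
  }, numeric(1)))
  MSG <- SSG / sum(n_i)
  SSI <- sum(vapply(seq_len(r), function(i) {
    2 * sum((ybar_ij[[i]] - ybar_i[i])^2)
  }, numeric(1)))
  MSI <- SSI / sum(n_i - 1)
  SSP <- sum(2 * n_i * (ybar_i - ybar)^2)
  MSP <- SSP / (r - 1)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc != 0) a / (a + b + cc) else NA_real_)
}

# random genotype-count table for r populations (ensures >= 2 diploids each)
random_geno_counts <- function(r = 2) {
  t(vapply(seq_len(r), function(i) {
    n <- sample(2:12, 1)
    as.numeric(stats::rmultinom(1, n, prob = stats::runif(3, 0.05, 1)))
  }, numeric(3)))
}

# stack single-site count arrays along the site dimension
abind_sites <- function(...) {
  parts <- list(...)
  n_ind <- dim(parts[[1]])[2]
  out <- array(0L, dim = c(length(parts), n_ind, 4),
               dimnames = c(list(NULL), dimnames(parts[[1]])[2:3]))
  for (i in seq_along(parts)) out[i, , ] <- parts[[i]][1, , ]
  out
}

# site x ind dosage matrix -> site_table via simulated read counts
make_gl_table <- function(dosage, depth = 30, qual = 30) {
  n_min <- round(depth * dosage / 2)
  cnt <- array(0L, dim = c(nrow(dosage), ncol(dosage), 4),
               dimnames = list(NULL, colnames(dosage), c("A", "C", "G", "T")))
  cnt[, , 1] <- depth - n_min
  cnt[, , 2] <- n_min
  call_snps(make_pileups(cnt, qual = qual))
}

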