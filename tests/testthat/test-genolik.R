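# Genotype likelihoods, SNP calling, the filter cascade, thinning, damage
# profiling and the complexity filter.

test_that("the read model reproduces hand-computed likelihoods", {
  ll <- genotype_likelihood("A", 20, c("A", "C"), normalize = FALSE)
  expect_equal(unname(10^ll), c(0.99, 0.4966667, 0.0033333), tolerance = 1e-6)
  # high quality limit: the matching homozygote dominates
  ll_inf <- genotype_likelihood(rep("A", 5), 1000, c("A", "C"))
  expect_equal(unname(ll_inf["hom1"]), 0)
  expect_lt(ll_inf["het"], -1)
  expect_lt(ll_inf["hom2"], ll_inf["het"])
  # balanced support: het is the ML genotype
  ll_het <- genotype_likelihood(c(rep("A", 5), rep("C", 5)), 30, c("A", "C"))
  expect_equal(unname(which.max(ll_het)), 2)
  # no reads: missing marker, not an error
  expect_true(all(is.na(genotype_likelihood(character(0), 30, c("A", "C")))))
})

test_that("normalized GL triples have max zero", {
  cnt <- diallelic_counts(n_major = c(10, 5, 0), n_minor = c(0, 5, 10))
  st <- call_snps(make_pileups(cnt))
  mx <- apply(st$gl, c(1, 2), max)
  expect_true(all(abs(mx) < 1e-12, na.rm = TRUE))
})

test_that("monomorphic pileups yield an empty site table", {
  cnt <- array(0L, dim = c(2, 3, 4))
  cnt[, , 1] <- 30   # all-A reads everywhere
  st <- call_snps(make_pileups(cnt))
  expect_equal(nrow(st$sites), 0)
})

test_that("a fixed difference among 16 diploids is called decisively", {
  cnt <- diallelic_counts(n_major = c(rep(30, 8), rep(0, 8)),
                          n_minor = c(rep(0, 8), rep(30, 8)))
  st <- call_snps(make_pileups(cnt, qual = 30))
  expect_equal(nrow(st$sites), 1)
  expect_equal(st$sites$maf, 0.5, tolerance = 0.02)
  expect_lt(st$sites$p_snp, 1e-6)
  expect_false(st$sites$triallelic)
})

test_that("a genuine third allele triggers the triallelic flag", {
  cnt <- array(0L, dim = c(1, 10, 4))
  cnt[1, 1:4, 1] <- 30     # A
  cnt[1, 5:8, 2] <- 30     # C
  cnt[1, 9:10, 3] <- 30    # G at frequency 0.2
  st <- call_snps(make_pileups(cnt, qual = 30))
  expect_equal(nrow(st$sites), 1)
  expect_true(st$sites$triallelic)
  expect_lt(st$sites$p_tri, 1e-6)
})

test_that("the ML minor-allele frequency approaches the truth with depth", {
  set.seed(42)
  f_true <- 0.3
  n_ind <- 40
  make_site <- function(depth) {
    g <- stats::rbinom(n_ind, 2, f_true)
    n_min <- stats::rbinom(n_ind, depth, g / 2 * 0.998 + 0.001)
    diallelic_counts(n_major = depth - n_min, n_minor = n_min)
  }
  st10 <- call_snps(make_pileups(make_site(10), qual = 30))
  st100 <- call_snps(make_pileups(make_site(100), qual = 30))
  expect_lt(abs(st100$sites$f_minor - f_true), abs(st10$sites$f_minor - f_true) + 0.05)
  expect_lt(abs(st100$sites$f_minor - f_true), 0.08)
})

test_that("the filter cascade applies depth, missingness and MAF rules", {
  # 16 diploids, one individual low depth (9), one high (101), the rest 30
  n_maj <- c(5, 51, rep(15, 6), rep(30, 8))
  n_min <- c(4, 50, rep(15, 6), rep(0, 8))
  st <- call_snps(make_pileups(diallelic_counts(n_maj, n_min), qual = 30))
  stf <- filter_sites(st)
  expect_equal(stf$sites$n_missing, 2)
  expect_true(stf$sites$flag_missing)
  expect_false(stf$sites$pass)
  # exactly one missing individual and healthy MAF passes
  n_maj2 <- c(5, rep(20, 9), rep(30, 6))
  n_min2 <- c(4, rep(20, 9), rep(0, 6))
  st2 <- filter_sites(call_snps(make_pileups(diallelic_counts(n_maj2, n_min2), qual = 30)))
  expect_equal(st2$sites$n_missing, 1)
  expect_false(st2$sites$flag_missing)
  expect_gt(st2$sites$maf, 0.12)
  expect_true(st2$sites$pass)
  # idempotence
  st3 <- filter_sites(st2)
  expect_identical(st2$sites, st3$sites)
  expect_identical(st2$gl, st3$gl)
})

test_that("the MAF cutoff implies at least 4 supporting chromosomes at n = 16", {
  expect_identical(min_minor_chromosomes(16, 0.12), 4L)
  expect_identical(min_minor_chromosomes(16, 0.05), 2L)
})

test_that("site calling is invariant to individual order", {
  set.seed(8)
  cnt <- array(0L, dim = c(6, 10, 4))
  for (s in 1:6) {
    g <- stats::rbinom(10, 2, 0.4)
    cnt[s, , 1] <- 30 - g * 15
    cnt[s, , 2] <- g * 15
  }
  dimnames(cnt) <- list(NULL, paste0("ind", 1:10), c("A", "C", "G", "T"))
  st1 <- call_snps(make_pileups(cnt))
  perm <- sample(10)
  st2 <- call_snps(make_pileups(cnt[, perm, , drop = FALSE]))
  expect_identical(st1$sites[, c("contig", "pos", "major", "minor")],
                   st2$sites[, c("contig", "pos", "major", "minor")])
  expect_equal(st1$sites$maf, st2$sites$maf, tolerance = 1e-10)
})

test_that("hard calls take the argmax and respect ties and depth bounds", {
  cnt <- diallelic_counts(n_major = c(30, 15, 0, 30, 2),
                          n_minor = c(0, 15, 30, 0, 3))
  st <- call_snps(make_pileups(cnt, qual = 30))
  dos <- hard_call(st)
  expect_identical(unname(dos[1, 1:3]), c(0L, 1L, 2L))
  expect_true(is.na(dos[1, 5]))          # depth 5 is below the bound
  # an exact GL tie is missing under the documented rule
  st_tie <- st
  st_tie$gl[1, 1, ] <- c(0, 0, -5)
  expect_true(is.na(hard_call(st_tie)[1, 1]))
})

test_that("greedy thinning keeps the documented site sets", {
  mk <- function(contig, pos) {
    n <- length(pos)
    cnt <- diallelic_counts(rep(15, 4), rep(15, 4))
    st <- call_snps(make_pileups(cnt))
    st$sites <- st$sites[rep(1, n), ]
    st$sites$contig <- contig; st$sites$pos <- as.integer(pos)
    rownames(st$sites) <- NULL
    st$gl <- st$gl[rep(1, n), , , drop = FALSE]
    st$depth <- st$depth[rep(1, n), , drop = FALSE]
    st
  }
  t1 <- thin_snps(mk("c1", c(1, 5000, 12000)))
  expect_equal(t1$sites$pos, c(1, 12000))
  t2 <- thin_snps(mk(c("c1", "c2", "c3"), c(1, 2, 3)))
  expect_equal(nrow(t2$sites), 3)
  t3 <- thin_snps(mk("c1", seq(1, 20000, by = 1000)))
  expect_equal(t3$sites$pos, c(1, 11001))
  expect_error(thin_snps(mk("c1", c(5000, 1))), "sort")
})

test_that("damage profiling recovers the injected geometric curve", {
  prof <- simulate_damage_experiment(seed = 4, coverage = 10, max_offset = 3)
  expect_true(all(abs(prof$recovered_ct5 - prof$injected_ct5) < 0.02))
  expect_true(all(abs(prof$recovered_ga3 - prof$injected_ga3) < 0.02))
  # damage-free reads profile flat zero
  cfg <- species_tree_config(labels = "A", merges = NULL, ne = c(A = 100),
                             samples = c(A = 2), mu = 1e-8,
                             window_length = 5000, n_windows = 2, seed = 2)
  panel <- mutate_sequences(simulate_genealogies(cfg))
  rs0 <- fragment_and_damage(panel, damage_model(d5 = 0, d3 = 0), coverage = 3)
  p0 <- estimate_damage_profile(rs0, max_offset = 5)
  expect_true(all(p0$ct5 == 0 & p0$ga3 == 0))
})

test_that("strand orientation does not change the damage profile", {
  cfg <- species_tree_config(labels = "A", merges = NULL, ne = c(A = 100),
                             samples = c(A = 2), mu = 1e-8,
                             window_length = 10000, n_windows = 3, seed = 6)
  panel <- mutate_sequences(simulate_genealogies(cfg))
  rs <- fragment_and_damage(panel, damage_model(d5 = 0.3, d3 = 0.2, lambda = 0.5),
                            coverage = 8)
  plus <- rs; plus$fragments <- plus$fragments[plus$fragments$strand == "+", ]
  minus <- rs; minus$fragments <- minus$fragments[minus$fragments$strand == "-", ]
  pp <- estimate_damage_profile(plus, max_offset = 2)
  pm <- estimate_damage_profile(minus, max_offset = 2)
  # binomial tolerance from the smaller denominator per offset
  for (k in 1:3) {
    se <- sqrt(0.25 / min(pp$n_c5[k], pm$n_c5[k]))
    expect_lt(abs(pp$ct5[k] - pm$ct5[k]), 5 * se)
    se3 <- sqrt(0.25 / min(pp$n_g3[k], pm$n_g3[k]))
    expect_lt(abs(pp$ga3[k] - pm$ga3[k]), 5 * se3)
  }
})

test_that("low-complexity filtering removes below-threshold reads only", {
  ent <- read_entropy(c("AAAAAAAA", "ACGTACGT", "ACACACAC"))
  expect_equal(ent, c(0, 2, 1))
  rs <- structure(list(fragments = data.frame(
    seq = c("AAAAAAAA", "ACGTACGT", "ACACACAC"),
    ref = c("AAAAAAAA", "ACGTACGT", "ACACACAC"),
    length = c(8L, 8L, 8L), strand = "+",
    stringsAsFactors = FALSE)), class = "read_set")
  out <- filter_low_complexity(rs, min_entropy = 1.0)
  expect_equal(out$fragments$seq, c("ACGTACGT", "ACACACAC"))
  expect_equal(attr(out, "n_removed"), 1L)
})
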