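# Patterson's D: frequencies, polarization, point estimate against a
# pattern-count oracle, jackknife behavior, and comparison enumeration.

test_that("population frequencies come from dosages with missing excluded", {
  dos <- matrix(c(1L, 0L, 1L, 2L, NA, 2L), nrow = 2,
                dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(pop_allele_freqs(dos, "a"), c(0.5, 0))
  expect_equal(pop_allele_freqs(dos, c("a", "b", "c")), c(0.5, 2 / 3))
  dos2 <- matrix(NA_integer_, 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(is.na(pop_allele_freqs(dos2, c("a", "b"))))
})

test_that("GL-mode frequencies agree with count mode at high depth", {
  set.seed(3)
  n_ind <- 20
  f <- 0.35
  g <- stats::rbinom(n_ind, 2, f)
  cnt <- diallelic_counts(n_major = 30 - 15 * g, n_minor = 15 * g)
  st <- call_snps(make_pileups(cnt, qual = 30))
  f_gl <- pop_allele_freqs(st, st$individuals, mode = "gl")
  f_ct <- pop_allele_freqs(st, st$individuals, mode = "counts")
  expect_lt(abs(f_gl - f_ct), 0.02)
})

test_that("outgroup polarization flips frequencies and drops polymorphic sites", {
  fr <- cbind(P1 = c(0.2, 0.9, 0.5), P2 = c(0.1, 0.8, 0.5),
              P3 = c(0, 0.7, 0.5), O = c(0.1, 0.9, 0.5))
  pol <- polarize_freqs(fr, "O")
  expect_equal(nrow(pol), 2)              # the pO = 0.5 site is dropped
  expect_equal(unname(pol[2, "P1"]), 0.1) # flipped because pO > 0.5
  expect_equal(unname(pol[2, "O"]), 0.1)
  expect_equal(attr(pol, "kept"), c(1L, 2L))
})

test_that("the point estimate matches a brute-force pattern-count oracle", {
  # haploid-style 0/1 frequencies so ABBA/BABA are literal pattern counts
  tab <- rbind(c(0, 1, 1, 0),   # ABBA
               c(1, 0, 1, 0),   # BABA
               c(0, 1, 1, 0),   # ABBA
               c(0, 0, 1, 0),   # BBBA-type: uninformative
               c(1, 1, 1, 0),   # shared derived: uninformative
               c(0, 1, 0, 0))   # derived only in P2: uninformative
  ds <- d_statistic(tab[, 1], tab[, 2], tab[, 3], tab[, 4])
  n_abba <- sum(tab[, 1] == 0 & tab[, 2] == 1 & tab[, 3] == 1 & tab[, 4] == 0)
  n_baba <- sum(tab[, 1] == 1 & tab[, 2] == 0 & tab[, 3] == 1 & tab[, 4] == 0)
  expect_equal(ds$ABBA, n_abba)
  expect_equal(ds$BABA, n_baba)
  expect_equal(ds$D, (n_abba - n_baba) / (n_abba + n_baba))
  expect_equal(ds$n_informative, 3)
  # pure ABBA and exact symmetry cancellation
  expect_equal(d_statistic(0, 1, 1, 0)$D, 1)
  p <- stats::runif(50)
  expect_equal(d_statistic(p, p, stats::runif(50), rep(0, 50))$D, 0)
})

test_that("D is exactly antisymmetric in P1/P2", {
  set.seed(7)
  p1 <- stats::runif(200); p2 <- stats::runif(200)
  p3 <- stats::runif(200); pO <- stats::rbinom(200, 1, 0.1) * 0.1
  d12 <- d_statistic(p1, p2, p3, pO)$D
  d21 <- d_statistic(p2, p1, p3, pO)$D
  expect_equal(d12, -d21)
})

test_that("the jackknife flags degenerate variance and few blocks", {
  abba <- rep(2, 200); baba <- rep(1, 200)
  blk <- rep(1:20, each = 10)
  jk <- block_jackknife(abba, baba, blk)
  expect_true(jk$degenerate)
  expect_true(is.na(jk$Z))
  expect_equal(jk$D, 1 / 3)
  expect_error(block_jackknife(abba, baba, rep(1:5, each = 40)), "blocks")
})

test_that("jackknife SE tracks the truth for equal and unequal block masses", {
  set.seed(12)
  run <- function(weighted) {
    g <- 150
    m <- if (weighted) round(stats::rexp(g)^2 * 20) + 1 else rep(20, g)
    d_j <- stats::rnorm(g, 0, 0.4)
    A_j <- pmax(m * (1 + d_j) / 2, 0); B_j <- pmax(m * (1 - d_j) / 2, 0)
    jk <- block_jackknife(A_j, B_j, seq_len(g))
    c(jk$D, jk$SE)
  }
  for (weighted in c(FALSE, TRUE)) {
    r <- t(replicate(150, run(weighted)))
    ratio <- stats::sd(r[, 1]) / mean(r[, 2])
    expect_gt(ratio, 0.75)
    expect_lt(ratio, 1.35)
  }
})

test_that("comparison enumeration respects the conspecific-P1P2 rule", {
  set.seed(2)
  inds <- c(M1 = "MEL", M2 = "MEL", T1 = "TRA", T2 = "TRA",
            R1 = "ROB", A1 = "ARD")
  pm <- inds
  n_site <- 120
  dos <- matrix(stats::rbinom(n_site * 6, 2, 0.3), n_site, 6,
                dimnames = list(NULL, names(pm)))
  dos[, "A1"] <- stats::rbinom(n_site, 2, 0.05)
  contig <- rep(paste0("w", 1:12), each = 10)
  res <- abba_baba_scan(dos, pm, outgroup = "ARD", mode = "individual",
                        contig = contig, pos = rep(1:10, 12))
  # 1 MEL pair x (2 TRA + 1 ROB) + 1 TRA pair x (2 MEL + 1 ROB) = 6
  expect_equal(nrow(res), 6)
  pop <- abba_baba_scan(dos, pm, outgroup = "ARD", mode = "population",
                        sisters = c("MEL", "TRA"),
                        contig = contig, pos = rep(1:10, 12))
  expect_equal(nrow(pop), 1)
  # swapping the sister order flips the sign of D
  pop_sw <- abba_baba_scan(dos, pm, outgroup = "ARD", mode = "population",
                           sisters = c("TRA", "MEL"),
                           contig = contig, pos = rep(1:10, 12))
  expect_equal(pop$D, -pop_sw$D)
})
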