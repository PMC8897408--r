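# Consensus building, window extraction, concatenation, p-distances and
# divergence scaling.

make_consensus_fixture <- function(len = 250000, n_ind = 4, seed = 1) {
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  dosage <- matrix(integer(0), 0, n_ind,
                   dimnames = list(NULL, paste0("i", seq_len(n_ind))))
  sites <- data.frame(contig = character(0), pos = integer(0),
                      major = character(0), minor = character(0))
  trk <- matrix(30L, n_ind, len, dimnames = list(paste0("i", seq_len(n_ind)), NULL))
  build_consensus(list(c1 = ref), sites, dosage, list(c1 = trk))
}

test_that("consensus emits IUPAC hets, minor alleles, and masks by depth", {
  ref <- strrep("A", 100)
  sites <- data.frame(contig = "c1", pos = c(10, 20, 30),
                      major = c("A", "A", "A"), minor = c("G", "C", "T"))
  dosage <- matrix(c(1L, 2L, NA), 3, 2,
                   dimnames = list(NULL, c("x", "y")))
  dosage[, 2] <- c(0L, 1L, 2L)
  trk <- matrix(20L, 2, 100, dimnames = list(c("x", "y"), NULL))
  trk[1, 50] <- 9L     # below the inclusive bound of 10
  trk[1, 51] <- 10L    # exactly 10 stays
  trk[1, 52] <- 61L    # above 3 x mean 20 = 60
  trk[1, 53] <- 60L    # exactly at the bound stays
  cons <- build_consensus(list(c1 = ref), sites, dosage, list(c1 = trk),
                          mean_depth = c(x = 20, y = 20))
  x <- rawToChar(cons$seqs$c1$x)
  y <- rawToChar(cons$seqs$c1$y)
  expect_equal(substr(x, 10, 10), "R")   # A/G het
  expect_equal(substr(x, 20, 20), "C")   # hom minor
  expect_equal(substr(x, 30, 30), "N")   # missing genotype
  expect_equal(substr(x, 50, 53), "NANA")
  expect_equal(substr(y, 10, 10), "A")
  expect_equal(substr(y, 20, 20), "M")   # A/C het
  expect_equal(substr(y, 30, 30), "T")
  expect_error(build_consensus(list(c1 = ref), sites, dosage, list(c1 = trk),
                               mean_depth = c(x = 0, y = 20)), "zero")
})

test_that("window extraction follows the strict contig-length and tiling rules", {
  cons100 <- make_consensus_fixture(len = 100000)
  expect_length(extract_windows(cons100), 0)
  cons210 <- make_consensus_fixture(len = 210000)
  w <- extract_windows(cons210)
  expect_length(w, 3)
  expect_equal(vapply(w, `[[`, numeric(1), "start"), c(0, 100000, 200000))
  expect_equal(vapply(w, function(x) x$end - x$start, numeric(1)), rep(10000, 3))
})

test_that("the 50/50 completeness rule decides window retention", {
  len <- 150000
  n_ind <- 16
  set.seed(2)
  ref <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  dosage <- matrix(integer(0), 0, n_ind,
                   dimnames = list(NULL, paste0("i", seq_len(n_ind))))
  sites <- data.frame(contig = character(0), pos = integer(0),
                      major = character(0), minor = character(0))
  trk <- matrix(30L, n_ind, len, dimnames = list(paste0("i", seq_len(n_ind)), NULL))
  trk[1:6, ] <- 0L                       # six individuals fully masked
  cons <- build_consensus(list(c1 = ref), sites, dosage, list(c1 = trk),
                          mean_depth = stats::setNames(rep(30, n_ind), paste0("i", 1:n_ind)))
  expect_length(extract_windows(cons), 2)  # 10 of 16 complete -> both retained
  trk[1:9, ] <- 0L                        # only 7 of 16 with data -> dropped
  cons2 <- build_consensus(list(c1 = ref), sites, dosage, list(c1 = trk),
                           mean_depth = stats::setNames(rep(30, n_ind), paste0("i", 1:n_ind)))
  expect_length(extract_windows(cons2), 0)
})

test_that("concatenation preserves columns and the coordinate map inverts", {
  mk_win <- function(ctg, start, seq1, seq2) {
    structure(list(contig = ctg, start = start, end = start + nchar(seq1),
                   seqs = c(a = seq1, b = seq2), completeness = NULL),
              class = "window_alignment")
  }
  w1 <- mk_win("c1", 0, "ACGT", "ACGA")
  w2 <- mk_win("c1", 100000, "TTTT", "TTTA")
  w3 <- mk_win("c2", 0, "GGGG", "GGGC")
  cc <- concatenate_windows(list(w1, w2, w3))
  expect_equal(unname(nchar(cc$seqs["a"])), 12)
  m <- concat_coordinate(cc, 6)
  expect_equal(m$contig, "c1")
  expect_equal(m$pos, 100002)
  expect_equal(substr(cc$seqs["a"], 6, 6),
               substr(w2$seqs["a"], 2, 2))
  expect_error(concat_coordinate(cc, 13), "outside")
  empty <- concatenate_windows(list())
  expect_length(empty$seqs, 0)
  expect_equal(nrow(empty$map), 0)
  bad <- mk_win("c3", 0, "AAAA", "AAAA")
  names(bad$seqs) <- c("a", "zz")
  expect_error(concatenate_windows(list(w1, bad)), "zz")
})

test_that("p-distances follow the IUPAC scoring table with pairwise deletion", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))$d[1, 2], 0)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))$d[1, 2], 0.25)
  expect_equal(p_distance(c(a = "AR", b = "AA"))$d[1, 2], 0.25)
  expect_equal(p_distance(c(a = "R", b = "W"))$d[1, 2], 0.75)
  expect_equal(p_distance(c(a = "R", b = "C"))$d[1, 2], 1)
  expect_equal(p_distance(c(a = "R", b = "Y"))$d[1, 2], 1)
  # pairwise deletion: N columns are skipped per pair
  d <- p_distance(c(a = "ANAT", b = "AGTT", c = "AGAT"))
  expect_equal(d$n["a", "b"], 3)
  expect_equal(d$d["a", "b"], 1 / 3)
  expect_equal(d$d["b", "c"], 0.25)
  # symmetry and zero diagonal
  expect_true(isSymmetric(d$d))
  expect_true(all(diag(d$d) == 0))
  # a pair with zero shared columns is flagged undefined
  u <- p_distance(c(a = "NNAA", b = "AANN", c = "AAAA"))
  expect_true(is.na(u$d["a", "b"]))
  expect_match(u$undefined, "a-b")
})

test_that("divergence scaling matches the two-lineage convention", {
  cfgd <- divergence_config()
  m <- matrix(c(0, 1.1684e-3, 1.1684e-3, 0), 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  gens <- divergence_generations(m, cfgd)
  expect_equal(gens["x", "y"], 127000, tolerance = 1e-6)
  yrs <- generations_to_years(gens, cfgd)
  expect_equal(yrs["x", "y"], 469900, tolerance = 1e-6)
  expect_lt(yrs["x", "y"], 500000)
  expect_equal(divergence_generations(matrix(0, 1, 1), cfgd)[1, 1], 0)
  expect_equal(generations_to_years(2 * gens, cfgd), 2 * yrs)
})
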