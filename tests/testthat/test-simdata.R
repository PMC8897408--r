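# Coalescent + damage simulator: configuration contracts, determinism, and
# quantitative recovery of the generating parameters.

test_that("configuration invariants are enforced with informative errors", {
  expect_error(species_tree_config(mu = 0), "mu")
  expect_error(
    species_tree_config(labels = c("A", "B", "C"),
                        merges = data.frame(time = c(10, 20),
                                            child = c("B", "B"),
                                            parent = c("A", "C")),
                        ne = c(A = 10, B = 10, C = 10),
                        samples = c(A = 1, B = 1, C = 1)),
    "already merged")
  expect_error(
    species_tree_config(labels = c("A", "B"),
                        merges = data.frame(time = 10, child = "B", parent = "A"),
                        ne = c(A = 10, B = 10), samples = c(A = 1, B = 1),
                        pulses = data.frame(source = "A", target = "B",
                                            time = 5, f = 1.5)),
    "f must lie")
})

test_that("identical seed and config reproduce every stage bit-for-bit", {
  cfg <- species_tree_config(n_windows = 3, seed = 7)
  g1 <- simulate_genealogies(cfg)
  g2 <- simulate_genealogies(cfg)
  expect_identical(lapply(g1$windows, `[[`, "derived"),
                   lapply(g2$windows, `[[`, "derived"))
  p1 <- mutate_sequences(g1); p2 <- mutate_sequences(g2)
  expect_identical(p1$windows[[2]]$seqs, p2$windows[[2]]$seqs)
  pi1 <- generate_pileups(p1, depth = 15)
  pi2 <- generate_pileups(p2, depth = 15)
  expect_identical(pi1$counts, pi2$counts)
})

test_that("a single population coalesces fully with no demographic events", {
  cfg <- species_tree_config(labels = "A", merges = NULL, ne = c(A = 100),
                             samples = c(A = 3), mu = 1e-8,
                             window_length = 1000, n_windows = 5, seed = 3)
  gen <- simulate_genealogies(cfg)
  for (w in gen$windows) {
    expect_true(is.finite(w$tmrca))
    expect_true(w$tmrca > 0)
    # derived states never fixed across all haplotypes
    if (ncol(w$derived)) {
      expect_true(all(colSums(w$derived) < nrow(w$derived)))
      expect_true(all(colSums(w$derived) > 0))
    }
  }
})

test_that("pairwise differences scale as 2 mu T within binomial noise", {
  # two populations of one diploid each with negligible Ne: haplotype pairs
  # across populations have TMRCA ~= the split time
  split <- 1e5
  mu <- 4.6e-9
  cfg <- species_tree_config(labels = c("A", "B"),
                             merges = data.frame(time = split, child = "B",
                                                 parent = "A"),
                             ne = c(A = 10, B = 10),
                             samples = c(A = 1, B = 1), mu = mu,
                             window_length = 20000, n_windows = 100, seed = 11)
  gen <- simulate_genealogies(cfg)
  diffs <- sum(vapply(gen$windows, function(w) {
    if (!ncol(w$derived)) return(0)
    sum(w$derived[1, ] != w$derived[3, ])   # one haplotype from each diploid
  }, numeric(1)))
  L_total <- 100 * 20000
  expected <- 2 * mu * (split + 2 * 10) * L_total
  expect_gt(diffs, expected - 5 * sqrt(expected))
  expect_lt(diffs, expected + 5 * sqrt(expected))
})

test_that("pulse admixture moves the configured fraction of lineages", {
  cfg <- species_tree_config(
    labels = c("P1", "P2", "P3", "O"),
    merges = data.frame(time = c(10000, 30000, 60000),
                        child = c("P2", "P3", "O"),
                        parent = c("P1", "P1", "P1")),
    ne = c(P1 = 5000, P2 = 5000, P3 = 5000, O = 5000),
    samples = c(P1 = 2, P2 = 2, P3 = 2, O = 1),
    pulses = data.frame(source = "P3", target = "P2", time = 2000, f = 0.2),
    mu = 1e-9, window_length = 1000, n_windows = 500, seed = 5)
  gen <- simulate_genealogies(cfg)
  mig <- do.call(rbind, lapply(gen$windows, function(w) w$migrants))
  p_hat <- sum(mig$n_moved) / sum(mig$n_target)
  se <- sqrt(0.2 * 0.8 / sum(mig$n_target))
  expect_lt(abs(p_hat - 0.2), 4 * se)
})

test_that("undamaged fragments are exact (rev-complemented) substrings", {
  cfg <- species_tree_config(labels = "A", merges = NULL, ne = c(A = 100),
                             samples = c(A = 2), mu = 1e-7,
                             window_length = 2000, n_windows = 2, seed = 9)
  panel <- mutate_sequences(simulate_genealogies(cfg))
  rs <- fragment_and_damage(panel, damage_model(d5 = 0, d3 = 0), coverage = 2)
  fr <- rs$fragments
  expect_true(all(fr$seq == fr$ref))
  for (i in sample(nrow(fr), 20)) {
    w <- match(fr$contig[i], rs$contigs)
    hap_seq <- panel$windows[[w]]$seqs[fr$hap[i], fr$start[i]:(fr$start[i] + fr$length[i] - 1)]
    expected <- if (fr$strand[i] == "-") {
      rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", rawToChar(hap_seq)))))
    } else rawToChar(hap_seq)
    expect_identical(fr$seq[i], expected)
  }
  expect_true(all(fr$length >= 20))
})

test_that("pileups follow the truth at zero error and the phred rate otherwise", {
  cfg <- species_tree_config(labels = "A", merges = NULL, ne = c(A = 50),
                             samples = c(A = 2), mu = 1e-8,
                             window_length = 5000, n_windows = 2, seed = 13)
  gen <- simulate_genealogies(cfg)
  panel <- mutate_sequences(gen)
  # zero-error: every read matches one of the two haplotype bases
  piles <- generate_pileups(panel, depth = 30, qual = 1000, positions = "all")
  tr <- truth_set(gen)
  expect_true(all(piles$depth >= 0))
  for (w in 1:2) {
    here <- piles$contig == gen$contigs[w]
    hom_cols <- setdiff(seq_len(cfg$window_length), gen$windows[[w]]$pos)
    some <- sample(hom_cols, 50)
    for (s in some) {
      i <- which(here & piles$pos == s)
      true_base <- rawToChar(panel$windows[[w]]$seqs[1, s])
      cnt <- piles$counts[i, 1, ]
      expect_equal(unname(cnt[true_base]), unname(sum(cnt)))
    }
  }
  # Q20: non-true base fraction ~ 0.01 at hom sites
  piles20 <- generate_pileups(panel, depth = 30, qual = 20, positions = "all")
  hom <- setdiff(seq_len(cfg$window_length), gen$windows[[1]]$pos)
  idx <- which(piles20$contig == gen$contigs[1] & piles20$pos %in% hom)
  total <- 0; wrong <- 0
  for (i in idx) {
    s <- piles20$pos[i]
    true_base <- rawToChar(panel$windows[[1]]$seqs[1, s])
    cnt <- piles20$counts[i, 1, ]
    total <- total + sum(cnt)
    wrong <- wrong + sum(cnt) - cnt[true_base]
  }
  p_hat <- wrong / total
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(p_hat - 0.01), 5 * se)
})

test_that("truth set genotypes sum the two haplotypes and label windows", {
  cfg <- species_tree_config(n_windows = 2, seed = 21)
  gen <- simulate_genealogies(cfg)
  tr <- truth_set(gen)
  expect_equal(length(tr$genotypes), 2)
  w <- gen$windows[[1]]
  expect_equal(unname(tr$genotypes[[1]][1, ]),
               unname(w$derived[1, ] + w$derived[2, ]))
  expect_true(all(grepl("^\\(", tr$newick)))
})

test_that("fragment-derived pileups place bases at their reference positions", {
  cfg <- species_tree_config(labels = "A", merges = NULL, ne = c(A = 100),
                             samples = c(A = 2), mu = 1e-7,
                             window_length = 3000, n_windows = 2, seed = 17)
  gen <- simulate_genealogies(cfg)
  panel <- mutate_sequences(gen)
  rs <- fragment_and_damage(panel, damage_model(d5 = 0, d3 = 0, qual = 1000),
                            coverage = 4)
  piles <- generate_pileups(rs, qual = 1000)
  # without damage or error every piled base equals one of the two haplotypes
  for (i in sample(length(piles$pos), 40)) {
    w <- match(piles$contig[i], piles$contigs)
    pos <- piles$pos[i]
    for (j in seq_along(piles$individuals)) {
      cnt <- piles$counts[i, j, ]
      if (sum(cnt) == 0) next
      h1 <- rawToChar(panel$windows[[w]]$seqs[2 * j - 1, pos])
      h2 <- rawToChar(panel$windows[[w]]$seqs[2 * j, pos])
      expect_equal(sum(cnt[unique(c(h1, h2))]), sum(cnt))
    }
  }
  # realized mean depth is near 2 x haploid coverage
  expect_gt(mean(piles$depth), 5)
})
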