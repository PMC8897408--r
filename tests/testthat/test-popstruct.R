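# Expected dosages, PCA, admixture EM, replicate runs and Evanno DeltaK.

test_that("expected dosages are the HWE-posterior mean with mean imputation", {
  dos <- matrix(c(0, 1, 2, 1), 1, 4,
                dimnames = list(NULL, paste0("i", 1:4)))
  st <- make_gl_table(dos)
  ed <- expected_genotypes(st)
  expect_equal(unname(ed[1, ]), c(0, 1, 2, 1), tolerance = 1e-3)
  # certain hom-minor dominates any prior
  st2 <- st
  st2$gl[1, 1, ] <- c(-300, -300, 0)
  expect_equal(unname(expected_genotypes(st2, freq = 0.01)[1, 1]), 2, tolerance = 1e-6)
  # flat likelihood at freq 0.5 gives the prior mean 1
  st3 <- st
  st3$gl[1, 2, ] <- c(0, 0, 0)
  expect_equal(unname(expected_genotypes(st3, freq = 0.5)[1, 2]),
               (2 * 0.25 + 1 * 0.5) / 1, tolerance = 1e-6)
  # hand-computed Bayes fixture
  gl <- 10^c(-2, 0, -1); f <- 0.3
  w <- gl * c((1 - f)^2, 2 * f * (1 - f), f^2)
  st4 <- st
  st4$gl[1, 3, ] <- c(-2, 0, -1)
  expect_equal(unname(expected_genotypes(st4, freq = f)[1, 3]),
               sum(c(0, 1, 2) * w / sum(w)), tolerance = 1e-9)
  # missing individual imputes 2f
  st5 <- st
  st5$gl[1, 4, ] <- NA
  expect_equal(unname(expected_genotypes(st5, freq = 0.3)[1, 4]), 0.6)
})

test_that("PCA conserves variance and separates distinct populations", {
  set.seed(5)
  n <- 10
  dos <- rbind(matrix(rep(c(rep(0, 5), rep(2, 5)), 200), 200, n, byrow = TRUE),
               matrix(stats::rbinom(50 * n, 2, 0.5), 50, n))
  colnames(dos) <- paste0("i", 1:n)
  p <- gl_pca(dos)
  expect_equal(sum(p$values), sum(diag(p$cov)), tolerance = 1e-8)
  pc1 <- p$coords[, 1]
  between <- abs(mean(pc1[1:5]) - mean(pc1[6:10]))
  within <- max(stats::sd(pc1[1:5]), stats::sd(pc1[6:10]))
  expect_gt(between, 10 * within)
  # identical individuals: essentially zero variance
  flat <- matrix(1, 50, 4, dimnames = list(NULL, paste0("i", 1:4)))
  flat[1:25, ] <- 2
  p0 <- gl_pca(flat)
  expect_lt(max(abs(p0$values)), 1e-20)
})

test_that("K = 1 degenerates to the frequency model", {
  set.seed(6)
  dos <- matrix(stats::rbinom(40 * 6, 2, 0.4), 40, 6,
                dimnames = list(NULL, paste0("i", 1:6)))
  st <- make_gl_table(dos)
  m <- admixture_em(st, K = 1, seed = 2)
  expect_true(all(m$Q == 1))
  expect_equal(dim(m$F), c(nrow(st$sites), 1))
  expect_equal(as.numeric(m$F), st$sites$f_minor, tolerance = 0.02)
  expect_error(admixture_em(st, K = 7), "exceeds")
})

test_that("EM log-likelihood is monotone and Q rows stay normalized", {
  set.seed(9)
  dos <- rbind(matrix(stats::rbinom(60 * 4, 2, 0.1), 60, 4),
               matrix(stats::rbinom(60 * 4, 2, 0.8), 60, 4))
  dos <- cbind(dos, rbind(matrix(stats::rbinom(60 * 4, 2, 0.8), 60, 4),
                          matrix(stats::rbinom(60 * 4, 2, 0.1), 60, 4)))
  colnames(dos) <- paste0("i", 1:8)
  st <- make_gl_table(dos)
  for (K in 1:3) {
    m <- admixture_em(st, K, seed = K + 1)
    expect_true(all(diff(m$loglik_trace) > -1e-6))
    expect_equal(unname(rowSums(m$Q)), rep(1, 8), tolerance = 1e-9)
    expect_true(all(m$F >= 0 & m$F <= 1))
  }
})

test_that("two deeply split populations are cleanly assigned at K = 2", {
  set.seed(10)
  n_site <- 300
  f1 <- stats::rbeta(n_site, 0.4, 0.4)
  f2 <- stats::rbeta(n_site, 0.4, 0.4)
  dos <- cbind(vapply(1:5, function(i) stats::rbinom(n_site, 2, f1), numeric(n_site)),
               vapply(1:5, function(i) stats::rbinom(n_site, 2, f2), numeric(n_site)))
  colnames(dos) <- paste0("i", 1:10)
  st <- make_gl_table(dos)
  m <- admixture_em(st, 2, seed = 4)
  assign1 <- m$Q[1:5, which.max(colMeans(m$Q[1:5, ]))]
  assign2 <- m$Q[6:10, which.max(colMeans(m$Q[6:10, ]))]
  expect_gt(min(assign1), 0.95)
  expect_gt(min(assign2), 0.95)
})

test_that("replicate tables record reproducible seeds and the best model wins", {
  set.seed(11)
  dos <- matrix(stats::rbinom(50 * 6, 2, 0.4), 50, 6,
                dimnames = list(NULL, paste0("i", 1:6)))
  st <- make_gl_table(dos)
  r1 <- replicate_runs(st, K_range = 1:3, reps = 2, seed = 5, max_iter = 200)
  r2 <- replicate_runs(st, K_range = 1:3, reps = 2, seed = 5, max_iter = 200)
  expect_identical(r1$table, r2$table)
  expect_equal(nrow(r1$table), 6)
  for (K in 1:3) {
    expect_equal(r1$best[[as.character(K)]]$loglik,
                 max(r1$table$loglik[r1$table$K == K]))
  }
  r_one <- replicate_runs(st, K_range = 1:3, reps = 1, seed = 5, max_iter = 200)
  expect_equal(nrow(r_one$table), 3)
})

test_that("DeltaK reproduces the worked trace and flags degenerate cases", {
  mk <- function(means, sds, reps = 2) {
    do.call(rbind, lapply(seq_along(means), function(i) {
      data.frame(K = i, rep = seq_len(reps),
                 loglik = means[i] + sds[i] * c(-1, 1) / sqrt(2))
    }))
  }
  tab <- mk(c(-1000, -800, -790, -788), c(1, 2, 2, 2))
  dk <- delta_k(tab)
  expect_equal(dk$delta_k[2], 95)
  expect_equal(dk$delta_k[3], 4)
  expect_equal(attr(dk, "best_k"), 2)
  # linear means: zero curvature everywhere
  lin <- mk(c(-900, -800, -700, -600), c(1, 1, 1, 1))
  dk_lin <- delta_k(lin)
  expect_true(all(abs(dk_lin$lsecond[2:3]) < 1e-9))
  # zero scatter: undefined DeltaK with a warning
  z <- mk(c(-1000, -800, -790), c(1, 0, 1))
  expect_warning(dkz <- delta_k(z), "zero")
  expect_true(is.na(dkz$delta_k[2]))
  expect_error(delta_k(mk(c(-1, -2), c(1, 1))), ">= 3")
})
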