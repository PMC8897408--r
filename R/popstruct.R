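# Genotype-likelihood population structure: HWE-posterior expected dosages,
# PCA on standardized dosages, admixture EM over genotype likelihoods,
# replicate runs across K and the Evanno DeltaK model choice.

#' Expected minor-allele dosages under a Hardy-Weinberg prior
#'
#' Per individual and site the genotype posterior is proportional to
#' GL(g) * HWE(g | f) with f the site's minor-allele frequency; the expected
#' dosage is the posterior mean. Missing individuals are mean-imputed with
#' `2 * f`.
#'
#' @param site_table a `site_table` (log10 GLs).
#' @param freq per-site frequencies (default: the table's ML minor-allele
#'   frequency).
#' @return numeric matrix site x individual of expected dosages in [0, 2].
#' @export
expected_genotypes <- function(site_table, freq = site_table$sites$f_minor) {
  gl <- site_table$gl
  n_site <- dim(gl)[1]; n_ind <- dim(gl)[2]
  L0 <- 10^gl[, , 1, drop = FALSE]; dim(L0) <- c(n_site, n_ind)
  L1 <- 10^gl[, , 2, drop = FALSE]; dim(L1) <- c(n_site, n_ind)
  L2 <- 10^gl[, , 3, drop = FALSE]; dim(L2) <- c(n_site, n_ind)
  w0 <- L0 * (1 - freq)^2
  w1 <- L1 * 2 * freq * (1 - freq)
  w2 <- L2 * freq^2
  s <- w0 + w1 + w2
  e <- (w1 + 2 * w2) / s
  miss <- is.na(e)
  e[miss] <- (matrix(2 * freq, n_site, n_ind))[miss]
  dimnames(e) <- dimnames(site_table$depth)
  e
}

#' PCA of a dosage matrix
#'
#' Sites are centered at `2f` and standardized by `sqrt(2 f (1 - f))`; the
#' individual x individual covariance is averaged over sites and
#' eigendecomposed. Coordinates are eigenvectors scaled by the square root of
#' their eigenvalue. Zero-variance sites are skipped (their count is
#' reported).
#'
#' @param dosage site x individual matrix of (expected) dosages.
#' @param freq per-site frequencies used for standardization (default: mean
#'   dosage / 2).
#' @return object of class `pca_result`: `cov`, `values` (descending),
#'   `vectors`, `coords` (individual x axis), `n_skipped`.
#' @export
gl_pca <- function(dosage, freq = NULL) {
  if (ncol(dosage) < 2 || nrow(dosage) < 2) stop("need >= 2 individuals and >= 2 sites")
  if (is.null(freq)) freq <- rowMeans(dosage) / 2
  keep <- freq > 0 & freq < 1
  n_skipped <- sum(!keep)
  d <- dosage[keep, , drop = FALSE]
  f <- freq[keep]
  x <- (d - 2 * f) / sqrt(2 * f * (1 - f))
  cv <- crossprod(x) / nrow(x)
  eg <- eigen(cv, symmetric = TRUE)
  coords <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow = length(eg$values))
  rownames(coords) <- colnames(dosage)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(cov = cv, values = eg$values, vectors = eg$vectors,
                 coords = coords, n_skipped = n_skipped),
            class = "pca_result")
}

#' Admixture proportions from genotype likelihoods (EM)
#'
#' Maximizes `sum_i sum_s log sum_g GL_isg P(g | h_is)` with
#' `h_is = sum_k Q_ik F_sk` and `P(g|h) = binomial(2, h)`, via EM from a
#' random Dirichlet start for Q and jittered site frequencies for F. The
#' log-likelihood is non-decreasing across iterations and Q rows sum to 1.
#'
#' @param site_table a `site_table`.
#' @param K number of clusters (>= 1; more clusters than individuals is an
#'   error).
#' @param seed integer seed for the random start.
#' @param max_iter iteration cap (default 2000).
#' @param tol stop when the log-likelihood gain drops below this (default
#'   1e-6).
#' @return object of class `admixture_model`: `Q` (individual x K), `F`
#'   (site x K minor-allele frequencies), `loglik`, `loglik_trace`,
#'   `iterations`, `K`, `seed`.
#' @export
admixture_em <- function(site_table, K, seed = 1L, max_iter = 2000, tol = 1e-6) {
  stopifnot(K >= 1)
  gl <- site_table$gl
  n_site <- dim(gl)[1]; n_ind <- dim(gl)[2]
  if (K > n_ind) stop("K exceeds the number of individuals")
  L0 <- t(10^gl[, , 1]); L1 <- t(10^gl[, , 2]); L2 <- t(10^gl[, , 3])
  dim(L0) <- dim(L1) <- dim(L2) <- c(n_ind, n_site)
  miss <- is.na(L0)
  L0[miss] <- 1; L1[miss] <- 1; L2[miss] <- 1   # flat likelihood = no information
  set.seed(seed)
  Q <- matrix(stats::rgamma(n_ind * K, 1), n_ind, K)
  Q <- Q / rowSums(Q)
  # F starts at k-means centers of the expected dosages (randomly seeded per
  # replicate), plus jitter: random starts around the pooled frequency tend
  # to fuse clusters into local optima, while center-seeded starts cover the
  # distinct clusters from the first iteration
  F_ <- tryCatch({
    ed <- expected_genotypes(site_table)
    km <- stats::kmeans(t(ed), centers = K, nstart = 20)
    t(km$centers) / 2
  }, error = function(e) {
    matrix(pmin(pmax(site_table$sites$f_minor, 0.02), 0.98), n_site, K)
  })
  F_ <- pmin(pmax(F_ + stats::runif(n_site * K, -0.05, 0.05), 0.01), 0.99)
  dim(F_) <- c(n_site, K)
  rownames(Q) <- site_table$individuals
  trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    H <- Q %*% t(F_)                     # ind x site expected minor freq
    H <- pmin(pmax(H, 1e-9), 1 - 1e-9)
    P0 <- (1 - H)^2; P1 <- 2 * H * (1 - H); P2 <- H^2
    mix <- L0 * P0 + L1 * P1 + L2 * P2
    ll <- sum(log(mix))
    trace <- c(trace, ll)
    # posterior expected minor / major allele counts per individual-site
    eg <- (L1 * P1 + 2 * L2 * P2) / mix  # E[g]
    # attribute copies to clusters: copy from cluster k is minor w.p. F_sk,
    # so minor copies split prop. to Q_ik F_sk / H and major copies prop. to
    # Q_ik (1-F_sk) / (1-H); written as four matrix products
    A <- eg / H                           # ind x site
    B <- (2 - eg) / (1 - H)
    CA <- crossprod(A, Q)                 # site x K: sum_i (a_is/H) Q_ik
    CB <- crossprod(B, Q)
    F_num <- F_ * CA
    F_den <- F_num + (1 - F_) * CB
    Q_new <- Q * (A %*% F_ + B %*% (1 - F_))
    F_new <- F_num / pmax(F_den, 1e-12)
    Q <- Q_new / rowSums(Q_new)
    F_ <- pmin(pmax(F_new, 1e-6), 1 - 1e-6)
    if ((ll - ll_old) < tol && it > 1) break
    if (it >= max_iter) break
    ll_old <- ll
  }
  rownames(Q) <- site_table$individuals
  colnames(Q) <- paste0("k", seq_len(K))
  structure(list(Q = Q, F = F_, loglik = trace[length(trace)],
                 loglik_trace = trace, iterations = it, K = K, seed = seed),
            class = "admixture_model")
}

#' Replicate admixture runs across a range of K
#'
#' Runs [admixture_em()] `reps` times per K with recorded per-run seeds
#' (derived reproducibly from `seed`), keeping the best-likelihood model per
#' K.
#'
#' @param site_table a `site_table`.
#' @param K_range integer vector of K values (default 1:10).
#' @param reps replicates per K (default 15).
#' @param seed integer master seed.
#' @param ... passed to [admixture_em()].
#' @return object of class `admixture_replicates`: `table` (K, rep, seed,
#'   loglik) and `best` (named list of best models per K).
#' @export
replicate_runs <- function(site_table, K_range = 1:10, reps = 15, seed = 1L, ...) {
  rows <- list(); best <- list()
  for (K in K_range) {
    best_ll <- -Inf
    for (r in seq_len(reps)) {
      s <- subseed(seed, 10L + K, r)
      m <- admixture_em(site_table, K, seed = s, ...)
      rows[[length(rows) + 1L]] <- data.frame(K = K, rep = r, seed = s,
                                              loglik = m$loglik)
      if (m$loglik > best_ll) { best_ll <- m$loglik; best[[as.character(K)]] <- m }
    }
  }
  structure(list(table = do.call(rbind, rows), best = best),
            class = "admixture_replicates")
}

#' Evanno DeltaK from a replicate likelihood table
#'
#' `L'(K) = meanL(K) - meanL(K-1)`, `L''(K) = |L'(K+1) - L'(K)|`,
#' `DeltaK = L''(K) / sd(L(K))`, defined for interior K only; K values with
#' zero replicate scatter get an undefined DeltaK and are excluded from the
#' argmax with a warning.
#'
#' @param lik_table data.frame with columns `K` and `loglik` (e.g.
#'   `replicate_runs()$table`); needs >= 3 distinct K with >= 2 replicates
#'   for a defined DeltaK.
#' @return object of class `delta_k_table`: data.frame per K (mean_l, sd_l,
#'   lprime, lsecond, delta_k) with attribute `best_k`.
#' @export
delta_k <- function(lik_table) {
  if (inherits(lik_table, "admixture_replicates")) lik_table <- lik_table$table
  ks <- sort(unique(lik_table$K))
  if (length(ks) < 3) stop("DeltaK needs >= 3 distinct K values")
  mean_l <- vapply(ks, function(k) mean(lik_table$loglik[lik_table$K == k]), numeric(1))
  sd_l <- vapply(ks, function(k) stats::sd(lik_table$loglik[lik_table$K == k]), numeric(1))
  lprime <- c(NA, diff(mean_l))
  lsecond <- rep(NA_real_, length(ks))
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    if (i == 1 || i == length(ks)) next
    lsecond[i] <- abs(lprime[i + 1] - lprime[i])
    if (!is.na(sd_l[i]) && sd_l[i] > 0) dk[i] <- lsecond[i] / sd_l[i]
  }
  interior <- seq_along(ks)[-c(1, length(ks))]
  undef <- interior[is.na(dk[interior]) & !is.na(lsecond[interior])]
  if (length(undef)) {
    warning("DeltaK undefined (zero replicate scatter) at K = ",
            paste(ks[undef], collapse = ", "))
  }
  best <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  out <- data.frame(K = ks, mean_l = mean_l, sd_l = sd_l,
                    lprime = lprime, lsecond = lsecond, delta_k = dk)
  attr(out, "best_k") <- best
  class(out) <- c("delta_k_table", "data.frame")
  out
}
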