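#' Admixture model fitted by expectation-maximization
#'
#' Fits the standard K-cluster admixture model: each individual's genome is a
#' mixture of K cluster allele-frequency profiles, with ancestry proportions
#' `Q` (rows summing to 1) and cluster frequencies `P`. The log-likelihood
#' `sum_ij [ g_ij log(sum_k q_ik p_kj) + (2 - g_ij) log(1 - sum_k q_ik p_kj) ]`
#' is maximized by plain EM from a seeded random start (Dirichlet(1) rows for
#' `Q`, Uniform(0.05, 0.95) for `P`). The first `prime_steps` EM iterations
#' are always performed before convergence is checked; afterwards iteration
#' stops when the relative log-likelihood change falls below `tol`. The EM
#' log-likelihood is non-decreasing at every step. Missing genotypes are
#' simply skipped. Intended for an LD-pruned panel.
#'
#' @param table A [genotype_table()].
#' @param K Number of ancestral clusters (1 <= K <= samples).
#' @param seed Integer seed for the random initialization.
#' @param prime_steps EM iterations run before convergence checking starts
#'   (default 5).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A list of class `admixture_fit`: `K`, `Q` (samples x K), `P`
#'   (K x SNPs), `loglik`, `loglik_trace`, `n_iter`, `seed`,
#'   `cv_error` (`NA`; filled by [admixture_cv()]).
#' @export
admixture_em <- function(table, K, seed, prime_steps = 5, tol = 1e-6,
                         max_iter = 500) {
  validate_genotype_table(table)
  n <- nrow(table$samples)
  m <- nrow(table$markers)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K must not exceed the number of samples")
  set.seed(as.integer(seed))
  G <- table$calls
  obs <- !is.na(G)
  Mi <- rowSums(obs)
  if (any(Mi == 0)) stop("individual with no genotyped SNPs")
  G0 <- G; G0[!obs] <- 0L
  G2 <- 2L - G; G2[!obs] <- 0L

  Q <- matrix(stats::rexp(n * K), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  eps <- 1e-9

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Fhat <- Q %*% P
    Fhat <- pmin(pmax(Fhat, eps), 1 - eps)
    ll <- sum(G0 * log(Fhat) + G2 * log1p(-Fhat))
    loglik_trace <- c(loglik_trace, ll)

    R1 <- G0 / Fhat
    R0 <- G2 / (1 - Fhat)
    numP <- matrix(0, K, m); denP <- matrix(0, K, m)
    numQ <- matrix(0, n, K)
    for (k in seq_len(K)) {
      Ak <- (Q[, k] %o% P[k, ]) * R1        # expected counted-allele copies
      Bk <- (Q[, k] %o% (1 - P[k, ])) * R0  # expected other-allele copies
      numP[k, ] <- colSums(Ak)
      denP[k, ] <- colSums(Ak) + colSums(Bk)
      numQ[, k] <- rowSums(Ak) + rowSums(Bk)
    }
    P <- ifelse(denP > 0, numP / denP, P)
    P <- pmin(pmax(P, eps), 1 - eps)
    Q <- numQ / (2 * Mi)
    Q <- Q / rowSums(Q)

    if (it > prime_steps && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * abs(ll_old)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  structure(list(K = K, Q = Q, P = P, loglik = ll_old,
                 loglik_trace = loglik_trace, n_iter = length(loglik_trace),
                 seed = seed, cv_error = NA_real_),
            class = "admixture_fit")
}

#' Cross-validation over the number of admixture clusters
#'
#' Genotype entries are partitioned at random into `folds` folds; each fold
#' is masked in turn, the admixture model is fitted on the remainder, and the
#' masked genotypes are predicted as `2 * sum_k q_ik p_kj`. The
#' cross-validation error for a given K is the root-mean-square deviation
#' between observed and predicted masked dosages, averaged over folds; the K
#' minimizing it indicates the number of clusters supported by the data.
#' Only the *ordering* of errors over K is meaningful -- the absolute scale
#' depends on the masking loss.
#'
#' @param table A [genotype_table()].
#' @param K_range Integer vector of K values to evaluate.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed (drives both the partition and the fits).
#' @param ... Passed on to [admixture_em()] (`tol`, `max_iter`, ...).
#' @return Data frame `K`, `cv_error`, sorted by `K`.
#' @export
admixture_cv <- function(table, K_range, folds = 5, seed, ...) {
  validate_genotype_table(table)
  if (folds < 2) stop("folds must be >= 2")
  set.seed(as.integer(seed))
  obs_idx <- which(!is.na(table$calls))
  fold_id <- sample(rep_len(seq_len(folds), length(obs_idx)))
  out <- lapply(K_range, function(K) {
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      masked <- obs_idx[fold_id == f]
      train <- table
      train$calls[masked] <- NA_integer_
      fit <- admixture_em(train, K, seed = as.integer(seed) + 1000L * f + K, ...)
      pred <- 2 * (fit$Q %*% fit$P)[masked]
      errs[f] <- sqrt(mean((table$calls[masked] - pred)^2))
    }
    data.frame(K = K, cv_error = mean(errs))
  })
  res <- do.call(rbind, out)
  res[order(res$K), ]
}
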