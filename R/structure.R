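# Population-structure inference: PCA with low-rank imputation of missing
# dosages, maximum-likelihood admixture proportions by EM with genotype-fold
# cross-validation for the choice of K, and DAPC-style assignment
# cross-validation.

#' Principal component analysis of a genotype matrix
#'
#' Sites are centred; missing dosages are imputed by a few rounds of
#' low-rank SVD reconstruction seeded with per-site means (svdImpute-style);
#' scores come from the SVD of the centred, imputed matrix. Axis signs are
#' fixed deterministically (largest-magnitude score positive) so results are
#' reproducible across platforms.
#'
#' @param g a [genotype_matrix()]
#' @param n_axes number of axes returned (default 10)
#' @param impute_rounds rounds of iterative low-rank reconstruction
#'   (default 3); rank used is `min(10, samples - 1)`
#' @return list of class `pca_result`: `scores` (samples x axes, rownames =
#'   sample ids), `variance_explained` (per-axis fractions of total
#'   variance), `d` (singular values)
#' @export
run_pca <- function(g, n_axes = 10, impute_rounds = 3) {
  X <- impute_dosages(g$dosage, rounds = impute_rounds)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) stop("zero-variance genotype matrix")
  n_axes <- min(n_axes, nrow(X) - 1, ncol(X))
  sv <- svd(Xc, nu = n_axes, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes, n_axes)
  for (k in seq_len(n_axes)) {     # deterministic sign convention
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- g$samples$sample_id
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores,
                 variance_explained = ve[seq_len(n_axes)],
                 d = sv$d[seq_len(n_axes)]),
            class = "pca_result")
}

impute_dosages <- function(d, rounds = 3, rank = NULL) {
  X <- d
  storage.mode(X) <- "double"
  na <- is.na(X)
  if (!any(na)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  X[na] <- mu[col(X)[na]]
  r <- if (is.null(rank)) min(10, nrow(X) - 1) else rank
  for (it in seq_len(rounds)) {
    cm <- colMeans(X)
    Xc <- sweep(X, 2, cm)
    sv <- svd(Xc, nu = r, nv = r)
    approx <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v)) +
      matrix(cm, nrow(X), ncol(X), byrow = TRUE)
    X[na] <- approx[na]
  }
  X
}

admixture_loglik <- function(dose, miss, Q, P) {
  D1 <- Q %*% P
  D0 <- Q %*% (1 - P)
  ll <- dose * log(pmax(D1, 1e-300)) + (2 - dose) * log(pmax(D0, 1e-300))
  sum(ll[!miss])
}

#' Maximum-likelihood admixture proportions by EM
#'
#' Fits the binomial admixture model: each of an individual's two allele
#' copies at site j comes from cluster k with probability `q_ik` and is the
#' ALT allele with probability `p_kj`. Q (ancestry proportions) and P
#' (cluster allele frequencies) maximise
#' `sum_ij [ g_ij log sum_k q_ik p_kj + (2 - g_ij) log sum_k q_ik (1 - p_kj) ]`
#' over non-missing genotypes, by plain EM from a seeded random start. The
#' run stops when successive log-likelihoods differ by less than `tol`
#' (default 1e-9) or at `max_iter`.
#'
#' @param g a [genotype_matrix()] (MAF-filtered, LD-pruned input
#'   recommended)
#' @param K number of ancestral clusters
#' @param seed integer seed for the random start
#' @param tol log-likelihood convergence tolerance (default 1e-9)
#' @param max_iter iteration guard (default 10000)
#' @return list of class `admixture_fit`: `K`, `Q` (samples x K, rows on
#'   the simplex), `P` (K x sites), `loglik`, `loglik_trace`, `n_iter`,
#'   `seed`
#' @export
fit_admixture <- function(g, K, seed = 1L, tol = 1e-9, max_iter = 10000) {
  n <- n_samples(g); m <- n_sites(g)
  if (K > n) stop("K exceeds the number of samples")
  d <- g$dosage
  miss <- is.na(d)
  dose <- d; dose[miss] <- 0L
  storage.mode(dose) <- "double"
  two_minus <- 2 - dose
  two_minus[miss] <- 0
  dose[miss] <- 0
  nonmiss_i <- rowSums(!miss)
  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    D1 <- pmax(Q %*% P, 1e-300)
    D0 <- pmax(Q %*% (1 - P), 1e-300)
    W1 <- dose / D1       # per-cell weights; 0 at missing cells
    W0 <- two_minus / D0
    # expected copy counts via matrix products:
    #   A[i,k] = q_ik sum_j w1_ij p_kj,  alt[k,j] = p_kj sum_i w1_ij q_ik
    A <- Q * (W1 %*% t(P))           # expected alt copies per (i, k)
    R <- Q * (W0 %*% t(1 - P))       # expected ref copies per (i, k)
    altM <- crossprod(W1, Q) * t(P)          # m x K
    refM <- crossprod(W0, Q) * t(1 - P)
    totM <- altM + refM
    Q <- (A + R) / (2 * pmax(nonmiss_i, 1))
    Q[nonmiss_i == 0, ] <- 1 / K  # all-missing samples carry no information
    Q <- Q / rowSums(Q)   # numerical guard; rows already sum to 1
    P_new <- t(ifelse(totM > 0, altM / totM, t(P)))
    P <- P_new
    ll <- admixture_loglik(dose, miss, Q, P)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  structure(list(K = K, Q = Q, P = P, loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_iter = length(ll_trace),
                 seed = seed),
            class = "admixture_fit")
}

#' Cross-validation choice of the number of clusters K
#'
#' Masks random folds of non-missing genotype cells, refits the admixture
#' model, and scores the squared prediction error of masked dosages against
#' their fitted expectation `2 sum_k q_ik p_kj`. Returns the per-K mean
#' error over folds and replicates, and the K minimising it.
#'
#' @param g a [genotype_matrix()]
#' @param K_range integer vector of K values to compare
#' @param folds genotype-cell folds per replicate (default 5)
#' @param replicates independent repeats with fresh starts (default 5)
#' @param seed integer seed
#' @param tol,max_iter passed to [fit_admixture()]
#' @return list: `table` (data.frame K, cv_error), `best_K`
#' @export
admixture_cv <- function(g, K_range, folds = 5, replicates = 5, seed = 1L,
                         tol = 1e-6, max_iter = 2000) {
  stopifnot(length(K_range) >= 1)
  d <- g$dosage
  obs <- which(!is.na(d))
  err <- matrix(NA_real_, length(K_range), folds * replicates)
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + 7919L * rep_i)
    fold_of <- sample(rep_len(seq_len(folds), length(obs)))
    for (f in seq_len(folds)) {
      cells <- obs[fold_of == f]
      d_mask <- d
      d_mask[cells] <- NA_integer_
      g_mask <- genotype_matrix(d_mask, g$sites, g$samples)
      for (ki in seq_along(K_range)) {
        fit <- fit_admixture(g_mask, K_range[ki],
                             seed = seed + 101L * rep_i + f,
                             tol = tol, max_iter = max_iter)
        pred <- 2 * (fit$Q %*% fit$P)
        err[ki, (rep_i - 1) * folds + f] <- mean((d[cells] - pred[cells])^2)
      }
    }
  }
  tab <- data.frame(K = K_range, cv_error = rowMeans(err))
  list(table = tab, best_K = K_range[which.min(tab$cv_error)])
}

#' DAPC-style assignment cross-validation
#'
#' For each number of retained PCA axes `a = 1..max_axes` and each
#' replicate: stratified 60/40 train/test split, PCA fit on the training
#' genotypes (missing cells imputed with per-site training means), linear
#' discriminant classifier on the first `a` training axes, and the
#' proportion of held-out samples assigned to their true group. Returns the
#' mean over the whole (axis, replicate) grid — chance level for two equal
#' groups is 0.5.
#'
#' @param g a [genotype_matrix()]
#' @param labels group label per sample (>= 2 groups, each with >= 2
#'   samples)
#' @param train_frac training fraction (default 0.6)
#' @param max_axes PCA axes examined (default 10)
#' @param replicates replicates per axis count (default 20)
#' @param seed integer seed
#' @return list: `mean_accuracy`, `grid` (axes x replicates accuracy
#'   matrix)
#' @export
dapc_assignment_cv <- function(g, labels, train_frac = 0.6, max_axes = 10,
                               replicates = 20, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 labelled groups")
  if (any(table(labels) < 2)) stop("every group needs >= 2 samples")
  d <- g$dosage
  storage.mode(d) <- "double"
  n <- nrow(d)
  max_axes <- min(max_axes, n - 2)
  grid <- matrix(NA_real_, max_axes, replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + 1009L * r)
    train <- unlist(lapply(levels(labels), function(lv) {
      i <- which(labels == lv)
      sample(i, max(2, round(train_frac * length(i))))
    }))
    test <- setdiff(seq_len(n), train)
    if (!length(test)) next
    Xtr <- d[train, , drop = FALSE]
    mu <- colMeans(Xtr, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    fill <- function(X) {
      na <- is.na(X); X[na] <- mu[col(X)[na]]
      sweep(X, 2, mu)
    }
    Xtr <- fill(Xtr)
    Xte <- fill(d[test, , drop = FALSE])
    keep <- apply(Xtr, 2, stats::sd) > 0
    sv <- svd(Xtr[, keep, drop = FALSE], nu = max_axes, nv = max_axes)
    str_sc <- sv$u %*% diag(sv$d[seq_len(max_axes)], max_axes)
    ste_sc <- Xte[, keep, drop = FALSE] %*% sv$v
    for (a in seq_len(max_axes)) {
      fit <- tryCatch(
        MASS::lda(str_sc[, seq_len(a), drop = FALSE],
                  grouping = droplevels(labels[train])),
        error = function(e) NULL)
      if (is.null(fit)) next
      pr <- stats::predict(fit, ste_sc[, seq_len(a), drop = FALSE])$class
      grid[a, r] <- mean(as.character(pr) == as.character(labels[test]))
    }
  }
  list(mean_accuracy = mean(grid, na.rm = TRUE), grid = grid)
}
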