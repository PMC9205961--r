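## Mean-imputed, column-centered dosage matrix (for PCA / distance work).
impute_dosage <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g
}

#' Principal components analysis of a genotype panel
#'
#' Column-centered PCA of the dosage matrix with missing calls imputed to the
#' per-SNP mean dosage.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} (normally post-filter).
#' @param n_components number of components to return (capped at the rank).
#' @return list with \code{scores} (samples x components) and
#'   \code{explained_variance_fraction} (non-increasing, sums to <= 1).
#' @export
snpPCA <- function(x, n_components = 10) {
  if (nSamples(x) < 2) stop("PCA needs at least 2 samples")
  g <- impute_dosage(genotypes(x))
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  expl <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance_fraction = expl[seq_len(k)])
}

## Log-likelihood of the admixture model: sum over observed calls of
## g*log(P) + (2-g)*log(1-P), with P = Q F clamped away from 0/1.
admix_loglik <- function(G, O, Q, F_) {
  P <- Q %*% F_
  P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
  G0 <- G; G0[!O] <- 0L
  sum((G0 * log(P) + (2 - G0) * log(1 - P))[O])
}

#' Maximum-likelihood admixture-proportion estimation
#'
#' Fits the standard admixture likelihood — genotype dosage g at SNP j for
#' sample i is Binomial(2, sum_k q_ik f_kj) — by EM block updates from a
#' seeded random start. Rows of Q are renormalized after every update and
#' the per-iteration log-likelihood trace is retained (it is non-decreasing,
#' an EM guarantee asserted in the test suite).
#'
#' @param x a post-filter \code{\linkS4class{GenotypeMatrix}} (no
#'   monomorphic SNPs).
#' @param K number of ancestral clusters.
#' @param seed integer seed for the random start.
#' @param tol stop when the log-likelihood gain falls below this.
#' @param max_iter iteration cap; non-convergence returns the best-so-far
#'   fit with a warning.
#' @return an \code{\linkS4class{AssignmentMatrix}} (bootstrap SE slots
#'   \code{NA}); the fitted cluster allele frequencies are attached as
#'   \code{metadata} attribute \code{"freqs"} (K x SNPs).
#' @seealso \code{\link{bootstrapSE}}, \code{\link{cvChooseK}},
#'   \code{\link{combineClusters}}
#' @export
estimateAdmixture <- function(x, K, seed = 1L, tol = 1e-4, max_iter = 500L) {
  G <- genotypes(x)
  n <- nrow(G); m <- ncol(G)
  K <- as.integer(K)
  if (K < 1 || K > n) stop("K must lie in [1, nSamples]")
  O <- !is.na(G)
  G0 <- G; G0[!O] <- 0L
  storage.mode(G0) <- "double"

  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, 1, 1), n, K)
  Q <- Q / rowSums(Q)
  pj <- colSums(G0) / pmax(2 * colSums(O), 1)
  F_ <- t(vapply(seq_len(K), function(k)
    pmin(pmax(pj + stats::runif(m, -0.1, 0.1), 0.01), 0.99), numeric(m)))

  trace <- admix_loglik(G, O, Q, F_)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- Q %*% F_
    P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
    Galt <- G0 / P
    Gref <- (2 - G0) / (1 - P)
    Galt[!O] <- 0; Gref[!O] <- 0
    Qnew <- matrix(0, n, K)
    Fnew <- matrix(0, K, m)
    for (k in seq_len(K)) {
      # expected alt / ref allele counts attributed to cluster k
      Ealt <- Galt * (Q[, k] %o% F_[k, ])
      Eref <- Gref * (Q[, k] %o% (1 - F_[k, ]))
      Qnew[, k] <- rowSums(Ealt) + rowSums(Eref)
      denom <- colSums(Ealt) + colSums(Eref)
      Fnew[k, ] <- ifelse(denom > 0, colSums(Ealt) / denom, F_[k, ])
    }
    Q <- Qnew / rowSums(Qnew)
    F_ <- pmin(pmax(Fnew, 1e-6), 1 - 1e-6)
    ll <- admix_loglik(G, O, Q, F_)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM did not converge within ", max_iter,
            " iterations; returning best-so-far estimate")
  labels <- sprintf("cluster%d", seq_len(K))
  rownames(Q) <- rownames(G); colnames(Q) <- labels
  SE <- matrix(NA_real_, n, K, dimnames = dimnames(Q))
  am <- new("AssignmentMatrix", Q = Q, SE = SE, K = K,
            clusterLabels = labels, logLik = trace[length(trace)],
            logLikTrace = trace, converged = converged)
  attr(am, "freqs") <- F_
  am
}

#' Choose K by masked-entry cross-validation
#'
#' Observed genotype entries are randomly partitioned into \code{folds}
#' folds; each fold is masked in turn (so each fit sees a 1 - 1/folds
#' training share; the default 10 folds masks 10\% per fit), the admixture
#' model is fitted on the unmasked entries, masked dosages are predicted as
#' 2 * sum_k q_ik f_kj, and the CV error is the mean squared deviation over
#' masked entries. The K minimizing the error is reported.
#'
#' @param x a \code{GenotypeMatrix}.
#' @param k_range integer vector of K values to evaluate.
#' @param folds number of folds (>= 2).
#' @param seed integer seed (fold assignment and EM starts).
#' @param ... further arguments to \code{\link{estimateAdmixture}}.
#' @return list: \code{cv} (data.frame K, cv_error) and \code{best_k}.
#' @export
cvChooseK <- function(x, k_range, folds = 10L, seed = 1L, ...) {
  if (folds < 2) stop("folds must be >= 2")
  G <- genotypes(x)
  n <- nrow(G)
  if (any(k_range < 1 | k_range > n))
    stop("k_range must lie within [1, nSamples]")
  obs <- which(!is.na(G))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs)))
  err <- vapply(k_range, function(K) {
    se <- 0; cnt <- 0
    for (f in seq_len(folds)) {
      mask <- obs[fold_of == f]
      if (!length(mask))
        stop("fold ", f, " has no masked entries; reduce folds")
      Gm <- G
      Gm[mask] <- NA_integer_
      xm <- genotypeMatrix(Gm, snpMeta = snpMeta(x))
      fit <- suppressWarnings(
        estimateAdmixture(xm, K, seed = seed + f, ...))
      pred <- 2 * (ancestryQ(fit) %*% attr(fit, "freqs"))
      se <- se + sum((G[mask] - pred[mask])^2)
      cnt <- cnt + length(mask)
    }
    se / cnt
  }, numeric(1))
  cv <- data.frame(K = k_range, cv_error = err)
  list(cv = cv, best_k = k_range[which.min(err)])
}

## Greedy alignment of replicate clusters to reference clusters by
## correlation of their allele-frequency vectors. Returns a permutation or
## NULL when matching is ambiguous (degenerate correlations).
align_clusters <- function(f_ref, f_rep) {
  K <- nrow(f_ref)
  cmat <- matrix(NA_real_, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    cmat[a, b] <- suppressWarnings(stats::cor(f_ref[a, ], f_rep[b, ]))
  if (any(!is.finite(cmat))) return(NULL)
  perm <- integer(K)
  for (step in seq_len(K)) {
    best <- which(cmat == max(cmat, na.rm = TRUE), arr.ind = TRUE)
    if (nrow(best) > 1) best <- best[1, , drop = FALSE]
    perm[best[1, 1]] <- best[1, 2]
    cmat[best[1, 1], ] <- -Inf
    cmat[, best[1, 2]] <- -Inf
  }
  perm
}

#' Bootstrap standard errors for ancestry proportions
#'
#' Refits the admixture model on \code{B} SNP-resampled panels (columns
#' drawn with replacement), aligns each replicate's clusters to the point
#' estimate by greedy correlation matching of cluster allele-frequency
#' vectors, and fills the per-cell standard deviation across aligned
#' replicates into the SE slot. Replicates with ambiguous alignment are
#' dropped with a message.
#'
#' @param x a \code{GenotypeMatrix}.
#' @param K number of clusters.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param ... further arguments to \code{\link{estimateAdmixture}}.
#' @return an \code{\linkS4class{AssignmentMatrix}} with SE filled.
#' @export
bootstrapSE <- function(x, K, B = 20L, seed = 1L, ...) {
  if (B < 2) stop("B must be >= 2")
  point <- suppressWarnings(estimateAdmixture(x, K, seed = seed, ...))
  f_ref <- attr(point, "freqs")
  m <- nSnps(x)
  set.seed(seed + 777L)
  reps <- list()
  for (b in seq_len(B)) {
    cols <- sample.int(m, m, replace = TRUE)
    xb <- x[, cols]
    fit <- suppressWarnings(
      estimateAdmixture(xb, K, seed = seed + 1000L + b, ...))
    perm <- align_clusters(f_ref[, cols, drop = FALSE], attr(fit, "freqs"))
    if (is.null(perm)) {
      message("bootstrap replicate ", b, ": ambiguous cluster alignment; ",
              "replicate dropped")
      next
    }
    reps[[length(reps) + 1L]] <- ancestryQ(fit)[, perm, drop = FALSE]
  }
  if (length(reps) < 2)
    stop("fewer than 2 alignable bootstrap replicates")
  arr <- simplify2array(reps)
  SE <- apply(arr, c(1, 2), stats::sd)
  dimnames(SE) <- dimnames(ancestryQ(point))
  initialize(point, SE = SE)
}

#' Combine ancestry clusters into summed sides
#'
#' Sums ancestry fractions over a partition of the cluster labels (e.g. all
#' mallard types: wild + game-farm + feral park) and propagates bootstrap
#' uncertainty as the square root of the summed squared standard errors.
#'
#' @param am an \code{\linkS4class{AssignmentMatrix}}.
#' @param group_map named list: new label -> character vector of cluster
#'   labels; must partition \code{clusterLabels(am)}.
#' @return an \code{AssignmentMatrix} over the combined clusters.
#' @export
combineClusters <- function(am, group_map) {
  labs <- clusterLabels(am)
  flat <- unlist(group_map, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, labs))
    stop("group_map must partition the cluster labels")
  Q <- ancestryQ(am); SE <- ancestrySE(am)
  newQ <- vapply(group_map, function(members)
    rowSums(Q[, match(members, labs), drop = FALSE]), numeric(nrow(Q)))
  newSE <- vapply(group_map, function(members)
    sqrt(rowSums(SE[, match(members, labs), drop = FALSE]^2)),
    numeric(nrow(SE)))
  if (nrow(Q) == 1) {   # vapply collapses single-row panels
    newQ <- matrix(newQ, 1, dimnames = list(rownames(Q), names(group_map)))
    newSE <- matrix(newSE, 1, dimnames = list(rownames(Q), names(group_map)))
  }
  rownames(newQ) <- rownames(Q); rownames(newSE) <- rownames(Q)
  new("AssignmentMatrix", Q = newQ, SE = newSE,
      K = length(group_map), clusterLabels = names(group_map),
      logLik = am@logLik, logLikTrace = am@logLikTrace,
      converged = am@converged)
}
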