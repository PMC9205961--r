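## Append one stage's bookkeeping to a GenotypeMatrix's filter report.
append_report <- function(x, stage, input, removed) {
  rep <- filterReport(x)
  rep <- rbind(rep, data.frame(stage = stage, input = input,
                               removed = removed,
                               retained = input - removed))
  x@metadata$filter_report <- rep
  x
}

## Minor-allele frequency per SNP among non-missing calls.
snp_maf <- function(g) {
  alt <- colSums(g, na.rm = TRUE)
  n <- 2L * colSums(!is.na(g))
  p <- ifelse(n > 0, alt / n, NA_real_)
  pmin(p, 1 - p)
}

#' Minor-allele-frequency filter
#'
#' Removes SNPs whose minor-allele frequency among non-missing calls is
#' strictly below \code{maf_min}; a SNP at exactly the threshold is
#' retained. The default 0.005 drops singletons in panels of a few hundred
#' samples.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param maf_min minimum minor-allele frequency (default 0.005).
#' @return the filtered \code{GenotypeMatrix}; the stage's counts are
#'   appended to \code{\link{filterReport}}.
#' @seealso \code{\link{filterMissingness}}, \code{\link{ldPrune}}
#' @export
filterMAF <- function(x, maf_min = 0.005) {
  maf <- snp_maf(genotypes(x))
  keep <- !is.na(maf) & maf >= maf_min
  out <- x[, keep]
  out@metadata <- x@metadata
  append_report(out, "maf", nSnps(x), sum(!keep))
}

#' Per-SNP missingness filter
#'
#' Removes SNPs missing in at least \code{max_missing} of samples
#' (inclusive: a SNP missing exactly 20\% of calls is removed under the
#' default).
#'
#' @param x a \code{GenotypeMatrix}.
#' @param max_missing missing-call fraction at or above which a SNP is
#'   dropped (default 0.2).
#' @return the filtered \code{GenotypeMatrix} with an updated report.
#' @export
filterMissingness <- function(x, max_missing = 0.2) {
  g <- genotypes(x)
  frac <- colMeans(is.na(g))
  keep <- frac < max_missing
  out <- x[, keep]
  out@metadata <- x@metadata
  append_report(out, "missingness", nSnps(x), sum(!keep))
}

## Complete-pairs Pearson r^2 between two dosage vectors.
pair_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(0)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(0)
  stats::cor(a[ok], b[ok])^2
}

#' Sliding-window linkage-disequilibrium pruning
#'
#' Slides a window of \code{window_snps} consecutive SNPs (in the supplied
#' SNP order) advancing by \code{step_snps}; within a window, whenever a pair
#' of SNPs has squared Pearson correlation of dosages strictly above
#' \code{r2_max} (complete pairs only), one member of the pair is removed
#' uniformly at random. Passes repeat until no surviving pair exceeds the
#' threshold. The defaults reproduce pairwise pruning of adjacent SNPs at
#' r-squared > 0.5. A pair at exactly \code{r2_max} is retained.
#'
#' @param x a \code{GenotypeMatrix} (SNPs ordered by locus/position).
#' @param window_snps window width in SNPs (default 2).
#' @param step_snps window step in SNPs (default 1).
#' @param r2_max squared-correlation threshold (default 0.5, strict >).
#' @param seed integer seed deciding which member of an offending pair is
#'   dropped.
#' @return the pruned \code{GenotypeMatrix} with an updated report.
#' @export
ldPrune <- function(x, window_snps = 2, step_snps = 1, r2_max = 0.5,
                    seed = 1L) {
  g <- genotypes(x)
  m <- ncol(g)
  set.seed(seed)
  alive <- rep(TRUE, m)
  repeat {
    removed_this_pass <- FALSE
    idx <- which(alive)
    if (length(idx) < 2) break
    start <- 1L
    while (start <= length(idx) - 1L) {
      win <- idx[start:min(start + window_snps - 1L, length(idx))]
      win <- win[alive[win]]
      if (length(win) >= 2) {
        pairs <- utils::combn(win, 2)
        for (p in seq_len(ncol(pairs))) {
          a <- pairs[1, p]; b <- pairs[2, p]
          if (!alive[a] || !alive[b]) next
          # small epsilon so a pair at exactly r2_max is retained despite
          # floating-point noise in cor()
          if (pair_r2(g[, a], g[, b]) > r2_max + 1e-10) {
            drop <- if (stats::runif(1) < 0.5) a else b
            alive[drop] <- FALSE
            removed_this_pass <- TRUE
          }
        }
      }
      start <- start + step_snps
    }
    if (!removed_this_pass) break
  }
  out <- x[, alive]
  out@metadata <- x@metadata
  append_report(out, "ld_prune", m, sum(!alive))
}

#' Run the full SNP filtering chain
#'
#' Applies, in order: minor-allele-frequency filter, per-SNP missingness
#' filter, and sliding-window LD pruning — the order the study's PLINK
#' filtering used.
#'
#' @param x a \code{GenotypeMatrix}.
#' @param maf_min see \code{\link{filterMAF}}.
#' @param max_missing see \code{\link{filterMissingness}}.
#' @param window_snps,step_snps,r2_max,seed see \code{\link{ldPrune}}.
#' @return the filtered \code{GenotypeMatrix}; \code{\link{filterReport}}
#'   holds one row per stage.
#' @export
filterChain <- function(x, maf_min = 0.005, max_missing = 0.2,
                        window_snps = 2, step_snps = 1, r2_max = 0.5,
                        seed = 1L) {
  x <- filterMAF(x, maf_min)
  x <- filterMissingness(x, max_missing)
  ldPrune(x, window_snps, step_snps, r2_max, seed)
}
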