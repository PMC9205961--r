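#' Assignment-threshold hybrid calling
#'
#' Calls a sample a hybrid when its summed ancestry is strictly greater than
#' \code{threshold} to BOTH sides of a two-way partition of the clusters
#' (the focal taxon vs the sum of all other types, e.g. all mallard
#' lineages). Confidence intervals come from
#' \code{\link{combineClusters}} (square root of summed squared bootstrap
#' SEs); samples whose second-side CI overlaps zero are flagged
#' low-confidence.
#'
#' @param am an \code{\linkS4class{AssignmentMatrix}} (with bootstrap SEs if
#'   CI flags are wanted).
#' @param group_map named list of exactly two character vectors partitioning
#'   the cluster labels; the second entry is the "other side" whose CI is
#'   checked against zero.
#' @param threshold assignment fraction above which a side counts as
#'   substantial (default 0.10, strict >; a sample at exactly 0.10 is pure).
#' @param ci_level normal-approximation confidence level for the flags.
#' @return data.frame: \code{sample_id}, per-side q and SE, \code{call}
#'   (\code{"hybrid"} or \code{"pure-<side>"}), \code{low_confidence}.
#' @export
callHybridsAssignment <- function(am, group_map, threshold = 0.10,
                                  ci_level = 0.95) {
  if (length(group_map) != 2)
    stop("group_map must define exactly two sides")
  if (length(intersect(group_map[[1]], group_map[[2]])))
    stop("the two sides must be disjoint")
  comb <- combineClusters(am, group_map)
  Q <- ancestryQ(comb); SE <- ancestrySE(comb)
  sides <- clusterLabels(comb)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  hyb <- Q[, 1] > threshold & Q[, 2] > threshold
  call <- ifelse(hyb, "hybrid",
                 paste0("pure-", sides[max.col(Q, ties.method = "first")]))
  lowconf <- if (all(is.na(SE[, 2]))) NA else (Q[, 2] - z * SE[, 2]) <= 0
  out <- data.frame(sample_id = rownames(Q),
                    q_a = Q[, 1], q_b = Q[, 2],
                    se_a = SE[, 1], se_b = SE[, 2],
                    call = call, low_confidence = lowconf,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:5] <- c(paste0("q_", sides), paste0("se_", sides))
  out
}

#' Co-ancestry hybrid calling
#'
#' A sample is called hybrid when its mean co-ancestry to EACH parental
#' reference group strictly exceeds the between-group background (the grand
#' mean co-ancestry between the two parental groups), AND its dendrogram
#' attachment lies outside both parental clades (its cophenetic merge height
#' with every member of a clade exceeds that clade's maximal internal merge
#' height). Samples with higher co-ancestry to a designated domestic group
#' than to wild mallards get a feral-parent suspicion flag.
#'
#' @param cm a \code{\linkS4class{CoancestryMatrix}}.
#' @param labels per-sample reference labels (defaults to the matrix's
#'   groups); only samples labelled with a side's group names form that
#'   side's reference set.
#' @param side_a,side_b character vectors of group labels making up the two
#'   parental sides (e.g. the Mexican duck populations vs all mallard
#'   clusters). Each side needs >= 2 reference samples.
#' @param domestic_groups,wild_groups optional label subsets of
#'   \code{side_b} used for the feral-parent flag.
#' @return data.frame: \code{sample_id}, mean co-ancestry to each side,
#'   \code{background}, \code{outside_clades}, \code{call}, \code{feral_flag}.
#' @export
callHybridsCoancestry <- function(cm, side_a, side_b, labels = NULL,
                                  domestic_groups = NULL,
                                  wild_groups = NULL) {
  C <- coancestry(cm)
  ids <- rownames(C)
  if (is.null(labels)) labels <- cm@groups
  a_idx <- which(labels %in% side_a)
  b_idx <- which(labels %in% side_b)
  if (length(a_idx) < 2 || length(b_idx) < 2)
    stop("each parental reference group needs >= 2 members")

  background <- mean(C[a_idx, b_idx], na.rm = TRUE)
  coph <- stats::cophenetic(cm@dendrogram)
  coph <- as.matrix(coph)[ids, ids]

  # a sample is "outside" the parental clades when its dendrogram merge
  # height with every single reference population exceeds that population's
  # internal maximal merge height (i.e. it sits inside no parental clade)
  ref_groups <- intersect(unique(labels), c(side_a, side_b))
  group_idx <- lapply(ref_groups, function(g) which(labels == g))
  group_max <- vapply(group_idx, function(idx) {
    if (length(idx) < 2) return(0)
    max(coph[idx, idx])
  }, numeric(1))

  mean_to <- function(s, idx) {
    idx2 <- setdiff(idx, s)
    mean(C[s, idx2], na.rm = TRUE)
  }
  n <- length(ids)
  mean_a <- vapply(seq_len(n), mean_to, numeric(1), idx = a_idx)
  mean_b <- vapply(seq_len(n), mean_to, numeric(1), idx = b_idx)
  outside <- vapply(seq_len(n), function(s) {
    all(vapply(seq_along(group_idx), function(gi) {
      idx <- setdiff(group_idx[[gi]], s)
      if (!length(idx)) return(TRUE)
      min(coph[s, idx]) > group_max[gi]
    }, logical(1)))
  }, logical(1))

  hyb <- mean_a > background & mean_b > background & outside
  call <- ifelse(hyb, "hybrid",
                 ifelse(mean_a >= mean_b, "pure-side_a", "pure-side_b"))

  feral <- rep(NA, n)
  if (!is.null(domestic_groups) && !is.null(wild_groups)) {
    d_idx <- which(labels %in% domestic_groups)
    w_idx <- which(labels %in% wild_groups)
    if (length(d_idx) && length(w_idx)) {
      mean_d <- vapply(seq_len(n), mean_to, numeric(1), idx = d_idx)
      mean_w <- vapply(seq_len(n), mean_to, numeric(1), idx = w_idx)
      feral <- hyb & mean_d > mean_w
    }
  }
  data.frame(sample_id = ids, mean_co_a = mean_a, mean_co_b = mean_b,
             background = background, outside_clades = outside,
             call = call, feral_flag = feral,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance between two hybrid-call vectors
#'
#' Cross-tabulates the calls of two rules over the same sample set and lists
#' the samples called hybrid by one rule only.
#'
#' @param calls_a,calls_b data.frames with \code{sample_id} and \code{call}
#'   (as returned by the two callers).
#' @return a \code{\linkS4class{HybridCallReport}}.
#' @export
concordance <- function(calls_a, calls_b) {
  if (!setequal(calls_a$sample_id, calls_b$sample_id))
    stop("the two call sets cover different samples")
  b <- calls_b[match(calls_a$sample_id, calls_b$sample_id), ]
  hyb_a <- calls_a$call == "hybrid"
  hyb_b <- b$call == "hybrid"
  per <- data.frame(sample_id = calls_a$sample_id,
                    call_a = calls_a$call, call_b = b$call,
                    agree = hyb_a == hyb_b,
                    stringsAsFactors = FALSE)
  smry <- list(
    n_hybrid_a = sum(hyb_a), n_hybrid_b = sum(hyb_b),
    n_both = sum(hyb_a & hyb_b),
    only_a = per$sample_id[hyb_a & !hyb_b],
    only_b = per$sample_id[hyb_b & !hyb_a],
    crosstab = table(rule_a = ifelse(hyb_a, "hybrid", "pure"),
                     rule_b = ifelse(hyb_b, "hybrid", "pure"))
  )
  new("HybridCallReport", perSample = per, summary = smry)
}
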