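#' Rarity-weighted co-ancestry matrix
#'
#' For each SNP j with minor-allele frequency p_j, the pairwise sharing
#' between two samples is the fraction of allele copies they share at j
#' (1 - |g_a - g_b| / 2 on dosages; complete pairs only). The co-ancestry of
#' a pair is the weighted average of sharing over SNPs with weight
#' w_j = -log(p_j), so the rarest SNPs contribute the most information. This
#' is a documented simplified analogue of chromosome-painting co-ancestry:
#' decision rules built on it (sibling detection, hybrid calling) match the
#' study's usage, but the numeric scale is this package's own.
#'
#' An average-linkage dendrogram over 1 - C accompanies the matrix, and
#' group-by-group mean co-ancestry is averaged directly from C.
#'
#' @param x a filtered \code{\linkS4class{GenotypeMatrix}}.
#' @param groups per-sample group labels (defaults to one group).
#' @return a \code{\linkS4class{CoancestryMatrix}}. Pairs with no jointly
#'   observed SNP get \code{NA}.
#' @export
coancestryMatrix <- function(x, groups = NULL) {
  g <- genotypes(x)
  n <- nrow(g)
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) stop("groups must have one label per sample")

  p <- snp_maf(g)
  w <- -log(pmax(p, 1e-6))
  O <- !is.na(g); storage.mode(O) <- "double"
  I0 <- (g == 0L) & !is.na(g); storage.mode(I0) <- "double"; I0[is.na(I0)] <- 0
  I1 <- (g == 1L) & !is.na(g); storage.mode(I1) <- "double"; I1[is.na(I1)] <- 0
  I2 <- (g == 2L) & !is.na(g); storage.mode(I2) <- "double"; I2[is.na(I2)] <- 0
  I0w <- sweep(I0, 2, w, "*"); I1w <- sweep(I1, 2, w, "*")
  I2w <- sweep(I2, 2, w, "*"); Ow <- sweep(O, 2, w, "*")

  # weighted sum of |g_a - g_b| over jointly observed SNPs
  A <- I0w %*% t(I1) + I1w %*% t(I0) + I1w %*% t(I2) + I2w %*% t(I1) +
    2 * (I0w %*% t(I2) + I2w %*% t(I0))
  D <- Ow %*% t(O)
  C <- 1 - A / (2 * D)
  C[D == 0] <- NA_real_
  C <- (C + t(C)) / 2
  dimnames(C) <- list(rownames(g), rownames(g))

  d <- 1 - C
  d[is.na(d)] <- max(d, na.rm = TRUE)
  dendro <- stats::hclust(stats::as.dist(d), method = "average")

  gl <- sort(unique(groups))
  gm <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  for (a in seq_along(gl)) for (b in seq_along(gl)) {
    block <- C[groups == gl[a], groups == gl[b], drop = FALSE]
    if (a == b) {
      if (nrow(block) > 1) diag(block) <- NA
      else block[] <- NA
    }
    gm[a, b] <- mean(block, na.rm = TRUE)
  }
  new("CoancestryMatrix", cmatrix = C, groups = groups, groupMeans = gm,
      dendrogram = dendro)
}

## Off-diagonal within-group coancestry values for one group.
within_group_values <- function(C, groups, g) {
  idx <- which(groups == g)
  if (length(idx) < 2) return(numeric(0))
  block <- C[idx, idx]
  block[upper.tri(block)]
}

#' Detect full-sibling groups from elevated co-ancestry
#'
#' Flags within-group sample pairs whose co-ancestry exceeds that group's
#' mean off-diagonal co-ancestry by more than \code{t_sd} standard
#' deviations, merges flagged pairs into groups by transitive closure, and
#' corroborates each group against the sampling metadata (all members share
#' a site) and the mtDNA haplotype table (all members share a haplotype).
#' A group failing an available corroboration is retained but flagged
#' unconfirmed; a missing haplotype table leaves that flag unknown. The
#' representative of each group is the lexicographically first sample id.
#'
#' @param cm a \code{\linkS4class{CoancestryMatrix}} built with the sampling
#'   groups of interest.
#' @param meta data.frame with \code{sample_id} and \code{site} for every
#'   sample in \code{cm}.
#' @param haplotypes optional data.frame with \code{sample_id} and
#'   \code{haplotype} (e.g. from \code{\link{collapseHaplotypes}}).
#' @param t_sd threshold in within-group standard deviations (default 3).
#' @return a \code{\linkS4class{SiblingGroups}}.
#' @export
detectSiblings <- function(cm, meta, haplotypes = NULL, t_sd = 3) {
  C <- coancestry(cm)
  ids <- rownames(C)
  if (!all(ids %in% meta$sample_id))
    stop("metadata missing for some samples")
  groups <- cm@groups

  # per-group baseline; groups too small for an SD fall back to the pooled
  # within-group distribution
  pooled <- unlist(lapply(unique(groups), function(g)
    within_group_values(C, groups, g)))
  pm <- mean(pooled, na.rm = TRUE); psd <- stats::sd(pooled, na.rm = TRUE)

  edges <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    vals <- within_group_values(C, groups, g)
    mu <- mean(vals, na.rm = TRUE); sdv <- stats::sd(vals, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) { mu <- pm; sdv <- psd }
    if (!is.finite(sdv) || sdv == 0) next
    thr <- mu + t_sd * sdv
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      cc <- C[idx[a], idx[b]]
      if (!is.na(cc) && cc > thr)
        edges[[length(edges) + 1L]] <- c(ids[idx[a]], ids[idx[b]])
    }
  }

  # transitive closure over flagged pairs
  memb <- list()
  for (e in edges) {
    hit <- which(vapply(memb, function(s) any(e %in% s), logical(1)))
    if (!length(hit)) memb[[length(memb) + 1L]] <- e
    else {
      merged <- unique(c(unlist(memb[hit]), e))
      memb <- memb[-hit]
      memb[[length(memb) + 1L]] <- merged
    }
  }
  memb <- lapply(memb, sort)

  if (!length(memb)) {
    return(new("SiblingGroups", groups = list(),
               evidence = data.frame(group = character(0),
                                     mean_coancestry = numeric(0),
                                     same_site = logical(0),
                                     same_haplotype = logical(0),
                                     confirmed = logical(0),
                                     representative = character(0))))
  }

  site_of <- stats::setNames(meta$site, meta$sample_id)
  hap_of <- if (!is.null(haplotypes))
    stats::setNames(haplotypes$haplotype, haplotypes$sample_id) else NULL
  ev <- do.call(rbind, lapply(seq_along(memb), function(i) {
    s <- memb[[i]]
    block <- C[s, s]
    same_site <- length(unique(site_of[s])) == 1
    same_hap <- if (is.null(hap_of) || any(!s %in% names(hap_of)))
      NA else length(unique(hap_of[s])) == 1
    data.frame(group = sprintf("sibgroup%02d", i),
               mean_coancestry = mean(block[upper.tri(block)], na.rm = TRUE),
               same_site = same_site,
               same_haplotype = same_hap,
               confirmed = same_site && (is.na(same_hap) || same_hap),
               representative = s[1],
               stringsAsFactors = FALSE)
  }))
  new("SiblingGroups", groups = memb, evidence = ev)
}

#' Drop sibling-group members down to one representative
#'
#' Removes every member of each detected sibling group except its
#' representative, so downstream structure analyses are not biased by
#' family replication. Removes sum(group size - 1) samples.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param sibs a \code{\linkS4class{SiblingGroups}}.
#' @param confirmed_only drop members of confirmed groups only.
#' @return the reduced \code{GenotypeMatrix}.
#' @export
dropToRepresentatives <- function(x, sibs, confirmed_only = FALSE) {
  groups <- siblingGroups(sibs)
  if (confirmed_only) groups <- groups[sibs@evidence$confirmed]
  reps <- if (confirmed_only)
    sibs@evidence$representative[sibs@evidence$confirmed]
  else sibs@evidence$representative
  drop <- setdiff(unlist(groups), reps)
  keep <- setdiff(sampleIds(x), drop)
  x[match(keep, sampleIds(x)), ]
}
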