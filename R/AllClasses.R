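#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

CHROM_CLASSES <- c("autosomal", "Z")
COHORTS <- c("MI", "MA", "FI", "FA")

#' GenotypeMatrix: bi-allelic SNP genotypes with per-SNP metadata
#'
#' Samples x SNPs matrix of alternate-allele dosages in \{0, 1, 2, NA\},
#' with per-SNP metadata (locus id, position, chromosome class) and a
#' metadata list that accumulates filtering reports.
#'
#' @slot geno integer matrix, samples in rows (rownames are sample ids),
#'   SNPs in columns; \code{NA} encodes a missing call.
#' @slot snpMeta \code{DataFrame} with one row per SNP: \code{locus},
#'   \code{position}, \code{chrom_class} (\code{"autosomal"} or \code{"Z"}).
#' @slot metadata list; filtering stages append their
#'   \code{\link{filterReport}} rows here.
#'
#' @seealso \code{\link{genotypeMatrix}}, \code{\link{filterMAF}},
#'   \code{\link{snpPCA}}, \code{\link{estimateAdmixture}}
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(geno = "matrix", snpMeta = "DataFrame", metadata = "list"),
  prototype(metadata = list())
)

setValidity("GenotypeMatrix", function(object) {
  g <- object@geno
  msg <- character()
  if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
    msg <- c(msg, "geno must have unique sample ids as rownames")
  if (nrow(object@snpMeta) != ncol(g))
    msg <- c(msg, "snpMeta must have one row per SNP column")
  if (!all(c("locus", "position", "chrom_class") %in% colnames(object@snpMeta)))
    msg <- c(msg, "snpMeta needs columns locus, position, chrom_class")
  else if (!all(object@snpMeta$chrom_class %in% CHROM_CLASSES))
    msg <- c(msg, "chrom_class must be 'autosomal' or 'Z'")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% 0:2))
    msg <- c(msg, "genotypes must be alternate-allele counts in {0,1,2}")
  if (length(msg)) msg else TRUE
})

#' AssignmentMatrix: per-sample ancestry proportions
#'
#' Holds the Q matrix of per-sample ancestry fractions over K clusters,
#' optional bootstrap standard errors, and the fitted log-likelihood.
#'
#' @slot Q numeric matrix, samples x K; rows sum to 1.
#' @slot SE numeric matrix of bootstrap standard errors, same shape as Q
#'   (all \code{NA} until \code{\link{bootstrapSE}} fills it).
#' @slot K integer cluster count.
#' @slot clusterLabels character vector of length K.
#' @slot logLik numeric; final log-likelihood of the admixture model.
#' @slot logLikTrace numeric; per-iteration log-likelihood (non-decreasing).
#' @slot converged logical.
#'
#' @seealso \code{\link{estimateAdmixture}}, \code{\link{combineClusters}}
#' @exportClass AssignmentMatrix
setClass("AssignmentMatrix",
  representation(Q = "matrix", SE = "matrix", K = "integer",
                 clusterLabels = "character", logLik = "numeric",
                 logLikTrace = "numeric", converged = "logical")
)

setValidity("AssignmentMatrix", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@K)
    msg <- c(msg, "Q must have K columns")
  if (any(object@Q < -1e-12))
    msg <- c(msg, "Q entries must be non-negative")
  if (any(abs(rowSums(object@Q) - 1) > 1e-8))
    msg <- c(msg, "Q rows must sum to 1 (tolerance 1e-8)")
  if (!identical(dim(object@SE), dim(object@Q)))
    msg <- c(msg, "SE must have the same shape as Q")
  se <- object@SE[!is.na(object@SE)]
  if (length(se) && any(se < 0))
    msg <- c(msg, "SE entries must be non-negative")
  if (length(object@clusterLabels) != object@K)
    msg <- c(msg, "clusterLabels must have length K")
  if (length(msg)) msg else TRUE
})

#' CoancestryMatrix: rarity-weighted allele-sharing similarity
#'
#' Symmetric samples x samples similarity emphasizing rare shared alleles,
#' with group-averaged means and an average-linkage dendrogram.
#'
#' @slot cmatrix numeric symmetric matrix; \code{NA} marks pairs with no
#'   jointly observed SNP.
#' @slot groups character; per-sample group label used for the group means.
#' @slot groupMeans numeric matrix of group x group average coancestry.
#' @slot dendrogram an \code{hclust} merge tree over samples.
#'
#' @seealso \code{\link{coancestryMatrix}}, \code{\link{detectSiblings}}
#' @exportClass CoancestryMatrix
setClass("CoancestryMatrix",
  representation(cmatrix = "matrix", groups = "character", groupMeans = "matrix",
                 dendrogram = "ANY")
)

setValidity("CoancestryMatrix", function(object) {
  C <- object@cmatrix
  msg <- character()
  if (nrow(C) != ncol(C)) msg <- c(msg, "C must be square")
  else {
    if (!isTRUE(all.equal(C, t(C), check.attributes = FALSE)))
      msg <- c(msg, "C must be symmetric")
    off <- C; diag(off) <- NA
    bad <- which(diag(C) < apply(off, 1, max, na.rm = TRUE) - 1e-9)
    if (length(bad))
      msg <- c(msg, "diagonal of C must be row-maximal")
  }
  if (length(object@groups) != nrow(C))
    msg <- c(msg, "groups must have one label per sample")
  if (length(msg)) msg else TRUE
})

#' SiblingGroups: detected full-sibling clusters
#'
#' Disjoint groups of sample ids flagged as putative full siblings from
#' elevated pairwise coancestry, with corroborating evidence (shared
#' sampling site, shared mtDNA haplotype) and a chosen representative.
#'
#' @slot groups list of character vectors (sample ids), each of size >= 2.
#' @slot evidence data.frame with one row per group: \code{group},
#'   \code{mean_coancestry}, \code{same_site}, \code{same_haplotype}
#'   (\code{TRUE}/\code{FALSE}/\code{NA} = unknown), \code{confirmed},
#'   \code{representative}.
#'
#' @seealso \code{\link{detectSiblings}}, \code{\link{dropToRepresentatives}}
#' @exportClass SiblingGroups
setClass("SiblingGroups",
  representation(groups = "list", evidence = "data.frame")
)

setValidity("SiblingGroups", function(object) {
  ids <- unlist(object@groups)
  msg <- character()
  if (anyDuplicated(ids)) msg <- c(msg, "sibling groups must be disjoint")
  if (length(object@groups) && any(lengths(object@groups) < 2))
    msg <- c(msg, "every sibling group must have size >= 2")
  if (nrow(object@evidence) != length(object@groups))
    msg <- c(msg, "evidence must have one row per group")
  if (length(msg)) msg else TRUE
})

#' TraitSchema: the ordinal trait-coding table
#'
#' The packaged default transcribes the study's trait table: 16 plumage
#' traits coded with consecutive ordinal scores starting at 0 (the focal
#' Mexican-duck state), plus 6 structural traits and mass. Each trait lists
#' the sex-age cohorts (MI, MA, FI, FA) it applies to and a provisional
#' per-cohort diagnostic flag.
#'
#' @slot traits data.frame, one row per trait: \code{trait}, \code{kind}
#'   (plumage/structural/mass), \code{max_score}, logical applicability
#'   columns \code{MI},\code{MA},\code{FI},\code{FA}, and diagnostic flags
#'   \code{diag_MI}..\code{diag_FA}.
#' @slot levels named list (plumage traits only) of data.frames with
#'   \code{score} and \code{state} columns.
#'
#' @seealso \code{\link{loadTraitSchema}}, \code{\link{scorePlumage}}
#' @exportClass TraitSchema
setClass("TraitSchema",
  representation(traits = "data.frame", levels = "list")
)

setValidity("TraitSchema", function(object) {
  tr <- object@traits
  msg <- character()
  if (anyDuplicated(tr$trait)) msg <- c(msg, "duplicate trait names")
  pl <- tr$trait[tr$kind == "plumage"]
  if (!all(pl %in% names(object@levels)))
    msg <- c(msg, "every plumage trait needs a levels table")
  for (nm in intersect(pl, names(object@levels))) {
    sc <- sort(object@levels[[nm]]$score)
    if (length(sc) < 2)
      msg <- c(msg, sprintf("trait '%s' must have >= 2 levels", nm))
    if (!identical(sc, seq(0L, length(sc) - 1L)))
      msg <- c(msg, sprintf(
        "trait '%s': ordinal scores must be consecutive integers from 0", nm))
  }
  if (length(msg)) msg else TRUE
})

#' CohortKey: plumage-score class intervals for one sex-age cohort
#'
#' Maps plumage-score (PS) intervals to classes. The Mexican-duck class is
#' always [0, 4]; hybrid and mallard intervals are calibrated from a
#' genetically vetted reference panel and merged into one
#' \code{"hybrid/mallard"} class when their observed PS ranges overlap.
#'
#' @slot cohort one of "MI", "MA", "FI", "FA".
#' @slot traits character; the diagnostic trait subset the key scores over
#'   (empty = all plumage traits applicable to the cohort).
#' @slot intervals data.frame with \code{class}, \code{lower}, \code{upper};
#'   a PS belongs to a class when \code{lower <= PS <= upper}, boundaries
#'   resolving to the lower class.
#' @slot calibration list of observed PS ranges per genetic class in the
#'   reference panel.
#'
#' @seealso \code{\link{buildKey}}, \code{\link{classifyPlumage}}
#' @exportClass CohortKey
setClass("CohortKey",
  representation(cohort = "character", traits = "character",
                 intervals = "data.frame", calibration = "list")
)

setValidity("CohortKey", function(object) {
  iv <- object@intervals
  msg <- character()
  if (!object@cohort %in% COHORTS)
    msg <- c(msg, "cohort must be one of MI, MA, FI, FA")
  if (!all(c("class", "lower", "upper") %in% colnames(iv)))
    msg <- c(msg, "intervals needs class, lower, upper")
  else {
    md <- iv[iv$class == "mexican_duck", ]
    if (nrow(md) != 1 || md$lower != 0 || md$upper != 4)
      msg <- c(msg, "mexican_duck interval must be [0, 4]")
    o <- order(iv$lower)
    lo <- iv$lower[o]; hi <- iv$upper[o]
    if (any(lo[-1] != hi[-length(hi)] + 1L))
      msg <- c(msg, "intervals must partition [0, max] without gaps/overlap")
  }
  if (length(msg)) msg else TRUE
})

#' HybridCallReport: per-sample hybrid calls and rule concordance
#'
#' @slot perSample data.frame keyed by \code{sample_id} with the calls of
#'   each rule and an agreement flag.
#' @slot summary list: per-rule tallies, cross-tabulation, and the samples
#'   called hybrid by one rule only.
#'
#' @seealso \code{\link{concordance}}
#' @exportClass HybridCallReport
setClass("HybridCallReport",
  representation(perSample = "data.frame", summary = "list")
)
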