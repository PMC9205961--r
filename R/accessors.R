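#' Construct a GenotypeMatrix
#'
#' @param geno samples x SNPs matrix of alternate-allele counts
#'   (0/1/2, \code{NA} = missing); rownames are sample ids.
#' @param snpMeta data.frame/DataFrame with per-SNP \code{locus},
#'   \code{position}, \code{chrom_class}; a default autosomal scaffold is
#'   built when omitted.
#' @param metadata optional list.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
genotypeMatrix <- function(geno, snpMeta = NULL, metadata = list()) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("S%03d", seq_len(nrow(geno)))
  if (is.null(snpMeta)) {
    snpMeta <- DataFrame(
      locus = sprintf("L%05d", seq_len(ncol(geno))),
      position = seq_len(ncol(geno)),
      chrom_class = rep("autosomal", ncol(geno))
    )
  } else {
    snpMeta <- DataFrame(snpMeta)
  }
  if (is.null(colnames(geno)))
    colnames(geno) <- snpMeta$locus
  new("GenotypeMatrix", geno = geno, snpMeta = snpMeta, metadata = metadata)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@geno))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@geno))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@geno))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@geno)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpMeta", "GenotypeMatrix", function(x) x@snpMeta)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("filterReport", "GenotypeMatrix", function(x) {
  rep <- x@metadata$filter_report
  if (is.null(rep)) {
    rep <- data.frame(stage = character(), input = integer(),
                      removed = integer(), retained = integer())
  }
  rep
})

#' Subset a GenotypeMatrix
#'
#' @param x a \code{GenotypeMatrix}.
#' @param i sample index (ids, logical or integer).
#' @param j SNP index.
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{GenotypeMatrix}.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  new("GenotypeMatrix", geno = x@geno[i, j, drop = FALSE],
      snpMeta = x@snpMeta[j, , drop = FALSE], metadata = x@metadata)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs\n",
              nSamples(object), nSnps(object)))
  tab <- table(object@snpMeta$chrom_class)
  cat("  chromosome classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(object@geno))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  fr <- filterReport(object)
  if (nrow(fr))
    cat("  filters applied:", paste(fr$stage, collapse = " -> "), "\n")
})

#' @rdname AssignmentMatrix-class
#' @export
setMethod("ancestryQ", "AssignmentMatrix", function(x) x@Q)

#' @rdname AssignmentMatrix-class
#' @export
setMethod("ancestrySE", "AssignmentMatrix", function(x) x@SE)

#' @rdname AssignmentMatrix-class
#' @export
setMethod("clusterLabels", "AssignmentMatrix", function(x) x@clusterLabels)

#' @rdname AssignmentMatrix-class
#' @export
setMethod("nSamples", "AssignmentMatrix", function(x) nrow(x@Q))

setMethod("show", "AssignmentMatrix", function(object) {
  cat(sprintf("AssignmentMatrix: %d samples, K = %d (%s)\n",
              nrow(object@Q), object@K,
              paste(object@clusterLabels, collapse = ", ")))
  cat(sprintf("  logLik = %.2f, converged = %s, bootstrap SE %s\n",
              object@logLik, object@converged,
              if (all(is.na(object@SE))) "absent" else "present"))
})

#' @rdname CoancestryMatrix-class
#' @export
setMethod("coancestry", "CoancestryMatrix", function(x) x@cmatrix)

#' @rdname CoancestryMatrix-class
#' @export
setMethod("groupMeans", "CoancestryMatrix", function(x) x@groupMeans)

#' @rdname CoancestryMatrix-class
#' @export
setMethod("sampleIds", "CoancestryMatrix", function(x) rownames(x@cmatrix))

setMethod("show", "CoancestryMatrix", function(object) {
  cat(sprintf("CoancestryMatrix: %d samples, %d groups\n",
              nrow(object@cmatrix), length(unique(object@groups))))
})

#' @rdname SiblingGroups-class
#' @export
setMethod("siblingGroups", "SiblingGroups", function(x) x@groups)

#' @rdname SiblingGroups-class
#' @export
setMethod("representatives", "SiblingGroups",
          function(x) x@evidence$representative)

setMethod("show", "SiblingGroups", function(object) {
  n <- length(object@groups)
  cat(sprintf("SiblingGroups: %d groups, %d samples (%d confirmed groups)\n",
              n, length(unlist(object@groups)),
              sum(object@evidence$confirmed)))
})

#' @rdname TraitSchema-class
#' @export
setMethod("traitTable", "TraitSchema", function(x) x@traits)

#' @rdname TraitSchema-class
#' @export
setMethod("traitLevels", "TraitSchema", function(x, trait) {
  if (!trait %in% names(x@levels))
    stop("no ordinal levels for trait '", trait, "'")
  x@levels[[trait]]
})

setMethod("show", "TraitSchema", function(object) {
  k <- table(object@traits$kind)
  cat(sprintf("TraitSchema: %d plumage, %d structural + mass traits\n",
              k[["plumage"]], sum(k) - k[["plumage"]]))
})

#' @rdname CohortKey-class
#' @export
setMethod("keyIntervals", "CohortKey", function(x) x@intervals)

setMethod("show", "CohortKey", function(object) {
  cat(sprintf("CohortKey [%s]:\n", object@cohort))
  iv <- object@intervals
  for (r in seq_len(nrow(iv)))
    cat(sprintf("  PS %d-%d -> %s\n", iv$lower[r], iv$upper[r], iv$class[r]))
})

setMethod("show", "HybridCallReport", function(object) {
  s <- object@summary
  cat("HybridCallReport:\n")
  cat(sprintf("  samples: %d; hybrids by rule A: %d, rule B: %d, both: %d\n",
              nrow(object@perSample), s$n_hybrid_a, s$n_hybrid_b, s$n_both))
})
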