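#' Extract bi-allelic SNPs from per-locus allele alignments
#'
#' Each locus is an alignment carrying two sequences (the two allele copies)
#' per sample, named \code{"<sample>_1"} and \code{"<sample>_2"}. Every
#' aligned site with exactly two observed bases (A/C/G/T) across the panel
#' becomes one SNP column; sites with more than two bases are dropped. The
#' genotype is the count of the alternate allele (the rarer base; ties broken
#' so the alphabetically first base is the reference). A sample with any
#' unresolved base (N, gap, IUPAC ambiguity) at a site is missing at that
#' SNP. Loci whose sequences differ in length are skipped with a message.
#'
#' @param loci named list of per-locus alignments: \code{DNAStringSet} or
#'   character vector, names \code{"<sample>_1"}/\code{"<sample>_2"}.
#' @param chrom_class per-locus chromosome class ("autosomal" or "Z"),
#'   recycled; loci mapped to mtDNA must be excluded upstream.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @examples
#' locus <- c(s1_1 = "AACG", s1_2 = "AACG",
#'            s2_1 = "AACG", s2_2 = "AGCG",
#'            s3_1 = "AGCG", s3_2 = "AGCG")
#' gm <- extractBiallelicSnps(list(loc1 = locus))
#' genotypes(gm)   # one A/G SNP: 0, 1, 2
#' @export
extractBiallelicSnps <- function(loci, chrom_class = "autosomal") {
  if (is.null(names(loci)))
    names(loci) <- sprintf("locus%04d", seq_along(loci))
  chrom_class <- rep_len(chrom_class, length(loci))

  cols <- list(); meta <- list()
  all_samples <- NULL
  for (li in seq_along(loci)) {
    aln <- as.character(loci[[li]])
    if (is.null(names(aln))) names(aln) <- names(loci[[li]])
    nm <- names(aln)
    if (is.null(nm) || !all(grepl("_[12]$", nm)))
      stop("locus '", names(loci)[li],
           "': sequences must be named <sample>_1 / <sample>_2")
    samples <- unique(sub("_[12]$", "", nm))
    if (!all(c(paste0(samples, "_1"), paste0(samples, "_2")) %in% nm))
      stop("locus '", names(loci)[li],
           "': need two allele sequences per sample")
    if (length(unique(nchar(aln))) != 1) {
      message("skipping length-mismatched locus '", names(loci)[li], "'")
      next
    }
    if (is.null(all_samples)) all_samples <- samples
    else if (!setequal(all_samples, samples))
      stop("loci cover different sample sets")

    a1 <- do.call(rbind, strsplit(toupper(aln[paste0(samples, "_1")]), ""))
    a2 <- do.call(rbind, strsplit(toupper(aln[paste0(samples, "_2")]), ""))
    ok1 <- a1 %in% c("A", "C", "G", "T"); dim(ok1) <- dim(a1)
    ok2 <- a2 %in% c("A", "C", "G", "T"); dim(ok2) <- dim(a2)
    for (s in seq_len(ncol(a1))) {
      res <- ok1[, s] & ok2[, s]
      obs <- c(a1[res, s], a2[res, s])
      ub <- unique(obs)
      if (length(ub) != 2) next
      counts <- table(factor(obs, levels = sort(ub)))
      # reference = major allele; ties -> alphabetically first is reference
      ref <- names(counts)[which.max(counts)]
      alt <- setdiff(names(counts), ref)
      g <- (a1[, s] == alt) + (a2[, s] == alt)
      g[!res] <- NA_integer_
      cols[[length(cols) + 1L]] <- as.integer(g)
      meta[[length(meta) + 1L]] <- data.frame(
        locus = names(loci)[li], position = s,
        chrom_class = chrom_class[li], stringsAsFactors = FALSE)
    }
  }
  if (!length(cols))
    return(genotypeMatrix(
      matrix(integer(0), nrow = length(all_samples), ncol = 0,
             dimnames = list(all_samples, NULL)),
      snpMeta = DataFrame(locus = character(0), position = integer(0),
                          chrom_class = character(0))))
  geno <- do.call(cbind, cols)
  rownames(geno) <- all_samples
  genotypeMatrix(geno, snpMeta = DataFrame(do.call(rbind, meta)))
}

#' Read and write genotype tables
#'
#' \code{writeGenotypeCsv}/\code{readGenotypeCsv} round-trip a
#' \code{GenotypeMatrix} through a plain CSV (samples in rows, SNP metadata
#' in a sidecar CSV). \code{writePedMap}/\code{readPedMap} use the
#' whitespace-delimited PED/MAP text convention (alleles coded A/B, missing
#' \code{0 0}).
#'
#' @param x a \code{GenotypeMatrix}.
#' @param path file path (for PED/MAP, the stem: \code{<stem>.ped} and
#'   \code{<stem>.map} are used).
#' @return \code{readGenotypeCsv} and \code{readPedMap} return a
#'   \code{GenotypeMatrix}; writers return the path invisibly.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
writeGenotypeCsv <- function(x, path) {
  g <- genotypes(x)
  utils::write.csv(data.frame(sample_id = rownames(g), g,
                              check.names = FALSE),
                   path, row.names = FALSE)
  utils::write.csv(as.data.frame(snpMeta(x)),
                   sub("\\.csv$", "", path) |> paste0(".snps.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname genotype-io
#' @export
readGenotypeCsv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  g <- as.matrix(d[, -1, drop = FALSE])
  rownames(g) <- d$sample_id
  meta_path <- sub("\\.csv$", "", path) |> paste0(".snps.csv")
  meta <- if (file.exists(meta_path)) {
    DataFrame(utils::read.csv(meta_path))
  } else NULL
  genotypeMatrix(g, snpMeta = meta)
}

#' @rdname genotype-io
#' @export
writePedMap <- function(x, path) {
  g <- genotypes(x)
  meta <- snpMeta(x)
  # map: chrom, snp id, genetic distance, position
  chrom <- ifelse(meta$chrom_class == "Z", "Z", "1")
  map <- data.frame(chrom, id = paste0(meta$locus, "_", meta$position),
                    cm = 0, pos = meta$position)
  utils::write.table(map, paste0(path, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  al <- function(gv) {
    a1 <- ifelse(is.na(gv), "0", ifelse(gv >= 1, "B", "A"))
    a2 <- ifelse(is.na(gv), "0", ifelse(gv == 2, "B", "A"))
    paste(a1, a2)
  }
  body <- apply(g, 1, function(row) paste(al(row), collapse = " "))
  lines <- paste("FAM", rownames(g), "0 0 0 -9", body)
  writeLines(lines, paste0(path, ".ped"))
  invisible(path)
}

#' @rdname genotype-io
#' @export
readPedMap <- function(path) {
  map <- utils::read.table(paste0(path, ".map"),
                           col.names = c("chrom", "id", "cm", "pos"))
  ped <- utils::read.table(paste0(path, ".ped"), colClasses = "character")
  ids <- ped[[2]]
  am <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- am[, seq(1, ncol(am), 2), drop = FALSE]
  a2 <- am[, seq(2, ncol(am), 2), drop = FALSE]
  g <- (a1 == "B") + (a2 == "B")
  g[a1 == "0" | a2 == "0"] <- NA_integer_
  rownames(g) <- ids
  meta <- DataFrame(locus = sub("_[0-9]+$", "", map$id),
                    position = map$pos,
                    chrom_class = ifelse(map$chrom == "Z", "Z", "autosomal"))
  genotypeMatrix(g, snpMeta = meta)
}
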