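## Character matrix (samples x sites) from sequences; uppercased.
seq_char_matrix <- function(seqs) {
  s <- toupper(as.character(seqs))
  if (length(unique(nchar(s))) != 1)
    stop("sequences must be aligned (equal lengths)")
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- names(seqs)
  m
}

## Pairwise proportion-of-differences matrix with pairwise deletion of
## non-ACGT characters.
pairwise_seq_diff <- function(seqs) {
  m <- seq_char_matrix(seqs)
  ok <- m %in% c("A", "C", "G", "T"); dim(ok) <- dim(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (a in seq_len(n)) for (b in seq_len(a - 1L)) {
    use <- ok[a, ] & ok[b, ]
    D[a, b] <- D[b, a] <-
      if (any(use)) mean(m[a, use] != m[b, use]) else NA_real_
  }
  D
}

## Pairwise expected allele-difference matrix from dosages: at one SNP the
## probability that one random allele from each individual differs is
## (g_a (2 - g_b) + (2 - g_a) g_b) / 4; averaged over jointly observed SNPs.
pairwise_geno_diff <- function(g) {
  O <- !is.na(g); storage.mode(O) <- "double"
  G0 <- g; G0[is.na(G0)] <- 0; storage.mode(G0) <- "double"
  H0 <- (2 - g); H0[is.na(g)] <- 0; storage.mode(H0) <- "double"
  num <- (G0 %*% t(H0) + H0 %*% t(G0)) / 4
  den <- O %*% t(O)
  D <- num / den
  D[den == 0] <- NA_real_
  dimnames(D) <- list(rownames(g), rownames(g))
  D
}

#' Nucleotide diversity
#'
#' For aligned sequences, the mean pairwise proportion of differing sites
#' (pairwise deletion of gaps/ambiguities), computed through
#' \code{ape::dist.dna}. For a genotype partition, the average over SNP
#' sites of the unbiased per-site heterozygosity 2p(1-p) n/(n-1) divided by
#' the total assayed sites (defaults to the number of SNP columns; pass the
#' partition's total base-pair span for per-base values).
#'
#' @param x a \code{DNAStringSet}/character vector of aligned sequences, or
#'   a \code{\linkS4class{GenotypeMatrix}}.
#' @param partition for a genotype matrix, restrict to this chromosome class
#'   (\code{"autosomal"}, \code{"Z"} or \code{NULL} = all).
#' @param total_sites denominator in sites (genotype input only).
#' @return per-site nucleotide diversity (unitless, >= 0).
#' @examples
#' nucleotideDiversity(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))  # 0.1
#' @importFrom ape dist.dna as.DNAbin
#' @export
nucleotideDiversity <- function(x, partition = NULL, total_sites = NULL) {
  if (is(x, "GenotypeMatrix")) {
    if (!is.null(partition))
      x <- x[, snpMeta(x)$chrom_class == partition]
    g <- genotypes(x)
    if (nrow(g) < 2) stop("need at least 2 samples")
    if (is.null(total_sites)) total_sites <- ncol(g)
    alt <- colSums(g, na.rm = TRUE)
    n_al <- 2 * colSums(!is.na(g))
    use <- n_al >= 2
    p <- alt[use] / n_al[use]
    h <- 2 * p * (1 - p) * n_al[use] / (n_al[use] - 1)
    return(sum(h) / total_sites)
  }
  if (length(x) < 2) stop("need at least 2 sequences")
  mat <- seq_char_matrix(x)
  bin <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  mean(d)
}

#' Hudson-form pairwise PhiST per genomic partition
#'
#' For every pair of groups, relative differentiation is estimated as
#' 1 - (mean within-group pairwise diversity) / (mean between-group pairwise
#' diversity), with the within term averaging the two groups' mean pairwise
#' differences. Loci of a partition are concatenated (composite estimate).
#' Negative estimates are clamped to 0 with the raw value kept; a pair with
#' zero between-group diversity but positive within diversity is undefined
#' and flagged.
#'
#' @param x aligned sequences (\code{DNAStringSet}/character) or a
#'   \code{\linkS4class{GenotypeMatrix}}.
#' @param groups per-sample group labels (>= 2 groups of >= 2 members each).
#' @param partition chromosome class restriction (genotype input only).
#' @return data.frame: \code{group_a}, \code{group_b}, \code{phi_st}
#'   (clamped at 0, <= 1), \code{raw_phi_st}, \code{undefined}.
#' @export
phiSt <- function(x, groups, partition = NULL) {
  if (is(x, "GenotypeMatrix")) {
    if (!is.null(partition))
      x <- x[, snpMeta(x)$chrom_class == partition]
    D <- pairwise_geno_diff(genotypes(x))
  } else {
    D <- pairwise_seq_diff(x)
  }
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 members")

  within_mean <- function(g) {
    idx <- which(groups == g)
    block <- D[idx, idx]
    mean(block[upper.tri(block)], na.rm = TRUE)
  }
  wm <- stats::setNames(vapply(gl, within_mean, numeric(1)), gl)

  pairs <- utils::combn(gl, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    between <- mean(D[groups == a, groups == b], na.rm = TRUE)
    within <- mean(c(wm[a], wm[b]))
    undef <- between == 0 && within > 0
    raw <- if (between > 0) 1 - within / between else
      if (within == 0) 0 else NA_real_
    data.frame(group_a = a, group_b = b,
               phi_st = if (is.na(raw)) NA_real_ else max(raw, 0),
               raw_phi_st = raw, undefined = undef,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Diversity table per group and partition
#'
#' Convenience wrapper tabulating nucleotide diversity per group for the
#' autosomal and Z genotype partitions and (optionally) mtDNA sequences.
#'
#' @param x a \code{GenotypeMatrix}.
#' @param groups per-sample group labels.
#' @param mtdna optional named, aligned sequences covering the same samples.
#' @return data.frame: \code{group}, \code{partition}, \code{pi}, \code{n}.
#' @export
diversityTable <- function(x, groups, mtdna = NULL) {
  gl <- unique(groups)
  rows <- list()
  for (g in gl) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    for (part in c("autosomal", "Z")) {
      sub <- x[idx, snpMeta(x)$chrom_class == part]
      if (nSnps(sub) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, partition = part,
        pi = nucleotideDiversity(sub), n = length(idx))
    }
    if (!is.null(mtdna)) {
      ids <- intersect(sampleIds(x)[idx], names(mtdna))
      if (length(ids) >= 2)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, partition = "mtDNA",
          pi = nucleotideDiversity(mtdna[ids]), n = length(ids))
    }
  }
  do.call(rbind, rows)
}

#' Collapse aligned mtDNA sequences into haplotypes
#'
#' Exact-sequence deduplication after uppercasing: identical sequences share
#' one haplotype id; a sequence with ambiguity characters is its own
#' haplotype unless byte-identical to another. Per-group unique-haplotype
#' counts are tallied.
#'
#' @param seqs named aligned sequences (\code{DNAStringSet} or character).
#' @param groups optional per-sample group labels (same order as
#'   \code{seqs}).
#' @return list: \code{table} (data.frame sample_id, haplotype, group) and
#'   \code{counts} (per-group unique-haplotype counts; groups with no
#'   sequences count 0).
#' @export
collapseHaplotypes <- function(seqs, groups = NULL) {
  s <- toupper(as.character(seqs))
  if (length(unique(nchar(s))) > 1)
    stop("sequences must be aligned (equal lengths)")
  if (is.null(names(seqs)))
    stop("sequences must be named by sample id")
  if (is.null(groups)) groups <- rep("all", length(s))
  uniq <- unique(s)
  hap_id <- sprintf("H%03d", match(s, uniq))
  tab <- data.frame(sample_id = names(seqs), haplotype = hap_id,
                    group = groups, stringsAsFactors = FALSE)
  counts <- vapply(split(tab$haplotype, tab$group),
                   function(h) length(unique(h)), integer(1))
  gl <- unique(groups)
  counts <- counts[gl]; names(counts) <- gl
  counts[is.na(counts)] <- 0L
  list(table = tab, counts = counts)
}

#' Assign haplotypes to a haplogroup by nearest reference
#'
#' Each query is assigned the haplogroup of its nearest reference sequence
#' by Hamming distance (sites where both bases are A/C/G/T); exact ties
#' between haplogroups give \code{"unassigned"}.
#'
#' @param queries named aligned sequences.
#' @param references named aligned reference sequences; names are haplogroup
#'   labels (e.g. \code{"OW-A"}, \code{"NW-B"}), repeated names allowed.
#' @return character vector of haplogroup labels, named by query.
#' @export
assignHaplogroup <- function(queries, references) {
  if (!length(references)) stop("empty reference set")
  qm <- seq_char_matrix(queries)
  rm_ <- seq_char_matrix(references)
  if (ncol(qm) != ncol(rm_))
    stop("queries and references must share the alignment length")
  groups <- names(references)
  out <- character(nrow(qm))
  for (i in seq_len(nrow(qm))) {
    d <- vapply(seq_len(nrow(rm_)), function(r) {
      use <- qm[i, ] %in% c("A", "C", "G", "T") &
        rm_[r, ] %in% c("A", "C", "G", "T")
      sum(qm[i, use] != rm_[r, use])
    }, numeric(1))
    best <- min(vapply(split(d, groups), min, numeric(1)))
    winners <- unique(groups[d == best])
    # nearest distance per haplogroup; tie between haplogroups -> unassigned
    per_group <- vapply(split(d, groups), min, numeric(1))
    winners <- names(per_group)[per_group == best]
    out[i] <- if (length(winners) == 1) winners else "unassigned"
  }
  stats::setNames(out, rownames(qm))
}
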