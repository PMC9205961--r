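# Shared fixture builders; everything is generated in code at test time.

# Flat multi-population config with no hybrids/siblings unless asked for.
flat_config <- function(seed, n_snps, n_per_pop, F, npop = length(n_per_pop),
                        hybrid_specs = defaultHybridSpecs()[0, ],
                        sibling_specs = defaultSiblingSpecs()[0, ],
                        missing_rate = 0.02, ...) {
  n_per_pop <- rep_len(n_per_pop, npop)
  F <- rep_len(F, npop)
  ps <- data.frame(name = LETTERS[seq_len(npop)], n_samples = n_per_pop,
                   F = F, p_owa = 0, is_mallard_type = FALSE,
                   stringsAsFactors = FALSE)
  simulationConfig(seed = seed, n_snps = n_snps, pop_specs = ps,
                   hybrid_specs = hybrid_specs,
                   sibling_specs = sibling_specs,
                   missing_rate = missing_rate, ...)
}

# Small genotype matrix straight from a literal dosage matrix.
gm_from <- function(..., nrow = NULL) {
  m <- rbind(...)
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  genotypeMatrix(m)
}

# Hudson FST from realized population allele-frequency vectors (oracle,
# independent of the package's pairwise-difference implementation).
fst_from_freqs <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# All-pairs brute-force mean pairwise difference proportion for sequences.
brute_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  n <- nrow(m)
  tot <- 0; cnt <- 0
  for (a in seq_len(n)) for (b in seq_len(a - 1)) {
    ok <- m[a, ] %in% c("A", "C", "G", "T") & m[b, ] %in% c("A", "C", "G", "T")
    tot <- tot + mean(m[a, ok] != m[b, ok])
    cnt <- cnt + 1
  }
  tot / cnt
}

# Brute-force Hudson-form PhiST from a raw pairwise difference matrix.
brute_phist <- function(D, groups, a, b) {
  ia <- which(groups == a); ib <- which(groups == b)
  wa <- D[ia, ia][upper.tri(D[ia, ia])]
  wb <- D[ib, ib][upper.tri(D[ib, ib])]
  within <- mean(c(mean(wa), mean(wb)))
  between <- mean(D[ia, ib])
  1 - within / between
}

# Default full panel used by several test files (cached per session).
default_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulatePanel(simulationConfig(seed = 42, n_snps = 800))
    cache
  }
})
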