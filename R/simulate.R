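#' Simulation configuration for the synthetic study panel
#'
#' Builds and validates the configuration driving the three generators
#' (\code{\link{simulateGenotypes}}, \code{\link{simulateMtdna}},
#' \code{\link{simulateTraits}}). Defaults emulate the study design: six
#' genetic clusters (three Mexican duck populations, wild mallard, game-farm
#' mallard, Khaki Campbell), F1 and first-generation backcross hybrids,
#' full-sibling groups, two mtDNA haplogroups (OW-A, NW-B), and
#' cohort-conditional plumage-trait distributions.
#'
#' Population drift follows a Balding-Nichols-style model: each SNP's
#' ancestral frequency p is drawn Uniform(0.05, 0.95) and each population's
#' frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), so two populations with equal
#' drift F have expected Hudson FST of about F.
#'
#' @param seed integer; the single source of randomness for the whole panel.
#' @param n_snps number of bi-allelic SNPs.
#' @param pop_specs data.frame with \code{name}, \code{n_samples}, \code{F}
#'   (drift, in (0,1)), \code{p_owa} (probability a lineage carries an OW-A
#'   mtDNA haplotype), \code{is_mallard_type} (TRUE for wild/domestic mallard
#'   clusters; drives trait draws and hybrid-calling group maps).
#' @param hybrid_specs data.frame (possibly empty) with \code{parent_a}
#'   (recurrent parent for BC1), \code{parent_b}, \code{generation}
#'   ("F1" or "BC1"), \code{n}, \code{maternal_parent}.
#' @param sibling_specs data.frame (possibly empty) with \code{population},
#'   \code{n_groups}, \code{group_size}.
#' @param mtdna list: \code{length} (aligned sites),
#'   \code{haplogroup_core_distance} (substitutions between the OW-A and
#'   NW-B cores, >= 1), \code{within_group_mutation_rate} (expected Poisson
#'   mutations per lineage).
#' @param trait_model list: \code{variant_expression_prob} (probability an
#'   immature male Mexican duck expresses mallard-like variant traits,
#'   default 0.25), \code{ps_le4_frac} (fraction of pure immature-male
#'   Mexican ducks whose plumage score stays <= 4, default 0.97),
#'   \code{mallard_max_prob} (per-trait probability a mallard draws the
#'   maximum ordinal, default 0.98), \code{hybrid_parent_mix} (mixture weight
#'   toward the mallard parental state distribution for hybrids, default
#'   0.5).
#' @param missing_rate per-call missing-completely-at-random rate.
#' @param z_fraction fraction of SNPs labelled Z-linked (generative model
#'   identical to autosomal; the label only partitions diversity statistics).
#' @param sites_per_pop sampling sites per population (siblings share one).
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_snps = 2000L,
                             pop_specs = defaultPopSpecs(),
                             hybrid_specs = defaultHybridSpecs(),
                             sibling_specs = defaultSiblingSpecs(),
                             mtdna = list(length = 655L,
                                          haplogroup_core_distance = 25L,
                                          within_group_mutation_rate = 1.5),
                             trait_model = list(variant_expression_prob = 0.25,
                                                ps_le4_frac = 0.97,
                                                mallard_max_prob = 0.98,
                                                hybrid_parent_mix = 0.5),
                             missing_rate = 0.02,
                             z_fraction = 0.05,
                             sites_per_pop = 3L) {
  cfg <- list(seed = as.integer(seed), n_snps = as.integer(n_snps),
              pop_specs = pop_specs, hybrid_specs = hybrid_specs,
              sibling_specs = sibling_specs, mtdna = mtdna,
              trait_model = trait_model, missing_rate = missing_rate,
              z_fraction = z_fraction, sites_per_pop = as.integer(sites_per_pop))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' @rdname simulationConfig
#' @export
defaultPopSpecs <- function() {
  data.frame(
    name = c("MEDU_north", "MEDU_westcoast", "MEDU_interior",
             "wild_mallard", "game_farm", "khaki_campbell"),
    n_samples = c(40L, 20L, 30L, 30L, 20L, 10L),
    F = c(0.10, 0.12, 0.10, 0.15, 0.30, 0.35),
    p_owa = c(0.01, 0.01, 0.01, 0.31, 1.0, 1.0),
    is_mallard_type = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulationConfig
#' @export
defaultHybridSpecs <- function() {
  data.frame(
    parent_a = c("MEDU_north", "MEDU_north", "MEDU_north"),
    parent_b = c("wild_mallard", "game_farm", "wild_mallard"),
    generation = c("F1", "F1", "BC1"),
    n = c(6L, 2L, 2L),
    maternal_parent = c("wild_mallard", "game_farm", "MEDU_north"),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulationConfig
#' @export
defaultSiblingSpecs <- function() {
  data.frame(population = c("MEDU_north", "MEDU_interior"),
             n_groups = c(2L, 1L),
             group_size = c(2L, 3L),
             stringsAsFactors = FALSE)
}

validateSimulationConfig <- function(cfg) {
  ps <- cfg$pop_specs
  stopifnot(is.data.frame(ps), nrow(ps) >= 1,
            all(c("name", "n_samples", "F") %in% colnames(ps)))
  if (anyDuplicated(ps$name)) stop("duplicate population names")
  if (any(ps$n_samples < 1)) stop("n_samples must be >= 1")
  if (any(ps$F <= 0 | ps$F >= 1)) stop("drift F must lie in (0, 1)")
  hs <- cfg$hybrid_specs
  if (nrow(hs)) {
    unknown <- setdiff(c(hs$parent_a, hs$parent_b, hs$maternal_parent),
                       ps$name)
    if (length(unknown))
      stop("hybrid spec names unknown population(s): ",
           paste(unique(unknown), collapse = ", "))
    if (!all(hs$generation %in% c("F1", "BC1")))
      stop("generation must be F1 or BC1")
    if (!all(hs$maternal_parent == hs$parent_a |
             hs$maternal_parent == hs$parent_b))
      stop("maternal_parent must be one of the two parents")
  }
  ss <- cfg$sibling_specs
  if (nrow(ss) && length(setdiff(ss$population, ps$name)))
    stop("sibling spec names unknown population(s)")
  probs <- c(cfg$trait_model$variant_expression_prob,
             cfg$trait_model$ps_le4_frac, cfg$trait_model$mallard_max_prob,
             cfg$trait_model$hybrid_parent_mix, cfg$missing_rate,
             cfg$z_fraction, if ("p_owa" %in% colnames(ps)) ps$p_owa)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (cfg$mtdna$haplogroup_core_distance < 1)
    stop("haplogroup core distance must be >= 1")
  invisible(cfg)
}

## Balding-Nichols population frequency draw.
bn_draw <- function(p_anc, F) {
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  stats::rbeta(length(p_anc), a, b)
}

## One gamete (per-SNP allele vector) from a population frequency vector.
gamete_from_freq <- function(p) stats::rbinom(length(p), 1L, p)

## One gamete transmitted by an individual genotype (Mendelian).
gamete_from_geno <- function(g) {
  # g in 0:2; transmit one of the two alleles uniformly
  het <- g == 1L
  out <- as.integer(g == 2L)
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

#' Simulate a genotype panel with ground truth
#'
#' Draws per-SNP ancestral frequencies from Uniform(0.05, 0.95), drifts each
#' population via a Balding-Nichols Beta draw parameterized by its F,
#' genotypes pure individuals as two binomial allele draws, builds F1s with
#' one gamete from each parental frequency vector, BC1s as a gamete from the
#' recurrent parent plus an F1 gamete (75/25 expected ancestry), and sibling
#' groups as Mendelian offspring of two latent parents from the population.
#' Missing calls are injected completely at random. Identical seeds give
#' identical panels.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{genotypes} (\code{\linkS4class{GenotypeMatrix}}),
#'   \code{truth} (data.frame: sample_id, class, population label used for
#'   grouping, sibling_group, haplogroup, sex, age, cohort, site),
#'   and \code{pop_freqs} (SNP x population frequency matrix, for oracles).
#' @examples
#' sim <- simulateGenotypes(simulationConfig(seed = 7, n_snps = 200))
#' sim$genotypes
#' @export
simulateGenotypes <- function(config) {
  validateSimulationConfig(config)
  set.seed(config$seed)
  m <- config$n_snps
  ps <- config$pop_specs

  p_anc <- stats::runif(m, 0.05, 0.95)
  pf <- vapply(seq_len(nrow(ps)),
               function(k) bn_draw(p_anc, ps$F[k]), numeric(m))
  colnames(pf) <- ps$name

  ids <- character(0); rows <- list(); truth <- list()
  add <- function(id, g, class, population, sib = NA_character_) {
    rows[[length(rows) + 1L]] <<- g
    ids[length(ids) + 1L] <<- id
    truth[[length(truth) + 1L]] <<- data.frame(
      sample_id = id, class = class, population = population,
      sibling_group = sib, stringsAsFactors = FALSE)
  }

  # pure individuals
  for (k in seq_len(nrow(ps))) {
    nm <- ps$name[k]
    for (i in seq_len(ps$n_samples[k]))
      add(sprintf("%s_%03d", nm, i),
          stats::rbinom(m, 2L, pf[, nm]), nm, nm)
  }

  # hybrids
  hs <- config$hybrid_specs
  if (nrow(hs)) for (r in seq_len(nrow(hs))) {
    a <- hs$parent_a[r]; b <- hs$parent_b[r]
    for (i in seq_len(hs$n[r])) {
      if (hs$generation[r] == "F1") {
        g <- gamete_from_freq(pf[, a]) + gamete_from_freq(pf[, b])
      } else {
        # BC1 = F1(a,b) x a; the F1 gamete is a 50/50 per-SNP mix
        f1_gam <- gamete_from_freq(0.5 * pf[, a] + 0.5 * pf[, b])
        g <- gamete_from_freq(pf[, a]) + f1_gam
      }
      id <- sprintf("%s_%sx%s_%02d", hs$generation[r], a, b, i)
      add(id, g, hs$generation[r], a)
    }
  }

  # sibling groups: Mendelian offspring of two latent parents
  ss <- config$sibling_specs
  sib_counter <- 0L
  if (nrow(ss)) for (r in seq_len(nrow(ss))) {
    nm <- ss$population[r]
    for (gidx in seq_len(ss$n_groups[r])) {
      sib_counter <- sib_counter + 1L
      sib_id <- sprintf("SIB%02d", sib_counter)
      p1 <- stats::rbinom(m, 2L, pf[, nm])
      p2 <- stats::rbinom(m, 2L, pf[, nm])
      for (i in seq_len(ss$group_size[r]))
        add(sprintf("%s_%s_%d", sib_id, nm, i),
            gamete_from_geno(p1) + gamete_from_geno(p2), nm, nm, sib_id)
    }
  }

  geno <- do.call(rbind, rows)
  rownames(geno) <- ids
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }

  truth <- do.call(rbind, truth)

  # sex, age cohort, site, mtDNA haplogroup truth
  n <- nrow(truth)
  truth$sex <- sample(c("M", "F"), n, replace = TRUE)
  truth$age <- sample(c("immature", "adult"), n, replace = TRUE)
  sites <- sprintf("site_%d", seq_len(config$sites_per_pop))
  truth$site <- paste(truth$population,
                      sample(sites, n, replace = TRUE), sep = ":")
  p_owa <- ps$p_owa[match(truth$population, ps$name)]
  mat_pop <- truth$population
  if (nrow(hs)) {
    hyb_rows <- which(truth$class %in% c("F1", "BC1"))
    # maternal population decides the haplogroup of each hybrid spec's output
    idx <- 0L
    for (r in seq_len(nrow(hs))) for (i in seq_len(hs$n[r])) {
      idx <- idx + 1L
      mat_pop[hyb_rows[idx]] <- hs$maternal_parent[r]
    }
    p_owa[hyb_rows] <- ps$p_owa[match(mat_pop[hyb_rows], ps$name)]
  }
  truth$haplogroup <- ifelse(stats::runif(n) < p_owa, "OW-A", "NW-B")
  # siblings share a mother: one haplogroup draw and one site per group
  for (sg in unique(stats::na.omit(truth$sibling_group))) {
    memb <- which(truth$sibling_group == sg)
    truth$haplogroup[memb] <- truth$haplogroup[memb[1]]
    truth$site[memb] <- truth$site[memb[1]]
  }
  truth$cohort <- paste0(truth$sex, ifelse(truth$age == "immature", "I", "A"))

  z <- stats::runif(m) < config$z_fraction
  meta <- DataFrame(locus = sprintf("L%05d", seq_len(m)),
                    position = seq_len(m),
                    chrom_class = ifelse(z, "Z", "autosomal"))
  gm <- genotypeMatrix(geno, snpMeta = meta)
  list(genotypes = gm, truth = truth, pop_freqs = pf)
}

#' Simulate aligned mtDNA control-region haplotypes
#'
#' Two haplogroup core sequences (OW-A, NW-B) are separated by the configured
#' number of substitutions; each lineage then accumulates Poisson-distributed
#' private mutations. Hybrids carry the haplotype of their maternal lineage
#' (already resolved into \code{truth$haplogroup}) and members of a sibling
#' group share one haplotype.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param truth the truth table from \code{\link{simulateGenotypes}}.
#' @return list with \code{sequences} (named \code{DNAStringSet}, aligned)
#'   and \code{cores} (the two haplogroup core sequences).
#' @importFrom Biostrings DNAStringSet
#' @export
simulateMtdna <- function(config, truth) {
  validateSimulationConfig(config)
  set.seed(config$seed + 1000L)
  len <- config$mtdna$length
  d <- config$mtdna$haplogroup_core_distance
  rate <- config$mtdna$within_group_mutation_rate
  bases <- c("A", "C", "G", "T")

  core_b <- sample(bases, len, replace = TRUE)
  core_a <- core_b
  pos <- sample.int(len, d)
  for (p in pos)
    core_a[p] <- sample(setdiff(bases, core_b[p]), 1L)

  mutate <- function(seqv) {
    k <- stats::rpois(1L, rate)
    if (k > 0) {
      at <- sample.int(len, min(k, len))
      for (p in at) seqv[p] <- sample(setdiff(bases, seqv[p]), 1L)
    }
    seqv
  }

  seqs <- vector("list", nrow(truth))
  names(seqs) <- truth$sample_id
  done_sib <- list()
  for (i in seq_len(nrow(truth))) {
    sg <- truth$sibling_group[i]
    if (!is.na(sg) && !is.null(done_sib[[sg]])) {
      seqs[[i]] <- done_sib[[sg]]
      next
    }
    core <- if (truth$haplogroup[i] == "OW-A") core_a else core_b
    h <- mutate(core)
    seqs[[i]] <- h
    if (!is.na(sg)) done_sib[[sg]] <- h
  }
  dna <- DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  cores <- DNAStringSet(c("OW-A" = paste(core_a, collapse = ""),
                          "NW-B" = paste(core_b, collapse = "")))
  list(sequences = dna, cores = cores)
}

## Mallard-side per-trait ordinal draw: each trait's maximum level with
## probability p_max, otherwise one level below (vectorized over traits).
draw_mallard_state <- function(max_scores, p_max) {
  out <- as.integer(max_scores)
  down <- stats::runif(length(out)) >= p_max
  out[down] <- pmax(out[down] - 1L, 0L)
  out
}

## Traits an immature male Mexican duck may transiently express, with the
## maximum level reachable through innate variant expression.
VARIANT_TRAIT_CAPS <- c(percent_green_head = 2L, central_tail_curl = 2L,
                        rump_pattern = 1L, black_spots_bill = 1L,
                        face_neck_pattern = 1L)

## Random bundle of variant-trait levels summing exactly to `target`.
draw_variant_bundle <- function(target) {
  caps <- VARIANT_TRAIT_CAPS
  lev <- stats::setNames(integer(length(caps)), names(caps))
  left <- target
  for (tr in sample(names(caps))) {
    if (left == 0L) break
    take <- sample.int(min(caps[[tr]], left) + 1L, 1L) - 1L
    lev[[tr]] <- take
    left <- left - take
  }
  # any remainder distributed over unsaturated traits in random order
  while (left > 0L) {
    room <- names(caps)[lev < caps]
    tr <- if (length(room) == 1L) room else sample(room, 1L)
    lev[[tr]] <- lev[[tr]] + 1L
    left <- left - 1L
  }
  lev
}

#' Simulate plumage and structural trait records
#'
#' Draws per-specimen trait states conditional on the genetic truth class and
#' sex-age cohort. Pure Mexican ducks draw null (0) states, except immature
#' males: with probability \code{variant_expression_prob} they innately
#' express a random bundle of mallard-like variant traits (green in head,
#' tail curl, rump, bill spotting, face/neck pattern), calibrated so that a
#' configurable fraction of all pure immature males (default 97\%) stays at
#' plumage score <= 4. Mallard-type lineages draw the alternative
#' (maximum) state per trait with high probability. Hybrids draw a 50/50
#' mixture of the two parental state distributions with the three-level
#' traits forced to their intermediate level.
#'
#' Structural traits are normal draws; tarsus length, wing arc and mass carry
#' class-dependent means (hybrids intermediate), the rest do not, mirroring
#' which structural contrasts the study found significant.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param truth truth table from \code{\link{simulateGenotypes}}.
#' @param schema a \code{\linkS4class{TraitSchema}} (default packaged schema).
#' @return data.frame: \code{sample_id}, \code{cohort}, one integer column
#'   per plumage trait (NA where inapplicable to the cohort), one numeric
#'   column per structural/mass trait.
#' @export
simulateTraits <- function(config, truth, schema = loadTraitSchema()) {
  validateSimulationConfig(config)
  set.seed(config$seed + 2000L)
  tm <- config$trait_model
  if (!all(truth$cohort %in% COHORTS))
    stop("truth contains cohorts absent from the schema: ",
         paste(setdiff(truth$cohort, COHORTS), collapse = ", "))
  tab <- traitTable(schema)
  plumage <- tab$trait[tab$kind == "plumage"]
  structural <- tab$trait[tab$kind != "plumage"]
  mallard_pops <- config$pop_specs$name[config$pop_specs$is_mallard_type]

  # overflow probability among expressers so that ps_le4_frac of ALL pure
  # immature males stays at PS <= 4
  p_expr <- tm$variant_expression_prob
  p_over <- if (p_expr > 0) min(1, (1 - tm$ps_le4_frac) / p_expr) else 0

  n <- nrow(truth)
  out <- data.frame(sample_id = truth$sample_id, cohort = truth$cohort,
                    stringsAsFactors = FALSE)
  for (tr in plumage) out[[tr]] <- NA_integer_

  three_level <- tab$trait[tab$kind == "plumage" & tab$max_score >= 2]

  for (i in seq_len(n)) {
    coh <- truth$cohort[i]
    appl <- applicableTraits(schema, coh)
    cls <- truth$class[i]
    mx <- tab$max_score[match(appl, tab$trait)]
    if (cls %in% mallard_pops) {
      states <- draw_mallard_state(mx, tm$mallard_max_prob)
    } else if (cls %in% c("F1", "BC1")) {
      pick_mall <- stats::runif(length(appl)) < tm$hybrid_parent_mix
      states <- ifelse(pick_mall,
                       draw_mallard_state(mx, tm$mallard_max_prob),
                       0L)
      states[appl %in% three_level] <- 1L  # forced intermediate level
    } else {
      states <- integer(length(appl))
      if (coh == "MI" && stats::runif(1) < p_expr) {
        target <- if (stats::runif(1) < p_over) sample(5:6, 1L)
                  else sample(1:4, 1L)
        bundle <- draw_variant_bundle(target)
        keep <- intersect(names(bundle), appl)
        states[match(keep, appl)] <- bundle[keep]
      }
    }
    out[i, appl] <- as.list(as.integer(states))
  }

  # structural / mass traits (units: mm for lengths, g for mass)
  side <- ifelse(truth$class %in% mallard_pops, "mall",
                 ifelse(truth$class %in% c("F1", "BC1"), "hyb", "medu"))
  means <- list(
    bill_length = c(medu = 52, hyb = 52, mall = 52),
    bill_width = c(medu = 21, hyb = 21, mall = 21),
    central_tail_length = c(medu = 85, hyb = 85, mall = 85),
    culmen_nares = c(medu = 38, hyb = 38, mall = 38),
    tarsus_length = c(medu = 42, hyb = 43, mall = 44.5),
    wing_arc = c(medu = 252, hyb = 259, mall = 267),
    mass = c(medu = 950, hyb = 1030, mall = 1110)
  )
  sds <- c(bill_length = 1.5, bill_width = 1, central_tail_length = 4,
           culmen_nares = 1.5, tarsus_length = 1.2, wing_arc = 4, mass = 45)
  for (tr in structural)
    out[[tr]] <- stats::rnorm(n, means[[tr]][side], sds[[tr]])
  out
}

#' Simulate the full panel (genotypes, mtDNA, traits) in one call
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param schema trait schema passed to \code{\link{simulateTraits}}.
#' @return list: \code{genotypes}, \code{truth}, \code{pop_freqs},
#'   \code{mtdna} (sequences + cores), \code{traits}.
#' @export
simulatePanel <- function(config, schema = loadTraitSchema()) {
  g <- simulateGenotypes(config)
  mt <- simulateMtdna(config, g$truth)
  tr <- simulateTraits(config, g$truth, schema)
  c(g, list(mtdna = mt, traits = tr))
}
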