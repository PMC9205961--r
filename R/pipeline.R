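#' Pipeline configuration
#'
#' One configuration object drives the full analysis (simulate or load ->
#' filter -> structure + coancestry -> hybrid calling -> vetted labels ->
#' cohort keys -> evaluation). Every stochastic stage carries an explicit
#' seed derived from \code{seed}. The object round-trips through JSON
#' (\code{\link[jsonlite]{toJSON}}) unchanged apart from attribute order.
#'
#' @param seed master integer seed.
#' @param sim a \code{\link{simulationConfig}} for the synthetic panel
#'   (its own seed is set from \code{seed}).
#' @param maf_min,max_missing,window_snps,step_snps,r2_max filter settings.
#' @param K clusters for the admixture stage.
#' @param bootstrap_B bootstrap replicates (0 = skip SEs).
#' @param hybrid_threshold assignment-rule threshold.
#' @param t_sd sibling-detection threshold in SDs.
#' @param alpha structural-trait ANOVA alpha.
#' @param stages character vector of stages to run (subset of
#'   \code{c("filter", "structure", "coancestry", "hybrids", "popgen",
#'   "morphology")}).
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, sim = NULL,
                           maf_min = 0.005, max_missing = 0.2,
                           window_snps = 2, step_snps = 1, r2_max = 0.5,
                           K = 6L, bootstrap_B = 0L,
                           hybrid_threshold = 0.10, t_sd = 3,
                           alpha = 0.001,
                           stages = c("filter", "structure", "coancestry",
                                      "hybrids", "popgen", "morphology")) {
  if (is.null(sim)) sim <- simulationConfig(seed = seed)
  else sim$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), sim = sim, maf_min = maf_min,
              max_missing = max_missing, window_snps = window_snps,
              step_snps = step_snps, r2_max = r2_max, K = as.integer(K),
              bootstrap_B = as.integer(bootstrap_B),
              hybrid_threshold = hybrid_threshold, t_sd = t_sd,
              alpha = alpha, stages = stages)
  class(cfg) <- "PipelineConfig"
  cfg
}

## Map simulation truth classes onto the three genetic key classes.
truth_to_key_class <- function(truth, pop_specs) {
  mall <- pop_specs$name[pop_specs$is_mallard_type]
  ifelse(truth$class %in% c("F1", "BC1"), "hybrid",
         ifelse(truth$class %in% mall, "mallard", "mexican_duck"))
}

#' Run the full synthetic-panel pipeline
#'
#' Simulates the panel, applies the SNP filter chain, estimates population
#' structure and co-ancestry, detects and collapses sibling groups, calls
#' hybrids under both rules, computes diversity statistics, builds and
#' evaluates the cohort plumage keys from the genetically vetted labels, and
#' returns every stage's artifact plus a manifest with seeds and counts.
#' Identical configurations give identical results.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param out_dir optional directory; when given, tables are written as
#'   CSV, the co-ancestry dendrogram as Newick, the mtDNA panel as FASTA,
#'   and the manifest as JSON.
#' @return a list of stage outputs with a \code{manifest} element.
#' @importFrom jsonlite write_json
#' @importFrom Biostrings writeXStringSet
#' @importFrom ape write.tree as.phylo
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest <- list(package_version = as.character(utils::packageVersion("vetkey")),
                   seed = config$seed, stages = list())
  res <- list()
  mark <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(status = "ok"), list(...))
  }

  panel <- simulatePanel(config$sim)
  res$truth <- panel$truth
  res$traits <- panel$traits
  res$mtdna <- panel$mtdna
  gm <- panel$genotypes
  mark("simulate", n_samples = nSamples(gm), n_snps = nSnps(gm))

  if ("filter" %in% config$stages) {
    gm <- filterChain(gm, config$maf_min, config$max_missing,
                      config$window_snps, config$step_snps, config$r2_max,
                      seed = config$seed + 10L)
    res$filter_report <- filterReport(gm)
    mark("filter", retained = nSnps(gm))
  }
  res$genotypes <- gm
  truth <- panel$truth

  haps <- collapseHaplotypes(panel$mtdna$sequences, truth$population)
  sibs <- NULL
  if ("coancestry" %in% config$stages) {
    cm <- coancestryMatrix(gm, groups = truth$population)
    sibs <- detectSiblings(cm, data.frame(sample_id = truth$sample_id,
                                          site = truth$site),
                           haplotypes = haps$table, t_sd = config$t_sd)
    gm_rep <- dropToRepresentatives(gm, sibs)
    keep <- match(sampleIds(gm_rep), truth$sample_id)
    res$coancestry <- cm
    res$siblings <- sibs
    res$genotypes_derep <- gm_rep
    mark("coancestry", sibling_groups = length(siblingGroups(sibs)),
         samples_removed = nSamples(gm) - nSamples(gm_rep))
  } else {
    gm_rep <- gm
    keep <- seq_len(nrow(truth))
  }
  truth_rep <- truth[keep, ]

  if ("structure" %in% config$stages) {
    am <- if (config$bootstrap_B >= 2)
      bootstrapSE(gm_rep, config$K, B = config$bootstrap_B,
                  seed = config$seed + 20L)
    else suppressWarnings(
      estimateAdmixture(gm_rep, config$K, seed = config$seed + 20L))
    res$pca <- snpPCA(gm_rep)
    res$assignment <- am
    mark("structure", K = config$K, logLik = am@logLik)
  }

  if ("hybrids" %in% config$stages && "structure" %in% config$stages &&
      "coancestry" %in% config$stages) {
    ps <- config$sim$pop_specs
    mall <- ps$name[ps$is_mallard_type]
    medu <- ps$name[!ps$is_mallard_type]
    # map each cluster to the side (Mexican duck vs mallard types) whose
    # pure samples carry more of it on average
    Q <- ancestryQ(res$assignment)
    pure <- !truth_rep$class %in% c("F1", "BC1")
    is_mall <- truth_rep$population %in% mall
    mall_side <- vapply(seq_len(ncol(Q)), function(k) {
      mean(Q[pure & is_mall, k]) > mean(Q[pure & !is_mall, k])
    }, logical(1))
    side_mall <- clusterLabels(res$assignment)[mall_side]
    side_medu <- setdiff(clusterLabels(res$assignment), side_mall)
    calls_a <- if (length(side_mall) && length(side_medu)) {
      callHybridsAssignment(res$assignment,
                            stats::setNames(list(side_medu, side_mall),
                                            c("mexican_duck", "mallard")),
                            threshold = config$hybrid_threshold)
    } else NULL
    cm_full <- coancestryMatrix(gm, groups = truth$population)
    labels <- ifelse(truth$class %in% c("F1", "BC1"), "hybrid",
                     truth$population)
    calls_b <- callHybridsCoancestry(
      cm_full, side_a = medu, side_b = mall, labels = labels,
      domestic_groups = ps$name[ps$is_mallard_type & ps$p_owa >= 0.99],
      wild_groups = setdiff(mall, ps$name[ps$p_owa >= 0.99]))
    res$hybrid_calls_assignment <- calls_a
    res$hybrid_calls_coancestry <- calls_b
    if (!is.null(calls_a)) {
      cb <- calls_b[match(calls_a$sample_id, calls_b$sample_id), ]
      res$hybrid_concordance <- concordance(
        calls_a[, c("sample_id", "call")], cb[, c("sample_id", "call")])
      mark("hybrids",
           assignment_rule = res$hybrid_concordance@summary$n_hybrid_a,
           coancestry_rule = res$hybrid_concordance@summary$n_hybrid_b)
    }
  }

  if ("popgen" %in% config$stages) {
    names(panel$mtdna$sequences) <- truth$sample_id
    res$diversity <- diversityTable(gm, truth$population,
                                    mtdna = panel$mtdna$sequences)
    res$phi_st <- list(
      autosomal = phiSt(gm, truth$population, partition = "autosomal"),
      Z = phiSt(gm, truth$population, partition = "Z"))
    res$haplotypes <- haps
    res$haplogroups <- assignHaplogroup(panel$mtdna$sequences,
                                        panel$mtdna$cores)
    mark("popgen", haplotypes = length(unique(haps$table$haplotype)))
  }

  if ("morphology" %in% config$stages) {
    schema <- loadTraitSchema()
    key_class <- truth_to_key_class(truth, config$sim$pop_specs)
    scores <- scorePlumage(panel$traits, schema)
    keys <- list()
    for (coh in COHORTS) {
      sel <- scores$cohort == coh
      if (sum(sel) < 2) next
      keys[[coh]] <- buildKey(scores[sel, ], key_class[sel], coh, schema)
    }
    preds <- do.call(rbind, lapply(names(keys), function(coh) {
      sel <- scores$cohort == coh
      data.frame(sample_id = scores$sample_id[sel], cohort = coh,
                 class = classifyPlumage(scores[sel, ], keys[[coh]]),
                 stringsAsFactors = FALSE)
    }))
    evalr <- evaluateKey(preds, data.frame(sample_id = truth$sample_id,
                                           class = key_class))
    res$scores <- scores
    res$keys <- keys
    res$key_evaluation <- evalr
    mark("morphology", overall_accuracy = evalr$overall)
  }

  res$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeGenotypeCsv(gm, file.path(out_dir, "genotypes_filtered.csv"))
    writePedMap(gm, file.path(out_dir, "genotypes_filtered"))
    utils::write.csv(res$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(res$traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    Biostrings::writeXStringSet(panel$mtdna$sequences,
                                file.path(out_dir, "mtdna.fasta"))
    if (!is.null(res$assignment))
      utils::write.csv(data.frame(sample_id = rownames(ancestryQ(res$assignment)),
                                  ancestryQ(res$assignment)),
                       file.path(out_dir, "assignment_Q.csv"),
                       row.names = FALSE)
    if (!is.null(res$coancestry)) {
      utils::write.csv(coancestry(res$coancestry),
                       file.path(out_dir, "coancestry.csv"))
      ape::write.tree(ape::as.phylo(res$coancestry@dendrogram),
                      file.path(out_dir, "coancestry_dendrogram.nwk"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
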