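#' Load an ordinal trait schema
#'
#' Reads a long-format trait-coding table (one row per ordinal level for
#' plumage traits; one row per structural/mass trait) and validates it. The
#' packaged default transcribes the study's 16 plumage + 6 structural + mass
#' trait codings, where ordinal 0 is the Mexican-duck (null) state and higher
#' ordinals move toward the mallard (alternative) state.
#'
#' Required columns: \code{trait}, \code{kind}, \code{label}, \code{score},
#' \code{state}, \code{cohorts} (semicolon-separated subset of MI, MA, FI,
#' FA), \code{diag_cohorts} (cohorts for which the trait is provisionally
#' flagged diagnostic).
#'
#' @param path CSV path; the packaged default schema when \code{NULL}.
#' @return a \code{\linkS4class{TraitSchema}}.
#' @examples
#' sch <- loadTraitSchema()
#' sum(traitTable(sch)$kind == "plumage")   # 16
#' @export
loadTraitSchema <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trait_schema.csv", package = "vetkey",
                        mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trait", "kind", "label", "score", "state", "cohorts",
            "diag_cohorts")
  if (!all(need %in% colnames(raw)))
    stop("schema file must have columns: ", paste(need, collapse = ", "))

  split_cohorts <- function(s) {
    s <- strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE)[[1]]
    s[nzchar(s)]
  }
  traits <- unique(raw$trait)
  rows <- lapply(traits, function(tn) {
    sub <- raw[raw$trait == tn, ]
    if (length(unique(sub$kind)) != 1)
      stop("trait '", tn, "' has inconsistent kind")
    coh <- split_cohorts(sub$cohorts[1])
    dcoh <- split_cohorts(sub$diag_cohorts[1])
    bad <- setdiff(c(coh, dcoh), COHORTS)
    if (length(bad))
      stop("trait '", tn, "': unknown cohort(s) ", paste(bad, collapse = ","))
    mx <- if (sub$kind[1] == "plumage") max(sub$score) else NA_integer_
    out <- data.frame(trait = tn, kind = sub$kind[1], label = sub$label[1],
                      max_score = mx, stringsAsFactors = FALSE)
    for (cc in COHORTS) {
      out[[cc]] <- cc %in% coh
      out[[paste0("diag_", cc)]] <- cc %in% dcoh
    }
    out
  })
  tab <- do.call(rbind, rows)
  lv <- raw[raw$kind == "plumage", c("trait", "score", "state")]
  levels <- split(lv[, c("score", "state")], lv$trait)
  levels <- lapply(levels, function(d) {
    d <- d[order(d$score), ]
    d$score <- as.integer(d$score)
    rownames(d) <- NULL
    d
  })
  new("TraitSchema", traits = tab, levels = levels)
}

#' Plumage traits applicable to a cohort
#'
#' @param schema a \code{TraitSchema}.
#' @param cohort one of "MI", "MA", "FI", "FA".
#' @param diagnostic_only restrict to the cohort's diagnostic-flagged traits.
#' @return character vector of trait ids, in schema order.
#' @export
applicableTraits <- function(schema, cohort, diagnostic_only = FALSE) {
  cohort <- match.arg(cohort, COHORTS)
  tab <- schema@traits
  sel <- tab$kind == "plumage" & tab[[cohort]]
  if (diagnostic_only) sel <- sel & tab[[paste0("diag_", cohort)]]
  tab$trait[sel]
}

#' Maximum plumage score attainable for a cohort
#'
#' Sum of the per-trait maximum ordinals over the traits applicable to the
#' cohort (optionally restricted to a trait subset).
#'
#' @inheritParams applicableTraits
#' @param traits optional trait subset.
#' @return integer.
#' @export
cohortMaxScore <- function(schema, cohort, traits = NULL) {
  tr <- applicableTraits(schema, cohort)
  if (!is.null(traits)) tr <- intersect(tr, traits)
  tab <- schema@traits
  sum(tab$max_score[match(tr, tab$trait)])
}
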