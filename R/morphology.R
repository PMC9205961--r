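## Validate ordinal states in a record block against the schema.
check_states <- function(records, schema) {
  tab <- traitTable(schema)
  for (tr in tab$trait[tab$kind == "plumage"]) {
    if (!tr %in% colnames(records)) next
    v <- records[[tr]]
    bad <- !is.na(v) & (v < 0 | v > tab$max_score[tab$trait == tr])
    if (any(bad))
      stop("state out of range for trait '", tr, "' (max ",
           tab$max_score[tab$trait == tr], ")")
  }
  invisible(TRUE)
}

#' Plumage score (PS) computation
#'
#' Sums the ordinal scores of the plumage traits applicable to each record's
#' sex-age cohort (optionally restricted to the cohort's diagnostic trait
#' subset). Missing traits contribute 0 — the conservative direction, biasing
#' toward the Mexican-duck class — and are counted in \code{n_missing} so the
#' bias stays auditable.
#'
#' @param records data.frame with \code{sample_id}, \code{cohort}, and one
#'   column per plumage trait (ordinal integers, NA = missing).
#' @param schema a \code{\linkS4class{TraitSchema}}.
#' @param cohort_filtered restrict to each cohort's diagnostic-flagged
#'   traits.
#' @param traits optional explicit trait subset (overrides
#'   \code{cohort_filtered}).
#' @return data.frame: \code{sample_id}, \code{cohort}, \code{PS},
#'   \code{traits_used}, \code{n_missing}.
#' @examples
#' sch <- loadTraitSchema()
#' rec <- data.frame(sample_id = "x", cohort = "MA",
#'                   percent_green_head = 1L, central_tail_curl = 1L,
#'                   rump_pattern = 1L)
#' scorePlumage(rec, sch)$PS   # 3
#' @export
scorePlumage <- function(records, schema, cohort_filtered = FALSE,
                         traits = NULL) {
  if (!all(records$cohort %in% COHORTS))
    stop("unknown cohort(s): ",
         paste(setdiff(records$cohort, COHORTS), collapse = ", "))
  check_states(records, schema)
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    coh <- records$cohort[i]
    tr <- applicableTraits(schema, coh, diagnostic_only = cohort_filtered)
    if (!is.null(traits)) tr <- intersect(tr, traits)
    present <- intersect(tr, colnames(records))
    v <- as.integer(records[i, present])
    data.frame(sample_id = records$sample_id[i], cohort = coh,
               PS = sum(v, na.rm = TRUE),
               traits_used = length(present),
               n_missing = sum(is.na(v)) + length(setdiff(tr, present)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PCA over ordinal plumage traits
#'
#' Centered decomposition of the ordinal trait columns; missing states are
#' imputed to the per-trait mean, and traits that are missing in every
#' record are dropped with a warning.
#'
#' @param records trait records (see \code{\link{scorePlumage}}).
#' @param schema a \code{TraitSchema}.
#' @return list with \code{scores} and \code{explained_variance_fraction}.
#' @export
plumagePCA <- function(records, schema) {
  if (nrow(records) < 2) stop("PCA needs at least 2 records")
  tab <- traitTable(schema)
  traits <- intersect(tab$trait[tab$kind == "plumage"], colnames(records))
  X <- as.matrix(records[, traits, drop = FALSE])
  storage.mode(X) <- "double"
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    warning("dropping all-missing trait(s): ",
            paste(traits[all_na], collapse = ", "))
    X <- X[, !all_na, drop = FALSE]
  }
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  rownames(pc$x) <- records$sample_id
  list(scores = pc$x,
       explained_variance_fraction =
         if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev)))
}

#' ANOVA screening of structural traits
#'
#' One-way ANOVA of each structural/mass trait against the genetic class,
#' per cohort, with Tukey HSD pairwise comparisons at the configured alpha.
#' Classes with fewer than 2 observations are excluded from a comparison
#' (with a message); traits constant within a cohort have an undefined F and
#' are flagged.
#'
#' @param records trait records including structural columns and
#'   \code{cohort}.
#' @param labels per-record genetic class labels.
#' @param schema a \code{TraitSchema}.
#' @param alpha significance level (default 0.001).
#' @return list: \code{anova} (data.frame trait, cohort, F, p, significant,
#'   undefined) and \code{pairwise} (data.frame trait, cohort, comparison,
#'   p_adj, significant).
#' @export
structuralTests <- function(records, labels, schema, alpha = 0.001) {
  tab <- traitTable(schema)
  traits <- intersect(tab$trait[tab$kind != "plumage"], colnames(records))
  rows <- list(); pw <- list()
  for (coh in intersect(COHORTS, unique(records$cohort))) {
    sel <- records$cohort == coh
    for (tr in traits) {
      v <- records[[tr]][sel]
      lab <- labels[sel]
      ok <- !is.na(v) & !is.na(lab)
      v <- v[ok]; lab <- factor(lab[ok])
      keep <- names(which(table(lab) >= 2))
      if (length(keep) < length(levels(lab)))
        message(tr, " [", coh, "]: excluding class(es) with < 2 obs")
      use <- lab %in% keep
      v <- v[use]; lab <- droplevels(lab[use])
      if (length(levels(lab)) < 2) next
      if (stats::sd(v) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, cohort = coh, F = NA_real_, p = NA_real_,
          significant = NA, undefined = TRUE)
        next
      }
      fit <- stats::aov(v ~ lab)
      sm <- summary(fit)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, cohort = coh, F = sm$`F value`[1], p = sm$`Pr(>F)`[1],
        significant = sm$`Pr(>F)`[1] < alpha, undefined = FALSE)
      tk <- stats::TukeyHSD(fit)$lab
      pw[[length(pw) + 1L]] <- data.frame(
        trait = tr, cohort = coh, comparison = rownames(tk),
        p_adj = tk[, "p adj"], significant = tk[, "p adj"] < alpha,
        row.names = NULL)
    }
  }
  list(anova = do.call(rbind, rows), pairwise = do.call(rbind, pw))
}

## Leave-one-out LDA classification accuracy; ridge fallback when the
## within-class covariance is singular for MASS::lda.
loo_lda_accuracy <- function(X, y) {
  y <- factor(y)
  fit <- tryCatch(
    MASS::lda(X, grouping = y, CV = TRUE),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    cl <- as.character(fit$class)
    return(mean(!is.na(cl) & cl == as.character(y)))
  }
  # regularized linear discriminant, leave-one-out by hand
  eps <- 1e-6 * mean(apply(X, 2, stats::var)) + 1e-12
  message("lda singular; using ridge-regularized discriminant (epsilon = ",
          signif(eps, 3), ")")
  n <- nrow(X)
  correct <- 0L
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- droplevels(y[-i])
    mu <- lapply(levels(yi), function(l)
      colMeans(Xi[yi == l, , drop = FALSE]))
    W <- Reduce(`+`, lapply(levels(yi), function(l) {
      Z <- sweep(Xi[yi == l, , drop = FALSE], 2,
                 colMeans(Xi[yi == l, , drop = FALSE]))
      crossprod(Z)
    })) / max(1, nrow(Xi) - length(levels(yi)))
    Winv <- solve(W + diag(eps, ncol(X)))
    d <- vapply(mu, function(m) {
      z <- X[i, ] - m
      drop(t(z) %*% Winv %*% z)
    }, numeric(1))
    if (levels(yi)[which.min(d)] == as.character(y[i]))
      correct <- correct + 1L
  }
  correct / n
}

#' Diagnostic-trait selection by discriminant analysis
#'
#' Fits a linear discriminant over the cohort's applicable ordinal plumage
#' traits, ranks traits by absolute standardized discriminant loading, then
#' runs a forward search adding the trait that most improves leave-one-out
#' classification accuracy, with ties broken toward fewer traits and then
#' schema order. Traits constant in the cohort's records are excluded.
#'
#' @param records trait records of the reference panel.
#' @param labels genetic class per record (>= 2 classes present).
#' @param cohort the cohort to select for.
#' @param schema a \code{TraitSchema}.
#' @return list: \code{traits} (selected subset, schema order),
#'   \code{loo_accuracy}, \code{ranking} (data.frame trait, loading).
#' @export
selectDiagnosticTraits <- function(records, labels, cohort, schema) {
  cohort <- match.arg(cohort, COHORTS)
  sel <- records$cohort == cohort
  if (length(unique(labels[sel])) < 2)
    stop("need >= 2 genetic classes in the cohort's reference records")
  traits <- intersect(applicableTraits(schema, cohort), colnames(records))
  X <- as.matrix(records[sel, traits, drop = FALSE])
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  y <- factor(labels[sel])
  varying <- apply(X, 2, stats::sd) > 0
  traits <- traits[varying]; X <- X[, varying, drop = FALSE]
  if (!length(traits)) stop("no varying traits in this cohort")

  fit <- tryCatch(MASS::lda(X, grouping = y),
                  error = function(e) NULL, warning = function(w) NULL)
  loading <- if (!is.null(fit)) {
    abs(fit$scaling[, 1]) * apply(X, 2, stats::sd)
  } else {
    # fall back to per-trait class separation when lda is singular
    vapply(seq_along(traits), function(j)
      abs(diff(range(tapply(X[, j], y, mean)))) /
        (stats::sd(X[, j]) + 1e-12), numeric(1))
  }
  ranking <- data.frame(trait = traits, loading = as.numeric(loading))
  ranking <- ranking[order(-ranking$loading), ]

  chosen <- character(0)
  best_acc <- 0
  repeat {
    cand <- setdiff(traits, chosen)
    if (!length(cand)) break
    accs <- vapply(cand, function(tr)
      loo_lda_accuracy(X[, c(chosen, tr), drop = FALSE], y), numeric(1))
    accs[is.na(accs)] <- 0
    top <- max(accs)
    if (top <= best_acc && length(chosen)) break
    # tie-break toward schema order (traits is already in schema order)
    pick <- cand[which.max(accs == top)]
    chosen <- c(chosen, pick)
    best_acc <- top
    if (best_acc >= 1) break
  }
  list(traits = traits[traits %in% chosen], loo_accuracy = best_acc,
       ranking = ranking)
}

#' Build a cohort plumage key from a genetically vetted reference panel
#'
#' Calibrates PS class intervals from the observed PS ranges of each genetic
#' class among the cohort's reference records. The Mexican-duck interval is
#' always forced to [0, 4]; when the observed hybrid and mallard PS ranges
#' overlap (or a class is absent), the upper classes are merged into a
#' combined \code{"hybrid/mallard"} interval.
#'
#' @param scores \code{\link{scorePlumage}} output for the reference panel
#'   (one cohort).
#' @param labels genetic class per score row: \code{"mexican_duck"},
#'   \code{"hybrid"} or \code{"mallard"}.
#' @param cohort the cohort the key is for.
#' @param schema a \code{TraitSchema}.
#' @param traits optional diagnostic trait subset the key applies to
#'   (affects the maximal PS).
#' @return a \code{\linkS4class{CohortKey}}.
#' @export
buildKey <- function(scores, labels, cohort, schema, traits = NULL) {
  cohort <- match.arg(cohort, COHORTS)
  sel <- scores$cohort == cohort
  ps <- scores$PS[sel]; lab <- labels[sel]
  maxps <- cohortMaxScore(schema, cohort, traits)
  rng <- lapply(split(ps, lab), range)
  missing_classes <- setdiff(c("mexican_duck", "hybrid", "mallard"),
                             names(rng))
  if (length(missing_classes))
    message("reference class(es) absent for ", cohort, ": ",
            paste(missing_classes, collapse = ", "))

  hyb_max <- if ("hybrid" %in% names(rng)) rng$hybrid[2] else NA
  mall_min <- if ("mallard" %in% names(rng)) rng$mallard[1] else NA
  merged <- is.na(hyb_max) || is.na(mall_min) || mall_min <= hyb_max ||
    hyb_max <= 4 || hyb_max >= maxps
  iv <- data.frame(class = "mexican_duck", lower = 0L, upper = 4L)
  if (merged) {
    if (maxps > 4)
      iv <- rbind(iv, data.frame(class = "hybrid/mallard",
                                 lower = 5L, upper = as.integer(maxps)))
  } else {
    iv <- rbind(iv,
                data.frame(class = "hybrid", lower = 5L,
                           upper = as.integer(hyb_max)),
                data.frame(class = "mallard",
                           lower = as.integer(hyb_max) + 1L,
                           upper = as.integer(maxps)))
  }
  new("CohortKey", cohort = cohort,
      traits = if (is.null(traits)) character(0) else traits,
      intervals = iv,
      calibration = list(observed_ranges = rng, merged = merged,
                         missing_classes = missing_classes))
}

#' Classify plumage scores with a cohort key
#'
#' Interval lookup: a PS belongs to the class whose interval contains it,
#' with boundary values resolving to the lower class (PS = 4 is Mexican
#' duck).
#'
#' @param scores \code{\link{scorePlumage}} output.
#' @param key a \code{\linkS4class{CohortKey}} matching the scores' cohort.
#' @return character vector of class labels.
#' @export
classifyPlumage <- function(scores, key) {
  if (any(scores$cohort != key@cohort))
    stop("cohort mismatch: key is for ", key@cohort)
  iv <- key@intervals
  vapply(scores$PS, function(ps) {
    hit <- which(iv$lower <= ps & ps <= iv$upper)
    if (!length(hit)) iv$class[nrow(iv)] else iv$class[hit[1]]
  }, character(1))
}

#' Evaluate key classifications against genetic labels
#'
#' @param predictions data.frame with \code{sample_id}, \code{cohort},
#'   \code{class} (key output; the merged \code{"hybrid/mallard"} class
#'   matches either genetic label).
#' @param labels data.frame with \code{sample_id} and \code{class} (genetic
#'   truth: mexican_duck / hybrid / mallard).
#' @return list: \code{accuracy} (data.frame cohort, n, accuracy) and
#'   \code{confusion} (table of genetic class x key class).
#' @export
evaluateKey <- function(predictions, labels) {
  ids <- intersect(predictions$sample_id, labels$sample_id)
  if (!length(ids)) stop("no overlapping sample ids")
  p <- predictions[match(ids, predictions$sample_id), ]
  l <- labels[match(ids, labels$sample_id), ]
  correct <- p$class == l$class |
    (p$class == "hybrid/mallard" & l$class %in% c("hybrid", "mallard"))
  acc <- do.call(rbind, lapply(split(seq_along(ids), p$cohort), function(i)
    data.frame(cohort = p$cohort[i[1]], n = length(i),
               accuracy = mean(correct[i]))))
  rownames(acc) <- NULL
  list(accuracy = acc,
       confusion = table(genetic = l$class, key = p$class),
       overall = mean(correct))
}

#' Reassess historical specimens with the developed keys
#'
#' Scores each historical trait record, classifies it with the key of its
#' cohort, and cross-tabulates the original label against the key class.
#' Specimens whose cohort has no key are skipped with a message.
#'
#' @param records historical trait records (with \code{sample_id},
#'   \code{cohort}, trait columns).
#' @param original_labels per-record original (pre-genetic) classification.
#' @param keys named list of \code{\linkS4class{CohortKey}}s keyed by
#'   cohort.
#' @param schema a \code{TraitSchema}.
#' @return list: \code{per_specimen} (data.frame sample_id, cohort, PS,
#'   original, key_class, changed) and \code{crosstab}.
#' @export
reassessSpecimens <- function(records, original_labels, keys, schema) {
  if (!nrow(records))
    return(list(per_specimen = data.frame(), crosstab = table(NULL)))
  have_key <- records$cohort %in% names(keys)
  if (any(!have_key))
    message("skipping ", sum(!have_key), " specimen(s) with no cohort key")
  rec <- records[have_key, , drop = FALSE]
  orig <- original_labels[have_key]
  if (!nrow(rec))
    return(list(per_specimen = data.frame(), crosstab = table(NULL)))
  out <- do.call(rbind, lapply(split(seq_len(nrow(rec)), rec$cohort),
                               function(i) {
    coh <- rec$cohort[i[1]]
    key <- keys[[coh]]
    tr <- if (length(key@traits)) key@traits else NULL
    sc <- scorePlumage(rec[i, , drop = FALSE], schema, traits = tr)
    data.frame(sample_id = sc$sample_id, cohort = coh, PS = sc$PS,
               original = orig[i], key_class = classifyPlumage(sc, key),
               stringsAsFactors = FALSE)
  }))
  out$changed <- out$original != out$key_class
  rownames(out) <- NULL
  list(per_specimen = out,
       crosstab = table(original = out$original, key = out$key_class))
}
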