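# Cohort-level tumor analyses over an activity profile: hierarchical
# clustering with uncentered-correlation distance, random train/test
# splitting, univariate Cox screening, K-means risk stratification and
# Kaplan-Meier/log-rank evaluation, and the assembled prognosis pipeline.

#' Uncentered-correlation distance matrix
#'
#' \eqn{d(x, y) = 1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}} between the
#' rows of a matrix (no mean-centering, so the measure is scale-invariant but
#' not location-invariant). Undefined for an all-zero vector.
#'
#' @param mat Numeric matrix; rows are the items to compare.
#' @return A \code{dist} object.
#' @export
uncentered_cor_dist <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  norms <- sqrt(rowSums(mat^2))
  zero <- norms == 0
  if (any(zero)) {
    stop("uncentered correlation undefined for all-zero vector(s): ",
         paste(utils::head(rownames(mat)[zero], 5), collapse = ", "))
  }
  sim <- (mat %*% t(mat)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0  # guard tiny negative round-off
  stats::as.dist(d)
}

#' Hierarchical clustering of an activity profile
#'
#' Complete-linkage agglomeration on uncentered-correlation distances, the
#' combination used to group tumor samples by their subpathway activity
#' fingerprints. Either axis can be clustered.
#'
#' @param profile An \code{activity_profile} (or plain matrix, items x
#'   variables when \code{axis} is ignored).
#' @param axis \code{"samples"} (default) or \code{"subpathways"}.
#' @param n_clusters Optional integer: also cut the tree into this many
#'   groups.
#' @param use \code{"spa_norm"} (default) or \code{"spa"}.
#' @return List with \code{hclust} (the tree), \code{order} (labels in
#'   dendrogram order) and, if requested, \code{clusters} (named integer
#'   vector).
#' @export
hierarchical_cluster <- function(profile, axis = c("samples", "subpathways"),
                                 n_clusters = NULL,
                                 use = c("spa_norm", "spa")) {
  axis <- match.arg(axis); use <- match.arg(use)
  mat <- if (inherits(profile, "activity_profile")) profile[[use]] else profile
  items <- if (axis == "samples") t(mat) else mat
  hc <- stats::hclust(uncentered_cor_dist(items), method = "complete")
  out <- list(hclust = hc, order = hc$labels[hc$order])
  if (!is.null(n_clusters)) {
    out$clusters <- stats::cutree(hc, k = n_clusters)
  }
  out
}

#' Randomly split a cohort into equal train and test halves
#'
#' Samples without usable survival data are excluded with a warning; the
#' remainder is split uniformly at random into two halves of equal size
#' (training receives the extra sample when the count is odd). Optionally
#' stratified by event status so both halves carry the same event fraction.
#'
#' @param clinical Clinical data frame (\code{sample_id}, \code{time},
#'   \code{event}).
#' @param seed Integer seed; recorded in the result.
#' @param stratify_by_event Stratify the split by event indicator
#'   (default \code{FALSE}).
#' @return List with \code{train}, \code{test} (character vectors),
#'   \code{seed}, \code{excluded}.
#' @export
split_cohort <- function(clinical, seed, stratify_by_event = FALSE) {
  usable <- is.finite(clinical$time) & clinical$time > 0 &
    clinical$event %in% c(0, 1)
  excluded <- clinical$sample_id[!usable]
  if (length(excluded)) {
    warning(length(excluded), " sample(s) without usable survival data excluded")
  }
  ids <- clinical$sample_id[usable]
  if (length(ids) < 4) stop("need >= 4 samples with survival data to split")
  set.seed(seed)
  pick_half <- function(v) sort(sample(v, ceiling(length(v) / 2)))
  if (stratify_by_event) {
    ev <- clinical$event[usable]
    train <- c(pick_half(ids[ev == 1]), pick_half(ids[ev == 0]))
  } else {
    train <- pick_half(ids)
  }
  list(train = sort(train), test = sort(setdiff(ids, train)),
       seed = seed, excluded = excluded)
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits survival against a single continuous covariate (Efron handling of
#' tied event times) and reports the coefficient, hazard ratio and two-sided
#' Wald p-value. A constant covariate or a cohort with fewer than two events
#' yields a flagged, estimate-free result rather than an error, so screening
#' loops can proceed.
#'
#' @param x Named numeric vector: covariate per sample id.
#' @param clinical Clinical data frame covering those samples.
#' @return One-row data frame: coefficient, hazard_ratio, wald_p, n,
#'   n_events, ok (logical).
#' @export
univariate_cox <- function(x, clinical) {
  common <- intersect(names(x), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  xx <- x[common]
  keep <- is.finite(xx)
  cl <- cl[keep, ]; xx <- xx[keep]
  bad <- data.frame(coefficient = NA_real_, hazard_ratio = NA_real_,
                    wald_p = NA_real_, n = length(xx),
                    n_events = sum(cl$event), ok = FALSE)
  if (length(xx) < 3 || sum(cl$event) < 2 || stats::sd(xx) == 0) return(bad)
  fit <- tryCatch(
    survival::coxph(survival::Surv(cl$time, cl$event) ~ xx, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      # ride through convergence warnings; refit quietly
      suppressWarnings(survival::coxph(
        survival::Surv(cl$time, cl$event) ~ xx, ties = "efron"))
    })
  if (is.null(fit) || !is.finite(stats::coef(fit))) return(bad)
  s <- summary(fit)
  data.frame(coefficient = unname(stats::coef(fit)),
             hazard_ratio = unname(exp(stats::coef(fit))),
             wald_p = unname(s$coefficients[1, "Pr(>|z|)"]),
             n = length(xx), n_events = sum(cl$event), ok = TRUE)
}

#' Univariate Cox screen over an activity profile
#'
#' One \code{\link{univariate_cox}} fit per subpathway row.
#'
#' @param profile An \code{activity_profile}.
#' @param clinical Clinical data frame.
#' @param use \code{"spa_norm"} (default) or \code{"spa"}.
#' @return Data frame with one row per subpathway, ordered as the profile.
#' @export
cox_screen <- function(profile, clinical, use = c("spa_norm", "spa")) {
  use <- match.arg(use)
  mat <- profile[[use]]
  rows <- lapply(rownames(mat), function(id) {
    res <- univariate_cox(mat[id, ], clinical)
    cbind(data.frame(subpathway_id = id, stringsAsFactors = FALSE), res)
  })
  do.call(rbind, rows)
}

#' Select a prognostic signature from Cox screen results
#'
#' Keeps subpathways whose Wald p-value is strictly below the threshold
#' (default 0.01); flagged (unavailable) fits are never selected.
#'
#' @param cox_results Data frame from \code{\link{cox_screen}}.
#' @param threshold Wald p-value cut-off (default 0.01).
#' @param subpathways Optional list of \code{subpathway_graph}s used to
#'   report the parent pathways of the signature.
#' @return List with \code{signature} (character vector of subpathway ids)
#'   and \code{parents} (character vector of parent pathway ids, if
#'   available).
#' @export
select_signature <- function(cox_results, threshold = 0.01,
                             subpathways = NULL) {
  keep <- cox_results$ok & is.finite(cox_results$wald_p) &
    cox_results$wald_p < threshold
  sig <- cox_results$subpathway_id[keep]
  parents <- character(0)
  if (!is.null(subpathways) && length(sig)) {
    ids <- vapply(subpathways, function(s) s$subpathway_id, character(1))
    parents <- sort(unique(vapply(subpathways[ids %in% sig],
                                  function(s) s$parent_id, character(1))))
  }
  list(signature = sig, parents = parents)
}

#' K-means risk groups from signature activities
#'
#' Euclidean K-means on the per-sample vectors of signature-subpathway
#' activities, with multiple random restarts (best total within-cluster sum
#' of squares kept). Group labels are renumbered by first appearance in
#' sample order, so a fixed seed yields stable labels.
#'
#' @param profile An \code{activity_profile}.
#' @param signature Character vector of subpathway ids (rows to use).
#' @param k Number of risk groups (default 2).
#' @param seed Integer seed.
#' @param nstart Random restarts (default 25).
#' @param samples Optional subset of sample ids (default: all columns).
#' @param use \code{"spa_norm"} (default) or \code{"spa"}.
#' @return List with \code{groups} (named integer vector sample -> group) and
#'   \code{fit} (the \code{kmeans} object).
#' @export
kmeans_risk_groups <- function(profile, signature, k = 2, seed = 1,
                               nstart = 25, samples = NULL,
                               use = c("spa_norm", "spa")) {
  use <- match.arg(use)
  mat <- profile[[use]]
  missing <- setdiff(signature, rownames(mat))
  if (length(missing)) {
    stop("signature subpathway(s) not in profile: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(samples)) samples <- colnames(mat)
  x <- t(mat[signature, samples, drop = FALSE])
  if (k > nrow(x)) stop("k exceeds the number of samples")
  set.seed(seed)
  fit <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  labels <- fit$cluster
  relabel <- stats::setNames(seq_along(unique(labels)), unique(labels))
  groups <- stats::setNames(as.integer(relabel[as.character(labels)]),
                            rownames(x))
  list(groups = groups, fit = fit)
}

#' Kaplan-Meier curves and log-rank test across risk groups
#'
#' Product-limit survival estimate per group and the k-group log-rank
#' statistic (chi-square with k-1 degrees of freedom, two-sided p).
#'
#' @param groups Named vector: sample id -> group label (>= 2 non-empty
#'   groups).
#' @param clinical Clinical data frame covering those samples.
#' @return List with \code{fit} (a \code{survfit} object), \code{chisq},
#'   \code{df}, \code{p}, \code{n_per_group}.
#' @export
km_logrank <- function(groups, clinical) {
  common <- intersect(names(groups), clinical$sample_id)
  if (length(common) < length(groups)) {
    warning(length(groups) - length(common),
            " grouped sample(s) lack clinical data and are dropped")
  }
  g <- factor(groups[common])
  if (nlevels(g) < 2) stop("need >= 2 non-empty groups")
  if (any(table(g) == 0)) stop("a group has zero samples")
  cl <- clinical[match(common, clinical$sample_id), ]
  df <- data.frame(time = cl$time, event = cl$event, group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- nlevels(g) - 1
  list(fit = fit, chisq = unname(sd_$chisq), df = dfree,
       p = stats::pchisq(sd_$chisq, dfree, lower.tail = FALSE),
       n_per_group = table(g))
}

#' Univariate Cox screen over individual features
#'
#' One proportional-hazards fit per row of an expression matrix (gene or
#' lncRNA expression as the single covariate); used to define the significant
#' feature set that feeds the enrichment comparison.
#'
#' @param values Numeric matrix, features x samples.
#' @param clinical Clinical data frame.
#' @param threshold Wald p-value cut-off for significance (default 0.05).
#' @return List with \code{results} (data frame feature_id, wald_p, ok) and
#'   \code{significant} (character vector).
#' @export
feature_cox_screen <- function(values, clinical, threshold = 0.05) {
  res <- lapply(rownames(values), function(f) {
    fit <- univariate_cox(values[f, ], clinical)
    data.frame(feature_id = f, wald_p = fit$wald_p, ok = fit$ok,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  list(results = res,
       significant = res$feature_id[res$ok & is.finite(res$wald_p) &
                                      res$wald_p < threshold])
}

#' Train/test prognostic signature discovery
#'
#' The full prognosis analysis: (i) split the cohort into equal random
#' training and testing halves; (ii) compute the activity profile of the
#' training half and screen every subpathway with univariate Cox, keeping
#' those with Wald p below \code{cox_p} as the signature; (iii) as a
#' comparator, screen individual features with Cox at \code{feature_p},
#' run the combined hypergeometric enrichment over all subpathways, and
#' measure the overlap between the Cox signature and the enrichment-derived
#' sets at adjusted-p cut-offs \code{overlap_cutoffs}; (iv) on the testing
#' half, stratify samples into \code{k_groups} K-means risk groups on the
#' signature activities and compare their survival with the log-rank test.
#'
#' @param gene_expr,lnc_expr Expression matrices (features x samples).
#' @param subpathways List of \code{subpathway_graph}s.
#' @param clinical Clinical data frame.
#' @param split_seed Seed for the random split.
#' @param cox_p Subpathway signature threshold (default 0.01).
#' @param feature_p Per-feature significance threshold feeding enrichment
#'   (default 0.05).
#' @param k_groups Number of K-means risk groups on the test set (default 2).
#' @param kmeans_seed Seed for K-means restarts (default \code{split_seed}).
#' @param overlap_cutoffs Adjusted-p cut-offs for the enrichment sets
#'   (default 0.01, 0.001, 0.0001).
#' @param exponent_sign Weighting exponent sign (default +1).
#' @param use Activity scale for Cox and K-means (default \code{"spa_norm"}).
#' @return A \code{prognosis_report} list: split, cox results, signature and
#'   parent pathways, enrichment table, overlap table, test-set groups and
#'   log-rank result, and the parameters used.
#' @export
prognosis_pipeline <- function(gene_expr, lnc_expr, subpathways, clinical,
                               split_seed, cox_p = 0.01, feature_p = 0.05,
                               k_groups = 2, kmeans_seed = split_seed,
                               overlap_cutoffs = c(0.01, 0.001, 0.0001),
                               exponent_sign = 1,
                               use = c("spa_norm", "spa")) {
  use <- match.arg(use)
  merged <- merge_profiles(gene_expr, lnc_expr)
  clinical <- clinical[clinical$sample_id %in% colnames(merged$values), ]
  split <- split_cohort(clinical, seed = split_seed)

  subset_merged <- function(ids) {
    structure(list(values = merged$values[, ids, drop = FALSE],
                   gene_ids = merged$gene_ids, lnc_ids = merged$lnc_ids),
              class = "merged_expression")
  }
  train_prof <- activity_profile(subset_merged(split$train), subpathways,
                                 exponent_sign = exponent_sign)
  test_prof <- activity_profile(subset_merged(split$test), subpathways,
                                exponent_sign = exponent_sign)

  cox <- cox_screen(train_prof, clinical, use = use)
  sig <- select_signature(cox, threshold = cox_p, subpathways = subpathways)

  feat <- feature_cox_screen(merged$values[, split$train, drop = FALSE],
                             clinical, threshold = feature_p)
  enr <- enrich_subpathways(subpathways, feat$significant,
                            universe_genes = intersect(merged$gene_ids,
                                                       rownames(merged$values)),
                            universe_lncs = intersect(merged$lnc_ids,
                                                      rownames(merged$values)))
  universe_size <- nrow(cox)
  overlap <- do.call(rbind, lapply(overlap_cutoffs, function(cut) {
    enr_set <- enr$subpathway_id[enr$p_adjusted < cut]
    data.frame(cutoff = cut, n_enriched = length(enr_set),
               n_signature = length(sig$signature),
               n_overlap = length(intersect(sig$signature, enr_set)),
               p = if (length(sig$signature) && length(enr_set))
                 signature_overlap(sig$signature, enr_set, universe_size)
               else NA_real_)
  }))

  risk <- NULL; logrank <- NULL
  if (length(sig$signature) >= 1) {
    risk <- kmeans_risk_groups(test_prof, sig$signature, k = k_groups,
                               seed = kmeans_seed, use = use)
    logrank <- km_logrank(risk$groups, clinical)
  }

  structure(list(
    split = split,
    cox = cox,
    signature = sig$signature,
    signature_parents = sig$parents,
    enrichment = enr,
    overlap = overlap,
    risk_groups = if (!is.null(risk)) risk$groups else NULL,
    logrank = if (!is.null(logrank))
      logrank[c("chisq", "df", "p")] else NULL,
    parameters = list(split_seed = split_seed, cox_p = cox_p,
                      feature_p = feature_p, k_groups = k_groups,
                      kmeans_seed = kmeans_seed,
                      overlap_cutoffs = overlap_cutoffs,
                      exponent_sign = exponent_sign, use = use)),
    class = "prognosis_report")
}

#' @export
print.prognosis_report <- function(x, ...) {
  cat(sprintf("prognosis_report: %d train / %d test samples\n",
              length(x$split$train), length(x$split$test)))
  cat(sprintf("signature: %d subpathway(s) at Cox p < %g\n",
              length(x$signature), x$parameters$cox_p))
  if (!is.null(x$logrank)) {
    cat(sprintf("test-set log-rank: chisq = %.4g on %d df, p = %.4g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p))
  }
  invisible(x)
}

#' Serialize a prognosis report to deterministic JSON
#'
#' Writes the machine-readable portion of the report (no model objects).
#' Output is byte-identical across reruns with the same seeds.
#'
#' @param report A \code{prognosis_report}.
#' @param path Output path.
#' @export
write_prognosis_report <- function(report, path) {
  out <- list(
    parameters = report$parameters,
    split = report$split[c("train", "test", "seed")],
    signature = report$signature,
    signature_parents = report$signature_parents,
    cox = report$cox,
    enrichment = report$enrichment,
    overlap = report$overlap,
    risk_groups = as.list(report$risk_groups),
    logrank = report$logrank)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
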