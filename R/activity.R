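# Per-sample subpathway activity scoring. The score is a modified FAIME
# statistic over the merged gene+lncRNA matrix: within each sample, features
# are ranked in ascending expression order and weighted w = r * exp(s*r/|N|);
# a subpathway's activity (sPA) is the mean member weight minus the mean
# weight of all non-member features, then z-normalized per subpathway across
# samples (sPA_norm).

#' Merge gene and lncRNA expression profiles
#'
#' Row-binds the two matrices restricted to their common samples (in the
#' order of the gene matrix), genes first then lncRNAs. The merged row set is
#' the feature universe \eqn{N} of the weighting scheme.
#'
#' @param gene_expr Numeric matrix, genes x samples (row/col names required).
#' @param lnc_expr Numeric matrix, lncRNAs x samples.
#' @return An object of class \code{merged_expression}: a list with
#'   \code{values} (matrix), \code{gene_ids} and \code{lnc_ids}.
#' @export
merge_profiles <- function(gene_expr, lnc_expr) {
  stopifnot(is.matrix(gene_expr), is.matrix(lnc_expr))
  common <- intersect(colnames(gene_expr), colnames(lnc_expr))
  if (length(common) == 0L) stop("no common samples between the two matrices")
  clash <- intersect(rownames(gene_expr), rownames(lnc_expr))
  if (length(clash)) {
    stop("feature id(s) present in both matrices: ",
         paste(clash, collapse = ", "))
  }
  common <- colnames(gene_expr)[colnames(gene_expr) %in% common]
  values <- rbind(gene_expr[, common, drop = FALSE],
                  lnc_expr[, common, drop = FALSE])
  if (any(!is.finite(values) | values < 0)) {
    stop("merged expression contains missing, infinite or negative values")
  }
  structure(list(values = values,
                 gene_ids = rownames(gene_expr),
                 lnc_ids = rownames(lnc_expr)),
            class = "merged_expression")
}

#' @export
print.merged_expression <- function(x, ...) {
  cat(sprintf("merged_expression: %d genes + %d lncRNAs x %d samples\n",
              length(x$gene_ids), length(x$lnc_ids), ncol(x$values)))
  invisible(x)
}

#' Rank-exponential feature weights
#'
#' For each sample, features are ranked 1..|N| in ascending expression order
#' (ties receive mid-ranks) and weighted
#' \deqn{w_{f,s} = r_{f,s} \cdot e^{\,sign \cdot r_{f,s}/|N|}.}
#' The default \code{exponent_sign = +1} follows the integrated scheme as
#' published; \code{-1} reproduces the decaying exponent of the FAIME
#' ancestor. Both are strictly increasing in rank on \eqn{r \in [1, |N|]}, so
#' order statistics downstream are insensitive to the choice.
#'
#' @param merged A \code{\link{merge_profiles}} result, or a plain numeric
#'   matrix (features x samples).
#' @param exponent_sign \code{+1} (default) or \code{-1}.
#' @return Numeric weight matrix, same dimnames as the input values.
#' @export
rank_weights <- function(merged, exponent_sign = 1) {
  stopifnot(exponent_sign %in% c(1, -1))
  values <- if (inherits(merged, "merged_expression")) merged$values else merged
  stopifnot(is.matrix(values), nrow(values) >= 1, ncol(values) >= 1)
  n <- nrow(values)
  w <- apply(values, 2, function(x) {
    r <- rank(x, ties.method = "average")
    r * exp(exponent_sign * r / n)
  })
  w <- matrix(w, nrow = n, dimnames = dimnames(values))
  w
}

#' Subpathway activity of one subpathway across samples
#'
#' \eqn{sPA_{i,s}} is the mean weight of the subpathway's measured components
#' (member genes and lncRNAs present in the weight matrix) minus the mean
#' weight of all measured features outside the subpathway. Unmeasured
#' components are ignored; their count is attached as attribute
#' \code{n_unmeasured}. If no component is measured, a vector of \code{NA}
#' with attribute \code{measured = 0} is returned so the caller can exclude
#' the subpathway.
#'
#' @param weights Weight matrix from \code{\link{rank_weights}}.
#' @param sub A \code{\link{subpathway_graph}} (or a character vector of
#'   member ids).
#' @return Named numeric vector of per-sample activities.
#' @export
subpathway_activity <- function(weights, sub) {
  members <- if (inherits(sub, "subpathway_graph")) subpathway_members(sub) else as.character(sub)
  feats <- rownames(weights)
  comp <- intersect(members, feats)
  rest <- setdiff(feats, members)
  if (length(rest) == 0L) {
    stop("complement is empty: subpathway covers every measured feature")
  }
  if (length(comp) == 0L) {
    out <- stats::setNames(rep(NA_real_, ncol(weights)), colnames(weights))
    attr(out, "measured") <- 0L
    attr(out, "n_unmeasured") <- length(members)
    return(out)
  }
  spa <- colMeans(weights[comp, , drop = FALSE]) -
    colMeans(weights[rest, , drop = FALSE])
  attr(spa, "measured") <- length(comp)
  attr(spa, "n_unmeasured") <- length(members) - length(comp)
  spa
}

#' Z-normalize raw activities across samples
#'
#' Per subpathway row: \eqn{(sPA - \bar{sPA}) / S(sPA)} with the sample
#' standard deviation (denominator \eqn{n-1}). Constant rows are undefined
#' under this statistic and are returned as all-zero, flagged in
#' \code{constant}.
#'
#' @param raw Numeric matrix, subpathways x samples (>= 2 samples).
#' @return An \code{activity_profile}: list with matrices \code{spa} and
#'   \code{spa_norm}, logical vector \code{constant}, numeric vectors
#'   \code{row_mean} and \code{row_sd}.
#' @export
normalize_activity <- function(raw) {
  stopifnot(is.matrix(raw))
  if (ncol(raw) < 2) stop("normalization needs >= 2 samples")
  m <- rowMeans(raw)
  s <- apply(raw, 1, stats::sd)
  constant <- s == 0 | !is.finite(s)
  if (any(constant)) {
    warning(sum(constant), " constant activity row(s) set to zero: ",
            paste(utils::head(rownames(raw)[constant], 5), collapse = ", "))
  }
  denom <- ifelse(constant, 1, s)
  z <- (raw - m) / denom
  z[constant, ] <- 0
  structure(list(spa = raw, spa_norm = z, constant = constant,
                 row_mean = m, row_sd = s),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("activity_profile: %d subpathways x %d samples (%d constant row(s))\n",
              nrow(x$spa), ncol(x$spa), sum(x$constant)))
  if (length(attr(x, "skipped"))) {
    cat("skipped (no measured component):",
        paste(attr(x, "skipped"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compute the subpathway activity profile
#'
#' Batch driver: weights the merged matrix once, scores every subpathway, and
#' z-normalizes, producing the profile with subpathways as rows and samples
#' as columns. Subpathways with fewer than \code{min_measured} measured
#' components are skipped with a warning; their ids are recorded in the
#' \code{"skipped"} attribute.
#'
#' @param merged A \code{\link{merge_profiles}} result.
#' @param subpathways List of \code{\link{subpathway_graph}} objects.
#' @param exponent_sign Passed to \code{\link{rank_weights}}.
#' @param min_measured Minimum measured components per subpathway (default 1).
#' @return An \code{activity_profile} (see \code{\link{normalize_activity}}).
#' @export
activity_profile <- function(merged, subpathways, exponent_sign = 1,
                             min_measured = 1) {
  stopifnot(length(subpathways) >= 1)
  w <- rank_weights(merged, exponent_sign)
  ids <- vapply(subpathways, function(s) s$subpathway_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subpathway ids")
  rows <- lapply(subpathways, function(s) subpathway_activity(w, s))
  measured <- vapply(rows, function(r) attr(r, "measured") %||% 0L, integer(1))
  skip <- measured < min_measured
  if (any(skip)) {
    warning(sum(skip), " subpathway(s) skipped (< ", min_measured,
            " measured component): ", paste(ids[skip], collapse = ", "))
  }
  if (all(skip)) stop("no subpathway has enough measured components")
  raw <- do.call(rbind, rows[!skip])
  rownames(raw) <- ids[!skip]
  prof <- normalize_activity(raw)
  attr(prof, "skipped") <- ids[skip]
  attr(prof, "exponent_sign") <- exponent_sign
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a
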