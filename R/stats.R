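# Statistical kernels: the combined gene+lncRNA hypergeometric enrichment
# test with Benjamini-Hochberg correction, Wilcoxon rank-sum differential
# activity, Pearson correlation of per-type mean activities, and the
# hypergeometric comparison of two subpathway signatures.

#' Combined gene+lncRNA hypergeometric enrichment p-value
#'
#' Upper-tail probability that a subpathway holds at least the observed
#' number of significant components, treating genes and lncRNAs as one pooled
#' population: with \eqn{m = m_g + m_{lnc}} features in the universe,
#' \eqn{t = t_g + t_{lnc}} of them in the subpathway and
#' \eqn{n = n_g + n_{lnc}} significant overall,
#' \deqn{P = P(X \ge r_g + r_{lnc}), \quad X \sim
#'   \mathrm{Hypergeom}(m, t, n).}
#' Computed through the hypergeometric survival function, so it is accurate
#' well beyond the populations used here.
#'
#' @param m_g,m_lnc Universe sizes (measured genes, measured lncRNAs).
#' @param t_g,t_lnc Subpathway members inside each universe.
#' @param n_g,n_lnc Significant features in each universe.
#' @param r_g,r_lnc Significant subpathway members.
#' @return The upper-tail p-value in [0, 1].
#' @export
combined_hypergeometric <- function(m_g, t_g, n_g, r_g,
                                    m_lnc = 0, t_lnc = 0, n_lnc = 0,
                                    r_lnc = 0) {
  chk <- function(ok, what) if (!ok) stop("violated: ", what, call. = FALSE)
  for (v in list(m_g, t_g, n_g, r_g, m_lnc, t_lnc, n_lnc, r_lnc)) {
    chk(length(v) == 1 && is.finite(v) && v >= 0 && v == round(v),
        "all counts must be single non-negative integers")
  }
  chk(t_g <= m_g, "t_g <= m_g")
  chk(t_lnc <= m_lnc, "t_lnc <= m_lnc")
  chk(n_g <= m_g, "n_g <= m_g")
  chk(n_lnc <= m_lnc, "n_lnc <= m_lnc")
  chk(r_g <= min(t_g, n_g), "r_g <= min(t_g, n_g)")
  chk(r_lnc <= min(t_lnc, n_lnc), "r_lnc <= min(t_lnc, n_lnc)")
  m <- m_g + m_lnc; t <- t_g + t_lnc; n <- n_g + n_lnc; r <- r_g + r_lnc
  chk(r <= n, "r_g + r_lnc <= n_g + n_lnc")
  if (r == 0) return(1)
  stats::phyper(r - 1, t, m - t, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR correction, returned in input order. Thin, validated
#' wrapper around \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment of subpathways in a significant feature set
#'
#' Applies \code{\link{combined_hypergeometric}} to every subpathway: the
#' universe is the measured merged matrix (genes and lncRNAs counted in their
#' own namespaces), the draw is the set of significant features, and the
#' overlap is counted per subpathway. BH-adjusted p-values are appended.
#'
#' @param subpathways List of \code{\link{subpathway_graph}} objects.
#' @param sig_features Character vector of significant feature ids.
#' @param universe_genes,universe_lncs Character vectors of all measured gene
#'   and lncRNA ids (e.g. the rows of the merged matrix).
#' @return Data frame: subpathway_id, the eight counts, p, p_adjusted.
#' @export
enrich_subpathways <- function(subpathways, sig_features,
                               universe_genes, universe_lncs) {
  if (length(intersect(universe_genes, universe_lncs))) {
    stop("gene and lncRNA universes overlap")
  }
  sig_features <- unique(sig_features)
  outside <- setdiff(sig_features, c(universe_genes, universe_lncs))
  if (length(outside)) {
    stop("significant feature(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  sig_g <- intersect(sig_features, universe_genes)
  sig_l <- intersect(sig_features, universe_lncs)
  rows <- lapply(subpathways, function(sp) {
    tg <- intersect(sp$genes, universe_genes)
    tl <- intersect(sp$lncrnas, universe_lncs)
    data.frame(
      subpathway_id = sp$subpathway_id,
      m_g = length(universe_genes), m_lnc = length(universe_lncs),
      t_g = length(tg), t_lnc = length(tl),
      n_g = length(sig_g), n_lnc = length(sig_l),
      r_g = length(intersect(tg, sig_g)),
      r_lnc = length(intersect(tl, sig_l)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p <- mapply(combined_hypergeometric,
                  m_g = out$m_g, t_g = out$t_g, n_g = out$n_g, r_g = out$r_g,
                  m_lnc = out$m_lnc, t_lnc = out$t_lnc, n_lnc = out$n_lnc,
                  r_lnc = out$r_lnc)
  out$p_adjusted <- bh_adjust(out$p)
  out
}

#' Differential subpathway activity between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test per subpathway on normalized activities
#' (exact when both groups have <= 10 samples and no ties, normal
#' approximation with continuity correction otherwise). Direction is the sign
#' of median(A) - median(B); \code{call} reports
#' \code{"higher_in_A"} / \code{"higher_in_B"} at level \code{alpha}, else
#' \code{"ns"}.
#'
#' @param profile An \code{activity_profile}.
#' @param group_a,group_b Disjoint character vectors of sample ids, each with
#'   >= 2 samples.
#' @param alpha Significance level for the direction call (default 0.05).
#' @param use \code{"spa_norm"} (default) or \code{"spa"}.
#' @return Data frame: subpathway_id, statistic (Mann-Whitney U for group A),
#'   p, p_adjusted, direction (-1, 0, +1), call.
#' @export
differential_activity <- function(profile, group_a, group_b, alpha = 0.05,
                                  use = c("spa_norm", "spa")) {
  use <- match.arg(use)
  mat <- profile[[use]]
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  missing <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing)) {
    stop("sample(s) not in profile: ", paste(missing, collapse = ", "))
  }
  res <- apply(mat, 1, function(row) {
    a <- row[group_a]; b <- row[group_b]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    c(statistic = unname(wt$statistic), p = wt$p.value,
      direction = sign(stats::median(a) - stats::median(b)))
  })
  out <- data.frame(subpathway_id = rownames(mat),
                    statistic = res["statistic", ],
                    p = res["p", ],
                    direction = res["direction", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adjusted <- bh_adjust(out$p)
  out$call <- ifelse(out$p >= alpha, "ns",
                     ifelse(out$direction > 0, "higher_in_A", "higher_in_B"))
  out
}

#' Pearson correlation of per-type mean activities
#'
#' For each sample type, the mean normalized activity vector over its samples
#' is taken as the type's activity fingerprint; all pairwise Pearson
#' correlations between fingerprints are returned with two-sided p-values
#' from the t distribution on (number of subpathways - 2) degrees of freedom.
#'
#' @param profile An \code{activity_profile} with >= 3 subpathways.
#' @param types Named character vector or factor: sample id -> type label
#'   (>= 2 types, each with >= 1 sample in the profile).
#' @return List with \code{means} (subpathway x type matrix), \code{r} and
#'   \code{p} (type x type matrices; the diagonal of \code{r} is 1 and of
#'   \code{p} is NA).
#' @export
type_mean_correlation <- function(profile, types) {
  mat <- profile$spa_norm
  if (nrow(mat) < 3) stop("need >= 3 subpathways for correlation p-values")
  types <- types[names(types) %in% colnames(mat)]
  lv <- sort(unique(as.character(types)))
  if (length(lv) < 2) stop("need >= 2 types")
  means <- vapply(lv, function(t) {
    ids <- names(types)[types == t]
    if (length(ids) == 0) stop("type '", t, "' has zero samples")
    rowMeans(mat[, ids, drop = FALSE])
  }, numeric(nrow(mat)))
  r <- stats::cor(means)
  df <- nrow(mat) - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  diag(p) <- NA_real_
  list(means = means, r = r, p = p)
}

#' Hypergeometric overlap of two subpathway signatures
#'
#' Upper-tail p-value for observing at least \eqn{|A \cap B|} common
#' subpathways when \eqn{|A|} subpathways are drawn from a universe of
#' \code{universe_size} containing \eqn{|B|} marked ones. Delegates to
#' \code{\link{combined_hypergeometric}} with the lncRNA counts zeroed.
#'
#' @param set_a,set_b Character vectors of subpathway ids.
#' @param universe_size Number of subpathways tested overall.
#' @return The overlap p-value.
#' @export
signature_overlap <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (universe_size < length(union(set_a, set_b))) {
    stop("universe_size smaller than |A union B|")
  }
  combined_hypergeometric(m_g = universe_size, t_g = length(set_b),
                          n_g = length(set_a),
                          r_g = length(intersect(set_a, set_b)))
}
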