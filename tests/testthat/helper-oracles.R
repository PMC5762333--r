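# Independent oracles: brute-force or closed-form implementations kept
# deliberately naive and separate from the package's code paths.

# All maximal node sets with pairwise shortest-path distance <= k, by
# exhaustive enumeration of node subsets.
brute_force_distk_sets <- function(pg, k) {
  nodes <- pg$nodes
  n <- length(nodes)
  if (n == 0) return(list())
  ig <- igraph::graph_from_data_frame(
    as.data.frame(pg$edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  d <- igraph::distances(ig)[nodes, nodes, drop = FALSE]
  ok <- list()
  for (mask in 1:(2^n - 1)) {
    sel <- nodes[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
    if (all(d[sel, sel] <= k)) ok[[length(ok) + 1]] <- sel
  }
  maximal <- Filter(function(s) {
    !any(vapply(ok, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, ok)
  sets <- lapply(maximal, sort)
  sizes <- lengths(sets)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  unique(sets[order(-sizes, keys)])
}

# Random labelled pathway graph on n nodes with edge probability p.
random_pathway_graph <- function(n, p) {
  nodes <- sprintf("g%02d", seq_len(n))
  pairs <- if (n >= 2) t(utils::combn(nodes, 2)) else
    matrix(character(0), ncol = 2)
  keep <- stats::runif(nrow(pairs)) < p
  pathway_graph("path:test", "random", nodes, pairs[keep, , drop = FALSE])
}

# Naive sPA: per sample, ranks computed by counting smaller/equal values,
# weights and the two means accumulated in an explicit loop.
naive_spa <- function(values, members, exponent_sign = 1) {
  n <- nrow(values)
  feats <- rownames(values)
  comp <- feats[feats %in% members]
  rest <- feats[!(feats %in% members)]
  out <- numeric(ncol(values))
  for (s in seq_len(ncol(values))) {
    x <- values[, s]
    r <- numeric(n)
    for (i in seq_len(n)) {
      n_less <- sum(x < x[i])
      n_tied <- sum(x == x[i])
      r[i] <- n_less + (n_tied + 1) / 2
    }
    w <- r * exp(exponent_sign * r / n)
    names(w) <- feats
    out[s] <- sum(w[comp]) / length(comp) - sum(w[rest]) / length(rest)
  }
  names(out) <- colnames(values)
  out
}

# Exact hypergeometric upper tail P(X >= r) by direct summation.
enum_hyper_tail <- function(m, t, n, r) {
  if (r <= 0) return(1)
  if (r > min(t, n)) return(0)
  ks <- r:min(t, n)
  ks <- ks[n - ks <= m - t]
  if (length(ks) == 0) return(0)
  sum(choose(t, ks) * choose(m - t, n - ks)) / choose(m, n)
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all group-A rank
# assignments (tie-free inputs only).
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Two-group log-rank chi-square from the observed-minus-expected tabulation
# at each distinct event time.
logrank_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(time == tt & event == 1)
    d1j <- sum(time == tt & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1j - dj * n1j / nj
    if (nj > 1) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Cox partial log-likelihood for a single covariate, tie-free data.
cox_partial_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Quiet wrappers for generator calls whose messages are not under test.
quiet_simulate <- function(cfg, ...) {
  suppressWarnings(suppressMessages(simulate_cohort(cfg, ...)))
}
quiet_profile <- function(merged, subs, ...) {
  suppressWarnings(activity_profile(merged, subs, ...))
}
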