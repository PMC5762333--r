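# Clustering, cohort splitting, Cox screening, K-means risk groups and
# Kaplan-Meier/log-rank.

test_that("uncentered correlation distance: identities and scale invariance", {
  m <- rbind(x = c(1, 0), y = c(0, 1), z = c(2, 0), w = c(1, 1))
  d <- as.matrix(uncentered_cor_dist(m))
  expect_equal(d["x", "y"], 1)
  expect_equal(d["x", "z"], 0)            # d(x, c*x) = 0 for c > 0
  expect_equal(d["x", "x"], 0)
  expect_equal(d["x", "w"], 1 - 1 / sqrt(2))
  expect_error(uncentered_cor_dist(rbind(a = c(0, 0), b = c(1, 1))),
               "all-zero")
})

test_that("hierarchical clustering is deterministic and rescale-invariant", {
  set.seed(31)
  mat <- matrix(rnorm(5 * 8) + 2, 5, 8,
                dimnames = list(paste0("p", 1:5), paste0("s", 1:8)))
  prof <- structure(list(spa = mat, spa_norm = mat, constant = rep(FALSE, 5)),
                    class = "activity_profile")
  c1 <- hierarchical_cluster(prof, axis = "samples", n_clusters = 3)
  c2 <- hierarchical_cluster(prof, axis = "samples", n_clusters = 3)
  expect_identical(c1$order, c2$order)
  expect_identical(c1$clusters, c2$clusters)
  expect_length(c1$order, 8)

  # positive per-sample rescaling leaves the tree untouched
  scale <- runif(8, 0.5, 4)
  mat_s <- sweep(mat, 2, scale, `*`)
  prof_s <- structure(list(spa = mat_s, spa_norm = mat_s,
                           constant = rep(FALSE, 5)),
                      class = "activity_profile")
  c3 <- hierarchical_cluster(prof_s, axis = "samples")
  expect_equal(c3$hclust$merge, c1$hclust$merge)
  expect_equal(c3$hclust$height, c1$hclust$height)
})

test_that("cohort splitting is an equal, seed-reproducible partition", {
  cl <- data.frame(sample_id = paste0("s", 1:10),
                   time = 1:10, event = rep(c(0, 1), 5))
  sp <- split_cohort(cl, seed = 5)
  expect_length(sp$train, 5)
  expect_length(sp$test, 5)
  expect_setequal(c(sp$train, sp$test), cl$sample_id)
  expect_identical(split_cohort(cl, seed = 5), sp)
  expect_false(identical(split_cohort(cl, seed = 6)$train, sp$train))

  # odd n: train gets the extra sample; unusable rows are excluded
  cl11 <- rbind(cl, data.frame(sample_id = "s11", time = 3, event = 1))
  sp11 <- split_cohort(cl11, seed = 1)
  expect_length(sp11$train, 6)
  cl_bad <- cl
  cl_bad$time[1] <- NA
  expect_warning(spb <- split_cohort(cl_bad, seed = 1), "excluded")
  expect_false("s1" %in% c(spb$train, spb$test))
})

test_that("univariate Cox matches a partial-likelihood grid maximizer", {
  set.seed(41)
  x <- c(0.3, -1.2, 0.8, 1.5, -0.4, 0.1)
  time <- c(2, 5, 1, 8, 3, 13)           # tie-free
  event <- rep(1, 6)
  cl <- data.frame(sample_id = paste0("s", 1:6), time = time, event = event)
  fit <- univariate_cox(setNames(x, cl$sample_id), cl)
  expect_true(fit$ok)
  opt <- optimize(function(b) cox_partial_loglik(b, x, time, event),
                  c(-10, 10), maximum = TRUE, tol = 1e-9)
  expect_equal(fit$coefficient, opt$maximum, tolerance = 1e-4)
  expect_equal(fit$hazard_ratio, exp(fit$coefficient))

  # negating the covariate flips the sign, keeps the magnitude
  fit_neg <- univariate_cox(setNames(-x, cl$sample_id), cl)
  expect_equal(fit_neg$coefficient, -fit$coefficient, tolerance = 1e-8)
  expect_equal(fit_neg$wald_p, fit$wald_p, tolerance = 1e-8)

  # degenerate inputs are flagged, not errors
  expect_false(univariate_cox(setNames(rep(1, 6), cl$sample_id), cl)$ok)
  cl0 <- cl; cl0$event <- 0
  expect_false(univariate_cox(setNames(x, cl$sample_id), cl0)$ok)
})

test_that("signature selection applies a strict threshold", {
  cox <- data.frame(subpathway_id = c("a", "b", "c"),
                    wald_p = c(0.009, 0.011, NA),
                    ok = c(TRUE, TRUE, FALSE))
  expect_equal(select_signature(cox)$signature, "a")
  expect_equal(select_signature(cox, threshold = 1)$signature, c("a", "b"))
  expect_length(select_signature(cox[0, ])$signature, 0)
})

test_that("K-means recovers well-separated blobs and is seed-stable", {
  set.seed(51)
  n <- 20
  centers <- rbind(rep(0, 3), rep(10, 3))
  truth <- rep(1:2, each = n)
  x <- centers[truth, ] + matrix(rnorm(2 * n * 3, sd = 1), 2 * n, 3)
  mat <- t(x)
  dimnames(mat) <- list(paste0("p", 1:3), paste0("s", 1:(2 * n)))
  prof <- structure(list(spa = mat, spa_norm = mat, constant = rep(FALSE, 3)),
                    class = "activity_profile")
  km <- kmeans_risk_groups(prof, paste0("p", 1:3), k = 2, seed = 3)
  tab <- table(km$groups, truth)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))  # pure groups
  km2 <- kmeans_risk_groups(prof, paste0("p", 1:3), k = 2, seed = 3)
  expect_identical(km$groups, km2$groups)
  expect_equal(unname(kmeans_risk_groups(prof, paste0("p", 1:3), k = 1,
                                         seed = 1)$groups),
               rep(1L, 2 * n))
  expect_error(kmeans_risk_groups(prof, paste0("p", 1:3), k = 100, seed = 1),
               "exceeds")
})

test_that("log-rank matches the hand tabulation and its invariances", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  group <- rep(c("A", "B"), 3)
  cl <- data.frame(sample_id = paste0("s", 1:6), time = time, event = event)
  groups <- setNames(group, cl$sample_id)
  res <- km_logrank(groups, cl)
  oracle <- logrank_oracle(time, event, group)
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$df, 1)

  # identical groups: statistic 0, p = 1
  cl2 <- data.frame(sample_id = paste0("s", 1:8),
                    time = rep(c(1, 4, 6, 9), 2),
                    event = rep(c(1, 0, 1, 1), 2))
  g2 <- setNames(rep(c("A", "B"), each = 4), cl2$sample_id)
  res2 <- km_logrank(g2, cl2)
  expect_equal(res2$chisq, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)

  # df = k - 1 for k groups
  cl3 <- data.frame(sample_id = paste0("s", 1:9), time = 1:9,
                    event = rep(1, 9))
  g3 <- setNames(rep(c("A", "B", "C"), each = 3), cl3$sample_id)
  expect_equal(km_logrank(g3, cl3)$df, 2)

  # censoring times matter only through their position relative to event
  # times: delaying a censoring beyond the last event changes nothing
  cl4 <- rbind(cl, data.frame(sample_id = "s7", time = 6.5, event = 0))
  cl5 <- rbind(cl, data.frame(sample_id = "s7", time = 99, event = 0))
  g4 <- c(groups, s7 = "A")
  expect_equal(km_logrank(g4, cl5)$chisq, km_logrank(g4, cl4)$chisq,
               tolerance = 1e-12)

  expect_error(km_logrank(setNames(rep("A", 6), cl$sample_id), cl),
               ">= 2")
})

test_that("the prognosis pipeline report is reproducible end to end", {
  cfg <- sim_config(seed = 77, n_tumor = 40, n_normal = 0, cox_beta = 1.2)
  sim <- quiet_simulate(cfg)
  run <- function() {
    suppressWarnings(prognosis_pipeline(
      sim$gene_expr[, sim$clinical$sample_id],
      sim$lnc_expr[, sim$clinical$sample_id],
      sim$subpathways, sim$clinical, split_seed = 3))
  }
  r1 <- run(); r2 <- run()
  f1 <- tempfile(); f2 <- tempfile()
  write_prognosis_report(r1, f1)
  write_prognosis_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_setequal(c(r1$split$train, r1$split$test), sim$clinical$sample_id)
  expect_equal(nrow(r1$cox), length(sim$subpathways))
  expect_equal(nrow(r1$overlap), 3)
  if (length(r1$signature)) {
    expect_true(all(r1$signature %in% r1$cox$subpathway_id))
    expect_true(all(r1$cox$wald_p[r1$cox$subpathway_id %in% r1$signature] <
                      0.01))
    expect_setequal(names(r1$risk_groups), r1$split$test)
  }
})
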