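# Synthetic-cohort generator: toy pathway graphs (optionally serialized as
# KGML), regulation tables, gene+lncRNA expression with planted multiplicative
# subpathway effects in a tumor group, and censored survival times whose
# hazard depends on a chosen subpathway's activity. One master seed fixes
# every downstream artifact, so the whole pipeline is testable offline.

#' Simulation configuration
#'
#' Defaults describe a compact but realistic study: a handful of sparse
#' connected pathways, lncRNAs each regulating a few genes, a 30-vs-30
#' tumor/normal cohort, a four-fold multiplicative effect on the members of
#' one planted subpathway in tumor samples, and exponential survival whose
#' log-hazard rises by \code{cox_beta} per unit of normalized activity with
#' roughly 30 percent uniform censoring.
#'
#' @param n_pathways Number of pathways (default 4).
#' @param genes_per_pathway Genes per pathway (default 15).
#' @param edge_prob Edge probability of the random pathway graph (default
#'   0.18; graphs are resampled until connected).
#' @param n_lncrnas Number of lncRNAs (default 40).
#' @param regs_per_lncrna Genes regulated by each lncRNA (default 4).
#' @param n_tumor,n_normal Cohort sizes (defaults 30 and 30).
#' @param effect_subpathways Subpathway ids carrying the planted effect;
#'   \code{NULL} (default) means the first reconstructed subpathway.
#' @param effect_fold Multiplicative expression effect on planted members in
#'   tumor samples (default 4; 1 = null).
#' @param expr_log_mean,expr_log_sd Log-normal baseline expression parameters
#'   (defaults 1 and 1, an RPKM-like scale).
#' @param cox_beta Log-hazard slope per unit normalized activity (default
#'   0.8; 0 = null).
#' @param baseline_hazard Baseline exponential hazard per day (default 0.002).
#' @param censor_rate Target fraction censored (default 0.3).
#' @param seed Mandatory integer master seed.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_pathways = 4, genes_per_pathway = 15,
                       edge_prob = 0.18, n_lncrnas = 40, regs_per_lncrna = 4,
                       n_tumor = 30, n_normal = 30,
                       effect_subpathways = NULL, effect_fold = 4,
                       expr_log_mean = 1, expr_log_sd = 1,
                       cox_beta = 0.8, baseline_hazard = 0.002,
                       censor_rate = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
              edge_prob = edge_prob, n_lncrnas = n_lncrnas,
              regs_per_lncrna = regs_per_lncrna, n_tumor = n_tumor,
              n_normal = n_normal, effect_subpathways = effect_subpathways,
              effect_fold = effect_fold, expr_log_mean = expr_log_mean,
              expr_log_sd = expr_log_sd, cox_beta = cox_beta,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              seed = as.integer(seed))
  with(cfg, stopifnot(n_pathways >= 1, genes_per_pathway >= 2,
                      edge_prob > 0, edge_prob <= 1, n_lncrnas >= 1,
                      regs_per_lncrna >= 1, n_tumor + n_normal >= 2,
                      effect_fold > 0, expr_log_sd > 0, baseline_hazard > 0,
                      censor_rate >= 0, censor_rate < 1))
  structure(cfg, class = "sim_config")
}

#' Generate random connected pathway graphs
#'
#' Erdos-Renyi graphs resampled until connected (bounded retries). Gene ids
#' are globally unique across pathways (\code{"hsa:<n>"} tokens) so pathway
#' membership is unambiguous.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed (omit when calling under an outer seed).
#' @param max_tries Resampling budget per pathway (default 500).
#' @return List of \code{\link{pathway_graph}} objects.
#' @export
generate_pathways <- function(config, seed = NULL, max_tries = 500) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$genes_per_pathway
  lapply(seq_len(config$n_pathways), function(i) {
    genes <- sprintf("hsa:%d", i * 1000 + seq_len(n))
    for (try in seq_len(max_tries)) {
      g <- igraph::sample_gnp(n, config$edge_prob)
      if (igraph::is_connected(g)) {
        el <- igraph::as_edgelist(g)
        return(pathway_graph(sprintf("path:9%04d", i),
                             sprintf("synthetic pathway %d", i),
                             genes,
                             cbind(genes[el[, 1]], genes[el[, 2]])))
      }
    }
    stop("could not sample a connected pathway graph with edge_prob = ",
         config$edge_prob, " after ", max_tries, " tries")
  })
}

#' Generate a random regulation table
#'
#' Each lncRNA regulates \code{regs_per_lncrna} genes drawn uniformly without
#' replacement from the pooled pathway genes.
#'
#' @param config A \code{\link{sim_config}}.
#' @param gene_ids Pool of gene identifiers.
#' @param seed Optional seed.
#' @return A \code{\link{regulation_table}}.
#' @export
generate_regulations <- function(config, gene_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- min(config$regs_per_lncrna, length(gene_ids))
  lnc <- sprintf("lnc:L%03d", seq_len(config$n_lncrnas))
  pairs <- lapply(lnc, function(l) cbind(l, sample(gene_ids, k)))
  pairs <- do.call(rbind, pairs)
  regulation_table(pairs[, 1], pairs[, 2])
}

#' Generate a gene+lncRNA expression cohort with a planted effect
#'
#' Baseline expression is i.i.d. log-normal. In tumor samples, every member
#' (gene or lncRNA) of each effect subpathway is multiplied by
#' \code{effect_fold}; an \code{effect_fold} of 1 therefore generates a null
#' cohort whose tumor and normal samples share one distribution.
#'
#' @param config A \code{\link{sim_config}}.
#' @param subpathways List of \code{subpathway_graph}s; those named in
#'   \code{config$effect_subpathways} carry the effect (\code{NULL} means the
#'   first one).
#' @param gene_ids,lnc_ids Feature universes; defaults are the unions over
#'   \code{subpathways}.
#' @param seed Optional seed.
#' @return List with \code{gene_expr}, \code{lnc_expr} (matrices),
#'   \code{design} (data frame: sample_id, tumor_type, condition) and
#'   \code{effect_subpathways}.
#' @export
generate_expression <- function(config, subpathways,
                                gene_ids = NULL, lnc_ids = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_ids)) {
    gene_ids <- sort(unique(unlist(lapply(subpathways, `[[`, "genes"))))
  }
  if (is.null(lnc_ids)) {
    lnc_ids <- sort(unique(unlist(lapply(subpathways, `[[`, "lncrnas"))))
  }
  ids <- vapply(subpathways, function(s) s$subpathway_id, character(1))
  effect_ids <- config$effect_subpathways
  if (is.null(effect_ids)) effect_ids <- ids[1]
  if (!all(effect_ids %in% ids)) {
    stop("effect subpathway(s) not found: ",
         paste(setdiff(effect_ids, ids), collapse = ", "))
  }
  members <- unique(unlist(lapply(subpathways[ids %in% effect_ids],
                                  subpathway_members)))
  samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
               sprintf("N%03d", seq_len(config$n_normal)))
  condition <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  all_feats <- c(gene_ids, lnc_ids)
  vals <- matrix(stats::rlnorm(length(all_feats) * length(samples),
                               config$expr_log_mean, config$expr_log_sd),
                 nrow = length(all_feats),
                 dimnames = list(all_feats, samples))
  hit <- rownames(vals) %in% members
  vals[hit, condition == "tumor"] <-
    vals[hit, condition == "tumor"] * config$effect_fold
  list(gene_expr = vals[gene_ids, , drop = FALSE],
       lnc_expr = vals[lnc_ids, , drop = FALSE],
       design = data.frame(sample_id = samples, tumor_type = "SIM",
                           condition = condition, stringsAsFactors = FALSE),
       effect_subpathways = effect_ids)
}

#' Generate activity-linked censored survival times
#'
#' Event times are exponential with hazard
#' \code{baseline_hazard * exp(cox_beta * activity)}; censoring is
#' independent uniform on \code{(0, tau)} with \code{tau} solved so the
#' expected censored fraction at zero activity equals \code{censor_rate}
#' (\code{censor_rate = 0} disables censoring).
#'
#' @param activity Named numeric vector (sample id -> activity, typically a
#'   normalized profile row).
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed.
#' @return A clinical data frame (sample_id, time, event).
#' @export
generate_survival <- function(activity, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(names(activity)), all(is.finite(activity)))
  n <- length(activity)
  haz <- config$baseline_hazard * exp(config$cox_beta * activity)
  t_event <- stats::rexp(n, rate = haz)
  if (config$censor_rate > 0) {
    lam <- config$baseline_hazard
    # P(censored) for T ~ Exp(lam), C ~ U(0, tau) is (1 - exp(-lam*tau))/(lam*tau)
    tau <- stats::uniroot(function(x) (1 - exp(-lam * x)) / (lam * x) -
                            config$censor_rate,
                          lower = 1e-9, upper = 1e12, tol = 1e-9)$root
    t_cens <- stats::runif(n, 0, tau)
    time <- pmin(t_event, t_cens)
    event <- as.numeric(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1, n)
  }
  data.frame(sample_id = names(activity), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' End-to-end generator under one master seed: pathways, regulations,
#' reconstructed subpathways, expression with the planted effect, the
#' activity profile of the tumor samples, and survival generated from the
#' planted subpathway's normalized activity. Optionally writes every artifact
#' (KGML files, regulation/expression/clinical TSVs, the subpathway
#' definition file and a ground-truth manifest) to \code{out_dir}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Optional output directory.
#' @param k,min_genes,min_lncrnas Reconstruction parameters (defaults 3/3/2).
#' @return List with all generated objects plus \code{truth} (planted
#'   subpathway ids, effect_fold, cox_beta).
#' @export
simulate_cohort <- function(config, out_dir = NULL, k = 3, min_genes = 3,
                            min_lncrnas = 2) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pathways <- generate_pathways(config)
  gene_ids <- sort(unique(unlist(lapply(pathways, `[[`, "nodes"))))
  regs <- generate_regulations(config, gene_ids)
  subs <- reconstruct_all(pathways, regs, k = k, min_genes = min_genes,
                          min_lncrnas = min_lncrnas)
  if (length(subs) == 0) stop("no subpathway survived reconstruction; ",
                              "adjust the simulation configuration")
  lnc_ids <- sort(unique(regs$lncrna))
  expr <- generate_expression(config, subs, gene_ids = gene_ids,
                              lnc_ids = lnc_ids)
  tumor_ids <- expr$design$sample_id[expr$design$condition == "tumor"]
  clinical <- NULL
  profile_tumor <- NULL
  if (length(tumor_ids) >= 2) {
    merged <- merge_profiles(expr$gene_expr[, tumor_ids, drop = FALSE],
                             expr$lnc_expr[, tumor_ids, drop = FALSE])
    profile_tumor <- activity_profile(merged, subs)
    gen_row <- profile_tumor$spa_norm[expr$effect_subpathways[1], ]
    clinical <- generate_survival(gen_row, config)
  }
  out <- list(config = config, pathways = pathways, regulations = regs,
              subpathways = subs, gene_expr = expr$gene_expr,
              lnc_expr = expr$lnc_expr, design = expr$design,
              profile_tumor = profile_tumor, clinical = clinical,
              truth = list(effect_subpathways = expr$effect_subpathways,
                           effect_fold = config$effect_fold,
                           cox_beta = config$cox_beta))
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# Serialize every simulated artifact as plain text under out_dir.
write_cohort <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kgml_dir <- file.path(out_dir, "kgml")
  dir.create(kgml_dir, showWarnings = FALSE)
  for (p in sim$pathways) {
    write_kgml(p, file.path(kgml_dir,
                            paste0(gsub("[^A-Za-z0-9]", "_", p$pathway_id),
                                   ".xml")))
  }
  utils::write.table(sim$regulations, file.path(out_dir, "regulations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("lncrna_id", "gene_id"))
  write_expression(sim$gene_expr, file.path(out_dir, "gene_expr.tsv"))
  write_expression(sim$lnc_expr, file.path(out_dir, "lnc_expr.tsv"))
  write_subpathways(sim$subpathways, file.path(out_dir, "subpathways.spw"))
  utils::write.table(sim$design, file.path(out_dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$clinical)) {
    write_clinical(sim$clinical, file.path(out_dir, "clinical.tsv"))
  }
  truth <- c(sim$truth, list(seed = sim$config$seed))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Serialize a pathway graph as KGML
#'
#' Writes a minimal KGML document (one gene entry per gene, one PPrel
#' relation per edge) that \code{\link{read_kgml}} parses back to the same
#' graph.
#'
#' @param graph A \code{\link{pathway_graph}}.
#' @param path Output path.
#' @export
write_kgml <- function(graph, path) {
  doc <- xml2::xml_new_root("pathway",
                            name = graph$pathway_id, title = graph$name,
                            org = "hsa")
  idx <- stats::setNames(seq_along(graph$nodes), graph$nodes)
  for (g in graph$nodes) {
    xml2::xml_add_child(doc, "entry", id = as.character(idx[[g]]),
                        name = g, type = "gene")
  }
  if (nrow(graph$edges) > 0) {
    for (i in seq_len(nrow(graph$edges))) {
      rel <- xml2::xml_add_child(
        doc, "relation",
        entry1 = as.character(idx[[graph$edges[i, 1]]]),
        entry2 = as.character(idx[[graph$edges[i, 2]]]),
        type = "PPrel")
      xml2::xml_add_child(rel, "subtype", name = "activation", value = "-->")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
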