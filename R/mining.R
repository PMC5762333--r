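# Subpathway mining: k-clique decomposition of pathway graphs (maximal gene
# sets with pairwise shortest-path distance <= k), lncRNA embedding through
# the competitive-regulation table, and the size filter that discards
# subpathways too small to score reliably.

#' Construct a subpathway graph
#'
#' A mined gene subgraph of a parent pathway plus the lncRNAs embedded into
#' it: every lncRNA regulates at least one member gene, and the regulation
#' edges are exactly the pairs of the regulation table whose gene lies inside
#' the subpathway.
#'
#' @param subpathway_id Identifier, \code{"<pathway_id>_<ordinal>"}.
#' @param parent_id Parent pathway identifier.
#' @param parent_name Parent pathway title.
#' @param genes Character vector of member gene ids.
#' @param lncrnas Character vector of embedded lncRNA ids.
#' @param gene_edges Two-column character matrix of gene-gene edges induced
#'   from the parent pathway.
#' @param reg_edges Two-column character matrix (lncrna, gene) of regulation
#'   edges; every gene must be a member.
#' @return An object of class \code{subpathway_graph}.
#' @export
subpathway_graph <- function(subpathway_id, parent_id, parent_name,
                             genes, lncrnas, gene_edges, reg_edges) {
  genes <- sort(unique(as.character(genes)))
  lncrnas <- sort(unique(as.character(lncrnas)))
  gene_edges <- canonical_edges(gene_edges)
  if (is.null(reg_edges) || length(reg_edges) == 0L) {
    reg_edges <- matrix(character(0), ncol = 2)
  }
  reg_edges <- unique(matrix(as.character(reg_edges), ncol = 2))
  reg_edges <- reg_edges[order(reg_edges[, 1], reg_edges[, 2]), , drop = FALSE]
  dimnames(reg_edges) <- list(NULL, c("lncrna", "gene"))
  sp <- structure(
    list(subpathway_id = as.character(subpathway_id),
         parent_id = as.character(parent_id),
         parent_name = as.character(parent_name),
         genes = genes, lncrnas = lncrnas,
         gene_edges = gene_edges, reg_edges = reg_edges),
    class = "subpathway_graph")
  validate_subpathway_graph(sp)
  sp
}

validate_subpathway_graph <- function(sp) {
  if (nrow(sp$gene_edges) > 0 &&
      length(setdiff(c(sp$gene_edges), sp$genes))) {
    stop("gene edge endpoint outside the subpathway gene set")
  }
  if (nrow(sp$reg_edges) > 0) {
    if (length(setdiff(sp$reg_edges[, 2], sp$genes))) {
      stop("regulation edge targets a gene outside the subpathway")
    }
    if (length(setdiff(sp$reg_edges[, 1], sp$lncrnas))) {
      stop("regulation edge from a lncRNA not in the embedded set")
    }
  }
  if (length(setdiff(sp$lncrnas, sp$reg_edges[, 1]))) {
    stop("embedded lncRNA(s) without any regulation edge: ",
         paste(setdiff(sp$lncrnas, sp$reg_edges[, 1]), collapse = ", "))
  }
  invisible(sp)
}

#' @export
print.subpathway_graph <- function(x, ...) {
  cat(sprintf("subpathway_graph %s (parent %s): %d genes, %d lncRNAs, %d gene edges, %d regulation edges\n",
              x$subpathway_id, x$parent_id, length(x$genes),
              length(x$lncrnas), nrow(x$gene_edges), nrow(x$reg_edges)))
  invisible(x)
}

#' All subpathway components (genes and lncRNAs)
#' @param sp A \code{subpathway_graph}.
#' @return Character vector of member gene and lncRNA ids.
#' @export
subpathway_members <- function(sp) c(sp$genes, sp$lncrnas)

#' Mine k-clique subpathways from a pathway graph
#'
#' Identifies all maximal gene sets in which every pair of members lies
#' within unweighted shortest-path distance \code{k} of each other in the
#' pathway graph. Implementation: threshold the all-pairs distance matrix at
#' \code{k} to build an auxiliary graph, then enumerate its maximal cliques.
#' Disconnected pathways are handled per component (infinite distances never
#' satisfy the threshold). Results are sorted by descending size, then
#' lexicographically by sorted member list, so ordinals assigned downstream
#' are stable across runs and input orderings.
#'
#' @param graph A \code{\link{pathway_graph}}.
#' @param k Maximum pairwise distance (default 3).
#' @return List of character vectors (sorted gene sets), possibly empty.
#' @export
mine_subpathways <- function(graph, k = 3) {
  stopifnot(inherits(graph, "pathway_graph"), k >= 1)
  n <- length(graph$nodes)
  if (n == 0L) return(list())
  ig <- pathway_igraph(graph)
  d <- igraph::distances(ig)
  adj <- d <= k & d > 0
  aux <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(aux)
  sets <- lapply(cliques, function(cl) sort(igraph::V(aux)$name[cl]))
  sets <- unique(sets)
  sizes <- lengths(sets)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  sets[order(-sizes, keys)]
}

#' Embed lncRNAs into a gene set
#'
#' A lncRNA is embedded if it competitively regulates at least one gene of
#' the set; the returned regulation edges are exactly the table pairs whose
#' gene lies inside the set.
#'
#' @param genes Character vector of gene ids.
#' @param regs A \code{\link{regulation_table}}.
#' @return List with elements \code{lncrnas} (character) and \code{reg_edges}
#'   (two-column character matrix: lncrna, gene).
#' @export
embed_lncrnas <- function(genes, regs) {
  inside <- regs$gene %in% genes
  edges <- cbind(regs$lncrna[inside], regs$gene[inside])
  list(lncrnas = sort(unique(edges[, 1])),
       reg_edges = matrix(edges, ncol = 2,
                          dimnames = list(NULL, c("lncrna", "gene"))))
}

# Gene-gene edges of the parent pathway induced on a member set.
induced_edges <- function(graph, genes) {
  keep <- graph$edges[, 1] %in% genes & graph$edges[, 2] %in% genes
  graph$edges[keep, , drop = FALSE]
}

#' Filter subpathways by size
#'
#' Subpathways with fewer than \code{min_genes} genes or fewer than
#' \code{min_lncrnas} embedded lncRNAs are discarded to reduce the bias of
#' very small graphs. Defaults follow the reconstruction procedure: at least
#' 3 genes and at least 2 lncRNAs.
#'
#' @param candidates List of \code{subpathway_graph} objects.
#' @param min_genes Minimum number of member genes (default 3).
#' @param min_lncrnas Minimum number of embedded lncRNAs (default 2).
#' @return Filtered list, in input order.
#' @export
filter_subpathways <- function(candidates, min_genes = 3, min_lncrnas = 2) {
  stopifnot(min_genes >= 1, min_lncrnas >= 0)
  ng <- vapply(candidates, function(s) length(s$genes), integer(1))
  nl <- vapply(candidates, function(s) length(s$lncrnas), integer(1))
  few_genes <- ng < min_genes
  few_lnc <- nl < min_lncrnas
  if (any(few_genes | few_lnc)) {
    message(sprintf("filtered %d subpathway(s): %d with < %d genes, %d with < %d lncRNAs",
                    sum(few_genes | few_lnc), sum(few_genes), min_genes,
                    sum(few_lnc), min_lncrnas))
  }
  candidates[!(few_genes | few_lnc)]
}

#' Reconstruct lncRNA-embedded subpathways for one pathway
#'
#' The full reconstruction for a single pathway: mine maximal distance-k gene
#' sets, induce gene edges, embed lncRNAs, apply the size filter, and assign
#' stable ordinals (\code{<pathway_id>_1}, \code{_2}, ... by descending size
#' then lexicographic member order, over the subpathways that survive the
#' filter).
#'
#' @param graph A \code{\link{pathway_graph}}.
#' @param regs A \code{\link{regulation_table}}.
#' @param k Maximum pairwise gene distance (default 3).
#' @param min_genes,min_lncrnas Size filter thresholds (defaults 3 and 2).
#' @return List of \code{subpathway_graph} objects.
#' @export
reconstruct_subpathways <- function(graph, regs, k = 3,
                                    min_genes = 3, min_lncrnas = 2) {
  sets <- mine_subpathways(graph, k = k)
  candidates <- lapply(sets, function(genes) {
    emb <- embed_lncrnas(genes, regs)
    subpathway_graph(subpathway_id = "pending", parent_id = graph$pathway_id,
                     parent_name = graph$name, genes = genes,
                     lncrnas = emb$lncrnas,
                     gene_edges = induced_edges(graph, genes),
                     reg_edges = emb$reg_edges)
  })
  kept <- filter_subpathways(candidates, min_genes, min_lncrnas)
  for (i in seq_along(kept)) {
    kept[[i]]$subpathway_id <- paste0(graph$pathway_id, "_", i)
  }
  kept
}

#' Reconstruct a whole pathway as a single lncRNA-embedded graph
#'
#' Treats the entire pathway gene set as one unit and embeds lncRNAs by the
#' same rule as for subpathways; used to compare subpathway-level with
#' entire-pathway-level activity. The size filter is bypassed, so a pathway
#' with no embeddable lncRNA is returned with an empty lncRNA set.
#'
#' @param graph A \code{\link{pathway_graph}}.
#' @param regs A \code{\link{regulation_table}}.
#' @return A \code{subpathway_graph} with id \code{"<pathway_id>_whole"}.
#' @export
reconstruct_pathway_graph <- function(graph, regs) {
  emb <- embed_lncrnas(graph$nodes, regs)
  subpathway_graph(subpathway_id = paste0(graph$pathway_id, "_whole"),
                   parent_id = graph$pathway_id, parent_name = graph$name,
                   genes = graph$nodes, lncrnas = emb$lncrnas,
                   gene_edges = graph$edges, reg_edges = emb$reg_edges)
}

#' Reconstruct subpathways across a list of pathways
#'
#' @param pathways List of \code{\link{pathway_graph}} objects.
#' @param regs A \code{\link{regulation_table}}.
#' @param k,min_genes,min_lncrnas See \code{\link{reconstruct_subpathways}}.
#' @param whole_pathway If \code{TRUE}, append one \code{"_whole"} graph per
#'   pathway (unfiltered) for entire-pathway comparisons.
#' @return Flat list of \code{subpathway_graph} objects.
#' @export
reconstruct_all <- function(pathways, regs, k = 3, min_genes = 3,
                            min_lncrnas = 2, whole_pathway = FALSE) {
  subs <- unlist(lapply(pathways, reconstruct_subpathways, regs = regs, k = k,
                        min_genes = min_genes, min_lncrnas = min_lncrnas),
                 recursive = FALSE)
  if (whole_pathway) {
    subs <- c(subs, lapply(pathways, reconstruct_pathway_graph, regs = regs))
  }
  subs
}
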