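# Readers and writers for every external format the pipeline touches:
# KGML pathway XML, lncRNA-gene regulation tables, expression matrices,
# clinical tables and the plain-text subpathway definition format (.spw).
# All readers validate hard: inputs violating a type invariant are rejected,
# never silently repaired.

#' Construct a pathway graph
#'
#' An undirected gene graph extracted from one pathway. Nodes are gene
#' identifiers kept verbatim (e.g. \code{"hsa:5290"}); edges are unordered
#' gene pairs stored canonically (endpoints sorted, each pair once, no
#' self-loops).
#'
#' @param pathway_id Pathway identifier, e.g. \code{"path:hsa05215"}.
#' @param name Human-readable pathway title.
#' @param nodes Character vector of gene identifiers.
#' @param edges Two-column character matrix of gene pairs (may have 0 rows).
#' @return An object of class \code{pathway_graph}.
#' @export
pathway_graph <- function(pathway_id, name, nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- canonical_edges(edges)
  g <- structure(
    list(pathway_id = as.character(pathway_id), name = as.character(name),
         nodes = nodes, edges = edges),
    class = "pathway_graph")
  validate_pathway_graph(g)
  g
}

# Sort endpoints within each pair, drop self-loops and duplicates.
canonical_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  edges <- matrix(as.character(edges), ncol = 2)
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, c(2, 1), drop = FALSE]
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges
}

validate_pathway_graph <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (anyDuplicated(g$nodes)) stop("duplicate node identifiers in pathway graph")
  if (nrow(g$edges) > 0) {
    if (any(g$edges[, 1] == g$edges[, 2])) stop("self-loop in pathway graph")
    missing <- setdiff(c(g$edges), g$nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not in node set: ", paste(missing, collapse = ", "))
    }
  }
  invisible(g)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph %s (%s): %d genes, %d edges\n",
              x$pathway_id, x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view of a pathway graph (undirected, unweighted).
pathway_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
}

#' Read a KGML pathway file
#'
#' Parses one KEGG KGML XML file into an undirected gene graph. Only entries
#' of type \code{"gene"} become nodes; entry \code{name} tokens are kept
#' verbatim, and multi-gene entries are expanded so every member inherits the
#' entry's relations. \code{group} entries are flattened to their member
#' genes, which form a clique. \code{map} (and by default \code{compound})
#' entries are dropped. Every KGML relation between two gene entries yields
#' one undirected edge per member pair; symmetric relations collapse to a
#' single edge.
#'
#' @param path Path to a KGML file.
#' @param bridge_compounds If \code{TRUE}, two gene entries that are both
#'   related to the same compound entry gain a direct edge. Default
#'   \code{FALSE}.
#' @return A \code{\link{pathway_graph}}.
#' @export
read_kgml <- function(path, bridge_compounds = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed KGML XML in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  root <- xml2::xml_root(doc)
  pathway_id <- xml2::xml_attr(root, "name")
  if (is.na(pathway_id)) pathway_id <- basename(path)
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- ""

  entries <- xml2::xml_find_all(doc, ".//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")

  # entry id -> character vector of member genes (gene entries only for now)
  genes_of <- list()
  compound_ids <- character(0)
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "gene")) {
      genes_of[[entry_id[i]]] <- strsplit(trimws(entry_name[i]), "\\s+")[[1]]
    } else if (identical(entry_type[i], "compound")) {
      compound_ids <- c(compound_ids, entry_id[i])
    }
  }

  # group entries: union of member genes; members form a clique
  edge_from <- character(0); edge_to <- character(0)
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_find_all(entries[[i]], ".//component")
      member_ids <- xml2::xml_attr(comp, "id")
      members <- unlist(genes_of[intersect(member_ids, names(genes_of))])
      members <- unique(members)
      genes_of[[entry_id[i]]] <- members
      if (length(members) >= 2) {
        pairs <- utils::combn(members, 2)
        edge_from <- c(edge_from, pairs[1, ])
        edge_to <- c(edge_to, pairs[2, ])
      }
    }
  }

  nodes <- unique(unlist(genes_of))
  if (length(nodes) == 0L) {
    warning("no gene entries in '", path, "'; returning empty pathway graph")
    return(pathway_graph(pathway_id, title, character(0), NULL))
  }

  relations <- xml2::xml_find_all(doc, ".//relation")
  r1 <- xml2::xml_attr(relations, "entry1")
  r2 <- xml2::xml_attr(relations, "entry2")

  # compound entry id -> gene entries adjacent through relations
  cpd_neighbours <- stats::setNames(vector("list", length(compound_ids)),
                                    compound_ids)
  for (i in seq_along(relations)) {
    a <- r1[i]; b <- r2[i]
    ga <- genes_of[[a]]; gb <- genes_of[[b]]
    if (!is.null(ga) && !is.null(gb)) {
      grid <- expand.grid(ga, gb, stringsAsFactors = FALSE)
      edge_from <- c(edge_from, grid[[1]])
      edge_to <- c(edge_to, grid[[2]])
    } else if (bridge_compounds) {
      if (a %in% compound_ids && !is.null(gb)) {
        cpd_neighbours[[a]] <- c(cpd_neighbours[[a]], b)
      }
      if (b %in% compound_ids && !is.null(ga)) {
        cpd_neighbours[[b]] <- c(cpd_neighbours[[b]], a)
      }
    }
  }

  if (bridge_compounds) {
    for (nb in cpd_neighbours) {
      nb <- unique(nb)
      if (length(nb) >= 2) {
        pairs <- utils::combn(nb, 2)
        for (j in seq_len(ncol(pairs))) {
          grid <- expand.grid(genes_of[[pairs[1, j]]], genes_of[[pairs[2, j]]],
                              stringsAsFactors = FALSE)
          edge_from <- c(edge_from, grid[[1]])
          edge_to <- c(edge_to, grid[[2]])
        }
      }
    }
  }

  pathway_graph(pathway_id, title, nodes, cbind(edge_from, edge_to))
}

#' Read a lncRNA-gene regulation table
#'
#' Two-column tab-separated file: \code{lncrna_id<TAB>gene_id}. A header row
#' is auto-detected (a first row whose fields look like column labels such as
#' \code{"lncRNA"}/\code{"gene"} rather than identifiers). Duplicate rows are
#' collapsed; the resulting table is the non-redundant set of competitive
#' regulations consumed by subpathway reconstruction.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class \code{regulation_table} with columns
#'   \code{lncrna} and \code{gene}.
#' @export
read_regulations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty regulation file '", path, "'")
    return(regulation_table(character(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1]]
  has_header <- length(first) >= 2 &&
    grepl("lnc", tolower(first[1]), fixed = TRUE) &&
    grepl("gene", tolower(first[2]), fixed = TRUE)
  start <- if (has_header) 2L else 1L
  if (start > length(fields)) {
    warning("regulation file '", path, "' has a header but no data rows")
    return(regulation_table(character(0), character(0)))
  }
  lnc <- character(0); gene <- character(0)
  for (i in start:length(fields)) {
    f <- fields[[i]]
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
      stop("regulation file '", path, "': missing field at line ", i)
    }
    lnc <- c(lnc, f[1]); gene <- c(gene, f[2])
  }
  tab <- regulation_table(lnc, gene)
  message(sprintf("read %d non-redundant regulations: %d lncRNAs, %d genes",
                  nrow(tab), length(unique(tab$lncrna)),
                  length(unique(tab$gene))))
  tab
}

#' Construct a regulation table
#'
#' @param lncrna,gene Character vectors of equal length; one regulation per
#'   element. Duplicate pairs are collapsed. The lncRNA and gene identifier
#'   namespaces must be disjoint.
#' @return A data frame of class \code{regulation_table}.
#' @export
regulation_table <- function(lncrna, gene) {
  stopifnot(length(lncrna) == length(gene))
  df <- unique(data.frame(lncrna = as.character(lncrna),
                          gene = as.character(gene),
                          stringsAsFactors = FALSE))
  clash <- intersect(df$lncrna, df$gene)
  if (length(clash)) {
    stop("identifier(s) appear in both lncRNA and gene columns: ",
         paste(clash, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("regulation_table", "data.frame")
  df
}

#' Read an expression matrix
#'
#' Tab-separated, UTF-8, \code{"."} decimal point: a header row of sample
#' identifiers, then one feature per row (first field the feature id). All
#' values must be finite and non-negative; missing values are not permitted.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, features in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression file '", path, "' needs >= 1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s) in '", path, "': ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, samples))
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("expression file '", path, "': non-numeric, missing or negative ",
         "value for feature '", ids[bad[1, 1]], "', sample '",
         samples[bad[1, 2]], "'")
  }
  vals
}

#' Write an expression matrix
#'
#' @param x Numeric matrix with feature row names and sample column names.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(format(r, trim = TRUE, digits = 15,
                                               scientific = FALSE),
                                        collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with header: \code{sample_id<TAB>time<TAB>event[<TAB>group]}.
#' Times are positive (days); event is 1 for an observed death, 0 for
#' censoring.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns \code{sample_id}, \code{time},
#'   \code{event} and optionally \code{group}.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("clinical file '", path, "' needs >= 3 columns")
  out <- data.frame(sample_id = as.character(df[[1]]),
                    time = suppressWarnings(as.numeric(df[[2]])),
                    event = suppressWarnings(as.numeric(df[[3]])),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$group <- as.character(df[[4]])
  validate_clinical(out, where = path)
  out
}

validate_clinical <- function(df, where = "clinical table") {
  if (anyDuplicated(df$sample_id)) {
    stop(where, ": duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_t)) {
    stop(where, ": non-positive or missing survival time for sample '",
         df$sample_id[bad_t[1]], "'")
  }
  bad_e <- which(!(df$event %in% c(0, 1)))
  if (length(bad_e)) {
    stop(where, ": event indicator not in {0,1} for sample '",
         df$sample_id[bad_e[1]], "'")
  }
  invisible(df)
}

#' Write a clinical table
#'
#' @param df Data frame as returned by \code{\link{read_clinical}}.
#' @param path Output path.
#' @export
write_clinical <- function(df, path) {
  validate_clinical(df)
  cols <- c("sample_id", "time", "event", if ("group" %in% names(df)) "group")
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# --- subpathway definition file (.spw) -------------------------------------
# Two lines per subpathway:
#   S<TAB>id<TAB>parent_id<TAB>parent_name<TAB>GENES=g1,g2,...<TAB>LNC=l1,...
#   E<TAB>id<TAB>g1-g2,g2-g3,...<TAB>l1-g1,l2-g3,...
# Identifiers therefore must not contain tab, comma or hyphen.

spw_check_ids <- function(ids) {
  bad <- grepl("[\t,-]", ids)
  if (any(bad)) {
    stop("identifier(s) contain tab/comma/hyphen, not representable in the ",
         "subpathway definition format: ", paste(ids[bad], collapse = ", "))
  }
  invisible(ids)
}

#' Write subpathway graphs to a definition file
#'
#' Serializes a list of subpathway graphs in a bit-exact plain-text format:
#' for each subpathway an \code{S} line (id, parent pathway id and name,
#' sorted gene and lncRNA member lists) and an \code{E} line (gene-gene edges
#' then lncRNA-gene regulation edges). \code{\link{read_subpathways}} is its
#' exact inverse. Identifiers must not contain tab, comma or hyphen.
#'
#' @param subs List of \code{subpathway_graph} objects.
#' @param path Output path.
#' @export
write_subpathways <- function(subs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in subs) {
    stopifnot(inherits(sp, "subpathway_graph"))
    spw_check_ids(c(sp$genes, sp$lncrnas))
    ge <- canonical_edges(sp$gene_edges)
    re <- sp$reg_edges
    re <- re[order(re[, 1], re[, 2]), , drop = FALSE]
    writeLines(paste("S", sp$subpathway_id, sp$parent_id, sp$parent_name,
                     paste0("GENES=", paste(sort(sp$genes), collapse = ",")),
                     paste0("LNC=", paste(sort(sp$lncrnas), collapse = ",")),
                     sep = "\t"), con)
    writeLines(paste("E", sp$subpathway_id,
                     paste(paste(ge[, 1], ge[, 2], sep = "-"), collapse = ","),
                     paste(paste(re[, 1], re[, 2], sep = "-"), collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read subpathway graphs from a definition file
#'
#' @param path Path written by \code{\link{write_subpathways}}.
#' @return List of \code{subpathway_graph} objects.
#' @export
read_subpathways <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 2 != 0) {
    stop("subpathway file '", path, "': odd number of lines")
  }
  split_pairs <- function(s) {
    if (!nzchar(s)) return(matrix(character(0), ncol = 2))
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    do.call(rbind, parts)
  }
  subs <- list()
  for (i in seq(1, length(lines), by = 2)) {
    sf <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    ef <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (sf[1] != "S" || ef[1] != "E" || sf[2] != ef[2]) {
      stop("subpathway file '", path, "': malformed record at line ", i)
    }
    genes <- sf[5]; lnc <- sf[6]
    genes <- sub("^GENES=", "", genes); lnc <- sub("^LNC=", "", lnc)
    genes <- if (nzchar(genes)) strsplit(genes, ",", fixed = TRUE)[[1]] else character(0)
    lnc <- if (nzchar(lnc)) strsplit(lnc, ",", fixed = TRUE)[[1]] else character(0)
    ge <- split_pairs(if (length(ef) >= 3) ef[3] else "")
    re <- split_pairs(if (length(ef) >= 4) ef[4] else "")
    subs[[length(subs) + 1L]] <- subpathway_graph(
      subpathway_id = sf[2], parent_id = sf[3], parent_name = sf[4],
      genes = genes, lncrnas = lnc, gene_edges = ge, reg_edges = re)
  }
  subs
}
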