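# Domain containers and plain-text readers/writers shared by all stages.
# Gene identifiers are opaque strings; lexicographic order is the canonical
# (and universal tie-break) order throughout the pipeline.

#' Construct a multi-study expression set
#'
#' Bundles one or more gene-by-sample expression matrices (log2 scale) with
#' per-sample condition and batch labels, restricted to the genes common to
#' all studies and put in canonical (lexicographic) gene order.
#'
#' @param studies named list; each element a list with components
#'   `matrix` (genes x samples, rownames = genes, colnames = sample ids),
#'   `condition` (character vector per sample, `"lesional"` or
#'   `"nonlesional"`) and `batch` (character vector per sample).
#' @return An object of class `ExpressionStudySet` with fields `genes`
#'   (common genes, sorted) and `studies`.
#' @export
expression_study_set <- function(studies) {
  if (length(studies) == 0L) stop("at least one study is required")
  if (is.null(names(studies)) || anyDuplicated(names(studies)))
    stop("studies must be uniquely named")
  common <- Reduce(intersect, lapply(studies, function(s) rownames(s$matrix)))
  if (length(common) == 0L) stop("no genes are common to all studies")
  common <- sort(common)
  studies <- lapply(studies, function(s) {
    m <- s$matrix[common, , drop = FALSE]
    if (anyNA(m)) stop("expression matrix contains missing values")
    cond <- as.character(s$condition)
    bad <- setdiff(unique(cond), c("lesional", "nonlesional"))
    if (length(bad) > 0L)
      stop("unknown condition label(s): ", paste(bad, collapse = ", "))
    if (length(cond) != ncol(m) || length(s$batch) != ncol(m))
      stop("condition/batch labels must match the number of samples")
    list(matrix = m, condition = cond, batch = as.character(s$batch))
  })
  structure(list(genes = common, studies = studies),
            class = "ExpressionStudySet")
}

#' @export
print.ExpressionStudySet <- function(x, ...) {
  ns <- vapply(x$studies, function(s) ncol(s$matrix), integer(1))
  cat(sprintf("ExpressionStudySet: %d genes, %d studies, %d samples\n",
              length(x$genes), length(x$studies), sum(ns)))
  invisible(x)
}

#' Read an expression study set from TSV files
#'
#' The expression TSV has a gene-identifier first column and one column per
#' sample; the metadata TSV has columns `sample_id`, `study_id`, `condition`
#' and `batch`. Genes are intersected across studies and ordered
#' lexicographically.
#'
#' @param path path to the expression TSV (genes x samples).
#' @param metadata_path path to the sample metadata TSV.
#' @return An [expression_study_set()].
#' @export
read_expression <- function(path, metadata_path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  meta <- read.delim(metadata_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  need <- c("sample_id", "study_id", "condition", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(colnames(m), meta$sample_id)
  if (length(unknown) > 0L)
    stop("sample(s) absent from metadata: ", paste(unknown, collapse = ", "))
  meta <- meta[match(colnames(m), meta$sample_id), ]
  studies <- lapply(split(seq_len(ncol(m)), meta$study_id), function(idx) {
    list(matrix = m[, idx, drop = FALSE],
         condition = meta$condition[idx],
         batch = meta$batch[idx])
  })
  expression_study_set(studies)
}

#' Write an expression study set to TSV files
#'
#' Inverse of [read_expression()]: all studies are written into one combined
#' genes-x-samples matrix plus a sample metadata table.
#'
#' @param x an `ExpressionStudySet`.
#' @param path,metadata_path output TSV paths.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "ExpressionStudySet"))
  m <- do.call(cbind, lapply(x$studies, function(s) s$matrix))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- do.call(rbind, lapply(names(x$studies), function(id) {
    s <- x$studies[[id]]
    data.frame(sample_id = colnames(s$matrix), study_id = id,
               condition = s$condition, batch = s$batch,
               stringsAsFactors = FALSE)
  }))
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Combine all studies into one matrix with sample annotations
#'
#' @param x an `ExpressionStudySet`.
#' @return A list with `matrix` (genes x all samples), `condition`, `batch`
#'   and `study` vectors aligned to its columns.
#' @export
combine_studies <- function(x) {
  stopifnot(inherits(x, "ExpressionStudySet"))
  m <- do.call(cbind, lapply(x$studies, function(s) s$matrix))
  list(matrix = m,
       condition = unlist(lapply(x$studies, function(s) s$condition),
                          use.names = FALSE),
       batch = unlist(lapply(x$studies, function(s) s$batch),
                      use.names = FALSE),
       study = rep(names(x$studies),
                   vapply(x$studies, function(s) ncol(s$matrix), integer(1))))
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, fields `set_id`, `description`, then one
#' gene per tab-separated field. Duplicate genes within a set are removed.
#'
#' @param path file path.
#' @param category label attached to the collection (`"cell_type"` or
#'   `"pathway"`).
#' @return `read_gmt()`: a `GeneSetCollection`, i.e. a named list of unique
#'   gene vectors with attributes `category` and `descriptions`.
#' @export
read_gmt <- function(path, category = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                   i, length(f)))
    sets[[f[1]]] <- unique(f[-(1:2)])
    descs[f[1]] <- f[2]
  }
  structure(sets, category = category, descriptions = descs,
            class = "GeneSetCollection")
}

#' @rdname read_gmt
#' @param collection a `GeneSetCollection` (or plain named list of gene
#'   vectors).
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    d <- if (!is.null(descs) && !is.na(descs[id])) descs[[id]] else "na"
    paste(c(id, d, collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Read / write one-gene-per-line prior-knowledge lists
#'
#' @param path file path.
#' @return `read_gene_list()`: a character vector of unique genes.
#' @export
read_gene_list <- function(path) {
  g <- readLines(path)
  unique(g[nzchar(g)])
}

#' @rdname read_gene_list
#' @param genes character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(genes)
}

#' Consensus weighted gene network container
#'
#' An edge table over genes with consensus weights in \[0,1\] and ranks that
#' form a permutation of `1..|E|`. Edges are stored with
#' `gene_a < gene_b` (lexicographic); self-loops are forbidden.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`, `rank`.
#' @param nodes character vector of all network genes (isolated nodes
#'   allowed).
#' @return An object of class `WeightedGeneNetwork`.
#' @export
weighted_gene_network <- function(edges, nodes) {
  stopifnot(all(c("gene_a", "gene_b", "weight", "rank") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  flip <- edges$gene_a > edges$gene_b
  if (any(flip)) {
    tmp <- edges$gene_a[flip]
    edges$gene_a[flip] <- edges$gene_b[flip]
    edges$gene_b[flip] <- tmp
  }
  if (!all(c(edges$gene_a, edges$gene_b) %in% nodes))
    stop("edge endpoints must be in the node set")
  if (nrow(edges) > 0L && !identical(sort(as.integer(edges$rank)),
                                     seq_len(nrow(edges))))
    stop("edge ranks must be a permutation of 1..|E|")
  edges <- edges[order(edges$rank), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges),
            class = "WeightedGeneNetwork")
}

#' @export
print.WeightedGeneNetwork <- function(x, ...) {
  cat(sprintf("WeightedGeneNetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a weighted gene network to an igraph graph
#'
#' @param x a `WeightedGeneNetwork`.
#' @param weighted keep consensus weights as edge attribute (default TRUE).
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(x, weighted = TRUE) {
  stopifnot(inherits(x, "WeightedGeneNetwork"))
  g <- igraph::graph_from_data_frame(
    x$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = x$nodes, stringsAsFactors = FALSE))
  if (weighted) igraph::E(g)$weight <- x$edges$weight
  g
}

#' Read / write a network edge list TSV
#'
#' Columns: `gene_a`, `gene_b`, `weight`, `rank`.
#'
#' @param path file path.
#' @param nodes optional full node set; defaults to the genes appearing in
#'   edges.
#' @return `read_edges()`: a `WeightedGeneNetwork`.
#' @export
read_edges <- function(path, nodes = NULL) {
  e <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(e$gene_a, e$gene_b))
  weighted_gene_network(e, nodes)
}

#' @rdname read_edges
#' @param network a `WeightedGeneNetwork`.
#' @export
write_edges <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(network)
}

#' Read / write disease-gene catalogues
#'
#' TSV with columns `disease_id`, `gene`; one association per row.
#'
#' @param path file path.
#' @param query_disease_id identifier of the query disease.
#' @param synonyms disease ids to be merged into the query by
#'   [filter_catalog()].
#' @return `read_disease_catalog()`: a `DiseaseGeneCatalog` — a list with
#'   `diseases` (named list of gene sets), `query` and `synonyms`.
#' @export
read_disease_catalog <- function(path, query_disease_id, synonyms = character(0)) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("disease_id", "gene") %in% names(tab)))
  diseases <- lapply(split(tab$gene, tab$disease_id), unique)
  disease_gene_catalog(diseases, query_disease_id, synonyms)
}

#' @rdname read_disease_catalog
#' @param diseases named list of gene vectors.
#' @export
disease_gene_catalog <- function(diseases, query_disease_id,
                                 synonyms = character(0)) {
  diseases <- lapply(diseases, function(g) sort(unique(as.character(g))))
  diseases <- diseases[order(names(diseases))]
  structure(list(diseases = diseases, query = query_disease_id,
                 synonyms = synonyms),
            class = "DiseaseGeneCatalog")
}

#' @rdname read_disease_catalog
#' @param catalog a `DiseaseGeneCatalog`.
#' @export
write_disease_catalog <- function(catalog, path) {
  tab <- do.call(rbind, lapply(names(catalog$diseases), function(d) {
    data.frame(disease_id = d, gene = catalog$diseases[[d]],
               stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(catalog)
}

#' Read / write disease-drug-target triples
#'
#' TSV with columns `disease_id`, `drug_id`, `target`, `source`.
#'
#' @param path file path.
#' @return `read_triples()`: a data.frame of triples.
#' @export
read_triples <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("disease_id", "drug_id", "target", "source") %in% names(tab)))
  tab
}

#' @rdname read_triples
#' @param triples data.frame of triples.
#' @export
write_triples <- function(triples, path) {
  write.table(triples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(triples)
}
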