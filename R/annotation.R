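#' Read a protein annotation table
#'
#' Long-format TSV with columns `gene, uniprot, facet, term`; one row per
#' (protein, facet, term) assignment. Lines starting with `#` are provenance
#' headers and are skipped. The package ships a synthetic fixture
#' (`inst/extdata/synthetic_annotations.tsv`) constructed to reproduce the
#' study's published gene-ontology aggregates.
#'
#' @param path TSV file path; default the packaged synthetic fixture.
#' @return data.frame with columns `gene, uniprot, facet, term`.
#' @export
read_annotations <- function(path = system.file("extdata", "synthetic_annotations.tsv",
                                                package = "dietredox")) {
  ann <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("gene", "uniprot", "facet", "term")
  if (!all(needed %in% names(ann))) {
    stop("annotation table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  ann
}

annotation_facets <- function() {
  c("cellular_component", "molecular_function", "protein_class",
    "biological_process")
}

#' Gene-ontology facet proportions
#'
#' Percentage of annotated proteins carrying each term of one facet. A
#' protein with several terms counts once per term, so multi-label facet
#' percentages can sum past 100. The denominator is the number of distinct
#' proteins with at least one term in the chosen facet.
#'
#' @param annotations annotation table as returned by [read_annotations()].
#' @param facet one of `"cellular_component"`, `"molecular_function"`,
#'   `"protein_class"`, `"biological_process"`.
#' @return data.frame `term, n_proteins, percent`, sorted by decreasing
#'   percentage; zero rows when no protein is annotated in the facet.
#' @export
facet_proportions <- function(annotations, facet) {
  if (!is.character(facet) || length(facet) != 1L ||
      !facet %in% annotation_facets()) {
    stop("unknown facet; must be one of: ",
         paste(annotation_facets(), collapse = ", "), call. = FALSE)
  }
  if (nrow(annotations) == 0L) stop("empty annotation table", call. = FALSE)
  sub <- annotations[annotations$facet == facet & nzchar(annotations$term), ]
  if (nrow(sub) == 0L) {
    return(data.frame(term = character(0), n_proteins = integer(0),
                      percent = numeric(0)))
  }
  denom <- length(unique(sub$gene))
  counts <- tapply(sub$gene, sub$term, function(g) length(unique(g)))
  out <- data.frame(term = names(counts), n_proteins = as.integer(counts),
                    percent = 100 * as.integer(counts) / denom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$term), ]
  rownames(out) <- NULL
  out
}

#' Read a protein interaction edge list
#'
#' TSV with columns `protein_a, protein_b, evidence` (`physical` or
#' `functional`) `, score` (confidence in \[0,1\]). `#` lines are provenance
#' headers. Self-loops and duplicate (unordered) edges are rejected.
#'
#' @param path TSV file path; default the packaged synthetic fixture.
#' @return data.frame edge list.
#' @export
read_interactions <- function(path = system.file("extdata", "synthetic_string_edges.tsv",
                                                 package = "dietredox")) {
  edges <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("protein_a", "protein_b", "evidence", "score")
  if (!all(needed %in% names(edges))) {
    stop("edge list needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  validate_interactions(edges)
}

validate_interactions <- function(edges) {
  if (any(edges$protein_a == edges$protein_b)) {
    stop("edge list contains self-loops", call. = FALSE)
  }
  key <- ifelse(edges$protein_a < edges$protein_b,
                paste(edges$protein_a, edges$protein_b),
                paste(edges$protein_b, edges$protein_a))
  if (anyDuplicated(key)) stop("edge list contains duplicate edges", call. = FALSE)
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("confidence scores must lie in [0, 1]", call. = FALSE)
  }
  if (!all(edges$evidence %in% c("physical", "functional"))) {
    stop("evidence must be 'physical' or 'functional'", call. = FALSE)
  }
  edges
}

#' Interaction-network summary after confidence filtering
#'
#' Drops edges whose confidence score is below `min_confidence` (the study's
#' convention: keep medium confidence 0.4 and above) and nodes left without
#' any edge, then summarizes the filtered graph.
#'
#' @param edges edge list as returned by [read_interactions()].
#' @param min_confidence minimum confidence score kept (default 0.4).
#' @return list `n_nodes`, `n_edges`, `degree` (named integer vector) and
#'   `components` (list `count`, `sizes`, `membership`).
#' @export
network_summary <- function(edges, min_confidence = 0.4) {
  validate_interactions(edges)
  keep <- edges$score >= min_confidence
  ed <- edges[keep, , drop = FALSE]
  if (nrow(ed) == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L, degree = integer(0),
                components = list(count = 0L, sizes = integer(0),
                                  membership = integer(0))))
  }
  g <- igraph::graph_from_data_frame(ed[, c("protein_a", "protein_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       degree = deg,
       components = list(count = comp$no, sizes = unname(comp$csize),
                         membership = comp$membership))
}
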