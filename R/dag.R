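# topological sort over a named parent-set list; NULL if cyclic
topoSort <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, 1L)
  children <- lapply(setNames(nodes, nodes), function(v)
    nodes[vapply(parents, function(p) v %in% p, TRUE)])
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

#' Construct a DAGStructure
#'
#' @param nodes ordered node names.
#' @param parents named list of parent sets; missing nodes get empty sets.
#' @param nodeOrder total order used by the greedy search; defaults to
#'   `nodes`.
#' @return a validated [DAGStructure-class]; cycles are rejected.
#' @examples
#' DAGStructure(c("a", "b"), list(b = "a"))
#' @export
DAGStructure <- function(nodes, parents = list(), nodeOrder = nodes) {
  full <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) full[[v]] <- as.character(parents[[v]])
  new("DAGStructure", nodes = as.character(nodes), parents = full,
      nodeOrder = as.character(nodeOrder))
}

#' @rdname accessors
#' @export
setMethod("parentSets", "DAGStructure", function(x) x@parents)
#' @rdname accessors
#' @export
setMethod("nodeOrder", "DAGStructure", function(x) x@nodeOrder)

#' Edge list of a DAG
#' @param dag a [DAGStructure-class].
#' @return two-column character matrix (`parent`, `child`); zero rows for an
#'   empty graph.
#' @export
edgeList <- function(dag) {
  e <- do.call(rbind, lapply(dag@nodes, function(v) {
    p <- dag@parents[[v]]
    if (length(p)) cbind(parent = p, child = v) else NULL
  }))
  if (is.null(e)) e <- matrix(character(0), 0, 2,
                              dimnames = list(NULL, c("parent", "child")))
  e
}

#' Number of edges of a DAG
#' @param dag a [DAGStructure-class].
#' @return integer edge count.
#' @export
nEdges <- function(dag) sum(lengths(dag@parents))

setMethod("show", "DAGStructure", function(object) {
  cat(sprintf("DAGStructure: %d nodes, %d edges\n", length(object@nodes),
              nEdges(object)))
  e <- edgeList(object)
  if (nrow(e)) {
    shown <- head(seq_len(nrow(e)), 12L)
    cat(paste0("  ", e[shown, 1], " -> ", e[shown, 2], collapse = "\n"), "\n")
    if (nrow(e) > 12L) cat(sprintf("  ... and %d more\n", nrow(e) - 12L))
  }
})

#' Rename the nodes of a DAG
#'
#' Used when imposing a donor structure onto another region's species: slot
#' names are replaced by the assigned species names everywhere (nodes,
#' parent sets, node order).
#'
#' @param dag a [DAGStructure-class].
#' @param mapping named character vector, old name -> new name, covering all
#'   nodes.
#' @return the relabelled [DAGStructure-class].
#' @export
renameNodes <- function(dag, mapping) {
  stopIfNot(all(dag@nodes %in% names(mapping)), "mapping must cover all nodes")
  ren <- function(v) unname(mapping[v])
  DAGStructure(ren(dag@nodes),
               setNames(lapply(dag@parents, ren), ren(dag@nodes)),
               ren(dag@nodeOrder))
}

#' Write / read a DAG as a tab-separated edge list
#'
#' The text format is one `parent<TAB>child` line per edge, preceded by a
#' header line `# nodes: a,b,c` so isolated nodes survive the round trip.
#'
#' @param dag a [DAGStructure-class].
#' @param file path to write to / read from.
#' @return `writeEdgeList()` returns `file` invisibly; `readEdgeList()`
#'   returns a [DAGStructure-class].
#' @export
writeEdgeList <- function(dag, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(dag@nodes, collapse = ",")), con)
  e <- edgeList(dag)
  if (nrow(e)) writeLines(paste(e[, 1], e[, 2], sep = "\t"), con)
  invisible(file)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(file) {
  lines <- readLines(file)
  stopIfNot(startsWith(lines[1], "# nodes: "), "missing node header")
  nodes <- strsplit(sub("^# nodes: ", "", lines[1]), ",")[[1]]
  parents <- list()
  for (ln in lines[-1]) {
    if (!nzchar(ln)) next
    pc <- strsplit(ln, "\t")[[1]]
    parents[[pc[2]]] <- c(parents[[pc[2]]], pc[1])
  }
  DAGStructure(nodes, parents)
}
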