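# Higher-order neighbour sets: simplicial complexes per node and the
# hypergraph G = (V, S).
#
# A "complex" is represented as a sorted character vector of variable names;
# a set of k variables is a (k-1)-dimensional simplicial complex.  A node's
# higher-order neighbours S_u is a list of such complexes, subsumption-free:
# no member may be a subset of another.

#' Higher-order neighbour structure of a dynamical system
#'
#' The hypergraph \eqn{G = (V, S)}: the variables \eqn{V} and, for each
#' variable \eqn{u}, the set \eqn{S_u} of simplicial complexes (inseparable
#' variable groups) entering its governing equation.
#'
#' @slot nodes character vector of variable names (\eqn{V}).
#' @slot neighbors named list; element \code{u} is a list of character
#'   vectors, the complexes \eqn{S_u}, each sorted and subsumption-free.
#'
#' @seealso [higherOrderStructure()], [inferStructure()], [trueStructure()]
#' @exportClass HigherOrderStructure
setClass("HigherOrderStructure",
         representation(nodes = "character", neighbors = "list"))

setValidity("HigherOrderStructure", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "duplicate node names")
  if (is.null(names(object@neighbors)) ||
      !all(names(object@neighbors) %in% object@nodes))
    msgs <- c(msgs, "neighbors must be named by nodes")
  for (u in names(object@neighbors)) {
    su <- object@neighbors[[u]]
    for (cx in su) {
      if (!is.character(cx) || length(cx) == 0 || anyDuplicated(cx))
        msgs <- c(msgs, sprintf("invalid complex for node %s", u))
      if (!all(cx %in% object@nodes))
        msgs <- c(msgs, sprintf("complex of node %s uses unknown variables", u))
      if (is.unsorted(cx))
        msgs <- c(msgs, sprintf("complex of node %s is not in canonical order", u))
    }
    if (length(su) >= 2) {
      for (i in seq_along(su)) for (j in seq_along(su)) {
        if (i != j && isSubcomplex(su[[i]], su[[j]]))
          msgs <- c(msgs, sprintf(
            "node %s: complex {%s} is subsumed by {%s}", u,
            paste(su[[i]], collapse = ","), paste(su[[j]], collapse = ",")))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HigherOrderStructure
#'
#' Complexes are put into canonical (sorted) member order; subsumed pairs
#' within one node's set are an error, matching the defining condition
#' \eqn{s_{u,i} \not\subset s_{u,j}}.
#'
#' @param nodes character vector of variable names.
#' @param neighbors named list mapping node -> list of character vectors.
#' @return A [HigherOrderStructure-class] object.
#' @examples
#' higherOrderStructure(c("x", "y", "z"),
#'   list(x = list("x", "y"),
#'        y = list("y", c("x", "z")),
#'        z = list("z", c("x", "y"))))
#' @export
higherOrderStructure <- function(nodes, neighbors) {
  neighbors <- lapply(neighbors, function(su) {
    su <- lapply(su, function(cx) sort(unique(as.character(cx))))
    orderComplexes(su)
  })
  new("HigherOrderStructure", nodes = as.character(nodes), neighbors = neighbors)
}

setMethod("show", "HigherOrderStructure", function(object) {
  cat(sprintf("HigherOrderStructure: %d nodes\n", length(object@nodes)))
  for (u in names(object@neighbors)) {
    cat(sprintf("  S_%s = {%s}\n", u,
                paste(vapply(object@neighbors[[u]],
                             function(cx) paste0("{", paste(cx, collapse = ","), "}"),
                             character(1)), collapse = ", ")))
  }
})

#' @describeIn higherOrderStructure Variable names of a structure.
#' @param x a \code{HigherOrderStructure}.
#' @export
structureNodes <- function(x) x@nodes

#' @describeIn higherOrderStructure The complex set \eqn{S_u} of one node
#'   (a list of sorted character vectors).
#' @param u node (variable) name.
#' @export
neighborsOf <- function(x, u) {
  if (!u %in% names(x@neighbors)) return(list())
  x@neighbors[[u]]
}

#' Subcomplex test
#'
#' @param a,b complexes (character vectors of variable names).
#' @return \code{TRUE} iff every member of \code{a} is a member of \code{b}
#'   (so the test is reflexive).
#' @examples
#' isSubcomplex("x", c("x", "y"))   # TRUE
#' isSubcomplex(c("x", "y"), c("y", "z"))  # FALSE
#' @export
isSubcomplex <- function(a, b) all(a %in% b)

#' Split a complex into its facets
#'
#' Reduces a complex of \eqn{k} variables (dimension \eqn{k-1}) to its
#' \eqn{k} subsets of size \eqn{k-1}, each in canonical order.  This is the
#' dimensionality-reduction move of the greedy structure search.
#'
#' @param cx a complex with at least two members.
#' @return List of complexes.
#' @examples
#' splitComplex(c("x", "y", "z"))  # {x,y}, {x,z}, {y,z}
#' @export
splitComplex <- function(cx) {
  cx <- sort(unique(as.character(cx)))
  if (length(cx) < 2)
    stopf("cannot split a 0-dimensional complex ({%s})", paste(cx, collapse = ","))
  orderComplexes(lapply(seq_along(cx), function(i) cx[-i]))
}

complexKey <- function(cx) paste(cx, collapse = ",")

# Canonical ordering: decreasing dimension, lexicographic key within one.
orderComplexes <- function(cxs) {
  if (length(cxs) == 0) return(cxs)
  keys <- vapply(cxs, complexKey, character(1))
  sizes <- lengths(cxs)
  cxs[order(-sizes, keys)]
}

#' Canonicalize a set of candidate complexes
#'
#' Sorts members, removes duplicates and complexes subsumed by another
#' retained complex, and orders the set from high to low dimension
#' (lexicographic within a dimension).  Idempotent.
#'
#' @param cxs list of complexes (character vectors).
#' @return Canonical, subsumption-free, ordered list of complexes.
#' @examples
#' canonicalizeComplexes(list("x", c("x", "y")))  # {x,y} only
#' @export
canonicalizeComplexes <- function(cxs) {
  cxs <- lapply(cxs, function(cx) sort(unique(as.character(cx))))
  keys <- vapply(cxs, complexKey, character(1))
  cxs <- cxs[!duplicated(keys)]
  keep <- vapply(seq_along(cxs), function(i) {
    !any(vapply(seq_along(cxs), function(j)
      j != i && isSubcomplex(cxs[[i]], cxs[[j]]), logical(1)))
  }, logical(1))
  orderComplexes(cxs[keep])
}

#' Read / write a hyperedge list
#'
#' Plain-text round-trip format, one line per complex:
#' \code{u <TAB> v1,v2,...,vk}.
#'
#' @param x a [HigherOrderStructure-class].
#' @param file path.
#' @param nodes optional node universe for the reader; defaults to every
#'   variable mentioned in the file.
#' @return \code{readHyperedges} returns a \code{HigherOrderStructure};
#'   \code{writeHyperedges} returns \code{file} invisibly.
#' @export
writeHyperedges <- function(x, file) {
  lines <- unlist(lapply(names(x@neighbors), function(u)
    vapply(x@neighbors[[u]], function(cx)
      paste0(u, "\t", paste(cx, collapse = ",")), character(1))))
  writeLines(lines %||% character(0), file)
  invisible(file)
}

#' @rdname writeHyperedges
#' @export
readHyperedges <- function(file, nodes = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  us <- character(0); cxs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stopf("malformed hyperedge line: %s", ln)
    us <- c(us, parts[1])
    cxs <- c(cxs, list(sort(strsplit(parts[2], ",", fixed = TRUE)[[1]])))
  }
  if (is.null(nodes))
    nodes <- sort(unique(c(us, unlist(cxs))))
  neighbors <- lapply(split(cxs, factor(us, levels = unique(us))), identity)
  higherOrderStructure(nodes, neighbors)
}

# All variables that appear in any complex of S_u (the pairwise projection,
# used by the parallel-RC baseline).
#' Pairwise projection of a higher-order structure
#'
#' Collapses each node's complexes to the union of their members: the set of
#' pairwise neighbours a conventional causal-network method would report.
#' The node itself is always included.
#'
#' @param x a [HigherOrderStructure-class].
#' @return Named list mapping node -> character vector of neighbours.
#' @export
pairwiseNeighbors <- function(x) {
  out <- lapply(names(x@neighbors), function(u)
    sort(unique(c(u, unlist(x@neighbors[[u]])))))
  names(out) <- names(x@neighbors)
  out
}
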