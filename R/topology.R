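#' Signed gene regulatory network topologies
#'
#' A `grn_topology` holds an ordered gene list and an ordered signed edge
#' list. The edge order is load-bearing: it defines the index of the
#' regulator, target and sign vectors used by the cross-cell correlation,
#' so it is preserved by all reading, writing and perturbation operations.
#'
#' @param genes character vector of unique, non-empty gene names.
#' @param edges data.frame with columns `source`, `target` (gene names) and
#'   `sign` (+1 activation, -1 inhibition), one row per interaction.
#' @return An object of class `grn_topology`: a list with elements `genes`
#'   (character), `edges` (data.frame as above) and `degenerate` (logical,
#'   TRUE when fewer than 2 edges remain so downstream correlations are
#'   undefined).
#' @examples
#' top <- grn_topology(c("A", "B"),
#'                     data.frame(source = c("A", "B"), target = c("B", "A"),
#'                                sign = c(-1, -1)))
#' print(top)
#' @export
grn_topology <- function(genes, edges) {
  genes <- as.character(genes)
  if (anyDuplicated(genes) || any(!nzchar(genes)))
    stop("gene names must be unique and non-empty")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "sign") %in% names(edges)))
    stop("edges need columns source, target, sign")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) > 0) {
    if (any(!nzchar(edges$source)) || any(!nzchar(edges$target)))
      stop("edge endpoints must be non-empty names")
    if (!all(edges$sign %in% c(1L, -1L)))
      stop("edge sign must be +1 or -1")
    missing <- setdiff(unique(c(edges$source, edges$target)), genes)
    if (length(missing))
      stop("edge endpoints not in gene list: ", paste(missing, collapse = ", "))
    key <- paste(edges$source, edges$target, edges$sign)
    if (anyDuplicated(key))
      stop("duplicate edges (same source, target and sign) are not allowed")
  }
  rownames(edges) <- NULL
  structure(list(genes = genes, edges = edges,
                 degenerate = nrow(edges) < 2L),
            class = "grn_topology")
}

#' @export
print.grn_topology <- function(x, ...) {
  cat(sprintf("GRN topology: %d genes, %d edges (%d activating, %d inhibiting)%s\n",
              length(x$genes), nrow(x$edges),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  cat("genes:", paste(x$genes, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    arrows <- ifelse(x$edges$sign == 1, "->", "-|")
    cat(paste0("  ", x$edges$source, " ", arrows, " ", x$edges$target),
        sep = "\n")
  }
  invisible(x)
}

#' Read a network topology from a tab-separated file
#'
#' Expects the sRACIPE-style dialect: a header line `Source Target Type`
#' and one row per edge, with Type 1 meaning activation and Type 2
#' inhibition. Genes are collected in first-appearance order over the edge
#' rows; edge order follows row order.
#'
#' @param path path to a TSV file.
#' @return A [grn_topology()].
#' @seealso [write_topology()]
#' @export
read_topology <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("Source", "Target", "Type")
  if (!all(need %in% names(df)))
    stop("topology file must have columns Source, Target, Type; found: ",
         paste(names(df), collapse = ", "))
  if (nrow(df) == 0) stop("topology file has an empty edge list")
  bad <- which(!(df$Type %in% c(1, 2)))
  if (length(bad))
    stop(sprintf("unknown interaction Type %s in row %d (expected 1 or 2)",
                 df$Type[bad[1]], bad[1]))
  src <- as.character(df$Source)
  tgt <- as.character(df$Target)
  genes <- unique(as.vector(rbind(src, tgt)))
  grn_topology(genes,
               data.frame(source = src, target = tgt,
                          sign = ifelse(df$Type == 1, 1L, -1L),
                          stringsAsFactors = FALSE))
}

#' Write a network topology to a tab-separated file
#'
#' Writes the dialect read by [read_topology()] (Source/Target/Type with
#' Type 1 = activation, 2 = inhibition), preserving edge order so that a
#' read/write round trip is the identity.
#'
#' @param topology a [grn_topology()].
#' @param path output file path.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "grn_topology"))
  if (nrow(topology$edges) == 0)
    stop("refusing to write a topology with no edges")
  df <- data.frame(Source = topology$edges$source,
                   Target = topology$edges$target,
                   Type = ifelse(topology$edges$sign == 1, 1L, 2L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a plain edge list (source, target, sign) for generic graph tools
#'
#' @inheritParams write_topology
#' @export
write_edge_list <- function(topology, path) {
  stopifnot(inherits(topology, "grn_topology"))
  utils::write.table(topology$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Built-in synthetic circuit fixtures
#'
#' Four small circuits with well-understood dynamics, used throughout for
#' simulation and testing:
#' \describe{
#'   \item{REP}{repressilator: three genes inhibiting each other in a cycle
#'     (A -| B -| C -| A); oscillatory, irreversible rotational flow.}
#'   \item{CTS}{coupled toggle switch: two mutual-inhibition pairs (A/B and
#'     C/D) coupled by activations A->C, C->A, B->D, D->B, so the major
#'     states are A/C-high and B/D-high with reversible switching.}
#'   \item{IFFL}{incoherent feedforward loop: I -> X, X -> Y, X -> Z, Y -| Z;
#'     X activates Z directly but inhibits it indirectly through Y,
#'     producing pulse-like adaptation.}
#'   \item{TSREP}{toggle switch/repressilator hybrid: toggle A -| C, C -| A
#'     plus a third gene closing a negative feedback loop A -| B, B -| C.}
#' }
#' CTS and TSREP wiring is chosen to reproduce the intended attractor
#' structure (verified by ensemble simulation in the test suite).
#'
#' @param name one of "REP", "CTS", "IFFL", "TSREP".
#' @return A [grn_topology()].
#' @examples
#' builtin_circuit("REP")
#' @export
builtin_circuit <- function(name = c("REP", "CTS", "IFFL", "TSREP")) {
  name <- match.arg(toupper(name), c("REP", "CTS", "IFFL", "TSREP"))
  e <- function(s, t, sg) data.frame(source = s, target = t, sign = sg,
                                     stringsAsFactors = FALSE)
  switch(name,
    REP = grn_topology(c("A", "B", "C"),
      e(c("A", "B", "C"), c("B", "C", "A"), c(-1L, -1L, -1L))),
    CTS = grn_topology(c("A", "B", "C", "D"),
      e(c("A", "B", "C", "D", "A", "C", "B", "D"),
        c("B", "A", "D", "C", "C", "A", "D", "B"),
        c(-1L, -1L, -1L, -1L, 1L, 1L, 1L, 1L))),
    IFFL = grn_topology(c("I", "X", "Y", "Z"),
      e(c("I", "X", "X", "Y"), c("X", "Y", "Z", "Z"), c(1L, 1L, 1L, -1L))),
    TSREP = grn_topology(c("A", "B", "C"),
      e(c("A", "C", "A", "B"), c("C", "A", "B", "C"), c(-1L, -1L, -1L, -1L))))
}

#' Remove edges or a node's edges from a topology
#'
#' Used by the edge-sensitivity analysis: the returned topology keeps the
#' full gene list (so expression columns stay aligned) and drops the
#' specified interactions. If fewer than two edges remain the result is
#' flagged degenerate, because the cross-cell correlation is undefined on
#' fewer than two edges.
#'
#' @param topology a [grn_topology()].
#' @param edges optional data.frame with columns `source` and `target`
#'   (and optionally `sign`) naming edges to remove.
#' @param node optional gene name whose edges are removed.
#' @param direction for `node`: remove "outgoing", "incoming" or "both".
#' @param strict if TRUE (default), referencing an absent edge is an error;
#'   if FALSE it is silently ignored.
#' @return A [grn_topology()]; check its `degenerate` flag before use.
#' @examples
#' perturb_topology(builtin_circuit("CTS"), node = "A", direction = "outgoing")
#' @export
perturb_topology <- function(topology, edges = NULL, node = NULL,
                             direction = c("both", "outgoing", "incoming"),
                             strict = TRUE) {
  stopifnot(inherits(topology, "grn_topology"))
  direction <- match.arg(direction)
  keep <- rep(TRUE, nrow(topology$edges))
  if (!is.null(edges)) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(edges))) {
      hit <- topology$edges$source == edges$source[r] &
             topology$edges$target == edges$target[r]
      if (!is.null(edges$sign))
        hit <- hit & topology$edges$sign == edges$sign[r]
      if (!any(hit)) {
        if (strict)
          stop(sprintf("no such edge to remove: %s -> %s",
                       edges$source[r], edges$target[r]))
      } else keep[hit] <- FALSE
    }
  }
  if (!is.null(node)) {
    if (!(node %in% topology$genes)) {
      if (strict) stop("no such gene: ", node)
    } else {
      if (direction %in% c("outgoing", "both"))
        keep[topology$edges$source == node] <- FALSE
      if (direction %in% c("incoming", "both"))
        keep[topology$edges$target == node] <- FALSE
    }
  }
  out <- topology
  out$edges <- topology$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$degenerate <- nrow(out$edges) < 2L
  out
}

# Edge-index vectors used by the CCC: regulator column, target column and
# sign per edge, in stable edge order.
topology_indices <- function(topology, gene_names) {
  ri <- match(topology$edges$source, gene_names)
  ti <- match(topology$edges$target, gene_names)
  if (anyNA(ri) || anyNA(ti)) {
    miss <- unique(c(topology$edges$source[is.na(ri)],
                     topology$edges$target[is.na(ti)]))
    stop("network genes missing from expression matrix: ",
         paste(miss, collapse = ", "))
  }
  list(regulator = ri, target = ti, sign = topology$edges$sign)
}
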