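#' Construct a branch-class-labeled tree
#'
#' Wraps an `ape::phylo` tree with an integer branch-class vector (one class
#' per edge).  Class 0 is the background class; a K-class model uses classes
#' `0..K-1`.  Used by branch-specific omega models: foreground branches carry
#' class >= 1, all other branches class 0.
#'
#' @param phylo an `ape::phylo` with branch lengths.
#' @param edge_class integer vector, one class per row of `phylo$edge`.
#' @return Object of class `labeled_tree`: list with `phylo`, `edge_class`,
#'   `n_classes`.
#' @export
labeled_tree <- function(phylo, edge_class = integer(nrow(phylo$edge))) {
  stopifnot(inherits(phylo, "phylo"))
  if (is.null(phylo$edge.length)) stop("tree has no branch lengths")
  if (any(phylo$edge.length < 0)) stop("negative branch length in tree")
  edge_class <- as.integer(edge_class)
  if (length(edge_class) != nrow(phylo$edge)) {
    stop("edge_class must have one entry per edge")
  }
  if (any(edge_class < 0L)) stop("branch classes must be non-negative")
  present <- sort(unique(c(0L, edge_class)))
  full <- seq(0L, max(present))
  missing <- setdiff(full, present)
  if (length(missing)) {
    stop("non-contiguous branch classes: class ", missing[1], " is missing")
  }
  structure(list(phylo = phylo, edge_class = edge_class,
                 n_classes = max(edge_class) + 1L),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("<labeled_tree>", length(x$phylo$tip.label), "tips,",
      nrow(x$phylo$edge), "edges,", x$n_classes, "branch class(es)\n")
  invisible(x)
}

## Move "#k" branch-class tokens into node labels that ape can carry, e.g.
## "(A:0.1,B:0.1):0.05 #1"  ->  ")..HC1:0.05" after ape-safe rewriting.
.newick_encode_classes <- function(s) {
  s <- gsub("\\s+", "", s)
  ## "#k" after a branch length -> move before the colon (onto the label)
  while (grepl("(:[0-9.eE+-]+)#([0-9]+)", s)) {
    s <- sub("(:[0-9.eE+-]+)#([0-9]+)", "#\\2\\1", s)
  }
  gsub("#([0-9]+)", "..HC\\1", s)
}

#' Parse a Newick string with #k branch-class labels
#'
#' Branch classes use the hash-number dialect: a `#k` token attached to a
#' branch (after the taxon/clade or after the branch length) assigns that
#' branch to class `k`; unlabeled branches are class 0.  Example:
#' `"((A:0.1,B:0.1):0.05 #1,C:0.2);"` puts one internal branch in class 1.
#'
#' @param text Newick string.
#' @return A `labeled_tree`.
#' @export
parse_labeled_newick <- function(text) {
  enc <- .newick_encode_classes(text)
  tr <- tryCatch(ape::read.tree(text = enc), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  ntip <- length(tr$tip.label)
  labels <- c(tr$tip.label,
              if (is.null(tr$node.label)) rep("", tr$Nnode) else tr$node.label)
  labels[is.na(labels)] <- ""
  m <- regmatches(labels, regexpr("\\.\\.HC([0-9]+)$", labels))
  node_class <- integer(length(labels))
  has <- grepl("\\.\\.HC[0-9]+$", labels)
  node_class[has] <- as.integer(sub("^.*\\.\\.HC([0-9]+)$", "\\1", labels[has]))
  clean <- sub("\\.\\.HC[0-9]+$", "", labels)
  tr$tip.label <- clean[seq_len(ntip)]
  if (!is.null(tr$node.label)) tr$node.label <- clean[-seq_len(ntip)]
  labeled_tree(tr, node_class[tr$edge[, 2]])
}

#' Read a branch-class-labeled Newick file
#' @param path file containing one Newick tree.
#' @return A `labeled_tree`.
#' @seealso [parse_labeled_newick()] for the `#k` dialect.
#' @export
read_labeled_newick <- function(path) {
  parse_labeled_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a labeled tree as Newick with #k branch-class labels
#' @param tree a `labeled_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_newick <- function(tree, path) {
  tr <- tree$phylo
  ntip <- length(tr$tip.label)
  nlab <- if (is.null(tr$node.label)) rep("", tr$Nnode) else tr$node.label
  cls <- tree$edge_class
  for (i in seq_along(cls)) {
    if (cls[i] > 0L) {
      child <- tr$edge[i, 2]
      tag <- paste0("..HC", cls[i])
      if (child <= ntip) tr$tip.label[child] <- paste0(tr$tip.label[child], tag)
      else nlab[child - ntip] <- paste0(nlab[child - ntip], tag)
    }
  }
  if (any(nzchar(nlab))) tr$node.label <- nlab
  s <- ape::write.tree(tr)
  s <- gsub("\\.\\.HC([0-9]+)", " #\\1", s)
  writeLines(s, path)
  invisible(path)
}
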