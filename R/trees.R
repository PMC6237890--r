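# Rooted phylogenies with foreground branch markings. Foreground clades
# are tagged in Newick with the PAML-style "#1" syntax on a tip or an
# internal node; a tag on an internal node marks every branch inside the
# clade plus its stem branch as foreground.

#' Read a Newick tree with optional foreground clade tags
#'
#' Accepts PAML-style `#1` tags attached to tip names (`seal#1`) or to
#' internal nodes (`(A,B)#1`). Every branch inside a tagged clade,
#' including the clade's stem branch, is labeled foreground; all other
#' branches are background.
#'
#' @param path file containing one Newick string (or the string itself
#'   via `text`).
#' @param text optional Newick string, used instead of `path`.
#' @return a `labeled_tree`: an `ape::phylo` with an additional logical
#'   component `foreground` aligned with the rows of `tree$edge`.
#' @export
read_labeled_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || inherits(tree, "multiPhylo"))
    stop("malformed Newick string")
  label_foreground_from_tags(tree)
}

#' Mark foreground branches from #-tags embedded in labels
#' @param tree `phylo` whose tip or node labels may end in `#<digit>`.
#' @return `labeled_tree` with tags stripped from the labels.
#' @export
label_foreground_from_tags <- function(tree) {
  tagged_tips <- grep("#\\d+\\s*$", tree$tip.label)
  tagged_nodes <- integer(0)
  if (!is.null(tree$node.label))
    tagged_nodes <- grep("#\\d+\\s*$", tree$node.label)
  tree$tip.label <- sub("\\s*#\\d+\\s*$", "", tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- sub("\\s*#\\d+\\s*$", "", tree$node.label)

  ntip <- length(tree$tip.label)
  fg_nodes <- integer(0)
  for (tip in tagged_tips) fg_nodes <- c(fg_nodes, tip)
  for (nd in tagged_nodes) {
    node_id <- ntip + nd
    desc <- .clade_nodes(tree, node_id)
    fg_nodes <- c(fg_nodes, node_id, desc)  # stem branch + internal branches
  }
  fg <- tree$edge[, 2] %in% fg_nodes
  tree$foreground <- fg
  class(tree) <- c("labeled_tree", class(tree))
  tree
}

# all descendant node ids of `node` (tips and internals), excluding node
.clade_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- tree$edge[tree$edge[, 1] %in% stack, 2]
  }
  out
}

#' Tip labels spanned by a clade
#' @keywords internal
.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ids <- .clade_nodes(tree, node)
  tree$tip.label[ids[ids <= ntip]]
}

#' Mark a clade as foreground by its tip set
#'
#' @param tree `phylo` or `labeled_tree`.
#' @param taxa tip labels forming the (monophyletic) foreground clade; a
#'   single tip marks just that terminal branch.
#' @return `labeled_tree` with the clade's branches (stem included)
#'   foreground.
#' @export
label_foreground <- function(tree, taxa) {
  missing_taxa <- setdiff(taxa, tree$tip.label)
  if (length(missing_taxa))
    stop("reference error: unknown taxa: ",
         paste(missing_taxa, collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(taxa) == 1L) {
    fg_nodes <- match(taxa, tree$tip.label)
  } else {
    mrca <- ape::getMRCA(tree, taxa)
    spanned <- .clade_tips(tree, mrca)
    if (!setequal(spanned, taxa))
      stop("taxa do not form a monophyletic clade (clade spans: ",
           paste(spanned, collapse = ", "), ")")
    fg_nodes <- c(mrca, .clade_nodes(tree, mrca))
  }
  tree$foreground <- tree$edge[, 2] %in% fg_nodes
  if (!inherits(tree, "labeled_tree"))
    class(tree) <- c("labeled_tree", class(tree))
  tree
}

#' Write a labeled tree as Newick with #1 tags on foreground clades
#' @param tree `labeled_tree`.
#' @param path output file; when `NULL` the Newick string is returned.
#' @export
write_labeled_tree <- function(tree, path = NULL) {
  out <- tree
  fg <- foreground_edges(tree)
  ntip <- length(tree$tip.label)
  # tag maximal foreground nodes: foreground child whose parent edge is
  # background (or root)
  fg_children <- tree$edge[fg, 2]
  parent_of <- function(node) {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) NA_integer_ else tree$edge[e, 1]
  }
  maximal <- fg_children[vapply(fg_children, function(nd) {
    p <- parent_of(nd)
    e <- which(tree$edge[, 2] == nd)
    pe <- which(tree$edge[, 2] == p)
    !length(pe) || !fg[pe]
  }, logical(1))]
  if (is.null(out$node.label))
    out$node.label <- rep("", out$Nnode)
  for (nd in maximal) {
    if (nd <= ntip)
      out$tip.label[nd] <- paste0(out$tip.label[nd], "#1")
    else
      out$node.label[nd - ntip] <- paste0(out$node.label[nd - ntip], "#1")
  }
  out$foreground <- NULL
  class(out) <- "phylo"
  nwk <- ape::write.tree(out)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Foreground indicator per edge
#' @param tree `labeled_tree` or plain `phylo` (then all background).
#' @return logical vector over `tree$edge` rows.
#' @export
foreground_edges <- function(tree) {
  if (!is.null(tree$foreground)) tree$foreground
  else rep(FALSE, nrow(tree$edge))
}

#' @export
print.labeled_tree <- function(x, ...) {
  fg <- sum(foreground_edges(x))
  cat("Labeled tree: ", length(x$tip.label), " tips, ", fg,
      " foreground branch(es)\n", sep = "")
  invisible(x)
}

# reorder edges to postorder while keeping the foreground flags aligned
.reorder_labeled <- function(tree) {
  fg_children <- tree$edge[foreground_edges(tree), 2]
  out <- ape::reorder.phylo(tree, "postorder")
  out$foreground <- out$edge[, 2] %in% fg_children
  out
}

#' Check tree/alignment taxon agreement
#' @keywords internal
.check_taxa <- function(tree, aln) {
  missing_taxa <- setdiff(tree$tip.label, aln$taxa)
  if (length(missing_taxa))
    stop("reference error: tree taxa absent from alignment: ",
         paste(missing_taxa, collapse = ", "))
  invisible(TRUE)
}
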