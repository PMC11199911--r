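#' @title The phylotree data model
#'
#' @description A `phylotree` is a rooted tree (or extended-Newick network)
#' stored as parallel vectors in *pre-order*: node 1 is the root, every
#' parent precedes its children, and siblings appear left-to-right.  Node
#' "references" are therefore stable 1-based integer ids; they are
#' reassigned after any topology change so that indexing into the node list
#' stays deterministic.
#'
#' Fields (all of length `n_nodes(tree)`):
#' \describe{
#'   \item{parent}{integer; `NA` for the root. Always `parent[i] < i`.}
#'   \item{label}{character; `NA` when a node is unlabelled.}
#'   \item{length}{numeric; length of the branch leading *into* the node,
#'     `NA` when undefined (the root usually has no length).}
#'   \item{annotation}{list of named lists (key -> scalar or vector), or
#'     `NULL` entries when a node carries no annotations.}
#'   \item{hybrid}{character hybrid id (e.g. `"H1"`); two records sharing a
#'     hybrid id denote the same network node. `NA` for ordinary nodes.}
#' }
#'
#' Branch lengths are non-negative for all generated trees; the Newick
#' parser is deliberately permissive and keeps (with a warning) the tiny
#' negative lengths that occur in real BEAST output.
#'
#' @name phylotree
NULL

# internal constructor -- trusts its inputs
new_phylotree <- function(parent, label, length, annotation = NULL,
                          hybrid = NULL) {
  n <- length(parent)
  if (is.null(annotation)) annotation <- vector("list", n)
  if (is.null(hybrid)) hybrid <- rep(NA_character_, n)
  structure(
    list(parent = as.integer(parent), label = as.character(label),
         length = as.numeric(length), annotation = annotation,
         hybrid = as.character(hybrid)),
    class = "phylotree"
  )
}

#' Build a single-node tree (a detached leaf)
#'
#' Convenience constructor used with [add_child()] and [graft()].
#'
#' @param label optional node label.
#' @param length optional length of the branch leading into the node.
#' @param annotations optional named list of annotations.
#' @return A `phylotree` with one node.
#' @examples
#' t <- leaf("t1", 0.5)
#' n_nodes(t)
#' @export
leaf <- function(label = NA_character_, length = NA_real_,
                 annotations = NULL) {
  ann <- vector("list", 1L)
  if (!is.null(annotations)) ann[[1L]] <- annotations
  new_phylotree(NA_integer_, label, length, ann)
}

#' Number of nodes / leaves, node and leaf ids
#'
#' Node ids are pre-order positions (root = 1); `node_ids()` is the node
#' list and `leaf_ids()` its subsequence of ids with no children.
#'
#' @param tree a `phylotree`.
#' @return An integer count or vector of ids.
#' @export
n_nodes <- function(tree) length(tree$parent)

#' @rdname n_nodes
#' @export
n_leaves <- function(tree) sum(child_counts(tree) == 0L)

#' @rdname n_nodes
#' @export
node_ids <- function(tree) seq_len(n_nodes(tree))

#' @rdname n_nodes
#' @export
leaf_ids <- function(tree) which(child_counts(tree) == 0L)

# number of children per node
child_counts <- function(tree) {
  n <- n_nodes(tree)
  p <- tree$parent
  if (n == 1L) return(0L)
  tabulate(p[-1L], nbins = n)
}

# ordered children per node (pre-order index order == sibling order)
children_list <- function(parent) {
  n <- length(parent)
  if (n == 1L) return(list(integer(0)))
  unname(split(seq_len(n)[-1L], factor(parent[-1L], levels = seq_len(n))))
}

#' Per-node topological depth (root = 0)
#'
#' @param tree a `phylotree`.
#' @return Integer vector of depths in node-id order.
#' @export
node_depths <- function(tree) {
  n <- n_nodes(tree)
  d <- integer(n)
  p <- tree$parent
  if (n > 1L) for (i in 2:n) d[i] <- d[p[i]] + 1L
  d
}

# subtree size (node count) per node, by a reverse pre-order sweep
subtree_sizes <- function(tree) {
  n <- n_nodes(tree)
  s <- rep(1L, n)
  p <- tree$parent
  if (n > 1L) for (i in n:2) s[p[i]] <- s[p[i]] + s[i]
  s
}

# leaf count per node
leaf_counts <- function(tree) {
  n <- n_nodes(tree)
  cc <- child_counts(tree)
  s <- as.integer(cc == 0L)
  p <- tree$parent
  if (n > 1L) for (i in n:2) s[p[i]] <- s[p[i]] + s[i]
  s
}

# resolve a node given as id or label to an id
resolve_node <- function(tree, node) {
  if (is.character(node)) {
    id <- match(node, tree$label)
    if (anyNA(id))
      stop("label(s) not found in tree: ",
           paste(node[is.na(id)], collapse = ", "))
    return(as.integer(id))
  }
  id <- as.integer(node)
  if (any(id < 1L | id > n_nodes(tree)))
    stop("node id out of range: ", paste(id[id < 1L | id > n_nodes(tree)],
                                         collapse = ", "))
  id
}

#' A plain-data view of one node
#'
#' Returns the fields of node `id` as a named list: `id`, `label`,
#' `branch_length`, `annotations` (named list, possibly empty), `is_leaf`,
#' `is_hybrid`, `hybrid_id`, `parent` and `children` ids.  This is the value
#' passed to traversal callbacks and annotation writers.
#'
#' @param tree a `phylotree`.
#' @param id node id (or label).
#' @return A named list.
#' @export
node_data <- function(tree, id) {
  id <- resolve_node(tree, id)[1L]
  ch <- which(tree$parent == id)
  ann <- tree$annotation[[id]]
  list(id = id, label = tree$label[id], branch_length = tree$length[id],
       annotations = if (is.null(ann)) list() else ann,
       is_leaf = length(ch) == 0L,
       is_hybrid = !is.na(tree$hybrid[id]), hybrid_id = tree$hybrid[id],
       parent = tree$parent[id], children = ch)
}

#' Ancestors of a node
#'
#' The sequence of ids from the node's parent up to and including the root;
#' empty for the root itself.  Its length equals the node's depth.
#'
#' @param tree a `phylotree`.
#' @param node node id or label.
#' @return Integer vector of ancestor ids, nearest first.
#' @export
get_ancestors <- function(tree, node) {
  v <- resolve_node(tree, node)[1L]
  out <- integer(0)
  p <- tree$parent[v]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[p]
  }
  out
}

#' Pre-order and post-order traversal
#'
#' Applies `fn` once to every node of the subtree rooted at `node` (default:
#' the whole tree), in pre-order (parents before children) or post-order
#' (children before parents), and collects the results in visit order.
#' `fn` receives a [node_data()] list.  Both traversals are iterative.
#'
#' @param tree a `phylotree`.
#' @param fn a function of one argument (a [node_data()] list).
#' @param node root of the traversed subtree (id or label); default whole
#'   tree.
#' @return A list of `fn` results in visit order.
#' @export
apply_preorder <- function(tree, fn, node = 1L) {
  v <- resolve_node(tree, node)[1L]
  size <- subtree_sizes(tree)[v]
  lapply(seq.int(v, v + size - 1L), function(i) fn(node_data(tree, i)))
}

#' @rdname apply_preorder
#' @export
apply_postorder <- function(tree, fn, node = 1L) {
  v <- resolve_node(tree, node)[1L]
  ord <- postorder_ids(tree, v)
  lapply(ord, function(i) fn(node_data(tree, i)))
}

# iterative post-order: pop-push-reverse of a pre-order with children
# visited right-to-left
postorder_ids <- function(tree, v = 1L) {
  ch <- children_list(tree$parent)
  out <- integer(subtree_sizes(tree)[v])
  stack <- v
  k <- 0L
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- x
    if (length(ch[[x]])) stack <- c(stack, ch[[x]])
  }
  rev(out[seq_len(k)])
}

#' Attach a subtree as a new child
#'
#' `child` (an independent `phylotree`, e.g. from [leaf()] or
#' [get_clade()]) is appended as the *last* child of node `parent`.  Its
#' root keeps its branch length.  Node ids are reassigned pre-order.
#' Because the child is supplied as an independent value, attaching a node
#' below one of its own descendants (a cycle) cannot be expressed.
#'
#' @param tree a `phylotree`.
#' @param parent id (or label) of the node gaining a child.
#' @param child a `phylotree` to attach.
#' @return The modified tree.
#' @examples
#' t <- read_newick("(a:1,b:1);")
#' t2 <- add_child(t, 1, leaf("c", 2))
#' n_leaves(t2)
#' @export
add_child <- function(tree, parent, child) {
  stopifnot(inherits(tree, "phylotree"), inherits(child, "phylotree"))
  p <- resolve_node(tree, parent)[1L]
  n1 <- n_nodes(tree)
  n2 <- n_nodes(child)
  at <- p + subtree_sizes(tree)[p]     # insertion position of the block
  shift <- function(x, ins, k) ifelse(!is.na(x) & x >= ins, x + k, x)
  idx_pre <- seq_len(at - 1L)
  idx_post <- if (at <= n1) at:n1 else integer(0)
  cp <- child$parent + (at - 1L)
  cp[1L] <- p
  new_phylotree(
    parent = c(shift(tree$parent[idx_pre], at, n2), cp,
               shift(tree$parent[idx_post], at, n2)),
    label = c(tree$label[idx_pre], child$label, tree$label[idx_post]),
    length = c(tree$length[idx_pre], child$length, tree$length[idx_post]),
    annotation = c(tree$annotation[idx_pre], child$annotation,
                   tree$annotation[idx_post]),
    hybrid = c(tree$hybrid[idx_pre], child$hybrid, tree$hybrid[idx_post])
  )
}

#' Detach a child subtree
#'
#' Removes `child` (which must currently be a child of `parent`) together
#' with all its descendants.  The parent is *not* suppressed if it is left
#' with a single child — see [suppress_unary()] — so annotation round-trips
#' are never silently broken.
#'
#' @param tree a `phylotree`.
#' @param parent id (or label) of the parent node.
#' @param child id (or label) of the child to detach.
#' @return The modified tree.
#' @export
remove_child <- function(tree, parent, child) {
  p <- resolve_node(tree, parent)[1L]
  v <- resolve_node(tree, child)[1L]
  if (is.na(tree$parent[v]) || tree$parent[v] != p)
    stop("node ", v, " is not a child of node ", p)
  drop_block(tree, v)
}

# remove the pre-order block of the subtree rooted at v (no suppression)
drop_block <- function(tree, v) {
  size <- subtree_sizes(tree)[v]
  keep <- setdiff(seq_len(n_nodes(tree)), seq.int(v, v + size - 1L))
  p <- tree$parent[keep]
  p <- ifelse(!is.na(p) & p > v, p - size, p)
  new_phylotree(p, tree$label[keep], tree$length[keep],
                tree$annotation[keep], tree$hybrid[keep])
}

#' Suppress unary (degree-2) internal nodes
#'
#' Merges every node that has exactly one child into that child: branch
#' lengths are summed (an undefined length counts as absent, two undefined
#' lengths stay undefined), the child's label and annotations win and the
#' suppressed node's annotations are dropped.  A unary root is suppressed
#' the same way, making its child the new root.
#'
#' @param tree a `phylotree`.
#' @return The modified tree.
#' @export
suppress_unary <- function(tree) {
  repeat {
    un <- which(child_counts(tree) == 1L)
    if (!length(un)) return(tree)
    tree <- merge_into_child(tree, un[1L])
  }
}

# sum of two optional branch lengths
na_sum <- function(a, b) {
  if (is.na(a) && is.na(b)) return(NA_real_)
  sum(c(a, b), na.rm = TRUE)
}

# remove unary node v, splicing its single child (at v + 1 in pre-order)
# into its place; lengths summed, child's label/annotations kept
merge_into_child <- function(tree, v) {
  ch <- v + 1L  # only child starts immediately after v in pre-order
  stopifnot(!is.na(tree$parent[ch]) && tree$parent[ch] == v)
  len <- tree$length
  len[ch] <- na_sum(len[ch], len[v])
  keep <- setdiff(seq_len(n_nodes(tree)), v)
  p <- tree$parent
  p[ch] <- p[v]  # NA when v was root
  p <- p[keep]
  p <- ifelse(!is.na(p) & p > v, p - 1L, p)
  new_phylotree(p, tree$label[keep], len[keep], tree$annotation[keep],
                tree$hybrid[keep])
}

#' Validate the structural invariants of a tree
#'
#' Checks that the vectors are parallel, that node 1 is the only root, that
#' the layout is a valid pre-order (`parent[i] < i`, every non-root parent
#' in range), that parent/child bookkeeping is bidirectionally consistent,
#' and that every hybrid flag carries an id.  Errors on the first
#' violation.
#'
#' @param tree a `phylotree`.
#' @return `TRUE`, invisibly.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  n <- length(tree$parent)
  if (length(tree$label) != n || length(tree$length) != n ||
      length(tree$annotation) != n || length(tree$hybrid) != n)
    stop("field vectors have unequal lengths")
  if (n == 0L) stop("tree has no nodes")
  if (!is.na(tree$parent[1L])) stop("node 1 must be the root (parent NA)")
  if (n > 1L) {
    p <- tree$parent[-1L]
    if (anyNA(p)) stop("non-root node with NA parent")
    if (any(p < 1L | p >= seq_len(n)[-1L]))
      stop("layout is not pre-order: parent[i] must be < i")
  }
  # bidirectional consistency by full traversal
  ch <- children_list(tree$parent)
  for (v in seq_len(n)) {
    for (c in ch[[v]]) {
      if (tree$parent[c] != v)
        stop("parent/child inconsistency at nodes ", v, "/", c)
    }
  }
  invisible(TRUE)
}

#' @export
print.phylotree <- function(x, ...) {
  nl <- n_leaves(x)
  cat(sprintf("<phylotree: %d nodes, %d leaves%s>\n", n_nodes(x), nl,
              if (any(!is.na(x$hybrid))) ", with hybrid nodes" else ""))
  labs <- x$label[leaf_ids(x)]
  labs <- labs[!is.na(labs)]
  if (length(labs))
    cat("  leaves:", paste(head(labs, 8L), collapse = ", "),
        if (length(labs) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.phylotree <- function(x, ...) {
  data.frame(id = node_ids(x), parent = x$parent, label = x$label,
             branch_length = x$length,
             is_leaf = child_counts(x) == 0L,
             hybrid_id = x$hybrid, stringsAsFactors = FALSE)
}
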