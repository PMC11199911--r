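# Topological operations.  All functions are pure: they return a new tree
# with node ids reassigned in pre-order, never mutating their input.

# rebuild canonical pre-order vectors from an explicit children list,
# starting at `root`; only nodes reachable from root are kept.  `parent` is
# re-derived from the children list, so callers only maintain `children`
# plus the per-node field vectors (which may be longer than the live set).
build_canonical <- function(root, children, label, len, annotation, hybrid) {
  nmax <- length(label)
  ord <- integer(nmax)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- v
    ch <- children[[v]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  ord <- ord[seq_len(k)]
  newid <- integer(nmax)
  newid[ord] <- seq_len(k)
  parent <- rep(NA_integer_, k)
  for (v in ord) {
    for (c in children[[v]]) parent[newid[c]] <- newid[v]
  }
  new_phylotree(parent, label[ord], len[ord], annotation[ord], hybrid[ord])
}

# hybrid ids occurring both inside and outside the pre-order block of v
hybrid_split_ids <- function(tree, v) {
  h <- tree$hybrid
  if (all(is.na(h))) return(character(0))
  size <- subtree_sizes(tree)[v]
  inside <- seq.int(v, v + size - 1L)
  intersect(h[inside][!is.na(h[inside])],
            h[-inside][!is.na(h[-inside])])
}

#' Reroot a tree on the branch above a node
#'
#' Places a new root on the branch leading into `node`, at fraction
#' `proportion` of that branch measured from `node` (default 0.5).  The new
#' root's two children are `node` (with branch length `proportion * L`) and
#' the re-oriented remainder of the tree: edges between the old root and
#' the attachment point are reversed, each keeping the length of the edge
#' it subtends.  If the old root is left with a single child it is
#' suppressed (lengths summed; the child's annotations win).  The new root
#' gets branch length 0, so rerooted trees serialise ending `:0;`.  The
#' leaf set, the total branch length and all leaf-to-leaf path lengths are
#' conserved.  Node ids are reassigned pre-order.
#'
#' Rerooting at the current root is a no-op with a warning.  Rerooting that
#' would separate two records of one hybrid node is an error.
#'
#' @param tree a [phylotree].
#' @param node id (or label) of the node below the split branch; must have
#'   a defined branch length.
#' @param proportion split point in `[0, 1]`, measured from `node`.
#' @return The rerooted tree.
#' @examples
#' t <- read_newick("((a:2,b:2):1,(c:1,d:1):4);")
#' write_newick(reroot(t, "c"))
#' @export
reroot <- function(tree, node, proportion = 0.5) {
  stopifnot(inherits(tree, "phylotree"))
  v <- resolve_node(tree, node)[1L]
  if (v == 1L) {
    warning("node is already the root; tree unchanged")
    return(tree)
  }
  if (!is.numeric(proportion) || proportion < 0 || proportion > 1)
    stop("proportion must be in [0, 1]")
  L <- tree$length[v]
  if (is.na(L))
    stop("cannot reroot: node ", v, " has an undefined branch length")
  bad <- hybrid_split_ids(tree, v)
  if (length(bad))
    stop("refusing to reroot across hybrid node(s): ",
         paste(bad, collapse = ", "))

  n <- n_nodes(tree)
  ch <- children_list(tree$parent)
  label <- c(tree$label, NA_character_)
  len <- c(tree$length, 0.0)
  ann <- c(tree$annotation, list(NULL))
  hyb <- c(tree$hybrid, NA_character_)
  newroot <- n + 1L
  ch[[newroot]] <- integer(0)
  oldlen <- tree$length

  anc <- c(tree$parent[v], get_ancestors(tree, tree$parent[v]))  # p0 .. 1
  p0 <- anc[1L]
  ch[[p0]] <- ch[[p0]][ch[[p0]] != v]
  ch[[newroot]] <- c(v, p0)
  len[v] <- proportion * L
  # reverse the chain from p0 up to the old root
  if (length(anc) >= 2L) {
    for (k in seq_len(length(anc) - 1L)) {
      a <- anc[k]
      b <- anc[k + 1L]
      ch[[b]] <- ch[[b]][ch[[b]] != a]
      ch[[a]] <- c(ch[[a]], b)
      len[b] <- oldlen[a]
    }
  }
  len[p0] <- (1 - proportion) * L

  # suppress the old root if it ended up unary
  oldroot <- anc[length(anc)]
  if (length(ch[[oldroot]]) == 1L) {
    only <- ch[[oldroot]][1L]
    par <- if (length(anc) >= 2L) anc[length(anc) - 1L] else newroot
    pos <- which(ch[[par]] == oldroot)
    ch[[par]][pos] <- only
    len[only] <- na_sum(len[only], len[oldroot])
    ch[[oldroot]] <- integer(0)
  }
  build_canonical(newroot, ch, label, len, ann, hyb)
}

#' Ladderise a tree
#'
#' Sorts the children of every internal node by descendant-leaf count,
#' ascending, with ties broken by the lexicographically smallest descendant
#' leaf label.  Only child order changes: the leaf set, branch lengths and
#' all leaf-to-leaf path lengths are untouched.  Idempotent.
#'
#' @param tree a [phylotree].
#' @return The ladderised tree.
#' @export
ladderise <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  n <- n_nodes(tree)
  if (n == 1L) return(tree)
  lc <- leaf_counts(tree)
  cc <- child_counts(tree)
  minlab <- ifelse(cc == 0L,
                   ifelse(is.na(tree$label), "", tree$label),
                   "\uffff")
  p <- tree$parent
  for (i in n:2) {
    if (minlab[i] < minlab[p[i]]) minlab[p[i]] <- minlab[i]
  }
  ch <- children_list(p)
  for (v in which(cc > 1L)) {
    k <- ch[[v]]
    ch[[v]] <- k[order(lc[k], minlab[k], method = "radix")]
  }
  build_canonical(1L, ch, tree$label, tree$length, tree$annotation,
                  tree$hybrid)
}

#' Extract the clade below a node
#'
#' Returns a new, fully independent tree whose root is a copy of `node`.
#' The copied root *retains* its incoming branch length — this matters for
#' clade-level statistics such as [ie_ratio()], where that branch counts as
#' internal.  Mutating the extracted clade never affects the source tree.
#'
#' @param tree a [phylotree].
#' @param node id (or label) of the clade root.
#' @return A [phylotree].
#' @examples
#' t <- read_newick("((a:2,b:2):1,(c:1,d:1):4);")
#' cl <- get_clade(t, get_mrca(t, c("a", "b")))
#' ie_ratio(cl)  # 1/4
#' @export
get_clade <- function(tree, node) {
  stopifnot(inherits(tree, "phylotree"))
  v <- resolve_node(tree, node)[1L]
  size <- subtree_sizes(tree)[v]
  idx <- seq.int(v, v + size - 1L)
  p <- tree$parent[idx] - (v - 1L)
  p[1L] <- NA_integer_
  new_phylotree(p, tree$label[idx], tree$length[idx],
                tree$annotation[idx], tree$hybrid[idx])
}

#' @rdname get_clade
#' @export
get_subtree <- get_clade

#' Most recent common ancestor
#'
#' The deepest node whose clade contains every input node.  A single input
#' is its own MRCA; the MRCA of all leaves is the root.
#'
#' @param tree a [phylotree].
#' @param nodes non-empty vector of node ids or labels.
#' @return The MRCA node id.
#' @examples
#' t <- read_newick("((a:2,b:2):1,(c:1,d:1):4);")
#' get_mrca(t, c("a", "d"))  # 1, the root
#' @export
get_mrca <- function(tree, nodes) {
  stopifnot(inherits(tree, "phylotree"))
  if (!length(nodes)) stop("getMRCA needs at least one node")
  ids <- resolve_node(tree, nodes)
  if (length(ids) == 1L) return(ids)
  sizes <- subtree_sizes(tree)
  lo <- min(ids)
  hi <- max(ids)
  v <- lo
  while (v + sizes[v] - 1L < hi) v <- tree$parent[v]
  v
}

#' Prune a clade out of a tree
#'
#' Detaches the clade below `node` and returns both pieces: `$tree`, the
#' source with the attachment edge removed and any resulting unary node
#' suppressed (lengths summed), and `$clade`, the detached subtree with its
#' root branch length retained.  Pruning the root, or pruning that would
#' separate two records of one hybrid node, is an error.
#'
#' @param tree a [phylotree].
#' @param node id (or label) of the clade to detach; not the root.
#' @return `list(tree = <remaining tree>, clade = <detached tree>)`.
#' @export
prune <- function(tree, node) {
  stopifnot(inherits(tree, "phylotree"))
  v <- resolve_node(tree, node)[1L]
  if (v == 1L) stop("cannot prune the root")
  bad <- hybrid_split_ids(tree, v)
  if (length(bad))
    stop("refusing to prune across hybrid node(s): ",
         paste(bad, collapse = ", "))
  clade <- get_clade(tree, v)
  size <- subtree_sizes(tree)[v]
  p <- tree$parent[v]
  rest <- drop_block(tree, v)
  p_new <- if (p > v) p - size else p  # parent's id after block removal
  if (child_counts(rest)[p_new] == 1L)
    rest <- merge_into_child(rest, p_new)
  list(tree = rest, clade = clade)
}

#' Graft a subtree onto a tree
#'
#' Attaches `subtree`'s root as a new (last) child of `target`, with the
#' given incoming branch length.  Inverse of [prune()] when reattached at
#' the same place with the same length.
#'
#' @param tree a [phylotree].
#' @param target id (or label) of the attachment node.
#' @param subtree a [phylotree] to attach.
#' @param branch_length non-negative length of the new branch; default: the
#'   subtree root's own (possibly undefined) length.
#' @return The modified tree.
#' @export
graft <- function(tree, target, subtree, branch_length = NULL) {
  stopifnot(inherits(tree, "phylotree"), inherits(subtree, "phylotree"))
  if (!is.null(branch_length)) {
    if (!is.na(branch_length) && branch_length < 0)
      stop("graft branch length must be non-negative")
    subtree$length[1L] <- as.numeric(branch_length)
  }
  add_child(tree, target, subtree)
}
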