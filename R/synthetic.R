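# Seeded synthetic-tree generator.  All randomness comes from an explicit
# splitmix64 stream (compiled in src/), keyed by the caller's seed: the
# same seed gives byte-identical Newick output on every platform, and
# generation never touches R's global RNG state.

#' Generate a random rooted binary tree
#'
#' Shapes:
#' \describe{
#'   \item{yule}{random pair-joins; every non-root branch length drawn iid
#'     from an Exponential with mean `branch_mean`.}
#'   \item{caterpillar}{fully pectinate (maximally unbalanced) topology,
#'     Exponential branch lengths.}
#'   \item{balanced}{complete binary tree; `n_tips` must be a power of
#'     two; Exponential branch lengths.}
#' }
#' Leaves are labelled `t1..tN` in pre-order leaf order.  With
#' `annotate = TRUE` every node gets a numeric `rate` annotation.  With
#' `hybrid_count = k`, `k` internal nodes are duplicated as extended-Newick
#' hybrid records (`#H1..#Hk`) attached elsewhere in the tree — a parser
#' fixture, not a biological model.
#'
#' @param n_tips number of leaves (>= 1).
#' @param shape one of `"yule"`, `"caterpillar"`, `"balanced"`.
#' @param branch_mean mean of the Exponential branch-length distribution.
#' @param seed integer seed; same seed, same tree.
#' @param annotate add a `rate` annotation to every node.
#' @param hybrid_count number of hybrid-node duplications to inject.
#' @return A [phylotree].
#' @examples
#' t <- generate_tree(10, "yule", seed = 42)
#' n_leaves(t)
#' @export
generate_tree <- function(n_tips, shape = c("yule", "caterpillar",
                                            "balanced"),
                          branch_mean = 1.0, seed = 1L, annotate = FALSE,
                          hybrid_count = 0L) {
  shape <- match.arg(shape)
  stopifnot(n_tips >= 1, branch_mean > 0, hybrid_count >= 0)
  tree <- switch(shape,
    yule = {
      sim <- cpp_sim_tree(as.integer(n_tips), as.numeric(seed),
                          branch_mean, FALSE)
      flat_with_tip_labels(sim$parent, sim$length)
    },
    caterpillar = caterpillar_tree(n_tips, branch_mean, seed),
    balanced = balanced_tree(n_tips, branch_mean, seed)
  )
  if (hybrid_count > 0L) tree <- inject_hybrids(tree, hybrid_count, seed)
  if (annotate) {
    u <- cpp_runif(n_nodes(tree), as.numeric(seed) + 1e6)
    tree$annotation <- lapply(seq_len(n_nodes(tree)),
                              function(i) list(rate = signif(u[i], 6)))
  }
  tree
}

flat_with_tip_labels <- function(parent, len) {
  t <- new_phylotree(parent, rep(NA_character_, length(parent)), len)
  lv <- leaf_ids(t)
  t$label[lv] <- paste0("t", seq_along(lv))
  t
}

caterpillar_tree <- function(n_tips, branch_mean, seed) {
  if (n_tips == 1L)
    return(new_phylotree(NA_integer_, "t1", NA_real_))
  N <- 2L * n_tips - 1L
  parent <- integer(N)
  parent[1L] <- NA_integer_
  k <- seq_len(n_tips - 1L)
  parent[2L * k] <- 2L * k - 1L
  parent[2L * k + 1L] <- 2L * k - 1L
  len <- -branch_mean * log(cpp_runif(N, as.numeric(seed)))
  len[1L] <- NA_real_
  flat_with_tip_labels(parent, len)
}

balanced_tree <- function(n_tips, branch_mean, seed) {
  k <- log2(n_tips)
  if (abs(k - round(k)) > 1e-9)
    stop("balanced shape requires n_tips to be a power of 2")
  parent <- balanced_parents(as.integer(n_tips))
  len <- -branch_mean * log(cpp_runif(length(parent), as.numeric(seed)))
  len[1L] <- NA_real_
  flat_with_tip_labels(parent, len)
}

# pre-order parent vector of a complete binary tree with nt leaves
balanced_parents <- function(nt) {
  if (nt == 1L) return(NA_integer_)
  sub <- balanced_parents(nt %/% 2L)
  m <- length(sub)
  left <- sub + 1L
  left[1L] <- 1L
  right <- sub + m + 1L
  right[1L] <- 1L
  c(NA_integer_, left, right)
}

inject_hybrids <- function(tree, k, seed) {
  u <- cpp_runif(2L * k, as.numeric(seed) + 2e6)
  for (j in seq_len(k)) {
    internals <- setdiff(which(child_counts(tree) > 0L), 1L)
    if (!length(internals)) break
    donor <- internals[1L + floor(u[2L * j - 1L] * length(internals))]
    tree$hybrid[donor] <- paste0("H", j)
    # duplicate record: a leaf carrying the same hybrid id, attached to a
    # node outside the donor's clade
    size <- subtree_sizes(tree)[donor]
    outside <- setdiff(node_ids(tree), seq.int(donor, donor + size - 1L))
    target <- outside[1L + floor(u[2L * j] * length(outside))]
    dup <- leaf(length = 0.5)
    dup$hybrid[1L] <- paste0("H", j)
    tree <- add_child(tree, target, dup)
  }
  tree
}

#' Generate an ultrametric pure-birth tree
#'
#' Coalescent-style construction: starting from `n_tips` lineages at the
#' tips, successive random pairs join at exponentially distributed depth
#' increments (rate proportional to the number of extant lineages), so all
#' root-to-tip distances are equal by construction.  Suitable input for
#' [gamma_statistic()], whose expectation under this process is ~0.
#'
#' @param n_tips number of leaves (>= 2).
#' @param seed integer seed.
#' @return An ultrametric binary [phylotree].
#' @export
generate_ultrametric_tree <- function(n_tips, seed = 1L) {
  stopifnot(n_tips >= 2)
  sim <- cpp_sim_tree(as.integer(n_tips), as.numeric(seed), 1.0, TRUE)
  flat_with_tip_labels(sim$parent, sim$length)
}

#' Write a suite of benchmark trees
#'
#' Generates one seeded Yule tree per requested size and writes each to
#' `<dir>/tree_<size>.nwk`.  Regenerating with the same seed gives
#' byte-identical files.
#'
#' @param sizes integer vector of tip counts.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
generate_benchmark_suite <- function(sizes, seed = 1L, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(sizes))
  for (i in seq_along(sizes)) {
    t <- generate_tree(sizes[i], "yule", seed = as.numeric(seed) + i)
    paths[i] <- file.path(dir, paste0("tree_", sizes[i], ".nwk"))
    write_newick(t, file = paths[i])
  }
  invisible(paths)
}
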