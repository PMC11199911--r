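# Summary statistics and data extraction.

#' Root-to-tip distances
#'
#' For each leaf, the sum of branch lengths on the path from the root
#' (exclusive of the root's own branch length) down to and including the
#' leaf.  Every branch on a needed path must have a defined length; an
#' undefined one is an error naming the first affected leaf.  A single-node
#' tree yields one entry of 0.
#'
#' @param tree a [phylotree].
#' @return Named numeric vector, one entry per leaf (keyed by label, or
#'   `node<id>` for unlabelled leaves), in pre-order leaf order.
#' @examples
#' rtt_distances(read_newick("((a:2,b:2):1,(c:1,d:1):4);"))
#' @export
rtt_distances <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  n <- n_nodes(tree)
  d <- numeric(n)
  p <- tree$parent
  len <- tree$length
  if (n > 1L) for (i in 2:n) d[i] <- d[p[i]] + len[i]
  lv <- leaf_ids(tree)
  bad <- lv[is.na(d[lv])]
  if (length(bad))
    stop("undefined branch length on the path to leaf ",
         leaf_name(tree, bad[1L]))
  setNames(d[lv], vapply(lv, function(i) leaf_name(tree, i), character(1L)))
}

leaf_name <- function(tree, i) {
  if (is.na(tree$label[i])) paste0("node", i) else tree$label[i]
}

#' All branch lengths
#'
#' Branch lengths in node-id (pre-order) order, undefined kept as `NA`.
#' The vector has one entry per node.
#'
#' @param tree a [phylotree].
#' @return Numeric vector of length `n_nodes(tree)`.
#' @export
branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  tree$length
}

#' Total tree length
#'
#' Sum of all defined branch lengths (0 for a tree with none).
#'
#' @param tree a [phylotree].
#' @return Numeric scalar.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  sum(tree$length, na.rm = TRUE)
}

#' Internal-to-external branch-length ratio
#'
#' The sum of defined branch lengths over internal nodes (including the
#' root's, when defined) divided by the sum over leaves.  Nodes with
#' undefined lengths are skipped in both sums.  Note the clade convention:
#' a clade extracted with [get_clade()] retains its root's incoming branch,
#' which counts as *internal* here — so for `((a:2,b:2):1,(c:1,d:1):4);`
#' the `{a,b}` clade gives 1/4 and the `{c,d}` clade 4/2.
#'
#' @param tree a [phylotree].
#' @return Numeric scalar.
#' @export
ie_ratio <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  is_lf <- child_counts(tree) == 0L
  ext <- sum(tree$length[is_lf], na.rm = TRUE)
  if (!any(!is.na(tree$length[is_lf])) || ext == 0)
    stop("IE ratio undefined: external branch-length sum is zero")
  sum(tree$length[!is_lf], na.rm = TRUE) / ext
}

#' Annotate every internal node with its clade's IE ratio
#'
#' For each internal node, computes [ie_ratio()] of [get_clade()] at that
#' node (root branch retained) and stores it as annotation key `ieRatio`,
#' formatted to two decimals (half away from zero).  Leaves are untouched.
#'
#' @param tree a [phylotree].
#' @return The annotated tree.
#' @examples
#' t <- annotate_ie_ratios(read_newick("((a:2,b:2):1,(c:1,d:1):4);"))
#' node_data(t, 1)$annotations$ieRatio  # "0.83"
#' @export
annotate_ie_ratios <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  for (v in which(child_counts(tree) > 0L)) {
    r <- ie_ratio(get_clade(tree, v))
    ann <- tree$annotation[[v]]
    if (is.null(ann)) ann <- list()
    ann$ieRatio <- format_fixed2(r)
    tree$annotation[[v]] <- ann
  }
  tree
}

# fixed two-decimal formatting, rounding half away from zero (sprintf
# alone rounds half to even)
format_fixed2 <- function(x) {
  sprintf("%.2f", sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100)
}

#' Sackin index
#'
#' Sum over leaves of their topological depth (root depth 0).  Defined for
#' any rooted tree, multifurcating or not.
#'
#' @param tree a [phylotree].
#' @return Non-negative integer.
#' @export
sackin_index <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  sum(node_depths(tree)[leaf_ids(tree)])
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference in descendant-leaf
#' counts between the two children.  Requires a strictly bifurcating tree;
#' a polytomy (or unary node) is an error naming the offending node.
#'
#' @param tree a [phylotree].
#' @return Non-negative integer.
#' @export
colless_index <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  cc <- child_counts(tree)
  bad <- which(cc != 0L & cc != 2L)
  if (length(bad))
    stop("Colless index needs a strictly bifurcating tree; node ",
         bad[1L], " has ", cc[bad[1L]], " children")
  lc <- leaf_counts(tree)
  ch <- children_list(tree$parent)
  tot <- 0L
  for (v in which(cc == 2L)) {
    k <- ch[[v]]
    tot <- tot + abs(lc[k[1L]] - lc[k[2L]])
  }
  tot
}

#' Pybus-Harvey gamma statistic
#'
#' Standardised summary of internode-interval spacing on an ultrametric,
#' strictly bifurcating tree with at least three leaves.  With `n` leaves
#' and internode intervals `g_2..g_n` (`g_k` = duration with `k` extant
#' lineages) and `T = sum_{j=2}^{n} j*g_j`:
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\sum_{j=2}^{i} j g_j
#'   - T/2}{T\sqrt{1/(12(n-2))}}}
#' Negative values indicate internal nodes concentrated early (near the
#' root); under a pure-birth process the statistic has mean approximately
#' zero.  Invariant under a global rescaling of branch lengths.
#' Ultrametricity is checked to a relative tolerance of 1e-6.
#'
#' @param tree a [phylotree].
#' @return Numeric scalar.
#' @examples
#' gammaStatistic <- gamma_statistic(read_newick("((A:1,B:1):1,C:2);"))
#' round(gammaStatistic, 3)  # -0.346
#' @export
gamma_statistic <- function(tree) {
  stopifnot(inherits(tree, "phylotree"))
  cc <- child_counts(tree)
  if (any(cc != 0L & cc != 2L))
    stop("gamma statistic needs a strictly bifurcating tree")
  lv <- leaf_ids(tree)
  n <- length(lv)
  if (n < 3L) stop("gamma statistic needs at least 3 leaves")
  d <- numeric(n_nodes(tree))
  p <- tree$parent
  len <- tree$length
  for (i in seq_len(n_nodes(tree))[-1L]) d[i] <- d[p[i]] + len[i]
  tipd <- d[lv]
  if (anyNA(tipd)) stop("undefined branch length on a root-to-tip path")
  H <- max(tipd)
  if (H <= 0 || (H - min(tipd)) / H > 1e-6)
    stop("gamma statistic needs an ultrametric tree ",
         "(all root-to-tip distances equal)")
  u <- sort(d[cc == 2L])          # internal-node depths, root first (0)
  g <- c(diff(u), H - u[n - 1L])  # g_2 .. g_n
  jg <- (2:n) * g
  cum <- cumsum(jg)
  Tt <- cum[n - 1L]
  if (Tt <= 0) stop("gamma statistic undefined: total depth is zero")
  (sum(cum[seq_len(n - 2L)]) / (n - 2L) - Tt / 2) /
    (Tt * sqrt(1 / (12 * (n - 2L))))
}

#' Root-to-tip regression
#'
#' Ordinary least squares of root-to-tip distance (response) on tip
#' sampling time (predictor): the slope estimates the molecular-clock rate
#' (distance units per time unit), the intercept extrapolates the distance
#' at time zero, and `r2` is the coefficient of determination.  Tip times
#' are caller-supplied; no dates are parsed from labels.
#'
#' @param tree a [phylotree].
#' @param tip_times named numeric vector mapping every leaf label to its
#'   sampling time; at least two distinct times required.
#' @return An object of class `rtt_regression`: a list with `slope`,
#'   `intercept`, `r2` and `n` (tips used).
#' @examples
#' t <- read_newick("(A:0,B:2);")
#' fit <- rtt_regression(t, c(A = 0, B = 1))
#' fit$slope  # 2
#' @export
rtt_regression <- function(tree, tip_times) {
  stopifnot(inherits(tree, "phylotree"), is.numeric(tip_times))
  d <- rtt_distances(tree)
  if (is.null(names(tip_times))) stop("tip_times must be named by leaf label")
  m <- match(names(d), names(tip_times))
  if (anyNA(m))
    stop("no sampling time for leaf ",
         paste(names(d)[is.na(m)], collapse = ", "))
  tt <- as.numeric(tip_times[m])
  if (length(unique(tt)) < 2L)
    stop("root-to-tip regression needs at least two distinct tip times")
  fit <- lm(d ~ tt)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((d - mean(d))^2)
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n = length(d)),
    class = "rtt_regression"
  )
}

#' @export
print.rtt_regression <- function(x, ...) {
  cat(sprintf(
    "Root-to-tip regression (n = %d tips)\n  slope (rate): %g\n  intercept:    %g\n  r2:           %g\n",
    x$n, x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Tree statistics bundle
#'
#' Computes tree length, Sackin index, Colless index, the gamma statistic
#' and the IE ratio in one call.  Statistics whose preconditions fail on
#' this tree (Colless/gamma on non-binary trees, gamma on non-ultrametric
#' trees, IE ratio with no external branch lengths) are reported as `NA`.
#'
#' @param tree a [phylotree].
#' @return An object of class `tree_stats` (a named list).
#' @export
tree_stats <- function(tree) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  structure(
    list(treeLength = tree_length(tree),
         sackin = sackin_index(tree),
         colless = safe(colless_index(tree)),
         gamma = safe(gamma_statistic(tree)),
         ieRatio = safe(ie_ratio(tree))),
    class = "tree_stats"
  )
}

#' @export
print.tree_stats <- function(x, ...) {
  for (k in names(x)) {
    if (!is.na(x[[k]])) cat(k, "\t", format(x[[k]]), "\n", sep = "")
  }
  invisible(x)
}
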