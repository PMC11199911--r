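test_that("rerooting the worked-example tree at leaf c halves its branch", {
  t <- read_newick(EXAMPLE_NEWICK)
  r <- reroot(t, which(t$label == "c"), proportion = 0.5)
  d <- rtt_distances(r)
  expect_equal(unname(d["c"]), 0.5)
  expect_equal(tree_length(r), tree_length(t), tolerance = 1e-12)
  expect_identical(sort(names(d)), c("a", "b", "c", "d"))
  # new root carries branch length 0 and the output ends ":0;"
  expect_identical(r$length[1], 0)
  expect_match(write_newick(r), ":0;$")
  expect_true(validate_tree(r))
})

test_that("rerooting at the root warns and is a no-op", {
  t <- read_newick(EXAMPLE_NEWICK)
  expect_warning(r <- reroot(t, 1), "already the root")
  expect_tree_equal(r, t)
  expect_error(reroot(t, 99), "out of range")
})

test_that("rerooting conserves leaf-to-leaf path lengths", {
  for (seed in 1:30) {
    withr::local_seed(seed)
    t <- generate_tree(3L + seed %% 12L, "yule", seed = seed)
    before <- leaf_dist_matrix(t)
    v <- sample(setdiff(node_ids(t), 1L), 1L)
    r <- reroot(t, v, proportion = runif(1))
    after <- leaf_dist_matrix(r)
    expect_equal(after, before[rownames(after), colnames(after)],
                 tolerance = 1e-9)
    expect_equal(tree_length(r), tree_length(t), tolerance = 1e-9)
  }
})

test_that("old-root suppression keeps annotations child-preferentially", {
  t <- read_newick("((a:1,b:1)[&x=1]:2,c:3[&y=2]);")
  # reroot on the internal node: old root becomes unary and is merged into
  # its remaining child c, whose annotations win
  r <- reroot(t, 2, proportion = 0.5)
  cc <- which(r$label == "c")
  expect_identical(node_data(r, cc)$annotations, list(y = 2))
})

test_that("ladderise sorts children by clade size and is idempotent", {
  t <- read_newick("(((a:1,b:1):1,c:1):1,d:1);")  # deep clade first
  l <- ladderise(t)
  ch <- treekit:::children_list(l$parent)
  lc <- treekit:::leaf_counts(l)
  for (v in which(treekit:::child_counts(l) > 1L))
    expect_true(all(diff(lc[ch[[v]]]) >= 0))
  expect_tree_equal(ladderise(l), l)
  # conserves everything but order
  expect_identical(sort(l$label[leaf_ids(l)]), sort(t$label[leaf_ids(t)]))
  expect_identical(sort(l$length), sort(t$length))
  expect_equal(leaf_dist_matrix(l), leaf_dist_matrix(t))
})

test_that("ladderise breaks size ties by smallest leaf label", {
  t <- read_newick("((z:1,x:1):1,(b:1,a:1):1);")
  l <- ladderise(t)
  # both clades have 2 leaves; the one containing 'a' must come first
  first_clade <- get_clade(l, node_data(l, 1)$children[1])
  expect_true("a" %in% first_clade$label)
})

test_that("clades extract independently with their root branch retained", {
  t <- read_newick(EXAMPLE_NEWICK)
  whole <- get_clade(t, 1)
  expect_tree_equal(whole, t)
  ab <- get_clade(t, get_mrca(t, c("a", "b")))
  expect_identical(n_leaves(ab), 2L)
  expect_identical(ab$length[1], 1)
  # independence: mutating the clade leaves the source untouched
  before <- write_newick(t)
  ab$length[1] <- 99
  ab$label[2] <- "zzz"
  expect_identical(write_newick(t), before)
  # alias
  expect_tree_equal(get_subtree(t, 2), get_clade(t, 2))
  # random trees: clade leaf count equals the node's descendant-leaf count
  r <- generate_tree(30, "yule", seed = 4)
  lc <- treekit:::leaf_counts(r)
  for (v in c(1L, 5L, 9L))
    expect_identical(n_leaves(get_clade(r, v)), lc[v])
})

test_that("MRCA matches hand traversal on the worked example", {
  t <- read_newick(EXAMPLE_NEWICK)
  ab <- get_mrca(t, c("a", "b"))
  expect_identical(t$length[ab], 1)
  expect_identical(get_mrca(t, c("a", "d")), 1L)
  expect_identical(get_mrca(t, "c"), which(t$label == "c"))
  expect_identical(get_mrca(t, t$label[leaf_ids(t)]), 1L)
  expect_error(get_mrca(t, character(0)), "at least one")
  expect_error(get_mrca(t, c("a", "zz")), "not found")
})

test_that("MRCA agrees with the ancestor-set oracle", {
  for (seed in 1:50) {
    withr::local_seed(seed)
    t <- generate_tree(4L + seed %% 20L, "yule", seed = seed)
    ids <- sample(node_ids(t), sample(2:4, 1L))
    expect_identical(get_mrca(t, ids), mrca_oracle(t, ids))
  }
})

test_that("prune then graft back restores path lengths", {
  t <- generate_tree(12, "yule", seed = 21)
  v <- which(treekit:::leaf_counts(t) == 2L)[1]
  pr <- prune(t, v)
  expect_identical(n_leaves(pr$tree), 10L)
  expect_identical(n_leaves(pr$clade), 2L)
  # conservation checked where the attachment node survives (a polytomy,
  # so pruning leaves no unary node to suppress)
  t2 <- read_newick("(a:1,b:2,c:3,(d:1,e:1):2);")
  b2 <- leaf_dist_matrix(t2)
  de <- get_mrca(t2, c("d", "e"))
  pr2 <- prune(t2, de)
  expect_identical(n_leaves(pr2$tree), 3L)
  g <- graft(pr2$tree, 1, pr2$clade, branch_length = 2)
  a2 <- leaf_dist_matrix(g)
  expect_equal(a2, b2[rownames(a2), colnames(a2)], tolerance = 1e-12)
})

test_that("pruning suppresses the unary attachment node", {
  t <- read_newick("((a:1,b:2):3,c:4);")
  pr <- prune(t, which(t$label == "a"))
  # parent of a kept b only; suppressed: b's length = 2 + 3
  b <- which(pr$tree$label == "b")
  expect_equal(pr$tree$length[b], 5)
  expect_identical(sum(treekit:::child_counts(pr$tree) == 1L), 0L)
  expect_error(prune(t, 1), "root")
})

test_that("pruning every leaf in turn always leaves a valid tree", {
  t <- generate_tree(8, "yule", seed = 6)
  for (v in leaf_ids(t)) {
    pr <- prune(t, v)
    expect_true(validate_tree(pr$tree))
    expect_identical(n_leaves(pr$tree), 7L)
  }
})

test_that("graft validates its branch length and keeps annotations", {
  t <- read_newick("(a:1,b:1);")
  sub <- leaf("X", 1, annotations = list(rate = 0.25))
  expect_error(graft(t, 1, sub, branch_length = -1), "non-negative")
  g <- graft(t, 1, sub, branch_length = 2)
  expect_identical(n_leaves(g), 3L)
  x <- which(g$label == "X")
  expect_identical(g$length[x], 2)
  back <- read_newick(write_newick(g, annotator = beast_annotation))
  expect_identical(node_data(back, which(back$label == "X"))$annotations,
                   list(rate = 0.25))
})

test_that("reroot and prune refuse to split a hybrid node", {
  t <- read_newick("((A:1,B:1)#H1:1,(#H1:0.5,C:1):1);")
  h <- which(!is.na(t$hybrid))[1]
  expect_error(reroot(t, h), "hybrid")
  expect_error(prune(t, h), "hybrid")
  # pruning a clade that contains no split hybrid is fine
  c_id <- which(t$label == "C")
  expect_silent(prune(t, c_id))
})
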