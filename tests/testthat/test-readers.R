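test_that("the four-leaf worked-example tree parses correctly", {
  t <- read_newick(EXAMPLE_NEWICK)
  expect_identical(n_leaves(t), 4L)
  expect_identical(sort(t$label[leaf_ids(t)]), c("a", "b", "c", "d"))
  expect_identical(n_nodes(t) - n_leaves(t), 3L)
  expect_true(is.na(t$length[1]))
  expect_identical(t$length[-1], c(1, 2, 2, 4, 1, 1))
})

test_that("a bare ';' is a single unlabelled root", {
  t <- read_newick(";")
  expect_identical(n_nodes(t), 1L)
  expect_true(is.na(t$label[1]) && is.na(t$length[1]))
})

test_that("BEAST annotations attach to the annotated node", {
  t <- read_newick("(A[&rate=0.5]:1,B:2);")
  a <- which(t$label == "A")
  expect_identical(node_data(t, a)$annotations, list(rate = 0.5))
  expect_identical(t$length[a], 1)
  # branch-placed annotation lands in the same map
  t2 <- read_newick("(A:1[&rate=0.5],B[&x=2]:2[&y=3]);")
  expect_identical(node_data(t2, which(t2$label == "A"))$annotations,
                   list(rate = 0.5))
  expect_identical(node_data(t2, which(t2$label == "B"))$annotations,
                   list(x = 2, y = 3))
  # vector values and quoted strings
  t3 <- read_newick('(A[&range={1,2.5},host="a,b"]:1,B:1);')
  ann <- node_data(t3, which(t3$label == "A"))$annotations
  expect_identical(ann$range, c(1, 2.5))
  expect_identical(ann$host, "a,b")
})

test_that("NHX blocks after the branch length parse into the same map", {
  t <- read_newick("(A:1[&&NHX:S=human:D=N],B:2);")
  ann <- node_data(t, which(t$label == "A"))$annotations
  expect_identical(ann, list(S = "human", D = "N"))
})

test_that("plain square-bracket comments are discarded", {
  t <- read_newick("[this is a comment](a:1,b:2)[another];")
  expect_identical(n_leaves(t), 2L)
  expect_true(all(vapply(t$annotation, is.null, logical(1))))
})

test_that("extended-Newick hybrid tags create linked records", {
  t <- read_newick("((A,B)#H1:1,(#H1:0.5,C):1);")
  h <- which(!is.na(t$hybrid))
  expect_identical(length(h), 2L)
  expect_identical(unique(t$hybrid[h]), "H1")
  expect_true(all(vapply(h, function(v) node_data(t, v)$is_hybrid,
                         logical(1))))
})

test_that("malformed input errors carry a character offset", {
  expect_error(read_newick("((a,b);"), "character")
  expect_error(read_newick("(a,b));"), "character")
  expect_error(read_newick("(a,b)"), "missing ';'")
  expect_error(read_newick("(a,);"), "dangling comma")
  expect_error(read_newick("('abc,d);"), "unterminated quoted")
  expect_error(read_newick("(a[&x=1,b);"), "unterminated")
  expect_error(read_newick("(a:xyz,b);"), "expected number")
  expect_error(read_newick("(a,b); junk"), "after ';'")
})

test_that("negative branch lengths parse with a warning", {
  expect_warning(t <- read_newick("(a:-0.001,b:1);"), "negative")
  expect_identical(t$length[which(t$label == "a")], -0.001)
})

test_that("whitespace between tokens never changes the parse", {
  spaced <- "(( a :2 ,\n b : 2 ) : 1 ,\t ( c :1 , d : 1 ) : 4 ) ;"
  expect_tree_equal(read_newick(spaced), read_newick(EXAMPLE_NEWICK))
})

test_that("quoted labels keep their special characters", {
  t <- read_newick("('sp one (A)':1,'it''s':2);")
  expect_identical(sort(t$label[leaf_ids(t)]), c("it's", "sp one (A)"))
})

test_that("underscores in unquoted labels are kept verbatim", {
  t <- read_newick("(Homo_sapiens:1,Pan:1);")
  expect_true("Homo_sapiens" %in% t$label)
})

test_that("newline-separated Newick reads as an ordered list", {
  two <- "((A:1,B:1):1,C:1);\n((A:1,B:1):1,C:1);"
  trees <- read_newick_trees(two)
  expect_length(trees, 2L)
  expect_identical(vapply(trees, n_leaves, integer(1)), c(3L, 3L))
  expect_length(read_newick_trees(""), 0L)
  k <- 5L
  joined <- paste(vapply(1:k, function(s)
    write_newick(generate_tree(6, "yule", seed = s)), character(1)),
    collapse = "\n")
  expect_length(read_newick_trees(joined), k)
  expect_error(read_newick_trees("(a,b);\n(a,b;"), "line 2")
})

test_that("Nexus documents parse with TRANSLATE substitution", {
  trees <- read_nexus(example_nexus())
  expect_length(trees, 1L)
  expect_tree_equal(trees[[1]], read_newick(EXAMPLE_NEWICK))

  nx <- paste0("#NEXUS\nBEGIN TREES;\nTRANSLATE\n 1 Homo,\n 2 Pan;\n",
               "TREE t1 = (1:1,2:2);\nEND;\n")
  t <- read_nexus(nx)[[1]]
  expect_identical(sort(t$label[leaf_ids(t)]), c("Homo", "Pan"))

  nx3 <- paste0("#NEXUS\nbegin trees;\n",
                "tree a = (x:1,y:1);\ntree b = (x:2,y:2);\n",
                "tree c = ((x:1,y:1):1,z:3);\nend;\n")
  expect_length(read_nexus(nx3), 3L)

  expect_error(read_nexus("#NEXUS\nbegin taxa;\nend;\n"), "TREES block")
  expect_error(read_nexus("(a,b);"), "#NEXUS")
})

test_that("PhyloXML parses to the same tree as Newick", {
  trees <- read_phyloxml(example_phyloxml())
  expect_length(trees, 1L)
  ref <- read_newick(EXAMPLE_NEWICK)
  expect_identical(trees[[1]]$parent, ref$parent)
  expect_identical(trees[[1]]$label, ref$label)
  expect_identical(trees[[1]]$length, ref$length)
})

test_that("unsupported PhyloXML elements warn but do not crash", {
  xml <- paste0('<phyloxml><phylogeny><clade>',
                '<clade><name>a</name><confidence type="x">1</confidence>',
                '<branch_length>1</branch_length></clade>',
                '<clade><name>b</name><branch_length>1</branch_length>',
                '</clade></clade></phylogeny></phyloxml>')
  expect_warning(trees <- read_phyloxml(xml), "confidence")
  expect_identical(n_leaves(trees[[1]]), 2L)
})

test_that("NeXML parses nodes, edges and otu labels", {
  xml <- paste0('<nexml><trees><tree>',
                '<node id="r" root="true"/>',
                '<node id="l1" label="A"/><node id="l2" label="B"/>',
                '<edge source="r" target="l1" length="1"/>',
                '<edge source="r" target="l2" length="1"/>',
                '</tree></trees></nexml>')
  t <- read_nexml(xml)[[1]]
  expect_identical(n_leaves(t), 2L)
  expect_identical(t$length[leaf_ids(t)], c(1, 1))

  trees <- read_nexml(example_nexml())
  ref <- read_newick(EXAMPLE_NEWICK)
  expect_identical(trees[[1]]$label, ref$label)
  expect_identical(trees[[1]]$length, ref$length)

  bad <- sub('target="l2"', 'target="nope"', xml)
  expect_error(read_nexml(bad), "unknown node id")
})

test_that("PhyJSON parses trees, counts and annotations", {
  trees <- read_phyjson(example_phyjson())
  ref <- read_newick(EXAMPLE_NEWICK)
  expect_identical(trees[[1]]$label, ref$label)
  expect_identical(trees[[1]]$length, ref$length)

  two <- '{"trees": [{"name": "x"}, {"name": "y"}]}'
  expect_length(read_phyjson(two), 2L)

  ann <- '{"root": {"children": [{"name": "a", "length": 1,
           "annotations": {"rate": 0.5}}, {"name": "b", "length": 2}]}}'
  t <- read_phyjson(ann)[[1]]
  expect_identical(node_data(t, which(t$label == "a"))$annotations,
                   list(rate = 0.5))
})

test_that("the same tree agrees across all five formats", {
  ref <- read_newick(EXAMPLE_NEWICK)
  others <- list(read_nexus(example_nexus())[[1]],
                 read_phyloxml(example_phyloxml())[[1]],
                 read_nexml(example_nexml())[[1]],
                 read_phyjson(example_phyjson())[[1]])
  for (t in others) {
    expect_identical(t$parent, ref$parent)
    expect_identical(t$label, ref$label)
    expect_identical(t$length, ref$length)
  }
})

test_that("read() always returns a list and validates its schema", {
  expect_length(read_trees(EXAMPLE_NEWICK, "newick"), 1L)
  expect_length(read_trees("((A:1,B:1):1,C:1);\n((A:1,B:1):1,C:1);",
                           "newick"), 2L)
  expect_error(read_trees(EXAMPLE_NEWICK, "nexus"), "#NEXUS")
  expect_error(read_trees(EXAMPLE_NEWICK, "fasta"))
})

test_that("stack parser agrees with the recursive-descent oracle", {
  for (seed in 1:100) {
    t <- random_messy_tree(seed)
    nwk <- write_newick(t, annotator = beast_annotation)
    expect_matches_oracle(read_newick(nwk), nwk)
  }
})

test_that("cross-parse agrees with ape on plain trees", {
  skip_if_not_installed("ape")
  for (seed in c(3, 14, 59)) {
    t <- generate_tree(20, "yule", seed = seed)
    ph <- ape::read.tree(text = write_newick(t))
    expect_setequal(ph$tip.label, t$label[leaf_ids(t)])
    expect_equal(sum(ph$edge.length), tree_length(t), tolerance = 1e-12)
  }
})

test_that("deep pectinate trees parse without recursion failure", {
  t <- generate_tree(2e4, "caterpillar", seed = 1)
  t2 <- read_newick(write_newick(t))
  expect_identical(n_leaves(t2), 20000L)
})
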