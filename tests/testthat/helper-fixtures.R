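# Fixture builders used across test files.  All randomness is seeded
# locally so tests are reproducible and leave the session RNG untouched.

EXAMPLE_NEWICK <- "((a:2,b:2):1,(c:1,d:1):4);"

# A random "messy" tree: multifurcations, undefined branch lengths, quoted
# labels and mixed BEAST/NHX-style annotation values — the hard cases for
# serialisation round-trips.
random_messy_tree <- function(seed) {
  withr::local_seed(seed)
  n <- sample(2:64, 1L)
  t <- generate_tree(n, "yule", seed = seed)
  # polytomies: graft extra leaves directly onto internal nodes
  internals <- which(treekit:::child_counts(t) > 0L)
  for (k in seq_len(min(3L, length(internals)))) {
    if (runif(1) < 0.6) {
      target <- sample(internals, 1L)
      t <- add_child(t, target,
                     leaf(paste0("x", k), round(runif(1), 3L)))
    }
  }
  # undefined branch lengths on a few nodes (root already has none)
  drop <- which(runif(n_nodes(t)) < 0.1)
  t$length[drop] <- NA_real_
  # labels that need quoting
  lv <- leaf_ids(t)
  fancy <- sample(lv, min(2L, length(lv)))
  t$label[fancy[1L]] <- "sp one (type 'A')"
  if (length(fancy) > 1L) t$label[fancy[2L]] <- "genus,species"
  # annotations of every supported shape
  pick <- sample(n_nodes(t), min(4L, n_nodes(t)))
  t$annotation[[pick[1L]]] <- list(rate = round(runif(1), 6L))
  if (length(pick) > 1L)
    t$annotation[[pick[2L]]] <- list(host = "human", S = "N")
  if (length(pick) > 2L)
    t$annotation[[pick[3L]]] <- list(range = c(round(runif(1), 4L),
                                               round(runif(1), 4L) + 1))
  if (length(pick) > 3L)
    t$annotation[[pick[4L]]] <- list(note = "a,b=c")
  t
}

# PhyloXML / NeXML / PhyJSON encodings of the four-leaf worked-example tree
example_phyloxml <- function() {
  paste0(
    '<phyloxml xmlns="http://www.phyloxml.org">\n',
    ' <phylogeny rooted="true">\n',
    '  <clade>\n',
    '   <clade><branch_length>1</branch_length>\n',
    '    <clade><name>a</name><branch_length>2</branch_length></clade>\n',
    '    <clade><name>b</name><branch_length>2</branch_length></clade>\n',
    '   </clade>\n',
    '   <clade><branch_length>4</branch_length>\n',
    '    <clade><name>c</name><branch_length>1</branch_length></clade>\n',
    '    <clade><name>d</name><branch_length>1</branch_length></clade>\n',
    '   </clade>\n',
    '  </clade>\n',
    ' </phylogeny>\n',
    '</phyloxml>')
}

example_nexml <- function() {
  paste0(
    '<nexml xmlns="http://www.nexml.org/2009" version="0.9">\n',
    ' <otus id="os1">\n',
    '  <otu id="o1" label="a"/><otu id="o2" label="b"/>\n',
    '  <otu id="o3" label="c"/><otu id="o4" label="d"/>\n',
    ' </otus>\n',
    ' <trees id="ts1" otus="os1">\n',
    '  <tree id="t1" xsi:type="nex:FloatTree" ',
    'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance">\n',
    '   <node id="r" root="true"/>\n',
    '   <node id="i1"/><node id="i2"/>\n',
    '   <node id="n1" otu="o1"/><node id="n2" otu="o2"/>\n',
    '   <node id="n3" otu="o3"/><node id="n4" otu="o4"/>\n',
    '   <edge id="e1" source="r" target="i1" length="1"/>\n',
    '   <edge id="e2" source="i1" target="n1" length="2"/>\n',
    '   <edge id="e3" source="i1" target="n2" length="2"/>\n',
    '   <edge id="e4" source="r" target="i2" length="4"/>\n',
    '   <edge id="e5" source="i2" target="n3" length="1"/>\n',
    '   <edge id="e6" source="i2" target="n4" length="1"/>\n',
    '  </tree>\n',
    ' </trees>\n',
    '</nexml>')
}

example_phyjson <- function() {
  paste0('{"trees": [{"root": ',
         '{"children": [',
         '{"length": 1, "children": [',
         '{"name": "a", "length": 2}, {"name": "b", "length": 2}]},',
         '{"length": 4, "children": [',
         '{"name": "c", "length": 1}, {"name": "d", "length": 1}]}',
         ']}}]}')
}

example_nexus <- function() {
  paste0("#NEXUS\nbegin trees;\n tree one = [&R] ",
         sub(";$", "", EXAMPLE_NEWICK), ";\nend;\n")
}
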