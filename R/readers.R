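#' Read a single Newick statement
#'
#' Parses one `;`-terminated Newick statement (leading/trailing whitespace,
#' including newlines between tokens, is ignored) into a [phylotree].  The
#' parser is iterative with an explicit stack, so arbitrarily deep
#' (pectinate) trees of a million or more tips parse without any
#' recursion-depth limit.  Node ids are assigned in pre-order as the
#' statement is consumed.
#'
#' Supported dialect:
#' * unquoted labels exclude `()[]{}:;,=` and whitespace; underscores are
#'   kept verbatim (not turned into spaces);
#' * single-quoted labels with `''` escaping;
#' * BEAST annotations `[&k=v,...]` after the label and/or after the branch
#'   length, and NHX blocks `[&&NHX:k=v:...]` — all merged into one
#'   annotation map per node;
#' * other square-bracket comments are discarded;
#' * extended-Newick hybrid tags: an unquoted label suffix `#H1` marks the
#'   node as hybrid with id `"H1"`; records sharing an id denote one
#'   network node;
#' * branch lengths in decimal or scientific notation; negative lengths
#'   are kept with a warning (they occur in real BEAST output).
#'
#' Malformed input (unbalanced parentheses, dangling comma, unterminated
#' quote or comment, missing `;`) raises an error carrying the 1-based
#' character offset.
#'
#' @param text a character scalar containing exactly one Newick statement.
#' @return A [phylotree].
#' @examples
#' t <- read_newick("((a:2,b:2):1,(c:1,d:1):4);")
#' n_leaves(t)
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- cpp_parse_newick(text)
  ann <- vector("list", length(raw$parent))
  has <- which(!is.na(raw$annotation))
  for (i in has) ann[[i]] <- parse_annotation_blocks(raw$annotation[i])
  new_phylotree(raw$parent, raw$label, raw$length, ann, raw$hybrid)
}

#' Read newline-separated Newick statements
#'
#' One tree per non-blank line, input order preserved; an empty input gives
#' an empty list.  A malformed statement raises an error identifying its
#' line number.
#'
#' @param text a character scalar (lines separated by `\n`; `\r\n` is
#'   normalised).
#' @return A list of [phylotree] objects.
#' @export
read_newick_trees <- function(text) {
  stopifnot(is.character(text))
  text <- gsub("\r\n", "\n", paste(text, collapse = "\n"), fixed = TRUE)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  keep <- which(nzchar(trimws(lines)))
  lapply(keep, function(i) {
    tryCatch(read_newick(lines[i]),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
}

# ---------------------------------------------------------------------------
# Nexus
# ---------------------------------------------------------------------------

# split Nexus text into `;`-terminated statements, respecting single quotes
# and square-bracket comments
nexus_statements <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  in_q <- FALSE
  depth <- 0L
  stmts <- character(0)
  start <- 1L
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (in_q) {
      if (c == "'") in_q <- FALSE
    } else if (c == "'") {
      in_q <- TRUE
    } else if (c == "[") {
      depth <- depth + 1L
    } else if (c == "]") {
      depth <- max(0L, depth - 1L)
    } else if (c == ";" && depth == 0L) {
      stmts <- c(stmts, paste(chars[start:(i - 1L)], collapse = ""))
      start <- i + 1L
    }
  }
  stmts
}

# strip [..] comments and collapse whitespace, for keyword matching only
nexus_keyword_form <- function(s) {
  s <- gsub("\\[[^][]*\\]", " ", s)
  tolower(trimws(gsub("\\s+", " ", s)))
}

#' Read trees from a Nexus document
#'
#' Requires a `#NEXUS` header and a TREES block.  An optional TRANSLATE
#' statement maps tokens to taxon labels; matching labels in each tree are
#' substituted.  Keywords are matched case-insensitively; rooting comments
#' (`[&R]`, `[&U]`) ahead of the tree are ignored; BEAST/NHX annotations
#' inside the tree are preserved.  Labels that are not translate keys (e.g.
#' internal-node names) are left verbatim.
#'
#' @param text a character scalar with the whole document.
#' @return A list of [phylotree] objects, one per `tree` statement.
#' @export
read_nexus <- function(text) {
  stopifnot(is.character(text))
  text <- gsub("\r\n", "\n", paste(text, collapse = "\n"), fixed = TRUE)
  if (!grepl("^\\s*#nexus", tolower(text)))
    stop("not a Nexus document: missing #NEXUS header")
  stmts <- nexus_statements(sub("^\\s*#[Nn][Ee][Xx][Uu][Ss]", "", text))
  kw <- vapply(stmts, nexus_keyword_form, character(1L), USE.NAMES = FALSE)
  b <- which(grepl("^begin\\s+trees$", kw))
  if (!length(b)) stop("Nexus document has no TREES block")
  e <- which(grepl("^end(block)?$", kw))
  e <- e[e > b[1L]]
  hi <- if (length(e)) e[1L] - 1L else length(stmts)
  block <- (b[1L] + 1L):hi
  translate <- NULL
  trees <- list()
  for (i in block) {
    if (grepl("^translate\\b", kw[i])) {
      translate <- parse_translate(stmts[i])
    } else if (grepl("^tree\\b", kw[i])) {
      eq <- find_top_level(stmts[i], "=")
      if (eq < 0) stop("malformed tree statement: no '='")
      nwk <- substr(stmts[i], eq + 1L, nchar(stmts[i]))
      # drop leading rooting/other comments before the tree itself
      nwk <- sub("^\\s*(\\[[^][]*\\]\\s*)*", "", nwk)
      t <- read_newick(paste0(nwk, ";"))
      if (!is.null(translate)) {
        m <- match(t$label, names(translate))
        hit <- !is.na(m)
        t$label[hit] <- unname(translate[m[hit]])
      }
      trees <- c(trees, list(t))
    }
  }
  trees
}

# first position of `what` outside quotes and comments, or -1
find_top_level <- function(s, what) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  in_q <- FALSE
  depth <- 0L
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (in_q) { if (c == "'") in_q <- FALSE }
    else if (c == "'") in_q <- TRUE
    else if (c == "[") depth <- depth + 1L
    else if (c == "]") depth <- max(0L, depth - 1L)
    else if (c == what && depth == 0L) return(i)
  }
  -1L
}

parse_translate <- function(stmt) {
  body <- sub("^\\s*(\\[[^][]*\\]\\s*)*[Tt][Rr][Aa][Nn][Ss][Ll][Aa][Tt][Ee]",
              "", stmt)
  entries <- split_top_level(body, ",")
  out <- character(0)
  for (en in entries) {
    en <- trimws(gsub("\\s+", " ", en))
    if (!nzchar(en)) next
    m <- regmatches(en, regexec("^(\\S+)\\s+(.*)$", en))[[1L]]
    if (length(m) != 3L) stop("malformed TRANSLATE entry: ", en)
    lab <- m[3L]
    if (startsWith(lab, "'") && endsWith(lab, "'"))
      lab <- gsub("''", "'", substr(lab, 2L, nchar(lab) - 1L))
    out[m[2L]] <- lab
  }
  out
}

# ---------------------------------------------------------------------------
# nested-object builder shared by the XML/JSON readers
# ---------------------------------------------------------------------------

# nested node: list(label, length, children = list(...), annotations,
# hybrid); built into flat pre-order vectors with an explicit stack
tree_from_nested <- function(root) {
  parent <- integer(0)
  label <- character(0)
  len <- numeric(0)
  ann <- list()
  hyb <- character(0)
  stack <- list(list(node = root, parent = NA_integer_))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    id <- length(parent) + 1L
    parent[id] <- top$parent
    label[id] <- if (is.null(nd$label)) NA_character_ else
      as.character(nd$label)
    len[id] <- if (is.null(nd$length)) NA_real_ else as.numeric(nd$length)
    ann[[id]] <- if (is.null(nd$annotations) || !length(nd$annotations))
      NULL else nd$annotations
    hyb[id] <- if (is.null(nd$hybrid)) NA_character_ else
      as.character(nd$hybrid)
    kids <- nd$children
    if (!is.null(kids) && length(kids)) {
      for (k in rev(seq_along(kids)))
        stack[[length(stack) + 1L]] <- list(node = kids[[k]], parent = id)
    }
  }
  new_phylotree(parent, label, len, ann, hyb)
}

# ---------------------------------------------------------------------------
# PhyloXML
# ---------------------------------------------------------------------------

#' Read trees from a PhyloXML document
#'
#' Parses nested `<clade>` elements, honouring `<name>` and
#' `<branch_length>` (element or attribute).  Other clade children (e.g.
#' taxonomy, confidence) are ignored with a single warning listing them.
#'
#' @param text a character scalar with the XML document.
#' @return A list of [phylotree] objects, one per `<phylogeny>`.
#' @export
read_phyloxml <- function(text) {
  doc <- xml2::read_xml(paste(text, collapse = "\n"))
  phys <- xml2::xml_find_all(doc, ".//*[local-name()='phylogeny']")
  ignored <- new.env(parent = emptyenv())
  ignored$names <- character(0)
  out <- lapply(phys, function(p) {
    clade <- xml2::xml_find_first(p, "./*[local-name()='clade']")
    if (inherits(clade, "xml_missing"))
      stop("phylogeny element without a clade")
    tree_from_nested(phyloxml_clade(clade, ignored))
  })
  if (length(ignored$names))
    warning("ignored PhyloXML element(s): ",
            paste(sort(unique(ignored$names)), collapse = ", "))
  out
}

phyloxml_clade <- function(x, ignored) {
  kids <- xml2::xml_children(x)
  nms <- xml2::xml_name(kids)
  lab <- NULL
  len <- NULL
  blattr <- xml2::xml_attr(x, "branch_length")
  if (!is.na(blattr)) len <- as.numeric(blattr)
  children <- list()
  for (i in seq_along(kids)) {
    nm <- nms[i]
    if (nm == "clade") {
      children[[length(children) + 1L]] <- phyloxml_clade(kids[[i]], ignored)
    } else if (nm == "name") {
      lab <- xml2::xml_text(kids[[i]])
    } else if (nm == "branch_length") {
      len <- as.numeric(xml2::xml_text(kids[[i]]))
    } else {
      ignored$names <- c(ignored$names, nm)
    }
  }
  list(label = lab, length = len, children = children)
}

# ---------------------------------------------------------------------------
# NeXML
# ---------------------------------------------------------------------------

#' Read trees from a NeXML document
#'
#' Builds each `<tree>` from its `<node>` and `<edge>` lists; node labels
#' come from the `label` attribute or the referenced `<otu>`.  The root is
#' the node flagged `root="true"`, or failing that the unique node that is
#' never an edge target.  An edge referencing an unknown node id is an
#' error.
#'
#' @param text a character scalar with the XML document.
#' @return A list of [phylotree] objects.
#' @export
read_nexml <- function(text) {
  doc <- xml2::read_xml(paste(text, collapse = "\n"))
  otus <- xml2::xml_find_all(doc, ".//*[local-name()='otu']")
  otu_lab <- setNames(xml2::xml_attr(otus, "label"),
                      xml2::xml_attr(otus, "id"))
  trees <- xml2::xml_find_all(doc, ".//*[local-name()='tree']")
  lapply(trees, function(tr) nexml_tree(tr, otu_lab))
}

nexml_tree <- function(tr, otu_lab) {
  nds <- xml2::xml_find_all(tr, "./*[local-name()='node']")
  ids <- xml2::xml_attr(nds, "id")
  labs <- xml2::xml_attr(nds, "label")
  otu <- xml2::xml_attr(nds, "otu")
  hit <- is.na(labs) & !is.na(otu)
  labs[hit] <- otu_lab[otu[hit]]
  rootflag <- xml2::xml_attr(nds, "root")
  eds <- xml2::xml_find_all(tr, "./*[local-name()='edge']")
  src <- xml2::xml_attr(eds, "source")
  tgt <- xml2::xml_attr(eds, "target")
  elen <- as.numeric(xml2::xml_attr(eds, "length"))
  bad <- setdiff(c(src, tgt), ids)
  if (length(bad))
    stop("NeXML edge references unknown node id: ",
         paste(bad, collapse = ", "))
  root <- ids[!is.na(rootflag) & tolower(rootflag) == "true"]
  if (!length(root)) root <- setdiff(ids, tgt)
  if (length(root) != 1L)
    stop("NeXML tree must have exactly one root node")
  len <- setNames(rep(NA_real_, length(ids)), ids)
  len[tgt] <- elen
  kids <- split(tgt, factor(src, levels = ids))
  lab <- setNames(labs, ids)
  build <- function(id) {
    list(label = if (is.na(lab[[id]])) NULL else lab[[id]],
         length = if (is.na(len[[id]])) NULL else len[[id]],
         children = lapply(kids[[id]], build))
  }
  tree_from_nested(build(root))
}

# ---------------------------------------------------------------------------
# PhyJSON
# ---------------------------------------------------------------------------

#' Read trees from a PhyJSON document
#'
#' The supported (deliberately minimal) schema is this package's own
#' convention: the document is either a single tree object or
#' `{"trees": [tree, ...]}`; a tree object is either a node or
#' `{"root": node}`; a node is
#' `{"name": str, "length": num, "children": [node, ...],
#' "annotations": {...}, "hybrid": str}`, all fields optional.
#'
#' @param text a character scalar with the JSON document.
#' @return A list of [phylotree] objects.
#' @export
read_phyjson <- function(text) {
  obj <- jsonlite::fromJSON(paste(text, collapse = "\n"),
                            simplifyVector = FALSE)
  entries <- if (!is.null(obj$trees)) obj$trees else list(obj)
  lapply(entries, function(t) {
    nd <- if (!is.null(t$root)) t$root else t
    tree_from_nested(phyjson_node(nd))
  })
}

phyjson_node <- function(nd) {
  ann <- nd$annotations
  if (!is.null(ann))
    ann <- lapply(ann, function(v) if (is.list(v)) unlist(v) else v)
  list(label = nd$name, length = nd$length,
       children = lapply(nd$children %||% list(), phyjson_node),
       annotations = ann, hybrid = nd$hybrid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# generic dispatch
# ---------------------------------------------------------------------------

#' Read trees from any supported format
#'
#' Dispatches on `schema` to the matching multi-tree reader and *always*
#' returns a list of trees, even for single-tree input.
#'
#' @param text a character scalar with the whole document.
#' @param schema one of `"newick"`, `"nexus"`, `"phyloxml"`, `"nexml"`,
#'   `"phyjson"`.
#' @return A list of [phylotree] objects.
#' @examples
#' read_trees("((a:2,b:2):1,(c:1,d:1):4);", "newick")
#' @export
read_trees <- function(text, schema = c("newick", "nexus", "phyloxml",
                                        "nexml", "phyjson")) {
  schema <- match.arg(schema)
  switch(schema,
         newick = read_newick_trees(text),
         nexus = read_nexus(text),
         phyloxml = read_phyloxml(text),
         nexml = read_nexml(text),
         phyjson = read_phyjson(text))
}
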