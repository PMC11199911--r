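#' Write a tree to Newick
#'
#' Serialises a [phylotree] to a single `;`-terminated Newick statement.
#' The writer is iterative (an explicit stack, symmetric to the parser), so
#' million-tip trees serialise without recursion-depth limits.  Undefined
#' branch lengths are omitted entirely (no `:` token); multifurcations are
#' written as-is, never resolved.  Branch lengths use the shortest decimal
#' representation that round-trips exactly.  Labels are quoted only when
#' they contain characters illegal in unquoted Newick.
#'
#' By default no annotations are written.  Pass `annotator =`
#' [beast_annotation] or [nhx_annotation] (or any function from a
#' [node_data()] list to a bracketed fragment) to include them; a
#' `placement` attribute of `"after"` on the function puts the fragment
#' after the branch length (NHX convention), anything else before it
#' (BEAST convention).
#'
#' @param tree a [phylotree].
#' @param annotator optional annotation callback.
#' @param file optional path; when given the statement is written there and
#'   returned invisibly.
#' @return The Newick statement as a character scalar.
#' @examples
#' t <- read_newick("((a:2,b:2):1,(c:1,d:1):4);")
#' write_newick(t)
#' @export
write_newick <- function(tree, annotator = NULL, file = NULL) {
  stopifnot(inherits(tree, "phylotree"))
  n <- n_nodes(tree)
  lab <- tree$label
  tok <- quote_labels(lab)
  tok[is.na(lab)] <- ""
  hyb <- tree$hybrid
  has_h <- !is.na(hyb)
  if (any(has_h)) tok[has_h] <- paste0(tok[has_h], "#", hyb[has_h])
  pre <- post <- NULL
  if (!is.null(annotator)) {
    frag <- vapply(seq_len(n),
                   function(i) annotator(node_data(tree, i)),
                   character(1L))
    if (identical(attr(annotator, "placement"), "after")) post <- frag
    else pre <- frag
  }
  out <- cpp_write_newick(tree$parent, tok, tree$length, pre, post)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# quote labels that contain characters illegal in unquoted Newick
quote_labels <- function(lab) {
  needs <- grepl("[][(){}:;,='\"#[:space:]]", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
  lab
}

#' Write a tree to Nexus
#'
#' Emits a `#NEXUS` document with a TREES block containing one tree
#' statement whose Newick part follows the [write_newick()] contract.  No
#' TRANSLATE block is written (labels are inline); [read_nexus()] accepts
#' both forms.
#'
#' @inheritParams write_newick
#' @return The Nexus document as a character scalar.
#' @export
write_nexus <- function(tree, annotator = NULL, file = NULL) {
  out <- write_nexus_multi(list(tree), annotator)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# multi-tree Nexus document (used by the CLI)
write_nexus_multi <- function(trees, annotator = NULL) {
  stmts <- vapply(seq_along(trees), function(k) {
    paste0("tree TREE", k, " = ", write_newick(trees[[k]], annotator))
  }, character(1L))
  paste0("#NEXUS\nbegin trees;\n", paste(stmts, collapse = "\n"), "\nend;\n")
}
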