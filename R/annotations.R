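# Parsing and formatting of BEAST ("[&k=v,...]") and NHX
# ("[&&NHX:k=v:...]") annotation blocks.  Both dialects land in the same
# per-node annotation map: numeric-looking tokens become numbers, "{a,b}"
# becomes an ordered vector, quoted values keep their text verbatim.

# split a string on `sep` at top level (outside {...}, "..." and '...')
split_top_level <- function(s, sep) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  q <- ""  # active quote char or ""
  parts <- character(0)
  buf <- character(0)
  for (c in chars) {
    if (q != "") {
      buf <- c(buf, c)
      if (c == q) q <- ""
    } else if (c == '"' || c == "'") {
      q <- c
      buf <- c(buf, c)
    } else if (c == "{") {
      depth <- depth + 1L
      buf <- c(buf, c)
    } else if (c == "}") {
      depth <- depth - 1L
      buf <- c(buf, c)
    } else if (c == sep && depth == 0L) {
      parts <- c(parts, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, c)
    }
  }
  c(parts, paste(buf, collapse = ""))
}

# one scalar token -> number or text (quotes stripped)
parse_ann_scalar <- function(tok) {
  tok <- trimws(tok)
  if (nchar(tok) >= 2 &&
      ((startsWith(tok, '"') && endsWith(tok, '"')) ||
       (startsWith(tok, "'") && endsWith(tok, "'"))))
    return(substr(tok, 2L, nchar(tok) - 1L))
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num) && grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$",
                           tok))
    return(num)
  tok
}

parse_ann_value <- function(tok) {
  tok <- trimws(tok)
  if (startsWith(tok, "{") && endsWith(tok, "}")) {
    items <- split_top_level(substr(tok, 2L, nchar(tok) - 1L), ",")
    vals <- lapply(items, parse_ann_scalar)
    if (all(vapply(vals, is.numeric, logical(1L))))
      return(unlist(vals))
    return(vapply(vals, as.character, character(1L)))
  }
  parse_ann_scalar(tok)
}

# raw concatenated "[...]" blocks from the parser -> named annotation list
parse_annotation_blocks <- function(raw) {
  blocks <- regmatches(raw, gregexpr("\\[(?:[^][]|\\[[^][]*\\])*\\]",
                                     raw))[[1L]]
  out <- list()
  for (b in blocks) {
    inner <- substr(b, 2L, nchar(b) - 1L)
    if (startsWith(inner, "&&NHX:") || identical(inner, "&&NHX")) {
      body <- sub("^&&NHX:?", "", inner)
      if (!nzchar(body)) next
      items <- split_top_level(body, ":")
    } else if (startsWith(inner, "&")) {
      items <- split_top_level(substr(inner, 2L, nchar(inner)), ",")
    } else {
      next  # plain comment; parser should not have kept it
    }
    for (it in items) {
      it <- trimws(it)
      if (!nzchar(it)) next
      eq <- regexpr("=", it, fixed = TRUE)
      if (eq < 0) {
        out[[parse_key(it)]] <- TRUE  # bare flag
      } else {
        key <- parse_key(substr(it, 1L, eq - 1L))
        out[[key]] <- parse_ann_value(substr(it, eq + 1L, nchar(it)))
      }
    }
  }
  out
}

parse_key <- function(k) {
  k <- trimws(k)
  if (nchar(k) >= 2 &&
      ((startsWith(k, '"') && endsWith(k, '"')) ||
       (startsWith(k, "'") && endsWith(k, "'"))))
    k <- substr(k, 2L, nchar(k) - 1L)
  k
}

# ---------------------------------------------------------------------------
# writing
# ---------------------------------------------------------------------------

format_ann_scalar <- function(v, dialect) {
  if (is.numeric(v)) return(cpp_format_shortest(as.numeric(v)))
  if (is.logical(v)) return(ifelse(v, "true", "false"))
  if (!is.character(v)) stop("unrepresentable annotation value of class ",
                             paste(class(v), collapse = "/"))
  needs_quote <- grepl('[][,={}: ]', v)
  if (dialect == "nhx" && any(needs_quote))
    stop("annotation value not representable in NHX: ",
         v[needs_quote][1L])
  bad <- grepl('"', v)
  if (any(bad)) stop("annotation value contains a double quote: ", v[bad][1L])
  ifelse(needs_quote, paste0('"', v, '"'), v)
}

#' BEAST- and NHX-dialect annotation writers
#'
#' Annotation callbacks for [write_newick()] / [write_nexus()].  Given a
#' [node_data()] list they render the node's annotation map as a bracketed
#' block: `beast_annotation()` produces `[&k1=v1,k2={v2a,v2b}]` (placed
#' after the label, before the branch length), `nhx_annotation()` produces
#' `[&&NHX:k1=v1:k2=v2]` (placed after the branch length).  An empty map
#' yields an empty string.  Key order follows map insertion order.  Values
#' containing characters illegal in the dialect are quoted where the
#' dialect allows it and rejected with an error otherwise.
#'
#' @param node a [node_data()] list.
#' @return A character scalar (possibly empty).
#' @examples
#' t <- read_newick("(A[&rate=0.5]:1,B:2);")
#' write_newick(t, annotator = beast_annotation)
#' @export
beast_annotation <- function(node) {
  ann <- node$annotations
  if (!length(ann)) return("")
  keys <- names(ann)
  if (is.null(keys) || any(!nzchar(keys)))
    stop("annotation map must have non-empty names")
  frags <- vapply(seq_along(ann), function(i) {
    v <- format_ann_scalar(ann[[i]], "beast")
    val <- if (length(v) > 1L) paste0("{", paste(v, collapse = ","), "}")
           else v
    paste0(format_ann_key(keys[i]), "=", val)
  }, character(1L))
  paste0("[&", paste(frags, collapse = ","), "]")
}

#' @rdname beast_annotation
#' @export
nhx_annotation <- function(node) {
  ann <- node$annotations
  if (!length(ann)) return("")
  keys <- names(ann)
  if (is.null(keys) || any(!nzchar(keys)))
    stop("annotation map must have non-empty names")
  frags <- vapply(seq_along(ann), function(i) {
    v <- format_ann_scalar(ann[[i]], "nhx")
    if (length(v) > 1L)
      stop("vector annotation values are not representable in NHX: ",
           keys[i])
    paste0(format_ann_key(keys[i], nhx = TRUE), "=", v)
  }, character(1L))
  paste0("[&&NHX:", paste(frags, collapse = ":"), "]")
}
attr(beast_annotation, "placement") <- "before"
attr(nhx_annotation, "placement") <- "after"

format_ann_key <- function(k, nhx = FALSE) {
  if (grepl('[][,={}: ]', k)) {
    if (nhx) stop("annotation key not representable in NHX: ", k)
    return(paste0('"', k, '"'))
  }
  k
}
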