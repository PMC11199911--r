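# Independent test oracles: a deliberately simple recursive-descent Newick
# parser, brute-force MRCA, naive recursive imbalance indices, and a
# leaf-to-leaf path-length matrix.  These stay separate from the package's
# iterative implementations so the two routes can be compared.

# --- recursive-descent Newick parser (oracle) ------------------------------

rd_parse_newick <- function(text) {
  env <- new.env(parent = emptyenv())
  env$s <- text
  env$i <- 1L
  env$n <- nchar(text)

  peek <- function() if (env$i > env$n) "" else substr(env$s, env$i, env$i)
  adv <- function() env$i <- env$i + 1L
  skip_ws <- function() {
    while (env$i <= env$n && grepl("[[:space:]]", peek())) adv()
  }
  read_block <- function() {
    start <- env$i
    depth <- 0L
    repeat {
      c <- peek()
      if (c == "") stop("oracle: unterminated comment")
      if (c == "[") depth <- depth + 1L
      if (c == "]") depth <- depth - 1L
      adv()
      if (depth == 0L) break
    }
    substr(env$s, start, env$i - 1L)
  }
  read_quoted <- function() {
    adv()  # opening '
    out <- character(0)
    repeat {
      c <- peek()
      if (c == "") stop("oracle: unterminated quote")
      if (c == "'") {
        adv()
        if (peek() == "'") {
          out <- c(out, "'")
          adv()
        } else break
      } else {
        out <- c(out, c)
        adv()
      }
    }
    paste(out, collapse = "")
  }
  read_number <- function() {
    rest <- substr(env$s, env$i, env$n)
    m <- regmatches(rest,
      regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest))
    if (!length(m) || !nzchar(m)) stop("oracle: expected number")
    env$i <- env$i + nchar(m)
    as.numeric(m)
  }

  parse_node <- function() {
    nd <- list(label = NA_character_, length = NA_real_,
               children = list(), ann_raw = "", hybrid = NA_character_)
    skip_ws()
    if (peek() == "(") {
      adv()
      repeat {
        nd$children[[length(nd$children) + 1L]] <- parse_node()
        skip_ws()
        if (peek() == ",") adv() else break
      }
      skip_ws()
      if (peek() != ")") stop("oracle: expected ')'")
      adv()
    }
    repeat {
      skip_ws()
      c <- peek()
      if (c == "[") {
        b <- read_block()
        if (startsWith(b, "[&")) nd$ann_raw <- paste0(nd$ann_raw, b)
      } else if (c == "'") {
        nd$label <- read_quoted()
      } else if (c == ":") {
        adv()
        repeat {
          skip_ws()
          if (peek() == "[") {
            b <- read_block()
            if (startsWith(b, "[&")) nd$ann_raw <- paste0(nd$ann_raw, b)
          } else break
        }
        nd$length <- read_number()
      } else if (c %in% c(",", ")", ";", "")) {
        break
      } else {
        rest <- substr(env$s, env$i, env$n)
        m <- regmatches(rest, regexpr("^[^][(){}:;,='[:space:]]+", rest))
        if (!length(m) || !nzchar(m)) stop("oracle: unexpected character ", c)
        env$i <- env$i + nchar(m)
        if (grepl("#", m, fixed = TRUE)) {
          parts <- strsplit(m, "#", fixed = TRUE)[[1L]]
          if (nzchar(parts[1L])) nd$label <- parts[1L]
          nd$hybrid <- parts[2L]
        } else {
          nd$label <- m
        }
      }
    }
    nd
  }

  root <- parse_node()
  skip_ws()
  if (peek() != ";") stop("oracle: expected ';'")
  root
}

# flatten the oracle's nested node to pre-order vectors (its own recursion,
# independent of the package's builders)
oracle_flatten <- function(root) {
  acc <- new.env(parent = emptyenv())
  acc$parent <- integer(0)
  acc$label <- character(0)
  acc$len <- numeric(0)
  acc$ann <- list()
  acc$hyb <- character(0)
  rec <- function(nd, p) {
    id <- length(acc$parent) + 1L
    acc$parent[id] <- p
    acc$label[id] <- nd$label
    acc$len[id] <- nd$length
    acc$ann[id] <- list(if (nzchar(nd$ann_raw))
      treekit:::parse_annotation_blocks(nd$ann_raw) else NULL)
    acc$hyb[id] <- nd$hybrid
    for (ch in nd$children) rec(ch, id)
  }
  rec(root, NA_integer_)
  acc
}

expect_matches_oracle <- function(tree, text) {
  o <- oracle_flatten(rd_parse_newick(text))
  expect_identical(tree$parent, o$parent)
  expect_identical(tree$label, o$label)
  # R's as.numeric and C's strtod can disagree by one ulp on 17-digit
  # decimals, so the oracle's lengths are compared to near machine precision
  expect_equal(tree$length, o$len, tolerance = 1e-14)
  expect_identical(tree$hybrid, o$hyb)
  expect_identical(tree$annotation, o$ann)
}

# --- structural comparison --------------------------------------------------

expect_tree_equal <- function(t1, t2) {
  expect_identical(t1$parent, t2$parent)
  expect_identical(t1$label, t2$label)
  expect_identical(t1$length, t2$length)
  expect_identical(t1$hybrid, t2$hybrid)
  norm <- function(a) lapply(a, function(x) if (length(x)) x else NULL)
  expect_identical(norm(t1$annotation), norm(t2$annotation))
}

# --- brute-force MRCA: intersect ancestor sets, pick maximum depth ---------

mrca_oracle <- function(tree, ids) {
  anc_incl <- lapply(ids, function(v) c(v, get_ancestors(tree, v)))
  common <- Reduce(intersect, anc_incl)
  common[which.max(node_depths(tree)[common])]
}

# --- naive recursive imbalance indices -------------------------------------

sackin_oracle <- function(tree) {
  ch <- treekit:::children_list(tree$parent)
  rec <- function(v, depth) {
    if (!length(ch[[v]])) return(depth)
    sum(vapply(ch[[v]], rec, numeric(1L), depth = depth + 1L))
  }
  rec(1L, 0L)
}

colless_oracle <- function(tree) {
  ch <- treekit:::children_list(tree$parent)
  nl <- function(v) {
    if (!length(ch[[v]])) return(1L)
    sum(vapply(ch[[v]], nl, integer(1L)))
  }
  rec <- function(v) {
    if (!length(ch[[v]])) return(0L)
    stopifnot(length(ch[[v]]) == 2L)
    abs(nl(ch[[v]][1L]) - nl(ch[[v]][2L])) + rec(ch[[v]][1L]) +
      rec(ch[[v]][2L])
  }
  rec(1L)
}

# --- all-pairs leaf path lengths, keyed by sorted labels -------------------

leaf_dist_matrix <- function(tree) {
  n <- n_nodes(tree)
  d <- numeric(n)
  if (n > 1L) for (i in 2:n) d[i] <- d[tree$parent[i]] + tree$length[i]
  lv <- leaf_ids(tree)
  labs <- tree$label[lv]
  ord <- order(labs)
  lv <- lv[ord]
  labs <- labs[ord]
  k <- length(lv)
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a < b) {
        anc <- get_mrca(tree, c(lv[a], lv[b]))
        m[a, b] <- m[b, a] <- d[lv[a]] + d[lv[b]] - 2 * d[anc]
      }
    }
  }
  m
}
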