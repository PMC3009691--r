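# Pattern computation: conserved columns of a multiple alignment become a
# deterministic PROSITE-syntax pattern attached to a tree node and its EC
# set. A pattern is an ordered list of elements:
#   LITERAL  one residue           (fully conserved column, "star")
#   CLASS    a set of residues     (strongly conserved column, "colon")
#   GAP      x(min,max) wildcards  (runs of unconserved columns)

# ClustalW strong groups: a gap-free column whose residue set lies inside
# one of these is "strongly conserved" (colon).
STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                   "MILV", "MILF", "HY", "FYW")

MIN_CONSERVED_POSITIONS <- 8L
MAX_NODE_SEQUENCES <- 1000L

#' Classify alignment columns by conservation
#'
#' A column is `STAR` when all rows carry the same residue and none has a
#' gap; `COLON` when it is gap-free and its residue set is contained in
#' one of the ClustalW strong groups ([STRONG_GROUPS]); otherwise `NONE`.
#' Weakly conserved ("period") columns are deliberately not used.
#'
#' @param msa named character vector of equal-length aligned rows (>= 2).
#' @return data.frame with `column`, `class` (`STAR`/`COLON`/`NONE`) and
#'   `residues` (collapsed observed residue set, gaps excluded).
#' @export
conservation_classes <- function(msa) {
  stopifnot(length(msa) >= 2L)
  if (length(unique(nchar(msa))) != 1L) stop("ragged alignment rows")
  mat <- do.call(rbind, strsplit(msa, ""))
  ncol_ <- ncol(mat)
  cls <- character(ncol_); res <- character(ncol_)
  groups <- lapply(STRONG_GROUPS, function(g) strsplit(g, "")[[1]])
  for (j in seq_len(ncol_)) {
    col <- mat[, j]
    u <- unique(col)
    has_gap <- "-" %in% u
    res[j] <- paste(sort(setdiff(u, "-")), collapse = "")
    if (!has_gap && length(u) == 1L) {
      cls[j] <- "STAR"
    } else if (!has_gap &&
               any(vapply(groups, function(g) all(u %in% g), logical(1)))) {
      cls[j] <- "COLON"
    } else {
      cls[j] <- "NONE"
    }
  }
  data.frame(column = seq_len(ncol_), class = cls, residues = res,
             stringsAsFactors = FALSE)
}

pattern_rejection <- function(reason) {
  structure(list(reason = reason), class = "pattern_rejection")
}

#' Was a pattern attempt rejected?
#'
#' [build_pattern()] returns a `pattern_rejection` (carrying the reason,
#' e.g. too few conserved columns or failed self-recognition) instead of
#' a pattern when the alignment cannot support one.
#'
#' @param x result of [build_pattern()].
#' @return logical scalar.
#' @export
is_rejected <- function(x) inherits(x, "pattern_rejection")

new_pattern <- function(elements, ec_set, source, span = NA_integer_) {
  n_conserved <- sum(elements$type != "GAP")
  structure(list(elements = elements, ec_set = sort(unique(ec_set)),
                 source = source, n_conserved = n_conserved, span = span),
            class = "enz_pattern")
}

element_row <- function(type, residues = NA_character_,
                        min = NA_integer_, max = NA_integer_) {
  data.frame(type = type, residues = residues, min = min, max = max,
             stringsAsFactors = FALSE)
}

#' Build a pattern from a multiple alignment
#'
#' STAR columns become literals, COLON columns become residue classes
#' holding the *observed* residue set (tighter than the whole strong
#' group), and each maximal run of unconserved columns between two
#' conserved ones becomes a gap element `x(min,max)` where min/max are
#' the fewest/most residues any row places in that run. The pattern is
#' trimmed to the first..last conserved column; it is rejected when fewer
#' than `min_conserved` positions are conserved (a pattern covering so
#' few positions has no discriminative value).
#'
#' @param msa named character vector of aligned rows (>= 2).
#' @param ec_set EC numbers to attach to the pattern.
#' @param source list describing provenance, e.g.
#'   `list(kind = "node", tree_id =, node_id =)`.
#' @param min_conserved minimum number of conserved positions.
#' @return an `enz_pattern`, or a `pattern_rejection` object (a list
#'   with a `reason` string) when rejected; see [is_rejected()].
#' @export
build_pattern <- function(msa, ec_set, source = list(kind = "node"),
                          min_conserved = MIN_CONSERVED_POSITIONS) {
  cons <- conservation_classes(msa)
  keep <- which(cons$class != "NONE")
  if (length(keep) == 0L)
    return(pattern_rejection("no conserved columns"))
  if (length(keep) < min_conserved)
    return(pattern_rejection(sprintf("only %d conserved positions (< %d)",
                                     length(keep), min_conserved)))
  mat <- do.call(rbind, strsplit(msa, ""))
  els <- list()
  prev <- NULL
  for (j in keep) {
    if (!is.null(prev) && j > prev + 1L) {
      run <- (prev + 1L):(j - 1L)
      counts <- rowSums(mat[, run, drop = FALSE] != "-")
      if (max(counts) > 0L)
        els[[length(els) + 1L]] <- element_row("GAP", min = min(counts),
                                               max = max(counts))
    }
    if (cons$class[j] == "STAR")
      els[[length(els) + 1L]] <- element_row("LITERAL",
                                             residues = cons$residues[j])
    else
      els[[length(els) + 1L]] <- element_row("CLASS",
                                             residues = cons$residues[j])
    prev <- j
  }
  pat <- new_pattern(do.call(rbind, els), ec_set, source,
                     span = keep[length(keep)] - keep[1L] + 1L)
  pat
}

#' Exact-sequence pattern for an unclustered record
#'
#' Unclustered sequences are represented by their full sequence as an
#' all-literal pattern, so an exact (substring) match of a query is still
#' possible and the enzyme's information is not lost.
#'
#' @param record one-row record data.frame (or list with `id`,
#'   `sequence`, `ec`).
#' @return an `enz_pattern`.
#' @export
exact_sequence_pattern <- function(record) {
  id <- if (is.data.frame(record)) record$id[1] else record$id
  seq <- if (is.data.frame(record)) record$sequence[1] else record$sequence
  ecs <- if (is.data.frame(record)) record$ec[[1]] else record$ec
  ch <- strsplit(seq, "")[[1]]
  els <- data.frame(type = "LITERAL", residues = ch,
                    min = NA_integer_, max = NA_integer_,
                    stringsAsFactors = FALSE)
  new_pattern(els, ecs, list(kind = "exact", record_id = id),
              span = length(ch))
}

#' Format a pattern as PROSITE text
#'
#' Elements joined by `-`: a literal residue, `[residues]` for a class,
#' `x` / `x(n)` / `x(n,m)` for gaps; terminated by `.`.
#'
#' @param pattern an `enz_pattern`.
#' @return single string, e.g. `"G-K-[ST]-x(2,4)-A."`.
#' @export
pattern_format <- function(pattern) {
  el <- pattern$elements
  toks <- vapply(seq_len(nrow(el)), function(i) {
    switch(el$type[i],
      LITERAL = el$residues[i],
      CLASS = paste0("[", el$residues[i], "]"),
      GAP = if (el$min[i] == 1L && el$max[i] == 1L) "x"
            else if (el$min[i] == el$max[i]) sprintf("x(%d)", el$min[i])
            else sprintf("x(%d,%d)", el$min[i], el$max[i]))
  }, character(1))
  paste0(paste(toks, collapse = "-"), ".")
}

#' Parse PROSITE pattern text
#'
#' Inverse of [pattern_format()].
#'
#' @param text pattern string.
#' @param ec_set,source optional metadata to attach.
#' @return an `enz_pattern`.
#' @export
pattern_parse <- function(text, ec_set = character(0),
                          source = list(kind = "parsed")) {
  s <- sub("\\.\\s*$", "", trimws(text))
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  els <- lapply(toks, function(tk) {
    if (grepl("^[A-Z]$", tk)) return(element_row("LITERAL", residues = tk))
    if (grepl("^\\[[A-Z]+\\]$", tk))
      return(element_row("CLASS",
        residues = paste(sort(strsplit(gsub("[][]", "", tk), "")[[1]]),
                         collapse = "")))
    if (tk == "x") return(element_row("GAP", min = 1L, max = 1L))
    m <- regmatches(tk, regexec("^x\\((\\d+)(?:,(\\d+))?\\)$", tk))[[1]]
    if (length(m)) {
      mn <- as.integer(m[2])
      mx <- if (nzchar(m[3])) as.integer(m[3]) else mn
      return(element_row("GAP", min = mn, max = mx))
    }
    stop("cannot parse pattern token: ", tk)
  })
  new_pattern(do.call(rbind, els), ec_set, source)
}

#' @export
print.enz_pattern <- function(x, ...) {
  cat(sprintf("<pattern: %d conserved positions, EC {%s}>\n %s\n",
              x$n_conserved, paste(x$ec_set, collapse = ", "),
              pattern_format(x)))
  invisible(x)
}

#' Match a pattern against a sequence
#'
#' Unanchored substring semantics: a literal matches its residue, a class
#' any of its residues, a gap `x(min,max)` between min and max arbitrary
#' residues. The pattern is compiled to a regular expression; only the
#' first occurrence is reported.
#'
#' @param pattern an `enz_pattern`.
#' @param sequence character vector of sequences.
#' @return logical vector; attribute `"match"` holds a data.frame of
#'   first-match `start`/`end` (NA where unmatched).
#' @export
pattern_match <- function(pattern, sequence) {
  re <- pattern_regex(pattern)
  m <- regexpr(re, sequence, perl = TRUE)
  hit <- m != -1L
  res <- hit
  attr(res, "match") <- data.frame(
    start = ifelse(hit, as.integer(m), NA_integer_),
    end = ifelse(hit, as.integer(m) + attr(m, "match.length") - 1L,
                 NA_integer_))
  res
}

pattern_regex <- function(pattern) {
  el <- pattern$elements
  paste(vapply(seq_len(nrow(el)), function(i) {
    switch(el$type[i],
      LITERAL = el$residues[i],
      CLASS = paste0("[", el$residues[i], "]"),
      GAP = if (el$min[i] == el$max[i]) sprintf(".{%d}", el$min[i])
            else sprintf(".{%d,%d}", el$min[i], el$max[i]))
  }, character(1)), collapse = "")
}

#' Check that a pattern recognizes all of its input sequences
#'
#' Guards against alignment artifacts: a kept pattern must match every
#' member sequence it was built from, otherwise it is rejected.
#'
#' @param pattern an `enz_pattern`.
#' @param sequences character vector of the source-node member sequences.
#' @return logical scalar.
#' @export
self_recognition <- function(pattern, sequences) {
  all(pattern_match(pattern, sequences))
}

#' Qualified nodes of a tree, in breadth-first top-down order
#'
#' A node qualifies for pattern computation when it is the root or its EC
#' set is strictly smaller than its parent's (the associated function
#' became more resolved), it has fewer than `max_members` member
#' sequences, and it is an internal node (single-sequence leaves are
#' handled by exact-sequence patterns for singleton trees only).
#'
#' @param tree a tree from an `enz_forest`.
#' @param max_members node-size cap (default 1000).
#' @return integer vector of node ids.
#' @export
qualified_nodes <- function(tree, max_members = MAX_NODE_SEQUENCES) {
  if (tree$singleton) return(integer(0))
  out <- integer(0)
  queue <- tree$root
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    nd <- tree$nodes[[as.character(id)]]
    if (is.na(nd$left)) next                     # leaf
    queue <- c(queue, nd$left, nd$right)
    big <- length(nd$members) >= max_members
    if (big) next
    if (id == tree$root) {
      out <- c(out, id)
    } else {
      par <- tree$nodes[[as.character(nd$parent)]]
      if (length(nd$ec_set) < length(par$ec_set)) out <- c(out, id)
    }
  }
  out
}

#' Fraction of pattern-covered enzymes in a tree
#'
#' The fraction of the tree's member records that belong to at least one
#' node holding a valid pattern ("%pce").
#'
#' @param tree a tree (with `pattern_id` set on pattern-bearing nodes).
#' @return numeric in `[0, 1]`.
#' @export
pce <- function(tree) {
  covered <- character(0)
  for (nd in tree$nodes)
    if (!is.na(nd$pattern_id)) covered <- union(covered, nd$members)
  length(intersect(covered, tree$members)) / length(tree$members)
}

# Attempt a pattern at one node; returns the pattern or NULL (with reason).
attempt_node_pattern <- function(tree, node_id, records, msa_fun,
                                 min_conserved = MIN_CONSERVED_POSITIONS) {
  nd <- tree$nodes[[as.character(node_id)]]
  seqs <- records$sequence[match(nd$members, records$id)]
  names(seqs) <- nd$members
  msa <- msa_fun(seqs)
  pat <- build_pattern(msa, nd$ec_set,
                       source = list(kind = "node", tree_id = tree$tree_id,
                                     node_id = node_id),
                       min_conserved = min_conserved)
  if (is_rejected(pat)) return(pat)
  if (!self_recognition(pat, seqs))
    return(pattern_rejection("failed self-recognition"))
  pat
}

#' Compute patterns for every tree of a forest
#'
#' For each multi-leaf tree, patterns are attempted top-down at all
#' qualified nodes ([qualified_nodes()]). If afterwards the fraction of
#' pattern-covered enzymes ([pce()]) is below `pce_threshold`, more
#' patterns are added iteratively: among internal nodes without a pattern
#' that were not tried before (and below the node-size cap), all nodes
#' sharing the current worst (highest) merge E-value are attempted in one
#' iteration; the loop stops when the threshold is reached or candidates
#' are exhausted. Singleton trees get an exact-sequence pattern.
#'
#' @param forest an `enz_forest`.
#' @param records deduplicated enzyme records.
#' @param pce_threshold coverage target in `[0, 1]` (default 0.9).
#' @param msa_fun multiple-alignment provider (default
#'   [center_star_msa()]).
#' @param max_members node-size cap.
#' @param min_conserved minimum conserved positions per pattern.
#' @return list with `forest` (nodes annotated with `pattern_id`),
#'   `patterns` (named list of `enz_pattern`), and `failures`
#'   (data.frame of tried-but-failed nodes with reasons).
#' @export
compute_patterns <- function(forest, records, pce_threshold = 0.9,
                             msa_fun = center_star_msa,
                             max_members = MAX_NODE_SEQUENCES,
                             min_conserved = MIN_CONSERVED_POSITIONS) {
  patterns <- list()
  failures <- list()
  next_id <- 1L
  for (ti in seq_along(forest$trees)) {
    tree <- forest$trees[[ti]]
    if (tree$singleton) {
      rec <- records[match(tree$members, records$id), , drop = FALSE]
      pat <- exact_sequence_pattern(rec)
      pid <- sprintf("P%05d", next_id); next_id <- next_id + 1L
      patterns[[pid]] <- pat
      tree$nodes[[as.character(tree$root)]]$pattern_id <- pid
      forest$trees[[ti]] <- tree
      next
    }
    try_nodes <- function(node_ids) {
      for (id in node_ids) {
        key <- as.character(id)
        tree$nodes[[key]]$tried <<- TRUE
        pat <- attempt_node_pattern(tree, id, records, msa_fun, min_conserved)
        if (is_rejected(pat)) {
          failures[[length(failures) + 1L]] <<- data.frame(
            tree_id = tree$tree_id, node_id = id,
            reason = pat$reason,
            stringsAsFactors = FALSE)
        } else {
          pid <- sprintf("P%05d", next_id); next_id <<- next_id + 1L
          patterns[[pid]] <<- pat
          tree$nodes[[key]]$pattern_id <<- pid
        }
      }
    }
    try_nodes(qualified_nodes(tree, max_members))
    # iterative coverage loop over untried internal nodes
    repeat {
      if (pce(tree) >= pce_threshold) break
      cand <- Filter(function(nd) {
        !is.na(nd$left) && !nd$tried && is.na(nd$pattern_id) &&
          length(nd$members) < max_members
      }, tree$nodes)
      if (length(cand) == 0L) break
      evs <- vapply(cand, `[[`, numeric(1), "merge_evalue")
      worst <- evs == max(evs)
      try_nodes(vapply(cand[worst], `[[`, integer(1), "node_id"))
    }
    forest$trees[[ti]] <- tree
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(tree_id = integer(0), node_id = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(forest = forest, patterns = patterns, failures = failures)
}

#' Write / read a pattern table
#'
#' TSV with columns `pattern_id`, `tree_id`, `node_id`, `ec_list`,
#' `n_conserved`, `pattern_text`.
#'
#' @param patterns named list of `enz_pattern`.
#' @param path TSV path.
#' @return invisibly (write) / a named pattern list (read).
#' @export
write_patterns <- function(patterns, path) {
  tab <- data.frame(
    pattern_id = names(patterns),
    tree_id = vapply(patterns, function(p) p$source$tree_id %||% NA_integer_,
                     integer(1)),
    node_id = vapply(patterns, function(p) p$source$node_id %||% NA_integer_,
                     integer(1)),
    ec_list = vapply(patterns, function(p) paste(p$ec_set, collapse = ";"), ""),
    n_conserved = vapply(patterns, `[[`, integer(1), "n_conserved"),
    pattern_text = vapply(patterns, pattern_format, ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    src <- if (is.na(tab$tree_id[i])) list(kind = "exact") else
      list(kind = "node", tree_id = tab$tree_id[i], node_id = tab$node_id[i])
    ecs <- if (nzchar(tab$ec_list[i]))
      strsplit(tab$ec_list[i], ";", fixed = TRUE)[[1]] else character(0)
    pattern_parse(tab$pattern_text[i], ec_set = ecs, source = src)
  })
  stats::setNames(pats, tab$pattern_id)
}
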