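# Independent reference implementations used to cross-check the package:
# a from-scratch complete-linkage oracle that recomputes every
# inter-cluster distance from the leaf matrix, and a recursive
# enumeration matcher for PROSITE patterns. Both are deliberately naive.

# ---- complete-linkage oracle -------------------------------------------

# distances: data.frame(id_a, id_b, evalue); returns list of merge events
# (members_a, members_b, height) and the final partition (list of sorted
# member vectors).
oracle_complete_linkage <- function(distances, ids, cutoff = 1e-3) {
  D <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(distances)) {
    D[cbind(distances$id_a, distances$id_b)] <- distances$evalue
    D[cbind(distances$id_b, distances$id_a)] <- distances$evalue
  }
  clusters <- as.list(ids)
  merges <- list()
  repeat {
    if (length(clusters) < 2L) break
    # recompute all inter-cluster max distances from scratch
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (!is.finite(d) || d > cutoff) next
        mi <- min(clusters[[i]]); mj <- min(clusters[[j]])
        key <- c(min(mi, mj), max(mi, mj))
        if (is.null(best) || d < best$d ||
            (d == best$d && (key[1] < best$key[1] ||
                             (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    if (is.null(best)) break
    merges[[length(merges) + 1L]] <- list(
      members_a = sort(clusters[[best$i]]),
      members_b = sort(clusters[[best$j]]),
      height = best$d)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(merges = merges,
       partition = sort(vapply(clusters,
                               function(m) paste(sort(m), collapse = ","),
                               character(1))))
}

# Signature of a forest comparable to the oracle output: internal-node
# (sorted child member sets + height) triples and the tree partition.
forest_signature <- function(forest) {
  sig <- list()
  for (tr in forest$trees) {
    for (nd in tr$nodes) {
      if (is.na(nd$left)) next
      l <- tr$nodes[[as.character(nd$left)]]$members
      r <- tr$nodes[[as.character(nd$right)]]$members
      ab <- sort(c(paste(sort(l), collapse = ","),
                   paste(sort(r), collapse = ",")))
      sig[[length(sig) + 1L]] <- sprintf("%s|%s|%.17g", ab[1], ab[2],
                                         nd$merge_evalue)
    }
  }
  list(merges = sort(as.character(unlist(sig))),
       partition = sort(vapply(forest$trees,
                               function(t) paste(sort(t$members), collapse = ","),
                               character(1))))
}

oracle_signature <- function(or) {
  sig <- vapply(or$merges, function(m) {
    ab <- sort(c(paste(m$members_a, collapse = ","),
                 paste(m$members_b, collapse = ",")))
    sprintf("%s|%s|%.17g", ab[1], ab[2], m$height)
  }, character(1))
  list(merges = sort(sig), partition = or$partition)
}

random_distances <- function(n, density = 0.7) {
  ids <- sprintf("s%02d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < density
  data.frame(id_a = pairs[1, keep], id_b = pairs[2, keep],
             evalue = 10^stats::runif(sum(keep), -60, 0),
             stringsAsFactors = FALSE)
}

# ---- brute-force pattern matcher ---------------------------------------

oracle_match <- function(pattern, sequence) {
  el <- pattern$elements
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  match_from <- function(e, i) {
    if (e > nrow(el)) return(TRUE)
    if (i > n + 1L) return(FALSE)
    switch(el$type[e],
      LITERAL = i <= n && ch[i] == el$residues[e] && match_from(e + 1L, i + 1L),
      CLASS = i <= n && ch[i] %in% strsplit(el$residues[e], "")[[1]] &&
        match_from(e + 1L, i + 1L),
      GAP = {
        ok <- FALSE
        for (k in el$min[e]:el$max[e]) {
          if (i + k > n + 1L) break
          if (match_from(e + 1L, i + k)) { ok <- TRUE; break }
        }
        ok
      })
  }
  any(vapply(seq_len(max(n, 1L)), function(s) match_from(1L, s), logical(1)))
}

random_pattern <- function(max_elements = 20L) {
  n <- sample(1:max_elements, 1)
  types <- sample(c("LITERAL", "CLASS", "GAP"), n, replace = TRUE,
                  prob = c(0.5, 0.25, 0.25))
  # no leading/trailing gap
  types[1] <- sample(c("LITERAL", "CLASS"), 1)
  types[n] <- sample(c("LITERAL", "CLASS"), 1)
  els <- do.call(rbind, lapply(types, function(tp) {
    if (tp == "LITERAL")
      data.frame(type = tp, residues = sample(enzpat:::AA20, 1),
                 min = NA_integer_, max = NA_integer_)
    else if (tp == "CLASS")
      data.frame(type = tp,
                 residues = paste(sort(sample(enzpat:::AA20,
                                              sample(2:4, 1))), collapse = ""),
                 min = NA_integer_, max = NA_integer_)
    else {
      mn <- sample(0:3, 1)
      data.frame(type = tp, residues = NA_character_, min = mn,
                 max = mn + sample(0:3, 1))
    }
  }))
  pattern_parse(enzpat::pattern_format(
    structure(list(elements = els, ec_set = character(0),
                   source = list(kind = "test"),
                   n_conserved = sum(els$type != "GAP")),
              class = "enz_pattern")))
}

random_sequence <- function(len) {
  paste(sample(enzpat:::AA20, len, replace = TRUE), collapse = "")
}
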