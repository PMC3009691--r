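# Pattern verification: every pattern is searched against the whole
# non-redundant database (all three groups) and each match is scored
# with the EC calculus. TP and FP counts give the pattern's specificity,
# which drives the selection of the strict and loose pattern sets.

#' Score one pattern/record match
#'
#' The record must already match the pattern. Matches on non-enzyme
#' records are false positives (the pattern claims a function the record
#' does not have); matches on putative records are neutral (`NA`) since
#' no safe assignment is possible; matches on enzymes are scored by the
#' EC-set calculus ([ec_set_relation()]).
#'
#' @param pattern an `enz_pattern`.
#' @param record one-row record data.frame (or list with `group`, `ec`).
#' @return `"TP"`, `"FP"` or `"NA"`.
#' @export
score_hit <- function(pattern, record) {
  grp <- if (is.data.frame(record)) record$group[1] else record$group
  switch(grp,
    NON_ENZYME = "FP",
    PUTATIVE = "NA",
    ENZYME = {
      ecs <- if (is.data.frame(record)) record$ec[[1]] else record$ec
      ec_set_relation(pattern$ec_set, ecs)
    },
    stop("unknown group: ", grp))
}

#' Verify all patterns against the database
#'
#' Matches each pattern against every (deduplicated) record; each
#' (pattern, record) pair contributes at most one verdict. Specificity is
#' `tp / (tp + fp)`, defined as 1.0 when `tp + fp = 0` (only neutral
#' evidence, no counterevidence).
#'
#' @param patterns named list of `enz_pattern`.
#' @param records classified, deduplicated records (all groups).
#' @return data.frame with `pattern_id`, `tp`, `fp`, `na`, `specificity`.
#' @export
verify_patterns <- function(patterns, records) {
  out <- lapply(names(patterns), function(pid) {
    p <- patterns[[pid]]
    hit <- pattern_match(p, records$sequence)
    tp <- 0L; fp <- 0L; na <- 0L
    for (i in which(hit)) {
      v <- score_hit(p, records[i, ])
      if (v == "TP") tp <- tp + 1L
      else if (v == "FP") fp <- fp + 1L
      else na <- na + 1L
    }
    data.frame(pattern_id = pid, tp = tp, fp = fp, na = na,
               specificity = if (tp + fp == 0L) 1.0 else tp / (tp + fp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select the strict and loose pattern sets
#'
#' The *strict* set holds patterns with specificity 1.0 (no false
#' positives in verification) whose EC numbers all lie in the same
#' sub-subclass, excluding patterns whose EC set is exactly one
#' unresolved EC (e.g. `{1.1.1.-}`). The *loose* set additionally admits
#' every pattern with specificity of at least `loose_min_specificity`,
#' with no constraint on EC structure; the strict set is always a subset
#' of the loose set.
#'
#' @param stats verification table from [verify_patterns()].
#' @param patterns the named pattern list.
#' @param loose_min_specificity specificity floor of the loose set.
#' @return the stats table with logical columns `in_strict`, `in_loose`.
#' @export
select_pattern_sets <- function(stats, patterns,
                                loose_min_specificity = 0.75) {
  strict_ok <- vapply(stats$pattern_id, function(pid) {
    p <- patterns[[pid]]
    ecs <- p$ec_set
    if (length(ecs) == 0L) return(FALSE)
    lv <- ec_levels(ecs)
    if (length(ecs) == 1L && anyNA(lv)) return(FALSE)  # single unresolved EC
    ss <- ec_sub_subclass(ecs)
    !anyNA(ss) && length(unique(ss)) == 1L
  }, logical(1))
  stats$in_strict <- stats$specificity == 1.0 & strict_ok
  stats$in_loose <- stats$in_strict |
    stats$specificity >= loose_min_specificity
  stats
}

#' Write the verification report
#'
#' @param stats table from [select_pattern_sets()].
#' @param path TSV path.
#' @export
write_verification <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
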