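# Annotation harness: search query proteomes with a pattern set and
# evaluate the predicted EC numbers against a standard-of-truth (SOT)
# list for the organism.

#' Search query sequences with a pattern set
#'
#' Every (query, matching pattern) pair yields one prediction carrying
#' the pattern's EC set; patterns are deterministic, so there is no score
#' thresholding.
#'
#' @param queries named character vector of protein sequences, or a path
#'   to a FASTA file.
#' @param patterns named list of `enz_pattern`.
#' @return data.frame with `query_id`, `pattern_id`, `ec_list`
#'   (semicolon-separated).
#' @export
search_sequences <- function(queries, patterns) {
  if (is.character(queries) && length(queries) == 1L && file.exists(queries)) {
    ss <- Biostrings::readAAStringSet(queries)
    queries <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  stopifnot(!is.null(names(queries)))
  rows <- list()
  for (pid in names(patterns)) {
    hit <- pattern_match(patterns[[pid]], queries)
    for (i in which(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(queries)[i], pattern_id = pid,
        ec_list = paste(patterns[[pid]]$ec_set, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query_id = character(0), pattern_id = character(0),
                      ec_list = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read a standard-of-truth EC list
#'
#' Plain text, one EC number per line; `#` starts a comment.
#'
#' @param path file path.
#' @return character vector of EC numbers.
#' @export
read_sot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  ecs <- lines[nzchar(lines)]
  stopifnot(all(ec_is_valid(ecs)))
  unique(ecs)
}

#' Compare predictions to a standard of truth
#'
#' Each predicted EC number is compared to the SOT with the asymmetric EC
#' calculus (prediction in the pattern role): a TP relation with a SOT EC
#' counts that SOT EC as identified (each SOT EC at most once, duplicate
#' predictions ignored). A predicted EC with no TP relation that agrees
#' with some SOT EC on the first three levels scores a sub-subclass hit
#' instead (each sub-subclass at most once) — this is also how unresolved
#' predicted ECs like `1.1.1.-` contribute.
#'
#' @param predictions data.frame from [search_sequences()], or a
#'   character vector of predicted EC numbers.
#' @param sot character vector of SOT EC numbers (nonempty).
#' @return list with `tp_ecs`, `sub_subclass_hits`, `sensitivity`
#'   (`|tp_ecs| / |SOT|`) and `sensitivity_with_subsub`
#'   (`(|tp_ecs| + |sub_subclass_hits|) / |SOT|`).
#' @export
compare_to_sot <- function(predictions, sot) {
  if (length(sot) == 0L) stop("empty standard of truth")
  sot <- unique(sot)
  pred_ecs <- if (is.data.frame(predictions)) {
    unique(unlist(strsplit(predictions$ec_list, ";", fixed = TRUE)))
  } else unique(as.character(predictions))
  pred_ecs <- pred_ecs[!is.na(pred_ecs) & nzchar(pred_ecs)]
  tp_ecs <- character(0)
  subsub <- character(0)
  for (p in pred_ecs) {
    tp_here <- sot[vapply(sot, function(t) ec_pair_relation(p, t) == "TP",
                          logical(1))]
    if (length(tp_here)) {
      tp_ecs <- union(tp_ecs, tp_here)
    } else {
      pss <- ec_sub_subclass(p)
      if (is.na(pss)) next
      hit_ss <- stats::na.omit(ec_sub_subclass(sot))
      if (pss %in% hit_ss) subsub <- union(subsub, pss)
    }
  }
  list(tp_ecs = sort(tp_ecs),
       sub_subclass_hits = sort(subsub),
       sensitivity = length(tp_ecs) / length(sot),
       sensitivity_with_subsub =
         (length(tp_ecs) + length(subsub)) / length(sot))
}

#' Unique and common true-positive contributions of two methods
#'
#' Evaluates both prediction sets against the same SOT and splits the
#' union of identified SOT ECs into the percentage found only by method
#' 1, only by method 2, and by both.
#'
#' @param pred_1,pred_2 prediction data.frames (or EC vectors) for the
#'   two methods.
#' @param sot SOT EC vector.
#' @return named numeric vector `c(pct_only_1, pct_only_2, pct_both)`,
#'   summing to 100 (all zero when neither method identifies anything).
#' @export
contribution_split <- function(pred_1, pred_2, sot) {
  h1 <- compare_to_sot(pred_1, sot)$tp_ecs
  h2 <- compare_to_sot(pred_2, sot)$tp_ecs
  u <- union(h1, h2)
  if (length(u) == 0L)
    return(c(pct_only_1 = 0, pct_only_2 = 0, pct_both = 0))
  both <- intersect(h1, h2)
  c(pct_only_1 = 100 * length(setdiff(h1, h2)) / length(u),
    pct_only_2 = 100 * length(setdiff(h2, h1)) / length(u),
    pct_both = 100 * length(both) / length(u))
}

#' Read predictions written by another tool
#'
#' TSV with at least columns `query_id` and `ec_list`
#' (semicolon-separated), so an external method's output can be fed to
#' [compare_to_sot()] and [contribution_split()].
#'
#' @param path TSV path.
#' @return prediction data.frame.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("query_id", "ec_list") %in% names(tab)))
  tab
}

#' Write predictions
#' @param predictions data.frame from [search_sequences()].
#' @param path TSV path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
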