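# One-call pipeline: classified database -> distances -> forest ->
# patterns -> verification -> strict/loose sets. Thin glue over the
# module functions; every stage's output is returned so callers can
# inspect or persist intermediates.

#' Run the full pattern-derivation pipeline
#'
#' @param input parsed records (data.frame from [read_flatfile()] or
#'   [read_fasta_db()]), or a path to a flat file.
#' @param ec_updates optional EC update map ([read_ec_updates()]).
#' @param cutoff clustering / hit-filter E-value threshold.
#' @param min_cols minimum alignment columns for a hit.
#' @param pce_threshold coverage target for the pattern loop.
#' @param loose_min_specificity specificity floor of the loose set.
#' @param aligner pairwise aligner (default [builtin_aligner()]).
#' @param msa_fun multiple-alignment provider (default
#'   [center_star_msa()]).
#' @param distances optional precomputed distance table (e.g. from
#'   imported BLAST output via [read_blast_tab()], [filter_hits()] and
#'   [symmetrify()]); skips the all-vs-all step.
#' @param keywords putative-marker keywords for classification.
#' @return list with `records` (classified, deduplicated), `hits`,
#'   `distances`, `forest`, `patterns`, `failures`, `stats` (verification
#'   + set membership).
#' @export
run_pipeline <- function(input, ec_updates = NULL, cutoff = 1e-3,
                         min_cols = 50L, pce_threshold = 0.9,
                         loose_min_specificity = 0.75,
                         aligner = builtin_aligner,
                         msa_fun = center_star_msa,
                         distances = NULL,
                         keywords = DEFAULT_PUTATIVE_KEYWORDS) {
  records <- if (is.character(input)) read_flatfile(input) else input
  if (!"group" %in% names(records))
    records <- classify_records(records, keywords = keywords)
  records <- deduplicate_records(records)
  if (!is.null(ec_updates))
    records <- apply_ec_updates(records, ec_updates)
  enz <- records[records$group == "ENZYME", , drop = FALSE]
  hits <- NULL
  if (is.null(distances)) {
    hits <- filter_hits(all_vs_all(enz, aligner = aligner),
                        min_cols = min_cols, max_evalue = cutoff)
    distances <- symmetrify(hits)
  }
  ec_sets <- stats::setNames(enz$ec, enz$id)
  forest <- complete_linkage(distances, ids = enz$id, ec_sets = ec_sets,
                             cutoff = cutoff)
  pats <- compute_patterns(forest, enz, pce_threshold = pce_threshold,
                           msa_fun = msa_fun)
  stats <- verify_patterns(pats$patterns, records)
  stats <- select_pattern_sets(stats, pats$patterns,
                               loose_min_specificity = loose_min_specificity)
  list(records = records, hits = hits, distances = distances,
       forest = pats$forest, patterns = pats$patterns,
       failures = pats$failures, stats = stats)
}
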