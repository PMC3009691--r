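# Pairwise similarity: a pluggable aligner contract producing tabular
# hits, converted into symmetric E-value distances for clustering.
# The built-in aligner is Smith-Waterman (Biostrings) with BLOSUM62,
# gap open 11 / extend 1, and a Karlin-Altschul E-value surrogate
# E = K * m * n * exp(-lambda * S).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Gapped BLOSUM62 (11,1) Karlin-Altschul parameters; refit with
# calibrate_evalue_params() if the scoring scheme changes.
DEFAULT_KA_PARAMS <- list(lambda = 0.267, K = 0.041)

#' Mask low-complexity sequence regions
#'
#' Sliding-window Shannon-entropy masker: every window of `window`
#' residues whose entropy (bits) falls below `threshold` has all its
#' positions replaced by `X`. Masking is applied to the similarity search
#' only; stored sequences are never modified. Pre-masked input (e.g. from
#' an external SEG run) can be supplied instead by the caller, in which
#' case this step is the identity.
#'
#' @param sequence character vector of protein sequences.
#' @param window window length in residues; `NULL` or 0 disables masking.
#' @param threshold entropy threshold in bits.
#' @return masked sequences.
#' @export
mask_low_complexity <- function(sequence, window = 12L, threshold = 2.2) {
  if (is.null(window) || window <= 0L) return(sequence)
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < window) return(s)
    ch <- strsplit(s, "")[[1]]
    mask <- logical(n)
    ent <- function(cnt) {
      p <- cnt[cnt > 0] / sum(cnt)
      -sum(p * log2(p))
    }
    for (i in seq_len(n - window + 1L)) {
      w <- ch[i:(i + window - 1L)]
      cnt <- tabulate(factor(w, levels = unique(w)))
      if (ent(cnt) < threshold) mask[i:(i + window - 1L)] <- TRUE
    }
    if (any(mask)) ch[mask] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Karlin-Altschul-style E-value surrogate
#'
#' @param score local alignment score(s).
#' @param m,n lengths of the two unaligned sequences.
#' @param params list with `lambda` and `K` (default [DEFAULT_KA_PARAMS]).
#' @return E-value(s), clamped below at `1e-180` so ordering and `max()`
#'   stay well-defined.
#' @export
evalue_from_score <- function(score, m, n, params = DEFAULT_KA_PARAMS) {
  e <- params$K * m * n * exp(-params$lambda * score)
  pmax(e, 1e-180)
}

#' Calibrate E-value parameters against shuffled sequence pairs
#'
#' Fits `lambda` and `K` of the surrogate `E = K m n exp(-lambda S)` to
#' the empirical score distribution of random residue pairs: for i.i.d.
#' sequences the tail `P(S >= x)` is approximately `K m n exp(-lambda x)`,
#' so a linear fit of `log` survival against score recovers both
#' parameters.
#'
#' @param n_pairs number of random pairs to score.
#' @param len sequence length used for the null pairs.
#' @param seed RNG seed.
#' @return list with `lambda` and `K`.
#' @export
calibrate_evalue_params <- function(n_pairs = 200L, len = 150L, seed = 1L) {
  scores <- local_with_seed(seed, {
    vapply(seq_len(n_pairs), function(i) {
      a <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      b <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      sw_score(a, b)
    }, numeric(1))
  })
  xs <- sort(unique(scores))
  surv <- vapply(xs, function(x) mean(scores >= x), numeric(1))
  ok <- surv > 0 & surv < 1
  if (sum(ok) < 3L) stop("degenerate null score distribution")
  fit <- stats::lm(log(surv[ok]) ~ xs[ok])
  lambda <- -unname(stats::coef(fit)[2])
  K <- exp(unname(stats::coef(fit)[1])) / (len * len)
  list(lambda = lambda, K = K)
}

sw_align <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "local")
}

sw_score <- function(a, b) {
  Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "local",
    scoreOnly = TRUE)
}

#' Built-in pairwise aligner
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1)
#' over all ordered pairs of the masked input sequences, with the
#' calibrated E-value surrogate. The scorer is symmetric, so both
#' directions of a pair carry the same E-value; hits with E-value above
#' `report_threshold` are not emitted (mirroring an aligner's reporting
#' cutoff).
#'
#' @param sequences named character vector (ids as names), already masked
#'   if masking is wanted.
#' @param params Karlin-Altschul parameters.
#' @param report_threshold maximum E-value reported.
#' @return data.frame of hits: `query_id`, `target_id`, `q_start`,
#'   `q_end`, `t_start`, `t_end`, `aligned_cols`, `evalue`.
#' @export
builtin_aligner <- function(sequences, params = DEFAULT_KA_PARAMS,
                            report_threshold = 10) {
  ids <- names(sequences)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(sequences)
  rows <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      al <- try(sw_align(sequences[[i]], sequences[[j]]), silent = TRUE)
      if (inherits(al, "try-error")) {
        warning("alignment failed for pair (", ids[i], ", ", ids[j], ")")
        next
      }
      s <- Biostrings::score(al)
      ev <- evalue_from_score(s, nchar(sequences[[i]]), nchar(sequences[[j]]),
                              params)
      if (ev > report_threshold) next
      pat <- Biostrings::pattern(al)
      sub <- Biostrings::subject(al)
      cols <- nchar(as.character(pat))
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = ids[i], target_id = ids[j],
        q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
        t_start = Biostrings::start(sub), t_end = Biostrings::end(sub),
        aligned_cols = cols, evalue = ev, stringsAsFactors = FALSE)
      # symmetric scorer: emit the reciprocal hit as well
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = ids[j], target_id = ids[i],
        q_start = Biostrings::start(sub), q_end = Biostrings::end(sub),
        t_start = Biostrings::start(pat), t_end = Biostrings::end(pat),
        aligned_cols = cols, evalue = ev, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  do.call(rbind, rows)
}

empty_hits <- function() {
  data.frame(query_id = character(0), target_id = character(0),
             q_start = integer(0), q_end = integer(0),
             t_start = integer(0), t_end = integer(0),
             aligned_cols = integer(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' All-vs-all similarity search over enzyme records
#'
#' Masks low-complexity regions (search only) and runs the aligner over
#' all pairs; self-hits are discarded.
#'
#' @param records enzyme records (data.frame with `id`, `sequence`).
#' @param aligner function taking a named character vector of sequences
#'   and returning a hit data.frame; default [builtin_aligner()].
#' @param mask logical, apply [mask_low_complexity()] before the search.
#' @param ... passed to the aligner.
#' @return hit data.frame (see [builtin_aligner()]).
#' @export
all_vs_all <- function(records, aligner = builtin_aligner, mask = TRUE, ...) {
  seqs <- records$sequence
  if (mask) seqs <- mask_low_complexity(seqs)
  names(seqs) <- records$id
  hits <- aligner(seqs, ...)
  hits[hits$query_id != hits$target_id, , drop = FALSE]
}

#' Filter pairwise hits by coverage and E-value
#'
#' A hit is retained iff it covers at least `min_cols` alignment columns
#' and its E-value is at most `max_evalue`; both boundary values are
#' retained. Idempotent.
#'
#' @param hits hit data.frame.
#' @param min_cols minimum alignment length (default 50).
#' @param max_evalue maximum E-value (default 1e-3).
#' @return filtered hits.
#' @export
filter_hits <- function(hits, min_cols = 50L, max_evalue = 1e-3) {
  hits[hits$aligned_cols >= min_cols & hits$evalue <= max_evalue, ,
       drop = FALSE]
}

#' Symmetrify directed hits into unordered pair distances
#'
#' Multiple hits in one direction are first reduced to that direction's
#' best (minimum) E-value. For each unordered pair with hits in *both*
#' directions the distance is the higher of the two E-values (less
#' similarity wins); pairs seen in only one direction yield no distance:
#' the missing reciprocal hit means its E-value exceeded the reporting
#' threshold, so the symmetrified distance would exceed the clustering
#' cutoff anyway.
#'
#' @param hits filtered hit data.frame.
#' @return data.frame of distances: `id_a`, `id_b` (with `id_a < id_b`),
#'   `evalue`.
#' @export
symmetrify <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  dir_key <- paste(hits$query_id, hits$target_id, sep = "\r")
  best <- tapply(hits$evalue, dir_key, min)
  qt <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  a <- pmin(qt[, 1], qt[, 2])
  b <- pmax(qt[, 1], qt[, 2])
  pair_key <- paste(a, b, sep = "\r")
  n_dir <- tapply(rep(1L, length(pair_key)), pair_key, sum)
  dmax <- tapply(as.numeric(best), pair_key, max)
  both <- names(n_dir)[n_dir == 2L]
  ab <- do.call(rbind, strsplit(both, "\r", fixed = TRUE))
  out <- data.frame(
    id_a = if (length(both)) ab[, 1] else character(0),
    id_b = if (length(both)) ab[, 2] else character(0),
    evalue = as.numeric(dmax[both]),
    stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Import BLAST tabular output (outfmt 6)
#'
#' Maps the standard 12 columns (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) onto
#' the hit table used by the pipeline. E-values of 0 are clamped to
#' `1e-180`.
#'
#' @param path path to the tabular file.
#' @return hit data.frame as from [builtin_aligner()].
#' @export
read_blast_tab <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected >= 12 tab-separated columns")
  data.frame(
    query_id = as.character(tab[[1]]), target_id = as.character(tab[[2]]),
    q_start = as.integer(tab[[7]]), q_end = as.integer(tab[[8]]),
    t_start = as.integer(tab[[9]]), t_end = as.integer(tab[[10]]),
    aligned_cols = as.integer(tab[[4]]),
    evalue = pmax(as.numeric(tab[[11]]), 1e-180),
    stringsAsFactors = FALSE)
}

#' Write / read the distance table
#'
#' @param distances data.frame from [symmetrify()].
#' @param path TSV path.
#' @export
write_distances <- function(distances, path) {
  utils::write.table(distances, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
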