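# Multiple alignments for pattern extraction. The built-in provider is a
# center-star progressive alignment: pick the sequence with the highest
# summed pairwise score as center, align every other sequence to it
# globally, and merge the pairwise alignments under "once a gap, always a
# gap". A ClustalW ALN importer is provided for externally computed
# alignments; conservation is always recomputed from the rows.

#' Center-star multiple alignment
#'
#' @param sequences named character vector (>= 1 sequence).
#' @return named character vector of equal-length aligned rows (residues
#'   and `-`), in the input order.
#' @export
center_star_msa <- function(sequences) {
  n <- length(sequences)
  stopifnot(n >= 1L, !is.null(names(sequences)))
  if (n == 1L) return(sequences)
  # center = maximal summed global alignment score against the rest
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- Biostrings::pairwiseAlignment(
        sequences[[i]], sequences[[j]], substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, type = "global",
        scoreOnly = TRUE)
      scores[i, j] <- s; scores[j, i] <- s
    }
  }
  center <- which.max(rowSums(scores))
  others <- setdiff(seq_len(n), center)
  L <- nchar(sequences[[center]])
  # per-alignment gap counts inserted into the center before position i
  # (slot L+1 = after the last residue)
  ins <- matrix(0L, nrow = length(others), ncol = L + 1L)
  aligned_pairs <- vector("list", length(others))
  for (k in seq_along(others)) {
    al <- Biostrings::pairwiseAlignment(
      sequences[[center]], sequences[[others[k]]],
      substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, type = "global")
    cal <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    sal <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    aligned_pairs[[k]] <- list(center = cal, other = sal)
    pos <- 1L; run <- 0L
    for (ch in cal) {
      if (ch == "-") run <- run + 1L
      else {
        ins[k, pos] <- run; run <- 0L; pos <- pos + 1L
      }
    }
    ins[k, L + 1L] <- run
  }
  master <- apply(ins, 2L, max)
  # rebuild each row in master coordinates
  center_chars <- strsplit(sequences[[center]], "")[[1]]
  build_center <- function() {
    out <- character(0)
    for (i in seq_len(L)) out <- c(out, rep("-", master[i]), center_chars[i])
    c(out, rep("-", master[L + 1L]))
  }
  build_other <- function(k) {
    cal <- aligned_pairs[[k]]$center
    sal <- aligned_pairs[[k]]$other
    out <- character(0)
    pos <- 1L                      # next center residue index
    buf <- character(0)            # subject chars in the current gap run
    for (t in seq_along(cal)) {
      if (cal[t] == "-") {
        buf <- c(buf, sal[t])
      } else {
        out <- c(out, rep("-", master[pos] - length(buf)), buf, sal[t])
        buf <- character(0)
        pos <- pos + 1L
      }
    }
    c(out, rep("-", master[L + 1L] - length(buf)), buf)
  }
  rows <- vector("list", n)
  rows[[center]] <- build_center()
  for (k in seq_along(others)) rows[[others[k]]] <- build_other(k)
  widths <- lengths(rows)
  stopifnot(length(unique(widths)) == 1L)
  stats::setNames(vapply(rows, paste, "", collapse = ""), names(sequences))
}

#' Read a ClustalW ALN multiple alignment
#'
#' Parses the interleaved ALN dialect (header line, blocks of
#' `name  chunk` rows, conservation lines ignored — conservation is
#' recomputed from the rows by [conservation_classes()]).
#'
#' @param path file path.
#' @return named character vector of equal-length aligned rows.
#' @export
read_aln <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("CLUSTAL", lines[1], ignore.case = TRUE))
    stop("not a CLUSTAL ALN file: ", path)
  body <- lines[-1]
  rows <- list()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    # conservation lines contain only spaces, '*', ':' and '.'
    if (grepl("^[ *:.]+$", ln)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z-]+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(m) == 0L) next
    nm <- m[2]; chunk <- m[3]
    rows[[nm]] <- paste0(rows[[nm]] %||% "", chunk)
  }
  if (length(rows) == 0L) stop("no alignment rows found in ", path)
  out <- toupper(unlist(rows))
  if (length(unique(nchar(out))) != 1L) stop("ragged alignment in ", path)
  out
}
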