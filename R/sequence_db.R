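# Sequence database: parsing, three-group classification, redundancy
# removal and EC bookkeeping. Records live in a plain data.frame with a
# list-column `ec` so the rest of the pipeline can use ordinary subsetting.

#' Keywords marking entries of unknown or non-catalytic status
#'
#' Descriptions containing any of these (case-insensitive) route an entry
#' to the putative group regardless of EC annotation.
#' @export
DEFAULT_PUTATIVE_KEYWORDS <- c("putative", "hypothetical", "fragment",
                               "probable", "by similarity")

#' Enzyme length bounds (amino acids)
#'
#' Entries with an EC number only count as enzymes when their length lies
#' in this closed interval; practically no complete enzyme is shorter than
#' 100 residues and sequences beyond 7000 residues are vanishingly rare.
#' @export
ENZYME_LENGTH_BOUNDS <- c(100L, 7000L)

ec_token_re <- "EC[ =]((?:[0-9]+)\\.(?:[0-9]+|-)\\.(?:[0-9]+|-)\\.(?:[0-9]+|-))"

extract_ec_tokens <- function(text) {
  m <- gregexpr(ec_token_re, text, perl = TRUE)
  hits <- regmatches(text, m)[[1]]
  if (length(hits) == 0L) return(character(0))
  ecs <- sub(ec_token_re, "\\1", hits, perl = TRUE)
  ecs <- ecs[ec_is_valid(ecs)]
  unique(ecs)
}

#' Parse a Swiss-Prot-style flat file
#'
#' Reads the DAT dialect: entries separated by `//` lines, with `ID`,
#' `AC`, `DE` and `SQ` blocks. EC numbers are extracted from the
#' description (`DE`) lines, where they appear as `EC x.x.x.x` or
#' `EC=x.x.x.x` tokens (trailing levels may be `-`). Malformed entries
#' (missing identifier or sequence) are skipped with a warning.
#'
#' @param path file path, or a character vector of lines via `text=`.
#' @param text optional character vector of lines (instead of `path`).
#' @return data.frame with columns `id`, `description`, `sequence` and
#'   list-column `ec` (character vector per entry, deduplicated, in order
#'   of appearance).
#' @export
read_flatfile <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  ends <- grep("^//\\s*$", lines)
  starts <- c(1L, ends[-length(ends)] + 1L)
  if (length(ends) == 0L) starts <- integer(0)
  recs <- vector("list", length(ends))
  kept <- 0L
  for (k in seq_along(ends)) {
    chunk <- lines[starts[k]:ends[k]]
    id_line <- grep("^ID\\s+", chunk, value = TRUE)
    ac_line <- grep("^AC\\s+", chunk, value = TRUE)
    de_lines <- grep("^DE\\s+", chunk, value = TRUE)
    sq_at <- grep("^SQ\\s+", chunk)
    id <- if (length(ac_line)) {
      sub(";.*$", "", sub("^AC\\s+", "", ac_line[1]))
    } else if (length(id_line)) {
      sub("\\s.*$", "", sub("^ID\\s+", "", id_line[1]))
    } else NA_character_
    seq <- if (length(sq_at)) {
      body <- chunk[seq(sq_at[1] + 1L, length(chunk) - 1L)]
      toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    } else ""
    if (is.na(id) || !nzchar(id) || !nzchar(seq)) {
      warning("skipping malformed entry #", k, " (missing ID or sequence)")
      next
    }
    desc <- paste(sub("^DE\\s+", "", de_lines), collapse = " ")
    kept <- kept + 1L
    recs[[kept]] <- list(id = id, description = desc, sequence = seq,
                         ec = extract_ec_tokens(desc))
  }
  recs <- recs[seq_len(kept)]
  data.frame(
    id = vapply(recs, `[[`, "", "id"),
    description = vapply(recs, `[[`, "", "description"),
    sequence = vapply(recs, `[[`, "", "sequence"),
    ec = I(lapply(recs, `[[`, "ec")),
    stringsAsFactors = FALSE
  )
}

#' Read a FASTA database with a sidecar annotation table
#'
#' Alternative input route: sequences in FASTA, annotation in a TSV with
#' columns `id`, `ec_list` (semicolon-separated, may be empty) and
#' `description`.
#'
#' @param fasta path to a FASTA file of protein sequences.
#' @param annotation path to the TSV annotation table.
#' @return data.frame as from [read_flatfile()].
#' @export
read_fasta_db <- function(fasta, annotation) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("id", "ec_list", "description") %in% names(ann)))
  idx <- match(ids, ann$id)
  data.frame(
    id = ids,
    description = ifelse(is.na(idx), "", ann$description[idx]),
    sequence = as.character(seqs),
    ec = I(lapply(seq_along(ids), function(i) {
      if (is.na(idx[i]) || !nzchar(ann$ec_list[idx[i]])) return(character(0))
      ecs <- strsplit(ann$ec_list[idx[i]], ";", fixed = TRUE)[[1]]
      unique(trimws(ecs))
    })),
    stringsAsFactors = FALSE
  )
}

#' Classify parsed entries into the three database groups
#'
#' Every entry goes to exactly one group:
#' * `PUTATIVE` — the description contains any of the configured keywords
#'   (default [DEFAULT_PUTATIVE_KEYWORDS], case-insensitive), or the entry
#'   carries an EC number but its length falls outside
#'   [ENZYME_LENGTH_BOUNDS]. Putative entries are neutral evidence in
#'   pattern verification.
#' * `ENZYME` — EC-annotated, within the length bounds, no keyword.
#' * `NON_ENZYME` — no EC number and no keyword.
#'
#' EC sets of non-enzyme and putative entries are ignored for all scoring.
#'
#' @param records data.frame from [read_flatfile()] / [read_fasta_db()].
#' @param keywords character vector of putative-marker keywords.
#' @return the records with an added `group` column.
#' @export
classify_records <- function(records, keywords = DEFAULT_PUTATIVE_KEYWORDS) {
  kw_re <- paste(sapply(tolower(keywords), function(k)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", k)), collapse = "|")
  has_kw <- grepl(kw_re, tolower(records$description))
  len <- nchar(records$sequence)
  has_ec <- vapply(records$ec, length, integer(1)) > 0L
  in_bounds <- len >= ENZYME_LENGTH_BOUNDS[1] & len <= ENZYME_LENGTH_BOUNDS[2]
  group <- ifelse(has_kw, "PUTATIVE",
           ifelse(has_ec & in_bounds, "ENZYME",
           ifelse(has_ec, "PUTATIVE", "NON_ENZYME")))
  records$group <- group
  records
}

#' Pairwise redundancy test
#'
#' `r` is redundant to `q` when both are enzymes with identical sequences
#' and `ec(r)` is a subset of `ec(q)` (set equality included); for the
#' putative and non-enzyme groups sequence identity alone suffices.
#' Comparing records across groups is a caller bug and errors.
#'
#' @param q,r one-row record data.frames (or lists with `sequence`, `ec`,
#'   `group`).
#' @return logical scalar: is `r` redundant to `q`?
#' @export
is_redundant <- function(q, r) {
  gq <- if (is.data.frame(q)) q$group[1] else q$group
  gr <- if (is.data.frame(r)) r$group[1] else r$group
  if (!identical(gq, gr)) stop("is_redundant() called across groups")
  sq <- if (is.data.frame(q)) q$sequence[1] else q$sequence
  sr <- if (is.data.frame(r)) r$sequence[1] else r$sequence
  if (!identical(sq, sr)) return(FALSE)
  if (identical(gq, "ENZYME")) {
    eq <- if (is.data.frame(q)) q$ec[[1]] else q$ec
    er <- if (is.data.frame(r)) r$ec[[1]] else r$ec
    all(er %in% eq)
  } else TRUE
}

#' Remove redundant records within each group
#'
#' Within each group, records are visited in order of decreasing EC-set
#' size (ties by lexicographic id) and a record is dropped iff it is
#' redundant to an already-retained one. Visiting superset-EC records
#' first maximizes the EC information retained.
#'
#' @param records classified records.
#' @return the non-redundant records (original row order restored).
#' @export
deduplicate_records <- function(records) {
  keep <- logical(nrow(records))
  for (g in unique(records$group)) {
    idx <- which(records$group == g)
    nec <- vapply(records$ec[idx], length, integer(1))
    ord <- idx[order(-nec, records$id[idx])]
    # bucket by sequence: redundancy requires identical sequences
    by_seq <- split(ord, records$sequence[ord])
    for (b in by_seq) {
      retained <- integer(0)
      for (i in b) {
        red <- any(vapply(retained, function(j)
          is_redundant(records[j, ], records[i, ]), logical(1)))
        if (!red) {
          retained <- c(retained, i)
          keep[i] <- TRUE
        }
      }
    }
  }
  records[sort(which(keep)), , drop = FALSE]
}

#' Read an EC update map
#'
#' TSV with columns `old_ec`, `action` (`transfer` or `delete`) and
#' `new_ecs` (semicolon-separated successors; empty for deletions).
#'
#' @param path file path.
#' @return list with `transferred` (named list old EC -> character vector
#'   of successors) and `deleted` (character vector).
#' @export
read_ec_updates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  stopifnot(all(c("old_ec", "action", "new_ecs") %in% names(tab)))
  tr <- tab[tab$action == "transfer", , drop = FALSE]
  transferred <- stats::setNames(
    lapply(tr$new_ecs, function(s) trimws(strsplit(s, ";", fixed = TRUE)[[1]])),
    tr$old_ec)
  deleted <- tab$old_ec[tab$action == "delete"]
  if (length(intersect(names(transferred), deleted)))
    stop("EC update map lists the same EC as transferred and deleted")
  list(transferred = transferred, deleted = deleted)
}

#' Apply EC transfers and deletions to the database
#'
#' Transferred EC numbers are replaced by their successor set (chains are
#' dereferenced up to `max_depth`, beyond which a cycle is assumed and an
#' error thrown). ECs listed as deleted are removed from every record;
#' enzyme records whose EC set becomes empty are dropped.
#'
#' @param records classified records.
#' @param updates list as from [read_ec_updates()].
#' @param max_depth maximum transfer-chain dereference depth.
#' @return updated records.
#' @export
apply_ec_updates <- function(records, updates, max_depth = 5L) {
  deref <- function(ec, depth = 0L) {
    if (!ec %in% names(updates$transferred)) return(ec)
    if (depth >= max_depth)
      stop("EC transfer chain exceeds depth ", max_depth, " at ", ec,
           " (cycle?)")
    unique(unlist(lapply(updates$transferred[[ec]], deref, depth = depth + 1L)))
  }
  records$ec <- I(lapply(records$ec, function(ecs) {
    if (length(ecs) == 0L) return(ecs)
    new <- unique(unlist(lapply(ecs, deref)))
    setdiff(new, updates$deleted)
  }))
  empty_enzyme <- records$group == "ENZYME" &
    vapply(records$ec, length, integer(1)) == 0L
  records[!empty_enzyme, , drop = FALSE]
}

#' Write the three groups as FASTA files plus a manifest
#'
#' @param records classified (and usually deduplicated) records.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame (`id`, `group`, `ec_list`,
#'   `length`).
#' @export
write_groups <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in c("ENZYME", "PUTATIVE", "NON_ENZYME")) {
    sub <- records[records$group == g, , drop = FALSE]
    ss <- Biostrings::AAStringSet(sub$sequence)
    names(ss) <- sub$id
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(tolower(g), ".fasta")))
  }
  manifest <- data.frame(
    id = records$id,
    group = records$group,
    ec_list = vapply(records$ec, paste, "", collapse = ";"),
    length = nchar(records$sequence),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
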