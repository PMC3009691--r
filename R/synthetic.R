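# Synthetic annotated protein databases with controlled family
# structure: mutated descendants of random ancestors with EC labels,
# keyworded "putative" decoys, random non-enzyme entries, and optional
# multidomain concatenations of two families. All randomness flows
# through explicit integer seeds (R's default Mersenne-Twister), so a
# fixed spec reproduces byte-identical output.

#' Specify a synthetic enzyme family
#'
#' @param ancestor_length ancestor length in residues (>= 100, so family
#'   members clear the enzyme length floor).
#' @param n_members number of descendant sequences (>= 1).
#' @param substitution_rate per-site substitution probability in `[0, 1)`
#'   (substitutions are uniform over the 19 alternative residues).
#' @param indel_rate per-site indel probability in `[0, 1)`; an indel
#'   deletes or inserts a geometric-length run (mean 2).
#' @param ec_labels character vector of EC numbers carried by every
#'   member.
#' @param seed integer RNG seed.
#' @return a `family_spec` list.
#' @export
family_spec <- function(ancestor_length = 300L, n_members = 8L,
                        substitution_rate = 0.08, indel_rate = 0,
                        ec_labels = "1.1.1.1", seed = 1L) {
  stopifnot(ancestor_length >= 100L, n_members >= 1L,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            all(ec_is_valid(ec_labels)))
  structure(list(ancestor_length = as.integer(ancestor_length),
                 n_members = as.integer(n_members),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 ec_labels = ec_labels, seed = as.integer(seed)),
            class = "family_spec")
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, substitution_rate, indel_rate) {
  ch <- strsplit(seq, "")[[1]]
  sub_at <- stats::runif(length(ch)) < substitution_rate
  if (any(sub_at)) {
    ch[sub_at] <- vapply(ch[sub_at], function(r)
      sample(setdiff(AA20, r), 1L), character(1))
  }
  if (indel_rate > 0) {
    out <- character(0)
    i <- 1L
    while (i <= length(ch)) {
      if (stats::runif(1) < indel_rate) {
        k <- stats::rgeom(1, 0.5) + 1L       # geometric run length, mean 2
        if (stats::runif(1) < 0.5) {
          i <- i + k                         # deletion of k residues
          next
        }
        out <- c(out, ch[i], sample(AA20, k, replace = TRUE))
      } else {
        out <- c(out, ch[i])
      }
      i <- i + 1L
    }
    ch <- out
  }
  paste(ch, collapse = "")
}

#' Generate one synthetic enzyme family
#'
#' Draws a uniform-random ancestor and `n_members` descendants by i.i.d.
#' per-site substitution and geometric-length indels. Deterministic for a
#' fixed spec (including its seed).
#'
#' @param spec a [family_spec()].
#' @return list with `ancestor` and named character vector `members`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  local_with_seed(spec$seed, {
    anc <- random_protein(spec$ancestor_length)
    members <- vapply(seq_len(spec$n_members), function(i)
      mutate_sequence(anc, spec$substitution_rate, spec$indel_rate),
      character(1))
    list(ancestor = anc,
         members = stats::setNames(members,
                                   sprintf("F%02dM%02d", spec$seed %% 100L,
                                           seq_len(spec$n_members))))
  })
}

format_flat_entry <- function(id, description, sequence) {
  body <- character(0)
  ch <- strsplit(sequence, "")[[1]]
  for (i in seq(1L, length(ch), by = 60L)) {
    block <- ch[i:min(i + 59L, length(ch))]
    groups <- split(block, (seq_along(block) - 1L) %/% 10L)
    body <- c(body, paste0("     ",
                           paste(vapply(groups, paste, "", collapse = ""),
                                 collapse = " ")))
  }
  c(sprintf("ID   %s_SYN            Reviewed; %9d AA.", id, nchar(sequence)),
    sprintf("AC   %s;", id),
    sprintf("DE   %s", description),
    sprintf("SQ   SEQUENCE %6d AA;  synthetic;", nchar(sequence)),
    body, "//")
}

#' Generate a synthetic annotated database flat file
#'
#' Emits one Swiss-Prot-dialect flat file containing: enzyme entries (EC
#' numbers in the `DE` line) for every family member; putative decoys
#' (lightly mutated copies of family members whose descriptions carry a
#' "putative" keyword, so matched patterns score a neutral verdict);
#' random non-enzyme entries; and optional multidomain entries
#' concatenating fresh descendants of two families and carrying the union
#' of both families' EC labels.
#'
#' @param family_specs list of [family_spec()] objects (member ids must
#'   end up distinct: give each spec a distinct seed).
#' @param n_putative_decoys number of putative decoy entries.
#' @param decoy_substitution_rate per-site mutation applied to decoys on
#'   top of their source member (default 0: exact keyworded copies, so
#'   family patterns are guaranteed to hit the neutral channel).
#' @param n_non_enzymes number of random non-enzyme entries.
#' @param multidomain_pairs list of integer pairs `c(i, j)` indexing
#'   `family_specs`; each yields one concatenated two-domain enzyme.
#' @param seed master seed for decoys, non-enzymes and multidomain
#'   sequences.
#' @return list with `lines` (flat-file text), `truth` (data.frame `id`,
#'   `kind`, `family`, `true_ec_list`) and `families` (the generated
#'   family sequences).
#' @export
generate_database <- function(family_specs, n_putative_decoys = 0L,
                              decoy_substitution_rate = 0,
                              n_non_enzymes = 0L,
                              multidomain_pairs = list(), seed = 1L) {
  fams <- lapply(family_specs, generate_family)
  lines <- character(0)
  truth <- list()
  add_truth <- function(id, kind, family, ecs) {
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, kind = kind, family = family,
      true_ec_list = paste(ecs, collapse = ";"), stringsAsFactors = FALSE)
  }
  for (fi in seq_along(fams)) {
    spec <- family_specs[[fi]]
    ecs <- spec$ec_labels
    de <- sprintf("RecName: Full=Synthetic family %d enzyme (%s).",
                  fi, paste(sprintf("EC %s", ecs), collapse = ", "))
    for (mi in seq_along(fams[[fi]]$members)) {
      id <- sprintf("ENZ%02d%03d", fi, mi)
      lines <- c(lines, format_flat_entry(id, de, fams[[fi]]$members[[mi]]))
      add_truth(id, "enzyme", fi, ecs)
    }
  }
  local_with_seed(seed, {
    for (k in seq_along(multidomain_pairs)) {
      pr <- multidomain_pairs[[k]]
      a <- family_specs[[pr[1]]]; b <- family_specs[[pr[2]]]
      seq_a <- mutate_sequence(fams[[pr[1]]]$ancestor,
                               a$substitution_rate, a$indel_rate)
      seq_b <- mutate_sequence(fams[[pr[2]]]$ancestor,
                               b$substitution_rate, b$indel_rate)
      ecs <- unique(c(a$ec_labels, b$ec_labels))
      id <- sprintf("MDM%05d", k)
      de <- sprintf("RecName: Full=Synthetic multidomain enzyme (%s).",
                    paste(sprintf("EC %s", ecs), collapse = ", "))
      lines <- c(lines, format_flat_entry(id, de, paste0(seq_a, seq_b)))
      add_truth(id, "multidomain", NA_integer_, ecs)
    }
    if (n_putative_decoys > 0L) {
      pool <- unlist(lapply(fams, `[[`, "members"))
      pick <- sample(length(pool), n_putative_decoys, replace = TRUE)
      for (k in seq_len(n_putative_decoys)) {
        id <- sprintf("PUT%05d", k)
        seqk <- mutate_sequence(pool[[pick[k]]], decoy_substitution_rate, 0)
        de <- "RecName: Full=Putative uncharacterized protein."
        lines <- c(lines, format_flat_entry(id, de, seqk))
        add_truth(id, "putative_decoy", NA_integer_, character(0))
      }
    }
    if (n_non_enzymes > 0L) {
      for (k in seq_len(n_non_enzymes)) {
        id <- sprintf("NON%05d", k)
        seqk <- random_protein(sample(120:400, 1L))
        de <- "RecName: Full=Synthetic structural protein."
        lines <- c(lines, format_flat_entry(id, de, seqk))
        add_truth(id, "non_enzyme", NA_integer_, character(0))
      }
    }
  })
  list(lines = lines, truth = do.call(rbind, truth), families = fams)
}
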