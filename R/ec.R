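# EC numbers are handled as canonical strings "c.s.ss.n" where trailing
# levels may be "-" (unspecified). Internally ec_levels() turns one EC into
# an integer 4-vector with NA marking unspecified levels.

#' Parse EC number strings into a level matrix
#'
#' An EC number is a four-level hierarchical classifier
#' (class.subclass.sub-subclass.serial). Trailing levels may be
#' unspecified and are written `-` (e.g. `"1.2.3.-"` or `"1.2.-.-"`).
#' A level may only be unspecified if all deeper levels are too, and the
#' class (level 1) must always be specified.
#'
#' @param ec character vector of EC numbers.
#' @return integer matrix with one row per EC and four columns; `NA`
#'   marks an unspecified level.
#' @examples
#' ec_levels(c("1.2.3.4", "1.2.-.-"))
#' @export
ec_levels <- function(ec) {
  parts <- strsplit(as.character(ec), ".", fixed = TRUE)
  out <- matrix(NA_integer_, nrow = length(ec), ncol = 4L)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4L) stop("malformed EC number: ", ec[i])
    v <- suppressWarnings(as.integer(p))
    bad <- is.na(v) & p != "-"
    if (any(bad)) stop("malformed EC number: ", ec[i])
    spec <- !is.na(v)
    if (!spec[1L]) stop("EC class level must be specified: ", ec[i])
    # once unspecified, all deeper levels must be unspecified
    if (any(diff(spec) > 0L)) stop("invalid EC form (gapped levels): ", ec[i])
    if (any(v[spec] <= 0L)) stop("EC levels must be positive: ", ec[i])
    out[i, ] <- v
  }
  out
}

#' Format a level matrix (or validate/canonicalize EC strings)
#'
#' @param levels integer matrix as returned by [ec_levels()], or a
#'   character vector of EC strings to canonicalize.
#' @return character vector of canonical EC strings.
#' @export
ec_format <- function(levels) {
  if (is.character(levels)) levels <- ec_levels(levels)
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  apply(levels, 1L, function(v) {
    paste(ifelse(is.na(v), "-", as.character(v)), collapse = ".")
  })
}

#' Test whether strings are valid EC numbers
#'
#' @param ec character vector.
#' @return logical vector.
#' @export
ec_is_valid <- function(ec) {
  vapply(ec, function(s) !inherits(try(ec_levels(s), silent = TRUE), "try-error"),
         logical(1), USE.NAMES = FALSE)
}

#' Sub-subclass key (first three levels) of EC numbers
#'
#' @param ec character vector of EC numbers.
#' @return character vector like `"1.1.1"`; `NA` where the sub-subclass
#'   itself is unspecified.
#' @export
ec_sub_subclass <- function(ec) {
  lv <- ec_levels(ec)
  key <- paste(lv[, 1L], lv[, 2L], lv[, 3L], sep = ".")
  key[is.na(lv[, 3L])] <- NA_character_
  key
}

#' EC relationship calculus for one (pattern EC, target EC) pair
#'
#' Scores the relation between the EC number attached to a pattern and the
#' EC number of a matched sequence. The rule is asymmetric: a pattern EC
#' claims function only down to its own resolution, so unspecified levels
#' in the pattern are "don't care"; a target that is *less* resolved than
#' the pattern cannot confirm the claim and is neutral.
#'
#' * `TP` — the target agrees with the pattern at every level the pattern
#'   specifies, and is itself specified at all of those levels.
#' * `FP` — some level is specified in both and differs.
#' * `NA` — otherwise (target under-resolved relative to the pattern,
#'   without any conflicting level).
#'
#' @param p pattern EC number (string).
#' @param t target EC number (string).
#' @return one of `"TP"`, `"FP"`, `"NA"`.
#' @examples
#' ec_pair_relation("1.2.3.-", "1.2.3.4")  # TP
#' ec_pair_relation("1.2.3.4", "1.2.3.-")  # NA
#' @export
ec_pair_relation <- function(p, t) {
  pv <- ec_levels(p)[1L, ]
  tv <- ec_levels(t)[1L, ]
  both <- !is.na(pv) & !is.na(tv)
  if (any(pv[both] != tv[both])) return("FP")
  # no conflict; TP iff t specified wherever p is
  if (any(!is.na(pv) & is.na(tv))) return("NA")
  "TP"
}

#' Aggregate the EC calculus over two EC sets
#'
#' Evaluates [ec_pair_relation()] over the cross product of the pattern's
#' and the target's EC sets and aggregates with the precedence
#' TP > FP > NA: any TP wins, otherwise any FP, otherwise NA.
#'
#' @param p_set character vector of pattern EC numbers (nonempty).
#' @param t_set character vector of target EC numbers (nonempty).
#' @return one of `"TP"`, `"FP"`, `"NA"`.
#' @export
ec_set_relation <- function(p_set, t_set) {
  stopifnot(length(p_set) > 0L, length(t_set) > 0L)
  saw_fp <- FALSE
  for (p in p_set) {
    for (t in t_set) {
      v <- ec_pair_relation(p, t)
      if (v == "TP") return("TP")
      if (v == "FP") saw_fp <- TRUE
    }
  }
  if (saw_fp) "FP" else "NA"
}
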