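# Small builders for records and flat-file snippets used across tests.

make_record <- function(id, sequence, ec = character(0), group = "ENZYME",
                        description = "") {
  data.frame(id = id, description = description, sequence = sequence,
             ec = I(list(ec)), group = group, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  do.call(rbind, list(...))
}

flat_entry <- function(id, de, seq) {
  c(sprintf("ID   %s_TST            Reviewed; %d AA.", id, nchar(seq)),
    sprintf("AC   %s;", id),
    sprintf("DE   %s", de),
    sprintf("SQ   SEQUENCE %d AA;", nchar(seq)),
    paste0("     ", seq),
    "//")
}

# a concrete string realizing one match of a pattern (gap runs at their
# minimum width, classes at their first residue)
realize_pattern <- function(pattern) {
  el <- pattern$elements
  paste(vapply(seq_len(nrow(el)), function(i) {
    switch(el$type[i],
      LITERAL = el$residues[i],
      CLASS = substr(el$residues[i], 1, 1),
      GAP = if (el$min[i] == 0L) "" else
        paste(sample(enzpat:::AA20, el$min[i], replace = TRUE), collapse = ""))
  }, character(1)), collapse = "")
}
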