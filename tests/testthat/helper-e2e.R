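# One shared end-to-end synthetic run (computed lazily, reused across
# test blocks): five enzyme families with distinct fully resolved EC
# numbers, putative decoys, random non-enzymes, and two multidomain
# concatenations.

e2e_cache <- new.env(parent = emptyenv())

e2e_family_specs <- function(seed_base = 100L) {
  lapply(1:5, function(i)
    family_spec(ancestor_length = 300L, n_members = 8L,
                substitution_rate = 0.08,
                ec_labels = sprintf("%d.1.1.%d", i, i),
                seed = seed_base + i))
}

e2e_run <- function() {
  if (!exists("res", envir = e2e_cache)) {
    specs <- e2e_family_specs()
    db <- generate_database(specs, n_putative_decoys = 20L,
                            n_non_enzymes = 50L,
                            multidomain_pairs = list(c(1, 2), c(3, 4)),
                            seed = 99L)
    recs <- read_flatfile(text = db$lines)
    res <- run_pipeline(recs)
    assign("res", list(db = db, pipeline = res, specs = specs),
           envir = e2e_cache)
  }
  get("res", envir = e2e_cache)
}

# family index (1..5, or NA) of each member id in a tree
e2e_family_of <- function(ids) {
  fam <- rep(NA_integer_, length(ids))
  m <- regmatches(ids, regexec("^ENZ(\\d{2})", ids))
  for (i in seq_along(ids))
    if (length(m[[i]])) fam[i] <- as.integer(m[[i]][2])
  fam
}
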