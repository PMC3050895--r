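# Shared fixtures: all built in code at test time.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), ""))
}

# a small tree with two phyla, two orders in one class, and known structure
# for LCA semantics tests
hand_tree <- function() {
  taxonomy(data.frame(
    id = 1:13,
    name = c("Bacteria", "P1", "P2", "C1", "C2", "O1", "O2", "F1", "F2",
             "F3", "G1", "G2", "G3"),
    rank = c("domain", "phylum", "phylum", "class", "class", "order",
             "order", "family", "family", "family", "genus", "genus",
             "genus"),
    parent = c(NA, 1, 1, 2, 3, 4, 4, 6, 7, 5, 8, 9, 10),
    stringsAsFactors = FALSE))
}

# small, fast reference set for search/triage unit tests
small_refs <- function(seed = 3, ...) {
  tr <- build_taxonomy(2, 2)
  list(tree = tr,
       refs = evolve_references(tr, ssu_len = 400L, lsu_len = 600L,
                                protein_len = 90L, cogs_per_category = 1L,
                                srna_families = 2L, seed = seed, ...))
}

# default-scale references shared by the heavier recovery tests
default_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- build_taxonomy(5, 4)
      cache <<- list(tree = tr, refs = evolve_references(tr, seed = 3))
    }
    cache
  }
})

# brute-force ungapped local alignment maximum (Kadane per diagonal),
# forward strand only; the independent oracle for extension scores
sw_ungapped_max <- function(q, s, match = 1, mismatch = -2) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  best <- 0
  for (d in seq(-(length(sv) - 1), length(qv) - 1)) {
    qi <- max(1, 1 + d); si <- qi - d
    run <- 0
    while (qi <= length(qv) && si <= length(sv)) {
      sc <- if (qv[qi] == sv[si]) match else mismatch
      run <- max(run + sc, 0)
      best <- max(best, run)
      qi <- qi + 1; si <- si + 1
    }
  }
  best
}
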