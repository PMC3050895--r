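test_that("protein-coding calls: planted positives, empty database negatives", {
  s <- small_refs(seed = 6)
  prot <- ref_class(s$refs, "protein")
  idx <- build_index(prot, alphabet = "aa")
  reads <- data.frame(id = c("hit", "junk"), sample = "S01",
                      sequence = c(substr(prot$cds[1], 1, 150),
                                   random_dna(150, seed = 55)),
                      stringsAsFactors = FALSE)
  calls <- call_protein_coding(reads, idx)
  expect_true(calls$calls$protein_coding[1])
  expect_equal(calls$calls$best_subject[1], prot$id[1])
})

test_that("random reads are overwhelmingly uncharacterized at E <= 1e-3", {
  s <- small_refs(seed = 6)
  idx <- build_index(ref_class(s$refs, "protein"), alphabet = "aa")
  set.seed(60)
  reads <- data.frame(id = sprintf("r%04d", 1:2000), sample = "S01",
                      sequence = vapply(1:2000, function(i) random_dna(120), ""),
                      stringsAsFactors = FALSE)
  calls <- call_protein_coding(reads, idx)
  # the Karlin expectation bounds false positives near E * n_reads
  expect_lte(sum(calls$calls$protein_coding), 20)
})

test_that("COG assignment: single group, homolog competition, fusion discard", {
  s <- small_refs(seed = 6)
  prot <- ref_class(s$refs, "protein")
  # one group only -> assigned
  r1 <- substr(prot$cds[1], 1, 180)
  # a fusion: two halves from different categories on disjoint read regions
  other <- which(prot$cog_category != prot$cog_category[1])[1]
  r2 <- paste0(substr(prot$cds[1], 1, 120), substr(prot$cds[other], 1, 120))
  reads <- data.frame(id = c("single", "fusion"), sample = "S01",
                      sequence = c(r1, r2), stringsAsFactors = FALSE)
  a <- assign_cog(reads, prot)
  expect_false(a$discarded[a$id == "single"])
  expect_equal(a$cog_id[a$id == "single"], prot$cog_id[1])
  expect_equal(a$category[a$id == "single"], prot$cog_category[1])
  expect_true(a$discarded[a$id == "fusion"])
  expect_equal(a$reason[a$id == "fusion"], "multi_cog")
  # homologs competing over the same region: same-COG references from two
  # genera both hit, best score wins, read is kept
  same_cog <- which(prot$cog_id == prot$cog_id[1])
  expect_gt(length(same_cog), 1L)
  idx <- build_index(prot, alphabet = "aa")
  hits <- translated_search(reads[1, ], idx, max_e = 1e-3)
  expect_gt(length(unique(hits$subject)), 1L)
})

test_that("overlapping hits to different groups resolve to the best score", {
  # two different-category proteins nearly identical over the whole read:
  # competing homologs, not a fusion
  set.seed(61)
  aa <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 120,
                     replace = TRUE), collapse = "")
  aa2 <- strsplit(aa, "")[[1]]
  pos <- sample(120, 6)
  aa2[pos] <- vapply(aa2[pos], function(x)
    sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], x), 1), "")
  db <- data.frame(id = c("p1", "p2"), class = "protein", tax_id = 1L,
                   lineage = "B", cog_id = c("COG_A1", "COG_B1"),
                   cog_category = c("A", "B"),
                   sequence = c(aa, paste(aa2, collapse = "")),
                   stringsAsFactors = FALSE)
  tab <- activeflora:::codon_table()
  cds <- paste(vapply(strsplit(aa, "")[[1]], function(a) tab[[a]][1], ""),
               collapse = "")
  reads <- data.frame(id = "q", sample = "S01", sequence = cds,
                      stringsAsFactors = FALSE)
  a <- assign_cog(reads, db)
  expect_false(a$discarded)
  expect_equal(a$cog_id, "COG_A1")  # exact match outscores the mutant
})

test_that("category distributions normalize and recover the injected profile", {
  a <- data.frame(id = paste0("r", 1:5), sample = c("S1", "S1", "S1", "S2", "S2"),
                  cog_id = "x", category = c("G", "G", "C", "I", "I"),
                  score = 1, evalue = 0,
                  discarded = c(FALSE, FALSE, FALSE, FALSE, FALSE),
                  reason = NA, stringsAsFactors = FALSE)
  cd <- category_distribution(a)
  expect_equal(unname(colSums(cd)), c(1, 1))
  expect_equal(cd["G", "S1"], 2 / 3)
  expect_equal(cd["I", "S2"], 1)
  # order invariance
  cd2 <- category_distribution(a[sample(5), ])
  expect_equal(cd, cd2)
  # empty sample flagged
  a$discarded[4:5] <- TRUE
  expect_warning(category_distribution(a), "S2")
})

test_that("rate ratios follow (nc/n)/(Nc/N) and the null is identically 1", {
  db <- data.frame(id = paste0("p", 1:100), class = "protein",
                   cog_id = paste0("COG", 1:100),
                   cog_category = rep(cog_categories(), each = 4),
                   stringsAsFactors = FALSE)
  # direct formula: n_c = 30, n = 100, N_c = 10, N = 100 -> 3.0
  rr0 <- rate_ratios(
    data.frame(id = paste0("r", 1:100), sample = "S1", cog_id = "x",
               category = rep(c("G", "C"), c(30, 70)), score = 1, evalue = 0,
               discarded = FALSE, reason = NA, stringsAsFactors = FALSE),
    db, db_counts = setNames(rep(c(10, 90 / 24), c(1, 24)),
                             c("G", setdiff(cog_categories(), "G"))))
  expect_equal(rr0$ratio[rr0$category == "G"], 3.0)
  # database against itself: every defined ratio is exactly 1
  self <- data.frame(id = db$id, sample = "db", cog_id = db$cog_id,
                     category = db$cog_category, score = 1, evalue = 0,
                     discarded = FALSE, reason = NA, stringsAsFactors = FALSE)
  rr <- rate_ratios(self, db)
  expect_true(all(rr$ratio[rr$defined] == 1))
  expect_equal(sum(rr$n_c), rr$n[1])
  expect_equal(sum(rr$N_c), rr$N[1])
  # absent category -> undefined, not zero
  db2 <- db[db$cog_category != "Z", ]
  rr2 <- rate_ratios(self[self$category != "Z", ], db2)
  expect_true(is.na(rr2$ratio[rr2$category == "Z"]))
  expect_false(rr2$defined[rr2$category == "Z"])
})

test_that("an injected 2x category yields a rate ratio near 2", {
  s <- default_refs()
  spec <- community_spec(n_samples = 2, reads_per_sample = 3000,
                         class_mix = c(SSU = 0, LSU = 0, mRNA = 1, sRNA = 0),
                         seed = 21)
  reads <- length_filter(simulate_reads(spec, s$refs, s$tree))$reads
  prot <- ref_class(s$refs, "protein")
  cogs <- assign_cog(reads, prot)
  expect_gte(sum(!cogs$discarded), 5000)
  rr <- rate_ratios(cogs, prot)
  expect_gt(rr$ratio[rr$category == "G"], 1.8)
  expect_lt(rr$ratio[rr$category == "G"], 2.2)
  expect_lt(rr$ratio[rr$category == "I"], 1)
  # per-sample category recovery of the injected profile
  cd <- category_distribution(cogs)
  spec_p <- spec$cog_profile[rownames(cd)]
  for (smp in colnames(cd))
    expect_lt(sum(abs(cd[, smp] - spec_p / sum(spec_p))), 0.10)
})

test_that("taxon-function matrix separates planted family blocks", {
  a <- data.frame(id = sprintf("r%02d", 1:60), sample = "S1", cog_id = "x",
                  category = rep(c("A", "B", "C", "D", "E", "F"), each = 10),
                  score = 1, evalue = 0, discarded = FALSE, reason = NA,
                  stringsAsFactors = FALSE)
  fam <- ifelse(a$category %in% c("A", "B", "C"), "FamX", "FamY")
  lca <- data.frame(id = a$id, sample = "S1", method = "lca",
                    domain = "B", phylum = "P", class = "C", order = "O",
                    family = fam, genus = "uc", stringsAsFactors = FALSE)
  tf <- taxon_function_matrix(a, lca)
  expect_equal(unname(colSums(tf$matrix)), rep(1, 6))
  # identical profiles merge at height zero
  expect_equal(min(tf$hclust$height), 0)
  # the top split separates {A,B,C} from {D,E,F}
  top <- cutree(tf$hclust, k = 2)
  expect_equal(length(unique(top[c("A", "B", "C")])), 1L)
  expect_equal(length(unique(top[c("D", "E", "F")])), 1L)
  expect_false(top[["A"]] == top[["D"]])
  # unassigned reads enter as their own row, and excluded categories listed
  expect_true(all(c("FamX", "FamY") %in% rownames(tf$matrix)))
  expect_equal(sort(tf$excluded), sort(setdiff(cog_categories(),
                                               unique(a$category))))
})

test_that("sRNA scan: planted consensus, strand symmetry, threshold semantics", {
  s <- small_refs(seed = 6)
  motifs <- build_motif_pwms(s$refs)
  cons <- motifs[[1]]$consensus
  set.seed(71)
  reads <- data.frame(
    id = c("planted", "planted_rc", "random"), sample = "S01",
    sequence = c(paste0(random_dna(40), cons, random_dna(40)),
                 paste0(random_dna(40), revcomp(cons), random_dna(40)),
                 random_dna(140)),
    stringsAsFactors = FALSE)
  sc <- srna_scan(reads, motifs)
  h1 <- sc$hits[sc$hits$family == names(motifs)[1], ]
  expect_true(all(c("planted", "planted_rc") %in% h1$id))
  max_score <- ncol(motifs[[1]]$pwm) * max(motifs[[1]]$pwm)
  expect_equal(h1$score[h1$id == "planted"], max_score, tolerance = 1e-9)
  expect_equal(h1$strand[h1$id == "planted"], "+")
  expect_equal(h1$strand[h1$id == "planted_rc"], "-")
  expect_equal(h1$start[h1$id == "planted"], 40L)
  # raising the threshold above the maximum kills all hits
  m2 <- motifs
  for (i in seq_along(m2)) m2[[i]]$threshold <- max_score + 1
  expect_equal(nrow(srna_scan(reads, m2)$hits), 0L)
  # motifs longer than the read are skipped
  short <- data.frame(id = "s", sample = "S01", sequence = random_dna(20),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(srna_scan(short, motifs)$hits), 0L)
})

test_that("fraction accounting matches a truth-label recount exactly", {
  s <- small_refs(seed = 6)
  spec <- community_spec(n_samples = 2, reads_per_sample = 1200, seed = 31)
  lf <- length_filter(simulate_reads(spec, s$refs, s$tree))
  part <- stepwise_triage(lf$reads, ref_class(s$refs, "SSU"),
                          ref_class(s$refs, "LSU"))
  nr <- lf$reads[lf$reads$id %in%
                   part$per_read$id[part$per_read$class == "non_rRNA"], ]
  idx <- build_index(ref_class(s$refs, "protein"), alphabet = "aa")
  calls <- call_protein_coding(nr, idx)
  contigs <- make_contigs(s$refs, seed = 2)
  maps <- map_to_contigs(nr, contigs)
  unchar <- nr[!nr$id %in% calls$calls$id[calls$calls$protein_coding], ]
  srna <- srna_scan(unchar, build_motif_pwms(s$refs))
  acct <- fraction_accounting(part, calls, maps, srna)
  expect_equal(sum(acct$count), nrow(nr))
  expect_lt(abs(sum(acct$percent) - 100), 0.1)
  # recount from the underlying flags
  pc <- calls$calls$protein_coding[match(nr$id, calls$calls$id)]
  mp <- maps$mapped[match(nr$id, maps$query)]
  expect_equal(acct$count[acct$fraction == "protein_mapped"], sum(pc & mp))
  expect_equal(acct$count[acct$fraction == "uncharacterized_unmapped"],
               sum(!pc & !mp))
  # mismatched universes are a hard error
  expect_error(fraction_accounting(part, calls, maps[-1, ], srna),
               "inconsistent")
})
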