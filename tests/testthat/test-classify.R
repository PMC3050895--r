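test_that("word model probabilities match a brute-force recount", {
  refs <- data.frame(
    id = paste0("r", 1:5),
    class = "SSU", tax_id = c(1L, 1L, 2L, 2L, 3L),
    lineage = c("B;P1;C1;O1;F1;G1", "B;P1;C1;O1;F1;G1",
                "B;P1;C1;O1;F2;G2", "B;P1;C1;O1;F2;G2",
                "B;P2;C2;O2;F3;G3"),
    sequence = vapply(1:5, function(i) random_dna(40, seed = 100 + i), ""),
    stringsAsFactors = FALSE)
  m <- train_word_model(refs, word_size = 4L)
  # recount: words of r1 on both strands, set semantics
  words_of <- function(s) {
    rc <- revcomp(s)
    unique(c(substring(s, 1:(nchar(s) - 3), 4:nchar(s)),
             substring(rc, 1:(nchar(rc) - 3), 4:nchar(rc))))
  }
  all_words <- lapply(refs$sequence, words_of)
  word_id <- function(w) {
    sum((match(strsplit(w, "")[[1]], c("A", "C", "G", "T")) - 1) *
          4^(3:0)) + 1
  }
  for (w in c("ACGT", all_words[[1]][1], all_words[[3]][5])) {
    n_w <- sum(vapply(all_words, function(x) w %in% x, TRUE))
    p_w <- (n_w + 0.5) / (5 + 1)
    expect_equal(m$p_w[word_id(w)], p_w)
    g <- match("G1", m$genera)
    m_gw <- sum(vapply(all_words[1:2], function(x) w %in% x, TRUE))
    expect_equal(exp(m$logp[word_id(w), g]), (m_gw + p_w) / (2 + 1))
  }
  # a word absent everywhere still has positive prior mass
  expect_true(all(m$p_w >= 0.5 / 6))
})

test_that("with a single genus every read is assigned to it", {
  refs <- data.frame(id = "r1", class = "SSU", tax_id = 1L,
                     lineage = "B;P;C;O;F;G",
                     sequence = random_dna(200, seed = 5),
                     stringsAsFactors = FALSE)
  m <- train_word_model(refs)
  reads <- data.frame(id = "q", sample = "S01",
                      sequence = random_dna(80, seed = 9),
                      stringsAsFactors = FALSE)
  cls <- classify_nb(reads, m, seed = 1)
  expect_equal(cls$genus, "G")
  expect_equal(cls$conf_genus, 1)
})

test_that("an exact slice of a family-unique reference gets confidence 1", {
  s <- small_refs(seed = 6)
  ssu <- ref_class(s$refs, "SSU")
  m <- train_word_model(ssu)
  reads <- data.frame(id = "q", sample = "S01",
                      sequence = substr(ssu$sequence[1], 101, 280),
                      stringsAsFactors = FALSE)
  cls <- classify_nb(reads, m, n_bootstrap = 100, seed = 2)
  lin <- strsplit(ssu$lineage[1], ";")[[1]]
  expect_equal(cls$family, lin[5])
  expect_equal(cls$conf_family, 1)
})

test_that("confidence threshold semantics truncate the lineage", {
  s <- small_refs(seed = 6)
  m <- train_word_model(ref_class(s$refs, "SSU"))
  reads <- data.frame(id = "q", sample = "S01",
                      sequence = random_dna(100, seed = 77),
                      stringsAsFactors = FALSE)
  # threshold 1 requires unanimity: any disagreement truncates
  cls <- classify_nb(reads, m, conf_threshold = 1, seed = 3)
  confs <- as.numeric(cls[1, paste0("conf_", tax_ranks())])
  assigned <- as.character(cls[1, tax_ranks()])
  expect_true(all(assigned[confs < 1] == "uc"))
  # once unclassified, deeper ranks stay unclassified
  uc_from <- which(assigned == "uc")
  if (length(uc_from))
    expect_true(all(assigned[seq(min(uc_from), 6)] == "uc"))
})

test_that("confidence is monotone non-increasing with depth", {
  s <- small_refs(seed = 6)
  m <- train_word_model(ref_class(s$refs, "SSU"))
  spec <- community_spec(n_samples = 1, reads_per_sample = 60,
                         class_mix = c(SSU = 1, LSU = 0, mRNA = 0, sRNA = 0),
                         seed = 19)
  reads <- length_filter(simulate_reads(spec, s$refs, s$tree))$reads
  cls <- classify_nb(reads, m, seed = 4)
  conf <- as.matrix(cls[, paste0("conf_", tax_ranks())])
  expect_true(all(apply(conf, 1, function(x) all(diff(x) <= 1e-12))))
})

test_that("LCA retention keeps near-best hits only", {
  tr <- hand_tree()
  refs <- data.frame(id = c("a", "b", "c"), class = "SSU",
                     tax_id = c(11L, 12L, 13L), lineage = "x",
                     sequence = "ACGT", stringsAsFactors = FALSE)
  hits <- data.frame(query = "q", subject = c("a", "b", "c"),
                     score = c(100, 99, 80), stringsAsFactors = FALSE)
  # top 10% window keeps scores >= 90: subjects a and b -> LCA = class C1
  res <- lca_assign(hits, refs, tr)
  expect_equal(res$class, "C1")
  expect_equal(res$order, "uc")
  # all retained hits in one family
  hits2 <- data.frame(query = "q", subject = c("a", "a"),
                      score = c(50, 50), stringsAsFactors = FALSE)
  expect_equal(lca_assign(hits2, refs, tr)$family, "F1")
  # fewer than min_support retained hits -> unassigned
  hits3 <- data.frame(query = "q", subject = "a", score = 10,
                      stringsAsFactors = FALSE)
  expect_equal(lca_assign(hits3, refs, tr)$domain, "uc")
})

test_that("composition normalizes per sample and pools the average", {
  cls <- data.frame(id = paste0("r", 1:6),
                    sample = c("S1", "S1", "S1", "S2", "S2", "S2"),
                    method = "naive_bayes",
                    domain = "B", phylum = "P", class = "C", order = "O",
                    family = c("F1", "F1", "F2", "F1", "uc", "uc"),
                    genus = "uc", stringsAsFactors = FALSE)
  comp <- composition(cls, rank = "family")
  expect_equal(unname(colSums(comp$rel_abund)), rep(1, 3))
  expect_equal(comp$rel_abund["F1", "S1"], 2 / 3)
  # the average column equals pooled counts / pooled total
  expect_equal(unname(comp$rel_abund[, "average"]),
               unname(rowSums(comp$counts) / 6))
  # single-family case
  one <- cls[1:2, ]
  expect_equal(unname(composition(one)$rel_abund["F1", "S1"]), 1)
})

test_that("naive Bayes recovers the true composition and agrees with LCA", {
  s <- small_refs(seed = 6)
  spec <- community_spec(n_samples = 2, reads_per_sample = 800,
                         class_mix = c(SSU = 1, LSU = 0, mRNA = 0, sRNA = 0),
                         seed = 23)
  reads <- length_filter(simulate_reads(spec, s$refs, s$tree))$reads
  ssu <- ref_class(s$refs, "SSU")
  m <- train_word_model(ssu)
  cls <- classify_nb(reads, m, seed = 7)
  # family-level L1 error against the truth labels
  comp <- composition(cls)
  fams <- sort(unique(reads$true_family))
  for (smp in c("S01", "S02")) {
    truth <- prop.table(table(factor(reads$true_family[reads$sample == smp],
                                     fams)))
    inf <- setNames(rep(0, length(fams)), fams)
    got <- intersect(rownames(comp$rel_abund), fams)
    inf[got] <- comp$rel_abund[got, smp]
    expect_lt(sum(abs(inf - as.vector(truth))), 0.10)
  }
  # LCA over the same hits lands on the same families (min_support 1: the
  # synthetic databases hold one reference per genus, so near-best windows
  # usually retain a single hit)
  idx <- build_index(ssu, alphabet = "dna")
  hits <- search_hits(reads, idx, max_e = 1e-6)
  lca <- lca_assign(hits, ssu, s$tree, min_support = 1L,
                    samples = setNames(reads$sample, reads$id))
  shared <- intersect(cls$id, lca$id)
  agree <- mean(cls$family[match(shared, cls$id)] ==
                  lca$family[match(shared, lca$id)])
  expect_gte(agree, 0.8)
})
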