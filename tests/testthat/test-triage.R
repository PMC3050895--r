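test_that("length filter keeps the 60 bp boundary read and preserves order", {
  reads <- data.frame(id = c("a", "b", "c"), sample = "S01",
                      sequence = c(strrep("A", 59), strrep("C", 60),
                                   strrep("G", 61)),
                      stringsAsFactors = FALSE)
  lf <- length_filter(reads)
  expect_equal(lf$reads$id, c("b", "c"))
  expect_equal(lf$dropped, 1L)
  lf2 <- length_filter(reads, min_len = 10)
  expect_equal(lf2$dropped, 0L)
  # dropped count equals a recount from the lengths themselves
  s <- small_refs(seed = 2)
  spec <- community_spec(n_samples = 1, reads_per_sample = 2000, seed = 13)
  sim <- simulate_reads(spec, s$refs, s$tree)
  expect_equal(length_filter(sim)$dropped, sum(nchar(sim$sequence) < 60))
})

test_that("step order wins: a read matching both databases is SSU", {
  set.seed(50)
  shared <- random_dna(300)
  ssu <- data.frame(id = "ssu1", class = "SSU", tax_id = 1L,
                    lineage = "Bacteria;P;C;O;F;G", sequence = shared,
                    stringsAsFactors = FALSE)
  lsu <- data.frame(id = "lsu1", class = "LSU", tax_id = 1L,
                    lineage = "Bacteria;P;C;O;F;G", sequence = shared,
                    stringsAsFactors = FALSE)
  reads <- data.frame(id = "r1", sample = "S01",
                      sequence = substr(shared, 51, 250),
                      stringsAsFactors = FALSE)
  part <- stepwise_triage(reads, ssu, lsu)
  expect_equal(part$per_read$class, "SSU_prok")
})

test_that("18S reads are sub-classed by the best hit's domain", {
  set.seed(51)
  ssu <- data.frame(id = c("bac", "euk"), class = "SSU", tax_id = 1:2,
                    lineage = c("Bacteria;P;C;O;F;G", "Eukaryota;P;C;O;F;G"),
                    sequence = c(random_dna(300), random_dna(300)),
                    stringsAsFactors = FALSE)
  lsu <- data.frame(id = "lsu1", class = "LSU", tax_id = 1L,
                    lineage = "Bacteria;P;C;O;F;G", sequence = random_dna(300),
                    stringsAsFactors = FALSE)
  reads <- data.frame(id = c("r1", "r2"), sample = "S01",
                      sequence = c(substr(ssu$sequence[1], 11, 210),
                                   substr(ssu$sequence[2], 11, 210)),
                      stringsAsFactors = FALSE)
  part <- stepwise_triage(reads, ssu, lsu)
  expect_equal(part$per_read$class, c("SSU_prok", "SSU_euk"))
})

test_that("triage refuses unfiltered reads and empty databases", {
  s <- small_refs(seed = 2)
  reads <- data.frame(id = "r", sample = "S01", sequence = strrep("A", 30),
                      stringsAsFactors = FALSE)
  expect_error(stepwise_triage(reads, ref_class(s$refs, "SSU"),
                               ref_class(s$refs, "LSU")),
               "length-filtered")
})

test_that("partition conservation holds and relaxing e_ssu never loses SSU reads", {
  s <- small_refs(seed = 2)
  spec <- community_spec(n_samples = 2, reads_per_sample = 1500, seed = 17)
  lf <- length_filter(simulate_reads(spec, s$refs, s$tree))
  ssu_idx <- build_index(ref_class(s$refs, "SSU"), alphabet = "dna")
  lsu_idx <- build_index(ref_class(s$refs, "LSU"), alphabet = "dna")
  cl <- c("SSU_prok", "SSU_euk", "LSU", "non_rRNA")
  prev <- 0
  for (e in c(1e-30, 1e-16, 1e-8, 1e-2)) {
    part <- stepwise_triage(lf$reads, ssu_idx, lsu_idx, e_ssu = e)
    expect_equal(rowSums(part$table[, cl]), part$table$total,
                 ignore_attr = TRUE)
    n_ssu <- sum(part$table$SSU_prok + part$table$SSU_euk)
    expect_gte(n_ssu, prev)
    prev <- n_ssu
  }
})

test_that("calibration sets have the stated size, placement and determinism", {
  s <- small_refs(seed = 2)
  cal <- make_calibration_sets(s$refs, n_per_class = 1000, frag_len = 100,
                               seed = 4)
  expect_equal(nrow(cal), 3000L)
  expect_equal(as.vector(table(cal$class)), rep(1000L, 3))
  expect_true(all(nchar(cal$sequence) == 100L))
  expect_identical(cal, make_calibration_sets(s$refs, 1000, 100, seed = 4))
  # full-length fragments reproduce the reference
  one <- data.frame(id = "x", class = "SSU", tax_id = 1L, lineage = "B",
                    sequence = random_dna(100, seed = 1), cds = NA,
                    stringsAsFactors = FALSE)
  one <- rbind(one,
               data.frame(id = c("y", "z"), class = c("LSU", "protein"),
                          tax_id = 1L, lineage = "B",
                          sequence = c(random_dna(120), strrep("M", 40)),
                          cds = c(NA, random_dna(120)),
                          stringsAsFactors = FALSE))
  cal1 <- make_calibration_sets(one, n_per_class = 5, frag_len = 100, seed = 2)
  expect_true(all(cal1$sequence[cal1$class == "SSU"] == one$sequence[1]))
})

test_that("fragment start positions are uniform (chi-square, 10 bins)", {
  s <- small_refs(seed = 2)
  cal <- make_calibration_sets(s$refs, n_per_class = 10000, frag_len = 100,
                               seed = 11)
  starts <- cal$start[cal$class == "SSU"]  # SSU refs are 400 bp here
  bins <- cut(starts, breaks = seq(0, 301, length.out = 11),
              include.lowest = TRUE, right = FALSE)
  p <- suppressWarnings(chisq.test(table(bins))$p.value)
  expect_gt(p, 0.001)
})

test_that("threshold sweep selects sanely on separable references", {
  s <- small_refs(seed = 2)
  cal <- make_calibration_sets(s$refs, n_per_class = 300, seed = 5)
  rep <- sweep_thresholds(cal, ref_class(s$refs, "SSU"),
                          ref_class(s$refs, "LSU"))
  tab <- rep$table
  for (db in c("ssu", "lsu")) {
    sel <- tab[tab$db == db & tab$evalue == rep$selected[[db]], ]
    expect_equal(sel$contamination, 0)
    expect_gte(sel$sensitivity, 0.99)
  }
  # calibration sanity: strictest grid point loses nothing here but at
  # E -> infinity contamination grows, sensitivity is already 1
  expect_gt(tab$contamination[tab$db == "ssu" & tab$evalue == 1], 0)
  # single-value grid selects that value
  one <- sweep_thresholds(cal, ref_class(s$refs, "SSU"),
                          ref_class(s$refs, "LSU"), grid = 1e-10)
  expect_equal(unname(one$selected), c(1e-10, 1e-10))
})

test_that("planted SSU contamination in mRNA forces a stricter SSU threshold", {
  s <- small_refs(seed = 2)
  cal <- make_calibration_sets(s$refs, n_per_class = 300, seed = 5)
  idx <- which(cal$class == "mRNA")[1:30]   # 10% of the mRNA fragments
  ssu_seq <- s$refs$sequence[s$refs$class == "SSU"][1]
  ins <- substr(ssu_seq, 201, 240)
  cal$sequence[idx] <- paste0(substr(cal$sequence[idx], 1, 30), ins,
                              substr(cal$sequence[idx], 31, 90))
  rep <- sweep_thresholds(cal, ref_class(s$refs, "SSU"),
                          ref_class(s$refs, "LSU"))
  expect_lt(rep$selected[["ssu"]], rep$selected[["lsu"]])
})
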