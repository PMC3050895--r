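# End-to-end orchestration: filter -> SSU -> LSU -> (16S classification,
# diversity, ordination) in parallel with (protein call -> COG -> ratios ->
# taxon-function matrix; uncharacterized -> sRNA -> accounting).

#' Pipeline run configuration
#'
#' Bundles every stated threshold of the analysis (length cutoff 60 bp,
#' SSU/LSU E-values 1e-16 and 1e-4, protein and COG E-values 1e-3, contig
#' mapping at 80% of the read length and 90% identity, naive-Bayes
#' confidence 0.5) together with the simulation layout and the master seed.
#' The configuration round-trips losslessly through JSON.
#'
#' @param n_phyla,families_per_phylum Taxonomy layout for the simulated
#'   community.
#' @param spec A [community_spec()]; its own seed is replaced by a
#'   stage-derived seed at run time.
#' @param refs_args Extra arguments passed to [evolve_references()].
#' @param min_len,e_ssu,e_lsu,e_protein,e_cog,map_fraction,map_identity,nb_conf
#'   Thresholds (documented defaults).
#' @param n_bootstrap Bootstrap trials for the 16S classifier.
#' @param seed Master seed: per-stage seeds are derived from it by hashing
#'   the stage name, so any stage can be rerun in isolation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_phyla = 5L, families_per_phylum = 4L,
                       spec = community_spec(),
                       refs_args = list(),
                       min_len = 60L, e_ssu = 1e-16, e_lsu = 1e-4,
                       e_protein = 1e-3, e_cog = 1e-3,
                       map_fraction = 0.8, map_identity = 0.9,
                       nb_conf = 0.5, n_bootstrap = 100L, seed = 1L) {
  structure(list(n_phyla = as.integer(n_phyla),
                 families_per_phylum = as.integer(families_per_phylum),
                 spec = spec, refs_args = refs_args,
                 min_len = as.integer(min_len),
                 e_ssu = e_ssu, e_lsu = e_lsu, e_protein = e_protein,
                 e_cog = e_cog, map_fraction = map_fraction,
                 map_identity = map_identity, nb_conf = nb_conf,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Stage seed derived from the master seed
#'
#' Deterministic splitting rule: a small integer hash of the stage name is
#' combined with the master seed so each stage has an independent,
#' reproducible stream.
#'
#' @param master Master seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 7919 + h * 131) %% 2147483647)
}

#' Run the full pipeline on a simulated community
#'
#' Executes the stage order of the analysis: simulate (taxonomy, references,
#' reads), length filter, SSU then LSU triage, naive-Bayes classification of
#' the prokaryotic SSU reads with family-level composition, diversity and
#' correspondence analysis; in the functional arm, protein-coding calls on
#' the non-rRNA fraction, COG assignment with the multi-COG discard rule,
#' rate ratios against the reference database, the taxon-by-function matrix,
#' contig mapping, the sRNA scan of the uncharacterized fraction, and the
#' four-way accounting. Identical configuration and seed give an identical
#' bundle.
#'
#' @param config A [run_config()].
#' @return A list of class `report_bundle`: `table1`, `composition`,
#'   `diversity`, `ordination`, `category_distribution`, `rate_ratios`,
#'   `taxon_function`, `accounting`, `srna_families`, `manifest`, plus the
#'   underlying `partition`, `reads` truth labels and `refs` for auditing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tree <- build_taxonomy(config$n_phyla, config$families_per_phylum)
  refs <- do.call(evolve_references,
                  c(list(tree = tree,
                         seed = stage_seed(config$seed, "references")),
                    config$refs_args))
  spec <- config$spec
  spec$seed <- stage_seed(config$seed, "reads")
  reads <- simulate_reads(spec, refs, tree)

  lf <- length_filter(reads, config$min_len)
  part <- stepwise_triage(lf$reads, ref_class(refs, "SSU"),
                          ref_class(refs, "LSU"),
                          e_ssu = config$e_ssu, e_lsu = config$e_lsu,
                          min_len = config$min_len)
  log_stage("triage", nrow(lf$reads), nrow(part$per_read))

  # taxonomic arm: 16S transcripts
  ssu_ids <- part$per_read$id[part$per_read$class == "SSU_prok"]
  ssu_reads <- lf$reads[lf$reads$id %in% ssu_ids, , drop = FALSE]
  model <- train_word_model(ref_class(refs, "SSU"))
  cls <- classify_nb(ssu_reads, model, n_bootstrap = config$n_bootstrap,
                     conf_threshold = config$nb_conf,
                     seed = stage_seed(config$seed, "classify"))
  comp <- composition(cls, rank = "family")
  divers <- diversity_table(comp$counts)
  ord <- correspondence_analysis(t(comp$counts))
  log_stage("classify", nrow(ssu_reads), nrow(cls))

  # functional arm: non-rRNA fraction
  nr_ids <- part$per_read$id[part$per_read$class == "non_rRNA"]
  nr_reads <- lf$reads[lf$reads$id %in% nr_ids, , drop = FALSE]
  prot_db <- ref_class(refs, "protein")
  prot_idx <- build_index(prot_db, alphabet = "aa")
  calls <- call_protein_coding(nr_reads, prot_idx, max_e = config$e_protein)
  prot_reads <- nr_reads[nr_reads$id %in%
                           calls$calls$id[calls$calls$protein_coding], ,
                         drop = FALSE]
  hits <- translated_search(prot_reads, prot_idx, max_e = config$e_cog)
  cogs <- assign_cog(prot_reads, prot_db, max_e = config$e_cog, hits = hits)
  catdist <- category_distribution(cogs)
  ratios <- rate_ratios(cogs, prot_db)
  lca <- lca_assign(hits, prot_db, tree,
                    samples = setNames(prot_reads$sample, prot_reads$id))
  txf <- taxon_function_matrix(cogs, lca)
  log_stage("function", nrow(nr_reads), sum(!cogs$discarded))

  contigs <- make_contigs(refs, seed = stage_seed(config$seed, "contigs"))
  maps <- map_to_contigs(nr_reads, contigs,
                         min_fraction = config$map_fraction,
                         min_identity = config$map_identity)
  unchar <- nr_reads[!nr_reads$id %in%
                       calls$calls$id[calls$calls$protein_coding], ,
                     drop = FALSE]
  srna <- srna_scan(unchar, build_motif_pwms(refs))
  acct <- fraction_accounting(part, calls, maps, srna)
  srna_fam <- if (nrow(srna$hits))
    as.data.frame.matrix(table(srna$hits$family, srna$hits$sample))
  else data.frame()
  log_stage("accounting", length(nr_ids), nrow(acct))

  manifest <- list(package = "activeflora",
                   version = as.character(utils::packageVersion("activeflora")),
                   seed = config$seed,
                   stage_seeds = vapply(c("references", "reads", "classify",
                                          "contigs"),
                                        function(s) stage_seed(config$seed, s),
                                        0L),
                   config_hash = config_hash(config))
  structure(list(table1 = part$table, composition = comp,
                 diversity = divers, ordination = ord,
                 category_distribution = catdist, rate_ratios = ratios,
                 taxon_function = txf, accounting = acct,
                 srna_families = srna_fam, manifest = manifest,
                 partition = part, classification = cls, reads = reads,
                 refs = refs, tree = tree, protein_calls = calls,
                 cog_assignments = cogs, contig_maps = maps, srna = srna),
            class = "report_bundle")
}

log_stage <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Validate the cross-consistency of a report bundle
#'
#' Checks the invariants every bundle must satisfy: the Table-1-style
#' partition sums (class counts add to the per-sample total), composition
#' and category-distribution column normalization, the rate-ratio count
#' sums, the accounting percentages adding to 100, and the consistency of
#' the read universes across tables.
#'
#' @param bundle A `report_bundle`.
#' @return Character vector of violated checks (empty means pass).
#' @export
validate_bundle <- function(bundle) {
  bad <- character(0)
  t1 <- bundle$table1
  cl <- c("SSU_prok", "SSU_euk", "LSU", "non_rRNA")
  if (!all(rowSums(t1[, cl]) == t1$total))
    bad <- c(bad, "partition_sum")
  rel <- bundle$composition$rel_abund
  if (any(abs(colSums(rel) - 1) > 1e-9))
    bad <- c(bad, "composition_norm")
  cd <- bundle$category_distribution
  if (any(abs(colSums(cd) - 1) > 1e-9))
    bad <- c(bad, "category_norm")
  rr <- bundle$rate_ratios
  if (sum(rr$n_c) != rr$n[1L] || sum(rr$N_c) != rr$N[1L])
    bad <- c(bad, "rate_ratio_sums")
  if (abs(sum(bundle$accounting$percent) - 100) > 0.1)
    bad <- c(bad, "accounting_sum")
  if (!setequal(colnames(bundle$composition$counts),
                t1$sample) ||
      attr(bundle$accounting, "n_non_rrna") != sum(t1$non_rRNA))
    bad <- c(bad, "universe")
  bad
}

#' Write a report bundle to a directory
#'
#' Emits the Table-1 analog, composition, diversity, category distribution,
#' rate ratios, taxon-by-function matrix (TSV + Newick dendrogram),
#' accounting, sRNA family counts and a JSON manifest. Output is
#' deterministic for a fixed configuration and seed.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, rn = FALSE) {
    if (rn) x <- data.frame(name = rownames(x), x, row.names = NULL,
                            check.names = FALSE)
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(bundle$table1, "table1.tsv")
  wt(bundle$composition$rel_abund, "composition.tsv", rn = TRUE)
  wt(bundle$diversity, "diversity.tsv")
  wt(round(bundle$category_distribution, 6), "category_distribution.tsv",
     rn = TRUE)
  wt(bundle$rate_ratios, "rate_ratios.tsv")
  wt(round(bundle$taxon_function$matrix, 6), "taxon_function.tsv", rn = TRUE)
  writeLines(bundle$taxon_function$newick, file.path(dir, "taxon_function.nwk"))
  wt(as.data.frame(bundle$accounting), "accounting.tsv")
  if (nrow(bundle$srna_families))
    wt(bundle$srna_families, "srna_families.tsv", rn = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
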