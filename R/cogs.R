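# Functional profiling of the non-rRNA fraction: protein-coding calls, COG
# assignment with the multi-COG discard rule, category distributions,
# rate-ratio enrichment, taxon-by-function matrix, sRNA scan, and the
# accounting of the uncharacterized fraction.

#' Call putative protein-coding reads
#'
#' A non-rRNA read is a putative protein-coding sequence iff its six-frame
#' translated search yields any hit with E-value at most `max_e` (default
#' 1e-3); the rest is the uncharacterized fraction.
#'
#' @param reads Non-rRNA reads (`id`, `sample`, `sequence`).
#' @param protein_index Protein [build_index()] (or a protein
#'   `reference_set`).
#' @param scheme Protein [scoring_scheme()].
#' @param max_e E-value threshold.
#' @return List of class `protein_calls`: `calls` (per read: `id`, `sample`,
#'   `protein_coding`, best-hit columns) and the threshold used.
#' @export
call_protein_coding <- function(reads, protein_index,
                                scheme = protein_scheme(), max_e = 1e-3) {
  idx <- if (inherits(protein_index, "seed_index")) protein_index
         else build_index(protein_index, alphabet = "aa")
  calls <- data.frame(id = reads$id, sample = reads$sample,
                      protein_coding = FALSE, best_subject = NA_character_,
                      best_score = NA_real_, best_evalue = NA_real_,
                      stringsAsFactors = FALSE)
  if (nrow(reads) && idx$n_refs > 0L) {
    hits <- translated_search(reads, idx, scheme, max_e = max_e,
                              best_only = TRUE)
    if (nrow(hits)) {
      i <- match(hits$query, calls$id)
      calls$protein_coding[i] <- TRUE
      calls$best_subject[i] <- hits$subject
      calls$best_score[i] <- hits$score
      calls$best_evalue[i] <- hits$evalue
    }
  }
  structure(list(calls = calls, max_e = max_e), class = "protein_calls")
}

#' COG assignment with the multi-COG discard rule
#'
#' Hits with E-value at most `max_e` are grouped by orthologous group. If
#' two or more distinct groups are supported on effectively disjoint parts
#' of the read — their best query intervals overlap by less than
#' `overlap_fraction` of the shorter interval — the read looks like a
#' chimera or fusion and is discarded (`multi_cog`). Groups competing over
#' the same region are homologs: the best-scoring group wins and the read is
#' assigned to its functional category.
#'
#' @param reads Putative protein-coding reads (`id`, `sample`, `sequence`).
#' @param cog_db Protein `reference_set` rows carrying `cog_id` and
#'   `cog_category`.
#' @param scheme Protein [scoring_scheme()].
#' @param max_e E-value threshold (default 1e-3).
#' @param overlap_fraction Interval-overlap fraction below which two groups
#'   count as non-overlapping signals (default 0.5).
#' @param cog_index Optional prebuilt protein index over `cog_db`.
#' @param hits Optional precomputed [translated_search()] hit table for
#'   `reads` against `cog_db` (it is re-filtered at `max_e`).
#' @return Data frame of class `cog_assignment`: `id`, `sample`, `cog_id`,
#'   `category`, `score`, `evalue`, `discarded`, `reason`
#'   (`no_hit`/`multi_cog`/NA).
#' @export
assign_cog <- function(reads, cog_db, scheme = protein_scheme(),
                       max_e = 1e-3, overlap_fraction = 0.5,
                       cog_index = NULL, hits = NULL) {
  cog_of <- setNames(cog_db$cog_id, cog_db$id)
  cat_of <- setNames(cog_db$cog_category, cog_db$id)
  out <- data.frame(id = reads$id, sample = reads$sample,
                    cog_id = NA_character_, category = NA_character_,
                    score = NA_real_, evalue = NA_real_,
                    discarded = TRUE, reason = "no_hit",
                    stringsAsFactors = FALSE)
  if (!nrow(reads)) { class(out) <- c("cog_assignment", "data.frame"); return(out) }
  if (is.null(hits)) {
    idx <- if (!is.null(cog_index)) cog_index
           else build_index(cog_db, alphabet = "aa")
    hits <- translated_search(reads, idx, scheme, max_e = max_e)
  } else {
    hits <- hits[hits$evalue <= max_e & hits$query %in% reads$id, , drop = FALSE]
  }
  if (nrow(hits)) {
    hits$cog <- unname(cog_of[hits$subject])
    by_q <- split(seq_len(nrow(hits)), hits$query)
    for (q in names(by_q)) {
      rows <- by_q[[q]]
      # best hit per orthologous group, with its query interval
      o <- rows[order(-hits$score[rows])]
      first <- o[!duplicated(hits$cog[o])]
      i <- match(q, out$id)
      if (length(first) > 1L) {
        b <- first[1L]
        disjoint <- FALSE
        for (j in first[-1L]) {
          ov <- min(hits$qend[b], hits$qend[j]) - max(hits$qstart[b], hits$qstart[j])
          shorter <- min(hits$qend[b] - hits$qstart[b],
                         hits$qend[j] - hits$qstart[j])
          if (ov < overlap_fraction * shorter) { disjoint <- TRUE; break }
        }
        if (disjoint) {
          out$discarded[i] <- TRUE
          out$reason[i] <- "multi_cog"
          next
        }
      }
      b <- first[1L]
      out$cog_id[i] <- hits$cog[b]
      out$category[i] <- unname(cat_of[hits$subject[b]])
      out$score[i] <- hits$score[b]
      out$evalue[i] <- hits$evalue[b]
      out$discarded[i] <- FALSE
      out$reason[i] <- NA_character_
    }
  }
  class(out) <- c("cog_assignment", "data.frame")
  out
}

#' Per-sample COG category distribution
#'
#' Proportions over non-discarded assignments; every sample column sums
#' to 1. Samples with no assignments are flagged by a warning and dropped.
#'
#' @param assignments A `cog_assignment` table.
#' @return Category x sample proportion matrix (rows restricted to observed
#'   categories, ordered by the standard category alphabet).
#' @export
category_distribution <- function(assignments) {
  a <- assignments[!assignments$discarded, , drop = FALSE]
  empty <- setdiff(unique(assignments$sample), unique(a$sample))
  if (length(empty))
    warning("samples with no COG assignment: ", paste(empty, collapse = ", "))
  if (!nrow(a)) stop("no non-discarded assignment in any sample")
  tab <- table(factor(a$category, levels = COG_CATEGORY_LETTERS), a$sample)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  prop.table(unclass(tab), margin = 2L)
}

#' Rate-ratio enrichment of COG categories
#'
#' For each category c the rate ratio is `(n_c / n) / (N_c / N)`: the
#' category's share among the pooled sample assignments relative to its
#' share in the reference database, with `N_c` counted one per database
#' protein's category (per-hit weighting is available via `db_counts`).
#' Values above 1 flag over-representation. Categories absent from the
#' database get an undefined (NA) ratio, flagged, rather than zero.
#'
#' @param assignments A `cog_assignment` table (pooled over samples).
#' @param cog_db Protein `reference_set` (the database being compared
#'   against).
#' @param db_counts Optional named per-category database counts overriding
#'   the per-protein tally.
#' @return Data frame of class `rate_ratio_table`: `category`, `n_c`, `n`,
#'   `N_c`, `N`, `ratio`, `defined`.
#' @export
rate_ratios <- function(assignments, cog_db, db_counts = NULL) {
  a <- assignments[!assignments$discarded, , drop = FALSE]
  n_c <- table(factor(a$category, levels = COG_CATEGORY_LETTERS))
  if (is.null(db_counts)) {
    prot <- cog_db[cog_db$class == "protein" | is.na(cog_db$class), , drop = FALSE]
    db_counts <- table(factor(prot$cog_category, levels = COG_CATEGORY_LETTERS))
  } else {
    db_counts <- db_counts[COG_CATEGORY_LETTERS]
    db_counts[is.na(db_counts)] <- 0
  }
  n <- sum(n_c)
  N <- sum(db_counts)
  if (N == 0) stop("empty reference database")
  ratio <- ifelse(db_counts > 0,
                  (as.vector(n_c) / n) / (as.vector(db_counts) / N),
                  NA_real_)
  out <- data.frame(category = COG_CATEGORY_LETTERS,
                    n_c = as.vector(n_c), n = n,
                    N_c = as.vector(db_counts), N = N,
                    ratio = as.vector(ratio),
                    defined = as.vector(db_counts) > 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("rate_ratio_table", "data.frame")
  out
}

#' Taxon-by-function matrix with category clustering
#'
#' Joins COG assignments with family-level taxonomic assignments (reads
#' unclassified at family level enter as `"unassigned"` so columns
#' normalize honestly), normalizes each category column to the family
#' proportions contributing to it, and clusters categories by average
#' linkage on the L1 distance between their family profiles. Leaf order ties
#' break on the category letter. Categories with zero reads are excluded and
#' listed.
#'
#' @param assignments A `cog_assignment` table.
#' @param lca_results A `classification` table for the same reads.
#' @return List of class `taxon_function`: `matrix` (family x category,
#'   columns sum to 1), `hclust`, `newick`, `excluded`.
#' @export
taxon_function_matrix <- function(assignments, lca_results) {
  a <- assignments[!assignments$discarded, , drop = FALSE]
  fam <- setNames(lca_results$family, lca_results$id)
  f <- unname(fam[a$id])
  f[is.na(f) | f == "uc"] <- "unassigned"
  tab <- table(factor(f), factor(a$category, levels = COG_CATEGORY_LETTERS))
  excluded <- colnames(tab)[colSums(tab) == 0]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  m <- prop.table(unclass(tab), margin = 2L)
  if (ncol(m) >= 2L) {
    d <- dist(t(m), method = "manhattan")
    hc <- hclust(d, method = "average")
    # deterministic leaf order: reorder ties by category letter
    hc <- stats::as.hclust(stats::reorder(stats::as.dendrogram(hc),
                                          match(colnames(m), COG_CATEGORY_LETTERS),
                                          agglo.FUN = mean))
    nwk <- ape::write.tree(ape::as.phylo(hc))
  } else {
    hc <- NULL
    nwk <- if (ncol(m) == 1L) paste0(colnames(m)[1L], ";") else ";"
  }
  structure(list(matrix = m, hclust = hc, newick = nwk, excluded = excluded),
            class = "taxon_function")
}

#' Scan uncharacterized reads for sRNA motifs
#'
#' Scores every read window against each family's log-odds position weight
#' matrix on both strands and reports hits whose best window reaches the
#' family threshold. Motifs longer than the read are skipped for that read.
#'
#' @param reads Uncharacterized reads (`id`, `sample`, `sequence`).
#' @param motifs A list from [build_motif_pwms()]: per family `pwm`
#'   (4 x L log-odds) and `threshold`.
#' @return List of class `srna_scan`: `hits` (`id`, `sample`, `family`,
#'   `score`, `start`, `end`, `strand`), `fraction` of reads with at least
#'   one hit, `n_reads`.
#' @export
srna_scan <- function(reads, motifs) {
  hits <- list()
  for (fam in names(motifs)) {
    m <- motifs[[fam]]
    if (!nrow(reads)) next
    sc <- cpp_pwm_scan(reads$sequence, m$pwm)
    keep <- which(sc$valid & sc$score >= m$threshold)
    if (length(keep))
      hits[[fam]] <- data.frame(id = reads$id[keep],
                                sample = reads$sample[keep],
                                family = fam, score = sc$score[keep],
                                start = sc$start[keep],
                                end = sc$start[keep] + ncol(m$pwm),
                                strand = sc$strand[keep],
                                stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(id = character(), sample = character(), family = character(),
               score = numeric(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  frac <- if (nrow(reads)) length(unique(hits$id)) / nrow(reads) else 0
  structure(list(hits = hits, fraction = frac, n_reads = nrow(reads)),
            class = "srna_scan")
}

#' Accounting of the non-ribosomal fraction
#'
#' Partitions the non-rRNA reads four ways — protein-coding and found in
#' the contig catalogue, protein-coding and absent from it, uncharacterized
#' and found, uncharacterized and absent — with percentages over the
#' non-rRNA total, plus the share of the uncharacterized fraction assigned
#' to sRNA families. All inputs must come from the same pipeline run: a
#' mismatch between the read universes is a hard error.
#'
#' @param partition A `read_partition` from [stepwise_triage()].
#' @param protein_calls A `protein_calls` object for the non-rRNA reads.
#' @param contig_maps A [map_to_contigs()] result for the non-rRNA reads.
#' @param srna A `srna_scan` over the uncharacterized reads.
#' @return Data frame of class `fraction_accounting`: `fraction`, `count`,
#'   `percent`; attribute `srna_share` (percent of uncharacterized reads
#'   with an sRNA hit).
#' @export
fraction_accounting <- function(partition, protein_calls, contig_maps, srna) {
  nr <- partition$per_read$id[partition$per_read$class == "non_rRNA"]
  if (!setequal(nr, protein_calls$calls$id) ||
      !setequal(nr, contig_maps$query))
    stop("inconsistent read universes between triage, protein calls and contig maps")
  pc <- setNames(protein_calls$calls$protein_coding, protein_calls$calls$id)[nr]
  mp <- setNames(contig_maps$mapped, contig_maps$query)[nr]
  unchar <- names(pc)[!pc]
  if (!all(srna$hits$id %in% unchar))
    stop("sRNA hits outside the uncharacterized fraction")
  n <- length(nr)
  cells <- c(protein_mapped = sum(pc & mp),
             protein_unmapped = sum(pc & !mp),
             uncharacterized_mapped = sum(!pc & mp),
             uncharacterized_unmapped = sum(!pc & !mp))
  out <- data.frame(fraction = names(cells), count = as.vector(cells),
                    percent = 100 * as.vector(cells) / n,
                    stringsAsFactors = FALSE)
  srna_share <- if (length(unchar))
    100 * length(unique(srna$hits$id)) / length(unchar) else 0
  structure(out, srna_share = srna_share, n_non_rrna = n,
            class = c("fraction_accounting", "data.frame"))
}
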