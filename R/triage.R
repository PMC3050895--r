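# Step-wise read sorting: length filter -> SSU search -> LSU search ->
# non-rRNA remainder, plus the E-value threshold calibration sweep.

#' Length filter
#'
#' Reads shorter than `min_len` are dropped before any homology step; the
#' boundary read of exactly `min_len` bases is retained. Order is preserved.
#'
#' @param reads A `read_set`-style data frame with `sequence`.
#' @param min_len Minimum retained length (default 60, the analysis cutoff).
#' @return `list(reads = retained data frame, dropped = count dropped)`.
#' @export
length_filter <- function(reads, min_len = 60L) {
  if (min_len < 1) stop("min_len must be >= 1")
  keep <- nchar(reads$sequence) >= min_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "abundance") <- attr(reads, "abundance")
  class(out) <- class(reads)
  list(reads = out, dropped = sum(!keep))
}

ref_domain_lookup <- function(refs) {
  setNames(vapply(strsplit(refs$lineage, ";", fixed = TRUE), `[`, "", 1L),
           refs$id)
}

#' Step-wise rRNA/mRNA triage
#'
#' Length-filtered reads are first compared to the SSU database: any hit
#' with E-value at most `e_ssu` classes the read as SSU (sub-classed
#' prokaryotic 16S vs eukaryotic 18S by the best hit's domain). Remaining
#' reads are compared to the LSU database at `e_lsu`; the remainder is the
#' non-rRNA fraction carried into functional analysis. Step order wins: a
#' read matching both databases is SSU.
#'
#' @param reads Length-filtered reads (`id`, `sample`, `sequence`); an error
#'   is raised if any read is shorter than `min_len`.
#' @param ssu_db,lsu_db `reference_set` rows (class SSU / LSU) or prebuilt
#'   DNA [build_index()] objects whose reference ids resolve in `refs`.
#' @param e_ssu,e_lsu E-value thresholds (defaults 1e-16 and 1e-4, the
#'   calibrated values).
#' @param scheme Nucleotide [scoring_scheme()].
#' @param min_len Enforced precondition on read length.
#' @return An object of class `read_partition`: `per_read` (id, sample,
#'   class in SSU_prok/SSU_euk/LSU/non_rRNA, best-hit subject and E-value)
#'   and `table` (per-sample counts with a `total` column).
#' @export
stepwise_triage <- function(reads, ssu_db, lsu_db, e_ssu = 1e-16,
                            e_lsu = 1e-4, scheme = nucleotide_scheme(),
                            min_len = 60L) {
  if (nrow(reads) == 0L) stop("no reads to triage")
  if (any(nchar(reads$sequence) < min_len))
    stop("reads must be length-filtered (>= ", min_len, " bp) before triage")
  ssu_dom <- NULL
  if (inherits(ssu_db, "reference_set") || (is.data.frame(ssu_db) && "lineage" %in% names(ssu_db)))
    ssu_dom <- ref_domain_lookup(ssu_db)
  ssu_idx <- if (inherits(ssu_db, "seed_index")) ssu_db else build_index(ssu_db, alphabet = "dna")
  lsu_idx <- if (inherits(lsu_db, "seed_index")) lsu_db else build_index(lsu_db, alphabet = "dna")
  if (ssu_idx$n_refs == 0L || lsu_idx$n_refs == 0L)
    stop("both rRNA databases must be non-empty")

  cls <- rep("non_rRNA", nrow(reads))
  best_subject <- rep(NA_character_, nrow(reads))
  best_e <- rep(NA_real_, nrow(reads))

  sh <- search_hits(reads, ssu_idx, scheme, max_e = e_ssu, best_only = TRUE)
  if (nrow(sh)) {
    i <- match(sh$query, reads$id)
    dom <- if (is.null(ssu_dom)) rep("Bacteria", nrow(sh)) else ssu_dom[sh$subject]
    cls[i] <- ifelse(!is.na(dom) & dom == "Eukaryota", "SSU_euk", "SSU_prok")
    best_subject[i] <- sh$subject
    best_e[i] <- sh$evalue
  }
  rest <- which(cls == "non_rRNA")
  if (length(rest)) {
    lh <- search_hits(reads[rest, , drop = FALSE], lsu_idx, scheme,
                      max_e = e_lsu, best_only = TRUE)
    if (nrow(lh)) {
      i <- match(lh$query, reads$id)
      cls[i] <- "LSU"
      best_subject[i] <- lh$subject
      best_e[i] <- lh$evalue
    }
  }
  per_read <- data.frame(id = reads$id, sample = reads$sample, class = cls,
                         best_subject = best_subject, best_evalue = best_e,
                         stringsAsFactors = FALSE)
  structure(list(per_read = per_read,
                 table = partition_table(per_read),
                 params = list(e_ssu = e_ssu, e_lsu = e_lsu,
                               min_len = min_len)),
            class = "read_partition")
}

partition_table <- function(per_read) {
  lv <- c("SSU_prok", "SSU_euk", "LSU", "non_rRNA")
  tab <- table(factor(per_read$class, levels = lv), per_read$sample)
  out <- as.data.frame.matrix(t(tab))
  out <- data.frame(sample = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$total <- rowSums(out[, lv])
  out
}

# ---- calibration ----------------------------------------------------------

#' Calibration fragment sets
#'
#' Draws `n_per_class` fragments of `frag_len` bases uniformly from the SSU,
#' LSU and mRNA (protein coding sequence) references, mirroring the
#' 100 bp test sets used to choose the database thresholds.
#'
#' @param refs A `reference_set`.
#' @param n_per_class Fragments per class.
#' @param frag_len Fragment length in bp.
#' @param seed Integer seed.
#' @return Data frame `id`, `class` (SSU/LSU/mRNA), `sequence`.
#' @export
make_calibration_sets <- function(refs, n_per_class = 1000L, frag_len = 100L,
                                  seed = 0L) {
  set.seed(seed)
  pools <- list(SSU = refs$sequence[refs$class == "SSU"],
                LSU = refs$sequence[refs$class == "LSU"],
                mRNA = refs$cds[refs$class == "protein"])
  out <- lapply(names(pools), function(cl) {
    pool <- pools[[cl]]
    pool <- pool[!is.na(pool) & nchar(pool) >= frag_len]
    if (!length(pool)) stop("no ", cl, " reference of length >= ", frag_len)
    src <- pool[sample.int(length(pool), n_per_class, replace = TRUE)]
    start <- floor(runif(n_per_class) * (nchar(src) - frag_len + 1L)) + 1L
    data.frame(id = sprintf("%s_frag_%04d", cl, seq_len(n_per_class)),
               class = cl, sequence = substr(src, start, start + frag_len - 1L),
               start = start - 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Default E-value grid for the calibration sweep
#' @return Ascending numeric grid.
#' @export
default_evalue_grid <- function() {
  c(1e-30, 1e-24, 1e-20, 1e-16, 1e-12, 1e-8, 1e-4, 1e-2, 1)
}

#' Threshold calibration sweep
#'
#' Each fragment set is searched against both rRNA databases once; for every
#' grid value and database, sensitivity is the fraction of in-class
#' fragments accepted and cross-contamination the out-of-class acceptance
#' rate averaged over the two foreign classes. The selected threshold per
#' database is lexicographic: minimum contamination, then maximum
#' sensitivity, then the largest (least stringent) E among ties — clean
#' calibration fragments understate the stringency cost on error-bearing
#' reads, so gratuitous stringency is never chosen.
#'
#' @param cal Calibration fragments from [make_calibration_sets()].
#' @param ssu_db,lsu_db Reference sets or DNA indexes.
#' @param grid Ascending E-value grid.
#' @param scheme Nucleotide [scoring_scheme()].
#' @return An object of class `calibration_report`: `table` (db, evalue,
#'   sensitivity, contamination, per-class acceptance counts) and `selected`
#'   (named vector, one threshold per database).
#' @export
sweep_thresholds <- function(cal, ssu_db, lsu_db, grid = default_evalue_grid(),
                             scheme = nucleotide_scheme()) {
  if (!length(grid)) stop("grid must be non-empty")
  if (is.unsorted(grid)) stop("grid must be ascending")
  dbs <- list(
    ssu = if (inherits(ssu_db, "seed_index")) ssu_db else build_index(ssu_db, alphabet = "dna"),
    lsu = if (inherits(lsu_db, "seed_index")) lsu_db else build_index(lsu_db, alphabet = "dna"))
  in_class <- c(ssu = "SSU", lsu = "LSU")
  n_class <- table(cal$class)
  rows <- list()
  selected <- c(ssu = NA_real_, lsu = NA_real_)
  for (db in names(dbs)) {
    hits <- search_hits(cal, dbs[[db]], scheme, max_e = max(grid),
                        best_only = TRUE)
    best_e <- setNames(rep(Inf, nrow(cal)), cal$id)
    best_e[hits$query] <- hits$evalue
    cls <- cal$class[match(names(best_e), cal$id)]
    tab <- do.call(rbind, lapply(grid, function(e) {
      acc <- tapply(best_e <= e, cls, sum)
      acc[is.na(acc)] <- 0
      foreign <- setdiff(names(n_class), in_class[[db]])
      data.frame(db = db, evalue = e,
                 sensitivity = acc[[in_class[[db]]]] / n_class[[in_class[[db]]]],
                 contamination = mean(acc[foreign] / as.vector(n_class[foreign])),
                 accepted_SSU = acc[["SSU"]], accepted_LSU = acc[["LSU"]],
                 accepted_mRNA = acc[["mRNA"]], stringsAsFactors = FALSE)
    }))
    o <- order(tab$contamination, -tab$sensitivity, -tab$evalue)
    selected[[db]] <- tab$evalue[o[1L]]
    rows[[db]] <- tab
  }
  structure(list(table = do.call(rbind, rows), selected = selected,
                 n_per_class = as.vector(n_class[c("SSU", "LSU", "mRNA")])),
            class = "calibration_report")
}

#' Write a Table-1-style partition table and per-read classes
#' @param partition A `read_partition`.
#' @param table_path,per_read_path Output TSV paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_partition <- function(partition, table_path = NULL, per_read_path = NULL) {
  if (!is.null(table_path))
    write.table(partition$table, table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(per_read_path))
    write.table(partition$per_read, per_read_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(table_path, per_read_path))
}
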