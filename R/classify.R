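# Taxonomic assignment of 16S transcripts (word-based naive Bayes with
# bootstrap confidence) and of protein hits (lowest common ancestor),
# plus family-level composition tables.

#' Train the word-based naive-Bayes taxonomic model
#'
#' Document-frequency training in the style of the classical 16S
#' classifier: with N references of which n(w) contain word w, the word
#' prior is `P(w) = (n(w) + 0.5) / (N + 1)`; with M_g references in genus g
#' of which m_g(w) contain w, the class conditional is
#' `P(w|g) = (m_g(w) + P(w)) / (M_g + 1)`. Words are collected from both
#' strands with set semantics (duplicates in a sequence count once).
#'
#' @param refs SSU `reference_set` rows with lineage strings; at least one
#'   reference per genus.
#' @param word_size Word length in bases (default 8).
#' @return An object of class `word_model`: log conditionals (`4^word_size`
#'   x genera matrix), word priors, genus lineages, training counts.
#' @export
train_word_model <- function(refs, word_size = 8L) {
  if (any(nchar(refs$sequence) < word_size))
    stop("all references must be at least word_size long")
  lin <- strsplit(refs$lineage, ";", fixed = TRUE)
  depth <- lengths(lin)
  if (any(depth < length(TAX_RANKS)))
    stop("references must carry full lineages down to genus")
  genus <- vapply(lin, function(x) x[[length(TAX_RANKS)]], "")
  genera <- sort(unique(genus))
  G <- length(genera)
  W <- 4L ^ word_size
  words <- cpp_word_sets(refs$sequence, as.integer(word_size))
  n_w <- integer(W)
  m_gw <- matrix(0L, W, G)
  M_g <- as.vector(table(factor(genus, levels = genera)))
  for (i in seq_along(words)) {
    w1 <- words[[i]] + 1L
    n_w[w1] <- n_w[w1] + 1L
    g <- match(genus[i], genera)
    m_gw[w1, g] <- m_gw[w1, g] + 1L
  }
  p_w <- (n_w + 0.5) / (length(words) + 1)
  logp <- log(sweep(m_gw + matrix(p_w, W, G), 2L, M_g + 1, "/"))
  lin_mat <- do.call(rbind, lin[match(genera, genus)])
  colnames(lin_mat) <- TAX_RANKS
  structure(list(word_size = as.integer(word_size), genera = genera,
                 lineage = lin_mat, logp = logp, p_w = p_w,
                 n_refs = length(words), M_g = M_g),
            class = "word_model")
}

#' Classify reads with the bootstrap naive-Bayes model
#'
#' Each read's word set is scored against every genus
#' (`sum log P(w|g)`, argmax wins, ties to the lexicographically first
#' genus). `n_bootstrap` trials redraw `ceiling(subsample * n_words)` words
#' with replacement and re-classify; the confidence at each rank is the
#' fraction of trials whose winner shares the assigned lineage at that rank.
#' The assignment is truncated at the last rank with confidence strictly
#' above `conf_threshold`; deeper ranks are reported as `"uc"`
#' (unclassified). Reads with no valid words are fully unclassified.
#'
#' @param reads Data frame with `id`, `sample`, `sequence`.
#' @param model A [train_word_model()] fit.
#' @param n_bootstrap Bootstrap trials (default 100).
#' @param subsample Fraction of the word set drawn per trial (default 1/8).
#' @param conf_threshold Confidence needed to keep a rank (strict `>`).
#' @param seed Integer seed for the bootstrap.
#' @return A data frame of class `classification`: `id`, `sample`, `method`,
#'   one column per rank (name or `"uc"`), and `conf_<rank>` columns.
#' @export
classify_nb <- function(reads, model, n_bootstrap = 100L, subsample = 1 / 8,
                        conf_threshold = 0.5, seed = 1L) {
  set.seed(seed)
  words <- cpp_word_sets(reads$sequence, model$word_size)
  res <- cpp_classify_nb(words, model$logp,
                         lineage_codes(model), as.integer(n_bootstrap),
                         subsample)
  n <- nrow(reads)
  R <- length(TAX_RANKS)
  assign <- matrix("uc", n, R, dimnames = list(NULL, TAX_RANKS))
  conf <- res$confidence
  colnames(conf) <- paste0("conf_", TAX_RANKS)
  ok <- !is.na(res$best)
  for (i in which(ok)) {
    lin <- model$lineage[res$best[i], ]
    keep <- conf[i, ] > conf_threshold
    # truncate at the first rank failing the threshold
    cut <- which(!keep)
    deepest <- if (length(cut)) cut[1L] - 1L else R
    if (deepest > 0L) assign[i, seq_len(deepest)] <- lin[seq_len(deepest)]
  }
  conf[!ok, ] <- 0
  out <- data.frame(id = reads$id, sample = reads$sample,
                    method = "naive_bayes", assign, conf,
                    stringsAsFactors = FALSE)
  class(out) <- c("classification", "data.frame")
  out
}

lineage_codes <- function(model) {
  # integer codes per (genus, rank) so the C++ side compares lineages fast
  lv <- unique(as.vector(model$lineage))
  matrix(match(model$lineage, lv), nrow(model$lineage), ncol(model$lineage))
}

#' Lowest-common-ancestor assignment from hit lists
#'
#' Per read, hits scoring at least `(1 - top_fraction)` of the best score
#' are retained; with fewer than `min_support` retained hits the read is
#' unassigned, otherwise it is assigned to the lowest common ancestor of the
#' retained hits' taxa, reported down to that node's rank with deeper ranks
#' unclassified.
#'
#' @param hits A hit table (multiple queries allowed) whose `subject` ids
#'   resolve in `refs`.
#' @param refs The `reference_set` the hits refer to.
#' @param tree The [taxonomy()].
#' @param top_fraction Score window below the best hit (default 0.1).
#' @param min_support Minimum retained hits (default 2).
#' @param samples Optional named vector mapping read id to sample.
#' @return A `classification` data frame (method `"lca"`, no confidences);
#'   unassigned reads have every rank `"uc"`.
#' @export
lca_assign <- function(hits, refs, tree, top_fraction = 0.1, min_support = 2L,
                       samples = NULL) {
  R <- length(TAX_RANKS)
  ids <- unique(hits$query)
  assign <- matrix("uc", length(ids), R, dimnames = list(NULL, TAX_RANKS))
  if (length(ids)) {
    tax_of <- setNames(refs$tax_id, refs$id)
    by_q <- split(seq_len(nrow(hits)), hits$query)
    for (qi in seq_along(ids)) {
      rows <- by_q[[ids[qi]]]
      sc <- hits$score[rows]
      keep <- rows[sc >= (1 - top_fraction) * max(sc)]
      if (length(keep) < min_support) next
      node <- lca_node(tree, unique(tax_of[hits$subject[keep]]))
      if (is.na(node)) next
      lin <- tax_lineage(tree, node, "name")
      got <- !is.na(lin)
      assign[qi, got] <- lin[got]
    }
  }
  smp <- if (is.null(samples)) NA_character_ else unname(samples[ids])
  out <- data.frame(id = ids, sample = smp, method = "lca", assign,
                    stringsAsFactors = FALSE)
  class(out) <- c("classification", "data.frame")
  out
}

#' Rank-level composition table
#'
#' Aggregates classification results at the requested rank; reads truncated
#' above that rank are pooled into an `"uc_<rank>"` bin so the per-sample
#' relative abundances sum to one honestly. The average column is computed
#' from the pooled counts over all samples.
#'
#' @param results A `classification` data frame (NB or LCA).
#' @param rank One of [tax_ranks()] (default `"family"`).
#' @return An object of class `composition_table`: `counts` (taxon x
#'   sample), `rel_abund` (with an `average` column), `rank`.
#' @export
composition <- function(results, rank = "family") {
  rank <- match.arg(rank, TAX_RANKS)
  if (nrow(results) == 0L) stop("no classification results")
  taxon <- results[[rank]]
  taxon[taxon == "uc"] <- paste0("uc_", rank)
  tab <- table(taxon, results$sample)
  counts <- as.data.frame.matrix(tab)
  counts <- as.matrix(counts[order(rownames(counts)), , drop = FALSE])
  rel <- sweep(counts, 2L, colSums(counts), "/")
  pooled <- rowSums(counts)
  rel <- cbind(rel, average = pooled / sum(pooled))
  structure(list(counts = counts, rel_abund = rel, rank = rank),
            class = "composition_table")
}

#' Write classification and composition tables as TSV
#' @param x A `classification` or `composition_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_classification
#' @export
write_composition <- function(x, path) {
  out <- data.frame(taxon = rownames(x$rel_abund), x$rel_abund,
                    row.names = NULL, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
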