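# Self-contained homology search: exact k-mer seeding, ungapped X-drop
# extension, gapless Karlin-Altschul E-values. Stands in for the external
# aligners everywhere the pipeline needs similarity search.

# Robinson & Robinson amino-acid background frequencies
ROBINSON_FREQS <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364,
                    C = 0.01925, Q = 0.04264, E = 0.06295, G = 0.07377,
                    H = 0.02199, I = 0.05142, L = 0.09019, K = 0.05744,
                    M = 0.02243, F = 0.03856, P = 0.05203, S = 0.07120,
                    T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Scoring schemes for the internal homology search
#'
#' A scheme bundles the alphabet, an integer substitution matrix, background
#' letter frequencies, the search-space constant K and the Karlin parameter
#' lambda (the per-unit-score scale of the extreme-value law), computed with
#' [karlin_lambda()] at construction. E-values follow the gapless
#' Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)`; extensions
#' are ungapped, so that formula is exact and the calibrated thresholds the
#' triage uses are meaningful.
#'
#' @param alphabet `"dna"` or `"aa"`.
#' @param matrix Integer substitution matrix over the alphabet (rows/columns
#'   in A,C,G,T order for DNA, in `ARNDCQEGHILKMFPSTWYV` order for protein).
#' @param background Named background letter frequencies.
#' @param K Search-space constant (the conventional gapless approximation
#'   0.1 by default; documented as approximate).
#' @param gap_open,gap_extend Recorded but unused: extensions are ungapped.
#' @return A list of class `scoring_scheme` with the computed `lambda`.
#' @export
scoring_scheme <- function(alphabet = c("dna", "aa"), matrix, background,
                           K = 0.1, gap_open = 5, gap_extend = 2) {
  alphabet <- match.arg(alphabet)
  letters <- if (alphabet == "dna") NT_LETTERS else AA_LETTERS
  if (!is.matrix(matrix) || any(dim(matrix) != length(letters)))
    stop("matrix must be ", length(letters), " x ", length(letters))
  storage.mode(matrix) <- "integer"
  dimnames(matrix) <- list(letters, letters)
  background <- background[letters]
  if (anyNA(background)) stop("background must name every letter")
  background <- background / sum(background)
  exp_score <- sum(outer(background, background) * matrix)
  if (exp_score >= 0) stop("expected per-letter score must be negative")
  if (max(matrix) <= 0) stop("maximum score must be positive")
  sch <- structure(list(alphabet = alphabet, letters = letters,
                        matrix = matrix, background = background,
                        K = K, gap_open = gap_open, gap_extend = gap_extend,
                        lambda = NA_real_),
                   class = "scoring_scheme")
  sch$lambda <- karlin_lambda(sch)
  sch
}

#' @rdname scoring_scheme
#' @param match,mismatch Nucleotide match reward and mismatch penalty.
#' @export
nucleotide_scheme <- function(match = 1L, mismatch = -2L, K = 0.1) {
  m <- matrix(as.integer(mismatch), 4L, 4L)
  diag(m) <- as.integer(match)
  scoring_scheme("dna", m, setNames(rep(0.25, 4), NT_LETTERS), K = K)
}

#' @rdname scoring_scheme
#' @export
protein_scheme <- function(K = 0.1) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  m <- data_env$BLOSUM62[AA_LETTERS, AA_LETTERS]
  scoring_scheme("aa", m, ROBINSON_FREQS, K = K)
}

#' Karlin parameter lambda of a scoring scheme
#'
#' The unique positive root of `sum_ij p_i p_j exp(lambda * s_ij) = 1`,
#' located by bisection to `|f| < 1e-12`. Exists whenever the expected
#' per-letter score is negative and the maximum score positive.
#'
#' @param scheme A [scoring_scheme()] (lambda need not be filled in yet).
#' @return The positive root, a scalar.
#' @export
karlin_lambda <- function(scheme) {
  p <- scheme$background
  s <- scheme$matrix
  pp <- outer(p, p)
  f <- function(l) sum(pp * exp(l * s)) - 1
  if (sum(pp * s) >= 0) stop("invalid scheme: expected score must be negative")
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  # f(0) = 0; step off zero to bracket the positive root
  lo <- hi / 2
  while (f(lo) > 0) lo <- lo / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-12) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Gapless Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct
#' ungapped alignments of score at least S between a query of length m and a
#' database of n letters.
#'
#' @param S Raw alignment score(s).
#' @param m Query length (peptide length for translated searches).
#' @param n Total database letters.
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value(s).
#' @export
evalue <- function(S, m, n, scheme) {
  if (any(S < 0) || any(m < 0) || any(n < 0)) stop("S, m, n must be >= 0")
  scheme$K * m * n * exp(-scheme$lambda * S)
}

# ---- index and search -----------------------------------------------------

#' Build an exact k-mer seed index over a sequence collection
#'
#' @param seqs Named character vector of sequences, or a `reference_set`
#'   (its `sequence` column is used, `cds` is not).
#' @param k Word size (>= 4). Defaults: 11 for DNA, 4 for protein.
#' @param alphabet `"dna"` or `"aa"`.
#' @return An object of class `seed_index`. Reverse-strand matches are found
#'   by searching the reverse complement of the query, so the index stores
#'   forward k-mer positions only.
#' @export
build_index <- function(seqs, k = NULL, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (inherits(seqs, "reference_set") || is.data.frame(seqs))
    seqs <- setNames(seqs$sequence, seqs$id)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty")
  if (is.null(k)) k <- if (alphabet == "dna") 11L else 4L
  if (k < 4L) stop("k must be >= 4")
  ptr <- cpp_build_index(unname(seqs), names(seqs), as.integer(k),
                         alphabet == "aa")
  info <- cpp_index_info(ptr)
  if (info$n_kmers == 0)
    warning("no reference is as long as k: empty index")
  structure(list(ptr = ptr, k = as.integer(k), alphabet = alphabet,
                 seqs = seqs, n_refs = info$n_refs,
                 n_kmers = info$n_kmers, n_positions = info$n_positions,
                 total_letters = info$total_letters),
            class = "seed_index")
}

index_handle <- function(index) {
  # external pointers do not survive serialization; rebuild transparently
  if (is.null(index$ptr) ||
      identical(class(try(cpp_index_info(index$ptr), silent = TRUE)), "try-error"))
    index$ptr <- cpp_build_index(unname(index$seqs), names(index$seqs),
                                 index$k, index$alphabet == "aa")
  index
}

#' Positions of one k-mer in a seed index (forward strand)
#' @param index A [build_index()] object.
#' @param kmer A k-length string.
#' @return Data frame of `subject`, `offset` (0-based).
#' @export
index_positions <- function(index, kmer) {
  index <- index_handle(index)
  cpp_index_positions(index$ptr, kmer)
}

as_query_set <- function(queries) {
  if (is.data.frame(queries))
    list(id = queries$id, seq = queries$sequence)
  else if (is.character(queries)) {
    if (is.null(names(queries)))
      names(queries) <- sprintf("query_%d", seq_along(queries))
    list(id = names(queries), seq = unname(queries))
  } else stop("queries must be a data frame or named character vector")
}

#' Seed-and-extend search of queries against an index
#'
#' Exact k-mer seeds are extended ungapped in both directions under an
#' X-drop rule; overlapping extensions are merged; hits with E-value at most
#' `max_e` are returned sorted by descending score, ties broken by subject
#' id. Nucleotide queries are searched on both strands (query interval
#' always reported in forward-read coordinates). Coordinates are 0-based,
#' half-open.
#'
#' @param queries Data frame with `id` and `sequence`, or named character
#'   vector.
#' @param index A [build_index()] object.
#' @param scheme A [scoring_scheme()] matching the index alphabet.
#' @param max_e E-value cutoff.
#' @param x_drop Extension stops when the running score falls this far below
#'   its running maximum.
#' @param best_only Keep only the top hit per query.
#' @return A hit table: `query`, `subject`, `score`, `evalue`, `pident`,
#'   `length`, `mismatch`, `qstart`, `qend`, `sstart`, `send`, `strand`,
#'   `frame`.
#' @export
search_hits <- function(queries, index, scheme = nucleotide_scheme(),
                        max_e = 10, x_drop = 20, best_only = FALSE) {
  q <- as_query_set(queries)
  if (length(q$id) == 0L)
    return(empty_hits())
  if (any(nchar(q$seq) == 0L)) stop("empty query sequence")
  index <- index_handle(index)
  if (scheme$alphabet != index$alphabet)
    stop("scheme alphabet does not match index")
  cpp_search(q$seq, q$id, index$ptr, scheme$matrix, scheme$lambda, scheme$K,
             max_e, as.integer(x_drop), best_only,
             index$alphabet == "dna")
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(), score = numeric(),
             evalue = numeric(), pident = numeric(), length = integer(),
             mismatch = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), strand = character(),
             frame = integer(), stringsAsFactors = FALSE)
}

#' Six-frame translated search against a protein index
#'
#' All six reading frames are translated with the standard genetic code,
#' split at stop codons, and each peptide searched as in [search_hits()].
#' The frame (+-1..3) is recorded and query intervals are reported in
#' forward-read nucleotide coordinates; alignment length and identity are in
#' amino acids, and the E-value uses the peptide length as m.
#'
#' @inheritParams search_hits
#' @return A hit table as in [search_hits()].
#' @export
translated_search <- function(queries, index, scheme = protein_scheme(),
                              max_e = 10, x_drop = 20, best_only = FALSE) {
  q <- as_query_set(queries)
  if (length(q$id) == 0L) return(empty_hits())
  index <- index_handle(index)
  if (index$alphabet != "aa") stop("translated search needs a protein index")
  cpp_translated_search(q$seq, q$id, index$ptr, scheme$matrix, scheme$lambda,
                        scheme$K, max_e, as.integer(x_drop), best_only)
}

#' Map reads to a contig catalogue
#'
#' A read is mapped iff some hit aligns at least `min_fraction` of the read
#' length ("fraction of the possible maximum alignment", read as the query
#' length) at identity of at least `min_identity`.
#'
#' @param queries Reads (data frame or named character vector).
#' @param contigs Named character vector of contigs, or a prebuilt DNA
#'   [build_index()].
#' @param min_fraction,min_identity The acceptance rule (defaults 0.8 / 0.9).
#' @param scheme,x_drop Search parameters.
#' @return Data frame per query: `query`, `mapped`, plus the best hit's
#'   subject/score/identity/length (NA when there is no hit at all).
#' @export
map_to_contigs <- function(queries, contigs, min_fraction = 0.8,
                           min_identity = 0.9, scheme = nucleotide_scheme(),
                           x_drop = 20) {
  q <- as_query_set(queries)
  index <- if (inherits(contigs, "seed_index")) contigs
           else build_index(contigs, alphabet = "dna")
  if (index$n_refs == 0L) stop("contigs must be non-empty")
  hits <- search_hits(queries, index, scheme, max_e = 1e6, x_drop = x_drop)
  qlen <- setNames(nchar(q$seq), q$id)
  out <- data.frame(query = q$id, mapped = FALSE, subject = NA_character_,
                    score = NA_real_, pident = NA_real_,
                    length = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hits$ok <- hits$length >= min_fraction * qlen[hits$query] &
      hits$pident >= 100 * min_identity
    # best hit per query: rule-satisfying hits first, then score
    hits <- hits[order(hits$query, -hits$ok, -hits$score, hits$subject), ]
    best <- hits[!duplicated(hits$query), ]
    i <- match(best$query, out$query)
    out$mapped[i] <- best$ok
    out$subject[i] <- best$subject
    out$score[i] <- best$score
    out$pident[i] <- best$pident
    out$length[i] <- best$length
  }
  out
}

#' Write hits as 12-column BLAST tabular records
#'
#' Coordinates are converted to the 1-based inclusive convention of the file
#' dialect; the bit-score column carries the raw score.
#'
#' @param hits A hit table from [search_hits()] or [translated_search()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(qseqid = hits$query, sseqid = hits$subject,
                    pident = sprintf("%.2f", hits$pident),
                    length = hits$length, mismatch = hits$mismatch,
                    gapopen = 0L,
                    qstart = hits$qstart + 1L, qend = hits$qend,
                    sstart = hits$sstart + 1L, send = hits$send,
                    evalue = format(hits$evalue, digits = 3),
                    bitscore = hits$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
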