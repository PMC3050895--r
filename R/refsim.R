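# Synthetic community generator: taxonomy-aware reference databases and
# truth-labeled reads with the statistical structure the pipeline assumes.

#' Community simulation parameters
#'
#' Defines the regime the simulator emulates: a ten-sample community
#' dominated by a few bacterial families, an RNA pool that is mostly rRNA
#' (SSU about 17%, LSU several-fold that, non-rRNA about 7% of which a small
#' part is sRNA), reads around 174 bp with a tail below the 60 bp analysis
#' cutoff, and an mRNA pool drawn from COG-annotated proteins with an
#' injected category skew (carbohydrate metabolism G at twice its database
#' share, lipid metabolism I at half).
#'
#' @param n_samples Number of samples.
#' @param reads_per_sample Read budget per sample (>= 0).
#' @param class_mix Named fractions for SSU/LSU/mRNA/sRNA; must sum to 1.
#' @param cog_profile Named probability per COG category (25 letters, sums
#'   to 1); `NULL` for the default skewed profile.
#' @param read_len_mean,read_len_sd,read_len_min,read_len_max Discretized
#'   truncated-normal read-length law, in bp.
#' @param error_rate Per-base substitution error rate.
#' @param family_alpha Optional explicit Dirichlet concentration vector over
#'   families (one draw per sample). If `NULL`, concentrations are
#'   `dirichlet_theta` times geometrically decaying weights
#'   (`family_weight_decay^(rank-1)`, normalized), which yields dominance by
#'   a small number of families.
#' @param dirichlet_theta,family_weight_decay See `family_alpha`.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A validated list of class `community_spec`.
#' @export
community_spec <- function(n_samples = 10L,
                           reads_per_sample = 20000L,
                           class_mix = c(SSU = 0.17, LSU = 0.76,
                                         mRNA = 0.06, sRNA = 0.01),
                           cog_profile = NULL,
                           read_len_mean = 174, read_len_sd = 80,
                           read_len_min = 30, read_len_max = 1000,
                           error_rate = 0.01,
                           family_alpha = NULL,
                           dirichlet_theta = 60,
                           family_weight_decay = 0.75,
                           seed = 1L) {
  if (is.null(cog_profile)) cog_profile <- default_cog_profile()
  spec <- list(n_samples = as.integer(n_samples),
               reads_per_sample = as.integer(reads_per_sample),
               class_mix = class_mix, cog_profile = cog_profile,
               read_len_mean = read_len_mean, read_len_sd = read_len_sd,
               read_len_min = read_len_min, read_len_max = read_len_max,
               error_rate = error_rate, family_alpha = family_alpha,
               dirichlet_theta = dirichlet_theta,
               family_weight_decay = family_weight_decay,
               seed = as.integer(seed))
  validate_community_spec(spec)
  structure(spec, class = "community_spec")
}

validate_community_spec <- function(spec) {
  cm <- spec$class_mix
  if (!all(c("SSU", "LSU", "mRNA", "sRNA") %in% names(cm)))
    stop("class_mix must name SSU, LSU, mRNA and sRNA")
  if (any(cm < 0 | cm > 1)) stop("class fractions must lie in [0, 1]")
  if (abs(sum(cm) - 1) > 1e-9) stop("class_mix must sum to 1")
  cp <- spec$cog_profile
  if (!setequal(names(cp), COG_CATEGORY_LETTERS))
    stop("cog_profile must cover the 25 COG categories")
  if (any(cp < 0) || abs(sum(cp) - 1) > 1e-9)
    stop("cog_profile must be a probability vector")
  if (is.na(spec$reads_per_sample) || spec$reads_per_sample < 0)
    stop("read budget must be >= 0")
  if (spec$n_samples < 1) stop("need at least one sample")
  if (spec$error_rate < 0 || spec$error_rate > 1) stop("error_rate in [0,1]")
  if (spec$read_len_min < 1 || spec$read_len_max < spec$read_len_min)
    stop("invalid read-length bounds")
  invisible(spec)
}

#' @rdname community_spec
#' @export
default_cog_profile <- function() {
  p <- setNames(rep((1 - 2.5 / 25) / 23, 25), COG_CATEGORY_LETTERS)
  p["G"] <- 2 / 25    # over-expressed at twice its database share
  p["I"] <- 0.5 / 25  # under-expressed at half its database share
  p
}

#' Read/write a community spec as JSON
#' @param spec A [community_spec()].
#' @param path File path.
#' @return `write_community_spec` returns the path invisibly;
#'   `read_community_spec` returns a `community_spec`.
#' @export
write_community_spec <- function(spec, path) {
  x <- lapply(unclass(spec), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_community_spec
#' @export
read_community_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("class_mix", "cog_profile"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  do.call(community_spec, x[!vapply(x, is.null, TRUE)])
}

# ---- reference evolution --------------------------------------------------

mutate_codes <- function(x, p, alpha) {
  # substitute positions with per-site probability p, excluding current state
  hit <- which(runif(length(x)) < p)
  if (length(hit))
    x[hit] <- (x[hit] + sample.int(alpha - 1L, length(hit), replace = TRUE)) %% alpha
  x
}

codes_to_nt <- function(x) paste(NT_LETTERS[x + 1L], collapse = "")
codes_to_aa <- function(x) paste(AA_LETTERS[x + 1L], collapse = "")

# aa (one letter) -> codon list, derived from the compiled genetic code so
# reverse translation and six-frame translation agree by construction
codon_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    codons <- apply(expand.grid(NT_LETTERS, NT_LETTERS, NT_LETTERS,
                                stringsAsFactors = FALSE)[, 3:1], 1L,
                    paste, collapse = "")
    aas <- vapply(codons, function(cd) cpp_translate(cd, 1L), "")
    tab <<- split(codons, aas)
    tab
  }
})

reverse_translate <- function(aa_seq) {
  tab <- codon_table()
  aas <- strsplit(aa_seq, "")[[1]]
  paste(vapply(aas, function(a) {
    cds <- tab[[a]]
    cds[sample.int(length(cds), 1L)]
  }, ""), collapse = "")
}

#' Evolve synthetic reference databases along a taxonomy
#'
#' Starting from i.i.d.-uniform ancestral sequences (one SSU, one LSU, one
#' protein per COG, one consensus per sRNA family), sequences are mutated
#' independently along every branch of the tree with per-branch substitution
#' probability `sub_prob` (substitutions never retain the current letter).
#' Positions under the SSU conserved-region mask mutate at `conserved_rate`
#' times the branch rate, giving the alignment-anchor structure real SSU
#' rRNA has. Each genus receives one SSU, one LSU, one protein per COG
#' (stored as amino acids together with a fixed uniform-codon nucleotide
#' coding sequence, so reads and contigs share codons), and one gene per
#' sRNA family (family consensus plus genus-specific divergence and flanks).
#'
#' @param tree A [taxonomy()].
#' @param sub_prob Per-branch substitution probability, in [0, 0.75].
#' @param conserved_frac Fraction of each 100 bp SSU window that is
#'   conserved.
#' @param conserved_rate Rate multiplier for conserved SSU positions.
#' @param ssu_len,lsu_len Reference rRNA lengths (defaults near the real
#'   16S/23S molecule sizes).
#' @param protein_len Protein length in amino acids.
#' @param cogs_per_category Number of orthologous groups per COG category.
#' @param srna_families,srna_motif_len,srna_flank,srna_divergence Small-RNA
#'   family count, conserved motif length, flank length, and per-genus motif
#'   divergence.
#' @param seed Integer seed.
#' @return A data frame of class `reference_set` with columns `id`, `class`
#'   (SSU/LSU/protein/sRNA), `tax_id`, `lineage`, `cog_id`, `cog_category`,
#'   `srna_family`, `sequence` (nucleotide; amino acids for proteins) and
#'   `cds` (nucleotide coding sequence, proteins only). Attributes:
#'   `conserved_mask` (logical of length `ssu_len`), `motifs` (per-family
#'   consensus strings) and `tree`.
#' @export
evolve_references <- function(tree, sub_prob = 0.1,
                              conserved_frac = 0.5, conserved_rate = 0.1,
                              ssu_len = 1500L, lsu_len = 2900L,
                              protein_len = 220L, cogs_per_category = 4L,
                              srna_families = 8L, srna_motif_len = 60L,
                              srna_flank = 50L, srna_divergence = 0.05,
                              seed = 0L) {
  if (!inherits(tree, "taxonomy") || nrow(tree) == 0L)
    stop("tree must be a non-empty taxonomy")
  if (sub_prob < 0 || sub_prob > 0.75)
    stop("sub_prob must lie in [0, 0.75]")
  if (conserved_rate < 0 || conserved_rate > 1)
    stop("conserved_rate must lie in [0, 1]")
  set.seed(seed)
  mask <- (seq_len(ssu_len) - 1L) %% 100L < round(100 * conserved_frac)
  ssu_site_mult <- ifelse(mask, conserved_rate, 1)

  cog_ids <- as.vector(t(outer(COG_CATEGORY_LETTERS, seq_len(cogs_per_category),
                               function(a, b) sprintf("COG_%s%d", a, b))))
  cog_cat <- rep(COG_CATEGORY_LETTERS, each = cogs_per_category)

  anc <- list(
    SSU = sample.int(4L, ssu_len, replace = TRUE) - 1L,
    LSU = sample.int(4L, lsu_len, replace = TRUE) - 1L,
    prot = lapply(seq_along(cog_ids), function(i)
      sample.int(20L, protein_len, replace = TRUE) - 1L),
    srna = lapply(seq_len(srna_families), function(i)
      sample.int(4L, srna_motif_len, replace = TRUE) - 1L)
  )

  ord <- order(match(tree$rank, TAX_RANKS))  # parents before children
  state <- vector("list", nrow(tree))
  names(state) <- as.character(tree$id)
  pidx <- match(tree$parent, tree$id)
  for (i in ord) {
    id <- as.character(tree$id[i])
    if (is.na(pidx[i])) {
      state[[id]] <- list(SSU = anc$SSU, LSU = anc$LSU, prot = anc$prot)
    } else {
      par <- state[[as.character(tree$id[pidx[i]])]]
      state[[id]] <- list(
        SSU = mutate_codes(par$SSU, sub_prob * ssu_site_mult, 4L),
        LSU = mutate_codes(par$LSU, sub_prob, 4L),
        prot = lapply(par$prot, mutate_codes, p = sub_prob, alpha = 20L)
      )
    }
  }

  genera <- tax_nodes_at_rank(tree, "genus")
  recs <- list()
  add <- function(df) recs[[length(recs) + 1L]] <<- df
  for (gi in seq_len(nrow(genera))) {
    gid <- genera$id[gi]
    gname <- genera$name[gi]
    st <- state[[as.character(gid)]]
    lin <- tax_lineage_string(tree, gid)
    add(data.frame(id = paste0("SSU_", gname), class = "SSU", tax_id = gid,
                   lineage = lin, cog_id = NA, cog_category = NA,
                   srna_family = NA, sequence = codes_to_nt(st$SSU),
                   cds = NA, stringsAsFactors = FALSE))
    add(data.frame(id = paste0("LSU_", gname), class = "LSU", tax_id = gid,
                   lineage = lin, cog_id = NA, cog_category = NA,
                   srna_family = NA, sequence = codes_to_nt(st$LSU),
                   cds = NA, stringsAsFactors = FALSE))
    aa <- vapply(st$prot, codes_to_aa, "")
    cds <- vapply(aa, reverse_translate, "")
    add(data.frame(id = paste0(cog_ids, "_", gname), class = "protein",
                   tax_id = gid, lineage = lin, cog_id = cog_ids,
                   cog_category = cog_cat, srna_family = NA,
                   sequence = aa, cds = unname(cds), stringsAsFactors = FALSE))
    srna_seq <- vapply(seq_len(srna_families), function(fi) {
      motif <- mutate_codes(anc$srna[[fi]], srna_divergence, 4L)
      fl1 <- sample.int(4L, srna_flank, replace = TRUE) - 1L
      fl2 <- sample.int(4L, srna_flank, replace = TRUE) - 1L
      codes_to_nt(c(fl1, motif, fl2))
    }, "")
    add(data.frame(id = sprintf("sRNA_%02d_%s", seq_len(srna_families), gname),
                   class = "sRNA", tax_id = gid, lineage = lin,
                   cog_id = NA, cog_category = NA,
                   srna_family = sprintf("sRNA_%02d", seq_len(srna_families)),
                   sequence = srna_seq, cds = NA, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  structure(out, conserved_mask = mask,
            motifs = setNames(vapply(anc$srna, codes_to_nt, ""),
                              sprintf("sRNA_%02d", seq_len(srna_families))),
            tree = tree,
            class = c("reference_set", "data.frame"))
}

#' Subset a reference set by molecule class
#' @param refs A `reference_set`.
#' @param class One of "SSU", "LSU", "protein", "sRNA".
#' @return The matching rows (attributes preserved).
#' @export
ref_class <- function(refs, class) {
  out <- refs[refs$class == class, , drop = FALSE]
  for (a in c("conserved_mask", "motifs", "tree"))
    attr(out, a) <- attr(refs, a)
  class(out) <- class(refs)
  out
}

# ---- read simulation ------------------------------------------------------

rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n - length(out), mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate truth-labeled community reads
#'
#' For each sample, family abundances are one Dirichlet realization; each
#' read draws its family from those abundances and its molecule class from
#' the class mixture, then is cut as a uniformly placed substring of a
#' reference of that family and class (mRNA reads come from the fixed
#' nucleotide coding sequence of a protein, with the COG category drawn from
#' the expression profile, so strand and frame are random). Per-base
#' substitution errors are applied i.i.d. and truth labels recorded.
#'
#' @param spec A [community_spec()].
#' @param refs A `reference_set` from [evolve_references()].
#' @param tree The [taxonomy()] the references were evolved on.
#' @return A data frame of class `read_set`: `id`, `sample`, `sequence`, and
#'   truth columns `true_class`, `true_genus`, `true_family`, `true_cog`,
#'   `true_category`, `source_ref`. Attribute `abundance` holds the realized
#'   per-sample family abundances.
#' @export
simulate_reads <- function(spec, refs, tree) {
  validate_community_spec(spec)
  set.seed(spec$seed)
  genera <- tax_nodes_at_rank(tree, "genus")
  fam_of_genus <- tax_lineage(tree, genera$id, "name")[, "family"]
  fams <- sort(unique(fam_of_genus))
  F <- length(fams)
  if (is.null(spec$family_alpha)) {
    w <- spec$family_weight_decay ^ (seq_len(F) - 1)
    alpha <- spec$dirichlet_theta * w / sum(w)
  } else {
    alpha <- rep_len(spec$family_alpha, F)
  }
  # reference lookup tables
  refs$family <- tax_lineage(tree, refs$tax_id, "name")[, "family"]
  if (!all(fams %in% refs$family[refs$class == "SSU"]))
    stop("references must cover every family with nonzero abundance")
  ssu_by_fam <- split(which(refs$class == "SSU"), refs$family[refs$class == "SSU"])
  lsu_by_fam <- split(which(refs$class == "LSU"), refs$family[refs$class == "LSU"])
  srna_by_fam <- split(which(refs$class == "sRNA"), refs$family[refs$class == "sRNA"])
  prot_idx <- which(refs$class == "protein")
  prot_key <- paste(refs$family[prot_idx], refs$cog_category[prot_idx])
  prot_by_key <- split(prot_idx, prot_key)

  classes <- c("SSU", "LSU", "mRNA", "sRNA")
  samples <- sprintf("S%02d", seq_len(spec$n_samples))
  all <- vector("list", spec$n_samples)
  abund <- matrix(NA_real_, F, spec$n_samples, dimnames = list(fams, samples))
  for (s in seq_len(spec$n_samples)) {
    g <- rgamma(F, shape = alpha)
    p <- g / sum(g)
    abund[, s] <- p
    n <- spec$reads_per_sample
    if (n == 0L) { all[[s]] <- NULL; next }
    fam <- sample(fams, n, replace = TRUE, prob = p)
    cls <- sample(classes, n, replace = TRUE, prob = spec$class_mix[classes])
    cat <- character(n)
    is_m <- cls == "mRNA"
    cat[is_m] <- sample(names(spec$cog_profile), sum(is_m), replace = TRUE,
                        prob = spec$cog_profile)
    ref_row <- integer(n)
    for (i in seq_len(n)) {
      ref_row[i] <- switch(cls[i],
        SSU = { v <- ssu_by_fam[[fam[i]]]; v[sample.int(length(v), 1L)] },
        LSU = { v <- lsu_by_fam[[fam[i]]]; v[sample.int(length(v), 1L)] },
        sRNA = { v <- srna_by_fam[[fam[i]]]; v[sample.int(length(v), 1L)] },
        mRNA = { v <- prot_by_key[[paste(fam[i], cat[i])]]
                 v[sample.int(length(v), 1L)] })
    }
    src <- ifelse(cls == "mRNA", refs$cds[ref_row], refs$sequence[ref_row])
    src_len <- nchar(src)
    if (any(src_len == 0L)) stop("zero-length reference sequence")
    len <- pmin(rtrunc_norm_int(n, spec$read_len_mean, spec$read_len_sd,
                                spec$read_len_min, spec$read_len_max),
                src_len)
    start <- floor(runif(n) * (src_len - len + 1L)) + 1L
    seqs <- substr(src, start, start + len - 1L)
    flip <- runif(n) < 0.5
    if (any(flip)) seqs[flip] <- revcomp_chr(seqs[flip])
    if (spec$error_rate > 0) seqs <- cpp_point_mutate(seqs, spec$error_rate)
    all[[s]] <- data.frame(
      id = sprintf("%s_R%06d", samples[s], seq_len(n)),
      sample = samples[s], sequence = seqs,
      true_class = cls, true_genus = refs$tax_id[ref_row],
      true_family = fam,
      true_cog = ifelse(is_m, refs$cog_id[ref_row], NA),
      true_category = ifelse(is_m, cat, NA),
      source_ref = refs$id[ref_row],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, all)
  if (is.null(out))
    out <- data.frame(id = character(), sample = character(),
                      sequence = character(), true_class = character(),
                      true_genus = integer(), true_family = character(),
                      true_cog = character(), true_category = character(),
                      source_ref = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, abundance = abund, class = c("read_set", "data.frame"))
}

#' Synthetic contig catalogue
#'
#' Emulates an external metagenomic assembly covering most, but not all, of
#' the community: a seeded sample of the protein coding sequences plus a
#' small share of sRNA genes. Reads from uncovered genes exercise the
#' "not in the catalogue" branches of the accounting.
#'
#' @param refs A `reference_set`.
#' @param protein_fraction,srna_fraction Fractions of protein CDSs and sRNA
#'   genes included.
#' @param seed Integer seed.
#' @return Named character vector of contig sequences.
#' @export
make_contigs <- function(refs, protein_fraction = 0.85, srna_fraction = 0.05,
                         seed = 0L) {
  set.seed(seed)
  pr <- which(refs$class == "protein")
  sr <- which(refs$class == "sRNA")
  take_p <- sort(sample(pr, round(protein_fraction * length(pr))))
  take_s <- if (length(sr)) sort(sample(sr, round(srna_fraction * length(sr)))) else integer(0)
  out <- c(setNames(refs$cds[take_p], sprintf("contig_%s", refs$id[take_p])),
           setNames(refs$sequence[take_s], sprintf("contig_%s", refs$id[take_s])))
  out
}

#' Position weight matrices for the sRNA motif families
#'
#' Builds log-odds PWMs from the family consensus motifs: the consensus base
#' gets probability `match_prob`, the others share the remainder; odds are
#' against a uniform background. Per-family score thresholds are
#' `threshold_fraction` of the motif's maximum attainable score.
#'
#' @param refs A `reference_set` carrying consensus motifs.
#' @param match_prob Consensus-base emission probability.
#' @param threshold_fraction Fraction of the maximum score used as the
#'   reporting threshold.
#' @return A list per family: `pwm` (4 x L matrix, ACGT rows, natural-log
#'   odds), `threshold`, `consensus`.
#' @export
build_motif_pwms <- function(refs, match_prob = 0.91, threshold_fraction = 0.5) {
  motifs <- attr(refs, "motifs")
  if (is.null(motifs)) stop("reference set carries no sRNA motifs")
  lapply(motifs, function(cons) {
    b <- match(strsplit(cons, "")[[1]], NT_LETTERS)
    L <- length(b)
    pwm <- matrix(log((1 - match_prob) / 3 / 0.25), 4L, L,
                  dimnames = list(NT_LETTERS, NULL))
    pwm[cbind(b, seq_len(L))] <- log(match_prob / 0.25)
    max_score <- L * log(match_prob / 0.25)
    list(pwm = pwm, threshold = threshold_fraction * max_score,
         consensus = cons)
  })
}

# ---- FASTA / TSV writers --------------------------------------------------

#' Write a reference set as FASTA plus annotation sidecar TSV
#' @param refs A `reference_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference_set <- function(refs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cl in unique(refs$class)) {
    sub <- refs[refs$class == cl, ]
    fa <- file.path(dir, paste0(tolower(cl), ".fasta"))
    seqs <- if (cl == "protein") Biostrings::AAStringSet(setNames(sub$sequence, sub$id))
            else Biostrings::DNAStringSet(setNames(sub$sequence, sub$id))
    Biostrings::writeXStringSet(seqs, fa)
    paths <- c(paths, fa)
    if (cl == "protein" && !all(is.na(sub$cds))) {
      cds_fa <- file.path(dir, "protein_cds.fasta")
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(sub$cds, sub$id)), cds_fa)
      paths <- c(paths, cds_fa)
    }
  }
  tsv <- file.path(dir, "references.tsv")
  write.table(refs[, c("id", "class", "tax_id", "lineage", "cog_id",
                       "cog_category", "srna_family")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tsv))
}

#' Write simulated reads as per-sample FASTA plus a truth-label TSV
#' @param reads A `read_set`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_reads <- function(reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in unique(reads$sample)) {
    sub <- reads[reads$sample == s, ]
    fa <- file.path(dir, paste0("reads_", s, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sub$sequence, sub$id)), fa)
    paths <- c(paths, fa)
  }
  tsv <- file.path(dir, "truth.tsv")
  write.table(as.data.frame(reads)[, setdiff(names(reads), "sequence")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tsv))
}

#' Read a FASTA file into a read_set-style data frame
#' @param path FASTA path.
#' @param sample Sample label attached to every read.
#' @return A data frame with `id`, `sample`, `sequence`.
#' @export
read_fasta_reads <- function(path, sample = "S01") {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), sample = sample, sequence = as.character(x),
             stringsAsFactors = FALSE)
}
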