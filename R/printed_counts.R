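# Published per-sample read counts of the ten-volunteer gut
# metatranscriptome survey this package models. Bundled as plain-text
# inputs for the arithmetic consistency checks the pipeline's data model
# must satisfy.

#' Published survey read counts
#'
#' `gut_survey_table1()` returns the per-sample read accounting of the
#' ten-sample human gut metatranscriptome survey (reads longer than 60 bp;
#' columns `total`, `ssu`, `lsu`, `non_rrna` — the SSU column includes both
#' the 16S and the small 18S sub-fractions). `gut_survey_homology_counts()`
#' returns the pooled downstream homology counts: non-rRNA reads, reads with
#' a protein homolog, and reads assigned to a COG category.
#'
#' @return A data frame.
#' @examples
#' t1 <- gut_survey_table1()
#' all(t1$ssu + t1$lsu + t1$non_rrna == t1$total)
#' @export
gut_survey_table1 <- function() {
  read.delim(system.file("extdata", "gut_survey_table1.tsv",
                         package = "activeflora"),
             stringsAsFactors = FALSE)
}

#' @rdname gut_survey_table1
#' @export
gut_survey_homology_counts <- function() {
  x <- read.delim(system.file("extdata", "gut_survey_homology_counts.tsv",
                              package = "activeflora"),
                  stringsAsFactors = FALSE)
  setNames(x$count, x$quantity)
}
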