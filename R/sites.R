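#' Study site table
#'
#' The 27 north-western Iberian sampling sites with their geographic context
#' (sympatric / allopatric / undetermined), species present, predominant
#' \emph{L. fabalis} ecotype, per-marker sample sizes and decimal coordinates.
#' Shipped as a plain-text fixture; used for local-scale calibration planning
#' and for context-stratified accounting.
#'
#' @return data frame with one row per site.
#' @export
littorina_sites <- function() {
  utils::read.csv(system.file("extdata", "littorina_sites.csv",
                              package = "hybridscan"),
                  stringsAsFactors = FALSE)
}

#' Published per-location mtDNA clade counts
#'
#' Per location: number of sequenced individuals genetically assigned to each
#' species and, of those, how many carry the clade typical of the other
#' species. Input for [expand_clade_counts()] / [introgression_summary()].
#'
#' @return data frame.
#' @export
littorina_mtdna_counts <- function() {
  utils::read.csv(system.file("extdata", "littorina_mtdna_clade_counts.csv",
                              package = "hybridscan"),
                  stringsAsFactors = FALSE)
}

#' Published per-location hybrid counts
#'
#' Per location: individuals analysed, hybrids detected by the global and
#' local admixture analyses, individuals confidently assigned by the
#' six-class analysis, hybrids among them, and their classes.
#'
#' @return data frame.
#' @export
littorina_hybrid_counts <- function() {
  utils::read.csv(system.file("extdata", "littorina_hybrid_counts.csv",
                              package = "hybridscan"),
                  stringsAsFactors = FALSE)
}

#' Published clade composition of detected hybrids
#'
#' Clade I / clade II counts of the hybrids detected by the admixture
#' analysis (per location) and of those assigned to a hybrid class (per
#' class).
#'
#' @return data frame with columns `group` (`location`/`class`), `label`,
#'   `n`, `clade1`, `clade2`.
#' @export
littorina_hybrid_clades <- function() {
  utils::read.csv(system.file("extdata", "littorina_hybrid_clades.csv",
                              package = "hybridscan"),
                  stringsAsFactors = FALSE)
}

#' Summarise a per-location hybrid count table
#'
#' Aggregates the per-location hybrid counts into totals (hybrids detected,
#' number of locations with hybrids, per-location percentages) for both the
#' admixture-based and the class-based analyses.
#'
#' @param counts a table as returned by [littorina_hybrid_counts()].
#' @return list with `structure_global`, `structure_local`, `newhybrids`
#'   (each: `total`, `n_locations`), and `per_location` with percentage
#'   columns.
#' @export
summarize_hybrid_counts <- function(counts = littorina_hybrid_counts()) {
  per <- counts
  per$structure_global_pct <- 100 * per$structure_global / per$n_analyzed
  per$structure_local_pct <- 100 * per$structure_local / per$n_analyzed
  per$nh_pct <- 100 * per$nh_hybrids / per$n_analyzed
  agg <- function(col) list(total = sum(per[[col]]),
                            n_locations = sum(per[[col]] > 0))
  list(structure_global = agg("structure_global"),
       structure_local = agg("structure_local"),
       newhybrids = agg("nh_hybrids"),
       per_location = per)
}
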