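#' Genotype frequency classes
#'
#' The six genotype classes used for hybrid classification: the two parentals
#' (F = \emph{L. fabalis}, O = \emph{L. obtusata}), first- and
#' second-generation hybrids (F1, F2) and the backcrosses to each parental
#' (BCF, BCO). Each class is characterised by its expected ancestry
#' proportions `(p_FF, p_FO, p_OO)` — the per-locus probability that both
#' alleles descend from the F pool, one from each, or both from the O pool.
#' The values follow from enumerating gametes over two generations of crosses.
#'
#' @return a data frame with columns `class`, `p_FF`, `p_FO`, `p_OO`.
#' @export
class_proportion_table <- function() {
  data.frame(
    class = c("F", "O", "F1", "F2", "BCF", "BCO"),
    p_FF = c(1, 0, 0, 0.25, 0.5, 0),
    p_FO = c(0, 0, 1, 0.5, 0.5, 0.5),
    p_OO = c(0, 1, 0, 0.25, 0, 0.5),
    stringsAsFactors = FALSE)
}

GENOTYPE_CLASSES <- c("F", "O", "F1", "F2", "BCF", "BCO")

#' Allele frequency model for the two parental gene pools
#'
#' @param freqF,freqO lists (one element per locus) of named relative allele
#'   frequencies for the \emph{fabalis} and \emph{obtusata} pools.
#' @param loci locus names.
#' @return an object of class `allele_freq_model`.
#' @export
allele_freq_model <- function(freqF, freqO, loci = names(freqF)) {
  if (is.null(loci)) loci <- paste0("L", seq_along(freqF))
  stopifnot(length(freqF) == length(freqO))
  norm <- function(fl) lapply(fl, function(f) {
    if (any(f < 0) || sum(f) <= 0) stop("invalid allele frequencies")
    f / sum(f)
  })
  structure(list(freqF = norm(freqF), freqO = norm(freqO),
                 loci = as.character(loci)),
            class = "allele_freq_model")
}

#' @export
print.allele_freq_model <- function(x, ...) {
  k <- vapply(x$freqF, length, 1L)
  cat(sprintf("allele_freq_model: %d loci, %d-%d alleles per locus\n",
              length(x$loci), min(k), max(k)))
  invisible(x)
}

#' Estimate parental allele frequencies from observed genotypes
#'
#' Plain counting of allele copies within each group; missing genotypes are
#' excluded. Mirrors the behaviour of HybridLab-style simulators: no
#' pseudo-counts are added unless `smooth = TRUE`, which adds 1/(2n) per
#' observed allele.
#'
#' @param dataset a [microsat_dataset()].
#' @param group_labels factor/character of length `n_samples(dataset)`; the
#'   levels `"fabalis"` and `"obtusata"` (or exactly two levels, taken in
#'   order) define the pools. Samples with other labels are ignored.
#' @param smooth add a small pseudo-frequency to observed alleles.
#' @return an [allele_freq_model()].
#' @export
estimate_allele_frequencies <- function(dataset, group_labels, smooth = FALSE) {
  group_labels <- as.character(group_labels)
  pools <- if (all(c("fabalis", "obtusata") %in% group_labels))
    c("fabalis", "obtusata") else unique(group_labels[!is.na(group_labels)])[1:2]
  if (any(is.na(pools))) stop("need two groups to estimate pool frequencies")
  count_pool <- function(g) {
    idx <- which(group_labels == g)
    lapply(seq_along(dataset$loci), function(l) {
      al <- c(dataset$a1[idx, l], dataset$a2[idx, l])
      al <- al[!is.na(al)]
      if (length(al) < 4)
        stop("locus ", dataset$loci[l], ": fewer than 2 non-missing genotypes in group ", g)
      tb <- table(al)
      f <- as.numeric(tb) / sum(tb)
      names(f) <- names(tb)
      if (smooth) { f <- f + 1 / sum(tb); f <- f / sum(f) }
      f
    })
  }
  allele_freq_model(count_pool(pools[1]), count_pool(pools[2]),
                    loci = dataset$loci)
}

draw_allele <- function(f) sample(names(f), 1L, prob = f)
draw_alleles <- function(f, n) sample(names(f), n, replace = TRUE, prob = f)

#' Simulate multilocus genotypes of a given genotype class
#'
#' HybridLab-style simulation from parental allele frequencies: parentals draw
#' two independent alleles per locus from their own pool; F1 draws one allele
#' from each pool; F2 draws one gamete from each of two independently
#' simulated F1 parents (a gamete being one allele chosen at random per locus
#' from the parent's pair); backcrosses draw one F1 gamete plus one allele
#' from the recurrent pool. Loci are independent.
#'
#' @param class one of `"F"`, `"O"`, `"F1"`, `"F2"`, `"BCF"`, `"BCO"`.
#' @param n number of individuals.
#' @param freqs an [allele_freq_model()].
#' @param seed optional integer seed.
#' @param prefix sample-id prefix.
#' @return a [microsat_dataset()] with `species` set to the class truth for
#'   parentals and `"unknown"` for hybrids.
#' @export
simulate_class <- function(class, n, freqs, seed = NULL, prefix = class) {
  class <- match.arg(class, GENOTYPE_CLASSES)
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs$loci)
  a1 <- matrix(NA_character_, n, L)
  a2 <- matrix(NA_character_, n, L)
  f1_pair <- function(l) c(draw_allele(freqs$freqF[[l]]),
                           draw_allele(freqs$freqO[[l]]))
  gamete <- function(pair) pair[sample.int(2L, 1L)]
  for (l in seq_len(L)) {
    fF <- freqs$freqF[[l]]; fO <- freqs$freqO[[l]]
    for (i in seq_len(n)) {
      g <- switch(class,
        F   = draw_alleles(fF, 2),
        O   = draw_alleles(fO, 2),
        F1  = c(draw_allele(fF), draw_allele(fO)),
        F2  = c(gamete(f1_pair(l)), gamete(f1_pair(l))),
        BCF = c(gamete(f1_pair(l)), draw_allele(fF)),
        BCO = c(gamete(f1_pair(l)), draw_allele(fO)))
      a1[i, l] <- g[1]; a2[i, l] <- g[2]
    }
  }
  species <- switch(class, F = "fabalis", O = "obtusata", "unknown")
  microsat_dataset(a1, a2, freqs$loci,
                   data.frame(sample_id = sprintf("%s_%03d", prefix, seq_len(n)),
                              location = "SIM", context = "undetermined",
                              species = species, stringsAsFactors = FALSE))
}

#' Simulate a labelled set covering all six genotype classes
#'
#' @param n_per_class individuals per class (single value or named vector).
#' @param freqs an [allele_freq_model()].
#' @param seed optional integer seed.
#' @return list with `dataset` (a [microsat_dataset()]) and `truth` (character
#'   vector of true classes).
#' @export
simulate_all_classes <- function(n_per_class, freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(n_per_class) == 1)
    n_per_class <- stats::setNames(rep(n_per_class, 6), GENOTYPE_CLASSES)
  parts <- list(); truth <- character(0)
  for (cl in GENOTYPE_CLASSES) {
    n <- n_per_class[[cl]]
    if (n > 0) {
      parts[[cl]] <- simulate_class(cl, n, freqs, prefix = paste0("sim", cl))
      truth <- c(truth, rep(cl, n))
    }
  }
  list(dataset = do.call(rbind, unname(parts)), truth = truth)
}
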