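#' Collapse an alignment into haplotypes
#'
#' Exact-string collapse: sequences are grouped by identity (sites with N are
#' not treated as wildcards at this stage; they only become wildcards in
#' pairwise distance computation). Haplotypes are numbered in order of first
#' appearance.
#'
#' @param alignment a [haplotype_alignment()].
#' @return data frame of class `haplotype_table` with columns `hap_id`,
#'   `sequence`, `n`, `members` (semicolon-joined sample ids).
#' @export
collapse_haplotypes <- function(alignment) {
  u <- unique(alignment$seqs)
  idx <- match(alignment$seqs, u)
  out <- data.frame(
    hap_id = sprintf("H%02d", seq_along(u)),
    sequence = u,
    n = as.integer(tabulate(idx, length(u))),
    members = vapply(seq_along(u), function(k)
      paste(alignment$ids[idx == k], collapse = ";"), ""),
    stringsAsFactors = FALSE)
  attr(out, "membership") <- stats::setNames(out$hap_id[idx], alignment$ids)
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' Pairwise mutational-step distances between haplotypes
#'
#' Number of differing sites; positions where either sequence carries N or a
#' gap are excluded pairwise (preserving the common alignment frame).
#'
#' @param haps a `haplotype_table` or character vector of sequences.
#' @return integer distance matrix.
#' @export
hap_distances <- function(haps) {
  seqs <- if (is.data.frame(haps)) haps$sequence else as.character(haps)
  ids <- if (is.data.frame(haps)) haps$hap_id else names(seqs) %||%
    paste0("H", seq_along(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  ok <- !(m == "N" | m == "-")
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      use <- ok[i, ] & ok[j, ]
      D[i, j] <- D[j, i] <- sum(m[i, use] != m[j, use])
    }
  D
}

#' Probability that an observed difference count is parsimonious
#'
#' For two sequences of length `seq_length` differing at `j` sites, the
#' probability that the true number of mutational steps separating them is
#' exactly `j` (no superimposed changes). The true step count `b` gets the
#' pairwise-coalescent geometric prior with mean theta (estimated by the
#' observed differences, `theta = j`); the likelihood of observing `j`
#' differing sites after `b` mutations placed uniformly over the sites is
#' computed exactly with a two-state occupancy chain (a site differs iff hit
#' an odd number of times).
#'
#' @param j observed number of differing sites (>= 0).
#' @param seq_length alignment length in sites.
#' @return probability in [0, 1].
#' @export
parsimony_probability <- function(j, seq_length) {
  if (j == 0) return(1)
  L <- seq_length
  if (j > L) stop("more differences than sites")
  theta <- j
  r <- theta / (1 + theta)
  # P(J = j | b): occupancy chain over the number of odd-hit sites o;
  # one more mutation moves o -> o+1 w.p. (L-o)/L, else o -> o-1.
  lik_upto <- function(bmax) {
    probs <- numeric(bmax + 1)            # index b+1
    v <- c(1, numeric(bmax))              # P(o) at step b, index o+1
    for (b in seq_len(bmax)) {
      vn <- numeric(bmax + 1)
      o <- 0:(bmax - 1)
      vn[o + 2] <- vn[o + 2] + v[o + 1] * (L - o) / L   # o -> o+1
      o <- 1:bmax
      vn[o] <- vn[o] + v[o + 1] * o / L                 # o -> o-1
      v <- vn
      if (b >= j) probs[b + 1] <- v[j + 1]
    }
    probs
  }
  bmax <- j + 200L
  f <- lik_upto(bmax)
  b <- j:bmax
  w <- f[b + 1] * r^(b - j)     # prior ratio relative to b = j
  w[1] / sum(w)
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` at which two haplotypes may be
#' connected while the probability of a parsimonious connection (see
#' [parsimony_probability()]) still reaches the confidence level. Single-step
#' connections are always trusted, so the limit is at least 1.
#'
#' @param seq_length alignment length in sites.
#' @param confidence connection criterion (default 0.95).
#' @return integer number of steps.
#' @export
connection_limit <- function(seq_length, confidence = 0.95) {
  if (seq_length < 1) stop("seq_length must be >= 1")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  limit <- 1L
  for (j in seq_len(seq_length)) {
    if (parsimony_probability(j, seq_length) >= confidence) limit <- j
    else break
  }
  limit
}

#' Build a statistical-parsimony haplotype network
#'
#' Minimum-spanning forest over haplotype pairs at distance up to the
#' connection limit (Kruskal order; ties broken by smaller distance, then by
#' the lexicographically smaller haplotype-id pair). Connected components are
#' clades; the two largest are labelled I and II (component members beyond
#' the two largest are flagged `"unconnected"`). Each edge implies
#' `steps - 1` unobserved intermediate haplotypes.
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()].
#' @param limit connection limit in steps (e.g. from [connection_limit()]).
#' @return an object of class `haplotype_network` with `haplotypes`, `edges`
#'   (`hap_i`, `hap_j`, `steps`, `missing_nodes`), `clade` (named vector over
#'   haplotypes), `components`, `limit`.
#' @export
build_network <- function(haps, limit) {
  if (limit < 1) stop("limit must be >= 1")
  D <- hap_distances(haps)
  ids <- haps$hap_id
  n <- length(ids)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  cand <- data.frame(i = pairs[, 1], j = pairs[, 2],
                     d = D[pairs])
  cand <- cand[cand$d <= limit, , drop = FALSE]
  cand <- cand[order(cand$d, ids[cand$i], ids[cand$j]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- cand[0, ]
  for (k in seq_len(nrow(cand))) {
    ri <- find(cand$i[k]); rj <- find(cand$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      edges <- rbind(edges, cand[k, ])
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  comp <- match(comp, unique(comp))
  sizes <- vapply(split(haps$n, comp), sum, 1.0)
  ord <- order(-sizes, vapply(split(ids, comp), min, ""))
  lab <- rep("unconnected", length(sizes))
  lab[ord[1]] <- "I"
  if (length(ord) > 1) lab[ord[2]] <- "II"
  clade <- stats::setNames(lab[comp], ids)
  ed <- if (nrow(edges)) data.frame(hap_i = ids[edges$i], hap_j = ids[edges$j],
                                    steps = edges$d,
                                    missing_nodes = edges$d - 1L,
                                    stringsAsFactors = FALSE)
  else data.frame(hap_i = character(0), hap_j = character(0),
                  steps = integer(0), missing_nodes = integer(0))
  structure(list(haplotypes = haps, edges = ed, clade = clade,
                 components = comp, limit = limit, distances = D),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d haplotypes, %d edges, limit %d steps\n",
              nrow(x$haplotypes), nrow(x$edges), x$limit))
  print(table(clade = x$clade))
  invisible(x)
}

#' Clade label per sequenced sample
#'
#' @param network a [build_network()] result.
#' @param haps the `haplotype_table` used to build it.
#' @return named character vector (sample id -> clade label).
#' @export
sample_clades <- function(network, haps = network$haplotypes) {
  mem <- attr(haps, "membership")
  stats::setNames(unname(network$clade[mem]), names(mem))
}

#' Mitochondrial introgression accounting
#'
#' Per-location and total counts of mtDNA clade membership within each
#' genetic species (labels from the global admixture classification), with
#' introgression defined as carrying a haplotype of the clade typical of the
#' other species. Clade/species polarity is set by the majority clade among
#' pure individuals of each species, so relabelling clades leaves all
#' percentages unchanged. Also reports, per hybrid (if hybrid labels or
#' classes are supplied), the clade composition, and the fraction of
#' sympatric vs allopatric sites showing at least one atypical haplotype.
#'
#' @param clade named character vector: sample id -> clade label (two main
#'   labels; `"unconnected"` entries are dropped with a note).
#' @param genetic named character vector: sample id -> `"pure_fab"`,
#'   `"pure_obt"` (synonyms `fabalis`/`obtusata` accepted) or `"hybrid"`.
#' @param metadata data frame with `sample_id`, `location`, `context`.
#' @param hybrid_class optional named vector: sample id -> genotype class for
#'   hybrids assigned by the class analysis.
#' @return an object of class `introgression_summary`.
#' @export
introgression_summary <- function(clade, genetic, metadata,
                                  hybrid_class = NULL) {
  genetic <- normalize_genetic_labels(genetic)
  ids <- intersect(names(clade), names(genetic))
  drop <- setdiff(names(clade), names(genetic))
  if (length(drop))
    message(length(drop), " sequenced sample(s) without genetic label excluded")
  clade <- clade[ids]; genetic <- genetic[ids]
  keep <- !(clade %in% "unconnected")
  clade <- clade[keep]; genetic <- genetic[keep]; ids <- ids[keep]
  meta <- metadata[match(ids, metadata$sample_id), ]
  loc <- meta$location

  # polarity: the clade typical of each pure species is its majority clade
  cl_levels <- sort(unique(clade))
  maj <- function(sp) {
    tb <- table(factor(clade[genetic == sp], levels = cl_levels))
    if (sum(tb) == 0) return(NA_character_)
    names(tb)[which.max(tb)]
  }
  typ_fab <- maj("pure_fab"); typ_obt <- maj("pure_obt")
  if (is.na(typ_fab) || is.na(typ_obt) || typ_fab == typ_obt)
    stop("cannot polarise clades: pure species share a majority clade")

  pure <- genetic %in% c("pure_fab", "pure_obt")
  locs <- unique(loc)
  row_for <- function(sel, label) {
    fab <- sel & genetic == "pure_fab"
    obt <- sel & genetic == "pure_obt"
    data.frame(location = label,
               N = sum(fab | obt),
               n_fab = sum(fab), n_obt = sum(obt),
               clade_fab_typical = sum((fab | obt) & clade == typ_fab),
               clade_obt_typical = sum((fab | obt) & clade == typ_obt),
               intro_fab = sum(fab & clade == typ_obt),
               intro_obt = sum(obt & clade == typ_fab),
               stringsAsFactors = FALSE)
  }
  by_loc <- do.call(rbind, lapply(locs, function(l) row_for(loc == l, l)))
  tot <- row_for(rep(TRUE, length(ids)), "Total")
  tab <- rbind(by_loc, tot)
  tab$intro_fab_pct <- ifelse(tab$n_fab > 0, 100 * tab$intro_fab / tab$n_fab, NA)
  tab$intro_obt_pct <- ifelse(tab$n_obt > 0, 100 * tab$intro_obt / tab$n_obt, NA)

  # site-level atypical-haplotype flags by geographic context
  ctx <- vapply(locs, function(l) meta$context[match(l, meta$location)], "")
  atyp <- vapply(locs, function(l) {
    r <- by_loc[by_loc$location == l, ]
    (r$n_fab > 0 && r$intro_fab > 0) || (r$n_obt > 0 && r$intro_obt > 0)
  }, TRUE)
  ctx_frac <- vapply(c(sympatric = "sympatric", allopatric = "allopatric"),
                     function(cx) {
                       sel <- ctx == cx
                       if (!any(sel)) NA_real_ else 100 * mean(atyp[sel])
                     }, 1.0)

  hyb <- genetic == "hybrid"
  hybrids_by_location <- NULL
  hybrids_total_pct_cladeII <- NA_real_
  if (any(hyb)) {
    hl <- data.frame(location = loc[hyb],
                     cladeI = clade[hyb] == typ_fab,
                     cladeII = clade[hyb] == typ_obt)
    hybrids_by_location <- do.call(rbind, lapply(split(hl, hl$location),
      function(d) data.frame(location = d$location[1], N = nrow(d),
                             cladeI = sum(d$cladeI), cladeII = sum(d$cladeII))))
    rownames(hybrids_by_location) <- NULL
    hybrids_total_pct_cladeII <- 100 * sum(hl$cladeII) / nrow(hl)
  }
  hybrids_by_class <- NULL
  if (!is.null(hybrid_class)) {
    hc <- hybrid_class[intersect(names(hybrid_class), ids)]
    hc <- hc[hc %in% c("F1", "F2", "BCF", "BCO")]
    if (length(hc)) {
      cl2 <- clade[names(hc)] == typ_obt
      hybrids_by_class <- do.call(rbind, lapply(split(seq_along(hc), hc),
        function(k) data.frame(class = hc[k][1], N = length(k),
                               cladeI = sum(!cl2[k]), cladeII = sum(cl2[k]))))
      rownames(hybrids_by_class) <- NULL
    }
  }
  structure(list(table = tab,
                 polarity = c(fabalis = typ_fab, obtusata = typ_obt),
                 site_atypical = stats::setNames(atyp, locs),
                 site_context = stats::setNames(ctx, locs),
                 context_pct_atypical = ctx_frac,
                 hybrids_by_location = hybrids_by_location,
                 hybrids_pct_cladeII = hybrids_total_pct_cladeII,
                 hybrids_by_class = hybrids_by_class),
            class = "introgression_summary")
}

normalize_genetic_labels <- function(x) {
  v <- as.character(x)
  v[v %in% c("fabalis", "pure_fab", "F")] <- "pure_fab"
  v[v %in% c("obtusata", "pure_obt", "O")] <- "pure_obt"
  v[v %in% c("F1", "F2", "BCF", "BCO", "hybrid")] <- "hybrid"
  names(v) <- names(x)
  v[v %in% c("pure_fab", "pure_obt", "hybrid")]
}

#' @export
print.introgression_summary <- function(x, ...) {
  tb <- x$table
  tot <- tb[tb$location == "Total", ]
  cat(sprintf("introgression into L. fabalis: %d/%d (%.2f%%)\n",
              tot$intro_fab, tot$n_fab, tot$intro_fab_pct))
  cat(sprintf("introgression into L. obtusata: %d/%d (%.2f%%)\n",
              tot$intro_obt, tot$n_obt, tot$intro_obt_pct))
  cat(sprintf("sites with atypical haplotypes: %.1f%% (sympatric) vs %.1f%% (allopatric)\n",
              x$context_pct_atypical["sympatric"],
              x$context_pct_atypical["allopatric"]))
  if (!is.na(x$hybrids_pct_cladeII))
    cat(sprintf("clade II among hybrids: %.1f%%\n", x$hybrids_pct_cladeII))
  invisible(x)
}

#' Expand a per-location clade count table into per-individual labels
#'
#' Utility for running [introgression_summary()] on published count tables:
#' each row gives, per location, the number of sequenced individuals of each
#' genetic species and how many of them carry the atypical clade.
#'
#' @param counts data frame with columns `location`, `context`, `n_fab`,
#'   `n_obt`, `intro_fab` (atypical among fabalis), `intro_obt`.
#' @return list with `clade`, `genetic`, `metadata` ready for
#'   [introgression_summary()].
#' @export
expand_clade_counts <- function(counts) {
  rows <- list(); k <- 0
  add <- function(loc, ctx, sp, cl, n) {
    if (n <= 0) return(invisible(NULL))
    for (i in seq_len(n)) {
      k <<- k + 1
      rows[[k]] <<- data.frame(sample_id = sprintf("%s_%s_%s_%d", loc, sp, cl, i),
                               location = loc, context = ctx,
                               genetic = sp, clade = cl,
                               stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(nrow(counts))) {
    cr <- counts[r, ]
    add(cr$location, cr$context, "pure_fab", "II", cr$intro_fab)
    add(cr$location, cr$context, "pure_fab", "I", cr$n_fab - cr$intro_fab)
    add(cr$location, cr$context, "pure_obt", "I", cr$intro_obt)
    add(cr$location, cr$context, "pure_obt", "II", cr$n_obt - cr$intro_obt)
  }
  df <- do.call(rbind, rows)
  list(clade = stats::setNames(df$clade, df$sample_id),
       genetic = stats::setNames(df$genetic, df$sample_id),
       metadata = df[c("sample_id", "location", "context")])
}
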