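random_alignment <- function(n, L = 60, seed = 1) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    k <- sample(0:8, 1)
    if (k > 0) {
      at <- sample.int(L, k)
      s[at] <- vapply(s[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    paste(s, collapse = "")
  }, "")
  haplotype_alignment(seqs, sprintf("ind%02d", seq_len(n)))
}

test_that("haplotype collapse counts exact sequence identity", {
  a <- haplotype_alignment(c(rep("ACGT", 5), "ACGA"),
                           paste0("s", 1:6))
  h <- collapse_haplotypes(a)
  expect_equal(nrow(h), 2L)
  expect_equal(h$n, c(5L, 1L))
  expect_equal(h$members[1], "s1;s2;s3;s4;s5")
  # one site difference -> two haplotypes
  b <- collapse_haplotypes(haplotype_alignment(c("AAAA", "AAAT")))
  expect_equal(nrow(b), 2L)
})

test_that("pairwise distances exclude N and gap sites pairwise", {
  D <- hap_distances(c("ACGTN", "ACGAA", "AC-TA"))
  expect_equal(D[1, 2], 1L)   # site 5 masked by N
  expect_equal(D[1, 3], 0L)   # sites 3 and 5 masked
  expect_equal(D[2, 3], 1L)   # site 3 masked by gap; site 4 differs
})

test_that("parsimony probability matches a Monte-Carlo evaluation of the model", {
  # brute-force oracle: simulate the generative model (geometric number of
  # mutations with mean j, uniform site hits, two-state visibility) and
  # estimate P(b = j | J = j) directly
  mc_oracle <- function(j, L, nsim = 60000, seed = 99) {
    set.seed(seed)
    theta <- j
    b <- stats::rgeom(nsim, 1 / (1 + theta))
    hits <- 0L
    ok <- 0L
    for (i in seq_len(nsim)) {
      if (b[i] < j) next
      sites <- sample.int(L, b[i], replace = TRUE)
      odd <- sum(table(sites) %% 2 == 1)
      if (odd == j) {
        hits <- hits + 1L
        if (b[i] == j) ok <- ok + 1L
      }
    }
    ok / hits
  }
  for (j in c(2, 6, 10)) {
    exact <- parsimony_probability(j, 569)
    approx <- mc_oracle(j, 569)
    expect_lt(abs(exact - approx), 0.02)
  }
  expect_equal(parsimony_probability(0, 569), 1)
})

test_that("connection limit behaves at the confidence extremes and in length", {
  # confidence -> 1: only single-step connections trusted
  expect_equal(connection_limit(569, 1 - 1e-12), 1L)
  # longer fragments admit at least as many steps
  expect_gte(connection_limit(1138, 0.95), connection_limit(569, 0.95))
  expect_error(connection_limit(569, 1.2), "confidence")
  expect_error(connection_limit(0), "seq_length")
  # the implemented estimator is the largest j meeting the criterion
  lim <- connection_limit(569, 0.95)
  expect_gte(parsimony_probability(lim, 569), 0.95)
  expect_lt(parsimony_probability(lim + 1, 569), 0.95)
})

test_that("network components equal the transitive closure of the <=limit graph", {
  for (seed in c(5, 17)) {
    a <- random_alignment(45, L = 60, seed = seed)
    h <- collapse_haplotypes(a)
    lim <- 3L
    net <- build_network(h, lim)
    # oracle: transitive closure by repeated boolean matrix multiplication
    D <- hap_distances(h)
    adj <- (D <= lim); diag(adj) <- TRUE
    reach <- adj
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach > 0)) break
      reach <- nxt
    }
    comp_oracle <- match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
                         unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
    expect_equal(as.integer(factor(net$components)),
                 as.integer(factor(comp_oracle)))
    # spanning forest: edges within limit, one fewer edge than nodes per comp
    expect_true(all(net$edges$steps <= lim))
    expect_equal(nrow(net$edges), nrow(h) - length(unique(net$components)))
  }
})

test_that("two clusters beyond the limit form two clades; stars stay connected", {
  two <- haplotype_alignment(c("AAAAAAAAAA", "AAAAAAAAAT",
                               "TTTTTTTTTA", "TTTTTTTTTT"))
  h <- collapse_haplotypes(two)
  net <- build_network(h, 2)
  expect_equal(length(unique(net$components)), 2L)
  expect_setequal(unname(net$clade), c("I", "I", "II", "II"))

  star <- haplotype_alignment(c("AAAAA", "TAAAA", "ATAAA", "AATAA"))
  nets <- build_network(collapse_haplotypes(star), 1)
  expect_equal(length(unique(nets$components)), 1L)
  expect_true(all(nets$edges$steps == 1))
  expect_true(all(nets$edges$missing_nodes == 0))
})

test_that("introgression accounting reproduces published per-location totals", {
  counts <- littorina_mtdna_counts()
  x <- expand_clade_counts(counts)
  isum <- introgression_summary(x$clade, x$genetic, x$metadata)
  tot <- isum$table[isum$table$location == "Total", ]
  expect_equal(tot$intro_fab, 85); expect_equal(tot$n_fab, 459)
  expect_equal(tot$intro_obt, 49); expect_equal(tot$n_obt, 303)
  expect_equal(tot$intro_fab_pct, 100 * 85 / 459)
  expect_equal(tot$intro_obt_pct, 100 * 49 / 303)
  # published table prints 18.51 (truncated) and 16.17
  expect_lt(abs(tot$intro_fab_pct - 18.51), 0.015)
  expect_lt(abs(tot$intro_obt_pct - 16.17), 0.015)
  alds <- isum$table[isum$table$location == "ALDS", ]
  expect_equal(round(alds$intro_fab_pct, 2), 91.67)
  expect_equal(round(unname(isum$context_pct_atypical["sympatric"]), 1), 84.6)
  expect_equal(round(unname(isum$context_pct_atypical["allopatric"]), 1), 30.8)
  # conservation: per-location counts sum to the Total row
  per <- isum$table[isum$table$location != "Total", ]
  expect_equal(sum(per$n_fab), tot$n_fab)
  expect_equal(sum(per$intro_obt), tot$intro_obt)
})

test_that("clade polarity is anchored by species, not by clade labels", {
  counts <- littorina_mtdna_counts()
  x <- expand_clade_counts(counts)
  flipped <- c(I = "II", II = "I")[x$clade]
  names(flipped) <- names(x$clade)
  a <- introgression_summary(x$clade, x$genetic, x$metadata)
  b <- introgression_summary(flipped, x$genetic, x$metadata)
  expect_equal(a$table$intro_fab_pct, b$table$intro_fab_pct)
  expect_equal(a$table$intro_obt_pct, b$table$intro_obt_pct)
})

test_that("hybrid clade composition is summarised per location and per class", {
  # rebuild the published hybrid clade counts as individual labels
  hc <- littorina_hybrid_clades()
  loc <- hc[hc$group == "location", ]
  cls <- hc[hc$group == "class", ]
  ids <- character(0); clade <- character(0); genetic <- character(0)
  location <- character(0); hclass <- character(0)
  k <- 0
  for (r in seq_len(nrow(loc))) {
    for (cl in c(rep("I", loc$clade1[r]), rep("II", loc$clade2[r]))) {
      k <- k + 1
      ids <- c(ids, paste0("h", k)); clade <- c(clade, cl)
      genetic <- c(genetic, "hybrid"); location <- c(location, loc$label[r])
    }
  }
  # anchor polarity with two pure individuals per species
  ids <- c(ids, "pf1", "pf2", "po1", "po2")
  clade <- c(clade, "I", "I", "II", "II")
  genetic <- c(genetic, "pure_fab", "pure_fab", "pure_obt", "pure_obt")
  location <- c(location, "REF", "REF", "REF", "REF")
  md <- data.frame(sample_id = ids, location = location,
                   context = "sympatric")
  isum <- introgression_summary(stats::setNames(clade, ids),
                                stats::setNames(genetic, ids), md)
  expect_equal(round(isum$hybrids_pct_cladeII, 1), 77.2)
  expect_equal(sum(isum$hybrids_by_location$N), 57)

  # per-class table from the class rows
  ids2 <- character(0); clade2 <- character(0); cls2 <- character(0)
  k <- 0
  for (r in seq_len(nrow(cls))) {
    for (cl in c(rep("I", cls$clade1[r]), rep("II", cls$clade2[r]))) {
      k <- k + 1
      ids2 <- c(ids2, paste0("c", k)); clade2 <- c(clade2, cl)
      cls2 <- c(cls2, cls$label[r])
    }
  }
  ids_all <- c(ids2, "pf1", "pf2", "po1", "po2")
  clade_all <- c(clade2, "I", "I", "II", "II")
  gen_all <- c(rep("hybrid", length(ids2)), "pure_fab", "pure_fab",
               "pure_obt", "pure_obt")
  md2 <- data.frame(sample_id = ids_all, location = "X",
                    context = "sympatric")
  isum2 <- introgression_summary(stats::setNames(clade_all, ids_all),
                                 stats::setNames(gen_all, ids_all), md2,
                                 hybrid_class = stats::setNames(cls2, ids2))
  bc <- isum2$hybrids_by_class
  expect_equal(sum(bc$N), 27)
  expect_equal(round(100 * sum(bc$cladeII) / sum(bc$N), 1), 81.5)
})

test_that("synthetic introgression is recovered within binomial error", {
  sim <- simulate_dataset(sim_config(
    n_per_group = 120, seed = 19,
    hybrid_fractions = c(F1 = 0, F2 = 0, BCF = 0, BCO = 0),
    mtdna_introgression = c(fabalis = 0.2, obtusata = 0.1)))
  net <- build_network(collapse_haplotypes(sim$haplotypes),
                       connection_limit(569))
  clades <- sample_clades(net)
  isum <- introgression_summary(clades, truth_genetic(sim$truth),
                                sim$genotypes$meta)
  tot <- isum$table[isum$table$location == "Total", ]
  expect_gt(tot$intro_fab_pct, 15); expect_lt(tot$intro_fab_pct, 25)
  expect_gt(tot$intro_obt_pct, 5);  expect_lt(tot$intro_obt_pct, 15)
})
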