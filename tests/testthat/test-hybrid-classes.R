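# Independent oracle: enumerate the per-locus ancestry state of each class by
# brute force over gamete combinations (Punnett-style), two generations deep.
# An allele is tracked only by its pool of origin ("f"/"o").
enumerate_ancestry <- function(class) {
  gametes <- function(pair) list(pair[1], pair[2])
  cross <- function(p1, p2) {
    out <- list()
    for (g1 in gametes(p1)) for (g2 in gametes(p2))
      out[[length(out) + 1]] <- c(g1, g2)
    out
  }
  parents <- list(F = c("f", "f"), O = c("o", "o"))
  f1 <- cross(parents$F, parents$O)   # every F1 is c("f","o")
  offspring <- switch(class,
    F = list(parents$F), O = list(parents$O), F1 = f1,
    F2 = { out <- list()
           for (a in f1) for (b in f1) out <- c(out, cross(a, b)); out },
    BCF = { out <- list()
            for (a in f1) out <- c(out, cross(a, parents$F)); out },
    BCO = { out <- list()
            for (a in f1) out <- c(out, cross(a, parents$O)); out })
  state <- vapply(offspring, function(g) sum(g == "o"), 1)  # 0, 1, 2 o-alleles
  tab <- tabulate(state + 1, 3)
  tab / sum(tab)
}

test_that("class ancestry proportions match the Punnett enumeration oracle", {
  tab <- class_proportion_table()
  for (i in seq_len(nrow(tab))) {
    expect_equal(unlist(tab[i, c("p_FF", "p_FO", "p_OO")], use.names = FALSE),
                 enumerate_ancestry(tab$class[i]),
                 info = tab$class[i])
  }
  expect_equal(rowSums(tab[, -1]), rep(1, 6), ignore_attr = TRUE)
})

test_that("allele frequencies are estimated by plain counting", {
  d <- microsat_dataset(rbind("a", "a"), rbind("a", "a"), "L1",
                        data.frame(sample_id = c("x", "y"),
                                   species = c("fabalis", "fabalis")))
  d2 <- microsat_dataset(rbind("a", "a"), rbind("b", "a"), "L1",
                         data.frame(sample_id = c("x", "y"),
                                    species = c("obtusata", "obtusata")))
  m <- estimate_allele_frequencies(rbind(d, d2),
                                   c(d$meta$species, d2$meta$species))
  expect_equal(m$freqF[[1]], c(a = 1))
  expect_equal(m$freqO[[1]], c(a = 0.75, b = 0.25))

  # a group with no observations at a locus is an error naming the locus
  d3 <- microsat_dataset(rbind(c("a", NA)), rbind(c("a", NA)), c("L1", "L2"),
                         data.frame(sample_id = "z", species = "fabalis"))
  d4 <- microsat_dataset(rbind(c("b", "c")), rbind(c("b", "c")), c("L1", "L2"),
                         data.frame(sample_id = "w", species = "obtusata"))
  expect_error(estimate_allele_frequencies(rbind(d3, d3, d4, d4),
                                           rep(c("fabalis", "obtusata"), each = 2)),
               "L2")
})

test_that("estimated frequencies converge to the generator frequencies", {
  set.seed(21)
  fr <- simulate_parental_frequencies(sim_config(seed = 21))
  d <- rbind(simulate_class("F", 1000, fr), simulate_class("O", 1000, fr))
  est <- estimate_allele_frequencies(d, d$meta$species)
  err <- 0
  for (l in 1:11) {
    f <- fr$freqF[[l]]
    e <- est$freqF[[l]][names(f)]
    e[is.na(e)] <- 0
    err <- max(err, max(abs(f - e)))
  }
  # binomial oracle: per-allele s.e. <= sqrt(0.25/2000) = 0.0112; the max
  # over 88 locus-allele estimates stays below 4 s.e. with prob > 99%
  expect_lt(err, 4 * sqrt(0.25 / 2000))
})

test_that("simulated classes follow Mendelian expectations at diagnostic loci", {
  fr <- fixed_freq_model()
  # every F1 heterozygous diagnostic at all 11 loci
  set.seed(31)
  f1 <- simulate_class("F1", 50, fr)
  expect_true(all(f1$a1 == "100" & f1$a2 == "200"))

  # F2 per-locus genotype proportions (0.25, 0.5, 0.25) within binomial error
  set.seed(32)
  f2 <- simulate_class("F2", 2000, fr)
  het <- mean(f2$a1 != f2$a2)
  homF <- mean(f2$a1 == "100" & f2$a2 == "100")
  homO <- mean(f2$a1 == "200" & f2$a2 == "200")
  n <- 2000 * 11
  tol <- 3 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), tol)
  expect_lt(abs(homF - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(homO - 0.25), 3 * sqrt(0.25 * 0.75 / n))

  # BCO: expected fraction of O-O homozygous loci = 0.5 (ancestry oracle)
  set.seed(33)
  bco <- simulate_class("BCO", 2000, fr)
  oo <- mean(bco$a1 == "200" & bco$a2 == "200")
  expect_lt(abs(oo - 0.5), tol)
  expect_equal(mean(bco$a1 == "100" & bco$a2 == "100"), 0)  # p_FF = 0
})

test_that("class allele frequencies mix the pools by expected ancestry", {
  # E[freq] = p_class * freqF + (1 - p_class) * freqO, p_class per class
  set.seed(41)
  fr <- simulate_parental_frequencies(sim_config(seed = 41))
  p_class <- c(F = 1, O = 0, F1 = 0.5, F2 = 0.5, BCF = 0.75, BCO = 0.25)
  for (cl in c("F1", "F2", "BCF", "BCO")) {
    sim <- simulate_class(cl, 5000, fr)
    w <- p_class[[cl]]
    worst <- 0
    for (l in c(1, 6, 11)) {
      f <- fr$freqF[[l]]; o <- fr$freqO[[l]]
      expected <- w * f + (1 - w) * o
      al <- c(sim$a1[, l], sim$a2[, l])
      obs <- table(factor(al, levels = names(f))) / length(al)
      worst <- max(worst, max(abs(as.numeric(obs) - expected)))
    }
    expect_lt(worst, 0.02)
  }
})

test_that("per-locus class likelihoods match direct enumeration", {
  # oracle: enumerate pool-of-origin assignments of the two allele copies
  fF <- c(a = 0.7, b = 0.2, c = 0.1)
  fO <- c(a = 0.1, b = 0.3, c = 0.6)
  oracle <- function(a1, a2, g) {
    G <- class_proportion_table()
    w <- unlist(G[G$class == g, -1])
    tot <- 0
    for (s in 0:2) {           # ancestry state: # alleles from O pool
      states <- if (s == 0) list(c("F", "F")) else
        if (s == 2) list(c("O", "O")) else list(c("F", "O"), c("O", "F"))
      lik <- 0
      for (st in states) {
        pick <- function(pool, al) if (pool == "F") fF[[al]] else fO[[al]]
        # unordered genotype: sum over orderings, halve duplicates
        lik <- lik + if (a1 == a2) pick(st[1], a1) * pick(st[2], a2) / length(states)
        else (pick(st[1], a1) * pick(st[2], a2) +
                pick(st[1], a2) * pick(st[2], a1)) / length(states)
      }
      tot <- tot + w[s + 1] * lik
    }
    unname(tot)
  }
  for (g in c("F", "O", "F1", "F2", "BCF", "BCO")) {
    expect_equal(genotype_class_likelihood("a", "b", fF, fO)$class[[g]],
                 oracle("a", "b", g), info = g)
    expect_equal(genotype_class_likelihood("c", "c", fF, fO)$class[[g]],
                 oracle("c", "c", g), info = g)
  }
})
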