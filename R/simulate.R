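#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the study conditions of the flat-periwinkle system:
#' 11 microsatellite loci at a between-species differentiation of
#' Fst = 0.45, mitochondrial clades separated by ~20 mutational steps over a
#' 569 bp fragment with moderate cross-species haplotype sharing (the overall
#' introgression proportions observed in north-western Iberia), two shell
#' shape/size distributions with allometry and among-location variation, and
#' a BCO-dominated hybrid composition at sympatric sites as seen in the one
#' high-hybridization contact.
#'
#' @param n_loci,alleles_per_locus microsatellite panel dimensions.
#' @param target_fst between-pool differentiation in [0, 1).
#' @param n_per_group individuals per species per location.
#' @param n_locations number of locations: the first two are sympatric, the
#'   remainder alternate allopatric \emph{fabalis}/\emph{obtusata} sites.
#' @param hybrid_fractions named proportions (F1, F2, BCF, BCO) of samples at
#'   sympatric locations that are hybrids; must sum to at most 1.
#' @param mtdna_length,mtdna_interclade_steps mitochondrial fragment length
#'   and divergence between clade centres.
#' @param mtdna_haps_per_clade satellite haplotypes per clade (1-3 steps from
#'   the clade centre, star topology).
#' @param mtdna_introgression named per-species probability that an
#'   individual carries the other species' typical clade.
#' @param hybrid_cladeII_prob probability that a hybrid carries the clade
#'   typical of \emph{L. obtusata} (maternal bias).
#' @param shape_separation Procrustes distance between the two species' mean
#'   shapes (unit-centroid-size scale).
#' @param landmark_noise_sd isotropic landmark noise (same scale).
#' @param size_means,size_sds per-species mean and s.d. of log centroid size.
#' @param allometry_slope shape displacement per unit log centroid size along
#'   the interspecific shape axis.
#' @param location_effect_sd s.d. of the per-location shape offset;
#'   `size_location_sd` the per-location log-size offset.
#' @param genital_means 2 x 7 matrix of genital feature means (rows fabalis,
#'   obtusata); `genital_sds` the common within-class s.d. per feature.
#' @param prop_male probability that an individual is male.
#' @param seed integer seed; a fixed seed makes the output fully reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 11, alleles_per_locus = 8, target_fst = 0.45,
                       n_per_group = 50, n_locations = 4,
                       hybrid_fractions = c(F1 = 0.01, F2 = 0.02,
                                            BCF = 0.02, BCO = 0.05),
                       mtdna_length = 569, mtdna_interclade_steps = 20,
                       mtdna_haps_per_clade = 5,
                       mtdna_introgression = c(fabalis = 0.185,
                                               obtusata = 0.162),
                       hybrid_cladeII_prob = 0.8,
                       shape_separation = 0.15, landmark_noise_sd = 0.01,
                       size_means = c(fabalis = 1.75, obtusata = 2.0),
                       size_sds = c(fabalis = 0.15, obtusata = 0.15),
                       allometry_slope = 0.1,
                       location_effect_sd = 0.01, size_location_sd = 0.1,
                       genital_means = NULL,
                       genital_sds = c(0.15, 0.3, 0.2, 0.5, 2, 0.1, 0.05),
                       prop_male = 0.5, seed = 1L) {
  if (target_fst < 0 || target_fst >= 1) stop("target_fst must be in [0, 1)")
  if (any(hybrid_fractions < 0) || sum(hybrid_fractions) > 1)
    stop("hybrid_fractions must be non-negative and sum to at most 1")
  if (is.null(genital_means))
    genital_means <- rbind(
      fabalis  = c(filament_length = 2.0, total_penis_length = 5.0,
                   gland_row_length = 1.5, n_rows = 3, n_glands = 12,
                   penis_width = 1.2, tip_width = 0.5),
      obtusata = c(filament_length = 0.9, total_penis_length = 5.5,
                   gland_row_length = 2.5, n_rows = 5, n_glands = 25,
                   penis_width = 1.5, tip_width = 0.6))
  cfg <- list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
              target_fst = target_fst, n_per_group = n_per_group,
              n_locations = n_locations, hybrid_fractions = hybrid_fractions,
              mtdna_length = mtdna_length,
              mtdna_interclade_steps = mtdna_interclade_steps,
              mtdna_haps_per_clade = mtdna_haps_per_clade,
              mtdna_introgression = mtdna_introgression,
              hybrid_cladeII_prob = hybrid_cladeII_prob,
              shape_separation = shape_separation,
              landmark_noise_sd = landmark_noise_sd,
              size_means = size_means, size_sds = size_sds,
              allometry_slope = allometry_slope,
              location_effect_sd = location_effect_sd,
              size_location_sd = size_location_sd,
              genital_means = genital_means, genital_sds = genital_sds,
              prop_male = prop_male, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate diverged parental allele frequencies
#'
#' Balding-Nichols parameterization: per locus, an ancestral frequency vector
#' is drawn from a flat Dirichlet and each parental pool draws its own
#' frequencies from Dirichlet(ancestral x (1 - F)/F). Because a handful of
#' loci leaves substantial between-run spread in the realized divergence, the
#' draw is calibrated: the parametric (infinite-sample) multilocus
#' Weir-Cockerham Fst of the drawn pools is computed and the concentration
#' adjusted (re-drawing) until it is within 0.01 of `target_fst`, so a run at
#' the study conditions really sits at the stated differentiation. At
#' `target_fst = 0` both pools share the ancestral draw.
#'
#' @param cfg a [sim_config()] (its `n_loci`, `alleles_per_locus`,
#'   `target_fst` and `seed` fields are used).
#' @return an [allele_freq_model()].
#' @export
simulate_parental_frequencies <- function(cfg) {
  if (cfg$alleles_per_locus < 2 && cfg$target_fst > 0)
    stop("cannot create divergence with a single allele per locus")
  A <- cfg$alleles_per_locus
  labels <- sprintf("%03d", 100 + 2 * seq_len(A))
  draw_set <- function(Fadj) {
    fF <- fO <- vector("list", cfg$n_loci)
    for (l in seq_len(cfg$n_loci)) {
      anc <- rdirichlet1(rep(1, A))
      if (cfg$target_fst == 0) {
        fF[[l]] <- fO[[l]] <- stats::setNames(anc, labels)
      } else {
        conc <- (1 - Fadj) / Fadj
        fF[[l]] <- stats::setNames(rdirichlet1(anc * conc), labels)
        fO[[l]] <- stats::setNames(rdirichlet1(anc * conc), labels)
      }
    }
    allele_freq_model(fF, fO, loci = paste0("Loc", seq_len(cfg$n_loci)))
  }
  if (cfg$target_fst == 0) return(draw_set(0))
  Fadj <- cfg$target_fst
  best <- NULL; best_err <- Inf
  for (it in 1:50) {
    m <- draw_set(Fadj)
    fst <- parametric_wc_fst(m)
    err <- abs(fst - cfg$target_fst)
    if (err < best_err) { best <- m; best_err <- err }
    if (err <= 0.01) break
    Fadj <- min(0.995, max(1e-4, Fadj * cfg$target_fst / fst))
  }
  best
}

#' Parametric Weir-Cockerham Fst of an allele-frequency model
#'
#' Infinite-sample-size limit of the two-population Weir-Cockerham theta for
#' the model's pool frequencies (ratio of sums over loci and alleles).
#'
#' @param freqs an [allele_freq_model()].
#' @return scalar Fst.
#' @export
parametric_wc_fst <- function(freqs) {
  num <- den <- 0
  for (l in seq_along(freqs$loci)) {
    p1 <- freqs$freqF[[l]]; p2 <- freqs$freqO[[l]]
    s2 <- (p1 - p2)^2 / 2
    pbar <- (p1 + p2) / 2
    num <- num + sum(s2)
    den <- den + sum(pbar * (1 - pbar) + s2 / 2)
  }
  num / den
}

#' Multiallelic Weir-Cockerham Fst between two groups
#'
#' The 1984 variance-components estimator (theta), summed over alleles and
#' loci (ratio of sums).
#'
#' @param dataset a [microsat_dataset()].
#' @param labels group labels (exactly two groups used).
#' @return scalar Fst estimate.
#' @export
wc_fst <- function(dataset, labels) {
  labels <- as.character(labels)
  gr <- unique(labels[!is.na(labels)])
  if (length(gr) != 2) stop("need exactly two groups")
  num <- den <- 0
  r <- 2
  for (l in seq_along(dataset$loci)) {
    alleles <- sort(unique(c(dataset$a1[, l], dataset$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    n_i <- p_i <- h_i <- NULL
    n_i <- vapply(gr, function(g) {
      idx <- labels == g
      sum(!is.na(dataset$a1[idx, l]))
    }, 1.0)
    if (any(n_i < 2)) next
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (a in alleles) {
      p_i <- vapply(gr, function(g) {
        idx <- labels == g & !is.na(dataset$a1[, l])
        mean(c(dataset$a1[idx, l] == a, dataset$a2[idx, l] == a))
      }, 1.0)
      h_i <- vapply(gr, function(g) {
        idx <- labels == g & !is.na(dataset$a1[, l])
        mean((dataset$a1[idx, l] == a) != (dataset$a2[idx, l] == a))
      }, 1.0)
      pbar <- sum(n_i * p_i) / sum(n_i)
      hbar <- sum(n_i * h_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      va <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                   hbar / 4) / (nbar - 1))
      vb <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                     hbar * (2 * nbar - 1) / (4 * nbar))
      vc <- hbar / 2
      num <- num + va
      den <- den + va + vb + vc
    }
  }
  num / den
}

#' Synthetic mean shell outlines
#'
#' Two hand-crafted 28-point outlines (4 fixed landmarks + 24 semilandmarks
#' in cyclic order) contrasting a rounder, wider-aperture form
#' (\emph{fabalis}-like) with a more elongate, narrower form
#' (\emph{obtusata}-like). Stored as a plain-text package fixture; both are
#' returned centred and scaled to unit centroid size.
#'
#' @return list with `fabalis` and `obtusata` 28 x 2 matrices.
#' @export
mean_shell_shapes <- function() {
  f <- system.file("extdata", "shell_mean_shapes_synthetic.csv",
                   package = "hybridscan")
  df <- utils::read.csv(f)
  unitize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  fab <- unitize(cbind(df$fab_x, df$fab_y))
  obt <- unitize(cbind(df$obt_x, df$obt_y))
  obt <- opa_rotate(obt, fab)
  list(fabalis = fab, obtusata = obt)
}

sim_locations <- function(cfg) {
  n <- cfg$n_locations
  code <- character(n); ctx <- character(n); fab <- obt <- logical(n)
  for (i in seq_len(n)) {
    if (i <= min(2, n)) {
      code[i] <- paste0("SY", i); ctx[i] <- "sympatric"
      fab[i] <- obt[i] <- TRUE
    } else if ((i - min(2, n)) %% 2 == 1) {
      code[i] <- paste0("AF", i); ctx[i] <- "allopatric"
      fab[i] <- TRUE
    } else {
      code[i] <- paste0("AO", i); ctx[i] <- "allopatric"
      obt[i] <- TRUE
    }
  }
  data.frame(code = code, context = ctx, fabalis = fab, obtusata = obt,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic study dataset
#'
#' Draws genotypes (Hardy-Weinberg within parental pools; hybrid classes via
#' the class simulator), mitochondrial haplotypes (two clades separated by
#' the configured number of mutational steps, star topology within clades,
#' species-typical clade flipped with the introgression probability), shell
#' landmark configurations (species mean shape + allometric displacement +
#' location offset + isotropic noise, scaled by centroid size and placed at a
#' random position/orientation) and male genital measurements. Every latent
#' label is recorded in the truth table. Output is fully determined by
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `hybridscan_sim`: `genotypes`
#'   ([microsat_dataset()]), `haplotypes` ([haplotype_alignment()]),
#'   `landmarks` ([landmark_set()]), `genitalia`
#'   ([genital_measurements()]), `truth` (data frame), `freqs`, `sites`,
#'   `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  freqs <- simulate_parental_frequencies(cfg)
  sites <- sim_locations(cfg)

  # --- assign per-individual location / class ---------------------------
  rows <- list()
  for (s in seq_len(nrow(sites))) {
    species_here <- c("F", "O")[c(sites$fabalis[s], sites$obtusata[s])]
    n_here <- cfg$n_per_group * length(species_here)
    cls <- rep(species_here, each = cfg$n_per_group)
    if (sites$context[s] == "sympatric" && sum(cfg$hybrid_fractions) > 0) {
      nh <- stats::rbinom(1, n_here, sum(cfg$hybrid_fractions))
      if (nh > 0) {
        hcls <- sample(names(cfg$hybrid_fractions), nh, replace = TRUE,
                       prob = cfg$hybrid_fractions)
        cls[sample.int(n_here, nh)] <- hcls
      }
    }
    rows[[s]] <- data.frame(location = sites$code[s],
                            context = sites$context[s], true_class = cls,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  n <- nrow(truth)
  truth$sample_id <- sprintf("sim_%04d", seq_len(n))
  truth$sex <- ifelse(stats::runif(n) < cfg$prop_male, "M", "F")

  # --- genotypes --------------------------------------------------------
  parts <- vector("list", n)
  for (i in seq_len(n))
    parts[[i]] <- simulate_class(truth$true_class[i], 1, freqs,
                                 prefix = truth$sample_id[i])
  geno <- do.call(rbind, parts)
  putative <- ifelse(truth$true_class == "F", "fabalis",
                     ifelse(truth$true_class == "O", "obtusata", "unknown"))
  geno$meta <- normalize_meta(
    data.frame(sample_id = truth$sample_id, location = truth$location,
               context = truth$context, species = putative,
               ecotype = NA_character_, sex = truth$sex,
               stringsAsFactors = FALSE), n)
  rownames(geno$a1) <- rownames(geno$a2) <- truth$sample_id

  # --- mtDNA ------------------------------------------------------------
  hap <- simulate_haplotype_pool(cfg)
  anc_fab <- ancestry_weight(truth$true_class)
  clade_typical <- ifelse(anc_fab >= 0.75, "I", ifelse(anc_fab <= 0.25, "II", NA))
  truth$true_clade <- vapply(seq_len(n), function(i) {
    cl <- truth$true_class[i]
    if (cl == "F") {
      if (stats::runif(1) < cfg$mtdna_introgression[["fabalis"]]) "II" else "I"
    } else if (cl == "O") {
      if (stats::runif(1) < cfg$mtdna_introgression[["obtusata"]]) "I" else "II"
    } else {
      if (stats::runif(1) < cfg$hybrid_cladeII_prob) "II" else "I"
    }
  }, "")
  hap_idx <- vapply(truth$true_clade, function(cl) {
    pool <- if (cl == "I") seq_len(cfg$mtdna_haps_per_clade)
    else cfg$mtdna_haps_per_clade + seq_len(cfg$mtdna_haps_per_clade)
    if (stats::runif(1) < 0.5) pool[1] else sample(pool[-1], 1)
  }, 1)
  truth$true_hap <- hap_idx
  haps <- haplotype_alignment(hap$seqs[hap_idx], truth$sample_id)

  # --- landmarks --------------------------------------------------------
  ms <- mean_shell_shapes()
  dif <- ms$fabalis - ms$obtusata
  d0 <- sqrt(sum(dif^2))
  mid <- (ms$fabalis + ms$obtusata) / 2
  dir <- if (d0 > 0) dif / d0 else dif
  mean_fab <- mid + dir * cfg$shape_separation / 2
  mean_obt <- mid - dir * cfg$shape_separation / 2
  loc_codes <- sites$code
  loc_shape <- lapply(loc_codes, function(l)
    matrix(stats::rnorm(56, 0, cfg$location_effect_sd), 28, 2))
  names(loc_shape) <- loc_codes
  loc_size <- stats::setNames(stats::rnorm(length(loc_codes), 0,
                                           cfg$size_location_sd), loc_codes)
  mu_size <- anc_fab * cfg$size_means[["fabalis"]] +
    (1 - anc_fab) * cfg$size_means[["obtusata"]]
  sd_size <- anc_fab * cfg$size_sds[["fabalis"]] +
    (1 - anc_fab) * cfg$size_sds[["obtusata"]]
  truth$logcs <- stats::rnorm(n, mu_size + loc_size[truth$location], sd_size)
  mean_logcs <- mean(truth$logcs)
  coords <- array(NA_real_, c(n, 28, 2))
  for (i in seq_len(n)) {
    shp <- anc_fab[i] * mean_fab + (1 - anc_fab[i]) * mean_obt +
      cfg$allometry_slope * (truth$logcs[i] - mean_logcs) * dir +
      loc_shape[[truth$location[i]]] +
      matrix(stats::rnorm(56, 0, cfg$landmark_noise_sd), 28, 2)
    ang <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    coords[i, , ] <- shp %*% R * exp(truth$logcs[i]) +
      rep(stats::runif(2, -10, 10), each = 28)
  }
  lms <- landmark_set(coords, ids = truth$sample_id)

  # --- genitalia (males only) -------------------------------------------
  males <- which(truth$sex == "M")
  gm <- cfg$genital_means
  G <- matrix(NA_real_, length(males), 7,
              dimnames = list(NULL, colnames(gm)))
  for (k in seq_along(males)) {
    w <- anc_fab[males[k]]
    mu <- w * gm["fabalis", ] + (1 - w) * gm["obtusata", ]
    G[k, ] <- stats::rnorm(7, mu, cfg$genital_sds)
  }
  G[, "n_rows"] <- pmax(1, round(G[, "n_rows"]))
  G[, "n_glands"] <- pmax(1, round(G[, "n_glands"]))
  G[G < 0.01] <- 0.01
  G[, "filament_length"] <- pmin(G[, "filament_length"],
                                 0.95 * G[, "total_penis_length"])
  genitalia <- genital_measurements(
    data.frame(sample_id = truth$sample_id[males], G,
               stringsAsFactors = FALSE))

  truth <- truth[c("sample_id", "location", "context", "true_class",
                   "true_clade", "true_hap", "sex", "logcs")]
  structure(list(genotypes = geno, haplotypes = haps, landmarks = lms,
                 genitalia = genitalia, truth = truth, freqs = freqs,
                 sites = sites, cfg = cfg),
            class = "hybridscan_sim")
}

# expected proportion of alleles from the fabalis pool per class
ancestry_weight <- function(cls) {
  w <- c(F = 1, O = 0, F1 = 0.5, F2 = 0.5, BCF = 0.75, BCO = 0.25)
  unname(w[cls])
}

transition <- c(A = "G", G = "A", C = "T", T = "C")

mutate_sites <- function(seq, sites) {
  s <- strsplit(seq, "")[[1]]
  s[sites] <- transition[s[sites]]
  paste(s, collapse = "")
}

# clade centres separated by the configured steps; satellites 1-3 steps out
simulate_haplotype_pool <- function(cfg) {
  L <- cfg$mtdna_length
  base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
  inter <- sample.int(L, cfg$mtdna_interclade_steps)
  centreI <- base
  centreII <- mutate_sites(base, inter)
  satellites <- function(centre, avoid) {
    out <- centre
    for (k in seq_len(cfg$mtdna_haps_per_clade - 1)) {
      nmut <- sample(1:3, 1)
      st <- sample(setdiff(seq_len(L), avoid), nmut)
      out <- c(out, mutate_sites(centre, st))
    }
    out
  }
  seqs <- c(satellites(centreI, inter), satellites(centreII, inter))
  list(seqs = seqs,
       clade = rep(c("I", "II"), each = cfg$mtdna_haps_per_clade))
}

#' @export
print.hybridscan_sim <- function(x, ...) {
  cat(sprintf("hybridscan_sim: %d individuals over %d locations (seed %d)\n",
              nrow(x$truth), nrow(x$sites), x$cfg$seed))
  print(table(class = x$truth$true_class))
  invisible(x)
}

#' Write all synthetic inputs to disk
#'
#' Serialises a simulated dataset in the package's interchange formats:
#' genotype CSV, FASTA, TPS, genitalia CSV and a truth-table CSV.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.csv"),
             haplotypes = file.path(dir, "haplotypes.fasta"),
             landmarks = file.path(dir, "shells.tps"),
             genitalia = file.path(dir, "genitalia.csv"),
             truth = file.path(dir, "truth.csv"))
  write_genotypes(sim$genotypes, paths["genotypes"])
  write_fasta(sim$haplotypes, paths["haplotypes"])
  write_tps(sim$landmarks, paths["landmarks"])
  utils::write.csv(as.data.frame(sim$genitalia), paths["genitalia"],
                   row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  paths
}
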