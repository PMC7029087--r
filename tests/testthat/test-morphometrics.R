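test_that("centroid size follows its defining formula on a unit square", {
  # hand computation: centred corners at (+-0.5, +-0.5), so the summed
  # squared distances are 4 * 0.5 = 2 and CS = sqrt(2)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq)^2, 2)
  expect_equal(centroid_size(sq), sqrt(2))
  # scaling the square scales CS linearly
  expect_equal(centroid_size(3 * sq), 3 * sqrt(2))
})

test_that("GPA is invariant under similarity transforms", {
  set.seed(81)
  base <- mean_shell_shapes()$fabalis
  arr <- array(NA_real_, c(8, 28, 2))
  for (i in 1:8) {
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    arr[i, , ] <- base %*% R * runif(1, 0.2, 5) + rep(runif(2, -9, 9), each = 28)
  }
  sh <- gpa_align(landmark_set(arr), slide = FALSE)
  expect_lt(max(apply(sh$shapes, 2, function(v) diff(range(v)))), 1e-9)
  # with sliding the invariance must hold too (same shape, same tangents)
  shs <- gpa_align(landmark_set(arr), slide = TRUE)
  expect_lt(max(apply(shs$shapes, 2, function(v) diff(range(v)))), 1e-9)
  # centroid sizes recorded before scaling
  expect_equal(sh$cs, apply(arr, 1, function(m) centroid_size(m)))
})

test_that("degenerate configurations are reported by sample", {
  arr <- array(0, c(2, 28, 2))
  arr[1, , ] <- mean_shell_shapes()$fabalis
  expect_error(gpa_align(landmark_set(arr, ids = c("ok", "flat"))), "flat")
})

test_that("plain GPA agrees with an independent superimposition oracle", {
  skip_if_not_installed("vegan")
  set.seed(82)
  ms <- mean_shell_shapes()
  arr <- array(NA_real_, c(5, 28, 2))
  for (i in 1:5) {
    w <- runif(1)
    arr[i, , ] <- (w * ms$fabalis + (1 - w) * ms$obtusata +
                     matrix(rnorm(56, 0, 0.01), 28, 2)) * runif(1, 1, 3)
  }
  sh <- gpa_align(landmark_set(arr), slide = FALSE, tol = 1e-12,
                  max_iter = 50)
  # oracle: vegan::procrustes rotation of each raw (centred, unit-size)
  # configuration onto the converged consensus
  for (i in 1:5) {
    x <- arr[i, , ]
    x <- sweep(x, 2, colMeans(x)); x <- x / sqrt(sum(x^2))
    v <- vegan::procrustes(sh$consensus, x, scale = FALSE)
    expect_equal(unname(v$Yrot), unname(sh$aligned[i, , ]), tolerance = 1e-6)
  }
})

test_that("effective shape dimensionality is at most 2p - 4", {
  sim <- simulate_dataset(sim_config(n_per_group = 40, seed = 83))
  sh <- gpa_align(sim$landmarks)
  M <- scale(sh$shapes, scale = FALSE)
  # the four similarity directions at the consensus carry (near-)zero
  # variance: translation and rotation are removed exactly, scale to second
  # order (the unit-size constraint is quadratic)
  p <- 28
  c0 <- as.numeric(sh$consensus)
  rot <- as.numeric(cbind(-sh$consensus[, 2], sh$consensus[, 1]))
  dirs <- cbind(c(rep(1, p), rep(0, p)) / sqrt(p),
                c(rep(0, p), rep(1, p)) / sqrt(p),
                rot / sqrt(sum(rot^2)), c0)
  v <- apply(M %*% dirs, 2, stats::var)
  per_dim <- mean(apply(M, 2, stats::var))
  expect_lt(max(v[1:2]), 1e-20)
  expect_lt(v[3], 1e-3 * per_dim)
  expect_lt(v[4], 0.2 * per_dim)
  # eigenvalues beyond the 52nd carry under 1% of total shape variance
  ev <- eigen(stats::cov(M), only.values = TRUE)$values
  expect_lt(sum(pmax(ev[-(1:52)], 0)), 0.01 * sum(ev))
})

test_that("bending-energy sliding reduces bending energy against the consensus", {
  sim <- simulate_dataset(sim_config(n_per_group = 20, seed = 84))
  plain <- gpa_align(sim$landmarks, slide = FALSE)
  slid <- gpa_align(sim$landmarks, slide = TRUE, criterion = "bending")
  be <- function(sh) {
    Lk <- hybridscan:::bending_energy_matrix(sh$consensus)
    mean(vapply(seq_along(sh$ids), function(i) {
      d <- sh$aligned[i, , ] - sh$consensus
      sum(d[, 1] %*% Lk %*% d[, 1] + d[, 2] %*% Lk %*% d[, 2])
    }, 1.0))
  }
  expect_lt(be(slid), be(plain))
  # procrustes-distance sliding reduces procrustes distance instead
  slp <- gpa_align(sim$landmarks, slide = TRUE, criterion = "procrustes")
  pd <- function(sh) mean(rowSums(sweep(sh$shapes, 2, as.numeric(sh$consensus))^2))
  expect_lt(pd(slp), pd(plain))
})

test_that("shape PCA conserves variance and separates constructed groups", {
  sim <- simulate_dataset(sim_config(n_per_group = 50, seed = 85,
                                     shape_separation = 0.2))
  sh <- gpa_align(sim$landmarks, slide = FALSE)
  pca <- shape_pca(sh)
  expect_equal(sum(pca$sdev^2),
               sum(apply(sh$shapes, 2, stats::var)))
  sp <- sim$truth$true_class
  pure <- sp %in% c("F", "O")
  expect_gt(abs(mean(pca$scores[sp == "F" & pure, 1]) -
                  mean(pca$scores[sp == "O" & pure, 1])),
            2 * mean(tapply(pca$scores[pure, 1], sp[pure], stats::sd)))
})

test_that("isotropic noise yields no dominant principal component", {
  set.seed(86)
  M <- matrix(rnorm(500 * 30), 500, 30)
  pca <- shape_pca(M)
  ev <- pca$sdev^2
  expect_lt(ev[1], 3 * mean(ev))
})

test_that("visual genitalia bands match the published rule", {
  expect_equal(genitalia_visual_classify(2, 10), "obtusata")     # 0.20
  expect_equal(genitalia_visual_classify(4.5, 10), "fabalis")    # 0.45
  expect_equal(genitalia_visual_classify(0.5, 10), "unknown")    # 0.05
  expect_equal(genitalia_visual_classify(2.7, 10), "intermediate")
  expect_equal(genitalia_visual_classify(2.5, 10), "obtusata")   # inclusive
  expect_equal(genitalia_visual_classify(3.0, 10), "fabalis")    # inclusive
  expect_equal(genitalia_visual_classify(7, 10), "unknown")      # 0.70
  expect_error(genitalia_visual_classify(-1, 10), "positive")
  expect_error(genitalia_visual_classify(1, 0), "positive")
})

test_that("genital DFA reproduces training priors and flags uncertain males", {
  set.seed(87)
  sim <- simulate_dataset(sim_config(n_per_group = 120, seed = 87,
                                     hybrid_fractions = c(F1 = 0, F2 = 0,
                                                          BCF = 0, BCO = 0)))
  g <- sim$genitalia
  truth <- sim$truth[match(g$sample_id, sim$truth$sample_id), ]
  # training set sized like the study's reference males (24 + 44)
  fab <- which(truth$true_class == "F")[1:24]
  obt <- which(truth$true_class == "O")[1:44]
  tr <- c(fab, obt)
  fit <- genitalia_dfa(g, tr, ifelse(seq_along(tr) <= 24, "fabalis",
                                     "obtusata"))
  expect_equal(unname(as.numeric(fit$priors)), c(24, 44) / 68)
  lab <- fit$assignments$label
  test_rows <- fit$assignments$set == "test"
  acc <- mean(lab[test_rows] ==
                c(F = "fabalis", O = "obtusata")[truth$true_class[test_rows]],
              na.rm = TRUE)
  expect_gte(acc, 0.95)   # well-separated classes at Pp >= .99

  # a male exactly between the class means is intermediate
  mid <- as.data.frame(t(colMeans(rbind(sim$cfg$genital_means))))
  mid$sample_id <- "mid"
  g2 <- genital_measurements(rbind(as.data.frame(g),
                                   mid[names(as.data.frame(g))]))
  fit2 <- genitalia_dfa(g2, tr, ifelse(seq_along(tr) <= 24, "fabalis",
                                       "obtusata"))
  expect_equal(fit2$assignments$label[nrow(g2)], "intermediate")

  # males with missing features are excluded and logged
  g3 <- as.data.frame(g); g3$penis_width[1] <- NA
  expect_message(fit3 <- genitalia_dfa(genital_measurements(g3),
                                       tr, ifelse(seq_along(tr) <= 24,
                                                  "fabalis", "obtusata")),
                 "excluded")
  expect_true(is.na(fit3$assignments$label[1]))
})

test_that("shell DFA accuracy matches the Gaussian error-rate bound", {
  # two multivariate normal shape groups at Mahalanobis distance D:
  # expected LOOCV error ~ Phi(-D/2)
  make_groups <- function(D, n = 100, d = 10, seed = 88) {
    set.seed(seed)
    mu <- rep(0, d); mu[1] <- D
    X <- rbind(matrix(rnorm(n * d), n, d),
               sweep(matrix(rnorm(n * d), n, d), 2, mu, "+"))
    list(X = X, lab = rep(c("fabalis", "obtusata"), each = n))
  }
  g6 <- make_groups(6)
  fit6 <- train_shape_dfa(g6$X, g6$lab)
  expect_gte(fit6$loocv_accuracy, 0.97)
  expect_equal(rowSums(fit6$loocv_posterior), rep(1, 200),
               ignore_attr = TRUE)
  g0 <- make_groups(0)
  fit0 <- train_shape_dfa(g0$X, g0$lab)
  expect_gt(fit0$loocv_accuracy, 0.35)
  expect_lt(fit0$loocv_accuracy, 0.65)
})

test_that("shell DFA assignment uses the inclusive 0.90 cutoff", {
  set.seed(89)
  sim <- simulate_dataset(sim_config(n_per_group = 60, seed = 89))
  sh <- gpa_align(sim$landmarks, slide = FALSE)
  meta <- sim$genotypes$meta
  ref <- meta$context == "allopatric" & meta$species != "unknown"
  fit <- train_shape_dfa(subset_shapes(sh, ref), meta$species[ref])
  pred <- predict_shape_dfa(fit, subset_shapes(sh, !ref))
  pmax_ <- pmax(pred$fabalis, pred$obtusata)
  expect_true(all(pred$label[pmax_ >= 0.90] != "intermediate"))
  expect_true(all(pred$label[pmax_ < 0.90] == "intermediate"))
  expect_equal(pred$fabalis + pred$obtusata, rep(1, nrow(pred)),
               tolerance = 1e-12)
})

test_that("concordance report cross-tabulates and handles edge cases", {
  gen <- stats::setNames(c("pure_fab", "pure_obt", "pure_fab", "hybrid"),
                         paste0("s", 1:4))
  same <- stats::setNames(c("fabalis", "obtusata", "fabalis", "fabalis"),
                          paste0("s", 1:4))
  md <- data.frame(sample_id = paste0("s", 1:4), location = "L1")
  rep1 <- concordance_report(gen, same, metadata = md)
  expect_equal(rep1$overall$pct_concordant, 100)
  expect_equal(rep1$overall$hybrids_assigned, 1)

  mixed <- stats::setNames(c("obtusata", "obtusata", "intermediate", "fabalis"),
                           paste0("s", 1:4))
  rep2 <- concordance_report(gen, mixed, metadata = md)
  expect_equal(rep2$overall$mismatch, 1)
  expect_equal(rep2$overall$intermediate, 1)

  disjoint <- stats::setNames("fabalis", "zz")
  expect_warning(rep3 <- concordance_report(gen, disjoint, metadata = md),
                 "no overlapping")
  expect_equal(rep3$n, 0)

  # synthetic truth-table concordance equals the generator's own value
  sim <- simulate_dataset(sim_config(n_per_group = 30, seed = 90))
  genT <- truth_genetic(sim$truth)
  shapeT <- stats::setNames(
    ifelse(sim$truth$true_class == "F", "fabalis",
           ifelse(sim$truth$true_class == "O", "obtusata", "intermediate")),
    sim$truth$sample_id)
  rep4 <- concordance_report(genT, shapeT, metadata = sim$genotypes$meta)
  expect_equal(rep4$overall$pct_concordant, 100)
})
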