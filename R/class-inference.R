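#' Six-class genotype-frequency inference
#'
#' MCMC over the six genotype classes (F, O, F1, F2, BCF, BCO): mixing
#' proportions with a flat Dirichlet prior, per-pool allele frequencies with
#' the "Jeffreys-like" Dirichlet(1/A_l) prior (accommodating rare or absent
#' alleles), and per-locus latent ancestry states weighted by each class's
#' expected ancestry proportions (see [class_proportion_table()]). No prior
#' population information is used; cluster identity is anchored afterwards
#' using the putative species of the samples (label-permutation alignment
#' across replicates swaps F with O and BCF with BCO where needed).
#'
#' @param dataset a [microsat_dataset()].
#' @param settings an [mcmc_settings()] object (lambda/alpha fields unused).
#' @param agreement_tol warn if the maximum row-wise total-variation distance
#'   between replicate posteriors exceeds this (default 0.1).
#' @return an object of class `class_posterior`: `$Pp` is a data frame with
#'   `sample_id`, one column per class, `assigned_class` and `assigned_pp`
#'   (arg-max summaries; thresholding is done by [classify_with_TPp()]);
#'   `$replicates` holds aligned per-replicate posterior matrices;
#'   `$agreement` the replicate total-variation statistic.
#' @export
run_class_inference <- function(dataset, settings = mcmc_settings(),
                                agreement_tol = 0.1) {
  if (length(dataset$loci) < 1) stop("need at least 1 locus")
  enc <- encode_alleles(dataset)
  all_missing <- rowSums(enc$A1 >= 0) + rowSums(enc$A2 >= 0) == 0
  G <- as.matrix(class_proportion_table()[, c("p_FF", "p_FO", "p_OO")])
  init <- match(dataset$meta$species, c("fabalis", "obtusata")) - 1L
  init[is.na(init)] <- -1L
  reps <- vector("list", settings$replicates)
  for (r in seq_len(settings$replicates)) {
    set.seed(settings$seed + r - 1L)
    fit <- newhybrids_gibbs_cpp(enc$A1, enc$A2, enc$nAlleles, G,
                                settings$burnin, settings$sweeps,
                                settings$thin, init)
    P <- fit$probs
    colnames(P) <- GENOTYPE_CLASSES
    reps[[r]] <- P
  }
  al <- align_class_replicates(reps, dataset$meta$species)
  P <- al$mean
  amax <- apply(P, 1, which.max)
  Pp <- data.frame(sample_id = dataset$meta$sample_id, P,
                   assigned_class = GENOTYPE_CLASSES[amax],
                   assigned_pp = P[cbind(seq_len(nrow(P)), amax)],
                   flag = ifelse(all_missing, "all_missing", ""),
                   stringsAsFactors = FALSE)
  if (al$agreement > agreement_tol)
    warning(sprintf("replicate posteriors disagree (max TV distance %.3f)",
                    al$agreement))
  structure(list(Pp = Pp, replicates = al$aligned, agreement = al$agreement,
                 pi = NULL, settings = settings),
            class = "class_posterior")
}

# the pool-swap permutation of the class labels
swap_classes <- function(P) P[, c("O", "F", "F1", "F2", "BCO", "BCF"),
                              drop = FALSE]

align_class_replicates <- function(reps, species) {
  ref <- reps[[1]]
  aligned <- lapply(reps, function(P) {
    colnames(P) <- GENOTYPE_CLASSES
    sw <- swap_classes(P); colnames(sw) <- GENOTYPE_CLASSES
    if (sum(abs(sw - ref)) < sum(abs(P - ref))) sw else P
  })
  # anchor F to the putative fabalis samples
  fab <- species == "fabalis"; obt <- species == "obtusata"
  if (any(fab) || any(obt)) {
    s <- mean(c(if (any(fab)) mean(ref[fab, "F"] - ref[fab, "O"]),
                if (any(obt)) mean(ref[obt, "O"] - ref[obt, "F"])))
    if (s < 0) aligned <- lapply(aligned, function(P) {
      sw <- swap_classes(P); colnames(sw) <- GENOTYPE_CLASSES; sw
    })
  }
  mean_P <- Reduce(`+`, aligned) / length(aligned)
  agree <- 0
  if (length(aligned) > 1)
    for (i in seq_along(aligned))
      for (j in seq_len(i - 1))
        agree <- max(agree,
                     max(rowSums(abs(aligned[[i]] - aligned[[j]])) / 2))
  list(mean = mean_P, aligned = aligned, agreement = agree)
}

#' @export
print.class_posterior <- function(x, ...) {
  cat(sprintf("class_posterior: %d samples over %d classes (preset %s)\n",
              nrow(x$Pp), length(GENOTYPE_CLASSES), x$settings$preset))
  cat(sprintf("replicate agreement: max TV distance %.4f\n", x$agreement))
  print(table(argmax = x$Pp$assigned_class))
  invisible(x)
}

#' Per-locus genotype-class likelihoods
#'
#' The per-locus genotype likelihood under each ancestry state, and the
#' resulting class likelihoods, for fixed pool allele frequencies. This is the
#' deterministic core of the class model, exposed for verification against
#' exact enumeration.
#'
#' @param a1,a2 allele labels of one genotype at one locus.
#' @param fF,fO named allele-frequency vectors of the two pools.
#' @return list with `state` (likelihood under FF/FO/OO ancestry) and `class`
#'   (likelihood under each of the six classes).
#' @export
genotype_class_likelihood <- function(a1, a2, fF, fO) {
  pf <- function(f, a) if (a %in% names(f)) unname(f[a]) else 0
  l <- if (a1 == a2) c(FF = pf(fF, a1)^2, FO = pf(fF, a1) * pf(fO, a1),
                       OO = pf(fO, a1)^2)
  else c(FF = 2 * pf(fF, a1) * pf(fF, a2),
         FO = pf(fF, a1) * pf(fO, a2) + pf(fF, a2) * pf(fO, a1),
         OO = 2 * pf(fO, a1) * pf(fO, a2))
  G <- class_proportion_table()
  cl <- stats::setNames(as.numeric(as.matrix(G[, -1]) %*% l), G$class)
  list(state = l, class = cl)
}
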