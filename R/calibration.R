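#' Simulation-based calibration of the admixture threshold TQ
#'
#' Hasselman-style procedure: simulate genotypes of all six classes from the
#' parental reference pools, run the admixture model on the simulated
#' individuals together with the references, and sweep a grid of thresholds
#' `t`, calling an individual pure when `max(Q) >= t`. The returned threshold
#' minimises the total misclassification (pure simulated called hybrid plus
#' hybrid simulated called pure, all classes weighted equally); ties are
#' broken by the plateau midpoint.
#'
#' @param parental_refs a [microsat_dataset()] whose `meta$species` identifies
#'   the two reference pools (typically allopatric reference sites).
#' @param n_sim simulated genotypes per class (default 200).
#' @param settings an [mcmc_settings()].
#' @param grid thresholds to sweep (default 0.50-0.99 by 0.01).
#' @param scale,locality bookkeeping labels stored in the result.
#' @return an object of class `threshold_result` with fields `threshold`,
#'   `curve` (threshold, pure_to_hybrid, hybrid_to_pure, total),
#'   `pct_correct`, `scale`, `locality`, `n_sim_per_class`, `warnings`.
#' @export
calibrate_TQ <- function(parental_refs, n_sim = 200,
                         settings = mcmc_settings(),
                         grid = seq(0.50, 0.99, by = 0.01),
                         scale = "global", locality = "all") {
  chk <- check_pools(parental_refs)
  freqs <- estimate_allele_frequencies(parental_refs, parental_refs$meta$species)
  set.seed(settings$seed)
  sim <- simulate_all_classes(n_sim, freqs)
  joint <- rbind(sim$dataset, parental_refs)
  q <- run_admixture(joint, settings)
  qsim <- q$Q[seq_len(n_samples(sim$dataset)), ]
  qmax <- pmax(qsim$q_fab, qsim$q_obt)
  is_pure <- sim$truth %in% c("F", "O")
  curve <- threshold_curve(grid, called_pure = function(t) qmax >= t,
                           is_pure = is_pure)
  make_threshold_result(curve, grid, scale, locality, n_sim, chk,
                        method = "TQ")
}

#' Simulation-based calibration of the class-posterior threshold TPp
#'
#' As [calibrate_TQ()] but the classifier is the six-class model: a simulated
#' individual is \emph{assigned} when its maximum class posterior reaches the
#' threshold, and pure/hybrid status follows the arg-max class. The objective
#' maximises correct classification: unassigned individuals count against a
#' threshold alongside pure/hybrid errors (the pure/hybrid error curve alone
#' is non-increasing in the threshold, so minimising it degenerates to the
#' top of the grid and discards nearly all individuals). The pure/hybrid
#' error rate, per-class correct-assignment rates and the unassigned
#' fraction are all reported.
#'
#' @inheritParams calibrate_TQ
#' @return a `threshold_result`; additionally carries `per_class` (correct
#'   assignment rate per class at the optimum) and `unassigned` (fraction).
#' @export
calibrate_TPp <- function(parental_refs, n_sim = 200,
                          settings = mcmc_settings(),
                          grid = seq(0.50, 0.99, by = 0.01),
                          scale = "global", locality = "all") {
  chk <- check_pools(parental_refs)
  freqs <- estimate_allele_frequencies(parental_refs, parental_refs$meta$species)
  set.seed(settings$seed)
  sim <- simulate_all_classes(n_sim, freqs)
  joint <- rbind(sim$dataset, parental_refs)
  pp <- run_class_inference(joint, settings)
  psim <- pp$Pp[seq_len(n_samples(sim$dataset)), ]
  is_pure <- sim$truth %in% c("F", "O")
  hyb_classes <- c("F1", "F2", "BCF", "BCO")
  curve <- data.frame(threshold = grid, pure_to_hybrid = NA_real_,
                      hybrid_to_pure = NA_real_, unassigned = NA_real_,
                      total = NA_real_)
  N <- nrow(psim)
  for (i in seq_along(grid)) {
    lab <- tpp_labels(psim, grid[i])
    assigned <- lab != "unassigned"
    called_pure <- assigned & lab %in% c("F", "O")
    called_hyb <- assigned & lab %in% hyb_classes
    p2h <- sum(is_pure & called_hyb)
    h2p <- sum(!is_pure & called_pure)
    curve$pure_to_hybrid[i] <- p2h / N
    curve$hybrid_to_pure[i] <- h2p / N
    curve$unassigned[i] <- mean(!assigned)
    # maximise correct classification: unassigned individuals count against
    # a threshold alongside pure<->hybrid errors, otherwise the errors-only
    # curve is non-increasing and the argmin degenerates to the grid top
    curve$total[i] <- (p2h + h2p + sum(!assigned)) / N
  }
  res <- make_threshold_result(curve, grid, scale, locality, n_sim, chk,
                               method = "TPp")
  lab <- tpp_labels(psim, res$threshold)
  res$per_class <- vapply(GENOTYPE_CLASSES, function(cl)
    mean(lab[sim$truth == cl] == cl), 1.0)
  res$unassigned <- mean(lab == "unassigned")
  res$error_rate <- curve$pure_to_hybrid[grid == res$threshold] +
    curve$hybrid_to_pure[grid == res$threshold]
  res$pct_correct <- 100 * mean(ifelse(is_pure, lab %in% c("F", "O"),
                                       lab %in% hyb_classes))
  res
}

check_pools <- function(refs) {
  w <- character(0)
  for (sp in c("fabalis", "obtusata")) {
    n <- sum(refs$meta$species == sp)
    if (n < 2) stop("parental pool '", sp, "' has fewer than 2 individuals")
    if (n < 10)
      w <- c(w, sprintf("parental pool '%s' has only %d individuals", sp, n))
  }
  if (length(w)) warning(paste(w, collapse = "; "))
  w
}

threshold_curve <- function(grid, called_pure, is_pure) {
  out <- data.frame(threshold = grid, pure_to_hybrid = NA_real_,
                    hybrid_to_pure = NA_real_, total = NA_real_)
  N <- length(is_pure)
  for (i in seq_along(grid)) {
    cp <- called_pure(grid[i])
    p2h <- sum(is_pure & !cp)
    h2p <- sum(!is_pure & cp)
    out$pure_to_hybrid[i] <- p2h / N
    out$hybrid_to_pure[i] <- h2p / N
    out$total[i] <- (p2h + h2p) / N
  }
  out
}

make_threshold_result <- function(curve, grid, scale, locality, n_sim,
                                  warnings, method) {
  best <- which(curve$total == min(curve$total))
  # plateau midpoint tie-break
  opt <- best[ceiling(length(best) / 2)]
  structure(list(threshold = grid[opt], curve = curve,
                 pct_correct = 100 * (1 - curve$total[opt]),
                 scale = scale, locality = locality,
                 n_sim_per_class = n_sim, warnings = warnings,
                 method = method),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("%s calibration (%s scale, %s): threshold = %.2f\n",
              x$method, x$scale, paste(x$locality, collapse = "+"),
              x$threshold))
  cat(sprintf("correct classification at optimum: %.2f%% (n = %d per class)\n",
              x$pct_correct, x$n_sim_per_class))
  if (!is.null(x$per_class)) {
    cat("per-class correct assignment:\n")
    print(round(x$per_class, 3))
    cat(sprintf("unassigned fraction: %.3f\n", x$unassigned))
  }
  invisible(x)
}

#' @export
plot.threshold_result <- function(x, ...) {
  plot(x$curve$threshold, x$curve$total, type = "l",
       xlab = "threshold", ylab = "misclassification rate", ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' Classify individuals as pure or hybrid from Q
#'
#' `pure_fab` when `q_fab >= TQ`, `pure_obt` when `q_obt >= TQ` (inclusive
#' boundaries), otherwise `hybrid`.
#'
#' @param q a [run_admixture()] result or a data frame with `q_fab`, `q_obt`.
#' @param TQ threshold in (0.5, 1).
#' @return character vector of labels.
#' @export
classify_with_TQ <- function(q, TQ) {
  if (TQ <= 0.5 || TQ >= 1) stop("TQ must be in (0.5, 1)")
  tq_labels(q, TQ)
}

tq_labels <- function(q, TQ) {
  if (inherits(q, "qmatrix")) q <- q$Q
  ifelse(q$q_fab >= TQ, "pure_fab",
         ifelse(q$q_obt >= TQ, "pure_obt", "hybrid"))
}

#' Classify individuals into genotype classes from class posteriors
#'
#' The arg-max class when its posterior reaches `TPp` (inclusive), otherwise
#' `"unassigned"`.
#'
#' @param pp a [run_class_inference()] result or a data frame with the six
#'   class columns.
#' @param TPp threshold in (0.5, 1).
#' @return character vector over F, O, F1, F2, BCF, BCO, unassigned.
#' @export
classify_with_TPp <- function(pp, TPp) {
  if (TPp <= 0.5 || TPp >= 1) stop("TPp must be in (0.5, 1)")
  tpp_labels(pp, TPp)
}

# grid sweeps may also probe the 0.5 boundary itself
tpp_labels <- function(pp, TPp) {
  if (inherits(pp, "class_posterior")) pp <- pp$Pp
  P <- as.matrix(pp[, GENOTYPE_CLASSES])
  amax <- max.col(P, ties.method = "first")
  pmax_ <- P[cbind(seq_len(nrow(P)), amax)]
  ifelse(pmax_ >= TPp, GENOTYPE_CLASSES[amax], "unassigned")
}

#' Local-scale calibration plan
#'
#' Groups sampling sites for local threshold calibration: each sympatric site
#' forms its own grouping (both parental pools are locally available); each
#' allopatric site is paired with the nearest site, by great-circle distance,
#' where the missing species occurs. Ties are broken toward the
#' lexicographically smaller site code, with a warning.
#'
#' @param sites data frame with columns `code`, `context`, `fabalis`,
#'   `obtusata` (logicals: species present), `lat`, `lon` (decimal degrees).
#'   See [littorina_sites()] for the study layout.
#' @return list of character vectors of site codes (one per grouping), with
#'   attribute `"log"` describing the pairing decisions.
#' @export
local_scale_plan <- function(sites) {
  sites <- as.data.frame(sites)
  need <- c("code", "context", "fabalis", "obtusata", "lat", "lon")
  if (!all(need %in% names(sites)))
    stop("sites must have columns ", paste(need, collapse = ", "))
  if (!any(sites$fabalis) || !any(sites$obtusata))
    stop("a species is missing from every site; local calibration impossible")
  log <- character(0)
  plan <- list()
  for (i in seq_len(nrow(sites))) {
    if (sites$context[i] == "sympatric") {
      plan[[length(plan) + 1]] <- sites$code[i]
      next
    }
    if (sites$context[i] != "allopatric") next
    missing_sp <- if (sites$fabalis[i]) "obtusata" else "fabalis"
    cand <- which(sites[[missing_sp]] & seq_len(nrow(sites)) != i)
    d <- geosphere::distHaversine(c(sites$lon[i], sites$lat[i]),
                                  cbind(sites$lon[cand], sites$lat[cand]))
    best <- cand[d == min(d)]
    if (length(best) > 1) {
      best <- best[order(sites$code[best])]
      warning("equidistant candidates for ", sites$code[i], ": picking ",
              sites$code[best[1]])
      log <- c(log, sprintf("%s: tie broken toward %s", sites$code[i],
                            sites$code[best[1]]))
    }
    plan[[length(plan) + 1]] <- sort(c(sites$code[i], sites$code[best[1]]))
    log <- c(log, sprintf("%s (allopatric, missing %s) paired with %s",
                          sites$code[i], missing_sp, sites$code[best[1]]))
  }
  attr(plan, "log") <- log
  plan
}
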