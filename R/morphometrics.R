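#' Generalized Procrustes analysis with sliding semilandmarks
#'
#' Iteratively centres each configuration, scales it to unit centroid size,
#' rotates it onto the current consensus, optionally slides the semilandmarks
#' along the local curve tangent, and recomputes the consensus, until the
#' consensus changes by less than `tol` or `max_iter` iterations. Centroid
#' sizes are recorded before scaling. Semilandmark sliding minimises thin
#' plate spline bending energy with respect to the consensus by default (the
#' operative criterion of the superimposition used here); Procrustes-distance
#' sliding (projection of the residual onto the tangent) is available via
#' `criterion = "procrustes"`.
#'
#' @param lms a [landmark_set()].
#' @param slide slide semilandmarks (default TRUE); `FALSE` gives plain GPA.
#' @param criterion `"bending"` or `"procrustes"`.
#' @param tol,max_iter convergence controls.
#' @return an object of class `aligned_shapes`: `aligned` (n x p x 2 array of
#'   unit-size aligned configurations), `cs` and `logcs`, `consensus`,
#'   `shapes` (n x 2p matrix of flattened aligned coordinates — the shape
#'   variables; their effective dimensionality is at most 2p - 4), `ids`.
#' @export
gpa_align <- function(lms, slide = TRUE, criterion = c("bending", "procrustes"),
                      tol = 1e-8, max_iter = 10) {
  criterion <- match.arg(criterion)
  arr <- lms$coords
  n <- dim(arr)[1]; p <- dim(arr)[2]
  cs <- numeric(n)
  X <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- arr[i, , ]
    xi <- sweep(xi, 2, colMeans(xi))
    cs[i] <- sqrt(sum(xi^2))
    if (cs[i] < 1e-12)
      stop("degenerate configuration (zero centroid size): ", lms$ids[i])
    X[[i]] <- xi / cs[i]
  }
  cons <- X[[1]]
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) X[[i]] <- opa_rotate(X[[i]], cons)
    if (slide && nrow(lms$sliders) > 0) {
      for (i in seq_len(n))
        X[[i]] <- slide_semilandmarks(X[[i]], cons, lms$sliders, criterion)
      # re-superimpose after sliding
      for (i in seq_len(n)) {
        xi <- sweep(X[[i]], 2, colMeans(X[[i]]))
        X[[i]] <- opa_rotate(xi / sqrt(sum(xi^2)), cons)
      }
    }
    new_cons <- Reduce(`+`, X) / n
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) break
  }
  shapes <- t(vapply(X, as.numeric, numeric(2 * p)))
  rownames(shapes) <- lms$ids
  aligned <- array(NA_real_, c(n, p, 2))
  for (i in seq_len(n)) aligned[i, , ] <- X[[i]]
  structure(list(aligned = aligned, cs = cs, logcs = log(cs),
                 consensus = cons, shapes = shapes, ids = lms$ids,
                 fixed = lms$fixed, sliders = lms$sliders,
                 slid = slide, criterion = if (slide) criterion else "none"),
            class = "aligned_shapes")
}

# optimal rotation (no reflection) of unit-size centred X onto consensus C
opa_rotate <- function(X, C) {
  s <- svd(crossprod(X, C))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 2] <- -u[, 2]
    R <- u %*% t(s$v)
  }
  X %*% R
}

# thin-plate-spline bending energy matrix of a p x 2 reference
bending_energy_matrix <- function(C) {
  p <- nrow(C)
  r2 <- as.matrix(stats::dist(C))^2
  K <- ifelse(r2 == 0, 0, r2 * log(r2))
  P <- cbind(1, C)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Linv <- tryCatch(solve(L), error = function(e) MASS::ginv(L))
  Linv[seq_len(p), seq_len(p)]
}

slide_semilandmarks <- function(X, cons, sliders, criterion) {
  p <- nrow(X)
  m <- nrow(sliders)
  # unit tangents along the chord between the neighbours of each slider
  tg <- X[sliders[, 3], , drop = FALSE] - X[sliders[, 1], , drop = FALSE]
  len <- sqrt(rowSums(tg^2))
  len[len < 1e-12] <- 1
  tg <- tg / len
  if (criterion == "procrustes") {
    d <- cons[sliders[, 2], , drop = FALSE] - X[sliders[, 2], , drop = FALSE]
    t_amt <- rowSums(d * tg)
    X[sliders[, 2], ] <- X[sliders[, 2], ] + tg * t_amt
    return(X)
  }
  # bending energy: minimise (x + U t - c)' B2 (x + U t - c) over slide
  # amounts t, with B2 the consensus bending energy applied to x and y
  Lk <- bending_energy_matrix(cons)
  U <- matrix(0, 2 * p, m)
  for (k in seq_len(m)) {
    pt <- sliders[k, 2]
    U[pt, k] <- tg[k, 1]
    U[p + pt, k] <- tg[k, 2]
  }
  x <- as.numeric(X); cvec <- as.numeric(cons)
  BU <- rbind(Lk %*% U[seq_len(p), , drop = FALSE],
              Lk %*% U[p + seq_len(p), , drop = FALSE])
  A <- crossprod(U, BU)
  Bres <- c(Lk %*% (x[seq_len(p)] - cvec[seq_len(p)]),
            Lk %*% (x[p + seq_len(p)] - cvec[p + seq_len(p)]))
  rhs <- -crossprod(U, Bres)
  t_amt <- tryCatch(solve(A + 1e-10 * diag(m), rhs),
                    error = function(e) MASS::ginv(A) %*% rhs)
  X + matrix(U %*% t_amt, p, 2)
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("aligned_shapes: %d configurations, %d landmarks (sliding: %s)\n",
              dim(x$aligned)[1], dim(x$aligned)[2], x$criterion))
  cat(sprintf("centroid size %.3g-%.3g\n", min(x$cs), max(x$cs)))
  invisible(x)
}

#' Centroid size of a single configuration
#' @param X p x 2 coordinate matrix.
#' @export
centroid_size <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  sqrt(sum(X^2))
}

#' Principal component analysis of shape variables
#'
#' @param shapes an [gpa_align()] result (or an n x d shape-variable matrix).
#' @return object of class `shape_pca`: `scores`, `sdev`, `var_explained`,
#'   `rotation`, `center`.
#' @export
shape_pca <- function(shapes) {
  M <- if (inherits(shapes, "aligned_shapes")) shapes$shapes else as.matrix(shapes)
  if (nrow(M) < 3) stop("need at least 3 configurations")
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  structure(list(scores = pc$x, sdev = pc$sdev,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 rotation = pc$rotation, center = pc$center),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf("shape_pca: %d components; PC1 %.1f%%, PC1-2 %.1f%% of variance\n",
              length(ve), 100 * ve[1], 100 * sum(ve[1:min(2, length(ve))])))
  invisible(x)
}

#' Visual classification of male genitalia
#'
#' Ratio of filament length to total penis length: 10--25% is typical of
#' \emph{L. obtusata}, 30--60% of \emph{L. fabalis}, 25--30% (exclusive) is
#' intermediate, and anything outside those bands is unknown.
#'
#' @param filament_length,total_length numeric vectors (mm).
#' @return character vector over obtusata/intermediate/fabalis/unknown.
#' @export
genitalia_visual_classify <- function(filament_length, total_length) {
  if (any(filament_length < 0) || any(total_length <= 0))
    stop("lengths must be positive")
  r <- filament_length / total_length
  ifelse(r >= 0.10 & r <= 0.25, "obtusata",
         ifelse(r > 0.25 & r < 0.30, "intermediate",
                ifelse(r >= 0.30 & r <= 0.60, "fabalis", "unknown")))
}

#' Linear discriminant analysis of the seven genital features
#'
#' Trains a linear discriminant on the training rows (priors equal to the
#' species frequencies in the training set), reports leave-one-out posteriors
#' for the training individuals, and classifies all complete-case individuals
#' with the posterior-probability cutoff (default 0.99, inclusive); samples
#' below the cutoff are `"intermediate"`. Samples with missing features are
#' excluded and listed in `$excluded`.
#'
#' @param measurements a [genital_measurements()] data frame.
#' @param training logical or index vector selecting the training rows.
#' @param labels species labels for the training rows.
#' @param cutoff posterior-probability cutoff (default 0.99).
#' @return an object of class `genital_dfa` with `$assignments` (sample_id,
#'   Pp per species, label, set), `$priors`, `$loocv_accuracy`, `$excluded`.
#' @export
genitalia_dfa <- function(measurements, training, labels, cutoff = 0.99) {
  X <- as.matrix(measurements[GENITAL_FEATURES])
  ok <- stats::complete.cases(X)
  excluded <- measurements$sample_id[!ok]
  if (length(excluded))
    message("excluded (missing features): ", paste(excluded, collapse = ", "))
  tr <- rep(FALSE, nrow(X)); tr[training] <- TRUE
  labels <- as.character(labels)
  if (sum(tr) != length(labels))
    stop("labels must match the training rows")
  use_tr <- tr & ok
  lab_tr <- labels[match(which(use_tr), which(tr))]
  prior <- table(lab_tr) / sum(table(lab_tr))
  fit <- MASS::lda(X[use_tr, , drop = FALSE], grouping = factor(lab_tr),
                   prior = as.numeric(prior))
  cv <- MASS::lda(X[use_tr, , drop = FALSE], grouping = factor(lab_tr),
                  prior = as.numeric(prior), CV = TRUE)
  post <- matrix(NA_real_, nrow(X), ncol(cv$posterior),
                 dimnames = list(NULL, colnames(cv$posterior)))
  post[use_tr, ] <- cv$posterior
  pred_idx <- ok & !tr
  if (any(pred_idx))
    post[pred_idx, ] <- stats::predict(fit, X[pred_idx, , drop = FALSE])$posterior
  lab_out <- rep(NA_character_, nrow(X))
  for (i in which(ok)) {
    k <- which.max(post[i, ])
    lab_out[i] <- if (post[i, k] >= cutoff) colnames(post)[k] else "intermediate"
  }
  structure(list(assignments = data.frame(sample_id = measurements$sample_id,
                                          post, label = lab_out,
                                          set = ifelse(tr, "training", "test"),
                                          stringsAsFactors = FALSE),
                 priors = prior,
                 loocv_accuracy = mean(cv$class == factor(lab_tr)),
                 excluded = excluded, cutoff = cutoff, fit = fit),
            class = "genital_dfa")
}

#' @export
print.genital_dfa <- function(x, ...) {
  cat(sprintf("genital_dfa: priors %s; LOOCV accuracy %.1f%%; cutoff Pp >= %.2f\n",
              paste(sprintf("%s=%.3f", names(x$priors), x$priors),
                    collapse = " "), 100 * x$loocv_accuracy, x$cutoff))
  print(table(x$assignments$label, x$assignments$set))
  invisible(x)
}

#' Train a shell-shape discriminant function
#'
#' Two-class linear discriminant built from the aligned shapes of allopatric
#' reference individuals. The shape variables are first reduced to principal
#' components retaining `var_cutoff` of the variance (the raw 2p coordinates
#' are rank-deficient); priors equal the training frequencies; leave-one-out
#' posteriors are reported for the training set.
#'
#' @param shapes an [gpa_align()] result for the training individuals (or a
#'   shape-variable matrix).
#' @param labels species labels, length = number of training shapes.
#' @param var_cutoff variance retained by the reduction (default 0.99).
#' @param cutoff assignment cutoff on the posterior (default 0.90).
#' @return an object of class `shape_dfa` with the reduction (center,
#'   rotation), the `MASS::lda` fit, LOOCV posteriors and accuracy, and the
#'   training consensus used to project new shapes.
#' @export
train_shape_dfa <- function(shapes, labels, var_cutoff = 0.99, cutoff = 0.90) {
  M <- if (inherits(shapes, "aligned_shapes")) shapes$shapes else as.matrix(shapes)
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2) stop("need exactly two species in the training set")
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  d <- which(ve >= var_cutoff)[1]
  nmin <- min(table(labels))
  if (d >= nmin) {
    warning("reducing to ", nmin - 1, " components (class sizes)")
    d <- nmin - 1
  }
  S <- pc$x[, seq_len(d), drop = FALSE]
  prior <- as.numeric(table(labels) / length(labels))
  fit <- MASS::lda(S, grouping = labels, prior = prior)
  cv <- MASS::lda(S, grouping = labels, prior = prior, CV = TRUE)
  structure(list(fit = fit, center = pc$center,
                 rotation = pc$rotation[, seq_len(d), drop = FALSE],
                 ndim = d, priors = prior, levels = levels(labels),
                 loocv_posterior = cv$posterior,
                 loocv_accuracy = mean(cv$class == labels),
                 consensus = if (inherits(shapes, "aligned_shapes"))
                   shapes$consensus else NULL,
                 cutoff = cutoff),
            class = "shape_dfa")
}

#' @export
print.shape_dfa <- function(x, ...) {
  cat(sprintf("shape_dfa: %d shape components, priors %s\n", x$ndim,
              paste(sprintf("%s=%.3f", x$levels, x$priors), collapse = " ")))
  cat(sprintf("LOOCV accuracy: %.2f%%; assignment cutoff Pp >= %.2f\n",
              100 * x$loocv_accuracy, x$cutoff))
  invisible(x)
}

#' Classify shells with a trained shape discriminant
#'
#' New configurations are projected into the model's frame: each is centred,
#' scaled to unit centroid size and rotated onto the training consensus, then
#' mapped through the stored principal-component reduction. Individuals are
#' assigned to the species whose posterior reaches the cutoff (inclusive),
#' otherwise labelled `"intermediate"`.
#'
#' @param model a [train_shape_dfa()] result.
#' @param shapes an `aligned_shapes`, `landmark_set`, or shape matrix.
#' @return data frame with `sample_id`, posterior per species, `label`.
#' @export
predict_shape_dfa <- function(model, shapes) {
  if (inherits(shapes, "landmark_set"))
    shapes <- gpa_align(shapes, slide = FALSE)
  if (inherits(shapes, "aligned_shapes")) {
    M <- shapes$shapes
    ids <- shapes$ids
    if (!is.null(model$consensus)) {
      p <- nrow(model$consensus)
      M <- t(vapply(seq_len(nrow(M)), function(i)
        as.numeric(opa_rotate(matrix(M[i, ], p, 2), model$consensus)),
        numeric(2 * p)))
    }
  } else {
    M <- as.matrix(shapes)
    ids <- rownames(M) %||% paste0("s", seq_len(nrow(M)))
  }
  S <- sweep(M, 2, model$center) %*% model$rotation
  post <- stats::predict(model$fit, S)$posterior
  k <- max.col(post, ties.method = "first")
  lab <- ifelse(post[cbind(seq_len(nrow(post)), k)] >= model$cutoff,
                colnames(post)[k], "intermediate")
  data.frame(sample_id = ids, post, label = lab, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Concordance between genetic, shell-shape and genital classifications
#'
#' Cross-tabulates, per location and overall, the agreement between label
#' sets (named vectors sample id -> label). Pure-species labels are compared
#' directly; `intermediate`/`hybrid`/`unassigned` labels are tallied
#' separately, mirroring the layout of concordance tables in hybridization
#' surveys (concordant, mismatch, intermediate, hybrid-by-other-method).
#'
#' @param genetic named vector of genetic labels (`pure_fab`/`pure_obt`/
#'   `hybrid`; synonyms accepted).
#' @param shape named vector of shell labels (`fabalis`/`obtusata`/
#'   `intermediate`).
#' @param genital optional named vector of genital labels.
#' @param metadata data frame with `sample_id` and `location`.
#' @return an object of class `concordance_report`.
#' @export
concordance_report <- function(genetic, shape, genital = NULL, metadata) {
  genetic <- normalize_genetic_labels(genetic)
  ids <- intersect(names(genetic), names(shape))
  if (length(ids) == 0) {
    warning("no overlapping samples between label sets")
    return(structure(list(by_location = NULL, overall = NULL, n = 0),
                     class = "concordance_report"))
  }
  g <- genetic[ids]
  s <- shape[ids]
  sp_of <- c(pure_fab = "fabalis", pure_obt = "obtusata", hybrid = "hybrid")
  g2 <- sp_of[g]
  loc <- metadata$location[match(ids, metadata$sample_id)]
  tab_one <- function(sel, label) {
    gi <- g2[sel]; si <- s[sel]
    pure <- gi %in% c("fabalis", "obtusata")
    data.frame(location = label, n = sum(sel),
               concordant_fab = sum(gi == "fabalis" & si == "fabalis"),
               concordant_obt = sum(gi == "obtusata" & si == "obtusata"),
               intermediate = sum(pure & si == "intermediate"),
               mismatch = sum(pure & si %in% c("fabalis", "obtusata") & si != gi),
               hybrids_assigned = sum(gi == "hybrid" &
                                        si %in% c("fabalis", "obtusata")),
               stringsAsFactors = FALSE)
  }
  by_loc <- do.call(rbind, lapply(unique(loc), function(l)
    tab_one(loc == l, l)))
  overall <- tab_one(rep(TRUE, length(ids)), "Total")
  overall$pct_concordant <- 100 *
    (overall$concordant_fab + overall$concordant_obt) /
    max(1, sum(g2 %in% c("fabalis", "obtusata")))
  gen_tab <- NULL
  if (!is.null(genital)) {
    ids2 <- intersect(names(genetic), names(genital))
    if (length(ids2)) {
      gg <- sp_of[genetic[ids2]]; pn <- genital[ids2]
      gen_tab <- table(genetic = gg, genital = pn)
    }
  }
  structure(list(by_location = by_loc, overall = overall,
                 genital_crosstab = gen_tab, n = length(ids)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  if (is.null(x$overall)) { cat("empty concordance report\n"); return(invisible(x)) }
  cat(sprintf("concordance over %d samples: %.1f%% of genetically pure individuals\n",
              x$n, x$overall$pct_concordant))
  print(x$overall)
  invisible(x)
}
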