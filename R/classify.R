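#' Train the pixel classifier for cell/background segmentation
#'
#' Fits a ridge-regularised logistic model on the handcrafted per-pixel
#' feature stack of [extract_features()], using labelled pixels sampled
#' (deterministically, given `seed`) from one or more ground-truth masks.
#' Features are standardised with parameters recorded in the model; a
#' held-out pixel split reports generalisation accuracy.
#'
#' @param images Intensity matrix or list of matrices.
#' @param masks Matching 0/1 ground-truth mask(s) (1 = cell).
#' @param seed Integer seed for pixel sampling and the train/holdout split.
#' @param n_per_class Maximum labelled pixels sampled per class.
#' @param holdout_frac Fraction of sampled pixels held out for accuracy.
#' @param lambda Ridge penalty of the logistic fit.
#' @param scales,log_sigma Feature parameters, stored with the model.
#' @return A `pixel_classifier`: feature names, standardisation parameters,
#'   weights (with intercept), `holdout_accuracy`, training metadata.
#' @export
train_pixel_classifier <- function(images, masks, seed = 1L,
                                   n_per_class = 4000, holdout_frac = 0.2,
                                   lambda = 1e-3,
                                   scales = c(2, 5), log_sigma = 2) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  stopifnot(length(images) == length(masks))
  X <- NULL; y <- NULL
  for (k in seq_along(images)) {
    fs <- extract_features(images[[k]], scales = scales, log_sigma = log_sigma)
    nf <- dim(fs)[3]
    X <- rbind(X, matrix(fs, ncol = nf,
                         dimnames = list(NULL, dimnames(fs)[[3]])))
    y <- c(y, as.integer(masks[[k]] > 0))
  }
  if (length(unique(y)) < 2)
    stop("labels must contain both classes (cell and background)")

  fit <- with_seed(substream_seed(seed, "classifier"), {
    i1 <- which(y == 1); i0 <- which(y == 0)
    i1 <- sample(i1, min(n_per_class, length(i1)))
    i0 <- sample(i0, min(n_per_class, length(i0)))
    idx <- sample(c(i1, i0))
    n_hold <- max(1, round(holdout_frac * length(idx)))
    hold <- idx[seq_len(n_hold)]
    train <- idx[-seq_len(n_hold)]
    ctr <- colMeans(X[train, , drop = FALSE])
    scl <- apply(X[train, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X[train, , drop = FALSE], 2, ctr), 2, scl, "/")
    gl <- glmnet::glmnet(Xs, y[train], family = "binomial", alpha = 0,
                         lambda = lambda, standardize = FALSE, thresh = 1e-9)
    cf <- as.numeric(stats::coef(gl))
    Xh <- sweep(sweep(X[hold, , drop = FALSE], 2, ctr), 2, scl, "/")
    score_h <- cf[1] + Xh %*% cf[-1]
    acc <- mean((score_h > 0) == (y[hold] == 1))
    list(ctr = ctr, scl = scl, cf = cf, acc = acc, n_train = length(train))
  })

  structure(list(
    feature_names = colnames(X),
    center = fit$ctr, scale = fit$scl,
    intercept = fit$cf[1], weights = stats::setNames(fit$cf[-1], colnames(X)),
    holdout_accuracy = fit$acc, n_train = fit$n_train,
    seed = as.integer(seed), lambda = lambda,
    scales = scales, log_sigma = log_sigma,
    schema_version = "1"
  ), class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("pixel_classifier: %d features, %d training pixels, held-out accuracy %.3f\n",
              length(x$feature_names), x$n_train, x$holdout_accuracy))
  invisible(x)
}

pixel_scores <- function(image, clf) {
  fs <- extract_features(image, scales = clf$scales, log_sigma = clf$log_sigma)
  have <- dimnames(fs)[[3]]
  missing <- setdiff(clf$feature_names, have)
  if (length(missing))
    stop("feature mismatch; missing features: ", paste(missing, collapse = ", "))
  nf <- dim(fs)[3]
  Xm <- matrix(fs, ncol = nf, dimnames = list(NULL, have))
  Xm <- Xm[, clf$feature_names, drop = FALSE]
  Xs <- sweep(sweep(Xm, 2, clf$center), 2, clf$scale, "/")
  matrix(clf$intercept + Xs %*% clf$weights, nrow(image), ncol(image))
}

#' Segment an image into a binary cell/background mask
#'
#' Classifies every pixel with a trained [train_pixel_classifier()] model
#' (score exactly 0 resolves to background — the conservative choice for
#' confluency) and post-processes the mask: connected components smaller
#' than `min_object_area` are removed and interior holes smaller than
#' `max_hole_area` are filled.
#'
#' @param image Intensity matrix.
#' @param clf A `pixel_classifier`.
#' @param min_object_area,max_hole_area Post-processing thresholds, pixels.
#' @return Integer 0/1 matrix of class `seg_mask`; attribute `provenance`
#'   records the classifier seed and post-processing applied.
#' @export
segment <- function(image, clf, min_object_area = 30, max_hole_area = 100) {
  stopifnot(inherits(clf, "pixel_classifier"))
  mask <- pixel_scores(image, clf) > 0
  if (min_object_area > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab)
    drop <- which(sizes < min_object_area)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  if (max_hole_area > 0 && any(!mask)) {
    labh <- EBImage::bwlabel(!mask)
    border_labels <- unique(c(labh[1, ], labh[nrow(labh), ],
                              labh[, 1], labh[, ncol(labh)]))
    sizes <- tabulate(labh)
    fill <- setdiff(which(sizes <= max_hole_area), border_labels)
    if (length(fill)) mask[labh %in% fill] <- TRUE
  }
  structure(matrix(as.integer(mask), nrow(image), ncol(image)),
            class = "seg_mask",
            provenance = list(classifier_seed = clf$seed,
                              min_object_area = min_object_area,
                              max_hole_area = max_hole_area))
}
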