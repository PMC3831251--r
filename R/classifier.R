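#' Training configuration for a per-class SVM
#'
#' @param kernel `"linear"`, `"polynomial"` or `"rbf"` (radial basis).
#' @param cost regularisation constant C (> 0).
#' @param gamma kernel width for polynomial/rbf; `NULL` uses the libsvm
#'   default `1/dim`.
#' @param degree polynomial degree.
#' @param scheme feature encoding, see [encode_peptides()].
#' @param window binary-profile window length (BIN scheme).
#' @param seed integer seed used by stochastic steps.
#' @return object of class `train_config`.
#' @export
train_config <- function(kernel = c("rbf", "linear", "polynomial"),
                         cost = 1, gamma = NULL, degree = 3L,
                         scheme = "DPC", window = 20L, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, is.null(gamma) || gamma > 0, degree >= 1L)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 degree = as.integer(degree), scheme = toupper(scheme),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "train_config")
}

#' Train a per-class SVM model
#'
#' Fits an SVM (via libsvm) on the encoded dataset and wraps it in a
#' self-contained bundle: the encoder scheme, every data-dependent encoder
#' artifact (the AAP propensity scale when `scheme = "AAP"`), the feature
#' standardisation statistics and a decision threshold. All artifacts are
#' fitted on the training data only, so the bundle can score unseen
#' peptides without leakage. Scores are oriented so that higher means more
#' positive-class-like.
#'
#' The default threshold (`threshold = "cv"`) is the score maximizing the
#' Matthews correlation coefficient over internal cross-validated training
#' scores; `threshold = "train"` uses in-sample scores (faster, slightly
#' optimistic) and a numeric value fixes the threshold directly.
#'
#' @param ds `labeled_dataset` with both positives and negatives.
#' @param cfg `train_config`.
#' @param threshold `"cv"`, `"train"` or a number.
#' @param threshold_folds folds for the internal threshold CV.
#' @return object of class `model_bundle`.
#' @export
train_model <- function(ds, cfg = train_config(), threshold = "cv",
                        threshold_folds = 5L) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(cfg, "train_config"))
  if (!nrow(ds$positives) || !nrow(ds$negatives))
    stop("dataset is single-label; need both positives and negatives")
  if (identical(threshold, "cv")) {
    cv <- cross_validate(ds, cfg, folds = threshold_folds, seed = cfg$seed)
    thr <- cv$best$threshold
  } else if (identical(threshold, "train")) {
    thr <- NA_real_   # filled after fitting
  } else {
    thr <- as.numeric(threshold)
  }
  xy <- dataset_xy(ds)
  artifacts <- list()
  if (cfg$scheme == "AAP")
    artifacts$aap_scale <- build_aap_scale(ds$positives, ds$negatives)
  X <- encode_peptides(xy$seq, cfg$scheme, artifacts, window = cfg$window)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1   # constant features stay constant, not NaN
  Xs <- scale(X, center = ctr, scale = scl)
  y <- factor(ifelse(xy$y == 1L, "pos", "neg"), levels = c("pos", "neg"))
  fit <- with_seed(cfg$seed, e1071::svm(
    x = Xs, y = y, kernel = svm_kernel(cfg$kernel), cost = cfg$cost,
    gamma = cfg$gamma %||% (1 / ncol(Xs)), degree = cfg$degree,
    scale = FALSE))
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE),
             "decision.values")[, 1L]
  flip <- if (mean(dv[xy$y == 1L]) >= mean(dv[xy$y == 0L])) 1 else -1
  bundle <- structure(list(
    class_name = ds$class_name, cfg = cfg, fit = fit, flip = flip,
    artifacts = artifacts, center = ctr, scale = scl,
    threshold = thr, feature_order_version = FEATURE_ORDER_VERSION),
    class = "model_bundle")
  if (is.na(bundle$threshold))
    bundle$threshold <- best_mcc_threshold(flip * dv, xy$y)$threshold
  bundle
}

svm_kernel <- function(k) c(linear = "linear", polynomial = "polynomial",
                            rbf = "radial")[[k]]

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle> class %s | %s kernel on %s | threshold %.3f\n",
    x$class_name, x$cfg$kernel, x$cfg$scheme, x$threshold))
  invisible(x)
}

#' Score peptides with a trained bundle
#'
#' Encodes the peptides with the bundle's scheme and fitted artifacts,
#' applies the stored standardisation and returns one real decision score
#' per peptide; higher means more epitope-like for the bundle's class.
#'
#' @param bundle `model_bundle`.
#' @param seqs peptide set or character vector.
#' @return named numeric vector of scores.
#' @export
score_peptides <- function(bundle, seqs) {
  stopifnot(inherits(bundle, "model_bundle"))
  X <- encode_peptides(seqs, bundle$cfg$scheme, bundle$artifacts,
                       window = bundle$cfg$window)
  Xs <- scale(X, center = bundle$center, scale = bundle$scale)
  dv <- attr(stats::predict(bundle$fit, Xs, decision.values = TRUE),
             "decision.values")[, 1L]
  stats::setNames(bundle$flip * dv, rownames(X))
}

#' Tune a configuration grid by cross-validated MCC
#'
#' Scores every configuration by its mean cross-validated maximum MCC;
#' the winner is the argmax, ties broken by higher AUC and then by grid
#' order. The full report is returned for inspection.
#'
#' @param ds `labeled_dataset`.
#' @param grid list of `train_config` objects; see [default_grid()].
#' @param folds CV folds per configuration.
#' @param seed fold-assignment seed (shared across configurations).
#' @return list with `best` (a `train_config`) and `report` (data.frame
#'   with one row per configuration: kernel, cost, gamma, degree, MCC,
#'   Acc, AUC).
#' @export
tune_grid <- function(ds, grid, folds = 5L, seed = 1L) {
  if (!length(grid)) stop("empty configuration grid")
  rows <- lapply(grid, function(cfg) {
    cv <- cross_validate(ds, cfg, folds = folds, seed = seed)
    data.frame(kernel = cfg$kernel, cost = cfg$cost,
               gamma = cfg$gamma %||% NA_real_, degree = cfg$degree,
               scheme = cfg$scheme, MCC = cv$best$metrics$MCC,
               Acc = cv$best$metrics$Acc, AUC = cv$auc)
  })
  report <- do.call(rbind, rows)
  ord <- order(-report$MCC, -report$AUC, seq_len(nrow(report)))
  list(best = grid[[ord[1L]]], report = report)
}

#' Default tuning grid
#'
#' Linear, radial-basis and degree-2/3 polynomial kernels crossed with
#' C in \{0.01, 0.1, 1, 10, 100\} and, for the non-linear kernels, gamma in
#' \{0.001, 0.01, 0.1, 1\}.
#'
#' @param scheme feature encoding for every configuration.
#' @param seed seed stored in every configuration.
#' @return list of `train_config` objects.
#' @export
default_grid <- function(scheme = "DPC", seed = 1L) {
  costs <- c(0.01, 0.1, 1, 10, 100)
  gammas <- c(0.001, 0.01, 0.1, 1)
  grid <- list()
  for (C in costs) {
    grid <- c(grid, list(train_config("linear", cost = C, scheme = scheme,
                                      seed = seed)))
    for (g in gammas) {
      grid <- c(grid, list(
        train_config("rbf", cost = C, gamma = g, scheme = scheme,
                     seed = seed),
        train_config("polynomial", cost = C, gamma = g, degree = 2L,
                     scheme = scheme, seed = seed),
        train_config("polynomial", cost = C, gamma = g, degree = 3L,
                     scheme = scheme, seed = seed)))
    }
  }
  grid
}

#' Non-exclusive class assignment
#'
#' Scores each peptide with every per-class bundle and returns every class
#' whose score reaches its threshold. Assignments are never forced to be
#' exclusive: a peptide scoring above threshold under two models is
#' reported for both classes, and a peptide below every threshold gets no
#' row.
#'
#' @param seqs peptide set or character vector.
#' @param bundles list of `model_bundle` objects.
#' @param thresholds optional named numeric vector overriding the stored
#'   per-class thresholds.
#' @return data.frame with columns `id`, `class`, `score`, `threshold`,
#'   one row per (peptide, class) call.
#' @export
assign_classes <- function(seqs, bundles, thresholds = NULL) {
  if (inherits(bundles, "model_bundle")) bundles <- list(bundles)
  rows <- lapply(bundles, function(b) {
    thr <- if (!is.null(thresholds) && b$class_name %in% names(thresholds))
      thresholds[[b$class_name]] else b$threshold
    sc <- score_peptides(b, seqs)
    hit <- sc >= thr
    if (!any(hit)) return(NULL)
    data.frame(id = names(sc)[hit], class = b$class_name,
               score = unname(sc[hit]), threshold = thr)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), class = character(),
                      score = numeric(), threshold = numeric())
  rownames(out) <- NULL
  out[order(out$id, -out$score), , drop = FALSE]
}

#' Save / load a model bundle
#'
#' Bundles are serialized with their encoder spec, fitted artifacts and the
#' frozen feature-ordering version, so a stored model scores identically
#' after reload.
#'
#' @param bundle `model_bundle`.
#' @param path file path.
#' @return `path` (save) or the restored `model_bundle` (load).
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "model_bundle")) stop("not a model bundle: ", path)
  if (!identical(bundle$feature_order_version, FEATURE_ORDER_VERSION))
    warning("bundle was built under feature-ordering version ",
            bundle$feature_order_version, "; this package uses ",
            FEATURE_ORDER_VERSION)
  bundle
}
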