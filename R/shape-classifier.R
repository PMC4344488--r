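#' Predict DNA shape features from sequence
#'
#' Slides a pentamer window along the sequence and assigns the table's four
#' shape parameters (MGW, ProT, Roll, HelT) to each pentamer's center base.
#' The two terminal positions at each end have no centered pentamer and are
#' returned as NA.
#'
#' @param sequence a single character string or DNAString (A/C/G/T only).
#' @param table pentamer shape table (see [synthetic_shape_table()]).
#' @return numeric matrix, `nchar(sequence)` rows x 4 columns (`MGW`,
#'   `ProT`, `Roll`, `HelT`); rows 1-2 and the last two rows are NA.
#' @export
predict_shape <- function(sequence, table) {
  tabm <- validate_shape_table(table)
  s <- as.character(sequence)
  L <- nchar(s)
  if (L < 5L) stopf("sequence must be at least 5 bases long")
  if (grepl("[^ACGT]", s)) stopf("sequence contains non-ACGT bases")
  pent <- substring(s, seq_len(L - 4L), seq_len(L - 4L) + 4L)
  idx <- match(pent, rownames(tabm))
  if (anyNA(idx)) stopf("pentamer absent from shape table: %s",
                        pent[which(is.na(idx))[1L]])
  out <- matrix(NA_real_, L, 4L, dimnames = list(NULL, colnames(tabm)))
  out[3:(L - 2L), ] <- tabm[idx, , drop = FALSE]
  out
}

# vectorized per-column pentamer lookup over many equal-length sequences;
# returns a list of n x W matrices, one per shape feature
shape_blocks <- function(seqs, tabm, W, context = 2L) {
  feats <- colnames(tabm)
  out <- lapply(feats, function(f) matrix(0, length(seqs), W))
  names(out) <- feats
  for (i in seq_len(W)) {
    pent <- substr(seqs, i + context - 2L, i + context + 2L)
    idx <- match(pent, rownames(tabm))
    if (anyNA(idx)) stopf("pentamer absent from shape table: %s",
                          pent[which(is.na(idx))[1L]])
    for (f in feats) out[[f]][, i] <- tabm[idx, f]
  }
  out
}

#' Build the classification design matrix
#'
#' Turns aligned site windows into features. The sequence block one-hot
#' encodes the flank positions only (the core is identical across sites, so
#' its columns are constant and carry no information); the shape block
#' covers *all* inner-window positions, core included, because flanking
#' bases alter core-edge shape through the pentamer model. The 2 bp of
#' extra context on each side of the window guarantees a defined pentamer
#' at every inner position. Columns are returned raw; standardization is
#' applied inside [cross_validate()] using training folds only.
#'
#' @param sites a site set from [gen_site_sets()] (or any data.frame with
#'   `sequence`, `label` plus `core`/`flank`/`context` attributes).
#' @param table pentamer shape table.
#' @param feature_set one of `"sequence"`, `"shape4"`,
#'   `"sequence+shape4"`, `"sequence+MGW"`.
#' @return list with `X` (numeric matrix), `y` (0/1 integer vector) and
#'   `feature_set`.
#' @export
build_features <- function(sites, table,
                           feature_set = c("sequence+shape4", "sequence",
                                           "shape4", "sequence+MGW")) {
  feature_set <- match.arg(feature_set)
  tabm <- validate_shape_table(table)
  core <- attr(sites, "core") %||% stopf("sites lack a core attribute")
  f <- attr(sites, "flank")
  context <- attr(sites, "context") %||% 2L
  W <- 6L + 2L * f
  seqs <- sites$sequence
  if (length(unique(nchar(seqs))) != 1L)
    stopf("site sequences must share one width")
  ambiguous <- grepl("[^ACGT]", seqs)
  if (any(ambiguous)) {
    warnf("dropping %d site(s) with ambiguous bases", sum(ambiguous))
    seqs <- seqs[!ambiguous]
    sites <- sites[!ambiguous, , drop = FALSE]
  }
  inner <- substr(seqs, context + 1L, context + W)
  core_seen <- unique(substr(inner, f + 1L, f + 6L))
  if (length(core_seen) != 1L || core_seen != core)
    stopf("windows are not aligned on a single core hexamer (%s)",
          paste(core_seen, collapse = ", "))

  blocks <- list()
  if (feature_set != "shape4") {
    fp <- site_flank_positions(f)
    seq_block <- matrix(0, length(seqs), 4L * length(fp))
    cn <- character(ncol(seq_block))
    for (j in seq_along(fp)) {
      ch <- substr(inner, fp[j], fp[j])
      for (b in seq_along(BASES)) {
        seq_block[, (j - 1L) * 4L + b] <- as.numeric(ch == BASES[b])
        cn[(j - 1L) * 4L + b] <- sprintf("seq_p%02d_%s", fp[j], BASES[b])
      }
    }
    colnames(seq_block) <- cn
    blocks$sequence <- seq_block
  }
  if (feature_set != "sequence") {
    sb <- shape_blocks(seqs, tabm, W, context)
    feats <- if (feature_set == "sequence+MGW") "MGW" else colnames(tabm)
    for (fe in feats) {
      m <- sb[[fe]]
      colnames(m) <- sprintf("%s_p%02d", fe, seq_len(W))
      blocks[[fe]] <- m
    }
  }
  X <- do.call(cbind, blocks)
  list(X = X, y = as.integer(sites$label), feature_set = feature_set)
}

#' L2-regularized linear regression (ridge)
#'
#' Solves `argmin ||Xw - y||^2 + lambda ||w||^2` in closed form via the
#' normal equations, with an unpenalized intercept by default. This is the
#' classifier used throughout: the 0/1 bound label is regressed on the
#' features and the linear predictor serves as the classification score.
#'
#' @param X numeric design matrix.
#' @param y numeric response (0/1 labels here).
#' @param lambda ridge penalty, >= 0.
#' @param intercept include an unpenalized intercept (default TRUE).
#' @return numeric coefficient vector; element `"(Intercept)"` first when
#'   an intercept is fitted.
#' @export
fit_ridge <- function(X, y, lambda, intercept = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("rows of X must match length of y")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stopf("lambda must be a single non-negative number")
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  pen <- rep(lambda, p)
  if (intercept) pen[1L] <- 0
  A <- crossprod(X) + diag(pen, p)
  w <- drop(solve(A, crossprod(X, y)))
  names(w) <- colnames(X)
  w
}

predict_ridge <- function(w, X, intercept = TRUE) {
  X <- as.matrix(X)
  if (intercept) drop(X %*% w[-1L]) + w[1L] else drop(X %*% w)
}

#' ROC curve and AUC
#'
#' The AUC is the probability that a random positive outscores a random
#' negative, with ties counted one half -- identical to the trapezoidal
#' area under the ROC curve with tied scores grouped.
#'
#' @param scores numeric classification scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return list of class `roc_result` with `auc` and `curve` (data.frame
#'   `fpr`, `tpr`, monotone nondecreasing, starting at (0,0)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stopf("AUC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tied group
  tp <- cumsum(l)[grp_end] / np
  fp <- cumsum(1L - l)[grp_end] / nn
  tpr <- c(0, tp); fpr <- c(0, fp)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  structure(list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n", x$auc,
              nrow(x$curve) - 1L))
  invisible(x)
}

stratified_folds <- function(y, n_folds, seed) {
  if (min(table(y)) < n_folds)
    stopf("each class must hold at least n_folds = %d observations", n_folds)
  fold <- integer(length(y))
  withr::with_seed(stage_seed(seed, "cv"), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  fold
}

scale_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(Xte, 2L, mu), 2L, sdv, "/"))
}

#' Cross-validated ridge classification
#'
#' Stratified, seeded k-fold cross-validation of the ridge classifier.
#' Within each fold the columns are standardized using training-fold
#' statistics only; the model is fit on k-1 folds and the held-out linear
#' predictors are pooled across folds for the reported ROC/AUC. The ridge
#' penalty is either fixed (numeric `lambda`) or chosen per outer fold by
#' an inner 5-fold grid search on the training data (`lambda = "grid"`,
#' the default).
#'
#' @param X design matrix (e.g. from [build_features()]).
#' @param y 0/1 labels.
#' @param n_folds number of folds (default 10).
#' @param lambda `"grid"` or a fixed non-negative number.
#' @param lambda_grid candidate penalties for the grid search.
#' @param seed integer; fixes fold assignment (and nothing else).
#' @param folds optional externally supplied fold assignment (overrides
#'   `n_folds`/`seed`); used to compare feature sets on identical folds.
#' @return list with `auc`, `curve`, `fold_auc` (per-fold AUCs),
#'   `lambda` (chosen per fold), `scores` (pooled out-of-fold scores in
#'   input order) and `folds`.
#' @export
cross_validate <- function(X, y, n_folds = 10L, lambda = "grid",
                           lambda_grid = c(0.01, 0.1, 1, 10, 100),
                           seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  if (is.null(folds)) folds <- stratified_folds(y, n_folds, seed)
  ks <- sort(unique(folds))
  scores <- numeric(length(y))
  fold_auc <- numeric(length(ks))
  lam_used <- numeric(length(ks))
  for (j in seq_along(ks)) {
    te <- folds == ks[j]
    Xs <- scale_train_test(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    ytr <- y[!te]
    lam <- if (identical(lambda, "grid")) {
      pick_lambda(Xs$train, ytr, lambda_grid, seed + j)
    } else lambda
    w <- fit_ridge(Xs$train, ytr, lam)
    scores[te] <- predict_ridge(w, Xs$test)
    fold_auc[j] <- roc_auc(scores[te], y[te])$auc
    lam_used[j] <- lam
  }
  roc <- roc_auc(scores, y)
  list(auc = roc$auc, curve = roc$curve, fold_auc = fold_auc,
       lambda = lam_used, scores = scores, folds = folds)
}

# inner grid search: 5-fold CV AUC on the training data only
pick_lambda <- function(X, y, grid, seed) {
  inner <- stratified_folds(y, min(5L, min(table(y))), seed)
  auc <- vapply(grid, function(lam) {
    sc <- numeric(length(y))
    for (k in sort(unique(inner))) {
      te <- inner == k
      Xs <- scale_train_test(X[!te, , drop = FALSE], X[te, , drop = FALSE])
      w <- fit_ridge(Xs$train, y[!te], lam)
      sc[te] <- predict_ridge(w, Xs$test)
    }
    roc_auc(sc, y)$auc
  }, numeric(1))
  grid[which.max(auc)]
}

#' Compare feature sets on identical folds
#'
#' Runs [cross_validate()] for the four feature sets -- sequence only, the
#' four shape features, sequence plus all four shape features, and sequence
#' plus minor groove width only -- with one shared fold assignment, and
#' reports the pooled out-of-fold AUC of each.
#'
#' @param sites a site set from [gen_site_sets()].
#' @param table pentamer shape table.
#' @param n_folds,lambda,lambda_grid,seed passed to [cross_validate()].
#' @return data.frame with columns `feature_set`, `auc`.
#' @export
compare_models <- function(sites, table, n_folds = 10L, lambda = "grid",
                           lambda_grid = c(0.01, 0.1, 1, 10, 100),
                           seed = 1L) {
  sets <- c("sequence", "shape4", "sequence+shape4", "sequence+MGW")
  y <- as.integer(sites$label)
  folds <- stratified_folds(y, n_folds, seed)
  auc <- vapply(sets, function(fs) {
    bf <- build_features(sites, table, fs)
    cross_validate(bf$X, bf$y, lambda = lambda, lambda_grid = lambda_grid,
                   seed = seed, folds = folds)$auc
  }, numeric(1))
  data.frame(feature_set = sets, auc = unname(auc), stringsAsFactors = FALSE)
}

#' Extract aligned site windows from a genome
#'
#' Builds a [gen_site_sets()]-compatible window set from genomic E-box
#' occurrences (e.g. bound occurrences inside peaks and a random intronic
#' background), taking `flank` bp each side of the core plus 2 bp of
#' context. Sites too close to a chromosome end are dropped.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param bound,unbound occurrence data.frames ([scan_eboxes()] layout),
#'   all sharing one core hexamer.
#' @param flank flank length in bp (default 10).
#' @return data.frame with `sequence`, `label` and the attributes
#'   [build_features()] expects.
#' @export
extract_site_windows <- function(genome, bound, unbound, flank = 10L) {
  core <- unique(c(bound$core, unbound$core))
  if (length(core) != 1L)
    stopf("bound and unbound occurrences must share a single core")
  grab <- function(df, label) {
    if (nrow(df) == 0L)
      return(data.frame(sequence = character(0), label = integer(0)))
    lo <- df$start - flank - 2L
    hi <- df$end + flank + 2L
    len <- Biostrings::width(genome)[match(df$chrom, names(genome))]
    ok <- lo >= 1L & hi <= len
    df <- df[ok, , drop = FALSE]; lo <- lo[ok]; hi <- hi[ok]
    seqs <- vapply(seq_len(nrow(df)), function(i)
      as.character(Biostrings::subseq(genome[[df$chrom[i]]], lo[i], hi[i])),
      character(1))
    data.frame(sequence = seqs, label = label, stringsAsFactors = FALSE)
  }
  out <- rbind(grab(bound, 1L), grab(unbound, 0L))
  attr(out, "core") <- core
  attr(out, "flank") <- as.integer(flank)
  attr(out, "context") <- 2L
  attr(out, "window_width") <- 6L + 2L * as.integer(flank)
  out
}
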