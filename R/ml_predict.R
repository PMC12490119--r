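#' Assemble the birth-available feature table
#'
#' Joins clinical features available at birth (sex, gestational age,
#' birth complications, insufficient oxygen) with genetic features
#' (per-child counts of de novo variant classes, mean CADD of passing
#' DNVs, inherited-variant counts by mode/class, standardized PRS) and
#' the ASD label, one row per child. Missing gestational age is imputed
#' as 40 weeks for term births and 34 weeks (a late-preterm value) for
#' preterm births with unknown GA; children without DNVs get a CADD
#' summary of 0. The returned table has no missing values.
#'
#' @param cohort A [Cohort].
#' @param dnvCalls Classified post-cascade DNV calls (from
#'   [dnvPipeline()]), or `NULL` to use zero counts.
#' @param inheritedCalls Inherited calls (from [inheritedPipeline()]), or
#'   `NULL`.
#' @param prs [scorePrs()] output, or `NULL`.
#' @param preterm_only Restrict to preterm children (the at-birth
#'   prediction population).
#' @return data.frame with `person_id`, `label` (factor no/yes) and
#'   numeric feature columns.
#' @export
buildFeatureTable <- function(cohort, dnvCalls = NULL,
                              inheritedCalls = NULL, prs = NULL,
                              preterm_only = FALSE) {
  ind <- individuals(cohort)
  ch <- ind[ind$role %in% c("proband", "sibling"), , drop = FALSE]
  if (preterm_only)
    ch <- ch[!is.na(ch$preterm) & ch$preterm == "yes", , drop = FALSE]
  ga <- ch$gestational_age_weeks
  ga[is.na(ga) & ch$preterm == "no"] <- 40L
  ga[is.na(ga) & ch$preterm == "yes"] <- 34L
  ft <- data.frame(
    person_id = ch$person_id,
    label = factor(ifelse(ch$asd == "yes", "yes", "no"),
                   levels = c("no", "yes")),
    sex_male = as.integer(ch$sex == "male"),
    gestational_age_weeks = as.numeric(ga),
    birth_complications = ifelse(is.na(ch$birth_complications), 0L,
                                 ch$birth_complications),
    insufficient_oxygen = ifelse(is.na(ch$insufficient_oxygen), 0L,
                                 ch$insufficient_oxygen),
    stringsAsFactors = FALSE
  )
  cnt <- function(calls, filter) {
    if (is.null(calls)) return(rep(0L, nrow(ft)))
    pc <- perChildCounts(calls, ch$person_id, filter,
                         drop_excluded = FALSE)
    pc$n[match(ft$person_id, pc$child_id)]
  }
  ft$dnv_total <- cnt(dnvCalls, "all")
  ft$dnv_exonic <- cnt(dnvCalls, "exonic")
  ft$dnv_lof <- cnt(dnvCalls, "lof")
  ft$dnv_ndd <- cnt(dnvCalls, "ndd")
  ft$dnv_lof_ndd <- cnt(dnvCalls, "lof_ndd")
  if (!is.null(dnvCalls)) {
    ok <- dnvCalls$passed & !is.na(dnvCalls$cadd)
    cadd <- tapply(dnvCalls$cadd[ok], dnvCalls$child_id[ok], mean)
    v <- as.numeric(cadd[ft$person_id])
    ft$dnv_cadd_mean <- ifelse(is.na(v), 0, v)
  } else ft$dnv_cadd_mean <- 0
  if (!is.null(inheritedCalls)) {
    ic <- inheritedCalls
    tab <- function(sel) {
      t <- table(factor(ic$child_id[sel], levels = ft$person_id))
      as.integer(t)
    }
    ft$inh_dominant <- tab(ic$mode == "dominant")
    ft$inh_recessive <- tab(ic$mode == "recessive")
    ft$inh_dom_lof <- tab(ic$class_lof)
    ft$inh_dom_dmis <- tab(ic$class_damaging_missense)
  } else {
    ft$inh_dominant <- ft$inh_recessive <- 0L
    ft$inh_dom_lof <- ft$inh_dom_dmis <- 0L
  }
  if (!is.null(prs)) {
    z <- prs$z_score[match(ft$person_id, prs$person_id)]
    ft$prs_z <- ifelse(is.na(z), 0, z)
  } else ft$prs_z <- 0
  ft
}

#' Default feature-generality ordering
#'
#' Ranking used to resolve correlated feature pairs: the more general
#' feature (earlier in the vector) is retained, e.g. total LOF count over
#' LOF on NDD genes.
#'
#' @return Character vector, most general first.
#' @export
featureGenerality <- function() {
  c("sex_male", "gestational_age_weeks", "birth_complications",
    "insufficient_oxygen", "prs_z",
    "dnv_total", "dnv_exonic", "dnv_lof", "dnv_ndd", "dnv_lof_ndd",
    "dnv_cadd_mean",
    "inh_dominant", "inh_recessive", "inh_dom_lof", "inh_dom_dmis")
}

#' Select features by RFE and correlation pruning
#'
#' Recursive feature elimination with random-forest importance and k-fold
#' cross-validation chooses the best-performing subset size; then, in any
#' pair of retained features with |Pearson r| strictly above the
#' threshold, only the more general member (per the generality ordering)
#' is kept. Constant features are dropped up front with a warning.
#'
#' @param ft Feature table from [buildFeatureTable()].
#' @param n_folds Cross-validation folds for RFE.
#' @param cor_threshold Correlation-pruning threshold (strict `>`).
#' @param generality Character vector ranking features, most general
#'   first; defaults to [featureGenerality()].
#' @param seed Integer seed.
#' @return Character vector of selected feature names.
#' @export
selectFeatures <- function(ft, n_folds = 10, cor_threshold = 0.7,
                           generality = featureGenerality(), seed = 1L) {
  x <- ft[, setdiff(names(ft), c("person_id", "label")), drop = FALSE]
  const <- vapply(x, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  stopifnot(ncol(x) >= 2, nrow(x) >= 20)
  set.seed(seed)
  ctrl <- caret::rfeControl(functions = caret::rfFuncs, method = "cv",
                            number = n_folds, verbose = FALSE)
  prof <- caret::rfe(x, ft$label, sizes = seq(2, ncol(x) - 1),
                     rfeControl = ctrl)
  .prune_correlated(prof$optVariables, x, cor_threshold, generality)
}

# keep the more general member of each |r| > threshold pair, resolving the
# tightest pairs first
.prune_correlated <- function(sel, data, cor_threshold, generality) {
  rank <- match(sel, generality)
  rank[is.na(rank)] <- length(generality) + seq_len(sum(is.na(rank)))
  repeat {
    if (length(sel) < 2) break
    cm <- abs(stats::cor(data[, sel, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= cor_threshold) break
    w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    drop_i <- if (rank[w[1]] <= rank[w[2]]) w[2] else w[1]
    sel <- sel[-drop_i]
    rank <- rank[-drop_i]
  }
  sel
}

.strat_folds <- function(y, k) {
  if (any(table(y) < k))
    stop("stratified folding impossible: a class has fewer members than folds")
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

.default_grid <- function(algorithm, p) {
  switch(algorithm,
         xgboost = expand.grid(nrounds = c(50, 100), max_depth = c(2, 3),
                               eta = 0.3),
         random_forest = data.frame(mtry = unique(c(2, max(2,
                                    floor(sqrt(p))))), ntree = 300),
         linear_svm = data.frame(cost = c(0.1, 1)))
}

.fit_model <- function(algorithm, params, x, y) {
  xm <- as.matrix(x)
  switch(algorithm,
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(xm, label = as.integer(y == "yes")),
      nrounds = params$nrounds, verbose = 0),
    random_forest = randomForest::randomForest(
      x = xm, y = y, ntree = params$ntree, mtry = params$mtry),
    linear_svm = e1071::svm(x = xm, y = y, kernel = "linear",
                            cost = params$cost, probability = TRUE,
                            scale = TRUE))
}

.pred_prob <- function(algorithm, model, x) {
  xm <- as.matrix(x)
  switch(algorithm,
    xgboost = stats::predict(model, xgboost::xgb.DMatrix(xm)),
    random_forest = stats::predict(model, xm, type = "prob")[, "yes"],
    linear_svm = attr(stats::predict(model, xm, probability = TRUE),
                      "probabilities")[, "yes"])
}

.auroc <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c("no", "yes"), direction = "<",
                                 quiet = TRUE)))
}

#' Nested cross-validation for at-birth ASD prediction
#'
#' Outer stratified k-fold loop: within each outer training set, a
#' repeated inner k-fold grid search picks the hyperparameters with the
#' best mean held-out AUROC (skipped when the grid has a single row); the
#' winning model is refit on the outer training fold and scored on the
#' held-out fold. Metrics are computed on the pooled out-of-fold
#' predictions: accuracy with an exact (Clopper-Pearson) 95% CI, AUROC,
#' sensitivity and specificity for the ASD class, and F1. The whole
#' procedure is deterministic under the seed.
#'
#' @param ft Feature table from [buildFeatureTable()].
#' @param features Feature names to use (e.g. from [selectFeatures()]).
#' @param algorithm `"xgboost"`, `"random_forest"` or `"linear_svm"`.
#' @param grid Hyperparameter data.frame (one row per candidate); `NULL`
#'   for a small default grid.
#' @param outer_folds,inner_folds,inner_repeats Loop dimensions.
#' @param seed Integer seed.
#' @return A `nested_cv` list: `predictions` (pooled out-of-fold),
#'   `metrics`, `per_fold` (chosen hyperparameters), `models`,
#'   `test_index`, `algorithm`, `features`.
#' @export
nestedCv <- function(ft, features, algorithm = c("xgboost",
                                                 "random_forest",
                                                 "linear_svm"),
                     grid = NULL, outer_folds = 10, inner_folds = 10,
                     inner_repeats = 10, seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- ft[, features, drop = FALSE]
  y <- ft$label
  if (is.null(grid)) grid <- .default_grid(algorithm, ncol(x))
  set.seed(seed)
  ofold <- .strat_folds(y, outer_folds)
  prob <- numeric(nrow(x))
  per_fold <- vector("list", outer_folds)
  models <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- which(ofold != f)
    te <- which(ofold == f)
    best <- 1L
    if (nrow(grid) > 1) {
      score <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        aucs <- numeric(inner_repeats)
        for (r in seq_len(inner_repeats)) {
          ifold <- .strat_folds(y[tr], inner_folds)
          p_in <- numeric(length(tr))
          for (ff in seq_len(inner_folds)) {
            itr <- tr[ifold != ff]; ite <- tr[ifold == ff]
            m <- .fit_model(algorithm, grid[g, , drop = FALSE],
                            x[itr, , drop = FALSE], y[itr])
            p_in[ifold == ff] <- .pred_prob(algorithm, m,
                                            x[ite, , drop = FALSE])
          }
          aucs[r] <- .auroc(y[tr], p_in)
        }
        score[g] <- mean(aucs)
      }
      best <- which.max(score)
    }
    m <- .fit_model(algorithm, grid[best, , drop = FALSE],
                    x[tr, , drop = FALSE], y[tr])
    prob[te] <- .pred_prob(algorithm, m, x[te, , drop = FALSE])
    per_fold[[f]] <- cbind(fold = f, grid[best, , drop = FALSE])
    models[[f]] <- m
  }
  metrics <- evaluateConfusion(prob, y, positive = "yes")
  structure(list(
    predictions = data.frame(person_id = ft$person_id, fold = ofold,
                             prob = prob, label = y,
                             stringsAsFactors = FALSE),
    metrics = metrics,
    per_fold = do.call(rbind, per_fold),
    models = models, test_index = split(seq_along(ofold), ofold),
    algorithm = algorithm, features = features, seed = seed
  ), class = "nested_cv")
}

#' Binary classification metrics
#'
#' Accuracy with exact binomial 95% CI, AUROC (from the scores),
#' sensitivity and specificity for the positive class, and F1.
#'
#' @param scores Predicted probabilities of the positive class.
#' @param labels Factor of true labels.
#' @param positive Positive class label.
#' @param threshold Classification threshold on the score.
#' @return List of metrics; AUROC is `NA` for single-class labels.
#' @export
evaluateConfusion <- function(scores, labels, positive = "yes",
                              threshold = 0.5) {
  pred_pos <- scores >= threshold
  is_pos <- labels == positive
  tp <- sum(pred_pos & is_pos)
  fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos)
  fp <- sum(pred_pos & !is_pos)
  n <- length(labels)
  acc <- (tp + tn) / n
  ci <- stats::binom.test(tp + tn, n)$conf.int
  list(accuracy = acc, accuracy_ci = as.numeric(ci),
       auroc = .auroc(factor(ifelse(is_pos, "yes", "no"),
                             levels = c("no", "yes")), scores),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
            else NA_real_,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' SHAP-style feature attributions for a nested-CV run
#'
#' For XGBoost models, exact TreeSHAP contributions are computed on each
#' outer fold's held-out rows and pooled; attributions plus the bias term
#' sum to the model's margin (log-odds) prediction. For random forest and
#' linear SVM, a permutation-based attribution is used instead (the drop
#' in predicted probability when the feature is permuted within the held
#' out fold) and the result is flagged `method = "permutation"`. The
#' summary ranks features by mean absolute attribution and reports the
#' direction as the sign of the correlation between feature value and
#' attribution.
#'
#' @param ncv A `nested_cv` result.
#' @param ft The feature table it was trained on.
#' @return List with `shap` (persons x features matrix), `summary`
#'   (ranked data.frame with mean |SHAP| and direction) and `method`.
#' @export
shapSummary <- function(ncv, ft) {
  stopifnot(inherits(ncv, "nested_cv"))
  x <- ft[, ncv$features, drop = FALSE]
  n <- nrow(x)
  p <- length(ncv$features)
  shap <- matrix(NA_real_, n, p, dimnames = list(ft$person_id,
                                                 ncv$features))
  bias <- numeric(n)
  method <- if (ncv$algorithm == "xgboost") "treeshap" else "permutation"
  set.seed(ncv$seed + 1L)
  for (f in seq_along(ncv$models)) {
    te <- ncv$test_index[[f]]
    m <- ncv$models[[f]]
    xm <- as.matrix(x[te, , drop = FALSE])
    if (method == "treeshap") {
      contrib <- stats::predict(m, xgboost::xgb.DMatrix(xm),
                                predcontrib = TRUE)
      shap[te, ] <- contrib[, ncv$features, drop = FALSE]
      bias[te] <- contrib[, ncol(contrib)]  # bias/intercept is last
    } else {
      base <- .pred_prob(ncv$algorithm, m, xm)
      for (j in seq_len(p)) {
        xp <- xm
        xp[, j] <- xp[sample(nrow(xp)), j]
        shap[te, j] <- base - .pred_prob(ncv$algorithm, m, xp)
      }
    }
  }
  dir <- vapply(seq_len(p), function(j) {
    if (stats::sd(x[[j]]) == 0 || stats::sd(shap[, j]) == 0) return(0)
    sign(stats::cor(x[[j]], shap[, j]))
  }, numeric(1))
  summ <- data.frame(feature = ncv$features,
                     mean_abs_shap = colMeans(abs(shap)),
                     direction = dir, stringsAsFactors = FALSE)
  summ <- summ[order(-summ$mean_abs_shap), ]
  rownames(summ) <- NULL
  list(shap = shap, bias = bias, summary = summ, method = method)
}
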