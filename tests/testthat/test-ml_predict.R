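.ml_cohort <- function(seed = 101, n_families = 150) {
  co <- simulateCohort(simConfig(n_families = n_families,
                                 preterm_rate = 1, seed = seed),
                       variants = FALSE)
  ind <- individuals(co)
  ch <- ind[ind$role %in% c("proband", "sibling"), ]
  sc <- scorePrs(prsGenotypes(co)[ch$person_id, ], co@prsVariants,
                 prsWeights(co))
  ft <- buildFeatureTable(co, prs = sc, preterm_only = TRUE)
  # per-child true counts stand in for pipeline output in count features
  ft$dnv_exonic <- ch$dnv_exonic_true[match(ft$person_id, ch$person_id)]
  ft$dnv_total <- ch$dnv_count_true[match(ft$person_id, ch$person_id)]
  ft
}

test_that("confusion metrics match hand arithmetic", {
  labels <- factor(rep(c("yes", "no"), each = 10), levels = c("no", "yes"))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.1, 8), rep(0.9, 2))
  m <- evaluateConfusion(scores, labels)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.8)
  expect_equal(unname(m$confusion), c(8, 2, 8, 2))
  ci <- binom.test(16, 20)$conf.int
  expect_equal(m$accuracy_ci, as.numeric(ci))
  perfect <- evaluateConfusion(as.numeric(labels == "yes"), labels)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auroc, 1)
  one_class <- evaluateConfusion(runif(5), factor(rep("yes", 5),
                                                  levels = c("no", "yes")))
  expect_true(is.na(one_class$auroc))
})

test_that("feature assembly imputes gestational age and fills genetic columns", {
  co <- simulateCohort(simConfig(n_families = 40, seed = 55),
                       variants = FALSE)
  ft <- buildFeatureTable(co)
  expect_false(any(is.na(ft[, setdiff(names(ft), "person_id")])))
  ind <- individuals(co)
  ch <- ind[ind$role %in% c("proband", "sibling"), ]
  na_term <- ch$person_id[is.na(ch$gestational_age_weeks) &
                            ch$preterm == "no"]
  expect_true(all(ft$gestational_age_weeks[
    ft$person_id %in% na_term] == 40))
  na_pre <- ch$person_id[is.na(ch$gestational_age_weeks) &
                           ch$preterm == "yes"]
  if (length(na_pre))
    expect_true(all(ft$gestational_age_weeks[
      ft$person_id %in% na_pre] == 34))
  ftp <- buildFeatureTable(co, preterm_only = TRUE)
  expect_true(all(ftp$gestational_age_weeks < 37 |
                    ftp$person_id %in% na_pre))
})

test_that("correlation pruning keeps the more general feature, strictly above 0.7", {
  set.seed(9)
  n <- 200
  x <- rnorm(n)
  # construct exact sample correlations by orthogonalization
  mkcor <- function(r) {
    z <- rnorm(n)
    z <- residuals(lm(z ~ x))
    r * scale(x)[, 1] + sqrt(1 - r^2) * scale(z)[, 1]
  }
  ft <- data.frame(
    person_id = paste0("p", 1:n),
    label = factor(sample(c("no", "yes"), n, TRUE),
                   levels = c("no", "yes")),
    dnv_lof = x,
    dnv_lof_ndd = x,             # r = 1 duplicate of a less general feature
    prs_z = mkcor(0.71),         # just above the threshold vs dnv_lof
    sex_male = mkcor(0.69),      # just below: retained
    gestational_age_weeks = rnorm(n)
  )
  sel <- pretermASD:::.prune_correlated(
    c("dnv_lof", "dnv_lof_ndd", "prs_z", "sex_male",
      "gestational_age_weeks"),
    ft, cor_threshold = 0.7, generality = featureGenerality())
  # the r = 1 duplicate resolves first, keeping the more general dnv_lof;
  # then the 0.71 pair with the still-more-general prs_z removes dnv_lof
  expect_false("dnv_lof_ndd" %in% sel)
  expect_false("dnv_lof" %in% sel)
  expect_true("prs_z" %in% sel)
  expect_true("sex_male" %in% sel)       # |r| = 0.69 pair untouched
  expect_true("gestational_age_weeks" %in% sel)
})

test_that("RFE keeps the informative feature among noise", {
  set.seed(12)
  n <- 240
  f <- rnorm(n)
  noise <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("noise", 1:6)))
  ft <- data.frame(person_id = paste0("p", 1:n),
                   label = factor(ifelse(plogis(2.5 * f) > runif(n),
                                         "yes", "no"),
                                  levels = c("no", "yes")),
                   signal = f, noise)
  sel <- suppressWarnings(selectFeatures(ft, n_folds = 5, seed = 3))
  expect_true("signal" %in% sel)
})

test_that("nested CV partitions the data, is deterministic, and nails separable toys", {
  set.seed(21)
  n <- 120
  # disjoint feature ranges: genuinely separable
  x1 <- c(runif(n / 2, -2, -1), runif(n / 2, 1, 2))
  ft <- data.frame(person_id = paste0("p", 1:n),
                   label = factor(rep(c("no", "yes"), each = n / 2),
                                  levels = c("no", "yes")),
                   x1 = x1, x2 = rnorm(n))
  ncv <- nestedCv(ft, c("x1", "x2"), "random_forest",
                  grid = data.frame(mtry = 1, ntree = 100),
                  outer_folds = 5, seed = 7)
  # every row appears in exactly one outer test fold
  expect_equal(sort(unname(unlist(ncv$test_index))), 1:n)
  expect_equal(ncv$metrics$accuracy, 1)
  expect_equal(ncv$metrics$auroc, 1)
  ncv2 <- nestedCv(ft, c("x1", "x2"), "random_forest",
                   grid = data.frame(mtry = 1, ntree = 100),
                   outer_folds = 5, seed = 7)
  expect_identical(ncv$predictions, ncv2$predictions)
  # random labels on noise: no separation signal
  ft$label <- factor(sample(c("no", "yes"), n, TRUE),
                     levels = c("no", "yes"))
  ft$x1 <- rnorm(n)
  ncv0 <- nestedCv(ft, c("x1", "x2"), "random_forest",
                   grid = data.frame(mtry = 1, ntree = 100),
                   outer_folds = 5, seed = 8)
  expect_true(ncv0$metrics$auroc > 0.25 && ncv0$metrics$auroc < 0.75)
  # single-class folding is refused
  ft$label <- factor(rep("yes", n), levels = c("no", "yes"))
  expect_error(nestedCv(ft, c("x1", "x2"), "random_forest",
                        grid = data.frame(mtry = 1, ntree = 100),
                        outer_folds = 5, seed = 9), "stratified")
})

test_that("grid search picks hyperparameters per outer fold", {
  ft <- .ml_cohort(seed = 61, n_families = 120)
  feats <- c("sex_male", "prs_z", "dnv_exonic", "gestational_age_weeks")
  ncv <- nestedCv(ft, feats, "xgboost",
                  grid = expand.grid(nrounds = c(20, 40), max_depth = 2,
                                     eta = 0.3),
                  outer_folds = 4, inner_folds = 3, inner_repeats = 1,
                  seed = 13)
  expect_equal(nrow(ncv$per_fold), 4)
  expect_true(all(ncv$per_fold$nrounds %in% c(20, 40)))
  expect_gt(ncv$metrics$auroc, 0.5)
})

test_that("TreeSHAP attributions are additive and rank planted effects sensibly", {
  ft <- .ml_cohort(seed = 71, n_families = 160)
  ft$pure_noise <- rnorm(nrow(ft))
  feats <- c("sex_male", "prs_z", "dnv_exonic", "pure_noise")
  ncv <- nestedCv(ft, feats, "xgboost",
                  grid = data.frame(nrounds = 40, max_depth = 2,
                                    eta = 0.3),
                  outer_folds = 5, seed = 17)
  sh <- shapSummary(ncv, ft)
  expect_equal(sh$method, "treeshap")
  # additivity: contributions + bias equal the margin prediction
  margin <- qlogis(ncv$predictions$prob)
  expect_lt(max(abs(rowSums(sh$shap) + sh$bias - margin)), 1e-3)
  # the no-effect feature ranks last
  expect_equal(sh$summary$feature[nrow(sh$summary)], "pure_noise")
  # planted positive effects point the right way
  expect_equal(sh$summary$direction[sh$summary$feature == "sex_male"], 1)
  # linear SVM falls back to permutation attributions, flagged
  ncv_svm <- nestedCv(ft, feats, "linear_svm",
                      grid = data.frame(cost = 1), outer_folds = 4,
                      seed = 19)
  sh_svm <- shapSummary(ncv_svm, ft)
  expect_equal(sh_svm$method, "permutation")
})
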