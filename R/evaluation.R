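#' Stratified, group-aware repeated k-fold split plan
#'
#' Builds `rounds` independent k-fold partitions at the level of groups
#' (e.g. identical peptide/MHC pairs), so complexes sharing a group key are
#' always co-assigned and never leak between training and evaluation.
#' Within each round, groups are stratified by their class so per-fold
#' class proportions track the global proportions; the non-test portion of
#' each fold is further split group-wise into training and validation so
#' the overall assignment is approximately `train_frac` / `val_frac` /
#' the remainder for test.
#'
#' @param labels Character class per complex.
#' @param group_keys Group key per complex (default: each complex its own
#'   group).
#' @param k Folds per round (default 10).
#' @param rounds Rounds (default 5).
#' @param train_frac,val_frac Target assignment fractions (0.7 / 0.2).
#' @param seed RNG seed; the plan is deterministic given
#'   `(seed, labels, group_keys)`.
#' @return data.frame of class `split_plan` with columns round, fold,
#'   index, group, label, assignment (train/val/test).
#' @export
make_splits <- function(labels, group_keys = NULL, k = 10, rounds = 5,
                        train_frac = 0.7, val_frac = 0.2, seed = 1) {
  n <- length(labels)
  stopifnot(n >= k)
  if (is.null(group_keys)) group_keys <- paste0("g", seq_len(n))
  stopifnot(length(group_keys) == n)
  gsize <- table(group_keys)
  cap <- ceiling(n / k)
  if (any(gsize > cap)) {
    big <- names(gsize)[gsize > cap]
    stop("group(s) exceed fold capacity (", cap, " complexes): ",
         paste(sprintf("%s (n=%d)", big, gsize[big]), collapse = ", "))
  }
  # group-level class = majority label of members
  gclass <- vapply(split(labels, group_keys), function(l) {
    names(sort(table(l), decreasing = TRUE))[1]
  }, character(1))
  out <- list()
  for (r in seq_len(rounds)) {
    set.seed(seed * 1000L + r)
    fold_of_group <- character(0)
    for (cl in unique(gclass)) {
      gs <- sample(names(gclass)[gclass == cl])
      folds <- rep(seq_len(k), length.out = length(gs))
      folds <- (folds + sample.int(k, 1) - 1L) %% k + 1L
      fold_of_group[gs] <- folds
    }
    for (f in seq_len(k)) {
      test_groups <- names(fold_of_group)[fold_of_group == as.character(f)]
      rest <- setdiff(names(gclass), test_groups)
      val_groups <- character(0)
      vfrac <- val_frac / (train_frac + val_frac)
      for (cl in unique(gclass)) {
        gs <- sample(rest[gclass[rest] == cl])
        nv <- round(vfrac * length(gs))
        val_groups <- c(val_groups, utils::head(gs, nv))
      }
      assignment <- ifelse(group_keys %in% test_groups, "test",
                           ifelse(group_keys %in% val_groups, "val", "train"))
      out[[length(out) + 1]] <- data.frame(
        round = r, fold = f, index = seq_len(n), group = group_keys,
        label = labels, assignment = assignment, stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, out)
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Classification metrics from scores and binary labels
#'
#' AUC by the rank statistic (ties handled by midranks); accuracy,
#' precision, recall and F1 from the confusion matrix at the threshold.
#' With a single class present the AUC is `NA` and the other metrics are
#' still computed.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: auc, accuracy, precision, recall, f1, tp, fp, tn,
#'   fn.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(scores)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(auc = auc, accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}

# fit-normalise-train-predict for one split; decoys (already in the train
# normalisation space once transformed) are appended to the training set
.fit_and_score <- function(graphs, labels, plan_rows, decoys = NULL,
                           cfg = egnn_config(), tcfg = train_config()) {
  tr <- plan_rows$index[plan_rows$assignment == "train"]
  va <- plan_rows$index[plan_rows$assignment == "val"]
  te <- plan_rows$index[plan_rows$assignment == "test"]
  norm <- normalize_features(graphs[tr], c(graphs[va], graphs[te]))
  train_g <- norm$train; train_y <- labels[tr]
  val_g <- norm$apply[seq_along(va)]
  test_g <- norm$apply[length(va) + seq_along(te)]
  if (!is.null(decoys) && length(decoys)) {
    train_g <- c(train_g, decoys)
    train_y <- c(train_y, rep("weak_aug", length(decoys)))
  }
  model <- train_egnn(train_g, train_y, val_g, labels[va], cfg, tcfg)
  preds <- predict_egnn(model, test_g)
  m <- compute_metrics(preds$binding_score, labels[te] == "strong",
                       cfg$decision_threshold)
  list(metrics = m, predictions = preds, test_index = te, model = model)
}

#' Repeated group-aware cross-validation of the EGNN classifier
#'
#' Runs the full evaluation protocol: for every (round, fold) of the split
#' plan, normalisation is fit on the training portion only, the classifier
#' is trained with early stopping on the validation portion (optionally
#' with generated decoys added to training) and scored on the test
#' portion. Metrics are for the binary strong-vs-rest task.
#'
#' @param graphs List of `interface_graph`s (unnormalised).
#' @param labels Labels in `c("strong","weak_exp")`.
#' @param group_keys Group keys (see [make_splits()]).
#' @param k,rounds Folds and rounds.
#' @param decoys Optional list of generated decoy graphs appended to every
#'   training set.
#' @param cfg,tcfg Model and training configurations.
#' @param seed Split seed.
#' @return List with `per_fold` (data.frame of metrics), `summary` (mean
#'   and sd per metric, aggregated over folds and over rounds) and `plan`.
#' @export
cross_validate <- function(graphs, labels, group_keys = NULL, k = 10,
                           rounds = 5, decoys = NULL, cfg = egnn_config(),
                           tcfg = train_config(), seed = 1) {
  plan <- make_splits(labels, group_keys, k = k, rounds = rounds, seed = seed)
  rows <- list()
  for (r in unique(plan$round)) {
    for (f in unique(plan$fold)) {
      pr <- plan[plan$round == r & plan$fold == f, ]
      res <- .fit_and_score(graphs, labels, pr, decoys, cfg, tcfg)
      rows[[length(rows) + 1]] <- data.frame(
        round = r, fold = f,
        auc = res$metrics$auc, accuracy = res$metrics$accuracy,
        precision = res$metrics$precision, recall = res$metrics$recall,
        f1 = res$metrics$f1, fp = res$metrics$fp, fn = res$metrics$fn)
    }
  }
  per_fold <- do.call(rbind, rows)
  mets <- c("auc", "accuracy", "precision", "recall", "f1")
  over_folds <- sapply(mets, function(m) {
    c(mean = mean(per_fold[[m]], na.rm = TRUE),
      sd = stats::sd(per_fold[[m]], na.rm = TRUE))
  })
  by_round <- stats::aggregate(per_fold[mets], by = list(round = per_fold$round),
                               mean, na.rm = TRUE)
  over_rounds <- sapply(mets, function(m) {
    c(mean = mean(by_round[[m]]), sd = stats::sd(by_round[[m]]))
  })
  list(per_fold = per_fold,
       summary = list(over_folds = over_folds, over_rounds = over_rounds),
       plan = plan)
}

#' Feature-group ablation
#'
#' Re-runs the identical cross-validation pipeline with one feature group
#' (residue physicochemical, edge, or surface features) removed end to end
#' from training and evaluation; the split plan and all seeds are shared
#' with the unablated run, so `group = "none"` reproduces the baseline.
#'
#' @param graphs,labels,group_keys,k,rounds,decoys,cfg,tcfg,seed As in
#'   [cross_validate()].
#' @param group Feature group to remove (`"residue_physchem"`,
#'   `"edge_features"`, `"surface_features"`, `"none"`).
#' @return As [cross_validate()], plus `removed_group`.
#' @export
run_ablation <- function(graphs, labels, group, group_keys = NULL, k = 10,
                         rounds = 5, decoys = NULL, cfg = egnn_config(),
                         tcfg = train_config(), seed = 1) {
  g2 <- ablate_feature_group(graphs, group)
  d2 <- if (is.null(decoys)) NULL else ablate_feature_group(decoys, group)
  res <- cross_validate(g2, labels, group_keys, k, rounds, d2, cfg, tcfg, seed)
  res$removed_group <- group
  res
}

#' Augmentation direction-of-effect experiment
#'
#' Quantifies the contribution of VAE-GAN decoy augmentation under class
#' imbalance: for each fold of a stratified group-aware k-fold plan, the
#' classifier is trained once without augmentation and once with decoys
#' generated by a VAE-GAN trained on the weak-binding graphs of that
#' training portion only (never on test data), then scored on the test
#' fold. Out-of-fold predictions are pooled over the plan (every complex
#' is scored exactly once while held out) and the AUC and false-positive
#' count of the pooled predictions are reported for both arms; per-fold
#' AUCs are returned as well but are noisy when test folds contain very
#' few weak binders.
#'
#' @param graphs,labels Dataset (typically imbalanced, e.g. 58 strong : 8
#'   weak).
#' @param k Folds.
#' @param n_decoys Decoys generated per fold (default: enough to balance).
#' @param gan_cfg,cfg,tcfg Generator / classifier configurations.
#' @param filter_percentile Latent-filter percentile applied to the
#'   generated decoys against the training strong binders (see
#'   [latent_filter()]); `NULL` disables filtering.
#' @param seed Split and generation seed.
#' @return List with `auc_noaug`, `auc_aug`, `fp_noaug`, `fp_aug`,
#'   `per_fold`.
#' @export
augmentation_experiment <- function(graphs, labels, k = 5, n_decoys = NULL,
                                    gan_cfg = gan_config(),
                                    cfg = egnn_config(),
                                    tcfg = train_config(),
                                    filter_percentile = 5, seed = 1) {
  if (is.null(n_decoys)) {
    n_decoys <- max(1, sum(labels == "strong") - sum(labels == "weak_exp"))
  }
  plan <- make_splits(labels, k = k, rounds = 1, seed = seed)
  rows <- list()
  for (f in unique(plan$fold)) {
    pr <- plan[plan$fold == f, ]
    base <- .fit_and_score(graphs, labels, pr, NULL, cfg, tcfg)
    tr <- pr$index[pr$assignment == "train"]
    weak_tr <- tr[labels[tr] == "weak_exp"]
    norm <- normalize_features(graphs[tr])
    weak_norm <- norm$train[match(weak_tr, tr)]
    gm <- train_gan(weak_norm, gan_cfg)
    decoys <- generate_decoys(gm, n_decoys, seed = seed * 100 + f)
    if (!is.null(filter_percentile)) {
      strong_norm <- norm$train[labels[tr] == "strong"]
      sz <- t(vapply(strong_norm, function(g) gan_encode(g, gm)$mu,
                     numeric(gm$cfg$latent_dim)))
      dz <- t(vapply(decoys, function(g) gan_encode(g, gm)$mu,
                     numeric(gm$cfg$latent_dim)))
      keep <- latent_filter(dz, sz, filter_percentile)$keep
      if (any(keep)) decoys <- decoys[keep]
    }
    aug <- .fit_and_score(graphs, labels, pr, decoys, cfg, tcfg)
    rows[[f]] <- data.frame(fold = f, index = base$test_index,
                            label = labels[base$test_index],
                            score_noaug = base$predictions$binding_score,
                            score_aug = aug$predictions$binding_score,
                            auc_noaug_fold = base$metrics$auc,
                            auc_aug_fold = aug$metrics$auc)
  }
  oof <- do.call(rbind, rows)
  m0 <- compute_metrics(oof$score_noaug, oof$label == "strong",
                        cfg$decision_threshold)
  m1 <- compute_metrics(oof$score_aug, oof$label == "strong",
                        cfg$decision_threshold)
  list(auc_noaug = m0$auc, auc_aug = m1$auc,
       fp_noaug = m0$fp, fp_aug = m1$fp,
       metrics_noaug = m0, metrics_aug = m1, per_fold = oof)
}

# ---- score-affinity mixture analysis ------------------------------------

# EM for a 2-component bivariate Gaussian mixture; each component encodes
# a linear score-affinity trend through its covariance
.gmm2_em <- function(X, restarts = 10, tol = 1e-6, max_iter = 200) {
  n <- nrow(X)
  best <- NULL
  for (rs in seq_len(restarts)) {
    ctr <- X[sample(n, 2), , drop = FALSE]
    mu <- list(ctr[1, ], ctr[2, ])
    Sg <- list(stats::cov(X) + diag(1e-6, 2), stats::cov(X) + diag(1e-6, 2))
    pi_k <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- sapply(1:2, function(k) {
        S <- Sg[[k]]
        di <- det(S)
        if (!is.finite(di) || di <= 1e-18) {  # degenerate: re-seed component
          Sg[[k]] <<- stats::cov(X) + diag(1e-4, 2)
          S <- Sg[[k]]; di <- det(S)
        }
        Si <- solve(S)
        dx <- sweep(X, 2, mu[[k]])
        q <- rowSums((dx %*% Si) * dx)
        pi_k[k] * exp(-0.5 * q) / (2 * pi * sqrt(di))
      })
      tot <- rowSums(dens) + 1e-300
      ll <- sum(log(tot))
      R <- dens / tot
      nk <- colSums(R)
      pi_k <- nk / n
      for (k in 1:2) {
        mu[[k]] <- colSums(R[, k] * X) / nk[k]
        dx <- sweep(X, 2, mu[[k]])
        Sg[[k]] <- crossprod(dx * sqrt(R[, k])) / nk[k] + diag(1e-9, 2)
      }
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, mu = mu, Sigma = Sg, pi = pi_k)
    }
  }
  best
}

.gmm2_predict <- function(fit, x) {
  comp <- lapply(1:2, function(k) {
    S <- fit$Sigma[[k]]; m <- fit$mu[[k]]
    slope <- S[1, 2] / S[1, 1]
    list(slope = slope, intercept = m[2] - slope * m[1],
         gate = fit$pi[k] * stats::dnorm(x, m[1], sqrt(S[1, 1])))
  })
  g1 <- comp[[1]]$gate; g2 <- comp[[2]]$gate
  w1 <- g1 / (g1 + g2 + 1e-300)
  yhat <- w1 * (comp[[1]]$intercept + comp[[1]]$slope * x) +
    (1 - w1) * (comp[[2]]$intercept + comp[[2]]$slope * x)
  list(yhat = yhat,
       slopes = c(comp[[1]]$slope, comp[[2]]$slope),
       intercepts = c(comp[[1]]$intercept, comp[[2]]$intercept))
}

#' Post-hoc score-affinity mixture analysis
#'
#' Relates predicted binding scores to measured affinities with a
#' two-component Gaussian mixture whose components each encode a linear
#' score-affinity trend, over repeated class-balanced subsampling. Per
#' round, an equal number of complexes per class is drawn, the mixture is
#' fit by EM (multiple restarts) on (score, affinity) pairs, and the R^2
#' of the mixture's gated prediction of affinity from score is recorded.
#'
#' @param scores Predicted binding scores.
#' @param affinities Measured affinities (e.g. Kd in uM); log10-transformed
#'   when `log10_affinity` is TRUE.
#' @param classes Class per observation (used for balanced subsampling).
#' @param n_rounds Subsampling rounds (default 500).
#' @param restarts,tol EM restarts and convergence tolerance.
#' @param log10_affinity Log-transform affinities first.
#' @param seed RNG seed.
#' @return List with `mean_r2`, `rounds` (data.frame: r2, slope1, slope2)
#'   and the last fit.
#' @export
score_affinity_gmm <- function(scores, affinities, classes = NULL,
                               n_rounds = 500, restarts = 10, tol = 1e-6,
                               log10_affinity = TRUE, seed = 1) {
  stopifnot(length(scores) == length(affinities))
  if (length(scores) < 10) stop("need at least 10 paired observations")
  y <- if (log10_affinity) log10(affinities) else affinities
  set.seed(seed)
  if (is.null(classes)) classes <- rep("all", length(scores))
  cls <- split(seq_along(scores), classes)
  nmin <- min(lengths(cls))
  rows <- list(); fit <- NULL
  for (r in seq_len(n_rounds)) {
    idx <- unlist(lapply(cls, function(ix) sample(ix, nmin)))
    X <- cbind(scores[idx], y[idx])
    fit <- .gmm2_em(X, restarts = restarts, tol = tol)
    pr <- .gmm2_predict(fit, X[, 1])
    sst <- sum((X[, 2] - mean(X[, 2]))^2)
    r2 <- if (sst > 0) 1 - sum((X[, 2] - pr$yhat)^2) / sst else NA_real_
    o <- order(pr$slopes)
    rows[[r]] <- data.frame(round = r, r2 = r2,
                            slope1 = pr$slopes[o[1]], slope2 = pr$slopes[o[2]],
                            intercept1 = pr$intercepts[o[1]],
                            intercept2 = pr$intercepts[o[2]])
  }
  rounds <- do.call(rbind, rows)
  list(mean_r2 = mean(rounds$r2, na.rm = TRUE), rounds = rounds, fit = fit)
}
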