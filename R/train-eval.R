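#' Stratified train/test split with cross-validation folds
#'
#' Deterministically (given the seed) holds out `test_frac` of each class,
#' then partitions the remaining patients into `n_folds` stratified folds:
#' within every class, shuffled patients are dealt round-robin, so per-fold
#' class proportions match the overall ones within one patient.
#'
#' @param labels named 0/1 vector (patient id to class).
#' @param seed integer.
#' @param test_frac held-out fraction (default 0.2).
#' @param n_folds number of folds (default 5).
#' @return A `split_plan`: `train_ids`, `test_ids`, `folds` (named fold
#'   index per train patient), `seed`.
#' @export
make_splits <- function(labels, seed = 1L, test_frac = 0.2, n_folds = 5L) {
  stopifnot(!is.null(names(labels)), all(labels %in% c(0L, 1L)))
  classes <- split(names(labels), labels)
  if (any(vapply(classes, length, integer(1)) < 10L)) {
    stop("need at least 10 patients per class")
  }
  test_ids <- character(0)
  train_ids <- character(0)
  with_seed(seed_mix(seed, 49979687), {
    for (cl in classes) {
      cl <- sample(cl)
      n_test <- round(test_frac * length(cl))
      test_ids <- c(test_ids, cl[seq_len(n_test)])
      train_ids <- c(train_ids, cl[-seq_len(n_test)])
    }
    train_by_class <- split(train_ids, labels[train_ids])
    if (any(vapply(train_by_class, length, integer(1)) < n_folds)) {
      stop("a class has fewer training patients than folds")
    }
    folds <- integer(0)
    offset <- 0L
    for (cl in train_by_class) {
      cl <- sample(cl)
      ids <- ((offset + seq_along(cl) - 1L) %% n_folds) + 1L
      folds <- c(folds, stats::setNames(ids, cl))
      offset <- offset + length(cl)
    }
  })
  structure(list(train_ids = sort(train_ids), test_ids = sort(test_ids),
                 folds = folds[sort(names(folds))], n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Jointly train backbone, encoders, fusion and classifier
#'
#' Cross-entropy on one bag per step (batch size one patient). Gradients
#' reach every learnable parameter including the backbone, unless
#' `freeze_backbone` is set, in which case patch features are computed once
#' and cached. Deterministic under the seed (seeded initialization order,
#' seeded epoch shuffling, deterministic kernels).
#'
#' @param model a [mil_model()].
#' @param backbone a [build_backbone()] network with
#'   `feature_dim == model$config$feature_dim`.
#' @param bags named list of `patch_bag`s.
#' @param gene_latents named list of `gene_latent`s (same patients).
#' @param labels named 0/1 vector.
#' @param patient_ids patients to train on (default: all bag names).
#' @param epochs,lr optimization settings.
#' @param weight_decay decoupled weight decay on weight matrices/kernels;
#'   regularizes against memorizing patients through high-dimensional
#'   instance features.
#' @param seed integer.
#' @param freeze_backbone keep backbone parameters fixed.
#' @return List with the trained `model`/`backbone` (updated in place via
#'   their parameter environments), `loss_trace` (per-epoch mean loss) and
#'   `first_step_backbone_grad_norm`.
#' @export
train_model <- function(model, backbone, bags, gene_latents, labels,
                        patient_ids = names(bags), epochs = 10L, lr = 1e-3,
                        weight_decay = 1e-2, seed = 1L,
                        freeze_backbone = FALSE) {
  missing_bag <- setdiff(patient_ids, names(bags))
  missing_gene <- setdiff(patient_ids, names(gene_latents))
  if (length(missing_bag) || length(missing_gene)) {
    stop(sprintf("patients missing a modality: %s",
                 paste(unique(c(missing_bag, missing_gene)), collapse = ", ")))
  }
  arrays <- lapply(patient_ids, function(p) bag_to_array(bags[[p]]))
  names(arrays) <- patient_ids
  feat_cache <- NULL
  bb_params <- collect_params(backbone$params)
  model_params <- collect_params(model$params)
  if (freeze_backbone) {
    feat_cache <- lapply(arrays, function(a) {
      backbone_forward(backbone, ag_const(a))$value
    })
    params <- model_params
  } else {
    params <- c(bb_params, model_params)
  }
  opt <- adam_new(params, lr = lr, weight_decay = weight_decay)
  trace <- numeric(epochs)
  first_bb_grad <- NA_real_
  step <- 0L
  for (ep in seq_len(epochs)) {
    order_ids <- with_seed(seed_mix(seed, 86028121, ep),
                           sample(patient_ids))
    ep_loss <- 0
    for (p in order_ids) {
      step <- step + 1L
      ag_zero_grad(params)
      feats <- if (freeze_backbone) {
        ag_const(feat_cache[[p]])
      } else {
        backbone_forward(backbone, ag_const(arrays[[p]]))
      }
      out <- mil_forward(model, feats, gene_latents[[p]]$features)
      loss <- ag_ce_logits(out$logits, labels[[p]] + 1L)
      ag_backward(loss)
      if (step == 1L && !freeze_backbone) {
        sq <- vapply(bb_params, function(pp) {
          if (is.null(pp$grad)) 0 else sum(pp$grad^2)
        }, numeric(1))
        first_bb_grad <- sqrt(sum(sq))
      }
      adam_step(opt)
      ep_loss <- ep_loss + loss$value
    }
    trace[ep] <- ep_loss / length(order_ids)
  }
  list(model = model, backbone = backbone, loss_trace = trace,
       first_step_backbone_grad_norm = first_bb_grad)
}

#' Predict class-1 probabilities for a set of patients
#'
#' @param model,backbone trained networks.
#' @param bags,gene_latents named lists.
#' @param patient_ids patients to score.
#' @return data.frame with `patient_id`, `prob1`, `pred`.
#' @export
predict_model <- function(model, backbone, bags, gene_latents,
                          patient_ids = names(bags)) {
  rows <- lapply(patient_ids, function(p) {
    feats <- backbone_forward(backbone,
                              ag_const(bag_to_array(bags[[p]])))$value
    out <- forward_patient(model, feats, gene_latents[[p]]$features)
    z <- out$logits
    pr <- exp(z - max(z))
    pr <- pr / sum(pr)
    data.frame(patient_id = p, prob1 = pr[2], pred = which.max(z) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Threshold-based classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1
#' `2TP/(2TP+FP+FN)` with a declared positive class.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @param positive the positive class label (default 1).
#' @return Named list `sensitivity`, `specificity`, `f1`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = 1L) {
  stopifnot(length(y_true) == length(y_pred))
  pos <- y_true == positive
  if (!any(pos)) stop("no positive-class patients in y_true")
  tp <- sum(pos & y_pred == positive)
  fn <- sum(pos & y_pred != positive)
  tn <- sum(!pos & y_pred != positive)
  fp <- sum(!pos & y_pred == positive)
  list(sensitivity = tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

#' Threshold-free ranking metrics
#'
#' ROC-AUC is the fraction of concordant positive/negative score pairs
#' (ties counted 1/2), computed via the rank formula. PR-AUC integrates
#' the monotone-interpolated precision over recall (precision made
#' non-increasing from the high-recall end before summation).
#'
#' @param y_true 0/1 vector with both classes present.
#' @param scores real-valued scores (higher = more class 1).
#' @param positive positive class label.
#' @return Named list `pr_auc`, `roc_auc`.
#' @export
auc_metrics <- function(y_true, scores, positive = 1L) {
  stopifnot(length(y_true) == length(scores))
  pos <- y_true == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  roc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # PR curve at distinct thresholds, descending
  ord <- order(-scores)
  y <- pos[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(diff(s) != 0, TRUE)  # last index within each tied block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  prec <- rev(cummax(rev(prec)))  # monotone interpolation
  pr <- sum(diff(c(0, rec)) * prec)
  list(pr_auc = pr, roc_auc = roc)
}

#' All five reported metrics from labels, scores and a threshold
#'
#' @param y_true 0/1 vector.
#' @param scores class-1 probabilities.
#' @param threshold decision threshold on the score (default 0.5, the
#'   argmax class of a two-way softmax).
#' @param positive positive class.
#' @return Named list with sensitivity, specificity, f1, pr_auc, roc_auc.
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5,
                                 positive = 1L) {
  pred <- as.integer(scores > threshold)
  if (positive == 0L) pred <- 1L - pred
  cm <- confusion_metrics(y_true, pred, positive)
  au <- auc_metrics(y_true, scores, positive)
  c(cm, au)
}

#' Paired t-test on fold-level metric values
#'
#' Two-sided paired t with `n - 1` degrees of freedom. Zero-variance
#' differences raise an error rather than returning NaN.
#'
#' @param fold_values_a,fold_values_b equal-length numeric vectors
#'   (length >= 2).
#' @return List with `t` and `p`.
#' @export
paired_t <- function(fold_values_a, fold_values_b) {
  stopifnot(length(fold_values_a) == length(fold_values_b),
            length(fold_values_a) >= 2)
  d <- fold_values_a - fold_values_b
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t statistic undefined")
  }
  ht <- stats::t.test(fold_values_a, fold_values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Mean and standard deviation across folds
#'
#' @param fold_values list or matrix of per-fold metric vectors.
#' @return data.frame with metric, mean, sd.
#' @export
fold_summary <- function(fold_values) {
  m <- as.matrix(as.data.frame(fold_values))
  data.frame(metric = rownames(m) %||% paste0("m", seq_len(nrow(m))),
             mean = rowMeans(m), sd = apply(m, 1L, stats::sd),
             row.names = NULL)
}
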