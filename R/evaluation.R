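# Evaluation protocol: balanced undersampling, five-fold cross-validation
# with leakage-safe per-fold recomputation of the disease-correlation
# similarity, per-drug ROC/PR AUC and top-k recall.

#' Balanced undersampling fold plan
#'
#' Splits the pair universe into subset A — every known association plus an
#' equal number of unknown pairs sampled uniformly without replacement — and
#' subset B, the remaining unknown pairs. Subset A's positives and negatives
#' are each dealt round-robin into `n_folds` near-equal folds, so every fold
#' is itself balanced.
#'
#' @param A an [association_matrix()].
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed; identical seeds give identical plans.
#' @return a `fold_plan`: list with `subset_A` (data frame: drug, disease,
#'   label, fold), `subset_B` (data frame of unknown pairs: drug, disease),
#'   `n_unknown` (total count of unknown pairs), `dims`, `n_folds`, `seed`.
#' @export
make_fold_plan <- function(A, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  Av <- unclass(A)
  pos <- which(Av == 1)
  neg <- which(Av == 0)
  n_pos <- length(pos)
  if (n_pos < n_folds) stop("need at least ", n_folds, " known associations")
  if (n_pos > length(neg))
    stop("more known associations than unknown pairs; undersampling impossible")
  with_seed(seed, {
    neg_sample <- sort(sample(neg, n_pos))
    fold_pos <- integer(n_pos); fold_neg <- integer(n_pos)
    fold_pos[sample.int(n_pos)] <- rep_len(seq_len(n_folds), n_pos)
    fold_neg[sample.int(n_pos)] <- rep_len(seq_len(n_folds), n_pos)
    idx2pair <- function(idx) arrayInd(idx, dim(Av))
    subset_A <- rbind(
      data.frame(idx2pair(pos), label = 1L, fold = fold_pos),
      data.frame(idx2pair(neg_sample), label = 0L, fold = fold_neg))
    names(subset_A)[1:2] <- c("drug", "disease")
    rest <- setdiff(neg, neg_sample)
    subset_B <- data.frame(idx2pair(rest))
    names(subset_B) <- c("drug", "disease")
    structure(list(subset_A = subset_A, subset_B = subset_B,
                   n_unknown = length(neg), dims = dim(Av),
                   n_folds = n_folds, seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' The area under the TPR-vs-FPR curve swept over all score thresholds equals
#' the probability that a random positive outscores a random negative, with
#' ties credited 1/2.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in \[0, 1\], or `NA_real_` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC by interpolation-free step integration
#'
#' Sweeps thresholds over the distinct score values in descending order; each
#' increase in recall contributes a rectangle with the precision at that
#' threshold. Ties are handled by moving the threshold across whole groups of
#' equal scores.
#'
#' @inheritParams roc_auc
#' @return PR AUC in \[0, 1\], or `NA_real_` with no positives.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) return(NA_real_)
  grp <- split(labels, -scores)          # groups ordered by decreasing score
  tp <- cumsum(vapply(grp, sum, 0L))
  n_at <- cumsum(lengths(grp))
  prec <- tp / n_at
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Average recall in the top k ranked candidates per drug
#'
#' For each drug with at least one positive among its scored candidates, the
#' fraction of its positives ranked within its k highest scores; averaged
#' over those drugs. Within a drug, ranking is by score descending.
#'
#' @param scored data frame with columns `drug`, `score`, `label`.
#' @param k positive integer cutoff (vectorised).
#' @return numeric vector of mean recalls, one per k.
#' @export
recall_at_k <- function(scored, k) {
  if (any(k <= 0)) stop("k must be positive")
  per_drug <- split(scored[c("score", "label")], scored$drug)
  per_drug <- Filter(function(d) sum(d$label == 1L) > 0, per_drug)
  if (!length(per_drug)) return(rep(NA_real_, length(k)))
  vapply(k, function(kk) {
    mean(vapply(per_drug, function(d) {
      top <- utils::head(order(d$score, decreasing = TRUE), kk)
      sum(d$label[top] == 1L) / sum(d$label == 1L)
    }, 0))
  }, 0)
}

#' Rank a drug's candidate diseases by predicted score
#'
#' Scores every disease whose association with the drug is unknown (known
#' positives are excluded from the candidate list), sorts by fused score
#' descending with ties broken by disease identifier, and returns the top-n
#' table.
#'
#' @param model a trained [train_dualcnn()] model (or a `scorer` function
#'   taking a pairs matrix and returning scores, for testing).
#' @param drug_id drug identifier present in the bundle.
#' @param bundle an [align_dataset()]-style bundle with `R` (list of four
#'   drug similarity matrices) added, or explicit `R`, `A`, `D` components.
#' @param n number of top candidates to keep (`Inf` for all).
#' @return a [score_table()] sorted by decreasing score.
#' @export
rank_candidates <- function(model, drug_id, bundle, n = 30L) {
  A <- bundle$A; D <- bundle$D; R <- bundle$R
  i <- match(drug_id, rownames(A))
  if (is.na(i)) stop("unknown drug identifier: ", drug_id)
  cand <- which(unclass(A)[i, ] == 0)
  pairs <- cbind(i, cand)
  scores <- if (is.function(model)) model(pairs)
            else predict_pairs(model, pairs, R, A, D)
  ids <- colnames(A)[cand]
  ord <- order(-scores, ids)
  keep <- utils::head(ord, n)
  score_table(rep(drug_id, length(keep)), ids[keep], scores[keep], NA)
}

# Fold context handed to an injected scorer: the masked association matrix,
# the per-fold similarity list and the fold number.
fold_context <- function(fold, A_masked, R, D) {
  list(fold = fold, A_masked = A_masked, R = R, D = D)
}

#' Run the cross-validation protocol
#'
#' Per fold: the fold's test positives are masked out of the association
#' matrix; the disease-correlation similarity is recomputed from the masked
#' copy; the model is trained on the other folds of subset A (embeddings also
#' read the masked matrix, so no test label leaks into its own input); and
#' the fold's subset-A part plus all of subset B are scored. Metrics are
#' macro-averaged per-drug ROC/PR AUC (pooled variants reported as
#' secondary), and mean top-k recall.
#'
#' @param bundle list with `features` (three feature tables), `D`, `A`
#'   (e.g. [align_dataset()] output or [generate_synthetic()]'s bundle).
#' @param config a [model_config()]; the per-fold training seed is derived
#'   from `config$seed` and the fold number.
#' @param plan a [make_fold_plan()] plan for `bundle$A`.
#' @param scorer optional function(pairs, context) -> scores replacing the
#'   trained model (used to validate the harness with oracle scorers).
#' @param ks top-k cutoffs for the recall table.
#' @param score_subset_B whether each fold also scores all of subset B
#'   (the full protocol); disable for quick harness checks.
#' @param verbose print per-fold progress.
#' @return an `evaluation_report` list: `macro_roc_auc`, `macro_pr_auc`,
#'   `pooled_roc_auc`, `pooled_pr_auc`, `recall_at_k`, `per_drug` (per-fold
#'   per-drug AUC table), `folds` (per-fold diagnostics), `scores` (all
#'   scored test pairs).
#' @export
run_cross_validation <- function(bundle, config, plan, scorer = NULL,
                                 ks = seq(30L, 240L, by = 30L),
                                 score_subset_B = TRUE, verbose = FALSE) {
  A <- bundle$A; D <- bundle$D
  R123 <- lapply(bundle$features, cosine_similarity)
  sa <- plan$subset_A
  all_scored <- list()
  fold_info <- list()
  for (f in seq_len(plan$n_folds)) {
    test <- sa[sa$fold == f, ]
    train <- sa[sa$fold != f, ]
    A_masked <- mask_associations(A, test[test$label == 1L, c("drug", "disease")])
    R <- c(R123, list(disease_correlation_similarity(A_masked, D)))
    eval_pairs <- test[c("drug", "disease")]
    eval_labels <- test$label
    if (score_subset_B && nrow(plan$subset_B)) {
      eval_pairs <- rbind(eval_pairs, plan$subset_B)
      eval_labels <- c(eval_labels, rep(0L, nrow(plan$subset_B)))
    }
    if (is.function(scorer)) {
      scores <- scorer(as.matrix(eval_pairs),
                       fold_context(f, A_masked, R, D))
      final_loss <- NA_real_
    } else {
      cfg <- config
      cfg$seed <- config$seed + f
      emb <- build_embedding_batch(train[c("drug", "disease")], R, A_masked, D,
                                   right_block = cfg$neighbor_right_block)
      model <- train_dualcnn(emb, train$label, cfg)
      final_loss <- utils::tail(model$loss_history, 1)
      scores <- predict_pairs(model, eval_pairs, R, A_masked, D)
    }
    all_scored[[f]] <- data.frame(fold = f, drug = eval_pairs$drug,
                                  disease = eval_pairs$disease,
                                  label = eval_labels, score = scores)
    fold_info[[f]] <- data.frame(fold = f, n_train = nrow(train),
                                 n_test = length(eval_labels),
                                 n_test_pos = sum(eval_labels == 1L),
                                 final_loss = final_loss)
    if (verbose) message("fold ", f, " done (",
                         sum(eval_labels == 1L), " test positives)")
  }
  scored <- do.call(rbind, all_scored)
  per_drug <- do.call(rbind, lapply(split(scored, scored[c("drug", "fold")],
                                          drop = TRUE), function(d) {
    data.frame(drug = d$drug[1], fold = d$fold[1],
               n_pos = sum(d$label == 1L),
               roc_auc = roc_auc(d$score, d$label),
               pr_auc = pr_auc(d$score, d$label))
  }))
  evaluated <- per_drug[per_drug$n_pos > 0 & !is.na(per_drug$roc_auc), ]
  # a drug's candidate list is per fold (subset B is rescored each fold), so
  # recall is computed per (drug, fold) group and averaged
  by_fold <- scored
  by_fold$drug <- paste(scored$drug, scored$fold, sep = "/")
  rec <- recall_at_k(by_fold, ks)
  structure(list(
    macro_roc_auc = mean(evaluated$roc_auc),
    macro_pr_auc = mean(evaluated$pr_auc, na.rm = TRUE),
    pooled_roc_auc = roc_auc(scored$score, scored$label),
    pooled_pr_auc = pr_auc(scored$score, scored$label),
    recall_at_k = data.frame(k = ks, recall = rec),
    n_drugs_evaluated = length(unique(evaluated$drug)),
    n_drug_folds_skipped = nrow(per_drug) - nrow(evaluated),
    averaging = "per-drug macro (pooled reported as secondary)",
    per_drug = per_drug,
    folds = do.call(rbind, fold_info),
    scores = scored), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("cross-validation report\n",
      "  macro ROC AUC :", round(x$macro_roc_auc, 4), "\n",
      "  macro PR AUC  :", round(x$macro_pr_auc, 4), "\n",
      "  pooled ROC AUC:", round(x$pooled_roc_auc, 4), "(secondary)\n",
      "  pooled PR AUC :", round(x$pooled_pr_auc, 4), "(secondary)\n",
      "  drugs evaluated:", x$n_drugs_evaluated,
      "| drug-folds skipped:", x$n_drug_folds_skipped, "\n")
  print(x$recall_at_k, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report summary to a tab-delimited file
#'
#' @param report an `evaluation_report`.
#' @param path destination file (metric, k, value rows).
#' @export
write_report <- function(report, path) {
  rows <- rbind(
    data.frame(metric = c("macro_roc_auc", "macro_pr_auc",
                          "pooled_roc_auc", "pooled_pr_auc"),
               k = NA_integer_,
               value = c(report$macro_roc_auc, report$macro_pr_auc,
                         report$pooled_roc_auc, report$pooled_pr_auc)),
    data.frame(metric = "recall_at_k", k = report$recall_at_k$k,
               value = report$recall_at_k$recall))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
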