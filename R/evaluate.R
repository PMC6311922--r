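#' Pooled ROC curve and AUC from local rankings
#'
#' Each test association contributes its rank `r` (average rank under
#' ties) within a candidate pool of size `n` — the held-out miRNA plus the
#' `n - 1` candidate miRNAs of the same disease. The decision statistic is
#' the normalized rank `(r - 1) / (n - 1)`; pooling over test samples,
#' `TPR(t)` is the fraction of test samples at or above percentile
#' threshold `t` while `FPR(t) = t` (candidates fill each pool uniformly).
#' The trapezoidal area under the resulting curve equals the mean
#' per-sample percentile `(n - r) / (n - 1)`, which for a single pool is
#' exactly the Wilcoxon-Mann-Whitney statistic of the positive against
#' its negatives.
#'
#' @param ranks numeric vector of test-sample ranks (1 = best; average
#'   rank under ties, so possibly non-integer).
#' @param pool_sizes integer vector of candidate-pool sizes (>= 2).
#' @param skipped count of test samples excluded upstream (carried in the
#'   result for reporting).
#' @return object of class `fmsm_roc`: `fpr`, `tpr`, `auc`, `n_test`,
#'   `skipped`, plus the input `ranks` and `pool_sizes`.
#' @export
roc_auc <- function(ranks, pool_sizes, skipped = 0L) {
  if (length(ranks) == 0) stop("no test samples")
  if (length(pool_sizes) != length(ranks)) stop("ranks/pool_sizes length mismatch")
  if (any(pool_sizes < 2)) stop("candidate pools must contain at least 2 miRNAs")
  if (any(ranks < 1 | ranks > pool_sizes)) stop("ranks must lie in [1, pool size]")
  u <- (ranks - 1) / (pool_sizes - 1)
  v <- sort(unique(u))
  cum <- cumsum(tabulate(match(sort(u), v), length(v))) / length(u)
  fpr <- c(0, rep(v, each = 2), 1)
  tpr <- c(0, as.vector(rbind(c(0, cum[-length(cum)]), cum)), 1)
  structure(list(fpr = fpr, tpr = tpr, auc = mean(1 - u),
                 n_test = length(u), skipped = as.integer(skipped),
                 ranks = ranks, pool_sizes = pool_sizes),
            class = "fmsm_roc")
}

#' @export
print.fmsm_roc <- function(x, ...) {
  cat(sprintf("local ROC: AUC = %.4f over %d test samples (%d skipped)\n",
              x$auc, x$n_test, x$skipped))
  invisible(x)
}

#' @export
plot.fmsm_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

# rank of the held-out score against the negative candidates (average ties)
.rank_against <- function(pos_score, neg_scores) {
  1 + sum(neg_scores > pos_score) + 0.5 * sum(neg_scores == pos_score)
}

# Core cross-validation engine. `folds` is a list of held-out row indices
# into dataset$pairs. For each fold the model sees only the training
# pairs: the training matrix, both GIP kernels and the integrated
# similarities are rebuilt from them, so held-out associations never leak
# into kernels, similarity integration or the training set. Candidate
# pools come from the full known-association *pair set* (a held-out
# association is ranked against the miRNAs with no known association to
# its disease).
eval_folds <- function(dataset, expression, mesh, control, mode,
                       folds, base_seed) {
  nd <- length(dataset$diseases)
  nm <- length(dataset$mirnas)
  known <- matrix(FALSE, nd, nm)
  known[dataset$pairs] <- TRUE
  ES <- if (!is.null(expression))
    expression_similarity(expression, dataset$mirnas, control$es_negative)
  else similarity_matrix(matrix(0, nm, nm), dataset$mirnas,
                         covered = rep(FALSE, nm), check = FALSE)
  SS <- if (!is.null(mesh))
    disease_semantic_similarity(mesh, dataset$diseases, control$delta)
  else similarity_matrix(matrix(0, nd, nd), dataset$diseases,
                         covered = rep(FALSE, nd), check = FALSE)
  all_rows <- seq_len(nrow(dataset$pairs))
  ranks <- numeric(0)
  pools <- integer(0)
  skipped <- 0L
  for (fold in folds) {
    train_ds <- subset_pairs(dataset, setdiff(all_rows, fold))
    if (nrow(train_ds$pairs) == 0) { skipped <- skipped + length(fold); next }
    KD <- gip_kernel(train_ds, "disease", control$gamma_prime_d)
    KM <- gip_kernel(train_ds, "mirna", control$gamma_prime_m)
    S_m <- switch(mode,
      none = identity_similarity(dataset$mirnas),
      expression_only = {
        S <- ES$S; diag(S) <- 1
        similarity_matrix(S, dataset$mirnas)
      },
      full = integrate_mirna_similarity(ES, KM))
    S_d <- integrate_disease_similarity(SS, KD)
    seed_f <- derive_seed(base_seed, min(fold))
    pars <- fmsm_train(train_ds, S_m$S, control, seed = seed_f)
    model <- c(pars, list(alpha = control$alpha, control = control))
    scores <- aggregate_scores(model, train_ds, S_d, S_m, control)
    n_train_d <- rowSums(train_ds$U)
    for (row in fold) {
      d <- dataset$pairs[row, 1]
      m <- dataset$pairs[row, 2]
      if (n_train_d[d] == 0) { skipped <- skipped + 1L; next }
      neg <- which(!known[d, ])
      if (length(neg) == 0) { skipped <- skipped + 1L; next }
      ranks <- c(ranks, .rank_against(scores[d, m], scores[d, neg]))
      pools <- c(pools, length(neg) + 1L)
    }
  }
  list(ranks = ranks, pool_sizes = pools, skipped = skipped)
}

.resolve_inputs <- function(associations, expression, mesh) {
  if (is.character(associations)) associations <- read_associations(associations)
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(mesh)) mesh <- read_mesh(mesh)
  stopifnot(inherits(associations, "association_dataset"))
  list(associations = associations, expression = expression, mesh = mesh)
}

.mode_arg <- function(similarity_mode) {
  similarity_mode <- match.arg(similarity_mode,
                               c("full", "expression_plus_gip",
                                 "expression_only", "none"))
  if (similarity_mode == "expression_plus_gip") "full" else similarity_mode
}

.base_seed <- function(control) {
  if (!is.null(control$seed)) as.integer(control$seed)
  else sample.int(2147483646L, 1)
}

#' Local leave-one-out cross-validation
#'
#' Each known association is held out in turn; the GIP kernels and the
#' integrated similarities are recomputed on the reduced association
#' matrix, the model is retrained, and the held-out miRNA is ranked
#' against the miRNAs with no known association to the same disease (the
#' local scoring scheme). Diseases whose only association was held out are
#' skipped and counted — the model cannot score a disease with no known
#' associated miRNA.
#'
#' @param associations an [association_dataset()] or TSV path.
#' @param expression optional [expression_profiles()] or TSV path.
#' @param mesh optional [mesh_forest()] or TSV path.
#' @param control a [fmsm_control()]; `control$seed` fixes the whole
#'   procedure.
#' @param similarity_mode miRNA-similarity mode (see [fmsm()]); the
#'   ablation alias `"expression_plus_gip"` is accepted for `"full"`.
#' @return an [roc_auc()] result (`fmsm_roc`) pooled over all test
#'   samples.
#' @export
local_loocv <- function(associations, expression = NULL, mesh = NULL,
                        control = fmsm_control(),
                        similarity_mode = "full") {
  inp <- .resolve_inputs(associations, expression, mesh)
  mode <- .mode_arg(similarity_mode)
  dataset <- inp$associations
  if (nrow(dataset$pairs) < 2) stop("LOOCV needs at least 2 known associations")
  res <- eval_folds(dataset, inp$expression, inp$mesh, control, mode,
                    folds = as.list(seq_len(nrow(dataset$pairs))),
                    base_seed = .base_seed(control))
  if (length(res$ranks) == 0) stop("all test samples were skipped")
  roc_auc(res$ranks, res$pool_sizes, res$skipped)
}

#' Repeated k-fold cross-validation
#'
#' The known associations are shuffled and split into `k` disjoint folds;
#' each fold is held out in turn with per-fold kernel recomputation and
#' retraining, and all held-out rankings of a repeat are pooled into one
#' AUC. The report gives the mean and standard deviation over repeats.
#' With `k = |R|` and `repeats = 1` this reduces exactly to
#' [local_loocv()] under the same seed.
#'
#' @inheritParams local_loocv
#' @param k number of folds (>= 2).
#' @param repeats number of independent shuffles.
#' @return object of class `fmsm_cv`: `auc_per_repeat`, `mean_auc`,
#'   `sd_auc`, `k`, `repeats`, `seed`, `skipped`.
#' @export
kfold_cv <- function(associations, expression = NULL, mesh = NULL,
                     control = fmsm_control(), k = 5, repeats = 20,
                     similarity_mode = "full") {
  if (k < 2) stop("k must be at least 2")
  inp <- .resolve_inputs(associations, expression, mesh)
  mode <- .mode_arg(similarity_mode)
  dataset <- inp$associations
  n_pairs <- nrow(dataset$pairs)
  if (n_pairs < k) stop("fewer associations than folds")
  base_seed <- .base_seed(control)
  aucs <- numeric(repeats)
  skipped <- 0L
  for (r in seq_len(repeats)) {
    assign_f <- with_seed(derive_seed(base_seed, 1000000 + r),
                          sample(rep(seq_len(k), length.out = n_pairs)))
    folds <- split(seq_len(n_pairs), assign_f)
    res <- eval_folds(dataset, inp$expression, inp$mesh, control, mode,
                      folds, base_seed)
    if (length(res$ranks) == 0) stop("all test samples were skipped")
    aucs[r] <- roc_auc(res$ranks, res$pool_sizes)$auc
    skipped <- skipped + res$skipped
  }
  structure(list(auc_per_repeat = aucs, mean_auc = mean(aucs),
                 sd_auc = if (repeats > 1) sd(aucs) else NA_real_,
                 k = k, repeats = repeats, seed = base_seed,
                 skipped = skipped),
            class = "fmsm_cv")
}

#' @export
print.fmsm_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV, %d repeat(s): mean AUC = %.4f", x$k, x$repeats,
              x$mean_auc))
  if (!is.na(x$sd_auc)) cat(sprintf(" +/- %.4f", x$sd_auc))
  cat(sprintf(" (%d skipped test samples)\n", x$skipped))
  invisible(x)
}

#' Similarity-ablation experiment
#'
#' Evaluates the contribution of the miRNA similarity sources by running
#' the identical cross-validation with (i) no extra miRNA similarity
#' (identity matrix), (ii) expression similarity only, and (iii)
#' expression similarity integrated with the miRNA GIP kernel. The
#' disease-side inputs are kept consistent across modes.
#'
#' @inheritParams kfold_cv
#' @param method `"kfold"` or `"loocv"`.
#' @return list with `reports` (per-mode `fmsm_cv`/`fmsm_roc` objects) and
#'   `summary` (data.frame of mode and AUC).
#' @export
ablation_experiment <- function(associations, expression = NULL, mesh = NULL,
                                control = fmsm_control(),
                                method = c("kfold", "loocv"),
                                k = 5, repeats = 2) {
  method <- match.arg(method)
  inp <- .resolve_inputs(associations, expression, mesh)
  modes <- c("none", "expression_only", "expression_plus_gip")
  reports <- lapply(modes, function(md) {
    if (method == "kfold")
      kfold_cv(inp$associations, inp$expression, inp$mesh, control,
               k = k, repeats = repeats, similarity_mode = md)
    else
      local_loocv(inp$associations, inp$expression, inp$mesh, control,
                  similarity_mode = md)
  })
  names(reports) <- modes
  auc <- vapply(reports, function(r)
    if (inherits(r, "fmsm_cv")) r$mean_auc else r$auc, 0)
  list(reports = reports,
       summary = data.frame(mode = modes, auc = unname(auc)))
}
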