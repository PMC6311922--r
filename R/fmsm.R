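#' Hyperparameter control for the factored miRNA similarity model
#'
#' Defaults follow the model's published setting: regularization weights
#' `beta = lambda = gamma = 0.1`, learning rate `eta = 0.01`, `epochs =
#' 100`, negative-sample factor `rho = 3`, similarity aggregation weights
#' `w_d = w_m = 1`, semantic decay `delta = 0.5`, GIP bandwidth numerators
#' `gamma_prime_d = gamma_prime_m = 1`. The disease-specific exponent
#' `alpha` (normalizer of the factored sum) defaults to 0.5; `latent_dim`
#' defaults to the number of miRNAs (`NULL`), in which case the factor
#' matrices are initialized directly from the integrated miRNA similarity.
#'
#' @param latent_dim latent dimension `d` of the factor matrices `P`, `Q`
#'   (`NULL` = number of miRNAs).
#' @param alpha normalizing exponent in `[0, 1]`.
#' @param beta,lambda,gamma regularization weights for the factors, the
#'   disease biases and the miRNA biases.
#' @param eta SGD learning rate.
#' @param epochs number of SGD passes (`T`).
#' @param rho negative-sample factor: `rho * |R|` unknown pairs are drawn
#'   per epoch.
#' @param w_d,w_m weights of the disease- and miRNA-similarity
#'   neighbourhood terms in the final score.
#' @param delta MeSH semantic contribution decay in (0, 1).
#' @param gamma_prime_d,gamma_prime_m GIP kernel bandwidth numerators.
#' @param es_negative policy for negative Pearson correlations
#'   (`"clip"` or `"affine"`).
#' @param seed optional integer seed; when set, sampling and shuffling are
#'   reproducible and the caller's RNG state is left untouched.
#' @param trace log the objective every `trace` epochs (0 = silent).
#' @return a list of class `fmsm_control`.
#' @export
fmsm_control <- function(latent_dim = NULL, alpha = 0.5,
                         beta = 0.1, lambda = 0.1, gamma = 0.1,
                         eta = 0.01, epochs = 100, rho = 3,
                         w_d = 1, w_m = 1, delta = 0.5,
                         gamma_prime_d = 1, gamma_prime_m = 1,
                         es_negative = c("clip", "affine"),
                         seed = NULL, trace = 0) {
  es_negative <- match.arg(es_negative)
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, lambda >= 0, gamma >= 0,
            eta >= 0, epochs >= 0, rho >= 0, w_d >= 0, w_m >= 0,
            delta > 0, delta < 1, gamma_prime_d > 0, gamma_prime_m > 0,
            is.null(latent_dim) || latent_dim >= 1)
  structure(list(latent_dim = latent_dim, alpha = alpha, beta = beta,
                 lambda = lambda, gamma = gamma, eta = eta,
                 epochs = as.integer(epochs), rho = rho, w_d = w_d,
                 w_m = w_m, delta = delta, gamma_prime_d = gamma_prime_d,
                 gamma_prime_m = gamma_prime_m, es_negative = es_negative,
                 seed = seed, trace = trace),
            class = "fmsm_control")
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-fold seed stream; kept below 2^31 - 1
derive_seed <- function(base, i) as.integer((as.numeric(base) + 7919 * i) %% 2147483647)

# per-disease training miRNA index sets R_d+ (1-based)
pos_sets_of <- function(dataset) {
  nd <- length(dataset$diseases)
  out <- split(dataset$pairs[, 2],
               factor(dataset$pairs[, 1], levels = seq_len(nd)))
  lapply(out, as.integer)
}

# initial factor matrices: P = Q = S_m when latent_dim = nm, otherwise the
# symmetric rank-d factor from the truncated eigendecomposition of S_m
# (negative eigenvalues clipped at 0)
init_factors <- function(S_m, latent_dim) {
  nm <- nrow(S_m)
  if (latent_dim > nm) stop("latent_dim exceeds the number of miRNAs")
  if (latent_dim == nm) return(S_m + 0)
  eig <- eigen(S_m, symmetric = TRUE)
  lam <- pmax(eig$values[seq_len(latent_dim)], 0)
  eig$vectors[, seq_len(latent_dim), drop = FALSE] %*%
    diag(sqrt(lam), latent_dim)
}

#' Sample unknown pairs as training negatives
#'
#' Uniform sample, without replacement, of `rho * |R|` zero entries of the
#' training association matrix. When fewer zero entries exist, all of them
#' are taken with a warning. Uses the current RNG state.
#'
#' @param dataset an [association_dataset()] (the training split).
#' @param rho negative-sample factor (>= 0).
#' @return integer matrix with columns `disease`, `mirna` (1-based);
#'   disjoint from the known-association set by construction.
#' @export
sample_negatives <- function(dataset, rho) {
  if (rho < 0) stop("rho must be non-negative")
  zeros <- which(dataset$U == 0L)
  want <- round(rho * nrow(dataset$pairs))
  if (want > length(zeros)) {
    warning("fewer zero entries than rho * |R|; taking all of them")
    want <- length(zeros)
  }
  lin <- if (want == 0) integer() else sample(zeros, want)
  nd <- length(dataset$diseases)
  cbind(disease = ((lin - 1L) %% nd) + 1L,
        mirna = ((lin - 1L) %/% nd) + 1L)
}

# raw factored prediction for arbitrary pair lists (vectorized);
# model: list with P, Q, b_d, b_m, alpha; dataset supplies R_d+
.predict_pairs <- function(model, dataset, d, m) {
  U <- dataset$U
  Tm <- U %*% model$P                      # T[d, ] = sum_{j in R_d+} p_j
  h <- rowSums(model$P * model$Q)          # h[m] = p_m . q_m
  s <- rowSums(Tm[d, , drop = FALSE] * model$Q[m, , drop = FALSE]) -
    U[cbind(d, m)] * h[m]
  cnt <- rowSums(U)[d] - U[cbind(d, m)]    # |R_d+ \ {m}|
  norm <- ifelse(cnt > 0, cnt^(-model$alpha), 0)
  unname(model$b_d[d] + model$b_m[m] + norm * s)
}

#' Raw model score for disease-miRNA pairs
#'
#' The factored prediction
#' `rhat(d, m) = b_d + b_m + |S|^(-alpha) * sum_{j in S} p_j q_m'` with
#' `S = R_d+ \ {m}`: the sum runs over the miRNAs associated with `d` in
#' the training split, excluding `m` itself (so the score of a pair never
#' depends on that pair's own entry in `U`). When `S` is empty the sum
#' term is 0 and the score reduces to the biases.
#'
#' @param model a fitted [fmsm()] object, or any list with elements `P`,
#'   `Q`, `b_d`, `b_m`, `alpha`.
#' @param dataset the training [association_dataset()].
#' @param d,m optional disease/miRNA indices (1-based, vectorized); when
#'   omitted the full `nd x nm` score matrix is returned.
#' @return numeric vector (pairs) or matrix (full grid).
#' @export
fmsm_predict_raw <- function(model, dataset, d = NULL, m = NULL) {
  if (is.null(model$alpha)) model$alpha <- model$control$alpha
  if (!is.null(d) || !is.null(m)) {
    stopifnot(length(d) == length(m))
    return(.predict_pairs(model, dataset, as.integer(d), as.integer(m)))
  }
  U <- dataset$U
  nd <- nrow(U); nm <- ncol(U)
  Tm <- U %*% model$P
  h <- rowSums(model$P * model$Q)
  G <- Tm %*% t(model$Q)
  s <- G - U * matrix(h, nd, nm, byrow = TRUE)
  cnt <- matrix(rowSums(U), nd, nm) - U
  norm <- ifelse(cnt > 0, cnt^(-model$alpha), 0)
  out <- outer(model$b_d, model$b_m, "+") + norm * s
  dimnames(out) <- dimnames(U)
  out
}

#' Regularized squared-error objective
#'
#' `1/2 sum_{(d,m) in R u A} (r_dm - rhat_dm)^2
#'  + beta/2 (||P||_F^2 + ||Q||_F^2) + lambda/2 sum b_d^2
#'  + gamma/2 sum b_m^2`, with target `r = 1` on known associations and
#' `0` on the sampled negatives.
#'
#' @param model fitted [fmsm()] object or parameter list (see
#'   [fmsm_predict_raw()]; regularization weights are read from
#'   `model$control` unless `beta`/`lambda`/`gamma` are present).
#' @param dataset the training [association_dataset()].
#' @param negatives integer matrix of negative pairs (columns disease,
#'   mirna), disjoint from the known set.
#' @return scalar loss.
#' @export
fmsm_objective <- function(model, dataset, negatives) {
  ctl <- if (!is.null(model$control)) model$control else model
  if (!all(is.finite(model$P)) || !all(is.finite(model$Q)) ||
      !all(is.finite(model$b_d)) || !all(is.finite(model$b_m)))
    stop("non-finite model parameters")
  if (is.null(model$alpha)) model$alpha <- ctl$alpha
  pos <- dataset$pairs
  if (nrow(negatives) > 0 &&
      any(dataset$U[negatives[, 1:2, drop = FALSE]] == 1L))
    stop("negatives overlap the known-association set")
  d <- c(pos[, 1], negatives[, 1])
  m <- c(pos[, 2], negatives[, 2])
  r <- c(rep(1, nrow(pos)), rep(0, nrow(negatives)))
  e <- r - .predict_pairs(model, dataset, d, m)
  0.5 * sum(e^2) +
    ctl$beta / 2 * (sum(model$P^2) + sum(model$Q^2)) +
    ctl$lambda / 2 * sum(model$b_d^2) +
    ctl$gamma / 2 * sum(model$b_m^2)
}

#' Analytic gradient of the regularized objective
#'
#' Full-batch gradient of [fmsm_objective()] with respect to all parameter
#' blocks; used to validate the SGD updates against central finite
#' differences.
#'
#' @inheritParams fmsm_objective
#' @return list with gradients `P`, `Q`, `b_d`, `b_m`.
#' @export
fmsm_gradient <- function(model, dataset, negatives) {
  ctl <- if (!is.null(model$control)) model$control else model
  if (is.null(model$alpha)) model$alpha <- ctl$alpha
  pos <- dataset$pairs
  d <- c(pos[, 1], negatives[, 1])
  m <- c(pos[, 2], negatives[, 2])
  r <- c(rep(1, nrow(pos)), rep(0, nrow(negatives)))
  gP <- ctl$beta * model$P
  gQ <- ctl$beta * model$Q
  gbd <- ctl$lambda * model$b_d
  gbm <- ctl$gamma * model$b_m
  psets <- pos_sets_of(dataset)
  for (k in seq_along(d)) {
    S <- setdiff(psets[[d[k]]], m[k])
    ns <- length(S)
    cc <- if (ns > 0) ns^(-model$alpha) else 0
    t_vec <- if (ns > 0) colSums(model$P[S, , drop = FALSE]) else
      numeric(ncol(model$P))
    e <- r[k] - (model$b_d[d[k]] + model$b_m[m[k]] +
                   cc * sum(t_vec * model$Q[m[k], ]))
    gbd[d[k]] <- gbd[d[k]] - e
    gbm[m[k]] <- gbm[m[k]] - e
    gQ[m[k], ] <- gQ[m[k], ] - e * cc * t_vec
    if (ns > 0)
      gP[S, ] <- gP[S, ] - matrix(e * cc * model$Q[m[k], ], ns,
                                  ncol(model$P), byrow = TRUE)
  }
  list(P = gP, Q = gQ, b_d = gbd, b_m = gbm)
}

# SGD training on a training dataset given an integrated miRNA similarity
# matrix (plain nm x nm numeric). Returns parameter list + objective trace.
fmsm_train <- function(dataset, S_m, control, seed = control$seed) {
  if (nrow(dataset$pairs) == 0) stop("cannot train on an empty association set")
  nd <- length(dataset$diseases)
  nm <- length(dataset$mirnas)
  dl <- if (is.null(control$latent_dim)) nm else as.integer(control$latent_dim)
  P <- init_factors(S_m, dl)
  Q <- P + 0
  b_d <- numeric(nd)
  b_m <- numeric(nm)
  psets0 <- lapply(pos_sets_of(dataset), function(v) v - 1L)
  pos <- dataset$pairs
  trace <- numeric(control$epochs)
  with_seed(seed, {
    for (ep in seq_len(control$epochs)) {
      neg <- sample_negatives(dataset, control$rho)
      d_all <- c(pos[, 1], neg[, 1])
      m_all <- c(pos[, 2], neg[, 2])
      r_all <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
      ord <- sample.int(length(d_all))
      fmsm_sgd_epoch(P, Q, b_d, b_m,
                     d_all[ord] - 1L, m_all[ord] - 1L, r_all[ord],
                     psets0, control$alpha, control$eta,
                     control$beta, control$lambda, control$gamma)
      if (!all(is.finite(P)) || !all(is.finite(Q)) ||
          !all(is.finite(b_d)) || !all(is.finite(b_m)))
        stop("SGD diverged (non-finite parameters); try a smaller eta")
      trace[ep] <- fmsm_objective(
        list(P = P, Q = Q, b_d = b_d, b_m = b_m, alpha = control$alpha,
             control = control),
        dataset, neg)
      if (control$trace > 0 && ep %% control$trace == 0)
        message(sprintf("epoch %d: objective %.6g", ep, trace[ep]))
    }
  })
  list(P = P, Q = Q, b_d = b_d, b_m = b_m, objective = trace)
}

#' Aggregate model scores with similarity neighbourhood terms
#'
#' Adds to the raw factored score of each pair `(d_i, m_j)` the average
#' disease similarity between `d_i` and the diseases known to associate
#' with `m_j` (weight `w_d`), and the average miRNA similarity between
#' `m_j` and the miRNAs known to associate with `d_i` (weight `w_m`).
#' A term with an empty neighbour set contributes 0.
#'
#' @param model fitted [fmsm()] object or parameter list.
#' @param dataset the training [association_dataset()].
#' @param S_d,S_m integrated disease/miRNA [similarity_matrix()] objects
#'   (or plain matrices) aligned to the dataset's indices.
#' @param control a [fmsm_control()] (supplies `w_d`, `w_m`, `alpha`).
#' @return `nd x nm` matrix of final prediction scores.
#' @export
aggregate_scores <- function(model, dataset, S_d, S_m,
                             control = model$control) {
  Sd <- if (inherits(S_d, "similarity_matrix")) S_d$S else S_d
  Sm <- if (inherits(S_m, "similarity_matrix")) S_m$S else S_m
  U <- dataset$U
  rhat <- fmsm_predict_raw(model, dataset)
  n_by_m <- colSums(U)
  n_by_d <- rowSums(U)
  term_d <- Sd %*% U
  term_d <- sweep(term_d, 2, ifelse(n_by_m > 0, n_by_m, 1), "/")
  term_d[, n_by_m == 0] <- 0
  term_m <- U %*% Sm
  term_m <- sweep(term_m, 1, ifelse(n_by_d > 0, n_by_d, 1), "/")
  term_m[n_by_d == 0, ] <- 0
  out <- rhat + control$w_d * term_d + control$w_m * term_m
  dimnames(out) <- dimnames(U)
  out
}

#' Fit a factored miRNA similarity model
#'
#' Learns an miRNA-miRNA similarity matrix as the product `P Q'` of two
#' latent factor matrices (plus disease and miRNA biases) by stochastic
#' gradient descent on a regularized squared-error loss over the known
#' associations and, per epoch, a fresh uniform sample of `rho * |R|`
#' unknown pairs. The factors are initialized from the integrated miRNA
#' similarity (expression Pearson similarity averaged with the miRNA GIP
#' kernel where expression covers both miRNAs); final prediction scores
#' add disease- and miRNA-similarity neighbourhood averages to the
#' factored score.
#'
#' @param associations an [association_dataset()] or path to a two-column
#'   TSV edge list.
#' @param expression optional [expression_profiles()] or TSV path.
#' @param mesh optional [mesh_forest()] or TSV path.
#' @param control a [fmsm_control()].
#' @param similarity_mode miRNA-similarity ablation mode: `"full"`
#'   (expression + GIP), `"expression_only"`, or `"none"` (identity).
#' @return an object of class `fmsm`: the training data, similarity
#'   stack, learned parameters `P`, `Q`, `b_d`, `b_m`, per-epoch
#'   `objective` trace and the final `scores` matrix.
#' @seealso [predict.fmsm()], [local_loocv()], [kfold_cv()]
#' @examples
#' syn <- simulate_mda(n_diseases = 8, n_mirnas = 16, seed = 1)
#' fit <- fmsm(syn$associations, syn$expression, syn$mesh,
#'             control = fmsm_control(epochs = 5, seed = 1))
#' head(predict(fit, type = "rankings")[[1]])
#' @export
fmsm <- function(associations, expression = NULL, mesh = NULL,
                 control = fmsm_control(),
                 similarity_mode = c("full", "expression_only", "none")) {
  similarity_mode <- match.arg(similarity_mode)
  cl <- match.call()
  if (is.character(associations)) associations <- read_associations(associations)
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(mesh)) mesh <- read_mesh(mesh)
  stopifnot(inherits(associations, "association_dataset"))
  sims <- fmsm_similarities(associations, expression, mesh, control,
                            similarity_mode)
  pars <- fmsm_train(associations, sims$S_m$S, control)
  scores <- aggregate_scores(
    c(pars, list(alpha = control$alpha, control = control)),
    associations, sims$S_d, sims$S_m, control)
  structure(list(call = cl, dataset = associations, similarities = sims,
                 control = control, similarity_mode = similarity_mode,
                 P = pars$P, Q = pars$Q, b_d = pars$b_d, b_m = pars$b_m,
                 alpha = control$alpha,
                 objective = pars$objective, scores = scores),
            class = "fmsm")
}

#' @export
print.fmsm <- function(x, ...) {
  cat("Factored miRNA similarity model\n")
  cat(sprintf("  %d diseases x %d miRNAs, |R| = %d (density %.3g%%)\n",
              length(x$dataset$diseases), length(x$dataset$mirnas),
              nrow(x$dataset$pairs), 100 * density(x$dataset)))
  cat(sprintf("  latent dim %d, %d epochs, miRNA similarity: %s\n",
              ncol(x$P), x$control$epochs, x$similarity_mode))
  if (length(x$objective))
    cat(sprintf("  objective: %.4g (initial epoch) -> %.4g (final)\n",
                x$objective[1], x$objective[length(x$objective)]))
  invisible(x)
}

#' @export
summary.fmsm <- function(object, ...) {
  unk <- object$scores[object$dataset$U == 0L]
  out <- list(
    n_diseases = length(object$dataset$diseases),
    n_mirnas = length(object$dataset$mirnas),
    n_associations = nrow(object$dataset$pairs),
    density = density(object$dataset),
    expression_coverage = mean(object$similarities$ES$covered),
    mesh_coverage = mean(object$similarities$SS$covered),
    similarity_mode = object$similarity_mode,
    latent_dim = ncol(object$P),
    final_objective = object$objective[length(object$objective)],
    unknown_score_quantiles = stats::quantile(unk, c(0, .25, .5, .75, 1))
  )
  class(out) <- "summary.fmsm"
  out
}

#' @export
print.summary.fmsm <- function(x, ...) {
  cat(sprintf("fmsm fit: %d diseases x %d miRNAs, |R| = %d (density %.3g%%)\n",
              x$n_diseases, x$n_mirnas, x$n_associations, 100 * x$density))
  cat(sprintf("  expression coverage %.0f%%, MeSH coverage %.0f%%, mode %s\n",
              100 * x$expression_coverage, 100 * x$mesh_coverage,
              x$similarity_mode))
  cat(sprintf("  latent dim %d, final objective %.4g\n",
              x$latent_dim, x$final_objective))
  cat("  score quantiles over unknown pairs:\n")
  print(signif(x$unknown_score_quantiles, 4))
  invisible(x)
}

#' @export
coef.fmsm <- function(object, ...) {
  list(P = object$P, Q = object$Q, b_d = object$b_d, b_m = object$b_m)
}

#' @export
fitted.fmsm <- function(object, ...) fmsm_predict_raw(object, object$dataset)

#' @export
residuals.fmsm <- function(object, ...) object$dataset$U - fitted(object)

#' Predict miRNA-disease scores or per-disease rankings
#'
#' @param object a fitted [fmsm()].
#' @param type `"scores"` for the full aggregated score matrix, `"raw"`
#'   for the factored score without neighbourhood terms, or `"rankings"`
#'   for per-disease candidate lists over unknown pairs (known
#'   associations masked out; descending score, ties broken by miRNA
#'   name).
#' @param top_n optional cap per disease for `type = "rankings"`.
#' @param ... ignored.
#' @return matrix, or a named list of named score vectors.
#' @export
predict.fmsm <- function(object, type = c("scores", "rankings", "raw"),
                         top_n = NULL, ...) {
  type <- match.arg(type)
  if (type == "scores") return(object$scores)
  if (type == "raw") return(fmsm_predict_raw(object, object$dataset))
  U <- object$dataset$U
  out <- lapply(seq_len(nrow(U)), function(i) {
    cand <- which(U[i, ] == 0L)
    s <- object$scores[i, cand]
    names(s) <- object$dataset$mirnas[cand]
    s <- s[order(-s, names(s))]
    if (!is.null(top_n)) s <- head(s, top_n)
    s
  })
  names(out) <- object$dataset$diseases
  out
}

#' @export
plot.fmsm <- function(x, ...) {
  graphics::plot(seq_along(x$objective), x$objective, type = "l",
                 xlab = "epoch", ylab = "regularized objective",
                 main = "FMSM training objective", ...)
  invisible(x)
}
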