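test_that("factor initialization reproduces S_m at full rank and rank-d structure below", {
  syn <- simulate_mda(n_diseases = 8, n_mirnas = 12, seed = 4)
  Sm <- fmsm_similarities(syn$associations, syn$expression, syn$mesh)$S_m$S
  P <- fmsm:::init_factors(Sm, ncol(Sm))
  expect_equal(P, Sm)
  expect_equal(P %*% t(P), Sm %*% t(Sm))

  # identity similarity stays identity
  I5 <- diag(5)
  expect_equal(fmsm:::init_factors(I5, 5), I5)

  # exact rank-3 PSD matrix recovered by the truncated eigenfactorization
  set.seed(1)
  B <- matrix(rnorm(36), 12, 3)
  S3 <- B %*% t(B)
  P3 <- fmsm:::init_factors(S3, 3)
  expect_lt(norm(P3 %*% t(P3) - S3, "F"), 1e-8)

  expect_error(fmsm:::init_factors(I5, 6), "latent_dim")
})

test_that("raw prediction follows the excluded-sum rule with bias and normalizer", {
  # disease d1 associated with m1, m2, m3; predict (d1, m3):
  # S = {m1, m2}, inner products 0.3 and 0.5, alpha = 0.5
  ds <- association_dataset("d1", c("m1", "m2", "m3"),
                            cbind(1, 1:3))
  model <- list(P = matrix(c(0.3, 0.5, 7), 3, 1),
                Q = matrix(c(9, 9, 1), 3, 1),
                b_d = 0.1, b_m = c(0, 0, 0.2), alpha = 0.5)
  expect_equal(fmsm_predict_raw(model, ds, 1, 3), 0.3 + 0.8 / sqrt(2))

  # alpha = 0: unweighted sum plus biases
  model0 <- model; model0$alpha <- 0
  expect_equal(fmsm_predict_raw(model0, ds, 1, 3), 0.3 + 0.8)

  # empty exclusion set: score reduces to the biases (here 0)
  ds1 <- association_dataset("d1", c("m1", "m2"), matrix(c(1L, 0L), 1))
  z <- list(P = matrix(0, 2, 1), Q = matrix(0, 2, 1),
            b_d = 0, b_m = c(0, 0), alpha = 0.5)
  expect_equal(fmsm_predict_raw(z, ds1, 1, 1), 0)

  # full-matrix path agrees with the pairwise path
  full <- fmsm_predict_raw(model, ds)
  expect_equal(full[1, 3], fmsm_predict_raw(model, ds, 1, 3))
})

test_that("prediction is invariant to toggling the predicted pair's own entry", {
  set.seed(8)
  U <- matrix(rbinom(80, 1, 0.25), 8, 10)
  U[3, 4] <- 1L
  ds_on <- association_dataset(paste0("d", 1:8), paste0("m", 1:10), U)
  U2 <- U; U2[3, 4] <- 0L
  ds_off <- association_dataset(paste0("d", 1:8), paste0("m", 1:10), U2)
  model <- random_model(8, 10, 4, fmsm_control(), seed = 99)
  expect_equal(fmsm_predict_raw(model, ds_on, 3, 4),
               fmsm_predict_raw(model, ds_off, 3, 4))
})

test_that("objective matches hand arithmetic for degenerate cases", {
  ds <- association_dataset("d1", c("m1", "m2"), matrix(c(1L, 0L), 1))
  zero <- list(P = matrix(0, 2, 2), Q = matrix(0, 2, 2), b_d = 0,
               b_m = c(0, 0), alpha = 0.5,
               control = fmsm_control(beta = 0, lambda = 0, gamma = 0))
  none <- matrix(integer(), 0, 2)
  expect_equal(fmsm_objective(zero, ds, none), 0.5)       # (1 - 0)^2 / 2
  neg <- cbind(1, 2)
  expect_equal(fmsm_objective(zero, ds, neg), 0.5)        # negative scored 0 adds 0

  # pure regularization: P = Q = I(2), empty sample set
  empty_ds <- association_dataset(c("d1"), c("m1", "m2"),
                                  matrix(integer(), 0, 2))
  reg <- list(P = diag(2), Q = diag(2), b_d = 0, b_m = c(0, 0), alpha = 0.5,
              control = fmsm_control(beta = 0.1, lambda = 0.1, gamma = 0.1))
  expect_equal(fmsm_objective(reg, empty_ds, none), 0.1 / 2 * 4)

  expect_error(fmsm_objective(zero, ds, cbind(1, 1)), "overlap")
})

test_that("analytic gradients match central finite differences on all blocks", {
  set.seed(10)
  U <- matrix(rbinom(150, 1, 0.2), 10, 15)
  U[1, 1] <- 1L
  ds <- association_dataset(paste0("d", 1:10), paste0("m", 1:15), U)
  ctl <- fmsm_control(alpha = 0.5, beta = 0.1, lambda = 0.1, gamma = 0.1)
  zeros <- which(ds$U == 0L)
  neg_lin <- sample(zeros, 20)
  negatives <- cbind(((neg_lin - 1L) %% 10L) + 1L, ((neg_lin - 1L) %/% 10L) + 1L)
  for (pt in 1:3) {
    model <- random_model(10, 15, 6, ctl, seed = 100 + pt)
    ana <- fmsm_gradient(model, ds, negatives)
    num <- fd_gradient(model, ds, negatives)
    for (block in names(ana)) {
      denom <- max(sqrt(sum(num[[block]]^2)), 1e-8)
      rel <- sqrt(sum((ana[[block]] - num[[block]])^2)) / denom
      expect_lt(rel, 1e-5)
    }
  }
})

test_that("the compiled SGD epoch reproduces a pure-R reference update", {
  set.seed(11)
  nd <- 6; nm <- 9; dl <- 4
  U <- matrix(rbinom(nd * nm, 1, 0.3), nd, nm); U[2, 3] <- 1L
  ds <- association_dataset(paste0("d", 1:nd), paste0("m", 1:nm), U)
  ctl <- fmsm_control(eta = 0.05)
  pos <- ds$pairs
  neg <- sample_negatives(ds, 2)
  d <- c(pos[, 1], neg[, 1]); m <- c(pos[, 2], neg[, 2])
  r <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  ord <- sample(length(d))
  psets <- fmsm:::pos_sets_of(ds)
  model <- random_model(nd, nm, dl, ctl, seed = 12)
  ref <- sgd_epoch_ref(model$P, model$Q, model$b_d, model$b_m,
                       d[ord], m[ord], r[ord], psets, ctl)
  P <- model$P + 0; Q <- model$Q + 0
  bd <- model$b_d + 0; bm <- model$b_m + 0
  fmsm:::fmsm_sgd_epoch(P, Q, bd, bm, d[ord] - 1L, m[ord] - 1L, r[ord],
                        lapply(psets, function(v) v - 1L),
                        ctl$alpha, ctl$eta, ctl$beta, ctl$lambda, ctl$gamma)
  expect_equal(P, ref$P, tolerance = 1e-12)
  expect_equal(Q, ref$Q, tolerance = 1e-12)
  expect_equal(bd, ref$b_d, tolerance = 1e-12)
  expect_equal(bm, ref$b_m, tolerance = 1e-12)
})

test_that("negative sampling honours rho, disjointness and seeded determinism", {
  syn <- simulate_mda(n_diseases = 10, n_mirnas = 20, density = 0.1, seed = 6)
  ds <- syn$associations
  set.seed(1)
  expect_equal(nrow(sample_negatives(ds, 0)), 0)
  A <- sample_negatives(ds, 3)
  expect_equal(nrow(A), 3 * nrow(ds$pairs))
  expect_true(all(ds$U[A] == 0))
  expect_equal(anyDuplicated(A), 0)
  set.seed(77); A1 <- sample_negatives(ds, 3)
  set.seed(77); A2 <- sample_negatives(ds, 3)
  expect_identical(A1, A2)
  expect_error(sample_negatives(ds, -1), "non-negative")
  # more negatives requested than zero entries available
  dense <- association_dataset(c("a", "b"), c("x", "y"),
                               cbind(c(1, 1, 2), c(1, 2, 1)))
  expect_warning(sample_negatives(dense, 5), "taking all")
})

test_that("training reduces the objective and eta = 0 leaves the model untouched", {
  syn <- simulate_mda(n_diseases = 20, n_mirnas = 30, density = 0.08, seed = 13)
  ds <- syn$associations
  ctl <- fmsm_control(seed = 13)
  sims <- fmsm_similarities(ds, syn$expression, syn$mesh, ctl)
  A <- fmsm:::with_seed(1, sample_negatives(ds, 3))
  init <- list(P = sims$S_m$S, Q = sims$S_m$S,
               b_d = numeric(20), b_m = numeric(30),
               alpha = ctl$alpha, control = ctl)
  obj0 <- fmsm_objective(init, ds, A)
  fit <- fmsm(ds, syn$expression, syn$mesh, control = ctl)
  expect_lt(fmsm_objective(fit, ds, A), obj0)
  expect_lt(fit$objective[length(fit$objective)], fit$objective[1])

  frozen <- fmsm:::fmsm_train(ds, sims$S_m$S, fmsm_control(eta = 0, epochs = 3, seed = 1))
  expect_equal(frozen$P, sims$S_m$S)
  expect_equal(frozen$b_d, numeric(20))
})

test_that("identical seeds give identical negative samples and final scores", {
  syn <- simulate_mda(n_diseases = 12, n_mirnas = 18, density = 0.1, seed = 21)
  ctl <- fmsm_control(seed = 5, epochs = 20)
  f1 <- fmsm(syn$associations, syn$expression, syn$mesh, control = ctl)
  f2 <- fmsm(syn$associations, syn$expression, syn$mesh, control = ctl)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$objective, f2$objective)
})

test_that("score aggregation adds neighbourhood means with empty-set fallback", {
  # d1-m1 known; score (d2, m1): rhat + S_d(d2, d1) + S_m neighbourhood
  ds <- association_dataset(c("d1", "d2"), c("m1", "m2"),
                            cbind(c(1, 2), c(1, 2)))
  model <- list(P = matrix(0, 2, 1), Q = matrix(0, 2, 1),
                b_d = c(0, 0.5), b_m = c(0, 0), alpha = 0.5,
                control = fmsm_control())
  S_d <- rbind(c(1, 0.8), c(0.8, 1))
  S_m <- rbind(c(1, 0.4), c(0.4, 1))
  sc <- aggregate_scores(model, ds, S_d, S_m, model$control)
  # (d2, m1): rhat = b_d2 = 0.5; disease neighbour d1 (S_d = 0.8);
  # miRNA neighbour m2 (S_m = 0.4)
  expect_equal(sc[2, 1], 0.5 + 0.8 + 0.4)

  # w_d = w_m = 0 collapses to the raw prediction
  ctl0 <- fmsm_control(w_d = 0, w_m = 0)
  model0 <- model; model0$control <- ctl0
  expect_equal(aggregate_scores(model0, ds, S_d, S_m, ctl0),
               fmsm_predict_raw(model0, ds))

  # miRNA never seen in training: its disease-neighbour term is 0
  ds2 <- association_dataset(c("d1", "d2"), c("m1", "m2"), cbind(1, 1))
  sc2 <- aggregate_scores(model, ds2, S_d, S_m, model$control)
  # (d2, m2): m2 has no associated disease, d2 has no associated miRNA
  expect_equal(sc2[2, 2], 0.5)
})

test_that("the fitted object exposes the standard modelling surface", {
  syn <- simulate_mda(n_diseases = 10, n_mirnas = 15, density = 0.1, seed = 30)
  fit <- fmsm(syn$associations, syn$expression, syn$mesh,
              control = fmsm_control(epochs = 10, seed = 3))
  expect_s3_class(fit, "fmsm")
  expect_output(print(fit), "Factored miRNA similarity model")
  expect_output(print(summary(fit)), "score quantiles")
  cf <- coef(fit)
  expect_equal(dim(cf$P), c(15, 15))
  expect_equal(dim(fitted(fit)), c(10, 15))
  expect_equal(residuals(fit), syn$associations$U - fitted(fit))
  rk <- predict(fit, type = "rankings", top_n = 5)
  expect_length(rk, 10)
  expect_true(all(lengths(rk) <= 5))
  expect_true(all(vapply(rk, function(s) !is.unsorted(rev(s)), TRUE)))
  # known pairs are masked out of rankings
  p1 <- syn$associations$pairs[1, ]
  expect_false(syn$associations$mirnas[p1[2]] %in%
                 names(predict(fit, type = "rankings")[[p1[1]]]))
})
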