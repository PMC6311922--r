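# shared fixture builders and independent oracles

toy_dataset <- function() {
  association_dataset(c("d1", "d2"), c("m1", "m2"),
                      cbind(c(1, 1, 2), c(1, 2, 1)))
}

# random parameter set for gradient/objective checks
random_model <- function(nd, nm, latent_dim, control, seed) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    list(P = matrix(rnorm(nm * latent_dim, sd = 0.3), nm),
         Q = matrix(rnorm(nm * latent_dim, sd = 0.3), nm),
         b_d = rnorm(nd, sd = 0.1), b_m = rnorm(nm, sd = 0.1),
         alpha = control$alpha, control = control)
  })
}

# central finite differences of the objective over every parameter block
fd_gradient <- function(model, dataset, negatives, h = 1e-5) {
  obj <- function(m) fmsm_objective(m, dataset, negatives)
  num <- list(P = model$P * 0, Q = model$Q * 0,
              b_d = model$b_d * 0, b_m = model$b_m * 0)
  for (block in names(num)) {
    for (i in seq_along(model[[block]])) {
      up <- model; up[[block]][i] <- up[[block]][i] + h
      dn <- model; dn[[block]][i] <- dn[[block]][i] - h
      num[[block]][i] <- (obj(up) - obj(dn)) / (2 * h)
    }
  }
  num
}

# brute-force Wilcoxon-Mann-Whitney statistic: P(pos > neg) + 0.5 P(tie)
wmw_brute <- function(pos_scores, neg_scores) {
  tot <- 0
  for (p in pos_scores)
    tot <- tot + sum(p > neg_scores) + 0.5 * sum(p == neg_scores)
  tot / (length(pos_scores) * length(neg_scores))
}

# trapezoidal area under a piecewise-linear curve
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# brute-force GIP kernel: explicit double loop over profile pairs
gip_brute <- function(U, axis, gamma_prime = 1) {
  P <- if (axis == "disease") U else t(U)
  n <- nrow(P)
  gamma <- gamma_prime / mean(rowSums(P^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  K
}

# pure-R reference for one SGD epoch (same update equations, same order)
sgd_epoch_ref <- function(P, Q, b_d, b_m, d, m, r, pos_sets, ctl) {
  for (k in seq_along(d)) {
    S <- setdiff(pos_sets[[d[k]]], m[k])
    ns <- length(S)
    cc <- if (ns > 0) ns^(-ctl$alpha) else 0
    tv <- if (ns > 0) colSums(P[S, , drop = FALSE]) else numeric(ncol(P))
    e <- r[k] - (b_d[d[k]] + b_m[m[k]] + cc * sum(tv * Q[m[k], ]))
    b_d[d[k]] <- b_d[d[k]] + ctl$eta * (e - ctl$lambda * b_d[d[k]])
    b_m[m[k]] <- b_m[m[k]] + ctl$eta * (e - ctl$gamma * b_m[m[k]])
    q_old <- Q[m[k], ]
    Q[m[k], ] <- q_old + ctl$eta * (e * cc * tv - ctl$beta * q_old)
    if (ns > 0)
      P[S, ] <- (1 - ctl$eta * ctl$beta) * P[S, ] +
        matrix(ctl$eta * e * cc * q_old, ns, ncol(P), byrow = TRUE)
  }
  list(P = P, Q = Q, b_d = b_d, b_m = b_m)
}
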