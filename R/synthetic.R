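#' Simulate a miRNA-disease benchmark with planted block structure
#'
#' Generates the three model inputs plus ground truth, emulating the shape
#' of curated association data: a sparse binary association matrix,
#' tissue expression profiles whose pairwise correlations partly reflect
#' shared disease associations, and a MeSH-like forest of dotted tree
#' codes. Diseases and miRNAs are partitioned into latent blocks;
#' associations fall preferentially within matched blocks, same-block
#' miRNAs share an expression centroid, and same-block diseases share a
#' tree-code prefix — the coupling between expression similarity and
#' shared disease structure that the model exploits. A held-out set of
#' true within-block pairs disjoint from the observed associations is
#' returned for recovery checks.
#'
#' @param n_diseases,n_mirnas panel sizes.
#' @param n_tissues expression panel width (default 172, the width of the
#'   public tissue/cell-line expression panel this emulates).
#' @param n_blocks number of planted blocks (<= min of panel sizes).
#' @param density target association density in (0, 1); the observed set
#'   has exactly `round(density * n_diseases * n_mirnas)` pairs.
#' @param within_block mass of association probability placed on matched
#'   blocks (default 0.9).
#' @param popularity_sd sdlog of the lognormal per-miRNA and per-disease
#'   popularity weights multiplying the block weights (default 1.1).
#'   Curated association databases are strongly disproportional — a few
#'   hub miRNAs and diseases carry a large share of the entries — and
#'   1.1 reproduces the max/mean degree ratio (about 14) seen in the
#'   benchmark-scale data this generator emulates. Set 0 for uniform
#'   degrees.
#' @param expression_noise sd of Gaussian noise around block centroids.
#' @param dag_depth dotted components per tree code (>= 2; the first two
#'   are shared within a block).
#' @param coverage_expression,coverage_mesh fraction of miRNAs with
#'   expression profiles / diseases with tree codes.
#' @param n_ground_truth held-out true pairs (default half the observed
#'   count, capped by availability).
#' @param seed integer seed; the whole generation is reproducible and the
#'   caller's RNG state is preserved.
#' @return list with `associations` ([association_dataset()]),
#'   `expression` ([expression_profiles()] or `NULL`), `mesh`
#'   ([mesh_forest()] or `NULL`), `ground_truth` (pair matrix disjoint
#'   from the observed set), `blocks` (disease/miRNA block labels) and
#'   `config`.
#' @export
simulate_mda <- function(n_diseases = 30, n_mirnas = 60, n_tissues = 172,
                         n_blocks = 2, density = 0.05, within_block = 0.9,
                         popularity_sd = 1.1,
                         expression_noise = 0.5, dag_depth = 3,
                         coverage_expression = 0.8, coverage_mesh = 0.9,
                         n_ground_truth = NULL, seed = NULL) {
  stopifnot(n_blocks <= min(n_diseases, n_mirnas), density > 0, density < 1,
            coverage_expression >= 0, coverage_expression <= 1,
            coverage_mesh >= 0, coverage_mesh <= 1, dag_depth >= 2)
  n_assoc <- round(density * n_diseases * n_mirnas)
  if (n_assoc < 1) stop("density infeasible: no associations to draw")
  config <- list(n_diseases = n_diseases, n_mirnas = n_mirnas,
                 n_tissues = n_tissues, n_blocks = n_blocks,
                 density = density, within_block = within_block,
                 popularity_sd = popularity_sd,
                 expression_noise = expression_noise, dag_depth = dag_depth,
                 coverage_expression = coverage_expression,
                 coverage_mesh = coverage_mesh, seed = seed)
  with_seed(seed, {
    diseases <- sprintf("disease-%03d", seq_len(n_diseases))
    mirnas <- sprintf("syn-mir-%04d", seq_len(n_mirnas))
    d_block <- sample(rep(seq_len(n_blocks), length.out = n_diseases))
    m_block <- sample(rep(seq_len(n_blocks), length.out = n_mirnas))
    match_bl <- outer(d_block, m_block, "==")
    # per-cell weights: `within_block` of the probability mass on matched
    # blocks, the rest spread over the remainder
    n_in <- sum(match_bl)
    n_out <- n_diseases * n_mirnas - n_in
    W <- ifelse(match_bl, within_block / n_in, (1 - within_block) / n_out)
    # disproportional coverage: hub miRNAs/diseases draw most associations
    if (popularity_sd > 0) {
      W <- sweep(W, 2, stats::rlnorm(n_mirnas, 0, popularity_sd), "*")
      W <- sweep(W, 1, stats::rlnorm(n_diseases, 0, popularity_sd), "*")
    }
    lin <- sample.int(n_diseases * n_mirnas, n_assoc, prob = as.vector(W))
    pairs <- cbind(((lin - 1L) %% n_diseases) + 1L,
                   ((lin - 1L) %/% n_diseases) + 1L)
    associations <- association_dataset(diseases, mirnas, pairs)

    # held-out true pairs: within-block cells not drawn above
    avail <- which(as.vector(match_bl) & !(seq_len(n_diseases * n_mirnas) %in% lin))
    if (is.null(n_ground_truth)) n_ground_truth <- round(n_assoc / 2)
    # further draws from the same association process, held out of R
    gt_lin <- sample(avail, min(n_ground_truth, length(avail)),
                     prob = as.vector(W)[avail])
    ground_truth <- cbind(disease = ((gt_lin - 1L) %% n_diseases) + 1L,
                          mirna = ((gt_lin - 1L) %/% n_diseases) + 1L)

    expression <- NULL
    if (coverage_expression > 0) {
      centroids <- matrix(stats::rnorm(n_blocks * n_tissues), n_blocks)
      E <- centroids[m_block, , drop = FALSE] +
        matrix(stats::rnorm(n_mirnas * n_tissues, sd = expression_noise),
               n_mirnas)
      covered <- sort(sample.int(n_mirnas, round(coverage_expression * n_mirnas)))
      if (length(covered) > 0)
        expression <- expression_profiles(
          E[covered, , drop = FALSE], mirnas[covered],
          sprintf("tissue-%03d", seq_len(n_tissues)))
    }

    mesh <- NULL
    if (coverage_mesh > 0) {
      # per block a shared two-component prefix, then a disease-specific tail
      prefix <- sprintf("C%02d.%03d", seq_len(n_blocks),
                        sample.int(999, n_blocks))
      tails <- if (dag_depth > 2)
        matrix(sprintf("%03d", sample.int(999, n_diseases * (dag_depth - 2),
                                          replace = TRUE)),
               n_diseases)
      else matrix(character(), n_diseases, 0)
      codes <- vapply(seq_len(n_diseases), function(i)
        paste(c(prefix[d_block[i]], tails[i, ]), collapse = "."), "")
      covered_d <- sort(sample.int(n_diseases, round(coverage_mesh * n_diseases)))
      if (length(covered_d) > 0) {
        code_list <- as.list(codes[covered_d])
        names(code_list) <- diseases[covered_d]
        mesh <- mesh_forest(code_list)
      }
    }
    list(associations = associations, expression = expression, mesh = mesh,
         ground_truth = ground_truth,
         blocks = list(disease = d_block, mirna = m_block),
         config = config)
  })
}

#' Benchmark-scale synthetic fixture
#'
#' Convenience wrapper of [simulate_mda()] at the dimensions of the
#' curated human benchmark this package targets: 383 diseases, 495
#' miRNAs, 5430 associations (density about 2.86%) and 172 expression
#' tissues. Intended for performance smoke tests.
#'
#' @param seed integer seed.
#' @return see [simulate_mda()].
#' @export
hmdd_scale_fixture <- function(seed = 1) {
  simulate_mda(n_diseases = 383, n_mirnas = 495, n_tissues = 172,
               n_blocks = 8, density = 5430 / (383 * 495), seed = seed)
}
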