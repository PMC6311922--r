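#' Construct a similarity matrix with a coverage mask
#'
#' Symmetric square matrix of pairwise scores in `[0, 1]` over a fixed
#' entity list, with a logical `covered` mask marking entities for which
#' the source data existed. Uncovered rows/columns are left at 0 (off the
#' diagonal) and are filled from another source downstream.
#'
#' @param S numeric square matrix.
#' @param names entity names (length `nrow(S)`).
#' @param covered logical mask, default all `TRUE`.
#' @param check validate symmetry/bounds/diagonal (tolerance 1e-9).
#' @return object of class `similarity_matrix` with elements `names`,
#'   `S`, `covered`.
#' @export
similarity_matrix <- function(S, names, covered = rep(TRUE, nrow(S)),
                              check = TRUE) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (length(names) != nrow(S)) stop("names length mismatch")
  if (length(covered) != nrow(S)) stop("covered mask length mismatch")
  dimnames(S) <- list(names, names)
  if (check) {
    if (max(abs(S - t(S))) > 1e-9) stop("similarity matrix not symmetric (tol 1e-9)")
    if (min(S) < -1e-9 || max(S) > 1 + 1e-9) stop("similarity entries outside [0, 1]")
    if (any(covered) && max(abs(diag(S)[covered] - 1)) > 1e-9)
      stop("covered diagonal entries must be 1")
  }
  structure(list(names = as.character(names), S = S, covered = covered),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity matrix: %d entities (%d covered), range [%.3g, %.3g]\n",
              length(x$names), sum(x$covered), min(x$S), max(x$S)))
  invisible(x)
}

#' Write/read a similarity matrix as TSV (square, named header row/column)
#' @param sm a [similarity_matrix()].
#' @param path file path.
#' @rdname similarity_io
#' @export
write_similarity <- function(sm, path) {
  dt <- data.table::as.data.table(sm$S, keep.rownames = "name")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname similarity_io
#' @export
read_similarity <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  nm <- dt[[1]]
  S <- as.matrix(dt[, -1])
  similarity_matrix(S, nm, check = FALSE)
}

#' miRNA expression similarity (Pearson correlation of tissue profiles)
#'
#' Pairwise Pearson correlation of per-miRNA expression vectors. The score
#' is kept in `[0, 1]`: with `negative = "clip"` (default) negative
#' correlations are truncated to 0 ("no similarity"); with
#' `negative = "affine"` the correlation is mapped by `(r + 1) / 2`.
#' miRNAs absent from the profiles, or with zero-variance profiles, are
#' marked uncovered and their rows/columns left at 0.
#'
#' @param profiles an [expression_profiles()] object.
#' @param mirnas full miRNA name vector to index the output by (profiles
#'   may cover only a subset).
#' @param negative policy for negative correlations, `"clip"` or `"affine"`.
#' @return a [similarity_matrix()] (`ES`) over `mirnas`.
#' @export
expression_similarity <- function(profiles, mirnas,
                                  negative = c("clip", "affine")) {
  negative <- match.arg(negative)
  nm <- length(mirnas)
  usable <- !profiles$zero_variance
  if (any(profiles$zero_variance))
    warning(sprintf("%d zero-variance expression profiles treated as uncovered",
                    sum(profiles$zero_variance)))
  row_of <- match(.norm_name(mirnas), .norm_name(profiles$mirnas[usable]))
  covered <- !is.na(row_of)
  S <- matrix(0, nm, nm)
  if (sum(covered) >= 2) {
    Ecov <- profiles$E[usable, , drop = FALSE][row_of[covered], , drop = FALSE]
    if (ncol(Ecov) < 2) stop("expression similarity needs at least 2 tissues")
    R <- cor(t(Ecov))
    S[covered, covered] <- if (negative == "clip") pmax(R, 0) else (R + 1) / 2
  } else if (sum(covered) == 1) {
    S[covered, covered] <- 1
  }
  diag(S)[covered] <- 1
  similarity_matrix(S, mirnas, covered)
}

#' Disease semantic similarity from MeSH DAG overlap
#'
#' Two diseases are similar in proportion to the shared part of their MeSH
#' DAGs: `SS(di, dj)` sums, over nodes in `T(di) n T(dj)`, the two
#' diseases' semantic contributions to that node, normalized by
#' `AC(di) + AC(dj)`. Equals 1 on the diagonal and 0 for disjoint DAGs.
#' Diseases absent from the forest are uncovered.
#'
#' @param forest a [mesh_forest()].
#' @param diseases full disease name vector to index the output by.
#' @param delta contribution decay parameter, default 0.5.
#' @return a [similarity_matrix()] (`SS`) over `diseases`.
#' @export
disease_semantic_similarity <- function(forest, diseases, delta = 0.5) {
  nd <- length(diseases)
  in_forest <- match(.norm_name(diseases), .norm_name(names(forest$dags)))
  covered <- !is.na(in_forest)
  contrib <- vector("list", nd)
  for (i in which(covered))
    contrib[[i]] <- semantic_contributions(forest, diseases[i], delta)
  S <- matrix(0, nd, nd)
  idx <- which(covered)
  for (a in seq_along(idx)) {
    i <- idx[a]
    Ci <- contrib[[i]]$contributions
    for (b in seq_len(a)) {
      j <- idx[b]
      Cj <- contrib[[j]]$contributions
      shared <- intersect(names(Ci), names(Cj))
      val <- if (length(shared))
        sum(Ci[shared] + Cj[shared]) /
          (contrib[[i]]$aggregate + contrib[[j]]$aggregate) else 0
      S[i, j] <- S[j, i] <- val
    }
  }
  similarity_matrix(S, diseases, covered)
}

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' RBF kernel on binary interaction profiles taken from the association
#' matrix `U`: rows for diseases, columns for miRNAs. The bandwidth is
#' `gamma = gamma_prime / mean(||IP||^2)`, i.e. normalized by the mean
#' squared profile norm over the chosen axis, and
#' `K(i, j) = exp(-gamma * ||IP_i - IP_j||^2)`. Recompute the kernel
#' whenever `U` changes (e.g. per cross-validation fold).
#'
#' @param dataset an [association_dataset()] (its `U` supplies profiles).
#' @param axis `"disease"` (rows of `U`) or `"mirna"` (columns).
#' @param gamma_prime bandwidth numerator, default 1.
#' @return a [similarity_matrix()] (`KD` or `KM`).
#' @export
gip_kernel <- function(dataset, axis = c("disease", "mirna"),
                       gamma_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(gamma_prime > 0)
  P <- if (axis == "disease") dataset$U else t(dataset$U)
  storage.mode(P) <- "double"
  nrm2 <- rowSums(P^2)
  mean_norm <- mean(nrm2)
  if (mean_norm == 0) stop("kernel bandwidth undefined: all interaction profiles are zero")
  gamma <- gamma_prime / mean_norm
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  D2 <- outer(nrm2, nrm2, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  K <- exp(-gamma * D2)
  diag(K) <- 1
  similarity_matrix(K, if (axis == "disease") dataset$diseases else dataset$mirnas)
}

#' Integrated miRNA similarity
#'
#' Averages expression similarity and the miRNA GIP kernel where both
#' miRNAs are expression-covered; elsewhere the GIP kernel alone fills in
#' (expression profiles rarely cover the full miRNA panel).
#'
#' @param ES expression [similarity_matrix()].
#' @param KM miRNA GIP kernel [similarity_matrix()].
#' @return a [similarity_matrix()] (`S_m`).
#' @export
integrate_mirna_similarity <- function(ES, KM) {
  if (!identical(.norm_name(ES$names), .norm_name(KM$names)))
    stop("ES and KM index different miRNA lists")
  both <- outer(ES$covered, ES$covered, "&")
  S <- KM$S
  S[both] <- (ES$S[both] + KM$S[both]) / 2
  diag(S) <- 1
  similarity_matrix(S, KM$names)
}

#' Integrated disease similarity
#'
#' Semantic similarity where both diseases carry MeSH annotation, the
#' disease GIP kernel otherwise.
#'
#' @param SS semantic [similarity_matrix()].
#' @param KD disease GIP kernel [similarity_matrix()].
#' @return a [similarity_matrix()] (`S_d`).
#' @export
integrate_disease_similarity <- function(SS, KD) {
  if (!identical(.norm_name(SS$names), .norm_name(KD$names)))
    stop("SS and KD index different disease lists")
  both <- outer(SS$covered, SS$covered, "&")
  S <- KD$S
  S[both] <- SS$S[both]
  diag(S) <- 1
  similarity_matrix(S, KD$names)
}

# identity similarity: the zero-information stand-in used by the
# "no extra miRNA similarity" ablation mode
identity_similarity <- function(names) {
  similarity_matrix(diag(length(names)), names)
}

#' Compute the full similarity stack for a dataset
#'
#' Convenience wrapper producing `ES`, `SS`, `KD`, `KM` and the integrated
#' `S_m`, `S_d` in one call, honouring the ablation mode used by the
#' similarity-contribution experiment: `"none"` replaces `S_m` by the
#' identity, `"expression_only"` uses expression similarity alone
#' (identity where uncovered), `"full"` integrates expression with the
#' miRNA GIP kernel. The disease side always integrates semantic
#' similarity with the disease GIP kernel.
#'
#' @param dataset an [association_dataset()].
#' @param expression optional [expression_profiles()].
#' @param mesh optional [mesh_forest()].
#' @param control a [fmsm_control()] list (supplies `delta`,
#'   `gamma_prime_d`, `gamma_prime_m`, `es_negative`).
#' @param mode `"full"`, `"expression_only"` or `"none"`.
#' @return named list with `ES`, `SS`, `KD`, `KM`, `S_m`, `S_d` (entries
#'   may be `NULL` when the source is absent).
#' @export
fmsm_similarities <- function(dataset, expression = NULL, mesh = NULL,
                              control = fmsm_control(),
                              mode = c("full", "expression_only", "none")) {
  mode <- match.arg(mode)
  KD <- gip_kernel(dataset, "disease", control$gamma_prime_d)
  KM <- gip_kernel(dataset, "mirna", control$gamma_prime_m)
  ES <- if (!is.null(expression))
    expression_similarity(expression, dataset$mirnas, control$es_negative)
  else similarity_matrix(matrix(0, length(dataset$mirnas), length(dataset$mirnas)),
                         dataset$mirnas, covered = rep(FALSE, length(dataset$mirnas)),
                         check = FALSE)
  SS <- if (!is.null(mesh))
    disease_semantic_similarity(mesh, dataset$diseases, control$delta)
  else similarity_matrix(matrix(0, length(dataset$diseases), length(dataset$diseases)),
                         dataset$diseases, covered = rep(FALSE, length(dataset$diseases)),
                         check = FALSE)
  S_m <- switch(mode,
    none = identity_similarity(dataset$mirnas),
    expression_only = {
      S <- ES$S
      diag(S) <- 1
      similarity_matrix(S, dataset$mirnas)
    },
    full = integrate_mirna_similarity(ES, KM))
  S_d <- integrate_disease_similarity(SS, KD)
  list(ES = ES, SS = SS, KD = KD, KM = KM, S_m = S_m, S_d = S_d, mode = mode)
}
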