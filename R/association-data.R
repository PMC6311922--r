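#' @useDynLib fmsm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor density predict coef fitted residuals sd wilcox.test
#' @importFrom utils head
NULL

# canonical matching key: names are matched case-insensitively after trimming
.norm_name <- function(x) tolower(trimws(x))

#' Construct a miRNA-disease association dataset
#'
#' The central container: a binary adjacency matrix `U` of size
#' `nd x nm` over ordered disease and miRNA name vectors, where
#' `U[d, m] == 1` records a known (experimentally supported) association.
#' The set of 1-entries is the known-association set `R`.
#'
#' @param diseases character vector of disease names (no duplicates after
#'   trimming/case-folding).
#' @param mirnas character vector of miRNA names (no duplicates).
#' @param pairs two-column matrix or data.frame of (disease index, miRNA
#'   index) pairs, 1-based, or a logical/numeric `nd x nm` matrix.
#' @return An object of class `association_dataset` with elements
#'   `diseases`, `mirnas`, `U` (0/1 integer matrix with dimnames) and
#'   `pairs` (integer matrix of the distinct 1-entries, one row per pair).
#' @export
association_dataset <- function(diseases, mirnas, pairs) {
  diseases <- as.character(diseases)
  mirnas <- as.character(mirnas)
  if (anyDuplicated(.norm_name(diseases)))
    stop("duplicate disease names (after trimming, case-insensitive)")
  if (anyDuplicated(.norm_name(mirnas)))
    stop("duplicate miRNA names (after trimming, case-insensitive)")
  nd <- length(diseases)
  nm <- length(mirnas)
  if (is.matrix(pairs) && nrow(pairs) == nd && ncol(pairs) == nm &&
      (is.logical(pairs) || all(pairs %in% c(0, 1)))) {
    U <- matrix(as.integer(pairs != 0), nd, nm)
    idx <- which(U == 1L, arr.ind = TRUE)
    pairs <- idx
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
    storage.mode(pairs) <- "integer"
    if (nrow(pairs) > 0 &&
        (any(pairs[, 1] < 1L | pairs[, 1] > nd) ||
         any(pairs[, 2] < 1L | pairs[, 2] > nm)))
      stop("pair indices out of range")
    pairs <- unique(pairs)
    U <- matrix(0L, nd, nm)
    U[pairs] <- 1L
  }
  dimnames(U) <- list(diseases, mirnas)
  colnames(pairs) <- c("disease", "mirna")
  structure(
    list(diseases = diseases, mirnas = mirnas, U = U,
         pairs = pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]),
    class = "association_dataset"
  )
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "miRNA-disease association dataset: %d diseases x %d miRNAs, |R| = %d (density %.3g%%)\n",
    length(x$diseases), length(x$mirnas), nrow(x$pairs), 100 * density(x)))
  invisible(x)
}

#' Density (sparsity) of an association dataset
#'
#' Fraction of observed associations, `|R| / (nd * nm)`.
#'
#' @param x an `association_dataset`.
#' @param ... ignored.
#' @return scalar in (0, 1).
#' @export
density.association_dataset <- function(x, ...) {
  nrow(x$pairs) / (length(x$diseases) * length(x$mirnas))
}

# restrict the known-association set to a subset of pair rows (training split);
# diseases/miRNAs and their order are preserved so indices remain comparable
subset_pairs <- function(dataset, keep) {
  association_dataset(dataset$diseases, dataset$mirnas,
                      dataset$pairs[keep, , drop = FALSE])
}

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a miRNA-disease association edge list
#'
#' Plain TSV, two columns per line: disease name, miRNA name. Lines
#' starting with `#` and blank lines are ignored. Duplicate pairs collapse
#' to a single association; names are matched case-insensitively after
#' trimming (first spelling seen is kept).
#'
#' @param path path to the TSV file.
#' @param quiet suppress the summary message.
#' @return an [association_dataset()].
#' @export
read_associations <- function(path, quiet = FALSE) {
  src <- .read_tsv_lines(path)
  if (length(src$lines) == 0) stop("empty association file: ", path)
  parts <- strsplit(src$lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop(sprintf("malformed association line %d in %s (expected 2 tab-separated columns)",
                 src$lineno[bad[1]], path))
  d_raw <- trimws(vapply(parts, `[[`, "", 1L))
  m_raw <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(d_raw)) || any(!nzchar(m_raw)))
    stop("empty disease or miRNA name in ", path)
  d_key <- .norm_name(d_raw)
  m_key <- .norm_name(m_raw)
  diseases <- d_raw[!duplicated(d_key)]
  mirnas <- m_raw[!duplicated(m_key)]
  di <- match(d_key, .norm_name(diseases))
  mi <- match(m_key, .norm_name(mirnas))
  ds <- association_dataset(diseases, mirnas, cbind(di, mi))
  if (!quiet)
    message(sprintf("read %d diseases, %d miRNAs, %d associations (density %.3g%%) from %s",
                    length(ds$diseases), length(ds$mirnas), nrow(ds$pairs),
                    100 * density(ds), path))
  ds
}

#' Write an association dataset as a two-column TSV edge list
#'
#' Inverse of [read_associations()]: writing then reading reproduces `U`.
#'
#' @param dataset an `association_dataset`.
#' @param path output path.
#' @export
write_associations <- function(dataset, path) {
  p <- dataset$pairs
  lines <- paste(dataset$diseases[p[, 1]], dataset$mirnas[p[, 2]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Construct miRNA expression profiles
#'
#' Expression levels of miRNAs across tissues/cell lines; each miRNA is a
#' row vector (the public tissue panel this emulates has 172 tissues;
#' any width is accepted). Rows with
#' zero variance are flagged: Pearson correlation is undefined for them
#' and they are treated as uncovered by expression similarity.
#'
#' @param E numeric matrix, rows = miRNAs, columns = tissues.
#' @param mirnas row names (miRNA names); defaults to `rownames(E)`.
#' @param tissue_names column names; defaults to `colnames(E)`.
#' @return object of class `expression_profiles` with elements `mirnas`,
#'   `E`, `tissue_names`, `zero_variance` (logical per row).
#' @export
expression_profiles <- function(E, mirnas = rownames(E),
                                tissue_names = colnames(E)) {
  E <- as.matrix(E)
  storage.mode(E) <- "double"
  if (is.null(mirnas)) stop("miRNA row names required")
  if (anyDuplicated(.norm_name(mirnas))) stop("duplicate miRNA rows in expression matrix")
  if (any(!is.finite(E))) stop("non-finite values in expression matrix")
  if (is.null(tissue_names)) tissue_names <- paste0("tissue_", seq_len(ncol(E)))
  zv <- apply(E, 1, function(r) length(unique(r)) == 1L)
  rownames(E) <- mirnas
  colnames(E) <- tissue_names
  structure(list(mirnas = as.character(mirnas), E = E,
                 tissue_names = as.character(tissue_names),
                 zero_variance = unname(zv)),
            class = "expression_profiles")
}

#' @export
print.expression_profiles <- function(x, ...) {
  cat(sprintf("miRNA expression profiles: %d miRNAs x %d tissues (%d zero-variance rows)\n",
              nrow(x$E), ncol(x$E), sum(x$zero_variance)))
  invisible(x)
}

#' Read a miRNA expression matrix from TSV
#'
#' First row: tab-separated tissue names (header). Each following row:
#' miRNA name then one numeric expression value per tissue.
#'
#' @param path path to the TSV file.
#' @return an [expression_profiles()] object.
#' @export
read_expression <- function(path) {
  src <- .read_tsv_lines(path)
  if (length(src$lines) < 2) stop("expression file needs a header and at least one row: ", path)
  tissues <- trimws(strsplit(src$lines[1], "\t", fixed = TRUE)[[1]])
  # header may or may not carry a leading cell for the miRNA-name column
  body <- strsplit(src$lines[-1], "\t", fixed = TRUE)
  n_col <- vapply(body, length, 1L)
  nt <- n_col[1] - 1L
  if (length(tissues) == nt + 1L) tissues <- tissues[-1]
  if (length(tissues) != nt)
    stop(sprintf("header names %d tissues but rows have %d value columns in %s",
                 length(tissues), nt, path))
  bad <- which(n_col != nt + 1L)
  if (length(bad))
    stop(sprintf("malformed expression line %d in %s", src$lineno[-1][bad[1]], path))
  mirnas <- trimws(vapply(body, `[[`, "", 1L))
  if (anyDuplicated(.norm_name(mirnas)))
    stop("duplicate miRNA row in ", path, ": ",
         mirnas[duplicated(.norm_name(mirnas))][1])
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(nt)))
  E <- if (nt == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(E)) {
    bad_row <- which(rowSums(is.na(E)) > 0)[1]
    stop(sprintf("non-numeric expression value at line %d in %s",
                 src$lineno[-1][bad_row], path))
  }
  ep <- expression_profiles(E, mirnas, tissues)
  if (any(ep$zero_variance))
    warning(sprintf("%d zero-variance expression rows flagged (Pearson undefined): %s",
                    sum(ep$zero_variance),
                    paste(head(mirnas[ep$zero_variance], 5), collapse = ", ")))
  ep
}

#' Write expression profiles as TSV (inverse of [read_expression()])
#'
#' @param profiles an [expression_profiles()] object.
#' @param path output path.
#' @export
write_expression <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("mirna", profiles$tissue_names), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(profiles$E)), function(i)
    paste(c(profiles$mirnas[i],
            format(profiles$E[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

#' Write per-disease miRNA rankings as TSV
#'
#' Four columns: disease, rank (1-based), miRNA, score. Within a disease,
#' rows are sorted by descending score with ties broken by miRNA name
#' (lexicographic), so output is deterministic. Diseases with no candidates
#' are omitted with a warning.
#'
#' @param scores named list: per disease, a named numeric vector of
#'   candidate miRNA scores.
#' @param path output path.
#' @param top_n optional cap on rows per disease.
#' @export
write_rankings <- function(scores, path, top_n = NULL) {
  rows <- vector("list", length(scores))
  for (i in seq_along(scores)) {
    s <- scores[[i]]
    d <- names(scores)[i]
    if (length(s) == 0) {
      warning("no candidate miRNAs for disease ", d, "; omitted")
      next
    }
    if (any(!is.finite(s))) stop("non-finite score for disease ", d)
    ord <- order(-s, names(s))
    s <- s[ord]
    if (!is.null(top_n)) s <- head(s, top_n)
    rows[[i]] <- data.frame(disease = d, rank = seq_along(s),
                            mirna = names(s), score = unname(s),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
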