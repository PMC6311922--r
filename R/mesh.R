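.mesh_code_pattern <- "^[A-Za-z][0-9]+(\\.[0-9]+)*$"

# all prefixes of a dotted MeSH tree code, from the code itself up to the
# top-level letter+digits root (C01.252.400 -> C01.252.400, C01.252, C01)
.code_chain <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(rev(seq_along(parts)),
         function(k) paste(parts[1:k], collapse = "."), "")
}

#' Construct a MeSH tree-code forest for diseases
#'
#' Each disease maps to one or more dotted MeSH tree codes (for example
#' `"C01.252"`). A disease's directed acyclic graph `DAG(D) = (T(D), E(D))`
#' is the union, over its codes, of the chain of prefixes obtained by
#' repeatedly removing the last dotted component; edges run from each
#' parent prefix to its child. The disease itself sits at its code(s);
#' all proper prefixes are ancestor diseases.
#'
#' @param disease_codes named list: disease name -> character vector of
#'   dotted tree codes.
#' @return object of class `mesh_forest` with elements `disease_codes`
#'   (the validated input) and `dags` (per disease: list with `nodes`
#'   = `T(D)`, `edges` = two-column parent/child matrix `E(D)`, and
#'   `roots` = the disease's own codes).
#' @export
mesh_forest <- function(disease_codes) {
  if (is.null(names(disease_codes)) || any(!nzchar(names(disease_codes))))
    stop("disease_codes must be a named list")
  dags <- lapply(names(disease_codes), function(d) {
    codes <- unique(trimws(as.character(disease_codes[[d]])))
    bad <- codes[!grepl(.mesh_code_pattern, codes)]
    if (length(bad))
      stop(sprintf("invalid MeSH tree code for disease '%s': '%s'", d, bad[1]))
    chains <- lapply(codes, .code_chain)
    nodes <- unique(unlist(chains))
    edges <- do.call(rbind, lapply(chains, function(ch) {
      if (length(ch) < 2) NULL else cbind(parent = ch[-1], child = ch[-length(ch)])
    }))
    edges <- if (is.null(edges)) {
      matrix(character(), 0, 2, dimnames = list(NULL, c("parent", "child")))
    } else unique(edges)
    list(nodes = nodes, edges = edges, roots = codes)
  })
  names(dags) <- names(disease_codes)
  structure(list(disease_codes = disease_codes, dags = dags),
            class = "mesh_forest")
}

#' @export
print.mesh_forest <- function(x, ...) {
  cat(sprintf("MeSH forest: %d diseases, %d distinct tree codes\n",
              length(x$dags),
              length(unique(unlist(lapply(x$dags, `[[`, "nodes"))))))
  invisible(x)
}

#' Read a disease-to-MeSH mapping from TSV
#'
#' Two columns per line: disease name, then its tree codes joined by `;`.
#' Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @return a [mesh_forest()].
#' @export
read_mesh <- function(path) {
  src <- .read_tsv_lines(path)
  if (length(src$lines) == 0) stop("empty MeSH mapping file: ", path)
  parts <- strsplit(src$lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop(sprintf("malformed MeSH line %d in %s", src$lineno[bad[1]], path))
  diseases <- trimws(vapply(parts, `[[`, "", 1L))
  codes <- lapply(parts, function(p) trimws(strsplit(p[[2]], ";", fixed = TRUE)[[1]]))
  if (anyDuplicated(.norm_name(diseases)))
    stop("duplicate disease entry in ", path)
  names(codes) <- diseases
  mesh_forest(codes)
}

#' Write a disease-to-MeSH mapping as TSV (inverse of [read_mesh()])
#'
#' @param forest a [mesh_forest()].
#' @param path output path.
#' @export
write_mesh <- function(forest, path) {
  lines <- vapply(names(forest$disease_codes), function(d)
    paste(d, paste(forest$dags[[d]]$roots, collapse = ";"), sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Semantic contribution of ancestors to a disease
#'
#' Within `DAG(D)` the disease's own code layer contributes 1; an ancestor
#' node contributes `delta` times the largest contribution among its
#' children in the DAG, so the contribution decays geometrically with
#' distance from the disease and, where a node is reachable along several
#' paths, the shortest (most-contributing) path wins. The aggregate
#' semantic value `AC(D)` is the sum of contributions over `T(D)`.
#'
#' @param forest a [mesh_forest()].
#' @param disease disease name (matched case-insensitively, trimmed).
#' @param delta decay parameter in (0, 1); default 0.5.
#' @return list with `disease`, `contributions` (named numeric over
#'   `T(D)`) and `aggregate` (`AC(D)`).
#' @export
semantic_contributions <- function(forest, disease, delta = 0.5) {
  stopifnot(delta > 0, delta < 1)
  i <- match(.norm_name(disease), .norm_name(names(forest$dags)))
  if (is.na(i)) stop("disease not in MeSH forest: ", disease)
  dag <- forest$dags[[i]]
  nodes <- dag$nodes
  depth <- lengths(strsplit(nodes, ".", fixed = TRUE))
  C <- setNames(rep(NA_real_, length(nodes)), nodes)
  C[dag$roots] <- 1
  # bottom-up: children are strictly deeper, so descending depth order works
  for (nd in nodes[order(-depth)]) {
    children <- dag$edges[dag$edges[, "parent"] == nd, "child"]
    val <- if (length(children)) delta * max(C[children]) else -Inf
    C[nd] <- max(val, if (nd %in% dag$roots) 1 else -Inf)
  }
  if (anyNA(C) || any(C <= 0)) stop("internal error: incomplete contribution recursion")
  list(disease = names(forest$dags)[i], contributions = C,
       aggregate = sum(C))
}
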