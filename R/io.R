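#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], ": need name, description, >=1 gene",
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1L), 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}

#' Read an expression study from TSV files
#'
#' @param matrix_path TSV: first column feature ids, remaining columns
#'   samples, header row of sample ids.
#' @param labels_path TSV with columns `sample` and `group`.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, labels_path) {
  m <- utils::read.delim(matrix_path, row.names = 1L, check.names = FALSE)
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(lab))) {
    stop("labels file needs columns `sample` and `group`", call. = FALSE)
  }
  idx <- match(colnames(m), lab$sample)
  if (anyNA(idx)) stop("sample(s) missing from labels file", call. = FALSE)
  expression_study(as.matrix(m), lab$group[idx])
}

#' Write an expression study to TSV files
#'
#' @param study An [expression_study()].
#' @param matrix_path,labels_path Output paths.
#' @export
write_expression_study <- function(study, matrix_path, labels_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(feature = rownames(study$exprs), study$exprs,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(study$exprs),
                                group = as.character(study$labels)),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene`, `t`, `p` and optionally `df`.
#' @return A `de_result`.
#' @export
read_de_result <- function(path) {
  de_result(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a differential-expression table
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @export
write_de_result <- function(de, path) {
  stopifnot(inherits(de, "de_result"))
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a network as an edge-list TSV
#'
#' @param net An `igraph` network with a `confidence` edge attribute.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  conf <- igraph::E(net)$confidence
  if (is.null(conf)) conf <- rep(1, nrow(el))
  utils::write.table(data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                                score = conf),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
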