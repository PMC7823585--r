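#' Gene-by-sample expression matrix with cohort and unit tags
#'
#' Lightweight container used throughout the pipeline.  The `values` slot is a
#' plain numeric matrix (genes in rows, samples in columns); `cohort` tags the
#' cohort the samples belong to and `unit` records what scale the values are
#' on.  Duplicate gene identifiers are averaged on the raw scale at
#' construction, mirroring the usual handling of repeated identifiers when
#' loading public expression tables.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids) and
#'   samples in columns (colnames = sample ids).
#' @param cohort single string naming the cohort.
#' @param unit one of `"counts"`, `"CPM"`, `"logCPM"`, `"TPM"`, `"zscore"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, cohort = "cohort1",
                        unit = c("counts", "CPM", "logCPM", "TPM", "zscore")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("expression matrix needs gene ids as rownames")
  }
  if (is.null(colnames(values))) {
    stop("expression matrix needs sample ids as colnames")
  }
  storage.mode(values) <- "double"
  if (anyDuplicated(rownames(values))) {
    warning("duplicate gene ids averaged on the raw scale")
    values <- rowsum(values, group = rownames(values), reorder = FALSE) /
      as.vector(table(rownames(values))[unique(rownames(values))])
  }
  if (unit == "counts" && any(values < 0)) {
    stop("counts must be non-negative")
  }
  structure(list(values = values, cohort = as.character(cohort)[1],
                 unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, cohort '%s', unit '%s'\n",
              nrow(x$values), ncol(x$values), x$cohort, x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Accept either an expr_matrix or a bare matrix; optionally insist on a unit.
expr_values <- function(x, unit = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (!is.null(unit) && !x$unit %in% unit) {
      stop(sprintf("expected unit '%s', got '%s'",
                   paste(unit, collapse = "/"), x$unit))
    }
    x$values
  } else if (is.matrix(x)) {
    x
  } else {
    stop("expected an expr_matrix or a matrix")
  }
}

#' Read / write gene-by-sample TSV matrices
#'
#' The on-disk format is a tab-separated table with a header row of sample
#' ids; the first column holds gene ids.  Duplicate gene ids are averaged at
#' load.
#'
#' @param path file path.
#' @param cohort,unit passed to [expr_matrix()].
#' @return [read_expression_tsv()] returns an `expr_matrix`;
#'   [write_expression_tsv()] returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, cohort = "cohort1", unit = "counts") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- genes
  expr_matrix(m, cohort = cohort, unit = unit)
}

#' @rdname read_expression_tsv
#' @param x `expr_matrix` or matrix to write.
#' @export
write_expression_tsv <- function(x, path) {
  m <- expr_values(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids, with the source file
#'   recorded in the `"source"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-c(1L, 2L)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
  attr(sets, "source") <- basename(path)
  sets
}

#' Restrict gene sets to an expression universe and to a size window
#'
#' Sets are intersected with `universe` and only sets whose post-intersection
#' size falls in `[min_size, max_size]` are kept (15-500 by default, the
#' conventional window for pathway collections).
#'
#' @param sets named list of gene-id vectors.
#' @param universe character vector of measured gene ids.
#' @param min_size,max_size inclusive size bounds after intersection.
#' @return Filtered named list.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 15, max_size = 500) {
  sets <- lapply(sets, intersect, y = universe)
  keep <- vapply(sets, length, integer(1))
  sets[keep >= min_size & keep <= max_size]
}

#' Read a gene-signature file
#'
#' One gene id per line; comment lines starting with `#` may carry
#' `# name: <label>` and `# mode: <mean_z|ca20>` headers.
#'
#' @param path signature file path.
#' @return List with `name`, `mode` and `genes`.
#' @export
read_signature <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- lines[startsWith(lines, "#")]
  genes <- lines[!startsWith(lines, "#")]
  pick <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1L]))
  }
  list(name = pick("name", basename(path)),
       mode = match.arg(pick("mode", "mean_z"), c("mean_z", "ca20")),
       genes = unique(genes))
}
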