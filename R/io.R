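# Readers/writers for the package's plain-text interchange formats:
# expression TSV (genes x samples, first column the gene ID), sample
# annotation TSV, survival TSV, and GMT gene-set collections.

#' Read a gene x sample expression matrix from TSV
#'
#' @param path Path to a tab-separated file with a header of sample IDs and
#'   gene IDs in the first column.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene IDs in ", path, ": ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
  }
  x <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric expression values in ", path)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("missing values are not permitted (first at gene ", genes[bad[1L]],
         ", sample ", colnames(x)[bad[2L]], ") in ", path)
  }
  rownames(x) <- genes
  .checkSampleIDs(colnames(x), path)
  x
}

#' Write an expression matrix as TSV at full double precision
#'
#' @param x Numeric matrix, genes x samples.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  dt <- data.table::data.table(gene = rownames(x))
  for (j in colnames(x)) data.table::set(dt, j = j, value = x[, j])
  ok <- tryCatch({
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write expression matrix to ", path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' @param path TSV with at least columns `sample`, `subtype`, `patient`.
#' @return A `data.frame`.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "subtype", "patient")
  if (!all(need %in% colnames(ann))) {
    stop(path, " must contain columns: ", paste(need, collapse = ", "))
  }
  .checkSampleIDs(ann$sample, path)
  ann
}

#' Read a survival table
#'
#' @param path TSV with columns `sample`, `os_time`, `event`.
#' @return A `data.frame` with positive times and 0/1 events.
#' @export
readSurvivalTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  surv <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "os_time", "event")
  if (!all(need %in% colnames(surv))) {
    stop(path, " must contain columns: ", paste(need, collapse = ", "))
  }
  .checkSampleIDs(surv$sample, path)
  if (any(surv$os_time <= 0)) stop("survival times must be positive in ", path)
  if (!all(surv$event %in% c(0L, 1L))) {
    stop("event indicator must be 0 or 1 in ", path)
  }
  surv
}

#' Parse a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate members within a set are dropped with a warning; lines with
#' fewer than three fields (i.e. empty sets) are an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors, with per-set descriptions in
#'   `attr(, "description")`.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) <= 2L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected name, description and at least one gene")
    }
    genes <- f[-c(1L, 2L)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop("malformed GMT line ", i, " in ", path, ": empty set")
    }
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1L], "' (line ", i,
              ") deduplicated")
      genes <- unique(genes)
    }
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(descs, nms)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions (recycled "na" if
#'   missing).
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("failed to write GMT to ", path)
  invisible(path)
}
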