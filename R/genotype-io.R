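#' Missing-value dialect for genotype matrix files
#'
#' Single-cell SNV matrices encode "no call" with various tokens; the de-facto
#' convention writes 3. All tokens in \code{sentinels} are read as missing;
#' \code{writeToken} is used on write and must be one of the sentinels.
#'
#' @param sentinels character vector of tokens treated as missing on read.
#' @param writeToken single token used to encode missing entries on write.
#' @return a list of class \code{missingDialect}.
#' @examples
#' missingDialect()                      # "3", "NA", "-", "" read as missing
#' missingDialect(c("?", "NA"), "?")
#' @export
missingDialect <- function(sentinels = MISSING_TOKENS_DEFAULT, writeToken = "3") {
  sentinels <- as.character(sentinels)
  if (length(sentinels) == 0L) stop("'sentinels' must be non-empty")
  if (!writeToken %in% sentinels)
    stop("'writeToken' must be one of the sentinels")
  structure(list(sentinels = sentinels, writeToken = writeToken),
            class = "missingDialect")
}

#' Construct a GenotypeMatrix from an R matrix
#'
#' @param values numeric matrix with entries 0, 1 or NA (missing).
#' @param cellIds,siteIds optional row/column labels; generated
#'   (\code{cell_0001}, \code{site_0001}) when absent.
#' @return a [GenotypeMatrix-class].
#' @examples
#' genotypeMatrix(rbind(c(1, NA), c(0, 1)))
#' @export
genotypeMatrix <- function(values, cellIds = NULL, siteIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cellIds)) cellIds <- rownames(values)
  if (is.null(siteIds)) siteIds <- colnames(values)
  if (is.null(cellIds)) cellIds <- sprintf("cell_%04d", seq_len(nrow(values)))
  if (is.null(siteIds)) siteIds <- sprintf("site_%04d", seq_len(ncol(values)))
  dimnames(values) <- list(cellIds, siteIds)
  new("GenotypeMatrix", values = values,
      cellIds = as.character(cellIds), siteIds = as.character(siteIds))
}

.sniffDelimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genotype matrix from a delimited text file
#'
#' Reads a rectangular TSV/CSV of binary mutation calls with missing entries
#' encoded by a sentinel token and normalizes it to the cells-as-rows
#' orientation. A header row and/or a leading row-label column are detected
#' automatically (any field that is not a genotype token marks them as labels)
#' and used as ids.
#'
#' @param path file path.
#' @param dialect a [missingDialect()].
#' @param orientation \code{"cells_as_rows"} (default) or
#'   \code{"sites_as_rows"}; the result always has cells as rows.
#' @param delimiter field separator; inferred from the extension when NULL
#'   (\code{.csv} is comma, anything else tab).
#' @return a [GenotypeMatrix-class].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("1,3", "0,1"), p)
#' readGenotypeMatrix(p)
#' @export
readGenotypeMatrix <- function(path, dialect = missingDialect(),
                               orientation = c("cells_as_rows", "sites_as_rows"),
                               delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- .sniffDelimiter(path, delimiter)
  lines <- readLines(path)
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("empty input file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged table: line %d has %d field(s), expected %d",
                 bad, widths[bad], widths[1L]))
  }
  tokens <- c("0", "1", dialect$sentinels)
  isDataTok <- function(x) trimws(x) %in% tokens
  headerRow <- !all(isDataTok(fields[[1L]][-1L]))  # first field may be a corner label
  colLabels <- if (headerRow) trimws(fields[[1L]]) else NULL
  if (headerRow) fields <- fields[-1L]
  if (length(fields) == 0L) stop("no data rows in: ", path)
  labelCol <- !all(vapply(fields, function(f) isDataTok(f[1L]), TRUE))
  rowLabels <- if (labelCol) vapply(fields, function(f) trimws(f[1L]), "") else NULL
  if (labelCol) {
    fields <- lapply(fields, function(f) f[-1L])
    if (headerRow && length(colLabels) > length(fields[[1L]]))
      colLabels <- colLabels[-1L]
  }
  nr <- length(fields); nc <- length(fields[[1L]])
  m <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    f <- trimws(fields[[i]])
    miss <- f %in% dialect$sentinels
    bad <- !miss & !f %in% c("0", "1")
    if (any(bad)) {
      j <- which(bad)[1L]
      stop(sprintf("invalid token '%s' at data row %d, column %d", f[j], i, j))
    }
    m[i, !miss] <- as.numeric(f[!miss])
  }
  if (orientation == "sites_as_rows") {
    m <- t(m)
    tmp <- rowLabels; rowLabels <- colLabels; colLabels <- tmp
  }
  if (all(is.na(m))) stop("degenerate input: every entry is missing")
  genotypeMatrix(m, cellIds = rowLabels, siteIds = colLabels)
}

#' Write a GenotypeMatrix to a delimited text file
#'
#' Inverse of [readGenotypeMatrix()]: cells as rows, header row of site ids,
#' leading column of cell ids, missing entries encoded with the dialect's
#' write token. \code{read(write(g))} is the identity on values, the observed
#' set and the labels.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file path.
#' @param dialect a [missingDialect()].
#' @param delimiter field separator; inferred from the extension when NULL.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeMatrix <- function(g, path, dialect = missingDialect(),
                                delimiter = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  sep <- .sniffDelimiter(path, delimiter)
  v <- g@values
  ch <- matrix(as.character(v), nrow(v), ncol(v))
  ch[is.na(v)] <- dialect$writeToken
  lines <- c(paste(c("cell_id", g@siteIds), collapse = sep),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(g@cellIds[i], ch[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Encode a GenotypeMatrix for the decomposition
#'
#' Applies the projection onto the observed-index set Omega: missing entries
#' are zero-filled in \code{X} and flagged 0 in \code{omegaMask}. The mask is
#' the single source of truth for observedness; an observed 0 and a missing
#' entry both appear as 0 in \code{X} but differ in the mask.
#'
#' @param g a [GenotypeMatrix-class].
#' @return list with \code{X} (n x m numeric, zero-filled) and
#'   \code{omegaMask} (n x m in \{0,1\}, 1 = observed).
#' @export
encodeForRDA <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  v <- g@values
  mask <- 1 - is.na(v)
  v[is.na(v)] <- 0
  dimnames(mask) <- dimnames(v)
  list(X = v, omegaMask = mask)
}

# order sites into presentation blocks by clustering the transposed call
# matrix with the same kNN-Jaccard-Louvain machinery (display only, never an
# inference step); falls back to the original order on any failure
.siteOrder <- function(calls, seed = 1L) {
  m <- ncol(calls)
  if (m < 4L) return(seq_len(m))
  ord <- tryCatch({
    a <- clusterSubclones(t(calls),
                          clusterConfig(kNeighbors = min(10L, m - 1L), seed = seed))
    order(a@labels, seq_len(m))
  }, error = function(e) seq_len(m), warning = function(w) seq_len(m))
  ord
}

#' Write the pipeline's tabular outputs
#'
#' Writes the standard artifact set for one run: \code{recovered.tsv} (binary
#' calls, cells ordered by subclone label then original index, sites ordered
#' by presentation blocks), \code{sparse.tsv}, \code{labels.tsv},
#' \code{subclone_genotypes.tsv}, \code{tree.nwk}, \code{tree_edges.tsv},
#' \code{metrics.json} and \code{convergence.tsv}.
#'
#' @param run a pipeline result list as returned by [runPipeline()] (fields
#'   \code{genotypes}, \code{decomposition}, \code{assignment}, \code{tree},
#'   \code{metrics}).
#' @param outdir output directory, created if needed.
#' @return character vector of the files written, invisibly.
#' @export
writeOutputs <- function(run, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("output directory is not writable: ", outdir)
  unlink(probe)

  g <- run$genotypes; dec <- run$decomposition
  asg <- run$assignment; tree <- run$tree
  calls <- dec@genotypeCalls
  cellOrd <- order(asg@labels, seq_along(asg@labels))
  siteOrd <- .siteOrder(calls)
  files <- character(0)
  wtab <- function(x, name, rn = TRUE) {
    p <- file.path(outdir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = NA)
    files <<- c(files, p)
  }
  ids <- cellIds(g); sids <- siteIds(g)
  dimnames(calls) <- list(ids, sids)
  wtab(calls[cellOrd, siteOrd, drop = FALSE], "recovered.tsv")
  Smat <- dec@S; dimnames(Smat) <- list(ids, sids)
  wtab(round(Smat[cellOrd, siteOrd, drop = FALSE], 6), "sparse.tsv")

  p <- file.path(outdir, "labels.tsv")
  utils::write.table(
    data.frame(cell_id = ids, subclone_label = asg@labels),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)

  cons <- tree@consensus
  dimnames(cons) <- list(sprintf("subclone_%d", seq_len(nrow(cons)) - 1L), sids)
  wtab(cons, "subclone_genotypes.tsv")

  p <- file.path(outdir, "tree.nwk")
  writeLines(tree@newick, p); files <- c(files, p)

  p <- file.path(outdir, "tree_edges.tsv")
  utils::write.table(tree@edges, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)

  p <- file.path(outdir, "metrics.json")
  metrics <- if (is.null(run$metrics)) structure(list(), names = character(0)) else run$metrics
  jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  files <- c(files, p)

  p <- file.path(outdir, "convergence.tsv")
  utils::write.table(dec@trace, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  invisible(files)
}
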