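## Readers and writers for the three standard inputs (association pair
## table, DAG edge lists, dense similarity matrices) and the ranked
## prediction output. All files are tab-separated; a comma delimiter is
## autodetected.

.detectSep <- function(line) if (grepl("\t", line)) "\t" else ","

.readDelimLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  lines
}

#' Read a two-column miRNA-disease association pair table
#'
#' Each row names one supported (miRNA, disease) pair. Entities are
#' indexed in first-appearance order; a header row is skipped when its
#' fields look like column labels. Duplicated pairs are collapsed to a
#' single 1-entry with a warning.
#'
#' @param path path to a 2-column TSV (comma autodetected).
#' @return an \linkS4class{AssociationMatrix}
#' @export
readAssociationPairs <- function(path) {
  lines <- .readDelimLines(path)
  sep <- .detectSep(lines[1L])
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop(sprintf("malformed row at line %d: expected 2 fields, got %d",
                 which(nf != 2L)[1L], nf[nf != 2L][1L]), call. = FALSE)
  first <- tolower(trimws(fields[[1L]]))
  if (any(grepl("^mi?rna$|^disease$|^name$", first)))
    fields <- fields[-1L]
  if (!length(fields)) stop("no data rows in ", path, call. = FALSE)
  mir <- trimws(vapply(fields, `[[`, character(1), 1L))
  dis <- trimws(vapply(fields, `[[`, character(1), 2L))
  dup <- duplicated(paste(mir, dis, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("%d duplicated pair(s) collapsed", sum(dup)),
            call. = FALSE)
    mir <- mir[!dup]; dis <- dis[!dup]
  }
  associationFromPairs(mir, dis)
}

#' Build an AssociationMatrix from pair vectors
#'
#' @param mirna,disease character vectors of equal length naming pairs.
#' @param mirnaLevels,diseaseLevels optional full entity vocabularies
#'   (defaults to first-appearance order of the pairs).
#' @return an \linkS4class{AssociationMatrix}
#' @export
associationFromPairs <- function(mirna, disease,
                                 mirnaLevels = unique(mirna),
                                 diseaseLevels = unique(disease)) {
  a <- matrix(0, length(mirnaLevels), length(diseaseLevels),
              dimnames = list(mirnaLevels, diseaseLevels))
  a[cbind(match(mirna, mirnaLevels), match(disease, diseaseLevels))] <- 1
  AssociationMatrix(a)
}

#' Read a collection of disease ancestor DAGs
#'
#' Flat edge-list dialect: three columns (disease-id, parent, child), one
#' row per edge of that disease's DAG. A row whose parent and child fields
#' are both empty (or ".") declares a disease whose DAG is the target
#' alone. A cycle raises an error naming the disease.
#'
#' @param path path to a 3-column TSV (comma autodetected).
#' @return a \linkS4class{DAGCollection}
#' @export
readDagCollection <- function(path) {
  lines <- .readDelimLines(path)
  sep <- .detectSep(lines[1L])
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, function(f) { length(f) <- 3L; trimws(f) })
  nf <- lengths(lapply(strsplit(lines, sep, fixed = TRUE), identity))
  if (any(nf < 1L | nf > 3L))
    stop(sprintf("malformed row at line %d", which(nf > 3L | nf < 1L)[1L]),
         call. = FALSE)
  first <- tolower(fields[[1L]])
  if (any(grepl("^disease$|^parent$|^child$", first)))
    fields <- fields[-1L]
  dis <- vapply(fields, `[[`, character(1), 1L)
  par <- vapply(fields, `[[`, character(1), 2L)
  chd <- vapply(fields, `[[`, character(1), 3L)
  par[is.na(par) | par == "."] <- ""
  chd[is.na(chd) | chd == "."] <- ""
  dags <- lapply(unique(dis), function(d) {
    sel <- dis == d & nzchar(par) & nzchar(chd)
    edges <- cbind(parent = par[sel], child = chd[sel])
    DiseaseDAG(d, edges)
  })
  DAGCollection(dags)
}

#' Read / write a dense similarity matrix
#'
#' The file is a dense square table with a header row and a leading name
#' column; row and column headers must agree. On read, asymmetry beyond
#' 1e-6 is reported with a warning and the matrix is symmetrized by
#' averaging with its transpose.
#'
#' @param path file path.
#' @return a \linkS4class{SimilarityMatrix}
#' @export
readSimilarityMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- .detectSep(first)
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(tab)
  if (nrow(v) != ncol(v))
    stop("similarity matrix must be square", call. = FALSE)
  if (anyNA(v)) stop("NaN/NA entry in similarity matrix", call. = FALSE)
  if (!identical(rownames(v), colnames(v)))
    stop("row and column headers must match", call. = FALSE)
  asym <- max(abs(v - t(v)))
  if (asym > 1e-6)
    warning(sprintf("asymmetry %.3g symmetrized by averaging", asym),
            call. = FALSE)
  v <- (v + t(v)) / 2
  SimilarityMatrix(v)
}

#' @rdname readSimilarityMatrix
#' @param sim a \linkS4class{SimilarityMatrix} to write.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  v <- simValues(sim)
  df <- data.frame(name = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("name", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ranked prediction table
#'
#' Rows are ordered by decreasing score with ties broken by miRNA id then
#' disease id; ranks are re-derived from that ordering (1..K, no gaps).
#'
#' @param table data.frame with columns miRNA, disease, score.
#' @param path output path (4-column TSV with header).
#' @return the ranked data.frame, invisibly.
#' @export
writePredictions <- function(table, path) {
  stopifnot(all(c("miRNA", "disease", "score") %in% colnames(table)))
  if (nrow(table)) {
    o <- order(-table$score, table$miRNA, table$disease)
    table <- table[o, c("miRNA", "disease", "score"), drop = FALSE]
    table$rank <- seq_len(nrow(table))
  } else {
    table <- data.frame(miRNA = character(), disease = character(),
                        score = numeric(), rank = integer())
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
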