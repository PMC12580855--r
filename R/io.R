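#' Read / write abundance matrices and traits as TSV
#'
#' Abundance TSV layout: proteins in rows, first column the protein id,
#' remaining columns the sample ids. Traits TSV: one row per sample with a
#' \code{sample_id} column. Missing values are empty fields.
#'
#' @param path file path.
#' @return \code{readAbundanceTsv}: numeric matrix with dimnames.
#' @export
readAbundanceTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readAbundanceTsv
#' @param x matrix or SummarizedExperiment to write.
#' @export
writeAbundanceTsv <- function(x, path) {
  X <- .abundance(x)
  df <- data.frame(protein_id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname readAbundanceTsv
#' @export
readTraitsTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                   stringsAsFactors = FALSE)
  rownames(df) <- df$sample_id
  df
}

#' @rdname readAbundanceTsv
#' @param traits traits data.frame to write.
#' @export
writeTraitsTsv <- function(traits, path) {
  write.table(.traits(traits), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene/protein sets from a GMT file
#'
#' GMT: one set per line, tab-separated: set name, description, then member
#' ids (ragged rows).
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)][nzchar(parts[-(1:2)])]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write / read a co-expression network as JSON
#'
#' Serializes parameters, module labels and the kME table; eigenproteins
#' travel as a separate TSV written by [writeAbundanceTsv()] if needed.
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param path JSON file path.
#' @export
writeNetworkJson <- function(network, path) {
  obj <- list(
    params = network@params,
    module_of_protein = as.list(network@moduleLabels),
    kme = list(proteins = rownames(network@kme),
               modules = colnames(network@kme),
               values = unname(apply(network@kme, 1, as.numeric,
                                     simplify = FALSE))),
    var_explained = as.list(network@varExplained)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}

#' @rdname writeNetworkJson
#' @return \code{readNetworkJson}: list with \code{params},
#'   \code{moduleLabels} and \code{kme}.
#' @export
readNetworkJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  kme <- obj$kme$values
  if (is.list(kme)) kme <- do.call(rbind, kme)
  dimnames(kme) <- list(obj$kme$proteins, obj$kme$modules)
  list(params = obj$params,
       moduleLabels = unlist(obj$module_of_protein),
       kme = kme,
       varExplained = unlist(obj$var_explained))
}
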