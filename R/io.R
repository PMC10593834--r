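#' Read gene signatures from a GMT file
#'
#' Broad-dialect GMT: one gene set per line, tab-separated fields
#' \code{name}, \code{description}, then gene ids. Paired sets named
#' \code{<name>_UP} and \code{<name>_DN} are merged into one two-sided
#' signature \code{<name>}; a \code{_UP} (or \code{_DN}) set without its
#' partner yields a one-sided signature; a set without either suffix is read
#' as an up-only signature.
#'
#' @param path path to a GMT file.
#' @return A named list of \code{\link{gene_signature}} objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " in ", path,
         ": expected at least 3 tab-separated fields")
  set_names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(set_names))
    stop("duplicate set name in GMT file: ",
         set_names[duplicated(set_names)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  descs <- vapply(fields, `[[`, "", 2L)
  names(sets) <- names(descs) <- set_names

  base <- sub("_(UP|DN)$", "", set_names)
  side <- ifelse(grepl("_UP$", set_names), "up",
                 ifelse(grepl("_DN$", set_names), "down", "up"))
  out <- list()
  for (b in unique(base)) {
    idx <- which(base == b)
    up <- unlist(sets[idx[side[idx] == "up"]], use.names = FALSE)
    down <- unlist(sets[idx[side[idx] == "down"]], use.names = FALSE)
    out[[b]] <- gene_signature(up = up, down = down, name = b,
                               provenance = descs[[idx[1L]]])
  }
  out
}

#' Write gene signatures to a GMT file
#'
#' Inverse of \code{\link{read_gmt}}: each non-empty side of every signature
#' becomes one \code{<name>_UP} / \code{<name>_DN} line. Reading the file
#' back recovers the signatures (sets are order-insensitive).
#'
#' @param signatures a \code{gene_signature} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- character()
  for (sig in signatures) {
    desc <- if (is.na(sig$provenance)) "na" else sig$provenance
    if (length(sig$up))
      lines <- c(lines, paste(c(paste0(sig$name, "_UP"), desc, sig$up),
                              collapse = "\t"))
    if (length(sig$down))
      lines <- c(lines, paste(c(paste0(sig$name, "_DN"), desc, sig$down),
                              collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a log2 expression matrix as TSV
#'
#' Layout: first column gene id, header row sample ids. The companion
#' sample-group map is a two-column TSV (\code{sample}, \code{group}).
#'
#' @param path TSV path.
#' @return \code{read_expression_tsv}: numeric matrix genes x samples.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @rdname read_expression_tsv
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression_tsv
#' @export
read_sample_groups <- function(path) {
  if (!file.exists(path)) stop("sample-group file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("sample-group map needs two columns: ", path)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_expression_tsv
#' @param groups named character vector, sample id -> group label.
#' @export
write_sample_groups <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a ranked-list (RNK) profile
#'
#' Two-column TSV without header: gene id, delta.
#'
#' @param path TSV path.
#' @param compound_id id for the returned profile (default: file base name).
#' @return \code{read_rnk}: a \code{\link{change_profile}}.
#' @export
read_rnk <- function(path, compound_id = NULL) {
  if (!file.exists(path)) stop("RNK file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.null(compound_id))
    compound_id <- tools::file_path_sans_ext(basename(path))
  change_profile(compound_id, universe = as.character(df[[1L]]),
                 delta = as.numeric(df[[2L]]))
}

#' @rdname read_rnk
#' @param profile a \code{\link{change_profile}}.
#' @export
write_rnk <- function(profile, path) {
  utils::write.table(data.frame(profile$universe, profile$delta),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a compound library matrix as TSV
#'
#' Layout: first column compound id, header row = gene universe; optional
#' metadata TSV with columns \code{compound_id}, \code{name},
#' \code{source_library}.
#'
#' @param path TSV path.
#' @param metadata_path optional metadata TSV path.
#' @return \code{read_library_tsv}: a \code{\link{compound_library}}.
#' @export
read_library_tsv <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("library file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  meta <- NULL
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path))
      stop("metadata file not found: ", metadata_path)
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  }
  compound_library(m, metadata = meta)
}

#' @rdname read_library_tsv
#' @param lib a \code{\link{compound_library}}.
#' @export
write_library_tsv <- function(lib, path) {
  df <- data.frame(compound_id = rownames(lib$delta), lib$delta,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
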