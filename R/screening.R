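#' Construct a compound library of change profiles on a shared universe
#'
#' @param delta numeric matrix, compounds x genes: rownames are unique
#'   compound ids, colnames the shared ordered gene universe. All entries
#'   finite.
#' @param metadata optional data.frame with a \code{compound_id} column and
#'   e.g. \code{name}, \code{source_library}.
#' @return An object of class \code{compound_library} with elements
#'   \code{delta}, \code{universe}, \code{metadata}.
#' @export
compound_library <- function(delta, metadata = NULL) {
  if (!is.matrix(delta) || !is.numeric(delta))
    stop("'delta' must be a numeric matrix (compounds x genes)")
  if (nrow(delta) > 0 &&
      (is.null(rownames(delta)) || anyDuplicated(rownames(delta))))
    stop("'delta' must have unique rownames (compound ids)")
  if (is.null(colnames(delta)) || anyDuplicated(colnames(delta)))
    stop("'delta' must have unique colnames (gene universe)")
  if (any(!is.finite(delta))) stop("non-finite delta values in library")
  if (!is.null(metadata)) {
    if (!"compound_id" %in% names(metadata))
      stop("'metadata' needs a compound_id column")
    metadata <- metadata[match(rownames(delta), metadata$compound_id), ,
                         drop = FALSE]
  }
  structure(list(delta = delta, universe = colnames(delta),
                 metadata = metadata),
            class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  cat("Compound library:", nrow(x$delta), "compounds x",
      length(x$universe), "genes\n")
  invisible(x)
}

#' @export
length.compound_library <- function(x) nrow(x$delta)

lib_profile <- function(lib, i) {
  change_profile(rownames(lib$delta)[i], lib$universe, lib$delta[i, ])
}

#' Score every library compound against one signature
#'
#' Each compound's profile is ranked and scored by
#' \code{\link{enrichment_score}} (orientation \code{"mimic"}: compounds
#' inducing the signature score high) or \code{\link{reversal_score}}
#' (orientation \code{"reverse"}: compounds opposing the signature score
#' high). The signature is restricted to the library universe first; genes
#' outside it are dropped with a warning.
#'
#' @param lib a \code{\link{compound_library}}.
#' @param sig a \code{\link{gene_signature}}.
#' @param orientation \code{"mimic"} or \code{"reverse"}.
#' @return Named numeric vector of scores in library order.
#' @export
score_library <- function(lib, sig, orientation = c("mimic", "reverse")) {
  stopifnot(inherits(lib, "compound_library"))
  orientation <- match.arg(orientation)
  if (nrow(lib$delta) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  sig <- restrict_to_universe(sig, lib$universe)
  scores <- vapply(seq_len(nrow(lib$delta)), function(i) {
    res <- enrichment_score(rank_profile(lib_profile(lib, i)), sig)
    if (orientation == "mimic") res$score else res$reversal_score
  }, numeric(1))
  stats::setNames(scores, rownames(lib$delta))
}

# 1..n ranks from score descending, compound id ascending (C locale);
# deterministic total order, every rank used exactly once
rank_descending <- function(scores, ids) {
  ord <- order(-scores, ids, method = "radix")
  rk <- integer(length(scores))
  rk[ord] <- seq_along(scores)
  rk
}

#' Dual-score screen: rank a library on two signature axes and select the
#' intersection of top-ranked compounds
#'
#' Scores every compound on a stemness axis and a tendon axis, ranks each
#' axis descending (rank 1 = best; score ties broken by compound id so the
#' selection is reproducible), and flags compounds ranked within the top K
#' on both axes. By default the stemness signature is scored in
#' \code{"mimic"} orientation (compounds inducing the stemness genes) and
#' the tendon signature in \code{"reverse"} orientation (compounds reversing
#' the adult-versus-neonatal expression changes).
#'
#' @param lib a \code{\link{compound_library}}.
#' @param stemness_sig,tendon_sig \code{\link{gene_signature}} objects.
#' @param top_k_stemness,top_k_tendon per-axis selection depth; default 5\%
#'   of the library (at least 1). Must be in \code{1..length(lib)}.
#' @param orientations named character vector with entries \code{stemness}
#'   and \code{tendon}, each \code{"mimic"} or \code{"reverse"}.
#' @return A \code{screen_table}: a data.frame with columns
#'   \code{compound_id}, \code{name}, \code{stemness_score},
#'   \code{tendon_score}, \code{stemness_rank}, \code{tendon_rank},
#'   \code{selected}, in library order, plus the screen configuration in
#'   \code{attr(, "config")}.
#' @examples
#' sigs <- list(stem = gene_signature(up = c("g1", "g2"), name = "stem"),
#'              tendon = gene_signature(up = "g3", down = "g4",
#'                                      name = "tendon"))
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
#' dual_score_screen(compound_library(m), sigs$stem, sigs$tendon,
#'                   top_k_stemness = 3, top_k_tendon = 3)
#' @export
dual_score_screen <- function(lib, stemness_sig, tendon_sig,
                              top_k_stemness = NULL, top_k_tendon = NULL,
                              orientations = c(stemness = "mimic",
                                               tendon = "reverse")) {
  stopifnot(inherits(lib, "compound_library"))
  n <- nrow(lib$delta)
  default_k <- max(1L, ceiling(0.05 * n))
  if (is.null(top_k_stemness)) top_k_stemness <- default_k
  if (is.null(top_k_tendon)) top_k_tendon <- default_k
  for (k in c(top_k_stemness, top_k_tendon))
    if (k < 1L || k > n)
      stop("top_k must be between 1 and the library size (", n, ")")
  orientations <- orientations[c("stemness", "tendon")]
  if (any(is.na(orientations)) ||
      !all(orientations %in% c("mimic", "reverse")))
    stop("'orientations' must name stemness and tendon, each mimic/reverse")

  s_scores <- score_library(lib, stemness_sig, orientations[["stemness"]])
  t_scores <- score_library(lib, tendon_sig, orientations[["tendon"]])
  ids <- rownames(lib$delta)
  s_rank <- rank_descending(s_scores, ids)
  t_rank <- rank_descending(t_scores, ids)
  nm <- if (!is.null(lib$metadata) && "name" %in% names(lib$metadata))
    as.character(lib$metadata$name) else ids
  tab <- data.frame(compound_id = ids, name = nm,
                    stemness_score = unname(s_scores),
                    tendon_score = unname(t_scores),
                    stemness_rank = s_rank, tendon_rank = t_rank,
                    selected = s_rank <= top_k_stemness &
                      t_rank <= top_k_tendon,
                    stringsAsFactors = FALSE)
  attr(tab, "config") <- list(
    top_k_stemness = top_k_stemness, top_k_tendon = top_k_tendon,
    orientations = as.list(orientations),
    stemness_signature = stemness_sig$name,
    tendon_signature = tendon_sig$name)
  class(tab) <- c("screen_table", "data.frame")
  tab
}

#' @export
print.screen_table <- function(x, n = 10L, ...) {
  cfg <- attr(x, "config")
  cat("Dual-score screen:", nrow(x), "compounds;",
      sum(x$selected), "selected")
  if (!is.null(cfg))
    cat(" (top", cfg$top_k_stemness, "stemness x top",
        cfg$top_k_tendon, "tendon)")
  cat("\n")
  ord <- order(pmax(x$stemness_rank, x$tendon_rank))
  print.data.frame(utils::head(as.data.frame(x)[ord, ], n),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.screen_table <- function(object, ...) {
  cfg <- attr(object, "config")
  sel <- object[object$selected, , drop = FALSE]
  structure(list(n_compounds = nrow(object), n_selected = nrow(sel),
                 selected_ids = sel$compound_id, config = cfg,
                 score_range = list(
                   stemness = range(object$stemness_score),
                   tendon = range(object$tendon_score))),
            class = "summary.screen_table")
}

#' @export
print.summary.screen_table <- function(x, ...) {
  cat("Screen of", x$n_compounds, "compounds:", x$n_selected,
      "selected in the top-rank intersection\n")
  cat("  stemness scores in [", sprintf("%.3f", x$score_range$stemness[1]),
      ", ", sprintf("%.3f", x$score_range$stemness[2]), "], tendon in [",
      sprintf("%.3f", x$score_range$tendon[1]), ", ",
      sprintf("%.3f", x$score_range$tendon[2]), "]\n", sep = "")
  if (x$n_selected)
    cat("  selected:", paste(x$selected_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.screen_table <- function(x, ...) {
  graphics::plot(x$stemness_score, x$tendon_score,
                 col = ifelse(x$selected, "red3", "grey55"),
                 pch = ifelse(x$selected, 19, 1),
                 xlab = "stemness score", ylab = "tendon score", ...)
  if (any(x$selected))
    graphics::legend("topleft", c("selected", "other"),
                     col = c("red3", "grey55"), pch = c(19, 1), bty = "n")
  invisible(x)
}

#' Write / read a screen table as TSV
#'
#' Fixed column order: compound_id, name, stemness_score, tendon_score,
#' stemness_rank, tendon_rank, selected.
#'
#' @param table a \code{screen_table} (or compatible data.frame).
#' @param path TSV path.
#' @export
write_screen_table <- function(table, path) {
  cols <- c("compound_id", "name", "stemness_score", "tendon_score",
            "stemness_rank", "tendon_rank", "selected")
  if (!all(cols %in% names(table)))
    stop("screen table is missing columns: ",
         paste(setdiff(cols, names(table)), collapse = ", "))
  ok <- try(utils::write.table(as.data.frame(table)[, cols], path,
                               sep = "\t", quote = FALSE, row.names = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write screen table to ", path, ": ",
         attr(ok, "condition")$message)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) stop("screen table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$selected <- as.logical(df$selected)
  class(df) <- c("screen_table", "data.frame")
  df
}
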