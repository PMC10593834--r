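#' Construct an up/down gene signature
#'
#' A gene signature is a pair of disjoint gene-identifier sets summarizing a
#' biological state contrast: genes expected to go up and genes expected to
#' go down. Either side may be empty (an up-only set such as the Yamanaka
#' stemness factors is valid), but not both.
#'
#' @param up character vector of up-gene identifiers (no duplicates).
#' @param down character vector of down-gene identifiers (no duplicates).
#' @param name signature name.
#' @param provenance free-text note on where the signature came from.
#' @return An object of class \code{gene_signature} with elements
#'   \code{up}, \code{down}, \code{name}, \code{provenance}.
#' @examples
#' gene_signature(up = c("Nes", "Sox2", "Nanog"), name = "stemness")
#' @export
gene_signature <- function(up = character(), down = character(),
                           name = "signature", provenance = NA_character_) {
  up <- as.character(up)
  down <- as.character(down)
  if (anyDuplicated(up)) stop("duplicate gene ids in 'up' set")
  if (anyDuplicated(down)) stop("duplicate gene ids in 'down' set")
  if (length(up) == 0L && length(down) == 0L)
    stop("signature must have at least one non-empty side")
  common <- intersect(up, down)
  if (length(common))
    stop("up and down sets must be disjoint; shared: ",
         paste(common, collapse = ", "))
  structure(list(up = up, down = down, name = as.character(name)[1L],
                 provenance = as.character(provenance)[1L]),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  if (!is.na(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# genewise Welch two-sample test on log2 expression, vectorised over rows.
# Returns data.frame(log2_fold_change = mean(A) - mean(B), p_value).
welch_by_gene <- function(expr, in_a, in_b) {
  na <- sum(in_a)
  nb <- sum(in_b)
  xa <- expr[, in_a, drop = FALSE]
  xb <- expr[, in_b, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  lfc <- ma - mb
  se2 <- va / na + vb / nb
  tval <- lfc / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  # zero-variance rows: constant everywhere -> no evidence (p = 1);
  # constant within groups but separated -> perfect separation (p = 0)
  degen <- se2 == 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
  data.frame(log2_fold_change = lfc, p_value = p, row.names = NULL)
}

#' Extract an up/down DEG signature from a two-group expression matrix
#'
#' Calls differentially expressed genes between two sample groups with a
#' genewise Welch unequal-variance test on log2-scale expression, filters on
#' the (optionally BH-adjusted) P value, splits by fold-change sign, ranks
#' each side by absolute log2 fold change descending, and truncates to the
#' requested set sizes. Fold change is the difference of group means of
#' log2 values, \code{contrast[1]} minus \code{contrast[2]}.
#'
#' @param expr numeric matrix, genes x samples, log2-scale expression, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param groups factor or character of length \code{ncol(expr)} with exactly
#'   two levels; each group must contain at least two samples.
#' @param p_threshold retain genes with P strictly below this (default 0.05).
#' @param max_up,max_down cap on the number of genes kept per side after
#'   ranking by |log2FC| (default unbounded).
#' @param contrast length-2 character: which group mean is subtracted from
#'   which; defaults to the group levels in order (first minus second).
#' @param adjust \code{"none"} (raw P, the default) or \code{"BH"}
#'   (Benjamini-Hochberg) applied before thresholding.
#' @param name name given to the returned signature.
#' @return A list with components \code{signature} (a
#'   \code{\link{gene_signature}}) and \code{deg_table}, a data.frame with
#'   one row per gene: \code{gene_id}, \code{log2_fold_change},
#'   \code{p_value}, \code{direction} (\code{"up"}/\code{"down"}, \code{NA}
#'   for zero fold change) and \code{selected}.
#' @examples
#' sim <- simulate_expression(n_genes = 300, n_up = 20, n_down = 20, seed = 1)
#' res <- compute_deg_signature(sim$expr, sim$groups)
#' res$signature
#' @export
compute_deg_signature <- function(expr, groups, p_threshold = 0.05,
                                  max_up = Inf, max_down = Inf,
                                  contrast = NULL,
                                  adjust = c("none", "BH"),
                                  name = "deg_signature") {
  adjust <- match.arg(adjust)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop("'expr' must have unique rownames (gene ids)")
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("'groups' must assign one group per sample column")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("'groups' must have exactly two levels")
  if (is.null(contrast)) contrast <- lev
  if (!setequal(contrast, lev) || length(contrast) != 2L)
    stop("'contrast' must be the two group labels")
  if (!(p_threshold > 0 && p_threshold <= 1))
    stop("'p_threshold' must be in (0, 1]")
  in_a <- groups == contrast[1L]
  in_b <- groups == contrast[2L]
  if (sum(in_a) < 2L || sum(in_b) < 2L)
    stop("insufficient replication: each group needs >= 2 samples")

  stats_tab <- welch_by_gene(expr, in_a, in_b)
  deg <- data.frame(gene_id = rownames(expr), stats_tab,
                    stringsAsFactors = FALSE)
  deg$direction <- ifelse(deg$log2_fold_change > 0, "up",
                          ifelse(deg$log2_fold_change < 0, "down",
                                 NA_character_))
  p_used <- if (adjust == "BH") stats::p.adjust(deg$p_value, "BH") else
    deg$p_value
  pass <- p_used < p_threshold & !is.na(deg$direction)

  pick_side <- function(side, cap) {
    cand <- deg[pass & deg$direction == side, , drop = FALSE]
    cand <- cand[order(-abs(cand$log2_fold_change), cand$gene_id,
                       method = "radix"), , drop = FALSE]
    utils::head(cand$gene_id, cap)
  }
  up <- pick_side("up", max_up)
  down <- pick_side("down", max_down)
  deg$selected <- deg$gene_id %in% c(up, down)
  if (length(up) == 0L && length(down) == 0L)
    stop("no genes pass the threshold; cannot build a signature")
  sig <- gene_signature(up = up, down = down, name = name,
                        provenance = sprintf(
                          "Welch DEG call, p<%g (%s), %d up / %d down",
                          p_threshold, adjust, length(up), length(down)))
  list(signature = sig, deg_table = deg)
}

#' Restrict a signature to a gene universe
#'
#' Drops signature genes that are absent from the scoring universe, warning
#' once for each dropped gene. Mirrors the common situation where curated
#' genes are missing from the profiled gene list.
#'
#' @param sig a \code{\link{gene_signature}}.
#' @param universe character vector of gene ids (unique, non-empty).
#' @return The restricted \code{gene_signature}.
#' @examples
#' sig <- gene_signature(up = c("Nes", "Sox2", "Nanog", "Ddx56", "Pou5f1"))
#' suppressWarnings(restrict_to_universe(sig, c("Nes", "Sox2", "Nanog")))
#' @export
restrict_to_universe <- function(sig, universe) {
  stopifnot(inherits(sig, "gene_signature"))
  universe <- as.character(universe)
  if (length(universe) == 0L || anyDuplicated(universe))
    stop("'universe' must be non-empty and unique")
  up <- intersect(sig$up, universe)
  down <- intersect(sig$down, universe)
  dropped <- setdiff(c(sig$up, sig$down), universe)
  for (g in dropped)
    warning("signature '", sig$name, "': gene '", g,
            "' not in universe, dropped", call. = FALSE)
  if (length(up) == 0L && length(down) == 0L)
    stop("signature disjoint from universe")
  gene_signature(up = up, down = down, name = sig$name,
                 provenance = sig$provenance)
}
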