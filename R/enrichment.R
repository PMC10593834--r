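#' Construct a per-compound transcriptional-change profile
#'
#' A change profile holds one predicted per-gene expression change (delta)
#' for each gene of a fixed, ordered universe.
#'
#' @param compound_id compound identifier.
#' @param universe ordered, unique gene ids (length n).
#' @param delta numeric vector of per-gene changes, length n, all finite.
#' @return An object of class \code{change_profile}.
#' @export
change_profile <- function(compound_id, universe, delta) {
  universe <- as.character(universe)
  delta <- as.numeric(delta)
  if (anyDuplicated(universe)) stop("duplicate gene ids in universe")
  if (length(delta) != length(universe))
    stop("'delta' must have one value per universe gene")
  if (any(!is.finite(delta)))
    stop("non-finite delta for gene '",
         universe[which(!is.finite(delta))[1L]], "'")
  structure(list(compound_id = as.character(compound_id)[1L],
                 universe = universe, delta = delta),
            class = "change_profile")
}

#' Rank a change profile
#'
#' Genes are sorted by delta descending (rank 1 = most upregulated); ties
#' are broken by gene id ascending in the C locale, so the ranking is
#' deterministic and independent of input row order. Ranks are 1-based.
#'
#' @param p a \code{\link{change_profile}}.
#' @return An object of class \code{ranked_profile}: \code{compound_id},
#'   \code{n}, and \code{rank_of}, a named integer vector mapping gene id to
#'   rank in \code{1..n} (a bijection).
#' @examples
#' p <- change_profile("c1", c("g1", "g2", "g3"), c(2, -1, 0))
#' rank_profile(p)$rank_of
#' @export
rank_profile <- function(p) {
  stopifnot(inherits(p, "change_profile"))
  n <- length(p$universe)
  ord <- order(-p$delta, p$universe, method = "radix")
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  names(rank_of) <- p$universe
  structure(list(compound_id = p$compound_id, n = n, rank_of = rank_of),
            class = "ranked_profile")
}

query_ranks <- function(r, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty query set")
  missing <- setdiff(genes, names(r$rank_of))
  if (length(missing))
    stop("query genes not in universe: ", paste(missing, collapse = ", "))
  sort(unname(r$rank_of[genes]))
}

#' KS running-sum statistics for a query gene set
#'
#' The up-set statistic is the maximal positive deviation of the query-rank
#' empirical step function above the uniform line,
#' \code{a = max_j [ j/t - V(j)/n ]}; the down-set statistic is the negated
#' maximal deviation below it, \code{b = -max_j [ (V(j)-1)/n - (j-1)/t ]},
#' where \code{V(1) < ... < V(t)} are the sorted ranks of the t query genes
#' in the n-gene ranked list. Always \code{0 <= a < 1} and \code{-1 < b <= 0}.
#'
#' @param r a \code{\link{ranked_profile}}.
#' @param genes non-empty character vector of query genes, all in the
#'   universe.
#' @return A single numeric value.
#' @examples
#' p <- change_profile("c1", paste0("g", 1:10), 10:1)
#' r <- rank_profile(p)
#' ks_up(r, c("g1", "g2"))    # 0.8
#' ks_down(r, c("g9", "g10")) # -0.8
#' @export
ks_up <- function(r, genes) {
  v <- query_ranks(r, genes)
  t <- length(v)
  max(seq_len(t) / t - v / r$n)
}

#' @rdname ks_up
#' @export
ks_down <- function(r, genes) {
  v <- query_ranks(r, genes)
  t <- length(v)
  -max((v - 1) / r$n - (seq_len(t) - 1) / t)
}

#' KS enrichment score of a ranked profile against an up/down signature
#'
#' Computes \code{a} on the up set and \code{b} on the down set (see
#' \code{\link{ks_up}}) and combines them: for a two-sided signature,
#' \code{Score = a - b} when \code{a*b < 0} and \code{0} when
#' \code{a*b > 0}; since \code{a >= 0} and \code{b <= 0} by construction the
#' second branch can never fire, and the boundary case \code{a*b = 0} (no
#' coherent deviation on one side) is assigned score 0. A one-sided
#' signature bypasses the sign condition: an up-only set scores \code{a}, a
#' down-only set scores \code{-b}. The reversal score is the negated score,
#' \code{(-1) * (a - b)}, ranking compounds whose induced changes oppose the
#' signature.
#'
#' The signature must already be restricted to the profile's universe
#' (\code{\link{restrict_to_universe}}).
#'
#' @param r a \code{\link{ranked_profile}}.
#' @param sig a \code{\link{gene_signature}} with all genes in the universe.
#' @return An object of class \code{enrichment_result}: \code{a}, \code{b},
#'   \code{score}, \code{reversal_score}, \code{t_up}, \code{t_down}.
#' @examples
#' p <- change_profile("c1", paste0("g", 1:10), 10:1)
#' sig <- gene_signature(up = c("g1", "g2"), down = c("g9", "g10"))
#' enrichment_score(rank_profile(p), sig)
#' @export
enrichment_score <- function(r, sig) {
  stopifnot(inherits(r, "ranked_profile"), inherits(sig, "gene_signature"))
  has_up <- length(sig$up) > 0L
  has_down <- length(sig$down) > 0L
  if (!has_up && !has_down) stop("both signature sides are empty")
  a <- if (has_up) ks_up(r, sig$up) else 0
  b <- if (has_down) ks_down(r, sig$down) else 0
  if (has_up && has_down) {
    score <- if (a * b < 0) a - b else 0
  } else if (has_up) {
    score <- a
  } else {
    score <- -b
  }
  structure(list(a = a, b = b, score = score, reversal_score = -score,
                 t_up = length(sig$up), t_down = length(sig$down),
                 compound_id = r$compound_id, signature = sig$name),
            class = "enrichment_result")
}

#' @rdname enrichment_score
#' @return \code{reversal_score}: the negated enrichment score, a single
#'   numeric value.
#' @export
reversal_score <- function(r, sig) {
  enrichment_score(r, sig)$reversal_score
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "KS enrichment: %s vs '%s'\n  a = %.4f (t_up = %d), b = %.4f (t_down = %d)\n  score = %.4f, reversal = %.4f\n",
    x$compound_id, x$signature, x$a, x$t_up, x$b, x$t_down,
    x$score, x$reversal_score))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(compound_id = x$compound_id, signature = x$signature,
             a = x$a, b = x$b, score = x$score,
             reversal_score = x$reversal_score,
             t_up = x$t_up, t_down = x$t_down, stringsAsFactors = FALSE)
}
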