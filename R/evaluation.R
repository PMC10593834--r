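#' Per-gene Pearson correlation between predicted and empirical profiles
#'
#' For every gene, computes Pearson r between its predicted and empirical
#' change values across molecules. Genes with zero variance in either
#' matrix have undefined r and are recorded as missing (excluded from the
#' mean and peak, with the count reported).
#'
#' @param predicted,empirical numeric matrices, molecules x genes, with
#'   identical dimensions and dimnames; at least 3 molecules.
#' @return An object of class \code{correlation_report}: \code{r_per_gene}
#'   (named, may contain \code{NA}), \code{mean_r}, \code{peak_r}
#'   (histogram mode, see \code{\link{summarize_distribution}}),
#'   \code{n_genes}, \code{n_molecules}, \code{n_missing}.
#' @examples
#' pair <- simulate_paired_profiles(n_molecules = 50, n_genes = 100,
#'                                  rho = 0.7, seed = 1)
#' per_gene_correlation(pair$predicted, pair$empirical)
#' @export
per_gene_correlation <- function(predicted, empirical) {
  if (!is.matrix(predicted) || !is.matrix(empirical))
    stop("'predicted' and 'empirical' must be matrices (molecules x genes)")
  if (!identical(dim(predicted), dim(empirical)))
    stop("shape mismatch between predicted and empirical matrices")
  if (!identical(dimnames(predicted), dimnames(empirical)))
    stop("dimname mismatch between predicted and empirical matrices")
  if (any(!is.finite(predicted)) || any(!is.finite(empirical)))
    stop("profile matrices must be finite")
  n_mol <- nrow(predicted)
  if (n_mol < 3L) stop("need at least 3 molecules to correlate")

  cx <- sweep(predicted, 2L, colMeans(predicted))
  cy <- sweep(empirical, 2L, colMeans(empirical))
  den <- sqrt(colSums(cx^2) * colSums(cy^2))
  r <- ifelse(den > 0, colSums(cx * cy) / den, NA_real_)
  names(r) <- colnames(predicted)
  n_missing <- sum(is.na(r))
  if (n_missing)
    message(n_missing, " zero-variance gene(s) excluded from the report")
  finite_r <- r[!is.na(r)]
  if (length(finite_r) == 0L) stop("no gene with defined correlation")
  peak <- summarize_distribution_values(finite_r)$mode
  structure(list(r_per_gene = r, mean_r = mean(finite_r), peak_r = peak,
                 n_genes = ncol(predicted), n_molecules = n_mol,
                 n_missing = n_missing),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "Per-gene correlation over %d molecules, %d genes (%d undefined)\n  mean r = %.3f, peak (mode) r = %.3f\n",
    x$n_molecules, x$n_genes, x$n_missing, x$mean_r, x$peak_r))
  invisible(x)
}

#' @export
plot.correlation_report <- function(x, n_bins = "auto", ...) {
  s <- summarize_distribution(x, n_bins)
  graphics::hist(x$r_per_gene[!is.na(x$r_per_gene)], breaks = s$breaks,
                 main = "Per-gene Pearson r", xlab = "r", ...)
  graphics::abline(v = c(x$mean_r, x$peak_r), col = c("blue", "red3"),
                   lty = 2)
  invisible(x)
}

# histogram summary of an r vector over [-1, 1]; Freedman-Diaconis bins by
# default, mode = midpoint of the tallest bin (ties -> lowest midpoint)
summarize_distribution_values <- function(r, n_bins = "auto") {
  if (length(r) == 0L) stop("empty correlation vector")
  if (identical(n_bins, "auto")) {
    h <- 2 * stats::IQR(r) / length(r)^(1 / 3)
    n_bins <- if (is.finite(h) && h > 0) min(200L, max(1L, ceiling(2 / h)))
      else 1L
  }
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  if (diff(range(r)) == 0) {
    # degenerate: all values identical
    v <- unname(r[1L])
    return(list(mean = v, median = v, mode = v, max = v,
                counts = length(r), breaks = c(v - 1e-9, v + 1e-9)))
  }
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  # clamp tiny numeric excursions outside [-1, 1]
  r_cl <- pmin(1, pmax(-1, r))
  hh <- graphics::hist(r_cl, breaks = breaks, plot = FALSE)
  list(mean = mean(r), median = stats::median(r),
       mode = hh$mids[which.max(hh$counts)], max = max(r),
       counts = hh$counts, breaks = breaks)
}

#' Summarize a per-gene correlation distribution
#'
#' Histogram summary of the finite per-gene r values over \code{[-1, 1]}:
#' mean, median, mode (the "peak" of the distribution, taken as the
#' midpoint of the tallest bin), maximum, and the bin counts. Default
#' binning is Freedman-Diaconis.
#'
#' @param report a \code{\link{per_gene_correlation}} report.
#' @param n_bins number of equal-width bins over \code{[-1, 1]}, or
#'   \code{"auto"}.
#' @return A list: \code{mean}, \code{median}, \code{mode}, \code{max},
#'   \code{counts}, \code{breaks}.
#' @export
summarize_distribution <- function(report, n_bins = "auto") {
  stopifnot(inherits(report, "correlation_report"))
  r <- report$r_per_gene
  summarize_distribution_values(r[!is.na(r)], n_bins)
}
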