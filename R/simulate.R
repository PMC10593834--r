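# run code under a fixed RNG seed, restoring the caller's RNG state, so
# every generator is a pure function of its arguments + seed
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a two-group expression experiment with planted DEGs
#'
#' Emulates a neonatal-versus-adult two-group tendon expression experiment
#' on the log2 scale: each gene gets a baseline drawn once, group "A" adds
#' \code{+effect} on the planted up genes and \code{-effect} on the planted
#' down genes relative to group "B", and every measurement carries
#' independent Gaussian noise. The planted truth is returned alongside.
#'
#' @param n_genes gene universe size (default 12328, the profiled gene
#'   list; tests use smaller presets).
#' @param n_up,n_down numbers of planted up/down genes (defaults 100/150,
#'   matching the scale of a 99-up/143-down signature).
#' @param effect planted |log2 fold change| (default 2).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.5).
#' @param n_per_group samples per group, length 2 (default 6 and 6).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return A list: \code{expr} (genes x samples matrix), \code{groups}
#'   (character, "A"/"B"), \code{truth} (list \code{up}, \code{down} of
#'   planted gene ids), \code{config}.
#' @export
simulate_expression <- function(n_genes = 12328L, n_up = 100L,
                                n_down = 150L, effect = 2, noise_sd = 0.5,
                                n_per_group = c(6L, 6L), seed = NULL) {
  if (n_up + n_down > n_genes)
    stop("planted DEG counts exceed the number of genes")
  if (any(n_per_group < 2L)) stop("need >= 2 samples per group")
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    n_a <- n_per_group[1L]
    n_b <- n_per_group[2L]
    baseline <- stats::rnorm(n_genes, mean = 7, sd = 2)
    shift <- numeric(n_genes)
    up_idx <- seq_len(n_up)
    down_idx <- n_up + seq_len(n_down)
    shift[up_idx] <- effect
    shift[down_idx] <- -effect
    mu <- cbind(matrix(baseline + shift, n_genes, n_a),
                matrix(baseline, n_genes, n_b))
    expr <- mu + matrix(stats::rnorm(n_genes * (n_a + n_b), sd = noise_sd),
                        n_genes, n_a + n_b)
    dimnames(expr) <- list(genes,
                           c(sprintf("A%02d", seq_len(n_a)),
                             sprintf("B%02d", seq_len(n_b))))
    list(expr = expr,
         groups = rep(c("A", "B"), c(n_a, n_b)),
         truth = list(up = genes[up_idx], down = genes[down_idx]),
         config = list(n_genes = n_genes, n_up = n_up, n_down = n_down,
                       effect = effect, noise_sd = noise_sd,
                       n_per_group = n_per_group, seed = seed))
  })
}

#' Simulate a compound library with planted signature hits
#'
#' Null compounds have i.i.d. Gaussian per-gene deltas. Planted stemness
#' hits shift the stemness signature genes in the mimic direction (up genes
#' up, down genes down); planted tendon hits shift the tendon signature
#' genes in the reversal direction (up genes down, down genes up); dual
#' hits do both. Shifts are \code{reversal_strength * noise_sd}.
#'
#' @param universe gene universe (character); signatures must be subsets.
#' @param stemness_sig,tendon_sig \code{\link{gene_signature}} objects
#'   already inside the universe.
#' @param n_compounds library size (default 3680, the merged
#'   natural-product + FDA-approved library scale).
#' @param n_stemness_hits,n_tendon_hits,n_dual_hits planted hit counts
#'   (single-axis hits, plus hits on both axes).
#' @param reversal_strength planted shift in noise-SD units (default 3).
#' @param noise_sd delta noise SD (default 1).
#' @param seed RNG seed.
#' @return A list: \code{library} (a \code{\link{compound_library}}),
#'   \code{truth} (lists \code{stemness_hits}, \code{tendon_hits},
#'   \code{dual_hits} of compound ids), \code{config}.
#' @export
simulate_ctp_library <- function(universe, stemness_sig, tendon_sig,
                                 n_compounds = 3680L,
                                 n_stemness_hits = 0L, n_tendon_hits = 0L,
                                 n_dual_hits = 0L, reversal_strength = 3,
                                 noise_sd = 1, seed = NULL) {
  universe <- as.character(universe)
  n_hits <- n_stemness_hits + n_tendon_hits + n_dual_hits
  if (n_hits > n_compounds)
    stop("planted hit counts exceed the number of compounds")
  for (sig in list(stemness_sig, tendon_sig))
    if (length(setdiff(c(sig$up, sig$down), universe)))
      stop("signature '", sig$name, "' is not inside the universe")
  with_seed(seed, {
    ids <- sprintf("cmpd%05d", seq_len(n_compounds))
    delta <- matrix(stats::rnorm(n_compounds * length(universe),
                                 sd = noise_sd),
                    n_compounds, length(universe),
                    dimnames = list(ids, universe))
    hit_ids <- sample(ids, n_hits)
    stem_ids <- hit_ids[seq_len(n_stemness_hits)]
    tendon_ids <- hit_ids[n_stemness_hits + seq_len(n_tendon_hits)]
    dual_ids <- hit_ids[n_stemness_hits + n_tendon_hits +
                          seq_len(n_dual_hits)]
    shift <- reversal_strength * noise_sd
    bump <- function(rows, genes, s) {
      if (length(rows) && length(genes))
        delta[rows, genes] <<- delta[rows, genes] + s
    }
    mimic_rows <- c(stem_ids, dual_ids)
    rev_rows <- c(tendon_ids, dual_ids)
    bump(mimic_rows, stemness_sig$up, +shift)
    bump(mimic_rows, stemness_sig$down, -shift)
    bump(rev_rows, tendon_sig$up, -shift)
    bump(rev_rows, tendon_sig$down, +shift)
    list(library = compound_library(delta),
         truth = list(stemness_hits = stem_ids, tendon_hits = tendon_ids,
                      dual_hits = dual_ids),
         config = list(n_compounds = n_compounds,
                       n_stemness_hits = n_stemness_hits,
                       n_tendon_hits = n_tendon_hits,
                       n_dual_hits = n_dual_hits,
                       reversal_strength = reversal_strength,
                       noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate paired predicted/empirical profiles with controlled per-gene
#' correlation
#'
#' For gene g with target correlation \eqn{\rho_g}, the predicted column is
#' standard normal and the empirical column is
#' \eqn{\rho_g Z + \sqrt{1 - \rho_g^2}\,\epsilon} with independent standard
#' normal noise, so the population Pearson correlation is exactly
#' \eqn{\rho_g}.
#'
#' @param n_molecules rows of both matrices (default 3000, the test-set
#'   scale; evaluation scenarios typically use 500).
#' @param n_genes columns; ignored when \code{rho} is a vector.
#' @param rho target correlation: a scalar (recycled), a vector of length
#'   \code{n_genes}, or a function \code{function(n)} drawing n values.
#'   All values must lie strictly inside (-1, 1).
#' @param seed RNG seed.
#' @return A list: \code{predicted}, \code{empirical} (molecules x genes),
#'   \code{truth} (the per-gene \code{rho} vector), \code{config}.
#' @export
simulate_paired_profiles <- function(n_molecules = 3000L, n_genes = 1000L,
                                     rho = 0.74, seed = NULL) {
  with_seed(seed, {
    if (is.function(rho)) rho <- rho(n_genes)
    if (length(rho) == 1L) rho <- rep(rho, n_genes)
    if (length(rho) != n_genes)
      stop("'rho' must be scalar, length n_genes, or a function")
    if (any(abs(rho) >= 1)) stop("target correlations must satisfy |rho| < 1")
    genes <- sprintf("g%05d", seq_len(n_genes))
    mols <- sprintf("m%05d", seq_len(n_molecules))
    z <- matrix(stats::rnorm(n_molecules * n_genes), n_molecules, n_genes)
    eps <- matrix(stats::rnorm(n_molecules * n_genes), n_molecules, n_genes)
    emp <- sweep(z, 2L, rho, `*`) + sweep(eps, 2L, sqrt(1 - rho^2), `*`)
    dimnames(z) <- dimnames(emp) <- list(mols, genes)
    list(predicted = z, empirical = emp,
         truth = stats::setNames(rho, genes),
         config = list(n_molecules = n_molecules, n_genes = n_genes,
                       seed = seed))
  })
}

#' Draw per-gene target correlations with a given mean
#'
#' Beta-distributed targets on (0, 1); the default shapes give mean 0.74
#' with right-skewed mass near 0.9, a plausible shape for the accuracy
#' distribution of a well-trained expression predictor.
#'
#' @param n number of genes.
#' @param shape1,shape2 Beta shapes (defaults 7.4 and 2.6, mean 0.74).
#' @return Numeric vector of length \code{n} in (0, 1).
#' @export
rho_beta <- function(n, shape1 = 7.4, shape2 = 2.6) {
  stats::rbeta(n, shape1, shape2)
}

#' Simulate footprint and grip measurements with a known injury effect
#'
#' Normal-paw measures are drawn uniformly from physiological rat ranges
#' (PL 25-35 mm, TS 15-22 mm, IT 8-12 mm); the experimental paw scales all
#' three by \code{injury_effect} with multiplicative Gaussian measurement
#' noise. \code{injury_effect = 1} is an uninjured paw (AFI near -5);
#' values below 1 shrink the toe spreads and drive the AFI down. Grip
#' readings are five draws around a per-animal baseline scaled by
#' \code{injury_effect}.
#'
#' @param n_animals number of rows.
#' @param injury_effect multiplicative effect on the experimental paw,
#'   > 0 (default 1).
#' @param noise_sd relative measurement noise SD (default 0.02).
#' @param seed RNG seed.
#' @return A data.frame with columns \code{animal}, \code{NPL}, \code{EPL},
#'   \code{NTS}, \code{ETS}, \code{NIT}, \code{EIT}, \code{grip1..grip5},
#'   \code{BW}; the config is attached as \code{attr(, "config")}.
#' @export
simulate_footprints <- function(n_animals = 10L, injury_effect = 1,
                                noise_sd = 0.02, seed = NULL) {
  if (injury_effect <= 0) stop("'injury_effect' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  with_seed(seed, {
    wobble <- function(n) pmax(0.2, 1 + stats::rnorm(n, sd = noise_sd))
    npl <- stats::runif(n_animals, 25, 35)
    nts <- stats::runif(n_animals, 15, 22)
    nit <- stats::runif(n_animals, 8, 12)
    base_grip <- stats::runif(n_animals, 500, 900)
    grips <- matrix(base_grip * injury_effect, n_animals, 5L) *
      matrix(wobble(n_animals * 5L), n_animals, 5L)
    df <- data.frame(animal = sprintf("rat%02d", seq_len(n_animals)),
                     NPL = npl, EPL = npl * injury_effect *
                       wobble(n_animals),
                     NTS = nts, ETS = nts * injury_effect *
                       wobble(n_animals),
                     NIT = nit, EIT = nit * injury_effect *
                       wobble(n_animals),
                     stringsAsFactors = FALSE)
    colnames(grips) <- paste0("grip", 1:5)
    df <- cbind(df, grips)
    df$BW <- stats::runif(n_animals, 250, 450)
    attr(df, "config") <- list(n_animals = n_animals,
                               injury_effect = injury_effect,
                               noise_sd = noise_sd, seed = seed)
    df
  })
}
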