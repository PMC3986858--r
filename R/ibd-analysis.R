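#' Pairwise chord-distance matrix of a cline dataset
#'
#' Computes per-population allele frequency spectra and the
#' Cavalli-Sforza & Edwards chord distance for every population pair.
#'
#' @param cline a `cline_dataset` (or plain list of [genotype_table()]s).
#' @return a [dist_matrix()] labelled by population.
#' @export
genetic_distance_matrix <- function(cline) {
  pops <- if (inherits(cline, "cline_dataset")) cline$populations else cline
  spectra <- lapply(pops, function(p) allele_frequencies(p, "all")[[1]])
  labels <- vapply(pops, function(p) p$populations[1], "")
  n <- length(pops)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- cavalli_sforza_chord(spectra[[i]], spectra[[j]])
  dist_matrix(m, labels = labels)
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation `r` between the lower triangles of a genetic and a
#' geographic distance matrix, the least-squares slope `b` of genetic on
#' geographic distance, and a one-tailed permutation p-value for positive
#' association: rows and columns of the genetic matrix are permuted
#' simultaneously and `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param genetic,geographic square symmetric matrices with matching
#'   labels/order, at least 4 populations.
#' @param n_perm permutations (default 9999).
#' @param seed RNG seed.
#' @return a `mantel_result`: `r`, `b`, `p`, `n_perm`, `seed`, `n`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 9999, seed = NULL) {
  genetic <- as.matrix(genetic); geographic <- as.matrix(geographic)
  n <- nrow(genetic)
  if (n < 4) stop("need at least 4 populations")
  if (!all(dim(geographic) == c(n, n))) stop("matrix dimensions differ")
  if (!is.null(rownames(genetic)) && !is.null(rownames(geographic)) &&
      !identical(rownames(genetic), rownames(geographic)))
    stop("matrix labels differ or are ordered differently")
  lt <- lower.tri(genetic)
  x <- geographic[lt]; y <- genetic[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a distance matrix: r undefined")
  r_obs <- stats::cor(x, y)
  b <- stats::cov(x, y) / stats::var(x)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (stats::cor(x, genetic[perm, perm][lt]) >= r_obs) hits <- hits + 1L
  }
  structure(list(r = r_obs, b = b, p = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, b = %.3g, p = %.4g (%d permutations)\n",
              x$r, x$b, x$p, x$n_perm))
  invisible(x)
}

#' Regression of IBD strength on simulated gene-flow level
#'
#' Fits `r ~ a0 + a1 * level` by ordinary least squares and
#' `b ~ b0 * exp(b1 * level)` — on `log |b|` when all `b` share a sign,
#' otherwise by direct nonlinear least squares.
#'
#' @param levels per-step hybridization increments (percent), at least 3.
#' @param r_values,b_values mean Mantel `r` and slope `b` per level.
#' @return a `gene_flow_fit`: `levels`, `r_values`, `b_values`, `linear`
#'   (coefficients `a0`, `a1` and `r_squared`), `exponential`
#'   (coefficients `b0`, `b1` and `r_squared`).
#' @export
fit_gene_flow_curves <- function(levels, r_values, b_values) {
  if (length(levels) < 3) stop("need at least 3 scenarios")
  stopifnot(length(r_values) == length(levels),
            length(b_values) == length(levels))
  lin <- stats::lm(r_values ~ levels)
  a <- unname(stats::coef(lin))
  r2_lin <- 1 - sum(stats::residuals(lin)^2) /
    sum((r_values - mean(r_values))^2)
  if (all(b_values > 0) || all(b_values < 0)) {
    sgn <- sign(b_values[1])
    lf <- stats::lm(log(abs(b_values)) ~ levels)
    b0 <- sgn * exp(unname(stats::coef(lf)[1]))
    b1 <- unname(stats::coef(lf)[2])
  } else {
    nl <- stats::nls(b_values ~ b0 * exp(b1 * levels),
                     start = list(b0 = mean(b_values), b1 = 0.1),
                     control = stats::nls.control(warnOnly = TRUE))
    b0 <- unname(stats::coef(nl)["b0"]); b1 <- unname(stats::coef(nl)["b1"])
  }
  pred_b <- b0 * exp(b1 * levels)
  r2_exp <- 1 - sum((b_values - pred_b)^2) /
    sum((b_values - mean(b_values))^2)
  structure(list(levels = levels, r_values = r_values, b_values = b_values,
                 linear = list(a0 = a[1], a1 = a[2], r_squared = r2_lin),
                 exponential = list(b0 = b0, b1 = b1, r_squared = r2_exp)),
            class = "gene_flow_fit")
}

#' Gene flow needed for a target IBD correlation
#'
#' Inverts the linear `r`-on-level fit at `target_r`. For a dataset of `n`
#' populations whose hybrid fraction rises by `level` percent per step, the
#' mean per-population hybrid fraction is `level * (n - 1) / 2` (5.5 times
#' the increment for 12 populations) and the maximum is `level * (n - 1)`.
#'
#' @param fit a [fit_gene_flow_curves()] result.
#' @param target_r the IBD correlation to be explained.
#' @param n_populations populations per dataset (default 12).
#' @return list with `increment_pct`, `mean_fraction_pct`,
#'   `max_fraction_pct`, `extrapolated` (`TRUE` when `target_r` lies outside
#'   the fitted `r` range).
#' @export
extrapolate_gene_flow <- function(fit, target_r, n_populations = 12) {
  a0 <- fit$linear$a0; a1 <- fit$linear$a1
  if (a1 == 0) stop("degenerate fit: zero slope")
  level <- (target_r - a0) / a1
  outside <- target_r < min(fit$r_values) || target_r > max(fit$r_values)
  list(increment_pct = level,
       mean_fraction_pct = level * (n_populations - 1) / 2,
       max_fraction_pct = level * (n_populations - 1),
       extrapolated = outside)
}

#' Run the full cline-to-IBD simulation experiment
#'
#' For each hybridization increment and replicate: build a cline dataset
#' (F1 or admixed mode), compute its chord-distance matrix, and run a
#' Mantel test against the geographic matrix. Replicates are aggregated by
#' mean and standard deviation of `r` and `b`, and the per-level means feed
#' [fit_gene_flow_curves()].
#'
#' @param increments vector of per-step increments in percent
#'   (default `c(1, 2, 3, 4)`).
#' @param mode `"f1_parents"` or `"admixed_fraction"`.
#' @param pools a [gen_species_pools()] result (pools and spectra).
#' @param geography a [dist_matrix()] with one row per population.
#' @param qdist [q_distribution()] for admixed mode.
#' @param n_replicates replicates per increment (default 20).
#' @param n_perm Mantel permutations per test (default 999).
#' @param seed global seed, split over all runs.
#' @param n_populations,n_pairs,offspring_per_population scenario sizes.
#' @return list with `results` (data frame: `increment`, `replicate`, `r`,
#'   `b`, `p`), `summary` (per-increment mean/sd of `r` and `b` and the
#'   fraction of tests with `p < 0.05`), `fit` (a `gene_flow_fit`, `NULL`
#'   with fewer than 3 increments).
#' @export
run_ibd_experiment <- function(increments = c(1, 2, 3, 4),
                               mode = c("f1_parents", "admixed_fraction"),
                               pools, geography,
                               qdist = q_distribution_uniform(),
                               n_replicates = 20, n_perm = 999, seed = 1,
                               n_populations = nrow(geography),
                               n_pairs = 50, offspring_per_population = 100) {
  mode <- match.arg(mode)
  grid <- expand.grid(increment = increments,
                      replicate = seq_len(n_replicates))
  # one seed pair per replicate, shared across increments: the clines of a
  # replicate are built from common random numbers, so increment contrasts
  # are paired and seed-averaged orderings stabilise quickly
  seeds <- split_seed(seed, 2L * n_replicates)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    inc <- grid$increment[i]
    rep_k <- grid$replicate[i]
    sc <- cline_scenario(inc, n_populations = n_populations,
                         n_pairs = n_pairs,
                         offspring_per_population = offspring_per_population,
                         mode = mode, seed = seeds[2 * rep_k - 1])
    cl <- if (mode == "f1_parents")
      build_f1_cline(sc, pools$pool_E, pools$pool_A)
    else
      build_admixed_cline(sc, pools$afs_A, pools$afs_E, qdist)
    gd <- genetic_distance_matrix(cl)
    mt <- mantel_test(unclass(gd), unclass(geography), n_perm = n_perm,
                      seed = seeds[2 * rep_k])
    rows[[i]] <- data.frame(increment = inc, replicate = rep_k,
                            r = mt$r, b = mt$b, p = mt$p)
  }
  results <- do.call(rbind, rows)
  agg <- lapply(split(results, results$increment), function(d)
    data.frame(increment = d$increment[1],
               mean_r = mean(d$r), sd_r = stats::sd(d$r),
               mean_b = mean(d$b), sd_b = stats::sd(d$b),
               frac_significant = mean(d$p < 0.05)))
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  fit <- NULL
  if (length(increments) >= 3)
    fit <- fit_gene_flow_curves(summary$increment, summary$mean_r,
                                summary$mean_b)
  list(results = results, summary = summary, fit = fit)
}
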