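#' Discretised distribution of admixture proportions
#'
#' Admixed (non-pure) individuals are summarised by the probability mass of
#' their ancestry proportion Q over bins of width 0.05 spanning
#' `[0.10, 0.90]` — the range left once pure individuals (`Q < 0.1` or
#' `Q > 0.9`) are removed. Sampling returns bin midpoints.
#'
#' @param mix either a two-column object (`bin_lower`, `probability`) or a
#'   named list/vector mapping bin lower edges to probabilities. Lower edges
#'   must lie on the 0.05 lattice within `[0.10, 0.85]`; probabilities must
#'   sum to 1 within `1e-9`.
#' @return a `q_distribution` object with elements `lower`, `upper`,
#'   `midpoint`, `prob`.
#' @export
q_distribution <- function(mix) {
  if (is.null(dim(mix))) {
    lower <- as.numeric(names(mix))
    prob <- as.numeric(mix)
  } else {
    mix <- as.data.frame(mix)
    lower <- as.numeric(mix[[1]])
    prob <- as.numeric(mix[[2]])
  }
  if (length(lower) == 0) stop("empty Q-bin mixture")
  lat <- round((lower - 0.10) / 0.05)
  if (any(abs(lower - (0.10 + 0.05 * lat)) > 1e-9))
    stop("bin lower edges must lie on the 0.05 lattice starting at 0.10")
  if (any(lower < 0.10 - 1e-9) || any(lower > 0.85 + 1e-9))
    stop("bins must lie within [0.10, 0.90]")
  if (anyDuplicated(lat)) stop("overlapping bins")
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-9)
    stop("probabilities must be nonnegative and sum to 1")
  o <- order(lower)
  structure(list(lower = lower[o], upper = lower[o] + 0.05,
                 midpoint = lower[o] + 0.025, prob = prob[o]),
            class = "q_distribution")
}

#' Uniform Q distribution over all 16 bins of `[0.10, 0.90]`
#' @return a [q_distribution()].
#' @export
q_distribution_uniform <- function() {
  lower <- seq(0.10, 0.85, by = 0.05)
  q_distribution(stats::setNames(rep(1 / 16, 16), lower))
}

#' Sample Q values from a discretised Q distribution
#'
#' Bins are drawn multinomially with the distribution's probabilities and
#' each draw returns the bin midpoint.
#'
#' @param qdist a [q_distribution()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_q <- function(qdist, n) {
  stopifnot(inherits(qdist, "q_distribution"))
  sample(qdist$midpoint, n, replace = TRUE, prob = qdist$prob)
}

#' Mean of a discretised Q distribution
#' @param qdist a [q_distribution()].
#' @return the probability-weighted mean of the bin midpoints.
#' @export
mean_q <- function(qdist) sum(qdist$midpoint * qdist$prob)

#' Empirical Q distribution of admixed individuals
#'
#' Histograms admixed Q values over the fixed 0.05 bins of `[0.10, 0.90]`.
#' Values outside the range are excluded: they belong to pure individuals
#' by the `Q < 0.1` / `Q > 0.9` cutoffs.
#'
#' @param admixed_q numeric vector of Q values.
#' @return a [q_distribution()].
#' @export
fit_q_distribution <- function(admixed_q) {
  q <- admixed_q[admixed_q >= 0.10 & admixed_q < 0.90]
  if (length(q) == 0) stop("no Q values inside [0.10, 0.90)")
  lower <- seq(0.10, 0.85, by = 0.05)
  bin <- findInterval(q, c(lower, 0.90), rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = 16)
  q_distribution(stats::setNames(counts / sum(counts), lower))
}
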