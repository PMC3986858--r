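#' Configuration for synthetic cytochrome b haplotypes
#'
#' Describes the mitochondrial marker system: a short cytb amplicon in which
#' one species cluster (American) carries a diagnostic HinfI restriction
#' site (motif `GANTC`) while the other cluster (European) is entirely free
#' of the motif, and the two clusters are separated by many more
#' substitutions than any within-cluster pair. The amplicon screened by RFLP
#' and the (shorter) alignment used for network building are configured
#' separately because the two roles use different fragment lengths.
#'
#' @param amplicon_length amplicon length in bp (default 362).
#' @param network_alignment_length alignment length used for the haplotype
#'   network, at most `amplicon_length` (default 276).
#' @param diagnostic_site_position 0-based offset of the diagnostic HinfI
#'   site in American sequences; `diagnostic_site_position + 5 <=
#'   amplicon_length` (default 60, inside the network alignment).
#' @param n_american_haplotypes,n_european_haplotypes distinct haplotypes
#'   per cluster (defaults 5 and 8).
#' @param within_cluster_max_diffs maximum substitutions between a cluster's
#'   consensus and any of its haplotypes (default 2).
#' @param between_cluster_diffs substitutions between the two cluster
#'   consensi, in addition to the diagnostic site (default 12).
#' @param seed RNG seed.
#' @return a `cytb_config` list.
#' @export
cytb_config <- function(amplicon_length = 362,
                        network_alignment_length = 276,
                        diagnostic_site_position = 60,
                        n_american_haplotypes = 5,
                        n_european_haplotypes = 8,
                        within_cluster_max_diffs = 2,
                        between_cluster_diffs = 12,
                        seed = 1) {
  stopifnot(diagnostic_site_position + 5 <= amplicon_length,
            network_alignment_length <= amplicon_length,
            amplicon_length >= 30,
            n_american_haplotypes >= 1, n_european_haplotypes >= 1,
            within_cluster_max_diffs >= 0,
            between_cluster_diffs > 2 * within_cluster_max_diffs)
  structure(list(amplicon_length = as.integer(amplicon_length),
                 network_alignment_length = as.integer(network_alignment_length),
                 diagnostic_site_position = as.integer(diagnostic_site_position),
                 n_american_haplotypes = as.integer(n_american_haplotypes),
                 n_european_haplotypes = as.integer(n_european_haplotypes),
                 within_cluster_max_diffs = as.integer(within_cluster_max_diffs),
                 between_cluster_diffs = as.integer(between_cluster_diffs),
                 seed = as.integer(seed)),
            class = "cytb_config")
}

has_hinfi <- function(seq_chars) {
  length(find_hinfi_sites(paste(seq_chars, collapse = ""))) > 0
}

# substitute positions `pos` of `seq_chars` with random different bases,
# rejecting any substitution that creates (or, if protect, destroys) a
# GANTC motif relative to the required state.
mutate_positions <- function(seq_chars, pos, forbid_motif, protect_window = NULL) {
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    for (attempt in 1:50) {
      cand <- seq_chars
      cand[p] <- sample(setdiff(bases, seq_chars[p]), 1)
      if (forbid_motif && has_hinfi(cand)) next
      if (!is.null(protect_window) &&
          !identical(cand[protect_window$idx], protect_window$chars)) next
      seq_chars <- cand
      break
    }
  }
  seq_chars
}

#' Generate the two-cluster synthetic cytb haplotype set
#'
#' Builds a European consensus containing no HinfI motif anywhere, derives
#' the American consensus from it by `between_cluster_diffs` substitutions
#' plus insertion of a `GACTC` HinfI site at the diagnostic position, and
#' radiates each cluster's haplotypes within `within_cluster_max_diffs`
#' substitutions of its consensus. European haplotypes never contain a
#' HinfI motif; American haplotypes always retain the diagnostic site.
#'
#' @param config a [cytb_config()].
#' @return a [haplotype_alignment()] with species tags (`"American"` /
#'   `"European"`) and attribute `diagnostic_site_position`.
#' @export
gen_cytb_haplotypes <- function(config = cytb_config()) {
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  L <- config$amplicon_length
  dpos <- config$diagnostic_site_position + 1  # 1-based
  site_idx <- dpos:(dpos + 4)
  # European consensus: motif-free everywhere
  repeat {
    eur <- sample(bases, L, replace = TRUE)
    for (attempt in 1:200) {
      hits <- find_hinfi_sites(paste(eur, collapse = ""))
      if (length(hits) == 0) break
      eur[hits[1] + 1] <- "T"  # break the motif at its G
    }
    if (!has_hinfi(eur)) break
  }
  # American consensus: diverged copy carrying GACTC at the diagnostic site
  amr <- eur
  amr[site_idx] <- c("G", "A", "C", "T", "C")
  free <- setdiff(seq_len(L), site_idx)
  diffpos <- sample(free, config$between_cluster_diffs)
  protect <- list(idx = site_idx, chars = amr[site_idx])
  amr <- mutate_positions(amr, diffpos, forbid_motif = FALSE,
                          protect_window = protect)
  radiate <- function(consensus, n, forbid_motif, protect_window) {
    seqs <- list(consensus)
    guard <- 0
    while (length(seqs) < n) {
      guard <- guard + 1
      if (guard > 500) stop("could not generate enough distinct haplotypes")
      k <- sample.int(max(config$within_cluster_max_diffs, 1), 1)
      pos <- sample(if (is.null(protect_window)) seq_len(L)
                    else setdiff(seq_len(L), protect_window$idx), k)
      cand <- mutate_positions(consensus, pos, forbid_motif, protect_window)
      if (forbid_motif && has_hinfi(cand)) next
      if (!any(vapply(seqs, identical, TRUE, y = cand))) seqs <- c(seqs, list(cand))
    }
    seqs[seq_len(n)]
  }
  am_seqs <- radiate(amr, config$n_american_haplotypes, FALSE, protect)
  eu_seqs <- radiate(eur, config$n_european_haplotypes, TRUE, NULL)
  seqs <- c(vapply(am_seqs, paste, "", collapse = ""),
            vapply(eu_seqs, paste, "", collapse = ""))
  ids <- c(sprintf("AME_h%02d", seq_along(am_seqs)),
           sprintf("EUR_h%02d", seq_along(eu_seqs)))
  species <- c(rep("American", length(am_seqs)), rep("European", length(eu_seqs)))
  out <- haplotype_alignment(stats::setNames(seqs, ids), species = species)
  attr(out, "diagnostic_site_position") <- config$diagnostic_site_position
  out
}

#' Configuration for the coastline-like geographic distance matrix
#'
#' Sampling sites are placed along a one-dimensional transect (an idealised
#' coastline from the southern-most to the northern-most locality); the
#' distance between two sites is the summed length of the segments between
#' them, so the matrix is exactly additive.
#'
#' @param n_sites number of sites (default 12), at least 3.
#' @param spacing_km segment length between adjacent sites (default 500).
#' @param irregular if `TRUE`, segment lengths are drawn log-normally with
#'   median `spacing_km` (sdlog 0.5) instead of being equal.
#' @param seed RNG seed (used only when `irregular`).
#' @return a `geography_config` list.
#' @export
geography_config <- function(n_sites = 12, spacing_km = 500,
                             irregular = FALSE, seed = 1) {
  stopifnot(n_sites >= 3, spacing_km > 0)
  structure(list(n_sites = as.integer(n_sites), spacing_km = spacing_km,
                 irregular = isTRUE(irregular), seed = as.integer(seed)),
            class = "geography_config")
}

#' Generate the transect geographic distance matrix
#'
#' @param config a [geography_config()].
#' @return a [dist_matrix()] of pairwise along-transect distances in km,
#'   labelled `site01 ... siteN` from south to north.
#' @export
gen_geography <- function(config = geography_config()) {
  n <- config$n_sites
  if (config$irregular) {
    set.seed(config$seed)
    seg <- stats::rlnorm(n - 1, meanlog = log(config$spacing_km), sdlog = 0.5)
  } else {
    seg <- rep(config$spacing_km, n - 1)
  }
  pos <- c(0, cumsum(seg))
  m <- abs(outer(pos, pos, `-`))
  diag(m) <- 0
  dist_matrix(m, labels = sprintf("site%02d", seq_len(n)))
}
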