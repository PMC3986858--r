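#' Locate HinfI recognition sites in a sequence
#'
#' HinfI cuts at `G^ANTC` (N any base). Every match start is reported,
#' overlapping matches included. An `N` in the input matches nothing — an
#' ambiguous base never produces a cut call.
#'
#' @param seq a DNA string over `{A,C,G,T,N}`.
#' @return integer vector of 0-based match offsets (empty for no match or an
#'   empty sequence).
#' @export
find_hinfi_sites <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 5) return(integer(0))
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over {A,C,G,T,N}")
  hits <- integer(0)
  from <- 1
  repeat {
    m <- regexpr("GA[ACGT]TC", substr(seq, from, nchar(seq)), perl = TRUE)
    if (m == -1) break
    pos <- as.integer(from + as.integer(m) - 1L)
    hits <- c(hits, pos - 1L)  # 0-based
    from <- pos + 1L           # allow overlaps
  }
  hits
}

#' Classify a cytb sequence by in-silico HinfI RFLP
#'
#' The diagnostic assay: a sequence that carries at least one HinfI site in
#' the amplicon is called American, otherwise European.
#'
#' @param seq DNA string.
#' @param id optional individual ID.
#' @return an `rflp_call` list: `id`, `species`, `n_cut_sites`,
#'   `cut_positions` (0-based).
#' @export
classify_species <- function(seq, id = NA_character_) {
  cuts <- find_hinfi_sites(seq)
  structure(list(id = id,
                 species = if (length(cuts) >= 1) "American" else "European",
                 n_cut_sites = length(cuts),
                 cut_positions = cuts),
            class = "rflp_call")
}

#' Classify every sequence of an alignment
#' @param alignment a [haplotype_alignment()].
#' @return a data frame with columns `id`, `species`, `n_cut_sites`.
#' @export
classify_alignment <- function(alignment) {
  calls <- lapply(seq_along(alignment$seqs), function(i)
    classify_species(alignment$seqs[[i]], names(alignment$seqs)[i]))
  data.frame(id = vapply(calls, `[[`, "", "id"),
             species = vapply(calls, `[[`, "", "species"),
             n_cut_sites = vapply(calls, `[[`, 0L, "n_cut_sites"))
}

#' Frequency of American haplotypes in a set of RFLP calls
#'
#' @param calls a list of `rflp_call`s, or a data frame with a `species`
#'   column (as from [classify_alignment()]).
#' @return list with `H` (frequency of American haplotypes) and `N`
#'   (sample size).
#' @export
haplotype_frequency <- function(calls) {
  species <- if (is.data.frame(calls)) calls$species
             else vapply(calls, `[[`, "", "species")
  N <- length(species)
  if (N == 0) stop("no calls")
  list(H = sum(species == "American") / N, N = N)
}

hamming <- function(a, b) {
  # positions where either sequence has N are skipped
  usable <- a != "N" & b != "N"
  sum(a[usable] != b[usable])
}

#' Minimum-spanning haplotype network
#'
#' Collapses identical sequences into haplotype nodes with multiplicities,
#' computes pairwise Hamming distances (sites with `N` in either sequence
#' skipped), and returns the minimum spanning tree by Kruskal's algorithm
#' with union-find. Ties are broken deterministically by sorting candidate
#' edges on (weight, lexicographic node-ID pair).
#'
#' @param alignment a [haplotype_alignment()].
#' @return a `haplotype_network`: `nodes` (data frame: `haplotype` ID,
#'   `count`, `species` — the majority tag among members, `NA` without
#'   tags), `edges` (data frame: `from`, `to`, `weight`),
#'   `members` (list of member sequence IDs per node).
#' @export
build_msn <- function(alignment) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  seqs <- alignment$seqs
  key <- unname(seqs)
  uniq <- !duplicated(key)
  hap_seq <- key[uniq]
  hap_id <- sprintf("H%02d", seq_along(hap_seq))
  map <- hap_id[match(key, hap_seq)]
  members <- split(names(seqs), map)[hap_id]
  counts <- lengths(members)
  species <- rep(NA_character_, length(hap_id))
  if (!is.null(alignment$species)) {
    sp <- split(alignment$species, map)[hap_id]
    species <- vapply(sp, function(s) names(sort(table(s), decreasing = TRUE))[1], "")
  }
  nodes <- data.frame(haplotype = hap_id, count = as.integer(counts),
                      species = species)
  n <- length(hap_id)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = integer(0))
  if (n > 1) {
    chars <- lapply(hap_seq, function(s) strsplit(s, "")[[1]])
    cand <- expand.grid(i = seq_len(n), j = seq_len(n))
    cand <- cand[cand$i < cand$j, ]
    cand$weight <- mapply(function(i, j) hamming(chars[[i]], chars[[j]]),
                          cand$i, cand$j)
    cand <- cand[order(cand$weight, hap_id[cand$i], hap_id[cand$j]), ]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(nrow(cand))
    for (e in seq_len(nrow(cand))) {
      ri <- find(cand$i[e]); rj <- find(cand$j[e])
      if (ri != rj) { parent[ri] <- rj; keep[e] <- TRUE }
    }
    sel <- cand[keep, ]
    edges <- data.frame(from = hap_id[sel$i], to = hap_id[sel$j],
                        weight = as.integer(sel$weight))
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, members = members,
                 haplotype_seqs = stats::setNames(hap_seq, hap_id)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d haplotypes, %d edges, total weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Write a haplotype network as edge-list TSV plus node table
#'
#' @param network a [build_msn()] result.
#' @param edge_path TSV of `node1`, `node2`, `weight`.
#' @param node_path TSV of `haplotype`, `count`, `species`.
#' @return invisibly, the two paths.
#' @export
write_network <- function(network, edge_path, node_path) {
  utils::write.table(network$edges, edge_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(network$nodes, node_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(edge_path, node_path))
}
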