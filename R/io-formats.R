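#' Aligned haplotype set
#'
#' Equal-length uppercase DNA sequences over `{A,C,G,T,N}` with IDs and
#' optional species/population tags.
#'
#' @param seqs named character vector of sequences.
#' @param species optional character vector of tags, one per sequence.
#' @return a `haplotype_alignment` object.
#' @export
haplotype_alignment <- function(seqs, species = NULL) {
  seqs <- toupper(unlist(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences need IDs")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[lens != lens[1]]
    stop("unequal sequence lengths; offending IDs: ",
         paste(bad, collapse = ", "))
  }
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequences must be over {A,C,G,T,N}")
  if (!is.null(species)) stopifnot(length(species) == length(seqs))
  structure(list(seqs = seqs, species = species),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("<haplotype_alignment> %d sequences x %d bp\n",
              length(x$seqs), nchar(x$seqs[1])))
  invisible(x)
}

# ---- Genepop ---------------------------------------------------------------

#' Read a Genepop file
#'
#' Accepts 2- or 3-digit allele encoding (auto-detected from the first
#' genotype), loci listed one per line or comma-separated, and `Pop`
#' separators in any capitalisation. `000`/`00` encodes a missing allele; a
#' half-missing call is treated as missing. An `allele_offset=<int>` note in
#' the title line (written by [write_genepop()] when allele sizes exceed the
#' encoding width) is added back to every allele code on read.
#'
#' @param path Genepop file.
#' @return a [genotype_table()] with populations `pop1, pop2, ...` (or the
#'   first individual ID of each population block if IDs carry a
#'   `label_...` structure they are kept as given).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  title <- lines[1]
  offset <- 0L
  m <- regmatches(title, regexec("allele_offset=(-?[0-9]+)", title))[[1]]
  if (length(m) == 2) offset <- as.integer(m[2])
  # locus block: lines 2.. until first 'pop'
  body <- lines[-1]
  pop_lines <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_lines) == 0) stop("no Pop separator found")
  loci <- unlist(strsplit(body[seq_len(pop_lines[1] - 1)], "\\s*,\\s*"))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  ids <- pops <- character(0)
  rows1 <- rows2 <- list()
  width <- NA_integer_
  pop_idx <- 0
  for (i in seq(pop_lines[1], length(body))) {
    ln <- body[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1
      next
    }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("line ", i + 1, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    genos <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(genos) != L)
      stop("line ", i + 1, ": ", length(genos), " genotypes for ", L, " loci")
    w <- unique(nchar(genos))
    if (length(w) != 1 || !(w %in% c(4, 6)))
      stop("line ", i + 1, ": inconsistent genotype field width")
    w <- w / 2
    if (is.na(width)) width <- w
    if (w != width)
      stop("line ", i + 1, ": mixed 2- and 3-digit encodings")
    a1 <- as.integer(substr(genos, 1, width))
    a2 <- as.integer(substr(genos, width + 1, 2 * width))
    miss <- a1 == 0 | a2 == 0
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", pop_idx))
    rows1[[length(rows1) + 1]] <- a1 + ifelse(is.na(a1), 0L, offset)
    rows2[[length(rows2) + 1]] <- a2 + ifelse(is.na(a2), 0L, offset)
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(ids, pops, loci,
                 do.call(rbind, rows1), do.call(rbind, rows2))
}

#' Write a Genepop file
#'
#' 3-digit encoding by default. When any allele size exceeds the encoding
#' capacity (999), sizes are shifted by a common offset recorded in the
#' title line as `allele_offset=<int>`, which [read_genepop()] undoes, so
#' the round trip is exact.
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "eelclines genotypes") {
  maxa <- suppressWarnings(max(table$allele1, table$allele2, na.rm = TRUE))
  offset <- 0L
  if (is.finite(maxa) && maxa > 999) {
    mina <- min(table$allele1, table$allele2, na.rm = TRUE)
    offset <- as.integer(mina - 1L)
  }
  header <- if (offset != 0)
    sprintf("%s allele_offset=%d", title, offset) else title
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, table$loci), con)
  fmt <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a - offset))
  for (p in unique(table$populations)) {
    writeLines("Pop", con)
    rows <- which(table$populations == p)
    for (r in rows) {
      genos <- paste0(fmt(table$allele1[r, ]), fmt(table$allele2[r, ]))
      writeLines(paste0(table$individuals[r], " ,  ",
                        paste(genos, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read / write a genotype table as CSV
#'
#' Flat dialect: columns `id`, `population`, then one column per locus with
#' the two allele sizes as `"100/102"`; missing calls are empty cells.
#'
#' @param table a [genotype_table()].
#' @param path CSV file.
#' @return `write_genotype_csv()` returns `path` invisibly;
#'   `read_genotype_csv()` returns a [genotype_table()].
#' @export
write_genotype_csv <- function(table, path) {
  df <- data.frame(id = table$individuals, population = table$populations)
  for (l in seq_along(table$loci)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    df[[table$loci[l]]] <- ifelse(is.na(a1), "", paste0(a1, "/", a2))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("id", "population") %in% names(df)))
    stop("genotype CSV needs 'id' and 'population' columns")
  loci <- setdiff(names(df), c("id", "population"))
  n <- nrow(df)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (l in seq_along(loci)) {
    cells <- df[[loci[l]]]
    filled <- nzchar(cells) & !is.na(cells)
    parts <- strsplit(cells[filled], "/", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("malformed call at locus ", loci[l],
           ": expected 'allele1/allele2'")
    a1[filled, l] <- as.integer(vapply(parts, `[`, "", 1))
    a2[filled, l] <- as.integer(vapply(parts, `[`, "", 2))
  }
  genotype_table(df$id, df$population, loci, a1, a2)
}

# ---- FASTA -----------------------------------------------------------------

#' Read an aligned FASTA file
#'
#' Standard FASTA (wrapped or unwrapped) via Biostrings; the equal-length
#' alignment invariant is enforced on read. Species tags are recovered from
#' a `" species=<tag>"` suffix in the description line when present.
#'
#' @param path FASTA file.
#' @return a [haplotype_alignment()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  desc <- names(set)
  species <- NULL
  m <- regmatches(desc, regexec("\\bspecies=(\\S+)", desc))
  if (all(lengths(m) == 2)) species <- vapply(m, `[`, "", 2)
  ids <- sub("\\s.*$", "", desc)
  haplotype_alignment(stats::setNames(as.character(set), ids),
                      species = species)
}

#' Write an aligned FASTA file
#' @param alignment a [haplotype_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  ids <- names(alignment$seqs)
  if (!is.null(alignment$species))
    ids <- paste0(ids, " species=", alignment$species)
  set <- Biostrings::DNAStringSet(stats::setNames(alignment$seqs, NULL))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

# ---- distance matrices -----------------------------------------------------

#' Read a distance matrix (PHYLIP square or labelled CSV)
#'
#' PHYLIP-style: first line the matrix order, then one labelled row per
#' taxon. CSV: a header of labels and a label column. Symmetry is validated
#' to `1e-6`.
#'
#' @param path input file.
#' @return a [dist_matrix()].
#' @export
read_distance_matrix <- function(path) {
  first <- trimws(readLines(path, n = 1))
  if (grepl("^[0-9]+$", first)) {
    n <- as.integer(first)
    tok <- scan(path, what = "character", skip = 1, quiet = TRUE)
    tok <- matrix(tok, nrow = n, byrow = TRUE)
    labels <- tok[, 1]
    vals <- matrix(as.numeric(tok[, -1]), n, n)
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    labels <- rownames(df)
    vals <- as.matrix(df)
  }
  if (max(abs(vals - t(vals))) > 1e-6)
    stop("matrix is asymmetric beyond 1e-6")
  dist_matrix(vals, labels = labels, tol = 1e-6)
}

#' Write a distance matrix
#'
#' @param m a [dist_matrix()] (or plain symmetric matrix).
#' @param path output file.
#' @param format `"phylip"` (square, labelled rows) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("phylip", "csv")) {
  format <- match.arg(format)
  labels <- rownames(m)
  if (format == "csv") {
    df <- as.data.frame(unclass(m))
    utils::write.csv(df, path, row.names = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d", nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(labels[i],
                         format(m[i, ], digits = 10, trim = TRUE)),
                       collapse = "  "), con)
  }
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
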