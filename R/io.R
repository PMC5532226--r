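#' Read a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into a named character vector.
#' Record ids are the first whitespace-delimited token of each header, must be
#' unique, and record order follows file order. Sequence characters are
#' validated against the molecule alphabet (20 amino acids plus X, or ACGTN).
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @return Named character vector of sequences with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stopf("read_fasta: file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("read_fasta: empty file: %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1])
    stopf("read_fasta: line 1 is not a FASTA header: '%s'", lines[1])
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(hdr)[!nzchar(ids) | is.na(ids)][1]
    stopf("read_fasta: empty header at line %d", bad)
  }
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    empty <- setdiff(seq_along(ids), as.integer(names(seqs)[nzchar(seqs)]))
    stopf("read_fasta: record '%s' (line %d) has no sequence",
          ids[empty[1]], which(hdr)[empty[1]])
  }
  seqs <- toupper(seqs)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("read_fasta: duplicate id(s): %s", paste(dup, collapse = ", "))
  names(seqs) <- ids
  for (i in seq_along(seqs)) check_alphabet(seqs[i], moltype, ids[i])
  structure(seqs, moltype = moltype)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stopf("write_fasta: sequences must be named")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read the transcribed family table
#'
#' Reads the TSV transcription of the published moso bamboo WRKY family table
#' (one row per gene: group label, heptapeptide(s), zinc-finger type(s) and the
#' spacer counts m and n of the C-Xm-C-Xn-H-X-H/C motif). `"/"` marks absent
#' values as in the printed table; an asterisked id marks group-1 members whose
#' C-terminal domain lacks the zinc finger (`incomplete_flag`).
#'
#' @param path Path to the TSV (defaults to the bundled transcription).
#' @return `data.frame` with columns `gene_id`, `group_label`,
#'   `heptapeptide_1/2`, `zf_type_1/2`, `m_1/2`, `n_1/2` (integer or NA),
#'   `incomplete_flag`, `verbatim`.
#' @export
read_family_table <- function(path = system.file("extdata",
                                                 "phewrky_family_table.tsv",
                                                 package = "wrkykit")) {
  if (!file.exists(path)) stopf("read_family_table: file not found: %s", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("gene_id", "group_label", "heptapeptide_1", "heptapeptide_2",
            "zf_type_1", "zf_type_2", "m_1", "m_2", "n_1", "n_2",
            "incomplete_flag")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("read_family_table: missing column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(tab$group_label, c(WRKY_GROUPS, "/"))
  if (length(bad))
    stopf("read_family_table: unknown group label(s): %s",
          paste(unique(bad), collapse = ", "))
  tab$group_label[tab$group_label == "/"] <- "unclassified"
  for (col in c("m_1", "m_2", "n_1", "n_2")) {
    v <- tab[[col]]
    num <- v != "/"
    if (any(num & !grepl("^[0-9]+$", v)))
      stopf("read_family_table: non-integer %s value '%s'",
            col, v[num & !grepl("^[0-9]+$", v)][1])
    tab[[col]] <- ifelse(num, suppressWarnings(as.integer(v)), NA_integer_)
  }
  for (col in c("zf_type_1", "zf_type_2")) {
    bad <- setdiff(tab[[col]], c("C2H2", "C2HC", "/"))
    if (length(bad))
      stopf("read_family_table: unknown zinc-finger type '%s'", bad[1])
  }
  tab$incomplete_flag <- tab$incomplete_flag %in% c("TRUE", "true", "1")
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup))
    stopf("read_family_table: duplicate gene id(s): %s",
          paste(dup, collapse = ", "))
  tab
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix/data.frame of 1-based inclusive
#'   (start, end) coding-exon intervals in genomic coordinates. They are
#'   reordered into transcription order (by start for `+`, reverse for `-`).
#' @return A `wrky_gene_model` list.
#' @export
gene_model <- function(gene_id, strand, exons) {
  if (!strand %in% c("+", "-")) stopf("gene_model: strand must be + or -")
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  if (any(exons[, 2] < exons[, 1]))
    stopf("gene_model %s: exon end before start", gene_id)
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stopf("gene_model %s: overlapping exons", gene_id)
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  len <- sum(exons[, 2] - exons[, 1] + 1L)
  if (len < 3L) stopf("gene_model %s: total exonic length < 3", gene_id)
  structure(list(gene_id = gene_id, strand = strand, exons = exons),
            class = "wrky_gene_model")
}

#' Intron phases of a gene model
#'
#' Phase of intron k is the cumulative length of coding exons 1..k
#' (transcription order) mod 3: 0 means the intron falls between codons,
#' 1 and 2 split a codon after its first or second base.
#'
#' @param model A [gene_model()].
#' @return Integer vector of phases in `{0,1,2}`, length `n_exons - 1`.
#' @export
intron_phases <- function(model) {
  stopifnot(inherits(model, "wrky_gene_model"))
  lens <- model$exons[, 2] - model$exons[, 1] + 1L
  if (sum(lens) %% 3L != 0L)
    stopf("intron_phases %s: CDS length %d not divisible by 3",
          model$gene_id, sum(lens))
  if (length(lens) == 1L) return(integer(0))
  cumsum(lens)[-length(lens)] %% 3L
}

#' Read coding gene models from a GFF3 file
#'
#' CDS features are grouped by their `Parent` (falling back to `ID`)
#' attribute; each group becomes one [gene_model()]. Backed by
#' `rtracklayer::import`.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `wrky_gene_model` objects.
#' @export
read_gff_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("read_gff_models requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[gr$type == "CDS", , drop = FALSE]
  if (!nrow(gr)) stopf("read_gff_models: no CDS features in %s", path)
  parent <- if ("Parent" %in% names(gr)) as.character(gr$Parent) else gr$ID
  if (!length(parent) || all(is.na(parent) | !nzchar(parent))) parent <- gr$ID
  keys <- unique(parent)
  models <- lapply(keys, function(k) {
    sel <- parent == k
    gene_model(k, as.character(gr$strand[sel])[1],
               cbind(gr$start[sel], gr$end[sel]))
  })
  names(models) <- keys
  models
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so trees
#' round-trip through plain text.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly if written to a file);
#'   `read_newick`: an `ape::phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
}
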