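# resolve a substitution matrix argument: name of a Biostrings data matrix
# (e.g. "BLOSUM62") or a numeric matrix with residue dimnames
get_submat <- function(matrix) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  matrix
}

encode_seq <- function(seq, alphabet, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx))
    stopf("align: %s contains residue(s) absent from the substitution matrix: %s",
          what, paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under an affine gap model: a gap of length L costs
#' `gap_open + L * gap_extend`. Fractional identity is matches divided by
#' aligned residue columns (columns containing a gap are excluded).
#'
#' @param a,b Protein sequences (single strings).
#' @param matrix Substitution matrix or the name of a Biostrings matrix
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 10 and 0.5).
#' @return List: `score`, `alignment` (character vector of the two gapped
#'   sequences), `identity`.
#' @export
align_global <- function(a, b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stopf("align_global: empty sequence")
  sub <- get_submat(matrix)
  alph <- rownames(sub)
  res <- .nw_align(encode_seq(a, alph, "a"), encode_seq(b, alph, "b"),
                   sub, gap_open, gap_extend)
  ga <- rep("-", length(res$a)); gb <- rep("-", length(res$b))
  ga[res$a >= 0] <- alph[res$a[res$a >= 0] + 1L]
  gb[res$b >= 0] <- alph[res$b[res$b >= 0] + 1L]
  resid <- res$a >= 0 & res$b >= 0
  identity <- if (any(resid)) sum(ga[resid] == gb[resid]) / sum(resid) else 0
  list(score = res$score,
       alignment = c(a = paste(ga, collapse = ""),
                     b = paste(gb, collapse = "")),
       identity = identity)
}

#' Local alignment score (Smith-Waterman, affine gaps)
#'
#' @inheritParams align_global
#' @return Numeric score (0 when no positive-scoring local alignment exists).
#' @export
align_local_score <- function(a, b, matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stopf("align_local_score: empty sequence")
  sub <- get_submat(matrix)
  alph <- rownames(sub)
  .sw_score(encode_seq(a, alph, "a"), encode_seq(b, alph, "b"),
            sub, gap_open, gap_extend)
}

#' Pairwise distance matrix from global alignments
#'
#' Distance is 1 - fractional identity over aligned columns. The result is
#' symmetric with zero diagonal and entries in \[0, 1\]; the triangle
#' inequality is not guaranteed.
#'
#' @param seqs Named character vector of protein sequences.
#' @param ... Passed to [align_global()].
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
distance_matrix <- function(seqs, ...) {
  n <- length(seqs)
  if (is.null(names(seqs))) stopf("distance_matrix: sequences must be named")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 1 - align_global(seqs[[i]], seqs[[j]], ...)$identity
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Bidirectional best hits between two sequence sets
#'
#' Scores every cross pair by local alignment ([align_local_score()]) and
#' reports (a, b) if and only if b is a's unique best-scoring hit in set B and
#' a is b's unique best in set A. Ties mean no unique best, hence no pair —
#' the conservative reading of a strict 1:1 orthologue ratio. With
#' `seqs_a` identical to `seqs_b` (same ids) self-hits are excluded and the
#' call finds within-species paralogue pairs.
#'
#' @param seqs_a,seqs_b Named character vectors of protein sequences.
#' @param species_a,species_b Species tag per set (scalar) or per sequence.
#' @param ... Passed to [align_local_score()].
#' @return `data.frame`: `id_a`, `id_b`, `species_a`, `species_b`, `score`,
#'   `relation` (`"ortholog"` when species differ, else `"paralog"`); pairs in
#'   canonical id order for within-species pairs.
#' @export
bbh <- function(seqs_a, species_a, seqs_b = seqs_a, species_b = species_a,
                ...) {
  if (!length(seqs_a) || !length(seqs_b)) stopf("bbh: empty sequence set")
  spa <- rep_len(species_a, length(seqs_a))
  spb <- rep_len(species_b, length(seqs_b))
  same_set <- identical(names(seqs_a), names(seqs_b))
  S <- matrix(NA_real_, length(seqs_a), length(seqs_b),
              dimnames = list(names(seqs_a), names(seqs_b)))
  for (i in seq_along(seqs_a)) for (j in seq_along(seqs_b)) {
    if (same_set && names(seqs_a)[i] == names(seqs_b)[j]) next  # self-hit
    if (same_set && !is.na(S[j, i])) { S[i, j] <- S[j, i]; next }
    S[i, j] <- align_local_score(seqs_a[[i]], seqs_b[[j]], ...)
  }
  unique_best <- function(v) {
    m <- max(v, na.rm = TRUE)
    w <- which(!is.na(v) & v == m)
    if (length(w) == 1L) w else NA_integer_
  }
  best_ab <- apply(S, 1, unique_best)   # for each a: its best b
  best_ba <- apply(S, 2, unique_best)   # for each b: its best a
  rows <- list()
  for (i in seq_along(best_ab)) {
    j <- best_ab[i]
    if (is.na(j) || is.na(best_ba[j]) || best_ba[j] != i) next
    ia <- names(seqs_a)[i]; ib <- names(seqs_b)[j]
    rel <- if (spa[i] == spb[j]) "paralog" else "ortholog"
    if (rel == "paralog") {
      if (ia >= ib) next  # canonical order; mutual pair appears once
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ia, id_b = ib, species_a = spa[i], species_b = spb[j],
        score = S[i, j], relation = rel, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ia, id_b = ib, species_a = spa[i], species_b = spb[j],
        score = S[i, j], relation = rel, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id_a = character(0), id_b = character(0),
                      species_a = character(0), species_b = character(0),
                      score = numeric(0), relation = character(0)))
  do.call(rbind, rows)
}
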