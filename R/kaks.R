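# standard genetic code from Biostrings; "*" = stop
codon_table <- function() Biostrings::GENETIC_CODE

#' Translate a coding sequence
#'
#' Standard genetic code. Errors on length not divisible by 3 and on
#' stop codons anywhere in frame (a trailing stop is allowed and dropped only
#' when `allow_final_stop = TRUE`).
#'
#' @param cds Nucleotide string (ACGT; codons containing N translate to X).
#' @param allow_final_stop Drop a trailing stop codon instead of erroring.
#' @return Protein string.
#' @export
translate_cds <- function(cds, allow_final_stop = FALSE) {
  cds <- toupper(unname(cds[[1]]))
  if (nchar(cds) %% 3 != 0)
    stopf("translate_cds: length %d not divisible by 3", nchar(cds))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- codon_table()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"                      # ambiguous (N-containing) codons
  if (allow_final_stop && length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]; codons <- codons[-length(codons)]
  }
  if (any(aa == "*"))
    stopf("translate_cds: in-frame stop codon at codon %d", which(aa == "*")[1])
  paste(aa, collapse = "")
}

#' Pair codons through a protein alignment
#'
#' Back-translates a pairwise protein alignment onto the two coding sequences:
#' each aligned residue column yields one codon pair; gap columns are dropped,
#' as are codon pairs in which either codon contains N. Each CDS must be
#' exactly 3x its protein length (stop excluded) and translate to the
#' ungapped protein, otherwise an error names the offending position.
#'
#' @param alignment Character vector of the two gapped protein sequences
#'   (e.g. `align_global(...)$alignment`).
#' @param cds_a,cds_b The coding sequences.
#' @return List with character vectors `codons_a` and `codons_b`.
#' @export
codon_align <- function(alignment, cds_a, cds_b) {
  ga <- strsplit(alignment[[1]], "")[[1]]
  gb <- strsplit(alignment[[2]], "")[[1]]
  if (length(ga) != length(gb)) stopf("codon_align: ragged alignment")
  check_cds <- function(cds, gapped, who) {
    prot <- paste(gapped[gapped != "-"], collapse = "")
    if (nchar(cds) != 3 * nchar(prot))
      stopf("codon_align: %s CDS length %d != 3 x protein length %d",
            who, nchar(cds), nchar(prot))
    tr <- translate_cds(cds)
    mism <- which(strsplit(tr, "")[[1]] != strsplit(prot, "")[[1]])
    # codons with N translate to X; treat X as wildcard
    if (length(mism)) mism <- mism[substring(tr, mism, mism) != "X"]
    if (length(mism))
      stopf("codon_align: %s CDS does not translate to the protein at residue %d",
            who, mism[1])
  }
  check_cds(cds_a, ga, "a"); check_cds(cds_b, gb, "b")
  codons_of <- function(cds) substring(cds, seq(1, nchar(cds), 3),
                                       seq(3, nchar(cds), 3))
  ca <- codons_of(cds_a); cb <- codons_of(cds_b)
  ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
  keep <- ga != "-" & gb != "-"
  pa <- ca[ia[keep]]; pb <- cb[ib[keep]]
  ok <- !grepl("N", pa) & !grepl("N", pb)
  list(codons_a = pa[ok], codons_b = pb[ok])
}

# fraction of synonymous single-nucleotide changes per position of a codon;
# changes to stop codons count as nonsynonymous
syn_fraction <- function(codon, gc = codon_table()) {
  aa <- gc[[codon]]
  nts <- c("A", "C", "G", "T")
  f <- 0
  for (p in 1:3) {
    from <- substr(codon, p, p)
    for (nt in setdiff(nts, from)) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (gc[[alt]] == aa && gc[[alt]] != "*") f <- f + 1 / 3
    }
  }
  f  # synonymous sites contributed by this codon
}

# pathway-averaged (synonymous, nonsynonymous) difference counts for one
# codon pair: all orders of the differing positions, equal weight; pathways
# passing through a stop codon are excluded (all pathways used if every one
# is blocked)
count_diffs <- function(ca, cb, gc = codon_table()) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else {
    p <- list()
    idx <- seq_len(k)
    rec <- function(prefix, rest) {
      if (!length(rest)) { p[[length(p) + 1]] <<- pos[prefix]; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), idx)
    p
  }
  walk <- function(order) {
    cur <- ca; s <- 0; n <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*") return(NULL)
      if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok)) {   # every pathway blocked by a stop: use them all
    res <- lapply(perms, function(order) {
      cur <- ca; s <- 0; n <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- colMeans(do.call(rbind, res[ok]))
  c(sd = m[1], nd = m[2])
}

#' Jukes-Cantor distance correction
#'
#' `JC(p) = -(3/4) log(1 - 4p/3)`; `NA` when `p >= 3/4`.
#' @param p Observed proportion of differences.
#' @return Corrected substitutions per site.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3) + 0)  # +0 kills -0
}

#' Nei-Gojobori Ka/Ks estimation
#'
#' The 1986 unweighted-pathway estimator: synonymous site counts from the
#' fraction of synonymous single-nucleotide changes per codon position
#' (changes to stops are nonsynonymous; S is averaged over the two
#' sequences), synonymous/nonsynonymous differences averaged with equal
#' weight over all shortest substitution pathways (stop-crossing pathways
#' excluded), proportions pS = sd/S and pN = nd/N, and Jukes-Cantor
#' correction Ks = JC(pS), Ka = JC(pN). When pS or pN reaches 3/4 the
#' corrected value is NA and `flagged` is set.
#'
#' @param codons_a,codons_b Equal-length codon vectors (e.g. from
#'   [codon_align()]); no stop codons.
#' @return List: `S`, `N`, `sd`, `nd`, `pS`, `pN`, `Ks`, `Ka`, `flagged`,
#'   `n_codons`.
#' @export
nei_gojobori <- function(codons_a, codons_b) {
  if (!length(codons_a) || length(codons_a) != length(codons_b))
    stopf("nei_gojobori: need equal, nonzero numbers of codons")
  gc <- codon_table()
  if (any(gc[codons_a] == "*") || any(gc[codons_b] == "*"))
    stopf("nei_gojobori: stop codon in input")
  L <- length(codons_a)
  Sa <- sum(vapply(codons_a, syn_fraction, 0, gc = gc))
  Sb <- sum(vapply(codons_b, syn_fraction, 0, gc = gc))
  S <- (Sa + Sb) / 2
  N <- 3 * L - S
  d <- vapply(seq_len(L), function(i)
    count_diffs(codons_a[i], codons_b[i], gc), c(sd = 0, nd = 0))
  sd_ <- sum(d["sd", ]); nd_ <- sum(d["nd", ])
  pS <- sd_ / S; pN <- nd_ / N
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  list(S = S, N = N, sd = sd_, nd = nd_, pS = pS, pN = pN,
       Ks = Ks, Ka = Ka, flagged = is.na(Ks) || is.na(Ka), n_codons = L)
}

#' Date a duplication from synonymous divergence
#'
#' `T = Ks / (2 lambda)`, reported in million years (mya). The default clock
#' rate is the grass synonymous rate 6.5e-9 substitutions/synonymous
#' site/year; use 1.5e-8 for *A. thaliana*.
#'
#' @param Ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda Clock rate in substitutions/synonymous site/year.
#' @return List: `Ks`, `lambda`, `T_mya`.
#' @export
divergence_time <- function(Ks, lambda = 6.5e-9) {
  if (any(Ks < 0, na.rm = TRUE)) stopf("divergence_time: negative Ks")
  if (lambda <= 0) stopf("divergence_time: lambda must be positive")
  list(Ks = Ks, lambda = lambda, T_mya = Ks / (2 * lambda) / 1e6)
}

#' Ka/Ks and duplication dates for a list of pairs
#'
#' Convenience wrapper: for each (id_a, id_b) pair, align the proteins,
#' back-translate onto the CDSs, run [nei_gojobori()] and date with
#' [divergence_time()].
#'
#' @param pairs `data.frame` with columns `id_a`, `id_b`.
#' @param cds Named character vector of coding sequences.
#' @param proteins Optional named protein vector (derived by translation when
#'   absent).
#' @param lambda Clock rate for [divergence_time()].
#' @param ... Passed to [align_global()].
#' @return `data.frame`: `id_a,id_b,S,N,pS,pN,Ka,Ks,T_mya,flagged`.
#' @export
kaks_pairs <- function(pairs, cds, proteins = NULL, lambda = 6.5e-9, ...) {
  if (is.null(proteins))
    proteins <- vapply(cds, translate_cds, "", allow_final_stop = TRUE)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$id_a[i]; b <- pairs$id_b[i]
    if (!a %in% names(cds) || !b %in% names(cds))
      stopf("kaks_pairs: missing CDS for pair %s / %s", a, b)
    aln <- align_global(proteins[[a]], proteins[[b]], ...)
    cp <- codon_align(aln$alignment,
                      substr(cds[[a]], 1, 3 * nchar(proteins[[a]])),
                      substr(cds[[b]], 1, 3 * nchar(proteins[[b]])))
    ng <- nei_gojobori(cp$codons_a, cp$codons_b)
    Tm <- if (is.na(ng$Ks)) NA_real_ else divergence_time(ng$Ks, lambda)$T_mya
    data.frame(id_a = a, id_b = b, S = ng$S, N = ng$N, pS = ng$pS,
               pN = ng$pN, Ka = ng$Ka, Ks = ng$Ks, T_mya = Tm,
               flagged = ng$flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
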