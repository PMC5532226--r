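# Independent oracles used to validate the package's implementations.
# These deliberately re-derive results by enumeration rather than calling the
# code paths they check.

# --- brute-force global alignment score --------------------------------------
# Enumerates every global alignment of a and b (as sequences of match /
# gap-in-b / gap-in-a columns) and scores it with affine gaps: a gap run of
# length L costs gap_open + L * gap_extend. Only usable for tiny sequences.
brute_force_nw <- function(a, b, sub, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    # state: 0 none/match, 1 gap consuming a, 2 gap consuming b
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, score + sub[av[i], bv[j]], 0)
    if (i <= length(av)) {
      open <- if (state == 1) 0 else gap_open
      rec(i + 1, j, score - open - gap_extend, 1)
    }
    if (j <= length(bv)) {
      open <- if (state == 2) 0 else gap_open
      rec(i, j + 1, score - open - gap_extend, 2)
    }
  }
  rec(1, 1, 0, 0)
  best
}

# --- exhaustive Nei-Gojobori pathway oracle ----------------------------------
# Counts synonymous/nonsynonymous differences for one codon pair by explicit
# enumeration of all orderings of the differing positions; pathways through a
# stop are dropped (all kept if every pathway is blocked). Site counts by
# explicit enumeration of the 9 single-nucleotide changes.
GC_TAB <- Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  total <- 0
  for (p in 1:3) {
    syn <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, p, p) == nt) next
      alt <- codon; substr(alt, p, p) <- nt
      if (GC_TAB[[alt]] != "*" && GC_TAB[[alt]] == GC_TAB[[codon]])
        syn <- syn + 1
    }
    total <- total + syn / 3
  }
  total
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  out
}

oracle_count_diffs <- function(ca, cb, drop_stop_paths = TRUE) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- all_perms(pos)
  walk <- function(ord, allow_stop) {
    cur <- ca; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(cb, p, p)
      if (!allow_stop && GC_TAB[[nxt]] == "*") return(NULL)
      if (GC_TAB[[nxt]] == GC_TAB[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(paths, walk, allow_stop = !drop_stop_paths)
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) res <- lapply(paths, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

oracle_nei_gojobori <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, 0)) +
          sum(vapply(codons_b, oracle_syn_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  d <- vapply(seq_along(codons_a), function(i)
    oracle_count_diffs(codons_a[i], codons_b[i]), c(0, 0))
  sd_ <- sum(d[1, ]); nd_ <- sum(d[2, ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd_, nd = nd_, Ks = jc(sd_ / S), Ka = jc(nd_ / N))
}

# random non-stop codon pair with <= max_diff differences
random_codon_pair <- function(max_diff = 3) {
  nts <- c("A", "C", "G", "T")
  repeat {
    ca <- paste(sample(nts, 3, replace = TRUE), collapse = "")
    if (GC_TAB[[ca]] != "*") break
  }
  repeat {
    cb <- ca
    k <- sample(0:max_diff, 1)
    if (k > 0) for (p in sample(3, k)) {
      substr(cb, p, p) <- sample(setdiff(nts, substr(cb, p, p)), 1)
    }
    if (GC_TAB[[cb]] != "*") break
  }
  c(ca, cb)
}

# --- misc fixtures ------------------------------------------------------------
# random additive distance matrix from a random binary tree (ape)
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  o <- sort(rownames(D))
  list(tree = tr, D = D[o, o])
}

# small substitution matrix access
blosum62 <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
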