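#' Scanner configuration
#'
#' Defaults reflect the family's canonical domain architecture: heptapeptides
#' within Hamming distance 2 of WRKYGQK (the largest observed variant distance,
#' CRKYGQA, is 2), zinc-finger spacers m in \[4, 8\] and n in \[20, 40\]
#' (covering every tabulated member except the single C-X5-C-X88 outlier), and
#' a 150-residue search window downstream of the heptapeptide. `extended = TRUE`
#' raises `n_max` to 120 and the window to 250 residues, enough to detect the
#' possibly mis-annotated C-X5-C-X88 arrangement; it is opt-in and off by
#' default.
#'
#' @param max_mismatch Maximum Hamming distance to WRKYGQK (default 2).
#' @param m_min,m_max Range searched for the Cys-Cys spacer m.
#' @param n_min,n_max Range searched for the Cys-His spacer n.
#' @param window Residues scanned downstream of a heptapeptide for the zinc
#'   finger.
#' @param extended Use the extended ranges (`n_max = 120`, `window = 250`).
#' @return List of scanner parameters.
#' @export
scan_config <- function(max_mismatch = 2, m_min = 4, m_max = 8,
                        n_min = 20, n_max = 40, window = 150,
                        extended = FALSE) {
  if (extended) { n_max <- max(n_max, 120); window <- max(window, 250) }
  stopifnot(max_mismatch >= 0, m_min >= 0, m_max >= m_min,
            n_min >= 0, n_max >= n_min, window > 0)
  list(max_mismatch = as.integer(max_mismatch), m_min = as.integer(m_min),
       m_max = as.integer(m_max), n_min = as.integer(n_min),
       n_max = as.integer(n_max), window = as.integer(window),
       extended = isTRUE(extended))
}

#' Find WRKY heptapeptides in a protein
#'
#' Scans every 7-mer for Hamming distance `max_mismatch` or less to WRKYGQK.
#' Overlapping candidate hits are resolved by keeping the lower-distance hit,
#' ties going to the leftmost.
#'
#' @param seq Protein sequence (single string).
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @return `data.frame` with columns `position` (0-based start), `sequence`
#'   (the 7-mer) and `hamming`, ordered by position.
#' @export
find_heptapeptides <- function(seq, max_mismatch = 2) {
  check_alphabet(seq, "protein")
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 7)
    return(data.frame(position = integer(0), sequence = character(0),
                      hamming = integer(0)))
  canon <- strsplit(WRKY_CANONICAL, "")[[1]]
  # mismatch count per window via 7 shifted comparisons
  mm <- integer(L - 6)
  for (k in 1:7) mm <- mm + (chars[k:(L - 7 + k)] != canon[k])
  pos <- which(mm <= max_mismatch)          # 1-based starts
  if (!length(pos))
    return(data.frame(position = integer(0), sequence = character(0),
                      hamming = integer(0)))
  cand <- data.frame(position = pos - 1L,
                     sequence = substring(seq, pos, pos + 6),
                     hamming = mm[pos])
  # resolve overlaps: best (lowest hamming, then leftmost) wins its window
  keep <- logical(nrow(cand))
  avail <- rep(TRUE, nrow(cand))
  ord <- order(cand$hamming, cand$position)
  for (i in ord) {
    if (!avail[i]) next
    keep[i] <- TRUE
    avail[abs(cand$position - cand$position[i]) < 7] <- FALSE
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

#' Locate the zinc-finger motif downstream of a heptapeptide
#'
#' Searches for the first match of `C X(m) C X(n) H X [H|C]` downstream of
#' `start`, trying the smallest first-Cys position, then the smallest m, then
#' the smallest n — a unique, reproducible parse. The final coordinating
#' residue determines the type: H gives C2H2, C gives C2HC.
#'
#' @param seq Protein sequence.
#' @param start 0-based position at which the search begins (typically the end
#'   of the heptapeptide).
#' @param config A [scan_config()].
#' @return `NULL` if no motif is found, otherwise a list with `zf_type`,
#'   `m`, `n` and `positions` (0-based positions of C, C, H, H/C).
#' @export
find_zinc_finger <- function(seq, start, config = scan_config()) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  start <- as.integer(start)
  first <- start + 1L                        # 1-based search origin
  if (first < 1L || first > L) stopf("find_zinc_finger: start out of range")
  last_c1 <- min(L, start + config$window)
  for (c1 in first:last_c1) {
    if (chars[c1] != "C") next
    for (m in config$m_min:config$m_max) {
      c2 <- c1 + m + 1L
      if (c2 > L || chars[c2] != "C") next
      for (n in config$n_min:config$n_max) {
        h1 <- c2 + n + 1L
        hx <- h1 + 2L
        if (hx > L) break
        if (chars[h1] != "H") next
        if (chars[hx] %in% c("H", "C")) {
          return(list(zf_type = if (chars[hx] == "H") "C2H2" else "C2HC",
                      m = m, n = n,
                      positions = c(c1, c2, h1, hx) - 1L))
        }
      }
    }
  }
  NULL
}

#' Scan a protein for WRKY domains
#'
#' Pairs each heptapeptide hit with its downstream zinc finger (if any).
#' Domains may not overlap: hits are taken greedily left to right, and a hit
#' falling inside the previous domain's extent is dropped. Terminal labels
#' follow domain order: a single domain is `"only"`; with several, the first is
#' `"N"` and later ones `"C"`.
#'
#' @param seq Protein sequence (a single string; a 1-element named vector works
#'   and supplies the gene id).
#' @param config A [scan_config()].
#' @return `data.frame` with one row per domain: `gene_id`, `domain_index`,
#'   `terminal`, `heptapeptide`, `position`, `hamming`, `zf_type`, `m`, `n`,
#'   `complete`.
#' @export
scan_protein <- function(seq, config = scan_config()) {
  gene_id <- if (!is.null(names(seq))) names(seq)[1] else NA_character_
  seq <- unname(seq[[1]])
  hits <- find_heptapeptides(seq, config$max_mismatch)
  rows <- list()
  dom_end <- -1L   # 0-based end (exclusive) of the previous domain
  for (i in seq_len(nrow(hits))) {
    if (hits$position[i] < dom_end) next
    zf <- find_zinc_finger(seq, hits$position[i] + 7L, config)
    dom_end <- if (is.null(zf)) hits$position[i] + 7L
               else zf$positions[4] + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, domain_index = NA_integer_, terminal = NA_character_,
      heptapeptide = hits$sequence[i], position = hits$position[i],
      hamming = hits$hamming[i],
      zf_type = if (is.null(zf)) NA_character_ else zf$zf_type,
      m = if (is.null(zf)) NA_integer_ else zf$m,
      n = if (is.null(zf)) NA_integer_ else zf$n,
      zf_end = if (is.null(zf)) NA_integer_ else zf$positions[4],
      complete = !is.null(zf))
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), domain_index = integer(0),
                      terminal = character(0), heptapeptide = character(0),
                      position = integer(0), hamming = integer(0),
                      zf_type = character(0), m = integer(0), n = integer(0),
                      zf_end = integer(0), complete = logical(0)))
  out <- do.call(rbind, rows)
  out$domain_index <- seq_len(nrow(out))
  out$terminal <- if (nrow(out) == 1L) "only" else
    c("N", rep("C", nrow(out) - 1L))
  out
}

#' Extract the domain region of a scanned protein
#'
#' Returns the substring from the heptapeptide start to the zinc finger's
#' last coordinating residue (or the heptapeptide end for incomplete
#' domains), i.e. the region subgroup classification aligns.
#'
#' @param seq The protein sequence the scan row came from.
#' @param scan_row One row of a [scan_protein()] result.
#' @return Domain substring.
#' @export
extract_domain <- function(seq, scan_row) {
  seq <- unname(seq[[1]])
  from <- scan_row$position + 1L
  to <- if (isTRUE(scan_row$complete)) scan_row$zf_end + 1L
        else scan_row$position + 7L
  substr(seq, from, to)
}

#' Scan a set of proteins
#'
#' @param seqs Named character vector of protein sequences.
#' @param config A [scan_config()].
#' @return Row-bound [scan_protein()] results.
#' @export
scan_proteins <- function(seqs, config = scan_config()) {
  do.call(rbind, lapply(names(seqs), function(id)
    scan_protein(setNames(seqs[id], id), config)))
}
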