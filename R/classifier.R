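#' Assign a WRKY group from domain descriptors
#'
#' Classification rules in priority order:
#' 1. two or more heptapeptides with at least one complete domain -> group 1
#'    (`two_domain_c2hc_override` set when any zinc finger is C2HC — the case
#'    of a two-domain protein carrying the group-3-type finger;
#'    `incomplete_cterm` set when the last domain lacks its zinc finger);
#' 2. a single complete domain with a C2HC finger -> group 3;
#' 3. a single complete domain with a C2H2 finger -> group 2, with the
#'    subgroup taken from `subgroup_hint` or from [assign_subgroup()] when
#'    references are supplied (plain `"group2"` otherwise);
#' 4. heptapeptide(s) but no complete domain (or no heptapeptide at all)
#'    -> unclassified.
#'
#' The m spacer plays no role in grouping: group 2 members carry both 4- and
#' 5-residue spacers.
#'
#' @param domains `data.frame` with one row per domain and columns
#'   `heptapeptide` (7-mer or NA), `zf_type` (`"C2H2"`, `"C2HC"` or NA) and
#'   `complete` (logical), e.g. a [scan_protein()] result.
#' @param subgroup_hint Optional subgroup label (`"group2a"`..`"group2e"`) used
#'   for rule 3.
#' @param refs Optional reference set for [assign_subgroup()]: a list with
#'   `seqs` (named character) and `labels`.
#' @param query_seq Query domain sequence, required when `refs` is given.
#' @return List: `group`, `incomplete_cterm`, `two_domain_c2hc_override`.
#' @export
assign_group <- function(domains, subgroup_hint = NULL, refs = NULL,
                         query_seq = NULL) {
  res <- list(group = "unclassified", incomplete_cterm = FALSE,
              two_domain_c2hc_override = FALSE)
  if (is.null(domains) || nrow(domains) == 0) return(res)
  has_hep <- !is.na(domains$heptapeptide) & domains$heptapeptide != "/"
  domains <- domains[has_hep | domains$complete, , drop = FALSE]
  n_hep <- sum(has_hep)
  complete <- domains$complete
  zf <- domains$zf_type
  if (n_hep >= 2 && any(complete)) {
    res$group <- "group1"
    res$two_domain_c2hc_override <- any(zf == "C2HC", na.rm = TRUE)
    res$incomplete_cterm <- !complete[nrow(domains)]
    return(res)
  }
  if (n_hep == 1 && sum(complete) == 1) {
    if (zf[complete] == "C2HC") { res$group <- "group3"; return(res) }
    if (zf[complete] == "C2H2") {
      sub2 <- c("group2a", "group2b", "group2c", "group2d", "group2e")
      if (!is.null(subgroup_hint) && subgroup_hint %in% sub2)
        res$group <- subgroup_hint
      else if (!is.null(refs) && !is.null(query_seq))
        res$group <- paste0("group", assign_subgroup(query_seq, refs$seqs,
                                                     refs$labels))
      else res$group <- "group2"
      return(res)
    }
  }
  res
}

#' Assign a group-2 subgroup by nearest labelled reference
#'
#' Scores the query against every reference by global alignment
#' ([align_global()]) and returns the best-scoring reference's label. Score
#' ties are broken by neighbour-joining placement: a joint NJ tree is built
#' over the query plus all references (distances 1 - fractional identity) and
#' the label of the reference leaf at the smallest patristic distance from the
#' query wins; remaining ties fall back to the lexicographically smallest
#' label.
#'
#' @param query Query domain sequence.
#' @param ref_seqs Named character vector of reference domain sequences.
#' @param ref_labels Subgroup label per reference (`"2a"`..`"2e"`).
#' @param ... Passed to [align_global()].
#' @return A subgroup label.
#' @export
assign_subgroup <- function(query, ref_seqs, ref_labels, ...) {
  if (!length(ref_seqs)) stopf("assign_subgroup: empty reference set")
  if (length(ref_labels) != length(ref_seqs))
    stopf("assign_subgroup: one label per reference required")
  scores <- vapply(ref_seqs, function(r)
    align_global(query, r, ...)$score, 0)
  best <- which(scores == max(scores))
  if (length(best) == 1L) return(ref_labels[best])
  # tie: NJ placement over query + all references
  seqs <- c(query = unname(query), ref_seqs)
  if (length(seqs) >= 3) {
    D <- distance_matrix(seqs, ...)
    tree <- nj_tree(D)
    pd <- ape::cophenetic.phylo(tree)["query", names(ref_seqs)[best]]
    best <- best[pd == min(pd)]
  }
  sort(ref_labels[best])[1]
}

#' Classify rows of the transcribed family table
#'
#' Two paths are provided because two printed rows conflict with the
#' zinc-finger rules. `"label"` takes the printed group label at face value;
#' `"rule"` rebuilds each row's domain descriptors (heptapeptide slots,
#' zinc-finger types, completeness) and runs [assign_group()], using the
#' printed subgroup as the rule-3 hint where available.
#'
#' @param tab A [read_family_table()] data.frame.
#' @param mode `"label"` or `"rule"`.
#' @return `data.frame`: `gene_id`, `group`, `incomplete_cterm`,
#'   `two_domain_c2hc_override`, `variant_domains`.
#' @export
classify_family_table <- function(tab, mode = c("label", "rule")) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    heps <- c(r$heptapeptide_1, r$heptapeptide_2)
    variant <- sum(heps != "/" & heps != WRKY_CANONICAL)
    if (mode == "label") {
      grp <- r$group_label
      inc <- r$incomplete_flag
      ovr <- grp == "group1" && "C2HC" %in% c(r$zf_type_1, r$zf_type_2)
    } else {
      slots <- data.frame(
        heptapeptide = ifelse(heps == "/", NA_character_, heps),
        zf_type = ifelse(c(r$zf_type_1, r$zf_type_2) == "/", NA_character_,
                         c(r$zf_type_1, r$zf_type_2)),
        stringsAsFactors = FALSE)
      slots$complete <- !is.na(slots$zf_type)
      slots <- slots[!is.na(slots$heptapeptide) | slots$complete, ,
                     drop = FALSE]
      hint <- if (grepl("^group2[a-e]$", r$group_label)) r$group_label
      a <- assign_group(slots, subgroup_hint = hint)
      grp <- a$group; inc <- a$incomplete_cterm
      ovr <- a$two_domain_c2hc_override
    }
    data.frame(gene_id = r$gene_id, group = grp, incomplete_cterm = inc,
               two_domain_c2hc_override = ovr, variant_domains = variant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify scanned proteins
#'
#' Runs [assign_group()] on each gene's [scan_proteins()] rows.
#'
#' @param scan A [scan_proteins()] data.frame.
#' @param gene_ids Optional ids to classify (defaults to those present;
#'   supply the full input set so genes without any hit appear as
#'   unclassified).
#' @param refs,seqs Optional subgroup references and the protein sequences,
#'   forwarded to [assign_group()].
#' @return Same shape as [classify_family_table()].
#' @export
classify_scan <- function(scan, gene_ids = NULL, refs = NULL, seqs = NULL) {
  if (is.null(gene_ids)) gene_ids <- unique(scan$gene_id)
  out <- lapply(gene_ids, function(id) {
    d <- scan[scan$gene_id == id, , drop = FALSE]
    qseq <- if (!is.null(seqs) && !is.null(seqs[[id]]) && any(d$complete))
      extract_domain(seqs[[id]], d[which(d$complete)[1], ])
    a <- assign_group(d, refs = refs, query_seq = qseq)
    data.frame(gene_id = id, group = a$group,
               incomplete_cterm = a$incomplete_cterm,
               two_domain_c2hc_override = a$two_domain_c2hc_override,
               variant_domains = sum(d$heptapeptide != WRKY_CANONICAL),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tally a set of family assignments
#'
#' @param assignments Output of [classify_family_table()] / [classify_scan()].
#' @return List: `counts` (named integer over group labels present),
#'   `variant_domains`, `incomplete_group1`, `total`.
#' @export
summarize_family <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0)
    stopf("summarize_family: no assignments")
  dup <- unique(assignments$gene_id[duplicated(assignments$gene_id)])
  if (length(dup))
    stopf("summarize_family: duplicate gene id(s): %s",
          paste(dup, collapse = ", "))
  lev <- c(WRKY_GROUPS, setdiff(unique(assignments$group), WRKY_GROUPS))
  counts <- table(factor(assignments$group, levels = lev))
  counts <- counts[counts > 0 | names(counts) %in% WRKY_GROUPS]
  list(counts = setNames(as.integer(counts), names(counts)),
       variant_domains = sum(assignments$variant_domains),
       incomplete_group1 = sum(assignments$incomplete_cterm &
                                 assignments$group == "group1"),
       total = nrow(assignments))
}
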