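# residue sampler that avoids accidental WRKY signals: no 7-mer within
# Hamming 2 of WRKYGQK anywhere; optionally C/H excluded (spacers/linkers)
rand_residues <- function(n, exclude = character(0)) {
  if (n <= 0) return("")
  pool <- setdiff(AA20, exclude)
  repeat {
    s <- paste(sample(pool, n, replace = TRUE), collapse = "")
    if (n < 7 || nrow(find_heptapeptides(s, 2)) == 0) return(s)
  }
}

plant_zf <- function(zf_type, m, n) {
  paste0("C", rand_residues(m, exclude = c("C", "H")),
         "C", rand_residues(n, exclude = c("C", "H")),
         "H", rand_residues(1, exclude = c("C", "H")),
         if (zf_type == "C2H2") "H" else "C")
}

pick_hepta <- function(variant_rate) {
  if (runif(1) < variant_rate) sample(WRKY_VARIANTS, 1) else WRKY_CANONICAL
}

# one planted domain: heptapeptide + C-free linker (+ optional subgroup tag)
# + zinc finger
plant_domain <- function(hepta, zf_type, m, n, tag = "") {
  linker <- rand_residues(sample(8:15, 1), exclude = "C")
  list(seq = paste0(hepta, tag, linker, plant_zf(zf_type, m, n)),
       hepta = hepta, zf_type = zf_type, m = m, n = n)
}

#' Synthetic group-2 subgroup signature tags
#'
#' Fixed C-free 7-mers inserted after the heptapeptide of generated group-2
#' domains, one per subgroup. They stand in for the subgroup-specific
#' conserved motifs real subgroups carry, giving reference-based subgroup
#' assignment a learnable signal; they are a generator artifact, not
#' biological motifs.
#' @export
WRKY2_SUBGROUP_TAGS <- c(group2a = "DEDNSLA", group2b = "QQTLESV",
                         group2c = "GGRPKIF", group2d = "MMYWTAV",
                         group2e = "PPLDKGT")

#' Generate a synthetic WRKY-like protein family
#'
#' Each gene receives random flanking sequence (rejection-sampled so no 7-mer
#' comes within Hamming distance 2 of WRKYGQK outside the planted sites) plus
#' planted domain(s) by group: two C2H2 domains for group 1 (a configurable
#' fraction instead carries a C-terminal heptapeptide with no zinc finger —
#' the "incomplete" architecture), one C2H2 domain for the group-2 subgroups,
#' one C2HC domain for group 3, and a bare heptapeptide for unclassified.
#' Spacer lengths follow the family table (group 2: m 4-5, n 23; group 3:
#' m 6-7, n 23-24; group 1: m 4, n 22-23). Heptapeptides mutate to a tabulated
#' variant with probability `variant_rate`. The CDS is a uniform random
#' back-translation of each protein. Everything is a pure function of
#' (parameters, seed).
#'
#' @param n_genes Number of genes.
#' @param group_mix Named nonnegative proportions over
#'   `WRKY_GROUPS` (need not name all); must sum to 1. Default: the family
#'   table proportions (20/121 group 1, 5/11/28/7/12 across 2a-2e, 27 group 3,
#'   11 unclassified).
#' @param variant_rate Per-heptapeptide probability of a variant (default 0.1,
#'   the order of the observed 15 variant domains among ~150).
#' @param incomplete_rate Fraction of group-1 genes with an incomplete
#'   C-terminal domain (default 0.25 = 5/20 as tabulated).
#' @param seed RNG seed.
#' @return List: `proteins`, `cds` (named character vectors) and `truth`
#'   (`data.frame` of planted group, heptapeptides, zinc-finger types, m, n,
#'   incomplete flag).
#' @export
make_family <- function(n_genes,
                        group_mix = c(group1 = 20, group2a = 5, group2b = 11,
                                      group2c = 28, group2d = 7,
                                      group2e = 12, group3 = 27,
                                      unclassified = 11) / 121,
                        variant_rate = 0.1, incomplete_rate = 0.25,
                        seed = 1) {
  if (any(group_mix < 0)) stopf("make_family: negative group proportion")
  if (abs(sum(group_mix) - 1) > 1e-8)
    stopf("make_family: group_mix must sum to 1")
  if (!all(names(group_mix) %in% WRKY_GROUPS))
    stopf("make_family: unknown group in group_mix")
  with_seed(seed, {
    groups <- sample(names(group_mix), n_genes, replace = TRUE,
                     prob = group_mix)
    res <- lapply(seq_len(n_genes), function(i) {
      g <- groups[i]
      id <- sprintf("synWRKY%03d", i)
      pre <- rand_residues(sample(15:40, 1))
      post <- rand_residues(sample(15:40, 1))
      t <- list(gene_id = id, group = g,
                hepta_1 = NA, hepta_2 = NA, zf_1 = NA, zf_2 = NA,
                m_1 = NA, m_2 = NA, n_1 = NA, n_2 = NA, incomplete = FALSE)
      if (g == "group1") {
        d1 <- plant_domain(pick_hepta(variant_rate), "C2H2", 4,
                           sample(22:23, 1))
        t$hepta_1 <- d1$hepta; t$zf_1 <- d1$zf_type
        t$m_1 <- d1$m; t$n_1 <- d1$n
        mid <- rand_residues(sample(20:40, 1))
        if (runif(1) < incomplete_rate) {
          h2 <- pick_hepta(variant_rate)
          t$hepta_2 <- h2; t$incomplete <- TRUE
          seq <- paste0(pre, d1$seq, mid, h2,
                        rand_residues(sample(5:10, 1), exclude = "C"))
        } else {
          d2 <- plant_domain(pick_hepta(variant_rate), "C2H2", 4, 23)
          t$hepta_2 <- d2$hepta; t$zf_2 <- d2$zf_type
          t$m_2 <- d2$m; t$n_2 <- d2$n
          seq <- paste0(pre, d1$seq, mid, d2$seq, post)
        }
      } else if (g == "group3") {
        d <- plant_domain(pick_hepta(variant_rate), "C2HC",
                          sample(6:7, 1), sample(23:24, 1))
        t$hepta_1 <- d$hepta; t$zf_1 <- d$zf_type
        t$m_1 <- d$m; t$n_1 <- d$n
        seq <- paste0(pre, d$seq, post)
      } else if (g == "unclassified") {
        h <- pick_hepta(variant_rate)
        t$hepta_1 <- h
        seq <- paste0(pre, h, rand_residues(sample(5:10, 1), exclude = "C"))
      } else {  # group2 subgroups: single C2H2; 2c uses m=4, others m=5
        m <- if (g == "group2c") 4 else 5
        d <- plant_domain(pick_hepta(variant_rate), "C2H2", m, 23,
                          tag = WRKY2_SUBGROUP_TAGS[[g]])
        t$hepta_1 <- d$hepta; t$zf_1 <- d$zf_type
        t$m_1 <- d$m; t$n_1 <- d$n
        seq <- paste0(pre, d$seq, post)
      }
      list(seq = seq, truth = as.data.frame(t, stringsAsFactors = FALSE))
    })
    proteins <- setNames(vapply(res, `[[`, "", "seq"),
                         vapply(res, function(x) x$truth$gene_id, ""))
    cds <- vapply(proteins, back_translate, "")
    truth <- do.call(rbind, lapply(res, `[[`, "truth"))
    list(proteins = proteins, cds = cds, truth = truth)
  })
}

#' Build synthetic group-2 subgroup reference exemplars
#'
#' Generates `n_per` clean (variant-free) exemplar domains per subgroup with
#' the generator's subgroup signature tags, in the form [assign_group()] and
#' [classify_scan()] expect for reference-based subgroup assignment.
#'
#' @param n_per Exemplars per subgroup.
#' @param seed RNG seed.
#' @return List with `seqs` (named domain strings) and `labels`
#'   (`"2a"`..`"2e"`).
#' @export
make_subgroup_refs <- function(n_per = 3, seed = 1) {
  subs <- paste0("group2", letters[1:5])
  seqs <- character(0); labels <- character(0)
  k <- 0
  for (g in subs) for (r in seq_len(n_per)) {
    k <- k + 1
    fam <- make_family(1, group_mix = setNames(1, g), variant_rate = 0,
                       seed = seed * 1000L + k)
    sc <- scan_proteins(fam$proteins)
    seqs[paste0("ref_", g, "_", r)] <- extract_domain(fam$proteins[[1]],
                                                      sc[1, ])
    labels[k] <- sub("group", "", g)
  }
  list(seqs = seqs, labels = labels)
}

#' Uniform random back-translation of a protein
#'
#' Each residue is encoded by a codon drawn uniformly from its synonymous
#' codons (standard code, no stop appended).
#'
#' @param protein Protein string.
#' @return CDS string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein) {
  gc <- codon_table()
  by_aa <- split(names(gc), gc)
  chars <- strsplit(unname(protein[[1]]), "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- by_aa[[a]]
    if (is.null(cods)) stopf("back_translate: no codon for residue '%s'", a)
    if (length(cods) == 1) cods else sample(cods, 1)
  }, ""), collapse = "")
}

#' Evolve a synonymously diverged CDS pair to a target Ks
#'
#' Starting from one CDS, synonymous substitutions are planted by rejection
#' sampling: a random (codon, position, alternative nucleotide) proposal is
#' accepted only if it leaves the protein unchanged and the codon is still
#' untouched (at most one change per codon, so observed synonymous
#' differences equal the number of changes). The number of changes is
#' `round(pS* x S)` where `S` is the Nei-Gojobori synonymous site count of
#' the input and `pS* = (3/4)(1 - exp(-4 Ks*/3))` inverts the Jukes-Cantor
#' correction, so the estimator recovers `target_Ks` in expectation.
#'
#' @param cds Input CDS (no in-frame stops).
#' @param target_Ks Target synonymous divergence (>= 0).
#' @param seed RNG seed.
#' @return List: `cds_a` (the input), `cds_b` (diverged copy), `log`
#'   (`data.frame` of codon index, position, from, to), `n_sub`.
#' @export
evolve_pair <- function(cds, target_Ks, seed = 1) {
  if (target_Ks < 0) stopf("evolve_pair: negative target_Ks")
  cds <- toupper(unname(cds[[1]]))
  translate_cds(cds)  # validates frame and stops
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- codon_table()
  S <- sum(vapply(codons, syn_fraction, 0, gc = gc))
  pS <- 0.75 * (1 - exp(-4 * target_Ks / 3))
  if (target_Ks > 0 && round(pS * S) == 0)
    stopf("evolve_pair: target Ks %.3g unreachable for a CDS with %.3g synonymous sites",
          target_Ks, S)
  mutable <- sum(vapply(codons, syn_fraction, 0, gc = gc) > 0)
  with_seed(seed, {
    # Poisson number of substitution events with mean pS* x S (the expected
    # synonymous divergence), capped by the one-change-per-codon design
    n_sub <- if (target_Ks == 0) 0L
             else as.integer(min(stats::rpois(1, pS * S), mutable))
    out <- codons
    touched <- logical(length(codons))
    logs <- list()
    nts <- c("A", "C", "G", "T")
    attempts <- 0L
    while (n_sub > 0 && length(logs) < n_sub) {
      attempts <- attempts + 1L
      if (attempts > 10000L * n_sub)
        stopf("evolve_pair: target Ks %.3g unreachable", target_Ks)
      ci <- sample(length(codons), 1)
      if (touched[ci]) next
      p <- sample(3L, 1)
      from <- substr(out[ci], p, p)
      to <- sample(setdiff(nts, from), 1)
      alt <- out[ci]
      substr(alt, p, p) <- to
      if (gc[[alt]] != gc[[out[ci]]] || gc[[alt]] == "*") next
      out[ci] <- alt
      touched[ci] <- TRUE
      logs[[length(logs) + 1L]] <- data.frame(codon = ci, pos = p,
                                              from = from, to = to,
                                              stringsAsFactors = FALSE)
    }
    empty <- data.frame(codon = integer(0), pos = integer(0),
                        from = character(0), to = character(0))
    list(cds_a = cds, cds_b = paste(out, collapse = ""),
         log = if (length(logs)) do.call(rbind, logs) else empty,
         n_sub = n_sub)
  })
}

#' Generate a synthetic expression matrix with planted structure
#'
#' Two sample groups (`treated_*`, `control_*`) of `n_samples` each.
#' Background genes are negative-binomial counts around log-normal baseline
#' means (dispersion `dispersion`); the first `n_de` background genes have
#' their treated-group mean multiplied by `fc` (no DE is planted when
#' `fc = 1`). The last `n_modules * module_size` genes form co-expression
#' modules: on the log2 scale each module shares a per-sample latent factor
#' with loading chosen so the pairwise within-module correlation equals
#' `module_r` exactly (`module_r = 1` drops the idiosyncratic noise, making
#' profiles identical up to scaling).
#'
#' @param n_genes Total genes.
#' @param n_samples Samples per group.
#' @param n_de Planted differentially expressed genes.
#' @param fc Planted fold change for DE genes.
#' @param n_modules,module_size Planted co-expression modules.
#' @param module_r Target within-module pairwise correlation in \[0, 1\].
#' @param base_mean Median baseline expression.
#' @param dispersion NB dispersion (default 0.1).
#' @param seed RNG seed.
#' @return List: `mat` (genes x samples), `meta` (`sample`, `condition`),
#'   `truth` (`gene`, `de`, `fc`, `module`).
#' @export
make_expression <- function(n_genes, n_samples, n_de = 0, fc = 1,
                            n_modules = 0, module_size = 10, module_r = 0.95,
                            base_mean = 100, dispersion = 0.1, seed = 1) {
  n_mod_genes <- n_modules * module_size
  if (n_de + n_mod_genes > n_genes)
    stopf("make_expression: n_de + module genes exceed n_genes")
  if (module_r < 0 || module_r > 1)
    stopf("make_expression: module_r must be in [0, 1]")
  if (n_genes < 1 || n_samples < 1)
    stopf("make_expression: invalid sizes")
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    samples <- c(paste0("treated_", seq_len(n_samples)),
                 paste0("control_", seq_len(n_samples)))
    cond <- rep(c("treated", "control"), each = n_samples)
    mu <- stats::rlnorm(n_genes, log(base_mean), 0.5)
    mat <- matrix(0, n_genes, 2 * n_samples,
                  dimnames = list(genes, samples))
    de <- rep(FALSE, n_genes)
    module <- rep(NA_integer_, n_genes)
    bg <- seq_len(n_genes - n_mod_genes)
    for (i in bg) {
      m_tr <- if (i <= n_de && fc != 1) mu[i] * fc else mu[i]
      mat[i, ] <- rnbinom(2 * n_samples,
                          mu = rep(c(m_tr, mu[i]), each = n_samples),
                          size = 1 / dispersion)
      de[i] <- i <= n_de && fc != 1
    }
    if (n_mod_genes > 0) {
      sig_e <- if (module_r == 1) 0 else 0.5
      b <- if (module_r == 1) 1 else sig_e * sqrt(module_r / (1 - module_r))
      idx <- n_genes - n_mod_genes + seq_len(n_mod_genes)
      for (k in seq_len(n_modules)) {
        z <- rnorm(2 * n_samples)
        rows <- idx[(k - 1) * module_size + seq_len(module_size)]
        for (i in rows) {
          e <- if (sig_e > 0) rnorm(2 * n_samples, 0, sig_e) else 0
          mat[i, ] <- 2^(log2(mu[i]) + b * z + e)
          module[i] <- k
        }
      }
    }
    list(mat = mat,
         meta = data.frame(sample = samples, condition = cond,
                           stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, de = de,
                            fc = ifelse(de, fc, 1), module = module,
                            stringsAsFactors = FALSE))
  })
}
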