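#' Build a run configuration
#'
#' Collects the inputs and thresholds of a [characterize()] run. Configs
#' round-trip through JSON ([read_run_config()] / [write_run_config()]).
#'
#' @param proteins,cds,family_table,expression,expression_groups Input paths
#'   (any may be `NULL`; stages without inputs are skipped). `expression`
#'   is a TSV of genes x samples; `expression_groups` a two-value vector or
#'   comma-separated string over its columns.
#' @param mode Classification mode: `"label"` or `"rule"` for the family
#'   table, `"scan"` to classify scanned proteins.
#' @param scanner A [scan_config()] list.
#' @param lambda Synonymous clock rate for duplication dating.
#' @param fdr_max,lfc_min,r2_min,hub_min Expression thresholds.
#' @param seed RNG seed echoed into the report.
#' @param out_dir Output directory.
#' @return A `wrky_run_config` list.
#' @export
run_config <- function(proteins = NULL, cds = NULL, family_table = NULL,
                       expression = NULL, expression_groups = NULL,
                       mode = c("label", "rule", "scan"),
                       scanner = scan_config(), lambda = 6.5e-9,
                       fdr_max = 0.05, lfc_min = 2, r2_min = 0.95,
                       hub_min = 9, seed = 1, out_dir = ".") {
  mode <- match.arg(mode)
  stopifnot(fdr_max > 0, fdr_max <= 1, lfc_min >= 0,
            r2_min >= 0, r2_min <= 1, hub_min >= 0, lambda > 0)
  structure(list(proteins = proteins, cds = cds, family_table = family_table,
                 expression = expression,
                 expression_groups = expression_groups, mode = mode,
                 scanner = scanner, lambda = as.numeric(lambda),
                 fdr_max = as.numeric(fdr_max), lfc_min = as.numeric(lfc_min),
                 r2_min = as.numeric(r2_min), hub_min = as.integer(hub_min),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "wrky_run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @param config A `wrky_run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$scanner <- do.call(scan_config,
                       x$scanner[setdiff(names(x$scanner), "extended")])
  do.call(run_config, x[setdiff(names(x), "scanner")]) |>
    (\(cfg) { cfg$scanner <- x$scanner; cfg })()
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s failed: %s", name, conditionMessage(e)))
}

#' Run the full characterization pipeline
#'
#' Executes every stage for which the config provides inputs — family
#' classification (table or scan), NJ phylogeny over protein distances,
#' within-set BBH paralogue detection, Ka/Ks + duplication dating of the
#' paralogous pairs, and the expression analyses (DE calls, clustering,
#' co-expression network) — and writes each stage's outputs as TSV/Newick
#' plus a JSON summary of the family tallies and thresholds. Deterministic
#' given config + seed; any stage error aborts with the stage name.
#'
#' @param config A [run_config()] (or path to its JSON).
#' @return Invisibly, a list with the in-memory results (`assignments`,
#'   `summary`, `tree`, `pairs`, `kaks`, `de`, `network`, `cluster`).
#' @export
characterize <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "wrky_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list()

  proteins <- if (!is.null(config$proteins))
    stage("read_proteins", read_fasta(config$proteins, "protein"))

  res$assignments <- if (config$mode %in% c("label", "rule")) {
    if (is.null(config$family_table))
      stopf("stage classify failed: mode '%s' needs a family table",
            config$mode)
    stage("classify",
          classify_family_table(read_family_table(config$family_table),
                                mode = config$mode))
  } else {
    if (is.null(proteins))
      stopf("stage classify failed: mode 'scan' needs proteins")
    stage("classify",
          classify_scan(scan_proteins(proteins, config$scanner),
                        gene_ids = names(proteins)))
  }
  write.table(res$assignments, out("assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res$summary <- stage("summarize", summarize_family(res$assignments))

  if (!is.null(proteins) && length(proteins) >= 3) {
    res$tree <- stage("phylogeny",
                      nj_tree(distance_matrix(proteins)))
    write_newick(res$tree, out("tree.nwk"))
  }
  if (!is.null(proteins) && length(proteins) >= 2) {
    res$pairs <- stage("bbh", bbh(proteins, species_a = "query"))
    write.table(res$pairs, out("pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(config$cds) && nrow(res$pairs)) {
      cds <- stage("read_cds", read_fasta(config$cds, "dna"))
      res$kaks <- stage("kaks",
                        kaks_pairs(res$pairs, cds, proteins = proteins,
                                   lambda = config$lambda))
      write.table(res$kaks, out("kaks.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  if (!is.null(config$expression)) {
    mat <- stage("read_expression", {
      m <- as.matrix(read.delim(config$expression, row.names = 1,
                                check.names = FALSE))
      storage.mode(m) <- "double"
      m
    })
    groups <- config$expression_groups
    if (is.character(groups) && length(groups) == 1)
      groups <- strsplit(groups, ",")[[1]]
    if (!is.null(groups)) {
      res$de <- stage("de_calls",
                      call_upregulated(mat, groups, fdr_max = config$fdr_max,
                                       lfc_min = config$lfc_min))
      write.table(res$de, out("de_calls.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    if (nrow(mat) >= 2) {
      res$cluster <- stage("cluster", hier_cluster(mat))
      writeLines(res$cluster$order, out("cluster_order.txt"))
    }
    res$network <- stage("network",
                         coexpression_network(mat, r2_min = config$r2_min,
                                              hub_min = config$hub_min))
    write.table(res$network$edges, out("network_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = names(res$network$degree),
                           degree = unname(res$network$degree),
                           hub = names(res$network$degree) %in%
                             res$network$hubs),
                out("network_degree.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  summary_json <- list(
    total = res$summary$total,
    counts = as.list(res$summary$counts),
    variant_domains = res$summary$variant_domains,
    incomplete_group1 = res$summary$incomplete_group1,
    thresholds = list(fdr_max = config$fdr_max, lfc_min = config$lfc_min,
                      r2_min = config$r2_min, hub_min = config$hub_min,
                      lambda = config$lambda, mode = config$mode),
    seed = config$seed)
  jsonlite::write_json(summary_json, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(res)
}
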