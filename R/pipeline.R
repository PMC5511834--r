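#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis — simulation parameters,
#' threshold cascade, TOPSIS weights/orientations and the output directory —
#' into one validated object. A YAML file with the same field names can be
#' loaded with [read_pipeline_config()].
#'
#' @param out_dir directory for all stage outputs (created if absent).
#' @param seed global seed; each generator derives its own substream from it.
#' @param n_genes,prop_de,lfc,up_fraction,dispersion,lib_size simulation
#'   parameters forwarded to [de_truth()] (`lib_size` is per sample, 3 + 3
#'   design).
#' @param p,fdr,lfc_cut,fpkm_floor,alpha threshold block: raw p cut, BH q
#'   cut, |log2FC| cut, key-gene FPKM floor, enrichment significance level.
#' @param weights TOPSIS criterion weights (`NULL` = equal).
#' @param orientations TOPSIS orientations (`"auto"` or per-criterion
#'   vector).
#' @param noise_sd indicator-panel noise scale (step units).
#' @param ct_noise_sd qPCR Ct noise (cycles).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "saltstress_out", seed = 1L,
                            n_genes = 2000, prop_de = 0.1, lfc = 3,
                            up_fraction = 0.395, dispersion = 0.01,
                            lib_size = 2e7,
                            p = 0.05, fdr = 0.001, lfc_cut = 1,
                            fpkm_floor = 0.05, alpha = 0.05,
                            weights = NULL, orientations = "auto",
                            noise_sd = 0.3, ct_noise_sd = 0.2) {
  for (nm in c("p", "fdr", "lfc_cut", "fpkm_floor", "alpha"))
    if (get(nm) <= 0) stop("threshold '", nm, "' must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full salt-stress analysis pipeline
#'
#' Chains every stage on synthetic inputs with planted ground truth:
#' simulate (indicator panel, counts, pathways, Ct table — all written to
#' disk), evaluate conditions (indicator screen + TOPSIS), differential
#' expression, pathway enrichment, expression profiles, and qPCR
#' concordance. Each stage reads its inputs from the files the previous
#' stage wrote, so the on-disk formats are exercised end to end; a stage
#' failure aborts the downstream stages with a clear message. All outputs
#' are headered TSV/CSV/GMT.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return invisibly, a manifest data frame (`file`, `stage`, `md5`) also
#'   written to `manifest.tsv`; the fitted stage objects are attached as
#'   attribute `results`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(out_dir = tempfile(), n_genes = 300,
#'                        lib_size = 1e6)
#' manifest <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- data.frame(file = character(0), stage = character(0),
                         md5 = character(0))
  note <- function(stage, files) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(files), stage = stage,
      md5 = unname(tools::md5sum(files))))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           "; downstream stages aborted", call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------
  res <- list()
  run_stage("simulate", {
    ind <- indicator_truth(noise_sd = config$noise_sd, seed = config$seed)
    panel <- gen_indicator_panel(ind)
    write_panel(panel, out("indicator_panel.csv"))

    det <- de_truth(n_genes = config$n_genes, prop_de = config$prop_de,
                    lfc_magnitude = config$lfc,
                    up_fraction = config$up_fraction,
                    dispersion = config$dispersion,
                    lib_sizes = rep(config$lib_size, 6), seed = config$seed)
    sim <- gen_count_matrix(det)
    write_counts(sim$counts, out("counts.tsv"))
    write_lengths(sim$lengths, out("lengths.tsv"))
    write_samples(sim$samples, out("samples.tsv"))
    write_tsv(data.frame(gene = names(sim$labels), label = sim$labels),
              out("labels.tsv"))

    pwt <- pathway_truth(seed = config$seed)
    sets <- gen_pathways(pwt, sim$labels)
    write_gmt(sets, out("pathways.gmt"))

    key <- names(sim$labels)[sim$labels != "null"]
    key <- utils::head(key, 17)       # desk-scale qPCR panel
    ct <- gen_ct_table(sim$labels, lfc_magnitude = config$lfc,
                       noise_sd = config$ct_noise_sd, seed = config$seed,
                       genes = key)
    write_ct_table(ct, out("ct.tsv"))
    res$truth <- list(indicator = ind, de = det, pathways = pwt)
    res$levels <- ind$levels
    res$enriched <- attr(sets, "enriched")
    note("simulate", out(c("indicator_panel.csv", "counts.tsv", "lengths.tsv",
                           "samples.tsv", "labels.tsv", "pathways.gmt",
                           "ct.tsv")))
  })

  # -- evaluate conditions ----------------------------------------------
  run_stage("evaluate-conditions", {
    panel <- read_panel(out("indicator_panel.csv"))
    ev <- evaluate_conditions(panel, levels = res$levels,
                              weights = config$weights,
                              orientations = config$orientations)
    write_tsv(ev$table, out("topsis.tsv"))
    scr <- ev$screen
    scr$r <- round_half_up(scr$r, 3)
    write_tsv(as.data.frame(scr), out("correlation.tsv"))
    res$condition_eval <- ev
    note("evaluate-conditions", out(c("topsis.tsv", "correlation.tsv")))
  })

  # -- differential expression ------------------------------------------
  run_stage("de", {
    counts <- read_counts(out("counts.tsv"))
    lengths <- read_lengths(out("lengths.tsv"))
    samples <- read_samples(out("samples.tsv"))
    de <- de_analysis(counts, lengths, samples$condition,
                      p = config$p, fdr = config$fdr, lfc = config$lfc_cut,
                      fpkm_floor = config$fpkm_floor)
    write_tsv(as.data.frame(de), out("de.tsv"))
    write_tsv(volcano_data(de), out("volcano.tsv"))
    res$de <- de
    note("de", out(c("de.tsv", "volcano.tsv")))
  })

  # -- enrichment --------------------------------------------------------
  run_stage("enrich", {
    de <- res$de
    sets <- read_gmt(out("pathways.gmt"))
    er <- enrich(de$gene[de$status != "not_significant"], de$gene, sets,
                 alpha = config$alpha)
    write_tsv(as.data.frame(er), out("enrichment.tsv"))
    res$enrichment <- er
    note("enrich", out("enrichment.tsv"))
  })

  # -- profiles ----------------------------------------------------------
  run_stage("profile", {
    de <- res$de
    key <- de$gene[de$key_gene]
    pr <- expression_profiles(de, genes = utils::head(key, 50))
    mat <- data.frame(gene = rownames(pr$matrix), pr$matrix,
                      check.names = FALSE)
    write_tsv(mat, out("profiles.tsv"))
    write_newick(pr, out("profiles.nwk"))
    res$profiles <- pr
    note("profile", out(c("profiles.tsv", "profiles.nwk")))
  })

  # -- qPCR --------------------------------------------------------------
  run_stage("qpcr", {
    ct <- read_ct_table(out("ct.tsv"), reference_gene = "ACTIN")
    rq <- ddct(ct)
    conc <- concordance(rq, res$de)
    qout <- merge(as.data.frame(rq),
                  as.data.frame(conc)[, c("gene", "concordant")],
                  by = "gene", sort = FALSE)
    write_tsv(qout, out("qpcr.tsv"))
    res$qpcr <- rq
    res$concordance <- conc
    note("qpcr", out("qpcr.tsv"))
  })

  manifest <- rbind(manifest, data.frame(
    file = "config", stage = "provenance",
    md5 = sprintf("seed=%d", config$seed)))
  write_tsv(manifest, out("manifest.tsv"))
  attr(manifest, "results") <- res
  invisible(manifest)
}
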