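#' Ground truth for a synthetic physiological indicator panel
#'
#' Describes the planted behaviour of a salt-stress indicator panel: ordered
#' treatment levels and, per indicator, a monotone trend (growth traits fall
#' with stress, antioxidant enzyme activities rise) plus Gaussian measurement
#' noise. The defaults emulate a tomato seedling NaCl dose series with
#' plant height and leaf number decreasing and POD/SOD/CAT activities
#' increasing across 0-250 mM.
#'
#' @param levels ordered numeric treatment levels (default `c(0, 50, 100,
#'   150, 200, 250)` mM NaCl).
#' @param criteria data frame with columns `name`, `direction`
#'   (`"increasing"`/`"decreasing"` with stress), `baseline` (value at the
#'   first level, criterion-native units) and `step` (positive effect size
#'   per level step).
#' @param noise_sd Gaussian noise scale, expressed in units of each
#'   criterion's per-step effect size (so one value is meaningful across
#'   criteria measured in different units); must be >= 0.
#' @param seed integer seed.
#' @return list of class `"indicator_truth"`.
#' @export
indicator_truth <- function(levels = c(0, 50, 100, 150, 200, 250),
                            criteria = NULL,
                            noise_sd = 0.3, seed = 1L) {
  if (is.null(criteria)) {
    criteria <- data.frame(
      name = c("plant_height", "leaf_blade_number", "POD_activity",
               "SOD_activity", "CAT_activity"),
      direction = c("decreasing", "decreasing", "increasing", "increasing",
                    "increasing"),
      baseline = c(12, 8, 45, 80, 30),
      step = c(1.6, 0.9, 16, 24, 12),
      stringsAsFactors = FALSE
    )
  }
  if (length(levels) < 2L) stop("need at least 2 treatment levels")
  if (is.unsorted(levels, strictly = TRUE))
    stop("treatment levels must be strictly increasing")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  req <- c("name", "direction", "baseline", "step")
  if (!all(req %in% names(criteria)))
    stop("criteria needs columns: ", paste(req, collapse = ", "))
  if (!all(criteria$direction %in% c("increasing", "decreasing")))
    stop("every criterion must declare direction 'increasing' or 'decreasing'")
  if (any(criteria$step <= 0)) stop("per-step effect sizes must be positive")
  if (any(criteria$baseline <= 0)) stop("baselines must be positive")
  span <- (length(levels) - 1L) * criteria$step
  bad <- criteria$direction == "decreasing" & criteria$baseline - span <= 0
  if (any(bad))
    stop("decreasing criterion would reach a non-positive rating: ",
         paste(criteria$name[bad], collapse = ", "))
  structure(list(levels = levels, criteria = criteria, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "indicator_truth")
}

#' Generate a synthetic indicator panel
#'
#' Draws an alternatives-by-criteria decision matrix from an
#' [indicator_truth()] description: each criterion moves linearly in its
#' declared direction across the treatment levels, with additive Gaussian
#' noise truncated just above zero (heights and enzyme activities cannot be
#' negative). With `noise_sd = 0` every criterion is strictly monotone and
#' perfectly linear in the level index, so its Pearson correlation with the
#' levels is exactly +1 or -1. Reproducible for a fixed seed.
#'
#' @param truth an [indicator_truth()] object.
#' @return a [decision_matrix()] with treatment levels as row labels.
#' @export
gen_indicator_panel <- function(truth) {
  stopifnot(inherits(truth, "indicator_truth"))
  m <- length(truth$levels)
  crit <- truth$criteria
  with_rng(substream_seed(truth$seed, "indicator_panel"), {
    mat <- vapply(seq_len(nrow(crit)), function(j) {
      sgn <- if (crit$direction[j] == "increasing") 1 else -1
      mu <- crit$baseline[j] + sgn * crit$step[j] * (seq_len(m) - 1L)
      x <- mu + stats::rnorm(m, sd = truth$noise_sd * crit$step[j])
      pmax(x, 1e-6)
    }, numeric(m))
    colnames(mat) <- crit$name
    decision_matrix(mat, alternatives = as.character(truth$levels))
  })
}

#' Ground truth for a synthetic two-condition RNA-seq count matrix
#'
#' Describes a planted differential-expression structure: a fixed fraction of
#' genes is differentially expressed between control and salt-treated
#' samples at a planted log2 fold-change magnitude, split into up- and
#' down-regulated sets. The default up fraction (0.395) mirrors the typical
#' predominance of down-regulation under salt stress.
#'
#' @param n_genes number of genes.
#' @param prop_de fraction of genes differentially expressed, in \[0, 1\].
#' @param lfc_magnitude planted |log2 fold change| (>= 0).
#' @param up_fraction fraction of DE genes that are up-regulated.
#' @param dispersion negative-binomial overdispersion (>= 0); 0 gives pure
#'   Poisson counts.
#' @param lib_sizes expected per-sample library sizes; default six samples
#'   (3 control + 3 salt) of 2e7 fragments.
#' @param seed integer seed.
#' @return list of class `"de_truth"`.
#' @export
de_truth <- function(n_genes = 2000, prop_de = 0.1, lfc_magnitude = 3,
                     up_fraction = 0.395, dispersion = 0.01,
                     lib_sizes = rep(2e7, 6), seed = 1L) {
  stop_if_not_scalar_prob(prop_de, "prop_de")
  stop_if_not_scalar_prob(up_fraction, "up_fraction")
  if (lfc_magnitude < 0) stop("lfc_magnitude must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(lib_sizes) %% 2L != 0L || length(lib_sizes) < 4L)
    stop("lib_sizes must cover two conditions with >= 2 replicates each")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  structure(list(n_genes = as.integer(n_genes), prop_de = prop_de,
                 lfc_magnitude = lfc_magnitude, up_fraction = up_fraction,
                 dispersion = dispersion, lib_sizes = lib_sizes,
                 seed = as.integer(seed)),
            class = "de_truth")
}

#' Generate a synthetic count matrix with planted differential expression
#'
#' Draws gene-level counts for a two-condition, replicated design from a
#' [de_truth()] description. Baseline relative abundances are log-normal;
#' counts are negative-binomial around `lib_size * abundance` (Poisson when
#' `dispersion = 0`). Planted DE genes have expected treated/control FPKM
#' ratio exactly `2^(+/- lfc_magnitude)`. When both up- and down-regulated
#' genes are planted, the baseline abundances of the down set are rescaled so
#' the expected total fragment flow is identical in the two conditions —
#' expected column sums then equal `lib_sizes` in both conditions and the
#' planted FPKM ratios are exact under column-sum library normalization.
#' (With a single DE direction no such balance exists; ratios stay exact and
#' treated totals drift by the planted signal.)
#'
#' Gene labels (`up` / `down` / `null`) partition the genes and are returned
#' alongside the counts, so downstream calls can be scored against the truth.
#'
#' @param truth a [de_truth()] object.
#' @return list of class `"sim_counts"`: integer `counts` matrix
#'   (genes x samples), `lengths` (bp, named), `samples` data frame
#'   (`sample`, `condition`, `replicate`), `labels` (named character:
#'   up/down/null), and `truth`.
#' @export
gen_count_matrix <- function(truth) {
  stopifnot(inherits(truth, "de_truth"))
  G <- truth$n_genes
  n_samp <- length(truth$lib_sizes)
  n_per <- n_samp %/% 2L
  n_de <- round(truth$prop_de * G)
  n_up <- round(truth$up_fraction * n_de)
  n_dn <- n_de - n_up

  genes <- sprintf("gene%05d", seq_len(G))
  labels <- rep("null", G)
  if (n_de > 0) labels[seq_len(n_de)] <- c(rep("up", n_up), rep("down", n_dn))
  names(labels) <- genes

  with_rng(substream_seed(truth$seed, "count_matrix"), {
    lengths <- as.integer(pmax(
      round(stats::rlnorm(G, meanlog = log(1500), sdlog = 0.5)), 200))
    names(lengths) <- genes

    ab <- stats::rlnorm(G, meanlog = 0, sdlog = 1)
    fc <- rep(1, G)
    fc[labels == "up"] <- 2^truth$lfc_magnitude
    fc[labels == "down"] <- 2^(-truth$lfc_magnitude)
    # balance expected fragment flow across conditions (ratio-preserving)
    if (n_up > 0 && n_dn > 0 && truth$lfc_magnitude > 0) {
      up_gain <- sum(ab[labels == "up"]) * (2^truth$lfc_magnitude - 1)
      dn_loss <- sum(ab[labels == "down"]) * (1 - 2^(-truth$lfc_magnitude))
      ab[labels == "down"] <- ab[labels == "down"] * up_gain / dn_loss
    }
    ab <- ab / sum(ab)

    mu <- matrix(0, nrow = G, ncol = n_samp)
    for (s in seq_len(n_samp)) {
      f <- if (s <= n_per) 1 else fc   # first half control, second half salt
      mu[, s] <- truth$lib_sizes[s] * ab * f
    }
    counts <- if (truth$dispersion == 0) {
      matrix(stats::rpois(G * n_samp, mu), nrow = G)
    } else {
      matrix(stats::rnbinom(G * n_samp, mu = mu, size = 1 / truth$dispersion),
             nrow = G)
    }
    storage.mode(counts) <- "integer"
    samples <- data.frame(
      sample = c(paste0("control_", seq_len(n_per)),
                 paste0("salt_", seq_len(n_samp - n_per))),
      condition = rep(c("control", "salt"), c(n_per, n_samp - n_per)),
      replicate = c(seq_len(n_per), seq_len(n_samp - n_per)),
      stringsAsFactors = FALSE
    )
    dimnames(counts) <- list(genes, samples$sample)
    structure(list(counts = counts, lengths = lengths, samples = samples,
                   labels = labels, truth = truth),
              class = "sim_counts")
  })
}

#' @export
print.sim_counts <- function(x, ...) {
  cat("Synthetic count matrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  cat("planted:", sum(x$labels == "up"), "up,", sum(x$labels == "down"),
      "down,", sum(x$labels == "null"), "null\n")
  invisible(x)
}

#' Ground truth for a synthetic pathway collection
#'
#' Describes a gene-set collection in which a chosen subset of pathways is
#' seeded with an excess of differentially expressed genes, so hypergeometric
#' over-representation analysis has a recoverable answer.
#'
#' @param n_pathways number of pathways.
#' @param sizes per-pathway set sizes (>= 1); `NULL` draws them uniformly in
#'   10-50.
#' @param enriched_ids pathway ids seeded with excess DE genes; default the
#'   first 5. Must be a subset of the generated ids `PW01, PW02, ...`.
#' @param de_fraction fraction of an enriched pathway's members drawn from
#'   the DE genes (default 0.5, well above typical backgrounds).
#' @param seed integer seed.
#' @return list of class `"pathway_truth"`.
#' @export
pathway_truth <- function(n_pathways = 25, sizes = NULL,
                          enriched_ids = NULL, de_fraction = 0.5,
                          seed = 1L) {
  n_pathways <- as.integer(n_pathways)
  if (n_pathways < 1L) stop("need at least one pathway")
  ids <- sprintf("PW%02d", seq_len(n_pathways))
  if (is.null(enriched_ids)) enriched_ids <- ids[seq_len(min(5L, n_pathways))]
  if (!all(enriched_ids %in% ids))
    stop("enriched_ids must be a subset of the pathway ids ", ids[1], "..")
  if (!is.null(sizes)) {
    if (length(sizes) != n_pathways) stop("need one size per pathway")
    if (any(sizes < 1)) stop("pathway sizes must be >= 1")
  }
  stop_if_not_scalar_prob(de_fraction, "de_fraction")
  structure(list(n_pathways = n_pathways, ids = ids, sizes = sizes,
                 enriched_ids = enriched_ids, de_fraction = de_fraction,
                 seed = as.integer(seed)),
            class = "pathway_truth")
}

#' Generate a synthetic gene-set collection with planted enrichment
#'
#' Builds pathways over the genes of a simulated count matrix. Enriched
#' pathways take `de_fraction` of their members from the planted DE genes
#' (an excess over the genome-wide DE rate by construction) and the rest
#' from non-DE genes; non-enriched pathways sample their members uniformly
#' from all genes, so their overlap with the DE set is exactly
#' hypergeometric under the null.
#'
#' @param truth a [pathway_truth()] object.
#' @param labels named gene labels (`up`/`down`/`null`) from
#'   [gen_count_matrix()].
#' @return named list of gene-id vectors (one per pathway), with attribute
#'   `enriched` giving the seeded pathway ids; writable with [write_gmt()].
#' @export
gen_pathways <- function(truth, labels) {
  stopifnot(inherits(truth, "pathway_truth"))
  genes <- names(labels)
  if (is.null(genes)) stop("labels must be a named vector of gene labels")
  de_genes <- genes[labels != "null"]
  bg_genes <- genes[labels == "null"]
  with_rng(substream_seed(truth$seed, "pathways"), {
    sizes <- truth$sizes
    if (is.null(sizes)) sizes <- sample(10:50, truth$n_pathways, replace = TRUE)
    if (any(sizes > length(genes)))
      stop("requested pathway size exceeds the number of genes")
    sets <- lapply(seq_len(truth$n_pathways), function(i) {
      K <- sizes[i]
      if (truth$ids[i] %in% truth$enriched_ids) {
        k_de <- min(round(truth$de_fraction * K), length(de_genes))
        c(sample(de_genes, k_de),
          sample(bg_genes, K - k_de))
      } else {
        sample(genes, K)
      }
    })
    names(sets) <- truth$ids
    attr(sets, "enriched") <- truth$enriched_ids
    sets
  })
}

#' Generate a synthetic qPCR Ct table from planted fold changes
#'
#' Builds a cycle-threshold table consistent with the planted RNA-seq truth:
#' for each target gene the salt-group Ct is shifted by minus the planted
#' signed log2 fold change relative to control (one PCR cycle per doubling),
#' so with `noise_sd = 0` the 2^-ddCt fold change of a planted up-regulated
#' gene is exactly `2^lfc_magnitude`. A reference (housekeeping) gene with
#' constant expected Ct is included in both groups.
#'
#' @param labels named gene labels (`up`/`down`/`null`); Cts are generated
#'   for `genes`.
#' @param lfc_magnitude planted |log2 fold change| matching the count
#'   simulation.
#' @param noise_sd Gaussian Ct noise in cycles (default 0.2, a typical
#'   technical-replicate scatter).
#' @param seed integer seed.
#' @param genes gene ids to assay; default all genes in `labels`.
#' @param reference_gene id of the reference gene (default `"ACTIN"`); must
#'   not collide with a target id.
#' @param n_reps technical replicates per gene and group (default 3).
#' @return data frame of class `"ct_table"` with columns `gene`, `group`
#'   (`control`/`salt`), `replicate`, `Ct`, and attribute `reference_gene`.
#' @export
gen_ct_table <- function(labels, lfc_magnitude = 2, noise_sd = 0.2, seed = 1L,
                         genes = names(labels), reference_gene = "ACTIN",
                         n_reps = 3) {
  if (is.null(names(labels))) stop("labels must be named by gene id")
  if (is.null(reference_gene) || !nzchar(reference_gene))
    stop("a reference gene must be designated")
  if (!all(genes %in% names(labels))) stop("unknown gene ids in 'genes'")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_rng(substream_seed(seed, "ct_table"), {
    base_ct <- stats::setNames(stats::runif(length(genes), 23, 29), genes)
    shift <- c(up = -lfc_magnitude, down = lfc_magnitude, null = 0)
    rows <- list()
    for (grp in c("control", "salt")) {
      for (g in genes) {
        mu <- base_ct[[g]] + if (grp == "salt") shift[[labels[[g]]]] else 0
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, group = grp, replicate = seq_len(n_reps),
          Ct = mu + stats::rnorm(n_reps, sd = noise_sd))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = reference_gene, group = grp, replicate = seq_len(n_reps),
        Ct = 20 + stats::rnorm(n_reps, sd = noise_sd))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$Ct <- pmax(out$Ct, 1e-6)  # Ct values are positive cycle numbers
    attr(out, "reference_gene") <- reference_gene
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
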