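#' Synthetic-data configuration
#'
#' Parameters for the seeded generator of benchmark interaction networks
#' and variant tables. The generated network is an Erdős–Rényi background
#' over `n_genes` genes with confidence scores uniform in
#' `background_score_range`, plus a planted, fully connected pathway
#' module of `module_size` genes whose scores are uniform in
#' `module_score_range` — strictly above and disjoint from the background
#' range, so module edges are always shorter than background edges. This
#' emulates the premise that causal genes of one phenotype cluster into a
#' high-confidence functional neighbourhood.
#'
#' @param n_genes Number of genes in the universe.
#' @param edge_prob Background edge probability.
#' @param background_score_range Length-2 numeric, background confidence
#'   scores (low, high), inside (0, 1).
#' @param module_size Number of genes in the planted module (0 disables
#'   planting).
#' @param module_score_range Length-2 numeric, module confidence scores;
#'   must lie strictly above the background range.
#' @param n_candidates Size of the candidate list drawn in recovery
#'   benchmarks.
#' @param seed Integer seed; all generator randomness flows through it.
#' @param degrade_module If `TRUE`, no module clique is planted: the
#'   designated module genes receive only ordinary background edges. This
#'   is the matched null for recovery benchmarks.
#' @param hub_gene If `TRUE`, one background gene is additionally wired to
#'   30\% of all genes with module-range scores, emulating a highly
#'   central core whose connectome discriminates poorly.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500, edge_prob = 0.02,
                         background_score_range = c(0.15, 0.40),
                         module_size = 10,
                         module_score_range = c(0.70, 0.95),
                         n_candidates = 200, seed = 1,
                         degrade_module = FALSE, hub_gene = FALSE) {
  stopifnot(n_genes >= 2, edge_prob > 0, edge_prob < 1,
            length(background_score_range) == 2,
            length(module_score_range) == 2,
            all(background_score_range > 0),
            all(background_score_range < 1),
            background_score_range[1] < background_score_range[2],
            all(module_score_range > 0), all(module_score_range <= 1),
            module_score_range[1] < module_score_range[2],
            n_candidates >= 1, is.numeric(seed))
  if (module_size > n_genes) {
    stop("planted module (", module_size, " genes) larger than the gene ",
         "universe (", n_genes, ")", call. = FALSE)
  }
  if (module_size > 0 && module_score_range[1] <= background_score_range[2]) {
    stop("module score range must lie strictly above the background range",
         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), edge_prob = edge_prob,
                 background_score_range = background_score_range,
                 module_size = as.integer(module_size),
                 module_score_range = module_score_range,
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed),
                 degrade_module = isTRUE(degrade_module),
                 hub_gene = isTRUE(hub_gene)),
            class = "synth_config")
}

synth_gene_names <- function(n) {
  sprintf(paste0("G%0", max(3L, nchar(as.character(n))), "d"), seq_len(n))
}

#' Generate a synthetic interaction network
#'
#' Deterministic for a fixed seed. Background edges are drawn
#' independently with probability `edge_prob` over all gene pairs; the
#' planted module is a clique whose edges override any coinciding
#' background edge (so exactly `choose(module_size, 2)` module edges are
#' present, all with module-range scores). With `degrade_module = TRUE`
#' the clique is omitted entirely and the module genes are
#' indistinguishable from background.
#'
#' @param config A `synth_config`.
#' @return A list with `records` (interaction data.frame: gene_a, gene_b,
#'   score), `module` (planted module gene symbols) and `genes` (the full
#'   gene universe, including isolated genes).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    genes <- synth_gene_names(n)
    module <- if (config$module_size > 0) {
      sort(sample(genes, config$module_size))
    } else {
      character(0)
    }
    pairs <- t(utils::combn(n, 2L))
    keep <- stats::runif(nrow(pairs)) < config$edge_prob
    bg <- pairs[keep, , drop = FALSE]
    rec <- data.frame(
      gene_a = genes[bg[, 1]],
      gene_b = genes[bg[, 2]],
      score = stats::runif(nrow(bg), config$background_score_range[1],
                           config$background_score_range[2]),
      stringsAsFactors = FALSE
    )
    if (length(module) >= 2 && !config$degrade_module) {
      mp <- t(utils::combn(module, 2L))
      mrec <- data.frame(
        gene_a = mp[, 1],
        gene_b = mp[, 2],
        score = stats::runif(nrow(mp), config$module_score_range[1],
                             config$module_score_range[2]),
        stringsAsFactors = FALSE
      )
      rec <- override_edges(rec, mrec)
    }
    if (config$hub_gene) {
      hub <- setdiff(genes, module)[1]
      others <- sample(setdiff(genes, hub), max(1L, floor(0.3 * n)))
      hrec <- data.frame(
        gene_a = pmin(hub, others),
        gene_b = pmax(hub, others),
        score = stats::runif(length(others), config$module_score_range[1],
                             config$module_score_range[2]),
        stringsAsFactors = FALSE
      )
      rec <- override_edges(rec, hrec)
    }
    rec <- rec[order(rec$gene_a, rec$gene_b), , drop = FALSE]
    rownames(rec) <- NULL
    list(records = rec, module = module, genes = genes)
  })
}

# replace any edge of `base` on a pair present in `over` by the `over` edge
override_edges <- function(base, over) {
  key <- function(df) paste(pmin(df$gene_a, df$gene_b),
                            pmax(df$gene_a, df$gene_b))
  rbind(base[!key(base) %in% key(over), , drop = FALSE], over)
}

#' Generate a synthetic variant table
#'
#' Builds a per-patient candidate variant table of known composition for
#' testing the filter and the end-to-end benchmark: a fixed fraction of
#' synonymous variants (dropped by rule i), of common variants with
#' population frequency well above 1\% (dropped by rule ii), of
#' cohort-frequent variants above the 0.6\% batch threshold (dropped by
#' rule iii), and the remainder rare nonsynonymous variants constructed to
#' pass every rule — plus one rare missense variant in `causal_gene`,
#' guaranteed to survive filtering. The analytically expected kept count
#' is returned alongside the records. Deterministic per seed.
#'
#' @param config A `synth_config` (supplies the gene universe and seed).
#' @param causal_gene Gene symbol receiving the guaranteed causal variant;
#'   must belong to the gene universe.
#' @param n_variants Total number of variants, causal one included.
#' @param frac_synonymous,frac_common,frac_cohort_frequent Composition
#'   fractions; the remainder is rare nonsynonymous.
#' @param exclude_genes Genes never used for non-causal variants (for
#'   benchmark candidate lists that must contain exactly one pathway
#'   gene).
#' @return A list with `variants` (data.frame with the [read_variants()]
#'   columns), `expected_kept` (integer) and `composition` (named counts).
#' @export
generate_variant_table <- function(config, causal_gene, n_variants = 400,
                                   frac_synonymous = 0.25,
                                   frac_common = 0.25,
                                   frac_cohort_frequent = 0.10,
                                   exclude_genes = character(0)) {
  stopifnot(inherits(config, "synth_config"), n_variants >= 1)
  genes <- synth_gene_names(config$n_genes)
  causal_gene <- toupper(causal_gene)
  if (!causal_gene %in% genes) {
    stop("causal gene '", causal_gene, "' is not in the gene universe",
         call. = FALSE)
  }
  pool <- setdiff(genes, c(toupper(exclude_genes), causal_gene))
  n_syn <- round(frac_synonymous * n_variants)
  n_common <- round(frac_common * n_variants)
  n_cohort <- round(frac_cohort_frequent * n_variants)
  n_rare <- n_variants - n_syn - n_common - n_cohort - 1L
  if (n_rare < 0) {
    stop("composition fractions exceed the variant budget", call. = FALSE)
  }
  nonsyn <- setdiff(EFFECT_CLASSES, "synonymous")
  withr::with_seed(config$seed + 1L, {
    rare_freq <- function(k) stats::runif(k, 0, 0.0099)
    ok_cohort <- function(k) stats::runif(k, 0, 0.006)
    blocks <- list(
      data.frame(gene = sample(pool, n_syn, replace = TRUE),
                 effect = "synonymous",
                 freq_db1 = rare_freq(n_syn), freq_db2 = rare_freq(n_syn),
                 cohort_freq = ok_cohort(n_syn), stringsAsFactors = FALSE),
      data.frame(gene = sample(pool, n_common, replace = TRUE),
                 effect = sample(nonsyn, n_common, replace = TRUE),
                 freq_db1 = stats::runif(n_common, 0.02, 0.2),
                 freq_db2 = stats::runif(n_common, 0.02, 0.2),
                 cohort_freq = ok_cohort(n_common), stringsAsFactors = FALSE),
      data.frame(gene = sample(pool, n_cohort, replace = TRUE),
                 effect = sample(nonsyn, n_cohort, replace = TRUE),
                 freq_db1 = rare_freq(n_cohort), freq_db2 = rare_freq(n_cohort),
                 cohort_freq = stats::runif(n_cohort, 0.0061, 0.05),
                 stringsAsFactors = FALSE),
      data.frame(gene = sample(pool, n_rare, replace = TRUE),
                 effect = sample(nonsyn, n_rare, replace = TRUE),
                 freq_db1 = rare_freq(n_rare), freq_db2 = rare_freq(n_rare),
                 cohort_freq = ok_cohort(n_rare), stringsAsFactors = FALSE),
      data.frame(gene = causal_gene, effect = "missense",
                 freq_db1 = 0, freq_db2 = 0, cohort_freq = 0,
                 stringsAsFactors = FALSE)
    )
    variants <- do.call(rbind, blocks)
    variants <- variants[sample(nrow(variants)), , drop = FALSE]
    rownames(variants) <- NULL
    list(variants = variants,
         expected_kept = n_rare + 1L,
         composition = c(synonymous = n_syn, common = n_common,
                         cohort_frequent = n_cohort, rare = n_rare,
                         causal = 1L))
  })
}
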