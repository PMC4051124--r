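#' Variant filter configuration
#'
#' Thresholds for the standard pre-prioritization variant filter:
#' (i) exclude variants whose effect class is in `drop_effects`
#' (synonymous by default); (ii) keep rare variants only, with frequency
#' strictly below `popfreq_max` (1\% by default) in each of the two
#' population databases; (iii) a batch/hypermutability filter that drops
#' variants seen in more than `cohort_max` (0.6\% by default) of patients
#' from other disease cohorts — variants at exactly the threshold are
#' kept.
#'
#' @param popfreq_max Population-frequency cutoff (strict `<`), in \[0, 1\].
#' @param cohort_max Cohort-frequency cutoff (keep `<=`), in \[0, 1\].
#' @param drop_effects Character vector of effect classes to exclude.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(popfreq_max = 0.01, cohort_max = 0.006,
                          drop_effects = "synonymous") {
  stopifnot(is.numeric(popfreq_max), length(popfreq_max) == 1,
            popfreq_max >= 0, popfreq_max <= 1,
            is.numeric(cohort_max), length(cohort_max) == 1,
            cohort_max >= 0, cohort_max <= 1)
  drop_effects <- tolower(drop_effects)
  unknown <- setdiff(drop_effects, EFFECT_CLASSES)
  if (length(unknown) > 0) {
    stop("unknown effect class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(popfreq_max = popfreq_max, cohort_max = cohort_max,
                 drop_effects = drop_effects), class = "filter_config")
}

#' Filter candidate variants
#'
#' Applies the three filtering rules of [filter_config()] in order. A
#' variant is kept iff its effect class is not excluded AND both
#' population frequencies are strictly below `popfreq_max` AND its cohort
#' frequency is at most `cohort_max`. The kept set does not depend on rule
#' order; only the per-rule drop attribution does (a dropped variant is
#' attributed to the first rule it fails).
#'
#' @param records Variant data.frame as from [read_variants()] or
#'   [generate_variant_table()].
#' @param config A `filter_config`.
#' @return A list with `kept` (the retained records, input order
#'   preserved) and `drops` (named integer vector: effect, popfreq,
#'   cohort).
#' @export
filter_variants <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  req <- c("gene", "effect", "freq_db1", "freq_db2", "cohort_freq")
  if (nrow0(records)) {
    return(list(kept = records, drops = c(effect = 0L, popfreq = 0L,
                                          cohort = 0L)))
  }
  stopifnot(all(req %in% names(records)))
  fail_effect <- tolower(records$effect) %in% config$drop_effects
  fail_pop <- records$freq_db1 >= config$popfreq_max |
    records$freq_db2 >= config$popfreq_max
  fail_cohort <- records$cohort_freq > config$cohort_max
  kept <- !(fail_effect | fail_pop | fail_cohort)
  drops <- c(
    effect = sum(fail_effect),
    popfreq = sum(!fail_effect & fail_pop),
    cohort = sum(!fail_effect & !fail_pop & fail_cohort)
  )
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  list(kept = out, drops = drops)
}

nrow0 <- function(x) is.null(x) || nrow(x) == 0

#' Unique genes of a variant set
#'
#' Bridges filtered variants to a candidate gene list for [prioritize()].
#'
#' @param records Variant data.frame (typically the `kept` element of
#'   [filter_variants()]).
#' @return Sorted character vector of unique gene symbols.
#' @export
genes_of <- function(records) {
  if (nrow0(records)) return(character(0))
  sort(unique(toupper(records$gene)))
}
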