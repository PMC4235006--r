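## End-to-end orchestration: per-unit paired-condition analysis, the
## population battery mirroring the recorded-data workflow, and a seeded
## one-command reproduction on synthetic data.

#' Analysis configuration
#'
#' Houses the named analysis constants: the 2-SD excitatory criterion, the
#' tenth-order FTC polynomial, the 25% non-monotonicity rule, the 20%
#' change criterion, the family alpha with its two Sidak-corrected post hoc
#' tests, and the DI variant.
#'
#' @param sdMultiplier excitatory-mask criterion multiplier (default 2).
#' @param degree FTC polynomial degree (default 10).
#' @param nonmonoFraction non-monotonicity reduction fraction (default
#'   0.25).
#' @param changeCriterion fractional change criterion (default 0.20).
#' @param alpha family-wise level (default 0.05).
#' @param postHocTests number of post hoc tests behind the Sidak correction
#'   (default 2).
#' @param diVariant `"absdev"` (sum of |AUC - 0.5|) or `"sumauc"`
#'   (diagnostic plain sum).
#' @param fallbackCriterion spike criterion of the fallback FRA area.
#' @param nBoot,seed bootstrap resamples and seed for median CIs.
#' @return a classed list of constants.
#' @export
analysisConfig <- function(sdMultiplier = 2, degree = 10L,
                           nonmonoFraction = 0.25, changeCriterion = 0.20,
                           alpha = 0.05, postHocTests = 2L,
                           diVariant = c("absdev", "sumauc"),
                           fallbackCriterion = 1L, nBoot = 2000L,
                           seed = 1L) {
  diVariant <- match.arg(diVariant)
  stopifnot(sdMultiplier >= 0, degree >= 1, nonmonoFraction > 0,
            nonmonoFraction < 1, changeCriterion > 0, changeCriterion < 1,
            alpha > 0, alpha < 1, postHocTests >= 1)
  structure(list(sdMultiplier = sdMultiplier, degree = as.integer(degree),
                 nonmonoFraction = nonmonoFraction,
                 changeCriterion = changeCriterion, alpha = alpha,
                 postHocTests = as.integer(postHocTests),
                 diVariant = diVariant,
                 fallbackCriterion = as.integer(fallbackCriterion),
                 nBoot = as.integer(nBoot), seed = seed),
            class = "AnalysisConfig")
}

.diOf <- function(metrics, cfg) {
  if (cfg$diVariant == "sumauc") metrics@sumAUC else metrics@di
}

#' Analyse one unit across conditions
#'
#' Runs the FRA and/or RLF analysis per condition and assembles the
#' per-measure change summary (modulation index, raw difference, and the
#' fractional change class) of control vs deactivated, with recovery values
#' alongside.
#'
#' @param triplet a [ConditionTriplet-class].
#' @param cfg an [analysisConfig()].
#' @return list with `fra` (per-condition [FTCResult-class]), `rlf`
#'   (per-condition [RLFMetrics-class]) and `changes` (data frame, one row
#'   per measure).
#' @export
analyzeUnit <- function(triplet, cfg = analysisConfig()) {
  stopifnot(is(triplet, "ConditionTriplet"))
  fraRes <- lapply(triplet@fra, analyzeFRA, sdMultiplier = cfg$sdMultiplier,
                   degree = cfg$degree,
                   fallbackCriterion = cfg$fallbackCriterion)
  rlfRes <- lapply(triplet@rlf, analyzeRLF,
                   nonmonoFraction = cfg$nonmonoFraction)

  val <- function(res, what) {
    vapply(conditionNames, function(cn) {
      if (!cn %in% names(res)) return(NA_real_)
      slot(res[[cn]], what)
    }, numeric(1))
  }
  rows <- list()
  if (length(fraRes)) {
    for (meas in c("totalSpikes", "areaBins", "threshold"))
      rows[[meas]] <- val(fraRes, meas)
  }
  if (length(rlfRes)) {
    rows$halfMaxLevel <- val(rlfRes, "halfMaxLevel")
    rows$di <- vapply(conditionNames, function(cn) {
      if (!cn %in% names(rlfRes)) return(NA_real_)
      .diOf(rlfRes[[cn]], cfg)
    }, numeric(1))
  }
  measureNames <- c(totalSpikes = "total_spikes", areaBins = "area_bins",
                    threshold = "threshold", halfMaxLevel = "half_max_level",
                    di = "di")
  changes <- do.call(rbind, lapply(names(rows), function(m) {
    v <- rows[[m]]
    ratioMeasure <- m %in% c("totalSpikes", "areaBins", "di")
    data.frame(
      unit_id = triplet@unit@unitId,
      fra_class = triplet@unit@fraClass,
      measure = measureNames[[m]],
      control = v[["control"]], deactivated = v[["deactivated"]],
      recovery = v[["recovery"]],
      mi = if (ratioMeasure && !is.na(v[["deactivated"]]))
        modulationIndex(v[["control"]], v[["deactivated"]]) else NA_real_,
      delta = v[["deactivated"]] - v[["control"]],
      change_class = if (ratioMeasure && !is.na(v[["deactivated"]]))
        classifyChange(v[["control"]], v[["deactivated"]],
                       cfg$changeCriterion) else NA_character_,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(fra = fraRes, rlf = rlfRes, changes = changes)
}

#' Analyse a population of paired-condition units
#'
#' Per-unit analyses followed by the population battery: KS comparisons of
#' the V vs nonV modulation-index distributions for FRA area and FRA
#' spikes; the RLF type-transition r x 2 table (type x changed/unchanged)
#' with the exact Fisher test; Friedman tests across the three conditions
#' for half-maximum level and DI with Sidak-corrected Wilcoxon post hocs
#' (control vs deactivated, control vs recovery); Spearman correlation
#' between the change in half-maximum level and the change in threshold for
#' units carrying both paradigms; and per-condition medians with bootstrap
#' CIs.
#'
#' @param triplets list of [ConditionTriplet-class] (>= 2 units).
#' @param cfg an [analysisConfig()].
#' @return a `PopulationReport` (classed list): `unitChanges`,
#'   `perUnit`, `ks`, `transitions`, `fisher`, `friedman`, `wilcoxon`,
#'   `spearman`, `medians`, `changeCounts`, `alphaPostHoc`, `provenance`.
#' @export
analyzePopulation <- function(triplets, cfg = analysisConfig()) {
  if (length(triplets) < 2L) stop("need >= 2 units")
  perUnit <- lapply(triplets, analyzeUnit, cfg = cfg)
  changes <- do.call(rbind, c(lapply(perUnit, `[[`, "changes"),
                              list(make.row.names = FALSE)))
  alphaPH <- sidakAlpha(cfg$alpha, cfg$postHocTests)

  pick <- function(measure, col = "mi", class = NULL) {
    sel <- changes$measure == measure
    if (!is.null(class)) sel <- sel & changes$fra_class == class
    v <- changes[[col]][sel]
    v[is.finite(v)]
  }

  ## --- FRA battery: V vs nonV modulation distributions -------------------
  ks <- list()
  for (meas in c("area_bins", "total_spikes")) {
    vmi <- pick(meas, "mi", "V"); nmi <- pick(meas, "mi", "nonV")
    if (length(vmi) && length(nmi))
      ks[[meas]] <- ksTwoSample(vmi, nmi, alpha = cfg$alpha)
  }

  ## --- RLF type transitions ---------------------------------------------
  labels <- lapply(perUnit, function(u) {
    if (length(u$rlf) < 2L || !all(c("control", "deactivated") %in%
                                   names(u$rlf))) return(NULL)
    c(control = u$rlf$control@typeLabel,
      deactivated = u$rlf$deactivated@typeLabel)
  })
  labels <- Filter(Negate(is.null), labels)
  transitions <- NULL; fisher <- NULL
  if (length(labels) >= 2L) {
    ctl <- vapply(labels, `[[`, "", "control")
    dea <- vapply(labels, `[[`, "", "deactivated")
    changed <- factor(ifelse(ctl == dea, "unchanged", "changed"),
                      levels = c("changed", "unchanged"))
    transitions <- table(type = factor(ctl, levels = rlfTypes), changed)
    keep <- rowSums(transitions) > 0
    tab <- transitions[keep, , drop = FALSE]
    if (nrow(tab) >= 2L && all(colSums(tab) > 0))
      fisher <- fisherExactRx2(unclass(tab), alpha = cfg$alpha)
  }

  ## --- condition matrices for half-max and DI ---------------------------
  condMatrix <- function(measure) {
    sel <- changes$measure == measure
    m <- as.matrix(changes[sel, c("control", "deactivated", "recovery")])
    rownames(m) <- changes$unit_id[sel]
    m[stats::complete.cases(m), , drop = FALSE]
  }
  friedman <- list(); wilcoxon <- list(); medians <- list()
  for (meas in c("half_max_level", "di")) {
    m <- condMatrix(meas)
    if (nrow(m) < 3L) next
    ## a degenerate battery (e.g. identical conditions) reports NULL for
    ## the affected test rather than aborting the population analysis
    tryNull <- function(expr) tryCatch(expr, error = function(e) NULL)
    friedman[[meas]] <- tryNull(friedmanTest(m, alpha = cfg$alpha))
    wilcoxon[[meas]] <- list(
      control_vs_deactivated = tryNull(
        wilcoxonSignedRank(m[, "control"], m[, "deactivated"],
                           alpha = alphaPH)),
      control_vs_recovery = tryNull(
        wilcoxonSignedRank(m[, "control"], m[, "recovery"],
                           alpha = alphaPH)))
    medians[[meas]] <- lapply(conditionNames, function(cn)
      bootstrapMedianCI(m[, cn], nBoot = cfg$nBoot,
                        seed = childSeed(cfg$seed, match(cn, conditionNames))))
    names(medians[[meas]]) <- conditionNames
  }

  ## --- half-max shift vs threshold shift (both-paradigm units) ----------
  spearman <- NULL
  dHalf <- changes$delta[changes$measure == "half_max_level"]
  names(dHalf) <- changes$unit_id[changes$measure == "half_max_level"]
  dThr <- changes$delta[changes$measure == "threshold"]
  names(dThr) <- changes$unit_id[changes$measure == "threshold"]
  both <- intersect(names(dHalf)[is.finite(dHalf)],
                    names(dThr)[is.finite(dThr)])
  if (length(both) >= 3L)
    spearman <- tryCatch(
      spearmanCorrelation(dHalf[both], dThr[both], alpha = cfg$alpha),
      error = function(e) NULL)

  ## --- fractional change counts by FRA class ----------------------------
  changeCounts <- NULL
  sel <- changes$measure == "total_spikes" & !is.na(changes$change_class)
  if (any(sel))
    changeCounts <- table(class = changes$fra_class[sel],
                          change = factor(changes$change_class[sel],
                                          levels = c("decrease", "none",
                                                     "increase")))

  structure(list(unitChanges = changes, perUnit = perUnit, ks = ks,
                 transitions = transitions, fisher = fisher,
                 friedman = friedman, wilcoxon = wilcoxon,
                 spearman = spearman, medians = medians,
                 changeCounts = changeCounts, alphaPostHoc = alphaPH,
                 provenance = list(config = cfg,
                                   config_hash = configHash(cfg),
                                   n_units = length(triplets))),
            class = "PopulationReport")
}

#' @export
print.PopulationReport <- function(x, ...) {
  cat("PopulationReport:", x$provenance$n_units, "units\n")
  for (nm in names(x$ks)) {
    cat(sprintf("  KS V-vs-nonV MI (%s): D = %.3g, p = %.3g\n", nm,
                x$ks[[nm]]$statistic, x$ks[[nm]]$p))
  }
  for (nm in names(x$friedman)) {
    cat(sprintf("  Friedman (%s): chi2(%g) = %.4g, p = %.3g\n", nm,
                x$friedman[[nm]]$df, x$friedman[[nm]]$statistic,
                x$friedman[[nm]]$p))
    for (w in names(x$wilcoxon[[nm]])) {
      if (is.null(x$wilcoxon[[nm]][[w]])) next
      cat(sprintf("    Wilcoxon %s: p = %.3g (alpha %.4g)\n", w,
                  x$wilcoxon[[nm]][[w]]$p, x$wilcoxon[[nm]][[w]]$alpha))
    }
    med <- x$medians[[nm]]
    cat(sprintf("    medians: %s\n", paste(sprintf(
      "%s %.3g [%.3g, %.3g]", names(med),
      vapply(med, `[[`, 0, "median"), vapply(med, `[[`, 0, "lo"),
      vapply(med, `[[`, 0, "hi")), collapse = ", ")))
  }
  if (!is.null(x$fisher))
    cat(sprintf("  Fisher exact (type transitions): p = %.3g\n",
                x$fisher$p))
  if (!is.null(x$spearman))
    cat(sprintf("  Spearman d(half-max) vs d(threshold): rho = %.3g, p = %.3g\n",
                x$spearman$statistic, x$spearman$p))
  invisible(x)
}

#' One-command synthetic reproduction run
#'
#' Generates the default seeded synthetic population, analyses it, and
#' writes the results under a run directory: the per-unit change table
#' (TSV with JSON provenance sidecar), the RLF type-transition table, a
#' JSON summary of the statistical battery, and (optionally, when ggplot2
#' is available) figures echoing the modulation-index CDFs and DI
#' distributions.
#'
#' @param popConfig a [populationConfig()].
#' @param cfg an [analysisConfig()].
#' @param dir output directory (created if needed).
#' @param figures also write figures (default `FALSE`).
#' @return the `PopulationReport`, invisibly.
#' @export
runRepro <- function(popConfig = populationConfig(),
                     cfg = analysisConfig(), dir = "icresp-run",
                     figures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- makePopulation(popConfig)
  report <- analyzePopulation(pop$triplets, cfg)

  writeResults(report$unitChanges, file.path(dir, "unit_changes.tsv"),
               config = list(pop = popConfig, analysis = cfg),
               seed = popConfig@seed)
  utils::write.table(pop$ledger, file.path(dir, "ground_truth_ledger.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$transitions))
    utils::write.table(as.data.frame(report$transitions),
                       file.path(dir, "rlf_transitions.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

  summarise <- function(s) if (is.null(s)) NULL else
    list(statistic = s$statistic, df = s$df, p = s$p, exact = s$exact,
         alpha = s$alpha)
  summary <- list(
    provenance = list(config_hash = report$provenance$config_hash,
                      seed = popConfig@seed,
                      n_units = report$provenance$n_units),
    alpha_post_hoc = report$alphaPostHoc,
    ks = lapply(report$ks, summarise),
    fisher = summarise(report$fisher),
    friedman = lapply(report$friedman, summarise),
    wilcoxon = lapply(report$wilcoxon, function(w) lapply(w, summarise)),
    spearman = summarise(report$spearman),
    medians = report$medians)
  jsonlite::write_json(summary, file.path(dir, "population_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  if (figures && requireNamespace("ggplot2", quietly = TRUE))
    .reproFigures(report, dir)
  invisible(report)
}

.reproFigures <- function(report, dir) {
  ch <- report$unitChanges
  mi <- ch[ch$measure %in% c("area_bins", "total_spikes") &
             is.finite(ch$mi), ]
  p1 <- ggplot2::ggplot(mi, ggplot2::aes(x = mi, colour = fra_class)) +
    ggplot2::stat_ecdf() + ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "modulation index", y = "cumulative proportion")
  ggplot2::ggsave(file.path(dir, "mi_cdfs.pdf"), p1, width = 7, height = 4)
  di <- ch[ch$measure == "di", ]
  long <- data.frame(condition = rep(conditionNames, each = nrow(di)),
                     di = c(di$control, di$deactivated, di$recovery))
  p2 <- ggplot2::ggplot(long[is.finite(long$di), ],
                        ggplot2::aes(condition, di)) +
    ggplot2::geom_boxplot() + ggplot2::labs(y = "Discriminability Index")
  ggplot2::ggsave(file.path(dir, "di_by_condition.pdf"), p2,
                  width = 5, height = 4)
}
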