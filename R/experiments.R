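# Repeated-runs protocol, statistical method comparison and variable
# ablation. One holdout split is shared across all runs and all methods; the
# per-run seeds vary only the evolutionary search.

derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Repeated-runs protocol for one basis family
#'
#' Splits the cohort once (the split is shared across every run), fits the
#' basis-specific scaler on the training part only, then runs the
#' evolutionary trainer `n_runs` times with distinct derived seeds. Each
#' run's best genome is evaluated on the generalisation set (CCR, minimum
#' sensitivity, AUC, connection count, active inputs). The selected best run
#' is the one with the highest training fitness, ties broken by fewer
#' connections — the generalisation set never influences selection.
#'
#' @param cohort a `cohort_table`.
#' @param basis `"PU"`, `"SU"` or `"RBF"`.
#' @param config an `ea_config` for that basis (its `seed` is overridden per
#'   run by seeds derived from `master_seed`).
#' @param n_runs number of repetitions (default 30).
#' @param master_seed seed deriving the per-run EA seeds.
#' @param split optional precomputed `split_result` (used by the ablation
#'   driver to share membership across arms); otherwise a split is drawn
#'   with `split_seed`.
#' @param n_train,split_seed,stratified forwarded to [holdout_split()].
#' @return a `run_summary`: per-run metric table, mean/sd per metric, the
#'   selected best run, its genome and generalisation metrics report, the
#'   split and scaler.
#' @export
run_protocol <- function(cohort, basis, config, n_runs = 30L,
                         master_seed = 1L, split = NULL,
                         n_train = default_n_train(nrow(cohort$features)),
                         split_seed = 1L, stratified = TRUE) {
  if (is.null(split))
    split <- holdout_split(cohort, n_train = n_train, seed = split_seed,
                           stratified = stratified)
  scaler <- fit_scaler(split$train, basis)
  x_tr <- apply_scaler(scaler, split$train)
  x_ge <- apply_scaler(scaler, split$generalisation)
  y_tr <- split$train$outcome
  y_ge <- split$generalisation$outcome
  seeds <- derive_seeds(master_seed, n_runs)
  runs <- data.frame(run = seq_len(n_runs), seed = seeds,
                     train_fitness = NA_real_, ccr = NA_real_, ms = NA_real_,
                     auc = NA_real_, n_conn = NA_integer_)
  genomes <- vector("list", n_runs)
  actives <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config; cfg$seed <- seeds[r]
    trace <- evolve(x_tr, y_tr, cfg)
    g <- trace$best_genome
    p <- forward(g, x_ge)
    cm <- confusion_matrix(y_ge, as.integer(p >= 0.5))
    runs$train_fitness[r] <- trace$best_fitness
    runs$ccr[r] <- ccr(cm)
    runs$ms[r] <- min_sensitivity(cm)
    runs$auc[r] <- auc(y_ge, p)
    runs$n_conn[r] <- count_connections(g)
    genomes[[r]] <- g
    actives[[r]] <- active_inputs(g)
  }
  best <- order(-runs$train_fitness, runs$n_conn)[1]
  best_report <- metrics_report(y_ge, forward(genomes[[best]], x_ge),
                                n_connections = runs$n_conn[best])
  summ <- sapply(c("ccr", "ms", "auc", "n_conn"), function(m)
    c(mean = mean(runs[[m]]),
      sd = if (n_runs > 1L) stats::sd(runs[[m]]) else 0))
  structure(list(basis = basis, runs = runs, summary = summ,
                 active_inputs = actives, best_run = best,
                 best_genome = genomes[[best]], best_report = best_report,
                 split = split, scaler = scaler, config = config,
                 master_seed = master_seed,
                 shared_split = TRUE),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("run_summary: %s basis, %d runs (shared split, master seed %d)\n",
              x$basis, nrow(x$runs), x$master_seed))
  s <- x$summary
  for (m in colnames(s))
    cat(sprintf("  %-6s %.3f +/- %.3f\n", m, s["mean", m], s["sd", m]))
  cat(sprintf("  best run: %d (train fitness %.4f, %d connections)\n",
              x$best_run, x$runs$train_fitness[x$best_run],
              x$runs$n_conn[x$best_run]))
  invisible(x)
}

#' Statistical comparison of methods over repeated runs
#'
#' For each metric: Kolmogorov-Smirnov normality check per method (against a
#' normal with the sample-estimated mean and sd — a Lilliefors-style usage,
#' so the printed p-values are approximate), one-way ANOVA across methods,
#' Levene's test for homogeneity of variances, and Tukey honest significant
#' difference pairwise comparisons, plus the ranking of method means. No
#' multiple-testing correction is applied across metrics (each metric is
#' presented on its own).
#'
#' @param summaries named list (>= 2) of `run_summary` objects with equal
#'   run counts, names identifying the methods.
#' @param alpha significance level recorded in the report (default 0.05).
#' @param metrics metric columns to compare.
#' @return a `comparison_report`: per-metric list with `ks_p` (per method),
#'   `anova_f`, `anova_p`, `levene_p`, `tukey` (data frame of pairwise
#'   comparisons), `means` (sorted).
#' @export
compare_methods <- function(summaries, alpha = 0.05,
                            metrics = c("ccr", "ms", "auc", "n_conn")) {
  if (length(summaries) < 2L) stop("need at least two methods to compare")
  if (is.null(names(summaries)) || any(names(summaries) == ""))
    names(summaries) <- vapply(summaries, function(s) s$basis, character(1))
  n_runs <- vapply(summaries, function(s) nrow(s$runs), integer(1))
  if (length(unique(n_runs)) != 1L)
    stop("all methods must contribute the same number of runs")
  per_metric <- lapply(metrics, function(m) {
    values <- unlist(lapply(summaries, function(s) s$runs[[m]]),
                     use.names = FALSE)
    method <- factor(rep(names(summaries), each = n_runs[1]),
                     levels = names(summaries))
    ks_p <- vapply(names(summaries), function(nm) {
      x <- summaries[[nm]]$runs[[m]]
      if (stats::sd(x) == 0) return(NA_real_)  # degenerate: no spread to test
      suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }, numeric(1))
    fit <- stats::aov(values ~ method)
    an <- summary(fit)[[1]]
    tk <- as.data.frame(stats::TukeyHSD(fit)$method)
    tk$comparison <- rownames(tk)
    names(tk) <- c("diff", "lwr", "upr", "p", "comparison")
    lev_p <- tryCatch(car::leveneTest(values ~ method)[1, "Pr(>F)"],
                      error = function(e) NA_real_)
    list(ks_p = ks_p,
         anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
         levene_p = lev_p,
         tukey = tk[, c("comparison", "diff", "lwr", "upr", "p")],
         means = sort(tapply(values, method, mean), decreasing = TRUE))
  })
  names(per_metric) <- metrics
  structure(list(metrics = per_metric, alpha = alpha,
                 methods = names(summaries), n_runs = n_runs[1]),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %s over %d runs (alpha = %g)\n",
              paste(x$methods, collapse = " vs "), x$n_runs, x$alpha))
  for (m in names(x$metrics)) {
    pm <- x$metrics[[m]]
    cat(sprintf("  %-6s ANOVA F = %.3f (p = %.3g); Levene p = %.3g\n",
                m, pm$anova_f, pm$anova_p, pm$levene_p))
    cat(sprintf("    means: %s\n",
                paste(sprintf("%s %.3f", names(pm$means), pm$means),
                      collapse = " >= ")))
  }
  invisible(x)
}

#' Variable-ablation study
#'
#' Runs the repeated-runs protocol twice with matched design: once on the
#' full feature set and once with the designated variable's column removed,
#' using the identical split membership and the identical per-run seeds, so
#' every difference is attributable to the missing variable. Removing one
#' member of a one-hot block leaves the remaining indicators in place.
#'
#' @param cohort a `cohort_table`.
#' @param basis basis family.
#' @param config an `ea_config`.
#' @param variable_id column name to ablate (e.g. `"X4"`).
#' @param n_runs matched runs per arm (default 10).
#' @param master_seed,n_train,split_seed,stratified as in [run_protocol()].
#' @return an `ablation_report`: both `run_summary` objects and
#'   `delta_mean`, the drop in each mean metric (full minus ablated).
#' @export
ablation_study <- function(cohort, basis, config, variable_id,
                           n_runs = 10L, master_seed = 1L,
                           n_train = default_n_train(nrow(cohort$features)),
                           split_seed = 1L, stratified = TRUE) {
  if (!variable_id %in% colnames(cohort$features))
    stop("variable '", variable_id, "' not found in the cohort")
  split <- holdout_split(cohort, n_train = n_train, seed = split_seed,
                         stratified = stratified)
  drop_col <- function(tab) cohort_table(
    tab$features[, setdiff(colnames(tab$features), variable_id), drop = FALSE],
    tab$outcome, ids = tab$ids, provenance = tab$provenance)
  split_reduced <- split
  split_reduced$train <- drop_col(split$train)
  split_reduced$generalisation <- drop_col(split$generalisation)
  full <- run_protocol(cohort, basis, config, n_runs = n_runs,
                       master_seed = master_seed, split = split)
  ablated <- run_protocol(drop_col(cohort), basis, config, n_runs = n_runs,
                          master_seed = master_seed, split = split_reduced)
  deltas <- full$summary["mean", ] - ablated$summary["mean", ]
  structure(list(variable = variable_id, full = full, ablated = ablated,
                 delta_mean = deltas), class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("ablation_report: variable %s (%d matched runs per arm)\n",
              x$variable, nrow(x$full$runs)))
  for (m in names(x$delta_mean))
    cat(sprintf("  %-6s with %.3f | without %.3f | drop %.3f\n",
                m, x$full$summary["mean", m], x$ablated$summary["mean", m],
                x$delta_mean[m]))
  invisible(x)
}
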