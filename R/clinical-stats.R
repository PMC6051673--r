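#' Read a clinical score table
#'
#' Expects a TSV with columns subject, PRE_OFF, PRE_ON, POST_OFF, POST_ON
#' holding non-negative integer UPDRS-III motor scores, one row per subject
#' with no missing cells.
#'
#' @param path TSV file path.
#' @return data.frame with the five columns, checked for completeness.
#' @export
readClinicalTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  checkClinicalTable(tab)
  tab
}

#' Bundled UPDRS-III scores from the STN-DBS/levodopa study cohort
#'
#' Motor scores of 13 patients with advanced Parkinson's disease assessed in
#' four sessions: before electrode implantation without and with levodopa
#' (PRE_OFF, PRE_ON) and after implantation without and with bilateral STN
#' stimulation (POST_OFF, POST_ON).
#'
#' @return data.frame with columns subject, PRE_OFF, PRE_ON, POST_OFF,
#'   POST_ON.
#' @export
updrsScores <- function() {
  readClinicalTable(system.file("extdata", "updrs_stn_dbs.tsv",
                                package = "ecmap", mustWork = TRUE))
}

checkClinicalTable <- function(tab) {
  need <- c("subject", "PRE_OFF", "PRE_ON", "POST_OFF", "POST_ON")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("clinical table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) < 2L) stop("need at least 2 subjects")
  if (anyNA(tab[need])) stop("clinical table has missing cells")
  invisible(tab)
}

#' Paired Student's t-test
#'
#' Two-tailed paired t on a - b.  As a convention for degenerate input,
#' identical vectors (all differences exactly zero) return t = 0, p = 1;
#' constant non-zero differences are an error because the statistic is
#' undefined.
#'
#' @param a,b equal-length numeric score vectors (n >= 2).
#' @return list: t, df (= n - 1), p (two-sided), meanDiff, sdDiff.
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1L, p = 1, meanDiff = 0, sdDiff = 0))
    stop("paired differences have zero variance; t statistic undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanDiff = mean(d), sdDiff = stats::sd(d))
}

#' 2x2 repeated-measures ANOVA on clinical scores
#'
#' Within-subject ANOVA with factors treatment method (PRE vs POST) and
#' treatment state (OFF vs ON).  With two levels per factor each F statistic
#' equals the squared paired t on the corresponding subject-level composite:
#' method uses mean(PRE) - mean(POST), state uses mean(OFF) - mean(ON), the
#' interaction uses (PRE_OFF - PRE_ON) - (POST_OFF - POST_ON).  All F have
#' df (1, n - 1).
#'
#' @param table clinical data.frame (see [readClinicalTable()]).
#' @return list of class "rmAnova2x2": FMethod, FState, FInteraction, df1,
#'   df2, pMethod, pState, pInteraction.
#' @export
rmAnova2x2 <- function(table) {
  checkClinicalTable(table)
  n <- nrow(table)
  comp <- list(
    method = (table$PRE_OFF + table$PRE_ON) / 2 -
             (table$POST_OFF + table$POST_ON) / 2,
    state = (table$PRE_OFF + table$POST_OFF) / 2 -
            (table$PRE_ON + table$POST_ON) / 2,
    interaction = (table$PRE_OFF - table$PRE_ON) -
                  (table$POST_OFF - table$POST_ON))
  Fs <- vapply(comp, function(x) {
    if (stats::sd(x) == 0)        # degenerate: no subject variability
      return(if (mean(x) == 0) 0 else Inf)
    (mean(x) / (stats::sd(x) / sqrt(n)))^2
  }, numeric(1))
  ps <- stats::pf(Fs, 1, n - 1, lower.tail = FALSE)
  structure(list(FMethod = Fs[["method"]], FState = Fs[["state"]],
                 FInteraction = Fs[["interaction"]],
                 df1 = 1L, df2 = n - 1L,
                 pMethod = ps[["method"]], pState = ps[["state"]],
                 pInteraction = ps[["interaction"]]),
            class = "rmAnova2x2")
}

#' @export
print.rmAnova2x2 <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA (df = %d, %d)\n", x$df1, x$df2))
  cat(sprintf("  treatment method:  F = %.1f, p = %.3g\n", x$FMethod, x$pMethod))
  cat(sprintf("  treatment state:   F = %.1f, p = %.3g\n", x$FState, x$pState))
  cat(sprintf("  interaction:       F = %.1f, p = %.3g\n",
              x$FInteraction, x$pInteraction))
  invisible(x)
}

#' Treatment-effect battery with a common baseline
#'
#' Computes the per-subject treatment effects
#' L = PRE_OFF - PRE_ON (levodopa), D = POST_OFF - POST_ON (DBS) and
#' B = PRE_OFF - POST_ON (DBS against the common untreated baseline),
#' reports mean +/- SD (n - 1 denominator) of each, and runs the two-tailed
#' paired t-tests: levodopa effect, DBS effect, L vs D, the two cross-method
#' comparisons in matching states (PRE_OFF vs POST_OFF, PRE_ON vs POST_ON),
#' and L vs B.  Each test is flagged significant at the Bonferroni-corrected
#' threshold `alpha`.
#'
#' @param table clinical data.frame.
#' @param alpha Bonferroni-corrected significance level (default 0.0083).
#' @return list of class "treatmentEffects": `effects` (data.frame with
#'   mean/sd rows for L, D, B) and `tests` (data.frame with t, df, p,
#'   meanDiff, sdDiff, significant).
#' @export
treatmentEffectBattery <- function(table, alpha = 0.0083) {
  checkClinicalTable(table)
  L <- table$PRE_OFF - table$PRE_ON
  D <- table$POST_OFF - table$POST_ON
  B <- table$PRE_OFF - table$POST_ON
  effects <- data.frame(
    effect = c("levodopa (PRE_OFF - PRE_ON)", "DBS (POST_OFF - POST_ON)",
               "DBS vs baseline (PRE_OFF - POST_ON)"),
    mean = c(mean(L), mean(D), mean(B)),
    sd = c(stats::sd(L), stats::sd(D), stats::sd(B)))
  tests <- list(
    levodopa = pairedT(table$PRE_OFF, table$PRE_ON),
    dbs = pairedT(table$POST_OFF, table$POST_ON),
    levodopa_vs_dbs = pairedT(L, D),
    off_pre_vs_post = pairedT(table$PRE_OFF, table$POST_OFF),
    on_pre_vs_post = pairedT(table$PRE_ON, table$POST_ON),
    levodopa_vs_baseline = pairedT(L, B))
  tdf <- do.call(rbind, lapply(names(tests), function(nm) {
    x <- tests[[nm]]
    data.frame(test = nm, t = x$t, df = x$df, p = x$p,
               meanDiff = x$meanDiff, sdDiff = x$sdDiff,
               significant = x$p < alpha)
  }))
  structure(list(effects = effects, tests = tdf, alpha = alpha),
            class = "treatmentEffects")
}

#' @export
print.treatmentEffects <- function(x, ...) {
  cat("Treatment effects (UPDRS-III points, mean +/- SD):\n")
  for (i in seq_len(nrow(x$effects)))
    cat(sprintf("  %-38s %.1f +/- %.1f\n", x$effects$effect[i],
                x$effects$mean[i], x$effects$sd[i]))
  cat(sprintf("Paired t-tests (Bonferroni alpha = %.4f):\n", x$alpha))
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("  %-22s t = %5.1f, df = %d, p = %.3g%s\n",
                x$tests$test[i], x$tests$t[i], x$tests$df[i], x$tests$p[i],
                if (x$tests$significant[i]) " *" else ""))
  invisible(x)
}
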