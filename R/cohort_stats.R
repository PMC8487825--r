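# Group-comparison layer: mean +/- SD summaries, one-way ANOVA for
# continuous measures, Pearson chi-square for incidence counts, and the
# per-segment incidence tables used to compare the three groups.

#' Per-group mean +/- SD summary
#'
#' @param values Numeric vector.
#' @param groups Grouping vector, same length.
#' @param variable Variable name carried into the output.
#' @return Data frame with columns `variable`, `group`, `n`, `mean`, `sd`
#'   (sample SD, n-1 divisor) and a formatted `label` "mean +/- sd".
#' @export
group_summary <- function(values, groups, variable = "value") {
  if (length(values) != length(groups)) stop("group_summary(): length mismatch")
  if (anyNA(groups)) stop("group_summary(): empty group label (NA)")
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  if (any(tabulate(factor(groups)) == 0L) || length(values) == 0L) {
    stop("group_summary(): empty group")
  }
  sp <- split(values, groups)
  out <- data.frame(
    variable = variable,
    group = names(sp),
    n = vapply(sp, length, 0L),
    mean = vapply(sp, mean, 0),
    sd = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0),
    stringsAsFactors = FALSE)
  out$label <- sprintf("%.2f ± %.2f", out$mean, out$sd)
  rownames(out) <- NULL
  out
}

comparison_result <- function(variable, test, statistic, df, p_value,
                              alpha = 0.05, groups = NULL) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 df = df, p_value = p_value,
                 significant = is.finite(p_value) && p_value < alpha,
                 groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  stat_name <- if (x$test == "anova") "F" else "X-squared"
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g%s\n",
              x$variable, stat_name, x$statistic,
              paste(x$df, collapse = ", "), x$p_value,
              if (x$significant) " (significant at 0.05)" else ""))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA, `F = MS_between / MS_within` with
#' `(k - 1, N - k)` degrees of freedom, fitted via [stats::lm()].
#'
#' @param values Numeric response.
#' @param groups Grouping vector with >= 2 levels, each with >= 2 values.
#' @param variable Name carried into the result.
#' @return A `group_comparison` object (statistic, df, p_value, significant,
#'   plus the per-group summary).
#' @export
anova_oneway <- function(values, groups, variable = "value") {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("anova_oneway(): need at least 2 groups")
  if (any(table(g) < 2L)) stop("anova_oneway(): every group needs >= 2 values")
  if (stats::var(values) == 0) {
    stop("anova_oneway(): all values identical (degenerate variance)")
  }
  a <- stats::anova(stats::lm(values ~ g))
  comparison_result(variable, "anova",
                    statistic = a[["F value"]][1],
                    df = c(a[["Df"]][1], a[["Df"]][2]),
                    p_value = a[["Pr(>F)"]][1],
                    groups = group_summary(values, groups, variable))
}

#' Pearson chi-square test on a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with `df = (r - 1)(c - 1)`; no continuity
#' correction by default (set `correct = TRUE` for the Yates-corrected 2x2
#' variant).
#'
#' @param tab Matrix of counts (r x c).
#' @param variable Name carried into the result.
#' @param correct Apply the continuity correction? Default `FALSE`.
#' @return A `group_comparison` object.
#' @export
chi_square <- function(tab, variable = "counts", correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("chi_square(): negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi_square(): zero marginal total")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("chi_square(): zero expected count")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  comparison_result(variable, "chi_square",
                    statistic = unname(ct$statistic),
                    df = unname(ct$parameter),
                    p_value = unname(ct$p.value))
}

incidence_predicates <- function() {
  c("grade_ge_I", "grade_ge_II", "grade_ge_III", "plaque", "imt_thickened")
}

apply_predicate <- function(cohort, predicate) {
  ann <- annotate_cohort(cohort)
  g <- ann$grade_derived
  switch(predicate,
         grade_ge_I = g >= "I",
         grade_ge_II = g >= "II",
         grade_ge_III = g >= "III",
         plaque = ann$plaque_call,
         imt_thickened = ann$imt_class == "thickened",
         stop("incidence_table(): unknown predicate '", predicate, "'; one of ",
              paste(incidence_predicates(), collapse = ", ")))
}

#' Per-group, per-segment incidence table
#'
#' Counts affected arteries (each side-segment row is one artery) per group
#' and anatomical segment under a predicate recomputed by the vessel-metrics
#' rules (stenosis grade thresholds, plaque call or IMT class), with
#' chi-square group comparisons attached per segment and overall.
#'
#' @param cohort Cohort data frame (schema of [generate_cohort()]).
#' @param predicate One of `"grade_ge_I"`, `"grade_ge_II"`, `"grade_ge_III"`,
#'   `"plaque"`, `"imt_thickened"`.
#' @return List of class `incidence_table`: `table` (data frame with
#'   `group`, `segment` — including `"all"` —, `total`, `affected`,
#'   `proportion`) and `tests` (chi-square per segment and overall).
#' @export
incidence_table <- function(cohort, predicate = "grade_ge_I") {
  if (nrow(cohort) == 0L) stop("incidence_table(): empty cohort")
  hit <- apply_predicate(cohort, predicate)
  grp <- factor(cohort$group)
  seg <- factor(cohort$segment, levels = arterial_segments())
  cells <- expand.grid(group = levels(grp),
                       segment = c(levels(seg), "all"),
                       stringsAsFactors = FALSE)
  tot <- function(g, s) {
    sel <- grp == g & (s == "all" | seg == s)
    c(total = sum(sel), affected = sum(hit[sel]))
  }
  cnt <- t(mapply(tot, cells$group, cells$segment))
  tab <- cbind(cells, as.data.frame(cnt))
  rownames(tab) <- NULL
  tab$proportion <- tab$affected / tab$total
  tests <- lapply(c(levels(seg), "all"), function(s) {
    sub <- tab[tab$segment == s, ]
    m <- rbind(affected = sub$affected,
               unaffected = sub$total - sub$affected)
    colnames(m) <- sub$group
    tryCatch(chi_square(t(m), variable = paste0(predicate, ":", s)),
             error = function(e) NULL)
  })
  names(tests) <- c(levels(seg), "all")
  structure(list(predicate = predicate, table = tab,
                 tests = Filter(Negate(is.null), tests)),
            class = "incidence_table")
}

#' Full three-group comparison report
#'
#' Runs the complete comparison battery on a cohort: demographic summaries
#' with ANOVA (age, TC, TG) and chi-square (sex, smoking); per-segment
#' bilateral-IMT ANOVA; per-segment PSV/RI/PI ANOVA; and plaque,
#' grade >= I and grade >= II incidence tables with chi-square tests.
#' Optionally writes each table as CSV plus a plain-text summary.
#'
#' @param cohort Cohort data frame with groups A, B and C present.
#' @param out_dir Output directory for CSVs and `report.txt`, or `NULL`.
#' @return List of class `cohort_report` with elements `demographics`,
#'   `demographic_tests`, `imt`, `hemodynamics`, `plaque`, `stenosis_ge_I`,
#'   `stenosis_ge_II`.
#' @export
run_full_comparison <- function(cohort, out_dir = NULL) {
  if (!all(c("A", "B", "C") %in% cohort$group)) {
    stop("run_full_comparison(): cohort must contain groups A, B and C")
  }
  ann <- annotate_cohort(cohort)
  subj <- ann[!duplicated(ann$subject_id), ]

  demographics <- rbind(
    group_summary(subj$age, subj$group, "age"),
    group_summary(subj$tc, subj$group, "tc"),
    group_summary(subj$tg, subj$group, "tg"))
  demographic_tests <- list(
    age = anova_oneway(subj$age, subj$group, "age"),
    tc = anova_oneway(subj$tc, subj$group, "tc"),
    tg = anova_oneway(subj$tg, subj$group, "tg"),
    sex = chi_square(table(subj$group, subj$sex), "sex"),
    smoker = chi_square(table(subj$group, factor(subj$smoker,
                                                 levels = c(FALSE, TRUE))),
                        "smoker"))

  # one bilateral IMT value per subject-segment
  bil <- ann[!duplicated(paste(ann$subject_id, ann$segment)), ]
  imt <- lapply(arterial_segments(), function(s) {
    sub <- bil[bil$segment == s, ]
    anova_oneway(sub$imt_bilateral_mm, sub$group, paste0("imt:", s))
  })
  names(imt) <- arterial_segments()

  hemodynamics <- list()
  for (v in c("psv", "ri", "pi")) {
    hemodynamics[[v]] <- lapply(arterial_segments(), function(s) {
      sub <- ann[ann$segment == s, ]
      anova_oneway(sub[[v]], sub$group, paste0(v, ":", s))
    })
    names(hemodynamics[[v]]) <- arterial_segments()
  }

  report <- structure(list(
    demographics = demographics,
    demographic_tests = demographic_tests,
    imt = imt,
    hemodynamics = hemodynamics,
    plaque = incidence_table(cohort, "plaque"),
    stenosis_ge_I = incidence_table(cohort, "grade_ge_I"),
    stenosis_ge_II = incidence_table(cohort, "grade_ge_II")),
    class = "cohort_report")
  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  report
}

comparison_df <- function(lst) {
  do.call(rbind, lapply(lst, function(x) {
    data.frame(variable = x$variable, test = x$test,
               statistic = x$statistic, df1 = x$df[1],
               df2 = if (length(x$df) > 1) x$df[2] else NA,
               p_value = x$p_value, significant = x$significant,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort report to disk
#'
#' CSV tables plus a deterministic plain-text summary (`report.txt`).
#'
#' @param rep A `cohort_report` from [run_full_comparison()].
#' @param out_dir Directory, created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_cohort_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(rep$demographics, "demographics_summary.csv")
  w(comparison_df(rep$demographic_tests), "demographics_tests.csv")
  w(comparison_df(rep$imt), "imt_anova.csv")
  for (v in names(rep$hemodynamics)) {
    w(comparison_df(rep$hemodynamics[[v]]), paste0(v, "_anova.csv"))
  }
  for (nm in c("plaque", "stenosis_ge_I", "stenosis_ge_II")) {
    w(rep[[nm]]$table, paste0(nm, "_incidence.csv"))
    w(comparison_df(rep[[nm]]$tests), paste0(nm, "_tests.csv"))
  }
  con <- file(file.path(out_dir, "report.txt"), open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("Three-group cohort comparison report")
  wl("====================================")
  wl("")
  wl("Demographics (mean ± sd):")
  for (i in seq_len(nrow(rep$demographics))) {
    r <- rep$demographics[i, ]
    wl("  %-4s group %s: %s (n = %d)", r$variable, r$group, r$label, r$n)
  }
  wl("")
  for (x in rep$demographic_tests) {
    wl("  %-7s %s = %.4f, p = %.4f", x$variable,
       if (x$test == "anova") "F" else "X2", x$statistic, x$p_value)
  }
  wl("")
  wl("Per-segment bilateral IMT ANOVA:")
  for (x in rep$imt) wl("  %-24s F = %.3f, p = %.3g", x$variable,
                        x$statistic, x$p_value)
  wl("")
  for (nm in c("plaque", "stenosis_ge_I", "stenosis_ge_II")) {
    it <- rep[[nm]]
    wl("%s incidence (affected / total arteries):", nm)
    sub <- it$table[it$table$segment == "all", ]
    for (i in seq_len(nrow(sub))) {
      wl("  group %s: %d / %d (%.1f%%)", sub$group[i], sub$affected[i],
         sub$total[i], 100 * sub$proportion[i])
    }
    if (!is.null(it$tests$all)) {
      wl("  X2 = %.3f, p = %.3g", it$tests$all$statistic, it$tests$all$p_value)
    }
    wl("")
  }
  invisible(out_dir)
}
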