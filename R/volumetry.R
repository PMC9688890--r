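#' Normalize absolute volumes by intracranial volume
#'
#' Converts each absolute nucleus volume to a percentage of the subject's
#' estimated total intracranial volume:
#' `structural volume (%) = absolute volume / eTIV x 100`.
#' Covariate columns are untouched.
#'
#' @param cohort a `"cohort_table"`.
#' @return Data frame of class `"normalized_volumes"` with nucleus columns on
#'   the percent scale.
#' @export
normalize_volumes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table") || is.data.frame(cohort))
  labs <- thalamic_nucleus_labels()
  out <- as.data.frame(cohort)
  if (any(out$eTIV <= 0)) stop("eTIV must be positive for every subject")
  for (col in labs) out[[col]] <- 100 * out[[col]] / out$eTIV
  class(out) <- c("normalized_volumes", "data.frame")
  out
}

#' Add derived whole-thalamus columns
#'
#' Appends `Left-Whole`, `Right-Whole` and `Whole` columns equal to the sum of
#' the hemisphere's (resp. all) nucleus values, on whatever scale the input
#' table carries.
#'
#' @param table cohort or normalized-volume table.
#' @return The table with three extra columns.
#' @export
add_whole_thalamus <- function(table) {
  labs <- thalamic_nucleus_labels()
  left <- labs[startsWith(labs, "Left-")]
  right <- labs[startsWith(labs, "Right-")]
  table$`Left-Whole` <- rowSums(as.matrix(table[left]))
  table$`Right-Whole` <- rowSums(as.matrix(table[right]))
  table$Whole <- table$`Left-Whole` + table$`Right-Whole`
  table
}

# one-way ANOVA from sums of squares; degenerate inputs handled explicitly
.oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  msb <- ssb / df1
  msw <- ssw / df2
  if (msb <= .Machine$double.eps * max(1, abs(mean(values)))^2) {
    return(list(F = 0, p = 1, msw = msw, df2 = df2))
  }
  if (msw == 0) {
    return(list(F = Inf, p = 0, msw = msw, df2 = df2))
  }
  f <- msb / msw
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE), msw = msw,
       df2 = df2)
}

#' Three-group ANOVA with Bonferroni post hoc for one region
#'
#' One-way ANOVA of a region's normalized volumes across the F-MS, NF-MS and
#' HC groups, followed by pooled-variance pairwise t-tests with Bonferroni
#' correction (x3). A region is flagged when a pairwise comparison passes
#' `alpha`, the 0.05/50 Bonferroni level across the 50 nuclei by default.
#' Degenerate inputs (no between-group variance) report `F = 0`, `p = 1`.
#'
#' @param norm a `"normalized_volumes"` table (or any data frame with `group`
#'   and the region column).
#' @param region column name, e.g. `"Right-MDm"`.
#' @param alpha per-region significance level (default 0.001).
#' @return One-row data frame: group means/SDs, `F`, `p_anova`, the three
#'   Bonferroni-adjusted pairwise p-values, and significance flags.
#' @export
anova_posthoc <- function(norm, region, alpha = 0.001) {
  if (!region %in% names(norm)) stop("no such region column: ", region)
  groups <- factor(norm$group, levels = c("F-MS", "NF-MS", "HC"))
  groups <- droplevels(groups)
  if (nlevels(groups) < 3) stop("all three groups must be present")
  if (any(table(groups) < 2)) stop("need at least 2 subjects per group")
  v <- norm[[region]]
  a <- .oneway_anova(v, groups)
  gm <- tapply(v, groups, mean)
  gs <- tapply(v, groups, stats::sd)
  gn <- tapply(v, groups, length)
  pair_p <- function(g1, g2) {
    if (a$msw == 0) {
      return(if (abs(gm[[g1]] - gm[[g2]]) == 0) 1 else 0)
    }
    se <- sqrt(a$msw * (1 / gn[[g1]] + 1 / gn[[g2]]))
    t <- (gm[[g1]] - gm[[g2]]) / se
    min(1, 3 * 2 * stats::pt(-abs(t), a$df2))
  }
  p_f_hc <- pair_p("F-MS", "HC")
  p_nf_hc <- pair_p("NF-MS", "HC")
  p_f_nf <- pair_p("F-MS", "NF-MS")
  data.frame(
    region = region,
    mean_FMS = gm[["F-MS"]], sd_FMS = gs[["F-MS"]],
    mean_NFMS = gm[["NF-MS"]], sd_NFMS = gs[["NF-MS"]],
    mean_HC = gm[["HC"]], sd_HC = gs[["HC"]],
    F = a$F, p_anova = a$p,
    p_FMS_vs_HC = p_f_hc, p_NFMS_vs_HC = p_nf_hc, p_FMS_vs_NFMS = p_f_nf,
    sig_FMS_vs_HC = p_f_hc < alpha,
    sig_NFMS_vs_HC = p_nf_hc < alpha,
    sig_FMS_vs_NFMS = p_f_nf < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Group volumetry statistics for all regions
#'
#' Runs [anova_posthoc()] for each of the 50 nuclei (plus derived
#' whole-thalamus columns when `include_whole = TRUE`), producing the familiar
#' per-region layout: group means and SDs, ANOVA F and p, pairwise
#' Bonferroni-adjusted p-values, and significance flags at `alpha`.
#'
#' @param norm a `"normalized_volumes"` table.
#' @param alpha per-region significance level (default 0.001).
#' @param include_whole also report `Left-Whole`, `Right-Whole`, `Whole`.
#' @return Data frame with one row per region.
#' @export
volumetry_stats <- function(norm, alpha = 0.001, include_whole = FALSE) {
  regions <- thalamic_nucleus_labels()
  if (include_whole) {
    norm <- add_whole_thalamus(norm)
    regions <- c("Whole", "Left-Whole", "Right-Whole", regions)
  }
  do.call(rbind, lapply(regions, function(r) anova_posthoc(norm, r, alpha)))
}

#' Correlate a region's volume with a clinical variable
#'
#' Spearman (default, rank-transform then product-moment) or Pearson
#' correlation between a region's normalized volume and a clinical variable.
#' Lesion volume and disease duration are only defined for patients, so the
#' correlation is computed on the F-MS and NF-MS subjects by default; set
#' `subjects = "all"` to use every row with a non-missing value.
#'
#' @param norm a `"normalized_volumes"` table.
#' @param region region column name.
#' @param variable one of `"lesion_volume"`, `"disease_duration"`, `"age"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param subjects `"patients"` (default) or `"all"`.
#' @return One-row data frame with `region`, `variable`, `method`, `n`,
#'   `rho`, `p`.
#' @export
correlate_clinical <- function(norm, region,
                               variable = c("lesion_volume",
                                            "disease_duration", "age"),
                               method = c("spearman", "pearson"),
                               subjects = c("patients", "all")) {
  variable <- match.arg(variable)
  method <- match.arg(method)
  subjects <- match.arg(subjects)
  if (!region %in% names(norm)) stop("no such region column: ", region)
  rows <- if (subjects == "patients") norm$group %in% c("F-MS", "NF-MS") else
    rep(TRUE, nrow(norm))
  x <- norm[[variable]][rows]
  y <- norm[[region]][rows]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4) stop("too few paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in ",
         if (stats::sd(x) == 0) variable else region)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(region = region, variable = variable, method = method,
             n = length(x), rho = unname(ct$estimate), p = ct$p.value,
             stringsAsFactors = FALSE, row.names = NULL)
}
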