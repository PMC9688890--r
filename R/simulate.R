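# Reference values for the default study conditions: three groups
# (25 fatigued MS, 25 non-fatigued MS, 40 controls), control-group nucleus
# volumes on the percent-of-eTIV scale, and per-group eTIV distributions.

# control-group mean and SD of each nucleus volume (% of eTIV), left then
# right hemisphere in canonical code order
.hc_percent_means <- c(
  # Left hemisphere
  0.0103, 0.0020, 0.0097, 0.0330, 0.0026, 0.0512, 0.0681, 0.0815, 0.0022,
  0.0054, 0.0028, 0.0003, 0.0208, 0.0048, 0.0006, 0.0011, 0.0639, 0.0216,
  0.0238, 0.0093, 0.0018, 0.0191, 0.0951, 0.0154, 0.0222,
  # Right hemisphere
  0.0101, 0.0019, 0.0093, 0.0323, 0.0026, 0.0484, 0.0631, 0.0698, 0.0020,
  0.0053, 0.0026, 0.0004, 0.0192, 0.0047, 0.0005, 0.0010, 0.0616, 0.0211,
  0.0199, 0.0093, 0.0016, 0.0169, 0.0875, 0.0132, 0.0191
)

.hc_percent_sds <- c(
  0.0019, 0.0008, 0.0017, 0.0050, 0.0004, 0.0075, 0.0102, 0.0144, 0.0004,
  0.0010, 0.0006, 0.0001, 0.0037, 0.0009, 0.0001, 0.0002, 0.0133, 0.0050,
  0.0043, 0.0024, 0.0006, 0.0037, 0.0162, 0.0029, 0.0040,
  0.0020, 0.0006, 0.0018, 0.0052, 0.0004, 0.0073, 0.0095, 0.0119, 0.0004,
  0.0010, 0.0006, 0.0001, 0.0032, 0.0008, 0.0001, 0.0003, 0.0111, 0.0044,
  0.0034, 0.0021, 0.0005, 0.0029, 0.0146, 0.0024, 0.0038
)

# default fractional volume reductions: the nuclei reported atrophied at the
# 0.001 level in fatigued / non-fatigued MS, with fractions matching the
# reported group-mean ratios
.default_atrophy <- list(
  `F-MS` = c(
    "Right-AV" = 0.198, "Left-LD" = 0.300, "Right-LD" = 0.368,
    "Right-CL" = 0.192, "Right-LGN" = 0.211, "Right-PuA" = 0.160,
    "Left-PuM" = 0.167, "Right-PuM" = 0.202, "Left-PuI" = 0.185,
    "Right-PuI" = 0.236
  ),
  `NF-MS` = c(
    "Left-LD" = 0.350, "Right-LD" = 0.421, "Right-PuM" = 0.185,
    "Right-PuI" = 0.199
  ),
  HC = numeric(0)
)

.default_etiv <- list(
  `F-MS` = c(mean = 1336.74, sd = 256.13),
  `NF-MS` = c(mean = 1328.01, sd = 278.80),
  HC = c(mean = 1396.01, sd = 282.20)
)

# planted-network presets: the target group's covariance is switched from the
# anatomical block model to a ring model with a global floor (correlation
# decaying with position along a fixed ring of the 50 nuclei, never below
# `floor`), which concentrates low-density edges on ring neighbours and
# lengthens shortest paths; the designated node is decoupled (its
# correlations scaled by `decouple`), starving it of edges. Constants fixed
# by a one-time calibration run (see the methods vignette).
.network_presets <- list(
  none = NULL,
  moderate = list(type = "ring", rho = 0.80, floor = 0.40, decouple = 0.15),
  strong = list(type = "ring", rho = 0.90, floor = 0.50, decouple = 0.02)
)

#' Specification of a synthetic cohort
#'
#' Defines the statistical structure of a simulated study: group sizes
#' (default 25 fatigued MS / 25 non-fatigued MS / 40 controls), the base mean
#' and SD of every nucleus volume on the percent-of-eTIV scale (defaults are
#' the control-group volumetry values), per-group fractional atrophy maps,
#' a block covariance model whose blocks default to the six anatomical
#' nucleus groups, linear covariate effects of age, sex and lesion load, and
#' per-group eTIV distributions. Volumes are simulated on the percent scale
#' and converted to absolute volumes through each subject's drawn eTIV, so
#' the normalization stage is exercised nontrivially.
#'
#' Covariate effect sizes are expressed in units of each region's SD
#' (per year of age, per mL of lesion volume, and for male vs female).
#'
#' @param n_fms,n_nfms,n_hc group sizes.
#' @param base_mean,base_sd length-50 vectors, percent scale.
#' @param atrophy named list (per group) of named vectors of fractional
#'   reductions, e.g. `c("Right-AV" = 0.2)`.
#' @param r_in,r_out within-/between-block correlations of the block model.
#' @param blocks block assignment of the 50 labels (default: anatomical
#'   groups, shared across hemispheres).
#' @param beta_age,beta_sex_male,beta_lesion covariate effects in SD units.
#' @param age_mean,age_sd per-group age distribution (years, truncated to
#'   18-45).
#' @param p_female probability of female sex.
#' @param lesion_meanlog,lesion_sdlog log-normal lesion volume (mL), patients
#'   only.
#' @param duration_meanlog,duration_sdlog log-normal disease duration
#'   (years), patients only.
#' @param etiv named list per group of `c(mean, sd)` in mL.
#' @param correlation_override named list (per group) of correlation-model
#'   overrides, as installed by [plant_network_difference()].
#' @param seed default seed used by [generate_cohort()].
#' @return List of class `"cohort_spec"`; the implied correlation matrices
#'   are checked for positive definiteness at build time.
#' @export
synthetic_cohort_spec <- function(n_fms = 25L, n_nfms = 25L, n_hc = 40L,
                                  base_mean = .hc_percent_means,
                                  base_sd = .hc_percent_sds,
                                  atrophy = .default_atrophy,
                                  r_in = 0.45, r_out = 0.15,
                                  blocks = NULL,
                                  beta_age = -0.015,
                                  beta_sex_male = -0.20,
                                  beta_lesion = -0.04,
                                  age_mean = c(`F-MS` = 33, `NF-MS` = 29.5,
                                               HC = 28),
                                  age_sd = 7,
                                  p_female = 0.65,
                                  lesion_meanlog = log(6.3),
                                  lesion_sdlog = 0.3,
                                  duration_meanlog = c(`F-MS` = log(2.5),
                                                       `NF-MS` = log(1.7)),
                                  duration_sdlog = 0.5,
                                  etiv = .default_etiv,
                                  correlation_override = list(),
                                  seed = 1L) {
  labs <- thalamic_nucleus_labels()
  stopifnot(n_fms >= 4, n_nfms >= 4, n_hc >= 4,
            length(base_mean) == 50, length(base_sd) == 50,
            all(base_mean > 0), all(base_sd > 0),
            r_in > r_out, r_out >= 0, r_in < 1)
  if (is.null(blocks)) {
    tab <- nucleus_label_table()
    blocks <- stats::setNames(tab$anatomical_group, tab$label)
  }
  names(base_mean) <- names(base_sd) <- labs
  spec <- structure(list(
    sizes = c(`F-MS` = as.integer(n_fms), `NF-MS` = as.integer(n_nfms),
              HC = as.integer(n_hc)),
    base_mean = base_mean, base_sd = base_sd, atrophy = atrophy,
    r_in = r_in, r_out = r_out, blocks = blocks,
    beta_age = beta_age, beta_sex_male = beta_sex_male,
    beta_lesion = beta_lesion,
    age_mean = age_mean, age_sd = age_sd, p_female = p_female,
    lesion_meanlog = lesion_meanlog, lesion_sdlog = lesion_sdlog,
    duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
    etiv = etiv, correlation_override = correlation_override,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  for (g in names(spec$sizes)) .group_correlation(spec, g)  # PD check
  spec
}

# correlation matrix for one group under the spec (block model or override);
# errors if not positive definite
.group_correlation <- function(spec, group) {
  labs <- thalamic_nucleus_labels()
  ov <- spec$correlation_override[[group]]
  if (is.null(ov)) {
    same <- outer(spec$blocks[labs], spec$blocks[labs], "==")
    R <- ifelse(same, spec$r_in, spec$r_out)
    diag(R) <- 1
  } else if (ov$type == "ring") {
    pos <- seq_along(labs)
    d <- abs(outer(pos, pos, "-"))
    d <- pmin(d, length(labs) - d)
    R <- ov$rho^d
    if (!is.null(ov$floor)) R <- pmax(R, ov$floor)
    diag(R) <- 1
  } else if (ov$type == "block") {
    blocks <- if (!is.null(ov$blocks)) ov$blocks else spec$blocks
    if (isTRUE(ov$fragment)) {
      # fragment: split every block by hemisphere, halving its size
      blocks <- paste(blocks[labs],
                      ifelse(startsWith(labs, "Left-"), "L", "R"))
      names(blocks) <- labs
    }
    same <- outer(blocks[labs], blocks[labs], "==")
    r_in <- if (!is.null(ov$r_in)) ov$r_in else spec$r_in
    r_out <- if (!is.null(ov$r_out)) ov$r_out else spec$r_out
    R <- ifelse(same, r_in, r_out)
    diag(R) <- 1
  } else {
    stop("unknown correlation model type: ", ov$type)
  }
  if (!is.null(ov) && length(ov$decouple) > 0) {
    dec <- ov$decouple
    if (is.null(names(dec))) names(dec) <- ov$node
    for (nd in names(dec)) {
      i <- match(nd, labs)
      R[i, -i] <- R[i, -i] * dec[[nd]]
      R[-i, i] <- R[-i, i] * dec[[nd]]
    }
  }
  dimnames(R) <- list(labs, labs)
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop("correlation model for group ", group,
         " is not positive definite (min eigenvalue ", format(ev), ")")
  }
  R
}

#' Plant a network difference into a synthetic spec
#'
#' Returns a spec whose target group's correlation model is replaced so that
#' its thresholded networks have systematically longer characteristic path
#' length, and one designated node loses nodal efficiency. `"none"` is the
#' identity; `"moderate"` and `"strong"` use fixed, calibrated ring/decouple
#' constants.
#'
#' @param spec a `"cohort_spec"`.
#' @param target_group group label receiving the altered structure.
#' @param preset `"none"`, `"moderate"` or `"strong"`.
#' @param node designated low-efficiency node (default `"Right-MDm"`).
#' @return The modified spec.
#' @export
plant_network_difference <- function(spec, target_group,
                                     preset = c("none", "moderate", "strong"),
                                     node = "Right-MDm") {
  preset <- match.arg(preset)
  stopifnot(inherits(spec, "cohort_spec"),
            target_group %in% names(spec$sizes))
  if (preset == "none") return(spec)
  ov <- .network_presets[[preset]]
  ov$decouple <- stats::setNames(ov$decouple, node)
  ov$node <- node
  spec$correlation_override[[target_group]] <- ov
  .group_correlation(spec, target_group)  # PD check
  spec
}

# truncated-normal draw by rejection (bounds loose; vectorized resampling)
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws covariates per subject, draws nucleus percent volumes from a
#' multivariate Gaussian with the spec's covariance, adds linear covariate
#' effects and group atrophy shifts, and converts to absolute volumes via
#' each subject's drawn eTIV. Lesion volume and disease duration are 0 / `NA`
#' for controls. Fully reproducible from the seed.
#'
#' @param spec a `"cohort_spec"`.
#' @param seed integer seed; default `spec$seed`.
#' @return A validated `"cohort_table"`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  labs <- thalamic_nucleus_labels()
  with_seed(seed, {
    rows <- lapply(names(spec$sizes), function(g) {
      n <- spec$sizes[[g]]
      patient <- g != "HC"
      age <- .rtrunc_norm(n, spec$age_mean[[g]], spec$age_sd, 18, 45)
      sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
      lesion <- if (patient) {
        stats::rlnorm(n, spec$lesion_meanlog, spec$lesion_sdlog)
      } else {
        rep(0, n)
      }
      duration <- if (patient) {
        stats::rlnorm(n, spec$duration_meanlog[[g]], spec$duration_sdlog)
      } else {
        rep(NA_real_, n)
      }
      etiv <- .rtrunc_norm(n, spec$etiv[[g]][["mean"]],
                           spec$etiv[[g]][["sd"]], 800, 2200)

      R <- .group_correlation(spec, g)
      L <- chol(R)
      Z <- matrix(stats::rnorm(n * 50), n, 50) %*% L
      Z <- sweep(Z, 2, spec$base_sd, `*`)

      mu <- spec$base_mean
      atr <- spec$atrophy[[g]]
      if (length(atr) > 0) {
        mu[names(atr)] <- mu[names(atr)] * (1 - atr)
      }
      eff <- outer(age - 30, spec$beta_age * spec$base_sd) +
        outer(as.numeric(sex == "male"), spec$beta_sex_male * spec$base_sd) +
        outer(lesion, spec$beta_lesion * spec$base_sd)
      pct <- sweep(Z + eff, 2, mu, `+`)
      # tiny nuclei can graze zero; clamp to a small positive floor
      floor_ <- matrix(spec$base_mean * 0.02, n, 50, byrow = TRUE)
      pct <- pmax(pct, floor_)

      abs_vol <- pct * etiv / 100
      colnames(abs_vol) <- labs
      cbind(
        data.frame(subject_id = sprintf("%s-%03d", gsub("-", "", g),
                                        seq_len(n)),
                   group = g, age = age, sex = sex, lesion_volume = lesion,
                   eTIV = etiv, disease_duration = duration,
                   stringsAsFactors = FALSE),
        as.data.frame(abs_vol, check.names = FALSE)
      )
    })
    as_cohort_table(do.call(rbind, rows))
  })
}
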