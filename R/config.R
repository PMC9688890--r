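#' Analysis configuration
#'
#' Collects every tunable of the pipeline: the sparsity grid over which the
#' correlation matrices are binarized, the number of degree-preserving null
#' networks behind the normalized small-world metrics, permutation counts,
#' significance levels, and the covariates removed before network
#' construction. All randomness in the package flows from `rng_seed`: each
#' stage derives its own stream with [derive_seed()], so the order in which
#' stages run cannot change any result.
#'
#' @param sparsity_min,sparsity_max,sparsity_step sparsity (network density)
#'   grid; defaults 0.05 to 0.40 in steps of 0.01, a 36-point grid.
#' @param n_null_networks randomized null networks used to normalize Cp and Lp
#'   into gamma/lambda/sigma for observed networks; must exceed 150.
#' @param n_null_networks_perm reduced null count used inside each permutation
#'   when testing gamma/lambda/sigma, to bound cost; the observed statistic
#'   always uses `n_null_networks`.
#' @param n_permutations group-relabeling permutations for AUC tests.
#' @param rng_seed integer root seed.
#' @param fdr_alpha significance level for BH-FDR-adjusted nodal tests.
#' @param volumetry_alpha per-region significance level of the volumetry ANOVA
#'   (0.05 Bonferroni-divided across the 50 nuclei).
#' @param covariates covariate columns regressed out of the volumes before the
#'   correlation networks are built.
#' @param correlation_mode `"residual_pearson"` (product-moment correlation of
#'   covariate-residualized volumes, the default) or `"full_partial"`
#'   (pairwise partial correlations from a shrinkage-regularized precision
#'   matrix of the residuals).
#' @param pooled_residualization if `TRUE`, covariates are regressed out once
#'   across all subjects instead of within each group.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sparsity_min = 0.05,
                       sparsity_max = 0.40,
                       sparsity_step = 0.01,
                       n_null_networks = 200L,
                       n_null_networks_perm = 50L,
                       n_permutations = 5000L,
                       rng_seed = 20221113L,
                       fdr_alpha = 0.05,
                       volumetry_alpha = 0.001,
                       covariates = c("age", "sex", "lesion_volume"),
                       correlation_mode = c("residual_pearson", "full_partial"),
                       pooled_residualization = FALSE) {
  correlation_mode <- match.arg(correlation_mode)
  stopifnot(
    sparsity_min > 0, sparsity_min < sparsity_max, sparsity_max < 1,
    sparsity_step > 0,
    n_null_networks >= 1, n_null_networks_perm >= 1, n_permutations >= 1,
    fdr_alpha > 0, fdr_alpha < 1, volumetry_alpha > 0, volumetry_alpha < 1
  )
  if (n_null_networks <= 150) {
    warning("n_null_networks should exceed 150 for stable gamma/lambda/sigma")
  }
  structure(list(
    sparsity_min = sparsity_min, sparsity_max = sparsity_max,
    sparsity_step = sparsity_step,
    n_null_networks = as.integer(n_null_networks),
    n_null_networks_perm = as.integer(n_null_networks_perm),
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed),
    fdr_alpha = fdr_alpha, volumetry_alpha = volumetry_alpha,
    covariates = covariates, correlation_mode = correlation_mode,
    pooled_residualization = pooled_residualization
  ), class = "run_config")
}

#' Read a configuration file
#'
#' Accepts a YAML or JSON file whose keys mirror the arguments of
#' [run_config()]; absent keys keep their defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(run_config, vals)
}

#' Derive a stage seed from the root seed
#'
#' Deterministically hashes the root seed together with arbitrary string/number
#' tags into an integer seed below 2^31, so every stage (group, density,
#' replicate, ...) gets its own reproducible stream.
#'
#' @param root integer root seed.
#' @param ... tags identifying the stage (coerced to character).
#' @return A single integer seed.
#' @export
derive_seed <- function(root, ...) {
  tag <- paste(c(as.character(root), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# round half away from zero (used for edge counts at a density)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
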