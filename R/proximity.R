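#' Dyadic proximity design from participant covariates
#'
#' One row per participant pair; for each selected covariate v the regressor
#' is the proximity \eqn{-|x_{v,i} - x_{v,j}|} (negative numerical distance:
#' 0 for identical scores, increasingly negative for dissimilar pairs).
#' Covariates are z-scored across participants before the distance is taken
#' (so 21-point attitude scales and composite scores are comparable); the
#' proximity columns themselves are left on that scale to keep their sign
#' interpretable. The proximity columns are invariant to adding a constant to
#' all scores of a covariate.
#'
#' @param covariates data.frame with `participant_id` and score columns.
#' @param pairs data.frame from [participant_pairs()] (columns i, j); row
#'   order must match the pair-map stack the design will be regressed on.
#' @param variables covariate column names to build proximities for.
#' @param standardize z-score covariates before the distance (default TRUE).
#' @param include_pair_means also add the pair-mean of each covariate.
#' @return object of class `proximity_design`: `X` (pairs x regressors matrix
#'   with an intercept column), `pairs`, `variables`, `scores` (the per
#'   participant, possibly standardized, score matrix used).
#' @export
build_proximity_design <- function(covariates, pairs, variables,
                                   standardize = TRUE,
                                   include_pair_means = FALSE) {
  if (!"participant_id" %in% names(covariates))
    stop("covariates must have a participant_id column")
  missing_vars <- setdiff(variables, names(covariates))
  if (length(missing_vars) > 0)
    stop("covariates missing columns: ", paste(missing_vars, collapse = ", "))
  all_ids <- unique(c(pairs$i, pairs$j))
  absent <- setdiff(all_ids, covariates$participant_id)
  if (length(absent) > 0)
    stop("participants missing from the covariate table: ",
         paste(absent, collapse = ", "))
  rows <- match(all_ids, covariates$participant_id)
  scores <- matrix(NA_real_, length(all_ids), length(variables),
                   dimnames = list(all_ids, variables))
  for (v in variables) {
    x <- covariates[[v]][rows]
    if (any(is.na(x)))
      stop("missing values in covariate ", v, " for participants: ",
           paste(all_ids[is.na(x)], collapse = ", "))
    if (sd(x) == 0)
      stop("covariate ", v, " has zero variance; its proximity column ",
           "would be all zeros")
    scores[, v] <- if (standardize) (x - mean(x)) / sd(x) else x
  }
  ii <- match(pairs$i, all_ids)
  jj <- match(pairs$j, all_ids)
  X <- matrix(1, nrow(pairs), 1, dimnames = list(NULL, "(intercept)"))
  for (v in variables)
    X <- cbind(X, setNames(data.frame(-abs(scores[ii, v] - scores[jj, v])),
                           paste0("proximity_", v)))
  if (include_pair_means)
    for (v in variables)
      X <- cbind(X, setNames(data.frame((scores[ii, v] + scores[jj, v]) / 2),
                             paste0("pairmean_", v)))
  X <- as.matrix(X)
  structure(list(X = X, pairs = pairs, variables = variables,
                 scores = scores, standardize = standardize,
                 include_pair_means = include_pair_means),
            class = "proximity_design")
}

#' @export
print.proximity_design <- function(x, ...) {
  cat(sprintf("Proximity design: %d pairs x %d regressors (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

# t map for a tested column against nuisance columns (partial regression):
# residualize response and tested regressor on the nuisance columns; the
# resulting simple-regression t with the full-model df equals the full-model
# t for that column.
partial_t <- function(ey, ex, df, ss_ref = NULL, t_cap = 1e6) {
  ssx <- sum(ex^2)
  if (ssx == 0) return(list(t = numeric(ncol(ey)), beta = numeric(ncol(ey))))
  num <- drop(crossprod(ex, ey))
  beta <- num / ssx
  rss <- colSums(ey^2) - num^2 / ssx
  s2 <- pmax(rss, 0) / df
  se <- sqrt(s2 / ssx)
  t <- ifelse(se > 0, beta / se, sign(beta) * t_cap)
  t[beta == 0 & se == 0] <- 0
  # voxels whose residualized response is numerically zero (e.g. a constant
  # map) are 0/0 degeneracies: report no effect rather than rounding noise
  if (!is.null(ss_ref)) t[colSums(ey^2) <= 1e-20 * (ss_ref + 1e-300)] <- 0
  list(t = pmin(pmax(t, -t_cap), t_cap), beta = beta)
}

# shared permutation engine for dyadic regression on a pairs x voxels response
dyadic_perm_test <- function(y, design, test_var, mask, params, n_perm, seed,
                             scheme = c("subject", "pair")) {
  scheme <- match.arg(scheme)
  col <- paste0("proximity_", test_var)
  if (!col %in% colnames(design$X)) stop("unknown regressor: ", test_var)
  j <- match(col, colnames(design$X))
  X <- design$X
  qx_full <- qr(X)
  if (qx_full$rank < ncol(X)) {
    dep <- colnames(X)[qx_full$pivot[(qx_full$rank + 1):ncol(X)]]
    stop("collinear proximity design; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  Z <- X[, -j, drop = FALSE]
  qz <- qr(Z)
  df <- nrow(X) - ncol(X)
  ey <- qr.resid(qz, y)                 # Freedman-Lane: response residualized
  ex_obs <- qr.resid(qz, X[, j])        # against the nuisance columns once
  voxel_ids <- which(mask != 0)
  dims <- dim(mask)

  ss_ref <- colSums(y^2)
  obs <- partial_t(ey, ex_obs, df, ss_ref)
  obs_tfce <- tfce_values(obs$t, dims, voxel_ids, params)

  ids <- rownames(design$scores)
  ii <- match(design$pairs$i, ids)
  jj <- match(design$pairs$j, ids)
  x_scores <- design$scores[, test_var]

  max_null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    if (scheme == "subject") {
      xs <- x_scores[sample.int(length(x_scores))]
      xcol <- -abs(xs[ii] - xs[jj])
    } else {
      xcol <- X[sample.int(nrow(X)), j]
    }
    ex <- qr.resid(qz, xcol)
    tmap <- partial_t(ey, ex, df, ss_ref)$t
    max_null[p] <- max(tfce_values(tmap, dims, voxel_ids, params))
  }
  p_fwe <- vapply(obs_tfce, function(o)
    (1 + sum(max_null >= o)) / (n_perm + 1), numeric(1))
  structure(list(contrast = setNames(1, col), name = col,
                 observed_stat = obs$t, observed_beta = obs$beta,
                 observed_tfce = obs_tfce, df = df, max_null = max_null,
                 p_fwe = p_fwe, p_fwe_across = NULL,
                 n_permutations = n_perm, seed = seed, exhaustive = FALSE,
                 scheme = scheme, tail_approximated = FALSE),
            class = "perm_result")
}

#' Regress ISC maps on covariate proximity with permutation inference
#'
#' Voxel-wise multiple regression of the baseline-subtracted, condition
#' averaged Fisher-z ISC maps on the dyadic proximity design. Each selected
#' regressor is tested with the other columns as nuisance covariates
#' (Freedman-Lane residualization). The default permutation scheme is
#' subject-level: the tested covariate's participant scores are permuted and
#' the pairwise proximities rebuilt, which respects the dependence between
#' pairs sharing a participant; `scheme = "pair"` permutes the dyadic values
#' directly (approximate, for sensitivity analysis). FWE control within a
#' regressor uses the max-TFCE null; `p_fwe_across` corrects over the tested
#' regressors of a condition via the per-permutation max across their nulls.
#'
#' @param pm a condition-level `pair_maps` object, baseline-subtracted (set
#'   `require_baseline = FALSE` to override).
#' @param design a [build_proximity_design()]; pair order must match `pm`.
#' @param mask 3D 0/1 array.
#' @param variables regressors to test (default: all design variables).
#' @param conditions condition labels to analyse (default: all in `pm`).
#' @param params a [tfce_params()].
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param scheme `"subject"` (default) or `"pair"`.
#' @param require_baseline error when `pm` is not baseline-subtracted.
#' @return nested list: per condition, per tested variable, a `perm_result`
#'   (with `observed_beta`, the proximity coefficient map).
#' @export
isc_proximity_regression <- function(pm, design, mask, variables = NULL,
                                     conditions = NULL,
                                     params = tfce_params(), n_perm = 1000,
                                     seed = 1,
                                     scheme = c("subject", "pair"),
                                     require_baseline = TRUE) {
  stopifnot(inherits(pm, "pair_maps"), pm$type == "condition",
            inherits(design, "proximity_design"))
  scheme <- match.arg(scheme)
  if (require_baseline && !pm$baseline_subtracted)
    stop("maps are not baseline-subtracted; subtract_baseline() first or ",
         "set require_baseline = FALSE")
  if (!identical(design$pairs$i, pm$pairs$i) ||
      !identical(design$pairs$j, pm$pairs$j))
    stop("design pair order does not match the pair-map stack")
  if (is.null(variables)) variables <- design$variables
  if (is.null(conditions)) conditions <- pm$scope$condition
  set.seed(as.integer(seed))
  out <- list()
  for (cond in conditions) {
    g <- match(cond, pm$scope$condition)
    if (is.na(g)) stop("condition not present in pair maps: ", cond)
    y <- t(pm$z[, , g])                  # pairs x voxels
    res <- list()
    for (v in variables) {
      res[[v]] <- dyadic_perm_test(y, design, v, mask, params, n_perm,
                                   seed, scheme)
    }
    # FWE across the tested regressors: max over their permutation nulls
    if (length(variables) > 1) {
      mx <- do.call(pmax, lapply(res, function(r) r$max_null))
      for (v in variables) {
        res[[v]]$p_fwe_across <- vapply(res[[v]]$observed_tfce, function(o)
          (1 + sum(mx >= o)) / (n_perm + 1), numeric(1))
      }
    }
    out[[cond]] <- res
  }
  out
}

#' Contrast proximity effects between conditions
#'
#' Per-voxel difference of the proximity coefficient between two conditions
#' (e.g. blame vs neutral), tested with the same dyadic permutation
#' machinery: the dependent variable is the per-pair difference of the two
#' conditions' Fisher-z maps, so the proximity coefficient on the difference
#' equals the between-condition coefficient difference. Swapping the
#' condition order negates the statistic maps.
#'
#' @inheritParams isc_proximity_regression
#' @param cond_a,cond_b condition labels; the effect reported is
#'   `cond_a - cond_b`.
#' @return per tested variable, a `perm_result` on the difference maps.
#' @export
condition_moderation <- function(pm, design, cond_a, cond_b, mask,
                                 variables = NULL, params = tfce_params(),
                                 n_perm = 1000, seed = 1,
                                 scheme = c("subject", "pair"),
                                 require_baseline = TRUE) {
  stopifnot(inherits(pm, "pair_maps"), pm$type == "condition")
  scheme <- match.arg(scheme)
  if (require_baseline && !pm$baseline_subtracted)
    stop("maps are not baseline-subtracted; subtract_baseline() first or ",
         "set require_baseline = FALSE")
  ga <- match(cond_a, pm$scope$condition)
  gb <- match(cond_b, pm$scope$condition)
  if (is.na(ga) || is.na(gb))
    stop("condition missing from pair maps: ",
         paste(c(cond_a, cond_b)[is.na(c(ga, gb))], collapse = ", "))
  if (is.null(variables)) variables <- design$variables
  set.seed(as.integer(seed))
  y <- t(pm$z[, , ga] - pm$z[, , gb])
  out <- list()
  for (v in variables)
    out[[v]] <- dyadic_perm_test(y, design, v, mask, params, n_perm, seed,
                                 scheme)
  out
}
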