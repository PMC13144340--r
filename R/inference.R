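#' Arrange condition-averaged pair maps as GLM samples
#'
#' Stacks the per-pair per-condition Fisher-z maps into a samples-by-voxels
#' response matrix with a condition label and an exchangeability block (the
#' participant pair) per sample. Samples are pair-major: all conditions of
#' pair 1, then pair 2, and so on, so every block has one sample per
#' condition.
#'
#' @param pm a condition-level `pair_maps` object.
#' @return list with `y` (samples x voxels), `condition` (factor),
#'   `block` (factor, one level per pair), `pairs`, `conditions`, `voxel_ids`.
#' @export
condition_samples <- function(pm) {
  stopifnot(inherits(pm, "pair_maps"), pm$type == "condition")
  v <- dim(pm$z)[1]; p <- dim(pm$z)[2]; g <- dim(pm$z)[3]
  y <- matrix(NA_real_, p * g, v)
  condition <- character(p * g)
  block <- integer(p * g)
  row <- 1L
  for (k in seq_len(p)) {
    for (c in seq_len(g)) {
      y[row, ] <- pm$z[, k, c]
      condition[row] <- pm$scope$condition[c]
      block[row] <- k
      row <- row + 1L
    }
  }
  list(y = y, condition = factor(condition, levels = pm$scope$condition),
       block = factor(block), pairs = pm$pairs,
       conditions = pm$scope$condition, voxel_ids = pm$voxel_ids)
}

# design matrix: one indicator per condition plus pair-mean regressors
# (block indicators, first dropped for identifiability)
condition_design <- function(condition, block) {
  cmat <- model.matrix(~ 0 + condition)
  colnames(cmat) <- levels(condition)
  bmat <- model.matrix(~ 0 + block)[, -1, drop = FALSE]
  colnames(bmat) <- paste0("pair", levels(block)[-1])
  list(cmat = cmat, bmat = bmat)
}

# voxel-wise OLS t for a contrast; X must be full rank
fit_contrast_t <- function(x, y, cvec, t_cap = 1e6) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dep <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  df <- nrow(x) - ncol(x)
  if (df < 1) stop("no residual degrees of freedom")
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  s2 <- colSums(res^2) / df
  vc <- drop(crossprod(cvec, chol2inv(chol(crossprod(x))) %*% cvec))
  num <- drop(crossprod(cvec, coefs))
  se <- sqrt(s2 * vc)
  t <- ifelse(se > 0, num / se, sign(num) * t_cap)
  t[num == 0 & se == 0] <- 0
  list(t = pmin(pmax(t, -t_cap), t_cap), df = df, effect = num)
}

#' Voxel-wise GLM t map for a condition contrast
#'
#' Ordinary least squares of the per-pair per-condition maps on condition
#' indicators plus pair-mean regressors (repeated-measures dependencies are
#' absorbed by the per-pair means, so with two conditions the t map is
#' algebraically the paired t-test). t = c'beta / se(c'beta), capped at 1e6
#' for zero-residual degeneracies.
#'
#' @param samples output of [condition_samples()].
#' @param contrast named numeric vector over (a subset of) condition levels,
#'   e.g. `c(neutral = 1, blame = -1)`.
#' @return list with `t` (per-voxel t map), `df`, `effect` (c'beta map).
#' @export
glm_contrast_stat <- function(samples, contrast) {
  des <- condition_design(samples$condition, samples$block)
  x <- cbind(des$cmat, des$bmat)
  lev <- levels(samples$condition)
  if (!all(names(contrast) %in% lev))
    stop("contrast names outside condition levels: ",
         paste(setdiff(names(contrast), lev), collapse = ", "))
  cvec <- c(setNames(rep(0, length(lev)), lev), rep(0, ncol(des$bmat)))
  cvec[names(contrast)] <- contrast
  fit_contrast_t(x, samples$y, cvec)
}

# distinct within-block relabelings (log scale, and per-block arrangements)
block_relabelings <- function(condition, block) {
  per_block <- lapply(split(seq_along(condition), block), function(idx) {
    labs <- as.character(condition[idx])
    n_b <- length(idx)
    perms <- all_permutations(n_b)
    keys <- apply(perms, 1, function(p) paste(labs[p], collapse = "\r"))
    list(idx = idx, perms = perms[!duplicated(keys), , drop = FALSE])
  })
  log_total <- sum(vapply(per_block, function(b) log(nrow(b$perms)),
                          numeric(1)))
  list(per_block = per_block, log_total = log_total)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# one random within-block relabeling: a permutation of sample indices that
# never crosses block boundaries
random_block_perm <- function(block) {
  idx <- seq_along(block)
  for (b in split(seq_along(block), block)) {
    idx[b] <- b[sample.int(length(b))]
  }
  idx
}

#' Block-restricted permutation test with TFCE and FWE correction
#'
#' For each contrast: computes the observed voxel-wise GLM t map and its TFCE
#' enhancement, then builds a null distribution by repeatedly relabeling the
#' condition labels independently within each participant-pair block
#' (exchangeability is only valid between samples of the same pair).
#' Family-wise error p-values use the max-TFCE statistic over the mask
#' (within-contrast) and over mask x contrasts (across-contrast):
#' p(v) = (1 + #\{perm max >= observed TFCE(v)\}) / (n_perm + 1), the
#' unpermuted labeling contributing the +1 as permutation 1. When fewer
#' distinct relabelings than `n_perm` exist, all of them are enumerated
#' (with a warning) and the p-values are exact.
#'
#' @param samples output of [condition_samples()].
#' @param mask 3D 0/1 array the maps live on.
#' @param contrasts named list of contrast vectors
#'   (see [glm_contrast_stat()]).
#' @param params a [tfce_params()].
#' @param n_perm number of permutations (>= 100 recommended; 1000 is the
#'   usual choice at study scale).
#' @param seed integer seed; identical seeds give identical results.
#' @param keep_perm_log record every permutation (as sample index vectors) for
#'   exchangeability audits.
#' @return object of class `perm_result_set`: list of `perm_result` per
#'   contrast (observed_stat, observed_tfce, max_null, p_fwe, p_fwe_across,
#'   n_permutations, seed, exhaustive, tail_approximated), plus `perm_log`
#'   (n_perm x n_samples matrix or NULL) and `block`.
#' @export
permute_and_correct <- function(samples, mask, contrasts,
                                params = tfce_params(), n_perm = 1000,
                                seed = 1, keep_perm_log = FALSE) {
  stopifnot(is.list(contrasts), length(contrasts) >= 1)
  if (is.null(names(contrasts)) || any(names(contrasts) == ""))
    names(contrasts) <- vapply(contrasts, function(cv)
      paste0(names(cv)[cv > 0][1], ">", names(cv)[cv < 0][1]), "")
  set.seed(as.integer(seed))
  voxel_ids <- which(mask != 0)
  dims <- dim(mask)
  condition <- samples$condition
  block <- samples$block
  des <- condition_design(condition, block)
  lev <- levels(condition)
  cvecs <- lapply(contrasts, function(cv) {
    if (!all(names(cv) %in% lev))
      stop("contrast names outside condition levels")
    out <- c(setNames(rep(0, length(lev)), lev), rep(0, ncol(des$bmat)))
    out[names(cv)] <- cv
    out
  })

  observed <- lapply(cvecs, function(cvec)
    fit_contrast_t(cbind(des$cmat, des$bmat), samples$y, cvec))
  obs_tfce <- lapply(observed, function(o)
    tfce_values(o$t, dims, voxel_ids, params))

  rel <- block_relabelings(condition, block)
  exhaustive <- is.finite(rel$log_total) && rel$log_total <= log(n_perm)
  if (exhaustive) {
    warning(sprintf(paste0("only %d distinct within-block relabelings ",
                           "(< n_perm = %d); enumerating exhaustively"),
                    round(exp(rel$log_total)), n_perm))
    grid_sizes <- vapply(rel$per_block, function(b) nrow(b$perms), integer(1))
    combos <- expand.grid(lapply(grid_sizes, seq_len))
    perm_idx <- t(apply(combos, 1, function(row) {
      idx <- seq_along(condition)
      for (bi in seq_along(rel$per_block)) {
        b <- rel$per_block[[bi]]
        idx[b$idx] <- b$idx[b$perms[row[bi], ]]
      }
      idx
    }))
  } else {
    perm_idx <- t(vapply(seq_len(n_perm), function(p) random_block_perm(block),
                         integer(length(block))))
  }
  n_used <- nrow(perm_idx)

  n_con <- length(contrasts)
  max_null <- matrix(NA_real_, n_used, n_con,
                     dimnames = list(NULL, names(contrasts)))
  for (p in seq_len(n_used)) {
    idx <- perm_idx[p, ]
    x <- cbind(des$cmat[idx, , drop = FALSE], des$bmat)
    for (ci in seq_len(n_con)) {
      tmap <- fit_contrast_t(x, samples$y, cvecs[[ci]])$t
      max_null[p, ci] <- max(tfce_values(tmap, dims, voxel_ids, params))
    }
  }
  max_across <- apply(max_null, 1, max)

  results <- vector("list", n_con)
  names(results) <- names(contrasts)
  for (ci in seq_len(n_con)) {
    obs <- obs_tfce[[ci]]
    if (exhaustive) {
      p_fwe <- vapply(obs, function(o) mean(max_null[, ci] >= o), numeric(1))
      p_across <- vapply(obs, function(o) mean(max_across >= o), numeric(1))
    } else {
      p_fwe <- vapply(obs, function(o)
        (1 + sum(max_null[, ci] >= o)) / (n_used + 1), numeric(1))
      p_across <- vapply(obs, function(o)
        (1 + sum(max_across >= o)) / (n_used + 1), numeric(1))
    }
    results[[ci]] <- structure(
      list(contrast = contrasts[[ci]], name = names(contrasts)[ci],
           observed_stat = observed[[ci]]$t, observed_tfce = obs,
           df = observed[[ci]]$df, max_null = max_null[, ci],
           p_fwe = p_fwe, p_fwe_across = p_across,
           n_permutations = n_used, seed = seed, exhaustive = exhaustive,
           tail_approximated = FALSE),
      class = "perm_result")
  }
  structure(list(results = results,
                 perm_log = if (keep_perm_log) perm_idx else NULL,
                 block = block, n_permutations = n_used, seed = seed,
                 exhaustive = exhaustive),
            class = "perm_result_set")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation result '%s': %d voxels, %d permutations%s\n",
              x$name, length(x$observed_stat), x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  max |t| %.2f, max TFCE %.3g, min FWE p %.4g, %d voxels with p <= 0.05\n",
              max(abs(x$observed_stat)), max(x$observed_tfce),
              min(x$p_fwe), sum(x$p_fwe <= 0.05)))
  invisible(x)
}

#' @export
print.perm_result_set <- function(x, ...) {
  cat(sprintf("Permutation test: %d contrasts, %d permutations, seed %d\n",
              length(x$results), x$n_permutations, x$seed))
  for (r in x$results) print(r)
  invisible(x)
}

#' Audit a permutation log against exchangeability blocks
#'
#' Counts samples that any logged permutation moved across a block boundary;
#' a valid block-restricted scheme yields zero.
#'
#' @param perm_log permutations x samples matrix of sample indices.
#' @param block block factor/vector, one entry per sample.
#' @return integer count of violations.
#' @export
check_exchangeability <- function(perm_log, block) {
  block <- as.integer(factor(block))
  sum(vapply(seq_len(nrow(perm_log)), function(p)
    sum(block[perm_log[p, ]] != block), integer(1)))
}

# ---- generalized Pareto tail refinement ------------------------------------

gpd_nll <- function(par, x) {
  sigma <- exp(par[1]); xi <- par[2]
  n <- length(x)
  if (abs(xi) < 1e-8) return(n * log(sigma) + sum(x) / sigma)
  z <- 1 + xi * x / sigma
  if (any(z <= 0)) return(Inf)
  n * log(sigma) + (1 + 1 / xi) * sum(log(z))
}

fit_gpd <- function(x) {
  m <- mean(x); v <- var(x)
  xi0 <- 0.5 * (1 - m^2 / v)
  xi0 <- min(max(xi0, -0.4), 0.4)
  s0 <- max(m * (1 - xi0), 1e-8)
  init <- c(log(s0), xi0)
  # a negative-shape moment init can violate the support constraint
  if (!is.finite(gpd_nll(init, x))) init <- c(log(m), 0.1)
  fit <- try(optim(init, gpd_nll, x = x, method = "Nelder-Mead",
                   control = list(maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(sigma = m, xi = 0, converged = FALSE))
  list(sigma = exp(fit$par[1]), xi = fit$par[2],
       converged = fit$convergence == 0)
}

gpd_survival <- function(q, sigma, xi) {
  q <- pmax(q, 0)
  if (abs(xi) < 1e-8) return(exp(-q / sigma))
  pmax(1 + xi * q / sigma, 0)^(-1 / xi)
}

gpd_quantile_fn <- function(u, sigma, xi) {
  if (abs(xi) < 1e-8) -sigma * log(1 - u) else sigma / xi * ((1 - u)^(-xi) - 1)
}

gpd_ad_stat <- function(x, sigma, xi) {
  n <- length(x)
  z <- sort(1 - gpd_survival(sort(x), sigma, xi))
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  -n - mean((2 * seq_len(n) - 1) * (log(z) + log(1 - rev(z))))
}

# parametric-bootstrap Anderson-Darling screen for the GPD fit
gpd_gof_ok <- function(x, fit, n_boot = 199, alpha = 0.05) {
  a_obs <- gpd_ad_stat(x, fit$sigma, fit$xi)
  a_boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xb <- gpd_quantile_fn(runif(length(x)), fit$sigma, fit$xi)
    fb <- fit_gpd(xb)
    a_boot[b] <- if (fb$converged) gpd_ad_stat(xb, fb$sigma, fb$xi) else Inf
  }
  p <- (1 + sum(a_boot >= a_obs)) / (n_boot + 1)
  p >= alpha
}

#' Tail-approximated permutation p-value via the generalized Pareto family
#'
#' Refines small permutation p-values below the resolution of the null
#' sample: when the empirical p is at most `p_threshold` (the P < .10
#' activation rule), a generalized Pareto distribution is fitted by maximum
#' likelihood to the null exceedances above the 90th percentile and the
#' refined p is the tail probability times the GPD survival at the observed
#' statistic. Falls back to the empirical p when the gate is not met, the
#' null sample is too small, the null is degenerate, or the fit fails a
#' parametric-bootstrap Anderson-Darling screen.
#'
#' @param observed observed statistic (scalar).
#' @param null permutation null values.
#' @param p_threshold activation gate on the empirical p (default 0.10).
#' @param min_null minimum null sample size for fitting (default 60).
#' @param seed seed for the bootstrap screen.
#' @return refined p-value; attribute `tail_approximated` says whether the
#'   GPD refinement was applied, attribute `empirical` holds the unrefined p.
#' @export
gpd_tail_pvalue <- function(observed, null, p_threshold = 0.10, min_null = 60,
                            seed = 1) {
  stopifnot(length(observed) == 1, is.numeric(null))
  n <- length(null)
  emp <- (1 + sum(null >= observed)) / (n + 1)
  done <- function(p, tail) {
    attr(p, "tail_approximated") <- tail
    attr(p, "empirical") <- emp
    p
  }
  if (emp > p_threshold || n < min_null) return(done(emp, FALSE))
  if (var(null) == 0) {
    warning("degenerate null tail; returning empirical p")
    return(done(emp, FALSE))
  }
  set.seed(as.integer(seed))
  # fit at the 90th percentile; if the fit fails the screen, raise the
  # threshold and retry with fewer exceedances before giving up
  for (q in c(0.90, 0.925, 0.95)) {
    u <- unname(quantile(null, q, type = 7))
    exceed <- null[null > u] - u
    if (length(exceed) < 10 || var(exceed) == 0) next
    fit <- fit_gpd(exceed)
    if (!fit$converged || !gpd_gof_ok(exceed, fit)) next
    p_tail <- length(exceed) / n
    refined <- p_tail * gpd_survival(observed - u, fit$sigma, fit$xi)
    return(done(max(refined, 0), TRUE))
  }
  warning("generalized Pareto fit failed the goodness-of-fit screen at all ",
          "thresholds; returning empirical p")
  done(emp, FALSE)
}
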