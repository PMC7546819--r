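#' Hyperparameter grid for model selection
#'
#' The full reference lattice is `n_top` = 50..6400 by near-doublings,
#' `alpha` = 0..1 in steps of 0.01 and `lambda` = \eqn{2^{-10}..2^{10}} in
#' powers of 2. Reduced lattices are obtained by passing shorter vectors.
#' For paired-tissue models `n_top` is a list of per-tissue feature budgets
#' (e.g. `list(c(600, 50), c(600, 100))`).
#'
#' @param n_top integer vector of preselection sizes, or a list of integer
#'   vectors (one budget per feature group) for paired models.
#' @param alpha mixing parameters in `[0, 1]`.
#' @param lambda penalty strengths, all > 0.
#' @return A `ParamGrid` object.
#' @export
param_grid <- function(n_top = default_n_grid(),
                       alpha = seq(0, 1, by = 0.01),
                       lambda = 2^seq(-10, 10)) {
  if (!is.list(n_top)) n_top <- as.list(as.integer(n_top))
  n_top <- lapply(n_top, as.integer)
  if (!length(n_top) || !length(alpha) || !length(lambda)) {
    stop("all three grids must be non-empty")
  }
  if (any(vapply(n_top, function(v) any(v < 1L), logical(1)))) {
    stop("n_top entries must be positive")
  }
  if (any(alpha < 0 | alpha > 1)) stop("alpha values must lie in [0, 1]")
  if (any(lambda <= 0)) stop("lambda values must be > 0")
  structure(list(n_top = n_top, alpha = as.numeric(alpha),
                 lambda = as.numeric(lambda)),
            class = "ParamGrid")
}

#' Split samples into k cross-validation folds
#'
#' Produces a random partition of `1:n_samples` into `k` folds whose sizes
#' differ by at most one, deterministically for a given seed. The global RNG
#' state is left untouched.
#'
#' @param n_samples number of samples, >= `k`.
#' @param k number of folds, >= 2.
#' @param seed integer seed controlling the permutation.
#' @return List of `k` integer index vectors partitioning `1:n_samples`.
#' @export
kfold_split <- function(n_samples, k = 10, seed = 1) {
  if (k < 2L) stop("'k' must be at least 2")
  if (n_samples < k) stop("cannot make ", k, " folds from ", n_samples, " samples")
  perm <- with_seed(seed, sample.int(n_samples))
  sizes <- rep(n_samples %/% k, k) + c(rep(1L, n_samples %% k),
                                       rep(0L, k - n_samples %% k))
  unname(split(perm, rep(seq_len(k), times = sizes)))
}

# Evaluate an expression while the RNG is seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Workhorse shared by cv_evaluate / grid_search: repeated k-fold CV with
# fold-internal gene reranking, evaluated jointly over all grid cells.
#
# x: samples x genes matrix over ALL candidate genes (log2 scale);
# groups: optional per-column feature-group factor (tissue of origin) whose
# levels align with the per-group budgets in grid$n_top entries.
# Returns a data.frame of cells with mean validation RMSE / PCC.
cv_grid_eval <- function(x, ages, grid, k = 10, repeats = 100, base_seed = 1,
                         groups = NULL, cv_scheme = c("repeated", "bootstrap"),
                         tol = 1e-5, maxit = 1e5) {
  cv_scheme <- match.arg(cv_scheme)
  stopifnot(inherits(grid, "ParamGrid"))
  n <- nrow(x)
  if (length(ages) != n) stop("'ages' must align with rows of 'x'")
  # canonical internal ordering so results do not depend on input row order
  if (!is.null(rownames(x))) {
    ord <- order(rownames(x), method = "radix")
    x <- x[ord, , drop = FALSE]
    ages <- ages[ord]
  }
  if (is.null(groups)) groups <- factor(rep("all", ncol(x)))
  groups <- as.factor(groups)
  glev <- levels(groups)
  gidx <- lapply(glev, function(g) which(groups == g))
  for (nt in grid$n_top) {
    if (length(nt) != length(glev)) {
      stop("each n_top budget must have one entry per feature group (",
           length(glev), ")")
    }
  }
  gene_names <- colnames(x)
  if (is.null(gene_names)) gene_names <- paste0("feature", seq_len(ncol(x)))

  cells <- expand.grid(n_idx = seq_along(grid$n_top),
                       alpha = grid$alpha, lambda = grid$lambda,
                       KEEP.OUT.ATTRS = FALSE)
  sum_rmse <- numeric(nrow(cells))
  sum_pcc <- numeric(nrow(cells))
  n_pcc <- integer(nrow(cells))
  n_eval <- 0L

  for (r in seq_len(repeats)) {
    seed_r <- base_seed + r
    if (cv_scheme == "repeated") {
      folds <- kfold_split(n, k, seed = seed_r)
    } else {
      train <- with_seed(seed_r, sample.int(n, n, replace = TRUE))
      folds <- list(setdiff(seq_len(n), unique(train)))
      attr(folds, "train") <- train
    }
    for (f in seq_along(folds)) {
      val_idx <- folds[[f]]
      train_idx <- if (cv_scheme == "repeated") {
        setdiff(seq_len(n), val_idx)
      } else {
        attr(folds, "train")
      }
      if (length(train_idx) < 3L) {
        stop("fold with fewer than 3 training samples")
      }
      # fold-internal reranking: correlations on training samples only
      rr <- correlate_with_age(x[train_idx, , drop = FALSE], ages[train_idx])
      keyed <- -abs(rr)
      keyed[is.na(keyed)] <- Inf      # degenerate genes rank last, never chosen
      sel_by_group <- lapply(gidx, function(ix) {
        ix[order(keyed[ix], gene_names[ix], method = "radix")]
      })
      n_n <- length(grid$n_top)
      n_a <- length(grid$alpha)
      truth <- ages[val_idx]
      for (ni in seq_len(n_n)) {
        budget <- grid$n_top[[ni]]
        sel <- unlist(lapply(seq_along(sel_by_group), function(g) {
          utils::head(sel_by_group[[g]], budget[g])
        }), use.names = FALSE)
        xt <- x[train_idx, sel, drop = FALSE]
        xv <- x[val_idx, sel, drop = FALSE]
        fitcache <- prepare_enet(xt, ages[train_idx])
        for (ai in seq_len(n_a)) {
          fits <- solve_enet_path(fitcache, grid$alpha[ai], grid$lambda,
                                  tol = tol, maxit = maxit)
          for (li in seq_along(grid$lambda)) {
            # expand.grid cell order: n_idx fastest, then alpha, then lambda
            ci <- ni + n_n * ((ai - 1L) + n_a * (li - 1L))
            fit <- fits[[li]]
            pred <- fit$intercept + as.vector(xv %*% fit$w)
            sum_rmse[ci] <- sum_rmse[ci] + rmse(truth, pred)
            p <- if (length(truth) >= 3L && stats::sd(truth) > 0 &&
                     stats::sd(pred) > 0) {
              stats::cor(truth, pred)
            } else NA_real_
            if (!is.na(p)) {
              sum_pcc[ci] <- sum_pcc[ci] + p
              n_pcc[ci] <- n_pcc[ci] + 1L
            }
          }
        }
      }
      n_eval <- n_eval + 1L
    }
  }
  data.frame(
    n_label = vapply(grid$n_top[cells$n_idx], paste, character(1), collapse = "+"),
    n_total = vapply(grid$n_top[cells$n_idx], sum, integer(1)),
    n_idx = cells$n_idx,
    alpha = cells$alpha, lambda = cells$lambda,
    mean_rmse = sum_rmse / n_eval,
    mean_pcc = ifelse(n_pcc > 0L, sum_pcc / n_pcc, NA_real_),
    stringsAsFactors = FALSE)
}

# Precompute centered/scaled design for repeated solves on the same fold.
# Returned as an environment so the thin SVD (used by exact ridge solves)
# is computed lazily, once.
prepare_enet <- function(x, y) {
  xm <- colMeans(x)
  ym <- mean(y)
  xc_raw <- sweep(x, 2L, xm, "-")
  s <- sqrt(colMeans(xc_raw^2))
  s[s == 0] <- 1
  cache <- new.env(parent = emptyenv())
  cache$xc <- sweep(xc_raw, 2L, s, "/")
  cache$xc_raw <- xc_raw
  cache$yc <- y - ym
  cache$xm <- xm
  cache$ym <- ym
  cache$s <- s
  cache$svd <- NULL
  cache
}

# Exact ridge (alpha = 0) for every lambda at once via the thin SVD of the
# centered raw-scale design: w(lambda) = V diag(d/(d^2 + lambda/2)) U'y.
solve_ridge_path <- function(cache, lambdas) {
  if (is.null(cache$svd)) {
    cache$svd <- svd(cache$xc_raw)
    cache$uty <- crossprod(cache$svd$u, cache$yc)
  }
  sv <- cache$svd
  lapply(lambdas, function(lam) {
    w <- as.vector(sv$v %*% (sv$d / (sv$d^2 + lam / 2) * cache$uty))
    list(w = w, intercept = cache$ym - sum(cache$xm * w), converged = TRUE)
  })
}

# Warm-started coordinate-descent solves over a lambda grid (internally
# descending) for one alpha; results returned in the order of `lambdas`.
solve_enet_path <- function(cache, alpha, lambdas, tol = 1e-7, maxit = 1e5) {
  if (alpha == 0) return(solve_ridge_path(cache, lambdas))
  p <- length(cache$s)
  ord <- order(lambdas, decreasing = TRUE)
  w <- numeric(p)
  out <- vector("list", length(lambdas))
  for (i in ord) {
    lam <- lambdas[i]
    l1 <- rep(lam * alpha, p) / cache$s
    q <- rep(lam * (1 - alpha), p) / cache$s^2
    fit <- enet_cd(cache$xc, cache$yc, l1, q, tol, as.integer(maxit), w)
    w <- as.numeric(fit$coefficients)
    w_raw <- w / cache$s
    out[[i]] <- list(w = w_raw,
                     intercept = cache$ym - sum(cache$xm * w_raw),
                     converged = fit$converged)
  }
  out
}

#' Cross-validate one hyperparameter combination
#'
#' Runs `repeats` re-randomized `k`-fold cross-validations. Within every
#' fold the gene ranking is recomputed on the training samples only
#' (fold-internal reranking), the top `n_top` genes are taken, the elastic
#' net is fitted on the training folds and evaluated on the held-out fold;
#' RMSE and PCC are averaged over all repeats and folds. No information from
#' a validation fold influences its fold's ranking or fit.
#'
#' @param x samples-by-genes log2 expression matrix over all candidate genes.
#' @param ages aligned response vector (years).
#' @param n_top number of top-ranked genes (or per-group budget vector when
#'   `groups` is given).
#' @param alpha,lambda elastic-net parameters.
#' @param k folds (default 10).
#' @param repeats number of re-randomized CV rounds (default 100).
#' @param base_seed master seed; repeat `r` uses `base_seed + r`.
#' @param groups optional per-feature tissue factor for paired models.
#' @param cv_scheme `"repeated"` (re-randomized splits, the reference
#'   behaviour) or `"bootstrap"` (resample training sets with replacement,
#'   validate out-of-bag).
#' @param solver_tol convergence tolerance used for the fold fits; the
#'   default 1e-5 is looser than [fit_elastic_net()]'s 1e-7 because the
#'   averaged validation metrics are insensitive at that level, and ridge
#'   cells (`alpha = 0`) are solved exactly regardless.
#' @return List with `mean_rmse` and `mean_pcc`.
#' @export
cv_evaluate <- function(x, ages, n_top, alpha, lambda, k = 10, repeats = 100,
                        base_seed = 1, groups = NULL,
                        cv_scheme = c("repeated", "bootstrap"),
                        solver_tol = 1e-5) {
  grid <- param_grid(n_top = list(as.integer(n_top)), alpha = alpha,
                     lambda = lambda)
  res <- cv_grid_eval(x, ages, grid, k = k, repeats = repeats,
                      base_seed = base_seed, groups = groups,
                      cv_scheme = match.arg(cv_scheme), tol = solver_tol)
  list(mean_rmse = res$mean_rmse[1L], mean_pcc = res$mean_pcc[1L])
}

#' Grid search over (N, alpha, lambda) by repeated cross-validation
#'
#' Evaluates every combination in `grid` with [cv_evaluate()]'s protocol
#' (jointly, sharing fold rankings across cells for speed), picks the
#' combination with the lowest mean validation RMSE, and refits the final
#' model on the full dataset with fold-free ranking at the chosen
#' parameters. Ties are broken towards the smallest total N, then the
#' largest lambda, then the largest alpha (the sparsest, most regularized
#' model).
#'
#' @inheritParams cv_evaluate
#' @param grid a [param_grid()].
#' @param refine_alpha after the grid pass, re-search alpha at step 0.01 in
#'   a +/-0.25 window around the winner (chosen N and lambda held fixed).
#' @return A `CVResult`: list with `cells` (per-combination data frame),
#'   `best` (the chosen row), `final_model` (an `AgeModel`), and the run
#'   parameters.
#' @export
grid_search <- function(x, ages, grid, k = 10, repeats = 100, base_seed = 1,
                        groups = NULL, cv_scheme = c("repeated", "bootstrap"),
                        refine_alpha = FALSE, solver_tol = 1e-5) {
  cv_scheme <- match.arg(cv_scheme)
  cells <- cv_grid_eval(x, ages, grid, k = k, repeats = repeats,
                        base_seed = base_seed, groups = groups,
                        cv_scheme = cv_scheme, tol = solver_tol)
  best <- pick_best_cell(cells)
  if (refine_alpha) {
    alphas <- seq(max(0, best$alpha - 0.25), min(1, best$alpha + 0.25), by = 0.01)
    alphas <- setdiff(round(alphas, 10), cells$alpha[cells$n_idx == best$n_idx &
                                                     cells$lambda == best$lambda])
    if (length(alphas)) {
      grid2 <- param_grid(n_top = grid$n_top[best$n_idx], alpha = alphas,
                          lambda = best$lambda)
      extra <- cv_grid_eval(x, ages, grid2, k = k, repeats = repeats,
                            base_seed = base_seed, groups = groups,
                            cv_scheme = cv_scheme, tol = solver_tol)
      extra$n_idx <- best$n_idx
      cells <- rbind(cells, extra)
      best <- pick_best_cell(cells)
    }
  }
  final_model <- refit_full(x, ages, groups,
                            budget = grid$n_top[[best$n_idx]],
                            alpha = best$alpha, lambda = best$lambda)
  structure(list(cells = cells, best = best, final_model = final_model,
                 k = k, repeats = repeats, base_seed = base_seed,
                 cv_scheme = cv_scheme),
            class = "CVResult")
}

pick_best_cell <- function(cells) {
  ord <- order(cells$mean_rmse, cells$n_total, -cells$lambda, -cells$alpha,
               method = "radix")
  cells[ord[1L], , drop = FALSE]
}

# Fold-free final refit: rank on all samples, take the per-group budget,
# fit at the chosen penalty.
refit_full <- function(x, ages, groups, budget, alpha, lambda) {
  if (is.null(groups)) groups <- factor(rep("all", ncol(x)))
  groups <- as.factor(groups)
  gene_names <- colnames(x)
  rr <- correlate_with_age(x, ages)
  keyed <- -abs(rr)
  keyed[is.na(keyed)] <- Inf
  sel <- unlist(lapply(seq_along(levels(groups)), function(g) {
    ix <- which(groups == levels(groups)[g])
    utils::head(ix[order(keyed[ix], gene_names[ix], method = "radix")], budget[g])
  }), use.names = FALSE)
  tissue_tags <- if (nlevels(groups) > 1L) as.character(groups[sel]) else NULL
  fit_elastic_net(x[, sel, drop = FALSE], ages, alpha = alpha, lambda = lambda,
                  tissue = tissue_tags)
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf(
    "CVResult: %d grid cells, %d x %d-fold CV (scheme: %s)\nbest: N = %s, alpha = %s, lambda = %s, mean RMSE = %.3f years, mean PCC = %.3f\n",
    nrow(x$cells), x$repeats, x$k, x$cv_scheme,
    x$best$n_label, format(x$best$alpha), format(x$best$lambda),
    x$best$mean_rmse, x$best$mean_pcc))
  invisible(x)
}

#' Export a cross-validation grid as TSV
#'
#' One row per grid cell: N (per-group budgets joined by `+`), alpha,
#' lambda, mean validation RMSE (2 decimals) and PCC.
#'
#' @param cv a `CVResult` from [grid_search()].
#' @param path output file.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "CVResult"))
  df <- data.frame(N = cv$cells$n_label, alpha = cv$cells$alpha,
                   lambda = cv$cells$lambda,
                   mean_rmse = sprintf("%.2f", cv$cells$mean_rmse),
                   mean_pcc = sprintf("%.4f", cv$cells$mean_pcc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
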