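#' Search space for the combined model/preprocessing optimization
#'
#' Bounds of the joint search over LSBoost hyperparameters and the
#' subject-wise standardizer: `n` in \[1, 500\], `rho` in \[0.01, 1\],
#' `leaf_min` and `max_splits` in \[1, 100\], standardizer in
#' \{zscore, minmax, median, none\}.
#'
#' @param max_evaluations Evaluation budget (default 100).
#' @param seed Integer seed for the optimizer.
#' @param n,rho,leaf_min,max_splits Numeric `c(lo, hi)` bounds.
#' @param standardizers Candidate standardization methods.
#' @return A `search_space` list.
#' @export
search_space <- function(max_evaluations = 100, seed = 1,
                         n = c(1, 500), rho = c(0.01, 1),
                         leaf_min = c(1, 100), max_splits = c(1, 100),
                         standardizers = c("zscore", "minmax", "median", "none")) {
  stopifnot(max_evaluations >= 1, length(standardizers) >= 1)
  for (b in list(n, rho, leaf_min, max_splits))
    stopifnot(length(b) == 2, b[1] <= b[2])
  stopifnot(n[1] > 0, rho[1] > 0, leaf_min[1] > 0)   # log-scale dimensions
  structure(list(max_evaluations = as.integer(max_evaluations),
                 seed = as.integer(seed),
                 bounds = list(n = n, rho = rho, leaf_min = leaf_min,
                               max_splits = max_splits),
                 standardizers = standardizers),
            class = "search_space")
}

# decode a unit-cube point (4 numeric dims + category index) to a config.
# n, rho and leaf_min are searched on log scale (the standard measure for
# ensemble sizes, learning rates and leaf sizes, whose useful values span
# orders of magnitude); max_splits stays linear.
decode_point <- function(u, cat_idx, space) {
  b <- space$bounds
  logmap <- function(u1, bb) exp(log(bb[1]) + u1 * (log(bb[2]) - log(bb[1])))
  list(n = as.integer(round(logmap(u[1], b$n))),
       rho = logmap(u[2], b$rho),
       leaf_min = as.integer(round(logmap(u[3], b$leaf_min))),
       max_splits = as.integer(round(b$max_splits[1] + u[4] * (b$max_splits[2] - b$max_splits[1]))),
       standardizer = space$standardizers[cat_idx])
}

# encode for the surrogate: 4 unit-scaled numerics + one-hot standardizer
encode_config <- function(cfg, space) {
  b <- space$bounds
  unit <- function(v, bb) if (bb[2] > bb[1]) (v - bb[1]) / (bb[2] - bb[1]) else 0.5
  logunit <- function(v, bb) if (bb[2] > bb[1])
    (log(v) - log(bb[1])) / (log(bb[2]) - log(bb[1])) else 0.5
  onehot <- as.numeric(space$standardizers == cfg$standardizer)
  c(logunit(cfg$n, b$n), logunit(cfg$rho, b$rho), logunit(cfg$leaf_min, b$leaf_min),
    unit(cfg$max_splits, b$max_splits), onehot)
}

# Gaussian-process posterior (squared-exponential kernel, length-scale by
# small marginal-likelihood grid) at candidate points
gp_posterior <- function(Xe, z, Xc) {
  d2 <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    outer(an, bn, "+") - 2 * A %*% t(B)
  }
  D <- pmax(d2(Xe, Xe), 0)
  s2 <- stats::var(z)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1
  best <- NULL
  for (ell in c(0.25, 0.5, 1, 2) * sqrt(ncol(Xe))) {
    K <- s2 * exp(-0.5 * D / ell^2) + diag(1e-6 * s2 + 1e-10, nrow(Xe))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), z))
    ll <- -0.5 * sum(z * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll) best <- list(ell = ell, ch = ch, alpha = alpha, ll = ll)
  }
  if (is.null(best)) return(NULL)
  Kc <- s2 * exp(-0.5 * pmax(d2(Xc, Xe), 0) / best$ell^2)
  mu <- as.numeric(Kc %*% best$alpha)
  v <- forwardsolve(t(best$ch), t(Kc))
  var <- pmax(s2 - colSums(v^2), 1e-12)
  list(mu = mu, sd = sqrt(var))
}

#' Bayesian optimization of the LSBoost + standardizer configuration
#'
#' Sequential model-based optimization of the cross-validated MAE: the first
#' 10 configurations are a quasi-random Latin-hypercube design over the
#' mixed space; afterwards a Gaussian-process surrogate (squared-exponential
#' kernel on the unit-scaled hyperparameters with the standardizer one-hot
#' encoded) is fit to the observed objectives and the expected-improvement
#' acquisition is maximized over a random candidate set. Failed evaluations
#' (for example a leaf size infeasible for the fold size) are recorded as
#' failed trials, imputed at the worst observed objective for the surrogate,
#' and the search continues. Deterministic given `space$seed`.
#'
#' @param table A [feature_table()].
#' @param attribute Target attribute.
#' @param space A [search_space()].
#' @param n_candidates Random acquisition candidates per iteration
#'   (default 256).
#' @return List with `best` (`hp`, `standardizer`, `objective`, `cv`) and
#'   `log` (one row per trial: configuration, objective, status).
#' @export
bayes_optimize <- function(table, attribute, space, n_candidates = 256) {
  stopifnot(inherits(space, "search_space"))
  evaluate <- function(cfg, eval_id) {
    res <- tryCatch(
      cv_mae(list(type = "lsboost",
                  hp = lsboost_hp(cfg$n, cfg$rho, cfg$leaf_min, cfg$max_splits)),
             table, attribute, standardizer = cfg$standardizer,
             seed = derive_seed(space$seed, "eval", eval_id)),
      error = function(e) e)
    if (inherits(res, "error"))
      list(objective = NA_real_, status = conditionMessage(res), cv = NULL)
    else list(objective = res$objective, status = "ok", cv = res)
  }

  with_seed(space$seed, {
    n_eval <- space$max_evaluations
    n_init <- min(10L, n_eval)
    ncat <- length(space$standardizers)
    init <- lhs::randomLHS(n_init, 5)
    configs <- vector("list", n_eval)
    results <- vector("list", n_eval)
    enc <- matrix(NA_real_, n_eval, 4 + ncat)
    for (i in seq_len(n_init)) {
      cfg <- decode_point(init[i, 1:4], pmin(ncat, ceiling(init[i, 5] * ncat)), space)
      configs[[i]] <- cfg
      enc[i, ] <- encode_config(cfg, space)
      results[[i]] <- evaluate(cfg, i)
    }
    i <- n_init
    while (i < n_eval) {
      i <- i + 1
      obj <- vapply(results[seq_len(i - 1)], `[[`, numeric(1), "objective")
      if (all(is.na(obj))) {            # nothing informative yet: random point
        u <- stats::runif(4); ci <- sample.int(ncat, 1)
        cfg <- decode_point(u, ci, space)
      } else {
        worst <- max(obj, na.rm = TRUE)
        z <- ifelse(is.na(obj), worst, obj)
        zs <- (z - mean(z)) / max(stats::sd(z), 1e-12)
        # candidates: global uniform draws plus a local cloud around the
        # incumbent (exploration + exploitation, SMAC-style)
        n_local <- n_candidates %/% 4
        Uc <- matrix(stats::runif((n_candidates - n_local) * 4), ncol = 4)
        cat_c <- sample.int(ncat, n_candidates - n_local, replace = TRUE)
        inc <- which.min(z)
        inc_u <- enc[inc, 1:4]
        inc_cat <- which(enc[inc, 4 + seq_len(ncat)] == 1)[1]
        Ul <- matrix(pmin(pmax(rep(inc_u, each = n_local) +
                                 stats::rnorm(n_local * 4, 0, 0.15), 0), 1),
                     ncol = 4)
        cat_l <- ifelse(stats::runif(n_local) < 0.5, inc_cat,
                        sample.int(ncat, n_local, replace = TRUE))
        Uc <- rbind(Uc, Ul)
        cat_c <- c(cat_c, cat_l)
        cand_cfg <- lapply(seq_len(n_candidates),
                           function(k) decode_point(Uc[k, ], cat_c[k], space))
        Xc <- t(vapply(cand_cfg, encode_config, numeric(4 + ncat), space))
        post <- gp_posterior(enc[seq_len(i - 1), , drop = FALSE], zs, Xc)
        if (is.null(post)) {
          cfg <- cand_cfg[[1]]
        } else {
          fmin <- min(zs)
          u <- (fmin - post$mu) / post$sd
          ei <- post$sd * (u * stats::pnorm(u) + stats::dnorm(u))
          cfg <- cand_cfg[[which.max(ei)]]
        }
      }
      configs[[i]] <- cfg
      enc[i, ] <- encode_config(cfg, space)
      results[[i]] <- evaluate(cfg, i)
    }

    log_df <- do.call(rbind, lapply(seq_len(n_eval), function(k) {
      cfg <- configs[[k]]
      data.frame(eval = k, n = cfg$n, rho = cfg$rho, leaf_min = cfg$leaf_min,
                 max_splits = cfg$max_splits, standardizer = cfg$standardizer,
                 objective = results[[k]]$objective,
                 status = results[[k]]$status, stringsAsFactors = FALSE)
    }))
    ok <- which(!is.na(log_df$objective))
    if (!length(ok)) stop("every optimization trial failed")
    best_i <- ok[which.min(log_df$objective[ok])]
    best_cfg <- configs[[best_i]]
    list(best = list(hp = lsboost_hp(best_cfg$n, best_cfg$rho,
                                     best_cfg$leaf_min, best_cfg$max_splits),
                     standardizer = best_cfg$standardizer,
                     objective = log_df$objective[best_i],
                     cv = results[[best_i]]$cv),
         log = log_df)
  })
}
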