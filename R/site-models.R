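# Site-class codon models M0/M1a/M2a/M3/M7/M8: parameterization, maximum
# likelihood fitting with multi-start bounded quasi-Newton, likelihood-ratio
# tests, and NEB per-site posteriors.

SITE_MODELS <- c("M0", "M1a", "M2a", "M3", "M7", "M8")

# Free parameters per model (natural scale), with their transforms.
# Proportions of >2-class mixtures use stick-breaking in logit space.
model_parameters <- function(model, K = 10) {
  switch(model,
    M0  = list(omega = list(init = 0.3, trans = "log")),
    M1a = list(p0 = list(init = 0.7, trans = "logit"),
               omega0 = list(init = 0.2, trans = "logit")),
    M2a = list(p0 = list(init = 0.7, trans = "logit"),
               v1 = list(init = 0.8, trans = "logit"),  # p1 = (1-p0) v1
               omega0 = list(init = 0.2, trans = "logit"),
               omega2 = list(init = 2.0, trans = "log1p_shift")),
    M3  = list(p0 = list(init = 0.4, trans = "logit"),
               v1 = list(init = 0.6, trans = "logit"),
               omega0 = list(init = 0.05, trans = "log"),
               omega1 = list(init = 0.3, trans = "log"),
               omega2 = list(init = 1.2, trans = "log")),
    M7  = list(beta_p = list(init = 0.8, trans = "log"),
               beta_q = list(init = 2.0, trans = "log")),
    M8  = list(p0 = list(init = 0.9, trans = "logit"),
               beta_p = list(init = 0.8, trans = "log"),
               beta_q = list(init = 2.0, trans = "log"),
               omega_s = list(init = 1.5, trans = "log1p_shift")),
    stop("unknown model: ", model)
  )
}

.to_unconstrained <- function(value, trans) {
  switch(trans,
    log = log(value),
    logit = stats::qlogis(pmin(pmax(value, 1e-9), 1 - 1e-9)),
    log1p_shift = log(pmax(value - 1, 1e-12))  # omega >= 1, boundary allowed
  )
}

.to_natural <- function(x, trans) {
  switch(trans,
    log = exp(pmin(pmax(x, -25), 8)),
    logit = stats::plogis(pmin(pmax(x, -25), 25)),
    log1p_shift = 1 + exp(pmin(pmax(x, -30), 6))
  )
}

#' Site-class mixture of a fitted or hypothesized model
#'
#' Expands model parameters into the discrete `(proportion, omega)` mixture
#' used by [codon_log_likelihood()]. M7/M8 beta classes use
#' [discretize_beta()] with K equal-probability categories.
#'
#' @param model One of `"M0","M1a","M2a","M3","M7","M8"`.
#' @param params Named list of natural-scale parameters (see
#'   [fit_codon_model()] for names).
#' @param K Number of beta discretization categories (M7/M8).
#' @return Data frame with columns `proportion` and `omega`.
#' @export
site_class_mixture <- function(model, params, K = 10) {
  p <- params
  out <- switch(model,
    M0  = data.frame(proportion = 1, omega = p$omega),
    M1a = data.frame(proportion = c(p$p0, 1 - p$p0),
                     omega = c(p$omega0, 1)),
    M2a = {
      p1 <- (1 - p$p0) * p$v1
      data.frame(proportion = c(p$p0, p1, 1 - p$p0 - p1),
                 omega = c(p$omega0, 1, p$omega2))
    },
    M3  = {
      p1 <- (1 - p$p0) * p$v1
      data.frame(proportion = c(p$p0, p1, 1 - p$p0 - p1),
                 omega = c(p$omega0, p$omega1, p$omega2))
    },
    M7  = data.frame(proportion = rep(1 / K, K),
                     omega = discretize_beta(p$beta_p, p$beta_q, K)),
    M8  = data.frame(proportion = c(rep(p$p0 / K, K), 1 - p$p0),
                     omega = c(discretize_beta(p$beta_p, p$beta_q, K),
                               p$omega_s)),
    stop("unknown model: ", model)
  )
  out$positive <- out$omega > 1
  out
}

#' Fit a codon site model by maximum likelihood
#'
#' Maximizes the GY94 mixture log-likelihood over the model's omega-class
#' parameters, the transition/transversion ratio kappa, and (optionally) a
#' single global branch-length scale factor, using bounded quasi-Newton
#' (L-BFGS-B) on transformed parameters from multiple documented starting
#' points. Naive empirical Bayes (NEB) per-column class posteriors are
#' computed at the optimum by plugging in the fitted parameters.
#'
#' @param aln A `codon_alignment`.
#' @param tree `ape::phylo` tree with branch lengths; tips = alignment taxa.
#' @param model One of `"M0","M1a","M2a","M3","M7","M8"`.
#' @param K Beta discretization categories for M7/M8 (default 10).
#' @param pi Sense-codon frequencies; default `"F3x4"` estimates them from
#'   the alignment, or pass a numeric vector / `"uniform"`.
#' @param kappa_init Initial kappa.
#' @param optimize_scale Optimize a global branch-length scale? Default TRUE.
#' @param n_starts Number of optimizer starts (first from defaults, the rest
#'   jittered deterministically; default 3).
#' @param start Optional named list of natural-scale starting parameters
#'   (may include `kappa`, `scale`); used as an additional start.
#' @param jitter_seed Seed for the start jitter (default 1).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param code Genetic code.
#' @return Object of class `codon_fit`: `model`, `params` (named list),
#'   `kappa`, `scale`, `lnL`, `classes` (mixture with `positive` flag),
#'   `site_posteriors` (columns x classes NEB matrix), `converged`,
#'   `n_eval`, `K`, `pi`.
#' @export
fit_codon_model <- function(aln, tree, model = "M0", K = 10, pi = "F3x4",
                            kappa_init = 2, optimize_scale = TRUE,
                            n_starts = 3, start = NULL, jitter_seed = 1,
                            maxit = 300, code = standard_genetic_code()) {
  model <- match.arg(model, SITE_MODELS)
  ctx <- likelihood_context(aln, tree, pi, code)
  pi <- ctx$pi
  spec <- model_parameters(model, K)
  pnames <- names(spec)
  trans <- vapply(spec, function(s) s$trans, "")
  init_nat <- lapply(spec, function(s) s$init)

  all_names <- c(pnames, "kappa", if (optimize_scale) "scale")
  all_trans <- c(trans, kappa = "log",
                 if (optimize_scale) c(scale = "log"))
  base_start <- c(init_nat, list(kappa = kappa_init),
                  if (optimize_scale) list(scale = 1))

  pack <- function(nat) {
    vapply(all_names, function(nm) .to_unconstrained(nat[[nm]],
                                                     all_trans[[nm]]), 0)
  }
  unpack <- function(x) {
    stats::setNames(lapply(seq_along(all_names), function(i) {
      .to_natural(unname(x[i]), all_trans[[i]])
    }), all_names)
  }

  n_eval <- 0L
  objective <- function(x) {
    nat <- unpack(x)
    classes <- site_class_mixture(model, nat, K)
    sc <- if (optimize_scale) nat$scale else 1
    n_eval <<- n_eval + 1L
    val <- tryCatch(
      -context_loglik(ctx, classes, kappa = nat$kappa, scale = sc)$lnL,
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  starts <- list(pack(base_start))
  if (n_starts > 1) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(jitter_seed)
    jit <- lapply(seq_len(n_starts - 1), function(i) {
      starts[[1]] + stats::rnorm(length(all_names), sd = 0.6)
    })
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else {
      rm(".Random.seed", envir = globalenv())
    }
    starts <- c(starts, jit)
  }
  if (!is.null(start)) {
    st <- base_start
    st[names(start)] <- start
    starts <- c(list(pack(st)), starts)
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B",
                   lower = rep(-25, length(s)), upper = rep(25, length(s)),
                   control = list(maxit = maxit, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")

  nat <- unpack(best$par)
  classes <- site_class_mixture(model, nat, K)
  sc <- if (optimize_scale) nat$scale else 1
  ll <- context_loglik(ctx, classes, kappa = nat$kappa, scale = sc)

  # NEB: posterior_k(col) = prop_k L_k(col) / sum_j prop_j L_j(col)
  sl <- ll$site_loglik
  m <- apply(sl, 1L, max)
  w <- exp(sl - m) * rep(classes$proportion, each = nrow(sl))
  post_pat <- w / rowSums(w)
  post <- post_pat[ll$map, , drop = FALSE]

  params <- nat[pnames]
  structure(list(model = model, params = params, kappa = nat$kappa,
                 scale = sc, lnL = ll$lnL, classes = classes,
                 site_posteriors = post,
                 converged = best$convergence == 0L,
                 convergence_info = best$message, n_eval = n_eval,
                 K = K, pi = pi, n_free = length(all_names)),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("codon_fit %s: lnL = %.3f, kappa = %.3f, scale = %.3f%s\n",
              x$model, x$lnL, x$kappa, x$scale,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  cat("  classes:\n")
  print(round(x$classes[c("proportion", "omega")], 4))
  invisible(x)
}

#' Likelihood-ratio test between nested codon model fits
#'
#' @param null_fit,alt_fit `codon_fit` objects (null nested in alternative),
#'   or bare log-likelihood numbers.
#' @param df Degrees of freedom; inferred from the difference in free
#'   parameter counts when both arguments are fits.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `lrt_result`: `statistic` (`max(0, 2 dlnL)`),
#'   `df`, `p_value`, `critical_value`, `significant`.
#' @export
#' @examples
#' lrt(-22007.790, -22005.004, df = 2)  # statistic 5.573 is not significant
lrt <- function(null_fit, alt_fit, df = NULL, alpha = 0.05) {
  ln0 <- if (inherits(null_fit, "codon_fit")) null_fit$lnL else null_fit
  ln1 <- if (inherits(alt_fit, "codon_fit")) alt_fit$lnL else alt_fit
  if (is.null(df)) {
    if (!inherits(null_fit, "codon_fit") || !inherits(alt_fit, "codon_fit")) {
      stop("df must be given when fits are not codon_fit objects")
    }
    df <- alt_fit$n_free - null_fit$n_free
  }
  if (df < 1) stop("df must be >= 1")
  delta <- ln1 - ln0
  if (delta < -1e-6) {
    stop("alternative log-likelihood below null by ", format(-delta),
         "; optimization failure upstream")
  }
  statistic <- max(0, 2 * delta)
  crit <- stats::qchisq(1 - alpha, df)
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 critical_value = crit, alpha = alpha,
                 significant = statistic > crit),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "LRT: 2dlnL = %.3f, df = %d, p = %.4g (critical %.3f at alpha %g): %s\n",
    x$statistic, x$df, x$p_value, x$critical_value, x$alpha,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Fit a nested site-model pair and test for positive selection
#'
#' Fits the null model, then the alternative initialized at the null optimum
#' (guaranteeing `lnL(alt) >= lnL(null)` up to optimizer tolerance) plus the
#' usual multi-starts, and runs the LRT.
#'
#' @inheritParams fit_codon_model
#' @param null,alt Model ids; defaults `"M7"` vs `"M8"` (df = 2).
#' @param alpha LRT significance level.
#' @param ... Passed to [fit_codon_model()].
#' @return List with `null_fit`, `alt_fit`, `lrt`.
#' @export
compare_site_models <- function(aln, tree, null = "M7", alt = "M8", K = 10,
                                alpha = 0.05, ...) {
  null_fit <- fit_codon_model(aln, tree, model = null, K = K, ...)
  alt_start <- nested_start(null, alt, null_fit)
  alt_fit <- fit_codon_model(aln, tree, model = alt, K = K,
                             start = alt_start, ...)
  df <- alt_fit$n_free - null_fit$n_free
  list(null_fit = null_fit, alt_fit = alt_fit,
       lrt = lrt(null_fit, alt_fit, df = df, alpha = alpha))
}

# Natural-scale starting parameters that make `alt` numerically equivalent
# to the fitted null model.
nested_start <- function(null, alt, null_fit) {
  p <- null_fit$params
  base <- list(kappa = null_fit$kappa, scale = null_fit$scale)
  extra <- switch(paste(null, alt, sep = "->"),
    "M7->M8" = list(p0 = 1 - 1e-9, beta_p = p$beta_p, beta_q = p$beta_q,
                    omega_s = 1 + 1e-9),
    "M1a->M2a" = list(p0 = p$p0, v1 = 1 - 1e-9, omega0 = p$omega0,
                      omega2 = 1 + 1e-9),
    "M0->M3" = list(p0 = 1 - 1e-9, v1 = 0.5,
                    omega0 = max(p$omega, 1e-6),
                    omega1 = max(p$omega, 1e-6),
                    omega2 = max(p$omega, 1e-6)),
    stop("no nested start mapping for ", null, " -> ", alt)
  )
  c(extra, base)
}

#' NEB positively selected sites
#'
#' Returns the alignment columns whose naive-empirical-Bayes posterior
#' probability of belonging to an omega > 1 class meets the threshold, with
#' fitted parameters plugged in. Models without a positive class return an
#' empty result with an explanatory attribute.
#'
#' @param fit A `codon_fit`.
#' @param positive_threshold Posterior threshold (default 0.95).
#' @return Data frame `site` (1-based column), `posterior`, `mean_omega`
#'   (posterior-weighted class omega); attribute `"note"` explains empty
#'   results for models lacking a positive class.
#' @export
neb_positive_sites <- function(fit, positive_threshold = 0.95) {
  stopifnot(inherits(fit, "codon_fit"))
  pos <- fit$classes$positive
  mean_omega <- as.vector(fit$site_posteriors %*% fit$classes$omega)
  if (!any(pos)) {
    out <- data.frame(site = integer(0), posterior = numeric(0),
                      mean_omega = numeric(0))
    attr(out, "note") <- paste0("model ", fit$model,
                                " has no class with omega > 1")
    return(out)
  }
  p_pos <- rowSums(fit$site_posteriors[, pos, drop = FALSE])
  keep <- which(p_pos >= positive_threshold)
  data.frame(site = keep, posterior = p_pos[keep],
             mean_omega = mean_omega[keep])
}

#' Tabulate site-model fits
#'
#' Mirrors the usual reporting layout: one row per fitted model with its
#' log-likelihood, parameter estimates and positively selected sites.
#'
#' @param fits List of `codon_fit` objects.
#' @param positive_threshold NEB posterior threshold.
#' @return Data frame with columns `model`, `lnL`, `kappa`, `parameters`,
#'   `positive_sites`.
#' @export
site_model_table <- function(fits, positive_threshold = 0.95) {
  rows <- lapply(fits, function(f) {
    sites <- neb_positive_sites(f, positive_threshold)$site
    data.frame(
      model = f$model, lnL = f$lnL, kappa = f$kappa,
      parameters = paste(sprintf("%s=%.4g", names(f$params),
                                 unlist(f$params)), collapse = "; "),
      positive_sites = paste(sites, collapse = ","))
  })
  do.call(rbind, rows)
}
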