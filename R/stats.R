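#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with 1 degree of freedom, with Yates continuity
#' correction by default — e.g. for group membership versus first-inspected
#' pattern type in the unrewarded learning test.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = first-inspected pattern type).
#' @param continuity_correction apply Yates correction (default TRUE).
#' @return List with `statistic`, `df` (= 1) and `p.value`.
#' @export
chi2_2x2 <- function(table, continuity_correction = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(abs(table - round(table)) < 1e-9))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- sum(table)
  num <- abs(a * d - b * c)
  if (continuity_correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / (sum(table[1, ]) * sum(table[2, ]) *
                         sum(table[, 1]) * sum(table[, 2]))
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# midranks of absolute values and the tie-correction term sum(t^3 - t)
.midranks <- function(x) {
  r <- rank(x, ties.method = "average")
  t <- table(x)
  list(ranks = r, tie_term = sum(t^3 - t))
}

#' Wilcoxon signed-rank test against a null value
#'
#' One-sample signed-rank test of symmetric location, reported as a signed
#' z statistic (normal approximation with midrank tie correction and a 0.5
#' continuity correction); positive z means values above the null. An
#' exact mode enumerates all 2^n sign assignments for small samples and is
#' used as the test oracle for the approximation.
#'
#' @param values numeric sample (e.g. per-bee proportions correct).
#' @param null hypothesised centre (default 0.5, chance level).
#' @param exact enumerate the exact permutation distribution (n <= 20).
#' @return List with `z`, `p.value` (two-sided), `n` (after dropping values
#'   equal to the null) and `W` (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(values, null = 0.5, exact = FALSE) {
  d <- values[!is.na(values)] - null
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all values equal the null")
  if (!exact && n < 5) stop("normal approximation needs n >= 5")
  mr <- .midranks(abs(d))
  W <- sum(mr$ranks[d > 0])
  mu <- n * (n + 1) / 4
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - mr$tie_term / 48)
  z <- if (sig == 0) 0 else (W - mu - 0.5 * sign(W - mu)) / sig
  if (exact) {
    if (n > 20) stop("exact enumeration limited to n <= 20")
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% mr$ranks)
    p <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p.value = p, n = n, W = W)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test reported as a signed z statistic (normal
#' approximation, midrank ties, 0.5 continuity correction); positive z
#' means sample `a` ranks higher. The exact mode enumerates all
#' `choose(na + nb, na)` allocations of the observed ranks.
#'
#' @param a,b numeric samples.
#' @param exact enumerate the exact distribution (total n <= 16).
#' @return List with `z`, `p.value` (two-sided), `W` (rank sum of `a`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both samples must be nonempty")
  pooled <- c(a, b)
  mr <- .midranks(pooled)
  W <- sum(mr$ranks[seq_len(na)])
  N <- na + nb
  mu <- na * (N + 1) / 2
  sig2 <- na * nb / 12 * ((N + 1) - mr$tie_term / (N * (N - 1)))
  sig <- sqrt(max(0, sig2))
  z <- if (sig == 0) 0 else (W - mu - 0.5 * sign(W - mu)) / sig
  if (exact) {
    if (N > 16) stop("exact enumeration limited to n <= 16")
    combos <- utils::combn(N, na)
    Wall <- colSums(matrix(mr$ranks[combos], nrow = na))
    p <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
  } else {
    p <- if (sig == 0) 1 else 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p.value = p, W = W)
}

#' Binomial GLMM for block-wise learning performance
#'
#' Fits the learning-curve model: the number of correct choices per
#' 10-choice block, binomial with logit link, fixed effects colony, group
#' and block index (trials), and a per-bee random intercept (Laplace
#' approximation via \pkg{lme4}). Confidence intervals are Wald.
#'
#' @param choices choice records ([simulate_learning_choices()] format) or
#'   pre-aggregated blocks with columns `bee`, `colony`, `group`, `block`,
#'   `k` (correct count) and `size`.
#' @param block_size choices per block when aggregating raw records.
#' @param conf_level confidence level for the Wald intervals.
#' @return Object of class `glmm_fit`: list with `coefficients` (term,
#'   estimate, se, tstat, df, p, ci_lo, ci_hi), `ranef_var` (bee intercept
#'   variance), `logLik`, `deviance`, `AIC`, `BIC`, `dropped` (fixed
#'   factors inestimable because they are constant), and the underlying
#'   `model`.
#' @export
fit_binomial_glmm <- function(choices, block_size = 10, conf_level = 0.95) {
  if (!"k" %in% names(choices)) {
    agg <- stats::aggregate(correct ~ bee + colony + group + block,
                            data = choices,
                            FUN = function(x) c(k = sum(x), size = length(x)))
    blocks <- data.frame(agg[, c("bee", "colony", "group", "block")],
                         k = agg$correct[, "k"], size = agg$correct[, "size"])
  } else blocks <- choices
  if (any(blocks$k < 0 | blocks$k > blocks$size |
            blocks$k != round(blocks$k)))
    stop("correct counts must be integers within the block size")
  if (length(unique(blocks$bee)) < 2) stop("at least 2 bees are required")
  if (min(table(blocks$bee)) < 2) stop("each bee needs at least 2 blocks")

  blocks$colony <- factor(blocks$colony)
  blocks$group <- factor(blocks$group)
  terms <- c("colony", "group")
  dropped <- terms[vapply(terms, function(t) nlevels(blocks[[t]]) < 2,
                          logical(1))]
  rhs <- c(setdiff(terms, dropped), "block")
  form <- stats::as.formula(paste("cbind(k, size - k) ~",
                                  paste(rhs, collapse = " + "), "+ (1 | bee)"))
  fit <- lme4::glmer(form, data = blocks, family = stats::binomial())
  sm <- summary(fit)$coefficients
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], tstat = sm[, "z value"],
                   df = nrow(blocks) - nrow(sm),
                   p = sm[, "Pr(>|z|)"],
                   ci_lo = sm[, "Estimate"] - zc * sm[, "Std. Error"],
                   ci_hi = sm[, "Estimate"] + zc * sm[, "Std. Error"],
                   row.names = NULL)
  structure(list(coefficients = co,
                 ranef_var = unname(lme4::VarCorr(fit)$bee[1, 1]),
                 logLik = as.numeric(stats::logLik(fit)),
                 deviance = stats::deviance(fit),
                 AIC = stats::AIC(fit), BIC = stats::BIC(fit),
                 dropped = dropped, model = fit),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial GLMM (logit link, random intercept per bee)\n")
  print(x$coefficients, digits = 3)
  cat(sprintf("bee intercept variance: %.3f | logLik %.2f AIC %.2f BIC %.2f\n",
              x$ranef_var, x$logLik, x$AIC, x$BIC))
  if (length(x$dropped))
    cat("inestimable (constant) factors dropped:",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Two-component Gaussian mixture fit for body-yaw angles
#'
#' EM fit of a two-component Gaussian mixture on the linear angle scale,
#' as used to summarise body-yaw distributions during inspection and
#' traverse flight. Initialisation is deterministic at plus/minus the
#' median absolute angle, plus a small number of seeded random restarts;
#' the best log-likelihood wins. Components are reported positive-mean
#' first (`mu[1] > mu[2]`).
#'
#' @param angles yaw angles in degrees, within `(-180, 180]`.
#' @param k number of components (only 2 supported).
#' @param seed seed for the random restarts.
#' @param n_restarts number of random restarts beyond the deterministic one.
#' @param max_iter,tol EM stopping rule.
#' @return Object of class `mixture_fit`: list with `mu`, `sd`, `weight`,
#'   `logLik`, `converged`, `loglik_trace` (of the winning run), `n`.
#' @export
fit_yaw_mixture <- function(angles, k = 2, seed = 1L, n_restarts = 5,
                            max_iter = 500, tol = 1e-8) {
  if (k != 2) stop("only k = 2 is supported")
  x <- angles[is.finite(angles)]
  if (length(x) < 50) stop("at least 50 angles are required")
  if (any(x <= -180 | x > 180)) stop("angles must lie in (-180, 180]")
  if (stats::var(x) == 0) stop("zero-variance sample")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  m0 <- stats::median(abs(x))
  inits <- c(list(c(m0, -m0)),
             lapply(seq_len(n_restarts), function(i)
               sort(sample(x, 2), decreasing = TRUE)))
  best <- NULL
  for (init in inits) {
    fit <- .em_gmm2(x, init, max_iter, tol)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  ord <- order(best$mu, decreasing = TRUE)
  structure(list(mu = best$mu[ord], sd = best$sd[ord],
                 weight = best$weight[ord], logLik = best$logLik,
                 converged = best$converged,
                 loglik_trace = best$trace, n = length(x)),
            class = "mixture_fit")
}

.em_gmm2 <- function(x, mu, max_iter, tol) {
  n <- length(x)
  sd_ <- rep(max(stats::sd(x) / 2, 1e-2), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd_[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break   # empty component
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sd_ <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                  sum((1 - g1) * (x - mu[2])^2) / n2))
    sd_ <- pmax(sd_, 1e-3)
  }
  list(mu = mu, sd = sd_, weight = w, logLik = trace[length(trace)],
       converged = converged, trace = trace)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "2-component Gaussian mixture (n = %d): mu = %+.1f / %+.1f deg, sd = %.1f / %.1f, w = %.2f / %.2f, logLik = %.1f%s\n",
    x$n, x$mu[1], x$mu[2], x$sd[1], x$sd[2], x$weight[1], x$weight[2],
    x$logLik, if (x$converged) "" else " (not converged)"))
  invisible(x)
}
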