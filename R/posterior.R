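#' Highest density interval of a sample
#'
#' Shortest contiguous window over the sorted sample containing
#' `ceiling(mass * n)` points; on ties the leftmost minimal window is
#' returned (deterministic).
#'
#' @param samples numeric vector, `n >= 2`.
#' @param mass probability mass `0 < mass < 1`.
#' @return numeric `c(lo, hi)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  n <- length(samples)
  stopifnot(n >= 2, mass > 0, mass < 1)
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)               # leftmost minimal window
  c(lo = x[i], hi = x[i + m - 1])
}

#' Summarise posterior tip ages from sampled trees
#'
#' Extracts each tip's age from every post-burn-in tree sample (tip age =
#' root age - root-to-tip path length; each sample is anchored by treating
#' its youngest tip as extant, age 0) and reports the per-tip posterior
#' median with the highest density interval at mass `mass`.
#'
#' @param trees list/`multiPhylo` of sampled trees with time-scaled branch
#'   lengths, or a list of `time_tree`s.
#' @param burnin fraction of initial samples to discard (default 0.1).
#' @param mass HDI mass (default 0.95).
#' @return data.frame: `tip`, `median`, `hdi_lo`, `hdi_hi`.
#' @export
parse_tip_ages <- function(trees, burnin = 0.1, mass = 0.95) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n <- length(trees)
  drop <- floor(burnin * n)
  trees <- trees[(drop + 1):n]
  if (length(trees) < 2) stop("need >= 2 post-burn-in samples")
  labs <- sort(trees[[1]]$tip.label)
  ages <- vapply(trees, function(phy) {
    if (!setequal(phy$tip.label, labs))
      stop("inconsistent tip sets across samples")
    if (inherits(phy, "time_tree")) return(tip_ages(phy)[labs])
    depth <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
    a <- max(depth) - depth
    names(a) <- phy$tip.label
    a[labs]
  }, numeric(length(labs)))
  h <- apply(ages, 1, hdi, mass = mass)
  data.frame(tip = labs,
             median = apply(ages, 1, stats::median),
             hdi_lo = h[1, ], hdi_hi = h[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-tip substitution rates implied by a non-clock tree
#'
#' For each tip, rate = (root-to-tip path length in substitutions/site) /
#' (root_age - tip_age), in substitutions/site/Ma. These rates feed the
#' clock-rate prior derivation.
#'
#' @param nonclock `phylo` with branch lengths in substitutions per site.
#' @param tip_ages named numeric tip ages (Ma); missing tips are extant.
#' @param root_age root age estimate (Ma), greater than every tip age.
#' @return named numeric vector of rates.
#' @export
implied_rates <- function(nonclock, tip_ages = NULL, root_age) {
  ages <- stats::setNames(rep(0, length(nonclock$tip.label)),
                          nonclock$tip.label)
  if (!is.null(tip_ages)) ages[names(tip_ages)] <- tip_ages
  span <- root_age - ages
  if (any(span <= 0)) stop("root_age must exceed every tip age")
  depth <- ape::node.depth.edgelength(nonclock)[seq_along(nonclock$tip.label)]
  stats::setNames(depth / span, nonclock$tip.label)
}

#' Derive a clock-rate prior by BIC model selection
#'
#' Maximum-likelihood fits of candidate distribution families to the implied
#' per-tip rates (via [fitdistrplus::fitdist]), ranked by
#' `BIC = k ln(n) - 2 lnL`; the family with the lowest BIC is selected.
#' Lognormal parameters are reported as mean and sd of the log rate, the
#' scale on which tip-dating software takes the prior.
#'
#' @param rates positive rates (n >= 4).
#' @param families candidate families among `"lognormal"`, `"gamma"`,
#'   `"exponential"`, `"normal"`.
#' @return object of class `clockrate_prior`: list with `fits` (data.frame:
#'   family, parameters, log_likelihood, n_par, bic) and `selected`
#'   (family, parameter vector).
#' @export
fit_clockrate_prior <- function(rates,
                                families = c("lognormal", "gamma",
                                             "exponential", "normal")) {
  stopifnot(length(rates) >= 4, all(rates > 0))
  if (stats::sd(rates) == 0) stop("degenerate zero-variance rates")
  dist_of <- c(lognormal = "lnorm", gamma = "gamma",
               exponential = "exp", normal = "norm")
  families <- match.arg(families, names(dist_of), several.ok = TRUE)
  n <- length(rates)
  rows <- list(); pars <- list()
  for (fam in families) {
    fit <- fitdistrplus::fitdist(as.numeric(rates), dist_of[[fam]],
                                 method = "mle")
    k <- length(fit$estimate)
    rows[[fam]] <- data.frame(family = fam,
                              log_likelihood = fit$loglik, n_par = k,
                              bic = k * log(n) - 2 * fit$loglik,
                              stringsAsFactors = FALSE)
    pars[[fam]] <- fit$estimate
  }
  fits <- do.call(rbind, rows)
  sel <- fits$family[which.min(fits$bic)]
  out <- list(fits = fits,
              selected = list(family = sel, parameters = pars[[sel]]),
              parameters = pars)
  class(out) <- "clockrate_prior"
  out
}

#' @export
print.clockrate_prior <- function(x, ...) {
  cat("Clock-rate prior: selected", x$selected$family, "(",
      paste(sprintf("%s = %.6f", names(x$selected$parameters),
                    x$selected$parameters), collapse = ", "), ")\n")
  print(x$fits[order(x$fits$bic), c("family", "log_likelihood", "bic")],
        row.names = FALSE)
  invisible(x)
}

#' Natural-log Bayes factor between two models
#'
#' `ln BF = lnL_a - lnL_b` from marginal log-likelihoods, with the usual
#' interpretive band on the ln-odds scale: > 5 "decisive" (odds >> 100:1),
#' > 3.9 "very strong" (odds > 50:1), > 3 "strong", > 1 "positive",
#' otherwise "weak".
#'
#' @param lnl_a,lnl_b marginal log-likelihoods (finite).
#' @return list with `ln_bf` and `evidence` label.
#' @export
ln_bayes_factor <- function(lnl_a, lnl_b) {
  stopifnot(is.finite(lnl_a), is.finite(lnl_b))
  bf <- lnl_a - lnl_b
  band <- function(x) {
    ax <- abs(x)
    if (ax > log(150)) "decisive"
    else if (ax > log(50)) "very strong"
    else if (ax > log(20)) "strong"
    else if (ax > log(3)) "positive"
    else "weak"
  }
  list(ln_bf = bf, evidence = band(bf))
}
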