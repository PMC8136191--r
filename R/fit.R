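#' Maximum-likelihood branch-class codon model fits and LRTs
#'
#' Three nested models mirror the classic codeml branch analysis:
#' `M0` (one omega for the whole tree), `b_free` (separate foreground
#' and background omegas) and `b_neut` (foreground omega fixed at 1,
#' background free).  In all models kappa and a global branch-length
#' scale are estimated, codon frequencies are fixed at their F3x4
#' estimates, and optimisation runs on log-transformed parameters with
#' two deterministic starts (omega 0.2 and 1.5), keeping the better.
#'
#' @name codon_model_ml
NULL

#' Fit a branch-class codon model
#'
#' @param aln A `codon_alignment`.
#' @param ltree A `labeled_tree`.
#' @param model `"M0"`, `"b_free"` or `"b_neut"`.
#' @param code A `genetic_code`.
#' @param codon_freqs Optional codon frequencies (default F3x4 from the
#'   alignment).
#' @param starts Omega start values for the multi-start (default
#'   `c(0.2, 1.5)`).
#' @return A `model_fit`: list with `model`, `lnL`, `kappa`, `omega_fg`,
#'   `omega_bg`, `scale`, `status` (`"ok"`, `"boundary"` or
#'   `"no_convergence"`), `n_free_params`, `n_sites`.
#' @export
fit_model <- function(aln, ltree, model = c("M0", "b_free", "b_neut"),
                      code = load_genetic_code(), codon_freqs = NULL,
                      starts = c(0.2, 1.5)) {
  model <- match.arg(model)
  struct <- codon_model_structure(code)
  if (is.null(codon_freqs)) codon_freqs <- f3x4_frequencies(aln, code)
  patterns <- compress_patterns(aln, ltree$phylo$tip.label, struct$codons)
  has_fg <- any(ltree$branch_class == "foreground")
  if (model != "M0" && !has_fg) stop("no foreground branches for ", model)

  par_omega <- function(theta) {
    # theta: log kappa, [log omega...], log scale
    switch(model,
      M0 = c(foreground = exp(theta[2]), background = exp(theta[2])),
      b_free = c(foreground = exp(theta[2]), background = exp(theta[3])),
      b_neut = c(foreground = 1, background = exp(theta[2])))
  }
  nll <- function(theta) {
    params <- list(kappa = exp(theta[1]), omega_by_class = par_omega(theta),
                   codon_freqs = codon_freqs, scale = exp(theta[length(theta)]))
    tryCatch(-log_likelihood(aln, ltree, params, code, struct, patterns),
             error = function(e) 1e10)
  }
  n_omega <- if (model == "b_free") 2L else 1L
  lower <- c(log(0.05), rep(log(1e-4), n_omega), log(1e-3))
  upper <- c(log(100), rep(log(50), n_omega), log(100))
  best <- NULL
  for (w0 in starts) {
    theta0 <- switch(model,
      M0 = c(log(2), log(w0), 0),
      b_free = c(log(2), log(w0), log(w0), 0),
      b_neut = c(log(2), log(w0), 0))
    opt <- try(stats::nlminb(theta0, nll, lower = lower, upper = upper,
                             control = list(rel.tol = 1e-10, iter.max = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    opt <- list(par = opt$par, value = opt$objective,
                convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("optimisation failed from every start")
  }
  omega <- par_omega(best$par)
  at_bound <- any(abs(best$par - lower) < 1e-7 | abs(best$par - upper) < 1e-7)
  status <- if (at_bound) "boundary"
            else if (best$convergence != 0) "no_convergence" else "ok"
  n_free <- length(best$par)
  structure(list(model = model, lnL = -best$value,
                 kappa = exp(best$par[1]),
                 omega_fg = unname(omega["foreground"]),
                 omega_bg = unname(omega["background"]),
                 scale = exp(best$par[length(best$par)]),
                 status = status, n_free_params = n_free,
                 codon_freqs = codon_freqs, n_sites = aln$sites),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, kappa = %.3f, omega_fg = %.4f, omega_bg = %.4f, scale = %.3f [%s]\n",
              x$model, x$lnL, x$kappa, x$omega_fg, x$omega_bg, x$scale,
              x$status))
  invisible(x)
}

#' Likelihood-ratio test between nested model fits
#'
#' @param fit_alt,fit_null `model_fit` objects, null nested in the
#'   alternative.
#' @param df Difference in free parameters (1 for both the
#'   b_free-vs-M0 and b_free-vs-b_neut comparisons).
#' @return List: `statistic` (`max(0, 2 delta lnL)`), `df`, `p` (chi-squared
#'   upper tail).
#' @export
lrt <- function(fit_alt, fit_null, df = fit_alt$n_free_params -
                  fit_null$n_free_params) {
  if (df <= 0) stop("df must be positive")
  stat <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Run the full branch-model comparison on one labeled tree
#'
#' Fits M0, b_free and b_neut and returns the two standard LRTs:
#' b_free vs M0 (is the foreground omega different from the rest of the
#' tree?) and b_free vs b_neut (is it different from neutrality?).
#'
#' @inheritParams fit_model
#' @return List: `fits` (named list of `model_fit`), `lrt_free_vs_m0`,
#'   `lrt_free_vs_neut`.
#' @export
branch_model_tests <- function(aln, ltree, code = load_genetic_code(),
                               codon_freqs = NULL) {
  if (is.null(codon_freqs)) codon_freqs <- f3x4_frequencies(aln, code)
  fits <- list(
    M0 = fit_model(aln, ltree, "M0", code, codon_freqs),
    b_free = fit_model(aln, ltree, "b_free", code, codon_freqs),
    b_neut = fit_model(aln, ltree, "b_neut", code, codon_freqs))
  list(fits = fits,
       lrt_free_vs_m0 = lrt(fits$b_free, fits$M0, df = 1L),
       lrt_free_vs_neut = lrt(fits$b_free, fits$b_neut, df = 1L))
}
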