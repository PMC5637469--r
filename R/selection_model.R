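# Two-class survival model of one selection round.
#
# A library member survives the capture step (catalysis of the aldol bond
# to the biotinylated reactant, then streptavidin pull-down) with a
# Bernoulli probability that depends only on its class: p_cat for the
# catalyst-bearing spike-in, p_bg for inactive members (non-specific
# retention / background biotinylation). Sequencing at finite depth is a
# multinomial draw from the (survival-reweighted) pool frequencies.

#' Parameters of one selection round
#'
#' @param p_cat survival probability of a catalyst-bearing member, in
#'   `(0, 1]`.
#' @param p_bg survival probability of an inactive member, in `[0, 1)`;
#'   a meaningful selection has `p_bg < p_cat`. Their ratio
#'   `R = p_cat / p_bg` is the survival ratio that drives enrichment.
#' @param depth_pre,depth_post sequencing depths (reads) for the
#'   pre-selection and post-selection samples.
#' @param pcr_bias_sd standard deviation (log scale) of optional
#'   per-member log-normal amplification-efficiency noise applied
#'   independently to each sample before the multinomial draw; 0 (the
#'   default) disables it. Factors are mean-one so depth is unaffected
#'   in expectation.
#' @param seed integer seed for the stochastic simulation.
#' @return an object of class `selection_params`.
#' @examples
#' selection_params(p_cat = 0.30, p_bg = 1e-4, depth_pre = 1e6,
#'                  depth_post = 1e6, seed = 1)
#' @export
selection_params <- function(p_cat, p_bg, depth_pre = 1e6, depth_post = 1e6,
                             pcr_bias_sd = 0, seed = NULL) {
  stopifnot(is.numeric(p_cat), length(p_cat) == 1L, p_cat > 0, p_cat <= 1,
            is.numeric(p_bg), length(p_bg) == 1L, p_bg >= 0, p_bg < 1,
            depth_pre >= 1, depth_post >= 1, pcr_bias_sd >= 0)
  if (p_bg > p_cat)
    warning("p_bg > p_cat: the 'selection' disfavours catalysts")
  structure(
    list(p_cat = p_cat, p_bg = p_bg,
         depth_pre = as.numeric(depth_pre),
         depth_post = as.numeric(depth_post),
         pcr_bias_sd = pcr_bias_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat("Selection parameters: p_cat =", x$p_cat, ", p_bg =", x$p_bg,
      if (x$p_bg > 0) paste0("(R = ", signif(x$p_cat / x$p_bg, 6), ")"),
      "\n  depths:", format(x$depth_pre, big.mark = ",", scientific = FALSE), "pre /",
      format(x$depth_post, big.mark = ",", scientific = FALSE), "post; seed:",
      if (is.null(x$seed)) "none" else x$seed, "\n")
  invisible(x)
}

#' Survival ratio of a selection
#' @param params a [selection_params()].
#' @return `p_cat / p_bg`.
#' @export
survival_ratio <- function(params) {
  if (params$p_bg <= 0)
    stop("survival ratio undefined at p_bg = 0")
  params$p_cat / params$p_bg
}

#' Expected post-selection frequency of the spike-in
#'
#' Closed form of the two-class survival model: starting at pre-selection
#' frequency `f0`, the expected frequency among survivors is
#' \deqn{f_1 = \frac{f_0\,p_{cat}}{f_0\,p_{cat} + (1-f_0)\,p_{bg}}.}
#'
#' @param f0 spike-in pre-selection frequency in `[0, 1]`.
#' @param p_cat,p_bg per-class survival probabilities in `[0, 1]`.
#' @return expected post-selection frequency.
#' @examples
#' expected_post_frequency(5e-4, 0.3, 1e-4)  # 0.60012
#' @export
expected_post_frequency <- function(f0, p_cat, p_bg) {
  stopifnot(all(f0 >= 0 & f0 <= 1),
            all(p_cat >= 0 & p_cat <= 1),
            all(p_bg >= 0 & p_bg <= 1))
  num <- f0 * p_cat
  den <- num + (1 - f0) * p_bg
  if (any(den == 0))
    stop("degenerate model: no member of the pool can survive")
  num / den
}

#' Expected fold enrichment of the spike-in
#'
#' Fold enrichment is the ratio of post- to pre-selection frequency. Under
#' the two-class survival model it depends only on `f0` and the survival
#' ratio `R = p_cat / p_bg`:
#' \deqn{E(f_0, R) = \frac{R}{1 + f_0 (R - 1)}.}
#' `E` is strictly increasing in `R`, equals 1 at `R = 1`, and is bounded
#' above by the dilution ceiling `1 / f0`: a spike-in diluted 500-fold can
#' be enriched at most 500-fold, one diluted 2000-fold at most 2000-fold.
#'
#' @param f0 spike-in pre-selection frequency in `(0, 1]`.
#' @param R survival ratio `p_cat / p_bg`, `> 0`.
#' @return expected fold enrichment.
#' @examples
#' expected_enrichment(1 / 2000, 3000)    # ~1200-fold
#' expected_enrichment(1 / 500, 124.75)   # 100-fold
#' expected_enrichment(1 / 500, 81.2326)  # ~70-fold
#' @export
expected_enrichment <- function(f0, R) {
  if (any(f0 <= 0))
    stop("f0 must be positive (the spike-in must be present)")
  stopifnot(all(f0 <= 1), all(R > 0))
  R / (1 + f0 * (R - 1))
}

#' Survival ratio required for a target fold enrichment
#'
#' Inverse of [expected_enrichment()] in `R`: the survival ratio at which
#' the expected enrichment at pre-frequency `f0` equals `E`. Used to
#' calibrate simulations to an observed enrichment (only the ratio, not
#' the absolute capture efficiencies, is constrained by an enrichment
#' measurement). `E` must lie below the ceiling `1 / f0`.
#'
#' @param f0 spike-in pre-selection frequency in `(0, 1]`.
#' @param E target fold enrichment, `0 < E < 1/f0`.
#' @return the survival ratio `R`.
#' @examples
#' calibrate_survival_ratio(1 / 2000, 1200)  # ~2999
#' @export
calibrate_survival_ratio <- function(f0, E) {
  stopifnot(f0 > 0, f0 <= 1, E > 0)
  if (E >= 1 / f0)
    stop("target enrichment ", E, " is at or above the dilution ceiling 1/f0 = ",
         1 / f0)
  E * (1 - f0) / (1 - E * f0)
}

#' Simulate sequencing of one selection round
#'
#' Draws the pre-selection sample as `multinomial(depth_pre, f)` over the
#' library frequencies `f`, and the post-selection sample as
#' `multinomial(depth_post, f')` where member `i`'s survival-reweighted
#' frequency is `f'_i = f_i p_class(i) / sum_j f_j p_class(j)`. Each count
#' table sums to its depth exactly, and the draw is deterministic given
#' `params$seed`.
#'
#' @param library a `library_table` (see [generate_library()],
#'   [spike_in()]).
#' @param params a [selection_params()].
#' @return a list with `pre` and `post` count tables (data.frames with
#'   columns barcode, count) and the survival-reweighted frequencies as
#'   attribute `"post_frequency"` on `post`.
#' @examples
#' arch <- library_architecture()
#' lib <- spike_in(generate_library(arch, 50, seed = 2), arch, 500)
#' sim <- simulate_selection(lib, selection_params(0.3, 1e-4, 1e4, 1e4, 7))
#' sum(sim$post$count)  # == depth_post
#' @export
simulate_selection <- function(library, params) {
  validate_library_table(library)
  stopifnot(inherits(params, "selection_params"))
  if (nrow(library) == 0)
    stop("empty library")
  p <- ifelse(library$class == "catalyst", params$p_cat, params$p_bg)
  w <- library$frequency * p
  if (sum(w) == 0)
    stop("degenerate model: no member of the pool can survive")
  post_freq <- w / sum(w)
  seeds <- child_seeds(params$seed, 4L)
  # optional per-member log-normal amplification bias, drawn independently
  # for the two library preps (mean-one factors)
  bias <- function(seed) {
    sd <- params$pcr_bias_sd
    if (is.null(sd) || sd == 0) return(rep(1, nrow(library)))
    with_seed(seed, exp(rnorm(nrow(library), -sd^2 / 2, sd)))
  }
  pre_w <- library$frequency * bias(seeds[3])
  post_w <- post_freq * bias(seeds[4])
  pre_counts <- with_seed(seeds[1],
    as.vector(rmultinom(1, params$depth_pre, pre_w / sum(pre_w))))
  post_counts <- with_seed(seeds[2],
    as.vector(rmultinom(1, params$depth_post, post_w / sum(post_w))))
  pre <- count_table(library$barcode, pre_counts)
  post <- count_table(library$barcode, post_counts)
  attr(post, "post_frequency") <- post_freq
  list(pre = pre, post = post)
}
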