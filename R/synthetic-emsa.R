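# Synthetic EMSA lane quantitations drawn from the
# specific-binding-with-Hill-slope model.

#' Hill binding isotherm
#'
#' `Y = bmax * X^h / (kd^h + X^h)` (specific binding with Hill slope).
#'
#' @param x protein concentration (nM), positive.
#' @param kd equilibrium dissociation constant (nM).
#' @param hill Hill slope (dimensionless).
#' @param bmax maximal response.
#' @return numeric vector of responses.
#' @export
hill_response <- function(x, kd, hill, bmax = 1) {
  bmax * x^hill / (kd^hill + x^hill)
}

#' Generate synthetic EMSA binding-curve replicates
#'
#' Bound intensity per lane is `bmax * X^h / (kd^h + X^h) * (1 + eps)`
#' with multiplicative Gaussian lane noise `eps ~ N(0, noise_sd)`;
#' unbound intensity is the complementary `(bmax - bound_true)` with its
#' own lane noise. A co-purified band of constant intensity
#' `constant_unbound_frac * bmax` is added to every lane's unbound
#' signal and also reported separately in the `copurified` column (the
#' separately quantitated band that [exclude_constant_unbound()]
#' removes).
#'
#' @param concentrations protein concentrations in nM (all > 0).
#' @param kd,hill,bmax true binding parameters (`kd > 0`, `hill > 0`).
#'   The default `kd = 30` nM emulates the affinity scale of an
#'   activator-operator interaction.
#' @param noise_sd multiplicative lane noise SD (fraction).
#' @param constant_unbound_frac co-purified band intensity as a fraction
#'   of `bmax`.
#' @param n_reps number of independent replicates.
#' @param seed integer RNG seed.
#' @return data.frame with columns `concentration_nM`, `rep`, `bound`,
#'   `unbound`, `copurified`; attribute `truth` records the generating
#'   parameters.
#' @export
gen_emsa <- function(concentrations, kd = 30, hill = 1.5, bmax = 1,
                     noise_sd = 0.05, constant_unbound_frac = 0,
                     n_reps = 3L, seed = 1L) {
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("concentrations must all be positive")
  stopifnot(kd > 0, hill > 0, bmax > 0,
            noise_sd >= 0, noise_sd <= 1,
            constant_unbound_frac >= 0, constant_unbound_frac <= 1)
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(n_reps),
                      concentration_nM = concentrations)
  x <- grid$concentration_nM
  b_true <- hill_response(x, kd, hill, bmax)
  baseline <- constant_unbound_frac * bmax
  out <- data.frame(
    concentration_nM = x,
    rep = grid$rep,
    bound = b_true * (1 + rnorm(length(x), 0, noise_sd)),
    unbound = (bmax - b_true) * (1 + rnorm(length(x), 0, noise_sd)) + baseline,
    copurified = rep(baseline, length(x)))
  attr(out, "truth") <- list(kd = kd, hill = hill, bmax = bmax,
                             noise_sd = noise_sd,
                             constant_unbound_frac = constant_unbound_frac)
  out
}

#' Write or read EMSA lane TSVs
#'
#' Columns: `concentration_nM`, `rep`, `bound`, `unbound`, and
#' optionally `copurified`.
#'
#' @param lanes data.frame as produced by [gen_emsa()].
#' @param path TSV file path.
#' @return `write_emsa_tsv`: invisibly, `path`; `read_emsa_tsv`: the
#'   lanes data.frame.
#' @export
write_emsa_tsv <- function(lanes, path) {
  write.table(lanes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emsa_tsv
#' @export
read_emsa_tsv <- function(path) {
  lanes <- read.delim(path, check.names = FALSE)
  need <- c("concentration_nM", "rep", "bound", "unbound")
  if (!all(need %in% names(lanes)))
    stop("EMSA TSV must have columns: ", paste(need, collapse = ", "))
  lanes
}
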