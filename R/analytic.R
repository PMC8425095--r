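# Closed-form expectations for the initial population. These are not used by
# the simulator itself (which only reports empirical moments) but serve as
# oracles and to standardize outputs.

#' Expected phenotypic variance of initial-population colonies
#'
#' For colonies headed by unrelated base-population queens mated to `n_drones`
#' unrelated drones each:
#' \deqn{\sigma^2_P = \sigma^2_{mat} + \frac{n_D + 2}{4 n_D} \sigma^2_{dir}
#'   + \sigma_{dir,mat} + \sigma^2_e.}
#' The direct-effect weight is 3/4 under monoandry and decreases toward 1/4
#' as the polyandry level grows.
#'
#' @param setup A [genetic_setup()] object.
#' @param n_drones Polyandry level nD (>= 1).
#' @return Expected phenotypic variance (trait^2 units).
#' @export
#' @examples
#' phenotypic_variance(preset_genetic_setup(1), 1)   # 47.5
#' phenotypic_variance(preset_genetic_setup(1), 8)   # 43.125
phenotypic_variance <- function(setup, n_drones) {
  stopifnot(inherits(setup, "genetic_setup"))
  if (!is.numeric(n_drones) || n_drones < 1)
    stop("n_drones must be >= 1")
  setup$var_mat + (n_drones + 2) / (4 * n_drones) * setup$var_dir +
    setup$cov_dir_mat + setup$var_residual
}

#' Initial-population heritabilities of direct and maternal effects
#'
#' Heritabilities are the ratios of the direct or maternal genetic variance
#' to the phenotypic variance of [phenotypic_variance()], and therefore
#' depend on the polyandry level.
#'
#' @inheritParams phenotypic_variance
#' @return A list with `phenotypic_variance`, `h2_dir` and `h2_mat`
#'   (full precision; round at the reporting layer).
#' @export
heritabilities <- function(setup, n_drones) {
  v_p <- phenotypic_variance(setup, n_drones)
  if (v_p <= 0) stop("phenotypic variance must be positive")
  list(phenotypic_variance = v_p,
       h2_dir = setup$var_dir / v_p,
       h2_mat = setup$var_mat / v_p)
}

#' Approximate phenotypic variance in a later year
#'
#' Applies the initial-population decomposition to the genetic
#' (co)variances of the queens of year t-1, assuming drones come from a
#' single DPQ per queen and treating breeding queens and DPQ as unrelated
#' (only approximately true under selection):
#' \deqn{V(P_{[t]}) \approx V_{mat} + \frac{n_D + 2}{4 n_D} V_{dir}
#'   + Cov_{dir,mat} + \sigma^2_e.}
#'
#' @param genetic_cov 2x2 positive semi-definite covariance matrix of the
#'   direct and maternal breeding values of year t-1 queens (order dir, mat).
#' @param n_drones Polyandry level nD (>= 1).
#' @param var_residual Residual variance.
#' @return Approximate phenotypic variance.
#' @export
variance_in_year <- function(genetic_cov, n_drones, var_residual) {
  stopifnot(is.matrix(genetic_cov), all(dim(genetic_cov) == 2L))
  if (n_drones < 1) stop("n_drones must be >= 1")
  if (abs(genetic_cov[1, 2] - genetic_cov[2, 1]) > 1e-8 ||
      min(eigen((genetic_cov + t(genetic_cov)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("genetic_cov must be a symmetric PSD 2x2 matrix")
  genetic_cov[2, 2] + (n_drones + 2) / (4 * n_drones) * genetic_cov[1, 1] +
    genetic_cov[1, 2] + var_residual
}

#' Grid of initial variances and heritabilities
#'
#' Tabulates [phenotypic_variance()] and [heritabilities()] for a set of
#' parameter setups and polyandry levels, rounded to two decimals for
#' display.
#'
#' @param setup_ids Integer vector of preset setup ids (see
#'   [preset_genetic_setup()]).
#' @param n_drones Integer vector of polyandry levels.
#' @return A data.frame with one row per (setup, nD) combination.
#' @export
variance_table <- function(setup_ids = 1:4, n_drones = c(1L, 8L)) {
  # half-up rounding for display (47.125 -> 47.13), as variance tables are
  # conventionally printed; base round() is half-even
  r2 <- function(x) floor(x * 100 + 0.5) / 100
  rows <- expand.grid(setup = setup_ids, n_drones = n_drones,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    gs <- preset_genetic_setup(rows$setup[i])
    h <- heritabilities(gs, rows$n_drones[i])
    data.frame(setup = rows$setup[i], n_drones = rows$n_drones[i],
               var_dir = gs$var_dir, var_mat = gs$var_mat,
               corr_dir_mat = gs$corr_dir_mat,
               sigma2_P = r2(h$phenotypic_variance),
               h2_dir = r2(h$h2_dir), h2_mat = r2(h$h2_mat))
  })
  do.call(rbind, res)
}
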