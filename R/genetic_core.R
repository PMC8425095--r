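# Breeding values are represented throughout as n x 2 numeric matrices with
# columns "dir" (direct effect, expressed by workers) and "mat" (maternal
# effect, expressed by the queen). Helpers below accept length-2 vectors too.

as_bv <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 2L)
    x <- matrix(x, 1L, 2L)
  }
  stopifnot(is.numeric(x), ncol(x) == 2L)
  colnames(x) <- c("dir", "mat")
  x
}

# n draws from N(0, scale * Sigma_BV); handles degenerate (zero) variances.
rbv <- function(n, setup, scale = 1) {
  S <- scale * setup$Sigma
  if (all(S == 0)) {
    m <- matrix(0, n, 2L)
  } else {
    m <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = S)
    if (n == 1L) m <- matrix(m, 1L, 2L)
  }
  colnames(m) <- c("dir", "mat")
  m
}

#' Sample base-population queens
#'
#' Draws `n` independent (direct, maternal) breeding-value pairs from the
#' bivariate normal \eqn{N(0, \Sigma_{BV})} describing the unrelated,
#' non-inbred base population.
#'
#' @param setup A [genetic_setup()] object.
#' @param n Number of queens (>= 1).
#' @return An `n x 2` matrix with columns `dir`, `mat`.
#' @export
sample_base_queens <- function(setup, n) {
  stopifnot(inherits(setup, "genetic_setup"), n >= 1)
  rbv(n, setup, scale = 1)
}

#' Sample unrelated environment drones
#'
#' Drones from the surrounding unselected population used to mate queens in
#' the build-up years. Being haploid gametes of unrelated non-inbred queens,
#' their breeding values follow \eqn{N(0, \tfrac12 \Sigma_{BV})}: half the
#' genetic variance of diploid queens.
#'
#' @inheritParams sample_base_queens
#' @return An `n x 2` matrix of drone breeding values.
#' @export
sample_environment_drones <- function(setup, n) {
  stopifnot(inherits(setup, "genetic_setup"), n >= 1)
  rbv(n, setup, scale = 0.5)
}

#' Mendelian sampling terms
#'
#' Draws deviations of offspring breeding values from the parental mean,
#' \eqn{\varphi \sim N(0, \tfrac14 (1 - F) \Sigma_{BV})}, where `F` is the
#' inbreeding coefficient of the offspring's dam. One term is produced per
#' element of `dam_inbreeding`, so a vector of dam F values yields one row
#' per meiosis.
#'
#' @param setup A [genetic_setup()] object.
#' @param dam_inbreeding Numeric vector of dam inbreeding coefficients in
#'   \eqn{[0, 1]}.
#' @return A `length(dam_inbreeding) x 2` matrix.
#' @export
meiosis_terms <- function(setup, dam_inbreeding) {
  stopifnot(inherits(setup, "genetic_setup"))
  if (any(dam_inbreeding < 0 | dam_inbreeding > 1))
    stop("dam inbreeding coefficients must lie in [0, 1]")
  n <- length(dam_inbreeding)
  phi <- rbv(n, setup, scale = 0.25)
  phi * sqrt(1 - dam_inbreeding)   # row-wise scaling, recycled by column
}

#' Breeding value of drones bred by a drone-producing queen
#'
#' A drone is genetically a gamete of its dam: its breeding value is half the
#' dam's plus one Mendelian sampling term drawn with the dam's inbreeding.
#'
#' @param dpq_bv Dam (DPQ) breeding values, `n x 2` or length-2 vector.
#' @param phi Mendelian sampling terms of matching shape (drawn with the
#'   DPQ's inbreeding via [meiosis_terms()]).
#' @return Matrix of drone breeding values.
#' @export
drone_bv <- function(dpq_bv, phi) {
  dpq_bv <- as_bv(dpq_bv); phi <- as_bv(phi)
  0.5 * dpq_bv + phi
}

#' Breeding value of a daughter queen
#'
#' A queen inherits half her dam's breeding value, the full breeding value of
#' one sire drone (drones produce gametes by mitosis, so the drone's genome
#' passes unchanged), and one Mendelian sampling term from the dam's meiosis.
#' In expectation over drone choice and meiosis this equals the mid-parent
#' value of the dam and the drone's own dam (the DPQ).
#'
#' @param bq_bv Dam (breeding queen) breeding values.
#' @param sire_drone_bv Breeding values of the sire drone, one uniform pick
#'   among the dam's mates.
#' @param phi Mendelian sampling terms drawn with the dam's inbreeding.
#' @return Matrix of daughter breeding values.
#' @export
queen_bv <- function(bq_bv, sire_drone_bv, phi) {
  bq_bv <- as_bv(bq_bv); sire_drone_bv <- as_bv(sire_drone_bv); phi <- as_bv(phi)
  0.5 * bq_bv + sire_drone_bv + phi
}

#' Mean breeding value of a colony's worker group
#'
#' Workers are represented by their group mean: half the queen's breeding
#' value plus the mean breeding value of the drones that inseminated her,
#' assuming each drone contributes equally. No Mendelian sampling term is
#' added because the mean of thousands of worker-level terms vanishes.
#'
#' @param queen_bv Queen breeding values (length-2 vector or 1 x 2 matrix).
#' @param mate_bvs `nD x 2` matrix of the queen's mates' breeding values.
#' @return A `1 x 2` matrix.
#' @export
worker_group_bv <- function(queen_bv, mate_bvs) {
  queen_bv <- as_bv(queen_bv)
  mate_bvs <- as_bv(mate_bvs)
  if (nrow(mate_bvs) < 1L) stop("a mated queen needs at least one drone")
  as_bv(0.5 * queen_bv[1L, ] + colMeans(mate_bvs))
}

#' Simulate colony performance
#'
#' Colony performance is the selection criterion:
#' \deqn{P = BV^Q_{mat} + \overline{BV^W_{dir}} + e,\qquad
#'       e \sim N(0, \sigma^2_e).}
#' Vectorized over colonies.
#'
#' @param queen_bv_mat Numeric vector of queen maternal breeding values.
#' @param worker_bv_dir Numeric vector of worker-group mean direct breeding
#'   values (same length).
#' @param setup A [genetic_setup()] supplying the residual variance.
#' @return A data.frame with columns `performance` and `residual`.
#' @export
colony_performance <- function(queen_bv_mat, worker_bv_dir, setup) {
  stopifnot(inherits(setup, "genetic_setup"),
            length(queen_bv_mat) == length(worker_bv_dir))
  n <- length(queen_bv_mat)
  e <- if (setup$var_residual > 0) {
    stats::rnorm(n, 0, sqrt(setup$var_residual))
  } else rep(0, n)
  data.frame(performance = queen_bv_mat + worker_bv_dir + e, residual = e)
}

#' Expected colony performance given the queen and her mates
#'
#' The expectation of [colony_performance()] over worker sampling and the
#' residual: \eqn{E(P) = BV^Q_{mat} + \tfrac12 BV^Q_{dir} +
#' \overline{BV^{Ds}_{dir}}}.
#'
#' @inheritParams worker_group_bv
#' @return A single numeric value.
#' @export
expected_performance <- function(queen_bv, mate_bvs) {
  queen_bv <- as_bv(queen_bv)
  mate_bvs <- as_bv(mate_bvs)
  if (nrow(mate_bvs) < 1L) stop("a mated queen needs at least one drone")
  unname(queen_bv[1L, "mat"] + 0.5 * queen_bv[1L, "dir"] +
           mean(mate_bvs[, "dir"]))
}
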