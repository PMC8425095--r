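#' Base-population genetic parameter setup
#'
#' Bundles the (co)variance components of direct and maternal breeding values
#' in the base population together with the residual variance of colony
#' performance. The implied 2x2 covariance matrix
#' \deqn{\Sigma_{BV} = \begin{pmatrix} \sigma^2_{dir} & \sigma_{dir,mat} \\
#'   \sigma_{dir,mat} & \sigma^2_{mat} \end{pmatrix}}
#' with \eqn{\sigma_{dir,mat} = r \sqrt{\sigma^2_{dir}\sigma^2_{mat}}} must be
#' positive semi-definite, which holds whenever \eqn{|r| \le 1}.
#'
#' @param var_dir Variance of direct breeding values (trait^2 units).
#' @param var_mat Variance of maternal breeding values (trait^2 units).
#' @param corr_dir_mat Genetic correlation between direct and maternal
#'   breeding values, in \eqn{[-1, 1]}.
#' @param var_residual Residual (non-heritable) variance of colony
#'   performance (trait^2 units).
#'
#' @return An object of class `genetic_setup`: a list with the four scalar
#'   components plus `cov_dir_mat` and the matrix `Sigma` (rows/columns
#'   `dir`, `mat`).
#' @export
#' @examples
#' gs <- genetic_setup(10, 10, 0, 30)
#' gs$Sigma
genetic_setup <- function(var_dir, var_mat, corr_dir_mat = 0, var_residual = 30) {
  stopifnot(
    is.numeric(var_dir), length(var_dir) == 1L, is.finite(var_dir),
    is.numeric(var_mat), length(var_mat) == 1L, is.finite(var_mat),
    is.numeric(corr_dir_mat), length(corr_dir_mat) == 1L, is.finite(corr_dir_mat),
    is.numeric(var_residual), length(var_residual) == 1L, is.finite(var_residual)
  )
  if (var_dir < 0 || var_mat < 0 || var_residual < 0)
    stop("variance components must be non-negative")
  if (abs(corr_dir_mat) > 1)
    stop("corr_dir_mat must lie in [-1, 1]")
  cov_dm <- corr_dir_mat * sqrt(var_dir * var_mat)
  Sigma <- matrix(c(var_dir, cov_dm, cov_dm, var_mat), 2L, 2L,
                  dimnames = list(c("dir", "mat"), c("dir", "mat")))
  # PSD is implied by |r| <= 1 but guard against numerical misuse anyway
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("implied breeding-value covariance matrix is not positive semi-definite")
  structure(
    list(var_dir = var_dir, var_mat = var_mat,
         corr_dir_mat = corr_dir_mat, cov_dir_mat = cov_dm,
         var_residual = var_residual, Sigma = Sigma),
    class = "genetic_setup")
}

#' Predefined genetic parameter setups 1-4
#'
#' The four base-population parameter combinations studied by the simulator:
#' maternal variance fixed at 10, direct variance 10 or 20, direct-maternal
#' correlation 0 or -0.5, residual variance 30.
#'
#' | setup | var_dir | var_mat | r     |
#' |-------|---------|---------|-------|
#' | 1     | 10      | 10      | 0     |
#' | 2     | 20      | 10      | 0     |
#' | 3     | 10      | 10      | -0.5  |
#' | 4     | 20      | 10      | -0.5  |
#'
#' @param id Integer in 1..4.
#' @return A [genetic_setup()] object.
#' @export
preset_genetic_setup <- function(id) {
  stopifnot(length(id) == 1L, id %in% 1:4)
  par <- list(
    list(10, 10, 0), list(20, 10, 0), list(10, 10, -0.5), list(20, 10, -0.5)
  )[[id]]
  genetic_setup(var_dir = par[[1]], var_mat = par[[2]],
                corr_dir_mat = par[[3]], var_residual = 30)
}

#' @export
print.genetic_setup <- function(x, ...) {
  cat("Genetic setup:\n")
  cat(sprintf("  var(BV_dir) = %g, var(BV_mat) = %g, r = %g, var(e) = %g\n",
              x$var_dir, x$var_mat, x$corr_dir_mat, x$var_residual))
  invisible(x)
}
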