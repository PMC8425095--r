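# Haplodiploid coancestry bookkeeping.
#
# Haplodiploid inheritance follows the same rules as X-linked genes with no
# X-Y crossover, so the numerator relationship matrix can be built by the
# tabular method for sex chromosomes. Internally the table stores coancestry
# (kinship) coefficients f(i, j): the probability that a random allele from i
# is identical by descent to a random allele from j. For a diploid female
# f(i, i) = (1 + F_i) / 2; for a haploid drone f(d, d) = 1. The relationship
# usually reported between females is 2 f.

#' Create an empty haplodiploid kinship table
#'
#' A mutable (environment-backed) coancestry table over diploid females and
#' haploid drones. Rows are added with [kt_add_founder_female()],
#' [kt_add_drone()] and [kt_add_female()]; entries are coancestry
#' coefficients f(i, j).
#'
#' @param capacity Initial matrix capacity (grows automatically).
#' @return An object of class `kinship_table` (reference semantics: the
#'   `kt_add_*` and [kt_prune()] functions modify it in place).
#' @export
kinship_table <- function(capacity = 64L) {
  kt <- new.env(parent = emptyenv())
  kt$n <- 0L
  kt$f <- matrix(0, capacity, capacity)
  kt$ploidy <- integer(capacity)      # 2 female, 1 drone
  kt$birth_year <- integer(capacity)
  kt$dam <- integer(capacity)         # 0 = founder / environment
  kt$sire <- integer(capacity)        # 0 = none (drones, founders)
  kt$id <- integer(capacity)          # stable external id
  kt$next_id <- 1L
  class(kt) <- "kinship_table"
  kt
}

#' @export
print.kinship_table <- function(x, ...) {
  cat(sprintf("Haplodiploid kinship table: %d individuals (%d females, %d drones)\n",
              x$n, sum(x$ploidy[seq_len(x$n)] == 2L),
              sum(x$ploidy[seq_len(x$n)] == 1L)))
  invisible(x)
}

kt_grow <- function(kt, need) {
  cap <- nrow(kt$f)
  if (need <= cap) return(invisible(kt))
  newcap <- max(need, 2L * cap)
  f <- matrix(0, newcap, newcap)
  f[seq_len(kt$n), seq_len(kt$n)] <- kt$f[seq_len(kt$n), seq_len(kt$n)]
  kt$f <- f
  for (fld in c("ploidy", "birth_year", "dam", "sire", "id")) {
    v <- kt[[fld]]
    length(v) <- newcap
    v[is.na(v)] <- 0L
    kt[[fld]] <- v
  }
  invisible(kt)
}

kt_row_of <- function(kt, id) {
  r <- match(id, kt$id[seq_len(kt$n)])
  if (any(is.na(r))) stop("unknown individual id: ",
                          paste(id[is.na(r)], collapse = ", "))
  r
}

kt_new_row <- function(kt, ploidy, birth_year, dam, sire) {
  kt_grow(kt, kt$n + 1L)
  i <- kt$n + 1L
  kt$n <- i
  kt$ploidy[i] <- ploidy
  kt$birth_year[i] <- birth_year
  kt$dam[i] <- dam
  kt$sire[i] <- sire
  kt$id[i] <- kt$next_id
  kt$next_id <- kt$next_id + 1L
  i
}

#' Add an unrelated founder female
#'
#' Founders are non-inbred and unrelated to everyone already in the table:
#' f = 0 to all prior individuals, f(i, i) = 1/2.
#'
#' @param kt A [kinship_table()].
#' @param birth_year Integer birth year (used by [kt_prune()]).
#' @return The new individual's id (integer).
#' @export
kt_add_founder_female <- function(kt, birth_year = 0L) {
  i <- kt_new_row(kt, 2L, as.integer(birth_year), 0L, 0L)
  kt$f[i, seq_len(i)] <- 0
  kt$f[seq_len(i), i] <- 0
  kt$f[i, i] <- 0.5
  kt$id[i]
}

#' Add a drone
#'
#' A drone is a gamete of its dam: its coancestry with any prior individual
#' equals the dam's, and f(d, d) = 1 (a single allele is always IBD with
#' itself). `dam_id = "environment"` (or `NA`) registers an unrelated
#' environment drone: f = 0 to everyone, f(d, d) = 1.
#'
#' @param kt A [kinship_table()].
#' @param dam_id Id of the dam (a female in the table), or `"environment"`.
#' @param birth_year Integer birth year.
#' @return The new drone's id.
#' @export
kt_add_drone <- function(kt, dam_id, birth_year = 0L) {
  env_drone <- (is.character(dam_id) && identical(dam_id, "environment")) ||
    (length(dam_id) == 1L && is.na(dam_id))
  dam_row <- if (env_drone) 0L else kt_row_of(kt, dam_id)
  if (!env_drone && kt$ploidy[dam_row] != 2L) stop("dam must be a female")
  i <- kt_new_row(kt, 1L, as.integer(birth_year), dam_row, 0L)
  prev <- seq_len(i - 1L)
  vals <- if (env_drone) rep(0, i - 1L) else kt$f[dam_row, prev]
  kt$f[i, prev] <- vals
  kt$f[prev, i] <- vals
  kt$f[i, i] <- 1
  kt$id[i]
}

#' Add a female with known dam and sire drone
#'
#' Tabular recursion for the sex-chromosome case: for every prior j,
#' f(i, j) = (f(dam, j) + f(sire, j)) / 2; the inbreeding of the new female
#' is F_i = f(dam, sire) and f(i, i) = (1 + F_i) / 2.
#'
#' @param kt A [kinship_table()].
#' @param dam_id Id of the dam (female).
#' @param sire_drone_id Id of the sire (drone).
#' @param birth_year Integer birth year.
#' @return The new female's id.
#' @export
kt_add_female <- function(kt, dam_id, sire_drone_id, birth_year = 0L) {
  dam_row <- kt_row_of(kt, dam_id)
  sire_row <- kt_row_of(kt, sire_drone_id)
  if (kt$ploidy[dam_row] != 2L) stop("dam must be a female")
  if (kt$ploidy[sire_row] != 1L) stop("sire must be a drone")
  i <- kt_new_row(kt, 2L, as.integer(birth_year), dam_row, sire_row)
  prev <- seq_len(i - 1L)
  vals <- 0.5 * (kt$f[dam_row, prev] + kt$f[sire_row, prev])
  kt$f[i, prev] <- vals
  kt$f[prev, i] <- vals
  kt$f[i, i] <- 0.5 * (1 + kt$f[dam_row, sire_row])
  kt$id[i]
}

#' Coancestry between two tracked individuals
#'
#' @param kt A [kinship_table()].
#' @param id_a,id_b Individual ids.
#' @return The coancestry coefficient f(a, b).
#' @export
kt_coancestry <- function(kt, id_a, id_b) {
  kt$f[kt_row_of(kt, id_a), kt_row_of(kt, id_b)]
}

#' Numerator relationship between two females (2 f)
#' @inheritParams kt_coancestry
#' @export
kt_relationship <- function(kt, id_a, id_b) 2 * kt_coancestry(kt, id_a, id_b)

#' Inbreeding coefficient of a tracked female
#' @inheritParams kt_coancestry
#' @param id Individual id (female).
#' @export
kt_inbreeding <- function(kt, id) {
  r <- kt_row_of(kt, id)
  if (kt$ploidy[r] != 2L) stop("inbreeding is defined for diploid females")
  2 * kt$f[r, r] - 1
}

#' Inbreeding of the daughters of a dam x drone cross
#'
#' The inbreeding coefficient of any daughter of the cross equals the
#' coancestry of dam and sire drone. The same value scales the Mendelian
#' sampling variance of the daughters' own offspring.
#'
#' @param kt A [kinship_table()].
#' @param dam_id,drone_id Ids of the prospective parents.
#' @return f(dam, drone).
#' @export
kt_inbreeding_of_cross <- function(kt, dam_id, drone_id) {
  kt_coancestry(kt, dam_id, drone_id)
}

#' Number of individuals currently tracked
#' @param kt A [kinship_table()].
#' @export
kt_size <- function(kt) kt$n

#' Ids currently tracked
#' @param kt A [kinship_table()].
#' @export
kt_ids <- function(kt) kt$id[seq_len(kt$n)]

#' Truncate old generations from the table
#'
#' Removes individuals born before `current_year - keep_generations` unless
#' they are (possibly indirect) parents of a retained individual. All stored
#' coancestry values among retained individuals are untouched, so inbreeding
#' coefficients of retained and future individuals are exactly invariant to
#' pruning.
#'
#' @param kt A [kinship_table()].
#' @param current_year Integer current year.
#' @param keep_generations Age cutoff in years (default 3).
#' @return The table, invisibly (pruned in place).
#' @export
kt_prune <- function(kt, current_year, keep_generations = 3L) {
  stopifnot(keep_generations >= 1L)
  n <- kt$n
  idx <- seq_len(n)
  keep <- kt$birth_year[idx] >= current_year - keep_generations
  # closure: parents of retained individuals are retained too
  repeat {
    par <- unique(c(kt$dam[idx][keep], kt$sire[idx][keep]))
    par <- par[par > 0L]
    par <- par[!keep[par]]
    if (!length(par)) break
    keep[par] <- TRUE
  }
  if (all(keep)) return(invisible(kt))
  sel <- idx[keep]
  m <- length(sel)
  kt$f[seq_len(m), seq_len(m)] <- kt$f[sel, sel]
  # remap parent row pointers
  newpos <- integer(n)
  newpos[sel] <- seq_len(m)
  remap <- function(v) ifelse(v[sel] > 0L, newpos[pmax(v[sel], 1L)], 0L)
  kt$dam[seq_len(m)] <- remap(kt$dam)
  kt$sire[seq_len(m)] <- remap(kt$sire)
  kt$ploidy[seq_len(m)] <- kt$ploidy[sel]
  kt$birth_year[seq_len(m)] <- kt$birth_year[sel]
  kt$id[seq_len(m)] <- kt$id[sel]
  kt$n <- m
  invisible(kt)
}

#' Export the pedigree of a kinship table
#'
#' @param kt A [kinship_table()].
#' @return A data.frame with columns `id`, `dam`, `sire`, `ploidy`,
#'   `birth_year` (dam/sire 0 for founders and environment drones).
#' @export
kt_pedigree <- function(kt) {
  idx <- seq_len(kt$n)
  data.frame(
    id = kt$id[idx],
    dam = ifelse(kt$dam[idx] > 0L, kt$id[pmax(kt$dam[idx], 1L)], 0L),
    sire = ifelse(kt$sire[idx] > 0L, kt$id[pmax(kt$sire[idx], 1L)], 0L),
    ploidy = kt$ploidy[idx],
    birth_year = kt$birth_year[idx]
  )
}

#' Monte Carlo gene-drop estimate of coancestry
#'
#' Independent validation of the tabular method: founder females receive two
#' unique alleles, founder drones one; a female inherits one random allele
#' from her dam plus the sire drone's single allele; a drone inherits one
#' random allele from his dam. The coancestry of a pair is estimated as the
#' probability that a random allele from one is IBD with a random allele
#' from the other, averaged over `n_reps` independent drops.
#'
#' @param pedigree A data.frame as returned by [kt_pedigree()] (parents must
#'   precede offspring; `dam`/`sire` 0 for founders).
#' @param pair Length-2 vector of ids.
#' @param n_reps Number of gene drops.
#' @return A list with `estimate` and Monte Carlo `se`.
#' @export
gene_drop_kinship <- function(pedigree, pair, n_reps = 1e5) {
  stopifnot(is.data.frame(pedigree), length(pair) == 2L)
  n <- nrow(pedigree)
  if (anyDuplicated(pedigree$id)) stop("duplicated ids in pedigree")
  dam <- match(pedigree$dam, pedigree$id)
  sire <- match(pedigree$sire, pedigree$id)
  if (any(!is.na(dam) & dam >= seq_len(n)) ||
      any(!is.na(sire) & sire >= seq_len(n)))
    stop("pedigree must be sorted parents-before-offspring (acyclic)")
  # allele matrices: a1 always present; a2 only for females
  a1 <- vector("list", n); a2 <- vector("list", n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    maternal <- if (is.na(dam[i])) {
      al <- rep.int(next_allele, n_reps); next_allele <- next_allele + 1L
      al
    } else {
      pick <- stats::runif(n_reps) < 0.5
      if (pedigree$ploidy[dam[i]] == 1L) stop("dam must be diploid")
      ifelse(pick, a1[[dam[i]]], a2[[dam[i]]])
    }
    if (pedigree$ploidy[i] == 1L) {
      a1[[i]] <- maternal
    } else {
      paternal <- if (is.na(sire[i])) {
        al <- rep.int(next_allele, n_reps); next_allele <- next_allele + 1L
        al
      } else {
        if (pedigree$ploidy[sire[i]] != 1L) stop("sire must be a drone")
        a1[[sire[i]]]
      }
      a1[[i]] <- maternal
      a2[[i]] <- paternal
    }
  }
  p <- match(pair, pedigree$id)
  if (any(is.na(p))) stop("pair ids not in pedigree")
  al_a <- if (pedigree$ploidy[p[1]] == 1L) list(a1[[p[1]]]) else list(a1[[p[1]]], a2[[p[1]]])
  al_b <- if (pedigree$ploidy[p[2]] == 1L) list(a1[[p[2]]]) else list(a1[[p[2]]], a2[[p[2]]])
  acc <- numeric(n_reps)
  for (x in al_a) for (y in al_b) acc <- acc + (x == y)
  per_rep <- acc / (length(al_a) * length(al_b))
  list(estimate = mean(per_rep),
       se = stats::sd(per_rep) / sqrt(n_reps))
}

# ---------------------------------------------------------------------------
# Vectorized cohort extension of a female-only coancestry matrix.
#
# Inside the breeding scheme drones never need rows of their own: a drone's
# coancestry with any individual born before him equals his dam's, and two
# distinct drones of one dam have f = (1 + F_dam) / 2 = f(dam, dam). Hence
# for daughters i, k with dams b_i, b_k and sire drones from DPQs s_i, s_k:
#   f(i, old j) = [f(b_i, j) + f(s_i, j)] / 2
#   f(i, k)     = [f(b_i,b_k) + f(b_i,s_k) + f(s_i,b_k) + f(d_i,d_k)] / 4
# where f(d_i, d_k) = f(s_i, s_k) unless the two daughters share the exact
# same sire drone, in which case f(d_i, d_i) = 1. Environment-sired cohorts
# set all sire terms to 0 (unrelated founder drones with one allele each).
# ---------------------------------------------------------------------------

# A: m x m coancestry matrix over currently tracked females.
# dam_idx: length-n rows of A for each new female's dam.
# sire_idx: length-n rows of A for the DPQ whose drone sired each new female,
#   or NA for environment-sired females.
# drone_key: length-n key identifying the exact sire drone (e.g. dam index
#   combined with mate slot); pairs with equal keys share one drone.
# Returns list(A = (m+n) x (m+n) matrix, new_idx = m + 1:n, F = inbreeding
# of the new females).
extend_cohort_coancestry <- function(A, dam_idx, sire_idx, drone_key) {
  m <- nrow(A)
  n <- length(dam_idx)
  stopifnot(length(sire_idx) == n, length(drone_key) == n)
  env <- is.na(sire_idx)
  if (any(env) && !all(env))
    stop("a cohort must be uniformly environment- or DPQ-sired")
  env <- all(env)

  Ad <- A[dam_idx, , drop = FALSE]                   # n x m
  if (env) {
    Fnew <- rep(0, n)
    M <- 0.5 * Ad
    N <- 0.25 * A[dam_idx, dam_idx, drop = FALSE]
    dd_same <- 1                                     # shared env drone: f(d,d)=1
    base_dd <- 0
  } else {
    As <- A[sire_idx, , drop = FALSE]
    Fnew <- A[cbind(dam_idx, sire_idx)]
    M <- 0.5 * (Ad + As)
    N <- 0.25 * (A[dam_idx, dam_idx, drop = FALSE] +
                 A[dam_idx, sire_idx, drop = FALSE] +
                 A[sire_idx, dam_idx, drop = FALSE] +
                 A[sire_idx, sire_idx, drop = FALSE])
    dd_same <- 1
    base_dd <- NULL                                  # computed per pair below
  }
  # correction for pairs sharing the exact same sire drone
  same <- outer(drone_key, drone_key, "==")
  diag(same) <- FALSE
  if (any(same)) {
    if (env) {
      N[same] <- N[same] + 0.25 * (dd_same - 0)
    } else {
      # base term used above was f(s_i, s_k) = f(s, s) = (1 + F_s) / 2
      Fs <- 2 * diag(A)[sire_idx] - 1
      corr <- 0.25 * (1 - 0.5 * (1 + Fs))            # per new female i
      idx <- which(same, arr.ind = TRUE)
      N[idx] <- N[idx] + corr[idx[, 1L]]
    }
  }
  diag(N) <- 0.5 * (1 + Fnew)

  out <- matrix(0, m + n, m + n)
  out[seq_len(m), seq_len(m)] <- A
  out[m + seq_len(n), seq_len(m)] <- M
  out[seq_len(m), m + seq_len(n)] <- t(M)
  out[m + seq_len(n), m + seq_len(n)] <- N
  list(A = out, new_idx = m + seq_len(n), F = Fnew)
}
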