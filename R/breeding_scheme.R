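# Annual cycle of the closed breeding program: reproduction, winter
# mortality, phenotyping, selection of breeding queens (mass or within
# maternal line), two-step selection of drone-producing queens (DPQ), and
# mating. Generation interval is 1 year on the dam path and 2 years on the
# sire path: queens born in year t are daughters of queens born in year t-1
# and (from year 4 on) granddaughters, via drones, of DPQ born in year t-2.

#' Demographic and selection configuration of the breeding scheme
#'
#' Defaults mirror a small national breeding program: 6 breeding queens each
#' producing 24 virgin queens and 36 potential DPQ per year; a first winter
#' randomly removes 25% of all colonies (leaving 108 candidate colonies and
#' 162 potential DPQ for phenotyping) and a second winter removes 33% of the
#' 1-year-old potential DPQ (108 of the initial 216 survive both). Four DPQ
#' families of up to three sisters supply all drones, each family siring an
#' equal share of queens.
#'
#' @param n_breeding_queens Number of breeding queens selected each year.
#' @param n_virgin_per_bq Virgin queens produced per breeding queen.
#' @param n_pdpq_per_bq Potential DPQ produced per breeding queen.
#' @param first_winter_survival Fraction of colonies surviving the first
#'   winter (fixed-count cull).
#' @param second_winter_survival Fraction of 1-year-old potential DPQ
#'   surviving the second winter.
#' @param n_dpq_families Number of DPQ sib groups selected.
#' @param n_dpq_per_family Maximum DPQ retained per selected sib group.
#' @param n_drones_per_queen Polyandry level nD (1, 8, 16, ...).
#' @param selection_strategy `"mass"` (best colonies population-wide) or
#'   `"within_line"` (best colony within each maternal line).
#' @param burn_in_years Years during which queens are mated to unrelated
#'   environment drones before the population closes on the sire path.
#' @param total_years Number of simulated birth cohorts.
#' @param random_selection If `TRUE`, breeding queens and DPQ are chosen at
#'   random instead of by performance (drift-only control).
#' @param include_pdpq_in_performance If `TRUE`, yearly performance
#'   statistics include potential-DPQ colonies in addition to the candidate
#'   colonies.
#' @return A list of class `scheme_config` with the above fields plus the
#'   derived cohort sizes (`n_virgin`, `n_candidates`, `n_pdpq`,
#'   `n_pdpq_phenotyped`, `n_pdpq_final`).
#' @export
scheme_config <- function(n_breeding_queens = 6L,
                          n_virgin_per_bq = 24L,
                          n_pdpq_per_bq = 36L,
                          first_winter_survival = 0.75,
                          second_winter_survival = 2 / 3,
                          n_dpq_families = 4L,
                          n_dpq_per_family = 3L,
                          n_drones_per_queen = 8L,
                          selection_strategy = c("within_line", "mass"),
                          burn_in_years = 3L,
                          total_years = 23L,
                          random_selection = FALSE,
                          include_pdpq_in_performance = FALSE) {
  selection_strategy <- match.arg(selection_strategy)
  stopifnot(n_breeding_queens >= 1, n_virgin_per_bq >= 1, n_pdpq_per_bq >= 1,
            first_winter_survival > 0, first_winter_survival <= 1,
            second_winter_survival > 0, second_winter_survival <= 1,
            n_dpq_families >= 1, n_dpq_families <= n_breeding_queens,
            n_dpq_per_family >= 1, n_drones_per_queen >= 1,
            burn_in_years >= 1, total_years > burn_in_years)
  cfg <- list(
    n_breeding_queens = as.integer(n_breeding_queens),
    n_virgin_per_bq = as.integer(n_virgin_per_bq),
    n_pdpq_per_bq = as.integer(n_pdpq_per_bq),
    first_winter_survival = first_winter_survival,
    second_winter_survival = second_winter_survival,
    n_dpq_families = as.integer(n_dpq_families),
    n_dpq_per_family = as.integer(n_dpq_per_family),
    n_drones_per_queen = as.integer(n_drones_per_queen),
    selection_strategy = selection_strategy,
    burn_in_years = as.integer(burn_in_years),
    total_years = as.integer(total_years),
    random_selection = isTRUE(random_selection),
    include_pdpq_in_performance = isTRUE(include_pdpq_in_performance)
  )
  cfg$n_virgin <- cfg$n_breeding_queens * cfg$n_virgin_per_bq
  cfg$n_pdpq <- cfg$n_breeding_queens * cfg$n_pdpq_per_bq
  cfg$n_candidates <- as.integer(round(cfg$n_virgin * first_winter_survival))
  cfg$n_pdpq_phenotyped <- as.integer(round(cfg$n_pdpq * first_winter_survival))
  cfg$n_pdpq_final <-
    as.integer(round(cfg$n_pdpq_phenotyped * second_winter_survival))
  class(cfg) <- "scheme_config"
  cfg
}

#' Fixed-count winter cull
#'
#' Winter mortality removes a fixed number of colonies chosen uniformly at
#' random: the count of survivors is deterministic, their identity random.
#'
#' @param ids Vector of colony/queen identifiers.
#' @param survivor_count Number of survivors (<= `length(ids)`).
#' @return The surviving ids (order of `ids` preserved).
#' @export
winter_cull <- function(ids, survivor_count) {
  n <- length(ids)
  if (survivor_count > n) stop("survivor_count exceeds number of colonies")
  if (survivor_count == n) return(ids)
  keep <- sort(sample.int(n, survivor_count))
  ids[keep]
}

#' Select breeding queens by mass or within-line selection
#'
#' Mass selection takes the best `n_select` colonies population-wide.
#' Within-line selection takes the best candidate of each maternal line; if
#' a line has no surviving candidate, a randomly chosen line with spare
#' candidates is split: its next-best candidate is also selected and founds
#' a new line under the vacated label, so the number of lines is conserved.
#' Ties in performance are broken uniformly at random.
#'
#' @param candidates A data.frame with columns `performance` and `line`
#'   (integer labels `1:n_select` under within-line selection).
#' @param strategy `"mass"`, `"within_line"`, or `"random"`.
#' @param n_select Number of queens to select.
#' @return A list with `index` (row indices of the selected queens, ordered
#'   by their assigned line/slot) and `line` (maternal-line label each
#'   selected queen carries forward).
#' @export
select_breeding_queens <- function(candidates, strategy, n_select = 6L) {
  stopifnot(is.data.frame(candidates),
            all(c("performance", "line") %in% names(candidates)))
  n <- nrow(candidates)
  if (n < n_select) stop("replicate failure: fewer candidates than breeding queens")
  strategy <- match.arg(strategy, c("mass", "within_line", "random"))
  ord <- order(-candidates$performance, sample.int(n))  # random tie-break
  if (strategy == "random") {
    idx <- sample.int(n, n_select)
    return(list(index = idx, line = candidates$line[idx]))
  }
  if (strategy == "mass") {
    idx <- ord[seq_len(n_select)]
    return(list(index = idx, line = candidates$line[idx]))
  }
  # within_line: best per line, split a random line for each extinct one
  lines <- seq_len(n_select)
  ranked_by_line <- split(ord, factor(candidates$line[ord], levels = lines))
  taken <- integer(n_select)            # candidates consumed per line
  idx <- integer(0); lab <- integer(0)
  for (ln in lines) {
    if (length(ranked_by_line[[ln]]) >= 1L) {
      idx <- c(idx, ranked_by_line[[ln]][1L])
      lab <- c(lab, ln)
      taken[ln] <- 1L
    }
  }
  missing <- setdiff(lines, lab)
  for (ln in missing) {
    avail <- which(vapply(lines, function(l)
      length(ranked_by_line[[l]]) > taken[l], logical(1)))
    if (!length(avail)) stop("replicate failure: no line left to split")
    donor <- if (length(avail) == 1L) avail else sample(avail, 1L)
    taken[donor] <- taken[donor] + 1L
    idx <- c(idx, ranked_by_line[[donor]][taken[donor]])
    lab <- c(lab, ln)                   # relabel: new line under vacated label
  }
  o <- order(lab)
  list(index = idx[o], line = lab[o])
}

#' Two-step selection of drone-producing queens
#'
#' Step 1 ranks the sib groups (families) by the mean performance of their
#' phenotyped members (first-winter survivors) and selects the
#' `n_families` best-ranking families that still have at least one
#' second-winter survivor. Step 2 keeps, within each selected family, the
#' up-to-`n_per_family` best performers among the second-winter survivors;
#' if only one or two sisters survive, all of them are used (the family
#' still supplies its full share of drones).
#'
#' @param pdpq A data.frame with columns `family`, `performance`, and
#'   `survived2` (logical, survived the second winter); one row per
#'   phenotyped potential DPQ.
#' @param n_families Number of sib groups to select.
#' @param n_per_family Maximum DPQ per selected sib group.
#' @param random If `TRUE`, families and queens are chosen at random among
#'   those with second-winter survivors (drift-only control).
#' @return Row indices into `pdpq` of the selected DPQ, with the family of
#'   each retained in `attr(, "family")`.
#' @export
select_dpq <- function(pdpq, n_families = 4L, n_per_family = 3L,
                       random = FALSE) {
  stopifnot(is.data.frame(pdpq),
            all(c("family", "performance", "survived2") %in% names(pdpq)))
  fams <- sort(unique(pdpq$family))
  fam_mean <- vapply(fams, function(f)
    mean(pdpq$performance[pdpq$family == f]), numeric(1))
  has_surv <- vapply(fams, function(f)
    any(pdpq$survived2[pdpq$family == f]), logical(1))
  if (sum(has_surv) < n_families)
    stop("replicate failure: fewer than ", n_families,
         " DPQ families with second-winter survivors")
  fam_order <- if (random) {
    sample(fams)
  } else {
    fams[order(-fam_mean, sample.int(length(fams)))]
  }
  chosen_fams <- fam_order[has_surv[match(fam_order, fams)]][seq_len(n_families)]
  idx <- integer(0); fam_of <- integer(0)
  for (f in chosen_fams) {
    rows <- which(pdpq$family == f & pdpq$survived2)
    o <- if (random) {
      sample(rows)
    } else {
      rows[order(-pdpq$performance[rows], sample.int(length(rows)))]
    }
    kept <- o[seq_len(min(n_per_family, length(o)))]
    idx <- c(idx, kept)
    fam_of <- c(fam_of, rep(f, length(kept)))
  }
  attr(idx, "family") <- fam_of
  idx
}

#' Assign drone sources to a cohort of new queens
#'
#' Each queen is inseminated by `n_drones` drones all bred by a single DPQ.
#' The selected DPQ families sire equal numbers of queens (balanced
#' assignment at the family level, randomized over queens); within a family
#' the DPQ is drawn uniformly per queen.
#'
#' @param n_queens Number of queens to mate.
#' @param dpq_family Integer vector: family of each available DPQ.
#' @return Integer vector of length `n_queens`: for each queen the index of
#'   the DPQ (into `dpq_family`) providing her drones.
#' @export
assign_drone_sources <- function(n_queens, dpq_family) {
  fams <- unique(dpq_family)
  fam_assign <- sample(rep(fams, length.out = n_queens))
  src <- integer(n_queens)
  for (f in fams) {
    rows <- which(dpq_family == f)
    qs <- which(fam_assign == f)
    src[qs] <- rows[sample.int(length(rows), length(qs), replace = TRUE)]
  }
  src
}

# Generate the mate drones of a cohort: n queens, source DPQ per queen.
# Returns list(dir = n x nD, mat = n x nD) of drone breeding values.
make_mate_drones <- function(setup, n, n_drones, src_bv = NULL, src_F = NULL) {
  total <- n * n_drones
  if (is.null(src_bv)) {                      # environment drones
    d <- sample_environment_drones(setup, total)
    return(list(dir = matrix(d[, "dir"], n, n_drones),
                mat = matrix(d[, "mat"], n, n_drones)))
  }
  phi <- meiosis_terms(setup, rep(src_F, times = n_drones))
  list(dir = matrix(0.5 * rep(src_bv[, "dir"], times = n_drones) + phi[, "dir"],
                    n, n_drones),
       mat = matrix(0.5 * rep(src_bv[, "mat"], times = n_drones) + phi[, "mat"],
                    n, n_drones))
}

#' Run one replicate of the breeding scheme
#'
#' Simulates `total_years` birth cohorts. The year-1 cohort consists of
#' unrelated, non-inbred queens drawn from the wild base population,
#' partitioned into `n_breeding_queens` maternal lines; during the build-up
#' years all queens are mated to environment drones, afterwards to drones
#' bred by DPQ selected within the (then closed) population. A cohort born
#' in year t
#' overwinters, is phenotyped in year t+1 (performance attributed to year
#' t+1), and supplies the next breeding queens (dam path, 1-year interval)
#' and, two years after birth, the DPQ (sire path, 2-year interval).
#'
#' @param setup A [genetic_setup()] object.
#' @param config A [scheme_config()] object.
#' @param seed Optional integer seed (a single stream drives the replicate).
#' @param track_pedigree If `TRUE`, the realized pedigree (queens and
#'   drones) and every queen's inbreeding coefficient are attached to the
#'   result as attributes `pedigree` and `queen_F`, in the format accepted
#'   by [gene_drop_kinship()]. Intended for validation on short runs.
#' @return A data.frame with one row per birth year: mean inbreeding
#'   (`mean_F`), means/variances of direct and maternal breeding values and
#'   their correlation over all queens born that year, and mean/variance of
#'   colony performance (`mean_P`, `var_P`, attributed to `perf_year` =
#'   birth year + 1) over the phenotyped candidate colonies.
#' @export
run_replicate <- function(setup, config = scheme_config(), seed = NULL,
                          track_pedigree = FALSE) {
  stopifnot(inherits(setup, "genetic_setup"), inherits(config, "scheme_config"))
  if (!is.null(seed)) set.seed(seed)
  nB <- config$n_breeding_queens
  nD <- config$n_drones_per_queen
  n_per_bq <- config$n_virgin_per_bq + config$n_pdpq_per_bq
  n <- nB * n_per_bq
  years <- config$total_years

  rec <- data.frame(
    year = seq_len(years), perf_year = seq_len(years) + 1L,
    mean_F = NA_real_, mean_bv_dir = NA_real_, mean_bv_mat = NA_real_,
    var_bv_dir = NA_real_, var_bv_mat = NA_real_, cor_bv = NA_real_,
    mean_P = NA_real_, var_P = NA_real_, n_colonies = NA_integer_
  )

  A <- matrix(numeric(0), 0L, 0L)
  bq <- NULL          # breeding queens producing the current cohort
  prev <- NULL        # cohort born t-1
  pdpq_old <- NULL    # potential DPQ born t-2 (phenotyped, pre 2nd winter)
  next_id <- 1L       # global individual ids (queens and drones)
  ped <- list(); f_tab <- list()

  for (t in seq_len(years + 1L)) {
    ## -- phenotype cohort t-1 (performance year t) ------------------------
    if (!is.null(prev)) {
      ph <- prev$alive | prev$pdpq_alive
      worker_dir <- 0.5 * prev$bv[ph, "dir"] + rowMeans(prev$mates_dir[ph, , drop = FALSE])
      perf <- colony_performance(prev$bv[ph, "mat"], worker_dir, setup)
      prev$perf <- rep(NA_real_, n)
      prev$perf[ph] <- perf$performance
      stat_rows <- if (config$include_pdpq_in_performance) ph else prev$alive
      rec$mean_P[t - 1L] <- mean(prev$perf[stat_rows])
      rec$var_P[t - 1L] <- stats::var(prev$perf[stat_rows])
      rec$n_colonies[t - 1L] <- sum(stat_rows)
    }
    if (t > years) break

    ## -- select breeding queens from last year's candidates ---------------
    if (!is.null(prev)) {
      cand <- which(prev$alive)
      sel <- select_breeding_queens(
        data.frame(performance = prev$perf[cand], line = prev$line[cand]),
        strategy = if (config$random_selection) "random" else config$selection_strategy,
        n_select = nB)
      pick <- cand[sel$index]
      bq <- list(bv = prev$bv[pick, , drop = FALSE], F_own = prev$F[pick],
                 f_mate = prev$f_mate[pick], line = sel$line,
                 a_idx = prev$a_idx[pick], src_aidx = prev$src_aidx[pick],
                 qid = prev$qid[pick],
                 mate_ids = prev$mate_ids[pick, , drop = FALSE],
                 mates_dir = prev$mates_dir[pick, , drop = FALSE],
                 mates_mat = prev$mates_mat[pick, , drop = FALSE])
    }

    ## -- DPQ selection (population closed on the sire path from year 4) ---
    dpq <- NULL
    if (t > config$burn_in_years) {
      if (is.null(pdpq_old)) stop("replicate failure: no DPQ cohort available")
      surv2 <- winter_cull(seq_len(pdpq_old$n), config$n_pdpq_final)
      pdpq_old$survived2 <- seq_len(pdpq_old$n) %in% surv2
      di <- select_dpq(
        data.frame(family = pdpq_old$family, performance = pdpq_old$perf,
                   survived2 = pdpq_old$survived2),
        n_families = config$n_dpq_families,
        n_per_family = config$n_dpq_per_family,
        random = config$random_selection)
      dpq <- list(bv = pdpq_old$bv[di, , drop = FALSE], F = pdpq_old$F[di],
                  a_idx = pdpq_old$a_idx[di], family = attr(di, "family"),
                  qid = pdpq_old$qid[di])
    }

    ## -- reproduction -------------------------------------------------------
    is_pdpq <- rep(c(rep(FALSE, config$n_virgin_per_bq),
                     rep(TRUE, config$n_pdpq_per_bq)), nB)
    if (t == 1L) {
      ## initial population: unrelated wild queens split into maternal lines
      line <- rep(seq_len(nB), each = n_per_bq)
      A <- diag(0.5, n)
      cohort <- list(n = n, bv = sample_base_queens(setup, n),
                     F = rep(0, n), line = line, family = line,
                     is_pdpq = is_pdpq, a_idx = seq_len(n))
      dam_qid <- integer(n); sire_qid <- integer(n)   # founders
    } else {
      dam <- rep(seq_len(nB), each = n_per_bq)
      slot <- sample.int(nD, n, replace = TRUE) # sire drone among dam's mates
      sire_bv <- cbind(dir = bq$mates_dir[cbind(dam, slot)],
                       mat = bq$mates_mat[cbind(dam, slot)])
      phi <- meiosis_terms(setup, bq$F_own[dam])
      bv <- queen_bv(bq$bv[dam, , drop = FALSE], sire_bv, phi)

      ext <- extend_cohort_coancestry(
        A, dam_idx = bq$a_idx[dam], sire_idx = bq$src_aidx[dam],
        drone_key = dam * (nD + 1L) + slot)
      A <- ext$A

      cohort <- list(
        n = n, bv = bv, F = ext$F, line = bq$line[dam], family = dam,
        is_pdpq = is_pdpq, a_idx = ext$new_idx
      )
      dam_qid <- bq$qid[dam]
      sire_qid <- bq$mate_ids[cbind(dam, slot)]
    }
    cohort$qid <- next_id + seq_len(n) - 1L
    next_id <- next_id + n
    if (track_pedigree) {
      ped[[length(ped) + 1L]] <- data.frame(
        id = cohort$qid, dam = dam_qid, sire = sire_qid,
        ploidy = 2L, birth_year = t)
      f_tab[[length(f_tab) + 1L]] <- data.frame(
        id = cohort$qid, year = t, F = cohort$F)
    }
    rec$mean_F[t] <- mean(cohort$F)
    rec$mean_bv_dir[t] <- mean(cohort$bv[, "dir"])
    rec$mean_bv_mat[t] <- mean(cohort$bv[, "mat"])
    rec$var_bv_dir[t] <- stats::var(cohort$bv[, "dir"])
    rec$var_bv_mat[t] <- stats::var(cohort$bv[, "mat"])
    rec$cor_bv[t] <- if (rec$var_bv_dir[t] > 0 && rec$var_bv_mat[t] > 0)
      stats::cor(cohort$bv[, "dir"], cohort$bv[, "mat"]) else NA_real_

    ## -- mating ------------------------------------------------------------
    if (t <= config$burn_in_years) {
      mates <- make_mate_drones(setup, n, nD)
      cohort$src_aidx <- rep(NA_integer_, n)
      cohort$f_mate <- rep(0, n)
      drone_dam_qid <- integer(n)                    # environment drones
    } else {
      src <- assign_drone_sources(n, dpq$family)
      mates <- make_mate_drones(setup, n, nD,
                                src_bv = dpq$bv[src, , drop = FALSE],
                                src_F = dpq$F[src])
      cohort$src_aidx <- dpq$a_idx[src]
      cohort$f_mate <- A[cbind(cohort$a_idx, cohort$src_aidx)]
      drone_dam_qid <- dpq$qid[src]
    }
    cohort$mates_dir <- mates$dir
    cohort$mates_mat <- mates$mat
    cohort$mate_ids <- matrix(next_id + seq_len(n * nD) - 1L, n, nD)
    next_id <- next_id + n * nD
    if (track_pedigree)
      ped[[length(ped) + 1L]] <- data.frame(
        id = as.vector(cohort$mate_ids),
        dam = rep(drone_dam_qid, times = nD), sire = 0L,
        ploidy = 1L, birth_year = t)

    ## -- first winter -------------------------------------------------------
    virgins <- which(!is_pdpq)
    pdpqs <- which(is_pdpq)
    cohort$alive <- seq_len(n) %in% winter_cull(virgins, config$n_candidates)
    cohort$pdpq_alive <- seq_len(n) %in%
      winter_cull(pdpqs, config$n_pdpq_phenotyped)

    ## -- roll state and prune the coancestry matrix -------------------------
    if (!is.null(prev)) {
      keep_pdpq <- which(prev$pdpq_alive)
      pdpq_old <- list(
        n = length(keep_pdpq), bv = prev$bv[keep_pdpq, , drop = FALSE],
        F = prev$F[keep_pdpq], family = prev$family[keep_pdpq],
        perf = prev$perf[keep_pdpq], a_idx = prev$a_idx[keep_pdpq],
        qid = prev$qid[keep_pdpq])
    }
    keep <- c(cohort$a_idx,
              if (!is.null(pdpq_old)) pdpq_old$a_idx,
              unique(cohort$src_aidx[!is.na(cohort$src_aidx)]))
    keep <- unique(keep)
    A <- A[keep, keep, drop = FALSE]
    remap <- match(seq_len(max(keep)), keep)
    cohort$a_idx <- remap[cohort$a_idx]
    if (!is.null(pdpq_old)) pdpq_old$a_idx <- remap[pdpq_old$a_idx]
    cohort$src_aidx <- ifelse(is.na(cohort$src_aidx), NA_integer_,
                              remap[pmax(cohort$src_aidx, 1L)])
    prev <- cohort
  }
  if (track_pedigree) {
    attr(rec, "pedigree") <- do.call(rbind, ped)
    attr(rec, "queen_F") <- do.call(rbind, f_tab)
  }
  rec
}
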