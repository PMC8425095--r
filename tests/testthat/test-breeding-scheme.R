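# Demography, winter mortality, queen and DPQ selection, and the annual
# cycle as a whole.

test_that("winter cull removes a fixed count at random", {
  set.seed(1)
  expect_length(winter_cull(1:144, 108L), 108L)
  expect_length(winter_cull(1:216, 162L), 162L)
  expect_identical(winter_cull(1:10, 10L), 1:10)
  expect_error(winter_cull(1:5, 6L), "exceeds")
  # identity random, count deterministic
  s <- replicate(20, length(winter_cull(1:144, 108L)))
  expect_true(all(s == 108L))
})

test_that("mass selection takes the overall best colonies", {
  set.seed(2)
  cand <- data.frame(performance = c(5, 1, 9, 3, 8, 7, 2, 6),
                     line = rep(1L, 8))
  sel <- select_breeding_queens(cand, "mass", n_select = 6L)
  expect_setequal(sel$index, c(1L, 3L, 4L, 5L, 6L, 8L))
  expect_error(select_breeding_queens(cand[1:3, ], "mass", 6L), "fewer")
})

test_that("within-line selection keeps one queen per line and splits on extinction", {
  set.seed(3)
  cand <- data.frame(performance = rnorm(60), line = rep(1:6, each = 10))
  sel <- select_breeding_queens(cand, "within_line", 6L)
  expect_identical(sort(sel$line), 1:6)
  expect_identical(cand$line[sel$index], sel$line)
  best_by_line <- as.vector(tapply(cand$performance, cand$line, max))
  expect_equal(cand$performance[sel$index], best_by_line)

  # line 4 extinct: a random surviving line contributes its two best
  cand2 <- cand[cand$line != 4L, ]
  sel2 <- select_breeding_queens(cand2, "within_line", 6L)
  expect_identical(sort(sel2$line), 1:6)   # registry still has 6 lines
  donor <- table(cand2$line[sel2$index])
  expect_identical(sort(as.integer(donor), decreasing = TRUE)[1:2], c(2L, 1L))
  # the doubled line contributes its two best candidates
  dbl <- as.integer(names(donor)[donor == 2L])
  perf_dbl <- sort(cand2$performance[cand2$line == dbl], decreasing = TRUE)
  expect_setequal(cand2$performance[sel2$index][cand2$line[sel2$index] == dbl],
                  perf_dbl[1:2])
})

test_that("DPQ selection ranks families then sisters, with survivor fallbacks", {
  set.seed(4)
  pdpq <- data.frame(family = rep(1:6, each = 27),
                     performance = rnorm(162), survived2 = TRUE)
  idx <- select_dpq(pdpq)
  expect_length(idx, 12L)
  fam <- attr(idx, "family")
  expect_equal(as.vector(table(fam)), rep(3L, 4L))
  fam_means <- tapply(pdpq$performance, pdpq$family, mean)
  expect_setequal(unique(fam), as.integer(names(sort(fam_means,
                                                     decreasing = TRUE)))[1:4])

  # the best-mean family loses all second-winter survivors: next family in
  pdpq2 <- pdpq
  best <- as.integer(names(which.max(fam_means)))
  pdpq2$survived2[pdpq2$family == best] <- FALSE
  idx2 <- select_dpq(pdpq2)
  expect_false(best %in% attr(idx2, "family"))
  expect_length(idx2, 12L)

  # a selected family with only two survivors supplies both sisters
  pdpq3 <- pdpq
  keep2 <- which(pdpq3$family == best)[1:2]
  pdpq3$survived2[pdpq3$family == best] <- FALSE
  pdpq3$survived2[keep2] <- TRUE
  idx3 <- select_dpq(pdpq3)
  expect_equal(sum(attr(idx3, "family") == best), 2L)
  expect_length(idx3, 11L)

  pdpq4 <- pdpq
  pdpq4$survived2[pdpq4$family %in% 1:3] <- FALSE
  expect_error(select_dpq(pdpq4), "replicate failure")
})

test_that("drone sources are balanced across DPQ families", {
  set.seed(5)
  fam <- rep(1:4, times = c(3, 3, 2, 3))
  src <- assign_drone_sources(360L, fam)
  expect_equal(as.vector(table(fam[src])), rep(90L, 4L))
  expect_true(all(src %in% seq_along(fam)))
})

test_that("the annual cycle reproduces the demographic counts and burn-in", {
  gs <- preset_genetic_setup(1)
  cfg <- scheme_config(n_drones_per_queen = 8L, total_years = 8L)
  r <- run_replicate(gs, cfg, seed = 99)
  expect_equal(nrow(r), 8L)
  expect_equal(r$perf_year, r$year + 1L)
  expect_true(all(r$n_colonies == 108L))
  # population open on the sire path through year 4: dams of cohorts 2-4
  # were env-mated, so inbreeding can first appear in cohort 5
  expect_true(all(r$mean_F[1:4] == 0))
  expect_gt(r$mean_F[8], 0)
})

test_that("replicates are exactly reproducible from their seed", {
  gs <- preset_genetic_setup(2)
  cfg <- scheme_config(n_drones_per_queen = 1L, selection_strategy = "mass",
                       total_years = 6L)
  r1 <- run_replicate(gs, cfg, seed = 1234)
  r2 <- run_replicate(gs, cfg, seed = 1234)
  expect_identical(r1, r2)
  r3 <- run_replicate(gs, cfg, seed = 1235)
  expect_false(identical(r1, r3))
})

test_that("zero genetic variance propagates to all-zero breeding values", {
  gs0 <- genetic_setup(0, 0, 0, 30)
  r <- run_replicate(gs0, scheme_config(total_years = 5L), seed = 8)
  expect_true(all(r$mean_bv_dir == 0))
  expect_true(all(r$var_bv_mat == 0))
  expect_true(all(r$mean_F[1:4] == 0))
})

test_that("every queen's F matches the tabular method on the realized pedigree", {
  gs <- preset_genetic_setup(1)
  cfg <- scheme_config(n_virgin_per_bq = 4L, n_pdpq_per_bq = 6L,
                       n_drones_per_queen = 2L, selection_strategy = "mass",
                       total_years = 7L)
  r <- run_replicate(gs, cfg, seed = 2024, track_pedigree = TRUE)
  ped <- attr(r, "pedigree")
  qf <- attr(r, "queen_F")
  expect_gt(max(qf$F), 0)   # inbreeding has appeared by year 7

  # rebuild the full (unpruned) coancestry table with explicit drones
  kt <- kinship_table(capacity = nrow(ped))
  for (i in seq_len(nrow(ped))) {
    if (ped$ploidy[i] == 1L) {
      dam <- if (ped$dam[i] == 0L) "environment" else ped$dam[i]
      kt_add_drone(kt, dam, birth_year = ped$birth_year[i])
    } else if (ped$dam[i] == 0L) {
      kt_add_founder_female(kt, birth_year = ped$birth_year[i])
    } else {
      kt_add_female(kt, ped$dam[i], ped$sire[i],
                    birth_year = ped$birth_year[i])
    }
  }
  f_ref <- vapply(qf$id, function(id) kt_inbreeding(kt, id), numeric(1))
  expect_equal(qf$F, f_ref, tolerance = 1e-12)

  # and an independent gene-drop spot check on the most inbred queen
  worst <- qf$id[which.max(qf$F)]
  gd <- gene_drop_kinship(ped, c(ped$dam[ped$id == worst],
                                 ped$sire[ped$id == worst]), n_reps = 2e4)
  expect_lt(abs(gd$estimate - max(qf$F)), 3 * gd$se + 1e-3)
})

test_that("disabling selection leaves no systematic genetic trend", {
  gs <- preset_genetic_setup(1)
  cfg <- scheme_config(n_drones_per_queen = 8L, random_selection = TRUE,
                       total_years = 23L)
  set.seed(31)
  reps <- vapply(sample.int(1e6, 8), function(s) {
    r <- run_replicate(gs, cfg, seed = s)
    r$mean_bv_dir[nrow(r)] / sqrt(gs$var_dir)
  }, numeric(1))
  tstat <- mean(reps) / (sd(reps) / sqrt(length(reps)))
  expect_lt(abs(tstat), 4)
})
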