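# Tabular haplodiploid coancestry: recursion rules, pruning, gene-drop
# validation, and equivalence of the vectorized cohort update.

test_that("founders, drones and daughters follow the tabular recursion rules", {
  kt <- kinship_table()
  a <- kt_add_founder_female(kt)
  b <- kt_add_founder_female(kt)
  expect_equal(kt_coancestry(kt, a, a), 0.5)
  expect_equal(kt_coancestry(kt, a, b), 0)
  expect_equal(kt_inbreeding(kt, a), 0)

  # drones are gametes of their dam
  d1 <- kt_add_drone(kt, a)
  d2 <- kt_add_drone(kt, a)
  expect_equal(kt_coancestry(kt, d1, a), 0.5)
  expect_equal(kt_coancestry(kt, d1, d2), 0.5)
  expect_equal(kt_coancestry(kt, d1, d1), 1)
  e1 <- kt_add_drone(kt, "environment")
  expect_equal(kt_coancestry(kt, e1, a), 0)
  expect_equal(kt_coancestry(kt, e1, e1), 1)

  # super-sisters: same dam, same sire drone
  s1 <- kt_add_female(kt, b, e1)
  s2 <- kt_add_female(kt, b, e1)
  expect_equal(kt_relationship(kt, s1, s2), 0.75)
  # maternal half-sisters via unrelated sire drones
  e2 <- kt_add_drone(kt, "environment")
  h <- kt_add_female(kt, b, e2)
  expect_equal(kt_relationship(kt, s1, h), 0.25)

  # dam mated to her own son
  son <- kt_add_drone(kt, b)
  expect_equal(kt_inbreeding_of_cross(kt, b, son), 0.5)
  inc <- kt_add_female(kt, b, son)
  expect_equal(kt_inbreeding(kt, inc), 0.5)
  expect_equal(kt_coancestry(kt, inc, inc), 0.75)

  expect_error(kt_add_female(kt, 9999L, son), "unknown")
  expect_error(kt_add_drone(kt, son), "female")
})

test_that("inbreeding is invariant to the insertion order of unrelated individuals", {
  build <- function(interleave) {
    kt <- kinship_table()
    a <- kt_add_founder_female(kt)
    d <- kt_add_drone(kt, "environment")
    if (interleave) kt_add_founder_female(kt)  # non-ancestral bystander
    f1 <- kt_add_female(kt, a, d)
    if (!interleave) kt_add_founder_female(kt)
    s <- kt_add_drone(kt, f1)
    g <- kt_add_female(kt, f1, s)
    kt_inbreeding(kt, g)
  }
  expect_identical(build(TRUE), build(FALSE))
})

test_that("pruning preserves retained coancestry exactly", {
  # six-generation chain of dam x environment-drone matings with an
  # occasional within-family cross to create inbreeding
  set.seed(11)
  kt <- kinship_table()
  dam <- kt_add_founder_female(kt, birth_year = 0L)
  for (g in 1:6) {
    sire <- if (g %% 2 == 0) kt_add_drone(kt, dam, birth_year = g)
            else kt_add_drone(kt, "environment", birth_year = g)
    dam <- kt_add_female(kt, dam, sire, birth_year = g)
  }
  f_unpruned <- kt_inbreeding(kt, dam)
  n_before <- kt_size(kt)
  kt_prune(kt, current_year = 6L, keep_generations = 3L)
  expect_lte(kt_size(kt), n_before)
  expect_identical(kt_inbreeding(kt, dam), f_unpruned)

  # shallow pedigree: pruning is the identity
  kt2 <- kinship_table()
  x <- kt_add_founder_female(kt2, birth_year = 0L)
  y <- kt_add_drone(kt2, x, birth_year = 0L)
  kt_prune(kt2, current_year = 1L, keep_generations = 3L)
  expect_equal(kt_size(kt2), 2L)

  # pruned table keeps supporting new additions with unchanged F
  kt3 <- kinship_table()
  a <- kt_add_founder_female(kt3, birth_year = 0L)
  chain <- a
  for (g in 1:5) {
    s <- kt_add_drone(kt3, chain, birth_year = g)
    chain <- kt_add_female(kt3, chain, s, birth_year = g)
  }
  son <- kt_add_drone(kt3, chain, birth_year = 5L)
  ref <- kt_coancestry(kt3, chain, son)
  kt_prune(kt3, current_year = 5L, keep_generations = 2L)
  daughter <- kt_add_female(kt3, chain, son, birth_year = 6L)
  expect_identical(kt_inbreeding(kt3, daughter), ref)
})

test_that("gene dropping reproduces tabular coancestry on fixed pedigrees", {
  set.seed(42)
  kt <- kinship_table()
  dam <- kt_add_founder_female(kt)
  sire <- kt_add_drone(kt, "environment")
  s1 <- kt_add_female(kt, dam, sire)
  s2 <- kt_add_female(kt, dam, sire)
  ped <- kt_pedigree(kt)
  # founder pair and drone self-pair are exact
  expect_equal(gene_drop_kinship(ped, c(dam, sire), n_reps = 500)$estimate, 0)
  expect_equal(gene_drop_kinship(ped, c(sire, sire), n_reps = 500)$estimate, 1)
  gd <- gene_drop_kinship(ped, c(s1, s2), n_reps = 2e4)
  expect_lt(abs(gd$estimate - 0.375), 3 * gd$se)
})

test_that("tabular coancestry matches gene dropping on random pedigrees", {
  set.seed(99)
  for (i in 1:6) {
    kt <- random_haplodiploid_pedigree(n_founders = 4L, n_extra = 18L)
    expect_lt(compare_tabular_genedrop(kt, n_pairs = 3L, n_reps = 1e4), 3.6)
  }
})

test_that("the female relationship submatrix is positive semi-definite", {
  set.seed(5)
  for (i in 1:4) {
    kt <- random_haplodiploid_pedigree(n_founders = 3L, n_extra = 15L)
    idx <- which(kt$ploidy[seq_len(kt$n)] == 2L)
    A2 <- 2 * kt$f[idx, idx]
    ev <- eigen(A2, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("vectorized cohort update equals explicit tabular bookkeeping", {
  set.seed(123)
  # explicit table: 3 dams, 2 DPQs, drones, then daughters
  kt <- kinship_table()
  f0 <- kt_add_founder_female(kt)
  e0 <- kt_add_drone(kt, "environment")
  dams <- c(kt_add_female(kt, f0, e0), kt_add_female(kt, f0, e0),
            kt_add_founder_female(kt))
  dpqs <- c(kt_add_female(kt, f0, e0), kt_add_founder_female(kt))
  # matrix route operates on the females only, in table insertion order
  females <- c(f0, dams, dpqs)
  A <- kt$f[match(females, kt_ids(kt)), match(females, kt_ids(kt))]

  # each dam is mated to 2 drones of one DPQ; daughters pick a drone
  dam_of <- c(1L, 1L, 2L, 3L, 3L, 3L)          # index into dams
  dpq_of <- c(1L, 1L, 1L, 2L, 2L, 2L)          # dam's drone source
  slot_of <- c(1L, 1L, 2L, 1L, 2L, 1L)         # which of the 2 drones
  ext <- beebreedsim:::extend_cohort_coancestry(
    A,
    dam_idx = match(dams[dam_of], females),
    sire_idx = match(dpqs[dpq_of], females),
    drone_key = dam_of * 10L + slot_of)

  # same structure via explicit drones in the tabular table
  drone_ids <- matrix(NA_integer_, 3, 2)
  for (d in 1:3) for (s in 1:2)
    drone_ids[d, s] <- kt_add_drone(kt, dpqs[dpq_of[match(d, dam_of)]])
  girls <- vapply(seq_along(dam_of), function(i)
    kt_add_female(kt, dams[dam_of[i]], drone_ids[dam_of[i], slot_of[i]]),
    integer(1))

  for (i in seq_along(girls)) {
    expect_equal(ext$F[i], kt_inbreeding(kt, girls[i]))
    for (j in seq_along(girls))
      expect_equal(ext$A[ext$new_idx[i], ext$new_idx[j]],
                   kt_coancestry(kt, girls[i], girls[j]))
    for (j in seq_along(females))
      expect_equal(ext$A[ext$new_idx[i], j],
                   kt_coancestry(kt, girls[i], females[j]))
  }

  # environment-sired cohort: zero F, quarter kinship between half sisters,
  # three-eighths between super-sisters
  ext0 <- beebreedsim:::extend_cohort_coancestry(
    A, dam_idx = rep(match(dams[3], females), 3),
    sire_idx = rep(NA_integer_, 3), drone_key = c(1L, 1L, 2L))
  expect_equal(ext0$F, rep(0, 3))
  expect_equal(ext0$A[ext0$new_idx[1], ext0$new_idx[2]], 0.375)
  expect_equal(ext0$A[ext0$new_idx[1], ext0$new_idx[3]],
               0.25 * A[match(dams[3], females), match(dams[3], females)] + 0)
})
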