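# Shared test utilities: breeding-value matrix shorthand, random
# haplodiploid pedigrees and a comparator
# between the tabular coancestry table and the gene-drop oracle.

as_bv_mat <- function(v) {
  matrix(v, 1L, 2L, dimnames = list(NULL, c("dir", "mat")))
}

# Build a random haplodiploid pedigree of roughly `n_extra` non-founder
# individuals on top of a founder layer, mixing drones (incl. environment
# drones) and females. Returns the kinship_table.
random_haplodiploid_pedigree <- function(n_founders = 4L, n_extra = 20L,
                                         p_drone = 0.45, p_env = 0.15) {
  kt <- kinship_table()
  females <- vapply(seq_len(n_founders), function(i)
    kt_add_founder_female(kt, birth_year = 0L), integer(1))
  pick1 <- function(x) x[sample.int(length(x), 1L)]
  drones <- integer(0)
  for (k in seq_len(n_extra)) {
    yr <- k %/% 5L
    if (stats::runif(1) < p_drone || !length(drones)) {
      dam <- if (stats::runif(1) < p_env) "environment" else pick1(females)
      drones <- c(drones, kt_add_drone(kt, dam, birth_year = yr))
    } else {
      females <- c(females,
                   kt_add_female(kt, pick1(females), pick1(drones),
                                 birth_year = yr))
    }
  }
  kt
}

# Compare tabular coancestry with the gene-drop estimate for `n_pairs`
# random pairs of a table; returns max |z| over compared pairs.
compare_tabular_genedrop <- function(kt, n_pairs = 4L, n_reps = 1e4) {
  ped <- kt_pedigree(kt)
  ids <- kt_ids(kt)
  zmax <- 0
  for (p in seq_len(n_pairs)) {
    pair <- sample(ids, 2L)
    f_tab <- kt_coancestry(kt, pair[1L], pair[2L])
    gd <- gene_drop_kinship(ped, pair, n_reps = n_reps)
    se <- max(gd$se, 1e-6)   # exact-zero pairs have zero empirical SE
    zmax <- max(zmax, abs(gd$estimate - f_tab) / se)
  }
  zmax
}
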