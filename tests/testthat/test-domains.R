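# build a fold_result from an explicit structure (bypassing the folder) so
# coordinate rules can be tested against hand-constructed registers
manual_fold <- function(sequence, dotbracket) {
  structure(
    list(sequence = sequence, dotbracket = dotbracket,
         pair_table = dotbracket_to_pairs(dotbracket),
         delta_g = NA_real_),
    class = "fold_result"
  )
}

# hairpin whose stem runs (21..40) paired with (61..80), loop 41..60 unpaired
toy_hairpin <- function(len = 100) {
  db <- rep(".", len)
  db[21:40] <- "("
  db[61:80] <- ")"
  manual_fold(strrep("A", len), paste(db, collapse = ""))
}

test_that("terminal loop region starts after miR-5p and ends at its partner", {
  f <- toy_hairpin()
  # miR-5p ends at 40, which pairs with 61 -> region [41, 60]
  rec <- list(id = "t", mir5p_start = 19L, mir5p_end = 40L)
  expect_identical(terminal_loop_region(rec, f), c(41L, 60L))
  # miR-5p ends at an unpaired position: scan 5'-ward to the anchor pair
  rec2 <- list(id = "t", mir5p_start = 19L, mir5p_end = 42L)  # 41,42 unpaired
  expect_identical(terminal_loop_region(rec2, f), c(43L, 60L))
  # entirely unpaired miR-5p is an error
  rec3 <- list(id = "t", mir5p_start = 41L, mir5p_end = 50L)
  expect_error(terminal_loop_region(rec3, f), "no anchoring pair")
})

test_that("minimal hairpin gives the symmetric loop region", {
  f <- manual_fold("GGGAAAACCC", "(((....)))")
  rec <- list(id = "t", mir5p_start = 1L, mir5p_end = 3L)
  expect_identical(terminal_loop_region(rec, f), c(4L, 7L))
})

test_that("the missing 5p arm is predicted from partners with the 2-nt shift", {
  # helix with pairs u + v = 87 covering (5..26) x (61..82)
  db <- rep(".", 90)
  db[5:26] <- "("
  db[61:82] <- ")"
  f <- manual_fold(strrep("A", 90), paste(db, collapse = ""))
  rec <- list(id = "t", species = NA, sequence = strrep("A", 90),
              mir5p_start = NA_integer_, mir5p_end = NA_integer_,
              mir3p_start = 61L, mir3p_end = 82L, family = NA)
  out <- predict_missing_arm(rec, f)
  expect_identical(c(out$mir5p_start, out$mir5p_end), c(3L, 24L))
  # both arms present: identity pass-through
  rec2 <- tibble::as_tibble(rec)
  rec2$mir5p_start <- 3L; rec2$mir5p_end <- 24L
  expect_identical(predict_missing_arm(rec2, f)$mir5p_start, 3L)
  # fully unpaired annotated arm is an error
  rec3 <- rec
  rec3$mir3p_start <- 84L; rec3$mir3p_end <- 89L
  expect_error(predict_missing_arm(rec3, f), "unpaired")
})

test_that("the missing 3p arm prediction shifts toward the 3' end", {
  db <- rep(".", 90)
  db[5:26] <- "("
  db[61:82] <- ")"
  f <- manual_fold(strrep("A", 90), paste(db, collapse = ""))
  rec <- list(id = "t", species = NA, sequence = strrep("A", 90),
              mir5p_start = 5L, mir5p_end = 26L,
              mir3p_start = NA_integer_, mir3p_end = NA_integer_, family = NA)
  out <- predict_missing_arm(rec, f)
  # partners of (5, 26) are (82, 61); shifted +2 -> (63, 84)
  expect_identical(c(out$mir3p_start, out$mir3p_end), c(63L, 84L))
})

test_that("domains tile the molecule with the 12-nt proximal rule", {
  f <- toy_hairpin(130)
  rec <- list(id = "t", species = NA, sequence = strrep("A", 130),
              mir5p_start = 31L, mir5p_end = 40L,
              mir3p_start = 61L, mir3p_end = 90L, family = NA)
  part <- partition_domains(rec, f)
  expect_identical(part$pre_span, c(31L, 90L))
  expect_identical(part$proximal_domain, c(19:30, 91:102))
  expect_identical(part$distal_domain, c(1:18, 103:130))
  tiles <- sort(c(part$pre_span[1]:part$pre_span[2], part$proximal_domain,
                  part$distal_domain))
  expect_identical(tiles, 1:130)
  # duplex + loop partition the pre-miRNA
  expect_identical(
    sort(c(part$duplex_region,
           part$terminal_loop_region[1]:part$terminal_loop_region[2])),
    31:90)
})

test_that("short flanks clip the proximal domain with a warning", {
  f <- toy_hairpin(110)
  rec <- list(id = "t", species = NA, sequence = strrep("A", 110),
              mir5p_start = 8L, mir5p_end = 40L,
              mir3p_start = 61L, mir3p_end = 90L, family = NA)
  expect_warning(part <- partition_domains(rec, f), "clipped")
  expect_identical(part$proximal_domain, c(1:7, 91:102))
})

test_that("domain free energies satisfy the construction identities", {
  coh <- generate_cohort(cohort_config(n_mirnas = 12, seed = 5))
  m <- energy_model()
  for (i in seq_len(nrow(coh$records))) {
    rec <- coh$records[i, ]
    f <- fold_mfe(rec$sequence, m)
    part <- domain_deltaG(rec, f, m)
    expect_equal(part$dg_duplex + part$dg_loop, part$dg_pre,
                 tolerance = 1e-12)
    expect_identical(part$dg_pri, f$delta_g)
    expect_identical(
      region_energy(rec$sequence, f$dotbracket,
                    seq_len(nchar(rec$sequence)), m),
      f$delta_g)
  }
})

test_that("stronger basal stems lower the proximal free energy", {
  # same hairpin body, growing all-GC basal stem
  m <- energy_model()
  make <- function(b) {
    cfg <- cohort_config(n_mirnas = 1, basal_range = c(b, b),
                         gc_range = c(0.99, 0.99), upper_range = c(4L, 4L),
                         loop_range = c(6L, 6L), seed = 99)
    generate_cohort(cfg, m)
  }
  dg <- vapply(c(6L, 9L, 12L), function(b) {
    coh <- make(b)
    hairpin_features(coh$records, m)$dg_proximal
  }, numeric(1))
  expect_true(all(diff(dg) < 0))

  # enlarging the apical loop raises the terminal-loop free energy toward 0
  make_loop <- function(l, e) {
    cfg <- cohort_config(n_mirnas = 1, loop_range = c(l, l),
                         upper_range = c(e, e), gc_range = c(0.6, 0.6),
                         seed = 41)
    hairpin_features(generate_cohort(cfg, m)$records, m)$dg_loop
  }
  expect_true(make_loop(16L, 2L) > make_loop(6L, 8L))
})

test_that("cohort feature extraction is reproducible", {
  coh <- generate_cohort(cohort_config(n_mirnas = 6, seed = 77))
  a <- hairpin_features(coh$records)
  b <- hairpin_features(coh$records)
  expect_identical(a, b)
})
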