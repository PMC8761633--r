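# a record/partition/fold triple with full control over the flanks
planted_hairpin <- function(flank5 = "", flank3 = "",
                            loop_start_seq = NULL) {
  cfg <- cohort_config(n_mirnas = 1, p_ug = 0, p_ugu = 0, p_cnnc = 0,
                       seed = 3)
  coh <- generate_cohort(cfg)
  rec <- as.list(coh$records[1, ])
  f <- fold_mfe(rec$sequence)
  part <- partition_domains(rec, f)
  list(rec = rec, fold = f, part = part)
}

set_base <- function(rec, pos, base) {
  s <- strsplit(rec$sequence, "")[[1]]
  s[pos] <- base
  rec$sequence <- paste(s, collapse = "")
  rec
}

test_that("UG is detected only at the -14/-13 basal window", {
  h <- planted_hairpin()
  pre_start <- h$part$pre_span[1]
  rec <- set_base(h$rec, pre_start - 14L, "U")
  rec <- set_base(rec, pre_start - 13L, "G")
  prof <- scan_motifs(rec, h$part, h$fold)
  expect_true(prof$has_ug)
  expect_identical(prof$pos_ug, pre_start - 14L)
  # one position off does not count
  rec2 <- set_base(h$rec, pre_start - 15L, "U")
  rec2 <- set_base(rec2, pre_start - 14L, "G")
  rec2 <- set_base(rec2, pre_start - 13L, "A")
  expect_false(scan_motifs(rec2, h$part, h$fold)$has_ug)
})

test_that("UGU must start within the first loop-region positions", {
  h <- planted_hairpin()
  ls <- h$part$terminal_loop_region[1]
  rec <- set_base(h$rec, ls:(ls + 3L), c("G", "U", "U", "A"))
  expect_false(scan_motifs(rec, h$part, h$fold)$has_ugu)
  rec <- set_base(h$rec, ls:(ls + 3L), c("U", "G", "U", "A"))
  prof <- scan_motifs(rec, h$part, h$fold)
  expect_true(prof$has_ugu)
  expect_identical(prof$pos_ugu, ls)
})

test_that("CNNC wildcard matching works in the 16-18 nt downstream window", {
  h <- planted_hairpin()
  pre_end <- h$part$pre_span[2]
  rec <- set_base(h$rec, pre_end + 17L + 0:3, c("C", "A", "G", "C"))
  prof <- scan_motifs(rec, h$part, h$fold)
  expect_true(prof$has_cnnc)
  expect_identical(prof$pos_cnnc, pre_end + 17L)
  # a CNNC whose first C is outside the window does not count
  rec2 <- set_base(h$rec, pre_end + 22L + 0:3, c("C", "A", "G", "C"))
  expect_false(scan_motifs(rec2, h$part, h$fold)$has_cnnc)
  expect_identical(scan_motifs(rec2, h$part, h$fold)$motif_count, 0L)
})

test_that("motif flags are invariant to padding outside the windows", {
  h <- planted_hairpin()
  prof <- scan_motifs(h$rec, h$part, h$fold, mghg_demo_table())
  rec2 <- h$rec
  rec2$sequence <- paste0(h$rec$sequence, strrep("A", 25))
  f2 <- fold_mfe(rec2$sequence)
  part2 <- partition_domains(rec2, f2)
  prof2 <- scan_motifs(rec2, part2, f2, mghg_demo_table())
  expect_identical(prof[c("has_ug", "has_ugu", "has_cnnc", "mghg_score")],
                   prof2[c("has_ug", "has_ugu", "has_cnnc", "mghg_score")])
})

test_that("mGHG score is a pure lookup keyed on the basal window", {
  coh <- generate_cohort(cohort_config(n_mirnas = 8, seed = 21))
  tab <- mghg_demo_table()
  prof <- motif_profiles(coh$records, mghg_table = tab)
  joined <- dplyr::inner_join(prof, coh$truth[c("id", "mghg_key")], by = "id")
  expect_identical(prof$mghg_score,
                   tab$score[match(joined$mghg_key, tab$key)])
  # determinism: identical windows, identical scores
  prof2 <- motif_profiles(coh$records, mghg_table = tab)
  expect_identical(prof$mghg_score, prof2$mghg_score)
  # no table -> absent scores but motif flags intact
  prof3 <- motif_profiles(coh$records, mghg_table = NULL)
  expect_true(all(is.na(prof3$mghg_score)))
  expect_identical(prof3$has_ug, prof$has_ug)
  # unknown key -> absent, no nearest-key imputation
  tiny <- tab[1, ]
  tiny$key <- "ZZ/ZZ/ZZ"
  prof4 <- motif_profiles(coh$records, mghg_table = tiny)
  expect_true(all(is.na(prof4$mghg_score)))
})

test_that("mGHG table files round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- mghg_demo_table()[1:20, ]
  readr::write_tsv(tab, path)
  expect_equal(read_mghg_table(path), tab, ignore_attr = TRUE)
  example <- read_mghg_table(
    system.file("extdata", "mghg_table_example.tsv", package = "mirhairpin"))
  # the packaged example uses the demo table's scoring rule
  full <- mghg_demo_table()
  expect_equal(example$score, full$score[match(example$key, full$key)])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_mghg_table(bad), "key")
})

test_that("motif-count strata summarize and test the 0-vs-3 contrast", {
  profiles <- tibble::tibble(
    id = sprintf("m%d", 1:8),
    motif_count = c(0L, 0L, 0L, 1L, 2L, 3L, 3L, 3L))
  meas <- tibble::tibble(id = profiles$id,
                         value = c(1, 2, 3, 10, 20, 30, 31, 32))
  strata <- stratify_by_motif_count(profiles, meas, "value")
  expect_identical(strata$motif_count, 0:3)
  expect_identical(strata$n, c(3L, 1L, 1L, 3L))
  expect_equal(strata$mean[1], 2)
  expect_equal(strata$mean[4], 31)
  expect_identical(length(unique(strata$p_0_vs_3)), 1L)
  expect_equal(strata$p_0_vs_3[1],
               mann_whitney_u(c(1, 2, 3), c(30, 31, 32))$p_value)
  # all records in one stratum: the others report n = 0 and no test
  strata2 <- stratify_by_motif_count(
    dplyr::mutate(profiles, motif_count = 0L), meas, "value")
  expect_identical(strata2$n, c(8L, 0L, 0L, 0L))
  expect_true(all(is.na(strata2$p_0_vs_3)))
})

test_that("a planted additive motif effect produces increasing strata", {
  cfg <- cohort_config(n_mirnas = 120,
                       beta = c(intercept = 0, proximal = 0, loop = 0,
                                duplex = 0, distal = 0, motif = 0.8,
                                mghg = 0),
                       noise_sd = 0.3, seed = 17)
  coh <- generate_cohort(cfg)
  res <- analyze_cohort(coh$records, coh$lanes, mghg_table = mghg_demo_table())
  strata <- res$strata$drosha_efficiency
  populated <- strata[strata$n > 0, ]
  expect_true(all(diff(populated$mean) > 0))
  expect_lt(strata$p_0_vs_3[1], 0.05)
})
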