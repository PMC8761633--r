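#' Configuration for the synthetic hairpin cohort generator
#'
#' The generator builds pri-miRNA hairpins base by base around a planted
#' structure: a continuous stem of `basal` + 22 (duplex) + `upper` base
#' pairs, an apical loop, unpaired flanks of `flank5`/`flank3` nt (the
#' substrate-design lengths), an optional small stem-loop in the 5' distal
#' flank, planted UG/UGU/CNNC motifs at their canonical windows, and a
#' planted basal mGHG window drawn pair by pair. Latent log-odds cleavage
#' efficiency is a linear model in the cohort-standardized true domain free
#' energies, the motif count and the mGHG score, plus Gaussian noise; lane
#' intensities are back-computed so the raw cleavage ratio recovers it
#' exactly, and expression is negative-binomial around a linear coupling to
#' relative efficiency.
#'
#' @param n_mirnas Cohort size.
#' @param duplex_len miRNA arm length (nt).
#' @param upper_range,loop_range,basal_range,distal_stem_range Ranges
#'   (inclusive) for the upper-stem pairs, apical loop size, basal-stem
#'   pairs, and distal stem-loop pairs.
#' @param flank5,flank3 Flank lengths, nt.
#' @param gc_range Range of the per-hairpin GC-pair probability in stems.
#' @param p_ug,p_ugu,p_cnnc Motif planting probabilities.
#' @param beta Named effect sizes on the latent log-odds Drosha efficiency:
#'   `intercept`, `proximal`, `loop`, `duplex`, `distal` (per SD of the true
#'   domain free energy), `motif` (per planted motif), `mghg` (per SD of the
#'   mGHG score).
#' @param dicer_beta Named effects for the Dicer latent: `intercept`,
#'   `loop`.
#' @param noise_sd SD of the Gaussian noise on both latents.
#' @param expr_slope,expr_dispersion Expression coupling: mean reads per
#'   unit relative efficiency, and the negative-binomial dispersion
#'   (`size = 1/dispersion`).
#' @param n_batches Lane batches per enzyme; each gets its own control lane.
#' @param n_families Number of miRNA family labels to distribute (some get
#'   two or more members, making them "conserved").
#' @param seed Integer seed fixing the whole cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_mirnas = 150L, duplex_len = 22L,
                          upper_range = c(2L, 8L), loop_range = c(4L, 10L),
                          basal_range = c(6L, 12L),
                          distal_stem_range = c(0L, 5L),
                          flank5 = 30L, flank3 = 40L,
                          gc_range = c(0.25, 0.85),
                          p_ug = 0.5, p_ugu = 0.5, p_cnnc = 0.5,
                          beta = c(intercept = 0, proximal = -0.5,
                                   loop = 0.5, duplex = -0.3, distal = 0.3,
                                   motif = 0.15, mghg = 0.5),
                          dicer_beta = c(intercept = 0.5, loop = 0.4),
                          noise_sd = 0.5,
                          expr_slope = 20, expr_dispersion = 0.4,
                          n_batches = 1L, n_families = 60L, seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              duplex_len = as.integer(duplex_len),
              upper_range = as.integer(upper_range),
              loop_range = as.integer(loop_range),
              basal_range = as.integer(basal_range),
              distal_stem_range = as.integer(distal_stem_range),
              flank5 = as.integer(flank5), flank3 = as.integer(flank3),
              gc_range = gc_range, p_ug = p_ug, p_ugu = p_ugu,
              p_cnnc = p_cnnc, beta = beta, dicer_beta = dicer_beta,
              noise_sd = noise_sd, expr_slope = expr_slope,
              expr_dispersion = expr_dispersion,
              n_batches = as.integer(n_batches),
              n_families = as.integer(n_families), seed = as.integer(seed))
  stopifnot(cfg$basal_range[1] >= 6L,  # mGHG window must sit in basal pairs
            cfg$flank5 >= 14L, cfg$flank3 >= 21L,
            all(diff(cfg$upper_range) >= 0), all(diff(cfg$loop_range) >= 0))
  structure(cfg, class = "cohort_config")
}

# pair sampler: first char goes on the 5' strand, second on the 3' strand
sample_pair <- function(n, gc) {
  au <- max(1 - gc - 0.1, 0)
  sample(c("GC", "CG", "AU", "UA", "GU", "UG"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, au / 2, au / 2, 0.05, 0.05))
}

# one planted hairpin; returns sequence, dotbracket, coordinates, truth flags
build_hairpin <- function(cfg) {
  rint <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
  e <- rint(cfg$upper_range)
  l <- rint(cfg$loop_range)
  b <- rint(cfg$basal_range)
  ds <- rint(cfg$distal_stem_range)
  # stems under 4 bp are net-destabilizing (loop penalty beats the stacks)
  # and would not survive in the MFE structure, so they are not planted
  if (ds > 0L && ds < 4L) ds <- 0L
  gc <- runif(1, cfg$gc_range[1], cfg$gc_range[2])
  dl <- cfg$duplex_len

  pre_len <- 2L * (dl + e) + l
  pre_start <- cfg$flank5 + 1L
  pre_end <- cfg$flank5 + pre_len
  L <- cfg$flank5 + pre_len + cfg$flank3
  C <- pre_start + pre_end  # helix register: partner(u) = C - u

  # flank filler is A-rich with scattered C so single-stranded regions have
  # little pairing potential against the planted helices
  s <- sample(c("A", "C"), L, replace = TRUE, prob = c(0.82, 0.18))
  db <- rep(".", L)

  # continuous stem: basal + duplex + upper
  stem5 <- (pre_start - b):(pre_start + dl + e - 1L)
  for (u in stem5) {
    p <- sample_pair(1, gc)
    v <- C - u
    s[u] <- substr(p, 1, 1); s[v] <- substr(p, 2, 2)
    db[u] <- "("; db[v] <- ")"
  }

  # planted basal mGHG window: 3' positions pre_end+4..pre_end+6
  mghg_pairs <- sample_pair(3, 0.5)
  for (k in 1:3) {
    v <- pre_end + 3L + k
    u <- C - v
    s[u] <- substr(mghg_pairs[k], 1, 1)
    s[v] <- substr(mghg_pairs[k], 2, 2)
  }
  mghg_key <- paste(mghg_pairs, collapse = "/")

  # distal 5' stem-loop (4-nt apical loop), GC-rich so the fold keeps it
  if (ds > 0) {
    for (k in seq_len(ds)) {
      u <- 1L + k
      v <- 2L + 2L * ds + 4L + 1L - k
      p <- sample(c("GC", "CG"), 1)  # strong pairs so the stem survives MFE
      s[u] <- substr(p, 1, 1); s[v] <- substr(p, 2, 2)
      db[u] <- "("; db[v] <- ")"
    }
    s[(2L + ds + 1L):(2L + ds + 4L)] <- "A"
  }

  # ---- sequence motifs ----
  has_ug <- runif(1) < cfg$p_ug
  p_ug <- pre_start - 14L
  s[p_ug] <- if (has_ug) "U" else "A"
  s[p_ug + 1L] <- if (has_ug) "G" else s[p_ug + 1L]

  has_ugu <- runif(1) < cfg$p_ugu
  ls <- pre_start + dl  # first nt of the terminal loop region
  if (has_ugu) {
    for (k in 0:2) {
      pos <- ls + k
      s[pos] <- c("U", "G", "U")[k + 1]
      if (db[pos] == "(") {
        s[C - pos] <- c("A", "C", "A")[k + 1]
      }
    }
  } else {
    # make sure no accidental UGU sits in the search window
    for (p in ls:(ls + 5L)) {
      if (s[p] == "U" && s[p + 1] == "G" && s[p + 2] == "U") {
        s[p + 1] <- "C"
        if (db[p + 1] == "(") s[C - p - 1L] <- "G"
      }
    }
  }

  has_cnnc <- runif(1) < cfg$p_cnnc
  s[(pre_end + 16L):(pre_end + 21L)] <- "A"
  if (has_cnnc) {
    off <- sample(16:18, 1)
    s[pre_end + off] <- "C"
    s[pre_end + off + 3L] <- "C"
  }

  list(sequence = paste(s, collapse = ""),
       dotbracket = paste(db, collapse = ""),
       mir5p = c(pre_start, pre_start + dl - 1L) |> as.integer(),
       mir3p = c(pre_end - dl + 1L, pre_end) |> as.integer(),
       mghg_key = mghg_key,
       has_ug = has_ug, has_ugu = has_ugu, has_cnnc = has_cnnc,
       upper = e, loop = l, basal = b)
}

#' Generate a synthetic hairpin cohort with planted effects
#'
#' See [cohort_config()] for the generative model. Everything is driven by
#' one seeded generator, so the same config yields byte-identical output.
#'
#' @param config A [cohort_config()].
#' @param model [energy_model()] used for the ground-truth domain energies.
#' @param mghg_table mGHG score table used for the ground-truth scores
#'   (default [mghg_demo_table()]).
#' @return A list of class `mir_cohort`: `records` (hairpin tibble),
#'   `truth` (per-hairpin ground-truth features, latents and raw ratios),
#'   `lanes` (gel lane intensities incl. control lanes), `expression`
#'   (long arm-by-tissue count table), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            model = energy_model(),
                            mghg_table = mghg_demo_table()) {
  withr::with_seed(config$seed, {
    n <- config$n_mirnas
    hp <- vector("list", n)
    for (i in seq_len(n)) hp[[i]] <- build_hairpin(config)
    ids <- sprintf("syn-mir-%04d", seq_len(n))

    fam_pool <- sprintf("fam-%03d", seq_len(config$n_families))
    family <- sample(fam_pool, n, replace = TRUE)

    records <- tibble::new_tibble(list(
      id = ids, species = rep("syn", n),
      sequence = vapply(hp, function(h) h$sequence, character(1)),
      mir5p_start = vapply(hp, function(h) h$mir5p[1], integer(1)),
      mir5p_end = vapply(hp, function(h) h$mir5p[2], integer(1)),
      mir3p_start = vapply(hp, function(h) h$mir3p[1], integer(1)),
      mir3p_end = vapply(hp, function(h) h$mir3p[2], integer(1)),
      family = family, annotated = rep(TRUE, n)
    ), nrow = n)

    # ground-truth features from the planted structure
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      h <- hp[[i]]
      planted <- new_fold_result(
        h$sequence, h$dotbracket,
        evaluate_structure_energy(h$sequence, h$dotbracket, model))
      parts[[i]] <- domain_deltaG(as.list(records[i, ]), planted, model)
    }
    num <- function(f) vapply(parts, f, numeric(1))
    lgl <- function(nm) vapply(hp, function(h) h[[nm]], logical(1))
    truth <- tibble::new_tibble(list(
      id = ids,
      dotbracket = vapply(hp, function(h) h$dotbracket, character(1)),
      dg_pri = num(function(p) p$dg_pri),
      dg_pre = num(function(p) p$dg_pre),
      dg_loop = num(function(p) p$dg_loop),
      dg_duplex = num(function(p) p$dg_duplex),
      dg_proximal = num(function(p) p$dg_proximal),
      dg_distal = num(function(p) p$dg_distal),
      has_ug = lgl("has_ug"), has_ugu = lgl("has_ugu"),
      has_cnnc = lgl("has_cnnc"),
      motif_count = as.integer(lgl("has_ug")) + lgl("has_ugu") +
        lgl("has_cnnc"),
      mghg_key = vapply(hp, function(h) h$mghg_key, character(1)),
      mghg_score = mghg_table$score[
        match(vapply(hp, function(h) h$mghg_key, character(1)),
              mghg_table$key)]
    ), nrow = n)

    zs <- function(x) {
      s <- sd(x)
      if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
    b <- config$beta
    eta <- b[["intercept"]] +
      b[["proximal"]] * zs(truth$dg_proximal) +
      b[["loop"]] * zs(truth$dg_loop) +
      b[["duplex"]] * zs(truth$dg_duplex) +
      b[["distal"]] * zs(truth$dg_distal) +
      b[["motif"]] * truth$motif_count +
      b[["mghg"]] * zs(truth$mghg_score) +
      rnorm(n, 0, config$noise_sd)
    db_ <- config$dicer_beta
    eta_dicer <- db_[["intercept"]] + db_[["loop"]] * zs(truth$dg_loop) +
      rnorm(n, 0, config$noise_sd)
    truth$eta_drosha <- eta
    truth$eta_dicer <- eta_dicer
    truth$raw_ratio_drosha <- stats::plogis(eta)
    truth$raw_ratio_dicer <- stats::plogis(eta_dicer)

    # lanes: intensities back-computed from the latent raw ratio; the first
    # cohort substrate is the designated control for both enzymes
    control_id <- ids[1]
    batch <- rep(seq_len(config$n_batches), length.out = n)
    lane_rows <- function(enzyme, ratio) {
      main <- tibble::tibble(
        substrate_id = ids, enzyme = enzyme, batch = batch,
        total = exp(rnorm(n, 9, 0.3)),
        is_control = ids == control_id
      )
      main$ratio <- ratio
      extra <- main[main$substrate_id == control_id, ][
        rep(1, config$n_batches), ]
      extra$batch <- seq_len(config$n_batches)
      extra$total <- exp(rnorm(config$n_batches, 9, 0.3))
      out <- dplyr::bind_rows(main[main$substrate_id != control_id, ], extra)
      out$product_intensity <- out$ratio * out$total
      out$substrate_intensity <- (1 - out$ratio) * out$total
      out[c("substrate_id", "enzyme", "batch", "product_intensity",
            "substrate_intensity", "is_control")]
    }
    lanes <- dplyr::bind_rows(
      lane_rows("drosha", truth$raw_ratio_drosha),
      lane_rows("dicer", truth$raw_ratio_dicer)
    )

    # expression: NB around coupling x relative Drosha efficiency
    rel <- 100 * truth$raw_ratio_drosha /
      truth$raw_ratio_drosha[match(control_id, ids)]
    mu <- pmax(config$expr_slope * rel, 1)
    total <- rnbinom(n, mu = mu, size = 1 / config$expr_dispersion)
    frac5 <- 0.65
    reads_5p <- rbinom(n, total, frac5)
    reads_3p <- total - reads_5p
    split_t <- function(x) {
      a <- rbinom(length(x), x, 0.5)
      list(a = a, b = x - a)
    }
    s5 <- split_t(reads_5p); s3 <- split_t(reads_3p)
    expression <- dplyr::bind_rows(
      tibble::tibble(mirna_id = ids, arm = "5p",
                     tissue_a = s5$a, tissue_b = s5$b),
      tibble::tibble(mirna_id = ids, arm = "3p",
                     tissue_a = s3$a, tissue_b = s3$b)
    ) |> dplyr::arrange(.data$mirna_id, .data$arm)

    structure(list(records = records, truth = truth, lanes = lanes,
                   expression = expression, config = config),
              class = "mir_cohort")
  })
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat("<mir_cohort>", nrow(x$records), "synthetic pri-miRNAs, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Simulate saturating time-course cleavage assays
#'
#' Each substrate follows first-order saturation `ratio(t) = 1 - exp(-k t)`
#' with per-substrate rates log-spaced across `k_range`, measured at several
#' timepoints with additive Gaussian noise on the ratio. The default rate
#' range keeps the final timepoint inside the assay's dynamic range
#' (largest end-point ratio about 0.88): an end-point assay is informative
#' only when the end point has not saturated, which is how such panels are
#' designed. Used to check that end-point ratios rank substrates the same
#' way as the full time-course area under the curve.
#'
#' @param n_substrates Number of substrates.
#' @param timepoints Assay timepoints, minutes.
#' @param k_range Range of the first-order rate constants (per minute);
#'   the panel's rates are log-spaced across it, emulating a designed set of
#'   substrates with distinct processing efficiencies.
#' @param noise_sd SD of the measurement noise on each ratio.
#' @param seed Integer seed.
#' @return Tibble: `substrate_id`, `timepoint`, `k_true`, `raw_ratio`.
#' @export
simulate_timecourse <- function(n_substrates = 8L,
                                timepoints = c(10, 20, 40, 60),
                                k_range = c(0.002, 0.035), noise_sd = 0.01,
                                seed = 1L) {
  withr::with_seed(seed, {
    k <- exp(seq(log(k_range[1]), log(k_range[2]),
                 length.out = n_substrates))
    ids <- sprintf("sub-%02d", seq_len(n_substrates))
    grid <- tidyr::expand_grid(i = seq_len(n_substrates), t = timepoints)
    grid |>
      dplyr::mutate(
        substrate_id = ids[.data$i], timepoint = .data$t,
        k_true = k[.data$i],
        raw_ratio = pmin(pmax(
          1 - exp(-.data$k_true * .data$t) +
            rnorm(dplyr::n(), 0, noise_sd), 0), 1)
      ) |>
      dplyr::select("substrate_id", "timepoint", "k_true", "raw_ratio")
  })
}
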