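#' Raw cleavage ratio from gel band intensities
#'
#' Intensity of the predicted cleavage products divided by the summed
#' intensity of the products and the remaining full-length substrate.
#'
#' @param product_intensity,substrate_intensity Non-negative band
#'   intensities (vectorized).
#' @return Ratio in `[0, 1]`.
#' @examples
#' raw_cleavage_ratio(3000, 1000)  # 0.75
#' @export
raw_cleavage_ratio <- function(product_intensity, substrate_intensity) {
  if (any(product_intensity < 0 | substrate_intensity < 0)) {
    stop("band intensities must be non-negative")
  }
  tot <- product_intensity + substrate_intensity
  if (any(tot == 0)) stop("empty lane: product and substrate both zero")
  product_intensity / tot
}

#' Relative cleavage efficiency against a control RNA
#'
#' Raw ratio divided by the control RNA's raw ratio, scaled so the control
#' maps to exactly 100.
#'
#' @param raw Raw cleavage ratio(s).
#' @param control_raw Raw cleavage ratio of the control RNA in the same
#'   experiment (must be positive).
#' @return Relative efficiency (control = 100).
#' @examples
#' relative_efficiency(0.3, 0.6)  # 50
#' @export
relative_efficiency <- function(raw, control_raw) {
  if (length(control_raw) != 1 || is.na(control_raw) || control_raw <= 0) {
    stop("unusable control: control raw ratio must be a single positive value")
  }
  100 * raw / control_raw
}

#' Cleavage efficiency table from lane measurements
#'
#' Computes raw ratios per lane, normalizes within each (enzyme, batch) to
#' that batch's control lane, and aggregates replicate lanes per substrate.
#'
#' @param lanes Tibble with columns `substrate_id`, `enzyme`,
#'   `product_intensity`, `substrate_intensity`, logical `is_control`, and
#'   optionally `batch` (default single batch) and `timepoint`.
#' @param aggregate Replicate aggregation for the per-substrate value:
#'   `"mean"` (default) or `"median"`.
#' @return Tibble: `substrate_id`, `enzyme`, `n_lanes`, `raw_ratio` (mean),
#'   `relative_efficiency`.
#' @export
cleavage_efficiencies <- function(lanes, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  if (!"batch" %in% names(lanes)) lanes$batch <- 1L
  lanes <- lanes |>
    dplyr::mutate(raw_ratio = raw_cleavage_ratio(.data$product_intensity,
                                                 .data$substrate_intensity))
  lanes |>
    dplyr::group_by(.data$enzyme, .data$batch) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$raw_ratio[d$is_control]
      if (length(ctrl) < 1) {
        stop("no control lane for enzyme ", key$enzyme,
             " batch ", key$batch)
      }
      d$relative_efficiency <- relative_efficiency(d$raw_ratio, mean(ctrl))
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$substrate_id, .data$enzyme) |>
    dplyr::summarise(
      n_lanes = dplyr::n(),
      raw_ratio = agg(.data$raw_ratio),
      relative_efficiency = agg(.data$relative_efficiency),
      is_control = any(.data$is_control),
      .groups = "drop"
    )
}

#' Spearman rank correlation with tie correction
#'
#' The coefficient is the Pearson correlation of midranks. Pairs with a
#' missing value in either vector are dropped and `n` reflects the drop.
#' For `n <= 9` the two-sided p value is computed by exact enumeration over
#' all permutations of one rank vector; for larger `n` by the
#' t-approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @param feature,response Optional labels carried into the result.
#' @return One-row tibble: `feature`, `response`, `n`, `rho`, `p_value`,
#'   `method`.
#' @export
spearman_test <- function(x, y, feature = NA_character_,
                          response = NA_character_) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    # only the cross-product term varies under permutation of one ranking
    cross <- perms %*% ry  # permuted x-ranks against fixed y-ranks
    obs <- sum(rx * ry)
    mu <- n * mean(rx) * mean(ry)
    denom <- sd(rx) * sd(ry) * (n - 1)
    rho_perm <- (as.numeric(cross) - mu) / denom
    p <- mean(abs(rho_perm) >= abs((obs - mu) / denom) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    p <- max(p, 2.2e-16)
    method <- "t-approximation"
  }
  tibble::tibble(feature = feature, response = response, n = n, rho = rho,
                 p_value = p, method = method)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact enumeration over all group labelings when both groups have at most
#' 8 members (midranks make it valid under ties); otherwise the tie-corrected
#' normal approximation without continuity correction, which keeps the
#' p value exactly symmetric under swapping the groups. Two groups with all
#' values identical give p = 1.
#'
#' @param group_a,group_b Numeric vectors.
#' @return One-row tibble: `n1`, `n2`, `u` (U statistic of `group_a`),
#'   `p_value`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    idx <- combn(n1 + n2, n1)
    usum <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    lo <- min(u, n1 * n2 - u)
    hi <- max(u, n1 * n2 - u)
    p <- mean(usum <= lo + 1e-9 | usum >= hi - 1e-9)
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    v <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble::tibble(n1 = n1, n2 = n2, u = u, p_value = p, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n is kept small by callers
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Correlate structural/motif features with cleavage and expression
#'
#' One Spearman test per (feature, response) pair with pairwise-complete
#' deletion, mirroring a correlation table whose N differs per row. Constant
#' features are flagged and get no coefficient. A Benjamini-Hochberg column
#' is emitted for reference; calls are based on the raw p values. Rank
#' statistics are invariant to monotone transforms, so expression enters
#' untransformed (log-scaling is for plotting only).
#'
#' @param features Tibble with an `id` column and numeric feature columns.
#' @param efficiencies Output of [cleavage_efficiencies()] (long, with
#'   `enzyme`), or `NULL`.
#' @param expression Tibble with `id` (or `mirna_id`) and `total`, or `NULL`.
#' @param feature_cols Feature columns to test; defaults to the domain
#'   free-energy columns plus `mghg_score` when present.
#' @return Tibble: `feature`, `response`, `n`, `rho`, `p_value`, `p_bh`,
#'   `note`.
#' @export
correlation_report <- function(features, efficiencies = NULL,
                               expression = NULL, feature_cols = NULL) {
  feature_cols <- feature_cols %||% intersect(
    c("dg_pri", "dg_pre", "dg_loop", "dg_duplex", "dg_proximal",
      "dg_distal", "mghg_score"),
    names(features)
  )
  responses <- list()
  if (!is.null(efficiencies)) {
    for (enz in unique(efficiencies$enzyme)) {
      d <- efficiencies[efficiencies$enzyme == enz & !efficiencies$is_control, ]
      responses[[paste0(tolower(enz), "_efficiency")]] <-
        setNames(d$relative_efficiency, d$substrate_id)
    }
  }
  if (!is.null(expression)) {
    idc <- if ("id" %in% names(expression)) "id" else "mirna_id"
    responses[["expression"]] <-
      setNames(expression$total, expression[[idc]])
  }
  if (!length(responses)) stop("no responses supplied")

  rows <- list()
  for (fc in feature_cols) {
    for (rn in names(responses)) {
      resp <- responses[[rn]]
      xv <- features[[fc]]
      yv <- unname(resp[features$id])
      keep <- stats::complete.cases(xv, yv)
      if (sum(keep) < 3) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          feature = fc, response = rn, n = sum(keep), rho = NA_real_,
          p_value = NA_real_, note = "fewer than 3 complete pairs")
        next
      }
      if (sd(xv[keep]) == 0 || sd(yv[keep]) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          feature = fc, response = rn, n = sum(keep), rho = NA_real_,
          p_value = NA_real_, note = "constant feature or response")
        next
      }
      st <- spearman_test(xv[keep], yv[keep], feature = fc, response = rn)
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = fc, response = rn, n = st$n, rho = st$rho,
        p_value = st$p_value, note = NA_character_)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out[c("feature", "response", "n", "rho", "p_value", "p_bh", "note")]
}

#' Compare conserved (family >= 2 members) vs unique miRNAs
#'
#' A miRNA is conserved when its family, within the supplied records, has at
#' least two members; all others are unique. Group means/SDs of a response
#' plus the two-sided Mann-Whitney p value. With either group empty the
#' comparison is skipped with a warning.
#'
#' @param records Hairpin record tibble with a `family` column.
#' @param values Tibble with `id` and `value` columns.
#' @return Tibble with rows `conserved` and `unique`: `group`, `n`, `mean`,
#'   `sd`, `p_value` (repeated; NA when skipped).
#' @export
conserved_vs_unique <- function(records, values) {
  fam <- records$family
  sizes <- table(fam[!is.na(fam)])
  conserved_ids <- records$id[!is.na(fam) & fam %in%
                                names(sizes)[sizes >= 2]]
  joined <- dplyr::inner_join(records["id"], values, by = "id")
  joined$group <- ifelse(joined$id %in% conserved_ids, "conserved", "unique")
  summ <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
                     .groups = "drop")
  summ <- dplyr::left_join(
    tibble::tibble(group = c("conserved", "unique")), summ, by = "group") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  if (any(summ$n == 0)) {
    warning("one group is empty; comparison skipped", call. = FALSE)
    summ$p_value <- NA_real_
  } else {
    summ$p_value <- mann_whitney_u(
      joined$value[joined$group == "conserved"],
      joined$value[joined$group == "unique"])$p_value
  }
  summ
}

#' Summarize time-course cleavage measurements
#'
#' Mean and SD of the raw cleavage ratio per substrate and timepoint, with a
#' flag for whether the mean ratio is monotone nondecreasing over time --
#' the sanity check behind using end-point assays in place of full time
#' courses.
#'
#' @param measurements Tibble with `substrate_id`, `timepoint` (minutes) and
#'   `raw_ratio` (or `product_intensity`/`substrate_intensity`, from which
#'   the ratio is computed).
#' @return Tibble: `substrate_id`, `timepoint`, `n`, `mean_ratio`,
#'   `sd_ratio`, `monotone` (per substrate, repeated across its rows).
#' @export
timecourse_summary <- function(measurements) {
  if (!"raw_ratio" %in% names(measurements)) {
    measurements$raw_ratio <- raw_cleavage_ratio(
      measurements$product_intensity, measurements$substrate_intensity)
  }
  measurements |>
    dplyr::group_by(.data$substrate_id, .data$timepoint) |>
    dplyr::summarise(n = dplyr::n(), mean_ratio = mean(.data$raw_ratio),
                     sd_ratio = ifelse(dplyr::n() > 1, sd(.data$raw_ratio), 0),
                     .groups = "drop_last") |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::mutate(monotone = !is.unsorted(.data$mean_ratio)) |>
    dplyr::ungroup()
}
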