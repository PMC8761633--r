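#' Motif search windows
#'
#' Canonical positions of the primary-sequence processing motifs relative to
#' the pre-miRNA ends, all configurable: the basal UG dinucleotide starting
#' 14 nt upstream of the pre-miRNA 5' end; the apical UGU starting within
#' the first `ugu_width` nt of the terminal loop region; CNNC with its first
#' C 16-18 nt downstream of the pre-miRNA 3' end; and the bulged-GHG (mGHG)
#' basal-stem window of three 3'-strand positions centered
#' `mghg_center_offset` nt below the 3' Drosha site.
#'
#' @param ug_offset Offset of the UG start relative to the pre-miRNA 5' end
#'   (negative = upstream).
#' @param ugu_width Number of leading terminal-loop positions searched for
#'   the UGU start.
#' @param cnnc_offsets Offsets downstream of the pre-miRNA 3' end at which
#'   the first C of CNNC may sit.
#' @param mghg_center_offset Center of the 3-nt mGHG window, nt downstream
#'   of the pre-miRNA 3' end.
#' @return A list of window parameters.
#' @export
motif_windows <- function(ug_offset = -14L, ugu_width = 4L,
                          cnnc_offsets = 16:18, mghg_center_offset = 5L) {
  list(ug_offset = as.integer(ug_offset), ugu_width = as.integer(ugu_width),
       cnnc_offsets = as.integer(cnnc_offsets),
       mghg_center_offset = as.integer(mghg_center_offset))
}

#' Scan one hairpin for the UG, UGU and CNNC motifs and the mGHG score
#'
#' Presence/absence flags at the canonical windows (see [motif_windows()]),
#' the motif count (0-3 of UG, UGU, CNNC), and the mGHG score looked up from
#' `mghg_table`. A motif whose window falls outside the available flank is
#' scored absent. The mGHG score is `NA` when no table is supplied, when the
#' basal window is unresolvable (out of bounds or entirely unpaired), or when
#' its key is not in the table -- no imputation is attempted.
#'
#' @inheritParams terminal_loop_region
#' @param partition A `domain_partition` from [partition_domains()].
#' @param mghg_table Tibble with columns `key`, `score` (see
#'   [read_mghg_table()] and [mghg_demo_table()]), or `NULL`.
#' @param windows Window parameters from [motif_windows()].
#' @return One-row tibble: `id`, `has_ug`, `has_ugu`, `has_cnnc`,
#'   `motif_count`, `mghg_score`, and found positions `pos_ug`, `pos_ugu`,
#'   `pos_cnnc` (NA when absent).
#' @export
scan_motifs <- function(record, partition, pri_fold, mghg_table = NULL,
                        windows = motif_windows()) {
  tibble::as_tibble(scan_motifs_list(as.list(record), partition, pri_fold,
                                     mghg_table, windows))
}

scan_motifs_list <- function(rec, partition, pri_fold, mghg_table,
                             windows) {
  s <- strsplit(rec$sequence, "")[[1]]
  n <- length(s)
  pre <- partition$pre_span
  loop <- partition$terminal_loop_region

  # UG at a fixed offset upstream of the pre-miRNA 5' end
  p_ug <- pre[1] + windows$ug_offset
  has_ug <- p_ug >= 1L && p_ug + 1L <= n &&
    s[p_ug] == "U" && s[p_ug + 1L] == "G"

  # UGU starting in the first few nt of the terminal loop region
  p_ugu <- NA_integer_
  if (loop[2] >= loop[1]) {
    starts <- seq2(loop[1], min(loop[1] + windows$ugu_width - 1L,
                                loop[2], n - 2L))
    for (p in starts) {
      if (s[p] == "U" && s[p + 1L] == "G" && s[p + 2L] == "U") {
        p_ugu <- p
        break
      }
    }
  }
  has_ugu <- !is.na(p_ugu)

  # CNNC with its first C in the downstream window
  p_cnnc <- NA_integer_
  for (off in windows$cnnc_offsets) {
    p <- pre[2] + off
    if (p >= 1L && p + 3L <= n && s[p] == "C" && s[p + 3L] == "C") {
      p_cnnc <- p
      break
    }
  }
  has_cnnc <- !is.na(p_cnnc)

  score <- mghg_score(rec, pri_fold, mghg_table, pre_end = pre[2],
                      windows = windows)

  list(
    id = rec$id,
    has_ug = has_ug, has_ugu = has_ugu, has_cnnc = has_cnnc,
    motif_count = as.integer(has_ug + has_ugu + has_cnnc),
    mghg_score = score,
    pos_ug = if (has_ug) p_ug else NA_integer_,
    pos_ugu = p_ugu, pos_cnnc = p_cnnc
  )
}

#' mGHG score of a hairpin's basal-stem window
#'
#' Builds the lookup key from the three 3'-strand positions centered
#' `mghg_center_offset` nt downstream of the pre-miRNA 3' end: each position
#' contributes `"<partner base><base>"` when paired in `pri_fold`, or
#' `"-<base>"` when unpaired, joined with `/`. The score is the table value
#' for that key, unchanged.
#'
#' @inheritParams scan_motifs
#' @param pre_end 3' end of the pre-miRNA (the 3p Drosha site).
#' @return The table score, or `NA` when the window is unresolvable, the
#'   table is `NULL`, or the key is absent from it.
#' @export
mghg_score <- function(record, pri_fold, mghg_table, pre_end,
                       windows = motif_windows()) {
  if (is.null(mghg_table)) return(NA_real_)
  key <- mghg_window_key(record, pri_fold, pre_end, windows)
  if (is.na(key)) return(NA_real_)
  hit <- match(key, mghg_table$key)
  if (is.na(hit)) NA_real_ else mghg_table$score[hit]
}

#' @rdname mghg_score
#' @export
mghg_window_key <- function(record, pri_fold, pre_end,
                            windows = motif_windows()) {
  rec <- as.list(record)
  s <- strsplit(rec$sequence, "")[[1]]
  pt <- pri_fold$pair_table
  center <- pre_end + windows$mghg_center_offset
  pos <- (center - 1L):(center + 1L)
  if (pos[1] < 1L || pos[3] > length(s)) return(NA_character_)
  if (all(pt[pos] == 0L)) return(NA_character_)  # no basal pairs to anchor
  elts <- vapply(pos, function(p) {
    if (pt[p] > 0L) paste0(s[pt[p]], s[p]) else paste0("-", s[p])
  }, character(1))
  paste(elts, collapse = "/")
}

#' Read an mGHG scoring table
#'
#' Tab-delimited file with header columns `key` and `score`. Keys use the
#' window encoding of [mghg_window_key()]. The packaged
#' `extdata/mghg_table_example.tsv` shows the format.
#'
#' @param path TSV path.
#' @return Tibble with columns `key`, `score`.
#' @export
read_mghg_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  if (!all(c("key", "score") %in% names(tab))) {
    stop("mGHG table needs columns 'key' and 'score'")
  }
  if (anyDuplicated(tab$key)) stop("duplicate keys in mGHG table")
  tab[c("key", "score")]
}

#' Synthetic demonstration mGHG table
#'
#' A fully synthetic score table covering every possible basal-window key
#' (all combinations of the six admissible pairs and the four unpaired
#' bases at the three window positions). Scores are a deterministic function
#' of the window composition -- paired positions score higher than unpaired
#' ones, stronger pairs higher than weaker -- so that cohorts planted with
#' varying windows produce a spread of scores. The values are NOT the
#' published mGHG scores; they exist so the lookup-and-correlate machinery
#' can be exercised and tested without external data.
#'
#' @return Tibble with columns `key`, `score`.
#' @export
mghg_demo_table <- function() {
  elements <- c(AU = 0.6, UA = 0.5, CG = 0.9, GC = 1.0, GU = 0.3, UG = 0.2,
                `-A` = 0.05, `-C` = 0.05, `-G` = 0.1, `-U` = 0.05)
  grid <- expand.grid(e1 = names(elements), e2 = names(elements),
                      e3 = names(elements), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    key = paste(grid$e1, grid$e2, grid$e3, sep = "/"),
    score = unname(round((elements[grid$e1] + 2 * elements[grid$e2] +
                            elements[grid$e3]) / 4, 4))
  )
}

#' Motif profiles for a hairpin cohort
#'
#' Tidy front end over [scan_motifs()]: folds each record (or reuses
#' `folds`), partitions it, and scans the motif windows.
#'
#' @inheritParams hairpin_features
#' @param mghg_table Optional mGHG score table.
#' @param windows Window parameters from [motif_windows()].
#' @param folds Optional named list of precomputed [fold_mfe()] results.
#' @return Tibble with one row per hairpin (see [scan_motifs()]).
#' @export
motif_profiles <- function(records, model = energy_model(),
                           mghg_table = NULL, windows = motif_windows(),
                           folds = NULL) {
  rows <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    rec <- as.list(records[r, ])
    if (is.na(rec$mir5p_start) && is.na(rec$mir3p_start)) {
      warning("skipping ", rec$id, ": no arm annotation", call. = FALSE)
      next
    }
    pri_fold <- folds[[rec$id]] %||% fold_mfe(rec$sequence, model)
    part <- partition_domains(rec, pri_fold)
    rows[[r]] <- scan_motifs_list(rec, part, pri_fold, mghg_table, windows)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tibble::new_tibble(list(
    id = vapply(rows, function(x) x$id, character(1)),
    has_ug = vapply(rows, function(x) x$has_ug, logical(1)),
    has_ugu = vapply(rows, function(x) x$has_ugu, logical(1)),
    has_cnnc = vapply(rows, function(x) x$has_cnnc, logical(1)),
    motif_count = vapply(rows, function(x) x$motif_count, integer(1)),
    mghg_score = vapply(rows, function(x) x$mghg_score, numeric(1)),
    pos_ug = vapply(rows, function(x) x$pos_ug, integer(1)),
    pos_ugu = vapply(rows, function(x) x$pos_ugu, integer(1)),
    pos_cnnc = vapply(rows, function(x) x$pos_cnnc, integer(1))
  ), nrow = length(rows))
}

#' Stratify a response by motif count
#'
#' Groups hairpins by how many of the UG, UGU and CNNC motifs they carry
#' (0-3) and summarizes a response value per stratum; strata with no members
#' are reported with `n = 0`. The 0-vs-3 contrast gets a Mann-Whitney p value
#' when both strata are populated.
#'
#' @param profiles Motif profile tibble from [motif_profiles()].
#' @param measurements Tibble with an `id` column and the response column.
#' @param value Name of the response column in `measurements`.
#' @return Tibble: `motif_count`, `n`, `mean`, `sd`, plus the two-sided
#'   Mann-Whitney p value between strata 0 and 3 in the `p_0_vs_3` attribute
#'   column (same value repeated; NA when either stratum is empty).
#' @export
stratify_by_motif_count <- function(profiles, measurements, value) {
  joined <- dplyr::inner_join(profiles, measurements, by = "id")
  vals <- joined[[value]]
  if (is.null(vals)) stop("no column '", value, "' in measurements")
  strata <- dplyr::left_join(
    tibble::tibble(motif_count = 0:3),
    joined |>
      dplyr::group_by(.data$motif_count) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data[[value]]),
                       sd = ifelse(dplyr::n() > 1, sd(.data[[value]]), 0)),
    by = "motif_count"
  ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  g0 <- vals[joined$motif_count == 0]
  g3 <- vals[joined$motif_count == 3]
  strata$p_0_vs_3 <- if (length(g0) && length(g3)) {
    mann_whitney_u(g0, g3)$p_value
  } else {
    NA_real_
  }
  strata
}
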