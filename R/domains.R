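#' Construct a single hairpin record
#'
#' One row of the tabular hairpin-record format used throughout the package:
#' a pri-miRNA sequence with 1-based inclusive mature-arm coordinates.
#'
#' @param id Hairpin identifier (miRBase-style, e.g. `"dre-mir-430a"`).
#' @param sequence Hairpin sequence 5'->3' (DNA input is converted to RNA).
#' @param mir5p,mir3p Length-2 integer vectors `c(start, end)` of the mature
#'   arms on the hairpin, or `NULL` when unannotated (at most one may be
#'   missing for structural analyses).
#' @param species,family Optional metadata.
#' @return A one-row tibble.
#' @examples
#' hairpin_record("toy-mir-1", strrep("ACGU", 20), mir5p = c(5, 26))
#' @export
hairpin_record <- function(id, sequence, mir5p = NULL, mir3p = NULL,
                           species = NA_character_, family = NA_character_) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  chk <- function(span, nm) {
    if (is.null(span)) return(c(NA_integer_, NA_integer_))
    span <- as.integer(span)
    if (length(span) != 2 || anyNA(span) || span[1] > span[2] ||
        span[1] < 1 || span[2] > n) {
      stop(nm, " span out of bounds for ", id)
    }
    span
  }
  s5 <- chk(mir5p, "mir5p")
  s3 <- chk(mir3p, "mir3p")
  if (!anyNA(s5) && !anyNA(s3) && s5[2] >= s3[1]) {
    stop("mir5p span must precede mir3p span for ", id)
  }
  tibble::tibble(
    id = id, species = species, sequence = sequence,
    mir5p_start = s5[1], mir5p_end = s5[2],
    mir3p_start = s3[1], mir3p_end = s3[2],
    family = family
  )
}

#' Terminal loop region of a folded hairpin
#'
#' The terminal loop region starts at the first nucleotide after the 3' end
#' of the (actual or predicted) miR-5p and ends at the nucleotide just inside
#' its corresponding partner on the 3' arm. "Corresponding" is resolved
#' structurally: the partner of the last paired position at or 5'-ward of the
#' miR-5p 3' end (scanning inward when that end itself is unpaired). Both
#' anchor positions are excluded from the region.
#'
#' @param record One hairpin record (see [hairpin_record()]); its `mir5p`
#'   span must be present (use [predict_missing_arm()] first otherwise).
#' @param pri_fold [fold_mfe()] result for the full record sequence.
#' @return Integer `c(start, end)` of the loop region.
#' @export
terminal_loop_region <- function(record, pri_fold) {
  record <- as.list(record)
  k <- record$mir5p_end
  if (is.null(k) || is.na(k)) stop("record has no miR-5p annotation")
  pt <- pri_fold$pair_table
  anchor <- k
  while (anchor >= record$mir5p_start && pt[anchor] == 0L) {
    anchor <- anchor - 1L
  }
  if (anchor < record$mir5p_start) {
    stop("no anchoring pair: miR-5p is entirely unpaired in the fold")
  }
  q <- pt[anchor]
  if (q <= anchor) stop("miR-5p anchor pairs 5'-ward; not a hairpin fold")
  c(k + 1L, q - 1L)
}

#' Predict the unannotated mature arm from the fold
#'
#' When only one arm is annotated, the partner arm is inferred from the pair
#' table: the annotated arm's end positions are mapped to their pairing
#' partners (scanning inward with offset compensation when an end is
#' unpaired) and the resulting span is shifted 2 nt toward the hairpin 5'
#' end when predicting miR-5p, or 2 nt toward the 3' end when predicting
#' miR-3p -- the usual 2-nt 3'-overhang register of a miRNA duplex.
#'
#' @inheritParams terminal_loop_region
#' @return The record with both arm spans filled; with both arms already
#'   annotated the record is returned unchanged.
#' @export
predict_missing_arm <- function(record, pri_fold) {
  rec <- complete_arms(as.list(record), pri_fold)
  tibble::as_tibble(rec[c("id", "species", "sequence", "mir5p_start",
                          "mir5p_end", "mir3p_start", "mir3p_end", "family")])
}

# list-in/list-out core of predict_missing_arm
complete_arms <- function(rec, pri_fold) {
  has5 <- !is.na(rec$mir5p_start)
  has3 <- !is.na(rec$mir3p_start)
  if (has5 && has3) return(rec)
  if (!has5 && !has3) stop("neither arm is annotated for ", rec$id)
  pt <- pri_fold$pair_table
  n <- length(pt)

  # estimated partner of `pos`, scanning inward (by `dir`) over unpaired ends
  est_partner <- function(pos, dir, lo, hi) {
    d <- 0L
    while (pos + dir * d >= lo && pos + dir * d <= hi &&
           pt[pos + dir * d] == 0L) {
      d <- d + 1L
    }
    p <- pos + dir * d
    if (p < lo || p > hi) {
      stop("annotated arm is entirely unpaired for ", rec$id)
    }
    # partner indices run antiparallel, so compensate in the other direction
    pt[p] + dir * d
  }

  if (!has5) {
    s <- rec$mir3p_start; e <- rec$mir3p_end
    span <- sort(c(est_partner(e, -1L, s, e), est_partner(s, +1L, s, e))) - 2L
    rec$mir5p_start <- max(1L, span[1])
    rec$mir5p_end <- min(n, span[2])
  } else {
    s <- rec$mir5p_start; e <- rec$mir5p_end
    span <- sort(c(est_partner(s, +1L, s, e), est_partner(e, -1L, s, e))) + 2L
    rec$mir3p_start <- max(1L, span[1])
    rec$mir3p_end <- min(n, span[2])
  }
  rec
}

#' Partition a pri-miRNA into its named domains
#'
#' The pre-miRNA spans miR-5p start through miR-3p end. The terminal loop
#' region is taken from [terminal_loop_region()]; the miRNA duplex region is
#' the rest of the pre-miRNA. The proximal domain (basal stem) is the 12-nt
#' extension beyond each pre-miRNA end, clipped to the sequence (with a
#' warning when a flank is absent); the distal domain is all remaining
#' flanking sequence. Distal, proximal and pre-miRNA spans tile the molecule.
#'
#' @inheritParams terminal_loop_region
#' @param proximal_width Width in nt of the proximal extension on each side.
#' @return A `domain_partition`: list with `pre_span`, `terminal_loop_region`
#'   (intervals) and `duplex_region`, `proximal_domain`, `distal_domain`
#'   (integer position vectors).
#' @export
partition_domains <- function(record, pri_fold, proximal_width = 12L) {
  rec <- complete_arms(as.list(record), pri_fold)
  n <- nchar(rec$sequence)
  pre <- c(rec$mir5p_start, rec$mir3p_end)
  loop <- terminal_loop_region(rec, pri_fold)
  duplex <- setdiff(pre[1]:pre[2], seq2(loop[1], loop[2]))

  p5 <- seq2(pre[1] - proximal_width, pre[1] - 1L)
  p3 <- seq2(pre[2] + 1L, pre[2] + proximal_width)
  clipped5 <- p5[p5 >= 1L]
  clipped3 <- p3[p3 <= n]
  if (length(clipped5) < length(p5) || length(clipped3) < length(p3) ||
      pre[1] == 1L || pre[2] == n) {
    warning("flank shorter than the proximal extension for ", rec$id,
            "; proximal domain clipped", call. = FALSE)
  }
  proximal <- c(clipped5, clipped3)
  distal <- setdiff(seq_len(n), c(pre[1]:pre[2], proximal))

  structure(
    list(id = rec$id, pre_span = pre, terminal_loop_region = loop,
         duplex_region = duplex, proximal_domain = proximal,
         distal_domain = distal),
    class = "domain_partition"
  )
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition>", x$id %||% "", "\n")
  cat("  pre-miRNA: [", x$pre_span[1], ",", x$pre_span[2], "]",
      "  terminal loop: [", x$terminal_loop_region[1], ",",
      x$terminal_loop_region[2], "]\n")
  cat("  proximal:", length(x$proximal_domain), "nt  distal:",
      length(x$distal_domain), "nt\n")
  if (!is.null(x$dg_pri)) {
    cat(sprintf("  dG (kcal/mol): pri %.2f pre %.2f loop %.2f duplex %.2f proximal %.2f distal %.2f\n",
                x$dg_pri, x$dg_pre, x$dg_loop, x$dg_duplex,
                x$dg_proximal, x$dg_distal))
  }
  invisible(x)
}

#' @rdname partition_domains
#' @param x A `domain_partition`.
#' @param ... Unused.
#' @return For `tidy()`: one row per domain with its span(s), width and,
#'   when filled by [domain_deltaG()], its free energy.
#' @export
tidy.domain_partition <- function(x, ...) {
  spans <- list(
    pre = x$pre_span[1]:x$pre_span[2],
    terminal_loop = seq2(x$terminal_loop_region[1],
                         x$terminal_loop_region[2]),
    duplex = x$duplex_region,
    proximal = x$proximal_domain,
    distal = x$distal_domain
  )
  dg <- c(pre = x$dg_pre, terminal_loop = x$dg_loop, duplex = x$dg_duplex,
          proximal = x$dg_proximal, distal = x$dg_distal)
  tibble::tibble(
    domain = names(spans),
    start = vapply(spans, function(p) if (length(p)) min(p) else NA_integer_,
                   integer(1)),
    end = vapply(spans, function(p) if (length(p)) max(p) else NA_integer_,
                 integer(1)),
    width = lengths(spans),
    delta_g = if (is.null(x$dg_pre)) NA_real_ else unname(dg[names(spans)])
  )
}

#' Attribute free energy to each hairpin domain
#'
#' The terminal-loop, proximal and distal free energies are region-restricted
#' sums over the pri-miRNA fold's loop decomposition. The pre-miRNA free
#' energy comes from folding the pre-miRNA subsequence on its own, and the
#' duplex free energy is the pre-miRNA value minus the terminal-loop value,
#' so `dg_duplex + dg_loop == dg_pre` holds exactly by construction.
#'
#' @inheritParams partition_domains
#' @param model An [energy_model()].
#' @return The `domain_partition` with `dg_loop`, `dg_duplex`, `dg_pre`,
#'   `dg_proximal`, `dg_distal`, `dg_pri` filled in (kcal/mol).
#' @export
domain_deltaG <- function(record, pri_fold, model = energy_model(),
                          proximal_width = 12L) {
  rec <- complete_arms(as.list(record), pri_fold)
  part <- partition_domains(rec, pri_fold, proximal_width)
  dec <- decompose_structure(rec$sequence, pri_fold$dotbracket, model)
  rsum <- function(region) {
    if (!nrow(dec)) return(0)
    sum_kcal(dec$energy[vapply(dec$positions,
                               function(p) all(p %in% region), logical(1))])
  }
  loop_pos <- seq2(part$terminal_loop_region[1], part$terminal_loop_region[2])
  part$dg_loop <- rsum(loop_pos)
  pre_seq <- substr(rec$sequence, part$pre_span[1], part$pre_span[2])
  part$dg_pre <- fold_mfe(pre_seq, model)$delta_g
  part$dg_duplex <- part$dg_pre - part$dg_loop
  part$dg_proximal <- rsum(part$proximal_domain)
  part$dg_distal <- rsum(part$distal_domain)
  part$dg_pri <- pri_fold$delta_g
  part
}

#' Structural feature table for a hairpin cohort
#'
#' Folds every record, partitions it into domains and attributes free energy
#' to each: the tidy front end over [fold_mfe()], [partition_domains()] and
#' [domain_deltaG()].
#'
#' @param records Hairpin record tibble (one row per pri-miRNA; see
#'   [hairpin_record()] and [read_hairpins()]). Records lacking both arm
#'   annotations are skipped with a warning.
#' @param model An [energy_model()].
#' @param proximal_width Proximal-domain extension per side, nt.
#' @param folds Optional named list of precomputed [fold_mfe()] results
#'   (keyed by record id), e.g. to share folds with [motif_profiles()].
#' @return A tibble with one row per hairpin: domain coordinates and the six
#'   free-energy columns `dg_pri`, `dg_pre`, `dg_loop`, `dg_duplex`,
#'   `dg_proximal`, `dg_distal` (kcal/mol).
#' @export
hairpin_features <- function(records, model = energy_model(),
                             proximal_width = 12L, folds = NULL) {
  recs <- as.list(seq_len(nrow(records)))
  parts <- vector("list", nrow(records))
  keep <- logical(nrow(records))
  for (r in seq_len(nrow(records))) {
    rec <- as.list(records[r, ])
    if (is.na(rec$mir5p_start) && is.na(rec$mir3p_start)) {
      warning("skipping ", rec$id, ": no arm annotation", call. = FALSE)
      next
    }
    pri_fold <- folds[[rec$id]] %||% fold_mfe(rec$sequence, model)
    parts[[r]] <- domain_deltaG(rec, pri_fold, model, proximal_width)
    recs[[r]] <- rec
    keep[r] <- TRUE
  }
  parts <- parts[keep]
  recs <- recs[keep]
  num <- function(f) vapply(parts, f, numeric(1))
  int <- function(f) vapply(parts, f, integer(1))
  tibble::new_tibble(list(
    id = vapply(recs, function(x) x$id, character(1)),
    length = vapply(recs, function(x) nchar(x$sequence), integer(1)),
    pre_start = int(function(p) p$pre_span[1]),
    pre_end = int(function(p) p$pre_span[2]),
    loop_start = int(function(p) p$terminal_loop_region[1]),
    loop_end = int(function(p) p$terminal_loop_region[2]),
    dg_pri = num(function(p) p$dg_pri),
    dg_pre = num(function(p) p$dg_pre),
    dg_loop = num(function(p) p$dg_loop),
    dg_duplex = num(function(p) p$dg_duplex),
    dg_proximal = num(function(p) p$dg_proximal),
    dg_distal = num(function(p) p$dg_distal)
  ), nrow = length(parts))
}

# integer sequence that is empty when from > to (seq() would count down)
seq2 <- function(from, to) {
  if (from > to) integer(0) else from:to
}
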