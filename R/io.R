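#' Read an annotated hairpin cohort
#'
#' Assembles pri-miRNA records from a FASTA of hairpin sequences plus an arm
#' annotation: either a flat TSV (`id`, `mir5p_start`, `mir5p_end`,
#' `mir3p_start`, `mir3p_end`, optional `species`, `family`; empty cells for
#' an unannotated arm) or a miRBase-style GFF3 with hairpin-relative, 1-based
#' inclusive `miRNA` features whose `Name` ends in `-5p`/`-3p`. Sequences
#' are normalized to the RNA alphabet (T -> U). Hairpins present in the
#' FASTA but absent from the annotation are kept and flagged
#' (`annotated = FALSE`), never dropped; an annotation row referencing a
#' missing FASTA id is a hard error naming the offenders, as is any
#' coordinate outside its sequence.
#'
#' @param fasta_path FASTA of hairpin sequences (DNA or RNA alphabet).
#' @param annotation_path TSV or GFF3 arm annotation (dialect chosen by file
#'   extension).
#' @return Tibble of hairpin records with an `annotated` flag.
#' @export
read_hairpins <- function(fasta_path, annotation_path) {
  seqs <- read_fasta(fasta_path)
  ann <- if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    read_arm_gff3(annotation_path)
  } else {
    read_arm_tsv(annotation_path)
  }
  missing <- setdiff(ann$id, names(seqs))
  if (length(missing)) {
    stop("annotation references hairpins absent from the FASTA: ",
         paste(missing, collapse = ", "))
  }
  recs <- purrr::map(names(seqs), function(id) {
    row <- ann[ann$id == id, ]
    if (nrow(row) == 0) {
      rec <- hairpin_record(id, seqs[[id]])
      rec$annotated <- FALSE
      return(rec)
    }
    span_or_null <- function(s, e) {
      if (is.na(s) || is.na(e)) NULL else c(s, e)
    }
    col <- function(nm) {
      if (nm %in% names(row)) row[[nm]] else NA_character_
    }
    rec <- hairpin_record(
      id, seqs[[id]],
      mir5p = span_or_null(row$mir5p_start, row$mir5p_end),
      mir3p = span_or_null(row$mir3p_start, row$mir3p_end),
      species = col("species"), family = col("family")
    )
    rec$annotated <- !is.na(rec$mir5p_start) || !is.na(rec$mir3p_start)
    rec
  })
  dplyr::bind_rows(recs)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
  } else {
    ln <- readLines(path)
    hdr <- grep("^>", ln)
    if (!length(hdr)) stop("no FASTA records in ", path)
    ends <- c(hdr[-1] - 1L, length(ln))
    seqs <- setNames(
      vapply(seq_along(hdr), function(i) {
        paste(ln[seq2(hdr[i] + 1L, ends[i])], collapse = "")
      }, character(1)),
      sub("^>", "", ln[hdr])
    )
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA ids in ", path)
  vapply(seqs, normalize_rna, character(1))
}

read_arm_tsv <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("id", "mir5p_start", "mir5p_end", "mir3p_start", "mir3p_end")
  if (!all(need %in% names(ann))) {
    stop("arm annotation TSV must have columns: ",
         paste(need, collapse = ", "))
  }
  ann
}

read_arm_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 annotations requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "miRNA"]
  df <- tibble::tibble(
    id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$Name)) as.character(gr$Name) else
      as.character(gr$ID)
  )
  df |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(d, key) {
      arm <- dplyr::case_when(
        grepl("-5p$", d$name) ~ "5p",
        grepl("-3p$", d$name) ~ "3p",
        TRUE ~ NA_character_
      )
      if (anyNA(arm)) {  # fall back to coordinate order
        arm[order(d$start)] <- c("5p", "3p")[seq_len(nrow(d))]
      }
      tibble::tibble(
        mir5p_start = if ("5p" %in% arm) d$start[arm == "5p"] else NA_integer_,
        mir5p_end = if ("5p" %in% arm) d$end[arm == "5p"] else NA_integer_,
        mir3p_start = if ("3p" %in% arm) d$start[arm == "3p"] else NA_integer_,
        mir3p_end = if ("3p" %in% arm) d$end[arm == "3p"] else NA_integer_
      )
    }) |>
    dplyr::ungroup()
}

#' Write a hairpin cohort as FASTA plus arm-annotation TSV
#'
#' Inverse of [read_hairpins()]; a write/read round trip is lossless for
#' all record fields.
#'
#' @param records Hairpin record tibble.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the annotation path.
#' @export
write_hairpins <- function(records, fasta_path, annotation_path) {
  writeLines(
    as.vector(rbind(paste0(">", records$id), records$sequence)),
    fasta_path
  )
  readr::write_tsv(
    records[c("id", "species", "mir5p_start", "mir5p_end",
              "mir3p_start", "mir3p_end", "family")],
    annotation_path
  )
  invisible(annotation_path)
}

#' Read a small-RNA expression table and aggregate per hairpin
#'
#' The table has one row per mature arm: columns `mirna_id` (parent hairpin
#' id), `arm` (`"5p"`/`"3p"`), and one numeric column per tissue. Tissue
#' columns are combined (sum by default) into a single value per arm, and
#' the expression level of a miRNA is the 5p + 3p sum; an absent arm
#' contributes 0 reads. Totals are invariant to row and tissue-column order.
#'
#' @param tsv_path Path to the tab-delimited table (header required).
#' @param combine How tissue columns are combined: `"sum"` (default) or
#'   `"mean"`.
#' @return Tibble: `id`, `reads_5p`, `reads_3p`, `total`.
#' @export
read_expression_table <- function(tsv_path, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  tab <- readr::read_tsv(tsv_path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("mirna_id", "arm") %in% names(tab))) {
    stop("expression table must have columns 'mirna_id' and 'arm'")
  }
  tissue_cols <- setdiff(names(tab), c("mirna_id", "arm"))
  if (!length(tissue_cols)) stop("expression table has no tissue columns")
  vals <- as.matrix(tab[tissue_cols])
  if (any(vals < 0, na.rm = TRUE)) stop("negative read counts in ", tsv_path)
  tab$reads <- if (combine == "sum") rowSums(vals, na.rm = TRUE) else
    rowMeans(vals, na.rm = TRUE)
  tab |>
    dplyr::group_by(id = .data$mirna_id) |>
    dplyr::summarise(
      reads_5p = sum(.data$reads[.data$arm == "5p"]),
      reads_3p = sum(.data$reads[.data$arm == "3p"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(total = .data$reads_5p + .data$reads_3p)
}

#' Restrict human miRNAs to names numbered below 1000
#'
#' Later-numbered human miRNAs are less likely to be characterized canonical
#' miRNAs, so human records (`hsa-` prefix) with a name/number of 1000 or
#' above are removed. Non-human records pass through unfiltered. Human ids
#' whose numeric component cannot be parsed are excluded with a warning.
#'
#' @param records Hairpin record tibble (ids in miRBase style, e.g.
#'   `hsa-mir-155`, `dme-mir-2492`).
#' @param max_number Exclusive upper bound for the human name number.
#' @return The filtered record tibble.
#' @export
filter_human_mirna_number <- function(records, max_number = 1000L) {
  is_human <- grepl("^hsa-", records$id, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(
    sub("^hsa-(mir|mirn|let|lin)-?([0-9]+).*$", "\\2", records$id,
        ignore.case = TRUE)
  ))
  unparsable <- is_human & is.na(num)
  if (any(unparsable)) {
    warning("excluding human ids with unparsable numbers: ",
            paste(records$id[unparsable], collapse = ", "), call. = FALSE)
  }
  keep <- !is_human | (!is.na(num) & num < max_number)
  records[keep, , drop = FALSE]
}
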